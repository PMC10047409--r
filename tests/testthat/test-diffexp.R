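make_counts <- function(mat, stages, reps = NULL) {
  if (is.null(reps)) reps <- ave(seq_along(stages), stages, FUN = seq_along)
  colnames(mat) <- paste(stages, reps, sep = "-")
  rownames(mat) <- sprintf("f%04d", seq_len(nrow(mat)))
  mat
}

test_that("TMM factors: symmetry, geometric mean, depth correction", {
  set.seed(1)
  y <- matrix(rnbinom(500 * 4, mu = 100, size = 10), 500, 4)
  same <- make_counts(cbind(y[, 1], y[, 1], y[, 1]), rep("A", 3))
  expect_equal(unname(tmm_factors(same)), rep(1, 3), ignore_attr = TRUE)

  # one library is another times 3 with no composition change
  two <- make_counts(cbind(y[, 1], y[, 1] * 3L), c("A", "B"), c(1, 1))
  f <- tmm_factors(two)
  cpm <- sweep(two, 2, colSums(two) * f, "/") * 1e6
  expect_equal(cpm[, 1], cpm[, 2], tolerance = 1e-9)

  f2 <- tmm_factors(make_counts(y, c("A", "A", "B", "B")))
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-9)
  y0 <- y; y0[, 2] <- 0L
  expect_error(tmm_factors(make_counts(y0, c("A", "A", "B", "B"))),
               "all-zero")
})

test_that("TMM factors agree with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(2)
  mu <- rlnorm(800, log(80), 1.2)
  y <- matrix(rnbinom(800 * 6, mu = rep(mu, 6), size = 8), 800, 6)
  y[, 3] <- y[, 3] * 2L  # depth difference
  y <- make_counts(y, rep(c("A", "B"), each = 3))
  f_pkg <- tmm_factors(y)
  f_ref <- edgeR::calcNormFactors(y, method = "TMM")
  f_ref <- f_ref / exp(mean(log(f_ref)))
  expect_equal(unname(f_pkg), unname(f_ref), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("exact NB test: exchangeability and antisymmetry", {
  set.seed(3)
  base <- rnbinom(300, mu = 50, size = 10)
  y <- make_counts(matrix(rep(base, 6), ncol = 6),
                   rep(c("A", "B"), each = 3))
  res <- exact_nb_test(y, stage_a = "A", stage_b = "B")
  expect_equal(res$pvalue, rep(1, nrow(y)), tolerance = 1e-9)
  expect_true(all(res$logFC == 0))

  set.seed(4)
  y2 <- make_counts(matrix(rnbinom(300 * 6, mu = 60, size = 5), ncol = 6),
                    rep(c("A", "B"), each = 3))
  ab <- exact_nb_test(y2, stage_a = "A", stage_b = "B")
  ba <- exact_nb_test(y2, stage_a = "B", stage_b = "A")
  expect_equal(ab$pvalue, ba$pvalue, tolerance = 1e-12)
  expect_equal(ab$logFC, -ba$logFC, tolerance = 1e-12)
  expect_error(exact_nb_test(y2, stage_a = "A", stage_b = "Z"), "absent")
})

test_that("Poisson-limit p-values match the exact binomial split test", {
  set.seed(5)
  y <- make_counts(matrix(rpois(2000 * 6, lambda = 40), ncol = 6),
                   rep(c("A", "B"), each = 3))
  # factors that equalize effective library sizes, so the quantile
  # adjustment is the identity and raw pooled counts are the test input
  f <- 1 / colSums(y)
  f <- setNames(f / exp(mean(log(f))), colnames(y))
  res0 <- exact_nb_test(y, stage_a = "A", stage_b = "B", factors = f,
                        dispersion = 0)
  ya <- rowSums(y[, 1:3]); t <- rowSums(y)
  want <- vapply(seq_len(nrow(y)), function(i)
    oracle_binom_split(ya[i], t[i], 3, 3), numeric(1))
  expect_equal(res0$pvalue, want, tolerance = 1e-12)
  # a small nonzero dispersion converges to the same limit through the
  # full negative-binomial branch
  res_eps <- exact_nb_test(y, stage_a = "A", stage_b = "B", factors = f,
                           dispersion = 1e-5)
  expect_lt(max(abs(res_eps$pvalue - want)), 1e-3)
})

test_that("detection power increases with planted effect size", {
  set.seed(6)
  n <- 2000
  de_idx <- seq_len(n / 10)  # 10% of features carry the effect
  power_at <- function(lfc) {
    muA <- rep(80, n)
    muB <- muA
    muB[de_idx] <- muA[de_idx] * 2^lfc
    y <- cbind(matrix(rnbinom(n * 3, mu = rep(muA, 3), size = 10), n, 3),
               matrix(rnbinom(n * 3, mu = rep(muB, 3), size = 10), n, 3))
    y <- make_counts(y, rep(c("A", "B"), each = 3))
    de <- call_de(exact_nb_test(y, stage_a = "A", stage_b = "B"))
    mean(de$significant[de_idx])
  }
  p <- vapply(c(0.5, 1, 2), power_at, numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_gt(p[3], 0.9)
})

test_that("DE calling is inclusive at both thresholds", {
  res <- data.frame(feature = c("a", "b", "c", "d"),
                    comparison = "A.vs.B",
                    logFC = c(1.2, 0.5, 1.0, -1.3),
                    pvalue = c(0.04, 0.04, 0.05, 0.02),
                    fdr = NA_real_)
  out <- call_de(res)
  expect_equal(out$significant, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$direction, c("up", "none", "up", "down"))
})

test_that("profile classification follows the thresholded sign patterns", {
  mk <- function(m) {
    y <- matrix(rep(m * 100L, each = 2), nrow = 1, byrow = TRUE)
    make_counts(balance_columns(y), rep(c("S1", "S2", "S3"), each = 2))
  }
  cases <- list(list(c(10L, 20L, 40L), "incremental"),
                list(c(40L, 20L, 10L), "decreasing"),
                list(c(40L, 10L, 40L), "high_low_high"),
                list(c(10L, 40L, 10L), "low_high_low"),
                list(c(10L, 10L, 10L), "irregular"),
                # one weak step does not break a monotone trend
                list(c(10L, 20L, 21L), "incremental"),
                list(c(40L, 20L, 19L), "decreasing"))
  for (cs in cases) {
    y <- mk(cs[[1]])
    got <- classify_profiles(y)
    expect_equal(got$category[1], cs[[2]],
                 label = paste(cs[[1]], collapse = ","))
  }
  expect_error(classify_profiles(mk(c(1L, 2L, 3L))[, 1:4, drop = FALSE]),
               "3 stages")
})

test_that("classifier recovers planted shapes exactly on noise-free means", {
  cfg <- small_config(seed = 51L)
  ex <- build_reference(cfg)
  lab <- ex$truth$de_labels
  lab <- lab[lab$kind == "miRNA", ]
  mu <- vapply(seq_len(nrow(lab)), function(i)
    100 * 2^oracle_offsets(lab$shape[i], cfg$effect_size), numeric(3))
  y <- t(mu)[, rep(1:3, each = 3)]
  y <- balance_columns(matrix(as.integer(round(y)), nrow(lab), 9))
  y <- make_counts(y, rep(c("S1", "S2", "S3"), each = 3))
  got <- classify_profiles(y, factors = setNames(rep(1, 9), colnames(y)))
  expect_equal(got$category[seq_len(nrow(lab))], lab$shape)
})

test_that("Venn partition equals exhaustive set algebra", {
  v <- venn_overlap(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
                         C = c("c", "e")))
  expect_equal(v$core, "c")
  expect_equal(v$regions$A, "a")
  expect_equal(v$regions$`A&B`, "b")
  expect_equal(v$regions$`B&C`, character(0))
  expect_equal(v$regions$C, "e")
  expect_equal(sort(unlist(v$regions)), sort(unique(c("a", "b", "c", "d", "e"))),
               ignore_attr = TRUE)

  expect_equal(venn_overlap(list(A = "x", B = "y", C = "z"))$core,
               character(0))

  set.seed(8)
  ids <- sprintf("id%03d", 1:150)
  sets <- list(A = sample(ids, 100), B = sample(ids, 100),
               C = sample(ids, 100))
  v2 <- venn_overlap(sets)
  for (id in ids) {
    inA <- id %in% sets$A; inB <- id %in% sets$B; inC <- id %in% sets$C
    if (!(inA || inB || inC)) next
    key <- paste(c("A", "B", "C")[c(inA, inB, inC)], collapse = "&")
    expect_true(id %in% v2$regions[[key]], label = id)
  }
  sizes <- vapply(v2$regions, length, integer(1))
  expect_equal(sum(sizes), length(unique(unlist(sets))))
  expect_lte(length(v2$core), min(lengths(sets)))
})

test_that("sequence-duplicate merging collapses ids as in a 16-to-14 case", {
  set.seed(9)
  ids <- sprintf("mir%02d", 1:16)
  seqs <- setNames(vapply(rep(22, 16), rand_rna, character(1)), ids)
  seqs["mir09"] <- seqs["mir02"]   # two duplicate pairs
  seqs["mir14"] <- seqs["mir05"]
  m <- merge_duplicate_matures(ids, seqs)
  expect_length(m$ids, 14L)
  expect_equal(m$aliases$mir02, "mir09")
  expect_equal(m$aliases$mir05, "mir14")

  all_diff <- merge_duplicate_matures(ids[1:5], seqs[1:5])
  expect_setequal(all_diff$ids, ids[1:5])
  expect_length(all_diff$aliases, 0L)

  three <- merge_duplicate_matures(
    c("z", "a", "m"), setNames(rep("ACGU", 3), c("z", "a", "m")))
  expect_equal(three$ids, "a")
  expect_setequal(three$aliases$a, c("m", "z"))
  expect_error(merge_duplicate_matures(c("a", "q"), c(a = "ACGU")), "q")
})
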