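#' Trimmed-mean-of-M-values library normalization factors
#'
#' Computes per-sample scale factors by a doubly trimmed, precision-weighted
#' mean of per-feature log2 expression ratios against a reference sample
#' (the sample whose upper-quartile of library-scaled counts is closest to
#' the mean upper quartile; ties broken by sample id). Features zero in
#' either member of a pair are excluded pairwise. Factors are rescaled to
#' geometric mean 1.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param logratio_trim fraction of extreme log-ratios trimmed from each
#'   tail (default 0.3).
#' @param abs_trim fraction of extreme average-expression values trimmed
#'   from each tail (default 0.05).
#' @return named numeric vector of factors with attribute `reference`.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  f75 <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
  cand <- which(abs(f75 - mean(f75)) == min(abs(f75 - mean(f75))))
  ref <- cand[order(colnames(counts)[cand])][1]
  yr <- counts[, ref]; nr <- lib[ref]

  one_factor <- function(j) {
    if (j == ref) return(1)
    y <- counts[, j]; n <- lib[j]
    ok <- y > 0 & yr > 0
    if (!any(ok)) return(1)
    m <- log2((y[ok] / n) / (yr[ok] / nr))
    a <- 0.5 * log2((y[ok] / n) * (yr[ok] / nr))
    w <- (n - y[ok]) / (n * y[ok]) + (nr - yr[ok]) / (nr * yr[ok])
    if (max(abs(m)) < 1e-6) return(1)
    nn <- length(m)
    lo_m <- floor(nn * logratio_trim) + 1; hi_m <- nn + 1 - lo_m
    lo_a <- floor(nn * abs_trim) + 1; hi_a <- nn + 1 - lo_a
    keep <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    if (!any(keep) || sum(1 / w[keep]) == 0) return(1)
    # w is the asymptotic variance of each M; weight by its inverse
    2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(setNames(f, colnames(counts)), reference = colnames(counts)[ref])
}

# deterministic mid-quantile map of NB counts from library size lj to l0
.q2q_nb <- function(y, lambda, lj, l0, phi) {
  if (abs(lj - l0) < 1e-9 * l0) return(y)
  mu_j <- lambda * lj; mu_0 <- lambda * l0
  if (phi <= 1e-6) {
    p <- stats::ppois(y - 1, mu_j) + 0.5 * stats::dpois(y, mu_j)
    stats::qpois(pmin(pmax(p, 1e-12), 1 - 1e-12), mu_0)
  } else {
    sz <- 1 / phi
    p <- stats::pnbinom(y - 1, mu = mu_j, size = sz) +
      0.5 * dnbinom(y, mu = mu_j, size = sz)
    stats::qnbinom(pmin(pmax(p, 1e-12), 1 - 1e-12), mu = mu_0, size = sz)
  }
}

# moment estimator of the common NB dispersion on equal-library counts:
# phi = sum(v - m) / sum(m^2 - v/n), pooled over features and groups
.common_dispersion <- function(adj, group) {
  num <- 0; den <- 0
  for (g in unique(group)) {
    yg <- adj[, group == g, drop = FALSE]
    n <- ncol(yg)
    m <- rowMeans(yg)
    v <- apply(yg, 1, stats::var)
    num <- num + sum(v - m)
    den <- den + sum(pmax(m^2 - v / n, 0))
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

# two-sided exact conditional p for the split of pooled count t between
# groups of sizes na, nb under a common NB with dispersion phi: sums the
# probabilities of all splits at most as likely as the observed one
.exact_split_p <- function(ya, t, na, nb, phi) {
  if (t == 0) return(1)
  y <- 0:t
  # below ~1e-6 the NB log-gamma terms lose the precision needed for the
  # tail comparison; the Poisson-limit binomial split is exact there
  if (phi <= 1e-6) {
    logf <- stats::dbinom(y, t, na / (na + nb), log = TRUE)
  } else {
    ra <- na / phi; rb <- nb / phi
    logf <- lgamma(y + ra) - lgamma(y + 1) + lgamma(t - y + rb) -
      lgamma(t - y + 1)
  }
  f <- exp(logf - max(logf))
  f <- f / sum(f)
  min(1, sum(f[f <= f[ya + 1] * (1 + 1e-7)]))
}

#' Exact conditional negative-binomial test between two stages
#'
#' Re-implements the classic exact-test core for small replicated count
#' data: counts are quantile-adjusted (deterministic mid-quantile map) to
#' the geometric-mean effective library size, a single common dispersion
#' is estimated across features by a moment estimator (unless supplied),
#' and each feature's pooled count is tested with a two-sided exact
#' conditional test on its split between the two groups. The log2 fold
#' change is computed from adjusted group means with a 0.5 pseudo-count,
#' oriented as `stage_b` over `stage_a`.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param stages character vector of stage labels per column (defaults to
#'   parsing column names with [sample_stages()]).
#' @param stage_a,stage_b the two stages to compare (each needs >= 2
#'   replicates).
#' @param factors normalization factors from [tmm_factors()]; computed
#'   from `counts` when NULL.
#' @param dispersion common NB dispersion; estimated when NULL. Use 0 for
#'   the Poisson limit (binomial split test).
#' @return data.frame with columns `feature`, `comparison`, `logFC`,
#'   `pvalue`, `fdr` (Benjamini-Hochberg, informational only), and the
#'   estimated `dispersion` as an attribute.
#' @export
exact_nb_test <- function(counts, stages = NULL, stage_a, stage_b,
                          factors = NULL, dispersion = NULL) {
  if (is.null(stages)) stages <- sample_stages(colnames(counts))
  stopifnot(length(stages) == ncol(counts))
  for (s in c(stage_a, stage_b)) {
    if (!s %in% stages) stop("stage absent from metadata: ", s)
    if (sum(stages == s) < 2L) stop("stage ", s, " has < 2 replicates")
  }
  if (is.null(factors)) factors <- tmm_factors(counts)
  sel <- stages %in% c(stage_a, stage_b)
  y <- counts[, sel, drop = FALSE]
  grp <- stages[sel]
  eff <- colSums(counts)[sel] * factors[sel]
  l0 <- exp(mean(log(eff)))

  lambda <- rowSums(y) / sum(eff)
  # first-pass equal-library counts for dispersion estimation
  adj0 <- round(sweep(y, 2, l0 / eff, "*"))
  phi <- if (is.null(dispersion)) .common_dispersion(adj0, grp) else
    dispersion
  adj <- y
  for (j in seq_len(ncol(y)))
    adj[, j] <- .q2q_nb(y[, j], lambda, eff[j], l0, phi)

  a_cols <- grp == stage_a
  na <- sum(a_cols); nb <- sum(!a_cols)
  ya <- rowSums(adj[, a_cols, drop = FALSE])
  yb <- rowSums(adj[, !a_cols, drop = FALSE])
  pv <- vapply(seq_len(nrow(y)), function(i)
    .exact_split_p(ya[i], ya[i] + yb[i], na, nb, phi), numeric(1))
  lfc <- log2((yb / nb + 0.5) / (ya / na + 0.5))
  out <- data.frame(feature = rownames(counts),
                    comparison = paste(stage_a, "vs", stage_b, sep = "."),
                    logFC = lfc, pvalue = pv,
                    fdr = stats::p.adjust(pv, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- phi
  out
}

#' Call differential expression at fixed screening thresholds
#'
#' Applies the inclusive screen `pvalue <= p_thresh` and
#' `|logFC| >= lfc_thresh` (boundary values are significant) and assigns
#' the direction of change from the sign of the log fold change.
#'
#' @param results data.frame from [exact_nb_test()].
#' @param p_thresh raw p-value threshold (default 0.05).
#' @param lfc_thresh absolute log2 fold-change threshold (default 1).
#' @return the input with added logical `significant` and `direction` in
#'   `{"up", "down", "none"}`.
#' @export
call_de <- function(results, p_thresh = 0.05, lfc_thresh = 1) {
  stopifnot(p_thresh > 0, lfc_thresh > 0)
  sig <- results$pvalue <= p_thresh & abs(results$logFC) >= lfc_thresh
  results$significant <- sig
  results$direction <- ifelse(!sig, "none",
                              ifelse(results$logFC > 0, "up", "down"))
  results
}

#' Classify temporal expression profiles over three stages
#'
#' Computes normalized stage means m1, m2, m3 and the consecutive log
#' ratios d1 = log2(m2/m1), d2 = log2(m3/m2) (0.5 pseudo-count), then
#' thresholds each step's sign at `tau`: `+` when d >= tau, `-` when
#' d <= -tau, `0` otherwise. The sign pattern maps to a category:
#' `(+,+)`, `(+,0)`, `(0,+)` are `incremental`; `(-,-)`, `(-,0)`, `(0,-)`
#' are `decreasing` (one weak step does not break a monotone trend);
#' `(-,+)` is `high_low_high` and `(+,-)` is `low_high_low` (a reversal
#' must be strong on both sides); `(0,0)` is `irregular`.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param stages stage labels per column (defaults to parsing column
#'   names); exactly 3 distinct stages required.
#' @param factors normalization factors; computed when NULL.
#' @param tau minimal absolute log2 change per step (default log2(1.5)).
#' @param stage_order order of the stages; defaults to order of first
#'   appearance.
#' @return data.frame with `feature`, `d1`, `d2`, `category`.
#' @export
classify_profiles <- function(counts, stages = NULL, factors = NULL,
                              tau = log2(1.5), stage_order = NULL) {
  if (is.null(stages)) stages <- sample_stages(colnames(counts))
  if (is.null(stage_order)) stage_order <- unique(stages)
  if (length(stage_order) != 3L)
    stop("profile classification requires exactly 3 stages, got ",
         length(stage_order))
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- colSums(counts) * factors
  norm <- sweep(counts, 2, exp(mean(log(eff))) / eff, "*")
  m <- vapply(stage_order, function(s)
    rowMeans(norm[, stages == s, drop = FALSE]), numeric(nrow(counts)))
  d1 <- log2((m[, 2] + 0.5) / (m[, 1] + 0.5))
  d2 <- log2((m[, 3] + 0.5) / (m[, 2] + 0.5))
  s1 <- ifelse(d1 >= tau, 1L, ifelse(d1 <= -tau, -1L, 0L))
  s2 <- ifelse(d2 >= tau, 1L, ifelse(d2 <= -tau, -1L, 0L))
  pat <- rep("irregular", length(d1))
  pat[(s1 > 0 & s2 >= 0) | (s1 >= 0 & s2 > 0)] <- "incremental"
  pat[(s1 < 0 & s2 <= 0) | (s1 <= 0 & s2 < 0)] <- "decreasing"
  pat[s1 < 0 & s2 > 0] <- "high_low_high"
  pat[s1 > 0 & s2 < 0] <- "low_high_low"
  data.frame(feature = rownames(counts), d1 = d1, d2 = d2, category = pat,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Three-way Venn partition of DE feature sets
#'
#' @param sets named list of exactly three character vectors sharing an id
#'   space.
#' @return list with `membership` (data.frame: feature + one logical
#'   column per set), `regions` (named list of the 7 exclusive regions)
#'   and `core` (the three-way intersection).
#' @export
venn_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) == 3L, !is.null(names(sets)))
  ids <- sort(unique(unlist(sets)))
  mem <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) mem <- matrix(mem, nrow = 1,
                                       dimnames = list(NULL, names(sets)))
  membership <- data.frame(feature = ids, mem, check.names = FALSE,
                           stringsAsFactors = FALSE)
  nm <- names(sets)
  key <- apply(mem, 1, function(r) paste(nm[r], collapse = "&"))
  all_keys <- c(nm, paste(nm[1], nm[2], sep = "&"),
                paste(nm[1], nm[3], sep = "&"),
                paste(nm[2], nm[3], sep = "&"),
                paste(nm, collapse = "&"))
  regions <- lapply(setNames(all_keys, all_keys), function(k)
    ids[key == k])
  list(membership = membership, regions = regions,
       core = regions[[paste(nm, collapse = "&")]])
}

#' Merge features with identical mature sequences
#'
#' Database-derived miRNA lists may carry the same mature sequence under
#' several names (e.g. orthologous annotations); such ids are merged under
#' the lexicographically first name.
#'
#' @param ids character vector of feature ids.
#' @param sequences named character vector giving each id's mature
#'   sequence.
#' @return list with `ids` (merged representative ids, input order of
#'   first occurrence) and `aliases` (named list: representative ->
#'   absorbed ids).
#' @export
merge_duplicate_matures <- function(ids, sequences) {
  missing <- setdiff(ids, names(sequences))
  if (length(missing))
    stop("missing sequence for id(s): ", paste(missing, collapse = ", "))
  seqs <- toupper(sequences[ids])
  reps <- vapply(split(ids, seqs), function(g) sort(g)[1], character(1))
  rep_of <- setNames(reps[seqs], ids)
  merged <- unique(unname(rep_of))
  aliases <- lapply(split(ids, unname(rep_of)), function(g)
    setdiff(sort(g), sort(g)[1]))
  aliases <- aliases[vapply(aliases, length, integer(1)) > 0]
  list(ids = merged, aliases = aliases)
}
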