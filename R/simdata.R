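#' Simulation configuration for a staged small-RNA ceRNA experiment
#'
#' Bundles every tunable of the synthetic-data generator: the sampling
#' design (stages x replicates), feature counts per RNA class, the planted
#' differential-expression structure (fraction DE, temporal profile mix,
#' effect size), negative-binomial dispersion, library sizes, read-level
#' noise rates, and the sponge-coupling strength.
#'
#' Planted temporal profiles are defined on stage means as log2 offsets
#' relative to stage 1. Monotone shapes (`incremental`, `decreasing`)
#' spread `effect_size` across the full stage range (per-step change
#' `effect_size / (n_stages - 1)`), so the last-vs-first log2 fold change
#' equals `effect_size`. V-shapes (`high_low_high`, `low_high_low`) use a
#' per-step change of `effect_size`. Targets of a planted miRNA get stage
#' means `baseline * (1 - repression_strength)^(miRNA log2 elevation over
#' its stage-1 mean)`: mean-shift repression proportional to the miRNA's
#' elevation, and symmetrically de-repression when the miRNA falls.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_stages number of developmental stages (fixed design: 3).
#' @param n_replicates replicates per stage.
#' @param stage_names stage labels used in sample ids (`stage-replicate`).
#' @param n_mirna,n_lncrna,n_mrna feature counts per RNA class.
#' @param n_triplets number of planted lncRNA-miRNA-mRNA sponge triplets.
#' @param frac_de fraction of miRNAs planted as differentially expressed
#'   (at least `n_triplets` miRNAs are always planted).
#' @param profile_mix named weights over the four non-flat profile shapes
#'   (`incremental`, `decreasing`, `high_low_high`, `low_high_low`);
#'   irregular profiles are simulated as flat, i.e. non-DE.
#' @param effect_size log2 fold-change magnitude of planted DE (see above).
#' @param nb_dispersion common negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param repression_strength fraction in `[0, 1)` by which a target's mean
#'   drops per log2 unit of miRNA elevation.
#' @param lib_size_range integer pair: range of per-sample miRNA library
#'   sizes (column sums, in reads).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of
#'   per-feature baseline mean counts.
#' @param mirna_len_range mature miRNA length range (nt).
#' @param lnc_len,utr_len lncRNA / mRNA 3'UTR fragment lengths (nt).
#' @param n_contaminant,contaminant_len contaminant decoy reference count
#'   and length (emulating rRNA/tRNA-style filter databases).
#' @param sites_per_target integer pair: range of planted sites per
#'   (miRNA, transcript) pair.
#' @param adapter 3' sequencing adapter (DNA, at least 6 nt).
#' @param read_length single-end read length.
#' @param contaminant_frac,lowqual_frac,n_base_frac,short_frac noise read
#'   rates as fractions of the raw read total.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [build_reference()], [simulate_counts()], [simulate_reads()]
#' @export
sim_config <- function(seed = 1L,
                       n_stages = 3L,
                       n_replicates = 3L,
                       stage_names = c("D85", "D105", "D135"),
                       n_mirna = 200L,
                       n_lncrna = 300L,
                       n_mrna = 2000L,
                       n_triplets = 50L,
                       frac_de = 0.25,
                       profile_mix = c(incremental = 107, decreasing = 151,
                                       high_low_high = 91, low_high_low = 45),
                       effect_size = 2,
                       nb_dispersion = 0.1,
                       repression_strength = 0.5,
                       lib_size_range = c(20000L, 30000L),
                       baseline_meanlog = log(50),
                       baseline_sdlog = 1,
                       mirna_len_range = c(20L, 23L),
                       lnc_len = 300L,
                       utr_len = 300L,
                       n_contaminant = 20L,
                       contaminant_len = 200L,
                       sites_per_target = c(1L, 3L),
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 50L,
                       contaminant_frac = 0.05,
                       lowqual_frac = 0.02,
                       n_base_frac = 0.01,
                       short_frac = 0.02) {
  cfg <- list(seed = as.integer(seed), n_stages = as.integer(n_stages),
              n_replicates = as.integer(n_replicates),
              stage_names = stage_names, n_mirna = as.integer(n_mirna),
              n_lncrna = as.integer(n_lncrna), n_mrna = as.integer(n_mrna),
              n_triplets = as.integer(n_triplets), frac_de = frac_de,
              profile_mix = profile_mix / sum(profile_mix),
              effect_size = effect_size, nb_dispersion = nb_dispersion,
              repression_strength = repression_strength,
              lib_size_range = as.integer(lib_size_range),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              mirna_len_range = as.integer(mirna_len_range),
              lnc_len = as.integer(lnc_len), utr_len = as.integer(utr_len),
              n_contaminant = as.integer(n_contaminant),
              contaminant_len = as.integer(contaminant_len),
              sites_per_target = as.integer(sites_per_target),
              adapter = toupper(adapter),
              read_length = as.integer(read_length),
              contaminant_frac = contaminant_frac,
              lowqual_frac = lowqual_frac, n_base_frac = n_base_frac,
              short_frac = short_frac)
  fracs <- c(cfg$frac_de, cfg$contaminant_frac, cfg$lowqual_frac,
             cfg$n_base_frac, cfg$short_frac)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (cfg$n_stages < 2L) stop("n_stages must be >= 2")
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (cfg$repression_strength >= 1 || cfg$repression_strength < 0)
    stop("repression_strength must lie in [0, 1)")
  if (nchar(cfg$adapter) < 6L)
    stop("adapter must be at least 6 nt to be detectable downstream")
  if (length(cfg$stage_names) != cfg$n_stages)
    stop("stage_names must have length n_stages")
  if (min(cfg$n_mirna, cfg$n_lncrna, cfg$n_mrna) < 1L)
    stop("feature counts must be >= 1")
  if (cfg$n_triplets > min(cfg$n_mirna, cfg$n_lncrna, cfg$n_mrna))
    stop("n_triplets exceeds available features")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("ceRNA simulation config\n")
  cat(sprintf("  design: %d stages (%s) x %d replicates, seed %d\n",
              x$n_stages, paste(x$stage_names, collapse = ", "),
              x$n_replicates, x$seed))
  cat(sprintf("  features: %d miRNA, %d lncRNA, %d mRNA; %d planted triplets\n",
              x$n_mirna, x$n_lncrna, x$n_mrna, x$n_triplets))
  cat(sprintf("  effect_size %.2g, dispersion %.3g, repression %.2g\n",
              x$effect_size, x$nb_dispersion, x$repression_strength))
  invisible(x)
}

# log2 offsets per stage (relative to stage 1) for a planted profile shape
.profile_offsets <- function(shape, effect_size, n_stages = 3L) {
  e <- effect_size
  switch(shape,
         incremental   = c(0, e / 2, e),
         decreasing    = c(0, -e / 2, -e),
         high_low_high = c(0, -e, 0),
         low_high_low  = c(0, e, 0),
         flat          = c(0, 0, 0),
         stop("unknown profile shape: ", shape))
}

# direction of change between stage i and stage j given log2 offsets
.offset_direction <- function(offsets, i, j) {
  d <- offsets[j] - offsets[i]
  if (d > 1e-9) "up" else if (d < -1e-9) "down" else "none"
}

.random_seq <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len[min(i, length(len))], replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Generate a synthetic reference set with planted binding sites
#'
#' Builds mature miRNA, lncRNA, mRNA-3'UTR and contaminant-decoy sequences,
#' assigns planted differential-expression profiles, and overwrites 8mer
#' seed-match sites (reverse complement of miRNA positions 2-8 followed by
#' an A opposite position 1) into the transcripts of every planted sponge
#' triplet. Ground truth records exact 0-based half-open site intervals,
#' per-feature profile shapes with per-comparison directions, and the
#' planted triplets.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `refs` (class `reference_set`: named
#'   character vectors `mirnas` (RNA), `lncrnas`, `mrna_utrs`,
#'   `contaminants` (DNA)) and `truth` (class `ground_truth`: data frames
#'   `de_labels`, `planted_sites`, `planted_triplets`).
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  mir_names <- sprintf("sim-miR-%03d", seq_len(cfg$n_mirna))
  lnc_names <- sprintf("MSTRG.%04d", seq_len(cfg$n_lncrna))
  mrna_names <- sprintf("GENE%04d", seq_len(cfg$n_mrna))
  dec_names <- sprintf("decoy-%02d", seq_len(cfg$n_contaminant))

  mir_len <- sample(seq(cfg$mirna_len_range[1], cfg$mirna_len_range[2]),
                    cfg$n_mirna, replace = TRUE)
  mirnas <- setNames(
    dna_to_rna(.random_seq(cfg$n_mirna, mir_len)), mir_names)
  lncrnas <- setNames(
    .random_seq(cfg$n_lncrna, rep(cfg$lnc_len, cfg$n_lncrna)), lnc_names)
  mrna_utrs <- setNames(
    .random_seq(cfg$n_mrna, rep(cfg$utr_len, cfg$n_mrna)), mrna_names)
  contaminants <- setNames(
    .random_seq(cfg$n_contaminant,
                rep(cfg$contaminant_len, cfg$n_contaminant)), dec_names)

  n_de <- max(cfg$n_triplets, round(cfg$frac_de * cfg$n_mirna))
  de_mirnas <- sample(mir_names, n_de)
  shapes <- sample(names(cfg$profile_mix), n_de, replace = TRUE,
                   prob = cfg$profile_mix)
  trip_mirnas <- de_mirnas[seq_len(cfg$n_triplets)]
  trip_lnc <- sample(lnc_names, cfg$n_triplets)
  trip_mrna <- sample(mrna_names, cfg$n_triplets)

  # plant 8mer sites: revcomp(miRNA 2-8) + 'A' opposite position 1
  site_rows <- list()
  plant <- function(transcript_seq, mir_seq, n_sites, tname, mname, kind) {
    m <- strsplit(rna_to_dna(mir_seq), "", fixed = TRUE)[[1]]
    site <- paste0(rev_comp_dna(paste(m[2:8], collapse = "")), "A")
    len <- nchar(transcript_seq)
    if (len < 20L * n_sites)
      stop("transcript ", tname, " too short to host ", n_sites, " sites")
    # non-overlapping starts on an 8 nt grid
    slots <- sample(seq(1L, len - 8L + 1L, by = 10L), n_sites)
    for (s in slots) {
      substr(transcript_seq, s, s + 7L) <- site
      site_rows[[length(site_rows) + 1L]] <<- data.frame(
        mirna = mname, transcript = tname, kind = kind,
        start = s - 1L, end = s + 7L, site_class = "8mer",
        stringsAsFactors = FALSE)
    }
    transcript_seq
  }

  smin <- cfg$sites_per_target[1]; smax <- cfg$sites_per_target[2]
  for (i in seq_len(cfg$n_triplets)) {
    n1 <- sample(seq(smin, smax), 1L)
    n2 <- sample(seq(smin, smax), 1L)
    lncrnas[trip_lnc[i]] <- plant(lncrnas[trip_lnc[i]],
                                  mirnas[trip_mirnas[i]], n1,
                                  trip_lnc[i], trip_mirnas[i], "lncRNA")
    mrna_utrs[trip_mrna[i]] <- plant(mrna_utrs[trip_mrna[i]],
                                     mirnas[trip_mirnas[i]], n2,
                                     trip_mrna[i], trip_mirnas[i], "mRNA")
  }

  # Truth consistency: the recorded truth must be exhaustive, so chance
  # seed-core complements of planted-DE miRNAs that arise in the random
  # transcript background are mutated away (planted intervals are left
  # untouched). Without this, "ground truth" would silently omit real,
  # correctly detectable sites.
  site_df <- if (length(site_rows)) do.call(rbind, site_rows) else NULL
  cores <- vapply(de_mirnas, function(m) {
    mc <- strsplit(rna_to_dna(mirnas[[m]]), "", fixed = TRUE)[[1]]
    rev_comp_dna(paste(mc[2:7], collapse = ""))
  }, character(1))
  txseqs <- c(lncrnas, mrna_utrs)
  planted_iv <- function(tname) {
    if (is.null(site_df)) return(NULL)
    site_df[site_df$transcript == tname, c("start", "end"), drop = FALSE]
  }
  for (iter in 1:10) {
    dirty <- FALSE
    for (core in unique(cores)) {
      hits <- gregexpr(core, txseqs, fixed = TRUE)
      for (k in seq_along(txseqs)) {
        pos <- hits[[k]]
        if (pos[1] == -1L) next
        iv <- planted_iv(names(txseqs)[k])
        for (p in pos) {
          w0 <- p - 1L; w1 <- p + 5L   # 0-based half-open core window
          if (!is.null(iv) && nrow(iv) &&
              any(pmax(iv$start, w0) < pmin(iv$end, w1))) next
          mid <- p + 3L
          old <- substr(txseqs[k], mid, mid)
          substr(txseqs[k], mid, mid) <-
            c(A = "C", C = "G", G = "T", T = "A")[[old]]
          dirty <- TRUE
        }
      }
    }
    if (!dirty) break
  }
  lncrnas <- txseqs[seq_along(lncrnas)]
  mrna_utrs <- txseqs[length(lncrnas) + seq_along(mrna_utrs)]

  # profile labels: DE miRNAs carry their shape; triplet transcripts carry
  # the repression-mirrored shape implied by (1 - r)^elevation
  comp <- utils::combn(cfg$n_stages, 2)
  comp_names <- apply(comp, 2, function(ij)
    paste(cfg$stage_names[ij[1]], "vs", cfg$stage_names[ij[2]], sep = "."))

  label_feature <- function(feature, kind, shape, offsets) {
    dirs <- vapply(seq_len(ncol(comp)), function(k)
      .offset_direction(offsets, comp[1, k], comp[2, k]), character(1))
    out <- data.frame(feature = feature, kind = kind, shape = shape,
                      stringsAsFactors = FALSE)
    out[comp_names] <- as.list(dirs)
    out
  }

  labels <- list()
  mir_shape <- setNames(shapes, de_mirnas)
  for (m in de_mirnas) {
    off <- .profile_offsets(mir_shape[[m]], cfg$effect_size, cfg$n_stages)
    labels[[length(labels) + 1L]] <- label_feature(m, "miRNA",
                                                   mir_shape[[m]], off)
  }
  r <- cfg$repression_strength
  target_shape_name <- function(off) {
    d <- diff(off)
    s <- ifelse(abs(d) < 1e-9, "0", ifelse(d > 0, "+", "-"))
    key <- paste(s, collapse = "")
    c("++" = "incremental", "--" = "decreasing", "-+" = "high_low_high",
      "+-" = "low_high_low")[key]
  }
  for (i in seq_len(cfg$n_triplets)) {
    moff <- .profile_offsets(mir_shape[[trip_mirnas[i]]], cfg$effect_size,
                             cfg$n_stages)
    toff <- moff * log2(1 - r)
    tshape <- if (r > 0) unname(target_shape_name(toff)) else "flat"
    labels[[length(labels) + 1L]] <-
      label_feature(trip_lnc[i], "lncRNA", tshape, toff)
    labels[[length(labels) + 1L]] <-
      label_feature(trip_mrna[i], "mRNA", tshape, toff)
  }
  de_labels <- if (length(labels)) do.call(rbind, labels) else {
    empty <- data.frame(feature = character(0), kind = character(0),
                        shape = character(0), stringsAsFactors = FALSE)
    empty[comp_names] <- list(character(0))
    empty
  }
  rownames(de_labels) <- NULL

  refs <- structure(list(mirnas = mirnas, lncrnas = lncrnas,
                         mrna_utrs = mrna_utrs, contaminants = contaminants),
                    class = "reference_set")
  truth <- structure(list(
    de_labels = de_labels,
    planted_sites = if (length(site_rows)) do.call(rbind, site_rows) else
      data.frame(),
    planted_triplets = data.frame(lncrna = trip_lnc, mirna = trip_mirnas,
                                  mrna = trip_mrna, stringsAsFactors = FALSE),
    comparisons = comp_names,
    true_lib_factors = NULL), class = "ground_truth")
  list(refs = refs, truth = truth)
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(
    "reference_set: %d miRNAs, %d lncRNAs, %d mRNA 3'UTRs, %d decoys\n",
    length(x$mirnas), length(x$lncrnas), length(x$mrna_utrs),
    length(x$contaminants)))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth: %d DE labels, %d planted sites, %d planted triplets\n",
    nrow(x$de_labels), nrow(x$planted_sites), nrow(x$planted_triplets)))
  invisible(x)
}

#' Simulate negative-binomial count matrices from planted truth
#'
#' Draws one miRNA matrix and one transcript (lncRNA + mRNA) matrix with
#' per-feature log-normal baseline means, per-sample library-size factors,
#' planted stage-mean profiles for DE features, and sponge repression on
#' planted targets. Counts are NB with the configured common dispersion
#' (Poisson when dispersion is 0); non-DE features are flat in expectation.
#'
#' @param config a [sim_config()] object.
#' @param truth ground truth from [build_reference()] on the same config.
#' @return list with integer matrices `mirna` and `transcript` (features x
#'   samples), character vector `stages` (per sample), and `truth` with
#'   `true_lib_factors` filled (per-sample factors, geometric mean 1).
#' @export
simulate_counts <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (config$repression_strength >= 1)
    stop("repression_strength must be < 1")
  cfg <- config
  set.seed(cfg$seed + 1L)

  n_samp <- cfg$n_stages * cfg$n_replicates
  stages <- rep(cfg$stage_names, each = cfg$n_replicates)
  samp_ids <- paste(stages, rep(seq_len(cfg$n_replicates), cfg$n_stages),
                    sep = "-")

  mir_names <- sprintf("sim-miR-%03d", seq_len(cfg$n_mirna))
  tx_names <- c(sprintf("MSTRG.%04d", seq_len(cfg$n_lncrna)),
                sprintf("GENE%04d", seq_len(cfg$n_mrna)))

  offsets_for <- function(features) {
    off <- matrix(0, length(features), cfg$n_stages,
                  dimnames = list(features, cfg$stage_names))
    lab <- truth$de_labels
    if (nrow(lab)) {
      for (i in seq_len(nrow(lab))) {
        f <- lab$feature[i]
        if (f %in% features) {
          if (lab$kind[i] == "miRNA") {
            off[f, ] <- .profile_offsets(lab$shape[i], cfg$effect_size,
                                         cfg$n_stages)
          } else {
            trip <- truth$planted_triplets
            m <- trip$mirna[trip$lncrna == f | trip$mrna == f][1]
            mshape <- lab$shape[lab$feature == m & lab$kind == "miRNA"][1]
            moff <- .profile_offsets(mshape, cfg$effect_size, cfg$n_stages)
            off[f, ] <- moff * log2(1 - cfg$repression_strength)
          }
        }
      }
    }
    off
  }

  lib <- round(runif(n_samp, cfg$lib_size_range[1], cfg$lib_size_range[2]))
  rel <- lib / exp(mean(log(lib)))

  draw_matrix <- function(features, offsets, size_factors) {
    base <- rlnorm(length(features), cfg$baseline_meanlog, cfg$baseline_sdlog)
    mu <- outer(base, size_factors) * 2^offsets[, rep(seq_len(cfg$n_stages),
                                                      each = cfg$n_replicates)]
    m <- matrix(0L, length(features), length(size_factors),
                dimnames = list(features, samp_ids))
    for (j in seq_len(ncol(m))) {
      m[, j] <- if (cfg$nb_dispersion < 1e-12)
        stats::rpois(nrow(m), mu[, j])
      else rnbinom(nrow(m), mu = mu[, j], size = 1 / cfg$nb_dispersion)
    }
    storage.mode(m) <- "integer"
    m
  }

  # scale miRNA means so expected column sums hit the drawn library sizes
  mir_sf <- lib / (cfg$n_mirna *
                     exp(cfg$baseline_meanlog + cfg$baseline_sdlog^2 / 2))
  mirna <- draw_matrix(mir_names, offsets_for(mir_names), mir_sf)
  transcript <- draw_matrix(tx_names, offsets_for(tx_names), rel)

  truth$true_lib_factors <- setNames(rel, samp_ids)
  list(mirna = mirna, transcript = transcript, stages = stages,
       sample_ids = samp_ids, truth = truth)
}

#' Simulate raw single-end small-RNA FASTQ files
#'
#' Each miRNA contributes exactly its count-matrix value in reads of the
#' form mature sequence + adapter, truncated to the read length, at
#' uniformly high base quality. Noise reads (contaminant fragments,
#' N-containing, low mean quality, and short/adapter-dimer inserts) are
#' injected at the configured rates, expressed as fractions of the raw
#' read total. Per-sample accounting is returned so that
#' raw = clean + noise holds exactly.
#'
#' @param config a [sim_config()] object (adapter at least 6 nt).
#' @param refs reference set from [build_reference()].
#' @param mirna_counts integer matrix of miRNA counts (features x samples);
#'   row names must be a subset of the miRNA reference names.
#' @param dir output directory; one `<sample>.fastq` per sample.
#' @return data.frame manifest: per sample the FASTQ path, clean read
#'   count, per-category noise counts, and raw total.
#' @export
simulate_reads <- function(config, refs, mirna_counts, dir) {
  stopifnot(inherits(config, "sim_config"), inherits(refs, "reference_set"))
  cfg <- config
  if (nchar(cfg$adapter) < 6L)
    stop("adapter must be at least 6 nt to be detectable downstream")
  if (!all(rownames(mirna_counts) %in% names(refs$mirnas)))
    stop("count matrix rows must be a subset of miRNA reference names")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 2L)

  mature_dna <- rna_to_dna(refs$mirnas[rownames(mirna_counts)])
  rl <- cfg$read_length
  trunc_read <- function(x) substr(x, 1L, rl)

  f_noise <- c(cont = cfg$contaminant_frac, lowq = cfg$lowqual_frac,
               nbase = cfg$n_base_frac, short = cfg$short_frac)
  rows <- list()
  for (j in seq_len(ncol(mirna_counts))) {
    smp <- colnames(mirna_counts)[j]
    cnt <- mirna_counts[, j]
    n_clean <- as.integer(sum(cnt))
    n_raw <- if (sum(f_noise) > 0)
      as.integer(round(n_clean / (1 - sum(f_noise)))) else n_clean
    n_cat <- setNames(as.integer(round(f_noise * n_raw)), names(f_noise))

    seqs <- trunc_read(paste0(rep(mature_dna, cnt), cfg$adapter))
    quals <- strrep("I", nchar(seqs))

    if (n_cat[["cont"]] > 0) {
      dec <- sample(refs$contaminants, n_cat[["cont"]], replace = TRUE)
      len <- sample(20:30, n_cat[["cont"]], replace = TRUE)
      start <- vapply(nchar(dec) - len + 1L, function(m) sample(m, 1L),
                      integer(1))
      ins <- substr(dec, start, start + len - 1L)
      s <- trunc_read(paste0(ins, cfg$adapter))
      seqs <- c(seqs, s); quals <- c(quals, strrep("I", nchar(s)))
    }
    if (n_cat[["lowq"]] > 0) {
      ins <- sample(mature_dna, n_cat[["lowq"]], replace = TRUE)
      s <- trunc_read(paste0(ins, cfg$adapter))
      # Phred 2..12 (mean < 20): Phred+33 code points 35..45
      q <- vapply(nchar(s), function(L) {
        intToUtf8(sample(35:45, L, replace = TRUE))
      }, character(1))
      seqs <- c(seqs, s); quals <- c(quals, q)
    }
    if (n_cat[["nbase"]] > 0) {
      ins <- sample(mature_dna, n_cat[["nbase"]], replace = TRUE)
      pos <- vapply(nchar(ins), function(L) sample(L, 1L), integer(1))
      substr(ins, pos, pos) <- "N"
      s <- trunc_read(paste0(ins, cfg$adapter))
      seqs <- c(seqs, s); quals <- c(quals, strrep("I", nchar(s)))
    }
    if (n_cat[["short"]] > 0) {
      len <- sample(0:17, n_cat[["short"]], replace = TRUE)
      ins <- vapply(len, function(L) {
        if (L == 0L) "" else paste(sample(c("A", "C", "G", "T"), L,
                                          replace = TRUE), collapse = "")
      }, character(1))
      s <- trunc_read(paste0(ins, cfg$adapter))
      seqs <- c(seqs, s); quals <- c(quals, strrep("I", nchar(s)))
    }

    ord <- sample(length(seqs))
    seqs <- seqs[ord]; quals <- quals[ord]
    path <- file.path(dir, paste0(smp, ".fastq"))
    ids <- sprintf("@%s:%06d", smp, seq_along(seqs))
    writeLines(paste(ids, seqs, "+", quals, sep = "\n"), path)
    rows[[j]] <- data.frame(
      sample = smp, path = path, n_clean = n_clean,
      n_contaminant = n_cat[["cont"]], n_lowqual = n_cat[["lowq"]],
      n_with_n = n_cat[["nbase"]], n_short = n_cat[["short"]],
      n_raw = n_clean + sum(n_cat), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full generator: references, truth, counts and (optionally) reads
#'
#' @param config a [sim_config()] object.
#' @param reads_dir if non-NULL, also write per-sample FASTQ files there.
#' @return list with `refs`, `truth`, `counts` (as from
#'   [simulate_counts()]) and, when requested, the read `manifest`.
#' @export
sim_cerna_experiment <- function(config, reads_dir = NULL) {
  br <- build_reference(config)
  cnt <- simulate_counts(config, br$truth)
  out <- list(refs = br$refs, truth = cnt$truth, counts = cnt)
  if (!is.null(reads_dir))
    out$manifest <- simulate_reads(config, br$refs, cnt$mirna, reads_dir)
  out
}
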