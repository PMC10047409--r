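# Independent brute-force oracles used across the suite. These re-derive
# expected results directly from the definitions, character by character,
# and deliberately share no code with the package implementation.

.ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "?")

# exhaustive window-by-window seed matcher
oracle_scan <- function(mirna, transcript,
                        classes = c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                        noncanonical = FALSE, allow_wobble = TRUE,
                        min_run = 7L) {
  m <- strsplit(chartr("Uu", "Tt", toupper(mirna)), "", fixed = TRUE)[[1]]
  tt <- strsplit(toupper(transcript), "", fixed = TRUE)[[1]]
  L <- length(tt)
  rows <- list()
  canon_iv <- list()
  for (s in seq_len(max(L - 5L, 0L))) {
    if (!all(tt[s:(s + 5L)] == .ORACLE_COMP[rev(m[2:7])])) next
    has_m8 <- s >= 2L && tt[s - 1L] == .ORACLE_COMP[[m[8]]]
    has_a1 <- s + 6L <= L && tt[s + 6L] == "A"
    full_cls <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    iv_of <- function(cl) switch(cl,
      "8mer" = c(s - 2L, s + 6L), "7mer-m8" = c(s - 2L, s + 5L),
      "7mer-A1" = c(s - 1L, s + 6L), "6mer" = c(s - 1L, s + 5L))
    canon_iv[[length(canon_iv) + 1L]] <- iv_of(full_cls)
    elig <- c(if (has_m8 && has_a1) "8mer", if (has_m8) "7mer-m8",
              if (has_a1) "7mer-A1", "6mer")
    elig <- elig[elig %in% classes]
    if (!length(elig)) next
    iv <- iv_of(elig[1])
    rows[[length(rows) + 1L]] <- data.frame(
      start = iv[1], end = iv[2], site_class = elig[1],
      stringsAsFactors = FALSE)
  }
  if (noncanonical) {
    n10 <- min(10L, length(m))
    for (q in seq_len(L + n10 - 1L)) {
      paired <- logical(n10)
      for (i in seq_len(n10)) {
        tp <- q - i + 1L
        if (tp < 1L || tp > L) next
        wc <- tt[tp] == .ORACLE_COMP[[m[i]]]
        wob <- allow_wobble && (i < 2L || i > 7L) &&
          ((m[i] == "G" && tt[tp] == "T") ||
             (m[i] == "T" && tt[tp] == "G"))
        paired[i] <- wc || wob
      }
      r <- rle(paired)
      ends <- cumsum(r$lengths)
      ok <- which(r$values & r$lengths >= min_run)
      if (!length(ok)) next
      best_len <- max(r$lengths[ok])
      k <- ok[r$lengths[ok] == best_len][1]
      i_end <- ends[k]; i_start <- i_end - r$lengths[k] + 1L
      start0 <- q - i_end; end0 <- q - i_start + 1L
      if (start0 < 0L || end0 > L) next
      overl <- any(vapply(canon_iv, function(iv)
        max(iv[1], start0) < min(iv[2], end0), logical(1)))
      if (overl) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = start0, end = end0, site_class = "noncanonical",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      site_class = character(0), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$start, out$end, out$site_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# two-sided exact binomial split test (Poisson-limit reference)
oracle_binom_split <- function(ya, total, na, nb) {
  if (total == 0) return(1)
  f <- dbinom(0:total, total, na / (na + nb))
  min(1, sum(f[f <= f[ya + 1] * (1 + 1e-7)]))
}

# exhaustive mature-miRNA read assignment
oracle_quantify <- function(reads, refs, allow_3p_trim = 2L) {
  mature <- chartr("Uu", "Tt", toupper(refs))
  counts <- setNames(integer(length(refs)), names(refs))
  unassigned <- 0L
  for (i in seq_along(reads)) {
    s <- names(reads)[i]
    hits <- character(0)
    for (nm in names(mature)) {
      mt <- mature[[nm]]
      dl <- nchar(s) - nchar(mt)
      match <- if (dl <= 0) {
        -dl <= allow_3p_trim && substr(mt, 1, nchar(s)) == s
      } else {
        dl <= allow_3p_trim && substr(s, 1, nchar(mt)) == mt
      }
      if (match) hits <- c(hits, nm)
    }
    if (length(hits) == 0L) unassigned <- unassigned + reads[[i]]
    else counts[sort(hits)[1]] <- counts[sort(hits)[1]] + reads[[i]]
  }
  list(counts = counts, unassigned = unassigned)
}

# random sequence helpers for fixtures
rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
rand_rna <- function(n) chartr("T", "U", rand_dna(n))

# small fast simulation config used by several test files; `...` overrides
# any default, including the smallness defaults themselves
small_config <- function(seed = 42L, ...) {
  args <- list(seed = seed, n_mirna = 40L, n_lncrna = 30L, n_mrna = 120L,
               n_triplets = 8L, lib_size_range = c(6000L, 9000L))
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

triplet_key <- function(df) paste(df$lncrna, df$mirna, df$mrna)

# stage-mean log2 offsets implied by each planted profile shape (the
# package-wide convention, restated independently)
oracle_offsets <- function(shape, e) {
  switch(shape,
         incremental   = c(0, e / 2, e),
         decreasing    = c(0, -e / 2, -e),
         high_low_high = c(0, -e, 0),
         low_high_low  = c(0, e, 0),
         flat          = c(0, 0, 0))
}

# append a balancing feature so every column sum is identical, making
# library normalization the identity for noise-free classifier checks
balance_columns <- function(y) {
  total <- max(colSums(y)) + 10000L
  rbind(y, balance = as.integer(total - colSums(y)))
}
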