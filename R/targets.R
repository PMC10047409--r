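#' Seed-matcher configuration
#'
#' Controls which site classes [scan_sites()] reports and how sites are
#' scored. Canonical classes are defined on miRNA positions counted
#' 1-based from the 5' end: `6mer` = Watson-Crick (WC) match to positions
#' 2-7; `7mer-m8` = positions 2-8; `7mer-A1` = positions 2-7 plus an A in
#' the transcript opposite position 1; `8mer` = positions 2-8 plus the A.
#' The noncanonical mode reports any alignment whose best duplex pairs at
#' least `noncanonical_min_run` consecutive positions (WC, plus G:U wobble
#' outside the 2-7 core when `allow_wobble`) against miRNA positions 1-10
#' and is not a canonical site.
#'
#' @param classes canonical site classes to report.
#' @param noncanonical also scan for noncanonical sites (default FALSE).
#' @param allow_wobble permit G:U pairs outside the seed core in
#'   noncanonical duplexes.
#' @param noncanonical_min_run minimum consecutive paired run (>= 6).
#' @param wc_weight,wobble_weight per-pair score weights.
#' @param class_bonus named numeric bonus per site class; the defaults
#'   preserve the canonical hierarchy 8mer > 7mer-m8 > 7mer-A1 > 6mer.
#' @return an object of class `matcher_config`.
#' @export
matcher_config <- function(classes = c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                           noncanonical = FALSE,
                           allow_wobble = TRUE,
                           noncanonical_min_run = 7L,
                           wc_weight = 1,
                           wobble_weight = 0.5,
                           class_bonus = c("8mer" = 2, "7mer-m8" = 1.5,
                                           "7mer-A1" = 1, "6mer" = 0.5,
                                           "noncanonical" = 0)) {
  known <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  if (!all(classes %in% known))
    stop("unknown site class(es): ",
         paste(setdiff(classes, known), collapse = ", "))
  if (noncanonical_min_run < 6L) stop("noncanonical_min_run must be >= 6")
  structure(list(classes = classes, noncanonical = noncanonical,
                 allow_wobble = allow_wobble,
                 noncanonical_min_run = as.integer(noncanonical_min_run),
                 wc_weight = wc_weight, wobble_weight = wobble_weight,
                 class_bonus = class_bonus),
            class = "matcher_config")
}

.CLASS_ORDER <- c("8mer" = 4L, "7mer-m8" = 3L, "7mer-A1" = 2L, "6mer" = 1L,
                  "noncanonical" = 0L)

.check_alphabet <- function(x, alphabet, what) {
  if (grepl(paste0("[^", alphabet, "]"), x))
    stop(what, " contains characters outside its alphabet")
}

# canonical sites for one (miRNA, transcript) pair; mirna as DNA char
# vector, transcript string. Returns rows with 1-based core start i.
.canonical_hits <- function(mchars, transcript) {
  L <- nchar(transcript)
  core <- rev_comp_dna(paste(mchars[2:7], collapse = ""))
  m8c <- chartr("ACGT", "TGCA", mchars[8])
  # zero-width lookahead so overlapping core windows are all found
  hits <- gregexpr(paste0("(?=", core, ")"), transcript, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(NULL)
  out <- vector("list", length(hits))
  for (k in seq_along(hits)) {
    i <- hits[k]
    has_m8 <- i >= 2L && substr(transcript, i - 1L, i - 1L) == m8c
    has_a1 <- i + 6L <= L && substr(transcript, i + 6L, i + 6L) == "A"
    cls <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    out[[k]] <- list(i = i, class = cls, has_m8 = has_m8, has_a1 = has_a1)
  }
  out
}

# interval (0-based half-open) and paired-position count for a canonical
# hit, possibly downgraded to a lower class
.canonical_interval <- function(i, cls) {
  switch(cls,
         "8mer"    = c(i - 2L, i + 6L, 7L),
         "7mer-m8" = c(i - 2L, i + 5L, 7L),
         "7mer-A1" = c(i - 1L, i + 6L, 6L),
         "6mer"    = c(i - 1L, i + 5L, 6L))
}

#' Scan one transcript for miRNA seed-match sites
#'
#' Reports canonical seed sites (and optionally noncanonical duplex sites)
#' of a single miRNA on a single transcript, left to right. Overlapping
#' canonical windows are reported once, under the highest enabled class
#' they satisfy; noncanonical sites overlapping a canonical site are
#' suppressed.
#'
#' @param mirna mature miRNA sequence (RNA or DNA alphabet), >= 18 nt.
#' @param transcript transcript sequence (DNA alphabet), >= 8 nt.
#' @param cfg a [matcher_config()].
#' @return data.frame with columns `start`, `end` (0-based half-open on
#'   the transcript sense strand), `site_class`, `pairing` (one symbol per
#'   transcript position: `|` WC pair, `:` wobble, `.` unpaired) and
#'   `score`; zero rows when no site is found.
#' @export
scan_sites <- function(mirna, transcript, cfg = matcher_config()) {
  mirna <- dna_to_rna(toupper(mirna)); transcript <- toupper(transcript)
  .check_alphabet(mirna, "ACGU", "miRNA (RNA alphabet)")
  .check_alphabet(transcript, "ACGTN", "transcript (DNA alphabet)")
  if (nchar(mirna) < 18L) stop("miRNA must be at least 18 nt")
  if (nchar(transcript) < 8L) stop("transcript must be at least 8 nt")
  mdna <- strsplit(rna_to_dna(mirna), "", fixed = TRUE)[[1]]
  L <- nchar(transcript)

  rows <- list()
  canon <- .canonical_hits(mdna, transcript)
  canon_iv <- matrix(integer(0), ncol = 2)
  for (h in if (is.null(canon)) list() else canon) {
    canon_iv <- rbind(canon_iv,
                      .canonical_interval(h$i, h$class)[1:2])
    # downgrade to the highest enabled class this window satisfies
    eligible <- c("8mer"[h$has_m8 && h$has_a1],
                  "7mer-m8"[h$has_m8], "7mer-A1"[h$has_a1], "6mer")
    cls <- eligible[eligible %in% cfg$classes][1]
    if (is.na(cls)) next
    iv <- .canonical_interval(h$i, cls)
    pairing <- strrep("|", iv[3])
    if (cls %in% c("8mer", "7mer-A1")) pairing <- paste0(pairing, ".")
    rows[[length(rows) + 1L]] <- data.frame(
      start = iv[1], end = iv[2], site_class = cls, pairing = pairing,
      score = iv[3] * cfg$wc_weight + cfg$class_bonus[[cls]],
      stringsAsFactors = FALSE)
  }

  if (cfg$noncanonical) {
    nc <- .noncanonical_hits(mdna, transcript, cfg, canon_iv)
    rows <- c(rows, nc)
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      site_class = character(0), pairing = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, -out$score), , drop = FALSE]
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# noncanonical duplex scan of miRNA positions 1-10 against every
# antiparallel alignment; q indexes the transcript position opposite
# miRNA position 1 (1-based, 1 .. L+9)
.noncanonical_hits <- function(mdna, transcript, cfg, canon_iv) {
  L <- nchar(transcript)
  tch <- strsplit(transcript, "", fixed = TRUE)[[1]]
  m10 <- mdna[seq_len(min(10L, length(mdna)))]
  compl <- chartr("ACGT", "TGCA", m10)
  nq <- L + length(m10) - 1L
  # paired[i, q]: 1 WC, 0.5 wobble (outside core), 0 otherwise
  paired <- matrix(0, nrow = length(m10), ncol = nq)
  for (i in seq_along(m10)) {
    tpos <- seq_len(nq) - i + 1L
    ok <- tpos >= 1L & tpos <= L
    tb <- rep(NA_character_, nq)
    tb[ok] <- tch[tpos[ok]]
    wc <- !is.na(tb) & tb == compl[i]
    wob <- rep(FALSE, nq)
    if (cfg$allow_wobble && (i < 2L || i > 7L)) {
      # G:U wobble: miRNA G with transcript T, or miRNA U (DNA T) with G
      wob <- !is.na(tb) & ((m10[i] == "G" & tb == "T") |
                             (m10[i] == "T" & tb == "G"))
    }
    paired[i, ] <- ifelse(wc, 1, ifelse(wob, 0.5, 0))
  }
  isp <- paired > 0
  run <- matrix(0L, nrow = nrow(isp), ncol = ncol(isp))
  run[1, ] <- as.integer(isp[1, ])
  for (i in 2:nrow(isp))
    run[i, ] <- ifelse(isp[i, ], run[i - 1, ] + 1L, 0L)
  best <- apply(run, 2, max)
  hit_q <- which(best >= cfg$noncanonical_min_run)
  out <- list()
  for (q in hit_q) {
    i_end <- which.max(run[, q])            # last miRNA position of run
    i_start <- i_end - run[i_end, q] + 1L   # first miRNA position of run
    start0 <- q - i_end                      # 0-based start
    end0 <- q - i_start + 1L                 # 0-based half-open end
    if (start0 < 0L || end0 > L) next
    if (nrow(canon_iv) &&
        any(pmax(canon_iv[, 1], start0) < pmin(canon_iv[, 2], end0))) next
    w <- paired[i_start:i_end, q]
    score <- sum(ifelse(w == 1, cfg$wc_weight, cfg$wobble_weight)) +
      cfg$class_bonus[["noncanonical"]]
    pairing <- paste(rev(ifelse(w == 1, "|", ":")), collapse = "")
    out[[length(out) + 1L]] <- data.frame(
      start = start0, end = end0, site_class = "noncanonical",
      pairing = pairing, score = score, stringsAsFactors = FALSE)
  }
  out
}

#' Score a predicted site
#'
#' Additive proxy score: one `wc_weight` per WC pair, one `wobble_weight`
#' per wobble pair, plus the class bonus. Recomputed from the `pairing`
#' string, so a site re-scored after editing weights stays consistent.
#'
#' @param site one row of a [scan_sites()] result.
#' @param cfg a [matcher_config()].
#' @return numeric score.
#' @export
score_site <- function(site, cfg = matcher_config()) {
  sym <- strsplit(site$pairing, "", fixed = TRUE)[[1]]
  sum(sym == "|") * cfg$wc_weight + sum(sym == ":") * cfg$wobble_weight +
    cfg$class_bonus[[site$site_class]]
}

#' Predict miRNA target sites across a transcript set
#'
#' Runs [scan_sites()] for every (miRNA, transcript) combination and
#' aggregates one row per pair with at least one site, in deterministic
#' (miRNA, transcript) order.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param cfg a [matcher_config()].
#' @return data.frame with `mirna`, `transcript`, `n_sites`, `best_class`,
#'   `best_score`, `first_start`.
#' @export
predict_targets <- function(mirnas, transcripts, cfg = matcher_config()) {
  if (length(mirnas) == 0L || length(transcripts) == 0L)
    return(data.frame(mirna = character(0), transcript = character(0),
                      n_sites = integer(0), best_class = character(0),
                      best_score = numeric(0), first_start = integer(0)))
  if (any(is.na(mirnas)) || is.null(names(mirnas)))
    stop("every requested miRNA needs a named, non-missing sequence")
  rows <- list()
  for (m in sort(names(mirnas))) {
    for (tx in sort(names(transcripts))) {
      s <- scan_sites(mirnas[[m]], transcripts[[tx]], cfg)
      if (nrow(s)) {
        best <- which.max(.CLASS_ORDER[s$site_class] * 1000 + s$score)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = m, transcript = tx, n_sites = nrow(s),
          best_class = s$site_class[best], best_score = s$score[best],
          first_start = s$start[1], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(mirna = character(0), transcript = character(0),
                      n_sites = integer(0), best_class = character(0),
                      best_score = numeric(0), first_start = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert 0-based half-open site intervals to 1-based closed coordinates
#'
#' @param sites a [scan_sites()] or site-table data.frame with `start`,
#'   `end` columns.
#' @return the input with `start`/`end` rewritten 1-based closed.
#' @export
sites_one_based <- function(sites) {
  sites$start <- sites$start + 1L
  sites
}
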