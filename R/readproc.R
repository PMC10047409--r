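# minimal 4-line FASTQ reader with per-record validation; returns
# list(seq, qual). Record-indexed errors are part of the cleaning contract.
.read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(list(seq = character(0), qual = character(0)))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: truncated record at record ",
         length(lines) %/% 4L + 1L)
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]; seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]; quals <- lines[idx + 3L]
  bad <- which(substr(hdr, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+" |
                 nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("malformed FASTQ record at record ", bad[1])
  list(seq = toupper(seqs), qual = quals)
}

# per-read mean Phred quality (offset 33), vectorised over a character vector
.mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

# locate the 3' adapter as the earliest position whose read suffix equals a
# prefix of the adapter with >= min_overlap nt; returns insert length
# (0-based: 0 = adapter dimer), or NA when the adapter is not found
.find_adapter <- function(seqs, adapter, min_overlap = 6L) {
  out <- rep(NA_integer_, length(seqs))
  la <- nchar(adapter)
  for (len in split(seq_along(seqs), nchar(seqs))) {
    rl <- nchar(seqs[len[1]])
    if (rl < min_overlap) next
    for (ins in 0:(rl - min_overlap)) {
      ov <- min(rl - ins, la)
      todo <- len[is.na(out[len])]
      if (!length(todo)) break
      hit <- substr(seqs[todo], ins + 1L, ins + ov) ==
        substr(adapter, 1L, ov)
      out[todo[hit]] <- ins
    }
  }
  out
}

#' Clean raw small-RNA reads and collapse to unique sequences
#'
#' Applies the standard small-RNA pre-processing filters in a fixed order
#' so that category counts are well defined: adapter dimer, low mean
#' quality, N-containing insert, short insert, contaminant match. Each
#' read is counted once under its first failing filter; survivors are
#' collapsed to unique insert sequences with counts. The 3' adapter is
#' located by the longest (earliest) exact prefix match at the read's 3'
#' end with at least 6 nt of overlap; reads without any adapter match keep
#' their full length as the insert.
#'
#' @param fastq path to a Phred+33 FASTQ file.
#' @param adapter 3' adapter sequence (DNA, non-empty).
#' @param min_len minimum insert length kept (default 18 nt).
#' @param min_mean_q minimum mean Phred quality (default 20).
#' @param contaminants named character vector of contaminant decoy
#'   sequences; an insert matching a decoy exactly or as a substring is
#'   removed.
#' @return list with `reads` (named integer vector: unique insert sequence
#'   to count) and `stats` (one-row data.frame: `n_raw`,
#'   `n_adapter_dimer`, `n_low_quality`, `n_with_n`, `n_short`,
#'   `n_contaminant`, `n_valid`, `valid_rate`). The accounting identity
#'   `n_raw = n_valid + sum(removals)` holds exactly; an empty FASTQ gives
#'   all-zero stats with `valid_rate = 0`.
#' @export
clean_reads <- function(fastq, adapter, min_len = 18L, min_mean_q = 20,
                        contaminants = character(0)) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  adapter <- toupper(adapter)
  fq <- .read_fastq(fastq)
  n_raw <- length(fq$seq)
  stats0 <- data.frame(n_raw = 0L, n_adapter_dimer = 0L, n_low_quality = 0L,
                       n_with_n = 0L, n_short = 0L, n_contaminant = 0L,
                       n_valid = 0L, valid_rate = 0)
  if (n_raw == 0L)
    return(list(reads = setNames(integer(0), character(0)), stats = stats0))

  ins_len <- .find_adapter(fq$seq, adapter)
  if (mean(is.na(ins_len)) > 0.9)
    warning("adapter not found in >90% of reads; wrong adapter sequence?")
  ins_len[is.na(ins_len)] <- nchar(fq$seq)[is.na(ins_len)]
  insert <- substr(fq$seq, 1L, ins_len)
  ins_qual <- substr(fq$qual, 1L, ins_len)

  fate <- rep("valid", n_raw)
  is_dimer <- ins_len == 0L
  fate[is_dimer] <- "dimer"
  open <- !is_dimer
  lowq <- open & .mean_phred(fq$qual) < min_mean_q
  fate[lowq] <- "lowq"; open <- open & !lowq
  hasn <- open & grepl("N", insert, fixed = TRUE)
  fate[hasn] <- "withn"; open <- open & !hasn
  short <- open & ins_len < min_len
  fate[short] <- "short"; open <- open & !short
  if (length(contaminants) && any(open)) {
    uniq <- unique(insert[open])
    is_cont <- vapply(uniq, function(s)
      any(vapply(contaminants, function(d) grepl(s, d, fixed = TRUE),
                 logical(1))), logical(1))
    cont <- open & insert %in% uniq[is_cont]
    fate[cont] <- "cont"; open <- open & !cont
  }

  tab <- table(factor(fate, levels = c("dimer", "lowq", "withn", "short",
                                       "cont", "valid")))
  kept <- insert[fate == "valid"]
  reads <- if (length(kept)) {
    t2 <- table(kept)
    setNames(as.integer(t2), names(t2))
  } else setNames(integer(0), character(0))
  stats <- data.frame(
    n_raw = n_raw,
    n_adapter_dimer = as.integer(tab[["dimer"]]),
    n_low_quality = as.integer(tab[["lowq"]]),
    n_with_n = as.integer(tab[["withn"]]),
    n_short = as.integer(tab[["short"]]),
    n_contaminant = as.integer(tab[["cont"]]),
    n_valid = as.integer(tab[["valid"]]),
    valid_rate = as.integer(tab[["valid"]]) / n_raw)
  list(reads = reads, stats = stats)
}

#' Count-weighted read length distribution
#'
#' @param reads named integer vector of collapsed clean reads (sequence to
#'   count), as returned by [clean_reads()].
#' @return data.frame with columns `length` and `fraction`; fractions sum
#'   to 1.
#' @export
length_distribution <- function(reads) {
  if (length(reads) == 0L || sum(reads) == 0L) stop("no clean reads")
  len <- nchar(names(reads))
  agg <- tapply(reads, len, sum)
  data.frame(length = as.integer(names(agg)),
             fraction = as.numeric(agg) / sum(reads), row.names = NULL)
}

#' Assign collapsed reads to mature miRNAs
#'
#' A read is assigned to a mature miRNA when it equals the mature sequence
#' or differs from it only at the 3' end by at most `allow_3p_trim`
#' trimmed or additional nucleotides (the common 3' length-variant isomiR
#' convention); no internal mismatches are allowed. A read compatible with
#' several references (e.g. sequence-identical matures deposited under
#' different names) is counted once, under the lexicographically first
#' name, and the collision is recorded.
#'
#' @param reads named integer vector of collapsed clean reads.
#' @param refs named character vector of mature miRNA sequences (RNA or
#'   DNA alphabet; converted to DNA internally).
#' @param allow_3p_trim maximum 3' length difference (default 2).
#' @return list with `counts` (named integer vector per miRNA),
#'   `unassigned` (total count of unassigned reads) and `collisions`
#'   (data.frame: read sequence, chosen name, number of candidates).
#'   `sum(counts) + unassigned` equals `sum(reads)`.
#' @export
quantify_mirnas <- function(reads, refs, allow_3p_trim = 2L) {
  if (length(refs) == 0L) stop("empty miRNA reference set")
  if (anyDuplicated(names(refs))) stop("reference names must be unique")
  mature <- rna_to_dna(toupper(refs))
  counts <- setNames(integer(length(refs)), names(refs))
  unassigned <- 0L
  collisions <- list()
  ml <- nchar(mature)
  for (i in seq_along(reads)) {
    s <- names(reads)[i]; ls <- nchar(s)
    # 3' trim: read is a prefix of the mature; 3' extension: mature is a
    # prefix of the read; in both cases |length difference| <= allow_3p_trim
    cand <- which((ls <= ml & ml - ls <= allow_3p_trim &
                     substring(mature, 1L, ls) == s) |
                    (ls > ml & ls - ml <= allow_3p_trim &
                       substring(s, 1L, ml) == mature))
    if (length(cand) == 0L) {
      unassigned <- unassigned + reads[[i]]
    } else {
      nm <- sort(names(refs)[cand])[1]
      counts[nm] <- counts[nm] + reads[[i]]
      if (length(cand) > 1L)
        collisions[[length(collisions) + 1L]] <- data.frame(
          read = s, assigned = nm, n_candidates = length(cand),
          stringsAsFactors = FALSE)
    }
  }
  list(counts = counts, unassigned = unassigned,
       collisions = if (length(collisions)) do.call(rbind, collisions) else
         data.frame())
}
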