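#' Sequence alphabet helpers
#'
#' Small utilities shared across modules: DNA/RNA conversion and reverse
#' complement on plain character vectors. Sequences are handled as upper-case
#' character strings throughout; Biostrings is used at file boundaries.
#'
#' @param x character vector of sequences.
#' @return character vector of the same length.
#' @examples
#' rev_comp_dna("AACGT")
#' @name sequtils
NULL

#' @rdname sequtils
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname sequtils
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' @rdname sequtils
#' @export
rev_comp_dna <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# complement of a single RNA base vector (U-form)
.comp_rna <- function(b) chartr("ACGU", "UGCA", b)

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings returning/accepting named character
#' vectors, the in-memory sequence representation used by this package.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read and write count matrices as TSV
#'
#' First column holds feature identifiers, remaining columns one sample
#' each, named like `D85-1` (stage, then replicate, separated by the final
#' dash).
#'
#' @param path file path.
#' @param counts integer matrix, features in rows, samples in columns.
#' @return `read_counts_tsv()` returns an integer matrix with dimnames.
#' @export
read_counts_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  d <- data.frame(feature = rownames(counts), counts, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive stage labels from sample identifiers
#'
#' Sample ids follow the `stage-replicate` convention (e.g. `D85-1`); the
#' stage is everything before the final dash.
#'
#' @param sample_ids character vector of sample identifiers.
#' @return character vector of stage labels.
#' @export
sample_stages <- function(sample_ids) {
  sub("-[^-]*$", "", sample_ids)
}
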