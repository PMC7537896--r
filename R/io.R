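# File IO: FASTA and the small TSV side files.

#' Read protein sequences from FASTA
#'
#' @param path FASTA file (wrapped or single-line records).
#' @return named character vector of sequences (first token of each header
#'   as the id).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width (default 70).
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::AAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# two-column TSVs (id -> value) used for labels, lengths, totals, organ maps
read_map_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(x[[2]], x[[1]])
}

read_counts_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "numeric"
  m
}
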