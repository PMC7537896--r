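# Global alignment and the center-star master alignment used for
# column bootstrapping.

#' Global pairwise alignment
#'
#' Needleman-Wunsch alignment with simple match/mismatch scores and a linear
#' gap penalty. The traceback is deterministic with tie order
#' diagonal > up > left, so identical inputs always give the identical
#' alignment.
#'
#' @param a,b non-empty amino-acid strings.
#' @param match,mismatch,gap scores (defaults 2, -1, -2).
#' @return list with `score`, and the gapped `a_aln`/`b_aln` strings.
#' @export
#' @examples
#' global_align("AC", "C", match = 1, mismatch = -1, gap = -1)$score  # 0
global_align <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) {
    abort_kit("validation_error", "sequences must be non-empty")
  }
  al <- .cpp_nw_align(aa_encode(a), aa_encode(b), match, mismatch, gap)
  list(score = al$score, a_aln = aa_decode(al$a), b_aln = aa_decode(al$b))
}

#' Center-star master alignment
#'
#' Builds one multiple alignment by picking the center sequence maximising
#' its summed pairwise alignment score to all others, aligning every other
#' sequence to the center, and merging the pairwise alignments on the center
#' coordinates (gap columns inserted in the center are pooled across pairs;
#' shorter insertions are right-padded). This is a guide-tree-free
#' progressive scheme: adequate for the well-conserved MYB domain columns
#' the bootstrap resamples, not a general-purpose aligner. Pre-aligned
#' input (all sequences the same length, possibly with `-`) is returned
#' as-is.
#'
#' @param seqs named character vector of (unaligned) amino-acid sequences.
#' @param match,mismatch,gap alignment scores.
#' @return named character vector of equal-length gapped sequences.
#' @export
align_center_star <- function(seqs, match = 2, mismatch = -1, gap = -2) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), length(seqs) >= 2L)
  if (length(unique(nchar(seqs))) == 1L) {
    # equal-length input (pre-aligned, or an indel-free domain set):
    # columns are taken as homologous as-is
    return(seqs)
  }
  plain <- gsub("-", "", seqs, fixed = TRUE)
  n <- length(plain)
  codes <- lapply(plain, aa_encode)
  # center = max total score
  tot <- numeric(n)
  pair_cache <- vector("list", n)
  for (i in seq_len(n)) pair_cache[[i]] <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- .cpp_nw_align(codes[[i]], codes[[j]], match, mismatch, gap)
      tot[i] <- tot[i] + al$score
      tot[j] <- tot[j] + al$score
      pair_cache[[i]][[j]] <- al
    }
  }
  c_idx <- which.max(tot)
  Lc <- length(codes[[c_idx]])
  others <- setdiff(seq_len(n), c_idx)
  # per pair: insertion counts before each center position (slots 0..Lc)
  ins <- matrix(0L, nrow = n, ncol = Lc + 1L)
  rows <- vector("list", n)
  for (k in others) {
    al <- if (k > c_idx) pair_cache[[c_idx]][[k]] else {
      a <- pair_cache[[k]][[c_idx]]
      list(score = a$score, a = a$b, b = a$a)  # orient center first
    }
    ca <- al$a   # center with gaps (0)
    sa <- al$b
    slot <- cumsum(ca != 0L)          # center residue index at each column
    gapcols <- which(ca == 0L)
    if (length(gapcols)) {
      tab <- table(slot[gapcols])     # insertions after center residue s
      ins[k, as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
    rows[[k]] <- list(ca = ca, sa = sa)
  }
  master_ins <- apply(ins, 2, max)
  pad_row <- function(sa, ca) {
    # rebuild the row on master coordinates: for slot s (0..Lc), emit the
    # row's own insertion characters right-padded with gaps to
    # master_ins[s+1], then the character aligned to center residue s+1
    slot <- cumsum(ca != 0L)
    out <- integer(0)
    for (s in 0:Lc) {
      here <- sa[ca == 0L & slot == s]
      out <- c(out, here, rep(0L, master_ins[s + 1L] - length(here)))
      if (s < Lc) out <- c(out, sa[which(ca != 0L)[s + 1L]])
    }
    out
  }
  aligned <- vector("list", n)
  # center row: its own residues with master insertions as gaps
  cen <- integer(0)
  for (s in 0:Lc) {
    cen <- c(cen, rep(0L, master_ins[s + 1L]))
    if (s < Lc) cen <- c(cen, codes[[c_idx]][s + 1L])
  }
  aligned[[c_idx]] <- cen
  for (k in others) aligned[[k]] <- pad_row(rows[[k]]$sa, rows[[k]]$ca)
  out <- vapply(aligned, aa_decode, character(1))
  names(out) <- names(seqs)
  out
}

# character matrix (sequences x columns) from equal-length gapped strings
alignment_matrix <- function(aligned) {
  stopifnot(length(unique(nchar(aligned))) == 1L)
  m <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  rownames(m) <- names(aligned)
  m
}
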