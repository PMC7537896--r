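# bHLH-interaction motif scanning.
#
# R2R3-MYBs that take part in MYB-bHLH-WD40 (MBW) complexes carry the
# bHLH-binding consensus [D/E]Lx2[R/K]x3Lx6Lx3R: a 20-residue window with
# D or E at position 1, L at 2, R or K at 5, L at 9, L at 16 and R at 20.

BHLH_MOTIF_REGEX <- "(?=[DE]L..[RK]...L......L...R)"
BHLH_MOTIF_WIDTH <- 20L

#' Find bHLH-interaction motifs in a protein
#'
#' Reports every 20-residue window satisfying the positional pattern
#' `[D/E]Lx2[R/K]x3Lx6Lx3R`. `x` positions match any residue including `X`;
#' `X` never matches a constrained position. Overlapping occurrences are all
#' reported. Matching is case-insensitive.
#'
#' @param protein amino-acid string (standard residues plus `X`).
#' @param protein_id optional identifier carried into the result.
#' @return data.frame with columns `protein_id`, `start`, `end`
#'   (`end = start + 19`), `matched` (the 20-residue window); zero rows when
#'   there is no match or the sequence is shorter than 20 residues.
#' @export
#' @examples
#' find_bhlh_motifs("DLAARAAALAAAAAALAAAR")$start  # 1
find_bhlh_motifs <- function(protein, protein_id = NA_character_) {
  stopifnot(is.character(protein), length(protein) == 1L)
  seq <- toupper(protein)
  aa_encode(seq)  # residue validation only
  empty <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), matched = character())
  if (nchar(seq) < BHLH_MOTIF_WIDTH) return(empty)
  m <- gregexpr(BHLH_MOTIF_REGEX, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  data.frame(
    protein_id = protein_id,
    start = starts,
    end = starts + BHLH_MOTIF_WIDTH - 1L,
    matched = substring(seq, starts, starts + BHLH_MOTIF_WIDTH - 1L)
  )
}

#' Scan a set of proteins for bHLH-interaction motifs
#'
#' @param proteins named character vector of amino-acid sequences.
#' @return data.frame of all hits (`protein_id`, `start`, `end`, `matched`).
#' @export
scan_bhlh_motifs <- function(proteins) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  out <- do.call(rbind, lapply(names(proteins), function(id) {
    find_bhlh_motifs(proteins[[id]], protein_id = id)
  }))
  rownames(out) <- NULL
  out
}
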