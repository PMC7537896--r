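# Repeat profiles: the consensus description of one MYB repeat against which
# candidate regions are aligned.

#' Construct a MYB repeat profile
#'
#' A repeat profile describes one MYB repeat unit: a consensus sequence of
#' about 50--53 residues, per-position substitution scores, length bounds for
#' an intact repeat, and the three consensus positions expected to carry the
#' regularly spaced tryptophan (or hydrophobic) core residues of the
#' helix-turn-helix fold.
#'
#' By default the position weights are the BLOSUM62 rows of the consensus
#' residues, i.e. aligning a window against the profile scores like aligning
#' it against the consensus under BLOSUM62. Supply `position_weights` to use
#' a custom profile (rows = consensus positions, columns = the 21-letter
#' package alphabet `ACDEFGHIKLMNPQRSTVWYX`).
#'
#' @param consensus consensus amino-acid sequence of the repeat.
#' @param name profile name.
#' @param position_weights optional numeric matrix,
#'   `nchar(consensus)` x 21, of per-position residue scores.
#' @param min_len,max_len residue-span bounds for an intact repeat hit.
#' @param w_anchors integer vector of exactly three strictly increasing
#'   1-based consensus positions holding the tryptophan anchors; defaults to
#'   the positions of `W` in the consensus.
#' @return an object of class `myb_profile`.
#' @seealso [default_myb_profile()], [detect_repeats()]
#' @export
myb_profile <- function(consensus, name = "profile", position_weights = NULL,
                        min_len = 45L, max_len = 60L, w_anchors = NULL) {
  codes <- aa_encode(consensus)
  L <- length(codes)
  if (L == 0L) abort_kit("validation_error", "consensus must be non-empty")
  if (!(min_len < max_len)) {
    abort_kit("validation_error", "min_len must be < max_len")
  }
  if (is.null(w_anchors)) {
    w_anchors <- which(codes == match("W", AA_ALPHABET21))
  }
  w_anchors <- as.integer(w_anchors)
  if (length(w_anchors) != 3L || is.unsorted(w_anchors, strictly = TRUE) ||
      any(w_anchors < 1L) || any(w_anchors > L)) {
    abort_kit("validation_error",
              "w_anchors must be exactly 3 strictly increasing positions ",
              "within the consensus")
  }
  if (is.null(position_weights)) {
    position_weights <- blosum62_weights(codes)
  }
  position_weights <- as.matrix(position_weights)
  if (nrow(position_weights) != L || ncol(position_weights) != 21L) {
    abort_kit("validation_error",
              "position_weights must be length(consensus) x 21")
  }
  structure(
    list(name = name, consensus = toupper(consensus), codes = codes,
         position_weights = position_weights,
         min_len = as.integer(min_len), max_len = as.integer(max_len),
         w_anchors = w_anchors),
    class = "myb_profile"
  )
}

# BLOSUM62 rows of the consensus residues, reordered to the package alphabet
blosum62_weights <- function(codes) {
  B <- get_blosum62()
  W <- B[AA_ALPHABET21[codes], AA_ALPHABET21, drop = FALSE]
  unname(W)
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Default plant R2R3-MYB repeat profile
#'
#' A package-authored 52-residue consensus of a plant MYB repeat with the
#' canonical tryptophan anchors at positions 6, 26 and 46 (spacing of ~19
#' residues, the "three regularly spaced tryptophans" of the MYB fold). It is
#' a synthetic consensus intended as a sensible default for scanning and for
#' the synthetic-data generator; surveys of a real proteome should supply
#' their own curated consensus via [myb_profile()].
#'
#' @return a `myb_profile`.
#' @export
default_myb_profile <- function() {
  myb_profile(
    consensus = "LNKGAWTAEEDRLLAEYVKAHGEGRWRDIARHAGLKRSGKSCRLRWMNYLRP",
    name = "plant-R2R3-repeat"
  )
}

#' Self-alignment score of a profile
#'
#' The score of aligning the consensus against its own profile, used to set
#' the default detection threshold (`min_score = frac * self_score`).
#'
#' @param profile a [myb_profile()].
#' @return numeric scalar.
#' @export
profile_self_score <- function(profile) {
  stopifnot(inherits(profile, "myb_profile"))
  sum(profile$position_weights[cbind(seq_along(profile$codes),
                                     profile$codes)])
}

#' @export
print.myb_profile <- function(x, ...) {
  cat("MYB repeat profile '", x$name, "': ", length(x$codes),
      " residues, W anchors at ", paste(x$w_anchors, collapse = "/"),
      ", intact span ", x$min_len, "-", x$max_len,
      ", self-score ", profile_self_score(x), "\n", sep = "")
  invisible(x)
}
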