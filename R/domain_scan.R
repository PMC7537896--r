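# Tandem MYB repeat detection and domain-architecture classification.

#' Score a window against a repeat profile
#'
#' Optimal local-alignment (Smith-Waterman) score of a candidate region
#' against the profile consensus under the profile's position weights and a
#' linear gap penalty. The score of the empty alignment is 0, so the result
#' is always non-negative.
#'
#' @param window amino-acid string.
#' @param profile a [myb_profile()].
#' @param gap_penalty negative per-gap score (default -8, in keeping with the
#'   BLOSUM62 integer scale of the default profile).
#' @return numeric alignment score, `>= 0`.
#' @export
#' @examples
#' p <- default_myb_profile()
#' score_window(p$consensus, p) == profile_self_score(p)
score_window <- function(window, profile, gap_penalty = -8) {
  stopifnot(inherits(profile, "myb_profile"))
  if (!is.character(window) || length(window) != 1L || nchar(window) == 0L) {
    abort_kit("validation_error", "window must be a non-empty string")
  }
  if (gap_penalty >= 0) {
    abort_kit("configuration_error", "gap_penalty must be negative")
  }
  codes <- aa_encode(window)
  .cpp_profile_local_align(codes, profile$position_weights, gap_penalty)$score
}

#' Detect tandem MYB repeats in a protein
#'
#' Greedy iterative search: the best-scoring local alignment of the protein
#' against the repeat profile is recorded as a hit, its residues are masked,
#' and the search repeats until no alignment reaches `min_score`. Hits are
#' therefore non-overlapping; they are returned sorted by start coordinate
#' and ranked from the N-terminus. Ties in score are broken deterministically
#' at the smallest end (hence start) coordinate.
#'
#' A hit must span at least `profile$min_len` residues to count as an intact
#' repeat; shorter local matches above threshold are discarded. For each hit
#' the protein positions aligned to the three consensus tryptophan anchors
#' are reported together with the number of them carrying a tryptophan or
#' hydrophobic residue (`W F Y L I V M A`). Anchor matches are reported, not
#' required -- imperfect repeats keep their hit.
#'
#' @param protein amino-acid string, length `>= profile$min_len`.
#' @param profile a [myb_profile()].
#' @param min_score detection threshold; defaults to
#'   `min_score_frac * profile_self_score(profile)`.
#' @param min_score_frac fraction of the profile self-score used when
#'   `min_score` is not given (default 0.5).
#' @param gap_penalty linear gap penalty, negative.
#' @param max_hits safety cap on the number of greedy passes.
#' @return data.frame with one row per hit: `start`, `end`, `score`,
#'   `rank`, `anchor_matches`, and a list-column `w_positions` of the three
#'   anchor-aligned protein coordinates (NA where the anchor fell in a gap).
#' @export
detect_repeats <- function(protein, profile = default_myb_profile(),
                           min_score = NULL, min_score_frac = 0.5,
                           gap_penalty = -8, max_hits = 16L) {
  stopifnot(inherits(profile, "myb_profile"))
  if (!is.character(protein) || length(protein) != 1L ||
      nchar(protein) == 0L) {
    abort_kit("validation_error", "protein must be a non-empty string")
  }
  if (is.null(min_score)) {
    min_score <- min_score_frac * profile_self_score(profile)
  }
  if (min_score <= 0) {
    abort_kit("configuration_error", "min_score must be > 0")
  }
  codes <- aa_encode(protein)
  if (length(codes) < profile$min_len) {
    return(empty_hits())
  }
  hydro <- match(c("W", "F", "Y", "L", "I", "V", "M", "A"), AA_ALPHABET21)
  hits <- list()
  masked <- codes
  for (k in seq_len(max_hits)) {
    al <- .cpp_profile_local_align(masked, profile$position_weights,
                                   gap_penalty)
    if (al$score < min_score || is.na(al$start)) break
    # mask regardless of span so a short high-scoring fragment cannot stall
    # the greedy loop; only intact-length hits are reported
    masked[al$start:al$end] <- 0L
    span <- al$end - al$start + 1L
    if (span < profile$min_len) next
    wpos <- al$seq_idx[match(profile$w_anchors, al$prof_idx)]
    amatch <- sum(codes[wpos[!is.na(wpos)]] %in% hydro)
    hits[[length(hits) + 1L]] <- data.frame(
      start = al$start, end = al$end, score = al$score,
      anchor_matches = amatch
    )
    hits[[length(hits)]]$w_positions <- list(as.integer(wpos))
  }
  if (length(hits) == 0L) return(empty_hits())
  out <- do.call(rbind, hits)
  out <- out[order(out$start), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("start", "end", "score", "rank", "anchor_matches", "w_positions")]
}

empty_hits <- function() {
  out <- data.frame(start = integer(), end = integer(), score = numeric(),
                    rank = integer(), anchor_matches = integer())
  out$w_positions <- list()
  out
}

#' Classify a domain architecture from repeat hits
#'
#' Maps the repeat count to the MYB class: 0 repeats -> `none`, 1 -> `1R`,
#' 2 -> `R2R3`, 3 -> `3R`, 4 or more -> `4R`. Proteins with fewer than two
#' repeats are flagged as excluded: a family survey retains only proteins
#' with an intact multi-repeat MYB domain.
#'
#' @param hits data.frame of hits from [detect_repeats()] (non-overlapping,
#'   sorted by start).
#' @param protein_id optional identifier carried through.
#' @return list of class `myb_architecture` with elements `protein_id`,
#'   `n_repeats`, `myb_type`, `retained`, `hits`.
#' @export
classify_architecture <- function(hits, protein_id = NA_character_) {
  n <- nrow(hits)
  if (n > 1L) {
    if (is.unsorted(hits$start)) {
      abort_kit("validation_error", "hits must be sorted by start")
    }
    if (any(hits$start[-1L] <= hits$end[-n])) {
      abort_kit("validation_error", "hits must be non-overlapping")
    }
  }
  type <- if (n == 0L) "none" else if (n == 1L) "1R" else if (n == 2L) {
    "R2R3"
  } else if (n == 3L) "3R" else "4R"
  structure(
    list(protein_id = protein_id, n_repeats = n, myb_type = type,
         retained = n >= 2L, hits = hits),
    class = "myb_architecture"
  )
}

#' Scan a set of proteins for MYB repeat architectures
#'
#' Runs [detect_repeats()] and [classify_architecture()] over a named vector
#' of protein sequences.
#'
#' @param proteins named character vector of amino-acid sequences (e.g. from
#'   [read_fasta()]).
#' @param profile a [myb_profile()].
#' @param ... passed to [detect_repeats()].
#' @return list with `architectures` (per-protein `myb_architecture`s),
#'   `summary` (data.frame: `protein_id`, `n_repeats`, `myb_type`,
#'   `retained`) and `hits` (long data.frame, one row per repeat hit).
#' @export
scan_proteins <- function(proteins, profile = default_myb_profile(), ...) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  archs <- lapply(names(proteins), function(id) {
    h <- detect_repeats(proteins[[id]], profile, ...)
    classify_architecture(h, protein_id = id)
  })
  names(archs) <- names(proteins)
  summ <- data.frame(
    protein_id = names(proteins),
    n_repeats = vapply(archs, `[[`, integer(1), "n_repeats"),
    myb_type = vapply(archs, `[[`, character(1), "myb_type"),
    retained = vapply(archs, `[[`, logical(1), "retained"),
    row.names = NULL
  )
  long <- do.call(rbind, lapply(archs, function(a) {
    if (a$n_repeats == 0L) return(NULL)
    cbind(protein_id = a$protein_id,
          a$hits[, c("start", "end", "score", "rank", "anchor_matches")])
  }))
  rownames(long) <- NULL
  list(architectures = archs, summary = summ,
       hits = long %||% data.frame(protein_id = character(),
                                   start = integer(), end = integer(),
                                   score = numeric(), rank = integer(),
                                   anchor_matches = integer()))
}
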