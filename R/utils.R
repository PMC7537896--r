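# Shared helpers: residue alphabet, validation, rounding.

# 20 standard residues plus X (unknown). Code 21 = X.
AA_ALPHABET21 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X"
)

#' Encode an amino-acid string as integer codes
#'
#' Uppercases the input and maps each residue to its index in the package
#' alphabet (20 standard residues plus `X`). Any other character is a
#' validation error.
#'
#' @param x single amino-acid string.
#' @return integer vector of codes in `1:21`.
#' @keywords internal
#' @noRd
aa_encode <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  codes <- match(chars, AA_ALPHABET21)
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    abort_kit("validation_error", "non-amino-acid characters: ",
              paste(bad, collapse = ", "))
  }
  codes
}

aa_decode <- function(codes) {
  # code 0 = gap; shift by one so 0 indexes "-" instead of dropping
  paste(c("-", AA_ALPHABET21)[codes + 1L], collapse = "")
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in gene-family
#' surveys conventionally round half up (54.3859 -> 54.4), so statistics
#' functions use this variant throughout.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.5)          # 1, where round(0.5) is 0
#' round_half_up(54.3859, 1)   # 54.4
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# round_half_up to `sig` significant digits (used for family shares where the
# convention is two significant figures: 0.81%, 9.0%).
signif_half_up <- function(x, sig = 2) {
  out <- x
  nz <- is.finite(x) & x != 0
  if (any(nz)) {
    mag <- floor(log10(abs(x[nz])))
    out[nz] <- round_half_up(x[nz], sig - 1 - mag)
  }
  out
}

# stop() with a classed condition so callers/tests can distinguish errors
abort_kit <- function(class, ...) {
  msg <- paste0(...)
  cond <- structure(
    class = c(class, "mybkit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic substream seed derived from a master seed and a stream name;
# kept below 2^31 so it is a valid R integer seed
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}
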