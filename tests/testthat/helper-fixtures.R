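# Helpers shared across the suite. Fixtures are built in code; nothing is
# read from outside the package.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# match/mismatch position-weight matrix for a consensus, for tiny hand-checked
# alignment cases
mm_weights <- function(consensus, match = 1, mismatch = -1) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  codes <- match(chars, c(AA20, "X"))
  W <- matrix(mismatch, length(codes), 21)
  W[cbind(seq_along(codes), codes)] <- match
  W
}

# independent brute-force oracle for the bHLH motif: explicit positional
# checks over every 20-mer, no regular expressions
brute_bhlh <- function(seq) {
  n <- nchar(seq)
  if (n < 20L) return(integer(0))
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  hits <- integer(0)
  for (s in seq_len(n - 19L)) {
    w <- ch[s:(s + 19L)]
    if (w[1] %in% c("D", "E") && w[2] == "L" && w[5] %in% c("R", "K") &&
        w[9] == "L" && w[16] == "L" && w[20] == "R") {
      hits <- c(hits, s)
    }
  }
  hits
}

# a small additive distance matrix from a known 4-taxon tree
# ((a:1,b:2):3,(c:4,d:5)) with internal edge 3
additive4 <- function() {
  ids <- c("a", "b", "c", "d")
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D["a", "b"] <- D["b", "a"] <- 1 + 2
  D["a", "c"] <- D["c", "a"] <- 1 + 3 + 4
  D["a", "d"] <- D["d", "a"] <- 1 + 3 + 5
  D["b", "c"] <- D["c", "b"] <- 2 + 3 + 4
  D["b", "d"] <- D["d", "b"] <- 2 + 3 + 5
  D["c", "d"] <- D["d", "c"] <- 4 + 5
  D
}
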