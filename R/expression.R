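# FPKM normalisation and expression-breadth classification across organs.

#' Default organ grouping of the 17-sample banana expression design
#'
#' Maps the 17 RNA-Seq samples (embryogenic cell suspension, seedling, root,
#' four leaf stages, pulp and four pulp ripening stages, peel and four peel
#' ripening stages) to the six organ groups used for breadth
#' classification.
#'
#' @return named character vector: sample id -> organ group.
#' @export
default_organ_map <- function() {
  c(embryogenic = "embryogenic", seedling = "seedling", root = "root",
    leaf = "leaf", young_leaf = "leaf", adult_leaf = "leaf",
    old_leaf = "leaf",
    pulp = "pulp", pulpS1 = "pulp", pulpS2 = "pulp", pulpS3 = "pulp",
    pulpS4 = "pulp",
    peel = "peel", peelS1 = "peel", peelS2 = "peel", peelS3 = "peel",
    peelS4 = "peel")
}

ORGAN_GROUPS <- c("embryogenic", "seedling", "root", "leaf", "pulp", "peel")

#' FPKM from a count matrix
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `counts * 1e9 / (length * total)` elementwise, with `length` the
#' transcript length in nucleotides and `total` the mapped fragments of the
#' sample. Invariant to scaling all counts of a sample together with its
#' total.
#'
#' @param counts numeric gene x sample matrix (genes in rows, named).
#' @param lengths named numeric vector of transcript lengths (nt), `> 0`.
#' @param totals named numeric vector of mapped fragments per sample, `> 0`.
#' @return FPKM matrix with the same dimnames.
#' @export
#' @examples
#' fpkm(matrix(10, 1, 1, dimnames = list("g", "s")),
#'      c(g = 1000), c(s = 1e6))  # 10
fpkm <- function(counts, lengths, totals) {
  counts <- as.matrix(counts)
  lengths <- lengths[rownames(counts)]
  totals <- totals[colnames(counts)]
  if (anyNA(lengths) || any(lengths <= 0)) {
    abort_kit("validation_error", "every gene needs a positive length")
  }
  if (anyNA(totals) || any(totals <= 0)) {
    abort_kit("per_sample_error", "every sample needs a positive total")
  }
  counts * 1e9 / outer(as.numeric(lengths), as.numeric(totals))
}

#' Read an FPKM (or count) matrix from TSV
#'
#' First column = gene id, remaining columns = samples.
#'
#' @param path TSV file.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path = system.file("extdata",
                                               "table2_expression.tsv",
                                               package = "mybkit")) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Classify expression breadth across organ groups
#'
#' A gene is expressed in a sample when its value exceeds `threshold`, and
#' in an organ group when any member sample is expressed. The breadth class
#' is `all_samples` when every sample is expressed, `none` when no sample
#' is, and `some` otherwise; a gene expressed in exactly one organ group is
#' additionally marked organ-exclusive.
#'
#' @param m FPKM matrix, genes x samples.
#' @param organ_map named character vector sample -> organ group covering
#'   every column of `m`.
#' @param threshold expression threshold on the FPKM scale (default 0:
#'   any signal counts, the convention when the survey's own cutoff is not
#'   stated).
#' @return data.frame with `gene_id`, `class`, `exclusive_organ` (empty
#'   when not exclusive), `n_organs`, and logical columns `organ_<group>`.
#' @export
classify_breadth <- function(m, organ_map = default_organ_map(),
                             threshold = 0) {
  if (threshold < 0) abort_kit("configuration_error", "threshold must be >= 0")
  m <- as.matrix(m)
  unmapped <- setdiff(colnames(m), names(organ_map))
  if (length(unmapped)) {
    abort_kit("configuration_error", "unmapped samples: ",
              paste(unmapped, collapse = ", "))
  }
  groups <- organ_map[colnames(m)]
  expressed <- m > threshold
  organs <- unique(unname(groups))
  org_mat <- vapply(organs, function(g) {
    rowSums(expressed[, groups == g, drop = FALSE]) > 0
  }, logical(nrow(m)))
  if (nrow(m) == 1L) org_mat <- matrix(org_mat, nrow = 1,
                                       dimnames = list(NULL, organs))
  n_org <- rowSums(org_mat)
  cls <- ifelse(rowSums(expressed) == ncol(m), "all_samples",
                ifelse(n_org == 0L, "none", "some"))
  excl <- ifelse(n_org == 1L,
                 organs[apply(org_mat, 1, which.max)], "")
  out <- data.frame(gene_id = rownames(m), class = cls,
                    exclusive_organ = excl, n_organs = n_org,
                    row.names = NULL)
  colnames(org_mat) <- paste0("organ_", organs)
  cbind(out, as.data.frame(org_mat, row.names = NULL))
}

#' Per-organ expressed-gene counts
#'
#' @param classes result of [classify_breadth()].
#' @return data.frame with `organ`, `count`, `percent` (of all genes,
#'   rounded half-up to one decimal).
#' @export
organ_expressed_counts <- function(classes) {
  stopifnot(nrow(classes) > 0L)
  org_cols <- grep("^organ_", names(classes), value = TRUE)
  data.frame(
    organ = sub("^organ_", "", org_cols),
    count = vapply(org_cols, function(cc) sum(classes[[cc]]), integer(1)),
    percent = round_half_up(
      100 * vapply(org_cols, function(cc) sum(classes[[cc]]), integer(1)) /
        nrow(classes), 1),
    row.names = NULL
  )
}

#' Compare the expression profiles of a paralog pair
#'
#' Pearson correlation of the `log2(FPKM + 1)` profiles, plus the Jaccard
#' overlap of the expressed-organ sets at the given threshold.
#'
#' @param m FPKM matrix.
#' @param pair character vector of two gene ids.
#' @param organ_map sample -> organ group map.
#' @param threshold expression threshold.
#' @return list with `pearson`, `jaccard`, `organs` (list of the two
#'   expressed-organ sets).
#' @export
compare_paralogs <- function(m, pair, organ_map = default_organ_map(),
                             threshold = 0) {
  if (!all(pair %in% rownames(m))) {
    abort_kit("lookup_error", "genes not in matrix: ",
              paste(setdiff(pair, rownames(m)), collapse = ", "))
  }
  x <- log2(m[pair[1], ] + 1)
  y <- log2(m[pair[2], ] + 1)
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else {
    stats::cor(x, y)
  }
  cb <- classify_breadth(m[pair, , drop = FALSE], organ_map, threshold)
  org_cols <- grep("^organ_", names(cb), value = TRUE)
  s1 <- sub("^organ_", "", org_cols[as.logical(cb[1, org_cols])])
  s2 <- sub("^organ_", "", org_cols[as.logical(cb[2, org_cols])])
  uni <- union(s1, s2)
  jac <- if (length(uni) == 0L) 1 else length(intersect(s1, s2)) / length(uni)
  list(pearson = r, jaccard = jac, organs = list(s1, s2))
}
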