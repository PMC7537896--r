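# Distance-based phylogeny: p-distances, neighbor-joining, column bootstrap
# with majority-rule consensus, and reference-clade assignment.
#
# The classification stage deliberately uses pairwise-alignment p-distances
# and neighbor-joining with bootstrap rather than maximum-likelihood
# inference: clades are matched by reference labels, so a monotone distance
# and a supported topology are sufficient for assignment.

#' Bundle MYB domain sequences with roles and clade labels
#'
#' @param sequences named character vector of extracted MYB-domain
#'   amino-acid sequences (unique ids).
#' @param roles named character vector (`query` or `reference`) or NULL to
#'   infer: ids present in `clade_labels` are references, the rest queries.
#' @param clade_labels named character vector mapping every reference id to
#'   its clade label.
#' @return object of class `domain_set`.
#' @export
domain_set <- function(sequences, clade_labels = character(), roles = NULL) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  if (anyDuplicated(names(sequences))) {
    abort_kit("validation_error", "sequence ids must be unique")
  }
  if (is.null(roles)) {
    roles <- ifelse(names(sequences) %in% names(clade_labels),
                    "reference", "query")
    names(roles) <- names(sequences)
  }
  refs <- names(sequences)[roles[names(sequences)] == "reference"]
  if (!all(refs %in% names(clade_labels))) {
    abort_kit("validation_error", "every reference needs a clade label")
  }
  structure(list(sequences = sequences, roles = roles,
                 clade_labels = clade_labels[refs]),
            class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  cat("domain_set:", length(x$sequences), "sequences (",
      sum(x$roles == "reference"), "reference /",
      sum(x$roles == "query"), "query ),",
      length(unique(x$clade_labels)), "clades\n")
  invisible(x)
}

#' Pairwise p-distance matrix
#'
#' For each pair the sequences are globally aligned ([global_align()]) and
#' the p-distance is the fraction of mismatched columns among columns where
#' neither sequence has a gap. Saturated pairs with no comparable columns
#' get distance 1 with a warning. With `correction = "poisson"` distances
#' are transformed to `-ln(1 - p)` (capped below saturation).
#'
#' @param set a [domain_set()] (or named character vector of sequences),
#'   at least 3 sequences.
#' @param aligned if TRUE, sequences are already columnar (equal length,
#'   `-` = gap) and no pairwise alignment is run.
#' @param correction `"none"` (p-distance) or `"poisson"`.
#' @param match,mismatch,gap alignment scores for the pairwise stage.
#' @return symmetric numeric matrix with the sequence ids as dimnames.
#' @export
pairwise_distances <- function(set, aligned = FALSE, correction = "none",
                               match = 2, mismatch = -1, gap = -2) {
  seqs <- if (inherits(set, "domain_set")) set$sequences else set
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  n <- length(seqs)
  if (n < 3L) abort_kit("size_error", "need at least 3 sequences")
  ids <- names(seqs)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  chars <- strsplit(toupper(seqs), "", fixed = TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (aligned) {
        a <- chars[[i]]; b <- chars[[j]]
        if (length(a) != length(b)) {
          abort_kit("validation_error",
                    "aligned = TRUE requires equal-length sequences")
        }
      } else {
        al <- global_align(seqs[[i]], seqs[[j]], match, mismatch, gap)
        a <- strsplit(al$a_aln, "", fixed = TRUE)[[1]]
        b <- strsplit(al$b_aln, "", fixed = TRUE)[[1]]
      }
      keep <- a != "-" & b != "-"
      if (!any(keep)) {
        warning("no comparable columns for pair ", ids[i], "/", ids[j],
                "; distance set to 1")
        p <- 1
      } else {
        p <- mean(a[keep] != b[keep])
      }
      D[i, j] <- D[j, i] <- p
    }
  }
  if (correction == "poisson") {
    D <- -log(1 - pmin(D, 0.999))
    diag(D) <- 0
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor-joining on a symmetric distance matrix: at
#' each step the pair minimising the Q criterion is joined; ties are broken
#' by the lexicographically smallest pair of representative ids (an internal
#' node is represented by the smallest leaf id below it), so the topology is
#' deterministic. Branch lengths follow the NJ formulas with negative
#' estimates clamped to zero; the number of clamped branches is recorded in
#' the `"clamped"` attribute of the result.
#'
#' @param D symmetric numeric matrix with unique dimnames, `n >= 3`.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_build <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    abort_kit("validation_error", "D must be a square matrix")
  }
  if (max(abs(D - t(D))) > 1e-8) {
    abort_kit("validation_error", "D must be symmetric")
  }
  n <- nrow(D)
  if (n < 3L) abort_kit("size_error", "need at least 3 taxa")
  ids <- rownames(D)
  if (is.null(ids) || anyDuplicated(ids)) {
    abort_kit("validation_error", "D needs unique dimnames")
  }
  clamped <- 0L
  cl <- function(x) {
    if (x < 0) clamped <<- clamped + 1L
    max(x, 0)
  }
  fmt <- function(x) sprintf("%.15g", x)
  # active nodes: newick fragment + representative (smallest) leaf label
  newick <- ids
  rep_lab <- ids
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pl <- cbind(pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]]),
                pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]]))
    pick <- order(pl[, 1], pl[, 2])[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- cl(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- cl(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    dn <- pmax((D[i, ] + D[j, ] - D[i, j]) / 2, 0)[-c(i, j)]
    nw <- paste0("(", newick[i], ":", fmt(li), ",",
                 newick[j], ":", fmt(lj), ")")
    rl <- min(rep_lab[i], rep_lab[j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn), c(dn, 0))
    newick <- c(newick[keep], nw)
    rep_lab <- c(rep_lab[keep], rl)
    rownames(D) <- colnames(D) <- rep_lab
  }
  # closed-form three-point join
  la <- cl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- cl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- cl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", newick[1], ":", fmt(la), ",", newick[2], ":", fmt(lb),
                ",", newick[3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap a domain alignment and annotate the consensus
#'
#' Builds the master alignment (unless `aligned` input is supplied), then
#' resamples alignment columns with replacement `B` times, rebuilding a
#' neighbor-joining tree from p-distances each time. Returns the
#' majority-rule (>50%) consensus annotated with percent bootstrap supports,
#' plus the full-data NJ tree (with branch lengths) annotated with the same
#' supports.
#'
#' @param set a [domain_set()] or named character vector of sequences.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed for the column-resampling stream.
#' @param aligned if TRUE, input sequences are already columnar.
#' @param correction distance correction passed to the p-distance stage.
#' @return object of class `myb_boot_tree`: list with `consensus` and
#'   `full_tree` (`ape::phylo`, node labels = percent support), `B`, `seed`,
#'   `n_columns`.
#' @export
bootstrap_consensus <- function(set, B = 1000L, seed = 1L, aligned = FALSE,
                                correction = "none") {
  if (B < 1L) abort_kit("configuration_error", "B must be >= 1")
  seqs <- if (inherits(set, "domain_set")) set$sequences else set
  aligned_seqs <- if (aligned) seqs else align_center_star(seqs)
  M <- alignment_matrix(aligned_seqs)
  dist_of <- function(cols) {
    sub <- M[, cols, drop = FALSE]
    strs <- apply(sub, 1, paste, collapse = "")
    names(strs) <- rownames(M)
    pairwise_distances(strs, aligned = TRUE, correction = correction)
  }
  full_tree <- nj_build(dist_of(seq_len(ncol(M))))
  set.seed(seed)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
    reps[[b]] <- nj_build(dist_of(cols))
  }
  class(reps) <- "multiPhylo"
  cons <- ape::consensus(reps, p = 0.5, rooted = FALSE)
  annotate <- function(tree) {
    cnt <- ape::prop.clades(tree, reps, rooted = FALSE)
    cnt[is.na(cnt)] <- 0L
    sup <- round(100 * cnt / B, 1)
    sup[1] <- 100  # root split of the stored orientation is trivial
    tree$node.label <- as.character(sup)
    tree
  }
  structure(
    list(consensus = annotate(cons), full_tree = annotate(full_tree),
         B = as.integer(B), seed = as.integer(seed), n_columns = ncol(M)),
    class = "myb_boot_tree"
  )
}

#' @export
print.myb_boot_tree <- function(x, ...) {
  cat("bootstrap NJ tree:", length(x$full_tree$tip.label), "leaves,",
      x$n_columns, "columns, B =", x$B, ", seed =", x$seed, "\n")
  invisible(x)
}

#' Write a tree with supports as Newick
#'
#' @param tree an `ape::phylo` (or the `full_tree`/`consensus` of a
#'   [bootstrap_consensus()] result); supports are written as internal node
#'   labels, branch lengths with 6 decimals.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "myb_boot_tree")) tree <- tree$full_tree
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 6)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Assign query leaves to labelled reference clades
#'
#' Works on the splits (bipartitions) of the tree, so the arbitrary rooting
#' of the stored topology does not matter. For each query the smallest
#' well-supported split side (support at least `threshold` percent; missing
#' supports count as resolved) containing the query and at least one
#' reference yields the assignment by majority vote over the reference
#' clade labels on that side; a tied vote gives `"unresolved"`. Equally
#' small candidate sides are disambiguated by the mean patristic distance
#' from the query to the references on each side (unit branch lengths are
#' assumed when the tree carries none, as in a bare consensus topology).
#'
#' Before per-query assignment, maximal well-supported reference-free sides
#' of two or more tips are checked for lineage specificity: a group is
#' lineage-specific when the smallest enclosing reference-containing
#' context holds references from two or more different clades (it branches
#' between established clades rather than within one), or when the context
#' is a single clade but the group sits much further from that clade's
#' references than those references sit from each other (mean patristic
#' distance exceeding `ls_distance_factor` times the reference spread --
#' a long-stemmed sister lineage, not a member). Such queries are labelled
#' `"lineage-specific:k"` with `k` numbering the groups. A query-only
#' group nested among references of a single clade simply takes that
#' clade's label.
#'
#' @param tree `ape::phylo` with optional percent supports in `node.label`,
#'   or a [bootstrap_consensus()] result (its `full_tree` is used).
#' @param labels named character vector: reference tip id -> clade label.
#' @param queries character vector of query tip ids (default: all tips
#'   without a label).
#' @param threshold minimum percent support for a split to anchor an
#'   assignment (default 50).
#' @param ls_distance_factor single-clade contexts flag a reference-free
#'   group as lineage-specific when its mean patristic distance to the
#'   context references exceeds this multiple of the maximum distance
#'   among those references (default 2); set to `Inf` to disable the
#'   distance criterion.
#' @return data.frame with `query_id`, `clade`, `support`.
#' @export
assign_clades <- function(tree, labels, queries = NULL, threshold = 50,
                          ls_distance_factor = 2) {
  if (inherits(tree, "myb_boot_tree")) tree <- tree$full_tree
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  refs <- intersect(tips, names(labels))
  if (is.null(queries)) queries <- setdiff(tips, refs)
  if (!all(queries %in% tips)) {
    abort_kit("lookup_error", "queries not in tree: ",
              paste(setdiff(queries, tips), collapse = ", "))
  }
  ntip <- length(tips)
  nnode <- tree$Nnode
  desc <- phangorn::Descendants(tree, ntip + seq_len(nnode), type = "tips")
  sup <- rep(100, nnode)
  if (!is.null(tree$node.label)) {
    parsed <- suppressWarnings(as.numeric(tree$node.label))
    sup[!is.na(parsed)] <- parsed[!is.na(parsed)]
  }
  sup[1] <- 100  # the root "split" is trivial
  # candidate sides: both sides of every non-root internal edge, plus the
  # full tip set as the final fallback
  side_list <- list()
  side_sup <- numeric(0)
  add_side <- function(members, s) {
    side_list[[length(side_list) + 1L]] <<- members
    side_sup[length(side_sup) + 1L] <<- s
  }
  all_tips <- seq_len(ntip)
  for (k in seq(2L, length.out = max(0L, nnode - 1L))) {
    if (sup[k] < threshold) next
    add_side(desc[[k]], sup[k])
    add_side(setdiff(all_tips, desc[[k]]), sup[k])
  }
  add_side(all_tips, 100)
  n_side <- length(side_list)
  size <- vapply(side_list, length, integer(1))
  is_ref_tip <- tips %in% refs
  ref_in <- lapply(side_list, function(m) tips[m[is_ref_tip[m]]])
  n_ref <- vapply(ref_in, length, integer(1))
  vote <- function(side_refs) {
    votes <- sort(table(labels[side_refs]), decreasing = TRUE)
    if (length(votes) > 1L && votes[1] == votes[2]) "unresolved"
    else names(votes)[1]
  }
  # patristic distances for breaking size ties between candidate sides
  dtree <- tree
  if (is.null(dtree$edge.length)) {
    dtree$edge.length <- rep(1, nrow(dtree$edge))
  }
  patristic <- ape::cophenetic.phylo(dtree)[tips, tips]
  mean_ref_dist <- function(from_tips, side) {
    mean(patristic[from_tips, ref_in[[side]], drop = FALSE])
  }
  # smallest candidates, distance-disambiguated: returns the indices of the
  # minimal-size sides still in play after the distance tie-break
  closest_minimal <- function(cand, from_tips) {
    cand <- cand[size[cand] == min(size[cand])]
    if (length(cand) > 1L) {
      d <- vapply(cand, function(s) mean_ref_dist(from_tips, s), numeric(1))
      cand <- cand[d <= min(d) + 1e-9]
    }
    cand
  }
  # lineage-specific pre-pass
  ls_of <- rep(NA_integer_, ntip)
  ls_sup <- numeric(0)
  reffree <- which(n_ref == 0L & size >= 2L & size < ntip)
  if (length(reffree)) {
    keys <- vapply(side_list, function(m) paste(m, collapse = ","),
                   character(1))
    maximal <- reffree[vapply(reffree, function(i) {
      !any(vapply(reffree, function(j) {
        j != i && size[j] >= size[i] && keys[j] != keys[i] &&
          all(side_list[[i]] %in% side_list[[j]])
      }, logical(1)))
    }, logical(1))]
    maximal <- maximal[!duplicated(keys[maximal])]
    grp <- 0L
    for (i in maximal) {
      enclosing <- which(n_ref > 0L & size > size[i] &
                           vapply(seq_len(n_side), function(j) {
                             all(side_list[[i]] %in% side_list[[j]])
                           }, logical(1)))
      context <- closest_minimal(enclosing, tips[side_list[[i]]])
      ctx_refs <- unique(unlist(ref_in[context]))
      ctx_labels <- unique(labels[ctx_refs])
      if (length(ctx_labels) <= 1L) {
        # single-clade context: lineage-specific only if the group is far
        # outside the spread of the clade's own references
        if (length(ctx_refs) < 2L) next
        spread <- max(patristic[ctx_refs, ctx_refs])
        d_grp <- mean(patristic[tips[side_list[[i]]], ctx_refs])
        if (spread <= 0 || d_grp <= ls_distance_factor * spread) next
      }
      grp <- grp + 1L
      ls_of[side_list[[i]]] <- grp
      ls_sup[grp] <- side_sup[i]
    }
  }
  out <- lapply(queries, function(q) {
    tip <- match(q, tips)
    if (!is.na(ls_of[tip])) {
      return(data.frame(query_id = q,
                        clade = paste0("lineage-specific:", ls_of[tip]),
                        support = ls_sup[ls_of[tip]]))
    }
    cand <- which(n_ref > 0L &
                    vapply(side_list, function(m) tip %in% m, logical(1)))
    cand <- closest_minimal(cand, q)
    best <- cand[order(-side_sup[cand])][1]
    data.frame(query_id = q, clade = vote(ref_in[[best]]),
               support = side_sup[best])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
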