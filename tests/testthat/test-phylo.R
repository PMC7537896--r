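test_that("p-distances behave on identical, disjoint and half-diverged pairs", {
  seqs <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "CCCCCCCCCC",
            d = "AAAAACCCCC")
  D <- pairwise_distances(seqs, aligned = TRUE)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1)
  expect_equal(D["a", "d"], 0.5)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)
})

test_that("the Poisson correction transforms p to -ln(1 - p)", {
  seqs <- c(a = "AAAAAAAAAA", b = "AAAAACCCCC", c = "AAAAAAAAAC")
  Dp <- pairwise_distances(seqs, aligned = TRUE)
  Dc <- pairwise_distances(seqs, aligned = TRUE, correction = "poisson")
  expect_equal(Dc["a", "b"], -log(1 - 0.5))
  expect_equal(Dc["a", "c"], -log(1 - 0.1))
  expect_true(all(Dc >= Dp))
})

test_that("fewer than three sequences is a size error", {
  expect_error(pairwise_distances(c(a = "AA", b = "AA")),
               class = "size_error")
})

test_that("three-taxon branch lengths follow the closed form", {
  ids <- c("a", "b", "c")
  D <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, dimnames = list(ids, ids))
  tr <- nj_build(D)
  # l_a = (d_ab + d_ac - d_bc)/2 = 0, l_b = 2, l_c = 3
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[ids]), c(0, 2, 3), tolerance = 1e-9)
})

test_that("an additive 4-taxon matrix is reconstructed exactly", {
  D <- additive4()
  tr <- nj_build(D)
  # oracle: of the 3 unrooted 4-taxon topologies only ab|cd fits D;
  # verify split and every pairwise path length
  expect_equal(phangorn::RF.dist(tr, ape::read.tree(text = "((a,b),(c,d));")),
               0)
  path <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(path, D, tolerance = 1e-9)
})

test_that("neighbor-joining recovers random additive topologies", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    t0 <- ape::rtree(n, br = stats::runif(2 * n - 2, 0.1, 1))
    D <- ape::cophenetic.phylo(t0)
    tr <- nj_build(D)
    expect_equal(phangorn::RF.dist(ape::unroot(t0), tr), 0)
    # cross-check against the independent reference implementation
    expect_equal(phangorn::RF.dist(ape::nj(as.dist(D)), tr), 0)
  }
})

test_that("equidistant taxa are joined by the lexicographic tie rule", {
  ids <- c("a", "b", "c", "d")
  D <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(D) <- 0
  tr <- nj_build(D)
  # the first join must be the lexicographically smallest pair (a, b)
  expect_equal(phangorn::RF.dist(tr, ape::read.tree(text = "((a,b),(c,d));")),
               0)
})

test_that("invalid distance matrices are rejected", {
  D <- additive4()
  D[1, 2] <- 99
  expect_error(nj_build(D), class = "validation_error")
  expect_error(nj_build(additive4()[1:2, 1:2]), class = "size_error")
})

test_that("negative branch-length estimates are clamped and counted", {
  ids <- c("a", "b", "c", "d")
  # a strongly non-additive matrix known to push NJ estimates negative
  D <- matrix(c(0, 1, 5, 5,
                1, 0, 5, 5,
                5, 5, 0, 1,
                5, 5, 1, 0), 4, dimnames = list(ids, ids))
  D["a", "b"] <- D["b", "a"] <- 6
  tr <- nj_build(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("a perfectly congruent alignment gives full support to its split", {
  # every column separates {A*} from {B*}
  seqs <- c(A1 = strrep("A", 40), A2 = strrep("A", 40),
            A3 = strrep("A", 40), B1 = strrep("C", 40),
            B2 = strrep("C", 40), B3 = strrep("C", 40))
  bt <- bootstrap_consensus(seqs, B = 50, seed = 4, aligned = TRUE)
  sup <- as.numeric(bt$full_tree$node.label)
  expect_true(all(sup == 100))
})

test_that("bootstrap supports are reproducible under a fixed seed", {
  set.seed(8)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- sample(AA20, k, replace = TRUE)
    paste(ch, collapse = "")
  }
  base1 <- random_protein(60); base2 <- random_protein(60)
  seqs <- c(setNames(vapply(1:4, function(i) mut(base1, 3), ""), paste0("A", 1:4)),
            setNames(vapply(1:4, function(i) mut(base2, 3), ""), paste0("B", 1:4)))
  b1 <- bootstrap_consensus(seqs, B = 60, seed = 11, aligned = TRUE)
  b2 <- bootstrap_consensus(seqs, B = 60, seed = 11, aligned = TRUE)
  expect_identical(ape::write.tree(b1$full_tree), ape::write.tree(b2$full_tree))
  expect_identical(b1$consensus$node.label, b2$consensus$node.label)
  # strong two-clade structure: the separating split is near-unanimous
  tipsets <- phangorn::Descendants(b1$full_tree,
                                   length(seqs) + seq_len(b1$full_tree$Nnode),
                                   type = "tips")
  tips <- b1$full_tree$tip.label
  sep <- which(vapply(tipsets, function(d) {
    setequal(tips[d], paste0("A", 1:4)) || setequal(tips[d], paste0("B", 1:4))
  }, logical(1)))
  sup <- as.numeric(b1$full_tree$node.label)
  expect_true(all(sup[sep] >= 95))
})

test_that("consensus splits all appear in a majority of replicates", {
  set.seed(21)
  seqs <- setNames(vapply(1:6, function(i) random_protein(40), ""),
                   paste0("t", 1:6))
  bt <- bootstrap_consensus(seqs, B = 80, seed = 3, aligned = TRUE)
  sup <- as.numeric(bt$consensus$node.label)
  expect_true(all(sup >= 50))
  expect_true(all(sup <= 100))
})

test_that("B = 0 is a configuration error", {
  expect_error(bootstrap_consensus(c(a = "AA", b = "AC", c = "CC"), B = 0),
               class = "configuration_error")
})

test_that("a domain set configured like a full survey carries 468 leaves", {
  # 293 query domains + 132 + 43 labelled references
  qs <- setNames(rep("ACDE", 293), sprintf("Q%03d", 1:293))
  r1 <- setNames(rep("ACDF", 132), sprintf("R%03d", 1:132))
  r2 <- setNames(rep("ACDG", 43), sprintf("L%02d", 1:43))
  labels <- setNames(rep("x", 175), c(names(r1), names(r2)))
  set <- domain_set(c(qs, r1, r2), clade_labels = labels)
  expect_equal(length(set$sequences), 468L)
  expect_equal(sum(set$roles == "reference"), 175L)
  expect_equal(sum(set$roles == "query"), 293L)
})

test_that("clade assignment resolves the textbook cases", {
  labels <- c(r25 = "25", a1 = "x", a2 = "x", b1 = "y", b2 = "y")
  # query sister to a single clade-25 reference
  t1 <- ape::read.tree(
    text = "((q:1,r25:1):1,(a1:1,a2:1):1,(b1:1,b2:1):1);")
  cl <- assign_clades(t1, labels, queries = "q")
  expect_equal(cl$clade, "25")

  # query equidistant between two equally sized label sets -> unresolved
  t2 <- ape::read.tree(text = "((q:1,(a1:1,b1:1):1):1,a2:5,b2:5);")
  cl2 <- assign_clades(t2, labels[c("a1", "b1", "a2", "b2")], queries = "q")
  expect_equal(cl2$clade, "unresolved")

  # five queries in a reference-free subtree between clades
  qs <- paste0("(", paste(sprintf("q%d:1", 1:5), collapse = ","), ")")
  t3 <- ape::read.tree(text = paste0(
    "(", qs, ":1,(a1:1,a2:1):1,(b1:1,b2:1):1);"))
  cl3 <- assign_clades(t3, labels[c("a1", "a2", "b1", "b2")])
  expect_equal(unique(cl3$clade), "lineage-specific:1")
  expect_equal(nrow(cl3), 5L)

  # a query-only subtree nested inside one clade takes that clade's label
  t4 <- ape::read.tree(text = "(((q1:1,q2:1):1,(a1:1,a2:1):1):1,b1:4,b2:4);")
  cl4 <- assign_clades(t4, labels[c("a1", "a2", "b1", "b2")],
                       queries = c("q1", "q2"))
  expect_equal(cl4$clade, c("x", "x"))
})

test_that("a long-stemmed query group beside one clade is lineage-specific", {
  # context is a single clade (x) but the group sits far outside the
  # spread of its references
  tr <- ape::read.tree(text = "((q1:3,q2:3):3,a1:1,a2:1);")
  labels <- c(a1 = "x", a2 = "x")
  cl <- assign_clades(tr, labels)
  expect_equal(unique(cl$clade), "lineage-specific:1")
  # with the distance criterion disabled the group is absorbed into x
  cl2 <- assign_clades(tr, labels, ls_distance_factor = Inf)
  expect_equal(unique(cl2$clade), "x")
})

test_that("queries missing from the tree raise a lookup error", {
  t1 <- ape::read.tree(text = "((q:1,r:1):1,s:1,u:1);")
  expect_error(assign_clades(t1, c(r = "x"), queries = "nope"),
               class = "lookup_error")
})

test_that("unsupported splits are ignored when anchoring assignments", {
  # the small clade holding q has support 10 (< threshold): assignment must
  # fall through to the larger supported side and use all its references
  t1 <- ape::read.tree(
    text = "(((q:1,a1:1)10:1,(a2:1,a3:1)90:1)95:1,b1:4,b2:4);")
  labels <- c(a1 = "x", a2 = "x", a3 = "x", b1 = "y", b2 = "y")
  cl <- assign_clades(t1, labels, queries = "q", threshold = 50)
  expect_equal(cl$clade, "x")
  expect_equal(cl$support, 95)
})
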