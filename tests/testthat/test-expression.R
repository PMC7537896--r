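test_that("FPKM follows the definition and its invariances", {
  cm <- matrix(c(10, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  f <- fpkm(cm, c(g1 = 1000, g2 = 500), c(s1 = 1e6))
  expect_equal(f["g1", "s1"], 10)
  expect_equal(f["g2", "s1"], 0)

  # doubling all counts of a sample together with its total changes nothing
  cm2 <- matrix(sample(0:50, 12), 4, 3,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  lens <- setNames(c(1000, 1500, 200, 3000), rownames(cm2))
  tots <- setNames(c(1e6, 2e6, 5e5), colnames(cm2))
  f1 <- fpkm(cm2, lens, tots)
  cm3 <- cm2; cm3[, 2] <- cm3[, 2] * 2
  tots2 <- tots; tots2[2] <- tots2[2] * 2
  expect_equal(fpkm(cm3, lens, tots2), f1)

  expect_error(fpkm(cm, c(g1 = 1000, g2 = 500), c(s1 = 0)),
               class = "per_sample_error")
  expect_error(fpkm(cm, c(g1 = 0, g2 = 500), c(s1 = 1e6)),
               class = "validation_error")
})

test_that("fixture rows classify as printed: silent, ubiquitous, leaf-only", {
  m <- read_expression()
  cb <- classify_breadth(m)
  cls <- setNames(cb$class, cb$gene_id)
  expect_equal(unname(cls["Ma00_g04960"]), "none")
  expect_equal(unname(cls["Ma11_g06880"]), "all_samples")
  leaf_only <- c("Ma02_g16570", "Ma03_g09310", "Ma07_g11110",
                 "Ma10_g01730", "Ma10_g05260", "Ma10_g09100")
  excl <- setNames(cb$exclusive_organ, cb$gene_id)
  expect_equal(unname(excl[leaf_only]), rep("leaf", 6))
})

test_that("unmapped samples are a configuration error", {
  m <- matrix(1, 1, 1, dimnames = list("g", "mystery_sample"))
  expect_error(classify_breadth(m), class = "configuration_error")
})

test_that("breadth classes partition the genes and respect thresholds", {
  m <- read_expression()
  cb0 <- classify_breadth(m, threshold = 0)
  expect_equal(sum(cb0$class == "all_samples") + sum(cb0$class == "none") +
                 sum(cb0$class == "some"), nrow(m))
  # raising the threshold never resurrects expression
  prev <- cb0
  for (thr in c(1, 5, 20)) {
    cur <- classify_breadth(m, threshold = thr)
    expect_true(all(!(prev$class == "none" & cur$class != "none")))
    expect_true(all(cur$n_organs <= prev$n_organs))
    prev <- cur
  }
})

test_that("per-organ counts match a hand-built example", {
  om <- c(e = "embryogenic", s = "seedling", r = "root", l = "leaf",
          pu = "pulp", pe = "peel")
  m <- rbind(
    root_only = c(0, 0, 5, 0, 0, 0),
    leaf_only = c(0, 0, 0, 5, 0, 0),
    everywhere = c(1, 1, 1, 1, 1, 1))
  colnames(m) <- names(om)
  oc <- organ_expressed_counts(classify_breadth(m, om))
  cnt <- setNames(oc$count, oc$organ)
  expect_equal(unname(cnt[c("root", "leaf")]), c(2L, 2L))
  expect_equal(unname(cnt[c("embryogenic", "seedling", "pulp", "peel")]),
               rep(1L, 4))
  expect_equal(oc$percent, round(100 * oc$count / 3, 1), tolerance = 0.051)

  zero <- matrix(0, 2, 6, dimnames = list(c("a", "b"), names(om)))
  oc0 <- organ_expressed_counts(classify_breadth(zero, om))
  expect_true(all(oc0$count == 0))
})

test_that("paralog comparison reports correlation and organ overlap", {
  m <- read_expression()
  same <- compare_paralogs(m, c("Ma11_g06880", "Ma11_g06880"))
  expect_equal(same$pearson, 1)
  expect_equal(same$jaccard, 1)

  # independent oracle from the printed rows: organ sets by direct
  # column grouping
  organ_sets <- function(gene) {
    om <- default_organ_map()
    v <- m[gene, ]
    sort(unique(unname(om[names(v)[v > 0]])))
  }
  p1 <- compare_paralogs(m, c("Ma03_g07840", "Ma03_g07850"))
  s1 <- organ_sets("Ma03_g07840"); s2 <- organ_sets("Ma03_g07850")
  expect_equal(p1$jaccard,
               length(intersect(s1, s2)) / length(union(s1, s2)))
  expect_true(all(c("root", "leaf", "pulp", "peel") %in% s1))
  expect_true(all(c("root", "leaf", "pulp", "peel") %in% s2))

  p2 <- compare_paralogs(m, c("Ma07_g19880", "Ma07_g19890"))
  expect_lte(p2$jaccard, 0.2)  # second copy nearly silent
  expect_error(compare_paralogs(m, c("Ma07_g19880", "nope")),
               class = "lookup_error")
})

test_that("planted breadth classes are recovered exactly at threshold 0", {
  spec <- family_spec(n_per_type = c(none = 0, `1R` = 0, R2R3 = 60,
                                     `3R` = 2, `4R` = 1), seed = 55)
  b <- generate_family(spec)
  f <- fpkm(b$counts, b$lengths, b$totals)
  cb <- classify_breadth(f, b$organ_map)
  man <- b$manifest[b$manifest$retained, ]
  i <- match(man$gene_id, cb$gene_id)
  expect_equal(cb$class[i], man$breadth_class)
  got_organs <- lapply(seq_len(nrow(cb)), function(r) {
    oc <- grep("^organ_", names(cb), value = TRUE)
    sort(sub("^organ_", "", oc[as.logical(cb[r, oc])]))
  })
  expect_equal(got_organs[i],
               lapply(man$organs, sort), ignore_attr = TRUE)
})
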