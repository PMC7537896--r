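write_test_gff <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("a single gene with three exons parses to n_exons = 3", {
  gff <- write_test_gff(c(
    "Ma01\tsrc\tgene\t100\t900\t.\t+\t.\tID=g1",
    "Ma01\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=g1.t1;Parent=g1",
    "Ma01\tsrc\texon\t100\t200\t.\t+\t.\tParent=g1.t1",
    "Ma01\tsrc\texon\t300\t500\t.\t+\t.\tParent=g1.t1",
    "Ma01\tsrc\texon\t700\t900\t.\t+\t.\tParent=g1.t1"))
  m <- parse_gff(gff)
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_exons, 3L)
  expect_equal(m$start, 100L)
  expect_equal(m$end, 900L)
})

test_that("minus-strand exons are reported in ascending genomic order", {
  gff <- write_test_gff(c(
    "Ma02\tsrc\tgene\t100\t900\t.\t-\t.\tID=g2",
    "Ma02\tsrc\tmRNA\t100\t900\t.\t-\t.\tID=g2.t1;Parent=g2",
    "Ma02\tsrc\texon\t700\t900\t.\t-\t.\tParent=g2.t1",
    "Ma02\tsrc\texon\t100\t200\t.\t-\t.\tParent=g2.t1"))
  m <- parse_gff(gff)
  expect_equal(m$strand, "-")
  ex <- attr(m, "exons")[["g2"]]
  expect_equal(ex$start, c(100L, 700L))
})

test_that("CDS-based counting is available behind the flag", {
  gff <- write_test_gff(c(
    "Ma03\tsrc\tgene\t100\t900\t.\t+\t.\tID=g3",
    "Ma03\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=g3.t1;Parent=g3",
    "Ma03\tsrc\texon\t100\t400\t.\t+\t.\tParent=g3.t1",
    "Ma03\tsrc\texon\t600\t900\t.\t+\t.\tParent=g3.t1",
    "Ma03\tsrc\tCDS\t150\t400\t.\t+\t0\tParent=g3.t1",
    "Ma03\tsrc\tCDS\t600\t700\t.\t+\t0\tParent=g3.t1",
    "Ma03\tsrc\tCDS\t750\t850\t.\t+\t0\tParent=g3.t1"))
  expect_equal(parse_gff(gff)$n_exons, 2L)
  expect_equal(parse_gff(gff, count = "cds")$n_exons, 3L)
})

test_that("features without parents are a parse error", {
  gff <- write_test_gff(c(
    "Ma01\tsrc\tgene\t100\t900\t.\t+\t.\tID=g1",
    "Ma01\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=g1.t1;Parent=g1",
    "Ma01\tsrc\texon\t100\t200\t.\t+\t.\tID=orphan"))
  expect_error(parse_gff(gff), class = "parse_error")
})

test_that("generated gene models round-trip through GFF3", {
  spec <- family_spec(n_per_type = c(none = 5, `1R` = 5, R2R3 = 35,
                                     `3R` = 3, `4R` = 2), seed = 402)
  b <- generate_family(spec)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(b$gff, gff)
  m <- parse_gff(gff)
  man <- b$manifest
  expect_setequal(m$gene_id, man$gene_id)
  i <- match(man$gene_id, m$gene_id)
  expect_equal(m$n_exons[i], man$n_exons)
  expect_equal(m$chrom[i], man$chrom)
  expect_equal(m$start[i], man$start)
  expect_equal(m$end[i], man$end)
  expect_equal(m$strand[i], man$strand)
})

test_that("exon histogram counts partition the filtered set", {
  cat <- read_catalog()
  eh <- exon_histogram(cat, "R2R3")
  expect_equal(sum(eh$count), sum(cat$myb_type == "R2R3"))
  eh_all <- exon_histogram(cat, NULL)
  expect_equal(sum(eh_all$count), nrow(cat))
  expect_equal(nrow(exon_histogram(cat, "no-such-type")), 0L)
})

test_that("chromosome counts sum to the catalog size", {
  cat <- read_catalog()
  cd <- chromosome_distribution(cat)
  expect_equal(sum(cd$by_chrom), cd$total)
  expect_equal(cd$placed + cd$unplaced, cd$total)

  one <- data.frame(gene_id = sprintf("Ma05_g%05d", 1:7),
                    chrom = rep("Ma05", 7))
  cd1 <- chromosome_distribution(one)
  expect_equal(unname(cd1$by_chrom["Ma05"]), 7L)
  expect_equal(sum(cd1$by_chrom != 0), 1L)
})

test_that("family shares round half-up to two significant figures", {
  expect_equal(family_share(0, 100), 0)
  expect_equal(family_share(1, 3), 33)
  expect_error(family_share(5, 0), class = "division_error")
})

test_that("catalog assembly retains multi-repeat and CDC5 genes only", {
  summ <- data.frame(
    protein_id = c("Ma01_g00010", "Ma01_g00020", "Ma01_g00030",
                   "Ma02_g00010"),
    n_repeats = c(2L, 3L, 1L, 2L),
    myb_type = c("R2R3", "3R", "1R", "R2R3"),
    retained = c(TRUE, TRUE, FALSE, TRUE))
  models <- data.frame(
    gene_id = summ$protein_id,
    chrom = c("Ma01", "Ma01", "Ma01", "Ma02"),
    start = c(500L, 100L, 900L, 50L), end = c(700L, 300L, 950L, 90L),
    strand = "+", n_exons = c(3L, 7L, 1L, 2L))
  motifs <- data.frame(protein_id = "Ma01_g00010", start = 1L, end = 20L,
                       matched = "DLAARAAALAAAAAALAAAR")
  cat <- build_catalog(summ, motifs, models)
  expect_equal(nrow(cat), 3L)
  expect_false("Ma01_g00030" %in% cat$gene_id)
  # ordered by chromosome then start
  expect_equal(cat$gene_id,
               c("Ma01_g00020", "Ma01_g00010", "Ma02_g00010"))
  expect_equal(cat$bhlh_motif, c(FALSE, TRUE, FALSE))

  # CDC5 supplied by annotation
  cat2 <- build_catalog(summ, motifs, models, cdc5_ids = "Ma01_g00030")
  expect_equal(nrow(cat2), 4L)
  expect_equal(cat2$myb_type[cat2$gene_id == "Ma01_g00030"], "2R/CDC5")

  # empty inputs give an empty catalog
  empty <- build_catalog(summ[0, ], motifs[0, ], models[0, ])
  expect_equal(nrow(empty), 0L)

  # a retained gene without a model is a reconciliation error
  expect_error(build_catalog(summ, motifs, models[-1, ]),
               class = "reconciliation_error")
})

test_that("the packaged catalog re-serialises losslessly", {
  cat <- read_catalog()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat, path)
  again <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = NULL)
  again$bhlh_motif <- as.logical(again$bhlh_motif)
  expect_equal(again, as.data.frame(cat), ignore_attr = TRUE)
  # and a second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  again2 <- again
  again2$chrom <- substr(again2$gene_id, 1, 4)
  write_catalog(again2[names(cat)], path2)
  expect_identical(readLines(path), readLines(path2))
})
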