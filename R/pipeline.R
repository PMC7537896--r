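# End-to-end orchestration: scan -> motif -> tree/clades -> catalog ->
# expression -> summary.

#' Run the full annotation pipeline
#'
#' Executes every stage on an input bundle (in-memory
#' [generate_family()] result, or a named list of file paths) and returns
#' the per-stage results plus a summary of the family statistics. Stages:
#' repeat scan and architecture classification; bHLH motif scan; optional
#' NJ/bootstrap tree of the detected-repeat concatenations against labelled
#' reference domains with clade assignment; gene-structure catalog;
#' FPKM and expression breadth.
#'
#' When `outdir` is given, per-stage TSVs, the Newick tree and a summary
#' JSON are written there.
#'
#' @param input a `family_bundle`, or a list with paths `proteins`, `gff`,
#'   `counts`, `lengths`, `totals`, and optionally `references`, `labels`,
#'   `organ_map`.
#' @param profile repeat profile for the scan stage.
#' @param min_score_frac detection threshold as a fraction of the profile
#'   self-score.
#' @param do_tree build the bootstrap tree and assign clades (skipped when
#'   no reference domains are available).
#' @param bootstrap_B bootstrap replicates for the tree stage.
#' @param seed seed for the bootstrap stream.
#' @param fpkm_threshold expression threshold for breadth classification.
#' @param cdc5_ids gene ids annotated as CDC5-like.
#' @param outdir optional output directory.
#' @param quiet suppress stage messages.
#' @return list of class `myb_run` with `scan`, `motifs`, `models`,
#'   `clades` (or NULL), `catalog`, `fpkm`, `breadth`, `summary`.
#' @export
run_all <- function(input, profile = default_myb_profile(),
                    min_score_frac = 0.5, do_tree = TRUE,
                    bootstrap_B = 100L, seed = 1L, fpkm_threshold = 0,
                    cdc5_ids = character(), outdir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[mybkit] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  from_bundle <- inherits(input, "family_bundle")
  proteins <- stage("input", {
    if (from_bundle) input$proteins else read_fasta(input$proteins)
  })
  say("scan: ", length(proteins), " proteins")
  scan <- stage("scan", scan_proteins(proteins, profile,
                                      min_score_frac = min_score_frac))
  say("motif scan")
  motifs <- stage("motif", scan_bhlh_motifs(proteins))
  models <- stage("structure", {
    if (from_bundle) input$models else parse_gff(input$gff)
  })
  clades <- NULL
  tree <- NULL
  refs <- if (from_bundle) input$reference_domains else {
    if (!is.null(input$references)) read_fasta(input$references) else NULL
  }
  labels <- if (from_bundle) input$labels else {
    if (!is.null(input$labels)) read_map_tsv(input$labels) else NULL
  }
  retained_ids <- scan$summary$protein_id[scan$summary$retained]
  if (do_tree && !is.null(refs) && length(retained_ids) >= 2L) {
    say("tree: ", length(retained_ids), " queries, ", length(refs),
        " references, B = ", bootstrap_B)
    tree <- stage("tree", {
      dom <- vapply(retained_ids, function(id) {
        h <- scan$architectures[[id]]$hits
        paste(substring(proteins[[id]], h$start, h$end), collapse = "")
      }, character(1))
      set <- domain_set(c(dom, refs), clade_labels = labels)
      bootstrap_consensus(set, B = bootstrap_B, seed = seed)
    })
    clades <- stage("clades", assign_clades(tree, labels,
                                            queries = retained_ids))
  }
  say("catalog")
  catalog <- stage("catalog", {
    build_catalog(scan, motifs, models, clade_assignments = clades,
                  cdc5_ids = cdc5_ids,
                  peptide_lengths = nchar(proteins))
  })
  say("expression")
  counts <- if (from_bundle) input$counts else read_counts_tsv(input$counts)
  lens <- if (from_bundle) input$lengths else read_map_tsv(input$lengths)
  tots <- if (from_bundle) input$totals else read_map_tsv(input$totals)
  omap <- if (from_bundle) input$organ_map else {
    if (!is.null(input$organ_map)) read_map_tsv(input$organ_map) else {
      default_organ_map()
    }
  }
  fpkm_m <- stage("expression", fpkm(counts, lens, tots))
  breadth <- stage("expression",
                   classify_breadth(fpkm_m, omap, fpkm_threshold))
  summary <- summarize_family(catalog, breadth)
  res <- structure(
    list(scan = scan, motifs = motifs, models = models, tree = tree,
         clades = clades, catalog = catalog, fpkm = fpkm_m,
         breadth = breadth, summary = summary, seed = seed),
    class = "myb_run"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_catalog(catalog, file.path(outdir, "catalog.tsv"))
    utils::write.table(scan$hits, file.path(outdir, "repeat_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(motifs, file.path(outdir, "motif_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(clades)) {
      utils::write.table(clades, file.path(outdir, "clades.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_newick(tree, file.path(outdir, "tree.nwk"))
    }
    utils::write.table(
      data.frame(gene_id = rownames(fpkm_m), round(fpkm_m, 3),
                 check.names = FALSE),
      file.path(outdir, "fpkm.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    bt <- breadth
    utils::write.table(bt, file.path(outdir, "breadth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  res
}

#' Summarise a family catalog and breadth classification
#'
#' The survey-style summary block: per-type counts, the R2R3 exon histogram,
#' chromosome distribution, bHLH count and flavonoid-clade cross-tab, and
#' expression breadth counts.
#'
#' @param catalog catalog data.frame ([build_catalog()] / [read_catalog()]).
#' @param breadth optional [classify_breadth()] result.
#' @param n_protein_coding,n_tf background gene counts for the family-share
#'   statistics; defaults are the DH-Pahang v2 annotation totals (35,276
#'   protein-coding genes, 3,155 transcription factor genes).
#' @return nested list of summary statistics.
#' @export
summarize_family <- function(catalog, breadth = NULL,
                             n_protein_coding = 35276, n_tf = 3155) {
  is_cdc5 <- catalog$myb_type %in% c("2R", "2R/CDC5")
  type_counts <- list(
    total = nrow(catalog),
    r2r3 = sum(catalog$myb_type == "R2R3"),
    myb3r = sum(catalog$myb_type == "3R"),
    myb4r = sum(catalog$myb_type == "4R"),
    cdc5 = sum(is_cdc5)
  )
  eh <- exon_histogram(catalog, "R2R3")
  cd <- chromosome_distribution(catalog)
  out <- list(
    types = type_counts,
    family_share = list(
      of_protein_coding = family_share(type_counts$r2r3, n_protein_coding),
      of_transcription_factors = family_share(type_counts$r2r3, n_tf)
    ),
    exon_histogram_r2r3 = eh,
    chromosomes = list(placed = cd$placed, unplaced = cd$unplaced,
                       by_chrom = as.list(cd$by_chrom)),
    bhlh = list(count = sum(catalog$bhlh_motif),
                crosstab = bhlh_crosstab(catalog))
  )
  if (!is.null(breadth) && nrow(breadth) > 0L) {
    oc <- organ_expressed_counts(breadth)
    out$expression <- list(
      genes = nrow(breadth),
      all_samples = sum(breadth$class == "all_samples"),
      none = sum(breadth$class == "none"),
      at_least_one = sum(breadth$class != "none"),
      by_organ = oc
    )
  }
  out
}

#' @export
print.myb_run <- function(x, ...) {
  s <- x$summary
  cat("mybkit run:", s$types$total, "catalog entries (",
      s$types$r2r3, "R2R3,", s$types$myb3r, "3R,", s$types$myb4r, "4R,",
      s$types$cdc5, "CDC5 ),", s$bhlh$count, "bHLH-flagged\n")
  invisible(x)
}
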