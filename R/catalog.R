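# Gene models, structure statistics and the per-gene family catalog.

#' Parse gene models from a GFF3 file
#'
#' Imports a GFF3 (via rtracklayer) and collapses the gene/mRNA/exon/CDS
#' hierarchy to one model per gene. The exon count is taken from the primary
#' transcript, defined as the transcript with the largest summed exon length
#' (ties: first by id); `count = "cds"` counts CDS segments instead of exon
#' features. Coordinates stay 1-based inclusive; exons are reported in
#' ascending genomic order regardless of strand.
#'
#' @param path GFF3 file.
#' @param count `"exon"` or `"cds"`.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `n_exons`, plus the per-gene exon coordinate table in the `"exons"`
#'   attribute (list of data.frames with `start`, `end`).
#' @export
parse_gff <- function(path, count = c("exon", "cds")) {
  count <- match.arg(count)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), n_exons = integer())
    attr(out, "exons") <- list()
    return(out)
  }
  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  feat_type <- if (count == "exon") "exon" else "CDS"
  feats <- df[df$type == feat_type, , drop = FALSE]
  if (nrow(feats) == 0L) {
    abort_kit("parse_error", "no ", feat_type, " features in ", path)
  }
  parent1 <- function(p) vapply(p, function(x) {
    if (length(x) == 0L) NA_character_ else as.character(x[[1]])
  }, character(1))
  feats$parent <- parent1(feats$Parent)
  if (anyNA(feats$parent)) {
    abort_kit("parse_error", "missing Parent on ", feat_type,
              " features in ", path)
  }
  tx$parent <- parent1(tx$Parent)
  if (anyNA(tx$parent)) {
    abort_kit("parse_error", "missing Parent on transcripts in ", path)
  }
  exon_list <- vector("list", nrow(genes))
  n_exons <- integer(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    gid <- genes$ID[g]
    gtx <- tx[tx$parent == gid, , drop = FALSE]
    if (nrow(gtx) == 0L) {
      abort_kit("parse_error", "gene ", gid, " has no transcript")
    }
    per_tx <- lapply(gtx$ID, function(tid) {
      fe <- feats[feats$parent == tid, , drop = FALSE]
      fe[order(fe$start), , drop = FALSE]
    })
    span <- vapply(per_tx, function(fe) sum(fe$end - fe$start + 1L),
                   numeric(1))
    primary <- per_tx[[which.max(span)]]
    exon_list[[g]] <- data.frame(start = primary$start, end = primary$end)
    n_exons[g] <- nrow(primary)
  }
  out <- data.frame(
    gene_id = as.character(genes$ID),
    chrom = as.character(genes$seqnames),
    start = genes$start, end = genes$end,
    strand = as.character(genes$strand),
    n_exons = n_exons, row.names = NULL
  )
  names(exon_list) <- out$gene_id
  ord <- order(chrom_rank(out$chrom), out$start)
  exon_list <- exon_list[ord]
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exons") <- exon_list
  out
}

# Ma01..Ma11 first, the unplaced Ma00 bin last, other names after that
chrom_rank <- function(chrom) {
  r <- match(chrom, c(paste0("Ma", sprintf("%02d", 1:11)), "Ma00"))
  r[is.na(r)] <- 99L
  r
}

#' Read the packaged banana MYB gene catalog
#'
#' The curated catalog of the 294 annotated MYB genes of the Musa acuminata
#' DH-Pahang v2 genome: position, strand, bHLH-motif flag, coding exon
#' count, peptide length, MYB type (`R2R3`, `3R`, `4R`, or `2R` for the
#' CDC5-like gene) and functional clade assignment.
#'
#' @param path TSV path; default the packaged fixture.
#' @return data.frame of catalog entries with a derived `chrom` column.
#' @export
read_catalog <- function(path = system.file("extdata", "table1_catalog.tsv",
                                            package = "mybkit")) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(synonym = "character",
                                        functional_assignment = "character"),
                         na.strings = NULL)
  x$bhlh_motif <- as.logical(x$bhlh_motif)
  x$chrom <- substr(x$gene_id, 1, 4)
  x <- x[order(chrom_rank(x$chrom), x$start), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Exon-count histogram with printed percents
#'
#' Counts catalog entries by exon number, restricted to one MYB type, with
#' percents of the filtered total rounded half-up to one decimal (the
#' convention of printed survey tables).
#'
#' @param entries catalog data.frame with `n_exons` and `myb_type`.
#' @param type_filter MYB type to keep (default `"R2R3"`); NULL keeps all.
#' @return data.frame with `n_exons`, `count`, `percent`.
#' @export
exon_histogram <- function(entries, type_filter = "R2R3") {
  if (!is.null(type_filter)) {
    entries <- entries[entries$myb_type %in% type_filter, , drop = FALSE]
  }
  if (nrow(entries) == 0L) {
    return(data.frame(n_exons = integer(), count = integer(),
                      percent = numeric()))
  }
  tab <- table(entries$n_exons)
  data.frame(
    n_exons = as.integer(names(tab)),
    count = as.integer(tab),
    percent = round_half_up(100 * as.integer(tab) / nrow(entries), 1),
    row.names = NULL
  )
}

#' Chromosomal distribution of catalog entries
#'
#' @param entries catalog data.frame with a `chrom` column (or gene ids
#'   carrying the `MaNN_` chromosome prefix).
#' @return list with `by_chrom` (named counts, Ma01..Ma11 then Ma00),
#'   `placed`, `unplaced`, `total`.
#' @export
chromosome_distribution <- function(entries) {
  chrom <- entries$chrom %||% substr(entries$gene_id, 1, 4)
  lev <- c(paste0("Ma", sprintf("%02d", 1:11)), "Ma00")
  cnt <- table(factor(chrom, levels = lev))
  list(by_chrom = c(cnt),
       placed = sum(cnt[lev != "Ma00"]),
       unplaced = unname(cnt["Ma00"]),
       total = length(chrom))
}

#' Share of a gene family in a background set
#'
#' `100 * n_family / n_background`, rounded half-up to two significant
#' figures -- the convention behind printed shares such as 0.81% of all
#' protein-coding genes and 9.0% of transcription factor genes.
#'
#' @param n_family,n_background counts; `n_background > 0`.
#' @param sig significant figures (default 2).
#' @return percent.
#' @export
#' @examples
#' family_share(285, 35276)  # 0.81
#' family_share(285, 3155)   # 9.0
family_share <- function(n_family, n_background, sig = 2) {
  if (n_background <= 0) {
    abort_kit("division_error", "n_background must be > 0")
  }
  signif_half_up(100 * n_family / n_background, sig)
}

#' Assemble the per-gene family catalog
#'
#' Joins repeat architectures, motif hits, gene models and clade
#' assignments into one catalog row per retained gene. A gene is retained
#' when its architecture has two or more repeats, or when it is listed in
#' `cdc5_ids` (CDC5-like proteins are supplied by annotation, not called
#' from sequence). Entries are ordered by chromosome (Ma01..Ma11, then the
#' unplaced Ma00 bin) and start coordinate.
#'
#' @param scan result of [scan_proteins()] (or its `summary` data.frame).
#' @param motif_hits data.frame from [scan_bhlh_motifs()].
#' @param models gene models from [parse_gff()].
#' @param clade_assignments optional data.frame from [assign_clades()].
#' @param cdc5_ids gene ids to annotate as CDC5-like (`2R/CDC5`).
#' @param peptide_lengths optional named integer vector of protein lengths.
#' @return catalog data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `bhlh_motif`, `n_exons`, `peptide_length`, `myb_type`,
#'   `functional_assignment`).
#' @export
build_catalog <- function(scan, motif_hits, models,
                          clade_assignments = NULL,
                          cdc5_ids = character(),
                          peptide_lengths = NULL) {
  summ <- if (is.data.frame(scan)) scan else scan$summary
  keep <- summ$retained | summ$protein_id %in% cdc5_ids
  ids <- summ$protein_id[keep]
  if (length(ids) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), bhlh_motif = logical(),
                      n_exons = integer(), peptide_length = integer(),
                      myb_type = character(),
                      functional_assignment = character()))
  }
  missing <- setdiff(ids, models$gene_id)
  if (length(missing)) {
    abort_kit("reconciliation_error",
              "retained genes without a gene model: ",
              paste(missing, collapse = ", "))
  }
  mi <- match(ids, models$gene_id)
  type <- summ$myb_type[keep]
  type[ids %in% cdc5_ids] <- "2R/CDC5"
  assign <- rep("", length(ids))
  if (!is.null(clade_assignments)) {
    m <- match(ids, clade_assignments$query_id)
    assign[!is.na(m)] <- clade_assignments$clade[m[!is.na(m)]]
  }
  plen <- if (is.null(peptide_lengths)) rep(NA_integer_, length(ids)) else {
    as.integer(peptide_lengths[ids])
  }
  out <- data.frame(
    gene_id = ids,
    chrom = models$chrom[mi],
    start = models$start[mi],
    end = models$end[mi],
    strand = models$strand[mi],
    bhlh_motif = ids %in% motif_hits$protein_id,
    n_exons = models$n_exons[mi],
    peptide_length = plen,
    myb_type = type,
    functional_assignment = assign,
    row.names = NULL
  )
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# The five flavonoid-related functional labels relevant to the MBW
# (MYB-bHLH-WD40) cross-tabulation, keyed by the clade they mark.
FLAVONOID_CLADE_LABELS <- list(
  "22" = "repressors PP, sinapate, lignin",
  "23" = "general flavonoid, trichome",
  "24" = "anthocyanins",
  "25" = "proanthocyanidins",
  "27" = c("flavonoid repressor", "starch degradation, flavonoid repressor")
)

#' Cross-tabulate bHLH-flagged genes by flavonoid-related clade
#'
#' Among catalog entries carrying the bHLH-interaction motif, counts the
#' members of each flavonoid-related functional clade (22: phenylpropanoid /
#' sinapate / lignin repressors, 23: general flavonoid and trichome, 24:
#' anthocyanins, 25: proanthocyanidins, 27: flavonoid repressors) plus the
#' flagged genes with no functional assignment (in the banana survey these
#' fall in the lineage-specific clade 26) and any flagged genes with other
#' assignments.
#'
#' @param entries catalog data.frame with `bhlh_motif` and
#'   `functional_assignment`.
#' @return data.frame with `clade`, `count`; includes rows `unassigned`
#'   and `other`.
#' @export
bhlh_crosstab <- function(entries) {
  fl <- entries[entries$bhlh_motif, , drop = FALSE]
  assign <- trimws(fl$functional_assignment)
  counted <- rep(FALSE, nrow(fl))
  rows <- lapply(names(FLAVONOID_CLADE_LABELS), function(cl) {
    hit <- assign %in% FLAVONOID_CLADE_LABELS[[cl]]
    counted[hit] <<- TRUE
    data.frame(clade = cl, count = sum(hit))
  })
  unass <- assign == ""
  counted[unass] <- TRUE
  out <- rbind(do.call(rbind, rows),
               data.frame(clade = "unassigned", count = sum(unass)),
               data.frame(clade = "other", count = sum(!counted)))
  rownames(out) <- NULL
  out
}

#' Write a catalog as TSV
#'
#' @param entries catalog data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_catalog <- function(entries, path) {
  out <- entries
  if (is.logical(out$bhlh_motif)) out$bhlh_motif <- as.integer(out$bhlh_motif)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
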