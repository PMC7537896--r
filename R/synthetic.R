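# Synthetic family generator: proteins with planted MYB repeats and bHLH
# motifs, GFF3 gene models, organ-structured count matrices, reference
# domains with clade labels, and a truth manifest for oracle tests.

#' Specify a synthetic MYB family
#'
#' Defaults mirror the marginals of the banana survey the package models:
#' 285 R2R3 / 6 3R / 2 4R retained genes plus background proteins without a
#' multi-repeat domain; the exon-count distribution and the unplaced-gene
#' fraction follow the published catalog; roughly one retained gene in ten
#' carries a bHLH-interaction motif; expression breadth fractions follow the
#' published all-sample/none counts. Sizes and rates are freely
#' overridable for smaller test bundles.
#'
#' @param n_per_type named counts of generated genes per architecture
#'   (`none`, `1R`, `R2R3`, `3R`, `4R`).
#' @param profile repeat profile whose consensus is planted.
#' @param mutation_rate per-residue substitution rate applied to planted
#'   repeat copies (0 = exact copies).
#' @param clade_divergence per-residue rate separating clade ancestor
#'   repeats from the profile consensus.
#' @param motif_fraction probability that a retained gene carries a planted
#'   bHLH motif.
#' @param exon_probs probability over 1..12 coding exons.
#' @param unplaced_fraction probability a gene lands in the unplaced `Ma00`
#'   bin instead of `Ma01`..`Ma11`.
#' @param n_clades number of R2R3 clades.
#' @param unlabeled_clades how many of the `n_clades` get no reference
#'   domains -- the lineage-specific analogue (the banana survey found 7 of
#'   its 42 R2R3 clades to be banana-only; one in eight keeps that ratio).
#' @param refs_per_clade labelled reference domains generated per clade.
#' @param p_none,p_all breadth-class probabilities (`some` takes the rest).
#' @param p_organ per-organ inclusion probability for `some` genes.
#' @param p_exclusive probability a `some` gene is organ-exclusive.
#' @param fpkm_meanlog,fpkm_sdlog log-normal parameters of expressed FPKM.
#' @param total_fragments mapped fragments per sample.
#' @param seed master seed; named substreams (`sequence`, `structure`,
#'   `expression`) are derived from it.
#' @return list of class `family_spec`.
#' @export
family_spec <- function(n_per_type = c(none = 50, `1R` = 50, R2R3 = 285,
                                       `3R` = 6, `4R` = 2),
                        profile = default_myb_profile(),
                        mutation_rate = 0.05,
                        clade_divergence = 0.15,
                        motif_fraction = 30 / 294,
                        exon_probs = c(7, 23, 155, 67, 21, 8, 2, 0, 0, 0,
                                       0, 2) / 285,
                        unplaced_fraction = 3 / 294,
                        n_clades = 8L,
                        unlabeled_clades = 1L,
                        refs_per_clade = 3L,
                        p_none = 13 / 293,
                        p_all = 40 / 293,
                        p_organ = 0.5,
                        p_exclusive = 0.15,
                        fpkm_meanlog = 2,
                        fpkm_sdlog = 1,
                        total_fragments = 2e7,
                        seed = 1L) {
  probs <- c(mutation_rate, clade_divergence, motif_fraction,
             unplaced_fraction, p_none, p_all, p_organ, p_exclusive)
  if (any(probs < 0 | probs > 1) || any(n_per_type < 0)) {
    abort_kit("generation_error", "invalid spec: probabilities must lie in ",
              "[0,1] and counts must be >= 0")
  }
  if (abs(sum(exon_probs) - 1) > 1e-8 || length(exon_probs) != 12L) {
    abort_kit("generation_error", "exon_probs must be 12 values summing to 1")
  }
  if (unlabeled_clades >= n_clades) {
    abort_kit("generation_error", "unlabeled_clades must be < n_clades")
  }
  structure(as.list(environment()), class = "family_spec")
}

random_aa <- function(n) {
  paste(sample(AA_ALPHABET21[1:20], n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(AA_ALPHABET21[1:20], ch[i]), 1)
  }
  paste(ch, collapse = "")
}

random_bhlh_motif <- function() {
  ch <- strsplit(random_aa(20), "", fixed = TRUE)[[1]]
  ch[1] <- sample(c("D", "E"), 1)
  ch[2] <- "L"
  ch[5] <- sample(c("R", "K"), 1)
  ch[9] <- "L"
  ch[16] <- "L"
  ch[20] <- "R"
  paste(ch, collapse = "")
}

#' Generate a synthetic family bundle
#'
#' Deterministic given `spec$seed`. Produces in-memory data plus, when `dir`
#' is given, the file set a real survey would consume: protein FASTA, GFF3
#' gene models, counts/lengths/totals TSVs, a reference-clade label TSV and
#' a JSON manifest of the planted truth.
#'
#' @param spec a [family_spec()].
#' @param dir optional output directory (created if missing).
#' @return list of class `family_bundle` with `proteins`, `domains`
#'   (planted repeat concatenations), `reference_domains`, `labels`, `gff`
#'   (lines), `models`, `counts`, `lengths`, `totals`, `organ_map`, and
#'   `manifest` (per-gene truth data.frame with list-columns
#'   `repeat_intervals` and `organs`).
#' @export
generate_family <- function(spec = family_spec(), dir = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  types <- rep(names(spec$n_per_type), spec$n_per_type)
  n <- length(types)
  if (n == 0L) abort_kit("generation_error", "spec generates no genes")
  n_rep <- c(none = 0L, `1R` = 1L, R2R3 = 2L, `3R` = 3L, `4R` = 4L)[types]

  ## -- structure stream: chromosomes, coordinates, ids, exon models --------
  set.seed(derive_seed(spec$seed, "structure"))
  chroms <- ifelse(stats::runif(n) < spec$unplaced_fraction, "Ma00",
                   sample(paste0("Ma", sprintf("%02d", 1:11)), n,
                          replace = TRUE))
  pos <- sample.int(4e7, n)
  ord <- order(chrom_rank(chroms), pos)
  chroms <- chroms[ord]; pos <- pos[ord]
  # position-ordered locus numbers within each chromosome
  idx_in_chrom <- stats::ave(seq_len(n), chroms, FUN = seq_along)
  ids <- sprintf("%s_g%05d", chroms, idx_in_chrom * 10L)
  types <- sample(types)               # architecture independent of locus
  n_rep <- c(none = 0L, `1R` = 1L, R2R3 = 2L, `3R` = 3L, `4R` = 4L)[types]
  n_ex <- sample.int(12L, n, replace = TRUE, prob = spec$exon_probs)
  exon_models <- vector("list", n)
  gene_end <- integer(n)
  for (g in seq_len(n)) {
    el <- sample(60:300, n_ex[g], replace = TRUE)
    il <- if (n_ex[g] > 1L) sample(80:1500, n_ex[g] - 1L, replace = TRUE)
          else integer(0)
    starts <- pos[g] + cumsum(c(0L, el[-n_ex[g]] + il))
    exon_models[[g]] <- data.frame(start = starts, end = starts + el - 1L)
    gene_end[g] <- starts[n_ex[g]] + el[n_ex[g]] - 1L
  }
  strands <- sample(c("+", "-"), n, replace = TRUE)

  ## -- sequence stream: clades, repeats, proteins, motifs ------------------
  set.seed(derive_seed(spec$seed, "sequence"))
  consensus <- spec$profile$consensus
  clade_names <- paste0("clade_", seq_len(spec$n_clades))
  clade_repeat <- vapply(clade_names, function(cl) {
    mutate_seq(consensus, spec$clade_divergence)
  }, character(1))
  clade_repeat <- c(clade_repeat,
                    MYB3R = mutate_seq(consensus, spec$clade_divergence),
                    MYB4R = mutate_seq(consensus, spec$clade_divergence))
  clade <- rep(NA_character_, n)
  clade[types == "R2R3"] <- sample(clade_names, sum(types == "R2R3"),
                                   replace = TRUE)
  clade[types == "3R"] <- "MYB3R"
  clade[types == "4R"] <- "MYB4R"
  proteins <- character(n)
  domains <- rep(NA_character_, n)
  rep_intervals <- vector("list", n)
  has_motif <- rep(FALSE, n)
  motif_start <- rep(NA_integer_, n)
  for (g in seq_len(n)) {
    k <- n_rep[g]
    if (k == 0L) {
      proteins[g] <- random_aa(sample(150:400, 1))
      rep_intervals[[g]] <- data.frame(start = integer(), end = integer())
      next
    }
    base <- if (is.na(clade[g])) consensus else clade_repeat[[clade[g]]]
    reps <- vapply(seq_len(k), function(i) {
      mutate_seq(base, spec$mutation_rate)
    }, character(1))
    linkers <- vapply(seq_len(k + 1L), function(i) {
      random_aa(sample(15:40, 1))
    }, character(1))
    if (k >= 2L && stats::runif(1) < spec$motif_fraction) {
      motif <- random_bhlh_motif()
      tail_link <- linkers[k + 1L]
      at <- sample.int(nchar(tail_link) - 1L, 1)
      linkers[k + 1L] <- paste0(substr(tail_link, 1, at), motif,
                                substr(tail_link, at + 1L,
                                       nchar(tail_link)))
      has_motif[g] <- TRUE
      motif_at_tail <- at + 1L
    }
    pieces <- character(0)
    offset <- 0L
    iv <- data.frame(start = integer(k), end = integer(k))
    for (i in seq_len(k)) {
      pieces <- c(pieces, linkers[i], reps[i])
      offset <- offset + nchar(linkers[i])
      iv$start[i] <- offset + 1L
      iv$end[i] <- offset + nchar(reps[i])
      offset <- offset + nchar(reps[i])
    }
    pieces <- c(pieces, linkers[k + 1L])
    proteins[g] <- paste(pieces, collapse = "")
    if (has_motif[g]) motif_start[g] <- offset + motif_at_tail
    rep_intervals[[g]] <- iv
    domains[g] <- paste(reps, collapse = "")
  }
  names(proteins) <- ids
  # labelled reference domains per clade; the last `unlabeled_clades` R2R3
  # clades get none and so should surface as lineage-specific groups
  unlabeled <- if (spec$unlabeled_clades > 0L) {
    utils::tail(clade_names, spec$unlabeled_clades)
  } else character(0)
  ref_ids <- character(0); ref_seqs <- character(0); ref_clade <- character(0)
  for (cl in setdiff(names(clade_repeat), unlabeled)) {
    k_rep <- switch(cl, MYB3R = 3L, MYB4R = 4L, 2L)
    for (r in seq_len(spec$refs_per_clade)) {
      ref_ids <- c(ref_ids, sprintf("REF_%s_%d", cl, r))
      ref_seqs <- c(ref_seqs, paste(vapply(seq_len(k_rep), function(i) {
        mutate_seq(clade_repeat[[cl]], spec$mutation_rate)
      }, character(1)), collapse = ""))
      ref_clade <- c(ref_clade, cl)
    }
  }
  names(ref_seqs) <- ref_ids
  labels <- stats::setNames(ref_clade, ref_ids)

  ## -- expression stream ----------------------------------------------------
  set.seed(derive_seed(spec$seed, "expression"))
  organ_map <- default_organ_map()
  samples <- names(organ_map)
  retained <- n_rep >= 2L
  cls <- rep(NA_character_, n)
  organs <- vector("list", n)
  expressed <- matrix(FALSE, n, length(samples),
                      dimnames = list(ids, samples))
  for (g in which(retained)) {
    u <- stats::runif(1)
    if (u < spec$p_none) {
      cls[g] <- "none"; organs[[g]] <- character(0)
    } else if (u < spec$p_none + spec$p_all) {
      cls[g] <- "all_samples"
      organs[[g]] <- ORGAN_GROUPS
      expressed[g, ] <- TRUE
    } else {
      cls[g] <- "some"
      S <- if (stats::runif(1) < spec$p_exclusive) {
        sample(ORGAN_GROUPS, 1)
      } else {
        repeat {
          S0 <- ORGAN_GROUPS[stats::runif(6) < spec$p_organ]
          if (length(S0) >= 1L) break
        }
        S0
      }
      organs[[g]] <- S
      for (og in S) {
        ss <- samples[organ_map == og]
        on <- stats::runif(length(ss)) < 0.7
        if (!any(on)) on[sample.int(length(ss), 1)] <- TRUE
        expressed[g, ss] <- on
      }
      if (all(expressed[g, ])) {
        # keep `some` distinct from `all_samples`: pulp has 5 samples
        expressed[g, "pulpS4"] <- FALSE
      }
    }
  }
  lengths <- vapply(exon_models, function(e) sum(e$end - e$start + 1),
                    numeric(1))
  names(lengths) <- ids
  totals <- stats::setNames(rep(spec$total_fragments, length(samples)),
                            samples)
  counts <- matrix(0, n, length(samples), dimnames = list(ids, samples))
  ne <- sum(expressed)
  if (ne > 0L) {
    vals <- stats::rlnorm(ne, spec$fpkm_meanlog, spec$fpkm_sdlog)
    cnt <- round(vals * lengths[row(expressed)[expressed]] *
                   spec$total_fragments / 1e9)
    counts[expressed] <- pmax(1, cnt)
  }

  manifest <- data.frame(
    gene_id = ids, myb_type = types, n_repeats = unname(n_rep),
    retained = retained, chrom = chroms, start = pos, end = gene_end,
    strand = strands, n_exons = n_ex,
    peptide_length = nchar(proteins),
    has_motif = has_motif, motif_start = motif_start,
    clade = clade,
    clade_labeled = !is.na(clade) & !(clade %in% unlabeled),
    breadth_class = cls, row.names = NULL
  )
  manifest$repeat_intervals <- rep_intervals
  manifest$organs <- organs

  gff <- build_gff_lines(ids, chroms, pos, gene_end, strands, exon_models)
  models <- data.frame(gene_id = ids, chrom = chroms, start = pos,
                       end = gene_end, strand = strands, n_exons = n_ex,
                       row.names = NULL)
  bundle <- structure(
    list(proteins = proteins,
         domains = stats::setNames(domains, ids),
         reference_domains = ref_seqs, labels = labels,
         gff = gff, models = models,
         counts = counts, lengths = lengths, totals = totals,
         organ_map = organ_map, manifest = manifest,
         spec = spec),
    class = "family_bundle"
  )
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

build_gff_lines <- function(ids, chroms, starts, ends, strands,
                            exon_models) {
  out <- c("##gff-version 3")
  for (g in seq_along(ids)) {
    id <- ids[g]
    tid <- paste0(id, ".t1")
    row <- function(type, s, e, attrs) {
      paste(chroms[g], "mybkit", type, s, e, ".", strands[g], ".", attrs,
            sep = "\t")
    }
    out <- c(out,
             row("gene", starts[g], ends[g], paste0("ID=", id)),
             row("mRNA", starts[g], ends[g],
                 paste0("ID=", tid, ";Parent=", id)))
    em <- exon_models[[g]]
    for (e in seq_len(nrow(em))) {
      out <- c(out,
               row("exon", em$start[e], em$end[e], paste0("Parent=", tid)),
               row("CDS", em$start[e], em$end[e], paste0("Parent=", tid)))
    }
  }
  out
}

#' Write a synthetic bundle to disk
#'
#' @param bundle a [generate_family()] result.
#' @param dir output directory.
#' @return named character vector of the written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteins = file.path(dir, "proteins.fasta"),
    gff = file.path(dir, "genes.gff3"),
    counts = file.path(dir, "counts.tsv"),
    lengths = file.path(dir, "lengths.tsv"),
    totals = file.path(dir, "totals.tsv"),
    references = file.path(dir, "reference_domains.fasta"),
    labels = file.path(dir, "labels.tsv"),
    organ_map = file.path(dir, "organ_map.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_fasta(bundle$proteins, paths["proteins"])
  writeLines(bundle$gff, paths["gff"])
  write_named_tsv <- function(x, path, key, value) {
    utils::write.table(
      stats::setNames(data.frame(names(x), unname(x)), c(key, value)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cts <- data.frame(gene = rownames(bundle$counts), bundle$counts,
                    check.names = FALSE)
  utils::write.table(cts, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_named_tsv(bundle$lengths, paths["lengths"], "gene", "length")
  write_named_tsv(bundle$totals, paths["totals"], "sample", "total")
  write_fasta(bundle$reference_domains, paths["references"])
  write_named_tsv(bundle$labels, paths["labels"], "id", "clade")
  write_named_tsv(bundle$organ_map, paths["organ_map"], "sample", "organ")
  man <- bundle$manifest
  man$repeat_intervals <- lapply(man$repeat_intervals, as.list)
  jsonlite::write_json(man, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(paths)
}
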