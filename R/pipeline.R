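# End-to-end runner: read inputs, annotate, classify every contig, write the
# standard output trio (combined FASTA, score table, boundary table) plus a
# cached annotation that lets outputs be regenerated under new options
# without re-reading the hit table.

format_score <- function(x) sprintf("%.6f", x)

write_outputs <- function(anns, scores, preds, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  s <- scores
  score_cols <- setdiff(names(s), c("seqname", "max_score_group", "length"))
  for (cc in score_cols) s[[cc]] <- format_score(s[[cc]])
  utils::write.table(s, file.path(outdir, "final-viral-score.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  b <- preds[, c("contig_id", "start_bp", "end_bp", "first_gene",
                 "last_gene", "group", "score", "kind")]
  b$score <- format_score(b$score)
  utils::write.table(b, file.path(outdir, "final-viral-boundary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  seqs <- character(0)
  if (nrow(preds) > 0) {
    have_seq <- vapply(anns, function(a) !is.null(a$seq), logical(1))
    names(have_seq) <- vapply(anns, `[[`, character(1), "id")
    for (i in seq_len(nrow(preds))) {
      id <- preds$contig_id[i]
      if (!isTRUE(have_seq[[id]])) next
      a <- anns[[match(id, names(have_seq))]]
      nm <- if (preds$kind[i] == "full") paste0(id, "||", preds$group[i], "||full")
      else sprintf("%s||%s||%d-%d||%s", id, preds$group[i],
                   preds$start_bp[i], preds$end_bp[i], preds$kind[i])
      seqs[nm] <- substr(a$seq, preds$start_bp[i], preds$end_bp[i])
    }
  }
  fa <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(fa, file.path(outdir, "final-viral-combined.fa"))
  invisible(outdir)
}

write_cache <- function(anns, outdir) {
  flat <- flatten_annotation(anns)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(flat$contigs, file.path(outdir, "cache-contigs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  g <- flat$genes
  if (is.null(g)) {
    g <- data.frame(contig_id = character(), index = integer(),
                    start = integer(), end = integer(), strand = character(),
                    start_codon = character(), gc = numeric(),
                    rbs = character(), category = character(),
                    best_score = numeric(), hallmark = character())
  }
  utils::write.table(g, file.path(outdir, "cache-annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

read_cache <- function(outdir, contigs = NULL) {
  cfile <- file.path(outdir, "cache-contigs.tsv")
  gfile <- file.path(outdir, "cache-annotation.tsv")
  if (!file.exists(cfile) || !file.exists(gfile)) {
    stop("no cached annotation in ", outdir)
  }
  lens <- utils::read.delim(cfile, stringsAsFactors = FALSE)
  genes <- utils::read.delim(gfile, stringsAsFactors = FALSE,
                             colClasses = c(hallmark = "character",
                                            contig_id = "character"))
  if (nrow(genes) == 0) genes <- NULL
  unflatten_annotation(list(genes = genes, contigs = lens), contigs = contigs)
}

#' Run the full viral-detection pipeline on input files
#'
#' Reads contigs, gene calls and profile hits; assigns per-gene categories;
#' classifies each contig with every included group model; and (when
#' `outdir` is given) writes `final-viral-combined.fa`,
#' `final-viral-score.tsv`, `final-viral-boundary.tsv` and a cached
#' annotation enabling [rerun_detection()].
#'
#' @param fasta Contig FASTA path (or a `DNAStringSet`).
#' @param gff GFF3 path of CDS features.
#' @param hits Hit-table TSV path.
#' @param catalog Profile-catalog TSV path.
#' @param models Named list of `group_model` objects (or a directory of
#'   `<group>.rds` model files).
#' @param include_groups Groups to run; default all groups in `models`.
#' @param min_score Score cutoff, default 0.5.
#' @param hit_cutoff Bit-score cutoff for the annotation step, default 30.
#' @param outdir Optional output directory.
#' @return List with `scores` (one row per contig) and `predictions`.
#' @export
detect_viruses <- function(fasta, gff, hits, catalog, models,
                           include_groups = NULL, min_score = 0.5,
                           hit_cutoff = 30, outdir = NULL) {
  contigs <- if (inherits(fasta, "DNAStringSet")) fasta else read_contigs(fasta)
  genes <- read_genes(gff, contigs)
  cat_tab <- read_profile_catalog(catalog)
  hit_tab <- read_hit_table(hits, cat_tab)
  anns <- annotate_contigs(contigs, genes, hit_tab, score_cutoff = hit_cutoff)
  res <- classify_all(anns, models, include_groups, min_score)
  if (!is.null(outdir)) {
    write_cache(anns, outdir)
    write_outputs(anns, res$scores, res$predictions, outdir)
  }
  res
}

#' Classify a list of annotated contigs
#'
#' @param anns Named list of `contig_ann` objects.
#' @inheritParams detect_viruses
#' @return List with `scores` and `predictions` data frames.
#' @export
classify_all <- function(anns, models, include_groups = NULL,
                         min_score = 0.5) {
  models <- resolve_models(models, include_groups)
  per <- lapply(anns, classify_contig, models = models, cutoff = min_score)
  scores <- do.call(rbind, lapply(per, `[[`, "scores"))
  preds <- do.call(rbind, lapply(per, `[[`, "predictions"))
  rownames(scores) <- NULL
  rownames(preds) <- NULL
  list(scores = scores, predictions = preds)
}

resolve_models <- function(models, include_groups = NULL) {
  if (is.character(models)) {
    files <- list.files(models, pattern = "\\.rds$", full.names = TRUE)
    if (length(files) == 0) stop("no model files in ", models)
    models <- lapply(files, load_model)
  }
  stopifnot(length(models) > 0,
            all(vapply(models, inherits, logical(1), "group_model")))
  names(models) <- vapply(models, `[[`, character(1), "group")
  if (!is.null(include_groups)) {
    missing <- setdiff(include_groups, names(models))
    if (length(missing)) stop("no model for group(s): ",
                              paste(missing, collapse = ", "))
    models <- models[include_groups]
  }
  models
}

#' Regenerate outputs from a previous run's cached annotation
#'
#' Re-runs classification under new options (cutoff, group subset) using the
#' annotation cached in `outdir`, without re-reading the hit table or gene
#' calls. Output sequences are written when the original FASTA is supplied.
#'
#' @param outdir Output directory of a previous [detect_viruses()] run.
#' @param models Named list of `group_model` objects or a model directory.
#' @param fasta Optional contig FASTA (for `final-viral-combined.fa`).
#' @inheritParams detect_viruses
#' @return List with `scores` and `predictions`.
#' @export
rerun_detection <- function(outdir, models, fasta = NULL,
                            include_groups = NULL, min_score = 0.5) {
  contigs <- if (is.null(fasta)) NULL else
    if (inherits(fasta, "DNAStringSet")) fasta else read_contigs(fasta)
  anns <- read_cache(outdir, contigs = contigs)
  res <- classify_all(anns, models, include_groups, min_score)
  write_outputs(anns, res$scores, res$predictions, outdir)
  res
}
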