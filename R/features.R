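# The 27-feature layer. Every classifier consumes the same fixed-order
# vector: 1 hallmark count, 6 category percentages, 4 gene-architecture
# statistics, 3 start-codon percentages, 2 GC statistics, 11 RBS-bin
# percentages. Only the hallmark count depends on the viral group; the other
# 26 features are identical across groups.

#' Ordered names of the 27 sequence features
#'
#' The order is fixed and shared by every trained model; the last 11 entries
#' are the RBS motif bins prefixed with `rbs_`.
#'
#' @return Character vector of length 27.
#' @export
feature_names <- function() {
  c("hallmark_count",
    "pct_viral", "pct_archaeal", "pct_bacterial", "pct_eukaryotic",
    "pct_mixed", "pct_unaligned",
    "avg_gene_size", "overlap_freq", "gene_density", "strand_switch_freq",
    "pct_atg", "pct_gtg", "pct_ttg",
    "gc_mean", "gc_sd",
    paste0("rbs_", rbs_bins()))
}

# Does each gene's hallmark field contain `group`?
hallmark_flags <- function(genes, group) {
  hm <- genes$hallmark
  flags <- logical(length(hm))
  has <- !is.na(hm) & nzchar(hm)
  if (any(has)) {
    flags[has] <- vapply(strsplit(hm[has], ",", fixed = TRUE),
                         function(s) group %in% s, logical(1))
  }
  flags
}

#' Extract the 27-feature vector for a gene interval of an annotated contig
#'
#' The region runs from gene `first_gene` to `last_gene` (0-based inclusive
#' indices) and its base-pair length is the span from the first gene's start
#' to the last gene's end (the full contig length when the region covers all
#' genes of the contig). Percent features are on the 0-100 scale. Gene
#' overlap counts adjacent same-strand pairs with the next start at or before
#' the previous end; strand switching counts genes on the opposite strand
#' from their upstream neighbor; both use the (n - 1) adjacent pairs as
#' denominator and are 0 for single-gene regions. `gc_sd` is the population
#' standard deviation.
#'
#' @param ann A `contig_ann` object.
#' @param first_gene,last_gene 0-based inclusive gene indices of the region.
#' @param group Viral group name used for the hallmark count.
#' @return Named numeric vector of length 27 (see [feature_names()]). For a
#'   region with no genes, a vector of `NA` with attribute `no_genes = TRUE`
#'   is returned; such sentinels are never fed to a classifier.
#' @export
extract_features <- function(ann, first_gene, last_gene, group) {
  g <- ann$genes
  n_all <- nrow(g)
  if (n_all == 0) {
    out <- rep(NA_real_, 27)
    names(out) <- feature_names()
    attr(out, "no_genes") <- TRUE
    return(out)
  }
  stopifnot(first_gene >= 0, first_gene <= last_gene, last_gene < n_all)
  region_features(g, first_gene + 1L, last_gene + 1L,
                  hallmark_flags(g, group),
                  full_len = if (first_gene == 0 && last_gene == n_all - 1)
                    ann$length else NULL)
}

# Core feature computation over gene-table rows i1..i2 (1-based). `hm` is the
# per-gene hallmark flag vector for the whole table. When `full_len` is given
# the region spans the whole contig and that length is used.
region_features <- function(g, i1, i2, hm, full_len = NULL) {
  n <- i2 - i1 + 1L
  rows <- i1:i2
  L <- if (!is.null(full_len)) full_len else g$end[i2] - g$start[i1] + 1L
  cat_counts <- tabulate(match(g$category[rows], ALL_CATEGORIES),
                         nbins = length(ALL_CATEGORIES))
  pct_cat <- 100 * cat_counts / n
  sizes <- g$end[rows] - g$start[rows] + 1L
  if (n > 1) {
    a <- rows[-n]; b <- rows[-1]
    same <- g$strand[a] == g$strand[b]
    overlap <- 100 * sum(same & g$start[b] <= g$end[a]) / (n - 1)
    switch_f <- 100 * sum(!same) / (n - 1)
  } else {
    overlap <- 0
    switch_f <- 0
  }
  sc <- g$start_codon[rows]
  gc <- g$gc[rows]
  gc_mean <- mean(gc)
  gc_sd <- sqrt(mean((gc - gc_mean)^2))
  rbs_counts <- tabulate(match(g$rbs[rows], rbs_bins()),
                         nbins = length(rbs_bins()))
  out <- c(
    sum(hm[rows]),
    pct_cat[match(c("viral", "archaeal", "bacterial", "eukaryotic", "mixed",
                    "unaligned"), ALL_CATEGORIES)],
    mean(sizes),
    overlap,
    1000 * n / L,
    switch_f,
    100 * sum(sc == "ATG") / n,
    100 * sum(sc == "GTG") / n,
    100 * sum(sc == "TTG") / n,
    gc_mean,
    gc_sd,
    100 * rbs_counts / n
  )
  names(out) <- feature_names()
  out
}

#' Feature matrix for many regions of one annotated contig
#'
#' @param ann A `contig_ann` object.
#' @param regions Data frame with 0-based inclusive columns `first_gene`,
#'   `last_gene`.
#' @param group Viral group name for the hallmark count.
#' @return Numeric matrix, one row per region, 27 named columns.
#' @export
features_matrix <- function(ann, regions, group) {
  g <- ann$genes
  hm <- hallmark_flags(g, group)
  n_all <- nrow(g)
  m <- matrix(NA_real_, nrow(regions), 27,
              dimnames = list(NULL, feature_names()))
  for (k in seq_len(nrow(regions))) {
    i1 <- regions$first_gene[k] + 1L
    i2 <- regions$last_gene[k] + 1L
    stopifnot(i1 >= 1, i1 <= i2, i2 <= n_all)
    m[k, ] <- region_features(g, i1, i2, hm,
                              full_len = if (i1 == 1L && i2 == n_all)
                                ann$length else NULL)
  }
  m
}

#' Write a labeled feature table to TSV
#'
#' One row per region: `contig_id`, `first_gene`, `last_gene`, `group`,
#' `label`, then the 27 feature columns.
#'
#' @param tab Feature table (data frame as produced by
#'   [build_training_sets()]).
#' @param path Output TSV path.
#' @export
write_feature_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
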