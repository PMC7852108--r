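# Shared fixtures and independent oracles.

# Hand-built annotated contig from per-gene vectors (recycled).
make_ann <- function(start, end, id = "c1", length_bp = NULL, strand = "+",
                     start_codon = "ATG", gc = 0.5, rbs = "None",
                     category = "unaligned", best_score = NA_real_,
                     hallmark = "") {
  n <- length(start)
  genes <- data.frame(
    index = seq_len(n) - 1L, start = as.integer(start), end = as.integer(end),
    strand = rep_len(strand, n), start_codon = rep_len(start_codon, n),
    gc = rep_len(gc, n), rbs = rep_len(rbs, n),
    category = rep_len(category, n),
    best_score = rep_len(best_score, n),
    hallmark = rep_len(hallmark, n), stringsAsFactors = FALSE)
  if (is.null(length_bp)) length_bp <- if (n > 0) max(end) + 100L else 500L
  viroscan:::new_contig_ann(id, as.integer(length_bp), genes)
}

# Naive loop-over-genes re-implementation of the 27 features, independent of
# the package's vectorized path.
naive_features <- function(ann, first, last, group) {
  g <- ann$genes
  idx <- which(g$index >= first & g$index <= last)
  n <- length(idx)
  L <- if (first == 0 && last == nrow(g) - 1) ann$length else
    g$end[idx[n]] - g$start[idx[1]] + 1
  hm <- 0
  for (i in idx) {
    parts <- strsplit(g$hallmark[i], ",", fixed = TRUE)[[1]]
    if (group %in% parts) hm <- hm + 1
  }
  pct <- function(test) {
    cnt <- 0
    for (i in idx) if (test(i)) cnt <- cnt + 1
    100 * cnt / n
  }
  cats <- c("viral", "archaeal", "bacterial", "eukaryotic", "mixed", "unaligned")
  cat_p <- vapply(cats, function(cc) pct(function(i) g$category[i] == cc),
                  numeric(1))
  sizes <- numeric(0)
  for (i in idx) sizes <- c(sizes, g$end[i] - g$start[i] + 1)
  ov <- 0; sw <- 0
  if (n > 1) for (k in 2:n) {
    a <- idx[k - 1]; b <- idx[k]
    if (g$strand[a] == g$strand[b]) {
      if (g$start[b] <= g$end[a]) ov <- ov + 1
    } else sw <- sw + 1
  }
  gcv <- g$gc[idx]
  out <- c(hm, cat_p, mean(sizes),
           if (n > 1) 100 * ov / (n - 1) else 0,
           1000 * n / L,
           if (n > 1) 100 * sw / (n - 1) else 0,
           pct(function(i) g$start_codon[i] == "ATG"),
           pct(function(i) g$start_codon[i] == "GTG"),
           pct(function(i) g$start_codon[i] == "TTG"),
           mean(gcv), sqrt(sum((gcv - mean(gcv))^2) / n),
           vapply(rbs_bins(), function(b) pct(function(i) g$rbs[i] == b),
                  numeric(1)))
  names(out) <- feature_names()
  out
}

# Score a region through the naive feature path (independent oracle for the
# detection-layer scores; shares only the trained forest).
naive_score <- function(ann, model, first, last) {
  predict(model, naive_features(ann, first, last, model$group))
}

.fix <- new.env()

# Small two-group model set for unit tests (memoized across test files).
small_models <- function() {
  if (is.null(.fix$models)) {
    .fix$models <- suppressWarnings(
      train_models(groups = c("dsDNAphage", "ssDNA"),
                   n_per_group = 10, n_negative = 10, seed = 7))
  }
  .fix$models
}

# Full five-group model set at benchmark scale (memoized; used by the
# acceptance suite).
acc_models <- function() {
  if (is.null(.fix$acc_models)) {
    .fix$acc_models <- suppressWarnings(
      train_models(groups = default_groups(),
                   n_per_group = 50, n_negative = 50, seed = 42))
  }
  .fix$acc_models
}
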