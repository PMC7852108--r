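# Evaluation layer: precision/recall/F1 from confusion counts, the
# >= 50%-recovery rule for proviruses, and false-positive rates on
# non-viral fragment sets.

#' Precision, recall and F1 from confusion counts
#'
#' Recall is `tp / (tp + fn)`, precision `tp / (tp + fp)`, F1 their harmonic
#' mean. Undefined ratios (zero denominators) yield 0 and set the
#' `degenerate` flag.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return List with `recall`, `precision`, `f1`, `degenerate`.
#' @export
prf <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  degenerate <- FALSE
  recall <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- TRUE; 0 }
  precision <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- TRUE; 0 }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else { degenerate <- TRUE; 0 }
  list(recall = recall, precision = precision, f1 = f1,
       degenerate = degenerate)
}

#' Does a prediction recover at least half of a provirus?
#'
#' @param pred_start,pred_end Predicted region (bp, inclusive).
#' @param truth_start,truth_end True provirus span (bp, inclusive).
#' @return TRUE iff the base-pair overlap covers >= 50% of the truth span.
#' @export
provirus_match <- function(pred_start, pred_end, truth_start, truth_end) {
  ov <- pmax(0, pmin(pred_end, truth_end) - pmax(pred_start, truth_start) + 1)
  ov / (truth_end - truth_start + 1) >= 0.5
}

#' Match predictions to true proviruses (many-to-one)
#'
#' Each truth is satisfied by its best-overlapping prediction; a truth with
#' >= 50% of its span recovered is a true positive, otherwise a false
#' negative. A prediction that recovers >= 50% of no truth is a false
#' positive (one prediction may satisfy several truths).
#'
#' @param preds Prediction data frame (`contig_id`, `start_bp`, `end_bp`).
#' @param truths Truth data frame (`contig_id`, `start_bp`, `end_bp`).
#' @return List with counts `tp`, `fp`, `fn` and data frame `truth_status`
#'   (per truth: recovered fraction, matched prediction row or NA).
#' @export
match_proviruses <- function(preds, truths) {
  n_t <- nrow(truths)
  frac <- numeric(n_t)
  best_pred <- rep(NA_integer_, n_t)
  pred_hit <- rep(FALSE, max(0L, nrow(preds)))
  for (i in seq_len(n_t)) {
    same <- which(preds$contig_id == truths$contig_id[i])
    if (length(same) == 0) next
    ov <- pmax(0, pmin(preds$end_bp[same], truths$end_bp[i]) -
                 pmax(preds$start_bp[same], truths$start_bp[i]) + 1)
    f <- ov / (truths$end_bp[i] - truths$start_bp[i] + 1)
    k <- which.max(f)
    frac[i] <- f[k]
    if (f[k] >= 0.5) best_pred[i] <- same[k]
    pred_hit[same[f >= 0.5]] <- TRUE
  }
  tp <- sum(frac >= 0.5)
  list(tp = tp, fn = n_t - tp, fp = sum(!pred_hit),
       truth_status = data.frame(contig_id = truths$contig_id,
                                 recovered = frac, pred_row = best_pred))
}

#' False-positive rate on a non-viral fragment set
#'
#' A fragment counts as flagged when any prediction (full, trimmed or
#' partial) was emitted for it. The rate is reported as a percentage, with a
#' per-group decomposition (fraction of fragments flagged by each
#' classifier; a fragment can contribute to several groups).
#'
#' @param preds Prediction data frame from [classify_all()].
#' @param nonviral_ids Character vector of non-viral fragment ids.
#' @return List with `rate` (percent) and `by_group` (named percent vector).
#' @export
false_positive_rate <- function(preds, nonviral_ids) {
  n <- length(nonviral_ids)
  stopifnot(n > 0)
  p <- preds[preds$contig_id %in% nonviral_ids, , drop = FALSE]
  rate <- 100 * length(unique(p$contig_id)) / n
  by_group <- vapply(split(p$contig_id, p$group),
                     function(ids) 100 * length(unique(ids)) / n, numeric(1))
  list(rate = rate, by_group = by_group)
}

#' Evaluate fragment-classification benchmarks
#'
#' Runs detection on each simulated benchmark dataset and scores it at the
#' fragment level: a fragment is "predicted viral" when any prediction was
#' emitted for it.
#'
#' @param datasets Benchmark datasets from [simulate_benchmark()].
#' @param models Named list of `group_model` objects.
#' @param min_score Score cutoff, default 0.5.
#' @return Data frame with one row per dataset: `length_bp`, `replicate`,
#'   `tp`, `fp`, `fn`, `recall`, `precision`, `f1`.
#' @export
evaluate_fragment_benchmark <- function(datasets, models, min_score = 0.5) {
  rows <- lapply(datasets, function(d) {
    res <- classify_all(d$anns, models, min_score = min_score)
    flagged <- unique(res$predictions$contig_id)
    viral <- d$truth$contig_id[d$truth$label == "viral"]
    nonviral <- d$truth$contig_id[d$truth$label == "nonviral"]
    tp <- sum(viral %in% flagged)
    fp <- sum(nonviral %in% flagged)
    fn <- sum(!(viral %in% flagged))
    m <- prf(tp, fp, fn)
    data.frame(length_bp = d$length, replicate = d$replicate,
               tp = tp, fp = fp, fn = fn,
               recall = m$recall, precision = m$precision, f1 = m$f1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
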