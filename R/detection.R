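# Detection layer: full-sequence scoring, host-edge trimming, gene-stepped
# sliding-window provirus scan, and cross-classifier overlap resolution.
# Significance is score >= cutoff, inclusive, everywhere.

#' Score a gene region with one group model
#'
#' The score is the forest's viral-class probability on the scaled 27-feature
#' vector of the region. Regions (or contigs) with no genes score 0 by
#' convention.
#'
#' @param ann A `contig_ann`.
#' @param first_gene,last_gene 0-based inclusive gene indices; defaults cover
#'   the whole contig.
#' @param model A `group_model`.
#' @return Score in `[0, 1]`.
#' @export
score_region <- function(ann, model, first_gene = 0L,
                         last_gene = nrow(ann$genes) - 1L) {
  if (nrow(ann$genes) == 0 || last_gene < first_gene) return(0)
  score_regions(ann, data.frame(first_gene = first_gene,
                                last_gene = last_gene), model)
}

# Vectorized region scoring (one ranger predict call).
score_regions <- function(ann, regions, model) {
  if (nrow(regions) == 0) return(numeric(0))
  m <- features_matrix(ann, regions, model$group)
  predict(model, m)
}

# Edge-trim budget: 5 genes or 10% of the gene count, whichever larger.
trim_budget <- function(n) max(5L, as.integer(ceiling(0.10 * n)))

#' Trim putative host edges off a fully viral contig
#'
#' All sub-sequences with `a` genes removed from the 5' end and `b` genes
#' from the 3' end, for `0 <= a, b <= t` with `a + b < n` where
#' `t = max(5, ceiling(0.1 n))`, are rescored; the best-scoring candidate is
#' returned, flagged `trimmed` only when its score strictly exceeds the
#' untrimmed score.
#'
#' @param ann A `contig_ann` whose full-sequence score reached the cutoff.
#' @param model A `group_model`.
#' @param cutoff Score cutoff (used only to annotate the prediction).
#' @return One-row prediction data frame (`contig_id`, `first_gene`,
#'   `last_gene`, `start_bp`, `end_bp`, `group`, `score`, `kind`).
#' @export
trim_edges <- function(ann, model, cutoff = 0.5) {
  g <- ann$genes
  n <- nrow(g)
  t <- trim_budget(n)
  cand <- expand.grid(a = 0:min(t, n - 1L), b = 0:min(t, n - 1L))
  cand <- cand[cand$a + cand$b < n, , drop = FALSE]
  cand <- cand[order(cand$a + cand$b, cand$a), , drop = FALSE]  # (0,0) first
  regions <- data.frame(first_gene = cand$a,
                        last_gene = n - 1L - cand$b)
  scores <- score_regions(ann, regions, model)
  full_score <- scores[1]
  best <- which.max(scores)  # ties: least-trimmed candidate wins
  if (scores[best] > full_score) {
    i1 <- regions$first_gene[best]; i2 <- regions$last_gene[best]
    kind <- "trimmed"
  } else {
    i1 <- 0L; i2 <- n - 1L
    best <- 1L
    kind <- "full"
  }
  data.frame(contig_id = ann$id, first_gene = i1, last_gene = i2,
             start_bp = if (kind == "full") 1L else g$start[i1 + 1L],
             end_bp = if (kind == "full") ann$length else g$end[i2 + 1L],
             group = model$group, score = scores[best], kind = kind,
             stringsAsFactors = FALSE)
}

#' Sliding-window provirus scan with one group model
#'
#' The window is the minimal run of consecutive genes spanning at least the
#' model's `min_window_bp`. It starts at the 5' edge and shifts one gene at
#' a time while no score is significant; the first significant window is
#' extended one gene at a time in 3' as long as the score stays at or above
#' the cutoff, the maximal extended region is emitted, and scanning resumes
#' after its 3' end.
#'
#' @param ann A `contig_ann` (whose full-sequence score stayed below cutoff).
#' @param model A `group_model`.
#' @param cutoff Score cutoff, default 0.5.
#' @return Prediction data frame (possibly 0 rows), `kind = "partial"`.
#' @export
sliding_window_detect <- function(ann, model, cutoff = 0.5) {
  g <- ann$genes
  n <- nrow(g)
  empty <- data.frame(contig_id = character(), first_gene = integer(),
                      last_gene = integer(), start_bp = integer(),
                      end_bp = integer(), group = character(),
                      score = numeric(), kind = character(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  w <- model$spec$min_window_bp
  # Minimal window end index per start (1-based rows); NA when no run from
  # this start reaches the bp span. Two-pointer over sorted genes.
  jmin <- rep(NA_integer_, n)
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j <= n && g$end[j] - g$start[i] + 1L < w) j <- j + 1L
    if (j > n) break
    jmin[i] <- j
  }
  valid <- which(!is.na(jmin))
  if (length(valid) == 0) return(empty)
  win_scores <- score_regions(
    ann, data.frame(first_gene = valid - 1L, last_gene = jmin[valid] - 1L),
    model)
  score_of <- rep(NA_real_, n)
  score_of[valid] <- win_scores

  preds <- list()
  i <- 1L
  while (i <= n) {
    if (is.na(jmin[i])) break
    if (score_of[i] >= cutoff) {
      jm <- jmin[i]
      # Batch-score all 3' extensions; keep the maximal contiguous
      # significant run starting at the minimal window.
      ks <- jm:n
      ext_scores <- if (jm == n) score_of[i] else
        score_regions(ann, data.frame(first_gene = i - 1L,
                                      last_gene = ks - 1L), model)
      sig <- ext_scores >= cutoff
      stop_at <- which(!sig)
      last_k <- if (length(stop_at) == 0) n else ks[stop_at[1] - 1L]
      preds[[length(preds) + 1]] <- data.frame(
        contig_id = ann$id, first_gene = i - 1L, last_gene = last_k - 1L,
        start_bp = g$start[i], end_bp = g$end[last_k],
        group = model$group,
        score = ext_scores[match(last_k, ks)], kind = "partial",
        stringsAsFactors = FALSE)
      i <- last_k + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(preds) == 0) empty else do.call(rbind, preds)
}

#' Resolve overlapping predictions from different classifiers
#'
#' Predictions on the same contig are clustered by transitive base-pair
#' overlap (intersection of at least 1 bp); within each cluster the longest
#' span is retained, ties broken by higher score, then by a fixed group
#' order. Non-overlapping predictions are all retained.
#'
#' @param preds Prediction data frame (rows from one or more groups).
#' @param group_order Character vector fixing the tie-break order of groups.
#' @return Filtered prediction data frame with pairwise non-overlapping
#'   regions per contig.
#' @export
resolve_overlaps <- function(preds, group_order = default_groups()) {
  if (nrow(preds) <= 1) return(preds)
  out <- lapply(split(preds, preds$contig_id), function(p) {
    p <- p[order(p$start_bp, p$end_bp), , drop = FALSE]
    cluster <- integer(nrow(p))
    cur <- 1L; cur_end <- p$end_bp[1]; cluster[1] <- 1L
    for (i in seq_len(nrow(p))[-1]) {
      if (p$start_bp[i] <= cur_end) {
        cluster[i] <- cur
        cur_end <- max(cur_end, p$end_bp[i])
      } else {
        cur <- cur + 1L
        cluster[i] <- cur
        cur_end <- p$end_bp[i]
      }
    }
    keep <- lapply(split(seq_len(nrow(p)), cluster), function(idx) {
      pp <- p[idx, , drop = FALSE]
      span <- pp$end_bp - pp$start_bp + 1L
      o <- order(-span, -pp$score, match(pp$group, group_order))
      idx[o[1]]
    })
    p[sort(unlist(keep)), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify one contig with all group models
#'
#' Every model first scores the full contig. If any score reaches the
#' cutoff, the contig is treated as (near-)entirely viral: each significant
#' model's prediction is edge-trimmed and emitted. Otherwise each model runs
#' the sliding-window scan and the union of partial predictions is passed
#' through [resolve_overlaps()]. A score record with all per-group
#' full-sequence scores is always produced.
#'
#' @param ann A `contig_ann`.
#' @param models Named list of `group_model` objects.
#' @param cutoff Score cutoff, default 0.5.
#' @return List with `scores` (one-row data frame: `seqname`, one
#'   `<group>_score` column per model, `max_score`, `max_score_group`,
#'   `length`, `hallmark`, `viral`, `cellular`) and `predictions`
#'   (data frame, possibly 0 rows).
#' @export
classify_contig <- function(ann, models, cutoff = 0.5) {
  stopifnot(length(models) > 0)
  groups <- vapply(models, `[[`, character(1), "group")
  names(models) <- groups
  n <- nrow(ann$genes)
  full <- vapply(models, function(m) score_region(ann, m), numeric(1))
  max_i <- which.max(full)
  max_group <- groups[max_i]

  if (n == 0) {
    preds <- trim_edges_empty()
  } else if (any(full >= cutoff)) {
    sig <- which(full >= cutoff)
    preds <- do.call(rbind, lapply(models[sig], function(m)
      trim_edges(ann, m, cutoff)))
    rownames(preds) <- NULL
  } else {
    parts <- lapply(models, function(m) sliding_window_detect(ann, m, cutoff))
    preds <- do.call(rbind, parts)
    rownames(preds) <- NULL
    if (nrow(preds) > 0) preds <- resolve_overlaps(preds, group_order = groups)
  }

  # Score-record summary computed on the winning region (best prediction if
  # any, else the full contig), with the max-score group's hallmark set.
  if (n > 0) {
    if (nrow(preds) > 0) {
      b <- which.max(preds$score)
      fv <- extract_features(ann, preds$first_gene[b], preds$last_gene[b],
                             if (preds$group[b] %in% groups) preds$group[b]
                             else max_group)
    } else {
      fv <- extract_features(ann, 0L, n - 1L, max_group)
    }
    hallmark <- unname(fv["hallmark_count"])
    pct_viral <- unname(fv["pct_viral"])
    pct_cellular <- unname(fv["pct_archaeal"] + fv["pct_bacterial"] +
                             fv["pct_eukaryotic"])
  } else {
    hallmark <- 0; pct_viral <- 0; pct_cellular <- 0
  }
  scores <- data.frame(seqname = ann$id, t(full), max_score = unname(full[max_i]),
                       max_score_group = max_group, length = ann$length,
                       hallmark = hallmark, viral = pct_viral,
                       cellular = pct_cellular,
                       stringsAsFactors = FALSE, check.names = FALSE)
  names(scores)[2:(1 + length(groups))] <- paste0(groups, "_score")
  rownames(scores) <- NULL
  list(scores = scores, predictions = preds)
}

trim_edges_empty <- function() {
  data.frame(contig_id = character(), first_gene = integer(),
             last_gene = integer(), start_bp = integer(), end_bp = integer(),
             group = character(), score = numeric(), kind = character(),
             stringsAsFactors = FALSE)
}
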