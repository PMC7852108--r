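test_that("region scores are probabilities and gene-free contigs score zero", {
  models <- small_models()
  m <- models$dsDNAphage
  p <- load_preset("easy")
  sim <- simulate_contig(p$viral$dsDNAphage, 12000, seed = 41)
  s <- score_region(sim$ann, m)
  expect_true(s >= 0 && s <= 1)
  expect_gte(s, 0.5)  # pure viral contig under a trained model

  empty <- make_ann(integer(0), integer(0), length_bp = 5000)
  expect_equal(score_region(empty, m), 0)
})

test_that("trim budget is 5 genes or 10% of genes, whichever larger", {
  expect_equal(viroscan:::trim_budget(100), 10L)
  expect_equal(viroscan:::trim_budget(20), 5L)
  expect_equal(viroscan:::trim_budget(3), 5L)
})

test_that("edge trimming never returns a score below the full sequence", {
  models <- small_models()
  m <- models$dsDNAphage
  p <- load_preset("easy")
  set.seed(61)
  for (k in 1:4) {
    pv <- simulate_provirus(p$nonviral$prokaryote, p$viral$dsDNAphage,
                            2000 + 500 * k, 12000)
    full <- score_region(pv$ann, m)
    tr <- trim_edges(pv$ann, m)
    expect_gte(tr$score, full)
    if (tr$kind == "full") {
      expect_equal(tr$score, full)
      expect_equal(c(tr$first_gene, tr$last_gene + 1L),
                   c(0L, nrow(pv$ann$genes)))
      expect_equal(c(tr$start_bp, tr$end_bp), c(1L, pv$ann$length))
    } else {
      expect_gt(tr$score, full)
    }
  }
})

test_that("trimming a host-flanked phage recovers a higher-scoring core", {
  models <- small_models()
  m <- models$dsDNAphage
  p <- load_preset("easy")
  pv <- simulate_provirus(p$nonviral$prokaryote, p$viral$dsDNAphage,
                          3000, 20000, seed = 63)
  full <- score_region(pv$ann, m)
  tr <- trim_edges(pv$ann, m)
  expect_equal(tr$kind, "trimmed")
  expect_gt(tr$score, full)
})

test_that("windows that cannot fit the contig yield no detections", {
  models <- small_models()
  m <- models$dsDNAphage
  m$spec$min_window_bp <- 10000
  p <- load_preset("easy")
  sim <- simulate_contig(p$viral$dsDNAphage, 5000, seed = 43)
  expect_equal(nrow(sliding_window_detect(sim$ann, m)), 0)
})

test_that("uniformly host-like contigs produce no sliding-window detections", {
  models <- small_models()
  p <- load_preset("easy")
  sim <- simulate_contig(p$nonviral$prokaryote, 40000, seed = 47)
  expect_equal(nrow(sliding_window_detect(sim$ann, models$dsDNAphage)), 0)
})

test_that("the sliding window localizes an integrated provirus", {
  models <- small_models()
  p <- load_preset("easy")
  pv <- simulate_provirus(p$nonviral$prokaryote, p$viral$dsDNAphage,
                          30000, 25000, seed = 49)
  cc <- classify_contig(pv$ann, models["dsDNAphage"])
  pr <- cc$predictions
  expect_gte(nrow(pr), 1)
  expect_equal(pr$kind[1], "partial")
  truth_genes <- pv$truth$first_gene:pv$truth$last_gene
  pred_genes <- pr$first_gene[1]:pr$last_gene[1]
  overlap <- length(intersect(truth_genes, pred_genes))
  expect_gte(overlap / length(truth_genes), 0.9)
})

test_that("sliding-window emissions agree with brute-force interval enumeration", {
  models <- small_models()
  m <- models$ssDNA   # data-derived window of a few kb
  p <- load_preset("easy")
  set.seed(71)
  cutoff <- 0.5
  for (k in 1:15) {
    pr <- list(p$nonviral$prokaryote, p$viral$ssDNA,
               p$nonviral$plasmid)[[1 + k %% 3]]
    sim <- simulate_contig(pr, sample(4000:9000, 1))
    ann <- sim$ann
    g <- ann$genes
    n <- nrow(g)
    if (n > 30) next
    w <- m$spec$min_window_bp
    # independent oracle: naive features + the shared forest, single regions
    oracle <- function(i, j) naive_score(ann, m, i, j)
    # independent minimal-window table by double loop
    jmin <- rep(NA_integer_, n)
    for (i in seq_len(n)) for (j in i:n) {
      if (g$end[j] - g$start[i] + 1 >= w) { jmin[i] <- j; break }
    }
    emitted <- sliding_window_detect(ann, m, cutoff)
    if (nrow(emitted) > 0) for (r in seq_len(nrow(emitted))) {
      i <- emitted$first_gene[r]; j <- emitted$last_gene[r]
      # emitted region is significant
      expect_gte(oracle(i, j), cutoff)
      expect_equal(emitted$score[r], oracle(i, j), tolerance = 1e-9)
      # no significant single-gene 3' extension exists
      if (j + 1 < n) expect_lt(oracle(i, j + 1), cutoff)
      # the emitted start is the first scannable start whose minimal window
      # is significant (scan resumes after the previous emission)
      prev_end <- if (r == 1) -1L else emitted$last_gene[r - 1]
      starts_before <- which(seq_len(n) - 1 > prev_end & seq_len(n) - 1 < i)
      for (s in starts_before) {
        if (!is.na(jmin[s])) {
          expect_lt(oracle(s - 1, jmin[s] - 1), cutoff)
        }
      }
    }
    # conversely: if any minimal window is significant, something is emitted
    sig_any <- FALSE
    for (s in seq_len(n)) {
      if (!is.na(jmin[s]) && oracle(s - 1, jmin[s] - 1) >= cutoff) {
        sig_any <- TRUE; break
      }
    }
    expect_equal(nrow(emitted) > 0, sig_any)
  }
})

pred_row <- function(id, s, e, group, score, kind = "partial") {
  data.frame(contig_id = id, first_gene = 0L, last_gene = 1L,
             start_bp = s, end_bp = e, group = group, score = score,
             kind = kind, stringsAsFactors = FALSE)
}

test_that("overlap resolution keeps the longest prediction, ties by score", {
  a <- pred_row("c1", 1, 12000, "dsDNAphage", 0.7)
  b <- pred_row("c1", 8000, 16000, "ssDNA", 0.9)
  kept <- resolve_overlaps(rbind(a, b))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$group, "dsDNAphage")  # longest span wins

  c1 <- pred_row("c1", 1, 5000, "dsDNAphage", 0.7)
  c2 <- pred_row("c1", 9000, 14000, "ssDNA", 0.9)
  expect_equal(nrow(resolve_overlaps(rbind(c1, c2))), 2)  # disjoint: both kept

  d1 <- pred_row("c1", 1, 5000, "dsDNAphage", 0.7)
  d2 <- pred_row("c1", 3000, 7999, "ssDNA", 0.9)
  kept <- resolve_overlaps(rbind(d1, d2))  # equal spans
  expect_equal(kept$score, 0.9)
})

test_that("resolved predictions are pairwise non-overlapping per contig", {
  set.seed(81)
  for (k in 1:10) {
    n <- sample(3:8, 1)
    s <- sample(1:20000, n)
    preds <- do.call(rbind, lapply(seq_len(n), function(i)
      pred_row("cX", s[i], s[i] + sample(1000:9000, 1),
               sample(default_groups(), 1), runif(1))))
    kept <- resolve_overlaps(preds)
    if (nrow(kept) > 1) {
      kept <- kept[order(kept$start_bp), ]
      expect_true(all(kept$start_bp[-1] > kept$end_bp[-nrow(kept)]))
    }
    # the longest prediction always survives (it wins its cluster)
    span <- preds$end_bp - preds$start_bp
    longest <- preds[which.max(span), ]
    expect_true(any(kept$start_bp == longest$start_bp &
                      kept$end_bp == longest$end_bp))
  }
})

test_that("contig classification reports one score column per included group", {
  models <- small_models()
  p <- load_preset("easy")
  sim <- simulate_contig(p$viral$dsDNAphage, 15000, seed = 91)
  res <- classify_all(list(c1 = sim$ann), models,
                      include_groups = c("dsDNAphage", "ssDNA"))
  expect_true(all(c("dsDNAphage_score", "ssDNA_score") %in% names(res$scores)))
  expect_equal(sum(endsWith(names(res$scores), "_score"))
               - ("max_score" %in% names(res$scores)), 2)
  one <- classify_all(list(c1 = sim$ann), models, include_groups = "ssDNA")
  expect_false("dsDNAphage_score" %in% names(one$scores))

  cc <- classify_contig(sim$ann, models)
  grp_scores <- unlist(cc$scores[paste0(names(models), "_score")])
  expect_equal(cc$scores$max_score, max(grp_scores))
  expect_equal(cc$scores$max_score_group,
               names(models)[which.max(grp_scores)])
})

test_that("gene-free contigs get an all-zero score record and no predictions", {
  models <- small_models()
  empty <- make_ann(integer(0), integer(0), id = "bare", length_bp = 3000)
  cc <- classify_contig(empty, models)
  expect_equal(cc$scores$max_score, 0)
  expect_equal(nrow(cc$predictions), 0)
  expect_equal(cc$scores$hallmark, 0)
})

test_that("rerun regenerates outputs from the cached annotation", {
  models <- small_models()
  p <- load_preset("easy")
  v <- simulate_contig(p$viral$dsDNAphage, 8000, id = "rr1", seed = 211,
                       with_seq = TRUE)
  h <- simulate_contig(p$nonviral$prokaryote, 8000, id = "rr2", seed = 212,
                       with_seq = TRUE)
  indir <- tempfile(); outdir <- tempfile()
  paths <- write_synthetic_inputs(list(rr1 = v$ann, rr2 = h$ann),
                                  rbind(v$hits, h$hits), v$catalog, indir)
  res <- detect_viruses(paths$fasta, paths$gff, paths$hits, paths$catalog,
                        models, outdir = outdir)
  # same options: identical scores without re-reading gene calls or hits
  re <- rerun_detection(outdir, models, fasta = paths$fasta)
  expect_equal(re$scores, res$scores)
  # restricted group subset drops that group's score column
  re2 <- rerun_detection(outdir, models, fasta = paths$fasta,
                         include_groups = "ssDNA")
  expect_false("dsDNAphage_score" %in% names(re2$scores))
  expect_true(file.exists(file.path(outdir, "final-viral-score.tsv")))
})
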