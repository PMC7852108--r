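# Training layer: random genome fragmentation, balanced per-group training
# sets, min-max scaling, and grid-searched random-forest fitting (one
# probability forest per viral group).

#' Default per-group classifier specifications
#'
#' `min_window_bp` is the sliding-window width used for provirus detection:
#' the minimal genome size expected for the group. Defaults are
#' user-overridable configuration values.
#'
#' @return Named list of specs, each a list with `name` and `min_window_bp`.
#' @export
default_group_specs <- function() {
  w <- c(dsDNAphage = 10000, NCLDV = 100000, RNA = 1000, ssDNA = 1000,
         lavidaviridae = 15000)
  out <- lapply(names(w), function(g) list(name = g, min_window_bp = w[[g]]))
  names(out) <- names(w)
  out
}

#' Hyperparameter grid for the random-forest search
#'
#' Ten cells: tree counts \{20, 50, 100, 150, 200\} crossed with two split
#' rules (gini impurity and extremely randomized splits).
#'
#' @return Data frame with columns `num_trees`, `criterion`.
#' @export
rf_grid <- function() {
  expand.grid(num_trees = c(20L, 50L, 100L, 150L, 200L),
              criterion = c("gini", "extratrees"),
              stringsAsFactors = FALSE)
}

#' Draw random fragments from an annotated genome and snap them to genes
#'
#' Each fragment starts at a uniform random base position and has length
#' uniform between `min_len` and the distance to the 3' end. The fragment's
#' gene region comprises all genes whose midpoint falls inside the window;
#' fragments whose snapped gene span is shorter than `min_len`, or that
#' contain no gene, are redrawn (bounded retries).
#'
#' @param ann A `contig_ann` (the genome).
#' @param n Number of fragments, default 5.
#' @param min_len Minimum fragment length in bp, default 1000.
#' @param max_tries Redraw budget per fragment.
#' @return Data frame of regions (`first_gene`, `last_gene`, `start_bp`,
#'   `end_bp`, `length_bp`; gene indices 0-based inclusive). Genomes shorter
#'   than `min_len` yield a 0-row frame with a warning. Uses the caller's RNG
#'   stream (call `set.seed()` for reproducibility).
#' @export
generate_fragments <- function(ann, n = 5, min_len = 1000, max_tries = 100) {
  empty <- data.frame(first_gene = integer(), last_gene = integer(),
                      start_bp = integer(), end_bp = integer(),
                      length_bp = integer())
  L <- ann$length
  if (L < min_len) {
    warning("genome ", ann$id, " shorter than ", min_len, " bp; skipped")
    return(empty)
  }
  g <- ann$genes
  if (nrow(g) == 0) {
    warning("genome ", ann$id, " has no genes; skipped")
    return(empty)
  }
  mids <- (g$start + g$end) / 2
  out <- vector("list", n)
  for (k in seq_len(n)) {
    reg <- NULL
    for (try in seq_len(max_tries)) {
      s <- sample.int(L - min_len + 1L, 1)
      len <- min_len + sample.int(L - s + 1L - min_len + 1L, 1) - 1L
      e <- s + len - 1L
      sel <- which(mids >= s & mids <= e)
      if (length(sel) == 0) next
      i1 <- sel[1]; i2 <- sel[length(sel)]
      span <- g$end[i2] - g$start[i1] + 1L
      if (span < min_len) next
      reg <- data.frame(first_gene = g$index[i1], last_gene = g$index[i2],
                        start_bp = g$start[i1], end_bp = g$end[i2],
                        length_bp = span)
      break
    }
    out[[k]] <- reg
  }
  got <- do.call(rbind, out)
  if (is.null(got)) empty else got
}

# Fragment a list of genomes; returns a feature-ready table of region rows
# tagged with the source genome. Features are computed later, per group.
fragment_genomes <- function(anns, n = 5, min_len = 1000) {
  rows <- lapply(anns, function(a) {
    fr <- generate_fragments(a, n = n, min_len = min_len)
    if (nrow(fr) == 0) return(NULL)
    fr$contig_id <- a$id
    fr
  })
  keep <- !vapply(rows, is.null, logical(1))
  list(regions = do.call(rbind, rows[keep]), anns = anns[keep])
}

# Feature table (data frame) for fragment regions drawn from a set of
# genomes, under one group's hallmark set.
fragment_features <- function(anns, regions, group, label) {
  ann_by_id <- anns
  names(ann_by_id) <- vapply(anns, `[[`, character(1), "id")
  mats <- lapply(split(regions, regions$contig_id), function(rr) {
    cbind(rr[, c("contig_id", "first_gene", "last_gene", "length_bp")],
          as.data.frame(features_matrix(ann_by_id[[rr$contig_id[1]]],
                                        rr, group), check.names = FALSE))
  })
  tab <- do.call(rbind, mats)
  rownames(tab) <- NULL
  tab$group <- group
  tab$label <- label
  tab
}

#' Build balanced per-group train/test feature tables from genome collections
#'
#' Genomes (not fragments) are split 9:1 into train and test; fragments are
#' then drawn from each genome. Negative fragments are subsampled so the
#' three non-viral sources contribute equally, and per viral group the viral
#' and negative fragment sets are subsampled to the smaller class size.
#'
#' @param viral Named list: group name -> list of `contig_ann` genomes.
#' @param negatives Named list: source name (prokaryote/eukaryote/plasmid) ->
#'   list of `contig_ann` genomes.
#' @param split_ratio Genome-level train fraction, default 0.9.
#' @param n_fragments Fragments per genome, default 5.
#' @param min_len Minimum fragment length, default 1000 bp.
#' @param seed Optional integer seed.
#' @return Named list per group with elements `train` and `test`, each a
#'   feature table (`contig_id`, region columns, 27 features, `group`,
#'   `label` in \{viral, nonviral\}).
#' @export
build_training_sets <- function(viral, negatives, split_ratio = 0.9,
                                n_fragments = 5, min_len = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(viral) > 0, length(negatives) > 0)

  split_genomes <- function(anns) {
    n <- length(anns)
    if (n == 0) stop("empty genome set")
    n_train <- max(1L, round(split_ratio * n))
    idx <- sample.int(n)
    list(train = anns[idx[seq_len(n_train)]],
         test = anns[idx[-seq_len(n_train)]])
  }
  frag_set <- function(anns) {
    if (length(anns) == 0) return(NULL)
    fragment_genomes(anns, n = n_fragments, min_len = min_len)
  }

  neg_split <- lapply(negatives, split_genomes)
  neg_frags <- lapply(neg_split, function(s)
    list(train = frag_set(s$train), test = frag_set(s$test)))

  # Equal-contribution rule across the three negative sources (per partition).
  subsample_regions <- function(fr, m) {
    if (is.null(fr) || nrow(fr$regions) <= m) return(fr)
    fr$regions <- fr$regions[sort(sample.int(nrow(fr$regions), m)), ,
                             drop = FALSE]
    fr
  }
  for (part in c("train", "test")) {
    sizes <- vapply(neg_frags, function(x)
      if (is.null(x[[part]])) 0L else nrow(x[[part]]$regions), integer(1))
    if (all(sizes == 0)) next
    m <- min(sizes[sizes > 0])
    for (s in names(neg_frags)) {
      neg_frags[[s]][[part]] <- subsample_regions(neg_frags[[s]][[part]], m)
    }
  }

  out <- vector("list", length(viral))
  names(out) <- names(viral)
  for (grp in names(viral)) {
    v_split <- split_genomes(viral[[grp]])
    v_frags <- list(train = frag_set(v_split$train),
                    test = frag_set(v_split$test))
    tabs <- list()
    for (part in c("train", "test")) {
      vf <- v_frags[[part]]
      if (is.null(vf) || nrow(vf$regions) == 0) {
        if (part == "train") stop("no viral training fragments for group ", grp)
        tabs[[part]] <- NULL
        next
      }
      v_tab <- fragment_features(vf$anns, vf$regions, grp, "viral")
      n_tabs <- lapply(neg_frags, function(x) {
        f <- x[[part]]
        if (is.null(f) || nrow(f$regions) == 0) return(NULL)
        fragment_features(f$anns, f$regions, grp, "nonviral")
      })
      n_tab <- do.call(rbind, n_tabs[!vapply(n_tabs, is.null, logical(1))])
      if (is.null(n_tab) || nrow(n_tab) == 0) {
        if (part == "train") stop("no negative training fragments for group ", grp)
        tabs[[part]] <- v_tab
        next
      }
      m <- min(nrow(v_tab), nrow(n_tab))
      if (nrow(v_tab) > m) v_tab <- v_tab[sort(sample.int(nrow(v_tab), m)), ]
      if (nrow(n_tab) > m) n_tab <- n_tab[sort(sample.int(nrow(n_tab), m)), ]
      tab <- rbind(v_tab, n_tab)
      rownames(tab) <- NULL
      tabs[[part]] <- tab
    }
    out[[grp]] <- tabs
  }
  out
}

#' Fit a per-feature min-max scaler on training features
#'
#' @param x Numeric matrix or feature table containing the 27 feature
#'   columns (extra columns are ignored).
#' @return Data frame with columns `feature`, `min`, `max`.
#' @export
fit_scaler <- function(x) {
  m <- as.matrix(as.data.frame(x, check.names = FALSE)[, feature_names()])
  if (nrow(m) < 2) stop("scaler requires at least 2 training rows")
  data.frame(feature = feature_names(),
             min = apply(m, 2, min), max = apply(m, 2, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply a min-max scaler
#'
#' Scaled value is `(x - min) / (max - min)`. Constant training features
#' (max equal to min) map to 0 for every input. Values outside the training
#' range are not clipped, so scaled features can fall outside `[0, 1]` at
#' prediction time; random forests are insensitive to monotone range excess
#' and clipping would hide covariate shift.
#'
#' @param scaler Scaler from [fit_scaler()].
#' @param x Numeric matrix (or single named vector) of raw features.
#' @return Matrix of scaled features, same shape and column order as the
#'   scaler's feature order.
#' @export
apply_scaler <- function(scaler, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  m <- as.matrix(x[, scaler$feature, drop = FALSE])
  rng <- scaler$max - scaler$min
  out <- sweep(m, 2, scaler$min, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out
}

#' Train one group's random-forest classifier with a grid search
#'
#' Hyperparameters are chosen by k-fold cross-validated grid search over the
#' 10-cell grid of [rf_grid()]; the final probability forest is refitted on
#' the full training table with the winning pair. Feature scaling is fitted
#' on the training data only and stored with the model.
#'
#' @param train Balanced training feature table from [build_training_sets()]
#'   (27 feature columns plus `label`).
#' @param group_spec Spec list with `name` and `min_window_bp` (see
#'   [default_group_specs()]), or a group name present in the defaults.
#' @param seed Integer seed controlling fold assignment and forest fits.
#' @param n_folds Cross-validation folds, default 5.
#' @return An object of class `group_model`: list with `group`, `spec`,
#'   `scaler`, `forest`, `feature_order`, `cutoff`, `meta` (seed, training
#'   size, grid with CV accuracies, chosen cell).
#' @export
train_group_classifier <- function(train, group_spec, seed = 1, n_folds = 5) {
  if (is.character(group_spec)) {
    specs <- default_group_specs()
    if (!group_spec %in% names(specs)) {
      group_spec <- list(name = group_spec, min_window_bp = 10000)
    } else group_spec <- specs[[group_spec]]
  }
  y <- factor(train$label, levels = c("nonviral", "viral"))
  if (length(unique(train$label)) < 2) {
    stop("degenerate single-class training set for group ", group_spec$name)
  }
  X <- as.matrix(as.data.frame(train, check.names = FALSE)[, feature_names()])
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  n <- nrow(Xs)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(n_folds), n))
  grid <- rf_grid()
  grid$cv_accuracy <- NA_real_
  for (cell in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) next
      fit <- ranger::ranger(
        x = Xs[tr, , drop = FALSE], y = y[tr], probability = TRUE,
        num.trees = grid$num_trees[cell], splitrule = grid$criterion[cell],
        seed = seed + cell, num.threads = 1)
      p <- predict(fit, data = Xs[!tr, , drop = FALSE],
                   num.threads = 1)$predictions[, "viral"]
      correct <- correct + sum((p >= 0.5) == (y[!tr] == "viral"))
    }
    grid$cv_accuracy[cell] <- correct / n
  }
  best <- which.max(grid$cv_accuracy)  # ties: first cell (fewer trees, gini)
  forest <- ranger::ranger(
    x = Xs, y = y, probability = TRUE,
    num.trees = grid$num_trees[best], splitrule = grid$criterion[best],
    importance = "impurity", seed = seed, num.threads = 1)
  structure(list(
    group = group_spec$name,
    spec = group_spec,
    scaler = scaler,
    forest = forest,
    feature_order = feature_names(),
    cutoff = 0.5,
    meta = list(seed = seed, n_train = n, grid = grid,
                chosen = grid[best, c("num_trees", "criterion")])
  ), class = "group_model")
}

#' Predict viralness probabilities from a group model
#'
#' @param object A `group_model`.
#' @param newdata Raw (unscaled) feature matrix or named feature vector.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.group_model <- function(object, newdata, ...) {
  xs <- apply_scaler(object$scaler, newdata)
  unname(predict(object$forest, data = xs,
                 num.threads = 1)$predictions[, "viral"])
}

#' @export
print.group_model <- function(x, ...) {
  ch <- x$meta$chosen
  cat("<group_model> ", x$group,
      ": random forest (", ch$num_trees, " trees, ", ch$criterion,
      " splits), trained on ", x$meta$n_train, " fragments; ",
      "min window ", x$spec$min_window_bp, " bp\n", sep = "")
  invisible(x)
}

MODEL_FORMAT <- "viroscan_group_model/1"

#' Save / load a group model
#'
#' The file carries a format tag and the feature order; loading fails
#' loudly on corrupt files, wrong formats, or a feature-order mismatch with
#' the running package.
#'
#' @param model A `group_model`.
#' @param path File path (RDS).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `group_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "group_model"))
  saveRDS(list(format = MODEL_FORMAT, feature_order = model$feature_order,
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file ", path,
                                           ": ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT)) {
    stop("not a viroscan model file (or unsupported format): ", path)
  }
  if (!identical(obj$feature_order, feature_names())) {
    stop("model feature set (", length(obj$feature_order),
         " features) does not match this package (",
         length(feature_names()), "): ", path)
  }
  obj$model
}

#' Train classifiers for all groups from synthetic genome collections
#'
#' Convenience wrapper chaining [simulate_training_genomes()],
#' [build_training_sets()] and [train_group_classifier()].
#'
#' @param groups Viral groups to train.
#' @param preset Synthetic preset name or list.
#' @param n_per_group,n_negative Genomes per viral group / negative source.
#' @param seed Integer seed for the whole procedure.
#' @param specs Group specs used as fall-backs when `window_from_data` is
#'   FALSE (default [default_group_specs()]).
#' @param window_from_data Set each group's sliding-window width to the
#'   minimal genome size observed in its training genomes (default TRUE);
#'   otherwise the static `specs` values are used.
#' @return Named list of `group_model` objects, with the per-group held-out
#'   test tables attached as attribute `"test_sets"`.
#' @export
train_models <- function(groups = default_groups(), preset = "easy",
                         n_per_group = 50, n_negative = 50, seed = 1,
                         specs = default_group_specs(),
                         window_from_data = TRUE) {
  genomes <- simulate_training_genomes(preset, groups, n_per_group,
                                       n_negative, seed = seed)
  sets <- build_training_sets(genomes$viral, genomes$negatives,
                              seed = seed + 1L)
  models <- vector("list", length(groups))
  names(models) <- groups
  tests <- vector("list", length(groups))
  names(tests) <- groups
  for (i in seq_along(groups)) {
    g <- groups[i]
    sp <- if (g %in% names(specs)) specs[[g]] else
      list(name = g, min_window_bp = 10000)
    if (window_from_data) {
      sp$min_window_bp <- min(vapply(genomes$viral[[g]], `[[`, integer(1),
                                     "length"))
    }
    models[[g]] <- train_group_classifier(sets[[g]]$train, sp,
                                          seed = seed + 10L + i)
    tests[[g]] <- sets[[g]]$test
  }
  attr(models, "test_sets") <- tests
  models
}
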