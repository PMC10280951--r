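#' Stratified k-fold partition
#'
#' Partitions all indices into k disjoint folds with an (as near as
#' possible) equal proportion of positive outcomes in each fold: within
#' each class, shuffled indices are dealt round-robin, so per-fold class
#' counts differ by at most one.
#'
#' @param outcome 0/1 vector.
#' @param k number of folds (>= 2); every class must have at least k
#'   members.
#' @param seed integer seed.
#' @return List of k integer index vectors.
#' @export
#' @examples
#' folds <- stratified_folds(rep(c(0, 1), c(90, 10)), k = 10, seed = 1)
#' sapply(folds, function(f) sum(rep(c(0, 1), c(90, 10))[f]))
stratified_folds <- function(outcome, k, seed = 1) {
  y <- check_outcome(outcome, length(outcome), require_both = TRUE)
  check_scalar(k, "k", lo = 2)
  k <- as.integer(k)
  counts <- table(y)
  if (any(counts < k)) {
    kv_stop("class %s has fewer than k = %d members",
            paste(names(counts)[counts < k], collapse = ", "), k)
  }
  folds <- with_seed(seed, {
    out <- vector("list", k)
    for (cls in names(counts)) {
      idx <- sample(which(y == as.numeric(cls)))
      assign_to <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k)) {
        out[[f]] <- c(out[[f]], idx[assign_to == f])
      }
    }
    out
  })
  lapply(folds, sort)
}

#' Cross-validated hyperparameter grid search
#'
#' Reproduces the standard tuning protocol for a regression forest on a
#' 0/1 outcome: for every pair (x, y) in the grid, set
#' `mtry = max(1, floor(x * p))` and `min_node_size = max(1, round(N^y))`,
#' train on k - 1 stratified folds, score the held-out fold, and report the
#' root mean squared error of the held-out scores against the 0/1 outcome,
#' pooled over all folds. The best point attains the minimum RMSE, ties
#' broken toward smaller `mtry` then smaller `min_node_size`.
#'
#' By default `N` in the node-size formula is the full sample size (the
#' scale on which such grids are usually quoted); set
#' `node_size_n = "fold"` to use the per-fold training size instead.
#'
#' @param x feature matrix or [kv_dataset].
#' @param y 0/1 outcome (from the dataset if omitted).
#' @param x_grid,y_grid numeric vectors in (0, 1\]; defaults
#'   `seq(0.1, 1, 0.1)` each (a 10 x 10 grid).
#' @param k folds (default 10).
#' @param n_trees trees per forest (default 500).
#' @param node_size_n `"full"` (default) or `"fold"`.
#' @param seed integer seed (folds and forests).
#' @return An object of class `rf_tuning`: data frame `grid` with columns
#'   `x`, `y`, `mtry`, `min_node_size`, `cv_rmse`; `best_x`, `best_y`,
#'   `best_mtry`, `best_min_node_size`, `k`, `seed`.
#' @export
tune_forest <- function(x, y = NULL, x_grid = seq(0.1, 1, 0.1),
                        y_grid = seq(0.1, 1, 0.1), k = 10, n_trees = 500,
                        node_size_n = c("full", "fold"), seed = 1) {
  if (inherits(x, "kv_dataset")) {
    if (is.null(y)) y <- x$outcome
    x <- x$features
  }
  x <- as_feature_matrix(x)
  y <- check_outcome(y, nrow(x), require_both = FALSE)
  node_size_n <- match.arg(node_size_n)
  if (length(x_grid) == 0L || length(y_grid) == 0L ||
      any(x_grid <= 0 | x_grid > 1) || any(y_grid <= 0 | y_grid > 1)) {
    kv_stop("grid values must lie in (0, 1]")
  }
  p <- ncol(x)
  n <- nrow(x)
  folds <- if (length(unique(y)) > 1L) {
    stratified_folds(y, k, seed = substream_seed(seed, "folds"))
  } else {
    idx <- with_seed(substream_seed(seed, "folds"), sample.int(n))
    split(idx, rep_len(seq_len(as.integer(k)), n))
  }
  grid <- expand.grid(x = x_grid, y = y_grid, KEEP.OUT.ATTRS = FALSE)
  grid$mtry <- pmax(1L, as.integer(floor(grid$x * p)))
  grid$min_node_size <- NA_integer_
  grid$cv_rmse <- NA_real_
  for (g in seq_len(nrow(grid))) {
    sq_err <- 0
    n_pred <- 0L
    for (f in seq_along(folds)) {
      te <- folds[[f]]
      tr <- setdiff(seq_len(n), te)
      N <- if (node_size_n == "full") n else length(tr)
      mns <- max(1L, as.integer(round(N^grid$y[g])))
      grid$min_node_size[g] <- mns
      rf <- grow_forest(x[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                        mtry = grid$mtry[g], min_node_size = mns,
                        seed = substream_seed(seed, "tune", g * 1000 + f))
      sc <- predict_scores(rf, x[te, , drop = FALSE])
      sq_err <- sq_err + sum((sc - y[te])^2)
      n_pred <- n_pred + length(te)
    }
    grid$cv_rmse[g] <- sqrt(sq_err / n_pred)
  }
  ord <- order(grid$cv_rmse, grid$mtry, grid$min_node_size)
  best <- grid[ord[1L], ]
  structure(
    list(grid = grid, best_x = best$x, best_y = best$y,
         best_mtry = best$mtry, best_min_node_size = best$min_node_size,
         best_cv_rmse = best$cv_rmse, k = as.integer(k),
         node_size_n = node_size_n, seed = seed),
    class = "rf_tuning"
  )
}

#' @export
print.rf_tuning <- function(x, ...) {
  cat(sprintf(
    "<rf_tuning> %d grid points, %d-fold CV\n  best: x = %.2g (mtry = %d), y = %.2g (min node = %d), RMSE = %.5g\n",
    nrow(x$grid), x$k, x$best_x, x$best_mtry, x$best_y,
    x$best_min_node_size, x$best_cv_rmse))
  invisible(x)
}

#' Youden's J optimal probability threshold
#'
#' Scans candidate thresholds — the midpoints between consecutive sorted
#' unique scores, plus 0 and 1 — and returns the smallest candidate
#' maximizing J = sensitivity + specificity - 1 under the
#' `score >= threshold` classification rule. The smallest-maximizer
#' tie-break keeps sensitivity maximal among the optima, the conservative
#' choice for a screening threshold.
#'
#' @param scores numeric score vector in \[0, 1\].
#' @param labels 0/1 truth vector; both classes must be present.
#' @return Scalar threshold in \[0, 1\].
#' @export
#' @examples
#' youden_threshold(c(0.1, 0.2, 0.6, 0.8), c(0, 0, 1, 1))  # 0.4
youden_threshold <- function(scores, labels) {
  y <- check_outcome(labels, length(labels), require_both = TRUE)
  if (length(scores) != length(y)) kv_stop("scores/labels length mismatch")
  u <- sort(unique(scores))
  cand <- unique(c(0, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, 1))
  j <- vapply(cand, function(t) {
    pred <- as.numeric(scores >= t)
    sensitivity(y, pred) + specificity(y, pred) - 1
  }, numeric(1))
  # smallest candidate among the maximizers; J values within 1e-12 are
  # treated as tied so float noise cannot override the tie-break
  cand[which(j >= max(j) - 1e-12)][1]
}

#' Cross-validated Youden threshold
#'
#' For each of k stratified folds: train a regression forest on the other
#' folds, score the held-out fold, and compute its Youden-optimal
#' threshold. Reports the per-fold thresholds with their mean and sample
#' standard deviation — the quantity usually quoted as "the optimal
#' cut-off (sd)". For rare outcomes the mean lands far below 0.5, which is
#' why downstream classification should not default to 0.5.
#'
#' @param x feature matrix or [kv_dataset].
#' @param y 0/1 outcome (from the dataset if omitted).
#' @param k folds (default 10).
#' @param n_trees,mtry,min_node_size forest hyperparameters.
#' @param seed integer seed.
#' @return An object of class `threshold_cv`: list with
#'   `per_fold_thresholds`, `mean_threshold`, `sd_threshold`, `k`.
#' @export
youden_threshold_cv <- function(x, y = NULL, k = 10, n_trees = 500,
                                mtry = NULL, min_node_size = NULL,
                                seed = 1) {
  if (inherits(x, "kv_dataset")) {
    if (is.null(y)) y <- x$outcome
    x <- x$features
  }
  x <- as_feature_matrix(x)
  y <- check_outcome(y, nrow(x), require_both = TRUE)
  folds <- stratified_folds(y, k, seed = substream_seed(seed, "folds"))
  thresholds <- vapply(seq_along(folds), function(f) {
    te <- folds[[f]]
    tr <- setdiff(seq_along(y), te)
    if (length(unique(y[te])) < 2L) {
      kv_stop("fold %d holds a single outcome class; raise n or lower k", f)
    }
    rf <- grow_forest(x[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                      mtry = mtry, min_node_size = min_node_size,
                      seed = substream_seed(seed, "cvfold", f))
    youden_threshold(predict_scores(rf, x[te, , drop = FALSE]), y[te])
  }, numeric(1))
  structure(
    list(per_fold_thresholds = thresholds,
         mean_threshold = mean(thresholds),
         sd_threshold = stats::sd(thresholds),
         k = as.integer(k), seed = seed),
    class = "threshold_cv"
  )
}

#' @export
print.threshold_cv <- function(x, ...) {
  cat(sprintf(
    "<threshold_cv> %d-fold Youden threshold: mean %.4g (sd %.4g)\n",
    x$k, x$mean_threshold, x$sd_threshold))
  invisible(x)
}
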