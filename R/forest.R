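#' Grow a random forest with bootstrap bookkeeping
#'
#' Trains a ranger forest (classic Breiman bagging: each tree on a size-n
#' bootstrap resample drawn with replacement) and records, for every tree,
#' which participants were in its bootstrap sample — the table that defines
#' each participant's out-of-bag sub-forest. Regression mode ("probability
#' machine" on a 0/1 outcome) is the default; classification mode (majority
#' vote) exists for the classical out-of-bag importance.
#'
#' @param x feature matrix, data frame or [kv_dataset] (if a dataset with
#'   outcome, `y` may be omitted).
#' @param y 0/1 outcome vector.
#' @param n_trees number of trees (default 500).
#' @param mtry candidate features per split; default `floor(sqrt(p))`.
#' @param min_node_size minimum terminal node size; default 5 (regression)
#'   or 1 (classification).
#' @param mode `"regression"` or `"classification"`.
#' @param seed integer seed; fixes both the bootstrap resamples and the
#'   split search, so the same seed reproduces the forest exactly.
#' @return An object of class `kv_forest`: the fitted ranger model plus
#'   `inbag_counts` (n x T integer matrix), `membership` (n x T logical,
#'   `TRUE` iff participant i is in tree t's bootstrap sample), `mode`,
#'   `hyperparams`, and the training dimensions.
#' @export
#' @examples
#' d <- make_bias_scenario(200, rho = 0.5, seed = 1)$dataset
#' rf <- grow_forest(d, n_trees = 50, seed = 7)
#' rf
grow_forest <- function(x, y = NULL, n_trees = 500, mtry = NULL,
                        min_node_size = NULL,
                        mode = c("regression", "classification"), seed = 1) {
  if (inherits(x, "kv_dataset")) {
    if (is.null(y)) y <- x$outcome
    x <- x$features
  }
  x <- as_feature_matrix(x)
  mode <- match.arg(mode)
  n <- nrow(x)
  p <- ncol(x)
  y <- check_outcome(y, n, require_both = (mode == "classification"))
  check_scalar(n_trees, "n_trees", lo = 1)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  if (mtry < 1 || mtry > p) kv_stop("'mtry' must be in 1..%d, got %g", p, mtry)
  if (is.null(min_node_size)) {
    min_node_size <- if (mode == "regression") 5L else 1L
  }
  check_scalar(min_node_size, "min_node_size", lo = 1)
  yy <- if (mode == "classification") factor(y, levels = c(0, 1)) else y
  fit <- ranger::ranger(
    x = x, y = yy, num.trees = n_trees, mtry = mtry,
    min.node.size = min_node_size, keep.inbag = TRUE,
    seed = as.integer(seed), num.threads = 1
  )
  inbag <- do.call(cbind, fit$inbag.counts)
  stopifnot(nrow(inbag) == n, ncol(inbag) == n_trees)
  structure(
    list(fit = fit, inbag_counts = inbag, membership = inbag > 0L,
         mode = mode, n = n, p = p,
         feature_names = colnames(x),
         hyperparams = list(n_trees = as.integer(n_trees),
                            mtry = as.integer(mtry),
                            min_node_size = as.integer(min_node_size),
                            seed = as.integer(seed))),
    class = "kv_forest"
  )
}

#' @export
print.kv_forest <- function(x, ...) {
  h <- x$hyperparams
  cat(sprintf(
    "<kv_forest> %s forest: %d trees, mtry = %d, min node = %d (n = %d, p = %d)\n",
    x$mode, h$n_trees, h$mtry, h$min_node_size, x$n, x$p))
  cat(sprintf("  mean OOB fraction per participant: %.3f\n",
              mean(1 - colMeans(t(x$membership)))))
  invisible(x)
}

# Per-tree predictions on the 0/1 scale: n_query x T matrix. Regression
# trees return their raw mean response; classification trees return the
# predicted class as 0/1.
tree_predictions <- function(forest, newdata) {
  stopifnot(inherits(forest, "kv_forest"))
  if (inherits(newdata, "kv_dataset")) newdata <- newdata$features
  newdata <- as_feature_matrix(newdata)
  if (ncol(newdata) != forest$p) {
    kv_stop("query has %d columns; forest was trained on %d",
            ncol(newdata), forest$p)
  }
  pr <- stats::predict(forest$fit, data = newdata, predict.all = TRUE,
                       num.threads = 1)$predictions
  if (forest$mode == "classification") {
    lev <- forest$fit$forest$levels
    pr <- matrix(as.numeric(lev[pr]), nrow(pr), ncol(pr))
  }
  pr
}

#' Forest prediction scores, optionally over a tree subset
#'
#' Averages per-tree predictions over exactly the requested trees; with the
#' default (all trees) this reproduces the standard forest prediction. In
#' regression mode the score is the mean tree response; in classification
#' mode it is the fraction of trees voting class 1.
#'
#' @param forest a [grow_forest] model.
#' @param newdata feature matrix or [kv_dataset]; column order must match
#'   training.
#' @param trees integer vector of tree indices (default all).
#' @param tree_matrix optional precomputed [tree_predictions] matrix for
#'   `newdata`, to avoid repeated prediction passes.
#' @return Numeric score vector in \[0, 1\], one per query row.
#' @export
predict_scores <- function(forest, newdata, trees = NULL,
                           tree_matrix = NULL) {
  stopifnot(inherits(forest, "kv_forest"))
  if (is.null(tree_matrix)) tree_matrix <- tree_predictions(forest, newdata)
  T_ <- forest$hyperparams$n_trees
  if (is.null(trees)) trees <- seq_len(T_)
  trees <- as.integer(trees)
  if (length(trees) == 0L) kv_stop("empty tree subset")
  if (min(trees) < 1L || max(trees) > T_) {
    kv_stop("tree index out of range 1..%d", T_)
  }
  rowMeans(tree_matrix[, trees, drop = FALSE])
}

#' @export
predict.kv_forest <- function(object, newdata, trees = NULL, ...) {
  predict_scores(object, newdata, trees = trees)
}

#' Out-of-bag sub-forest for a participant
#'
#' Returns the indices of exactly those trees whose bootstrap sample
#' excluded training row `i` — the participant's sub-forest used by the
#' out-of-bag importance. May be empty (the caller must handle that).
#'
#' @param forest a [grow_forest] model.
#' @param i training-row index (1-based).
#' @return Integer vector of tree indices.
#' @export
oob_subforest <- function(forest, i) {
  stopifnot(inherits(forest, "kv_forest"))
  if (length(i) != 1L || i < 1L || i > forest$n) {
    kv_stop("participant index must be in 1..%d", forest$n)
  }
  which(!forest$membership[i, ])
}

#' Threshold scores into class labels
#'
#' Label 1 iff `score >= threshold` (the boundary rule used consistently
#' throughout the package, including Youden scanning).
#'
#' @param scores numeric vector in \[0, 1\].
#' @param threshold scalar in \[0, 1\].
#' @return Numeric 0/1 vector.
#' @export
#' @examples
#' classify(c(0.02, 0.05), 0.033)
classify <- function(scores, threshold) {
  check_scalar(threshold, "threshold", lo = 0, hi = 1)
  as.numeric(scores >= threshold)
}

#' Save / load a forest archive
#'
#' Round-trips the fitted forest (trees, hyperparameters, bootstrap
#' membership) through a versioned RDS archive; predictions after reload
#' are identical bit for bit.
#'
#' @param forest a [grow_forest] model.
#' @param path file path.
#' @return `path` invisibly (`save_forest`); the restored `kv_forest`
#'   (`load_forest`).
#' @export
save_forest <- function(forest, path) {
  stopifnot(inherits(forest, "kv_forest"))
  saveRDS(list(format = "knockvimp-forest", version = 1L, forest = forest),
          path)
  invisible(path)
}

#' @rdname save_forest
#' @export
load_forest <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "knockvimp-forest")) {
    kv_stop("not a knockvimp forest archive: %s", path)
  }
  obj$forest
}
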