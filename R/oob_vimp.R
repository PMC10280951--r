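#' Per-participant out-of-bag permutation importance
#'
#' The classical out-of-bag VIMP, computed exactly as defined for a single
#' forest: for every participant i with a non-empty sub-forest (the trees
#' whose bootstrap sample excluded i), score the sub-forest prediction on
#' the original observation set (accuracy indicator `P_i`), replace the
#' value of feature j with a randomly selected value of that feature drawn
#' from the other participants, re-score (`P_i*`), and average
#' `P_i - P_i*` over participants and over `n_repeats` independent
#' substitution draws. This is the importance measure whose inflation under
#' feature correlation the package demonstrates; it asks only about the
#' feature's role inside this particular forest.
#'
#' The accuracy indicator follows the forest mode: classification forests
#' use majority-vote correctness, regression forests threshold the
#' sub-forest score at 0.5 — the implicit operating point of the classical
#' measure, which is one of its documented weaknesses for rare outcomes.
#'
#' @param forest a [grow_forest] model trained on exactly these rows.
#' @param x training feature matrix or [kv_dataset].
#' @param y training 0/1 outcome (taken from `x` if it is a dataset).
#' @param features feature names or indices to evaluate (default: all).
#' @param n_repeats independent substitution draws per feature (default 5).
#' @param seed base seed; every (feature, repeat) pair uses its own derived
#'   substream.
#' @param method `"substitution"` (default) follows the per-participant
#'   algorithm above verbatim. `"permutation"` is the synchronized variant
#'   matching standard random-forest software (ranger's
#'   `importance = "permutation"`): one permutation of the feature column
#'   per repeat, scored as the mean over trees of the drop in that tree's
#'   out-of-bag accuracy. The permutation variant averages indicator deltas
#'   over (tree, participant) pairs rather than participant-level
#'   sub-forest votes, and is therefore far less noisy; it is what
#'   published OOB importance rankings are computed with.
#' @return An object of class `oob_vimp` (a data frame sorted by descending
#'   importance) with columns `feature`, `vimp`, `n_contributing`, `rank`.
#'   Attributes record the metric, mode, seed and `n_repeats`.
#' @export
#' @examples
#' sc <- make_bias_scenario(300, rho = 0.8, seed = 2)
#' rf <- grow_forest(sc$dataset, n_trees = 60, seed = 3)
#' oob_vimp(rf, sc$dataset, n_repeats = 2, seed = 4)
oob_vimp <- function(forest, x, y = NULL, features = NULL, n_repeats = 5,
                     seed = 1, method = c("substitution", "permutation")) {
  method <- match.arg(method)
  if (inherits(x, "kv_dataset")) {
    if (is.null(y)) y <- x$outcome
    x <- x$features
  }
  x <- as_feature_matrix(x)
  stopifnot(inherits(forest, "kv_forest"))
  if (nrow(x) != forest$n) {
    kv_stop("row count %d does not match the forest's training size %d",
            nrow(x), forest$n)
  }
  y <- check_outcome(y, nrow(x), require_both = FALSE)
  check_scalar(n_repeats, "n_repeats", lo = 1)
  p <- forest$p
  if (is.null(features)) features <- seq_len(p)
  if (is.character(features)) {
    idx <- match(features, forest$feature_names)
    if (anyNA(idx)) {
      kv_stop("unknown feature(s): %s",
              paste(features[is.na(idx)], collapse = ", "))
    }
    features <- idx
  }
  features <- as.integer(features)
  if (min(features) < 1L || max(features) > p) {
    kv_stop("feature index out of range 1..%d", p)
  }

  oob <- !forest$membership                     # n x T, TRUE = tree OOB for i
  n_oob <- rowSums(oob)
  contributing <- n_oob > 0L
  base_tree <- tree_predictions(forest, x)
  base_correct <- subforest_correct(base_tree, oob, n_oob, y)

  rows <- lapply(features, function(j) {
    if (method == "substitution") {
      oob_vimp_feature_impl(forest, x, y, j, n_repeats, seed, oob, n_oob,
                            contributing, base_correct)
    } else {
      oob_vimp_perm_impl(forest, x, y, j, n_repeats, seed, oob, base_tree)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$vimp, out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out,
            class = c("oob_vimp", "data.frame"),
            metric = if (method == "substitution") {
              "accuracy (sub-forest, 0.5 threshold)"
            } else {
              "accuracy (per-tree OOB, synchronized permutation)"
            },
            method = method,
            mode = forest$mode, seed = seed, n_repeats = n_repeats)
}

#' @rdname oob_vimp
#' @param j single feature name or index.
#' @export
oob_vimp_feature <- function(forest, x, y = NULL, j, n_repeats = 5,
                             seed = 1) {
  res <- oob_vimp(forest, x, y, features = j, n_repeats = n_repeats,
                  seed = seed)
  as.list(res[1, c("feature", "vimp", "n_contributing")])
}

# Accuracy indicator per participant from a per-tree prediction matrix:
# sub-forest score over the OOB trees, thresholded at 0.5, compared to y.
# Participants with empty sub-forests get NA.
subforest_correct <- function(tree_mat, oob, n_oob, y) {
  score <- rowSums(tree_mat * oob) / n_oob      # NaN where n_oob == 0
  correct <- as.numeric((score >= 0.5) == (y == 1))
  correct[n_oob == 0L] <- NA_real_
  correct
}

oob_vimp_feature_impl <- function(forest, x, y, j, n_repeats, seed, oob,
                                  n_oob, contributing, base_correct) {
  n <- nrow(x)
  drop_sum <- rep(0, n)
  for (r in seq_len(n_repeats)) {
    sub_seed <- substream_seed(seed, paste0("oob-subst-", j), r)
    # draw for each i a value of feature j from the other participants
    k <- with_seed(sub_seed, sample.int(n - 1L, n, replace = TRUE))
    donor <- k + (k >= seq_len(n))              # skip position i itself
    x_star <- x
    x_star[, j] <- x[donor, j]
    star_tree <- tree_predictions(forest, x_star)
    star_correct <- subforest_correct(star_tree, oob, n_oob, y)
    drop_sum <- drop_sum + (base_correct - star_correct)
  }
  vimp_i <- drop_sum / n_repeats
  data.frame(
    feature = forest$feature_names[j],
    vimp = mean(vimp_i[contributing]),
    n_contributing = sum(contributing),
    stringsAsFactors = FALSE
  )
}

# Synchronized-permutation variant: per tree, the drop in out-of-bag
# accuracy when feature j's column is globally permuted, averaged over
# trees and repeats. Per-tree 0/1 predictions are thresholded at 0.5
# (exact class votes for classification trees).
oob_vimp_perm_impl <- function(forest, x, y, j, n_repeats, seed, oob,
                               base_tree) {
  n <- nrow(x)
  n_per_tree <- colSums(oob)
  valid <- n_per_tree > 0L
  correct_base <- (base_tree >= 0.5) == (y == 1)
  acc_base <- colSums(correct_base * oob)[valid] / n_per_tree[valid]
  drop_sum <- 0
  for (r in seq_len(n_repeats)) {
    sub_seed <- substream_seed(seed, paste0("oob-perm-", j), r)
    perm <- with_seed(sub_seed, sample.int(n))
    x_star <- x
    x_star[, j] <- x[perm, j]
    star_tree <- tree_predictions(forest, x_star)
    correct_star <- (star_tree >= 0.5) == (y == 1)
    acc_star <- colSums(correct_star * oob)[valid] / n_per_tree[valid]
    drop_sum <- drop_sum + mean(acc_base - acc_star)
  }
  data.frame(
    feature = forest$feature_names[j],
    vimp = drop_sum / n_repeats,
    n_contributing = sum(rowSums(oob) > 0L),
    stringsAsFactors = FALSE
  )
}

#' @export
print.oob_vimp <- function(x, n = 10, ...) {
  cat(sprintf("Out-of-bag permutation VIMP (%s mode, %d repeats)\n",
              attr(x, "mode"), attr(x, "n_repeats")))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4,
                   row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("  ... %d more feature(s)\n", nrow(x) - n))
  invisible(x)
}

#' @export
plot.oob_vimp <- function(x, ...) {
  d <- as.data.frame(x)
  d <- d[order(d$vimp), ]
  graphics::barplot(d$vimp, names.arg = d$feature, horiz = TRUE, las = 1,
                    xlab = "OOB VIMP (drop in sub-forest accuracy)", ...)
  invisible(x)
}
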