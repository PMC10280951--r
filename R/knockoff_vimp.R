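#' Stratified train/test split
#'
#' Splits participants into disjoint, exhaustive train and test index sets.
#' With `stratify = TRUE` (default) the split is drawn within each outcome
#' class, so test-set prevalence matches the sample within one participant
#' per class.
#'
#' @param outcome 0/1 vector (or a [kv_dataset]).
#' @param test_fraction fraction held out for testing, in (0, 1);
#'   default 0.2.
#' @param stratify draw the split within class (default `TRUE`).
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
#' @examples
#' split_train_test(rep(c(0, 1), c(90, 10)), seed = 1)$test
split_train_test <- function(outcome, test_fraction = 0.2, stratify = TRUE,
                             seed = 1) {
  if (inherits(outcome, "kv_dataset")) outcome <- outcome$outcome
  check_scalar(test_fraction, "test_fraction", lo = 0, hi = 1, strict = TRUE)
  y <- check_outcome(outcome, length(outcome), require_both = TRUE)
  n <- length(y)
  if (stratify) {
    classes <- split(seq_len(n), y)
    small <- names(classes)[lengths(classes) < 2L]
    if (length(small) > 0L) {
      kv_stop("class %s has fewer than 2 members; cannot split",
              paste(small, collapse = ", "))
    }
    test <- with_seed(seed, {
      unlist(lapply(classes, function(idx) {
        k <- round(test_fraction * length(idx))
        k <- max(1L, min(length(idx) - 1L, k))
        sample(idx, k)
      }), use.names = FALSE)
    })
  } else {
    k <- max(1L, min(n - 1L, round(test_fraction * n)))
    test <- with_seed(seed, sample.int(n, k))
  }
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Sensitivity and specificity
#'
#' `sensitivity()` is TP / (TP + FN) and `specificity()` TN / (TN + FP) for
#' 0/1 truth and predicted labels. A truth vector without positives
#' (respectively negatives) makes the metric undefined and is an error,
#' never a silent zero.
#'
#' @param truth 0/1 vector of true labels.
#' @param pred 0/1 vector of predicted labels.
#' @return Scalar in \[0, 1\].
#' @export
#' @examples
#' sensitivity(c(1, 1, 0, 0), c(1, 0, 0, 1))  # 0.5
#' specificity(c(1, 1, 0, 0), c(1, 0, 0, 1))  # 0.5
sensitivity <- function(truth, pred) {
  check_label_pair(truth, pred)
  pos <- truth == 1
  if (!any(pos)) kv_stop("sensitivity undefined: no positives in 'truth'")
  mean(pred[pos] == 1)
}

#' @rdname sensitivity
#' @export
specificity <- function(truth, pred) {
  check_label_pair(truth, pred)
  neg <- truth == 0
  if (!any(neg)) kv_stop("specificity undefined: no negatives in 'truth'")
  mean(pred[neg] == 0)
}

check_label_pair <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    kv_stop("'truth' and 'pred' lengths differ (%d vs %d)", length(truth),
            length(pred))
  }
  if (!all(truth %in% c(0, 1)) || !all(pred %in% c(0, 1))) {
    kv_stop("labels must be coded 0/1")
  }
  invisible(TRUE)
}

#' Knockoff VIMP for one feature group
#'
#' The dual-forest knockoff importance: train `RF1` on the true features
#' and `RF2` on the same training rows with every member of `group`
#' replaced by its knockoff column (other features untouched, identical
#' hyperparameters, independent tree seed); score both on the held-out test
#' rows — `RF1` on the true features, `RF2` with the group knocked off —
#' and report the drop in sensitivity, specificity and accuracy at the
#' supplied probability threshold. Because the knockoffs preserve the
#' group's correlations with everything else but carry no outcome signal,
#' the drop measures the group's *conditional* predictive contribution.
#'
#' @param dataset a [kv_dataset] with outcome.
#' @param knockoffs knockoff matrix aligned row- and column-wise with the
#'   dataset (as produced by [generate_knockoffs] on the full sample).
#' @param group character vector of member feature names (or indices).
#' @param split train/test index list from [split_train_test].
#' @param threshold probability threshold in \[0, 1\] for classifying a
#'   score as predicted outcome 1.
#' @param n_trees,mtry,min_node_size forest hyperparameters shared by both
#'   forests (see [grow_forest]).
#' @param seed base seed for the two forests' tree-growing streams.
#' @param rf1 optional pre-trained `RF1` (reused across groups by
#'   [knockoff_vimp]); must have been trained on the training rows of
#'   `split` with the same hyperparameters.
#' @return A one-row data frame: `group`, `n_features`, `vimp_sens`,
#'   `vimp_spec`, `vimp_acc`, `sens_true`, `spec_true`, `sens_ko`,
#'   `spec_ko`, `threshold`, `n_train`, `n_test`. The per-participant
#'   accuracy-indicator deltas are attached as attribute `"delta"`.
#' @export
knockoff_vimp_group <- function(dataset, knockoffs, group, split,
                                threshold, n_trees = 500, mtry = NULL,
                                min_node_size = NULL, seed = 1, rf1 = NULL) {
  stopifnot(inherits(dataset, "kv_dataset"))
  x <- dataset$features
  y <- dataset$outcome
  if (is.null(y)) kv_stop("dataset has no outcome")
  knockoffs <- align_knockoffs(knockoffs, dataset)
  if (is.numeric(group)) group <- dataset$feature_names[group]
  unknown <- setdiff(group, dataset$feature_names)
  if (length(unknown) > 0L) {
    kv_stop("unknown group feature(s): %s", paste(unknown, collapse = ", "))
  }
  if (length(group) == 0L) kv_stop("empty group")
  check_scalar(threshold, "threshold", lo = 0, hi = 1)

  x_swapped <- x
  x_swapped[, group] <- knockoffs[, group]

  tr <- split$train
  te <- split$test
  if (is.null(rf1)) {
    rf1 <- grow_forest(x[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                       mtry = mtry, min_node_size = min_node_size,
                       seed = substream_seed(seed, "rf1"))
  }
  rf2 <- grow_forest(x_swapped[tr, , drop = FALSE], y[tr],
                     n_trees = rf1$hyperparams$n_trees,
                     mtry = rf1$hyperparams$mtry,
                     min_node_size = rf1$hyperparams$min_node_size,
                     seed = substream_seed(seed, paste0(
                       "rf2-", paste(group, collapse = "|"))))

  pred1 <- classify(predict_scores(rf1, x[te, , drop = FALSE]), threshold)
  pred2 <- classify(predict_scores(rf2, x_swapped[te, , drop = FALSE]),
                    threshold)
  truth <- y[te]
  sens1 <- sensitivity(truth, pred1); sens2 <- sensitivity(truth, pred2)
  spec1 <- specificity(truth, pred1); spec2 <- specificity(truth, pred2)
  acc1 <- mean(pred1 == truth); acc2 <- mean(pred2 == truth)
  out <- data.frame(
    group = paste(group, collapse = "+"),
    n_features = length(group),
    vimp_sens = sens1 - sens2,
    vimp_spec = spec1 - spec2,
    vimp_acc = acc1 - acc2,
    sens_true = sens1, spec_true = spec1,
    sens_ko = sens2, spec_ko = spec2,
    threshold = threshold,
    n_train = length(tr), n_test = length(te),
    stringsAsFactors = FALSE
  )
  attr(out, "delta") <- as.numeric(pred1 == truth) - as.numeric(pred2 == truth)
  attr(out, "test_truth") <- truth
  out
}

# Knockoffs must be row-aligned with the dataset; accept either original
# names or ".ko"-suffixed names, return a matrix indexed by original names.
align_knockoffs <- function(knockoffs, dataset) {
  knockoffs <- as_feature_matrix(knockoffs, what = "knockoffs")
  if (nrow(knockoffs) != nrow(dataset$features) ||
      ncol(knockoffs) != ncol(dataset$features)) {
    kv_stop("knockoffs (%d x %d) are not aligned with the dataset (%d x %d)",
            nrow(knockoffs), ncol(knockoffs), nrow(dataset$features),
            ncol(dataset$features))
  }
  nm <- sub("\\.ko$", "", colnames(knockoffs))
  if (!identical(nm, dataset$feature_names)) {
    kv_stop("knockoff columns do not match the dataset's feature order")
  }
  colnames(knockoffs) <- nm
  knockoffs
}

#' Grouped knockoff VIMP study
#'
#' Runs the full dual-forest knockoff importance analysis: one knockoff
#' matrix for the complete sample (generated before splitting, so train and
#' test use the same draw), one stratified train/test split, one reference
#' forest `RF1`, and then one knockoff forest per group per level of the
#' grouping scheme. Each group's `RF2` seed is derived deterministically
#' from the base seed and the group name, so the study is reproducible as a
#' whole and per group.
#'
#' @param dataset a [kv_dataset] with outcome.
#' @param grouping a [grouping_scheme]; `NULL` means one singleton group
#'   per feature (level `"features"`).
#' @param knockoffs optional precomputed knockoff matrix; by default fitted
#'   (`[fit_knockoffs]`) and sampled on the full dataset.
#' @param threshold numeric threshold in \[0, 1\], or `"auto"` (default) to
#'   use the mean cross-validated Youden threshold from
#'   [youden_threshold_cv] computed on the training rows.
#' @param test_fraction held-out fraction (default 0.2).
#' @param n_trees,mtry,min_node_size forest hyperparameters.
#' @param s_rule decorrelation rule for the knockoff fit (`"equi"`/`"sdp"`).
#' @param k_folds folds for the `"auto"` threshold (default 10).
#' @param seed base seed for knockoff draw, split, thresholds and forests.
#' @return An object of class `knockoff_vimp` (a data frame): one row per
#'   group per level, columns `level`, `group`, `n_features`, `vimp_sens`,
#'   `vimp_spec`, `vimp_acc`, `sens_true`, `spec_true`, `sens_ko`,
#'   `spec_ko`, `threshold`, plus an `error` column (NA unless that group
#'   failed). Attributes record the configuration, split sizes, test
#'   prevalence and seed.
#' @export
#' @examples
#' sc <- make_bias_scenario(400, rho = 0.7, seed = 5)
#' kv <- knockoff_vimp(sc$dataset, sc$grouping, threshold = 0.2,
#'                     n_trees = 50, seed = 5)
#' kv
knockoff_vimp <- function(dataset, grouping = NULL, knockoffs = NULL,
                          threshold = "auto", test_fraction = 0.2,
                          n_trees = 500, mtry = NULL, min_node_size = NULL,
                          s_rule = c("equi", "sdp"), k_folds = 10,
                          seed = 1) {
  stopifnot(inherits(dataset, "kv_dataset"))
  if (is.null(dataset$outcome)) kv_stop("dataset has no outcome")
  s_rule <- match.arg(s_rule)
  if (is.null(grouping)) {
    grouping <- grouping_scheme(list(features = stats::setNames(
      as.list(dataset$feature_names), dataset$feature_names)))
  }
  stopifnot(inherits(grouping, "grouping_scheme"))
  for (lev in names(grouping$levels)) {
    unknown <- setdiff(unlist(grouping$levels[[lev]]), dataset$feature_names)
    if (length(unknown) > 0L) {
      kv_stop("level '%s': unknown feature name(s): %s", lev,
              paste(unknown, collapse = ", "))
    }
  }
  if (is.null(knockoffs)) {
    km <- fit_knockoffs(dataset$features, s_rule = s_rule)
    knockoffs <- generate_knockoffs(km, dataset$features,
                                    seed = substream_seed(seed, "knockoffs"))
  } else {
    km <- NULL
  }
  knockoffs <- align_knockoffs(knockoffs, dataset)
  split <- split_train_test(dataset$outcome, test_fraction = test_fraction,
                            seed = substream_seed(seed, "split"))
  tr <- split$train
  if (identical(threshold, "auto")) {
    x_tr <- dataset$features[tr, , drop = FALSE]
    thr <- youden_threshold_cv(
      x_tr, dataset$outcome[tr], k = k_folds, n_trees = n_trees,
      mtry = mtry, min_node_size = min_node_size,
      seed = substream_seed(seed, "threshold"))
    threshold <- thr$mean_threshold
  } else {
    check_scalar(threshold, "threshold", lo = 0, hi = 1)
    thr <- NULL
  }
  rf1 <- grow_forest(dataset$features[tr, , drop = FALSE],
                     dataset$outcome[tr], n_trees = n_trees, mtry = mtry,
                     min_node_size = min_node_size,
                     seed = substream_seed(seed, "rf1"))

  rows <- list()
  for (lev in names(grouping$levels)) {
    for (g in names(grouping$levels[[lev]])) {
      feats <- grouping$levels[[lev]][[g]]
      row <- tryCatch({
        r <- knockoff_vimp_group(
          dataset, knockoffs, feats, split, threshold = threshold,
          n_trees = n_trees, mtry = mtry, min_node_size = min_node_size,
          seed = substream_seed(seed, paste0("group-", lev, "/", g)),
          rf1 = rf1)
        r$group <- g
        r$error <- NA_character_
        r
      }, error = function(e) {
        data.frame(group = g, n_features = length(feats),
                   vimp_sens = NA_real_, vimp_spec = NA_real_,
                   vimp_acc = NA_real_, sens_true = NA_real_,
                   spec_true = NA_real_, sens_ko = NA_real_,
                   spec_ko = NA_real_,
                   threshold = if (is.numeric(threshold)) threshold
                               else NA_real_,
                   n_train = length(tr), n_test = length(split$test),
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      })
      row <- cbind(data.frame(level = lev, stringsAsFactors = FALSE), row)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("knockoff_vimp", "data.frame"),
            threshold = threshold,
            threshold_cv = thr,
            test_prevalence = mean(dataset$outcome[split$test]),
            split = split,
            knockoff_model = km,
            config = list(test_fraction = test_fraction, n_trees = n_trees,
                          mtry = mtry, min_node_size = min_node_size,
                          s_rule = s_rule, k_folds = k_folds, seed = seed))
}

#' Replicated knockoff VIMP
#'
#' Re-runs the split, knockoff draw and both forests `R` times on the same
#' dataset and reports the mean and standard deviation of each group's
#' VIMPs — a direct handle on the Monte-Carlo instability expected when
#' resampling is involved.
#'
#' @inheritParams knockoff_vimp
#' @param R number of replicates.
#' @param ... passed on to [knockoff_vimp].
#' @return A data frame with per-group means and standard deviations of
#'   `vimp_sens`, `vimp_spec`, `vimp_acc` across replicates.
#' @export
knockoff_vimp_replicates <- function(dataset, grouping = NULL, R = 5,
                                     seed = 1, ...) {
  runs <- lapply(seq_len(R), function(r) {
    kv <- knockoff_vimp(dataset, grouping,
                        seed = substream_seed(seed, "replicate", r), ...)
    kv$replicate <- r
    as.data.frame(kv)
  })
  all <- do.call(rbind, runs)
  agg <- function(v) {
    stats::aggregate(all[[v]], by = list(level = all$level, group = all$group),
                     FUN = function(z) c(mean = mean(z), sd = stats::sd(z)))
  }
  out <- agg("vimp_sens")
  res <- data.frame(level = out$level, group = out$group,
                    vimp_sens_mean = out$x[, "mean"],
                    vimp_sens_sd = out$x[, "sd"])
  for (v in c("vimp_spec", "vimp_acc")) {
    o <- agg(v)
    res[[paste0(v, "_mean")]] <- o$x[, "mean"]
    res[[paste0(v, "_sd")]] <- o$x[, "sd"]
  }
  res$replicates <- R
  res
}

#' Restrict a knockoff VIMP table to jointly positive groups
#'
#' Report view keeping only the rows whose sensitivity and specificity
#' VIMPs are both strictly above zero — the groups with an unambiguous
#' positive conditional contribution on both operating characteristics.
#'
#' @param x a `knockoff_vimp` table (or plain data frame with `vimp_sens`
#'   and `vimp_spec` columns).
#' @return The filtered table (same class).
#' @export
positive_vimp_view <- function(x) {
  stopifnot(all(c("vimp_sens", "vimp_spec") %in% names(x)))
  keep <- !is.na(x$vimp_sens) & !is.na(x$vimp_spec) &
    x$vimp_sens > 0 & x$vimp_spec > 0
  x[keep, , drop = FALSE]
}

#' @export
print.knockoff_vimp <- function(x, ...) {
  cat(sprintf(
    "Knockoff VIMP study: %d group(s), threshold = %.4g, test prevalence = %.4g\n",
    nrow(x), attr(x, "threshold"), attr(x, "test_prevalence")))
  cols <- c("level", "group", "n_features", "vimp_sens", "vimp_spec",
            "vimp_acc")
  print.data.frame(as.data.frame(x)[, cols], digits = 4, row.names = FALSE)
  if (any(!is.na(x$error))) {
    cat(sprintf("  %d group(s) failed; see $error\n", sum(!is.na(x$error))))
  }
  invisible(x)
}

#' @export
summary.knockoff_vimp <- function(object, ...) {
  ok <- is.na(object$error)
  cat(sprintf("Groups evaluated: %d (failed: %d)\n", sum(ok), sum(!ok)))
  cat(sprintf("Jointly positive (sens & spec > 0): %d\n",
              nrow(positive_vimp_view(object))))
  top <- as.data.frame(object)[ok, ]
  top <- top[order(-top$vimp_sens), c("level", "group", "vimp_sens",
                                      "vimp_spec", "vimp_acc")]
  cat("Top groups by sensitivity VIMP:\n")
  print.data.frame(utils::head(top, 5), digits = 4, row.names = FALSE)
  invisible(object)
}

#' @export
plot.knockoff_vimp <- function(x, ...) {
  d <- as.data.frame(x)
  d <- d[is.na(d$error), ]
  graphics::plot(d$vimp_spec, d$vimp_sens,
                 xlab = "VIMP (specificity)", ylab = "VIMP (sensitivity)",
                 pch = 19, ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  graphics::text(d$vimp_spec, d$vimp_sens, labels = d$group, pos = 3,
                 cex = 0.7)
  invisible(x)
}
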