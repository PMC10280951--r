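# Independent exhaustive recomputation of the per-participant OOB VIMP:
# walks every (participant, tree, substitution draw) triple explicitly,
# sharing only the substitution draws (inputs) with the implementation.
brute_force_oob_vimp <- function(forest, x, y, j, n_repeats, seed) {
  n <- nrow(x)
  T_ <- forest$hyperparams$n_trees
  per_part <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sub <- oob_subforest(forest, i)
    if (length(sub) == 0L) next
    # baseline: average this participant's row over each OOB tree, one
    # tree at a time
    preds <- vapply(sub, function(t) {
      predict_scores(forest, x[i, , drop = FALSE], trees = t)
    }, numeric(1))
    p_base <- as.numeric((mean(preds) >= 0.5) == (y[i] == 1))
    drops <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      sub_seed <- substream_seed(seed, paste0("oob-subst-", j), r)
      k <- with_seed(sub_seed, sample.int(n - 1L, n, replace = TRUE))
      donor <- k + (k >= seq_len(n))
      zi <- x[i, , drop = FALSE]
      zi[1, j] <- x[donor[i], j]
      preds_star <- vapply(sub, function(t) {
        predict_scores(forest, zi, trees = t)
      }, numeric(1))
      p_star <- as.numeric((mean(preds_star) >= 0.5) == (y[i] == 1))
      drops[r] <- p_base - p_star
    }
    per_part[i] <- mean(drops)
  }
  mean(per_part, na.rm = TRUE)
}


# Independent brute-force Youden maximizer: evaluate J on a dense candidate
# set (all observed scores, their midpoints, 0 and 1) and take the smallest
# maximizer.
brute_force_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, u, (u[-1] + u[-length(u)]) / 2, 1)))
  best_j <- -Inf
  best_t <- NA_real_
  for (t in cand) {
    pred <- as.numeric(scores >= t)
    tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
    tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  best_t
}

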