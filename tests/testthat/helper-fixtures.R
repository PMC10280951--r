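# Shared fixtures, built in code at test time.

# Small supervised dataset with two informative and several null features.
tiny_signal_dataset <- function(n = 200, n_noise = 3, seed = 11,
                                prevalence = 0.35) {
  simulate_scenario(
    n, corr = list(list(type = "identity", size = 2 + n_noise)),
    causal_idx = c(1L, 2L), effects = c(1.5, 1.5),
    prevalence = prevalence, seed = seed
  )
}

# Deterministic forest on a tiny problem (cheap to predict exhaustively).
tiny_forest <- function(n = 30, p = 4, n_trees = 3, seed = 5) {
  d <- simulate_scenario(
    n, p = p, causal_idx = 1L, effects = 2, prevalence = 0.4, seed = seed
  )
  rf <- grow_forest(d, n_trees = n_trees, mtry = 2, min_node_size = 2,
                    seed = seed + 1)
  list(dataset = d, forest = rf)
}

# t-based 95% interval for the mean of a replicate vector.
replicate_ci <- function(z, level = 0.95) {
  m <- mean(z)
  se <- stats::sd(z) / sqrt(length(z))
  m + c(-1, 1) * stats::qt(1 - (1 - level) / 2, length(z) - 1) * se
}

covers_zero <- function(z) {
  ci <- replicate_ci(z)
  ci[1] <= 0 && 0 <= ci[2]
}
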