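test_that("stratified splits are disjoint, exhaustive, proportionate", {
  y <- rep(c(0, 1), c(90, 10))
  sp <- split_train_test(y, test_fraction = 0.2, seed = 1)
  expect_length(sp$test, 20L)
  expect_length(sp$train, 80L)
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_identical(sum(y[sp$test]), 2)  # 2 of 20 positives at prevalence 0.10
  expect_identical(split_train_test(y, seed = 7), split_train_test(y, seed = 7))
  expect_false(identical(split_train_test(y, seed = 7),
                         split_train_test(y, seed = 8)))
  expect_error(split_train_test(rep(c(0, 1), c(99, 1))), "fewer than 2")
})

test_that("sensitivity and specificity follow the 2x2 table", {
  expect_identical(sensitivity(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_identical(specificity(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_identical(sensitivity(c(1, 1, 0, 0), c(1, 1, 1, 1)), 1)
  expect_identical(specificity(c(1, 1, 0, 0), c(1, 1, 1, 1)), 0)
  expect_identical(sensitivity(c(1, 1, 0, 0), c(1, 0, 0, 1)), 0.5)
  expect_identical(specificity(c(1, 1, 0, 0), c(1, 0, 0, 1)), 0.5)
  expect_error(sensitivity(c(0, 0), c(0, 0)), "no positives")
  expect_error(specificity(c(1, 1), c(1, 1)), "no negatives")
})

test_that("accuracy VIMP decomposes into the prevalence-weighted mixture", {
  sc <- make_bias_scenario(500, rho = 0.6, seed = 91)
  kv <- knockoff_vimp(sc$dataset, sc$grouping, threshold = 0.2,
                      n_trees = 40, seed = 92)
  pi_t <- attr(kv, "test_prevalence")
  for (r in seq_len(nrow(kv))) {
    expect_lt(abs(kv$vimp_acc[r] -
                    (pi_t * kv$vimp_sens[r] + (1 - pi_t) * kv$vimp_spec[r])),
              1e-12)
  }
})

test_that("study tables are complete, deterministic, and well-formed", {
  sc <- make_domain_scenario(300, groups = c(a = 4, b = 3, c = 3),
                             causal_groups = "a", seed = 93)
  kv <- knockoff_vimp(sc$dataset, sc$grouping, threshold = 0.3,
                      n_trees = 30, seed = 94)
  # 3 level-1 + 6 level-2 groups
  expect_identical(nrow(kv), 9L)
  expect_true(all(is.na(kv$error)))
  expect_true(all(abs(kv[, c("vimp_sens", "vimp_spec", "vimp_acc")]) <= 1))
  kv2 <- knockoff_vimp(sc$dataset, sc$grouping, threshold = 0.3,
                       n_trees = 30, seed = 94)
  expect_identical(as.data.frame(kv), as.data.frame(kv2))
})

test_that("the jointly-positive report view drops non-positive rows", {
  tab <- data.frame(group = c("a", "b", "c"),
                    vimp_sens = c(0.05, 0.04, -0.01),
                    vimp_spec = c(0.02, -0.01, 0.02),
                    error = NA_character_)
  kept <- positive_vimp_view(tab)
  expect_identical(kept$group, "a")
})

test_that("misaligned knockoffs and bad thresholds are rejected", {
  sc <- make_bias_scenario(200, rho = 0.5, seed = 95)
  km <- fit_knockoffs(sc$dataset$features)
  xk <- generate_knockoffs(km, sc$dataset$features, seed = 1)
  sp <- split_train_test(sc$dataset$outcome, seed = 1)
  expect_error(
    knockoff_vimp_group(sc$dataset, xk[, -1], "X1", sp, threshold = 0.2),
    "aligned")
  expect_error(
    knockoff_vimp_group(sc$dataset, xk[, c(2, 1, 3:8)], "X1", sp,
                        threshold = 0.2),
    "order")
  expect_error(
    knockoff_vimp_group(sc$dataset, xk, "X1", sp, threshold = 1.7),
    "threshold")
  expect_error(
    knockoff_vimp_group(sc$dataset, xk, character(), sp, threshold = 0.2),
    "empty group")
})

test_that("knocking off everything under a pure-noise outcome is null", {
  accs <- sapply(1:6, function(r) {
    d <- simulate_scenario(250, p = 5, causal_idx = integer(),
                           effects = numeric(), prevalence = 0.4,
                           seed = 700 + r)
    kv <- knockoff_vimp(d, grouping_scheme(list(
      l1 = list(all = paste0("X", 1:5)))), threshold = 0.4, n_trees = 40,
      seed = 800 + r)
    kv$vimp_acc
  })
  expect_true(covers_zero(accs))
})

test_that("a null singleton is centered while the causal group stands out", {
  res <- t(sapply(1:8, function(r) {
    sc <- make_bias_scenario(700, rho = 0.8, n_noise = 2, seed = 900 + r)
    kv <- knockoff_vimp(
      sc$dataset,
      grouping_scheme(list(l1 = list(causal = c("X1", "X2"), x3 = "X3"))),
      threshold = 0.2, n_trees = 60, seed = 1000 + r)
    c(causal = kv$vimp_acc[kv$group == "causal"],
      x3 = kv$vimp_acc[kv$group == "x3"])
  }))
  expect_true(covers_zero(res[, "x3"]))
  expect_gt(mean(res[, "causal"]), 0)
  expect_gt(mean(res[, "causal"]), mean(res[, "x3"]))
})

test_that("correlated causal features dampen each other's singleton VIMP", {
  # two strongly correlated causal features can substitute for one another,
  # so each singleton VIMP is (on average) no larger than their union's
  res <- t(sapply(1:6, function(r) {
    d <- simulate_scenario(
      600, corr = list(list(type = "exchangeable", size = 2, rho = 0.9),
                       list(type = "identity", size = 2)),
      causal_idx = c(1L, 2L), effects = c(1, 1), prevalence = 0.3,
      seed = 1100 + r)
    kv <- knockoff_vimp(d, grouping_scheme(list(
      singletons = list(x1 = "X1", x2 = "X2"),
      unions = list(both = c("X1", "X2")))),
      threshold = 0.3, n_trees = 60, seed = 1200 + r)
    c(x1 = kv$vimp_acc[kv$group == "x1"],
      x2 = kv$vimp_acc[kv$group == "x2"],
      both = kv$vimp_acc[kv$group == "both"])
  }))
  expect_lte(mean(pmax(res[, "x1"], res[, "x2"])), mean(res[, "both"]) + 0.02)
})

test_that("replicated runs report stable per-group summaries", {
  sc <- make_bias_scenario(300, rho = 0.5, n_noise = 1, seed = 96)
  rep_tab <- knockoff_vimp_replicates(
    sc$dataset, grouping_scheme(list(l1 = list(causal = c("X1", "X2")))),
    R = 3, threshold = 0.2, n_trees = 30, seed = 97)
  expect_identical(nrow(rep_tab), 1L)
  expect_true(is.finite(rep_tab$vimp_sens_sd))
  expect_identical(rep_tab$replicates, 3)
})
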