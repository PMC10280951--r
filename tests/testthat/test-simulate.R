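test_that("feature simulation is deterministic and seed-isolated", {
  a <- simulate_features(4, p = 2, seed = 1)
  b <- simulate_features(4, p = 2, seed = 1)
  expect_identical(a$features, b$features)
  c <- simulate_features(4, p = 2, seed = 2)
  expect_false(identical(a$features, c$features))
  # serialization-level identity
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset(a, f1); write_dataset(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulated features match the population correlation", {
  d <- simulate_features(
    50000, corr = list(list(type = "exchangeable", size = 2, rho = 0.7)),
    seed = 3)
  expect_lt(abs(cor(d$features)[1, 2] - 0.7), 0.02)

  d3 <- simulate_features(
    50000, corr = list(list(type = "ar1", size = 3, rho = 0.5)), seed = 4)
  C <- cor(d3$features)
  expect_lt(abs(C[1, 2] - 0.5), 0.02)
  expect_lt(abs(C[1, 3] - 0.25), 0.02)  # AR(1): rho^|j-k|
  # every entry close to the population matrix
  R <- 0.5^abs(outer(1:3, 1:3, "-"))
  expect_lt(max(abs(C - R)), 0.02)
})

test_that("invalid correlation specs are rejected with a diagnostic", {
  expect_error(
    simulate_features(10, corr = list(list(type = "exchangeable", size = 3,
                                           rho = -0.9)), seed = 1),
    "block 1")
  expect_error(
    simulate_features(10, corr = list(list(type = "ar1", size = 2,
                                           rho = 1.2)), seed = 1),
    "block 1")
  bad <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(simulate_features(10, corr = bad, seed = 1),
               "positive definite")
})

test_that("outcome simulation hits the target prevalence", {
  d <- simulate_features(20000, p = 2, seed = 5)
  out <- simulate_outcome(d, integer(), numeric(), prevalence = 0.5,
                          seed = 6)
  expect_gte(mean(out$outcome), 0.48)
  expect_lte(mean(out$outcome), 0.52)

  d2 <- simulate_features(100000, p = 1, seed = 7)
  rare <- simulate_outcome(d2, integer(), numeric(), prevalence = 0.027,
                           seed = 8)
  expect_gte(mean(rare$outcome), 0.024)
  expect_lte(mean(rare$outcome), 0.030)
  # determinism
  rare2 <- simulate_outcome(d2, integer(), numeric(), prevalence = 0.027,
                            seed = 8)
  expect_identical(rare$outcome, rare2$outcome)
})

test_that("the intercept solves its defining prevalence equation", {
  d <- simulate_features(20000, p = 2, seed = 9)
  out <- simulate_outcome(d, c(1L, 2L), c(1, 1), prevalence = 0.3, seed = 10)
  # defining equation: mean over the realized sample, re-evaluated directly
  expect_lt(abs(mean(plogis(out$alpha + out$eta)) - 0.3), 1e-6)
  # population cross-check: alpha from quadrature over the N(0, 2) linear
  # predictor distribution agrees with the sample-solved alpha
  pop_prev <- function(a) {
    stats::integrate(function(z) plogis(a + sqrt(2) * z) * dnorm(z),
                     -Inf, Inf)$value
  }
  a_pop <- uniroot(function(a) pop_prev(a) - 0.3, c(-20, 20),
                   tol = 1e-10)$root
  expect_lt(abs(out$alpha - a_pop), 0.05)
})

test_that("outcome simulation rejects invalid inputs", {
  d <- simulate_features(50, p = 2, seed = 1)
  expect_error(simulate_outcome(d, 1L, 1, prevalence = 0, seed = 1),
               "prevalence")
  expect_error(simulate_outcome(d, 1L, 1, prevalence = 1.2, seed = 1),
               "prevalence")
  expect_error(simulate_outcome(d, 3L, 1, prevalence = 0.3, seed = 1),
               "out of range")
  expect_error(simulate_outcome(d, 1L, c(1, 2), prevalence = 0.3, seed = 1),
               "length")
})

test_that("bias scenario builds the stated correlation and null structure", {
  expect_error(make_bias_scenario(100, rho = 1), "< 1")

  sc0 <- make_bias_scenario(3000, rho = 0, n_noise = 1, seed = 21)
  expect_lt(abs(cor(sc0$dataset$features[, "X2"],
                    sc0$dataset$features[, "X3"])), 0.05)

  sc <- make_bias_scenario(50000, rho = 0.7, n_noise = 0, seed = 22)
  expect_lt(abs(cor(sc$dataset$features[, "X2"],
                    sc$dataset$features[, "X3"]) - 0.7), 0.02)
  # X3's generating coefficient is exactly zero, assertable from metadata
  expect_identical(sc$dataset$meta$causal_idx, c(1L, 2L))
  expect_false(3L %in% sc$dataset$meta$causal_idx)
  # grouping marks the roles
  expect_identical(sc$grouping$levels$level1$causal, c("X1", "X2"))
  expect_identical(sc$grouping$levels$level1$correlated_null, "X3")
})

test_that("X3 carries no signal beyond X2 (partial association null)", {
  # by construction the partial correlation of X3 with the linear predictor
  # given X2 is 0; check the realized outcome partial association across
  # replicates
  pcor <- sapply(1:10, function(r) {
    sc <- make_bias_scenario(2000, rho = 0.7, n_noise = 0, seed = 100 + r)
    x <- sc$dataset$features
    y <- sc$dataset$outcome
    r3 <- resid(lm(x[, "X3"] ~ x[, "X2"]))
    ry <- resid(lm(y ~ x[, "X2"]))
    cor(r3, ry)
  })
  expect_true(covers_zero(pcor))
})

test_that("domain scenario nests level 2 inside level 1 and confines effects", {
  sc <- make_domain_scenario(300, groups = c(a = 4, b = 4, c = 4),
                             causal_groups = "a", beta = 1, seed = 31)
  g <- sc$grouping
  expect_length(g$levels, 2L)
  # every level-2 feature appears in exactly one level-1 group (set cover)
  l1 <- g$levels$level1
  for (feats in g$levels$level2) {
    hits <- vapply(l1, function(f1) sum(feats %in% f1), integer(1))
    expect_identical(sum(hits), length(feats))
    expect_identical(sum(hits > 0), 1L)
  }
  # causal features exactly the causal group's, others zero-effect
  causal_feats <- sc$dataset$feature_names[sc$dataset$meta$causal_idx]
  expect_setequal(causal_feats, l1$a)
  expect_true(all(sc$dataset$meta$effects == 1))
  # grouping round-trips through YAML unchanged
  f <- tempfile(fileext = ".yaml")
  write_grouping(g, f)
  expect_identical(read_grouping(f, sc$dataset)$levels, g$levels)
})

test_that("overlapping groups within a level are rejected", {
  expect_error(
    grouping_scheme(list(l1 = list(a = c("f1", "f2"), b = c("f2", "f3")))),
    "more than one group")
})
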