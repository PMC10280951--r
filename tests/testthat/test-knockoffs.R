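test_that("equicorrelated s matches the closed form", {
  expect_equal(solve_s_equi(diag(3)), rep(1, 3), tolerance = 1e-10)
  # 2x2 equicorrelation: lambda_min = 1 - rho, s = min(2 (1 - rho), 1)
  for (rho in c(0.3, 0.5, 0.8)) {
    s <- solve_s_equi(matrix(c(1, rho, rho, 1), 2))
    expect_equal(s, rep(min(2 * (1 - rho), 1), 2), tolerance = 1e-10)
  }
  # rescaling by the diagonal of a covariance (not correlation) matrix
  Sigma <- matrix(c(4, 3, 3, 9), 2)  # corr 0.5, sds 2 and 3
  s <- solve_s_equi(Sigma)
  expect_equal(s, min(2 * 0.5, 1) * c(4, 9), tolerance = 1e-10)
  expect_error(solve_s_equi(matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("coordinate-ascent s dominates the equicorrelated point", {
  expect_equal(solve_s_sdp(diag(2)), rep(1, 2), tolerance = 1e-8)
  # symmetric problem keeps symmetric solution (rho = 0.8: the
  # equicorrelated point is the optimum of the 2x2 program)
  s <- solve_s_sdp(matrix(c(1, .8, .8, 1), 2))
  expect_equal(s[1], s[2], tolerance = 1e-6)
  expect_equal(s, c(0.4, 0.4), tolerance = 1e-4)
  # random PD matrices: sum(s_sdp) >= sum(s_equi) - 1e-6 and G stays PSD
  for (seed in 1:5) {
    p <- 4
    A <- with_seed(seed, matrix(rnorm(p * p), p))
    Sigma <- crossprod(A) + diag(p) * 0.5
    s_e <- solve_s_equi(Sigma)
    s_o <- solve_s_sdp(Sigma)
    expect_gte(sum(s_o), sum(s_e) - 1e-6)
    lmin <- min(eigen(2 * Sigma - diag(s_o, p), symmetric = TRUE,
                      only.values = TRUE)$values)
    expect_gte(lmin, -1e-8 * mean(diag(Sigma)))
  }
})

test_that("fitting recovers the population covariance on iid data", {
  x <- with_seed(41, matrix(rnorm(10000 * 3), ncol = 3))
  km <- fit_knockoffs(x)
  expect_lt(max(abs(km$Sigma - diag(3))), 0.05)
  expect_true(all(abs(km$s - 1) < 0.05))
  # no randomness in fitting
  km2 <- fit_knockoffs(x)
  expect_identical(km[c("mu", "Sigma", "s", "cond_coef", "cond_cov")],
                   km2[c("mu", "Sigma", "s", "cond_coef", "cond_cov")])
})

test_that("degenerate inputs are rejected by name", {
  x <- cbind(a = rnorm(50), b = rep(2, 50), c = rnorm(50))
  expect_error(fit_knockoffs(x), "b")
  expect_error(fit_knockoffs(x[1, , drop = FALSE]), "n > 1")
})

test_that("joint covariance is assembled exactly from Sigma and s", {
  x <- with_seed(42, matrix(rnorm(500), ncol = 1))
  km <- fit_knockoffs(x)
  km$Sigma <- matrix(1); km$s <- 1  # p = 1 canonical case
  G <- joint_covariance(km)
  expect_equal(unname(G), matrix(c(1, 0, 0, 1), 2), tolerance = 1e-12)

  x3 <- with_seed(43, matrix(rnorm(3000), ncol = 3))
  km3 <- fit_knockoffs(x3)
  G3 <- joint_covariance(km3)
  expect_true(isSymmetric(G3, tol = 1e-10))
  expect_gte(min(eigen(G3, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # diag of the cross block is Sigma_jj - s_j
  expect_equal(unname(diag(G3[1:3, 4:6])), unname(diag(km3$Sigma) - km3$s),
               tolerance = 1e-12)
})

test_that("knockoffs are independent copies when Sigma = I and s = 1", {
  n <- 20000
  x <- with_seed(44, matrix(rnorm(n * 2), ncol = 2))
  km <- fit_knockoffs(x)
  xk <- generate_knockoffs(km, x, seed = 45)
  for (j in 1:2) expect_lt(abs(cor(x[, j], xk[, j])), 0.02)
  # determinism and column naming
  expect_identical(xk, generate_knockoffs(km, x, seed = 45))
  expect_identical(colnames(xk), c("X1.ko", "X2.ko"))
})

test_that("the s = 0 limit returns an exact copy", {
  x <- with_seed(46, matrix(rnorm(200), ncol = 2))
  km <- fit_knockoffs(x)
  p <- 2
  km$s <- rep(0, p)
  km$cond_coef <- diag(p)
  km$cond_cov <- matrix(0, p, p)
  xk <- generate_knockoffs(km, x, seed = 1)
  expect_equal(unname(xk), unname(x), tolerance = 1e-12)
})

test_that("empirical joint second moments match the analytic G", {
  # AR(1) originals: the fitted sampler's G should be realized empirically
  n <- 50000
  d <- simulate_features(
    n, corr = list(list(type = "ar1", size = 4, rho = 0.5)), seed = 47)
  x <- d$features
  km <- fit_knockoffs(x)
  xk <- generate_knockoffs(km, x, seed = 48)
  emp <- cov(cbind(x, xk))
  expect_lt(max(abs(emp - joint_covariance(km))), 0.05)
})

test_that("swapping a column with its knockoff preserves joint covariance", {
  n <- 20000
  d <- simulate_features(
    n, corr = list(list(type = "exchangeable", size = 3, rho = 0.4)),
    seed = 49)
  x <- d$features
  km <- fit_knockoffs(x)
  xk <- generate_knockoffs(km, x, seed = 50)
  full <- cbind(x, xk)
  for (j in 1:3) {
    swapped <- full
    swapped[, c(j, j + 3)] <- swapped[, c(j + 3, j)]
    expect_lt(max(abs(cov(full) - cov(swapped))), 0.06)
  }
})

test_that("knockoffs carry no outcome association beyond the originals", {
  # with the outcome never entering generation, corr(xk_j, y | x) is
  # centered on zero across redraws of the knockoff matrix
  d <- tiny_signal_dataset(n = 1500, seed = 51)
  km <- fit_knockoffs(d$features)
  pc <- sapply(1:12, function(r) {
    xk <- generate_knockoffs(km, d$features, seed = 600 + r)
    rk <- resid(lm(xk[, 1] ~ d$features))
    ry <- resid(lm(d$outcome ~ d$features))
    cor(rk, ry)
  })
  expect_true(covers_zero(pc))
})

test_that("dimension mismatches are rejected", {
  x <- with_seed(52, matrix(rnorm(300), ncol = 3))
  km <- fit_knockoffs(x)
  expect_error(generate_knockoffs(km, x[, 1:2]), "does not match")
})
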