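#' Fit a second-order Gaussian knockoff model
#'
#' Estimates the Gaussian approximation used to generate model-X knockoffs:
#' column means `mu`, a shrinkage covariance `Sigma` guaranteed positive
#' definite, and the decorrelation vector `s` chosen so that the joint
#' covariance of originals and knockoffs,
#' `G = [[Sigma, Sigma - diag(s)], [Sigma - diag(s), Sigma]]`,
#' is positive semidefinite. Knockoffs sampled from the fitted model match
#' the originals' first two joint moments (approximately) while carrying no
#' association with any outcome, which is exactly what makes them a valid
#' null reference for conditional importance.
#'
#' Covariance shrinkage is a convex combination
#' `(1 - gamma) * S + gamma * diag(S)` with the analytic
#' Schafer-Strimmer intensity for the off-diagonal entries as the starting
#' point, escalated geometrically until the correlation matrix has minimum
#' eigenvalue above `1e-8`. This keeps the fit usable in the p close to n
#' regimes typical of epidemiological feature panels.
#'
#' @param x numeric matrix, data frame, or [kv_dataset] of features (no
#'   missing values; no constant columns).
#' @param s_rule `"equi"` (closed-form equicorrelated, default) or `"sdp"`
#'   (coordinate-ascent maximization of `sum(s)`, see [solve_s_sdp]).
#' @param shrinkage `"auto"` (default) for the analytic intensity, or a
#'   numeric value in \[0, 1\] to force a specific gamma (still escalated if
#'   the result is not positive definite).
#' @return An object of class `knockoff_model` with elements `mu`, `Sigma`,
#'   `s`, `cond_coef` (matrix C such that E\[Xko | X = x\] = mu + (x - mu) C),
#'   `cond_cov`, `shrinkage`, `s_rule`, `feature_names`, `n`.
#' @seealso [generate_knockoffs], [joint_covariance], [solve_s_equi]
#' @export
#' @examples
#' x <- matrix(rnorm(600), 200, 3)
#' km <- fit_knockoffs(x)
#' km
fit_knockoffs <- function(x, s_rule = c("equi", "sdp"), shrinkage = "auto") {
  if (inherits(x, "kv_dataset")) x <- x$features
  x <- as_feature_matrix(x)
  s_rule <- match.arg(s_rule)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) kv_stop("need n > 1 rows to fit a covariance")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    kv_stop("constant column(s) cannot be knocked off: %s",
            paste(colnames(x)[v == 0], collapse = ", "))
  }
  S <- stats::cov(x)
  gamma <- if (identical(shrinkage, "auto")) {
    shrinkage_intensity(x, S)
  } else {
    check_scalar(shrinkage, "shrinkage", lo = 0, hi = 1)
  }
  repeat {
    Sigma <- (1 - gamma) * S + gamma * diag(diag(S), p)
    R <- stats::cov2cor(Sigma)
    lmin <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (lmin > 1e-8) break
    if (gamma >= 1) kv_stop("covariance cannot be made positive definite")
    gamma <- min(1, gamma + (1 - gamma) / 2 + 1e-3)
  }
  s <- switch(s_rule, equi = solve_s_equi(Sigma), sdp = solve_s_sdp(Sigma))
  Sinv_s <- solve(Sigma, diag(s, p))          # Sigma^{-1} diag(s)
  cond_coef <- diag(p) - Sinv_s               # Sigma^{-1} (Sigma - diag(s))
  cond_cov <- diag(2 * s, p) - diag(s, p) %*% Sinv_s
  cond_cov <- (cond_cov + t(cond_cov)) / 2
  if (!all(is.finite(cond_coef)) || !all(is.finite(cond_cov))) {
    kv_stop("non-finite conditional parameters; covariance is too
ill-conditioned")
  }
  structure(
    list(mu = colMeans(x), Sigma = Sigma, s = s, cond_coef = cond_coef,
         cond_cov = cond_cov, shrinkage = gamma, s_rule = s_rule,
         feature_names = colnames(x), n = n),
    class = "knockoff_model"
  )
}

# Schafer-Strimmer analytic shrinkage intensity toward diag(S):
# gamma = sum of estimated variances of the off-diagonal covariance entries
# over the sum of their squares, clamped to [0, 1].
shrinkage_intensity <- function(x, S = stats::cov(x)) {
  n <- nrow(x)
  if (n < 4L) return(0.1)
  xc <- sweep(x, 2, colMeans(x))
  # var-hat of S_ij = n / (n-1)^3 * sum_k (w_kij - wbar_ij)^2,
  # with w_kij = xc_ki * xc_kj; computed via crossproducts.
  W2 <- crossprod(xc^2)            # sum_k w_kij^2
  Wb <- crossprod(xc) / n          # wbar_ij
  Vs <- n / (n - 1)^3 * (W2 - n * Wb^2)
  off <- upper.tri(S)
  denom <- sum(S[off]^2)
  if (denom <= 0) return(0)
  min(1, max(0, sum(Vs[off]) / denom))
}

#' Equicorrelated decorrelation vector
#'
#' Closed-form s for second-order knockoffs: on the correlation scale every
#' coordinate gets `min(2 * lambda_min(R), 1)` where `R = cov2cor(Sigma)`,
#' then the vector is rescaled by `diag(Sigma)`. If the resulting joint
#' matrix G fails positive semidefiniteness numerically (minimum eigenvalue
#' below `-1e-10` relative), a backing-off multiplier just below 1 is
#' applied until it passes.
#'
#' @param Sigma positive-definite covariance matrix.
#' @return Numeric vector `s` of length `ncol(Sigma)`.
#' @export
#' @examples
#' solve_s_equi(matrix(c(1, .8, .8, 1), 2))   # c(0.4, 0.4)
solve_s_equi <- function(Sigma) {
  Sigma <- check_covariance(Sigma)
  R <- stats::cov2cor(Sigma)
  lmin <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  s_corr <- min(2 * lmin, 1)
  s <- s_corr * diag(Sigma)
  backoff_s(s, Sigma)
}

#' Decorrelation vector by coordinate-ascent SDP
#'
#' Maximizes `sum(s)` subject to `0 <= s_j <= 1` (correlation scale) and
#' `diag(s)` \eqn{\preceq} `2R`, the semidefinite program whose solution gives
#' more powerful knockoffs than the equicorrelated point. The program is
#' solved by cyclic coordinate ascent started at the (always feasible)
#' equicorrelated vector: with `M = 2R - diag(s)` positive definite, the
#' largest feasible increase of coordinate j is `1 / (M^{-1})_jj` (Schur
#' complement), so each step is exact and the objective never decreases —
#' in particular the returned `sum(s)` is never below the equicorrelated
#' value. The result is rescaled by `diag(Sigma)`.
#'
#' @param Sigma positive-definite covariance matrix.
#' @param max_sweeps maximum number of full coordinate sweeps.
#' @param tol stop when a full sweep improves `sum(s)` by less than this.
#' @return Numeric vector `s`.
#' @export
solve_s_sdp <- function(Sigma, max_sweeps = 50, tol = 1e-10) {
  Sigma <- check_covariance(Sigma)
  R <- stats::cov2cor(Sigma)
  p <- nrow(R)
  lmin <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  s <- rep(min(2 * lmin, 1), p)
  # shave a hair off the equicorrelated start so M = 2R - diag(s) is
  # numerically invertible at the initial point
  s <- s * (1 - 1e-9)
  for (sweep in seq_len(max_sweeps)) {
    gain <- 0
    for (j in seq_len(p)) {
      M <- 2 * R - diag(s, p)
      Minv_jj <- tryCatch(solve(M)[j, j], error = function(e) NA_real_)
      if (!is.finite(Minv_jj) || Minv_jj <= 0) next
      # step back slightly from the PSD boundary to keep M invertible
      delta <- min(1 - s[j], (1 / Minv_jj) * (1 - 1e-9))
      if (delta > 0) {
        s[j] <- s[j] + delta
        gain <- gain + delta
      }
    }
    if (gain < tol) break
  }
  backoff_s(s * diag(Sigma), Sigma)
}

# Shared validation: symmetric positive-definite covariance.
check_covariance <- function(Sigma) {
  if (!is.matrix(Sigma) || !isSymmetric(unname(Sigma), tol = 1e-8)) {
    kv_stop("'Sigma' must be a symmetric matrix")
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    kv_stop("'Sigma' must be positive definite (min eigenvalue %.3g)",
            min(ev))
  }
  Sigma
}

# Multiply s by 0.999 until G = [[Sigma, Sigma - diag(s)], ...] passes the
# numerical PSD check (min eigenvalue >= -1e-10 * scale). G is PSD iff
# 2*Sigma - diag(s) is PSD (for PD Sigma), which is the cheaper check.
backoff_s <- function(s, Sigma) {
  scale <- mean(diag(Sigma))
  for (k in 1:100) {
    lmin <- min(eigen(2 * Sigma - diag(s, nrow(Sigma)), symmetric = TRUE,
                      only.values = TRUE)$values)
    if (lmin >= -1e-10 * scale) return(pmax(s, 0))
    s <- s * 0.999
  }
  kv_stop("could not restore positive semidefiniteness of the joint matrix")
}

#' Joint covariance of originals and knockoffs
#'
#' Returns the 2p x 2p matrix
#' `G = [[Sigma, Sigma - diag(s)], [Sigma - diag(s), Sigma]]`
#' exactly as used by the conditional sampler — the population covariance of
#' `cbind(X, Xko)` under the fitted model.
#'
#' @param model a fitted [fit_knockoffs] model.
#' @return A 2p x 2p symmetric matrix.
#' @export
joint_covariance <- function(model) {
  stopifnot(inherits(model, "knockoff_model"))
  p <- length(model$s)
  C <- model$Sigma - diag(model$s, p)
  G <- rbind(cbind(model$Sigma, C), cbind(C, model$Sigma))
  nm <- c(model$feature_names, paste0(model$feature_names, ".ko"))
  dimnames(G) <- list(nm, nm)
  G
}

#' Sample knockoff copies of a feature matrix
#'
#' Draws each knockoff row from the Gaussian conditional of the fitted
#' model: mean `mu + (x_i - mu) %*% cond_coef`, covariance `cond_cov`
#' (eigenvalues clipped at zero for the factorization). Column order and
#' names follow the originals with a `.ko` suffix. The same seed always
#' yields identical output. Because the outcome never enters, knockoffs are
#' conditionally null by construction.
#'
#' @param model a fitted [fit_knockoffs] model.
#' @param x feature matrix (or [kv_dataset]) to knock off; columns must
#'   match the fitted model.
#' @param seed integer seed.
#' @return An n x p numeric matrix of knockoffs.
#' @export
#' @examples
#' x <- matrix(rnorm(400), 100, 4)
#' km <- fit_knockoffs(x)
#' xk <- generate_knockoffs(km, x, seed = 1)
generate_knockoffs <- function(model, x, seed) {
  stopifnot(inherits(model, "knockoff_model"))
  if (inherits(x, "kv_dataset")) x <- x$features
  x <- as_feature_matrix(x)
  p <- length(model$s)
  if (ncol(x) != p) {
    kv_stop("feature count %d does not match fitted model (p = %d)",
            ncol(x), p)
  }
  n <- nrow(x)
  ctr <- sweep(x, 2, model$mu)
  mean_mat <- sweep(ctr %*% model$cond_coef, 2, model$mu, "+")
  e <- eigen(model$cond_cov, symmetric = TRUE)
  lam <- e$values
  if (min(lam) < -1e-10 * max(abs(lam), 1)) {
    kv_stop("conditional covariance is not positive semidefinite")
  }
  lam[lam < 0] <- 0
  root <- e$vectors %*% diag(sqrt(lam), p)
  Z <- with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  xk <- mean_mat + Z %*% t(root)
  colnames(xk) <- paste0(colnames(x), ".ko")
  xk
}

#' @export
print.knockoff_model <- function(x, ...) {
  cat(sprintf(
    "<knockoff_model> second-order Gaussian, p = %d (fit on n = %d)\n",
    length(x$s), x$n))
  cat(sprintf("  s rule: %s | shrinkage gamma = %.4g\n", x$s_rule,
              x$shrinkage))
  cat(sprintf("  s: min %.4g, median %.4g, max %.4g\n", min(x$s),
              stats::median(x$s), max(x$s)))
  invisible(x)
}

#' @export
coef.knockoff_model <- function(object, ...) {
  list(mu = object$mu, Sigma = object$Sigma, s = object$s)
}

#' Simulate method for knockoff models
#'
#' `simulate()` draws `nsim` independent knockoff matrices for `x`
#' (wrapping [generate_knockoffs]); returns a list of matrices.
#'
#' @param object a `knockoff_model`.
#' @param nsim number of independent knockoff draws.
#' @param seed base seed; draw k uses substream `k`.
#' @param x feature matrix to knock off.
#' @param ... unused.
#' @return List of `nsim` knockoff matrices.
#' @export
simulate.knockoff_model <- function(object, nsim = 1, seed = 1, x, ...) {
  lapply(seq_len(nsim), function(k) {
    generate_knockoffs(object, x, seed = substream_seed(seed, "ko-draw", k))
  })
}
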