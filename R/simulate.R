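#' Build a block correlation matrix
#'
#' Assembles a p x p correlation matrix from a list of independent blocks.
#' Each block is a list with `size` (number of features), `rho` (within-block
#' correlation parameter) and `type`: `"identity"` (rho ignored),
#' `"exchangeable"` (constant off-diagonal rho) or `"ar1"`
#' (corr(j, k) = rho^|j-k|). Blocks are placed on the diagonal in order;
#' features in different blocks are independent.
#'
#' @param blocks list of block descriptors (see Details).
#' @return A correlation matrix, verified positive definite.
#' @export
#' @examples
#' corr_from_blocks(list(list(type = "ar1", size = 3, rho = 0.5)))
corr_from_blocks <- function(blocks) {
  if (!is.list(blocks) || length(blocks) == 0L) {
    kv_stop("'blocks' must be a non-empty list")
  }
  mats <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    size <- blk$size
    if (is.null(size) || size < 1L) kv_stop("block %d: invalid size", b)
    type <- match.arg(blk$type, c("identity", "exchangeable", "ar1"))
    rho <- if (is.null(blk$rho)) 0 else blk$rho
    m <- switch(type,
      identity = diag(size),
      exchangeable = {
        if (rho <= -1 / max(1, size - 1) || rho >= 1) {
          kv_stop("block %d (exchangeable, size %d): rho = %g is outside the
positive-definite range (-1/(size-1), 1)", b, size, rho)
        }
        matrix(rho, size, size) + diag(1 - rho, size)
      },
      ar1 = {
        if (abs(rho) >= 1) {
          kv_stop("block %d (ar1): |rho| = %g must be < 1", b, abs(rho))
        }
        rho^abs(outer(seq_len(size), seq_len(size), "-"))
      }
    )
    mats[[b]] <- m
  }
  p <- sum(vapply(mats, nrow, integer(1)))
  R <- matrix(0, p, p)
  at <- 0L
  for (m in mats) {
    idx <- at + seq_len(nrow(m))
    R[idx, idx] <- m
    at <- at + nrow(m)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) {
    kv_stop("assembled correlation matrix is not positive definite (min
eigenvalue %.3g)", min(ev))
  }
  R
}

#' Simulate correlated Gaussian features
#'
#' Draws n i.i.d. rows from a zero-mean multivariate Gaussian with the
#' correlation structure given either as a block descriptor list
#' (see [corr_from_blocks]) or as an explicit correlation matrix. The same
#' seed always yields a bitwise-identical matrix.
#'
#' @param n number of rows (participants).
#' @param corr block descriptor list, or a p x p correlation/covariance
#'   matrix. `NULL` with `p` supplied means independent standard normals.
#' @param p number of features; required when `corr` is `NULL`, otherwise
#'   inferred.
#' @param seed integer seed.
#' @param feature_names optional column names (default `X1..Xp`).
#' @return A [kv_dataset] without outcome; `meta` records the seed and the
#'   population correlation matrix.
#' @export
#' @examples
#' d <- simulate_features(100, corr = list(list(type = "exchangeable",
#'   size = 2, rho = 0.7)), seed = 1)
#' cor(d$features)
simulate_features <- function(n, corr = NULL, p = NULL, seed,
                              feature_names = NULL) {
  check_scalar(n, "n", lo = 2)
  if (is.null(corr)) {
    if (is.null(p)) kv_stop("supply 'p' when 'corr' is NULL")
    R <- diag(p)
  } else if (is.matrix(corr)) {
    if (!isSymmetric(unname(corr), tol = 1e-8)) {
      kv_stop("'corr' matrix must be symmetric")
    }
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12) {
      kv_stop("'corr' matrix is not positive definite (min eigenvalue %.3g)",
              min(ev))
    }
    R <- corr
  } else {
    R <- corr_from_blocks(corr)
  }
  p <- nrow(R)
  L <- chol(R)
  X <- with_seed(seed, matrix(stats::rnorm(n * p), n, p) %*% L)
  colnames(X) <- if (is.null(feature_names)) paste0("X", seq_len(p)) else {
    if (length(feature_names) != p) kv_stop("feature_names length != p")
    feature_names
  }
  kv_dataset(X, meta = list(seed = seed, corr = R, n = n, p = p))
}

#' Solve the intercept for a target outcome prevalence
#'
#' Finds alpha such that the mean of plogis(alpha + eta) over the supplied
#' linear predictor equals the target prevalence, by monotone root-finding.
#'
#' @param eta numeric vector of linear-predictor values (without intercept).
#' @param prevalence target rate in (0, 1).
#' @param tol root tolerance on the prevalence scale.
#' @return The intercept alpha.
#' @export
solve_prevalence_intercept <- function(eta, prevalence, tol = 1e-10) {
  check_scalar(prevalence, "prevalence", lo = 0, hi = 1, strict = TRUE)
  f <- function(a) mean(stats::plogis(a + eta)) - prevalence
  lo <- -50; hi <- 50
  while (f(lo) > 0) lo <- lo * 2
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Simulate a binary outcome from a logistic model
#'
#' Draws outcome_i ~ Bernoulli(plogis(alpha + sum_j beta_j x_ij)) over the
#' causal features, with the intercept alpha solved numerically so that the
#' expected prevalence over the realized sample equals the target.
#'
#' @param features numeric matrix or [kv_dataset].
#' @param causal_idx integer indices of the truly causal columns (may be
#'   empty for a pure-noise outcome).
#' @param effects log-odds coefficients, aligned with `causal_idx`.
#' @param prevalence target outcome rate in (0, 1).
#' @param seed integer seed.
#' @return List with `outcome` (0/1 vector), `alpha` (solved intercept) and
#'   `eta` (linear predictor without intercept).
#' @export
simulate_outcome <- function(features, causal_idx, effects, prevalence, seed) {
  if (inherits(features, "kv_dataset")) features <- features$features
  features <- as_feature_matrix(features)
  p <- ncol(features)
  causal_idx <- as.integer(causal_idx)
  if (length(causal_idx) > 0 &&
      (min(causal_idx) < 1L || max(causal_idx) > p)) {
    kv_stop("causal index out of range 1..%d", p)
  }
  if (length(effects) != length(causal_idx)) {
    kv_stop("'effects' length %d does not match %d causal indices",
            length(effects), length(causal_idx))
  }
  eta <- if (length(causal_idx) == 0) rep(0, nrow(features)) else {
    drop(features[, causal_idx, drop = FALSE] %*% effects)
  }
  alpha <- solve_prevalence_intercept(eta, prevalence)
  pr <- stats::plogis(alpha + eta)
  outcome <- with_seed(seed, stats::rbinom(length(pr), 1L, pr))
  list(outcome = as.numeric(outcome), alpha = alpha, eta = eta)
}

#' Simulate a full scenario (features + outcome)
#'
#' Convenience wrapper: draws features and outcome from one base seed,
#' using independent derived substreams for each stage so either stage can
#' be re-run on its own.
#'
#' @inheritParams simulate_features
#' @inheritParams simulate_outcome
#' @return A [kv_dataset] with outcome; `meta` stores the full scenario
#'   specification including the generating coefficients.
#' @export
simulate_scenario <- function(n, corr = NULL, p = NULL, causal_idx = integer(),
                              effects = numeric(), prevalence = 0.3, seed,
                              feature_names = NULL) {
  d <- simulate_features(n, corr = corr, p = p,
                         seed = substream_seed(seed, "features"),
                         feature_names = feature_names)
  out <- simulate_outcome(d$features, causal_idx, effects, prevalence,
                          seed = substream_seed(seed, "outcome"))
  meta <- d$meta
  meta$causal_idx <- causal_idx
  meta$effects <- effects
  meta$prevalence <- prevalence
  meta$alpha <- out$alpha
  meta$base_seed <- seed
  kv_dataset(d$features, outcome = out$outcome, meta = meta)
}

#' The correlated-null bias scenario
#'
#' Generates the canonical three-feature demonstration of the inflation of
#' out-of-bag importances under correlation: X1 and X2 are independent true
#' causal risk factors, X3 is correlated with X2 (corr = rho) but has
#' exactly zero generating coefficient, and `n_noise` additional features
#' are independent pure noise. The returned grouping marks `{X1, X2}`
#' causal, `{X3}` correlated-null, and each noise feature as a singleton.
#'
#' @param n sample size.
#' @param rho correlation between X2 and X3, in \[0, 1).
#' @param betas length-2 log-odds effects for X1 and X2.
#' @param prevalence target outcome rate.
#' @param n_noise number of extra independent null features.
#' @param seed integer seed.
#' @return List with `dataset` (a [kv_dataset]) and `grouping`
#'   (a [grouping_scheme]).
#' @export
#' @examples
#' sc <- make_bias_scenario(500, rho = 0.7, seed = 1)
#' sc$dataset
make_bias_scenario <- function(n, rho, betas = c(1, 1), prevalence = 0.2,
                               n_noise = 5, seed = 1) {
  check_scalar(rho, "rho", lo = 0, hi = 1)
  if (rho >= 1) kv_stop("'rho' must be < 1")
  stopifnot(length(betas) == 2L, n_noise >= 0L)
  blocks <- list(
    list(type = "identity", size = 1),                     # X1
    list(type = "exchangeable", size = 2, rho = rho)       # X2, X3
  )
  if (n_noise > 0) {
    blocks <- c(blocks, list(list(type = "identity", size = n_noise)))
  }
  nms <- c("X1", "X2", "X3",
           if (n_noise > 0) paste0("noise", seq_len(n_noise)))
  d <- simulate_scenario(
    n, corr = blocks, causal_idx = c(1L, 2L), effects = betas,
    prevalence = prevalence, seed = seed, feature_names = nms
  )
  d$meta$scenario <- "bias"
  d$meta$rho <- rho
  groups <- c(
    list(causal = c("X1", "X2"), correlated_null = "X3"),
    if (n_noise > 0) {
      stats::setNames(as.list(paste0("noise", seq_len(n_noise))),
                      paste0("noise", seq_len(n_noise)))
    }
  )
  list(dataset = d,
       grouping = grouping_scheme(list(level1 = groups),
                                  feature_names = d$feature_names))
}

#' A nested feature-domain scenario
#'
#' Generates features partitioned into named level-1 domains, each split
#' into two nested level-2 sub-domains, with all causal effects confined to
#' the stated causal domain(s). Features within a domain share an
#' exchangeable correlation; domains are mutually independent.
#'
#' @param n sample size.
#' @param groups named integer vector: features per level-1 domain (each
#'   must be >= 2 so it can be split into two sub-domains).
#' @param causal_groups names of the domains whose features carry effects.
#' @param beta log-odds effect given to every feature in a causal domain.
#' @param rho_within exchangeable correlation within each domain.
#' @param prevalence target outcome rate.
#' @param seed integer seed.
#' @return List with `dataset` and a two-level nested `grouping`.
#' @export
make_domain_scenario <- function(n, groups = c(cardio = 4, sleep = 4,
                                               labs = 4),
                                 causal_groups = names(groups)[1], beta = 1,
                                 rho_within = 0.3, prevalence = 0.3,
                                 seed = 1) {
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    kv_stop("'groups' must be uniquely named")
  }
  if (any(groups < 2L)) kv_stop("every domain needs >= 2 features")
  unknown <- setdiff(causal_groups, names(groups))
  if (length(unknown) > 0L) {
    kv_stop("unknown causal group(s): %s", paste(unknown, collapse = ", "))
  }
  blocks <- lapply(unname(groups), function(sz) {
    list(type = "exchangeable", size = sz, rho = rho_within)
  })
  nms <- unlist(lapply(names(groups), function(g) {
    paste0(g, "_", seq_len(groups[[g]]))
  }))
  causal_idx <- which(sub("_[0-9]+$", "", nms) %in% causal_groups)
  d <- simulate_scenario(
    n, corr = blocks, causal_idx = causal_idx,
    effects = rep(beta, length(causal_idx)), prevalence = prevalence,
    seed = seed, feature_names = nms
  )
  d$meta$scenario <- "domains"
  d$meta$causal_groups <- causal_groups
  level1 <- lapply(names(groups), function(g) {
    nms[sub("_[0-9]+$", "", nms) == g]
  })
  names(level1) <- names(groups)
  level2 <- list()
  for (g in names(groups)) {
    feats <- level1[[g]]
    half <- ceiling(length(feats) / 2)
    level2[[paste0(g, "_a")]] <- feats[seq_len(half)]
    level2[[paste0(g, "_b")]] <- feats[(half + 1):length(feats)]
  }
  list(dataset = d,
       grouping = grouping_scheme(list(level1 = level1, level2 = level2),
                                  feature_names = d$feature_names))
}
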