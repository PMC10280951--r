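#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the default generator, evaluates
#' `expr`, and restores the previous state on exit. Every stochastic
#' operation in the package routes through this so that user-level RNG
#' state is never consumed or clobbered.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic substream seed
#'
#' Maps a base seed plus a stage label (and optional index) to a new seed in
#' \[0, 2^31 - 2\] via an FNV-1a style string hash. Used so that independent
#' stages (feature draw, outcome draw, per-feature substitution streams,
#' per-group forest seeds) get reproducible but non-overlapping streams from
#' one base seed.
#'
#' @param seed integer base seed.
#' @param label character stage label (e.g. `"features"`, a group name).
#' @param index optional integer appended to the label.
#' @return integer seed.
#' @export
#' @examples
#' substream_seed(1, "features")
#' substream_seed(1, "outcome", 3)
substream_seed <- function(seed, label, index = NULL) {
  stopifnot(length(label) == 1L, is.character(label))
  key <- paste0(seed, "/", label, if (!is.null(index)) paste0("#", index))
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # 16777619 * h mod 2^31, kept in double precision exactly
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483646L) + 1L
}

# Stop with a formatted message, no call in the condition.
kv_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Assert a numeric scalar in [lo, hi]; name used in the error message.
check_scalar <- function(x, name, lo = -Inf, hi = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    kv_stop("'%s' must be a finite numeric scalar", name)
  }
  ok <- if (strict) (x > lo && x < hi) else (x >= lo && x <= hi)
  if (!ok) {
    kv_stop(
      "'%s' must be in %s%s, %s%s; got %g", name,
      if (strict) "(" else "[", lo, hi, if (strict) ")" else "]", x
    )
  }
  invisible(x)
}

# Coerce a feature table (matrix or data.frame) to a numeric matrix with
# column names, failing loudly on non-numeric columns or missing values.
as_feature_matrix <- function(features, what = "features") {
  if (is.data.frame(features)) {
    bad <- names(features)[!vapply(features, is.numeric, logical(1))]
    if (length(bad) > 0L) {
      kv_stop("non-numeric %s column(s): %s", what, paste(bad, collapse = ", "))
    }
    features <- as.matrix(features)
  }
  if (!is.matrix(features) || !is.numeric(features)) {
    kv_stop("'%s' must be a numeric matrix or all-numeric data frame", what)
  }
  if (anyNA(features)) kv_stop("'%s' contains missing values", what)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("X", seq_len(ncol(features)))
  }
  features
}

# Validate a 0/1 outcome vector against a feature matrix.
check_outcome <- function(outcome, n, require_both = TRUE) {
  if (anyNA(outcome)) kv_stop("'outcome' contains missing values")
  if (!is.numeric(outcome) || !all(outcome %in% c(0, 1))) {
    kv_stop(
      "'outcome' must be coded 0/1; offending values: %s",
      paste(utils::head(unique(outcome[!outcome %in% c(0, 1)]), 5),
            collapse = ", ")
    )
  }
  if (length(outcome) != n) {
    kv_stop("'outcome' length %d does not match %d rows", length(outcome), n)
  }
  if (require_both && (sum(outcome == 1) == 0L || sum(outcome == 0) == 0L)) {
    kv_stop("'outcome' must contain both classes (at least one 0 and one 1)")
  }
  invisible(as.numeric(outcome))
}
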