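#' Construct a modelling dataset
#'
#' Bundles an n x p numeric feature matrix, an optional 0/1 outcome vector
#' and free-form provenance metadata into a validated `kv_dataset` object,
#' the container every stage of the package consumes.
#'
#' @param features numeric matrix or all-numeric data frame (rows =
#'   participants, columns = features). Column names are taken as feature
#'   names; unnamed columns get `X1..Xp`.
#' @param outcome optional numeric 0/1 vector, one entry per row. Supervised
#'   stages require both classes present.
#' @param meta named list of provenance (seed, generator parameters, ...).
#' @param require_both_classes if `TRUE` (default) and an outcome is given,
#'   both classes must be present.
#' @return An object of class `kv_dataset`: a list with elements `features`
#'   (matrix), `outcome` (numeric or `NULL`), `feature_names`, `meta`.
#' @export
#' @examples
#' d <- kv_dataset(matrix(rnorm(20), 10, 2), outcome = rep(c(0, 1), 5))
#' d
kv_dataset <- function(features, outcome = NULL, meta = list(),
                       require_both_classes = TRUE) {
  features <- as_feature_matrix(features)
  if (nrow(features) < 2L) kv_stop("need at least 2 rows, got %d", nrow(features))
  if (ncol(features) < 1L) kv_stop("need at least 1 feature column")
  nm <- colnames(features)
  if (anyDuplicated(nm)) {
    kv_stop("duplicate feature names: %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (!is.null(outcome)) {
    outcome <- check_outcome(outcome, nrow(features),
                             require_both = require_both_classes)
  }
  structure(
    list(features = features, outcome = outcome, feature_names = nm,
         meta = meta),
    class = "kv_dataset"
  )
}

#' @export
print.kv_dataset <- function(x, ...) {
  cat(sprintf("<kv_dataset> %d participants x %d features\n",
              nrow(x$features), ncol(x$features)))
  if (!is.null(x$outcome)) {
    cat(sprintf("  outcome: %d/%d positive (prevalence %.4f)\n",
                sum(x$outcome == 1), length(x$outcome), mean(x$outcome)))
  } else {
    cat("  outcome: absent\n")
  }
  cat("  features:", paste(utils::head(x$feature_names, 8), collapse = ", "),
      if (length(x$feature_names) > 8) "...", "\n")
  invisible(x)
}

#' @export
dim.kv_dataset <- function(x) dim(x$features)

#' Read a dataset from CSV
#'
#' Reads a header-ed CSV feature table with one 0/1 outcome column. All
#' cells must be numeric and complete: rows with missing values are an
#' error (imputation is upstream of this package), as are outcome codings
#' other than 0/1.
#'
#' @param path CSV file path.
#' @param outcome_col name of the outcome column (default `"outcome"`); use
#'   `NULL` for a features-only table.
#' @return A [kv_dataset].
#' @export
read_dataset <- function(path, outcome_col = "outcome") {
  if (!file.exists(path)) kv_stop("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) kv_stop("empty table: %s", path)
  if (!is.null(outcome_col)) {
    if (!outcome_col %in% names(df)) {
      kv_stop("outcome column '%s' not found in %s", outcome_col, path)
    }
    outcome <- df[[outcome_col]]
    df <- df[setdiff(names(df), outcome_col)]
  } else {
    outcome <- NULL
  }
  n_miss <- sum(!stats::complete.cases(df) |
                  if (is.null(outcome)) FALSE else is.na(outcome))
  if (n_miss > 0L) {
    kv_stop("%d row(s) with missing values rejected; impute upstream", n_miss)
  }
  kv_dataset(df, outcome = outcome, meta = list(source = path),
             require_both_classes = FALSE)
}

#' Write a dataset to CSV
#'
#' Inverse of [read_dataset]: header row of feature names (plus the outcome
#' column when present), comma-separated, no row-index column.
#'
#' @param dataset a [kv_dataset].
#' @param path output CSV path.
#' @param outcome_col name to give the outcome column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, outcome_col = "outcome") {
  stopifnot(inherits(dataset, "kv_dataset"))
  df <- as.data.frame(dataset$features, check.names = FALSE)
  if (!is.null(dataset$outcome)) df[[outcome_col]] <- dataset$outcome
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
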