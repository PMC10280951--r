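#' Run configuration
#'
#' Validated bundle of the run-level settings shared by the pipeline
#' stages, serializable to and from a single YAML document.
#'
#' @param seed base seed (integer).
#' @param n_trees trees per forest (default 500).
#' @param test_fraction held-out fraction (default 0.2).
#' @param k_folds cross-validation folds (default 10).
#' @param threshold numeric in \[0, 1\] or `"auto"`.
#' @param s_rule `"equi"` or `"sdp"`.
#' @param replicates replicate count for replicated runs (default 1).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1, n_trees = 500, test_fraction = 0.2,
                       k_folds = 10, threshold = "auto",
                       s_rule = c("equi", "sdp"), replicates = 1) {
  s_rule <- match.arg(s_rule)
  check_scalar(seed, "seed")
  check_scalar(n_trees, "n_trees", lo = 1)
  check_scalar(test_fraction, "test_fraction", lo = 0, hi = 1, strict = TRUE)
  check_scalar(k_folds, "k_folds", lo = 2)
  if (!identical(threshold, "auto")) {
    check_scalar(threshold, "threshold", lo = 0, hi = 1)
  }
  check_scalar(replicates, "replicates", lo = 1)
  structure(list(seed = as.integer(seed), n_trees = as.integer(n_trees),
                 test_fraction = test_fraction, k_folds = as.integer(k_folds),
                 threshold = threshold, s_rule = s_rule,
                 replicates = as.integer(replicates)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(run_config, obj)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>",
      paste(names(x), vapply(x, format, character(1)), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

# Deterministic short hash of a configuration (FNV over its YAML form),
# embedded in every results file for provenance.
config_hash <- function(config) {
  sprintf("%08x", substream_seed(0, yaml::as.yaml(unclass(config))))
}

#' Write a VIMP results table
#'
#' Emits a VIMP table (from [knockoff_vimp] or [oob_vimp]) as TSV or JSON.
#' Both formats embed the package version and, when a configuration is
#' supplied, its hash (TSV as leading `#` comment lines, JSON as fields);
#' JSON additionally embeds the full configuration. `positive_only = TRUE`
#' applies [positive_vimp_view] before writing.
#'
#' @param x results table (data frame).
#' @param path output path.
#' @param format `"tsv"` or `"json"` (default from the file extension).
#' @param config optional [run_config] (or plain list) for provenance.
#' @param positive_only keep only rows with both `vimp_sens` and
#'   `vimp_spec` above zero.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = NULL, config = NULL,
                          positive_only = FALSE) {
  if (nrow(x) == 0L) kv_stop("refusing to write an empty results table")
  if (positive_only) x <- positive_vimp_view(x)
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  format <- match.arg(format, c("tsv", "json"))
  df <- as.data.frame(x)
  ver <- as.character(utils::packageVersion("knockvimp"))
  hash <- if (!is.null(config)) config_hash(config) else NA_character_
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# knockvimp %s", ver), con)
    if (!is.na(hash)) writeLines(sprintf("# config_hash %s", hash), con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(package = "knockvimp", version = ver, results = df)
    if (!is.null(config)) {
      payload$config <- unclass(config)
      payload$config_hash <- hash
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read back a TSV results table
#'
#' @param path TSV written by [write_results].
#' @return Data frame (comment header lines skipped).
#' @export
read_results <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
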