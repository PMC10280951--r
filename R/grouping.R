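#' Construct a feature grouping scheme
#'
#' A grouping scheme organizes features into named groups ("domains") at one
#' or more named levels, from broad constructs down to individual measures.
#' Within a level the groups must be pairwise disjoint and non-empty;
#' different levels may slice the features differently (typically nested,
#' coarse to fine).
#'
#' @param levels named list; each element is one level, itself a named list
#'   mapping group name to a character vector of feature names.
#' @param feature_names optional character vector; when supplied, every
#'   grouped feature must appear in it.
#' @return An object of class `grouping_scheme`.
#' @export
#' @examples
#' grouping_scheme(list(level1 = list(
#'   demo = c("age", "sex"), psg = c("ahi", "sleep_eff"))))
grouping_scheme <- function(levels, feature_names = NULL) {
  if (!is.list(levels) || length(levels) == 0L || is.null(names(levels)) ||
      any(names(levels) == "")) {
    kv_stop("'levels' must be a non-empty named list of levels")
  }
  for (lev in names(levels)) {
    groups <- levels[[lev]]
    if (!is.list(groups) || length(groups) == 0L || is.null(names(groups)) ||
        any(names(groups) == "")) {
      kv_stop("level '%s' must be a non-empty named list of groups", lev)
    }
    if (anyDuplicated(names(groups))) {
      kv_stop("level '%s' has duplicate group names", lev)
    }
    groups <- lapply(groups, function(g) as.character(unlist(g)))
    sizes <- lengths(groups)
    if (any(sizes == 0L)) {
      kv_stop("level '%s': empty group(s): %s", lev,
              paste(names(groups)[sizes == 0L], collapse = ", "))
    }
    all_feats <- unlist(groups, use.names = FALSE)
    if (anyDuplicated(all_feats)) {
      dup <- unique(all_feats[duplicated(all_feats)])
      kv_stop("level '%s': feature(s) in more than one group: %s", lev,
              paste(dup, collapse = ", "))
    }
    if (!is.null(feature_names)) {
      unknown <- setdiff(all_feats, feature_names)
      if (length(unknown) > 0L) {
        kv_stop("level '%s': unknown feature name(s): %s", lev,
                paste(unknown, collapse = ", "))
      }
    }
    levels[[lev]] <- groups
  }
  structure(list(levels = levels), class = "grouping_scheme")
}

#' @export
print.grouping_scheme <- function(x, ...) {
  cat(sprintf("<grouping_scheme> %d level(s)\n", length(x$levels)))
  for (lev in names(x$levels)) {
    groups <- x$levels[[lev]]
    cat(sprintf("  %s: %d group(s), %d feature(s)\n", lev, length(groups),
                length(unlist(groups))))
  }
  invisible(x)
}

#' Read a grouping scheme from YAML or JSON
#'
#' Expects the schema `levels: {level1: {GroupName: [feat, ...]}, ...}`.
#' When `dataset` is given, all named features are validated against it and
#' unknown names are listed exhaustively in the error.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @param dataset optional [kv_dataset] to validate feature names against.
#' @return A [grouping_scheme].
#' @export
read_grouping <- function(path, dataset = NULL) {
  if (!file.exists(path)) kv_stop("file not found: %s", path)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(obj) || is.null(obj$levels)) {
    kv_stop("grouping file must have a top-level 'levels' mapping: %s", path)
  }
  grouping_scheme(obj$levels,
                  feature_names = if (!is.null(dataset)) dataset$feature_names)
}

#' Write a grouping scheme to YAML
#'
#' @param grouping a [grouping_scheme].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grouping <- function(grouping, path) {
  stopifnot(inherits(grouping, "grouping_scheme"))
  yaml::write_yaml(list(levels = grouping$levels), path)
  invisible(path)
}
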