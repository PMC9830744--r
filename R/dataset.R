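#' Per-feature metadata
#'
#' Describes one column of a [survival_dataset()]: its name, its kind
#' (continuous, boolean or categorical), the ordered level labels for
#' categorical features, and whether the column is a permutation probe
#' derived from another feature.
#'
#' @param name Unique feature name.
#' @param kind One of `"continuous"`, `"boolean"`, `"categorical"`.
#' @param levels Ordered character vector of category labels; required for
#'   (and only allowed for) categorical features. Stored values are 0-based
#'   integer codes into this vector.
#' @param is_probe Logical flag marking permutation probes.
#' @param probe_source Name of the originating feature (probes only).
#' @return An object of class `feature_meta`.
#' @export
feature_meta <- function(name, kind, levels = NULL, is_probe = FALSE,
                         probe_source = NA_character_) {
  kind <- match.arg(kind, c("continuous", "boolean", "categorical"))
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) == 0)
      stop("categorical feature '", name, "' requires non-empty levels")
    levels <- as.character(levels)
  } else if (!is.null(levels)) {
    stop("levels are only allowed for categorical features ('", name, "')")
  }
  if (isTRUE(is_probe) && (is.na(probe_source) || !nzchar(probe_source)))
    stop("probe '", name, "' must name its source feature")
  structure(
    list(name = as.character(name), kind = kind, levels = levels,
         is_probe = isTRUE(is_probe), probe_source = probe_source),
    class = "feature_meta")
}

#' Survival dataset with mixed-type features
#'
#' The central data container: an `m x p` numeric matrix of features
#' (continuous values as-is, booleans as 0/1, categoricals as 0-based level
#' codes), per-feature metadata, and a right-censored outcome given by a
#' positive event/censoring time and a 0/1 event indicator.
#'
#' @param features Numeric matrix (or data.frame) of `m` samples by `p`
#'   features with column names.
#' @param time Positive numeric vector of length `m` (time since baseline,
#'   units carried verbatim from input).
#' @param event Integer/numeric vector in \{0, 1\}; 1 = event observed,
#'   0 = censored.
#' @param meta List of [feature_meta()] objects, one per column, in column
#'   order. If omitted, kinds are inferred: 0/1 columns become boolean,
#'   everything else continuous.
#' @return An object of class `survival_dataset`.
#' @export
survival_dataset <- function(features, time, event, meta = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  m <- nrow(features)
  if (m < 2L) stop("a survival dataset needs at least 2 samples")
  if (is.null(colnames(features)))
    stop("feature matrix must have column names")
  if (anyDuplicated(colnames(features)))
    stop("duplicate feature names: ",
         paste(unique(colnames(features)[duplicated(colnames(features))]),
               collapse = ", "))
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != m || length(event) != m)
    stop("time/event length must match the number of rows")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("all times must be positive and finite")
  if (!all(event %in% c(0, 1)))
    stop("event indicator must be 0 (censored) or 1 (event)")
  if (is.null(meta)) {
    meta <- lapply(colnames(features), function(nm) {
      v <- features[, nm]
      ok <- stats::na.omit(v)
      kind <- if (length(ok) && all(ok %in% c(0, 1))) "boolean" else "continuous"
      feature_meta(nm, kind)
    })
  }
  if (length(meta) != ncol(features))
    stop("meta must describe every feature column")
  names(meta) <- vapply(meta, `[[`, "", "name")
  if (!identical(names(meta), colnames(features)))
    stop("meta names must match feature columns in order")
  ds <- structure(list(features = features, meta = meta,
                       time = time, event = event),
                  class = "survival_dataset")
  validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  for (mt in ds$meta) {
    v <- ds$features[, mt$name]
    ok <- v[!is.na(v)]
    if (mt$kind == "boolean" && !all(ok %in% c(0, 1)))
      stop("boolean feature '", mt$name, "' contains values outside {0,1}")
    if (mt$kind == "categorical") {
      codes <- seq_along(mt$levels) - 1L
      if (!all(ok %in% codes))
        stop("categorical feature '", mt$name,
             "' contains codes outside 0..", length(mt$levels) - 1L)
    }
  }
  invisible(ds)
}

#' @export
print.survival_dataset <- function(x, ...) {
  kinds <- feature_kinds(x)
  cat(sprintf(
    "survival_dataset: %d samples, %d features (%d continuous, %d boolean, %d categorical%s)\n",
    n_samples(x), ncol(x$features),
    sum(kinds == "continuous" & !probe_flags(x)),
    sum(kinds == "boolean" & !probe_flags(x)),
    sum(kinds == "categorical" & !probe_flags(x)),
    if (any(probe_flags(x))) sprintf(", +%d probes", sum(probe_flags(x))) else ""))
  cat(sprintf("  events: %d / %d (censoring rate %.1f%%)\n",
              sum(x$event), n_samples(x), 100 * censoring_rate(x$event)))
  invisible(x)
}

#' @rdname survival_dataset
#' @param ds A `survival_dataset`.
#' @export
n_samples <- function(ds) length(ds$time)

#' @rdname survival_dataset
#' @export
feature_names <- function(ds) colnames(ds$features)

#' @rdname survival_dataset
#' @export
feature_kinds <- function(ds)
  vapply(ds$meta, `[[`, "", "kind")

probe_flags <- function(ds)
  vapply(ds$meta, function(m) isTRUE(m$is_probe), logical(1))

#' Names of the original (non-probe) features
#' @param ds A `survival_dataset`.
#' @export
original_features <- function(ds) feature_names(ds)[!probe_flags(ds)]

#' Censoring rate of an event indicator
#'
#' The fraction of censored observations, `1 - mean(event)`.
#'
#' @param event 0/1 event-indicator vector (or a `survival_dataset`).
#' @return Censoring fraction in \[0, 1\].
#' @export
censoring_rate <- function(event) {
  if (inherits(event, "survival_dataset")) event <- event$event
  1 - mean(event)
}

#' Row and column subsetting of survival datasets
#'
#' @param ds A `survival_dataset`.
#' @param rows Integer row indices (duplicates allowed, e.g. bootstrap).
#' @export
subset_rows <- function(ds, rows) {
  rows <- as.integer(rows)
  if (length(rows) < 2L) stop("a dataset subset needs at least 2 rows")
  structure(list(features = ds$features[rows, , drop = FALSE],
                 meta = ds$meta,
                 time = ds$time[rows], event = ds$event[rows]),
            class = "survival_dataset")
}

#' @rdname subset_rows
#' @param keep Character vector of feature names to retain.
#' @export
subset_features <- function(ds, keep) {
  miss <- setdiff(keep, feature_names(ds))
  if (length(miss)) stop("unknown features: ", paste(miss, collapse = ", "))
  structure(list(features = ds$features[, keep, drop = FALSE],
                 meta = ds$meta[keep],
                 time = ds$time, event = ds$event),
            class = "survival_dataset")
}

#' Read a survival dataset from a delimited text file
#'
#' Reads a CSV/TSV file with a header row, validates it against the run
#' configuration and encodes it as a [survival_dataset()]. Categorical
#' columns are coded as 0-based indices into their sorted unique labels.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param config A list (or path to a YAML/JSON file) with entries
#'   `time_col`, `event_col`, optional `feature_kinds` (named map
#'   feature -> kind; unnamed columns are inferred) and optional `na_policy`
#'   (`"error"`, the default, or `"impute"` to defer to the imputation hook
#'   inside the evaluation loop).
#' @return A `survival_dataset`. Missing values are retained as `NA` only
#'   under `na_policy = "impute"`.
#' @export
read_survival_data <- function(path, config) {
  if (!file.exists(path)) stop("file not found: ", path)
  config <- load_run_config(config)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(config$time_col, config$event_col))
    if (!col %in% names(df))
      stop("schema error: required column '", col, "' not found")
  time <- suppressWarnings(as.numeric(df[[config$time_col]]))
  if (anyNA(time))
    stop("parse error: non-numeric time at row ",
         which(is.na(time))[1], ", column '", config$time_col, "'")
  if (any(time <= 0))
    stop("invalid time (must be > 0) at row ", which(time <= 0)[1],
         ", column '", config$time_col, "'")
  ev_raw <- df[[config$event_col]]
  event <- suppressWarnings(as.numeric(ev_raw))
  bad <- which(is.na(event) | !(event %in% c(0, 1)))
  if (length(bad))
    stop("invalid event value '", ev_raw[bad[1]], "' at row ", bad[1],
         ", column '", config$event_col, "' (must be 0 or 1)")
  fcols <- setdiff(names(df), c(config$time_col, config$event_col))
  if (!length(fcols)) stop("schema error: no feature columns")
  kinds <- config$feature_kinds
  meta <- vector("list", length(fcols))
  feats <- matrix(NA_real_, nrow(df), length(fcols),
                  dimnames = list(NULL, fcols))
  for (i in seq_along(fcols)) {
    nm <- fcols[i]
    v <- df[[nm]]
    kind <- if (!is.null(kinds) && nm %in% names(kinds)) kinds[[nm]]
            else infer_kind(v)
    if (kind == "categorical") {
      lv <- sort(unique(as.character(v[!is.na(v)])))
      if (!length(lv)) stop("parse error: all-missing categorical '", nm, "'")
      meta[[i]] <- feature_meta(nm, "categorical", levels = lv)
      feats[, i] <- match(as.character(v), lv) - 1
    } else {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop("parse error: unparseable value '", v[bad[1]], "' at row ",
             bad[1], ", column '", nm, "'")
      if (kind == "boolean" && !all(stats::na.omit(num) %in% c(0, 1)))
        stop("invalid boolean value at column '", nm, "'")
      meta[[i]] <- feature_meta(nm, kind)
      feats[, i] <- num
    }
  }
  na_policy <- config$na_policy %||% "error"
  if (anyNA(feats) && !identical(na_policy, "impute")) {
    idx <- which(is.na(feats), arr.ind = TRUE)[1, ]
    stop("imputation required: missing value at row ", idx[1],
         ", column '", fcols[idx[2]],
         "' and na_policy is not 'impute'")
  }
  survival_dataset(feats, time, event, meta)
}

infer_kind <- function(v) {
  if (is.character(v) || is.factor(v)) return("categorical")
  num <- suppressWarnings(as.numeric(v))
  if (all(stats::na.omit(num) %in% c(0, 1))) "boolean" else "continuous"
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config) || is.null(config$time_col) || is.null(config$event_col))
    stop("config must name time_col and event_col")
  config
}

#' Write a survival dataset to CSV
#'
#' The canonical writer: `time` and `event` columns followed by the feature
#' columns, categorical codes decoded back to their labels. Reading the file
#' back with the matching configuration reproduces the dataset.
#'
#' @param ds A `survival_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survival_data <- function(ds, path) {
  out <- data.frame(time = ds$time, event = ds$event, check.names = FALSE)
  for (mt in ds$meta) {
    v <- ds$features[, mt$name]
    out[[mt$name]] <- if (mt$kind == "categorical") mt$levels[v + 1] else v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
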