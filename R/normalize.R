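#' Fit normalization parameters on training rows
#'
#' Estimates a per-feature centre and scale (mean and sample standard
#' deviation, denominator `m - 1`) for every continuous feature, using only
#' the given rows. Boolean and categorical features are left untouched by
#' the transform. Zero-variance features are flagged degenerate and mapped
#' to all-zeros rather than raising an error.
#'
#' @param ds A [survival_dataset()].
#' @param rows Integer indices of the training rows; defaults to all rows.
#' @return An object of class `normalization_params` with `center`, `scale`
#'   and `degenerate` entries, named by continuous feature.
#' @export
fit_normalization <- function(ds, rows = seq_len(n_samples(ds))) {
  rows <- as.integer(rows)
  if (!length(rows)) stop("rows must be non-empty")
  cont <- feature_names(ds)[feature_kinds(ds) == "continuous"]
  center <- scale <- stats::setNames(numeric(length(cont)), cont)
  degenerate <- stats::setNames(logical(length(cont)), cont)
  for (nm in cont) {
    v <- ds$features[rows, nm]
    v <- v[!is.na(v)]
    center[nm] <- mean(v)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      degenerate[nm] <- TRUE
      scale[nm] <- 0
    } else scale[nm] <- s
  }
  structure(list(center = center, scale = scale, degenerate = degenerate),
            class = "normalization_params")
}

#' Apply fitted normalization parameters
#'
#' Transforms each continuous feature to `(x - center) / scale` using
#' parameters fitted on (possibly different) training rows; degenerate
#' features become all-zeros. Other feature kinds pass through unchanged.
#'
#' @param ds A [survival_dataset()].
#' @param params A `normalization_params` object from [fit_normalization()].
#' @return The transformed `survival_dataset`.
#' @export
apply_normalization <- function(ds, params) {
  stopifnot(inherits(params, "normalization_params"))
  feats <- ds$features
  for (nm in names(params$center)) {
    if (!nm %in% colnames(feats)) next
    feats[, nm] <- if (params$degenerate[nm]) 0
      else (feats[, nm] - params$center[nm]) / params$scale[nm]
  }
  structure(list(features = feats, meta = ds$meta,
                 time = ds$time, event = ds$event),
            class = "survival_dataset")
}

#' Median/mode imputation hook
#'
#' The default imputation hook used inside the cross-validation loop: fits
#' the per-feature median (continuous) or mode (boolean/categorical) on
#' training rows only, then fills missing values anywhere the parameters
#' are applied. Any object with the same two-function contract
#' (`fit(ds, rows)` returning parameters; `apply(ds, params)` returning a
#' completed dataset) can replace it, e.g. a multiple-imputation wrapper.
#'
#' @return A list with elements `fit` and `apply`.
#' @export
median_mode_imputer <- function() {
  list(
    fit = function(ds, rows = seq_len(n_samples(ds))) {
      vals <- lapply(ds$meta, function(mt) {
        v <- ds$features[rows, mt$name]
        v <- v[!is.na(v)]
        if (!length(v)) return(0)
        if (mt$kind == "continuous") stats::median(v)
        else as.numeric(names(which.max(table(v))))
      })
      stats::setNames(vals, feature_names(ds))
    },
    apply = function(ds, params) {
      feats <- ds$features
      for (nm in colnames(feats)) {
        na <- is.na(feats[, nm])
        if (any(na)) feats[na, nm] <- params[[nm]]
      }
      structure(list(features = feats, meta = ds$meta,
                     time = ds$time, event = ds$event),
                class = "survival_dataset")
    })
}
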