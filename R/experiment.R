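#' Ridge-penalised Cox risk model on a selected feature subset
#'
#' Fits an L2-penalised Cox model on the selected (already normalised)
#' features and returns a risk scorer: a function mapping a dataset to a
#' real-valued risk per sample, higher meaning higher hazard. The penalty
#' defaults to a fixed value for determinism; internal cross-validated
#' tuning can be switched on. With a single selected feature the penalised
#' linear predictor is a monotone transform of the unpenalised one, so a
#' plain Cox fit is used there.
#'
#' @param ds Training [survival_dataset()] (normalised), >= 1 event.
#' @param selected Non-empty character vector of feature names.
#' @param lambda Fixed ridge penalty (ignored when `cv = TRUE`).
#' @param cv Tune the penalty by internal cross-validation.
#' @param seed Seed for the internal CV fold assignment.
#' @return A function `(survival_dataset) -> numeric` of class
#'   `ridge_cox_scorer`.
#' @export
fit_ridge_cox <- function(ds, selected, lambda = 0.1, cv = FALSE, seed = 1L) {
  stopifnot(length(selected) >= 1L)
  if (sum(ds$event) < 1) stop("ridge Cox fit needs at least one event")
  sub <- subset_features(ds, selected)
  ex <- expand_features(sub)
  y <- survival::Surv(ds$time, ds$event)
  if (ncol(ex$x) >= 2L) {
    fit <- glmnet::glmnet(ex$x, y, family = "cox", alpha = 0)
    if (cv) {
      foldid <- with_seed(derive_seed(seed, 21L),
                          sample(rep_len(1:5, n_samples(ds))))
      lambda <- glmnet::cv.glmnet(ex$x, y, family = "cox", alpha = 0,
                                  foldid = foldid)$lambda.min
    }
    beta <- drop(as.matrix(stats::coef(fit, s = lambda)))
  } else {
    cf <- tryCatch(
      stats::coef(suppressWarnings(survival::coxph(y ~ ex$x))),
      error = function(e) stop("ridge Cox fit failed: ",
                               conditionMessage(e)))
    beta <- stats::setNames(ifelse(is.na(cf), 0, cf), colnames(ex$x))
  }
  if (any(!is.finite(beta)))
    stop("ridge Cox fit did not converge (non-finite coefficients)")
  scorer <- function(newds) {
    nx <- expand_features(subset_features(newds, selected))$x
    drop(nx[, names(beta), drop = FALSE] %*% beta)
  }
  structure(scorer, class = c("ridge_cox_scorer", "function"),
            beta = beta, lambda = lambda)
}

#' Euclidean performance-stability score
#'
#' Distance from the origin in the (stability, accuracy) plane, both on
#' their natural `[0, 1]` scales, used to rank model configurations.
#'
#' @param stability Stability value (e.g. [cw_rel()]).
#' @param performance Accuracy value (e.g. mean concordance index).
#' @return `sqrt(stability^2 + performance^2)`.
#' @export
euclidean_score <- function(stability, performance) {
  stopifnot(is.finite(stability), is.finite(performance))
  sqrt(stability^2 + performance^2)
}

empty_ranked_list <- function(universe)
  structure(list(items = character(0),
                 scores = stats::setNames(numeric(0), character(0)),
                 norm_rank = stats::setNames(numeric(0), character(0)),
                 partial = TRUE, universe_size = length(universe)),
            class = "ranked_list")

new_experiment_result <- function(subsets, cindex, universe, provenance) {
  stability <- tryCatch(
    suppressWarnings(cw_rel(subsets, universe)),
    error = function(e) NA_real_)
  mean_c <- mean(cindex)
  structure(list(subsets = subsets,
                 cindex = cindex,
                 mean_cindex = mean_c,
                 stability = stability,
                 euclidean = if (is.na(stability)) NA_real_
                             else euclidean_score(stability, mean_c),
                 provenance = provenance),
            class = "efs_experiment")
}

#' Run an ensemble feature-selection experiment
#'
#' The full harness: for every training fold of a repeated, event-stratified
#' K-fold cross-validation, missing values are imputed and continuous
#' features normalised with parameters fitted on the training rows only;
#' the base selector is fitted on `B` bootstrap resamples (with permutation
#' probes regenerated per resample when enabled); the resulting ranked
#' lists are aggregated and thresholded; probes are stripped; and a ridge
#' Cox model on the selected features is scored by the concordance index
#' on the held-out fold. Stability is the relative weighted consistency of
#' the `folds * repeats` final subsets.
#'
#' @param ds A [survival_dataset()].
#' @param selector_id Base selector identifier (see [register_selector()]).
#' @param aggregator_id `MR`, `MW`, `RRA:<p>`, `TA` or `MA`. The latter
#'   three self-threshold and require `threshold_id = "none"`.
#' @param threshold_id `fixed:<fraction>`, `q75`, `kde`, `probe` or `none`.
#' @param B Bootstrap resamples per fold.
#' @param folds,repeats Cross-validation design.
#' @param probes Inject permutation probes (required for `probe`
#'   thresholding; defaults accordingly).
#' @param seed Master seed; all stage seeds derive from it, so identical
#'   configuration and seed reproduce the result exactly.
#' @param imputer Imputation hook (see [median_mode_imputer()]).
#' @param ridge_lambda Ridge penalty for the evaluation model.
#' @param k Optional subset size for TA/MA.
#' @param selector_args Extra arguments passed to the selector.
#' @return An object of class `efs_experiment`.
#' @export
run_experiment <- function(ds, selector_id, aggregator_id,
                           threshold_id = "none",
                           B = 50L, folds = 5L, repeats = 5L,
                           probes = identical(threshold_id, "probe"),
                           seed = 1L,
                           imputer = median_mode_imputer(),
                           ridge_lambda = 0.1, k = NULL,
                           selector_args = list()) {
  if (self_thresholding(aggregator_id) && !identical(threshold_id, "none"))
    stop("aggregator '", aggregator_id, "' performs its own thresholding; ",
         "use threshold_id = 'none'")
  if (identical(threshold_id, "probe") && !probes)
    stop("probe thresholding requires probes = TRUE")
  selector <- get_selector(selector_id)
  splits <- make_cv_splits(n_samples(ds), ds$event, folds, repeats, seed)
  feats <- original_features(ds)
  warnings_log <- character(0)
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  subsets <- vector("list", length(splits))
  cindex <- numeric(length(splits))
  k_used <- integer(length(splits))
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    res <- withCallingHandlers(
      run_one_fold(ds, sp, selector, selector_id, aggregator_id,
                   threshold_id, B, probes, seed, imputer, ridge_lambda,
                   k, selector_args),
      warning = log_warning)
    subsets[[si]] <- res$selected
    cindex[si] <- res$cindex
    k_used[si] <- length(res$selected)
  }
  new_experiment_result(
    subsets, cindex, feats,
    provenance = list(mode = "ensemble", selector = selector_id,
                      aggregator = aggregator_id, threshold = threshold_id,
                      B = B, folds = folds, repeats = repeats,
                      probes = probes, seed = seed,
                      ridge_lambda = ridge_lambda,
                      subset_sizes = k_used, warnings = warnings_log))
}

run_one_fold <- function(ds, sp, selector, selector_id, aggregator_id,
                         threshold_id, B, probes, seed, imputer,
                         ridge_lambda, k, selector_args) {
  prep <- prepare_fold(ds, sp, imputer)
  train <- prep$train; test <- prep$test
  feats <- original_features(ds)
  probe_names <- if (probes)
    paste0(PROBE_PREFIX,
           feats[feature_kinds(ds)[feats] != "boolean"])
    else character(0)
  universe <- c(feats, probe_names)
  lists <- vector("list", B)
  ever_selected <- character(0)
  any_probe_selected <- FALSE
  sparse <- FALSE
  for (b in seq_len(B)) {
    sub_seed <- derive_seed(seed, sp$repeat_index, sp$fold_index, b)
    bs <- bootstrap_sample(train, sub_seed)
    fit_ds <- if (probes) inject_probes(bs$data, derive_seed(sub_seed, 9L))
              else bs$data
    result <- tryCatch(
      do.call(selector, c(list(fit_ds, seed = sub_seed), selector_args)),
      error = function(e) {
        warning("selector '", selector_id, "' failed on bootstrap ", b,
                " (", conditionMessage(e), "); using an empty list")
        NULL
      })
    if (is.null(result)) {
      lists[[b]] <- empty_ranked_list(universe)
    } else {
      lists[[b]] <- ranked_list(result, universe)
      if (result$is_sparse) {
        sparse <- TRUE
        ever_selected <- union(ever_selected, result$selected)
        if (any(is_probe_name(result$selected))) any_probe_selected <- TRUE
      }
    }
  }
  run <- ensemble_run(lists, universe, selector_id)
  agg <- aggregate_run(run, aggregator_id, k)
  fallback <- intersect(agg$ordering, setdiff(ever_selected, probe_names))
  selected <- apply_threshold(
    agg, threshold_id, probe_names,
    sparse_no_probe = sparse && probes && !any_probe_selected,
    fallback_selected = if (sparse) fallback else NULL)
  selected <- selected[!is_probe_name(selected)]
  if (!length(selected)) {
    warning("empty final subset in repeat ", sp$repeat_index, " fold ",
            sp$fold_index, "; falling back to all features")
    selected <- feats
  }
  score_fold(train, test, selected, ridge_lambda, seed)
}

prepare_fold <- function(ds, sp, imputer) {
  imp <- imputer$apply(ds, imputer$fit(ds, sp$train))
  norm <- fit_normalization(imp, sp$train)
  normed <- apply_normalization(imp, norm)
  list(train = subset_rows(normed, sp$train),
       test = subset_rows(normed, sp$test),
       normalization = norm)
}

score_fold <- function(train, test, selected, ridge_lambda, seed) {
  scorer <- fit_ridge_cox(train, selected, lambda = ridge_lambda,
                          seed = seed)
  list(selected = selected,
       cindex = concordance_index(test$time, test$event, scorer(test)))
}

#' Run a base selector in its individual (non-ensemble) form
#'
#' One selector fit per training fold: no bootstraps and no aggregation.
#' Sparse selectors already return a subset, so an explicit threshold is
#' rejected; filters return only scores, so a threshold must always be
#' applied (`fixed:<fraction>`, `q75` or `kde`). Cross-validation folds are
#' shared with [run_experiment()] under the same seed, for paired
#' comparison.
#'
#' @inheritParams run_experiment
#' @param threshold_id Threshold for filters; must be `"none"` for sparse
#'   selectors.
#' @return An object of class `efs_experiment`.
#' @export
run_individual <- function(ds, selector_id, threshold_id = "none",
                           folds = 5L, repeats = 5L, seed = 1L,
                           imputer = median_mode_imputer(),
                           ridge_lambda = 0.1, selector_args = list()) {
  if (identical(threshold_id, "probe"))
    stop("probe thresholding applies to ensemble runs only")
  selector <- get_selector(selector_id)
  splits <- make_cv_splits(n_samples(ds), ds$event, folds, repeats, seed)
  feats <- original_features(ds)
  warnings_log <- character(0)
  subsets <- vector("list", length(splits))
  cindex <- numeric(length(splits))
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    res <- withCallingHandlers({
      prep <- prepare_fold(ds, sp, imputer)
      sub_seed <- derive_seed(seed, sp$repeat_index, sp$fold_index, 0L)
      result <- do.call(selector,
                        c(list(prep$train, seed = sub_seed), selector_args))
      selected <- if (result$is_sparse) {
        if (!identical(threshold_id, "none"))
          stop("sparse selector '", selector_id,
               "' takes no explicit threshold")
        result$selected
      } else {
        if (identical(threshold_id, "none"))
          stop("filter '", selector_id,
               "' requires a threshold, even in individual form")
        ord <- order(-result$scores, names(result$scores), method = "radix")
        agg <- new_aggregated_ranking("IND", result$scores,
                                      names(result$scores)[ord], "desc")
        apply_threshold(agg, threshold_id)
      }
      if (!length(selected)) {
        warning("empty individual subset in repeat ", sp$repeat_index,
                " fold ", sp$fold_index, "; falling back to all features")
        selected <- feats
      }
      score_fold(prep$train, prep$test, selected, ridge_lambda, seed)
    }, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    subsets[[si]] <- res$selected
    cindex[si] <- res$cindex
  }
  new_experiment_result(
    subsets, cindex, feats,
    provenance = list(mode = "individual", selector = selector_id,
                      threshold = threshold_id, folds = folds,
                      repeats = repeats, seed = seed,
                      ridge_lambda = ridge_lambda,
                      subset_sizes = lengths(subsets),
                      warnings = warnings_log))
}

#' @export
print.efs_experiment <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("efs_experiment (%s): selector=%s%s%s\n", p$mode, p$selector,
              if (!is.null(p$aggregator)) paste0(", aggregator=", p$aggregator)
              else "",
              if (!identical(p$threshold, "none"))
                paste0(", threshold=", p$threshold) else ""))
  cat(sprintf("  %d subsets (median size %d), mean C-index %.4f\n",
              length(x$subsets), stats::median(lengths(x$subsets)),
              x$mean_cindex))
  cat(sprintf("  stability (CW_rel) %.4f, euclidean score %.4f\n",
              x$stability, x$euclidean))
  invisible(x)
}

#' @export
summary.efs_experiment <- function(object, ...) {
  sizes <- lengths(object$subsets)
  freq <- sort(table(unlist(object$subsets)), decreasing = TRUE)
  out <- list(mean_cindex = object$mean_cindex,
              sd_cindex = stats::sd(object$cindex),
              stability = object$stability,
              euclidean = object$euclidean,
              subset_size = summary(sizes),
              top_features = utils::head(freq, 10L),
              n_warnings = length(object$provenance$warnings))
  class(out) <- "summary.efs_experiment"
  out
}

#' @export
print.summary.efs_experiment <- function(x, ...) {
  cat(sprintf("mean C-index %.4f (sd %.4f), CW_rel %.4f, euclidean %.4f\n",
              x$mean_cindex, x$sd_cindex, x$stability, x$euclidean))
  cat("subset sizes:\n"); print(x$subset_size)
  cat("most frequently selected features:\n")
  print(x$top_features)
  if (x$n_warnings) cat(x$n_warnings, "warnings collected in provenance\n")
  invisible(x)
}

#' Serialise an experiment result to canonical JSON
#'
#' Deterministic serialisation used for provenance and reproducibility
#' checks: identical configuration and seed give byte-identical output.
#'
#' @param result An `efs_experiment`.
#' @return A JSON string.
#' @export
result_json <- function(result) {
  as.character(jsonlite::toJSON(
    list(provenance = result$provenance[setdiff(names(result$provenance),
                                                "warnings")],
         mean_cindex = result$mean_cindex,
         stability = result$stability,
         euclidean = result$euclidean,
         cindex = result$cindex,
         subsets = result$subsets),
    auto_unbox = TRUE, digits = NA, pretty = TRUE))
}

#' Consensus features over the best-performing configurations
#'
#' Ranks a collection of experiment results by their Euclidean
#' performance-stability score, takes the `top_n` best, and reports the
#' features selected by at least `min_fraction` of them. A feature counts
#' as selected by one model when it appears in more than half of that
#' model's fold subsets.
#'
#' @param results List of `efs_experiment` objects.
#' @param top_n Number of top models to pool (all, with a warning, if
#'   fewer are available).
#' @param min_fraction Minimum fraction of the top models that must select
#'   a feature (0.5 by default; 0.8 for a stricter consensus).
#' @return A data.frame with `feature` and `frequency`, sorted by
#'   decreasing frequency.
#' @export
consensus_features <- function(results, top_n = 10L, min_fraction = 0.5) {
  stopifnot(length(results) >= 1L)
  if (length(results) < top_n) {
    warning("only ", length(results), " results available; using all")
    top_n <- length(results)
  }
  eu <- vapply(results, function(r)
    if (is.na(r$euclidean)) -Inf else r$euclidean, 0)
  top <- utils::head(order(-eu), top_n)
  model_sel <- lapply(results[top], function(r) {
    counts <- table(unlist(r$subsets))
    names(counts)[counts > length(r$subsets) / 2]
  })
  counts <- table(unlist(model_sel))
  freq <- as.numeric(counts) / top_n
  keep <- freq >= min_fraction
  out <- data.frame(feature = names(counts)[keep],
                    frequency = freq[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$feature), , drop = FALSE]
}
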