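#' Base selector output
#'
#' The uniform contract every base feature selector must satisfy: a
#' nonnegative, finite importance score per original feature; for sparse
#' selectors additionally the selected subset, every member of which must
#' carry a strictly positive score. Filters attach no selected set —
#' sparsification is the thresholding stage's job.
#'
#' @param scores Named numeric vector, one nonnegative score per feature.
#' @param selected Character vector of selected features (sparse selectors
#'   only), or `NULL` for filters.
#' @param is_sparse Logical flag.
#' @param selector_id Identifier string.
#' @return A validated object of class `selector_result`.
#' @export
selector_result <- function(scores, selected = NULL, is_sparse,
                            selector_id) {
  res <- structure(list(scores = scores, selected = selected,
                        is_sparse = isTRUE(is_sparse),
                        selector_id = as.character(selector_id)),
                   class = "selector_result")
  validate_selector_result(res)
}

#' @rdname selector_result
#' @param res An object to validate against the contract.
#' @export
validate_selector_result <- function(res) {
  if (!is.numeric(res$scores) || is.null(names(res$scores)))
    stop("selector result: scores must be a named numeric vector")
  if (any(!is.finite(res$scores)) || any(res$scores < 0))
    stop("selector result: scores must be finite and nonnegative")
  if (res$is_sparse) {
    if (is.null(res$selected))
      stop("selector result: sparse selectors must report a selected set")
    extra <- setdiff(res$selected, names(res$scores))
    if (length(extra))
      stop("selector result: selected features missing from scores: ",
           paste(extra, collapse = ", "))
    if (length(res$selected) && any(res$scores[res$selected] <= 0))
      stop("selector result: every selected feature needs a positive score")
  } else if (!is.null(res$selected)) {
    stop("selector result: filters must not attach a selected set")
  }
  res
}

# One-hot expansion of a dataset's features for penalised fits; returns the
# numeric design matrix and a map from design column to original feature.
expand_features <- function(ds) {
  cols <- list(); origin <- character(0)
  for (mt in ds$meta) {
    v <- ds$features[, mt$name]
    if (mt$kind == "categorical") {
      for (li in seq_along(mt$levels)) {
        cols[[paste0(mt$name, "=", mt$levels[li])]] <- as.numeric(v == li - 1)
        origin <- c(origin, mt$name)
      }
    } else {
      cols[[mt$name]] <- v
      origin <- c(origin, mt$name)
    }
  }
  x <- do.call(cbind, cols)
  list(x = x, origin = stats::setNames(origin, colnames(x)))
}

# Collapse per-design-column values to per-original-feature values by
# maximum absolute value over a feature's dummies.
collapse_to_original <- function(values, origin, features) {
  out <- stats::setNames(numeric(length(features)), features)
  for (nm in names(values)) {
    f <- origin[[nm]]
    out[f] <- max(out[f], abs(values[[nm]]))
  }
  out
}

#' Univariate Cox concordance filter
#'
#' Scores each original feature by the Harrell concordance index of a Cox
#' proportional-hazards model fitted to that feature alone (categoricals
#' entered as factors). A feature whose fit fails or degenerates scores
#' 0.5, i.e. uninformative, with a warning.
#'
#' @param ds A [survival_dataset()] with at least one event.
#' @param seed Unused; accepted for the uniform selector contract.
#' @return A `selector_result` filter (`is_sparse = FALSE`).
#' @export
univariate_cox_filter <- function(ds, seed = NULL) {
  if (sum(ds$event) < 1) stop("univariate Cox filter needs >= 1 event")
  y <- survival::Surv(ds$time, ds$event)
  feats <- feature_names(ds)
  scores <- stats::setNames(rep(0.5, length(feats)), feats)
  for (mt in ds$meta) {
    v <- ds$features[, mt$name]
    xv <- if (mt$kind == "categorical") factor(v, levels = seq_along(mt$levels) - 1)
          else v
    sc <- tryCatch({
      fit <- suppressWarnings(survival::coxph(y ~ xv))
      lp <- if (any(is.na(stats::coef(fit)))) rep(0, length(v))
            else unname(fit$linear.predictors)
      concordance_index(ds$time, ds$event, lp)
    }, error = function(e) {
      warning("univariate Cox fit failed for '", mt$name,
              "'; scoring 0.5: ", conditionMessage(e))
      0.5
    })
    scores[mt$name] <- sc
  }
  selector_result(scores, NULL, is_sparse = FALSE, selector_id = "unicox")
}

#' Regularisation-strength policies for penalised Cox selectors
#'
#' `lambda_cv()` (the default, with 3 internal folds) picks the penalty by
#' internal k-fold cross-validated partial-likelihood deviance on the
#' (sub)sample being fitted, with fold assignment derived deterministically
#' from the selector seed; `rule = "1se"` (default) takes the sparsest
#' penalty within one standard error of the deviance minimum — the
#' standard parsimony rule when the fit is used for selection rather than
#' prediction — while `rule = "min"` takes the deviance minimiser. `lambda_bic()` picks it along the glmnet path by
#' a BIC-type criterion, `deviance + df * log(number of events)`:
#' resampling-free and cheaper, but prone to under-penalising bootstrap
#' resamples, whose duplicated rows inflate the apparent likelihood.
#' `lambda_fixed()` uses a fixed penalty, for fully deterministic tests.
#'
#' @return A policy object consumed by [sparse_cox_selector()].
#' @export
lambda_bic <- function()
  structure(list(type = "bic"), class = "lambda_policy")

#' @rdname lambda_bic
#' @param nfolds Internal CV folds.
#' @param rule `"1se"` or `"min"`.
#' @export
lambda_cv <- function(nfolds = 3L, rule = c("1se", "min"))
  structure(list(type = "cv", nfolds = as.integer(nfolds),
                 rule = match.arg(rule)),
            class = "lambda_policy")

#' @rdname lambda_bic
#' @param lambda Fixed penalty value.
#' @export
lambda_fixed <- function(lambda)
  structure(list(type = "fixed", lambda = lambda), class = "lambda_policy")

#' Sparse penalised Cox selectors (lasso / elastic-net)
#'
#' Fits the Cox partial likelihood with an L1 (`penalty = "lasso"`) or
#' elastic-net penalty via \pkg{glmnet}. Selected features are those with a
#' nonzero coefficient at the chosen penalty; importance scores are
#' absolute coefficients, mapped back to original features as the maximum
#' over a categorical feature's dummies. Coefficient magnitudes are
#' comparable because the harness normalises continuous features before
#' selection.
#'
#' @param ds A [survival_dataset()] with at least one event.
#' @param penalty `"lasso"` (alpha = 1) or `"elastic_net"`.
#' @param mixing Elastic-net mixing parameter alpha in (0, 1\]; ignored for
#'   lasso.
#' @param lambda_policy A [lambda_bic()], [lambda_cv()] or
#'   [lambda_fixed()] policy.
#' @param seed Integer seed (drives the internal CV fold assignment).
#' @return A sparse `selector_result`. An empty selected set is valid.
#' @export
sparse_cox_selector <- function(ds, penalty = c("lasso", "elastic_net"),
                                mixing = 0.5, lambda_policy = lambda_cv(),
                                seed = 1L) {
  penalty <- match.arg(penalty)
  if (sum(ds$event) == 0) stop("penalised Cox requires at least one event")
  alpha <- if (penalty == "lasso") 1 else mixing
  ex <- expand_features(ds)
  if (ncol(ex$x) < 2)
    stop("penalised Cox needs at least 2 design columns")
  y <- survival::Surv(ds$time, ds$event)
  # trimmed path: subset selection is insensitive to the tail of the
  # lambda sequence and to the last decades of coordinate-descent accuracy
  path_args <- list(nlambda = 30L, lambda.min.ratio = 0.05, thresh = 1e-5)
  fit <- do.call(glmnet::glmnet,
                 c(list(ex$x, y, family = "cox", alpha = alpha), path_args))
  lam <- switch(lambda_policy$type,
    fixed = lambda_policy$lambda,
    bic = {
      bic <- stats::deviance(fit) + fit$df * log(sum(ds$event))
      fit$lambda[which.min(bic)]
    },
    cv = {
      foldid <- with_seed(derive_seed(seed %||% 1L, 7L),
                          sample(rep_len(seq_len(lambda_policy$nfolds),
                                         n_samples(ds))))
      cv <- with_seed(derive_seed(seed %||% 1L, 8L),
                      do.call(glmnet::cv.glmnet,
                              c(list(ex$x, y, family = "cox",
                                     alpha = alpha, foldid = foldid),
                                path_args)))
      if (identical(lambda_policy$rule, "min")) cv$lambda.min
      else cv$lambda.1se
    })
  cf <- drop(as.matrix(stats::coef(fit, s = lam)))
  scores <- collapse_to_original(cf, ex$origin, feature_names(ds))
  selected <- names(scores)[scores > 0]
  selector_result(scores, selected, is_sparse = TRUE,
                  selector_id = if (penalty == "lasso") "lasso" else "enet")
}

#' Survival random-forest filter
#'
#' Permutation-importance filter built on \pkg{ranger}'s survival forest
#' with maximally-selected-rank-statistics splitting. Negative permutation
#' importances are clipped to zero so that scores remain valid aggregation
#' weights.
#'
#' @param ds A [survival_dataset()].
#' @param seed Integer seed passed to the forest.
#' @param num_trees Number of trees.
#' @return A `selector_result` filter.
#' @export
survival_forest_selector <- function(ds, seed = 1L, num_trees = 250L) {
  df <- data.frame(.time = ds$time, .event = ds$event, check.names = FALSE)
  for (mt in ds$meta) {
    v <- ds$features[, mt$name]
    df[[mt$name]] <- if (mt$kind == "categorical")
      factor(v, levels = seq_along(mt$levels) - 1) else v
  }
  fit <- ranger::ranger(
    dependent.variable.name = ".time", status.variable.name = ".event",
    data = df, importance = "permutation", num.trees = num_trees,
    splitrule = "maxstat", seed = seed %||% 1L, num.threads = 1L,
    verbose = FALSE)
  imp <- fit$variable.importance
  scores <- pmax(imp[feature_names(ds)], 0)
  names(scores) <- feature_names(ds)
  selector_result(scores, NULL, is_sparse = FALSE, selector_id = "rsf")
}

# ---- registry ---------------------------------------------------------------

.selector_registry <- new.env(parent = emptyenv())

#' Selector registry
#'
#' Selectors are looked up by identifier so that runs are fully described
#' by a config string. Built-ins: `unicox` (univariate Cox concordance
#' filter), `lasso`, `enet` (penalised Cox), `rsf` (survival forest
#' permutation importance). The boosted-Cox identifiers `glmboost` and
#' `coxboost` are reserved adapter slots: registering an implementation
#' with the matching contract makes them available; until then requesting
#' them raises an error listing the available selectors.
#'
#' @param id Selector identifier.
#' @param fn A function `(ds, seed, ...) -> selector_result`.
#' @export
register_selector <- function(id, fn) {
  stopifnot(is.character(id), is.function(fn))
  assign(id, fn, envir = .selector_registry)
  invisible(id)
}

#' @rdname register_selector
#' @export
list_selectors <- function() sort(ls(.selector_registry))

#' @rdname register_selector
#' @export
get_selector <- function(id) {
  if (!exists(id, envir = .selector_registry, inherits = FALSE))
    stop("unknown selector '", id, "'; available: ",
         paste(list_selectors(), collapse = ", "))
  fn <- get(id, envir = .selector_registry, inherits = FALSE)
  function(ds, seed = 1L, ...) validate_selector_result(fn(ds, seed, ...))
}

register_builtin_selectors <- function() {
  register_selector("unicox", function(ds, seed = NULL, ...)
    univariate_cox_filter(ds))
  register_selector("lasso", function(ds, seed = 1L, ...)
    sparse_cox_selector(ds, "lasso", seed = seed, ...))
  register_selector("enet", function(ds, seed = 1L, mixing = 0.5, ...)
    sparse_cox_selector(ds, "elastic_net", mixing = mixing, seed = seed, ...))
  register_selector("rsf", function(ds, seed = 1L, ...)
    survival_forest_selector(ds, seed = seed, ...))
}
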