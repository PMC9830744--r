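# Per-feature score on a "higher is better" scale, restricted to original
# (non-probe) features. Rank-directed aggregations (mean rank, RRA) are
# negated around the universe size so all thresholds cut from above.
high_better_scores <- function(agg, features = NULL) {
  sc <- agg$score
  if (identical(agg$direction, "asc"))
    sc <- (length(agg$score) + 1) - sc
  if (!is.null(features)) sc <- sc[intersect(names(sc), features)]
  sc
}

round_half_up <- function(x) floor(x + 0.5)

#' Fixed-fraction threshold
#'
#' Keeps the top `round_half_up(fraction * p)` original features of the
#' aggregated ordering, where `p` counts original (non-probe) features
#' only; probes are excluded from both the count and the result. The usual
#' fractions are 0.10, 0.25 and 0.33.
#'
#' @param agg An `aggregated_ranking`.
#' @param fraction Fraction in (0, 1).
#' @return Character vector of selected feature names.
#' @export
fixed_fraction <- function(agg, fraction) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  feats <- agg$ordering[!is_probe_name(agg$ordering)]
  count <- round_half_up(fraction * length(feats))
  if (count < 1L) {
    warning("fraction ", fraction, " rounds to 0 features; keeping top 1")
    count <- 1L
  }
  utils::head(feats, count)
}

#' 75% quantile threshold
#'
#' Keeps the original features whose aggregated importance score is
#' strictly greater than the 75th percentile (linear-interpolation
#' quantile) of all original-feature scores. If nothing clears the
#' quantile (e.g. all scores equal) the cut degenerates and all features
#' are kept with a warning, so the downstream model can always be fitted.
#'
#' @param agg An `aggregated_ranking`.
#' @param prob Quantile level (default 0.75).
#' @return Character vector of selected feature names.
#' @export
quantile75 <- function(agg, prob = 0.75) {
  feats <- agg$ordering[!is_probe_name(agg$ordering)]
  sc <- high_better_scores(agg, feats)
  q <- stats::quantile(sc, prob, type = 7, names = FALSE)
  sel <- names(sc)[sc > q]
  if (!length(sel)) {
    warning("quantile threshold selected no features; keeping all")
    return(feats)
  }
  feats[feats %in% sel]
}

# Silverman's rule-of-thumb bandwidth, robust form.
silverman_bw <- function(x) {
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.34
  spread <- if (iqr > 0) min(s, iqr) else s
  0.9 * spread * length(x)^(-1 / 5)
}

#' Kernel-density-estimate threshold
#'
#' Clusters the one-dimensional importance scores with a Gaussian KDE
#' (Silverman's rule-of-thumb bandwidth) on a 512-point grid spanning
#' `[min - 3h, max + 3h]`. Assuming most features are irrelevant, the
#' highest-density local maximum marks the irrelevant cluster; features
#' scoring strictly above the first local minimum beyond that peak are
#' selected. If the density has a single maximum (no cut), the bandwidth
#' is shrunk by 0.75 and the estimate repeated, up to `max_iter` times;
#' if no valid cut is ever found, no thresholding is performed and all
#' features are returned.
#'
#' @param scores Named numeric vector of per-feature aggregated scores
#'   (higher = better), or an `aggregated_ranking`.
#' @param max_iter Maximum bandwidth-shrink iterations.
#' @return Character vector of selected feature names, with attributes
#'   `cut` (the score cut-off, or `NA` on fallback) and `bandwidth`.
#' @export
kde_threshold <- function(scores, max_iter = 10L) {
  if (inherits(scores, "aggregated_ranking")) {
    feats <- scores$ordering[!is_probe_name(scores$ordering)]
    scores <- high_better_scores(scores, feats)
  }
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (length(unique(scores)) < 4L) {
    warning("fewer than 4 distinct scores; no thresholding performed")
    return(structure(names(scores), cut = NA_real_, bandwidth = NA_real_))
  }
  h <- silverman_bw(scores)
  for (iter in seq_len(max_iter)) {
    d <- stats::density(scores, bw = h, n = 512L,
                        from = min(scores) - 3 * h,
                        to = max(scores) + 3 * h)
    sgn <- sign(diff(d$y))
    turns <- diff(sgn)
    maxima <- which(turns < 0) + 1L     # grid index of each local maximum
    minima <- which(turns > 0) + 1L
    if (length(maxima) >= 2L && length(minima) >= 1L) {
      peak <- maxima[which.max(d$y[maxima])]
      min_after <- minima[minima > peak]
      if (length(min_after)) {
        cut <- d$x[min_after[1]]
        return(structure(names(scores)[scores > cut],
                         cut = cut, bandwidth = h))
      }
    }
    h <- h * 0.75
  }
  warning("no valid KDE cut found after ", max_iter,
          " bandwidth reductions; no thresholding performed")
  structure(names(scores), cut = NA_real_, bandwidth = h)
}

#' Best-random-probe threshold
#'
#' Any original feature ranked strictly better than the best-ranked probe
#' in the aggregated ordering is kept; everything at or below the best
#' probe (including score ties with it) is discarded. Special case for
#' sparse selectors: if no probe was ever selected in any bootstrap, the
#' probes carry no importance information and all features selected by the
#' aggregation are kept unchanged.
#'
#' @param agg An `aggregated_ranking` computed over the feature + probe
#'   universe.
#' @param probe_names Names of the probe columns in the universe.
#' @param sparse_no_probe Set to `TRUE` when a sparse selector never
#'   selected any probe in any bootstrap; then `fallback_selected` is
#'   returned unchanged.
#' @param fallback_selected The aggregation-selected original features for
#'   the sparse special case (defaults to the features with any support,
#'   i.e. a better-than-worst aggregated score).
#' @return Character vector of selected feature names.
#' @export
best_probe_threshold <- function(agg, probe_names, sparse_no_probe = FALSE,
                                 fallback_selected = NULL) {
  if (!length(probe_names) || !any(probe_names %in% names(agg$score)))
    stop("no probes in the aggregated universe; enable probe injection")
  feats <- agg$ordering[!is_probe_name(agg$ordering)]
  if (sparse_no_probe) {
    if (!is.null(fallback_selected)) return(fallback_selected)
    sc <- high_better_scores(agg, feats)
    return(names(sc)[sc > min(sc)])
  }
  sc_all <- high_better_scores(agg)
  best_probe <- max(sc_all[intersect(probe_names, names(sc_all))])
  sc <- sc_all[feats]
  feats[sc > best_probe]
}

#' Apply a threshold identifier to an aggregated ranking
#'
#' Identifiers: `fixed:<fraction>`, `q75`, `kde`, `probe`, `none`.
#' Self-thresholding aggregators (RRA, TA, MA) carry their own selection
#' and reject an explicit threshold.
#'
#' @param agg An `aggregated_ranking`.
#' @param id Threshold identifier.
#' @param probe_names Probe names (required for `probe`).
#' @param sparse_no_probe,fallback_selected Passed to
#'   [best_probe_threshold()].
#' @return Character vector of selected original feature names.
#' @export
apply_threshold <- function(agg, id, probe_names = character(0),
                            sparse_no_probe = FALSE,
                            fallback_selected = NULL) {
  if (!is.null(agg$selected) && !identical(id, "none"))
    stop("aggregator '", agg$method,
         "' performs its own thresholding; use threshold 'none'")
  if (identical(id, "none")) {
    sel <- if (!is.null(agg$selected)) agg$selected else agg$ordering
    return(sel[!is_probe_name(sel)])
  }
  if (grepl("^fixed:", id))
    return(fixed_fraction(agg, as.numeric(sub("^fixed:", "", id))))
  switch(id,
         q75 = quantile75(agg),
         kde = as.character(kde_threshold(agg)),
         probe = best_probe_threshold(agg, probe_names, sparse_no_probe,
                                      fallback_selected),
         stop("unknown threshold '", id,
              "'; use fixed:<fraction>, q75, kde, probe or none"))
}
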