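#' Ranked list over a fixed feature universe
#'
#' Converts one bootstrap's [selector_result()] into a ranked list over the
#' run's feature universe (original features plus probes). Filters yield a
#' full list of every universe member ordered by decreasing score; sparse
#' selectors yield a partial list containing only their selected features.
#' Normalised rank is `position / |universe|`, so the best possible rank is
#' `1/|universe|` and an unlisted feature is treated downstream as rank 1.
#' Ties in score are broken by a stable sort with the feature name as
#' secondary key, for bit-reproducibility.
#'
#' @param result A `selector_result`.
#' @param universe Character vector: the fixed feature universe.
#' @return An object of class `ranked_list` with fields `items` (best to
#'   worst), `scores` (for the listed items), `norm_rank`, `partial`.
#' @export
ranked_list <- function(result, universe) {
  stopifnot(inherits(result, "selector_result"))
  miss <- setdiff(names(result$scores), universe)
  if (length(miss))
    stop("scored features outside the universe: ", paste(miss, collapse = ", "))
  pool <- if (result$is_sparse) result$selected else
    intersect(universe, names(result$scores))
  sc <- result$scores[pool]
  ord <- order(-sc, names(sc), method = "radix")
  items <- names(sc)[ord]
  structure(list(items = items,
                 scores = sc[ord],
                 norm_rank = stats::setNames(
                   seq_along(items) / length(universe), items),
                 partial = result$is_sparse,
                 universe_size = length(universe)),
            class = "ranked_list")
}

#' Ensemble run: B ranked lists over one universe
#'
#' @param lists List of [ranked_list()] objects (B >= 2) sharing one universe.
#' @param universe The common feature universe.
#' @param selector_id Identifier of the base selector.
#' @param seeds Optional integer vector of per-bootstrap seeds (audit).
#' @return An object of class `ensemble_run`.
#' @export
ensemble_run <- function(lists, universe, selector_id = "unknown",
                         seeds = NULL) {
  if (length(lists) < 2L) stop("an ensemble run needs at least 2 lists")
  for (l in lists) {
    stopifnot(inherits(l, "ranked_list"))
    if (l$universe_size != length(universe) ||
        length(setdiff(l$items, universe)))
      stop("all ranked lists must share the run's universe")
  }
  structure(list(lists = lists, universe = sort(universe),
                 selector_id = selector_id, seeds = seeds,
                 subset_sizes = vapply(
                   lists, function(l) if (l$partial) length(l$items)
                   else NA_integer_, integer(1))),
            class = "ensemble_run")
}

#' @export
print.ensemble_run <- function(x, ...) {
  cat(sprintf("ensemble_run: %d lists from '%s' over %d features\n",
              length(x$lists), x$selector_id, length(x$universe)))
  invisible(x)
}

# Matrix of per-list integer positions (unlisted = |universe|, the worst).
position_matrix <- function(run) {
  U <- run$universe
  out <- matrix(length(U), length(U), length(run$lists),
                dimnames = list(U, NULL))
  for (b in seq_along(run$lists)) {
    l <- run$lists[[b]]
    out[l$items, b] <- seq_along(l$items)
  }
  out
}

# Matrix of per-list scores (unlisted = 0).
score_matrix <- function(run) {
  U <- run$universe
  out <- matrix(0, length(U), length(run$lists), dimnames = list(U, NULL))
  for (b in seq_along(run$lists)) {
    l <- run$lists[[b]]
    out[l$items, b] <- l$scores
  }
  out
}

new_aggregated_ranking <- function(method, score, ordering, direction,
                                   selected = NULL, k = NULL, rho = NULL,
                                   extras = list()) {
  structure(c(list(method = method, score = score, ordering = ordering,
                   direction = direction, selected = selected, k = k,
                   rho = rho), extras),
            class = "aggregated_ranking")
}

#' @export
print.aggregated_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("aggregated_ranking (%s): %d features%s\n", x$method,
              length(x$ordering),
              if (!is.null(x$selected))
                sprintf(", %d selected", length(x$selected)) else ""))
  top <- utils::head(x$ordering, n)
  cat("  top:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

# Default k for the self-thresholding aggregators: round-half-up mean
# per-list selected-subset size; pure filters have no natural subset
# length, so fall back to a quarter of the original features.
default_k <- function(run) {
  sizes <- run$subset_sizes[!is.na(run$subset_sizes)]
  n_orig <- sum(!is_probe_name(run$universe))
  if (length(sizes)) max(1L, as.integer(floor(mean(sizes) + 0.5)))
  else {
    warning("filter ensemble has no subset sizes; defaulting k to ",
            "ceiling(0.25 * number of original features)")
    max(1L, as.integer(ceiling(0.25 * n_orig)))
  }
}
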