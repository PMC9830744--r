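#' Mean-rank aggregation (Borda)
#'
#' Averages each feature's per-list rank position across the ensemble;
#' features missing from a partial list receive the worst possible rank,
#' `|universe|`. The final ordering is ascending in mean rank with
#' lexicographic tie-breaks, and is identical to a Borda count.
#'
#' @param run An [ensemble_run()].
#' @return An `aggregated_ranking` whose `score` is the mean rank (lower is
#'   better, `direction = "asc"`).
#' @export
mean_rank <- function(run) {
  pos <- position_matrix(run)
  mr <- rowMeans(pos)
  ord <- order(mr, names(mr), method = "radix")
  new_aggregated_ranking("MR", mr, names(mr)[ord], "asc")
}

#' Mean-weight aggregation
#'
#' Averages importance scores across the ensemble; features absent from a
#' sparse list contribute score 0. Ordering is descending in mean score
#' with lexicographic tie-breaks.
#'
#' @param run An [ensemble_run()].
#' @return An `aggregated_ranking` with `direction = "desc"`.
#' @export
mean_weight <- function(run) {
  mw <- rowMeans(score_matrix(run))
  ord <- order(-mw, names(mw), method = "radix")
  new_aggregated_ranking("MW", mw, names(mw)[ord], "desc")
}

#' Binomial tail probability for robust rank aggregation
#'
#' Under the null that normalised ranks are iid uniform on (0, 1\], the
#' probability that the k-th smallest of n ranks is at most `x` is the
#' binomial tail `sum_{l=k}^{n} C(n,l) x^l (1-x)^(n-l)`, evaluated here via
#' the numerically stable binomial survival function.
#'
#' @param k Order index, `1 <= k <= n`.
#' @param n Number of lists.
#' @param x Normalised rank value(s) in `[0, 1]`.
#' @return `P(r_(k) <= x)` under the uniform null.
#' @export
rra_beta <- function(k, n, x) {
  if (any(k < 1) || any(k > n)) stop("k must satisfy 1 <= k <= n")
  if (any(x < 0) || any(x > 1)) stop("x must lie in [0, 1]")
  stats::pbinom(k - 1, size = n, prob = x, lower.tail = FALSE)
}

#' Robust rank aggregation score for one feature
#'
#' Given a feature's sorted normalised ranks `r_(1) <= ... <= r_(n)` across
#' the ensemble, the score is `rho = min_k beta_{k,n}(r_(k))`: the most
#' surprising order statistic relative to the uniform null. Reported
#' uncorrected by default; `correct = TRUE` applies a Bonferroni factor of
#' `n` (capped at 1), as in the original formulation of the method.
#'
#' @param ranks Sorted ascending normalised ranks in (0, 1\].
#' @param correct Apply the Bonferroni correction.
#' @return The score `rho` in `[0, 1]`.
#' @export
rra_score <- function(ranks, correct = FALSE) {
  n <- length(ranks)
  stopifnot(n >= 1, all(ranks > 0), all(ranks <= 1))
  if (is.unsorted(ranks)) stop("ranks must be sorted ascending")
  rho <- min(rra_beta(seq_len(n), n, ranks))
  if (correct) min(1, rho * n) else rho
}

#' Robust rank aggregation over an ensemble run
#'
#' Computes each feature's `rho` from its sorted normalised ranks across
#' the B lists (unlisted features in partial lists count as normalised
#' rank 1) and selects the features with `rho` strictly below the
#' significance threshold. This aggregator both ranks and thresholds; no
#' separate thresholding step is applied to its output.
#'
#' @param run An [ensemble_run()].
#' @param p_threshold Significance level in (0, 1); the method's usual
#'   presets are 0.05, 0.10, 0.15, 0.20, 0.25.
#' @param correct Apply the per-feature Bonferroni correction (default off).
#' @return An `aggregated_ranking` with per-feature `rho`, ascending
#'   ordering, and the selected set (possibly empty).
#' @export
rra_select <- function(run, p_threshold = 0.05, correct = FALSE) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  U <- run$universe
  nr <- matrix(1, length(U), length(run$lists), dimnames = list(U, NULL))
  for (b in seq_along(run$lists)) {
    l <- run$lists[[b]]
    nr[l$items, b] <- l$norm_rank
  }
  rho <- apply(nr, 1, function(r) rra_score(sort(r), correct = correct))
  ord <- order(rho, names(rho), method = "radix")
  ordering <- names(rho)[ord]
  selected <- ordering[rho[ordering] < p_threshold]
  new_aggregated_ranking(sprintf("RRA:%g", p_threshold), rho,
                         ordering, "asc",
                         selected = selected,
                         rho = rho,
                         extras = list(p_threshold = p_threshold))
}

#' Threshold Algorithm (top-k rank aggregation with early stopping)
#'
#' Sequentially walks the B score-sorted lists depth by depth. At depth d
#' the stopping threshold is the sum of the d-th scores over the lists; any
#' newly seen feature is immediately completed by random access (its score
#' in every list, missing = 0) to form its aggregate, the best k aggregates
#' seen so far are maintained, and the walk terminates once all best-k
#' aggregates are at least the threshold. The result equals the top k
#' features by total score; ties at the k-th place keep the
#' lexicographically smaller name.
#'
#' @param run An [ensemble_run()].
#' @param k Number of features to return; defaults to the round-half-up
#'   mean per-list subset size (see [ensemble_run()]), and is clamped to
#'   the universe size with a warning if larger.
#' @return An `aggregated_ranking` with the selected set of size `k`.
#' @export
threshold_algorithm <- function(run, k = NULL) {
  if (is.null(k)) k <- default_k(run)
  stopifnot(k >= 1)
  U <- run$universe
  if (k > length(U)) {
    warning("k = ", k, " exceeds the universe size; clamping to ", length(U))
    k <- length(U)
  }
  sm <- score_matrix(run)          # random-access oracle
  totals <- rowSums(sm)
  depth_max <- max(vapply(run$lists, function(l) length(l$items), 0L))
  seen <- character(0)
  agg <- numeric(0)
  for (d in seq_len(max(depth_max, 1L))) {
    threshold <- sum(vapply(run$lists, function(l)
      if (length(l$scores) >= d) l$scores[[d]] else 0, 0))
    new_items <- unique(unlist(lapply(run$lists, function(l)
      if (length(l$items) >= d) l$items[[d]] else NULL)))
    new_items <- setdiff(new_items, seen)
    if (length(new_items)) {
      seen <- c(seen, new_items)
      agg <- c(agg, totals[new_items])
    }
    ord <- order(-agg, seen, method = "radix")
    best <- utils::head(ord, k)
    if (length(best) == k && all(agg[best] >= threshold)) break
  }
  ord <- order(-agg, seen, method = "radix")
  sel <- seen[utils::head(ord, k)]
  new_aggregated_ranking("TA", stats::setNames(agg, seen)[ord],
                         seen[ord], "desc", selected = sel, k = k)
}

#' MedRank aggregation
#'
#' Sequential access over the B rank-ordered lists: a feature is output to
#' the aggregated list the moment its cumulative appearance count exceeds
#' `fraction * B`, lists being processed in index order within each depth.
#' The walk stops early once `k` features have been output; if the lists
#' are exhausted first the shorter output is returned.
#'
#' @param run An [ensemble_run()].
#' @param k Target output length; defaults as for [threshold_algorithm()].
#' @param fraction Appearance fraction required before output (the
#'   weak-signal default is 0.2 rather than the classical majority 0.5).
#' @return An `aggregated_ranking`; `ordering`/`selected` follow the output
#'   order, `score` holds the appearance counts at termination.
#' @export
medrank <- function(run, k = NULL, fraction = 0.2) {
  stopifnot(fraction > 0, fraction < 1)
  if (is.null(k)) k <- default_k(run)
  stopifnot(k >= 1)
  B <- length(run$lists)
  need <- fraction * B
  counts <- stats::setNames(numeric(length(run$universe)), run$universe)
  output <- character(0)
  depth_max <- max(vapply(run$lists, function(l) length(l$items), 0L))
  for (d in seq_len(max(depth_max, 1L))) {
    for (b in seq_len(B)) {
      l <- run$lists[[b]]
      if (length(l$items) < d) next
      f <- l$items[[d]]
      counts[f] <- counts[f] + 1
      if (counts[f] > need && !(f %in% output)) {
        output <- c(output, f)
        if (length(output) == k) break
      }
    }
    if (length(output) == k) break
  }
  new_aggregated_ranking("MA", counts[output], output, "desc",
                         selected = output, k = k)
}

#' Parse an aggregator identifier and apply it
#'
#' Identifiers: `MR`, `MW`, `TA`, `MA`, `RRA:<p>` (e.g. `RRA:0.15`); the
#' bare `RRA` defaults to p = 0.05.
#'
#' @param run An [ensemble_run()].
#' @param id Aggregator identifier string.
#' @param k Optional k for TA/MA.
#' @return An `aggregated_ranking`.
#' @export
aggregate_run <- function(run, id, k = NULL) {
  if (grepl("^RRA(:|$)", id)) {
    p <- if (grepl(":", id)) as.numeric(sub("^RRA:", "", id)) else 0.05
    if (is.na(p)) stop("bad RRA threshold in '", id, "'")
    return(rra_select(run, p))
  }
  switch(id,
         MR = mean_rank(run),
         MW = mean_weight(run),
         TA = threshold_algorithm(run, k),
         MA = medrank(run, k),
         stop("unknown aggregator '", id,
              "'; use MR, MW, RRA:<p>, TA or MA"))
}

#' Does an aggregator perform its own thresholding?
#' @param id Aggregator identifier.
#' @export
self_thresholding <- function(id)
  grepl("^RRA(:|$)", id) || id %in% c("TA", "MA")
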