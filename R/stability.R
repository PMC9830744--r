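#' Kuncheva's stability index for two equal-size subsets
#'
#' `I_c(S1, S2) = (r*n - k^2) / (k * (n - k))` with `k` the common subset
#' size, `n` the universe size and `r` the intersection size. Equals 1 for
#' identical subsets and corrects for the intersection expected by chance;
#' negative values are possible. Only defined for `0 < k < n` and subsets
#' of identical size.
#'
#' @param s1,s2 Feature subsets (character vectors) of equal size.
#' @param n Universe size.
#' @return The index value (<= 1).
#' @export
kuncheva <- function(s1, s2, n) {
  k <- length(s1)
  if (length(s2) != k)
    stop("Kuncheva's index requires subsets of identical size")
  if (k == 0 || k >= n)
    stop("Kuncheva's index is undefined for k = 0 or k = n")
  r <- length(intersect(s1, s2))
  (r * n - k^2) / (k * (n - k))
}

#' Lustgarten's adjusted stability measure
#'
#' `S_A(Si, Sj) = (r - ki*kj/n) / (min(ki, kj) - max(0, ki + kj - n))`,
#' a chance-corrected overlap that, unlike Kuncheva's index, handles
#' subsets of differing sizes.
#'
#' @param si,sj Feature subsets (character vectors).
#' @param n Universe size.
#' @return The measure value.
#' @export
lustgarten <- function(si, sj, n) {
  ki <- length(si); kj <- length(sj)
  if (ki == 0 || kj == 0 || ki >= n || kj >= n)
    stop("Lustgarten's measure requires 0 < |Si|, |Sj| < n")
  denom <- min(ki, kj) - max(0, ki + kj - n)
  if (denom == 0) stop("Lustgarten's measure: zero denominator")
  r <- length(intersect(si, sj))
  (r - ki * kj / n) / denom
}

#' Subset system for consistency scoring
#'
#' Bundles `n >= 2` feature subsets drawn from a universe `Y` together with
#' the derived occurrence statistics used by [cw_rel()]: the per-feature
#' occurrence counts `F_f`, their total `N`, and the remainders `D` and `H`.
#'
#' @param subsets List of character vectors (the subsets `S_i`).
#' @param universe Character vector `Y`, or a single integer universe size
#'   (features are then taken to be the union of the subsets, padded
#'   conceptually to that size).
#' @return An object of class `subset_system`.
#' @export
subset_system <- function(subsets, universe) {
  stopifnot(is.list(subsets), length(subsets) >= 2L)
  if (is.numeric(universe) && length(universe) == 1L) {
    y_size <- as.integer(universe)
    pool <- sort(unique(unlist(subsets)))
    if (length(pool) > y_size)
      stop("universe size smaller than the union of the subsets")
  } else {
    universe <- as.character(universe)
    y_size <- length(universe)
    bad <- setdiff(unlist(subsets), universe)
    if (length(bad))
      stop("subset members outside the universe: ",
           paste(utils::head(bad, 5), collapse = ", "))
    pool <- universe
  }
  counts <- table(factor(unlist(subsets), levels = pool))
  n <- length(subsets)
  N <- sum(lengths(subsets))
  structure(list(subsets = subsets, y_size = y_size, n = n,
                 F_f = as.numeric(counts), N = N),
            class = "subset_system")
}

#' Relative weighted consistency of a subset system
#'
#' A stability measure for collections of feature subsets of varying size,
#' normalised so that 0 marks the least and 1 the most consistent system
#' attainable with the observed total number of feature occurrences `N`:
#' \deqn{CW_{rel} = \frac{|Y|(N - D + \sum_f F_f(F_f - 1)) - N^2 + D^2}
#'                       {|Y|(H^2 + n(N - H) - D) - N^2 + D^2}}
#' with remainders `D = N mod |Y|` and `H = N mod n` by default. (Some
#' renderings of the formula print `D = n mod |Y|`; that convention is
#' available via `d_convention = "n"`, but the `N`-based remainder is the
#' original definition and the default.)
#'
#' @param system A [subset_system()], or a list of subsets with `universe`
#'   supplied.
#' @param universe Universe (names or size) when `system` is a plain list.
#' @param d_convention `"N"` (default) or `"n"`: the dividend of the `D`
#'   remainder.
#' @return Value in `[0, 1]`, or `NA` with a warning when the denominator
#'   degenerates (e.g. every subset is the full universe).
#' @export
cw_rel <- function(system, universe = NULL, d_convention = c("N", "n")) {
  d_convention <- match.arg(d_convention)
  if (!inherits(system, "subset_system"))
    system <- subset_system(system, universe)
  Y <- system$y_size; N <- system$N; n <- system$n
  if (N == 0) stop("all subsets are empty")
  D <- (if (d_convention == "N") N else n) %% Y
  H <- N %% n
  wsum <- sum(system$F_f * (system$F_f - 1))
  num <- Y * (N - D + wsum) - N^2 + D^2
  den <- Y * (H^2 + n * (N - H) - D) - N^2 + D^2
  if (den == 0) {
    warning("relative weighted consistency: degenerate denominator ",
            "(system admits no variation); returning NA")
    return(NA_real_)
  }
  num / den
}

#' Mean pairwise stability over a collection of subsets
#'
#' Applies a pairwise stability metric to every unordered pair of subsets
#' and averages. Pairs on which the metric is undefined (e.g. Kuncheva
#' with unequal sizes) are skipped with a warning and counted in the
#' `skipped` attribute.
#'
#' @param metric A function `(s1, s2, n) -> numeric`, e.g. [kuncheva()].
#' @param subsets List of feature subsets.
#' @param n Universe size.
#' @return Mean pairwise value, with attribute `skipped`.
#' @export
mean_pairwise <- function(metric, subsets, n) {
  stopifnot(length(subsets) >= 2L)
  vals <- c(); skipped <- 0L
  for (i in seq_len(length(subsets) - 1L))
    for (j in seq(i + 1L, length(subsets))) {
      v <- tryCatch(metric(subsets[[i]], subsets[[j]], n),
                    error = function(e) NA_real_)
      if (is.na(v)) skipped <- skipped + 1L else vals <- c(vals, v)
    }
  if (skipped > 0L)
    warning(skipped, " pair(s) skipped: metric undefined")
  if (!length(vals)) stop("metric undefined on every pair")
  structure(mean(vals), skipped = skipped)
}
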