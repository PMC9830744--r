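# Builders for small in-code fixtures shared across the test files.

# A ranked list from explicit scores (full filter list over the universe,
# or a sparse partial list when `selected` is given).
mk_list <- function(scores, universe, selected = NULL) {
  res <- selector_result(scores, selected, is_sparse = !is.null(selected),
                         selector_id = "test")
  ranked_list(res, universe)
}

# An ensemble run from a list of score maps.
mk_run <- function(score_maps, universe, selected = NULL) {
  lists <- lapply(seq_along(score_maps), function(i)
    mk_list(score_maps[[i]], universe,
            selected = if (is.null(selected)) NULL else selected[[i]]))
  ensemble_run(lists, universe)
}

# Scores that force a given rank ordering in a full list.
scores_for_ranks <- function(ranks) {
  stats::setNames((length(ranks) + 1 - ranks) / (length(ranks) + 1),
                  names(ranks))
}

# A small hand-rolled survival dataset with mixed feature kinds.
mixed_dataset <- function(m = 40, seed = 1) {
  set.seed(seed)
  feats <- cbind(x1 = rnorm(m), x2 = rnorm(m), x3 = rnorm(m),
                 b1 = rbinom(m, 1, 0.5), b2 = rbinom(m, 1, 0.5),
                 c1 = sample(0:2, m, replace = TRUE))
  meta <- list(feature_meta("x1", "continuous"),
               feature_meta("x2", "continuous"),
               feature_meta("x3", "continuous"),
               feature_meta("b1", "boolean"),
               feature_meta("b2", "boolean"),
               feature_meta("c1", "categorical", levels = c("A", "B", "C")))
  time <- rexp(m, exp(0.8 * feats[, "x1"]))
  event <- rbinom(m, 1, 0.6)
  survival_dataset(feats, pmax(time, 1e-6), event, meta)
}

# Independent brute-force oracles, implemented separately from the package.

brute_cindex <- function(time, event, risk) {
  num <- den <- 0
  m <- length(time)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

brute_rra_beta <- function(k, n, x) {
  total <- 0
  for (l in k:n) total <- total + choose(n, l) * x^l * (1 - x)^(n - l)
  total
}

brute_kuncheva <- function(s1, s2, n) {
  k <- length(s1); r <- sum(s1 %in% s2)
  (r * n - k^2) / (k * (n - k))
}

brute_lustgarten <- function(si, sj, n) {
  ki <- length(si); kj <- length(sj); r <- sum(si %in% sj)
  (r - ki * kj / n) / (min(ki, kj) - max(0, ki + kj - n))
}

brute_cw_rel <- function(subsets, y_size) {
  all_f <- unlist(subsets)
  N <- length(all_f); n <- length(subsets)
  Ff <- table(all_f)
  D <- N %% y_size; H <- N %% n
  num <- y_size * (N - D + sum(Ff * (Ff - 1))) - N^2 + D^2
  den <- y_size * (H^2 + n * (N - H) - D) - N^2 + D^2
  num / den
}

# Brute-force top-k by total score with lexicographic tie-break.
brute_topk <- function(score_maps, universe, k) {
  totals <- vapply(universe, function(f)
    sum(vapply(score_maps, function(s)
      if (f %in% names(s)) s[[f]] else 0, 0)), 0)
  universe[order(-totals, universe)][seq_len(k)]
}
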