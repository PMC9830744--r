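agg_from_scores <- function(scores) {
  ord <- order(-scores, names(scores), method = "radix")
  survefs:::new_aggregated_ranking("MW", scores, names(scores)[ord], "desc")
}

test_that("fixed fractions keep a round-half-up share of the original
           features and are monotone", {
  scores <- stats::setNames(seq(140, 1), sprintf("f%03d", 1:140))
  agg <- agg_from_scores(scores)
  expect_length(fixed_fraction(agg, 0.10), 14)
  expect_length(fixed_fraction(agg, 0.25), 35)
  expect_length(fixed_fraction(agg, 0.33), round(0.33 * 140 + 1e-9))
  expect_error(fixed_fraction(agg, 1.2), "between 0 and 1")
  expect_error(fixed_fraction(agg, 0), "between 0 and 1")
  # monotone: larger fraction gives a superset
  prev <- character(0)
  for (f in c(0.05, 0.1, 0.25, 0.33, 0.8)) {
    cur <- fixed_fraction(agg, f)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  # probes excluded from both count and result
  sc2 <- c(scores[1:10], stats::setNames(1000, "__probe__f001"))
  agg2 <- agg_from_scores(sc2)
  sel <- fixed_fraction(agg2, 0.5)
  expect_length(sel, 5)
  expect_false(any(is_probe_name(sel)))
  # rounding to zero keeps the top feature with a warning
  expect_warning(one <- fixed_fraction(agg_from_scores(scores[1:3]), 0.1),
                 "top 1")
  expect_equal(one, "f001")
})

test_that("quantile threshold cuts strictly above the interpolated 75th
           percentile", {
  scores <- stats::setNames(1:8, letters[1:8])
  sel <- quantile75(agg_from_scores(scores))
  expect_setequal(sel, c("g", "h"))     # q75 of 1..8 = 6.25
  expect_warning(all_f <- quantile75(agg_from_scores(
    stats::setNames(rep(2, 6), letters[1:6]))), "no features")
  expect_setequal(all_f, letters[1:6])
  one <- c(stats::setNames(rep(0, 9), letters[1:9]), z = 1)
  expect_equal(quantile75(agg_from_scores(one)), "z")
})

test_that("KDE threshold recovers a well-separated high cluster and falls
           back to all features when no valid cut exists", {
  set.seed(101)
  scores <- stats::setNames(
    c(rnorm(90, 0.01, 0.005), rnorm(10, 1.0, 0.005)),
    sprintf("f%03d", 1:100))
  sel <- kde_threshold(scores)
  expect_setequal(as.character(sel), sprintf("f%03d", 91:100))
  expect_true(attr(sel, "cut") > max(scores[1:90]))
  expect_true(attr(sel, "cut") < min(scores[91:100]))

  flat <- stats::setNames(rep(0.3, 50), paste0("f", 1:50))
  expect_warning(sel <- kde_threshold(flat), "no thresholding")
  expect_setequal(as.character(sel), names(flat))

  # whatever cut is found, the selection is upward-closed in score:
  # every kept feature outscores every discarded one
  for (s in 1:5) {
    set.seed(s)
    uni <- stats::setNames(rnorm(80), paste0("f", 1:80))
    res <- suppressWarnings(kde_threshold(uni))
    kept <- as.character(res)
    if (length(kept) < 80)
      expect_gt(min(uni[kept]), max(uni[setdiff(names(uni), kept)]))
  }
})

test_that("KDE recovers clusters exactly when the gap is many bandwidths
           wide, across cluster proportions", {
  set.seed(77)
  for (prop_high in c(0.1, 0.25, 0.45)) {
    n <- 100; n_high <- round(n * prop_high)
    scores <- stats::setNames(
      c(rnorm(n - n_high, 0, 0.01), rnorm(n_high, 5, 0.01)),
      paste0("f", seq_len(n)))
    sel <- suppressWarnings(kde_threshold(scores))
    expect_setequal(as.character(sel), paste0("f", (n - n_high + 1):n))
  }
})

test_that("best-probe threshold keeps features strictly above the best
           probe and honours the sparse special case", {
  sc <- c(stats::setNames(c(10, 9, 8, 7), paste0("f", 1:4)),
          "__probe__x" = 6, f5 = 5, "__probe__y" = 2)
  agg <- agg_from_scores(sc)
  probes <- c("__probe__x", "__probe__y")
  expect_setequal(best_probe_threshold(agg, probes), paste0("f", 1:4))

  # probes at the bottom keep every original feature
  sc2 <- c(stats::setNames(5:1, paste0("f", 1:5)),
           "__probe__x" = 0.5, "__probe__y" = 0.1)
  expect_setequal(best_probe_threshold(agg_from_scores(sc2), probes),
                  paste0("f", 1:5))

  # tie with the best probe discards the tied feature
  sc3 <- c(f1 = 3, f2 = 2, "__probe__x" = 2, f3 = 1, "__probe__y" = 0)
  expect_equal(best_probe_threshold(agg_from_scores(sc3), probes), "f1")

  # sparse run in which no bootstrap ever selected a probe
  keep <- c("f2", "f9")
  expect_equal(best_probe_threshold(agg, probes, sparse_no_probe = TRUE,
                                    fallback_selected = keep), keep)
  expect_error(best_probe_threshold(agg_from_scores(sc2[1:5]), character(0)),
               "probe")
})

test_that("threshold identifiers dispatch and self-thresholding aggregators
           reject explicit thresholds", {
  scores <- stats::setNames(10:1, paste0("f", 1:10))
  agg <- agg_from_scores(scores)
  expect_length(apply_threshold(agg, "fixed:0.25"), 3)  # round_half_up(2.5)
  expect_setequal(apply_threshold(agg, "none"), names(scores))
  expect_error(apply_threshold(agg, "weird"), "unknown threshold")
  selected_agg <- survefs:::new_aggregated_ranking(
    "TA", scores, names(scores), "desc", selected = paste0("f", 1:3))
  expect_error(apply_threshold(selected_agg, "q75"), "own thresholding")
  expect_equal(apply_threshold(selected_agg, "none"), paste0("f", 1:3))
})

test_that("score thresholds work on rank-directed aggregations via the
           uniform higher-is-better conversion", {
  U <- paste0("f", 1:8)
  maps <- replicate(3, scores_for_ranks(stats::setNames(1:8, U)),
                    simplify = FALSE)
  run <- mk_run(maps, U)
  agg <- mean_rank(run)
  sel <- quantile75(agg)
  expect_setequal(sel, c("f1", "f2"))   # best two mean ranks
})
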