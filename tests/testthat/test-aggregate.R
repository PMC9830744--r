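test_that("mean rank averages positions, worst-ranks unlisted features and
           breaks ties lexicographically", {
  U <- c("a", "b")
  run <- mk_run(list(scores_for_ranks(c(a = 1, b = 2)),
                     scores_for_ranks(c(a = 2, b = 1))), U)
  agg <- mean_rank(run)
  expect_equal(unname(agg$score[c("a", "b")]), c(1.5, 1.5))
  expect_equal(agg$ordering, c("a", "b"))

  U <- c("a", "b", "c")
  run <- mk_run(list(scores_for_ranks(c(a = 1, b = 2, c = 3)),
                     scores_for_ranks(c(a = 1, c = 2, b = 3)),
                     scores_for_ranks(c(b = 1, c = 2, a = 3))), U)
  agg <- mean_rank(run)
  expect_equal(unname(agg$score[c("a", "b", "c")]), c(5, 6, 7) / 3)
  expect_equal(agg$ordering, c("a", "b", "c"))

  # unlisted features of a sparse list get the worst rank
  run <- mk_run(list(c(a = 0.9, b = 0.5), c(a = 0.8, b = 0.4)), U,
                selected = list(c("a", "b"), c("a", "b")))
  agg <- mean_rank(run)
  expect_equal(unname(agg$score["c"]), 3)
})

test_that("mean rank ordering coincides with the Borda count", {
  set.seed(42)
  for (rep in 1:20) {
    p <- sample(3:8, 1); B <- sample(2:6, 1)
    U <- paste0("f", seq_len(p))
    maps <- lapply(seq_len(B), function(b)
      stats::setNames(runif(p), U))
    run <- mk_run(maps, U)
    agg <- mean_rank(run)
    # Borda: points = (p - position), summed over lists, descending
    borda <- rowSums(vapply(maps, function(s) {
      pos <- rank(-s, ties.method = "first")
      p - pos
    }, numeric(p)))
    expect_equal(agg$ordering, U[order(-borda, U)])
  }
})

test_that("mean weight averages scores with absent-as-zero", {
  U <- c("a", "b")
  run <- mk_run(list(c(a = 0.4, b = 0.1), c(a = 0.6, b = 0.2)), U)
  expect_equal(unname(mean_weight(run)$score["a"]), 0.5)

  run <- mk_run(list(c(a = 0.8, b = 0.3), c(b = 0.5)), U,
                selected = list(c("a", "b"), "b"))
  expect_equal(unname(mean_weight(run)$score["a"]), 0.4)

  run <- mk_run(list(c(a = 0, b = 0), c(a = 0, b = 0)), U)
  agg <- mean_weight(run)
  expect_equal(unname(agg$score), c(0, 0))
  expect_equal(agg$ordering, c("a", "b"))
})

test_that("rra_beta equals the binomial tail and honours its domain", {
  expect_equal(rra_beta(1, 1, 0.2), 0.2)
  expect_equal(rra_beta(2, 3, 0.5), 0.5)
  expect_equal(rra_beta(3, 7, 1), 1)
  expect_error(rra_beta(0, 3, 0.5), "k")
  expect_error(rra_beta(4, 3, 0.5), "k")
  expect_error(rra_beta(1, 3, 1.5), "x")
  # monotone nondecreasing in x
  xs <- seq(0, 1, by = 0.01)
  for (n in c(3, 10)) for (k in c(1, n %/% 2 + 1, n))
    expect_true(all(diff(rra_beta(k, n, xs)) >= -1e-14))
  # tail symmetry: beta_{k,n}(x) = 1 - beta_{n-k+1,n}(1-x)
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:15, 1); k <- sample(n, 1); x <- runif(1)
    expect_lt(abs(rra_beta(k, n, x) - (1 - rra_beta(n - k + 1, n, 1 - x))),
              1e-12)
  }
})

test_that("rra_score is the minimum order-statistic p-value", {
  expect_equal(rra_score(c(1, 1, 1)), 1)
  expect_equal(rra_score(0.2), 0.2)
  r <- c(0.1, 0.2, 0.9)
  expect_equal(rra_score(r), 0.104, tolerance = 1e-12)
  expect_error(rra_score(c(0.5, 0.2)), "sorted")
  # Bonferroni correction multiplies by n, capped at 1
  expect_equal(rra_score(r, correct = TRUE), 3 * 0.104, tolerance = 1e-12)
  expect_equal(rra_score(c(1, 1, 1), correct = TRUE), 1)
})

test_that("rra_select thresholds by rho and never selects all-unlisted
           features", {
  U <- c("a", "b", "c", "d")
  # a always first of 4; b second; c third; d never listed
  maps <- lapply(1:5, function(i) c(a = 0.9, b = 0.6, c = 0.3))
  run <- mk_run(maps, U, selected = replicate(5, c("a", "b", "c"),
                                              simplify = FALSE))
  agg <- rra_select(run, 0.9)
  expect_equal(unname(agg$rho["d"]), 1)
  expect_false("d" %in% agg$selected)
  # a ranked 1/4 in all 5 lists: the minimum over k of beta_{k,5}(0.25)
  # is attained at k = 5, giving 0.25^5 (all five null ranks in the top
  # quarter simultaneously)
  expect_equal(unname(agg$rho["a"]), 0.25^5, tolerance = 1e-12)
  # a feature always ranked 1 of 100 over 50 lists is overwhelmingly
  # significant: rho = 0.01^50
  U2 <- c(paste0("f", 1:100))
  maps2 <- replicate(50, stats::setNames(c(1, runif(99, 0, 0.5)), U2),
                     simplify = FALSE)
  run2 <- mk_run(maps2, U2)
  agg2 <- rra_select(run2, 0.5)
  expect_lt(unname(agg2$rho["f1"]), 1e-90)
  expect_equal(agg2$ordering[1], "f1")
})

test_that("threshold algorithm walks its sequential accesses and matches
           the brute-force top-k oracle exhaustively", {
  U <- c("a", "b", "c")
  maps <- list(c(a = 0.9, b = 0.5, c = 0.1), c(b = 0.8, a = 0.7, c = 0.2))
  run <- mk_run(maps, U)
  agg <- threshold_algorithm(run, k = 1)
  expect_equal(agg$selected, "a")
  expect_equal(unname(agg$score["a"]), 1.6)

  # k = universe size returns everything
  expect_setequal(threshold_algorithm(run, k = 3)$selected, U)
  expect_warning(big <- threshold_algorithm(run, k = 10), "clamp")
  expect_setequal(big$selected, U)

  set.seed(11)
  for (p in 2:6) for (B in 2:4) for (rep in 1:5) {
    U <- paste0("f", seq_len(p))
    maps <- replicate(B, stats::setNames(round(runif(p), 2), U),
                      simplify = FALSE)
    run <- mk_run(maps, U)
    for (k in seq_len(p))
      expect_setequal(threshold_algorithm(run, k = k)$selected,
                      brute_topk(maps, U, k))
  }
})

test_that("medrank outputs features on crossing the appearance fraction and
           stops early at k", {
  U <- c("a", "b", "c")
  # L1=(a,b,c) L2=(a,c,b) L3=(b,a,c) L4=(a,b,c) L5=(c,a,b), k=2 -> (a,b)
  mk <- function(...) scores_for_ranks(stats::setNames(1:3, c(...)))
  run <- mk_run(list(mk("a","b","c"), mk("a","c","b"), mk("b","a","c"),
                     mk("a","b","c"), mk("c","a","b")), U)
  agg <- medrank(run, k = 2, fraction = 0.2)
  expect_equal(agg$selected, c("a", "b"))

  # all lists identical, k=1 -> the common first feature
  run <- mk_run(replicate(5, mk("b", "a", "c"), simplify = FALSE), U)
  expect_equal(medrank(run, k = 1, fraction = 0.2)$selected, "b")

  # lists exhausted before k features cross the fraction -> shorter output
  run <- mk_run(list(c(a = 0.9), c(b = 0.8), c(c = 0.7), c(a = 0.6),
                     c(b = 0.5)),
                U, selected = list("a", "b", "c", "a", "b"))
  agg <- medrank(run, k = 3, fraction = 0.5)
  expect_true(length(agg$selected) < 3)
})

test_that("aggregators are equivariant to list order (medrank excepted)", {
  set.seed(23)
  U <- paste0("f", 1:6)
  maps <- replicate(4, stats::setNames(runif(6), U), simplify = FALSE)
  run1 <- mk_run(maps, U)
  run2 <- mk_run(rev(maps), U)
  expect_equal(mean_rank(run1)$ordering, mean_rank(run2)$ordering)
  expect_equal(mean_weight(run1)$ordering, mean_weight(run2)$ordering)
  expect_equal(rra_select(run1, 0.2)$selected, rra_select(run2, 0.2)$selected)
  expect_setequal(threshold_algorithm(run1, 3)$selected,
                  threshold_algorithm(run2, 3)$selected)
})

test_that("aggregator identifiers parse and self-thresholding is flagged", {
  U <- c("a", "b", "c")
  run <- mk_run(list(c(a = 3, b = 2, c = 1), c(a = 3, b = 1, c = 2)), U)
  expect_equal(aggregate_run(run, "MR")$method, "MR")
  expect_equal(aggregate_run(run, "RRA:0.15")$p_threshold, 0.15)
  expect_error(aggregate_run(run, "XX"), "unknown aggregator")
  expect_true(self_thresholding("RRA:0.25"))
  expect_true(self_thresholding("TA"))
  expect_false(self_thresholding("MW"))
})
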