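test_that("concordance index handles the canonical limit cases", {
  expect_equal(concordance_index(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)), 1)
  # censored middle observation: comparable pairs (1,2) and (1,3)
  expect_equal(concordance_index(c(1, 2, 3), c(1, 0, 1), c(3, 1, 2)), 1)
  expect_equal(concordance_index(c(1, 2, 3), c(1, 1, 1), c(5, 5, 5)), 0.5)
  expect_equal(concordance_index(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3)), 0)
  expect_error(concordance_index(c(1, 2), c(0, 0), c(1, 2)),
               "no comparable pairs")
})

test_that("concordance index equals brute-force pair enumeration and the
           survival package on random censored instances", {
  set.seed(66)
  for (rep in 1:25) {
    m <- sample(5:30, 1)
    # tied times exercise the comparability rule against the brute force
    time <- round(rexp(m, 1), 3) + 0.001
    event <- rbinom(m, 1, 0.6)
    risk <- sample(1:5, m, replace = TRUE)   # risk ties likely
    if (sum(outer(time, time, "<") & (event == 1)) == 0) next
    expect_equal(concordance_index(time, event, risk),
                 brute_cindex(time, event, risk))
    # tie-free times for the cross-check: the survival package weights
    # tied event times differently from the strict earlier-event rule
    time2 <- rexp(m, 1)
    if (sum(outer(time2, time2, "<") & (event == 1)) == 0) next
    ours <- concordance_index(time2, event, risk)
    ref <- survival::concordance(
      survival::Surv(time2, event) ~ risk, reverse = TRUE)$concordance
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("ridge Cox scorer orders risk sensibly and degenerates under an
           overwhelming penalty", {
  set.seed(4)
  m <- 200
  x <- rnorm(m)
  time <- rexp(m, exp(x))
  ds <- survival_dataset(cbind(s = x, junk = rnorm(m)),
                         time = time, event = rep(1, m))
  train <- subset_rows(ds, 1:150); test <- subset_rows(ds, 151:200)
  sc <- fit_ridge_cox(train, c("s", "junk"), lambda = 0.1)
  ci <- concordance_index(test$time, test$event, sc(test))
  truth_ci <- concordance_index(test$time, test$event,
                                test$features[, "s"])
  expect_gt(ci, truth_ci - 0.05)
  # penalty -> infinity: coefficients shrink toward 0; in the exact limit
  # all risks tie and C = 0.5
  sc0 <- fit_ridge_cox(train, c("s", "junk"), lambda = 1e9)
  expect_lt(sum(abs(attr(sc0, "beta"))), 1e-2 * sum(abs(attr(sc, "beta"))))
  expect_equal(concordance_index(test$time, test$event,
                                 rep(0, n_samples(test))), 0.5)
})

test_that("ridge symmetry: duplicated feature columns share the weight", {
  set.seed(5)
  m <- 150
  x <- rnorm(m)
  ds <- survival_dataset(cbind(a = x, b = x), time = rexp(m, exp(x)),
                         event = rep(1, m))
  sc <- fit_ridge_cox(ds, c("a", "b"), lambda = 0.5)
  beta <- attr(sc, "beta")
  expect_equal(unname(beta["a"]), unname(beta["b"]), tolerance = 0.01)
})

test_that("a single selected feature still yields a usable risk scorer", {
  set.seed(6)
  m <- 120
  x <- rnorm(m)
  ds <- survival_dataset(cbind(only = x, other = rnorm(m)),
                         time = rexp(m, exp(1.2 * x)), event = rep(1, m))
  sc <- fit_ridge_cox(ds, "only")
  expect_gt(concordance_index(ds$time, ds$event, sc(ds)), 0.7)
})

test_that("euclidean score is the plane distance from the origin", {
  expect_equal(euclidean_score(0, 0), 0)
  expect_equal(euclidean_score(0.6, 0.8), 1)
  expect_equal(euclidean_score(1, 1), sqrt(2))
  expect_error(euclidean_score(NA, 1), "finite")
})

test_that("consensus features pool the top models by euclidean score", {
  mk_result <- function(subsets, cindex, stability) {
    structure(list(subsets = subsets, cindex = cindex,
                   mean_cindex = mean(cindex), stability = stability,
                   euclidean = euclidean_score(stability, mean(cindex)),
                   provenance = list(mode = "test")),
              class = "efs_experiment")
  }
  good <- lapply(1:10, function(i)
    mk_result(replicate(4, c("a", "b"), simplify = FALSE), rep(0.9, 4), 0.9))
  # weaker models select d, and should be excluded from the top 10
  weak <- lapply(1:3, function(i)
    mk_result(replicate(4, "d", simplify = FALSE), rep(0.5, 4), 0.1))
  out <- consensus_features(c(good, weak), top_n = 10, min_fraction = 0.5)
  expect_setequal(out$feature, c("a", "b"))
  expect_equal(out$frequency, c(1, 1))

  # a feature in fewer than half the top models is excluded
  mixed <- c(lapply(1:4, function(i)
    mk_result(replicate(4, c("a", "z"), simplify = FALSE), rep(0.9, 4), 0.9)),
    lapply(1:6, function(i)
      mk_result(replicate(4, "a", simplify = FALSE), rep(0.9, 4), 0.9)))
  out <- consensus_features(mixed, top_n = 10, min_fraction = 0.5)
  expect_false("z" %in% out$feature)
  expect_true("a" %in% out$feature)

  # tightening the fraction can only shrink the output
  loose <- consensus_features(mixed, top_n = 10, min_fraction = 0.5)
  strict <- consensus_features(mixed, top_n = 10, min_fraction = 0.8)
  expect_true(all(strict$feature %in% loose$feature))
  expect_warning(consensus_features(good[1:3], top_n = 10), "using all")
})
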