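test_that("bin proportions recount trials in complete windows", {
  expect_equal(bin_proportions(rep(TRUE, 8))$proportions, c(1, 1))
  expect_equal(bin_proportions(refresco_exp1())$proportions,
               c(0.75, 1, 1, 1, 1))
  # trailing partial bin dropped
  expect_equal(bin_proportions(rep(TRUE, 11))$n_bins, 2)

  set.seed(5)
  outcomes <- stats::runif(40) < 0.7
  series <- bin_proportions(outcomes)
  manual <- vapply(1:10, function(b) mean(outcomes[(4 * b - 3):(4 * b)]),
                   numeric(1))
  expect_equal(series$proportions, manual)
  expect_true(all(series$proportions %in% c(0, 0.25, 0.5, 0.75, 1)))

  expect_error(bin_proportions(rep(TRUE, 3)), "full bin")
  expect_error(bin_proportions(rep(TRUE, 8), bin_width = 0), "positive")
})

test_that("ols_slope matches exact lines and the lm fit", {
  expect_equal(ols_slope(c(0.5, 0.75, 1.0)), 0.25)
  expect_equal(ols_slope(rep(0.6, 5)), 0)
  set.seed(9)
  for (i in 1:20) {
    y <- stats::runif(10)
    expect_equal(ols_slope(y),
                 unname(stats::coef(stats::lm(y ~ seq_along(y)))[2]),
                 tolerance = 1e-12)
  }
  expect_error(ols_slope(0.5), "at least 2")
})

test_that("strategy labels follow the error-prefix / slope rules", {
  lab <- classify_strategy(refresco_exp1())
  expect_equal(lab$label, "epsilon_first")
  expect_equal(lab$exploration_end, 1L)

  # no error at all is also an entirely exploitative record
  expect_equal(classify_strategy(rep(TRUE, 20))$label, "epsilon_first")

  # errors interleaved through trial 25 of 30 with rising bins
  set.seed(21)
  gradual <- c(stats::runif(12) < 0.55, stats::runif(13) < 0.85,
               rep(TRUE, 5))
  gradual[25] <- FALSE
  lab <- classify_strategy(gradual, allow_incomplete = TRUE)
  expect_equal(lab$label, "epsilon_decreasing")
  expect_gt(lab$bin_slope, 0)

  # flat alternation: zero slope, errors everywhere
  lab <- classify_strategy(rep(c(TRUE, FALSE), 10), allow_incomplete = TRUE)
  expect_equal(lab$label, "unclassified")
  expect_equal(lab$bin_slope, 0)

  expect_error(classify_strategy(rep(c(TRUE, FALSE), 10)),
               "not reached criterion")
  expect_error(classify_strategy(rep(TRUE, 7), allow_incomplete = TRUE),
               "2 complete bins")
})

test_that("epsilon-first labels are invariant to trailing correct padding", {
  set.seed(3)
  for (i in 1:20) {
    prefix <- stats::runif(4) < 0.5
    outcomes <- c(prefix, rep(TRUE, 20))
    base <- classify_strategy(outcomes, allow_incomplete = TRUE)
    expect_equal(base$label, "epsilon_first")
    padded <- classify_strategy(c(outcomes, rep(TRUE, 12)),
                                allow_incomplete = TRUE)
    expect_equal(padded$label, "epsilon_first")
    expect_equal(padded$exploration_end, base$exploration_end)
  }
})

test_that("anomaly flags mark late dips and irregular starts", {
  # two high bins then a collapse: a second exploration phase
  dip <- c(rep(TRUE, 8), c(TRUE, FALSE, FALSE, FALSE), rep(TRUE, 8))
  lab <- classify_strategy(dip, allow_incomplete = TRUE)
  expect_true("late_dip" %in% lab$anomalies)

  # early two-step drop: non-monotone first half
  irregular <- c(rep(TRUE, 4), c(FALSE, FALSE, TRUE, FALSE),
                 rep(TRUE, 16))
  lab <- classify_strategy(irregular, allow_incomplete = TRUE)
  expect_true("irregular_start" %in% lab$anomalies)

  # a clean gradual curve raises neither flag
  clean <- c(rep(c(FALSE, TRUE), 4), rep(TRUE, 16))
  expect_length(classify_strategy(clean, allow_incomplete = TRUE)$anomalies, 0)
})
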