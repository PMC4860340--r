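test_that("two-tailed binomial matches direct summation and binom.test", {
  expect_equal(binom_two_tailed(17, 20)$p_raw, 0.002576828, tolerance = 1e-6)
  expect_equal(binom_two_tailed(16, 32)$p_raw, 1)
  expect_equal(binom_two_tailed(33, 43)$p_raw, naive_binom_two_tailed(33, 43),
               tolerance = 1e-12)
  # at p0 = 0.5 tail doubling equals the minimum-likelihood two-sided test
  for (case in list(c(17, 20), c(33, 43), c(28, 37), c(10, 39), c(16, 32))) {
    expect_equal(binom_two_tailed(case[1], case[2])$p_raw,
                 stats::binom.test(case[1], case[2])$p.value,
                 tolerance = 1e-12)
  }
  expect_error(binom_two_tailed(21, 20), "successes")
  expect_error(binom_two_tailed(5, 10, p0 = 1), "strictly between")
})

test_that("binomial p is symmetric around chance", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(5:80, 1)
    k <- sample(0:n, 1)
    expect_equal(binom_two_tailed(k, n)$p_raw,
                 binom_two_tailed(n - k, n)$p_raw, tolerance = 1e-12)
  }
})

test_that("Holm adjustment reproduces the hand-worked step-down", {
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(17)
  p <- stats::runif(8)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # permutation equivariance
  perm <- sample(8)
  expect_equal(holm_adjust(p[perm]), adj[perm])
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(holm_adjust(numeric(0)), "empty")
})

test_that("holm_adjust_results fills family bookkeeping", {
  fam <- holm_adjust_results(list(binom_two_tailed(9, 10),
                                  binom_two_tailed(6, 10)))
  expect_equal(fam[[1]]$family_size, 2)
  expect_gte(fam[[1]]$p_adjusted, fam[[1]]$p_raw)
  expect_gte(fam[[2]]$p_adjusted, fam[[2]]$p_raw)
})

test_that("tie-corrected Spearman matches the rank-then-Pearson oracle", {
  ident <- spearman_tied(1:3, 1:3)
  expect_equal(ident$rho, 1)
  expect_equal(ident$S, 0)

  set.seed(19)
  for (i in 1:40) {
    n <- sample(5:15, 1)
    x <- sample(1:5, n, replace = TRUE)   # heavy ties
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    got <- spearman_tied(x, y)
    oracle <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(got$rho, unname(oracle$estimate), tolerance = 1e-12)
    expect_equal(got$S, unname(oracle$statistic), tolerance = 1e-9)
    expect_equal(got$p_approx, oracle$p.value, tolerance = 1e-9)
    # S identity holds by construction
    expect_equal(got$S, (1 - got$rho) * (n^3 - n) / 6, tolerance = 1e-12)
  }
})

test_that("Spearman reduces to the sum of squared rank differences without ties", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    x <- sample(n)   # permutations: no ties
    y <- sample(n)
    got <- spearman_tied(x, y)
    expect_equal(got$S, sum((rank(x) - rank(y))^2), tolerance = 1e-9)
    expect_false(got$tie_corrected)
  }
  expect_error(spearman_tied(c(1, 1, 1), 1:3), "constant ranks")
  expect_error(spearman_tied(1:2, 1:2), "n >= 3")
  expect_error(spearman_tied(1:4, 1:3), "equal length")
})

test_that("Akaike weights normalize and shift-invariance holds", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  expect_equal(akaike_weights(42), 1)
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  set.seed(29)
  ic <- stats::rnorm(6, 100, 10)
  expect_equal(sum(akaike_weights(ic)), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(ic), akaike_weights(ic + 57.3),
               tolerance = 1e-12)
  expect_error(akaike_weights(numeric(0)), "at least one")
  expect_error(akaike_weights(c(1, Inf)), "finite")
})
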