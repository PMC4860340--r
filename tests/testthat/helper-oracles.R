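# Independent oracles and small fixture builders used across test files.

# brute-force criterion scan: re-counts every window and block at every
# completed block boundary, independent of evaluate_criterion's early exit
naive_criterion <- function(outcomes, window = 20, min_window = 17,
                            block = 10, min_block = 8) {
  n <- length(outcomes)
  T <- window
  while (T <= n) {
    w_ok <- sum(outcomes[(T - window + 1):T]) >= min_window
    b1_ok <- sum(outcomes[(T - 2 * block + 1):(T - block)]) >= min_block
    b2_ok <- sum(outcomes[(T - block + 1):T]) >= min_block
    if (w_ok && b1_ok && b2_ok) return(as.integer(T))
    T <- T + block
  }
  NA_integer_
}

# exact two-tailed binomial by direct coefficient summation (no pbinom)
naive_binom_two_tailed <- function(k, n, p0 = 0.5) {
  pmf <- vapply(0:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
                numeric(1))
  min(1, 2 * min(sum(pmf[1:(k + 1)]), sum(pmf[(k + 1):(n + 1)])))
}

# builds a one-choice-per-trial event table from a logical outcome vector
assoc_events <- function(outcomes, bird = "b1", exp = "EXP1_COLOR") {
  rewarded <- banditflex::functional_option(exp)
  other <- setdiff(banditflex::option_domain(exp), rewarded)
  data.frame(
    bird_id = bird, experiment_id = exp,
    trial_index = seq_along(outcomes), choice_index = 1L,
    option = ifelse(outcomes, rewarded, other),
    is_correct = outcomes, is_accidental = FALSE,
    trial_success = outcomes, stringsAsFactors = FALSE
  )
}

# the published error-then-perfect initial-learning pattern
refresco_exp1 <- function() c(FALSE, rep(TRUE, 19))
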