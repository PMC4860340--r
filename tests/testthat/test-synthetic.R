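test_that("side sequences alternate first and never triple-repeat", {
  expect_true(paste(gen_side_sequence(2, seed = 1), collapse = "") %in%
                c("LR", "RL"))
  expect_error(gen_side_sequence(1), "n >= 2")

  # fixed seed: bit-identical
  expect_identical(gen_side_sequence(10, seed = 42),
                   gen_side_sequence(10, seed = 42))

  set.seed(37)
  for (i in 1:500) {
    s <- gen_side_sequence(sample(2:60, 1))
    expect_true(s[1] != s[2])
    runs <- rle(s)$lengths
    expect_lte(max(runs), 2)
  }
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  gen_side_sequence(20, seed = 5)
  simulate_agent(agent_params("epsilon_decreasing"), seed = 5)
  simulate_water_tube(seed = 5)
  expect_identical(.Random.seed, before)
})

test_that("agent simulation honors the epsilon schedules", {
  expect_error(agent_params(decay_rate = 1.5), "strictly in")
  expect_error(simulate_agent(agent_params(), n_max = 10), "n_max >= 20")

  # epsilon-first with room for both options errs at most in the prefix
  # and the resulting sequence is labeled epsilon_first
  for (seed in 1:20) {
    s <- simulate_agent(agent_params("epsilon_first"), seed = seed)
    wrong <- which(!s$outcomes)
    expect_true(all(wrong <= 2))
    expect_equal(classify_strategy(s, allow_incomplete = TRUE)$label,
                 "epsilon_first")
    expect_identical(s$outcomes,
                     simulate_agent(agent_params("epsilon_first"),
                                    seed = seed)$outcomes)
  }

  # m = 1 with a wrong first pick mirrors the error-prefix pattern
  first_wrong <- NULL
  for (seed in 1:50) {
    s <- simulate_agent(agent_params("epsilon_first",
                                     exploration_trials = 1), seed = seed)
    if (!s$outcomes[1]) { first_wrong <- s; break }
  }
  expect_false(is.null(first_wrong))
  expect_true(all(first_wrong$outcomes[-1]))
  expect_equal(classify_strategy(first_wrong, allow_incomplete = TRUE)$label,
               "epsilon_first")

  # a floor of 1 keeps the agent at chance: criterion almost never met
  stuck <- simulate_agent(agent_params("epsilon_decreasing",
                                       epsilon_floor = 1), seed = 77)
  expect_false(evaluate_criterion(stuck)$passed)
  expect_equal(length(stuck), 200)

  # sequences truncate at the criterion evaluation point
  s <- simulate_agent(agent_params("epsilon_decreasing"), seed = 123)
  res <- evaluate_criterion(s)
  expect_true(res$passed)
  expect_equal(res$trials_to_criterion, length(s))
  expect_equal(length(s$side_sequence), length(s))
})

test_that("per-trial correctness tracks 1 - eps/2 for decreasing agents", {
  # Monte-Carlo over agents, compared to the analytic per-trial probability
  # (binomial standard errors); untruncated early trials only
  params <- agent_params("epsilon_decreasing", decay_rate = 0.3)
  n_agents <- 2000
  set.seed(55)
  first10 <- t(vapply(seq_len(n_agents), function(i) {
    simulate_agent(params, n_max = 20)$outcomes[1:10]
  }, logical(10)))
  eps_t <- pmax(0.02, 0.7^(0:9))
  expected <- 1 - eps_t / 2
  observed <- colMeans(first10)
  se <- sqrt(expected * (1 - expected) / n_agents)
  expect_true(all(abs(observed - expected) <= 3 * se + 1e-9))
})

test_that("water-tube simulation respects its parameters and structure", {
  expect_error(watertube_sim_params(pref_correct = 2), "\\[0, 1\\]")
  s <- simulate_water_tube(watertube_sim_params(pref_correct = 1,
                                                accident_rate = 0),
                           seed = 8)
  expect_true(all(s$events$option == "heavy"))
  expect_true(all(s$events$is_correct))
  expect_true(all(!s$events$is_accidental))
  expect_s3_class(choice_events(s$events), "choice_events")
  expect_equal(max(s$events$trial_index), 20)

  # success flag recounts functional insertions against the threshold
  set.seed(61)
  s2 <- simulate_water_tube(watertube_sim_params(pref_correct = 0.6,
                                                 success_threshold = 2),
                            seed = 9)
  for (t in unique(s2$events$trial_index)) {
    ev <- s2$events[s2$events$trial_index == t, ]
    expect_equal(unique(ev$trial_success),
                 sum(ev$option == "heavy") >= 2)
  }

  expect_identical(simulate_water_tube(seed = 14)$events,
                   simulate_water_tube(seed = 14)$events)
})

test_that("strategy-recovery harness tabulates generated vs assigned", {
  empty <- strategy_recovery(0)
  expect_equal(sum(empty), 0)
  expect_equal(dim(empty), c(2L, 3L))

  conf <- strategy_recovery(25, seed = 4)
  expect_equal(sum(conf), 50)
  expect_identical(conf, strategy_recovery(25, seed = 4))
  # epsilon-first agents exploit deterministically after the prefix
  expect_equal(unname(conf["epsilon_first", "epsilon_first"]), 25)
})
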