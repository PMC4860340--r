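test_that("reversal scores difference the two learning phases", {
  summaries <- grackle_data("color_summary")
  scores <- reversal_score(summaries)
  expect_equal(unname(scores["Tequila"]), 70L)
  expect_equal(unname(scores["Michelada"]), 30L)
  expect_true(is.na(scores["Batido"]))   # reversal incomplete

  same <- data.frame(bird_id = "b", sex = "F", exp1_trials = 30,
                     refresher_trials = 10, exp2_trials = 30)
  expect_equal(unname(reversal_score(same)), 0L)

  faster <- data.frame(bird_id = "b", sex = "F", exp1_trials = 40,
                       refresher_trials = 10, exp2_trials = 20)
  expect_warning(s <- reversal_score(faster), "negative")
  expect_equal(unname(s), -20L)

  bad <- data.frame(bird_id = "b", sex = "F", exp1_trials = 33,
                    refresher_trials = 10, exp2_trials = 40)
  expect_error(reversal_score(bad), "multiple of the block")
})

test_that("summary means cover all learners but only reversal completers", {
  m <- summary_means(grackle_data("color_summary"))
  expect_equal(round(m$exp1_mean), 31)
  expect_equal(round(m$exp2_mean), 91)
  one <- summary_means(data.frame(bird_id = "b", sex = "M",
                                  exp1_trials = 20, refresher_trials = 10,
                                  exp2_trials = 70))
  expect_equal(one$exp1_mean, 20)
  expect_equal(one$exp2_mean, 70)
})

test_that("preference labels require a Holm-significant majority", {
  # even split: p = 1, no label, whatever the family
  even <- simulate_water_tube(watertube_sim_params(pref_correct = 1,
                                                   accident_rate = 0,
                                                   choices_per_trial = 1),
                              seed = 1, experiment_id = "EXP4_MAGIC")
  # force an exact 16/16 split from the table interface instead
  tests <- preference_tests(data.frame(
    bird_id = "Horchata", experiment_id = "EXP4_MAGIC",
    n_functional = 16, n_other = 16))
  expect_equal(tests$p_raw, 1)
  expect_equal(tests$preferred, "none")

  # all choices one option, family of one: label sticks, adjusted = raw
  lab <- preference_label(even)
  expect_equal(lab$preferred, "light")
  expect_equal(lab$binomial$p_adjusted, lab$binomial$p_raw)
  expect_equal(lab$binomial$family_size, 1)

  # orientation invariance: relabeling which option is functional flips
  # the label but not the p-values
  splits <- data.frame(bird_id = c("a", "b"), experiment_id = "EXP3_HVL",
                       n_functional = c(33, 10), n_other = c(10, 33))
  flipped <- splits
  flipped[, c("n_functional", "n_other")] <- splits[, c("n_other", "n_functional")]
  t1 <- preference_tests(splits)
  t2 <- preference_tests(flipped)
  expect_equal(t1$p_raw, t2$p_raw)
  expect_equal(t1$p_adjusted, t2$p_adjusted)
  expect_equal(t1$preferred, c("heavy", "light"))
  expect_equal(t2$preferred, c("light", "heavy"))
})

test_that("published water-tube splits give the published labels", {
  tests <- preference_tests(grackle_data("water_splits"))
  hvl <- tests[tests$experiment_id == "EXP3_HVL", ]
  expect_equal(hvl$preferred[hvl$bird_id %in%
                               c("Tequila", "Margarita", "Batido", "Refresco")],
               rep("heavy", 4))
  expect_equal(hvl$preferred[hvl$bird_id %in% c("Cerveza", "Horchata")],
               rep("none", 2))
  magic <- tests[tests$experiment_id == "EXP4_MAGIC", ]
  expect_equal(round(magic$p_adjusted[magic$bird_id == "Tequila"], 2), 0.60)
  expect_equal(magic$preferred[magic$bird_id == "Margarita"], "heavy")
})

test_that("water flexibility moves only in the functional direction", {
  expect_equal(water_flexibility("heavy", "none"), "yes")
  expect_equal(water_flexibility("heavy", "light"), "yes")
  expect_equal(water_flexibility("none", "light"), "yes")
  expect_equal(water_flexibility("heavy", "heavy"), "no")
  expect_equal(water_flexibility("none", "heavy"), "no")
  expect_equal(water_flexibility("none", "heavy", confound = TRUE),
               "confounded")
  # staying put is never flexible, for every label
  for (l in c("heavy", "none", "light")) {
    expect_true(water_flexibility(l, l) %in% c("no", "confounded"))
  }
  # backward moves are inflexible for every ordered pair
  scale <- c("heavy", "none", "light")
  for (i in seq_along(scale)) {
    for (j in seq_along(scale)) {
      expected <- if (j > i) "yes" else "no"
      expect_equal(water_flexibility(scale[i], scale[j]), expected)
    }
  }
  expect_error(water_flexibility("heavy", "narrow"), "labels must be")
})

test_that("cross-context correlation codes water flexibility as binary", {
  records <- data.frame(
    bird_id = c("Tequila", "Margarita", "Cerveza", "Horchata", "Refresco"),
    color_flex_score = c(70, 70, 60, 100, 50),
    water_flex = c("yes", "confounded", "confounded", "no", "yes"))
  got <- cross_context(records)
  expect_equal(round(got$S, 2), 28.89)
  expect_equal(round(got$rho, 2), -0.44)
  expect_equal(got$n, 5)

  # agrees with the stats-module route on a synthetic 12-bird table
  set.seed(31)
  synth <- data.frame(
    bird_id = paste0("b", 1:12),
    color_flex_score = sample(seq(10, 120, by = 10)),
    water_flex = sample(c("yes", "no"), 12, replace = TRUE))
  if (length(unique(synth$water_flex)) > 1) {
    direct <- spearman_tied(as.numeric(synth$water_flex == "yes"),
                            synth$color_flex_score)
    got <- cross_context(synth)
    expect_equal(got$rho, direct$rho, tolerance = 1e-12)
  }

  records$water_flex <- "no"
  expect_error(cross_context(records), "constant ranks")
  expect_error(cross_context(records[1:2, ]), "at least 3")
})

test_that("first-choice tallies count trial-1 first choices per experiment", {
  sessions <- lapply(1:6, function(i) {
    simulate_water_tube(watertube_sim_params(pref_correct = 1,
                                             accident_rate = 0),
                        bird_id = paste0("b", i), seed = 100 + i)
  })
  tally <- first_choice_tally(sessions)
  expect_equal(unname(tally$EXP3_HVL$counts["heavy"]), 6L)
  expect_equal(unname(tally$EXP3_HVL$counts["light"]), 0L)
  expect_length(first_choice_tally(list()), 0)

  # manual recount on mixed sessions
  mixed <- lapply(1:5, function(i) {
    simulate_water_tube(watertube_sim_params(pref_correct = 0.5),
                        bird_id = paste0("m", i), seed = 200 + i)
  })
  tally <- first_choice_tally(mixed)
  manual <- table(factor(vapply(mixed, function(s) {
    s$events$option[s$events$trial_index == 1 & s$events$choice_index == 1]
  }, character(1)), levels = c("heavy", "light")))
  expect_equal(as.integer(tally$EXP3_HVL$counts), as.integer(manual))
})
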