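# All generators take an explicit integer seed and restore the caller's RNG
# state on exit, so a fixed seed gives bit-identical output and nothing
# leaks into the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Epsilon-schedule bandit-agent parameters
#'
#' Parameters for the two simulated learning strategies on the two-option
#' task. An *epsilon-first* agent explores uniformly at random for its
#' first `exploration_trials` trials and exploits (always picks the
#' rewarded option) afterwards. An *epsilon-decreasing* agent explores at
#' trial `t` with probability `eps_t = max(epsilon_floor,
#' (1 - decay_rate)^(t - 1))` — exploration decays geometrically from
#' complete uncertainty toward a small floor — and exploits otherwise.
#' Exploring means a uniform pick over both options, so the per-trial
#' probability of a correct choice is `1 - eps_t / 2`.
#'
#' The default decay rate (0.05) is chosen so that a decreasing agent's
#' errors extend well past any plausible exploration budget, making the
#' two generating strategies identifiable from their sequences (see the
#' package vignette for the identifiability argument); much faster decay
#' produces sequences indistinguishable from epsilon-first.
#'
#' @param strategy `"epsilon_first"` or `"epsilon_decreasing"`.
#' @param exploration_trials Length of the pure exploration prefix for
#'   epsilon-first agents (default 2 = one sample per option).
#' @param decay_rate Geometric decay rate of exploration per trial for
#'   epsilon-decreasing agents, in (0, 1) (default 0.05).
#' @param epsilon_floor Minimum exploration probability (default 0.02).
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(strategy = c("epsilon_first", "epsilon_decreasing"),
                         exploration_trials = 2, decay_rate = 0.05,
                         epsilon_floor = 0.02) {
  strategy <- match.arg(strategy)
  exploration_trials <- as.integer(exploration_trials)
  if (is.na(exploration_trials) || exploration_trials < 1) {
    stop("exploration_trials must be a positive integer", call. = FALSE)
  }
  if (!is.finite(decay_rate) || decay_rate <= 0 || decay_rate >= 1) {
    stop("decay_rate must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.finite(epsilon_floor) || epsilon_floor < 0 || epsilon_floor > 1) {
    stop("epsilon_floor must lie in [0, 1]", call. = FALSE)
  }
  structure(list(strategy = strategy,
                 exploration_trials = exploration_trials,
                 decay_rate = decay_rate, epsilon_floor = epsilon_floor),
            class = "agent_params")
}

#' Pseudorandomized side sequence
#'
#' Generates left/right placements of the rewarded option under the
#' protocol's pseudorandomization rule: the first two placements alternate,
#' and the same side never occurs on more than two consecutive trials.
#' Among the admissible continuations the draw is uniform.
#'
#' @param n Sequence length (at least 2).
#' @param seed Optional integer seed.
#' @return Character vector of `"L"`/`"R"` of length `n`.
#' @export
gen_side_sequence <- function(n, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("need n >= 2", call. = FALSE)
  with_seed(seed, {
    sides <- character(n)
    sides[1] <- sample(c("L", "R"), 1)
    sides[2] <- setdiff(c("L", "R"), sides[1])
    for (t in seq_len(n)[-(1:2)]) {
      if (sides[t - 1] == sides[t - 2]) {
        sides[t] <- setdiff(c("L", "R"), sides[t - 1])
      } else {
        sides[t] <- sample(c("L", "R"), 1)
      }
    }
    sides
  })
}

#' Simulate a bandit agent on an association experiment
#'
#' Plays an epsilon-schedule agent ([agent_params()]) against the
#' two-option task and returns its trial sequence, truncated — like the
#' study's stopping rule — at the first evaluation point where the
#' proficiency criterion of `spec` holds, or at `n_max` trials if it never
#' does. A pseudorandomized side sequence is attached.
#'
#' @param params An [agent_params()].
#' @param n_max Maximum trials to play (default 200, at least 20).
#' @param seed Optional integer seed.
#' @param spec [criterion_spec()] used for truncation.
#' @param bird_id,experiment_id Identifiers for the returned sequence.
#' @return A [trial_sequence()].
#' @export
simulate_agent <- function(params, n_max = 200, seed = NULL,
                           spec = criterion_spec(), bird_id = "agent",
                           experiment_id = "EXP1_COLOR") {
  stopifnot(inherits(params, "agent_params"))
  n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 20) stop("need n_max >= 20", call. = FALSE)
  spec <- as_criterion_spec(spec)
  with_seed(seed, {
    sides <- gen_side_sequence(n_max)
    # epsilon-first exploration samples each option once when it has room
    # (the "one trial per color" optimal exploration), then uniformly
    if (params$strategy == "epsilon_first") {
      m <- min(params$exploration_trials, n_max)
      explore_correct <- logical(m)
      if (m >= 2) {
        explore_correct[1:2] <- sample(c(TRUE, FALSE))
        if (m > 2) explore_correct[3:m] <- stats::runif(m - 2) < 0.5
      } else {
        explore_correct[1] <- stats::runif(1) < 0.5
      }
    }
    outcomes <- logical(n_max)
    stop_at <- n_max
    for (t in seq_len(n_max)) {
      if (params$strategy == "epsilon_first") {
        outcomes[t] <- if (t <= m) explore_correct[t] else TRUE
      } else {
        eps_t <- max(params$epsilon_floor,
                     (1 - params$decay_rate)^(t - 1))
        explore <- stats::runif(1) < eps_t
        outcomes[t] <- if (explore) stats::runif(1) < 0.5 else TRUE
      }
      if (t >= spec$window && (t - spec$window) %% spec$block == 0 &&
          criterion_holds_at(outcomes, t, spec)) {
        stop_at <- t
        break
      }
    }
    trial_sequence(outcomes[seq_len(stop_at)], bird_id = bird_id,
                   experiment_id = experiment_id,
                   side_sequence = sides[seq_len(stop_at)])
  })
}

#' Water-tube session simulation parameters
#'
#' Parameters for simulating a multi-choice water-tube session: each trial
#' draws a number of object insertions uniformly from
#' `choices_per_trial`; each insertion is the bird's preferred-class pick
#' (the functional option with probability `pref_correct`) unless it is an
#' accidental insertion (probability `accident_rate`), in which case the
#' option is uniform. A trial succeeds when the functional-option
#' insertions reach `success_threshold` (roughly the number of heavy-object
#' drops needed to lift the food within reach).
#'
#' @param pref_correct Probability each chosen insertion is the functional
#'   option (default 0.75, the strength of preference typical of birds
#'   labeled as preferring the functional object).
#' @param n_trials Trials per session (default 20, the design length).
#' @param choices_per_trial Integer vector of admissible insertion counts
#'   per trial (default `1:4`, objects available per trial).
#' @param accident_rate Probability an insertion is accidental
#'   (default 0.03).
#' @param success_threshold Functional insertions needed for trial success
#'   (default 2).
#' @return An object of class `watertube_sim_params`.
#' @export
watertube_sim_params <- function(pref_correct = 0.75, n_trials = 20,
                                 choices_per_trial = 1:4,
                                 accident_rate = 0.03,
                                 success_threshold = 2) {
  if (!is.finite(pref_correct) || pref_correct < 0 || pref_correct > 1) {
    stop("pref_correct must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(accident_rate) || accident_rate < 0 || accident_rate > 1) {
    stop("accident_rate must lie in [0, 1]", call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1) stop("need n_trials >= 1",
                                            call. = FALSE)
  choices_per_trial <- as.integer(choices_per_trial)
  if (length(choices_per_trial) < 1 || anyNA(choices_per_trial) ||
      any(choices_per_trial < 1)) {
    stop("choices_per_trial must be positive integers", call. = FALSE)
  }
  success_threshold <- as.integer(success_threshold)
  if (is.na(success_threshold) || success_threshold < 1) {
    stop("success_threshold must be a positive integer", call. = FALSE)
  }
  structure(list(pref_correct = pref_correct, n_trials = n_trials,
                 choices_per_trial = choices_per_trial,
                 accident_rate = accident_rate,
                 success_threshold = success_threshold),
            class = "watertube_sim_params")
}

#' Simulate a water-tube session
#'
#' @param params A [watertube_sim_params()].
#' @param bird_id,experiment_id Identifiers (a water-tube experiment).
#' @param seed Optional integer seed.
#' @return A [water_tube_session()] whose events validate against the
#'   choice-table invariants.
#' @export
simulate_water_tube <- function(params = watertube_sim_params(),
                                bird_id = "bird",
                                experiment_id = "EXP3_HVL", seed = NULL) {
  stopifnot(inherits(params, "watertube_sim_params"))
  func <- functional_option(experiment_id)
  other <- setdiff(option_domain(experiment_id), func)
  with_seed(seed, {
    rows <- vector("list", params$n_trials)
    for (t in seq_len(params$n_trials)) {
      n_choices <- if (length(params$choices_per_trial) == 1) {
        params$choices_per_trial
      } else {
        sample(params$choices_per_trial, 1)
      }
      accidental <- stats::runif(n_choices) < params$accident_rate
      option <- ifelse(accidental,
                       ifelse(stats::runif(n_choices) < 0.5, func, other),
                       ifelse(stats::runif(n_choices) < params$pref_correct,
                              func, other))
      success <- sum(option == func) >= params$success_threshold
      rows[[t]] <- data.frame(
        bird_id = bird_id, experiment_id = experiment_id,
        trial_index = t, choice_index = seq_len(n_choices),
        option = option, is_correct = option == func,
        is_accidental = accidental, trial_success = success,
        stringsAsFactors = FALSE)
    }
    water_tube_session(do.call(rbind, rows), n_trials = params$n_trials)
  })
}

#' Strategy-recovery harness
#'
#' Simulates `n_agents` agents of each strategy, classifies their sequences
#' with [classify_strategy()] at the given settings, and tabulates
#' generated against assigned labels — the validation that the classifier
#' recovers what the generator produced.
#'
#' @param n_agents Agents per strategy (0 gives an empty table).
#' @param params_first,params_decreasing [agent_params()] for the two
#'   strategies.
#' @param seed Optional integer seed.
#' @param exploration_budget,bin_width Passed to [classify_strategy()].
#' @param n_max,spec Passed to [simulate_agent()].
#' @return A contingency table, generated strategy in rows and assigned
#'   label in columns.
#' @export
strategy_recovery <- function(n_agents,
                              params_first = agent_params("epsilon_first"),
                              params_decreasing = agent_params("epsilon_decreasing"),
                              seed = NULL, exploration_budget = 4,
                              bin_width = 4, n_max = 200,
                              spec = criterion_spec()) {
  n_agents <- as.integer(n_agents)
  if (is.na(n_agents) || n_agents < 0) stop("need n_agents >= 0",
                                            call. = FALSE)
  labels <- c("epsilon_first", "epsilon_decreasing", "unclassified")
  generated <- character(0)
  assigned <- character(0)
  with_seed(seed, {
    for (params in list(params_first, params_decreasing)) {
      for (i in seq_len(n_agents)) {
        seq_i <- simulate_agent(params, n_max = n_max, spec = spec)
        lab <- classify_strategy(seq_i,
                                 exploration_budget = exploration_budget,
                                 bin_width = bin_width,
                                 allow_incomplete = TRUE, spec = spec)
        generated <- c(generated, params$strategy)
        assigned <- c(assigned, lab$label)
      }
    }
  })
  table(generated = factor(generated, levels = labels[1:2]),
        assigned = factor(assigned, levels = labels))
}
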