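#' Packaged grackle summary tables
#'
#' Small plain-text encodings of the published grackle summary tables that
#' the pipeline consumes: `"color_summary"` is the per-bird
#' trials-to-criterion table of the color-association experiments (initial
#' learning, refresher, reversal), and `"water_splits"` holds the per-bird
#' choice splits of the two heavy/light water-tube experiments as counts of
#' the functional option versus the other (the narrow/wide experiment's
#' splits were not published at choice level and are therefore absent).
#' For Batido's follow-up (magic) cell the published count is encoded as
#' the majority-option split, consistent with its published "heavy"
#' preference annotation; the cell's orientation is internally inconsistent
#' in the source table and the two-tailed p-value is unaffected either way.
#'
#' @param which `"color_summary"` or `"water_splits"`.
#' @return A data frame ([bird_summaries()] for the color summary).
#' @examples
#' grackle_data("color_summary")
#' @export
grackle_data <- function(which = c("color_summary", "water_splits")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("grackle_", which, ".csv"),
                      package = "banditflex", mustWork = TRUE)
  if (which == "color_summary") {
    read_bird_summaries(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Behavioral-flexibility analysis
#'
#' The central fitting/analysis function of the package. From per-bird
#' summary tables (and optionally trial-level choice records) it assembles
#' the full cross-context flexibility analysis:
#' \enumerate{
#'   \item per-bird reversal scores (`exp2 - exp1` trials) and the mean
#'     trials to criterion for initial learning and reversal;
#'   \item the tie-corrected Spearman correlation between learning speed
#'     and reversal score;
#'   \item exact binomial preference tests per water-tube experiment, Holm
#'     corrected within experiment, with preference labels;
#'   \item per-bird water-context flexibility calls (preference moved in
#'     the functional direction between the baseline and follow-up
#'     object experiments), honoring per-bird confound annotations;
#'   \item the cross-context Spearman correlation between water-context
#'     flexibility (yes = 1) and the reversal score;
#'   \item when trial-level `choices` are supplied: criterion results and
#'     learning-strategy labels per bird and association experiment;
#'   \item when full water-tube `sessions` are supplied: first-choice
#'     tallies on first trials.
#' }
#'
#' @param color_summary A [bird_summaries()] table (or path/data frame).
#' @param water_splits Choice-split table as in [preference_tests()]
#'   (columns `bird_id`, `experiment_id`, `n_functional`, `n_other`), or
#'   `NULL`.
#' @param choices Optional [choice_events()] table of association-trial
#'   records.
#' @param sessions Optional list of [water_tube_session()] objects (used
#'   for first-choice tallies and, when `water_splits` is `NULL`, to derive
#'   the splits).
#' @param confounded Character vector of bird ids whose follow-up
#'   water-tube behavior was confounded (e.g. magnet fixation).
#' @param baseline_exp,followup_exp The water-tube experiment pair that
#'   defines the flexibility call (defaults `"EXP3_HVL"`, `"EXP4_MAGIC"`).
#' @param spec A [criterion_spec()].
#' @param exploration_budget,bin_width Passed to [classify_strategy()].
#' @param alpha Significance level for preference labels.
#' @return An object of class `flex_analysis`; see Details.
#' @examples
#' fit <- flex_analysis(color_summary = grackle_data("color_summary"),
#'                      water_splits = grackle_data("water_splits"),
#'                      confounded = c("Margarita", "Cerveza"))
#' fit
#' @export
flex_analysis <- function(color_summary, water_splits = NULL,
                          choices = NULL, sessions = NULL,
                          confounded = character(),
                          baseline_exp = "EXP3_HVL",
                          followup_exp = "EXP4_MAGIC",
                          spec = criterion_spec(),
                          exploration_budget = 4, bin_width = 4,
                          alpha = 0.05) {
  if (is.character(color_summary) && length(color_summary) == 1) {
    color_summary <- read_bird_summaries(color_summary)
  }
  color_summary <- bird_summaries(color_summary)
  spec <- as_criterion_spec(spec)

  scores <- reversal_score(color_summary)
  means <- summary_means(color_summary)

  has_score <- !is.na(scores)
  spearman_color <- if (sum(has_score) >= 3) {
    spearman_tied(color_summary$exp1_trials[has_score], scores[has_score])
  } else NULL

  # water-tube preference tests
  if (is.null(water_splits) && !is.null(sessions)) {
    water_splits <- splits_from_sessions(sessions)
  }
  preferences <- if (!is.null(water_splits)) {
    preference_tests(water_splits, alpha = alpha)
  } else NULL

  # per-bird flexibility calls between the baseline and follow-up pair
  flexibility <- flexibility_table(color_summary, scores, preferences,
                                   confounded, baseline_exp, followup_exp)
  n_both <- sum(flexibility$water_flex != "absent" &
                  !is.na(flexibility$color_flex_score))
  # a degenerate table (every bird equally flexible) has no defined rho;
  # the fit then simply carries no cross-context correlation
  spearman_cross <- if (n_both >= 3) {
    tryCatch(cross_context(flexibility), error = function(e) {
      if (grepl("constant ranks", conditionMessage(e))) NULL else stop(e)
    })
  } else NULL

  # optional trial-level analyses
  sequences <- criterion <- strategies <- NULL
  if (!is.null(choices)) {
    choices <- choice_events(choices)
    assoc <- choices[vapply(choices$experiment_id, is_association,
                            logical(1)), , drop = FALSE]
    key <- paste(assoc$bird_id, assoc$experiment_id, sep = "\r")
    sequences <- lapply(unique(key), function(k) {
      to_trial_sequence(assoc[key == k, , drop = FALSE])
    })
    criterion <- do.call(rbind, lapply(sequences, function(s) {
      res <- evaluate_criterion(s, spec)
      data.frame(bird_id = s$bird_id, experiment_id = s$experiment_id,
                 n_trials = length(s), passed = res$passed,
                 trials_to_criterion = res$trials_to_criterion,
                 stringsAsFactors = FALSE)
    }))
    strategies <- do.call(rbind, lapply(sequences, function(s) {
      lab <- classify_strategy(s, exploration_budget = exploration_budget,
                               bin_width = bin_width,
                               allow_incomplete = TRUE, spec = spec)
      data.frame(bird_id = s$bird_id, experiment_id = s$experiment_id,
                 label = lab$label, exploration_end = lab$exploration_end,
                 bin_slope = lab$bin_slope,
                 anomalies = paste(lab$anomalies, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  }

  first_choices <- if (!is.null(sessions)) first_choice_tally(sessions) else NULL

  structure(
    list(summary_table = color_summary, reversal_scores = scores,
         means = means, spearman_color = spearman_color,
         preferences = preferences, flexibility = flexibility,
         spearman_cross = spearman_cross,
         criterion = criterion, strategies = strategies,
         sequences = sequences, first_choices = first_choices,
         settings = list(spec = spec, alpha = alpha,
                         exploration_budget = exploration_budget,
                         bin_width = bin_width,
                         baseline_exp = baseline_exp,
                         followup_exp = followup_exp,
                         confounded = confounded)),
    class = "flex_analysis"
  )
}

splits_from_sessions <- function(sessions, include_accidental = TRUE) {
  do.call(rbind, lapply(sessions, function(s) {
    k <- count_session_choices(s, include_accidental = include_accidental)
    data.frame(bird_id = s$bird_id, experiment_id = s$experiment_id,
               n_functional = k[1], n_other = k[2],
               stringsAsFactors = FALSE)
  }))
}

flexibility_table <- function(color_summary, scores, preferences,
                              confounded, baseline_exp, followup_exp) {
  flex <- data.frame(bird_id = color_summary$bird_id,
                     learning_speed = color_summary$exp1_trials,
                     color_flex_score = as.integer(scores),
                     water_flex = "absent", stringsAsFactors = FALSE)
  if (!is.null(preferences)) {
    base <- preferences[preferences$experiment_id == baseline_exp, ]
    follow <- preferences[preferences$experiment_id == followup_exp, ]
    extra <- setdiff(union(base$bird_id, follow$bird_id), flex$bird_id)
    if (length(extra) > 0) {
      flex <- rbind(flex, data.frame(bird_id = extra,
                                     learning_speed = NA_integer_,
                                     color_flex_score = NA_integer_,
                                     water_flex = "absent",
                                     stringsAsFactors = FALSE))
    }
    for (b in intersect(base$bird_id, follow$bird_id)) {
      flex$water_flex[flex$bird_id == b] <- water_flexibility(
        base$preferred[base$bird_id == b],
        follow$preferred[follow$bird_id == b],
        confound = b %in% confounded,
        initial_functional = functional_option(baseline_exp),
        newly_functional = functional_option(followup_exp))
    }
  }
  flex
}

#' @export
print.flex_analysis <- function(x, ...) {
  cat("Behavioral-flexibility analysis\n")
  cat(sprintf("  %d birds; mean trials to criterion: %.0f (learning), %.0f (reversal, completers)\n",
              nrow(x$summary_table), x$means$exp1_mean, x$means$exp2_mean))
  if (!is.null(x$spearman_color)) {
    cat("  Learning speed vs reversal score: ")
    print(x$spearman_color)
  }
  if (!is.null(x$spearman_cross)) {
    cat("  Flexibility across contexts:      ")
    print(x$spearman_cross)
  }
  cat("\nFlexibility summary:\n")
  print(x$flexibility, row.names = FALSE)
  invisible(x)
}

#' @export
summary.flex_analysis <- function(object, ...) {
  x <- object
  print(x)
  if (!is.null(x$preferences)) {
    cat("\nWater-tube preference tests (Holm within experiment):\n")
    pr <- x$preferences
    pr$p_raw <- format_p(pr$p_raw)
    pr$p_adjusted <- format_p(pr$p_adjusted)
    print(pr, row.names = FALSE)
  }
  if (!is.null(x$criterion)) {
    cat("\nCriterion results:\n")
    print(x$criterion, row.names = FALSE)
  }
  if (!is.null(x$strategies)) {
    cat("\nLearning strategies:\n")
    print(x$strategies, row.names = FALSE)
  }
  if (!is.null(x$first_choices)) {
    cat("\nFirst choices on first trials:\n")
    for (exp in names(x$first_choices)) {
      fc <- x$first_choices[[exp]]
      cat(" ", exp, ": ",
          paste(names(fc$counts), fc$counts, sep = ": ", collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Learning-curve plot
#'
#' Plots per-bird learning curves (proportion correct in non-overlapping
#' 4-trial bins against bin index) for the trial sequences carried by a
#' [flex_analysis()] fit, one panel per sequence.
#'
#' @param x A `flex_analysis` object fitted with `choices`.
#' @param bin_width Bin width in trials.
#' @param ... Passed on to [graphics::plot()].
#' @export
plot.flex_analysis <- function(x, bin_width = x$settings$bin_width, ...) {
  if (is.null(x$sequences) || length(x$sequences) == 0) {
    stop("no trial sequences to plot; fit with choices = ...", call. = FALSE)
  }
  n <- length(x$sequences)
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  old <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (s in x$sequences) {
    series <- bin_proportions(s, bin_width)
    graphics::plot(seq_len(series$n_bins), series$proportions, type = "b",
                   pch = 16, ylim = c(0, 1),
                   xlab = sprintf("%d-trial bin", bin_width),
                   ylab = "proportion correct",
                   main = paste(s$bird_id, s$experiment_id), ...)
    graphics::abline(h = 0.5, lty = 3)
  }
  invisible(x)
}

#' Write a machine-readable report bundle
#'
#' Writes the tables and statistics of a [flex_analysis()] fit to a
#' directory: CSV replicas of the criterion/strategy, preference, and
#' flexibility tables plus a single JSON file with every statistic at full
#' precision. Output is deterministic — re-running on the same fit
#' produces byte-identical files.
#'
#' @param fit A `flex_analysis` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_flex_report <- function(fit, dir) {
  stopifnot(inherits(fit, "flex_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  write_one <- function(df, name) {
    p <- file.path(dir, name)
    con <- file(p, open = "wb")
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
    p
  }
  paths <- c(paths, write_one(fit$flexibility, "flexibility_summary.csv"))
  if (!is.null(fit$preferences)) {
    paths <- c(paths, write_one(fit$preferences, "preference_tests.csv"))
  }
  if (!is.null(fit$criterion)) {
    paths <- c(paths, write_one(fit$criterion, "criterion_results.csv"))
  }
  if (!is.null(fit$strategies)) {
    paths <- c(paths, write_one(fit$strategies, "strategy_labels.csv"))
  }
  sp <- function(s) if (is.null(s)) NULL else {
    list(S = s$S, rho = s$rho, n = s$n, p = s$p_approx,
         tie_corrected = s$tie_corrected)
  }
  stats_list <- list(
    means = fit$means,
    reversal_scores = as.list(fit$reversal_scores),
    spearman_color = sp(fit$spearman_color),
    spearman_cross = sp(fit$spearman_cross),
    settings = list(alpha = fit$settings$alpha,
                    exploration_budget = fit$settings$exploration_budget,
                    bin_width = fit$settings$bin_width,
                    confounded = fit$settings$confounded,
                    criterion = unclass(fit$settings$spec))
  )
  json_path <- file.path(dir, "statistics.json")
  writeLines(jsonlite::toJSON(stats_list, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             con = json_path, useBytes = TRUE)
  paths <- c(paths, json_path)
  invisible(paths)
}
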