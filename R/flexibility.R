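#' Per-bird summary tables for the color-association experiments
#'
#' A bird-summary table holds one row per bird with its trials-to-criterion
#' counts: initial learning (`exp1_trials`), the memory-check/refresher
#' before reversal (`refresher_trials`), and reversal learning
#' (`exp2_trials`, `NA` with `exp2_status = "incomplete"` for birds that
#' stopped participating). Because the criterion is evaluated at completed
#' block boundaries, all counts must be positive multiples of the block
#' length.
#'
#' @param summaries Data frame with columns `bird_id`, `sex` (`"M"`/`"F"`),
#'   `exp1_trials`, `refresher_trials`, `exp2_trials` (integers or `NA`),
#'   and optionally `exp2_status` (`"complete"`/`"incomplete"`; defaults to
#'   complete wherever `exp2_trials` is present).
#' @param block Evaluation-block length the counts must respect (default 10).
#' @return The validated data frame with class
#'   `c("bird_summaries", "data.frame")`.
#' @export
bird_summaries <- function(summaries, block = 10) {
  summaries <- as.data.frame(summaries, stringsAsFactors = FALSE)
  required <- c("bird_id", "sex", "exp1_trials", "refresher_trials",
                "exp2_trials")
  missing_cols <- setdiff(required, names(summaries))
  if (length(missing_cols) > 0) {
    stop("summary table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  summaries$bird_id <- as.character(summaries$bird_id)
  summaries$sex <- as.character(summaries$sex)
  if (!all(summaries$sex %in% c("M", "F"))) {
    stop("sex must be 'M' or 'F'", call. = FALSE)
  }
  for (col in c("exp1_trials", "refresher_trials", "exp2_trials")) {
    v <- suppressWarnings(as.integer(summaries[[col]]))
    bad <- which(!is.na(v) & (v < 1 | v %% block != 0))
    if (length(bad) > 0) {
      stop(col, " must be a positive multiple of the block length (",
           block, "); violated for ",
           paste(summaries$bird_id[bad], collapse = ", "), call. = FALSE)
    }
    summaries[[col]] <- v
  }
  if (is.null(summaries$exp2_status)) {
    summaries$exp2_status <- ifelse(is.na(summaries$exp2_trials),
                                    "incomplete", "complete")
  }
  summaries$exp2_status[summaries$exp2_status == ""] <- NA_character_
  summaries$exp2_status[is.na(summaries$exp2_status)] <-
    ifelse(is.na(summaries$exp2_trials[is.na(summaries$exp2_status)]),
           "incomplete", "complete")
  class(summaries) <- c("bird_summaries", "data.frame")
  summaries
}

#' @rdname bird_summaries
#' @param path CSV file with the columns above ("incomplete" encoded as an
#'   empty `exp2_trials` cell plus the status column).
#' @export
read_bird_summaries <- function(path, block = 10) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bird_summaries(utils::read.csv(path, stringsAsFactors = FALSE),
                 block = block)
}

#' Reversal-learning flexibility score
#'
#' The color-context flexibility score of a bird is the number of trials it
#' needed to reverse the learned preference minus the number it needed to
#' learn it initially (`exp2_trials - exp1_trials`); fewer extra trials
#' mean greater flexibility. The score is missing for birds that did not
#' complete reversal. A negative score (reversing faster than learning) is
#' possible in principle and flagged with a warning.
#'
#' @param summaries A [bird_summaries()] table (or a data frame coercible
#'   to one).
#' @return Integer vector of scores, named by `bird_id`, `NA` where
#'   undefined.
#' @examples
#' reversal_score(data.frame(bird_id = "b", sex = "M", exp1_trials = 30,
#'                           refresher_trials = 30, exp2_trials = 100))
#' @export
reversal_score <- function(summaries) {
  summaries <- bird_summaries(summaries)
  score <- summaries$exp2_trials - summaries$exp1_trials
  score[summaries$exp2_status != "complete"] <- NA_integer_
  if (any(!is.na(score) & score < 0)) {
    warning("negative reversal score for ",
            paste(summaries$bird_id[!is.na(score) & score < 0],
                  collapse = ", "),
            " (reversed faster than initial learning)", call. = FALSE)
  }
  stats::setNames(score, summaries$bird_id)
}

#' Mean trials to criterion
#'
#' Arithmetic means of the initial-learning trial counts (all birds with a
#' value) and the reversal trial counts (completers only). Rounding to
#' whole trials is left to the report layer.
#'
#' @inheritParams reversal_score
#' @return List with `exp1_mean` and `exp2_mean`.
#' @export
summary_means <- function(summaries) {
  summaries <- bird_summaries(summaries)
  if (nrow(summaries) < 1) stop("need at least one bird", call. = FALSE)
  completers <- summaries$exp2_status == "complete"
  list(exp1_mean = mean(summaries$exp1_trials, na.rm = TRUE),
       exp2_mean = mean(summaries$exp2_trials[completers], na.rm = TRUE))
}

# ---- water-tube preference tests -------------------------------------------

count_session_choices <- function(session, include_accidental = TRUE) {
  ev <- session$events
  if (!include_accidental) ev <- ev[!ev$is_accidental, , drop = FALSE]
  dom <- option_domain(session$experiment_id)
  counts <- table(factor(ev$option, levels = dom))
  as.integer(counts)
}

#' Object/tube preference of a water-tube session
#'
#' Counts choices per option over a whole session (accidental insertions
#' included by default — a falling object teaches the bird about the task
#' whether or not it was chosen), tests the split against chance with an
#' exact two-tailed binomial, Holm-adjusts the p-value within the family of
#' all birds given the same experiment, and labels the majority option as
#' preferred when the adjusted p-value is below `alpha`; otherwise the
#' preference is `"none"`.
#'
#' @param session A [water_tube_session()].
#' @param family List of sessions defining the Holm family (all birds of
#'   the same experiment). Must contain `session` itself; defaults to the
#'   degenerate family of just `session`.
#' @param alpha Significance level for labeling (default 0.05).
#' @param include_accidental Count accidental insertions (default `TRUE`).
#' @return An object of class `preference_label`: list with
#'   `experiment_id`, `bird_id`, `preferred` (an option token or
#'   `"none"`), and `binomial` (the family-adjusted [binom_two_tailed()]
#'   result).
#' @export
preference_label <- function(session, family = list(session), alpha = 0.05,
                             include_accidental = TRUE) {
  stopifnot(inherits(session, "water_tube_session"))
  if (!any(vapply(family, identical, logical(1), session))) {
    family <- c(list(session), family)
  }
  exp_ids <- vapply(family, function(s) s$experiment_id, character(1))
  if (length(unique(exp_ids)) != 1) {
    stop("a Holm family must come from a single experiment", call. = FALSE)
  }
  counts <- lapply(family, count_session_choices,
                   include_accidental = include_accidental)
  if (any(vapply(counts, sum, integer(1)) == 0)) {
    stop("a session in the family has zero countable choices", call. = FALSE)
  }
  tests <- lapply(counts, function(k) binom_two_tailed(k[1], sum(k)))
  tests <- holm_adjust_results(tests)
  i <- which(vapply(family, identical, logical(1), session))[1]
  dom <- option_domain(session$experiment_id)
  k <- counts[[i]]
  preferred <- if (tests[[i]]$p_adjusted < alpha && k[1] != k[2]) {
    dom[which.max(k)]
  } else {
    "none"
  }
  structure(
    list(experiment_id = session$experiment_id, bird_id = session$bird_id,
         preferred = preferred, binomial = tests[[i]]),
    class = "preference_label"
  )
}

#' @export
print.preference_label <- function(x, ...) {
  cat(sprintf("Preference (%s, %s): %s\n", x$bird_id, x$experiment_id,
              x$preferred))
  print(x$binomial)
  invisible(x)
}

#' Preference tests from per-bird choice splits
#'
#' The count-level interface to the same test: one row per bird with the
#' number of choices of the experiment's functional option and of the other
#' option, as summary tables print them. All rows of one experiment form
#' one Holm family.
#'
#' @param splits Data frame with columns `bird_id`, `experiment_id`,
#'   `n_functional`, `n_other`.
#' @param alpha Significance level for the preference label.
#' @return Data frame with one row per input row and columns `bird_id`,
#'   `experiment_id`, `n_functional`, `n_total`, `p_raw`, `p_adjusted`, and
#'   `preferred` (majority option when significant, else `"none"`).
#' @export
preference_tests <- function(splits, alpha = 0.05) {
  splits <- as.data.frame(splits, stringsAsFactors = FALSE)
  required <- c("bird_id", "experiment_id", "n_functional", "n_other")
  missing_cols <- setdiff(required, names(splits))
  if (length(missing_cols) > 0) {
    stop("splits table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(splits, splits$experiment_id),
                               function(fam) {
    n_total <- fam$n_functional + fam$n_other
    tests <- holm_adjust_results(
      mapply(binom_two_tailed, fam$n_functional, n_total, SIMPLIFY = FALSE))
    preferred <- character(nrow(fam))
    for (i in seq_len(nrow(fam))) {
      dom <- option_domain(fam$experiment_id[i])
      func <- functional_option(fam$experiment_id[i])
      other <- setdiff(dom, func)
      preferred[i] <-
        if (tests[[i]]$p_adjusted < alpha &&
            fam$n_functional[i] != fam$n_other[i]) {
          if (fam$n_functional[i] > fam$n_other[i]) func else other
        } else "none"
    }
    data.frame(bird_id = fam$bird_id, experiment_id = fam$experiment_id,
               n_functional = fam$n_functional, n_total = n_total,
               p_raw = vapply(tests, function(t) t$p_raw, numeric(1)),
               p_adjusted = vapply(tests, function(t) t$p_adjusted,
                                   numeric(1)),
               preferred = preferred, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Flexibility in the water-tube context
#'
#' A bird counts as flexible when its preference moved in the *functional
#' direction* between the baseline experiment (where the initially
#' functional option — e.g. heavy objects — is favored) and the follow-up
#' (where the other option becomes the functional one): initial-functional
#' to none, initial-functional to newly-functional, or none to
#' newly-functional. Any other transition (including keeping the same
#' preference or moving back toward the old option) is inflexible. A
#' per-bird confound annotation (e.g. fixation on the magnet that disabled
#' the heavy objects) overrides the call with `"confounded"`.
#'
#' @param label3,label4 [preference_label()] objects — or bare option
#'   tokens/`"none"` — from the baseline and follow-up experiments.
#' @param confound Logical annotation supplied per bird (default `FALSE`).
#' @param initial_functional,newly_functional Option tokens defining the
#'   functional direction; inferred from the labels' experiments when
#'   `preference_label` objects are supplied, defaulting to the heavy/light
#'   pair otherwise.
#' @return `"yes"`, `"no"`, or `"confounded"`.
#' @examples
#' water_flexibility("heavy", "none")    # yes
#' water_flexibility("heavy", "heavy")   # no
#' @export
water_flexibility <- function(label3, label4, confound = FALSE,
                              initial_functional = NULL,
                              newly_functional = NULL) {
  pref <- function(l) if (inherits(l, "preference_label")) l$preferred else as.character(l)
  if (inherits(label3, "preference_label") && is.null(initial_functional)) {
    initial_functional <- functional_option(label3$experiment_id)
  }
  if (inherits(label4, "preference_label") && is.null(newly_functional)) {
    newly_functional <- functional_option(label4$experiment_id)
  }
  if (is.null(initial_functional)) initial_functional <- "heavy"
  if (is.null(newly_functional)) newly_functional <- "light"
  scale <- c(initial_functional, "none", newly_functional)
  p3 <- match(pref(label3), scale)
  p4 <- match(pref(label4), scale)
  if (is.na(p3) || is.na(p4)) {
    stop("preference labels must be one of ",
         paste(scale, collapse = "/"), call. = FALSE)
  }
  if (isTRUE(confound)) return("confounded")
  if (p4 > p3) "yes" else "no"
}

#' Cross-context flexibility correlation
#'
#' Tie-corrected Spearman correlation between flexibility in the water-tube
#' context (binary: `yes` = 1, everything else 0 — confounded birds are
#' retained and coded 0 to keep the sample size up) and the color-context
#' reversal score. Birds lacking either measure (`water_flex = "absent"` or
#' a missing score) are dropped.
#'
#' @param records Data frame with columns `bird_id`, `color_flex_score`
#'   (integer or `NA`), and `water_flex`
#'   (`"yes"`/`"no"`/`"confounded"`/`"absent"`).
#' @return A [spearman_tied()] result.
#' @export
cross_context <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("bird_id", "color_flex_score", "water_flex")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("records table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ok_levels <- c("yes", "no", "confounded", "absent")
  if (!all(records$water_flex %in% ok_levels)) {
    stop("water_flex must be one of ", paste(ok_levels, collapse = "/"),
         call. = FALSE)
  }
  keep <- records$water_flex != "absent" & !is.na(records$color_flex_score)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) < 3) {
    stop("need at least 3 birds with both measures", call. = FALSE)
  }
  coded <- as.numeric(records$water_flex == "yes")
  spearman_tied(coded, records$color_flex_score)
}

#' First choices on first trials
#'
#' Tallies, per experiment, which option each bird chose first in its first
#' trial — an indicator of initial biases or inferences brought to the task
#' before any trial-and-error learning.
#'
#' @param sessions List of [water_tube_session()] objects.
#' @return List with one entry per experiment: a list holding `counts`
#'   (named integer vector over the option domain) and `missing` (birds
#'   without trial-1 data). An empty input gives an empty list.
#' @export
first_choice_tally <- function(sessions) {
  stopifnot(all(vapply(sessions, inherits, logical(1), "water_tube_session")))
  exp_ids <- vapply(sessions, function(s) s$experiment_id, character(1))
  out <- list()
  for (exp in unique(exp_ids)) {
    dom <- option_domain(exp)
    counts <- stats::setNames(integer(length(dom)), dom)
    missing <- character(0)
    for (s in sessions[exp_ids == exp]) {
      first <- s$events[s$events$trial_index == 1 & s$events$choice_index == 1, ]
      if (nrow(first) == 0) {
        missing <- c(missing, s$bird_id)
      } else {
        counts[first$option[1]] <- counts[first$option[1]] + 1L
      }
    }
    out[[exp]] <- list(counts = counts, missing = missing)
  }
  out
}
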