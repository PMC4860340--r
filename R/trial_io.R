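#' Choice-event tables
#'
#' A choice-event table is an ordinary data frame with one row per choice,
#' ordered by bird, trial, and choice within trial. It is the common input
#' format for both task families: color-association trials carry exactly one
#' choice per trial; water-tube trials may carry several (objects inserted
#' one after the other), plus flags for accidental insertions and for
#' whether the trial ended in success (food obtained).
#'
#' Required columns:
#' \describe{
#'   \item{bird_id}{character label}
#'   \item{experiment_id}{one of [flex_experiments()]`$experiment_id`}
#'   \item{trial_index}{1-based trial number, non-decreasing within bird}
#'   \item{choice_index}{1-based choice number within trial, consecutive}
#'   \item{option}{token from the experiment's option domain}
#'   \item{is_correct}{logical; chose the currently functional option}
#'   \item{is_accidental}{logical; object entered the tube accidentally}
#'   \item{trial_success}{logical; food obtained by the end of the trial}
#' }
#'
#' @param events A data frame with the columns above.
#' @return `choice_events()` returns the validated data frame with class
#'   `c("choice_events", "data.frame")`.
#' @seealso [read_choices()], [write_choices()], [to_trial_sequence()]
#' @export
choice_events <- function(events) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  required <- c("bird_id", "experiment_id", "trial_index", "choice_index",
                "option", "is_correct", "is_accidental", "trial_success")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    stop("choice table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  events <- events[, required]
  events$bird_id <- as.character(events$bird_id)
  events$experiment_id <- as.character(events$experiment_id)
  events$trial_index <- as.integer(events$trial_index)
  events$choice_index <- as.integer(events$choice_index)
  events$option <- as.character(events$option)
  for (col in c("is_correct", "is_accidental", "trial_success")) {
    events[[col]] <- parse_logical(events[[col]], col)
  }

  bad_exp <- !events$experiment_id %in% experiment_ids()
  if (any(bad_exp)) {
    stop("unknown experiment_id at row(s) ",
         paste(utils::head(which(bad_exp), 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(events$trial_index < 1) || any(events$choice_index < 1)) {
    bad <- which(events$trial_index < 1 | events$choice_index < 1)
    stop("trial_index and choice_index must be >= 1; see row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  # per-row option domain check
  for (exp in unique(events$experiment_id)) {
    dom <- option_domain(exp)
    rows <- which(events$experiment_id == exp)
    bad <- rows[!events$option[rows] %in% dom]
    if (length(bad) > 0) {
      stop("option token outside the domain {",
           paste(dom, collapse = ", "), "} for ", exp, " at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }

  # ordering within bird x experiment: trials non-decreasing, choices
  # consecutive from 1 within each trial
  key <- paste(events$bird_id, events$experiment_id, sep = "\r")
  for (k in unique(key)) {
    rows <- which(key == k)
    ti <- events$trial_index[rows]
    if (any(diff(ti) < 0)) {
      r <- rows[which(diff(ti) < 0)[1] + 1]
      stop("trial_index decreases at row ", r, call. = FALSE)
    }
    for (t in unique(ti)) {
      trows <- rows[ti == t]
      ci <- events$choice_index[trows]
      if (!identical(ci, seq_along(ci))) {
        stop("choice_index must run 1, 2, ... within a trial; violated at row ",
             trows[which(ci != seq_along(ci))[1]], call. = FALSE)
      }
    }
    if (is_association(events$experiment_id[rows[1]])) {
      n_choices <- table(ti)
      if (any(n_choices > 1)) {
        t_bad <- names(n_choices)[n_choices > 1][1]
        stop("association experiments allow one choice per trial; trial ",
             t_bad, " of ", k, " has more", call. = FALSE)
      }
    }
  }

  class(events) <- c("choice_events", "data.frame")
  events
}

parse_logical <- function(x, col) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1")] <- TRUE
  out[x %in% c("false", "f", "0")] <- FALSE
  if (anyNA(out)) {
    stop("column ", col, " is not interpretable as logical at row(s) ",
         paste(utils::head(which(is.na(out)), 5), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Read and write choice-event CSV files
#'
#' `read_choices()` reads a choice CSV (columns as in [choice_events()],
#' logicals written as `true`/`false`) and validates it; `write_choices()`
#' writes one with a stable column order so that repeated writes of the same
#' table are byte-identical and `read_choices(write_choices(x))` returns `x`.
#'
#' @param path Path to a CSV file.
#' @param experiment_id Optional: restrict/validate to a single experiment.
#' @return `read_choices()` returns a [choice_events()] table.
#' @export
read_choices <- function(path, experiment_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  events <- choice_events(raw)
  if (!is.null(experiment_id)) {
    bad <- which(events$experiment_id != experiment_id)
    if (length(bad) > 0) {
      stop("expected experiment ", experiment_id, " but found ",
           events$experiment_id[bad[1]], " at row ", bad[1], call. = FALSE)
    }
  }
  events
}

#' @rdname read_choices
#' @param events A [choice_events()] table (or data frame coercible to one).
#' @return `write_choices()` invisibly returns `path`.
#' @export
write_choices <- function(events, path) {
  if (nrow(as.data.frame(events)) > 0) {
    events <- choice_events(events)
  } else {
    events <- empty_choice_events()
  }
  out <- as.data.frame(events)
  for (col in c("is_correct", "is_accidental", "trial_success")) {
    out[[col]] <- ifelse(out[[col]], "true", "false")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

empty_choice_events <- function() {
  ev <- data.frame(
    bird_id = character(0), experiment_id = character(0),
    trial_index = integer(0), choice_index = integer(0),
    option = character(0), is_correct = logical(0),
    is_accidental = logical(0), trial_success = logical(0),
    stringsAsFactors = FALSE
  )
  class(ev) <- c("choice_events", "data.frame")
  ev
}

#' Trial sequences for association experiments
#'
#' A trial sequence is the per-trial correct/incorrect record of one bird in
#' one color-association experiment (one choice per trial). It is the input
#' to the proficiency criterion and the learning-strategy classifier.
#'
#' @param outcomes Logical vector, `TRUE` for a correct trial.
#' @param bird_id,experiment_id Identifiers (experiment must be an
#'   association experiment).
#' @param rewarded_option Option token rewarded throughout the sequence;
#'   defaults to the experiment's functional option.
#' @param side_sequence Optional character vector of `"L"`/`"R"` placements
#'   of the rewarded option, same length as `outcomes`.
#' @return An object of class `trial_sequence`.
#' @export
trial_sequence <- function(outcomes, bird_id = "bird",
                           experiment_id = "EXP1_COLOR",
                           rewarded_option = NULL, side_sequence = NULL) {
  outcomes <- as.logical(outcomes)
  if (length(outcomes) < 1 || anyNA(outcomes)) {
    stop("outcomes must be a non-empty logical vector without NA",
         call. = FALSE)
  }
  if (!is_association(experiment_id)) {
    stop(experiment_id, " is not an association experiment", call. = FALSE)
  }
  if (is.null(rewarded_option)) rewarded_option <- functional_option(experiment_id)
  if (!rewarded_option %in% option_domain(experiment_id)) {
    stop("rewarded_option must be one of ",
         paste(option_domain(experiment_id), collapse = "/"), call. = FALSE)
  }
  if (!is.null(side_sequence)) {
    side_sequence <- as.character(side_sequence)
    if (length(side_sequence) != length(outcomes)) {
      stop("side_sequence must match outcomes in length", call. = FALSE)
    }
    if (!all(side_sequence %in% c("L", "R"))) {
      stop("side_sequence entries must be 'L' or 'R'", call. = FALSE)
    }
  }
  structure(
    list(bird_id = as.character(bird_id),
         experiment_id = experiment_id,
         outcomes = outcomes,
         rewarded_option = rewarded_option,
         side_sequence = side_sequence),
    class = "trial_sequence"
  )
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat("Trial sequence:", x$bird_id, "/", x$experiment_id, "\n")
  cat(sprintf("  %d trials, %d correct (%.2f)\n", length(x$outcomes),
              sum(x$outcomes), mean(x$outcomes)))
  cat("  ", paste(ifelse(x$outcomes, "+", "-"), collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
length.trial_sequence <- function(x) length(x$outcomes)

#' Convert single-choice events to a trial sequence
#'
#' @param events A [choice_events()] table containing one bird and one
#'   association experiment, with exactly one choice per trial.
#' @return A [trial_sequence()] whose `outcomes[t]` is the `is_correct` flag
#'   of trial `t`'s single choice.
#' @export
to_trial_sequence <- function(events) {
  events <- choice_events(events)
  if (nrow(events) == 0) stop("no events", call. = FALSE)
  if (length(unique(events$bird_id)) != 1 ||
      length(unique(events$experiment_id)) != 1) {
    stop("events must cover exactly one bird and one experiment",
         call. = FALSE)
  }
  exp <- events$experiment_id[1]
  if (!is_association(exp)) {
    stop(exp, " is not an association experiment; ",
         "use water_tube_session() instead", call. = FALSE)
  }
  # choice_events() already guarantees one choice per trial here
  events <- events[order(events$trial_index), ]
  trial_sequence(events$is_correct, bird_id = events$bird_id[1],
                 experiment_id = exp)
}

#' Water-tube sessions
#'
#' A water-tube session wraps the multi-choice-per-trial events of one bird
#' in one object/tube experiment (design target: 20 trials, 1 or more
#' choices each, occasional accidental insertions, a success flag per
#' trial).
#'
#' @param events A [choice_events()] table for one bird and one water-tube
#'   experiment.
#' @param n_trials Design number of trials (default 20). Events must not
#'   refer to trials beyond it; fewer is allowed (refused trials are simply
#'   absent).
#' @return An object of class `water_tube_session`.
#' @export
water_tube_session <- function(events, n_trials = 20) {
  events <- choice_events(events)
  if (nrow(events) == 0) stop("no events", call. = FALSE)
  if (length(unique(events$bird_id)) != 1 ||
      length(unique(events$experiment_id)) != 1) {
    stop("events must cover exactly one bird and one experiment",
         call. = FALSE)
  }
  exp <- events$experiment_id[1]
  if (is_association(exp)) {
    stop(exp, " is an association experiment; use to_trial_sequence()",
         call. = FALSE)
  }
  if (any(events$trial_index > n_trials)) {
    stop("events refer to trials beyond n_trials = ", n_trials, call. = FALSE)
  }
  structure(
    list(bird_id = events$bird_id[1], experiment_id = exp,
         events = events, n_trials = as.integer(n_trials)),
    class = "water_tube_session"
  )
}

#' @export
print.water_tube_session <- function(x, ...) {
  counts <- table(factor(x$events$option, levels = option_domain(x$experiment_id)))
  cat("Water-tube session:", x$bird_id, "/", x$experiment_id, "\n")
  cat(sprintf("  %d trials attempted of %d, %d choices (%s)\n",
              length(unique(x$events$trial_index)), x$n_trials,
              nrow(x$events),
              paste(names(counts), counts, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Split a choice table into per-bird water-tube sessions
#'
#' @param events A [choice_events()] table (water-tube experiments only).
#' @param n_trials Design trial count passed to [water_tube_session()].
#' @return A list of [water_tube_session()] objects, one per
#'   bird-by-experiment combination, in order of first appearance.
#' @export
as_sessions <- function(events, n_trials = 20) {
  events <- choice_events(events)
  key <- paste(events$bird_id, events$experiment_id, sep = "\r")
  lapply(unique(key), function(k) {
    water_tube_session(events[key == k, ], n_trials = n_trials)
  })
}
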