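#' Learning curves as bin proportions
#'
#' Collapses a trial sequence into the proportion of correct choices within
#' consecutive, non-overlapping bins of `bin_width` trials (default 4, the
#' width used for grackle learning curves). A trailing partial bin is
#' dropped.
#'
#' @inheritParams evaluate_criterion
#' @param bin_width Trials per bin (default 4).
#' @return An object of class `bin_series`: list with `proportions` (one
#'   value per complete bin), `bin_width`, and `n_bins`.
#' @examples
#' bin_proportions(c(FALSE, rep(TRUE, 19)))  # 0.75 then a ceiling at 1
#' @export
bin_proportions <- function(seq, bin_width = 4) {
  outcomes <- sequence_outcomes(seq)
  bin_width <- as.integer(bin_width)
  if (is.na(bin_width) || bin_width < 1) {
    stop("bin_width must be a positive integer", call. = FALSE)
  }
  if (length(outcomes) < bin_width) {
    stop("need at least one full bin (", bin_width, " trials)", call. = FALSE)
  }
  n_bins <- length(outcomes) %/% bin_width
  idx <- rep(seq_len(n_bins), each = bin_width)
  props <- as.numeric(tapply(outcomes[seq_len(n_bins * bin_width)], idx, mean))
  structure(list(proportions = props, bin_width = bin_width, n_bins = n_bins),
            class = "bin_series")
}

#' @export
print.bin_series <- function(x, ...) {
  cat("Bin series (width ", x$bin_width, "): ",
      paste(format(x$proportions), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Least-squares slope of a bin series
#'
#' Ordinary least-squares slope of proportion correct against 1-based bin
#' index, in proportion per bin. Used as the operational reading of a
#' "linear" (gradually rising) learning curve; with so few bins no
#' significance test is attached — the sign alone is used downstream.
#'
#' @param series A [bin_series()] or plain numeric vector of proportions.
#' @return A single number.
#' @export
ols_slope <- function(series) {
  y <- if (inherits(series, "bin_series")) series$proportions else as.numeric(series)
  if (length(y) < 2) stop("need at least 2 bins for a slope", call. = FALSE)
  x <- seq_along(y)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Classify the learning strategy of a trial sequence
#'
#' Assigns one of the two approximate solutions of the contextual binary
#' bandit, or neither:
#' \describe{
#'   \item{epsilon_first}{every incorrect trial falls within the first
#'     `exploration_budget` trials (default 4 = two samples per option) and
#'     none occurs afterwards — a pure exploration prefix followed by pure
#'     exploitation. A sequence with no errors at all also satisfies this.}
#'   \item{epsilon_decreasing}{otherwise, if the least-squares slope of the
#'     4-trial-bin learning curve is positive — exploration tapering off
#'     gradually.}
#'   \item{unclassified}{otherwise (flat or falling curve).}
#' }
#'
#' Two diagnostic anomaly flags are recorded but never change the label:
#' `late_dip` when some bin at or below 0.5 follows two consecutive bins at
#' or above 0.75 (a second exploration phase late in learning), and
#' `irregular_start` when the first half of the curve contains a drop of
#' two or more bin steps (a non-monotone early phase that the bandit
#' framework does not classify).
#'
#' @inheritParams bin_proportions
#' @param exploration_budget Trials allowed to the pure exploration prefix
#'   (default 4).
#' @param allow_incomplete If `FALSE` (default), the sequence must have
#'   reached the proficiency criterion of `spec`; set `TRUE` to classify
#'   unfinished sequences.
#' @param spec [criterion_spec()] used for the completeness check.
#' @return An object of class `strategy_label`: list with `label`,
#'   `exploration_end` (last incorrect trial, 0 if none), `bin_slope`, and
#'   `anomalies` (character vector).
#' @examples
#' classify_strategy(c(FALSE, rep(TRUE, 19)))   # epsilon_first
#' @export
classify_strategy <- function(seq, exploration_budget = 4, bin_width = 4,
                              allow_incomplete = FALSE,
                              spec = criterion_spec()) {
  outcomes <- sequence_outcomes(seq)
  if (!allow_incomplete && !evaluate_criterion(outcomes, spec)$passed) {
    stop("sequence has not reached criterion; set allow_incomplete = TRUE ",
         "to classify it anyway", call. = FALSE)
  }
  series <- bin_proportions(outcomes, bin_width)
  if (series$n_bins < 2) {
    stop("need at least 2 complete bins to classify", call. = FALSE)
  }
  slope <- ols_slope(series)
  wrong <- which(!outcomes)
  exploration_end <- if (length(wrong) == 0) 0L else max(wrong)

  label <- if (exploration_end <= exploration_budget) {
    "epsilon_first"
  } else if (slope > 0) {
    "epsilon_decreasing"
  } else {
    "unclassified"
  }

  anomalies <- character(0)
  p <- series$proportions
  high <- p >= 0.75
  for (i in seq_along(p)) {
    if (i >= 3 && p[i] <= 0.5 && high[i - 1] && high[i - 2]) {
      anomalies <- c(anomalies, "late_dip")
      break
    }
  }
  first_half <- p[seq_len(ceiling(length(p) / 2))]
  step <- 1 / bin_width
  if (length(first_half) >= 2 &&
      any(diff(first_half) <= -2 * step + 1e-12)) {
    anomalies <- c(anomalies, "irregular_start")
  }

  structure(
    list(label = label, exploration_end = as.integer(exploration_end),
         bin_slope = slope, anomalies = anomalies),
    class = "strategy_label"
  )
}

#' @export
print.strategy_label <- function(x, ...) {
  cat("Strategy:", x$label, "\n")
  cat(sprintf("  exploration ends at trial %d; bin slope %.4f/bin\n",
              x$exploration_end, x$bin_slope))
  if (length(x$anomalies) > 0) {
    cat("  anomalies:", paste(x$anomalies, collapse = ", "), "\n")
  }
  invisible(x)
}
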