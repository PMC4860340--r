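#' Proficiency-criterion specification
#'
#' A bird is proficient once, at the end of a completed evaluation block, it
#' has chosen correctly in at least `min_correct_window` of the most recent
#' `window` trials *and* in at least `min_correct_per_block` of each of the
#' two most recent blocks. The defaults encode the 17-of-20 rule with
#' 10-trial blocks and a minimum of 8 correct per block; under chance
#' responding, 17/20 has a two-tailed exact binomial probability of about
#' 0.003 (see [criterion_tail_probability()]).
#'
#' `refresher_first_block_min` is the separate memory-check rule applied
#' before reversal training: a bird is taken to remember the original
#' association when its first block holds at least that many correct
#' choices (default 9, i.e. 9 or 10 of 10).
#'
#' @param window Number of most recent trials inspected (default 20).
#' @param min_correct_window Correct choices required in the window
#'   (default 17).
#' @param block Evaluation-block length in trials (must divide `window`;
#'   default 10).
#' @param min_correct_per_block Correct choices required in each of the two
#'   most recent blocks (default 8).
#' @param refresher_first_block_min Correct choices in the first block
#'   needed to skip refresher training (default 9).
#' @return An object of class `criterion_spec`.
#' @export
criterion_spec <- function(window = 20, min_correct_window = 17,
                           block = 10, min_correct_per_block = 8,
                           refresher_first_block_min = 9) {
  spec <- list(window = as.integer(window),
               min_correct_window = as.integer(min_correct_window),
               block = as.integer(block),
               min_correct_per_block = as.integer(min_correct_per_block),
               refresher_first_block_min = as.integer(refresher_first_block_min))
  if (spec$window < 1 || spec$block < 1) {
    stop("window and block must be positive", call. = FALSE)
  }
  if (spec$min_correct_window > spec$window) {
    stop("min_correct_window must not exceed window", call. = FALSE)
  }
  if (spec$window %% spec$block != 0) {
    stop("block must divide window", call. = FALSE)
  }
  if (spec$min_correct_per_block > spec$block) {
    stop("min_correct_per_block must not exceed block", call. = FALSE)
  }
  if (spec$refresher_first_block_min > spec$block) {
    stop("refresher_first_block_min must not exceed block", call. = FALSE)
  }
  structure(spec, class = "criterion_spec")
}

as_criterion_spec <- function(spec) {
  if (inherits(spec, "criterion_spec")) return(spec)
  do.call(criterion_spec, as.list(spec))
}

#' Sequential proficiency-criterion detection
#'
#' Scans a trial sequence at the end of each completed evaluation block
#' (the earliest evaluation point being one full window of trials) and
#' reports the first point at which the criterion of [criterion_spec()]
#' holds. Because evaluation happens only at completed block boundaries,
#' trials-to-criterion is always a multiple of the block length.
#'
#' @param seq A [trial_sequence()] (or plain logical vector of per-trial
#'   correctness).
#' @param spec A [criterion_spec()].
#' @return An object of class `criterion_result`: a list with `passed`
#'   (logical), `trials_to_criterion` (integer or `NA` when never
#'   satisfied), and `evaluated_at` (integer vector of trial counts at
#'   which the rule was checked).
#' @examples
#' evaluate_criterion(rep(TRUE, 20))                  # passes at 20
#' evaluate_criterion(c(FALSE, rep(TRUE, 19)))        # error-prefix, still 20
#' @export
evaluate_criterion <- function(seq, spec = criterion_spec()) {
  outcomes <- sequence_outcomes(seq)
  spec <- as_criterion_spec(spec)
  n <- length(outcomes)
  eval_points <- seq.int(spec$window, n, by = spec$block)
  if (spec$window > n) eval_points <- integer(0)
  passed_at <- NA_integer_
  for (T in eval_points) {
    if (criterion_holds_at(outcomes, T, spec)) {
      passed_at <- T
      eval_points <- eval_points[eval_points <= T]
      break
    }
  }
  structure(
    list(passed = !is.na(passed_at),
         trials_to_criterion = passed_at,
         evaluated_at = as.integer(eval_points)),
    class = "criterion_result"
  )
}

criterion_holds_at <- function(outcomes, T, spec) {
  window <- outcomes[(T - spec$window + 1):T]
  if (sum(window) < spec$min_correct_window) return(FALSE)
  b1 <- outcomes[(T - 2 * spec$block + 1):(T - spec$block)]
  b2 <- outcomes[(T - spec$block + 1):T]
  sum(b1) >= spec$min_correct_per_block &&
    sum(b2) >= spec$min_correct_per_block
}

sequence_outcomes <- function(seq) {
  if (inherits(seq, "trial_sequence")) return(seq$outcomes)
  outcomes <- as.logical(seq)
  if (length(outcomes) < 1 || anyNA(outcomes)) {
    stop("sequence must be non-empty and NA-free", call. = FALSE)
  }
  outcomes
}

#' @export
print.criterion_result <- function(x, ...) {
  if (x$passed) {
    cat("Criterion reached after", x$trials_to_criterion, "trials\n")
  } else {
    cat("Criterion not reached (checked at ",
        paste(x$evaluated_at, collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' Memory check before reversal training
#'
#' Applied at the start of the reversal phase: if the bird is correct in at
#' least `refresher_first_block_min` of its first block of trials (default
#' 9 of 10) it is deemed to remember the original association and proceeds
#' directly to reversal; otherwise it needs refresher training back to the
#' full criterion.
#'
#' @inheritParams evaluate_criterion
#' @return `"remembered"` or `"needs_refresher"`.
#' @export
refresher_outcome <- function(seq, spec = criterion_spec()) {
  outcomes <- sequence_outcomes(seq)
  spec <- as_criterion_spec(spec)
  if (length(outcomes) < spec$block) {
    stop("need at least one full block (", spec$block, " trials) to assess ",
         "the refresher rule", call. = FALSE)
  }
  first_block <- outcomes[seq_len(spec$block)]
  if (sum(first_block) >= spec$refresher_first_block_min) {
    "remembered"
  } else {
    "needs_refresher"
  }
}

#' Chance probability of the criterion window
#'
#' The two-tailed exact binomial probability of the window rule under chance
#' responding (p = 0.5): for the default 17-of-20 this is about 0.0026,
#' conventionally reported as 0.003.
#'
#' @param spec A [criterion_spec()].
#' @return A single probability.
#' @export
criterion_tail_probability <- function(spec = criterion_spec()) {
  spec <- as_criterion_spec(spec)
  binom_two_tailed(spec$min_correct_window, spec$window, 0.5)$p_raw
}
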