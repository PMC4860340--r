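#' Experiment identifiers and option domains
#'
#' The pipeline recognizes seven experiments: the color-association tasks
#' (one choice per trial; gold vs. silver tubes) and the water-tube
#' object/tube-choice tasks (up to several choices per trial). Each
#' experiment has a fixed two-level option domain and a designated
#' *functional* option (the one currently rewarded, or the one that raises
#' the water level enough to reach the food).
#'
#' @format `flex_experiments()` returns a data frame with one row per
#'   experiment and columns `experiment_id`, `class` (`"association"` or
#'   `"water_tube"`), `option_a`, `option_b`, and `functional`
#'   (the functional option).
#' @examples
#' flex_experiments()
#' @export
flex_experiments <- function() {
  data.frame(
    experiment_id = c("EXP1_COLOR", "EXP1_REFRESHER", "EXP2_REVERSAL",
                      "EXP3_HVL", "EXP4_MAGIC", "EXP5_NW", "EXP6_NW_UNEQ"),
    class = c("association", "association", "association",
              "water_tube", "water_tube", "water_tube", "water_tube"),
    option_a = c("gold", "gold", "gold", "heavy", "heavy", "narrow", "narrow"),
    option_b = c("silver", "silver", "silver", "light", "light", "wide", "wide"),
    functional = c("gold", "gold", "silver", "heavy", "light", "narrow", "wide"),
    stringsAsFactors = FALSE
  )
}

experiment_ids <- function() flex_experiments()$experiment_id

experiment_row <- function(experiment_id) {
  reg <- flex_experiments()
  i <- match(experiment_id, reg$experiment_id)
  if (is.na(i)) {
    stop("unknown experiment_id: ", experiment_id, call. = FALSE)
  }
  reg[i, , drop = FALSE]
}

#' @rdname flex_experiments
#' @param experiment_id One of the identifiers listed by [flex_experiments()].
#' @return `option_domain()` returns the two admissible option tokens for an
#'   experiment; `functional_option()` returns the functional one.
#' @export
option_domain <- function(experiment_id) {
  row <- experiment_row(experiment_id)
  c(row$option_a, row$option_b)
}

#' @rdname flex_experiments
#' @export
functional_option <- function(experiment_id) {
  experiment_row(experiment_id)$functional
}

is_association <- function(experiment_id) {
  experiment_row(experiment_id)$class == "association"
}
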