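#' Exact two-tailed binomial test by tail doubling
#'
#' Computes `p_raw = min(1, 2 * min(P(X <= k), P(X >= k)))` for
#' `X ~ Binomial(n, p0)` from the exact binomial CDF. At `p0 = 0.5` (the
#' only null used for two-choice preference data) tail doubling coincides
#' with the minimum-likelihood two-sided test, so the convention only
#' matters for off-center nulls.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials.
#' @param p0 Null success probability, strictly inside (0, 1); default 0.5.
#' @return An object of class `binomial_result`: list with `successes`,
#'   `n`, `p0`, `p_raw`, and (filled in by [holm_adjust_results()])
#'   `p_adjusted` and `family_size`.
#' @examples
#' binom_two_tailed(17, 20)$p_raw   # ~0.0026, the 17-of-20 chance level
#' @export
binom_two_tailed <- function(successes, n, p0 = 0.5) {
  successes <- as.integer(successes)
  n <- as.integer(n)
  if (is.na(successes) || is.na(n) || n < 1 ||
      successes < 0 || successes > n) {
    stop("need 0 <= successes <= n with n >= 1", call. = FALSE)
  }
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) {
    stop("p0 must lie strictly between 0 and 1", call. = FALSE)
  }
  lower <- stats::pbinom(successes, n, p0)
  upper <- stats::pbinom(successes - 1, n, p0, lower.tail = FALSE)
  structure(
    list(successes = successes, n = n, p0 = p0,
         p_raw = min(1, 2 * min(lower, upper)),
         p_adjusted = NULL, family_size = NULL),
    class = "binomial_result"
  )
}

#' @export
print.binomial_result <- function(x, ...) {
  cat(sprintf("Exact binomial: %d/%d vs p0 = %g, two-tailed p = %s\n",
              x$successes, x$n, x$p0, format_p(x$p_raw)))
  if (!is.null(x$p_adjusted)) {
    cat(sprintf("  Holm-adjusted (family of %d): %s\n", x$family_size,
                format_p(x$p_adjusted)))
  }
  invisible(x)
}

# report-layer rounding: 2 decimals at or above 0.01, 1 significant
# figure below
format_p <- function(p) {
  ifelse(p >= 0.01, sprintf("%.2f", p), format(signif(p, 1), scientific = FALSE))
}

#' Bonferroni-Holm step-down adjustment
#'
#' Standard Holm correction (ascending step-down with cumulative-maximum
#' enforcement, capped at 1, returned in input order), applied within one
#' family of tests — here always the set of birds tested in the same
#' experiment.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))   # 0.03 0.06 0.06
#' @export
holm_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0) stop("empty p-value vector", call. = FALSE)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

#' @rdname holm_adjust
#' @param results A list of [binom_two_tailed()] results forming one family.
#' @return `holm_adjust_results()` returns the list with `p_adjusted` and
#'   `family_size` filled in.
#' @export
holm_adjust_results <- function(results) {
  stopifnot(all(vapply(results, inherits, logical(1), "binomial_result")))
  adj <- holm_adjust(vapply(results, function(r) r$p_raw, numeric(1)))
  for (i in seq_along(results)) {
    results[[i]]$p_adjusted <- adj[i]
    results[[i]]$family_size <- length(results)
  }
  results
}

#' Tie-corrected Spearman rank correlation
#'
#' Computes rho as the Pearson correlation of mid-ranks (average ranks for
#' ties), the statistic `S = (1 - rho) (n^3 - n) / 6` (which reduces to the
#' classical sum of squared rank differences when there are no ties), and a
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' The t approximation is used throughout because the tie-corrected
#' statistic has no exact null distribution.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return An object of class `spearman_result`: list with `rho`, `S`, `n`,
#'   `p_approx`, and `tie_corrected` (whether either input contained ties).
#' @examples
#' spearman_tied(1:3, 1:3)   # rho = 1, S = 0
#' @export
spearman_tied <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("inputs must be NA-free", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("constant ranks: rho is undefined", call. = FALSE)
  }
  # Pearson correlation of mid-ranks, written out
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  S <- (1 - rho) * (n^3 - n) / 6
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  }
  structure(
    list(rho = rho, S = S, n = n, p_approx = p,
         tie_corrected = anyDuplicated(x) > 0 || anyDuplicated(y) > 0),
    class = "spearman_result"
  )
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation%s: S = %.2f, rho = %.2f, n = %d, p = %s\n",
              if (x$tie_corrected) " (tie-corrected)" else "",
              x$S, x$rho, x$n, format_p(x$p_approx)))
  invisible(x)
}

#' Akaike weights
#'
#' Normalized evidence weights `w_i = exp(-d_i / 2) / sum_j exp(-d_j / 2)`
#' with `d_i = IC_i - min(IC)`, for externally supplied information-criterion
#' values (AIC, DIC, ...). Weights sum to 1 and are invariant to adding a
#' constant to every input.
#'
#' @param information_criteria Finite numeric vector, one value per model.
#' @return Numeric vector of weights in the input order.
#' @examples
#' akaike_weights(c(100, 102))
#' @export
akaike_weights <- function(information_criteria) {
  ic <- as.numeric(information_criteria)
  if (length(ic) == 0) stop("need at least one model", call. = FALSE)
  if (any(!is.finite(ic))) stop("information criteria must be finite",
                                call. = FALSE)
  rel <- exp(-(ic - min(ic)) / 2)
  rel / sum(rel)
}
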