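#' Continuity-corrected McNemar statistic on discordant counts
#'
#' The test statistic is `(b - c - 1) / sqrt(b + c)`, where `b` counts
#' matched pairs with treated outcome 0 and control outcome 1, and `c` the
#' reverse. Under the null of no causal effect it is approximately standard
#' normal; the `-1` is the continuity correction. The statistic requires at
#' least one discordant pair.
#'
#' @param b,c Nonnegative integer discordant-pair counts (vectorised).
#' @return A numeric vector of statistic values, full precision.
#' @examples
#' lambda_stat(12082, 9448) # 17.94 to two decimals
#' lambda_stat(1, 0)
#' @export
lambda_stat <- function(b, c) {
  check_count(b, "b")
  check_count(c, "c")
  if (any(b + c < 1)) {
    abort_validation("The statistic is undefined without a discordant pair (b + c must be >= 1).")
  }
  (b - c - 1) / sqrt(b + c)
}

#' Optimal discordant split at a fixed total
#'
#' With the total discordant-pair count fixed at `m`, the statistic is
#' monotone in each count separately, so its extrema over all admissible
#' assignments have a closed form in the aggregate capacities. The maximum
#' fills type-one pairs first (`b = min(m, b_max)`), the minimum fills
#' type-two pairs first (`c = min(m, c_max)`); the remainder goes to the
#' other type. `m` is feasible on `1 <= m <= b_max + c_max`.
#'
#' @param m Total number of discordant pairs (scalar).
#' @param capacities A `capacity_set` (from [aggregate_capacities()] or
#'   [capacity_set()]).
#' @param sense `"max"` or `"min"`: which extremum to construct.
#' @return A one-row tibble with columns `m`, `b`, `c`, `lambda`.
#' @examples
#' caps <- capacity_set(12082, 9448)
#' optimal_discordant_split(10000, caps, "min") # b = 552, c = 9448
#' optimal_discordant_split(10000, caps, "max") # b = 10000, c = 0
#' @export
optimal_discordant_split <- function(m, capacities, sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (!inherits(capacities, "capacity_set")) {
    abort_validation("`capacities` must be a capacity_set.")
  }
  check_count(m, "m")
  if (length(m) != 1L) abort_validation("`m` must be a single count.")
  m_max <- capacities$b_max + capacities$c_max
  if (m < 1 || m > m_max) {
    abort_infeasible(sprintf(
      "m = %g is infeasible; the feasible range is 1 <= m <= b_max + c_max = %g.", m, m_max
    ))
  }
  if (sense == "max") {
    b <- min(m, capacities$b_max)
    c <- m - b
  } else {
    c <- min(m, capacities$c_max)
    b <- m - c
  }
  tibble::tibble(m = m, b = b, c = c, lambda = lambda_stat(b, c))
}

#' Normal-approximation p-value for the statistic
#'
#' The statistic is referred to the standard normal law. The one-sided
#' upper-tail p-value suits the directional alternative (treatment increases
#' the outcome rate); the two-sided p-value doubles the tail of the absolute
#' value, capped at 1.
#'
#' @param lambda Statistic value(s).
#' @param sided `"one_sided_upper"` (default) or `"two_sided"`.
#' @return Numeric p-value(s) in \[0, 1\].
#' @examples
#' lambda_p_value(0)              # 0.5
#' lambda_p_value(1.959964, "two_sided") # 0.05
#' @export
lambda_p_value <- function(lambda, sided = c("one_sided_upper", "two_sided")) {
  sided <- match.arg(sided)
  if (any(!is.finite(lambda))) abort_validation("`lambda` must be finite.")
  if (sided == "one_sided_upper") {
    stats::pnorm(lambda, lower.tail = FALSE)
  } else {
    pmin(1, 2 * stats::pnorm(abs(lambda), lower.tail = FALSE))
  }
}

#' Robustness classification from the two extreme p-values
#'
#' Classifies a test by where the largest and smallest attainable p-values
#' fall relative to the significance level: if they are equal the conclusion
#' is assignment-free (`absolute-robust`); if both are at or below `alpha`
#' every admissible pairing rejects (`alpha-robust-reject`); if both exceed
#' `alpha` every pairing fails to reject (`alpha-robust-fail`); otherwise the
#' conclusion depends on which pairs were matched (`not-robust`).
#'
#' @param p_from_lambda_min,p_from_lambda_max The p-values attached to the
#'   minimum and maximum attainable statistics.
#' @param alpha Significance level in (0, 1).
#' @return A single classification string.
#' @examples
#' robust_decision(0.001, 0.02, alpha = 0.05)
#' @export
robust_decision <- function(p_from_lambda_min, p_from_lambda_max, alpha = 0.05) {
  p1 <- p_from_lambda_min; p2 <- p_from_lambda_max
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1) || length(p1) != 1L || length(p2) != 1L) {
    abort_validation("p-values must be single probabilities in [0, 1].")
  }
  if (alpha <= 0 || alpha >= 1) abort_validation("`alpha` must lie in (0, 1).")
  if (p1 == p2) return("absolute-robust")
  if (max(p1, p2) <= alpha) return("alpha-robust-reject")
  if (min(p1, p2) > alpha) return("alpha-robust-fail")
  "not-robust"
}
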