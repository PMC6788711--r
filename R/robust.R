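as_capacities <- function(x) {
  if (inherits(x, "capacity_set")) return(x)
  if (inherits(x, "matched_set") || is.data.frame(x)) return(aggregate_capacities(x))
  abort_validation("Expected a matched_set, a tally data frame, or a capacity_set.")
}

#' Absolute-robust McNemar test at the robustness condition
#'
#' Fixing the total discordant-pair count at `m = b_max + c_max` forces every
#' admissible assignment to realise both discordant types at capacity, so the
#' maximum and minimum of the statistic coincide and the test conclusion is
#' independent of which one-to-one pairing a matching algorithm happened to
#' pick. This function evaluates the statistic at that condition, attaches
#' normal p-values, and classifies the result.
#'
#' @param x A `matched_set` from [build_partitions()], a data frame of
#'   per-partition tallies, or a `capacity_set`.
#' @param alpha Significance level, default 0.05.
#' @return An object of class `robust_mcnemar`: the statistic, `m_robust`,
#'   the aggregate capacities, one- and two-sided p-values, `alpha` and the
#'   classification (always `"absolute-robust"` at this `m`). Supports
#'   [generics::tidy()] and [generics::glance()].
#' @examples
#' robust_mcnemar_test(capacity_set(12082, 9448))
#' @export
robust_mcnemar_test <- function(x, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort_validation("`alpha` must lie in (0, 1).")
  caps <- as_capacities(x)
  m_robust <- caps$b_max + caps$c_max
  if (m_robust < 1) {
    abort_infeasible("No discordant pairs are attainable (b_max + c_max = 0); the test is undefined.")
  }
  statistic <- lambda_stat(caps$b_max, caps$c_max)
  p_one <- lambda_p_value(statistic, "one_sided_upper")
  p_two <- lambda_p_value(statistic, "two_sided")
  structure(
    list(
      statistic = statistic,
      m_robust = m_robust,
      b_max = caps$b_max,
      c_max = caps$c_max,
      p_value = p_one,
      p_two_sided = p_two,
      alpha = alpha,
      classification = robust_decision(p_one, p_one, alpha),
      capacities = caps
    ),
    class = "robust_mcnemar"
  )
}

#' @export
print.robust_mcnemar <- function(x, ...) {
  cat("Robust McNemar test (assignment-independent, at the robustness condition)\n")
  cat(sprintf("  b_max = %g, c_max = %g, m_robust = %g\n", x$b_max, x$c_max, x$m_robust))
  cat(sprintf("  statistic = %.2f\n", x$statistic))
  cat(sprintf("  one-sided upper p = %.4g, two-sided p = %.4g\n", x$p_value, x$p_two_sided))
  cat(sprintf("  classification at alpha = %g: %s\n", x$alpha, x$classification))
  invisible(x)
}

default_increment <- function(m_max, max_rows = 200L) {
  max(1L, as.integer(ceiling(m_max / max_rows)))
}

#' Uncertainty profile over the number of matched discordant pairs
#'
#' For each total discordant count `m` on a grid, computes the minimum and
#' maximum attainable statistic via the closed-form split and the
#' corresponding band of attainable p-values. The band shows how much the
#' test conclusion can depend on the matching algorithm's pair choices; it
#' collapses to a point at `m = b_max + c_max`, which is always appended to
#' the grid.
#'
#' @inheritParams robust_mcnemar_test
#' @param increment Step of the `m` grid. Default chooses a step so the grid
#'   has at most 200 rows.
#' @param m_grid Explicit grid of `m` values (overrides `increment`). Every
#'   value must be feasible.
#' @param alpha Significance level used for the per-row classification.
#' @return A tibble of class `mcnemar_profile` with one row per `m`:
#'   `lambda_min`, `lambda_max`, the optimal splits (`b_at_min`, `c_at_min`,
#'   `b_at_max`, `c_at_max`), the p-value band (`p_high` from `lambda_min`,
#'   `p_low` from `lambda_max`, one-sided upper) and the classification.
#'   Capacities and settings are carried in attributes. Supports
#'   [ggplot2::autoplot()].
#' @examples
#' uncertainty_profile(capacity_set(12082, 9448), m_grid = c(50, 10000, 21530))
#' @export
uncertainty_profile <- function(x, increment = NULL, m_grid = NULL, alpha = 0.05) {
  caps <- as_capacities(x)
  m_max <- caps$b_max + caps$c_max
  if (m_max < 1) {
    abort_infeasible("No discordant pairs are attainable (b_max + c_max = 0).")
  }
  if (is.null(m_grid)) {
    if (is.null(increment)) increment <- default_increment(m_max)
    check_count(increment, "increment")
    if (increment < 1) abort_validation("`increment` must be >= 1.")
    m_grid <- seq(from = min(increment, m_max), to = m_max, by = increment)
  } else {
    check_count(m_grid, "m_grid")
    bad <- m_grid[m_grid < 1 | m_grid > m_max]
    if (length(bad)) {
      abort_infeasible(sprintf(
        "Infeasible m value(s) in grid: %s (feasible range 1..%g).",
        paste(bad, collapse = ", "), m_max
      ))
    }
    increment <- NA_integer_
  }
  m_grid <- sort(unique(c(m_grid, m_max)))

  rows <- purrr::map_dfr(m_grid, function(m) {
    lo <- optimal_discordant_split(m, caps, "min")
    hi <- optimal_discordant_split(m, caps, "max")
    tibble::tibble(
      m = m,
      lambda_min = lo$lambda, lambda_max = hi$lambda,
      b_at_min = lo$b, c_at_min = lo$c,
      b_at_max = hi$b, c_at_max = hi$c,
      p_high = lambda_p_value(lo$lambda, "one_sided_upper"),
      p_low = lambda_p_value(hi$lambda, "one_sided_upper")
    )
  })
  rows$classification <- vapply(
    seq_len(nrow(rows)),
    function(i) robust_decision(rows$p_high[i], rows$p_low[i], alpha),
    character(1)
  )
  structure(
    rows,
    b_max = caps$b_max, c_max = caps$c_max, m_max = m_max,
    increment = increment, alpha = alpha,
    class = c("mcnemar_profile", class(tibble::tibble()))
  )
}
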