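#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a robust McNemar test
#'
#' @param x A `robust_mcnemar` object.
#' @param ... Unused.
#' @return A one-row tibble with the statistic, capacities, `m_robust`,
#'   p-values and classification.
#' @exportS3Method generics::tidy
#' @export
tidy.robust_mcnemar <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    b_max = x$b_max,
    c_max = x$c_max,
    m_robust = x$m_robust,
    p_value = x$p_value,
    p_two_sided = x$p_two_sided,
    classification = x$classification
  )
}

#' @rdname tidy.robust_mcnemar
#' @exportS3Method generics::glance
#' @export
glance.robust_mcnemar <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p_value = x$p_value,
    alpha = x$alpha,
    n_partitions = x$capacities$n_partitions,
    max_pairs = x$capacities$max_pairs,
    classification = x$classification
  )
}

#' Tidy a capacity set
#'
#' @param x A `capacity_set`.
#' @param ... Unused.
#' @return The per-partition capacity tibble (`tidy`) or a one-row aggregate
#'   summary (`glance`).
#' @exportS3Method generics::tidy
#' @export
tidy.capacity_set <- function(x, ...) {
  if (is.null(x$per_partition)) {
    abort_validation("This capacity set carries no per-partition detail.")
  }
  x$per_partition
}

#' @rdname tidy.capacity_set
#' @exportS3Method generics::glance
#' @export
glance.capacity_set <- function(x, ...) {
  tibble::tibble(
    b_max = x$b_max, c_max = x$c_max,
    a_max = x$a_max, d_max = x$d_max,
    m_robust = x$b_max + x$c_max,
    max_pairs = x$max_pairs,
    n_partitions = x$n_partitions
  )
}

#' Plot an uncertainty profile
#'
#' Draws the envelope of attainable values against the total number of
#' matched discordant pairs `m`: either the statistic's extrema or the band
#' of attainable one-sided p-values. The band narrows with `m` and closes at
#' the robustness condition.
#'
#' @param object An `mcnemar_profile` from [uncertainty_profile()].
#' @param what `"p_value"` (default) or `"lambda"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.mcnemar_profile <- function(object, what = c("p_value", "lambda"), ...) {
  what <- match.arg(what)
  df <- tibble::as_tibble(object)
  if (what == "lambda") {
    lower <- df$lambda_min; upper <- df$lambda_max
    ylab <- "test statistic"
  } else {
    lower <- df$p_low; upper <- df$p_high
    ylab <- "attainable one-sided p-value"
  }
  plot_df <- tibble::tibble(m = df$m, lower = lower, upper = upper)
  ggplot2::ggplot(plot_df, ggplot2::aes(x = .data$m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = attr(object, "m_max"), linetype = "dashed") +
    ggplot2::labs(x = "total matched discordant pairs (m)", y = ylab) +
    ggplot2::theme_minimal()
}
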