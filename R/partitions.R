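#' Tally binary outcomes of the two arms of a partition
#'
#' @param treated_outcomes,control_outcomes Vectors of 0/1 outcomes for the
#'   treated and control members of one partition.
#' @return A one-row tibble with counts `n_t_pos`, `n_t_neg`, `n_c_pos`,
#'   `n_c_neg` (positive/negative outcomes per arm).
#' @examples
#' tally_outcomes(c(1, 1, 0), c(0, 1))
#' @export
tally_outcomes <- function(treated_outcomes, control_outcomes) {
  if (length(treated_outcomes) + length(control_outcomes) == 0L) {
    abort_validation("Cannot tally an empty partition.")
  }
  if (!all(is_binary01(treated_outcomes)) || !all(is_binary01(control_outcomes))) {
    abort_validation("Outcomes must be 0 or 1.")
  }
  tibble::tibble(
    n_t_pos = sum(treated_outcomes == 1),
    n_t_neg = sum(treated_outcomes == 0),
    n_c_pos = sum(control_outcomes == 1),
    n_c_neg = sum(control_outcomes == 0)
  )
}

#' Group coarsened units into exact-match partitions
#'
#' Units are grouped by exact equality of their full covariate signature (the
#' ordered tuple of category labels). Within a partition any treated unit is
#' an admissible match for any control unit, so the partition plays the role
#' of one cell of the good-match set. Signatures carrying only one arm have
#' no admissible pairs (no common support); those units are dropped from the
#' matched set and counted in the provenance attributes.
#'
#' @param units A unit table whose covariates are all categorical (see
#'   [coarsen()]).
#' @return A `matched_set`: a tibble with one row per partition, sorted by
#'   signature key, holding the key, member ids (`treated_ids`,
#'   `control_ids`, list-columns), arm sizes and the four outcome counts.
#'   Attributes: `covariates`, `n_units`, `n_dropped_units`,
#'   `n_dropped_partitions`.
#' @examples
#' u <- tibble::tibble(
#'   unit_id = paste0("u", 1:5),
#'   treatment = c(1, 1, 0, 0, 0),
#'   outcome = c(1, 0, 1, 0, 0),
#'   sex = "F"
#' )
#' build_partitions(u)
#' @export
build_partitions <- function(units) {
  validate_units(units)
  if (nrow(units) == 0L) {
    abort_validation("Cannot build partitions from an empty unit table.")
  }
  covs <- setdiff(names(units), c("unit_id", "treatment", "outcome"))
  for (cov in covs) {
    if (is.numeric(units[[cov]])) {
      abort_validation(sprintf(
        "Covariate '%s' is numeric; coarsen() it to categories before partitioning.", cov
      ))
    }
    if (anyNA(units[[cov]])) {
      abort_validation(sprintf("Covariate '%s' has missing values.", cov))
    }
  }
  sig <- if (length(covs)) {
    do.call(paste, c(lapply(covs, function(cv) as.character(units[[cv]])), sep = "|"))
  } else {
    rep("(none)", nrow(units))
  }

  grouped <- units |>
    dplyr::mutate(key = sig) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("key", covs)))) |>
    dplyr::summarise(
      treated_ids = list(.data$unit_id[.data$treatment == 1]),
      control_ids = list(.data$unit_id[.data$treatment == 0]),
      n_t_pos = sum(.data$treatment == 1 & .data$outcome == 1),
      n_t_neg = sum(.data$treatment == 1 & .data$outcome == 0),
      n_c_pos = sum(.data$treatment == 0 & .data$outcome == 1),
      n_c_neg = sum(.data$treatment == 0 & .data$outcome == 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_t = .data$n_t_pos + .data$n_t_neg,
      n_c = .data$n_c_pos + .data$n_c_neg
    ) |>
    dplyr::arrange(.data$key)

  two_armed <- grouped$n_t >= 1L & grouped$n_c >= 1L
  dropped <- grouped[!two_armed, , drop = FALSE]
  kept <- grouped[two_armed, , drop = FALSE]
  if (nrow(kept) == 0L) {
    abort_validation("No common support: every covariate signature has only one arm.")
  }
  structure(
    kept,
    covariates = covs,
    n_units = nrow(units),
    n_dropped_units = sum(dropped$n_t + dropped$n_c),
    n_dropped_partitions = nrow(dropped),
    class = c("matched_set", class(tibble::tibble()))
  )
}

#' @export
print.matched_set <- function(x, ...) {
  cat(sprintf(
    "Matched set: %d partition(s), %d treated, %d control units (%d unit(s) in %d single-armed signature(s) dropped)\n",
    nrow(x), sum(x$n_t), sum(x$n_c),
    attr(x, "n_dropped_units"), attr(x, "n_dropped_partitions")
  ))
  NextMethod()
}
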