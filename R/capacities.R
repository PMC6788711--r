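#' Discordant-pair capacities of a partition
#'
#' Within one exact-match partition, the largest attainable number of
#' type-one discordant pairs (treated outcome 0 paired with control outcome
#' 1) is `min(n_t_neg, n_c_pos)`, and of type-two pairs (treated 1 with
#' control 0) is `min(n_t_pos, n_c_neg)`: each discordant type draws on its
#' own disjoint pool of units, so both bounds are achieved simultaneously.
#'
#' @param n_t_pos,n_t_neg,n_c_pos,n_c_neg Outcome counts per arm (vectors of
#'   equal length are allowed; capacities are computed per element).
#' @return A tibble with columns `b_cap` (type-one capacity) and `c_cap`
#'   (type-two capacity).
#' @examples
#' discordant_capacities(2, 3, 2, 3)
#' @export
discordant_capacities <- function(n_t_pos, n_t_neg, n_c_pos, n_c_neg) {
  check_count(n_t_pos, "n_t_pos"); check_count(n_t_neg, "n_t_neg")
  check_count(n_c_pos, "n_c_pos"); check_count(n_c_neg, "n_c_neg")
  tibble::tibble(
    b_cap = pmin(n_t_neg, n_c_pos),
    c_cap = pmin(n_t_pos, n_c_neg)
  )
}

#' Concordant fill after discordant pairing
#'
#' After assigning the discordant capacities, the leftover units of each arm
#' are paired into the concordant cells to their limit:
#' `a_cap = min(n_t_pos - c_cap, n_c_pos - b_cap)` (both outcomes positive)
#' and `d_cap = min(n_t_neg - b_cap, n_c_neg - c_cap)` (both negative). The
#' four counts then exhaust the partition's pairing capacity:
#' `b_cap + c_cap + a_cap + d_cap = min(arm sizes)`.
#'
#' @inheritParams discordant_capacities
#' @param b_cap,c_cap The discordant capacities of the same tallies, as
#'   returned by [discordant_capacities()].
#' @return A tibble with columns `a_cap` and `d_cap`.
#' @examples
#' concordant_fill(2, 3, 2, 3, b_cap = 2, c_cap = 2)
#' @export
concordant_fill <- function(n_t_pos, n_t_neg, n_c_pos, n_c_neg, b_cap, c_cap) {
  caps <- discordant_capacities(n_t_pos, n_t_neg, n_c_pos, n_c_neg)
  check_count(b_cap, "b_cap"); check_count(c_cap, "c_cap")
  if (any(b_cap > caps$b_cap) || any(c_cap > caps$c_cap)) {
    abort_validation("`b_cap`/`c_cap` exceed the discordant capacities of these tallies.")
  }
  tibble::tibble(
    a_cap = pmin(n_t_pos - c_cap, n_c_pos - b_cap),
    d_cap = pmin(n_t_neg - b_cap, n_c_neg - c_cap)
  )
}

#' Build a capacity set from aggregate capacities
#'
#' Constructs a `capacity_set` directly from known aggregate discordant
#' capacities, without per-partition detail. Useful when the capacities are
#' reported quantities rather than recomputed from unit data.
#'
#' @param b_max,c_max Aggregate type-one and type-two discordant capacities.
#' @param per_partition Optional tibble of per-partition capacities
#'   (columns `key`, `b_cap`, `c_cap`, `a_cap`, `d_cap`, `max_pairs`).
#' @return A `capacity_set` object.
#' @examples
#' capacity_set(12082, 9448)
#' @export
capacity_set <- function(b_max, c_max, per_partition = NULL) {
  check_count(b_max, "b_max"); check_count(c_max, "c_max")
  if (length(b_max) != 1L || length(c_max) != 1L) {
    abort_validation("`b_max` and `c_max` must be single counts.")
  }
  structure(
    list(
      per_partition = per_partition,
      b_max = as.numeric(b_max),
      c_max = as.numeric(c_max),
      a_max = if (is.null(per_partition)) NA_real_ else sum(per_partition$a_cap),
      d_max = if (is.null(per_partition)) NA_real_ else sum(per_partition$d_cap),
      max_pairs = if (is.null(per_partition)) NA_real_ else sum(per_partition$max_pairs),
      n_partitions = if (is.null(per_partition)) NA_integer_ else nrow(per_partition)
    ),
    class = "capacity_set"
  )
}

#' Aggregate pairing capacities over a matched set
#'
#' Computes per-partition discordant capacities and concordant fills and sums
#' them across partitions. The aggregates `b_max` and `c_max` bound the two
#' discordant counts over every admissible one-to-one assignment; their sum
#' is the robustness condition's total discordant-pair count.
#'
#' @param matched_set A `matched_set` from [build_partitions()], or any data
#'   frame with columns `n_t_pos`, `n_t_neg`, `n_c_pos`, `n_c_neg` (and
#'   optionally `key`).
#' @return A `capacity_set`: per-partition tibble plus aggregates `b_max`,
#'   `c_max`, `a_max`, `d_max` and `max_pairs` (the total one-to-one pairing
#'   capacity, per partition the smaller arm size).
#' @examples
#' u <- tibble::tibble(unit_id = as.character(1:6), treatment = rep(c(1, 0), 3),
#'                     outcome = c(1, 0, 0, 1, 1, 1), g = "x")
#' aggregate_capacities(build_partitions(u))
#' @export
aggregate_capacities <- function(matched_set) {
  needed <- c("n_t_pos", "n_t_neg", "n_c_pos", "n_c_neg")
  if (!all(needed %in% names(matched_set))) {
    abort_validation("`matched_set` must carry the four per-partition outcome counts.")
  }
  if (nrow(matched_set) == 0L) {
    abort_validation("`matched_set` has no partitions.")
  }
  per <- matched_set |>
    tibble::as_tibble() |>
    dplyr::transmute(
      key = if ("key" %in% names(matched_set)) .data$key else sprintf("p%d", dplyr::row_number()),
      n_t_pos = .data$n_t_pos, n_t_neg = .data$n_t_neg,
      n_c_pos = .data$n_c_pos, n_c_neg = .data$n_c_neg
    ) |>
    dplyr::bind_cols(
      discordant_capacities(matched_set$n_t_pos, matched_set$n_t_neg,
                            matched_set$n_c_pos, matched_set$n_c_neg)
    )
  per <- dplyr::bind_cols(
    per,
    concordant_fill(per$n_t_pos, per$n_t_neg, per$n_c_pos, per$n_c_neg,
                    per$b_cap, per$c_cap)
  ) |>
    dplyr::mutate(
      max_pairs = pmin(.data$n_t_pos + .data$n_t_neg, .data$n_c_pos + .data$n_c_neg)
    ) |>
    dplyr::select("key", "b_cap", "c_cap", "a_cap", "d_cap", "max_pairs")
  capacity_set(sum(per$b_cap), sum(per$c_cap), per_partition = per)
}

#' @export
print.capacity_set <- function(x, ...) {
  cat("Discordant-pair capacity set\n")
  cat(sprintf("  b_max (treated 0 / control 1): %g\n", x$b_max))
  cat(sprintf("  c_max (treated 1 / control 0): %g\n", x$c_max))
  cat(sprintf("  robustness condition m = b_max + c_max: %g\n", x$b_max + x$c_max))
  if (!is.na(x$max_pairs)) {
    cat(sprintf("  partitions: %d; total pairing capacity: %g\n",
                x$n_partitions, x$max_pairs))
  }
  invisible(x)
}
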