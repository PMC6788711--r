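# Brute-force assignment enumeration for small matched sets. Ground truth for
# the closed-form extrema: every admissible one-to-one assignment is explored,
# either through per-partition discordant-split counts (units of equal arm and
# outcome within a partition are exchangeable, so only the counts matter) or,
# for tiny single-partition instances, through raw pair-assignment matrices.

check_oracle_guard <- function(matched_set, guard) {
  n_t <- sum(matched_set$n_t_pos + matched_set$n_t_neg)
  n_c <- sum(matched_set$n_c_pos + matched_set$n_c_neg)
  if (n_t > guard[["treated"]] || n_c > guard[["control"]]) {
    abort_validation(sprintf(
      "Instance too large for exhaustive enumeration (%d treated, %d control; guard %d/%d).",
      n_t, n_c, guard[["treated"]], guard[["control"]]
    ))
  }
}

# All jointly attainable (b, c) totals: cross-product of per-partition splits
# 0 <= b_p <= B^p, 0 <= c_p <= C^p. Within a partition the two discordant
# types draw on disjoint unit pools, so every such split is realisable.
enumerate_split_table <- function(matched_set) {
  caps <- aggregate_capacities(matched_set)$per_partition
  per <- purrr::map(seq_len(nrow(caps)), function(p) {
    tidyr::expand_grid(b = 0:caps$b_cap[p], c = 0:caps$c_cap[p])
  })
  first <- per[[1]]
  base <- tibble::tibble(
    b = first$b, c = first$c,
    detail = purrr::map(seq_len(nrow(first)), function(i) list(first[i, ]))
  )
  purrr::reduce(per[-1], function(acc, nxt) {
    out <- tidyr::expand_grid(i = seq_len(nrow(acc)), j = seq_len(nrow(nxt)))
    tibble::tibble(
      b = acc$b[out$i] + nxt$b[out$j],
      c = acc$c[out$i] + nxt$c[out$j],
      detail = purrr::map2(acc$detail[out$i], out$j, function(d, j) c(d, list(nxt[j, ])))
    )
  }, .init = base)
}

#' Exhaustive extrema of the statistic at a fixed discordant total
#'
#' Enumerates every admissible pair assignment of a small matched set with
#' total discordant count `m` and returns the exact minimum and maximum of
#' the statistic, with witness per-partition splits. Serves as ground truth
#' for [optimal_discordant_split()].
#'
#' @param matched_set A small `matched_set` (or tally data frame).
#' @param m Total discordant-pair count.
#' @param guard Named limits `c(treated = , control = )` on total arm sizes;
#'   larger instances are refused.
#' @param mode `"counts"` (default) enumerates per-partition discordant
#'   splits; `"pairs"` enumerates raw assignment matrices (single partition,
#'   arms at most 4x4) as an independent double-check.
#' @return A list with `lambda_min`, `lambda_max`, and witness splits
#'   `witness_min`, `witness_max` (tibbles of per-partition `b`, `c`).
#' @examples
#' u <- tibble::tibble(unit_id = as.character(1:4), treatment = c(1, 1, 0, 0),
#'                     outcome = c(1, 0, 1, 0), g = "x")
#' enumerate_extrema(build_partitions(u), m = 1)
#' @export
enumerate_extrema <- function(matched_set, m,
                              guard = c(treated = 12, control = 12),
                              mode = c("counts", "pairs")) {
  mode <- match.arg(mode)
  check_oracle_guard(matched_set, guard)
  check_count(m, "m")
  if (mode == "pairs") {
    return(enumerate_extrema_pairs(matched_set, m))
  }
  combos <- enumerate_split_table(matched_set)
  hit <- combos[combos$b + combos$c == m, , drop = FALSE]
  if (nrow(hit) == 0L) {
    abort_infeasible(sprintf("No admissible assignment has exactly m = %g discordant pairs.", m))
  }
  lam <- lambda_stat(hit$b, hit$c)
  i_min <- which.min(lam); i_max <- which.max(lam)
  witness <- function(i) {
    dplyr::bind_rows(hit$detail[[i]]) |>
      dplyr::mutate(partition = dplyr::row_number(), .before = 1)
  }
  list(
    lambda_min = lam[i_min], lambda_max = lam[i_max],
    witness_min = witness(i_min), witness_max = witness(i_max)
  )
}

# Raw-matrix enumeration: recursively assign each treated unit to an unused
# control or leave it unmatched, tracking the discordant counts.
enumerate_extrema_pairs <- function(matched_set, m) {
  if (nrow(matched_set) != 1L) {
    abort_validation("`mode = \"pairs\"` requires a single-partition matched set.")
  }
  n_t <- matched_set$n_t_pos + matched_set$n_t_neg
  n_c <- matched_set$n_c_pos + matched_set$n_c_neg
  if (n_t > 4L || n_c > 4L) {
    abort_validation("`mode = \"pairs\"` is limited to arms of at most 4 units each.")
  }
  t_out <- c(rep(1L, matched_set$n_t_pos), rep(0L, matched_set$n_t_neg))
  c_out <- c(rep(1L, matched_set$n_c_pos), rep(0L, matched_set$n_c_neg))
  results <- list()
  recurse <- function(i, used, b, c) {
    if (i > length(t_out)) {
      results[[length(results) + 1L]] <<- c(b = b, c = c)
      return(invisible())
    }
    recurse(i + 1L, used, b, c) # leave treated unit i unmatched
    for (j in seq_along(c_out)) {
      if (!used[j]) {
        used[j] <- TRUE
        db <- as.integer(t_out[i] == 0L && c_out[j] == 1L)
        dc <- as.integer(t_out[i] == 1L && c_out[j] == 0L)
        recurse(i + 1L, used, b + db, c + dc)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, length(c_out)), 0L, 0L)
  counts <- do.call(rbind, results)
  hit <- counts[counts[, "b"] + counts[, "c"] == m, , drop = FALSE]
  if (nrow(hit) == 0L) {
    abort_infeasible(sprintf("No admissible assignment has exactly m = %g discordant pairs.", m))
  }
  lam <- unname(lambda_stat(hit[, "b"], hit[, "c"]))
  i_min <- which.min(lam); i_max <- which.max(lam)
  list(
    lambda_min = lam[i_min], lambda_max = lam[i_max],
    witness_min = tibble::tibble(partition = 1L,
                                 b = unname(hit[i_min, "b"]), c = unname(hit[i_min, "c"])),
    witness_max = tibble::tibble(partition = 1L,
                                 b = unname(hit[i_max, "b"]), c = unname(hit[i_max, "c"]))
  )
}

#' Exhaustive uncertainty profile for a small matched set
#'
#' Enumerates all admissible assignments once and reports the exact extrema
#' of the statistic for every feasible discordant total `m`. Row-for-row
#' comparable with [uncertainty_profile()] at increment 1.
#'
#' @inheritParams enumerate_extrema
#' @return A tibble with columns `m`, `lambda_min`, `lambda_max`, one row per
#'   feasible `m` in `1..b_max + c_max`.
#' @export
oracle_profile <- function(matched_set, guard = c(treated = 12, control = 12)) {
  check_oracle_guard(matched_set, guard)
  combos <- enumerate_split_table(matched_set)
  combos |>
    dplyr::mutate(m = .data$b + .data$c) |>
    dplyr::filter(.data$m >= 1) |>
    dplyr::mutate(lambda = lambda_stat(.data$b, .data$c)) |>
    dplyr::group_by(.data$m) |>
    dplyr::summarise(lambda_min = min(.data$lambda),
                     lambda_max = max(.data$lambda), .groups = "drop") |>
    dplyr::arrange(.data$m)
}
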