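# Independent brute-force helpers, written against the assignment problem
# itself (count enumeration over the four pair types), not against the
# package's closed forms. Used to freeze expected values and as ground truth
# in property tests.

# Every realisable (a, b, c, d) pair-type count vector for one partition:
# a: treated-positive with control-positive, b: treated-negative with
# control-positive, c: treated-positive with control-negative, d:
# treated-negative with control-negative. Units of equal (arm, outcome) are
# exchangeable, so counts fully describe an assignment.
brute_pair_counts <- function(n_t_pos, n_t_neg, n_c_pos, n_c_neg) {
  out <- list()
  for (a in 0:min(n_t_pos, n_c_pos))
    for (b in 0:min(n_t_neg, n_c_pos - a))
      for (c in 0:min(n_t_pos - a, n_c_neg))
        for (d in 0:min(n_t_neg - b, n_c_neg - c))
          out[[length(out) + 1L]] <- c(a = a, b = b, c = c, d = d)
  do.call(rbind, out)
}

# Extremal capacities of one partition by exhaustive enumeration.
brute_capacities <- function(n_t_pos, n_t_neg, n_c_pos, n_c_neg) {
  counts <- brute_pair_counts(n_t_pos, n_t_neg, n_c_pos, n_c_neg)
  list(
    b_cap = max(counts[, "b"]),
    c_cap = max(counts[, "c"]),
    max_pairs = max(rowSums(counts)),
    counts = counts
  )
}

# Build a unit table realising the given per-partition tallies; each row of
# `tallies` needs n_t_pos, n_t_neg, n_c_pos, n_c_neg and optionally a key.
units_from_tallies <- function(tallies) {
  rows <- lapply(seq_len(nrow(tallies)), function(i) {
    tl <- tallies[i, ]
    y <- c(rep(1, tl$n_t_pos), rep(0, tl$n_t_neg), rep(1, tl$n_c_pos), rep(0, tl$n_c_neg))
    trt <- c(rep(1, tl$n_t_pos + tl$n_t_neg), rep(0, tl$n_c_pos + tl$n_c_neg))
    tibble::tibble(
      treatment = trt, outcome = y,
      stratum = if ("key" %in% names(tallies)) tl$key else sprintf("g%03d", i)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$unit_id <- sprintf("u%05d", seq_len(nrow(out)))
  dplyr::relocate(out, "unit_id")
}

random_tallies <- function(n, max_arm = 6, min_arm = 0) {
  tibble::tibble(
    n_t_pos = sample(min_arm:max_arm, n, replace = TRUE),
    n_t_neg = sample(min_arm:max_arm, n, replace = TRUE),
    n_c_pos = sample(min_arm:max_arm, n, replace = TRUE),
    n_c_neg = sample(min_arm:max_arm, n, replace = TRUE)
  )
}

write_units_csv <- function(units, path = tempfile(fileext = ".csv")) {
  readr::write_csv(dplyr::rename(units, id = "unit_id"), path)
  path
}
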