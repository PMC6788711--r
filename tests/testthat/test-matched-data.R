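test_that("read_units parses a valid file and rejects malformed ones", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "id,treatment,outcome,sex",
    "u1,0,1,F", "u2,0,0,F", "u3,1,1,M", "u4,1,0,M"
  ), path)
  units <- read_units(path)
  expect_equal(nrow(units), 4L)
  expect_equal(sum(units$treatment), 2)
  expect_equal(attr(units, "n_read"), 4L)
  expect_named(units, c("unit_id", "treatment", "outcome", "sex"))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("id,treatment,outcome", "u1,0,1", "u2,1,0", "u3,1,2"), bad)
  expect_error(read_units(bad), "u3", class = "rmn_validation_error")

  nocol <- tempfile(fileext = ".csv")
  writeLines(c("id,treatment", "u1,0"), nocol)
  expect_error(read_units(nocol), "outcome", class = "rmn_validation_error")

  expect_error(read_units(tempfile()), class = "rmn_io_error")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("id,treatment,outcome", "u1,0,1", "u1,1,0"), dup)
  expect_error(read_units(dup), "unique", class = "rmn_validation_error")
})

test_that("read_units round-trips the synthetic generator's output", {
  gen <- generate_units(synthetic_config(n_partitions = 40, n_treated = c(5, 20),
                                         n_control = c(5, 20), seed = 11))
  path <- write_units_csv(gen$units)
  units <- read_units(path)
  expect_equal(nrow(units), nrow(gen$units))
  expect_equal(sum(units$treatment), sum(gen$units$treatment))
  expect_equal(units$outcome, gen$units$outcome)
})

test_that("coarsen maps numeric covariates to half-open bands", {
  age_rule <- rule_bins(
    c(0, 21, 31, 41, 51, 65, Inf),
    c("0-20", "21-30", "31-40", "41-50", "51-65", "65 and above")
  )
  scheme <- coarsening_scheme(age = age_rule, sex = rule_categorical())
  u <- tibble::tibble(
    unit_id = c("a", "b", "c", "d"), treatment = c(0, 0, 1, 1),
    outcome = c(0, 1, 0, 1), age = c(67, 65, 20, 21), sex = c("Male", "F", "F", "F")
  )
  out <- coarsen(u, scheme)
  expect_equal(out$age, c("65 and above", "65 and above", "0-20", "21-30"))
  expect_equal(out$sex[1], "Male") # pass-through

  u$age[1] <- -1
  expect_error(coarsen(u, scheme), "age", class = "rmn_validation_error")

  u$age[1] <- NA
  expect_error(coarsen(u, scheme), "age", class = "rmn_validation_error")

  # scheme must cover every covariate
  expect_error(coarsen(u[, -5], coarsening_scheme(sex = rule_categorical())),
               "age", class = "rmn_validation_error")
})

test_that("bin rules validate their boundaries", {
  expect_error(rule_bins(c(0, 10, 10), c("a", "b")), class = "rmn_validation_error")
  expect_error(rule_bins(c(0, 10), c("a", "b")), class = "rmn_validation_error")
  expect_error(coarsening_scheme(rule_categorical()), class = "rmn_validation_error")
})

test_that("build_partitions groups by exact signature and drops single arms", {
  u <- tibble::tibble(
    unit_id = paste0("u", 1:5),
    treatment = c(1, 1, 0, 0, 0),
    outcome = c(1, 1, 0, 1, 0),
    g = "x"
  )
  ms <- build_partitions(u)
  expect_s3_class(ms, "matched_set")
  expect_equal(nrow(ms), 1L)
  expect_equal(ms$n_t, 2)
  expect_equal(ms$n_c, 3)
  expect_equal(ms$n_t_pos, 2)
  expect_equal(ms$n_c_pos, 1)

  # treated-only and control-only signatures: no common support at all
  v <- tibble::tibble(
    unit_id = paste0("v", 1:4),
    treatment = c(1, 1, 0, 0),
    outcome = c(1, 0, 1, 0),
    g = c("A", "A", "B", "B")
  )
  expect_error(build_partitions(v), "common support", class = "rmn_validation_error")

  expect_error(build_partitions(u[0, ]), class = "rmn_validation_error")
  expect_error(
    build_partitions(tibble::tibble(unit_id = "a", treatment = 1, outcome = 0, x = 1.5)),
    "coarsen", class = "rmn_validation_error"
  )
})

test_that("planted signature structure is recovered with drops recorded", {
  gen <- generate_units(synthetic_config(
    n_partitions = 12, single_armed_frac = 0.25, seed = 3
  ))
  ms <- build_partitions(gen$units)
  expect_equal(nrow(ms), 12L)
  expect_equal(attr(ms, "n_dropped_partitions"), 3L)
  # conservation: kept + dropped units account for everything ingested
  expect_equal(sum(ms$n_t + ms$n_c) + attr(ms, "n_dropped_units"),
               nrow(gen$units))
})

test_that("partitioning is idempotent and signatures are exact", {
  gen <- generate_units(synthetic_config(n_partitions = 25, seed = 9))
  ms1 <- build_partitions(gen$units)
  # rebuild from the member units recovered out of the matched set
  members <- unlist(c(ms1$treated_ids, ms1$control_ids))
  ms2 <- build_partitions(dplyr::filter(gen$units, unit_id %in% members))
  expect_equal(ms1$key, ms2$key)
  expect_equal(ms1[c("n_t_pos", "n_t_neg", "n_c_pos", "n_c_neg")],
               ms2[c("n_t_pos", "n_t_neg", "n_c_pos", "n_c_neg")])

  # exactness: every member's signature equals its partition key
  sig <- setNames(paste(gen$units$stratum, gen$units$block, sep = "|"),
                  gen$units$unit_id)
  for (i in seq_len(nrow(ms1))) {
    ids <- c(ms1$treated_ids[[i]], ms1$control_ids[[i]])
    expect_true(all(sig[ids] == ms1$key[i]))
  }
})

test_that("tally_outcomes counts the four cells", {
  tl <- tally_outcomes(c(1, 1, 0), c(0, 1))
  expect_equal(unlist(tl), c(n_t_pos = 2, n_t_neg = 1, n_c_pos = 1, n_c_neg = 1))
  all_pos <- tally_outcomes(c(1, 1), c(1, 1, 1))
  expect_equal(all_pos$n_t_neg + all_pos$n_c_neg, 0)
  expect_error(tally_outcomes(numeric(), numeric()), class = "rmn_validation_error")
  expect_error(tally_outcomes(c(1, 2), 0), class = "rmn_validation_error")
})

test_that("degenerate planted outcome rates force one-sided tallies", {
  gen <- generate_units(synthetic_config(
    n_partitions = 6, p_treated = 1, p_control = 0, seed = 5
  ))
  ms <- build_partitions(gen$units)
  expect_true(all(ms$n_t_neg == 0))
  expect_true(all(ms$n_c_pos == 0))
})
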