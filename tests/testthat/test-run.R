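test_that("the end-to-end run writes the three reports and recovers planted capacities", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_partitions = 8, single_armed_frac = 0.25, seed = 21)
  sim <- simulate_units(cfg, file.path(dir, "sim"))
  expect_true(file.exists(sim$units_path))
  expect_true(file.exists(sim$truth_path))

  out <- run_robust_test(sim$units_path, file.path(dir, "report"))
  expect_true(all(file.exists(unlist(out$paths))))

  planted <- planted_capacities(sim$generated$truth)
  expect_equal(out$capacities$b_max, planted$b_max)
  expect_equal(out$capacities$c_max, planted$c_max)

  decision <- readLines(out$paths$decision)
  expect_true(any(grepl(sprintf("^b_max: %g$", planted$b_max), decision)))
  cls <- sub("classification: ", "", grep("^classification:", decision, value = TRUE))
  expect_true(cls %in% c("absolute-robust", "alpha-robust-reject",
                         "alpha-robust-fail", "not-robust"))
  expect_length(cls, 1L)

  # profile file parses back and ends closed at the robustness condition
  prof <- readr::read_tsv(out$paths$profile, comment = "#", show_col_types = FALSE)
  expect_equal(max(prof$m), planted$b_max + planted$c_max)
  expect_equal(prof$lambda_min_2dp[nrow(prof)], prof$lambda_max_2dp[nrow(prof)])
})

test_that("reports are byte-stable for a fixed seed and configuration", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_partitions = 5, seed = 7)
  sim1 <- simulate_units(cfg, file.path(dir, "a"))
  sim2 <- simulate_units(cfg, file.path(dir, "b"))
  expect_identical(readLines(sim1$units_path), readLines(sim2$units_path))

  out1 <- run_robust_test(sim1$units_path, file.path(dir, "ra"))
  out2 <- run_robust_test(sim2$units_path, file.path(dir, "rb"))
  for (f in c("capacities", "profile", "decision")) {
    expect_identical(readLines(out1$paths[[f]]), readLines(out2$paths[[f]]))
  }
})

test_that("a planted single-partition cohort reproduces the published-scale report", {
  dir <- withr::local_tempdir()
  # one partition whose tallies realise capacities (12082, 9448)
  tallies <- tibble::tibble(key = "site", n_t_pos = 9448, n_t_neg = 12082,
                            n_c_pos = 12082, n_c_neg = 9448)
  path <- write_units_csv(units_from_tallies(tallies))
  out <- run_robust_test(path, dir, increment = 5000)
  expect_equal(out$result$m_robust, 21530)
  expect_equal(round(out$result$statistic, 2), 17.94)
  decision <- readLines(out$paths$decision)
  expect_true(any(grepl("lambda_robust: 17.94", decision, fixed = TRUE)))
  expect_true(any(grepl("m_robust: 21530", decision, fixed = TRUE)))
})

test_that("invalid inputs fail with typed conditions and write nothing", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.csv")
  writeLines("id,treatment,outcome", empty)
  expect_error(run_robust_test(empty, file.path(dir, "r1")),
               class = "rmn_validation_error")
  expect_false(dir.exists(file.path(dir, "r1")))
  expect_error(run_robust_test(file.path(dir, "nope.csv"), file.path(dir, "r2")),
               class = "rmn_io_error")
})

test_that("run configuration files parse into schemes and settings", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "columns:",
    "  id: id",
    "  treatment: treatment",
    "  outcome: outcome",
    "alpha: 0.01",
    "increment: 10",
    "covariates:",
    "  sex: categorical",
    "  age:",
    "    breaks: [0, 21, 31, 41, 51, 65, .inf]",
    "    labels: ['0-20', '21-30', '31-40', '41-50', '51-65', '65 and above']"
  ), cfg_path)
  cfg <- read_run_config(cfg_path)
  expect_equal(cfg$alpha, 0.01)
  expect_equal(cfg$increment, 10)
  expect_s3_class(cfg$scheme, "coarsening_scheme")
  expect_equal(cfg$scheme$age$breaks[7], Inf)
  expect_error(read_run_config(file.path(tempdir(), "missing.yaml")),
               class = "rmn_io_error")
})

test_that("the command-line script runs a simulate/run round trip", {
  script <- system.file("cli", "robust-mcnemar.R", package = "rmcnemar")
  expect_true(nzchar(script))
  dir <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  sim_status <- system2(rscript, c(script, "simulate", "--partitions", "4",
                                   "--seed", "5", "--out", file.path(dir, "sim")),
                        stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "sim", "units.csv")))
  run_status <- system2(rscript, c(script, "run", "--input",
                                   file.path(dir, "sim", "units.csv"),
                                   "--out", file.path(dir, "rep")),
                        stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "rep", "decision.txt")))
  # validation failures exit non-zero
  bad <- system2(rscript, c(script, "run", "--input", file.path(dir, "nope.csv"),
                            "--out", file.path(dir, "rep2")),
                 stdout = NULL, stderr = NULL)
  expect_gt(bad, 0)
})
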