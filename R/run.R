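# End-to-end front end: CSV + coarsening config in, report files out. This is
# the surface the command-line script (inst/cli/robust-mcnemar.R) wraps.

#' Read a run configuration file
#'
#' The YAML configuration holds the column map (`columns: {id, treatment,
#' outcome}`), the coarsening scheme (`covariates:` with `categorical` or
#' `{breaks: [...], labels: [...]}` per covariate), and optionally `alpha`,
#' `increment` or `m_grid`.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `columns`, `scheme`, `alpha`, `increment`,
#'   `m_grid` (absent entries take package defaults).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("Config file does not exist: '%s'", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort_io(sprintf("Failed to parse '%s': %s",
                                                       path, conditionMessage(e))))
  scheme <- NULL
  if (!is.null(cfg$covariates)) {
    rules <- lapply(cfg$covariates, function(rule) {
      if (identical(rule, "categorical")) return(rule_categorical())
      if (is.list(rule) && !is.null(rule$breaks) && !is.null(rule$labels)) {
        breaks <- vapply(rule$breaks, function(b) {
          if (identical(b, ".inf") || identical(b, "Inf")) Inf else as.numeric(b)
        }, numeric(1))
        return(rule_bins(breaks, rule$labels))
      }
      abort_validation("Each covariate rule must be 'categorical' or have breaks + labels.")
    })
    scheme <- do.call(coarsening_scheme, rules)
  }
  list(
    columns = cfg$columns %||% list(),
    scheme = scheme,
    alpha = cfg$alpha %||% 0.05,
    increment = cfg$increment,
    m_grid = cfg$m_grid
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the robust test end-to-end from a CSV file
#'
#' Reads unit-level data, optionally coarsens covariates, builds exact-match
#' partitions, computes capacities, the uncertainty profile and the
#' absolute-robust test, and writes three report files to `output_dir`:
#' `capacities.tsv` (per-partition and aggregate capacities),
#' `uncertainty_profile.tsv` (the sweep, two-decimal display columns next to
#' full-precision ones) and `decision.txt` (the test result). Profile files
#' carry a comment header with a configuration hash so a report can be tied
#' to the run that produced it.
#'
#' @param input Path to the unit CSV.
#' @param output_dir Directory for report files (created if needed).
#' @param columns Optional list overriding column names: `id`, `treatment`,
#'   `outcome`.
#' @param scheme Optional [coarsening_scheme()]; `NULL` treats all covariates
#'   as already categorical.
#' @param alpha Significance level.
#' @param increment,m_grid Passed to [uncertainty_profile()].
#' @param verbose Print progress messages.
#' @return Invisibly, a list with the `robust_mcnemar` result, the profile,
#'   the capacity set, the matched set and the report file paths.
#' @export
run_robust_test <- function(input, output_dir, columns = list(), scheme = NULL,
                            alpha = 0.05, increment = NULL, m_grid = NULL,
                            verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  units <- read_units(
    input,
    id = columns$id %||% "id",
    treatment = columns$treatment %||% "treatment",
    outcome = columns$outcome %||% "outcome"
  )
  say("read %d units from %s", nrow(units), input)
  if (!is.null(scheme)) units <- coarsen(units, scheme)
  matched <- build_partitions(units)
  say("built %d partitions (%d units dropped for lack of common support)",
      nrow(matched), attr(matched, "n_dropped_units"))
  caps <- aggregate_capacities(matched)
  profile <- uncertainty_profile(caps, increment = increment, m_grid = m_grid,
                                 alpha = alpha)
  result <- robust_mcnemar_test(caps, alpha = alpha)

  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  cfg_hash <- rlang::hash(list(input = basename(input), columns = columns,
                               alpha = alpha, increment = increment, m_grid = m_grid))
  header <- c(
    sprintf("# rmcnemar %s", as.character(utils::packageVersion("rmcnemar"))),
    sprintf("# config_hash: %s", cfg_hash)
  )
  paths <- list(
    capacities = file.path(output_dir, "capacities.tsv"),
    profile = file.path(output_dir, "uncertainty_profile.tsv"),
    decision = file.path(output_dir, "decision.txt")
  )

  cap_tab <- tidy(caps)
  writeLines(c(
    header,
    sprintf("# partitions: %d\ttreated: %d\tcontrol: %d\tdropped_units: %d",
            nrow(matched), sum(matched$n_t), sum(matched$n_c),
            attr(matched, "n_dropped_units")),
    sprintf("# b_max: %g\tc_max: %g\tm_robust: %g\tmax_pairs: %g",
            caps$b_max, caps$c_max, caps$b_max + caps$c_max, caps$max_pairs),
    paste(names(cap_tab), collapse = "\t"),
    apply(cap_tab, 1, paste, collapse = "\t")
  ), paths$capacities)

  prof_tab <- tibble::as_tibble(profile) |>
    dplyr::mutate(
      lambda_min_2dp = sprintf("%.2f", .data$lambda_min),
      lambda_max_2dp = sprintf("%.2f", .data$lambda_max)
    )
  writeLines(c(
    header,
    paste(names(prof_tab), collapse = "\t"),
    apply(prof_tab, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                         collapse = "\t"))
  ), paths$profile)

  writeLines(c(
    header,
    sprintf("b_max: %g", caps$b_max),
    sprintf("c_max: %g", caps$c_max),
    sprintf("m_robust: %g", result$m_robust),
    sprintf("lambda_robust: %.2f", result$statistic),
    sprintf("lambda_robust_full: %.15g", result$statistic),
    sprintf("p_one_sided: %.6g", result$p_value),
    sprintf("p_two_sided: %.6g", result$p_two_sided),
    sprintf("alpha: %g", alpha),
    sprintf("classification: %s", result$classification)
  ), paths$decision)

  say("finished in %.2f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(result = result, profile = profile, capacities = caps,
                 matched_set = matched, paths = paths))
}

#' Write a synthetic dataset and its ground truth to disk
#'
#' Thin wrapper over [generate_units()] that writes `units.csv` (the dialect
#' [read_units()] consumes) and `ground_truth.yaml` (planted tallies and
#' configuration) into `output_dir`.
#'
#' @param config A [synthetic_config()].
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, a list with `units_path`, `truth_path` and the
#'   generated object.
#' @export
simulate_units <- function(config, output_dir) {
  gen <- generate_units(config)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  units_path <- file.path(output_dir, "units.csv")
  truth_path <- file.path(output_dir, "ground_truth.yaml")
  out <- gen$units |> dplyr::rename(id = "unit_id")
  readr::write_csv(out, units_path)
  yaml::write_yaml(list(
    n_single_armed = gen$truth$n_single_armed,
    seed = gen$truth$config$seed,
    tallies = lapply(seq_len(nrow(gen$truth$tallies)), function(i) {
      as.list(gen$truth$tallies[i, ])
    })
  ), truth_path)
  invisible(list(units_path = units_path, truth_path = truth_path, generated = gen))
}
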