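#' Read unit-level data from a CSV file
#'
#' Reads one row per observational unit: an identifier, a binary treatment
#' indicator (1 = treated / post-policy), a binary outcome, and any number of
#' covariate columns. Treatment and outcome must parse as integers 0/1; rows
#' violating this are reported by unit id and the read is rejected, since a
#' silently dropped unit would change the good-match set downstream.
#'
#' @param path Path to a comma-separated file with a header row.
#' @param id,treatment,outcome Names of the identifier, treatment and outcome
#'   columns in the file. Defaults `"id"`, `"treatment"`, `"outcome"`.
#' @param covariates Character vector of covariate column names. `NULL`
#'   (default) takes every column other than id/treatment/outcome.
#'
#' @return A tibble with columns `unit_id`, `treatment`, `outcome` followed by
#'   the covariate columns, one row per unit. The number of rows read is
#'   attached as attribute `n_read`.
#'
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,treatment,outcome,sex", "u1,0,1,F", "u2,1,0,M"), f)
#' read_units(f)
#' @export
read_units <- function(path, id = "id", treatment = "treatment",
                       outcome = "outcome", covariates = NULL) {
  if (!file.exists(path)) {
    abort_io(sprintf("Input file does not exist: '%s'", path))
  }
  raw <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_io(sprintf("Failed to read '%s': %s", path, conditionMessage(e)))
  )
  if (nrow(raw) == 0L) {
    abort_validation(sprintf("Input file '%s' contains no data rows.", path))
  }
  for (col in c(id, treatment, outcome)) {
    if (!col %in% names(raw)) {
      abort_validation(sprintf("Required column '%s' is missing from '%s'.", col, path))
    }
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(raw), c(id, treatment, outcome))
  } else {
    missing_cov <- setdiff(covariates, names(raw))
    if (length(missing_cov)) {
      abort_validation(sprintf(
        "Covariate column(s) not found: %s", paste0("'", missing_cov, "'", collapse = ", ")
      ))
    }
  }
  units <- tibble::tibble(
    unit_id = as.character(raw[[id]]),
    treatment = suppressWarnings(as.numeric(raw[[treatment]])),
    outcome = suppressWarnings(as.numeric(raw[[outcome]]))
  )
  units <- dplyr::bind_cols(units, raw[covariates])
  validate_units(units)
  attr(units, "n_read") <- nrow(raw)
  units
}

#' Validate a unit table
#'
#' Checks the contract every downstream operation relies on: treatment and
#' outcome are exactly 0 or 1 and unit ids are unique. Used by [read_units()]
#' and available directly for data assembled in R.
#'
#' @param units A data frame with columns `unit_id`, `treatment`, `outcome`.
#' @return `units`, invisibly, if valid; otherwise an error naming the
#'   offending unit ids.
#' @export
validate_units <- function(units) {
  for (col in c("unit_id", "treatment", "outcome")) {
    if (!col %in% names(units)) {
      abort_validation(sprintf("Unit table lacks required column '%s'.", col))
    }
  }
  bad_t <- !is_binary01(units$treatment)
  bad_y <- !is_binary01(units$outcome)
  if (any(bad_t) || any(bad_y)) {
    offenders <- units$unit_id[bad_t | bad_y]
    abort_validation(sprintf(
      "Treatment and outcome must be 0 or 1; invalid value(s) for unit(s): %s",
      paste(utils::head(offenders, 10L), collapse = ", ")
    ))
  }
  if (anyNA(units$unit_id) || anyDuplicated(units$unit_id)) {
    dups <- unique(units$unit_id[duplicated(units$unit_id)])
    abort_validation(sprintf(
      "Unit ids must be unique and non-missing; duplicated: %s",
      paste(utils::head(dups, 10L), collapse = ", ")
    ))
  }
  invisible(units)
}
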