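#' Coarsening rules and schemes
#'
#' Exact matching on a continuous covariate is hopeless, so continuous
#' covariates are first coarsened into ordered bands and the bands are matched
#' exactly (coarsened exact matching). A scheme holds one rule per covariate:
#' either pass-through for an already-categorical covariate, or a set of bin
#' boundaries mapping a numeric covariate to a band label.
#'
#' Bins are left-closed/right-open: a value `x` falls in bin `i` when
#' `breaks[i] <= x < breaks[i + 1]`. Declare an open-ended last band with
#' `Inf` as the final break. Values outside every bin are rejected rather than
#' clamped, because silently reassigning a unit would alter the match set.
#'
#' @param breaks Strictly increasing numeric boundaries, length
#'   `length(labels) + 1`.
#' @param labels Character labels, one per bin.
#' @param ... For [coarsening_scheme()], named rules, one per covariate.
#'
#' @return `rule_categorical()` and `rule_bins()` return rule objects;
#'   `coarsening_scheme()` returns a named list of rules with class
#'   `"coarsening_scheme"`.
#'
#' @examples
#' scheme <- coarsening_scheme(
#'   sex = rule_categorical(),
#'   age = rule_bins(c(0, 21, 31, 41, 51, 65, Inf),
#'                   c("0-20", "21-30", "31-40", "41-50", "51-65", "65 and above"))
#' )
#' @export
rule_bins <- function(breaks, labels) {
  breaks <- as.numeric(breaks)
  if (length(breaks) != length(labels) + 1L) {
    abort_validation("`breaks` must have exactly one more element than `labels`.")
  }
  if (any(diff(breaks) <= 0)) {
    abort_validation("Bin boundaries must be strictly increasing.")
  }
  structure(list(type = "bins", breaks = breaks, labels = as.character(labels)),
            class = "rmn_rule")
}

#' @rdname rule_bins
#' @export
rule_categorical <- function() {
  structure(list(type = "categorical"), class = "rmn_rule")
}

#' @rdname rule_bins
#' @export
coarsening_scheme <- function(...) {
  rules <- list(...)
  if (length(rules) && (is.null(names(rules)) || any(names(rules) == ""))) {
    abort_validation("Every rule in a coarsening scheme must be named after a covariate.")
  }
  if (!all(vapply(rules, inherits, logical(1), "rmn_rule"))) {
    abort_validation("Scheme entries must be rule_categorical() or rule_bins() rules.")
  }
  structure(rules, class = "coarsening_scheme")
}

apply_rule <- function(x, rule, covariate) {
  if (rule$type == "categorical") {
    if (anyNA(x)) {
      abort_validation(sprintf("Covariate '%s' has missing values; missing covariates are rejected.", covariate))
    }
    return(as.character(x))
  }
  x <- as.numeric(x)
  if (anyNA(x)) {
    abort_validation(sprintf("Covariate '%s' has missing or non-numeric values.", covariate))
  }
  # findInterval implements the left-closed/right-open convention directly
  idx <- findInterval(x, rule$breaks)
  out_of_range <- idx < 1L | idx > length(rule$labels) |
    (is.finite(rule$breaks[length(rule$breaks)]) & x >= rule$breaks[length(rule$breaks)])
  list(labels = rule$labels[idx], out_of_range = out_of_range)
}

#' Coarsen unit covariates to categorical bands
#'
#' Applies a [coarsening_scheme()] to a unit table: categorical covariates
#' pass through unchanged, numeric covariates are replaced by their band
#' label. The result is a unit table whose covariates are all categorical and
#' can be matched exactly by [build_partitions()].
#'
#' @param units A unit table (see [read_units()]).
#' @param scheme A [coarsening_scheme()] covering every covariate column in
#'   `units`.
#' @return A tibble like `units` with every covariate column character-valued.
#' @examples
#' u <- tibble::tibble(unit_id = c("a", "b"), treatment = c(0, 1),
#'                     outcome = c(1, 0), age = c(67, 34))
#' scheme <- coarsening_scheme(age = rule_bins(
#'   c(0, 21, 31, 41, 51, 65, Inf),
#'   c("0-20", "21-30", "31-40", "41-50", "51-65", "65 and above")))
#' coarsen(u, scheme)
#' @export
coarsen <- function(units, scheme) {
  validate_units(units)
  if (!inherits(scheme, "coarsening_scheme")) {
    abort_validation("`scheme` must be a coarsening_scheme().")
  }
  covs <- setdiff(names(units), c("unit_id", "treatment", "outcome"))
  uncovered <- setdiff(covs, names(scheme))
  if (length(uncovered)) {
    abort_validation(sprintf(
      "Scheme has no rule for covariate(s): %s", paste0("'", uncovered, "'", collapse = ", ")
    ))
  }
  out <- units
  for (cov in covs) {
    res <- apply_rule(units[[cov]], scheme[[cov]], cov)
    if (is.list(res)) {
      if (any(res$out_of_range)) {
        bad <- units$unit_id[res$out_of_range]
        abort_validation(sprintf(
          "Covariate '%s' out of the configured bins for unit(s): %s",
          cov, paste(utils::head(bad, 10L), collapse = ", ")
        ))
      }
      out[[cov]] <- res$labels
    } else {
      out[[cov]] <- res
    }
  }
  out
}
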