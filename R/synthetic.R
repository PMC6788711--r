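#' Configuration for the partition-structured generator
#'
#' Describes a synthetic matched-cohort dataset: a number of two-armed
#' exact-match groups, per-group arm sizes (fixed or sampled from a range),
#' per-arm probabilities of a positive outcome, and optionally some
#' single-armed signatures planted to exercise common-support dropping.
#' Outcome probabilities are constant within a group — the exchangeability
#' that the closed-form extrema exploit.
#'
#' @param n_partitions Number of two-armed groups to generate (>= 1).
#' @param n_treated,n_control Arm sizes: a single count, or a length-2 range
#'   `c(lo, hi)` sampled per group.
#' @param p_treated,p_control Probability of a positive outcome per arm:
#'   a scalar, or a vector of length `n_partitions`.
#' @param single_armed_frac Fraction (of `n_partitions`) of extra signatures
#'   generated with only one arm.
#' @param seed Integer seed; a fixed seed reproduces the dataset exactly.
#' @return A `synthetic_config` list.
#' @examples
#' synthetic_config(n_partitions = 5, seed = 7)
#' @export
synthetic_config <- function(n_partitions, n_treated = c(2, 6), n_control = c(2, 6),
                             p_treated = 0.5, p_control = 0.5,
                             single_armed_frac = 0, seed = 1) {
  check_count(n_partitions, "n_partitions")
  if (n_partitions < 1) abort_validation("`n_partitions` must be >= 1.")
  for (nm in c("n_treated", "n_control")) {
    v <- get(nm)
    check_count(v, nm)
    if (!length(v) %in% 1:2 || any(v < 0) || (length(v) == 2 && v[2] < v[1])) {
      abort_validation(sprintf("`%s` must be a count or an increasing range c(lo, hi).", nm))
    }
  }
  for (nm in c("p_treated", "p_control")) {
    v <- get(nm)
    if (any(v < 0) || any(v > 1) || !length(v) %in% c(1L, n_partitions)) {
      abort_validation(sprintf(
        "`%s` must be probabilities in [0, 1], length 1 or n_partitions.", nm
      ))
    }
  }
  if (single_armed_frac < 0 || single_armed_frac > 1) {
    abort_validation("`single_armed_frac` must lie in [0, 1].")
  }
  n_single <- round(single_armed_frac * n_partitions)
  if (n_partitions + n_single > 9999) {
    abort_validation("At most 9999 signatures are supported by the label alphabet.")
  }
  structure(
    list(n_partitions = as.integer(n_partitions),
         n_treated = as.integer(n_treated), n_control = as.integer(n_control),
         p_treated = p_treated, p_control = p_control,
         n_single_armed = as.integer(n_single), seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

draw_size <- function(range) {
  if (length(range) == 1L) range else sample(range[1]:range[2], 1L)
}

#' Generate a unit table with known partition structure
#'
#' Draws a unit-level dataset realising exactly the configured number of
#' two-armed covariate signatures (plus any planted single-armed ones) with
#' Bernoulli outcomes per arm. Alongside the units it returns a ground-truth
#' record — per-group tallies kept at draw time — so the analysis path can be
#' cross-validated against what was planted. The generator uses R's default
#' Mersenne-Twister stream; a fixed seed gives an identical table.
#'
#' @param config A [synthetic_config()].
#' @return A list with `units` (tibble: `unit_id`, `treatment`, `outcome`,
#'   covariates `stratum` and `block`) and `truth` (list: `tallies` tibble
#'   with per-group outcome counts, `n_single_armed`, `config`).
#' @examples
#' gen <- generate_units(synthetic_config(3, seed = 7))
#' gen$truth$tallies
#' @export
generate_units <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort_validation("`config` must come from synthetic_config().")
  }
  set.seed(config$seed)
  n_all <- config$n_partitions + config$n_single_armed
  strata <- sprintf("P%04d", seq_len(n_all))
  blocks <- sample(LETTERS[1:4], n_all, replace = TRUE)
  p_t <- rep_len(config$p_treated, config$n_partitions)
  p_c <- rep_len(config$p_control, config$n_partitions)

  rows <- vector("list", n_all)
  tallies <- vector("list", config$n_partitions)
  uid <- 0L
  mk <- function(n, trt, p) {
    y <- stats::rbinom(n, 1L, p)
    ids <- sprintf("u%06d", uid + seq_len(n))
    uid <<- uid + n
    list(ids = ids, treatment = rep(trt, n), outcome = y)
  }
  for (i in seq_len(config$n_partitions)) {
    nt <- draw_size(config$n_treated)
    nc <- draw_size(config$n_control)
    # two-armed groups need at least one unit per arm to survive partitioning
    nt <- max(nt, 1L); nc <- max(nc, 1L)
    t_arm <- mk(nt, 1L, p_t[i])
    c_arm <- mk(nc, 0L, p_c[i])
    rows[[i]] <- tibble::tibble(
      unit_id = c(t_arm$ids, c_arm$ids),
      treatment = c(t_arm$treatment, c_arm$treatment),
      outcome = c(t_arm$outcome, c_arm$outcome),
      stratum = strata[i], block = blocks[i]
    )
    tallies[[i]] <- tibble::tibble(
      stratum = strata[i], block = blocks[i],
      n_t_pos = sum(t_arm$outcome == 1), n_t_neg = sum(t_arm$outcome == 0),
      n_c_pos = sum(c_arm$outcome == 1), n_c_neg = sum(c_arm$outcome == 0)
    )
  }
  for (k in seq_len(config$n_single_armed)) {
    i <- config$n_partitions + k
    trt <- as.integer(k %% 2L == 0L) # alternate treated-only / control-only
    arm <- mk(max(1L, draw_size(config$n_treated)), trt, 0.5)
    rows[[i]] <- tibble::tibble(
      unit_id = arm$ids, treatment = arm$treatment, outcome = arm$outcome,
      stratum = strata[i], block = blocks[i]
    )
  }
  list(
    units = dplyr::bind_rows(rows),
    truth = list(
      tallies = dplyr::bind_rows(tallies),
      n_single_armed = config$n_single_armed,
      config = config
    )
  )
}

#' Planted capacities from a generator ground-truth record
#'
#' Recomputes the discordant capacities and concordant fills from the
#' tallies the generator recorded at draw time, using its own scalar
#' arithmetic rather than the analysis path, so the two routes can be
#' compared on every generated dataset.
#'
#' @param truth The `truth` element returned by [generate_units()].
#' @return A `capacity_set`.
#' @export
planted_capacities <- function(truth) {
  tl <- truth$tallies
  if (is.null(tl) || nrow(tl) == 0L) {
    return(capacity_set(0, 0, per_partition = tibble::tibble(
      key = character(), b_cap = numeric(), c_cap = numeric(),
      a_cap = numeric(), d_cap = numeric(), max_pairs = numeric()
    )))
  }
  n <- nrow(tl)
  b <- c <- a <- d <- mp <- numeric(n)
  for (i in seq_len(n)) {
    # deliberately element-wise and branch-based, independent of pmin()
    b[i] <- if (tl$n_t_neg[i] < tl$n_c_pos[i]) tl$n_t_neg[i] else tl$n_c_pos[i]
    c[i] <- if (tl$n_t_pos[i] < tl$n_c_neg[i]) tl$n_t_pos[i] else tl$n_c_neg[i]
    ra <- tl$n_t_pos[i] - c[i]; rb <- tl$n_c_pos[i] - b[i]
    a[i] <- if (ra < rb) ra else rb
    rd <- tl$n_t_neg[i] - b[i]; rc <- tl$n_c_neg[i] - c[i]
    d[i] <- if (rd < rc) rd else rc
    nt <- tl$n_t_pos[i] + tl$n_t_neg[i]; ncn <- tl$n_c_pos[i] + tl$n_c_neg[i]
    mp[i] <- if (nt < ncn) nt else ncn
  }
  per <- tibble::tibble(
    key = paste(tl$stratum, tl$block, sep = "|"),
    b_cap = b, c_cap = c, a_cap = a, d_cap = d, max_pairs = mp
  )
  capacity_set(sum(b), sum(c), per_partition = per)
}

hrrp_marginals <- function() {
  list(
    gender = c("Female" = 49.80, "Male" = 50.20),
    income = c("Quartile 1" = 24.77, "Quartile 2" = 24.99,
               "Quartile 3" = 24.79, "Quartile 4" = 25.45),
    diagnosis = c("CHF" = 55.40, "AMI" = 13.20, "Pneumonia" = 31.40),
    teaching = c("Teaching Hospital" = 11.30, "Non-teaching Hospital" = 88.70),
    ownership = c("Non-profit Hospital" = 64.70, "Investor Hospital" = 19.80,
                  "Public Hospital" = 15.50),
    size = c("Small" = 5.50, "Medium" = 67.60, "Large" = 26.90),
    location = c("Rural" = 2.68, "Metro" = 97.32)
  )
}

# age bands and their draw ranges; band shares from the readmitted-cohort table
hrrp_age_bands <- function() {
  tibble::tibble(
    lo = c(0, 21, 31, 41, 51, 65),
    hi = c(20, 30, 40, 50, 64, 95),
    share = c(0.70, 1.18, 2.41, 7.00, 23.21, 65.49)
  )
}

hrrp_charlson_bands <- function() {
  tibble::tibble(
    lo = c(0, 3, 7, 11),
    hi = c(2, 6, 10, 15),
    share = c(39.09, 56.65, 3.75, 0.51)
  )
}

#' Generate a readmission-policy-like synthetic cohort
#'
#' Emulates the covariate scheme of a hospital-readmission policy evaluation:
#' nine covariates (numeric age and comorbidity index; categorical gender,
#' income quartile, primary diagnosis, teaching status, ownership, hospital
#' size, location) with marginals approximating a large readmitted-patient
#' cohort. The treatment indicator marks the post-policy era (planted
#' treated share 37200/90553); the outcome is a non-index readmission
#' indicator drawn per arm. Covariate draws are independent across columns —
#' the real data's correlations are not emulated.
#'
#' @param seed Integer seed.
#' @param scale Total number of rows (>= 100).
#' @param p_treated_outcome,p_control_outcome Per-arm probability of a
#'   non-index readmission.
#' @return A unit tibble ready for [coarsen()] with
#'   [hrrp_coarsening_scheme()] and [build_partitions()].
#' @examples
#' units <- generate_hrrp_like(seed = 1, scale = 500)
#' @export
generate_hrrp_like <- function(seed, scale = 10000,
                               p_treated_outcome = 0.28,
                               p_control_outcome = 0.24) {
  check_count(scale, "scale")
  if (scale < 100) abort_validation("`scale` must be at least 100.")
  set.seed(seed)
  marg <- hrrp_marginals()
  draw_cat <- function(tab) sample(names(tab), scale, replace = TRUE, prob = tab)
  draw_band <- function(bands) {
    idx <- sample(seq_len(nrow(bands)), scale, replace = TRUE, prob = bands$share)
    bands$lo[idx] + floor(stats::runif(scale) * (bands$hi[idx] - bands$lo[idx] + 1))
  }
  treatment <- stats::rbinom(scale, 1L, 37200 / 90553)
  outcome <- stats::rbinom(scale, 1L,
                           ifelse(treatment == 1L, p_treated_outcome, p_control_outcome))
  tibble::tibble(
    unit_id = sprintf("h%06d", seq_len(scale)),
    treatment = treatment,
    outcome = outcome,
    age = draw_band(hrrp_age_bands()),
    gender = draw_cat(marg$gender),
    income = draw_cat(marg$income),
    diagnosis = draw_cat(marg$diagnosis),
    charlson = draw_band(hrrp_charlson_bands()),
    teaching = draw_cat(marg$teaching),
    ownership = draw_cat(marg$ownership),
    hospital_size = draw_cat(marg$size),
    location = draw_cat(marg$location)
  )
}

#' Coarsening scheme matching the readmission-like cohort
#'
#' Age is banded into six groups and the comorbidity index into four; the
#' remaining covariates pass through. Bands are left-closed/right-open with
#' an open-ended top band, so 65 falls in "65 and above".
#'
#' @return A [coarsening_scheme()].
#' @export
hrrp_coarsening_scheme <- function() {
  coarsening_scheme(
    age = rule_bins(c(0, 21, 31, 41, 51, 65, Inf),
                    c("0-20", "21-30", "31-40", "41-50", "51-65", "65 and above")),
    gender = rule_categorical(),
    income = rule_categorical(),
    diagnosis = rule_categorical(),
    charlson = rule_bins(c(0, 3, 7, 11, Inf),
                         c("Low", "Medium", "Medium High", "High")),
    teaching = rule_categorical(),
    ownership = rule_categorical(),
    hospital_size = rule_categorical(),
    location = rule_categorical()
  )
}
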