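---
title: "Matching-independent McNemar tests: model, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching-independent McNemar tests: model, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmcnemar)
library(dplyr)
```

## The problem

In a one-to-one matched observational study with a binary outcome, the
McNemar statistic is computed from the discordant matched pairs: `B` pairs
where the treated member had outcome 0 and its control had outcome 1, and
`C` pairs with the reverse pattern. With the continuity correction the
statistic is

\[ \Lambda = \frac{B - C - 1}{\sqrt{B + C}}, \]

approximately standard normal under the null of no causal effect, defined
whenever at least one discordant pair exists.

The trouble is that `B` and `C` are not functions of the data alone: they
depend on *which* admissible pairing the matching algorithm picked. Two
analysts who match the same cohort with different (equally defensible)
algorithms can land on different sides of the significance threshold. The
remedy implemented here is to treat the pairing as the adversary: compute
the exact maximum and minimum of \(\Lambda\) over *every* admissible
one-to-one assignment, and report conclusions only where the whole range
agrees.

## From an assignment program to counting

Admissibility is encoded as exact-match partitions: after coarsening,
units sharing a covariate signature form a cell in which any treated unit
may be paired with any control unit, and pairs never cross cells. Units of
equal arm and outcome within a cell are exchangeable, so an assignment is
fully described by how many pairs of each of the four outcome patterns it
forms. Per cell, the largest attainable discordant counts are

\[ B^p = \min(n^p_{t-}, n^p_{c+}), \qquad C^p = \min(n^p_{t+}, n^p_{c-}), \]

and because the two types draw on disjoint unit pools both are achieved
simultaneously. Summing over cells gives the aggregate capacities
\(B_{\max}\) and \(C_{\max}\). The leftover units fill the concordant
cells to their limit,
\(A^p = \min(n^p_{t+} - C^p,\; n^p_{c+} - B^p)\) and
\(D^p = \min(n^p_{t-} - B^p,\; n^p_{c-} - C^p)\), and the four counts
always exhaust the cell's pairing capacity
\(B^p + C^p + A^p + D^p = \min(N^p_t, N^p_c)\) — `aggregate_capacities()`
reports all of these.

With the total discordant count fixed at `m`, \(\Lambda\) is strictly
increasing in `B` and non-increasing in `C`, so the extremisation
collapses to a counting rule (`optimal_discordant_split()`): the maximum
puts `min(m, B_max)` pairs into `B`, the minimum puts `min(m, C_max)` into
`C`, the remainder spills into the other type. Feasibility requires
\(1 \le m \le B_{\max} + C_{\max}\). At the upper end both rules are forced
to \((B_{\max}, C_{\max})\), the envelope closes, and the statistic value
there — the *absolute-robust* statistic computed by
`robust_mcnemar_test()` — cannot be moved by any choice of pairing. When
both capacities are positive this is the **only** `m` at which the
envelope closes; if one capacity is zero the envelope is flat everywhere,
which is why that degenerate case is documented rather than asserted in
the equality-only-at-the-top property test.

```{r}
caps <- capacity_set(b_max = 12082, c_max = 9448)
robust_mcnemar_test(caps)
uncertainty_profile(caps, m_grid = c(100, 10000, 19000, 21000)) |>
  as_tibble() |>
  select(m, lambda_min, lambda_max, p_low, p_high, classification)
```

A published analysis of a hospital readmission-penalty policy with these
capacities is reproduced by the sweep above: at `m = 19000` the attainable
one-sided p-values span essentially 0 to 0.23 — an honest account of how
much the pairing choice could have mattered — while from about 20,000
discordant pairs onward every admissible pairing rejects, and at
`m = 21530` the statistic is pinned at 17.94. Two cells of that study's
printed profile (the maximum at `m = 1000` and at `m = 20000`) contradict
the closed form that the study's own monotonicity results imply (likely
typesetting slips); this package reproduces the closed form, and those two
cells are deliberately not matched.

## Decision rule

`robust_decision()` classifies a test from the two extreme p-values:
*absolute-robust* when they coincide, *alpha-robust-reject* when both are
at or below \(\alpha\), *alpha-robust-fail* when both exceed it, and
*not-robust* when they straddle \(\alpha\) — the case in which the
published conclusion would have depended on the matching algorithm.

## Tunable parameters

* **`alpha`** (default 0.05): the significance level of the study being
  audited; only the classification depends on it.
* **p-value sidedness**: the reference distribution behind the published
  p-values is not stated in the source analyses; the one-sided upper tail
  of the standard normal is the default because the alternative there is
  directional (the policy *increases* the outcome rate) and because it is
  the convention that reproduces the published 0.23 bound. Two-sided
  values are always computed alongside.
* **`increment` / `m_grid`** in `uncertainty_profile()`: the default
  increment keeps the grid at no more than 200 rows and always appends
  `m = B_max + C_max`, so the profile always ends at the closed envelope.
* **Coarsening bins** are left-closed/right-open with an optional
  open-ended top band (`Inf` break). Published covariate tables often
  print overlapping integer bands ("51–65", "65 and above"); the half-open
  convention resolves the shared boundary upward, so 65 falls in the top
  band. Out-of-range and missing values are rejected, not imputed or
  clamped: silently moving a unit changes the match set, which is the
  object under study.

## The exhaustive oracle

`enumerate_extrema()` and `oracle_profile()` provide ground truth for
small instances by enumerating every admissible assignment. The default
mode enumerates per-partition discordant splits \(0 \le b^p \le B^p\),
\(0 \le c^p \le C^p\) — equivalent to unit-level enumeration by
exchangeability and factorially smaller. A raw assignment-matrix mode
(`mode = "pairs"`, single partitions up to 4×4) double-checks that
equivalence. A size guard (12 units per arm overall, configurable) keeps
enumeration honest; the oracle exists to certify the closed form on small
instances, not to scale.

## The synthetic generators

No unit-level data from the motivating study is public, so the package
ships two seeded generators:

* `generate_units()` plants an exact partition structure: a configured
  number of two-armed signatures, arm sizes fixed or drawn from a range,
  Bernoulli outcomes with per-arm probabilities constant within a
  partition (the exchangeability the closed form exploits), and
  optionally single-armed signatures to exercise the common-support drop.
  It returns the drawn tallies as a ground-truth record, and
  `planted_capacities()` recomputes capacities from that record with
  separate arithmetic, so generator bookkeeping and the analysis path
  check each other.
* `generate_hrrp_like()` emulates the *shape* of a readmission-policy
  cohort: nine covariates with marginals matching a published
  readmitted-patient table (e.g. 55.4% of primary diagnoses are
  congestive heart failure), a post-policy treated share of 37200/90553,
  and per-arm non-index readmission rates defaulting to 0.24 (control)
  and 0.28 (treated) — chosen once to sit around the cohort's overall
  25.6% non-index share with the positive policy effect the study
  reports, since per-era outcome rates are not printed. Covariates are
  drawn independently across columns, so the fixture does **not**
  reproduce the real cohort's covariate correlations, its 1822 partitions
  or its 35,584 pairs. Tests passing on it certify the algebra and the
  pipeline, not epidemiological realism.

Both generators use R's default Mersenne-Twister stream; a fixed seed
reproduces a dataset byte for byte.

## Numerical choices and degenerate inputs

* The continuity-correction constant −1 is applied identically in both
  extremisation senses; it is part of the statistic, not a tuning knob.
* All statistic values are kept at full double precision; the two-decimal
  presentation used in reports is display-only (report files carry a
  full-precision column next to the rounded one).
* `b + c = 0` is rejected as undefined rather than returned as NaN;
  `m` outside \([1, B_{\max}+C_{\max}]\) raises a typed infeasibility
  error stating the range.
* Partition keys are the ordered tuple of coarsened labels over all
  configured covariates, joined in configuration order, and partitions are
  processed in sorted key order — reports are byte-stable for a fixed
  seed and configuration.
* Per-partition witness splits for audit fill the favoured discordant
  type in sorted key order; reallocating across partitions cannot change
  the aggregate counts, hence never the statistic.

## Problem sizes used in the test suite

The suite certifies the closed form against exhaustive enumeration on 200
random instances of up to 3 partitions with arms of up to 6 units —
chosen because enumeration is exact there and every feasible `m` can be
checked — and exercises conservation on 1,000 random tallies, the
monotonicity/reflection identities on a 200×200 lattice, generator
recovery on 50 seeded configurations, and cohort marginals at 10,000
rows. The published-scale sweep itself is closed-form counting and runs in
well under a second at `m_max = 21530`.

## Known limitations

* Only exact-partition admissibility is supported; caliper or other
  user-defined balance constraints must be applied upstream when
  constructing the unit table (any matching algorithm may do so — the
  test then audits the pairing freedom that remains).
* The test is a hypothesis test only; no effect-size (ATE/ATT) estimator
  is provided.
* p-values use the normal approximation with continuity correction; exact
  binomial McNemar p-values are out of scope.
* Continuous outcomes are out of scope.
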