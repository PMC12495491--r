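---
title: "A lifetime Markov cost-utility model for KRT initiation strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime Markov cost-utility model for KRT initiation strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The decision problem

In critically ill patients with severe acute kidney injury (AKI), kidney
replacement therapy (KRT, acute dialysis) can be started early
("accelerated") or only once a conventional indication develops
("standard"). The two strategies have similar 90-day mortality but differ
in longer-term dialysis dependence and in resource use, so the economically
relevant comparison is lifetime costs against lifetime quality-adjusted
life-years (QALYs). `krtcua` implements that comparison as a cohort-level
decision model, together with the machinery needed to run it without access
to the confidential patient-level data it was designed around: a synthetic
cohort generator, a parameter-estimation layer, a probabilistic sensitivity
analysis (PSA) engine, and reporting helpers.

# Model structure

The model has four mutually exclusive health states assessed from kidney
function and treatment:

* **no CKD** — alive, estimated glomerular filtration rate (eGFR) >= 60
  mL/min/1.73 m²;
* **CKD, not KRT dependent** — alive, eGFR < 60, no dialysis;
* **alive and KRT dependent** — receiving dialysis (dialysis dominates the
  eGFR reading);
* **dead** — absorbing.

The classification boundary places eGFR = 60 in the no-CKD state. The model
starts at day 90 after randomization (cycle 0) and runs 480 monthly cycles
(40 years), long enough for the cohort to be fully absorbed into the dead
state; `run_deterministic()` verifies > 99.9% absorption in the base case.
Cycle-0 occupancy is built from the arm's 90-day survival (68.5%
accelerated, 78.1% standard) and the KRT-dependence share among survivors
(2.1% / 9.8%). Two structural choices here are the package's own:

* **The dead fraction is part of the starting vector.** Model outputs are
  therefore unconditional per-randomized-patient expectations rather than
  survivor-conditional ones. This reading is inferred from the published
  per-arm QALYs: dividing them by 90-day survival gives nearly identical
  survivor-conditional values in the two arms, which is what one expects if
  the printed values are unconditional means. The inference is configurable
  — pass any starting vector to `run_cohort()`.
* **The no-CKD / CKD split of the remaining survivors is a parameter**
  (`nockd_share`, default 0.5). The published material reports survival and
  KRT dependence but not this split; base-case state occupancy (and hence
  costs and QALYs) depends on it, so it is exposed in
  `default_parameters()` rather than buried.

# Transition probabilities

Static monthly probabilities (recovery from CKD to no CKD — the only
arm-specific transition — CKD onset of dialysis, and movements out of the
KRT state) enter each cycle's matrix directly; the diagonal absorbs the
remainder and the dead row is fixed at (0, 0, 0, 1). The published table
reports each probability both as a mean and as beta shape parameters, and
the two disagree in the third decimal for several transition rows (e.g.
mean 0.139 vs 0.396/2.875 = 0.1377). The package resolves this by using
**printed means for deterministic runs and shape parameters for PSA
sampling**, and does not attempt to reconcile them.

The three death probabilities (means 0.022, 0.030, 0.033 per month) and the
no-CKD-to-CKD onset probability (mean 0.001) are time dependent, but only
their mean and range are published. `generate_mortality_schedule()`
reconstructs a per-cycle vector as a log-linear (Gompertz-like) increasing
curve from the range minimum toward the maximum, rescaled by a single
factor — found by root-finding with clamping to the published range — so
the vector mean matches the published mean (to ~1e-10, asserted at 1e-3).
Monotonicity is preserved by construction. When the published minimum is 0
(CKD onset), a small positive value (1e-6) replaces it before taking logs.
This shape is a modelling choice, not published fact: any increasing curve
with the right mean and range is equally compatible with the printed
summaries, which is the central reason the published lifetime totals are
not exactly reproducible (see *Limitations*).

When patient-level data are available instead, `classify_state()`,
`estimate_transition_matrix()` and `period_to_monthly()` estimate the
day-90 to day-365 period matrix as row-normalized transition counts and
convert it to monthly values with the constant-hazard formula
$p_m = 1 - (1 - p)^{1/9}$ applied per competing transition (renormalized in
the rare case the converted off-diagonals exceed 1). Rows with no day-90
occupants are flagged inestimable and the caller must supply a fallback —
there is no silent zero-filling. Note that the constant-hazard
back-conversion is a convention, not an inverse: with competing risks and
return transitions, the monthly matrix whose 9th power equals the period
matrix is not the entrywise converted one. Recovery tests therefore
validate the estimator against the matrix power of the generator's monthly
matrix, which is the quantity the data identify.

# Costs

Costs (2024 Canadian dollars, health-system perspective) are periodized the
way the cost data behaved: a one-time 0–90 day cost booked undiscounted at
cycle 0 (ICU-dominated, mean 182,626 / 161,601 CAD by arm), a distinct
month-4 cost applied at cycle 1, and a steady monthly cost applied
uniformly to every later cycle. The steady cost is extrapolated beyond the
first year for the remaining lifetime; the published description covers
costs only to one year, and uniform extrapolation is the natural reading of
applying them "to the remaining months". Each period total is split across
the three alive states by fixed shares — KRT dependent 71%, CKD 17%, no CKD
12% — so the per-cycle cost is the occupancy-weighted sum of state costs.
Accumulation uses end-of-cycle occupancy; a half-cycle correction
(averaging start- and end-of-cycle occupancy) is available via
`model_config(half_cycle_correction = TRUE)` but off by default, since at
monthly cycles its effect is negligible and the published methods do not
mention one.

Both costs and QALYs are discounted at 1.5% per year with the
annual-equivalent convention $(1.015)^{-t/12}$ for cycle $t$.

# Utilities and QALYs

State utilities (no CKD 0.85, CKD 0.74, KRT dependent 0.60; dead 0) weight
time in state: each cycle contributes occupancy-weighted utility times 1/12
year, discounted. The utility beta shapes imply means of 0.8475, 0.7349 and
0.5989; the CKD value rounds to 0.73 rather than the printed 0.74, a
one-printed-unit inconsistency the package simply records (tests assert
agreement within 0.01).

# Probabilistic sensitivity analysis

`run_psa()` draws 5000 parameter sets by default:

* utilities and static transition probabilities from their published beta
  shapes;
* cost parameters from gamma distributions fitted by method of moments
  (`fit_gamma_mom()`; a zero SD degenerates to the constant);
* per-cycle time-dependent probabilities from per-cycle beta distributions
  fitted by moments to the output of a schedule-uncertainty simulation:
  the schedule-level mean is drawn from a beta around its published value,
  the schedule recalibrated per draw, and the resulting cycles-by-draws
  matrix summarized into per-cycle means and SDs
  (`simulate_schedule_uncertainty()`, `summarize_schedule_draws()`). Where
  a cycle's moments are beta-infeasible, a [0,1]-truncated normal is used
  instead and the fallback is counted in the result and the run manifest.

Two sampling choices matter and are deliberate:

* **Coherent schedule draws.** Within one PSA draw, all 480 cycles of one
  time-dependent parameter share a single uniform quantile, so a draw
  represents a coherently high- or low-mortality trajectory while each
  cycle keeps its fitted marginal. Sampling cycles independently would
  average the noise away within every draw and collapse the between-draw
  QALY spread to nearly zero, which is inconsistent with the published
  QALY SDs of about 1.8–2.0.
* **Common random numbers across arms.** Arms share the draws of every
  common parameter (utilities, death schedules, shared statics), and the
  arm-specific cost cells share their quantiles across arms (comonotone
  gamma draws); only the arm-specific recovery probability is sampled
  independently per arm. Means are untouched, but the Monte Carlo error of
  the increments no longer carries the full spread of two independent
  heavy-tailed cost draws — without this, the sign of the equal-cost
  scenario's incremental cost (whose magnitude is a few thousand CAD
  against a per-arm cost SD near 200,000) would be seed noise at 5000
  draws.
* **Schedule-level uncertainty defaults to a CV of 0.5**, the order of the
  binomial standard error of a 2–3% monthly risk estimated from the 50–70
  patients observed per state in a 146-patient cohort. It is configurable
  (`model_config(schedule_cv = )`).

Starting distributions are fixed, not sampled: no sampling distribution is
published for them, and the starting-state question is explored by scenario
instead.

Results are summarized as per-arm means and SDs over draws, increments
(standard minus accelerated), the ICER of mean increments (ratio-of-means,
with southwest/northeast dominance flags from `compute_icer()`), the
incremental net monetary benefit at 50,000 CAD/QALY, and the
cost-effectiveness acceptability curve over a 0–100,000 grid in steps of
1,000, with `ceac_threshold()` interpolating the 0.5 crossing. Two interval
conventions are reported for the INMB: the 2.5th–97.5th percentile of the
draw distribution (`inmb_cri`), and a normal-approximation interval on the
*mean* INMB (`inmb_cri_mean`). The published intervals' half-widths equal
$1.96\,\mathrm{SD}/\sqrt{5000}$ for all three analyses, i.e. they are
intervals on the mean, so the rendered results table uses that convention;
the percentile interval is the honest statement of decision uncertainty
and is retained alongside.

# Scenarios

* `scenario_start_states()` replaces the KRT-dependence shares among
  90-day survivors with the trial-wide 10.4% / 6.0% while keeping local
  survival, isolating the effect of the starting mix.
* `scenario_equal_costs()` sets both arms' month-4 and steady monthly cost
  parameters to their unweighted two-arm average (SDs averaged likewise),
  leaving the 0–90 day costs unchanged. "Equal monthly costs" is not
  further specified in the source; the pooled average is the default and
  `pool_monthly_costs()` is exposed so alternatives (e.g. adopting one
  arm's values) can be constructed directly.

# The synthetic cohort generator

`generate_cohort()` emulates the linked trial/administrative records the
analysis consumes: per-arm 90-day survival and KRT dependence, a
`nockd_share` split of the remaining survivors, truncated-normal eGFR
values on either side of the 60 boundary (only the classification matters
downstream, so the within-side shape is a free choice), beta-distributed
utilities by state, gamma-distributed 0–90 day and month-4 costs by method
of moments, and day-365 states simulated cycle-by-cycle over 9 monthly
steps of the configured transition matrix (one transition per patient per
cycle), so estimator recovery can be checked against a matrix-power oracle.

The steady monthly cost is state-linked: state means are proportional to
$\text{share}_s / \hat\pi_s$ (target cost share over realized occupancy),
with a common coefficient of variation, so the cohort's cost shares and the
overall monthly mean hit their targets. The overall monthly SD is *not* a
target for this period: with realistic occupancies, the between-state
spread implied by the 71/17/12 shares already exceeds the published total
variance, so no within-state variance can reconcile both. The 0–90 day and
month-4 costs carry no state link and match both mean and SD.

What the generator does **not** emulate: correlation between cost and
severity within a state, per-patient cost autocorrelation over months,
site-level heterogeneity, censoring or loss to follow-up, and utility
missingness patterns. Tests passing on synthetic data therefore validate
the estimation and modelling machinery, not the clinical conclusions.

# Numerical and degenerate-input conventions

* Method-of-moments fitters are exact inverses of the forward moment maps
  on their feasible domains (`fit_beta_mom()` rejects
  $\sigma^2 \ge m(1-m)$; `fit_gamma_mom()` rejects nonpositive moments);
  both reproduce their inputs to 1e-9 in tests.
* Schedule calibration uses `stats::uniroot` at tolerance 1e-12; the
  uncertainty simulation inverts the factor–mean map by monotone
  interpolation on a 400-point grid, and a zero CV returns the calibrated
  schedule exactly.
* Zero-SD cost specifications emit constants everywhere.
* PSA cycle matrices renormalize a row's off-diagonals if sampled values
  sum past 1 (possible in late cycles for extreme draws); deterministic
  construction treats that as an error naming the row, since point
  estimates should never trigger it.
* CSV exports print doubles with `%.17g`, making cohort and trace
  round-trips lossless.

# Problem sizes

Unit tests run reduced configurations (60–240 cycles, 200–500 PSA draws,
cohorts of a few thousand) chosen to exercise every code path; the
full-scale checks — 10⁵ patients per arm for parameter recovery and
5000-draw, 480-cycle PSA runs for the directional comparisons — run in the
acceptance suite. The analysis scripts use 5 × 10⁴ patients per arm and
5000 draws.

# Limitations

The published lifetime results cannot be reproduced exactly from published
inputs: the time-dependent death schedules are summarized only as mean and
range (their shape is unidentified), the no-CKD/CKD starting split is
unpublished, and the utility/transition tables carry internal rounding
inconsistencies noted above. Under this package's reconstruction the model
reproduces every sign and ordering of the published analysis — standard
initiation costs more and yields more QALYs in the base case and
starting-state scenario, and dominates under equal monthly costs — with an
ICER of the same order as the published value; the absolute QALY totals run
higher, consistent with a front-loaded-low mortality reconstruction.
Survivor utilities are state-constant (no age decline), steady monthly
costs are extrapolated indefinitely, and no value-of-information analysis
is provided.
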