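# Time-dependent transition-probability schedules: construction, calibration
# to published mean/range summaries, and uncertainty simulation.

# raw log-linear (Gompertz-like) increasing curve from lo to hi over n cycles;
# a zero lower bound is replaced by a small positive start before taking logs
schedule_shape <- function(lo, hi, n_cycles) {
  if (lo <= 0) lo <- min(1e-6, hi / 1000)
  if (hi < lo) stop("schedule range must have min <= max")
  if (hi == lo) return(rep(lo, n_cycles))
  exp(seq(log(lo), log(hi), length.out = n_cycles))
}

# mean of the clamped, scaled shape as a function of the scale factor
.sched_mean <- function(f, shape, lo, hi) mean(pmin(pmax(f * shape, lo), hi))

#' Calibrate a time-dependent probability schedule
#'
#' Builds the per-cycle probability vector for a transition summarized in the
#' published tables only as a mean and a range: a log-linear increasing curve
#' from `min_p` toward `max_p`, rescaled by a single calibration factor and
#' clamped to `[min_p, max_p]`, with the factor chosen so the vector mean
#' equals `mean_target` (within 1e-3; in practice to ~1e-10 via root
#' finding). The result is monotone nondecreasing.
#'
#' @param mean_target target mean of the schedule, in `[min_p, max_p]`.
#' @param min_p,max_p bounds of the schedule, `0 <= min_p <= max_p <= 1`.
#' @param n_cycles schedule length (default 480).
#' @return List of class `mortality_schedule`: `p` (length `n_cycles`),
#'   `calibration_factor`, `mean_target`, `min_p`, `max_p`.
#' @export
generate_mortality_schedule <- function(mean_target, min_p, max_p,
                                        n_cycles = 480L) {
  if (min_p < 0 || max_p > 1 || min_p > max_p) {
    stop("require 0 <= min_p <= max_p <= 1")
  }
  if (mean_target < min_p || mean_target > max_p) {
    stop("calibration error: mean_target outside [min_p, max_p]")
  }
  shape <- schedule_shape(min_p, max_p, n_cycles)
  if (max_p == min_p) {
    out <- list(p = shape, calibration_factor = 1, mean_target = mean_target,
                min_p = min_p, max_p = max_p)
    class(out) <- c("mortality_schedule", "list")
    return(out)
  }
  g <- function(lf) .sched_mean(exp(lf), shape, min_p, max_p) - mean_target
  lo <- log(min_p / max(shape)); hi <- log(max(1, max_p / min(shape[shape > 0])))
  if (!is.finite(lo)) lo <- -30
  f <- exp(stats::uniroot(g, c(lo - 1, hi + 1), tol = 1e-12)$root)
  p <- pmin(pmax(f * shape, min_p), max_p)
  if (abs(mean(p) - mean_target) > 1e-3) {
    stop("calibration error: could not match target mean")
  }
  out <- list(p = p, calibration_factor = f, mean_target = mean_target,
              min_p = min_p, max_p = max_p)
  class(out) <- c("mortality_schedule", "list")
  out
}

#' Simulate schedule-level uncertainty
#'
#' Generates `n_sims` realizations of a time-dependent probability schedule
#' by drawing the schedule-level mean from a beta distribution (method of
#' moments at the published mean with coefficient of variation `cv`,
#' truncated to the feasible `[min_p, max_p]` interval) and recalibrating the
#' log-linear schedule for each draw. The result is a cycles-by-simulations
#' matrix whose per-cycle mean and SD define the per-cycle sampling
#' distributions used in probabilistic sensitivity analysis.
#'
#' @param mean_target,min_p,max_p,n_cycles as in
#'   [generate_mortality_schedule()].
#' @param n_sims number of simulated schedules (default 5000).
#' @param cv coefficient of variation of the schedule-level mean.
#' @return `n_cycles` x `n_sims` matrix.
#' @export
simulate_schedule_uncertainty <- function(mean_target, min_p, max_p,
                                          n_cycles = 480L, n_sims = 5000L,
                                          cv = 0.5) {
  stopifnot(n_sims >= 2)
  sd <- cv * mean_target
  if (sd == 0) { # degenerate: every simulation is the calibrated schedule
    p <- generate_mortality_schedule(mean_target, min_p, max_p, n_cycles)$p
    return(matrix(p, nrow = n_cycles, ncol = n_sims))
  }
  means <- if (sd > 0 && sd^2 < mean_target * (1 - mean_target)) {
    spec <- fit_beta_mom(mean_target, sd)
    stats::rbeta(n_sims, spec$alpha, spec$beta)
  } else {
    rep(mean_target, n_sims)
  }
  means <- pmin(pmax(means, min_p), max_p)
  shape <- schedule_shape(min_p, max_p, n_cycles)
  # invert factor -> mean once on a log-factor grid, then interpolate
  lf_grid <- seq(-25, 5, length.out = 400)
  m_grid <- vapply(lf_grid, function(lf) .sched_mean(exp(lf), shape, min_p, max_p), 0.0)
  keep <- c(TRUE, diff(m_grid) > 1e-15) # strictly increasing part
  lf <- stats::approx(m_grid[keep], lf_grid[keep], xout = means, rule = 2)$y
  out <- vapply(exp(lf), function(f) pmin(pmax(f * shape, min_p), max_p),
                numeric(n_cycles))
  matrix(out, nrow = n_cycles, ncol = n_sims)
}

#' Per-cycle moments of simulated schedules
#'
#' @param draws cycles x simulations matrix from
#'   [simulate_schedule_uncertainty()].
#' @return data.frame with columns cycle, mean, sd.
#' @export
summarize_schedule_draws <- function(draws) {
  data.frame(cycle = seq_len(nrow(draws)),
             mean = rowMeans(draws),
             sd = apply(draws, 1, stats::sd))
}
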