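# Four-state monthly-cycle Markov cohort engine: cycle matrices, trace
# propagation, discounting, cost and QALY accumulation.

#' Calibrated time-dependent schedules for a parameter set
#'
#' Calibrates the four time-dependent transition schedules (no CKD -> CKD,
#' and the three state-specific death probabilities) to their published
#' mean/range summaries via [generate_mortality_schedule()]. Death schedules
#' are arm independent.
#'
#' @param params `krt_params` list.
#' @param n_cycles schedule length.
#' @return Named list of `mortality_schedule` objects keyed
#'   `"<from>.<to>"`.
#' @export
calibrated_schedules <- function(params, n_cycles = 480L) {
  td <- params$trans_time_dep
  out <- lapply(seq_len(nrow(td)), function(i) {
    generate_mortality_schedule(td$mean[i], td$min[i], td$max[i], n_cycles)
  })
  names(out) <- paste(td$from, td$to, sep = ".")
  out
}

# static monthly off-diagonal probabilities for one arm (point means)
static_probs <- function(params, arm) {
  ts <- params$trans_static
  ts <- ts[ts$arm %in% c("both", arm), ]
  p <- matrix(0, 4, 4, dimnames = list(health_states(), health_states()))
  for (k in seq_len(nrow(ts))) p[ts$from[k], ts$to[k]] <- ts$mean[k]
  p
}

#' Build the transition matrix for one cycle
#'
#' Combines the static monthly probabilities (point means; the CKD -> no-CKD
#' recovery is arm specific) with the cycle's time-dependent death and
#' no-CKD -> CKD probabilities. The diagonal absorbs the remainder, and the
#' DEAD row is the absorbing (0, 0, 0, 1).
#'
#' @param params `krt_params` list.
#' @param arm `"accelerated"` or `"standard"`.
#' @param cycle cycle index, 1-based, in `1..n_cycles`.
#' @param schedules output of [calibrated_schedules()]; computed on the fly
#'   if NULL (pass precomputed schedules when building many cycles).
#' @param n_cycles schedule length when `schedules` is NULL.
#' @return 4x4 row-stochastic matrix.
#' @export
build_cycle_matrix <- function(params, arm, cycle, schedules = NULL,
                               n_cycles = 480L) {
  if (is.null(schedules)) schedules <- calibrated_schedules(params, n_cycles)
  if (cycle < 1 || cycle > length(schedules[[1]]$p)) stop("cycle out of range")
  m <- static_probs(params, arm)
  m["NO_CKD", "CKD_NO_KRT"] <- schedules[["NO_CKD.CKD_NO_KRT"]]$p[cycle]
  m["NO_CKD", "DEAD"] <- schedules[["NO_CKD.DEAD"]]$p[cycle]
  m["CKD_NO_KRT", "DEAD"] <- schedules[["CKD_NO_KRT.DEAD"]]$p[cycle]
  m["KRT_DEPENDENT", "DEAD"] <- schedules[["KRT_DEPENDENT.DEAD"]]$p[cycle]
  for (i in 1:3) {
    off <- sum(m[i, -i])
    if (off > 1) {
      stop("infeasible transition row '", health_states()[i],
           "': off-diagonal probabilities sum to ", signif(off, 4))
    }
    m[i, i] <- 1 - off
  }
  m["DEAD", ] <- c(0, 0, 0, 1)
  m
}

#' Propagate a cohort through per-cycle transition matrices
#'
#' @param start occupancy vector over the 4 states (nonnegative, sums to 1).
#' @param matrices a list of 4x4 matrices (one per cycle) or a 4x4xn array.
#' @return `markov_trace`: an (n_cycles + 1) x 4 occupancy matrix; row 1 is
#'   the starting distribution.
#' @export
run_cohort <- function(start, matrices) {
  if (is.array(matrices) && length(dim(matrices)) == 3) {
    matrices <- lapply(seq_len(dim(matrices)[3]), function(i) matrices[, , i])
  }
  stopifnot(length(start) == 4, all(start >= 0),
            abs(sum(start) - 1) < 1e-9)
  n <- length(matrices)
  trace <- matrix(NA_real_, n + 1, 4,
                  dimnames = list(NULL, health_states()))
  trace[1, ] <- start
  v <- as.numeric(start)
  for (t in seq_len(n)) {
    M <- matrices[[t]]
    if (!all(dim(M) == c(4, 4))) stop("dimension mismatch: matrix ", t)
    v <- as.numeric(v %*% M)
    trace[t + 1, ] <- v
  }
  class(trace) <- c("markov_trace", class(trace))
  trace
}

#' Discount factor for a cycle
#'
#' Annual-equivalent convention: `(1 + rate)^(-cycle * cycle_length)`.
#'
#' @param rate_annual annual discount rate.
#' @param cycle cycle index (0 = model start).
#' @param cycle_length cycle length in years.
#' @return numeric factor (vectorized over `cycle`).
#' @export
discount_factor <- function(rate_annual, cycle, cycle_length = 1 / 12) {
  if (any(cycle < 0)) stop("cycle must be >= 0")
  (1 + rate_annual)^(-cycle * cycle_length)
}

# per-cycle occupancy used for accumulation: end-of-cycle rows, or the
# start/end average under half-cycle correction
cycle_occupancy <- function(trace, config) {
  n <- nrow(trace) - 1L
  occ <- trace[1L + seq_len(n), , drop = FALSE]
  if (config$half_cycle_correction) {
    occ <- (occ + trace[seq_len(n), , drop = FALSE]) / 2
  }
  occ
}

#' Accumulate discounted costs over a trace
#'
#' Cost periodization: the one-time 0-90 day cost is booked undiscounted at
#' cycle 0; cycle 1 (days 91-120) applies the month-4 state costs; every
#' later cycle applies the steady monthly state costs, occupancy-weighted
#' and discounted. The dead state contributes nothing.
#'
#' @param trace `markov_trace`.
#' @param cost_inputs list with `one_time` (scalar), `month4` and `monthly`
#'   (each a named vector of costs for NO_CKD, CKD_NO_KRT, KRT_DEPENDENT);
#'   see [deterministic_cost_inputs()].
#' @param config `krt_config`.
#' @return expected discounted cost per randomized patient (CAD).
#' @export
accumulate_costs <- function(trace, cost_inputs, config) {
  st <- c("NO_CKD", "CKD_NO_KRT", "KRT_DEPENDENT")
  for (nm in c("month4", "monthly")) {
    if (!all(st %in% names(cost_inputs[[nm]]))) {
      stop("missing state cost in '", nm, "'")
    }
  }
  occ <- cycle_occupancy(trace, config)
  n <- nrow(occ)
  df <- discount_factor(config$discount_rate_annual, seq_len(n),
                        config$cycle_length)
  state_cost <- matrix(0, n, 3)
  state_cost[1, ] <- cost_inputs$month4[st]
  if (n > 1) {
    state_cost[2:n, ] <- matrix(cost_inputs$monthly[st], n - 1, 3, byrow = TRUE)
  }
  cost_inputs$one_time + sum(rowSums(occ[, st, drop = FALSE] * state_cost) * df)
}

#' Accumulate discounted QALYs over a trace
#'
#' Each cycle contributes occupancy-weighted state utility times the cycle
#' length in years, discounted; the dead state has utility 0.
#'
#' @param trace `markov_trace`.
#' @param utilities named utilities for NO_CKD, CKD_NO_KRT, KRT_DEPENDENT,
#'   each in \[0, 1\].
#' @param config `krt_config`.
#' @return expected discounted QALYs per randomized patient.
#' @export
accumulate_qalys <- function(trace, utilities, config) {
  st <- c("NO_CKD", "CKD_NO_KRT", "KRT_DEPENDENT")
  u <- utilities[st]
  if (any(is.na(u)) || any(u < 0) || any(u > 1)) {
    stop("utilities must be present and in [0, 1]")
  }
  occ <- cycle_occupancy(trace, config)
  n <- nrow(occ)
  df <- discount_factor(config$discount_rate_annual, seq_len(n),
                        config$cycle_length)
  sum((occ[, st, drop = FALSE] %*% u) * df) * config$cycle_length
}

#' Deterministic cost inputs for one arm
#'
#' Builds the `cost_inputs` list for [accumulate_costs()] from a parameter
#' set: the 0-90 day total mean as the one-time cost and the state-share
#' decomposition of the month-4 and steady monthly totals.
#'
#' @param params `krt_params` list.
#' @param arm arm label.
#' @return list(one_time, month4, monthly).
#' @export
deterministic_cost_inputs <- function(params, arm) {
  one <- params$costs_total[params$costs_total$arm == arm &
                            params$costs_total$period == "d0_90", "mean"]
  as_vec <- function(period) {
    sc <- state_costs(params, arm, period)
    stats::setNames(sc$mean, sc$state)
  }
  list(one_time = one, month4 = as_vec("d91_120"), monthly = as_vec("gt120"))
}

#' Run the deterministic lifetime model for one arm
#'
#' Point-estimate run: calibrated schedules, printed-mean statics and
#' utilities, state-share cost decomposition.
#'
#' @param params `krt_params` list.
#' @param config `krt_config`.
#' @param arm arm label.
#' @param schedules optional precomputed [calibrated_schedules()].
#' @param start optional starting distribution override.
#' @return list(arm, trace, cost, qalys).
#' @export
run_deterministic <- function(params, config = model_config(), arm,
                              schedules = NULL, start = NULL) {
  if (is.null(schedules)) schedules <- calibrated_schedules(params, config$n_cycles)
  if (is.null(start)) start <- starting_distribution(params, arm)
  mats <- lapply(seq_len(config$n_cycles), function(t) {
    build_cycle_matrix(params, arm, t, schedules)
  })
  trace <- run_cohort(start, mats)
  u <- stats::setNames(params$utilities$mean, params$utilities$state)
  list(arm = arm,
       trace = trace,
       cost = accumulate_costs(trace, deterministic_cost_inputs(params, arm),
                               config),
       qalys = accumulate_qalys(trace, u, config))
}
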