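# Parameter estimation: state classification, transition matrices,
# method-of-moments distribution fitting, cost summaries.

#' Classify a patient observation into a health state
#'
#' Vectorized. KRT status dominates eGFR; the eGFR >= 60 boundary itself
#' classifies as no CKD.
#'
#' @param alive logical, alive at the time point.
#' @param krt logical, receiving kidney replacement therapy (only meaningful
#'   when alive).
#' @param egfr eGFR in mL/min/1.73 m2; may be NA for the dead or for KRT
#'   patients.
#' @return Character vector of state labels (see [health_states()]).
#' @export
classify_state <- function(alive, krt, egfr) {
  n <- max(length(alive), length(krt), length(egfr))
  alive <- rep_len(as.logical(alive), n)
  krt <- rep_len(as.logical(krt), n)
  egfr <- rep_len(as.numeric(egfr), n)
  need_egfr <- alive & !krt
  if (any(need_egfr & is.na(egfr))) {
    stop("classification error: alive patient without KRT has missing eGFR")
  }
  out <- character(n)
  out[!alive] <- "DEAD"
  out[alive & krt] <- "KRT_DEPENDENT"
  out[need_egfr & egfr >= 60] <- "NO_CKD"
  out[need_egfr & egfr < 60] <- "CKD_NO_KRT"
  out
}

#' Convert a period transition probability to a per-cycle value
#'
#' Constant-hazard conversion: `1 - (1 - p)^(1/n)`, the probability per cycle
#' that reproduces the period probability after `n` independent cycles.
#'
#' @param p_period probability over the whole period, in \[0, 1\].
#' @param n_cycles number of cycles in the period (>= 1).
#' @return per-cycle probability.
#' @export
period_to_monthly <- function(p_period, n_cycles) {
  if (any(p_period < 0 | p_period > 1)) stop("p_period must be in [0, 1]")
  if (any(n_cycles < 1)) stop("n_cycles must be >= 1")
  1 - (1 - p_period)^(1 / n_cycles)
}

#' Estimate the 4x4 transition matrix from paired state observations
#'
#' Counts transitions from day-90 to day-365 states, row-normalizes to the
#' period matrix (DEAD row forced to the absorbing (0,0,0,1)), and derives a
#' monthly matrix by applying the constant-hazard conversion to each
#' off-diagonal competing transition, renormalizing if the converted
#' off-diagonals exceed 1. Alive states with no day-90 occupants are flagged
#' as inestimable (`NA` rows), never silently zero-filled.
#'
#' @param state_t1,state_t2 character vectors of state labels at the two
#'   time points (same length).
#' @param n_cycles cycles between the time points (default 9, day 90 to 365).
#' @return List with `counts` (4x4 integer), `matrix_period`,
#'   `matrix_monthly` (4x4, rows of inestimable states are NA) and
#'   `inestimable` (character vector of flagged states).
#' @export
estimate_transition_matrix <- function(state_t1, state_t2, n_cycles = 9L) {
  st <- health_states()
  stopifnot(length(state_t1) == length(state_t2))
  if (!all(state_t1 %in% st) || !all(state_t2 %in% st)) {
    stop("unknown state label in input")
  }
  counts <- table(factor(state_t1, levels = st), factor(state_t2, levels = st))
  counts <- matrix(as.integer(counts), 4, 4, dimnames = list(st, st))
  period <- matrix(NA_real_, 4, 4, dimnames = list(st, st))
  inest <- character(0)
  for (i in 1:3) {
    n_i <- sum(counts[i, ])
    if (n_i == 0L) {
      inest <- c(inest, st[i])
    } else {
      period[i, ] <- counts[i, ] / n_i
    }
  }
  period["DEAD", ] <- c(0, 0, 0, 1)
  monthly <- period
  for (i in 1:3) {
    if (st[i] %in% inest) next
    off <- setdiff(1:4, i)
    m <- period_to_monthly(period[i, off], n_cycles)
    s <- sum(m)
    if (s > 1) m <- m / s # renormalize competing transitions
    monthly[i, off] <- m
    monthly[i, i] <- 1 - sum(m)
  }
  monthly["DEAD", ] <- c(0, 0, 0, 1)
  list(counts = counts, matrix_period = period, matrix_monthly = monthly,
       inestimable = inest)
}

# forward moment maps (used as oracles in tests and for round-trip checks)
beta_moments <- function(alpha, beta) {
  m <- alpha / (alpha + beta)
  v <- alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1))
  list(mean = m, sd = sqrt(v))
}

gamma_moments <- function(shape, scale) {
  list(mean = shape * scale, sd = sqrt(shape) * scale)
}

#' Fit a beta distribution by the method of moments
#'
#' Inverts the beta mean/variance map:
#' `alpha = m * (m(1-m)/s^2 - 1)`, `beta = (1-m) * (m(1-m)/s^2 - 1)`.
#' Only feasible when `s^2 < m(1-m)`.
#'
#' @param mean mean in (0, 1).
#' @param sd standard deviation, with `sd^2 < mean*(1-mean)`.
#' @return List of class `dist_spec`: family, alpha, beta, mean, sd.
#' @export
fit_beta_mom <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("beta mean must be in (0, 1)")
  v <- sd^2
  if (v <= 0) stop("beta sd must be > 0")
  if (v >= mean * (1 - mean)) {
    stop("moment infeasibility: sd^2 >= mean*(1-mean) for beta fit")
  }
  nu <- mean * (1 - mean) / v - 1
  spec <- list(family = "beta", alpha = mean * nu, beta = (1 - mean) * nu,
               mean = mean, sd = sd)
  class(spec) <- c("dist_spec", "list")
  spec
}

#' Fit a gamma distribution by the method of moments
#'
#' `shape = mean^2/sd^2`, `scale = sd^2/mean`; shape*scale reproduces the
#' mean exactly.
#'
#' @param mean mean > 0.
#' @param sd standard deviation > 0.
#' @return List of class `dist_spec`: family, shape, scale, mean, sd.
#' @export
fit_gamma_mom <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("gamma mean and sd must be > 0")
  spec <- list(family = "gamma", shape = mean^2 / sd^2, scale = sd^2 / mean,
               mean = mean, sd = sd)
  class(spec) <- c("dist_spec", "list")
  spec
}

#' Summarize periodized costs from patient-level records
#'
#' Per arm: mean/SD of the one-time 0-90 day cost (all randomized patients),
#' of the month-4 (days 91-120) cost (90-day survivors) and of the steady
#' monthly cost beyond day 120 (365-day survivors), plus the state-level
#' decomposition obtained by multiplying the period totals by the supplied
#' state shares.
#'
#' @param records cohort data.frame (see [generate_cohort()]).
#' @param state_shares named shares of monthly cost for KRT_DEPENDENT,
#'   CKD_NO_KRT and NO_CKD, summing to 1 (default 0.71/0.17/0.12).
#' @return List with `totals` (data.frame arm x period mean/sd) and
#'   `by_state` (data.frame arm x period x state).
#' @export
estimate_cost_params <- function(records,
                                 state_shares = c(KRT_DEPENDENT = 0.71,
                                                  CKD_NO_KRT = 0.17,
                                                  NO_CKD = 0.12)) {
  if (abs(sum(state_shares) - 1) > 1e-6) {
    stop("state_shares must sum to 1")
  }
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
  }
  rows <- list()
  for (arm in unique(records$arm)) {
    r <- records[records$arm == arm, ]
    rows[[length(rows) + 1L]] <- data.frame(
      arm = arm,
      period = c("d0_90", "d91_120", "gt120"),
      rbind(msd(r$cost_0_90),
            msd(r$cost_91_120[r$alive_90]),
            msd(r$monthly_cost_121_365[r$alive_365])),
      stringsAsFactors = FALSE)
  }
  totals <- do.call(rbind, rows)
  rownames(totals) <- NULL
  st <- c("NO_CKD", "CKD_NO_KRT", "KRT_DEPENDENT")
  by_state <- do.call(rbind, lapply(seq_len(nrow(totals)), function(i) {
    data.frame(arm = totals$arm[i], period = totals$period[i], state = st,
               mean = totals$mean[i] * unname(state_shares[st]),
               sd = totals$sd[i] * unname(state_shares[st]),
               stringsAsFactors = FALSE)
  }))
  by_state <- by_state[by_state$period != "d0_90", ]
  rownames(by_state) <- NULL
  list(totals = totals, by_state = by_state)
}

#' Share of monthly cost attributable to each alive state
#'
#' Fraction of total post-day-120 monthly cost incurred by patients in each
#' alive state at day 365. Returned in the order (KRT_DEPENDENT, CKD_NO_KRT,
#' NO_CKD), matching the published 71/17/12 convention.
#'
#' @param records cohort data.frame with day-365 states and monthly costs.
#' @return Named numeric vector of 3 shares summing to 1.
#' @export
compute_state_shares <- function(records) {
  alive <- records[records$alive_365 %in% TRUE, ]
  state <- classify_state(alive$alive_365, alive$krt_365, alive$egfr_365)
  cost <- alive$monthly_cost_121_365
  tot <- sum(cost, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) stop("undefined shares: zero total monthly cost")
  sh <- vapply(c("KRT_DEPENDENT", "CKD_NO_KRT", "NO_CKD"),
               function(s) sum(cost[state == s], na.rm = TRUE) / tot, 0.0)
  sh
}

#' Estimate a full parameter set from a patient-level cohort
#'
#' Fills the estimable parts of a `krt_params` object from records: static
#' monthly transition probabilities (from the day-90 to day-365 period matrix
#' via constant-hazard adjustment over 9 cycles), utility means/SDs by day-90
#' state with beta fits, and periodized costs. Quantities the two-time-point
#' records cannot identify (the time-dependent mortality schedules) are
#' carried over from `template`; inestimable transition rows fall back to the
#' template values and are reported in `$inestimable`.
#'
#' @param records cohort data.frame.
#' @param template `krt_params` providing structure and fallback values
#'   (default [default_parameters()]).
#' @param state_shares monthly-cost state shares passed to
#'   [estimate_cost_params()]; if NULL, computed from the records via
#'   [compute_state_shares()].
#' @return List with elements `params` (krt_params), `transitions` (per-arm
#'   output of [estimate_transition_matrix()]), `costs`, `state_shares`,
#'   `inestimable`.
#' @export
estimate_parameters <- function(records, template = default_parameters(),
                                state_shares = NULL) {
  if (is.null(state_shares)) {
    state_shares <- compute_state_shares(records)
  }
  trans <- list()
  inest <- list()
  params <- template
  for (arm in c("accelerated", "standard")) {
    r <- records[records$arm == arm, ]
    s1 <- classify_state(r$alive_90, r$krt_90, r$egfr_90)
    s2 <- classify_state(r$alive_365 %in% TRUE,
                         r$krt_365 %in% TRUE, r$egfr_365)
    est <- estimate_transition_matrix(s1, s2, n_cycles = 9L)
    trans[[arm]] <- est
    inest[[arm]] <- est$inestimable
    m <- est$matrix_monthly
    ts <- params$trans_static
    for (k in seq_len(nrow(ts))) {
      if (!(ts$arm[k] %in% c("both", arm))) next
      v <- m[ts$from[k], ts$to[k]]
      if (!is.na(v)) ts$mean[k] <- v
    }
    params$trans_static <- ts
  }
  # utilities: pooled across arms by day-90 state
  s90 <- classify_state(records$alive_90, records$krt_90, records$egfr_90)
  u <- params$utilities
  for (k in seq_len(nrow(u))) {
    x <- records$utility_90[s90 == u$state[k]]
    x <- x[!is.na(x)]
    if (length(x) > 1 && stats::sd(x) > 0) {
      fit <- try(fit_beta_mom(mean(x), stats::sd(x)), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        u$mean[k] <- fit$mean; u$alpha[k] <- fit$alpha; u$beta[k] <- fit$beta
      }
    }
  }
  params$utilities <- u
  costs <- estimate_cost_params(records, state_shares = state_shares)
  ct <- costs$totals
  params$costs_total <- ct[order(ct$arm, ct$period), ]
  params$state_shares <- state_shares
  list(params = params, transitions = trans, costs = costs,
       state_shares = state_shares, inestimable = inest)
}
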