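# Model parameters: health states, trial-derived inputs, configuration.

#' Health state labels
#'
#' The four states of the post-acute-kidney-injury Markov model, in the
#' canonical order used by every matrix and trace in the package:
#' no CKD (eGFR >= 60 mL/min/1.73 m2), CKD without kidney replacement therapy
#' (eGFR < 60), alive and KRT dependent, and dead (absorbing).
#'
#' @return Character vector of length 4.
#' @export
health_states <- function() {
  c("NO_CKD", "CKD_NO_KRT", "KRT_DEPENDENT", "DEAD")
}

# internal numeric codes
.ST <- c(NO_CKD = 1L, CKD_NO_KRT = 2L, KRT_DEPENDENT = 3L, DEAD = 4L)

#' Base-case model parameters
#'
#' Returns the full parameter set of the cost-utility analysis: state
#' utilities with their beta shape parameters, static monthly transition
#' probabilities with beta shapes (the CKD -> no-CKD recovery probability is
#' arm specific), time-dependent transition probabilities summarized as
#' mean and range (per-cycle schedules are calibrated from these by
#' [generate_mortality_schedule()]), periodized health-care costs per arm
#' (one-time 0-90 day cost, month-4 monthly cost, steady monthly cost beyond
#' day 120; 2024 Canadian dollars), the 71/17/12 split of monthly cost across
#' the three alive states, and the arm-specific starting-state inputs
#' (90-day survival and KRT dependence among survivors).
#'
#' Printed means are used for deterministic runs; the beta shape parameters
#' are used for probabilistic sampling (the two disagree in the third decimal
#' for some transition rows; see the methods vignette).
#'
#' @param nockd_share Share of non-KRT 90-day survivors starting in the
#'   no-CKD state (the NO_CKD / CKD_NO_KRT split of the remaining survivors
#'   is not identified by the published summaries; default 0.5).
#' @return A list of class `krt_params`.
#' @export
default_parameters <- function(nockd_share = 0.5) {
  p <- list(
    utilities = data.frame(
      state = c("NO_CKD", "CKD_NO_KRT", "KRT_DEPENDENT"),
      mean  = c(0.85, 0.74, 0.60),
      alpha = c(80.00, 49.90, 44.80),
      beta  = c(14.40, 18.00, 30.00),
      stringsAsFactors = FALSE
    ),
    # static monthly transition probabilities (arm = "both" unless split)
    trans_static = data.frame(
      from  = c("NO_CKD", "CKD_NO_KRT", "CKD_NO_KRT", "CKD_NO_KRT",
                "KRT_DEPENDENT", "KRT_DEPENDENT"),
      to    = c("KRT_DEPENDENT", "NO_CKD", "NO_CKD", "KRT_DEPENDENT",
                "NO_CKD", "CKD_NO_KRT"),
      arm   = c("both", "standard", "accelerated", "both", "both", "both"),
      mean  = c(0.001, 0.139, 0.063, 0.016, 0.073, 0.063),
      alpha = c(0.059, 0.396, 0.110, 0.064, 0.359, 0.036),
      beta  = c(56.413, 2.479, 1.659, 4.265, 4.379, 0.521),
      stringsAsFactors = FALSE
    ),
    # time-dependent monthly probabilities: mean (min-max) summaries
    trans_time_dep = data.frame(
      from = c("NO_CKD", "NO_CKD", "CKD_NO_KRT", "KRT_DEPENDENT"),
      to   = c("CKD_NO_KRT", "DEAD", "DEAD", "DEAD"),
      mean = c(0.001, 0.022, 0.030, 0.033),
      min  = c(0.000, 0.001, 0.003, 0.005),
      max  = c(0.017, 0.990, 0.990, 0.990),
      stringsAsFactors = FALSE
    ),
    # periodized total costs, mean (SD), CAD 2024
    costs_total = data.frame(
      arm    = rep(c("accelerated", "standard"), each = 3),
      period = rep(c("d0_90", "d91_120", "gt120"), 2),
      mean   = c(182626, 28486, 3293, 161601, 9141, 5558),
      sd     = c(175710, 126302, 4335, 104048, 25820, 8280),
      stringsAsFactors = FALSE
    ),
    # share of monthly cost by alive state: KRT-dependent, CKD, no CKD
    state_shares = c(KRT_DEPENDENT = 0.71, CKD_NO_KRT = 0.17, NO_CKD = 0.12),
    start = data.frame(
      arm = c("accelerated", "standard"),
      survival_90 = c(0.685, 0.781),
      krt_among_survivors = c(0.021, 0.098),
      nockd_share = c(nockd_share, nockd_share),
      stringsAsFactors = FALSE
    )
  )
  class(p) <- c("krt_params", "list")
  p
}

#' State-level periodized costs implied by a parameter set
#'
#' Applies the state-share decomposition of the published cost table: the
#' cost attached to each alive state for a period is the period's total mean
#' multiplied by that state's share of monthly cost (KRT dependent 71%,
#' CKD 17%, no CKD 12% in the base case). SDs are scaled by the same factor.
#'
#' @param params `krt_params` list.
#' @param arm `"accelerated"` or `"standard"`.
#' @param period `"d91_120"` (month 4) or `"gt120"` (steady monthly).
#' @return data.frame with columns state, mean, sd (3 rows, state order
#'   NO_CKD, CKD_NO_KRT, KRT_DEPENDENT).
#' @export
state_costs <- function(params, arm, period = c("d91_120", "gt120")) {
  period <- match.arg(period)
  row <- params$costs_total[params$costs_total$arm == arm &
                            params$costs_total$period == period, ]
  if (nrow(row) != 1L) stop("no cost row for arm '", arm, "' period '", period, "'")
  sh <- params$state_shares
  if (abs(sum(sh) - 1) > 1e-6) stop("state shares must sum to 1")
  st <- c("NO_CKD", "CKD_NO_KRT", "KRT_DEPENDENT")
  data.frame(state = st,
             mean = row$mean * unname(sh[st]),
             sd   = row$sd * unname(sh[st]),
             stringsAsFactors = FALSE)
}

#' Starting-state distribution for one arm
#'
#' The cycle-0 occupancy vector over the four states. It includes the dead
#' fraction (1 minus 90-day survival), so model outputs are unconditional
#' per-randomized-patient expectations. Among survivors, the KRT-dependent
#' share is applied first; the remaining survivors are split between no CKD
#' and CKD according to `nockd_share`.
#'
#' @param params `krt_params` list.
#' @param arm `"accelerated"` or `"standard"`.
#' @param krt_among_survivors Optional override of the KRT-dependent share
#'   among 90-day survivors (used by the starting-state scenario).
#' @return Named numeric vector of length 4 summing to 1.
#' @export
starting_distribution <- function(params, arm, krt_among_survivors = NULL) {
  row <- params$start[params$start$arm == arm, ]
  if (nrow(row) != 1L) stop("unknown arm '", arm, "'")
  krt <- if (is.null(krt_among_survivors)) row$krt_among_survivors else krt_among_survivors
  stopifnot(krt >= 0, krt <= 1)
  alive <- row$survival_90
  rest <- alive * (1 - krt)
  out <- c(NO_CKD = rest * row$nockd_share,
           CKD_NO_KRT = rest * (1 - row$nockd_share),
           KRT_DEPENDENT = alive * krt,
           DEAD = 1 - alive)
  stopifnot(abs(sum(out) - 1) < 1e-12)
  out
}

#' Model run configuration
#'
#' @param n_cycles Number of monthly cycles (default 480, i.e. 40 years).
#' @param cycle_length Cycle length in years (1/12).
#' @param discount_rate_annual Annual discount rate for costs and QALYs
#'   (default 0.015).
#' @param starting_age Cohort starting age in years at day 90 (default 61;
#'   recorded in the run manifest, mortality is calibrated to the published
#'   schedule summaries rather than looked up in a life table).
#' @param wtp Willingness-to-pay threshold, CAD per QALY (default 50000).
#' @param half_cycle_correction If TRUE, per-cycle cost/QALY accumulation
#'   weights the average of start- and end-of-cycle occupancy (default FALSE;
#'   negligible at monthly cycles).
#' @param lambda_grid Willingness-to-pay grid for the acceptability curve.
#' @param schedule_cv Coefficient of variation of the schedule-level mean in
#'   the time-dependent probability uncertainty simulation (default 0.5, the
#'   order of the binomial SE of a 2-3% monthly risk estimated from the
#'   50-70 patients observed per state).
#' @param n_schedule_sims Number of schedule simulations used to summarize
#'   per-cycle sampling distributions (default 5000).
#' @return A list of class `krt_config`.
#' @export
model_config <- function(n_cycles = 480L, cycle_length = 1 / 12,
                         discount_rate_annual = 0.015, starting_age = 61,
                         wtp = 50000, half_cycle_correction = FALSE,
                         lambda_grid = seq(0, 100000, by = 1000),
                         schedule_cv = 0.5, n_schedule_sims = 5000L) {
  stopifnot(n_cycles >= 1, discount_rate_annual >= 0, discount_rate_annual < 1,
            wtp > 0, cycle_length > 0)
  cfg <- list(n_cycles = as.integer(n_cycles), cycle_length = cycle_length,
              discount_rate_annual = discount_rate_annual,
              starting_age = starting_age, wtp = wtp,
              half_cycle_correction = isTRUE(half_cycle_correction),
              lambda_grid = lambda_grid, schedule_cv = schedule_cv,
              n_schedule_sims = as.integer(n_schedule_sims))
  class(cfg) <- c("krt_config", "list")
  cfg
}

#' Write / read model parameters
#'
#' Serializes a `krt_params` list to JSON or YAML (chosen by file
#' extension) and reads it back. Round-trips are lossless for the numeric
#' content.
#'
#' @param params `krt_params` list.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_parameters` returns a `krt_params` list.
#' @export
write_parameters <- function(params, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(params)
  if (ext == "json") {
    jsonlite::write_json(x, path, dataframe = "columns", auto_unbox = TRUE,
                         digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lapply(x, function(el)
      if (is.data.frame(el)) as.list(el) else as.list(el)), path)
  } else stop("unsupported parameter file extension: ", ext)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else stop("unsupported parameter file extension: ", ext)
  for (nm in c("utilities", "trans_static", "trans_time_dep", "costs_total",
               "start")) {
    x[[nm]] <- as.data.frame(x[[nm]], stringsAsFactors = FALSE)
  }
  x$state_shares <- unlist(x$state_shares)
  class(x) <- c("krt_params", "list")
  x
}
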