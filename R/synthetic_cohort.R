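# Synthetic trial-cohort generator: patient-level records with the
# statistical structure the downstream estimation and model assume, standing
# in for confidential linked trial/administrative data.

# monthly 4x4 transition matrix implied by a parameter set for one arm
# (static means + time-dependent means as constants over the 9-cycle window)
monthly_matrix_from_params <- function(params, arm) {
  m <- static_probs(params, arm)
  td <- params$trans_time_dep
  for (i in seq_len(nrow(td))) m[td$from[i], td$to[i]] <- td$mean[i]
  for (i in 1:3) m[i, i] <- 1 - sum(m[i, -i])
  m["DEAD", ] <- c(0, 0, 0, 1)
  if (any(m < 0)) stop("infeasible monthly matrix for arm ", arm)
  m
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions: 90-day survival 68.5% / 78.1%
#' (accelerated / standard), KRT dependence among survivors 2.1% / 9.8%,
#' a 50/50 split of the remaining survivors between no CKD and CKD,
#' gamma-distributed period costs with the published means/SDs,
#' beta-distributed utilities with the published shape parameters, and
#' day-90 to day-365 evolution simulated cycle-by-cycle over 9 monthly steps
#' with the published monthly transition probabilities.
#'
#' @param n_per_arm patients per arm (>= 0).
#' @param params `krt_params` supplying defaults for probabilities, costs
#'   and utilities.
#' @param seed RNG seed used by [generate_cohort()].
#' @param age_mean,age_sd per-arm age moments (years), named by arm.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_arm = 73L, params = default_parameters(),
                          seed = 1L,
                          age_mean = c(accelerated = 59.67, standard = 61.88),
                          age_sd = c(accelerated = 14.5, standard = 12.9)) {
  if (n_per_arm < 0) stop("n_per_arm must be >= 0")
  u <- params$utilities
  bm <- beta_moments(u$alpha, u$beta)
  cfg <- list(
    n_per_arm = as.integer(n_per_arm),
    survival_90 = stats::setNames(params$start$survival_90, params$start$arm),
    krt_among_survivors = stats::setNames(params$start$krt_among_survivors,
                                          params$start$arm),
    nockd_share = params$start$nockd_share[1],
    costs_total = params$costs_total,
    state_shares = params$state_shares,
    utility = data.frame(state = u$state, mean = bm$mean, sd = bm$sd,
                         stringsAsFactors = FALSE),
    monthly_matrix = list(
      accelerated = monthly_matrix_from_params(params, "accelerated"),
      standard = monthly_matrix_from_params(params, "standard")),
    age_mean = age_mean, age_sd = age_sd,
    seed = seed
  )
  probs <- c(cfg$survival_90, cfg$krt_among_survivors, cfg$nockd_share,
             unlist(cfg$monthly_matrix))
  if (any(probs < 0 | probs > 1)) stop("invalid probability in cohort config")
  if (any(cfg$costs_total$sd < 0)) stop("cost SDs must be >= 0")
  class(cfg) <- c("cohort_config", "list")
  cfg
}

# truncated normal via inverse-CDF
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

# gamma draw by method of moments; SD = 0 emits the constant
rgamma_mom <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  spec <- fit_gamma_mom(mean, sd)
  stats::rgamma(n, shape = spec$shape, scale = spec$scale)
}

# eGFR draws: only the >=60 / <60 classification matters downstream
regfr <- function(state) {
  n <- length(state)
  out <- rep(NA_real_, n)
  i <- state == 1L; out[i] <- rtruncnorm(sum(i), 75, 15, 60, 150)
  i <- state == 2L; out[i] <- rtruncnorm(sum(i), 45, 12, 5, 60 - 1e-9)
  i <- state == 3L; out[i] <- rtruncnorm(sum(i), 15, 8, 2, 60 - 1e-9)
  out
}

rutility <- function(state, util) {
  n <- length(state)
  out <- rep(NA_real_, n)
  for (k in 1:3) {
    i <- which(state == k)
    if (!length(i)) next
    m <- util$mean[util$state == health_states()[k]]
    s <- util$sd[util$state == health_states()[k]]
    spec <- fit_beta_mom(m, s)
    out[i] <- stats::rbeta(length(i), spec$alpha, spec$beta)
  }
  out
}

# state-linked steady monthly cost: state means proportional to
# share_s / occupancy_s so the cohort's cost shares hit the configured target;
# per-state CV equals the configured total CV
rmonthly_cost <- function(state, total_mean, total_sd, shares) {
  n <- length(state)
  out <- rep(NA_real_, n)
  alive <- state %in% 1:3
  if (!any(alive)) return(out)
  share_by_code <- c(shares[["NO_CKD"]], shares[["CKD_NO_KRT"]],
                     shares[["KRT_DEPENDENT"]])
  n_s <- tabulate(state[alive], nbins = 3)
  present <- n_s > 0
  w <- share_by_code * present
  w <- w / sum(w)
  cv <- total_sd / total_mean
  for (k in 1:3) {
    if (!present[k]) next
    mu <- w[k] * sum(alive) * total_mean / n_s[k]
    i <- which(state == k)
    out[i] <- rgamma_mom(length(i), mu, cv * mu)
  }
  out
}

#' Generate a synthetic patient-level cohort
#'
#' One row per patient with arm, 90/365-day vital status, eGFR, monthly KRT
#' status at the two landmarks, periodized costs and EQ-5D-style utilities.
#' Day-365 states are obtained by simulating 9 monthly cycles of the
#' configured transition matrix from the day-90 state, so the estimation
#' module's recovered period matrix can be compared with the matrix power of
#' the generator's input. Reproducible under the configured seed.
#'
#' @param config `cohort_config`.
#' @return data.frame of patient records (possibly 0 rows).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  arms <- c("accelerated", "standard")
  res <- lapply(arms, function(arm) generate_arm(config, arm))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

generate_arm <- function(config, arm) {
  n <- config$n_per_arm
  cols <- c("patient_id", "arm", "age", "alive_90", "alive_365", "egfr_90",
            "egfr_365", "krt_90", "krt_365", "cost_0_90", "cost_91_120",
            "monthly_cost_121_365", "utility_90", "utility_365")
  if (n == 0L) {
    out <- data.frame(patient_id = character(0), arm = character(0),
                      age = numeric(0), alive_90 = logical(0),
                      alive_365 = logical(0), egfr_90 = numeric(0),
                      egfr_365 = numeric(0), krt_90 = logical(0),
                      krt_365 = logical(0), cost_0_90 = numeric(0),
                      cost_91_120 = numeric(0),
                      monthly_cost_121_365 = numeric(0),
                      utility_90 = numeric(0), utility_365 = numeric(0),
                      stringsAsFactors = FALSE)
    return(out[, cols])
  }
  age <- rtruncnorm(n, config$age_mean[[arm]], config$age_sd[[arm]], 18, 95)
  alive_90 <- stats::runif(n) < config$survival_90[[arm]]
  krt_90 <- alive_90 & (stats::runif(n) < config$krt_among_survivors[[arm]])
  nockd <- stats::runif(n) < config$nockd_share
  state90 <- rep(4L, n)
  state90[alive_90 & krt_90] <- 3L
  state90[alive_90 & !krt_90] <- ifelse(nockd[alive_90 & !krt_90], 1L, 2L)
  # 9 monthly cycles of the configured matrix
  M <- config$monthly_matrix[[arm]]
  state365 <- state90
  for (cycle in 1:9) {
    cur <- state365 # snapshot: one transition per patient per cycle
    for (s in 1:3) {
      i <- which(cur == s)
      if (length(i)) {
        state365[i] <- sample.int(4L, length(i), replace = TRUE, prob = M[s, ])
      }
    }
  }
  alive_365 <- state365 != 4L
  ct <- config$costs_total
  cmean <- function(period) ct$mean[ct$arm == arm & ct$period == period]
  csd <- function(period) ct$sd[ct$arm == arm & ct$period == period]
  cost_0_90 <- rgamma_mom(n, cmean("d0_90"), csd("d0_90"))
  cost_91_120 <- rep(NA_real_, n)
  cost_91_120[alive_90] <- rgamma_mom(sum(alive_90), cmean("d91_120"),
                                      csd("d91_120"))
  monthly <- rmonthly_cost(ifelse(alive_365, state365, 4L),
                           cmean("gt120"), csd("gt120"), config$state_shares)
  out <- data.frame(
    patient_id = sprintf("%s-%04d", substr(arm, 1, 3), seq_len(n)),
    arm = arm,
    age = age,
    alive_90 = alive_90,
    alive_365 = alive_365,
    egfr_90 = regfr(state90),
    egfr_365 = regfr(ifelse(alive_365, state365, 4L)),
    krt_90 = ifelse(alive_90, krt_90, NA),
    krt_365 = ifelse(alive_365, state365 == 3L, NA),
    cost_0_90 = cost_0_90,
    cost_91_120 = cost_91_120,
    monthly_cost_121_365 = monthly,
    utility_90 = rutility(state90, config$utility),
    utility_365 = rutility(ifelse(alive_365, state365, 4L), config$utility),
    stringsAsFactors = FALSE)
  # invariants: dead at 90 => dead at 365 with all day-365 fields absent
  dead90 <- !out$alive_90
  out$alive_365[dead90] <- FALSE
  out[dead90, c("egfr_90", "egfr_365", "cost_91_120",
                "monthly_cost_121_365", "utility_90", "utility_365")] <- NA
  out$egfr_365[!out$alive_365] <- NA
  out$utility_365[!out$alive_365] <- NA
  out$monthly_cost_121_365[!out$alive_365] <- NA
  out[, cols]
}

.cohort_numeric <- c("age", "egfr_90", "egfr_365", "cost_0_90",
                     "cost_91_120", "monthly_cost_121_365", "utility_90",
                     "utility_365")
.cohort_logical <- c("alive_90", "alive_365", "krt_90", "krt_365")

#' Write / read a cohort as CSV
#'
#' One row per patient, columns exactly the patient-record fields, missing
#' values as empty cells. Numeric columns are written at full double
#' precision so that `read_cohort(write_cohort(x))` is lossless.
#'
#' @param records cohort data.frame.
#' @param path CSV file path.
#' @return `read_cohort` returns the cohort data.frame; validation failures
#'   (negative costs, out-of-range utilities, day-365 data for 90-day
#'   decedents) raise a parse error naming the row and column.
#' @export
write_cohort <- function(records, path) {
  out <- records
  for (col in .cohort_numeric) {
    v <- rep(NA_character_, nrow(out))
    ok <- !is.na(out[[col]])
    v[ok] <- sprintf("%.17g", out[[col]][ok])
    out[[col]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cls <- c(patient_id = "character", arm = "character", age = "numeric",
           alive_90 = "logical", alive_365 = "logical", egfr_90 = "numeric",
           egfr_365 = "numeric", krt_90 = "logical", krt_365 = "logical",
           cost_0_90 = "numeric", cost_91_120 = "numeric",
           monthly_cost_121_365 = "numeric", utility_90 = "numeric",
           utility_365 = "numeric")
  x <- utils::read.csv(path, colClasses = NA, stringsAsFactors = FALSE,
                       na.strings = "")
  missing_cols <- setdiff(names(cls), names(x))
  if (length(missing_cols)) {
    stop("parse error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  x <- x[, names(cls)]
  for (col in names(cls)) {
    v <- x[[col]]
    x[[col]] <- switch(cls[[col]],
                       character = as.character(v),
                       numeric = as.numeric(v),
                       logical = as.logical(v))
  }
  validate_cohort(x)
  x
}

validate_cohort <- function(x) {
  bad <- function(col, rows, why) {
    stop("parse error in column '", col, "', row ", rows[1], ": ", why)
  }
  for (col in c("cost_0_90", "cost_91_120", "monthly_cost_121_365")) {
    i <- which(!is.na(x[[col]]) & x[[col]] < 0)
    if (length(i)) bad(col, i, "negative cost")
  }
  for (col in c("utility_90", "utility_365")) {
    i <- which(!is.na(x[[col]]) & (x[[col]] < 0 | x[[col]] > 1))
    if (length(i)) bad(col, i, "utility outside [0, 1]")
  }
  i <- which(!x$alive_90 %in% TRUE & x$alive_365 %in% TRUE)
  if (length(i)) bad("alive_365", i, "alive at 365 but dead at 90")
  for (col in c("egfr_365", "utility_365", "monthly_cost_121_365")) {
    i <- which(!x$alive_365 %in% TRUE & !is.na(x[[col]]))
    if (length(i)) bad(col, i, "day-365 data for a decedent")
  }
  i <- which(!x$alive_90 %in% TRUE & !is.na(x$krt_90))
  if (length(i)) bad("krt_90", i, "KRT flag for a decedent")
  invisible(x)
}
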