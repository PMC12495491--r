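# Estimation layer: state classification, transition matrices, monthly
# adjustment, method-of-moments fitters, cost summaries.

test_that("state classification follows the eGFR/KRT/death rules", {
  expect_identical(classify_state(TRUE, FALSE, 75), "NO_CKD")
  expect_identical(classify_state(TRUE, FALSE, 60), "NO_CKD") # boundary
  expect_identical(classify_state(TRUE, FALSE, 59.9), "CKD_NO_KRT")
  expect_identical(classify_state(TRUE, TRUE, 80), "KRT_DEPENDENT") # KRT wins
  expect_identical(classify_state(FALSE, NA, NA), "DEAD")
  expect_error(classify_state(TRUE, FALSE, NA), "missing eGFR")
})

test_that("period-to-monthly conversion is the constant-hazard formula", {
  expect_identical(period_to_monthly(0, 9), 0)
  expect_identical(period_to_monthly(1, 5), 1)
  expect_equal(period_to_monthly(0.75, 2), 0.5) # (1-0.5)^2 = 0.25 survival
  expect_equal(period_to_monthly(0.3, 1), 0.3)
  expect_error(period_to_monthly(1.2, 9), "\\[0, 1\\]")
  expect_error(period_to_monthly(0.5, 0), ">= 1")
})

test_that("transition matrix estimation: counts, normalization, absorbing dead", {
  # all patients keep their state -> identity period matrix
  s <- rep(health_states(), times = c(5, 5, 5, 5))
  est <- estimate_transition_matrix(s, s)
  expect_equal(unname(est$matrix_period), diag(4))

  # 10 NO_CKD at day 90, 4 dead at day 365 -> P14 = 0.4
  s1 <- c(rep("NO_CKD", 10), rep("CKD_NO_KRT", 4), rep("KRT_DEPENDENT", 3),
          rep("DEAD", 2))
  s2 <- c(rep("NO_CKD", 6), rep("DEAD", 4), rep("CKD_NO_KRT", 4),
          rep("KRT_DEPENDENT", 3), rep("DEAD", 2))
  est <- estimate_transition_matrix(s1, s2)
  expect_equal(est$matrix_period["NO_CKD", "DEAD"], 0.4)
  expect_equal(est$matrix_period["NO_CKD", "NO_CKD"], 0.6)
  expect_equal(unname(est$matrix_period["DEAD", ]), c(0, 0, 0, 1))
  expect_equal(unname(est$counts["DEAD", ]), c(0L, 0L, 0L, 2L))
  # counts conserved: row sums equal day-90 occupancy
  expect_equal(unname(rowSums(est$counts)), c(10L, 4L, 3L, 2L))
  # both matrices row-stochastic
  expect_equal(unname(rowSums(est$matrix_period)), rep(1, 4))
  expect_equal(unname(rowSums(est$matrix_monthly)), rep(1, 4))
  # monthly off-diagonal matches the scalar conversion
  expect_equal(est$matrix_monthly["NO_CKD", "DEAD"],
               period_to_monthly(0.4, 9))

  # an unoccupied alive state is flagged, not zero-filled
  est2 <- estimate_transition_matrix(c("NO_CKD", "DEAD"), c("NO_CKD", "DEAD"))
  expect_setequal(est2$inestimable, c("CKD_NO_KRT", "KRT_DEPENDENT"))
  expect_true(all(is.na(est2$matrix_period["CKD_NO_KRT", ])))
})

test_that("beta/gamma method-of-moments fits invert the forward moment maps", {
  # uniform case
  u <- fit_beta_mom(0.5, sqrt(1 / 12))
  expect_equal(u$alpha, 1, tolerance = 1e-9)
  expect_equal(u$beta, 1, tolerance = 1e-9)

  # round-trips over a grid, via the forward-moment oracle
  for (ab in list(c(80, 14.40), c(49.9, 18), c(44.8, 30), c(0.396, 2.479),
                  c(2, 5), c(0.5, 0.5))) {
    mom <- krtcua:::beta_moments(ab[1], ab[2])
    fit <- fit_beta_mom(mom$mean, mom$sd)
    expect_equal(fit$alpha, ab[1], tolerance = 1e-9)
    expect_equal(fit$beta, ab[2], tolerance = 1e-9)
  }
  for (ks in list(c(1, 2), c(3.5, 1000), c(0.2, 5))) {
    mom <- krtcua:::gamma_moments(ks[1], ks[2])
    fit <- fit_gamma_mom(mom$mean, mom$sd)
    expect_equal(fit$shape, ks[1], tolerance = 1e-9)
    expect_equal(fit$scale, ks[2], tolerance = 1e-9)
    expect_equal(fit$shape * fit$scale, mom$mean, tolerance = 1e-12)
  }

  # mean = sd -> exponential (shape 1); published 0-90 d cost moments
  expect_equal(fit_gamma_mom(5, 5)$shape, 1)
  g <- fit_gamma_mom(182626, 175710)
  expect_equal(g$shape * g$scale / 182626, 1, tolerance = 1e-6)

  expect_error(fit_beta_mom(0.5, 0.6), "infeasibility")
  expect_error(fit_beta_mom(1.1, 0.1), "\\(0, 1\\)")
  expect_error(fit_gamma_mom(-1, 1), "> 0")
})

test_that("method-of-moments fits agree with an independent fitter", {
  skip_if_not_installed("fitdistrplus")
  set.seed(42)
  x <- rbeta(5000, 3, 7)
  n <- length(x)
  # fitdistrplus matches moments with the population (1/n) variance
  sd_n <- sqrt(mean((x - mean(x))^2))
  ours <- fit_beta_mom(mean(x), sd_n)
  ref <- fitdistrplus::fitdist(x, "beta", method = "mme")$estimate
  expect_equal(ours$alpha, unname(ref["shape1"]), tolerance = 1e-6)
  expect_equal(ours$beta, unname(ref["shape2"]), tolerance = 1e-6)

  y <- rgamma(5000, shape = 2.5, scale = 400)
  sdy <- sqrt(mean((y - mean(y))^2))
  oursg <- fit_gamma_mom(mean(y), sdy)
  refg <- fitdistrplus::fitdist(y, "gamma", method = "mme")$estimate
  expect_equal(oursg$shape, unname(refg["shape"]), tolerance = 1e-6)
  expect_equal(1 / oursg$scale, unname(refg["rate"]), tolerance = 1e-6)
})

test_that("cost summaries and state-share decomposition", {
  cohort <- generate_cohort(cohort_config(n_per_arm = 400L, seed = 9L))
  est <- estimate_cost_params(cohort)
  expect_setequal(unique(est$totals$period), c("d0_90", "d91_120", "gt120"))
  # state costs are share-scaled totals
  acc <- est$totals[est$totals$arm == "accelerated" &
                    est$totals$period == "gt120", ]
  by <- est$by_state[est$by_state$arm == "accelerated" &
                     est$by_state$period == "gt120", ]
  expect_equal(by$mean[by$state == "KRT_DEPENDENT"], acc$mean * 0.71)
  expect_equal(sum(by$mean), acc$mean)
  expect_error(estimate_cost_params(cohort, state_shares = c(0.5, 0.2, 0.2)),
               "sum to 1")

  # degenerate share vectors
  one <- estimate_cost_params(cohort,
    state_shares = c(KRT_DEPENDENT = 1, CKD_NO_KRT = 0, NO_CKD = 0))
  b1 <- one$by_state[one$by_state$arm == "accelerated" &
                     one$by_state$period == "gt120", ]
  expect_equal(b1$mean[b1$state == "KRT_DEPENDENT"], acc$mean)
  expect_equal(b1$mean[b1$state == "NO_CKD"], 0)

  # constant costs -> SD 0
  toy <- cohort[cohort$alive_365 %in% TRUE, ][1:5, ]
  toy$cost_0_90 <- 100
  toy$cost_91_120 <- 10
  toy$monthly_cost_121_365 <- 1
  t_est <- estimate_cost_params(toy)
  expect_equal(t_est$totals$mean, c(100, 10, 1))
  expect_equal(t_est$totals$sd, c(0, 0, 0))
})

test_that("state shares computed from records behave at the extremes", {
  base <- generate_cohort(cohort_config(n_per_arm = 300L, seed = 13L))
  alive <- base$alive_365 %in% TRUE
  # all monthly cost on KRT patients -> (1, 0, 0)
  x <- base
  st <- classify_state(x$alive_365[alive], x$krt_365[alive], x$egfr_365[alive])
  x$monthly_cost_121_365[alive] <- ifelse(st == "KRT_DEPENDENT", 50, 0)
  if (any(st == "KRT_DEPENDENT")) {
    expect_equal(unname(compute_state_shares(x)), c(1, 0, 0))
  }
  # two equal-cost states, zero third -> (0.5, 0.5, 0)
  y <- base
  nk <- sum(st == "KRT_DEPENDENT"); nc <- sum(st == "CKD_NO_KRT")
  cost <- numeric(length(st))
  cost[st == "KRT_DEPENDENT"] <- 10 / max(nk, 1)
  cost[st == "CKD_NO_KRT"] <- 10 / max(nc, 1)
  y$monthly_cost_121_365[alive] <- cost
  if (nk > 0 && nc > 0) {
    expect_equal(unname(compute_state_shares(y)), c(0.5, 0.5, 0))
  }
  # zero total cost is undefined
  z <- base
  z$monthly_cost_121_365[alive] <- 0
  expect_error(compute_state_shares(z), "undefined")
})

test_that("full parameter estimation returns a usable parameter set", {
  cohort <- generate_cohort(cohort_config(n_per_arm = 2000L, seed = 21L))
  est <- estimate_parameters(cohort)
  expect_s3_class(est$params, "krt_params")
  expect_equal(sum(est$params$state_shares), 1, tolerance = 1e-12)
  # estimated statics stay probabilities and the deterministic model runs
  expect_true(all(est$params$trans_static$mean >= 0 &
                  est$params$trans_static$mean <= 1))
  r <- run_deterministic(est$params, fast_config(n_cycles = 60L), "standard",
                         schedules = calibrated_schedules(est$params, 60L))
  expect_true(is.finite(r$cost) && is.finite(r$qalys))
})
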