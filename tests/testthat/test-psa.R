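# Probabilistic sensitivity analysis: sampling, incremental summaries,
# acceptability curves, scenarios.

test_that("ICER quadrants and dominance flags", {
  expect_identical(compute_icer(-16041, 0.77)$flag, "dominant")
  expect_identical(compute_icer(16041, -0.77)$flag, "dominated")
  expect_identical(compute_icer(100, 0)$flag, "undefined")
  expect_equal(compute_icer(0, 1)$icer, 0)
  r <- compute_icer(19852, 0.86)
  expect_identical(r$flag, "ratio")
  expect_equal(r$icer, 19852 / 0.86, tolerance = 1e-12)
  expect_equal(round(r$icer), 23084)
})

test_that("INMB arithmetic and the sign flip at the ICER", {
  expect_equal(compute_inmb(50000, 1, 50000), 0)
  expect_equal(compute_inmb(19852, 0.86, 50000), 23148)
  expect_error(compute_inmb(1, 1, 0), "wtp")
  # sign(INMB) flips exactly at lambda = ICER when dQ > 0
  dc <- 19852; dq <- 0.86
  icer <- dc / dq
  expect_lt(compute_inmb(dc, dq, icer * 0.999), 0)
  expect_gt(compute_inmb(dc, dq, icer * 1.001), 0)
  expect_equal(compute_inmb(dc, dq, icer), 0, tolerance = 1e-9)
})

test_that("CEAC threshold interpolation and flags", {
  expect_equal(ceac_threshold(data.frame(lambda = c(30000, 40000),
                                         probability = c(0.4, 0.6)))$lambda,
               35000)
  always <- ceac_threshold(data.frame(lambda = 0:3 * 1000,
                                      probability = rep(1, 4)))
  expect_identical(always$flag, "always-cost-effective")
  never <- ceac_threshold(data.frame(lambda = 0:3 * 1000,
                                     probability = rep(0.2, 4)))
  expect_identical(never$flag, "never-cost-effective")
})

test_that("single-parameter draws reproduce their sampling distributions", {
  p <- default_parameters()
  cfg <- fast_config(n_cycles = 36L)
  set.seed(1)
  d <- krtcua:::sample_psa_draws(p, cfg, 4000L)
  # utility beta(80, 14.40): sample mean within 3 SEs of 80/94.4
  m <- 80 / 94.4
  se <- sd(d$utilities[, "NO_CKD"]) / sqrt(4000)
  expect_lt(abs(mean(d$utilities[, "NO_CKD"]) - m), 3 * se)
  # arm-specific recovery probability uses its own shapes
  m21 <- 0.396 / (0.396 + 2.479)
  se21 <- sd(d$statics$p21$standard) / sqrt(4000)
  expect_lt(abs(mean(d$statics$p21$standard) - m21), 3 * se21)
  # schedules respect their published ranges
  expect_true(all(d$schedules[["NO_CKD.DEAD"]] >= 0.001 - 1e-12))
  expect_true(all(d$schedules[["NO_CKD.DEAD"]] <= 0.990 + 1e-12))
  # costs are nonnegative with the configured means
  expect_true(all(d$costs$accelerated$one_time >= 0))
  expect_equal(mean(d$costs$accelerated$one_time), 182626,
               tolerance = 3 * 175710 / sqrt(4000) / 182626)

  # degenerate specs collapse to constants
  dp <- degenerate_parameters()
  dd <- krtcua:::sample_psa_draws(dp, model_config(n_cycles = 36L,
                                                   schedule_cv = 0,
                                                   n_schedule_sims = 5L), 50L)
  expect_equal(sd(dd$costs$standard$one_time), 0)
  expect_lt(sd(dd$utilities[, "NO_CKD"]), 1e-3)

  # fixed seed -> identical draw sequence
  set.seed(7); a <- sample_draw(p, cfg)
  set.seed(7); b <- sample_draw(p, cfg)
  expect_identical(a, b)
})

test_that("PSA summaries: identity, CEAC endpoints, credible intervals", {
  p <- default_parameters()
  cfg <- fast_config(n_cycles = 120L)
  res <- run_psa(p, cfg, n_sims = 400L, seed = 5L)
  dr <- res$draws
  # INMB identity on every draw, recomputed from the per-arm draws
  inmb <- cfg$wtp * (dr$qaly$standard - dr$qaly$accelerated) -
    (dr$cost$standard - dr$cost$accelerated)
  expect_equal(inmb, dr$inmb, tolerance = 1e-9)
  expect_equal(res$inmb_mean,
               cfg$wtp * res$delta_qaly_mean - res$delta_cost_mean,
               tolerance = 1e-6)
  # CEAC at lambda = 0 equals P(delta cost < 0)
  expect_equal(res$ceac$probability[res$ceac$lambda == 0],
               mean(dr$delta_cost < 0))
  # CEAC is nondecreasing when every draw has positive incremental QALYs
  if (all(dr$delta_qaly > 0)) {
    expect_true(all(diff(res$ceac$probability) >= 0))
  }
  expect_true(all(res$ceac$probability >= 0 & res$ceac$probability <= 1))
  # percentile interval brackets the mean
  expect_lt(res$inmb_cri[1], res$inmb_mean)
  expect_gt(res$inmb_cri[2], res$inmb_mean)
  # determinism under the seed
  res2 <- run_psa(p, cfg, n_sims = 400L, seed = 5L)
  expect_equal(res$inmb_mean, res2$inmb_mean)
  expect_error(run_psa(p, cfg, n_sims = 1L), "n_sims")
})

test_that("PSA collapses to the deterministic run when variances vanish", {
  dp <- degenerate_parameters()
  cfg <- model_config(n_cycles = 240L, schedule_cv = 0, n_schedule_sims = 5L)
  res <- run_psa(dp, cfg, n_sims = 50L, seed = 2L)
  sch <- calibrated_schedules(dp, cfg$n_cycles)
  det_acc <- run_deterministic(dp, cfg, "accelerated", schedules = sch)
  det_std <- run_deterministic(dp, cfg, "standard", schedules = sch)
  arms <- res$arms
  expect_equal(arms$cost_mean[arms$arm == "accelerated"], det_acc$cost,
               tolerance = 1e-3)
  expect_equal(arms$cost_mean[arms$arm == "standard"], det_std$cost,
               tolerance = 1e-3)
  expect_equal(arms$qaly_mean[arms$arm == "accelerated"], det_acc$qalys,
               tolerance = 1e-3)
  expect_equal(arms$qaly_mean[arms$arm == "standard"], det_std$qalys,
               tolerance = 1e-3)
  # credible interval contains the deterministic value
  det_inmb <- cfg$wtp * (det_std$qalys - det_acc$qalys) -
    (det_std$cost - det_acc$cost)
  expect_gte(det_inmb, res$inmb_cri[1])
  expect_lte(det_inmb, res$inmb_cri[2])
})

test_that("starting-state scenario changes only the starting mix", {
  p <- default_parameters()
  cfg <- fast_config(n_cycles = 120L)
  base <- run_psa(p, cfg, n_sims = 300L, seed = 31L)
  # identity scenario: base-case shares reproduce the base case
  same <- scenario_start_states(p, cfg, n_sims = 300L, seed = 31L,
                                krt_share_acc = 0.021, krt_share_std = 0.098)
  expect_equal(same$inmb_mean, base$inmb_mean)
  expect_equal(same$arms, base$arms)
  # a higher accelerated KRT share lowers accelerated QALYs (utility 0.60
  # is the lowest alive-state utility)
  shifted <- scenario_start_states(p, cfg, n_sims = 300L, seed = 31L,
                                   krt_share_acc = 0.104,
                                   krt_share_std = 0.060)
  q_base <- base$arms$qaly_mean[base$arms$arm == "accelerated"]
  q_shift <- shifted$arms$qaly_mean[shifted$arms$arm == "accelerated"]
  expect_lt(q_shift, q_base)
  # standard remains more effective
  expect_gt(shifted$delta_qaly_mean, 0)
  expect_error(scenario_start_states(p, cfg, krt_share_acc = 1.5), "<= 1")
})

test_that("equal-cost scenario pools monthly costs and flips the cost sign", {
  p <- default_parameters()
  pooled <- pool_monthly_costs(p)
  ct <- pooled$costs_total
  expect_equal(unique(ct$mean[ct$period == "gt120"]), (3293 + 5558) / 2)
  expect_equal(unique(ct$mean[ct$period == "d91_120"]), (28486 + 9141) / 2)
  # one-time costs unchanged
  expect_equal(ct$mean[ct$period == "d0_90"], c(182626, 161601))
  # arms already equal -> pooling is a no-op
  eq <- p
  eq$costs_total$mean <- rep(c(100, 10, 1), 2)
  eq$costs_total$sd <- rep(c(1, 1, 1), 2)
  expect_equal(pool_monthly_costs(eq)$costs_total, eq$costs_total)

  cfg <- fast_config(n_cycles = 120L)
  res <- scenario_equal_costs(p, cfg, n_sims = 300L, seed = 17L)
  # with equal monthly costs, the cheaper 0-90 d standard arm dominates
  expect_lt(res$delta_cost_mean, 0)
  expect_gt(res$delta_qaly_mean, 0)
  expect_identical(res$icer_flag, "dominant")
})
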