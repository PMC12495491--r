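#!/usr/bin/env Rscript
# Step 3: deterministic lifetime model at the published point estimates.
#
# 480 monthly cycles from day 90, starting distributions built from 90-day
# survival and KRT dependence among survivors, time-dependent death and
# CKD-onset schedules calibrated to the published mean/range summaries,
# 1.5% annual discounting, and the published cost periodization (one-time
# 0-90 d cost; month-4 cost; steady monthly cost thereafter, split across
# states 71/17/12).

suppressPackageStartupMessages(library(krtcua))
dir.create("results", showWarnings = FALSE)

params <- default_parameters()
config <- model_config()
schedules <- calibrated_schedules(params, config$n_cycles)

cat("Calibrated schedule means (targets 0.001 / 0.022 / 0.030 / 0.033):\n")
print(round(vapply(schedules, function(s) mean(s$p), 0.0), 5))

runs <- lapply(c("accelerated", "standard"), function(arm) {
  run_deterministic(params, config, arm, schedules = schedules)
})
names(runs) <- c("accelerated", "standard")

for (arm in names(runs)) {
  r <- runs[[arm]]
  export_trace(r$trace, sprintf("results/trace_%s.csv", arm))
  cat(sprintf("\n%s: discounted cost %s CAD, %0.2f QALYs, dead at cycle 480: %.4f\n",
              arm, format(round(r$cost), big.mark = " "), r$qalys,
              r$trace[nrow(r$trace), "DEAD"]))
}

dc <- runs$standard$cost - runs$accelerated$cost
dq <- runs$standard$qalys - runs$accelerated$qalys
icer <- compute_icer(dc, dq)
cat(sprintf("\nDeterministic increments (standard - accelerated): %s CAD, %0.2f QALYs\n",
            format(round(dc), big.mark = " "), dq))
cat(sprintf("Deterministic ICER: %s CAD/QALY; INMB at 50 000: %s CAD\n",
            format(round(icer$icer), big.mark = " "),
            format(round(compute_inmb(dc, dq, config$wtp)), big.mark = " ")))
cat("\nNote: the published lifetime totals are not exactly reproducible from\n",
    "printed inputs alone (the death schedules are summarized as mean/range\n",
    "and the no-CKD/CKD starting split is unpublished); signs and orders of\n",
    "magnitude are the meaningful comparison.\n")
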