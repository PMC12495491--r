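# Shared fixtures: small configurations that keep unit tests fast while
# exercising the same code paths as the full 480-cycle model.

fast_config <- function(...) {
  model_config(n_schedule_sims = 200L, ...)
}

# parameters whose sampling distributions are (near-)degenerate at the
# deterministic point values: beta shapes rescaled to the printed means with
# huge concentration, zero cost SDs, zero schedule-level uncertainty
degenerate_parameters <- function(concentration = 1e7) {
  p <- default_parameters()
  for (tab in c("utilities", "trans_static")) {
    m <- p[[tab]]$mean
    p[[tab]]$alpha <- m * concentration
    p[[tab]]$beta <- (1 - m) * concentration
    p[[tab]]$mean <- m
  }
  p$costs_total$sd <- 0
  p
}

# random feasible transition-matrix sequence for property tests
random_matrices <- function(n_cycles, rng_max = 0.9) {
  lapply(seq_len(n_cycles), function(i) {
    m <- matrix(0, 4, 4, dimnames = list(health_states(), health_states()))
    for (r in 1:3) {
      off <- stats::runif(3)
      off <- off / sum(off) * stats::runif(1, 0, rng_max)
      m[r, -r] <- off
      m[r, r] <- 1 - sum(off)
    }
    m[4, ] <- c(0, 0, 0, 1)
    m
  })
}

random_start <- function() {
  s <- stats::runif(4)
  s <- s / sum(s)
  names(s) <- health_states()
  s
}
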