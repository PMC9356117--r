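# Shared fixtures: all data are generated in code at test time.

# reduced-scale MCMC configuration for fast fits
quick_cfg <- function(seed = 1L, chains = 2L, iterations = 1000L,
                      burn_in = 500L, grid_step = 0.05, ...) {
  borrow_config(chains = chains, iterations = iterations, burn_in = burn_in,
                grid_step = grid_step, grid_iterations = 150L,
                grid_burn_in = 50L, seed = seed, ...)
}

# small simulated trial pair
small_trial <- function(seed = 1L, scenario = "No", effect = 0,
                        n_per_arm = 40L) {
  simulate_trial(scenario_spec(scenario, effect = effect,
                               n_per_arm = n_per_arm), seed = seed)
}

# hand-built longitudinal dataset: one subject per row-spec
manual_data <- function(subject, study, arm, time, y) {
  longitudinal_data(data.frame(subject = subject, study = study, arm = arm,
                               time = time, y = y))
}

# a tiny historical-control dataset with hand-picked outcomes
toy_historical <- function(n = 3L, m = 3L, seed = 99L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    tt <- seq(0, 1, length.out = m)
    data.frame(subject = sprintf("h%02d", i), study = "historical",
               arm = "control", time = tt,
               y = 2 + tt + rnorm(m, 0, 0.8))
  })) |> longitudinal_data()
}

# combined Monte Carlo SE of the difference of two posterior means
combined_mcse <- function(fit_a, fit_b, par = "trt_time") {
  sa <- stats::sd(fit_a$draws[[par]]) / sqrt(ess_bulk(fit_a$draws[[par]]))
  sb <- stats::sd(fit_b$draws[[par]]) / sqrt(ess_bulk(fit_b$draws[[par]]))
  sqrt(sa^2 + sb^2)
}
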