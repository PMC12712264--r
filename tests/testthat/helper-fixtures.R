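# Shared fixtures: fast solver settings for property tests (accuracy checks
# use the package defaults explicitly where it matters).
fast_ctrl <- list(rtol = 1e-7, atol = 1e-9, hmax = 0.25, dt_out = 0.25)

fast_config <- function(..., ctrl = fast_ctrl) {
  do.call(simulation_config, c(list(...), ctrl))
}

# Batch-free design configuration at a given initial feed rate.
design_config <- function(F0, ..., ctrl = list()) {
  args <- c(list(parameters = design_parameters(),
                 feed = feed_settings(0.2, F0 = F0, mode = "fixed-time"),
                 X0 = 0.696, S0 = 5, P0 = 0, A0 = 0, V0 = 10, v0 = 10),
            ctrl, list(...))
  do.call(simulation_config, args)
}

# One small, quickly simulated triggered fed-batch experiment.
small_fedbatch_config <- function(params = kinetic_parameters(),
                                  mu_F = 0.25, ctrl = fast_ctrl) {
  do.call(simulation_config, c(
    list(parameters = params,
         feed = feed_settings(mu_F, mode = "triggered"),
         X0 = 1, S0 = 250, P0 = 0, A0 = 0, V0 = 10, v0 = 6),
    ctrl))
}

# Noiseless, jitter-free synthetic observations at the given rates.
noiseless_set <- function(params = kinetic_parameters(),
                          rates = 0.25, seed = 1,
                          sampling_interval = 1) {
  generate_experiment_set(
    params = params, feeding_rates = rates, replicates = 1,
    noise = noise_model(cv = c(X = 0, S = 0, P = 0, A = 0), floor = 0),
    sampling_interval = sampling_interval,
    jitter = list(X0 = 0, S0 = 0, t_lag = 0),
    seed = seed, sim_control = fast_ctrl)
}
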