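test_that("rmse matches hand-computed values and drops missing pairs", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(rep(2, 7), rep(0, 7)), 2)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt((9 + 16) / 2))
  expect_equal(rmse(c(1, NA, 3), c(1, 5, NA)), 0)
  expect_error(rmse(c(NA, NA), c(1, 2)), "overlapping")
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("rmse is scale-equivariant", {
  set.seed(8)
  m <- runif(20, 0, 50); o <- runif(20, 0, 50)
  for (k in c(0.1, 3, 1000)) {
    expect_equal(rmse(k * m, k * o), k * rmse(m, o))
  }
})

test_that("objective is zero at the generating parameters on noiseless data", {
  p <- kinetic_parameters()
  set <- noiseless_set(p, rates = c(0.2, 0.25))
  spec <- fit_spec("mu_max_S", sim_control = fast_ctrl)
  res <- fit_objective(p, set, spec)
  expect_lt(res$loss, 1e-5)
  expect_true(all(res$rmse_table[, c("RMSE_X", "RMSE_S", "RMSE_P",
                                     "RMSE_A")] < 1e-5))
  # table means mirror the per-state arithmetic means over experiments
  expect_equal(res$mean_rmse[["X"]], mean(res$rmse_table$RMSE_X))
  # perturbing a free parameter away from the optimum increases the loss
  p_off <- p; p_off$mu_max_S <- p$mu_max_S * 1.1
  expect_gt(fit_objective(p_off, set, spec)$loss, res$loss + 0.1)
})

test_that("objective is deterministic given parameters and data", {
  p <- kinetic_parameters()
  set <- noiseless_set(p, rates = 0.25)
  spec <- fit_spec("b_max", sim_control = fast_ctrl)
  expect_identical(fit_objective(p, set, spec)$loss,
                   fit_objective(p, set, spec)$loss)
})

test_that("free parameters are recovered from noiseless data within 1%", {
  truth <- kinetic_parameters(mu_max_S = 0.55, b_max = 0.09, t_lag = 2.5)
  set <- noiseless_set(truth, rates = 0.25)
  set[[1]]$t_lag <- NA_real_ # estimate the lag instead of pinning it
  spec <- fit_spec(c("mu_max_S", "b_max", "t_lag"),
                   n_starts = 8, n_polish = 2, seed = 42,
                   sim_control = fast_ctrl)
  start <- kinetic_parameters() # defaults, away from the truth
  fit <- fit_parameters(set, spec, start)
  rel <- abs(fit$free - unlist(truth[names(fit$free)])) /
    unlist(truth[names(fit$free)])
  expect_true(all(rel <= 0.01))
  # fixed parameters are untouched and bounds are honoured
  fixed <- setdiff(names(start), spec$free)
  expect_identical(fit$parameters[fixed], start[fixed])
  expect_true(all(fit$free >= spec$lower & fit$free <= spec$upper))
})

test_that("growth rate is recovered within 10% from 5%-CV noisy data", {
  truth <- kinetic_parameters(mu_max_S = 0.55)
  set <- generate_experiment_set(
    params = truth, feeding_rates = 0.25, replicates = 1,
    noise = noise_model(cv = c(X = 0.05, S = 0.05, P = 0.05, A = 0.05),
                        floor = 0),
    jitter = list(X0 = 0, S0 = 0, t_lag = 0),
    seed = 99, sim_control = fast_ctrl)
  spec <- fit_spec("mu_max_S", n_starts = 6, n_polish = 1, seed = 1,
                   sim_control = fast_ctrl)
  fit <- fit_parameters(set, spec, kinetic_parameters())
  expect_lt(abs(fit$free[["mu_max_S"]] - 0.55) / 0.55, 0.10)
})

test_that("failed simulations are penalised, not fatal, in the objective", {
  p <- kinetic_parameters()
  set <- noiseless_set(p, rates = 0.25)
  set[[1]]$init$S0 <- 0.1 # glucose below the feed trigger: simulation fails
  spec <- fit_spec("mu_max_S", sim_control = fast_ctrl)
  res <- fit_objective(p, set, spec)
  expect_true(res$rmse_table$failed[1])
  expect_gte(res$loss, spec$penalty)
})
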