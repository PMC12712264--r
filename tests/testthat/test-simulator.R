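test_that("triggered fed-batch runs through batch, trigger and depletion", {
  cfg <- small_fedbatch_config()
  traj <- simulate_fed_batch(cfg)
  ev <- trajectory_events(traj)
  p <- cfg$parameters
  # feed triggered when glucose crossed the critical concentration
  i_fs <- which.min(abs(traj$t - ev$feed_start))
  expect_equal(traj$S_conc[i_fs], p$c_S_crit, tolerance = 1e-4)
  expect_gt(ev$feed_start, p$t_lag)
  expect_true(ev$Y_XS_batch > 0 && ev$Y_XS_batch < p$Y_true_XS)
  # batch phase at constant volume
  batch <- traj$V[traj$t <= ev$feed_start]
  expect_equal(batch, rep(cfg$V0, length(batch)))
  # terminal event: feed reservoir empty
  expect_lt(traj$v[nrow(traj)], 1e-6)
  # state non-negativity and strictly increasing time grid
  expect_true(all(traj$X >= 0 & traj$S >= 0 & traj$P >= 0 & traj$A >= 0))
  expect_true(all(diff(traj$t) > 0))
})

test_that("feed and volume ledgers are conserved along trajectories", {
  for (mu_F in c(0.15, 0.3)) {
    cfg <- small_fedbatch_config(mu_F = mu_F)
    traj <- simulate_fed_batch(cfg)
    ev <- trajectory_events(traj)
    n <- nrow(traj)
    p <- cfg$parameters
    # volume ledger: reactor gain is c_vol times the feed volume delivered
    expect_equal(traj$V[n] - cfg$V0, p$c_vol * (cfg$v0 - traj$v[n]),
                 tolerance = 1e-6)
    # feed ledger: glucose delivered matches the analytic feed integral
    fed_analytic <- ev$F0 / (p$rho_feed * mu_F) *
      (exp(mu_F * (traj$t[n] - ev$feed_start)) - 1) * p$c_S_feed
    expect_equal(p$c_S_feed * (cfg$v0 - traj$v[n]), fed_analytic,
                 tolerance = 1e-4 * fed_analytic)
  }
})

test_that("without an acetate source the acetate state stays at zero", {
  p <- kinetic_parameters(b_max = 0, .validate = FALSE)
  cfg <- small_fedbatch_config(params = p)
  traj <- simulate_fed_batch(cfg)
  expect_true(all(traj$A == 0))
  expect_true(all(traj$mu_A == 0))
})

test_that("saturating glucose gives closed-form exponential growth", {
  # S >> K_S and no overflow: X(t) = X0 * exp(mu_max * (t - t_lag))
  p <- kinetic_parameters(t_lag = 1)
  cfg <- fast_config(parameters = p,
                     feed = feed_settings(0.2, mode = "triggered"),
                     X0 = 0.5, S0 = 2000, V0 = 10, v0 = 5,
                     variant = "no_overflow")
  traj <- simulate_fed_batch(cfg)
  win <- traj$t >= 1 & traj$t <= 6
  expect_equal(traj$X[win], 0.5 * exp(p$mu_max_S * (traj$t[win] - 1)),
               tolerance = 0.01)
  # lag-phase contract: state untouched before t_lag
  lag <- traj$t <= 1
  expect_equal(traj$X[lag], rep(0.5, sum(lag)))
  expect_equal(traj$S[lag], rep(2000, sum(lag)))
})

test_that("no-overflow variant matches the full model when acetate is absent", {
  p0 <- kinetic_parameters(b_max = 0, .validate = FALSE)
  cfg_full <- small_fedbatch_config(params = p0)
  cfg_red <- small_fedbatch_config()
  cfg_red$variant <- "no_overflow"
  tf <- simulate_fed_batch(cfg_full)
  tr <- simulate_fed_batch(cfg_red)
  expect_equal(max(tf$t), max(tr$t), tolerance = 1e-5)
  tt <- seq(0, min(max(tf$t), max(tr$t)), by = 1)
  sf <- sample_trajectory(tf, tt)
  sr <- sample_trajectory(tr, tt)
  for (col in c("X_conc", "S_conc", "P_conc", "A_conc")) {
    expect_equal(sf[[col]], sr[[col]], tolerance = 1e-5)
  }
})

test_that("acetate formation and consumption are never simultaneously active", {
  for (mu_F in c(0.25, 0.4)) {
    traj <- simulate_fed_batch(small_fedbatch_config(mu_F = mu_F))
    expect_false(any(traj$mu_A > 0 & traj$b > 0))
  }
})

test_that("halving solver tolerances leaves the endpoint titre unchanged", {
  cfg1 <- small_fedbatch_config()
  cfg2 <- small_fedbatch_config(ctrl = list(rtol = 5e-8, atol = 5e-10,
                                            hmax = 0.25, dt_out = 0.25))
  p1 <- compute_performance(simulate_fed_batch(cfg1))
  p2 <- compute_performance(simulate_fed_batch(cfg2))
  expect_equal(p1$final_titre, p2$final_titre, tolerance = 1e-3)
})

test_that("batch-free mode starts feeding at the fixed time", {
  cfg <- design_config(28, ctrl = fast_ctrl)
  traj <- simulate_batch_free(cfg)
  ev <- trajectory_events(traj)
  expect_equal(ev$feed_start, 1 / 60)
  # volume already rising between feed start and lag end
  i <- traj$t > 0.05 & traj$t < 0.25
  expect_true(all(diff(traj$V[which(i)]) > 0))
  # biology silent during lag even though feed runs
  expect_equal(traj$X[traj$t <= 0.25], rep(0.696, sum(traj$t <= 0.25)))
  expect_lt(traj$v[nrow(traj)], 1e-6)
})

test_that("performance indicators satisfy their defining identities", {
  traj <- simulate_fed_batch(small_fedbatch_config())
  perf <- compute_performance(traj)
  expect_equal(perf$P_V, perf$P_end / (perf$V_end * perf$t_end))
  expect_gte(perf$max_titre, perf$final_titre)
  expect_equal(perf$Y_PX / perf$t_end, perf$q_PX)
  # overall yields from the endpoint ledgers are positive and below 1
  expect_true(perf$Y_PX > 0 && perf$Y_PX < 1)
  expect_true(perf$Y_XS > 0 && perf$Y_XS < 1)
  # saturating-glucose productivity approaches mu_max * Y_PX
  i <- which(traj$S_conc > 5 & traj$t > trajectory_events(traj)$lag_end)
  prod_rate <- traj$mu_S[i] * attr(traj, "config")$parameters$Y_PX
  expect_lt(max(prod_rate), 0.5 * 0.71 + 1e-9)
})

test_that("trajectory interpolation is exact at nodes and at the origin", {
  traj <- simulate_fed_batch(small_fedbatch_config())
  nodes <- traj$t[c(3, 10, 25)]
  s <- sample_trajectory(traj, nodes)
  expect_equal(s$X_conc, traj$X_conc[c(3, 10, 25)])
  s0 <- sample_trajectory(traj, 0)
  cfg <- attr(traj, "config")
  expect_equal(s0$S_conc, cfg$S0 / cfg$V0)
  expect_error(sample_trajectory(traj, max(traj$t) + 1), "span")
})

test_that("degenerate configurations fail with informative errors", {
  cfg <- small_fedbatch_config()
  cfg$S0 <- 0.1 # below the trigger threshold from the start
  expect_error(simulate_fed_batch(cfg), "c_S_crit")
  expect_error(simulation_config(V0 = -1), "V0")
  expect_error(feed_settings(0.2, mode = "fixed-time"), "F0")
})
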