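test_that("glucose growth rate follows Monod kinetics with acetate inhibition", {
  p <- kinetic_parameters()
  # half-saturation without acetate gives mu_max / 2
  expect_equal(monod_growth_rate_glucose(p$K_S, 0, p), p$mu_max_S / 2)
  # no substrate, no growth
  expect_equal(monod_growth_rate_glucose(0, 3, p), 0)
  # direct evaluation with acetate at the inhibition constant
  expect_equal(monod_growth_rate_glucose(5, 5, p), 0.5 * (5 / 5.05) * 0.5)
  expect_error(monod_growth_rate_glucose(-1, 0, p), "non-negative")
})

test_that("glucose growth rate is monotone in substrate and inhibitor", {
  p <- kinetic_parameters()
  set.seed(11)
  for (i in 1:20) {
    S <- sort(runif(10, 0, 30))
    A <- runif(1, 0, 10)
    mu <- monod_growth_rate_glucose(S, A, p)
    expect_true(all(diff(mu) >= 0))
    expect_true(all(mu >= 0 & mu <= p$mu_max_S))
    A2 <- sort(runif(10, 0, 10))
    mu2 <- monod_growth_rate_glucose(runif(1, 0, 30), A2, p)
    expect_true(all(diff(mu2) <= 0))
  }
})

test_that("acetate growth rate respects its three gating conditions", {
  p <- kinetic_parameters()
  # half-saturation in the active regime
  expect_equal(monod_growth_rate_acetate(0.01, p$K_A, p), p$mu_max_A / 2)
  # glucose above the critical level gates acetate use off
  expect_equal(monod_growth_rate_acetate(0.2, 1, p), 0)
  # no glucose at all also gates it off
  expect_equal(monod_growth_rate_acetate(0, 1, p), 0)
  # no acetate, no rate
  expect_equal(monod_growth_rate_acetate(0.01, 0, p), 0)
})

test_that("acetate formation ramp is continuous, clamped and piecewise linear", {
  p <- kinetic_parameters()
  expect_equal(acetate_formation_rate(p$c_S_crit_A1, p), 0)
  expect_equal(acetate_formation_rate(p$c_S_crit_A2, p), p$b_max)
  mid <- (p$c_S_crit_A1 + p$c_S_crit_A2) / 2
  expect_equal(acetate_formation_rate(mid, p), p$b_max / 2)
  set.seed(5)
  for (i in 1:20) {
    a1 <- runif(1, 0.01, 2); a2 <- a1 + runif(1, 0.5, 8)
    pp <- kinetic_parameters(c_S_crit_A1 = a1, c_S_crit_A2 = a2,
                             .validate = FALSE)
    S <- seq(0, a2 * 1.5, length.out = 200)
    b <- acetate_formation_rate(S, pp)
    expect_true(all(b[S <= a1] == 0))
    expect_true(all(b[S >= a2] == pp$b_max))
    # continuity: neighbouring grid values differ by at most the local slope
    expect_true(max(abs(diff(b))) <=
                  pp$b_max / (a2 - a1) * max(diff(S)) + 1e-12)
  }
  expect_error(
    acetate_formation_rate(1, kinetic_parameters(c_S_crit_A1 = 6,
                                                 .validate = FALSE)),
    "c_S_crit_A1")
})

test_that("Pirt yield interpolates between 0 and the true yield", {
  p <- kinetic_parameters()
  expect_equal(pirt_biomass_yield(0.3, kinetic_parameters(m_S = 0)),
               kinetic_parameters()$Y_true_XS)
  expect_equal(pirt_biomass_yield(0, p), 0)
  expect_equal(pirt_biomass_yield(0.2, p), 0.2 / (0.2 / 0.45 + 0.05))
  mu <- seq(0.01, 50, length.out = 300)
  y <- pirt_biomass_yield(mu, p)
  expect_true(all(diff(y) > 0))
  expect_true(all(y < p$Y_true_XS))
  expect_lt(p$Y_true_XS - pirt_biomass_yield(1e4, p), 1e-3)
})

test_that("exponential feed satisfies the semigroup property and its limits", {
  fs <- feed_settings(0.2, F0 = 28, mode = "fixed-time")
  expect_equal(feed_rate(0, fs), 28)
  expect_equal(feed_rate(log(2) / 0.2, fs), 56)
  fs0 <- feed_settings(0, F0 = 28, mode = "fixed-time")
  expect_equal(feed_rate(17.3, fs0), 28)
  set.seed(3)
  t1 <- runif(20, 0, 10); t2 <- runif(20, 0, 10)
  expect_equal(feed_rate(t1 + t2, fs),
               feed_rate(t1, fs) * feed_rate(t2, fs) / fs$F0)
  expect_error(feed_rate(-0.1, fs), "non-negative")
})

test_that("initial feed rate follows the design rule", {
  p <- kinetic_parameters()
  expect_equal(initial_feed_rate(84, 0.2, p),
               (0.2 / 0.28 + 0.05) * 84 / 500 * 1180)
  p1 <- kinetic_parameters(Y_XS_batch = 0.5, m_S = 0, .validate = FALSE)
  expect_equal(initial_feed_rate(500, 0.5, p1, Y_XS_batch = 0.5), 1180)
  expect_equal(initial_feed_rate(168, 0.2, p), 2 * initial_feed_rate(84, 0.2, p))
  expect_error(initial_feed_rate(0, 0.2, p), "X_FS")
})

test_that("state derivatives implement the mass balances and lag contract", {
  p <- kinetic_parameters()
  s <- list(X = 10, S = 40, P = 5, A = 2, V = 10, v = 6)
  # dormant system: nothing present, no feed
  d0 <- state_derivatives(list(X = 10, S = 0, P = 5, A = 0, V = 10, v = 6), p)
  expect_equal(unname(d0$derivatives), rep(0, 6))
  # lag phase: biology off regardless of substrate
  dl <- state_derivatives(s, p, in_lag = TRUE)
  expect_equal(unname(dl$derivatives[c("dX", "dP", "dA", "dS")]), rep(0, 4))
  # growth-coupled product term
  d <- state_derivatives(list(X = 10, S = 500, P = 0, A = 0, V = 10, v = 6), p)
  mu <- d$rates[["mu_S"]]
  expect_equal(d$derivatives[["dP"]], mu * p$Y_PX * 10)
  expect_equal(state_derivatives(
    list(X = 10, S = 1e9, P = 0, A = 0, V = 10, v = 1),
    kinetic_parameters(Y_PX = 0.71))$derivatives[["dP"]],
    0.5 * 0.71 * 10, tolerance = 1e-6)
})

test_that("glucose ledger closes: dS equals inflow minus independent drains", {
  p <- kinetic_parameters()
  fs <- feed_settings(0.2, F0 = 28, mode = "fixed-time")
  set.seed(21)
  for (i in 1:25) {
    s <- list(X = runif(1, 0.1, 100), S = runif(1, 0.1, 300),
              P = runif(1, 0, 50), A = runif(1, 0, 20),
              V = runif(1, 10, 18), v = runif(1, 0.5, 10))
    feeding <- i %% 2 == 0
    d <- state_derivatives(s, p, fs = fs, t_since_feed_start = runif(1, 0, 5),
                           feeding_active = feeding)
    # independent reconstruction from the exported rate laws
    Sc <- s$S / s$V; Ac <- s$A / s$V
    mu_S <- monod_growth_rate_glucose(Sc, Ac, p)
    mu_A <- monod_growth_rate_acetate(Sc, Ac, p)
    b <- acetate_formation_rate(Sc, p)
    inflow <- d$rates[["F"]] / p$rho_feed * p$c_S_feed
    growth_drain <- if (mu_S > 0) mu_S / pirt_biomass_yield(mu_S, p) * s$X
                    else p$m_S * s$X
    product_drain <- mu_S * p$Y_PX * s$X / p$Y_PS
    acetate_drain <- if (mu_A > 0) 0 else b * s$X / p$Y_AS
    expect_equal(d$derivatives[["dS"]],
                 inflow - growth_drain - product_drain - acetate_drain,
                 tolerance = 1e-10)
    # acetate formation and consumption never simultaneously active
    expect_false(d$rates[["mu_A"]] > 0 && d$rates[["b"]] > 0)
  }
})
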