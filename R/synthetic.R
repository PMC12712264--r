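#' Measurement noise model for synthetic observations
#'
#' Multiplicative log-normal noise with a per-state coefficient of variation
#' (defaults: 5% for biomass and surfactin, 3% for the enzymatic glucose and
#' acetate assays), an additive Gaussian floor, and censoring of glucose
#' readings below the assay detection limit.
#'
#' @param cv named CVs per state (fractions).
#' @param floor additive noise standard deviation (g/L).
#' @param detection_limit_S glucose detection limit (g/L).
#' @param censor what to do with glucose below the limit: `"drop"` records
#'   `NA`, `"clamp"` records the limit itself.
#' @return A list of class `surfkin_noise`.
#' @export
noise_model <- function(cv = c(X = 0.05, S = 0.03, P = 0.05, A = 0.03),
                        floor = 0.01,
                        detection_limit_S = 0.05,
                        censor = c("drop", "clamp")) {
  censor <- match.arg(censor)
  if (any(cv < 0) || floor < 0 || detection_limit_S < 0) {
    stop("noise magnitudes must be non-negative", call. = FALSE)
  }
  if (!all(c("X", "S", "P", "A") %in% names(cv))) {
    stop("cv must name X, S, P, A", call. = FALSE)
  }
  structure(list(cv = cv, floor = floor,
                 detection_limit_S = detection_limit_S, censor = censor),
            class = "surfkin_noise")
}

#' Apply the noise model to a vector of true concentrations
#'
#' @param x true concentrations (g/L).
#' @param cv coefficient of variation of the multiplicative term.
#' @param floor additive noise sd (g/L).
#' @return noisy concentrations, clipped at zero. With `cv = 0` and
#'   `floor = 0` the input is returned unchanged.
#' @keywords internal
.apply_noise <- function(x, cv, floor) {
  if (cv > 0) {
    sdlog <- sqrt(log1p(cv^2))
    x <- x * exp(stats::rnorm(length(x), -sdlog^2 / 2, sdlog))
  }
  if (floor > 0) x <- x + stats::rnorm(length(x), 0, floor)
  pmax(x, 0)
}

#' Generate a synthetic set of fed-batch experiments
#'
#' Emulates the study layout of duplicate fed-batch runs across a set of
#' exponential feeding growth rates: for every (rate, replicate) pair the
#' fed-batch model is simulated from jittered initial conditions and lag
#' duration, sampled on a regular grid, and degraded with assay noise and
#' glucose detection-limit censoring. Deterministic under the seed.
#'
#' @param params a [kinetic_parameters()] set (the generating truth).
#' @param feeding_rates feeding growth rates (1/h); default the six study
#'   rates 0.075-0.4 1/h.
#' @param replicates runs per rate (default 2, giving 12 experiments).
#' @param noise a [noise_model()]; use zero CVs/floor for noiseless data.
#' @param sampling_interval sampling spacing (h).
#' @param init initial amounts/volumes shared by all runs (g, L); defaults
#'   emulate a 10 L batch at 25 g/L glucose with a 6 L feed reservoir.
#' @param jitter list with relative jitter on `X0`, `S0` and absolute jitter
#'   (h) on `t_lag`; set all to 0 for identical replicates.
#' @param seed RNG seed.
#' @param sim_control solver overrides for the generating simulations.
#' @return list of [observations()] objects, one per experiment, each with a
#'   `truth` attribute holding the generating trajectory sample and settings.
#' @export
generate_experiment_set <- function(params = kinetic_parameters(),
                                    feeding_rates = c(0.075, 0.15, 0.2,
                                                      0.25, 0.3, 0.4),
                                    replicates = 2,
                                    noise = noise_model(),
                                    sampling_interval = 1,
                                    init = list(X0 = 1, S0 = 250, P0 = 0,
                                                A0 = 0, V0 = 10, v0 = 6),
                                    jitter = list(X0 = 0.1, S0 = 0.05,
                                                  t_lag = 0.5),
                                    seed = 42,
                                    sim_control = list(rtol = 1e-8,
                                                       atol = 1e-10,
                                                       hmax = 0.1,
                                                       dt_out = 0.1)) {
  set.seed(seed)
  tab <- parameter_table()
  lag_lo <- tab$lower[tab$name == "t_lag"]
  lag_hi <- tab$upper[tab$name == "t_lag"]
  out <- list()
  for (mu_F in feeding_rates) {
    for (rep_i in seq_len(replicates)) {
      run_init <- init
      run_init$X0 <- init$X0 * (1 + stats::runif(1, -jitter$X0, jitter$X0))
      run_init$S0 <- init$S0 * (1 + stats::runif(1, -jitter$S0, jitter$S0))
      t_lag <- params$t_lag + stats::runif(1, -jitter$t_lag, jitter$t_lag)
      t_lag <- min(max(t_lag, lag_lo), lag_hi)
      p_run <- params
      p_run$t_lag <- t_lag
      cfg <- do.call(simulation_config, c(
        list(parameters = p_run,
             feed = feed_settings(mu_F = mu_F, mode = "triggered"),
             X0 = run_init$X0, S0 = run_init$S0, P0 = run_init$P0,
             A0 = run_init$A0, V0 = run_init$V0, v0 = run_init$v0),
        sim_control))
      traj <- simulate_fed_batch(cfg)
      t_end <- max(traj$t)
      times <- unique(c(seq(0, t_end, by = sampling_interval), t_end))
      truth <- sample_trajectory(traj, times)
      X <- .apply_noise(truth$X_conc, noise$cv[["X"]], noise$floor)
      S <- .apply_noise(truth$S_conc, noise$cv[["S"]], noise$floor)
      P <- .apply_noise(truth$P_conc, noise$cv[["P"]], noise$floor)
      A <- .apply_noise(truth$A_conc, noise$cv[["A"]], noise$floor)
      low <- S < noise$detection_limit_S
      if (any(low)) {
        S[low] <- if (noise$censor == "drop") NA_real_ else
          noise$detection_limit_S
      }
      id <- sprintf("muF%.3g_rep%d", mu_F, rep_i)
      obs <- observations(id = id, mu_F = mu_F, times = times,
                          X = X, S = S, P = P, A = A,
                          init = run_init, t_lag = t_lag)
      attr(obs, "truth") <- list(sample = truth, t_lag = t_lag,
                                 init = run_init,
                                 events = trajectory_events(traj))
      out[[id]] <- obs
    }
  }
  out
}

#' Convert optical density to cell dry weight
#'
#' Linear OD600-to-CDW correlation, `CDW = 0.232 * OD600` (g/L).
#'
#' @param od600 optical density at 600 nm (vectorised, >= 0).
#' @param factor correlation factor (g/L per OD unit).
#' @return cell dry weight (g/L).
#' @export
od_to_cdw <- function(od600, factor = 0.232) {
  if (any(od600 < 0)) stop("OD must be non-negative", call. = FALSE)
  factor * od600
}
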