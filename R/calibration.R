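#' Observations from one fed-batch experiment
#'
#' Container for the sampled concentration time series of a single bioreactor
#' run: cell dry weight `X`, glucose `S`, surfactin `P` and acetate `A`
#' (all g/L, `NA` = missing/censored), the feeding growth rate the run was
#' operated at, and the initial amounts/volumes needed to re-simulate it.
#'
#' @param id experiment identifier.
#' @param mu_F feeding growth rate of the run (1/h).
#' @param times sampling times (h), strictly increasing.
#' @param X,S,P,A measured concentrations (g/L); `NA` allowed.
#' @param init named list with `X0`, `S0`, `P0`, `A0` (g), `V0`, `v0` (L).
#' @param t_lag optional per-experiment lag duration (h) overriding the
#'   shared parameter during simulation.
#' @return A list of class `surfkin_observations` with element `data`
#'   (a data.frame `t`, `X`, `S`, `P`, `A`).
#' @export
observations <- function(id, mu_F, times, X, S, P, A,
                         init, t_lag = NA_real_) {
  n <- length(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  for (v in list(X, S, P, A)) {
    if (length(v) != n) stop("all series must match the time grid",
                             call. = FALSE)
    if (any(v < 0, na.rm = TRUE)) stop("concentrations must be >= 0 or NA",
                                       call. = FALSE)
  }
  need <- c("X0", "S0", "P0", "A0", "V0", "v0")
  if (!all(need %in% names(init))) {
    stop("init must provide ", paste(need, collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, mu_F = mu_F,
                 data = data.frame(t = times, X = X, S = S, P = P, A = A),
                 init = init[need], t_lag = t_lag),
            class = "surfkin_observations")
}

#' Root-mean-square error between model and observed series
#'
#' `sqrt(mean((model - obs)^2))` over pairwise complete values; shares the
#' units of the series (g/L here), is zero iff the overlapping values are
#' identical, and scales linearly under joint rescaling of both series.
#'
#' @param model_series,obs_series numeric vectors of equal length.
#' @return RMSE (same units as the inputs).
#' @export
#' @examples
#' rmse(c(1, 2), c(4, 6))  # residuals 3, 4 -> sqrt(25/2)
rmse <- function(model_series, obs_series) {
  if (length(model_series) != length(obs_series)) {
    stop("series lengths differ", call. = FALSE)
  }
  ok <- stats::complete.cases(model_series, obs_series)
  if (!any(ok)) stop("no overlapping observations for RMSE", call. = FALSE)
  sqrt(mean((model_series[ok] - obs_series[ok])^2))
}

#' Fit specification
#'
#' Declares which parameters are free, their bounds, the per-state objective
#' weights, and the optimizer/simulation controls used by [fit_parameters()]
#' and [fit_objective()].
#'
#' @param free character vector of free parameter names; bounds default to
#'   the ranges in [parameter_table()].
#' @param lower,upper optional named numeric overrides of the bounds.
#' @param weights named weights for the per-state RMSEs (states share g/L
#'   units, so equal weights by default).
#' @param n_starts number of multistart points for the global stage.
#' @param n_polish how many of the best starts get a local bounded polish.
#' @param seed RNG seed for the multistart sample.
#' @param penalty loss assigned to a failed simulation.
#' @param sim_control list of solver overrides used during fitting
#'   (trading a little accuracy for speed; the objective stays deterministic).
#' @return A list of class `surfkin_fitspec`.
#' @export
fit_spec <- function(free,
                     lower = NULL, upper = NULL,
                     weights = c(X = 1, S = 1, P = 1, A = 1),
                     n_starts = 20, n_polish = 2, seed = 42,
                     penalty = 1e6,
                     sim_control = list(rtol = 1e-7, atol = 1e-9,
                                        hmax = 0.25, dt_out = 0.25)) {
  if (length(free) < 1L) stop("at least one free parameter", call. = FALSE)
  tab <- parameter_table()
  unknown <- setdiff(free, tab$name)
  if (length(unknown)) stop("unknown free parameter(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  lo <- tab$lower[match(free, tab$name)]
  hi <- tab$upper[match(free, tab$name)]
  names(lo) <- names(hi) <- free
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(!is.finite(lo)) || any(!is.finite(hi))) {
    stop("free parameters need finite bounds (supply lower/upper for ",
         paste(free[!is.finite(lo) | !is.finite(hi)], collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(lo >= hi)) stop("bounds must satisfy lower < upper", call. = FALSE)
  structure(list(free = free, lower = lo, upper = hi, weights = weights,
                 n_starts = n_starts, n_polish = n_polish, seed = seed,
                 penalty = penalty, sim_control = sim_control),
            class = "surfkin_fitspec")
}

# Simulate one experiment under a parameter set and return the model
# concentrations at the observation times. `feed` overrides the default
# threshold-triggered feed (e.g. to replay an experiment's realised feed
# profile with a fixed start time and F0).
.simulate_experiment <- function(p, obs, sim_control, feed = NULL) {
  p_run <- p
  if (!is.na(obs$t_lag)) p_run$t_lag <- obs$t_lag
  if (is.null(feed)) feed <- feed_settings(mu_F = obs$mu_F, mode = "triggered")
  cfg <- do.call(simulation_config, c(
    list(parameters = p_run, feed = feed,
         X0 = obs$init$X0, S0 = obs$init$S0, P0 = obs$init$P0,
         A0 = obs$init$A0, V0 = obs$init$V0, v0 = obs$init$v0),
    sim_control))
  traj <- if (feed$mode == "triggered") simulate_fed_batch(cfg) else
    simulate_batch_free(cfg)
  tt <- pmin(obs$data$t, max(traj$t))
  sample_trajectory(traj, tt)
}

#' RMSE objective over a set of experiments
#'
#' Simulates every experiment under the supplied parameters and returns the
#' weighted total RMSE loss together with the full per-experiment, per-state
#' RMSE table. A failed simulation contributes the configured penalty and is
#' flagged in the table.
#'
#' @param params a [kinetic_parameters()] set.
#' @param experiments list of [observations()] objects.
#' @param spec a [fit_spec()].
#' @return list with `loss` (scalar), `rmse_table` (data.frame: experiment,
#'   mu_F, RMSE_X, RMSE_S, RMSE_P, RMSE_A, failed), and `mean_rmse`
#'   (per-state means over experiments).
#' @export
fit_objective <- function(params, experiments, spec) {
  states <- c("X", "S", "P", "A")
  rows <- lapply(experiments, function(obs) {
    sim <- tryCatch(.simulate_experiment(params, obs, spec$sim_control),
                    error = function(e) NULL)
    if (is.null(sim)) {
      return(data.frame(experiment = obs$id, mu_F = obs$mu_F,
                        RMSE_X = NA_real_, RMSE_S = NA_real_,
                        RMSE_P = NA_real_, RMSE_A = NA_real_, failed = TRUE))
    }
    r <- vapply(states, function(st) {
      o <- obs$data[[st]]
      m <- sim[[paste0(st, "_conc")]]
      if (all(is.na(o))) NA_real_ else rmse(m, o)
    }, numeric(1))
    data.frame(experiment = obs$id, mu_F = obs$mu_F,
               RMSE_X = r["X"], RMSE_S = r["S"], RMSE_P = r["P"],
               RMSE_A = r["A"], failed = FALSE, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  w <- spec$weights[states]
  per_exp <- as.matrix(tab[, paste0("RMSE_", states)])
  loss <- sum(t(per_exp) * w, na.rm = TRUE) + spec$penalty * sum(tab$failed)
  mean_rmse <- colMeans(per_exp, na.rm = TRUE)
  names(mean_rmse) <- states
  list(loss = loss, rmse_table = tab, mean_rmse = mean_rmse)
}

#' Bounded estimation of the free kinetic parameters
#'
#' Minimises the weighted multi-state RMSE loss of [fit_objective()] over the
#' free parameters within their bounds: a seeded stratified multistart over
#' the (normalised) bound box, followed by a bounded local polish (`nlminb`)
#' of the best candidates. All remaining parameters are held fixed at their
#' values in `start`.
#'
#' @param experiments list of [observations()] objects.
#' @param spec a [fit_spec()].
#' @param start a [kinetic_parameters()] set providing the fixed values and
#'   an initial guess for the free ones.
#' @return list with `parameters` (fitted set), `loss`, `rmse_table`,
#'   `converged` (logical), `evaluations`, and `free` (the fitted values).
#' @export
fit_parameters <- function(experiments, spec, start = kinetic_parameters()) {
  free <- spec$free
  lo <- spec$lower; hi <- spec$upper
  span <- hi - lo
  to_unit <- function(theta) (theta - lo) / span
  from_unit <- function(u) lo + pmin(pmax(u, 0), 1) * span
  n_eval <- 0L
  f_unit <- function(u) {
    theta <- from_unit(u)
    p <- start
    p[free] <- as.list(theta)
    n_eval <<- n_eval + 1L
    tryCatch(fit_objective(p, experiments, spec)$loss,
             error = function(e) spec$penalty)
  }
  k <- length(free)
  set.seed(spec$seed)
  # stratified (latin-hypercube style) multistart in the unit box
  n <- max(spec$n_starts, 1L)
  starts <- vapply(seq_len(k), function(j) {
    (sample.int(n) - stats::runif(n)) / n
  }, numeric(n))
  starts <- matrix(starts, nrow = n)
  starts <- rbind(to_unit(unlist(start[free])), starts)
  starts[1, ] <- pmin(pmax(starts[1, ], 0), 1)
  losses <- apply(starts, 1L, f_unit)
  ord <- order(losses)
  best <- NULL
  # derivative-free local polish: the loss is continuous but has event-grid
  # kinks, so simplex search is more reliable than finite-difference gradients
  for (i in ord[seq_len(min(spec$n_polish, nrow(starts)))]) {
    cand <- starts[i, ]
    fit <- NULL
    for (round in 1:2) {
      fit <- if (k == 1L) {
        stats::optim(cand, f_unit, method = "Brent", lower = 0, upper = 1,
                     control = list(reltol = 1e-12))
      } else {
        stats::optim(cand, f_unit, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-12))
      }
      cand <- fit$par
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= spec$penalty) {
    stop("all optimisation restarts failed to produce a valid simulation",
         call. = FALSE)
  }
  theta <- from_unit(best$par)
  fitted <- start
  fitted[free] <- as.list(theta)
  final <- fit_objective(fitted, experiments, spec)
  list(parameters = fitted, loss = final$loss, rmse_table = final$rmse_table,
       converged = best$convergence == 0L, evaluations = n_eval,
       free = stats::setNames(theta, free))
}
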