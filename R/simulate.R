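#' Simulation configuration
#'
#' Bundles initial state, kinetic parameters, feed settings, model variant and
#' solver controls for one fed-batch (or batch-free) simulation. State is kept
#' in absolute amounts: `X0`, `S0`, `P0`, `A0` in grams, volumes in litres.
#'
#' @param parameters a [kinetic_parameters()] set.
#' @param feed a [feed_settings()] object.
#' @param X0,S0,P0,A0 initial biomass, glucose, surfactin, acetate amounts (g).
#' @param V0 initial reactor filling volume (L).
#' @param v0 feed reservoir volume (L).
#' @param variant `"full"` model or `"no_overflow"` reduction (no acetate
#'   formation/consumption and no growth inhibition).
#' @param rtol,atol relative/absolute solver tolerances.
#' @param hmax maximum internal step size (h); keeps the exponential feed and
#'   the overflow regime switches resolved.
#' @param dt_out output grid spacing (h).
#' @param t_max_batch give up if the batch glucose threshold is not crossed by
#'   this time (h).
#' @return A list of class `surfkin_config`.
#' @export
simulation_config <- function(parameters = kinetic_parameters(),
                              feed = feed_settings(mu_F = 0.2, F0 = 28,
                                                   mode = "fixed-time"),
                              X0 = 0.696, S0 = 5, P0 = 0, A0 = 0,
                              V0 = 10, v0 = 10,
                              variant = c("full", "no_overflow"),
                              rtol = 1e-8, atol = 1e-10,
                              hmax = 0.05, dt_out = 0.05,
                              t_max_batch = 60) {
  variant <- match.arg(variant)
  if (any(c(X0, S0, P0, A0) < 0)) {
    stop("initial amounts must be non-negative", call. = FALSE)
  }
  if (V0 <= 0) stop("V0 must be positive", call. = FALSE)
  if (v0 <= 0) stop("v0 must be positive when feeding is enabled", call. = FALSE)
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive", call. = FALSE)
  structure(list(parameters = parameters, feed = feed,
                 X0 = X0, S0 = S0, P0 = P0, A0 = A0, V0 = V0, v0 = v0,
                 variant = variant, rtol = rtol, atol = atol,
                 hmax = hmax, dt_out = dt_out, t_max_batch = t_max_batch),
            class = "surfkin_config")
}

# Right-hand side shared by all phases. ctx: p, overflow, t_lag, feeding,
# F0, mu_F, t_feed_start, V_floor. Extra outputs: rates and feed flow.
.surfkin_rhs <- function(ctx) {
  p <- ctx$p
  force(ctx)
  function(t, y, parms) {
    X <- max(y[1L], 0); S <- max(y[2L], 0); A <- max(y[4L], 0)
    V <- max(y[5L], ctx$V_floor)
    Fm <- if (ctx$feeding) ctx$F0 * exp(ctx$mu_F * (t - ctx$t_feed_start)) else 0
    Fv <- Fm / p$rho_feed
    if (t < ctx$t_lag) {
      mu_S <- 0; mu_A <- 0; b <- 0; cons <- FALSE; maint_S <- 0
    } else {
      Sc <- S / V; Ac <- A / V
      inhib <- if (ctx$overflow) p$K_I / (Ac + p$K_I) else 1
      mu_S <- p$mu_max_S * Sc / (Sc + p$K_S) * inhib
      cons <- ctx$overflow && A > 0 && S > 0 && Sc < p$c_S_crit
      mu_A <- if (cons) p$mu_max_A * Ac / (Ac + p$K_A) else 0
      b <- if (ctx$overflow) {
        min(max(p$b_max * (Sc - p$c_S_crit_A1) /
                  (p$c_S_crit_A2 - p$c_S_crit_A1), 0), p$b_max)
      } else 0
      maint_S <- if (S > 0) p$m_S * S / (S + 1e-6) else 0
    }
    dX <- (mu_S + mu_A) * X
    dP <- mu_S * p$Y_PX * X
    a_form <- b * X
    # the A/(A + eps) factor regularises the depletion boundary so the
    # constant m_A drain vanishes continuously as acetate runs out
    a_cons <- if (cons) {
      (p$m_A + mu_A / p$Y_XA) * X * A / (A + 1e-6)
    } else 0
    dA <- a_form - a_cons
    dS <- Fv * p$c_S_feed - (mu_S / p$Y_true_XS + maint_S) * X -
      dP / p$Y_PS - (if (cons) 0 else a_form / p$Y_AS)
    dV <- if (ctx$feeding) p$c_vol * Fv else 0
    dv <- if (ctx$feeding) -Fv else 0
    list(c(dX, dS, dP, dA, dV, dv),
         c(mu_S = mu_S, mu_A = mu_A, b = b, F_gph = Fm))
  }
}

# Integrate one phase segment on a regular grid; optional root stops the
# integration (lsodar). Returns the deSolve output matrix.
.integrate_segment <- function(y, t0, t1, ctx, cfg, rootfunc = NULL) {
  if (t1 <= t0) return(NULL)
  times <- unique(c(seq(t0, t1, by = cfg$dt_out), t1))
  rhs <- .surfkin_rhs(ctx)
  out <- deSolve::ode(y = y, times = times, func = rhs, parms = NULL,
                      method = "lsodar", rootfunc = rootfunc,
                      rtol = cfg$rtol, atol = cfg$atol, hmax = cfg$hmax,
                      maxsteps = 20000)
  if (attr(out, "istate")[1L] < 0) {
    stop(sprintf("ODE integration failed in [%g, %g] h", t0, t1),
         call. = FALSE)
  }
  out
}

.feed_duration <- function(v0, F0, mu_F, rho_feed) {
  if (mu_F > 0) log1p(v0 * rho_feed * mu_F / F0) / mu_F else v0 * rho_feed / F0
}

.assemble_trajectory <- function(pieces, cfg, events) {
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  names(out)[1:7] <- c("t", "X", "S", "P", "A", "V", "v")
  out <- out[!duplicated(round(out$t, 9), fromLast = TRUE), , drop = FALSE]
  out <- out[order(out$t), , drop = FALSE]
  rownames(out) <- NULL
  for (col in c("X", "S", "P", "A", "v")) out[[col]] <- pmax(out[[col]], 0)
  out$X_conc <- out$X / out$V
  out$S_conc <- out$S / out$V
  out$P_conc <- out$P / out$V
  out$A_conc <- out$A / out$V
  fstart <- events$feed_start
  out$phase <- ifelse(out$t < events$lag_end, "lag",
                      ifelse(!is.na(fstart) & out$t >= fstart,
                             "feeding", "batch"))
  structure(out, events = events, config = cfg,
            class = c("surfkin_trajectory", "data.frame"))
}

#' Simulate a fed-batch process with threshold-triggered feeding
#'
#' Integrates the batch phase (constant reactor volume) until the glucose
#' concentration drops to the critical value `c_S_crit`, records the biomass
#' `X_FS` and time `t_FS` at that event, estimates the batch biomass yield
#' `Y_XS_batch = (X_FS - X0)/(S0 - S_FS)` from the batch ledger, derives the
#' initial feed rate from it (see [initial_feed_rate()]), then integrates the
#' exponential feeding phase until the feed reservoir is empty (`v = 0`,
#' terminal event).
#'
#' @param cfg a [simulation_config()] whose `feed` has `mode = "triggered"`.
#'   If `cfg$feed$F0` is non-`NULL` it overrides the computed value.
#' @return A `surfkin_trajectory` data.frame (time grid, amounts,
#'   concentrations, specific rates, phase labels) with an `events` attribute
#'   recording `lag_end`, `feed_start`, `feed_depleted`, `X_FS`, `S_FS`, `F0`
#'   and the estimated `Y_XS_batch`.
#' @export
simulate_fed_batch <- function(cfg) {
  p <- cfg$parameters
  fs <- cfg$feed
  if (fs$mode != "triggered") {
    stop("simulate_fed_batch requires feed mode 'triggered'", call. = FALSE)
  }
  if (cfg$S0 / cfg$V0 <= p$c_S_crit) {
    stop("initial glucose concentration must exceed c_S_crit", call. = FALSE)
  }
  y <- c(X = cfg$X0, S = cfg$S0, P = cfg$P0, A = cfg$A0, V = cfg$V0, v = cfg$v0)
  ctx <- list(p = p, overflow = cfg$variant == "full", t_lag = p$t_lag,
              feeding = FALSE, F0 = 0, mu_F = fs$mu_F, t_feed_start = 0,
              V_floor = cfg$V0)
  pieces <- list()
  t0 <- 0
  if (p$t_lag > 0) {
    seg <- .integrate_segment(y, 0, p$t_lag, ctx, cfg)
    pieces <- c(pieces, list(seg))
    y <- seg[nrow(seg), 2:7]
    t0 <- p$t_lag
  }
  rootf <- function(t, y, parms) max(y[2L], 0) / max(y[5L], cfg$V0) - p$c_S_crit
  seg <- .integrate_segment(y, t0, cfg$t_max_batch, ctx, cfg, rootfunc = rootf)
  t_FS <- attr(seg, "troot")
  if (is.null(t_FS) || length(t_FS) == 0L) {
    stop("glucose never crossed c_S_crit within t_max_batch; no feed start",
         call. = FALSE)
  }
  t_FS <- t_FS[1L]
  pieces <- c(pieces, list(seg))
  y <- seg[nrow(seg), 2:7]
  X_FS <- unname(y["X"]); S_FS <- unname(y["S"])
  Y_batch <- (X_FS - cfg$X0) / (cfg$S0 - S_FS)
  if (!is.finite(Y_batch) || Y_batch <= 0) Y_batch <- p$Y_XS_batch
  F0 <- if (is.null(fs$F0)) {
    initial_feed_rate(X_FS, fs$mu_F, p, Y_XS_batch = Y_batch)
  } else {
    fs$F0
  }
  ctx$feeding <- TRUE; ctx$F0 <- F0; ctx$t_feed_start <- t_FS
  t_end_guess <- t_FS + .feed_duration(cfg$v0, F0, fs$mu_F, p$rho_feed)
  rootv <- function(t, y, parms) y[6L]
  seg <- .integrate_segment(y, t_FS, t_end_guess * 1.001 + cfg$dt_out, ctx,
                            cfg, rootfunc = rootv)
  t_end <- attr(seg, "troot")
  if (is.null(t_end) || length(t_end) == 0L) {
    stop("feeding phase did not reach feed depletion", call. = FALSE)
  }
  pieces <- c(pieces, list(seg))
  events <- list(lag_end = p$t_lag, feed_start = t_FS,
                 feed_depleted = t_end[1L], X_FS = X_FS, S_FS = S_FS,
                 F0 = F0, Y_XS_batch = Y_batch, mode = "fed-batch")
  .assemble_trajectory(pieces, cfg, events)
}

#' Simulate the batch-free design process (fixed-time feeding)
#'
#' Same model as [simulate_fed_batch()], but the exponential feed starts at a
#' fixed time after inoculation (one minute by default) with a user-supplied
#' initial rate `F0`; there is no batch phase. Integration stops when the feed
#' reservoir is depleted (`v = 0`).
#'
#' @param cfg a [simulation_config()] whose `feed` has `mode = "fixed-time"`
#'   and a positive `F0`.
#' @return A `surfkin_trajectory`, as for [simulate_fed_batch()].
#' @export
#' @examples
#' cfg <- simulation_config(parameters = design_parameters(),
#'                          feed = feed_settings(0.2, F0 = 28, "fixed-time"),
#'                          dt_out = 0.1)
#' traj <- simulate_batch_free(cfg)
#' max(traj$P_conc)
simulate_batch_free <- function(cfg) {
  p <- cfg$parameters
  fs <- cfg$feed
  if (fs$mode != "fixed-time" || is.null(fs$F0)) {
    stop("simulate_batch_free requires feed mode 'fixed-time' with F0",
         call. = FALSE)
  }
  t_fs <- fs$t_feed_start
  y <- c(X = cfg$X0, S = cfg$S0, P = cfg$P0, A = cfg$A0, V = cfg$V0, v = cfg$v0)
  ctx <- list(p = p, overflow = cfg$variant == "full", t_lag = p$t_lag,
              feeding = FALSE, F0 = fs$F0, mu_F = fs$mu_F,
              t_feed_start = t_fs, V_floor = cfg$V0)
  pieces <- list()
  if (t_fs > 0) {
    # split the pre-feed segment at the lag kink when it falls inside
    t_mid <- if (p$t_lag > 0 && p$t_lag < t_fs) p$t_lag else NULL
    t_prev <- 0
    for (tb in c(t_mid, t_fs)) {
      seg <- .integrate_segment(y, t_prev, tb, ctx, cfg)
      pieces <- c(pieces, list(seg))
      y <- seg[nrow(seg), 2:7]
      t_prev <- tb
    }
  }
  ctx$feeding <- TRUE
  t_end_guess <- t_fs + .feed_duration(cfg$v0, fs$F0, fs$mu_F, p$rho_feed)
  rootv <- function(t, y, parms) y[6L]
  t0 <- t_fs
  if (p$t_lag > t_fs) {
    # lag ends inside the feeding phase: restart the solver at the kink
    seg <- .integrate_segment(y, t0, min(p$t_lag, t_end_guess), ctx, cfg)
    pieces <- c(pieces, list(seg))
    y <- seg[nrow(seg), 2:7]
    t0 <- min(p$t_lag, t_end_guess)
  }
  seg <- .integrate_segment(y, t0, t_end_guess * 1.001 + cfg$dt_out, ctx, cfg,
                            rootfunc = rootv)
  t_end <- attr(seg, "troot")
  if (is.null(t_end) || length(t_end) == 0L) {
    stop("feeding phase did not reach feed depletion", call. = FALSE)
  }
  pieces <- c(pieces, list(seg))
  events <- list(lag_end = p$t_lag, feed_start = t_fs,
                 feed_depleted = t_end[1L], X_FS = cfg$X0, S_FS = cfg$S0,
                 F0 = fs$F0, Y_XS_batch = p$Y_XS_batch, mode = "batch-free")
  .assemble_trajectory(pieces, cfg, events)
}

#' Trajectory event log
#'
#' @param traj a `surfkin_trajectory`.
#' @return the `events` attribute: lag end, feed start and feed depletion
#'   times, biomass and glucose at feed start, the initial feed rate actually
#'   used and the batch-phase biomass yield.
#' @export
trajectory_events <- function(traj) attr(traj, "events")

#' Performance indicators of a completed run
#'
#' Computes the endpoint indicators at feed depletion: product amount
#' `P_end` (g), final volume `V_end` (L), process time `t_end` (h), the
#' maximum product titre along the trajectory (g/L), the space-time-yield
#' `P_V = P_end / (V_end * t_end)` (g/(L*h)), overall yields from the
#' endpoint ledgers (`Y_PX = dP/dX`, `Y_PS = dP/dS_consumed`,
#' `Y_XS = dX/dS_consumed`) and the specific rates `q_PX`, `q_PS`
#' (yield divided by process time, g/(g*h)). Total glucose consumed is
#' `S0 + c_S_feed * (v0 - v_end) - S_end`.
#'
#' @param traj a `surfkin_trajectory`.
#' @return A list of class `surfkin_performance`.
#' @export
compute_performance <- function(traj) {
  cfg <- attr(traj, "config")
  ev <- attr(traj, "events")
  n <- nrow(traj)
  P_end <- traj$P[n]; V_end <- traj$V[n]; t_end <- traj$t[n]
  v_end <- traj$v[n]
  S_in <- cfg$S0 + cfg$parameters$c_S_feed * (cfg$v0 - v_end)
  S_consumed <- S_in - traj$S[n]
  dX <- traj$X[n] - cfg$X0
  dP <- P_end - cfg$P0
  Y_PX <- if (dX > 0) dP / dX else NA_real_
  Y_PS <- if (S_consumed > 0) dP / S_consumed else NA_real_
  Y_XS <- if (S_consumed > 0) dX / S_consumed else NA_real_
  structure(list(
    P_end = P_end, V_end = V_end, t_end = t_end,
    max_titre = max(traj$P_conc),
    final_titre = traj$P_conc[n],
    P_V = P_end / (V_end * t_end),
    Y_PX = Y_PX, Y_PS = Y_PS, Y_XS = Y_XS,
    q_PX = Y_PX / t_end, q_PS = Y_PS / t_end,
    S_consumed = S_consumed,
    X_end_conc = traj$X_conc[n], S_end_conc = traj$S_conc[n],
    A_end_conc = traj$A_conc[n],
    F0 = ev$F0, v_end = v_end
  ), class = "surfkin_performance")
}

#' @export
print.surfkin_performance <- function(x, ...) {
  cat(sprintf(
    paste0("Fed-batch performance\n",
           "  process time        %7.2f h\n",
           "  final volume        %7.2f L\n",
           "  product amount      %7.1f g\n",
           "  max titre           %7.2f g/L\n",
           "  space-time-yield    %7.3f g/(L*h)\n",
           "  Y_P/X %.3f  Y_P/S %.3f  Y_X/S %.3f g/g\n"),
    x$t_end, x$V_end, x$P_end, x$max_titre, x$P_V, x$Y_PX, x$Y_PS, x$Y_XS))
  invisible(x)
}

#' Interpolate a trajectory at observation times
#'
#' Linear interpolation of the concentration columns (and amounts) of a dense
#' trajectory at arbitrary times within its span; used to align model output
#' with sampled observations.
#'
#' @param traj a `surfkin_trajectory`.
#' @param times ordered times (h) within the trajectory span.
#' @return data.frame with `t` and interpolated `X_conc`, `S_conc`, `P_conc`,
#'   `A_conc` (g/L) plus `V` (L).
#' @export
sample_trajectory <- function(traj, times) {
  if (any(diff(times) < 0)) stop("times must be non-decreasing", call. = FALSE)
  eps <- 1e-9
  if (min(times) < traj$t[1] - eps || max(times) > traj$t[nrow(traj)] + eps) {
    stop("requested times outside the trajectory span", call. = FALSE)
  }
  cols <- c("X_conc", "S_conc", "P_conc", "A_conc", "V")
  out <- data.frame(t = times)
  for (col in cols) {
    out[[col]] <- stats::approx(traj$t, traj[[col]], xout = times,
                                rule = 2)$y
  }
  out
}
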