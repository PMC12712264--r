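#' Specific growth rate on glucose with acetate inhibition
#'
#' Monod kinetics on glucose extended by a general (non-competitive style)
#' inhibition term in the acetate concentration:
#' `mu_S = mu_max_S * S/(S + K_S) * K_I/(A + K_I)`, with `S` and `A` the
#' glucose and acetate concentrations (g/L).
#'
#' @param S_conc glucose concentration (g/L); vectorised.
#' @param A_conc acetate concentration (g/L); vectorised.
#' @param p a [kinetic_parameters()] set.
#' @return specific growth rate (1/h), in `[0, mu_max_S]`.
#' @export
#' @examples
#' p <- kinetic_parameters()
#' monod_growth_rate_glucose(p$K_S, 0, p)  # half-saturation: mu_max_S / 2
monod_growth_rate_glucose <- function(S_conc, A_conc, p) {
  if (any(S_conc < 0) || any(A_conc < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  p$mu_max_S * S_conc / (S_conc + p$K_S) * p$K_I / (A_conc + p$K_I)
}

#' Specific growth rate on acetate
#'
#' Monod kinetics on acetate, active only when three conditions hold
#' simultaneously: acetate is present, the glucose concentration is below the
#' critical level `c_S_crit`, and glucose is still present (the organism
#' cannot grow on acetate as sole carbon source). Otherwise the rate is zero.
#'
#' @inheritParams monod_growth_rate_glucose
#' @return specific growth rate (1/h), in `[0, mu_max_A]`.
#' @export
monod_growth_rate_acetate <- function(S_conc, A_conc, p) {
  if (any(S_conc < 0) || any(A_conc < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  active <- (A_conc > 0) & (S_conc > 0) & (S_conc < p$c_S_crit)
  ifelse(active, p$mu_max_A * A_conc / (A_conc + p$K_A), 0)
}

#' Specific acetate formation rate (overflow ramp)
#'
#' Piecewise-linear overflow switch: zero below the lower glucose threshold
#' `c_S_crit_A1`, equal to `b_max` above the upper threshold `c_S_crit_A2`,
#' and linearly interpolated in between. Continuous at both breakpoints.
#'
#' @param S_conc glucose concentration (g/L); vectorised.
#' @param p a [kinetic_parameters()] set (requires `c_S_crit_A1 < c_S_crit_A2`).
#' @return formation rate `b` (1/h) in `[0, b_max]`.
#' @export
acetate_formation_rate <- function(S_conc, p) {
  if (any(S_conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (p$c_S_crit_A1 >= p$c_S_crit_A2) {
    stop("c_S_crit_A1 must be strictly below c_S_crit_A2", call. = FALSE)
  }
  raw <- p$b_max * (S_conc - p$c_S_crit_A1) / (p$c_S_crit_A2 - p$c_S_crit_A1)
  pmin(pmax(raw, 0), p$b_max)
}

#' Pirt biomass yield on glucose
#'
#' Growth-rate-dependent biomass yield accounting for non-growth-associated
#' maintenance: `Y_XS(mu) = mu / (mu / Y_true_XS + m_S)`. Monotone increasing
#' in `mu` with supremum `Y_true_XS`. At `mu = 0` the yield is defined as 0
#' (maintenance dominates; convention also applied when `m_S = 0`).
#'
#' @param mu_S specific growth rate on glucose (1/h); vectorised.
#' @param p a [kinetic_parameters()] set.
#' @return yield (g biomass / g glucose).
#' @export
pirt_biomass_yield <- function(mu_S, p) {
  if (any(mu_S < 0)) stop("mu_S must be non-negative", call. = FALSE)
  ifelse(mu_S == 0, 0, mu_S / (mu_S / p$Y_true_XS + p$m_S))
}

#' Exponential feed mass rate
#'
#' `F(t) = F0 * exp(mu_F * t)` with `t` the time since feed start (h).
#'
#' @param t_since_feed_start hours since feeding began; vectorised.
#' @param fs a [feed_settings()] object (or any list with `F0` and `mu_F`).
#' @return feed mass rate (g/h).
#' @export
feed_rate <- function(t_since_feed_start, fs) {
  if (any(t_since_feed_start < 0)) {
    stop("time since feed start must be non-negative", call. = FALSE)
  }
  if (is.null(fs$F0)) stop("feed settings carry no F0", call. = FALSE)
  fs$F0 * exp(fs$mu_F * t_since_feed_start)
}

#' Initial feed rate from the biomass at feed start
#'
#' Design rule for the initial exponential feed rate:
#' `F0 = (mu_F / Y_XS_batch + m_S) * X_FS / c_S_feed * rho_feed`,
#' sizing the glucose delivery to sustain the target feeding growth rate
#' `mu_F` plus maintenance for the biomass `X_FS` present at feed start.
#'
#' @param X_FS biomass amount at feed start (g).
#' @param mu_F feeding growth rate (1/h).
#' @param p a [kinetic_parameters()] set (uses `Y_XS_batch`, `m_S`,
#'   `c_S_feed`, `rho_feed`).
#' @param Y_XS_batch optional batch-phase biomass yield (g/g) overriding
#'   `p$Y_XS_batch`, e.g. the value estimated from the simulated batch phase.
#' @return initial feed mass rate F0 (g/h).
#' @export
#' @examples
#' p <- kinetic_parameters()
#' initial_feed_rate(84, 0.2, p)  # ~151.5 g/h
initial_feed_rate <- function(X_FS, mu_F, p, Y_XS_batch = NULL) {
  Y <- if (is.null(Y_XS_batch)) p$Y_XS_batch else Y_XS_batch
  if (X_FS <= 0) stop("X_FS must be positive", call. = FALSE)
  if (mu_F < 0) stop("mu_F must be non-negative", call. = FALSE)
  if (Y <= 0) stop("batch biomass yield must be positive", call. = FALSE)
  if (p$c_S_feed <= 0) stop("c_S_feed must be positive", call. = FALSE)
  (mu_F / Y + p$m_S) * X_FS / p$c_S_feed * p$rho_feed
}

#' Time derivatives of the fed-batch state
#'
#' Evaluates the right-hand side of the four-state mass-balance system plus
#' the two volume equations at a single state, in absolute amounts:
#' \itemize{
#'   \item `dX = (mu_S + mu_A) * X`
#'   \item `dP = mu_S * Y_PX * X` (growth-coupled product)
#'   \item `dA = b*X - m_A*X - (mu_A/Y_XA)*X`, the consumption terms active
#'     only in the acetate-consumption regime
#'   \item `dS = (F/rho_feed)*c_S_feed - (mu_S/Y_true_XS + m_S)*X
#'     - (1/Y_PS)*dP - (1/Y_AS)*b*X`, the acetate-formation drain set to zero
#'     while acetate is being consumed; the biomass drain is the Pirt term
#'     `mu_S / Y_XS(mu_S)` in its algebraically reduced form
#'   \item `dV = c_vol * F/rho_feed` and `dv = -F/rho_feed` during feeding,
#'     zero otherwise
#' }
#' During the lag phase (`in_lag = TRUE`) all biological rates are zero and
#' the substrate is untouched; feeding and volume dynamics still apply.
#'
#' @param state named numeric vector or list with `X`, `S`, `P`, `A` (g) and
#'   `V`, `v` (L).
#' @param p a [kinetic_parameters()] set.
#' @param fs a [feed_settings()] object; only used when `feeding_active`.
#' @param t_since_feed_start hours since feed start (for the exponential feed).
#' @param in_lag logical: is the culture still in its lag phase?
#' @param feeding_active logical: is the feed pump running?
#' @param variant `"full"` or `"no_overflow"` (acetate dynamics, inhibition
#'   and acetate growth disabled).
#' @return list with `derivatives` (named: dX, dS, dP, dA, dV, dv) and
#'   `rates` (named: mu_S, mu_A, b, F).
#' @export
state_derivatives <- function(state, p, fs = NULL, t_since_feed_start = 0,
                              in_lag = FALSE, feeding_active = FALSE,
                              variant = c("full", "no_overflow")) {
  variant <- match.arg(variant)
  s <- as.list(state)
  X <- max(s$X, 0); S <- max(s$S, 0); A <- max(s$A, 0)
  V <- s$V
  if (V <= 0) stop("reactor volume must be positive", call. = FALSE)
  if (feeding_active) {
    if (is.null(fs)) stop("feeding_active requires feed settings", call. = FALSE)
    if (s$v <= 0) stop("feeding active with empty feed reservoir", call. = FALSE)
    Fm <- feed_rate(t_since_feed_start, fs)
  } else {
    Fm <- 0
  }
  overflow <- variant == "full"
  Sc <- S / V; Ac <- A / V
  if (in_lag) {
    mu_S <- 0; mu_A <- 0; b <- 0; cons <- FALSE; maint_S <- 0
  } else {
    inhib <- if (overflow) p$K_I / (Ac + p$K_I) else 1
    mu_S <- p$mu_max_S * Sc / (Sc + p$K_S) * inhib
    cons <- overflow && A > 0 && S > 0 && Sc < p$c_S_crit
    mu_A <- if (cons) p$mu_max_A * Ac / (Ac + p$K_A) else 0
    b <- if (overflow) acetate_formation_rate(Sc, p) else 0
    maint_S <- if (S > 0) p$m_S else 0
  }
  Fv <- Fm / p$rho_feed
  dX <- (mu_S + mu_A) * X
  dP <- mu_S * p$Y_PX * X
  a_form <- b * X
  a_cons <- if (cons) (p$m_A + mu_A / p$Y_XA) * X else 0
  dA <- a_form - a_cons
  dS <- Fv * p$c_S_feed - (mu_S / p$Y_true_XS + maint_S) * X -
    dP / p$Y_PS - (if (cons) 0 else a_form / p$Y_AS)
  dV <- if (feeding_active) p$c_vol * Fv else 0
  dv <- if (feeding_active) -Fv else 0
  list(
    derivatives = c(dX = dX, dS = dS, dP = dP, dA = dA, dV = dV, dv = dv),
    rates = c(mu_S = mu_S, mu_A = mu_A, b = b, F = Fm)
  )
}
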