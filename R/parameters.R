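#' Reference parameter table for the surfactin fed-batch model
#'
#' Returns the full set of model parameters with their default values, units,
#' fixed/free status, and the fitting bounds used when a parameter is free.
#' Defaults correspond to the calibrated *B. subtilis* BMV9 process at 37 degC,
#' pH 7, pO2 50%: Monod constants, stoichiometric and Pirt yields, maintenance
#' coefficients, acetate overflow thresholds and the feed characteristics
#' (500 g/L glucose feed of density 1180 g/L, volume correction factor 0.8).
#'
#' @return A data.frame with columns `name`, `value`, `lower`, `upper`,
#'   `fixed`, `unit`. `lower`/`upper` are `NA` for parameters that are never
#'   fitted.
#' @export
#' @examples
#' parameter_table()
parameter_table <- function() {
  data.frame(
    name = c("mu_max_S", "mu_max_A", "K_S", "K_A", "K_I",
             "Y_true_XS", "Y_PX", "Y_PS", "Y_AS", "Y_XS_batch", "Y_XA",
             "m_S", "m_A", "t_lag",
             "c_S_crit", "c_S_crit_A1", "c_S_crit_A2", "b_max",
             "c_S_feed", "rho_feed", "c_vol"),
    value = c(0.5, 0.5, 0.05, 0.05, 5,
              0.45, 0.71, 0.46, 0.67, 0.28, 0.45,
              0.05, 0.05, 3,
              0.05, 0.075, 5, 0.072,
              500, 1180, 0.8),
    lower = c(0.36, 0.36, NA, NA, 1,
              0.40, 0.54, NA, NA, 0.22, 0.30,
              NA, NA, 0.25,
              0.005, 0.05, 1, 0.01,
              NA, NA, NA),
    upper = c(1, 1, NA, NA, 10,
              0.46, 0.75, NA, NA, 0.37, 0.60,
              NA, NA, 5.25,
              0.5, 0.1, 10, 0.2,
              NA, NA, NA),
    fixed = c(FALSE, FALSE, TRUE, TRUE, FALSE,
              FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
              TRUE, TRUE, FALSE,
              FALSE, FALSE, FALSE, FALSE,
              TRUE, TRUE, TRUE),
    unit = c("1/h", "1/h", "g/L", "g/L", "g/L",
             "g/g", "g/g", "g/g", "g/g", "g/g", "g/g",
             "g/(g*h)", "g/(g*h)", "h",
             "g/L", "g/L", "g/L", "1/h",
             "g/L", "g/L", "-"),
    stringsAsFactors = FALSE
  )
}

#' Construct a kinetic parameter set
#'
#' Builds a validated named list of kinetic parameters, starting from the
#' package defaults (see [parameter_table()]) and applying any overrides given
#' as named arguments.
#'
#' Parameters (all non-negative):
#' \describe{
#'   \item{mu_max_S, mu_max_A}{maximum specific growth rates on glucose and
#'     acetate (1/h)}
#'   \item{K_S, K_A}{Monod half-saturation constants (g/L)}
#'   \item{K_I}{acetate inhibition constant in the growth term (g/L)}
#'   \item{Y_true_XS}{theoretical maximum biomass-per-glucose yield (g/g)}
#'   \item{Y_PX}{surfactin-per-biomass yield (g/g)}
#'   \item{Y_PS, Y_AS}{stoichiometric surfactin/acetate-per-glucose yields (g/g)}
#'   \item{Y_XS_batch}{batch-phase biomass yield used in the initial feed-rate
#'     rule when no batch trajectory is available (g/g)}
#'   \item{Y_XA}{biomass-per-acetate yield (g/g)}
#'   \item{m_S, m_A}{glucose and acetate maintenance coefficients (g/(g*h))}
#'   \item{t_lag}{lag-phase duration (h)}
#'   \item{c_S_crit}{critical glucose concentration triggering the feed and
#'     gating acetate consumption (g/L)}
#'   \item{c_S_crit_A1, c_S_crit_A2}{lower/upper glucose thresholds of the
#'     acetate formation ramp (g/L)}
#'   \item{b_max}{maximum specific acetate formation rate (1/h)}
#'   \item{c_S_feed}{feed glucose concentration (g/L)}
#'   \item{rho_feed}{feed solution density (g/L)}
#'   \item{c_vol}{volume correction factor applied to feed volume inflow}
#' }
#'
#' @param ... named parameter overrides, e.g. `kinetic_parameters(b_max = 0.1)`.
#' @param .validate set `FALSE` to skip validation (internal use).
#' @return A named list of class `surfkin_parameters`.
#' @export
#' @examples
#' p <- kinetic_parameters(t_lag = 0.25, Y_PX = 0.71)
#' p$mu_max_S
kinetic_parameters <- function(..., .validate = TRUE) {
  tab <- parameter_table()
  p <- stats::setNames(as.list(tab$value), tab$name)
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over)))) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(over), tab$name)
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(over)] <- lapply(over, as.numeric)
  }
  class(p) <- "surfkin_parameters"
  if (.validate) validate_parameters(p)
  p
}

#' Parameter set for the model-based (batch-free) process design
#'
#' The reference parameter set with the design-stage overrides applied:
#' growth-coupled product yield `Y_PX = 0.71` g/g and a short lag phase
#' `t_lag = 0.25` h.
#'
#' @param ... further overrides passed to [kinetic_parameters()].
#' @return A `surfkin_parameters` list.
#' @export
design_parameters <- function(...) {
  kinetic_parameters(Y_PX = 0.71, t_lag = 0.25, ...)
}

#' Validate a kinetic parameter set
#'
#' Checks non-negativity of every rate, yield and threshold, the ordering of
#' the acetate-formation thresholds (`c_S_crit_A1 < c_S_crit_A2`), positivity
#' of the feed characteristics, and - where fitting bounds exist - that each
#' value lies inside its bounds.
#'
#' @param p a `surfkin_parameters` list.
#' @return `p`, invisibly; stops with an informative error otherwise.
#' @export
validate_parameters <- function(p) {
  tab <- parameter_table()
  missing <- setdiff(tab$name, names(p))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- unlist(p[tab$name])
  if (any(!is.finite(vals))) {
    stop("non-finite parameter value(s): ",
         paste(tab$name[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("negative parameter value(s): ",
         paste(tab$name[vals < 0], collapse = ", "), call. = FALSE)
  }
  if (p$c_S_crit_A1 >= p$c_S_crit_A2) {
    stop("c_S_crit_A1 must be strictly below c_S_crit_A2", call. = FALSE)
  }
  if (p$c_S_feed <= 0 || p$rho_feed <= 0) {
    stop("c_S_feed and rho_feed must be positive", call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    lo <- tab$lower[i]; hi <- tab$upper[i]
    if (!is.na(lo) && !is.na(hi)) {
      v <- p[[tab$name[i]]]
      if (v < lo - 1e-12 || v > hi + 1e-12) {
        stop(sprintf("parameter %s = %g outside its allowed range [%g, %g]",
                     tab$name[i], v, lo, hi), call. = FALSE)
      }
    }
  }
  invisible(p)
}

#' @export
print.surfkin_parameters <- function(x, ...) {
  tab <- parameter_table()
  cat("Surfactin fed-batch kinetic parameters\n")
  df <- data.frame(name = tab$name,
                   value = unlist(x[tab$name]),
                   unit = tab$unit,
                   fixed = tab$fixed,
                   row.names = NULL)
  print(df, ...)
  invisible(x)
}

#' Feed settings for an exponential feeding phase
#'
#' The exponential feed delivers a mass flow `F(t) = F0 * exp(mu_F * t)` with
#' `t` counted from the start of feeding. Feeding starts either when the batch
#' glucose concentration drops below `c_S_crit` (`mode = "triggered"`), in
#' which case `F0` is derived from the biomass at feed start, or at a fixed
#' time (`mode = "fixed-time"`, used by the batch-free design) with `F0`
#' supplied explicitly.
#'
#' @param mu_F feeding growth rate (1/h), the growth rate the feed is designed
#'   to impose.
#' @param F0 initial feed mass rate (g/h); required for `mode = "fixed-time"`,
#'   computed from the batch phase otherwise.
#' @param mode feed start mode.
#' @param t_feed_start feed start time for `"fixed-time"` mode (h); default one
#'   minute after inoculation.
#' @return A list of class `surfkin_feed`.
#' @export
feed_settings <- function(mu_F,
                          F0 = NULL,
                          mode = c("triggered", "fixed-time"),
                          t_feed_start = 1 / 60) {
  mode <- match.arg(mode)
  if (!is.numeric(mu_F) || length(mu_F) != 1L || mu_F < 0) {
    stop("mu_F must be a single non-negative number", call. = FALSE)
  }
  if (!is.null(F0)) {
    if (!is.numeric(F0) || length(F0) != 1L || F0 <= 0) {
      stop("F0 must be a single positive number", call. = FALSE)
    }
  }
  if (mode == "fixed-time") {
    if (is.null(F0)) stop("fixed-time feeding requires F0", call. = FALSE)
    if (t_feed_start < 0) stop("t_feed_start must be >= 0", call. = FALSE)
  }
  structure(list(mu_F = mu_F, F0 = F0, mode = mode,
                 t_feed_start = t_feed_start),
            class = "surfkin_feed")
}
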