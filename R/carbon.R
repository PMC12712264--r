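#' Carbon conversion factor of a species
#'
#' mol carbon per gram: number of carbon atoms per molecule divided by the
#' molar mass (for biomass, the convention is 1 atom per "C-mol" of formula
#' mass).
#'
#' @param atoms carbon atoms per molecule (>= 1).
#' @param molar_mass molar mass (g/mol).
#' @return factor in mol C per g.
#' @export
#' @examples
#' carbon_factor(6, 180.16)    # glucose, ~0.0333
#' carbon_factor(53, 1036.34)  # surfactin, ~0.0511
carbon_factor <- function(atoms, molar_mass) {
  if (any(atoms < 1)) stop("atoms must be >= 1", call. = FALSE)
  if (any(molar_mass <= 0)) stop("molar mass must be positive", call. = FALSE)
  atoms / molar_mass
}

#' Default carbon factors of the model's pools
#'
#' Glucose (6 C, 180.16 g/mol), biomass (C-mol mass 24.83 g/mol for
#' *B. subtilis*), surfactin (53 C, 1036.34 g/mol) and acetate
#' (2 C, 60.05 g/mol).
#'
#' @return named numeric vector (mol C/g) with elements `glucose`,
#'   `biomass`, `surfactin`, `acetate`.
#' @export
carbon_factors <- function() {
  c(glucose = carbon_factor(6, 180.16),
    biomass = carbon_factor(1, 24.83),
    surfactin = carbon_factor(53, 1036.34),
    acetate = carbon_factor(2, 60.05))
}

#' Carbon recovery of a fed-batch run
#'
#' Percentage of the carbon supplied as glucose that is recovered in the
#' biomass, product and by-product pools:
#' `100 * (C_X + C_P + C_A) / C_S_in`. The model carries no explicit CO2
#' sink, so recovery below 100% reflects respiration and unmodelled
#' by-products; no upper bound is enforced.
#'
#' @param glucose_in total glucose supplied (g; initial plus fed).
#' @param biomass,product,acetate endpoint masses (g).
#' @param factors carbon factors (mol C/g), as from [carbon_factors()].
#' @return recovery in percent.
#' @export
carbon_recovery <- function(glucose_in, biomass, product, acetate,
                            factors = carbon_factors()) {
  if (glucose_in <= 0) stop("glucose input must be positive", call. = FALSE)
  if (any(c(biomass, product, acetate) < 0)) {
    stop("masses must be non-negative", call. = FALSE)
  }
  c_in <- glucose_in * factors[["glucose"]]
  c_out <- biomass * factors[["biomass"]] +
    product * factors[["surfactin"]] +
    acetate * factors[["acetate"]]
  100 * c_out / c_in
}

#' Carbon balance of a simulated trajectory
#'
#' Converts the endpoint masses of a trajectory to carbon equivalents and
#' computes the recovery. Glucose input is the initial glucose plus the feed
#' actually delivered, `S0 + c_S_feed * (v0 - v_end)`.
#'
#' @param traj a `surfkin_trajectory`.
#' @param factors carbon factors (mol C/g).
#' @return one-row data.frame: mol C per pool (`C_in`, `C_X`, `C_P`, `C_A`)
#'   and `recovery_pct`.
#' @export
carbon_balance <- function(traj, factors = carbon_factors()) {
  cfg <- attr(traj, "config")
  n <- nrow(traj)
  glucose_in <- cfg$S0 + cfg$parameters$c_S_feed * (cfg$v0 - traj$v[n])
  data.frame(
    C_in = glucose_in * factors[["glucose"]],
    C_X = traj$X[n] * factors[["biomass"]],
    C_P = traj$P[n] * factors[["surfactin"]],
    C_A = traj$A[n] * factors[["acetate"]],
    recovery_pct = carbon_recovery(glucose_in, traj$X[n], traj$P[n],
                                   traj$A[n], factors)
  )
}
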