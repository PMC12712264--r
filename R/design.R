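#' Default initial-feed-rate grid for the design sweep
#'
#' 1 to 100 g/h in 0.5 g/h steps, augmented with the operating points of
#' interest (14.7, 28, 38, 38.5, 40, 100 g/h) so that the titre plateau, the
#' space-time-yield peak and the overflow collapse are all resolved.
#'
#' @return sorted numeric vector of feed rates (g/h).
#' @export
default_f0_grid <- function() {
  sort(unique(c(seq(1, 100, by = 0.5), 14.7, 28, 38, 38.5, 40, 100)))
}

#' Sweep the initial feed rate of the batch-free design
#'
#' Runs one batch-free simulation per grid point and collects the endpoint
#' performance: maximum and final titre, product amount, final volume,
#' process time, space-time-yield and endpoint concentrations. Individual
#' failures are recorded as `NA` rows rather than aborting the sweep.
#'
#' @param cfg a [simulation_config()] in `"fixed-time"` feed mode; its `F0`
#'   is replaced by each grid value in turn.
#' @param F0_grid positive feed rates (g/h) to evaluate.
#' @return A data.frame of class `surfkin_design` sorted by `F0`, with an
#'   attribute `argmax` listing the grid points maximising titre and STY.
#' @export
sweep_initial_feed_rate <- function(cfg, F0_grid = default_f0_grid()) {
  if (!length(F0_grid) || any(F0_grid <= 0)) {
    stop("F0 grid must be positive and non-empty", call. = FALSE)
  }
  if (cfg$feed$mode != "fixed-time") {
    stop("the design sweep runs in batch-free (fixed-time) mode", call. = FALSE)
  }
  F0_grid <- sort(unique(F0_grid))
  rows <- lapply(F0_grid, function(F0) {
    cfg$feed$F0 <- F0
    perf <- tryCatch(compute_performance(simulate_batch_free(cfg)),
                     error = function(e) NULL)
    if (is.null(perf)) {
      return(data.frame(F0 = F0, max_titre = NA_real_, final_titre = NA_real_,
                        P_end = NA_real_, V_end = NA_real_, t_end = NA_real_,
                        P_V = NA_real_, X_end_conc = NA_real_,
                        S_end_conc = NA_real_, A_end_conc = NA_real_))
    }
    data.frame(F0 = F0, max_titre = perf$max_titre,
               final_titre = perf$final_titre, P_end = perf$P_end,
               V_end = perf$V_end, t_end = perf$t_end, P_V = perf$P_V,
               X_end_conc = perf$X_end_conc, S_end_conc = perf$S_end_conc,
               A_end_conc = perf$A_end_conc)
  })
  res <- do.call(rbind, rows)
  argmax <- list(
    titre_F0 = res$F0[which.max(res$max_titre)],
    titre = max(res$max_titre, na.rm = TRUE),
    sty_F0 = res$F0[which.max(res$P_V)],
    sty = max(res$P_V, na.rm = TRUE)
  )
  structure(res, argmax = argmax,
            class = c("surfkin_design", "data.frame"))
}

#' Select an operating point from a design sweep
#'
#' Deterministic selection policies on a [sweep_initial_feed_rate()] result:
#' \describe{
#'   \item{`max_titre`}{the grid point with the highest maximum titre.}
#'   \item{`max_sty`}{the grid point with the highest space-time-yield.}
#'   \item{`sty_backoff`}{the grid point closest to `(1 - backoff)` times the
#'     STY-maximising feed rate, from below; a conservative margin under the
#'     STY peak (e.g. 25% backoff from 38 g/h lands near 28 g/h).}
#' }
#'
#' @param res a `surfkin_design`.
#' @param policy selection policy.
#' @param backoff fractional feed-rate backoff for `"sty_backoff"`.
#' @return one row of `res` (the chosen operating point).
#' @export
select_operating_point <- function(res,
                                   policy = c("max_sty", "max_titre",
                                              "sty_backoff"),
                                   backoff = 0.25) {
  policy <- match.arg(policy)
  ok <- !is.na(res$P_V)
  if (!any(ok)) stop("no successful grid points", call. = FALSE)
  res_ok <- res[ok, , drop = FALSE]
  i <- switch(policy,
    max_titre = which.max(res_ok$max_titre),
    max_sty = which.max(res_ok$P_V),
    sty_backoff = {
      f_star <- res_ok$F0[which.max(res_ok$P_V)]
      target <- (1 - backoff) * f_star
      cand <- which(res_ok$F0 <= target + 1e-9)
      if (!length(cand)) 1L else cand[which.max(res_ok$F0[cand])]
    })
  res_ok[i, , drop = FALSE]
}
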