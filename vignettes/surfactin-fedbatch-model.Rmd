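---
title: "A kinetic model of fed-batch surfactin production: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of fed-batch surfactin production: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfkin)
```

## The process and the model

`surfkin` models the production of surfactin — a cyclic lipopeptide
biosurfactant made non-ribosomally by *Bacillus subtilis* — in a stirred
bioreactor operated as a fed-batch: after (or instead of) an initial batch
phase on glucose, a concentrated glucose feed is pumped in at an
exponentially increasing mass rate

$$F(t) = F_0 \, e^{\mu_F t},$$

with $t$ counted from the start of feeding. The feeding growth rate $\mu_F$
(1/h) is the specific growth rate the feed is designed to impose on the
culture; the initial rate $F_0$ (g/h) is sized from the biomass present at
feed start,

$$F_0 = \left(\frac{\mu_F}{Y_{X/S,\mathrm{batch}}} + m_S\right)
        \frac{X_{FS}}{c_{S,\mathrm{feed}}}\,\rho_\mathrm{feed}.$$

The state is tracked in **absolute amounts**: biomass $X$, glucose $S$,
surfactin $P$ and acetate $A$ in grams, plus the reactor filling volume $V$
and the remaining feed volume $v$ in litres. Working in amounts keeps the
mass balances exact while the volume grows during feeding; concentrations
entering the rate laws are always the ratios $S/V$, $A/V$.

The four biological balances are:

* **Growth.** $dX/dt = (\mu_S + \mu_A)X$. Growth on glucose is Monod
  kinetics damped by a general acetate-inhibition factor,
  $\mu_S = \mu_{max}^S \frac{S/V}{S/V + K_S}\frac{K_I}{A/V + K_I}$.
  Growth on acetate, $\mu_A = \mu_{max}^A \frac{A/V}{A/V + K_A}$, is active
  only while three conditions hold at once: acetate is present, glucose is
  below the critical concentration $c_{S,crit}$, and glucose is not fully
  exhausted (the organism cannot grow on acetate as sole carbon source).
* **Product.** $dP/dt = \mu_S Y_{P/X} X$: purely growth-coupled formation
  (the non-growth-associated term of the classical growth/product coupling
  is zero), driven by glucose-supported growth only.
* **Glucose.** $dS/dt = \frac{F}{\rho_\mathrm{feed}} c_{S,\mathrm{feed}}
  - \frac{\mu_S}{Y_{X/S}(\mu_S)}X - \frac{1}{Y_{P/S}}\frac{dP}{dt}
  - \frac{1}{Y_{A/S}} bX$, where the biomass yield follows the Pirt
  relation $Y_{X/S}(\mu) = \mu / (\mu/Y^{true}_{X/S} + m_S)$ so that the
  drain reduces algebraically to $(\mu_S/Y^{true}_{X/S} + m_S)X$: growth
  plus maintenance. The acetate-formation drain is dropped whenever the
  culture is *consuming* acetate (it is then zero anyway, because the
  formation and consumption regimes are separated by the glucose
  thresholds; see below).
* **Acetate (overflow).** $dA/dt = bX - m_A X - \frac{\mu_A}{Y_{X/A}}X$.
  The specific formation rate $b$ is a continuous piecewise-linear ramp in
  the glucose concentration: zero below $c_{S,crit,A1}$, saturating at
  $b_{max}$ above $c_{S,crit,A2}$. The consumption terms ($m_A$ and
  $\mu_A$) are active only in the acetate-consumption regime. Because
  consumption requires $S/V < c_{S,crit} < c_{S,crit,A1}$, formation and
  consumption can never be active at the same time — an invariant the test
  suite asserts along whole trajectories.

Volumes follow $dV/dt = c \, F/\rho_\mathrm{feed}$ (the correction factor
$c$ absorbs sampling, pH agents, antifoam and the water content of the
feed) and $dv/dt = -F/\rho_\mathrm{feed}$; a run ends when the feed
reservoir is empty ($v = 0$). During the batch phase the reactor volume is
held constant. During the lag phase ($t < t_{lag}$) all biological rates
are zero and the substrate is untouched; feeding and volume dynamics still
apply if the pump is already running. This is the simplest lag mechanism
consistent with the role the fitted $t_{lag}$ plays; whether product
formation should pause independently of $\mu_S$ is unanswerable from the
data, so `surfkin` lets $dP/dt$ follow $\mu_S$ (which is zero in lag
anyway).

Defaults for every constant, with units, fixed/free status and fitting
bounds, are in `parameter_table()`. `design_parameters()` applies the two
design-stage overrides ($Y_{P/X} = 0.71$, $t_{lag} = 0.25$ h).

## Numerical treatment

The right-hand side is piecewise-defined, so the integrator matters:

* `deSolve::ode(method = "lsodar")` — a stiff-capable multistep solver with
  root finding — integrates each phase. Terminal events (the batch-phase
  feed trigger at $S/V = c_{S,crit}$ and feed depletion at $v = 0$) are
  located by root functions; integration restarts at the lag-end and
  feed-start kinks so the discontinuities are never smeared across a step.
* The interior overflow switches (the $b$ ramp breakpoints and the
  consumption gate) are left inside the right-hand side, as the reference
  implementation style for this model family does; a maximum step size
  (`hmax`, default 0.05 h) keeps them and the exponential feed resolved.
* The constant maintenance drains switch discontinuously at the $A = 0$
  and $S = 0$ boundaries, which makes a naive implementation chatter when a
  pool empties. The consumption and maintenance terms are therefore
  multiplied by $A/(A + \varepsilon)$ resp. $S/(S + \varepsilon)$ with
  $\varepsilon = 10^{-6}$ g — about nine orders of magnitude below typical
  pool sizes — so the drains vanish continuously at depletion.
* Default tolerances are `rtol = 1e-8`, `atol = 1e-10`; the suite checks
  that halving them moves the endpoint titre by far less than 0.1%. State
  amounts are clipped at zero in post-processing.
* `pirt_biomass_yield()` returns 0 at exactly $\mu = 0$ (maintenance
  dominates); the ODE never divides by it, using the reduced Pirt drain
  instead.

## Synthetic experiments: what they emulate and what they do not

No raw time series ship with the package, so calibration, screening and
reporting are exercised on synthetic data from
`generate_experiment_set()`. Its defaults emulate the layout of the
historical campaign the model was built on: duplicate runs at feeding
growth rates 0.075, 0.15, 0.2, 0.25, 0.3 and 0.4 1/h (12 experiments),
hourly sampling, a batch phase at 25 g/L glucose in a 10 L reactor with a
6 L feed of 500 g/L glucose, and a 0.05 g/L glucose assay detection limit.
Values the historical record does not state were fixed once at realistic
values: 1 g of inoculated biomass, a 3 h default lag (which puts the feed
start in the 12.5–16 h window the campaign reported), ±10%/±5% jitter on
the inoculum and batch glucose, and ±0.5 h jitter on the lag. Measurement
error is multiplicative log-normal (CV 5% for the dry-weight and product
assays, 3% for the enzymatic glucose/acetate kits) plus a 0.01 g/L
additive floor — invented magnitudes standing in for unreported assay
error, configurable throughout.

Passing tests on these data show that the pipeline is self-consistent
(parameters used to generate data are recovered, ledgers close, ranks are
stable under the stated noise), not that the model fits any particular
real bioreactor run: real data carry correlated disturbances (pO2
excursions, foam events, sampling-volume effects) that the noise model
deliberately omits.

## Calibration

The objective is the sum over experiments and states of the RMSE between
simulated and observed concentrations (all four states share g/L, so equal
weights are the default and the aggregation is configurable).
Observations below the glucose detection limit are excluded by default
(`censor = "drop"`); a clamp-at-limit mode exists for sensitivity checks.
`fit_parameters()` runs a seeded stratified multistart over the normalised
bound box followed by a derivative-free simplex polish — the loss surface
is continuous but has event-grid kinks that defeat finite-difference
gradients. Recovery on noiseless synthetic data is within 1% for the free
parameters, and within 10% for $\mu_{max}^S$ at 5% measurement CV; both
bounds are asserted in the suite. Each experiment may carry its own lag
duration (runs are inoculated separately), while all kinetic constants are
shared in a joint fit; a per-experiment fit is obtained by passing a
single-experiment set.

## Sensitivity screening

`run_morris()` implements Morris elementary-effects screening: 17
biological parameters varied ±10% around nominal, trajectories of
one-at-a-time steps of 0.2 on the normalised axis with 6 levels, and the
mean absolute elementary effect $\mu^*$ reported per parameter against the
four per-state RMSE objectives. Effects are computed in normalised [0, 1]
space because the parameters span four orders of magnitude; $\mu^*$ is
therefore range-relative. The estimator is exact on linear maps
($\mu^*_i = |a_i|$ for every trajectory), which the suite uses as its
oracle, and the sampler is sequential in the seed so a small screen is a
prefix of a larger one.

Two design choices matter for interpretation:

* The screen replays the reference experiment's **realised feed profile**
  (recorded $F_0$ and feed-start time) for every perturbed parameter
  vector. Re-deriving the feed from each candidate would let the
  feed-sizing rule compensate a perturbed maintenance coefficient almost
  exactly, hiding $m_S$ — physically wrong, since the data were produced
  by a pump running a fixed programme.
* $\mu^*$ for the lag duration is proportional to the nominal lag, because
  the perturbation is relative. Against the package's default 3 h synthetic
  reference, $t_{lag}$ ranks near the top; against a short-lag reference it
  drops toward the bottom. Rank statements about $t_{lag}$ are therefore
  tied to the reference condition, not structural.

Failed simulations inside a screen are dropped from $\mu^*$ with a
warning.

## Carbon balance and process design

`carbon_balance()` converts endpoint masses to carbon equivalents
(glucose 6 C at 180.16 g/mol, biomass 24.83 g per C-mol, surfactin 53 C at
1036.34 g/mol, acetate 2 C at 60.05 g/mol) and reports the recovery
relative to the glucose supplied (initial plus fed). The model has no CO2
sink, so recovery is far below 100% — the gap is respiration plus
unmodelled by-products — and the suite only asserts it is finite and
positive.

`sweep_initial_feed_rate()` maps the batch-free design space: one
simulation per initial feed rate (default grid 1–100 g/h in 0.5 g/h steps
plus the named operating points), recording titres, space–time-yield
$P_V = P_\mathrm{end}/(V_\mathrm{end} t_\mathrm{end})$ and endpoint
concentrations. The curves have a characteristic shape: a near-flat titre
plateau (~49 g/L) up to a critical feed rate, then a collapse where the
feed outruns the culture, glucose accumulates past the overflow
thresholds, acetate inhibition slows growth further, and the run ends (at
the fixed feed-depletion time) with unconverted substrate.
`select_operating_point()` offers three policies, including the
backoff-from-the-STY-peak rule (interpreted on the feed-rate axis) that
motivates a ~28 g/h operating point.

## Known limitations

* **Inoculation-state sensitivity.** The batch-free transient — when the
  accumulated glucose peaks, and where the titre collapse sits on the
  $F_0$ axis — is strongly sensitive to the inoculum size. The package's
  documented default (OD600 0.3 × 0.232 g/L/OD in 10 L = 0.696 g, 0.5 g/L
  carry-over glucose, no carry-over acetate) is an informed guess at an
  unpublished quantity; endpoint predictions (final titre, biomass,
  process time) are insensitive to it, transient landmarks can shift by
  tens of percent. With a ~40% larger inoculum the simulated glucose peak
  and collapse position move onto the historically reported values almost
  exactly.
* **Overflow is acetate-only.** Acetoin, butanediol, lactate and other
  excess metabolites are not modelled; at high feeding growth rates (0.3
  and 0.4 1/h) and under feed extensions the real system departs from the
  model.
* **No product degradation** and no foam-phase partitioning: extending the
  feed beyond the nominal reservoir is outside the model's validity.
* **No closed-loop control**: the feed profile is open-loop exponential.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run everything at reduced but
representative sizes, chosen as the package's own defaults for quick,
deterministic verification: single-experiment calibrations with up to
three free parameters, Morris screens with 10 trajectories (180 model
runs), and design sweeps on ~150-point feed-rate grids with slightly
relaxed solver tolerances (`rtol = 1e-7`, `hmax = 0.1`) whose effect on
the reported quantities is below 0.1%.
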