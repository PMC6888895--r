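---
title: "Quantifying oxic methane production from an SML mass balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying oxic methane production from an SML mass balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limnoch4)
```

## The problem

Surface waters of stratified lakes are persistently oversaturated in
methane even though the surface mixed layer (SML) is fully oxygenated —
the "methane paradox". Two explanations compete: methane produced in
anoxic littoral sediments and transported laterally into the SML, and
net methane production within the oxic water column itself (oxic methane
production, OMP). `limnoch4` quantifies OMP as the residual of a
whole-basin mass balance of the SML and expresses its importance as the
oxic methane contribution (OMC) to total surface emission.

## The mass balance

The SML (volume $\forall$, surface area $A_{tot}$, thermocline-top area
$A_{th}$, littoral sediment area $A_{sed}$) is treated as a single box:

$$\frac{\partial C}{\partial t}\,\forall =
  (A_{th} F_z) + (A_{sed} F_L) + (P_{net}\,\forall)
  - (MOx\,\forall + A_{tot} F_S)$$

with surface emission $F_S$, lateral littoral input $F_L$, diffusive
thermocline input $F_z$, methanotrophic oxidation $MOx$, and net internal
production $P_{net}$. River throughflow and ebullition are fixed at zero:
the target systems are river-free, and bubbles dissolve before reaching
the SML from depths of 20 m or more. At steady state
($\partial C/\partial t = 0$) and with oxidation parameterised as a fixed
fraction $\alpha$ of internal production, the closure is

$$P_{net} = \frac{A_{tot}F_S - A_{sed}F_L - A_{th}F_z}{(1-\alpha)\,\forall}.$$

When all components are already expressed per unit SML volume (or the
water column is laterally enclosed so areas cancel), this collapses to
$P_{net} = (F_S - F_L - F_z)/(1-\alpha)$, which is what
`solve_pnet()` evaluates on per-volume component sets.

Key assumptions, and where they matter:

* **Steady state.** Weekly SML concentrations change slowly relative to
  the daily fluxes during mid-stratification. A finite-difference
  `dc_dt` term is supported in `balance_config()` for the onset period
  but is off by default.
* **Oxidation closure.** $\alpha = 0.3$ during stratification, 0
  otherwise. With $\alpha$ applied to internal production only
  (`mox_scope = "internal_only"`) the component-table arithmetic is
  reproduced; the enclosure comparison in `solve_lateral()` necessarily
  applies the factor to the combined internal-plus-lateral supply
  (`"internal_plus_lateral"`). Both closures are implemented and the
  mode is recorded in every output, because the two are not mutually
  reducible and the field parameterisation does not pick one for every
  use. Ignoring oxidation entirely ($\alpha = 0$) lowers inferred
  production when net emission is positive — the sensitivity direction
  tested in `test-mass-balance.R`.
* **Seasonality.** `seasonal_config()` switches the parameterisation at
  the stratification calendar, splitting the transitional month at
  mid-month (day 15) — a deliberate, simple convention; a day-resolved
  onset would require density profiles the balance does not otherwise
  need.

## Uncertainty propagation

Each measured component carries a mean and a standard deviation from
replicate field sampling. `monte_carlo_pnet()` draws the components
independently from *untruncated* normal distributions (9999 iterations
by default) and applies the closure per draw. Negative flux draws are
retained deliberately: the probability that production is positive,
`p_positive`, is only meaningful if the negative tail is kept. For this
linear closure the Monte Carlo limits are known in closed form
($\sigma_{P} = \sqrt{\sigma_{F_S}^2+\sigma_{F_L}^2+\sigma_{F_z}^2}/(1-\alpha)$,
$P(>0) = \Phi(\mu/\sigma)$), which the test suite uses as an independent
oracle; the Monte Carlo machinery is still the deliverable because field
workflows extend it with non-Gaussian or correlated components. The seed
is a required argument; summaries are bit-reproducible given it.

## Surface emission: chambers and wind

`chamber_flux()` converts a floating-chamber headspace time series
(mixing ratio or trapped amount) into an areal flux by the linear slope
of trapped CH~4~ versus time, assuming ideal-gas headspace at 1 atm.
`k600_from_flux()` inverts the bulk flux law
$F = k\,(C_{sfc}-C_{eq})$ and normalises to a Schmidt number of 600.
Fixed parameterisations (all stated in the function documentation):

* Schmidt number: Wanninkhof (1992) freshwater polynomial
  (Sc~CH4~(20 °C) = 615.8).
* Schmidt exponent $n$: 1/2 (wavy surface) by default, 2/3 available via
  `sc_exponent` for smooth-surface conditions.
* Solubility: Henry's law with van 't Hoff correction (Sander
  compilation constants), atmospheric CH~4~ 1.9 ppm by default.

`fit_k600_wind()` fits the conventional linear k600–U10 model by
ordinary least squares, and `estimate_emission()` applies it per wind
time step. Alternative published emission models plug in through
`k600_wind_model(slope, intercept)` without refitting. A vanishing
air–water gradient with nonzero flux is an error, and zero flux with
zero gradient yields a flagged `NA` — never a silent zero.

## Thermocline flux: heat budget and Fick's law

`heat_budget_diffusivity()` estimates basin-scale vertical diffusivity
from the time evolution of heat content below each depth divided by the
area-weighted local temperature gradient. Numerical choices:

* Trapezoidal hypsometric integrals, centred temperature gradients
  (one-sided at the boundaries), calendar-day $\Delta t$.
* Cells with $|\partial T/\partial z| < 0.01$ °C m⁻¹ (configurable
  `gradient_floor`) are *undefined*, not zero: the method degenerates in
  well-mixed water, and division blow-ups must not masquerade as
  diffusivity.

`thermocline_flux()` applies Fick's first law with the 1-m
finite-difference concentration gradient at the SML base and, as a
conservative choice for the input to the SML, the *maximum defined*
K~z~ within the bottom 3 m of the SML. The sign convention is fixed
repository-wide: a concentration increasing downward (peak below the
SML) gives a positive flux *into* the SML.

The inversion is validated against an explicit forward diffusion
simulator: an imposed uniform K~z~ = 2×10⁻⁶ m² s⁻¹ is recovered within
10 % below the SML on a 1-m grid. The residual error is dominated by the
centred-difference representation of the thermocline curvature, which is
why validation profiles use thermocline steepness that a 1-m grid
resolves (logistic slope parameter ≤ 0.7 m⁻¹).

## Geometry

`derive_geometry()` integrates a piecewise-linear hypsometry:
$\forall$ by the trapezoid rule over the SML, $A_{tot}$ and $A_{th}$ by
interpolation. The littoral sediment area $A_{sed}$ has no unique
convention; the default computes the lateral frustum surface from
equivalent-circle radii $r(z)=\sqrt{A(z)/\pi}$, with a `"planar"`
($A_{tot}-A_{th}$) fallback for tables too coarse to carry slope
information. For basins with moderately steep littoral slopes the two
agree to a few percent. The packaged `stechlin_hypsometry()` tables are
synthetic reconstructions calibrated so the 6-m-SML integrals reproduce
the two study basins' published geometry; they are not survey
bathymetry.

## The OMC scaling model and upscaling

`omc()` computes the oxic share of the whole-system source partition,
$OMC = 100\,P\forall/(P\forall + A_{sed}F_L + A_{th}F_z)$. Across lakes,
OMC falls exponentially with the ratio $x = A_{sed}/\forall$:
`fit_omc_model()` fits $OMC = a e^{-bx}$ by least squares *after log
linearisation*, reporting $R^2$ and $p$ on the linearised scale (the
scale on which the fit is performed) and the standard error in OMC
percentage points (the scale on which predictions are used). Lakes
reported as OMC ranges enter as midpoints (`read_omc_points()`).
`omc_threshold()` solves $x^* = \ln(a/t)/b$ for the morphometry at which
oxic production reaches a target share; predictions clamp to [0, 100].

`global_upscale()` takes a size-class lake inventory and an
area-to-predictor rule, predicts per-class OMC at the class mean area,
and averages with emission weights (class count × mean area × areal
emission intensity; constant intensity by default). The packaged
defaults are deliberately labelled emulations: the inventory is a
power-law abundance table consistent in shape and total area with
satellite lake censuses, and the default allometry
$x(A) = 0.063\,A^{-1.33}$ is calibrated only to the two study basins.
Global results from these defaults are therefore order-of-magnitude
checks (the test suite asserts a 50–70 % band), not a census-grade
estimate.

## The synthetic campaign generator

Real campaigns of this kind are published as figures and tables, not
deposited series, so validation runs on synthetic lakes with known
truths. `generate_campaign()` builds, from a `synthetic_lake_spec()`:

* a temperature series evolved by conservative forward diffusion under
  the spec's true K~z~ profile with surface heating;
* CH~4~ profiles with an SML plateau (~350 nmol l⁻¹), a Gaussian
  thermocline peak (~1350 nmol l⁻¹), and a low hypolimnion;
* hourly wind and floating-chamber deployments generated through the
  true k600–wind relation; and
* a component table and a `truth` manifest recording every generating
  value.

The bundle is self-consistent by construction: the surface emission
synthesised into the chamber and wind data is exactly the steady-state
emission implied by the true production, lateral and diffusive terms
(the identity is tested to 1e-8). Default truths follow the study
conditions: 6-m SML, production 72/88/101 nmol l⁻¹ d⁻¹ for the
open-basin and enclosure presets, lateral flux 1.4 mmol m⁻² d⁻¹, k600
slope/intercept 1.98/0.94, K~z~ reaching 10⁻⁶ m² s⁻¹ at the SML base,
SML oversaturation within 300–900 nmol l⁻¹, 5 % Gaussian noise on
concentrations and wind and 5 % lognormal noise on chamber slopes.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real data: internal seiching and storm-driven
mixing events, correlated component errors, chamber artefacts
(surface-film disruption, bubble capture), horizontal heterogeneity of
surface concentration, and any biological mechanism behind the
production term. The generator's noise is stationary and independent;
real replicate scatter is neither.

Validation problem sizes (chosen to exercise every code path at desk
scale): 28-day campaigns, 21-depth profiles at weekly resolution, 7
chamber deployments, Monte Carlo at n = 9999 (with one 10⁶-draw
law-of-large-numbers check), 20 noisy campaigns for the bias test, and
1000 random component sets for the residual property.

## Degenerate inputs and numerical conventions

* Hypsometries must be strictly monotone in depth and non-increasing in
  area; violations are errors, not repairs.
* $\alpha = 1$ makes the closure singular and is rejected.
* All-zero OMC sources are an explicit error, not 0 %.
* Negative derived lateral input is returned with a warning flag rather
  than clamped — a physically questionable value should be visible.
* Percent values are rounded only at the reporting layer, never inside
  computations.
* File writes go through a temp-file-plus-rename so partial outputs
  never parse as complete.
* Molar mass of CH~4~: 16.04 g mol⁻¹ for mol–kg conversions; per-volume
  and whole-system unit tracks are independent (component tables printed
  in different unit systems need not be mutually consistent under a
  single fixed volume, and no reconciliation is attempted).

## Known limitations

* The heat-budget method is undefined wherever stratification is weak;
  thermocline fluxes inherit that window, and the conservative
  window-maximum rule biases F~z~ high by design.
* The enclosure-derived lateral input assumes enclosures differ from
  adjacent open water *only* by shore disconnection.
* The scaling model is fitted to temperate, stratified,
  oligo-to-mesotrophic lakes; eutrophic or warm systems plausibly shift
  the curve right, and the default upscaling inherits every caveat of
  its emulated inventory and basin-calibrated allometry.

## A minimal run

```{r example, eval = FALSE}
camp <- generate_campaign(synthetic_lake_spec("stechlin_s", seed = 7))
res <- run_pipeline(camp, seed = 11)
res
write_pipeline_result(res, "south_basin.json")
```
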