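# limnoch4

Surface mixed layer (SML) methane mass balance for stratified lakes:
estimating net oxic methane production (OMP) as a budget residual,
propagating its uncertainty by Monte Carlo, and scaling the oxic methane
contribution (OMC) to surface emission against lake morphometry.

## The science

Oxygenated surface waters of lakes are routinely oversaturated in
methane. Part of that methane is conventional — produced in anoxic
littoral sediments and moved laterally into the SML, or diffusing up
through the thermocline — but a system-wide budget of a stratified basin
often cannot be closed without a net *in situ* source in the oxic water
column. `limnoch4` implements that budget. With SML volume `V`, surface
area `A_tot`, thermocline-top area `A_th` and littoral sediment area
`A_sed`, the steady-state balance

```
(1 - alpha) * P_net * V = A_tot * F_S - A_sed * F_L - A_th * F_z
```

is solved for the production rate `P_net`, where `F_S` is surface
emission (floating chambers, or a fitted linear k600–wind model), `F_L`
the lateral littoral flux (derived by comparing shore-disconnected
enclosures with adjacent open water), `F_z` the Fick's-law diffusive
flux at the SML base (heat-budget vertical diffusivity), and oxidation
is parameterised as a fraction `alpha` (0.3 during stratification) of
production. Uncertainty is propagated by drawing each component from an
untruncated normal distribution (9999 iterations). The oxic share of
the methane supply,

```
OMC [%] = 100 * P_net*V / (P_net*V + A_sed*F_L + A_th*F_z)
```

falls exponentially with the morphometric ratio `x = A_sed / V`
(`OMC = a * exp(-b x)`, fitted after log linearisation), which makes OMC
predictable from lake geometry and lets it be upscaled over a lake
size inventory.

Because raw field series for this kind of study are published as tables
and figures rather than deposited data, the package ships a synthetic
campaign generator (`generate_campaign()`) that produces complete,
self-consistent observation bundles — temperature and CH4 profiles,
wind, chamber deployments — from known ground truths, so the entire
pipeline is testable end to end.

## Worked example

Basin geometry from a hypsometric table, the Monte Carlo production
closure on a per-volume component set, and the source partition:

```r
library(limnoch4)

geom <- derive_geometry(stechlin_hypsometry("northeast"), sml_thickness = 6)
geom
#> Lake SML geometry (frustum A_sed convention)
#>   SML thickness : 6.00 m
#>   A_tot         : 2.007 km^2
#>   A_th          : 1.727 km^2
#>   A_sed         : 0.2816 km^2
#>   SML volume    : 1.12e+07 m^3

comp <- flux_components(f_s = c(90, 52), f_l = c(36, 6), f_z = c(5, 5))
monte_carlo_pnet(comp, cfg = balance_config("stratified"), seed = 1)
#> Monte Carlo production closure (n = 9999, seed = 1)
#>   P_net = 69.5 +/- 76.0 nmol l-1 d-1  (P(>0) = 82%)

round(omc(752, 372, 56))          # oxic share of the basin's sources
#> [1] 64
omc_threshold(omc_model(87.49, 7.61))   # x at which OMC crosses 50%
#> [1] 0.07352188
```

The emission distribution is wide (sd comparable to the mean — surface
emission dominates the error budget), yet production is positive in 82 %
of draws: the budget cannot be closed without an oxic source. The last
two lines partition the whole-system sources (64 % oxic) and solve the
fitted scaling curve for the morphometry at which oxic production
reaches half the supply (`A_sed/V ≈ 0.07 m² m⁻³`).

A full synthetic campaign through the pipeline:

```r
camp <- generate_campaign(synthetic_lake_spec("stechlin_s", seed = 7))
run_pipeline(camp, seed = 11)
#> SML methane mass-balance pipeline
#>   F_S   = 0.733 +/- 0.271 mmol m-2 d-1
#>   F_L   = 1.400 +/- 0.210 mmol m-2 d-1
#>   F_z   = 0.0344 +/- 0.0040 mmol m-2 d-1
#>   P_net = 91.3 +/- 77.4 nmol l-1 d-1 (MC, n = 9999)
#>   OMC   = 52.7 %
```

The preset's generating truth is `P_net = 88 nmol l⁻¹ d⁻¹`; the
recovered 91.3 reflects the campaign's 5 % observation noise (noise-free
campaigns recover the truth to within 1 %).

See `vignettes/methane-mass-balance.Rmd` for the model assumptions,
parameter choices and the generator's scope.

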