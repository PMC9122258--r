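---
title: "Methods: coupled river temperature and juvenile salmonid growth modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled river temperature and juvenile salmonid growth modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`thermosalmon` couples two process models that are standard tools in
Pacific-Northwest river management:

1. a one-dimensional heat-budget model of summer river temperature along a
   lake-fed coastal reach, driven by meteorology, riparian and topographic
   shading, steady low-flow hydraulics and streambed heat exchange; and
2. a Wisconsin bioenergetics model of juvenile salmonid growth, driven by
   the daily mean temperatures the first model produces at every node.

The package also ships a seeded synthetic-river generator so that the full
chain — forcing, shading, routing, calibration, scenarios, growth,
summaries — is testable end to end without any field data or downloads.
This vignette records the model equations, the default parameter choices
and why they were made, what the synthetic world does and does not emulate,
and the numerical decisions that a maintainer would otherwise have to
reverse-engineer.

# The temperature model

## State and transport

Water temperature $T(x,t)$ is tracked at nodes spaced $\Delta x = 500$ m
along the reach and advanced at $\Delta t = 120$ s. The governing balance
is advection from the upstream neighbour plus a net heat flux divided by
the heat capacity of the water column:

$$\frac{\partial T}{\partial t} + v \frac{\partial T}{\partial x}
  = \frac{\Phi_{net}}{\rho_w c_w d}$$

with $v$ and depth $d$ from steady Manning hydraulics (below), $\rho_w c_w$
the volumetric heat capacity of water. The upstream boundary node is pinned
to the (lake outlet) boundary temperature series; tributaries enter as
flow-weighted mixing applied to the water advected into their junction
node.

**Numerics.** Space is discretised with first-order upwind differencing and
the combined operator (advection, junction mixing, all
temperature-dependent fluxes) is advanced with SSP-RK2 (Heun's method).
Two properties drove this choice:

* *Monotonicity*: upwind + SSP-RK2 with CFL $\le 1$ cannot create spurious
  extrema, which is what makes the scenario-ordering guarantees (more shade
  never warms a node's daily maximum) hold numerically and not just
  physically. The CFL condition is checked every hour and violation aborts
  with the offending node.
* *Timestep convergence*: a first-order split scheme (advect, then Euler
  flux update) leaves an $O(\Delta t)$ splitting error that accumulates
  downstream; on the default reach it moved hourly output by more than
  0.01 °C when $\Delta t$ was halved. The unsplit SSP-RK2 integration
  reduces that sensitivity by roughly two orders of magnitude (measured
  max difference ≈ 3·10⁻⁴ °C for 120 s → 60 s).

No explicit longitudinal dispersion term is carried; at this resolution the
upwind scheme's intrinsic numerical diffusion ($\approx v\,\Delta x/2$)
plays that role, a documented limitation shared with the explicit
finite-difference mode of the operational models this follows. Hourly
output is the instantaneous value on the hour (logger semantics, not a
sub-step mean). A 5-day spin-up "flush" precedes the output window and is
discarded; forcing must cover it.

## Surface fluxes

All fluxes are in W m⁻², positive warming the water. Defaults live in
`heat_constants()` and are deliberately few and visible:

* **Shortwave** $(1-\alpha)\,[(1-S)\,I_{dir} + V\,I_{dif}]$ with albedo
  $\alpha = 0.05$, effective shade $S$ (below), view-to-sky $V$, and a
  direct/diffuse split $I_{dif}/I_{glob} = \min(0.3 + 0.7\,C, 1)$ in cloud
  fraction $C$ — a standard two-stream simplification.
* **Atmospheric longwave** with Brutsaert clear-sky emissivity
  $1.24\,(e_a/T_a)^{1/7}$ and cloud enhancement $(1 + 0.22\,C^2)$, absorbed
  with the water emissivity 0.96.
* **Back radiation** $-0.96\,\sigma\,(T_w + 273.15)^4$.
* **Latent**: mass-transfer evaporation $E = (a + b\,W)(e_s(T_w) - e_a)$
  with vapour pressures in mmHg and the calibrated coefficients
  $a = 2.21\times10^{-9}$, $b = 0$ — evaporation independent of wind, as
  calibrated in the study this emulates; $\Phi_{lat} = -\rho_w L_v E$.
* **Sensible**: the Bowen ratio applied to the same transfer coefficient,
  $-\rho_w L_v (a + bW)\, 0.4636\,(T_w - T_a)$, which stays well defined
  when the vapour gradient vanishes.

## Streambed

A substrate layer of calibrated thickness $h$ exchanges heat by conduction
with the water above and with deep alluvium at a fixed 12.0 °C below, each
across half the layer ($k/(h/2)$); an optional hyporheic term adds a linear
coupling $\phi\,Q\,\rho_w c_w/(w\,\Delta x)$ for exchange fraction $\phi$.
The layer temperature follows the exact exponential solution of its linear
ODE each substep, so thin or low-capacity layers cannot destabilise the
scheme. Its volumetric heat capacity is porosity-weighted between water and
sediment grains, the grain value being conductivity/diffusivity.

**A deliberate inconsistency.** The source table this package emulates
prints sediment diffusivity 1.54 cm² s⁻¹ alongside conductivity
0.0064 W m⁻¹ °C⁻¹, which together imply a grain heat capacity of
~42 J m⁻³ K⁻¹ — physically impossible; the two values are evidently
transposed. `substrate_params()` keeps the printed values as defaults for
fidelity and offers `physical_sediment = TRUE` to swap them (conductivity
1.54, diffusivity 0.0064, grain capacity ≈ 2.4 MJ m⁻³ K⁻¹). The synthetic
truth world uses the physical preset: with the verbatim constants the bed
is thermally inert (~0.1 W m⁻² K⁻¹) and the calibration exercise could not
distinguish substrate candidates at all.

# Solar geometry and shading

Solar position uses the NOAA calculator equations (accuracy well under
0.5°; verified in tests against an independent PSA-algorithm computation).
Solar time uses the fixed UTC offset — no daylight-saving arithmetic — for
reproducibility. Clear-sky global radiation is
$S_0\,\varepsilon(doy)\,\sin\alpha\cdot\tau^{m}$ with solar constant 1367
W m⁻², broadband transmissivity $\tau = 0.75$, and Kasten–Young air mass
$m$ pressure-corrected for elevation.

Cloudiness is not an input: it is inverted each daylight hour from the
ratio of measured to clear-sky radiation through an attenuation polynomial,
by a bracketing root-finder on $C\in[0,1]$. The published cubic the study
used is not reproducible from its text, so the relation is configurable
with default $E_o/E_m = 1 - 0.65\,C^2$; the inversion *procedure* is what
is preserved. Night hours carry the last daylight estimate forward.

Shading follows the transect convention of the GIS tooling it emulates:
per node, seven radial transects (compass bearings 45°–315°, every 45°,
omitting due north) with ten samples at 10 m spacing carry vegetation
height and canopy density; topographic shade angles are kept for east,
south and west, each the larger of a near-field (first 25 cells) and
far-field (to 20 km) local maximum. Effective shade for a solar position
is 1 if the topographic angle in the solar direction exceeds the solar
altitude; otherwise the transect nearest the solar azimuth (ties toward
south) attenuates the direct beam by $1 - \prod(1 - \rho_i)$ over samples
whose angular height above the channel centre exceeds the altitude.
Diffuse radiation is reduced only by a static view-to-sky factor from the
mean angular blocking across transects. Canopy density is input data
(75–90 % in the emulated reach), not computed.

# Hydraulics

Summer low flow justifies steady hydraulics per hour: tributary inflows
are fixed fractions of the gaged boundary flow (the two largest default to
7.9 % and 2.4 %), discharge is piecewise constant between junctions, and
depth/velocity solve Manning's equation for a rectangular section
($z = 0$, Manning $n = 0.035$) by damped Newton iteration with a bisection
fallback. The emulated study measured that tributaries explain only about
70 % of the downstream flow gain; the residual (groundwater and diffuse
accrual) is deliberately not modelled here either, so simulated warming
downstream is, if anything, conservative.

# The bioenergetics model

Daily growth follows the Wisconsin energy balance,
Growth = Consumption − Metabolism − Waste, in J g⁻¹ d⁻¹:

$$C_E = CA\,W^{CB}\,p\,f_c(T)\,ED_{prey},\quad
  F_E = FA\,T^{FB}e^{FG\,p}\,C_E,\quad
  U_E = UA\,T^{UB}e^{UG\,p}(C_E - F_E)$$
$$SDA_E = s\,(C_E - F_E),\qquad
  R_E = RA\,W^{RB}\,f_r(T, W)\cdot 13560$$

with the mass increment $\Delta W = W\,(C_E - F_E - U_E - SDA_E -
R_E)/ED_{pred}$. The oxycalorific coefficient 13 560 J g⁻¹ O₂ is the
Wisconsin-model convention. Energy densities are constant over the run
(predator 4.7, prey 3.0 kJ g⁻¹), the default fish starts at 5.0 g feeding
at $p = 0.5$ of maximum consumption, and the daily driver is the daily
mean of the hourly temperature field. Mass is floored at 0.1 g with a
flag — the balance is not credible near total mass loss.

**Parameter provenance.** Species parameters are shipped as YAML files
under `inst/extdata/species/` and treated as configuration. The Chinook
set combines the re-estimated Thornton–Lessem consumption parameters for
juveniles (Plumb & Moffitt 2015; CQ 1.25, CTO = CTM 20.93, CTL 24.05, CK1
0.36, CK4 0.53) with the classic swim-speed respiration and Elliott waste
coefficients (Stewart & Ibarra 1991) — the Fish Bioenergetics 4.0
juvenile-Chinook defaults. This set was chosen because it reproduces both
published zero-growth isotherms for this input set (18.6 °C at $p=0.5$
vs 18.9 printed; 22.8 °C at $p=0.9$ vs 22.7 printed, within the ±0.3 °C
transcription tolerance); the older consumption dome fails the $p=0.9$
anchor by ~2.4 °C. The coho file is the published Stewart & Ibarra set;
the sockeye, steelhead and cutthroat files are *approximate
transcriptions* (flagged as such in the files) used only for the
qualitative species comparison — steelhead and cutthroat carry the warmer
thermal performance the comparison relies on, and no quantitative claim is
anchored to them.

The zero-growth isotherm is found by locating the growth optimum on a
coarse grid and bisecting the daily balance above it to 0.01 °C.

# Scenarios

A scenario is (climate period, RCP, vegetation treatment). Treatments:
`loss` zeroes all riparian vegetation on both banks over the whole reach;
`increase` raises every transect sample within a 100 m buffer to at least
24.4 m (samples taller than that keep their height); `current` is the
identity. Both are idempotent. The emulated study states the buffer as
100 m in its methods and as 300 ft (91.4 m) in its scenario table; 100 m
is the default and the width is an argument. Future climate applies the
delta method with diurnal disaggregation: each day's projected daily-mean
air temperature replaces the observed daily mean while hourly anomalies
are preserved exactly; only air temperature is perturbed (the study names
no other adjusted variable), and the lake-outlet boundary temperature is
held constant in all scenarios, making simulated future warming a
conservative estimate. Synthetic daily deltas default to the reported
end-of-century means (+2.11 °C RCP 4.5, +3.48 °C RCP 8.5, day-to-day SD
0.63/0.59 °C) scaled 0.25/0.5/0.75/1 across the four periods — a linear
warming ramp, the simplest stand-in for the downscaled archive.

`scenario_grid()` enumerates 25 scenarios (current baseline + 4 periods ×
2 RCPs × 3 treatments). The riparian-management comparisons additionally
need the loss/increase treatments under current climate;
`scenario_grid(current_vegetation_variants = TRUE)` yields those 27.

# Calibration

Substrate thickness and hyporheic exchange are calibrated by explicit
candidate-model selection, mirroring the two-stage procedure of the study:
run all eight candidates (thickness {0.06, 0.12, 0.25, 0.5} m × exchange
{0, 3}%, bracketing the expected values), compute hourly bias/RMSE/NSE per
station, average across stations, rank by hourly RMSE; recompute fit for
the top two on daily means (what the growth model consumes) and select the
lower daily RMSE, breaking ties by higher NSE, then lower |bias|, then
first listed. A continuous optimiser would be statistically stronger but
would not be the documented procedure. On the synthetic observation twin
the selection recovers the truth candidate exactly at zero noise and in
≥ 95 % of replicates at 0.1 °C logger noise.

# The synthetic world

The generator's defaults state the emulated conditions: 82 nodes at 500 m
(river kilometre 54.1 down to ~13.6), June 10 – September 18 (101 days)
plus the 5-day flush, meteorology inside the study's printed ranges (air
8.3–31.9 °C, wind 0–12.1 m s⁻¹, RH 0–100 %, cloudiness ≤ 0.87), a warm
lake-outlet boundary (damped diurnal cycle of ±1 °C around a ~19–21 °C
seasonal bump) over a summer recession from ~25 to ~16 m³ s⁻¹, six
tributaries (7.9 %, 2.4 %, four < 2 %) running 3 °C cooler than the
boundary's daily mean with half its diurnal amplitude, and vegetation,
topographic-angle, width and elevation fields inside the printed ranges.
Diurnal air temperature peaks at 15:00 (sinusoid), boundary water at
17:00 (lakes lag the sun). Boundary noise varies at daily granularity
only, so one generated day's range is exactly twice the configured
amplitude. Observation noise defaults to 0.1 °C — a choice, not a printed
value; the emulated loggers agreed within ±0.2 °C across sections.

What the generator does *not* emulate — and therefore what a green test
does not establish: real LiDAR/orthoimage geometry, channel migration,
groundwater accrual and microclimate beneath canopy, gaps or sensor drift
in the observation record, and any particular year's weather. Reach-scale
temperature numbers from the real river are consequently *not* claimed
reproducible; the temperature model is accepted on its property suite,
calibration recovery, and the sign/ordering of scenario effects, while the
bioenergetics component is anchored quantitatively by the zero-growth
isotherms.

# Summary statistics

7DADM is the trailing, right-labelled 7-day mean of daily maxima on
complete local calendar days (window alignment and day boundary are not
dictated by the sources; both are fixed here and configurable), with the
per-node "maximum 7DADM" its period maximum. Threshold exceedance is the
percentage of complete days whose daily maximum exceeds the threshold;
the shipped registry carries smoltification 12–15 °C, embryo development
12–15 °C, spawning migration 19–23 °C and adult/juvenile mortality
24–26 °C, all assessed on the daily-maximum statistic (the mortality maps
use the 24 °C lower bound). Scenario growth differences use a fixed-effects
two-way ANOVA with interaction (nodes as replicates within cells), with
the degenerate all-equal case reported as F = 0, p = 1.

# Known limitations

* One-dimensional: no thermal stratification, no cold-water-refuge
  microhabitat, no lake model upstream.
* The ~30 % of downstream flow gain not attributable to tributaries is
  unmodelled, as in the emulated study.
* Flux formulations are standard but not bit-compatible with any
  particular operational model build.
* Bioenergetics ignores diet composition dynamics, prey availability and
  behavioural thermoregulation; $p$ and energy densities are constants.
* The future-climate machinery perturbs air temperature only and holds
  the boundary constant; reported future warming is a lower bound in that
  respect.
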