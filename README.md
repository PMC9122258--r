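# thermosalmon

Coupled river-temperature and juvenile-salmonid growth modelling for
lake-fed coastal rivers.

Resource managers weighing riparian-vegetation protection or restoration
need to know how shading changes summer river temperature, and what those
temperatures mean for the fish that rear in the river. `thermosalmon`
answers both questions in one chain: a process-based one-dimensional
heat-budget model predicts hourly water temperature at 500 m nodes along a
reach under riparian-vegetation and future-climate scenarios, and a
Wisconsin bioenergetics model converts each node's daily mean temperatures
into juvenile Pacific salmon growth. The package targets the situation of
a warm, moraine-dammed-lake-fed river (the kind of system where summer
temperatures already brush physiological limits), and ships a seeded
synthetic-river generator so the entire analysis is reproducible and
testable with no field data.

## The models in brief

**Temperature.** Water temperature obeys

    dT/dt + v dT/dx = Phi_net / (rho_w c_w d)

advanced by monotone SSP-RK2/upwind at a 2-minute step on 500 m nodes,
with a 5-day discarded spin-up. `Phi_net` sums shortwave (reduced by
riparian/topographic effective shade and a diffuse view-to-sky factor),
atmospheric longwave with cloud enhancement, back radiation, mass-transfer
latent and Bowen-ratio sensible flux, and two-layer streambed conduction
with optional hyporheic exchange. Cloudiness is inverted from measured
solar radiation against a clear-sky curve. Hydraulics are steady Manning
flow (rectangular section, z = 0) with tributaries as fixed fractions of
gaged flow, mixed flow-weighted at junctions. Substrate parameters are
calibrated by an explicit 8-candidate, two-stage selection on
bias/RMSE/Nash-Sutcliffe fit.

**Growth.** Daily growth = consumption − metabolism − waste:
`C = CA W^CB p f(T)` energy intake against temperature-dependent
respiration, egestion, excretion and specific dynamic action, at fixed
predator/prey energy densities (4.7 / 3.0 kJ/g) and feeding rate `p`
(fraction of maximum consumption). Species parameter sets (Chinook, coho,
sockeye, steelhead, cutthroat) are shipped as data files with provenance
notes.

## Worked example

```r
library(thermosalmon)

# Zero-growth isotherms for a 5.0 g juvenile Chinook on a low-energy diet
chin <- species_params("chinook")
zero_growth_temperature(0.5, bioe_inputs(), chin)   # 18.61 degC at p = 0.5
zero_growth_temperature(0.9, bioe_inputs(), chin)   # 22.78 degC at p = 0.9

# A full synthetic summer: 82 nodes, June 10 - September 18
cfg <- synth_config(seed = 1)
inp <- make_synthetic_inputs(cfg)
field <- run_model(inp$reach, inp$met, inp$boundary,
                   tributaries = inp$tributaries,
                   trib_temps = inp$trib_temps,
                   substrate = substrate_params(physical_sediment = TRUE),
                   dates = c(cfg$start_date, cfg$end_date),
                   latitude = cfg$latitude, longitude = cfg$longitude,
                   utc_offset = cfg$utc_offset, flush_days = cfg$flush_days)
field
#> temperature_field: 82 nodes x 2424 hours ( 2019-06-10 to 2019-09-18 23:00:00 )
#>   rkm 54.1 to 13.6 ; dx = 500 m; dt = 120 s

range(sevendadm(field)$max$max_7dadm_c)       # 22.59 25.47  (max 7DADM, degC)
range(exceedance_frequency(field, 24)$pct_days)  # 0.0 39.6  (% days > 24 degC)

bg <- batch_growth(field, bioe_inputs(), chin)
bg$summary
#> mean_change_g -1.05, sd_change_g 0.43, n_nodes 82
```

Read: the warm lake outlet keeps maximum 7DADM between ~22.6 and ~25.5 °C
along the reach, up to ~40 % of summer days exceed the 24 °C mortality
threshold at the warmest nodes, and a 5 g juvenile Chinook feeding at half
its maximum ration *loses* about a gram over the 101-day season — the
river is above the 18.6 °C zero-growth isotherm most of the summer.
Scenario machinery (`scenario_grid()`, `build_scenario()`,
`run_pipeline()`) then quantifies how vegetation removal/growth and
RCP 4.5/8.5 warming shift those numbers; on the synthetic reach the
orderings are as expected: removal warms and worsens growth, buffer
growth cools and improves it, future climates worsen everything.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/thermosalmon.R", package="thermosalmon"))')" \
    all --seed 1 --out out/
```

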