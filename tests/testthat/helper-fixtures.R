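# Shared fixtures, built once per test run and cached. The "small world" is
# a scaled-down synthetic river (10 nodes, 15 output days) used wherever a
# full-size run would waste budget; acceptance-level properties that the
# stated world defines at full scale build their own 82-node fixtures.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_config <- function(seed = 11) {
  synth_config(seed = seed, n_nodes = 10, start_date = "2019-06-10",
               end_date = "2019-06-24")
}

small_inputs <- function() {
  fixture("small_inputs", function() make_synthetic_inputs(small_config()))
}

small_positions <- function() {
  fixture("small_positions", function() {
    cfg <- small_config()
    solar_position(cfg$latitude, cfg$longitude,
                   small_inputs()$met$timestamp, cfg$utc_offset)
  })
}

small_shade <- function() {
  fixture("small_shade",
          function() shade_series(small_inputs()$reach, small_positions()))
}

small_field <- function() {
  fixture("small_field", function() {
    cfg <- small_config()
    inp <- small_inputs()
    run_model(inp$reach, inp$met, inp$boundary,
              tributaries = inp$tributaries, trib_temps = inp$trib_temps,
              substrate = substrate_params(physical_sediment = TRUE),
              dates = c(cfg$start_date, cfg$end_date),
              latitude = cfg$latitude, longitude = cfg$longitude,
              utc_offset = cfg$utc_offset, shade = small_shade(),
              flush_days = cfg$flush_days)
  })
}

run_small <- function(inp, cfg = small_config(), shade = NULL,
                      substrate = substrate_params(physical_sediment = TRUE),
                      ...) {
  run_model(inp$reach, inp$met, inp$boundary,
            tributaries = inp$tributaries, trib_temps = inp$trib_temps,
            substrate = substrate, dates = c(cfg$start_date, cfg$end_date),
            latitude = cfg$latitude, longitude = cfg$longitude,
            utc_offset = cfg$utc_offset, shade = shade,
            flush_days = cfg$flush_days, ...)
}

# constants/evaporation settings that switch off every surface flux
no_flux_const <- function() heat_constants(albedo = 1, emissivity_water = 0)
no_evap <- function() evaporation_params(0, 0)
# substrate with negligible conduction (verbatim table constants, thick layer)
inert_substrate <- function() substrate_params(layer_thickness = 5,
                                               hyporheic_pct = 0)

# a constant-forcing copy of the small world: flat boundary, no tributaries
constant_world <- function(temp = 18) {
  inp <- small_inputs()
  inp$boundary$temp_c[] <- temp
  inp$tributaries <- inp$tributaries[0, ]
  inp$trib_temps <- inp$trib_temps[, 0, drop = FALSE]
  inp
}
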