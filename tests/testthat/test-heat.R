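test_that("surface fluxes honour the calibrated evaporation settings", {
  met <- list(air_c = 18, rh_pct = 60, wind_mps = 2)
  met_windy <- list(air_c = 18, rh_pct = 60, wind_mps = 11)
  f1 <- surface_fluxes(met, 20, 0.3, 0.4, 1, solar_global = 600)
  f2 <- surface_fluxes(met_windy, 20, 0.3, 0.4, 1, solar_global = 600)
  # slope coefficient 0: latent (and sensible) independent of wind
  expect_identical(f1$latent, f2$latent)
  expect_identical(f1$sensible, f2$sensible)
  # with a non-zero slope the wind matters again
  ew <- evaporation_params(2.21e-9, 1e-9)
  f3 <- surface_fluxes(met_windy, 20, 0.3, 0.4, 1, solar_global = 600,
                       evap = ew)
  expect_lt(f3$latent, f1$latent)
})

test_that("zero vapour and thermal gradients give zero latent and sensible flux", {
  met <- list(air_c = 17.5, rh_pct = 100, wind_mps = 3)
  f <- surface_fluxes(met, 17.5, 0, 0, 1)
  expect_equal(f$latent, 0, tolerance = 1e-12)
  expect_equal(f$sensible, 0, tolerance = 1e-12)
})

test_that("back radiation matches the Stefan-Boltzmann plug-in", {
  f <- surface_fluxes(list(air_c = 20, rh_pct = 50, wind_mps = 0),
                      20, 0, 0, 1)
  expect_equal(f$back_radiation, -0.96 * 5.670374419e-8 * 293.15^4,
               tolerance = 1e-9)
  expect_lt(f$back_radiation, 0)
})

test_that("shortwave assembly applies albedo, shade and the diffuse split", {
  met <- list(air_c = 15, rh_pct = 50, wind_mps = 0)
  cloud <- 0.5
  f <- surface_fluxes(met, 15, 0.4, cloud, 1, solar_global = 800,
                      view_to_sky = 0.7)
  dfrac <- 0.3 + 0.7 * cloud
  expect_equal(f$shortwave,
               0.95 * ((1 - 0.4) * (1 - dfrac) * 800 + 0.7 * dfrac * 800),
               tolerance = 1e-12)
  expect_gte(f$shortwave, 0)
})

test_that("bed flux: isothermal zero, correct sign, two-resistor steady state", {
  sub <- substrate_params(physical_sediment = TRUE)
  iso <- bed_flux(sub, 12, 12, dt = 120)
  expect_equal(iso$flux, 0)
  expect_equal(iso$substrate_t_next, 12)
  warm <- bed_flux(sub, 20, 14, dt = 120)
  expect_lt(warm$flux, 0)                   # heat leaves the water
  expect_gt(warm$substrate_t_next, 14)      # substrate warms
  # long constant forcing relaxes the layer to the two-resistor midpoint
  ts <- 14
  for (i in 1:5000) ts <- bed_flux(sub, 20, ts, dt = 120)$substrate_t_next
  expect_equal(ts, (20 + 12) / 2, tolerance = 1e-6)
  k <- sub$thermal_conductivity
  h <- sub$layer_thickness
  steady <- bed_flux(sub, 20, ts, dt = 120)
  expect_equal(steady$flux, k * (12 - 20) / h, tolerance = 1e-6)
})

test_that("temperature stepping conserves and matches hand arithmetic", {
  flow <- list(velocity = rep(0.4, 10), depth = rep(0.8, 10))
  t0 <- rep(16, 10)
  # all fluxes zero, uniform field: constant in time
  t1 <- step_temperature(t0, rep(0, 10), flow, 120, 500, 16)
  expect_equal(t1, t0, tolerance = 1e-12)
  # constant flux, no advection: dT = phi dt / (rho c d) exactly
  still <- list(velocity = rep(0, 10), depth = rep(0.8, 10))
  phi <- 350
  t2 <- step_temperature(t0, rep(phi, 10), still, 120, 500, 16)
  expect_equal(t2 - t0,
               rep(phi * 120 / (998.2 * 4182 * 0.8), 10),
               tolerance = 1e-12)
  expect_error(step_temperature(t0, rep(0, 10),
                                list(velocity = rep(6, 10),
                                     depth = rep(0.8, 10)),
                                120, 500, 16),
               "CFL")
})

test_that("advection of a step front arrives at the characteristic time", {
  n <- 50; dx <- 100; dt <- 100; v <- 0.5
  flow <- list(velocity = rep(v, n), depth = rep(1, n))
  temps <- c(rep(20, 25), rep(10, 25))
  target_node <- 40
  crossing <- NA
  for (k in 1:6000) {
    temps <- step_temperature(temps, rep(0, n), flow, dt, dx, 20)
    if (is.na(crossing) && temps[target_node] >= 15) {
      crossing <- k * dt
      break
    }
  }
  travel <- (target_node - 25.5) * dx / v    # method of characteristics
  expect_equal(crossing, travel, tolerance = 0.1)
})

test_that("run_model output window, flush and node count are as configured", {
  cfg <- small_config()
  f <- small_field()
  expect_s3_class(f, "temperature_field")
  expect_equal(ncol(f$temps), cfg$n_nodes)
  expect_equal(nrow(f$temps), 15 * 24)
  expect_equal(as.Date(format(min(f$time), "%Y-%m-%d")), cfg$start_date)
  expect_equal(as.Date(format(max(f$time), "%Y-%m-%d")), cfg$end_date)
  expect_true(all(is.finite(f$temps)))
  # boundary node pinned to the boundary series
  inp <- small_inputs()
  idx <- match(as.numeric(f$time), as.numeric(inp$boundary$timestamp))
  expect_equal(f$temps[, 1], inp$boundary$temp_c[idx], tolerance = 1e-9)
})

test_that("with every flux disabled a constant world stays constant", {
  inp <- constant_world(18)
  zero_sub <- substrate_params(thermal_conductivity = 0,
                               thermal_diffusivity = 1)
  f <- run_small(inp, substrate = zero_sub, shade = small_shade(),
                 const = no_flux_const(), evap = no_evap())
  expect_lt(max(abs(f$temps - 18)), 1e-9)
})

test_that("halving the timestep changes hourly output by less than 0.01 degC", {
  inp <- small_inputs()
  f120 <- small_field()
  f60 <- run_small(inp, shade = small_shade(), dt = 60)
  expect_lt(max(abs(f120$temps - f60$temps)), 0.01)
})

test_that("missing forcing hours are rejected, short gaps interpolated", {
  cfg <- small_config()
  inp <- small_inputs()
  inp_gap <- inp
  inp_gap$met <- inp$met[-(200:210), ]
  expect_error(run_small(inp_gap, shade = small_shade()),
               "missing forcing")
  inp_short <- inp
  inp_short$met <- inp$met[-(200:201), ]
  f <- run_small(inp_short, shade = small_shade())
  expect_true(all(is.finite(f$temps)))
})

test_that("fit_report and calibrate recover a known candidate on the small world", {
  cfg <- synth_config(seed = 33, n_nodes = 10, start_date = "2019-06-10",
                      end_date = "2019-06-24", noise_sd = 0)
  inp <- small_inputs()
  candidates <- list(
    substrate_params(layer_thickness = 0.06, physical_sediment = TRUE),
    substrate_params(layer_thickness = 0.12, physical_sediment = TRUE),
    substrate_params(layer_thickness = 0.5, hyporheic_pct = 0.03,
                     physical_sediment = TRUE))
  twin <- make_observation_twin(candidates[[2]], cfg, inputs = inp,
                                shade = small_shade())
  cal <- calibrate(candidates, twin$observations,
                   modifyList(inp, list(cfg = cfg)), shade = small_shade())
  expect_equal(cal$selected, 2)
  expect_equal(cal$stage1$rmse_c[2], 0, tolerance = 1e-9)
  expect_equal(cal$stage1$nse[2], 1, tolerance = 1e-9)
  # duplicate candidates: documented tie-break picks the first listed
  dup <- calibrate(list(candidates[[2]], candidates[[2]]),
                   twin$observations, modifyList(inp, list(cfg = cfg)),
                   fields = list(twin$field, twin$field))
  expect_equal(dup$selected, 1)
  # misaligned observations are rejected
  obs_bad <- twin$observations
  obs_bad$timestamp <- obs_bad$timestamp + 1800
  expect_error(fit_report(twin$field, obs_bad), "aligned")
})
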