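test_that("generators are bit-deterministic in the seed and leave the RNG alone", {
  cfg <- synth_config(seed = 42, n_nodes = 20,
                      start_date = "2019-06-10", end_date = "2019-06-20")
  set.seed(999)
  before <- .Random.seed
  r1 <- make_reach(cfg)
  m1 <- make_meteorology(cfg)
  b1 <- make_boundary_and_tributaries(cfg)
  expect_identical(.Random.seed, before)
  expect_identical(r1, make_reach(cfg))
  expect_identical(m1, make_meteorology(cfg))
  expect_identical(b1, make_boundary_and_tributaries(cfg))
  # a different seed changes the draws
  cfg2 <- synth_config(seed = 43, n_nodes = 20,
                       start_date = "2019-06-10", end_date = "2019-06-20")
  expect_false(identical(make_reach(cfg2)$width_m, r1$width_m))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(n_nodes = 1), "n_nodes")
  expect_error(synth_config(dx = 0), "dx")
  expect_error(synth_config(start_date = "2019-09-19"), "end_date")
  expect_error(synth_config(tributary_fractions = c(0.1, -0.01)),
               "fractions")
  expect_error(synth_config(tributary_fractions = numeric(0)), "tributary")
})

test_that("reach fields honour the study's printed ranges", {
  reach <- fixture("reach82", function() make_reach(synth_config(seed = 7)))
  expect_equal(nrow(reach), 82)
  expect_equal(reach$rkm[1], 54.1)
  expect_true(all(reach$width_m >= 22.7 & reach$width_m <= 200.6))
  expect_true(all(reach$elevation_m >= 8.5 & reach$elevation_m <= 99.9))
  expect_true(all(diff(reach$elevation_m) < 0))
  topo <- unlist(reach[c("topo_e_deg", "topo_s_deg", "topo_w_deg")])
  expect_true(all(topo >= 0.5 & topo <= 52.5))
  expect_true(all(reach$canopy_density_pct >= 75 &
                    reach$canopy_density_pct <= 90))
  expect_true(all(reach$overhang_m >= 0 & reach$overhang_m <= 2))
  heights <- unlist(reach[grep("height_m$", names(reach))])
  expect_true(all(heights >= 0 & heights <= 82.3))
})

test_that("gradients recomputed from emitted elevations are positive", {
  reach <- fixture("reach82", function() make_reach(synth_config(seed = 7)))
  recomputed <- -diff(reach$elevation_m) / 500
  expect_true(all(recomputed > 0))
  expect_equal(reach$gradient[-1], recomputed, tolerance = 1e-12)
})

test_that("meteorology stays within configured bounds", {
  met <- small_inputs()$met
  expect_true(all(met$air_c >= 8.3 & met$air_c <= 31.9))
  expect_true(all(met$rh_pct >= 0 & met$rh_pct <= 100))
  expect_true(all(met$wind_mps >= 0 & met$wind_mps <= 12.1))
  expect_true(all(met$solar_wm2 >= 0))
  # night hours are dark
  pos <- small_positions()
  expect_true(all(met$solar_wm2[pos$altitude <= 0] == 0))
})

test_that("daily mean air temperature tracks the configured seasonal trend", {
  cfg <- small_config()
  met <- small_inputs()$met
  day <- as.Date(format(met$timestamp, "%Y-%m-%d"))
  daily <- tapply(met$air_c, day, mean)
  trend <- met_seasonal_mean(cfg, as.Date(names(daily)))
  # AR(1) noise (sd 0.5, rho 0.8) leaves daily means within ~3 sd of trend
  expect_true(all(abs(daily - trend) < 1.5))
  expect_lt(mean(abs(daily - trend)), 0.6)
})

test_that("boundary is a damped warm diurnal signal; tributaries cooler", {
  cfg <- synth_config(seed = 5, n_nodes = 10,
                      start_date = "2019-06-10", end_date = "2019-06-24")
  bt <- make_boundary_and_tributaries(cfg)
  b <- bt$boundary
  day <- as.Date(format(b$timestamp, "%Y-%m-%d"))
  # pick a full mid-window day: range is twice the diurnal amplitude
  d10 <- b$temp_c[day == as.Date("2019-06-15")]
  expect_equal(max(d10) - min(d10), 2 * cfg$boundary_diurnal_amplitude,
               tolerance = 0.01)
  expect_equal(nrow(bt$tributaries), 6)
  expect_setequal(bt$tributaries$fraction[1:2], c(0.079, 0.024))
  expect_true(all(bt$tributaries$fraction[3:6] < 0.02))
  # tributary mean temperature sits below the boundary mean
  expect_true(all(colMeans(bt$trib_temps) < mean(b$temp_c) - 1.5))
})

test_that("zero-fraction tributary contributes an identically zero inflow", {
  inflow <- tributary_inflow(small_inputs()$boundary$q_cms, 0)
  expect_true(all(inflow == 0))
})

test_that("height grids support flat, wall and area conventions", {
  cfg <- small_config()
  g0 <- make_height_grids(cfg, nx = 50, ny = 20, canopy_height = 0)
  expect_true(all(g0$veg == 0))
  expect_equal(g0$cell_area_m2, 9)
  gw <- make_height_grids(cfg, nx = 50, ny = 20,
                          features = list(list(type = "wall", x_m = 100,
                                               height_m = 30)))
  expect_true(any(gw$veg == 30))
  expect_error(make_height_grids(cfg, cell_m = 0), "cell size")
})

test_that("observation twin: zero noise reproduces the model exactly;
           noise sd is recovered; seeds only change the noise", {
  cfg0 <- synth_config(seed = 21, n_nodes = 8, start_date = "2019-06-10",
                       end_date = "2019-06-20", noise_sd = 0)
  truth <- substrate_params(physical_sediment = TRUE)
  twin0 <- make_observation_twin(truth, cfg0)
  f <- twin0$field
  for (s in unique(twin0$observations$node_id)) {
    o <- twin0$observations[twin0$observations$node_id == s, ]
    expect_identical(o$temp_c, f$temps[, match(s, f$node_id)])
  }
  cfgn <- synth_config(seed = 21, n_nodes = 8, start_date = "2019-06-10",
                       end_date = "2019-06-20", noise_sd = 0.1)
  twin1 <- make_observation_twin(truth, cfgn, inputs = twin0$inputs,
                                 field = f)
  resid <- twin1$observations$temp_c - twin0$observations$temp_c
  expect_equal(sd(resid), 0.1, tolerance = 0.02)
  twin2 <- make_observation_twin(truth, cfgn, inputs = twin0$inputs,
                                 field = f, noise_seed = 77)
  expect_false(identical(twin1$observations$temp_c,
                         twin2$observations$temp_c))
  expect_identical(twin1$field$temps, twin2$field$temps)
})
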