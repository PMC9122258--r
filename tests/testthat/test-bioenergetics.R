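chinook <- species_params("chinook")
tbl3 <- bioe_inputs()   # 5.0 g, p = 0.5, ED 4.7 / 3.0 kJ/g

test_that("registry contains the five species with sane parameters", {
  expect_setequal(list_species(),
                  c("chinook", "coho", "sockeye", "steelhead", "cutthroat"))
  for (sp in list_species()) {
    p <- species_params(sp)
    expect_gt(p$consumption$CA, 0)
    expect_gt(p$respiration$RA, 0)
    expect_equal(p$oxycal, 13560)
  }
  expect_error(species_params("pike"), "unknown species")
})

test_that("cmax follows the allometry", {
  expect_equal(cmax(5, chinook), 0.303 * 5^-0.275, tolerance = 1e-12)
  flat <- chinook
  flat$consumption$CB <- 0
  expect_equal(cmax(c(1, 5, 50), flat), rep(0.303, 3))
  # CB < 0: specific cmax decreases with mass
  expect_true(all(diff(cmax(c(1, 5, 20, 100), chinook)) < 0))
  expect_error(cmax(-1, chinook), "mass")
})

test_that("consumption temperature dependence is bounded and anchored", {
  grid <- seq(-5, 40, by = 0.5)
  for (sp in list_species()) {
    f <- f_temp_consumption(grid, species_params(sp))
    expect_true(all(f >= 0 & f <= 1))
  }
  # double sigmoid reproduces its defining proportions at the anchor
  # temperatures (the opposite limb is ~1 there)
  for (sp in c("chinook", "coho")) {
    p <- species_params(sp)$consumption
    expect_equal(f_temp_consumption(p$CQ, species_params(sp)), p$CK1,
                 tolerance = 0.02)
    expect_equal(f_temp_consumption(p$CTL, species_params(sp)), p$CK4,
                 tolerance = 0.03)
  }
  # dome form: zero at and above the lethal temperature
  sh <- species_params("steelhead")
  expect_equal(f_temp_consumption(sh$consumption$CTM, sh), 0)
  expect_equal(f_temp_consumption(30, sh), 0)
  bad <- chinook
  bad$consumption$form <- "banana"
  expect_error(f_temp_consumption(10, bad), "unknown consumption form")
  expect_error(f_temp_consumption(NaN, chinook), "finite")
})

test_that("starved fish lose mass at any temperature", {
  for (t in c(4, 10, 16, 22)) {
    expect_lt(daily_growth(5, t, tbl3, chinook, p_cmax = 0)$delta_g, 0)
  }
})

test_that("the daily energy ledger balances term by term", {
  set.seed(8)
  for (i in 1:25) {
    mass <- runif(1, 0.5, 60)
    t <- runif(1, 2, 24)
    p <- runif(1, 0.1, 1)
    g <- daily_growth(mass, t, tbl3, chinook, p_cmax = p)
    # independent recomputation of the balance from the reported terms
    net <- g$consumption - g$egestion - g$excretion - g$sda - g$respiration
    expect_equal(g$growth, net, tolerance = 1e-10)
    expect_equal(g$delta_g, net * mass / (tbl3$ed_pred * 1000),
                 tolerance = 1e-10)
    # waste terms are fractions of intake
    expect_true(g$egestion >= 0 && g$egestion < g$consumption ||
                  g$consumption == 0)
  }
})

test_that("growth trajectories integrate daily and respect the mass floor", {
  zg <- zero_growth_temperature(0.5, tbl3, chinook)
  tr <- simulate_growth(rep(zg, 101), tbl3, chinook)
  expect_equal(nrow(tr), 101)
  expect_equal(tr$mass_g[101], 5.0, tolerance = 0.01)
  expect_false(attr(tr, "floored"))
  # hot water: monotone harm above the optimum
  finals <- vapply(c(19, 21, 23, 24.5), function(t)
    attr(simulate_growth(rep(t, 60), tbl3, chinook), "final_change_g"),
    numeric(1))
  expect_true(all(diff(finals) < 0))
  # lethal-side temperatures drive mass to the floor, flagged
  hot <- simulate_growth(rep(26, 300), tbl3, chinook)
  expect_true(attr(hot, "floored"))
  expect_true(all(hot$mass_g >= tbl3$mass_floor))
  expect_error(simulate_growth(c(15, NA), tbl3, chinook), "non-finite")
})

test_that("batch growth reduces to per-node simulations with exact summary", {
  f <- small_field()
  bg <- batch_growth(f, tbl3, chinook)
  expect_equal(length(bg$trajectories), ncol(f$temps))
  expect_equal(nrow(bg$final), ncol(f$temps))
  expect_equal(bg$summary$mean_change_g, mean(bg$final$final_change_g),
               tolerance = 1e-12)
  # single-node field equals simulate_growth on that node's daily means
  one <- list(time = f$time, temps = f$temps[, 3, drop = FALSE],
              node_id = f$node_id[3])
  bg1 <- batch_growth(one, tbl3, chinook)
  day <- as.Date(format(f$time, "%Y-%m-%d"))
  direct <- simulate_growth(as.numeric(tapply(f$temps[, 3], day, mean)),
                            tbl3, chinook)
  expect_equal(bg1$final$final_change_g, attr(direct, "final_change_g"))
  expect_error(batch_growth(list(temps = NULL), tbl3, chinook), "empty")
})

test_that("zero-growth temperature rises with feeding rate and prey quality", {
  zs <- vapply(c(0.3, 0.5, 0.7, 0.9, 1.0), zero_growth_temperature,
               numeric(1), inputs = tbl3, params = chinook)
  expect_true(all(diff(zs) > 0))
  rich <- bioe_inputs(ed_prey = 4.0)
  expect_gt(zero_growth_temperature(0.5, rich, chinook),
            zero_growth_temperature(0.5, tbl3, chinook))
  expect_error(zero_growth_temperature(0.5, tbl3, chinook,
                                       t_search = c(0, 10)),
               "zero crossing|negative everywhere")
})

test_that("growth curves cross zero at the isotherm and order the species", {
  zg <- zero_growth_temperature(0.5, tbl3, chinook)
  gc <- growth_curve(chinook, tbl3, t_range = c(zg - 0.5, zg, zg + 0.5),
                     p_levels = 0.5)
  expect_gt(gc$growth_g_d[1], 0)
  expect_equal(gc$growth_g_d[2], 0, tolerance = 1e-3)
  expect_lt(gc$growth_g_d[3], 0)
  # trout species tolerate warmer water than Chinook at p = 0.5
  for (sp in c("steelhead", "cutthroat")) {
    expect_gt(zero_growth_temperature(0.5, tbl3, species_params(sp)), zg)
  }
  # curve maximum sits at the grid argmax of daily growth
  grid <- seq(1, 24, by = 0.25)
  gcc <- growth_curve(chinook, tbl3, t_range = grid, p_levels = 0.5)
  oracle <- grid[which.max(vapply(grid, function(t)
    daily_growth(5, t, tbl3, chinook)$delta_g, numeric(1)))]
  expect_equal(gcc$temp_c[which.max(gcc$growth_g_d)], oracle)
})
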