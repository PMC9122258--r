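#' Configuration for the synthetic river world
#'
#' Bundles every knob of the seeded synthetic-data generator. Defaults state
#' the study world being emulated: an ~41 km lake-fed coastal reach at 500 m
#' nodes (82 nodes, river kilometre 54.1 down to ~13.6), a 101-day summer
#' window (June 10 to September 18), a warm lake-outlet boundary with a
#' damped diurnal cycle, six tributaries of which two carry 7.9% and 2.4% of
#' gaged main-stem flow, and meteorology within the study's printed ranges
#' (air 8.3-31.9 degC, wind 0-12.1 m/s, RH 0-100%).
#'
#' @param seed integer; the single seed feeding every stochastic operation.
#' @param n_nodes number of 500 m model nodes (>= 2).
#' @param dx node spacing, m.
#' @param start_date,end_date output window (Date or yyyy-mm-dd strings).
#' @param flush_days spin-up days generated before `start_date` and
#'   discarded from model output.
#' @param met_ranges list with `air`, `wind`, `rh` bounds (length-2 each).
#' @param boundary_mean seasonal mean boundary water temperature, degC.
#' @param boundary_diurnal_amplitude half-range of the boundary diurnal
#'   cycle, degC (damped, lake-outlet-like).
#' @param tributary_fractions dimensionless flow fractions, one per
#'   tributary.
#' @param noise_sd observation noise for the virtual logger stations, degC.
#' @param latitude,longitude,utc_offset site location and fixed clock
#'   offset.
#' @return object of class `synth_config` (a validated list).
#' @export
#' @examples
#' cfg <- synth_config(seed = 1)
#' cfg$n_nodes
synth_config <- function(seed = 1L,
                         n_nodes = 82L,
                         dx = 500,
                         start_date = "2019-06-10",
                         end_date = "2019-09-18",
                         flush_days = 5L,
                         met_ranges = list(air = c(8.3, 31.9),
                                           wind = c(0, 12.1),
                                           rh = c(0, 100)),
                         boundary_mean = 19.0,
                         boundary_diurnal_amplitude = 1.0,
                         tributary_fractions = c(0.079, 0.024, 0.018,
                                                 0.012, 0.008, 0.005),
                         noise_sd = 0.1,
                         latitude = 47.4,
                         longitude = -124.0,
                         utc_offset = -7) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  if (dx <= 0) stop("dx must be positive")
  if (end_date < start_date) stop("end_date must be >= start_date")
  if (length(tributary_fractions) < 1) stop("need at least one tributary fraction")
  if (any(tributary_fractions < 0)) stop("tributary fractions must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
                 dx = dx, start_date = start_date, end_date = end_date,
                 flush_days = as.integer(flush_days), met_ranges = met_ranges,
                 boundary_mean = boundary_mean,
                 boundary_diurnal_amplitude = boundary_diurnal_amplitude,
                 tributary_fractions = tributary_fractions,
                 noise_sd = noise_sd, latitude = latitude,
                 longitude = longitude, utc_offset = utc_offset),
            class = "synth_config")
}

# internal: hourly timestamp axis covering flush + output window, fixed
# standard local time (no DST)
synth_hours <- function(cfg) {
  tz <- sprintf("Etc/GMT%+d", -cfg$utc_offset)
  seq(as.POSIXct(paste(cfg$start_date - cfg$flush_days, "00:00:00"), tz = tz),
      as.POSIXct(paste(cfg$end_date, "23:00:00"), tz = tz), by = 3600)
}

#' Generate the synthetic reach node and landcover table
#'
#' One row per 500 m node, river kilometre decreasing downstream from 54.1.
#' Elevation decreases strictly downstream within 8.5-99.9 m (so Manning
#' gradients are positive everywhere); bottom width grows downstream within
#' 22.7-200.6 m; topographic shade angles lie in 0.5-52.5 degrees, canopy
#' density in 75-90%, overhang in 0-2 m, and riparian vegetation heights in
#' 0-82.3 m. Vegetation is sampled on seven radial transects of ten 10-m
#' steps per node (`veg_d<k>_s<j>_height_m` and matching `_density`
#' columns); patches of tall conifer alternate with open bar ground along
#' the reach.
#'
#' @param cfg [synth_config()].
#' @return data.frame with columns `node_id`, `rkm`, `elevation_m`,
#'   `gradient`, `width_m`, `aspect_deg`, `topo_e_deg`, `topo_s_deg`,
#'   `topo_w_deg`, `canopy_density_pct`, `overhang_m` and 140 vegetation
#'   transect columns.
#' @export
make_reach <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_nodes
  with_seed(child_seed(cfg$seed, 1L), {
    rkm <- 54.1 - (seq_len(n) - 1) * cfg$dx / 1000

    # strictly decreasing elevation 99.9 -> 8.5 with gamma-distributed drops
    drops <- stats::rgamma(n - 1, shape = 2, rate = 2) + 0.05
    drops <- drops / sum(drops) * (99.9 - 8.5)
    elevation <- 99.9 - c(0, cumsum(drops))
    gradient <- c(drops[1], drops) / cfg$dx

    frac <- (seq_len(n) - 1) / (n - 1)
    width <- 45 + 110 * frac^1.3 + stats::rnorm(n, 0, 6)
    width <- pmin(pmax(width, 22.7), 200.6)

    # channel meanders around a SW trend
    aspect <- (225 + 60 * sin(2 * pi * frac * 3) +
                 stats::rnorm(n, 0, 15)) %% 360

    topo_e <- pmin(pmax(8 + 12 * sin(pi * frac) + stats::rnorm(n, 0, 5),
                        0.5), 52.5)
    topo_s <- pmin(pmax(4 + 6 * sin(pi * frac) + stats::rnorm(n, 0, 3),
                        0.5), 52.5)
    topo_w <- pmin(pmax(10 + 15 * sin(pi * frac) + stats::rnorm(n, 0, 6),
                        0.5), 52.5)

    canopy_density <- stats::runif(n, 75, 90)
    overhang <- stats::runif(n, 0, 2)

    reach <- data.frame(node_id = seq_len(n), rkm = rkm,
                        elevation_m = elevation, gradient = gradient,
                        width_m = width, aspect_deg = aspect,
                        topo_e_deg = topo_e, topo_s_deg = topo_s,
                        topo_w_deg = topo_w,
                        canopy_density_pct = canopy_density,
                        overhang_m = overhang)

    # vegetation: AR(1) stand height along the reach, thinning with distance
    # from the bank; occasional gravel-bar gaps
    stand <- numeric(n)
    stand[1] <- 35
    for (i in 2:n) stand[i] <- 0.9 * stand[i - 1] + 0.1 * 35 +
      stats::rnorm(1, 0, 6)
    stand <- pmin(pmax(stand, 0), 70)
    gap <- stats::runif(n) < 0.1
    for (k in 1:7) {
      for (j in 1:10) {
        taper <- 1 - 0.35 * (j - 1) / 9
        h <- stand * taper * stats::runif(n, 0.55, 1.15)
        h[gap] <- h[gap] * 0.1
        h <- pmin(pmax(h, 0), 82.3)
        dens <- ifelse(h > 0.5, canopy_density / 100, 0)
        reach[[sprintf("veg_d%d_s%d_height_m", k, j)]] <- h
        reach[[sprintf("veg_d%d_s%d_density", k, j)]] <- dens
      }
    }
    reach
  })
}

# internal: deterministic seasonal daily-mean air temperature, degC
air_seasonal <- function(cfg, dates) {
  all_days <- seq(cfg$start_date - cfg$flush_days, cfg$end_date, by = "day")
  frac <- as.numeric(dates - all_days[1]) / max(as.numeric(all_days[length(all_days)] - all_days[1]), 1)
  14 + 4.5 * sin(pi * pmin(pmax(frac, 0), 1))
}

#' Seasonal daily-mean air temperature trend of the generator
#'
#' Exposed so tests can compare emitted daily means against the configured
#' trend (the generator adds diurnal structure and AR(1) noise on top).
#'
#' @param cfg [synth_config()].
#' @param dates Date vector.
#' @return degC vector.
#' @export
met_seasonal_mean <- function(cfg, dates) air_seasonal(cfg, as.Date(dates))

#' Generate hourly synthetic meteorology
#'
#' Air temperature is a seasonal trend plus a sinusoidal diurnal cycle
#' peaking at 15:00 local plus AR(1) noise, clamped to the configured
#' bounds. Wind has a weak afternoon peak, relative humidity moves in
#' anti-phase with air temperature, and global solar radiation is the
#' clear-sky curve attenuated by a slowly varying stochastic cloud process
#' (attenuation 1 - 0.65 C^2, cloudiness capped at 0.87 as in the study's
#' printed range).
#'
#' @param cfg [synth_config()].
#' @return data.frame `timestamp`, `air_c`, `rh_pct`, `wind_mps`,
#'   `solar_wm2`.
#' @export
make_meteorology <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  hours <- synth_hours(cfg)
  nh <- length(hours)
  lt <- as.POSIXlt(hours)
  hr <- lt$hour
  dates <- as.Date(format(hours, "%Y-%m-%d"))
  with_seed(child_seed(cfg$seed, 2L), {
    seasonal <- air_seasonal(cfg, dates)
    diurnal <- 5.0 * cos(2 * pi * (hr - 15) / 24)
    ar <- stats::filter(stats::rnorm(nh, 0, 0.5), 0.8, method = "recursive")
    air <- seasonal + diurnal + as.numeric(ar)
    air <- pmin(pmax(air, cfg$met_ranges$air[1]), cfg$met_ranges$air[2])

    wind <- 2.5 + 1.8 * cos(2 * pi * (hr - 16) / 24) +
      as.numeric(stats::filter(stats::rnorm(nh, 0, 0.6), 0.7,
                               method = "recursive"))
    wind <- pmin(pmax(wind, cfg$met_ranges$wind[1]), cfg$met_ranges$wind[2])

    rh <- 78 - 14 * cos(2 * pi * (hr - 15) / 24) + stats::rnorm(nh, 0, 4)
    rh <- pmin(pmax(rh, cfg$met_ranges$rh[1]), cfg$met_ranges$rh[2])

    # daily cloudiness: logistic AR(1), capped at the printed 87% maximum
    udays <- unique(dates)
    z <- stats::filter(stats::rnorm(length(udays), 0, 1.2), 0.75,
                       method = "recursive")
    cloud_day <- 0.87 * stats::plogis(as.numeric(z) - 0.8)
    cloud <- cloud_day[match(dates, udays)]

    pos <- solar_position(cfg$latitude, cfg$longitude, hours, cfg$utc_offset)
    doy <- lt$yday + 1
    cs <- clear_sky_radiation(pos$altitude, elevation_m = 55, doy = doy)
    solar <- cs * (1 - 0.65 * cloud^2)

    data.frame(timestamp = hours, air_c = air, rh_pct = rh, wind_mps = wind,
               solar_wm2 = solar)
  })
}

#' Generate boundary forcing and tributary specifications
#'
#' The boundary water temperature is a warm, lake-outlet-like signal: a
#' seasonal bump around `boundary_mean` plus a damped diurnal cycle of
#' half-range `boundary_diurnal_amplitude` peaking at 17:00 (lakes lag the
#' sun) plus small AR(1) noise. Boundary discharge follows a summer
#' recession toward baseflow. Tributaries are cooler: each runs at the
#' boundary's daily mean minus 3 degC with half the diurnal amplitude.
#'
#' @param cfg [synth_config()].
#' @return list with `boundary` (data.frame `timestamp`, `temp_c`, `q_cms`),
#'   `tributaries` (data.frame `name`, `rkm`, `fraction`), and `trib_temps`
#'   (matrix hours x tributaries, degC, columns named).
#' @export
make_boundary_and_tributaries <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  hours <- synth_hours(cfg)
  nh <- length(hours)
  lt <- as.POSIXlt(hours)
  hr <- lt$hour + lt$min / 60
  dates <- as.Date(format(hours, "%Y-%m-%d"))
  day_idx <- as.numeric(dates - dates[1])
  ndays <- max(day_idx) + 1
  with_seed(child_seed(cfg$seed, 3L), {
    # seasonal bump and synoptic noise vary at daily granularity only, so
    # each generated day's range is exactly twice the diurnal amplitude
    seasonal <- cfg$boundary_mean +
      2.2 * sin(pi * pmin(day_idx / (ndays - 1), 1))
    diurnal <- cfg$boundary_diurnal_amplitude * cos(2 * pi * (hr - 17) / 24)
    noise_day <- as.numeric(stats::filter(stats::rnorm(ndays, 0, 0.15),
                                          0.8, method = "recursive"))
    temp <- seasonal + diurnal + noise_day[day_idx + 1]

    q <- 16 + 9 * exp(-day_idx / 35) +
      as.numeric(stats::filter(stats::rnorm(nh, 0, 0.05), 0.95,
                               method = "recursive"))
    q <- pmax(q, 2)

    boundary <- data.frame(timestamp = hours, temp_c = temp, q_cms = q)

    nf <- length(cfg$tributary_fractions)
    rkm_lo <- 54.1 - (cfg$n_nodes - 1) * cfg$dx / 1000
    trib_rkm <- round(seq(52.0, rkm_lo + 2, length.out = nf), 1)
    tribs <- data.frame(name = sprintf("trib%02d", seq_len(nf)),
                        rkm = trib_rkm,
                        fraction = cfg$tributary_fractions)

    daily_mean <- stats::ave(temp, day_idx)
    tt <- daily_mean - 3 +
      (cfg$boundary_diurnal_amplitude / 2) * cos(2 * pi * (hr - 16) / 24)
    trib_temps <- matrix(rep(tt, nf), ncol = nf,
                         dimnames = list(NULL, tribs$name))
    # mild per-tributary offsets, still cooler than the boundary
    offs <- stats::runif(nf, -0.8, 0.4)
    trib_temps <- sweep(trib_temps, 2, offs, "+")

    list(boundary = boundary, tributaries = tribs, trib_temps = trib_temps)
  })
}

#' Generate vegetation-height and ground-elevation grids
#'
#' Axis-aligned rectangular grids around a north-south channel, for testing
#' the landcover sampler: a riverbank strip of zero vegetation, optional
#' uniform canopy beyond the bank, and optional inserted features (a
#' vegetation "wall" at a known offset, a topographic ridge).
#'
#' @param cfg [synth_config()] (used only for the seed).
#' @param nx,ny grid size in cells (x = east, y = north).
#' @param cell_m cell edge length, m (default 3; cell area 9 m2).
#' @param channel_x channel centreline easting, m.
#' @param channel_halfwidth half-width of the unvegetated channel strip, m.
#' @param canopy_height uniform vegetation height outside the channel, m
#'   (0 gives a flat grid of zeros).
#' @param features list of feature lists: `list(type = "wall", x_m =,
#'   height_m =)` inserts a one-cell-thick north-south vegetation wall;
#'   `list(type = "ridge", x_m =, height_m =)` a ground-elevation ridge.
#' @return list `veg` (matrix nx x ny), `ground` (matrix), `cell_m`,
#'   `cell_area_m2`, `channel_x`.
#' @export
make_height_grids <- function(cfg, nx = 400, ny = 200, cell_m = 3,
                              channel_x = nx * cell_m / 2,
                              channel_halfwidth = 40, canopy_height = 0,
                              features = list()) {
  if (cell_m <= 0) stop("cell size must be positive")
  veg <- matrix(0, nx, ny)
  ground <- matrix(0, nx, ny)
  xc <- (seq_len(nx) - 0.5) * cell_m
  outside <- abs(xc - channel_x) > channel_halfwidth
  veg[outside, ] <- canopy_height
  for (f in features) {
    i <- max(1, min(nx, floor(f$x_m / cell_m) + 1))
    if (identical(f$type, "wall")) veg[i, ] <- f$height_m
    if (identical(f$type, "ridge")) ground[i, ] <- f$height_m
  }
  list(veg = veg, ground = ground, cell_m = cell_m,
       cell_area_m2 = cell_m^2, channel_x = channel_x)
}

#' Build the full synthetic input bundle
#'
#' Convenience wrapper generating reach, meteorology, boundary and
#' tributaries from one config.
#'
#' @param cfg [synth_config()].
#' @return list `reach`, `met`, `boundary`, `tributaries`, `trib_temps`,
#'   `cfg`.
#' @export
make_synthetic_inputs <- function(cfg) {
  bt <- make_boundary_and_tributaries(cfg)
  list(reach = make_reach(cfg), met = make_meteorology(cfg),
       boundary = bt$boundary, tributaries = bt$tributaries,
       trib_temps = bt$trib_temps, cfg = cfg)
}

#' Synthetic observation twin for calibration tests
#'
#' Runs the heat-budget model under a known "truth" substrate
#' parameterisation, samples six virtual logger stations along the reach,
#' and adds i.i.d. Gaussian noise, returning both the observations and the
#' truth record so calibration can be tested for parameter recovery.
#'
#' @param truth_params substrate parameter set ([substrate_params()]) used
#'   as truth.
#' @param cfg [synth_config()]; `cfg$noise_sd` sets the observation noise.
#' @param inputs optional pre-built [make_synthetic_inputs()] bundle.
#' @param shade optional precomputed shade matrix (see [shade_series()]).
#' @param noise_seed optional separate seed for the noise draw (defaults to
#'   a child of `cfg$seed`), so replicate noise realisations can share one
#'   truth run.
#' @param field optional precomputed truth temperature field (skips the
#'   model run).
#' @return list `observations` (data.frame `node_id`, `timestamp`,
#'   `temp_c`), `stations` (node ids), `truth` (params), `field` (truth
#'   temperature field), `inputs`.
#' @export
make_observation_twin <- function(truth_params, cfg, inputs = NULL,
                                  shade = NULL, noise_seed = NULL,
                                  field = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(inputs)) inputs <- make_synthetic_inputs(cfg)
  if (is.null(field)) {
    field <- run_model(inputs$reach, inputs$met, inputs$boundary,
                       tributaries = inputs$tributaries,
                       trib_temps = inputs$trib_temps,
                       substrate = truth_params,
                       dates = c(cfg$start_date, cfg$end_date),
                       latitude = cfg$latitude, longitude = cfg$longitude,
                       utc_offset = cfg$utc_offset, shade = shade,
                       flush_days = cfg$flush_days)
  }
  n <- cfg$n_nodes
  stations <- unique(pmax(2, round(seq(0.15, 0.98, length.out = 6) * n)))
  obs <- do.call(rbind, lapply(stations, function(s) {
    data.frame(node_id = s, timestamp = field$time,
               temp_c = field$temps[, s])
  }))
  if (cfg$noise_sd > 0) {
    sd_seed <- noise_seed %||% child_seed(cfg$seed, 4L)
    obs$temp_c <- obs$temp_c +
      with_seed(sd_seed, stats::rnorm(nrow(obs), 0, cfg$noise_sd))
  }
  list(observations = obs, stations = stations, truth = truth_params,
       field = field, inputs = inputs)
}
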