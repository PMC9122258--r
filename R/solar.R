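#' Solar position (altitude, azimuth, declination, hour angle)
#'
#' Low-accuracy solar ephemeris following the NOAA Solar Calculator
#' equations (Meeus-derived), adequate for shading geometry (documented
#' accuracy better than 0.5 degrees for years 1900-2100). Solar time is
#' computed from longitude and a fixed UTC offset; no daylight-saving
#' arithmetic is applied, so timestamps must be in standard local time.
#'
#' @param latitude degrees north.
#' @param longitude degrees east (west negative).
#' @param timestamp POSIXct (vectorised) in the fixed local standard time.
#' @param utc_offset hours east of UTC (e.g. -7 for PDT-less Pacific summer
#'   convention used throughout this package).
#' @return data.frame with columns `altitude`, `azimuth` (degrees clockwise
#'   from north, in [0, 360)), `declination`, `hour_angle` (degrees).
#' @export
#' @examples
#' solar_position(47.4, -124, as.POSIXct("2019-07-01 13:00", tz = "UTC"), -7)
solar_position <- function(latitude, longitude, timestamp, utc_offset) {
  if (!is.numeric(latitude) || abs(latitude) > 90)
    stop("latitude must be in [-90, 90]")
  if (abs(longitude) > 180) stop("longitude must be in [-180, 180]")
  tt <- as.POSIXlt(timestamp, tz = attr(timestamp, "tzone") %||% "UTC")
  # Julian day from calendar fields (local clock time -> UTC via offset)
  frac_day <- (tt$hour + tt$min / 60 + tt$sec / 3600 - utc_offset) / 24
  y <- tt$year + 1900L
  m <- tt$mon + 1L
  d <- tt$mday
  adj <- m <= 2
  y[adj] <- y[adj] - 1L
  m[adj] <- m[adj] + 12L
  a <- floor(y / 100)
  b <- 2 - a + floor(a / 4)
  jd <- floor(365.25 * (y + 4716)) + floor(30.6001 * (m + 1)) + d + b - 1524.5 +
    frac_day
  t <- (jd - 2451545) / 36525                       # Julian centuries (J2000)

  l0 <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
  m_anom <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  e <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  mr <- m_anom * pi / 180
  eqc <- sin(mr) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * mr) * (0.019993 - 0.000101 * t) + sin(3 * mr) * 0.000289
  true_long <- l0 + eqc
  omega <- 125.04 - 1934.136 * t
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * pi / 180)

  seconds <- 21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))
  obliq0 <- 23 + (26 + seconds / 60) / 60
  obliq <- obliq0 + 0.00256 * cos(omega * pi / 180)

  or <- obliq * pi / 180
  alr <- app_long * pi / 180
  declination <- asin(sin(or) * sin(alr)) * 180 / pi

  vy <- tan(or / 2)^2
  l0r <- l0 * pi / 180
  eqtime <- 4 * (180 / pi) *
    (vy * sin(2 * l0r) - 2 * e * sin(mr) + 4 * e * vy * sin(mr) * cos(2 * l0r) -
       0.5 * vy^2 * sin(4 * l0r) - 1.25 * e^2 * sin(2 * mr))   # minutes

  clock_min <- tt$hour * 60 + tt$min + tt$sec / 60
  tst <- (clock_min + eqtime + 4 * longitude - 60 * utc_offset) %% 1440
  hour_angle <- tst / 4 - 180
  hour_angle[hour_angle < -180] <- hour_angle[hour_angle < -180] + 360

  latr <- latitude * pi / 180
  decr <- declination * pi / 180
  har <- hour_angle * pi / 180
  cos_zen <- sin(latr) * sin(decr) + cos(latr) * cos(decr) * cos(har)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  zen <- acos(cos_zen)
  altitude <- 90 - zen * 180 / pi

  az_num <- sin(latr) * cos_zen - sin(decr)
  az_den <- cos(latr) * sin(zen)
  cos_az <- ifelse(az_den == 0, 1, pmin(1, pmax(-1, az_num / az_den)))
  azimuth <- ifelse(hour_angle > 0,
                    (acos(cos_az) * 180 / pi + 180) %% 360,
                    (540 - acos(cos_az) * 180 / pi) %% 360)

  data.frame(altitude = altitude, azimuth = azimuth,
             declination = declination, hour_angle = hour_angle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clear-sky global solar radiation on a horizontal surface
#'
#' Simple broadband clear-sky model: extraterrestrial irradiance with orbital
#' eccentricity, attenuated by a constant broadband transmissivity raised to
#' the relative optical air mass (Kasten & Young), with an exponential
#' pressure correction for site elevation. Zero when the sun is at or below
#' the horizon. This is the "maximum radiation" reference against which
#' cloudiness is inverted from measured radiation.
#'
#' @param pos data.frame from [solar_position()] (only `altitude` is used),
#'   or a numeric vector of altitudes in degrees.
#' @param elevation_m site elevation, m.
#' @param doy day of year for the eccentricity term (default 172); ignored
#'   when `pos` carries a `doy` attribute.
#' @param const constants list from [heat_constants()].
#' @return global clear-sky irradiance, W/m2 (vectorised).
#' @export
clear_sky_radiation <- function(pos, elevation_m = 0, doy = 172,
                                const = heat_constants()) {
  alt <- if (is.data.frame(pos)) pos$altitude else pos
  ecc <- 1 + 0.033 * cos(2 * pi * doy / 365)
  altr <- pmax(alt, 0) * pi / 180
  # Kasten & Young (1989) air mass, pressure-corrected for elevation
  m <- exp(-elevation_m / const$scale_height_m) /
    (sin(altr) + 0.50572 * (pmax(alt, 0) + 6.07995)^(-1.6364))
  flux <- const$solar_constant * ecc * sin(altr) * const$transmissivity^m
  flux[alt <= 0] <- 0
  flux
}

#' Cloudiness inferred from measured solar radiation
#'
#' Inverts a cloud-attenuation relation `ratio = f(C)` for cloudiness C in
#' [0, 1], where `ratio` is observed over modelled clear-sky radiation.
#' The attenuation relation is a polynomial in C, configurable because the
#' published cubic's coefficients are not reproducible from the study; the
#' default is the quadratic `ratio = 1 - 0.65 C^2`. The inversion uses a
#' bracketing root-finder on [0, 1] so that arbitrary monotone polynomials
#' can be supplied; values outside the attainable ratio range are clamped to
#' C = 0 or C = 1. Night hours (em <= `night_em`) carry forward the last
#' daylight estimate (initial night hours get the first daylight estimate).
#'
#' @param eo observed global radiation, W/m2 (vectorised).
#' @param em modelled clear-sky maximum radiation, W/m2.
#' @param coefficients polynomial coefficients of f: ratio = 1 + sum(coef_k
#'   * C^k) for k = 1..length(coefficients); default `c(0, -0.65)` encodes
#'   1 - 0.65 C^2.
#' @param night_em threshold (W/m2) below which an hour is treated as night.
#' @param tol root-finder tolerance on C.
#' @return data.frame with columns `cloudiness`, `eo`, `em`.
#' @export
#' @examples
#' cloudiness_from_radiation(837.5, 1000)$cloudiness   # ~ 0.5
cloudiness_from_radiation <- function(eo, em, coefficients = c(0, -0.65),
                                      night_em = 1, tol = 1e-6) {
  if (any(eo < 0, na.rm = TRUE)) stop("eo must be non-negative")
  if (length(em) == 1L) em <- rep(em, length(eo))
  f <- function(c) 1 + sum(coefficients * c^seq_along(coefficients))
  f_min <- f(1)                               # heaviest attenuation
  cl <- rep(NA_real_, length(eo))
  day <- which(em > night_em)
  for (i in day) {
    ratio <- min(eo[i] / em[i], 1)
    if (ratio >= 1) {
      cl[i] <- 0
    } else if (ratio <= f_min) {
      cl[i] <- 1
    } else {
      cl[i] <- stats::uniroot(function(c) f(c) - ratio, c(0, 1),
                              tol = tol)$root
    }
  }
  # carry last daylight value through the night
  if (length(day)) {
    filled <- cl
    last <- cl[day[1]]
    for (i in seq_along(cl)) {
      if (is.na(filled[i])) filled[i] <- last else last <- filled[i]
    }
    cl <- filled
  } else {
    cl[] <- 0
  }
  data.frame(cloudiness = cl, eo = eo, em = em)
}

# Transect bearings used for riparian sampling: seven radial directions
# (every 45 degrees, omitting due north, which cannot shade a northern-
# hemisphere channel).
transect_bearings <- function() c(45, 90, 135, 180, 225, 270, 315)

#' Sample landcover grids into per-node shade geometry
#'
#' Emulates the GIS sampling step that prepares shading inputs: topographic
#' shade angles toward east, south and west from an elevation grid, and
#' riparian vegetation height/density along seven radial transects of ten
#' samples spaced ten metres apart from a vegetation-height grid. The
#' topographic angle in each direction is the larger of a near-field angle
#' (local maxima over the first 25 grid cells) and a far-field angle (local
#' maxima out to 20 km); cells beyond the grid are treated as zero height.
#'
#' @param height_grid matrix of vegetation heights (m); rows index x
#'   (east), columns index y (north).
#' @param elevation_grid matrix of ground elevation (m), same shape.
#' @param node_xy numeric length-2, node position (m) in grid coordinates
#'   (origin at grid corner (0, 0), cell centres at (i-0.5)*cell).
#' @param channel_aspect channel aspect, degrees (informational; transects
#'   are fixed compass bearings).
#' @param cell_m grid cell edge length, m (default 3, i.e. 9 m2 cells).
#' @param density canopy density fraction assigned to vegetated samples
#'   (single value or 7x10 matrix).
#' @param overhang bank overhang, m.
#' @param near_cells number of cells defining the near-field topographic
#'   search (default 25).
#' @param far_m far-field topographic search distance, m (default 20000).
#' @return A shade-geometry list with elements `topo` (named vector e/s/w,
#'   degrees), `veg_height` and `veg_density` (7 x 10 matrices, transects in
#'   rows), `dist` (7 x 10 matrix of sample distances from the bank, m),
#'   `overhang`, and `bearings`.
#' @export
sample_landcover <- function(height_grid, elevation_grid, node_xy,
                             channel_aspect = 0, cell_m = 3, density = 0.85,
                             overhang = 0, near_cells = 25, far_m = 20000) {
  if (cell_m <= 0) stop("cell size must be positive")
  nx <- nrow(elevation_grid); ny <- ncol(elevation_grid)
  x0 <- node_xy[1]; y0 <- node_xy[2]
  if (x0 < 0 || y0 < 0 || x0 > nx * cell_m || y0 > ny * cell_m)
    stop("node lies outside the grid")

  cell_at <- function(grid, x, y) {
    i <- floor(x / cell_m) + 1
    j <- floor(y / cell_m) + 1
    inside <- i >= 1 & i <= nx & j >= 1 & j <= ny
    out <- numeric(length(x))
    out[inside] <- grid[cbind(i[inside], j[inside])]
    out
  }
  z0 <- cell_at(elevation_grid, x0, y0)

  topo_dir <- function(bearing) {
    br <- bearing * pi / 180
    d <- seq(cell_m, far_m, by = cell_m)
    x <- x0 + sin(br) * d
    y <- y0 + cos(br) * d
    z <- cell_at(elevation_grid, x, y)
    ang <- atan2(z - z0, d) * 180 / pi
    near <- max(ang[seq_len(min(near_cells, length(ang)))], 0)
    far <- max(ang, 0)
    max(near, far)
  }
  topo <- c(e = topo_dir(90), s = topo_dir(180), w = topo_dir(270))

  bearings <- transect_bearings()
  veg <- matrix(0, 7, 10)
  dist <- matrix(rep(10 * (1:10), each = 7), 7, 10)
  for (k in seq_along(bearings)) {
    br <- bearings[k] * pi / 180
    d <- dist[k, ]
    veg[k, ] <- cell_at(height_grid, x0 + sin(br) * d, y0 + cos(br) * d)
  }
  dens <- if (is.matrix(density)) density else matrix(density, 7, 10)
  dens[veg <= 0] <- 0

  structure(list(topo = topo, veg_height = veg, veg_density = dens,
                 dist = dist, overhang = overhang, bearings = bearings),
            class = "shade_geometry")
}

#' Construct shade geometry directly from per-node landcover values
#'
#' Builds the same shade-geometry object as [sample_landcover()] from
#' tabular inputs (the node landcover table written by the synthetic
#' generator), bypassing raster sampling.
#'
#' @param topo_e,topo_s,topo_w topographic shade angles, degrees.
#' @param veg_height 7 x 10 matrix (or length-70 vector, transect-major) of
#'   vegetation heights, m.
#' @param veg_density matching canopy density fractions in [0, 1].
#' @param overhang bank overhang, m.
#' @return shade-geometry list; see [sample_landcover()].
#' @export
shade_geometry <- function(topo_e, topo_s, topo_w, veg_height,
                           veg_density, overhang = 0) {
  vh <- matrix(veg_height, 7, 10)
  vd <- matrix(veg_density, 7, 10)
  if (any(vd < 0 | vd > 1)) stop("densities must be in [0, 1]")
  topo <- c(e = topo_e, s = topo_s, w = topo_w)
  if (any(topo < 0 | topo >= 90)) stop("topographic angles must be in [0, 90)")
  structure(list(topo = topo, veg_height = vh, veg_density = vd,
                 dist = matrix(rep(10 * (1:10), each = 7), 7, 10),
                 overhang = overhang, bearings = transect_bearings()),
            class = "shade_geometry")
}

#' Effective shade on the water surface for one solar position
#'
#' Fraction of the direct solar beam blocked before reaching the channel
#' centre. Full topographic blocking (shade = 1) applies when the
#' topographic shade angle in the solar direction (nearest of east, south,
#' west) is at least the solar altitude. Otherwise riparian vegetation along
#' the transect whose bearing is closest to the solar azimuth (ties broken
#' toward south) attenuates the beam: every sample whose angular height
#' above the channel centre exceeds the solar altitude blocks a fraction
#' equal to its canopy density, combining as `1 - prod(1 - density_i)`.
#' Sample angular height uses the distance from the channel centre
#' (bank distance + width/2), with bank overhang shortening the first
#' sample's distance.
#'
#' @param geom shade geometry from [shade_geometry()]/[sample_landcover()].
#' @param pos single-row solar position ([solar_position()]).
#' @param width_m channel width, m.
#' @return shade fraction in [0, 1]; 0 when the sun is below the horizon.
#' @export
effective_shade <- function(geom, pos, width_m) {
  alt <- pos$altitude
  az <- pos$azimuth
  if (alt <= 0) return(0)
  # topographic direction: nearest of east/south/west
  topo_az <- c(e = 90, s = 180, w = 270)
  topo_dir <- names(which.min(abs(az - topo_az)))
  if (geom$topo[[topo_dir]] >= alt) return(1)
  # vegetation transect nearest the solar azimuth, ties toward south
  dd <- abs(geom$bearings - az)
  dd <- pmin(dd, 360 - dd)
  cand <- which(dd == min(dd))
  k <- cand[which.min(abs(geom$bearings[cand] - 180))]
  d <- geom$dist[k, ] + width_m / 2
  d[1] <- max(d[1] - geom$overhang, 0.5)
  ang <- atan2(geom$veg_height[k, ], d) * 180 / pi
  blocking <- ang > alt
  1 - prod(1 - geom$veg_density[k, blocking])
}

#' View-to-sky fraction of a shade geometry
#'
#' Diffuse radiation is reduced by the mean angular blocking of the sky
#' hemisphere: the average over transects of the maximum angular height
#' (vegetation or topography) divided by 90 degrees, subtracted from 1.
#'
#' @param geom shade geometry.
#' @param width_m channel width, m.
#' @return fraction of the sky dome open to the channel, in [0, 1].
#' @export
view_to_sky <- function(geom, width_m) {
  d <- geom$dist + width_m / 2
  ang <- atan2(geom$veg_height, d) * 180 / pi
  per_transect <- apply(ang, 1, max)
  # east/south/west topographic angles apply to their nearest transects
  topo_by_transect <- c(geom$topo[["e"]], geom$topo[["e"]], geom$topo[["s"]],
                        geom$topo[["s"]], geom$topo[["s"]], geom$topo[["w"]],
                        geom$topo[["w"]])
  blocked <- pmax(per_transect, topo_by_transect)
  max(0, 1 - mean(blocked) / 90)
}
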