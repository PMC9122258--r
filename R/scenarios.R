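#' Scenario specification (climate period x RCP x vegetation)
#'
#' A scenario is a climate period (`current` or one of the four 20-year
#' future windows centred on 2020/2040/2060/2080), an emission pathway
#' (`none` for current climate, else RCP `4.5` or `8.5`), and a riparian
#' vegetation treatment (`increase`, `current`, `loss`).
#'
#' @param climate_period one of "current", "2020", "2040", "2060", "2080".
#' @param rcp one of "none", "4.5", "8.5"; must be "none" iff
#'   `climate_period == "current"`.
#' @param vegetation one of "increase", "current", "loss".
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(climate_period = "current", rcp = "none",
                          vegetation = "current") {
  climate_period <- match.arg(climate_period,
                              c("current", "2020", "2040", "2060", "2080"))
  rcp <- match.arg(as.character(rcp), c("none", "4.5", "8.5"))
  vegetation <- match.arg(vegetation, c("increase", "current", "loss"))
  if ((climate_period == "current") != (rcp == "none"))
    stop("rcp must be 'none' exactly when climate_period is 'current'")
  structure(list(climate_period = climate_period, rcp = rcp,
                 vegetation = vegetation,
                 tag = paste(climate_period, rcp, vegetation, sep = "_")),
            class = "scenario_spec")
}

#' Enumerate the scenario grid
#'
#' The 25-scenario grid: the current-climate baseline plus every future
#' climate (4 periods x 2 RCPs) under each of the three vegetation
#' treatments. Setting `current_vegetation_variants = TRUE` additionally
#' includes the vegetation treatments under current climate (27 scenarios),
#' which the riparian-management comparisons use.
#'
#' @param current_vegetation_variants include `loss`/`increase` under
#'   current climate.
#' @return list of [scenario_spec()].
#' @export
scenario_grid <- function(current_vegetation_variants = FALSE) {
  veg_current <- if (current_vegetation_variants)
    c("increase", "current", "loss") else "current"
  specs <- lapply(veg_current, function(v) scenario_spec("current", "none", v))
  for (period in c("2020", "2040", "2060", "2080"))
    for (rcp in c("4.5", "8.5"))
      for (v in c("increase", "current", "loss"))
        specs[[length(specs) + 1]] <- scenario_spec(period, rcp, v)
  specs
}

#' Apply a riparian vegetation treatment to the landcover table
#'
#' `loss` zeroes every vegetation transect height over the entire reach and
#' both banks (and zeroes the matching densities and overhang). `increase`
#' raises every transect sample lying within `buffer_width_m` of the bank
#' to at least `min_height_m` (24.4 m, the lower bound of mature mixed
#' forest height); taller stands are left at their original height.
#' `current` is the identity. All treatments are idempotent.
#'
#' @param landcover reach/landcover table ([make_reach()]).
#' @param mode "increase", "current" or "loss".
#' @param buffer_width_m buffer distance from the bank, m (default 100; the
#'   study's table equivalently describes a 300-ft, 91.4 m, buffer).
#' @param min_height_m minimum tree height inside the buffer, m.
#' @return modified landcover table.
#' @export
modify_vegetation <- function(landcover, mode, buffer_width_m = 100,
                              min_height_m = 24.4) {
  mode <- match.arg(mode, c("increase", "current", "loss"))
  if (mode == "current") return(landcover)
  for (k in 1:7) for (j in 1:10) {
    hcol <- sprintf("veg_d%d_s%d_height_m", k, j)
    dcol <- sprintf("veg_d%d_s%d_density", k, j)
    if (mode == "loss") {
      landcover[[hcol]] <- 0
      landcover[[dcol]] <- 0
    } else {
      if (10 * j <= buffer_width_m) {
        raised <- pmax(landcover[[hcol]], min_height_m)
        newly <- landcover[[hcol]] < min_height_m
        landcover[[hcol]] <- raised
        # a planted buffer carries at least the node's canopy density
        landcover[[dcol]] <- ifelse(newly & landcover[[dcol]] <= 0,
                                    landcover$canopy_density_pct / 100,
                                    landcover[[dcol]])
      }
    }
  }
  if (mode == "loss") landcover$overhang_m <- 0
  landcover
}

#' Synthetic daily climate deltas (projected daily mean air temperature)
#'
#' Stands in for downscaled GCM output: for each simulation day, the
#' projected daily mean air temperature equals the observed daily mean plus
#' a period/RCP offset plus day-to-day noise. End-of-century (2080) offsets
#' default to the study's reported means (+2.11 degC RCP 4.5, SD 0.63;
#' +3.48 degC RCP 8.5, SD 0.59); earlier periods scale those offsets by
#' 0.25/0.5/0.75, a linear-in-time warming ramp.
#'
#' @param met observed hourly meteorology (baseline year).
#' @param climate_period "2020", "2040", "2060" or "2080".
#' @param rcp "4.5" or "8.5".
#' @param seed integer seed for the day-to-day noise.
#' @return data.frame `date`, `mean_air_c` (projected daily mean, degC).
#' @export
make_climate_delta <- function(met, climate_period, rcp, seed = 1L) {
  climate_period <- match.arg(as.character(climate_period),
                              c("2020", "2040", "2060", "2080"))
  rcp <- match.arg(as.character(rcp), c("4.5", "8.5"))
  scale <- c("2020" = 0.25, "2040" = 0.5, "2060" = 0.75, "2080" = 1)[[climate_period]]
  mean_off <- if (rcp == "4.5") 2.11 else 3.48
  sd_off <- if (rcp == "4.5") 0.63 else 0.59
  day <- as.Date(format(met$timestamp, "%Y-%m-%d"))
  obs_daily <- tapply(met$air_c, day, mean)
  dates <- as.Date(names(obs_daily))
  stream <- child_seed(seed, 10L + round(scale * 4) * 2 + (rcp == "8.5"))
  offs <- with_seed(stream,
                    stats::rnorm(length(dates), mean_off * scale,
                                 sd_off * scale))
  data.frame(date = dates, mean_air_c = as.numeric(obs_daily) + offs)
}

#' Delta-method climate adjustment with diurnal disaggregation
#'
#' Replaces each day's mean air temperature with the projected daily mean
#' while preserving the observed within-day anomalies exactly:
#' `future(d, h) = projected_mean(d) + (observed(d, h) - observed_mean(d))`.
#' Only air temperature is adjusted; humidity, wind and radiation pass
#' through unchanged.
#'
#' @param met observed hourly meteorology.
#' @param delta data.frame `date`, `mean_air_c` covering every simulation
#'   day.
#' @return adjusted meteorology data.frame.
#' @export
climate_adjust <- function(met, delta) {
  day <- as.Date(format(met$timestamp, "%Y-%m-%d"))
  idx <- match(day, delta$date)
  if (anyNA(idx))
    stop("climate delta missing ", sum(is.na(idx)), " simulation hours' days")
  obs_mean <- stats::ave(met$air_c, day)
  met$air_c <- delta$mean_air_c[idx] + (met$air_c - obs_mean)
  met
}

#' Assemble a model-ready input bundle for one scenario
#'
#' Applies the vegetation treatment to the landcover, then the climate
#' adjustment to the meteorology. The boundary water temperature (lake
#' outlet) and discharge, and the tributary series, are passed through
#' unmodified for every scenario — future lake warming is deliberately not
#' modelled, so the temperature responses are conservative. The bundle
#' carries a provenance record of the transforms applied.
#'
#' @param spec [scenario_spec()].
#' @param base_inputs bundle from [make_synthetic_inputs()] (fields `reach`,
#'   `met`, `boundary`, `tributaries`, `trib_temps`, `cfg`).
#' @param buffer_width_m,min_height_m vegetation treatment settings.
#' @param delta optional precomputed [make_climate_delta()]; generated from
#'   the bundle's config seed when omitted.
#' @return bundle list like `base_inputs` plus `spec` and `provenance`.
#' @export
build_scenario <- function(spec, base_inputs, buffer_width_m = 100,
                           min_height_m = 24.4, delta = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  out <- base_inputs
  prov <- list(spec = spec$tag)
  out$reach <- modify_vegetation(base_inputs$reach, spec$vegetation,
                                 buffer_width_m, min_height_m)
  prov$vegetation <- spec$vegetation
  if (spec$climate_period != "current") {
    if (is.null(delta))
      delta <- make_climate_delta(base_inputs$met, spec$climate_period,
                                  spec$rcp,
                                  seed = base_inputs$cfg$seed %||% 1L)
    out$met <- climate_adjust(base_inputs$met, delta)
    prov$climate <- paste0(spec$climate_period, "/RCP", spec$rcp)
  } else {
    prov$climate <- "current"
  }
  prov$boundary <- "held constant"
  out$spec <- spec
  out$provenance <- prov
  out
}
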