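# CSV/YAML artifact dialects. All timestamps are written ISO-8601 with the
# explicit fixed UTC offset; temperatures degC; discharge m3/s.

fmt_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S%z")

parse_ts <- function(x, what = "timestamp") {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop("malformed ", what, " at row ", bad, ": '", x[bad], "'")
  }
  out
}

#' Write / read a temperature field as wide CSV
#'
#' First column `timestamp` (ISO-8601 with offset), one column per node
#' (`node_<id>`). Node river-kilometres are carried in a comment-free
#' sidecar attribute row convention: a `rkm` attribute is rebuilt from the
#' node ids when read back if not supplied.
#'
#' @param field `temperature_field`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_temperature_field <- function(field, path) {
  df <- data.frame(timestamp = fmt_ts(field$time))
  for (i in seq_along(field$node_id))
    df[[sprintf("node_%d", field$node_id[i])]] <- field$temps[, i]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_temperature_field
#' @param rkm optional river-kilometre vector for the nodes.
#' @export
read_temperature_field <- function(path, rkm = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  time <- parse_ts(df$timestamp)
  temps <- as.matrix(df[, -1, drop = FALSE])
  node_id <- as.integer(sub("^node_", "", colnames(temps)))
  structure(list(time = time, temps = unname(temps), node_id = node_id,
                 rkm = rkm %||% rep(NA_real_, length(node_id)),
                 dx = NA_real_, dt = NA_real_),
            class = "temperature_field")
}

#' Write the synthetic input bundle to a directory
#'
#' Emits `reach.csv` (node geometry), `landcover.csv` (vegetation transect
#' columns), `met.csv`, `boundary.csv`, `tributaries.csv` (with the
#' tributary temperature series as `trib_temps.csv`) and `truth.yaml` when
#' a truth parameterisation is supplied.
#'
#' @param inputs bundle from [make_synthetic_inputs()].
#' @param dir output directory (created if needed).
#' @param truth optional [substrate_params()] truth record.
#' @return `dir`, invisibly.
#' @export
write_inputs <- function(inputs, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base_cols <- c("node_id", "rkm", "elevation_m", "gradient", "width_m",
                 "aspect_deg", "topo_e_deg", "topo_s_deg", "topo_w_deg",
                 "canopy_density_pct", "overhang_m")
  utils::write.csv(inputs$reach[, base_cols],
                   file.path(dir, "reach.csv"), row.names = FALSE)
  veg_cols <- grep("^veg_", names(inputs$reach), value = TRUE)
  utils::write.csv(inputs$reach[, c("node_id", veg_cols)],
                   file.path(dir, "landcover.csv"), row.names = FALSE)
  met <- inputs$met
  met$timestamp <- fmt_ts(met$timestamp)
  utils::write.csv(met, file.path(dir, "met.csv"), row.names = FALSE)
  b <- inputs$boundary
  b$timestamp <- fmt_ts(b$timestamp)
  utils::write.csv(b, file.path(dir, "boundary.csv"), row.names = FALSE)
  utils::write.csv(inputs$tributaries, file.path(dir, "tributaries.csv"),
                   row.names = FALSE)
  tt <- data.frame(timestamp = fmt_ts(inputs$met$timestamp),
                   inputs$trib_temps, check.names = FALSE)
  utils::write.csv(tt, file.path(dir, "trib_temps.csv"), row.names = FALSE)
  if (!is.null(truth))
    yaml::write_yaml(unclass(truth), file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read a synthetic input bundle written by [write_inputs()]
#'
#' @param dir directory containing the CSV artifacts.
#' @param cfg optional [synth_config()] to attach.
#' @return input bundle list.
#' @export
read_inputs <- function(dir, cfg = NULL) {
  reach <- utils::read.csv(file.path(dir, "reach.csv"))
  lc <- utils::read.csv(file.path(dir, "landcover.csv"))
  reach <- merge(reach, lc, by = "node_id", sort = FALSE)
  met <- utils::read.csv(file.path(dir, "met.csv"))
  met$timestamp <- parse_ts(met$timestamp, "met timestamp")
  b <- utils::read.csv(file.path(dir, "boundary.csv"))
  b$timestamp <- parse_ts(b$timestamp, "boundary timestamp")
  tribs <- utils::read.csv(file.path(dir, "tributaries.csv"))
  tt <- utils::read.csv(file.path(dir, "trib_temps.csv"),
                        check.names = FALSE)
  trib_temps <- as.matrix(tt[, -1, drop = FALSE])
  list(reach = reach, met = met, boundary = b, tributaries = tribs,
       trib_temps = trib_temps, cfg = cfg)
}

#' Run the full synthetic pipeline
#'
#' End-to-end orchestration: generate (or load) inputs, optionally
#' calibrate the substrate candidates against twin observations, run the
#' temperature model for every scenario in the list (shade geometry is
#' computed once per vegetation treatment and reused), run batch growth per
#' scenario, and write the comparison reports. All randomness derives from
#' the single seed in the config; intermediate artifacts are always
#' written so each stage can be inspected independently.
#'
#' @param cfg [synth_config()].
#' @param out_dir output directory.
#' @param scenarios list of [scenario_spec()] (default:
#'   `scenario_grid(current_vegetation_variants = TRUE)`).
#' @param species species name for the growth stage (default "chinook").
#' @param inputs optional prebuilt input bundle.
#' @param calibrate_first run the candidate calibration against a synthetic
#'   observation twin before the scenario runs.
#' @param substrate substrate parameters for the scenario runs (defaults to
#'   the calibrated selection when `calibrate_first`, else the physical-
#'   sediment study values).
#' @param bioe [bioe_inputs()].
#' @return run manifest list (also written as `manifest.json`): seed,
#'   scenario tags, per-stage timings, output paths, and the scenario
#'   report.
#' @export
run_pipeline <- function(cfg, out_dir,
                         scenarios = scenario_grid(TRUE),
                         species = "chinook", inputs = NULL,
                         calibrate_first = FALSE, substrate = NULL,
                         bioe = bioe_inputs()) {
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(start) as.numeric(difftime(Sys.time(), start,
                                             units = "secs"))

  st <- tic()
  if (is.null(inputs)) inputs <- make_synthetic_inputs(cfg)
  write_inputs(inputs, file.path(out_dir, "inputs"))
  timings$synth <- toc(st)

  truth <- substrate %||% substrate_params(physical_sediment = TRUE)

  pos <- solar_position(cfg$latitude, cfg$longitude,
                        synth_hours(cfg), cfg$utc_offset)
  # shade per vegetation treatment, cached
  st <- tic()
  veg_modes <- unique(vapply(scenarios, function(s) s$vegetation, ""))
  shade_cache <- list()
  reach_cache <- list()
  for (vm in veg_modes) {
    reach_cache[[vm]] <- modify_vegetation(inputs$reach, vm)
    shade_cache[[vm]] <- shade_series(reach_cache[[vm]], pos)
  }
  timings$shade <- toc(st)

  if (calibrate_first) {
    st <- tic()
    twin <- make_observation_twin(truth, cfg, inputs = inputs,
                                  shade = shade_cache[["current"]] %||%
                                    shade_series(inputs$reach, pos))
    cal <- calibrate(candidate_grid(physical_sediment = TRUE),
                     twin$observations, inputs,
                     shade = shade_cache[["current"]])
    truth <- cal$params
    jsonlite::write_json(list(selected = cal$selected,
                              stage1 = cal$stage1, stage2 = cal$stage2),
                         file.path(out_dir, "fit_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    timings$calibrate <- toc(st)
  }

  params <- species_params(species)
  outputs <- list()
  st <- tic()
  for (s in scenarios) {
    bundle <- build_scenario(s, inputs)
    bundle$reach <- reach_cache[[s$vegetation]]
    field <- run_model(bundle$reach, bundle$met, bundle$boundary,
                       tributaries = bundle$tributaries,
                       trib_temps = bundle$trib_temps, substrate = truth,
                       dates = c(cfg$start_date, cfg$end_date),
                       latitude = cfg$latitude, longitude = cfg$longitude,
                       utc_offset = cfg$utc_offset,
                       shade = shade_cache[[s$vegetation]],
                       flush_days = cfg$flush_days)
    growth <- batch_growth(field, bioe, params)
    tag <- if (s$tag == "current_none_current") "current" else s$tag
    sdir <- file.path(out_dir, "scenarios", tag)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    write_temperature_field(field, file.path(sdir, "temps.csv"))
    utils::write.csv(growth$final, file.path(sdir, "growth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(growth$summary,
                         file.path(sdir, "growth_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs[[tag]] <- list(field = field, growth = growth, spec = s)
  }
  timings$scenarios <- toc(st)

  st <- tic()
  report <- scenario_report(outputs)
  rep_dir <- file.path(out_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  utils::write.csv(report$delta_7dadm,
                   file.path(rep_dir, "delta_7dadm.csv"), row.names = FALSE)
  utils::write.csv(report$reach_means,
                   file.path(rep_dir, "reach_means.csv"), row.names = FALSE)
  utils::write.csv(report$exceedance,
                   file.path(rep_dir, "exceedance.csv"), row.names = FALSE)
  sd_series <- sevendadm(outputs$current$field)$series
  utils::write.csv(sd_series, file.path(rep_dir, "sevendadm.csv"),
                   row.names = FALSE)
  timings$report <- toc(st)

  manifest <- list(
    package_version = as.character(utils::packageVersion("thermosalmon")),
    seed = cfg$seed,
    n_nodes = cfg$n_nodes,
    scenarios = names(outputs),
    substrate = unclass(truth),
    timings_s = timings,
    total_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, list(outputs = outputs, report = report)))
}
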