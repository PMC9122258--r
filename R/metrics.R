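#' Model-fit statistics: bias, RMSE, Nash-Sutcliffe efficiency
#'
#' `bias = mean(pred - obs)`, `rmse = sqrt(mean((pred - obs)^2))`,
#' `nse = 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)`. NSE is
#' undefined (returned as `NA`) when the observations have zero variance.
#'
#' @param pred,obs aligned numeric series of equal length >= 2.
#' @return list `bias`, `rmse`, `nse`.
#' @export
#' @examples
#' fit_metrics(c(11, 12, 13), c(10, 12, 14))  # bias 0, rmse sqrt(2/3), nse 0.75
fit_metrics <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs must be equal length")
  if (length(obs) < 2) stop("need at least 2 points")
  err <- pred - obs
  ss_obs <- sum((obs - mean(obs))^2)
  list(bias = mean(err), rmse = sqrt(mean(err^2)),
       nse = if (ss_obs > 0) 1 - sum(err^2) / ss_obs else NA_real_)
}

# internal: daily maxima of an hourly series on complete local days
daily_maxima <- function(time, values, min_hours = 24) {
  day <- as.Date(format(time, "%Y-%m-%d"))
  counts <- table(day)
  complete <- names(counts)[counts >= min_hours]
  if (length(complete) < length(counts))
    warning("excluding ", length(counts) - length(complete),
            " incomplete day(s)")
  keep <- day %in% as.Date(complete)
  mx <- tapply(values[keep], day[keep], max)
  data.frame(date = as.Date(names(mx)), max_c = as.numeric(mx))
}

#' Seven-day average daily maximum (7DADM)
#'
#' Daily maxima on complete local calendar days, smoothed with a trailing
#' (right-aligned) 7-day arithmetic mean; the first value falls on day 7.
#' Returns the series per node and each node's period maximum (the "maximum
#' 7DADM" used for reach profiles).
#'
#' @param field `temperature_field`, or a list with `time` and `temps`
#'   (matrix hours x nodes) and optionally `node_id`.
#' @return list `series` (data.frame `node_id`, `date`, `value_c`) and
#'   `max` (data.frame `node_id`, `max_7dadm_c`).
#' @export
sevendadm <- function(field) {
  temps <- field$temps
  node_id <- field$node_id %||% seq_len(ncol(temps))
  out <- vector("list", ncol(temps))
  for (i in seq_len(ncol(temps))) {
    dm <- daily_maxima(field$time, temps[, i])
    if (nrow(dm) < 7) stop("need at least 7 complete days")
    v <- stats::filter(dm$max_c, rep(1 / 7, 7), sides = 1)
    keep <- !is.na(v)
    out[[i]] <- data.frame(node_id = node_id[i], date = dm$date[keep],
                           value_c = as.numeric(v[keep]))
  }
  series <- do.call(rbind, out)
  mx <- stats::aggregate(value_c ~ node_id, series, max)
  names(mx)[2] <- "max_7dadm_c"
  list(series = series, max = mx)
}

#' Threshold exceedance frequency
#'
#' Percentage of complete days whose daily maximum temperature exceeds a
#' threshold, per node.
#'
#' @param field `temperature_field` (or list with `time`, `temps`,
#'   `node_id`).
#' @param threshold_c threshold, degC (daily maximum statistic).
#' @return data.frame `node_id`, `pct_days`.
#' @export
exceedance_frequency <- function(field, threshold_c) {
  temps <- field$temps
  node_id <- field$node_id %||% seq_len(ncol(temps))
  pct <- vapply(seq_len(ncol(temps)), function(i) {
    dm <- daily_maxima(field$time, temps[, i])
    100 * sum(dm$max_c > threshold_c) / nrow(dm)
  }, numeric(1))
  data.frame(node_id = node_id, pct_days = pct)
}

#' Life-stage temperature threshold registry
#'
#' The salmonid life-stage thresholds the exceedance summaries use:
#' smoltification 12-15 degC, embryo development 12-15 degC, spawning
#' migration 19-23 degC, adult/juvenile mortality 24-26 degC. Exceedance is
#' assessed on the daily maximum statistic (the mortality mapping uses the
#' lower bound, 24 degC, as its exceedance threshold).
#'
#' @return data.frame `label`, `lower_c`, `upper_c`, `statistic`.
#' @export
threshold_registry <- function() {
  data.frame(
    label = c("smoltification", "embryo_development", "spawning_migration",
              "adult_juvenile_mortality"),
    lower_c = c(12, 12, 19, 24),
    upper_c = c(15, 15, 23, 26),
    statistic = "daily_max")
}

#' Two-way factorial ANOVA of scenario growth changes
#'
#' Fixed-effects two-way ANOVA with interaction of per-node growth change
#' on climate and vegetation factors (nodes are the replicates within each
#' scenario cell), as used to compare scenario growth. Degenerate inputs
#' with zero total variance return F = 0, p = 1 for all terms.
#'
#' @param growth data.frame with columns `change_g`, `climate`,
#'   `vegetation`.
#' @return data.frame `term`, `df`, `sum_sq`, `f_value`, `p_value`.
#' @export
scenario_growth_anova <- function(growth) {
  growth$climate <- factor(growth$climate)
  growth$vegetation <- factor(growth$vegetation)
  if (nlevels(growth$climate) < 2 || nlevels(growth$vegetation) < 2)
    stop("need at least 2 levels per factor")
  cells <- table(growth$climate, growth$vegetation)
  if (any(cells == 0)) stop("empty scenario cell(s)")
  if (any(cells < 2)) stop("need at least 2 replicates per cell")
  if (stats::var(growth$change_g) == 0) {
    return(data.frame(
      term = c("climate", "vegetation", "climate:vegetation"),
      df = NA_integer_, sum_sq = 0, f_value = 0, p_value = 1))
  }
  fit <- stats::aov(change_g ~ climate * vegetation, data = growth)
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  keep <- terms != "Residuals"
  data.frame(term = terms[keep], df = s$Df[keep],
             sum_sq = s$`Sum Sq`[keep], f_value = s$`F value`[keep],
             p_value = s$`Pr(>F)`[keep])
}

#' Cross-scenario comparison report
#'
#' Compares every scenario against the current baseline: per-node and
#' reach-average changes in maximum 7DADM, growth summaries, and mortality-
#' threshold exceedance by river kilometre — the tabular equivalents of the
#' study's scenario figures.
#'
#' @param outputs named list of per-scenario results; each element is a
#'   list with `field` (`temperature_field`) and optionally `growth` (from
#'   [batch_growth()]). A scenario named `"current"` must be present.
#' @param mortality_threshold_c threshold for the exceedance map (default
#'   24).
#' @return list `delta_7dadm` (data.frame `scenario`, `node_id`, `rkm`,
#'   `delta_c`), `reach_means` (data.frame `scenario`,
#'   `mean_delta_7dadm_c`, `mean_change_g`, `sd_change_g`), `exceedance`
#'   (data.frame `scenario`, `node_id`, `rkm`, `pct_days`).
#' @export
scenario_report <- function(outputs, mortality_threshold_c = 24) {
  if (!"current" %in% names(outputs))
    stop("scenario_report requires a 'current' baseline scenario")
  base <- sevendadm(outputs$current$field)$max
  rkm <- outputs$current$field$rkm
  rows_delta <- list(); rows_mean <- list(); rows_exc <- list()
  for (nm in names(outputs)) {
    f <- outputs[[nm]]$field
    mx <- sevendadm(f)$max
    delta <- mx$max_7dadm_c - base$max_7dadm_c
    rows_delta[[nm]] <- data.frame(scenario = nm, node_id = mx$node_id,
                                   rkm = rkm, delta_c = delta)
    g <- outputs[[nm]]$growth
    rows_mean[[nm]] <- data.frame(
      scenario = nm, mean_delta_7dadm_c = mean(delta),
      mean_change_g = if (!is.null(g)) g$summary$mean_change_g else NA_real_,
      sd_change_g = if (!is.null(g)) g$summary$sd_change_g else NA_real_)
    exc <- exceedance_frequency(f, mortality_threshold_c)
    rows_exc[[nm]] <- data.frame(scenario = nm, node_id = exc$node_id,
                                 rkm = rkm, pct_days = exc$pct_days)
  }
  list(delta_7dadm = do.call(rbind, rows_delta),
       reach_means = do.call(rbind, rows_mean),
       exceedance = do.call(rbind, rows_exc))
}
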