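#' Physical constants and default heat-budget coefficients
#'
#' Returns the fixed physical constants and the documented default flux
#' coefficients used by the heat-budget model. The stream-temperature
#' literature defers most of these to model documentation rather than
#' printing them; they are collected here so every choice is visible and
#' overridable.
#'
#' @param ... named overrides for any element of the returned list.
#' @return A named list:
#' \describe{
#'   \item{rho_w}{density of water, kg/m3}
#'   \item{c_w}{specific heat of water, J/kg/K}
#'   \item{sigma}{Stefan-Boltzmann constant, W/m2/K4}
#'   \item{albedo}{water-surface shortwave albedo (dimensionless)}
#'   \item{emissivity_water}{longwave emissivity of the water surface}
#'   \item{latent_heat}{latent heat of vaporisation, J/kg}
#'   \item{bowen_coeff}{Bowen-ratio coefficient, mmHg/degC
#'     (0.00061 degC^-1 x 760 mmHg standard pressure)}
#'   \item{cloud_longwave_coeff}{cloud enhancement of atmospheric emissivity,
#'     applied as (1 + coeff * C^2)}
#'   \item{solar_constant}{extraterrestrial irradiance, W/m2}
#'   \item{transmissivity}{clear-sky broadband atmospheric transmissivity at
#'     unit air mass}
#'   \item{scale_height_m}{atmospheric pressure scale height used for the
#'     elevation correction of optical air mass, m}
#' }
#' @export
#' @examples
#' heat_constants()$rho_w
#' heat_constants(albedo = 0.06)$albedo
heat_constants <- function(...) {
  const <- list(
    rho_w = 998.2,
    c_w = 4182,
    sigma = 5.670374419e-8,
    albedo = 0.05,
    emissivity_water = 0.96,
    latent_heat = 2.45e6,
    bowen_coeff = 0.4636,
    cloud_longwave_coeff = 0.22,
    solar_constant = 1367,
    transmissivity = 0.75,
    scale_height_m = 8435
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(const))
    if (length(bad)) stop("unknown constant(s): ", paste(bad, collapse = ", "))
    const[names(dots)] <- dots
  }
  const
}

#' Saturation vapour pressure over water
#'
#' Magnus-form saturation vapour pressure, returned in mmHg to match the
#' mass-transfer evaporation coefficients (offset 2.21e-9 m s-1 mmHg-1).
#'
#' @param t_c temperature, degC (vectorised).
#' @return saturation vapour pressure, mmHg.
#' @export
saturation_vapour_pressure <- function(t_c) {
  hpa <- 6.112 * exp(17.62 * t_c / (243.12 + t_c))
  hpa * 0.750062
}

# internal: restore RNG state after seeded generation so generators never
# disturb the caller's random stream
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# internal: derive a stream-specific child seed, kept below 2^31
child_seed <- function(seed, stream) {
  (as.integer(seed) * 101L + as.integer(stream) * 7919L) %% 2147483629L
}
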