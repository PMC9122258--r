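#' Tributary inflow as a fixed fraction of gaged boundary flow
#'
#' Summer baseflow tributary discharge is modelled as a constant percentage
#' of the upstream gaged flow, held fixed over the whole modelling period.
#'
#' @param boundary_q boundary discharge series, m3/s.
#' @param fraction dimensionless flow fraction in [0, 1).
#' @return inflow series, m3/s, same length as `boundary_q`.
#' @export
#' @examples
#' tributary_inflow(c(10, 12), 0.079)
tributary_inflow <- function(boundary_q, fraction) {
  if (length(fraction) != 1L || is.na(fraction) || fraction < 0 || fraction >= 1)
    stop("fraction must be a single value in [0, 1)")
  fraction * boundary_q
}

#' Route steady flow down the reach with tributary accrual
#'
#' Discharge at a node is the boundary discharge plus all tributary inflows
#' entering at or upstream of that node; piecewise constant between
#' junctions (steady low-flow routing, no wave propagation).
#'
#' @param boundary_q boundary discharge series, m3/s (length = hours).
#' @param tributaries data.frame with columns `rkm` and `fraction` (may have
#'   zero rows).
#' @param reach node table with a decreasing `rkm` column.
#' @return matrix hours x nodes of discharge, m3/s.
#' @export
route_flow <- function(boundary_q, tributaries, reach) {
  rkm <- reach$rkm
  frac_at_node <- numeric(length(rkm))
  if (!is.null(tributaries) && nrow(tributaries)) {
    if (any(tributaries$fraction < 0)) stop("negative tributary fraction")
    if (any(tributaries$rkm > max(rkm) | tributaries$rkm < min(rkm)))
      stop("tributary outside the reach")
    for (i in seq_len(nrow(tributaries))) {
      node <- junction_node(tributaries$rkm[i], rkm)
      frac_at_node[node] <- frac_at_node[node] + tributaries$fraction[i]
    }
  }
  mult <- 1 + cumsum(frac_at_node)
  outer(boundary_q, mult)
}

# internal: index of the first node at or downstream of a tributary mouth
junction_node <- function(trib_rkm, node_rkm) {
  which(node_rkm <= trib_rkm + 1e-9)[1]
}

#' Depth and velocity from Manning's equation (rectangular channel)
#'
#' Solves `q = (1/n) (w d) R^(2/3) S^(1/2)` with hydraulic radius
#' `R = w d / (w + 2 d)` for depth `d`, by damped Newton iteration with a
#' bisection fallback (the conveyance is strictly increasing in depth).
#' Vectorised over all arguments.
#'
#' @param q discharge, m3/s (>= 0).
#' @param width bottom width, m (> 0). Side slope is zero (the wide, shallow
#'   study channel justifies a purely rectangular section).
#' @param slope energy slope (> 0), dimensionless.
#' @param n Manning roughness (default 0.035).
#' @param tol relative tolerance on the recovered discharge.
#' @return list with vectors `depth` (m) and `velocity` (m/s).
#' @export
#' @examples
#' manning_depth_velocity(16, 80, 0.001)
manning_depth_velocity <- function(q, width, slope, n = 0.035, tol = 1e-10) {
  len <- max(length(q), length(width), length(slope))
  q <- rep_len(q, len); w <- rep_len(width, len); s <- rep_len(slope, len)
  if (any(w <= 0)) stop("width must be positive")
  if (any(s <= 0)) stop("slope must be positive")
  if (any(q < 0)) stop("discharge must be non-negative")
  conv <- function(d) (1 / n) * (w * d) * ((w * d) / (w + 2 * d))^(2 / 3) *
    sqrt(s)
  # wide-channel initial guess: R ~ d
  d <- pmax((q * n / (w * sqrt(s)))^(3 / 5), 1e-6)
  lo <- rep(0, len); hi <- pmax(d * 8, 10)
  while (any(conv(hi) < q)) hi[conv(hi) < q] <- hi[conv(hi) < q] * 2
  for (iter in 1:100) {
    f <- conv(d) - q
    lo[f < 0] <- d[f < 0]; hi[f > 0] <- d[f > 0]
    eps <- pmax(d * 1e-7, 1e-12)
    df <- (conv(d + eps) - conv(d)) / eps
    step <- f / pmax(df, 1e-12)
    d_new <- d - step
    bad <- d_new <= lo | d_new >= hi | !is.finite(d_new)
    d_new[bad] <- (lo[bad] + hi[bad]) / 2
    d <- d_new
    if (all(abs(conv(d) - q) <= tol * pmax(q, 1e-12) + 1e-14)) break
  }
  resid <- abs(conv(d) - q) / pmax(q, 1e-12)
  if (any(resid > 1e-6 & q > 0))
    stop("Manning solve failed to converge: q=", q[which.max(resid)],
         " w=", w[which.max(resid)], " s=", s[which.max(resid)])
  d[q == 0] <- 0
  v <- ifelse(q > 0, q / (w * d), 0)
  list(depth = d, velocity = v)
}

#' Flow-weighted junction temperature mixing
#'
#' Complete-mix energy balance at a tributary junction:
#' `(q_m T_m + q_t T_t) / (q_m + q_t)`.
#'
#' @param main_q,main_t main-stem discharge (m3/s) and temperature (degC).
#' @param trib_q,trib_t tributary discharge and temperature.
#' @return mixed temperature, degC (vectorised).
#' @export
mix_temperature <- function(main_q, main_t, trib_q, trib_t) {
  if (any(main_q < 0 | trib_q < 0)) stop("flows must be non-negative")
  tot <- main_q + trib_q
  if (any(tot <= 0)) stop("zero total flow at junction")
  (main_q * main_t + trib_q * trib_t) / tot
}
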