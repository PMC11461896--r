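#' Stream energy dissipation rate
#'
#' Turbulent kinetic-energy dissipation per unit mass of a stream,
#' eD = g * S * v, from gravitational acceleration, channel slope and water
#' velocity. Drives the high-energy k600 scaling of steep channels.
#'
#' @param slope Dimensionless channel slope, > 0.
#' @param velocity Water velocity, m s-1, > 0.
#' @param gravity Gravitational acceleration, m s-2; must lie in
#'   \[9.7, 9.9\]. Default `ch4_constants$gravity` (9.8).
#'
#' @return eD in W kg-1.
#' @export
#' @examples
#' energy_dissipation(0.01, 4)  # 0.392 W kg-1
energy_dissipation <- function(slope, velocity,
                               gravity = ch4_constants$gravity) {
  if (slope <= 0) stop("slope must be positive")
  if (velocity <= 0) stop("velocity must be positive")
  if (gravity < 9.7 || gravity > 9.9)
    stop("gravity must lie in [9.7, 9.9] m s-2")
  gravity * slope * velocity
}

#' River k600 from energy dissipation
#'
#' High-energy-dissipation scaling ln(k600) = 6.43 + 1.18 ln(eD), appropriate
#' for steep turbulent channels such as glacial melt rivers.
#'
#' @param ed Energy dissipation rate, W kg-1, > 0.
#'
#' @return k600 in m d-1.
#' @export
#' @examples
#' k600_river(energy_dissipation(0.01, 4))  # 205.4 m d-1
k600_river <- function(ed) {
  if (any(ed <= 0)) stop("energy dissipation must be positive")
  p <- ch4_constants$k600_river
  exp(p$intercept + p$slope * log(ed))
}

#' Lake k600 from wind speed
#'
#' Bilinear wind-speed relationship for low-wind lakes: a constant
#' 1.0 cm h-1 below the 3.7 m s-1 breakpoint and 5.14 * u10 - 17.9 cm h-1
#' above it, converted to m d-1. Returns 0.27 m d-1 at u10 = 3.7 m s-1.
#'
#' @param u10 Wind speed 10 m above the lake surface, m s-1, >= 0;
#'   vectorized.
#'
#' @return k600 in m d-1, nondecreasing in u10.
#' @export
#' @examples
#' k600_lake_wind(3.7)  # 0.27 m d-1
k600_lake_wind <- function(u10) {
  if (any(u10 < 0)) stop("wind speed must be >= 0")
  p <- ch4_constants$k600_lake
  cm_h <- ifelse(u10 < p$breakpoint_ms, p$low_cm_h,
                 p$slope * u10 + p$intercept)
  cm_h * 24 / 100  # cm h-1 -> m d-1
}

#' Scale k600 to the in-situ gas transfer velocity kx
#'
#' Schmidt-number scaling k600 / kx = (600 / Scx)^n converts the normalized
#' transfer velocity to the velocity for CH4 at ambient temperature. The
#' exponent n = -1/2 applies to turbulent, wavy interfaces (rivers, windy
#' lakes); Scx = 600 returns k600 unchanged.
#'
#' @param k600 Normalized gas transfer velocity, m d-1, > 0.
#' @param schmidt_number Schmidt number of the gas at ambient temperature,
#'   > 0 (see [schmidt_number_ch4()]).
#' @param exponent Scaling exponent n, in \[-1, -1/3\]. Default -0.5.
#'
#' @return kx in m d-1.
#' @export
#' @examples
#' schmidt_scale(205.4, schmidt_number_ch4(1))  # ~118.8 m d-1
schmidt_scale <- function(k600, schmidt_number, exponent = -0.5) {
  if (any(k600 <= 0)) stop("k600 must be positive")
  if (any(schmidt_number <= 0)) stop("Schmidt number must be positive")
  if (exponent < -1 || exponent > -1/3)
    stop("exponent must lie in [-1, -1/3]")
  k600 / (600 / schmidt_number)^exponent
}

#' Full gas transfer estimate for a site
#'
#' Chains the k600 model (river hydraulics or lake wind) with the Schmidt
#' scaling to CH4 at the ambient water temperature.
#'
#' @param model `"river_energy_dissipation"` or `"lake_wind"`.
#' @param temperature_c Ambient water temperature, degrees Celsius.
#' @param slope,velocity,gravity River hydraulics (used by the river model).
#' @param u10 Wind speed at 10 m, m s-1 (used by the lake model).
#' @param exponent Schmidt-scaling exponent. Default -0.5.
#'
#' @return An object of class `gas_transfer_estimate`: list with `k600`,
#'   `kx` (both m d-1), `schmidt_number`, `exponent` and `model`.
#' @export
#' @examples
#' gas_transfer_estimate("river_energy_dissipation", 1,
#'                       slope = 0.01, velocity = 4)
#' gas_transfer_estimate("lake_wind", 1, u10 = 3.7)
gas_transfer_estimate <- function(model = c("river_energy_dissipation",
                                            "lake_wind"),
                                  temperature_c,
                                  slope = NULL, velocity = NULL,
                                  gravity = ch4_constants$gravity,
                                  u10 = NULL, exponent = -0.5) {
  model <- match.arg(model)
  k600 <- if (model == "river_energy_dissipation") {
    if (is.null(slope) || is.null(velocity))
      stop("river model requires slope and velocity")
    k600_river(energy_dissipation(slope, velocity, gravity))
  } else {
    if (is.null(u10)) stop("lake model requires u10")
    k600_lake_wind(u10)
  }
  sc <- schmidt_number_ch4(temperature_c)
  structure(list(k600 = k600, kx = schmidt_scale(k600, sc, exponent),
                 schmidt_number = sc, exponent = exponent, model = model),
            class = "gas_transfer_estimate")
}

#' @export
print.gas_transfer_estimate <- function(x, ...) {
  cat(sprintf(
    "Gas transfer (%s):\n  k600 = %.4g m d-1, Sc = %.1f, n = %g, kx = %.4g m d-1\n",
    x$model, x$k600, x$schmidt_number, x$exponent, x$kx))
  invisible(x)
}
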