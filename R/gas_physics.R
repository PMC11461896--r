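#' Ambient gas conditions at a sampling site
#'
#' Bundles the water temperature, total barometric pressure and atmospheric
#' CH4 mixing ratio that determine solubility and the air-equilibrium
#' concentration.
#'
#' @param temperature Water temperature, degrees Celsius. Must lie in
#'   \[-2, 40\].
#' @param pressure Total barometric pressure, atm. Must be positive.
#' @param atm_mixing_ratio Dry-air CH4 mole fraction, ppb. Defaults to
#'   `ch4_constants$default_atm_ch4_ppb`.
#'
#' @return An object of class `gas_conditions`.
#' @export
#' @examples
#' gas_conditions(1, 1)
gas_conditions <- function(temperature, pressure = 1,
                           atm_mixing_ratio = ch4_constants$default_atm_ch4_ppb) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.numeric(pressure), length(pressure) == 1L,
            is.numeric(atm_mixing_ratio), length(atm_mixing_ratio) == 1L)
  if (temperature < -2 || temperature > 40)
    stop("temperature must be within [-2, 40] degrees C, got ", temperature)
  if (pressure <= 0) stop("pressure must be positive, got ", pressure)
  if (atm_mixing_ratio < 0) stop("atm_mixing_ratio must be >= 0")
  structure(list(temperature = temperature, pressure = pressure,
                 atm_mixing_ratio = atm_mixing_ratio),
            class = "gas_conditions")
}

#' @export
print.gas_conditions <- function(x, ...) {
  cat(sprintf("Gas conditions: %.2f degC, %.3f atm, CH4 %.0f ppb\n",
              x$temperature, x$pressure, x$atm_mixing_ratio))
  invisible(x)
}

#' CH4 solubility in fresh water (Henry-law coefficient)
#'
#' Evaluates the Bunsen solubility coefficient of methane in fresh water
#' (salinity 0) from the fit tabulated in `ch4_constants$solubility` and
#' converts it to a molar Henry coefficient. The Bunsen coefficient is the
#' volume of gas at STP absorbed per volume of water at a partial pressure of
#' one atmosphere; division by the STP molar volume gives mol L-1 atm-1.
#'
#' @param conditions A [gas_conditions()] object, or a temperature in degrees
#'   Celsius (pressure does not enter the coefficient itself).
#'
#' @return Henry-law coefficient, mol L-1 atm-1. Strictly decreasing in
#'   temperature.
#' @export
#' @examples
#' ch4_solubility(gas_conditions(1, 1))   # cold meltwater
#' ch4_solubility(20)                     # laboratory equilibration
ch4_solubility <- function(conditions) {
  tc <- if (inherits(conditions, "gas_conditions")) conditions$temperature
        else conditions
  stopifnot(is.numeric(tc))
  rng <- ch4_constants$solubility$temp_range_c
  if (any(tc < rng[1] | tc > rng[2]))
    stop("temperature ", paste(tc[tc < rng[1] | tc > rng[2]], collapse = ", "),
         " degC outside solubility fit range [", rng[1], ", ", rng[2], "]")
  tk <- tc + 273.15
  s <- ch4_constants$solubility
  bunsen <- exp(s$a1 + s$a2 * (100 / tk) + s$a3 * log(tk / 100))
  bunsen / ch4_constants$molar_volume_stp
}

#' Atmospheric-equilibrium CH4 concentration
#'
#' Concentration of dissolved methane in surface water at equilibrium with
#' the atmosphere (Ceq): the Henry coefficient times the CH4 partial
#' pressure. Linear in both the mixing ratio and the total pressure.
#'
#' @param conditions A [gas_conditions()] object.
#'
#' @return Ceq in umol L-1 (uM).
#' @export
#' @examples
#' equilibrium_concentration(gas_conditions(1, 1, 1900))  # ~0.0047 uM
equilibrium_concentration <- function(conditions) {
  stopifnot(inherits(conditions, "gas_conditions"))
  kh <- ch4_solubility(conditions)                       # mol L-1 atm-1
  p_ch4 <- conditions$pressure * conditions$atm_mixing_ratio * 1e-9  # atm
  kh * p_ch4 * 1e6                                       # mol/L -> umol/L
}

#' Schmidt number of CH4 in fresh water
#'
#' Third-order polynomial in temperature from the coefficient set in
#' `ch4_constants$schmidt`. The Schmidt number (kinematic viscosity over gas
#' diffusivity) is the temperature- and gas-specific quantity through which
#' gas transfer velocities are normalized (Sc = 600 is CO2 at 20 degC).
#'
#' @param temperature Water temperature, degrees Celsius; vectorized.
#'
#' @return Dimensionless Schmidt number, positive and strictly decreasing in
#'   temperature.
#' @export
#' @examples
#' schmidt_number_ch4(1)    # cold glacial river, ~1787
#' schmidt_number_ch4(20)
schmidt_number_ch4 <- function(temperature) {
  stopifnot(is.numeric(temperature))
  rng <- ch4_constants$schmidt$temp_range_c
  if (any(temperature < rng[1] | temperature > rng[2]))
    stop("temperature outside Schmidt polynomial fit range [",
         rng[1], ", ", rng[2], "] degC")
  cf <- ch4_constants$schmidt$coef
  Reduce(function(acc, k) acc + cf[k] * temperature^(k - 1),
         seq_along(cf), accumulate = FALSE, init = 0)
}

#' Convert a dissolved CH4 concentration between units
#'
#' Exact conversions between the three concentration units used in this
#' package: `"uM"` (umol L-1, the internal canonical unit), `"ug_L"`
#' (ug L-1, via the molar mass of CH4) and `"mmol_m3"` (mmol m-3, numerically
#' equal to uM).
#'
#' @param value Numeric concentration(s), must be non-negative.
#' @param from,to Unit names, each one of `"uM"`, `"ug_L"`, `"mmol_m3"`.
#'
#' @return Converted concentration(s). Round trips are exact to machine
#'   precision.
#' @export
#' @examples
#' convert_concentration(8.6, "ug_L", "uM")   # 0.536 uM
#' convert_concentration(0.12, "uM", "ug_L")  # 1.9 ug
convert_concentration <- function(value, from, to) {
  stopifnot(is.numeric(value))
  if (any(value < 0)) stop("concentrations must be >= 0")
  units <- c("uM", "ug_L", "mmol_m3")
  if (!from %in% units) stop("unknown unit: ", from)
  if (!to %in% units) stop("unknown unit: ", to)
  # to canonical uM
  um <- switch(from,
    uM      = value,
    ug_L    = value / ch4_constants$molar_mass_ch4,
    mmol_m3 = value
  )
  switch(to,
    uM      = um,
    ug_L    = um * ch4_constants$molar_mass_ch4,
    mmol_m3 = um
  )
}
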