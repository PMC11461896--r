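#' Physical constants and published coefficient sets
#'
#' Read-only list of the physical constants and literature coefficient sets
#' used throughout the package, each with its provenance.
#'
#' @format A named list:
#' \describe{
#'   \item{molar_mass_ch4}{16.04 g mol-1.}
#'   \item{gas_constant_l_atm}{0.0820573 L atm mol-1 K-1 (ideal gas).}
#'   \item{molar_volume_stp}{22.414 L mol-1, converts Bunsen coefficients to
#'     molar Henry coefficients.}
#'   \item{default_atm_ch4_ppb}{1870 ppb, default dry-air CH4 mole fraction
#'     used for the atmospheric-equilibrium concentration when a site value
#'     is not supplied.}
#'   \item{gravity}{9.8 m s-2 default gravitational acceleration.}
#'   \item{solubility}{Wiesenburg & Guinasso (1979) Bunsen-coefficient fit
#'     for CH4 in fresh water (salinity 0): coefficients of
#'     ln(beta) = a1 + a2*(100/T) + a3*ln(T/100), T in kelvin, and the
#'     temperature range of the fit in degrees Celsius.}
#'   \item{schmidt}{Wanninkhof (1992) third-order polynomial in temperature
#'     (degrees C) for the Schmidt number of CH4 in fresh water, with its fit
#'     range.}
#'   \item{k600_river}{Ulseth et al. (2019) high-energy-dissipation scaling
#'     ln(k600 [m d-1]) = intercept + slope * ln(eD [W kg-1]).}
#'   \item{k600_lake}{Crusius & Wanninkhof (2003) bilinear wind relationship,
#'     k600 [cm h-1] = low below the wind breakpoint [m s-1], otherwise
#'     slope * u10 + intercept.}
#' }
#' @export
ch4_constants <- list(
  molar_mass_ch4      = 16.04,      # g mol-1
  gas_constant_l_atm  = 0.0820573,  # L atm mol-1 K-1
  molar_volume_stp    = 22.414,     # L mol-1 at STP
  default_atm_ch4_ppb = 1870,       # dry-air mole fraction, ppb
  gravity             = 9.8,        # m s-2
  solubility = list(
    citation = "Wiesenburg & Guinasso (1979), J. Chem. Eng. Data 24:356-360",
    a1 = -67.1962, a2 = 99.1624, a3 = 27.9015,
    temp_range_c = c(-2, 35)
  ),
  schmidt = list(
    citation = "Wanninkhof (1992), J. Geophys. Res. 97:7373-7382, fresh water CH4",
    coef = c(1897.8, -114.28, 3.2902, -0.039061),
    temp_range_c = c(-2, 40)
  ),
  k600_river = list(
    citation = "Ulseth et al. (2019), Nat. Geosci. 12:259-263, high-eD branch",
    intercept = 6.43, slope = 1.18
  ),
  k600_lake = list(
    citation = "Crusius & Wanninkhof (2003), Limnol. Oceanogr. 48:1010-1017, Eq. 6 (bilinear)",
    low_cm_h = 1.0, breakpoint_ms = 3.7, slope = 5.14, intercept = -17.9
  )
)
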