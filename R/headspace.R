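#' Headspace equilibration vial
#'
#' Describes one water sample after introduction of an ultra-pure helium
#' headspace: 70 mL serum vials with a 20 mL headspace leave 50 mL of water,
#' which equilibrates with the headspace for 24 h before the gas phase is
#' sampled for gas chromatography.
#'
#' @param water_volume_ml Water remaining after headspace introduction, mL.
#' @param headspace_volume_ml Helium headspace volume, mL.
#' @param equil_temp_c Temperature during equilibration, degrees Celsius.
#' @param pressure_atm Total pressure in the headspace during equilibration,
#'   atm.
#' @param ch4_ppm CH4 mole fraction measured in the headspace after
#'   equilibration, ppm.
#' @param nominal_vial_ml Nominal vial volume; water + headspace must agree
#'   with it within 1 mL. Default 70.
#'
#' @return An object of class `headspace_vial`.
#' @export
#' @examples
#' headspace_vial(50, 20, 20, 1, 12.5)
headspace_vial <- function(water_volume_ml, headspace_volume_ml,
                           equil_temp_c, pressure_atm, ch4_ppm,
                           nominal_vial_ml = 70) {
  stopifnot(is.numeric(water_volume_ml), is.numeric(headspace_volume_ml),
            is.numeric(equil_temp_c), is.numeric(pressure_atm),
            is.numeric(ch4_ppm))
  if (water_volume_ml <= 0) stop("water_volume_ml must be positive")
  if (headspace_volume_ml <= 0) stop("headspace_volume_ml must be positive")
  if (abs(water_volume_ml + headspace_volume_ml - nominal_vial_ml) > 1)
    stop("water + headspace volume (",
         water_volume_ml + headspace_volume_ml,
         " mL) differs from the nominal vial volume (", nominal_vial_ml,
         " mL) by more than 1 mL")
  if (ch4_ppm < 0) stop("ch4_ppm must be >= 0")
  if (pressure_atm <= 0) stop("pressure_atm must be positive")
  structure(list(water_volume_ml = water_volume_ml,
                 headspace_volume_ml = headspace_volume_ml,
                 equil_temp_c = equil_temp_c,
                 pressure_atm = pressure_atm,
                 ch4_ppm = ch4_ppm),
            class = "headspace_vial")
}

# Moles of CH4 per ppm of headspace mole fraction, split into the gas and
# aqueous reservoirs at the equilibration temperature. Shared by the inverse
# (measurement -> concentration) and forward (truth -> measurement) paths.
.headspace_moles_per_ppm <- function(vial) {
  tk <- vial$equil_temp_c + 273.15
  vh <- vial$headspace_volume_ml / 1000   # L
  vw <- vial$water_volume_ml / 1000       # L
  kh <- ch4_solubility(vial$equil_temp_c) # mol L-1 atm-1
  p_per_ppm <- vial$pressure_atm * 1e-6   # atm of CH4 per ppm
  n_gas <- p_per_ppm * vh / (ch4_constants$gas_constant_l_atm * tk)
  n_aq <- kh * p_per_ppm * vw
  list(gas = n_gas, aqueous = n_aq)
}

#' Dissolved CH4 concentration of the original water sample
#'
#' Inverts the headspace equilibration by mass balance: the measured
#' headspace mole fraction fixes the CH4 partial pressure, the ideal-gas law
#' gives the moles in the headspace, Henry's law gives the moles still
#' dissolved, and their sum divided by the water volume is the concentration
#' the sample had before the helium headspace was introduced (the headspace
#' is initially CH4-free).
#'
#' @param vial A [headspace_vial()] object.
#'
#' @return Original dissolved concentration, umol L-1 (uM).
#' @export
#' @examples
#' v <- headspace_vial(50, 20, 20, 1, ch4_ppm = 12.5)
#' dissolved_concentration(v)
dissolved_concentration <- function(vial) {
  stopifnot(inherits(vial, "headspace_vial"))
  n <- .headspace_moles_per_ppm(vial)
  n_total <- (n$gas + n$aqueous) * vial$ch4_ppm        # mol
  conc <- n_total / (vial$water_volume_ml / 1000) * 1e6  # uM
  if (conc < 0) stop("nonphysical negative concentration")
  conc
}

#' Forward-partition a known concentration into a headspace measurement
#'
#' The closed-form forward model of the headspace equilibration: given the
#' true dissolved concentration of the original water sample, returns the
#' CH4 mole fraction (ppm) the gas chromatograph would read in the headspace
#' after full equilibration. Inverse of [dissolved_concentration()]; used by
#' the synthetic-data generator and for round-trip validation.
#'
#' @param true_concentration_um True original concentration, uM.
#' @param vial A [headspace_vial()] object supplying geometry, equilibration
#'   temperature and pressure (its `ch4_ppm` is ignored).
#'
#' @return Headspace mole fraction, ppm.
#' @export
headspace_mole_fraction <- function(true_concentration_um, vial) {
  stopifnot(inherits(vial, "headspace_vial"),
            is.numeric(true_concentration_um))
  if (any(true_concentration_um < 0)) stop("concentration must be >= 0")
  n <- .headspace_moles_per_ppm(vial)
  n_total <- true_concentration_um * 1e-6 * (vial$water_volume_ml / 1000)
  n_total / (n$gas + n$aqueous)
}

#' Read a table of headspace vial measurements
#'
#' Reads a CSV with columns `site_id, replicate, water_volume_ml,
#' headspace_volume_ml, equil_temp_c, pressure_atm, ch4_ppm` and computes the
#' original dissolved concentration for every row.
#'
#' @param path CSV file path.
#'
#' @return A data.frame with the input columns plus `ch4_um` and `ch4_ug_l`.
#' @export
read_headspace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("site_id", "replicate", "water_volume_ml",
              "headspace_volume_ml", "equil_temp_c", "pressure_atm",
              "ch4_ppm")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("headspace CSV is missing columns: ", paste(missing, collapse = ", "))
  df$ch4_um <- vapply(seq_len(nrow(df)), function(i) {
    v <- headspace_vial(df$water_volume_ml[i], df$headspace_volume_ml[i],
                        df$equil_temp_c[i], df$pressure_atm[i],
                        df$ch4_ppm[i])
    dissolved_concentration(v)
  }, numeric(1))
  df$ch4_ug_l <- convert_concentration(df$ch4_um, "uM", "ug_L")
  df
}
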