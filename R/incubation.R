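#' Sediment-water incubation assay
#'
#' One bottle experiment measuring the net balance of microbial methane
#' production and oxidation at the sediment-water interface: replicate
#' bottles sacrificed at time zero give the initial concentration, replicate
#' bottles incubated in situ give the final concentration.
#'
#' @param site_id Site label.
#' @param initial_um,final_um Replicate dissolved CH4 concentrations, uM.
#' @param duration_h Incubation duration, hours.
#' @param water_volume_l Overlying water volume per bottle, L (default 0.070).
#' @param sediment_volume_ml Sediment slurry volume per bottle, mL (default 5).
#' @param bulk_density_g_ml Sediment bulk density, g mL-1; must lie in
#'   (0.1, 3).
#' @param bottle_diameter_mm Inner diameter of the bottle, mm (default 41);
#'   its circular cross-section is the sediment surface area.
#'
#' @return An object of class `incubation_assay`.
#' @export
#' @examples
#' incubation_assay("river", c(3, 3, 3), c(0.4, 0.4, 0.4), duration_h = 21)
incubation_assay <- function(site_id, initial_um, final_um, duration_h,
                             water_volume_l = 0.070, sediment_volume_ml = 5,
                             bulk_density_g_ml = 0.96,
                             bottle_diameter_mm = 41) {
  if (!length(initial_um) || !length(final_um))
    stop("replicate concentration lists must be nonempty")
  if (any(initial_um < 0) || any(final_um < 0))
    stop("concentrations must be >= 0")
  if (duration_h <= 0) stop("duration_h must be positive")
  if (water_volume_l <= 0) stop("water_volume_l must be positive")
  if (sediment_volume_ml <= 0) stop("sediment_volume_ml must be positive")
  if (bulk_density_g_ml <= 0.1 || bulk_density_g_ml >= 3)
    stop("bulk_density_g_ml must lie in (0.1, 3)")
  if (bottle_diameter_mm <= 0) stop("bottle_diameter_mm must be positive")
  structure(list(site_id = site_id, initial_um = initial_um,
                 final_um = final_um, duration_h = duration_h,
                 water_volume_l = water_volume_l,
                 sediment_volume_ml = sediment_volume_ml,
                 bulk_density_g_ml = bulk_density_g_ml,
                 bottle_diameter_mm = bottle_diameter_mm),
            class = "incubation_assay")
}

#' Net volumetric methane rate from an incubation
#'
#' The difference between the mean final and mean initial concentration,
#' normalized to one day. Negative values are net oxidation (consumption
#' exceeded production over the incubation), positive values net production.
#'
#' @param assay An [incubation_assay()] object.
#'
#' @return Signed rate, umol L-1 d-1.
#' @export
#' @examples
#' a <- incubation_assay("river", c(3, 3, 3), c(0.4, 0.4, 0.4), 21)
#' net_volumetric_rate(a)  # -2.97: net oxidation
net_volumetric_rate <- function(assay) {
  stopifnot(inherits(assay, "incubation_assay"))
  (mean(assay$final_um) - mean(assay$initial_um)) / (assay$duration_h / 24)
}

#' Sediment surface area of an incubation bottle
#'
#' Circular cross-section pi * (d/2)^2 of the bottle's inner diameter.
#'
#' @param bottle_inner_diameter_mm Inner diameter, mm.
#'
#' @return Area in mm^2 (41 mm gives 1320 mm^2 to 4 significant digits).
#' @export
sediment_surface_area <- function(bottle_inner_diameter_mm) {
  if (any(bottle_inner_diameter_mm <= 0))
    stop("bottle diameter must be positive")
  pi * (bottle_inner_diameter_mm / 2)^2
}

#' Convert a volumetric rate to an areal rate
#'
#' Scales a per-liter-of-water rate to a per-square-meter-of-sediment rate
#' using the water volume and sediment surface area of the bottle. Sign is
#' preserved.
#'
#' @param rate_um_l_d Volumetric rate, umol L-1 d-1 (signed).
#' @param water_volume_l Water volume, L.
#' @param sediment_area_m2 Sediment surface area, m^2.
#'
#' @return Areal rate, umol m-2 d-1.
#' @export
volumetric_to_areal <- function(rate_um_l_d, water_volume_l,
                                sediment_area_m2) {
  if (water_volume_l <= 0) stop("water_volume_l must be positive")
  if (sediment_area_m2 <= 0) stop("sediment_area_m2 must be positive")
  rate_um_l_d * water_volume_l / sediment_area_m2
}

#' Convert a volumetric rate to a sediment-mass-specific rate
#'
#' Scales a per-liter-of-water rate to a per-gram-of-sediment rate using the
#' sediment volume and bulk density.
#'
#' @param rate_um_l_d Volumetric rate, umol L-1 d-1 (signed).
#' @param water_volume_l Water volume, L.
#' @param sediment_volume_ml Sediment volume, mL.
#' @param bulk_density_g_ml Sediment bulk density, g mL-1.
#'
#' @return Mass-specific rate, umol g-1 d-1.
#' @export
volumetric_to_mass_specific <- function(rate_um_l_d, water_volume_l,
                                        sediment_volume_ml,
                                        bulk_density_g_ml) {
  if (sediment_volume_ml <= 0 || bulk_density_g_ml <= 0)
    stop("sediment mass must be positive")
  rate_um_l_d * water_volume_l / (sediment_volume_ml * bulk_density_g_ml)
}

#' Full net-rate estimate for an incubation assay
#'
#' Computes the net rate in all three expressions used for reporting —
#' volumetric, areal and sediment-mass-specific — plus the direction of the
#' net balance. All three share the sign of the volumetric rate.
#'
#' @param assay An [incubation_assay()] object.
#' @param balanced_tol Absolute volumetric rate (umol L-1 d-1) below which
#'   the assay is called `"balanced"`. Default 1e-12.
#'
#' @return An object of class `net_rate`: a list with `volumetric`, `areal`,
#'   `mass_specific` (all signed), `direction` (one of `"net_production"`,
#'   `"net_oxidation"`, `"balanced"`) and `site_id`.
#' @export
#' @examples
#' a <- incubation_assay("river", c(3, 3, 3), c(0.4, 0.4, 0.4), 21)
#' net_rate(a)
net_rate <- function(assay, balanced_tol = 1e-12) {
  vol <- net_volumetric_rate(assay)
  area_m2 <- sediment_surface_area(assay$bottle_diameter_mm) * 1e-6
  structure(list(
    site_id = assay$site_id,
    volumetric = vol,
    areal = volumetric_to_areal(vol, assay$water_volume_l, area_m2),
    mass_specific = volumetric_to_mass_specific(
      vol, assay$water_volume_l, assay$sediment_volume_ml,
      assay$bulk_density_g_ml),
    direction = if (abs(vol) <= balanced_tol) "balanced"
                else if (vol > 0) "net_production" else "net_oxidation"
  ), class = "net_rate")
}

#' @export
print.net_rate <- function(x, ...) {
  cat(sprintf(
    "Net CH4 rate at %s (%s):\n  %10.3g umol L-1 d-1\n  %10.3g umol m-2 d-1\n  %10.3g umol g-1 d-1\n",
    x$site_id, gsub("_", " ", x$direction),
    x$volumetric, x$areal, x$mass_specific))
  invisible(x)
}

#' Read a table of incubation measurements
#'
#' Reads a long-format CSV with columns `site_id, phase, replicate, ch4_um,
#' duration_h, water_volume_ml, sediment_volume_ml, bulk_density_g_ml,
#' bottle_diameter_mm` (phase is `"initial"` or `"final"`) and assembles one
#' [incubation_assay()] per site.
#'
#' @param path CSV file path.
#'
#' @return A named list of `incubation_assay` objects, one per site.
#' @export
read_incubation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("site_id", "phase", "replicate", "ch4_um", "duration_h",
              "water_volume_ml", "sediment_volume_ml", "bulk_density_g_ml",
              "bottle_diameter_mm")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("incubation CSV is missing columns: ",
         paste(missing, collapse = ", "))
  if (!all(df$phase %in% c("initial", "final")))
    stop("phase must be 'initial' or 'final'")
  sites <- unique(df$site_id)
  assays <- lapply(sites, function(s) {
    d <- df[df$site_id == s, ]
    meta <- d[1, ]
    incubation_assay(
      site_id = s,
      initial_um = d$ch4_um[d$phase == "initial"],
      final_um = d$ch4_um[d$phase == "final"],
      duration_h = meta$duration_h,
      water_volume_l = meta$water_volume_ml / 1000,
      sediment_volume_ml = meta$sediment_volume_ml,
      bulk_density_g_ml = meta$bulk_density_g_ml,
      bottle_diameter_mm = meta$bottle_diameter_mm
    )
  })
  names(assays) <- sites
  assays
}
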