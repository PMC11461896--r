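#' Glacier methane source
#'
#' A glacier's annual CH4 export and surface area, the inputs of per-area
#' normalization and global extrapolation.
#'
#' @param name Glacier label.
#' @param annual_flux_mg_yr Annual CH4 flux, Mg yr-1, >= 0.
#' @param area_km2 Glacier surface area, km^2, > 0.
#'
#' @return An object of class `glacier_source`.
#' @export
#' @examples
#' glacier_source("Leverett", 6.3, 20)
glacier_source <- function(name, annual_flux_mg_yr, area_km2) {
  if (annual_flux_mg_yr < 0) stop("annual flux must be >= 0")
  if (area_km2 <= 0) stop("area must be positive")
  structure(list(name = name, annual_flux_mg_yr = annual_flux_mg_yr,
                 area_km2 = area_km2),
            class = "glacier_source")
}

#' Per-area methane flux of a glacier
#'
#' Annual flux divided by glacier surface area.
#'
#' @param glacier A [glacier_source()] object.
#'
#' @return Flux density, Mg CH4 km-2 yr-1.
#' @export
#' @examples
#' per_area_flux(glacier_source("Leverett", 6.3, 20))  # 0.315
per_area_flux <- function(glacier) {
  stopifnot(inherits(glacier, "glacier_source"))
  glacier$annual_flux_mg_yr / glacier$area_km2
}

#' Extrapolate a per-area flux to global glacier coverage
#'
#' Multiplies a per-area flux density by the global glacierized area and
#' converts Mg to Tg.
#'
#' @param per_area_mg_km2_yr Flux density, Mg km-2 yr-1, > 0.
#' @param global_area_km2 Global glacier coverage, km^2, > 0; default
#'   680000.
#'
#' @return Global flux, Tg CH4 yr-1.
#' @export
#' @examples
#' global_upscale(0.315)  # 0.21 Tg yr-1
global_upscale <- function(per_area_mg_km2_yr, global_area_km2 = 680000) {
  if (any(per_area_mg_km2_yr <= 0)) stop("per-area flux must be positive")
  if (global_area_km2 <= 0) stop("global area must be positive")
  per_area_mg_km2_yr * global_area_km2 * 1e-6
}

#' Per-area and global upscaling table for a set of glaciers
#'
#' Normalizes each glacier's annual flux by its area and extrapolates each
#' flux density to global glacier coverage.
#'
#' @param glaciers A data.frame with columns `name`, `annual_flux_mg_yr`,
#'   `area_km2` (the CSV layout), or a list of [glacier_source()] objects.
#' @param global_area_km2 Global glacier coverage, km^2; default 680000.
#'
#' @return A data.frame with `name`, `annual_flux_mg_yr`, `area_km2`,
#'   `per_area_mg_km2_yr` and `global_tg_yr`.
#' @export
#' @examples
#' upscale_table(data.frame(
#'   name = c("Leverett", "Svalbard", "Solheimajokull"),
#'   annual_flux_mg_yr = c(6.3, 2310, 2460),
#'   area_km2 = c(20, 6268, 9)))
upscale_table <- function(glaciers, global_area_km2 = 680000) {
  if (is.data.frame(glaciers)) {
    glaciers <- lapply(seq_len(nrow(glaciers)), function(i)
      glacier_source(glaciers$name[i], glaciers$annual_flux_mg_yr[i],
                     glaciers$area_km2[i]))
  }
  per_area <- vapply(glaciers, per_area_flux, numeric(1))
  data.frame(
    name = vapply(glaciers, `[[`, character(1), "name"),
    annual_flux_mg_yr = vapply(glaciers, `[[`, numeric(1),
                               "annual_flux_mg_yr"),
    area_km2 = vapply(glaciers, `[[`, numeric(1), "area_km2"),
    per_area_mg_km2_yr = per_area,
    global_tg_yr = global_upscale(per_area, global_area_km2)
  )
}
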