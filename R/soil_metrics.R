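# Soil-water and resource-efficiency metrics.

#' Water-filled pore space
#'
#' `WFPS = theta / (1 - rho_b / rho_p) * 100 / 100` expressed in percent:
#' the volumetric moisture content divided by total porosity. With theta
#' already in percent the result is in percent directly.
#'
#' @param theta_v Volumetric soil moisture in percent (cutting-ring method).
#' @param rho_b Bulk density, g cm-3.
#' @param rho_p Particle density, g cm-3 (mineral-soil default 2.65).
#' @return WFPS in percent.
#' @examples
#' wfps(22.4, 1.48)  # 50.73 %
#' @export
wfps <- function(theta_v, rho_b, rho_p = 2.65) {
  if (any(rho_b <= 0) || any(rho_b >= rho_p)) {
    stop("porosity error: need 0 < rho_b < rho_p", call. = FALSE)
  }
  if (any(theta_v < 0)) stop("theta_v must be >= 0", call. = FALSE)
  theta_v / (1 - rho_b / rho_p)
}

#' Gravimetric to volumetric soil moisture
#'
#' `theta_v = theta_g * rho_b` (water density 1 g cm-3); both moistures in
#' percent. Field capacity is commonly reported gravimetrically while the
#' WFPS formula takes the volumetric value.
#'
#' @param theta_g Gravimetric moisture, percent.
#' @param rho_b Bulk density, g cm-3.
#' @return Volumetric moisture, percent.
#' @export
gravimetric_to_volumetric <- function(theta_g, rho_b) {
  theta_g * rho_b
}

#' Irrigation water productivity
#'
#' Hay yield per cubic metre of irrigation water: `IWP = Y / I` with I in
#' m3 ha-1 (1 mm over one hectare = 10 m3). Undefined for unirrigated
#' treatments; returns `NA` there (rendered as an em dash in reports).
#'
#' @param yield_kg_ha Hay yield, kg ha-1.
#' @param irrigation_mm Irrigation depth, mm.
#' @return IWP in kg m-3, `NA` where irrigation is zero.
#' @export
iwp <- function(yield_kg_ha, irrigation_mm) {
  out <- yield_kg_ha / (10 * irrigation_mm)
  out[irrigation_mm <= 0] <- NA_real_
  out
}

#' Partial factor productivity of nitrogen
#'
#' Hay yield per kilogram of fertiliser N: `PFPN = Y / N`. Undefined for
#' unfertilised treatments; returns `NA` there.
#'
#' @param yield_kg_ha Hay yield, kg ha-1.
#' @param n_rate Nitrogen rate, kg N ha-1.
#' @return PFPN in kg kg-1, `NA` where the nitrogen rate is zero.
#' @export
pfpn <- function(yield_kg_ha, n_rate) {
  out <- yield_kg_ha / n_rate
  out[n_rate <= 0] <- NA_real_
  out
}
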