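# Per-gas physical constants and unit bookkeeping.
#
# Flux units follow chamber convention: ug m-2 h-1 for N2O and CH4,
# mg m-2 h-1 for CO2. Cumulative emissions are element-mass areal totals
# (kg N ha-1 for N2O, kg C ha-1 for CO2 and CH4); the unit factor K maps
# (flux unit x hours) to kg ha-1: 1 ug m-2 = 1e-5 kg ha-1, 1 mg m-2 =
# 1e-2 kg ha-1.

.gas_table <- tibble::tibble(
  gas             = c("N2O", "CO2", "CH4"),
  molar_mass_gas  = c(44, 44, 16),          # g mol-1 of the gas molecule
  molar_mass_elem = c(28, 12, 12),          # g mol-1 of N2 / C per molecule
  unit_factor_K   = c(1e-5, 1e-2, 1e-5),
  flux_unit       = c("ug m-2 h-1", "mg m-2 h-1", "ug m-2 h-1"),
  dcdt_unit       = c("nL L-1 min-1", "uL L-1 min-1", "nL L-1 min-1"),
  cumulative_unit = c("kg N ha-1", "kg C ha-1", "kg C ha-1"),
  standard_c0     = c(350, 500, 2),         # certified standard-gas concentration
  standard_unit   = c("uL m-3", "mL m-3", "uL m-3"),
  ambient         = c(332, 420, 1900),      # typical ambient, in dC/dt conc units
  gwp100          = c(265, NA_real_, 28)    # 100-yr CO2-eq weight (CO2 excluded)
)

#' Supported greenhouse gases
#'
#' @return Character vector of gas names understood by the package.
#' @export
gases <- function() .gas_table$gas

#' Physical constants and unit conventions for one gas
#'
#' Returns the molar masses (gas-molecule and element basis), the unit
#' conversion factor `unit_factor_K` used in cumulative integration, the
#' flux / concentration-slope / cumulative units, the certified standard-gas
#' concentration, a typical ambient concentration, and the 100-year global
#' warming potential weight (undefined for CO2, which is excluded from the
#' soil GWP term).
#'
#' @param gas One of `"N2O"`, `"CO2"`, `"CH4"`.
#' @return A one-row list of gas properties.
#' @examples
#' gas_info("N2O")$unit_factor_K  # 1e-5
#' @export
gas_info <- function(gas) {
  gas <- match_gas(gas)
  as.list(.gas_table[.gas_table$gas == gas, ])
}

#' Molar mass of a gas on a chosen basis
#'
#' @param gas Gas name.
#' @param basis `"gas"` for the whole molecule (44, 44, 16 g mol-1 for N2O,
#'   CO2, CH4) or `"element"` for the N or C it carries (28, 12, 12).
#' @return Molar mass in g mol-1.
#' @export
molar_mass <- function(gas, basis = c("gas", "element")) {
  basis <- match.arg(basis)
  info <- gas_info(gas)
  if (basis == "gas") info$molar_mass_gas else info$molar_mass_elem
}

# ratio converting a gas-mass quantity to element mass (e.g. 28/44 for N2O)
element_gas_ratio <- function(gas) {
  info <- gas_info(gas)
  info$molar_mass_elem / info$molar_mass_gas
}

match_gas <- function(gas) {
  gas <- toupper(as.character(gas))
  if (length(gas) != 1L || !gas %in% .gas_table$gas) {
    stop("unknown gas: ", paste(gas, collapse = ", "),
         " (expected one of ", paste(.gas_table$gas, collapse = ", "), ")",
         call. = FALSE)
  }
  gas
}

#' Certified standard gas used for peak-area calibration
#'
#' @param gas Gas name.
#' @param peak_area_a0 Peak area measured for the standard (must be > 0).
#' @param c0 Certified concentration; defaults to the per-gas certified
#'   standard (N2O 350 uL m-3, CO2 500 mL m-3, CH4 2 uL m-3).
#' @return A list with `gas`, `c0` and `a0`, used by
#'   [peak_area_to_concentration()].
#' @export
standard_gas <- function(gas, peak_area_a0, c0 = NULL) {
  gas <- match_gas(gas)
  if (is.null(c0)) c0 <- gas_info(gas)$standard_c0
  stopifnot(is.numeric(c0), length(c0) == 1L)
  if (!is.numeric(peak_area_a0) || length(peak_area_a0) != 1L ||
      !is.finite(peak_area_a0) || peak_area_a0 <= 0) {
    stop("invalid standard: peak_area_a0 must be a positive number",
         call. = FALSE)
  }
  if (c0 <= 0) stop("invalid standard: c0 must be > 0", call. = FALSE)
  list(gas = gas, c0 = c0, a0 = peak_area_a0)
}
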