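# Climate metrics: N2O emission factor, life-cycle GWP, GHGI, contrasts.

#' Fertiliser-induced N2O emission factor
#'
#' Fraction of applied fertiliser N emitted as N2O-N relative to the
#' unfertilised control at the same irrigation level:
#' `EF = (GF_F - GF_N) / N_F * 100`.
#'
#' @param gf_fertilized Cumulative N2O emission of the fertilised
#'   treatment, kg N ha-1.
#' @param gf_control Cumulative N2O emission of the matched N0 control,
#'   kg N ha-1.
#' @param n_rate Nitrogen rate, kg N ha-1.
#' @return EF in percent; `NA` where the nitrogen rate is zero (EF is
#'   undefined for unfertilised treatments).
#' @export
emission_factor <- function(gf_fertilized, gf_control, n_rate) {
  out <- (gf_fertilized - gf_control) / n_rate * 100
  out[n_rate <= 0] <- NA_real_
  out
}

#' Input-chain global warming potential
#'
#' `GWP_inputs = sum_i Amount_i * EF_i` over the agricultural inputs
#' (fertiliser N, P2O5, K2O, irrigation electricity, diesel). Amounts and
#' factors are matched by name; an amount without a factor is a
#' configuration error.
#'
#' @param amounts Named numeric vector of input amounts (kg ha-1, mm, or a
#'   per-ha flag for diesel).
#' @param factors Named numeric vector of CO2-eq emission factors
#'   (default [default_emission_factors()]).
#' @return GWP of inputs, kg CO2-eq ha-1.
#' @examples
#' gwp_inputs(c(n_fertilizer = 180, p2o5 = 75, k2o = 90,
#'              irrigation_mm = 300, diesel_ha = 1))  # 2456.15
#' @export
gwp_inputs <- function(amounts, factors = default_emission_factors()) {
  miss <- setdiff(names(amounts), names(factors))
  if (length(miss)) {
    stop("no emission factor configured for inventory item(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(factors < 0)) stop("emission factors must be >= 0", call. = FALSE)
  sum(amounts * factors[names(amounts)])
}

#' Soil (direct non-CO2 flux) global warming potential
#'
#' `GWP_soil = 265 * GF_N2O + 28 * GF_CH4` over a 100-year horizon. CH4 may
#' be negative (soil sink). Chamber-measured soil CO2 is deliberately
#' excluded: a dark chamber sees only ecosystem respiration, not the
#' photosynthetic uptake that balances it, so including it would distort
#' the net balance — passing a CO2 total is an error.
#'
#' The cumulative totals arrive on the element-mass basis (kg N ha-1,
#' kg C ha-1). The default applies the warming-potential weights to those
#' totals literally; `basis = "gas"` first converts them to gas mass
#' (x44/28 for N2O, x16/12 for CH4).
#'
#' @param gf_n2o Cumulative N2O, kg N ha-1.
#' @param gf_ch4 Cumulative CH4, kg C ha-1 (negative = net uptake).
#' @param gf_co2 Must stay `NULL`; supplied CO2 is rejected.
#' @param basis `"element"` (default) or `"gas"`.
#' @return GWP_soil, kg CO2-eq ha-1.
#' @export
gwp_soil <- function(gf_n2o, gf_ch4, gf_co2 = NULL,
                     basis = c("element", "gas")) {
  basis <- match.arg(basis)
  if (!is.null(gf_co2)) {
    stop("chamber-measured soil CO2 is excluded from GWP: a dark chamber ",
         "captures ecosystem respiration without photosynthetic uptake",
         call. = FALSE)
  }
  if (basis == "gas") {
    gf_n2o <- gf_n2o / element_gas_ratio("N2O")  # x 44/28
    gf_ch4 <- gf_ch4 / element_gas_ratio("CH4")  # x 16/12
  }
  gas_info("N2O")$gwp100 * gf_n2o + gas_info("CH4")$gwp100 * gf_ch4
}

#' Total life-cycle global warming potential
#'
#' `GWP = GWP_soil + GWP_inputs` for one treatment and interval.
#'
#' @param soil GWP of direct soil fluxes, kg CO2-eq ha-1.
#' @param inputs GWP of the input chain, kg CO2-eq ha-1.
#' @return Total GWP, kg CO2-eq ha-1.
#' @export
gwp_total <- function(soil, inputs) soil + inputs

#' Greenhouse-gas emission intensity
#'
#' Yield-scaled GWP: `GHGI = GWP / Y` with yield in t ha-1, i.e. GWP per
#' tonne of hay.
#'
#' @param gwp Total GWP, kg CO2-eq ha-1.
#' @param yield_kg_ha Hay yield, kg ha-1.
#' @return GHGI in kg CO2-eq t-1; `NA` where yield is zero.
#' @export
ghgi <- function(gwp, yield_kg_ha) {
  out <- gwp / (yield_kg_ha / 1000)
  out[yield_kg_ha <= 0] <- NA_real_
  out
}

#' Relative change of a metric against a reference treatment
#'
#' Reductions are `(ref - x) / ref * 100` (positive when the candidate is
#' lower than the reference), improvements `(x - ref) / ref * 100`
#' (positive when higher).
#'
#' @param x Candidate metric value(s).
#' @param reference Reference value (e.g. the conventional high-input
#'   regime).
#' @param type `"reduction"` or `"improvement"`.
#' @return Percent change relative to the reference; `NA` when the
#'   reference is zero or undefined.
#' @examples
#' contrast(2823.20, 3721.54)  # 24.1 % reduction
#' @export
contrast <- function(x, reference, type = c("reduction", "improvement")) {
  type <- match.arg(type)
  out <- if (type == "reduction") (reference - x) / reference * 100
         else (x - reference) / reference * 100
  out[!is.finite(out)] <- NA_real_
  if (length(reference) == 1L && (is.na(reference) || reference == 0)) {
    out[] <- NA_real_
  }
  out
}

#' Allocate seasonal input GWP to harvest cycles
#'
#' Inputs tied to the calendar (fertiliser N and irrigation water) are
#' allocated to the harvest cycle in which they are applied; season-wide
#' inputs (P2O5, K2O, diesel) are split in proportion to the cycle length.
#' The allocation sums exactly to the annual input GWP whatever the split.
#'
#' @param inventory_row One-row inventory tibble for a treatment.
#' @param design_row Matching design row (per-harvest irrigation columns).
#' @param n_split Fraction of the seasonal N rate charged to each harvest
#'   cycle; the default follows a 40 % basal / 30 % / 30 % topdressing
#'   programme with no application in the third cycle: c(0.7, 0.3, 0).
#' @param cycle_weights Relative lengths of the harvest cycles for the
#'   season-wide items (default equal).
#' @param factors Emission factors.
#' @return Numeric vector of per-harvest input GWP, kg CO2-eq ha-1.
#' @export
allocate_inputs_by_harvest <- function(inventory_row, design_row,
                                       n_split = c(0.7, 0.3, 0),
                                       cycle_weights = c(1, 1, 1) / 3,
                                       factors = default_emission_factors()) {
  stopifnot(abs(sum(n_split) - 1) < 1e-9, abs(sum(cycle_weights) - 1) < 1e-9)
  irr <- c(design_row$irr_h1, design_row$irr_h2, design_row$irr_h3)
  vapply(1:3, function(h) {
    gwp_inputs(c(
      n_fertilizer  = inventory_row$n_fertilizer * n_split[h],
      p2o5          = inventory_row$p2o5 * cycle_weights[h],
      k2o           = inventory_row$k2o * cycle_weights[h],
      irrigation_mm = irr[h],
      diesel_ha     = inventory_row$diesel_ha * cycle_weights[h]
    ), factors)
  }, numeric(1))
}
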