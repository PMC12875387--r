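# Static-chamber flux estimation.
#
# A closed opaque chamber accumulates gas; the areal flux is recovered from
# the linear rise of headspace concentration over the deployment,
#
#   F = (M / 22.4) * (273 / (273 + Ta)) * 60 * H * dC/dt
#
# with M the molar mass (g mol-1), 22.4 L mol-1 the molar volume at STP
# (ideal gas, 1 atm), Ta the chamber air temperature (degC), H the chamber
# height (m) and dC/dt the concentration slope in uL L-1 min-1 (CO2) or
# nL L-1 min-1 (N2O, CH4). The factor 60 converts per-minute slopes to
# per-hour fluxes; the volumetric mixing-ratio slope times M/22.4 gives a
# mass concentration, so F lands in mg m-2 h-1 for CO2 and ug m-2 h-1 for
# N2O and CH4.

#' Convert a GC peak area to a concentration
#'
#' Single-point calibration against a certified standard:
#' `C_S = A_S * C0 / A0`. The result is in the unit of the standard's
#' certified concentration.
#'
#' @param peak_area Sample peak area(s), >= 0.
#' @param standard A standard gas from [standard_gas()].
#' @return Concentration(s) in the standard's unit.
#' @examples
#' std <- standard_gas("N2O", peak_area_a0 = 1200)
#' peak_area_to_concentration(2400, std)  # 700 uL m-3
#' @export
peak_area_to_concentration <- function(peak_area, standard) {
  if (!is.list(standard) || is.null(standard$a0) || standard$a0 <= 0) {
    stop("invalid standard: a0 must be > 0", call. = FALSE)
  }
  if (any(peak_area < 0, na.rm = TRUE)) {
    stop("peak_area must be >= 0", call. = FALSE)
  }
  peak_area * standard$c0 / standard$a0
}

#' Ordinary least-squares slope of a chamber concentration series
#'
#' Fits concentration against elapsed minutes by OLS and returns the slope
#' (the dC/dt of the chamber flux formula), the coefficient of
#' determination and the number of points. For an exactly constant series
#' the slope is 0 and r-squared is `NA` (the total sum of squares is zero,
#' so r-squared carries no information); QC handles that case through the
#' near-zero-slope band.
#'
#' @param elapsed_min Elapsed minutes, strictly increasing (default chamber
#'   protocol samples at 0, 10, 20, 30 min).
#' @param concentration Concentrations in the per-gas dC/dt unit.
#' @return List with `slope`, `r_squared`, `n`.
#' @export
estimate_slope <- function(elapsed_min, concentration) {
  keep <- is.finite(elapsed_min) & is.finite(concentration)
  t <- as.numeric(elapsed_min[keep])
  y <- as.numeric(concentration[keep])
  n <- length(t)
  if (n < 3L) {
    return(list(slope = NA_real_, r_squared = NA_real_, n = n))
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("elapsed times must be strictly increasing (duplicate or unordered timestamps)",
         call. = FALSE)
  }
  sxx <- sum((t - mean(t))^2)
  if (sxx == 0) stop("zero variance in elapsed times", call. = FALSE)
  sxy <- sum((t - mean(t)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  r2 <- if (syy == 0) NA_real_ else (sxy^2) / (sxx * syy)
  list(slope = slope, r_squared = r2, n = n)
}

#' Areal gas flux from a concentration slope
#'
#' Applies the closed-chamber formula (see file header) to a fitted dC/dt.
#' Linear in both the slope and the chamber height; strictly decreasing in
#' chamber temperature for a positive slope (warmer air holds fewer moles
#' per volume). Negative slopes give negative fluxes (uptake) and are
#' preserved.
#'
#' @param slope dC/dt in the per-gas slope unit (uL L-1 min-1 for CO2,
#'   nL L-1 min-1 for N2O/CH4).
#' @param gas Gas name.
#' @param ta_c Chamber air temperature in degC (> -273).
#' @param h_m Chamber height in m (> 0; default 0.30).
#' @param basis Molar-mass basis, `"gas"` (default) or `"element"`.
#' @return Flux in the per-gas flux unit (ug m-2 h-1; mg m-2 h-1 for CO2).
#' @examples
#' flux_from_slope(1, "N2O", ta_c = 0, h_m = 0.3)  # 35.357... ug m-2 h-1
#' @export
flux_from_slope <- function(slope, gas, ta_c, h_m = 0.30,
                            basis = c("gas", "element")) {
  basis <- match.arg(basis)
  if (any(ta_c <= -273)) stop("ta_c must exceed -273 degC", call. = FALSE)
  if (any(h_m <= 0)) stop("chamber height h_m must be > 0", call. = FALSE)
  m <- molar_mass(gas, basis)
  (m / 22.4) * (273 / (273 + ta_c)) * 60 * h_m * slope
}

# slope implied by a flux: exact inverse of flux_from_slope
slope_from_flux <- function(flux, gas, ta_c, h_m = 0.30,
                            basis = c("gas", "element")) {
  basis <- match.arg(basis)
  m <- molar_mass(gas, basis)
  flux / ((m / 22.4) * (273 / (273 + ta_c)) * 60 * h_m)
}

#' Quality-control classification of a fitted chamber slope
#'
#' A deployment passes when it has at least three usable points and either
#' its r-squared clears the threshold or its slope magnitude falls inside a
#' near-zero band where r-squared is uninformative (with no concentration
#' change, noise dominates the fit). The band defaults to twice the
#' concentration measurement SD propagated to slope units over the standard
#' 0/10/20/30-min protocol.
#'
#' @param n Number of points in the fit.
#' @param r_squared Fit r-squared (may be `NA` for a constant series).
#' @param slope Fitted slope.
#' @param r2_threshold Minimum r-squared (default 0.80).
#' @param slope_band Half-width of the near-zero slope exemption band, in
#'   slope units. Use [near_zero_slope_band()] to derive it from a
#'   concentration SD.
#' @return One of `"pass"`, `"nonlinear"`, `"insufficient"`.
#' @export
qc_classify <- function(n, r_squared, slope, r2_threshold = 0.8,
                        slope_band = 0) {
  stopifnot(length(n) == 1L)
  if (is.na(n) || n < 3L) return("insufficient")
  if (is.na(slope)) return("insufficient")
  if (!is.na(r_squared) && r_squared >= r2_threshold) return("pass")
  if (abs(slope) <= slope_band) return("pass")
  "nonlinear"
}

#' Near-zero slope exemption band from the concentration measurement SD
#'
#' Propagates a per-sample concentration SD to the SD of the OLS slope over
#' the sampling protocol, `sd / sqrt(sum((t - mean(t))^2))`, and returns
#' twice that value.
#'
#' @param conc_sd Concentration measurement SD (slope-unit concentration).
#' @param elapsed_min Protocol sampling times (default 0/10/20/30 min).
#' @return Band half-width in slope units.
#' @export
near_zero_slope_band <- function(conc_sd, elapsed_min = c(0, 10, 20, 30)) {
  2 * conc_sd / sqrt(sum((elapsed_min - mean(elapsed_min))^2))
}

#' Estimate fluxes from a table of chamber series
#'
#' Runs calibration (peak-area mode), slope estimation, the chamber flux
#' formula and QC for every chamber deployment in a long-format table.
#'
#' @param series Tibble with columns `plot_id`, `gas`, `date`,
#'   `chamber_temp_c`, `elapsed_min`, and either `concentration` or
#'   `peak_area`; one row per syringe sample.
#' @param chamber_height_m Chamber height (m).
#' @param qc_r2 QC r-squared threshold.
#' @param conc_sd Per-gas named vector of concentration measurement SDs used
#'   for the near-zero-slope QC band; `NULL` disables the band.
#' @param standards Named list of [standard_gas()] objects (required when
#'   `series` carries `peak_area` instead of `concentration`).
#' @param basis Molar-mass basis for the flux.
#' @return Tibble of flux records: `plot_id`, `gas`, `date`, `flux`,
#'   `slope`, `r_squared`, `n_points`, `qc_flag`.
#' @export
estimate_fluxes <- function(series, chamber_height_m = 0.30, qc_r2 = 0.8,
                            conc_sd = NULL, standards = NULL,
                            basis = c("gas", "element")) {
  basis <- match.arg(basis)
  need <- c("plot_id", "gas", "date", "chamber_temp_c", "elapsed_min")
  miss <- setdiff(need, names(series))
  if (length(miss)) {
    stop("chamber series table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"concentration" %in% names(series)) {
    if (!"peak_area" %in% names(series)) {
      stop("chamber series table needs a concentration or peak_area column",
           call. = FALSE)
    }
    if (is.null(standards)) {
      stop("peak-area series require a standards list", call. = FALSE)
    }
    series$concentration <- vapply(seq_len(nrow(series)), function(i) {
      std <- standards[[series$gas[i]]]
      if (is.null(std)) stop("no standard gas for ", series$gas[i], call. = FALSE)
      # standard is certified in the C0 unit; rescale to the slope unit
      peak_area_to_concentration(series$peak_area[i], std) *
        standard_to_slope_unit(series$gas[i])
    }, numeric(1))
  }
  # grouped closed-form OLS (one pass over the table)
  fits <- series |>
    dplyr::group_by(.data$plot_id, .data$gas, .data$date) |>
    dplyr::summarise(
      chamber_temp_c = .data$chamber_temp_c[1],
      n_points = sum(is.finite(.data$elapsed_min) & is.finite(.data$concentration)),
      n_times = dplyr::n_distinct(.data$elapsed_min),
      sxx = sum((.data$elapsed_min - mean(.data$elapsed_min))^2),
      sxy = sum((.data$elapsed_min - mean(.data$elapsed_min)) *
                  (.data$concentration - mean(.data$concentration))),
      syy = sum((.data$concentration - mean(.data$concentration))^2),
      .groups = "drop"
    )
  if (any(fits$n_times < fits$n_points)) {
    stop("duplicated elapsed times within a chamber deployment", call. = FALSE)
  }
  if (any(fits$sxx == 0 & fits$n_points >= 3)) {
    stop("zero variance in elapsed times", call. = FALSE)
  }
  fits |>
    dplyr::mutate(
      slope = ifelse(.data$n_points >= 3, .data$sxy / .data$sxx, NA_real_),
      r_squared = ifelse(.data$n_points >= 3 & .data$syy > 0,
                         .data$sxy^2 / (.data$sxx * .data$syy), NA_real_)
    ) |>
    (\(d) {
      m <- vapply(d$gas, molar_mass, numeric(1), basis = basis)
      d$flux <- (m / 22.4) * (273 / (273 + d$chamber_temp_c)) * 60 *
        chamber_height_m * d$slope
      band <- if (is.null(conc_sd)) rep(0, nrow(d)) else
        vapply(d$gas, function(g) near_zero_slope_band(conc_sd[[g]]), numeric(1))
      d$qc_flag <- dplyr::case_when(
        d$n_points < 3 | is.na(d$slope) ~ "insufficient",
        !is.na(d$r_squared) & d$r_squared >= qc_r2 ~ "pass",
        abs(d$slope) <= band ~ "pass",
        TRUE ~ "nonlinear"
      )
      d[, c("plot_id", "gas", "date", "flux", "slope", "r_squared",
            "n_points", "qc_flag")]
    })()
}

# standard-gas certified units (uL m-3 / mL m-3) to slope concentration
# units (nL L-1 / uL L-1): 1 uL m-3 = 1 nL L-1, 1 mL m-3 = 1 uL L-1, so the
# factor is 1 for every supported gas; kept explicit so a differently
# certified standard can be accommodated in one place.
standard_to_slope_unit <- function(gas) {
  1
}
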