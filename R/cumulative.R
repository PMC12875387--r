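# Time integration of flux series to cumulative emissions.
#
# GF = sum_i (F_{i+1} + F_i)/2 * (t_{i+1} - t_i) * 24 * K
#
# with t in days, 24 converting days to hours, and K the per-gas unit
# factor (1e-5 for N2O/CH4 in ug m-2 h-1, 1e-2 for CO2 in mg m-2 h-1)
# mapping the areal mass to kg ha-1. Fluxes estimated on the gas-molecule
# mass basis are converted to element mass here (x28/44 for N2O, x12/44
# for CO2, x12/16 for CH4) so cumulative totals land in kg N ha-1 (N2O)
# and kg C ha-1 (CO2, CH4).

as_days <- function(t) {
  if (inherits(t, "Date")) as.numeric(t) else as.numeric(t)
}

#' Cumulative emission of one gas over an interval (trapezoid rule)
#'
#' @param time_days Measurement times, `Date` or numeric days, strictly
#'   increasing.
#' @param flux Fluxes in the per-gas flux unit at those times.
#' @param gas Gas name.
#' @param interval Optional length-2 interval (same scale as `time_days`).
#'   Records outside it are dropped (their count is reported in the
#'   `n_excluded` attribute); the integral never extrapolates beyond the
#'   first and last retained record.
#' @param flux_basis Mass basis of the incoming fluxes: `"gas"` (default;
#'   converted to element mass here) or `"element"` (already kg-N/kg-C
#'   consistent, no conversion).
#' @return Cumulative emission in kg N ha-1 (N2O) or kg C ha-1 (CO2, CH4),
#'   with attributes `n_used` and `n_excluded`.
#' @examples
#' # 100 -> 300 ug m-2 h-1 over 10 days, N2O:
#' cumulate(c(0, 10), c(100, 300), "N2O")  # 0.48 * 28/44 = 0.3055 kg N ha-1
#' @export
cumulate <- function(time_days, flux, gas, interval = NULL,
                     flux_basis = c("gas", "element")) {
  flux_basis <- match.arg(flux_basis)
  gas <- match_gas(gas)
  t <- as_days(time_days)
  f <- as.numeric(flux)
  keep <- is.finite(t) & is.finite(f)
  n_excluded <- sum(!keep)
  if (!is.null(interval)) {
    iv <- as_days(interval)
    inside <- keep & t >= iv[1] & t <= iv[2]
    n_excluded <- n_excluded + sum(keep & !inside)
    keep <- inside
  }
  t <- t[keep]; f <- f[keep]
  if (length(t) < 2L) {
    stop("insufficient coverage: need >= 2 flux records inside the interval",
         call. = FALSE)
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("flux record times must be strictly increasing", call. = FALSE)
  }
  k <- gas_info(gas)$unit_factor_K
  conv <- if (flux_basis == "gas") element_gas_ratio(gas) else 1
  gf <- sum((f[-1] + f[-length(f)]) / 2 * diff(t)) * 24 * k * conv
  structure(gf, n_used = length(t), n_excluded = n_excluded)
}

# linear interpolation of the flux at an arbitrary time inside the series
interp_flux <- function(t, f, at) {
  stats::approx(t, f, xout = at, rule = 1)$y
}

#' Partition a flux series into per-harvest cumulative emissions
#'
#' Splits the season at the harvest dates into contiguous intervals
#' `[start, h1]`, `(h1, h2]`, ..., `(h_k, end]` and integrates each. When no
#' flux record falls exactly on a boundary, the boundary flux is obtained by
#' linear interpolation, which makes the per-harvest totals sum exactly to
#' the whole-season integral.
#'
#' @param time_days Record times (`Date` or numeric), strictly increasing.
#' @param flux Fluxes in the per-gas flux unit.
#' @param gas Gas name.
#' @param harvest_dates Sorted harvest dates strictly inside the record
#'   span.
#' @param flux_basis Passed to [cumulate()].
#' @return Tibble with `harvest` (1..k+1), `start`, `end`, `gf`,
#'   `n_measurements`.
#' @export
partition_by_harvest <- function(time_days, flux, gas, harvest_dates,
                                 flux_basis = c("gas", "element")) {
  flux_basis <- match.arg(flux_basis)
  t <- as_days(time_days); f <- as.numeric(flux)
  hb <- sort(as_days(harvest_dates))
  if (length(t) < 2L) stop("insufficient coverage for partitioning", call. = FALSE)
  if (any(hb <= t[1]) || any(hb >= t[length(t)])) {
    stop("harvest dates must fall strictly inside the flux record span",
         call. = FALSE)
  }
  bounds <- c(t[1], hb, t[length(t)])
  out <- lapply(seq_len(length(bounds) - 1L), function(i) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    inside <- t > lo & t < hi
    tt <- c(lo, t[inside], hi)
    ff <- c(interp_flux(t, f, lo), f[inside], interp_flux(t, f, hi))
    gf <- cumulate(tt, ff, gas, flux_basis = flux_basis)
    tibble::tibble(harvest = i, start = lo, end = hi,
                   gf = as.numeric(gf), n_measurements = sum(inside) + 2L)
  })
  dplyr::bind_rows(out)
}

#' Share of the seasonal cumulative emission inside post-event windows
#'
#' Integrates the piecewise-linear flux interpolant over the union of
#' `[event, event + window_days]` windows (clipped to the record span) and
#' divides by the whole-season integral. With non-negative fluxes the share
#' lies in [0, 1].
#'
#' @param time_days Record times, strictly increasing.
#' @param flux Fluxes.
#' @param gas Gas name.
#' @param event_dates Event dates (`Date` or numeric days).
#' @param window_days Window length after each event (> 0; default 7).
#' @param flux_basis Passed to [cumulate()].
#' @return Ratio of in-window to seasonal cumulative emission.
#' @export
event_window_share <- function(time_days, flux, gas, event_dates,
                               window_days = 7,
                               flux_basis = c("gas", "element")) {
  flux_basis <- match.arg(flux_basis)
  stopifnot(window_days > 0)
  t <- as_days(time_days); f <- as.numeric(flux)
  total <- as.numeric(cumulate(t, f, gas, flux_basis = flux_basis))
  if (total == 0) stop("seasonal cumulative emission is zero; share undefined",
                       call. = FALSE)
  ev <- sort(as_days(event_dates))
  if (length(ev) == 0L) return(0)
  # merge overlapping windows, clip to the record span
  win <- cbind(pmax(ev, t[1]), pmin(ev + window_days, t[length(t)]))
  win <- win[win[, 1] < win[, 2], , drop = FALSE]
  if (nrow(win) == 0L) return(0)
  merged <- list()
  cur <- win[1, ]
  for (i in seq_len(nrow(win))[-1]) {
    if (win[i, 1] <= cur[2]) cur[2] <- max(cur[2], win[i, 2])
    else { merged[[length(merged) + 1L]] <- cur; cur <- win[i, ] }
  }
  merged[[length(merged) + 1L]] <- cur
  inside <- sum(vapply(merged, function(w) {
    tt <- sort(unique(c(w, t[t > w[1] & t < w[2]])))
    ff <- interp_flux(t, f, tt)
    as.numeric(cumulate(tt, ff, gas, flux_basis = flux_basis))
  }, numeric(1)))
  inside / total
}

#' Cumulative emissions for every plot, gas and harvest cycle
#'
#' Applies [partition_by_harvest()] to the pass-QC records of each
#' plot x gas series and appends the seasonal total (`harvest = 0`).
#'
#' @param flux_records Tibble from [estimate_fluxes()] (columns `plot_id`,
#'   `gas`, `date`, `flux`, `qc_flag`).
#' @param harvest_dates Harvest dates.
#' @param flux_basis Mass basis of the fluxes.
#' @return Tibble `plot_id`, `gas`, `harvest` (0 = season), `gf`,
#'   `n_measurements`.
#' @export
cumulative_by_plot <- function(flux_records, harvest_dates,
                               flux_basis = c("gas", "element")) {
  flux_basis <- match.arg(flux_basis)
  flux_records |>
    dplyr::filter(.data$qc_flag == "pass") |>
    dplyr::group_by(.data$plot_id, .data$gas) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::reframe(
      {
        hb <- as_days(harvest_dates)
        hb <- hb[hb > as_days(.data$date[1]) & hb < as_days(.data$date[dplyr::n()])]
        per <- partition_by_harvest(.data$date, .data$flux, .data$gas[1], hb,
                                    flux_basis = flux_basis)
        season <- tibble::tibble(
          harvest = 0L, start = per$start[1], end = per$end[nrow(per)],
          gf = sum(per$gf), n_measurements = dplyr::n()
        )
        dplyr::bind_rows(season, per)
      }
    )
}
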