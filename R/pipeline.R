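# End-to-end pipeline: chamber series -> fluxes -> cumulative emissions ->
# treatment-level resource and climate metrics.

#' Estimate fluxes for a simulated or loaded campaign bundle
#'
#' Thin wrapper over [estimate_fluxes()] wiring in the bundle's chamber
#' geometry, QC threshold and measurement-noise band.
#'
#' @param bundle Campaign bundle (needs `chamber_series` and `config`).
#' @return Flux record tibble.
#' @export
campaign_fluxes <- function(bundle) {
  cfg <- bundle$config
  estimate_fluxes(bundle$chamber_series,
                  chamber_height_m = cfg$sim$chamber$height_m,
                  qc_r2 = cfg$qc_r2,
                  conc_sd = cfg$sim$conc_noise_sd,
                  basis = cfg$flux_basis)
}

#' Treatment-level seasonal and per-harvest cumulative emissions
#'
#' Averages plot-level cumulative emissions over replicates.
#'
#' @param cum_plot Plot-level table from [cumulative_by_plot()].
#' @param plots Plot table (`plot_id`, `treatment`).
#' @return Tibble `treatment`, `gas`, `harvest` (0 = season), `gf_mean`,
#'   `gf_se`, `n_plots`.
#' @export
cumulative_by_treatment <- function(cum_plot, plots) {
  cum_plot |>
    dplyr::left_join(plots[, c("plot_id", "treatment")], by = "plot_id") |>
    dplyr::group_by(.data$treatment, .data$gas, .data$harvest) |>
    dplyr::summarise(
      gf_mean = mean(.data$gf),
      gf_se = stats::sd(.data$gf) / sqrt(dplyr::n()),
      n_plots = dplyr::n(),
      .groups = "drop"
    )
}

#' Treatment metrics table (yield, IWP, PFPN, EF, GWP, GHGI)
#'
#' Assembles the full per-treatment metric set from treatment-level
#' cumulative emissions and yields. The N2O emission factor is computed
#' against the unfertilised (N0) control at the same irrigation level.
#' Undefined metrics (IWP without irrigation, PFPN and EF without
#' fertiliser) are `NA` and render as an em dash in written reports.
#' IWP divides each yield by the seasonal irrigation volume (10 x mm,
#' in m3 ha-1).
#'
#' @param cum_treat Treatment-level cumulative table
#'   ([cumulative_by_treatment()]), seasonal rows (`harvest == 0`).
#' @param yields Plot-level yield table (`plot_id`, `treatment`, `harvest`,
#'   `yield_kg_ha`).
#' @param config Campaign configuration (design, inventory, factors,
#'   GWP basis).
#' @return Tibble, one row per treatment: annual yield, IWP, PFPN, EF (%),
#'   GWP_soil, GWP_inputs, GWP_total (kg CO2-eq ha-1), GHGI
#'   (kg CO2-eq t-1).
#' @export
treatment_metrics <- function(cum_treat, yields, config) {
  design <- config$design
  season <- cum_treat[cum_treat$harvest == 0, ]
  wide <- tidyr::pivot_wider(season[, c("treatment", "gas", "gf_mean")],
                             names_from = "gas", values_from = "gf_mean")
  y_annual <- yields |>
    dplyr::group_by(.data$plot_id, .data$treatment) |>
    dplyr::summarise(yield_kg_ha = sum(.data$yield_kg_ha), .groups = "drop") |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(yield_annual = mean(.data$yield_kg_ha), .groups = "drop")

  out <- design |>
    dplyr::left_join(wide, by = "treatment") |>
    dplyr::left_join(y_annual, by = "treatment")

  # matched N0 control at the same irrigation level for the emission factor
  ctrl <- out[out$nitrogen == "N0", c("water", "N2O")]
  names(ctrl)[2] <- "n2o_control"
  out <- dplyr::left_join(out, ctrl, by = "water")

  inv <- config$inventory
  gwp_in <- vapply(seq_len(nrow(out)), function(i) {
    row <- inv[inv$treatment == out$treatment[i], ]
    gwp_inputs(c(n_fertilizer = row$n_fertilizer, p2o5 = row$p2o5,
                 k2o = row$k2o, irrigation_mm = row$irrigation_mm,
                 diesel_ha = row$diesel_ha),
               config$emission_factors)
  }, numeric(1))

  out |>
    dplyr::mutate(
      iwp = iwp(.data$yield_annual, .data$irrigation_total),
      pfpn = pfpn(.data$yield_annual, .data$n_rate),
      ef_pct = emission_factor(.data$N2O, .data$n2o_control, .data$n_rate),
      gwp_soil = gwp_soil(.data$N2O, .data$CH4, basis = config$gwp_basis),
      gwp_inputs = gwp_in,
      gwp_total = gwp_total(.data$gwp_soil, .data$gwp_inputs),
      ghgi = ghgi(.data$gwp_total, .data$yield_annual)
    ) |>
    dplyr::select("treatment", "water", "nitrogen", "irrigation_total",
                  "n_rate", "yield_annual", "iwp", "pfpn",
                  gf_n2o = "N2O", gf_co2 = "CO2", gf_ch4 = "CH4",
                  "ef_pct", "gwp_soil", "gwp_inputs", "gwp_total", "ghgi")
}

#' Contrast every treatment against a reference regime
#'
#' Reports percent reductions (GWP, GHGI, EF, cumulative N2O) and percent
#' improvements (yield, IWP, PFPN) relative to the reference treatment,
#' conventionally the high-input regime.
#'
#' @param metrics Metrics table from [treatment_metrics()].
#' @param reference Reference treatment id (default from the table's
#'   conventional high-input regime, `"W2N3"`).
#' @return Tibble of percent changes, labelled with the reference.
#' @export
contrast_report <- function(metrics, reference = "W2N3") {
  ref <- metrics[metrics$treatment == reference, ]
  if (nrow(ref) != 1L) {
    stop("reference treatment ", reference, " not found in metrics table",
         call. = FALSE)
  }
  out <- tibble::tibble(
    treatment = metrics$treatment,
    reference = reference,
    gwp_reduction_pct  = contrast(metrics$gwp_total, ref$gwp_total),
    ghgi_reduction_pct = contrast(metrics$ghgi, ref$ghgi),
    ef_reduction_pct   = contrast(metrics$ef_pct, ref$ef_pct),
    n2o_reduction_pct  = contrast(metrics$gf_n2o, ref$gf_n2o),
    yield_improvement_pct = contrast(metrics$yield_annual, ref$yield_annual,
                                     type = "improvement"),
    iwp_improvement_pct   = contrast(metrics$iwp, ref$iwp, type = "improvement"),
    pfpn_improvement_pct  = contrast(metrics$pfpn, ref$pfpn, type = "improvement")
  )
  out
}

#' Run the full accounting chain on a campaign bundle
#'
#' Fluxes, QC, cumulative emissions (per plot, then per treatment), and the
#' treatment metrics and contrast tables.
#'
#' @param bundle Campaign bundle ([simulate_campaign()] or loaded via the
#'   readers).
#' @return List: `flux_records`, `cumulative_plot`, `cumulative_treatment`,
#'   `metrics`, `contrasts`.
#' @export
run_campaign <- function(bundle) {
  cfg <- bundle$config
  fluxes <- campaign_fluxes(bundle)
  cum_plot <- cumulative_by_plot(fluxes, bundle$harvest_dates,
                                 flux_basis = cfg$flux_basis)
  cum_treat <- cumulative_by_treatment(cum_plot, bundle$plots)
  metrics <- treatment_metrics(cum_treat, bundle$yields, cfg)
  contrasts <- contrast_report(metrics, cfg$reference_treatment)
  list(flux_records = fluxes, cumulative_plot = cum_plot,
       cumulative_treatment = cum_treat, metrics = metrics,
       contrasts = contrasts)
}
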