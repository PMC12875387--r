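# Factorial water x nitrogen design, management calendar and input inventory.

#' Default 3 x 4 water-nitrogen factorial design
#'
#' Twelve treatments crossing three seasonal irrigation levels (W0 0 mm,
#' W1 100 mm, W2 300 mm; split over three harvest cycles as 0/0/0, 40/30/30
#' and 120/90/90 mm) with four nitrogen rates (N0 0, N1 60, N2 120,
#' N3 180 kg N ha-1), three replicate plots each.
#'
#' @param replicates Number of replicate plots per treatment (default 3).
#' @return A tibble with one row per treatment: `treatment`, `water`,
#'   `nitrogen`, per-harvest irrigation columns `irr_h1..irr_h3` (mm),
#'   `irrigation_total` (mm) and `n_rate` (kg N ha-1).
#' @export
default_design <- function(replicates = 3) {
  water <- tibble::tibble(
    water  = c("W0", "W1", "W2"),
    irr_h1 = c(0, 40, 120),
    irr_h2 = c(0, 30, 90),
    irr_h3 = c(0, 30, 90)
  )
  nitrogen <- tibble::tibble(
    nitrogen = c("N0", "N1", "N2", "N3"),
    n_rate   = c(0, 60, 120, 180)
  )
  design <- tidyr::crossing(water, nitrogen)
  design$treatment <- paste0(design$water, design$nitrogen)
  design$irrigation_total <- design$irr_h1 + design$irr_h2 + design$irr_h3
  design$replicates <- as.integer(replicates)
  design[, c("treatment", "water", "nitrogen", "irr_h1", "irr_h2", "irr_h3",
             "irrigation_total", "n_rate", "replicates")]
}

#' Plot identifiers for a design
#'
#' @param design A design tibble from [default_design()].
#' @return Tibble with `plot_id`, `treatment` and replicate index `rep`.
#' @export
design_plots <- function(design) {
  tidyr::crossing(treatment = design$treatment, rep = seq_len(design$replicates[1])) |>
    dplyr::mutate(plot_id = paste0(.data$treatment, "_r", .data$rep)) |>
    dplyr::left_join(design, by = "treatment") |>
    dplyr::select("plot_id", "treatment", "rep", "water", "nitrogen",
                  "irr_h1", "irr_h2", "irr_h3", "irrigation_total", "n_rate")
}

#' Default management calendar for the sampled season
#'
#' The sampled season runs from first regreening (13 March) to the final
#' harvest (28 September). Irrigation is applied on 14 March and 14 April
#' (first harvest cycle, per-harvest amount split equally), 4 June (second)
#' and 11 August (third). Nitrogen topdressings of 30 % of the seasonal rate
#' are applied on 14 March and 4 June; the 40 % basal application at autumn
#' sowing precedes the sampled season and is not an in-season event. Harvest
#' dates are 15 May, 20 July and 27 September.
#'
#' Amounts are expressed as fractions: `fraction_of` names the treatment
#' column the fraction applies to (`irr_h1..irr_h3` or `n_rate`), so one
#' calendar serves every treatment.
#'
#' @param year Calendar year of the season (default 2024).
#' @return Tibble with `date`, `kind` (`irrigation`/`fertilization`/`harvest`),
#'   `fraction` and `fraction_of`.
#' @export
default_calendar <- function(year = 2024) {
  d <- function(m, day) as.Date(sprintf("%d-%02d-%02d", year, m, day))
  tibble::tibble(
    date = c(d(3, 14), d(4, 14), d(6, 4), d(8, 11),
             d(3, 14), d(6, 4),
             d(5, 15), d(7, 20), d(9, 27)),
    kind = c(rep("irrigation", 4), rep("fertilization", 2), rep("harvest", 3)),
    fraction = c(0.5, 0.5, 1, 1, 0.3, 0.3, NA, NA, NA),
    fraction_of = c("irr_h1", "irr_h1", "irr_h2", "irr_h3",
                    "n_rate", "n_rate", NA, NA, NA)
  )
}

#' Season window for a calendar year
#' @param year Calendar year.
#' @return Length-2 Date vector: 13 March to 28 September.
#' @export
default_season <- function(year = 2024) {
  as.Date(c(sprintf("%d-03-13", year), sprintf("%d-09-28", year)))
}

#' Resolve the calendar into per-treatment management events
#'
#' Expands the fractional calendar of [default_calendar()] against a design
#' row, yielding absolute amounts (mm of water, kg N ha-1). Rainfall events
#' may be appended; rain > 10 mm is flagged heavy (it triggers extra gas
#' sampling).
#'
#' @param design Design tibble.
#' @param calendar Calendar tibble (default [default_calendar()]).
#' @return Tibble `treatment`, `date`, `kind`, `amount`, `heavy`.
#' @export
treatment_events <- function(design, calendar = default_calendar()) {
  ev <- calendar[!is.na(calendar$fraction_of), ]
  out <- tidyr::crossing(treatment = design$treatment, ev) |>
    dplyr::left_join(design[, c("treatment", "irr_h1", "irr_h2", "irr_h3", "n_rate")],
                     by = "treatment")
  base <- vapply(seq_len(nrow(out)), function(i) {
    out[[out$fraction_of[i]]][i]
  }, numeric(1))
  out$amount <- base * out$fraction
  out$heavy <- out$kind == "rainfall" & out$amount > 10
  out[, c("treatment", "date", "kind", "amount", "heavy")]
}

#' Default agricultural input inventory for one treatment
#'
#' Seasonal input amounts feeding the life-cycle GWP of inputs: fertiliser N
#' equals the treatment nitrogen rate, P2O5 75 kg ha-1 and K2O 90 kg ha-1
#' applied uniformly at sowing, irrigation equal to the seasonal total, and
#' one per-hectare diesel term for tillage and harvest operations.
#'
#' @param design Design tibble.
#' @return Tibble `treatment`, `n_fertilizer`, `p2o5`, `k2o`,
#'   `irrigation_mm`, `diesel_ha`.
#' @export
default_inventory <- function(design = default_design()) {
  tibble::tibble(
    treatment     = design$treatment,
    n_fertilizer  = design$n_rate,
    p2o5          = 75,
    k2o           = 90,
    irrigation_mm = design$irrigation_total,
    diesel_ha     = 1
  )
}

#' Default input-chain emission factors
#'
#' CO2-equivalent factors for producing/delivering each input: 8.3 kg CO2-eq
#' per kg fertiliser N, 0.79 per kg P2O5, 0.55 per kg K2O, 2.66 per mm
#' irrigation water (pumping electricity) and 55.4 kg CO2-eq ha-1 for diesel
#' used in tillage and harvest.
#'
#' @return Named numeric vector keyed like the inventory columns.
#' @export
default_emission_factors <- function() {
  c(n_fertilizer = 8.3, p2o5 = 0.79, k2o = 0.55,
    irrigation_mm = 2.66, diesel_ha = 55.4)
}

#' Assemble a campaign configuration
#'
#' Bundles the design, calendar, inventory, emission factors, QC thresholds,
#' chamber geometry, unit-basis switches and simulation parameters into one
#' list that every pipeline stage reads.
#'
#' @param design Design tibble ([default_design()]).
#' @param calendar Calendar tibble ([default_calendar()]).
#' @param season Length-2 Date vector.
#' @param inventory Inventory tibble ([default_inventory()]).
#' @param emission_factors Named vector ([default_emission_factors()]).
#' @param qc_r2 Minimum regression r-squared for a flux to pass QC.
#' @param chamber_height_m Chamber height H in m.
#' @param gwp_basis Mass basis fed to the soil GWP term: `"element"` uses
#'   the cumulative kg N / kg C totals literally, `"gas"` converts them to
#'   gas mass (x44/28, x16/12) first.
#' @param flux_basis Molar-mass basis of flux estimation (`"gas"` default).
#' @param reference_treatment Reference for management contrasts.
#' @param seed Master random seed for simulation.
#' @param sim Simulation parameter list ([sim_params()]); built lazily if
#'   `NULL`.
#' @return A list of class `campaign_config`.
#' @export
campaign_config <- function(design = default_design(),
                            calendar = default_calendar(),
                            season = default_season(),
                            inventory = default_inventory(design),
                            emission_factors = default_emission_factors(),
                            qc_r2 = 0.8,
                            chamber_height_m = 0.30,
                            gwp_basis = c("element", "gas"),
                            flux_basis = c("gas", "element"),
                            reference_treatment = "W2N3",
                            seed = 1L,
                            sim = NULL) {
  cfg <- list(
    design = design,
    calendar = calendar,
    season = as.Date(season),
    inventory = inventory,
    emission_factors = emission_factors,
    qc_r2 = qc_r2,
    chamber_height_m = chamber_height_m,
    gwp_basis = match.arg(gwp_basis),
    flux_basis = match.arg(flux_basis),
    reference_treatment = reference_treatment,
    seed = as.integer(seed),
    sim = if (is.null(sim)) sim_params() else sim
  )
  class(cfg) <- "campaign_config"
  cfg
}

#' Validate a campaign configuration
#'
#' Checks every structural invariant the pipeline relies on and returns a
#' character vector of human-readable violations (empty when the
#' configuration is valid): per-harvest irrigation must sum to the seasonal
#' total, nitrogen rates and event amounts must be non-negative, emission
#' factors non-negative, QC threshold in [0, 1], chamber height positive,
#' season end after start.
#'
#' @param config A `campaign_config` list.
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))
  d <- config$design
  bad_tot <- abs(d$irr_h1 + d$irr_h2 + d$irr_h3 - d$irrigation_total) > 1e-9
  if (any(bad_tot)) {
    say("design: irrigation_total != sum of per-harvest amounts for %s",
        paste(d$treatment[bad_tot], collapse = ", "))
  }
  if (any(d$n_rate < 0)) say("design: negative n_rate")
  if (any(c(d$irr_h1, d$irr_h2, d$irr_h3) < 0)) say("design: negative per-harvest irrigation")
  if (anyDuplicated(d$treatment)) say("design: duplicated treatment ids")
  ef <- config$emission_factors
  if (any(ef < 0)) {
    say("emission_factors: negative factor for %s",
        paste(names(ef)[ef < 0], collapse = ", "))
  }
  inv <- config$inventory
  num <- vapply(inv, is.numeric, logical(1))
  if (any(vapply(inv[num], function(x) any(x < 0), logical(1)))) {
    bad <- names(inv[num])[vapply(inv[num], function(x) any(x < 0), logical(1))]
    say("inventory: negative amount in %s", paste(bad, collapse = ", "))
  }
  if (!is.numeric(config$qc_r2) || config$qc_r2 < 0 || config$qc_r2 > 1) {
    say("qc_r2: must lie in [0, 1]")
  }
  if (!is.numeric(config$chamber_height_m) || config$chamber_height_m <= 0) {
    say("chamber_height_m: must be > 0")
  }
  if (length(config$season) != 2 || config$season[2] <= config$season[1]) {
    say("season: end must be after start")
  }
  if (!config$reference_treatment %in% d$treatment) {
    say("reference_treatment: %s not in design", config$reference_treatment)
  }
  sp <- config$sim
  if (!is.null(sp)) {
    if (sp$wfps$decay_rate <= 0) say("sim$wfps$decay_rate: must be > 0")
    if (sp$navail$decay_rate <= 0) say("sim$navail$decay_rate: must be > 0")
    if (sp$flux$n2o$pulse_peak_day <= 0) say("sim$flux$n2o$pulse_peak_day: must be > 0")
    if (sp$flux$ch4$base_uptake > 0) say("sim$flux$ch4$base_uptake: CH4 mean response must be <= 0")
  }
  v
}

#' Check bulk/particle density consistency for soil observations
#'
#' @param rho_b Bulk density g cm-3.
#' @param rho_p Particle density g cm-3 (default 2.65).
#' @return Character vector of violations (empty when valid).
#' @export
validate_soil_densities <- function(rho_b, rho_p = 2.65) {
  v <- character(0)
  if (any(rho_b <= 0)) v <- c(v, "bulk density rho_b must be > 0")
  if (any(rho_b >= rho_p)) v <- c(v, "bulk density rho_b must be < particle density rho_p")
  v
}
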