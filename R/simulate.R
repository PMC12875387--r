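# Synthetic water x nitrogen campaign generator.
#
# The generator is phenomenological, not process-based: drivers (soil
# temperature, WFPS, available N) follow event-pulsed piecewise-exponential
# dynamics, and each gas responds to the drivers through a simple response
# surface. N2O is pulsed by fertiliser N and gated by a 50-60 % WFPS
# window; CO2 follows a temperature optimum near 15-20 degC with a
# moisture modifier; CH4 is a persistent sink whose uptake weakens as WFPS
# rises. Every random stream is seeded from (master seed, stream name) so
# adding plots or gases never perturbs existing streams.

#' Simulation parameters for a synthetic campaign
#'
#' Defaults emulate a semi-arid alfalfa season (mid-March to late
#' September) under the 3 x 4 water-nitrogen factorial: routine chamber
#' sampling every 8 days, alternate-day sampling on days 1/3/5/7 after
#' irrigation or fertilisation, and an extra visit the day after heavy
#' (> 10 mm) rain.
#'
#' @param routine_interval_days Routine sampling interval (7-10 d practice;
#'   default 8).
#' @param event_days Days after an event on which extra samples are taken.
#' @param temp Soil-temperature model: season-edge base (degC), seasonal
#'   amplitude, daily noise SD.
#' @param rain Rainfall model: number of events, lognormal meanlog/sdlog of
#'   event depth (mm).
#' @param wfps WFPS model: per-water-level baseline (%), pulse height per
#'   mm of water, exponential decay rate (d-1), upper bound, noise SD.
#' @param navail Available-N model: baseline (mg kg-1), pulse per kg N
#'   applied, decay rate (d-1), seasonal decline fraction, lognormal noise.
#' @param flux Per-gas response blocks (see source for fields).
#' @param flux_noise_sd Lognormal sdlog of daily multiplicative flux noise.
#' @param conc_noise_sd Per-gas chamber concentration measurement SD, in
#'   slope-concentration units (nL L-1 for N2O/CH4, uL L-1 for CO2).
#' @param chamber Chamber geometry/protocol: height (m), sample times
#'   (min), air-temperature offset above soil temperature (degC).
#' @param yield Yield model: per-harvest base yields for the unirrigated,
#'   unfertilised reference (kg ha-1), water multipliers, nitrogen response
#'   coefficients (concave, optimum near 120 kg N ha-1 under high water),
#'   lognormal noise.
#' @param soil Bulk and particle density used to translate WFPS to
#'   volumetric moisture.
#' @return A nested list of simulation parameters.
#' @export
sim_params <- function(routine_interval_days = 8,
                       event_days = c(0, 1, 3, 5, 7, 9),
                       temp = list(base = 8, amplitude = 20, noise_sd = 1.5),
                       rain = list(n_events = 16, meanlog = log(8), sdlog = 0.8),
                       wfps = list(baseline = c(W0 = 27, W1 = 29.5, W2 = 33),
                                   pulse_per_mm = 0.28, decay_rate = 0.07,
                                   max = 95, noise_sd = 1.5),
                       navail = list(baseline = 25, pulse_per_kg = 2.0,
                                     decay_rate = 0.05, season_decline = 0.4,
                                     noise_sd = 0.08),
                       flux = list(
                         n2o = list(base = 25, k_n = 10, wfps_center = 55,
                                    wfps_width = 18, wfps_floor = 0.25,
                                    pulse_peak_day = 5),
                         co2 = list(amplitude = 800, temp_opt = 17.5,
                                    temp_width = 12, moisture_base = 0.6,
                                    moisture_gain = 0.4, n_gain = 5e-4),
                         ch4 = list(base_uptake = -90, wfps_slope = 1.2)
                       ),
                       flux_noise_sd = 0.1,
                       conc_noise_sd = c(N2O = 1, CO2 = 4, CH4 = 4),
                       chamber = list(height_m = 0.30,
                                      sample_times = c(0, 10, 20, 30),
                                      air_offset_c = 2),
                       yield = list(base_harvest = c(2664.7, 5477.9, 3669.2),
                                    water_mult = c(W0 = 1, W1 = 1.12, W2 = 1.35),
                                    n_resp_low = c(a = 0.28, b = 0.09),
                                    n_resp_high = c(a = 0.35, b = 0.175),
                                    n_scale = 120, noise_sd = 0.02),
                       soil = list(rho_b = 1.48, rho_p = 2.65)) {
  list(routine_interval_days = routine_interval_days, event_days = event_days,
       temp = temp, rain = rain, wfps = wfps, navail = navail, flux = flux,
       flux_noise_sd = flux_noise_sd, conc_noise_sd = conc_noise_sd,
       chamber = chamber, yield = yield, soil = soil)
}

# deterministic 32-bit stream seed from (master seed, stream name)
stream_seed <- function(master, key) {
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(((as.numeric(master) %% 2147483647 + 1) * 48271 + h) %% 2147483647)
}

with_stream <- function(master, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(master, key))
  force(expr)
}

#' Simulate a seasonal rainfall calendar
#'
#' Draws event dates uniformly over the season and lognormal depths; events
#' above 10 mm are flagged heavy (they trigger extra gas sampling).
#'
#' @param config Campaign configuration.
#' @return Tibble `date`, `amount` (mm), `heavy`.
#' @export
simulate_rainfall <- function(config) {
  p <- config$sim$rain
  season <- config$season
  ndays <- as.numeric(season[2] - season[1])
  with_stream(config$seed, "rainfall", {
    offs <- sort(sample.int(ndays, p$n_events))
    amt <- stats::rlnorm(p$n_events, p$meanlog, p$sdlog)
    tibble::tibble(date = season[1] + offs, amount = amt, heavy = amt > 10)
  })
}

# water and fertiliser event tables for one treatment (irrigation splits
# from the calendar, rain shared by all)
plot_water_events <- function(events_tr, rain) {
  irr <- events_tr[events_tr$kind == "irrigation" & events_tr$amount > 0, ]
  rbind(data.frame(date = irr$date, amount = irr$amount),
        data.frame(date = rain$date, amount = rain$amount))
}

# sum of decaying event pulses evaluated on a daily grid
pulse_sum <- function(dates, event_dates, event_amounts, per_unit, decay) {
  out <- numeric(length(dates))
  d <- as.numeric(dates)
  for (i in seq_along(event_dates)) {
    dt <- d - as.numeric(event_dates[i])
    on <- dt >= 0
    out[on] <- out[on] + event_amounts[i] * per_unit * exp(-decay * dt[on])
  }
  out
}

#' Simulate daily soil drivers for every plot
#'
#' Soil temperature follows a seasonal half-sine with daily noise; WFPS sits
#' on a per-water-level baseline and jumps at each irrigation or rain event
#' by `pulse_per_mm x mm`, decaying exponentially (repeated wet-dry cycles);
#' available N jumps at fertilisation and declines over the season.
#' Deterministic given the master seed.
#'
#' @param config Campaign configuration.
#' @param rain Rainfall table ([simulate_rainfall()]); simulated if `NULL`.
#' @return Tibble `plot_id`, `treatment`, `water`, `date`, `soil_temp`,
#'   `wfps`, `theta_v`, `available_n`.
#' @export
simulate_drivers <- function(config, rain = NULL) {
  p <- config$sim
  if (is.null(rain)) rain <- simulate_rainfall(config)
  season <- config$season
  dates <- seq(season[1], season[2], by = "day")
  frac <- as.numeric(dates - season[1]) / as.numeric(season[2] - season[1])
  temp_mean <- p$temp$base + p$temp$amplitude * sin(pi * frac)
  plots <- design_plots(config$design)
  events <- treatment_events(config$design, config$calendar)
  out <- lapply(seq_len(nrow(plots)), function(i) {
    pl <- plots[i, ]
    ev <- events[events$treatment == pl$treatment, ]
    water_ev <- plot_water_events(ev, rain)
    fert_ev <- ev[ev$kind == "fertilization" & ev$amount > 0, ]
    wf_mean <- p$wfps$baseline[[pl$water]] +
      pulse_sum(dates, water_ev$date, water_ev$amount,
                p$wfps$pulse_per_mm, p$wfps$decay_rate)
    na_mean <- p$navail$baseline * (1 - p$navail$season_decline * frac) +
      pulse_sum(dates, fert_ev$date, fert_ev$amount,
                p$navail$pulse_per_kg, p$navail$decay_rate)
    with_stream(config$seed, paste0("drivers/", pl$plot_id), {
      st <- temp_mean + stats::rnorm(length(dates), 0, p$temp$noise_sd)
      wf <- pmin(pmax(wf_mean + stats::rnorm(length(dates), 0, p$wfps$noise_sd), 1),
                 p$wfps$max)
      nav <- na_mean * stats::rlnorm(length(dates),
                                     -p$navail$noise_sd^2 / 2, p$navail$noise_sd)
      tibble::tibble(
        plot_id = pl$plot_id, treatment = pl$treatment, water = pl$water,
        date = dates, soil_temp = st, wfps = wf,
        theta_v = wf * (1 - p$soil$rho_b / p$soil$rho_p),
        available_n = nav
      )
    })
  })
  dplyr::bind_rows(out)
}

# gamma-shaped event pulse: rises from 0 to a unit peak at tp days, then
# decays; emission maxima trail management events by a few days
gamma_pulse <- function(dt, tp) {
  out <- numeric(length(dt))
  on <- dt >= 0
  out[on] <- (dt[on] / tp) * exp(1 - dt[on] / tp)
  out
}

# per-gas mean flux responses to the drivers (noise-free given the drivers)
flux_response <- function(gas, drivers, p, fert_events = NULL) {
  w <- drivers$wfps
  switch(gas,
    N2O = {
      q <- p$flux$n2o
      gate <- q$wfps_floor + (1 - q$wfps_floor) *
        exp(-((w - q$wfps_center) / q$wfps_width)^2)
      base <- q$base * (0.5 + 0.8 * w / 100)
      pulse <- numeric(nrow(drivers))
      if (!is.null(fert_events) && nrow(fert_events)) {
        d <- as.numeric(drivers$date)
        for (i in seq_len(nrow(fert_events))) {
          pulse <- pulse + q$k_n * fert_events$amount[i] *
            gamma_pulse(d - as.numeric(fert_events$date[i]), q$pulse_peak_day)
        }
      }
      base + pulse * gate
    },
    CO2 = {
      q <- p$flux$co2
      tresp <- exp(-((drivers$soil_temp - q$temp_opt) / q$temp_width)^2)
      moist <- q$moisture_base + q$moisture_gain * w / 100
      nmul <- 1 + q$n_gain * drivers$available_n
      q$amplitude * tresp * moist * nmul
    },
    CH4 = {
      q <- p$flux$ch4
      pmin(q$base_uptake + q$wfps_slope * w, 0)
    },
    stop("unknown gas ", gas))
}

#' Simulate daily true flux series for every plot and gas
#'
#' Evaluates the per-gas response surfaces on the simulated drivers and
#' applies mean-one multiplicative lognormal noise. Both the noise-free
#' response (`mean_flux`) and the realised series (`flux`) are returned;
#' the realised daily series is the ground truth the pipeline is asked to
#' recover.
#'
#' @param drivers Driver table from [simulate_drivers()].
#' @param config Campaign configuration.
#' @return Tibble `plot_id`, `treatment`, `date`, `gas`, `mean_flux`,
#'   `flux` (per-gas flux units, gas-molecule mass basis).
#' @export
simulate_true_fluxes <- function(drivers, config) {
  p <- config$sim
  sd <- p$flux_noise_sd
  events <- treatment_events(config$design, config$calendar)
  out <- lapply(split(drivers, drivers$plot_id), function(dr) {
    dr <- dr[order(dr$date), ]
    fert <- events[events$treatment == dr$treatment[1] &
                     events$kind == "fertilization" & events$amount > 0, ]
    per_gas <- lapply(gases(), function(g) {
      mf <- flux_response(g, dr, p, fert)
      noise <- with_stream(config$seed, paste0("flux/", dr$plot_id[1], "/", g),
                           stats::rlnorm(nrow(dr), -sd^2 / 2, sd))
      tibble::tibble(plot_id = dr$plot_id, treatment = dr$treatment,
                     date = dr$date, gas = g, mean_flux = mf,
                     flux = mf * noise)
    })
    dplyr::bind_rows(per_gas)
  })
  dplyr::bind_rows(out)
}

#' Forward chamber model: concentration series implied by a flux
#'
#' Inverts the chamber flux formula: the headspace concentration rises
#' linearly from ambient with slope `F / [(M/22.4) (273/(273+Ta)) 60 H]`,
#' plus optional Gaussian measurement noise. Uses the current RNG state.
#'
#' @param flux True flux in the per-gas flux unit.
#' @param gas Gas name.
#' @param ta_c Chamber air temperature, degC.
#' @param h_m Chamber height, m.
#' @param sample_times Syringe times in minutes.
#' @param conc_noise_sd Gaussian concentration noise SD (slope units).
#' @param ambient Ambient concentration; per-gas typical value if `NULL`.
#' @param basis Molar-mass basis matching the flux.
#' @return Tibble `elapsed_min`, `concentration`.
#' @export
chamber_forward_model <- function(flux, gas, ta_c, h_m = 0.30,
                                  sample_times = c(0, 10, 20, 30),
                                  conc_noise_sd = 0, ambient = NULL,
                                  basis = c("gas", "element")) {
  basis <- match.arg(basis)
  gas <- match_gas(gas)
  if (is.null(ambient)) ambient <- gas_info(gas)$ambient
  slope <- slope_from_flux(flux, gas, ta_c, h_m, basis)
  conc <- ambient + slope * sample_times
  if (conc_noise_sd > 0) {
    conc <- conc + stats::rnorm(length(sample_times), 0, conc_noise_sd)
  }
  tibble::tibble(elapsed_min = sample_times, concentration = conc)
}

#' Chamber sampling schedule for a campaign
#'
#' Routine visits every `routine_interval_days` from the season start, plus
#' alternate-day visits on the configured days after every irrigation or
#' fertilisation event, plus a visit the day after heavy (> 10 mm) rain.
#' The final season day is always sampled.
#'
#' @param config Campaign configuration.
#' @param rain Rainfall table.
#' @return Sorted unique vector of sampling dates.
#' @export
sampling_schedule <- function(config, rain) {
  p <- config$sim
  season <- config$season
  routine <- seq(season[1], season[2], by = p$routine_interval_days)
  mgmt <- unique(config$calendar$date[config$calendar$kind %in%
                                        c("irrigation", "fertilization")])
  event_extra <- as.Date(unlist(lapply(mgmt, function(d) d + p$event_days)),
                         origin = "1970-01-01")
  rain_extra <- rain$date[rain$heavy] + 1
  out <- sort(unique(c(routine, event_extra, rain_extra, season[2])))
  out[out >= season[1] & out <= season[2]]
}

#' Simulate a complete chamber campaign
#'
#' Generates drivers, daily true fluxes, the sampling schedule, chamber
#' concentration series for every plot x gas x visit, and per-harvest
#' yields — everything the downstream pipeline consumes. Deterministic
#' given `config$seed`.
#'
#' @param config Campaign configuration ([campaign_config()]).
#' @return A list bundle: `config`, `plots`, `rain`, `events`, `drivers`,
#'   `true_fluxes`, `sampling_dates`, `chamber_series`, `yields`,
#'   `harvest_dates`.
#' @export
simulate_campaign <- function(config = campaign_config()) {
  p <- config$sim
  rain <- simulate_rainfall(config)
  drivers <- simulate_drivers(config, rain)
  truth <- simulate_true_fluxes(drivers, config)
  dates <- sampling_schedule(config, rain)
  plots <- design_plots(config$design)
  st <- p$chamber$sample_times

  sampled <- truth[truth$date %in% dates, ]
  temp_lookup <- drivers[, c("plot_id", "date", "soil_temp")]
  sampled <- dplyr::left_join(sampled, temp_lookup, by = c("plot_id", "date"))
  sampled$ta <- sampled$soil_temp + p$chamber$air_offset_c

  series <- lapply(split(sampled, list(sampled$plot_id, sampled$gas), drop = TRUE),
    function(rec) {
      g <- rec$gas[1]
      with_stream(config$seed, paste0("chamber/", rec$plot_id[1], "/", g), {
        slope <- slope_from_flux(rec$flux, g, rec$ta, p$chamber$height_m,
                                 config$flux_basis)
        n <- nrow(rec) * length(st)
        tibble::tibble(
          plot_id = rep(rec$plot_id, each = length(st)),
          gas = g,
          date = rep(rec$date, each = length(st)),
          chamber_temp_c = rep(rec$ta, each = length(st)),
          elapsed_min = rep(st, nrow(rec)),
          concentration = gas_info(g)$ambient +
            rep(slope, each = length(st)) * rep(st, nrow(rec)) +
            stats::rnorm(n, 0, p$conc_noise_sd[[g]])
        )
      })
    })
  chamber_series <- dplyr::bind_rows(series)

  harvest_dates <- sort(config$calendar$date[config$calendar$kind == "harvest"])
  yields <- simulate_yields(config, plots)

  list(config = config, plots = plots, rain = rain,
       events = treatment_events(config$design, config$calendar),
       drivers = drivers, true_fluxes = truth, sampling_dates = dates,
       chamber_series = chamber_series, yields = yields,
       harvest_dates = harvest_dates)
}

# concave water x nitrogen yield response with per-harvest bases
simulate_yields <- function(config, plots = design_plots(config$design)) {
  p <- config$sim$yield
  out <- lapply(seq_len(nrow(plots)), function(i) {
    pl <- plots[i, ]
    x <- pl$n_rate / p$n_scale
    cf <- if (pl$water == "W2") p$n_resp_high else p$n_resp_low
    fn <- 1 + cf[["a"]] * x - cf[["b"]] * x^2
    fw <- p$water_mult[[pl$water]]
    mean_y <- p$base_harvest * fw * fn
    noise <- with_stream(config$seed, paste0("yield/", pl$plot_id),
                         stats::rlnorm(3, -p$noise_sd^2 / 2, p$noise_sd))
    tibble::tibble(plot_id = pl$plot_id, treatment = pl$treatment,
                   harvest = 1:3, yield_kg_ha = mean_y * noise)
  })
  dplyr::bind_rows(out)
}

#' Ground-truth cumulative emissions of a simulated campaign
#'
#' Integrates the generator's daily flux series (trapezoid on the daily
#' grid — the model is piecewise linear between days, so this is its exact
#' integral) to seasonal cumulative emissions per plot and gas, on the
#' element-mass basis the pipeline reports.
#'
#' @param bundle Campaign bundle from [simulate_campaign()].
#' @param truth `"realized"` integrates the noisy daily series the chambers
#'   sampled; `"expected"` integrates the noise-free response.
#' @return Tibble `plot_id`, `treatment`, `gas`, `gf_true` (kg N or
#'   kg C ha-1).
#' @export
true_cumulative <- function(bundle, truth = c("realized", "expected")) {
  truth <- match.arg(truth)
  col <- if (truth == "realized") "flux" else "mean_flux"
  basis <- bundle$config$flux_basis
  bundle$true_fluxes |>
    dplyr::group_by(.data$plot_id, .data$treatment, .data$gas) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::summarise(
      gf_true = as.numeric(cumulate(.data$date, .data[[col]], .data$gas[1],
                                    flux_basis = basis)),
      .groups = "drop"
    )
}
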