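# Synthetic campaign generator: determinism, driver dynamics, flux
# phenomenology, forward chamber model, schedule and yields.

test_that("campaigns are bit-identical under a fixed seed", {
  cfg <- campaign_config(seed = 11L)
  b1 <- simulate_campaign(cfg)
  b2 <- simulate_campaign(cfg)
  expect_identical(b1$drivers, b2$drivers)
  expect_identical(b1$true_fluxes, b2$true_fluxes)
  expect_identical(b1$chamber_series, b2$chamber_series)
  expect_identical(b1$yields, b2$yields)
})

test_that("adding replicate plots never perturbs existing plot streams", {
  cfg3 <- campaign_config(design = default_design(replicates = 3), seed = 5L)
  cfg4 <- campaign_config(design = default_design(replicates = 4), seed = 5L)
  d3 <- simulate_drivers(cfg3)
  d4 <- simulate_drivers(cfg4)
  keep <- d4$plot_id %in% unique(d3$plot_id)
  expect_identical(d3$wfps, d4$wfps[keep])
  expect_identical(d3$available_n, d4$available_n[keep])
})

test_that("with no events and no noise WFPS stays flat at its baseline", {
  cfg <- noise_free_config(rain_events = 0L)
  cfg$calendar <- harvest_only_calendar()
  d <- simulate_drivers(cfg)
  w0 <- d[d$plot_id == "W0N0_r1", ]
  expect_equal(w0$wfps, rep(cfg$sim$wfps$baseline[["W0"]], nrow(w0)),
               tolerance = 1e-12)
  # available N declines monotonically without fertilisation pulses
  expect_true(all(diff(w0$available_n) <= 1e-12))
})

test_that("an irrigation event produces a decaying WFPS pulse of the stated height", {
  cfg <- noise_free_config(rain_events = 0L)
  d <- simulate_drivers(cfg)
  w2 <- d[d$plot_id == "W2N0_r1", ]
  ev <- as.Date("2024-06-04")  # 90 mm split: single 90-mm event that day
  base_before <- w2$wfps[w2$date == ev - 1]
  jump <- w2$wfps[w2$date == ev]
  # residual decay of earlier pulses is tiny by June; height ~ mm x pulse height
  expect_equal(jump - base_before, 90 * cfg$sim$wfps$pulse_per_mm,
               tolerance = 0.05 * 90 * cfg$sim$wfps$pulse_per_mm)
  after <- w2$wfps[w2$date %in% (ev + 0:14)]
  expect_true(all(diff(after) < 0))  # monotone decay until the next event
})

test_that("wetter regimes span a wider WFPS range than unirrigated plots", {
  d <- default_bundle()$drivers
  rng <- tapply(d$wfps, d$water, function(x) diff(range(x)))
  expect_gt(rng[["W2"]], rng[["W0"]])
})

test_that("unfertilised plots without events keep N2O at its base level", {
  cfg <- noise_free_config(rain_events = 0L)
  cfg$calendar <- harvest_only_calendar()
  d <- simulate_drivers(cfg)
  f <- simulate_true_fluxes(d, cfg)
  n2o <- f[f$plot_id == "W0N0_r1" & f$gas == "N2O", ]
  expect_equal(diff(range(n2o$mean_flux)), 0, tolerance = 1e-9)
})

test_that("methane stays a sink everywhere and weakens with irrigation", {
  tf <- default_bundle()$true_fluxes
  ch4 <- tf[tf$gas == "CH4", ]
  expect_true(all(ch4$mean_flux <= 0))
  m <- tapply(ch4$flux, sub("N.*", "", ch4$treatment), mean)
  expect_gt(m[["W2"]], m[["W0"]])  # less negative under high water
})

test_that("the forward chamber model is the exact inverse of flux estimation", {
  ser <- chamber_forward_model(0, "CO2", 20, conc_noise_sd = 0)
  expect_equal(diff(range(ser$concentration)), 0)  # flat at ambient
  # noisy Monte-Carlo: mean recovered flux within 2 SE of truth
  set.seed(77)
  f_true <- 150
  rec <- replicate(1000, {
    s <- chamber_forward_model(f_true, "N2O", 15, conc_noise_sd = 1)
    fit <- estimate_slope(s$elapsed_min, s$concentration)
    flux_from_slope(fit$slope, "N2O", 15)
  })
  se <- sd(rec) / sqrt(length(rec))
  expect_lt(abs(mean(rec) - f_true), 2 * se + 1e-9)
})

test_that("a default campaign has the full factorial structure and schedule", {
  b <- default_bundle()
  expect_equal(nrow(b$plots), 36L)
  expect_equal(length(unique(b$plots$treatment)), 12L)
  expect_equal(nrow(b$yields), 36L * 3L)
  # alternate-day sampling after each management event
  cfg <- b$config
  mgmt <- unique(cfg$calendar$date[cfg$calendar$kind %in%
                                     c("irrigation", "fertilization")])
  for (d in mgmt) {
    expected <- as.Date(d, origin = "1970-01-01") + cfg$sim$event_days
    expected <- expected[expected <= cfg$season[2]]
    expect_true(all(expected %in% b$sampling_dates))
  }
  # heavy rain triggers a next-day visit
  heavy <- b$rain$date[b$rain$heavy]
  expect_true(all((heavy + 1)[heavy + 1 <= cfg$season[2]] %in% b$sampling_dates))
  expect_true(all(b$rain$heavy == (b$rain$amount > 10)))
})

test_that("simulated yield peaks at moderate nitrogen under high water", {
  y <- default_bundle()$yields
  ann <- aggregate(yield_kg_ha ~ treatment, y,
                   function(x) sum(x) / 1)  # per-plot sums averaged below
  ann <- aggregate(yield_kg_ha ~ treatment,
                   aggregate(yield_kg_ha ~ plot_id + treatment, y, sum), mean)
  w2 <- ann[grep("^W2", ann$treatment), ]
  expect_equal(w2$treatment[which.max(w2$yield_kg_ha)], "W2N2")
  # yield increases with irrigation at fixed N
  n2 <- ann[grep("N2$", ann$treatment), ]
  expect_true(n2$yield_kg_ha[n2$treatment == "W2N2"] >
                n2$yield_kg_ha[n2$treatment == "W0N2"])
})
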