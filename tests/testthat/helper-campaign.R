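# Shared fixtures, built in code. The default bundle is simulated once per
# test run and reused by every test that only reads it.

bundle_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(bundle_cache$bundle)) {
    bundle_cache$bundle <- simulate_campaign(campaign_config(seed = 1L))
  }
  bundle_cache$bundle
}

default_results <- function() {
  if (is.null(bundle_cache$results)) {
    bundle_cache$results <- run_campaign(default_bundle())
  }
  bundle_cache$results
}

# configuration with all stochastic terms switched off
noise_free_config <- function(seed = 1L, rain_events = 0L) {
  sp <- sim_params(flux_noise_sd = 1e-12,
                   conc_noise_sd = c(N2O = 0, CO2 = 0, CH4 = 0))
  sp$temp$noise_sd <- 0
  sp$wfps$noise_sd <- 0
  sp$navail$noise_sd <- 1e-12
  sp$yield$noise_sd <- 1e-12
  sp$rain$n_events <- rain_events
  campaign_config(seed = seed, sim = sp)
}

# calendar with no in-season management events (harvests only)
harvest_only_calendar <- function(year = 2024) {
  cal <- default_calendar(year)
  cal[cal$kind == "harvest", ]
}
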