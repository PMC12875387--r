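# Trapezoid cumulative emissions, harvest partitioning, event-window share.

# independent oracle: rectangle-rule integration of the piecewise-linear
# interpolant on a 1-minute grid
rectangle_oracle <- function(t_days, flux, gas, flux_basis = "gas") {
  grid <- seq(t_days[1], t_days[length(t_days)], by = 1 / (24 * 60))
  f <- stats::approx(t_days, flux, xout = grid)$y
  k <- gas_info(gas)$unit_factor_K
  conv <- if (flux_basis == "gas") {
    gas_info(gas)$molar_mass_elem / gas_info(gas)$molar_mass_gas
  } else 1
  sum((f[-1] + f[-length(f)]) / 2) * (1 / (24 * 60)) * 24 * k * conv
}

test_that("constant flux integrates to the closed form", {
  # F * D days * 24 h * K * element conversion
  gf <- cumulate(c(0, 4, 10), rep(50, 3), "N2O")
  expect_equal(as.numeric(gf), 50 * 10 * 24 * 1e-5 * 28 / 44, tolerance = 1e-12)
  gf_co2 <- cumulate(c(0, 10), rep(200, 2), "CO2")
  expect_equal(as.numeric(gf_co2), 200 * 10 * 24 * 1e-2 * 12 / 44, tolerance = 1e-12)
})

test_that("two-record trapezoid matches hand arithmetic on both mass bases", {
  # (100+300)/2 * 10 d * 24 * 1e-5 = 0.48 kg N2O/ha; x28/44 in kg N/ha
  gf <- cumulate(c(0, 10), c(100, 300), "N2O")
  expect_equal(as.numeric(gf), 0.48 * 28 / 44, tolerance = 1e-12)
  expect_equal(as.numeric(gf), 0.3054545, tolerance = 1e-6)
  gf_el <- cumulate(c(0, 10), c(100, 300), "N2O", flux_basis = "element")
  expect_equal(as.numeric(gf_el), 0.48, tolerance = 1e-12)
})

test_that("all-negative methane series yields net uptake", {
  gf <- cumulate(c(0, 5, 12), c(-40, -60, -20), "CH4")
  expect_lt(as.numeric(gf), 0)
})

test_that("trapezoid equals the fine-grid rectangle oracle on random series", {
  set.seed(19)
  for (i in 1:20) {
    g <- sample(gases(), 1)
    n <- sample(5:25, 1)
    t <- sort(sample(0:180, n))
    f <- rlnorm(n, 3, 1) * sample(c(-1, 1), n, replace = TRUE)
    got <- as.numeric(cumulate(t, f, g))
    want <- rectangle_oracle(t, f, g)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("scaling all fluxes scales the cumulative emission", {
  t <- c(0, 3, 9, 20)
  f <- c(10, 80, 40, 5)
  expect_equal(as.numeric(cumulate(t, 7 * f, "N2O")),
               7 * as.numeric(cumulate(t, f, "N2O")), tolerance = 1e-12)
})

test_that("insufficient or malformed series raise informative errors", {
  expect_error(cumulate(0, 10, "N2O"), "insufficient coverage")
  expect_error(cumulate(c(0, 5, 5), c(1, 2, 3), "N2O"), "strictly increasing")
  gf <- cumulate(c(0, 5, 10, 50), c(1, 2, 3, 4), "N2O", interval = c(0, 10))
  expect_equal(attr(gf, "n_excluded"), 1L)
  expect_equal(attr(gf, "n_used"), 3L)
})

test_that("harvest partition is additive and symmetric", {
  # one harvest splitting a constant-flux series in half: equal halves
  per <- partition_by_harvest(c(0, 10, 20), rep(60, 3), "N2O", 10)
  expect_equal(per$gf[1], per$gf[2], tolerance = 1e-12)

  # boundaries at record times: exact additivity
  t <- c(0, 5, 10, 15, 30)
  f <- c(10, 50, 20, 80, 5)
  per <- partition_by_harvest(t, f, "N2O", c(10, 15))
  expect_equal(nrow(per), 3L)
  expect_equal(sum(per$gf), as.numeric(cumulate(t, f, "N2O")), tolerance = 1e-12)

  # boundary between records: interpolated; sum still equals season total
  set.seed(31)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    t <- sort(sample(seq(0, 200, by = 0.5), n))
    f <- rlnorm(n, 3, 0.8)
    hb <- sort(runif(2, t[2], t[n - 1]))
    per <- partition_by_harvest(t, f, "N2O", hb)
    expect_equal(sum(per$gf), as.numeric(cumulate(t, f, "N2O")),
                 tolerance = 1e-9)
  }
})

test_that("harvest dates outside the record span are rejected", {
  expect_error(partition_by_harvest(c(0, 10), c(1, 2), "N2O", 12),
               "inside the flux record span")
})

test_that("event-window share behaves at its extremes and on pulses", {
  t <- 0:20
  f <- rep(10, 21)
  # windows covering the whole season
  expect_equal(event_window_share(t, f, "N2O", c(0, 7, 14), window_days = 7), 1)
  # no events
  expect_equal(event_window_share(t, f, "N2O", numeric(0)), 0)

  # rectangular pulse entirely inside one window
  f2 <- rep(1, 21)
  f2[t >= 5 & t <= 8] <- 101
  share <- event_window_share(t, f2, "N2O", 4, window_days = 7)
  # manual integral of the piecewise-linear series
  total <- as.numeric(cumulate(t, f2, "N2O"))
  inside <- as.numeric(cumulate(4:11, f2[t %in% 4:11], "N2O"))
  expect_equal(share, inside / total, tolerance = 1e-12)
  expect_gt(share, 0.5)
  expect_true(share >= 0 && share <= 1)
})

test_that("zero seasonal total makes the event share undefined", {
  expect_error(event_window_share(0:5, rep(0, 6), "N2O", 2), "undefined")
})
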