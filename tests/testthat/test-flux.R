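# GC calibration, chamber slope estimation, flux formula and QC.

test_that("peak-area calibration is linear through the certified standard", {
  std <- standard_gas("N2O", peak_area_a0 = 1200)
  expect_equal(peak_area_to_concentration(1200, std), 350)   # identity case
  expect_equal(peak_area_to_concentration(0, std), 0)
  expect_equal(peak_area_to_concentration(2400, std), 700)   # 2x the standard
  # linearity at arbitrary areas
  a <- c(13, 130, 1300)
  expect_equal(peak_area_to_concentration(10 * a, std),
               10 * peak_area_to_concentration(a, std))
})

test_that("invalid standards are rejected", {
  expect_error(standard_gas("N2O", peak_area_a0 = 0), "positive")
  expect_error(standard_gas("N2O", peak_area_a0 = -5), "positive")
  expect_error(peak_area_to_concentration(10, list(c0 = 350, a0 = 0)),
               "invalid standard")
})

test_that("slope estimation recovers exact lines to machine precision", {
  t <- c(0, 10, 20, 30)
  fit <- estimate_slope(t, 300 + 1 * t)
  expect_equal(fit$slope, 1, tolerance = 1e-14)
  expect_equal(fit$r_squared, 1, tolerance = 1e-14)
  expect_equal(fit$n, 4L)

  flat <- estimate_slope(t, rep(305, 4))
  expect_equal(flat$slope, 0)
  expect_true(is.na(flat$r_squared))  # zero total variance: r2 carries nothing
})

test_that("slope estimation agrees with lm() on perturbed series", {
  t <- c(0, 10, 20, 30)
  y <- c(300, 311, 320, 330)  # one perturbed value
  fit <- estimate_slope(t, y)
  ref <- stats::lm(y ~ t)
  expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(fit$r_squared, summary(ref)$r.squared, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    yy <- 400 + 2 * t + rnorm(4, 0, 5)
    fit <- estimate_slope(t, yy)
    ref <- stats::lm(yy ~ t)
    expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(fit$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  }
})

test_that("degenerate chamber series are rejected or flagged", {
  expect_error(estimate_slope(c(0, 10, 10, 30), c(1, 2, 3, 4)),
               "strictly increasing")
  expect_equal(estimate_slope(c(0, 10), c(1, 2))$n, 2L)
  expect_true(is.na(estimate_slope(c(0, 10), c(1, 2))$slope))
})

test_that("chamber flux formula matches hand arithmetic and its symmetries", {
  # M/22.4 * 273/273 * 60 * 0.3 * 1 for N2O at 0 degC
  expect_equal(flux_from_slope(1, "N2O", ta_c = 0, h_m = 0.3),
               44 / 22.4 * 60 * 0.3, tolerance = 1e-12)
  expect_equal(flux_from_slope(1, "N2O", ta_c = 0, h_m = 0.3),
               35.3571428571, tolerance = 1e-9)
  for (g in gases()) expect_equal(flux_from_slope(0, g, 20), 0)

  # linear in slope and in H; sign preserved; decreasing in Ta
  set.seed(11)
  for (i in 1:10) {
    s <- runif(1, -5, 5); h <- runif(1, 0.1, 0.6); ta <- runif(1, -5, 35)
    expect_equal(flux_from_slope(2 * s, "CO2", ta, h),
                 2 * flux_from_slope(s, "CO2", ta, h))
    expect_equal(flux_from_slope(s, "CO2", ta, 2 * h),
                 2 * flux_from_slope(s, "CO2", ta, h))
    expect_equal(sign(flux_from_slope(s, "CH4", ta, h)), sign(s))
  }
  expect_lt(flux_from_slope(1, "N2O", 25), flux_from_slope(1, "N2O", 5))

  # element-mass basis uses the N / C molar masses
  expect_equal(flux_from_slope(1, "N2O", 0, 0.3, basis = "element") /
                 flux_from_slope(1, "N2O", 0, 0.3, basis = "gas"),
               28 / 44)
})

test_that("QC classification follows the r2 threshold and near-zero band", {
  expect_equal(qc_classify(4, 1.0, 2), "pass")
  expect_equal(qc_classify(2, NA, NA), "insufficient")
  expect_equal(qc_classify(4, 0.2, 5, r2_threshold = 0.8), "nonlinear")
  # r2 meaningless near zero slope: band exemption
  band <- near_zero_slope_band(2)
  expect_equal(qc_classify(4, 0.1, band * 0.9, slope_band = band), "pass")
  expect_equal(qc_classify(4, 0.1, band * 1.1, slope_band = band), "nonlinear")
  # constant series: r2 NA, zero slope, passes through the band
  expect_equal(qc_classify(4, NA, 0, slope_band = band), "pass")
})

test_that("forward chamber model then flux estimation recovers the flux exactly", {
  set.seed(3)
  for (i in 1:25) {
    g <- sample(gases(), 1)
    f <- runif(1, -200, 400)
    ta <- runif(1, 0, 35)
    ser <- chamber_forward_model(f, g, ta, h_m = 0.3, conc_noise_sd = 0)
    fit <- estimate_slope(ser$elapsed_min, ser$concentration)
    f_hat <- flux_from_slope(fit$slope, g, ta, 0.3)
    expect_equal(f_hat, f, tolerance = 1e-9)
  }
})

test_that("peak-area mode and concentration mode give identical fluxes", {
  std <- list(N2O = standard_gas("N2O", peak_area_a0 = 1000))
  ser <- chamber_forward_model(120, "N2O", ta_c = 20, conc_noise_sd = 0)
  tbl_conc <- tibble::tibble(plot_id = "p1", gas = "N2O",
                             date = as.Date("2024-05-01"), chamber_temp_c = 20,
                             elapsed_min = ser$elapsed_min,
                             concentration = ser$concentration)
  # areas consistent with the calibration line: A = C / C0 * A0
  tbl_area <- tbl_conc
  tbl_area$peak_area <- tbl_area$concentration / 350 * 1000
  tbl_area$concentration <- NULL
  f1 <- estimate_fluxes(tbl_conc)
  f2 <- estimate_fluxes(tbl_area, standards = std)
  expect_equal(f2$flux, f1$flux, tolerance = 1e-12)
  expect_equal(f1$qc_flag, "pass")
})

test_that("estimate_fluxes validates schema and duplicate timestamps", {
  tbl <- tibble::tibble(plot_id = "p", gas = "N2O", date = as.Date("2024-05-01"),
                        chamber_temp_c = 20, elapsed_min = c(0, 10, 10, 30),
                        concentration = c(1, 2, 3, 4))
  expect_error(estimate_fluxes(tbl), "duplicated elapsed times")
  expect_error(estimate_fluxes(tbl[, -5]), "lacks column")
  tbl2 <- tbl
  tbl2$concentration <- NULL
  expect_error(estimate_fluxes(tbl2), "concentration or peak_area")
})
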