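noiseless_series <- function(slope = 1, intercept = -3,
                             conc = 10^(6:10), k = Inf) {
  cfg <- spike_series_config(concentrations = conc, response_slope = slope,
                             response_intercept_log10 = intercept,
                             saturation_k = k, baseline_tfi_mean = 0,
                             baseline_tfi_sd = 0, rep_noise_log10_sd = 0)
  simulate_spikein_series(cfg, seed = 1)
}

test_that("the noiseless spike model reproduces its closed form", {
  ser <- noiseless_series()
  expect_equal(ser$tfi[ser$concentration == 1e7][1], 1e4)
  expect_true(all(ser$tfi[ser$concentration == 0] == 0))
})

test_that("expected TFI is monotone in concentration, even with baseline", {
  cfg <- spike_series_config(concentrations = 10^seq(6, 10, 0.5),
                             baseline_tfi_mean = 100, baseline_tfi_sd = 0,
                             rep_noise_log10_sd = 0, saturation_k = 1e9)
  ser <- simulate_spikein_series(cfg, seed = 2)
  means <- tapply(ser$tfi[ser$concentration > 0],
                  ser$concentration[ser$concentration > 0], mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) >= 0))
})

test_that("the 3-sigma LOD rule reproduces hand-computed examples", {
  # blank mean 100, sd 10; means 105 / 200 / 2000 -> LOD = 1e7
  ser <- dplyr::bind_rows(
    tibble::tibble(concentration = 0, replicate = 1:3,
                   tfi = c(90, 100, 110)),
    tibble::tibble(concentration = rep(c(1e6, 1e7, 1e8), each = 2),
                   replicate = rep(1:2, 3),
                   tfi = c(105, 105, 200, 200, 2000, 2000)))
  expect_equal(sd(c(90, 100, 110)), 10)
  expect_equal(estimate_lod(ser), 1e7)
  # all means below blank + 3 sd -> above tested range
  low <- dplyr::bind_rows(
    tibble::tibble(concentration = 0, replicate = 1:3, tfi = c(90, 100, 110)),
    tibble::tibble(concentration = c(1e6, 1e7), replicate = 1,
                   tfi = c(105, 120)))
  expect_equal(estimate_lod(low), Inf)
  # degenerate blank sd 0: any exceedance qualifies at the lowest point
  deg <- dplyr::bind_rows(
    tibble::tibble(concentration = 0, replicate = 1:2, tfi = c(100, 100)),
    tibble::tibble(concentration = c(1e6, 1e7), replicate = 1,
                   tfi = c(101, 500)))
  expect_equal(estimate_lod(deg), 1e6)
  expect_error(
    estimate_lod(tibble::tibble(concentration = 1e6, replicate = 1,
                                tfi = 10)),
    class = "evtirf_input_error")
})

test_that("an exactly log-linear series is fit to machine precision", {
  fit <- fit_calibration(noiseless_series(), subtract_baseline = FALSE)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, -3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("slope is recovered within 0.05 under log-normal replicate noise", {
  cfg <- spike_series_config(concentrations = 10^(6:10),
                             response_slope = 0.8,
                             response_intercept_log10 = -3,
                             baseline_tfi_mean = 0, baseline_tfi_sd = 0,
                             rep_noise_log10_sd = 0.05, replicates = 3)
  slopes <- sapply(1:5, function(s) {
    fit_calibration(simulate_spikein_series(cfg, seed = s),
                    subtract_baseline = FALSE)$slope
  })
  expect_true(all(abs(slopes - 0.8) <= 0.05))
})

test_that("excluding the saturated top point restores the linear slope", {
  ser <- noiseless_series(k = 5e9)
  full_fit <- fit_calibration(ser, subtract_baseline = FALSE)
  sub_fit <- fit_calibration(ser, subtract_baseline = FALSE,
                             fit_range = 10^(6:8))
  expect_lt(full_fit$slope, 0.95)  # roll-off drags the pooled slope down
  expect_equal(sub_fit$slope, 1, tolerance = 0.05)
})

test_that("TFI-to-equivalents inverts the fitted line", {
  fit <- fit_calibration(noiseless_series(), subtract_baseline = FALSE)
  expect_equal(tfi_to_equivalents(fit, 1e4)$equivalents, 1e7,
               tolerance = 1e-6)
  # round trip across the series
  ser <- noiseless_series()
  means <- tapply(ser$tfi[ser$concentration > 0],
                  ser$concentration[ser$concentration > 0], mean)
  eq <- tfi_to_equivalents(fit, as.numeric(means))$equivalents
  expect_equal(eq, as.numeric(names(means)), tolerance = 1e-6)
  # below the fitted range -> extrapolation flag
  expect_true(tfi_to_equivalents(fit, 10)$extrapolated)
  zero <- fit; zero$slope <- 0
  expect_error(tfi_to_equivalents(zero, 100),
               class = "evtirf_conversion_error")
})

test_that("LOD never decreases when the blank gets noisier", {
  base <- tibble::tibble(concentration = rep(c(1e6, 1e7, 1e8), each = 2),
                         replicate = rep(1:2, 3),
                         tfi = c(140, 140, 200, 200, 2000, 2000))
  lods <- sapply(c(5, 10, 20, 40), function(bsd) {
    ser <- dplyr::bind_rows(
      tibble::tibble(concentration = 0, replicate = 1:2,
                     tfi = c(100 - bsd, 100 + bsd)),
      base)
    estimate_lod(ser)
  })
  expect_true(all(diff(lods) >= 0))
})

test_that("rescaling TFI shifts the intercept by log10(k) only", {
  ser <- noiseless_series()
  f1 <- fit_calibration(ser, subtract_baseline = FALSE)
  ser2 <- dplyr::mutate(ser, tfi = tfi * 50)
  f2 <- fit_calibration(ser2, subtract_baseline = FALSE)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-9)
  expect_equal(f2$intercept - f1$intercept, log10(50), tolerance = 1e-9)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
})

test_that("tidy and glance expose the fit parameters", {
  fit <- fit_calibration(noiseless_series(), subtract_baseline = FALSE)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "slope"], 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n_points, 5L)
})
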