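test_that("scale-to-period mapping matches the analytical form", {
  a <- sine_actogram(24)
  wf <- cwt_morlet(a, scales = 1:400)
  expect_equal(wf$periods_hours, (1:400) * 360 / (3600 * 1.5))
  expect_equal(wf$periods_hours[400], 26.7, tolerance = 0.01)
  expect_equal(wf$periods_hours[1], 0.0667, tolerance = 0.001)
  expect_true(all(diff(wf$periods_hours) > 0))
  expect_error(cwt_morlet(sine_actogram(24, days = 0.5), scales = 1:400),
               "max scale")
})

test_that("the transform localizes tones and is linear", {
  a12 <- sine_actogram(12)
  wf <- cwt_morlet(a12, scales = seq(60, 300, by = 4))
  power <- rowMeans(Mod(wf$coefficients)^2)
  best <- wf$periods_hours[which.max(power)]
  expect_equal(best, 12, tolerance = 0.5)
  # zero input -> zero coefficients
  z <- cwt_morlet(rep(0, 1000), scales = 1:50, bin_seconds = 360)
  expect_equal(max(Mod(z$coefficients)), 0)
  # linearity
  set.seed(2)
  x <- rnorm(800); y <- rnorm(800)
  wx <- cwt_morlet(x, scales = 1:40, bin_seconds = 360)$coefficients
  wy <- cwt_morlet(y, scales = 1:40, bin_seconds = 360)$coefficients
  wxy <- cwt_morlet(2 * x + 3 * y, scales = 1:40,
                    bin_seconds = 360)$coefficients
  expect_lt(max(Mod(wxy - 2 * wx - 3 * wy)), 1e-8 * max(Mod(wxy)))
})

test_that("peak lags at a tone's scale equal its period", {
  a12 <- sine_actogram(12)
  wf <- cwt_morlet(a12)
  lg <- peak_lag_times(wf, 12)
  expect_equal(lg$mean_lag_hours, 12, tolerance = 0.2)
  expect_equal(lg$n_peaks, 13)  # 2 peaks a day over 6.5 days
  expect_error(peak_lag_times(wf, 50), "outside")
})

test_that("peak count doubles from the 24 h row to its 12 h subharmonic", {
  a <- sine_actogram(c(24, 12), amplitudes = c(10, 10))
  wf <- cwt_morlet(a)
  n24 <- peak_lag_times(wf, 24)$n_peaks
  n12 <- peak_lag_times(wf, 12)$n_peaks
  expect_equal(n24, 7)
  expect_equal(n12, 13)
})

test_that("synchrony is reflexive, symmetric, scale-calibrated", {
  a <- sine_actogram(c(24, 12), amplitudes = c(10, 6), noise_sd = 2,
                     seed = 5)
  wf <- cwt_morlet(a, scales = seq(5, 400, by = 5))
  self <- synchrony(wf, wf)
  expect_equal(self$rho[!is.na(self$rho)], rep(1, sum(!is.na(self$rho))), tolerance = 1e-10)
  # different amplitudes, same phase: rho ~ 1 at the rhythm scale
  b <- sine_actogram(24, amplitudes = 3, noise_sd = 0.5, seed = 6)
  wb <- cwt_morlet(b, scales = seq(5, 400, by = 5))
  s <- synchrony(wf, wb)
  i24 <- which.min(abs(s$period_hours - 24))
  expect_gt(s$rho[i24], 0.95)
  s_rev <- synchrony(wb, wf)
  expect_equal(s$rho, s_rev$rho)
  # positive rescaling leaves the profile unchanged
  b2 <- b; b2$percents <- b2$percents * 2
  expect_equal(synchrony(wf, cwt_morlet(b2, scales = seq(5, 400, by = 5)))$rho,
               s$rho)
  # antiphase 12 h sinusoids anti-correlate at the 12 h scale
  p1 <- cwt_morlet(sine_actogram(12), scales = seq(5, 400, by = 5))
  p2 <- cwt_morlet(sine_actogram(12, phases = pi), scales = seq(5, 400, by = 5))
  sa <- synchrony(p1, p2)
  expect_lt(sa$rho[which.min(abs(sa$period_hours - 12))], -0.95)
  # mismatched grids are rejected
  expect_error(synchrony(wf, cwt_morlet(b, scales = 1:10)), "grids")
})

test_that("group synchrony averages all pairs", {
  a <- sine_actogram(24, noise_sd = 1, seed = 7)
  b <- sine_actogram(24, noise_sd = 1, seed = 8)
  fa <- cwt_morlet(a, scales = seq(10, 200, by = 10))
  fb <- cwt_morlet(b, scales = seq(10, 200, by = 10))
  g2 <- group_synchrony(list(fa, fb))
  expect_equal(g2$rho_mean, synchrony(fa, fb)$rho)
  g3 <- group_synchrony(list(fa, fa, fa))
  expect_equal(max(abs(g3$rho_mean[!is.na(g3$rho_mean)] - 1)), 0, tolerance = 1e-10)
  expect_error(group_synchrony(list(fa)), "at least 2")
})
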