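test_that("power spectrum localizes tones and conserves variance", {
  # pure 24 h sine sampled at 30 s over 6.5 days
  x <- gen_sum_of_sines(rhythm_components(24), 6.5, dt = 30)
  ps <- power_spectrum(x, dt = 30)
  pk <- ps$periods_hours[which.max(ps$power)]
  expect_gt(pk, 22)  # within one frequency bin of 24 h on a 6.5-day record
  expect_lt(pk, 26.5)
  # the 24/12/8 triple yields its three component peaks
  tri <- gen_sum_of_sines(rhythm_components(c(24, 12, 8)), 6.5, dt = 30)
  pst <- power_spectrum(tri, dt = 30)
  top3 <- sort(pst$periods_hours[order(-pst$power)[1:3]])
  # the frequency grid of a 6.5-day record quantizes each period to its
  # nearest resolved cycle count (24 h -> 26 or 22.3 h)
  expect_equal(top3, c(8, 12, 24), tolerance = 0.1)
  # Parseval: one-sided power sums to the population variance
  set.seed(5)
  y <- rnorm(1000)
  psy <- power_spectrum(y, dt = 1)
  expect_equal(sum(psy$power), mean((y - mean(y))^2), tolerance = 1e-9)
  expect_error(power_spectrum(rnorm(8), dt = 1), "too short")
  expect_warning(power_spectrum(rep(3, 100), dt = 1), "constant")
})

test_that("peak significance flags a tone but not noise frequencies", {
  set.seed(21)
  n <- 2048
  x <- 5 * sin(2 * pi * (1:n) / 64) + rnorm(n, sd = 0.5)
  ps <- peak_significance(power_spectrum(x, dt = 1), alpha_level = 0.001)
  tone_bin <- which.min(abs(ps$frequency_hz - 1 / 64))
  expect_true(ps$significant[tone_bin])
  expect_lte(sum(ps$significant[-tone_bin]), 2)  # ~1 false flag per 1000
  # constant (zero-variance) series: nothing flagged
  suppressWarnings({
    pz <- peak_significance(power_spectrum(rep(1, 100), dt = 1), 0.001)
  })
  expect_false(any(pz$significant))
  # sidak correction is stricter than per-frequency flagging
  ps2 <- peak_significance(power_spectrum(x, dt = 1), 0.05, "sidak")
  ps3 <- peak_significance(power_spectrum(x, dt = 1), 0.05, "none")
  expect_lte(sum(ps2$significant), sum(ps3$significant))
})

test_that("spectral slope recovers beta = 2 alpha - 1 on fGn", {
  b <- vapply(1:5, function(s)
    spectral_slope(power_spectrum(gen_fgn(0.85, 2^15, seed = s), dt = 1))$beta,
    numeric(1))
  expect_equal(mean(b), 0.7, tolerance = 0.1)
  bw <- vapply(1:5, function(s)
    spectral_slope(power_spectrum(gen_fgn(0.5, 2^15, seed = 10 + s),
                                  dt = 1))$beta, numeric(1))
  expect_equal(mean(bw), 0, tolerance = 0.1)
  ps <- power_spectrum(rnorm(256), dt = 1)
  expect_error(spectral_slope(ps, fit_range = c(1e6, 1e7)), "fewer than 10")
})

test_that("Q_P reaches its closed-form maximum on an exact periodic signal", {
  # exact period-12 square wave, 40 repeats: within-column variance is zero,
  # so Q_P = N at the true period
  x <- rep(rep(c(0, 60), each = 6), 40)
  en <- enright_periodogram(x, periods = 2:240)
  expect_equal(en$qp[en$period_bins == 12], length(x))
  expect_true(en$significant[en$period_bins == 12])
  # harmonics of the folding period also reach the maximum; off-periods do not
  expect_lt(en$qp[en$period_bins == 13], 0.2 * length(x))
  expect_error(enright_periodogram(rep(2, 100)), "constant")
})

test_that("Q_P is invariant to offset and scale of the actogram", {
  set.seed(8)
  x <- rnorm(600)
  q1 <- enright_periodogram(x, periods = 2:100)$qp
  q2 <- enright_periodogram(5 + 3 * x, periods = 2:100)$qp
  expect_equal(q1, q2, tolerance = 1e-10)
})

test_that("Enright flags rhythm periods in synthetic actograms", {
  a <- sine_actogram(c(24, 12), amplitudes = c(10, 8), noise_sd = 1,
                     seed = 13)
  en <- enright_periodogram(a)
  expect_true(en$significant[en$period_bins == 240])
  expect_true(en$significant[en$period_bins == 120])
  expect_equal(en$periods_hours[en$period_bins == 240], 24)
})

test_that("peak selection sorts ascending and removes integer multiples", {
  # peaks at 6, 12, 24 h (60/120/240 six-minute bins): only 6 h survives
  r <- fake_enright(c(60, 120, 240), c(50, 80, 100))
  sel <- enright_select_peaks(r)
  expect_equal(sel$period_bins, 60)
  # 8 h and 12 h: neither is a multiple of the other
  r2 <- fake_enright(c(80, 120), c(90, 100))
  expect_equal(enright_select_peaks(r2)$period_bins, c(80, 120))
  # single peak survives
  r3 <- fake_enright(200, 50)
  expect_equal(enright_select_peaks(r3)$period_bins, 200)
  # sub-threshold local maxima (< 10% of max) are dropped
  r4 <- fake_enright(c(60, 150), c(5, 100))
  expect_equal(enright_select_peaks(r4)$period_bins, 150)
  # output is an anti-chain under the integer-multiple relation
  set.seed(4)
  pb <- sort(sample(10:395, 25))
  r5 <- fake_enright(pb, runif(25, 20, 100))
  keep <- enright_select_peaks(r5)$period_bins
  for (i in seq_along(keep))
    for (j in seq_along(keep))
      if (i != j && keep[j] > keep[i]) {
        m <- round(keep[j] / keep[i])
        expect_false(m >= 2 && abs(keep[j] - m * keep[i]) <= 0.5)
      }
})
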