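test_that("event extraction applies run lengths and the 1 s threshold", {
  s <- locomotion_series(c(1, 0, 0, 0, 1))
  expect_equal(as.numeric(extract_events(s, "immobile")), 1.5)
  # 1.0 s is not > 1 s
  s2 <- locomotion_series(c(1, 0, 0, 1))
  expect_length(extract_events(s2, "immobile"), 0)
  # runs at record boundaries are censored
  s3 <- locomotion_series(c(0, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0))
  expect_equal(as.numeric(extract_events(s3, "immobile")), 1.5)
  # runs touching an excluded gap are censored, not bridged
  v <- c(1, 0, 0, 0, 0, 1, 1, 0, 0, 0, 1)
  excl <- rep(FALSE, 11); excl[6:7] <- TRUE
  s4 <- locomotion_series(v, excluded = excl)
  expect_length(extract_events(s4, "immobile"), 0)
})

test_that("bout table conserves total recording time", {
  set.seed(33)
  v <- rbinom(20000, 1, 0.3)
  excl <- rep(FALSE, 20000); excl[5001:5500] <- TRUE
  s <- locomotion_series(v, excluded = excl)
  bt <- bout_table(s)
  expect_equal(sum(bt$duration_s) + 500 * s$dt, 20000 * s$dt)
  # uncensored immobility durations match extract_events
  d1 <- sort(bt$duration_s[bt$kind == "immobile" & !bt$censored &
                             bt$duration_s > 1])
  expect_equal(d1, sort(as.numeric(extract_events(s, "immobile"))))
})

test_that("generator bout means transfer to extracted events", {
  spec <- synthetic_spec(components = rhythm_components(24, amplitude = 0),
                         noise_sd = 0, trend_amplitude = 0, duration = 2,
                         seed = 5)
  ser <- gen_fractal_locomotion(spec)
  dur <- extract_events(ser, "immobile", min_duration = 0)
  grid <- seq(1, 250, by = 0.5)
  target_mean <- sum(grid * grid^-1.5) / sum(grid^-1.5)
  expect_equal(mean(dur), target_mean, tolerance = 0.05 * target_mean)
})

test_that("FDD fit recovers a known power-law slope", {
  set.seed(12)
  dur <- rbout_powerlaw(1e4, -1.5, c(1, 250), resolution = 1)
  f <- fdd_fit(dur, bin_seconds = 1, fit_range = c(1, 250))
  expect_equal(f$slope_S, -1.5, tolerance = 0.15)
  expect_gt(f$r_squared, 0.85)
  expect_equal(f$bin_seconds, 1)
  # exponential durations prefer the exponential fit
  set.seed(13)
  de <- round(rexp(1e4, 1 / 15)) + 1
  fp <- fdd_fit(de, fit_kind = "power_law")
  fe <- fdd_fit(de, fit_kind = "exponential")
  expect_gt(fe$r_squared, fp$r_squared)
  # degenerate histogram
  expect_error(fdd_fit(rep(10, 100)), "bins")
  expect_error(fdd_fit(rbout_powerlaw(30, -1.5)), "at least 50")
})

test_that("shuffling destroys the power law in favor of an exponential", {
  pl_r2 <- exp_r2 <- numeric(3)
  for (s in 1:3) {
    spec <- synthetic_spec(components = rhythm_components(24, amplitude = 0),
                           noise_sd = 0, trend_amplitude = 0, duration = 1.5,
                           seed = 40 + s)
    ser <- gen_fractal_locomotion(spec)
    sh <- randomize_series(ser, seed = 50 + s)
    dur <- extract_events(sh, "immobile")
    pl_r2[s] <- fdd_fit(dur, fit_kind = "power_law")$r_squared
    exp_r2[s] <- fdd_fit(dur, fit_kind = "exponential")$r_squared
  }
  expect_true(all(exp_r2 > pl_r2))
  expect_true(all(exp_r2 > 0.8))
})

test_that("bin-size sensitivity reports slopes per bin and flags the regime", {
  set.seed(14)
  dur <- rbout_powerlaw(2e4, -1.5, c(1, 250), resolution = 0.5)
  tab <- bin_size_sensitivity(dur, bin_grid = c(0.5, 1, 5, 10, 60))
  pl <- tab[tab$fit_kind == "power_law", ]
  expect_true(all(pl$r_squared > 0.85))
  # slope depends on bin width
  expect_gt(abs(pl$S[pl$bin_seconds == 1] - pl$S[pl$bin_seconds == 5]), 0)
  expect_true(all(pl$beyond_mean_duration == (pl$bin_seconds > mean(dur))))
  one <- bin_size_sensitivity(dur, bin_grid = 1, fit_kind = "power_law")
  expect_equal(nrow(one), 1)
  expect_equal(one$S, fdd_fit(dur, 1)$slope_S)
})
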