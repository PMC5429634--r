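test_that("sum-of-sines matches the closed-form construction", {
  # single 24 h sine over 6.5 days, phase 0: maxima at 6, 30, ..., 150 h -> 7
  s <- gen_sum_of_sines(rhythm_components(24), duration = 6.5, dt = 30)
  n_max <- sum(diff(sign(diff(s))) < 0)
  expect_equal(n_max, 7)
  # phase pi shifts maxima to 18, 42, ..., 138 h -> 6
  s2 <- gen_sum_of_sines(rhythm_components(24, phase = pi), 6.5, dt = 30)
  expect_equal(sum(diff(sign(diff(s2))) < 0), 6)
  # antiphase equal sines cancel exactly
  z <- gen_sum_of_sines(rhythm_components(c(12, 12), phase = c(0, pi)),
                        1, dt = 30)
  expect_lt(max(abs(z)), 1e-12)
  # periodicity at the fundamental (24 h) for the 24/12/8 triple
  tri <- gen_sum_of_sines(rhythm_components(c(24, 12, 8)), 3, dt = 30)
  shift <- 24 * 3600 / 30
  expect_lt(max(abs(tri[-(1:shift)] - tri[seq_len(length(tri) - shift)])),
            1e-9)
  expect_error(gen_sum_of_sines(rhythm_components(24), duration = 0), "duration")
  expect_error(rhythm_components(0), "positive")
})

test_that("fGn generator is reproducible and hits the white-noise limit", {
  x1 <- gen_fgn(0.85, 2^12, seed = 9)
  x2 <- gen_fgn(0.85, 2^12, seed = 9)
  expect_identical(x1, x2)
  expect_equal(mean(x1), 0, tolerance = 1e-10)
  expect_equal(sd(x1), 1, tolerance = 1e-10)
  expect_error(gen_fgn(0.85, 512), "too small")
  expect_error(gen_fgn(1.5, 2^12), "alpha_target")
  # white-noise limit: DFA3 exponent 0.5 +/- 0.05
  a <- dfa(gen_fgn(0.5, 2^16, seed = 3), order = 3)$alpha
  expect_equal(a, 0.5, tolerance = 0.05)
})

test_that("fractal locomotion series has the prescribed bout law", {
  spec <- synthetic_spec(components = rhythm_components(24, amplitude = 0),
                         noise_sd = 0, trend_amplitude = 0, duration = 2,
                         seed = 7)
  ser <- gen_fractal_locomotion(spec)
  expect_s3_class(ser, "locomotion_series")
  expect_equal(length(ser$values), 2 * 86400 / 0.5)
  # empirical immobile-bout CDF vs the target truncated power law
  dur <- extract_events(ser, "immobile", min_duration = 0)
  expect_gt(length(dur), 5e3)
  grid <- seq(1, 250, by = 0.5)
  p <- grid^-1.5; cdf <- cumsum(p) / sum(p)
  ks <- max(abs(ecdf(dur)(grid) - cdf))
  expect_lt(ks, 0.05)
  # reproducibility under the same spec
  ser2 <- gen_fractal_locomotion(spec)
  expect_identical(ser$values, ser2$values)
})

test_that("realized mean activity tracks the requested fraction", {
  ser <- gen_fractal_locomotion(synthetic_spec(seed = 31))
  h <- percent_ambulating_hourly(ser)
  expect_equal(mean(h), 25, tolerance = 3)
  # infeasible request is reported with the achievable range
  expect_error(gen_fractal_locomotion(
    synthetic_spec(mean_activity = 1e-5, seed = 1)), "achievable")
})

test_that("randomization permutes values and preserves their multiset", {
  ones <- locomotion_series(rep(1, 100))
  expect_equal(randomize_series(ones, seed = 1)$values, rep(1, 100))
  set.seed(11)
  s <- locomotion_series(rbinom(5000, 1, 0.3))
  r <- randomize_series(s, seed = 2)
  expect_equal(sum(r$values), sum(s$values))
  expect_false(identical(r$values, s$values))
  # excluded positions keep their values untouched
  excl <- rep(FALSE, 5000); excl[1:100] <- TRUE
  s2 <- locomotion_series(c(rep(1, 100), rbinom(4900, 1, 0.3)),
                          excluded = excl)
  r2 <- randomize_series(s2, seed = 3)
  expect_equal(r2$values[1:100], rep(1, 100))
})
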