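test_that("DFA recovers the uncorrelated limit on Bernoulli series", {
  set.seed(19)
  x <- rbinom(2^16, 1, 0.5)
  d <- dfa(x, order = 3)
  expect_equal(d$alpha, 0.5, tolerance = 0.05)
  expect_gt(d$r_squared, 0.99)
  expect_error(dfa(rep(1, 1000)), "constant")
})

test_that("DFA matches the fGn generator across the study's exponent range", {
  for (a in c(0.7, 1.0)) {
    est <- vapply(1:3, function(s)
      dfa(gen_fgn(a, 2^16, seed = 100 * a + s), order = 3)$alpha, numeric(1))
    expect_equal(mean(est), a, tolerance = 0.05)
  }
})

test_that("fluctuation function is non-decreasing and refit works", {
  x <- gen_fgn(0.85, 2^15, seed = 77)
  d <- dfa(x, order = 3)
  expect_true(all(diff(d$fluctuations) > 0))
  d2 <- dfa_refit(d, fit_range = c(100, 2000))
  expect_gte(d2$fit_range[1], 100)
  expect_lte(d2$fit_range[2], 2000)
  expect_error(dfa_refit(d, c(1, 2)), "fewer than 3")
})

test_that("detrending order: cubic trends need order >= 3", {
  n <- 2^15
  tt <- seq(0, 1, length.out = n)
  trend <- 80 * (tt - 0.3)^3
  a1 <- a3 <- a4 <- numeric(3)
  for (s in 1:3) {
    x <- gen_fgn(0.8, n, seed = 500 + s)
    a1[s] <- dfa(x + trend, 1)$alpha
    a3[s] <- dfa(x + trend, 3)$alpha
    a4[s] <- dfa(x + trend, 4)$alpha
  }
  expect_gt(mean(a1) - 0.8, 0.1)          # order 1 is corrupted by the trend
  expect_equal(mean(a3), 0.8, tolerance = 0.05)
  expect_equal(mean(a4), 0.8, tolerance = 0.05)
  # trend-free orders agree
  x <- gen_fgn(0.85, n, seed = 600)
  expect_lt(abs(dfa(x, 2)$alpha - dfa(x, 3)$alpha), 0.05)
})

test_that("alpha is robust to 30% random data loss", {
  for (a in c(0.7, 1.0)) {
    x <- gen_fgn(a, 2^16, seed = 700 + 10 * a)
    set.seed(701)
    keep <- sort(sample(length(x), round(0.7 * length(x))))
    expect_lt(abs(dfa(x[keep], 3)$alpha - dfa(x, 3)$alpha), 0.05)
  }
})

test_that("beta and alpha satisfy the 2 alpha - 1 identity", {
  for (a in c(0.5, 0.85)) {
    x <- gen_fgn(a, 2^15, seed = 800 + 100 * a)
    beta <- spectral_slope(power_spectrum(x, dt = 1))$beta
    alpha <- dfa(x, 3)$alpha
    expect_lt(abs(beta - (2 * alpha - 1)), 0.15)
  }
})

test_that("scaling-range selection finds crossovers", {
  ws <- round(exp(seq(log(10), log(10000), length.out = 20)))
  # exact power law: full range selected
  d <- fake_dfa(ws, 0.3 * ws^0.85)
  sel <- select_scaling_range(d)
  expect_equal(sel$fit_range, range(ws))
  expect_false(sel$flagged)
  # two-slope crossover at n* = 500: selected range ends near n*
  nstar <- 500
  f2 <- ifelse(ws <= nstar, ws^0.9, nstar^(0.9 - 0.3) * ws^0.3)
  sel2 <- select_scaling_range(fake_dfa(ws, f2))
  expect_true(sel2$flagged)
  log_step <- diff(log(ws))[1]
  expect_lt(abs(log(sel2$fit_range[2]) - log(nstar)), 1.5 * log_step)
  # white noise: the selected range typically covers most of the log-range
  spans <- vapply(1:10, function(s) {
    set.seed(s)
    dw <- dfa(rnorm(2^16), order = 3)
    selw <- select_scaling_range(dw)
    diff(log(selw$fit_range)) / diff(log(range(dw$window_sizes)))
  }, numeric(1))
  expect_gte(median(spans), 0.8)
  expect_error(select_scaling_range(fake_dfa(ws[1:5], ws[1:5])), ">= 10")
})

test_that("comb moving-average filter removes its own period exactly", {
  expect_equal(moving_average_filter(rep(4.2, 5000), 0.5, dt = 1),
               rep(0, 5000))
  per <- 23.5 * 3600
  x <- 3 * sin(2 * pi * (1:250000) / per) + 7
  r <- moving_average_filter(x, 23.5, dt = 1)
  expect_lt(max(abs(r)), 0.05 * 3)
  expect_error(moving_average_filter(1:10, 23.5, dt = 1), "longer")
})

test_that("filtering leaves the scaling exponent essentially unchanged", {
  ws <- unique(round(exp(seq(log(8), log(4.4 * 3600 / 4), length.out = 18))))
  a0 <- af <- numeric(4)
  alphas <- c(0.65, 0.75, 0.85, 0.95)
  for (i in seq_along(alphas)) {
    rhythm <- gen_sum_of_sines(rhythm_components(c(24, 12),
                                                 amplitude = c(2, 1)),
                               duration = 6.1, dt = 4)
    x <- rhythm[1:2^17] + gen_fgn(alphas[i], 2^17, seed = 900 + i)
    a0[i] <- dfa(x, 3, window_sizes = ws)$alpha
    af[i] <- dfa(moving_average_filter(x, 23.5, dt = 4), 3,
                 window_sizes = ws)$alpha
  }
  expect_lt(max(abs(af - a0)), 0.05)
  expect_gt(cor(a0, af), 0.9)
})
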