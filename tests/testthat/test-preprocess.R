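test_that("realized bandpass meets the stopband spec at both edges", {
  spec <- design_bandpass(1000, 0.4, 8)
  # frequency-response oracle: evaluate |H| on a dense grid straight from
  # the pole-zero form and compare band edges against mid-passband
  mid <- filter_response(spec, 2)
  tol <- 1e-6   # the design places exactly -20 dB at the band edges
  expect_lte(20 * log10(filter_response(spec, 0.4) / mid), -20 + tol)
  expect_lte(20 * log10(filter_response(spec, 8) / mid), -20 + tol)
  expect_lte(20 * log10(filter_response(spec, 50) / mid), -20 + tol)
  # passband essentially flat
  f_pass <- seq(1, 4, by = 0.25)
  expect_true(all(abs(20 * log10(filter_response(spec, f_pass) / mid)) < 0.5))
  # stability of the cascade realization
  expect_true(all(Mod(spec$pole) < 1))
})

test_that("bandpass design rejects invalid cutoffs", {
  expect_ppg_error(design_bandpass(1000, 8, 0.4), "ppg_parameter_error")
  expect_ppg_error(design_bandpass(1000, 0.4, 600), "ppg_nyquist_error")
})

test_that("zero-phase filtering removes DC, passes the band, stops 50 Hz", {
  spec <- design_bandpass(1000, 0.4, 8)
  t <- (0:2099) / 1000
  dc <- apply_filter(rep(5, 2100), spec)
  expect_lt(max(abs(dc[200:1900])), 0.05)
  inband <- apply_filter(sin(2 * pi * 1 * t), spec)
  expect_lt(abs(max(abs(inband[400:1700])) - 1), 0.1)
  mains <- apply_filter(sin(2 * pi * 50 * t), spec)
  expect_lt(max(abs(mains[400:1700])), 10^(-20 / 20))
})

test_that("filtering is zero-phase: a symmetric pulse keeps its peak", {
  spec <- design_bandpass(1000, 0.4, 8)
  x <- exp(-((0:2099) - 1050)^2 / (2 * 60^2))
  y <- apply_filter(x, spec)
  expect_lte(abs(which.max(y) - 1051), 1)
})

test_that("apply_filter rejects too-short or missing input", {
  spec <- design_bandpass(1000, 0.4, 8)
  expect_ppg_error(apply_filter(rnorm(10), spec), "ppg_length_error")
  expect_ppg_error(apply_filter(c(rnorm(100), NA), spec), "ppg_parse_error")
})

test_that("moving_average matches centered edge-shrinking semantics", {
  expect_identical(moving_average(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  expect_equal(moving_average(rep(2.5, 40), 7), rep(2.5, 40))
  expect_equal(moving_average(c(1, 2, 3, 4), 3), c(1.5, 2, 3, 3.5))
  expect_ppg_error(moving_average(1:10, 0), "ppg_parameter_error")
})

test_that("moving_average stays within the input's range", {
  set.seed(7)
  for (w in c(2, 5, 12)) {
    x <- rnorm(200)
    y <- moving_average(x, w)
    expect_gte(min(y), min(x))
    expect_lte(max(y), max(x))
  }
})

test_that("derivatives agree with direct difference formulas", {
  set.seed(11)
  y <- cumsum(rnorm(500))
  st <- compute_derivatives(y, smooth_window = 1)
  n <- length(y)
  i <- 2:(n - 4)
  # first difference, left-aligned
  expect_equal(st$vpg[i], y[i + 1] - y[i], tolerance = 1e-12)
  # second difference: the centered form evaluated one sample ahead of the
  # left-aligned assignment
  expect_equal(st$apg[i], y[i + 2] - 2 * y[i + 1] + y[i], tolerance = 1e-12)
  # third difference (iterated diff, binomial weights)
  expect_equal(st$jpg[i], y[i + 3] - 3 * y[i + 2] + 3 * y[i + 1] - y[i],
               tolerance = 1e-12)
})

test_that("derivatives of simple signals behave as calculus dictates", {
  ramp <- compute_derivatives(as.numeric(0:99), 1)
  expect_equal(ramp$vpg[1:98], rep(1, 98))
  expect_equal(ramp$apg[1:97], rep(0, 97))
  expect_equal(ramp$jpg[1:96], rep(0, 96))
  const <- compute_derivatives(rep(3.3, 50), 1)
  expect_true(all(const$vpg == 0) && all(const$apg == 0) && all(const$jpg == 0))
  expect_ppg_error(compute_derivatives(c(1, 2, 3)), "ppg_length_error")
})

test_that("the derivative stack is linear in its input", {
  set.seed(3)
  x <- rnorm(300); y <- rnorm(300)
  a <- 1.7; b <- -0.4
  s_mix <- compute_derivatives(a * x + b * y, smooth_window = 5)
  s_x <- compute_derivatives(x, smooth_window = 5)
  s_y <- compute_derivatives(y, smooth_window = 5)
  for (w in c("vpg", "apg", "jpg"))
    expect_equal(s_mix[[w]], a * s_x[[w]] + b * s_y[[w]], tolerance = 1e-12)
})
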