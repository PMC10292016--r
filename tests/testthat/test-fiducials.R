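test_that("zero crossings follow the stated sign-regime convention", {
  expect_identical(zero_crossings(c(1, 1, -1, -1, 1)), c(3L, 5L))
  expect_identical(zero_crossings(c(1, 2, 3)), integer(0))
  # exact zeros belong to the following regime
  expect_identical(zero_crossings(c(1, 0, -1)), 2L)
  expect_identical(zero_crossings(c(1, 0, 1)), integer(0))
  expect_identical(zero_crossings(c(1, 1, -1, -1, 1), start = 4), 5L)
})

test_that("zero crossings of a sampled sine sit at the analytic roots", {
  fs <- 1000
  t <- (0:999) / fs
  x <- sin(2 * pi * 2 * t + 0.3)     # two full cycles
  got <- zero_crossings(x)
  roots <- (pi * (1:4) - 0.3) / (2 * pi * 2)       # analytic root oracle
  expected <- ceiling(roots * fs) + 1   # first sample of the new sign regime
  expect_length(got, 4)
  expect_true(all(abs(got - expected) <= 1))
})

test_that("O and S are the segment onset and global maximum", {
  expect_identical(detect_O_S(c(0, 1, 2, 1, 0)), list(O = 1L, S = 3L))
  expect_ppg_error(detect_O_S(rep(2, 10)), "ppg_degenerate_error")
})

test_that("a and b locate the early systolic APG excursion", {
  apg <- c(0, 3, 0, -2, 0, 1, 0.5, 0, -0.2, 0)
  ab <- detect_ab(apg)
  expect_identical(ab$a, 2L)
  expect_identical(ab$b, 4L)
  expect_ppg_error(detect_ab(as.numeric(1:10)), "ppg_detection_error")
})

test_that("N/D map from e/f as an identity on the shared grid", {
  expect_identical(map_ND(612, 701), list(N = 612L, D = 701L))
  expect_ppg_error(map_ND(701, 701), "ppg_parameter_error")
})

test_that("the three synthetic archetypes classify as their cases", {
  for (cs in c("I", "II", "III")) {
    beat <- simulate_beat(case_params(cs))
    expect_identical(beat$truth$case, cs)
    fid <- extract_fiducials(compute_derivatives(beat$samples, 1, 1000))
    expect_true(fid$ok)
    expect_identical(fid$case, cs)
  }
})

test_that("Case II c/d arithmetic applies the +/- 2.5% wavelength rule", {
  # crafted jerk: a deep first minimum before b, the counted second minimum
  # at index 400 inside (b, e); flat APG so no Case III extrema interfere
  T <- 800
  jpg <- rep(0.5, T)
  jpg[140:160] <- -5                      # first minimum (pre-b trough)
  jpg[390:410] <- 0.5 - 3 * exp(-((390:410) - 400)^2 / 18)  # second dip
  jpg[400] <- -3                          # unambiguous minimum at 400
  apg <- seq(-1, 1, length.out = T)       # monotone: no APG extrema
  res <- locate_cd("II", apg, jpg, b = 200, e = 700, T = T)
  expect_identical(res$cd_present, 1L)
  expect_identical(res$c, as.integer(400 - round(0.025 * T)))
  expect_identical(res$d, as.integer(400 + round(0.025 * T)))
  expect_identical(res$c, 380L)
  expect_identical(res$d, 420L)
})

test_that("locate_cd never hard-fails when structure is absent", {
  apg <- seq(-1, 1, length.out = 500)
  jpg <- rep(1, 500)
  res <- locate_cd("II", apg, jpg, b = 100, e = 400, T = 500)
  expect_identical(res$cd_present, 0L)
  expect_true(is.na(res$c) && is.na(res$d))
  expect_ppg_error(locate_cd("II", apg, jpg, 400, 100, 500), "ppg_parameter_error")
})

test_that("fiducial ordering invariants hold across a generated ensemble", {
  set.seed(21)
  for (r in 1:9) {
    cs <- sample(c("I", "II", "III"), 1)
    p <- case_params(cs, length_s = runif(1, 1.02, 1.12),
                     systolic_amp = runif(1, 0.85, 1.2))
    beat <- simulate_beat(p)
    fid <- extract_fiducials(compute_derivatives(beat$samples, 1, 1000))
    expect_true(fid$ok)
    i <- fid$indices
    expect_true(i[["O"]] <= i[["w"]] && i[["w"]] < i[["S"]])
    expect_identical(i[["x"]], i[["S"]])
    expect_true(i[["S"]] < i[["y"]])
    expect_true(i[["a"]] < i[["b"]] && i[["b"]] < i[["e"]] && i[["e"]] < i[["f"]])
    expect_identical(i[["N"]], i[["e"]])
    expect_identical(i[["D"]], i[["f"]])
    if (fid$cd_present == 1L)
      expect_true(i[["b"]] < i[["c"]] && i[["c"]] <= i[["d"]] && i[["d"]] < i[["e"]])
  }
})

test_that("amplitudes equal the owning waveform at the stored indices", {
  beat <- simulate_beat(case_params("III"))
  stack <- compute_derivatives(beat$samples, 1, 1000)
  fid <- extract_fiducials(stack)
  owner <- c(O = "ppg", S = "ppg", N = "ppg", D = "ppg",
             w = "vpg", x = "vpg", y = "vpg", z = "vpg",
             a = "apg", b = "apg", c = "apg", d = "apg", e = "apg", f = "apg")
  for (p in names(owner)) {
    i <- fid$indices[[p]]
    if (!is.na(i))
      expect_identical(fid$amplitudes[[p]], stack[[owner[[p]]]][i])
  }
  # velocity sign structure: steep rise at w, steep fall at y
  expect_gt(fid$amplitudes[["w"]], 0)
  expect_lt(fid$amplitudes[["y"]], 0)
})

test_that("fiducials are equivariant to a time shift of the beat", {
  p <- case_params("I")
  model <- ppgfiducial:::gauss_model(p)
  n <- round(p$length_s * 1000)
  k <- 7L
  s1 <- model$g((seq_len(n) - 1) / 1000)
  s2 <- model$g((seq_len(n) - 1 - k) / 1000)   # same waveform, k samples later
  f1 <- extract_fiducials(compute_derivatives(s1, 1, 1000))
  f2 <- extract_fiducials(compute_derivatives(s2, 1, 1000))
  common <- !is.na(f1$indices) & !is.na(f2$indices)
  expect_true(all(abs((f2$indices - f1$indices)[common] - k)[
    names(f1$indices)[common] != "O"] <= 1))
})

test_that("degenerate beats yield an invalid flag, not an error", {
  stack <- compute_derivatives(rep(1, 500) + c(rep(0, 499), 1e-9), 1, 1000)
  fid <- extract_fiducials(stack, subject_id = "S099")
  expect_false(fid$ok)
  expect_match(fid$message, "S099")
  expect_true(all(is.na(fid$indices)))
})

test_that("Case III classification is stable under tiny noise", {
  beat <- simulate_beat(case_params("III"))
  stack0 <- compute_derivatives(beat$samples, 1, 1000)
  f0 <- extract_fiducials(stack0)
  expect_identical(f0$case, "III")
  set.seed(4)
  for (r in 1:3) {
    noisy <- beat$samples +
      rnorm(length(beat$samples), 0, 1e-4 * diff(range(beat$samples)))
    fr <- extract_fiducials(compute_derivatives(noisy, 5, 1000))
    expect_identical(fr$case, "III")
  }
})
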