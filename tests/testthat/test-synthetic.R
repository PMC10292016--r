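test_that("a single dominant pulse peaks at its center with zero velocity", {
  p <- beat_params(systolic_amp = 1, systolic_center = 0.3,
                   shoulder_amp = 0, bump_amp = 0,
                   diastolic_amp = 1e-9, diastolic_center = 0.7,
                   tail_amp = 0)
  beat <- simulate_beat(p, fs = 1000)
  ctr <- round(0.3 * p$length_s * 1000) + 1
  expect_lte(abs(which.max(beat$samples) - ctr), 1)
  vpg <- compute_derivatives(beat$samples, 1, 1000)$vpg
  expect_lte(abs(zero_crossings(vpg)[1] - ctr), 2)
})

test_that("simulate_beat is deterministic and internally consistent", {
  p <- case_params("I")
  b1 <- simulate_beat(p); b2 <- simulate_beat(p)
  expect_identical(b1$samples, b2$samples)
  expect_identical(b1$truth$indices, b2$truth$indices)
  i <- b1$truth$indices
  expect_true(i[["a"]] < i[["b"]] && i[["b"]] < i[["e"]] && i[["e"]] < i[["f"]])
  expect_identical(i[["N"]], i[["e"]])
})

test_that("ground truth and detection agree on the noiseless sampled beat", {
  # end-to-end sanity oracle: the truth comes from dense search on the
  # continuous model, detection from the sampled discrete pipeline
  set.seed(31)
  for (cs in c("I", "II", "III")) for (r in 1:2) {
    p <- case_params(cs, length_s = runif(1, 1.02, 1.12),
                     systolic_amp = runif(1, 0.85, 1.2))
    beat <- simulate_beat(p)
    fid <- extract_fiducials(compute_derivatives(beat$samples, 1, 1000))
    expect_true(fid$ok)
    err <- abs(fid$indices - beat$truth$indices)
    expect_lte(max(err, na.rm = TRUE), 3)
    expect_identical(fid$case, beat$truth$case)
    expect_identical(fid$cd_present, beat$truth$cd_present)
  }
})

test_that("records have the requested shape and clean limit", {
  rec <- simulate_record(n_beats = 3, params = beat_params(), noise_sd = 0,
                         drift = c(0, 0.25))
  expect_length(rec$samples, 2100)
  expect_identical(rec$samples, rec$clean)
  expect_gte(length(rec$truths), 1)
  expect_identical(length(rec$onsets), 2L)
  expect_ppg_error(simulate_record(noise_sd = -1), "ppg_parameter_error")
  expect_ppg_error(simulate_record(n_beats = 0), "ppg_parameter_error")
})

test_that("noise and drift alter neither record length nor the truth", {
  p <- case_params("III")
  clean <- simulate_record(params = p)
  noisy <- simulate_record(params = p, noise_sd = 0.05, drift = c(0.1, 0.25),
                           seed = 9)
  expect_length(noisy$samples, 2100)
  expect_identical(noisy$truths[[1]]$indices, clean$truths[[1]]$indices)
  expect_identical(noisy$onsets, clean$onsets)
  expect_false(identical(noisy$samples, clean$samples))
})

test_that("per-beat truths are offset to record coordinates", {
  p <- case_params("II")
  rec <- simulate_record(params = p)
  tr <- rec$truths[[1]]
  expect_identical(tr$indices[["O"]], rec$onsets[1])
  expect_true(all(tr$indices <= rec$onsets[2], na.rm = TRUE))
})

test_that("the skewness SQI of default records clears the threshold", {
  for (cs in c("I", "II", "III"))
    expect_gt(skewness_sqi(clean_record(cs)$samples), 0.41)
})

test_that("benchmarks are seeded, sized and mixed as requested", {
  b1 <- make_benchmark(n_subjects = 24, seed = 5)
  b2 <- make_benchmark(n_subjects = 24, seed = 5)
  expect_identical(b1$dataset$x, b2$dataset$x)
  expect_identical(b1$reference, b2$reference)
  expect_identical(dim(b1$dataset$x), c(24L, 2100L))
  expect_identical(nrow(b1$reference), 24L)
  # single-case benchmark
  b3 <- make_benchmark(n_subjects = 1, case_mix = c(I = 0, II = 0, III = 1),
                       seed = 2)
  expect_identical(b3$reference$case, "III")
  expect_ppg_error(make_benchmark(0), "ppg_parameter_error")
  expect_ppg_error(make_benchmark(5, case_mix = c(0.9, 0.9, 0.1)),
                   "ppg_parameter_error")
})

test_that("the default case mix approximates the 140/54/25 proportions", {
  b <- make_benchmark(n_subjects = 219, seed = 13, snr_db = Inf)
  counts <- table(factor(b$reference$case, levels = c("I", "II", "III")))
  expected <- c(140, 54, 25)
  # multinomial tolerance: four standard deviations
  sds <- sqrt(expected * (1 - expected / 219))
  expect_true(all(abs(as.numeric(counts) - expected) <= 4 * sds))
})

test_that("generator rejects degenerate morphology", {
  expect_ppg_error(beat_params(systolic_amp = 0, shoulder_amp = 0,
                               bump_amp = 0, diastolic_amp = 0.2,
                               tail_amp = 0),
                   "ppg_parameter_error")
  expect_ppg_error(beat_params(length_s = -1), "ppg_parameter_error")
})
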