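#' Parameters of the synthetic beat model
#'
#' A synthetic PPG beat is a sum of Gaussian pulses on the beat interval:
#' a systolic pulse, an optional late-systolic bump (whose amplitude controls
#' how prominent the APG c and d waves are, steering the beat between the
#' three morphology cases), and a diastolic pulse that forms the dicrotic
#' shoulder.  Centers and widths are expressed as fractions of the beat
#' length.
#'
#' A decay "shoulder" pulse after the systolic peak makes the upstroke much
#' steeper than the decline, as in real pulses, which is what puts the APG
#' a/b waves unambiguously on the upstroke side.
#'
#' @param length_s beat length in seconds (default 1.08, ~56 bpm).
#' @param systolic_amp,systolic_center,systolic_width systolic pulse
#'   (amplitude in a.u., center and width as beat fractions).
#' @param shoulder_amp,shoulder_center,shoulder_width systolic decay
#'   shoulder.
#' @param bump_amp,bump_center,bump_width late-systolic bump; `bump_amp = 0`
#'   removes it.
#' @param diastolic_amp,diastolic_center,diastolic_width diastolic pulse.
#' @param tail_amp,tail_center,tail_width slow diastolic runoff wave; it
#'   feeds the inter-beat valley so that consecutive beats meet in a sharp,
#'   well-conditioned onset minimum.
#' @return object of class `"beat_params"`.
#' @seealso [case_params()] for the three calibrated morphology presets.
#' @export
beat_params <- function(length_s = 1.08,
                        systolic_amp = 1, systolic_center = 0.20,
                        systolic_width = 0.08,
                        shoulder_amp = 0.60, shoulder_center = 0.30,
                        shoulder_width = 0.10,
                        bump_amp = 0, bump_center = 0.35, bump_width = 0.08,
                        diastolic_amp = 0.45, diastolic_center = 0.62,
                        diastolic_width = 0.085,
                        tail_amp = 0.35, tail_center = 0.86,
                        tail_width = 0.08) {
  comp <- data.frame(
    amp = c(systolic_amp, shoulder_amp, bump_amp, diastolic_amp, tail_amp),
    center = c(systolic_center, shoulder_center, bump_center, diastolic_center,
               tail_center),
    width = c(systolic_width, shoulder_width, bump_width, diastolic_width,
              tail_width))
  comp <- comp[comp$amp > 0, , drop = FALSE]
  comp <- comp[order(comp$center), , drop = FALSE]
  if (nrow(comp) < 2L)
    ppg_error("ppg_parameter_error", "need at least systolic and diastolic pulses")
  if (any(comp$amp < 0) || any(diff(comp$center) <= 0))
    ppg_error("ppg_parameter_error",
              "amplitudes must be >= 0 and pulse centers strictly increasing")
  if (length_s <= 0)
    ppg_error("ppg_parameter_error", "`length_s` must be positive")
  structure(list(length_s = length_s, components = comp), class = "beat_params")
}

#' Morphology-case presets for the synthetic generator
#'
#' Calibrated bump amplitudes that reproduce the three archetype APG shapes:
#' Case III (prominent c/d: the APG itself carries a local max/min pair),
#' Case I (c/d visible as a jerk double-hump only) and Case II (c/d weaker
#' still, recovered from the jerk minimum +/- 2.5% of the wavelength).
#'
#' @param case `"I"`, `"II"` or `"III"`.
#' @param ... further arguments passed to [beat_params()].
#' @return object of class `"beat_params"`.
#' @export
case_params <- function(case = c("I", "II", "III"), ...) {
  case <- match.arg(case)
  switch(case,
         III = beat_params(bump_amp = 0.60, bump_width = 0.07, ...),
         I   = beat_params(bump_amp = 0.35, bump_width = 0.08, ...),
         II  = beat_params(bump_amp = 0.03, bump_width = 0.08, ...))
}

# continuous Gaussian-sum model and its first three analytic derivatives;
# `offsets` replicates the beat at multiples of the beat length
gauss_model <- function(params, offsets = 0) {
  comp <- params$components
  L <- params$length_s
  A <- rep(comp$amp, times = length(offsets))
  C <- rep(comp$center * L, times = length(offsets)) +
    rep(offsets, each = nrow(comp))
  W <- rep(comp$width * L, times = length(offsets))
  d <- function(t, k) {
    out <- numeric(length(t))
    for (j in seq_along(A)) {
      u <- (t - C[j]) / W[j]
      e <- A[j] * exp(-u^2 / 2)
      out <- out + switch(k + 1L,
                          e,
                          -u / W[j] * e,
                          (u^2 - 1) / W[j]^2 * e,
                          u * (3 - u^2) / W[j]^3 * e)
    }
    out
  }
  list(g = function(t) d(t, 0L), g1 = function(t) d(t, 1L),
       g2 = function(t) d(t, 2L), g3 = function(t) d(t, 3L))
}

# Ground truth for the beat spanning [t0, t1] of a continuous model, by
# dense numerical search (default 10x oversampling).  Applies the same
# geometric definitions as the detector, but to the analytic noiseless
# derivatives -- never to the sampled/filtered/differenced signal path.
truth_from_model <- function(model, t0, t1, fs, oversample = 10,
                             prominence_frac = 0.03, systolic_frac = 0.4,
                             jerk_prominence_frac = 0.035) {
  tt <- seq(t0, t1, by = 1 / (fs * oversample))
  g  <- model$g(tt);  g1 <- model$g1(tt)
  g2 <- model$g2(tt); g3 <- model$g3(tt)
  n <- length(tt)
  Tsec <- t1 - t0
  tm <- rep(NA_real_, 14L); names(tm) <- .ppg_point_names

  tm["O"] <- tt[1L]
  S <- which.max(g); tm["S"] <- tt[S]
  case <- NA_character_; cd_present <- 0L
  # beats lacking some landmark structure (e.g. a single-pulse waveform
  # with no diastolic wave) yield NA for the affected points, not an error
  try(silent = TRUE, {
  lim <- max(3L, min(floor(systolic_frac * n), S))
  a <- which.max(g2[seq_len(lim)])
  lev <- g2[a] - 0.10 * (g2[a] - min(g2[seq_len(lim)]))
  lo <- a; while (lo > 1L && g2[lo - 1L] >= lev) lo <- lo - 1L
  hi2 <- a; while (hi2 < lim && g2[hi2 + 1L] >= lev) hi2 <- hi2 + 1L
  a <- as.integer(round_half_away((lo + hi2) / 2)); tm["a"] <- tt[a]
  b <- a + which.min(g2[(a + 1L):n]); tm["b"] <- tt[b]
  ef <- ef_rule(g, g1, g2, g3, S, b)
  e <- ef$e; f <- ef$f
  tm["e"] <- tt[e]; tm["f"] <- tt[f]
  tm["N"] <- tt[e]; tm["D"] <- tt[f]

  case <- classify_case(g2, g3, b, e, prominence_frac, jerk_prominence_frac)
  region <- if (e - b >= 2L) (b + 1L):(e - 1L) else integer(0)
  if (case == "III") {
    p <- prominence_frac * diff(range(g2))
    mx <- local_extrema(g2, "max", prominence = p); mx <- mx[mx %in% region]
    mn <- local_extrema(g2, "min", prominence = p)
    if (length(mx)) {
      mn <- mn[mn %in% region & mn >= mx[1L]]
      if (length(mn)) { tm["c"] <- tt[mx[1L]]; tm["d"] <- tt[mn[1L]]; cd_present <- 1L }
    }
  } else if (case == "I") {
    zc <- zero_crossings(g3)
    jmx <- local_extrema(g3, "max")
    cc <- jmx[jmx > max(zc[2L], b) & jmx < e]
    azc <- zero_crossings(g2, start = b + 1L); azc <- azc[azc < e]
    if (length(cc) && length(azc)) {
      tm["c"] <- tt[cc[1L]]; tm["d"] <- tt[azc[1L]]; cd_present <- 1L
    }
  } else {
    jmn <- local_extrema(g3, "min", prominence = 0.04 * diff(range(g3)))
    if (length(jmn) >= 2L && jmn[2L] > b && jmn[2L] < e) {
      tm["c"] <- tt[jmn[2L]] - 0.025 * Tsec
      tm["d"] <- tt[jmn[2L]] + 0.025 * Tsec
      cd_present <- 1L
    }
  }
  if (cd_present == 1L &&
      (tm["c"] <= tm["b"] || tm["d"] >= tm["e"] || tm["c"] > tm["d"])) {
    tm["c"] <- NA_real_; tm["d"] <- NA_real_; cd_present <- 0L
  }

  w <- which.max(g1[seq_len(S - 1L)]); tm["w"] <- tt[w]
  tm["x"] <- tt[S]
  y <- S + which.min(g1[(S + 1L):n]); tm["y"] <- tt[y]
  zc2 <- zero_crossings(g2, start = e + 1L)
  if (length(zc2)) tm["z"] <- tt[zc2[1L]] else {
    vmx <- local_extrema(g1, "max")
    if (length(vmx) >= 2L) tm["z"] <- tt[vmx[2L]]
  }

  })
  idx <- ifelse(is.na(tm), NA_integer_, as.integer(round_half_away(tm * fs)) + 1L)
  names(idx) <- .ppg_point_names
  list(times = tm, indices = idx, case = case, cd_present = cd_present,
       onset = t0, end = t1)
}

#' Simulate one noiseless synthetic beat with ground truth
#'
#' Evaluates the continuous Gaussian-sum beat model on the sample grid and
#' computes the analytically known ground-truth fiducials by dense numerical
#' search on the continuous model (10x oversampling) -- never by running the
#' detector, so the truth is an independent oracle.
#'
#' @param params a `"beat_params"` object.
#' @param fs sampling rate in Hz.
#' @return list with `samples` (length `round(length_s * fs)`), `truth`
#'   (times, 1-based sample `indices`, `case`, `cd_present`) and `fs`.
#' @export
simulate_beat <- function(params, fs = 1000) {
  stopifnot(inherits(params, "beat_params"))
  model <- gauss_model(params)
  n <- round(params$length_s * fs)
  t <- (seq_len(n) - 1) / fs
  samples <- model$g(t)
  if (which.max(samples) %in% c(1L, n))
    ppg_error("ppg_degenerate_error",
              "degenerate morphology: beat maximum at the segment edge")
  truth <- truth_from_model(model, 0, (n - 1) / fs, fs)
  list(samples = samples, truth = truth, fs = fs)
}

#' Simulate a multi-beat PPG record with ground truth
#'
#' Concatenates `n_beats` identical beats, adds white Gaussian noise and a
#' sinusoidal baseline drift, and pads (with zeros) or truncates to exactly
#' `length_samples` samples.  Ground truth is computed on the noiseless
#' continuous record model: onsets are the continuous local minima at the
#' beat junctions, and per-beat truths are reported for every beat bounded
#' by two interior onsets.  Noise and drift never alter the truth.
#'
#' @param n_beats number of beats laid down (default 3: with the default
#'   beat length, one fully onset-bounded beat inside a 2.1 s record).
#' @param params a `"beat_params"` object.
#' @param noise_sd standard deviation of the additive white noise (a.u.).
#' @param drift length-2 vector `c(amplitude, frequency_hz)` of the baseline
#'   drift sinusoid.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @param fs sampling rate in Hz.
#' @param length_samples record length (default 2100, i.e. 2.1 s at 1 kHz).
#' @return list with `samples`, `onsets` (record-relative 1-based indices of
#'   the interior junction minima), `truths` (one per bounded beat; indices
#'   record-relative), `fs`.
#' @export
simulate_record <- function(n_beats = 3, params = beat_params(),
                            noise_sd = 0, drift = c(0, 0.25), seed = NULL,
                            fs = 1000, length_samples = 2100) {
  stopifnot(inherits(params, "beat_params"))
  if (n_beats < 1) ppg_error("ppg_parameter_error", "`n_beats` must be >= 1")
  if (noise_sd < 0) ppg_error("ppg_parameter_error", "`noise_sd` must be >= 0")
  L <- params$length_s
  # the record starts mid-beat (in the diastolic tail of a truncated beat),
  # which keeps both record edges in quiet low-frequency regions and so
  # minimizes bandpass edge transients downstream
  phase <- 0.45 * L
  offsets <- (seq_len(n_beats) - 1) * L - phase
  model <- gauss_model(params, offsets = offsets)
  t <- (seq_len(length_samples) - 1) / fs
  clean <- model$g(t)

  # interior junction minima of the continuous model (the true onsets)
  onset_t <- numeric(0)
  if (n_beats >= 2) for (k in 1:(n_beats - 1)) {
    tj <- seq((k - 0.35) * L - phase, (k + 0.2) * L - phase, by = 1 / (10 * fs))
    tj <- tj[tj >= 0]
    j <- which.min(model$g(tj))
    if (j > 1L && j < length(tj)) onset_t <- c(onset_t, tj[j])
  }
  onset_idx <- as.integer(round_half_away(onset_t * fs)) + 1L
  keep <- onset_idx >= 1L & onset_idx <= length_samples
  onset_t <- onset_t[keep]; onset_idx <- onset_idx[keep]

  truths <- list()
  if (length(onset_t) >= 2L) for (k in 1:(length(onset_t) - 1L)) {
    if (onset_idx[k + 1L] <= length_samples)
      truths[[length(truths) + 1L]] <-
        truth_from_model(model, onset_t[k], onset_t[k + 1L], fs)
  }

  samples <- clean
  if (noise_sd > 0 || drift[1] != 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    if (noise_sd > 0) samples <- samples + rnorm(length_samples, 0, noise_sd)
    if (drift[1] != 0) samples <- samples + drift[1] * sin(2 * pi * drift[2] * t)
  }
  list(samples = samples, clean = clean, onsets = onset_idx, truths = truths,
       fs = fs)
}

#' Generate a seeded benchmark dataset with reference annotations
#'
#' Builds a dataset of synthetic subjects with per-subject morphology drawn
#' around the three case presets (multinomial case assignment, mild jitter
#' of beat length, pulse amplitudes and centers), 20 dB additive noise by
#' default, and a reference annotation table holding the ground-truth
#' record-relative indices of the first onset-bounded beat of each record.
#'
#' @param n_subjects number of subjects.
#' @param case_mix probabilities of cases I, II, III (default the 140/54/25
#'   proportions of a 219-subject study population).
#' @param seed integer seed governing every stochastic draw.
#' @param snr_db per-record signal-to-noise ratio in dB (`Inf` for
#'   noiseless records).
#' @param drift_amp,drift_freq baseline drift amplitude (a.u.) and
#'   frequency (Hz).
#' @param fs sampling rate in Hz.
#' @param length_samples record length (default 2100).
#' @return list with `dataset` (a `"ppg_dataset"`: sample matrix, ids, fs,
#'   per-subject SQI) and `reference` (data.frame: `subject_id`, `min1`,
#'   `min2`, the 14 point-index columns, `case`, `cd_present`).
#' @export
make_benchmark <- function(n_subjects = 219,
                           case_mix = c(I = 140, II = 54, III = 25) / 219,
                           seed = 1, snr_db = 20,
                           drift_amp = 0.05, drift_freq = 0.25,
                           fs = 1000, length_samples = 2100) {
  if (n_subjects < 1) ppg_error("ppg_parameter_error", "`n_subjects` must be >= 1")
  if (abs(sum(case_mix) - 1) > 1e-8)
    ppg_error("ppg_parameter_error", "`case_mix` must sum to 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  ids <- sprintf("S%03d", seq_len(n_subjects))
  cases <- sample(c("I", "II", "III"), n_subjects, replace = TRUE,
                  prob = case_mix)
  x <- matrix(0, n_subjects, length_samples)
  ref <- vector("list", n_subjects)
  sqi <- numeric(n_subjects)
  for (i in seq_len(n_subjects)) {
    scale <- runif(1, 0.8, 1.25)
    p <- case_params(cases[i],
                     length_s = runif(1, 1.02, 1.12),
                     systolic_amp = scale,
                     systolic_center = 0.20 + runif(1, -0.006, 0.006),
                     systolic_width = 0.08 * runif(1, 0.97, 1.03),
                     shoulder_amp = 0.60 * scale * runif(1, 0.97, 1.03),
                     diastolic_amp = 0.45 * scale * runif(1, 0.95, 1.05),
                     diastolic_center = 0.62 + runif(1, -0.008, 0.008),
                     tail_amp = 0.35 * scale)
    bump_row <- which.min(abs(p$components$center - 0.35))
    p$components$amp[bump_row] <- p$components$amp[bump_row] * scale
    clean_sd <- sd(gauss_model(p)$g((seq_len(length_samples) - 1) / fs))
    noise_sd <- if (is.finite(snr_db)) clean_sd / 10^(snr_db / 20) else 0
    rec <- simulate_record(n_beats = 3, params = p, noise_sd = noise_sd,
                           drift = c(drift_amp, drift_freq),
                           fs = fs, length_samples = length_samples)
    x[i, ] <- rec$samples
    sqi[i] <- skewness_sqi(rec$samples)
    tr <- rec$truths[[1L]]
    ref[[i]] <- data.frame(subject_id = ids[i],
                           min1 = rec$onsets[1L], min2 = rec$onsets[2L],
                           as.list(tr$indices),
                           case = tr$case, cd_present = tr$cd_present,
                           stringsAsFactors = FALSE)
  }
  dataset <- structure(list(x = x, ids = ids, fs = fs,
                            sqi = stats::setNames(sqi, ids)),
                       class = "ppg_dataset")
  list(dataset = dataset, reference = do.call(rbind, ref))
}
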