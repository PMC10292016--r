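#' Skewness signal-quality index
#'
#' The skewness SQI of a PPG segment: the third standardized moment of the
#' samples.  A clean PPG beat (sharp systolic upstroke, long diastolic tail)
#' is right-skewed, so a positive value indicates a plausible pulse; segments
#' with an SQI of at least 0.41 are conventionally retained.
#'
#' @param samples numeric vector, length >= 3, non-degenerate.
#' @param bias_corrected if `TRUE`, apply the small-sample adjustment
#'   `sqrt(n(n-1))/(n-2)`; the default is the plain divisor-n moment
#'   estimator.
#' @return skewness value (dimensionless scalar).
#' @export
skewness_sqi <- function(samples, bias_corrected = FALSE) {
  n <- length(samples)
  if (n < 3L) ppg_error("ppg_length_error", "need at least 3 samples for skewness")
  if (anyNA(samples)) ppg_error("ppg_parse_error", "samples contain missing values")
  m <- mean(samples)
  s2 <- mean((samples - m)^2)
  if (s2 == 0) ppg_error("ppg_degenerate_error", "zero-variance input has no skewness")
  g1 <- mean((samples - m)^3) / s2^1.5
  if (bias_corrected) g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g1
}

#' Select the highest-quality candidate segment
#'
#' Among candidate segments whose skewness SQI reaches `threshold`, returns
#' the name of the one with maximal SQI (ties broken by earliest candidate);
#' `NA` if none passes.
#'
#' @param candidates named list of numeric sample vectors.
#' @param threshold SQI acceptance threshold, boundary inclusive
#'   (default 0.41).
#' @return the chosen candidate's name, or `NA_character_` if all fall below
#'   threshold.
#' @export
select_segment <- function(candidates, threshold = 0.41) {
  if (!is.list(candidates) || length(candidates) == 0L)
    ppg_error("ppg_parameter_error", "`candidates` must be a nonempty list")
  ids <- names(candidates) %||% as.character(seq_along(candidates))
  sqi <- vapply(candidates, skewness_sqi, numeric(1))
  ok <- sqi >= threshold
  if (!any(ok)) return(NA_character_)
  ids[ok][which.max(sqi[ok])]
}

#' Detect pulse onsets
#'
#' Pulse onsets are the local minima of the filtered PPG that delimit beats:
#' minima whose prominence is at least `prominence_frac` of the record's
#' peak-to-peak range and that are followed within `upstroke_window_s` by a
#' systolic upstroke reaching the record's upper level (its
#' `upstroke_quantile`) -- a dicrotic-notch dip is followed only by the
#' modest diastolic hump and is thereby rejected.  Candidates are thinned
#' so that consecutive onsets are at least `min_spacing_s` apart (deeper
#' minima win).  Plateau minima are reported at their first sample.
#'
#' @param filtered_ppg numeric vector.
#' @param fs sampling rate in Hz.
#' @param prominence_frac minimum prominence as a fraction of the
#'   peak-to-peak range (default 0.10).
#' @param min_spacing_s minimum spacing between onsets in seconds
#'   (default 0.3, a 200 bpm ceiling).
#' @param upstroke_window_s window after a candidate within which the
#'   systolic rise must occur (default 0.35 s).
#' @param upstroke_quantile record quantile the rise must reach
#'   (default 0.75).
#' @return increasing vector of onset sample indices (1-based).
#' @export
detect_onsets <- function(filtered_ppg, fs = 1000,
                          prominence_frac = 0.10, min_spacing_s = 0.3,
                          upstroke_window_s = 0.35, upstroke_quantile = 0.75) {
  if (length(filtered_ppg) < 3L)
    ppg_error("ppg_length_error", "record too short for onset detection")
  n <- length(filtered_ppg)
  rng <- diff(range(filtered_ppg))
  idx <- local_extrema(filtered_ppg, "min", prominence = prominence_frac * rng)
  lvl <- stats::quantile(filtered_ppg, upstroke_quantile)
  idx <- idx[vapply(idx, function(m)
    max(filtered_ppg[m:min(n, m + round(upstroke_window_s * fs))]) >= lvl,
    logical(1))]
  if (length(idx) > 1L) {
    # enforce spacing, keeping deeper minima
    ord <- idx[order(filtered_ppg[idx])]
    kept <- integer(0)
    for (i in ord)
      if (!length(kept) || all(abs(kept - i) >= min_spacing_s * fs))
        kept <- c(kept, i)
    idx <- sort(kept)
  }
  if (length(idx) < 2L)
    ppg_error("ppg_nobeat_error", "fewer than two pulse onsets found")
  idx
}

#' Extract a single-beat segment
#'
#' Slices the filtered PPG between two onset indices, inclusive.  Segments
#' longer than 1200 samples are flagged (`truncated = TRUE`) because the
#' zero-padded export matrices are fixed at 1200 columns.
#'
#' @param filtered_ppg numeric vector.
#' @param min1,min2 onset indices bounding the beat, `min1 < min2`.
#' @param fs sampling rate in Hz.
#' @param subject_id identifier carried along for provenance.
#' @return An object of class `"beat_segment"`: list with `subject_id`,
#'   `min1`, `min2`, `samples` (length `min2 - min1 + 1`), `fs`, `truncated`.
#' @export
extract_beat <- function(filtered_ppg, min1, min2, fs = 1000, subject_id = "S001") {
  n <- length(filtered_ppg)
  if (min1 < 1 || min2 > n || min1 >= min2)
    ppg_error("ppg_bounds_error",
              sprintf("invalid beat bounds [%s, %s] for record of length %d",
                      format(min1), format(min2), n))
  samples <- filtered_ppg[min1:min2]
  truncated <- length(samples) > 1200L
  if (truncated)
    warning(sprintf("beat of %d samples exceeds the 1200-sample export window",
                    length(samples)))
  structure(list(subject_id = subject_id, min1 = as.integer(min1),
                 min2 = as.integer(min2), samples = samples, fs = fs,
                 truncated = truncated),
            class = "beat_segment")
}
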