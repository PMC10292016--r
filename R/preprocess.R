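#' Design the Chebyshev type-II bandpass filter
#'
#' Builds the 4th-order Chebyshev type-II bandpass with 20 dB stopband
#' attenuation used to condition raw PPG records before fiducial-point
#' extraction.  `fl` and `fh` are the stopband edges: the realized magnitude
#' response is attenuated by 20 dB at (and beyond) both cutoffs relative to
#' the mid-passband, while the band in between is passed essentially flat.
#'
#' The design is kept in zero-pole-gain form and realized as a cascade of
#' biquad (second-order) sections.  The usual single transfer-function
#' polynomial is severely ill-conditioned at a normalized edge of
#' `0.4/(fs/2)` and produces an unstable recursion after coefficient
#' rounding; the cascade realization is stable and accurate.
#'
#' @param fs sampling rate in Hz (default 1000).
#' @param fl low stopband edge in Hz (default 0.4).
#' @param fh high stopband edge in Hz (default 8).
#' @return An object of class `"ppg_filter"`: the pole/zero/gain design, the
#'   biquad section matrix (columns b0,b1,b2,a0,a1,a2), and the design
#'   parameters (`fs`, `fl`, `fh`, `order = 4`, `rs = 20`).
#' @seealso [apply_filter()], [filter_response()]
#' @examples
#' spec <- design_bandpass(1000, 0.4, 8)
#' 20 * log10(filter_response(spec, c(0.4, 2, 8)))
#' @export
design_bandpass <- function(fs = 1000, fl = 0.4, fh = 8) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    ppg_error("ppg_parameter_error", "`fs` must be a positive number")
  if (fl <= 0 || fl >= fh)
    ppg_error("ppg_parameter_error",
              sprintf("cutoffs must satisfy 0 < fl < fh (got fl=%g, fh=%g)", fl, fh))
  if (fh >= fs / 2)
    ppg_error("ppg_nyquist_error",
              sprintf("high cutoff fh=%g Hz must be below the Nyquist rate %g Hz", fh, fs / 2))
  n <- 4L; rs <- 20
  W <- c(fl, fh) * 2 / fs

  # Chebyshev type-II analog lowpass prototype (stopband-edge normalized),
  # then band transform + bilinear mapping via the signal package.
  T <- 2
  Wp <- 2 / T * tan(pi * W / T)
  lambda <- 10^(rs / 20)
  phi <- log(lambda + sqrt(lambda^2 - 1)) / n
  theta <- pi * ((1:n) - 0.5) / n
  alpha <- -sinh(phi) * sin(theta)
  beta <- cosh(phi) * cos(theta)
  zero <- 1i / cos(theta)                       # n even: all prototype zeros finite
  pole <- 1 / (alpha^2 + beta^2) * (alpha - 1i * beta)
  gain <- abs(Re(prod(pole) / prod(zero)))
  zpg <- signal::Zpg(zero = zero, pole = pole, gain = gain)
  zpg <- signal::sftrans(zpg, W = Wp, stop = FALSE)
  zpg <- signal::bilinear(zpg, T = T)

  structure(list(zero = zpg$zero, pole = zpg$pole, gain = zpg$gain,
                 sos = zpg_to_sos(zpg),
                 fs = fs, fl = fl, fh = fh, order = n, rs = rs),
            class = "ppg_filter")
}

# multiply out monic polynomial from roots
poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - ri * c(0, p)
  p
}

# Pair conjugate poles (closest to the unit circle first) with the nearest
# conjugate zero pair; one biquad row per pair.
zpg_to_sos <- function(zpg) {
  p <- zpg$pole[order(-Mod(zpg$pole))]
  z <- zpg$zero
  pused <- rep(FALSE, length(p)); zused <- rep(FALSE, length(z))
  secs <- list()
  for (i in seq_along(p)) {
    if (pused[i]) next
    pused[i] <- TRUE
    pp <- p[i]
    if (abs(Im(p[i])) > 1e-12) {
      j <- which(!pused & abs(p - Conj(p[i])) < 1e-8)[1]
      pused[j] <- TRUE
      pp <- c(pp, p[j])
    }
    idx <- which(!zused)
    j <- idx[which.min(abs(abs(Arg(z[idx])) - abs(Arg(pp[1]))))]
    zused[j] <- TRUE
    zz <- z[j]
    if (abs(Im(z[j])) > 1e-12) {
      j2 <- which(!zused & abs(z - Conj(z[j])) < 1e-8)[1]
      zused[j2] <- TRUE
      zz <- c(zz, z[j2])
    }
    b <- Re(poly_from_roots(zz)); a <- Re(poly_from_roots(pp))
    secs[[length(secs) + 1L]] <- c(b, rep(0, 3 - length(b)), a, rep(0, 3 - length(a)))
  }
  do.call(rbind, secs)
}

#' Magnitude response of a designed filter
#'
#' Evaluates `|H(e^{i 2 pi f / fs})|` directly from the pole-zero form on an
#' arbitrary frequency grid (single-pass response; the zero-phase application
#' in [apply_filter()] squares it).
#'
#' @param spec a `"ppg_filter"` from [design_bandpass()].
#' @param f frequencies in Hz.
#' @return numeric vector of magnitudes.
#' @export
filter_response <- function(spec, f) {
  stopifnot(inherits(spec, "ppg_filter"))
  ej <- exp(1i * 2 * pi * f / spec$fs)
  vapply(ej, function(e)
    abs(spec$gain * prod(e - spec$zero) / prod(e - spec$pole)), numeric(1))
}

#' @export
print.ppg_filter <- function(x, ...) {
  cat(sprintf("Chebyshev type-II bandpass: order %d, %g dB stopband\n", x$order, x$rs))
  cat(sprintf("  edges %g-%g Hz at fs = %g Hz, %d biquad sections\n",
              x$fl, x$fh, x$fs, nrow(x$sos)))
  invisible(x)
}

# one biquad, steady-state initial conditions (pre-history assumed constant
# at x[1]); direct form I with the AR part done by stats::filter
biquad_filter <- function(x, b, a) {
  n <- length(x)
  h1 <- sum(b) / sum(a)                 # DC gain of the section
  xp <- c(x[1], x[1], x)
  v <- b[1] * xp[3:(n + 2)] + b[2] * xp[2:(n + 1)] + b[3] * xp[1:n]
  as.numeric(stats::filter(v, -a[2:3], method = "recursive",
                           init = rep(h1 * x[1], 2)))
}

sos_filter_once <- function(spec, x) {
  y <- x * spec$gain
  for (k in seq_len(nrow(spec$sos)))
    y <- biquad_filter(y, spec$sos[k, 1:3], spec$sos[k, 4:6])
  y
}

#' Zero-phase bandpass filtering
#'
#' Applies the realized Chebyshev type-II bandpass forward and backward
#' (zero-phase), so fiducial timing is not biased by filter phase delay.
#' Edge transients are suppressed by symmetric-reflection padding combined
#' with steady-state section initialization; for quasi-periodic pulse
#' records this keeps the residual low-frequency bend from the 0.4 Hz
#' highpass small.
#'
#' @param samples numeric vector (arbitrary amplitude units).
#' @param spec a `"ppg_filter"` from [design_bandpass()].
#' @return filtered vector, same length as the input.
#' @export
apply_filter <- function(samples, spec) {
  stopifnot(inherits(spec, "ppg_filter"))
  if (anyNA(samples)) ppg_error("ppg_parse_error", "samples contain missing values")
  n <- length(samples)
  state_len <- 2L * nrow(spec$sos) + 1L
  if (n < 3L * state_len)
    ppg_error("ppg_length_error",
              sprintf("input of length %d is too short to filter (need >= %d)",
                      n, 3L * state_len))
  npad <- min(n - 1L, 300L)
  xp <- c(samples[(npad + 1):2], samples, samples[(n - 1):(n - npad)])
  y <- sos_filter_once(spec, xp)
  y <- rev(sos_filter_once(spec, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Centered moving average
#'
#' Moving mean with a centered window that shrinks at the edges, matching
#' MATLAB `movmean` semantics: sample `i` averages
#' `x[(i - floor((n-1)/2)) : (i + ceiling((n-1)/2))]` clipped to the signal.
#' `window = 1` is the identity.
#'
#' @param samples numeric vector.
#' @param window positive integer window length in samples.
#' @return vector of the same length.
#' @export
moving_average <- function(samples, window) {
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window != floor(window))
    ppg_error("ppg_parameter_error", "`window` must be a positive integer")
  n <- length(samples)
  if (window == 1L || n == 0L) return(samples)
  lo <- pmax(seq_len(n) - floor((window - 1) / 2), 1L)
  hi <- pmin(seq_len(n) + ceiling((window - 1) / 2), n)
  cs <- c(0, cumsum(samples))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Velocity, acceleration and jerk plethysmograms
#'
#' Computes the first three discrete derivatives of a (filtered) PPG segment:
#' VPG (velocity), APG (acceleration) and JPG (jerk).  Each derivative is the
#' first difference of the previous waveform, assigned to the left sample
#' index with the final value repeated so that all four vectors share the PPG
#' index grid, and is then smoothed with a centered moving average of
#' `smooth_window` samples.
#'
#' @param filtered_ppg numeric vector, length >= 4.
#' @param smooth_window moving-average window (samples) applied to each
#'   derivative after differencing; 1 disables smoothing.
#' @param fs sampling rate in Hz, carried along for time conversion.
#' @return An object of class `"derivative_stack"`: list with `ppg`, `vpg`,
#'   `apg`, `jpg` (equal lengths) and `fs`.
#' @export
compute_derivatives <- function(filtered_ppg, smooth_window = 1, fs = 1000) {
  if (length(filtered_ppg) < 4L)
    ppg_error("ppg_length_error", "need at least 4 samples to form three derivatives")
  if (anyNA(filtered_ppg) || any(!is.finite(filtered_ppg)))
    ppg_error("ppg_parse_error", "filtered_ppg must be finite")
  n <- length(filtered_ppg)
  # each difference is assigned to the left sample index; the trailing
  # samples that a k-th difference cannot reach are filled with the last
  # validly computed value (never with the artificial zero that repeated
  # values would induce in the next difference)
  d1 <- function(x, k) {
    d <- c(diff(x), 0)
    d[(n - k + 1L):n] <- d[n - k]
    d
  }
  vpg <- moving_average(d1(filtered_ppg, 1L), smooth_window)
  apg <- moving_average(d1(vpg, 2L), smooth_window)
  jpg <- moving_average(d1(apg, 3L), smooth_window)
  structure(list(ppg = filtered_ppg, vpg = vpg, apg = apg, jpg = jpg, fs = fs),
            class = "derivative_stack")
}
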