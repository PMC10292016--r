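# internal helpers shared across modules

# round half away from zero to integer (MATLAB-style round())
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Strict local extrema of a numeric vector with plateau ties resolved to the
# leftmost plateau sample.  Endpoints are never extrema.  `prominence` filters
# maxima (minima) whose height above (depth below) the surrounding terrain is
# too small: for a maximum it is x[i] minus the higher of the two minima
# separating it from taller terrain (or the signal edge); for minima the
# signal is negated.
local_extrema <- function(x, what = c("max", "min"), prominence = 0) {
  what <- match.arg(what)
  if (what == "min") x <- -x
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  is_peak <- c(FALSE, v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k], FALSE)
  idx <- starts[is_peak]
  if (!length(idx) || prominence <= 0) return(idx)
  keep <- vapply(idx, function(i) peak_prominence(x, i) >= prominence, logical(1))
  idx[keep]
}

# prominence of the peak at index i of x (x oriented so that i is a maximum)
peak_prominence <- function(x, i) {
  n <- length(x)
  h <- x[i]
  left <- if (i > 1L) {
    higher <- which(x[1:(i - 1L)] > h)
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(x[lo:(i - 1L)])
  } else h
  right <- if (i < n) {
    higher <- which(x[(i + 1L):n] > h)
    hi <- if (length(higher)) i + min(higher) - 1L else n
    min(x[(i + 1L):hi])
  } else h
  h - max(left, right)
}

# condition constructors: all package errors carry a subclass for testing
ppg_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(class = c(class, "ppgfiducial_error", "error", "condition"),
                 list(message = msg, call = call)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noise-averaged localization helpers.  A flat extremum located by argmax
# wanders under noise; re-localizing as the vertex of a least-squares
# parabola over a window pools ~2w+1 samples.  Likewise a zero-crossing is
# re-localized as the root of a least-squares line.  Both keep the coarse
# index when the fit is degenerate or disagrees grossly.
ls_vertex <- function(v, i, halfwin = 20L) {
  n <- length(v)
  win <- max(1L, i - halfwin):min(n, i + halfwin)
  if (length(win) < 5L) return(i)
  t <- win - i
  fit <- stats::lm.fit(cbind(1, t, t^2), v[win])
  cf <- fit$coefficients
  if (!is.finite(cf[3]) || cf[3] == 0) return(i)
  vx <- -cf[2] / (2 * cf[3])
  if (!is.finite(vx) || abs(vx) > halfwin) return(i)
  as.integer(i + round_half_away(vx))
}

ls_root <- function(v, i, halfwin = 15L) {
  n <- length(v)
  win <- max(1L, i - halfwin):min(n, i + halfwin)
  if (length(win) < 4L) return(i)
  t <- win - i
  fit <- stats::lm.fit(cbind(1, t), v[win])
  cf <- fit$coefficients
  if (!is.finite(cf[2]) || cf[2] == 0) return(i)
  rt <- -cf[1] / cf[2]
  if (!is.finite(rt) || abs(rt) > halfwin) return(i)
  as.integer(i + round_half_away(rt))
}
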