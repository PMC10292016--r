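#' Zero-crossing indices of a signal
#'
#' Reports index `i >= start` whenever the sign of the signal differs between
#' `i - 1` and `i` (the crossing is attributed to the first sample of the new
#' sign regime).  Exact zeros belong to the following sign regime, so a
#' touch-and-go zero that does not change sign is not a crossing.
#'
#' @param signal numeric vector.
#' @param start first index eligible to be reported (default 1).
#' @return increasing integer vector of crossing indices (possibly empty).
#' @export
zero_crossings <- function(signal, start = 1L) {
  n <- length(signal)
  if (n < 2L) return(integer(0))
  s <- sign(signal)
  if (!any(s != 0)) return(integer(0))
  # zeros adopt the sign of the next nonzero sample; trailing zeros drop out
  nxt <- rev(cummin(rev(ifelse(s != 0, seq_len(n), Inf))))
  s <- ifelse(is.finite(nxt), s[pmin(nxt, n)], 0)
  cross <- which(s[-1L] != 0 & s[-n] != 0 & s[-1L] != s[-n]) + 1L
  cross[cross >= start]
}

#' O and S points of a beat segment
#'
#' The O (onset) point is the first sample of the onset-bounded segment; the
#' S (systolic peak) point is the segment's global maximum.
#'
#' @param ppg_segment filtered PPG samples of one beat.
#' @return list with integer indices `O` and `S` (segment-relative, 1-based).
#' @export
detect_O_S <- function(ppg_segment) {
  if (length(ppg_segment) < 3L)
    ppg_error("ppg_length_error", "segment too short")
  if (diff(range(ppg_segment)) == 0)
    ppg_error("ppg_degenerate_error", "flat segment has no systolic peak")
  list(O = 1L, S = which.max(ppg_segment))
}

#' a and b waves of the APG
#'
#' The a wave is the global maximum of the APG within the systolic search
#' region -- the first `systolic_frac` of the beat, further capped at the
#' systolic peak S when known, since the a wave rides the upstroke.  Because
#' the top of the a dome can be broad, the reported index is the midpoint of
#' the dome's level set 10% below its maximum (the dome's steep flanks
#' localize far more sharply than its flat top).  The b wave is the global
#' minimum of the APG after a.
#'
#' @param apg APG samples aligned to the beat segment grid.
#' @param S optional index of the systolic peak, capping the a-wave search.
#' @param systolic_frac fraction of the beat searched for the a wave
#'   (default 0.4).
#' @return list with integer indices `a` and `b`.
#' @export
detect_ab <- function(apg, S = NULL, systolic_frac = 0.4) {
  T <- length(apg)
  lim <- max(3L, floor(systolic_frac * T))
  if (!is.null(S)) lim <- max(3L, min(lim, as.integer(S)))
  a <- which.max(apg[seq_len(lim)])
  lev <- apg[a] - 0.10 * (apg[a] - min(apg[seq_len(lim)]))
  lo <- a; while (lo > 1L && apg[lo - 1L] >= lev) lo <- lo - 1L
  hi <- a; while (hi < lim && apg[hi + 1L] >= lev) hi <- hi + 1L
  a <- as.integer(round_half_away((lo + hi) / 2))
  if (a >= T - 1L)
    ppg_error("ppg_detection_error", "no b wave: a falls at the segment end")
  b <- a + which.min(apg[(a + 1L):T])
  if (apg[b] >= apg[a])
    ppg_error("ppg_detection_error", "no b wave after a (monotone APG)")
  list(a = as.integer(a), b = as.integer(b))
}

#' e and f waves of the APG
#'
#' The e wave is the APG maximum at the dicrotic notch and is located by
#' anchoring on the notch itself, a pulse-level feature that is robust to
#' bandpass conditioning: the anchor is the most prominent local minimum of
#' the PPG between the systolic peak and 92% of the beat (or, for beats so
#' damped that the notch is a mere inflection, the most prominent VPG local
#' maximum there).  e is the downward JPG zero-crossing nearest the anchor
#' (each such crossing marks an APG local maximum); f -- the diastolic
#' negative wave -- is the first upward JPG crossing after e, with APG
#' local extrema as fallbacks.
#'
#' @param apg,jpg waveforms aligned to the beat segment grid.
#' @param b index of the b wave.
#' @param ppg,vpg optional aligned PPG and VPG vectors enabling the
#'   notch-anchored search.
#' @param S optional systolic peak index (required with `ppg`).
#' @return list with integer indices `e` and `f`.
#' @export
detect_ef <- function(apg, jpg, b, ppg = NULL, vpg = NULL, S = NULL) {
  ef_rule(ppg, vpg, apg, jpg, S, b)
}

# Shared e/f rule: applied to the discrete waveforms by the detector and,
# in the synthetic truth oracle, to the densely sampled analytic
# derivatives.  Falls back to a b-anchored window when no pulse-level
# anchor is available.
ef_rule <- function(ppg, vpg, apg, jpg, S, b) {
  n <- length(apg)
  hi <- floor(0.92 * n)
  anchor <- NULL
  if (!is.null(ppg) && !is.null(S) && S + 2L < hi) {
    win <- (S + 1L):hi
    most_prominent <- function(v, what) {
      ex <- local_extrema(v, what)
      ex <- ex[ex %in% win]
      if (!length(ex)) return(NULL)
      pr <- vapply(ex, function(i)
        peak_prominence(if (what == "min") -v else v, i), numeric(1))
      ex[which.max(pr)]
    }
    anchor <- most_prominent(ppg, "min")
    if (is.null(anchor) && !is.null(vpg)) anchor <- most_prominent(vpg, "max")
  }
  cr <- zero_crossings(jpg, start = b + 1L)
  cr <- cr[cr <= hi]
  down <- cr[jpg[cr] < jpg[cr - 1L]]
  up <- cr[jpg[cr] > jpg[cr - 1L]]
  e <- if (!is.null(anchor) && length(down)) {
    cand <- down[abs(down - anchor) <= 0.1 * n]
    # among crossings near the notch, e is the one on the tallest APG hump
    if (length(cand)) cand[which.max(apg[cand])] else NULL
  } else if (is.null(anchor) && length(down)) {
    # damped-notch fallback: last APG maximum crossing in the diastolic
    # search window starting 20% of the beat after b
    cand <- down[down > b + 0.2 * n]
    if (length(cand)) cand[length(cand)] else NULL
  } else NULL
  if (is.null(e)) {
    mx <- local_extrema(apg, "max")
    mx <- mx[mx > b + 0.15 * n & mx <= hi]
    if (!is.null(anchor) && length(mx)) mx <- mx[order(abs(mx - anchor))][1L]
    if (!length(mx))
      ppg_error("ppg_detection_error", "no e wave found after b")
    e <- mx[1L]
  }
  f <- up[up > e]
  if (length(f)) f <- f[1L] else {
    mn <- local_extrema(apg, "min")
    mn <- mn[mn > e]
    if (!length(mn))
      ppg_error("ppg_detection_error", "no f wave found after e")
    f <- mn[1L]
  }
  list(e = as.integer(e), f = as.integer(f))
}

#' Classify the c/d morphology of a beat
#'
#' Examines the APG (and its derivative, the JPG) strictly between the b and
#' e waves and assigns one of three morphology classes:
#'
#' * **Case III** - the c and d waves are prominent: the APG itself has a
#'   local maximum followed by a local minimum in (b, e), each with
#'   prominence at least `prominence_frac` of the APG peak-to-peak range.
#' * **Case I** - the c/d excursion is visible only as an inflection: the
#'   JPG has an interior local minimum in (b, e) (a distinct double-hump in
#'   the jerk) with prominence at least `jerk_prominence_frac` of the JPG
#'   peak-to-peak range.
#' * **Case II** - neither; any c/d signature is weaker still.
#'
#' The jerk threshold is the higher of the two because the jerk waveform of
#' a conditioned (bandpassed, differenced, smoothed) pulse carries residual
#' ripple that the raw APG does not.
#'
#' @param apg,jpg waveforms aligned to the beat segment grid.
#' @param b,e indices of the b and e waves, `b < e`.
#' @param prominence_frac APG-pair prominence threshold as a fraction of
#'   the APG peak-to-peak range (default 0.03).
#' @param jerk_prominence_frac JPG-dip prominence threshold as a fraction
#'   of the JPG peak-to-peak range (default 0.045).
#' @return `"I"`, `"II"` or `"III"`.
#' @export
classify_case <- function(apg, jpg, b, e, prominence_frac = 0.03,
                          jerk_prominence_frac = 0.035) {
  if (b >= e) ppg_error("ppg_parameter_error", "need b < e")
  if (e - b >= 3L) {
    region <- (b + 1L):(e - 1L)
    p_apg <- prominence_frac * diff(range(apg))
    mx <- local_extrema(apg, "max", prominence = p_apg)
    mn <- local_extrema(apg, "min", prominence = p_apg)
    mx <- mx[mx %in% region]; mn <- mn[mn %in% region]
    if (length(mx) && length(mn) && any(outer(mx, mn, "<")))
      return("III")
    p_jpg <- jerk_prominence_frac * diff(range(jpg))
    dip <- local_extrema(jpg, "min", prominence = p_jpg)
    if (any(dip %in% region)) return("I")
  }
  "II"
}

#' Locate the c and d waves
#'
#' Applies the rule of the assigned morphology case:
#'
#' * **Case I**: c is the first JPG local maximum after the JPG's second
#'   zero-crossing (counted from the segment start, i.e. after the b wave);
#'   d is the first zero-crossing of the APG signal itself inside (b, e).
#' * **Case II**: the JPG's second local minimum (counted from the segment
#'   start) marks the midpoint between c and d; c and d are that index minus
#'   and plus 2.5% of the beat wavelength `T` (rounded half away from zero).
#' * **Case III**: c is the first prominent APG local maximum in (b, e) and
#'   d the following APG local minimum.
#'
#' Whenever a required extremum or crossing is absent, or the located points
#' violate `b < c <= d < e`, the beat is flagged `cd_present = 0` with `c`
#' and `d` unset -- never a hard failure.
#'
#' @param case_label `"I"`, `"II"` or `"III"` from [classify_case()].
#' @param apg,jpg waveforms aligned to the beat segment grid.
#' @param b,e indices of the b and e waves.
#' @param T beat wavelength in samples (segment length).
#' @param prominence_frac prominence threshold used for Case III extrema.
#' @return list with `c`, `d` (integer or `NA`) and `cd_present` (0/1).
#' @export
locate_cd <- function(case_label, apg, jpg, b, e, T, prominence_frac = 0.03) {
  if (b >= e) ppg_error("ppg_parameter_error", "need b < e")
  absent <- list(c = NA_integer_, d = NA_integer_, cd_present = 0L)
  region <- if (e - b >= 2L) (b + 1L):(e - 1L) else integer(0)
  res <- switch(case_label,
    III = {
      p_apg <- prominence_frac * diff(range(apg))
      mx <- local_extrema(apg, "max", prominence = p_apg)
      mx <- mx[mx %in% region]
      if (!length(mx)) return(absent)
      cc <- mx[1L]
      mn <- local_extrema(apg, "min", prominence = p_apg)
      mn <- mn[mn %in% region & mn >= cc]
      if (!length(mn)) return(absent)
      list(c = ls_vertex(apg, cc, 12L), d = ls_vertex(apg, mn[1L], 12L))
    },
    I = {
      zc <- zero_crossings(jpg)
      if (length(zc) < 2L) return(absent)
      jmx <- local_extrema(jpg, "max")
      cc <- jmx[jmx > max(zc[2L], b) & jmx < e]
      if (!length(cc)) return(absent)
      cc <- cc[1L]
      azc <- zero_crossings(apg, start = b + 1L)
      dd <- azc[azc < e]
      if (!length(dd)) return(absent)
      list(c = cc, d = ls_root(apg, dd[1L]))
    },
    II = {
      # counting floor: ignore jerk wiggles below 4% prominence -- the
      # ripple level of a conditioned pulse -- so the "second minimum"
      # count is stable under residual noise
      jmn <- local_extrema(jpg, "min", prominence = 0.04 * diff(range(jpg)))
      if (length(jmn) < 2L) return(absent)
      m <- jmn[2L]
      if (!(m > b && m < e)) return(absent)
      r <- round_half_away(0.025 * T)
      list(c = as.integer(m - r), d = as.integer(m + r))
    },
    ppg_error("ppg_parameter_error", sprintf("unknown case label '%s'", case_label))
  )
  if (res$c <= b || res$d >= e || res$c > res$d || res$c < 1) return(absent)
  list(c = as.integer(res$c), d = as.integer(res$d), cd_present = 1L)
}

#' w, x, y and z points of the VPG
#'
#' w is the global maximum of the VPG on the systolic upstroke (before S);
#' x is the VPG sample aligned with the systolic peak (where the VPG crosses
#' zero); y is the global minimum of the VPG after S (steepest systolic
#' decay); z is the first zero-crossing of the APG after the e wave (a VPG
#' local maximum in the diastolic phase) or, when e is unavailable, the
#' second VPG local maximum.
#'
#' @param vpg VPG samples aligned to the beat segment grid.
#' @param S index of the systolic peak.
#' @param apg optional APG vector (enables the primary z rule).
#' @param e optional index of the APG e wave.
#' @return list with integer indices `w`, `x`, `y`, `z` (`z` may be `NA`).
#' @export
detect_vpg_points <- function(vpg, S, apg = NULL, e = NULL) {
  T <- length(vpg)
  if (S < 3L || S > T - 2L)
    ppg_error("ppg_detection_error", "systolic peak too close to the segment edge")
  w <- which.max(vpg[seq_len(S - 1L)])
  x <- as.integer(S)
  y <- S + which.min(vpg[(S + 1L):T])
  if (!(vpg[w] > vpg[y]))
    ppg_error("ppg_detection_error", "degenerate VPG: no w/y excursion")
  z <- NA_integer_
  if (!is.null(apg) && !is.null(e) && !is.na(e) && e < T) {
    zc <- zero_crossings(apg, start = e + 1L)
    if (length(zc)) z <- zc[1L]
  }
  if (is.na(z)) {
    mx <- local_extrema(vpg, "max")
    if (length(mx) >= 2L) z <- mx[2L]
  }
  list(w = as.integer(w), x = x, y = as.integer(y), z = z)
}

#' Map APG e/f waves to the PPG dicrotic notch and diastolic peak
#'
#' The dicrotic notch N and the diastolic peak D of the PPG coincide in time
#' with the e and f waves of the APG; the mapping is the identity on the
#' shared index grid.
#'
#' @param e,f indices of the APG e and f waves, `e < f`.
#' @return list with `N = e` and `D = f`.
#' @export
map_ND <- function(e, f) {
  if (!(e < f)) ppg_error("ppg_parameter_error", "need e < f")
  list(N = as.integer(e), D = as.integer(f))
}

#' Extract all 14 fiducial points from one beat
#'
#' Orchestrates the full per-beat detection: O/S on the PPG, a/b then e/f on
#' the APG (via JPG zero-crossings), morphology classification and c/d
#' location, w/x/y/z on the VPG, and the N/D mapping.  A beat on which
#' detection fails yields an invalid result (`ok = FALSE`, all points `NA`)
#' rather than an error.
#'
#' @param stack a `"derivative_stack"` for the beat segment (see
#'   [compute_derivatives()]).
#' @param min1,min2 record-relative onset indices bounding the segment
#'   (`min2 - min1 + 1` must equal the segment length).
#' @param subject_id identifier carried into error messages and results.
#' @param prominence_frac APG prominence threshold for case classification.
#' @param systolic_frac systolic search region for the a wave.
#' @param jerk_prominence_frac JPG prominence threshold for case
#'   classification.
#' @return An object of class `"fiducial_set"`: segment-relative `indices`
#'   (named integer vector over O,S,N,D,w,x,y,z,a,b,c,d,e,f), `amplitudes`
#'   (value of the owning waveform at each index), `min1`, `min2`,
#'   `min2_amplitude`, `case`, `cd_present`, `ok`, `message`.
#' @export
extract_fiducials <- function(stack, min1 = 1L, min2 = NULL,
                              subject_id = "S001",
                              prominence_frac = 0.03, systolic_frac = 0.4,
                              jerk_prominence_frac = 0.035) {
  stopifnot(inherits(stack, "derivative_stack"))
  T <- length(stack$ppg)
  min2 <- min2 %||% (min1 + T - 1L)
  empty <- structure(list(
    indices = stats::setNames(rep(NA_integer_, 14L), .ppg_point_names),
    amplitudes = stats::setNames(rep(NA_real_, 14L), .ppg_point_names),
    min1 = as.integer(min1), min2 = as.integer(min2),
    min2_amplitude = NA_real_, case = NA_character_, cd_present = 0L,
    fs = stack$fs, ok = FALSE, message = "", stack = stack),
    class = "fiducial_set")

  out <- tryCatch({
    os <- detect_O_S(stack$ppg)
    ab <- detect_ab(stack$apg, os$S, systolic_frac = systolic_frac)
    ef <- detect_ef(stack$apg, stack$jpg, ab$b, stack$ppg, stack$vpg, os$S)
    if (!(ab$b < ef$e))
      ppg_error("ppg_detection_error", "b does not precede e")
    case <- classify_case(stack$apg, stack$jpg, ab$b, ef$e, prominence_frac,
                          jerk_prominence_frac)
    cd <- locate_cd(case, stack$apg, stack$jpg, ab$b, ef$e, T, prominence_frac)
    vp <- detect_vpg_points(stack$vpg, os$S, stack$apg, ef$e)
    nd <- map_ND(ef$e, ef$f)
    idx <- c(O = os$O, S = os$S, N = nd$N, D = nd$D,
             w = vp$w, x = vp$x, y = vp$y, z = vp$z,
             a = ab$a, b = ab$b, c = cd$c, d = cd$d,
             e = ef$e, f = ef$f)
    # left-aligned differencing estimates each derivative roughly half a
    # sample late per order, so indices of derivative-borne points are
    # mapped back onto the PPG grid with a one-sample compensation
    shift_pts <- c("w", "y", "z", "a", "b", "c", "d", "e", "f", "N", "D")
    idx[shift_pts] <- pmin(idx[shift_pts] + 1L, T)
    amp <- vapply(.ppg_point_names, function(p) {
      i <- idx[[p]]
      if (is.na(i)) NA_real_ else stack[[.ppg_point_owner[[p]]]][i]
    }, numeric(1))
    res <- empty
    res$indices <- idx
    res$amplitudes <- amp
    res$min2_amplitude <- stack$ppg[T]
    res$case <- case
    res$cd_present <- cd$cd_present
    res$ok <- TRUE
    res
  }, ppgfiducial_error = function(cnd) {
    res <- empty
    res$message <- sprintf("%s: %s", subject_id, conditionMessage(cnd))
    res
  })
  out
}

#' @export
print.fiducial_set <- function(x, ...) {
  if (!x$ok) {
    cat("invalid beat:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("fiducial set (case %s, c/d %s), beat [%d, %d], fs = %g Hz\n",
              x$case, if (x$cd_present) "present" else "absent",
              x$min1, x$min2, x$fs))
  df <- data.frame(point = names(x$indices),
                   index = unname(x$indices),
                   time_s = unname(x$indices - 1) / x$fs,
                   amplitude = unname(signif(x$amplitudes, 5)))
  print(df, row.names = FALSE)
  invisible(x)
}
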