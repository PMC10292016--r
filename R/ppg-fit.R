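#' Control parameters for a fiducial-extraction run
#'
#' Collects every tunable of the pipeline with its defaults: a 0.4-8 Hz
#' Chebyshev type-II bandpass at 1 kHz, 25 ms / 30 ms moving-average
#' smoothing for the PPG and its derivatives, an SQI acceptance threshold
#' of 0.41, upstroke-gated 10%-prominence onset detection with a 0.3 s
#' beat-spacing floor, a 40%-of-beat systolic search region and
#' prominence-thresholded case classification.
#'
#' @param fl,fh bandpass stopband edges in Hz.
#' @param sqi_threshold skewness-SQI acceptance threshold (inclusive).
#' @param skip_sqi if `TRUE` (or no SQI table is available), the SQI is
#'   computed from the raw samples and a record is retained iff it is
#'   positive.
#' @param smooth_window_ppg_ms,smooth_window_deriv_ms centered moving-average
#'   windows (milliseconds) for the filtered PPG and for each derivative.
#' @param onset_prominence_frac,min_beat_spacing_s onset-detector settings
#'   (see [detect_onsets()]).
#' @param systolic_frac,prominence_frac fiducial-detector settings (see
#'   [detect_ab()] and [classify_case()]).
#' @return list of class `"ppg_control"`.
#' @export
ppg_control <- function(fl = 0.4, fh = 8,
                            sqi_threshold = 0.41, skip_sqi = FALSE,
                            smooth_window_ppg_ms = 25,
                            smooth_window_deriv_ms = 30,
                            onset_prominence_frac = 0.10,
                            min_beat_spacing_s = 0.3,
                            systolic_frac = 0.4,
                            prominence_frac = 0.03,
                            jerk_prominence_frac = 0.035) {
  structure(as.list(environment()), class = "ppg_control")
}

#' Extract PPG fiducial points and features from raw records
#'
#' The single entry point of the pipeline.  For every record: bandpass
#' filter (zero-phase Chebyshev type-II) and moving-average smoothing;
#' skewness-SQI screening; pulse-onset detection; extraction of the first
#' onset-bounded beat (Min1-Min2); velocity/acceleration/jerk derivatives;
#' the 14 fiducial points via the three-case c/d algorithm; and the
#' 30-value feature row.  Records that fail SQI screening or beat detection
#' are kept in the result with an invalid (all-`NA`) row and a reason --
#' a bad record never aborts the run.
#'
#' @param x a numeric vector (one record), a numeric matrix (one record per
#'   row), or a `"ppg_dataset"` from [read_ppg_matrix()] /
#'   [make_benchmark()].
#' @param fs sampling rate in Hz (ignored when `x` is a dataset).
#' @param sqi optional named numeric vector of per-subject SQI values
#'   (overrides the dataset's own table).
#' @param min1,min2 optional onset overrides (scalars or per-subject
#'   vectors); by default the first two detected onsets bound the beat.
#' @param control a [ppg_control()] list.
#' @return An object of class `"ppg_fit"`; see [summary.ppg_fit()],
#'   [coef.ppg_fit()], [plot.ppg_fit()], [output_bundle()] and
#'   [evaluate_detections()].
#' @examples
#' bench <- make_benchmark(n_subjects = 3, seed = 42)
#' fit <- ppg_fiducials(bench$dataset)
#' fit
#' head(coef(fit))[, 1:6]
#' @export
ppg_fiducials <- function(x, fs = 1000, sqi = NULL, min1 = NULL, min2 = NULL,
                    control = ppg_control()) {
  if (inherits(x, "ppg_dataset")) {
    fs <- x$fs
    sqi <- sqi %||% x$sqi
    ids <- x$ids
    x <- x$x
  } else if (is.numeric(x) && is.null(dim(x))) {
    x <- matrix(x, nrow = 1)
    ids <- "S001"
  } else ids <- rownames(x) %||% sprintf("S%03d", seq_len(nrow(x)))
  stopifnot(is.matrix(x), is.numeric(x))
  n <- nrow(x)
  spec <- design_bandpass(fs, control$fl, control$fh)
  win_ppg <- max(1L, round(control$smooth_window_ppg_ms / 1000 * fs))
  win_der <- max(1L, round(control$smooth_window_deriv_ms / 1000 * fs))

  fids <- vector("list", n)
  filtered <- matrix(NA_real_, n, ncol(x))
  segs_ppg <- matrix(0, n, 1200L)
  segs_apg <- matrix(0, n, 1200L)
  mm <- data.frame(subject_id = ids, Min1 = NA_integer_, Min2 = NA_integer_)
  status <- character(n)
  rows <- vector("list", n)

  for (i in seq_len(n)) {
    res <- tryCatch({
      raw <- x[i, ]
      s <- if (!is.null(sqi) && !control$skip_sqi) {
        if (!ids[i] %in% names(sqi))
          ppg_error("ppg_format_error", "subject missing from SQI table")
        sqi[[ids[i]]]
      } else skewness_sqi(raw)
      thr <- if (!is.null(sqi) && !control$skip_sqi) control$sqi_threshold else 0
      if (s < thr || (is.null(sqi) || control$skip_sqi) && s <= 0)
        ppg_error("ppg_sqi_reject", sprintf("SQI %.3f below threshold", s))
      f <- moving_average(apply_filter(raw, spec), win_ppg)
      filtered[i, ] <- f
      on <- detect_onsets(f, fs, control$onset_prominence_frac,
                          control$min_beat_spacing_s)
      m1 <- if (!is.null(min1)) rep_len(min1, n)[i] else on[1L]
      m2 <- if (!is.null(min2)) rep_len(min2, n)[i] else on[2L]
      beat <- extract_beat(f, m1, m2, fs, ids[i])
      stack <- compute_derivatives(beat$samples, win_der, fs)
      fid <- extract_fiducials(stack, m1, m2, ids[i],
                               control$prominence_frac, control$systolic_frac,
                               control$jerk_prominence_frac)
      segs_ppg[i, ] <- zero_pad(stack$ppg)
      segs_apg[i, ] <- zero_pad(stack$apg)
      mm$Min1[i] <- m1; mm$Min2[i] <- m2
      list(fid = fid, status = if (fid$ok) "ok" else fid$message)
    }, error = function(cnd) {
      list(fid = NULL, status = sprintf("%s: %s", ids[i], conditionMessage(cnd)))
    })
    fids[i] <- list(res$fid)
    status[i] <- res$status
    rows[[i]] <- if (!is.null(res$fid)) build_feature_row(res$fid, fs)
                 else stats::setNames(rep(NA_real_, 30L), .ppg_feature_names)
  }
  structure(list(ids = ids, fs = fs, control = control, filter = spec,
                 fiducials = fids, features = build_feature_table(rows, ids),
                 filtered = filtered, ppg_segments = segs_ppg,
                 apg_segments = segs_apg, min1min2 = mm, status = status),
            class = "ppg_fit")
}

#' @export
print.ppg_fit <- function(x, ...) {
  ok <- x$status == "ok"
  cat(sprintf("PPG fiducial extraction: %d/%d record(s) extracted at %g Hz\n",
              sum(ok), length(ok), x$fs))
  if (any(ok)) {
    cs <- table(factor(vapply(x$fiducials[ok], `[[`, "", "case"),
                       levels = c("I", "II", "III")))
    cat(sprintf("  morphology cases: I %d, II %d, III %d; c/d present in %d\n",
                cs[["I"]], cs[["II"]], cs[["III"]],
                sum(vapply(x$fiducials[ok], `[[`, 0L, "cd_present"))))
  }
  if (any(!ok)) cat(sprintf("  failed: %s\n",
                            paste(x$ids[!ok], collapse = ", ")))
  invisible(x)
}

#' @export
summary.ppg_fit <- function(object, ...) {
  ok <- object$status == "ok"
  tms <- object$features[ok, grep("_t$", names(object$features)), drop = FALSE]
  out <- list(n = length(ok), n_ok = sum(ok),
              cases = table(factor(vapply(object$fiducials[ok], `[[`, "", "case"),
                                   levels = c("I", "II", "III"))),
              time_summary = if (nrow(tms)) t(apply(tms, 2, function(v)
                c(mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE)))),
              failures = object$status[!ok])
  class(out) <- "summary.ppg_fit"
  out
}

#' @export
print.summary.ppg_fit <- function(x, ...) {
  cat(sprintf("%d/%d records extracted; cases I/II/III: %d/%d/%d\n",
              x$n_ok, x$n, x$cases[["I"]], x$cases[["II"]], x$cases[["III"]]))
  if (!is.null(x$time_summary)) {
    cat("fiducial times from beat onset (s):\n")
    print(round(x$time_summary, 4))
  }
  if (length(x$failures)) cat("failures:\n ", paste(x$failures, collapse = "\n  "), "\n")
  invisible(x)
}

#' Extract the feature table from a fitted object
#'
#' @param object a `"ppg_fit"` object.
#' @param ... unused.
#' @return the n x 30 feature data.frame (plus `subject_id`).
#' @export
coef.ppg_fit <- function(object, ...) object$features

#' Plot one beat with its fiducial markers
#'
#' Draws the extracted beat's PPG, VPG and APG with the detected fiducial
#' points highlighted, mirroring the standard three-panel pulse-wave-analysis
#' view.
#'
#' @param x a `"ppg_fit"` object.
#' @param subject subject id or row index (default first valid record).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ppg_fit <- function(x, subject = NULL, ...) {
  i <- if (is.null(subject)) which(x$status == "ok")[1L]
       else if (is.character(subject)) match(subject, x$ids) else subject
  if (is.na(i) || is.null(x$fiducials[[i]]) || !x$fiducials[[i]]$ok)
    ppg_error("ppg_parameter_error", "no valid extraction to plot for that subject")
  fid <- x$fiducials[[i]]
  stack <- fid$stack
  t <- (seq_along(stack$ppg) - 1) / x$fs
  old <- par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(par(old))
  panels <- list(ppg = c("O", "S", "N", "D"), vpg = c("w", "x", "y", "z"),
                 apg = c("a", "b", "c", "d", "e", "f"))
  for (wave in names(panels)) {
    v <- stack[[wave]]
    plot(t, v, type = "l", xlab = "", ylab = toupper(wave),
         main = if (wave == "ppg")
           sprintf("%s (case %s)", x$ids[i], fid$case) else "", ...)
    pts <- panels[[wave]]
    idx <- fid$indices[pts]
    keep <- !is.na(idx)
    if (any(keep)) {
      points(t[idx[keep]], v[idx[keep]], col = "red", pch = 19)
      text(t[idx[keep]], v[idx[keep]], labels = pts[keep], pos = 3, col = "red")
    }
  }
  invisible(x)
}

#' Assemble the exportable output bundle
#'
#' Collects the six standard outputs (feature table, filtered records,
#' zero-padded PPG and APG segments, Min1/Min2 table, c/d presence flags)
#' for [write_outputs()].  Rows are restricted to records that passed SQI
#' screening and onset detection (invalid extractions keep their all-`NA`
#' feature row).
#'
#' @param object a `"ppg_fit"` object.
#' @return list of class `"ppg_output_bundle"`.
#' @export
output_bundle <- function(object) {
  stopifnot(inherits(object, "ppg_fit"))
  keep <- !is.na(object$min1min2$Min1)
  structure(list(
    feature_table = object$features[keep, , drop = FALSE],
    filtered_ppg = object$filtered[keep, , drop = FALSE],
    ppg_segments = object$ppg_segments[keep, , drop = FALSE],
    apg_segments = object$apg_segments[keep, , drop = FALSE],
    id_min1_min2 = object$min1min2[keep, , drop = FALSE],
    c_d_presence = vapply(object$fiducials[keep], function(f)
      if (is.null(f)) 0L else f$cd_present, integer(1))),
    class = "ppg_output_bundle")
}

#' Evaluate detections against a reference annotation
#'
#' Matches every subject's detected fiducials (in record-relative indices)
#' against the same-named reference points at a timing tolerance, counts
#' TP/FP/FN per subject, and reports sensitivity, positive predictivity,
#' error rate and accuracy per morphology case and pooled.  Stratification
#' uses the reference's `case` column when present, otherwise the detected
#' case.
#'
#' @param object a `"ppg_fit"` object.
#' @param reference data.frame as produced by [make_benchmark()] or
#'   [read_reference()].
#' @param tol_s matching tolerance in seconds (default 0.01).
#' @param fp_only see [match_points()].
#' @return list of class `"ppg_eval"`: `per_subject` counts and the
#'   stratified `report`.
#' @export
evaluate_detections <- function(object, reference, tol_s = 0.01,
                                fp_only = FALSE) {
  stopifnot(inherits(object, "ppg_fit"), is.data.frame(reference))
  common <- intersect(object$ids, reference$subject_id)
  if (!length(common))
    ppg_error("ppg_format_error", "no overlapping subject ids to evaluate")
  per <- vector("list", length(common))
  for (k in seq_along(common)) {
    i <- match(common[k], object$ids)
    r <- reference[match(common[k], reference$subject_id), ]
    fid <- object$fiducials[[i]]
    det <- stats::setNames(rep(NA_integer_, 14L), .ppg_point_names)
    if (!is.null(fid) && fid$ok)
      det <- fid$indices + fid$min1 - 1L       # record-relative
    ref <- vapply(.ppg_point_names, function(p)
      suppressWarnings(as.integer(r[[p]])), integer(1))
    mp <- match_points(det, ref, tol_s, object$fs, fp_only)
    cs <- if (!is.null(r$case)) r$case
          else if (!is.null(fid) && fid$ok) fid$case else "I"
    per[[k]] <- data.frame(subject_id = common[k], case = cs,
                           TP = mp$counts[["TP"]], FP = mp$counts[["FP"]],
                           FN = mp$counts[["FN"]], TFP = mp$counts[["TFP"]])
  }
  per <- do.call(rbind, per)
  structure(list(per_subject = per, report = stratified_report(per),
                 tol_s = tol_s), class = "ppg_eval")
}

#' @export
print.ppg_eval <- function(x, ...) {
  cat(sprintf("Fiducial detection performance (tolerance %g ms)\n",
              1000 * x$tol_s))
  rep <- x$report
  rep[c("S", "PP", "Err", "Acc")] <- lapply(rep[c("S", "PP", "Err", "Acc")], round2)
  names(rep)[names(rep) == "case"] <- "Algorithm"
  print(rep, row.names = FALSE)
  invisible(x)
}
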