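#' Match detected fiducials against a reference annotation
#'
#' Compares each of the 14 named points of a detection with its same-named
#' reference index (never across names).  A detected point within `tol_s`
#' seconds of the reference is a true positive; a detected point with no
#' reference within tolerance is a false positive; an annotated point that
#' was missed is a false negative.  By default a mislocated point (both
#' present, too far apart) counts as a miss *and* a spurious detection
#' (FP + FN); set `fp_only = TRUE` to count it once as FP.
#'
#' @param detected named integer vector of detected indices (record- or
#'   segment-relative, as long as the reference uses the same convention),
#'   or a `"fiducial_set"` (compared segment-relative).
#' @param reference named integer vector of reference indices; `NA` means
#'   the point is not annotated.
#' @param tol_s matching tolerance in seconds (default 0.01).
#' @param fs sampling rate in Hz.
#' @param fp_only count a mislocated point as FP only (default `FALSE`).
#' @return list with `labels` (per point: "TP", "FP", "FN", "FP+FN" or "")
#'   and `counts` (`TP`, `FP`, `FN`, `TFP` with `TFP = 14`).
#' @export
match_points <- function(detected, reference, tol_s = 0.01, fs = 1000,
                         fp_only = FALSE) {
  if (tol_s <= 0) ppg_error("ppg_parameter_error", "`tol_s` must be positive")
  if (inherits(detected, "fiducial_set")) detected <- detected$indices
  unknown <- setdiff(names(reference), .ppg_point_names)
  if (length(unknown))
    ppg_error("ppg_format_error",
              sprintf("unknown point name(s) in reference: %s",
                      paste(unknown, collapse = ", ")))
  tol <- tol_s * fs
  labels <- stats::setNames(character(14L), .ppg_point_names)
  tp <- fp <- fn <- 0L
  for (p in .ppg_point_names) {
    d <- if (p %in% names(detected)) detected[[p]] else NA_integer_
    r <- if (p %in% names(reference)) reference[[p]] else NA_integer_
    if (is.na(d) && is.na(r)) { labels[p] <- ""; next }
    if (is.na(d)) { labels[p] <- "FN"; fn <- fn + 1L; next }
    if (is.na(r)) { labels[p] <- "FP"; fp <- fp + 1L; next }
    if (abs(d - r) <= tol) { labels[p] <- "TP"; tp <- tp + 1L }
    else if (fp_only) { labels[p] <- "FP"; fp <- fp + 1L }
    else { labels[p] <- "FP+FN"; fp <- fp + 1L; fn <- fn + 1L }
  }
  list(labels = labels,
       counts = c(TP = tp, FP = fp, FN = fn, TFP = 14L))
}

#' Detection metrics from contingency counts
#'
#' The four standard detector metrics, as percentages:
#' accuracy `Acc = 100 TP / (TP + FP + FN)`,
#' error rate `Err = 100 (FP + FN) / TFP`,
#' sensitivity `S = 100 TP / (TP + FN)` and
#' positive predictivity `PP = 100 TP / (TP + FP)`.
#'
#' @param counts named numeric vector or list with `TP`, `FP`, `FN`, `TFP`.
#' @return list with raw (unrounded) `Acc`, `Err`, `S`, `PP` and the counts.
#' @export
compute_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN; tfp <- counts$TFP
  if (any(c(tp, fp, fn, tfp) < 0))
    ppg_error("ppg_parameter_error", "counts must be non-negative")
  if (tp + fp + fn == 0 || tfp == 0)
    ppg_error("ppg_undefined_metric_error",
              "metrics undefined: no attempted points")
  list(Acc = 100 * tp / (tp + fp + fn),
       Err = 100 * (fp + fn) / tfp,
       S   = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       PP  = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
       counts = c(TP = tp, FP = fp, FN = fn, TFP = tfp))
}

#' Per-case and pooled detection report
#'
#' Aggregates per-subject contingency counts by morphology case, computes
#' the four metrics for each case, and appends a pooled row whose counts are
#' summed *before* the metrics are computed.
#'
#' @param per_subject data.frame with columns `case` (in `"I"`, `"II"`,
#'   `"III"`), `TP`, `FP`, `FN`, `TFP`, one row per subject (a column `N`
#'   is accepted and ignored).
#' @return data.frame with rows `I`, `II`, `III` (cases present) and
#'   `Pooled`; columns `case`, `N`, `TFP`, `TP`, `FP`, `FN`, `S`, `PP`,
#'   `Err`, `Acc` (metrics unrounded).
#' @export
stratified_report <- function(per_subject) {
  stopifnot(is.data.frame(per_subject),
            all(c("case", "TP", "FP", "FN", "TFP") %in% names(per_subject)))
  if (nrow(per_subject) == 0L)
    ppg_error("ppg_parameter_error", "no subjects to report on")
  one <- function(df, label) {
    m <- compute_metrics(c(TP = sum(df$TP), FP = sum(df$FP),
                           FN = sum(df$FN), TFP = sum(df$TFP)))
    data.frame(case = label, N = nrow(df),
               TFP = sum(df$TFP), TP = sum(df$TP),
               FP = sum(df$FP), FN = sum(df$FN),
               S = m$S, PP = m$PP, Err = m$Err, Acc = m$Acc)
  }
  cases <- intersect(c("I", "II", "III"), unique(per_subject$case))
  rows <- lapply(cases, function(cs) one(per_subject[per_subject$case == cs, ], cs))
  rows[[length(rows) + 1L]] <- one(per_subject, "Pooled")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# display rounding used for reports: half away from zero, 2 decimals
round2 <- function(x) round_half_away(x * 100) / 100
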