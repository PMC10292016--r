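#' Build the 30-value feature row for one beat
#'
#' Converts a fiducial set into the standard feature row: 15 magnitudes
#' (`O, S, N, D, Min2, w, x, y, z, a, b, c, d, e, f`, each read off the
#' waveform that owns the point -- PPG for O/S/N/D and Min2, VPG for w-z,
#' APG for a-f) followed by 15 time-domain values (`O_t ... f_t`, seconds
#' from the beat onset, so `O_t = 0`).  A beat whose c/d pair was not
#' detected carries `NA` in `c`, `d`, `c_t`, `d_t`; an invalid beat yields an
#' all-`NA` row.
#'
#' @param fid a `"fiducial_set"` from [extract_fiducials()].
#' @param fs sampling rate in Hz (defaults to the one stored in `fid`).
#' @return named numeric vector of length 30.
#' @export
build_feature_row <- function(fid, fs = fid$fs) {
  stopifnot(inherits(fid, "fiducial_set"))
  row <- stats::setNames(rep(NA_real_, 30L), .ppg_feature_names)
  if (!isTRUE(fid$ok)) return(row)
  idx <- fid$indices
  mag <- fid$amplitudes
  ord <- c("O", "S", "N", "D", "w", "x", "y", "z",
           "a", "b", "c", "d", "e", "f")
  for (p in ord) {
    row[[p]] <- mag[[p]]
    row[[paste0(p, "_t")]] <- (idx[[p]] - idx[["O"]]) / fs
  }
  row[["Min2"]] <- fid$min2_amplitude
  row[["Min2_t"]] <- (fid$min2 - fid$min1) / fs
  row
}

#' Assemble the n x 30 feature table
#'
#' Stacks per-beat feature rows into the canonical feature table, one row
#' per subject, with the frozen column order of the 15 magnitude and 15
#' time-domain features.
#'
#' @param rows list of feature rows (from [build_feature_row()]).
#' @param ids character vector of subject ids, same length as `rows`.
#' @return data.frame with a `subject_id` column followed by the 30 feature
#'   columns.
#' @export
build_feature_table <- function(rows, ids) {
  if (length(rows) != length(ids))
    ppg_error("ppg_consistency_error", "`rows` and `ids` lengths differ")
  if (anyDuplicated(ids))
    ppg_error("ppg_consistency_error",
              sprintf("duplicate subject id '%s'", ids[anyDuplicated(ids)]))
  if (length(rows) == 0L) {
    tab <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), 30L), .ppg_feature_names))
    return(cbind(data.frame(subject_id = character(0)), tab))
  }
  bad <- which(vapply(rows, function(r)
    length(r) != 30L || !identical(names(r), .ppg_feature_names), logical(1)))
  if (length(bad))
    ppg_error("ppg_consistency_error",
              sprintf("row %d is not a 30-column feature row", bad[1]))
  tab <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(subject_id = as.character(ids), stringsAsFactors = FALSE), tab)
}
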