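#' Read a raw PPG matrix from CSV
#'
#' Reads a headerless rectangular numeric CSV, one subject per row, one
#' sample per column (the reference layout is 219 rows x 2100 columns at
#' 1 kHz).  Subject ids default to `"S001"`, `"S002"`, ... in row order.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz shared by all records.
#' @param ids optional character vector of subject ids (length = rows).
#' @return An object of class `"ppg_dataset"`: list with `x` (numeric
#'   matrix), `ids`, `fs` and (optional, here `NULL`) `sqi`.
#' @export
read_ppg_matrix <- function(path, fs = 1000, ids = NULL) {
  if (!file.exists(path)) ppg_error("ppg_io_error", sprintf("no such file: %s", path))
  if (fs <= 0) ppg_error("ppg_parameter_error", "`fs` must be positive")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) ppg_error("ppg_empty_input_error", sprintf("empty file: %s", path))
  split <- strsplit(lines, ",", fixed = TRUE)
  w <- lengths(split)
  if (length(unique(w)) != 1L)
    ppg_error("ppg_format_error",
              sprintf("ragged rows: row 1 has %d columns but row %d has %d",
                      w[1], which(w != w[1])[1], w[w != w[1]][1]))
  x <- matrix(NA_real_, length(split), w[1])
  for (i in seq_along(split)) {
    v <- suppressWarnings(as.numeric(split[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      ppg_error("ppg_parse_error",
                sprintf("non-numeric value '%s' at row %d, column %d",
                        split[[i]][j], i, j))
    }
    x[i, ] <- v
  }
  n <- nrow(x)
  ids <- ids %||% sprintf("S%03d", seq_len(n))
  if (length(ids) != n || anyDuplicated(ids))
    ppg_error("ppg_format_error", "`ids` must be unique, one per row")
  structure(list(x = x, ids = as.character(ids), fs = fs, sqi = NULL),
            class = "ppg_dataset")
}

#' @export
print.ppg_dataset <- function(x, ...) {
  cat(sprintf("PPG dataset: %d record(s) x %d samples at %g Hz%s\n",
              nrow(x$x), ncol(x$x), x$fs,
              if (!is.null(x$sqi)) " (with SQI table)" else ""))
  invisible(x)
}

#' Read a per-subject skewness-SQI table
#'
#' Two-column CSV (subject id, SQI value), with or without a header row.
#'
#' @param path CSV file path.
#' @return named numeric vector keyed by subject id (possibly empty, with a
#'   warning).
#' @export
read_sqi_table <- function(path) {
  if (!file.exists(path)) ppg_error("ppg_io_error", sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) &&
      grepl("^\\s*(subject_?id|id)\\s*,", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) {
    warning("empty SQI table")
    return(stats::setNames(numeric(0), character(0)))
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    ppg_error("ppg_format_error", "SQI table must have exactly two columns")
  id <- trimws(vapply(parts, `[`, character(1), 1L))
  val <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(val))
    ppg_error("ppg_parse_error",
              sprintf("non-numeric SQI for subject '%s'", id[which(is.na(val))[1]]))
  if (anyDuplicated(id))
    ppg_error("ppg_duplicate_key_error",
              sprintf("duplicate subject id '%s' in SQI table", id[anyDuplicated(id)]))
  stats::setNames(val, id)
}

#' Read a reference fiducial annotation table
#'
#' CSV with a header: `subject_id`, optionally `min1`/`min2`, the 14 point
#' columns (`O,S,N,D,w,x,y,z,a,b,c,d,e,f`; 1-based record-relative sample
#' indices, empty cells for unannotated points), optionally `case` and
#' `cd_present`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) ppg_error("ppg_io_error", sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("subject_id", .ppg_point_names), names(df))
  if (length(missing))
    ppg_error("ppg_format_error",
              sprintf("reference lacks column(s): %s", paste(missing, collapse = ", ")))
  df
}

#' Write the standard output file suite
#'
#' Writes the six canonical CSV outputs of a fiducial-extraction run:
#' `PPG_features.csv` (n x 30 feature table plus a subject id column),
#' `PPG_Filtered_HighSQI.csv` (n x w filtered records),
#' `PPG_Segments.csv` and `APG_Segments.csv` (n x 1200, trailing
#' zero-padded beat segments), `ID_min1_min2.csv` (id, Min1, Min2; 1-based)
#' and `c_d_presence.csv` (0/1 per subject).  All components must agree on
#' the subject count and ordering; nothing is written on a mismatch.
#'
#' @param bundle output bundle from [output_bundle()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress the per-file log messages.
#' @return invisible character vector of written paths.
#' @export
write_outputs <- function(bundle, outdir, quiet = FALSE) {
  stopifnot(inherits(bundle, "ppg_output_bundle"))
  n <- nrow(bundle$feature_table)
  dims <- c(nrow(bundle$filtered_ppg), nrow(bundle$ppg_segments),
            nrow(bundle$apg_segments), nrow(bundle$id_min1_min2),
            length(bundle$c_d_presence))
  if (any(dims != n))
    ppg_error("ppg_consistency_error",
              "output components disagree on the number of subjects")
  if (ncol(bundle$feature_table) != 31L)  # subject_id + 30 features
    ppg_error("ppg_consistency_error", "feature table must have 30 feature columns")
  if (ncol(bundle$ppg_segments) != 1200L || ncol(bundle$apg_segments) != 1200L)
    ppg_error("ppg_consistency_error", "segment matrices must have 1200 columns")
  if (n > 0 && !all(bundle$c_d_presence %in% c(0L, 1L)))
    ppg_error("ppg_consistency_error", "c_d_presence must be 0/1")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  fmt_col <- function(v) {
    if (!is.numeric(v)) return(as.character(v))
    out <- sprintf("%.15g", v)
    out[is.na(v)] <- ""
    out
  }
  write_mat <- function(m, file, col_names = FALSE) {
    path <- file.path(outdir, file)
    df <- as.data.frame(m)
    ch <- vapply(df, fmt_col, character(nrow(df) %||% 0))
    if (nrow(df) == 1L) ch <- matrix(ch, nrow = 1L, dimnames = list(NULL, names(df)))
    if (nrow(df) == 0L) ch <- matrix(character(0), 0L, ncol(df),
                                     dimnames = list(NULL, names(df)))
    lines <- if (nrow(df)) apply(ch, 1L, paste, collapse = ",") else character(0)
    if (col_names) lines <- c(paste(names(df), collapse = ","), lines)
    writeLines(lines, path)
    if (!quiet) message("wrote ", path)
    path
  }
  paths <- c(
    write_mat(bundle$feature_table, "PPG_features.csv", col_names = TRUE),
    write_mat(bundle$filtered_ppg, "PPG_Filtered_HighSQI.csv"),
    write_mat(bundle$ppg_segments, "PPG_Segments.csv"),
    write_mat(bundle$apg_segments, "APG_Segments.csv"),
    write_mat(bundle$id_min1_min2, "ID_min1_min2.csv", col_names = TRUE),
    write_mat(data.frame(c_d_presence = bundle$c_d_presence),
              "c_d_presence.csv", col_names = TRUE))
  invisible(paths)
}

zero_pad <- function(v, width = 1200L) {
  v <- v[seq_len(min(length(v), width))]
  c(v, rep(0, width - length(v)))
}
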