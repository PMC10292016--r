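test_that("raw PPG matrices round-trip through CSV", {
  d <- withr::local_tempdir()
  x <- matrix(round(rnorm(5 * 300), 6), 5, 300)
  path <- file.path(d, "ppg.csv")
  writeLines(apply(x, 1, function(r) paste(r, collapse = ",")), path)
  ds <- read_ppg_matrix(path, fs = 1000)
  expect_s3_class(ds, "ppg_dataset")
  expect_identical(dim(ds$x), c(5L, 300L))
  expect_equal(ds$x, x, ignore_attr = TRUE)
  expect_identical(ds$ids, sprintf("S%03d", 1:5))
})

test_that("a one-row file of zeros reads as one record", {
  d <- withr::local_tempdir()
  path <- file.path(d, "z.csv")
  writeLines(paste(rep(0, 10), collapse = ","), path)
  ds <- read_ppg_matrix(path)
  expect_identical(dim(ds$x), c(1L, 10L))
  expect_true(all(ds$x == 0))
})

test_that("malformed PPG matrices are rejected with located errors", {
  d <- withr::local_tempdir()
  ragged <- file.path(d, "ragged.csv")
  writeLines(c(paste(1:5, collapse = ","), paste(1:4, collapse = ",")), ragged)
  expect_ppg_error(read_ppg_matrix(ragged), "ppg_format_error")
  bad <- file.path(d, "bad.csv")
  writeLines(c("1,2,3", "4,x,6"), bad)
  err <- tryCatch(read_ppg_matrix(bad), error = identity)
  expect_s3_class(err, "ppg_parse_error")
  expect_match(conditionMessage(err), "row 2, column 2")
  empty <- file.path(d, "empty.csv")
  writeLines(character(0), empty)
  expect_ppg_error(read_ppg_matrix(empty), "ppg_empty_input_error")
  expect_ppg_error(read_ppg_matrix(file.path(d, "nope.csv")), "ppg_io_error")
})

test_that("SQI tables read into keyed maps with validation", {
  d <- withr::local_tempdir()
  path <- file.path(d, "sqi.csv")
  writeLines(c("S001,0.52", "S002,0.30"), path)
  sq <- read_sqi_table(path)
  expect_identical(sq, c(S001 = 0.52, S002 = 0.30))
  writeLines(c("S001,0.52", "S001,0.30"), path)
  expect_ppg_error(read_sqi_table(path), "ppg_duplicate_key_error")
  writeLines(c("S001,abc"), path)
  expect_ppg_error(read_sqi_table(path), "ppg_parse_error")
  writeLines(character(0), path)
  expect_warning(sq0 <- read_sqi_table(path), "empty")
  expect_length(sq0, 0)
})

test_that("the output suite is written, consistent and re-readable", {
  bench <- small_bench()
  fit <- ppg_fiducials(bench$dataset)
  bundle <- output_bundle(fit)
  d <- withr::local_tempdir()
  paths <- suppressMessages(write_outputs(bundle, d))
  expect_setequal(basename(paths),
                  c("PPG_features.csv", "PPG_Filtered_HighSQI.csv",
                    "PPG_Segments.csv", "APG_Segments.csv",
                    "ID_min1_min2.csv", "c_d_presence.csv"))
  seg <- read_ppg_matrix(file.path(d, "PPG_Segments.csv"))
  expect_identical(dim(seg$x), c(6L, 1200L))
  expect_equal(seg$x, bundle$ppg_segments, ignore_attr = TRUE,
               tolerance = 1e-10)
  filt <- read_ppg_matrix(file.path(d, "PPG_Filtered_HighSQI.csv"))
  expect_equal(filt$x, bundle$filtered_ppg, ignore_attr = TRUE,
               tolerance = 1e-10)
  feats <- utils::read.csv(file.path(d, "PPG_features.csv"))
  expect_identical(dim(feats), c(6L, 31L))
  # row alignment: every file's i-th row describes the same subject
  mm <- utils::read.csv(file.path(d, "ID_min1_min2.csv"))
  expect_identical(mm$subject_id, feats$subject_id)
  cd <- utils::read.csv(file.path(d, "c_d_presence.csv"))
  expect_true(all(cd$c_d_presence %in% 0:1))
})

test_that("inconsistent bundles are refused before writing", {
  bench <- small_bench()
  bundle <- output_bundle(ppg_fiducials(bench$dataset))
  d <- withr::local_tempdir()
  broken <- bundle
  broken$feature_table <- broken$feature_table[, -5]
  expect_ppg_error(write_outputs(broken, d), "ppg_consistency_error")
  broken2 <- bundle
  broken2$c_d_presence <- broken2$c_d_presence[-1]
  expect_ppg_error(write_outputs(broken2, d), "ppg_consistency_error")
  expect_length(list.files(d), 0)
})

test_that("an empty bundle writes header-only files", {
  bench <- small_bench()
  bundle <- output_bundle(ppg_fiducials(bench$dataset))
  for (nm in c("feature_table", "filtered_ppg", "ppg_segments",
               "apg_segments", "id_min1_min2"))
    bundle[[nm]] <- bundle[[nm]][0, , drop = FALSE]
  bundle$c_d_presence <- integer(0)
  d <- withr::local_tempdir()
  paths <- suppressMessages(write_outputs(bundle, d))
  expect_length(paths, 6)
  feats <- utils::read.csv(file.path(d, "PPG_features.csv"))
  expect_identical(nrow(feats), 0L)
  expect_identical(ncol(feats), 31L)
})

test_that("written CSVs preserve at least 10 significant digits", {
  bench <- small_bench()
  fit <- ppg_fiducials(bench$dataset)
  bundle <- output_bundle(fit)
  d <- withr::local_tempdir()
  suppressMessages(write_outputs(bundle, d))
  feats <- utils::read.csv(file.path(d, "PPG_features.csv"))
  orig <- bundle$feature_table
  num <- names(orig)[-1]
  for (cn in num) {
    o <- orig[[cn]]; r <- feats[[cn]]
    sel <- !is.na(o)
    expect_true(all(abs(r[sel] - o[sel]) <=
                      pmax(abs(o[sel]), 1e-300) * 1e-10))
    expect_identical(is.na(r), is.na(o))
  }
})
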