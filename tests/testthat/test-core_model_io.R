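# Data model, archive/DICOM dialects, NIfTI map output.

test_that("dynamic series and study constructors enforce their invariants", {
  m <- frame_meta(0:4, 0:4)
  expect_error(dynamic_series(array(1, c(4, 8, 8)), m), class = "pq_invalid_series")
  expect_error(frame_meta(c(0, 1, 1), 0:2), class = "pq_invalid_meta")
  expect_error(frame_meta(0:2, 0:2, pixel_spacing_row = 0),
               class = "pq_invalid_meta")
  # frames sorted by trigger_index regardless of input order
  perm <- c(3, 1, 5, 2, 4)
  fr <- array(0, c(5, 4, 4)); for (i in 1:5) fr[i, , ] <- perm[i]
  ds <- dynamic_series(fr, frame_meta(perm - 1, perm - 1), role = "MYO")
  expect_equal(ds$frames[, 1, 1], as.numeric(1:5))
  expect_equal(ds$meta$trigger_index, 0:4)

  ph <- tiny_phantom()
  conds <- ph$study$conditions
  broken <- conds
  broken$stress$pd[[2]] <- NULL
  expect_error(perfusion_study(broken), class = "pq_missing_role")
  broken2 <- conds
  broken2$stress$aif <- NULL
  err <- tryCatch(perfusion_study(broken2), error = function(e) e)
  expect_s3_class(err, "pq_missing_role")
  expect_match(conditionMessage(err), "AIF")
})

test_that("phantom study has the dual-sequence frame counts", {
  ph <- cached("counts", function()
    build_phantom(phantom_spec(image_size = 48, aif_size = c(24, 18)),
                  seed = 1))
  for (cond in c("stress", "rest")) {
    cnd <- ph$study$conditions[[cond]]
    expect_equal(dim(cnd$aif$frames)[1], 60)
    for (sl in 1:3) {
      expect_equal(dim(cnd$myo[[sl]]$frames)[1], 60)
      expect_equal(dim(cnd$pd[[sl]]$frames)[1], 2)
    }
  }
})

test_that("archive round trip is bit-exact and structurally complete", {
  ph <- tiny_phantom()
  dir <- withr::local_tempdir()
  manifest <- write_study(ph$study, dir)
  expect_setequal(names(manifest$conditions), c("stress", "rest"))
  for (cond in manifest$conditions) {
    expect_length(cond$myo, 3)
    expect_length(cond$pd, 3)
    expect_false(is.null(cond$aif))
  }
  back <- read_study(dir, "archive")
  expect_identical(back$subject_id, ph$study$subject_id)
  expect_equal(back$rr_interval_s, ph$study$rr_interval_s)
  for (cond in c("stress", "rest")) {
    a <- ph$study$conditions[[cond]]; b <- back$conditions[[cond]]
    expect_identical(a$aif$frames, b$aif$frames)
    for (sl in 1:3) {
      expect_identical(a$myo[[sl]]$frames, b$myo[[sl]]$frames)
      expect_identical(a$pd[[sl]]$frames, b$pd[[sl]]$frames)
      expect_equal(a$myo[[sl]]$meta, b$myo[[sl]]$meta)
    }
  }
  # defined error cases
  expect_error(write_study(structure(list(conditions = list()),
                                     class = "PerfusionStudy"),
                           withr::local_tempdir()),
               class = "pq_invalid_study")
  expect_error(read_study(file.path(dir, "no-such"), "archive"),
               class = "pq_io")
})

test_that("DICOM dialect round-trips integer studies and resolves roles", {
  ph <- tiny_phantom()
  st <- ph$study
  for (cond in names(st$conditions)) {           # quantize to integers
    st$conditions[[cond]]$aif$frames <- round(st$conditions[[cond]]$aif$frames)
    for (sl in 1:3) {
      st$conditions[[cond]]$myo[[sl]]$frames <-
        round(st$conditions[[cond]]$myo[[sl]]$frames)
      st$conditions[[cond]]$pd[[sl]]$frames <-
        round(st$conditions[[cond]]$pd[[sl]]$frames)
    }
  }
  dir <- withr::local_tempdir()
  write_dicom_study(st, dir)
  back <- read_study(dir, "dicom", rr_interval_s = st$rr_interval_s)
  for (cond in c("stress", "rest")) {
    expect_identical(back$conditions[[cond]]$aif$frames,
                     st$conditions[[cond]]$aif$frames)
    for (sl in 1:3) {
      expect_identical(back$conditions[[cond]]$myo[[sl]]$frames,
                       st$conditions[[cond]]$myo[[sl]]$frames)
      expect_equal(back$conditions[[cond]]$myo[[sl]]$meta$acquisition_time,
                   st$conditions[[cond]]$myo[[sl]]$meta$acquisition_time)
      expect_equal(back$conditions[[cond]]$myo[[sl]]$meta$trigger_index,
                   st$conditions[[cond]]$myo[[sl]]$meta$trigger_index)
    }
  }
  # reading is insensitive to file listing order (trigger sort is canonical)
  expect_equal(back$conditions$stress$myo[[1]]$meta$trigger_index, 0:39)
  # missing role: drop all PD files
  unlink(list.files(dir, pattern = "PD", full.names = TRUE))
  expect_error(read_study(dir, "dicom"), class = "pq_missing_role")
})

test_that("write_map float image is lossless; tables enumerate the mask", {
  vals <- matrix(c(1, 2, 3, 4), 2, 2)
  map <- mbf_map(vals, matrix(TRUE, 2, 2), 0L, "stress")
  nii <- withr::local_tempfile(fileext = ".nii")
  write_map(map, nii, "float_image")
  expect_identical(read_nifti(nii), vals)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_map(map, csv, "table")
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$value[tab$row == 2 & tab$col == 1], 2)

  empty <- mbf_map(matrix(NA_real_, 2, 2), matrix(FALSE, 2, 2), 0L, "rest")
  write_map(empty, csv, "table")
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 0)
  expect_named(tab, c("row", "col", "value"))

  # random 3-D stack round trip through the NIfTI container
  set.seed(1)
  x <- array(rnorm(5 * 7 * 6), c(5, 7, 6))
  write_nifti(x, nii)
  expect_identical(read_nifti(nii), x)
})

test_that("mbf_map validates masked values", {
  bad <- matrix(c(-1, 1, 1, 1), 2, 2)
  expect_error(mbf_map(bad, matrix(TRUE, 2, 2), 0L, "stress"),
               class = "pq_invalid_map")
  # failed pixels may be NA when flagged
  ok <- mbf_map(matrix(c(NA, 1, 1, 1), 2, 2), matrix(TRUE, 2, 2), 0L, "stress",
                failed = matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_s3_class(ok, "MBFMap")
})
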