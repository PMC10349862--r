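test_that("text rasters parse values and geometry", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# pixel_spacing_mm: 0.8 0.8", "# slice_thickness_mm: 5",
               paste(rep("725", 4), collapse = " "),
               paste(rep("725", 4), collapse = " "),
               paste(rep("725", 4), collapse = " "),
               paste(rep("725", 4), collapse = " ")), f)
  m <- read_adc_map(f)
  expect_equal(dim(m$values), c(4L, 4L))
  expect_true(all(m$values == 725))
  expect_equal(m$pixel_spacing_mm, c(0.8, 0.8))
  expect_equal(voxel_volume(m), 3.2)
})

test_that("map writers round-trip losslessly", {
  m <- adc_map(matrix(runif(120, 500, 1800), 10, 12),
               pixel_spacing_mm = c(0.8, 0.9), slice_thickness_mm = 5)
  ftxt <- withr::local_tempfile(fileext = ".txt")
  write_adc_map(m, ftxt)
  m2 <- read_adc_map(ftxt)
  expect_lt(max(abs(m$values - m2$values)), 1e-6)
  expect_equal(m2$pixel_spacing_mm, m$pixel_spacing_mm)

  fnii <- withr::local_tempfile(fileext = ".nii.gz")
  write_adc_map(m, fnii)
  m3 <- read_adc_map(fnii)
  expect_lt(max(abs(m$values - m3$values)), 1e-6)
  expect_equal(m3$pixel_spacing_mm, m$pixel_spacing_mm, tolerance = 1e-6)
  expect_equal(m3$slice_thickness_mm, 5, tolerance = 1e-6)
})

test_that("multi-slice volumes need an explicit slice selection", {
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(runif(200), c(10, 10, 2))), f)
  expect_error(read_adc_map(f), "slice")
  m <- read_adc_map(f, slice = 2)
  expect_equal(dim(m$values), c(10L, 10L))
})

test_that("DICOM input is rejected with a clear message", {
  f <- withr::local_tempfile(fileext = ".dcm")
  writeLines("x", f)
  expect_error(read_adc_map(f), "DICOM")
})

test_that("LOI and landmark annotations round-trip and validate", {
  lois <- list(loi(c(1, 1), c(5, 8), "s1", "loi1"),
               loi(c(2.5, 2), c(6, 6.5), "s1", "loi2"))
  f <- withr::local_tempfile(fileext = ".json")
  write_loi_json(lois, f)
  back <- read_loi_json(f)
  expect_equal(lapply(back, unclass), lapply(lois, unclass))

  lms <- list(loi1 = profile_landmarks(2, 5, 10, 14, 17, 25))
  g <- withr::local_tempfile(fileext = ".json")
  write_landmarks_json(lms, g)
  expect_equal(unclass(read_landmarks_json(g)$loi1), unclass(lms$loi1))

  # ordering violation (b <= a) is caught at load time
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"loi1": {"a": 5, "b": 3, "c": 10, "d": 14, "e": 17, "f": 25}}',
             bad)
  expect_error(read_landmarks_json(bad), "loi1")

  # an out-of-image endpoint is fine at load time, an error at sampling time
  m <- adc_map(matrix(725, 8, 8))
  out <- loi(c(1, 1), c(20, 20), "s1", "loiX")
  h <- withr::local_tempfile(fileext = ".json")
  write_loi_json(list(out), h)
  loaded <- read_loi_json(h)[[1]]
  expect_error(sample_loi(m, loaded), "bounds")
})

test_that("feature CSVs keep the column contract and round-trip", {
  co <- generate_cohort(cohort_spec(n_gbm = 2, n_abscess = 2, seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(co, f)
  back <- read_features_csv(f)
  expect_identical(names(back),
                   c("subject_id", "loi_id", "label", "grad_E_rise", "mean_E",
                     "std_E", "median_E", "grad_E_fall", "grad_T_rise",
                     "mean_T", "std_T", "median_T"))
  expect_equal(back$median_T, co$median_T, tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(subject_id = "s", loi_id = "l"), bad,
                   row.names = FALSE)
  expect_error(read_features_csv(bad), "missing column")
})
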