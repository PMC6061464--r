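test_that("hu_volume and stone_roi validate their invariants", {
  expect_error(hu_volume(matrix(0, 3, 3)), "3D")
  expect_error(hu_volume(array(c(NA, rep(0, 26)), c(3, 3, 3))), "finite")
  expect_error(hu_volume(array(0, c(3, 3, 3)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(stone_roi(c(5, 5, 5), c(4, 6, 6)), "lo <= hi")
  vol <- hu_volume(array(0, c(4, 4, 4)))
  expect_error(find_peak(vol, stone_roi(c(1, 1, 1), c(5, 4, 4))), "bounds")
})

test_that("NIfTI round trip preserves voxels exactly and spacing to 1e-6 mm", {
  set.seed(11)
  vol <- hu_volume(array(rnorm(5 * 6 * 7, sd = 300), c(5, 6, 7)),
                   spacing = c(0.8, 0.8, 1.0))
  for (ext in c("nii", "nii.gz")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_nifti(vol, path)
    back <- read_nifti(path)
    expect_identical(back$voxels, vol$voxels)
    expect_lt(max(abs(back$spacing - vol$spacing)), 1e-6)
  }
})

test_that("anisotropic spacing survives the round trip in order-consistent form", {
  vol <- centered_phantom(peak = 500, sigma = 1.5)$volume
  expect_equal(vol$spacing, c(0.8, 0.8, 1.0))
  path <- withr::local_tempfile(fileext = ".nii")
  write_nifti(vol, path)
  expect_lt(max(abs(read_nifti(path)$spacing - c(0.8, 0.8, 1.0))), 1e-6)
})

test_that("read_nifti agrees with an independent NIfTI implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  path <- withr::local_tempfile(fileext = ".nii")
  vol <- hu_volume(array(seq_len(60), c(3, 4, 5)), spacing = c(0.8, 0.8, 1))
  write_nifti(vol, path)
  out <- system2("python", c("-c", shQuote(paste0(
    "import nibabel, numpy; img = nibabel.load('", path, "'); ",
    "d = numpy.asarray(img.dataobj); ",
    "print(d.shape, float(d.sum()), [round(float(z), 6) for z in ",
    "img.header.get_zooms()])"
  ))), stdout = TRUE)
  expect_equal(out, "(3, 4, 5) 1830.0 [0.8, 0.8, 1.0]")
})

test_that("mask writing produces a label image that reloads to the same set", {
  ph <- centered_phantom()
  mask <- segment_stone(ph$volume)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(mask, ph$volume, path)
  lab <- read_nifti(path)
  expect_setequal(which(lab$voxels == 1),
                  which(stonequant:::mask_array(mask)))
  expect_equal(sum(lab$voxels), nrow(mask$indices))

  # empty mask -> all-zero label volume
  path0 <- withr::local_tempfile(fileext = ".nii")
  write_mask(NULL, ph$volume, path0)
  expect_true(all(read_nifti(path0)$voxels == 0))

  # single-voxel semantics: exactly one nonzero at the right place
  one <- mask
  one$indices <- matrix(c(4L, 5L, 6L), 1)
  one$hole_filled <- FALSE
  write_mask(one, ph$volume, path0)
  lab1 <- read_nifti(path0)
  expect_equal(which(lab1$voxels != 0),
               stonequant:::vox_linear(one$indices, dim(ph$volume$voxels)))
  # out-of-bounds indices are refused
  bad <- mask
  bad$indices <- matrix(c(99L, 1L, 1L), 1)
  expect_error(write_mask(bad, ph$volume, path0), "bounds")
})

test_that("DICOM rescale converts stored values to HU", {
  dir <- withr::local_tempdir()
  hu1 <- matrix(0L, 6, 5); hu1[3, 2] <- 600L  # stored 1624 after +1024
  write_test_series(dir, hu1 = hu1)
  vol <- read_dicom_series(dir)
  expect_equal(dim(vol$voxels), c(6L, 5L, 2L))
  expect_equal(vol$voxels[1, 1, 1], 0)       # stored 1024, intercept -1024
  expect_equal(vol$voxels[3, 2, 1], 600)     # stored 1624
  expect_equal(vol$spacing, c(0.8, 0.8, 1))
})

test_that("DICOM file order on disk never affects the volume", {
  set.seed(5)
  hu1 <- matrix(sample(0:500, 30), 6, 5)
  hu2 <- matrix(sample(0:500, 30), 6, 5)
  d1 <- write_test_series(withr::local_tempdir(), hu1 = hu1, hu2 = hu2,
                          names = c("a.dcm", "b.dcm"))
  # shuffled: file names reverse the slice order on disk
  d2 <- write_test_series(withr::local_tempdir(), hu1 = hu1, hu2 = hu2,
                          names = c("z_last.dcm", "a_first.dcm"))
  expect_identical(read_dicom_series(d1)$voxels, read_dicom_series(d2)$voxels)
  expect_equal(read_dicom_series(d1)$voxels[, , 1], hu1 + 0)
})

test_that("DICOM reader rejects broken series", {
  dir <- withr::local_tempdir()
  writeBin(raw(200), file.path(dir, "junk.dcm"))
  expect_error(read_dicom_series(dir), "DICOM")
  expect_error(read_dicom_series(file.path(dir, "missing")), "directory")

  # mixed series UIDs
  dir2 <- withr::local_tempdir()
  write_dicom_slice(file.path(dir2, "a.dcm"), matrix(1024L, 4, 4), 0,
                    series_uid = "1.1")
  write_dicom_slice(file.path(dir2, "b.dcm"), matrix(1024L, 4, 4), 1,
                    series_uid = "2.2")
  expect_error(read_dicom_series(dir2), "series")

  # inconsistent slice gaps beyond the 1% tolerance
  dir3 <- withr::local_tempdir()
  for (s in seq_len(3))
    write_dicom_slice(file.path(dir3, sprintf("s%d.dcm", s)),
                      matrix(1024L, 4, 4), z_mm = c(0, 1, 2.2)[s],
                      instance = s)
  expect_error(read_dicom_series(dir3), "spacing")

  # duplicate positions cannot be ordered
  dir4 <- withr::local_tempdir()
  write_dicom_slice(file.path(dir4, "a.dcm"), matrix(1024L, 4, 4), 0)
  write_dicom_slice(file.path(dir4, "b.dcm"), matrix(1024L, 4, 4), 0,
                    instance = 2L)
  expect_error(read_dicom_series(dir4), "duplicate")
})

test_that("feature tables round trip, with NA sphericity for coplanar stones", {
  ph <- centered_phantom(peak = 500, sigma = 1.8)
  f <- extract_features(ph$volume)
  path <- withr::local_tempfile(fileext = ".csv")

  write_features_table(list(), path)
  empty <- read_features_table(path)
  expect_equal(nrow(empty), 0L)
  expect_named(empty, stonequant:::FEATURE_COLUMNS)

  write_features_table(list(f), path)
  back <- read_features_table(path)
  for (col in stonequant:::FEATURE_COLUMNS)
    expect_equal(back[[col]], as.data.frame(f)[[col]], tolerance = 1e-9,
                 label = col)

  # coplanar stone: volume 0 written, sphericity as an empty (NA) cell
  flat <- f
  flat$volume_mm3 <- 0
  flat$sphericity <- NA_real_
  write_features_table(list(f, flat), path)
  back2 <- read_features_table(path)
  expect_true(is.na(back2$sphericity[2]))
  expect_identical(back2$volume_mm3[2], 0)
})
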