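test_that("find_peak returns the ROI maximum with raster-order tie breaking", {
  vox <- array(0, c(6, 6, 4))
  vox[3, 4, 2] <- 600
  vol <- hu_volume(vox)
  pk <- find_peak(vol)
  expect_identical(pk$peak, c(3L, 4L, 2L))
  expect_identical(pk$max_hu, 600)

  # tie: two voxels at 500, the one earlier in (k, j, i) raster order wins
  vox2 <- array(0, c(6, 6, 4))
  vox2[5, 2, 3] <- 500   # later slice
  vox2[2, 6, 2] <- 500   # earlier slice -> wins
  expect_identical(find_peak(hu_volume(vox2))$peak, c(2L, 6L, 2L))
  # same slice: smaller j wins
  vox3 <- array(0, c(6, 6, 4))
  vox3[6, 3, 2] <- 500
  vox3[1, 4, 2] <- 500
  expect_identical(find_peak(hu_volume(vox3))$peak, c(6L, 3L, 2L))

  # degenerate uniform ROI: first raster voxel plus a warning
  expect_warning(pk0 <- find_peak(hu_volume(array(0, c(3, 3, 3)))), "peak")
  expect_identical(pk0$peak, c(1L, 1L, 1L))
  expect_identical(pk0$max_hu, 0)
})

test_that("a single hot voxel segments to itself at half its value", {
  vox <- array(0, c(7, 7, 7))
  vox[4, 4, 4] <- 500
  mask <- segment_stone(hu_volume(vox))
  expect_equal(nrow(mask$indices), 1L)
  expect_identical(mask$indices[1, ], c(i = 4L, j = 4L, k = 4L))
  expect_identical(mask$threshold, 250)
  expect_identical(mask$max_hu, 500)
  expect_identical(mask$n_hole_filled, 0L)
})

test_that("noiseless gaussian mask equals the analytic half-max voxelization", {
  ph <- centered_phantom(peak = 600, sigma = c(2, 2.5, 1.8))
  mask <- segment_stone(ph$volume)
  # brute-force scan of the analytic profile over the whole grid
  d <- dim(ph$volume$voxels)
  g <- as.matrix(expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3]))
  pts <- sweep(g - 1, 2, ph$volume$spacing, `*`)
  ctr <- ph$truth$stones[[1]]$center_mm
  r2 <- rowSums(sweep(sweep(pts, 2, ctr), 2,
                      ph$truth$stones[[1]]$sigma_mm, `/`)^2)
  analytic <- g[600 * exp(-r2 / 2) >= 300, , drop = FALSE]
  expect_equal(nrow(mask$indices), nrow(analytic))
  expect_identical(unname(mask$indices), unname(analytic))
  expect_identical(mask$threshold, 300)
  expect_gte(nrow(mask$indices), 1)
})

test_that("hollow shells are hole-filled and flagged", {
  vox <- array(0, c(9, 9, 9))
  vox[3:7, 3:7, 3:7] <- 600      # solid cube ...
  vox[4:6, 4:6, 4:6] <- 0        # ... with a 3^3 cavity
  mask <- segment_stone(hu_volume(vox))
  expect_equal(nrow(mask$indices), 125L)           # shell plus cavity
  expect_identical(mask$n_hole_filled, 27L)
  cavity <- mask$indices[mask$hole_filled, , drop = FALSE]
  expect_true(all(cavity >= 4 & cavity <= 6))
  # every member is supra-threshold or flagged hole-filled (spec invariant)
  vals <- vox[stonequant:::mask_linear(mask)]
  expect_true(all(vals >= mask$threshold | mask$hole_filled))
  # with filling disabled the cavity stays out
  open_mask <- segment_stone(hu_volume(vox), fill_holes = FALSE)
  expect_equal(nrow(open_mask$indices), 98L)
})

test_that("fill_holes restores interior cavities but not through-tunnels", {
  # solid cube: unchanged
  cube <- as.matrix(expand.grid(i = 2:4, j = 2:4, k = 2:4))
  expect_equal(nrow(fill_holes(cube, c(6, 6, 6))), 27L)
  # 5^3 cube with center removed: center restored
  c5 <- as.matrix(expand.grid(i = 2:6, j = 2:6, k = 2:6))
  holed <- c5[!(c5[, 1] == 4 & c5[, 2] == 4 & c5[, 3] == 4), ]
  filled <- fill_holes(holed, c(8, 8, 8))
  expect_equal(nrow(filled), 125L)
  # torus-like: tunnel open to the exterior is not a hole
  g <- as.matrix(expand.grid(i = 2:6, j = 2:6, k = 3:5))
  torus <- g[!(g[, 1] == 4 & g[, 2] == 4), ]       # open along all of k
  expect_equal(nrow(fill_holes(torus, c(8, 8, 8))), nrow(torus))
})

test_that("component growth and hole filling match brute-force BFS oracles", {
  set.seed(202)
  for (rep in 1:6) {
    d <- sample(8:14, 3, replace = TRUE)
    vox <- array(stats::runif(prod(d)) * 800, d)
    vol <- hu_volume(vox)
    pk <- find_peak(vol)
    mask <- suppressWarnings(segment_stone(vol))
    fg <- vox >= pk$max_hu / 2
    comp <- oracle_component_26(fg, pk$peak)
    want <- oracle_fill_holes(comp)
    expect_identical(stonequant:::mask_array(mask), want,
                     label = sprintf("grid %s", paste(d, collapse = "x")))
  }
})

test_that("segmentation is idempotent and anchored to the 0 HU background", {
  ph <- centered_phantom(peak = 800, sigma = 2, noise_sd = 10, seed = 4L)
  m1 <- segment_stone(ph$volume)
  # re-segment the masked volume (everything else zeroed): same mask
  vox2 <- array(0, dim(ph$volume$voxels))
  vox2[stonequant:::mask_linear(m1)] <-
    ph$volume$voxels[stonequant:::mask_linear(m1)]
  m2 <- segment_stone(hu_volume(vox2, ph$volume$spacing))
  expect_identical(m1$indices, m2$indices)

  # NOT shift invariant: the threshold is maxHU/2 by definition, anchored
  # to a ~0 HU background, so adding +200 HU everywhere changes the mask
  shifted <- hu_volume(ph$volume$voxels + 200, ph$volume$spacing)
  m3 <- segment_stone(shifted)
  expect_gt(nrow(m3$indices), nrow(m1$indices))
  expect_identical(m3$threshold, (m1$max_hu + 200) / 2)
})

test_that("degenerate and truncated stones are reported", {
  expect_error(suppressWarnings(segment_stone(hu_volume(array(0, c(4, 4, 4))))),
               "no stone")
  vox <- array(0, c(6, 6, 6))
  vox[1:3, 3, 3] <- 700                     # touches the x = 1 face
  expect_warning(segment_stone(hu_volume(vox)), "boundary")
  # ROI-clipped growth stays inside the box
  vox2 <- array(0, c(10, 10, 10))
  vox2[3:8, 5, 5] <- 600
  roi <- stone_roi(c(3, 4, 4), c(5, 6, 6))
  clipped <- segment_stone(hu_volume(vox2), roi, clip_to_roi = TRUE)
  expect_true(all(clipped$indices[, 1] <= 5))
  full <- segment_stone(hu_volume(vox2), roi)
  expect_equal(nrow(full$indices), 6L)
})
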