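stub_mask <- function(indices, dim) {
  idx <- matrix(as.integer(indices), ncol = 3,
                dimnames = list(NULL, c("i", "j", "k")))
  structure(list(indices = idx, hole_filled = rep(FALSE, nrow(idx)),
                 peak = idx[1, ], max_hu = 0, threshold = 0,
                 n_hole_filled = 0L, dim = as.integer(dim)),
            class = "stone_mask")
}

test_that("histogram statistics use the documented moment conventions", {
  # eight voxels valued {0 x4, 1 x4}: symmetric Bernoulli(1/2)
  vox <- array(0, c(2, 2, 2))
  vox[, , 2] <- 1
  vol <- hu_volume(vox)
  mask <- stub_mask(as.matrix(expand.grid(1:2, 1:2, 1:2)), c(2, 2, 2))
  hs <- histogram_stats(vol, mask)
  expect_equal(hs$mean_hu, 0.5)
  expect_equal(hs$skewness, 0)
  expect_equal(hs$kurtosis, 1)                    # m4/m2^2 = .0625/.0625
  expect_equal(hs$sd_hu, sd(c(rep(0, 4), rep(1, 4))))

  # constant mask: sd 0, kurtosis and skewness missing
  hs0 <- histogram_stats(hu_volume(array(7, c(2, 2, 2))), mask)
  expect_equal(hs0$sd_hu, 0)
  expect_true(is.na(hs0$kurtosis) && is.na(hs0$skewness))
})

test_that("large normal samples give kurtosis near 3 and skewness near 0", {
  set.seed(1234)
  n <- 1e5
  d <- c(50, 50, 40)
  vol <- hu_volume(array(rnorm(prod(d)), d))
  idx <- stonequant:::linear_to_vox(seq_len(n), d)
  hs <- histogram_stats(vol, stub_mask(idx, d))
  expect_lt(abs(hs$kurtosis - 3), 0.1)
  expect_lt(abs(hs$skewness), 0.05)
})

test_that("coplanar and tiny point sets yield volume 0 and missing sphericity", {
  plane <- as.matrix(expand.grid(i = 1:5, j = 1:5, k = 3))
  a <- alpha_shape_metrics(plane, c(0.8, 0.8, 1.0))
  expect_identical(a$volume_mm3, 0)
  expect_true(is.na(a$sphericity))
  line <- cbind(1:7, 1, 1)
  expect_identical(alpha_shape_metrics(line, c(1, 1, 1))$volume_mm3, 0)
  expect_identical(alpha_shape_metrics(cbind(2, 2, 2), c(1, 1, 1))$volume_mm3, 0)
})

test_that("the 2x2x2 voxel cube has unit volume and closed-form sphericity", {
  cube <- as.matrix(expand.grid(i = 1:2, j = 1:2, k = 1:2))
  a <- alpha_shape_metrics(cube, c(1, 1, 1))
  expect_equal(a$volume_mm3, 1, tolerance = 1e-2)
  expect_equal(a$surface_area_mm2, 6, tolerance = 1e-2)
  expect_equal(a$sphericity, pi^(1 / 3) * 6^(2 / 3) / 6, tolerance = 1e-2)
})

test_that("a voxelized 6 mm ball measures as a sphere", {
  sp <- c(0.8, 0.8, 1.0)
  ball <- oracle_ball_indices(6, sp, c(24, 24, 20))
  a <- alpha_shape_metrics(ball, sp)
  expect_gte(a$sphericity, 0.9)
  expect_lt(abs(a$volume_mm3 - 4 / 3 * pi * 6^3) / (4 / 3 * pi * 6^3), 0.15)
})

test_that("alpha-shape volume never exceeds the convex-hull volume", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  sp <- c(0.8, 0.8, 1.0)
  shapes <- list(
    oracle_ball_indices(4, sp, c(20, 20, 16)),
    segment_stone(centered_phantom(peak = 700, sigma = c(2.5, 1.5, 2))$volume)$indices)
  for (idx in shapes) {
    pts <- sweep(idx - 1, 2, sp, `*`)
    f <- withr::local_tempfile(fileext = ".txt")
    write.table(pts, f, row.names = FALSE, col.names = FALSE)
    hull <- as.numeric(system2("python", c("-c", shQuote(paste0(
      "import numpy; from scipy.spatial import ConvexHull; ",
      "print(ConvexHull(numpy.loadtxt('", f, "')).volume)"))),
      stdout = TRUE))
    a <- alpha_shape_metrics(idx, sp)
    expect_lte(a$volume_mm3, hull * (1 + 1e-6))
  }
})

test_that("axial diameter approximates an edge-to-edge caliper", {
  sp <- c(0.8, 0.8, 1.0)
  diag_mm <- sqrt(2 * 0.8^2)
  expect_equal(max_axial_diameter(cbind(4, 4, 4), sp), diag_mm)
  row10 <- cbind(1:10, 3, 2)
  expect_equal(max_axial_diameter(row10, sp), 9 * 0.8 + diag_mm)
  ball <- oracle_ball_indices(5, sp, c(20, 20, 16))
  expect_lt(abs(max_axial_diameter(ball, sp) - 10), diag_mm)
})

test_that("extract_features composes the stages deterministically", {
  ph <- centered_phantom(peak = 600, sigma = 3)
  f <- extract_features(ph$volume)
  expect_identical(f$max_hu, 600)
  expect_gt(f$mean_hu, 300)
  expect_lt(f$mean_hu, 600)
  expect_gt(f$sd_hu, 0)
  expect_identical(f$threshold_hu, 300)
  f2 <- extract_features(ph$volume)
  expect_identical(as.data.frame(f), as.data.frame(f2))

  # single hot voxel: fully degenerate composition
  vox <- array(0, c(7, 7, 7))
  vox[4, 4, 4] <- 500
  g <- extract_features(hu_volume(vox))
  expect_identical(g$n_voxels, 1L)
  expect_equal(g$mean_hu, 500)
  expect_equal(g$sd_hu, 0)
  expect_true(is.na(g$kurtosis))
  expect_identical(g$volume_mm3, 0)
  expect_true(is.na(g$sphericity))
})

test_that("feature invariants hold across phantoms", {
  set.seed(3)
  for (case in 1:4) {
    peak <- runif(1, 350, 1500)
    sig <- runif(1, 1, 3.2)
    ph <- centered_phantom(peak = peak, sigma = sig)
    f <- extract_features(ph$volume)
    expect_lte(f$mean_hu, f$max_hu)
    expect_lt(f$sd_hu, f$max_hu)
    # hole-free mask: every voxel >= threshold, so the mean is too
    expect_identical(f$n_hole_filled, 0L)
    expect_gte(f$mean_hu, f$threshold_hu)
    expect_true(f$sphericity > 0 && f$sphericity <= 1)
  }
})

test_that("maxHU bias under noise is positive and bounded by the max-statistic", {
  # an off-center broad stone read on a noisy grid: several near-equal top
  # voxels make the max biased upward, but not beyond ~4 noise sd
  noise <- 15
  shape <- c(41, 41, 31); spacing <- c(0.8, 0.8, 1.0)
  center <- (shape - 1) * spacing / 2 + c(0.4, 0.4, 0.5)
  bias <- vapply(1:20, function(s) {
    ph <- make_phantom(phantom_spec(shape, spacing,
      stones = list(phantom_stone(center, 700, 3)),
      noise_sd = noise, seed = 1000L + s))
    find_peak(ph$volume)$max_hu - 700
  }, 0)
  expect_gt(mean(bias), 0)
  expect_lt(max(bias), 4 * noise)
})
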