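#' Histogram statistics over a stone mask
#'
#' Mean attenuation (meanHU), standard deviation (sdHU, sample n-1
#' denominator), and the population-moment skewness (`m3 / m2^1.5`) and
#' non-excess kurtosis (`m4 / m2^2`; a normal distribution gives 3).
#' Skewness and kurtosis are `NA` for a degenerate (constant) mask, and
#' sdHU is defined as 0 for a single-voxel mask.
#'
#' @param vol an [hu_volume].
#' @param mask a `stone_mask` on the same grid (hole-filled voxels are
#'   part of the stone and are included).
#' @return A list with `mean_hu`, `sd_hu`, `kurtosis`, `skewness`.
#' @export
histogram_stats <- function(vol, mask) {
  stopifnot(inherits(vol, "hu_volume"), inherits(mask, "stone_mask"))
  if (!identical(mask$dim, dim(vol$voxels)))
    stop("mask and volume grids differ")
  v <- vol$voxels[mask_linear(mask)]
  n <- length(v)
  if (n == 0L) stop("empty mask")
  m <- mean(v)
  s <- if (n == 1L) 0 else stats::sd(v)
  if (s == 0) return(list(mean_hu = m, sd_hu = 0,
                          kurtosis = NA_real_, skewness = NA_real_))
  m2 <- mean((v - m)^2)
  m3 <- mean((v - m)^3)
  m4 <- mean((v - m)^4)
  list(mean_hu = m, sd_hu = s,
       kurtosis = m4 / m2^2, skewness = m3 / m2^1.5)
}

#' Alpha-shape volume, surface area and sphericity of a stone
#'
#' Builds the alpha shape enclosing all segmented voxel-center locations
#' (in mm), using the smallest alpha for which the alpha complex contains
#' every point and forms one connected region — the canonical
#' parameter-free choice when every point must be enclosed. Volume and
#' surface area are those of the resulting simplicial complex, and
#' sphericity is `pi^(1/3) * (6 V)^(2/3) / A` (1 for a perfect sphere).
#'
#' Degenerate point sets (fewer than 4 points, or all points collinear or
#' coplanar, e.g. a stone segmented within a single image plane) have no
#' 3D alpha shape: they are reported with volume 0 and missing sphericity.
#'
#' Because voxel centers lie on a regular grid (a degenerate configuration
#' for the underlying Delaunay tetrahedralization), a deterministic jitter
#' of at most 1e-3 mm is applied to each point; the effect on volume and
#' area is far below every reported digit.
#'
#' At the critical alpha itself the surface follows every voxel step, so
#' a discretized sphere reads as far less spherical than it is.
#' `alpha_scale` inflates the radius used to `alpha_scale * critical`,
#' bridging sub-voxel staircase concavities while leaving real
#' (supra-voxel) concavities alone; the default is chosen so that a
#' voxelized 6 mm-radius ball measures as a sphere (sphericity > 0.9).
#' Set `alpha_scale = 1` for the strict critical-alpha shape.
#'
#' @param mask a `stone_mask` (or an n x 3 index matrix).
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @param alpha_scale multiple of the critical alpha to use (default 2).
#' @return A list with `volume_mm3`, `surface_area_mm2`, `sphericity`
#'   (`NA` when degenerate), `alpha` (the radius used, mm) and
#'   `critical_alpha` (mm).
#' @export
alpha_shape_metrics <- function(mask, spacing, alpha_scale = 2) {
  idx <- if (inherits(mask, "stone_mask")) mask$indices else as.matrix(mask)
  if (NROW(idx) == 0L) stop("empty mask")
  spacing <- as.numeric(spacing)
  pts <- (idx - 1) * matrix(spacing, nrow(idx), 3, byrow = TRUE)
  degenerate <- list(volume_mm3 = 0, surface_area_mm2 = NA_real_,
                     sphericity = NA_real_, alpha = NA_real_,
                     critical_alpha = NA_real_)
  if (nrow(pts) < 4L) return(degenerate)
  centered <- sweep(pts, 2, colMeans(pts))
  if (qr(centered)$rank < 3L) return(degenerate)  # coplanar / collinear
  res <- .alpha_shape_cpp(jitter_points(pts, idx), alpha_scale)
  if (res$volume <= 0 || res$area <= 0) return(degenerate)
  sph <- pi^(1 / 3) * (6 * res$volume)^(2 / 3) / res$area
  list(volume_mm3 = res$volume, surface_area_mm2 = res$area,
       sphericity = min(sph, 1), alpha = res$alpha,
       critical_alpha = res$critical_alpha)
}

# deterministic symbolic perturbation (<= 1e-3 mm) keyed on voxel index
jitter_points <- function(pts, idx) {
  h <- function(a, b, c, m1, m2, m3)
    (((a * m1) %% 100003) + ((b * m2) %% 100019) + ((c * m3) %% 100043)) %%
      1009 / 1009 - 0.5
  i <- as.numeric(idx[, 1]); j <- as.numeric(idx[, 2]); k <- as.numeric(idx[, 3])
  pts[, 1] <- pts[, 1] + 2e-3 * h(i, j, k, 7369, 2917, 6151)
  pts[, 2] <- pts[, 2] + 2e-3 * h(i, j, k, 3079, 8209, 4621)
  pts[, 3] <- pts[, 3] + 2e-3 * h(i, j, k, 5381, 1543, 9241)
  pts
}

#' Maximum axial diameter of a stone
#'
#' Automated stand-in for the manual caliper measurement of the largest
#' in-plane stone diameter: for each axial slice, the maximum pairwise
#' distance between in-slice mask voxel centers, maximised over slices,
#' plus one in-plane voxel diagonal to approximate edge-to-edge caliper
#' placement. A single-voxel slice contributes one voxel diagonal. This
#' is an approximation of a manual measurement and is informational only.
#'
#' @param mask a `stone_mask` (or an n x 3 index matrix).
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @return Diameter in mm.
#' @export
max_axial_diameter <- function(mask, spacing) {
  idx <- if (inherits(mask, "stone_mask")) mask$indices else as.matrix(mask)
  if (NROW(idx) == 0L) stop("empty mask")
  spacing <- as.numeric(spacing)
  diag_mm <- sqrt(spacing[1]^2 + spacing[2]^2)
  best <- 0
  for (k in unique(idx[, 3])) {
    sl <- idx[idx[, 3] == k, , drop = FALSE]
    xy <- cbind((sl[, 1] - 1) * spacing[1], (sl[, 2] - 1) * spacing[2])
    if (nrow(xy) == 1L) {
      best <- max(best, 0)
      next
    }
    if (nrow(xy) > 8L) {
      hull <- grDevices::chull(xy)
      if (length(hull) >= 2L) xy <- xy[hull, , drop = FALSE]
    }
    best <- max(best, stats::dist(xy))
  }
  best + diag_mm
}

#' Extract the full quantitative feature vector for one stone
#'
#' Runs the whole per-stone pipeline: half-of-peak segmentation
#' ([segment_stone()]), the scaled 3D Laplacian ([scaled_laplacian()]),
#' histogram statistics, alpha-shape volume and sphericity, and the
#' maximum axial diameter, and assembles them into a `stone_features`
#' record. Deterministic for a fixed input volume and ROI.
#'
#' @param vol an [hu_volume].
#' @param roi a [stone_roi] containing the stone; defaults to the whole
#'   volume.
#' @inheritParams laplacian_kernel
#' @param fill_holes,clip_to_roi passed to [segment_stone()].
#' @return A `stone_features` object (also a one-row data frame via
#'   [as.data.frame()]): `n_voxels`, `mean_hu`, `sd_hu`, `kurtosis`,
#'   `skewness`, `max_hu`, `pp_lapl`, `mean_lapl`, `volume_mm3`,
#'   `sphericity`, `max_axial_diameter_mm`, `peak_i/j/k`, `threshold_hu`,
#'   `n_hole_filled`.
#' @examples
#' sp <- phantom_spec(c(32, 32, 24), stones = list(
#'   phantom_stone(c(12.8, 12.8, 12), peak_hu = 600, sigma_mm = 2.5)))
#' f <- extract_features(make_phantom(sp)$volume)
#' f$max_hu  # 600
#' @export
extract_features <- function(vol, roi = NULL,
                             kernel = c("inverse-square", "uniform"),
                             metric = c("index", "mm"),
                             fill_holes = TRUE, clip_to_roi = FALSE) {
  stopifnot(inherits(vol, "hu_volume"))
  mask <- segment_stone(vol, roi, fill_holes = fill_holes,
                        clip_to_roi = clip_to_roi)
  lap <- scaled_laplacian(vol, kernel, metric)
  hs <- histogram_stats(vol, mask)
  as_ <- alpha_shape_metrics(mask, vol$spacing)
  structure(list(
    n_voxels = nrow(mask$indices),
    mean_hu = hs$mean_hu, sd_hu = hs$sd_hu,
    kurtosis = hs$kurtosis, skewness = hs$skewness,
    max_hu = mask$max_hu,
    pp_lapl = peak_point_laplacian(lap, mask$peak),
    mean_lapl = mean_laplacian(lap, mask),
    volume_mm3 = as_$volume_mm3,
    sphericity = as_$sphericity,
    max_axial_diameter_mm = max_axial_diameter(mask, vol$spacing),
    peak_i = mask$peak[1], peak_j = mask$peak[2], peak_k = mask$peak[3],
    threshold_hu = mask$threshold,
    n_hole_filled = mask$n_hole_filled),
    class = "stone_features")
}

#' @export
print.stone_features <- function(x, ...) {
  cat("<stone_features>\n")
  cat(sprintf("  maxHU %.1f HU at (%d,%d,%d), ppLapl %.1f HU\n",
              x$max_hu, x$peak_i, x$peak_j, x$peak_k, x$pp_lapl))
  cat(sprintf("  %d voxels, meanHU %.1f, sdHU %.1f, meanLapl %.1f\n",
              x$n_voxels, x$mean_hu, x$sd_hu, x$mean_lapl))
  cat(sprintf("  volume %.1f mm^3, sphericity %s, axial diameter %.1f mm\n",
              x$volume_mm3,
              if (is.na(x$sphericity)) "NA" else sprintf("%.2f", x$sphericity),
              x$max_axial_diameter_mm))
  invisible(x)
}

#' @export
as.data.frame.stone_features <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

FEATURE_COLUMNS <- c("n_voxels", "mean_hu", "sd_hu", "kurtosis", "skewness",
                     "max_hu", "pp_lapl", "mean_lapl", "volume_mm3",
                     "sphericity", "max_axial_diameter_mm",
                     "peak_i", "peak_j", "peak_k", "threshold_hu",
                     "n_hole_filled")

#' Write / read a stone feature table
#'
#' CSV with one row per stone in a fixed, documented column order (the
#' order of the `stone_features` fields). Missing sphericity (coplanar
#' stones with alpha-shape volume 0) is written as an empty cell.
#'
#' @param rows a list of `stone_features` objects (possibly empty).
#' @param path destination CSV path.
#' @return `path` invisibly; `read_features_table()` returns a data frame
#'   with the documented columns.
#' @export
write_features_table <- function(rows, path) {
  df <- if (length(rows) == 0L) {
    as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(FEATURE_COLUMNS)), FEATURE_COLUMNS))
  } else {
    do.call(rbind, lapply(rows, as.data.frame))
  }
  utils::write.csv(df[, FEATURE_COLUMNS, drop = FALSE], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_features_table
#' @export
read_features_table <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}
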