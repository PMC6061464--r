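#' Build the 3x3x3 scaled Laplacian kernel
#'
#' Neighbor weights for the scaled 3D Laplacian. The filtered value at a
#' voxel is the voxel minus a weighted mean of its 26 neighbors, with the
#' weights summing to exactly 1 so that constant regions map to 0 and the
#' output stays in HU.
#'
#' The default `"inverse-square"` scheme weights each neighbor by the
#' reciprocal of its squared center-to-neighbor distance: face neighbors 1,
#' edge neighbors 1/2, corner neighbors 1/3 before normalisation (so
#' w_face = 3/44, w_edge = 3/88, w_corner = 1/44). `"uniform"` weights all
#' 26 neighbors equally (1/26). Distances are measured in voxel index
#' units by default; `metric = "mm"` uses physical distances instead,
#' which matters only for anisotropic spacing.
#'
#' @param kernel `"inverse-square"` or `"uniform"`.
#' @param metric `"index"` (default) or `"mm"`.
#' @param spacing voxel spacing, used only when `metric = "mm"`.
#' @return A 3x3x3 array of neighbor weights (center 0) summing to 1.
#' @export
laplacian_kernel <- function(kernel = c("inverse-square", "uniform"),
                             metric = c("index", "mm"),
                             spacing = c(1, 1, 1)) {
  kernel <- match.arg(kernel)
  metric <- match.arg(metric)
  step <- if (metric == "mm") as.numeric(spacing) else c(1, 1, 1)
  w <- array(0, c(3, 3, 3))
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    d2 <- (di * step[1])^2 + (dj * step[2])^2 + (dk * step[3])^2
    w[di + 2, dj + 2, dk + 2] <- if (kernel == "uniform") 1 else 1 / d2
  }
  w / sum(w)
}

#' Apply the scaled 3D Laplacian texture filter
#'
#' Filters a CT volume so that each voxel becomes the difference between
#' its own attenuation and a weighted mean of its 26 neighbors (see
#' [laplacian_kernel()]). The filter is linear, invariant to adding a
#' constant, and maps constant volumes to zero. Border voxels use
#' replicate padding.
#'
#' @param vol an [hu_volume] with at least 3 voxels along every axis.
#' @inheritParams laplacian_kernel
#' @return A `laplacian_volume`: `voxels` (same shape as the source, HU),
#'   `spacing`, and `kernel` (the 3x3x3 weights used).
#' @examples
#' vol <- hu_volume(array(100, c(5, 5, 5)))
#' range(scaled_laplacian(vol)$voxels)  # all zero
#' @export
scaled_laplacian <- function(vol, kernel = c("inverse-square", "uniform"),
                             metric = c("index", "mm")) {
  stopifnot(inherits(vol, "hu_volume"))
  d <- dim(vol$voxels)
  if (any(d < 3L))
    stop("volume must have at least 3 voxels along every axis for the ",
         "26-neighbor Laplacian; got ", paste(d, collapse = "x"))
  w <- laplacian_kernel(kernel, metric, vol$spacing)
  # replicate padding by one voxel
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vol$voxels
  pad[1, , ] <- pad[2, , ]; pad[d[1] + 2, , ] <- pad[d[1] + 1, , ]
  pad[, 1, ] <- pad[, 2, ]; pad[, d[2] + 2, ] <- pad[, d[2] + 1, ]
  pad[, , 1] <- pad[, , 2]; pad[, , d[3] + 2] <- pad[, , d[3] + 1]
  nbr_mean <- array(0, d)
  for (di in 0:2) for (dj in 0:2) for (dk in 0:2) {
    wt <- w[di + 1, dj + 1, dk + 1]
    if (wt == 0) next
    nbr_mean <- nbr_mean +
      wt * pad[di + seq_len(d[1]), dj + seq_len(d[2]), dk + seq_len(d[3])]
  }
  structure(list(voxels = vol$voxels - nbr_mean,
                 spacing = vol$spacing, kernel = w),
            class = "laplacian_volume")
}

#' @export
print.laplacian_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<laplacian_volume> %d x %d x %d voxels, range [%.2f, %.2f] HU\n",
              d[1], d[2], d[3], min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Peak point Laplacian (ppLapl)
#'
#' The filtered value at exactly the peak point: a measure of the
#' peakedness of the stone's attenuation profile. Sharp narrow peaks give
#' large values; broad plateaus give values near zero.
#'
#' @param lap a `laplacian_volume` from [scaled_laplacian()].
#' @param peak integer `(i, j, k)` voxel index of the peak point.
#' @return The ppLapl value in HU.
#' @export
peak_point_laplacian <- function(lap, peak) {
  stopifnot(inherits(lap, "laplacian_volume"))
  peak <- as.integer(peak)
  d <- dim(lap$voxels)
  if (length(peak) != 3L || any(peak < 1L) || any(peak > d))
    stop("peak index (", paste(peak, collapse = ","),
         ") out of bounds for a ", paste(d, collapse = "x"), " grid")
  lap$voxels[peak[1], peak[2], peak[3]]
}

#' Mean Laplacian over a stone mask (meanLapl)
#'
#' Arithmetic mean of the filtered values over every mask voxel,
#' hole-filled voxels included.
#'
#' @param lap a `laplacian_volume` from [scaled_laplacian()].
#' @param mask a `stone_mask` on the same grid.
#' @return The meanLapl value in HU.
#' @export
mean_laplacian <- function(lap, mask) {
  stopifnot(inherits(lap, "laplacian_volume"),
            inherits(mask, "stone_mask"))
  if (!identical(mask$dim, dim(lap$voxels)))
    stop("mask and filtered volume grids differ")
  if (nrow(mask$indices) == 0L) stop("empty mask")
  mean(lap$voxels[mask_linear(mask)])
}
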