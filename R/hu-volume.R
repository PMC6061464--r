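#' CT volume in Hounsfield units
#'
#' Container for a 3D attenuation grid with physical voxel spacing. The
#' voxel array is indexed `voxels[i, j, k]` with `i` along x (in-plane
#' column), `j` along y (in-plane row) and `k` along z (the slice axis);
#' the physical position of voxel center `(i, j, k)` is
#' `((i-1)*dx, (j-1)*dy, (k-1)*dz)` mm. R's column-major layout therefore
#' orders voxels by slice first, so "first in raster order" means smallest
#' `k`, then `j`, then `i`.
#'
#' @param voxels numeric 3D array of attenuation values (HU), all finite.
#' @param spacing numeric length-3 vector `(dx, dy, dz)` in mm, all > 0.
#' @return An object of class `hu_volume`.
#' @examples
#' vol <- hu_volume(array(0, c(5, 5, 3)), spacing = c(0.8, 0.8, 1.0))
#' dim(vol$voxels)
#' @export
hu_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels)))
    stop("all voxel values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers (mm)")
  structure(list(voxels = voxels, spacing = spacing),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<hu_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.hu_volume <- function(x) dim(x$voxels)

#' Rectangular region of interest in voxel indices
#'
#' A closed box `[lo, hi]` of 1-based voxel indices `(i, j, k)` selecting
#' the subvolume that contains one stone. Stone localization is left to
#' the caller; the analysis itself is operator independent.
#'
#' @param lo,hi integer length-3 vectors, `lo <= hi` on every axis.
#' @return An object of class `stone_roi`.
#' @examples
#' stone_roi(c(10, 10, 5), c(30, 30, 15))
#' @export
stone_roi <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || anyNA(lo) || anyNA(hi))
    stop("`lo` and `hi` must be integer vectors of length 3")
  if (any(lo < 1L)) stop("ROI indices must be >= 1")
  if (any(lo > hi)) stop("ROI must satisfy lo <= hi on every axis")
  structure(list(lo = lo, hi = hi), class = "stone_roi")
}

#' @export
print.stone_roi <- function(x, ...) {
  cat(sprintf("<stone_roi> [%s] .. [%s]\n",
              paste(x$lo, collapse = ","), paste(x$hi, collapse = ",")))
  invisible(x)
}

check_roi <- function(roi, vol) {
  if (!inherits(roi, "stone_roi")) stop("`roi` must be a stone_roi")
  d <- dim(vol$voxels)
  if (any(roi$hi > d))
    stop("ROI exceeds volume bounds (", paste(d, collapse = "x"), ")")
  invisible(roi)
}

# full ROI covering a volume
whole_volume_roi <- function(vol) stone_roi(c(1, 1, 1), dim(vol$voxels))

# linear index helpers for the (nx, ny, nz) column-major layout
vox_linear <- function(idx, d) {
  (as.numeric(idx[, 1]) - 1) + (as.numeric(idx[, 2]) - 1) * d[1] +
    (as.numeric(idx[, 3]) - 1) * d[1] * d[2] + 1
}

linear_to_vox <- function(lin, d) {
  lin0 <- lin - 1
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  cbind(i = as.integer(i + 1), j = as.integer(j + 1), k = as.integer(k + 1))
}
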