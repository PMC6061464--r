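#' Locate the peak point within a region of interest
#'
#' Returns the maximum attenuation (maxHU) within the ROI and the voxel
#' attaining it, the "peak point". Ties are broken by the smallest raster
#' index (slice k first, then row j, then column i). A warning is emitted
#' when the ROI maximum is not positive, since the half-of-peak rule is
#' anchored to a ~0 HU background.
#'
#' @param vol an [hu_volume].
#' @param roi a [stone_roi]; defaults to the whole volume.
#' @return A list with `peak` (integer `(i, j, k)` index) and `max_hu`.
#' @export
find_peak <- function(vol, roi = NULL) {
  stopifnot(inherits(vol, "hu_volume"))
  if (is.null(roi)) roi <- whole_volume_roi(vol)
  check_roi(roi, vol)
  sub <- vol$voxels[roi$lo[1]:roi$hi[1], roi$lo[2]:roi$hi[2],
                    roi$lo[3]:roi$hi[3], drop = FALSE]
  # column-major linear order = lexicographic (k, j, i): the tie rule
  lin <- which.max(sub)
  idx <- linear_to_vox(lin, dim(sub))[1, ] + roi$lo - 1L
  max_hu <- sub[lin]
  if (max_hu <= 0)
    warning("ROI maximum is ", max_hu, " HU; no stone-like peak present")
  list(peak = as.integer(idx), max_hu = max_hu)
}

#' Segment one stone by half-of-peak thresholding
#'
#' Implements the operator-independent 3D segmentation: the threshold is
#' half way between the peak attenuation (maxHU) and the background, which
#' is approximated to 0 HU, i.e. `maxHU / 2`. The stone mask is the
#' 26-connected component of supra-threshold voxels (comparison inclusive,
#' so the peak always belongs) grown from the peak point, after which any
#' interior hole is filled and considered part of the stone.
#'
#' By default the component may grow beyond the ROI box (the ROI only
#' selects the stone via its peak); set `clip_to_roi = TRUE` to confine it.
#'
#' @param vol an [hu_volume].
#' @param roi a [stone_roi] containing the stone; defaults to the whole
#'   volume.
#' @param fill_holes fill interior cavities (default `TRUE`).
#' @param clip_to_roi restrict component growth to the ROI box.
#' @return A `stone_mask`: `indices` (n x 3 integer matrix in raster
#'   order), `hole_filled` (logical per row), `peak`, `max_hu`,
#'   `threshold` (= maxHU/2), `n_hole_filled`, and the grid `dim`.
#' @examples
#' sp <- phantom_spec(c(32, 32, 24), stones = list(
#'   phantom_stone(c(12.8, 12.8, 12), peak_hu = 600, sigma_mm = 2)))
#' m <- segment_stone(make_phantom(sp)$volume)
#' m$threshold  # 300 HU
#' @export
segment_stone <- function(vol, roi = NULL, fill_holes = TRUE,
                          clip_to_roi = FALSE) {
  stopifnot(inherits(vol, "hu_volume"))
  if (is.null(roi)) roi <- whole_volume_roi(vol)
  pk <- find_peak(vol, roi)
  if (pk$max_hu <= 0)
    stop("maxHU is ", pk$max_hu, " HU: no stone to segment in this ROI")
  thr <- pk$max_hu / 2
  d <- dim(vol$voxels)
  fg <- vol$voxels >= thr
  if (clip_to_roi) {
    keep <- array(FALSE, d)
    keep[roi$lo[1]:roi$hi[1], roi$lo[2]:roi$hi[2],
         roi$lo[3]:roi$hi[3]] <- TRUE
    fg <- fg & keep
  }
  comp <- array(.flood_fill_26(as.vector(fg), d, pk$peak), d)
  filled <- array(FALSE, d)
  if (fill_holes) {
    exterior <- array(.exterior_background_6(as.vector(comp), d), d)
    filled <- !comp & !exterior
    comp <- comp | filled
  }
  lin <- which(comp)
  idx <- linear_to_vox(lin, d)
  on_boundary <- any(idx == 1L) ||
    any(idx == matrix(d, nrow(idx), 3, byrow = TRUE))
  if (on_boundary)
    warning("segmented stone touches the volume boundary; ",
            "the stone may be truncated")
  structure(list(indices = idx,
                 hole_filled = filled[lin],
                 peak = pk$peak,
                 max_hu = pk$max_hu,
                 threshold = thr,
                 n_hole_filled = sum(filled[lin]),
                 dim = d),
            class = "stone_mask")
}

#' @export
print.stone_mask <- function(x, ...) {
  cat(sprintf(
    "<stone_mask> %d voxels (%d hole-filled), maxHU %.1f, threshold %.1f\n",
    nrow(x$indices), x$n_hole_filled, x$max_hu, x$threshold))
  cat(sprintf("  peak point (%s) on a %s grid\n",
              paste(x$peak, collapse = ","), paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Fill interior holes of a 3D voxel set
#'
#' A hole is any background voxel not reachable from the grid's exterior
#' faces by 6-connected background steps; foreground connectivity is 26.
#' A tunnel open to the exterior is therefore not a hole and is left
#' untouched. Runs in full 3D, not slice by slice.
#'
#' @param indices n x 3 integer matrix of voxel indices (i, j, k).
#' @param shape grid shape `(nx, ny, nz)`.
#' @return Integer matrix of indices of the filled set, in raster order.
#' @export
fill_holes <- function(indices, shape) {
  shape <- as.integer(shape)
  fg <- array(FALSE, shape)
  if (NROW(indices) > 0) fg[vox_linear(indices, shape)] <- TRUE
  exterior <- array(.exterior_background_6(as.vector(fg), shape), shape)
  linear_to_vox(which(fg | !(exterior | fg)), shape)
}

# logical array view of a stone_mask
mask_array <- function(mask) {
  fg <- array(FALSE, mask$dim)
  fg[vox_linear(mask$indices, mask$dim)] <- TRUE
  fg
}

mask_linear <- function(mask) vox_linear(mask$indices, mask$dim)
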