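# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Implemented in-package because no NIfTI library is among the declared
# dependencies; covers 3D scalar images, which is all this package needs.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

read_all_raw <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  chunks <- list()
  repeat {
    ch <- readBin(con, raw(), n = 4194304L)
    if (length(ch) == 0L) break
    chunks[[length(chunks) + 1L]] <- ch
  }
  do.call(c, chunks)
}

#' Read a 3D NIfTI-1 volume in Hounsfield units
#'
#' Reads a scalar 3D NIfTI-1 image (`.nii` or `.nii.gz`), applying the
#' header scale slope/intercept, and returns it with its voxel spacing.
#' The stored values are assumed to already be calibrated HU.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [hu_volume].
#' @seealso [write_nifti()], [read_dicom_series()]
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read_all_raw(path)
  if (length(raw) < 352L) stop("not a NIfTI-1 file (too short): ", path)
  endian <- "little"
  hdr_size <- readBin(raw[1:4], "integer", size = 4, endian = endian)
  if (hdr_size != 348L) {
    endian <- "big"
    hdr_size <- readBin(raw[1:4], "integer", size = 4, endian = endian)
    if (hdr_size != 348L) stop("not a NIfTI-1 file: ", path)
  }
  rd <- function(off, what, size, n = 1L, signed = TRUE)
    readBin(raw[(off + 1):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  magic <- rawToChar(raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("missing NIfTI magic in ", path)
  dim_ <- rd(40, "integer", 2, n = 8)
  nd <- dim_[1]
  if (nd < 3L) stop("expected a 3D image, got ", nd, "D: ", path)
  if (nd > 3L && any(dim_[seq(5, nd + 1)] > 1L))
    stop("expected a 3D scalar image, got ", nd, "D: ", path)
  shape <- dim_[2:4]
  datatype <- rd(70, "integer", 2)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd(76, "double", 4, n = 8)
  vox_offset <- rd(108, "double", 4)
  scl_slope <- rd(112, "double", 4)
  scl_inter <- rd(116, "double", 4)
  n_vox <- prod(shape)
  off <- as.integer(round(vox_offset))
  if (length(raw) < off + n_vox * dt$size)
    stop("truncated NIfTI data in ", path)
  vals <- readBin(raw[(off + 1):(off + n_vox * dt$size)], dt$what,
                  n = n_vox, size = dt$size, signed = dt$signed,
                  endian = endian)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  hu_volume(array(vals, dim = shape), spacing = abs(pixdim[2:4]))
}

nifti_header_raw <- function(shape, spacing, datatype, bitpix) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wc <- function(s, n) {
    b <- charToRaw(s)
    writeBin(c(b, raw(n - length(b))), con)
  }
  wi(348, 4)                                  # sizeof_hdr
  wc("", 10); wc("", 18)                      # data_type, db_name
  wi(0, 4); wi(0, 2); wc("r", 1); wc("", 1)   # extents..dim_info
  wi(c(3, shape, 1, 1, 1, 1), 2)              # dim
  wf(c(0, 0, 0)); wi(0, 2)                    # intent
  wi(datatype, 2); wi(bitpix, 2); wi(0, 2)    # datatype, bitpix, slice_start
  wf(c(1, spacing, 0, 0, 0, 0))               # pixdim (qfac = 1)
  wf(352)                                     # vox_offset
  wf(1); wf(0)                                # scl_slope, scl_inter
  wi(0, 2); wc("", 1)                         # slice_end, slice_code
  writeBin(as.raw(10L), con)                  # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0))                           # cal_max..toffset
  wi(c(0, 0), 4)                              # glmax, glmin
  wc("stonequant", 80); wc("", 24)            # descrip, aux_file
  wi(0, 2); wi(1, 2)                          # qform_code, sform_code
  wf(c(0, 0, 0)); wf(c(0, 0, 0))              # quatern, qoffset
  wf(c(spacing[1], 0, 0, 0))                  # srow_x
  wf(c(0, spacing[2], 0, 0))                  # srow_y
  wf(c(0, 0, spacing[3], 0))                  # srow_z
  wc("", 16); wc("n+1", 4)                    # intent_name, magic
  writeBin(raw(4), con)                       # extension indicator
  rawConnectionValue(con)
}

#' Write a volume as NIfTI-1
#'
#' Writes an [hu_volume] as a single-file NIfTI-1 image. HU values are
#' stored as float64 so that round trips preserve them exactly; use
#' [write_mask()] for compact uint8 label images.
#'
#' @param vol an [hu_volume].
#' @param path destination path; compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "hu_volume"))
  hdr <- nifti_header_raw(dim(vol$voxels), vol$spacing,
                          datatype = 64L, bitpix = 64L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.vector(vol$voxels), con, size = 8, endian = "little")
  invisible(path)
}

#' Write a stone mask as a NIfTI-1 label image
#'
#' Writes a binary (0/1, uint8) label volume on the same grid and with the
#' same geometry as the reference volume the mask was segmented from.
#'
#' @param mask a [stone_mask] (or `NULL`/empty mask for an all-zero label).
#' @param reference the [hu_volume] supplying grid shape and spacing.
#' @param path destination path; compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, reference, path) {
  stopifnot(inherits(reference, "hu_volume"))
  d <- dim(reference$voxels)
  lab <- integer(prod(d))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "stone_mask"))
    if (!identical(mask$dim, d))
      stop("mask grid ", paste(mask$dim, collapse = "x"),
           " does not match reference ", paste(d, collapse = "x"))
    if (nrow(mask$indices) > 0) {
      if (any(mask$indices < 1L) ||
          any(mask$indices > matrix(d, nrow(mask$indices), 3, byrow = TRUE)))
        stop("mask indices out of reference bounds")
      lab[vox_linear(mask$indices, d)] <- 1L
    }
  }
  hdr <- nifti_header_raw(d, reference$spacing, datatype = 2L, bitpix = 8L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.raw(lab), con)
  invisible(path)
}
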