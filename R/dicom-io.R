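# Minimal DICOM reader for uncompressed explicit-VR little-endian axial CT
# series: enough to recover geometry and rescaled HU values. Implemented
# in-package because no DICOM library is among the declared dependencies.

dicom_parse_file <- function(path) {
  raw <- read_all_raw(path)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 132L
  n <- length(raw)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                               size = 2, signed = FALSE, endian = "little")
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer",
                               size = 4, endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elems <- list()
  while (pos + 8L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 5L):(pos + 6L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      data_off <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      data_off <- pos + 8L
    }
    if (len < 0 || data_off + len > n)
      stop("corrupt DICOM element at offset ", pos, " in ", path)
    tag <- sprintf("%04X,%04X", group, elem)
    elems[[tag]] <- list(vr = vr,
                         data = raw[seq_len(len) + data_off])
    pos <- data_off + len
  }
  elems
}

dicom_str <- function(elems, tag, default = NULL) {
  e <- elems[[tag]]
  if (is.null(e)) return(default)
  trimws(rawToChar(e$data))
}

dicom_num <- function(elems, tag, default = NULL) {
  s <- dicom_str(elems, tag)
  if (is.null(s) || !nzchar(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_us <- function(elems, tag) {
  e <- elems[[tag]]
  if (is.null(e)) return(NULL)
  readBin(e$data, "integer", size = 2, signed = FALSE, endian = "little")
}

#' Read an axial CT series from a DICOM directory
#'
#' Reads every DICOM file in a directory as one axial series, sorts the
#' slices by their z position, converts stored pixel values to HU using the
#' rescale slope and intercept, and assembles an [hu_volume]. Only
#' uncompressed explicit-VR little-endian files are supported.
#'
#' The on-disk file order never matters: slices are ordered by
#' ImagePositionPatient. Successive slice gaps must agree to within 1%
#' relative deviation (the acquisition protocol this package targets uses
#' contiguous 1 mm slices); larger deviations, duplicate positions, or
#' mixed series raise errors.
#'
#' @param dir directory containing the files of a single series.
#' @param pattern optional regular expression restricting which file names
#'   are read (default: all regular files).
#' @return An [hu_volume].
#' @export
read_dicom_series <- function(dir, pattern = NULL) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files found in ", dir)
  slices <- lapply(files, function(f) {
    elems <- dicom_parse_file(f)
    rows <- dicom_us(elems, "0028,0010")
    cols <- dicom_us(elems, "0028,0011")
    bits <- dicom_us(elems, "0028,0100")
    if (is.null(rows) || is.null(cols)) stop("missing image shape in ", f)
    if (is.null(bits) || bits != 16L)
      stop("only 16-bit pixel data supported (", f, ")")
    pixrep <- dicom_us(elems, "0028,0103")
    signed <- !is.null(pixrep) && pixrep == 1L
    pix <- elems[["7FE0,0010"]]
    if (is.null(pix)) stop("missing pixel data in ", f)
    stored <- readBin(pix$data, "integer", n = rows * cols, size = 2,
                      signed = signed, endian = "little")
    if (length(stored) != rows * cols)
      stop("pixel data length mismatch in ", f)
    slope <- dicom_num(elems, "0028,1053", 1)[1]
    inter <- dicom_num(elems, "0028,1052", 0)[1]
    ps <- dicom_num(elems, "0028,0030")  # (row spacing, column spacing)
    if (is.null(ps) || length(ps) != 2L) stop("missing pixel spacing in ", f)
    ipp <- dicom_num(elems, "0020,0032")
    zpos <- if (!is.null(ipp) && length(ipp) == 3L) ipp[3] else
      dicom_num(elems, "0020,1041")[1]
    if (is.null(zpos) || is.na(zpos)) stop("missing slice position in ", f)
    list(series = dicom_str(elems, "0020,000E", ""),
         # pixel data is row-major: column (x) fastest within a row (y)
         hu = matrix(as.double(stored) * slope + inter, nrow = cols),
         dx = ps[2], dy = ps[1], z = zpos)
  })
  series <- unique(vapply(slices, `[[`, "", "series"))
  if (length(series) > 1L)
    stop("directory contains ", length(series),
         " series; expected a single axial series")
  z <- vapply(slices, `[[`, 0, "z")
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  if (anyDuplicated(z))
    stop("duplicate slice positions; cannot order the series")
  dx <- vapply(slices, `[[`, 0, "dx")
  dy <- vapply(slices, `[[`, 0, "dy")
  if (diff(range(dx)) > 1e-6 || diff(range(dy)) > 1e-6)
    stop("inconsistent in-plane pixel spacing across slices")
  nz <- length(slices)
  if (nz > 1L) {
    gaps <- diff(z)
    if (nz > 2L && (max(gaps) - min(gaps)) / mean(gaps) > 0.01)
      stop(sprintf(
        "inconsistent slice spacing (gaps %.4g..%.4g mm exceed 1%% tolerance)",
        min(gaps), max(gaps)))
    dz <- mean(gaps)
  } else {
    dz <- 1
  }
  shapes <- vapply(slices, function(s) dim(s$hu), integer(2))
  if (any(shapes != shapes[, 1]))
    stop("inconsistent slice dimensions across the series")
  vox <- array(0, c(shapes[1, 1], shapes[2, 1], nz))
  for (k in seq_len(nz)) vox[, , k] <- slices[[k]]$hu
  hu_volume(vox, spacing = c(dx[1], dy[1], dz))
}
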