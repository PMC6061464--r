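# Fixture builders. The DICOM writer below emits explicit-VR
# little-endian part-10 bytes directly from the standard's wire format,
# independent of the package's parser.

write_dicom_slice <- function(path, pixels, z_mm, pixel_spacing = c(0.8, 0.8),
                              slope = 1, intercept = -1024,
                              series_uid = "1.2.3.4.5",
                              instance = 1L) {
  stopifnot(is.matrix(pixels))  # [x, y] layout, stored values
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  evenstr <- function(s) if (nchar(s) %% 2) paste0(s, " ") else s
  elem_str <- function(group, el, vr, s) {
    s <- evenstr(s)
    u16(group); u16(el); writeChar(vr, con, eos = NULL)
    u16(nchar(s)); writeChar(s, con, eos = NULL)
  }
  elem_us <- function(group, el, v) {
    u16(group); u16(el); writeChar("US", con, eos = NULL); u16(2); u16(v)
  }
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  elem_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  elem_str(0x0008, 0x0018, "UI", sprintf("%s.%d", series_uid, instance))
  elem_str(0x0020, 0x000E, "UI", series_uid)
  elem_str(0x0020, 0x0013, "IS", as.character(instance))
  elem_str(0x0020, 0x0032, "DS", sprintf("0\\0\\%g", z_mm))
  elem_us(0x0028, 0x0002, 1L)
  elem_us(0x0028, 0x0010, ncol(pixels))           # Rows (y)
  elem_us(0x0028, 0x0011, nrow(pixels))           # Columns (x)
  elem_str(0x0028, 0x0030, "DS",
           sprintf("%g\\%g", pixel_spacing[2], pixel_spacing[1]))
  elem_us(0x0028, 0x0100, 16L)
  elem_us(0x0028, 0x0101, 16L)
  elem_us(0x0028, 0x0102, 15L)
  elem_us(0x0028, 0x0103, 1L)                     # signed
  elem_str(0x0028, 0x1052, "DS", as.character(intercept))
  elem_str(0x0028, 0x1053, "DS", as.character(slope))
  # pixel data, row-major (x fastest within each row y) = column-major
  # order of the [x, y] matrix
  u16(0x7FE0); u16(0x0010); writeChar("OW", con, eos = NULL); u16(0)
  u32(2L * length(pixels))
  writeBin(as.integer(pixels), con, size = 2, endian = "little")
  invisible(path)
}

# two-slice DICOM series on disk; stored values chosen so HU = stored - 1024
write_test_series <- function(dir, nx = 6, ny = 5, hu1 = NULL, hu2 = NULL,
                              spacing = c(0.8, 0.8), dz = 1,
                              names = c("a.dcm", "b.dcm")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(hu1)) hu1 <- matrix(0L, nx, ny)
  if (is.null(hu2)) hu2 <- matrix(0L, nx, ny)
  write_dicom_slice(file.path(dir, names[1]), hu1 + 1024L, z_mm = 0,
                    pixel_spacing = spacing, instance = 1L)
  write_dicom_slice(file.path(dir, names[2]), hu2 + 1024L, z_mm = dz,
                    pixel_spacing = spacing, instance = 2L)
  dir
}

# small gaussian phantom centered exactly on a voxel center (odd extents)
centered_phantom <- function(peak = 600, sigma = 2, shape = c(33, 33, 25),
                             spacing = c(0.8, 0.8, 1.0), noise_sd = 0,
                             seed = NULL) {
  center <- (shape - 1) * spacing / 2
  make_phantom(phantom_spec(shape, spacing,
                            stones = list(phantom_stone(center, peak, sigma)),
                            noise_sd = noise_sd, seed = seed))
}
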