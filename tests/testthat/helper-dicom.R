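# minimal explicit-VR little-endian DICOM writer for test fixtures

dcm_elem <- function(grp, el, vr, value_raw) {
  hdr <- writeBin(c(as.integer(grp), as.integer(el)), raw(), size = 2,
                  endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

dcm_str <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
  r
}

# write one slice; pixels: integer matrix [col, row] of stored values
write_test_dicom_slice <- function(path, pixels, z_mm, series_uid = "1.2.3.4",
                                   pixel_spacing = c(0.5, 0.5),
                                   slope = 1, intercept = -1024,
                                   instance = 1L) {
  rows <- ncol(pixels); cols <- nrow(pixels)
  px <- writeBin(as.integer(as.vector(pixels)), raw(), size = 2,
                 endian = "little")
  body <- c(
    dcm_elem(0x0020, 0x000e, "UI", dcm_str(series_uid)),
    dcm_elem(0x0020, 0x0013, "IS", dcm_str(as.character(instance))),
    dcm_elem(0x0020, 0x0032, "DS",
             dcm_str(sprintf("0\\0\\%g", z_mm))),
    dcm_elem(0x0028, 0x0010, "US",
             writeBin(rows, raw(), size = 2, endian = "little")),
    dcm_elem(0x0028, 0x0011, "US",
             writeBin(cols, raw(), size = 2, endian = "little")),
    dcm_elem(0x0028, 0x0030, "DS",
             dcm_str(sprintf("%g\\%g", pixel_spacing[1], pixel_spacing[2]))),
    dcm_elem(0x0028, 0x0100, "US",
             writeBin(16L, raw(), size = 2, endian = "little")),
    dcm_elem(0x0028, 0x0103, "US",
             writeBin(1L, raw(), size = 2, endian = "little")),
    dcm_elem(0x0028, 0x1052, "DS", dcm_str(as.character(intercept))),
    dcm_elem(0x0028, 0x1053, "DS", dcm_str(as.character(slope))),
    dcm_elem(0x7fe0, 0x0010, "OW", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

# write a whole series for a small HU volume (slope 1, intercept -1024)
write_test_dicom_series <- function(dir, hu_array, spacing = c(0.5, 0.5, 1),
                                    series_uid = "1.2.3.4") {
  dir.create(dir, showWarnings = FALSE)
  for (k in seq_len(dim(hu_array)[3])) {
    stored <- hu_array[, , k] + 1024
    write_test_dicom_slice(
      file.path(dir, sprintf("slice%03d.dcm", k)), stored,
      z_mm = (k - 1) * spacing[3], series_uid = series_uid,
      pixel_spacing = spacing[1:2], instance = k)
  }
  invisible(dir)
}
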