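# Minimal DICOM series reader: uncompressed explicit-VR little-endian CT
# slices only, which covers the common exported-CT case.  Written in-package
# because no DICOM reader is among the package's dependencies.

# parse one DICOM file, returning the handful of tags the reader needs
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  pos <- 1L
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  u16 <- function(p) as.integer(raw[p]) + 256L * as.integer(raw[p + 1L])
  u32 <- function(p) sum(as.numeric(raw[p + 0:3]) * 256^(0:3))
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  out <- list()
  while (pos + 7L <= length(raw)) {
    grp <- u16(pos); el <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("header error: unsupported (implicit VR?) DICOM encoding",
           call. = FALSE)
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    vend <- vstart + len - 1L
    key <- sprintf("%04x,%04x", grp, el)
    if (key == "7fe0,0010") {
      out$pixel_data_raw <- raw[vstart:vend]
      break
    }
    want <- c("0020,000e", "0020,0032", "0020,0013", "0028,0010", "0028,0011",
              "0028,0030", "0028,0100", "0028,0103", "0028,1052", "0028,1053")
    if (key %in% want) {
      if (vr %in% c("US", "SS")) {
        out[[key]] <- u16(vstart)
      } else {
        out[[key]] <- trimws(rawToChar(raw[vstart:vend]))
      }
    }
    pos <- vend + 1L
  }
  out
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("empty DICOM directory", call. = FALSE)
  slices <- lapply(files, parse_dicom_file)
  uids <- vapply(slices, function(s) s[["0020,000e"]] %||% "", "")
  if (length(unique(uids)) > 1)
    stop("ambiguous-series error: directory contains ",
         length(unique(uids)), " SeriesInstanceUIDs", call. = FALSE)
  pos <- lapply(slices, function(s) {
    p <- s[["0020,0032"]]
    if (is.null(p)) return(NULL)
    as.numeric(strsplit(p, "\\\\")[[1]])
  })
  if (any(vapply(pos, is.null, TRUE)))
    stop("header error: missing ImagePositionPatient", call. = FALSE)
  z <- vapply(pos, `[`, 0, 3)
  ord <- order(z)                      # inferior -> superior
  slices <- slices[ord]; pos <- pos[ord]; z <- z[ord]
  s1 <- slices[[1]]
  rows <- s1[["0028,0010"]]; cols <- s1[["0028,0011"]]
  psp <- as.numeric(strsplit(s1[["0028,0030"]], "\\\\")[[1]])
  if (length(psp) != 2 || any(!is.finite(psp)))
    stop("header error: missing PixelSpacing", call. = FALSE)
  dz <- if (length(z) > 1) stats::median(diff(z)) else 1
  slope <- as.numeric(s1[["0028,1053"]] %||% "1")
  inter <- as.numeric(s1[["0028,1052"]] %||% "0")
  signed <- (s1[["0028,0103"]] %||% 1L) == 1L
  vals <- array(0, dim = c(cols, rows, length(slices)))
  for (k in seq_along(slices)) {
    px <- readBin(slices[[k]]$pixel_data_raw, "integer", n = rows * cols,
                  size = 2, signed = signed, endian = "little")
    # DICOM pixel data is row-major: fastest index is the column
    vals[, , k] <- matrix(px, nrow = cols, ncol = rows)
  }
  ct_volume(vals * slope + inter,
            spacing = c(psp[2], psp[1], abs(dz)),
            origin = c(0, 0, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
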