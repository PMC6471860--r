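#' Read a chest CT volume
#'
#' Reads a NIfTI file or an uncompressed DICOM series directory into a
#' [ct_volume()].  For DICOM the rescale slope/intercept is applied so the
#' returned values are HU; slices are ordered by their patient z position so
#' the cranial end sits at the top (high k) of the array, matching the
#' package's canonical orientation.
#'
#' @param path path to a `.nii`/`.nii.gz` file, or a directory containing a
#'   single DICOM series.
#' @return A [ct_volume()].
#' @export
read_ct <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3 || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("header error: missing or invalid voxel spacing", call. = FALSE)
  # NIfTI qform/sform offsets are not carried; the package convention is a
  # zero world origin with geometry identity enforced via shape + spacing
  ct_volume(vals, spacing = sp[1:3], origin = c(0, 0, 0))
}

#' Write a CT volume as NIfTI
#'
#' @param ct a [ct_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_ct <- function(ct, path) {
  img <- RNifti::asNifti(ct$values)
  RNifti::pixdim(img) <- ct$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a binary mask as NIfTI
#'
#' Masks are written as 0/1 integer volumes.  On read, the geometry is
#' checked against a reference volume (shape exactly, spacing within
#' 1e-4 mm, origin within 1e-3 mm) and any mismatch is an alignment error.
#'
#' @param mask a [binary_mask()].
#' @param path NIfTI path.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$values), dim = dim(mask$values)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @param reference a [ct_volume()] (or mask) defining the expected grid.
#' @export
read_mask <- function(path, reference) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  m <- binary_mask(array(as.numeric(img) != 0, dim = dim(img)),
                   spacing = sp, origin = reference$origin)
  check_geometry(m, reference)
  m
}

#' Write subject metrics or a cohort table
#'
#' Subject metrics are written as JSON with documented snake_case keys and
#' explicit `null` for missing values; cohort tables as CSV with a `#`-prefixed
#' sidecar header line documenting units.
#'
#' @param metrics a `subject_metrics` list or a cohort `data.frame`.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @export
write_metrics <- function(metrics, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    if (is.data.frame(metrics)) stop("use csv format for tables", call. = FALSE)
    req <- intersect(c("awv_ml", "rlv_ml", "awv_percent"), names(metrics))
    bad <- vapply(metrics[req], function(v) length(v) == 1 && is.na(v), FALSE)
    if (any(bad))
      stop("validation error: NaN/NA in required key column: ",
           paste(req[bad], collapse = ", "), call. = FALSE)
    jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = 10,
                         null = "null", na = "null", pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# units: volumes ml, areas mm2, percents %, ",
                      "lengths mm, age yr, BMI kg/m2"), con)
    utils::write.csv(metrics, con, row.names = FALSE)
  }
  invisible(path)
}

#' Read a cohort table written by [write_metrics()]
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Export / import an airway graph as JSON
#'
#' @param graph an `airway_graph`.
#' @param path JSON path.
#' @export
write_airway_graph <- function(graph, path) {
  obj <- list(
    spacing = graph$spacing,
    nodes = graph$nodes,
    branches = graph$branches[, setdiff(names(graph$branches), "centerline")],
    centerlines = lapply(graph$centerlines, function(m) unname(as.matrix(m)))
  )
  jsonlite::write_json(obj, path, digits = 10, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_airway_graph
#' @export
read_airway_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(spacing = as.numeric(obj$spacing),
                 nodes = as.data.frame(obj$nodes),
                 branches = as.data.frame(obj$branches),
                 centerlines = lapply(obj$centerlines, function(m) {
                   storage.mode(m) <- "double"
                   m
                 })),
            class = "airway_graph")
}
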