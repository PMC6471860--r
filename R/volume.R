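#' CT volume container
#'
#' A 3-D grid of Hounsfield units with voxel spacing and world origin in mm.
#' The canonical internal orientation is: axis 1 (x) increases from the
#' patient's right to left, axis 2 (y) from anterior to posterior, axis 3 (z)
#' from inferior to superior, so the trachea enters near the top (high z)
#' slices and the right lung occupies low x.  World coordinates of the voxel
#' at array index `(i, j, k)` (1-based) are `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @param values 3-D numeric array of HU values.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of the first voxel.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L || any(dim(values) == 0L))
    stop("values must be a non-empty 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (mm)", call. = FALSE)
  rng <- range(values, finite = TRUE)
  if (rng[1] < -1024 - 1e-6 || rng[2] > 3071 + 1e-6)
    warning("HU values outside the plausible CT range [-1024, 3071]")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary mask on the grid of a CT volume
#'
#' @param values 3-D logical array.
#' @param spacing voxel spacing in mm.
#' @param origin world origin in mm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("values must be a 3-D array", call. = FALSE)
  storage.mode(values) <- "logical"
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d set (%.2f ml)\n",
              paste(dim(x$values), collapse = "x"), sum(x$values),
              mask_volume_ml(x)))
  invisible(x)
}

#' Volume of a mask in millilitres
#'
#' @param mask a `binary_mask`.
#' @return Volume in ml (voxel count times voxel volume / 1000).
#' @export
mask_volume_ml <- function(mask) {
  sum(mask$values) * prod(mask$spacing) / 1000
}

# geometry agreement between a mask (or volume) and its reference grid;
# tolerances: spacing 1e-4 mm, origin 1e-3 mm
check_geometry <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("alignment error: grid shapes differ", call. = FALSE)
  if (any(abs(a$spacing - b$spacing) > 1e-4))
    stop("alignment error: voxel spacing differs beyond 1e-4 mm", call. = FALSE)
  if (any(abs(a$origin - b$origin) > 1e-3))
    stop("alignment error: origin differs beyond 1e-3 mm", call. = FALSE)
  invisible(TRUE)
}

# world-mm coordinates (n x 3) of 1-based voxel index matrix
voxel_to_world <- function(idx, spacing, origin = c(0, 0, 0)) {
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b `binary_mask` objects on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_geometry(a, b)
  i <- sum(a$values & b$values)
  2 * i / (sum(a$values) + sum(b$values))
}
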