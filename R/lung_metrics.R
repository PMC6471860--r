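#' Segment the lungs from a chest CT
#'
#' Thresholds the volume below `threshold_hu` (default -320 HU), removes
#' components touching the lateral image border (outside air), keeps the
#' largest one or two components above `min_volume_ml`, fills internal
#' holes in 3-D, and subtracts the airway lumen so tracheal/bronchial air
#' is not counted as lung.
#'
#' @param ct a [ct_volume()].
#' @param airway_mask optional [binary_mask()] of the airway lumen to
#'   subtract.
#' @param threshold_hu lung threshold (voxels strictly below are candidate
#'   lung).
#' @param min_volume_ml smallest plausible single-lung volume.
#' @return A [binary_mask()] of the lungs (airway excluded).
#' @export
segment_lungs <- function(ct, airway_mask = NULL, threshold_hu = -320,
                          min_volume_ml = 5) {
  dm <- dim(ct$values)
  cand <- ct$values < threshold_hu
  if (!any(cand))
    stop("segmentation-failed error: no voxels below ", threshold_hu,
         call. = FALSE)
  lab <- cpp_label_components(as.logical(cand), dm, 26L)
  tab <- tabulate(lab[lab > 0])
  min_vox <- min_volume_ml * 1000 / prod(ct$spacing)
  # drop components touching the lateral (x/y) border: outside air
  border <- unique(c(lab[1, , ], lab[dm[1], , ], lab[, 1, ], lab[, dm[2], ]))
  border <- setdiff(border, 0L)
  keep <- setdiff(order(tab, decreasing = TRUE), border)
  keep <- keep[tab[keep] >= min_vox]
  keep <- utils::head(keep, 2)
  if (length(keep) == 0)
    stop("segmentation-failed error: no lung-sized component", call. = FALSE)
  m <- array(lab %in% keep, dm)
  m <- fill_holes3d(m)
  if (!is.null(airway_mask)) {
    check_geometry(binary_mask(m, ct$spacing, ct$origin), airway_mask)
    m <- m & !airway_mask$values
  }
  binary_mask(m, ct$spacing, ct$origin)
}

# fill 3-D cavities: background 6-components not reaching the volume border
fill_holes3d <- function(m) {
  dm <- dim(m)
  bg <- cpp_label_components(as.logical(!m), dm, 6L)
  edge <- unique(c(bg[1, , ], bg[dm[1], , ], bg[, 1, ], bg[, dm[2], ],
                   bg[, , 1], bg[, , dm[3]]))
  edge <- setdiff(edge, 0L)
  holes <- bg > 0 & !(bg %in% edge)
  m | array(holes, dm)
}

#' Split a lung mask into right and left lungs
#'
#' Connected components are assigned by centroid position relative to the
#' mid-sagittal plane: in the canonical orientation the patient's right lung
#' has the smaller x centroid.  A single fused component is split at the
#' sagittal plane with the fewest mask voxels near the midline; if that
#' fails, a warning is raised and the whole mask is returned as `fused`.
#'
#' @param lung_mask a [binary_mask()].
#' @return List with `right` and `left` [binary_mask()]s (and `fused = TRUE`
#'   plus `right = NULL`, `left = NULL` on failure).
#' @export
split_left_right <- function(lung_mask) {
  dm <- dim(lung_mask$values)
  lab <- cpp_label_components(as.logical(lung_mask$values), dm, 26L)
  n <- max(lab)
  if (n == 0) stop("empty lung mask", call. = FALSE)
  if (n == 1) {
    # attempt minimum-sagittal-cut split near the midline
    counts <- vapply(seq_len(dm[1]), function(i) sum(lab[i, , ] > 0), 0)
    mid <- which(seq_len(dm[1]) > dm[1] * 0.3 & seq_len(dm[1]) < dm[1] * 0.7)
    cut <- mid[which.min(counts[mid])]
    if (counts[cut] > 0.2 * max(counts)) {
      warning("split-failed: lungs fused centrally; both-lung metrics only")
      return(list(right = NULL, left = NULL, fused = TRUE))
    }
    right <- lung_mask$values; right[(cut + 1):dm[1], , ] <- FALSE
    left <- lung_mask$values; left[1:cut, , ] <- FALSE
  } else {
    cx <- vapply(seq_len(n), function(l)
      mean(arrayInd(which(lab == l), dm)[, 1]), 0)
    sizes <- tabulate(lab[lab > 0], n)
    big2 <- order(sizes, decreasing = TRUE)[1:2]
    rlab <- big2[which.min(cx[big2])]
    right <- array(lab == rlab, dm)
    left <- array(lab > 0 & lab != rlab, dm)
  }
  list(right = binary_mask(right, lung_mask$spacing, lung_mask$origin),
       left = binary_mask(left, lung_mask$spacing, lung_mask$origin),
       fused = FALSE)
}

#' Low attenuation volume percent (LAV%)
#'
#' Percentage of region voxels strictly below the threshold (default
#' -950 HU), the standard CT emphysema surrogate.
#'
#' @param ct a [ct_volume()].
#' @param region a [binary_mask()] of the lung region of interest.
#' @param threshold_hu attenuation threshold (strict `<`).
#' @return Percent in \[0, 100\].
#' @export
lav_percent <- function(ct, region, threshold_hu = -950) {
  check_geometry(region, ct)
  n <- sum(region$values)
  if (n == 0) stop("undefined-measure error: empty region", call. = FALSE)
  100 * sum(ct$values[region$values] < threshold_hu) / n
}

#' Lung volumes from right/left masks
#'
#' @param right,left [binary_mask()]s on a common grid (either may be empty).
#' @return List with `rlv_ml`, `llv_ml`, `ct_tlv_ml`.
#' @export
lung_volumes <- function(right, left) {
  if (!is.null(right) && !is.null(left)) {
    check_geometry(right, left)
    if (any(right$values & left$values))
      stop("consistency error: right and left masks overlap", call. = FALSE)
  }
  rlv <- if (is.null(right)) NA_real_ else mask_volume_ml(right)
  llv <- if (is.null(left)) NA_real_ else mask_volume_ml(left)
  list(rlv_ml = rlv, llv_ml = llv,
       ct_tlv_ml = sum(c(rlv, llv), na.rm = TRUE))
}
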