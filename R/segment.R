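#' Segmentation parameters for airway region growing
#'
#' @param initial_hu starting threshold (region = voxels below threshold).
#' @param step_hu threshold increment per iteration (> 0).
#' @param max_hu final threshold candidate.
#' @param leak_factor volume-jump ratio that triggers leakage rollback (> 1).
#' @param connectivity 6 or 26.
#' @param max_iter safety cap on iterations.
#' @return A `seg_params` list.
#' @export
seg_params <- function(initial_hu = -960, step_hu = 4, max_hu = -850,
                       leak_factor = 2.0, connectivity = 26,
                       max_iter = 200L) {
  if (step_hu <= 0) stop("step must be > 0", call. = FALSE)
  if (leak_factor <= 1) stop("leakage factor must be > 1", call. = FALSE)
  if (!connectivity %in% c(6, 26))
    stop("connectivity must be 6 or 26", call. = FALSE)
  structure(list(initial_hu = initial_hu, step_hu = step_hu, max_hu = max_hu,
                 leak_factor = leak_factor, connectivity = connectivity,
                 max_iter = as.integer(max_iter)),
            class = "seg_params")
}

#' Locate a trachea seed voxel
#'
#' Searches the top 10% of axial slices for air (< -900 HU) components,
#' excludes those touching the lateral image border, requires a plausible
#' tracheal cross-section (> 20 mm2 on some slice), and returns a voxel of
#' the component whose centroid is nearest the in-plane centre.
#'
#' @param ct a [ct_volume()].
#' @return Integer voxel index (1-based, length 3).
#' @export
find_trachea_seed <- function(ct) {
  dm <- dim(ct$values)
  z0 <- max(1L, ceiling(dm[3] * 0.9))
  sub <- ct$values[, , z0:dm[3], drop = FALSE]
  air <- sub < -900
  if (!any(air)) stop("seed-not-found error: no air component", call. = FALSE)
  lab <- cpp_label_components(as.logical(air), dim(sub), 26L)
  min_vox <- 20 / (ct$spacing[1] * ct$spacing[2])   # 20 mm2 in one slice
  ctr <- c(dm[1] / 2, dm[2] / 2)
  best <- NULL; best_d <- Inf
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l)
    w <- arrayInd(idx, dim(sub))
    if (any(w[, 1] <= 1 | w[, 1] >= dm[1] | w[, 2] <= 1 | w[, 2] >= dm[2]))
      next                                   # touches lateral border
    per_slice <- max(table(w[, 3]))
    if (per_slice < min_vox) next
    cen <- colMeans(w[, 1:2, drop = FALSE])
    d <- sum((cen - ctr)^2)
    if (d < best_d) {
      best_d <- d
      # pick the component voxel nearest its centroid on the top slice
      top <- w[w[, 3] == max(w[, 3]), , drop = FALSE]
      dd <- (top[, 1] - cen[1])^2 + (top[, 2] - cen[2])^2
      v <- top[which.min(dd), ]
      best <- c(v[1], v[2], v[3] + z0 - 1L)
    }
  }
  if (is.null(best))
    stop("seed-not-found error: no component of plausible tracheal area",
         call. = FALSE)
  as.integer(best)
}

#' Grow the airway tree by iterative-threshold region growing
#'
#' The region of voxels below a threshold and connected to the seed is grown
#' while the threshold is relaxed from `initial_hu` toward `max_hu` in
#' `step_hu` increments.  If the region volume jumps by more than
#' `leak_factor` between consecutive thresholds, leakage into the parenchyma
#' is assumed and the previous threshold is kept (rollback).  The accepted
#' threshold, the volume trace, and whether a rollback occurred are attached
#' as attributes.
#'
#' @param ct a [ct_volume()].
#' @param seed 1-based voxel index (length 3), e.g. from
#'   [find_trachea_seed()].
#' @param params a [seg_params()].
#' @return A [binary_mask()] of the airway lumen with attributes
#'   `accepted_threshold`, `rollback`, `volume_trace`.
#' @export
grow_airway_tree <- function(ct, seed, params = seg_params()) {
  dm <- dim(ct$values)
  thr <- seq(min(params$initial_hu, params$max_hu), params$max_hu,
             by = params$step_hu)
  thr <- thr[seq_len(min(length(thr), params$max_iter))]
  sv <- ct$values[seed[1], seed[2], seed[3]]
  if (sv >= thr[1])
    stop("invalid-seed error: seed HU (", sv, ") not below initial threshold",
         call. = FALSE)
  prev <- NULL; prev_n <- 0; accepted <- NA_real_; rollback <- FALSE
  trace <- numeric(0)
  for (t in thr) {
    cur <- cpp_flood_fill(ct$values, dm, as.integer(seed) - 1L, t,
                          params$connectivity)
    n <- sum(cur)
    trace <- c(trace, n)
    if (!is.null(prev) && prev_n > 0 && n > params$leak_factor * prev_n) {
      rollback <- TRUE
      break
    }
    prev <- cur; prev_n <- n; accepted <- t
  }
  if (is.null(prev) || prev_n == 0)
    stop("segmentation-failed error: empty region", call. = FALSE)
  out <- binary_mask(prev, ct$spacing, ct$origin)
  attr(out, "accepted_threshold") <- accepted
  attr(out, "rollback") <- rollback
  attr(out, "volume_trace") <- trace
  out
}
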