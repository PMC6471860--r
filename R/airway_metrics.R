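#' Airway-tree volume in millilitres
#'
#' Assigns every lumen-mask voxel to its nearest centerline point and sums
#' the voxel volume of voxels whose branch carries one of the requested
#' subtree labels.  With `labels = NULL` the whole mask volume is returned.
#' The airway volume AWV of the right lung is the sum over the RUL and RMLL
#' subtrees.
#'
#' @param mask a [binary_mask()] of the airway lumen.
#' @param graph a partitioned `airway_graph` on the same grid.
#' @param labels subtree labels to include (default `c("RUL", "RMLL")`).
#' @return Volume in ml.
#' @export
airway_volume_ml <- function(mask, graph = NULL, labels = c("RUL", "RMLL")) {
  if (is.null(graph) || is.null(labels))
    return(mask_volume_ml(mask))
  br <- graph$branches
  pts <- list(); pt_lab <- list()
  for (i in seq_len(nrow(br))) {
    cl <- graph$centerlines[[br$id[i]]]
    pts[[i]] <- cl
    pt_lab[[i]] <- rep(br$label[i], nrow(cl))
  }
  P <- do.call(rbind, pts)
  L <- unlist(pt_lab)
  vox <- arrayInd(which(mask$values), dim(mask$values))
  if (nrow(vox) == 0) {
    warning("empty labelled set; volume 0")
    return(0)
  }
  nn <- cpp_nearest_point(voxel_to_world(vox, mask$spacing),
                          voxel_to_world(P, mask$spacing))
  n_in <- sum(L[nn] %in% labels)
  if (n_in == 0) warning("no voxels assigned to labels ",
                         paste(labels, collapse = "/"))
  n_in * prod(mask$spacing) / 1000
}

# arc-length parameterization of a smoothed centerline (world mm);
# returns function(position_mm) -> list(point, tangent)
centerline_param <- function(cl_vox, spacing, smooth_k = 5) {
  w <- voxel_to_world(cl_vox, spacing)
  if (nrow(w) >= smooth_k) {
    sm <- apply(w, 2, function(v)
      stats::filter(v, rep(1 / smooth_k, smooth_k), sides = 2))
    keep <- !is.na(sm[, 1])
    sm <- rbind(w[1, , drop = FALSE], sm[keep, , drop = FALSE],
                w[nrow(w), , drop = FALSE])
  } else sm <- w
  d <- sqrt(rowSums(diff(sm)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  list(length = total, at = function(pos) {
    if (pos < -1e-9 || pos > total + 1e-9)
      stop("range error: position ", pos, " outside branch length ",
           round(total, 2), call. = FALSE)
    pos <- min(max(pos, 0), total)
    i <- findInterval(pos, s, rightmost.closed = TRUE)
    i <- min(max(i, 1), nrow(sm) - 1)
    f <- if (d[i] > 0) (pos - s[i]) / d[i] else 0
    pt <- sm[i, ] + f * (sm[i + 1, ] - sm[i, ])
    # tangent over a window for stability
    i0 <- max(1, i - 2); i1 <- min(nrow(sm), i + 3)
    tg <- sm[i1, ] - sm[i0, ]
    tg <- tg / sqrt(sum(tg^2))
    list(point = pt, tangent = tg)
  })
}

#' Extract a cross-sectional image orthogonal to a branch centerline
#'
#' Resamples the CT on a plane orthogonal to the local (smoothed) centerline
#' tangent by trilinear interpolation.
#'
#' @param ct a [ct_volume()].
#' @param graph an `airway_graph`.
#' @param branch_id branch to section.
#' @param position_mm arc-length position along the branch (0..length).
#' @param plane_res_mm in-plane sampling step (default 0.1 mm).
#' @param plane_size_mm side length of the square plane; default six times
#'   the largest voxel spacing plus 12 mm.
#' @return A `cross_section`: list with `values` (matrix), `res_mm`, and the
#'   in-plane mm coordinates of the centre.
#' @export
extract_cross_section <- function(ct, graph, branch_id, position_mm,
                                  plane_res_mm = 0.1, plane_size_mm = NULL) {
  br <- graph$branches
  if (!branch_id %in% br$id) stop("lookup error: no branch ", branch_id,
                                  call. = FALSE)
  cl <- graph$centerlines[[branch_id]]
  par <- centerline_param(cl, graph$spacing)
  loc <- par$at(position_mm)
  tg <- loc$tangent
  # orthonormal in-plane basis
  a <- if (abs(tg[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- pracma_cross(tg, a); u <- u / sqrt(sum(u^2))
  v <- pracma_cross(tg, u)
  if (is.null(plane_size_mm)) plane_size_mm <- 12 + 6 * max(ct$spacing)
  half <- plane_size_mm / 2
  g <- seq(-half, half, by = plane_res_mm)
  gg <- as.matrix(expand.grid(s = g, t = g))
  pts <- sweep(gg[, 1, drop = FALSE] %*% rbind(u) +
                 gg[, 2, drop = FALSE] %*% rbind(v), 2, loc$point, "+")
  vals <- interp_trilinear(ct, pts)
  list(values = matrix(vals, nrow = length(g)), res_mm = plane_res_mm,
       axis_mm = g, center = c(0, 0), branch_id = branch_id,
       position_mm = position_mm)
}

# trilinear interpolation of ct$values at world-mm points (n x 3);
# outside points take the nearest border value
interp_trilinear <- function(ct, pts) {
  dm <- dim(ct$values)
  # continuous voxel coordinates (1-based)
  cv <- sweep(sweep(pts, 2, ct$origin), 2, ct$spacing, "/") + 1
  cv <- pmin(pmax(cv, 1), matrix(rep(dm, each = nrow(cv)), ncol = 3))
  f0 <- floor(cv)
  f0 <- pmin(f0, matrix(rep(dm - 1, each = nrow(cv)), ncol = 3))
  fr <- cv - f0
  v <- ct$values
  idx <- function(a, b, c) v[cbind(a, b, c)]
  x0 <- f0[, 1]; y0 <- f0[, 2]; z0 <- f0[, 3]
  c000 <- idx(x0, y0, z0);     c100 <- idx(x0 + 1, y0, z0)
  c010 <- idx(x0, y0 + 1, z0); c110 <- idx(x0 + 1, y0 + 1, z0)
  c001 <- idx(x0, y0, z0 + 1); c101 <- idx(x0 + 1, y0, z0 + 1)
  c011 <- idx(x0, y0 + 1, z0 + 1); c111 <- idx(x0 + 1, y0 + 1, z0 + 1)
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# bilinear sampling of a cross_section at in-plane mm coordinates
section_sample <- function(section, s, t) {
  g <- section$axis_mm
  n <- length(g)
  i <- (s - g[1]) / section$res_mm + 1
  j <- (t - g[1]) / section$res_mm + 1
  i <- pmin(pmax(i, 1), n); j <- pmin(pmax(j, 1), n)
  i0 <- pmin(floor(i), n - 1); j0 <- pmin(floor(j), n - 1)
  fi <- i - i0; fj <- j - j0
  v <- section$values
  v[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    v[cbind(i0 + 1, j0)] * fi * (1 - fj) +
    v[cbind(i0, j0 + 1)] * (1 - fi) * fj +
    v[cbind(i0 + 1, j0 + 1)] * fi * fj
}

#' Measure lumen and wall areas by the full-width-half-maximum principle
#'
#' Casts `n_rays` rays from the lumen centre.  Along each ray the lumen
#' minimum and wall-peak HU are located; the inner wall boundary is the
#' first outward crossing of `(min + peak)/2`, the outer boundary the
#' crossing of `(peak + outer plateau)/2` beyond the peak, where the
#' plateau is the median HU over the last quarter of the ray.  Rays with no
#' distinct wall peak (or an adjacent bright structure) are excluded; the
#' measure is flagged invalid when more than 25% of rays fail.
#' `Ai` and the outer area are polygon areas of the boundary points;
#' `WA% = 100 * WA / (Ai + WA)`.
#'
#' @param section a `cross_section` from [extract_cross_section()].
#' @param center in-plane mm coordinates of the lumen centre.
#' @param n_rays number of rays (default 64).
#' @param max_radius_mm ray length; default reaches the plane edge.
#' @param min_contrast_hu minimum peak prominence above the lumen minimum.
#' @return A `cross_section_measure`: list with `ai_mm2`, `wa_mm2`,
#'   `wa_percent`, `n_failed`, `valid`.
#' @export
fwhm_measure <- function(section, center = c(0, 0), n_rays = 64,
                         max_radius_mm = NULL, min_contrast_hu = 150) {
  if (is.null(max_radius_mm))
    max_radius_mm <- max(section$axis_mm) * 0.95
  step <- section$res_mm / 2
  rr <- seq(0, max_radius_mm, by = step)
  c_hu <- section_sample(section, center[1], center[2])
  if (c_hu > -500)
    stop("invalid-center error: centre HU ", round(c_hu),
         " is not in a low-attenuation lumen", call. = FALSE)
  th <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  r_in <- r_out <- rep(NA_real_, n_rays)
  for (k in seq_len(n_rays)) {
    prof <- section_sample(section, center[1] + rr * cos(th[k]),
                           center[2] + rr * sin(th[k]))
    m <- which.max(prof)
    if (m <= 1 || m >= length(prof)) next
    lum_min <- min(prof[1:m])
    peak <- prof[m]
    if (peak - lum_min < min_contrast_hu) next
    plateau <- stats::median(prof[seq(floor(length(prof) * 0.75),
                                      length(prof))])
    if (peak - plateau < min_contrast_hu / 3) next   # no distinct outer edge
    i_min <- which.min(prof[1:m])
    half_in <- (lum_min + peak) / 2
    ii <- i_min
    while (ii < m && prof[ii + 1] < half_in) ii <- ii + 1
    if (ii >= m) next
    f <- (half_in - prof[ii]) / (prof[ii + 1] - prof[ii])
    r_in[k] <- rr[ii] + f * step
    half_out <- (peak + plateau) / 2
    jj <- m
    while (jj < length(prof) && prof[jj + 1] > half_out) jj <- jj + 1
    if (jj >= length(prof)) next
    f <- (prof[jj] - half_out) / (prof[jj] - prof[jj + 1])
    r_out[k] <- rr[jj] + f * step
  }
  ok <- !is.na(r_in) & !is.na(r_out)
  n_failed <- sum(!ok)
  if (n_failed > 0.25 * n_rays)
    stop("quality error: ", n_failed, " of ", n_rays,
         " rays failed (no distinct wall peak)", call. = FALSE)
  poly_area <- function(r, t) {
    x <- r * cos(t); y <- r * sin(t)
    n <- length(x)
    0.5 * abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y))
  }
  ai <- poly_area(r_in[ok], th[ok])
  ao <- poly_area(r_out[ok], th[ok])
  wa <- max(ao - ai, 0)
  structure(list(ai_mm2 = ai, wa_mm2 = wa,
                 wa_percent = 100 * wa / (ai + wa),
                 n_failed = n_failed, valid = TRUE),
            class = "cross_section_measure")
}

#' Measure Ai and WA% along named airway paths
#'
#' For each path (e.g. RB1, RB10), cross-sections are taken at the stated
#' fractions of each branch's length (default 25/50/75%), measured with
#' [fwhm_measure()], and averaged per branch, then per role (segmental /
#' sub-segmental), then per path.  The overall means are the arithmetic
#' means over paths, equally weighted.
#'
#' @param ct a [ct_volume()].
#' @param graph an `airway_graph`.
#' @param paths named list; each element a list with elements `segmental`
#'   and `subsegmental`, vectors of branch ids.
#' @param positions fractions of branch length to sample.
#' @param n_rays rays per cross-section.
#' @return List with `paths` (per-path data frame) and `mean_ai_mm2`,
#'   `mean_wa_percent`.
#' @export
measure_paths <- function(ct, graph, paths, positions = c(0.25, 0.5, 0.75),
                          n_rays = 64) {
  measure_branch <- function(id) {
    if (!id %in% graph$branches$id)
      stop("lookup error: no branch ", id, call. = FALSE)
    len <- graph$branches$length_mm[graph$branches$id == id]
    ms <- lapply(positions, function(f) {
      sec <- extract_cross_section(ct, graph, id, f * len)
      tryCatch(fwhm_measure(sec, n_rays = n_rays),
               error = function(e) list(ai_mm2 = NA, wa_percent = NA,
                                        valid = FALSE))
    })
    ai <- vapply(ms, function(m) if (isTRUE(m$valid)) m$ai_mm2 else NA_real_, 0)
    wp <- vapply(ms, function(m) if (isTRUE(m$valid)) m$wa_percent else NA_real_, 0)
    c(ai = mean(ai, na.rm = TRUE), wa = mean(wp, na.rm = TRUE))
  }
  rows <- lapply(names(paths), function(pn) {
    p <- paths[[pn]]
    seg <- sapply(p$segmental, measure_branch)
    sub <- sapply(p$subsegmental, measure_branch)
    seg_ai <- mean(seg["ai", ], na.rm = TRUE)
    seg_wa <- mean(seg["wa", ], na.rm = TRUE)
    sub_ai <- mean(sub["ai", ], na.rm = TRUE)
    sub_wa <- mean(sub["wa", ], na.rm = TRUE)
    data.frame(path = pn,
               segmental_ai_mm2 = seg_ai, segmental_wa_percent = seg_wa,
               subsegmental_ai_mm2 = sub_ai,
               subsegmental_wa_percent = sub_wa,
               ai_mm2 = mean(c(seg_ai, sub_ai), na.rm = TRUE),
               wa_percent = mean(c(seg_wa, sub_wa), na.rm = TRUE),
               valid = is.finite(seg_ai) || is.finite(sub_ai),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$valid
  if (!all(ok)) warning("paths excluded by quality flag: ",
                        paste(tab$path[!ok], collapse = ", "))
  list(paths = tab,
       mean_ai_mm2 = mean(tab$ai_mm2[ok], na.rm = TRUE),
       mean_wa_percent = mean(tab$wa_percent[ok], na.rm = TRUE))
}

#' Synthetic blurred-annulus cross-section
#'
#' Rasterizes an airway-like annulus (dark lumen, bright wall, parenchymal
#' background) on a fine grid and applies an in-plane Gaussian blur,
#' producing a `cross_section` with exactly known geometry for validating
#' [fwhm_measure()].
#'
#' @param lumen_radius_mm,wall_mm inner radius and wall thickness, mm.
#' @param res_mm grid resolution (default 0.1 mm).
#' @param blur_sigma_mm Gaussian blur SD in mm.
#' @param hu_lumen,hu_wall,hu_background HU levels.
#' @param size_mm image side length; default fits 3x the outer radius.
#' @return A `cross_section` list usable with [fwhm_measure()].
#' @export
synthetic_annulus <- function(lumen_radius_mm, wall_mm, res_mm = 0.1,
                              blur_sigma_mm = 0.6, hu_lumen = -1000,
                              hu_wall = 0, hu_background = -870,
                              size_mm = NULL) {
  if (is.null(size_mm)) size_mm <- 6 * (lumen_radius_mm + wall_mm)
  g <- seq(-size_mm / 2, size_mm / 2, by = res_mm)
  d <- sqrt(outer(g^2, g^2, "+"))
  img <- matrix(hu_background, length(g), length(g))
  img[d <= lumen_radius_mm + wall_mm] <- hu_wall
  img[d <= lumen_radius_mm] <- hu_lumen
  if (blur_sigma_mm > 0) {
    s <- blur_sigma_mm / res_mm
    rad <- ceiling(3 * s)
    k <- exp(-0.5 * ((-rad):rad)^2 / s^2); k <- k / sum(k)
    pad <- function(m) m   # reflect handled by filter NA trim below
    img <- apply(img, 2, function(col) as.numeric(stats::filter(
      c(rev(col[seq_len(rad)]), col, rev(col[length(col) - seq_len(rad) + 1])),
      k, sides = 2))[(rad + 1):(rad + length(col))])
    img <- t(apply(t(img), 2, function(col) as.numeric(stats::filter(
      c(rev(col[seq_len(rad)]), col, rev(col[length(col) - seq_len(rad) + 1])),
      k, sides = 2))[(rad + 1):(rad + length(col))]))
  }
  list(values = img, res_mm = res_mm, axis_mm = g, center = c(0, 0),
       branch_id = NA_integer_, position_mm = NA_real_)
}
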