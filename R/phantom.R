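#' Build the geometry of a synthetic bifurcating airway tree
#'
#' Generates a full binary tree of straight cylindrical branches.  The root
#' (trachea surrogate) points caudally (down the z axis); each branch splits
#' into two children rotated by `+/- angle` about an axis perpendicular to the
#' parent, with the branching plane rolled 90 degrees at every generation so
#' the tree fills 3-D space.  Radii and lengths taper geometrically: a branch
#' of generation g has radius `root_radius * taper^g` and length
#' `branch_length * taper^g`.  Wall thickness is `wall_fraction * radius`
#' with a 1 mm floor so voxelized walls stay watertight at clinical voxel
#' sizes.
#'
#' @param depth number of generations (>= 1); the tree has `2^depth - 1`
#'   branches.
#' @param root_radius lumen radius of the root branch in mm.
#' @param taper child-to-parent radius (and length) ratio in (0, 1].
#' @param branch_length root branch length in mm.
#' @param angle half branching angle in degrees.
#' @param wall_fraction wall thickness as a fraction of lumen radius.
#' @param seed integer seed (reserved for optional jitter; the default
#'   geometry is deterministic).
#' @param jitter SD (degrees) of seeded random perturbation of branch angles.
#' @return A `tree_geometry`: data frame with one row per branch (`id`,
#'   `parent`, proximal/distal points in mm, `radius_mm`, `wall_mm`,
#'   `generation`).
#' @export
build_tree_spec <- function(depth, root_radius = 4, taper = 0.8,
                            branch_length = 18, angle = 35,
                            wall_fraction = 0.3, seed = 1L, jitter = 0) {
  if (depth < 1 || depth != round(depth))
    stop("invalid-parameter error: depth must be a positive integer",
         call. = FALSE)
  if (root_radius <= 0 || branch_length <= 0)
    stop("invalid-parameter error: radius and length must be positive",
         call. = FALSE)
  if (taper <= 0 || taper > 1)
    stop("invalid-parameter error: taper must be in (0, 1]", call. = FALSE)
  set.seed(seed)
  rot <- function(v, axis, theta) {      # Rodrigues rotation
    axis <- axis / sqrt(sum(axis^2))
    v * cos(theta) + pracma_cross(axis, v) * sin(theta) +
      axis * sum(axis * v) * (1 - cos(theta))
  }
  rows <- list()
  # stack entries: id, parent, prox, dir, lateral axis, generation
  root_dir <- c(0, 0, -1)
  stack <- list(list(id = 1L, parent = NA_integer_, prox = c(0, 0, 0),
                     dir = root_dir, lat = c(1, 0, 0), gen = 0L))
  next_id <- 2L
  while (length(stack) > 0) {
    b <- stack[[1]]; stack <- stack[-1]
    r <- root_radius * taper^b$gen
    len <- branch_length * taper^b$gen
    dist <- b$prox + b$dir * len
    rows[[b$id]] <- data.frame(
      id = b$id, parent = b$parent,
      px = b$prox[1], py = b$prox[2], pz = b$prox[3],
      dx = dist[1], dy = dist[2], dz = dist[3],
      radius_mm = r, wall_mm = max(wall_fraction * r, 1.0),
      generation = b$gen)
    if (b$gen + 1L < depth) {
      th <- (angle + if (jitter > 0) stats::rnorm(2, 0, jitter) else c(0, 0)) *
        pi / 180
      for (s in 1:2) {
        d2 <- rot(b$dir, b$lat, ifelse(s == 1, th[1], -th[2]))
        lat2 <- rot(b$lat, b$dir, pi / 2)   # roll branching plane 90 deg
        stack[[length(stack) + 1L]] <-
          list(id = next_id, parent = b$id, prox = dist, dir = d2,
               lat = lat2, gen = b$gen + 1L)
        next_id <- next_id + 1L
      }
    }
  }
  out <- do.call(rbind, rows)
  validate_tree(out)
  structure(out, class = c("tree_geometry", "data.frame"))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

validate_tree <- function(tree) {
  if (sum(is.na(tree$parent)) != 1)
    stop("tree must have exactly one root", call. = FALSE)
  if (any(tree$radius_mm <= 0) || any(tree$wall_mm <= 0))
    stop("radii and wall thickness must be positive", call. = FALSE)
  kid <- tree[!is.na(tree$parent), ]
  if (nrow(kid) > 0) {
    pr <- tree$radius_mm[match(kid$parent, tree$id)]
    if (any(kid$radius_mm > pr + 1e-9))
      stop("child radius exceeds parent radius", call. = FALSE)
  }
  invisible(TRUE)
}

#' Phantom acquisition specification
#'
#' HU levels default to physiologic values that straddle the -950 HU
#' emphysema threshold: lumen air -1000, wall soft tissue 0, normal
#' parenchyma -870, emphysema -980, body (non-lung) tissue +40.
#'
#' @param shape grid size in voxels (length 3).
#' @param spacing voxel spacing in mm.
#' @param hu_lumen,hu_wall,hu_parenchyma,hu_emphysema,hu_body HU levels.
#' @param emph_fraction fraction of parenchyma voxels set to emphysema HU.
#' @param blur_sigma_mm Gaussian point-spread SD in mm (applied to the CT
#'   volume only; truth masks stay crisp).
#' @param noise_sd_hu additive Gaussian noise SD in HU (after blur).
#' @param seed integer seed for emphysema placement and noise.
#' @param emph_clustered place emphysema as clustered blobs instead of
#'   independent voxels (the voxel count is exact either way).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(192, 192, 192), spacing = c(0.5, 0.5, 0.5),
                         hu_lumen = -1000, hu_wall = 0, hu_parenchyma = -870,
                         hu_emphysema = -980, hu_body = 40,
                         emph_fraction = 0, blur_sigma_mm = 0.6,
                         noise_sd_hu = 0, seed = 1L, emph_clustered = FALSE) {
  if (!(hu_lumen < -950 && hu_parenchyma > -950))
    stop("lumen HU must be < -950 < parenchyma HU", call. = FALSE)
  if (hu_wall <= -500) stop("wall HU must be > -500", call. = FALSE)
  if (hu_emphysema >= -950) stop("emphysema HU must be < -950", call. = FALSE)
  if (emph_fraction < 0 || emph_fraction > 1)
    stop("emphysema fraction must be in [0, 1]", call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 hu_lumen = hu_lumen, hu_wall = hu_wall,
                 hu_parenchyma = hu_parenchyma, hu_emphysema = hu_emphysema,
                 hu_body = hu_body, emph_fraction = emph_fraction,
                 blur_sigma_mm = blur_sigma_mm, noise_sd_hu = noise_sd_hu,
                 seed = as.integer(seed), emph_clustered = emph_clustered),
            class = "phantom_spec")
}

# distance-to-segment paint of one cylinder into logical array `m`
paint_cylinder <- function(m, spacing, p, q, radius) {
  dm <- dim(m)
  lo <- pmax(floor(pmin(p, q) / spacing - radius / spacing - 1) + 1, 1)
  hi <- pmin(ceiling(pmax(p, q) / spacing + radius / spacing + 1) + 1, dm)
  if (any(lo > hi)) return(m)
  xs <- (seq(lo[1], hi[1]) - 1) * spacing[1]
  ys <- (seq(lo[2], hi[2]) - 1) * spacing[2]
  zs <- (seq(lo[3], hi[3]) - 1) * spacing[3]
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  v <- q - p
  L2 <- sum(v^2)
  w <- sweep(g, 2, p)
  t <- as.numeric(w %*% v) / L2
  d2 <- rowSums((w - outer(t, v))^2)
  # flat caps: the analytic truth is the finite cylinder pi r^2 L
  sel <- array(t >= 0 & t <= 1 & d2 <= radius^2, dim = hi - lo + 1)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] | sel
  m
}

tree_world_offset <- function(tree, spec) {
  # place the root proximal point at the top-center of the grid, snapped to
  # a voxel center so the vertical trachea axis is not exactly mirror
  # symmetric between two voxel columns (which would leave a two-voxel-wide
  # skeleton)
  ext <- (spec$shape - 1) * spec$spacing
  c(spec$spacing[1] * round(ext[1] / 2 / spec$spacing[1]),
    spec$spacing[2] * round(ext[2] / 2 / spec$spacing[2]),
    ext[3] - 2 * spec$spacing[3])
}

#' Rasterize a phantom chest CT from a tree geometry
#'
#' Builds a body-filled grid containing two ellipsoidal lungs, paints the
#' airway tree (wall shell then lumen core), seeds exactly
#' `round(emph_fraction * N_parenchyma)` emphysema voxels into the
#' parenchyma, then applies Gaussian blur and noise to the CT volume only.
#' The returned truth masks (lumen, wall, lung = parenchyma incl. emphysema,
#' emphysema, right/left lung) are crisp and mutually disjoint.
#'
#' @param tree a `tree_geometry` from [build_tree_spec()].
#' @param spec a [phantom_spec()].
#' @return A list with `ct` ([ct_volume()]), truth [binary_mask()]s
#'   (`lumen_mask`, `wall_mask`, `lung_mask`, `emph_mask`, `right_mask`,
#'   `left_mask`) and the voxel-exact emphysema count `n_emph`.
#' @export
rasterize_phantom <- function(tree, spec) {
  off <- tree_world_offset(tree, spec)
  ext <- (spec$shape - 1) * spec$spacing
  P <- cbind(tree$px, tree$py, tree$pz)
  Q <- cbind(tree$dx, tree$dy, tree$dz)
  marg <- rep(tree$radius_mm + tree$wall_mm, 2)
  pts <- rbind(sweep(P, 2, off, "+"), sweep(Q, 2, off, "+"))
  # full clearance in x/y and at the caudal end; the root may reach the
  # cranial (top z) face so the trachea surrogate enters the top slices
  bad <- pts[, 1] < marg | pts[, 1] > ext[1] - marg |
    pts[, 2] < marg | pts[, 2] > ext[2] - marg |
    pts[, 3] < marg | pts[, 3] > ext[3] + 1e-9
  if (any(bad))
    stop("geometry error: tree exceeds grid bounds", call. = FALSE)

  dm <- spec$shape
  lumen <- array(FALSE, dm); outer_m <- array(FALSE, dm)
  for (i in seq_len(nrow(tree))) {
    p <- c(tree$px[i], tree$py[i], tree$pz[i]) + off
    q <- c(tree$dx[i], tree$dy[i], tree$dz[i]) + off
    lumen <- paint_cylinder(lumen, spec$spacing, p, q, tree$radius_mm[i])
    outer_m <- paint_cylinder(outer_m, spec$spacing, p, q,
                              tree$radius_mm[i] + tree$wall_mm[i])
  }
  wall <- outer_m & !lumen

  # two ellipsoidal lungs; the large right lung is centred on the airway
  # tree so intrapulmonary branches are surrounded by parenchyma, the
  # smaller left lung sits at high x (patient left, canonical orientation)
  ctr_r <- ext * c(0.50, 0.5, 0.42); ctr_l <- ext * c(0.89, 0.5, 0.45)
  ax_r <- ext * c(0.30, 0.40, 0.40); ax_l <- ext * c(0.07, 0.28, 0.32)
  xs <- (seq_len(dm[1]) - 1) * spec$spacing[1]
  ys <- (seq_len(dm[2]) - 1) * spec$spacing[2]
  zs <- (seq_len(dm[3]) - 1) * spec$spacing[3]
  ell <- function(ctr, ax) {
    dx2 <- ((xs - ctr[1]) / ax[1])^2
    dy2 <- ((ys - ctr[2]) / ax[2])^2
    dz2 <- ((zs - ctr[3]) / ax[3])^2
    outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  }
  right <- ell(ctr_r, ax_r); left <- ell(ctr_l, ax_l)
  lung_all <- (right | left) & !lumen & !wall
  right <- right & lung_all; left <- left & lung_all

  # exact emphysema voxel count inside the parenchyma
  set.seed(spec$seed)
  par_idx <- which(lung_all)
  n_emph <- round(spec$emph_fraction * length(par_idx))
  emph <- array(FALSE, dm)
  if (n_emph > 0) {
    if (spec$emph_clustered) {
      # blobs: take the n_emph parenchyma voxels nearest to seeded centers,
      # so the count stays exact
      centers <- sample(par_idx, max(1L, n_emph %/% 200L))
      d <- rep(Inf, length(par_idx))
      pw <- voxel_to_world(arrayInd(par_idx, dm), spec$spacing)
      cw <- voxel_to_world(arrayInd(centers, dm), spec$spacing)
      for (j in seq_len(nrow(cw)))
        d <- pmin(d, rowSums(sweep(pw, 2, cw[j, ])^2))
      chosen <- par_idx[order(d)[seq_len(n_emph)]]
      emph[chosen] <- TRUE
    } else {
      emph[sample(par_idx, n_emph)] <- TRUE
    }
  }

  vals <- array(spec$hu_body, dm)
  vals[lung_all] <- spec$hu_parenchyma
  vals[emph] <- spec$hu_emphysema
  vals[wall] <- spec$hu_wall
  vals[lumen] <- spec$hu_lumen

  if (spec$blur_sigma_mm > 0)
    vals <- cpp_gaussian_blur(vals, dm, spec$blur_sigma_mm / spec$spacing)
  if (spec$noise_sd_hu > 0)
    vals <- vals + array(stats::rnorm(prod(dm), 0, spec$noise_sd_hu), dm)

  sp <- spec$spacing
  list(ct = ct_volume(vals, sp),
       lumen_mask = binary_mask(lumen, sp),
       wall_mask = binary_mask(wall, sp),
       lung_mask = binary_mask(lung_all, sp),
       emph_mask = binary_mask(emph, sp),
       right_mask = binary_mask(right, sp),
       left_mask = binary_mask(left, sp),
       n_emph = n_emph)
}

#' Analytic ground-truth metrics of a phantom tree
#'
#' Closed-form cylinder-model values: per-branch lumen area `Ai = pi r^2`,
#' wall area percent `WA% = 100 ((r+t)^2 - r^2) / (r+t)^2`, lumen volume
#' `sum(pi r^2 L)` in ml, overall and per root-child subtree.
#'
#' @param tree a `tree_geometry`.
#' @param spec optional [phantom_spec()]; if given, the requested emphysema
#'   fraction is echoed into the truth.
#' @return A list of truth metrics.
#' @export
analytic_truth <- function(tree, spec = NULL) {
  len <- sqrt((tree$dx - tree$px)^2 + (tree$dy - tree$py)^2 +
              (tree$dz - tree$pz)^2)
  vol_mm3 <- pi * tree$radius_mm^2 * len
  ai <- pi * tree$radius_mm^2
  rout <- tree$radius_mm + tree$wall_mm
  wa_pct <- 100 * (rout^2 - tree$radius_mm^2) / rout^2
  root <- tree$id[is.na(tree$parent)]
  kids <- tree$id[!is.na(tree$parent) & tree$parent == root]
  desc <- function(id) {
    out <- id
    repeat {
      more <- tree$id[!is.na(tree$parent) & tree$parent %in% out &
                        !(tree$id %in% out)]
      if (length(more) == 0) break
      out <- c(out, more)
    }
    out
  }
  sub <- lapply(kids, desc)
  subtree_ml <- vapply(sub, function(ids)
    sum(vol_mm3[tree$id %in% ids]) / 1000, 0)
  list(branch_count = nrow(tree),
       lumen_volume_ml = sum(vol_mm3) / 1000,
       subtree_ids = sub,
       subtree_volume_ml = subtree_ml,
       ai_mm2 = ai,
       wa_percent = wa_pct,
       branch_length_mm = len,
       emph_fraction = if (is.null(spec)) NA_real_ else spec$emph_fraction)
}

#' Simulate a COPD cohort table with a known generating model
#'
#' Predictors (CT indices and demographics) are drawn from a multivariate
#' normal with configurable means, SDs and correlation; outcomes are linear
#' combinations of the z-scored predictors (standardized coefficients) plus
#' Gaussian noise.  Defaults emulate the published cohort scale: n = 147
#' males, age 71 +/- 9 yr, LAV% 29 +/- 9, TAC 212 +/- 51, AWV% about
#' 0.52 +/- 0.14 %, outcomes %FEV1 61 +/- 20 and RV/TLC 42 +/- 7 with
#' standardized effects matching the published multivariate models.
#'
#' @param n number of subjects.
#' @param means,sds named numeric vectors of predictor means/SDs.
#' @param corr predictor correlation matrix (positive definite).
#' @param beta named list of outcomes, each a named vector of standardized
#'   coefficients over (a subset of) predictors.
#' @param out_means,out_sds named numeric vectors for the outcomes.
#' @param noise_sd residual SD on the z scale per outcome; `NULL` sets
#'   `sqrt(1 - b' R b)` so outcome z-variance is ~1.
#' @param n_symptomatic if not `NULL`, CAT scores are assigned so exactly
#'   this many subjects have CAT >= 10.
#' @param seed integer seed.
#' @return A `data.frame` with predictors, outcomes, CAT, `symptomatic`,
#'   and GOLD grade.
#' @export
simulate_cohort <- function(n = 147,
                            means = c(awv_percent = 0.52, lav_percent = 29,
                                      wa_percent = 58, tac = 212, age = 71,
                                      bmi = 22, pack_years = 63,
                                      ct_tlv = 5200),
                            sds = c(awv_percent = 0.14, lav_percent = 9,
                                    wa_percent = 5, tac = 51, age = 9,
                                    bmi = 3, pack_years = 35, ct_tlv = 900),
                            corr = default_predictor_corr(),
                            beta = list(
                              pct_fev1 = c(lav_percent = -0.50,
                                           wa_percent = -0.26, tac = 0.21,
                                           awv_percent = 0.35),
                              rv_tlc = c(lav_percent = 0.24,
                                         wa_percent = -0.17, tac = -0.17,
                                         awv_percent = -0.28)),
                            out_means = c(pct_fev1 = 61, rv_tlc = 42),
                            out_sds = c(pct_fev1 = 20, rv_tlc = 7),
                            noise_sd = NULL, n_symptomatic = NULL,
                            seed = 1L) {
  if (n < 2) stop("simulation error: n must be >= 2", call. = FALSE)
  vars <- names(means)
  corr <- as.matrix(corr)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("simulation error: correlation matrix not positive semi-definite",
         call. = FALSE)
  if (min(ev) < 1e-10)
    stop("simulation error: singular correlation matrix", call. = FALSE)
  set.seed(seed)
  Z <- MASS::mvrnorm(n, mu = rep(0, length(vars)), Sigma = corr)
  colnames(Z) <- vars
  X <- sweep(sweep(Z, 2, sds[vars], "*"), 2, means[vars], "+")
  out <- as.data.frame(X)
  for (oc in names(beta)) {
    b <- beta[[oc]]
    bz <- Z[, names(b), drop = FALSE] %*% b
    R <- corr[names(b), names(b), drop = FALSE]
    s <- if (is.null(noise_sd)) {
      v <- 1 - as.numeric(t(b) %*% R %*% b)
      sqrt(max(v, 0))
    } else noise_sd
    yz <- as.numeric(bz) + if (s > 0) stats::rnorm(n, 0, s) else 0
    out[[oc]] <- out_means[oc] + out_sds[oc] * yz
  }
  if ("pct_fev1" %in% names(out))
    out$pct_fev1 <- pmax(out$pct_fev1, 10)   # keep spirometry physiologic
  # CAT: latent score loosely anti-correlated with AWV% (or the first
  # predictor when the default CT indices are not simulated)
  anchor <- if ("awv_percent" %in% names(out)) out$awv_percent
  else out[[vars[1]]]
  lat <- -scale(anchor)[, 1] + stats::rnorm(n, 0, 1.2)
  if (is.null(n_symptomatic)) {
    cat_score <- pmin(pmax(round(10 + 6 * lat), 0), 40)
  } else {
    r <- rank(lat, ties.method = "first")
    sym <- r > (n - n_symptomatic)
    cat_score <- integer(n)
    cat_score[sym] <- pmin(10L + round(4 * (lat[sym] - min(lat[sym]))), 40L)
    cat_score[!sym] <- pmax(9L - round(2 * (max(lat[!sym]) - lat[!sym])), 0L)
  }
  out$cat_score <- as.integer(cat_score)
  out$symptomatic <- out$cat_score >= 10
  if ("pct_fev1" %in% names(out))
    out$gold <- vapply(out$pct_fev1, gold_grade, 0L)
  out$subject <- sprintf("S%03d", seq_len(n))
  out[, c("subject", setdiff(names(out), "subject"))]
}

#' Default correlation structure of the simulated predictors
#' @return A positive-definite correlation matrix.
#' @export
default_predictor_corr <- function() {
  v <- c("awv_percent", "lav_percent", "wa_percent", "tac", "age", "bmi",
         "pack_years", "ct_tlv")
  R <- diag(length(v)); dimnames(R) <- list(v, v)
  set_r <- function(a, b, r) { R[a, b] <<- r; R[b, a] <<- r }
  set_r("awv_percent", "lav_percent", -0.24)
  set_r("awv_percent", "tac", 0.55)
  set_r("awv_percent", "wa_percent", -0.15)
  set_r("lav_percent", "tac", -0.35)
  set_r("lav_percent", "wa_percent", 0.20)
  set_r("tac", "wa_percent", -0.20)
  set_r("awv_percent", "ct_tlv", -0.30)
  set_r("lav_percent", "ct_tlv", 0.35)
  set_r("age", "pack_years", 0.15)
  set_r("bmi", "lav_percent", -0.25)
  R
}
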