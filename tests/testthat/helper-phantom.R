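# shared small phantoms, built once per test session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# depth-3 noise/blur-free phantom at 0.75 mm on a 128^3 grid
small_phantom <- function() {
  cached("small_phantom", {
    tree <- build_tree_spec(3)
    spec <- phantom_spec(shape = c(128, 128, 128),
                         spacing = c(0.75, 0.75, 0.75), blur_sigma_mm = 0)
    c(rasterize_phantom(tree, spec), list(tree = tree, spec = spec))
  })
}

# its segmentation + partitioned graph
small_graph <- function() {
  cached("small_graph", {
    ph <- small_phantom()
    seed <- find_trachea_seed(ph$ct)
    aw <- grow_airway_tree(ph$ct, seed)
    g <- prune_spurs(build_branch_graph(skeletonize_mask(aw)))
    r <- auto_lobe_roots(g)
    list(airway = aw, graph = partition_subtrees(g, r[1], r[2]), seed = seed)
  })
}

# single-cylinder phantom (default r = 2 mm, L = 10 mm) at a given spacing
cylinder_phantom <- function(spacing_mm = 0.5, shape = NULL, radius = 2,
                             length = 10, ...) {
  tree <- build_tree_spec(1, root_radius = radius, branch_length = length)
  if (is.null(shape)) shape <- rep(ceiling(48 / spacing_mm), 3)
  spec <- phantom_spec(shape = shape, spacing = rep(spacing_mm, 3),
                       blur_sigma_mm = 0, ...)
  c(rasterize_phantom(tree, spec), list(tree = tree, spec = spec))
}

# logical-array mask helpers -------------------------------------------------

# axis-aligned straight line of n voxels along z in a cube
line_mask <- function(n = 21, pad = 4, spacing = 0.5) {
  dm <- c(2 * pad + 1, 2 * pad + 1, n + 2 * pad)
  m <- array(FALSE, dm)
  m[pad + 1, pad + 1, pad + seq_len(n)] <- TRUE
  binary_mask(m, rep(spacing, 3))
}

# Y-shaped voxel path: stem up z, two arms diverging in x
y_mask <- function(stem = 10, arm = 8, spacing = 0.5) {
  dm <- c(2 * (arm + 3) + 1, 7, stem + arm + 6)
  m <- array(FALSE, dm)
  cx <- (dm[1] + 1) / 2
  m[cx, 4, 3 + seq_len(stem)] <- TRUE
  top <- 3 + stem
  for (i in seq_len(arm)) {
    m[cx + i, 4, top + i] <- TRUE
    m[cx - i, 4, top + i] <- TRUE
  }
  binary_mask(m, rep(spacing, 3))
}

# one-voxel 26-neighbourhood dilation
dilate1 <- function(mask) {
  m <- mask$values; dm <- dim(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- max(1, 1 + dx):min(dm[1], dm[1] + dx)
    tx <- max(1, 1 - dx):min(dm[1], dm[1] - dx)
    sy <- max(1, 1 + dy):min(dm[2], dm[2] + dy)
    ty <- max(1, 1 - dy):min(dm[2], dm[2] - dy)
    sz <- max(1, 1 + dz):min(dm[3], dm[3] + dz)
    tz <- max(1, 1 - dz):min(dm[3], dm[3] - dz)
    out[tx, ty, tz] <- out[tx, ty, tz] | m[sx, sy, sz]
  }
  binary_mask(out, mask$spacing, mask$origin)
}
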