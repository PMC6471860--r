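test_that("mask volume arithmetic: 1000 voxels at 1 mm is 1 ml", {
  m <- array(FALSE, c(20, 20, 20))
  m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(airway_volume_ml(binary_mask(m, c(1, 1, 1))), 1)
})

test_that("subtree volumes are additive and match analytic truth", {
  sg <- small_graph(); ph <- small_phantom()
  awv_r <- airway_volume_ml(sg$airway, sg$graph, "RUL")
  awv_m <- airway_volume_ml(sg$airway, sg$graph, "RMLL")
  awv <- airway_volume_ml(sg$airway, sg$graph, c("RUL", "RMLL"))
  expect_equal(awv_r + awv_m, awv, tolerance = 1e-12)
  truth <- sum(analytic_truth(ph$tree)$subtree_volume_ml)
  expect_lt(abs(awv - truth) / truth, 0.15)
})

test_that("FWHM recovers annulus lumen area within tolerance (r >= 3)", {
  for (r in c(3, 4, 5)) {
    m <- fwhm_measure(synthetic_annulus(r, 2, blur_sigma_mm = 0.6))
    expect_true(m$valid)
    expect_lt(abs(m$ai_mm2 - pi * r^2) / (pi * r^2), 0.10)
    truth_wa <- 100 * ((r + 2)^2 - r^2) / (r + 2)^2
    expect_lt(abs(m$wa_percent - truth_wa), 6)
    expect_gte(m$wa_percent, 0); expect_lt(m$wa_percent, 100)
  }
})

test_that("Ai estimate is monotone in true radius", {
  ai <- vapply(2:5, function(r)
    fwhm_measure(synthetic_annulus(r, 2, blur_sigma_mm = 0.6))$ai_mm2, 0)
  expect_true(all(diff(ai) > 0))
})

test_that("small-lumen underestimation grows as radius approaches the blur", {
  rel_err <- vapply(c(2, 4), function(r) {
    m <- fwhm_measure(synthetic_annulus(r, 2, blur_sigma_mm = 0.6))
    (m$ai_mm2 - pi * r^2) / (pi * r^2)
  }, 0)
  expect_true(all(rel_err < 0))           # always an underestimate
  expect_lt(rel_err[1], rel_err[2])       # worse for the smaller lumen
})

test_that("degenerate sections are rejected", {
  flat <- synthetic_annulus(4, 2, blur_sigma_mm = 0)
  flat$values[] <- -900                              # uniform: no wall peak
  expect_error(fwhm_measure(flat), "quality error")
  bright <- synthetic_annulus(4, 2, blur_sigma_mm = 0)
  bright$values[] <- 40
  expect_error(fwhm_measure(bright), "invalid-center")
})

test_that("cross-sections honour branch extent and measure true areas", {
  ph <- cached("fwhm_phantom", {
    tree <- build_tree_spec(3)
    spec <- phantom_spec(shape = c(160, 160, 160),
                         spacing = c(0.5, 0.5, 0.5), blur_sigma_mm = 0.3)
    ph <- rasterize_phantom(tree, spec)
    aw <- grow_airway_tree(ph$ct, find_trachea_seed(ph$ct))
    g <- prune_spurs(build_branch_graph(skeletonize_mask(aw)))
    r <- auto_lobe_roots(g)
    c(ph, list(graph = partition_subtrees(g, r[1], r[2])))
  })
  g <- ph$graph
  br <- g$branches
  id <- br$id[br$generation == 1][1]
  len <- br$length_mm[br$id == id]
  expect_error(extract_cross_section(ph$ct, g, id, len + 1), "range error")
  expect_error(extract_cross_section(ph$ct, g, 999, 1), "lookup error")
  sec <- extract_cross_section(ph$ct, g, id, 0.5 * len)
  m <- fwhm_measure(sec)
  truth_ai <- pi * (4 * 0.8)^2
  expect_lt(abs(m$ai_mm2 - truth_ai) / truth_ai, 0.10)
})

test_that("path measures average branches and flag failures", {
  ph <- cached("fwhm_phantom", stop("fixture built above"))
  g <- ph$graph
  br <- g$branches
  seg <- br$id[br$generation == 1]
  sub <- br$id[br$generation == 2]
  pm <- measure_paths(ph$ct, g,
                      list(P1 = list(segmental = seg[1],
                                     subsegmental = sub[1]),
                           P2 = list(segmental = seg[2],
                                     subsegmental = sub[2])))
  expect_equal(nrow(pm$paths), 2L)
  expect_equal(pm$mean_ai_mm2, mean(pm$paths$ai_mm2), tolerance = 1e-12)
  # per-generation recovery within 10%
  for (gen in 1:2) {
    truth <- pi * (4 * 0.8^gen)^2
    col <- if (gen == 1) "segmental_ai_mm2" else "subsegmental_ai_mm2"
    expect_lt(max(abs(pm$paths[[col]] - truth)) / truth, 0.10)
  }
  expect_error(measure_paths(ph$ct, g, list(P = list(segmental = 999,
                                                     subsegmental = 999))),
               "lookup error")
})
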