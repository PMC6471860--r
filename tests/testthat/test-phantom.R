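test_that("tree generator produces full binary trees with monotone taper", {
  expect_equal(nrow(build_tree_spec(1)), 1L)
  expect_equal(nrow(build_tree_spec(3)), 7L)
  t2 <- build_tree_spec(2, root_radius = 4, taper = 0.8)
  kids <- t2[!is.na(t2$parent), ]
  expect_equal(kids$radius_mm, c(3.2, 3.2))
  expect_equal(sum(is.na(t2$parent)), 1L)
  # generation bookkeeping
  t4 <- build_tree_spec(4)
  expect_equal(as.vector(table(t4$generation)), c(1, 2, 4, 8))
  pr <- t4$radius_mm[match(t4$parent, t4$id)]
  expect_true(all(t4$radius_mm[!is.na(t4$parent)] <= pr[!is.na(t4$parent)]))
  expect_error(build_tree_spec(0), "invalid-parameter")
  expect_error(build_tree_spec(2, root_radius = -1), "invalid-parameter")
  expect_error(build_tree_spec(2, taper = 1.2), "invalid-parameter")
})

test_that("voxelized cylinder volume approaches the analytic value", {
  ph <- cylinder_phantom(0.5)
  vol <- sum(ph$lumen_mask$values) * 0.5^3
  expect_lt(abs(vol - pi * 4 * 10) / (pi * 4 * 10), 0.10)
  # error strictly decreasing as spacing shrinks
  errs <- vapply(c(1.0, 0.5, 0.25), function(sp) {
    ph <- cylinder_phantom(sp)
    abs(sum(ph$lumen_mask$values) * sp^3 - pi * 4 * 10) / (pi * 4 * 10)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("analytic truth follows the cylinder model", {
  tree <- build_tree_spec(1, root_radius = 2, branch_length = 10)
  tr <- analytic_truth(tree)
  expect_equal(tr$lumen_volume_ml, pi * 4 * 10 / 1000, tolerance = 1e-12)
  expect_equal(tr$ai_mm2, pi * 4, tolerance = 1e-12)
  # wall t = r (sqrt(2) - 1) makes the outer area twice the inner: WA% = 50
  tree$wall_mm <- tree$radius_mm * (sqrt(2) - 1)
  tr <- analytic_truth(tree)
  expect_equal(tr$wa_percent, 50, tolerance = 1e-9)
})

test_that("truth masks are crisp, disjoint, and emphysema count is exact", {
  ph <- small_phantom()
  expect_false(any(ph$lumen_mask$values & ph$wall_mask$values))
  expect_false(any(ph$lumen_mask$values & ph$lung_mask$values))
  expect_false(any(ph$wall_mask$values & ph$lung_mask$values))
  # airway (lumen+wall) remains one 26-connected component
  aw <- ph$lumen_mask$values | ph$wall_mask$values
  lab <- airwayvol:::cpp_label_components(as.logical(aw), dim(aw), 26L)
  expect_equal(max(lab), 1L)
  # fraction 0: no truth-parenchyma voxel below -950 pre-blur
  expect_true(all(ph$ct$values[ph$lung_mask$values] > -950))
  # fraction 0.3: exactly round(0.3 * N) emphysema voxels
  ph2 <- cylinder_phantom(0.75, emph_fraction = 0.3)
  expect_equal(sum(ph2$emph_mask$values),
               round(0.3 * sum(ph2$lung_mask$values | ph2$emph_mask$values)))
  expect_error(
    rasterize_phantom(build_tree_spec(2, branch_length = 100),
                      phantom_spec(shape = c(64, 64, 64))),
    "geometry error")
})

test_that("phantom output is bit-identical for a fixed seed", {
  tree <- build_tree_spec(2)
  spec <- phantom_spec(shape = c(64, 64, 64), spacing = c(1.5, 1.5, 1.5),
                       emph_fraction = 0.2, noise_sd_hu = 20, seed = 7)
  a <- rasterize_phantom(tree, spec)
  b <- rasterize_phantom(tree, spec)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$emph_mask$values, b$emph_mask$values)
})

test_that("simulated cohorts follow the generating linear model", {
  # no noise: refitting the generating model gives R^2 = 1
  d <- simulate_cohort(n = 200, noise_sd = 0, seed = 3)
  f <- lm(pct_fev1 ~ lav_percent + wa_percent + tac + awv_percent, data = d)
  expect_gt(summary(f)$r.squared, 0.999999)
  # all-zero coefficients: null correlation within ~2/sqrt(n)
  d0 <- simulate_cohort(
    n = 10000,
    beta = list(pct_fev1 = c(lav_percent = 0), rv_tlc = c(lav_percent = 0)),
    seed = 11)
  r <- cor(d0$lav_percent, d0$pct_fev1)
  expect_lt(abs(r), 0.05)
  # determinism
  expect_identical(simulate_cohort(n = 50, seed = 9),
                   simulate_cohort(n = 50, seed = 9))
  # singular correlation matrix rejected
  R <- default_predictor_corr()
  R["lav_percent", ] <- R["awv_percent", ]
  R[, "lav_percent"] <- R[, "awv_percent"]
  R["lav_percent", "lav_percent"] <- 1
  expect_error(simulate_cohort(n = 10, corr = R), "simulation error")
  expect_error(simulate_cohort(n = 1), "n must be >= 2")
})

test_that("exact symptomatic counts can be requested", {
  d <- simulate_cohort(n = 147, n_symptomatic = 81, seed = 5)
  expect_equal(sum(d$cat_score >= 10), 81L)
  expect_true(all(d$cat_score >= 0 & d$cat_score <= 40))
})
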