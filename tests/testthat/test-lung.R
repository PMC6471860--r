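test_that("lung segmentation matches truth and excludes the airway", {
  ph <- small_phantom(); sg <- small_graph()
  lungs <- segment_lungs(ph$ct, sg$airway)
  expect_gte(dice(lungs, ph$lung_mask), 0.95)
  expect_false(any(lungs$values & sg$airway$values))
  solid <- ct_volume(array(40, c(32, 32, 32)), c(1, 1, 1))
  expect_error(segment_lungs(solid), "segmentation-failed")
})

test_that("left/right split follows the mid-sagittal convention", {
  ph <- small_phantom(); sg <- small_graph()
  lungs <- segment_lungs(ph$ct, sg$airway)
  lr <- split_left_right(lungs)
  expect_false(lr$fused)
  dm <- dim(lungs$values)
  cx_r <- mean(arrayInd(which(lr$right$values), dm)[, 1])
  cx_l <- mean(arrayInd(which(lr$left$values), dm)[, 1])
  expect_lt(cx_r, cx_l)
  # mirroring the volume swaps the assignment
  mir <- binary_mask(lungs$values[dm[1]:1, , ], lungs$spacing)
  lr2 <- split_left_right(mir)
  expect_equal(sum(lr2$right$values), sum(lr$left$values))
  # right-lung volume recovery within 5%
  truth <- mask_volume_ml(ph$right_mask)
  expect_lt(abs(mask_volume_ml(lr$right) - truth) / truth, 0.05)
})

test_that("LAV% follows the strict -950 threshold", {
  v <- array(-1000, c(10, 10, 10))
  ct <- ct_volume(v, c(1, 1, 1))
  all_mask <- binary_mask(array(TRUE, dim(v)), c(1, 1, 1))
  expect_equal(lav_percent(ct, all_mask), 100)
  ct$values[] <- -940
  expect_equal(lav_percent(ct, all_mask), 0)
  ct$values[] <- -950                       # boundary: strict <
  expect_equal(lav_percent(ct, all_mask), 0)
  expect_error(lav_percent(ct, binary_mask(array(FALSE, dim(v)), c(1, 1, 1))),
               "undefined-measure")
})

test_that("constructed emphysema fraction is recovered exactly", {
  ph <- cached("emph_phantom", cylinder_phantom(0.75, emph_fraction = 0.3))
  region <- binary_mask(ph$lung_mask$values | ph$emph_mask$values,
                        ph$ct$spacing)
  lav <- lav_percent(ph$ct, region)
  expect_equal(lav, 100 * ph$n_emph / sum(region$values), tolerance = 1e-12)
  expect_equal(lav, 30, tolerance = 0.01)
})

test_that("LAV% is monotone in threshold and disease burden", {
  ph <- cached("emph_phantom", stop("built above"))
  region <- binary_mask(ph$lung_mask$values | ph$emph_mask$values,
                        ph$ct$spacing)
  lavs <- vapply(c(-990, -950, -900, -850), function(th)
    lav_percent(ph$ct, region, th), 0)
  expect_true(all(diff(lavs) >= 0))
  ph2 <- cylinder_phantom(0.75, emph_fraction = 0.5)
  region2 <- binary_mask(ph2$lung_mask$values | ph2$emph_mask$values,
                         ph2$ct$spacing)
  expect_gt(lav_percent(ph2$ct, region2), lav_percent(ph$ct, region))
})

test_that("lung volumes add and overlap is rejected", {
  m1 <- array(FALSE, c(20, 20, 20)); m1[1:8, , ] <- TRUE
  m2 <- array(FALSE, c(20, 20, 20)); m2[12:20, , ] <- TRUE
  r <- binary_mask(m1, c(1, 1, 1)); l <- binary_mask(m2, c(1, 1, 1))
  v <- lung_volumes(r, l)
  expect_equal(v$rlv_ml, sum(m1) / 1000)
  expect_equal(v$ct_tlv_ml, v$rlv_ml + v$llv_ml)
  # zero-voxel left mask: CT-TLV = rLV
  v0 <- lung_volumes(r, binary_mask(array(FALSE, c(20, 20, 20)), c(1, 1, 1)))
  expect_equal(v0$ct_tlv_ml, v0$rlv_ml)
  bad <- binary_mask(m1, c(1, 1, 1))
  expect_error(lung_volumes(r, bad), "consistency error")
})
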