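test_that("a solid cylinder thins to a single unbranched path", {
  m <- array(FALSE, c(17, 17, 40))
  for (z in 3:37) m[, , z] <- outer((1:17 - 9)^2, (1:17 - 9)^2, "+") <= 25
  mask <- binary_mask(m, c(0.5, 0.5, 0.5))
  sk <- skeletonize_mask(mask)
  g <- prune_spurs(build_branch_graph(sk))
  expect_equal(nrow(g$branches), 1L)
  expect_equal(sum(g$nodes$degree >= 3), 0L)
  # skeleton voxels form a 26-connected set
  lab <- airwayvol:::cpp_label_components(as.logical(sk$values),
                                          dim(sk$values), 26L)
  expect_equal(max(lab), 1L)
})

test_that("a Y-shaped mask yields three branches around one bifurcation", {
  sk <- skeletonize_mask(y_mask())      # already thin; idempotent input
  g <- prune_spurs(build_branch_graph(sk))
  expect_equal(nrow(g$branches), 3L)
  expect_equal(sum(g$nodes$kind == "bifurcation"), 1L)
  expect_equal(sum(g$nodes$degree <= 1), 3L)   # 2 endpoints + root
  expect_equal(sum(g$nodes$kind == "root"), 1L)
})

test_that("skeletonization of a single voxel is that voxel", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  sk <- skeletonize_mask(binary_mask(m, c(1, 1, 1)))
  expect_identical(sk$values, m)
  expect_error(skeletonize_mask(binary_mask(array(FALSE, c(4, 4, 4)),
                                            c(1, 1, 1))), "empty-input")
})

test_that("a straight 21-voxel path at 0.5 mm is one 10 mm branch", {
  g <- build_branch_graph(line_mask(21, spacing = 0.5))
  expect_equal(nrow(g$branches), 1L)
  expect_equal(g$branches$length_mm, 10, tolerance = 1e-9)
})

test_that("spur pruning removes short twigs, merges chains, is idempotent", {
  # Y with one 2-voxel terminal twig
  m <- line_mask(21, pad = 5, spacing = 0.5)
  v <- m$values
  v[7, 6, 15] <- TRUE; v[8, 6, 16] <- TRUE   # short diagonal twig
  mask <- binary_mask(v, m$spacing)
  g <- build_branch_graph(mask)
  expect_gt(nrow(g$branches), 1L)
  p1 <- prune_spurs(g, 2)
  expect_equal(nrow(p1$branches), 1L)
  # min_length 0 is the identity
  expect_equal(nrow(prune_spurs(g, 0)$branches), nrow(g$branches))
  # idempotence
  p2 <- prune_spurs(p1, 2)
  expect_equal(p2$branches$length_mm, p1$branches$length_mm)
  expect_equal(nrow(p2$branches), nrow(p1$branches))
})

test_that("phantom depth-3 tree recovers exactly 7 branches", {
  g <- small_graph()$graph
  expect_equal(nrow(g$branches), 7L)
  expect_equal(sort(g$branches$generation), c(0, 1, 1, 2, 2, 2, 2))
})

test_that("branch count is invariant to one-voxel mask dilation", {
  sg <- small_graph()
  gd <- prune_spurs(build_branch_graph(skeletonize_mask(dilate1(sg$airway))))
  expect_equal(nrow(gd$branches), nrow(sg$graph$branches))
})

test_that("subtree partition labels descendants and rejects nested roots", {
  g <- small_graph()$graph
  br <- g$branches
  expect_setequal(unique(br$label), c("trachea", "RUL", "RMLL"))
  expect_equal(sum(br$label == "RUL"), 3L)
  expect_equal(sum(br$label == "RMLL"), 3L)
  # conservation: labelled + unlabelled = total
  expect_equal(sum(br$label %in% c("RUL", "RMLL")) +
                 sum(!br$label %in% c("RUL", "RMLL")), nrow(br))
  # nested roots are invalid
  rul <- br$id[br$label == "RUL" & br$generation == 1]
  child <- br$id[br$parent == rul & !is.na(br$parent)][1]
  expect_error(partition_subtrees(g, rul, child), "invalid-partition")
  expect_error(partition_subtrees(g, rul, rul), "invalid-partition")
})

test_that("TAC counts RUL plus RMLL branches only", {
  g <- small_graph()$graph
  expect_equal(total_airway_count(g), 6L)        # 2^3 - 2
  # unpartitioned graph errors
  g2 <- g; g2$branches$label <- "unassigned"
  expect_error(total_airway_count(g2), "missing-labels")
  # empty RUL subtree: count is the RMLL side alone
  g3 <- g; g3$branches$label[g3$branches$label == "RUL"] <- "other"
  expect_equal(total_airway_count(g3), 3L)
})

test_that("disconnected centerlines are reported unless explicitly kept", {
  v <- line_mask(9, pad = 3)$values
  v2 <- array(FALSE, dim(v) + c(0, 0, 14))
  v2[, , 1:dim(v)[3]] <- v
  v2[4, 4, dim(v)[3] + (8:12)] <- TRUE          # second far component
  mask <- binary_mask(v2, c(0.5, 0.5, 0.5))
  expect_error(build_branch_graph(mask), "multiple-components")
  g <- build_branch_graph(mask, largest_only = TRUE)
  expect_equal(nrow(g$branches), 1L)
})
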