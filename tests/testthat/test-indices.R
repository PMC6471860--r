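test_that("AWV% worked examples and scale invariance", {
  expect_equal(awv_percent(18, 2519), 100 * 18 / 2519, tolerance = 1e-12)
  expect_equal(round(awv_percent(18, 2519), 4), 0.7146)
  expect_equal(round(awv_percent(9, 2998), 4), 0.3002)
  expect_lt(awv_percent(9, 2998), awv_percent(18, 2519))
  expect_equal(awv_percent(0, 1000), 0)
  k <- 3.7
  expect_equal(awv_percent(k * 18, k * 2519), awv_percent(18, 2519),
               tolerance = 1e-12)
  expect_error(awv_percent(18, 0), "domain error")
})

test_that("pTLC registry evaluates and swaps equations", {
  expect_equal(predicted_tlc(1.67), 7.99 * 1.67 - 7.08, tolerance = 1e-12)
  expect_equal(round(predicted_tlc(1.67), 3), 6.263)
  expect_error(predicted_tlc(0), "domain error")
  expect_error(predicted_tlc(1.7, equation = "nope"), "config error")
  register_ptlc_equation("flat8", function(h, a) 8)
  expect_equal(predicted_tlc(1.5, equation = "flat8"), 8)
  expect_false(predicted_tlc(1.67) == predicted_tlc(1.67, equation = "flat8"))
})

test_that("size normalizations use the stated unit conventions", {
  m <- normalized_indices(list(awv_ml = 18, rlv_ml = 2519,
                               mean_ai_mm2 = 12.566), ptlc_ml = 6263)
  expect_equal(round(m$awv_ptlc_percent, 4), 0.2874)
  expect_equal(round(m$ai_rlv23_percent, 4), 0.0679)
  # rLV = pTLC gives 100%
  m2 <- normalized_indices(list(awv_ml = 1, rlv_ml = 6263), ptlc_ml = 6263)
  expect_equal(m2$rlv_ptlc_percent, 100)
  # missing Ai: explicit NA, no silent default
  m3 <- normalized_indices(list(awv_ml = 1, rlv_ml = 2000), 6000)
  expect_true(is.na(m3$ai_ptlc23_percent))
  expect_error(normalized_indices(list(awv_ml = 1, rlv_ml = 1), 0),
               "domain error")
})

test_that("GOLD grading follows inclusive lower bounds, monotonically", {
  expect_equal(gold_grade(81), 1L)
  expect_equal(gold_grade(80), 1L)
  expect_equal(gold_grade(50), 2L)
  expect_equal(gold_grade(49.99), 3L)
  expect_equal(gold_grade(30), 3L)
  expect_equal(gold_grade(29), 4L)
  grades <- vapply(seq(5, 120, by = 0.5), gold_grade, 0L)
  expect_true(all(diff(grades) <= 0))
  expect_error(gold_grade(0), "domain error")
})

test_that("symptomatic flag is CAT >= 10 inclusive, range checked", {
  expect_true(symptomatic_flag(10))
  expect_false(symptomatic_flag(9))
  expect_true(symptomatic_flag(40))
  expect_error(symptomatic_flag(41), "domain error")
  expect_error(symptomatic_flag(-1), "domain error")
})

test_that("cohort summary formats means, SDs, and flag percentages", {
  d <- data.frame(x = c(1, 2, 3), flag = c(TRUE, TRUE, FALSE))
  s <- cohort_summary(d)
  expect_equal(s$mean[s$variable == "x"], 2)
  expect_equal(s$sd[s$variable == "x"], 1)
  expect_equal(s$display[s$variable == "flag"], "2 (67%)")
  # the published-table case: 81 of 147 symptomatic reads 55%
  d2 <- data.frame(symptomatic = rep(c(TRUE, FALSE), c(81, 66)))
  expect_equal(cohort_summary(d2)$display, "81 (55%)")
  # single row: SD reported as NA; constant column: SD 0
  expect_true(is.na(cohort_summary(data.frame(x = 1))$sd))
  expect_equal(cohort_summary(data.frame(x = rep(5, 4)))$sd, 0)
  expect_error(cohort_summary(data.frame()), "empty-input")
})
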