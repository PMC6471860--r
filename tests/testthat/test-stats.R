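# brute-force product-moment correlation, the independent oracle
brute_r <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

test_that("pearson_matrix agrees with the brute-force oracle to 1e-12", {
  set.seed(42)
  d <- as.data.frame(matrix(rnorm(60 * 5), 60, 5))
  pm <- pearson_matrix(d, names(d))
  for (k in seq_len(nrow(pm))) {
    expect_equal(pm$r[k], brute_r(d[[pm$var1[k]]], d[[pm$var2[k]]]),
                 tolerance = 1e-12)
  }
})

test_that("exact linear relations give r = +/-1 and degenerates flag", {
  d <- data.frame(x = 1:20)
  d$up <- 2 * d$x + 1
  d$down <- -d$x
  d$flat <- 5
  pm <- pearson_matrix(d, c("x", "up", "down", "flat"))
  get <- function(a, b) pm[pm$var1 == a & pm$var2 == b, ]
  expect_equal(get("x", "up")$r, 1, tolerance = 1e-12)
  expect_equal(get("x", "down")$r, -1, tolerance = 1e-12)
  expect_true(is.na(get("x", "flat")$r))
  expect_equal(get("x", "flat")$flag, "undefined-correlation")
})

test_that("correlation recovery on a simulated cohort", {
  R <- diag(2); R[1, 2] <- R[2, 1] <- 0.5
  dimnames(R) <- list(c("a", "b"), c("a", "b"))
  d <- simulate_cohort(n = 5000, means = c(a = 0, b = 0), sds = c(a = 1, b = 1),
                       corr = R, beta = list(pct_fev1 = c(a = 0)),
                       out_means = c(pct_fev1 = 60),
                       out_sds = c(pct_fev1 = 1), seed = 8)
  pm <- pearson_matrix(d, c("a", "b"))
  expect_lt(abs(pm$r[1] - 0.5), 0.03)
})

test_that("standardized beta equals Pearson r for one predictor", {
  set.seed(1)
  d <- data.frame(x = rnorm(100))
  d$y <- 0.6 * d$x + rnorm(100)
  fit <- fit_standardized_ols(d, "y", "x", covariates = character(0))
  expect_equal(fit$coef$beta, cor(d$x, d$y), tolerance = 1e-12)
  expect_equal(fit$coef$vif, 1)
})

test_that("orthogonal designs have unit VIF; duplicates are singular", {
  # exactly orthogonal +/-1 design
  g <- expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1))
  d <- g[rep(seq_len(8), 10), ]
  set.seed(2)
  d$y <- d$a - d$b + rnorm(80)
  fit <- fit_standardized_ols(d, "y", c("a", "b", "c"),
                              covariates = character(0))
  expect_equal(fit$coef$vif, rep(1, 3), tolerance = 1e-9)
  d$a2 <- d$a
  expect_error(fit_standardized_ols(d, "y", c("a", "a2", "b"),
                                    covariates = character(0)),
               "singular-design")
})

test_that("standardized coefficients rescale to raw coefficients", {
  set.seed(3)
  d <- data.frame(x1 = rnorm(200, 10, 4), x2 = rnorm(200, 0, 2))
  d$y <- 3 + 0.5 * d$x1 - 1.2 * d$x2 + rnorm(200, 0, 2)
  fit <- fit_standardized_ols(d, "y", c("x1", "x2"),
                              covariates = character(0))
  raw <- coef(lm(y ~ x1 + x2, data = d))
  expect_equal(fit$coef$beta[1] * sd(d$y) / sd(d$x1), unname(raw["x1"]),
               tolerance = 1e-9)
  expect_equal(fit$coef$beta[2] * sd(d$y) / sd(d$x2), unname(raw["x2"]),
               tolerance = 1e-9)
})

test_that("VIF matches the car reference on a correlated design", {
  skip_if_not_installed("car")
  d <- simulate_cohort(n = 300, seed = 12)
  fit <- fit_standardized_ols(d, "pct_fev1",
                              c("lav_percent", "wa_percent", "tac",
                                "awv_percent"), covariates = character(0))
  ref <- car::vif(lm(pct_fev1 ~ lav_percent + wa_percent + tac + awv_percent,
                     data = d))
  expect_equal(fit$coef$vif, unname(ref), tolerance = 1e-9)
})

test_that("known standardized coefficients are recovered within 0.05", {
  R <- diag(2); R[1, 2] <- R[2, 1] <- -0.24
  dimnames(R) <- list(c("a", "b"), c("a", "b"))
  d <- simulate_cohort(n = 2000, means = c(a = 0.5, b = 29),
                       sds = c(a = 0.14, b = 9), corr = R,
                       beta = list(y = c(a = 0.35, b = -0.50)),
                       out_means = c(y = 60), out_sds = c(y = 20), seed = 21)
  fit <- fit_standardized_ols(d, "y", c("a", "b"), covariates = character(0))
  expect_lt(abs(fit$coef$beta[fit$coef$term == "a"] - 0.35), 0.05)
  expect_lt(abs(fit$coef$beta[fit$coef$term == "b"] + 0.50), 0.05)
  expect_gt(fit$r_squared, 0.35); expect_lt(fit$r_squared, 0.6)
})

test_that("group comparison handles identical and undersized groups", {
  d <- data.frame(flag = rep(c(TRUE, FALSE), each = 10),
                  v = rep(1:10, 2))
  gc <- group_compare(d, "flag", "v")
  expect_equal(gc$difference, 0)
  expect_gt(gc$p, 0.999)
  d2 <- data.frame(flag = rep(c(TRUE, FALSE), c(1, 10)), v = rnorm(11))
  expect_error(group_compare(d2, "flag", "v"), "insufficient-data")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(4)
  d <- data.frame(gold = rep(c(1, 2), each = 15),
                  awv_percent = c(rnorm(15, 0.6, 0.1), rnorm(15, 0.5, 0.1)))
  an <- anova_across_gold(d, "awv_percent")
  tt <- t.test(awv_percent ~ gold, data = d, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(an$p, tt$p.value, tolerance = 1e-9)
  # strongly separated grades
  d2 <- data.frame(gold = rep(1:4, each = 20),
                   awv_percent = rep(c(0.8, 0.6, 0.4, 0.2), each = 20) +
                     rnorm(80, 0, 0.02))
  expect_lt(anova_across_gold(d2, "awv_percent")$p, 1e-6)
  d3 <- data.frame(gold = rep(1, 10), awv_percent = rnorm(10))
  expect_error(anova_across_gold(d3, "awv_percent"), "insufficient-groups")
})

test_that("null ANOVA p-values are approximately uniform", {
  set.seed(5)
  ps <- replicate(400, {
    d <- data.frame(gold = rep(1:3, each = 12), awv_percent = rnorm(36))
    anova_across_gold(d, "awv_percent")$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
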