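#' Pairwise Pearson correlations with p-values
#'
#' Product-moment correlation for every pair of the requested variables
#' using pairwise complete observations; two-sided p-value from the
#' t-transform with n - 2 degrees of freedom.  Zero-variance variables are
#' flagged (`NA` correlation) rather than erroring.
#'
#' @param table cohort `data.frame`.
#' @param variables column names to correlate.
#' @return A `data.frame` with `var1`, `var2`, `r`, `p`, `n`, `flag`.
#' @export
pearson_matrix <- function(table, variables) {
  stopifnot(all(variables %in% names(table)))
  pairs <- utils::combn(variables, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- table[[pairs[1, k]]]; b <- table[[pairs[2, k]]]
    ok <- is.finite(a) & is.finite(b)
    n <- sum(ok)
    if (n < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      return(data.frame(var1 = pairs[1, k], var2 = pairs[2, k],
                        r = NA_real_, p = NA_real_, n = n,
                        flag = "undefined-correlation",
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
    data.frame(var1 = pairs[1, k], var2 = pairs[2, k],
               r = unname(ct$estimate), p = ct$p.value, n = n, flag = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multiple linear regression with standardized coefficients and VIF
#'
#' Ordinary least squares on the z-scored outcome and independent variables
#' (sample SD, n-1), so the reported coefficients are standardized betas.
#' The variance inflation factor of each independent variable j is
#' `1 / (1 - R2_j)` where `R2_j` comes from regressing variable j on the
#' others.  Complete-case analysis; the case count is reported.
#'
#' @param table cohort `data.frame`.
#' @param outcome outcome column name.
#' @param predictors CT-index predictor column names.
#' @param covariates adjustment covariates (default age, BMI, pack-years and
#'   CT-measured total lung volume).
#' @return A `regression_result`: list with `coef` data frame (`term`,
#'   `beta`, `p`, `vif`, `role`), `r_squared`, `n`, `outcome`.
#' @export
fit_standardized_ols <- function(table, outcome, predictors,
                                 covariates = c("age", "bmi", "pack_years",
                                                "ct_tlv")) {
  covariates <- intersect(covariates, names(table))
  vars <- c(outcome, predictors, covariates)
  stopifnot(all(vars %in% names(table)))
  d <- table[stats::complete.cases(table[vars]), vars, drop = FALSE]
  k <- length(predictors) + length(covariates)
  if (nrow(d) <= k + 2)
    stop("insufficient complete cases (n = ", nrow(d), ") for ", k,
         " parameters", call. = FALSE)
  z <- as.data.frame(lapply(d, function(x) {
    s <- stats::sd(x)
    if (s == 0) x * 0 else (x - mean(x)) / s
  }))
  X <- as.matrix(z[, c(predictors, covariates), drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("singular-design error: perfectly collinear predictors: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  f <- stats::as.formula(paste(outcome, "~",
                               paste(c(predictors, covariates),
                                     collapse = " + ")))
  fit <- stats::lm(f, data = z)
  sm <- summary(fit)
  terms <- c(predictors, covariates)
  vif <- if (length(terms) == 1) stats::setNames(1, terms) else
    vapply(terms, function(v) {
      r2 <- summary(stats::lm(
        stats::as.formula(paste(v, "~",
                                paste(setdiff(terms, v), collapse = " + "))),
        data = z))$r.squared
      1 / (1 - r2)
    }, 0)
  coefs <- sm$coefficients[terms, , drop = FALSE]
  structure(list(
    outcome = outcome,
    coef = data.frame(term = terms, beta = coefs[, 1], p = coefs[, 4],
                      vif = vif,
                      role = ifelse(terms %in% predictors, "predictor",
                                    "covariate"),
                      row.names = NULL, stringsAsFactors = FALSE),
    r_squared = sm$r.squared, n = nrow(d)), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Standardized OLS: %s (n = %d, R2 = %.3f)\n", x$outcome, x$n,
              x$r_squared))
  print(x$coef, digits = 3)
  invisible(x)
}

#' Compare a variable between two groups
#'
#' Group means +/- SD and a two-sided two-sample t-test; Welch by default,
#' pooled-variance optionally.
#'
#' @param table cohort `data.frame`.
#' @param flag logical grouping column name (e.g. `"symptomatic"`).
#' @param variable variable column name.
#' @param var_equal use the pooled-variance t-test.
#' @return List with per-group `n`, `mean`, `sd`, the mean difference and
#'   `p`.
#' @export
group_compare <- function(table, flag, variable, var_equal = FALSE) {
  g <- table[[flag]]; x <- table[[variable]]
  ok <- !is.na(g) & is.finite(x)
  g <- g[ok]; x <- x[ok]
  n1 <- sum(g); n0 <- sum(!g)
  if (min(n1, n0) < 2)
    stop("insufficient-data error: a group has fewer than 2 subjects",
         call. = FALSE)
  tt <- stats::t.test(x[g], x[!g], var.equal = var_equal)
  list(group = c("TRUE", "FALSE"), n = c(n1, n0),
       mean = c(mean(x[g]), mean(x[!g])),
       sd = c(stats::sd(x[g]), stats::sd(x[!g])),
       difference = mean(x[g]) - mean(x[!g]),
       p = tt$p.value, welch = !var_equal)
}

#' One-way ANOVA of a variable across GOLD grades
#'
#' Fixed-effects one-way ANOVA (equal-variance F test).
#'
#' @param table cohort `data.frame` with a grade column.
#' @param variable variable column name.
#' @param grade_col grade column name (default `"gold"`).
#' @return List with per-grade `n`/`mean`/`sd`, `F`, `df`, `p`.
#' @export
anova_across_gold <- function(table, variable, grade_col = "gold") {
  g <- factor(table[[grade_col]])
  x <- table[[variable]]
  ok <- !is.na(g) & is.finite(x)
  g <- droplevels(g[ok]); x <- x[ok]
  sizes <- table(g)
  if (sum(sizes >= 2) < 2)
    stop("insufficient-groups error: need >= 2 grades with >= 2 subjects",
         call. = FALSE)
  fit <- stats::aov(x ~ g)
  an <- summary(fit)[[1]]
  list(grades = names(sizes), n = as.integer(sizes),
       mean = as.numeric(tapply(x, g, mean)),
       sd = as.numeric(tapply(x, g, stats::sd)),
       F = an[["F value"]][1], df = an[["Df"]],
       p = an[["Pr(>F)"]][1])
}
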