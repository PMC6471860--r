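# registry of predicted-TLC reference equations (male; the analysis cohort
# convention).  Inputs: height in m, age in yr; output litres.
.ptlc_registry <- new.env(parent = emptyenv())

#' Register a predicted-TLC reference equation
#'
#' @param id short equation id.
#' @param fun `function(height_m, age_yr)` returning litres.
#' @export
register_ptlc_equation <- function(id, fun) {
  stopifnot(is.function(fun))
  assign(id, fun, .ptlc_registry)
  invisible(id)
}

#' Predicted total lung capacity (pTLC)
#'
#' Evaluates a registered male reference equation; the default is the ECSC
#' male equation `7.99 * height(m) - 7.08` litres.  Equations are swappable
#' via [register_ptlc_equation()] without code changes.
#'
#' @param height_m standing height in metres (> 0).
#' @param age_yr age in years (available to equations that use it).
#' @param equation registered equation id.
#' @return pTLC in litres.
#' @export
predicted_tlc <- function(height_m, age_yr = NA_real_,
                          equation = "ecsc_male") {
  if (!is.finite(height_m) || height_m <= 0)
    stop("domain error: height must be positive", call. = FALSE)
  fun <- mget(equation, .ptlc_registry,
              ifnotfound = list(NULL))[[1]]
  if (is.null(fun))
    stop("config error: unregistered pTLC equation '", equation, "'",
         call. = FALSE)
  fun(height_m, age_yr)
}

register_default_equations <- function() {
  register_ptlc_equation("ecsc_male",
                         function(height_m, age_yr) 7.99 * height_m - 7.08)
}

#' Airway volume percent (AWV%)
#'
#' `AWV% = 100 * AWV / rLV`, the ratio of the right-lung airway-tree volume
#' to the right lung volume.
#'
#' @param awv_ml airway tree volume (RUL + RMLL), ml.
#' @param rlv_ml right lung volume, ml.
#' @return AWV% in percent.
#' @export
awv_percent <- function(awv_ml, rlv_ml) {
  if (any(!is.finite(rlv_ml)) || any(rlv_ml <= 0))
    stop("domain error: rLV must be positive", call. = FALSE)
  if (any(awv_ml < 0)) stop("domain error: AWV must be >= 0", call. = FALSE)
  100 * awv_ml / rlv_ml
}

#' Size-normalized airway and lung indices
#'
#' Fills `AWV/pTLC`, `rLV/pTLC` (ratios of ml over ml, x100) and
#' `Ai/(pTLC)^(2/3)`, `Ai/(rLV)^(2/3)` where volumes are converted to mm3
#' before the 2/3 exponent so the ratio is dimensionless, x100.
#'
#' @param metrics named list with at least `awv_ml`, `rlv_ml`; optionally
#'   `mean_ai_mm2`.
#' @param ptlc_ml predicted TLC in ml (> 0).
#' @return The metrics list with normalization fields added (explicit `NA`
#'   where an input is missing).
#' @export
normalized_indices <- function(metrics, ptlc_ml) {
  if (!is.finite(ptlc_ml) || ptlc_ml <= 0)
    stop("domain error: pTLC must be positive", call. = FALSE)
  m <- metrics
  m$ptlc_ml <- ptlc_ml
  m$awv_ptlc_percent <- if (is.null(m$awv_ml)) NA_real_ else
    100 * m$awv_ml / ptlc_ml
  m$rlv_ptlc_percent <- if (is.null(m$rlv_ml)) NA_real_ else
    100 * m$rlv_ml / ptlc_ml
  ai <- m$mean_ai_mm2
  m$ai_ptlc23_percent <- if (is.null(ai) || !is.finite(ai)) NA_real_ else
    100 * ai / (ptlc_ml * 1000)^(2 / 3)
  m$ai_rlv23_percent <- if (is.null(ai) || !is.finite(ai) ||
                              is.null(m$rlv_ml)) NA_real_ else
    100 * ai / (m$rlv_ml * 1000)^(2 / 3)
  m
}

#' GOLD spirometric grade from %FEV1
#'
#' Standard cut-offs with inclusive lower bounds: grade 1 for
#' `%FEV1 >= 80`, 2 for 50-79.99, 3 for 30-49.99, 4 below 30.
#'
#' @param pct_fev1 FEV1 percent predicted (> 0).
#' @return Integer grade 1-4.
#' @export
gold_grade <- function(pct_fev1) {
  if (!is.finite(pct_fev1) || pct_fev1 <= 0)
    stop("domain error: %FEV1 must be positive", call. = FALSE)
  if (pct_fev1 >= 80) 1L else if (pct_fev1 >= 50) 2L
  else if (pct_fev1 >= 30) 3L else 4L
}

#' Symptomatic flag from the CAT score
#'
#' `TRUE` iff CAT >= 10 (the inclusive convention).
#'
#' @param cat_score COPD Assessment Test score, 0-40.
#' @return Logical.
#' @export
symptomatic_flag <- function(cat_score) {
  if (any(!is.finite(cat_score)) || any(cat_score < 0) || any(cat_score > 40))
    stop("domain error: CAT score must be in [0, 40]", call. = FALSE)
  cat_score >= 10
}

#' Cohort summary table (mean +/- SD, n (%) for flags)
#'
#' Numeric variables are summarized as mean and sample SD (n-1 denominator,
#' `NA` SD for a single row); logical variables as count and percent rounded
#' to the nearest integer, formatted as `"n (p%)"`.
#'
#' @param table cohort `data.frame`.
#' @return A `data.frame` with columns `variable`, `mean`, `sd`, `n`,
#'   `display`.
#' @export
cohort_summary <- function(table) {
  if (nrow(table) == 0) stop("empty-input error", call. = FALSE)
  rows <- lapply(names(table), function(v) {
    x <- table[[v]]
    if (is.logical(x)) {
      n1 <- sum(x, na.rm = TRUE)
      pct <- round(100 * n1 / sum(!is.na(x)))
      data.frame(variable = v, mean = NA_real_, sd = NA_real_,
                 n = sum(!is.na(x)),
                 display = sprintf("%d (%d%%)", n1, pct),
                 stringsAsFactors = FALSE)
    } else if (is.numeric(x)) {
      n <- sum(!is.na(x))
      s <- if (n > 1) stats::sd(x, na.rm = TRUE) else NA_real_
      data.frame(variable = v, mean = mean(x, na.rm = TRUE), sd = s, n = n,
                 display = if (is.na(s)) sprintf("%.2f", mean(x, na.rm = TRUE))
                 else sprintf("%.2f ± %.2f", mean(x, na.rm = TRUE), s),
                 stringsAsFactors = FALSE)
    } else NULL
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
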