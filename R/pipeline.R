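#' Pipeline configuration
#'
#' One block per stage; unknown keys are rejected (typo safety).
#'
#' @param seg [seg_params()] block.
#' @param prune_mm spur-pruning threshold for the skeleton graph.
#' @param lav_threshold_hu LAV% threshold.
#' @param lung_threshold_hu lung-segmentation threshold.
#' @param height_m,age_yr subject demographics for pTLC.
#' @param ptlc_equation registered pTLC equation id.
#' @param measure_fwhm run cross-sectional FWHM measurement.
#' @param paths path specification for [measure_paths()], or `"auto"` to
#'   derive generation-2/3 paths per lobe from the graph.
#' @param seed integer seed recorded with the provenance.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seg = seg_params(), prune_mm = 2,
                            lav_threshold_hu = -950,
                            lung_threshold_hu = -320,
                            height_m = 1.67, age_yr = 71,
                            ptlc_equation = "ecsc_male",
                            measure_fwhm = TRUE, paths = "auto",
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

# derive a segmental/sub-segmental path spec per lobe label from generations
auto_paths <- function(graph) {
  br <- graph$branches
  out <- list()
  for (lb in c("RUL", "RMLL")) {
    seg <- br$id[br$label == lb & br$generation == 2]
    sub <- br$id[br$label == lb & br$generation == 3]
    if (length(seg) >= 1) {
      out[[lb]] <- list(segmental = seg[1],
                        subsegmental = if (length(sub)) sub[1] else integer(0))
    }
  }
  out
}

#' Run the full single-subject pipeline on a chest CT
#'
#' Seed finding, airway region growing, skeletonization, branch graph with
#' spur pruning, lobe partition (automatic lobe roots at the main
#' bifurcation), TAC, lung segmentation and left/right split, LAV%, lung
#' volumes, AWV by nearest-branch voxel assignment, AWV%, optional FWHM
#' path measures, and size-normalized indices.  With `out_dir` set, all
#' artifacts (masks, graph, per-stage metrics, provenance) are written.
#'
#' @param ct a [ct_volume()] or path readable by [read_ct()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return A `subject_metrics` list.
#' @export
run_subject <- function(ct, config = pipeline_config(), out_dir = NULL) {
  if (is.character(ct)) ct <- read_ct(ct)
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  seed_vox <- stage("find_trachea_seed", find_trachea_seed(ct))
  airway <- stage("grow_airway_tree",
                  grow_airway_tree(ct, seed_vox, config$seg))
  skel <- stage("skeletonize", skeletonize_mask(airway))
  graph <- stage("branch_graph", build_branch_graph(skel))
  graph <- stage("prune_spurs", prune_spurs(graph, config$prune_mm))
  roots <- stage("lobe_roots", auto_lobe_roots(graph))
  graph <- stage("partition", partition_subtrees(graph, roots[1], roots[2]))
  tac <- stage("tac", total_airway_count(graph))
  lungs <- stage("segment_lungs",
                 segment_lungs(ct, airway, config$lung_threshold_hu))
  lr <- stage("split_left_right", split_left_right(lungs))
  vols <- stage("lung_volumes", lung_volumes(lr$right, lr$left))
  lav_both <- stage("lav", lav_percent(ct, lungs, config$lav_threshold_hu))
  lav_right <- if (!is.null(lr$right))
    lav_percent(ct, lr$right, config$lav_threshold_hu) else NA_real_
  awv <- stage("airway_volume", airway_volume_ml(airway, graph))
  awvp <- awv_percent(awv, vols$rlv_ml)
  pm <- NULL
  if (isTRUE(config$measure_fwhm)) {
    paths <- if (identical(config$paths, "auto")) auto_paths(graph)
    else config$paths
    if (length(paths) > 0)
      pm <- tryCatch(measure_paths(ct, graph, paths),
                     warning = function(w) suppressWarnings(
                       measure_paths(ct, graph, paths)),
                     error = function(e) NULL)
  }
  metrics <- list(
    awv_ml = awv, rlv_ml = vols$rlv_ml, awv_percent = awvp,
    ct_tlv_ml = vols$ct_tlv_ml, lav_percent = lav_both,
    lav_percent_right = lav_right, tac = tac,
    mean_ai_mm2 = if (is.null(pm)) NA_real_ else pm$mean_ai_mm2,
    mean_wa_percent = if (is.null(pm)) NA_real_ else pm$mean_wa_percent,
    accepted_threshold_hu = attr(airway, "accepted_threshold"),
    leakage_rollback = attr(airway, "rollback"))
  ptlc_ml <- 1000 * predicted_tlc(config$height_m, config$age_yr,
                                  config$ptlc_equation)
  metrics <- normalized_indices(metrics, ptlc_ml)
  class(metrics) <- "subject_metrics"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mask(airway, file.path(out_dir, "airway_mask.nii.gz"))
    write_mask(lungs, file.path(out_dir, "lung_mask.nii.gz"))
    write_airway_graph(graph, file.path(out_dir, "airway_graph.json"))
    write_metrics(unclass(metrics), file.path(out_dir, "metrics.json"))
    cfgf <- file.path(out_dir, "config.json")
    jsonlite::write_json(config[!vapply(config, is.function, TRUE)],
                         cfgf, auto_unbox = TRUE, digits = 10, force = TRUE)
    prov <- list(package_version = as.character(
      utils::packageVersion("airwayvol")),
      config_md5 = unname(tools::md5sum(cfgf)),
      seed = config$seed,
      accepted_threshold_hu = attr(airway, "accepted_threshold"))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  metrics
}

#' @export
print.subject_metrics <- function(x, ...) {
  cat(sprintf(paste0("<subject_metrics> AWV %.2f ml | rLV %.0f ml | ",
                     "AWV%% %.3f%% | TAC %d | LAV%% %.1f%%\n"),
              x$awv_ml, x$rlv_ml, x$awv_percent, x$tac, x$lav_percent))
  invisible(x)
}

#' Run the cohort statistics layer over a cohort table
#'
#' Emits the demographic summary, the correlation table of CT indices
#' against lung function, the standardized-beta regression models for
#' %FEV1 and RV/TLC, the symptomatic-group comparison of AWV%, and the
#' ANOVA of AWV% across GOLD grades.  Stages needing more subjects than are
#' available are skipped with a notice.
#'
#' @param table cohort `data.frame` (e.g. from [simulate_cohort()]).
#' @param out_dir optional directory for CSV reports.
#' @param predictors CT-index predictors for the regression models.
#' @param outcomes outcome variables.
#' @return List with `summary`, `correlations`, `models`, `group`, `anova`.
#' @export
run_cohort <- function(table, out_dir = NULL,
                       predictors = c("lav_percent", "wa_percent", "tac",
                                      "awv_percent"),
                       outcomes = c("pct_fev1", "rv_tlc")) {
  if (nrow(table) == 0) stop("empty-input error", call. = FALSE)
  res <- list(summary = cohort_summary(table))
  if (nrow(table) >= 10) {
    corr_vars <- intersect(c(predictors, outcomes), names(table))
    res$correlations <- pearson_matrix(table, corr_vars)
    res$models <- lapply(outcomes, function(oc)
      fit_standardized_ols(table, oc, predictors))
    names(res$models) <- outcomes
    if ("symptomatic" %in% names(table) &&
        min(table(table$symptomatic)) >= 2)
      res$group <- group_compare(table, "symptomatic", "awv_percent")
    if ("gold" %in% names(table))
      res$anova <- tryCatch(anova_across_gold(table, "awv_percent"),
                            error = function(e) NULL)
  } else {
    message("fewer than 10 subjects: statistics stages skipped")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metrics(res$summary, file.path(out_dir, "cohort_summary.csv"),
                  "csv")
    if (!is.null(res$correlations))
      write_metrics(res$correlations,
                    file.path(out_dir, "correlations.csv"), "csv")
    if (!is.null(res$models)) {
      coefs <- do.call(rbind, lapply(names(res$models), function(oc)
        cbind(outcome = oc, res$models[[oc]]$coef,
              r_squared = res$models[[oc]]$r_squared,
              n = res$models[[oc]]$n)))
      write_metrics(coefs, file.path(out_dir, "regression.csv"), "csv")
    }
  }
  res
}
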