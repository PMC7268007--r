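#' Configure an end-to-end pipeline run
#'
#' Validates and bundles everything [run_pipeline()] needs. The cohort
#' source is either a [cohort_spec()] (synthetic cohort) or a directory of
#' per-subject TSV time series written by a previous run.
#'
#' @param cohort A [cohort_spec()], a cohort tibble already in memory, or
#'   the path of a directory written by [write_cohort()].
#' @param costs Proportional costs for the graph stage.
#' @param low,high Band-pass edges (Hz).
#' @param n_components Noise-compartment components regressed out.
#' @param motion_mm,rot_rad,gs_sd,max_outlier_fraction Outlier thresholds.
#' @param alpha Significance level for every corrected decision.
#' @param hdi_cost Cost at which the hub-disruption result is highlighted.
#' @param out_dir Output directory (created on run); `NULL` keeps
#'   everything in memory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(cohort = cohort_spec(),
                       costs = c(0.05, 0.10, 0.15, 0.20),
                       low = 0.008, high = 0.09, n_components = 5,
                       motion_mm = 2, rot_rad = 0.02, gs_sd = 3,
                       max_outlier_fraction = 0.125,
                       alpha = 0.05, hdi_cost = 0.05,
                       out_dir = NULL) {
  if (is.character(cohort) && length(cohort) == 1) {
    cohort <- read_cohort(cohort)
  }
  if (!inherits(cohort, "cohort_spec") && !is.data.frame(cohort)) {
    stop("`cohort` must be a cohort_spec, a cohort tibble, or a directory path",
         call. = FALSE)
  }
  stopifnot(all(costs > 0 & costs <= 1), hdi_cost %in% costs,
            alpha > 0, alpha < 1)
  structure(list(cohort = cohort, costs = costs, low = low, high = high,
                 n_components = n_components, motion_mm = motion_mm,
                 rot_rad = rot_rad, gs_sd = gs_sd,
                 max_outlier_fraction = max_outlier_fraction,
                 alpha = alpha, hdi_cost = hdi_cost, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort synthesis (or use of the supplied cohort),
#' denoising with subject exclusion, per-subject connectivity, edge-wise
#' group statistics (each patient group vs controls, Bonferroni and FDR),
#' efficiency metrics at every cost, patient-vs-control nodal z-scores,
#' the cohort hub-disruption analysis, and metric-score Spearman
#' correlations for any score columns present. Identical configs (same
#' spec seed) give identical results.
#'
#' @param config A [run_config()].
#' @return A `pipeline_run` list: `cohort` (denoised), `edge_stats` (one
#'   table per patient group), `metrics`, `zscores`, `hdi`, `cognition`,
#'   `excluded`, and `manifest` (parameters, seeds, counts). If
#'   `config$out_dir` is set, tables are written there as TSV/JSON via
#'   [export_report()].
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  spec <- config$cohort
  cohort <- if (inherits(spec, "cohort_spec")) simulate_cohort(spec) else spec
  tr <- if (inherits(spec, "cohort_spec")) spec$sampling_interval else
    attr(cohort, "sampling_interval") %||% 2

  den <- denoise_cohort(cohort, sampling_interval = tr,
                        low = config$low, high = config$high,
                        n_components = config$n_components,
                        motion_mm = config$motion_mm, rot_rad = config$rot_rad,
                        gs_sd = config$gs_sd,
                        max_outlier_fraction = config$max_outlier_fraction)
  if (!any(den$group == "control")) stop("no control subjects retained", call. = FALSE)

  den <- cohort_connectivity(den)
  ctrl_z <- den$conn_z[den$group == "control"]
  pat_groups <- setdiff(unique(den$group), "control")
  edge_stats <- purrr::map(rlang::set_names(pat_groups), function(pg) {
    edgewise_welch(den$conn_z[den$group == pg], ctrl_z, alpha = config$alpha)
  })

  metrics <- nodal_metrics(den, costs = config$costs)
  zsc <- nodal_zscores(metrics, alpha = config$alpha)
  hdi_res <- cohort_hdi(metrics, cost = config$hdi_cost)

  score_cols <- intersect(names(den), names(default_score_effects()))
  cognition <- NULL
  if (length(score_cols) > 0) {
    enod_focus <- metrics |>
      dplyr::filter(.data$cost == config$hdi_cost) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(e_glob = .data$e_glob[1], .groups = "drop")
    dat <- dplyr::left_join(den[, c("subject_id", "group", score_cols)],
                            enod_focus, by = "subject_id")
    cognition <- purrr::map_dfr(pat_groups, function(pg) {
      d <- dat[dat$group == pg, ]
      out <- spearman_fc_cognition(d, "e_glob", score_cols, alpha = config$alpha)
      out$group <- pg
      out
    })
  }

  manifest <- list(
    n_subjects = nrow(cohort), n_retained = nrow(den),
    groups = as.list(table(den$group)),
    costs = config$costs, alpha = config$alpha, hdi_cost = config$hdi_cost,
    thresholds = list(motion_mm = config$motion_mm, rot_rad = config$rot_rad,
                      gs_sd = config$gs_sd,
                      max_outlier_fraction = config$max_outlier_fraction),
    bandpass = c(low = config$low, high = config$high),
    n_components = config$n_components,
    seed = if (inherits(spec, "cohort_spec")) spec$seed else NA_integer_,
    n_edges_tested = if (length(edge_stats)) attr(edge_stats[[1]], "k") else 0L
  )
  run <- structure(list(cohort = den, edge_stats = edge_stats,
                        metrics = metrics, zscores = zsc, hdi = hdi_res,
                        cognition = cognition,
                        excluded = attr(den, "excluded"), manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) export_report(run, config$out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d/%d subjects retained; %d edges tested; costs %s\n",
              x$manifest$n_retained, x$manifest$n_subjects,
              x$manifest$n_edges_tested,
              paste(x$manifest$costs, collapse = "/")))
  invisible(x)
}

#' Write a pipeline run's tables to disk
#'
#' Emits, under `out_dir`: the significant-edge lists of each patient
#' group (FWE and FDR separately, with headers even when empty), the full
#' edge tables, the nodal metric and z-score tables, the per-subject HDI
#' table, the subject-exclusion report, cognition correlations if
#' present, and the JSON manifest. Re-export is idempotent.
#'
#' @param run A `pipeline_run` from [run_pipeline()].
#' @param out_dir Output directory (created recursively).
#' @return `out_dir`, invisibly.
#' @export
export_report <- function(run, out_dir) {
  stopifnot(inherits(run, "pipeline_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  for (pg in names(run$edge_stats)) {
    es <- run$edge_stats[[pg]]
    w(es, sprintf("edges_%s_full.tsv", pg))
    w(es[es$reject_bonferroni, ], sprintf("edges_%s_fwe.tsv", pg))
    w(es[es$reject_fdr, ], sprintf("edges_%s_fdr.tsv", pg))
  }
  w(run$metrics, "nodal_metrics.tsv")
  w(run$zscores$subject_z, "nodal_z_subjects.tsv")
  w(run$zscores$group_tests, "nodal_z_group_tests.tsv")
  w(run$hdi$kappa, "hdi_subjects.tsv")
  w(run$hdi$tests, "hdi_tests.tsv")
  w(run$excluded, "exclusion_report.tsv")
  if (!is.null(run$cognition)) w(run$cognition, "cognition_correlations.tsv")
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
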