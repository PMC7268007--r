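#' Write a cohort to a directory of TSV files
#'
#' Emits `nodes.tsv` (the node table), `covariates.tsv` (one row per
#' subject: group, volumes, scores — every non-list column), and per
#' subject `<id>_timeseries.tsv` (T rows x N columns, header = node
#' labels), `<id>_motion.tsv` and `<id>_noise.tsv`.
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @param dir Output directory (created recursively).
#' @param node_table Node table matching the time-series columns.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, node_table = lmn_node_table()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  w(node_table, "nodes.tsv")
  labels <- node_table$label[order(node_table$node_id)]
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    ts <- cohort$timeseries[[i]]
    colnames(ts) <- labels
    w(as.data.frame(ts), paste0(id, "_timeseries.tsv"))
    mot <- cohort$motion[[i]]
    colnames(mot) <- c(paste0("trans_", c("x", "y", "z")),
                       paste0("rot_", c("x", "y", "z")))
    w(as.data.frame(mot), paste0(id, "_motion.tsv"))
    noi <- cohort$noise_signals[[i]]
    colnames(noi) <- paste0("noise_", seq_len(ncol(noi)))
    w(as.data.frame(noi), paste0(id, "_noise.tsv"))
  }
  keep <- !vapply(cohort, is.list, logical(1))
  w(cohort[, keep], "covariates.tsv")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `covariates.tsv` and the per-subject
#'   TSV files.
#' @return A cohort tibble with the same columns as [simulate_cohort()]
#'   (numeric values round-trip through full-precision text).
#' @export
read_cohort <- function(dir) {
  cov_path <- file.path(dir, "covariates.tsv")
  if (!file.exists(cov_path)) stop("no covariates.tsv in ", dir, call. = FALSE)
  covs <- tibble::as_tibble(utils::read.delim(cov_path, check.names = FALSE))
  rd <- function(id, suffix) {
    as.matrix(utils::read.delim(file.path(dir, paste0(id, "_", suffix, ".tsv")),
                                check.names = FALSE))
  }
  covs$timeseries <- purrr::map(covs$subject_id, function(id) {
    m <- rd(id, "timeseries"); dimnames(m) <- NULL; m
  })
  covs$motion <- purrr::map(covs$subject_id, function(id) {
    m <- rd(id, "motion"); dimnames(m) <- NULL; m
  })
  covs$noise_signals <- purrr::map(covs$subject_id, function(id) {
    m <- rd(id, "noise"); dimnames(m) <- NULL; m
  })
  covs
}
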