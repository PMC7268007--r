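#' Pearson connectivity matrix of an ROI time-series
#'
#' @param values T x N matrix (T >= 3, every channel non-constant).
#' @return Symmetric N x N correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 3) stop("need at least 3 time points", call. = FALSE)
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop("constant channel(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(values)
  (r + t(r)) / 2
}

#' Fisher z-transform of correlation values
#'
#' `z = arctanh(r)`; values at exactly +/-1 are clipped to `1 - 1e-7` in
#' magnitude with a warning.
#'
#' @param r Numeric vector or matrix of correlations.
#' @return Transformed values, same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| > 1", call. = FALSE)
  if (any(abs(r) == 1, na.rm = TRUE)) {
    warning("correlations at |r| = 1 clipped to 1 - 1e-7")
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  }
  atanh(r)
}

#' Per-subject connectivity for a whole cohort
#'
#' Computes each subject's Pearson matrix and its Fisher-z transform
#' (diagonal set to `NA`: self-correlations carry no information).
#'
#' @param cohort Cohort tibble with a `timeseries` list-column.
#' @return The cohort tibble with list-columns `conn_r` and `conn_z`.
#' @export
cohort_connectivity <- function(cohort) {
  cohort$conn_r <- purrr::map(cohort$timeseries, pearson_matrix)
  cohort$conn_z <- purrr::map(cohort$conn_r, function(r) {
    diag(r) <- NA_real_
    z <- suppressWarnings(fisher_z(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)))
    z
  })
  cohort
}

upper_edges <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
}

#' Edge-wise Welch two-sample test between two groups of z-matrices
#'
#' Stacks the upper-triangle Fisher-z values of each group and performs,
#' per unordered edge, a Welch two-sample t test (unequal variances,
#' Welch-Satterthwaite degrees of freedom, two-sided p). Edges with zero
#' variance in both groups are flagged `degenerate` and excluded from the
#' multiple-testing count.
#'
#' @param z_a,z_b Lists of N x N z-matrices (group A is conventionally the
#'   patient group: `direction` is the sign of mean(A) - mean(B)).
#' @param alpha Significance level used for the corrected decisions.
#' @param labels Optional length-N node labels.
#' @return Tibble with one row per edge `i < j` (0-based node ids):
#'   `t`, `df`, `p`, `p_bonferroni`, `p_fdr`, `direction`,
#'   `reject_bonferroni`, `reject_fdr`, `degenerate`, and attribute
#'   `k` = number of tests entering the corrections.
#' @export
edgewise_welch <- function(z_a, z_b, alpha = 0.05, labels = NULL) {
  stopifnot(length(z_a) >= 2, length(z_b) >= 2)
  n <- nrow(z_a[[1]])
  idx <- upper_edges(n)
  stack <- function(zl) t(vapply(zl, function(z) z[idx], numeric(nrow(idx))))
  a <- stack(z_a)
  b <- stack(z_b)
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  degenerate <- va == 0 & vb == 0
  tstat[degenerate] <- NA_real_
  df[degenerate] <- NA_real_
  p <- 2 * stats::pt(-abs(tstat), df)
  k <- sum(!degenerate)
  p_bonf <- pmin(1, p * k)
  p_fdr <- rep(NA_real_, length(p))
  p_fdr[!degenerate] <- stats::p.adjust(p[!degenerate], method = "BH")
  out <- tibble::tibble(
    node_i = idx[, "row"] - 1L,
    node_j = idx[, "col"] - 1L,
    t = tstat, df = df, p = p,
    p_bonferroni = p_bonf, p_fdr = p_fdr,
    direction = ifelse(ma - mb >= 0, "increased", "decreased"),
    reject_bonferroni = !degenerate & p < alpha / k,
    reject_fdr = !degenerate & p_fdr < alpha,
    degenerate = degenerate
  )
  if (!is.null(labels)) {
    out$label_i <- labels[out$node_i + 1L]
    out$label_j <- labels[out$node_j + 1L]
  }
  attr(out, "k") <- k
  out
}

#' Adjust p-values for multiple comparisons
#'
#' Bonferroni (family-wise error: reject when `p < alpha / k`) or
#' Benjamini-Hochberg step-up false discovery rate.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method `"bonferroni"` or `"fdr_bh"`.
#' @param alpha Significance level.
#' @param k Number of tests (defaults to `length(p)`).
#' @return Tibble with `p`, `p_adjusted`, `reject`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "fdr_bh"), alpha = 0.05,
                           k = length(p)) {
  method <- match.arg(method)
  if (length(p) == 0) {
    return(tibble::tibble(p = numeric(0), p_adjusted = numeric(0), reject = logical(0)))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (method == "bonferroni") {
    adj <- pmin(1, p * k)
    reject <- p < alpha / k
  } else {
    adj <- stats::p.adjust(p, method = "BH", n = k)
    reject <- adj < alpha
  }
  tibble::tibble(p = p, p_adjusted = adj, reject = reject)
}
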