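#' Mann-Whitney U test (midrank tie handling)
#'
#' `U` counts the pairs `(x_i, y_j)` with `x_i > y_j`, plus one half per
#' tied pair: the statistic for the first sample. The complementary
#' statistic satisfies `U1 + U2 = n1 * n2`. The p-value uses the normal
#' approximation with the tie-corrected variance (two-sided).
#'
#' @param x,y Numeric samples (both non-empty).
#' @param comparison Optional label carried into the result.
#' @return One-row tibble: `comparison`, `U` (= U1), `U2`, `z`, `p`,
#'   `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(2, 3, 4))$U # 2 (one win, two ties)
mann_whitney_u <- function(x, y, comparison = "x vs y") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (v > 0) (u1 - n1 * n2 / 2) / sqrt(v) else 0
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(comparison = comparison, U = u1, U2 = n1 * n2 - u1,
                 z = z, p = min(1, p), n1 = n1, n2 = n2)
}

#' Paired t test on two matched vectors
#'
#' Standard paired t on the differences `x - y` with `n - 1` degrees of
#' freedom; zero-variance differences are a degenerate input and raise an
#' error.
#'
#' @param x,y Equal-length numeric vectors (n >= 2); pairs with a missing
#'   value are dropped.
#' @param comparison Optional label.
#' @return One-row tibble: `comparison`, `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t <- function(x, y, comparison = "x vs y") {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  stopifnot(length(x) >= 2)
  d <- x - y
  if (stats::sd(d) <= sqrt(.Machine$double.eps) * max(1, abs(mean(d)))) {
    stop("zero-variance differences: paired t undefined", call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(comparison = comparison, t = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 mean_diff = unname(ht$estimate), n = length(x))
}

#' Convert a standardized composite index to a z score
#'
#' Composite indices are scaled to mean 100, SD 15; the pathological
#' cutoff of 70 corresponds to z = -2.
#'
#' @param index Numeric index values.
#' @return `(index - 100) / 15`.
#' @export
index_to_z <- function(index) (index - 100) / 15

#' Spearman correlations between nodal metrics and cognitive scores
#'
#' One Spearman rank correlation (midrank ties) per (metric, score) pair,
#' with Bonferroni family-wise correction over all pairs tested. Rows with
#' a missing value in either variable are dropped pairwise; constant
#' inputs are flagged rather than tested.
#'
#' @param data Tibble with one row per subject.
#' @param metric_cols,score_cols Column names of the nodal metrics and the
#'   scores to cross-correlate.
#' @param alpha Level for the corrected decisions.
#' @param n_comparisons Number of tests the correction assumes (defaults
#'   to the number of pairs).
#' @return Tibble: `metric`, `score`, `rho`, `p`, `p_fwe`, `significant`,
#'   `n`, `degenerate`.
#' @export
spearman_fc_cognition <- function(data, metric_cols, score_cols, alpha = 0.05,
                                  n_comparisons = NULL) {
  pairs <- tidyr::expand_grid(metric = metric_cols, score = score_cols)
  if (is.null(n_comparisons)) n_comparisons <- nrow(pairs)
  res <- purrr::pmap_dfr(pairs, function(metric, score) {
    m <- data[[metric]]; s <- data[[score]]
    keep <- !is.na(m) & !is.na(s)
    m <- m[keep]; s <- s[keep]
    if (length(m) < 4 || stats::sd(m) == 0 || stats::sd(s) == 0) {
      return(tibble::tibble(metric = metric, score = score, rho = NA_real_,
                            p = NA_real_, n = length(m), degenerate = TRUE))
    }
    ht <- suppressWarnings(stats::cor.test(m, s, method = "spearman", exact = FALSE))
    tibble::tibble(metric = metric, score = score, rho = unname(ht$estimate),
                   p = ht$p.value, n = length(m), degenerate = FALSE)
  })
  res$p_fwe <- pmin(1, res$p * n_comparisons)
  res$significant <- !is.na(res$p) & res$p < alpha / n_comparisons
  res[, c("metric", "score", "rho", "p", "p_fwe", "significant", "n", "degenerate")]
}

#' Correlation between hippocampal volume and nodal efficiency
#'
#' @param volumes,e_nod Per-subject numeric vectors (>= 4 complete pairs).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return One-row tibble: `r`, `p`, `n`, `method`.
#' @export
volume_enod_correlation <- function(volumes, e_nod, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- !is.na(volumes) & !is.na(e_nod)
  volumes <- volumes[keep]; e_nod <- e_nod[keep]
  if (length(volumes) < 4) stop("need >= 4 complete pairs", call. = FALSE)
  if (stats::sd(volumes) == 0 || stats::sd(e_nod) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ht <- suppressWarnings(stats::cor.test(volumes, e_nod, method = method, exact = FALSE))
  tibble::tibble(r = unname(ht$estimate), p = ht$p.value,
                 n = length(volumes), method = method)
}
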