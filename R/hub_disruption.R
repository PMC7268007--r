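#' Hub disruption index of one subject
#'
#' Ordinary least-squares fit of the node-wise difference
#' `subject - reference` against the reference profile across nodes. The
#' slope is the hub disruption index kappa: kappa near 0 means the
#' subject's nodal profile tracks the reference; kappa < 0 means
#' high-efficiency reference hubs lost efficiency while low-efficiency
#' nodes gained it.
#'
#' @param subject Numeric vector of a subject's nodal metric (one value
#'   per node).
#' @param reference Numeric vector of the reference (control-mean) nodal
#'   metric; must be non-constant, same length >= 3.
#' @return An object of class `hdi_fit` with fields `kappa`, `intercept`,
#'   `r_squared`, and the underlying `lm` fit; supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @export
#' @examples
#' ref <- c(0.2, 0.4, 0.6, 0.8)
#' hdi(0.5 * ref, ref)$kappa # -0.5
hdi <- function(subject, reference) {
  stopifnot(length(subject) == length(reference), length(subject) >= 3)
  if (stats::sd(reference) == 0) stop("reference profile is constant", call. = FALSE)
  fit <- stats::lm(I(subject - reference) ~ reference)
  y <- subject - reference
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    kappa = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (tss > 0) 1 - rss / tss else 1,
    n_nodes = length(subject),
    fit = fit,
    data = tibble::tibble(reference = reference, difference = subject - reference)
  ), class = "hdi_fit")
}

#' @export
print.hdi_fit <- function(x, ...) {
  cat(sprintf("<hdi_fit> kappa = %.4f (intercept %.4f, R^2 %.3f, %d nodes)\n",
              x$kappa, x$intercept, x$r_squared, x$n_nodes))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy hdi_fit
#' @export
tidy.hdi_fit <- function(x, ...) {
  co <- suppressWarnings(summary(x$fit)$coefficients)
  tibble::tibble(term = c("intercept", "kappa"),
                 estimate = c(x$intercept, x$kappa),
                 std.error = unname(co[, "Std. Error"]))
}

#' @method glance hdi_fit
#' @export
glance.hdi_fit <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, intercept = x$intercept,
                 r.squared = x$r_squared, n_nodes = x$n_nodes)
}

#' @method autoplot hdi_fit
#' @export
autoplot.hdi_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$reference, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$kappa,
                         colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "reference nodal efficiency (control mean)",
                  y = "subject - reference",
                  title = sprintf("hub disruption index: kappa = %.3f", object$kappa)) +
    ggplot2::theme_minimal()
}

#' Cohort-level hub disruption analysis
#'
#' Computes the hub disruption index of every subject at one cost:
#' patients against the control-mean nodal profile, controls against the
#' leave-one-out control mean (avoiding self-inclusion bias). Then tests
#' (a) each patient group's kappa against 0 (one-sample t), (b) each
#' patient group against the controls' kappa (Welch t), and (c) the two
#' patient groups against each other.
#'
#' @param metrics Long metric table from [nodal_metrics()].
#' @param cost Which cost layer to analyse (default 0.05).
#' @param metric Metric column (default `"e_nod"`).
#' @param control_group Label of the control group.
#' @return An object of class `hdi_cohort`: list with `kappa` (per-subject
#'   tibble: `subject_id`, `group`, `kappa`, `intercept`, `r_squared`,
#'   `reference`) and `tests` (tibble of group-level comparisons); supports
#'   `tidy()`, `glance()` and `autoplot()`.
#' @export
cohort_hdi <- function(metrics, cost = 0.05, metric = "e_nod",
                       control_group = "control") {
  stopifnot(metric %in% names(metrics))
  layer <- metrics[metrics$cost == cost, c("subject_id", "group", "node_id", metric)]
  names(layer)[4] <- "value"
  wide <- tidyr::pivot_wider(layer, names_from = "node_id", values_from = "value")
  mat <- as.matrix(wide[, -(1:2)])
  rownames(mat) <- wide$subject_id
  grp <- wide$group
  is_ctrl <- grp == control_group
  if (sum(is_ctrl) < 2) stop("need >= 2 controls", call. = FALSE)
  ctrl_mat <- mat[is_ctrl, , drop = FALSE]
  ctrl_mean <- colMeans(ctrl_mat)

  one <- function(i) {
    if (is_ctrl[i]) {
      ref <- colMeans(mat[is_ctrl & rownames(mat) != rownames(mat)[i], , drop = FALSE])
      ref_kind <- "leave_one_out"
    } else {
      ref <- ctrl_mean
      ref_kind <- "control_mean"
    }
    f <- hdi(mat[i, ], ref)
    tibble::tibble(subject_id = rownames(mat)[i], group = grp[i],
                   kappa = f$kappa, intercept = f$intercept,
                   r_squared = f$r_squared, reference = ref_kind)
  }
  kappa_tbl <- purrr::map_dfr(seq_len(nrow(mat)), one)

  tt_row <- function(label, ht) {
    tibble::tibble(comparison = label, statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p = ht$p.value,
                   estimate = unname(ht$estimate[1]) -
                     ifelse(length(ht$estimate) > 1, unname(ht$estimate[2]), 0))
  }
  pat_groups <- setdiff(unique(grp), control_group)
  tests <- purrr::map_dfr(pat_groups, function(pg) {
    kp <- kappa_tbl$kappa[kappa_tbl$group == pg]
    kc <- kappa_tbl$kappa[kappa_tbl$group == control_group]
    dplyr::bind_rows(
      tt_row(paste0(pg, " kappa vs 0"), stats::t.test(kp, mu = 0)),
      tt_row(paste0(pg, " vs control"), stats::t.test(kp, kc))
    )
  })
  if (length(pat_groups) == 2) {
    tests <- dplyr::bind_rows(tests, tt_row(
      paste(pat_groups, collapse = " vs "),
      stats::t.test(kappa_tbl$kappa[kappa_tbl$group == pat_groups[1]],
                    kappa_tbl$kappa[kappa_tbl$group == pat_groups[2]])))
  }
  structure(list(kappa = kappa_tbl, tests = tests, cost = cost, metric = metric),
            class = "hdi_cohort")
}

#' @export
print.hdi_cohort <- function(x, ...) {
  cat(sprintf("<hdi_cohort> %s at cost %.2f; %d subjects\n",
              x$metric, x$cost, nrow(x$kappa)))
  print(x$tests)
  invisible(x)
}

#' @method tidy hdi_cohort
#' @export
tidy.hdi_cohort <- function(x, ...) x$kappa

#' @method glance hdi_cohort
#' @export
glance.hdi_cohort <- function(x, ...) {
  x$kappa |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_kappa = mean(.data$kappa), sd_kappa = stats::sd(.data$kappa),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(cost = x$cost, metric = x$metric)
}

#' @method autoplot hdi_cohort
#' @export
autoplot.hdi_cohort <- function(object, ...) {
  ggplot2::ggplot(object$kappa, ggplot2::aes(x = .data$group, y = .data$kappa)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(y = expression(kappa),
                  title = sprintf("hub disruption index at cost %.0f%%", 100 * object$cost)) +
    ggplot2::theme_minimal()
}
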