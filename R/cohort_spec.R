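#' Specify a synthetic resting-state cohort
#'
#' Bundles every parameter of the synthetic BOLD cohort generator. The
#' defaults reproduce the acquisition and group structure the downstream
#' analysis assumes: 48 controls, 19 left-focus and 18 right-focus patients,
#' 400 volumes per subject at a 2-second sampling interval over a 72-node
#' homotopic network, with patient groups carrying a hyperconnected limbic
#' block and hypoconnected remote cortical nodes, hippocampal volumes
#' negatively tied to the planted limbic connectivity on the focus side, and
#' cognitive scores monotonically tied to the planted effects.
#'
#' @param group_sizes Named integer vector with entries `control`,
#'   `L_patient`, `R_patient` (each >= 2).
#' @param n_volumes Number of time points per subject.
#' @param sampling_interval Sampling interval (TR) in seconds.
#' @param node_table Node table, see [lmn_node_table()].
#' @param baseline_covariance Baseline N x N correlation template shared by
#'   all groups; defaults to [baseline_covariance()] on `node_table`.
#' @param delta_limbic Additive hyperconnectivity planted on within-limbic
#'   edges in patient groups (correlation units).
#' @param delta_remote Subtractive effect planted on remote-cortical edges
#'   in patient groups (correlation units).
#' @param noise_sd Standard deviation of white observation noise added to
#'   each channel (signal channels have unit marginal variance).
#' @param drift_amplitude Amplitude of slow sinusoidal drifts (< 0.008 Hz).
#' @param nuisance_amplitude Amplitude with which the noise-compartment
#'   channels leak into the ROI channels.
#' @param spike_rate Expected fraction of volumes hit by a motion/intensity
#'   artifact (step displacement with a matched motion jump); in [0, 0.5).
#' @param volume_effect Slope (cm^3 per correlation unit) linking each
#'   patient's planted limbic connectivity strength to the hippocampal
#'   volume on the focus side; negative by default so stronger planted
#'   limbic connectivity goes with a smaller (more sclerotic) hippocampus.
#' @param score_effects Named list of planted score definitions, see
#'   [default_score_effects()].
#' @param seed Integer seed; the whole cohort is reproducible from it.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(group_sizes = c(control = 48L, L_patient = 19L, R_patient = 18L),
                        n_volumes = 400L,
                        sampling_interval = 2,
                        node_table = lmn_node_table(),
                        baseline_covariance = NULL,
                        delta_limbic = 0.2,
                        delta_remote = 0.08,
                        noise_sd = 0.4,
                        drift_amplitude = 0.6,
                        nuisance_amplitude = 0.3,
                        spike_rate = 0.02,
                        volume_effect = -6,
                        score_effects = default_score_effects(),
                        seed = 1L) {
  validate_node_table(node_table)
  need <- c("control", "L_patient", "R_patient")
  if (!all(need %in% names(group_sizes))) {
    stop("`group_sizes` needs entries control, L_patient, R_patient", call. = FALSE)
  }
  if (any(group_sizes < 2L)) stop("every group needs >= 2 subjects", call. = FALSE)
  if (spike_rate < 0 || spike_rate >= 0.5) stop("`spike_rate` must lie in [0, 0.5)", call. = FALSE)
  if (n_volumes < 2L) stop("`n_volumes` must be >= 2", call. = FALSE)
  if (is.null(baseline_covariance)) {
    baseline_covariance <- baseline_covariance(node_table)
  }
  n <- nrow(node_table)
  stopifnot(identical(dim(baseline_covariance), c(n, n)))
  if (max(abs(baseline_covariance - t(baseline_covariance))) > 1e-10) {
    stop("baseline covariance must be symmetric", call. = FALSE)
  }
  if (min(eigen(baseline_covariance, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("baseline covariance must be positive definite", call. = FALSE)
  }
  structure(list(
    group_sizes = vapply(group_sizes[need], as.integer, integer(1)),
    n_volumes = as.integer(n_volumes),
    sampling_interval = sampling_interval,
    node_table = node_table,
    baseline_covariance = baseline_covariance,
    delta_limbic = delta_limbic,
    delta_remote = delta_remote,
    noise_sd = noise_sd,
    drift_amplitude = drift_amplitude,
    nuisance_amplitude = nuisance_amplitude,
    spike_rate = spike_rate,
    volume_effect = volume_effect,
    score_effects = score_effects,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>",
      sprintf("  groups: %s", paste(names(x$group_sizes), x$group_sizes,
                                    sep = "=", collapse = ", ")),
      sprintf("  T = %d volumes, TR = %gs, N = %d nodes",
              x$n_volumes, x$sampling_interval, nrow(x$node_table)),
      sprintf("  planted effects: delta_limbic=%g, delta_remote=%g, volume_effect=%g",
              x$delta_limbic, x$delta_remote, x$volume_effect),
      sprintf("  noise: sd=%g, drift=%g, nuisance=%g, spike_rate=%g, seed=%d",
              x$noise_sd, x$drift_amplitude, x$nuisance_amplitude,
              x$spike_rate, x$seed),
      sep = "\n")
  invisible(x)
}

#' Default planted cognitive-score effects
#'
#' Each entry defines one standardized score as a linear function of a
#' subject's planted connectivity strength plus Gaussian noise, then
#' standardized across the cohort. Signs differ between patient groups so
#' left-focus patients show negative metric-score correlations and
#' right-focus patients positive ones.
#'
#' @param noise_sd Residual noise standard deviation (planted-strength
#'   signal has SD of order `20 * delta / sqrt(12)`).
#' @return Named list of score definitions (`target` is the region class
#'   whose planted strength drives the score; `effect` gives the per-group
#'   slopes).
#' @export
default_score_effects <- function(noise_sd = 0.5) {
  list(
    AMI = list(target = "limbic",
               effect = c(control = 0, L_patient = -20, R_patient = 10),
               noise_sd = noise_sd),
    phono_fluency = list(target = "remote_cortical",
                         effect = c(control = 0, L_patient = -15, R_patient = 15),
                         noise_sd = noise_sd)
  )
}

#' Baseline correlation template for the synthetic network
#'
#' Block structure by lobe with inflated homotopic-pair correlations and a
#' hub gradient: every off-diagonal entry starts at `base`, same-lobe
#' pairs are raised to `within_lobe`, homotopic partners to `homotopic`,
#' and each entry is then scaled by the geometric mean of the two nodes'
#' hub strengths (a linear gradient over `hub_range` across homotopic
#' pairs, identical for the two members of a pair). The gradient gives the
#' network genuine hubs - nodes whose expected nodal efficiency clearly
#' exceeds that of peripheral nodes - which is the structure the hub
#' disruption index presumes. The result is projected to the nearest
#' positive-definite correlation matrix.
#'
#' @param node_table Node table, see [lmn_node_table()].
#' @param base,within_lobe,homotopic Correlation levels for the three tiers.
#' @param hub_range Length-2 range of the multiplicative hub-strength
#'   gradient across pairs; `c(1, 1)` disables it.
#' @return An N x N positive-definite correlation matrix.
#' @export
baseline_covariance <- function(node_table, base = 0.05, within_lobe = 0.25,
                                homotopic = 0.55, hub_range = c(0.5, 1.5)) {
  nodes <- node_table[order(node_table$node_id), ]
  n <- nrow(nodes)
  s <- matrix(base, n, n)
  same_lobe <- outer(nodes$lobe, nodes$lobe, `==`)
  s[same_lobe] <- within_lobe
  idx <- cbind(seq_len(n), nodes$homotopic_partner + 1L)
  s[idx] <- homotopic
  s[idx[, c(2, 1)]] <- homotopic
  n_pairs <- n %/% 2L
  g_pair <- seq(hub_range[1], hub_range[2], length.out = n_pairs)
  g <- g_pair[nodes$pair_id + 1L]
  s <- s * sqrt(tcrossprod(g))
  s <- pmin(s, 0.95)
  diag(s) <- 1
  nearest_correlation(s)
}

#' Project a symmetric matrix to a positive-definite correlation matrix
#'
#' Eigenvalue clipping at `floor` followed by rescaling to unit diagonal.
#'
#' @param s Symmetric matrix.
#' @param floor Smallest admissible eigenvalue before rescaling.
#' @return Positive-definite matrix with unit diagonal.
#' @export
nearest_correlation <- function(s, floor = 1e-4) {
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  if (any(!is.finite(out))) stop("positive-definite projection failed", call. = FALSE)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  (out + t(out)) / 2
}

#' Group-level target covariance with planted patient effects
#'
#' Controls receive the baseline template unchanged. Patient groups receive
#' the baseline with `delta_limbic` added on every within-limbic edge
#' (ipsilateral to the focus together with the contralateral homotopes,
#' i.e. the full bilateral limbic block) and `delta_remote` subtracted on
#' every remote-cortical edge, then a positive-definite projection
#' (eigenvalue clipping at 1e-4) and rescaling to unit diagonal.
#'
#' @param spec A [cohort_spec()].
#' @param group One of `"control"`, `"L_patient"`, `"R_patient"`.
#' @param effect_scale Multiplier on both planted deltas (used to give
#'   individual patients heterogeneous effect sizes).
#' @return N x N positive-definite correlation matrix.
#' @export
build_group_covariance <- function(spec, group, effect_scale = 1) {
  group <- match.arg(group, c("control", "L_patient", "R_patient"))
  s <- spec$baseline_covariance
  if (group == "control") return(s)
  nodes <- spec$node_table[order(spec$node_table$node_id), ]
  limbic <- nodes$region_class == "limbic"
  remote <- nodes$region_class == "remote_cortical"
  bump <- outer(limbic, limbic) * spec$delta_limbic -
    outer(remote, remote) * spec$delta_remote
  diag(bump) <- 0
  nearest_correlation(s + effect_scale * bump)
}
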