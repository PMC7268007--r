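#' Simulate one subject's resting-state record
#'
#' Draws a T x N ROI time-series from the subject's group covariance and
#' contaminates it, in order, with: low-frequency sinusoidal drifts (below
#' 0.008 Hz), leakage from the noise-compartment channels, white
#' observation noise, and artifact events. Each artifact is a transient
#' single-volume intensity offset of 5 channel-SD with a random sign per
#' channel (it is exactly absorbed by the downstream scrubbing regressor
#' and leaves the global signal quiet) plus a matched persistent jump on
#' one motion channel (3 mm / 0.03 rad), so the interscan outlier rules
#' flag exactly the event volume. Motion channels otherwise follow a
#' small-amplitude random walk. Hippocampal
#' volumes and planted score signals are drawn from the subject's effect
#' scale.
#'
#' @param spec A [cohort_spec()].
#' @param group `"control"`, `"L_patient"` or `"R_patient"`.
#' @param subject_seed Integer seed for this subject; together with the
#'   spec the record is fully reproducible.
#' @return A list with elements `timeseries` (T x N matrix, columns in
#'   node-id order), `motion` (T x 6: translations mm, rotations rad),
#'   `noise_signals` (T x 4 noise-compartment channels), `spike_volumes`
#'   (1-based indices of artifact events), `effect_scale` (planted
#'   per-subject multiplier on the group deltas), `vol_hippo_l`,
#'   `vol_hippo_r` (cm^3), and `target_covariance`.
#' @export
simulate_subject <- function(spec, group, subject_seed) {
  group <- match.arg(group, c("control", "L_patient", "R_patient"))
  tt <- spec$n_volumes
  n <- nrow(spec$node_table)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(subject_seed))

  effect_scale <- if (group == "control") 0 else stats::runif(1, 0.2, 1.8)
  sigma <- build_group_covariance(spec, group, effect_scale)
  ts <- MASS::mvrnorm(tt, mu = rep(0, n), Sigma = sigma)

  # slow drifts strictly below the 0.008 Hz passband edge
  if (spec$drift_amplitude > 0) {
    tsec <- (seq_len(tt) - 1) * spec$sampling_interval
    for (j in seq_len(n)) {
      f <- stats::runif(1, 0.001, 0.007)
      ph <- stats::runif(1, 0, 2 * pi)
      ts[, j] <- ts[, j] + spec$drift_amplitude * sin(2 * pi * f * tsec + ph)
    }
  }

  noise_signals <- matrix(stats::rnorm(tt * 4), tt, 4)
  if (spec$nuisance_amplitude > 0) {
    loadings <- matrix(stats::rnorm(4 * n, sd = 1 / sqrt(4)), 4, n)
    ts <- ts + spec$nuisance_amplitude * (noise_signals %*% loadings)
  }
  if (spec$noise_sd > 0) {
    ts <- ts + matrix(stats::rnorm(tt * n, sd = spec$noise_sd), tt, n)
  }

  motion <- apply(matrix(stats::rnorm(tt * 6, sd = rep(c(0.05, 0.002), each = tt * 3)),
                         tt, 6), 2, cumsum)

  spike_volumes <- integer(0)
  if (spec$spike_rate > 0 && tt > 2) {
    spike_volumes <- which(stats::runif(tt - 1) < spec$spike_rate) + 1L
    ch_sd <- apply(ts, 2, stats::sd)
    for (v in spike_volumes) {
      # transient intensity offset of 5 channel-SD with random per-channel
      # sign (leaves the global signal quiet); the matched motion jump is a
      # persistent step, so the interscan rules flag exactly this volume
      signs <- sample(rep(c(-1, 1), length.out = n)) # balanced: global mean untouched
      ts[v, ] <- ts[v, ] + signs * 5 * ch_sd
      ch <- sample.int(6, 1)
      jump <- if (ch <= 3) 3 else 0.03
      motion[v:tt, ch] <- motion[v:tt, ch] + jump * sample(c(-1, 1), 1)
    }
  }

  base_vol <- 4.3
  vol_l <- base_vol + stats::rnorm(1, sd = 0.2)
  vol_r <- base_vol + stats::rnorm(1, sd = 0.2)
  planted <- spec$volume_effect * effect_scale * spec$delta_limbic
  if (group == "L_patient") vol_l <- vol_l + planted
  if (group == "R_patient") vol_r <- vol_r + planted

  dimnames(ts) <- NULL
  list(timeseries = ts, motion = motion, noise_signals = noise_signals,
       spike_volumes = spike_volumes, effect_scale = effect_scale,
       vol_hippo_l = vol_l, vol_hippo_r = vol_r, target_covariance = sigma)
}

#' Simulate a full synthetic cohort
#'
#' Generates every subject of the three groups under `spec`, then plants
#' the cognitive scores: each score is a per-group linear function of the
#' subject's planted effect strength plus noise, standardized across the
#' cohort. Deterministic given the spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   list-columns `timeseries`, `motion`, `noise_signals`, `spike_volumes`,
#'   plus `effect_scale`, `vol_hippo_l`, `vol_hippo_r`, and one column per
#'   planted score.
#' @export
#' @examples
#' spec <- cohort_spec(group_sizes = c(control = 3, L_patient = 2, R_patient = 2),
#'                     n_volumes = 60, seed = 7)
#' cohort <- simulate_cohort(spec)
#' dplyr::count(cohort, group)
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  n_sub <- length(groups)
  subject_seed <- (spec$seed %% 100000L) * 20011L + seq_len(n_sub)

  rows <- purrr::map(seq_len(n_sub), function(i) {
    rec <- simulate_subject(spec, groups[i], subject_seed[i])
    tibble::tibble(
      subject_id = sprintf("S%03d", i),
      group = groups[i],
      timeseries = list(rec$timeseries),
      motion = list(rec$motion),
      noise_signals = list(rec$noise_signals),
      spike_volumes = list(rec$spike_volumes),
      effect_scale = rec$effect_scale,
      vol_hippo_l = rec$vol_hippo_l,
      vol_hippo_r = rec$vol_hippo_r
    )
  })
  cohort <- dplyr::bind_rows(rows)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 777L)
  limbic_strength <- cohort$effect_scale * spec$delta_limbic
  remote_strength <- cohort$effect_scale * spec$delta_remote
  for (score in names(spec$score_effects)) {
    def <- spec$score_effects[[score]]
    strength <- if (identical(def$target, "limbic")) limbic_strength else remote_strength
    slope <- def$effect[cohort$group]
    raw <- slope * strength + stats::rnorm(nrow(cohort), sd = def$noise_sd)
    cohort[[score]] <- as.numeric(scale(raw))
  }
  cohort$limbic_strength <- limbic_strength
  cohort$remote_strength <- remote_strength
  cohort
}

# save/restore the global RNG state so simulators are pure given their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
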