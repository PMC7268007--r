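#' Flag outlier volumes from interscan motion and global-signal change
#'
#' A volume `t` (t >= 2) is flagged when, relative to volume `t - 1`, any
#' translation component moves more than `motion_mm` (default 2 mm), any
#' rotation component more than `rot_rad` (default 0.02 rad), or the global
#' signal changes by more than `gs_sd` standard deviations of all interscan
#' global-signal changes for that subject. The first volume is never
#' flagged by the interscan rule.
#'
#' @param motion T x 6 matrix (3 translations in mm, 3 rotations in rad).
#' @param global_signal Length-T vector; typically the mean across ROI
#'   channels per volume (see [denoise_cohort()]).
#' @param motion_mm,rot_rad,gs_sd Thresholds.
#' @return Logical vector of length T.
#' @export
detect_outlier_volumes <- function(motion, global_signal,
                                   motion_mm = 2, rot_rad = 0.02, gs_sd = 3) {
  motion <- as.matrix(motion)
  tt <- nrow(motion)
  stopifnot(tt >= 2, ncol(motion) == 6, length(global_signal) == tt)
  dmot <- abs(diff(motion))
  motion_flag <- apply(dmot[, 1:3, drop = FALSE] > motion_mm, 1, any) |
    apply(dmot[, 4:6, drop = FALSE] > rot_rad, 1, any)
  dgs <- diff(global_signal)
  s <- stats::sd(dgs)
  if (!is.finite(s) || s == 0) {
    warning("interscan global-signal change has zero variance: no intensity outliers flagged")
    gs_flag <- rep(FALSE, tt - 1)
  } else {
    gs_flag <- abs(dgs) > gs_sd * s
  }
  c(FALSE, motion_flag | gs_flag)
}

#' Retain subjects whose outlier fraction does not exceed the cutoff
#'
#' A subject is excluded when strictly more than `max_fraction` of its
#' volumes are flagged (default 12.5%); a subject at exactly the cutoff is
#' retained.
#'
#' @param masks Named list of logical outlier masks, one per subject.
#' @param max_fraction Exclusion cutoff on the flagged fraction.
#' @return Tibble with `subject`, `n_outliers`, `fraction`, `retained`.
#' @export
exclude_deviant_subjects <- function(masks, max_fraction = 0.125) {
  stopifnot(length(masks) > 0)
  if (is.null(names(masks))) names(masks) <- paste0("S", seq_along(masks))
  tibble::tibble(
    subject = names(masks),
    n_outliers = vapply(masks, sum, integer(1)),
    fraction = vapply(masks, mean, numeric(1)),
    retained = vapply(masks, mean, numeric(1)) <= max_fraction
  )
}

#' Regress nuisance signals out of ROI time series
#'
#' For each ROI channel, returns the residuals of an ordinary least-squares
#' fit on: the top `n_components` principal components of the
#' noise-compartment channels (component-based noise correction), the six
#' motion parameters, one indicator column per flagged outlier volume
#' (scrubbing), and an intercept. Collinear design columns are dropped
#' (with a message) before fitting, so residuals are exactly orthogonal to
#' every retained regressor.
#'
#' @param values T x N ROI matrix.
#' @param motion T x 6 motion matrix.
#' @param noise_signals T x C noise-compartment matrix.
#' @param outlier_mask Logical length-T vector (default none flagged).
#' @param n_components Number of principal components of `noise_signals`
#'   to keep (capped at C).
#' @return T x N matrix of residuals.
#' @export
regress_confounds <- function(values, motion, noise_signals,
                              outlier_mask = NULL, n_components = 5) {
  values <- as.matrix(values)
  tt <- nrow(values)
  stopifnot(nrow(motion) == tt, nrow(noise_signals) == tt)
  n_components <- min(n_components, ncol(noise_signals))
  pcs <- stats::prcomp(noise_signals, center = TRUE, scale. = FALSE)$x[, seq_len(n_components), drop = FALSE]
  x <- cbind(intercept = 1, as.matrix(motion), pcs)
  if (!is.null(outlier_mask) && any(outlier_mask)) {
    scrub <- diag(tt)[, outlier_mask, drop = FALSE]
    colnames(scrub) <- paste0("outlier_", which(outlier_mask))
    x <- cbind(x, scrub)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    message("dropping collinear confound columns: ", paste(dropped, collapse = ", "))
    x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(x)
  }
  values - x %*% qr.coef(qx, values)
}

#' Zero-phase band-pass filter by discrete-Fourier masking
#'
#' Transforms each channel to the frequency domain, zeroes every bin whose
#' frequency lies outside `[low, high]` (hard cutoffs; the DC bin is
#' removed whenever `low > 0`), and transforms back. Masking the symmetric
#' bin pairs makes the filter zero-phase by construction; bin-aligned
#' passband components are preserved exactly and stopband components
#' removed exactly.
#'
#' @param values T x N matrix (or length-T vector).
#' @param sampling_interval Sampling interval in seconds.
#' @param low,high Passband edges in Hz; requires
#'   `0 <= low < high < 1 / (2 * sampling_interval)` (the Nyquist rate).
#' @return Filtered matrix of the same shape.
#' @export
bandpass <- function(values, sampling_interval, low = 0.008, high = 0.09) {
  vec <- is.null(dim(values))
  values <- as.matrix(values)
  tt <- nrow(values)
  nyquist <- 1 / (2 * sampling_interval)
  if (low < 0 || low >= high) stop("need 0 <= low < high", call. = FALSE)
  if (high >= nyquist) stop("`high` must be below the Nyquist rate ", nyquist, " Hz", call. = FALSE)
  freq <- (seq_len(tt) - 1) / (tt * sampling_interval)
  freq <- pmin(freq, 1 / sampling_interval - freq) # fold to [0, Nyquist]
  keep <- freq >= low & freq <= high
  if (low == 0) keep[1] <- TRUE
  out <- apply(values, 2, function(ch) {
    Re(stats::fft(stats::fft(ch) * keep, inverse = TRUE)) / tt
  })
  out <- matrix(out, tt, ncol(values), dimnames = dimnames(values))
  if (vec) drop(out) else out
}

#' Denoise every subject of a cohort
#'
#' Runs the per-subject pipeline in the fixed order: interscan outlier
#' detection (global signal = mean across ROI channels per volume), then
#' confound regression (noise-compartment components and motion, both
#' band-limited to the analysis band, plus outlier indicators), then
#' zero-phase band-pass filtering of the residuals. Band-limiting the
#' continuous confounds makes regression and filtering commute, so
#' re-running the pipeline on its own output is a no-op for subjects with
#' no flagged volumes.
#' Subjects whose outlier fraction strictly exceeds `max_outlier_fraction`
#' are dropped from the returned cohort.
#'
#' @param cohort Cohort tibble from [simulate_cohort()] (or with the same
#'   list-columns `timeseries`, `motion`, `noise_signals`).
#' @param sampling_interval Sampling interval in seconds.
#' @param low,high Band-pass edges in Hz.
#' @param n_components Noise-compartment components to regress out.
#' @param motion_mm,rot_rad,gs_sd Outlier-detection thresholds.
#' @param max_outlier_fraction Subject exclusion cutoff.
#' @return The cohort tibble with `timeseries` replaced by the cleaned
#'   series and new columns `outlier_mask` (list) and `outlier_fraction`;
#'   excluded subjects are dropped and reported in the
#'   `"excluded"` attribute (an [exclude_deviant_subjects()] table).
#' @export
denoise_cohort <- function(cohort, sampling_interval = 2,
                           low = 0.008, high = 0.09, n_components = 5,
                           motion_mm = 2, rot_rad = 0.02, gs_sd = 3,
                           max_outlier_fraction = 0.125) {
  masks <- purrr::map2(cohort$timeseries, cohort$motion, function(ts, mot) {
    detect_outlier_volumes(mot, rowMeans(ts), motion_mm, rot_rad, gs_sd)
  })
  names(masks) <- cohort$subject_id
  report <- exclude_deviant_subjects(masks, max_outlier_fraction)

  cleaned <- purrr::pmap(
    list(cohort$timeseries, cohort$motion, cohort$noise_signals, masks),
    function(ts, mot, noise, mask) {
      # confounds are restricted to the analysis band before regression so
      # that filtering the residuals cannot reintroduce confound
      # correlation (and the pipeline is idempotent on its own output)
      mot_f <- bandpass(mot, sampling_interval, low, high)
      noise_f <- bandpass(noise, sampling_interval, low, high)
      res <- regress_confounds(ts, mot_f, noise_f, mask, n_components)
      bandpass(res, sampling_interval, low, high)
    }
  )
  out <- cohort
  out$timeseries <- cleaned
  out$outlier_mask <- unname(masks)
  out$outlier_fraction <- report$fraction
  out <- out[report$retained, , drop = FALSE]
  attr(out, "excluded") <- report
  out
}
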