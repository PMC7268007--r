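test_that("outlier rules flag interscan threshold crossings and only those", {
  tt <- 100
  motion <- matrix(0, tt, 6)
  gs <- rep(1, tt)
  expect_warning(mask <- detect_outlier_volumes(motion, gs), "zero variance")
  expect_false(any(mask))

  motion[57:tt, 1] <- 3  # 3 mm x-translation step at volume 57
  set.seed(1)
  gs <- rnorm(tt)
  mask <- detect_outlier_volumes(motion, gs)
  expect_true(mask[57])
  expect_false(mask[1])
  expect_equal(sum(mask[-57]), sum(abs(diff(gs)) > 3 * sd(diff(gs))))

  motion2 <- matrix(0, tt, 6)
  motion2[30, 5] <- 0.03  # transient rotation: flagged at onset and return
  # a linear global signal has constant interscan change (SD = 0): warns
  expect_warning(mask2 <- detect_outlier_volumes(motion2, seq_len(tt)),
                 "zero variance")
  expect_true(all(mask2[c(30, 31)]))
  expect_equal(sum(mask2), 2)
})

test_that("generator artifacts are all detected at close to the planted rate", {
  spec <- cohort_spec(group_sizes = c(control = 2, L_patient = 2, R_patient = 2),
                      n_volumes = 400, spike_rate = 0.05, seed = 31)
  tot <- 0; ntot <- 0; missed <- 0; false_flags <- 0; n_spikes <- 0
  for (i in 1:50) {
    rec <- simulate_subject(spec, "control", 1000 + i)
    mask <- detect_outlier_volumes(rec$motion, rowMeans(rec$timeseries))
    tot <- tot + sum(mask); ntot <- ntot + length(mask)
    missed <- missed + sum(!mask[rec$spike_volumes])
    n_spikes <- n_spikes + length(rec$spike_volumes)
    false_flags <- false_flags + sum(mask[setdiff(seq_len(400), rec$spike_volumes)])
  }
  expect_equal(missed, 0)              # every planted artifact volume flagged
  expect_lt(false_flags / (ntot - n_spikes), 0.01)  # 3-SD rule tail only
  # total fraction within binomial bounds of the model-implied rate
  # (spike_rate on volumes 2..T plus the Gaussian 3-SD tail on clean volumes)
  p_star <- 0.05 * 399 / 400 + (1 - 0.05) * 2 * pnorm(-3)
  half <- 1.96 * sqrt(p_star * (1 - p_star) / ntot)
  expect_gt(tot / ntot, p_star - half)
  expect_lt(tot / ntot, p_star + half)
})

test_that("subject exclusion uses a strict 12.5% rule", {
  mk <- function(k) c(rep(TRUE, k), rep(FALSE, 400 - k))
  rep_tbl <- exclude_deviant_subjects(list(a = mk(50), b = mk(51), c = mk(0)))
  expect_equal(unname(rep_tbl$retained), c(TRUE, FALSE, TRUE))  # 12.5% exactly is retained
  expect_equal(unname(rep_tbl$fraction), c(0.125, 0.1275, 0))
})

test_that("confound regression returns exact least-squares residuals", {
  set.seed(42)
  tt <- 80
  motion <- matrix(rnorm(tt * 6), tt, 6)
  noise <- matrix(rnorm(tt * 4), tt, 4)
  # channel equal to a motion channel is annihilated
  values <- cbind(motion[, 3], rnorm(tt))
  res <- regress_confounds(values, motion, noise)
  expect_lt(max(abs(res[, 1])), 1e-10)
  # orthogonality to every regressor, over random inputs with scrubbing
  for (i in 1:100) {
    vals <- matrix(rnorm(tt * 3), tt, 3)
    mask <- seq_len(tt) %in% sample(tt, 3)
    res <- regress_confounds(vals, motion, noise, outlier_mask = mask)
    pcs <- prcomp(noise)$x[, 1:4]
    x <- cbind(1, motion, pcs, diag(tt)[, mask])
    expect_lt(max(abs(crossprod(x, res))), 1e-8)
  }
  # collinear design columns are dropped with a message
  expect_message(regress_confounds(values, cbind(motion[, 1:5], motion[, 5]), noise),
                 "collinear")
})

test_that("band-pass keeps in-band sinusoids, kills out-of-band, and is zero-phase", {
  tt <- 400; dt <- 2
  tsec <- (seq_len(tt) - 1) * dt
  keep <- sin(2 * pi * 0.05 * tsec + 0.7)
  kill <- sin(2 * pi * 0.2 * tsec + 0.2)
  bk <- bandpass(keep, dt)
  expect_gt(cor(bk, keep), 0.99)
  expect_equal(bk, keep, tolerance = 1e-8)  # bin-aligned passband tone preserved exactly, no phase shift
  expect_lt(sqrt(mean(bandpass(kill, dt)^2)) / sqrt(mean(kill^2)), 0.01)
  expect_equal(bandpass(rep(0, tt), dt), rep(0, tt))
  expect_error(bandpass(keep, dt, low = 0.01, high = 0.3), "Nyquist")
  expect_error(bandpass(keep, dt, low = 0.05, high = 0.01), "low < high")
})

test_that("denoising is idempotent and never increases channel variance", {
  spec <- tiny_spec(spike_rate = 0, seed = 9)
  coh <- simulate_cohort(spec)
  den1 <- denoise_cohort(coh)
  den2 <- denoise_cohort(den1)
  # compare only subjects with no flagged volumes in either pass (the
  # 3-SD intensity rule can tail-flag clean volumes by construction)
  clean <- den1$outlier_fraction == 0 & den2$outlier_fraction == 0
  expect_gt(sum(clean), 0)
  for (i in which(clean)) {
    n1 <- apply(den1$timeseries[[i]], 2, function(x) sqrt(sum(x^2)))
    n2 <- apply(den2$timeseries[[i]], 2, function(x) sqrt(sum(x^2)))
    expect_lt(max(abs(n1 - n2)), 1e-6)
  }
  for (i in seq_len(nrow(den1))) {
    v_before <- apply(coh$timeseries[[i]], 2, var)
    v_after <- apply(den1$timeseries[[i]], 2, var)
    expect_true(all(v_after <= v_before + 1e-12))
  }
})

test_that("denoising clean data leaves correlations unbiased", {
  spec <- cohort_spec(group_sizes = c(control = 3, L_patient = 2, R_patient = 2),
                      n_volumes = 400, noise_sd = 0, drift_amplitude = 0,
                      nuisance_amplitude = 0, spike_rate = 0, seed = 42)
  coh <- simulate_cohort(spec)
  den <- denoise_cohort(coh)
  for (i in 1:3) {
    delta <- cor(den$timeseries[[i]]) - cor(coh$timeseries[[i]])
    expect_lt(abs(mean(delta[upper.tri(delta)])), 0.05)  # no systematic shift
    expect_lt(mean(abs(delta[upper.tri(delta)])), 0.1)   # reduced-dof scatter only
  }
})
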