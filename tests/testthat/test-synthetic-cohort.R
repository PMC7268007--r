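test_that("group covariance builder plants additive effects and stays PD", {
  spec <- tiny_spec()
  # null effects: patient covariance equals control covariance exactly
  spec0 <- tiny_spec(delta_limbic = 0, delta_remote = 0)
  expect_equal(build_group_covariance(spec0, "L_patient"),
               build_group_covariance(spec0, "control"))
  # additive definition on a toy 4-node network before PD projection
  nodes <- lmn_node_table(n_pairs = 2, limbic_pairs = 0:1, remote_pairs = integer(0))
  base <- matrix(0.2, 4, 4); diag(base) <- 1
  toy <- cohort_spec(group_sizes = c(control = 2, L_patient = 2, R_patient = 2),
                     n_volumes = 10, node_table = nodes, baseline_covariance = base,
                     delta_limbic = 0.15, delta_remote = 0, seed = 1)
  target <- base
  target[upper.tri(target)] <- 0.35  # all 4 nodes limbic here
  target[lower.tri(target)] <- 0.35
  # projection is a no-op when the bumped matrix is already PD
  expect_equal(build_group_covariance(toy, "R_patient"), target, tolerance = 1e-8)
  # eigenvalue floor holds over randomized specs
  set.seed(99)
  for (i in 1:100) {
    s <- nearest_correlation(crossprod(matrix(rnorm(16), 4)) / 4 + diag(4) * 0.1)
    sp <- cohort_spec(group_sizes = c(control = 2, L_patient = 2, R_patient = 2),
                      n_volumes = 10, node_table = nodes, baseline_covariance = s,
                      delta_limbic = runif(1, 0, 0.5), delta_remote = runif(1, 0, 0.3),
                      seed = 1)
    ev <- eigen(build_group_covariance(sp, "L_patient"), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), 1e-4 / 2)  # floor before unit-diagonal rescaling
    expect_equal(diag(build_group_covariance(sp, "L_patient")), rep(1, 4))
  }
})

test_that("simulation is bit-reproducible from its seeds", {
  spec <- tiny_spec(seed = 5)
  expect_identical(simulate_subject(spec, "L_patient", 42),
                   simulate_subject(spec, "L_patient", 42))
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
})

test_that("with contamination off, sample correlations converge to the target", {
  spec <- cohort_spec(group_sizes = c(control = 2, L_patient = 2, R_patient = 2),
                      n_volumes = 10000, noise_sd = 0, drift_amplitude = 0,
                      nuisance_amplitude = 0, spike_rate = 0, seed = 8)
  rec <- simulate_subject(spec, "control", 123)
  emp <- cor(rec$timeseries)
  expect_lt(max(abs(emp - spec$baseline_covariance)), 0.05)
})

test_that("patient groups show elevated within-limbic correlation, growing with delta", {
  nodes <- lmn_node_table()
  limbic <- which(nodes$region_class[order(nodes$node_id)] == "limbic")
  mean_limbic <- function(delta, group, seed) {
    spec <- cohort_spec(group_sizes = c(control = 2, L_patient = 2, R_patient = 2),
                        n_volumes = 400, delta_limbic = delta, noise_sd = 0,
                        drift_amplitude = 0, nuisance_amplitude = 0, spike_rate = 0,
                        seed = seed)
    r <- cor(simulate_subject(spec, group, seed * 7L)$timeseries)[limbic, limbic]
    mean(r[upper.tri(r)])
  }
  margins <- sapply(1:8, function(s) {
    c(mean_limbic(0.10, "L_patient", s) - mean_limbic(0, "control", s),
      mean_limbic(0.25, "L_patient", s) - mean_limbic(0, "control", s))
  })
  expect_true(all(margins[2, ] > 0))
  expect_gt(mean(margins[2, ]), mean(margins[1, ]))
})

test_that("negative volume effect yields negative volume-strength correlation", {
  spec <- cohort_spec(seed = 7)  # volume_effect < 0 by default
  recs <- lapply(1:200, function(i) simulate_subject(spec, "L_patient", 5000 + i))
  vols <- vapply(recs, `[[`, numeric(1), "vol_hippo_l")
  strength <- vapply(recs, `[[`, numeric(1), "effect_scale") * spec$delta_limbic
  expect_lt(cor(vols, strength, method = "spearman"), 0)
})

test_that("planted scores track planted strength with per-group signs", {
  spec <- cohort_spec(group_sizes = c(control = 4, L_patient = 20, R_patient = 20),
                      n_volumes = 4, seed = 31)
  coh <- simulate_cohort(spec)
  l <- coh[coh$group == "L_patient", ]
  r <- coh[coh$group == "R_patient", ]
  expect_lt(cor(l$AMI, l$limbic_strength, method = "spearman"), 0)
  expect_gt(cor(r$AMI, r$limbic_strength, method = "spearman"), 0)
  # standardized across the cohort
  expect_equal(mean(coh$AMI), 0, tolerance = 1e-10)
  expect_equal(sd(coh$AMI), 1, tolerance = 1e-10)
})
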