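test_that("proportional thresholding keeps the top weights with deterministic ties", {
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(0.9, 0.1, 0.8, 0.3, 0.2, 0.7)  # (1,2) (1,3) (2,3) (1,4) (2,4) (3,4)
  w <- w + t(w)
  g <- threshold_proportional(w, 1 / 3)  # top 2 of 6
  expect_equal(sum(g$adjacency) / 2, 2)
  expect_true(g$adjacency[1, 2] && g$adjacency[2, 3])
  # cost 1: complete graph
  gc <- threshold_proportional(w, 1)
  expect_true(all(gc$adjacency[upper.tri(gc$adjacency)]))
  # study-size edge count at 10% cost
  set.seed(2)
  w72 <- matrix(rnorm(72^2), 72); w72 <- w72 + t(w72)
  expect_equal(sum(threshold_proportional(w72, 0.10)$adjacency) / 2, 256)
  # ties at the cut: lexicographically earliest edges win
  wt <- matrix(0, 4, 4); wt[upper.tri(wt)] <- c(1, 1, 1, 1, 1, 1); wt <- wt + t(wt)
  gt <- threshold_proportional(wt, 1 / 3)
  expect_true(gt$adjacency[1, 2] && gt$adjacency[1, 3])
  expect_equal(sum(gt$adjacency) / 2, 2)
  expect_warning(threshold_proportional(w, 1e-9), "zero edges")
})

test_that("shortest paths match hand cases and a Floyd-Warshall oracle", {
  path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  d <- shortest_paths(path3)
  expect_equal(d[1, 3], 2)
  two_dyads <- rbind(c(0, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 0, 1), c(0, 0, 1, 0))
  d2 <- shortest_paths(two_dyads)
  expect_true(all(is.infinite(d2[1:2, 3:4])))
  set.seed(7)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n, runif(1, 0.1, 0.7))
    expect_equal(shortest_paths(adj), fw_distances(adj))
  }
})

test_that("efficiency metrics match closed forms", {
  complete5 <- matrix(1, 5, 5); diag(complete5) <- 0
  expect_equal(global_efficiency(complete5), 1)
  el <- local_efficiency(complete5)
  expect_equal(el$network, 1)
  empty <- matrix(0, 4, 4)
  expect_equal(global_efficiency(empty), 0)
  path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(global_efficiency(path3), 5 / 6)
  star4 <- matrix(0, 4, 4); star4[1, 2:4] <- 1; star4 <- star4 + t(star4)
  expect_equal(nodal_efficiency(star4, node = 0), 1)       # hub
  expect_equal(nodal_efficiency(star4, node = 1), 2 / 3)   # leaf
  expect_equal(local_efficiency(star4)$network, 0)
  triangle <- matrix(1, 3, 3); diag(triangle) <- 0
  expect_equal(local_efficiency(triangle)$nodal, rep(1, 3))
  # isolated node has zero nodal efficiency
  iso <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0))
  expect_equal(nodal_efficiency(iso, node = 2), 0)
})

test_that("efficiency metrics equal brute-force oracles on random graphs", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n, runif(1, 0.15, 0.8))
    g <- binary_graph(adj)
    expect_equal(global_efficiency(g), oracle_global_efficiency(adj))
    expect_equal(nodal_efficiency(g), oracle_nodal_efficiency(adj))
    expect_equal(local_efficiency(g)$nodal, oracle_local_efficiency(adj))
  }
})

test_that("thresholded graphs from one weight matrix match oracles at every edge count", {
  set.seed(17)
  for (n in 3:8) {
    w <- matrix(rnorm(n * n), n); w <- w + t(w)
    m_max <- n * (n - 1) / 2
    prev_eglob <- 0
    for (m in 1:m_max) {
      g <- threshold_proportional(w, m / m_max)
      expect_equal(sum(g$adjacency) / 2, m)
      eg <- global_efficiency(g)
      expect_equal(eg, oracle_global_efficiency(g$adjacency))
      expect_equal(mean(nodal_efficiency(g)), eg)
      expect_gte(eg, prev_eglob)  # monotone in cost for nested graphs
      prev_eglob <- eg
    }
  }
})

test_that("adding an edge never decreases global or nodal efficiency", {
  set.seed(19)
  for (i in 1:50) {
    adj <- random_adjacency(8, 0.3)
    off <- which(!adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(off) == 0) next
    pick <- off[sample(nrow(off), 1), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- TRUE
    expect_gte(global_efficiency(adj2), global_efficiency(adj))
    expect_true(all(nodal_efficiency(adj2) >= nodal_efficiency(adj) - 1e-12))
  }
})

test_that("small-world sigma separates lattice-with-shortcuts from random graphs", {
  skip_if_not_installed("igraph")
  ws_sigmas <- sapply(1:10, function(s) {
    set.seed(s)
    g <- igraph::sample_smallworld(1, 100, 3, 0.1)
    small_world_sigma(as.matrix(igraph::as_adjacency_matrix(g)), n_null = 5, seed = s)
  })
  expect_gte(mean(ws_sigmas > 1), 0.95)
  er_sigmas <- sapply(1:5, function(s) {
    set.seed(100 + s)
    g <- igraph::sample_gnp(100, 0.06)
    small_world_sigma(as.matrix(igraph::as_adjacency_matrix(g)), n_null = 5, seed = s)
  })
  expect_lt(abs(mean(er_sigmas) - 1), 0.15)
  # the null rewiring preserves every node's degree
  set.seed(5)
  adj <- random_adjacency(20, 0.3)
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  rw <- igraph::rewire(ig, igraph::keeping_degseq(niter = 200))
  expect_equal(igraph::degree(rw), igraph::degree(ig))
  expect_error(small_world_sigma(matrix(0, 3, 3)), "4 nodes")
})

test_that("nodal z-scores standardize against controls and respect affine invariance", {
  set.seed(23)
  mk_metrics <- function(values_by_subject, groups) {
    purrr::map_dfr(seq_along(values_by_subject), function(i) {
      tibble::tibble(subject_id = sprintf("S%02d", i), group = groups[i],
                     cost = 0.1, node_id = seq_along(values_by_subject[[i]]) - 1L,
                     e_nod = values_by_subject[[i]])
    })
  }
  ctrl_vals <- lapply(1:6, function(i) rnorm(5, mean = 1:5 / 10))
  ctrl_mean <- colMeans(do.call(rbind, ctrl_vals))
  pat_vals <- list(ctrl_mean)  # patient at the control mean: z = 0 everywhere
  m <- mk_metrics(c(ctrl_vals, pat_vals), c(rep("control", 6), "L_patient"))
  z <- nodal_zscores(m)
  expect_equal(z$subject_z$z, rep(0, 5))
  # common affine rescaling of all subjects leaves z unchanged
  m2 <- m; m2$e_nod <- 3 * m2$e_nod + 7
  z2 <- nodal_zscores(m2)
  expect_equal(z2$subject_z$z, z$subject_z$z)
})

test_that("planted disruption yields stable limbic-positive remote-negative z pattern", {
  nodes <- lmn_node_table()
  limbic_ids <- nodes$node_id[nodes$region_class == "limbic"]
  remote_ids <- nodes$node_id[nodes$region_class == "remote_cortical"]
  ok <- 0
  for (s in 1:3) {
    spec <- cohort_spec(group_sizes = c(control = 10, L_patient = 6, R_patient = 2),
                        n_volumes = 300, delta_limbic = 0.2, delta_remote = 0.12,
                        seed = 400 + s)
    den <- cohort_connectivity(denoise_cohort(simulate_cohort(spec)))
    m <- nodal_metrics(den, costs = c(0.05, 0.10, 0.15, 0.20))
    z <- nodal_zscores(m, patient_group = "L_patient")
    by_cost <- z$group_tests |>
      dplyr::mutate(class = dplyr::case_when(
        node_id %in% limbic_ids ~ "limbic",
        node_id %in% remote_ids ~ "remote",
        TRUE ~ "other")) |>
      dplyr::filter(class != "other") |>
      dplyr::group_by(cost, class) |>
      dplyr::summarise(mz = mean(mean_z), .groups = "drop")
    good <- all(by_cost$mz[by_cost$class == "limbic"] > 0) &&
      all(by_cost$mz[by_cost$class == "remote"] < 0)
    ok <- ok + good
  }
  expect_gte(ok, 2)
})

test_that("subject clustering merges duplicates first and recovers planted blobs", {
  x <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  cl <- cluster_subjects(x)
  expect_equal(cl$hclust$height[1], 0)
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])
  set.seed(29)
  blob <- rbind(matrix(rnorm(40, 0), 8), matrix(rnorm(40, 6), 8))
  rownames(blob) <- paste0("S", 1:16)
  cl2 <- cluster_subjects(blob)
  expect_equal(length(unique(cl2$labels[1:8])), 1)
  expect_equal(length(unique(cl2$labels[9:16])), 1)
  expect_false(cl2$labels[[1]] == cl2$labels[[16]])
  # permuting subjects permutes labels consistently
  perm <- sample(16)
  cl3 <- cluster_subjects(blob[perm, ])
  agree <- cl3$labels[rownames(blob)] == cl2$labels
  expect_true(all(agree) || all(!agree))
})
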