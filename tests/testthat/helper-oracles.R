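# Independent brute-force oracles for graph metrics, kept free of any
# package shortest-path code.

# all-pairs shortest paths by Floyd-Warshall dynamic programming
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj != 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  }
  tot / (n * (n - 1))
}

oracle_nodal_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  sapply(seq_len(n), function(i) {
    tot <- 0
    for (j in seq_len(n)) if (j != i && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
    tot / (n - 1)
  })
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  })
}

random_adjacency <- function(n, p = 0.4) {
  a <- matrix(stats::runif(n * n) < p, n, n)
  a[lower.tri(a, diag = TRUE)] <- FALSE
  a | t(a)
}

# small cohort spec used across tests; scaled-down sizes, study TR and network
tiny_spec <- function(..., seed = 1L) {
  cohort_spec(group_sizes = c(control = 4L, L_patient = 3L, R_patient = 3L),
              n_volumes = 120L, seed = seed, ...)
}
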