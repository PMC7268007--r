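#' Binarize a weighted connectivity matrix at a proportional cost
#'
#' Retains the `round(cost * N * (N - 1) / 2)` largest off-diagonal weights
#' (signed ranking: most-positive first; upper triangle) and symmetrizes.
#' Ties at the cut are broken by ascending `(i, j)` lexicographic order so
#' the result is deterministic.
#'
#' @param weights Symmetric N x N weight matrix (e.g. Fisher-z
#'   connectivity); the diagonal is ignored.
#' @param cost Fraction of possible edges to retain, in (0, 1].
#' @return A `binary_graph` object: list with `adjacency` (logical N x N,
#'   zero diagonal), `cost`, and `distances` (hop counts, `Inf` when
#'   unreachable).
#' @export
threshold_proportional <- function(weights, cost) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  stopifnot(n == ncol(weights), cost > 0, cost <= 1)
  idx <- upper_edges(n)
  w <- weights[idx]
  m <- round(cost * n * (n - 1) / 2)
  if (m == 0) warning("cost yields zero edges: returning the empty graph")
  ord <- order(-w, idx[, "row"], idx[, "col"])
  keep <- ord[seq_len(m)]
  adj <- matrix(FALSE, n, n)
  adj[idx[keep, , drop = FALSE]] <- TRUE
  adj <- adj | t(adj)
  binary_graph(adj, cost = cost)
}

#' Construct a binary graph with its shortest-path matrix
#'
#' @param adjacency Logical (or 0/1) symmetric matrix; diagonal forced to
#'   zero.
#' @param cost Optional recorded edge fraction.
#' @return A `binary_graph` object (see [threshold_proportional()]).
#' @export
binary_graph <- function(adjacency, cost = NULL) {
  adj <- as.matrix(adjacency) != 0
  stopifnot(nrow(adj) == ncol(adj))
  if (max(abs(adj - t(adj))) > 0) stop("adjacency must be symmetric", call. = FALSE)
  diag(adj) <- FALSE
  structure(list(adjacency = adj,
                 cost = if (is.null(cost)) mean(adj[upper.tri(adj)]) else cost,
                 distances = shortest_paths(adj)),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat(sprintf("<binary_graph> %d nodes, %d edges (cost %.3f)\n",
              n, sum(x$adjacency) / 2, x$cost))
  invisible(x)
}

#' Unweighted shortest-path (hop) distances
#'
#' Breadth-first distances between every node pair; unreachable pairs are
#' `Inf`, the diagonal 0.
#'
#' @param adjacency Logical symmetric adjacency matrix.
#' @return N x N numeric distance matrix.
#' @export
shortest_paths <- function(adjacency) {
  adj <- as.matrix(adjacency) != 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- igraph::distances(g)
  dimnames(d) <- NULL
  d
}

inv_dist <- function(d) {
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  inv
}

as_binary_graph <- function(g) {
  if (inherits(g, "binary_graph")) g else binary_graph(g)
}

#' Global efficiency of a binary graph
#'
#' Mean of the inverse shortest-path length over all ordered node pairs
#' `i != j`, with `1 / Inf = 0` for disconnected pairs. Equals 1 on the
#' complete graph and 0 on the empty graph.
#'
#' @param g A `binary_graph` or an adjacency matrix.
#' @return Scalar in [0, 1].
#' @export
global_efficiency <- function(g) {
  g <- as_binary_graph(g)
  n <- nrow(g$adjacency)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  sum(inv_dist(g$distances)) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' For each node, the mean of `1 / d_ij` over the other nodes: how well
#' the node is integrated in the network. The average of the nodal
#' efficiencies over all nodes equals the global efficiency exactly.
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @param node Optional single 0-based node id; default returns all nodes.
#' @return Numeric vector (or scalar) in [0, 1].
#' @export
nodal_efficiency <- function(g, node = NULL) {
  g <- as_binary_graph(g)
  n <- nrow(g$adjacency)
  e <- rowSums(inv_dist(g$distances)) / (n - 1)
  if (is.null(node)) e else e[node + 1L]
}

#' Local efficiency
#'
#' The nodal value for node `i` is the global efficiency of the subgraph
#' induced by the neighbors of `i` (excluding `i` itself); nodes with
#' fewer than two neighbors contribute 0. The network value is the mean
#' over all nodes.
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @param node Optional single 0-based node id.
#' @return With `node = NULL`, a list with `nodal` (per-node vector) and
#'   `network` (mean); otherwise the scalar nodal value.
#' @export
local_efficiency <- function(g, node = NULL) {
  g <- as_binary_graph(g)
  adj <- g$adjacency
  one <- function(i) {
    nb <- which(adj[i, ])
    if (length(nb) < 2) return(0)
    global_efficiency(binary_graph(adj[nb, nb, drop = FALSE]))
  }
  if (!is.null(node)) return(one(node + 1L))
  nodal <- vapply(seq_len(nrow(adj)), one, numeric(1))
  list(nodal = nodal, network = mean(nodal))
}

#' Small-world index sigma
#'
#' `sigma = (C / C_null) / (L / L_null)` where `C` is the mean local
#' clustering coefficient, `L` the characteristic path length on the
#' largest connected component, and the null values are means over
#' degree-preserving edge rewirings of the graph. `sigma > 1` flags a
#' small-world topology.
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @param n_null Number of rewired null graphs.
#' @param seed Integer seed for the rewiring.
#' @return Scalar sigma.
#' @export
small_world_sigma <- function(g, n_null = 20, seed = 1L) {
  g <- as_binary_graph(g)
  if (nrow(g$adjacency) < 4) stop("need at least 4 nodes", call. = FALSE)
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  cl <- function(graph) {
    cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
    mean(cc)
  }
  cpl <- function(graph) {
    comp <- igraph::components(graph)
    main <- igraph::induced_subgraph(graph, which(comp$membership == which.max(comp$csize)))
    igraph::mean_distance(main, directed = FALSE)
  }
  c_obs <- cl(ig)
  l_obs <- cpl(ig)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  nulls <- purrr::map(seq_len(n_null), function(i) {
    igraph::rewire(ig, igraph::keeping_degseq(niter = 10 * igraph::ecount(ig)))
  })
  c_null <- mean(vapply(nulls, cl, numeric(1)))
  l_null <- mean(vapply(nulls, cpl, numeric(1)))
  (c_obs / c_null) / (l_obs / l_null)
}

#' Subject x node x cost efficiency table for a cohort
#'
#' Thresholds each subject's connectivity at every cost and computes the
#' nodal, local and network efficiency metrics.
#'
#' @param cohort Cohort tibble with a `conn_z` list-column (see
#'   [cohort_connectivity()]).
#' @param costs Proportional costs, defaults to 5/10/15/20%.
#' @return Long tibble: `subject_id`, `group`, `cost`, `node_id`, `e_nod`,
#'   `e_loc_nodal`, plus the per-subject network values `e_glob` and
#'   `e_loc` repeated across nodes.
#' @export
nodal_metrics <- function(cohort, costs = c(0.05, 0.10, 0.15, 0.20)) {
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    w <- cohort$conn_z[[i]]
    w[!is.finite(w)] <- 0
    purrr::map_dfr(costs, function(cost) {
      g <- threshold_proportional(w, cost)
      en <- nodal_efficiency(g)
      el <- local_efficiency(g)
      tibble::tibble(
        subject_id = cohort$subject_id[i],
        group = cohort$group[i],
        cost = cost,
        node_id = seq_along(en) - 1L,
        e_nod = en,
        e_loc_nodal = el$nodal,
        e_glob = mean(en),
        e_loc = el$network
      )
    })
  })
}

#' Patient-versus-control nodal z-scores and group tests
#'
#' Standardizes each patient's nodal value against the control
#' distribution (`z = (value - control mean) / control SD`, per node and
#' cost) and tests the patient-control difference per node with a Welch t
#' test, Benjamini-Hochberg corrected across nodes within each cost.
#'
#' @param metrics Long metric table from [nodal_metrics()].
#' @param metric Column to analyse (default `"e_nod"`).
#' @param control_group,patient_group Group labels; patients default to
#'   every non-control group pooled.
#' @param alpha Level for the corrected decisions.
#' @return A list with `subject_z` (per patient x node x cost z-scores)
#'   and `group_tests` (per node x cost Welch t, mean patient z, BH
#'   decisions, and cross-cost sign stability).
#' @export
nodal_zscores <- function(metrics, metric = "e_nod", control_group = "control",
                          patient_group = NULL, alpha = 0.05) {
  stopifnot(metric %in% names(metrics))
  metrics$value <- metrics[[metric]]
  ctrl <- dplyr::filter(metrics, .data$group == control_group)
  pats <- if (is.null(patient_group)) {
    dplyr::filter(metrics, .data$group != control_group)
  } else {
    dplyr::filter(metrics, .data$group %in% patient_group)
  }
  if (dplyr::n_distinct(ctrl$subject_id) < 2) stop("need >= 2 controls", call. = FALSE)

  ref <- ctrl |>
    dplyr::group_by(.data$cost, .data$node_id) |>
    dplyr::summarise(ctrl_mean = mean(.data$value), ctrl_sd = stats::sd(.data$value),
                     .groups = "drop")
  if (any(ref$ctrl_sd == 0)) warning("zero control SD at some nodes: z undefined there")

  subject_z <- pats |>
    dplyr::left_join(ref, by = c("cost", "node_id")) |>
    dplyr::mutate(z = ifelse(.data$ctrl_sd > 0,
                             (.data$value - .data$ctrl_mean) / .data$ctrl_sd,
                             NA_real_)) |>
    dplyr::select("subject_id", "group", "cost", "node_id", "value", "z")

  welch_row <- function(x, y) {
    ht <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
    if (is.null(ht)) return(tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_))
    tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
  }
  group_tests <- subject_z |>
    dplyr::group_by(.data$cost, .data$node_id) |>
    dplyr::summarise(
      mean_z = mean(.data$z, na.rm = TRUE),
      welch_row(.data$value, ctrl$value[ctrl$cost == .data$cost[1] &
                                          ctrl$node_id == .data$node_id[1]]),
      .groups = "drop") |>
    dplyr::group_by(.data$cost) |>
    dplyr::mutate(p_fdr = stats::p.adjust(.data$p, method = "BH"),
                  significant = .data$p_fdr < alpha) |>
    dplyr::ungroup()
  stability <- group_tests |>
    dplyr::group_by(.data$node_id) |>
    dplyr::summarise(stable_sign = dplyr::n_distinct(sign(.data$mean_z)) == 1,
                     .groups = "drop")
  group_tests <- dplyr::left_join(group_tests, stability, by = "node_id")
  list(subject_z = subject_z, group_tests = group_tests)
}

#' Hierarchical clustering of subjects on their nodal profiles
#'
#' Agglomerative clustering (average linkage) on Euclidean distances
#' between subject rows of a subjects x nodes metric matrix, with a k = 2
#' cut.
#'
#' @param x Numeric matrix (subjects x nodes) with subject row names, or a
#'   long metric tibble from [nodal_metrics()] (then `cost` selects one
#'   cost layer and `metric` the value column).
#' @param cost,metric Used only for the tibble input form.
#' @return List with `hclust` (the merge tree) and `labels` (named k = 2
#'   cluster memberships).
#' @export
cluster_subjects <- function(x, cost = NULL, metric = "e_nod") {
  if (inherits(x, "data.frame")) {
    if (!is.null(cost)) x <- dplyr::filter(x, .data$cost == !!cost)
    wide <- tidyr::pivot_wider(
      dplyr::select(x, "subject_id", "node_id", dplyr::all_of(metric)),
      names_from = "node_id", values_from = dplyr::all_of(metric))
    x <- as.matrix(wide[, -1])
    rownames(x) <- wide$subject_id
  }
  stopifnot(nrow(x) >= 2)
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "average")
  list(hclust = hc, labels = stats::cutree(hc, k = 2))
}
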