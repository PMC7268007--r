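#' Build the node table for a homotopic language-and-memory network
#'
#' Constructs the table describing a network of `n_pairs` homotopic region
#' pairs (2 * `n_pairs` nodes: all left-hemisphere nodes first, then their
#' right-hemisphere homotopes). The default 36-pair layout mirrors a
#' 72-region language-and-memory network: 10 pairs tagged `language`,
#' 20 `memory`, and 6 `both`. A subset of pairs is tagged `limbic`
#' (amygdalo-hippocampal complex and neighbours) and another subset
#' `remote_cortical` (lateral fronto-temporo-parietal cortex); these tags
#' drive the planted group effects of the synthetic cohort generator.
#'
#' @param n_pairs Number of homotopic pairs (>= 2).
#' @param limbic_pairs Integer vector of 0-based pair ids tagged as limbic.
#' @param remote_pairs Integer vector of 0-based pair ids tagged as remote
#'   cortical. Must be disjoint from `limbic_pairs`.
#'
#' @return A tibble with one row per node and columns `node_id` (0-based,
#'   left hemisphere `0..n_pairs-1`, right `n_pairs..2*n_pairs-1`), `label`,
#'   `hemisphere`, `lobe`, `system`, `homotopic_partner` (0-based node id; a
#'   perfect cross-hemisphere involution), and `region_class`
#'   (`limbic`/`remote_cortical`/`other`).
#' @export
#' @examples
#' nodes <- lmn_node_table()
#' nrow(nodes) # 72
#' table(nodes$system) / 2 # pairs per system
lmn_node_table <- function(n_pairs = 36,
                           limbic_pairs = 10:15,
                           remote_pairs = c(0:7, 20:23)) {
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 2) stop("`n_pairs` must be >= 2", call. = FALSE)
  limbic_pairs <- as.integer(limbic_pairs)
  remote_pairs <- as.integer(remote_pairs)
  if (n_pairs < 36) {
    # shrink the default tag sets rather than erroring on small toy networks
    limbic_pairs <- limbic_pairs[limbic_pairs < n_pairs]
    remote_pairs <- remote_pairs[remote_pairs < n_pairs]
  }
  if (anyDuplicated(limbic_pairs) || anyDuplicated(remote_pairs)) {
    stop("duplicate pair ids in `limbic_pairs`/`remote_pairs`", call. = FALSE)
  }
  if (any(limbic_pairs < 0L) || any(limbic_pairs >= n_pairs) ||
      any(remote_pairs < 0L) || any(remote_pairs >= n_pairs)) {
    stop("pair ids must lie in [0, n_pairs)", call. = FALSE)
  }
  if (length(intersect(limbic_pairs, remote_pairs)) > 0L) {
    stop("`limbic_pairs` and `remote_pairs` must be disjoint", call. = FALSE)
  }

  pair_id <- seq_len(n_pairs) - 1L

  # system tags: proportions of the default 10/20/6 split
  n_lang <- max(1L, round(n_pairs * 10 / 36))
  n_both <- max(0L, round(n_pairs * 6 / 36))
  if (n_lang + n_both >= n_pairs) {
    n_both <- 0L
    n_lang <- min(n_lang, n_pairs - 1L)
  }
  system <- rep("memory", n_pairs)
  system[pair_id < n_lang] <- "language"
  system[pair_id >= n_pairs - n_both] <- "both"

  lobe <- rep("temporal", n_pairs)
  lobe[pair_id < n_lang] <- "frontal"
  lobe[pair_id %in% limbic_pairs] <- "limbic"
  lobe[pair_id >= n_pairs - max(n_both, round(n_pairs / 6))] <- "parietal"

  region_class <- rep("other", n_pairs)
  region_class[pair_id %in% limbic_pairs] <- "limbic"
  region_class[pair_id %in% remote_pairs] <- "remote_cortical"

  limbic_labels <- c("Hippocampus_1", "Hippocampus_2", "ParaHippocampal_1",
                     "ParaHippocampal_2", "Amygdala_1", "Fusiform_1")
  base_label <- sprintf("%s_%02d", tools::toTitleCase(lobe), pair_id)
  if (identical(sort(limbic_pairs), 10:15) && n_pairs >= 16) {
    base_label[limbic_pairs + 1L] <- limbic_labels
  }

  half <- tibble::tibble(
    pair_id = pair_id, label = base_label, lobe = lobe,
    system = system, region_class = region_class
  )
  dplyr::bind_rows(
    dplyr::mutate(half,
      node_id = pair_id, hemisphere = "left",
      label = paste0(label, "_L"),
      homotopic_partner = pair_id + n_pairs
    ),
    dplyr::mutate(half,
      node_id = pair_id + n_pairs, hemisphere = "right",
      label = paste0(label, "_R"),
      homotopic_partner = pair_id
    )
  ) |>
    dplyr::select("node_id", "label", "hemisphere", "lobe", "system",
                  "homotopic_partner", "region_class", "pair_id")
}

#' Validate a node table
#'
#' Checks the structural invariants: consecutive 0-based ids, an even node
#' count, and a homotopic partner map that is a perfect cross-hemisphere
#' involution.
#'
#' @param nodes A node table as returned by [lmn_node_table()].
#' @return `nodes`, invisibly; errors if an invariant fails.
#' @export
validate_node_table <- function(nodes) {
  n <- nrow(nodes)
  if (n %% 2L != 0L) stop("node table must have an even number of rows", call. = FALSE)
  if (!identical(sort(nodes$node_id), seq_len(n) - 1L)) {
    stop("node ids must be 0..N-1 without gaps", call. = FALSE)
  }
  partner <- nodes$homotopic_partner[match(seq_len(n) - 1L, nodes$node_id)]
  if (!identical(partner[partner + 1L], seq_len(n) - 1L)) {
    stop("homotopic partner map is not an involution", call. = FALSE)
  }
  hemi <- nodes$hemisphere[match(seq_len(n) - 1L, nodes$node_id)]
  if (any(hemi == hemi[partner + 1L])) {
    stop("homotopic partners must lie in opposite hemispheres", call. = FALSE)
  }
  invisible(nodes)
}
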