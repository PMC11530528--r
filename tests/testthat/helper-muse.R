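# Shared fixtures, all built in code at test time.

# Random generic molecular graph with n nodes and Erdos-Renyi edges.
random_graph <- function(n = 10L, d = 4L, p = 0.3, coords = FALSE,
                         id = "G1") {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE] - 1L
  molecular_graph(id, "generic",
                  node_features = matrix(stats::rnorm(n * d), n, d),
                  edges = edges,
                  coords = if (coords) matrix(stats::rnorm(n * 3, sd = 5), n, 3))
}

# Apply a node permutation to a graph (perm[i] = new index of old node i).
permute_graph <- function(g, perm) {
  inv <- order(perm)
  molecular_graph(g$entity_id, g$entity_kind,
                  node_features = g$node_features[inv, , drop = FALSE],
                  edges = if (nrow(g$edges) > 0L)
                    cbind(perm[g$edges[, 1L] + 1L], perm[g$edges[, 2L] + 1L]) - 1L
                  else g$edges,
                  edge_features = g$edge_features,
                  coords = if (!is.null(g$coords)) g$coords[inv, , drop = FALSE])
}

# Tiny interaction table written to a temp file; returns the path.
write_tiny_table <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(rows, path)
  path
}

# Small synthetic dataset cached across tests (expensive pieces reused).
.muse_test_cache <- new.env(parent = emptyenv())

small_dataset <- function(seed = 5L) {
  key <- paste0("small", seed)
  if (is.null(.muse_test_cache[[key]])) {
    spec <- synthetic_spec(n_entities = 50L, n_links = 220L,
                           graph_size = c(10L, 16L), seed = seed)
    .muse_test_cache[[key]] <- generate_multiscale_network(spec)
  }
  .muse_test_cache[[key]]
}

fast_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, epochs_per_step = 15L, max_em_iterations = 2L,
         encoder = list(hidden = 12L), network = list(hidden = 12L)),
    list(...))
  do.call(muse_config, args)
}

hidden_truth <- function(data) {
  idx <- which(data$network$links$status == "unobserved")
  list(idx = idx, labels = data$truth$labels[idx, , drop = FALSE])
}
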