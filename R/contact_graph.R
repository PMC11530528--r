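#' Build a residue contact graph from a C-alpha trace
#'
#' Two residues are connected iff the Euclidean distance between their
#' C-alpha atoms is strictly below `cutoff` (default 10 Angstroms, the
#' standard contact-map threshold for intra-chain residue graphs). Node
#' features come from [featurize_residues()]; coordinates are retained on the
#' graph for geometric encoders.
#'
#' @param sequence One-letter residue sequence of length `L`.
#' @param coords Numeric `L x 3` matrix of C-alpha coordinates (Angstroms).
#' @param cutoff Contact distance threshold in Angstroms; strict `<`.
#' @param entity_id Identifier stored on the graph.
#' @return A [molecular_graph()] with `entity_kind = "protein"`.
#' @export
build_contact_graph <- function(sequence, coords, cutoff = 10,
                                entity_id = "protein") {
  coords <- as.matrix(coords)
  L <- nrow(coords)
  if (L == 0L) stop("build_contact_graph: empty chain")
  if (nchar(sequence) != L) {
    stop("build_contact_graph: sequence length must equal nrow(coords)")
  }
  D <- as.matrix(stats::dist(coords))
  hits <- which(upper.tri(D) & D < cutoff, arr.ind = TRUE)
  edges <- cbind(hits[, 1L], hits[, 2L]) - 1L
  molecular_graph(entity_id, "protein",
                  node_features = featurize_residues(sequence),
                  edges = edges, coords = coords)
}

#' Build a k-nearest-neighbor edge list from coordinates
#'
#' For each node `i`, emits directed edges `j -> i` from its `k` nearest
#' neighbors (Euclidean distance), ties broken by lower node index for
#' cross-platform determinism.
#'
#' @param coords Numeric `L x 3` coordinate matrix.
#' @param k Number of neighbors per node; must satisfy `0 < k < L`.
#' @param symmetrize If `TRUE`, return the union of both edge directions as
#'   undirected canonical pairs.
#' @return Integer matrix with columns `from`, `to` (0-based indices);
#'   directed `j -> i` rows unless `symmetrize = TRUE`.
#' @export
build_knn_graph <- function(coords, k, symmetrize = FALSE) {
  coords <- as.matrix(coords)
  L <- nrow(coords)
  if (k <= 0L) stop("build_knn_graph: k must be positive")
  if (k >= L) stop("build_knn_graph: k must be smaller than the number of nodes")
  D <- as.matrix(stats::dist(coords))
  from <- integer(0); to <- integer(0)
  for (i in seq_len(L)) {
    d <- D[i, ]
    d[i] <- Inf
    nb <- order(d, seq_len(L))[seq_len(k)]
    from <- c(from, nb - 1L)
    to <- c(to, rep(i - 1L, k))
  }
  edges <- cbind(from = from, to = to)
  if (symmetrize) {
    canon <- unique(cbind(pmin(edges[, 1L], edges[, 2L]),
                          pmax(edges[, 1L], edges[, 2L])))
    colnames(canon) <- c("from", "to")
    return(canon[order(canon[, 1L], canon[, 2L]), , drop = FALSE])
  }
  edges
}
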