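#' Construct a molecular structural graph
#'
#' A `molecular_graph` is one entity's atomic/residue-level structural graph:
#' node feature matrix, canonical undirected edge list, optional edge feature
#' matrix and optional 3D coordinates (Angstroms). Proteins are residue contact
#' graphs over C-alpha atoms, drugs are hydrogen-suppressed atom/bond graphs,
#' and `generic` graphs come from the bundled interchange format or the
#' synthetic generator.
#'
#' Edges are stored 0-based and canonicalized with the smaller index first;
#' duplicates (in either orientation) are collapsed. Self-loops are rejected.
#'
#' @param entity_id Character scalar identifying the entity.
#' @param entity_kind One of `"protein"`, `"drug"`, `"generic"`.
#' @param node_features Numeric matrix, one row per node.
#' @param edges Integer matrix with two columns of 0-based node indices
#'   (may have zero rows).
#' @param edge_features Optional numeric matrix with one row per edge (after
#'   canonicalization), or `NULL`.
#' @param coords Optional numeric matrix `n x 3` of coordinates in Angstroms.
#' @return An object of class `molecular_graph`.
#' @export
molecular_graph <- function(entity_id, entity_kind = c("generic", "protein", "drug"),
                            node_features, edges, edge_features = NULL,
                            coords = NULL) {
  entity_kind <- match.arg(entity_kind)
  node_features <- as.matrix(node_features)
  n <- nrow(node_features)
  if (n == 0L) stop("molecular_graph: graph must have at least one node")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 0L) || any(edges >= n)) {
      stop("molecular_graph: edge endpoint out of range [0, n)")
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("molecular_graph: self-loop edges are not allowed")
    }
    canon <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    key <- canon[, 1L] * n + canon[, 2L]
    keep <- !duplicated(key)
    edges <- canon[keep, , drop = FALSE]
    if (!is.null(edge_features)) {
      edge_features <- as.matrix(edge_features)[keep, , drop = FALSE]
    }
    ord <- order(edges[, 1L], edges[, 2L])
    edges <- edges[ord, , drop = FALSE]
    if (!is.null(edge_features)) edge_features <- edge_features[ord, , drop = FALSE]
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3L) {
      stop("molecular_graph: coords must be an n x 3 matrix")
    }
  }
  structure(list(entity_id = as.character(entity_id),
                 entity_kind = entity_kind,
                 node_features = node_features,
                 edges = edges,
                 edge_features = edge_features,
                 coords = coords),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph %s [%s]: %d nodes, %d edges, d_n=%d%s>\n",
              x$entity_id, x$entity_kind, nrow(x$node_features), nrow(x$edges),
              ncol(x$node_features),
              if (!is.null(x$coords)) ", coords" else ""))
  invisible(x)
}

n_nodes <- function(g) nrow(g$node_features)

# Dense symmetric 0/1 adjacency of a molecular graph (no self-loops).
graph_adjacency <- function(g) {
  n <- n_nodes(g)
  A <- matrix(0, n, n)
  if (nrow(g$edges) > 0L) {
    A[g$edges + 1L] <- 1
    A[g$edges[, c(2L, 1L), drop = FALSE] + 1L] <- 1
  }
  A
}

INTERCHANGE_SCHEMA <- "muse-graph/1"

#' Write a molecular graph to the bundled JSON interchange format
#'
#' The schema (`muse-graph/1`) is a plain JSON object with fields `schema`,
#' `entity_id`, `entity_kind`, `node_features` (row-major nested arrays),
#' `edges` (m x 2, 0-based), and optional `edge_features` and `coords`.
#' Numbers are serialized at full precision so that write/read round-trips are
#' lossless.
#'
#' @param graph A [molecular_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_interchange <- function(graph, path) {
  stopifnot(inherits(graph, "molecular_graph"))
  obj <- list(schema = INTERCHANGE_SCHEMA,
              entity_id = graph$entity_id,
              entity_kind = graph$entity_kind,
              node_features = graph$node_features,
              edges = graph$edges)
  if (!is.null(graph$edge_features)) obj$edge_features <- graph$edge_features
  if (!is.null(graph$coords)) obj$coords <- graph$coords
  json <- jsonlite::toJSON(obj, digits = NA, matrix = "rowmajor",
                           auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a molecular graph from the bundled JSON interchange format
#'
#' @param path File written by [write_graph_interchange()].
#' @return A [molecular_graph()].
#' @export
read_graph_interchange <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyMatrix = TRUE)
  if (is.null(obj$schema) || !identical(obj$schema, INTERCHANGE_SCHEMA)) {
    stop(sprintf("read_graph_interchange: schema-version mismatch (found %s, expected %s)",
                 if (is.null(obj$schema)) "<missing>" else obj$schema,
                 INTERCHANGE_SCHEMA))
  }
  for (key in c("entity_id", "entity_kind", "node_features", "edges")) {
    if (is.null(obj[[key]])) {
      stop(sprintf("read_graph_interchange: missing required key '%s'", key))
    }
  }
  edges <- obj$edges
  if (length(edges) == 0L) edges <- matrix(integer(0), 0L, 2L)
  molecular_graph(obj$entity_id, obj$entity_kind,
                  node_features = obj$node_features,
                  edges = edges,
                  edge_features = obj$edge_features,
                  coords = obj$coords)
}
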