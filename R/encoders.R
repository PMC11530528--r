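# Structure-scale encoders (the E-step model q_phi).
#
# Three encoder families share one contract: map a molecular graph's node
# features (and, for the geometric variant, coordinates) to node embeddings of
# the configured hidden width; a sum readout then gives the entity embedding.
# All entity graphs of one kind are packed into a single block-diagonal batch
# so a full pass over the dataset is a handful of sparse-dense products.

#' Create parameters for a structure-scale encoder
#'
#' @param encoder_kind `"gcn"` (contact-map graph convolution),
#'   `"geometric"` (message passing over k-NN geometry), or `"gin"`
#'   (atom/bond graph isomorphism network, used for drugs).
#' @param d_in Node feature dimension.
#' @param d_edge Edge feature dimension (`gin` only; 0 otherwise).
#' @param layers Number of message-passing layers (>= 1).
#' @param hidden Hidden width (> 0).
#' @param dropout Dropout rate in `[0,1)` applied inside geometric updates.
#' @param self_loops For `gcn`: normalize `A + I` (standard convention)
#'   rather than the bare adjacency.
#' @param knn_k Neighbors per node for the geometric variant.
#' @param rbf_bins Number of Gaussian radial basis functions encoding
#'   distances on `[0, 20]` Angstroms.
#' @return A `structure_encoder_params` object (opaque weight container plus
#'   architecture metadata).
#' @export
structure_encoder_params <- function(encoder_kind = c("gcn", "geometric", "gin"),
                                     d_in, d_edge = 0L, layers = 2L,
                                     hidden = 32L, dropout = 0.1,
                                     self_loops = TRUE, knn_k = 10L,
                                     rbf_bins = 16L) {
  encoder_kind <- match.arg(encoder_kind)
  stopifnot(layers >= 1L, hidden > 0L)
  params <- list()
  bn <- list()
  if (encoder_kind == "gcn") {
    d <- d_in
    for (l in seq_len(layers)) {
      lin <- nn_linear(d, hidden)
      params[[sprintf("l%d.W", l)]] <- lin$W
      params[[sprintf("l%d.gamma", l)]] <- matrix(1, 1L, hidden)
      params[[sprintf("l%d.beta", l)]] <- matrix(0, 1L, hidden)
      bn[[sprintf("l%d", l)]] <- nn_bn_state(hidden)
      d <- hidden
    }
  } else if (encoder_kind == "gin") {
    d <- d_in
    for (l in seq_len(layers)) {
      if (d_edge > 0L) {
        params[[sprintf("l%d.We", l)]] <- nn_linear(d_edge, d)$W
      }
      lin <- nn_linear(d, hidden)
      params[[sprintf("l%d.W", l)]] <- lin$W
      params[[sprintf("l%d.b", l)]] <- lin$b
      params[[sprintf("l%d.gamma", l)]] <- matrix(1, 1L, hidden)
      params[[sprintf("l%d.beta", l)]] <- matrix(0, 1L, hidden)
      bn[[sprintf("l%d", l)]] <- nn_bn_state(hidden)
      d <- hidden
    }
  } else { # geometric
    d_node <- d_in + 7L              # residue features ++ chain-frame geometry
    d_e <- rbf_bins + 3L + 9L        # distance RBF ++ direction ++ orientation
    proj <- nn_linear(d_node, hidden)
    params[["proj.W"]] <- proj$W
    params[["proj.b"]] <- proj$b
    for (l in seq_len(layers)) {
      m1 <- nn_linear(hidden + d_e, hidden)
      m2 <- nn_linear(hidden, hidden)
      params[[sprintf("l%d.M1", l)]] <- m1$W
      params[[sprintf("l%d.M1b", l)]] <- m1$b
      params[[sprintf("l%d.M2", l)]] <- m2$W
      params[[sprintf("l%d.M2b", l)]] <- m2$b
    }
  }
  structure(list(kind = encoder_kind, d_in = d_in, d_edge = d_edge,
                 layers = layers, hidden = hidden, dropout = dropout,
                 self_loops = self_loops, knn_k = knn_k, rbf_bins = rbf_bins,
                 params = params, bn = bn),
            class = "structure_encoder_params")
}

# Symmetrically normalized adjacency D^{-1/2} (A [+ I]) D^{-1/2} as a sparse
# Matrix, built from a 0-based canonical edge list.
normalized_adjacency <- function(n, edges, self_loops = TRUE) {
  i <- c(edges[, 1L], edges[, 2L]) + 1L
  j <- c(edges[, 2L], edges[, 1L]) + 1L
  if (self_loops) {
    i <- c(i, seq_len(n)); j <- c(j, seq_len(n))
  }
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Matrix::Diagonal(x = dinv) %*% A %*% Matrix::Diagonal(x = dinv)
}

# Directed incidence: for edge list (src -> dst), T is n x m with T[dst, k] = 1
# so that T %*% M sums incoming messages per node.
incidence_matrix <- function(n, dst) {
  m <- length(dst)
  if (m == 0L) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                           x = numeric(0), dims = c(n, 0L)))
  Matrix::sparseMatrix(i = dst + 1L, j = seq_len(m), x = 1, dims = c(n, m))
}

# ---- geometric features ----------------------------------------------------

rbf_expand <- function(d, bins = 16L, d_max = 20) {
  centers <- seq(0, d_max, length.out = bins)
  width <- (d_max / (bins - 1L))
  exp(-((outer(d, centers, "-") / width)^2))
}

# Per-residue local orthonormal frame from chain geometry (rows of `coords`
# are taken in chain order). Returns an L x 9 matrix of row-major frames.
local_frames <- function(coords) {
  L <- nrow(coords)
  frames <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), L), L, 9L, byrow = TRUE)
  if (L < 2L) return(frames)
  unit <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) c(1, 0, 0) else v / nv
  }
  for (i in seq_len(L)) {
    fwd <- if (i < L) coords[i + 1L, ] - coords[i, ] else coords[i, ] - coords[i - 1L, ]
    bwd <- if (i > 1L) coords[i - 1L, ] - coords[i, ] else coords[i + 1L, ] - coords[i, ]
    e1 <- unit(fwd)
    b <- bwd - sum(bwd * e1) * e1
    if (sqrt(sum(b^2)) < 1e-8) {
      # collinear chain: pick any vector orthogonal to e1
      b <- if (abs(e1[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      b <- b - sum(b * e1) * e1
    }
    e2 <- unit(b)
    e3 <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
            e1[3L] * e2[1L] - e1[1L] * e2[3L],
            e1[1L] * e2[2L] - e1[2L] * e2[1L])
    frames[i, ] <- c(e1, e2, e3)
  }
  frames
}

# Geometric node features: forward/backward chain unit vectors expressed in the
# residue's own frame (6) plus the cosine of the chain bend angle (1). All are
# functions of coordinate differences only, hence translation invariant.
geometric_node_features <- function(coords) {
  L <- nrow(coords)
  frames <- local_frames(coords)
  out <- matrix(0, L, 7L)
  unit <- function(v) { nv <- sqrt(sum(v^2)); if (nv < 1e-8) rep(0, 3) else v / nv }
  for (i in seq_len(L)) {
    R <- matrix(frames[i, ], 3L, 3L, byrow = TRUE) # rows e1,e2,e3
    fwd <- if (i < L) unit(coords[i + 1L, ] - coords[i, ]) else rep(0, 3)
    bwd <- if (i > 1L) unit(coords[i - 1L, ] - coords[i, ]) else rep(0, 3)
    out[i, 1:3] <- as.numeric(R %*% fwd)
    out[i, 4:6] <- as.numeric(R %*% bwd)
    out[i, 7L] <- sum(fwd * bwd)
  }
  out
}

# Geometric edge features for directed edges src -> dst: distance RBF, the
# direction to the source expressed in the destination residue's local frame,
# and the relative rotation R_dst^T R_src flattened (9 values).
geometric_edge_features <- function(coords, src, dst, rbf_bins = 16L) {
  frames <- local_frames(coords)
  m <- length(src)
  delta <- coords[src + 1L, , drop = FALSE] - coords[dst + 1L, , drop = FALSE]
  d <- sqrt(rowSums(delta^2))
  rbf <- rbf_expand(d, bins = rbf_bins)
  dirs <- matrix(0, m, 3L)
  rel <- matrix(0, m, 9L)
  for (k in seq_len(m)) {
    Rd <- matrix(frames[dst[k] + 1L, ], 3L, 3L, byrow = TRUE)
    Rs <- matrix(frames[src[k] + 1L, ], 3L, 3L, byrow = TRUE)
    u <- delta[k, ]
    nu <- sqrt(sum(u^2))
    if (nu > 1e-8) dirs[k, ] <- as.numeric(Rd %*% (u / nu))
    rel[k, ] <- as.numeric(Rd %*% t(Rs))
  }
  cbind(rbf, dirs, rel)
}

# ---- batched forward passes ------------------------------------------------

# Pack one kind's graphs into a block-diagonal batch.
build_encoder_batch <- function(graphs, enc) {
  ns <- vapply(graphs, n_nodes, integer(1))
  offsets <- c(0L, cumsum(ns))
  n_tot <- offsets[length(offsets)]
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  pool <- Matrix::sparseMatrix(
    i = rep(seq_along(graphs), ns),
    j = seq_len(n_tot), x = 1, dims = c(length(graphs), n_tot))
  batch <- list(n_tot = n_tot, offsets = offsets, X = X, pool = pool)
  if (enc$kind == "gcn") {
    edges <- do.call(rbind, lapply(seq_along(graphs), function(gi) {
      graphs[[gi]]$edges + offsets[gi]
    }))
    if (is.null(edges)) edges <- matrix(integer(0), 0L, 2L)
    batch$Ahat <- normalized_adjacency(n_tot, edges, enc$self_loops)
  } else if (enc$kind == "gin") {
    src <- integer(0); dst <- integer(0); ef <- NULL
    for (gi in seq_along(graphs)) {
      g <- graphs[[gi]]
      if (nrow(g$edges) == 0L) next
      e <- g$edges + offsets[gi]
      src <- c(src, e[, 1L], e[, 2L])
      dst <- c(dst, e[, 2L], e[, 1L])
      if (enc$d_edge > 0L) {
        fe <- if (is.null(g$edge_features)) {
          matrix(0, nrow(g$edges), enc$d_edge)
        } else g$edge_features
        ef <- rbind(ef, fe, fe)
      }
    }
    batch$src <- src
    batch$Tinc <- incidence_matrix(n_tot, dst)
    batch$edge_feat <- ef
  } else { # geometric
    src <- integer(0); dst <- integer(0); ef <- NULL
    Xg <- NULL
    for (gi in seq_along(graphs)) {
      g <- graphs[[gi]]
      if (is.null(g$coords)) {
        stop("geometric encoder requires coordinates on every graph")
      }
      L <- n_nodes(g)
      k_eff <- min(enc$knn_k, L - 1L)
      if (k_eff >= 1L) {
        kn <- build_knn_graph(g$coords, k_eff)
        e_src <- kn[, "from"]; e_dst <- kn[, "to"]
        src <- c(src, e_src + offsets[gi])
        dst <- c(dst, e_dst + offsets[gi])
        ef <- rbind(ef, geometric_edge_features(g$coords, e_src, e_dst,
                                                enc$rbf_bins))
      }
      Xg <- rbind(Xg, geometric_node_features(g$coords))
    }
    batch$src <- src
    batch$Tinc <- incidence_matrix(n_tot, dst)
    batch$edge_feat <- ef
    batch$X <- cbind(X, Xg)
  }
  batch
}

# Forward pass over a packed batch; returns the node-embedding tape node.
# `params` is a flat named list whose keys are `prefix` + the layer-local
# names chosen in structure_encoder_params(); the default arguments run a
# standalone encoder, while the full structure model passes one shared flat
# parameter list with per-kind prefixes so all encoders can sit on one tape.
encoder_forward <- function(tape, enc, batch, training = FALSE, prefix = "",
                            params = enc$params) {
  gp <- function(nm) ag_param(tape, params[[paste0(prefix, nm)]], paste0(prefix, nm))
  H <- ag_const(tape, batch$X)
  if (enc$kind == "gcn") {
    for (l in seq_len(enc$layers)) {
      Z <- ag_matmul(tape, ag_spmm(tape, batch$Ahat, H), gp(sprintf("l%d.W", l)))
      Z <- ag_relu(tape, Z)
      Z <- ag_batchnorm(tape, Z, enc$bn[[sprintf("l%d", l)]], training)
      H <- ag_add(tape, ag_mul(tape, Z, gp(sprintf("l%d.gamma", l))),
                  gp(sprintf("l%d.beta", l)))
    }
  } else if (enc$kind == "gin") {
    for (l in seq_len(enc$layers)) {
      if (length(batch$src) > 0L) {
        msg <- ag_rows(tape, H, batch$src + 1L)
        if (enc$d_edge > 0L && !is.null(batch$edge_feat)) {
          E <- ag_matmul(tape, ag_const(tape, batch$edge_feat),
                         gp(sprintf("l%d.We", l)))
          msg <- ag_add(tape, msg, E)
        }
        msg <- ag_relu(tape, msg)
        agg <- ag_spmm(tape, batch$Tinc, msg)
        comb <- ag_add(tape, H, agg)
      } else {
        comb <- H
      }
      Z <- ag_add(tape, ag_matmul(tape, comb, gp(sprintf("l%d.W", l))),
                  gp(sprintf("l%d.b", l)))
      Z <- ag_relu(tape, Z)
      Z <- ag_batchnorm(tape, Z, enc$bn[[sprintf("l%d", l)]], training)
      H <- ag_add(tape, ag_mul(tape, Z, gp(sprintf("l%d.gamma", l))),
                  gp(sprintf("l%d.beta", l)))
    }
  } else { # geometric
    H <- ag_add(tape, ag_matmul(tape, H, gp("proj.W")), gp("proj.b"))
    for (l in seq_len(enc$layers)) {
      if (length(batch$src) > 0L) {
        hs <- ag_rows(tape, H, batch$src + 1L)
        inp <- ag_cbind(tape, hs, ag_const(tape, batch$edge_feat))
        msg <- ag_relu(tape, ag_add(tape, ag_matmul(tape, inp, gp(sprintf("l%d.M1", l))),
                                    gp(sprintf("l%d.M1b", l))))
        msg <- ag_add(tape, ag_matmul(tape, msg, gp(sprintf("l%d.M2", l))),
                      gp(sprintf("l%d.M2b", l)))
        agg <- ag_spmm(tape, batch$Tinc, msg)
        agg <- ag_dropout(tape, agg, enc$dropout, training)
        H <- ag_layernorm(tape, ag_add(tape, H, agg))
      } else {
        H <- ag_layernorm(tape, H)
      }
    }
  }
  H
}

encode_one_graph <- function(graph, enc, training = FALSE) {
  batch <- build_encoder_batch(list(graph), enc)
  tape <- ag_tape()
  ag_value(encoder_forward(tape, enc, batch, training = training))
}

#' Encode a molecular graph with the contact-map GCN
#'
#' Each layer computes `BatchNorm(ReLU(Ahat %*% H %*% W))` where `Ahat` is the
#' symmetrically normalized adjacency (self-loops included by default). Batch
#' normalization uses stored running statistics outside training, so the
#' operation is deterministic and permutation-equivariant at inference.
#'
#' @param graph A [molecular_graph()] with node features.
#' @param params A `"gcn"` [structure_encoder_params()].
#' @param training Use batch statistics and update running statistics.
#' @return Numeric matrix `n x hidden` of node embeddings.
#' @export
encode_structure_gcn <- function(graph, params, training = FALSE) {
  stopifnot(inherits(params, "structure_encoder_params"), params$kind == "gcn")
  encode_one_graph(graph, params, training)
}

#' Encode a molecular graph with the geometric message-passing network
#'
#' Builds k-NN edges over the stored coordinates, computes translation-
#' invariant geometric node and edge features (distance radial basis,
#' local-frame directions, relative frame rotations), and runs residual
#' message passing: each node update is
#' `LayerNorm(h + Dropout(sum of incoming messages))` with a two-layer
#' message MLP on `concat(h_source, edge_features)`.
#'
#' @param graph A [molecular_graph()] with `coords`.
#' @param params A `"geometric"` [structure_encoder_params()].
#' @param training Enables dropout inside updates.
#' @return Numeric matrix `n x hidden` of node embeddings.
#' @export
encode_structure_geometric <- function(graph, params, training = FALSE) {
  stopifnot(inherits(params, "structure_encoder_params"),
            params$kind == "geometric")
  if (is.null(graph$coords)) {
    stop("encode_structure_geometric: graph has no coordinates")
  }
  encode_one_graph(graph, params, training)
}

#' Encode a drug atom/bond graph with a GIN
#'
#' Layer `l` aggregates, for every atom, the multiset of
#' `ReLU(h_neighbor + W_e e_bond)` messages over incident bonds, adds the
#' atom's own embedding, and applies the layer's learnable update
#' (linear + ReLU + BatchNorm). After `layers` rounds each embedding
#' summarizes the atom's `layers`-hop neighborhood.
#'
#' @param graph A [molecular_graph()] with node (and optionally edge)
#'   features.
#' @param params A `"gin"` [structure_encoder_params()].
#' @param training Use batch statistics in normalization layers.
#' @return Numeric matrix `n x hidden` of node embeddings.
#' @export
encode_drug_gin <- function(graph, params, training = FALSE) {
  stopifnot(inherits(params, "structure_encoder_params"), params$kind == "gin")
  encode_one_graph(graph, params, training)
}

#' Sum readout of node embeddings
#'
#' Permutation-invariant pooling of node embeddings into one graph-level
#' embedding (column sums).
#'
#' @param node_embeddings Numeric `n x h` matrix, `n >= 1`.
#' @return Numeric vector of length `h`.
#' @export
readout <- function(node_embeddings) {
  node_embeddings <- as.matrix(node_embeddings)
  if (nrow(node_embeddings) == 0L) stop("readout: empty embedding matrix")
  colSums(node_embeddings)
}
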