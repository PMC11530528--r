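# The M-step model p_theta: GIN message passing over the (augmented)
# interaction network with structural embeddings as initial node attributes,
# and a neighborhood-common-neighbor (NCN) pairwise scorer.

#' Create parameters for the network-scale model
#'
#' @param d_in Width of the initial node attributes (the structure-scale
#'   entity embeddings).
#' @param blocks Number of GIN blocks (>= 1).
#' @param hidden Hidden width of each block.
#' @param n_classes Number of interaction classes.
#' @param head `"sigmoid"` or `"softmax"` classifier head.
#' @return A `network_model_params` object.
#' @export
network_model_params <- function(d_in, blocks = 2L, hidden = 32L,
                                 n_classes = 1L,
                                 head = c("sigmoid", "softmax")) {
  head <- match.arg(head)
  stopifnot(blocks >= 1L)
  params <- list()
  bn <- list()
  d <- d_in
  for (l in seq_len(blocks)) {
    u1 <- nn_linear(d, hidden)
    u2 <- nn_linear(hidden, hidden)
    params[[sprintf("b%d.W1", l)]] <- u1$W
    params[[sprintf("b%d.b1", l)]] <- u1$b
    params[[sprintf("b%d.W2", l)]] <- u2$W
    params[[sprintf("b%d.b2", l)]] <- u2$b
    params[[sprintf("b%d.gamma", l)]] <- matrix(1, 1L, d)
    params[[sprintf("b%d.beta", l)]] <- matrix(0, 1L, d)
    bn[[sprintf("b%d", l)]] <- nn_bn_state(d)
    d <- hidden
  }
  p1 <- nn_linear(hidden, hidden)
  pc <- nn_linear(2L * hidden, n_classes)
  params[["pair.W1"]] <- p1$W
  params[["pair.b1"]] <- p1$b
  params[["cls.W"]] <- pc$W
  params[["cls.b"]] <- pc$b
  structure(list(d_in = d_in, blocks = blocks, hidden = hidden,
                 n_classes = n_classes, head = head,
                 params = params, bn = bn),
            class = "network_model_params")
}

#' One GIN block update on the interaction network
#'
#' Computes `BatchNorm(ReLU(H + A %*% H))` — each biomolecule adds the sum of
#' its neighbors' representations to its own — followed by the block's
#' two-layer learnable update network. Exposed as a plain-matrix operation;
#' training passes run the same computation on the autograd tape.
#'
#' @param H Numeric `N x d` node representation matrix.
#' @param A Adjacency (`N x N`, dense or sparse).
#' @param params A [network_model_params()].
#' @param layer Block index.
#' @param training Use batch statistics in the normalization.
#' @return Updated `N x hidden` matrix.
#' @export
gin_network_layer <- function(H, A, params, layer = 1L, training = FALSE) {
  stopifnot(inherits(params, "network_model_params"))
  H <- as.matrix(H)
  if (nrow(H) != nrow(as.matrix(A))) {
    stop("gin_network_layer: dimension mismatch between H and A")
  }
  tape <- ag_tape()
  node <- nm_block(tape, params, ag_const(tape, H),
                   methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
                   layer, training = training, params_flat = params$params,
                   ablate_network = FALSE)
  ag_value(node)
}

# One block on the tape. `params_flat` carries current weights (possibly under
# an empty prefix); `ablate_network` replaces the neighbor aggregate with its
# column mean (feature-mean substitution of the network scale).
nm_block <- function(tape, nm, H, A, l, training, params_flat,
                     prefix = "", ablate_network = FALSE) {
  gp <- function(x) ag_param(tape, params_flat[[paste0(prefix, x)]], paste0(prefix, x))
  agg <- ag_spmm(tape, A, H)
  if (ablate_network) agg <- ag_rowmean_broadcast(tape, agg)
  Z <- ag_relu(tape, ag_add(tape, H, agg))
  Z <- ag_batchnorm(tape, Z, nm$bn[[sprintf("b%d", l)]], training)
  Z <- ag_add(tape, ag_mul(tape, Z, gp(sprintf("b%d.gamma", l))),
              gp(sprintf("b%d.beta", l)))
  Z <- ag_relu(tape, ag_add(tape, ag_matmul(tape, Z, gp(sprintf("b%d.W1", l))),
                            gp(sprintf("b%d.b1", l))))
  ag_add(tape, ag_matmul(tape, Z, gp(sprintf("b%d.W2", l))),
         gp(sprintf("b%d.b2", l)))
}

#' Common neighbors of two nodes
#'
#' Exact intersection of the two neighbor sets under the given adjacency.
#'
#' @param A Adjacency matrix (dense or sparse 0/1).
#' @param i,j Node indices (1-based), `i != j`.
#' @return Sorted integer vector of common-neighbor indices.
#' @export
common_neighbors <- function(A, i, j) {
  if (i == j) stop("common_neighbors: i and j must differ")
  ni <- which(as.numeric(A[i, ]) != 0)
  nj <- which(as.numeric(A[j, ]) != 0)
  sort(intersect(ni, nj))
}

# Sparse (npairs x N) common-neighbor indicator: row k marks the nodes adjacent
# to both endpoints of pair k.
cn_indicator <- function(A, pairs) {
  Ai <- A[pairs[, 1L], , drop = FALSE]
  Aj <- A[pairs[, 2L], , drop = FALSE]
  M <- Ai * Aj
  methods::as(Matrix::Matrix(M > 0, sparse = TRUE) * 1, "generalMatrix")
}

# Pairwise logits for the network model on the tape.
nm_pair_logits <- function(tape, nm, H, A, pairs, params_flat, prefix = "",
                           ablate_network = FALSE) {
  gp <- function(x) ag_param(tape, params_flat[[paste0(prefix, x)]], paste0(prefix, x))
  Hi <- ag_rows(tape, H, pairs[, 1L])
  Hj <- ag_rows(tape, H, pairs[, 2L])
  # layer-normalized product pair term (see the structure-scale pair head)
  P <- ag_layernorm(tape, ag_mul(tape, Hi, Hj))
  P <- ag_relu(tape, ag_add(tape, ag_matmul(tape, P, gp("pair.W1")), gp("pair.b1")))
  CN <- cn_indicator(A, pairs)
  cn_term <- ag_spmm(tape, CN, H)
  if (ablate_network) cn_term <- ag_rowmean_broadcast(tape, cn_term)
  feat <- ag_cbind(tape, P, cn_term)
  ag_add(tape, ag_matmul(tape, feat, gp("cls.W")), gp("cls.b"))
}

# Node representations after all blocks. ablate = "none" | "structure" |
# "network"; "structure" mean-substitutes the initial node attributes,
# "network" mean-substitutes every neighbor aggregate and (in the pair head)
# the common-neighbor term — i.e. the network-derived features.
nm_node_reprs <- function(tape, nm, H0, A, training = FALSE,
                          params_flat = NULL, prefix = "", ablate = "none") {
  if (is.null(params_flat)) params_flat <- nm$params
  H <- if (is.environment(H0)) H0 else ag_const(tape, H0)
  if (ablate == "structure") H <- ag_rowmean_broadcast(tape, H)
  for (l in seq_len(nm$blocks)) {
    H <- nm_block(tape, nm, H, A, l, training, params_flat, prefix,
                  ablate_network = (ablate == "network"))
  }
  H
}

# Full forward: blocks then pair logits for one pair set.
nm_forward <- function(tape, nm, H0, A, pairs, training = FALSE,
                       params_flat = NULL, prefix = "", ablate = "none") {
  if (is.null(params_flat)) params_flat <- nm$params
  H <- nm_node_reprs(tape, nm, H0, A, training, params_flat, prefix, ablate)
  nm_pair_logits(tape, nm, H, A, pairs, params_flat, prefix,
                 ablate_network = (ablate == "network"))
}

#' NCN pairwise link prediction
#'
#' Scores a candidate pair from the final GIN-block representations: the sum
#' of the common neighbors' representations, concatenated with the symmetric
#' pair term `MLP(h_i * h_j)`, feeds the classifier head. With no common
#' neighbors the neighbor term is the zero vector and the prediction is
#' carried by the pair term alone.
#'
#' @param i,j Node indices (1-based), `i != j`.
#' @param H Final-layer node representations (`N x hidden`).
#' @param A Adjacency used for the common-neighbor lookup.
#' @param params A [network_model_params()].
#' @return A `pair_prediction` list (`label_distribution`, `logits`).
#' @export
ncn_predict <- function(i, j, H, A, params) {
  stopifnot(inherits(params, "network_model_params"))
  if (i == j) stop("ncn_predict: i and j must differ")
  tape <- ag_tape()
  Asp <- methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix")
  z <- nm_pair_logits(tape, params, ag_const(tape, as.matrix(H)), Asp,
                      cbind(i, j), params$params)
  logits <- ag_value(z)
  structure(list(link = c(i, j),
                 label_distribution = as.numeric(head_probs(logits, params$head)),
                 logits = as.numeric(logits)),
            class = "pair_prediction")
}

#' Augment an interaction network with pseudo edges
#'
#' Adds every candidate pair whose structure-scale existence probability
#' exceeds `1 - t` as a pseudo edge. The base network is not modified;
#' augmentation at `t = 0` is the identity, and pseudo-edge sets are nested
#' and monotone in `t`. Candidates that duplicate observed links are ignored.
#'
#' @param network An [interaction_network()].
#' @param q_probs Data frame or matrix with columns `i`, `j`, `prob`: the
#'   structure-scale model's existence probabilities on candidate pairs.
#' @param t Threshold parameter in `[0, 1)`.
#' @return An `augmented_network` list: `base`, `pseudo_edges`
#'   (`i`, `j`, `prob`), `t`.
#' @export
augment_with_pseudo_edges <- function(network, q_probs, t) {
  if (t < 0 || t >= 1) stop("augment_with_pseudo_edges: t must lie in [0,1)")
  q <- as.data.frame(as.matrix(q_probs))
  names(q) <- c("i", "j", "prob")[seq_len(ncol(q))]
  ii <- pmin(q$i, q$j); jj <- pmax(q$i, q$j)
  q$i <- ii; q$j <- jj
  N <- length(network$entity_ids)
  obs <- network$links[network$links$status == "observed", , drop = FALSE]
  obs_key <- obs$i * (N + 1) + obs$j
  keep <- q$prob > 1 - t & !(q$i * (N + 1) + q$j) %in% obs_key & q$i != q$j
  pe <- q[keep, , drop = FALSE]
  pe <- pe[!duplicated(pe$i * (N + 1) + pe$j), , drop = FALSE]
  rownames(pe) <- NULL
  structure(list(base = network, pseudo_edges = pe, t = t),
            class = "augmented_network")
}

#' @export
print.augmented_network <- function(x, ...) {
  cat(sprintf("<augmented_network: %d pseudo edges at t=%.2f over %d observed links>\n",
              nrow(x$pseudo_edges), x$t,
              sum(x$base$links$status == "observed")))
  invisible(x)
}

# Adjacency of base observed links plus pseudo edges.
augmented_adjacency <- function(aug) {
  if (inherits(aug, "interaction_network")) return(network_adjacency(aug))
  A <- network_adjacency(aug$base, include_pseudo = TRUE)
  if (nrow(aug$pseudo_edges) > 0L) {
    N <- nrow(A)
    P <- Matrix::sparseMatrix(i = c(aug$pseudo_edges$i, aug$pseudo_edges$j),
                              j = c(aug$pseudo_edges$j, aug$pseudo_edges$i),
                              x = 1, dims = c(N, N), use.last.ij = TRUE)
    A <- ((A + P) > 0) * 1
  }
  methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix")
}

# Serialize an augmented network as an interaction_network with pseudo links
# appended (labels zero, confidence = existence probability).
as_interaction_network <- function(aug) {
  stopifnot(inherits(aug, "augmented_network"))
  base <- aug$base
  # a pseudo edge may coincide with an unobserved (held-out) link: its
  # existence is then already represented, so keep the base row only
  N <- length(base$entity_ids)
  pe <- aug$pseudo_edges
  if (nrow(pe) > 0L) {
    base_key <- base$links$i * (N + 1) + base$links$j
    pe <- pe[!(pe$i * (N + 1) + pe$j) %in% base_key, , drop = FALSE]
  }
  if (nrow(pe) == 0L) return(base)
  C <- base$label_space$n_classes
  links <- rbind(base$links,
                 data.frame(i = pe$i, j = pe$j, status = "pseudo",
                            confidence = pe$prob))
  labels <- rbind(base$labels, matrix(0, nrow(pe), C))
  interaction_network(base$entity_ids, base$label_space, links, labels)
}

#' M-step training objective
#'
#' `beta * CE(p, pseudo)` on unobserved links (conditioning graph includes
#' pseudo edges) plus `(1 - beta) * CE(p, y)` on observed links, mean-reduced
#' over link-class entries. The pseudo targets are the E-step model's
#' predicted label distributions.
#'
#' @param predictions List with probability matrices `observed` and
#'   `unobserved`.
#' @param observed_labels Target matrix for observed links.
#' @param pseudo_labels Soft target matrix for unobserved links, or `NULL`.
#' @param beta Distillation weight in `[0, 1]`.
#' @return Scalar loss.
#' @export
mstep_loss <- function(predictions, observed_labels, pseudo_labels, beta) {
  if (beta < 0 || beta > 1) stop("mstep_loss: beta must lie in [0,1]")
  sup <- ce_probs(predictions$observed, observed_labels)
  if (is.null(pseudo_labels) || length(pseudo_labels) == 0L) return(sup)
  dist <- ce_probs(predictions$unobserved, pseudo_labels)
  beta * dist + (1 - beta) * sup
}

#' Train the network-scale model (one M-step)
#'
#' Full-batch AdamW epochs on the M-step objective over the augmented
#' network: GIN message passing initialized with the structure-scale entity
#' embeddings, NCN pairwise scoring, supervised loss on observed links and a
#' distillation term (weight `beta`) against the E-step's pseudo-labels on
#' unobserved links. Reproducible under a fixed seed; pass `model` to
#' warm-start.
#'
#' @param network An [interaction_network()] or `augmented_network`.
#' @param structural_embeddings Numeric `N x d` matrix from the E-step.
#' @param pseudo_labels Soft targets on unobserved links (their order in
#'   `links`), or `NULL`.
#' @param config A [muse_config()].
#' @param model Optional warm-start model.
#' @param train_links Row indices of links used for the supervised term;
#'   defaults to all observed links.
#' @return List with `model`, `p_unobserved` (probabilities on unobserved
#'   links), and per-epoch `loss`.
#' @export
train_mstep <- function(network, structural_embeddings, pseudo_labels = NULL,
                        config = muse_config(), model = NULL,
                        train_links = NULL) {
  base <- if (inherits(network, "augmented_network")) network$base else network
  A <- augmented_adjacency(network)
  obs_idx <- which(base$links$status == "observed")
  if (is.null(train_links)) train_links <- obs_idx
  if (length(train_links) == 0L) stop("train_mstep: no observed links to train on")
  unobs_idx <- which(base$links$status == "unobserved")
  if (is.null(model)) {
    model <- network_model_params(
      d_in = ncol(structural_embeddings),
      blocks = config$network$blocks, hidden = config$network$hidden,
      n_classes = base$label_space$n_classes,
      head = if (base$label_space$type == "multiclass") "softmax" else "sigmoid")
  }
  obs_pairs <- as.matrix(base$links[train_links, c("i", "j")])
  obs_labels <- base$labels[train_links, , drop = FALSE]
  unobs_pairs <- as.matrix(base$links[unobs_idx, c("i", "j")])
  if (!is.null(pseudo_labels) && nrow(unobs_pairs) > 0L) {
    stopifnot(nrow(pseudo_labels) == nrow(unobs_pairs))
  } else {
    pseudo_labels <- NULL
  }
  loss_fn <- if (model$head == "softmax") ag_softmax_ce else ag_bce_logits
  opt <- adamw_state(model$params)
  losses <- numeric(config$epochs_per_step)
  H0 <- as.matrix(structural_embeddings)
  for (ep in seq_len(config$epochs_per_step)) {
    tape <- ag_tape()
    H <- nm_node_reprs(tape, model, H0, A, training = TRUE)
    z_obs <- nm_pair_logits(tape, model, H, A, obs_pairs, model$params)
    sup <- loss_fn(tape, z_obs, obs_labels)
    loss <- if (is.null(pseudo_labels)) sup else {
      z_un <- nm_pair_logits(tape, model, H, A, unobs_pairs, model$params)
      dist <- loss_fn(tape, z_un, pseudo_labels)
      ag_add(tape, ag_scale(tape, dist, config$beta),
             ag_scale(tape, sup, 1 - config$beta))
    }
    losses[ep] <- ag_value(loss)[1L]
    grads <- ag_backward(tape, loss)
    step <- adamw_step(model$params, grads, opt, lr = config$lr,
                       weight_decay = config$weight_decay)
    model$params <- step$params
    opt <- step$state
  }
  p_un <- nm_predict(model, H0, A, unobs_pairs)
  list(model = model, p_unobserved = p_un, loss = losses)
}

# Inference-mode pair probabilities for the network model.
nm_predict <- function(model, H0, A, pairs, ablate = "none") {
  if (nrow(pairs) == 0L) return(matrix(numeric(0), 0L, model$n_classes))
  tape <- ag_tape()
  z <- nm_forward(tape, model, H0, A, pairs, training = FALSE, ablate = ablate)
  head_probs(ag_value(z), model$head)
}
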