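# The E-step model q_phi: structure encoders feeding a symmetric pair
# classifier, trained on observed labels plus (after the first EM iteration)
# the network-scale model's pseudo-label distributions on unobserved links.

#' Create parameters for the symmetric pair classifier
#'
#' The pair representation is `MLP(h_i * h_j)` (elementwise product, hence
#' symmetric in the two entities) followed by a per-class sigmoid head
#' (binary/multilabel) or a softmax head (multiclass).
#'
#' @param hidden Embedding width of the incoming entity embeddings.
#' @param n_classes Number of interaction classes.
#' @param head `"sigmoid"` or `"softmax"`.
#' @return A `pair_head_params` object.
#' @export
pair_head_params <- function(hidden, n_classes, head = c("sigmoid", "softmax")) {
  head <- match.arg(head)
  l1 <- nn_linear(hidden, hidden)
  lc <- nn_linear(hidden, n_classes)
  structure(list(hidden = hidden, n_classes = n_classes, head = head,
                 params = list(W1 = l1$W, b1 = l1$b, Wc = lc$W, bc = lc$b)),
            class = "pair_head_params")
}

# Tape version: Hg is the entity-embedding node, pairs a 2-column (i, j)
# 1-based index matrix. Returns the logits node (npairs x C).
pair_head_logits <- function(tape, ph, Hg, pairs, prefix = "pair.",
                             params = NULL) {
  if (is.null(params)) {
    params <- stats::setNames(ph$params, paste0(prefix, names(ph$params)))
  }
  gp <- function(nm) ag_param(tape, params[[paste0(prefix, nm)]], paste0(prefix, nm))
  Hi <- ag_rows(tape, Hg, pairs[, 1L])
  Hj <- ag_rows(tape, Hg, pairs[, 2L])
  # layer-normalize the product pair representation: sum readouts scale with
  # graph size and their elementwise product squares that scale, which makes
  # optimization badly conditioned without this (0 maps to 0, so symmetry
  # and the zero-embedding contract are unaffected)
  P <- ag_layernorm(tape, ag_mul(tape, Hi, Hj))
  Z1 <- ag_relu(tape, ag_add(tape, ag_matmul(tape, P, gp("W1")), gp("b1")))
  ag_add(tape, ag_matmul(tape, Z1, gp("Wc")), gp("bc"))
}

head_probs <- function(logits, head) {
  if (head == "softmax") {
    zs <- sweep(logits, 1L, apply(logits, 1L, max), "-")
    ez <- exp(zs)
    sweep(ez, 1L, rowSums(ez), "/")
  } else {
    1 / (1 + exp(-logits))
  }
}

#' Predict an interaction label distribution for one entity pair
#'
#' Applies the symmetric pair classifier to two entity embeddings. Because the
#' pair representation is built from the elementwise product, the prediction
#' is exactly symmetric under argument swap.
#'
#' @param emb_i,emb_j Numeric embedding vectors of equal length.
#' @param params A [pair_head_params()].
#' @return A `pair_prediction` list with `label_distribution` (in `[0,1]^C`,
#'   summing to 1 for a softmax head) and raw `logits`.
#' @export
predict_pair_q <- function(emb_i, emb_j, params) {
  stopifnot(inherits(params, "pair_head_params"))
  if (length(emb_i) != length(emb_j)) {
    stop("predict_pair_q: embedding widths differ")
  }
  p <- matrix(as.numeric(emb_i) * as.numeric(emb_j), 1L)
  p <- (p - mean(p)) / sqrt(mean((p - mean(p))^2) + 1e-5)
  z1 <- matrix(pmax(p %*% params$params$W1 + params$params$b1, 0), 1L)
  logits <- z1 %*% params$params$Wc + params$params$bc
  structure(list(link = NULL,
                 label_distribution = as.numeric(head_probs(logits, params$head)),
                 logits = as.numeric(logits)),
            class = "pair_prediction")
}

# Cross-entropy of probability matrix `p` against target matrix `y`
# (mean over link x class entries); used by the reference loss functions.
ce_probs <- function(p, y, eps = 1e-9) {
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' E-step training objective
#'
#' `alpha * CE(q, pseudo)` on unobserved links plus `(1 - alpha) * CE(q, y)`
#' on observed links, both mean-reduced over link-class entries. The first
#' term distills the network-scale model's pseudo-label distributions into
#' the structure-scale model; with no pseudo-labels (EM iteration 0) the loss
#' is the plain supervised term.
#'
#' @param predictions List with probability matrices `observed` and
#'   `unobserved` (rows = links, columns = classes).
#' @param observed_labels Target matrix for observed links.
#' @param pseudo_labels Soft target matrix for unobserved links, or `NULL`.
#' @param alpha Distillation weight in `[0, 1]`.
#' @return Scalar loss.
#' @export
estep_loss <- function(predictions, observed_labels, pseudo_labels, alpha) {
  if (alpha < 0 || alpha > 1) stop("estep_loss: alpha must lie in [0,1]")
  sup <- ce_probs(predictions$observed, observed_labels)
  if (is.null(pseudo_labels) || length(pseudo_labels) == 0L) return(sup)
  dist <- ce_probs(predictions$unobserved, pseudo_labels)
  alpha * dist + (1 - alpha) * sup
}

# ---- full structure-scale model -------------------------------------------

# Bundles per-kind encoders, the pair head, the packed batches, and the
# entity-index bookkeeping for a dataset.
structure_model_init <- function(graphs, space, config) {
  kinds <- vapply(graphs, function(g) g$entity_kind, character(1))
  enc_specs <- list()
  flat <- list()
  batches <- list()
  idx <- list()
  for (kind in unique(kinds)) {
    which_k <- which(kinds == kind)
    g1 <- graphs[[which_k[1L]]]
    ek <- config$encoder[[kind]]
    if (is.null(ek)) ek <- if (kind == "drug") "gin" else "gcn"
    d_edge <- if (!is.null(g1$edge_features)) ncol(g1$edge_features) else 0L
    enc <- structure_encoder_params(ek, d_in = ncol(g1$node_features),
                                    d_edge = d_edge,
                                    layers = config$encoder$layers,
                                    hidden = config$encoder$hidden,
                                    dropout = config$dropout,
                                    knn_k = config$encoder$knn_k)
    prefix <- paste0("enc.", kind, ".")
    flat <- c(flat, stats::setNames(enc$params, paste0(prefix, names(enc$params))))
    batches[[kind]] <- build_encoder_batch(graphs[which_k], enc)
    enc_specs[[kind]] <- enc
    idx[[kind]] <- which_k
  }
  ph <- pair_head_params(config$encoder$hidden, space$n_classes,
                         head = if (space$type == "multiclass") "softmax" else "sigmoid")
  flat <- c(flat, stats::setNames(ph$params, paste0("pair.", names(ph$params))))
  # existence head: same architecture, one sigmoid output; trained against
  # sampled negative pairs so that pseudo-edge augmentation gets a calibrated
  # probability that a candidate pair interacts at all
  eh <- pair_head_params(config$encoder$hidden, 1L, head = "sigmoid")
  flat <- c(flat, stats::setNames(eh$params, paste0("exist.", names(eh$params))))
  list(kinds = kinds, encoders = enc_specs, batches = batches,
       entity_idx = idx, pair = ph, exist = eh, params = flat,
       hidden = config$encoder$hidden, head = ph$head,
       n_entities = length(graphs))
}

# Entity embeddings (N x hidden) as a tape node: encode each kind's batch,
# sum-pool per graph, scatter into dataset entity order.
sm_entity_embeddings <- function(tape, model, training = FALSE) {
  pooled <- list()
  for (kind in names(model$encoders)) {
    enc <- model$encoders[[kind]]
    H <- encoder_forward(tape, enc, model$batches[[kind]], training = training,
                         prefix = paste0("enc.", kind, "."),
                         params = model$params)
    pooled[[kind]] <- ag_spmm(tape, model$batches[[kind]]$pool, H)
  }
  if (length(pooled) == 1L) {
    kind <- names(pooled)[1L]
    if (identical(model$entity_idx[[kind]], seq_len(model$n_entities))) {
      return(pooled[[kind]])
    }
  }
  ag_scatter_rows(tape, unname(pooled), unname(model$entity_idx),
                  model$n_entities)
}

sm_pair_logits <- function(tape, model, Hg, pairs) {
  pair_head_logits(tape, model$pair, Hg, pairs, prefix = "pair.",
                   params = model$params)
}

sm_exist_logits <- function(tape, model, Hg, pairs) {
  pair_head_logits(tape, model$exist, Hg, pairs, prefix = "exist.",
                   params = model$params)
}

# Existence probabilities for arbitrary candidate pairs (used by pseudo-edge
# augmentation: sigmoid of the pairwise existence score).
sm_predict_existence <- function(model, pairs) {
  if (nrow(pairs) == 0L) return(numeric(0))
  tape <- ag_tape()
  Hg <- sm_entity_embeddings(tape, model, training = FALSE)
  z <- sm_exist_logits(tape, model, Hg, pairs)
  as.numeric(1 / (1 + exp(-ag_value(z))))
}

# Scalar loss node for a tape-built E-step pass.
sm_loss_node <- function(tape, model, Hg, obs_pairs, obs_labels,
                         unobs_pairs = NULL, pseudo = NULL, alpha = 0.5) {
  loss_fn <- if (model$head == "softmax") ag_softmax_ce else ag_bce_logits
  z_obs <- sm_pair_logits(tape, model, Hg, obs_pairs)
  sup <- loss_fn(tape, z_obs, obs_labels)
  if (is.null(pseudo) || is.null(unobs_pairs) || nrow(unobs_pairs) == 0L) {
    return(sup)
  }
  z_un <- sm_pair_logits(tape, model, Hg, unobs_pairs)
  dist <- loss_fn(tape, z_un, pseudo)
  ag_add(tape, ag_scale(tape, dist, alpha), ag_scale(tape, sup, 1 - alpha))
}

# Inference: entity embeddings and pair probabilities without gradients.
sm_predict <- function(model, pairs) {
  tape <- ag_tape()
  Hg <- sm_entity_embeddings(tape, model, training = FALSE)
  if (nrow(pairs) == 0L) {
    return(list(embeddings = ag_value(Hg),
                probs = matrix(numeric(0), 0L, model$pair$n_classes)))
  }
  z <- sm_pair_logits(tape, model, Hg, pairs)
  list(embeddings = ag_value(Hg), probs = head_probs(ag_value(z), model$head))
}

#' Train the structure-scale model (one E-step)
#'
#' Runs full-batch AdamW epochs on the E-step objective: supervised
#' cross-entropy on the observed links plus, when pseudo-labels from the
#' network-scale model are supplied, a distillation term on the unobserved
#' links weighted by `alpha`. Training is reproducible under a fixed seed;
#' pass `model` to warm-start from a previous iteration's parameters.
#'
#' @param dataset List with `graphs` (list of [molecular_graph()], one per
#'   entity) and `network` (an [interaction_network()]).
#' @param pseudo_labels Matrix of soft targets for the unobserved links (row
#'   order = unobserved links in `network$links` order), or `NULL`.
#' @param config A [muse_config()].
#' @param model Optional model returned by a previous call (warm start).
#' @param train_links Integer indices (rows of `network$links`) used for the
#'   supervised term; defaults to all observed links.
#' @return List with the updated `model`, `q_unobserved` (probability matrix
#'   on unobserved links), `embeddings` (N x hidden), and the per-epoch
#'   `loss` vector.
#' @export
train_estep <- function(dataset, pseudo_labels = NULL, config = muse_config(),
                        model = NULL, train_links = NULL) {
  network <- dataset$network
  obs_idx <- which(network$links$status == "observed")
  if (is.null(train_links)) train_links <- obs_idx
  if (length(train_links) == 0L) stop("train_estep: no observed links to train on")
  unobs_idx <- which(network$links$status == "unobserved")
  if (is.null(model)) {
    model <- structure_model_init(dataset$graphs, network$label_space, config)
  }
  obs_pairs <- as.matrix(network$links[train_links, c("i", "j")])
  obs_labels <- network$labels[train_links, , drop = FALSE]
  unobs_pairs <- as.matrix(network$links[unobs_idx, c("i", "j")])
  if (!is.null(pseudo_labels) && nrow(unobs_pairs) > 0L) {
    stopifnot(nrow(pseudo_labels) == nrow(unobs_pairs))
  } else {
    pseudo_labels <- NULL
  }
  # existence supervision: observed pairs vs an equal number of uniformly
  # sampled non-linked pairs (resampled per E-step from the seeded stream)
  n_neg <- length(train_links)
  neg_pairs <- tryCatch(
    sample_negative_pairs(network, n_neg,
                          seed = sample.int(.Machine$integer.max, 1L)),
    error = function(e) NULL)
  exist_pairs <- if (is.null(neg_pairs)) NULL else rbind(obs_pairs, neg_pairs)
  exist_targets <- if (is.null(neg_pairs)) NULL else
    matrix(c(rep(1, nrow(obs_pairs)), rep(0, nrow(neg_pairs))), ncol = 1L)

  opt <- adamw_state(model$params)
  losses <- numeric(config$epochs_per_step)
  for (ep in seq_len(config$epochs_per_step)) {
    tape <- ag_tape()
    Hg <- sm_entity_embeddings(tape, model, training = TRUE)
    loss <- sm_loss_node(tape, model, Hg, obs_pairs, obs_labels,
                         unobs_pairs, pseudo_labels, config$alpha)
    if (!is.null(exist_pairs)) {
      z_ex <- sm_exist_logits(tape, model, Hg, exist_pairs)
      loss <- ag_add(tape, loss,
                     ag_scale(tape, ag_bce_logits(tape, z_ex, exist_targets), 0.5))
    }
    losses[ep] <- ag_value(loss)[1L]
    grads <- ag_backward(tape, loss)
    step <- adamw_step(model$params, grads, opt, lr = config$lr,
                       weight_decay = config$weight_decay)
    model$params <- step$params
    opt <- step$state
  }
  pred <- sm_predict(model, unobs_pairs)
  list(model = model, q_unobserved = pred$probs,
       embeddings = pred$embeddings, loss = losses)
}
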