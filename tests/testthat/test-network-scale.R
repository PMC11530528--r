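make_adj <- function(n, edges) {
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    A[edges[r, 1], edges[r, 2]] <- 1
    A[edges[r, 2], edges[r, 1]] <- 1
  }
  A
}

test_that("gin_network_layer aggregates neighbors like the dense product", {
  set.seed(1)
  d <- 4L
  nm <- network_model_params(d_in = d, blocks = 1L, hidden = d)
  # near-identity configuration: BN with fresh stats ~ identity, identity
  # transforms; output ~ ReLU(H + A H)
  nm$params[["b1.W1"]] <- diag(d); nm$params[["b1.W2"]] <- diag(d)
  nm$params[["b1.b1"]] <- matrix(0, 1, d); nm$params[["b1.b2"]] <- matrix(0, 1, d)

  # 3-cycle with all-ones embeddings: each pre-activation is 1 + 2 = 3
  A3 <- make_adj(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  H3 <- matrix(1, 3, d)
  out <- gin_network_layer(H3, A3, nm, 1L)
  expect_equal(out, matrix(3, 3, d), tolerance = 1e-3)

  # isolated node: empty neighbor sum, update of own embedding only
  A1 <- matrix(0, 2, 2); A1[1, 2] <- A1[2, 1] <- 1
  Aiso <- rbind(cbind(A1, 0), 0)[1:3, 1:3]
  Hx <- matrix(stats::rnorm(3 * d), 3, d)
  o2 <- gin_network_layer(Hx, Aiso, nm, 1L)
  expect_equal(o2[3, ], pmax(Hx[3, ], 0), tolerance = 1e-3)

  # random 15-node graph: neighbor sums equal the dense A %*% H oracle
  set.seed(2)
  A15 <- make_adj(15, which(upper.tri(matrix(0, 15, 15)) &
                              matrix(stats::runif(225), 15) < 0.3, arr.ind = TRUE))
  H15 <- abs(matrix(stats::rnorm(15 * d), 15, d))
  o3 <- gin_network_layer(H15, A15, nm, 1L)
  expect_equal(o3, pmax(H15 + A15 %*% H15, 0), tolerance = 5e-2)

  expect_error(gin_network_layer(H15[1:4, ], A15, nm, 1L), "dimension mismatch")
})

test_that("common_neighbors equals brute-force intersection", {
  A <- make_adj(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(common_neighbors(A, 1, 2), 3L)
  A2 <- matrix(0, 4, 4)
  expect_equal(common_neighbors(A2, 1, 4), integer(0))
  expect_error(common_neighbors(A, 2, 2), "must differ")
  set.seed(3)
  n <- 20L
  Ar <- make_adj(n, which(upper.tri(matrix(0, n, n)) &
                            matrix(stats::runif(n * n), n) < 0.25, arr.ind = TRUE))
  for (q in 1:50) {
    ij <- sample(n, 2)
    oracle <- sort(intersect(which(Ar[ij[1], ] == 1), which(Ar[ij[2], ] == 1)))
    expect_equal(common_neighbors(Ar, ij[1], ij[2]), oracle)
  }
})

test_that("ncn_predict is symmetric and handles empty common-neighbor sets", {
  set.seed(4)
  nm <- network_model_params(d_in = 5L, blocks = 2L, hidden = 6L, n_classes = 2L)
  n <- 10L
  A <- make_adj(n, which(upper.tri(matrix(0, n, n)) &
                           matrix(stats::runif(100), 10) < 0.3, arr.ind = TRUE))
  H <- matrix(stats::rnorm(n * 6), n, 6)
  p1 <- ncn_predict(2, 7, H, A, nm)
  p2 <- ncn_predict(7, 2, H, A, nm)
  expect_equal(p1$label_distribution, p2$label_distribution, tolerance = 1e-12)
  expect_error(ncn_predict(3, 3, H, A, nm), "must differ")

  # the common-neighbor indicator matches explicit intersections, and
  # disconnected pairs yield the empty (all-zero) neighbor term
  pairs <- t(utils::combn(n, 2))[1:20, ]
  CN <- as.matrix(muse:::cn_indicator(Matrix::Matrix(A, sparse = TRUE), pairs))
  for (r in 1:20) {
    oracle <- rep(0, n)
    oracle[intersect(which(A[pairs[r, 1], ] == 1), which(A[pairs[r, 2], ] == 1))] <- 1
    expect_equal(unname(CN[r, ]), oracle)
  }

  # scores depend on common neighbors only through their representation sum
  A0 <- matrix(0, 6, 6)
  A0[1, 3] <- A0[3, 1] <- 1; A0[2, 3] <- A0[3, 2] <- 1   # CN(1,2) = {3}
  B0 <- matrix(0, 6, 6)
  B0[1, 4] <- B0[4, 1] <- 1; B0[2, 4] <- B0[4, 2] <- 1   # CN(1,2) = {4}
  H6 <- matrix(stats::rnorm(36), 6, 6)
  H6[4, ] <- H6[3, ]  # same representation, different identity
  # pair-head logits on identical H with equal CN representation sums agree
  tpa <- muse:::ag_tape()
  za <- muse:::ag_value(muse:::nm_pair_logits(
    tpa, nm, muse:::ag_const(tpa, H6),
    Matrix::Matrix(A0, sparse = TRUE), cbind(1, 2), nm$params))
  tpb <- muse:::ag_tape()
  zb <- muse:::ag_value(muse:::nm_pair_logits(
    tpb, nm, muse:::ag_const(tpb, H6),
    Matrix::Matrix(B0, sparse = TRUE), cbind(1, 2), nm$params))
  expect_equal(za, zb, tolerance = 1e-12)
})

test_that("augment_with_pseudo_edges thresholds at 1 - t and is monotone", {
  data <- small_dataset()
  net <- data$network
  # t = 0 is the identity augmentation
  q <- cbind(i = c(1, 2), j = c(9, 17), prob = c(0.99, 0.5))
  a0 <- augment_with_pseudo_edges(net, q, 0)
  expect_equal(nrow(a0$pseudo_edges), 0L)

  # threshold semantics: prob 0.95 passes at t = 0.1, prob 0.85 does not
  free <- muse:::pseudo_edge_candidates(net, "whole_graph")[1:2, ]
  q2 <- cbind(free, prob = c(0.95, 0.85))
  a1 <- augment_with_pseudo_edges(net, q2, 0.1)
  expect_equal(nrow(a1$pseudo_edges), 1L)
  expect_equal(a1$pseudo_edges$prob, 0.95)

  # observed duplicates are never added; the base network is untouched
  obs1 <- net$links[net$links$status == "observed", ][1, ]
  q3 <- cbind(i = obs1$i, j = obs1$j, prob = 0.999)
  expect_equal(nrow(augment_with_pseudo_edges(net, q3, 0.5)$pseudo_edges), 0L)
  expect_identical(a1$base, net)

  # sweep: pseudo-edge sets are nested and counts non-decreasing in t
  set.seed(5)
  cand <- muse:::pseudo_edge_candidates(net, "whole_graph")
  cand <- cand[sample(nrow(cand), 100), ]
  qr <- cbind(cand, prob = stats::runif(100))
  prev <- NULL
  for (t in c(0, 0.1, 0.2, 0.3, 0.4)) {
    at <- augment_with_pseudo_edges(net, qr, t)
    keys <- paste(at$pseudo_edges$i, at$pseudo_edges$j)
    oracle <- qr[qr[, "prob"] > 1 - t, , drop = FALSE]
    expect_equal(sort(keys), sort(paste(oracle[, "i"], oracle[, "j"])))
    if (!is.null(prev)) expect_true(all(prev %in% keys))
    prev <- keys
  }
  expect_error(augment_with_pseudo_edges(net, qr, 1), "t must lie")
})

test_that("mstep_loss decomposes linearly in beta", {
  set.seed(6)
  preds <- list(observed = matrix(stats::runif(10), 5, 2),
                unobserved = matrix(stats::runif(6), 3, 2))
  y <- matrix(stats::rbinom(10, 1, 0.5), 5, 2)
  ps <- matrix(stats::runif(6), 3, 2)
  l0 <- mstep_loss(preds, y, ps, 0)
  l1 <- mstep_loss(preds, y, ps, 1)
  for (b in c(0.3, 0.5, 0.9)) {
    expect_equal(mstep_loss(preds, y, ps, b), b * l1 + (1 - b) * l0,
                 tolerance = 1e-12)
  }
  expect_error(mstep_loss(preds, y, ps, -0.1), "beta")
})

test_that("train_mstep is reproducible with a non-increasing loss curve", {
  data <- small_dataset()
  H0 <- matrix(stats::rnorm(50 * 8), 50, 8)
  cfg <- fast_config(seed = 7)
  set.seed(7); m1 <- train_mstep(data$network, H0, NULL, cfg)
  set.seed(7); m2 <- train_mstep(data$network, H0, NULL, cfg)
  expect_identical(m1$p_unobserved, m2$p_unobserved)

  cfg2 <- muse_config(seed = 8, epochs_per_step = 40L,
                      network = list(hidden = 12L))
  set.seed(8)
  m3 <- train_mstep(data$network, H0, NULL, cfg2)
  expect_gte(mean(diff(m3$loss) <= 1e-8), 0.8)

  # augmentation tagging: pseudo links excluded from the supervised term by
  # construction (train on observed indices of the BASE network only)
  cand_all <- muse:::pseudo_edge_candidates(data$network)
  N <- length(data$network$entity_ids)
  link_key <- data$network$links$i * (N + 1) + data$network$links$j
  cand_all <- cand_all[!(cand_all[, 1] * (N + 1) + cand_all[, 2]) %in% link_key, ]
  aug <- augment_with_pseudo_edges(
    data$network, cbind(cand_all[1:5, , drop = FALSE], prob = 0.99), 0.3)
  expect_equal(nrow(aug$pseudo_edges), 5L)
  serialized <- muse:::as_interaction_network(aug)
  expect_equal(sum(serialized$links$status == "pseudo"), 5L)
  A <- muse:::augmented_adjacency(aug)
  expect_equal(sum(A) / 2,
               sum(data$network$links$status == "observed") + 5)
})
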