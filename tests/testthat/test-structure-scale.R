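test_that("GCN layer reduces to ReLU(x) for a single self-looped node", {
  # Ahat = [[1]]; identity weights; fresh BN running stats (mean 0, var 1)
  # approximate the identity at inference
  d <- 4L
  set.seed(1)
  enc <- structure_encoder_params("gcn", d_in = d, layers = 1L, hidden = d)
  enc$params[["l1.W"]] <- diag(d)
  x <- c(-1, 0.5, 2, -0.3)
  g <- molecular_graph("n1", "generic", matrix(x, 1, d),
                       edges = matrix(integer(0), 0, 2))
  out <- encode_structure_gcn(g, enc)
  expect_equal(as.numeric(out), pmax(x, 0), tolerance = 1e-4)
})

test_that("normalized adjacency of a 2-node path matches the hand result", {
  Ahat <- as.matrix(muse:::normalized_adjacency(2L, matrix(c(0L, 1L), 1, 2), TRUE))
  expect_equal(Ahat, matrix(0.5, 2, 2), tolerance = 1e-12)
  # without self-loops: off-diagonal 1 (degree 1 each)
  A0 <- as.matrix(muse:::normalized_adjacency(2L, matrix(c(0L, 1L), 1, 2), FALSE))
  expect_equal(A0, matrix(c(0, 1, 1, 0), 2, 2), tolerance = 1e-12)
})

test_that("encoders are permutation equivariant at inference", {
  set.seed(2)
  enc <- structure_encoder_params("gcn", d_in = 4L, layers = 2L, hidden = 8L)
  g <- random_graph(9, d = 4, p = 0.4)
  H <- encode_structure_gcn(g, enc)
  for (rep in 1:10) {
    perm <- sample(9)
    Hp <- encode_structure_gcn(permute_graph(g, perm), enc)
    # row perm[i] of the permuted encoding equals row i of the original
    expect_equal(Hp[perm, , drop = FALSE], H, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("GIN drug encoder: isolation, isomorphism, and aggregation oracle", {
  set.seed(3)
  enc <- structure_encoder_params("gin", d_in = 3L, d_edge = 2L,
                                  layers = 2L, hidden = 6L)
  # isolated node depends only on its own features
  iso1 <- molecular_graph("a", "generic", matrix(c(1, 2, 3), 1, 3),
                          edges = matrix(integer(0), 0, 2))
  out1 <- encode_drug_gin(iso1, enc)
  iso2 <- molecular_graph("b", "generic", matrix(c(1, 2, 3), 1, 3),
                          edges = matrix(integer(0), 0, 2))
  expect_equal(encode_drug_gin(iso2, enc), out1)

  # isomorphic graphs (zero edge features, so only topology matters) give
  # identical multisets of node embeddings
  g <- random_graph(7, d = 3, p = 0.5)
  H <- encode_drug_gin(g, enc)
  perm <- sample(7)
  Hp <- encode_drug_gin(permute_graph(g, perm), enc)
  expect_equal(apply(Hp, 2, sort), apply(H, 2, sort), tolerance = 1e-8)

  # star graph: center's layer-1 aggregation equals the explicit leaf sum
  star <- molecular_graph("s", "generic",
                          matrix(stats::rnorm(12), 4, 3),
                          edges = rbind(c(0, 1), c(0, 2), c(0, 3)))
  b <- muse:::build_encoder_batch(list(star), enc)
  M <- matrix(stats::rnorm(4 * 3), 4, 3)
  tp <- muse:::ag_tape()
  msg <- pmax(M[b$src + 1L, , drop = FALSE], 0)
  agg <- as.matrix(b$Tinc %*% msg)
  loop <- M * 0
  for (k in seq_along(b$src)) {
    dst <- which(as.matrix(b$Tinc)[, k] == 1)
    loop[dst, ] <- loop[dst, ] + pmax(M[b$src[k] + 1L, ], 0)
  }
  expect_equal(agg, loop)
  expect_equal(agg[1, ], colSums(pmax(M[2:4, ], 0)))
})

test_that("geometric encoder: empty-sum case, translation invariance, oracle", {
  set.seed(4)
  enc <- structure_encoder_params("geometric", d_in = 3L, layers = 2L,
                                  hidden = 8L, knn_k = 3L, dropout = 0)
  g <- random_graph(10, d = 3, p = 0, coords = TRUE)
  H <- encode_structure_geometric(g, enc)
  # global rigid translation leaves embeddings unchanged
  gt <- g
  gt$coords <- g$coords + matrix(rep(c(11.5, -3.2, 7.7), each = 10), 10, 3)
  expect_equal(encode_structure_geometric(gt, enc), H, tolerance = 1e-9)

  # single node: no edges possible, update reduces to LayerNorm chain
  g1 <- molecular_graph("one", "generic", matrix(c(1, 2, 3), 1, 3),
                        edges = matrix(integer(0), 0, 2),
                        coords = matrix(0, 1, 3))
  expect_silent(h1 <- encode_structure_geometric(g1, enc))
  expect_equal(dim(h1), c(1L, 8L))
  expect_error(encode_structure_geometric(random_graph(5, d = 3), enc),
               "no coordinates")

  # message accumulation equals an explicit per-edge loop
  b <- muse:::build_encoder_batch(list(g), enc)
  M <- matrix(stats::rnorm(length(b$src) * 4), length(b$src), 4)
  agg <- as.matrix(b$Tinc %*% M)
  loop <- matrix(0, 10, 4)
  dst_of <- apply(as.matrix(b$Tinc), 2, which.max)
  for (k in seq_along(b$src)) loop[dst_of[k], ] <- loop[dst_of[k], ] + M[k, ]
  expect_equal(agg, loop)
})

test_that("readout sums nodes and is permutation invariant", {
  expect_equal(readout(matrix(c(1, 2, 3), 1, 3)), c(1, 2, 3))
  expect_equal(readout(matrix(1, 5, 3)), c(5, 5, 5))
  set.seed(5)
  H <- matrix(stats::rnorm(24), 8, 3)
  expect_equal(readout(H[sample(8), ]), readout(H))
  expect_error(readout(matrix(0, 0, 3)), "empty")
})

test_that("predict_pair_q is symmetric with the documented degenerate cases", {
  set.seed(6)
  ph <- pair_head_params(6L, 3L)
  a <- stats::rnorm(6); b <- stats::rnorm(6)
  p1 <- predict_pair_q(a, b, ph)
  p2 <- predict_pair_q(b, a, ph)
  expect_identical(p1$label_distribution, p2$label_distribution)
  expect_true(all(p1$label_distribution >= 0 & p1$label_distribution <= 1))

  # zero embedding absorbs: output independent of the other argument
  z1 <- predict_pair_q(rep(0, 6), b, ph)
  z2 <- predict_pair_q(rep(0, 6), stats::rnorm(6), ph)
  expect_equal(z1$label_distribution, z2$label_distribution)

  # zero classifier weights give probability 0.5 under the sigmoid head
  ph0 <- ph
  ph0$params$Wc <- ph0$params$Wc * 0
  ph0$params$bc <- ph0$params$bc * 0
  expect_equal(predict_pair_q(a, b, ph0)$label_distribution, rep(0.5, 3))

  expect_error(predict_pair_q(a, b[1:3], ph), "widths differ")
})

test_that("estep_loss decomposes linearly in alpha", {
  set.seed(7)
  preds <- list(observed = matrix(stats::runif(12), 4, 3),
                unobserved = matrix(stats::runif(9), 3, 3))
  y <- matrix(stats::rbinom(12, 1, 0.5), 4, 3)
  ps <- matrix(stats::runif(9), 3, 3)
  l0 <- estep_loss(preds, y, ps, 0)
  l1 <- estep_loss(preds, y, ps, 1)
  for (a in c(0.2, 0.5, 0.77)) {
    expect_equal(estep_loss(preds, y, ps, a), a * l1 + (1 - a) * l0,
                 tolerance = 1e-12)
  }
  # empty pseudo set behaves as the pure supervised term
  expect_equal(estep_loss(preds, y, NULL, 0.7), l0)
  # matching hard targets give (numerically) zero loss
  hard <- list(observed = y, unobserved = ps * 0)
  expect_lt(estep_loss(hard, y, ps * 0, 0.5), 1e-6)
  expect_error(estep_loss(preds, y, ps, 1.2), "alpha")
})

test_that("train_estep is reproducible and learns on a small synthetic set", {
  data <- small_dataset()
  cfg <- fast_config(seed = 3)
  set.seed(cfg$seed)
  e1 <- train_estep(data, NULL, cfg)
  set.seed(cfg$seed)
  e2 <- train_estep(data, NULL, cfg)
  expect_identical(e1$q_unobserved, e2$q_unobserved)

  # training curve: non-increasing in >= 80% of consecutive epoch pairs
  cfg2 <- muse_config(seed = 4, epochs_per_step = 40L,
                      encoder = list(hidden = 12L))
  set.seed(cfg2$seed)
  e3 <- train_estep(data, NULL, cfg2)
  dec <- mean(diff(e3$loss) <= 1e-8)
  expect_gte(dec, 0.8)

  # iteration-0 call with empty pseudo set is alpha-independent
  cfgA <- fast_config(seed = 5); cfgA$alpha <- 0
  cfgB <- fast_config(seed = 5); cfgB$alpha <- 0.9
  set.seed(5); eA <- train_estep(data, NULL, cfgA)
  set.seed(5); eB <- train_estep(data, NULL, cfgB)
  expect_identical(eA$q_unobserved, eB$q_unobserved)

  expect_error(train_estep(list(graphs = data$graphs,
                                network = local({
                                  n <- data$network
                                  n$links$status <- "unobserved"
                                  n
                                })), NULL, fast_config()),
               "no observed links")
})
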