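test_that("check_convergence implements the patience rule", {
  expect_false(check_convergence(c(0.5, 0.6, 0.7, 0.8), 2, 0.01))
  expect_true(check_convergence(rep(0.6, 3), 2, 0.01))
  expect_true(check_convergence(c(0.5, 0.6, 0.6, 0.6), 2, 0.01))
  expect_false(check_convergence(c(0.5, 0.6, 0.6), 2, 0.01))
  expect_false(check_convergence(c(0.5), 2, 0.01))
  expect_error(check_convergence(numeric(0), 2, 0.01), "empty")
})

test_that("muse_config validates its ranges", {
  expect_error(muse_config(alpha = 1.2), "alpha")
  expect_error(muse_config(beta = -0.1), "beta")
  expect_error(muse_config(t = 1), "t must")
  expect_error(muse_config(max_em_iterations = 0), "max_em_iterations")
  expect_error(muse_config(patience = 0), "patience")
})

test_that("run_em with coupling off equals the manual uncoupled pipeline", {
  data <- small_dataset()
  cfg <- fast_config(seed = 11, alpha = 0, beta = 0, t = 0,
                     max_em_iterations = 1L)
  st <- run_em(data, cfg)

  # replay the same seeded sequence manually: split, E-step, M-step
  set.seed(cfg$seed)
  split <- muse:::validation_split(data$network, cfg)
  est <- train_estep(data, NULL, cfg, train_links = split$train)
  mst <- train_mstep(data$network, est$embeddings, NULL, cfg,
                     train_links = split$train)
  expect_equal(st$structure_model$params, est$model$params, tolerance = 1e-12)
  expect_equal(st$network_model$params, mst$model$params, tolerance = 1e-12)
  expect_equal(st$predictions, mst$p_unobserved, tolerance = 1e-12)
  # t = 0: no pseudo edges were added
  expect_equal(nrow(st$augmented$pseudo_edges), 0L)
})

test_that("run_em exchanges pseudo-labels with alternating provenance", {
  data <- small_dataset()
  cfg <- fast_config(seed = 12, max_em_iterations = 3L, patience = 3L)
  st <- run_em(data, cfg)
  expect_s3_class(st, "em_state")
  expect_equal(attr(st$pseudo_from_structure, "source"), "structure_scale")
  expect_equal(attr(st$pseudo_from_network, "source"), "network_scale")
  expect_true(all(c("mstep", "next_estep") %in% st$provenance$consumer))
  # the E-step at iteration k consumes what the M-step produced at k-1
  prov <- st$provenance
  expect_true(all(prov$producer[prov$consumer == "next_estep"] == "network_scale"))
  expect_true(all(prov$producer[prov$consumer == "mstep"] == "structure_scale"))
  # history carries the baseline entry plus one value per iteration
  expect_equal(length(st$history), st$iteration + 1L)
  # augmented network never loses observed links
  expect_true(all(data$network$links$status == st$augmented$base$links$status))
  # predictions are probabilities on the unobserved links
  expect_equal(dim(st$predictions),
               c(sum(data$network$links$status == "unobserved"), 3L))
  expect_true(all(st$predictions >= 0 & st$predictions <= 1))
})

test_that("run_em and run_joint_baseline are deterministic given a seed", {
  data <- small_dataset()
  cfg <- fast_config(seed = 13)
  s1 <- run_em(data, cfg); s2 <- run_em(data, cfg)
  expect_identical(s1$history, s2$history)
  expect_identical(s1$predictions, s2$predictions)
  j1 <- run_joint_baseline(data, cfg); j2 <- run_joint_baseline(data, cfg)
  expect_identical(j1$history, j2$history)
  expect_identical(j1$predictions, j2$predictions)
})

test_that("training never touches validation or test labels", {
  data <- small_dataset()
  cfg <- fast_config(seed = 14)
  st <- run_em(data, cfg)
  unobs <- which(data$network$links$status == "unobserved")
  expect_length(intersect(st$train_idx, unobs), 0L)
  expect_length(intersect(st$train_idx, st$val_idx), 0L)
  # pseudo-labels exist exactly for the unobserved links
  expect_equal(nrow(st$pseudo_from_network), length(unobs))
})

test_that("utilization estimation reports all fields of the ablation study", {
  data <- small_dataset()
  cfg <- fast_config(seed = 15)
  st <- run_em(data, cfg)
  tr <- hidden_truth(data)
  u <- estimate_utilization(st, tr$labels)
  expect_s3_class(u, "utilization_report")
  expect_equal(u$u_structure,
               (u$f_multi - u$f_network_only) / u$f_network_only)
  expect_equal(u$u_network,
               (u$f_multi - u$f_structure_only) / u$f_structure_only)
  if (u$u_structure != 0) {
    expect_equal(u$ratio, trunc(u$u_network / u$u_structure * 100) / 100)
  }
})

test_that("targeted augmentation candidates are one-sided neighbor pairs", {
  data <- small_dataset()
  net <- data$network
  whole <- muse:::pseudo_edge_candidates(net, "whole_graph")
  targ <- muse:::pseudo_edge_candidates(net, "targeted")
  N <- length(net$entity_ids)
  expect_lt(nrow(targ), nrow(whole))
  expect_true(all((targ[, 1] * (N + 1) + targ[, 2]) %in%
                    (whole[, 1] * (N + 1) + whole[, 2])))
  # every targeted candidate pairs an endpoint of an unobserved link with a
  # one-sided neighbor of the other endpoint
  A <- as.matrix(network_adjacency(net, include_pseudo = FALSE))
  unobs <- net$links[net$links$status == "unobserved", ]
  ok <- logical(nrow(targ))
  for (r in seq_len(nrow(unobs))) {
    i <- unobs$i[r]; j <- unobs$j[r]
    ni <- which(A[i, ] != 0); nj <- which(A[j, ] != 0)
    u1 <- setdiff(setdiff(nj, ni), c(i, j))
    u2 <- setdiff(setdiff(ni, nj), c(i, j))
    keys <- c(if (length(u1)) pmin(i, u1) * (N + 1) + pmax(i, u1),
              if (length(u2)) pmin(j, u2) * (N + 1) + pmax(j, u2))
    ok <- ok | (targ[, 1] * (N + 1) + targ[, 2]) %in% keys
  }
  expect_true(all(ok))
})

test_that("joint baseline supports the structure-supervised variant", {
  data <- small_dataset()
  cfg <- fast_config(seed = 16)
  j1 <- run_joint_baseline(data, cfg)
  j2 <- run_joint_baseline(data, cfg, structure_supervision = TRUE)
  expect_false(identical(j1$predictions, j2$predictions))
  expect_equal(j1$mode, "joint")
})
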