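# Synthetic multi-scale networks with planted, independently tunable signal
# at both scales.
#
# Every entity draws a latent class z. The structure scale carries class
# signal through a planted motif subgraph (plus a motif-indicator feature
# bump) with fidelity rho_struct; the network scale carries class signal
# through stochastic-block-model assortativity and class-dependent label
# mixing with fidelity rho_net. Interaction labels depend on the latent
# classes through a K x K x C mixing tensor, so the two scales are
# complementary: structural motifs identify *which* class an entity belongs
# to, while network topology (common neighbors under assortative mixing)
# mostly reveals whether two entities share a class.

default_motifs <- function(K) {
  templates <- list(
    triangle_tail = matrix(c(0, 1, 1, 2, 2, 0, 2, 3), ncol = 2L, byrow = TRUE),
    square = matrix(c(0, 1, 1, 2, 2, 3, 3, 0), ncol = 2L, byrow = TRUE),
    clique4 = matrix(c(0, 1, 0, 2, 0, 3, 1, 2, 1, 3, 2, 3), ncol = 2L, byrow = TRUE),
    path5 = matrix(c(0, 1, 1, 2, 2, 3, 3, 4), ncol = 2L, byrow = TRUE),
    cycle5 = matrix(c(0, 1, 1, 2, 2, 3, 3, 4, 4, 0), ncol = 2L, byrow = TRUE),
    bowtie = matrix(c(0, 1, 1, 2, 2, 0, 2, 3, 3, 4, 4, 2), ncol = 2L, byrow = TRUE))
  templates[rep_len(seq_along(templates), K)]
}

default_mixing <- function(K, C) {
  mix <- array(0.15, dim = c(K, K, C))
  if (C >= 1L) {
    for (a in seq_len(K)) mix[a, a, 1L] <- 0.9          # same-class interaction type
  }
  if (C >= 2L) {
    mix[, , 2L] <- 0.9
    for (a in seq_len(K)) mix[a, a, 2L] <- 0.1          # cross-class interaction type
  }
  if (C >= 3L) {
    mix[1L, 1L, 3L] <- 0.85                             # class-identity-specific type
  }
  mix
}

#' Specify a synthetic multi-scale network
#'
#' Defaults define the package's desk-scale reference world: 300 entities
#' with structural graphs of 15-30 nodes, roughly 1500 links of which 30%
#' are hidden, and strong (0.9) but imperfect planted signal at both scales.
#'
#' @param n_entities Number of entities N.
#' @param n_classes Number of latent entity classes K.
#' @param n_label_classes Number of interaction label classes C
#'   (multilabel).
#' @param mixing `K x K x C` tensor of per-class label probabilities;
#'   defaults to a same-class / cross-class / class-identity pattern.
#' @param motifs List of K motif edge templates (0-based, 4-6 nodes).
#' @param rho_struct Probability that an entity's graph contains its own
#'   class motif rather than a random one.
#' @param rho_net Probability that a link's labels follow the mixing tensor
#'   rather than coin flips; 0 removes all label signal.
#' @param graph_size Integer range `c(min, max)` of structural graph sizes.
#' @param background_density Erdos-Renyi edge probability of the structural
#'   background graph.
#' @param n_links Expected number of interaction links.
#' @param assortativity Ratio of within-class to between-class link
#'   probability in the stochastic block model.
#' @param hidden_fraction Fraction of links marked `unobserved` (held out).
#' @param feature_noise Standard deviation of node feature noise.
#' @param motif_amplitude Feature bump added on motif nodes in the motif's
#'   indicator channel.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_entities = 300L, n_classes = 3L,
                           n_label_classes = 3L, mixing = NULL, motifs = NULL,
                           rho_struct = 0.75, rho_net = 0.9,
                           graph_size = c(15L, 30L),
                           background_density = 0.08, n_links = 1500L,
                           assortativity = 8, hidden_fraction = 0.3,
                           feature_noise = 0.5, motif_amplitude = 1.5,
                           seed = 1L) {
  if (hidden_fraction <= 0 || hidden_fraction >= 1) {
    stop("synthetic_spec: hidden_fraction must lie in (0,1)")
  }
  if (is.null(mixing)) mixing <- default_mixing(n_classes, n_label_classes)
  if (is.null(motifs)) motifs <- default_motifs(n_classes)
  stopifnot(length(motifs) == n_classes,
            all(dim(mixing) == c(n_classes, n_classes, n_label_classes)),
            all(mixing >= 0 & mixing <= 1))
  structure(list(n_entities = as.integer(n_entities),
                 n_classes = as.integer(n_classes),
                 n_label_classes = as.integer(n_label_classes),
                 mixing = mixing, motifs = motifs,
                 rho_struct = rho_struct, rho_net = rho_net,
                 graph_size = as.integer(graph_size),
                 background_density = background_density,
                 n_links = as.integer(n_links),
                 assortativity = assortativity,
                 hidden_fraction = hidden_fraction,
                 feature_noise = feature_noise,
                 motif_amplitude = motif_amplitude,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' The imbalance scenario preset
#'
#' A variant of the default world in which the network scale is easy (high
#' `rho_net`, strong assortativity) while the structure scale is noisy (low
#' `rho_struct`, high feature noise) — the regime in which greedy joint
#' multi-scale training under-uses the structure scale.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
synthetic_spec_imbalance <- function(seed = 1L, ...) {
  synthetic_spec(rho_net = 0.95, rho_struct = 0.7, feature_noise = 1.6,
                 assortativity = 10, seed = seed, ...)
}

plant_motif <- function(edges, n, motif) {
  m_nodes <- max(motif) + 1L
  anchor <- sample.int(n, m_nodes)
  rbind(edges, cbind(anchor[motif[, 1L] + 1L], anchor[motif[, 2L] + 1L]) - 1L)
}

#' Generate a synthetic multi-scale network
#'
#' Draws latent classes, structural graphs with planted motifs, stochastic-
#' block-model interaction links and class-mixed labels according to the
#' spec, and hides `hidden_fraction` of the links (`status = "unobserved"`).
#' Fully deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `graphs` (list of [molecular_graph()]), `network`
#'   (an [interaction_network()]), and `truth` (latent classes `z`, the full
#'   label matrix including hidden links, and the mixing tensor).
#' @export
generate_multiscale_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  motif_sizes <- vapply(spec$motifs, function(m) as.integer(max(m)) + 1L, integer(1))
  if (max(motif_sizes) > spec$graph_size[1L]) {
    stop("generate_multiscale_network: motif larger than the smallest graph")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  N <- spec$n_entities
  K <- spec$n_classes
  C <- spec$n_label_classes
  d_n <- K + 2L
  z <- sample.int(K, N, replace = TRUE)

  graphs <- vector("list", N)
  for (i in seq_len(N)) {
    n <- sample(seq(spec$graph_size[1L], spec$graph_size[2L]), 1L)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    bg <- pairs[stats::runif(nrow(pairs)) < spec$background_density, , drop = FALSE] - 1L
    motif_class <- if (stats::runif(1) < spec$rho_struct) z[i] else sample.int(K, 1L)
    edges <- plant_motif(bg, n, spec$motifs[[motif_class]])
    X <- matrix(stats::rnorm(n * d_n, sd = spec$feature_noise), n, d_n)
    planted <- unique(as.integer(edges[seq(nrow(bg) + 1L, nrow(edges)), ])) + 1L
    X[planted, motif_class] <- X[planted, motif_class] + spec$motif_amplitude
    # guard against isolated duplicate-free degenerate graphs: ensure >= 1 edge
    if (nrow(edges) == 0L) edges <- matrix(c(0L, 1L), 1L, 2L)
    graphs[[i]] <- molecular_graph(sprintf("E%04d", i), "generic",
                                   node_features = X, edges = edges)
  }

  # stochastic-block-model links, calibrated to the expected link count
  pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  same <- z[pairs[, 1L]] == z[pairs[, 2L]]
  w_in <- mean(same)
  p_bar <- spec$n_links / nrow(pairs)
  p_out <- p_bar / (w_in * spec$assortativity + (1 - w_in))
  p_in <- min(spec$assortativity * p_out, 1)
  keep <- stats::runif(nrow(pairs)) < ifelse(same, p_in, p_out)
  li <- pairs[keep, 1L]; lj <- pairs[keep, 2L]
  M <- length(li)

  follow <- stats::runif(M) < spec$rho_net
  labels <- matrix(0, M, C)
  for (m in seq_len(M)) {
    pr <- if (follow[m]) spec$mixing[z[li[m]], z[lj[m]], ] else rep(0.5, C)
    labels[m, ] <- as.numeric(stats::runif(C) < pr)
  }

  hidden <- sample.int(M, floor(spec$hidden_fraction * M))
  status <- rep("observed", M)
  status[hidden] <- "unobserved"
  space <- label_space("multilabel", classes = sprintf("type%d", seq_len(C)))
  links <- data.frame(i = li, j = lj, status = status,
                      confidence = ifelse(status == "observed", 1, 0))
  visible <- labels
  visible[hidden, ] <- 0  # hidden links carry no visible label
  network <- interaction_network(sprintf("E%04d", seq_len(N)), space, links,
                                 visible)
  list(graphs = graphs, network = network,
       truth = list(z = z, labels = labels, mixing = spec$mixing))
}

#' Partition links into train and test sets
#'
#' `random` draws a uniform link sample; `bfs`/`dfs` grow a node set by
#' breadth-/depth-first traversal from a random seed node and take the links
#' incident to visited nodes, producing clustered, harder held-out regions.
#' When a connected component is exhausted before the fraction is reached,
#' the traversal restarts from a fresh random node.
#'
#' @param network An [interaction_network()].
#' @param strategy `"random"`, `"bfs"` or `"dfs"`.
#' @param test_fraction Fraction of links in the test set, in `(0, 1)`.
#' @param seed Integer seed.
#' @return List with integer link-row indices `train_idx`, `test_idx`, and
#'   the `visited` node set (traversal strategies only).
#' @export
split_links <- function(network, strategy = c("random", "bfs", "dfs"),
                        test_fraction = 0.2, seed = 1L) {
  strategy <- match.arg(strategy)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("split_links: test_fraction must lie in (0,1)")
  }
  M <- nrow(network$links)
  target <- max(1L, floor(test_fraction * M))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  if (strategy == "random") {
    test <- sort(sample.int(M, target))
    return(list(train_idx = setdiff(seq_len(M), test), test_idx = test,
                visited = integer(0)))
  }
  N <- length(network$entity_ids)
  adj <- vector("list", N)
  for (r in seq_len(M)) {
    adj[[network$links$i[r]]] <- c(adj[[network$links$i[r]]], network$links$j[r])
    adj[[network$links$j[r]]] <- c(adj[[network$links$j[r]]], network$links$i[r])
  }
  visited <- logical(N)
  visit_order <- integer(0)
  frontier <- integer(0)
  test_mask <- logical(M)
  n_test <- 0L
  while (n_test < target) {
    if (length(frontier) == 0L) {
      remaining <- which(!visited)
      if (length(remaining) == 0L) break
      frontier <- remaining[sample.int(length(remaining), 1L)]
    }
    v <- if (strategy == "bfs") frontier[1L] else frontier[length(frontier)]
    frontier <- if (strategy == "bfs") frontier[-1L] else frontier[-length(frontier)]
    if (visited[v]) next
    visited[v] <- TRUE
    visit_order <- c(visit_order, v)
    inc <- which(!test_mask & (network$links$i == v | network$links$j == v))
    if (length(inc) > 0L) {
      take <- inc[seq_len(min(length(inc), target - n_test))]
      test_mask[take] <- TRUE
      n_test <- n_test + length(take)
    }
    nbrs <- adj[[v]]
    nbrs <- nbrs[!visited[nbrs]]
    if (length(nbrs) > 0L) frontier <- c(frontier, sort(unique(nbrs)))
  }
  test <- which(test_mask)
  list(train_idx = setdiff(seq_len(M), test), test_idx = test,
       visited = visit_order)
}

#' Sample negative (non-interacting) entity pairs
#'
#' Uniform sample without replacement from the unordered, non-self pairs
#' absent from the network (any link status counts as present). Used to
#' balance binary interaction tasks with an equal number of negatives.
#'
#' @param network An [interaction_network()].
#' @param count Number of pairs to draw.
#' @param seed Integer seed.
#' @return Integer matrix `count x 2` of entity indices (`i < j`).
#' @export
sample_negative_pairs <- function(network, count, seed = 1L) {
  N <- length(network$entity_ids)
  linked <- matrix(FALSE, N, N)
  linked[cbind(network$links$i, network$links$j)] <- TRUE
  cand <- which(upper.tri(linked) & !linked, arr.ind = TRUE)
  if (count > nrow(cand)) {
    stop(sprintf("sample_negative_pairs: requested %d negatives but only %d non-linked pairs exist",
                 count, nrow(cand)))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sel <- sample.int(nrow(cand), count)
  out <- cand[sel, , drop = FALSE]
  colnames(out) <- c("i", "j")
  out
}
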