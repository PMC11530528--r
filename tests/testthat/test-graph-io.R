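test_that("read_interaction_table builds, dedupes and validates networks", {
  sp <- label_space("multilabel", c("binding", "catalysis"))
  path <- write_tiny_table(c("P1\tP2\tbinding", "P2\tP3\tcatalysis",
                             "P3\tP4\tbinding,catalysis"))
  net <- read_interaction_table(path, sp)
  expect_s3_class(net, "interaction_network")
  expect_length(net$entity_ids, 4L)
  expect_equal(nrow(net$links), 3L)
  expect_true(all(net$links$status == "observed"))
  expect_equal(net$labels[3, ], c(1, 1))

  # self-interaction forbidden
  expect_error(read_interaction_table(
    write_tiny_table("P1\tP1\tbinding"), sp), "self-interaction")

  # unknown label token names the row
  expect_error(read_interaction_table(
    write_tiny_table(c("P1\tP2\tbinding", "P2\tP3\tfoo")), sp),
    "unknown label token 'foo' at row 2")

  # duplicate pair with identical labels collapses; count matches the
  # set-of-canonical-pairs oracle
  rows <- c("A\tB\tbinding", "B\tA\tbinding", "B\tC\tcatalysis")
  oracle_pairs <- unique(t(apply(rbind(c("A", "B"), c("B", "A"), c("B", "C")),
                                 1L, sort)))
  net2 <- read_interaction_table(write_tiny_table(rows), sp)
  expect_equal(nrow(net2$links), nrow(oracle_pairs))

  # conflicting duplicate labels are an error
  expect_error(read_interaction_table(
    write_tiny_table(c("A\tB\tbinding", "B\tA\tcatalysis")), sp),
    "conflicting")
})

test_that("interaction tables round-trip with status column", {
  sp <- label_space("multilabel", c("t1", "t2"))
  path <- write_tiny_table(c("A\tB\tt1\tobserved", "B\tC\tt2\tunobserved"))
  net <- read_interaction_table(path, sp)
  expect_equal(net$links$status, c("observed", "unobserved"))
  out <- tempfile()
  write_interaction_table(net, out)
  net2 <- read_interaction_table(out, sp)
  expect_equal(net2$links, net$links)
  expect_equal(net2$labels, net$labels)
})

test_that("network adjacency is symmetric with zero diagonal", {
  for (s in 1:5) {
    set.seed(s)
    N <- 12L
    pr <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
    sel <- pr[sample(nrow(pr), 15L), ]
    links <- data.frame(i = sel[, 1], j = sel[, 2],
                        status = sample(c("observed", "unobserved", "pseudo"),
                                        15L, replace = TRUE),
                        confidence = 1)
    links$confidence[links$status != "observed"] <- 0.5
    net <- interaction_network(sprintf("e%d", 1:N), label_space("binary"),
                               links, matrix(1, 15L, 1L))
    A <- as.matrix(network_adjacency(net))
    expect_equal(A, t(A))
    expect_true(all(diag(A) == 0))
    expect_equal(sum(A) / 2, sum(links$status != "unobserved"))
  }
})

test_that("parse_structure_chain extracts C-alpha traces from PDB fixtures", {
  coords <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  pdb <- tempfile(fileext = ".pdb")
  muse:::write_pdb_chain(pdb, "ACD", coords, chain_id = "A")
  ch <- parse_structure_chain(pdb, "A")
  expect_equal(ch$sequence, "ACD")
  expect_equal(ch$coords, coords, tolerance = 1e-6)

  # residue lacking a C-alpha is dropped with a warning
  pdb2 <- tempfile(fileext = ".pdb")
  muse:::write_pdb_chain(pdb2, "ACD", coords, chain_id = "A", skip_ca = 2L)
  expect_warning(ch2 <- parse_structure_chain(pdb2, "A"), "lacking a C-alpha")
  expect_equal(ch2$sequence, "AD")
  expect_equal(nrow(ch2$coords), 2L)

  # missing chain error names the available chains
  expect_error(parse_structure_chain(pdb, "Z"), "available chains: A")
})

test_that("build_contact_graph uses a strict 10 A threshold", {
  two <- function(d) matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(nrow(build_contact_graph("AC", two(9.5))$edges), 1L)
  expect_equal(nrow(build_contact_graph("AC", two(10.5))$edges), 0L)
  expect_equal(nrow(build_contact_graph("AC", two(10.0))$edges), 0L) # strict <
  expect_equal(nrow(build_contact_graph("A", matrix(0, 1, 3))$edges), 0L)
  expect_error(build_contact_graph("", matrix(0, 0, 3)), "empty")
})

test_that("contact graphs match the brute-force distance oracle", {
  set.seed(7)
  for (rep in 1:20) {
    L <- sample(5:50, 1)
    coords <- matrix(stats::rnorm(L * 3, sd = 6), L, 3)
    g <- build_contact_graph(paste(rep("A", L), collapse = ""), coords)
    D <- as.matrix(dist(coords))
    oracle <- which(upper.tri(D) & D < 10, arr.ind = TRUE)
    oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE] - 1L
    expect_equal(unname(g$edges), unname(cbind(oracle[, 1], oracle[, 2])))
  }
})

test_that("build_knn_graph returns k nearest with deterministic ties", {
  # three collinear points: middle point 1 A from both ends; ties to lower index
  coords <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3, byrow = TRUE)
  e <- build_knn_graph(coords, 1)
  nb <- function(i) unname(e[e[, "to"] == i - 1L, "from"])
  expect_equal(nb(1), 1L)  # endpoint picks the middle
  expect_equal(nb(3), 1L)
  expect_equal(nb(2), 0L)  # middle ties broken by lower index

  # k = L - 1 gives the complete directed graph
  set.seed(1)
  c2 <- matrix(stats::rnorm(15), 5, 3)
  e2 <- build_knn_graph(c2, 4)
  expect_equal(nrow(e2), 20L)

  expect_error(build_knn_graph(c2, 0), "positive")
  expect_error(build_knn_graph(c2, 5), "smaller")

  # 30 random points, k = 5: neighbor sets equal brute-force sorted rows
  set.seed(2)
  c3 <- matrix(stats::rnorm(90), 30, 3)
  e3 <- build_knn_graph(c3, 5)
  D <- as.matrix(dist(c3))
  for (i in 1:30) {
    d <- D[i, ]; d[i] <- Inf
    oracle <- sort(order(d, seq_len(30))[1:5] - 1L)
    expect_equal(sort(e3[e3[, "to"] == i - 1L, "from"]), oracle)
  }
})

test_that("featurize_residues maps codes to the 7-property table", {
  f <- featurize_residues("AAA")
  expect_equal(dim(f), c(3L, 7L))
  expect_equal(f[1, ], f[3, ])
  expect_warning(f2 <- featurize_residues("AXA"), "non-standard")
  expect_equal(unname(f2[2, ]), rep(0, 7))
  expect_equal(f2[1, ], f2[3, ])
  expect_error(featurize_residues(""), "nonempty")
  tab <- residue_feature_table()
  expect_equal(dim(tab), c(20L, 7L))
  expect_setequal(rownames(tab), strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
})

test_that("SMILES parsing produces correct atom/bond graphs", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  g1 <- molecular_graph_from_line_notation("C")
  expect_equal(nrow(g1$node_features), 1L)
  expect_equal(nrow(g1$edges), 0L)

  g2 <- molecular_graph_from_line_notation("CCO")
  expect_equal(nrow(g2$node_features), 3L)
  expect_equal(nrow(g2$edges), 2L)

  g3 <- molecular_graph_from_line_notation("c1ccccc1")
  expect_equal(nrow(g3$node_features), 6L)
  expect_equal(nrow(g3$edges), 6L)
  expect_true(all(g3$node_features[, "aromatic"] == 1))
  expect_true(all(g3$edge_features[, "aromatic"] == 1))

  expect_error(molecular_graph_from_line_notation("not_a_molecule("),
               "cannot parse")
})

test_that("graph interchange round-trips losslessly", {
  set.seed(3)
  g <- random_graph(8, d = 5, coords = TRUE)
  p1 <- tempfile(fileext = ".json")
  write_graph_interchange(g, p1)
  g2 <- read_graph_interchange(p1)
  expect_equal(g2$node_features, g$node_features)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$coords, g$coords)  # full precision
  expect_equal(g2$entity_id, g$entity_id)

  # re-serialization is byte-identical (reader determinism)
  p2 <- tempfile(fileext = ".json")
  write_graph_interchange(g2, p2)
  expect_identical(readLines(p1), readLines(p2))

  # schema guards
  obj <- jsonlite::fromJSON(readLines(p1))
  obj$edges <- NULL
  p3 <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), p3)
  expect_error(read_graph_interchange(p3), "missing required key 'edges'")
  obj2 <- jsonlite::fromJSON(readLines(p1))
  obj2$schema <- "muse-graph/99"
  writeLines(jsonlite::toJSON(obj2, auto_unbox = TRUE), p3)
  expect_error(read_graph_interchange(p3), "schema-version mismatch")
})

test_that("molecular_graph canonicalizes and validates edges", {
  g <- molecular_graph("x", "generic", matrix(0, 4, 2),
                       edges = rbind(c(2, 0), c(0, 2), c(3, 1)))
  expect_equal(g$edges, rbind(c(0L, 2L), c(1L, 3L)))
  expect_error(molecular_graph("x", "generic", matrix(0, 3, 2),
                               edges = rbind(c(0, 3))), "out of range")
  expect_error(molecular_graph("x", "generic", matrix(0, 3, 2),
                               edges = rbind(c(1, 1))), "self-loop")
})
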