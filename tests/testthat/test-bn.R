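test_that("family score matches the closed-form Dirichlet-multinomial", {
  fp <- fp_named(matrix(c(1L, 0L), ncol = 1), "a_b")
  # single binary node, no parents, column [1,0], ess = 1:
  # log[ B(0.5+1, 0.5+1) / B(0.5, 0.5) ]
  expect_equal(family_score(fp, "a_b", ess = 1),
               lbeta(1.5, 1.5) - lbeta(0.5, 0.5))
  empty <- fp_named(matrix(integer(0), ncol = 2), c("a_b", "c_d"))
  expect_equal(family_score(empty, "a_b"), 0)
  expect_error(family_score(fp, "a_b", parents = "a_b"), "own parent")
  fp2 <- fp_named(cbind(c(1L, 0L), c(0L, 1L)), c("a_b", "c_d"))
  expect_error(family_score(fp2, "a_b", parents = "c_d", max_parents = 0),
               "exceeds cap")
})

test_that("an uninformative parent of a constant child is penalized on average", {
  # brute-force over all 16 possible 4-row parent columns: the expected
  # parent-conditional score of a constant child sits below its parent-free
  # score (individual splits can gain from smoothing, the average cannot)
  child <- rep(1L, 4)
  deltas <- vapply(0:15, function(code) {
    parent <- as.integer(intToBits(code)[1:4])
    fp <- fp_named(cbind(child, parent), c("a_b", "c_d"))
    family_score(fp, "a_b", parents = "c_d") - family_score(fp, "a_b")
  }, numeric(1))
  expect_lt(mean(deltas), 0)
})

test_that("the network score decomposes over families", {
  fx <- make_interface_fixture(n_nodes = 6, n_frames = 200, seed = 2)
  fp <- fx$fingerprints
  empty_net <- contact_bn(fp, data.frame(from = character(0), to = character(0)))
  expect_equal(empty_net$score,
               sum(vapply(node_labels(fp), function(v) family_score(fp, v),
                          numeric(1))))
  expect_error(
    contact_bn(fp, data.frame(from = node_labels(fp)[c(1, 2)],
                              to = node_labels(fp)[c(2, 1)])),
    "cyclic")
})

test_that("removing an edge changes the score by strength times frames", {
  fx <- make_interface_fixture(n_nodes = 8, n_frames = 500, seed = 4)
  fp <- fx$fingerprints
  net <- learn_structure(fp, restarts = 5, seed = 1)
  skip_if(nrow(net$edges) == 0)
  e <- net$edges[1, ]
  reduced <- net$edges[-1, c("from", "to")]
  net_minus <- contact_bn(fp, reduced)
  expect_equal(net$score - net_minus$score, e$strength * n_frames(fp),
               tolerance = 1e-8)
  expect_error(edge_strength(net, fp, net$nodes[1], net$nodes[1]), "not in network")
})

test_that("Markov-equivalent orientations score identically", {
  set.seed(5)
  a <- rbinom(400, 1, 0.5)
  b <- ifelse(runif(400) < 0.85, a, 1 - a)
  fp <- fp_named(cbind(a, b), c("a_b", "c_d"))
  ab <- contact_bn(fp, data.frame(from = "a_b", to = "c_d"))
  ba <- contact_bn(fp, data.frame(from = "c_d", to = "a_b"))
  expect_equal(ab$score, ba$score, tolerance = 1e-12)
})

test_that("learning recovers a deterministic copy as exactly one edge", {
  set.seed(42)
  a <- rbinom(1000, 1, 0.5)
  fp <- fp_named(cbind(a, a), c("a_b", "c_d"))
  net <- learn_structure(fp, restarts = 5, seed = 1)
  expect_equal(nrow(net$edges), 1)
  # strength approaches the mutual information of a deterministic binary
  # relation, log 2 per observation, up to Dirichlet smoothing
  expect_equal(net$edges$strength, log(2), tolerance = 0.01)
  # per-observation strengths are stable under duplicating the data
  fp2 <- fp_named(rbind(fp$values, fp$values), c("a_b", "c_d"))
  net2 <- learn_structure(fp2, restarts = 5, seed = 1)
  expect_equal(net2$edges$strength, net$edges$strength, tolerance = 0.005)
})

test_that("independent fair coins yield an empty network", {
  set.seed(7)
  fp <- fp_named(cbind(rbinom(1000, 1, 0.5), rbinom(1000, 1, 0.5)),
                 c("a_b", "c_d"))
  net <- learn_structure(fp, restarts = 5, seed = 1)
  expect_equal(nrow(net$edges), 0)
  # independent oracle: among the 3 two-node structures the empty one wins
  ex <- exhaustive_best_score(fp)
  expect_equal(net$score, ex$score, tolerance = 1e-9)
})

test_that("hill climbing attains the exhaustive optimum on 3 nodes", {
  for (s in 1:5) {
    dag <- sample_random_dag(3, 0.5, seed = s)
    mod <- planted_model(dag$parents, nodes = c("a_b", "c_d", "e_f"),
                         n_frames = 500, seed = 100 + s)
    fp <- sample_fingerprints(mod)
    net <- learn_structure(fp, restarts = 10, seed = s)
    ex <- exhaustive_best_score(fp)
    expect_equal(ex$n_dags, 25)
    expect_equal(net$score, ex$score, tolerance = 1e-9)
  }
})

test_that("learned networks are acyclic and locally optimal", {
  fx <- make_interface_fixture(n_nodes = 10, n_frames = 800, seed = 6)
  fp <- fx$fingerprints
  net <- learn_structure(fp, restarts = 10, seed = 2)
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     vertices = net$nodes)
  expect_true(igraph::is_dag(g)) # independent acyclicity check
  # no single-edge addition improves the score
  labels <- net$nodes
  for (u in labels) for (v in labels) {
    if (u == v || u %in% net$parents[[v]]) next
    cand <- rbind(net$edges[, c("from", "to")], data.frame(from = u, to = v))
    gc2 <- igraph::graph_from_data_frame(cand, vertices = labels)
    if (!igraph::is_dag(gc2)) next
    expect_lte(contact_bn(fp, cand)$score, net$score + 1e-6)
  }
})

test_that("learning is deterministic given seed, and degenerate data errors", {
  fx <- make_interface_fixture(n_nodes = 8, n_frames = 300, seed = 9)
  n1 <- learn_structure(fx$fingerprints, restarts = 8, seed = 3)
  n2 <- learn_structure(fx$fingerprints, restarts = 8, seed = 3)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$score, n2$score)

  const <- fp_named(cbind(rep(1L, 20), rep(0L, 20)), c("a_b", "c_d"))
  expect_error(learn_structure(const), "degenerate")
})

test_that("constant columns stay isolated and flagged", {
  set.seed(8)
  a <- rbinom(500, 1, 0.5)
  b <- ifelse(runif(500) < 0.9, a, 1 - a)
  fp <- fp_named(cbind(a, b, rep(1L, 500)), c("a_b", "c_d", "e_f"))
  net <- learn_structure(fp, restarts = 5, seed = 1)
  expect_equal(net$meta$constant_nodes, "e_f")
  expect_false("e_f" %in% c(net$edges$from, net$edges$to))
  expect_true("e_f" %in% net$nodes)
})
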