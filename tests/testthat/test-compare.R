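bn_from_parents <- function(parents, labels) {
  # data-free carrier for moralization tests
  edges <- do.call(rbind, lapply(seq_along(parents), function(v) {
    if (!length(parents[[v]])) return(NULL)
    data.frame(from = labels[parents[[v]]], to = labels[v],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) edges <- data.frame(from = character(0), to = character(0))
  structure(list(nodes = labels,
                 edges = edges,
                 parents = stats::setNames(lapply(parents, function(p) labels[p]),
                                           labels)),
            class = "contact_bn")
}

lab5 <- paste0(1:5, "×50_G.A1.0", 1:5)

test_that("moralization marries co-parents and drops directions", {
  # collider a -> c <- b
  mg <- moralize(bn_from_parents(list(integer(0), integer(0), c(1L, 2L)), lab5[1:3]))
  expect_equal(moral_edge_keys(mg, lab5[1:3]), c("1-2", "1-3", "2-3"))
  # chain a -> b -> c: single parents, no marriage
  mg2 <- moralize(bn_from_parents(list(integer(0), 1L, 2L), lab5[1:3]))
  expect_equal(moral_edge_keys(mg2, lab5[1:3]), c("1-2", "2-3"))
  # already-married parents are not duplicated
  mg3 <- moralize(bn_from_parents(list(integer(0), 1L, c(1L, 2L)), lab5[1:3]))
  expect_equal(moral_edge_keys(mg3, lab5[1:3]), c("1-2", "1-3", "2-3"))
})

test_that("moralization equals brute force on all DAGs up to 4 nodes", {
  for (n in 1:4) {
    labels <- lab5[1:n]
    for (parents in enumerate_dags(n)) {
      mg <- moralize(bn_from_parents(parents, labels))
      bf <- brute_force_moral(parents)
      bf_keys <- if (nrow(bf)) {
        sort(paste(pmin(bf[, 1], bf[, 2]), pmax(bf[, 1], bf[, 2]), sep = "-"))
      } else character(0)
      expect_equal(moral_edge_keys(mg, labels), bf_keys)
    }
  }
})

moral_from_pairs <- function(pairs, labels) {
  edges <- if (length(pairs)) {
    do.call(rbind, lapply(pairs, function(p) {
      data.frame(a = min(labels[p]), b = max(labels[p]), stringsAsFactors = FALSE)
    }))
  } else data.frame(a = character(0), b = character(0))
  structure(list(nodes = labels, edges = edges, source = NA), class = "moral_graph")
}

test_that("common subgraph keeps supported edges and the largest component", {
  g1 <- moral_from_pairs(list(c(1, 2), c(2, 3), c(4, 5)), lab5)
  g2 <- moral_from_pairs(list(c(1, 2), c(2, 3)), lab5)
  g3 <- moral_from_pairs(list(c(1, 2), c(4, 5)), lab5)
  cs <- common_subgraph(list(g1, g2, g3), min_support = 2)
  # edges 1-2 (support 3), 2-3 (2), 4-5 (2): component {1,2,3} is larger
  expect_setequal(cs$nodes, lab5[1:3])
  expect_equal(nrow(cs$edges), 2)
  expect_equal(sort(cs$edges$support), c(2L, 3L))

  # identical graphs reproduce themselves
  cs2 <- common_subgraph(list(g2, g2), min_support = 2)
  expect_equal(nrow(cs2$edges), 2)

  # edge-disjoint graphs leave nothing
  d1 <- moral_from_pairs(list(c(1, 2)), lab5)
  d2 <- moral_from_pairs(list(c(3, 4)), lab5)
  expect_equal(nrow(common_subgraph(list(d1, d2), 2)$edges), 0)

  expect_error(common_subgraph(list(g1, g2), min_support = 3), "min_support")
})

test_that("raising min_support never adds edges (monotonicity)", {
  set.seed(3)
  graphs <- lapply(1:4, function(i) {
    pairs <- unique(lapply(1:6, function(j) sort(sample(5, 2))))
    moral_from_pairs(pairs, lab5)
  })
  prev <- Inf
  for (ms in 1:4) {
    cur <- nrow(common_subgraph(graphs, ms)$edges)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("Markov neighborhood is adjacency, not the Markov blanket", {
  chain <- bn_from_parents(list(integer(0), 1L, 2L), lab5[1:3])
  expect_setequal(markov_neighborhood(chain, lab5[2]), lab5[c(1, 3)])
  collider <- bn_from_parents(list(integer(0), integer(0), c(1L, 2L)), lab5[1:3])
  expect_equal(markov_neighborhood(collider, lab5[1]), lab5[3]) # co-parent excluded
  iso <- bn_from_parents(list(integer(0), integer(0)), lab5[1:2])
  expect_length(markov_neighborhood(iso, lab5[1]), 0)
  expect_error(markov_neighborhood(chain, "9×99_G.Z9.99"), "unknown node")
})

test_that("empirical joints normalize, smooth, and respect the state cap", {
  fp <- fp_named(matrix(rep(c(1L, 0L), each = 6), nrow = 6), c("a_b", "c_d"))
  j0 <- empirical_joint(fp, c("a_b", "c_d"), pseudocount = 0)
  expect_equal(sum(j0$prob), 1, tolerance = 1e-12)
  expect_equal(j0$prob[2], 1) # state a=1, c=0 is a point mass
  js <- empirical_joint(fp, c("a_b", "c_d"), pseudocount = 0.5)
  expect_equal(sum(js$prob), 1, tolerance = 1e-12)
  expect_true(all(js$prob > 0))
  none <- fp_named(matrix(integer(0), ncol = 2), c("a_b", "c_d"))
  expect_error(empirical_joint(none, "a_b", pseudocount = 0), "undefined")
  expect_error(empirical_joint(fp, c("a_b", "c_d"), state_cap = 2), "cap")

  # law of large numbers: uniform joint at m = 2, n = 10000
  set.seed(9)
  big <- fp_named(cbind(rbinom(10000, 1, 0.5), rbinom(10000, 1, 0.5)),
                  c("a_b", "c_d"))
  ju <- empirical_joint(big, c("a_b", "c_d"))
  expect_true(all(abs(ju$prob - 0.25) < 0.02))
})

test_that("JSD is zero on identity, ln 2 on disjoint supports, and symmetric", {
  fp <- fp_named(cbind(rbinom(50, 1, 0.5), rbinom(50, 1, 0.5)), c("a_b", "c_d"))
  p <- empirical_joint(fp, c("a_b", "c_d"))
  expect_equal(jsd(p, p), 0)
  ones <- fp_named(matrix(1L, 10, 1), "a_b")
  zeros <- fp_named(matrix(0L, 10, 1), "a_b")
  expect_equal(jsd(empirical_joint(ones, "a_b"), empirical_joint(zeros, "a_b")),
               log(2))
  # symmetry, nonnegativity, boundedness over random smoothed distributions
  set.seed(13)
  for (i in 1:20) {
    m1 <- fp_named(cbind(rbinom(40, 1, runif(1)), rbinom(40, 1, runif(1))),
                   c("a_b", "c_d"))
    m2 <- fp_named(cbind(rbinom(40, 1, runif(1)), rbinom(40, 1, runif(1))),
                   c("a_b", "c_d"))
    pq <- list(empirical_joint(m1, c("a_b", "c_d"), 0.5),
               empirical_joint(m2, c("a_b", "c_d"), 0.5))
    d12 <- jsd(pq[[1]], pq[[2]])
    expect_equal(d12, jsd(pq[[2]], pq[[1]]))
    expect_gte(d12, 0)
    expect_lte(d12, log(2) + 1e-12)
  }
  q <- empirical_joint(fp, "a_b")
  expect_error(jsd(p, q), "different node subsets")
})

test_that("the JSD matrix separates populations and reports exclusions", {
  # two planted models over the same node universe: a dependency chain vs
  # full independence; two independent samples from each
  labels <- paste0(1:8, "×50_G.A1.0", 1:8)
  chain <- c(list(integer(0)), lapply(1:3, identity),
             replicate(4, integer(0), simplify = FALSE))
  indep <- replicate(8, integer(0), simplify = FALSE)
  sample_pop <- function(parents, seed) {
    sample_fingerprints(planted_model(parents, nodes = labels,
                                      n_frames = 5000, seed = seed))
  }
  dsets <- list(A1 = sample_pop(chain, 311), A2 = sample_pop(chain, 312),
                B1 = sample_pop(indep, 321), B2 = sample_pop(indep, 322))
  sub <- list(nodes = labels[1:4])
  jm <- jsd_matrix(dsets[c("A1", "A2")], sub, pseudocount = 0.5)
  expect_equal(diag(jm), c(A1 = 0, A2 = 0))
  expect_equal(jm, t(jm))

  # same-model pairs diverge less than cross-model pairs
  all_named <- dsets
  jm2 <- jsd_matrix(all_named, sub, pseudocount = 0.5)
  within <- c(jm2["A1", "A2"], jm2["B1", "B2"])
  across <- c(jm2["A1", "B1"], jm2["A1", "B2"], jm2["A2", "B1"], jm2["A2", "B2"])
  expect_gt(min(across), max(within))

  # a dataset lacking a subgraph node is excluded and reported
  small <- fp_named(matrix(rbinom(20, 1, 0.5), ncol = 2),
                    c("zz_yy", labels[1]))
  jm3 <- jsd_matrix(c(dsets[1:2], list(H1 = small)), sub, pseudocount = 0.5)
  expect_equal(attr(jm3, "excluded"), "H1")
  expect_equal(nrow(jm3), 2)
  expect_error(jsd_matrix(list(A1 = dsets$A1, H1 = small), sub, 0.5),
               "fewer than 2")

  # two copies of one dataset give a zero matrix
  jm4 <- jsd_matrix(list(x = dsets$A1, y = dsets$A1), sub, pseudocount = 0.5)
  expect_true(all(jm4 == 0))
})
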