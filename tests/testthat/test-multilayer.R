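test_that("single-layer Q matches hand evaluation on the clique fixture", {
  net <- multilayerNetwork(list(conn(clique_pair())), omega = 0, gamma = 1,
                           coupling_pairs = matrix(integer(0), 0, 2))
  lab <- matrix(c(1, 1, 1, 2, 2, 2), nrow = 1)
  expect_equal(modularityQ(net, lab), 0.5, tolerance = 1e-12)
  # all nodes in one community -> Q = 0 (configuration-null identity)
  expect_equal(modularityQ(net, matrix(1, 1, 6)), 0, tolerance = 1e-12)
})

test_that("two identical layers with coupling decompose into layer terms", {
  A <- random_graph(5, seed = 3)
  l1 <- conn(A, "MID", "w1"); l2 <- conn(A, "SST", "w1")
  omega <- 0.5
  net <- multilayerNetwork(list(l1, l2), omega = omega, gamma = 1,
                           coupling_pairs = rbind(c(1, 2)))
  set.seed(4)
  lab <- matrix(sample(1:3, 10, replace = TRUE), nrow = 2)
  # independent dense evaluation: per-layer Newman-Girvan numerators plus
  # interlayer matches, over the combined 2*mu
  v <- sum(A); s <- rowSums(A)
  B <- A - outer(s, s) / v
  per_layer <- sum(B[outer(lab[1, ], lab[1, ], "==")]) +
    sum(B[outer(lab[2, ], lab[2, ], "==")])
  inter <- 2 * omega * sum(lab[1, ] == lab[2, ])
  twomu <- 2 * v + 2 * omega * 5
  expect_equal(modularityQ(net, lab), (per_layer + inter) / twomu,
               tolerance = 1e-12)
})

test_that("single-layer Q equals an independent Newman-Girvan formula", {
  for (seed in 1:20) {
    A <- random_graph(7, density = 0.6, seed = seed)
    net <- multilayerNetwork(list(conn(A)), omega = 0, gamma = 1,
                             coupling_pairs = matrix(integer(0), 0, 2))
    set.seed(seed + 100)
    lab <- sample(1:3, 7, replace = TRUE)
    expect_lt(abs(modularityQ(net, matrix(lab, 1)) -
                    newman_girvan(A, lab)), 1e-10)
  }
})

test_that("louvain recovers the unambiguous clique optimum across layers", {
  l1 <- conn(clique_pair(), "MID", "w1")
  l2 <- conn(clique_pair(), "SST", "w1")
  net <- multilayerNetwork(list(l1, l2), omega = 0.5,
                           coupling_pairs = rbind(c(1, 2)))
  res <- louvainMultilayer(net, seed = 5)
  expect_equal(length(unique(res$labels[1, 1:3])), 1)
  expect_equal(length(unique(res$labels[1, 4:6])), 1)
  # persistent across layers
  expect_equal(res$labels[1, ], res$labels[2, ])
  expect_equal(res$Q, modularityQ(net, res$labels), tolerance = 1e-9)
})

test_that("louvain is deterministic given the seed", {
  A <- random_graph(8, seed = 2)
  net <- multilayerNetwork(list(conn(A, "MID", "w1"), conn(A, "SST", "w1")),
                           omega = 0.3, coupling_pairs = rbind(c(1, 2)))
  r1 <- louvainMultilayer(net, seed = 99)
  r2 <- louvainMultilayer(net, seed = 99)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$Q, r2$Q)
})

test_that("louvain beats trivial partitions and matches brute force on toys", {
  for (seed in 1:5) {
    A1 <- random_graph(4, density = 0.8, seed = seed)
    A2 <- random_graph(4, density = 0.8, seed = seed + 50)
    net <- multilayerNetwork(list(conn(A1, "MID", "w1"),
                                  conn(A2, "SST", "w1")),
                             omega = 0.4, coupling_pairs = rbind(c(1, 2)))
    res <- louvainMultilayer(net, seed = seed)
    singletons <- matrix(seq_len(8), nrow = 2, byrow = TRUE)
    allone <- matrix(1, 2, 4)
    expect_gte(res$Q, modularityQ(net, singletons) - 1e-12)
    expect_gte(res$Q, modularityQ(net, allone) - 1e-12)
    expect_gte(res$Q, 0.999 * brute_force_q(net))
  }
})

test_that("label permutation changes neither Q nor the node metrics", {
  A <- random_graph(6, seed = 13)
  net <- multilayerNetwork(list(conn(A, "MID", "w1"), conn(A, "SST", "w1")),
                           omega = 0.2, coupling_pairs = rbind(c(1, 2)))
  set.seed(77)
  lab <- matrix(sample(1:3, 12, replace = TRUE), nrow = 2)
  relabel <- c(3, 1, 2)[lab]
  dim(relabel) <- dim(lab)
  expect_equal(modularityQ(net, lab), modularityQ(net, relabel),
               tolerance = 1e-12)
  mk_ens <- function(lbl) new("PartitionEnsemble",
                              labels = array(lbl, c(1, 2, 6)),
                              q_values = 0, layer_names = c("MID_w1", "SST_w1"),
                              parcel_ids = sprintf("p%02d", 1:6))
  e1 <- mk_ens(lab); e2 <- mk_ens(relabel)
  sys <- rep(c("a", "b"), each = 3)
  expect_equal(flexibility(e1, list(w1 = c(1, 2))),
               flexibility(e2, list(w1 = c(1, 2))))
  expect_equal(recruitment(e1, sys), recruitment(e2, sys))
})

test_that("ensemble records per-iteration Q and obeys the seed ladder", {
  l1 <- conn(clique_pair(), "MID", "w1")
  l2 <- conn(clique_pair(), "SST", "w1")
  net <- multilayerNetwork(list(l1, l2), omega = 0.5,
                           coupling_pairs = rbind(c(1, 2)))
  ens <- runEnsemble(net, n_iterations = 10, base_seed = 1)
  expect_equal(dim(partitionLabels(ens)), c(10, 2, 6))
  # unambiguous optimum: all restarts identical up to labels
  expect_equal(length(unique(qValues(ens))), 1)
  fl <- flexibility(ens, list(w1 = c(1, 2)))
  expect_true(all(fl == 0))
})

test_that("flexibility counts cross-task label changes as fractions", {
  # constructed ensemble: parcel 1 differs in 40 of 100 iterations
  labels <- array(1L, c(100, 2, 3))
  labels[1:40, 2, 1] <- 2L
  labels[, 2, 3] <- 5L   # always different
  ens <- new("PartitionEnsemble", labels = labels, q_values = numeric(100),
             layer_names = c("MID_w1", "SST_w1"),
             parcel_ids = c("a", "b", "c"))
  fl <- flexibility(ens, list(w1 = c(1, 2)))
  expect_equal(unname(fl[, "w1"]), c(0.4, 0, 1))
  expect_error(flexibility(ens, list(w1 = c(1, 3))), "valid layers")
})

test_that("recruitment is the within-system co-assignment fraction", {
  # 10 parcels, one system of 10; parcel 1 co-assigned with 3 of its 9 mates
  labels <- array(2L, c(1, 1, 10))
  labels[1, 1, 1:4] <- 1L     # parcel 1 + three mates in community 1
  ens <- new("PartitionEnsemble", labels = labels, q_values = 0,
             layer_names = "MID_w1", parcel_ids = sprintf("p%02d", 1:10))
  rc <- recruitment(ens, rep("sys", 10))
  expect_equal(unname(rc[1, 1]), 3 / 9)
  # partition equal to native systems -> recruitment 1 everywhere
  labels2 <- array(rep(c(1L, 2L), each = 5), c(1, 1, 10))
  ens2 <- new("PartitionEnsemble", labels = labels2, q_values = 0,
              layer_names = "MID_w1", parcel_ids = sprintf("p%02d", 1:10))
  rc2 <- recruitment(ens2, rep(c("a", "b"), each = 5))
  expect_true(all(rc2 == 1))
  # parcel never co-assigned with any mate -> 0
  labels3 <- labels2; labels3[1, 1, 1] <- 9L
  ens3 <- new("PartitionEnsemble", labels = labels3, q_values = 0,
              layer_names = "MID_w1", parcel_ids = sprintf("p%02d", 1:10))
  expect_equal(unname(recruitment(ens3, rep(c("a", "b"), each = 5))[1, 1]), 0)
  # singleton system is NA with a warning
  expect_warning(rs <- recruitment(ens2, c("solo", rep("rest", 9))),
                 "singleton")
  expect_true(is.na(rs[1, 1]))
})

test_that("single-layer louvain agrees with igraph on weighted graphs", {
  skip_if_not_installed("igraph")
  for (seed in c(21, 22, 23)) {
    A <- random_graph(12, density = 0.4, seed = seed)
    net <- multilayerNetwork(list(conn(A)), omega = 0, gamma = 1,
                             coupling_pairs = matrix(integer(0), 0, 2))
    res <- louvainMultilayer(net, seed = seed)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    q_ig <- igraph::modularity(g, res$labels[1, ],
                               weights = igraph::E(g)$weight)
    expect_equal(res$Q, q_ig, tolerance = 1e-10)
  }
})

test_that("empty networks are rejected", {
  z <- conn(matrix(0, 4, 4))
  net <- multilayerNetwork(list(z), omega = 0, gamma = 1,
                           coupling_pairs = matrix(integer(0), 0, 2))
  expect_error(louvainMultilayer(net), "empty network")
})
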