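test_that("propagation of identity incidence is the identity in both modes", {
  H <- diag(4)
  expect_equal(hypergraph_propagation_matrix(H, mode = "raw"), diag(4))
  expect_equal(hypergraph_propagation_matrix(H, mode = "symmetric"), diag(4))
})

test_that("raw propagation equals the brute-force double sum over hyperedges", {
  set.seed(4)
  for (i in 1:20) {
    H <- matrix(rbinom(36, 1, 0.5), 6, 6)
    W <- runif(6, 0.5, 2)
    expect_matrices_equal(hypergraph_propagation_matrix(H, W, "raw"),
                          propagation_loop_oracle(H, W), 1e-10)
  }
})

test_that("symmetric propagation on a regular hypergraph scales the raw operator by 1/(node deg * edge deg)", {
  # 6 nodes, each in exactly 2 hyperedges; each hyperedge holds 3 nodes
  H <- rbind(c(1, 0, 0, 1), c(1, 0, 0, 1), c(1, 1, 0, 0),
             c(0, 1, 1, 0), c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(unname(rowSums(H)), rep(2, 6))
  expect_equal(unname(colSums(H)), rep(3, 4))
  raw <- hypergraph_propagation_matrix(H, mode = "raw")
  sym <- hypergraph_propagation_matrix(H, mode = "symmetric")
  expect_matrices_equal(sym, raw / (2 * 3), 1e-10)
})

test_that("zero-degree nodes yield zero rows rather than division failures", {
  H <- diag(4); H[2, 2] <- 0  # node 2 isolated, hyperedge 2 empty
  G <- hypergraph_propagation_matrix(H, mode = "symmetric")
  expect_true(all(is.finite(G)))
  expect_equal(G[2, ], rep(0, 4))
  expect_error(hypergraph_propagation_matrix(matrix(0.5, 3, 3)), "binary")
})

test_that("a static identity hypergraph with identity weights is a no-op layer", {
  g <- random_dyn_hypergraph(N = 4, s = 1, Fdim = 4, seed = 2)
  g$snapshots[[1]]$incidence <- diag(4)
  g$snapshots[[1]]$edge_weights <- rep(1, 4)
  out <- evolving_hyperconv(g$node_features, g, diag(4),
                            activation = "identity",
                            normalization = "raw")
  expect_equal(out[[1]], g$node_features[[1]])
})

test_that("the vectorized evolving convolution matches the explicit loop oracle", {
  for (seed in 1:10) {
    g <- random_dyn_hypergraph(N = 5, s = 3, Fdim = 4, seed = seed)
    set.seed(seed + 100)
    P <- matrix(rnorm(4 * 3), 4, 3)
    for (norm in c("raw", "symmetric")) {
      out <- evolving_hyperconv(g$node_features, g, P, "elu", norm, "adjacent")
      ref <- hyperconv_loop_oracle(g$node_features, g, P, "elu", norm)
      for (t in 1:3) expect_matrices_equal(out[[t]], ref[[t]], 1e-6)
    }
  }
})

test_that("with one snapshot the evolving convolution equals the static layer in both temporal modes", {
  g <- random_dyn_hypergraph(N = 6, s = 1, Fdim = 5, seed = 3)
  set.seed(31)
  P <- matrix(rnorm(5 * 2), 5, 2)
  G <- hypergraph_propagation_matrix(g$snapshots[[1]]$incidence,
                                     g$snapshots[[1]]$edge_weights,
                                     "symmetric")
  static <- act_fun("elu")((G %*% g$node_features[[1]]) %*% P)
  adj <- evolving_hyperconv(g$node_features, g, P, "elu", "symmetric", "adjacent")
  all_ <- evolving_hyperconv(g$node_features, g, P, "elu", "symmetric", "all")
  expect_identical(adj[[1]], static)
  expect_identical(all_[[1]], static)
})

test_that("attention scores are softmax-normalized over each node's three-snapshot neighbourhood", {
  g <- random_dyn_hypergraph(N = 6, s = 4, Fdim = 3, seed = 5)
  H <- lapply(g$snapshots, function(sn) sn$incidence)
  set.seed(51)
  P <- matrix(rnorm(3 * 2), 3, 2)
  a <- rnorm(4)
  sc <- attention_scores(g$node_features, H, P, a)
  for (t in 1:4) {
    win <- attr(sc[[t]], "window")
    mass <- Reduce(`+`, lapply(sc[[t]], rowSums))
    expect_equal(unname(mass), rep(1, 6), tolerance = 1e-6)
    for (k in seq_along(win))
      expect_true(all(sc[[t]][[k]][H[[win[k]]] == 0] == 0))
  }
})

test_that("identical node features give uniform attention over incident pairs", {
  g <- random_dyn_hypergraph(N = 5, s = 3, Fdim = 3, seed = 6)
  X <- lapply(1:3, function(t) matrix(1, 5, 3))
  H <- lapply(g$snapshots, function(sn) sn$incidence)
  sc <- attention_scores(X, H, matrix(rnorm(6), 3, 2), rnorm(4))
  for (t in 1:3) {
    win <- attr(sc[[t]], "window")
    n_inc <- Reduce(`+`, lapply(win, function(tau) rowSums(H[[tau]])))
    for (k in seq_along(win)) {
      expected <- H[[win[k]]] / n_inc
      expect_matrices_equal(sc[[t]][[k]], expected, 1e-9)
    }
  }
})

test_that("attention scores match the explicit loop oracle", {
  for (seed in 1:10) {
    g <- random_dyn_hypergraph(N = 5, s = 3, Fdim = 4, seed = seed + 20)
    H <- lapply(g$snapshots, function(sn) sn$incidence)
    set.seed(seed)
    P <- matrix(rnorm(4 * 3), 4, 3)
    a <- rnorm(6)
    sc <- attention_scores(g$node_features, H, P, a)
    ref <- attention_loop_oracle(g$node_features, H, P, a)
    for (t in 1:3) for (k in seq_along(attr(sc[[t]], "window")))
      expect_matrices_equal(sc[[t]][[k]], ref[[t]][[k]], 1e-6)
  }
})

test_that("uniform attention reduces the attention layer to a row-normalized convolution", {
  g <- random_dyn_hypergraph(N = 5, s = 3, Fdim = 3, seed = 77)
  X <- lapply(1:3, function(t) matrix(2, 5, 3))  # identical features
  g$node_features <- X
  set.seed(78)
  P <- matrix(rnorm(3 * 2), 3, 2)
  a <- rnorm(4)
  out <- evolving_hyperatten(X, g, P, a, activation = "identity")
  H <- lapply(g$snapshots, function(sn) sn$incidence)
  W <- lapply(g$snapshots, function(sn) sn$edge_weights)
  for (t in 1:3) {
    win <- intersect((t - 1):(t + 1), 1:3)
    n_inc <- Reduce(`+`, lapply(win, function(tau) rowSums(H[[tau]])))
    agg <- 0
    for (tau in win) {
      HW <- H[[tau]] * rep(W[[tau]], each = 5)
      agg <- agg + HW %*% crossprod(H[[tau]] / n_inc, X[[tau]])
    }
    expect_matrices_equal(out[[t]], agg %*% P, 1e-9)
  }
})

test_that("with one snapshot the evolving attention equals static hypergraph attention", {
  g <- random_dyn_hypergraph(N = 6, s = 1, Fdim = 4, seed = 9)
  set.seed(91)
  P <- matrix(rnorm(4 * 2), 4, 2)
  a <- rnorm(4)
  out <- evolving_hyperatten(g$node_features, g, P, a)
  # static attention computed directly: softmax over incident edges at t=1
  H <- g$snapshots[[1]]$incidence
  sc <- attention_scores(g$node_features, list(H), P, a)
  HW <- H * rep(g$snapshots[[1]]$edge_weights, each = 6)
  ref <- act_fun("elu")(HW %*% crossprod(sc[[1]][[1]], g$node_features[[1]]) %*% P)
  expect_matrices_equal(out[[1]], ref, 1e-10)
})

test_that("layers are equivariant to node relabelling", {
  g <- random_dyn_hypergraph(N = 6, s = 3, Fdim = 4, seed = 15)
  set.seed(16)
  P <- matrix(rnorm(4 * 3), 4, 3)
  a <- rnorm(6)
  perm <- sample(6)
  gp <- g
  for (t in 1:3) {
    gp$snapshots[[t]]$incidence <- g$snapshots[[t]]$incidence[perm, perm]
    gp$snapshots[[t]]$edge_weights <- g$snapshots[[t]]$edge_weights[perm]
    gp$node_features[[t]] <- g$node_features[[t]][perm, ]
  }
  oc <- evolving_hyperconv(g$node_features, g, P)
  ocp <- evolving_hyperconv(gp$node_features, gp, P)
  oa <- evolving_hyperatten(g$node_features, g, P, a)
  oap <- evolving_hyperatten(gp$node_features, gp, P, a)
  for (t in 1:3) {
    expect_matrices_equal(ocp[[t]], oc[[t]][perm, ], 1e-10)
    expect_matrices_equal(oap[[t]], oa[[t]][perm, ], 1e-10)
  }
})

test_that("subjects with empty hyperedges still produce finite outputs", {
  g <- random_dyn_hypergraph(N = 5, s = 2, Fdim = 3, seed = 33)
  for (t in 1:2) {
    H <- matrix(0, 5, 5)
    H[1, 1] <- 1  # node 1 only; nodes 2..5 isolated
    g$snapshots[[t]]$incidence <- H
  }
  P <- matrix(rnorm(6), 3, 2)
  oc <- evolving_hyperconv(g$node_features, g, P)
  oa <- evolving_hyperatten(g$node_features, g, P, rnorm(4))
  for (t in 1:2) {
    expect_true(all(is.finite(oc[[t]])))
    expect_true(all(is.finite(oa[[t]])))
    expect_equal(unname(oa[[t]][3, ]), act_fun("elu")(c(0, 0)))
  }
})

test_that("readout pools features and returns a probability simplex", {
  state <- list(matrix(1:6 / 10, 3, 2), matrix(1, 3, 2))
  ro <- readout_and_classify(state, "mean")
  expect_equal(sum(ro$prob), 1, tolerance = 1e-9)
  expect_equal(ro$logits, (colSums(state[[1]]) + colSums(state[[2]])) / 6)
  # all-equal features: mean readout returns the shared row
  st2 <- list(matrix(rep(c(0.3, -0.2), each = 4), 4, 2))
  expect_equal(readout_and_classify(st2, "mean")$logits, c(0.3, -0.2))
  # sum mode on all-ones: s * N per dimension
  st3 <- replicate(3, matrix(1, 5, 2), simplify = FALSE)
  expect_equal(readout_and_classify(st3, "sum")$logits, c(15, 15))
})
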