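# Shared fixtures and independent oracles for the test suite.

# Small cohort used across tests (8 regions, 3 windows).
tiny_cohort <- function(seed = 3, noise_sd = 0.3) {
  generate_cohort(cohort_spec(n_per_class = 2, m_regions = 8,
                              d_timepoints = 30, n_windows = 3,
                              support_size = 2, n_varying = 2,
                              n_driven = 3, noise_sd = noise_sd,
                              seed = seed))
}

# Random dynamic hypergraph (structure drawn directly, not via the lasso),
# for layer-level tests.
random_dyn_hypergraph <- function(N = 5, s = 3, Fdim = 4, seed = 1,
                                  p_edge = 0.4, id = "rnd") {
  set.seed(seed)
  snapshots <- lapply(seq_len(s), function(t) {
    H <- matrix(rbinom(N * N, 1, p_edge), N, N)
    diag(H) <- 1
    structure(list(incidence = H, edge_weights = runif(N, 0.5, 1.5),
                   coefficients = matrix(0, N, N)),
              class = "hb_snapshot")
  })
  feats <- lapply(seq_len(s), function(t) matrix(rnorm(N * Fdim), N, Fdim))
  structure(list(snapshots = snapshots, node_features = feats,
                 window_bounds = cbind(start = seq_len(s) - 1,
                                       end = seq_len(s)),
                 subject_id = id, region_ids = paste0("r", seq_len(N)),
                 lam = NA, tau = NA),
            class = "dyn_hypergraph")
}

# Brute-force propagation: out[i,j] = sum_e H[i,e] W[e] H[j,e].
propagation_loop_oracle <- function(H, W) {
  N <- nrow(H); M <- ncol(H)
  out <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) for (e in seq_len(M))
    out[i, j] <- out[i, j] + H[i, e] * W[e] * H[j, e]
  out
}

# Loop oracle for one evolving hypergraph convolution layer (adjacent
# temporal window, explicit sums over tau, j and epsilon).
hyperconv_loop_oracle <- function(state, graphs, P, activation = "elu",
                                  normalization = "symmetric") {
  s <- length(graphs$snapshots)
  N <- nrow(state[[1]])
  sig <- act_fun(activation)
  out <- vector("list", s)
  for (t in seq_len(s)) {
    agg <- matrix(0, N, ncol(state[[1]]))
    for (tau in intersect((t - 1):(t + 1), seq_len(s))) {
      G <- hypergraph_propagation_matrix(graphs$snapshots[[tau]]$incidence,
                                         graphs$snapshots[[tau]]$edge_weights,
                                         normalization)
      for (i in seq_len(N)) for (j in seq_len(N))
        agg[i, ] <- agg[i, ] + G[i, j] * state[[tau]][j, ]
    }
    out[[t]] <- sig(agg %*% P)
  }
  out
}

# Loop oracle for the joint three-snapshot softmax attention scores.
attention_loop_oracle <- function(X, H, P, a_raw, slope = 0.2) {
  s <- length(H)
  N <- nrow(H[[1]]); M <- ncol(H[[1]])
  Fp <- ncol(P)
  a <- 1 / (1 + exp(-a_raw))
  U <- lapply(X, function(x) x %*% P)
  raw <- function(tau, j, e) {
    v <- c(U[[tau]][j, ], U[[tau]][e, ])  # centroid edge feature
    x <- sum(a * v)
    max(min(ifelse(x > 0, x, slope * x), 50), -50)
  }
  out <- vector("list", s)
  for (t in seq_len(s)) {
    win <- intersect((t - 1):(t + 1), seq_len(s))
    mats <- lapply(win, function(tau) matrix(0, N, M))
    for (j in seq_len(N)) {
      den <- 0
      for (k in seq_along(win)) {
        tau <- win[k]
        for (e in seq_len(M)) if (H[[tau]][j, e] == 1)
          den <- den + exp(raw(tau, j, e))
      }
      if (den > 0) {
        for (k in seq_along(win)) {
          tau <- win[k]
          for (e in seq_len(M)) if (H[[tau]][j, e] == 1)
            mats[[k]][j, e] <- exp(raw(tau, j, e)) / den
        }
      }
    }
    attr(mats, "window") <- win
    out[[t]] <- mats
  }
  out
}

# Coordinate-descent lasso oracle (glmnet), same objective convention.
glmnet_lasso_oracle <- function(X, y, lam) {
  fit <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
  as.numeric(stats::coef(fit))[-1]
}

expect_matrices_equal <- function(a, b, tol = 1e-8) {
  testthat::expect_lt(max(abs(a - b)), tol)
}
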