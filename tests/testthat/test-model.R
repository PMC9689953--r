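tiny_graphs <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) {
      c0 <- tiny_cohort(seed = 3)
      coh <<- list(
        graphs = build_cohort_hypergraphs(c0$subjects, window_config(3),
                                          lam = 0.1),
        labels = c0$labels)
    }
    coh
  }
})

test_that("the batched engine matches the composed reference layers for both variants", {
  dat <- tiny_graphs()
  set.seed(9)
  P1 <- matrix(rnorm(10 * 4, sd = 0.3), 10, 4)
  P2 <- matrix(rnorm(4 * 2, sd = 0.3), 4, 2)
  a1 <- runif(8, -0.5, 0.5); a2 <- runif(4, -0.5, 0.5)
  batch <- build_batch(dat$graphs, "symmetric", "centroid")
  pre <- conv_precompute(batch, "adjacent")
  zb <- list(b1 = numeric(4), b2 = numeric(2))
  fwd <- conv_forward(batch, c(list(P1 = P1, P2 = P2), zb), pre, "adjacent",
                      "elu", "mean")
  afwd <- atten_forward(batch, c(list(P1 = P1, P2 = P2, a1 = a1, a2 = a2), zb),
                        0.2, "elu", "mean")
  for (i in seq_along(dat$graphs)) {
    g <- dat$graphs[[i]]
    c1 <- evolving_hyperconv(g$node_features, g, P1, "elu", "symmetric")
    c2 <- evolving_hyperconv(c1, g, P2, "elu", "symmetric")
    expect_matrices_equal(readout_and_classify(c2, "mean")$logits,
                          fwd$logits[i, ], 1e-9)
    s1 <- evolving_hyperatten(g$node_features, g, P1, a1, "elu")
    s2 <- evolving_hyperatten(s1, g, P2, a2, "elu")
    expect_matrices_equal(readout_and_classify(s2, "mean")$logits,
                          afwd$logits[i, ], 1e-8)
  }
})

test_that("analytic gradients match finite differences for both variants", {
  dat <- tiny_graphs()
  batch <- build_batch(dat$graphs, "symmetric", "centroid")
  y <- diag(2)[match(dat$labels, sort(unique(dat$labels))), ]
  set.seed(17)
  P1 <- matrix(rnorm(10 * 4, sd = 0.3), 10, 4)
  P2 <- matrix(rnorm(4 * 2, sd = 0.3), 4, 2)
  cfg <- list(temporal_mode = "adjacent", activation = "elu",
              readout = "mean", dropout = 0, negative_slope = 0.2)
  check <- function(variant, params, cfgx = cfg) {
    pre <- if (variant == "conv") conv_precompute(batch, cfgx$temporal_mode)
    lg <- model_loss_grad(batch, params, y, variant, pre, cfgx)
    for (nm in names(params)) {
      for (k in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
        eps <- 1e-5
        pp <- params; pp[[nm]][k] <- pp[[nm]][k] + eps
        pm <- params; pm[[nm]][k] <- pm[[nm]][k] - eps
        fd <- (model_loss_grad(batch, pp, y, variant, pre, cfgx)$loss -
               model_loss_grad(batch, pm, y, variant, pre, cfgx)$loss) /
              (2 * eps)
        expect_equal(lg$grads[[nm]][k], fd, tolerance = 1e-4)
      }
    }
  }
  zb <- list(b1 = rnorm(4, sd = 0.2), b2 = rnorm(2, sd = 0.2))
  check("conv", c(list(P1 = P1, P2 = P2), zb))
  cfg_all <- cfg; cfg_all$temporal_mode <- "all"
  check("conv", c(list(P1 = P1, P2 = P2), zb), cfg_all)
  check("attention", c(list(P1 = P1, P2 = P2), zb,
                       list(a1 = runif(8, -0.5, 0.5), a2 = runif(4, -0.5, 0.5))))
})

test_that("training is deterministic under a fixed seed", {
  dat <- tiny_graphs()
  f1 <- ehgnn(dat$graphs, dat$labels, epochs = 15, seed = 4)
  f2 <- ehgnn(dat$graphs, dat$labels, epochs = 15, seed = 4)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loss_trace, f2$loss_trace)
  a1 <- ehgnn(dat$graphs, dat$labels, variant = "attention", epochs = 8,
              seed = 4)
  a2 <- ehgnn(dat$graphs, dat$labels, variant = "attention", epochs = 8,
              seed = 4)
  expect_identical(a1$params, a2$params)
})

test_that("zero epochs returns the initialized model unchanged", {
  dat <- tiny_graphs()
  f0 <- ehgnn(dat$graphs, dat$labels, epochs = 0, seed = 4)
  set.seed(4L)
  expect_identical(f0$params, init_params("conv", 10, 8, 2))
  expect_length(f0$loss_trace, 0)
})

test_that("eval-mode prediction is deterministic and returns a probability simplex", {
  dat <- tiny_graphs()
  fit <- ehgnn(dat$graphs, dat$labels, variant = "attention", epochs = 10,
               seed = 2)
  p1 <- predict(fit, dat$graphs, type = "prob")
  p2 <- predict(fit, dat$graphs, type = "prob")
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1)), rep(1, 4), tolerance = 1e-9)
  cl <- predict(fit, dat$graphs)
  expect_s3_class(cl, "factor")
  expect_length(cl, 4)
})

test_that("a separable noiseless cohort is fit to perfect training accuracy", {
  coh <- generate_cohort(cohort_spec(n_per_class = 10, m_regions = 12,
                                     d_timepoints = 90, n_windows = 3,
                                     support_size = 3, n_varying = 3,
                                     noise_sd = 0, seed = 6))
  graphs <- build_cohort_hypergraphs(coh$subjects, window_config(3),
                                     lam = 0.05)
  fit <- ehgnn(graphs, coh$labels, epochs = 150, dropout = 0, seed = 1)
  expect_equal(fit$train_accuracy, 1)
})

test_that("degenerate configurations are rejected", {
  dat <- tiny_graphs()
  expect_error(ehgnn(dat$graphs, rep(1, 4)), "single class")
  expect_error(ehgnn(dat$graphs, dat$labels[1:2]), "one label per subject")
  expect_error(ehgnn(dat$graphs, dat$labels, dropout = 1), "dropout")
  expect_error(ehgnn(dat$graphs, dat$labels, hidden_dim = 0), "hidden_dim")
})

test_that("model methods print, summarize, plot and expose coefficients", {
  dat <- tiny_graphs()
  fit <- ehgnn(dat$graphs, dat$labels, epochs = 5, seed = 1)
  expect_output(print(fit), "convolutional")
  expect_output(summary(fit), "parameters")
  expect_named(coef(fit), c("P1", "P2", "b1", "b2"))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
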