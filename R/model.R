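#' Fit an evolving hypergraph neural network
#'
#' Trains a two-layer evolving hypergraph network for subject-level
#' classification of dynamic hyperbrain networks. The `"conv"` variant is
#' an evolving hypergraph convolution: the feature of node i at snapshot t
#' aggregates its hyperedge neighbourhood over snapshots t-1, t, t+1
#' (degree-normalized by default). The `"attention"` variant replaces the
#' aggregation-side incidence entries by softmax attention scores over
#' each node's incident hyperedges across the same snapshot window, with
#' dropout on layer inputs and on the attention transition matrix during
#' training. Both end in a mean (or sum) readout over nodes and snapshots
#' followed by a softmax classifier, trained with Adam on the
#' cross-entropy loss plus L2 weight regularization.
#'
#' With a single snapshot (s = 1) the evolving layers reduce exactly to
#' static hypergraph convolution / attention, which serves as the static
#' baseline configuration.
#'
#' @param x list of [build_dynamic_hypergraph()] objects, one per subject,
#'   sharing N, s and feature dimension.
#' @param labels vector (or factor) of class labels, one per subject; at
#'   least two classes must be present.
#' @param variant `"conv"` or `"attention"`.
#' @param hidden_dim hidden representation width (default 8).
#' @param dropout dropout rate in \[0, 1), applied to layer inputs and (in
#'   the attention variant) to the attention transition matrix during
#'   training. Default: 0.6 for the attention variant, 0 for the
#'   convolution variant.
#' @param epochs full-batch training epochs (default 200); `epochs = 0`
#'   returns the initialized model unchanged.
#' @param learning_rate Adam learning rate (default 0.005).
#' @param weight_decay L2 coefficient added to gradients as
#'   `weight_decay * parameter` (default 3e-4).
#' @param activation hidden nonlinearity, default `"elu"`.
#' @param negative_slope LeakyReLU slope for attention scores (default 0.2).
#' @param normalization propagation normalization for the conv variant:
#'   `"symmetric"` (default) or `"raw"`.
#' @param temporal_mode `"adjacent"` (default) or `"all"` snapshot
#'   aggregation for the conv variant.
#' @param edge_feature_mode hyperedge feature for attention scores:
#'   `"centroid"` (default) or `"member_mean"`.
#' @param readout `"mean"` (default) or `"sum"`.
#' @param seed integer seed fixing initialization and dropout masks.
#' @param verbose print the loss every 50 epochs.
#' @return an object of class `ehgnn` with components `params` (fitted
#'   weights), `loss_trace`, `classes`, `config`, and the training-set
#'   accuracy `train_accuracy`.
#' @seealso [predict.ehgnn()], [cross_validate()]
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n_per_class = 5, m_regions = 10,
#'                                       d_timepoints = 60, n_windows = 3,
#'                                       support_size = 3, n_varying = 2,
#'                                       seed = 7))
#' graphs <- build_cohort_hypergraphs(cohort$subjects, window_config(3))
#' fit <- ehgnn(graphs, cohort$labels, epochs = 40, seed = 7)
#' print(fit)
#' }
#' @export
ehgnn <- function(x, labels, variant = c("conv", "attention"),
                  hidden_dim = 8, dropout = NULL, epochs = 200,
                  learning_rate = 0.005, weight_decay = 3e-4,
                  activation = "elu", negative_slope = 0.2,
                  normalization = c("symmetric", "raw"),
                  temporal_mode = c("adjacent", "all"),
                  edge_feature_mode = c("centroid", "member_mean"),
                  readout = c("mean", "sum"), seed = 1, verbose = FALSE) {
  variant <- match.arg(variant)
  normalization <- match.arg(normalization)
  temporal_mode <- match.arg(temporal_mode)
  edge_feature_mode <- match.arg(edge_feature_mode)
  readout <- match.arg(readout)
  if (length(x) == 0 || length(labels) != length(x))
    stop("configuration error: need one label per subject")
  if (is.null(dropout)) dropout <- if (variant == "attention") 0.6 else 0
  if (hidden_dim < 1) stop("configuration error: hidden_dim must be >= 1")
  if (dropout < 0 || dropout >= 1)
    stop("configuration error: dropout must be in [0, 1)")
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2)
    stop("configuration error: training set contains a single class")
  yi <- match(as.character(labels), classes)
  C <- length(classes)
  Y <- diag(C)[yi, , drop = FALSE]

  cfg <- list(variant = variant, hidden_dim = hidden_dim, out_dim = C,
              dropout = dropout,
              epochs = epochs, learning_rate = learning_rate,
              weight_decay = weight_decay, activation = activation,
              negative_slope = negative_slope, normalization = normalization,
              temporal_mode = temporal_mode,
              edge_feature_mode = edge_feature_mode, readout = readout,
              seed = as.integer(seed))

  batch <- build_batch(x, normalization, edge_feature_mode)
  set.seed(cfg$seed)
  params <- init_params(variant, batch$F0, hidden_dim, C)
  pre <- if (variant == "conv") conv_precompute(batch, temporal_mode) else NULL
  opt <- adam_init(params)
  trace <- numeric(epochs)
  if (epochs > 0) {
    for (ep in seq_len(epochs)) {
      lg <- model_loss_grad(batch, params, Y, variant, pre, cfg,
                            training = TRUE)
      grads <- lg$grads
      for (nm in names(params))
        grads[[nm]] <- grads[[nm]] + weight_decay * params[[nm]]
      st <- adam_step(params, grads, opt, learning_rate)
      params <- st$params; opt <- st$state
      trace[ep] <- lg$loss
      if (verbose && ep %% 50 == 0)
        message(sprintf("epoch %4d  loss %.4f", ep, lg$loss))
    }
  }
  eval <- model_loss_grad(batch, params, Y, variant, pre, cfg,
                          training = FALSE)
  pred <- max.col(eval$prob, ties.method = "first")
  obj <- structure(list(params = params, classes = classes, config = cfg,
                        loss_trace = trace,
                        train_accuracy = mean(pred == yi),
                        n_subjects = length(x),
                        dims = list(N = batch$N, s = batch$s,
                                    F0 = batch$F0)),
                   class = "ehgnn")
  obj
}

#' Predict classes for new dynamic hypergraphs
#'
#' @param object a fitted [ehgnn()] model.
#' @param newdata list of `dyn_hypergraph` objects with the same N, s and
#'   feature dimension as the training data.
#' @param type `"class"` (default) for labels, `"prob"` for the class
#'   probability matrix.
#' @param ... unused.
#' @export
predict.ehgnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  cfg <- object$config
  batch <- build_batch(newdata, cfg$normalization, cfg$edge_feature_mode)
  if (batch$F0 != object$dims$F0 || batch$s != object$dims$s)
    stop("structural error: newdata dimensions differ from the training data")
  if (cfg$variant == "conv") {
    pre <- conv_precompute(batch, cfg$temporal_mode)
    fwd <- conv_forward(batch, object$params, pre, cfg$temporal_mode,
                        cfg$activation, cfg$readout)
  } else {
    fwd <- atten_forward(batch, object$params, cfg$negative_slope,
                         cfg$activation, cfg$readout, dropout = 0,
                         training = FALSE)
  }
  P <- softmax_rows(fwd$logits)
  colnames(P) <- object$classes
  rownames(P) <- vapply(newdata, function(g) g$subject_id, character(1))
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.ehgnn <- function(x, ...) {
  cfg <- x$config
  cat("Evolving hypergraph", if (cfg$variant == "conv") "convolutional"
      else "attention", "network\n")
  cat(sprintf("  %d subjects, %d nodes, %d snapshots, %d -> %d -> %d\n",
              x$n_subjects, x$dims$N, x$dims$s, x$dims$F0, cfg$hidden_dim,
              cfg$out_dim))
  cat(sprintf("  trained %d epochs (Adam lr %.3g, L2 %.3g)",
              cfg$epochs, cfg$learning_rate, cfg$weight_decay))
  if (cfg$epochs > 0)
    cat(sprintf(", final loss %.4f, training accuracy %.3f",
                utils::tail(x$loss_trace, 1), x$train_accuracy))
  cat("\n")
  invisible(x)
}

#' @export
summary.ehgnn <- function(object, ...) {
  print(object)
  cat("  classes:", paste(object$classes, collapse = ", "), "\n")
  np <- sum(vapply(object$params, length, numeric(1)))
  cat("  parameters:", np, "(",
      paste(sprintf("%s[%s]", names(object$params),
                    vapply(object$params, function(p)
                      paste(dim(p) %||% length(p), collapse = "x"),
                      character(1))), collapse = ", "), ")\n")
  invisible(object)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.ehgnn <- function(object, ...) object$params

#' Plot the training loss trace
#'
#' @param x a fitted [ehgnn()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ehgnn <- function(x, ...) {
  if (x$config$epochs == 0) stop("model was not trained (epochs = 0)")
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "cross-entropy loss",
                 main = sprintf("ehgnn (%s) training loss",
                                x$config$variant), ...)
  invisible(x)
}
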