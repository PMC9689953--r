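# Nonlinearities used by the layers.
act_fun <- function(name) {
  switch(name,
         elu = function(x) {
           neg <- x < 0
           x[neg] <- exp(x[neg]) - 1
           x
         },
         relu = function(x) pmax(x, 0),
         identity = function(x) x,
         stop("unknown activation '", name, "'"))
}
act_grad <- function(name) {
  switch(name,
         elu = function(x) {
           g <- x
           neg <- x < 0
           g[!neg] <- 1
           g[neg] <- exp(x[neg])
           g
         },
         relu = function(x) (x > 0) * 1,
         identity = function(x) x * 0 + 1,
         stop("unknown activation '", name, "'"))
}
leaky_relu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)
leaky_relu_grad <- function(x, slope = 0.2) (x > 0) + slope * (x <= 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Clip on raw attention scores before exponentiation (overflow guard).
ATT_SCORE_CLIP <- 50

adjacent_window <- function(t, s, mode = c("adjacent", "all")) {
  mode <- match.arg(mode)
  if (mode == "all") seq_len(s) else intersect((t - 1L):(t + 1L), seq_len(s))
}

#' Hypergraph propagation matrix
#'
#' The node-to-node transition operator of one hypergraph snapshot.
#' `"raw"` returns the unnormalized operator \eqn{H W H^\top}
#' (the literal double sum over hyperedges); `"symmetric"` returns the
#' degree-normalized operator
#' \eqn{D_v^{-1/2} H W D_e^{-1} H^\top D_v^{-1/2}} standard in hypergraph
#' convolutional networks, where \eqn{D_v} and \eqn{D_e} are the node and
#' hyperedge degree diagonals. Nodes or hyperedges of degree zero
#' contribute zero rows/columns rather than dividing by zero.
#'
#' @param H N x M binary incidence matrix.
#' @param W length-M positive hyperedge weights (default all ones).
#' @param mode `"symmetric"` (default) or `"raw"`.
#' @return N x N dense matrix.
#' @export
hypergraph_propagation_matrix <- function(H, W = NULL,
                                          mode = c("symmetric", "raw")) {
  mode <- match.arg(mode)
  H <- as.matrix(H)
  if (!all(H %in% c(0, 1)))
    stop("structural error: incidence matrix must be binary")
  M <- ncol(H)
  if (is.null(W)) W <- rep(1, M)
  if (length(W) != M || any(W <= 0))
    stop("structural error: edge weights must be length M and positive")
  HW <- H * rep(W, each = nrow(H))
  if (mode == "raw") return(HW %*% t(H))
  dv <- drop(H %*% W)            # node degree (weighted)
  de <- colSums(H)               # hyperedge degree
  dvi <- ifelse(dv > 0, 1 / sqrt(dv), 0)
  dei <- ifelse(de > 0, 1 / de, 0)
  (dvi * HW) %*% (dei * t(H * dvi))
}

# Per-snapshot propagation matrices of a dynamic hypergraph.
propagation_matrices <- function(graphs, mode = "symmetric") {
  lapply(graphs$snapshots, function(sn)
    hypergraph_propagation_matrix(sn$incidence, sn$edge_weights, mode))
}

#' Evolving hypergraph convolution (single layer, reference implementation)
#'
#' Updates per-snapshot node features by aggregating each node's hyperedge
#' neighbourhood over the snapshot window: in `temporal_mode = "adjacent"`
#' the feature of snapshot t aggregates snapshots t-1, t, t+1 (boundary
#' snapshots drop absent neighbours); in `"all"` the sum runs over every
#' snapshot and the result is replicated per snapshot. With s = 1 both
#' modes reduce to a static hypergraph convolution.
#'
#' @param state list of s N x F node-feature matrices.
#' @param graphs a [build_dynamic_hypergraph()] result.
#' @param P F x F' propagation weight matrix.
#' @param activation `"elu"` (default), `"relu"`, or `"identity"`.
#' @param normalization `"symmetric"` (default) or `"raw"`, see
#'   [hypergraph_propagation_matrix()].
#' @param temporal_mode `"adjacent"` (default) or `"all"`.
#' @return list of s N x F' updated feature matrices.
#' @export
evolving_hyperconv <- function(state, graphs, P, activation = "elu",
                               normalization = "symmetric",
                               temporal_mode = "adjacent") {
  s <- length(graphs$snapshots)
  stopifnot(length(state) == s)
  N <- nrow(state[[1]])
  if (nrow(graphs$snapshots[[1]]$incidence) != N)
    stop("structural error: state and graphs disagree on N")
  G <- propagation_matrices(graphs, normalization)
  GX <- lapply(seq_len(s), function(t) G[[t]] %*% state[[t]])
  sig <- act_fun(activation)
  lapply(seq_len(s), function(t) {
    idx <- adjacent_window(t, s, temporal_mode)
    agg <- Reduce(`+`, GX[idx])
    sig(agg %*% P)
  })
}

#' Attention scores over incident hyperedges
#'
#' For every node j and snapshot t, computes softmax-normalized attention
#' scores over the hyperedges incident to j in snapshots t-1, t, t+1
#' (jointly normalized; boundary snapshots drop absent terms). The raw
#' score of a (node, hyperedge) pair is
#' `LeakyReLU(a' [x_j P ; x_e P])` with `a' = sigmoid(attention_vector)`
#' elementwise (so effective weights lie in \[0, 1\]) and the hyperedge
#' feature `x_e` either the centroid node's feature or the member mean.
#' Nodes with no incident hyperedge in the whole window get all-zero rows.
#'
#' @param X list of s N x F node-feature matrices (own-snapshot features
#'   are used for every term).
#' @param H list of s N x M binary incidence matrices.
#' @param P F x F' projection applied before scoring.
#' @param attention_vector unconstrained vector of length 2 F'.
#' @param negative_slope LeakyReLU slope (default 0.2).
#' @param edge_feature_mode `"centroid"` (default) or `"member_mean"`.
#' @return nested list: `out[[t]][[k]]` is the N x M normalized score
#'   matrix for the k-th snapshot of `attr(out[[t]], "window")` (the
#'   admissible window of t); each matrix is nonzero only where H is 1 and
#'   rows of each (j, t) group sum to 1 over the window.
#' @export
attention_scores <- function(X, H, P, attention_vector, negative_slope = 0.2,
                             edge_feature_mode = c("centroid", "member_mean")) {
  edge_feature_mode <- match.arg(edge_feature_mode)
  s <- length(H)
  stopifnot(length(X) == s)
  Fp <- ncol(P)
  if (length(attention_vector) != 2 * Fp)
    stop("structural error: attention_vector must have length 2 * ncol(P)")
  a_eff <- sigmoid(attention_vector)
  a1 <- a_eff[seq_len(Fp)]; a2 <- a_eff[Fp + seq_len(Fp)]
  U <- lapply(X, function(x) x %*% P)
  expE <- vector("list", s)
  for (t in seq_len(s)) {
    cj <- drop(U[[t]] %*% a1)
    ge <- if (edge_feature_mode == "centroid") {
      drop(U[[t]] %*% a2)
    } else {
      Hc <- H[[t]]
      cs <- colSums(Hc)
      drop(crossprod(Hc, U[[t]] %*% a2)) / ifelse(cs > 0, cs, 1)
    }
    E <- leaky_relu(outer(cj, rep(1, length(ge))) +
                    outer(rep(1, length(cj)), ge), negative_slope)
    E <- pmin(pmax(E, -ATT_SCORE_CLIP), ATT_SCORE_CLIP)
    expE[[t]] <- exp(E) * H[[t]]
  }
  out <- vector("list", s)
  for (t in seq_len(s)) {
    win <- adjacent_window(t, s, "adjacent")
    denom <- Reduce(`+`, lapply(expE[win], rowSums))
    scal <- ifelse(denom > 0, 1 / denom, 0)
    mats <- lapply(expE[win], function(Em) Em * scal)
    attr(mats, "window") <- win
    out[[t]] <- mats
  }
  out
}

#' Evolving hypergraph attention (single layer, reference implementation)
#'
#' Identical to [evolving_hyperconv()] except that the aggregation-side
#' incidence entries \eqn{H_{j\epsilon}} are replaced by the
#' [attention_scores()] while the masking side stays binary: the updated
#' feature of snapshot t is
#' \eqn{\sigma(\sum_\tau H^\tau W \hat H^{t\tau\top} X^\tau P)}. No degree
#' normalization is applied (the softmax already normalizes the attention
#' side). With s = 1 this is a static hypergraph attention layer.
#'
#' @inheritParams evolving_hyperconv
#' @param attention_vector,negative_slope,edge_feature_mode see
#'   [attention_scores()].
#' @return list of s N x F' updated feature matrices.
#' @export
evolving_hyperatten <- function(state, graphs, P, attention_vector,
                                activation = "elu", negative_slope = 0.2,
                                edge_feature_mode = "centroid") {
  s <- length(graphs$snapshots)
  stopifnot(length(state) == s)
  H <- lapply(graphs$snapshots, function(sn) sn$incidence)
  W <- lapply(graphs$snapshots, function(sn) sn$edge_weights)
  scores <- attention_scores(state, H, P, attention_vector, negative_slope,
                             edge_feature_mode)
  sig <- act_fun(activation)
  lapply(seq_len(s), function(t) {
    win <- attr(scores[[t]], "window")
    agg <- 0
    for (k in seq_along(win)) {
      tau <- win[k]
      HW <- H[[tau]] * rep(W[[tau]], each = nrow(H[[tau]]))
      agg <- agg + HW %*% crossprod(scores[[t]][[k]], state[[tau]])
    }
    sig(agg %*% P)
  })
}

#' Readout and classification head
#'
#' Pools per-snapshot node features into one subject-level vector (mean or
#' sum over nodes and snapshots) and maps it to class probabilities with a
#' softmax.
#'
#' @param state list of s N x C matrices (final-layer features, C =
#'   number of classes).
#' @param readout `"mean"` (default) or `"sum"`.
#' @return list with `logits` (length C) and `prob` (softmax of logits).
#' @export
readout_and_classify <- function(state, readout = c("mean", "sum")) {
  readout <- match.arg(readout)
  tot <- Reduce(`+`, lapply(state, colSums))
  if (readout == "mean") tot <- tot / (length(state) * nrow(state[[1]]))
  p <- exp(tot - max(tot))
  list(logits = tot, prob = p / sum(p))
}
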