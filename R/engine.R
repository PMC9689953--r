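# Internal batched training engine.
#
# Subjects are stacked into one block-diagonal hypergraph per snapshot:
# node features become (B*N) x F dense matrices and incidence /
# propagation operators sparse block-diagonal matrices, so one epoch is a
# handful of sparse-dense products regardless of the number of subjects.
# Gradients are analytic (verified against finite differences in the test
# suite).

as_dgc <- function(x) methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")

# Assemble the stacked representation of a list of dyn_hypergraph objects.
build_batch <- function(graphs, normalization = "symmetric",
                        edge_feature_mode = "centroid") {
  B <- length(graphs)
  s <- length(graphs[[1]]$snapshots)
  N <- nrow(graphs[[1]]$snapshots[[1]]$incidence)
  M <- ncol(graphs[[1]]$snapshots[[1]]$incidence)
  F0 <- ncol(graphs[[1]]$node_features[[1]])
  for (g in graphs) {
    if (length(g$snapshots) != s ||
        nrow(g$snapshots[[1]]$incidence) != N ||
        ncol(g$node_features[[1]]) != F0)
      stop("structural error: subjects disagree on (s, N, F)")
  }
  X <- vector("list", s); Hbd <- vector("list", s); HWbd <- vector("list", s)
  Gbd <- vector("list", s); Emap <- vector("list", s)
  ii <- vector("list", s); ee <- vector("list", s)
  for (t in seq_len(s)) {
    X[[t]] <- do.call(rbind, lapply(graphs, function(g) g$node_features[[t]]))
    Hs <- lapply(graphs, function(g) g$snapshots[[t]]$incidence)
    HWs <- lapply(graphs, function(g)
      g$snapshots[[t]]$incidence *
        rep(g$snapshots[[t]]$edge_weights, each = N))
    Hbd[[t]] <- as_dgc(Matrix::bdiag(Hs))
    HWbd[[t]] <- as_dgc(Matrix::bdiag(HWs))
    Gbd[[t]] <- as_dgc(Matrix::bdiag(lapply(graphs, function(g)
      hypergraph_propagation_matrix(g$snapshots[[t]]$incidence,
                                    g$snapshots[[t]]$edge_weights,
                                    normalization))))
    if (edge_feature_mode == "centroid") {
      # hyperedge m is generated by node m within each block
      Emap[[t]] <- as_dgc(Matrix::bdiag(replicate(B, Matrix::Diagonal(N),
                                                  simplify = FALSE)))
    } else {
      Emap[[t]] <- as_dgc(Matrix::bdiag(lapply(Hs, function(Hm) {
        cs <- colSums(Hm)
        Hm %*% diag(ifelse(cs > 0, 1 / cs, 0), ncol(Hm))
      })))
    }
    ii[[t]] <- Hbd[[t]]@i + 1L
    ee[[t]] <- rep(seq_len(ncol(Hbd[[t]])), diff(Hbd[[t]]@p))
  }
  list(B = B, s = s, N = N, M = M, F0 = F0,
       X = X, Hbd = Hbd, HWbd = HWbd, Gbd = Gbd, Emap = Emap,
       ii = ii, ee = ee,
       subj_row = rep(seq_len(B), each = N))
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

init_params <- function(variant, F0, hidden, out) {
  p <- list(P1 = glorot(F0, hidden), P2 = glorot(hidden, out),
            b1 = numeric(hidden), b2 = numeric(out))
  if (variant == "attention") {
    p$a1 <- stats::runif(2 * hidden, -0.1, 0.1)
    p$a2 <- stats::runif(2 * out, -0.1, 0.1)
  }
  p
}

add_bias <- function(Zm, b) Zm + rep(b, each = nrow(Zm))

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

sparse_with <- function(tmpl, vals) { tmpl@x <- vals; tmpl }

row_scale_vals <- function(vals, idx, scal) vals * scal[idx]

# Sum `vals` by integer group `idx` into a length-n vector (C-level rowsum).
group_sum <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

# ---- convolution variant ------------------------------------------------

conv_precompute <- function(batch, temporal_mode) {
  s <- batch$s
  GX <- lapply(seq_len(s), function(t)
    as.matrix(batch$Gbd[[t]] %*% batch$X[[t]]))
  B1 <- lapply(seq_len(s), function(t)
    Reduce(`+`, GX[adjacent_window(t, s, temporal_mode)]))
  # multiplicity of each source snapshot in the backward pass
  nwin <- vapply(seq_len(s), function(tau)
    sum(vapply(seq_len(s), function(t)
      tau %in% adjacent_window(t, s, temporal_mode), logical(1))),
    numeric(1))
  list(B1 = B1, nwin = nwin)
}

conv_forward <- function(batch, params, pre, temporal_mode, activation,
                         readout, dropout = 0, training = FALSE) {
  s <- batch$s
  sig <- act_fun(activation)
  use_drop <- training && dropout > 0
  if (use_drop) {
    m1 <- draw_masks(batch$X, dropout)
    GX <- lapply(seq_len(s), function(t)
      as.matrix(batch$Gbd[[t]] %*% (batch$X[[t]] * m1[[t]])))
    B1 <- lapply(seq_len(s), function(t)
      Reduce(`+`, GX[adjacent_window(t, s, temporal_mode)]))
  } else {
    B1 <- pre$B1
  }
  Z1 <- lapply(B1, function(Bm) add_bias(Bm %*% params$P1, params$b1))
  A1 <- lapply(Z1, sig)
  m2 <- if (use_drop) draw_masks(A1, dropout) else NULL
  A1d <- if (use_drop) Map(`*`, A1, m2) else A1
  GA <- lapply(seq_len(s), function(t)
    as.matrix(batch$Gbd[[t]] %*% A1d[[t]]))
  B2 <- lapply(seq_len(s), function(t)
    Reduce(`+`, GA[adjacent_window(t, s, temporal_mode)]))
  Z2 <- lapply(B2, function(Bm) add_bias(Bm %*% params$P2, params$b2))
  A2 <- lapply(Z2, sig)
  logits <- Reduce(`+`, lapply(A2, function(Zm) rowsum(Zm, batch$subj_row)))
  if (readout == "mean") logits <- logits / (batch$N * s)
  list(Z1 = Z1, A1 = A1, B1 = B1, m2 = m2, B2 = B2, Z2 = Z2,
       logits = logits)
}

conv_backward <- function(batch, params, pre, fwd, dlogits, temporal_mode,
                          activation, readout) {
  s <- batch$s
  dg <- act_grad(activation)
  scale <- if (readout == "mean") 1 / (batch$N * s) else 1
  dA2 <- dlogits[batch$subj_row, , drop = FALSE] * scale  # same for all t
  dZ2 <- lapply(fwd$Z2, function(Zm) dA2 * dg(Zm))
  dP2 <- Reduce(`+`, lapply(seq_len(s), function(t)
    crossprod(fwd$B2[[t]], dZ2[[t]])))
  db2 <- Reduce(`+`, lapply(dZ2, colSums))
  dB2 <- lapply(dZ2, function(d) d %*% t(params$P2))
  dP1 <- 0
  db1 <- 0
  for (tau in seq_len(s)) {
    # all t whose window contains tau (symmetric for adjacent mode)
    ts_hit <- adjacent_window(tau, s, temporal_mode)
    dGH <- Reduce(`+`, dB2[ts_hit])
    dA1 <- as.matrix(Matrix::crossprod(batch$Gbd[[tau]], dGH))
    if (!is.null(fwd$m2)) dA1 <- dA1 * fwd$m2[[tau]]
    dZ1 <- dA1 * dg(fwd$Z1[[tau]])
    dP1 <- dP1 + crossprod(fwd$B1[[tau]], dZ1)
    db1 <- db1 + colSums(dZ1)
  }
  list(P1 = dP1, P2 = dP2, b1 = db1, b2 = db2)
}

# ---- attention variant --------------------------------------------------

# One attention layer forward on stacked inputs. Xd: list of (B*N) x F
# dropped inputs. Returns everything the backward pass needs.
atten_layer_forward <- function(batch, Xd, P, a_raw, negative_slope,
                                amask = NULL) {
  s <- batch$s
  Fp <- ncol(P)
  a_eff <- sigmoid(a_raw)
  a1 <- a_eff[seq_len(Fp)]; a2 <- a_eff[Fp + seq_len(Fp)]
  U <- lapply(Xd, function(x) x %*% P)
  cvec <- lapply(U, function(u) drop(u %*% a1))
  gvec <- lapply(seq_len(s), function(t)
    drop(Matrix::crossprod(batch$Emap[[t]], U[[t]] %*% a2)))
  sim <- lapply(seq_len(s), function(t)
    cvec[[t]][batch$ii[[t]]] + gvec[[t]][batch$ee[[t]]])
  eraw <- lapply(seq_len(s), function(t) leaky_relu(sim[[t]], negative_slope))
  ecl <- lapply(eraw, function(v) pmin(pmax(v, -ATT_SCORE_CLIP), ATT_SCORE_CLIP))
  wv <- lapply(ecl, exp)
  nN <- nrow(batch$Hbd[[1]])
  rs <- lapply(seq_len(s), function(t)
    group_sum(wv[[t]], batch$ii[[t]], nN))
  hat <- vector("list", s)   # hat[[t]][[k]] value vectors, window of t
  den <- vector("list", s)
  Z <- vector("list", s)
  for (t in seq_len(s)) {
    win <- adjacent_window(t, s, "adjacent")
    dn <- Reduce(`+`, rs[win])
    scal <- ifelse(dn > 0, 1 / dn, 0)
    den[[t]] <- scal
    hv <- vector("list", length(win))
    agg <- 0
    for (k in seq_along(win)) {
      tau <- win[k]
      v <- row_scale_vals(wv[[tau]], batch$ii[[tau]], scal)
      hv[[k]] <- v
      vd <- if (is.null(amask)) v else v * amask[[t]][[k]]
      Hhat <- sparse_with(batch$Hbd[[tau]], vd)
      agg <- agg + batch$HWbd[[tau]] %*% Matrix::crossprod(Hhat, U[[tau]])
    }
    hat[[t]] <- hv
    Z[[t]] <- as.matrix(agg)
  }
  list(U = U, sim = sim, eraw = eraw, wv = wv, hat = hat, den = den,
       Z = Z, a_eff = a_eff, a1 = a1, a2 = a2)
}

# Backward for one attention layer. dZ: list over t of gradients w.r.t.
# the pre-activation layer output Z[[t]]. Returns dP, da_raw and dXd.
atten_layer_backward <- function(batch, Xd, P, a_raw, lay, dZ,
                                 negative_slope, amask = NULL) {
  s <- batch$s
  Fp <- ncol(P)
  dU <- lapply(lay$U, function(u) u * 0)
  de <- lapply(lay$wv, function(v) v * 0)
  for (t in seq_len(s)) {
    win <- adjacent_window(t, s, "adjacent")
    sdot <- 0  # per-node sum of hat * dhat over the window of t
    dhat_list <- vector("list", length(win))
    for (k in seq_along(win)) {
      tau <- win[k]
      dY <- as.matrix(Matrix::crossprod(batch$HWbd[[tau]], dZ[[t]]))
      v <- lay$hat[[t]][[k]]
      vd <- if (is.null(amask)) v else v * amask[[t]][[k]]
      Hhat <- sparse_with(batch$Hbd[[tau]], vd)
      dU[[tau]] <- dU[[tau]] + as.matrix(Hhat %*% dY)
      dhd <- rowSums(lay$U[[tau]][batch$ii[[tau]], , drop = FALSE] *
                     dY[batch$ee[[tau]], , drop = FALSE])
      dh <- if (is.null(amask)) dhd else dhd * amask[[t]][[k]]
      dhat_list[[k]] <- dh
      sdot <- sdot + group_sum(v * dh, batch$ii[[tau]], nrow(dZ[[t]]))
    }
    for (k in seq_along(win)) {
      tau <- win[k]
      v <- lay$hat[[t]][[k]]
      de[[tau]] <- de[[tau]] + v * (dhat_list[[k]] - sdot[batch$ii[[tau]]])
    }
  }
  da1 <- numeric(Fp); da2 <- numeric(Fp)
  for (tau in seq_len(s)) {
    gmask <- (lay$eraw[[tau]] > -ATT_SCORE_CLIP) &
             (lay$eraw[[tau]] < ATT_SCORE_CLIP)
    dsim <- de[[tau]] * leaky_relu_grad(lay$sim[[tau]], negative_slope) * gmask
    dc <- group_sum(dsim, batch$ii[[tau]], nrow(lay$U[[tau]]))
    dgv <- group_sum(dsim, batch$ee[[tau]], ncol(batch$Hbd[[tau]]))
    vmap <- as.matrix(batch$Emap[[tau]] %*% dgv)
    dU[[tau]] <- dU[[tau]] + outer(dc, lay$a1) + vmap %*% t(lay$a2)
    da1 <- da1 + drop(crossprod(lay$U[[tau]], dc))
    da2 <- da2 + drop(crossprod(lay$U[[tau]], vmap))
  }
  dP <- 0
  dXd <- vector("list", s)
  for (tau in seq_len(s)) {
    dP <- dP + crossprod(Xd[[tau]], dU[[tau]])
    dXd[[tau]] <- dU[[tau]] %*% t(P)
  }
  da_eff <- c(da1, da2)
  da_raw <- da_eff * lay$a_eff * (1 - lay$a_eff)
  list(dP = dP, da_raw = da_raw, dXd = dXd)
}

draw_masks <- function(shape_list, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  lapply(shape_list, function(x) {
    m <- matrix(stats::rbinom(length(x), 1, keep), nrow(x), ncol(x))
    m / keep
  })
}

draw_att_masks <- function(batch, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  s <- batch$s
  lapply(seq_len(s), function(t) {
    win <- adjacent_window(t, s, "adjacent")
    lapply(win, function(tau)
      stats::rbinom(length(batch$ii[[tau]]), 1, keep) / keep)
  })
}

atten_forward <- function(batch, params, negative_slope, activation, readout,
                          dropout = 0, training = FALSE) {
  s <- batch$s
  sig <- act_fun(activation)
  use_drop <- training && dropout > 0
  m1 <- if (use_drop) draw_masks(batch$X, dropout) else NULL
  Xd0 <- if (use_drop) Map(`*`, batch$X, m1) else batch$X
  am1 <- if (use_drop) draw_att_masks(batch, dropout) else NULL
  # the layer aggregates in projected space, so lay$Z already includes P
  lay1 <- atten_layer_forward(batch, Xd0, params$P1, params$a1,
                              negative_slope, am1)
  Z1b <- lapply(lay1$Z, function(Zm) add_bias(Zm, params$b1))
  A1 <- lapply(Z1b, sig)
  m2 <- if (use_drop) draw_masks(A1, dropout) else NULL
  Xd1 <- if (use_drop) Map(`*`, A1, m2) else A1
  am2 <- if (use_drop) draw_att_masks(batch, dropout) else NULL
  lay2 <- atten_layer_forward(batch, Xd1, params$P2, params$a2,
                              negative_slope, am2)
  Z2b <- lapply(lay2$Z, function(Zm) add_bias(Zm, params$b2))
  A2 <- lapply(Z2b, sig)
  logits <- Reduce(`+`, lapply(A2, function(Zm) rowsum(Zm, batch$subj_row)))
  if (readout == "mean") logits <- logits / (batch$N * s)
  list(Xd0 = Xd0, m1 = m1, am1 = am1, lay1 = lay1, Z1b = Z1b, A1 = A1,
       m2 = m2, am2 = am2, Xd1 = Xd1, lay2 = lay2, Z2b = Z2b,
       logits = logits)
}

atten_backward <- function(batch, params, fwd, dlogits, negative_slope,
                           activation, readout) {
  s <- batch$s
  dg <- act_grad(activation)
  scale <- if (readout == "mean") 1 / (batch$N * s) else 1
  dA2 <- dlogits[batch$subj_row, , drop = FALSE] * scale
  dZ2 <- lapply(fwd$Z2b, function(Zm) dA2 * dg(Zm))
  db2 <- Reduce(`+`, lapply(dZ2, colSums))
  bk2 <- atten_layer_backward(batch, fwd$Xd1, params$P2, params$a2,
                              fwd$lay2, dZ2, negative_slope, fwd$am2)
  dA1 <- bk2$dXd
  if (!is.null(fwd$m2)) dA1 <- Map(`*`, dA1, fwd$m2)
  dZ1 <- lapply(seq_len(s), function(t) dA1[[t]] * dg(fwd$Z1b[[t]]))
  db1 <- Reduce(`+`, lapply(dZ1, colSums))
  bk1 <- atten_layer_backward(batch, fwd$Xd0, params$P1, params$a1,
                              fwd$lay1, dZ1, negative_slope, fwd$am1)
  list(P1 = bk1$dP, P2 = bk2$dP, b1 = db1, b2 = db2,
       a1 = bk1$da_raw, a2 = bk2$da_raw)
}

# ---- loss and optimizer -------------------------------------------------

ce_loss_grad <- function(logits, y_onehot) {
  P <- softmax_rows(logits)
  eps <- 1e-12
  loss <- -mean(rowSums(y_onehot * log(P + eps)))
  list(loss = loss, dlogits = (P - y_onehot) / nrow(logits), prob = P)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# Full-batch loss + gradients for either variant (used by the training
# loop and by the finite-difference tests).
model_loss_grad <- function(batch, params, y_onehot, variant, pre = NULL,
                            cfg, training = FALSE) {
  if (variant == "conv") {
    fwd <- conv_forward(batch, params, pre, cfg$temporal_mode,
                        cfg$activation, cfg$readout, cfg$dropout, training)
    lg <- ce_loss_grad(fwd$logits, y_onehot)
    grads <- conv_backward(batch, params, pre, fwd, lg$dlogits,
                           cfg$temporal_mode, cfg$activation, cfg$readout)
  } else {
    fwd <- atten_forward(batch, params, cfg$negative_slope, cfg$activation,
                         cfg$readout, cfg$dropout, training)
    lg <- ce_loss_grad(fwd$logits, y_onehot)
    grads <- atten_backward(batch, params, fwd, lg$dlogits,
                            cfg$negative_slope, cfg$activation, cfg$readout)
  }
  list(loss = lg$loss, grads = grads, prob = lg$prob)
}
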