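#' Least-angle-regression lasso path
#'
#' Traces the piecewise-linear lasso coefficient path for the objective
#' \deqn{\frac{1}{2n}\|y - X\beta\|_2^2 + \lambda \|\beta\|_1}
#' by least-angle regression with the lasso modification (variables are
#' dropped from the active set when their coefficient crosses zero). The
#' path starts at \eqn{\lambda_{max} = \max_j |x_j^\top y| / n} (all-zero
#' solution) and ends when the residual correlation vanishes, the active
#' design becomes rank-deficient, or \eqn{\lambda} reaches `lambda_min`.
#'
#' Exact solutions at any intermediate penalty follow by linear
#' interpolation between knots, since the lasso path is piecewise linear
#' in \eqn{\lambda}.
#'
#' @param X n x p design matrix (no intercept; columns used as given).
#' @param y length-n response.
#' @param lambda_min smallest penalty to trace down to.
#' @param max_steps safety cap on path steps.
#' @return list with `lambda` (decreasing knot values) and `beta`
#'   (p x length(lambda) coefficient matrix, one column per knot).
#' @export
lars_lasso <- function(X, y, lambda_min = 1e-10, max_steps = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (is.null(max_steps)) max_steps <- 8L * (min(n, p) + 1L)
  cvec <- drop(crossprod(X, y)) / n
  lam <- max(abs(cvec), 0)
  knots_lam <- lam
  knots_beta <- matrix(0, p, 1)
  if (lam <= lambda_min) return(list(lambda = knots_lam, beta = knots_beta))
  G <- crossprod(X) / n
  beta <- numeric(p)
  active <- integer(0)
  rank_cap <- min(n, p)
  just_dropped <- integer(0)
  tol <- 1e-9

  for (step in seq_len(max_steps)) {
    thr <- lam * (1 - tol) - 1e-14
    join <- setdiff(which(abs(cvec) >= thr), active)
    join <- setdiff(join, just_dropped)
    active <- c(active, join)
    just_dropped <- integer(0)
    if (length(active) == 0) break
    sgn <- sign(cvec[active])
    w <- tryCatch(solve(G[active, active, drop = FALSE], sgn),
                  error = function(e) NULL)
    if (is.null(w) || any(!is.finite(w))) break
    # beta_A(lam - g) = beta_A + g * w ; c_k(lam - g) = c_k - g * a_k
    a <- drop(G[, active, drop = FALSE] %*% w)
    gmax <- lam - lambda_min
    g_join <- rep(Inf, p)
    inact <- setdiff(seq_len(p), active)
    if (length(inact)) {
      # |c_k - g a_k| = lam - g  =>  g = (lam -+ c_k)/(1 -+ a_k)
      g1 <- (lam - cvec[inact]) / (1 - a[inact])
      g2 <- (lam + cvec[inact]) / (1 + a[inact])
      g1[!is.finite(g1) | g1 <= tol * lam] <- Inf
      g2[!is.finite(g2) | g2 <= tol * lam] <- Inf
      g_join[inact] <- pmin(g1, g2)
    }
    g_drop <- rep(Inf, length(active))
    cross <- -beta[active] / w
    cross[!is.finite(cross) | cross <= tol * lam] <- Inf
    g_drop <- cross
    g_event <- min(gmax, min(g_join), min(g_drop))
    beta[active] <- beta[active] + g_event * w
    cvec <- cvec - g_event * a
    lam <- lam - g_event
    knots_lam <- c(knots_lam, lam)
    knots_beta <- cbind(knots_beta, beta)
    if (g_event >= gmax - 1e-15 || lam <= lambda_min) break
    if (g_event == min(g_drop) && min(g_drop) <= min(g_join)) {
      di <- active[which.min(g_drop)]
      beta[di] <- 0
      just_dropped <- di
      active <- setdiff(active, di)
    } else if (length(active) >= rank_cap) {
      break
    }
  }
  list(lambda = knots_lam, beta = knots_beta)
}

# Exact lasso solution at penalty `lam` from a traced path.
lasso_at <- function(path, lam) {
  lams <- path$lambda
  if (lam >= lams[1]) return(path$beta[, 1])
  k <- length(lams)
  if (lam <= lams[k]) return(path$beta[, k])
  hi <- max(which(lams >= lam))
  lo <- hi + 1L
  if (lams[hi] == lams[lo]) return(path$beta[, lo])
  wgt <- (lams[hi] - lam) / (lams[hi] - lams[lo])
  path$beta[, hi] * (1 - wgt) + path$beta[, lo] * wgt
}

#' Sparse representation of one region within a window
#'
#' Expresses region `m`'s windowed signal as an l1-penalized linear
#' combination of the remaining regions (the m-th column of the design is
#' zeroed, so the region never selects itself), solved on the
#' least-angle-regression lasso path. The objective is
#' \eqn{\frac{1}{2w}\|z_m - A_m\alpha\|^2 + \lambda\|\alpha\|_1} with
#' `w` the window length; `lam` is expressed in that convention.
#'
#' @param Zt M x w window matrix (rows = regions).
#' @param m target region index (1-based).
#' @param lam penalty \eqn{\lambda \ge 0}.
#' @return object of class `sparse_solution`: `target_region`,
#'   `coefficients` (length M, entry m fixed at 0), `penalty`,
#'   `residual_norm`.
#' @export
fit_sparse_representation <- function(Zt, m, lam) {
  Zt <- as.matrix(Zt)
  M <- nrow(Zt)
  if (ncol(Zt) < 2) stop("fit_sparse_representation: window needs >= 2 time points")
  if (m < 1 || m > M) stop("fit_sparse_representation: region index out of range")
  if (lam < 0) stop("fit_sparse_representation: lam must be >= 0")
  y <- Zt[m, ]
  X <- t(Zt)
  X[, m] <- 0
  if (all(y == 0)) {
    alpha <- numeric(M)
  } else {
    path <- lars_lasso(X, y, lambda_min = max(lam * 1e-6, 1e-12))
    alpha <- lasso_at(path, lam)
    alpha[m] <- 0
  }
  res <- y - drop(X %*% alpha)
  structure(list(target_region = m,
                 coefficients = alpha,
                 penalty = lam,
                 residual_norm = sqrt(sum(res^2))),
            class = "sparse_solution")
}
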