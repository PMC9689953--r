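#' Assemble a hypergraph snapshot from sparse solutions
#'
#' Each region m generates one hyperedge: the regions whose sparse
#' coefficients exceed `tau` in magnitude, plus (by default) region m
#' itself as the hyperedge centroid. The result is a binary N x M
#' incidence matrix with N = M = number of regions.
#'
#' @param solutions list of M [fit_sparse_representation()] results, one
#'   per region, in region order.
#' @param tau magnitude threshold above which a coefficient counts as a
#'   member (default 1e-6).
#' @param centroid include region m in its own hyperedge (default `TRUE`).
#' @param weight_mode `"ones"` (all hyperedge weights 1) or
#'   `"mean_abs_coef"` (mean absolute member coefficient; 1 for hyperedges
#'   with no above-threshold coefficients).
#' @return object of class `hb_snapshot`: `incidence` (N x M 0/1 matrix),
#'   `edge_weights` (length M, positive), `coefficients` (M x M matrix,
#'   column m = the coefficient vector of region m).
#' @export
build_incidence <- function(solutions, tau = 1e-6, centroid = TRUE,
                            weight_mode = c("ones", "mean_abs_coef")) {
  weight_mode <- match.arg(weight_mode)
  M <- length(solutions)
  if (M == 0) stop("build_incidence: no solutions given")
  lens <- vapply(solutions, function(s) length(s$coefficients), integer(1))
  if (any(lens != M))
    stop("structural error: solution coefficient lengths (",
         paste(unique(lens), collapse = ","),
         ") inconsistent with the number of regions (", M, ")")
  A <- vapply(solutions, function(s) s$coefficients, numeric(M))
  H <- (abs(A) > tau) * 1L
  if (centroid) H[cbind(seq_len(M), seq_len(M))] <- 1L
  w <- rep(1, M)
  if (weight_mode == "mean_abs_coef") {
    for (m in seq_len(M)) {
      nz <- abs(A[, m]) > tau
      if (any(nz)) w[m] <- mean(abs(A[nz, m]))
    }
  }
  structure(list(incidence = H, edge_weights = w, coefficients = A),
            class = "hb_snapshot")
}

#' Build a subject's dynamic hyperbrain network
#'
#' Composes sliding-window segmentation, per-region l1 sparse
#' representation on the least-angle-regression lasso path, and incidence
#' assembly, once per snapshot. Node features default to the segmented
#' window signal rows (standardized when the window config says so), i.e.
#' F = window length.
#'
#' @param ts a [roi_time_series()].
#' @param cfg a [window_config()].
#' @param lam lasso penalty (see [fit_sparse_representation()] for the
#'   convention).
#' @param tau incidence threshold, see [build_incidence()].
#' @param centroid,weight_mode passed to [build_incidence()].
#' @return object of class `dyn_hypergraph`: `snapshots` (list of s
#'   `hb_snapshot`), `node_features` (list of s N x F matrices),
#'   `window_bounds`, `subject_id`, `region_ids`.
#' @export
build_dynamic_hypergraph <- function(ts, cfg, lam = 0.1, tau = 1e-6,
                                     centroid = TRUE,
                                     weight_mode = c("ones", "mean_abs_coef")) {
  weight_mode <- match.arg(weight_mode)
  seg <- segment_time_series(ts, cfg)
  M <- nrow(ts$values)
  snapshots <- lapply(seg$windows, function(W) {
    sols <- lapply(seq_len(M), function(m) fit_sparse_representation(W, m, lam))
    build_incidence(sols, tau = tau, centroid = centroid,
                    weight_mode = weight_mode)
  })
  structure(list(snapshots = snapshots,
                 node_features = seg$windows,
                 window_bounds = seg$window_bounds,
                 subject_id = ts$subject_id,
                 region_ids = ts$region_ids,
                 lam = lam, tau = tau),
            class = "dyn_hypergraph")
}

#' @export
print.dyn_hypergraph <- function(x, ...) {
  N <- nrow(x$snapshots[[1]]$incidence)
  cat("<dyn_hypergraph> subject", x$subject_id, "-", length(x$snapshots),
      "snapshots,", N, "nodes/hyperedges, lambda =", x$lam, "\n")
  invisible(x)
}

#' Build dynamic hypergraphs for a whole cohort
#'
#' @param subjects list of `roi_ts` objects.
#' @param cfg,lam,tau,... passed to [build_dynamic_hypergraph()].
#' @return list of `dyn_hypergraph`, named by subject id.
#' @export
build_cohort_hypergraphs <- function(subjects, cfg, lam = 0.1, tau = 1e-6, ...) {
  out <- lapply(subjects, build_dynamic_hypergraph, cfg = cfg, lam = lam,
                tau = tau, ...)
  names(out) <- vapply(subjects, function(s) s$subject_id, character(1))
  out
}
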