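#' Sliding-window configuration
#'
#' Controls how a subject's time series is segmented into snapshots. By
#' default the series is partitioned into `n_snapshots` consecutive,
#' non-overlapping windows of length `floor(d / n_snapshots)`; trailing time
#' points that do not fill a window are discarded. A smaller `step` yields
#' overlapping windows.
#'
#' @param n_snapshots number of snapshots s (>= 1).
#' @param window_length window length in time points; derived from the
#'   series length when `NULL`.
#' @param step distance between window starts; defaults to `window_length`
#'   (non-overlapping).
#' @param standardize z-score each region's row within each window
#'   (constant rows map to zeros). Default `TRUE`.
#' @return object of class `window_config`.
#' @export
window_config <- function(n_snapshots, window_length = NULL, step = NULL,
                          standardize = TRUE) {
  if (n_snapshots < 1) stop("configuration error: n_snapshots must be >= 1")
  if (!is.null(window_length) && window_length < 2)
    stop("configuration error: window_length must be >= 2")
  if (!is.null(step) && step < 1)
    stop("configuration error: step must be >= 1")
  structure(list(n_snapshots = as.integer(n_snapshots),
                 window_length = if (is.null(window_length)) NULL else as.integer(window_length),
                 step = if (is.null(step)) NULL else as.integer(step),
                 standardize = isTRUE(standardize)),
            class = "window_config")
}

zscore_rows <- function(W) {
  mu <- rowMeans(W)
  sd <- apply(W, 1, stats::sd)
  out <- (W - mu) / ifelse(sd > 0, sd, 1)
  out[sd == 0, ] <- 0
  out
}

#' Segment a regional time series into snapshots
#'
#' @param ts a [roi_time_series()].
#' @param cfg a [window_config()].
#' @return object of class `snapshot_series`: `windows` (list of s M x w
#'   matrices) and `window_bounds` (0-based, half-open start/end indices).
#' @examples
#' ts <- roi_time_series("s1", matrix(rnorm(3 * 10), 3, 10))
#' seg <- segment_time_series(ts, window_config(3, window_length = 3))
#' seg$window_bounds
#' @export
segment_time_series <- function(ts, cfg) {
  stopifnot(inherits(ts, "roi_ts"), inherits(cfg, "window_config"))
  d <- ncol(ts$values)
  s <- cfg$n_snapshots
  wl <- cfg$window_length
  if (is.null(wl)) wl <- d %/% s
  step <- if (is.null(cfg$step)) wl else cfg$step
  if (wl < 2 || (s - 1L) * step + wl > d)
    stop("configuration error: ", s, " windows of length ", wl,
         " at step ", step, " do not fit in d = ", d, " time points")
  starts <- (seq_len(s) - 1L) * step
  windows <- lapply(starts, function(st) {
    W <- ts$values[, st + seq_len(wl), drop = FALSE]
    if (cfg$standardize) W <- zscore_rows(W)
    W
  })
  structure(list(windows = windows,
                 window_bounds = cbind(start = starts, end = starts + wl),
                 subject_id = ts$subject_id,
                 region_ids = ts$region_ids),
            class = "snapshot_series")
}
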