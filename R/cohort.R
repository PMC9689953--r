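#' Specification of a synthetic cohort
#'
#' Describes a labelled synthetic cohort of regional brain-signal time series
#' with planted sparse structure. Regions are split into *driver* (root)
#' regions, whose signals are i.i.d. standard Gaussian series, and *driven*
#' regions, whose signal in each window is a sparse linear combination of a
#' few root regions plus Gaussian noise. Each driven region's support set is
#' the ground-truth membership of its hyperedge; supports are shared by all
#' subjects of a class, so class membership is encoded in network structure
#' rather than in marginal signal statistics.
#'
#' Supports are sampled so that any two hyperedges of the same class share at
#' most one root region. Together with coefficient magnitudes bounded by 1
#' this makes the planted coefficients the minimum-l1 least-squares solution
#' in the noiseless case, so exact support recovery by the lasso is
#' well-posed.
#'
#' @param n_per_class subjects per class.
#' @param n_classes number of classes.
#' @param m_regions number of brain regions M.
#' @param d_timepoints number of time points d per subject.
#' @param n_windows number of generation windows (structure is constant
#'   within a window; align with the snapshot count used downstream).
#' @param support_size number of root regions driving each driven region.
#' @param coeff_range interval for the absolute value of nonzero generating
#'   coefficients; signs are drawn uniformly.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   driven regions.
#' @param n_varying number of hyperedges whose membership differs between
#'   class 1 and each other class (per window).
#' @param support_size_varying support size of the varying hyperedges in
#'   classes other than 1; default `max(1, support_size - 2)`, emulating
#'   the loss of inter-regional driving connections that characterizes the
#'   disease class (set equal to `support_size` for a pure remapping of
#'   memberships).
#' @param temporal_shift if `TRUE`, the varying hyperedges of classes > 1
#'   are re-drawn in every window while class 1 stays stationary.
#' @param n_driven number of driven regions; default
#'   `max(n_varying, ceiling(m_regions / 4))` (keeping the root pool large
#'   enough that many support sets satisfy the overlap constraint, so
#'   class-dependent and window-varying supports can actually differ).
#' @param seed integer RNG seed; identical spec + seed gives an identical
#'   cohort.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_per_class = 50, n_classes = 2, m_regions = 20,
                        d_timepoints = 150, n_windows = 5, support_size = 4,
                        coeff_range = c(0.4, 1.0), noise_sd = 0.2,
                        n_varying = 6, temporal_shift = FALSE,
                        support_size_varying = NULL, n_driven = NULL,
                        seed = 1) {
  if (is.null(n_driven)) {
    n_driven <- max(n_varying, ceiling(m_regions / 4))
  }
  if (is.null(support_size_varying)) {
    support_size_varying <- max(1, support_size - 2)
  }
  spec <- structure(list(
    n_per_class = as.integer(n_per_class), n_classes = as.integer(n_classes),
    m_regions = as.integer(m_regions), d_timepoints = as.integer(d_timepoints),
    n_windows = as.integer(n_windows), support_size = as.integer(support_size),
    coeff_range = as.numeric(coeff_range), noise_sd = as.numeric(noise_sd),
    n_varying = as.integer(n_varying),
    temporal_shift = isTRUE(temporal_shift),
    support_size_varying = as.integer(support_size_varying),
    n_driven = as.integer(n_driven), seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (support_size >= m_regions)
      stop("configuration error: support_size (", support_size,
           ") must be smaller than m_regions (", m_regions, ")", call. = FALSE)
    if (n_varying > m_regions)
      stop("configuration error: n_varying exceeds m_regions", call. = FALSE)
    if (noise_sd < 0) stop("configuration error: noise_sd must be >= 0", call. = FALSE)
    if (n_per_class < 0 || n_classes < 1)
      stop("configuration error: invalid cohort size", call. = FALSE)
    if (support_size_varying < 1 || support_size_varying > support_size)
      stop("configuration error: support_size_varying must lie in [1, support_size]",
           call. = FALSE)
    if (n_varying > n_driven)
      stop("configuration error: n_varying (", n_varying,
           ") exceeds the number of driven regions (", n_driven, ")", call. = FALSE)
    n_root <- m_regions - n_driven
    if (support_size > n_root)
      stop("configuration error: support_size (", support_size,
           ") exceeds the number of root regions (", n_root, ")", call. = FALSE)
    # capacity for the pairwise-intersection <= 1 support design
    if (n_driven * choose(support_size, 2) > choose(n_root, 2))
      stop("configuration error: cannot place ", n_driven, " supports of size ",
           support_size, " over ", n_root,
           " root regions with pairwise overlap <= 1", call. = FALSE)
    if (length(coeff_range) != 2 || any(coeff_range <= 0) || diff(coeff_range) < 0)
      stop("configuration error: coeff_range must be an increasing positive interval",
           call. = FALSE)
    if (n_windows < 1 || d_timepoints < 2 * n_windows)
      stop("configuration error: d_timepoints too small for n_windows", call. = FALSE)
    invisible(TRUE)
  })
}

#' A single subject's regional time series
#'
#' @param subject_id character identifier.
#' @param values numeric M x d matrix, one row per region.
#' @param region_ids region identifiers; default `"r1" ... "rM"`.
#' @return object of class `roi_ts`.
#' @export
roi_time_series <- function(subject_id, values, region_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(region_ids)) region_ids <- paste0("r", seq_len(nrow(values)))
  if (anyNA(values)) stop("roi_time_series: missing values in '", subject_id, "'")
  if (nrow(values) < 3 || ncol(values) < 2)
    stop("roi_time_series: need at least 3 regions and 2 time points")
  if (length(region_ids) != nrow(values))
    stop("roi_time_series: region_ids length does not match row count")
  rownames(values) <- region_ids
  structure(list(subject_id = as.character(subject_id),
                 region_ids = as.character(region_ids),
                 values = values),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat("<roi_ts> subject", x$subject_id, "-", nrow(x$values), "regions x",
      ncol(x$values), "time points\n")
  invisible(x)
}

# Sample n_driven supports of size k over roots 1..n_root such that any two
# supports share at most one root; `fixed` rows are kept as constraints.
sample_supports <- function(n_root, n_driven, k, fixed = list()) {
  pair_key <- function(s) {
    if (length(s) < 2) return(paste0("s-", s))
    cmb <- utils::combn(sort(s), 2)
    paste(cmb[1, ], cmb[2, ], sep = "-")
  }
  for (attempt in 1:500) {
    used <- character(0)
    for (s in fixed) used <- c(used, pair_key(s))
    out <- vector("list", n_driven)
    ok <- TRUE
    for (i in seq_len(n_driven)) {
      placed <- FALSE
      for (try in 1:400) {
        s <- sort(sample.int(n_root, k))
        keys <- pair_key(s)
        if (!any(keys %in% used)) {
          used <- c(used, keys)
          out[[i]] <- s
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(out)
  }
  stop("configuration error: unable to sample hyperedge supports with the ",
       "required overlap constraint; reduce support_size or n_driven")
}

# Class-c supports: start from class-1 supports, re-draw `vary_idx` entries
# with size `k_new` (must differ from the class-1 support and respect the
# overlap constraint within the class-c support set).
vary_supports <- function(base, vary_idx, n_root, k_new) {
  out <- base
  for (i in vary_idx) {
    others <- out[-i]
    repeat {
      cand <- sample_supports(n_root, 1, k_new, fixed = others)[[1]]
      if (!identical(cand, base[[i]])) break
    }
    out[[i]] <- cand
  }
  out
}

#' Generate a labelled synthetic cohort
#'
#' Realizes the generative model behind sparse-representation hyperbrain
#' networks: in each window, root regions are i.i.d. standard Gaussian
#' series and each driven region equals its planted linear combination of
#' root regions plus Gaussian noise. Supports (hence hyperedge memberships)
#' are class-dependent; `n_varying` hyperedges differ between class 1 and
#' each other class in every window.
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{subjects}{list of [roi_time_series()] objects,}
#'     \item{labels}{named integer vector of class labels (1-based),}
#'     \item{truth}{ground truth: `driven` (indices of driven regions),
#'       `roots`, `supports[[class]][[window]]` (list over driven regions of
#'       root index sets) and `alpha[[subject]][[window]]` (M x M matrix
#'       whose column m holds the planted coefficient vector of region m;
#'       zero columns for root regions),}
#'     \item{window_bounds}{0-based half-open generation window bounds.}
#'   }
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  M <- spec$m_regions
  n_root <- M - spec$n_driven
  roots <- seq_len(n_root)
  driven <- n_root + seq_len(spec$n_driven)
  s <- spec$n_windows
  wl <- spec$d_timepoints %/% s
  # remainder time points extend the last generation window
  lens <- rep(wl, s)
  lens[s] <- lens[s] + spec$d_timepoints - wl * s
  starts <- cumsum(c(0L, lens[-s]))

  vary_idx <- sort(sample.int(spec$n_driven, spec$n_varying))
  base_supports <- sample_supports(n_root, spec$n_driven, spec$support_size)
  supports <- vector("list", spec$n_classes)
  for (cl in seq_len(spec$n_classes)) {
    supports[[cl]] <- vector("list", s)
    if (cl == 1L) {
      for (t in seq_len(s)) supports[[cl]][[t]] <- base_supports
    } else if (spec$temporal_shift) {
      for (t in seq_len(s))
        supports[[cl]][[t]] <- vary_supports(base_supports, vary_idx, n_root,
                                             spec$support_size_varying)
    } else {
      fixed <- vary_supports(base_supports, vary_idx, n_root,
                             spec$support_size_varying)
      for (t in seq_len(s)) supports[[cl]][[t]] <- fixed
    }
  }

  n_sub <- spec$n_per_class * spec$n_classes
  labels <- rep(seq_len(spec$n_classes), each = spec$n_per_class)
  subjects <- vector("list", n_sub)
  alpha <- vector("list", n_sub)
  ids <- sprintf("subj%03d", seq_len(n_sub))
  names(labels) <- ids

  for (i in seq_len(n_sub)) {
    cl <- labels[i]
    Z <- matrix(0, M, spec$d_timepoints)
    alpha_i <- vector("list", s)
    for (t in seq_len(s)) {
      idx <- starts[t] + seq_len(lens[t])
      R <- matrix(stats::rnorm(n_root * lens[t]), n_root, lens[t])
      Z[roots, idx] <- R
      A <- matrix(0, M, M)
      for (j in seq_len(spec$n_driven)) {
        m <- driven[j]
        supp <- supports[[cl]][[t]][[j]]
        k <- length(supp)
        coef <- stats::runif(k, spec$coeff_range[1], spec$coeff_range[2]) *
          sample(c(-1, 1), k, replace = TRUE)
        A[supp, m] <- coef
        sig <- drop(crossprod(R[supp, , drop = FALSE], coef))
        if (spec$noise_sd > 0)
          sig <- sig + stats::rnorm(lens[t], sd = spec$noise_sd)
        Z[m, idx] <- sig
      }
      alpha_i[[t]] <- A
    }
    subjects[[i]] <- roi_time_series(ids[i], Z)
    alpha[[i]] <- alpha_i
  }
  names(alpha) <- ids

  list(subjects = subjects,
       labels = labels,
       truth = list(driven = driven, roots = roots,
                    supports = supports, vary_idx = vary_idx,
                    alpha = alpha),
       window_bounds = cbind(start = starts, end = starts + lens))
}

#' Write a cohort to delimited text files
#'
#' One CSV per subject (first column the region id, remaining columns the
#' time points) plus a `labels.csv` table with columns `subject_id,label`.
#' The files round-trip through [read_cohort()] to within 1e-12.
#'
#' @param subjects list of `roi_ts` objects.
#' @param labels named vector of labels, one per subject.
#' @param directory output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(subjects, labels, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_cohort: cannot create directory '", directory, "'")
  }
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (length(subjects) > 0 && !identical(sort(ids), sort(names(labels))))
    stop("write_cohort: subject ids and label names disagree")
  paths <- character(0)
  for (s in subjects) {
    df <- data.frame(region_id = s$region_ids,
                     format(s$values, digits = 17, trim = TRUE, scientific = TRUE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("region_id", paste0("t", seq_len(ncol(s$values))))
    p <- file.path(directory, paste0(s$subject_id, ".csv"))
    ok <- tryCatch({ utils::write.csv(df, p, row.names = FALSE, quote = FALSE); TRUE },
                   error = function(e) stop("write_cohort: failed writing '", p,
                                            "': ", conditionMessage(e)))
    paths <- c(paths, p)
  }
  lp <- file.path(directory, "labels.csv")
  utils::write.csv(data.frame(subject_id = names(labels),
                              label = unname(labels)),
                   lp, row.names = FALSE, quote = FALSE)
  invisible(c(paths, lp))
}
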