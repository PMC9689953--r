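# Stratified fold assignment: per-class seeded shuffle dealt round-robin.
make_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (n < k) stop("configuration error: fewer subjects (", n,
                  ") than folds (", k, ")")
  if (k < 2) stop("configuration error: k_folds must be >= 2")
  set.seed(seed)
  fold <- integer(n)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Re-initializes and trains an [ehgnn()] model on each training split and
#' measures accuracy on the held-out fold. Folds are stratified (per-class
#' proportions preserved where divisible) with a seeded shuffle; the model
#' seed is re-derived per fold so the whole run is reproducible from
#' `seed`.
#'
#' @param x list of `dyn_hypergraph` objects.
#' @param labels class labels, one per subject.
#' @param k_folds number of folds (default 10).
#' @param seed seed for fold shuffling and per-fold training.
#' @param ... passed on to [ehgnn()] (variant, epochs, hidden_dim, ...).
#' @return object of class `ehgnn_cv`: `fold_accuracy`, `mean_accuracy`,
#'   `folds` (assignment vector), `confusion` (summed confusion matrix),
#'   `config`.
#' @export
cross_validate <- function(x, labels, k_folds = 10, seed = 1, ...) {
  labels <- as.character(labels)
  fold <- make_folds(labels, k_folds, seed)
  classes <- sort(unique(labels))
  acc <- numeric(k_folds)
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  for (f in seq_len(k_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    fit <- ehgnn(x[tr], labels[tr], seed = seed + 7919L * f, ...)
    pred <- as.character(predict(fit, x[te]))
    acc[f] <- mean(pred == labels[te])
    for (i in seq_along(te))
      conf[labels[te[i]], pred[i]] <- conf[labels[te[i]], pred[i]] + 1L
  }
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 folds = fold, confusion = conf,
                 config = c(list(k_folds = k_folds, seed = seed),
                            list(...))),
            class = "ehgnn_cv")
}

#' @export
print.ehgnn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: mean accuracy %.4f (folds %s)\n",
              length(x$fold_accuracy), x$mean_accuracy,
              paste(sprintf("%.2f", x$fold_accuracy), collapse = " ")))
  invisible(x)
}

#' Sensitivity and specificity of a cross-validation run
#'
#' For two-class results, treating the second class as "positive".
#' @param cv an `ehgnn_cv` object.
#' @return named vector with sensitivity and specificity.
#' @export
cv_sens_spec <- function(cv) {
  stopifnot(nrow(cv$confusion) == 2)
  tp <- cv$confusion[2, 2]; fn <- cv$confusion[2, 1]
  tn <- cv$confusion[1, 1]; fp <- cv$confusion[1, 2]
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Parameter sweep with cross-validation
#'
#' Runs one cross-validation per parameter value with a shared seed.
#' `"lambda"` and `"n_snapshots"` rebuild the dynamic hypergraphs from the
#' raw time series for every value; `"hidden_dim"` reuses the hypergraphs
#' built once at the base settings.
#'
#' @param parameter one of `"n_snapshots"`, `"lambda"`, `"hidden_dim"`.
#' @param values numeric vector of values to sweep.
#' @param subjects list of [roi_time_series()] objects.
#' @param labels class labels.
#' @param n_snapshots,lam,tau base hypergraph-construction settings.
#' @param k_folds,seed cross-validation settings.
#' @param ... passed on to [ehgnn()].
#' @return data.frame with columns `parameter`, `value`, `mean_accuracy`.
#' @export
sweep_parameter <- function(parameter = c("n_snapshots", "lambda", "hidden_dim"),
                            values, subjects, labels, n_snapshots = 5,
                            lam = 0.1, tau = 1e-6, k_folds = 10, seed = 1,
                            ...) {
  parameter <- match.arg(parameter)
  if (length(values) == 0) stop("configuration error: no sweep values given")
  base_graphs <- NULL
  dots <- list(...)
  acc <- numeric(length(values))
  for (i in seq_along(values)) {
    v <- values[i]
    if (parameter == "hidden_dim") {
      if (is.null(base_graphs))
        base_graphs <- build_cohort_hypergraphs(
          subjects, window_config(n_snapshots), lam = lam, tau = tau)
      args <- dots[setdiff(names(dots), "hidden_dim")]
      cv <- do.call(cross_validate,
                    c(list(base_graphs, labels, k_folds = k_folds,
                           seed = seed, hidden_dim = v), args))
    } else {
      s_use <- if (parameter == "n_snapshots") as.integer(v) else n_snapshots
      l_use <- if (parameter == "lambda") v else lam
      graphs <- build_cohort_hypergraphs(subjects, window_config(s_use),
                                         lam = l_use, tau = tau)
      cv <- cross_validate(graphs, labels, k_folds = k_folds, seed = seed,
                           ...)
    }
    acc[i] <- cv$mean_accuracy
  }
  data.frame(parameter = parameter, value = values, mean_accuracy = acc)
}
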