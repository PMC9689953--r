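#' Read a cohort from a directory of delimited files
#'
#' Expects the layout written by [write_cohort()]: a `labels.csv` with
#' columns `subject_id,label` and one `<subject_id>.csv` per subject
#' (first column `region_id`, remaining columns time points). All
#' subjects must share the same regions; non-numeric cells, missing
#' values, ragged rows and missing files fail fast with the offending
#' subject named.
#'
#' @param directory path containing the cohort files.
#' @return list with `subjects` (list of [roi_time_series()]) and
#'   `labels` (named vector).
#' @export
read_cohort <- function(directory) {
  lp <- file.path(directory, "labels.csv")
  if (!file.exists(lp)) stop("read_cohort: labels file not found at '", lp, "'")
  lab <- utils::read.csv(lp, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(lab)))
    stop("read_cohort: labels.csv must have columns subject_id,label")
  subjects <- vector("list", nrow(lab))
  M_ref <- NULL; ids_ref <- NULL
  for (i in seq_len(nrow(lab))) {
    id <- lab$subject_id[i]
    p <- file.path(directory, paste0(id, ".csv"))
    if (!file.exists(p))
      stop("read_cohort: subject '", id, "' listed in labels.csv but file '",
           p, "' is missing")
    df <- utils::read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals) || anyNA(vals))
      stop("read_cohort: non-numeric or missing values in '", p, "'")
    if (is.null(M_ref)) {
      M_ref <- nrow(vals); ids_ref <- as.character(df[[1]])
    } else if (nrow(vals) != M_ref) {
      stop("read_cohort: subject '", id, "' has ", nrow(vals),
           " regions but previous subjects have ", M_ref)
    }
    subjects[[i]] <- roi_time_series(id, vals, as.character(df[[1]]))
  }
  labels <- lab$label
  names(labels) <- lab$subject_id
  list(subjects = subjects, labels = labels)
}

#' Write a dynamic hypergraph to disk
#'
#' One incidence CSV per snapshot (rows = nodes, columns = hyperedges,
#' cells 0/1), one coefficients CSV per snapshot, and a JSON sidecar with
#' subject id, snapshot count, penalty, threshold, window bounds and a
#' config hash.
#'
#' @param graph a `dyn_hypergraph`.
#' @param directory output directory (created if needed).
#' @return invisibly, the sidecar path.
#' @export
write_dynamic_hypergraph <- function(graph, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  id <- graph$subject_id
  for (t in seq_along(graph$snapshots)) {
    utils::write.csv(graph$snapshots[[t]]$incidence,
                     file.path(directory, sprintf("%s_H%02d.csv", id, t)),
                     row.names = FALSE)
    utils::write.csv(graph$snapshots[[t]]$coefficients,
                     file.path(directory, sprintf("%s_alpha%02d.csv", id, t)),
                     row.names = FALSE)
  }
  meta <- list(subject_id = id, s = length(graph$snapshots),
               lambda = graph$lam, tau = graph$tau,
               window_bounds = graph$window_bounds,
               tool = package_manifest())
  sp <- file.path(directory, paste0(id, "_meta.json"))
  jsonlite::write_json(meta, sp, auto_unbox = TRUE, digits = NA)
  invisible(sp)
}

package_manifest <- function(config = NULL) {
  m <- list(package = "hyperbrain",
            version = as.character(utils::packageVersion("hyperbrain")))
  if (!is.null(config)) m$config_hash <- config_hash(config)
  m
}

# Polynomial rolling hash of the canonical JSON encoding; stable run
# fingerprint (not cryptographic).
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

run_config_fields <- c("input_dir", "output_dir", "n_snapshots",
                       "window_length", "step", "standardize", "lambda",
                       "tau", "variant", "hidden_dim", "dropout", "epochs",
                       "learning_rate", "weight_decay", "temporal_mode",
                       "normalization", "k_folds", "seed", "cohort",
                       "log_level")

default_run_config <- function() {
  list(n_snapshots = 5, lambda = 0.1, tau = 1e-6, standardize = TRUE,
       variant = "conv", hidden_dim = 8, dropout = 0.6, epochs = 200,
       learning_rate = 0.005, weight_decay = 3e-4,
       temporal_mode = "adjacent", normalization = "symmetric",
       k_folds = 10, seed = 1, log_level = "info")
}

#' Read and validate a run configuration
#'
#' A flat JSON file of pipeline settings; unknown keys are rejected with a
#' clear message and missing keys fall back to defaults. The
#' configuration round-trips losslessly through [write_run_config()].
#'
#' @param path JSON file path.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: '", path, "'")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), run_config_fields)
  if (length(unknown))
    stop("configuration error: unknown config key(s): ",
         paste(unknown, collapse = ", "),
         " (allowed: ", paste(run_config_fields, collapse = ", "), ")")
  utils::modifyList(default_run_config(), cfg)
}

#' @rdname read_run_config
#' @param config named list of settings.
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), run_config_fields)
  if (length(unknown))
    stop("configuration error: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
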