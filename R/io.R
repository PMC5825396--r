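# Round-trip file formats: feature matrices, scale factors, model
# bundles, run configurations.

#' Write / read a scale-factor table
#'
#' CSV with the canonical pathway keys as header, one row per cell;
#' generation seed and log-normal parameters go to a JSON sidecar
#' `<path>.json`.
#'
#' @param table Matrix from [draw_scale_factors()].
#' @param path CSV path.
#' @return `path` (write) / the matrix with attributes restored (read).
#' @export
write_scale_factors <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  side <- list(seed = attr(table, "seed"), sigma_log = attr(table, "sigma_log"),
               mean_log = attr(table, "mean_log"), n_cells = nrow(table))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scale_factors
#' @export
read_scale_factors <- function(path) {
  tab <- as.matrix(utils::read.csv(path, check.names = FALSE))
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    attr(tab, "seed") <- side$seed
    attr(tab, "sigma_log") <- side$sigma_log
    attr(tab, "mean_log") <- side$mean_log
  }
  tab
}

#' Write / read a feature matrix
#'
#' Plain CSV with `"<protocol>.<feature>"` column names, the layout the
#' simulator emits; externally measured feature tables in the same
#' layout can be read back and used everywhere a simulated matrix is.
#'
#' @param x Feature matrix (e.g. from [retained_features()]).
#' @param path CSV path.
#' @return `path` / the matrix.
#' @export
write_feature_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' Serialize a fitted cross-cell model to JSON
#'
#' Stores the coefficient matrix, preprocessing statistics, component
#' count, CV summary and package version in a single JSON bundle that
#' [read_crosscell()] restores to a usable (predict-capable) model.
#'
#' @param object A `crosscell` model.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_crosscell <- function(object, path) {
  stopifnot(inherits(object, "crosscell"))
  bundle <- list(
    type = "crosscell",
    version = as.character(utils::packageVersion("crosscell")),
    ncomp = object$ncomp,
    k_folds = object$k_folds,
    seed = object$seed,
    n = object$n,
    x_names = rownames(object$B),
    y_names = colnames(object$B),
    B = unclass(object$B),
    x_stats = lapply(object$x_stats, unclass),
    y_stats = lapply(object$y_stats, unclass),
    r2 = as.list(object$r2),
    press = object$cv$press)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_crosscell
#' @export
read_crosscell <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(b$type, "crosscell")) stop("not a crosscell bundle: ", path)
  B <- matrix(unlist(b$B), nrow = length(b$x_names),
              dimnames = list(b$x_names, b$y_names))
  fix_stats <- function(s, names) {
    list(log = stats::setNames(as.logical(s$log), names),
         mean = stats::setNames(as.numeric(s$mean), names),
         sd = stats::setNames(as.numeric(s$sd), names))
  }
  structure(
    list(B = B, x_stats = fix_stats(b$x_stats, b$x_names),
         y_stats = fix_stats(b$y_stats, b$y_names),
         ncomp = b$ncomp, k_folds = b$k_folds, seed = b$seed, n = b$n,
         r2 = unlist(b$r2), adj_r2 = adjusted_r2(unlist(b$r2), b$n, b$ncomp),
         cv = list(press = b$press), fitted = NULL, y = NULL, x = NULL,
         n_dropped = NA_integer_, call = NULL),
    class = "crosscell")
}

#' Run configuration
#'
#' Loads a YAML (or JSON) run configuration and materialises defaults so
#' that every seed and setting is explicit; the result round-trips
#' through [write_run_config()] unchanged.
#'
#' @param path YAML/JSON file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  default_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Partial configuration list.
#' @export
default_config <- function(cfg = list()) {
  def <- list(
    source_model = "ipsc", target_model = "adult",
    n_cells = 600L, sigma_log = 0.2624, mean_log = 0, seed = 1L,
    duration = 120, protocol_set = "standard",
    k_folds = 5L, tol = 0.05, record_tail_ms = 5000,
    drop_threshold = 0.25, out_dir = ".")
  for (nm in names(def)) if (is.null(cfg[[nm]])) cfg[[nm]] <- def[[nm]]
  cfg$n_cells <- as.integer(cfg$n_cells)
  cfg$seed <- as.integer(cfg$seed)
  cfg$k_folds <- as.integer(cfg$k_folds)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
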