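# High-level pipeline steps tying the modules together; these back the
# command-line interface in inst/cli/crosscell.R.

.cfg_models <- function(config) {
  list(source = fixture_model(config$source_model),
       target = fixture_model(config$target_model))
}

.cfg_protocols <- function(config, kind) {
  standard_protocols(kind, duration = config$duration)
}

#' Simulate paired populations and write feature tables
#'
#' Draws the log-normal scale-factor table, simulates the source
#' population under its full standard protocol set and the target
#' population under its baseline protocol, and writes: the scale-factor
#' CSV (+ JSON sidecar), one feature CSV per protocol, and an
#' abnormality report JSON with the retained-condition decision.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the two `population_features` objects
#'   and the written paths.
#' @export
run_population_study <- function(config = default_config(),
                                 out_dir = config$out_dir) {
  config <- default_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- .cfg_models(config)
  sf <- draw_scale_factors(population_config(
    config$n_cells, config$sigma_log, config$mean_log, config$seed))
  write_scale_factors(sf, file.path(out_dir, "scale_factors.csv"))

  src_prot <- .cfg_protocols(config, config$source_model)
  tgt_base <- .cfg_protocols(config, config$target_model)
  tgt_base <- tgt_base[if (config$target_model == "adult") "pace1" else "spont"]

  src <- simulate_population(models$source, src_prot, scale_factors = sf,
                             record_tail_ms = config$record_tail_ms,
                             drop_threshold = config$drop_threshold,
                             steady_check = TRUE)
  tgt <- simulate_population(models$target, tgt_base, scale_factors = sf,
                             record_tail_ms = config$record_tail_ms,
                             drop_threshold = config$drop_threshold,
                             steady_check = TRUE)

  paths <- character(0)
  for (side in c("source", "target")) {
    res <- if (side == "source") src else tgt
    for (pid in names(res$features)) {
      p <- file.path(out_dir, paste0("features_", side, "_", pid, ".csv"))
      utils::write.csv(as.data.frame(res$features[[pid]]), p,
                       row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  report <- list(
    seed = config$seed, n_cells = config$n_cells,
    sigma_log = config$sigma_log,
    package_version = as.character(utils::packageVersion("crosscell")),
    source = list(model = models$source$id, abnormal = src$abnormal,
                  retained = src$retained,
                  steady_fraction = as.list(src$steady)),
    target = list(model = models$target$id, abnormal = tgt$abnormal,
                  retained = tgt$retained,
                  steady_fraction = as.list(tgt$steady)))
  jsonlite::write_json(report, file.path(out_dir, "abnormality_report.json"),
                       auto_unbox = TRUE, dataframe = "rows")
  dropped <- setdiff(names(src$features), src$retained)
  if (length(dropped)) {
    message("dropped condition(s) (>",
            100 * config$drop_threshold, "% abnormal): ",
            paste(dropped, collapse = ", "))
  }
  invisible(list(source = src, target = tgt, scale_factors = sf,
                 paths = paths, config = config))
}

#' Fit the cross-cell model from a population study
#'
#' @param study Result of [run_population_study()] (or a list with
#'   `source`/`target` `population_features`).
#' @param config A `run_config`.
#' @param out_dir If non-`NULL`, write the model bundle
#'   (`crosscell_model.json`) and a CV report JSON there.
#' @return The fitted `crosscell` model.
#' @export
fit_from_study <- function(study, config = study$config, out_dir = NULL) {
  config <- default_config(config)
  x <- retained_features(study$source)
  y <- retained_features(study$target)
  fit <- fit_crosscell(x, y, k_folds = config$k_folds, tol = config$tol,
                       seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_crosscell(fit, file.path(out_dir, "crosscell_model.json"))
    jsonlite::write_json(
      list(ncomp = fit$ncomp, press = fit$cv$press, r2 = as.list(fit$r2),
           adj_r2 = as.list(fit$adj_r2), k_folds = fit$k_folds,
           seed = fit$seed, n = fit$n,
           fold_sizes = as.integer(table(fit$cv$folds))),
      file.path(out_dir, "cv_report.json"), auto_unbox = TRUE)
  }
  fit
}

#' Rank protocols and enumerate triplets for a study
#'
#' @inheritParams fit_from_study
#' @return List with `inclusion` and `exclusion` `protocol_ranking`s and
#'   the `triplet_enumeration`.
#' @export
select_from_study <- function(study, config = study$config, out_dir = NULL) {
  config <- default_config(config)
  blocks <- study$source$features[study$source$retained]
  y <- retained_features(study$target)
  inc <- rank_protocols(blocks, y, "inclusion", k_folds = config$k_folds,
                        seed = config$seed, tol = config$tol)
  exc <- rank_protocols(blocks, y, "exclusion", k_folds = config$k_folds,
                        seed = config$seed, tol = config$tol)
  tri <- enumerate_triplets(blocks, y, k_folds = config$k_folds,
                            seed = config$seed, tol = config$tol)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(inclusion = list(ranking = inc$ranking, steps = inc$steps),
           exclusion = list(ranking = exc$ranking, steps = exc$steps),
           seed = config$seed),
      file.path(out_dir, "protocol_ranking.json"),
      auto_unbox = TRUE, dataframe = "rows")
    utils::write.csv(tri$table, file.path(out_dir, "triplet_models.csv"),
                     row.names = FALSE)
  }
  list(inclusion = inc, exclusion = exc, triplets = tri)
}
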