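# Heterogeneous model populations: log-normal parameter scaling, paired
# populations across cell types, abnormality accounting.

#' Population configuration
#'
#' @param n_cells Number of cells.
#' @param sigma_log Standard deviation of the log-transformed scale
#'   factors (default 0.2624, which puts 95% of expression levels between
#'   60% and 167% of control).
#' @param mean_log Mean of the log-transformed scale factors (default 0).
#' @param seed Integer seed; recorded in all derived outputs.
#' @return A `population_config` object.
#' @export
population_config <- function(n_cells, sigma_log = 0.2624, mean_log = 0,
                              seed = 1L) {
  if (!is.finite(n_cells) || n_cells < 1) stop("n_cells must be >= 1")
  if (!is.finite(sigma_log) || sigma_log <= 0) stop("sigma_log must be > 0")
  structure(list(n_cells = as.integer(n_cells), sigma_log = sigma_log,
                 mean_log = mean_log, seed = as.integer(seed)),
            class = "population_config")
}

# evaluate `expr` with the RNG seeded to `seed`, restoring global RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw a table of log-normal scale factors
#'
#' One row per cell, one column per transport pathway; entries are
#' i.i.d. log-normal with log-mean `mean_log` and log-SD `sigma_log`.
#' Reproducible given the config seed.
#'
#' @param config A `population_config`, or a number of cells (with the
#'   remaining settings at their defaults).
#' @param seed Seed override when `config` is given as a count.
#' @return `n_cells` x 13 matrix with pathway column names; attributes
#'   `seed`, `sigma_log`, `mean_log`.
#' @export
draw_scale_factors <- function(config, seed = 1L) {
  if (is.numeric(config)) config <- population_config(config, seed = seed)
  stopifnot(inherits(config, "population_config"))
  keys <- transport_pathways()
  tab <- with_seed(config$seed, {
    matrix(stats::rlnorm(config$n_cells * length(keys),
                         meanlog = config$mean_log,
                         sdlog = config$sigma_log),
           nrow = config$n_cells, ncol = length(keys),
           dimnames = list(NULL, keys))
  })
  attr(tab, "seed") <- config$seed
  attr(tab, "sigma_log") <- config$sigma_log
  attr(tab, "mean_log") <- config$mean_log
  tab
}

#' Build paired populations of two cell types
#'
#' Applies the same scale-factor table to both models, so cell i in the
#' two populations carries identical relative expression levels and the
#' populations are index-aligned for regression.
#'
#' @param modelA,modelB `cell_model` objects.
#' @param table Scale-factor matrix from [draw_scale_factors()].
#' @return List of two `cell_population` objects (`A`, `B`), each holding
#'   the base model and the table.
#' @export
build_paired_populations <- function(modelA, modelB, table) {
  stopifnot(inherits(modelA, "cell_model"), inherits(modelB, "cell_model"))
  keys <- transport_pathways()
  if (!identical(colnames(table), keys)) {
    stop("scale-factor table columns must be the canonical pathway keys ",
         "in order: ", paste(keys, collapse = ", "))
  }
  if (any(!is.finite(table)) || any(table <= 0)) {
    stop("scale factors must be positive and finite")
  }
  mk <- function(model) structure(list(model = model, scale_factors = table),
                                  class = "cell_population")
  list(A = mk(modelA), B = mk(modelB))
}

#' @export
print.cell_population <- function(x, ...) {
  cat("<cell_population> ", x$model$id, ", ", nrow(x$scale_factors),
      " cells (seed ", attr(x$scale_factors, "seed") %||% NA, ")\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of abnormal cells under one condition
#'
#' A condition is dropped when strictly more than `threshold` (default
#' 25%) of the population's cells exhibit abnormal dynamics
#' (afterdepolarizations, repolarization failure, or loss of beating).
#'
#' @param flags List (one element per cell) of character flag vectors as
#'   returned by [detect_abnormal()]; a cell is abnormal when its vector
#'   is non-empty.
#' @param threshold Drop threshold (exclusive).
#' @return List with `fraction`, `n_abnormal`, `n`, and `drop` (logical).
#' @export
condition_abnormal_fraction <- function(flags, threshold = 0.25) {
  if (length(flags) == 0L) stop("empty population")
  abnormal <- vapply(flags, function(f) length(f) > 0L, logical(1))
  frac <- mean(abnormal)
  list(fraction = frac, n_abnormal = sum(abnormal), n = length(abnormal),
       drop = frac > threshold)
}

#' Simulate a population under a set of protocols
#'
#' Runs every cell of a population under every protocol, segments the
#' final beat, extracts biomarkers and abnormality flags, and applies the
#' condition-retention rule (a condition is dropped when more than 25% of
#' cells are abnormal).
#'
#' @param population A `cell_population` from
#'   [build_paired_populations()], or a `cell_model` plus `scale_factors`.
#' @param protocols Named list of `protocol_spec`s.
#' @param scale_factors Scale-factor matrix when `population` is a bare
#'   model.
#' @param extra_scaling Optional single transport scaling applied to all
#'   cells on top of the population scaling (used for drug block).
#' @param record_tail_ms Length of the recorded trace tail used for
#'   segmentation (default 5000 ms, at least two cycles of the slowest
#'   protocol).
#' @param drop_threshold Abnormal-fraction threshold for dropping a
#'   condition.
#' @param steady_check Also compute the APD90 steady-state diagnostic on
#'   the final two beats of each paced trace.
#' @param ... Passed to [integrate_model()].
#' @return A `population_features` object: list with
#'   \describe{
#'     \item{features}{named list of cells x features matrices, one per
#'       protocol (all protocols, including dropped ones).}
#'     \item{flags}{named list (per protocol) of per-cell flag vectors.}
#'     \item{abnormal}{data frame of per-protocol abnormal fractions and
#'       the keep/drop decision.}
#'     \item{retained}{character vector of retained protocol ids.}
#'     \item{steady}{per-protocol fraction of cells passing the
#'       steady-state diagnostic (if `steady_check`).}
#'   }
#' @export
simulate_population <- function(population, protocols, scale_factors = NULL,
                                extra_scaling = NULL, record_tail_ms = 5000,
                                drop_threshold = 0.25, steady_check = FALSE,
                                ...) {
  if (inherits(population, "cell_model")) {
    if (is.null(scale_factors)) stop("scale_factors needed with a bare model")
    population <- structure(list(model = population,
                                 scale_factors = scale_factors),
                            class = "cell_population")
  }
  stopifnot(inherits(population, "cell_population"), is.list(protocols))
  if (is.null(names(protocols))) {
    names(protocols) <- vapply(protocols, `[[`, "", "id")
  }
  tab <- population$scale_factors
  n <- nrow(tab)
  base <- population$model
  if (!is.null(extra_scaling)) base <- apply_scaling(base, extra_scaling)

  features <- list(); flags <- list(); steady <- list()
  for (pid in names(protocols)) {
    pr <- protocols[[pid]]
    mode <- pr$mode
    nms <- feature_names(mode)
    fm <- matrix(NA_real_, n, length(nms), dimnames = list(NULL, nms))
    fl <- vector("list", n)
    st <- rep(NA, n)
    rec <- max(0, pr$duration * 1000 - record_tail_ms)
    for (i in seq_len(n)) {
      m <- apply_scaling(base, tab[i, ])
      tr <- integrate_model(m, pr, record_from = rec, ...)
      if (tr$failed) {
        fl[[i]] <- "integration_failure"
        next
      }
      beat <- segment_last_beat(tr)
      fl[[i]] <- detect_abnormal(beat)
      fm[i, ] <- extract_features(beat, mode = mode)
      if (steady_check && mode == "paced") {
        st[i] <- steady_state_check(tr)$steady
      }
    }
    features[[pid]] <- fm
    flags[[pid]] <- fl
    steady[[pid]] <- if (steady_check && pr$mode == "paced") {
      mean(st, na.rm = TRUE)
    } else NA_real_
  }

  ab <- do.call(rbind, lapply(names(protocols), function(pid) {
    cf <- condition_abnormal_fraction(flags[[pid]], drop_threshold)
    data.frame(protocol = pid, fraction = cf$fraction,
               n_abnormal = cf$n_abnormal, n = cf$n, drop = cf$drop,
               stringsAsFactors = FALSE)
  }))
  structure(
    list(features = features, flags = flags, abnormal = ab,
         retained = ab$protocol[!ab$drop],
         steady = unlist(steady),
         model_id = base$id, seed = attr(tab, "seed")),
    class = "population_features")
}

#' @export
print.population_features <- function(x, ...) {
  cat("<population_features> ", x$model_id, ", ",
      nrow(x$features[[1]]), " cells x ", length(x$features),
      " protocols\n", sep = "")
  cat("  retained: ", paste(x$retained, collapse = ", "), "\n", sep = "")
  dropped <- setdiff(names(x$features), x$retained)
  if (length(dropped)) {
    cat("  dropped (>25% abnormal): ", paste(dropped, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Feature matrix of the retained conditions
#'
#' @param x A `population_features` object.
#' @param protocols Protocol ids to include (default: retained ones).
#' @return Feature matrix as from [feature_table()].
#' @export
retained_features <- function(x, protocols = NULL) {
  stopifnot(inherits(x, "population_features"))
  if (is.null(protocols)) protocols <- x$retained
  feature_table(x$features[protocols])
}
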