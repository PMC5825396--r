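# Ranking experimental protocols by their contribution to cross-cell-type
# predictive strength.

# drop zero-variance columns from a block; NULL if nothing usable remains
.clean_block <- function(block, id) {
  v <- apply(block, 2, stats::sd, na.rm = TRUE)
  keep <- is.finite(v) & v > 0
  if (!any(keep)) {
    warning("protocol '", id, "' has no usable (non-degenerate) features; ",
            "excluded from selection")
    return(NULL)
  }
  block[, keep, drop = FALSE]
}

# mean held-out R2 across outputs for a given set of protocol blocks
.subset_metric <- function(blocks, y, k_folds, seed, tol, log_features) {
  x <- feature_table(blocks)
  cv <- press_cv(x, y, k_folds = k_folds, seed = seed,
                 log_features = log_features)
  nc <- as.integer(select_components(cv = cv, x = NULL, y = NULL, tol = tol))
  list(r2 = mean(cv$r2[min(nc, nrow(cv$r2)), ]), ncomp = nc,
       r2_by_output = cv$r2[min(nc, nrow(cv$r2)), ])
}

#' Rank protocols by sequential inclusion or exclusion
#'
#' Greedy ranking of candidate experimental conditions by their
#' contribution to cross-cell-type prediction.  The step metric is the
#' mean cross-validated held-out R-squared across all predicted target
#' features.
#' * `"inclusion"`: start from the single best protocol, then repeatedly
#'   add the protocol that raises the metric most.
#' * `"exclusion"`: start from all protocols, then repeatedly remove the
#'   protocol whose loss lowers the metric least.
#'
#' @param x_blocks Named list of per-protocol source feature matrices
#'   (cells x features), e.g. `population_features$features[retained]`.
#' @param y Target feature matrix, rows aligned with the blocks.
#' @param method `"inclusion"` or `"exclusion"`.
#' @param k_folds,seed,tol,log_features Passed to the cross-validated
#'   fits.
#' @return A `protocol_ranking`: list with `ranking` (protocol ids, most
#'   informative first), `steps` (data frame with per-step metric), and
#'   the settings.
#' @export
rank_protocols <- function(x_blocks, y, method = c("inclusion", "exclusion"),
                           k_folds = 5, seed = 1, tol = 0.05,
                           log_features = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(x_blocks), !is.null(names(x_blocks)))
  y <- as.matrix(y)
  blocks <- list()
  for (id in names(x_blocks)) {
    b <- .clean_block(as.matrix(x_blocks[[id]]), id)
    if (!is.null(b)) blocks[[id]] <- b
  }
  if (length(blocks) < 1) stop("no usable protocol blocks")
  ok <- stats::complete.cases(do.call(cbind, blocks)) &
    stats::complete.cases(y)
  blocks <- lapply(blocks, function(b) b[ok, , drop = FALSE])
  y <- y[ok, , drop = FALSE]
  ids <- names(blocks)

  steps <- data.frame(step = integer(), protocol = character(),
                      n_active = integer(), r2 = numeric(),
                      ncomp = integer(), stringsAsFactors = FALSE)
  if (method == "inclusion") {
    active <- character(0)
    remaining <- ids
    while (length(remaining)) {
      scores <- vapply(remaining, function(id) {
        .subset_metric(blocks[c(active, id)], y, k_folds, seed, tol,
                       log_features)$r2
      }, numeric(1))
      best <- remaining[which.max(scores)]
      active <- c(active, best)
      m <- .subset_metric(blocks[active], y, k_folds, seed, tol, log_features)
      steps <- rbind(steps, data.frame(
        step = length(active), protocol = best, n_active = length(active),
        r2 = m$r2, ncomp = m$ncomp, stringsAsFactors = FALSE))
      remaining <- setdiff(remaining, best)
    }
    ranking <- steps$protocol
  } else {
    active <- ids
    removed <- character(0)
    m <- .subset_metric(blocks[active], y, k_folds, seed, tol, log_features)
    steps <- rbind(steps, data.frame(
      step = 0L, protocol = NA_character_, n_active = length(active),
      r2 = m$r2, ncomp = m$ncomp, stringsAsFactors = FALSE))
    while (length(active) > 1) {
      scores <- vapply(active, function(id) {
        .subset_metric(blocks[setdiff(active, id)], y, k_folds, seed, tol,
                       log_features)$r2
      }, numeric(1))
      # reject the protocol whose exclusion hurts least
      drop_id <- active[which.max(scores)]
      active <- setdiff(active, drop_id)
      removed <- c(removed, drop_id)
      m <- .subset_metric(blocks[active], y, k_folds, seed, tol, log_features)
      steps <- rbind(steps, data.frame(
        step = length(removed), protocol = drop_id,
        n_active = length(active), r2 = m$r2, ncomp = m$ncomp,
        stringsAsFactors = FALSE))
    }
    ranking <- rev(c(removed, active))
  }
  structure(list(method = method, ranking = ranking, steps = steps,
                 k_folds = k_folds, seed = seed),
            class = "protocol_ranking")
}

#' @export
print.protocol_ranking <- function(x, ...) {
  cat("<protocol_ranking> sequential ", x$method, " (", x$k_folds,
      "-fold CV, seed ", x$seed, ")\n", sep = "")
  cat("  most -> least informative: ", paste(x$ranking, collapse = " > "),
      "\n", sep = "")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Evaluate every protocol triplet
#'
#' Fits and cross-validates one regression model per combination of
#' `size` protocols (all 56 triplets for 8 candidates) and reports
#' adjusted R-squared per target output, adjusted for the number of
#' PLSR components.
#'
#' @inheritParams rank_protocols
#' @param size Combination size (default 3).
#' @return List with `table` (data frame: protocols, ncomp, mean R2,
#'   mean adjusted R2) and `adj_r2` (combinations x outputs matrix),
#'   class `triplet_enumeration`.
#' @export
enumerate_triplets <- function(x_blocks, y, k_folds = 5, seed = 1,
                               tol = 0.05, size = 3, log_features = NULL) {
  stopifnot(is.list(x_blocks), !is.null(names(x_blocks)))
  if (length(x_blocks) < size) stop("need at least ", size, " protocols")
  y <- as.matrix(y)
  ok <- stats::complete.cases(do.call(cbind, x_blocks)) &
    stats::complete.cases(y)
  x_blocks <- lapply(x_blocks, function(b) as.matrix(b)[ok, , drop = FALSE])
  y <- y[ok, , drop = FALSE]
  combos <- utils::combn(names(x_blocks), size, simplify = FALSE)
  n <- nrow(y)
  adj <- matrix(NA_real_, length(combos), ncol(y),
                dimnames = list(NULL, colnames(y)))
  tab <- data.frame(protocols = vapply(combos, paste, "", collapse = "+"),
                    ncomp = NA_integer_, r2 = NA_real_, adj_r2 = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(combos)) {
    m <- .subset_metric(x_blocks[combos[[i]]], y, k_folds, seed, tol,
                        log_features)
    adj[i, ] <- adjusted_r2(m$r2_by_output, n, m$ncomp)
    tab$ncomp[i] <- m$ncomp
    tab$r2[i] <- m$r2
    tab$adj_r2[i] <- mean(adj[i, ])
  }
  structure(list(table = tab, adj_r2 = adj, members = combos, size = size,
                 k_folds = k_folds, seed = seed),
            class = "triplet_enumeration")
}

#' @export
print.triplet_enumeration <- function(x, n = 10, ...) {
  cat("<triplet_enumeration> ", nrow(x$table), " models of ", x$size,
      " protocols each\n", sep = "")
  ord <- order(-x$table$adj_r2)
  print(utils::head(x$table[ord, ], n), row.names = FALSE)
  invisible(x)
}
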