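# The cross-cell-type regression model: fitting, prediction, methods.

#' Fit a cross-cell-type regression model
#'
#' Fits a partial least squares regression that maps biomarkers measured
#' in a source cell type (e.g. an iPSC-derived cardiomyocyte population
#' simulated under several experimental conditions) to biomarkers of a
#' target cell type (e.g. adult ventricular myocytes at their baseline
#' condition).  Rows are cells of index-aligned heterogeneous
#' populations.  Features are log-transformed where strictly positive,
#' z-scored, and the coefficient matrix `B_cross` is estimated by
#' SIMPLS.  The number of latent components is chosen by k-fold
#' cross-validation as the smallest count whose PRESS is within `tol` of
#' the minimum.
#'
#' @param x Source feature matrix (cells x features; columns named
#'   `"<protocol>.<feature>"`), e.g. from [retained_features()].
#' @param y Target feature matrix (cells x features).
#' @param ncomp Number of components; `NULL` (default) selects by
#'   cross-validated PRESS.
#' @param k_folds Cross-validation folds (default 5).
#' @param tol Relative PRESS tolerance for component selection.
#' @param seed Seed for the fold assignment.
#' @param log_features See [preprocess_features()].
#' @return A `crosscell` object with components `B` (coefficients on
#'   preprocessed scales), `x_stats`/`y_stats` (preprocessing
#'   statistics), `ncomp`, `cv` (the `cv_report`), `r2` (per-output
#'   held-out R-squared at `ncomp`), `adj_r2`, `fitted`, `n`.
#' @examples
#' \donttest{
#' set.seed(1)
#' x <- matrix(rlnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- cbind(APD90 = x[, 1] * x[, 2]^0.5 * rlnorm(100, 0, 0.02))
#' fit <- fit_crosscell(x, y)
#' summary(fit)
#' }
#' @export
fit_crosscell <- function(x, y, ncomp = NULL, k_folds = 5, tol = 0.05,
                          seed = 1, log_features = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) {
    stop("x and y must describe the same cells (row counts differ: ",
         nrow(x), " vs ", nrow(y), ")")
  }
  ok <- stats::complete.cases(x) & stats::complete.cases(y)
  n_dropped <- sum(!ok)
  x <- x[ok, , drop = FALSE]; y <- y[ok, , drop = FALSE]

  cv <- press_cv(x, y, k_folds = k_folds, seed = seed, ncomp = ncomp,
                 log_features = log_features)
  if (is.null(ncomp)) {
    ncomp <- as.integer(select_components(cv = cv, x = NULL, y = NULL,
                                          tol = tol))
  }
  px <- preprocess_features(x, log_features)
  py <- preprocess_features(y, log_features)
  fit <- fit_plsr(px$z, py$z, ncomp)
  B <- plsr_coef(fit, ncomp)
  zhat <- px$z %*% B
  fitted <- invert_preprocess(zhat, py$stats)

  structure(
    list(B = B, x_stats = px$stats, y_stats = py$stats,
         ncomp = ncomp, cv = cv,
         r2 = cv$r2[min(ncomp, nrow(cv$r2)), ],
         adj_r2 = adjusted_r2(cv$r2[min(ncomp, nrow(cv$r2)), ],
                              nrow(x), ncomp),
         fitted = fitted, y = y, x = x, n = nrow(x),
         n_dropped = n_dropped, k_folds = k_folds, seed = seed,
         call = match.call()),
    class = "crosscell")
}

#' @export
print.crosscell <- function(x, ...) {
  cat("Cross-cell-type PLSR model\n")
  cat("  ", ncol(x$B), " target feature(s) from ", nrow(x$B),
      " source feature column(s), n = ", x$n, " cells",
      if (x$n_dropped > 0) paste0(" (", x$n_dropped, " dropped, incomplete)"),
      "\n", sep = "")
  cat("  components: ", x$ncomp, " (", x$k_folds,
      "-fold CV, PRESS-selected)\n", sep = "")
  cat("  mean held-out R2: ", round(mean(x$r2), 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.crosscell <- function(object, ...) {
  out <- data.frame(feature = names(object$r2),
                    r2 = as.numeric(object$r2),
                    adj_r2 = as.numeric(object$adj_r2))
  structure(list(table = out, ncomp = object$ncomp, n = object$n,
                 press = object$cv$press), class = "summary.crosscell")
}

#' @export
print.summary.crosscell <- function(x, ...) {
  cat("Cross-cell-type PLSR model: ", x$n, " cells, ", x$ncomp,
      " components\n", sep = "")
  cat("Held-out R2 by target feature:\n")
  tab <- x$table
  tab$r2 <- round(tab$r2, 4); tab$adj_r2 <- round(tab$adj_r2, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.crosscell <- function(object, ...) object$B

#' @export
residuals.crosscell <- function(object, ...) object$y - object$fitted

#' Predict target-cell features or drug-induced changes
#'
#' In `type = "response"` mode, source features are preprocessed with
#' the stored statistics, multiplied by `B_cross` and back-transformed,
#' giving absolute target-cell feature values.  In `type = "change"`
#' mode, `newdata` is a matrix (or vector) of drug-induced changes of
#' the source features - log-ratios post/pre for log-transformed
#' features, absolute differences for voltage features - and the return
#' value is the predicted change of the target features, reported as
#' percent change for log-scale features and absolute difference (mV)
#' for voltage features.
#'
#' @param object A `crosscell` model.
#' @param newdata Matrix (or single named vector) with exactly the
#'   model's source columns.
#' @param type `"response"` or `"change"`.
#' @param ... Unused.
#' @return Matrix of predictions (cells/conditions x target features).
#' @export
predict.crosscell <- function(object, newdata,
                              type = c("response", "change"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, 1, dimnames = list(NULL, names(newdata)))
  }
  newdata <- as.matrix(newdata)
  want <- names(object$x_stats$mean)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(want)) stop("newdata has wrong width")
    colnames(newdata) <- want
  }
  miss <- setdiff(want, colnames(newdata))
  extra <- setdiff(colnames(newdata), want)
  if (length(miss) || length(extra)) {
    stop("newdata columns do not match the model",
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
  }
  newdata <- newdata[, want, drop = FALSE]

  if (type == "response") {
    z <- preprocess_features(newdata, stats = object$x_stats)$z
    return(invert_preprocess(z %*% object$B, object$y_stats))
  }
  # change mode: delta on transformed scale -> delta z -> delta y
  dz <- sweep(newdata, 2, object$x_stats$sd, "/")
  dzy <- dz %*% object$B
  dty <- sweep(dzy, 2, object$y_stats$sd, "*")
  out <- dty
  lg <- object$y_stats$log
  out[, lg] <- 100 * (exp(dty[, lg, drop = FALSE]) - 1)
  attr(out, "units") <- ifelse(lg, "percent", "absolute")
  out
}

#' Drug-induced source-feature change vector
#'
#' Builds the change representation expected by
#' `predict(..., type = "change")` from pre- and post-drug source
#' feature matrices: log-ratio post/pre for log-scale features,
#' absolute difference for voltage features.
#'
#' @param object A `crosscell` model.
#' @param pre,post Source feature matrices (cells x features) before and
#'   after the perturbation.
#' @return Matrix of changes, same shape as `pre`.
#' @export
feature_change <- function(object, pre, post) {
  stopifnot(inherits(object, "crosscell"))
  pre <- as.matrix(pre); post <- as.matrix(post)
  want <- names(object$x_stats$mean)
  pre <- pre[, want, drop = FALSE]; post <- post[, want, drop = FALSE]
  lg <- object$x_stats$log
  out <- post - pre
  out[, lg] <- log(post[, lg, drop = FALSE] / pre[, lg, drop = FALSE])
  out
}

#' @export
plot.crosscell <- function(x, features = NULL, ...) {
  r2 <- x$r2
  if (is.null(features)) {
    features <- names(r2)[seq_len(min(2, length(r2)))]
  }
  a <- min(x$ncomp, dim(x$cv$pred)[3])
  old <- graphics::par(mfrow = c(1, length(features)))
  on.exit(graphics::par(old))
  for (f in features) {
    obs <- x$y[, f]
    prd <- x$cv$pred[, f, a]
    graphics::plot(obs, prd, xlab = paste("simulated", f),
                   ylab = paste("predicted", f),
                   main = sprintf("%s (R2 = %.3f)", f, r2[[f]]), ...)
    graphics::abline(0, 1, col = "grey50")
  }
  invisible(x)
}

#' Population-based parameter sensitivity coefficients
#'
#' Regresses log-transformed biomarker outputs on the log-transformed
#' parameter scale factors of a heterogeneous population using the same
#' PLSR machinery, yielding one coefficient per (parameter, output)
#' pair: the local power-law exponent linking relative parameter change
#' to relative output change.
#'
#' @param scale_factors Cells x parameters matrix of positive scale
#'   factors.
#' @param outputs Cells x outputs matrix of positive biomarkers (rows
#'   aligned with `scale_factors`; non-positive/`NA` rows are dropped).
#' @param ncomp Components (default: full rank of the predictors).
#' @return Parameters x outputs coefficient matrix (log-log scale,
#'   rescaled to unit parameter log-SD so entries are elasticities).
#' @export
compute_sensitivities <- function(scale_factors, outputs, ncomp = NULL) {
  sf <- as.matrix(scale_factors)
  y <- as.matrix(outputs)
  stopifnot(nrow(sf) == nrow(y))
  ok <- stats::complete.cases(y) & apply(y > 0, 1, all)
  sf <- sf[ok, , drop = FALSE]; y <- y[ok, , drop = FALSE]
  lx <- log(sf); ly <- log(y)
  if (is.null(ncomp)) ncomp <- qr(scale(lx, scale = FALSE))$rank
  zx <- scale(lx); zy <- scale(ly)
  fit <- fit_plsr(zx, zy, ncomp)
  B <- plsr_coef(fit, ncomp)
  # back to raw log-log slope: dy/dx = B * sd(ly)/sd(lx)
  out <- B * outer(1 / attr(zx, "scaled:scale"), attr(zy, "scaled:scale"))
  dimnames(out) <- list(colnames(sf), colnames(y))
  out
}
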