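# Partial least squares regression (SIMPLS) with PRESS-based
# cross-validated component selection, plus feature preprocessing.

#' Preprocess a feature matrix
#'
#' Log-transforms strictly positive biomarker columns (durations, Ca2+
#' levels, amplitudes, rates), leaves voltage columns (`Vpeak`, `Vrest`,
#' which can be negative) untransformed, then centres and scales every
#' column to mean 0, SD 1.  The transformation statistics are returned so
#' the identical mapping can be applied to new data and inverted.
#'
#' @param x Numeric matrix with named columns (`"<protocol>.<feature>"`
#'   or bare feature names).
#' @param log_features `NULL` for the automatic rule above, `TRUE`/
#'   `FALSE` for all/none, or a character vector of column names to log.
#' @param stats Statistics from a previous call, to apply the stored
#'   mapping to new rows.
#' @return List with `z` (transformed matrix) and `stats` (list of
#'   `log`, `mean`, `sd` per column).
#' @export
preprocess_features <- function(x, log_features = NULL, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(stats)) {
    if (is.null(log_features)) {
      feat <- sub(".*\\.", "", colnames(x))
      lg <- !(feat %in% c("Vpeak", "Vrest")) &
        apply(x, 2, function(v) all(is.finite(v) & v > 0))
    } else if (isTRUE(log_features)) {
      lg <- rep(TRUE, ncol(x))
    } else if (isFALSE(log_features)) {
      lg <- rep(FALSE, ncol(x))
    } else {
      lg <- colnames(x) %in% log_features
    }
    xt <- x
    xt[, lg] <- log(x[, lg, drop = FALSE])
    mu <- colMeans(xt)
    sd <- apply(xt, 2, stats::sd)
    bad <- colnames(x)[!is.finite(sd) | sd <= 0]
    if (length(bad)) {
      stop("zero-variance or non-finite column(s): ",
           paste(bad, collapse = ", "))
    }
    stats <- list(log = stats::setNames(lg, colnames(x)), mean = mu, sd = sd)
  } else {
    if (!identical(colnames(x), names(stats$mean))) {
      miss <- setdiff(names(stats$mean), colnames(x))
      extra <- setdiff(colnames(x), names(stats$mean))
      stop("column mismatch with stored preprocessing stats",
           if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
           if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
    }
    xt <- x
    lg <- stats$log
    xt[, lg] <- log(x[, lg, drop = FALSE])
  }
  z <- sweep(sweep(xt, 2, stats$mean), 2, stats$sd, "/")
  list(z = z, stats = stats)
}

#' Invert preprocessing
#'
#' @param z Matrix on the preprocessed (z) scale.
#' @param stats Statistics from [preprocess_features()].
#' @return Matrix on the original scale.
#' @export
invert_preprocess <- function(z, stats) {
  x <- sweep(sweep(as.matrix(z), 2, stats$sd, "*"), 2, stats$mean, "+")
  x[, stats$log] <- exp(x[, stats$log, drop = FALSE])
  x
}

#' Fit PLSR by the SIMPLS algorithm
#'
#' Deterministic SIMPLS on centred (preprocessed) matrices.  Returns the
#' quantities needed to form the coefficient matrix for any number of
#' components up to `ncomp`, so cross-validation over component counts
#' costs a single fit per fold.
#'
#' @param x,y Preprocessed (centred) matrices with aligned rows.
#' @param ncomp Number of latent components; must not exceed the rank
#'   of `x`.
#' @return List with weight matrix `R` (p x A), y-loadings `Q` (m x A),
#'   scores `T`, x-loadings `P`, and `ncomp`.
#' @export
fit_plsr <- function(x, y, ncomp) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y))
  p <- ncol(x); m <- ncol(y)
  qrx <- qr(x)
  if (ncomp > qrx$rank) {
    stop("ncomp (", ncomp, ") exceeds rank of x (", qrx$rank, ")")
  }
  S <- crossprod(x, y)
  R <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, m, ncomp); TT <- matrix(0, nrow(x), ncomp)
  V <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    q <- svd(S, nu = 0, nv = 1)$v[, 1]
    # deterministic sign: largest-magnitude element positive
    q <- q * sign(q[which.max(abs(q))])
    r <- S %*% q
    tt <- x %*% r
    nt <- sqrt(sum(tt^2))
    if (nt < 1e-12) stop("degenerate component ", a)
    tt <- tt / nt; r <- r / nt
    pp <- crossprod(x, tt)
    qq <- crossprod(y, tt)
    v <- pp
    if (a > 1) {
      v <- v - V[, 1:(a - 1), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1), drop = FALSE], pp)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; TT[, a] <- tt; P[, a] <- pp; Q[, a] <- qq; V[, a] <- v
  }
  structure(list(R = R, Q = Q, T = TT, P = P, ncomp = ncomp,
                 xnames = colnames(x), ynames = colnames(y)),
            class = "plsr_fit")
}

#' Coefficient matrix of a PLSR fit
#'
#' @param fit A `plsr_fit`.
#' @param ncomp Number of components to use (default: all fitted).
#' @return p x m coefficient matrix on the preprocessed scales.
#' @export
plsr_coef <- function(fit, ncomp = fit$ncomp) {
  stopifnot(inherits(fit, "plsr_fit"), ncomp >= 1, ncomp <= fit$ncomp)
  B <- fit$R[, 1:ncomp, drop = FALSE] %*% t(fit$Q[, 1:ncomp, drop = FALSE])
  dimnames(B) <- list(fit$xnames, fit$ynames)
  B
}

# seeded fold assignment: a permutation chopped into k nearly equal blocks
cv_folds <- function(n, k, seed) {
  if (k < 2) stop("k_folds must be >= 2")
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  folds <- integer(n)
  folds[perm] <- rep(seq_len(k), sizes)
  folds
}

#' PRESS cross-validation of a PLSR model
#'
#' k-fold cross-validation on raw feature matrices.  Within each fold the
#' preprocessing statistics are estimated on the training rows only and
#' applied to the held-out rows.  PRESS is the sum of squared held-out
#' residuals on the preprocessed scale; per-output R-squared is computed
#' from the pooled held-out predictions on the original scale.
#'
#' @param x,y Raw (untransformed) feature matrices, rows aligned.
#' @param k_folds Number of folds (default 5; 600 cells give folds of
#'   120).
#' @param ncomp Maximum number of components to evaluate.
#' @param seed Seed for the fold assignment.
#' @param log_features See [preprocess_features()].
#' @return A `cv_report`: list with `press` (vector over component
#'   counts), `r2` (components x outputs matrix, original scale),
#'   `folds` (assignment vector), `pred` (held-out predictions at each
#'   component count, original scale, as a 3-d array), `k_folds`, `seed`.
#' @export
press_cv <- function(x, y, k_folds = 5, ncomp = NULL, seed = 1,
                     log_features = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y))
  n <- nrow(x)
  folds <- cv_folds(n, k_folds, seed)
  if (is.null(ncomp)) ncomp <- min(ncol(x), 15L)
  ncomp <- min(ncomp, ncol(x))
  if (n - max(table(folds)) < ncomp) stop("folds too small for ncomp")

  press <- numeric(ncomp)
  pred <- array(NA_real_, c(n, ncol(y), ncomp),
                dimnames = list(NULL, colnames(y), NULL))
  for (kf in seq_len(k_folds)) {
    tr <- folds != kf
    px <- preprocess_features(x[tr, , drop = FALSE], log_features)
    py <- preprocess_features(y[tr, , drop = FALSE], log_features)
    zx_te <- preprocess_features(x[!tr, , drop = FALSE],
                                 stats = px$stats)$z
    zy_te <- preprocess_features(y[!tr, , drop = FALSE],
                                 stats = py$stats)$z
    a_max <- min(ncomp, qr(px$z)$rank)
    fit <- fit_plsr(px$z, py$z, a_max)
    for (a in seq_len(ncomp)) {
      aa <- min(a, a_max)
      B <- plsr_coef(fit, aa)
      zhat <- zx_te %*% B
      press[a] <- press[a] + sum((zhat - zy_te)^2)
      pred[!tr, , a] <- invert_preprocess(zhat, py$stats)
    }
  }
  r2 <- matrix(NA_real_, ncomp, ncol(y),
               dimnames = list(NULL, colnames(y)))
  for (a in seq_len(ncomp)) {
    sse <- colSums((pred[, , a] - y)^2)
    sst <- colSums(sweep(y, 2, colMeans(y))^2)
    r2[a, ] <- 1 - sse / sst
  }
  structure(list(press = press, r2 = r2, folds = folds, pred = pred,
                 k_folds = k_folds, seed = seed, ncomp_max = ncomp),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$k_folds, "-fold CV, components 1..",
      x$ncomp_max, "\n", sep = "")
  best <- which.min(x$press)
  cat("  PRESS minimum at ", best, " component(s)\n", sep = "")
  cat("  mean held-out R2 at minimum: ",
      round(mean(x$r2[best, ]), 4), "\n", sep = "")
  invisible(x)
}

#' Select the number of PLSR components
#'
#' Chooses the smallest component count whose PRESS is within a relative
#' tolerance of the PRESS minimum (default 5%), i.e. the most
#' parsimonious model that essentially minimises PRESS while keeping
#' R-squared high.  With `tol = 0` this reduces to the strict argmin
#' with a smallest-count tie-break.
#'
#' @inheritParams press_cv
#' @param tol Relative PRESS tolerance.
#' @param cv Optionally a precomputed `cv_report`.
#' @return Selected component count (integer, with the `cv_report` as
#'   attribute `cv`).
#' @export
select_components <- function(x, y, k_folds = 5, seed = 1, tol = 0.05,
                              ncomp = NULL, log_features = NULL, cv = NULL) {
  if (is.null(cv)) {
    cv <- press_cv(x, y, k_folds = k_folds, ncomp = ncomp, seed = seed,
                   log_features = log_features)
  }
  pmin <- min(cv$press)
  sel <- which(cv$press <= (1 + tol) * pmin)[1]
  structure(as.integer(sel), cv = cv)
}

#' Adjusted R-squared
#'
#' `1 - (1 - R2) (n - 1) / (n - p - 1)`, with `p` the number of PLSR
#' components.
#'
#' @param r2 R-squared value(s).
#' @param n_rows Number of observations.
#' @param n_components Number of model components.
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n_rows, n_components) {
  if (!is.finite(n_rows) || !is.finite(n_components) ||
      n_rows <= n_components + 1) {
    stop("need n_rows > n_components + 1")
  }
  1 - (1 - r2) * (n_rows - 1) / (n_rows - n_components - 1)
}
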