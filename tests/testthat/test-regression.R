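# PLSR machinery: preprocessing, SIMPLS, PRESS CV, component selection,
# prediction, sensitivities.

test_that("preprocessing round-trips and is idempotent given stats", {
  set.seed(4)
  x <- cbind(APD90 = rlnorm(30, 5, 0.3), CaTA = rlnorm(30, -7, 0.4),
             Vpeak = rnorm(30, 40, 5), Vrest = rnorm(30, -85, 2))
  p <- preprocess_features(x)
  expect_true(p$stats$log[["APD90"]])
  expect_false(p$stats$log[["Vpeak"]])
  expect_false(p$stats$log[["Vrest"]])
  expect_lt(max(abs(colMeans(p$z))), 1e-12)
  expect_equal(unname(apply(p$z, 2, sd)), rep(1, 4))

  # inverse(preprocess(x)) = x
  expect_equal(invert_preprocess(p$z, p$stats), x, tolerance = 1e-10)

  # applying stored stats is the identical mapping
  p2 <- preprocess_features(x, stats = p$stats)
  expect_identical(p2$z, p$z)

  xc <- x; xc[, 2] <- 1
  expect_error(preprocess_features(xc), "CaTA")
})

test_that("PLSR at full rank equals the least-squares oracle", {
  for (s in 1:3) {
    set.seed(s)
    X <- scale(matrix(rnorm(150), 30, 5), scale = FALSE)
    Y <- scale(matrix(rnorm(90), 30, 3), scale = FALSE)
    B <- plsr_coef(fit_plsr(X, Y, 5))
    B_ols <- qr.solve(X, Y)  # normal-equations solution, independent route
    expect_lt(max(abs(B - B_ols)), 1e-8)
  }
})

test_that("univariate PLSR slope equals cov/var", {
  set.seed(7)
  x <- scale(matrix(rnorm(50)), scale = FALSE)
  y <- scale(matrix(2.5 * x + rnorm(50, 0, 0.1)), scale = FALSE)
  expect_equal(as.numeric(plsr_coef(fit_plsr(x, y, 1))),
               as.numeric(cov(x, y) / var(as.numeric(x))),
               tolerance = 1e-10)
})

test_that("noiseless linear maps are recovered exactly", {
  set.seed(11)
  X <- matrix(rnorm(200), 50, 4)
  B_true <- matrix(rnorm(8), 4, 2)
  Y <- X %*% B_true
  fit <- fit_plsr(scale(X, scale = FALSE), scale(Y, scale = FALSE), 4)
  Yhat <- scale(X, scale = FALSE) %*% plsr_coef(fit)
  r2 <- 1 - colSums((Yhat - scale(Y, scale = FALSE))^2) /
    colSums(scale(Y, scale = FALSE)^2)
  expect_true(all(r2 > 1 - 1e-8))
  expect_error(fit_plsr(scale(X, scale = FALSE),
                        scale(Y, scale = FALSE), 5), "rank")
})

test_that("PRESS equals a brute-force refit oracle", {
  set.seed(21)
  n <- 12
  x <- matrix(rlnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  y <- matrix(rlnorm(n * 2), n, 2,
              dimnames = list(NULL, paste0("y", 1:2)))
  k <- 3
  cv <- press_cv(x, y, k_folds = k, ncomp = 2, seed = 5)

  # oracle: explicit loop, refitting on each complement
  folds <- crosscell:::cv_folds(n, k, seed = 5)
  for (a in 1:2) {
    press <- 0
    for (kf in 1:k) {
      tr <- folds != kf
      px <- preprocess_features(x[tr, , drop = FALSE])
      py <- preprocess_features(y[tr, , drop = FALSE])
      B <- plsr_coef(fit_plsr(px$z, py$z, a))
      zx <- preprocess_features(x[!tr, , drop = FALSE], stats = px$stats)$z
      zy <- preprocess_features(y[!tr, , drop = FALSE], stats = py$stats)$z
      press <- press + sum((zx %*% B - zy)^2)
    }
    expect_equal(cv$press[a], press, tolerance = 1e-12)
  }
})

test_that("fold assignment partitions rows into near-equal blocks", {
  folds <- crosscell:::cv_folds(600, 5, seed = 1)
  expect_equal(as.integer(table(folds)), rep(120L, 5))
  expect_length(folds, 600)
  expect_identical(sort(unique(folds)), 1:5)
  expect_error(crosscell:::cv_folds(10, 1, 1), "k_folds")
})

test_that("component selection recovers a 3-dimensional latent structure", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    T3 <- matrix(rnorm(500 * 3), 500, 3)
    P <- matrix(rnorm(30), 3, 10)
    Q <- matrix(rnorm(12), 3, 4)
    X <- T3 %*% P
    Y <- T3 %*% Q + matrix(rnorm(2000, 0, 0.05), 500)
    colnames(X) <- paste0("x", 1:10); colnames(Y) <- paste0("y", 1:4)
    nc <- select_components(X, Y, k_folds = 5, seed = s,
                            log_features = FALSE)
    if (nc == 3L) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("a noiseless rank-1 map selects one component", {
  set.seed(2)
  tt <- rnorm(100)
  x <- tt %*% t(c(1, -2, 0.5))        # rank-1 predictor block
  colnames(x) <- paste0("x", 1:3)
  y <- tt %*% t(c(1, 2))
  colnames(y) <- paste0("y", 1:2)
  nc <- select_components(x, y, k_folds = 5, seed = 1,
                          log_features = FALSE)
  expect_equal(as.integer(nc), 1L)
  # tol = 0 is the strict argmin with smallest-count tie-break
  cvfake <- list(press = c(5, 3, 3, 4))
  expect_equal(as.integer(select_components(cv = cvfake, x = NULL, y = NULL,
                                            tol = 0)), 2L)
})

test_that("adjusted R-squared follows its definition", {
  expect_equal(adjusted_r2(0.9, 600, 5), 0.89916, tolerance = 1e-5)
  expect_equal(adjusted_r2(1, 600, 5), 1)
  r2 <- runif(10)
  expect_true(all(adjusted_r2(r2, 100, 4) <= r2))
  expect_error(adjusted_r2(0.5, 5, 5), "n_rows")
})

test_that("crosscell predictions behave as a linear translation", {
  set.seed(33)
  n <- 120
  lf <- matrix(rnorm(n * 3), n, 3)
  X <- exp(cbind(lf %*% c(1, 0.5, 0), lf %*% c(0, 1, 0.3),
                 lf %*% c(0.2, 0, 1)) + rnorm(n * 3, 0, 0.02))
  colnames(X) <- c("spont.APD90", "spont.CaTA", "spont.rate")
  Y <- exp(cbind(lf %*% c(0.8, 0.3, 0.1)) + rnorm(n, 0, 0.02))
  colnames(Y) <- "pace1.APD90"
  fit <- fit_crosscell(X, Y, seed = 1)

  # training cells reproduce their fitted values
  pr <- predict(fit, X)
  expect_equal(pr, fit$fitted, tolerance = 1e-10)

  # zero change vector predicts exactly zero percent change
  z <- setNames(rep(0, 3), colnames(X))
  expect_equal(as.numeric(predict(fit, z, type = "change")), 0)

  # column mismatch errors name the offenders
  expect_error(predict(fit, matrix(1, 1, 2, dimnames = list(NULL,
    c("spont.APD90", "bogus")))), "bogus")

  # round-trip through the JSON bundle preserves predictions
  path <- tempfile(fileext = ".json")
  write_crosscell(fit, path)
  fit2 <- read_crosscell(path)
  expect_equal(predict(fit2, X), pr, tolerance = 1e-12)
  expect_equal(fit2$ncomp, fit$ncomp)
})

test_that("sensitivities recover known power-law exponents", {
  set.seed(8)
  n <- 500
  sf <- draw_scale_factors(population_config(n, seed = 44))
  a_apd <- c(GKr = -0.6, GCaL = 0.3, GK1 = -0.2)
  a_cat <- c(GCaL = 0.8, KSERCA = 0.4, KNCX = -0.5)
  mk <- function(a) {
    lg <- log(sf) %*% ifelse(transport_pathways() %in% names(a),
                             a[transport_pathways()], 0)
    as.numeric(exp(lg + rnorm(n, 0, 0.005)))
  }
  outputs <- cbind(APD90 = mk(a_apd), CaTA = mk(a_cat))
  S <- compute_sensitivities(sf, outputs)
  expect_lt(abs(S["GKr", "APD90"] - -0.6), 0.02)
  expect_lt(abs(S["GCaL", "CaTA"] - 0.8), 0.02)
  # a parameter with no effect has a near-zero coefficient
  expect_lt(abs(S["Gto", "APD90"]), 0.02)
  expect_lt(abs(S["GbNa", "CaTA"]), 0.02)
})

test_that("fixture sensitivity signs match the pharmacology", {
  study <- cached_study()
  ok <- stats::complete.cases(study$target$features$pace1)
  S <- compute_sensitivities(study$sf[ok, ],
                             study$target$features$pace1[ok, c("APD90",
                                                               "CaTA")])
  expect_lt(S["GKr", "APD90"], 0)   # more IKr -> shorter APs
  expect_gt(S["GCaL", "CaTA"], 0)   # more ICaL -> bigger transients
})
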