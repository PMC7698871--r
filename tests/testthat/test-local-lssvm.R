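test_that("the Gaussian kernel satisfies its identities", {
  set.seed(1)
  x <- rnorm(5); y <- rnorm(5)
  expect_equal(gaussian_kernel(x, x, 2), 1)
  expect_equal(gaussian_kernel(x, y, 1.7), gaussian_kernel(y, x, 1.7))
  s0 <- 0.8
  z <- x + c(s0 * sqrt(2), rep(0, 4))   # distance exactly sigma0 * sqrt(2)
  expect_equal(gaussian_kernel(x, z, s0), exp(-1))
  expect_error(gaussian_kernel(1:3, 1:2, 1), "dimension")
})

test_that("degenerate LS-SVM fits are solved exactly", {
  f1 <- fit_ls_svm(matrix(5), 7, gamma = 3, sigma0 = 1)
  expect_equal(f1$alpha, 0)
  expect_equal(f1$b, 7)
  expect_equal(predict(f1, matrix(c(-10, 0, 10))), c(7, 7, 7))

  f2 <- fit_ls_svm(matrix(c(-1, 1)), c(-1, 1), gamma = 42, sigma0 = 0.9)
  expect_equal(f2$b, 0, tolerance = 1e-12)
  expect_equal(predict(f2, matrix(0)), 0, tolerance = 1e-12)
})

test_that("every fitted dual solution satisfies the system contract", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:10, 1); d <- sample(1:4, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- rnorm(n)
    fit <- fit_ls_svm(X, y, gamma = 10^runif(1, -1, 3),
                      sigma0 = runif(1, 0.5, 3))
    expect_lt(abs(sum(fit$alpha)), 1e-8)
    expect_lt(fit$system_residual, 1e-8)
    td <- tidy(fit)
    expect_equal(td$residual, fit$alpha / fit$gamma)
    expect_equal(glance(fit)$n_support, n)
  }
})

test_that("the dual solve agrees with brute-force primal minimization", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(3:8, 1); d <- sample(1:3, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- rnorm(n)
    gamma <- 10^runif(1, 0, 2)
    sigma0 <- runif(1, 0.7, 2)
    Xtest <- matrix(rnorm(5 * d), 5, d)
    dual <- predict(fit_ls_svm(X, y, gamma, sigma0), Xtest)
    oracle <- primal_oracle_predict(primal_oracle(X, y, gamma, sigma0), Xtest)
    expect_equal(dual, oracle, tolerance = 1e-5)
  }
})

test_that("neighbour selection matches an exhaustive sort oracle", {
  set.seed(31)
  for (rep in 1:100) {
    N <- sample(5:40, 1); d <- sample(1:5, 1)
    X <- matrix(rnorm(N * d), N, d)
    xs <- rnorm(d)
    k <- sample(1:N, 1)
    sel <- knn_select(xs, X, k, standardize = FALSE)
    d_all <- sqrt(colSums((t(X) - xs)^2))
    oracle_idx <- order(d_all, seq_len(N))[seq_len(k)]
    expect_setequal(sel$indices, oracle_idx)
    expect_equal(sel$r_s, sort(d_all)[k])
    expect_equal(which(sel$lambda == 1), sort(sel$indices))
  }
})

test_that("neighbour ties at the k-th distance break by lowest index", {
  X <- matrix(c(0, 1, 1, 2), ncol = 1)  # rows 2 and 3 tie at distance 1
  sel <- knn_select(0, X, 2, standardize = FALSE)
  expect_equal(sort(sel$indices), c(1, 2))
  expect_equal(sel$r_s, 1)
  sel_all <- knn_select(0, X, 4, standardize = FALSE)
  expect_equal(sel_all$lambda, rep(1L, 4))
})

test_that("localized prediction reduces to known limits", {
  set.seed(41)
  N <- 20; d <- 3
  X <- matrix(rnorm(N * d), N, d)
  y <- rnorm(N)

  ## k = N: identical to the global (unweighted) fit
  hp_all <- hyperparams(k = N, gamma = 50, sigma0 = 1.5)
  std <- list(center = colMeans(X), scale = apply(X, 2, sd))
  Xs <- sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
  xq <- rnorm(d)
  xqs <- (xq - std$center) / std$scale
  global <- predict(fit_ls_svm(Xs, y, 50, 1.5), matrix(xqs, 1))
  expect_equal(predict_local(xq, X, y, hp_all), global, tolerance = 1e-8)

  ## k = 1: prediction equals the nearest neighbour's response
  hp1 <- hyperparams(k = 1, gamma = 50, sigma0 = 1.5)
  nn <- knn_select(xq, X, 1)$indices
  expect_equal(predict_local(xq, X, y, hp1), y[nn])

  ## constant responses are interpolated exactly through the bias
  expect_equal(predict_local(xq, X, rep(3.3, N), hyperparams(k = 5, gamma = 10)),
               3.3, tolerance = 1e-9)
})

test_that("predictions are invariant to shuffling the training pool", {
  set.seed(51)
  N <- 30; d <- 4
  X <- matrix(rnorm(N * d), N, d)
  y <- rnorm(N)
  xq <- rnorm(d)
  hp <- hyperparams(k = 7, gamma = 20, sigma0 = 2)
  base <- predict_local(xq, X, y, hp)
  for (rep in 1:5) {
    perm <- sample(N)
    expect_equal(predict_local(xq, X[perm, ], y[perm], hp), base,
                 tolerance = 1e-10)
  }
})

test_that("large gamma drives training-point predictions toward interpolation", {
  set.seed(61)
  n <- 8
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rnorm(n)
  errs <- vapply(c(1, 1e2, 1e4, 1e8), function(g) {
    fit <- fit_ls_svm(X, y, gamma = g, sigma0 = 1)
    max(abs(predict(fit, X) - y))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[length(errs)], 1e-5)
})

test_that("alternative metrics select sensible neighbourhoods", {
  set.seed(71)
  X <- matrix(rnorm(60), 20, 3)
  xs <- rnorm(3)
  cheb <- knn_select(xs, X, 5, metric = "chebyshev", standardize = FALSE)
  d_cheb <- apply(abs(sweep(X, 2, xs, "-")), 1, max)
  expect_setequal(cheb$indices, order(d_cheb, seq_len(20))[1:5])
  mah <- knn_select(xs, X, 5, metric = "mahalanobis")
  expect_length(mah$indices, 5)
})

test_that("hyperparameter tuning is deterministic and picks the grid optimum", {
  set.seed(81)
  N <- 40
  X <- matrix(runif(N * 2, -2, 2), N, 2)
  y <- sin(X[, 1]) + 0.1 * rnorm(N)

  single <- tibble::tibble(k = 10, gamma = 10, sigma0 = 1)
  hp <- tune_hyperparameters(X, y, single, folds = 4, seed = 2)
  expect_equal(hp$k, 10L)
  expect_equal(hp$gamma, 10)

  grid <- tidyr::crossing(k = c(5, 10), gamma = c(1, 100),
                          sigma0 = c(0.05, 1, 50))
  hp1 <- tune_hyperparameters(X, y, grid, folds = 4, seed = 3)
  hp2 <- tune_hyperparameters(X, y, grid, folds = 4, seed = 3)
  expect_equal(hp1[c("k", "gamma", "sigma0")], hp2[c("k", "gamma", "sigma0")])

  res <- attr(hp1, "cv_results")
  expect_equal(attr(hp1, "cv_mae"), min(res$cv_mae))
  extremes <- res$cv_mae[res$sigma0 %in% range(grid$sigma0)]
  expect_true(all(attr(hp1, "cv_mae") <= extremes))

  expect_error(tune_hyperparameters(X, y, grid[0, ], folds = 4), "empty")
  expect_error(tune_hyperparameters(X, y, single, folds = 100), "folds")
})
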