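#' Gaussian kernel
#'
#' `k(xi, xj) = exp(-||xi - xj||^2 / (2 sigma0^2))`.
#'
#' @param xi,xj Numeric vectors of equal dimension.
#' @param sigma0 Kernel bandwidth (> 0).
#' @return Similarity in (0, 1].
#' @export
gaussian_kernel <- function(xi, xj, sigma0) {
  if (length(xi) != length(xj)) abort("dimension mismatch.")
  if (sigma0 <= 0) abort("sigma0 must be > 0.")
  exp(-sum((xi - xj)^2) / (2 * sigma0^2))
}

## pairwise Gaussian kernel matrix between rows of X and Y
kernel_matrix <- function(X, Y, sigma0) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma0^2))
}

#' Hyperparameters of the localized regressor
#'
#' @param k Neighbourhood size (25 for cardiology/postsurgical profiles,
#'   15 for dialysis).
#' @param gamma Regularization constant (> 0).
#' @param sigma0 Gaussian kernel bandwidth (> 0); `NULL` defaults to
#'   `sqrt(d)` of the standardized feature space at fit time.
#' @param metric Distance for neighbour selection: `"euclidean"` (default),
#'   `"mahalanobis"` or `"chebyshev"`.
#' @param standardize Standardize features (training-pool location/scale)
#'   before distances and kernel evaluation? Default TRUE.
#' @return Object of class `vc_hyperparams`.
#' @export
hyperparams <- function(k = 25, gamma = 100, sigma0 = NULL,
                        metric = c("euclidean", "mahalanobis", "chebyshev"),
                        standardize = TRUE) {
  metric <- match.arg(metric)
  if (k < 1) abort("k must be >= 1.")
  if (gamma <= 0) abort("gamma must be > 0.")
  if (!is.null(sigma0) && sigma0 <= 0) abort("sigma0 must be > 0.")
  structure(list(k = as.integer(k), gamma = gamma, sigma0 = sigma0,
                 metric = metric, standardize = standardize),
            class = "vc_hyperparams")
}

#' Fit a least-squares SVM
#'
#' Solves the LS-SVM dual linear system
#' `[[0, 1'], [1, Omega + I/gamma]] [b; alpha] = [0; y]` with
#' `Omega_ij = k(x_i, x_j)` (Gaussian kernel). The prediction function is
#' `f(x) = sum_i alpha_i k(x, x_i) + b`; training residuals are recoverable
#' as `e_i = alpha_i / gamma`.
#'
#' @param X Numeric matrix `n x d` of training inputs (rows).
#' @param y Numeric response of length `n`.
#' @param gamma Regularization constant (> 0).
#' @param sigma0 Gaussian kernel bandwidth; `NULL` defaults to `sqrt(d)`.
#' @return Object of class `ls_svm` with elements `X, y, alpha, b, gamma,
#'   sigma0, system_residual`.
#' @export
#' @examples
#' fit <- fit_ls_svm(matrix(c(-1, 1)), c(-1, 1), gamma = 10, sigma0 = 1)
#' predict(fit, matrix(0))  # 0 by antisymmetry
fit_ls_svm <- function(X, y, gamma, sigma0 = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1) abort("need at least one training point.")
  if (length(y) != n) abort("length(y) must equal nrow(X).")
  if (gamma <= 0) abort("gamma must be > 0.")
  sigma0 <- sigma0 %||% sqrt(ncol(X))
  Omega <- kernel_matrix(X, X, sigma0)
  M <- rbind(c(0, rep(1, n)), cbind(1, Omega + diag(1 / gamma, n)))
  rhs <- c(0, y)
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    warn("dual system singular; retrying with ridge jitter 1e-10.")
    solve(M + diag(1e-10, n + 1), rhs)
  })
  structure(
    list(X = X, y = y, alpha = sol[-1], b = sol[1],
         gamma = gamma, sigma0 = sigma0,
         system_residual = max(abs(M %*% sol - rhs))),
    class = "ls_svm"
  )
}

#' @export
predict.ls_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  K <- kernel_matrix(newdata, object$X, object$sigma0)
  as.numeric(K %*% object$alpha + object$b)
}

#' @export
print.ls_svm <- function(x, ...) {
  cat(sprintf("LS-SVM: %d support points, d = %d, gamma = %g, sigma0 = %g\n",
              nrow(x$X), ncol(x$X), x$gamma, x$sigma0))
  cat(sprintf("  bias b = %.6g, sum(alpha) = %.3g, system residual = %.3g\n",
              x$b, sum(x$alpha), x$system_residual))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ls_svm <- function(x, ...) {
  tibble(support = seq_along(x$alpha), alpha = x$alpha,
         residual = x$alpha / x$gamma, y = x$y)
}

#' @exportS3Method generics::glance
glance.ls_svm <- function(x, ...) {
  tibble(n_support = nrow(x$X), b = x$b, gamma = x$gamma, sigma0 = x$sigma0,
         alpha_sum = sum(x$alpha), system_residual = x$system_residual)
}

## training-pool location/scale for distance standardization
pool_standardization <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl <= 0] <- 1
  list(center = ctr, scale = scl)
}

standardize_rows <- function(X, std) {
  sweep(sweep(as.matrix(X), 2, std$center, "-"), 2, std$scale, "/")
}

pool_distances <- function(xs, Xs, metric = "euclidean") {
  diffs <- sweep(Xs, 2, xs, "-")
  switch(metric,
    euclidean = sqrt(rowSums(diffs^2)),
    chebyshev = apply(abs(diffs), 1, max),
    mahalanobis = {
      S <- stats::cov(Xs)
      ## shrink toward the diagonal to keep the metric well conditioned
      S <- 0.9 * S + 0.1 * diag(diag(S), ncol(Xs))
      diag(S) <- diag(S) + 1e-8
      sqrt(stats::mahalanobis(Xs, center = xs, cov = S))
    }
  )
}

#' Select the k nearest training instances
#'
#' Distances are computed on standardized features (training-pool location
#' and scale). The binary similarity weight is 1 exactly for the selected
#' rows, i.e. those within the K-th smallest distance `r_s`; ties at `r_s`
#' are broken by lowest row index.
#'
#' @param x_s Query vector (d).
#' @param X Training pool matrix `N x d`.
#' @param k Neighbourhood size, `1 <= k <= N`.
#' @param metric Distance metric (see [hyperparams()]).
#' @param standardize Standardize features first? Default TRUE.
#' @return List `indices` (the K selected rows), `r_s` (K-th smallest
#'   distance), `lambda` (N-vector of binary weights).
#' @export
knn_select <- function(x_s, X, k, metric = "euclidean", standardize = TRUE) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (k > N) abort("k exceeds the pool size.")
  if (standardize) {
    std <- pool_standardization(X)
    Xs <- standardize_rows(X, std)
    xs <- as.numeric(standardize_rows(matrix(x_s, nrow = 1), std))
  } else {
    Xs <- X
    xs <- x_s
  }
  d <- pool_distances(xs, Xs, metric)
  ord <- order(d, seq_len(N))
  idx <- ord[seq_len(k)]
  lambda <- as.integer(seq_len(N) %in% idx)
  list(indices = idx, r_s = d[ord[k]], lambda = lambda)
}

#' Localized kNN-LS-SVM prediction
#'
#' For one query point: select its K nearest training instances (binary
#' similarity criterion), fit an LS-SVM on that neighbourhood and evaluate
#' it at the query. With `k = N` this reduces exactly to the global
#' (unweighted) LS-SVM.
#'
#' @param x_s Query vector (d).
#' @param X Training pool `N x d`.
#' @param y Training responses (length N).
#' @param hp A [hyperparams()] object.
#' @return Scalar prediction in the response's units.
#' @export
predict_local <- function(x_s, X, y, hp = hyperparams()) {
  X <- as.matrix(X)
  if (nrow(X) == 0) abort("empty training pool.")
  sel <- knn_select(x_s, X, hp$k, metric = hp$metric,
                    standardize = hp$standardize)
  if (hp$standardize) {
    std <- pool_standardization(X)
    Xf <- standardize_rows(X, std)
    xf <- as.numeric(standardize_rows(matrix(x_s, nrow = 1), std))
  } else {
    Xf <- X
    xf <- x_s
  }
  fit <- fit_ls_svm(Xf[sel$indices, , drop = FALSE], y[sel$indices],
                    gamma = hp$gamma, sigma0 = hp$sigma0)
  predict(fit, matrix(xf, nrow = 1))
}

#' Tune hyperparameters by cross-validated absolute error
#'
#' Exhaustive evaluation of a hyperparameter grid under random-fold
#' cross-validation; each held-out point is predicted by [predict_local()]
#' trained on the remaining folds. Ties are broken toward smaller `k`, then
#' smaller `gamma`, then smaller `sigma0`.
#'
#' @param X,y Training pool.
#' @param grid Tibble/data.frame with columns `k, gamma, sigma0` (one row
#'   per candidate).
#' @param folds Number of folds (>= 2, <= N).
#' @param seed Seed for the fold assignment.
#' @param metric,standardize Passed to [hyperparams()].
#' @return The selected [hyperparams()], with the CV mean absolute error in
#'   attribute `cv_mae` and the full grid results in attribute `cv_results`.
#' @export
tune_hyperparameters <- function(X, y, grid, folds = 5, seed = 1L,
                                 metric = "euclidean", standardize = TRUE) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (nrow(grid) == 0) abort("empty hyperparameter grid.")
  if (folds < 2) abort("folds must be >= 2.")
  if (folds > N) abort("more folds than training points.")
  set.seed(as.integer(seed))
  fold_id <- sample(rep(seq_len(folds), length.out = N))
  grid <- as_tibble(grid)
  grid$cv_mae <- vapply(seq_len(nrow(grid)), function(g) {
    hp <- hyperparams(k = grid$k[g], gamma = grid$gamma[g],
                      sigma0 = grid$sigma0[g], metric = metric,
                      standardize = standardize)
    errs <- purrr::map_dbl(seq_len(N), function(i) {
      tr <- which(fold_id != fold_id[i])
      if (length(tr) < hp$k) return(NA_real_)
      abs(predict_local(X[i, ], X[tr, , drop = FALSE], y[tr], hp) - y[i])
    })
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- grid[order(grid$cv_mae, grid$k, grid$gamma, grid$sigma0), ][1, ]
  hp <- hyperparams(k = best$k, gamma = best$gamma, sigma0 = best$sigma0,
                    metric = metric, standardize = standardize)
  attr(hp, "cv_mae") <- best$cv_mae
  attr(hp, "cv_results") <- grid
  hp
}

#' Default hyperparameter grid
#'
#' `gamma` over decades 1..1e4, `sigma0` in `{0.5, 1, 2, 5, 10} * sqrt(d)`,
#' `k` in `{5, 15, 25, 35}`.
#'
#' @param d Feature dimension.
#' @return Tibble with columns `k, gamma, sigma0`.
#' @export
default_grid <- function(d) {
  tidyr::crossing(k = c(5, 15, 25, 35), gamma = 10^(0:4),
                  sigma0 = c(0.5, 1, 2, 5, 10) * sqrt(d))
}
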