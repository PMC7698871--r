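# Independent oracle for the LS-SVM: direct numerical minimization of the
# primal least-squares objective in its representer form,
#   J(c, b) = 1/2 c' Omega c + gamma/2 sum_i (y_i - (Omega c)_i - b)^2,
# with analytic gradients, never touching the package's dual solve.

primal_oracle <- function(X, y, gamma, sigma0) {
  X <- as.matrix(X)
  n <- nrow(X)
  Omega <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    exp(-sum((X[i, ] - X[j, ])^2) / (2 * sigma0^2))
  }))
  obj <- function(par) {
    cc <- par[1:n]; b <- par[n + 1]
    e <- y - as.numeric(Omega %*% cc) - b
    0.5 * sum(cc * (Omega %*% cc)) + gamma / 2 * sum(e^2)
  }
  grad <- function(par) {
    cc <- par[1:n]; b <- par[n + 1]
    e <- y - as.numeric(Omega %*% cc) - b
    c(as.numeric(Omega %*% cc) - gamma * as.numeric(Omega %*% e),
      -gamma * sum(e))
  }
  fit <- stats::optim(rep(0, n + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  par <- fit$par
  ## the objective is quadratic, so polish with exact Newton steps from the
  ## analytic Hessian (still the primal route, independent of the dual solve)
  ## near-singular Omega leaves flat directions in the representer
  ## coordinates (they move neither w nor predictions); step only along
  ## well-determined eigendirections of the Hessian
  H <- rbind(cbind(Omega + gamma * Omega %*% Omega, gamma * Omega %*% rep(1, n)),
             c(gamma * rep(1, n) %*% Omega, gamma * n))
  eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
  keep <- eg$values > 1e-13 * max(eg$values)
  Hinv <- eg$vectors[, keep, drop = FALSE] %*%
    (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
  for (it in 1:5) {
    par <- par - as.numeric(Hinv %*% grad(par))
  }
  if (obj(par) > obj(fit$par) * (1 + 1e-8) + 1e-10) par <- fit$par
  list(c = par[1:n], b = par[n + 1], X = X, sigma0 = sigma0)
}

primal_oracle_predict <- function(oracle, newX) {
  newX <- as.matrix(newX)
  k <- apply(newX, 1, function(x) {
    apply(oracle$X, 1, function(xi) {
      exp(-sum((x - xi)^2) / (2 * oracle$sigma0^2))
    })
  })
  as.numeric(crossprod(k, oracle$c) + oracle$b)
}
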