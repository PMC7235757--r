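# Independent GLM oracles shared across test files.
# independent oracle: direct BFGS maximisation of the binomial
# log-likelihood (never IRLS)
direct_mle <- function(x, y) {
  X <- cbind(1, x)
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(beta) {
    mu <- stats::plogis(drop(X %*% beta))
    -drop(crossprod(X, y - mu))
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 2000))
  opt$par
}

# random non-separated small dataset
small_dataset <- function(n, k) {
  repeat {
    x <- matrix(stats::rnorm(n * k), n, k)
    eta <- drop(x %*% stats::runif(k, -1, 1)) - 0.2
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    if (sum(y) < 2 || sum(y) > n - 2) next
    fit <- suppressWarnings(fit_logistic(x, y))
    if (fit$converged && max(abs(fit$coefficients)) < 8) return(list(x = x, y = y))
  }
}
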