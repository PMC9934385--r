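## Shared fixtures and the independent convex-solver oracle.
## glmnet (an unrelated Fortran implementation of the same convex program,
## on the per-observation penalty scale) serves as the reference: a
## weighted-L1 problem is passed to it through the standard column
## rescaling, and objectives are compared on this package's scale.

suppressMessages(library(glmnet))

rand_instance <- function(n, p, seed, snr_beta = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- if (is.null(snr_beta)) rnorm(p) * rbinom(p, 1, 0.6) else snr_beta
  y <- drop(X %*% beta) + rnorm(n)
  standardize_xy(X, y)
}

## objective RSS + lambda * sum(w^q |beta|) on standardized data
objective_of <- function(d, beta, lambda, w = rep(1, d$p), q = 1) {
  sum((d$y - d$X %*% beta)^2) + lambda * sum(w^q * abs(beta))
}

## reference solution of the weighted-L1 problem via glmnet
oracle_beta <- function(d, lambda, w = rep(1, d$p), q = 1) {
  wq <- w^q
  g <- glmnet(sweep(d$X, 2, wq, "/"), d$y, lambda = lambda / (2 * d$n),
              intercept = FALSE, standardize = FALSE,
              thresh = 1e-14, maxit = 1e7)
  as.numeric(coef(g))[-1] / wq
}
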