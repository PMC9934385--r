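test_that("standardization centers, scales to second moment one, and inverts", {
  # closed form: column (1,2,3) becomes (-a, 0, a) with a = sqrt(3/2)
  d <- standardize_xy(cbind(x1 = c(1, 2, 3), x2 = c(0, 1, 0)), c(1, 0, 2))
  a <- sqrt(3 / 2)
  expect_equal(d$X[, "x1"], c(-a, 0, a), tolerance = 1e-12)

  set.seed(7)
  X <- matrix(rnorm(100), 20, 5)
  y <- rnorm(20)
  d <- standardize_xy(X, y)
  expect_lt(max(abs(colMeans(d$X))), 1e-10)
  expect_lt(max(abs(colMeans(d$X^2) - 1)), 1e-10)
  expect_lt(abs(mean(d$y)), 1e-10)

  # idempotence
  d2 <- standardize_xy(d$X, d$y)
  expect_equal(d2$X, d$X, tolerance = 1e-10)
  expect_equal(d2$y, d$y, tolerance = 1e-10)

  # invertibility through the scaling metadata
  Xr <- sweep(sweep(d$X, 2, d$scaling$scale, "*"), 2, d$scaling$center, "+")
  expect_equal(Xr, X, tolerance = 1e-12, ignore_attr = TRUE)

  X[, 3] <- 5
  colnames(X) <- paste0("g", 1:5)
  expect_error(standardize_xy(X, y), "g3")
})

test_that("lasso limits: OLS at lambda zero, null fit above the threshold", {
  d <- rand_instance(25, 6, seed = 11)
  ols <- drop(solve(crossprod(d$X), crossprod(d$X, d$y)))
  f0 <- lasso_cd(d, 0, tol = 1e-12)
  expect_equal(f0$beta, ols, tolerance = 1e-8)

  lam_null <- 2 * max(abs(crossprod(d$X, d$y)))
  fz <- lasso_cd(d, lam_null * 1.0001)
  expect_identical(fz$beta, rep(0, d$p))
  expect_identical(fz$active_set, integer(0))

  # reported objective is consistent with an independent recomputation
  f <- lasso_cd(d, 15, tol = 1e-10)
  expect_equal(f$objective,
               sum((d$y - d$X %*% f$beta)^2) + 15 * sum(abs(f$beta)),
               tolerance = 1e-10)
})

test_that("weighted lasso reduces to the lasso for constant weights", {
  d <- rand_instance(20, 7, seed = 3)
  f1 <- weighted_lasso(d, 12, rep(1, 7), tol = 1e-12)
  f2 <- lasso_cd(d, 12, tol = 1e-12)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)

  f3 <- weighted_lasso(d, 12, rep(0.5, 7), tol = 1e-12)
  f4 <- lasso_cd(d, 6, tol = 1e-12)
  expect_equal(f3$beta, f4$beta, tolerance = 1e-8)

  expect_error(weighted_lasso(d, 1, c(rep(1, 6), 0)), "positive")
})

test_that("lqsso at tau one-half is the lasso at half the penalty", {
  for (s in 1:5) {
    d <- rand_instance(22, 6, seed = 100 + s)
    f <- lqsso(d, 10, tau = 0.5, tol = 1e-12)
    g <- lasso_cd(d, 5, tol = 1e-12)
    expect_equal(f$beta, g$beta, tolerance = 1e-8)
  }
  # unpenalized limit
  d <- rand_instance(25, 5, seed = 9)
  ols <- drop(solve(crossprod(d$X), crossprod(d$X, d$y)))
  expect_equal(lqsso(d, 0, tau = 0.3, tol = 1e-12)$beta, ols,
               tolerance = 1e-8)
})

test_that("negating a column negates only its coefficient", {
  # exact symmetry of the weighted problem: flip the column, keep its
  # weight.  (For lqsso at tau != 0.5 flipping the initial estimate also
  # swaps that coordinate's weight tau <-> 1 - tau, so the sign-flipped
  # problem is a different one; tau = 0.5 is sign-free.)
  d <- rand_instance(24, 6, seed = 21)
  w <- c(0.8, 0.3, 0.6, 0.2, 0.7, 0.4)
  f <- weighted_lasso(d, 8, w, tol = 1e-12)
  d2 <- d
  d2$X[, 3] <- -d2$X[, 3]
  f2 <- weighted_lasso(d2, 8, w, tol = 1e-12)
  expect_equal(f2$beta[3], -f$beta[3], tolerance = 1e-8)
  expect_equal(f2$beta[-3], f$beta[-3], tolerance = 1e-8)

  f3 <- lqsso(d, 8, tau = 0.5, init = ols_init(d), tol = 1e-12)
  init2 <- ols_init(d)$beta
  init2[3] <- -init2[3]
  f4 <- lqsso(d2, 8, tau = 0.5, init = init2, tol = 1e-12)
  expect_equal(f4$beta[3], -f3$beta[3], tolerance = 1e-8)
  expect_equal(f4$beta[-3], f3$beta[-3], tolerance = 1e-8)
})

test_that("adaptive lasso reduces to the lasso for unit weights", {
  d <- rand_instance(20, 5, seed = 31)
  f <- adaptive_lasso(d, 9, gamma = 1, init = c(1, -1, 1, -1, 1),
                      tol = 1e-12)
  g <- lasso_cd(d, 9, tol = 1e-12)
  expect_equal(f$beta, g$beta, tolerance = 1e-8)

  # gamma -> 0 continuity toward the lasso
  init <- ols_init(d)
  fg <- adaptive_lasso(d, 9, gamma = 1e-8, init = init, tol = 1e-12)
  expect_equal(fg$beta, g$beta, tolerance = 1e-5)
})

test_that("initial estimators match closed-form linear algebra", {
  d <- rand_instance(30, 6, seed = 41)
  expect_equal(ols_init(d)$beta,
               drop(qr.solve(crossprod(d$X), crossprod(d$X, d$y))),
               tolerance = 1e-10)

  # p > n: OLS refuses and points to ridge
  dw <- rand_instance(15, 30, seed = 43)
  expect_error(ols_init(dw), "ridge_init")
  r <- ridge_init(dw, ridge_lambda = 2.5)
  direct <- solve(crossprod(dw$X) + diag(2.5, 30), crossprod(dw$X, dw$y))
  expect_equal(r$beta, drop(direct), tolerance = 1e-8)

  # shrinkage is monotone in the ridge penalty
  norms <- vapply(c(0.1, 1, 10, 100, 1000),
                  function(l) sqrt(sum(ridge_init(dw, l)$beta^2)), 0)
  expect_true(all(diff(norms) < 0))

  # automatic selection returns a usable estimate
  auto <- ridge_init(dw)
  expect_true(auto$ridge_lambda > 0)
  expect_true(all(is.finite(auto$beta)))
})

test_that("KKT verification certifies solutions and localizes violations", {
  d <- rand_instance(20, 8, seed = 51)
  f <- lasso_cd(d, 18, tol = 1e-12)
  k <- kkt_check(d, f, tol = 1e-6)
  expect_true(k$ok)

  # null fit above the threshold passes
  lam_null <- 2 * max(abs(crossprod(d$X, d$y)))
  kz <- kkt_check(d, lasso_cd(d, lam_null * 1.1), tol = 1e-6)
  expect_true(kz$ok)

  # perturbing one active coordinate fails exactly there
  j <- f$active_set[1]
  fbad <- f
  fbad$beta[j] <- fbad$beta[j] + 0.1
  kb <- kkt_check(d, fbad, tol = 1e-6)
  expect_false(kb$ok)
  expect_equal(which.max(kb$table$violation), j)
})

test_that("the solution path shrinks to zero and grows to OLS", {
  d <- rand_instance(26, 5, seed = 61)
  ols <- drop(solve(crossprod(d$X), crossprod(d$X, d$y)))
  lams <- c(1e-4, 1, 5, 20, 100, 1e4)
  B <- sapply(lams, function(l) lasso_cd(d, l, tol = 1e-11)$beta)
  expect_equal(B[, 1], ols, tolerance = 1e-4)
  expect_identical(B[, ncol(B)], rep(0, 5))
  # L1 norm is non-increasing in lambda
  expect_true(all(diff(colSums(abs(B))) < 1e-10))
  # local continuity in lambda
  b1 <- lasso_cd(d, 5, tol = 1e-11)$beta
  b2 <- lasso_cd(d, 5.001, tol = 1e-11)$beta
  expect_lt(max(abs(b1 - b2)), 1e-3)
})

test_that("rescaled coefficients are asymptotically normal on the support", {
  # when the penalty grows slower than sqrt(n) the penalty term vanishes
  # at the sqrt(n) scale, so sqrt(n)(beta_hat_A - beta*_A) is
  # asymptotically normal with the full-design information block
  # sigma^2 (C^-1)_AA.  (The oracle covariance sigma^2 C11^{-1} would
  # additionally require exact support recovery, which bounded
  # sign-based weights do not deliver at this rate; see the vignette.)
  beta_star <- c(3, 1.5, 0, 0, 2, 0, 0, 0)
  A <- which(beta_star != 0)
  Sigma <- ar1_cov(8, 0.5)
  target <- solve(Sigma)[A, A]        # sigma = 1
  n <- 800
  lam <- n^0.4
  set.seed(77)
  reps <- 150
  dev <- matrix(0, reps, length(A))
  for (r in 1:reps) {
    X <- gen_design(n, 8, 0.5)
    y <- drop(X %*% beta_star) + rnorm(n)
    d <- standardize_xy(X, y)
    f <- lqsso(d, lam, tau = 0.7)
    dev[r, ] <- sqrt(n) * (f$beta_original[A] - beta_star[A])
  }
  S <- cov(dev)
  expect_lt(norm(S - target, "F") / norm(target, "F"), 0.3)
})
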