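test_that("the AR design generator has the prescribed correlation structure", {
  X0 <- gen_design(2000, 4, rho = 0, seed = 2)
  expect_lt(max(abs(cor(X0)[upper.tri(diag(4))])), 0.08)

  X <- gen_design(50000, 3, rho = 0.5, seed = 3)
  expect_lt(abs(cor(X[, 1], X[, 3]) - 0.25), 0.01)
  expect_lt(abs(cor(X[, 1], X[, 2]) - 0.5), 0.01)
  expect_lt(max(abs(colMeans(X))), 0.02)

  expect_identical(gen_design(20, 5, 0.5, seed = 9),
                   gen_design(20, 5, 0.5, seed = 9))
  expect_error(gen_design(10, 3, rho = 1), "rho")
})

test_that("coefficient schemes have the stated supports", {
  b1 <- gen_beta(1, seed = 1)
  expect_length(b1$beta, 8)
  expect_identical(b1$beta[5:8], rep(0, 4))
  expect_identical(b1$support, 1:4)

  b2 <- gen_beta(2, seed = 1)
  expect_true(all(b2$beta != 0))

  b5 <- gen_beta(5, seed = 2)
  expect_length(b5$beta, 1000)
  expect_length(b5$support, 30)
  expect_identical(sum(b5$beta == 0), 970L)

  expect_identical(gen_beta(4, seed = 7), gen_beta(4, seed = 7))
  br <- gen_beta(5, support_positions = "random", seed = 3)
  expect_length(br$support, 30)
  expect_false(identical(br$support, 1:30))

  expect_equal(gen_beta(1, beta_mode = "fixed")$beta,
               c(3, 1.5, 0, 0, 2, 0, 0, 0))
  expect_equal(gen_beta(2, beta_mode = "fixed")$beta, rep(0.85, 8))
  expect_error(gen_beta(3, beta_mode = "fixed"), "fixed")
})

test_that("signal-to-noise ratio has its closed form", {
  b <- c(3, 1.5, 0, 0, 2, 0, 0, 0)
  S <- ar1_cov(8, 0.5)
  expect_equal(snr(b, S, 1), 21.25, tolerance = 1e-12)
  expect_equal(snr(b, S, 3), 21.25 / 9, tolerance = 1e-12)
  expect_identical(snr(rep(0, 8), S, 1), 0)
  expect_error(snr(b, S, 0), "positive")
})

test_that("relative prediction error estimators agree and hit their limits", {
  b <- c(1.4, 0, -2, 0.5)
  S <- ar1_cov(4, 0.5)
  expect_identical(rpe_analytic(b, b, S, 2), 0)
  expect_equal(rpe_analytic(rep(0, 4), b, S, 2), snr(b, S, 2),
               tolerance = 1e-12)

  bh <- b + c(0.3, -0.2, 0.1, 0)
  Xt <- gen_design(2e5, 4, 0.5, seed = 5)
  emp <- rpe_empirical(drop(Xt %*% bh), drop(Xt %*% b), 2)
  expect_equal(emp, rpe_analytic(bh, b, S, 2), tolerance = 0.02)
  expect_error(rpe_empirical(1:3, 1:3, -1), "positive")
})

test_that("bias metric and the identity-covariance identity hold", {
  expect_identical(bias_metric(c(1, 2), c(1, 2)), 0)
  expect_equal(bias_metric(rep(0, 4), rep(1, 4)), 4)
  expect_equal(bias_metric(rep(0, 4), rep(1, 4), "l2"), 2)
  set.seed(6)
  bh <- rnorm(5); bt <- rnorm(5)
  expect_equal(bias_metric(bh, bt, "l2"), sqrt(bias_metric(bh, bt)),
               tolerance = 1e-12)
  # with rho = 0 and sigma = 1 the analytic RPE is the squared-error bias
  expect_equal(rpe_analytic(bh, bt, diag(5), 1), bias_metric(bh, bt),
               tolerance = 1e-12)
})

test_that("selection counts partition the estimate's support", {
  expect_equal(selection_counts(rep(0, 10), 1:3), c(C = 0, I = 0))
  b <- numeric(1000); b[c(1:25, 995:999)] <- 1
  expect_equal(selection_counts(b, 1:30), c(C = 25, I = 5))
  b5 <- gen_beta(5, seed = 1)
  expect_equal(selection_counts(b5$beta, b5$support), c(C = 30, I = 0))
  # float dust below the tolerance does not count as selected
  expect_equal(selection_counts(c(1, 1e-12, 0), 1:2), c(C = 1, I = 0))
})

test_that("bootstrap median standard error matches exact enumeration", {
  expect_identical(bootstrap_median_se(rep(3, 10), seed = 1), 0)
  expect_identical(bootstrap_median_se(c(0, 1), 500, seed = 2),
                   bootstrap_median_se(c(0, 1), 500, seed = 2))
  # for values (0, 1) the four equiprobable resamples have medians
  # (0, 1/2, 1/2, 1): sd = sqrt(1/8)
  est <- bootstrap_median_se(c(0, 1), n_boot = 4000, seed = 3)
  expect_lt(abs(est - sqrt(0.125)), 0.02)
  expect_error(bootstrap_median_se(numeric(0)), "two")
})

test_that("experiments are deterministic and beat the null fit", {
  g <- tuning_grid(lambda = c(0.1, 0.5, 1, 2), tau = c(0.3, 0.5, 0.7),
                   gamma = c(0.5, 1, 2))
  sc <- scenario_spec(1, 40, 1, n_reps = 2, seed = 31, n_test = 200)
  r1 <- run_experiment(sc, methods = "lqsso", grid = g, n_boot = 50)
  r2 <- run_experiment(sc, methods = "lqsso", grid = g, n_boot = 50)
  expect_identical(r1, r2)

  # tuned lasso predicts better than the null fit (whose RPE is the SNR)
  sc2 <- scenario_spec(1, 40, 1, n_reps = 10, seed = 32, n_test = 400,
                       beta_mode = "fixed")
  rl <- run_experiment(sc2, methods = "lasso", grid = g, n_boot = 50)
  expect_lt(rl$rpe_mean, snr(gen_beta(1, beta_mode = "fixed")$beta,
                             ar1_cov(8, 0.5), 1))

  # near-noiseless recovery: full support found, tiny prediction error
  # (grid must reach down to effectively unpenalized fits for the
  # relative error, scaled by 1/sigma^2, to vanish)
  gtiny <- tuning_grid(lambda = c(1e-8, 1e-4, 0.1, 1))
  sc3 <- scenario_spec(1, 80, 0.01, n_reps = 3, seed = 33, n_test = 200,
                       beta_mode = "fixed")
  rn <- run_experiment(sc3, methods = "lasso", grid = gtiny, n_boot = 50)
  expect_equal(rn$c_median, 3)   # support of the fixed vector
  expect_lt(rn$rpe_mean, 0.2)

  # replicate table is internally consistent
  reps <- attr(rl, "replicates")
  expect_true(all(reps$C <= 3 & reps$I <= 5 & reps$rpe >= 0))
})
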