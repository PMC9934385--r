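#' AR(1) predictor covariance
#'
#' The benchmark scenarios correlate predictors through
#' \eqn{\mathrm{cor}(j, j') = \rho^{|j - j'|}}.
#'
#' @param p dimension.
#' @param rho base correlation in `[0, 1)`.
#' @return a `p x p` correlation matrix.
#' @export
ar1_cov <- function(p, rho = 0.5) {
  stopifnot(p >= 1, rho >= 0, rho < 1)
  rho^abs(outer(seq_len(p), seq_len(p), "-"))
}

#' Generate a correlated Gaussian design
#'
#' Rows are i.i.d. mean-zero multivariate normal with covariance
#' \eqn{\Sigma_{jj'} = \rho^{|j-j'|}}, generated by the AR(1) recursion
#' \eqn{x_j = \rho x_{j-1} + \sqrt{1-\rho^2}\, z_j} so the cost is
#' \eqn{O(np)} even at \eqn{p = 1000}.
#'
#' @param n,p dimensions.
#' @param rho base correlation in `[0, 1)`.
#' @param seed optional integer seed (local to this call).
#' @return an `n x p` numeric matrix.
#' @export
gen_design <- function(n, p, rho = 0.5, seed = NULL) {
  stopifnot(n >= 2, p >= 1)
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)")
  with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    if (p > 1 && rho > 0) {
      a <- sqrt(1 - rho^2)
      for (j in 2:p) X[, j] <- rho * X[, j - 1] + a * X[, j]
    }
    X
  })
}

#' True coefficient vectors for the benchmark models
#'
#' Five data-generating schemes: (1) `p = 8` with the first four
#' coefficients nonzero and four structural zeros; (2) `p = 8`, all
#' nonzero; (3) `p = 100`, dense; (4) `p = 100` with 30 nonzero; (5)
#' `p = 1000` with 30 nonzero drawn from N(0.5, 0.5^2) and 970 zeros.
#' With `beta_mode = "random"` (the default) nonzero coefficients are drawn
#' afresh, standard normal except model 5; `beta_mode = "fixed"` uses the
#' classical fixed vectors `(3, 1.5, 0, 0, 2, 0, 0, 0)` (model 1) and
#' `rep(0.85, 8)` (model 2), which reproduce the benchmark's stated
#' signal-to-noise ratios.
#'
#' @param model_id integer 1-5.
#' @param beta_mode `"random"` or `"fixed"` (fixed only for models 1-2).
#' @param support_positions `"leading"` places nonzero coefficients at the
#'   first indices (default); `"random"` scatters them.
#' @param seed optional integer seed (local to this call).
#' @return a list with `beta` (length `p`), `support` (indices of nonzero
#'   truth) and `p`.
#' @export
gen_beta <- function(model_id, beta_mode = c("random", "fixed"),
                     support_positions = c("leading", "random"),
                     seed = NULL) {
  beta_mode <- match.arg(beta_mode)
  support_positions <- match.arg(support_positions)
  stopifnot(model_id %in% 1:5)
  p <- c(8L, 8L, 100L, 100L, 1000L)[model_id]
  n_nonzero <- c(4L, 8L, 100L, 30L, 30L)[model_id]
  if (beta_mode == "fixed") {
    if (model_id == 1L) beta <- c(3, 1.5, 0, 0, 2, 0, 0, 0)
    else if (model_id == 2L) beta <- rep(0.85, 8)
    else stop("no fixed coefficient variant for model ", model_id)
    return(list(beta = beta, support = which(beta != 0), p = p))
  }
  with_seed(seed, {
    vals <- if (model_id == 5L) rnorm(n_nonzero, mean = 0.5, sd = 0.5)
            else rnorm(n_nonzero)
    idx <- if (support_positions == "leading" || n_nonzero == p)
      seq_len(n_nonzero) else sort(sample.int(p, n_nonzero))
    beta <- numeric(p)
    beta[idx] <- vals
    list(beta = beta, support = which(beta != 0), p = p)
  })
}

#' Signal-to-noise ratio
#'
#' \eqn{\mathrm{SNR} = \beta^{*\top} \Sigma \beta^* / \sigma^2} for a
#' Gaussian design with covariance \eqn{\Sigma}.
#'
#' @param beta_true true coefficient vector.
#' @param Sigma predictor covariance matrix.
#' @param sigma error standard deviation (> 0).
#' @return a single nonnegative number.
#' @examples
#' snr(c(3, 1.5, 0, 0, 2, 0, 0, 0), ar1_cov(8, 0.5), 1)  # 21.25
#' @export
snr <- function(beta_true, Sigma, sigma) {
  if (sigma <= 0) stop("'sigma' must be positive")
  stopifnot(length(beta_true) == nrow(Sigma), nrow(Sigma) == ncol(Sigma))
  drop(crossprod(beta_true, Sigma %*% beta_true)) / sigma^2
}

#' Relative prediction error, analytic form
#'
#' \eqn{(\hat\beta - \beta^*)^\top \Sigma (\hat\beta - \beta^*)/\sigma^2},
#' the population mean of \eqn{(\hat y - x^\top\beta^*)^2/\sigma^2} over a
#' design with covariance \eqn{\Sigma}.  At \eqn{\hat\beta = 0} this equals
#' the signal-to-noise ratio.
#'
#' @param beta_hat estimated coefficients (original scale).
#' @param beta_true true coefficients.
#' @param Sigma predictor covariance.
#' @param sigma error standard deviation.
#' @return a single nonnegative number.
#' @export
rpe_analytic <- function(beta_hat, beta_true, Sigma, sigma) {
  if (sigma <= 0) stop("'sigma' must be positive")
  d <- beta_hat - beta_true
  stopifnot(length(d) == nrow(Sigma))
  drop(crossprod(d, Sigma %*% d)) / sigma^2
}

#' Relative prediction error, empirical form
#'
#' \eqn{\mathrm{mean}\{(\hat y_i - x_i^\top \beta^*)^2\}/\sigma^2} over a
#' test design; the benchmark protocol uses 1000 held-out samples.
#'
#' @param yhat predictions on the test design.
#' @param mu_test true test-set means \eqn{X_{test}\beta^*}.
#' @param sigma error standard deviation.
#' @return a single nonnegative number.
#' @export
rpe_empirical <- function(yhat, mu_test, sigma) {
  if (sigma <= 0) stop("'sigma' must be positive")
  stopifnot(length(yhat) == length(mu_test))
  mean((yhat - mu_test)^2) / sigma^2
}

#' Estimation bias metric
#'
#' Sum of squared differences between estimated and true coefficients
#' (`form = "ss"`, the default) or its square root (`form = "l2"`).
#'
#' @param beta_hat,beta_true coefficient vectors of equal length.
#' @param form `"ss"` or `"l2"`.
#' @return a single nonnegative number.
#' @export
bias_metric <- function(beta_hat, beta_true, form = c("ss", "l2")) {
  form <- match.arg(form)
  stopifnot(length(beta_hat) == length(beta_true))
  ss <- sum((beta_hat - beta_true)^2)
  if (form == "ss") ss else sqrt(ss)
}

#' Correct and incorrect selection counts
#'
#' `C` is the number of truly nonzero coefficients with nonzero estimate;
#' `I` is the number of truly zero coefficients incorrectly selected.
#'
#' @param beta_hat estimated coefficients.
#' @param support_true indices of the truly nonzero coefficients.
#' @param zero_tol magnitudes at or below this count as zero (guards float
#'   dust; coordinate descent produces exact zeros).
#' @return named numeric vector `c(C = , I = )`.
#' @export
selection_counts <- function(beta_hat, support_true, zero_tol = 1e-10) {
  sel <- which(abs(beta_hat) > zero_tol)
  c(C = sum(sel %in% support_true), I = sum(!(sel %in% support_true)))
}

#' Bootstrap standard error of the median
#'
#' Draws `n_boot` resamples with replacement from the per-replicate metric
#' values, takes each resample's median, and returns the standard deviation
#' of those medians (the Monte Carlo sd used for the benchmark tables).
#'
#' @param values numeric vector of per-replicate metrics (length >= 2).
#' @param n_boot number of bootstrap resamples; default 500.
#' @param seed optional integer seed (local to this call).
#' @return a single nonnegative number.
#' @export
bootstrap_median_se <- function(values, n_boot = 500L, seed = NULL) {
  if (length(values) < 2L) stop("need at least two values")
  with_seed(seed, {
    meds <- vapply(seq_len(n_boot), function(b)
      median(sample(values, replace = TRUE)), numeric(1))
    sd(meds)
  })
}

#' Benchmark scenario specification
#'
#' One cell of the Monte Carlo study: a data-generating model, training
#' size, noise level and replication settings.
#'
#' @param model_id integer 1-5 (fixes `p` at 8, 8, 100, 100, 1000).
#' @param n_train training-set size (40 or 80 in the benchmark).
#' @param sigma error standard deviation (1, 3 or 6 in the benchmark).
#' @param n_test test-set size; default 1000.
#' @param rho AR correlation base; default 0.5.
#' @param n_reps number of Monte Carlo replicates.
#' @param seed integer master seed; all randomness (designs, coefficients,
#'   noise, folds, bootstrap) derives from it through named substreams.
#' @param beta_mode `"random"` (new truth each replicate) or `"fixed"`.
#' @param support_positions `"leading"` or `"random"`.
#' @return an object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(model_id, n_train, sigma, n_test = 1000L,
                          rho = 0.5, n_reps = 100L, seed = 1L,
                          beta_mode = c("random", "fixed"),
                          support_positions = c("leading", "random")) {
  beta_mode <- match.arg(beta_mode)
  support_positions <- match.arg(support_positions)
  stopifnot(model_id %in% 1:5, n_train >= 4, sigma > 0, n_test >= 1,
            rho >= 0, rho < 1, n_reps >= 1)
  p <- c(8L, 8L, 100L, 100L, 1000L)[model_id]
  structure(list(model_id = as.integer(model_id), n_train = as.integer(n_train),
                 n_test = as.integer(n_test), p = p, sigma = sigma,
                 rho = rho, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), beta_mode = beta_mode,
                 support_positions = support_positions),
            class = "scenario_spec")
}

#' Run one benchmark scenario
#'
#' For each replicate: draw the truth (or reuse the fixed vector), a
#' training design with AR-correlated Gaussian rows, Gaussian noise, and a
#' fresh test design; standardize; tune each method by K-fold
#' cross-validation over the grids (initial estimates recomputed per fold);
#' refit on the full training set at the selected parameters; and record
#' the empirical relative prediction error over the test design, the
#' squared-error bias, and the correct/incorrect selection counts.
#' Aggregates means, medians (for the counts) and bootstrap-median standard
#' errors.  Initial estimates are OLS when `p < n_train` and ridge
#' otherwise.
#'
#' @param scenario a [scenario_spec()].
#' @param methods subset of `c("lasso", "alasso", "lqsso")`.
#' @param grid a [tuning_grid()].
#' @param q weight exponent for lqsso.
#' @param n_boot bootstrap resamples for the standard errors.
#' @param verbose print per-replicate progress.
#' @return a data frame with one row per method and columns `model_id`,
#'   `n_train`, `sigma`, `method`, `rpe_mean`, `rpe_se`, `bias_mean`,
#'   `bias_se`, `c_median`, `i_median`, `c_se`, `i_se`, `n_reps_used`.
#'   Per-replicate metrics are attached as `attr(, "replicates")` and the
#'   number of failed replicates as `attr(, "failures")`.
#' @export
run_experiment <- function(scenario, methods = c("lasso", "alasso", "lqsso"),
                           grid = tuning_grid(), q = 1, n_boot = 500L,
                           verbose = FALSE) {
  stopifnot(inherits(scenario, "scenario_spec"))
  methods <- match.arg(methods, c("lasso", "alasso", "lqsso"),
                       several.ok = TRUE)
  sc <- scenario
  reps <- vector("list", sc$n_reps)
  failures <- 0L
  for (r in seq_len(sc$n_reps)) {
    row <- tryCatch(
      run_replicate(sc, r, methods, grid, q),
      error = function(e) {
        warning("replicate ", r, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(row)) failures <- failures + 1L else reps[[r]] <- row
    if (verbose) message("replicate ", r, "/", sc$n_reps, " done")
  }
  repdf <- do.call(rbind, reps)
  if (is.null(repdf)) stop("all replicates failed")
  boot_se <- function(v, seed) {
    if (length(v) < 2L) NA_real_ else bootstrap_median_se(v, n_boot, seed)
  }
  out <- do.call(rbind, lapply(seq_along(methods), function(m) {
    d <- repdf[repdf$method == methods[m], ]
    bseed <- substream_seed(sc$seed, 0L, 900L + m)
    data.frame(model_id = sc$model_id, n_train = sc$n_train,
               sigma = sc$sigma, method = methods[m],
               rpe_mean = mean(d$rpe),
               rpe_se = boot_se(d$rpe, bseed),
               bias_mean = mean(d$bias_ss),
               bias_se = boot_se(d$bias_ss, bseed + 1L),
               c_median = median(d$C), i_median = median(d$I),
               c_se = boot_se(d$C, bseed + 2L),
               i_se = boot_se(d$I, bseed + 3L),
               n_reps_used = nrow(d))
  }))
  attr(out, "replicates") <- repdf
  attr(out, "failures") <- failures
  out
}

run_replicate <- function(sc, r, methods, grid, q) {
  truth <- gen_beta(sc$model_id, beta_mode = sc$beta_mode,
                    support_positions = sc$support_positions,
                    seed = substream_seed(sc$seed, r, 1L))
  Xtr <- gen_design(sc$n_train, sc$p, sc$rho,
                    seed = substream_seed(sc$seed, r, 2L))
  noise <- with_seed(substream_seed(sc$seed, r, 3L),
                     rnorm(sc$n_train, sd = sc$sigma))
  ytr <- drop(Xtr %*% truth$beta) + noise
  Xte <- gen_design(sc$n_test, sc$p, sc$rho,
                    seed = substream_seed(sc$seed, r, 4L))
  mu_test <- drop(Xte %*% truth$beta)
  data <- standardize_xy(Xtr, ytr)
  do.call(rbind, lapply(seq_along(methods), function(m) {
    method <- methods[m]
    cv <- cv_tune(data, method, grid, q = q,
                  seed = substream_seed(sc$seed, r, 10L + m))
    ## final refit at the selected cell; sweep cap bounds the rare
    ## degenerate selections (endpoint tau with p >= n) whose fits are
    ## flagged unconverged rather than run to the single-fit default
    mi <- 2e4L
    fit <- switch(method,
                  lasso = lasso_cd(data, cv$best$lambda_objective,
                                   max_iter = mi),
                  alasso = adaptive_lasso(data, cv$best$lambda_objective,
                                          gamma = cv$best$gamma,
                                          max_iter = mi),
                  lqsso = lqsso(data, cv$best$lambda_objective,
                                tau = cv$best$tau, q = q, max_iter = mi))
    cnt <- selection_counts(fit$beta, truth$support)
    data.frame(method = method, rep = r,
               rpe = rpe_empirical(predict(fit, Xte), mu_test, sc$sigma),
               bias_ss = bias_metric(fit$beta_original, truth$beta, "ss"),
               bias_l2 = bias_metric(fit$beta_original, truth$beta, "l2"),
               C = cnt[["C"]], I = cnt[["I"]],
               lambda = cv$best$lambda,
               tau_or_gamma = if (method == "lasso") NA_real_ else
                 if (method == "alasso") cv$best$gamma else cv$best$tau)
  }))
}
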