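# Squared exponential kernel, marginal likelihood, bounded MLE and BLUP.

test_that("rbf kernel matches its closed form and basic geometry", {
  p <- kernel_params(sigma2 = 1, b = 1)
  # zero distance gives sigma2 on the diagonal
  A <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  K <- rbf_kernel(A, A, p)
  expect_equal(diag(K), c(1, 1))
  # squared distance 2 at unit parameters gives exp(-1)
  expect_equal(K[1, 2], exp(-1), tolerance = 1e-12)
  # symmetry is exact
  expect_identical(K, t(K))
  # monotone decay in distance, entries in (0, sigma2]
  d <- seq(0, 10, by = 0.5)
  vals <- rbf_kernel(matrix(d), matrix(0), kernel_params(2, 3))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 2))
  # the 2b2 convention squares the length scale
  expect_equal(rbf_kernel(A, A, kernel_params(1, 2), convention = "2b2")[1, 2],
               exp(-2 / (2 * 4)), tolerance = 1e-12)
})

test_that("kernel and parameter validation reject bad input", {
  expect_error(kernel_params(-1, 1), "sigma2")
  expect_error(kernel_params(1, 0), "'b'")
  expect_error(kernel_params(1, 1, -0.1), "tau2")
  expect_error(rbf_kernel(matrix(0, 1, 2), matrix(0, 1, 3),
                          kernel_params(1, 1)), "columns")
})

test_that("log marginal likelihood agrees with dense-algebra oracle", {
  # univariate standard normal at the origin
  expect_equal(log_marginal_likelihood(matrix(0), 0, kernel_params(1, 1)),
               -0.5 * log(2 * pi), tolerance = 1e-6)
  # fixed 2-point designs against explicit determinant/inverse
  X <- matrix(c(0.1, 0.4, 0.7, 0.2), 2, 2)
  Y <- c(0.5, -1.2)
  for (p in list(kernel_params(1, 1, 0), kernel_params(2.5, 0.3, 0.4))) {
    expect_equal(log_marginal_likelihood(X, Y, p), oracle_lml(X, Y, p),
                 tolerance = 1e-10)
  }
  # scaling Y by c shifts the value exactly per the quadratic form
  p <- kernel_params(1.7, 0.9, 0.2)
  K <- rbf_kernel(X, X, p)
  diag(K) <- diag(K) + p$tau2 + 1e-8 * p$sigma2
  q <- drop(Y %*% solve(K, Y))
  for (cc in c(2, -3)) {
    expect_equal(log_marginal_likelihood(X, cc * Y, p) -
                   log_marginal_likelihood(X, Y, p),
                 -0.5 * (cc^2 - 1) * q, tolerance = 1e-10)
  }
})

test_that("BLUP predictions match an explicit-inverse oracle", {
  set.seed(11)
  X <- matrix(runif(10), 5, 2)
  Y <- rnorm(5)
  p <- kernel_params(1.3, 0.7, 0.05)
  model <- gp_model(X, Y, p)
  Xstar <- matrix(runif(8), 4, 2)
  expect_equal(blup_predict(model, Xstar), oracle_blup(X, Y, p, Xstar),
               tolerance = 1e-10)
  # noise-free interpolation reproduces training targets up to the effect of
  # the mandatory stability jitter (1e-8 * sigma2 on the Gram diagonal)
  m0 <- gp_model(X, Y, kernel_params(1.3, 0.7, 0))
  expect_equal(blup_predict(m0, X), Y, tolerance = 1e-4)
  # far from the data the prediction reverts to the response mean
  far <- matrix(100, 2, 2)
  expect_equal(blup_predict(model, far), rep(mean(Y), 2), tolerance = 1e-8)
  # linearity in Y at fixed hyperparameters
  Y2 <- rnorm(5)
  m1 <- gp_model(X, Y, p)
  m2 <- gp_model(X, Y2, p)
  m12 <- gp_model(X, Y + Y2, p)
  expect_equal(blup_predict(m12, Xstar),
               blup_predict(m1, Xstar) + blup_predict(m2, Xstar),
               tolerance = 1e-10)
  expect_error(blup_predict(model, matrix(0, 1, 3)), "columns")
})

test_that("Gram matrices are positive semidefinite on random designs", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(5:50, 1)
    q <- sample(1:4, 1)
    X <- matrix(rnorm(n * q), n, q)
    p <- kernel_params(exp(runif(1, -1, 1)), exp(runif(1, -2, 2)))
    ev <- eigen(rbf_kernel(X, X, p), symmetric = TRUE, only.values = TRUE)
    expect_gte(min(ev$values), -1e-8 * p$sigma2)
  }
})

test_that("bounded MLE respects bounds, improves on its starts, and is deterministic", {
  set.seed(21)
  X <- matrix(runif(60), 30, 2)
  f <- sin(3 * X[, 1]) + X[, 2]
  Y <- f + rnorm(30, sd = 0.1)
  fit1 <- fit_gp_mle(X, Y, restarts = 3, seed = 99)
  fit2 <- fit_gp_mle(X, Y, restarts = 3, seed = 99)
  expect_identical(fit1$params, fit2$params)
  b <- fit1$bounds
  expect_true(fit1$params$sigma2 >= b$sigma2[1] &&
                fit1$params$sigma2 <= b$sigma2[2])
  expect_true(fit1$params$b >= b$b[1] && fit1$params$b <= b$b[2])
  expect_true(fit1$params$tau2 >= b$tau2[1] && fit1$params$tau2 <= b$tau2[2])
  # the chosen optimum is at least as good as every start's initial value
  expect_true(all(-fit1$loglik <= fit1$starts$init + 1e-6))
  # fitted likelihood matches the standalone evaluation (consistency of paths)
  expect_equal(fit1$loglik,
               log_marginal_likelihood(fit1$X, fit1$Y, fit1$params),
               tolerance = 1e-8)
})

test_that("a constant-zero response drives the spatial variance to its floor", {
  X <- matrix(seq(0, 1, length.out = 10))
  fit <- fit_gp_mle(X, rep(0, 10), seed = 1)
  expect_lte(fit$params$sigma2, fit$bounds$sigma2[1] * 10)
})

test_that("MLE recovers generating hyperparameters within a factor of two in the median", {
  truth <- kernel_params(sigma2 = 2, b = 0.5, tau2 = 0.1)
  ratios <- sapply(1:10, function(seed) {
    set.seed(1000 + seed)
    X <- matrix(runif(100), 50, 2)
    K <- rbf_kernel(X, X, truth)
    diag(K) <- diag(K) + truth$tau2
    Y <- drop(t(chol(K)) %*% rnorm(50))
    fit <- fit_gp_mle(X, Y, restarts = 2, seed = seed)
    c(fit$params$sigma2 / truth$sigma2, fit$params$b / truth$b)
  })
  med <- apply(ratios, 1, median)
  expect_true(all(med > 0.5 & med < 2))
})

test_that("empty input and impossible bounds fail loudly", {
  expect_error(fit_gp_mle(matrix(numeric(0), 0, 2), numeric(0)), "empty")
  expect_error(fit_gp_mle(matrix(1), 1,
                          bounds = list(sigma2 = c(-1, 1), b = c(1, 2),
                                        tau2 = c(0.1, 1))),
               "positive interval")
})
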