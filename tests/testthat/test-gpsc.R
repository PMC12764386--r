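# Units of the clustering loop: initialization, per-cluster fits, centers,
# reassignment, prediction of new observations, and loop invariants.

test_that("initialization strategies satisfy their contracts", {
  d <- toy_dataset(n = 40)
  cfg <- gpsc_config(L = 3, seed = 11)
  lab <- initialize_labels(d, cfg)
  expect_true(all(lab %in% 1:3))
  expect_equal(length(unique(lab)), 3)
  expect_identical(lab, initialize_labels(d, cfg))  # deterministic
  # L = 1 collapses to a single cluster
  expect_identical(initialize_labels(d, gpsc_config(L = 1)), rep(1L, 40))
  # given labels pass through untouched
  expect_identical(initialize_labels(d, cfg, strategy = "given",
                                     init = d$true_labels %% 3L + 1L),
                   d$true_labels %% 3L + 1L)
  # spatial k-means yields spatially coherent labels, deterministically
  km1 <- initialize_labels(d, gpsc_config(L = 2, seed = 5,
                                          init_strategy = "spatial-kmeans"))
  km2 <- initialize_labels(d, gpsc_config(L = 2, seed = 5,
                                          init_strategy = "spatial-kmeans"))
  expect_identical(km1, km2)
  # infeasible configuration: fewer observations than clusters
  expect_error(initialize_labels(toy_dataset(n = 2), gpsc_config(L = 5)),
               "infeasible")
})

test_that("cluster centers are coordinate-wise means with empty markers", {
  s <- rbind(c(0, 0), c(2, 2), c(1, 5))
  expect_equal(cluster_centers(s, c(1L, 1L, 2L), 3),
               rbind(c(1, 1), c(1, 5), c(NA_real_, NA_real_)))
  # single-point cluster sits at the point itself
  expect_equal(cluster_centers(s, c(1L, 2L, 3L), 3)[2, ], c(2, 2))
  # idempotent under unchanged labels
  lab <- c(1L, 2L, 1L)
  expect_identical(cluster_centers(s, lab, 2), cluster_centers(s, lab, 2))
})

test_that("per-cluster fits honor membership and reproduce a clean signal", {
  d <- toy_dataset(n = 60)
  cfg <- gpsc_config(L = 2, seed = 3)
  models <- fit_cluster_models(d, d$true_labels, cfg)
  expect_length(models, 2)
  expect_equal(models[[1]]$n, sum(d$true_labels == 1))
  # identical member sets and seed give identical models
  models2 <- fit_cluster_models(d, d$true_labels, cfg)
  expect_identical(models[[1]]$params, models2[[1]]$params)
  # an empty cluster yields a NULL marker, not a crash
  m3 <- fit_cluster_models(d, rep(1L, 60), gpsc_config(L = 2, seed = 3))
  expect_null(m3[[2]])
  # a noise-free linear signal is interpolated to high accuracy
  set.seed(44)
  n <- 100
  xs <- matrix(runif(2 * n), n, 2)
  dd <- spatial_dataset(matrix(runif(2 * n), n, 2), xs,
                        y = 2 * xs[, 1] - xs[, 2])
  m <- fit_cluster_models(dd, rep(1L, n), gpsc_config(L = 1, seed = 2))[[1]]
  scal <- gpsclust:::gpsc_scaling(dd, "space+covariates")
  Z <- gpsclust:::gpsc_design(dd, scal)$Z
  rmse <- sqrt(mean((blup_predict(m, Z) - dd$y)^2))
  expect_lt(rmse, 0.05 * sd(dd$y))
})

test_that("reassignment minimizes the penalized criterion with stated tie-breaks", {
  d <- toy_dataset(n = 50)
  p <- kernel_params(1, 1, 0.1)
  idx1 <- which(d$true_labels == 1)
  idx2 <- which(d$true_labels == 2)
  feats <- cbind(d$s, d$x)
  models <- list(gp_model(feats[idx1, ], d$y[idx1], p),
                 gp_model(feats[idx2, ], d$y[idx2], p))
  centers <- cluster_centers(d$s, d$true_labels, 2)
  # lambda = 0 reduces to the pure prediction-error argmin
  lab0 <- reassign(d, models, centers, lambda = 0)
  err <- sapply(models, function(m) (blup_predict(m, feats) - d$y)^2)
  expect_identical(lab0, max.col(-err, ties.method = "first"))
  # a huge lambda sends every point to its spatially nearest center
  labL <- reassign(d, models, centers, lambda = 1e9)
  dist <- sapply(1:2, function(j)
    sqrt((d$s[, 1] - centers[j, 1])^2 + (d$s[, 2] - centers[j, 2])^2))
  expect_identical(labL, max.col(-dist, ties.method = "first"))
  # exact ties break to the lowest cluster index
  same <- list(models[[1]], models[[1]])
  expect_true(all(reassign(d, same, centers[c(1, 1), ], lambda = 0) == 1L))
  # all-empty model list is an invalid state
  expect_error(reassign(d, list(NULL, NULL), centers, 0), "empty")
})

test_that("lambda monotonically increases nearest-center assignments", {
  d <- toy_dataset(n = 60)
  p <- kernel_params(1, 1, 0.1)
  feats <- cbind(d$s, d$x)
  set.seed(1)
  lab <- sample(1:2, 60, replace = TRUE)
  models <- list(gp_model(feats[lab == 1, ], d$y[lab == 1], p),
                 gp_model(feats[lab == 2, ], d$y[lab == 2], p))
  centers <- cluster_centers(d$s, lab, 2)
  dist <- sapply(1:2, function(j)
    sqrt((d$s[, 1] - centers[j, 1])^2 + (d$s[, 2] - centers[j, 2])^2))
  nearest <- max.col(-dist, ties.method = "first")
  counts <- sapply(c(0, 0.1, 1, 10, 100, 1e4), function(lam)
    sum(reassign(d, models, centers, lambda = lam) == nearest))
  expect_true(all(diff(counts) >= 0))
})

test_that("the fitted state satisfies its structural invariants", {
  d <- toy_dataset(n = 50)
  cfg <- gpsc_config(L = 2, seed = 13, n_init = 1, T = 40)
  fit <- gpsc_fit(d, cfg)
  expect_s3_class(fit, "gpsc_state")
  expect_true(all(fit$labels %in% 1:2))
  expect_lte(length(fit$history), cfg$T)
  expect_equal(fit$iteration, length(fit$history))
  # every non-empty cluster carries a fitted model
  for (j in 1:2) {
    if (any(fit$labels == j)) expect_s3_class(fit$models[[j]], "gp_model")
  }
  # determinism of the full loop under a fixed seed
  fit2 <- gpsc_fit(d, cfg)
  expect_identical(fit$labels, fit2$labels)
  expect_identical(fit$history, fit2$history)
  # convergence means reassignment is a fixed point of the final state
  if (fit$converged) {
    expect_identical(
      predict_cluster(fit, d$s, d$x, d$y, lambda = cfg$lambda), fit$labels)
  }
  # L = 1 converges immediately with all labels 1
  f1 <- gpsc_fit(d, gpsc_config(L = 1, seed = 1))
  expect_true(all(f1$labels == 1L))
  expect_true(f1$converged)
})

test_that("relabeling the initialization permutes the output labels identically", {
  d <- toy_dataset(n = 48)
  cfg <- gpsc_config(L = 2, seed = 7)
  init <- initialize_labels(d, gpsc_config(L = 2, seed = 21))
  fit_a <- gpsc_fit(d, cfg, init = init)
  fit_b <- gpsc_fit(d, cfg, init = 3L - init)
  expect_identical(fit_a$labels, 3L - fit_b$labels)
})

test_that("new observations are scored without refitting", {
  d <- toy_dataset(n = 60)
  fit <- gpsc_fit(d, gpsc_config(L = 2, seed = 9, n_init = 1))
  # scoring the training points reproduces the state's labels
  expect_identical(predict_cluster(fit, d$s, d$x, d$y), fit$labels)
  # empty input gives empty output
  expect_identical(predict_cluster(fit, matrix(0, 0, 2), matrix(0, 0, 2),
                                   numeric(0)), integer(0))
  # feature dimension mismatches are rejected
  expect_error(predict_cluster(fit, matrix(0.5, 1, 2), matrix(0.5, 1, 3), 0),
               "covariate")
})

test_that("an emptied cluster is reseeded with the worst-explained point", {
  sq <- matrix(c(1, 9, 2, 8, 3, 7), 3, 2, byrow = TRUE)
  out <- gpsclust:::reseed_empty(c(1L, 1L, 1L), sq, 2L, 1L)
  expect_equal(out$reseeded, 2L)
  # the point with the largest error under its assigned model moved
  expect_identical(out$labels, c(1L, 1L, 2L))
  # a donor at its minimum size refuses
  out2 <- gpsclust:::reseed_empty(c(1L, 1L, 1L), sq, 2L, 3L)
  expect_identical(out2$labels, c(1L, 1L, 1L))
})
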