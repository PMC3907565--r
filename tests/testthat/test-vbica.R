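test_that("standardize centers, scales, round-trips and rejects bad input", {
  set.seed(1)
  X <- cbind(a = rnorm(40, 5, 2), b = runif(40, -1, 1), c = rnorm(40))
  std <- standardize(X)
  expect_equal(unname(colMeans(std$Z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(std$Z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(destandardize(std$Z, std), X, tolerance = 1e-10,
               ignore_attr = TRUE)
  Xz <- cbind(X, dead = rep(3, 40))
  expect_error(standardize(Xz), "dead")
  expect_error(standardize(X[1, , drop = FALSE]), "2 rows")
  Xl <- X; colnames(Xl)[2] <- "fdt_label"
  expect_error(standardize(Xl), "labels")
})

test_that("initialisation is seeded, seed-sensitive and yields a finite ELBO", {
  set.seed(3)
  Z <- matrix(rnorm(200 * 6), 200, 6)
  cfg1 <- vim_config(K = 2, L_max = 3, m = 3, seed = 1)
  cfg2 <- vim_config(K = 2, L_max = 3, m = 3, seed = 2)
  m1 <- init_model(Z, cfg1)
  m1b <- init_model(Z, cfg1)
  m2 <- init_model(Z, cfg2)
  expect_identical(m1$clusters[[1]]$mu_mean, m1b$clusters[[1]]$mu_mean)
  expect_false(identical(m1$clusters[[1]]$mu_mean, m2$clusters[[1]]$mu_mean))
  e0 <- perimix:::elbo_value(m1, Z, m1$cache)
  expect_true(is.finite(e0))
  ## K = 1 k-means degenerates to the data mean
  mk1 <- init_model(Z, vim_config(K = 1, L_max = 2, seed = 4))
  expect_lt(max(abs(mk1$clusters[[1]]$mu_mean - colMeans(Z))), 0.05)
  expect_error(init_model(Z[1:3, ], vim_config(K = 5, L_max = 2)), "clusters")
  expect_error(init_model(Z, vim_config(K = 2, L_max = 6)), "dimension")
})

test_that("the ELBO is non-decreasing across sweeps on varied configurations", {
  configs <- list(
    list(K = 1, L = 3, m = 3, D = 6, n = 150),
    list(K = 2, L = 4, m = 2, D = 8, n = 200),
    list(K = 3, L = 2, m = 1, D = 6, n = 180)
  )
  for (cf in configs) {
    truth <- separated_truth(K = max(cf$K, 1), D = cf$D, L = 2, sep = 6,
                             seed = cf$n)
    sam <- sample_ica_mixture(truth, cf$n, seed = cf$D)
    Z <- standardize(sam$X)$Z
    fit <- fit_vbica_mm(Z, vim_config(K = cf$K, L_max = cf$L, m = cf$m,
                                      n_iterations = 25, seed = 7))
    expect_true(elbo_monotone(fit$model$elbo_trace),
                info = paste("config", cf$K, cf$L, cf$m))
    expect_equal(fit$elbo, tail(fit$model$elbo_trace, 1))
  }
})

test_that("fitting is deterministic given data and seed", {
  sam <- sample_ica_mixture(separated_truth(K = 2, D = 6), 250, seed = 12)
  Z <- standardize(sam$X)$Z
  cfg <- vim_config(K = 2, L_max = 3, m = 3, n_iterations = 30, seed = 5)
  f1 <- fit_vbica_mm(Z, cfg)
  f2 <- fit_vbica_mm(Z, cfg)
  expect_identical(f1$model$elbo_trace, f2$model$elbo_trace)
  expect_identical(f1$responsibilities, f2$responsibilities)
})

test_that("an infinite tolerance stops after one sweep", {
  Z <- matrix(rnorm(60 * 5), 60, 5)
  fit <- fit_vbica_mm(Z, vim_config(K = 1, L_max = 2, n_iterations = 50,
                                    convergence_tol = Inf, seed = 1))
  expect_equal(fit$n_sweeps, 1L)
  expect_true(fit$converged)
})

test_that("responsibilities normalise, specialise and degenerate correctly", {
  truth <- separated_truth(K = 2, D = 6, sep = 8)
  sam <- sample_ica_mixture(truth, 400, seed = 3)
  std <- standardize(sam$X)
  fit <- fit_vbica_mm(std$Z, vim_config(K = 2, L_max = 3, m = 3,
                                        n_iterations = 40, seed = 2))
  r <- responsibilities(fit$model, std$Z)
  expect_equal(rowSums(r), rep(1, 400), tolerance = 1e-10)
  expect_true(all(r >= 0 & r <= 1))
  ## a point at a fitted cluster mean is claimed by that cluster
  for (k in 1:2) {
    zk <- matrix(fit$model$clusters[[k]]$mu_mean, 1)
    expect_gt(responsibilities(fit$model, zk)[1, k], 0.99)
  }
  fit1 <- fit_vbica_mm(std$Z, vim_config(K = 1, L_max = 3,
                                         n_iterations = 10, seed = 2))
  expect_equal(responsibilities(fit1$model, std$Z[1:7, ]),
               matrix(1, 7, 1), tolerance = 1e-12)
  expect_error(responsibilities(fit$model, std$Z[, 1:4]), "columns")
})

test_that("axis magnitudes are homogeneous in the mixing column and vanish with it", {
  sf <- get_small_fit()
  model <- sf$fit$model
  base <- axis_magnitudes(model, 1)
  base <- base[order(base$axis), ]
  doubled <- model
  doubled$clusters[[1]]$A_mean[, 2] <- 2 * doubled$clusters[[1]]$A_mean[, 2]
  zeroed <- model
  zeroed$clusters[[1]]$A_mean[, 3] <- 0
  m2 <- axis_magnitudes(doubled, 1); m2 <- m2[order(m2$axis), ]
  m3 <- axis_magnitudes(zeroed, 1); m3 <- m3[order(m3$axis), ]
  expect_equal(m2$magnitude[2], 2 * base$magnitude[2], tolerance = 1e-12)
  expect_equal(m2$magnitude[-2], base$magnitude[-2], tolerance = 1e-12)
  expect_equal(m3$magnitude[3], 0)
  expect_error(axis_magnitudes(model, 9), "invalid")
})

test_that("clusters with strongly non-Gaussian sources are recovered (small scale)", {
  truth <- separated_truth(K = 2, D = 8, L = 2, sep = 7, seed = 55)
  sam <- sample_ica_mixture(truth, 500, seed = 56)
  Z <- standardize(sam$X)$Z
  fit <- fit_vbica_mm(Z, vim_config(K = 2, L_max = 4, m = 3,
                                    n_iterations = 60, seed = 1))
  hard <- assign_clusters(fit$responsibilities)
  agree <- max(mean(hard == sam$cluster), mean(hard == 3 - sam$cluster))
  expect_gt(agree, 0.98)
})
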