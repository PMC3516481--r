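test_that("gaussian kernel values match hand arithmetic", {
  x <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)   # squared distance 2
  K <- gaussian_kernel(x, h = 0.5, scaling = "none")
  expect_equal(diag(K), c(1, 1))                   # K(x, x) = 1
  expect_equal(K[1, 2], exp(-1), tolerance = 1e-9) # 0.367879...
  # h = 0 degenerates to the all-ones matrix
  expect_equal(gaussian_kernel(x, h = 0, scaling = "none"),
               matrix(1, 2, 2), ignore_attr = TRUE)
  expect_error(gaussian_kernel(x, matrix(0, 2, 3), h = 1), "column")
  expect_error(gaussian_kernel(x, h = -1), "h must")
})

test_that("default bandwidth grid scales with the observed distances", {
  set.seed(21)
  X <- matrix(rnorm(40 * 6), 40, 6)
  base <- c(0.1, 0.25, 0.5, 1, 2, 5)
  # by_median scaling pins the median scaled distance at 1
  gd <- default_h_grid(X, scaling = "by_median")
  expect_equal(gd$h_grid, base)
  # with no scaling, doubling all squared distances halves the grid
  g1 <- default_h_grid(X, scaling = "none")$h_grid
  g2 <- default_h_grid(X * sqrt(2), scaling = "none")$h_grid
  expect_equal(g2, g1 / 2, tolerance = 1e-10)
  expect_true(all(diff(gd$h_grid) > 0) && all(gd$h_grid > 0))
  expect_error(default_h_grid(matrix(1, 5, 3)), "identical")
})

test_that("kernels built from marker data are PSD within tolerance", {
  for (s in 1:5) {
    X <- marker_matrix(make_geno(30, 50, seed = 30 + s))
    for (h in c(0.25, 1, 5)) {
      K <- gaussian_kernel(X, h = h, scaling = "by_median")
      ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8 * max(ev))
    }
  }
})

test_that("two-point toy prediction matches hand arithmetic", {
  # custom kernel fit: yhat = mu + K_new alpha
  fit <- structure(list(mu_hat = 0.5,
                        u_hat = matrix(c(1, -1), 2, 1),
                        alpha_hat = matrix(c(2, -1), 2, 1),
                        custom_kernels = TRUE),
                   class = "gp_rkhs_fit")
  K_new <- matrix(c(1, 0.5, 0.25, 1), 2, 2, byrow = TRUE)
  # row 1: 0.5 + 1*2 + 0.5*(-1) = 2; row 2: 0.5 + 0.25*2 - 1 = 0
  expect_equal(predict(fit, K_new = list(K_new)), c(2, 0))
  # all-zero genetic effects predict the intercept
  fit$alpha_hat[] <- 0
  expect_equal(predict(fit, K_new = list(K_new)), c(0.5, 0.5))
})

test_that("fitting is self-consistent and handles degenerate grids", {
  G <- impute_genotypes(make_geno(80, 60, seed = 33))
  sim <- simulate_trait(G, n_qtl = 10, n_pairs = 0, h2_target = 0.6,
                        seed = 34)
  y <- sim$y[, 1]
  mc <- mcmc_settings(5000, 1000, seed = 35)
  fit <- fit_rkhs(G, y, mcmc = mc)
  # predicting the training inputs reproduces the in-sample fit exactly
  expect_lt(max(abs(predict(fit, G) - fit$fitted)), 1e-8)
  # duplicated kernel: predictions unchanged, variance redistributed.
  # (exact only when the data dominate the variance priors, so the check
  # uses a weakly informative prior; an informative prior on each copy
  # doubles the total prior genetic variance and shifts the fit)
  mc2 <- mcmc_settings(8000, 2000, seed = 36)
  f1 <- fit_rkhs(G, y, h_grid = 1, mcmc = mc2, df_k = 0.5, s_k = 0.5)
  f2 <- fit_rkhs(G, y, h_grid = c(1, 1), mcmc = mc2, df_k = 0.5, s_k = 0.5)
  expect_lt(mean(abs(f1$fitted - f2$fitted)), 0.05)
  # total kernel variance is shared between the two copies
  expect_lt(abs(sum(f2$sigma_k2_hat) - f1$sigma_k2_hat),
            0.75 * f1$sigma_k2_hat)
  # h -> 0 collapses to the intercept-plus-common-effect model
  f0 <- fit_rkhs(G, y, h_grid = 1e-8, scaling = "none", mcmc = mc)
  expect_lt(max(abs(predict(f0, G) - mean(y))), 0.1)
  expect_error(fit_rkhs(G, y, h_grid = numeric(0)), "h_grid")
  expect_error(fit_rkhs(G, y, h_grid = -1), "h_grid")
})

test_that("kernel averaging concentrates variance on the generating kernel", {
  hits <- 0
  h_grid <- c(0.1, 1, 10)
  for (s in 1:10) {
    set.seed(40 + s)
    X <- matrix(rnorm(200 * 8), 200, 8)
    K <- gaussian_kernel(X, h = h_grid[2], scaling = "by_median")
    ev <- eigen(K, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    g <- drop(ev$vectors %*% (sqrt(lam) * rnorm(200)))
    y <- g + rnorm(200, 0, sd(g) / sqrt(3))     # signal-to-noise 3:1
    fit <- fit_rkhs(X, y, h_grid = h_grid, scaling = "by_median",
                    mcmc = mcmc_settings(1500, 500, seed = 50 + s))
    if (which.max(fit$variance_share) == 2) hits <- hits + 1
  }
  expect_gte(hits, 7)
})
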