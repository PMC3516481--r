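test_that("Bayes B scale hyperparameter follows the printed formulas", {
  # q = 0.5 for all 100 markers: sigma_a2 = 1/(0.05 * 50) = 0.4,
  # s_beta = 0.4 * (4-2)/4 = 0.2
  s <- bayesb_scale_hyperparameter(rep(0.5, 100), pi = 0.95, df_beta = 4,
                                   sigma_S2 = 1)
  expect_equal(s, 0.2, tolerance = 1e-12)
  # df = 4 means s_beta = sigma_a2 / 2 for any sigma_a2
  q <- runif(50, 0.1, 0.9)
  s2 <- bayesb_scale_hyperparameter(q, pi = 0.4, df_beta = 4, sigma_S2 = 2.3)
  sigma_a2 <- 2.3 / (0.6 * sum(2 * q * (1 - q)))
  expect_equal(s2, sigma_a2 / 2, tolerance = 1e-12)
  # halving the (1 - pi) mass doubles the scale
  expect_equal(bayesb_scale_hyperparameter(q, pi = 0.5, df_beta = 4),
               2 * bayesb_scale_hyperparameter(q, pi = 0, df_beta = 4),
               tolerance = 1e-12)
  expect_error(bayesb_scale_hyperparameter(q, df_beta = 2), "df_beta")
  expect_error(bayesb_scale_hyperparameter(c(0, q)), "frequencies")
})

test_that("frozen-variance samplers match their conjugate ridge oracles", {
  fx <- make_std_fixture(20, 5, seed = 101)
  mc <- mcmc_settings(12000, 2000, seed = 3)
  se2 <- 0.25
  # BRR vs ridge
  fb <- fit_brr(fx$X, fx$y, mc, intercept = FALSE,
                fix_sigma_e2 = se2, fix_sigma_beta2 = 0.5)
  expect_lt(max(abs(fb$beta_hat -
                      ridge_oracle(fx$X, fx$y, se2, 0.5))), 0.02)
  # BL with all mixture variances frozen vs generalized ridge
  tau2 <- c(0.2, 0.5, 1, 2, 5)
  fl <- fit_bayesian_lasso(fx$X, fx$y, mc, intercept = FALSE,
                           fix_sigma_e2 = se2, fix_lambda2 = 1,
                           fix_tau2 = tau2)
  expect_lt(max(abs(fl$beta_hat -
                      ridge_oracle(fx$X, fx$y, se2, tau2 * se2))), 0.02)
  # Bayes B at pi = 0 with frozen per-marker variances vs generalized ridge
  sj2 <- c(1, 0.5, 0.25, 2, 0.75)
  fa <- fit_bayes_b(fx$X, fx$y, mc, pi = 0, intercept = FALSE,
                    fix_sigma_e2 = se2, fix_sigma_beta2 = sj2)
  expect_lt(max(abs(fa$beta_hat -
                      ridge_oracle(fx$X, fx$y, se2, sj2))), 0.02)
})

test_that("Bayes A is the pi = 0 code path of Bayes B, draw for draw", {
  fx <- make_std_fixture(30, 8, seed = 102)
  mc <- mcmc_settings(600, 100, seed = 9)
  fa <- fit_bayes_a(fx$X, fx$y, mc, s_beta = 0.3)
  fb <- fit_bayes_b(fx$X, fx$y, mc, pi = 0, s_beta = 0.3)
  expect_identical(fa$beta_hat, fb$beta_hat)
  expect_identical(fa$sigma_e2_trace, fb$sigma_e2_trace)
  expect_identical(fa$mu_hat, fb$mu_hat)
  expect_true(all(fa$inclusion_prob == 1))
  # defaults carried from the study: pi = 0.95, df_beta = 4
  expect_equal(formals(fit_bayes_b)$pi, 0.95)
  expect_equal(formals(fit_bayes_b)$df_beta, 4)
  expect_equal(unlist(formals(fit_brr)[c("df_beta", "s_beta",
                                         "df_e", "s_e")]),
               c(df_beta = 4, s_beta = 1, df_e = 4, s_e = 1))
})

test_that("Bayesian LASSO shrinks everything at huge fixed lambda", {
  fx <- make_std_fixture(25, 10, seed = 103)
  fl <- fit_bayesian_lasso(fx$X, fx$y, mcmc_settings(3000, 500, seed = 2),
                           fix_lambda2 = 1e8)
  expect_lt(max(abs(fl$beta_hat)), 0.01)
})

test_that("differential shrinkage: BL nulls shrink harder than BRR's", {
  wins <- 0
  for (s in 1:10) {
    G <- make_geno(120, 300, seed = 200 + s)
    set.seed(300 + s)
    qtl <- sample.int(300, 5)
    beta <- rnorm(5, 0, 1.5)
    y <- drop(G$X[, qtl] %*% beta + rnorm(120, 0, 1))
    mc <- mcmc_settings(1500, 500, seed = 400 + s)
    fl <- fit_bayesian_lasso(G$X, y, mc)
    fb <- fit_brr(G$X, y, mc)
    null_idx <- setdiff(seq_len(300), qtl)
    if (mean(abs(fl$beta_hat[null_idx])) < mean(abs(fb$beta_hat[null_idx])))
      wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("Bayes B inclusion probabilities rank true QTL above nulls", {
  hits <- 0
  for (s in 1:5) {
    G <- make_geno(1000, 500, seed = 500 + s)
    Gi <- impute_genotypes(G)
    p <- ncol(Gi$X)
    set.seed(600 + s)
    qtl <- sample.int(p, 10)
    beta <- rnorm(10, 0, 1)
    g <- drop(Gi$X[, qtl] %*% beta)
    y <- g + rnorm(1000, 0, sd(g) * 0.5)   # h2 = 0.8
    fb <- fit_bayes_b(Gi$X, y, mcmc_settings(1200, 400, seed = 700 + s))
    if (mean(fb$inclusion_prob[qtl]) >
          mean(fb$inclusion_prob[-qtl])) hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("linear predictions are mu + X beta with id alignment", {
  fit <- structure(list(model = "BRR", mu_hat = 1,
                        beta_hat = c(1, -1, 0),
                        marker_ids = c("M1", "M2", "M3")),
                   class = "gp_linear_fit")
  X <- matrix(c(1, 1, 0), 1, 3, dimnames = list("L1", c("M1", "M2", "M3")))
  expect_equal(predict(fit, X), 1)                 # 1 + 1 - 1 + 0
  # beta = 0 -> all predictions mu
  fit0 <- fit; fit0$beta_hat <- c(0, 0, 0)
  expect_equal(unname(predict(fit0, rbind(X, X))), c(1, 1))
  # reordered columns are matched by marker id
  Xr <- X[, c("M3", "M1", "M2"), drop = FALSE]
  expect_equal(predict(fit, Xr), 1)
  # missing marker ids named in the error
  expect_error(predict(fit, X[, 1:2, drop = FALSE]), "M3")
})

test_that("in-sample fitted values are consistent and chains are healthy", {
  fx <- make_std_fixture(40, 12, seed = 104)
  fit <- fit_brr(fx$X, fx$y, mcmc_settings(4000, 1000, seed = 5))
  expect_equal(predict(fit, fx$X), fit$fitted)
  expect_true(all(fit$sigma_e2_trace > 0))
  tr <- fit$sigma_e2_trace
  m_half <- mean(tr[(length(tr) / 2):length(tr)])
  m_quarter <- mean(tr[(3 * length(tr) / 4):length(tr)])
  expect_lt(abs(m_half - m_quarter) / m_quarter, 0.10)
  expect_error(fit_brr(fx$X, rep(1, 40)), "constant")
  expect_error(fit_brr(fx$X, fx$y[1:10]), "length")
})

test_that("the four linear models predict additive traits similarly", {
  # biparental additive world: accuracies must clear 0.35 and sit within
  # 0.1 of one another ("results are mixed, and all models gave similar
  # predictions")
  G <- impute_genotypes(simulate_genotypes(306, 500, seed = 101,
                                           n_founders = 2))
  sim <- simulate_trait(G, n_qtl = 30, n_pairs = 200, h2_target = 0.6,
                        prop_epistasis = 0, n_env = 1, seed = 1101)
  cfg <- run_config(n_partitions = 10, seed = 2101, n_iter = 4000,
                    burn_in = 1000)
  res <- cross_validate(c("BRR", "BL", "BayesA", "BayesB"), G,
                        y = sim$y[, 1], config = cfg)
  expect_true(all(res$metrics$mean_corr > 0.35))
  expect_lt(diff(range(res$metrics$mean_corr)), 0.1)
})
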