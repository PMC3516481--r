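test_that("an oracle predictor scores perfectly through the CV driver", {
  G <- impute_genotypes(make_geno(60, 30, seed = 170))
  sim <- simulate_trait(G, n_qtl = 8, n_pairs = 0, h2_target = 0.5,
                        seed = 171)
  y <- sim$y[, 1]
  oracle <- list(ORACLE = function(X_train, y_train, seed) {
    structure(list(ids = rownames(X_train)), class = "cv_oracle_fit")
  })
  # predict method resolves the true y by row name
  assign("predict.cv_oracle_fit",
         function(object, newdata, ...) y[match(rownames(newdata),
                                                G$line_ids)],
         envir = globalenv())
  withr::defer(rm("predict.cv_oracle_fit", envir = globalenv()))
  res <- cross_validate(oracle, G, y = y,
                        config = run_config(n_partitions = 5, seed = 172,
                                            n_iter = 100, burn_in = 10))
  expect_equal(res$metrics$mean_corr, 1, tolerance = 1e-12)
  expect_equal(res$metrics$mean_pmse, 0, tolerance = 1e-12)
})

test_that("cross-validation is deterministic and pairs partitions", {
  G <- impute_genotypes(make_geno(50, 40, seed = 173))
  sim <- simulate_trait(G, n_qtl = 10, n_pairs = 0, h2_target = 0.6,
                        seed = 174)
  cfg <- run_config(n_partitions = 4, seed = 175, n_iter = 400,
                    burn_in = 100)
  r1 <- cross_validate(c("BRR", "RKHS"), G, y = sim$y[, 1], config = cfg)
  r2 <- cross_validate(c("BRR", "RKHS"), G, y = sim$y[, 1], config = cfg)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$per_partition, r2$per_partition)
  # both models see the same partitions (paired comparisons)
  expect_equal(r1$per_partition$partition[r1$per_partition$model == "BRR"],
               r1$per_partition$partition[r1$per_partition$model == "RKHS"])
  # default configuration is the study protocol
  expect_equal(run_config()$n_partitions, 50)
  expect_equal(run_config()$validation_fraction, 0.10)
  expect_equal(run_config()$n_iter, 35000)
})

test_that("a failing model is recorded as NA without killing the run", {
  G <- impute_genotypes(make_geno(40, 20, seed = 176))
  y <- rnorm(40)
  models <- list(
    GOOD = function(X_train, y_train, seed)
      structure(list(m = mean(y_train), p = ncol(X_train)),
                class = "cv_const_fit"),
    BAD = function(X_train, y_train, seed) stop("boom"))
  assign("predict.cv_const_fit",
         function(object, newdata, ...)
           rep(object$m, nrow(newdata)) + seq_len(nrow(newdata)) * 1e-6,
         envir = globalenv())
  withr::defer(rm("predict.cv_const_fit", envir = globalenv()))
  expect_warning(
    cross_validate(models["BAD"], G, y = y,
                   config = run_config(n_partitions = 1, seed = 177,
                                       n_iter = 100, burn_in = 10)),
    "boom")
  res <- suppressWarnings(
    cross_validate(models, G, y = y,
                   config = run_config(n_partitions = 3, seed = 177,
                                       n_iter = 100, burn_in = 10)))
  expect_equal(res$metrics$n_partitions[res$metrics$model == "BAD"], 0)
  expect_true(all(is.na(
    res$per_partition$corr[res$per_partition$model == "BAD"])))
  expect_equal(res$metrics$n_partitions[res$metrics$model == "GOOD"], 3)
})

test_that("phenotype-table plumbing selects the right env and trait", {
  G <- impute_genotypes(make_geno(40, 25, seed = 178))
  sim <- simulate_trait(G, n_qtl = 6, n_pairs = 0, h2_target = 0.7,
                        n_env = 2, seed = 179)
  ph <- as_phenotype_table(sim, trait = "GY")
  cfg <- run_config(n_partitions = 3, seed = 180, n_iter = 300,
                    burn_in = 100)
  res <- cross_validate("BRR", G, pheno = ph, trait = "GY", env = "E2",
                        config = cfg)
  res_direct <- cross_validate("BRR", G, y = sim$y[, 2], config = cfg)
  expect_equal(res$metrics$mean_corr, res_direct$metrics$mean_corr)
  expect_error(cross_validate("BRR", G, pheno = ph, trait = "DTH",
                              env = "E1", config = cfg),
               "no phenotypes")
})

test_that("the CLI runs simulate and cv end to end on a tiny problem", {
  out <- withr::local_tempdir()
  gpbench_cli(c("simulate", "--n", "40", "--p", "30", "--n-qtl", "5",
                "--n-pairs", "0", "--h2", "0.6", "--seed", "3",
                "--out-dir", out, "--log-level", "quiet"))
  expect_true(file.exists(file.path(out, "geno.tsv")))
  expect_true(file.exists(file.path(out, "pheno.tsv")))
  expect_true(file.exists(file.path(out, "truth.json")))
  gpbench_cli(c("cv", "--geno", file.path(out, "geno.tsv"),
                "--pheno", file.path(out, "pheno.tsv"),
                "--models", "brr,rkhs", "--partitions", "3",
                "--iters", "300", "--burnin", "100", "--seed", "4",
                "--out-dir", out, "--log-level", "quiet"))
  for (f in c("metrics.csv", "pairs.csv", "ttests.csv", "report.md",
              "run_config.json"))
    expect_true(file.exists(file.path(out, f)), label = f)
  met <- read.csv(file.path(out, "metrics.csv"))
  expect_setequal(met$model, c("BRR", "RKHS"))
  cfg <- jsonlite::read_json(file.path(out, "run_config.json"))
  expect_equal(cfg$seed, 4)
  expect_equal(cfg$n_partitions, 3)
})
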