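#' Run configuration for fitting and cross-validation
#'
#' Collects the knobs shared by [cross_validate] and the command-line
#' interface, with the benchmarking defaults: 50 partitions at 90/10,
#' 35,000 Gibbs iterations (10,000-sample evidence-framework training for
#' the BRNN is governed by its own `max_iter`/`restarts` block).
#'
#' @param n_partitions number of random partitions (default 50).
#' @param validation_fraction validation share, in (0, 0.5] (default 0.1).
#' @param seed master seed; all partition and per-model seeds derive from
#'   it.
#' @param n_iter,burn_in,thin MCMC run length for the samplers.
#' @param bl,bayesb,rkhs,rbfnn,brnn named lists of model-specific
#'   arguments forwarded to the fitting functions.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_partitions = 50, validation_fraction = 0.10,
                       seed = 1L, n_iter = 35000, burn_in = 5000, thin = 1,
                       bl = list(), bayesb = list(), rkhs = list(),
                       rbfnn = list(), brnn = list()) {
  if (burn_in < 0 || burn_in >= n_iter) stop("need 0 <= burn_in < n_iter")
  if (validation_fraction <= 0 || validation_fraction > 0.5)
    stop("validation_fraction must be in (0, 0.5]")
  structure(list(n_partitions = n_partitions,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed),
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 bl = bl, bayesb = bayesb, rkhs = rkhs,
                 rbfnn = rbfnn, brnn = brnn),
            class = "run_config")
}

gp_models <- c("BRR", "BL", "BayesA", "BayesB", "RKHS", "RBFNN", "BRNN")

fit_one_model <- function(model, X_train, y_train, config, seed) {
  mc <- mcmc_settings(config$n_iter, config$burn_in, config$thin, seed)
  switch(model,
    BRR = fit_brr(X_train, y_train, mcmc = mc),
    BL = do.call(fit_bayesian_lasso,
                 c(list(G = X_train, y = y_train, mcmc = mc), config$bl)),
    BayesA = do.call(fit_bayes_a,
                     c(list(G = X_train, y = y_train, mcmc = mc),
                       config$bayesb[setdiff(names(config$bayesb), "pi")])),
    BayesB = do.call(fit_bayes_b,
                     c(list(G = X_train, y = y_train, mcmc = mc),
                       config$bayesb)),
    RKHS = do.call(fit_rkhs,
                   c(list(G = X_train, y = y_train, mcmc = mc),
                     config$rkhs)),
    RBFNN = do.call(train_rbfnn,
                    c(list(X = X_train, y = y_train, seed = seed),
                      config$rbfnn)),
    BRNN = do.call(train_brnn,
                   c(list(X = X_train, y = y_train, seed = seed),
                     config$brnn)),
    stop("unknown model '", model, "'"))
}

#' Cross-validated comparison of prediction models
#'
#' Builds one list of random 90/10 partitions (shared by every model so
#' per-partition metrics are paired), trains each model on each training
#' fold, predicts the validation fold, and aggregates Pearson correlation
#' and predictive mean-squared error. The "SE" reported next to each mean
#' is the standard deviation of the per-partition correlations. A model
#' failure on a partition is recorded as `NA` and excluded from that
#' model's aggregate with a warning.
#'
#' @param models character vector from
#'   BRR, BL, BayesA, BayesB, RKHS, RBFNN, BRNN; alternatively a *named
#'   list* of custom fitting functions `function(X_train, y_train, seed)`
#'   returning an object with a `predict(object, X_new)` method (used for
#'   oracle predictors in tests and for user extensions).
#' @param G a [genotype_matrix] (or plain matrix) without missing values.
#' @param pheno phenotype table (see [read_phenotypes]); alternatively
#'   pass `y` directly.
#' @param trait,env which records of `pheno` to use.
#' @param y numeric response aligned with the rows of `G`; overrides
#'   `pheno`.
#' @param config a [run_config].
#' @return a `gp_cv_result`: `metrics` (one row per model), long
#'   `per_partition` data.frame, the partition list and the config.
#' @export
cross_validate <- function(models, G, pheno = NULL, trait = NULL,
                           env = NULL, y = NULL, config = run_config()) {
  custom <- NULL
  if (is.list(models)) {
    if (is.null(names(models)) || any(!nzchar(names(models))))
      stop("custom model list must be named")
    custom <- models
    models <- names(models)
  } else {
    models <- match.arg(models, gp_models, several.ok = TRUE)
  }
  X <- resolve_X(G)
  if (is.null(y)) {
    if (is.null(pheno)) stop("supply either pheno or y")
    sel <- pheno$trait == trait & pheno$env == env
    if (!any(sel)) stop("no phenotypes for trait '", trait,
                        "' in env '", env, "'")
    ph <- pheno[sel, ]
    ids <- if (inherits(G, "genotype_matrix")) G$line_ids else rownames(X)
    miss <- setdiff(ph$line_id, ids)
    if (length(miss) > 0)
      stop("phenotyped lines missing from genotypes: ",
           paste(head(miss, 5), collapse = ", "))
    X <- X[match(ph$line_id, ids), , drop = FALSE]
    y <- ph$value
  }
  n <- length(y)
  parts <- make_partitions(n, config$n_partitions,
                           config$validation_fraction, config$seed)
  pp <- expand.grid(partition = seq_along(parts), model = models,
                    stringsAsFactors = FALSE)
  pp$corr <- NA_real_
  pp$pmse <- NA_real_
  for (i in seq_len(nrow(pp))) {
    part <- parts[[pp$partition[i]]]
    model <- pp$model[i]
    seed_i <- derive_seed(config$seed, part$partition_index, model)
    res <- tryCatch({
      fit <- if (!is.null(custom))
        custom[[model]](X[part$train_idx, , drop = FALSE],
                        y[part$train_idx], seed_i)
      else fit_one_model(model, X[part$train_idx, , drop = FALSE],
                         y[part$train_idx], config, seed_i)
      pred <- predict(fit, X[part$test_idx, , drop = FALSE])
      obs <- y[part$test_idx]
      list(corr = suppressWarnings(pearson_correlation(obs, pred)),
           pmse = pmse(obs, pred))
    }, error = function(cond) {
      warning(sprintf("%s failed on partition %d: %s", model,
                      part$partition_index, conditionMessage(cond)))
      list(corr = NA_real_, pmse = NA_real_)
    })
    pp$corr[i] <- res$corr
    pp$pmse[i] <- res$pmse
  }
  metrics <- do.call(rbind, lapply(models, function(mname) {
    sub <- pp[pp$model == mname, ]
    data.frame(model = mname,
               trait = if (is.null(trait)) NA_character_ else trait,
               env = if (is.null(env)) NA_character_ else env,
               mean_corr = mean(sub$corr, na.rm = TRUE),
               se_corr = sd(sub$corr, na.rm = TRUE),
               mean_pmse = mean(sub$pmse, na.rm = TRUE),
               n_partitions = sum(!is.na(sub$corr)),
               stringsAsFactors = FALSE)
  }))
  pp$trait <- if (is.null(trait)) NA_character_ else trait
  pp$env <- if (is.null(env)) NA_character_ else env
  structure(list(metrics = metrics, per_partition = pp,
                 partitions = parts, config = config,
                 models = models),
            class = "gp_cv_result")
}

#' @export
print.gp_cv_result <- function(x, ...) {
  cat("cross-validation over", length(x$partitions), "partitions\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

format_metric_cell <- function(mean, se) sprintf("%.2f (%.2f)", mean, se)

#' Table-style summary of one or more cross-validation runs
#'
#' Produces wide environment-by-model tables of "mean (SD)" correlation
#' strings and mean PMSE, flags the best model per environment (highest
#' correlation, lowest PMSE), and exports the paired per-partition
#' correlation point cloud for every two-model combination.
#'
#' @param results a `gp_cv_result` or a list of them (e.g. one per
#'   environment).
#' @return list with `correlation_table`, `pmse_table`,
#'   `best_correlation`, `best_pmse` (per-env vectors of model names) and
#'   `pairs` (long data.frame of per-partition correlation pairs).
#' @export
summarize_benchmark <- function(results) {
  if (inherits(results, "gp_cv_result")) results <- list(results)
  metrics <- do.call(rbind, lapply(results, `[[`, "metrics"))
  pp <- do.call(rbind, lapply(results, `[[`, "per_partition"))
  metrics$env[is.na(metrics$env)] <- "(all)"
  pp$env[is.na(pp$env)] <- "(all)"
  envs <- unique(metrics$env)
  models <- unique(metrics$model)
  corr_tab <- pmse_tab <- matrix(NA_character_, length(envs), length(models),
                                 dimnames = list(envs, models))
  best_corr <- best_pmse <- setNames(character(length(envs)), envs)
  for (e in envs) {
    sub <- metrics[metrics$env == e, ]
    for (i in seq_len(nrow(sub))) {
      corr_tab[e, sub$model[i]] <-
        format_metric_cell(sub$mean_corr[i], sub$se_corr[i])
      pmse_tab[e, sub$model[i]] <- sprintf("%.3f", sub$mean_pmse[i])
    }
    best_corr[e] <- sub$model[which.max(sub$mean_corr)]
    best_pmse[e] <- sub$model[which.min(sub$mean_pmse)]
  }
  pairs <- NULL
  for (e in envs) {
    sub <- pp[pp$env == e, ]
    ms <- unique(sub$model)
    if (length(ms) < 2) next
    cmb <- utils::combn(ms, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- sub[sub$model == cmb[1, j], ]
      b <- sub[sub$model == cmb[2, j], ]
      pairs <- rbind(pairs, data.frame(
        env = e, partition = a$partition,
        model_x = cmb[1, j], model_y = cmb[2, j],
        corr_x = a$corr, corr_y = b$corr,
        stringsAsFactors = FALSE))
    }
  }
  list(correlation_table = corr_tab, pmse_table = pmse_tab,
       best_correlation = best_corr, best_pmse = best_pmse,
       metrics = metrics, pairs = pairs)
}
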