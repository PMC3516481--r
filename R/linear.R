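#' MCMC settings
#'
#' @param n_iter total Gibbs iterations (default 35000).
#' @param burn_in discarded initial iterations (default 5000).
#' @param thin thinning interval (default 1).
#' @param seed integer seed.
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 35000, burn_in = 5000, thin = 1,
                          seed = 1L) {
  if (burn_in < 0 || burn_in >= n_iter) stop("need 0 <= burn_in < n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Scale hyperparameter for the Bayes A/B marker-variance prior
#'
#' Derives the scale of the scaled-inverse-chi-square prior on the
#' per-marker effect variance from the marker allele frequencies:
#' first the per-marker additive variance
#' `sigma_a2 = sigma_S2 / ((1 - pi) * sum(2 q (1 - q)))`, then
#' `s_beta = sigma_a2 * (df_beta - 2) / df_beta`, so that the prior mean of
#' each marker variance equals `sigma_a2`.
#'
#' @param q allele frequencies in (0, 1).
#' @param pi prior probability of a null marker effect, in [0, 1).
#' @param df_beta prior degrees of freedom (> 2).
#' @param sigma_S2 additive genetic variance attributed to markers.
#' @return the scale `s_beta`.
#' @export
bayesb_scale_hyperparameter <- function(q, pi = 0.95, df_beta = 4,
                                        sigma_S2 = 1) {
  if (df_beta <= 2) stop("df_beta must exceed 2 (prior mean undefined)")
  if (pi < 0 || pi >= 1) stop("pi must be in [0, 1)")
  if (any(q <= 0 | q >= 1)) stop("allele frequencies must be in (0, 1)")
  denom <- (1 - pi) * sum(2 * q * (1 - q))
  if (denom <= 0) stop("sum(2 q (1 - q)) is zero")
  sigma_a2 <- sigma_S2 / denom
  sigma_a2 * (df_beta - 2) / df_beta
}

check_training_data <- function(X, y) {
  if (anyNA(X)) stop("marker matrix has missing values; impute first")
  if (anyNA(y) || any(!is.finite(y))) stop("y must be finite and complete")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (length(y) < 2) stop("need at least 2 training lines")
  if (sd(y) == 0) stop("y is constant")
  invisible(TRUE)
}

new_linear_fit <- function(model, raw, X, marker_ids, extra = list()) {
  fit <- c(list(
    model = model,
    mu_hat = raw$mu_hat,
    beta_hat = drop(raw$beta_hat),
    sigma_e2_hat = raw$sigma_e2_hat,
    marker_ids = marker_ids,
    n_keep = raw$n_keep,
    sigma_e2_trace = drop(raw$sigma_e2_trace)), extra)
  fit$fitted <- drop(fit$mu_hat + X %*% fit$beta_hat)
  class(fit) <- "gp_linear_fit"
  fit
}

resolve_X <- function(G) {
  X <- marker_matrix(G)
  storage.mode(X) <- "double"
  X
}

#' Bayesian ridge regression (RR-BLUP) by Gibbs sampling
#'
#' Linear model `y = mu + X beta + e` with a common Gaussian prior
#' `beta_j ~ N(0, sigma_beta2)` and scaled-inverse-chi-square priors (df 4,
#' scale 1 by default) on both variance components. The posterior mean of
#' `beta` is the BLUP of marker effects.
#'
#' @param G marker data ([genotype_matrix] or numeric matrix, no missing
#'   values).
#' @param y numeric response for the training lines.
#' @param mcmc an [mcmc_settings].
#' @param df_beta,s_beta prior degrees of freedom and scale for
#'   `sigma_beta2`.
#' @param df_e,s_e prior degrees of freedom and scale for `sigma_e2`.
#' @param intercept include the intercept `mu` (default TRUE).
#' @param fix_sigma_e2,fix_sigma_beta2 freeze a variance at this value
#'   instead of sampling it (used by the conjugate-oracle tests).
#' @return a `gp_linear_fit` with posterior means `mu_hat`, `beta_hat`,
#'   variance components, in-sample `fitted` and the `sigma_e2` trace.
#' @export
fit_brr <- function(G, y, mcmc = mcmc_settings(), df_beta = 4, s_beta = 1,
                    df_e = 4, s_e = 1, intercept = TRUE,
                    fix_sigma_e2 = NA_real_, fix_sigma_beta2 = NA_real_) {
  X <- resolve_X(G)
  check_training_data(X, y)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(mcmc$seed)
  raw <- gibbs_brr_cpp(X, y, df_beta, s_beta, df_e, s_e,
                       mcmc$n_iter, mcmc$burn_in, mcmc$thin, intercept,
                       fix_sigma_e2, fix_sigma_beta2)
  new_linear_fit("BRR", raw, X, colnames(X),
                 list(sigma_beta2_hat = raw$sigma_beta2_hat))
}

#' Bayesian LASSO by Gibbs sampling
#'
#' Double-exponential prior on marker effects implemented through the
#' normal-exponential scale mixture: `beta_j | tau_j^2 ~ N(0, tau_j^2
#' sigma_e2)`, `1/tau_j^2` inverse-Gaussian, and `lambda^2` Gamma. The
#' Gamma hyperprior on the regularization parameter defaults to shape 0.55,
#' rate 1e-4.
#'
#' @inheritParams fit_brr
#' @param lambda2_shape,lambda2_rate Gamma hyperprior on `lambda^2`.
#' @param fix_lambda2 freeze `lambda^2` (NA = sample).
#' @param fix_tau2 length-p vector freezing all mixture variances
#'   (NULL = sample).
#' @return a `gp_linear_fit` with `tau2_hat` and `lambda2_hat`.
#' @export
fit_bayesian_lasso <- function(G, y, mcmc = mcmc_settings(),
                               lambda2_shape = 0.55, lambda2_rate = 1e-4,
                               df_e = 4, s_e = 1, intercept = TRUE,
                               fix_sigma_e2 = NA_real_,
                               fix_lambda2 = NA_real_, fix_tau2 = NULL) {
  X <- resolve_X(G)
  check_training_data(X, y)
  if (is.null(fix_tau2)) fix_tau2 <- numeric(0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(mcmc$seed)
  raw <- gibbs_bl_cpp(X, y, lambda2_shape, lambda2_rate, df_e, s_e,
                      mcmc$n_iter, mcmc$burn_in, mcmc$thin, intercept,
                      fix_sigma_e2, fix_lambda2, fix_tau2)
  new_linear_fit("BL", raw, X, colnames(X),
                 list(tau2_hat = drop(raw$tau2_hat),
                      lambda2_hat = raw$lambda2_hat))
}

#' Bayes B (and Bayes A) by Gibbs sampling
#'
#' Mixture prior on marker effects: zero with probability `pi`, otherwise
#' `N(0, sigma_j2)` with marker-specific variances under a
#' scaled-inverse-chi-square prior (df `df_beta`, scale `s_beta`). The
#' inclusion indicator is sampled with the effect integrated out (exact
#' two-component Gibbs). With `pi = 0` every marker is always included and
#' the model is Bayes A; [fit_bayes_a] is that code path. The residual
#' variance uses an improper flat prior by default.
#'
#' @inheritParams fit_brr
#' @param pi prior null-effect probability, in [0, 1) (default 0.95).
#' @param s_beta scale of the marker-variance prior; if `NULL` it is
#'   derived from allele frequencies via [bayesb_scale_hyperparameter]
#'   with `sigma_S2 = 0.5 * var(y)`.
#' @param sigma_S2 additive variance attributed to markers, used only when
#'   `s_beta` is derived (default `0.5 * var(y)`).
#' @param sigma_e2_prior `"flat"` (default) or `"scaled_inv_chi2"`.
#' @param fix_sigma_beta2 length-p vector freezing the per-marker
#'   variances (NULL = sample).
#' @return a `gp_linear_fit` with `inclusion_prob` and `sigma_j2_hat`.
#' @export
fit_bayes_b <- function(G, y, mcmc = mcmc_settings(), pi = 0.95,
                        df_beta = 4, s_beta = NULL, sigma_S2 = NULL,
                        sigma_e2_prior = c("flat", "scaled_inv_chi2"),
                        df_e = 4, s_e = 1, intercept = TRUE,
                        fix_sigma_e2 = NA_real_, fix_sigma_beta2 = NULL) {
  sigma_e2_prior <- match.arg(sigma_e2_prior)
  X <- resolve_X(G)
  check_training_data(X, y)
  if (pi < 0 || pi >= 1) stop("pi must be in [0, 1)")
  if (sigma_e2_prior == "flat" && length(y) <= 4)
    stop("flat sigma_e2 prior needs more than 4 training lines")
  if (is.null(s_beta)) {
    q <- if (inherits(G, "genotype_matrix") && !is.null(G$q)) G$q
         else colMeans(X)
    q <- pmin(pmax(q, 1e-6), 1 - 1e-6)
    if (is.null(sigma_S2)) sigma_S2 <- 0.5 * var(y)
    s_beta <- bayesb_scale_hyperparameter(q, pi, df_beta, sigma_S2)
  }
  if (is.null(fix_sigma_beta2)) fix_sigma_beta2 <- numeric(0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(mcmc$seed)
  raw <- gibbs_bayesb_cpp(X, y, pi, df_beta, s_beta,
                          sigma_e2_prior == "flat", df_e, s_e,
                          mcmc$n_iter, mcmc$burn_in, mcmc$thin, intercept,
                          fix_sigma_e2, fix_sigma_beta2)
  model <- if (pi == 0) "BayesA" else "BayesB"
  new_linear_fit(model, raw, X, colnames(X),
                 list(pi = pi, s_beta = s_beta,
                      inclusion_prob = drop(raw$inclusion_prob),
                      sigma_j2_hat = drop(raw$sigma_j2_hat)))
}

#' @rdname fit_bayes_b
#' @export
fit_bayes_a <- function(G, y, mcmc = mcmc_settings(), df_beta = 4,
                        s_beta = NULL, sigma_S2 = NULL,
                        sigma_e2_prior = c("flat", "scaled_inv_chi2"),
                        df_e = 4, s_e = 1, intercept = TRUE,
                        fix_sigma_e2 = NA_real_, fix_sigma_beta2 = NULL) {
  sigma_e2_prior <- match.arg(sigma_e2_prior)
  fit_bayes_b(G, y, mcmc = mcmc, pi = 0, df_beta = df_beta, s_beta = s_beta,
              sigma_S2 = sigma_S2, sigma_e2_prior = sigma_e2_prior,
              df_e = df_e, s_e = s_e, intercept = intercept,
              fix_sigma_e2 = fix_sigma_e2, fix_sigma_beta2 = fix_sigma_beta2)
}

align_markers <- function(new_ids, fit_ids, X_new) {
  if (is.null(new_ids) || is.null(fit_ids)) return(X_new)
  missing <- setdiff(fit_ids, new_ids)
  if (length(missing) > 0)
    stop("markers absent from new data: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  X_new[, fit_ids, drop = FALSE]
}

#' Predict from a fitted linear whole-genome regression
#'
#' @param object a `gp_linear_fit`.
#' @param newdata a [genotype_matrix] or numeric matrix; columns are
#'   matched to the training markers by id when both carry ids.
#' @param ... unused.
#' @return numeric vector `mu_hat + X_new beta_hat`.
#' @export
predict.gp_linear_fit <- function(object, newdata, ...) {
  X <- resolve_X(newdata)
  X <- align_markers(colnames(X), object$marker_ids, X)
  if (ncol(X) != length(object$beta_hat))
    stop("newdata has ", ncol(X), " markers; fit used ",
         length(object$beta_hat))
  unname(drop(object$mu_hat + X %*% object$beta_hat))
}

#' @export
print.gp_linear_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d markers, sigma_e2 = %.4g, %d kept draws\n",
              x$model, length(x$beta_hat), x$sigma_e2_hat, x$n_keep))
  invisible(x)
}
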