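#' Gaussian kernel matrix
#'
#' `K[i, i'] = exp(-h * d2(i, i'))` where `d2` is the squared Euclidean
#' distance between marker rows, optionally rescaled so the bandwidth grid
#' is dimensionless: `"by_p"` divides by the number of markers,
#' `"by_median"` by the median off-diagonal squared distance of the
#' reference matrix.
#'
#' @param X numeric matrix (rows = lines) or [genotype_matrix].
#' @param X2 optional second matrix for a cross-kernel (rows of `X`
#'   against rows of `X2`); defaults to `X`.
#' @param h bandwidth (>= 0).
#' @param scaling one of `"none"`, `"by_p"`, `"by_median"`.
#' @param d2_scale explicit divisor for the squared distances; overrides
#'   `scaling`-derived values (pass the training-set value when computing
#'   cross-kernels).
#' @return kernel matrix with attribute `"d2_scale"`.
#' @export
gaussian_kernel <- function(X, X2 = NULL, h, scaling = c("by_median",
                            "none", "by_p"), d2_scale = NULL) {
  scaling <- match.arg(scaling)
  X <- marker_matrix(X)
  X2 <- if (is.null(X2)) X else marker_matrix(X2)
  if (ncol(X) != ncol(X2)) stop("column counts differ")
  if (h < 0) stop("h must be >= 0")
  d2 <- squared_distances(X, X2)
  if (is.null(d2_scale)) {
    d2_scale <- switch(scaling,
      none = 1,
      by_p = ncol(X),
      by_median = {
        ref <- if (nrow(X) == nrow(X2) && isTRUE(all.equal(X, X2)))
          d2[upper.tri(d2)] else as.vector(d2)
        m <- median(ref[ref > 0])
        if (!is.finite(m) || m <= 0) stop("all rows identical")
        m
      })
  }
  K <- exp(-h * d2 / d2_scale)
  attr(K, "d2_scale") <- d2_scale
  K
}

squared_distances <- function(X, X2) {
  s1 <- rowSums(X^2)
  s2 <- rowSums(X2^2)
  d2 <- outer(s1, s2, "+") - 2 * tcrossprod(X, X2)
  d2[d2 < 0] <- 0
  d2
}

#' Default bandwidth grid for kernel averaging
#'
#' Returns the base grid \{0.1, 0.25, 0.5, 1, 2, 5\} divided by the median
#' (scaled) squared distance between rows, so the kernels span near-1 to
#' near-0 over the observed distances.
#'
#' @param X marker matrix or [genotype_matrix].
#' @param n_points how many of the base values to use (<= 6).
#' @param scaling distance scaling, as in [gaussian_kernel].
#' @return list with `h_grid`, `scaling` and `d2_scale`.
#' @export
default_h_grid <- function(X, n_points = 6, scaling = c("by_median",
                           "none", "by_p")) {
  scaling <- match.arg(scaling)
  X <- marker_matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows")
  base <- c(0.1, 0.25, 0.5, 1, 2, 5)[seq_len(min(n_points, 6))]
  d2 <- squared_distances(X, X)
  off <- d2[upper.tri(d2)]
  if (all(off <= 0)) stop("all rows identical")
  d2_scale <- switch(scaling, none = 1, by_p = ncol(X),
                     by_median = median(off[off > 0]))
  med <- median(off[off > 0]) / d2_scale
  list(h_grid = base / med, scaling = scaling, d2_scale = d2_scale)
}

#' Kernel-averaging RKHS regression by Gibbs sampling
#'
#' Bayesian model `y = mu + sum_k u_k + e` with `u_k ~ N(0, sigma_k2 K_k)`,
#' one Gaussian kernel per bandwidth in the grid. Each kernel's random
#' effect is sampled in its eigenbasis; variance components get
#' scaled-inverse-chi-square updates. The posterior variance shares weight
#' the kernels ("kernel averaging").
#'
#' @param G training markers ([genotype_matrix] or matrix, no missing
#'   values).
#' @param y numeric response.
#' @param h_grid candidate bandwidths; default from [default_h_grid].
#' @param scaling distance scaling for [gaussian_kernel].
#' @param kernels optional list of precomputed n x n kernel matrices;
#'   overrides `h_grid` (predictions then require explicit cross-kernels).
#' @param mcmc an [mcmc_settings].
#' @param df_k,s_k prior df and scale for each `sigma_k2`.
#' @param df_e,s_e prior df and scale for `sigma_e2`.
#' @param intercept include `mu`.
#' @param fix_sigma_e2 freeze the residual variance (NA = sample).
#' @param fix_sigma_k2 length-K vector freezing kernel variances
#'   (NULL = sample).
#' @param eig_tol relative eigenvalue truncation threshold.
#' @return a `gp_rkhs_fit` with `mu_hat`, per-kernel `u_hat` and
#'   `alpha_hat` (n x K), `sigma_k2_hat`, the realized per-kernel
#'   `genetic_var` (posterior mean of var(u_k), whose normalized version
#'   `variance_share` weights the kernels), `sigma_e2_hat`, `fitted`.
#' @export
fit_rkhs <- function(G, y, h_grid = NULL, scaling = "by_median",
                     kernels = NULL, mcmc = mcmc_settings(),
                     df_k = 4, s_k = 1, df_e = 4, s_e = 1,
                     intercept = TRUE, fix_sigma_e2 = NA_real_,
                     fix_sigma_k2 = NULL, eig_tol = 1e-10) {
  scaling <- match.arg(scaling, c("by_median", "none", "by_p"))
  X <- resolve_X(G)
  check_training_data(X, y)
  d2_scale <- NULL
  if (is.null(kernels)) {
    if (is.null(h_grid)) {
      gd <- default_h_grid(X, scaling = scaling)
      h_grid <- gd$h_grid
      d2_scale <- gd$d2_scale
    } else {
      h_grid <- as.numeric(h_grid)
      if (length(h_grid) == 0 || any(h_grid <= 0))
        stop("h_grid must be nonempty and strictly positive")
    }
    d2 <- squared_distances(X, X)
    if (is.null(d2_scale)) {
      off <- d2[upper.tri(d2)]
      if (all(off <= 0)) stop("all rows identical")
      d2_scale <- switch(scaling, none = 1, by_p = ncol(X),
                         by_median = median(off[off > 0]))
    }
    kernels <- lapply(h_grid, function(h) exp(-h * d2 / d2_scale))
    custom <- FALSE
  } else {
    custom <- TRUE
    h_grid <- rep(NA_real_, length(kernels))
  }
  K_n <- length(kernels)
  U_list <- vector("list", K_n)
  d_list <- vector("list", K_n)
  for (k in seq_len(K_n)) {
    Kk <- kernels[[k]]
    if (!isTRUE(all.equal(Kk, t(Kk), tolerance = 1e-8)))
      stop("kernel ", k, " is not symmetric")
    eg <- eigen((Kk + t(Kk)) / 2, symmetric = TRUE)
    lmax <- max(eg$values)
    if (min(eg$values) < -1e-8 * lmax)
      stop("kernel ", k, " is not positive semi-definite")
    keep <- eg$values > eig_tol * lmax
    U_list[[k]] <- eg$vectors[, keep, drop = FALSE]
    d_list[[k]] <- eg$values[keep]
  }
  if (is.null(fix_sigma_k2)) fix_sigma_k2 <- numeric(0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(mcmc$seed)
  raw <- gibbs_rkhs_cpp(U_list, d_list, y, df_k, s_k, df_e, s_e,
                        mcmc$n_iter, mcmc$burn_in, mcmc$thin, intercept,
                        fix_sigma_e2, fix_sigma_k2)
  u_hat <- matrix(0, nrow(X), K_n)
  alpha_hat <- matrix(0, nrow(X), K_n)
  for (k in seq_len(K_n)) {
    db <- raw$delta_hat[[k]]
    u_hat[, k] <- U_list[[k]] %*% db
    alpha_hat[, k] <- U_list[[k]] %*% (db / d_list[[k]])
  }
  fit <- list(
    model = "RKHS",
    mu_hat = raw$mu_hat,
    u_hat = u_hat,
    alpha_hat = alpha_hat,
    sigma_k2_hat = drop(raw$sigma_k2_hat),
    genetic_var = drop(raw$genetic_var),
    variance_share = drop(raw$genetic_var) / sum(raw$genetic_var),
    sigma_e2_hat = raw$sigma_e2_hat,
    sigma_e2_trace = drop(raw$sigma_e2_trace),
    h_grid = h_grid, scaling = scaling, d2_scale = d2_scale,
    custom_kernels = custom,
    X_train = if (custom) NULL else X,
    marker_ids = colnames(X),
    fitted = drop(raw$mu_hat + rowSums(u_hat)),
    n_keep = raw$n_keep)
  class(fit) <- "gp_rkhs_fit"
  fit
}

#' Predict from a fitted RKHS regression
#'
#' `yhat = mu_hat + sum_k K_k(X_new, X_train) alpha_k`, with the
#' cross-kernels built at the training bandwidths and distance scale.
#'
#' @param object a `gp_rkhs_fit`.
#' @param newdata new marker data (matched to training marker ids).
#' @param K_new list of cross-kernel matrices (rows = new lines, columns =
#'   training lines); required when the fit used custom kernels.
#' @param ... unused.
#' @return numeric prediction vector.
#' @export
predict.gp_rkhs_fit <- function(object, newdata = NULL, K_new = NULL, ...) {
  K_n <- ncol(object$u_hat)
  if (is.null(K_new)) {
    if (object$custom_kernels)
      stop("fit used custom kernels; supply K_new")
    X <- resolve_X(newdata)
    X <- align_markers(colnames(X), object$marker_ids, X)
    K_new <- lapply(object$h_grid, function(h)
      gaussian_kernel(X, object$X_train, h = h,
                      scaling = object$scaling,
                      d2_scale = object$d2_scale))
  }
  if (length(K_new) != K_n) stop("need one cross-kernel per fitted kernel")
  yhat <- rep(object$mu_hat, nrow(K_new[[1]]))
  for (k in seq_len(K_n))
    yhat <- yhat + drop(K_new[[k]] %*% object$alpha_hat[, k])
  yhat
}

#' @export
print.gp_rkhs_fit <- function(x, ...) {
  cat(sprintf("RKHS fit: %d kernel(s), sigma_e2 = %.4g\n",
              ncol(x$u_hat), x$sigma_e2_hat))
  if (!x$custom_kernels)
    cat("  h grid:", paste(signif(x$h_grid, 4), collapse = ", "), "\n")
  cat("  variance shares:",
      paste(signif(x$variance_share, 3), collapse = ", "), "\n")
  invisible(x)
}
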