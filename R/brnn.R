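#' Bayesian-regularized single-hidden-layer network (evidence framework)
#'
#' Trains a single-hidden-layer network with tanh activation by the
#' empirical-Bayes (evidence) procedure: for fixed regularization weights
#' it minimizes the penalized sum of squares
#' `F(theta) = beta * sum(e^2) + alpha * sum(theta^2)` over all weights,
#' biases and connection strengths by Levenberg-Marquardt, then updates
#' `alpha` and `beta` from the evidence approximation using the effective
#' number of parameters `gamma = sum(lambda_i / (lambda_i + alpha))`
#' (eigenvalues `lambda_i` of `beta * J'J`), i.e.
#' `alpha <- gamma / (2 sum(theta^2))`, `beta <- (n - gamma) / (2 sum(e^2))`,
#' and iterates the two steps to convergence. `alpha = 1/(2 sigma_theta2)`
#' and `beta = 1/(2 sigma_e2)`.
#'
#' Inputs are standardized internally and the response is centered; the
#' grouped inverse-gamma prior constants for the residual variance
#' (scale 0.05, df 0.5) and for the connection strengths
#' (scale `(0.05 / p^(1/0.5))^2`, df 0.5) are carried as configuration
#' metadata and seed the initial `(alpha, beta)`.
#'
#' @param X training marker matrix or [genotype_matrix].
#' @param y numeric response.
#' @param neurons number of hidden neurons S (default 2).
#' @param max_iter maximum outer evidence iterations (default 50).
#' @param tol relative change in F declaring convergence (default 1e-6).
#' @param restarts random restarts, best final F kept (default 5).
#' @param seed integer seed.
#' @param fix_alpha,fix_beta freeze a regularization weight instead of
#'   updating it (NA = update); `fix_alpha = 0` gives the unpenalized fit.
#' @param max_inner maximum Levenberg-Marquardt steps per outer iteration.
#' @return a `gp_brnn_network` with the unpacked parameters (`weights`,
#'   `biases`, `strengths`, `mu`), `alpha`, `beta_reg`, `sigma_theta2`,
#'   `sigma_e2`, `gamma`, `gamma_history`, `F_history`, `train_mse`.
#' @export
train_brnn <- function(X, y, neurons = 2, max_iter = 50, tol = 1e-6,
                       restarts = 5, seed = 1L,
                       fix_alpha = NA_real_, fix_beta = NA_real_,
                       max_inner = 200) {
  X <- resolve_X(X)
  check_training_data(X, y)
  S <- as.integer(neurons)
  if (S < 1) stop("neurons must be >= 1")
  n <- nrow(X); p <- ncol(X)
  m <- S * (p + 2) + 1

  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  y_center <- mean(y)
  yc <- y - y_center

  group_priors <- list(s_e = 0.05, df_e = 0.5,
                       s_u = (0.05 / p^(1 / 0.5))^2, df_u = 0.5)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  unpack <- function(th) {
    # strengths are packed neuron-by-neuron: theta[2S + (k-1)p + j] = B[k, j]
    list(w = th[1:S], b = th[S + (1:S)],
         B = matrix(th[2 * S + seq_len(S * p)], S, p, byrow = TRUE),
         mu = th[m])
  }
  forward <- function(th) {
    pr <- unpack(th)
    U <- sweep(Xs %*% t(pr$B), 2, pr$b, "+")     # n x S pre-activations
    Z <- tanh(U)
    f <- drop(pr$mu + Z %*% pr$w)
    list(f = f, Z = Z, pr = pr)
  }
  jacobian <- function(fw) {
    dZ <- (1 - fw$Z^2) * rep(fw$pr$w, each = n)  # n x S
    J <- matrix(0, n, m)
    J[, 1:S] <- fw$Z
    J[, S + (1:S)] <- dZ
    for (k in seq_len(S))
      J[, 2 * S + (k - 1) * p + seq_len(p)] <- dZ[, k] * Xs
    J[, m] <- 1
    J
  }
  obj <- function(th, a, b) {
    fw <- forward(th)
    e <- yc - fw$f
    b * sum(e^2) + a * sum(th^2)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    # Nguyen-Widrow-style scaled random initialization
    sc <- 0.7 * S^(1 / p)
    B <- matrix(runif(S * p, -1, 1), S, p)
    B <- B * sc / pmax(sqrt(rowSums(B^2)), 1e-8)
    th <- c(runif(S, -0.5, 0.5), runif(S, -sc, sc), as.vector(t(B)), 0)

    alpha <- if (is.na(fix_alpha)) 1 / (2 * group_priors$s_e) else fix_alpha
    beta <- if (is.na(fix_beta)) 1 / (2 * group_priors$s_e) else fix_beta
    F_hist <- numeric(0)
    g_hist <- numeric(0)
    gamma <- NA_real_
    F_prev <- Inf
    for (it in seq_len(max_iter)) {
      # (1) minimize F(theta) at the current (alpha, beta) by
      # Levenberg-Marquardt with the standard damping schedule
      lm_mu <- 1e-2
      F_cur <- obj(th, alpha, beta)
      for (inner in seq_len(max_inner)) {
        fw <- forward(th)
        e <- yc - fw$f
        J <- jacobian(fw)
        gvec <- -2 * beta * drop(crossprod(J, e)) + 2 * alpha * th
        H <- 2 * beta * crossprod(J) + diag(2 * alpha, m)
        step_ok <- FALSE
        while (lm_mu <= 1e12) {
          st <- tryCatch(solve(H + diag(lm_mu, m), -gvec),
                         error = function(cond) NULL)
          if (!is.null(st)) {
            F_new <- obj(th + st, alpha, beta)
            if (is.finite(F_new) && F_new < F_cur) {
              rel <- (F_cur - F_new) / max(F_cur, 1e-300)
              th <- th + st
              F_cur <- F_new
              lm_mu <- max(lm_mu / 10, 1e-12)
              step_ok <- TRUE
              if (rel < 1e-12) step_ok <- FALSE  # converged
              break
            }
          }
          lm_mu <- lm_mu * 10
        }
        if (!step_ok) break
      }
      # (2) evidence update of (alpha, beta)
      fw <- forward(th)
      e <- yc - fw$f
      J <- jacobian(fw)
      ev <- eigen(crossprod(J), symmetric = TRUE, only.values = TRUE)$values
      ev[ev < 0] <- 0
      gamma <- sum(beta * ev / (beta * ev + alpha))
      if (is.na(fix_alpha))
        alpha <- gamma / max(2 * sum(th^2), 1e-10)
      if (is.na(fix_beta))
        beta <- max(n - gamma, 1e-8) / max(2 * sum(e^2), 1e-10)
      F_cur <- obj(th, alpha, beta)
      if (!is.finite(F_cur)) stop("non-finite objective in BRNN training")
      F_hist <- c(F_hist, F_cur)
      g_hist <- c(g_hist, gamma)
      if (abs(F_prev - F_cur) / max(abs(F_cur), 1e-12) < tol) break
      F_prev <- F_cur
    }
    fw <- forward(th)
    mse <- mean((yc - fw$f)^2)
    cand <- list(theta = th, alpha = alpha, beta_reg = beta,
                 gamma = gamma, F_history = F_hist,
                 gamma_history = g_hist, F_final = F_cur,
                 train_mse = mse, restart = r)
    if (is.null(best) || cand$F_final < best$F_final) best <- cand
  }

  pr <- unpack(best$theta)
  structure(list(
    model = "BRNN", S = S, m = m,
    weights = pr$w, biases = pr$b, strengths = pr$B, mu = pr$mu,
    alpha = best$alpha, beta_reg = best$beta_reg,
    sigma_theta2 = 1 / (2 * max(best$alpha, 1e-300)),
    sigma_e2 = 1 / (2 * best$beta_reg),
    gamma = best$gamma,
    F_history = best$F_history, gamma_history = best$gamma_history,
    train_mse = best$train_mse, restart = best$restart,
    group_priors = group_priors,
    x_center = ctr, x_scale = scl, y_center = y_center,
    marker_ids = colnames(X), theta = best$theta),
    class = "gp_brnn_network")
}

#' Predict from a Bayesian-regularized network
#'
#' @param object a `gp_brnn_network`.
#' @param newdata new marker data (standardized with the training
#'   center/scale).
#' @param ... unused.
#' @return numeric prediction vector.
#' @export
predict.gp_brnn_network <- function(object, newdata, ...) {
  X <- resolve_X(newdata)
  X <- align_markers(colnames(X), object$marker_ids, X)
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  U <- sweep(Xs %*% t(object$strengths), 2, object$biases, "+")
  drop(object$y_center + object$mu + tanh(U) %*% object$weights)
}

#' @export
print.gp_brnn_network <- function(x, ...) {
  cat(sprintf(
    "BRNN: %d neurons (%d parameters), alpha = %.4g, beta = %.4g, gamma = %.3g\n",
    x$S, x$m, x$alpha, x$beta_reg, x$gamma))
  invisible(x)
}
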