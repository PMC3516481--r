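#' Bandwidth of a Gaussian radial basis unit from the spread parameter
#'
#' `h = (0.8326 / spread)^2`, so that a unit's response falls to 0.5 at a
#' Euclidean distance equal to `spread` from its center.
#'
#' @param spread positive design parameter of the network.
#' @return the bandwidth `h`.
#' @export
rbf_bandwidth <- function(spread) {
  if (any(spread <= 0)) stop("spread must be > 0")
  (0.8326 / spread)^2
}

#' Orthogonal least-squares center selection for an RBF network
#'
#' Greedy forward selection of hidden-unit centers from the training
#' inputs. At each step every remaining candidate's Gaussian basis column
#' is orthogonalized against the selected set and the candidate with the
#' largest error-reduction ratio is added; ties go to the lowest candidate
#' index. Selection stops when the training mean-squared error reaches
#' `goal` or `S_max` centers are in the net. Output weights and the
#' intercept are then refit by ordinary least squares on the selected
#' basis columns.
#'
#' @param X training marker matrix (rows = lines) or [genotype_matrix].
#' @param y numeric response.
#' @param h Gaussian bandwidth (see [rbf_bandwidth]).
#' @param goal target training MSE (absolute, same units as `var(y)`).
#' @param S_max maximum number of centers (default `nrow(X)`).
#' @return a `gp_rbf_network` with `centers`, `center_idx`, `weights`,
#'   `intercept`, `h`, `S`, `train_mse` and the selection `mse_path`.
#' @export
ols_select_centers <- function(X, y, h, goal = 0, S_max = NULL) {
  X <- resolve_X(X)
  if (anyNA(X)) stop("marker matrix has missing values; impute first")
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (is.null(S_max)) S_max <- n
  S_max <- min(S_max, n)
  mu <- mean(y)
  yres <- y - mu
  yy <- sum(yres^2)
  sel <- integer(0)
  mse_path <- numeric(0)
  if (yy > 1e-24) {
    Phi <- exp(-h * squared_distances(X, X))
    W <- sweep(Phi, 2, colMeans(Phi))  # intercept handled by centering
    norm0 <- pmax(colSums(W^2), 1e-300)
    alive <- rep(TRUE, n)
    for (s in seq_len(S_max)) {
      den <- colSums(W^2)
      ok <- alive & den > 1e-12 * norm0
      if (!any(ok)) {
        if (length(sel) == 0) stop("all candidate columns degenerate")
        break
      }
      num <- drop(crossprod(W, yres))^2
      ratio <- ifelse(ok, num / (den * yy), -Inf)
      k <- which.max(ratio)
      q <- W[, k] / sqrt(den[k])
      yres <- yres - q * sum(q * yres)
      W <- W - q %*% crossprod(q, W)
      alive[k] <- FALSE
      sel <- c(sel, k)
      mse <- sum(yres^2) / n
      mse_path <- c(mse_path, mse)
      if (mse <= goal) break
    }
    # refit weights by least squares on the selected raw columns
    A <- cbind(1, Phi[, sel, drop = FALSE])
    cf <- qr.coef(qr(A), y)
    cf[is.na(cf)] <- 0
    mu <- cf[1]
    w <- cf[-1]
    fitted <- drop(A %*% cf)
  } else {
    w <- numeric(0)
    fitted <- rep(mu, n)
  }
  structure(list(
    model = "RBFNN",
    centers = X[sel, , drop = FALSE],
    center_idx = sel,
    h = h, goal = goal, S = length(sel),
    weights = unname(w), intercept = unname(mu),
    marker_ids = colnames(X),
    train_mse = mean((y - fitted)^2),
    mse_path = mse_path,
    fitted = fitted), class = "gp_rbf_network")
}

#' Train an RBF network over a spread x goal grid
#'
#' Builds the grid from the median pairwise Euclidean distance of the
#' training inputs (spread axis) and from fractions of `var(y)` (goal
#' axis), runs [ols_select_centers] for every cell, scores each net on an
#' internal 80/20 tuning split of the training data, and refits the
#' winning cell on the full training set. The tuning split never touches
#' any outer validation data.
#'
#' @param X training marker matrix or [genotype_matrix].
#' @param y numeric response.
#' @param spread_multipliers multipliers of the median pairwise distance
#'   forming the spread axis (default 0.5, 1, 2).
#' @param goal_fractions fractions of `var(y)` forming the goal axis
#'   (default 0.02, 0.1).
#' @param spread_values,goal_values explicit axes; override the derived
#'   ones.
#' @param S_max maximum number of centers.
#' @param tune_fraction held-out fraction of the training data used to
#'   pick the grid winner (default 0.2).
#' @param seed integer seed for the tuning split.
#' @return a `gp_rbf_network` (refit on all of `X`) with `spread`,
#'   `grid` (per-cell tuning MSE) attached.
#' @export
train_rbfnn <- function(X, y, spread_multipliers = c(0.5, 1, 2),
                        goal_fractions = c(0.02, 0.1),
                        spread_values = NULL, goal_values = NULL,
                        S_max = NULL, tune_fraction = 0.2, seed = 1L) {
  X <- resolve_X(X)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (is.null(spread_values)) {
    d2 <- squared_distances(X, X)
    med <- median(sqrt(d2[upper.tri(d2)]))
    if (!is.finite(med) || med <= 0) stop("degenerate input distances")
    spread_values <- med * spread_multipliers
  }
  if (is.null(goal_values)) goal_values <- var(y) * goal_fractions
  grid <- expand.grid(spread = spread_values, goal = goal_values)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (nrow(grid) > 1) {
    tune <- sort(sample.int(n, max(2, round(tune_fraction * n))))
    core <- setdiff(seq_len(n), tune)
    grid$tune_mse <- vapply(seq_len(nrow(grid)), function(i) {
      net <- ols_select_centers(X[core, , drop = FALSE], y[core],
                                h = rbf_bandwidth(grid$spread[i]),
                                goal = grid$goal[i], S_max = S_max)
      mean((y[tune] - predict(net, X[tune, , drop = FALSE]))^2)
    }, numeric(1))
    best <- which.min(grid$tune_mse)
  } else {
    grid$tune_mse <- NA_real_
    best <- 1L
  }
  net <- ols_select_centers(X, y, h = rbf_bandwidth(grid$spread[best]),
                            goal = grid$goal[best], S_max = S_max)
  net$spread <- grid$spread[best]
  net$grid <- grid
  net
}

#' Predict from an RBF network
#'
#' @param object a `gp_rbf_network`.
#' @param newdata new marker data.
#' @param ... unused.
#' @return `intercept + sum_k w_k exp(-h ||x - c_k||^2)`.
#' @export
predict.gp_rbf_network <- function(object, newdata, ...) {
  X <- resolve_X(newdata)
  X <- align_markers(colnames(X), object$marker_ids, X)
  if (object$S == 0) return(rep(object$intercept, nrow(X)))
  Z <- exp(-object$h * squared_distances(X, object$centers))
  drop(object$intercept + Z %*% object$weights)
}

#' @export
print.gp_rbf_network <- function(x, ...) {
  cat(sprintf("RBF network: %d centers, h = %.4g, training MSE = %.4g\n",
              x$S, x$h, x$train_mse))
  invisible(x)
}
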