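#' Simulate a binary dominant marker matrix
#'
#' Each marker j draws an allele frequency q_j ~ Uniform(maf_range) and
#' line calls i.i.d. Bernoulli(q_j). An optional block mode gives markers
#' within a block a shared latent Gaussian factor (a crude stand-in for
#' linkage disequilibrium) while preserving the Bernoulli(q_j) margins.
#'
#' @param n number of lines.
#' @param p number of markers.
#' @param maf_range length-2 numeric, 0 < low <= high <= 0.5.
#' @param seed integer seed.
#' @param block_size optional block length for the latent-factor LD mode
#'   (and the haplotype-block length of the founder mode).
#' @param block_rho latent within-block correlation (default 0.8).
#' @param n_founders optional number of founder haplotypes. When set,
#'   each line is a block-wise mosaic of the founders, giving both
#'   linkage disequilibrium and relatedness between lines, as in an elite
#'   breeding panel; `block_size` (default 20) sets the haplotype-block
#'   length.
#' @return a [genotype_matrix] of 0/1 calls.
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.05, 0.5), seed = 1L,
                               block_size = NULL, block_rho = 0.8,
                               n_founders = NULL) {
  if (length(maf_range) != 2 || maf_range[1] <= 0 ||
      maf_range[1] > maf_range[2] || maf_range[2] > 0.5)
    stop("maf_range must satisfy 0 < low <= high <= 0.5")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  q <- runif(p, maf_range[1], maf_range[2])
  if (!is.null(n_founders)) {
    if (n_founders < 2) stop("n_founders must be >= 2")
    if (is.null(block_size)) block_size <- 20
    Fh <- matrix(rbinom(n_founders * p, 1, rep(q, each = n_founders)),
                 n_founders, p)
    X <- matrix(0, n, p)
    blocks <- split(seq_len(p), ceiling(seq_len(p) / block_size))
    for (b in blocks) {
      src <- sample.int(n_founders, n, replace = TRUE)
      X[, b] <- Fh[src, b, drop = FALSE]
    }
  } else if (is.null(block_size)) {
    X <- matrix(rbinom(n * p, 1, rep(q, each = n)), n, p)
  } else {
    X <- matrix(0, n, p)
    blocks <- split(seq_len(p), ceiling(seq_len(p) / block_size))
    for (b in blocks) {
      z <- rnorm(n)
      for (j in b) {
        u <- sqrt(block_rho) * z + sqrt(1 - block_rho) * rnorm(n)
        X[, j] <- as.numeric(u < stats::qnorm(q[j]))
      }
    }
  }
  genotype_matrix(X, paste0("L", seq_len(n)), paste0("M", seq_len(p)))
}

#' Simulate multi-environment phenotypes with additive and epistatic
#' architecture
#'
#' Builds a true genetic value per line and environment as the sum of an
#' additive component (a sparse set of QTL markers with sampled effects)
#' and an epistatic component (pairwise products of raw 0/1 marker codes).
#' The epistatic component is residualized against the intercept and the
#' additive design spanned by all markers involved, so the two components
#' are exactly orthogonal in-sample and `prop_epistasis` is the exact
#' in-sample share of genetic variance. Residual noise is then added so
#' that var(g)/var(y) targets `h2_target` per environment. Genetic values
#' across environments are correlated at `env_corr` by mixing a common and
#' an environment-specific effect vector.
#'
#' @param G a [genotype_matrix] with no missing values (see
#'   [impute_genotypes]).
#' @param n_qtl number of markers with additive effects.
#' @param n_pairs number of marker pairs with multiplicative effects.
#' @param h2_target target broad-sense heritability in [0, 1].
#' @param prop_epistasis share of genetic variance from interactions,
#'   in [0, 1].
#' @param n_env number of environments.
#' @param env_corr genetic correlation across environments, in [0, 1].
#' @param seed integer seed.
#' @param effect_dist `"normal"` (default) or `"laplace"` effect draws.
#' @param pairs_from `"qtl"` (default) draws interacting pairs among the
#'   QTL — epistasis between trait loci, as in the gene networks
#'   regulating heading time — while `"all"` draws them from every
#'   marker.
#' @return a `sim_result` list: `G`, `additive_effects` (p x n_env, zero
#'   off the QTL), `epistatic_effects` (pair table plus per-environment
#'   effects), `g`, `y` (n x n_env), `epsilon`, `sigma_e2`, `realized_h2`.
#' @export
simulate_trait <- function(G, n_qtl = 30, n_pairs = 30, h2_target = 0.6,
                           prop_epistasis = 0, n_env = 1, env_corr = 0.5,
                           seed = 1L, effect_dist = c("normal", "laplace"),
                           pairs_from = c("qtl", "all")) {
  effect_dist <- match.arg(effect_dist)
  pairs_from <- match.arg(pairs_from)
  X <- marker_matrix(G)
  if (anyNA(X)) stop("genotypes contain missing values; impute first")
  n <- nrow(X); p <- ncol(X)
  if (h2_target < 0 || h2_target > 1) stop("h2_target must be in [0, 1]")
  if (prop_epistasis < 0 || prop_epistasis > 1)
    stop("prop_epistasis must be in [0, 1]")
  if (env_corr < 0 || env_corr > 1) stop("env_corr must be in [0, 1]")
  if (h2_target == 0 && prop_epistasis > 0)
    stop("h2_target = 0 leaves no genetic variance to apportion")
  if (n_qtl > p) stop("n_qtl exceeds number of markers")
  pool_size <- if (pairs_from == "qtl") n_qtl else p
  if (n_pairs > pool_size * (pool_size - 1) / 2)
    stop("n_pairs exceeds available pairs")

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  rdraw <- function(k) {
    if (effect_dist == "normal") rnorm(k)
    else stats::rexp(k) * sample(c(-1, 1), k, replace = TRUE) / sqrt(2)
  }

  qtl <- sort(sample.int(p, n_qtl))
  pool <- if (pairs_from == "qtl") qtl else seq_len(p)
  pairs <- matrix(0L, 0, 2)
  if (n_pairs > 0) {
    seen <- character(0)
    while (nrow(pairs) < n_pairs) {
      cand <- sort(sample(pool, 2))
      key <- paste(cand, collapse = ":")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        pairs <- rbind(pairs, cand)
      }
    }
  }
  active <- sort(unique(c(qtl, as.integer(pairs))))
  # residualization basis: intercept + the additive design of the loci the
  # architecture touches, so epistatic products are invisible to additive
  # fits on those loci; when that design approaches full row rank the
  # residual would collapse, so fall back to the QTL columns only
  if (length(active) < 0.8 * n) {
    Xa <- X[, active, drop = FALSE]
  } else {
    Xa <- X[, qtl[seq_len(min(n_qtl, floor(0.8 * n)))], drop = FALSE]
  }
  P <- if (n_pairs > 0)
    X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
  else matrix(0, n, 0)

  beta0 <- rdraw(n_qtl)
  eff0 <- rdraw(n_pairs)

  g <- matrix(0, n, n_env)
  y <- matrix(0, n, n_env)
  eps <- matrix(0, n, n_env)
  add_eff <- matrix(0, p, n_env)
  epi_eff <- matrix(0, max(n_pairs, 1), n_env)
  sigma_e2 <- numeric(n_env)
  realized_h2 <- numeric(n_env)

  for (e in seq_len(n_env)) {
    beta_e <- sqrt(env_corr) * beta0 + sqrt(1 - env_corr) * rdraw(n_qtl)
    eff_e <- if (n_pairs > 0)
      sqrt(env_corr) * eff0 + sqrt(1 - env_corr) * rdraw(n_pairs)
    else numeric(0)

    if (h2_target == 0) {
      sigma_e2[e] <- 1
      eps[, e] <- rnorm(n, 0, 1)
      y[, e] <- eps[, e]
      realized_h2[e] <- 0
      next
    }

    a <- drop(X[, qtl, drop = FALSE] %*% beta_e)
    a <- a - mean(a)
    s_add <- 0
    if (prop_epistasis < 1) {
      va <- sum(a^2) / (n - 1)
      if (va < 1e-12) stop("degenerate additive component (no variance)")
      s_add <- sqrt((1 - prop_epistasis) / va)
    }
    epi <- numeric(n)
    s_epi <- 0
    if (prop_epistasis > 0 && n_pairs > 0) {
      raw <- drop(P %*% eff_e)
      # a is included explicitly so orthogonality to the additive
      # component is exact even under the truncated fallback basis
      epi <- qr.resid(qr(cbind(1, a, Xa)), raw)
      ve <- sum(epi^2) / (n - 1)
      if (ve < 1e-12) stop("degenerate epistatic component (no variance)")
      s_epi <- sqrt(prop_epistasis / ve)
    } else if (prop_epistasis > 0 && n_pairs == 0) {
      stop("prop_epistasis > 0 requires n_pairs > 0")
    }
    g[, e] <- s_add * a + s_epi * epi
    add_eff[qtl, e] <- s_add * beta_e
    if (n_pairs > 0) epi_eff[seq_len(n_pairs), e] <- s_epi * eff_e

    vg <- sum(g[, e]^2) / (n - 1)   # = 1 by construction
    sigma_e2[e] <- if (h2_target == 1) 0 else vg * (1 - h2_target) / h2_target
    eps[, e] <- if (h2_target == 1) rep(0, n) else rnorm(n, 0, sqrt(sigma_e2[e]))
    y[, e] <- g[, e] + eps[, e]
    realized_h2[e] <- vg / (sum((y[, e] - mean(y[, e]))^2) / (n - 1))
  }
  colnames(y) <- colnames(g) <- paste0("E", seq_len(n_env))
  rownames(y) <- rownames(g) <- G$line_ids
  structure(list(
    G = G, qtl = qtl,
    additive_effects = add_eff,
    epistatic_effects = list(
      pairs = if (n_pairs > 0)
        data.frame(j = pairs[, 1], k = pairs[, 2]) else
        data.frame(j = integer(0), k = integer(0)),
      effects = if (n_pairs > 0) epi_eff[seq_len(n_pairs), , drop = FALSE]
        else matrix(0, 0, n_env)),
    g = g, y = y, epsilon = eps, sigma_e2 = sigma_e2,
    realized_h2 = realized_h2, h2_target = h2_target,
    prop_epistasis = prop_epistasis, env_corr = env_corr, seed = seed),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "sim_result: %d lines, %d envs, target h2 %.2f (realized %s), %.0f%% epistatic\n",
    nrow(x$y), ncol(x$y), x$h2_target,
    paste(sprintf("%.2f", x$realized_h2), collapse = "/"),
    100 * x$prop_epistasis))
  invisible(x)
}

#' Flatten a simulation into a long phenotype table
#'
#' @param sim a `sim_result`.
#' @param trait trait label to use (default "SIM").
#' @return data.frame with columns line_id, env, trait, value.
#' @export
as_phenotype_table <- function(sim, trait = "SIM") {
  stopifnot(inherits(sim, "sim_result"))
  n_env <- ncol(sim$y)
  data.frame(
    line_id = rep(rownames(sim$y), n_env),
    env = rep(colnames(sim$y), each = nrow(sim$y)),
    trait = trait,
    value = as.vector(sim$y),
    stringsAsFactors = FALSE)
}
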