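# Shared fixtures and independent oracles used across test files.

# small binary genotype fixture with ids
make_geno <- function(n, p, seed = 1, maf = c(0.2, 0.5), ...) {
  simulate_genotypes(n, p, maf_range = maf, seed = seed, ...)
}

# closed-form (generalized) ridge solution, the conjugate oracle:
# beta = (X'X + sigma_e2 * D^-1)^-1 X'y, D = diag(prior variances)
ridge_oracle <- function(X, y, sigma_e2, prior_var) {
  p <- ncol(X)
  if (length(prior_var) == 1) prior_var <- rep(prior_var, p)
  solve(crossprod(X) + diag(sigma_e2 / prior_var, p), crossprod(X, y))
}

# standardized small regression fixture (columns scaled, y centered)
make_std_fixture <- function(n = 20, p = 5, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  beta <- rnorm(p)
  y <- drop(X %*% beta + rnorm(n, 0, 0.5))
  y <- y - mean(y)
  list(X = X, y = y, beta = beta)
}

# the biparental benchmark world used by the headline qualitative tests
benchmark_sim <- function(rep_seed, prop_epistasis, n = 306, p = 500) {
  G <- impute_genotypes(simulate_genotypes(n, p, seed = rep_seed,
                                           n_founders = 2))
  sim <- simulate_trait(G, n_qtl = 30, n_pairs = 200,
                        h2_target = 0.6, prop_epistasis = prop_epistasis,
                        n_env = 1, seed = rep_seed + 1000L)
  list(G = G, y = sim$y[, 1], sim = sim)
}
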