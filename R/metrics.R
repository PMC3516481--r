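#' Pearson product-moment correlation
#'
#' Returns `NA` (with a warning) when either vector is constant, so a
#' degenerate validation fold is recorded as missing rather than crashing
#' a cross-validation run.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1], or `NA_real_` for constant input.
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (anyNA(a) || anyNA(b)) stop("missing values")
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant input: correlation undefined")
    return(NA_real_)
  }
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

#' Predictive mean-squared error
#'
#' @param obs,pred numeric vectors of equal length.
#' @return mean of squared differences.
#' @export
pmse <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("length mismatch")
  if (length(obs) < 1) stop("empty input")
  mean((obs - pred)^2)
}

#' Paired t-test on per-partition correlations
#'
#' Tests the mean of the per-partition differences `corr_a - corr_b`
#' against zero with a two-sided t-test on n-1 degrees of freedom. The
#' same partitions must underlie both vectors. Pairs with a missing value
#' in either vector are dropped. Zero-variance differences return p = 1
#' and are flagged.
#'
#' @param corr_a,corr_b per-partition metric vectors of equal length.
#' @param alpha significance level (default 0.05).
#' @return list with `t`, `df`, `p`, `significant`, `mean_diff`,
#'   `n_used`, `degenerate`.
#' @export
paired_t_test <- function(corr_a, corr_b, alpha = 0.05) {
  if (length(corr_a) != length(corr_b)) stop("length mismatch")
  keep <- !is.na(corr_a) & !is.na(corr_b)
  d <- corr_a[keep] - corr_b[keep]
  if (length(d) < 3) stop("need at least 3 complete pairs")
  md <- mean(d)
  sdd <- sd(d)
  if (sdd == 0) {
    return(list(t = NA_real_, df = length(d) - 1, p = 1,
                significant = FALSE, mean_diff = md,
                n_used = length(d), degenerate = TRUE))
  }
  tt <- md / (sdd / sqrt(length(d)))
  p <- 2 * pt(abs(tt), df = length(d) - 1, lower.tail = FALSE)
  list(t = tt, df = length(d) - 1, p = p, significant = p < alpha,
       mean_diff = md, n_used = length(d), degenerate = FALSE)
}

#' Broad-sense heritability in a single environment
#'
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2 / nreps)` on an entry-mean basis.
#'
#' @param sigma_g2 genotypic variance component (>= 0).
#' @param sigma_e2 error variance component (>= 0).
#' @param nreps number of replicates (>= 1).
#' @return heritability in [0, 1].
#' @export
heritability_single_env <- function(sigma_g2, sigma_e2, nreps = 2) {
  if (sigma_g2 < 0 || sigma_e2 < 0) stop("variances must be nonnegative")
  if (nreps < 1) stop("nreps must be >= 1")
  den <- sigma_g2 + sigma_e2 / nreps
  if (den == 0) stop("zero denominator: all variance components are zero")
  sigma_g2 / den
}

#' Broad-sense heritability combined across environments
#'
#' `h2 = sigma_g2 / (sigma_g2 + sigma_ge2 / nenv +
#'  sigma_e2 / (nenv * nreps))`.
#'
#' @param sigma_g2 genotypic variance (>= 0).
#' @param sigma_ge2 genotype x environment interaction variance (>= 0).
#' @param sigma_e2 error variance (>= 0).
#' @param nenv number of environments (>= 1).
#' @param nreps number of replicates (>= 1).
#' @return heritability in [0, 1].
#' @export
heritability_combined <- function(sigma_g2, sigma_ge2, sigma_e2,
                                  nenv, nreps = 2) {
  if (sigma_g2 < 0 || sigma_ge2 < 0 || sigma_e2 < 0)
    stop("variances must be nonnegative")
  if (nenv < 1 || nreps < 1) stop("nenv and nreps must be >= 1")
  den <- sigma_g2 + sigma_ge2 / nenv + sigma_e2 / (nenv * nreps)
  if (den == 0) stop("zero denominator: all variance components are zero")
  sigma_g2 / den
}
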