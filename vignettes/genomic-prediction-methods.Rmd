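---
title: "Models and methods for genome-enabled prediction in gpbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for genome-enabled prediction in gpbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpbench)
```

## The problem

Genomic selection predicts the genetic value of breeding candidates from
genome-wide marker data. A phenotype is modeled as
$y_i = g_i + \varepsilon_i$, where $g_i$ is a genetic value and
$\varepsilon_i$ a residual. With $p$ markers on $n$ lines and $p \gg n$,
marker effects are not likelihood-identified and must be regularized.
`gpbench` implements seven regularized predictors of $g_i$ — four linear
in the markers, three non-linear — together with the replicated
random-partition cross-validation protocol used to compare them, and a
synthetic-data generator so that the whole pipeline is testable without
any external data. The genotype model is a binary dominant marker panel
(DArT-style presence/absence calls in $\{0,1\}$, missing allowed), the
setting of elite wheat panels genotyped with diversity array technology.

## Linear whole-genome regressions

All four linear models share the likelihood
$y_i \sim N(\mu + \sum_j x_{ij}\beta_j,\ \sigma^2_e)$ and differ in the
prior on $\beta_j$:

* **BRR** (Bayesian ridge regression / RR-BLUP): $\beta_j \sim
  N(0, \sigma^2_\beta)$ with one common variance. Both variances get
  scaled-inverse-$\chi^2$ priors with degrees of freedom 4 and scale 1 by
  default. The posterior mean of $\beta$ is the BLUP of marker effects.
* **Bayesian LASSO**: double-exponential prior implemented as the
  normal–exponential scale mixture
  $\beta_j \mid \tau^2_j \sim N(0, \tau^2_j \sigma^2_e)$, with
  $1/\tau^2_j$ inverse-Gaussian and
  $\lambda^2 \sim \mathrm{Gamma}(0.55, 10^{-4})$ by default. The source
  study defers its LASSO hyperpriors to earlier work without printing
  them; these defaults are conventional and configurable.
* **Bayes A / Bayes B**: marker-specific variances
  $\sigma^2_j \sim \chi^{-2}(\mathrm{df}_\beta = 4, s_\beta)$, and for
  Bayes B additional prior mass $\pi = 0.95$ on $\beta_j = 0$. The scale
  $s_\beta$ is derived from allele frequencies:
  $\tilde\sigma^2_a = \tilde\sigma^2_S / [(1-\pi)\sum_j 2q_j(1-q_j)]$ and
  $s_\beta = \tilde\sigma^2_a(\mathrm{df}_\beta - 2)/\mathrm{df}_\beta$.
  $\tilde\sigma^2_S$ (the additive variance attributed to markers) is
  unstated in the source study; the default here is half the training
  phenotypic variance, surfaced in the configuration. The residual
  variance uses an improper flat prior for Bayes B, implemented as the
  proper conditional draw $\sigma^2_e \mid \cdot \sim
  \mathrm{RSS}/\chi^2_{n-2}$ and guarded by $n > 4$. Bayes A **is** the
  $\pi = 0$ code path of the Bayes B sampler, so their chains are
  identical draw for draw under a shared seed — a structural identity the
  tests assert.

The samplers are single-site Gibbs with conjugate updates, written in
C++ (RcppArmadillo) and driven entirely by R's RNG, so `set.seed()`
makes every chain bit-reproducible. The Bayes B indicator is sampled
with the effect integrated out (exact two-component Gibbs), which avoids
the stickiness of naive Metropolis updates and is testable against the
closed-form conjugate oracle. Markers are kept in their raw $\{0,1\}$
dominant coding throughout; $y$ is used on its original scale with a
sampled intercept. Marker updates scan $j = 1..p$ in fixed order;
permutation equivariance therefore holds in distribution, not per seed.

Defaults follow the benchmarking protocol: 35,000 iterations with 5,000
burn-in (the burn-in is unstated in the source study; 5,000 is
conventional and configurable). Tests use much shorter chains.

## RKHS with kernel averaging

The semi-parametric model is $y = \mu 1 + \sum_k u_k + \varepsilon$ with
$u_k \sim N(0, \sigma^2_k K_k)$ and Gaussian kernels
$K_k(x, x') = \exp(-h_k \lVert x - x'\rVert^2)$. Rather than selecting
one bandwidth, several candidate kernels enter simultaneously and their
variance components weight them ("kernel averaging"). Each $u_k$ is
sampled in the eigenbasis of $K_k$ (eigenvalues below
$10^{-10}\lambda_{max}$ truncated for numerical stability); variance
components get scaled-inverse-$\chi^2$ updates.

Numerical and design choices:

* Squared distances are divided by their median by default so the
  bandwidth grid $\{0.1, 0.25, 0.5, 1, 2, 5\}$ is dimensionless. The
  source study's actual grid lives in unpublished code; this grid spans
  kernels from near-flat to near-diagonal over the observed distances.
* The *reported* weight of kernel $k$ is the posterior mean of the
  realized variance $\mathrm{var}(u_k)$, not $\sigma^2_k$ itself: an
  idle kernel's $\sigma^2_k$ stays near its prior mean because only a
  few of its eigendirections are data-identified, whereas
  $\mathrm{var}(u_k)$ goes to zero. The kernel-averaging consistency
  test (generating kernel dominates) uses this quantity.
* Duplicating a kernel in the grid leaves predictions unchanged only
  when the data dominate the variance priors; with informative priors
  each copy contributes its own prior scale, which slightly increases
  total prior genetic variance. The invariance test therefore runs under
  a weak prior.
* With a single *linear* kernel $K = X_cX_c'/p$ and the matched prior
  scale $s_k = p\, s_\beta$, the model is exactly BRR; held-out
  predictions from the two samplers agreeing within Monte-Carlo error is
  an acceptance criterion.

## Radial basis function network

A single hidden layer of Gaussian units
$z_k(x) = \exp(-h\lVert x - c_k\rVert^2)$ with centers $c_k$ chosen from
the training inputs by greedy orthogonal least squares: at each step
every remaining candidate's basis column is orthogonalized against the
selected set and the candidate with the largest error-reduction ratio
enters; ties go to the lowest index; selection stops at a target
training MSE (*goal*) or at $S = n$. Output weights and the intercept
are refit by ordinary least squares on the selected columns. The
bandwidth comes from the *spread* parameter as $h = (0.8326/s)^2$ (the
unit's response falls to $1/2$ at distance $s$; this is the MATLAB
`newrb` convention under which the source study trained its nets).

The spread axis of the tuning grid is anchored at the median pairwise
Euclidean distance of the training inputs (multipliers 0.5, 1, 2); the
goal axis at fractions 0.02 and 0.1 of $\mathrm{var}(y)$ — the study's
initial value 0.02 is unitless, so it is interpreted relative to the
phenotypic variance (configurable as absolute). How the study chose its
grid winner is unstated; here each cell is scored on an internal 80/20
split of the training fold (never the outer validation fold, avoiding
selection leakage) and the winner is refit on the whole training fold.

## Bayesian-regularized network

A single-hidden-layer tanh network
$\hat y = \mu + \sum_k w_k \tanh(b_k + x'\beta^{[k]})$ trained by the
MacKay evidence framework: minimize
$F(\theta) = \beta\sum e_i^2 + \alpha\sum\theta_j^2$ by
Levenberg–Marquardt at fixed $(\alpha, \beta)$, then update via the
evidence approximation $\gamma = \sum_i \lambda_i/(\lambda_i + \alpha)$
(eigenvalues $\lambda_i$ of $\beta J'J$),
$\alpha \leftarrow \gamma / 2\sum\theta_j^2$,
$\beta \leftarrow (n - \gamma)/2\sum e_i^2$, and iterate. Here
$\alpha = 1/2\sigma^2_\theta$, $\beta = 1/2\sigma^2_e$, and $\gamma$ is
the effective number of parameters, which is provably inside $[0, m]$ —
asserted numerically every iteration. Inputs are standardized and $y$
centered internally. Weight initialization is Nguyen–Widrow-style scaled
uniform with multiple restarts (default 5), keeping the lowest final
$F$. The network size is 2 neurons by default (the study never states
its architecture). Neal's grouped-prior constants ($s_e = 0.05$,
$\mathrm{df}_e = 0.5$; $s_u = (0.05/p^{1/\mathrm{df}_u})^2$,
$\mathrm{df}_u = 0.5$) are carried as configuration metadata; the
generic scale 0.05 seeds $(\alpha_0, \beta_0) = (10, 10)$, because the
connection-specific scale would start $\alpha$ at $\sim 10^{13}$ and
make the first evidence update degenerate. Full hybrid-Monte-Carlo
posterior sampling of network weights is out of scope; the printed
algorithm is the two-step evidence loop implemented here.

## Cross-validation and metrics

`cross_validate()` builds one list of random partitions (default 50,
each assigning 90% of lines to training and `round(0.1 n)` to
validation — 31 of 306; ties round half away from zero) and reuses it
across every model, so per-partition Pearson correlations and PMSE are
paired. The "SE" printed next to each mean correlation is the standard
deviation of the per-partition correlations (the magnitudes reported in
the source study are consistent with SDs, not SD/$\sqrt{50}$).
Significance testing is a paired t-test on per-partition differences at
$\alpha = 0.05$; partitions where a correlation is undefined (constant
predictions) are dropped pairwise and counted. Broad-sense heritability
helpers implement the entry-mean formulas
$h^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_e/n_{reps})$ and
$h^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_{ge}/n_{env} +
\sigma^2_e/(n_{env} n_{reps}))$; they take variance components as
inputs (estimating them from raw replicated trials is out of scope).

Reproducibility: per-(partition, model) RNG seeds derive
deterministically from the master seed, so models can run alone or in
any order against identical partitions, and the CLI writes the resolved
configuration (including the seed) next to its outputs.

## The synthetic-data generator: what it emulates, and what not

`simulate_genotypes()` draws allele frequencies
$q_j \sim U(\mathrm{maf\ range})$ and Bernoulli calls; options add
block-correlated markers (latent-factor LD) or a **founder mode** in
which each line is a block-wise mosaic of a small number of founder
haplotypes, giving both linkage disequilibrium and relatedness, as in a
breeding panel. `simulate_trait()` builds genetic values as an additive
part (sampled QTL, normal or Laplace effects) plus an epistatic part
(pairwise products of raw 0/1 codes over sampled pairs, drawn among the
QTL by default — epistasis between trait loci, as in the gene networks
regulating wheat heading time). The epistatic component is residualized
against the intercept, the realized additive component and the touched
marker columns, making the two parts *exactly* orthogonal in sample, so
`prop_epistasis` is the exact in-sample genetic-variance share; when the
touched design approaches full row rank the basis falls back to a
truncated one that always contains the additive component, preserving
the exact split. Residual noise is scaled so
$\mathrm{var}(g)/\mathrm{var}(y)$ hits the target $h^2$ per environment;
genetic values across environments are correlated at `env_corr` by
mixing a common and an environment-specific effect vector.

**What a green benchmark does and does not establish.** During
development we found that with *unrelated* Bernoulli lines the epistatic
variance is statistically unlearnable at $n \approx 300$ by every model
in the package — even a noiseless additive$\times$additive kernel-ridge
oracle stays below $r = 0.3$ — so no method ranking can emerge from that
world. This mirrors the field's observation (stated in the source study
as well) that genomic prediction requires genetic relatedness between
training and validation lines. The qualitative benchmark therefore uses
a **biparental** founder population (2 founders, haplotype blocks of 20
markers) carrying 30 QTL with a dense 200-pair interaction network at
$h^2 = 0.6$. In that world a purely epistatic trait is invisible to the
linear models ($r \approx 0$) yet predictable by RKHS and the RBF
network ($r \approx 0.4$), and at `prop_epistasis = 0.6` the non-linear
models hold a $\sim 0.1$–0.2 advantage in mean held-out correlation,
while on the purely additive twin the advantage vanishes. A green run
shows the implementations capture cross-locus interaction structure that
linear-in-markers models cannot; it does *not* certify the magnitudes
observed on real wheat data, whose relatedness and LD structure the
generator only caricatures.

## Numerical choices and degenerate inputs

* Missing genotypes are imputed by the marker mean (which preserves the
  allele-frequency estimate for a 0/1 dominant marker); monomorphic
  markers are removed before fitting. The source study is silent on
  missing-data handling.
* Validation sets: `round(fraction * n)`, half away from zero.
* Kernel eigenvalues below $10^{-10}\lambda_{max}$ are truncated;
  kernels failing PSD beyond $-10^{-8}\lambda_{max}$ raise an error.
* Constant training responses are rejected by the samplers; constant
  validation predictions yield an `NA` correlation that is dropped
  pairwise in tests and counted in reports.
* OLS center selection skips candidate columns whose orthogonalized norm
  falls below $10^{-12}$ of their original norm; exact ties in the
  error-reduction ratio go to the lowest candidate index.
* The inverse-Gaussian draw for the LASSO mixture guards $\beta_j^2 <
  10^{-20}$ by capping the conditional mean at $10^{10}$.

## Known limitations

* The generator does not simulate pedigrees, coalescent LD, selection or
  population structure beyond the founder-mosaic caricature; its LD is
  block-wise and uncalibrated to any real DArT panel.
* Bayes C$\pi$-type $\pi$ estimation, multi-trait and G$\times$E
  covariance models, and pedigree relationship matrices are not
  implemented.
* The BRNN optimizes to a posterior mode with an evidence approximation;
  it does not sample the weight posterior.
* Reported runtimes in the source study (minutes to days per model) are
  not reproduced; chains here are scaled to test budgets.
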