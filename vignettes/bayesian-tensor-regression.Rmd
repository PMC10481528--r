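---
title: "Integrative Bayesian tensor regression: model, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative Bayesian tensor regression: model, priors, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btreg)
```

## The problem

Imaging-genetics studies ask how much of a scalar clinical outcome (for
example a cognitive score) can be predicted jointly from a structural brain
image, gene-expression profiles, and demographics. The two high-dimensional
blocks have very different structure: an image is a spatially organized
$D$-way array whose neighbouring voxels carry correlated effects, while
expression features are collinear because genes share regulatory networks.
`btreg` fits the regression

$$y_i = \alpha + z_i'\gamma + z_{1i}'\eta + \langle X_i, B\rangle + \epsilon_i,
\qquad \epsilon_i \sim N(0, \sigma^2),$$

where $X_i \in \mathbb{R}^{p_1 \times \cdots \times p_D}$ is the image,
$B$ the coefficient tensor, $z_{1i}$ the $q$ gene features and $z_i$ the $p$
demographics, treating each block with a prior adapted to its structure.

## Low-rank tensor coefficient

An unstructured $B$ has $\prod_j p_j$ free parameters; `btreg` uses a
rank-$R$ PARAFAC (CP) representation
$B = \sum_{r=1}^R \beta_1^{(r)} \circ \cdots \circ \beta_D^{(r)}$, reducing
the count to $R\sum_j p_j$ (`count_parameters()` reports both). Because
neighbouring voxels share margin elements, the decomposition induces spatial
smoothing and pools information across tensor fibers and slices, which is
what lets the model cope with voxels that are missing or zero for some
subjects. Margins are *not* identifiability-constrained (only $B$ is
identifiable, and only $B$ is ever reported or compared). Voxels that are
zero in every subject carry no likelihood information; they are screened out
and reported as exact zeros in the posterior tensor.

## Priors

**Multiway shrinkage on the margins.** Margins carry the multiway Dirichlet
generalized double Pareto (M-DGDP) hierarchy

$$\beta_j^{(r)} \sim N\{0, (\phi_r\tau) W_{jr}\},\quad
w_{jr,k} \sim \mathrm{Exp}(s_{jr}^2/2),\quad
s_{jr} \sim \mathrm{Ga}(a_\lambda, b_\lambda),$$

with component scales $\tau_r = \phi_r\tau$. Marginally each margin element
is double-exponential, giving adaptive-lasso-like shrinkage within margins,
while the Dirichlet weights $\Phi$ shrink whole components away and thus
favour low effective rank. We parameterize the global scale through the
augmentation $\tau_r \sim \mathrm{iid}\ \mathrm{Ga}(\alpha, b_\tau)$, which
is exactly equivalent to $\tau \sim \mathrm{Ga}(R\alpha, b_\tau)$ with
$\Phi \sim \mathrm{Dirichlet}(\alpha,\ldots,\alpha)$ independent. We chose
this parameterization (rather than an independent $a_\tau$) because it is
the one under which the compositional update
$[\alpha \mid B, W][\Phi, \tau \mid \alpha, B, W]$ is an exact Gibbs step;
the joint-distribution validation below depends on that exactness.
$b_\tau = \alpha R^{1/D}$ keeps the prior mean of $\tau$ stable across
ranks. The concentration $\alpha$ has a discrete uniform prior on 10 equally
spaced points in $[R^{-D}, R^{-0.10}]$, and $a_\lambda$ on 10 points in
$[2, D+1]$ with $b_\lambda = a_\lambda^{1/(2D)}$; both are updated by griddy
Gibbs. The exponent reading of $b_\lambda$ follows the original M-DGDP
recommendation; the alternative reading $a_\lambda^{2D}$ grows explosively
with $D$ and was rejected.

**Graph-Laplacian prior on gene coefficients.** Conditional on $\sigma^2$,
$\eta \sim N\{0, (\sigma^2/m)\Lambda^{-1}\}$ where $\Lambda$ has diagonal
$1 + \lambda_{ii} + \sum_{j\ne i}|\lambda_{ij}|$ and off-diagonals
$\lambda_{ij}$: a diagonally dominant, always-invertible Laplacian-type
precision that encodes an unknown conditional-dependence graph among genes
and is learned from the data. Each $\lambda_{ii}$ carries an
inverse-gamma$(1/2, a^2/2)$ kernel and each $|\lambda_{ij}|$ a two-sided
version with penalty $b$, tilted jointly by $|\Lambda|^{-1/2}$. Two points
we settled during implementation:

* The element kernel $|x|^{-3/2}e^{-b^2/(2|x|)}$ *is* integrable through
  zero (it is an inverse-gamma kernel on each side), so the prior is a
  proper two-sided density and no point mass at zero is needed.
* In the full conditional of $\lambda$ the $|\Lambda|^{+1/2}$ factor from
  the $\eta$ likelihood cancels the $|\Lambda|^{-1/2}$ tilt, so every
  element has a *closed-form* full conditional — inverse-Gaussian for the
  diagonal, a two-sided inverse-Gaussian mixture for off-diagonals — and the
  sampler uses exact elementwise Gibbs draws rather than Metropolis-Hastings.

**Hyperpenalties $a$, $b$ and the scale $m$.** $m$ has a
$\mathrm{Ga}(h_m, h_m)$ prior and a conjugate gamma update; $a$ and $b$ have
exponential hyperpriors ($g_a = g_b = h_m = 0.1$ by default) whose
normalizing-constant factor cancels against the element-level prior, leaving
positive-truncated-normal conditionals. However, under that cancellation the
joint kernel over $(a, \lambda)$ is **improper**: integrating the diagonal
kernels gives an $a$-marginal behaving like $a^{-q}e^{-g_a a}$ near zero.
Empirically an exact chain drifts to the degenerate corner
$\lambda \to 0, a \to 0$ (where $\Lambda \to I$ and the prior collapses to
ridge). For this reason `btr_config(update_ab = FALSE)` is the default: $a$
and $b$ stay at their configured values (1 by default), the posterior is
proper, and the graph prior still adapts through $\lambda$ and $m$. The
updates remain available (`update_ab = TRUE`) and are validated against
quadrature oracles, but we document this as a limitation of the hierarchy
rather than hide it.

**Noise and demographics.** $\sigma^2 \sim \mathrm{IG}(\nu/2, \nu s_0^2/2)$
with $\nu = 2$ and $s_0^2$ calibrated by `calibrate_s0()` so that
$P(\sigma^2 \le 1) = 0.95$ for a centred, scaled response (`btr()` scales
the response internally and back-transforms every draw). The intercept and
demographics have a conjugate $N(0, \sigma^2 \cdot 100 I)$ prior.

## The Gibbs sampler

One sweep updates, in order: $(\alpha, \Phi, \tau)$ compositionally
(griddy Gibbs for $\alpha$ with $(\Phi,\tau)$ integrated out via Bessel-$K$
integrals, then independent giG draws of $\tau_r$); the margins by
back-fitting — for each component $r$ and mode $j$, draw
$s_{jr} \mid \beta$ (local scales integrated out), $w_{jr} \mid s, \beta$,
then $\beta_j^{(r)} \sim N(\mu_{jr}, \Sigma_{jr})$ with
$\Sigma_{jr} = (H_j^{(r)\prime}H_j^{(r)}/\sigma^2 + W_{jr}^{-1}/\tau_r)^{-1}$
against the residual that excludes every *other* component's contribution
(subtracting the full image term would wrongly zero-centre the update;
back-fitting is the only reading consistent with margin-level conditionals);
$a_\lambda$ by griddy Gibbs; $(\gamma, \sigma^2)$ jointly with $\gamma$
collapsed — note the inverse-gamma shape is $(n + q + \nu)/2$ and the rate
includes $m\,\eta'\Lambda\eta/2$, because the $\eta$ prior scales with
$\sigma^2$; $\eta$ from its Gaussian conditional; $\lambda$ elementwise; and
$(m, a, b)$. All updates are exact draws, which we verify three ways:

1. **Conditional oracles** — each closed-form conditional is compared to an
   independent quadrature or closed-form law (Kolmogorov-Smirnov at
   $10^5$ draws, or $10^{-10}$ agreement where analytic).
2. **Joint-distribution (Geweke-style) check** — on a tiny model
   ($2\times 2$ image, rank 1, $q = 2$, $n = 15$) the marginal-conditional
   simulator (iid prior draws) and the successive-conditional simulator
   (sweep, then redraw $y$) must agree in distribution; we compare ~35
   first/second-moment statistics with autocorrelation-robust standard
   errors and require $|z| < 4$ for at least 95%. This check is run with
   $\nu = 6$ (with $\nu = 2$ the prior $\sigma^2$ has no mean, so moment
   tests are undefined) and fixed $(a, b)$ (see the impropriety above).
   Prior draws of $\lambda$ use exact rejection with acceptance
   $|\Lambda|^{-1/2} \le 1$, valid because $\Lambda \succeq I$.
3. **Stationarity screening** — an in-package augmented Dickey-Fuller test
   (constant, lag order $\lfloor (n-1)^{1/3} \rfloor$, p-values interpolated
   from the published $\tau_\mu$ table) is applied to every monitored chain
   by `check_convergence()`.

giG draws use the exact inverse-Gaussian transform for the half-integer
orders that dominate the sweep, and ratio-of-uniforms with mode shift for
the general-order $\tau_r$ update; both are validated against Bessel-ratio
moments and quadrature CDFs. Chains are bit-reproducible under a seed.

## Rank selection, evaluation, and feature selection

`select_rank()` fits each candidate rank and minimizes
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\hat\theta)$
(Spiegelhalter form; the plug-in uses posterior means of all blocks).
Rank differences beyond the truth produce nearly identical deviances and a
small $p_D$ penalty, so adjacent-rank DIC gaps are of order a few units;
we use 3,000-iteration chains in the rank-selection checks to keep the
Monte Carlo error of $\bar D$ below those gaps.

Prediction error is reported as relative RMSE: prediction RMSE divided by
the standard deviation (with $1/n$) of the observed outcome, so the
mean-only predictor scores exactly 1 and values above 1 are worse than the
null model. The comparison harness runs, on identical seeded 80:20 splits,
the full model, an image-only tensor regression, an elastic net
($\alpha = 0.5$, penalty by 5-fold CV) on the vectorized voxels plus genes,
and a gene-only elastic net; demographics are included, unpenalized,
everywhere. A gene is flagged "significant" when its 95% equal-tailed
credible interval excludes zero; no multiplicity adjustment is applied, and
`significance_table()` instead reports, for each gene, the frequency and
percentage of fits (across slices/visits) in which it was flagged.

## The synthetic-data generator

`sim_scenario()`/`simulate_dataset()` emulate the statistical structure the
analysis assumes: a low-rank spatial signal (`make_low_rank_signal()`,
rectangles or Gaussian bumps of exact CP rank); a zero-mask shared by all
subjects (cortex-like sparsity) built from a one-voxel border — which is an
outer product of indicators, hence rank-1 and CP-rank-preserving — topped up
with random scatter away from the signal support to hit the target fraction
(defaults 0.30-0.45, matching typical per-slice sparsity of cortical
thickness maps); gene features from a Gaussian whose precision is a
chain-plus-hubs graph with edge weights 0.3-0.6 before the
diagonal-dominance rescale; sparse gene effects; and Gaussian noise at a
stated signal-to-noise ratio (default 3). The mask is applied to the true
$B$ as well, since fully masked voxels are inestimable by construction.

What the generator does *not* emulate: MRI physics and registration
artifacts, non-Gaussian expression marginals, and outcome floor/ceiling
effects. Passing the recovery and ordering tests therefore shows the method
works under its own assumptions at realistic dimensions, not that it
reproduces any particular clinical dataset.

## Problem sizes and numerical choices

The validation suite uses scaled-down dimensions chosen to exercise every
code path at desk scale: recovery at $16\times 16$ voxels, $n = 150$,
$q = 20$, 2,500 sweeps; method comparison at $12\times 12$, $n = 200$,
$q = 15$, ten splits; rank selection at $10\times 10$, $n = 120$, ten
seeds. Default production settings follow the larger-scale usage:
10,000 sweeps with 3,000 burn-in. Degenerate inputs are handled explicitly:
$R = 1$ pins $\alpha$ and $\Phi$ at 1; $q = 0$ skips the gene block (and the
$\sigma^2$ shape drops its $q/2$); margin-update precisions are
Cholesky-factorized with a logged jitter fallback; exact zeros in margins
route the giG draws to their gamma/inverse-gamma limits.

## Known limitations

* The $(a, b)$ hyperupdate is off by default (improper joint; see above).
* Like other adaptive ridge-type priors, the graph-Laplacian prior trades
  unbiasedness for stabilized prediction: when individual gene effects carry
  only a few standard errors of signal (as in the default recovery scenario,
  whose overall SNR is dominated by the image block), the learned global
  scale $m$ over-shrinks them and their 95% credible intervals undercover —
  the validation suite measures this directly. Prediction, tensor recovery,
  and the *null* calibration of gene flags (false-flag rate at the nominal
  level) are unaffected; treat individual gene intervals as conservative
  evidence of direction, not as calibrated frequentist intervals.
* DIC separates adjacent ranks only weakly when the shrinkage prior has
  already suppressed the surplus component; expect occasional selection of
  rank $R+1$.
* The PARAFAC grid treatment assumes images are already mapped to a regular
  grid; no resampling is performed.
* Posterior draws of the full tensor are stored densely; for grids much
  larger than $64\times 64$ per-voxel storage should be disabled
  (`store_B = FALSE`) or thinned.
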