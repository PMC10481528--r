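# btreg — integrative Bayesian tensor regression

`btreg` predicts a scalar outcome (e.g. a cognitive score) from a
**D-way image predictor**, **correlated gene-expression covariates**, and
**demographics**, in one Bayesian regression:

    y_i = alpha + z_i' gamma + z1_i' eta + <X_i, B> + eps_i,   eps_i ~ N(0, sigma^2)

The image coefficient `B` is a rank-R PARAFAC (CP) tensor,
`B = sum_r beta_1^(r) o ... o beta_D^(r)`, which cuts the parameter count
from `p + q + 2 + prod(p_j)` to `p + q + 2 + R * sum(p_j)` and pools
information across neighbouring voxels. The margins carry a multiway
Dirichlet generalized double Pareto (M-DGDP) shrinkage prior; the gene
coefficients carry a graph-Laplacian prior whose precision matrix — and
hence the gene dependence graph — is learned from the data. Inference is a
full Gibbs sampler with generalized-inverse-Gaussian updates; tensor rank is
chosen by DIC; genes are flagged by 95% credible intervals; prediction error
is reported as relative RMSE (a mean-only predictor scores exactly 1).

The package is aimed at imaging-genetics analyses (e.g. cortical-thickness
slices plus transcriptomics in cognitive-decline studies), but any
scalar-on-tensor regression with extra covariate blocks fits. Everything is
testable without external data through a synthetic-data generator with known
ground truth.

## Worked example

```r
library(btreg)

# a known-truth dataset: 150 subjects, 16 x 16 image with a rank-2 signal and
# 30% shared zero-mask, 20 correlated genes (5 with real effects), SNR 3
sc  <- sim_scenario(n = 150, p_dims = c(16, 16), rank = 2, sparsity = 0.3,
                    q = 20, prop_eta_nonzero = 0.25, snr = 3, seed = 11)
d   <- simulate_dataset(sc)

fit <- btr(d$y, d$X, d$Z, d$Z1, rank = 2,
           config = btr_config(n_iter = 2500, burn_in = 1000, seed = 12))
fit
#> Integrative Bayesian tensor regression fit
#>   image grid: 16 x 16   rank: 2   n = 150
#>   demographics: 2   genes: 20
#>   DIC: 616.82   stored draws: 1500

# how well is the planted tensor recovered?
sqrt(sum((fit$B - d$truth$B)^2) / sum(d$truth$B^2))
#> [1] 0.2241754

head(tidy(fit), 4)
#> # A tibble: 4 x 6
#>   term        type        estimate   lower upper flagged
#>   <chr>       <chr>          <dbl>   <dbl> <dbl> <lgl>
#> 1 (Intercept) intercept      3.84   2.29   5.41  TRUE
#> 2 demo1       demographic    0.345 -0.0374 0.740 FALSE
#> 3 demo2       demographic   -0.316 -0.954  0.346 FALSE
#> 4 gene1       gene           0.127 -0.195  0.559 FALSE
```

The relative Frobenius error of ~0.22 says the posterior-mean tensor
recovers the planted 16x16 signal to within a quarter of its magnitude from
150 noisy subjects. `flagged` marks coefficients whose 95% credible interval
excludes zero; here the correlated gene block shares credit across
neighbours, so individual gene intervals are wide but still cover their true
values (gene1's true effect is 0.5, inside its interval).

Rank selection and method comparison:

```r
sel <- select_rank(d$y, d$X, d$Z, d$Z1, rank_grid = 1:3,
                   config = btr_config(n_iter = 3000, burn_in = 1000, seed = 1))
sel$best_rank          # DIC-minimizing tensor rank
plot_dic_trace(sel)

ev <- evaluate_methods(d, split_train_test(150, n_splits = 10, seed = 2),
                       rank = 2)
plot_rrmse(ev)         # iBTR vs image-only, elastic net, gene-only baselines
```

Other entry points: `flag_significant()` / `significance_table()` for
credible-interval gene selection across many fits, `check_convergence()` for
augmented-Dickey-Fuller stationarity screening of the chains,
`screen_voxels()` / `filter_slices()` / `screen_genes()` for the
preprocessing rules, `longitudinal_change()` for visit-difference analyses,
and `write_dataset()` / `read_dataset()` for the plain-text on-disk formats.
A thin command-line wrapper lives at `inst/cli/btreg`
(`simulate | fit | select-rank | predict | evaluate | screen | report`).

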