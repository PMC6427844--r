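# methmix

Bayesian clustering and imputation of single-cell methylomes.

Single-cell bisulfite sequencing (scBS-seq / scRRBS) measures CpG
methylation in individual cells, but covers only a small fraction of CpGs
per cell. `methmix` addresses this sparsity by sharing information in two
directions at once: **along the genome**, by modelling each genomic
region's methylation as a smooth latent profile, and **across cells**, by
clustering cells with a Bayesian mixture so that similar cells inform each
other. The output is twofold — a methylome-based clustering of the cells,
and a posterior predictive probability for any unobserved CpG, usable for
imputation. The package is aimed at analysts of single-cell methylation
experiments who need cell sub-population structure and/or imputed
methylation states over regions of interest (promoters, enhancers, ...).

## The model

For cell *n*, region *m* and CpG *i* at scaled position *x* in [−1, 1]:

```
pi ~ Dirichlet(delta0, ..., delta0)
c_n | pi ~ Discrete(pi)                          # cluster of cell n
tau_k ~ Gamma(alpha0, beta0)                     # per-cluster shrinkage
w_mk | tau_k ~ N(0, tau_k^{-1} I)                # profile weights
z_nmi | c_n = k ~ N(w_mk' h(x_nmi), 1)           # probit augmentation
y_nmi = 1 if z_nmi > 0 else 0                    # observed CpG state
```

where `h(x)` is an intercept plus radial basis functions, so
`P(y = 1) = Phi(w' h(x))` is a smooth methylation profile. Inference is
mean-field variational Bayes (coordinate ascent with monitored ELBO) or,
for small problems and as a reference, Gibbs sampling. Fitting with a
generous number of components `k` automatically empties redundant ones, so
the number of occupied components estimates the number of cell
sub-populations. Held-out CpGs are imputed with the closed-form
posterior predictive
`sum_k omega_k Phi(h'lambda_mk / sqrt(1 + h'S_mk h))`.

The comparator methods from the single-cell methylation literature are
included behind the same interface: per-(cell, region) methylation rates,
a rate-only (intercept) variant of the mixture, a Gaussian mixture on
M-values, and independently fitted probit profiles per cell and region.

## Worked example

```r
library(methmix)

# simulate 200 cells, 4 sub-populations (40/25/20/15%), 30 regions
sim   <- simulate_dataset(sim_config(n_regions = 30, seed = 1))
parts <- split_train_test(sim$data, train_fraction = 0.5, seed = 1)

fit <- fit_methmix(parts$train, k = 10, seed = 1)
fit
#> <methmix_fit> 200 cells, 30 regions, k = 10 (effective 4)
#>   ELBO -27378.195 after 36 sweeps (converged), basis D = 5
```

Although 10 components were requested, the variational optimisation leaves
only 4 occupied — the true number of simulated sub-populations. The hard
labels recover the simulated clustering exactly:

```r
adjusted_rand_index(fit$hard_labels, sim$truth$labels$label)
#> [1] 1
```

Imputing the held-out half of the CpGs:

```r
preds <- impute_dataset(fit, parts$test)
evaluate_imputation(preds)
#> # A tibble: 1 × 8
#>     auc precision recall f_measure    tp    fp    tn    fn
#>   <dbl>     <dbl>  <dbl>     <dbl> <int> <int> <int> <int>
#> 1 0.873     0.817  0.841     0.829 26575  5943 22430  5039
```

AUC 0.87 against 0.72 for the rate-based baselines on the same split (see
`benchmark_methods()`). `tidy(fit)` returns per-cell responsibilities,
`autoplot(fit)` the ELBO trace, and `plot_profiles(fit, regions)` the
per-cluster posterior methylation profiles.

Real data enter through `read_cell_calls()` (Bismark-style counts, rates
or binary states), `read_region_annotations()` (BED or TSS tables),
`build_regions()` and `filter_regions()`; synthetic and real datasets share
one on-disk layout (`write_meth_dataset()` / `read_meth_dataset()`).

A thin command-line wrapper covers the same workflows:

```sh
inst/cli/methmix simulate --out sim --seed 1
inst/cli/methmix fit --data sim --out fit.json --k-init 10
inst/cli/methmix impute --fit fit.json --data sim --out preds.tsv
inst/cli/methmix evaluate --predictions preds.tsv --out metrics.json
```

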