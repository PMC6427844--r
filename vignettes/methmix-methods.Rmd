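---
title: "Model and methods behind methmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind methmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmix)
```

## The problem

Single-cell bisulfite sequencing (scBS-seq, scRRBS) reports the methylation
state of individual CpG sites in individual cells, but with very sparse
coverage: for most CpGs in most cells there is simply no read. Two sources
of structure can compensate for this sparsity. First, methylation varies
smoothly along a genomic region, so neighbouring CpGs are informative about
each other. Second, cells come from a (usually unknown) mixture of
sub-populations, so other cells with a similar methylome are informative
about a given cell. `methmix` exploits both at once: it clusters cells
genome-wide while fitting a smooth methylation profile per genomic region
per cluster, and imputes unobserved CpGs from the resulting posterior.

## The model

Each cell `n = 1..N` carries observations in `M` genomic regions (e.g.
promoter windows). Within region `m`, CpG positions are scaled to
`[-1, 1]` and the binary state of CpG `i` is modelled as a probit
regression on a fixed basis expansion:

* `y_nmi ~ Bernoulli(Phi(w' h(x_nmi)))`,

where `h(x)` is an intercept plus `L` radial basis functions (default
`L = 4`, design dimension `D = 5`). The probit link is handled by the
classical augmentation: a latent Gaussian `z_nmi ~ N(w' h(x), 1)` whose
sign generates `y`. This makes every conditional conjugate.

Cells are coupled through a finite Dirichlet mixture: a latent assignment
`c_n ~ Discrete(pi)` with `pi ~ Dirichlet(delta0)` selects, for every
region, which of `K` weight vectors `w_mk` generated that cell's data.
Cells in the same cluster share all `M` region profiles. The weights get
independent Gaussian priors `w_mk ~ N(0, tau_k^{-1} I)` with a
cluster-specific precision `tau_k ~ Gamma(alpha0, beta0)`, so each cluster
learns how strongly its profiles are shrunk toward flat.

The model deliberately does **not** describe bisulfite conversion errors;
these are rare, and the simulation study adds Gaussian noise to the
Bernoulli success probabilities precisely to check robustness against
unmodelled noise of this kind. It also assumes one profile per cluster per
region — within-cluster heterogeneity at a single locus is absorbed into
the Bernoulli noise.

## Variational inference

The posterior is intractable, so `fit_methmix()` uses mean-field
variational Bayes with the factorisation
`q(Z) q(C) q(W) q(pi) q(tau)` and coordinate ascent (CAVI). One sweep
updates, in this fixed order:

1. `q(z_nmi)`: a unit-variance Gaussian truncated to the half-line matching
   `y_nmi`, centred at the responsibility-weighted predictor
   `sum_k r_nk lambda_mk' h(x)`;
2. `q(w_mk)`: Gaussian with precision `E[tau_k] I + sum_n r_nk H_nm' H_nm`
   and mean solving the responsibility-weighted normal equations against
   `E[z]`;
3. `q(tau_k)`: Gamma with shape `alpha0 + MD/2` and rate
   `beta0 + sum_m E[w_mk' w_mk] / 2`;
4. `q(c_n)`: categorical with log-responsibilities
   `E[ln pi_k] + sum_m E[ln N(z_nm | H w_mk, I)]`;
5. `q(pi)`: Dirichlet with `delta_k = delta0 + sum_n r_nk`.

Every update is exact, so the evidence lower bound (ELBO) is
non-decreasing; the implementation recomputes it after each sweep and the
test suite fails if it ever drops (beyond a 1e-6 relative float
tolerance). The ELBO is also validated two independent ways: against a
naive loop-based reimplementation of the same updates, and against a
brute-force evidence computation (assignment enumeration plus nested
quadrature) on instances small enough to integrate numerically, where the
bound property `ELBO <= ln p(Y)` must hold.

All likelihood computations are organised around per-(cell, region) block
statistics `G_nm = sum_i h(x_i) h(x_i)'` and `b_nm = sum_i E[z_i] h(x_i)`,
so a sweep costs `O(total CpGs * D)` plus `O(N_blocks * K * D^2)` rather
than `O(total CpGs * K * D^2)`. Pairs `(cell, region)` with no observed
CpGs contribute nothing to any sum; their predictive profile comes purely
from the cluster posterior.

### Initialisation, restarts, convergence

Responsibilities are initialised from k-means on the `N x M` matrix of
per-region mean methylation rates (missing entries filled with the region
mean), falling back to random responsibilities when k-means degenerates.
The initial assignments are deliberately softened
(`r = 0.3 * onehot + 0.7 / K`): hard initial responsibilities lock the
optimisation into local optima where one true sub-population stays split
across two components — with soft starts the redundant components merge
and are then emptied. `n_init` restarts (default 3: one k-means, the rest
random) are run and the highest final ELBO wins, ties broken by the lowest
restart index. Convergence is declared when the relative ELBO change drops
below `tol = 1e-5`, with a hard cap of 400 sweeps. All randomness derives
from one `seed` through per-restart derived seeds.

### Model selection by pruning

Fitting with a generous `k` (say 10) lets the variational optimisation
empty redundant components: the KL term of the objective penalises
components that do not pay for themselves in likelihood. Pruning is
diagnostic, not structural — no component is deleted during a run;
`effective_clusters()` counts components whose expected occupancy
`sum_n r_nk` exceeds one cell-equivalent. Two prior presets are exposed:
`"broad"` (`delta0 = 0.5`) and `"shrinkage"` (`delta0 = 1e-6`), the latter
placing so little prior mass per component that occupancy must be earned
from the data, which prunes harder when clusters are similar. Both share
`alpha0 = 0.5, beta0 = 10` for the weight precisions (weakly informative,
mildly favouring smooth profiles). These values are package choices; they
matter mainly through the pruning aggressiveness and are configurable via
`prior_config()`.

## Gibbs sampler

`fit_methmix_gibbs()` samples the identical joint model (truncated-normal
draws for `z`, conjugate Gaussian draws for `w`, Gamma for `tau`,
categorical from the probit likelihood for `c`, Dirichlet for `pi`). It
exists as a correctness oracle for the variational approximation — on
small, well-identified instances the VB posterior means must sit within
Monte-Carlo error of the chain averages — and for scalability comparisons.
Burn-in defaults to half the chain and thinning to 5; both are
conventional choices, configurable. An empty cluster's weights are drawn
from the prior. Label switching is handled at evaluation time
(`gibbs_map_labels()` relabels draws against a reference partition; the
adjusted Rand index is invariant anyway).

## Prediction and imputation

The posterior predictive probability at position `x` in region `m` is

`p(y = 1) = sum_k omega_k * Phi( h(x)' lambda_mk / sqrt(1 + h(x)' S_mk h(x)) )`,

the probit-Gaussian integral in closed form. For a cell that was in the
training set the mixture weights `omega` are that cell's responsibilities
— its assignment was inferred from its training CpGs, and using it is what
lets clustering improve imputation. For an unseen cell the posterior
mixing proportions `delta_k / sum_j delta_j` are used instead (the "prior"
weighting; both modes are exposed). Probabilities are clamped to
`(1e-10, 1 - 1e-10)` so log-based metrics stay finite, and binarised at
0.5 (configurable threshold).

## Comparator methods

* **Rate** (`fit_rate_baseline()`): the per-(cell, region) mean training
  state with a half pseudo-count `(s + 0.5) / (n + 1)`, so degenerate
  blocks keep usable probabilities; unseen blocks fall back to the cell
  mean. Position-independent by construction.
* **Rate-only mixture** (`fit_methmix_rate()`): the full model with an
  intercept-only basis — shares across cells but not across neighbouring
  CpGs.
* **GMM on M-values** (`fit_gmm_mvalues()`): per-region mean rates mapped
  through `m_value(r) = log2((r + .01) / (1 - r + .01))`, missing entries
  column-mean imputed, then a diagonal-covariance Gaussian mixture by EM
  (monotone log-likelihood, k-means start). Imputation uses the
  responsibility-weighted cluster mean rates (inverse M-value); an
  optional flag projects onto leading principal components before EM.
  How this comparator should impute is not canonical; the inverse-M
  cluster-mean rule is this package's documented choice.
* **Independent probit profiles** (`fit_independent_profiles()`): one MAP
  probit regression per (cell, region) with fixed ridge precision
  `tau0 = 0.1`, fitted by iterating the augmentation updates; shares
  across CpGs but not cells. Verified against direct numerical
  optimisation of the penalised log-likelihood.

All of them implement the same `impute_dataset()` interface, so the
benchmarking harness (`benchmark_methods()`) is method-agnostic.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure of a clustered
single-cell methylation experiment:

* `N = 200` cells in `K = 4` sub-populations with proportions
  40/25/20/15% (exact block counts, then shuffled; a multinomial mode
  exists behind a flag);
* `M = 100` regions, each assigned one of five built-in prototype
  profiles (flat-high, flat-low, rising, falling, dip-at-centre). The
  prototypes are expressed in the working basis by probit-scale least
  squares, so any sufficiently rich basis can be used, and a hook accepts
  user-supplied weight matrices. A `dissimilarity` fraction of regions
  (default 0.5) has prototypes re-drawn independently per cluster, so
  clusters differ there; the rest share one prototype;
* per (cell, region), `Binomial(50, coverage)` CpGs at uniform scaled
  positions (default coverage 0.4), each methylated with probability
  `Phi(h(x)' w)` plus `N(0, 0.05^2)` noise (drawn per CpG, clamped to
  `(0, 1)`), mimicking bisulfite conversion error.

What it does *not* emulate: read-level structure (adjacent CpGs observed
together on one read), non-uniform CpG spacing, chromosome context, and
intermediate methylation levels. Tests passing on this generator therefore
demonstrate correct inference under the model's own assumptions plus
probability-level noise — they do not by themselves establish performance
on real scBS-seq data, for which the package provides the
`read_cell_calls()` / `build_regions()` / `filter_regions()` ingestion
path (Bismark-style counts, rates or binary states; BED or TSS-window
annotations; the published 50%-of-cells / 10-CpG / between-cell
variability region filters).

## Data ingestion choices

Input genomic positions are 1-based inclusive; BED annotations are 0-based
half-open and converted at the reader boundary. Duplicate count records at
one position are summed before binarisation (they represent split count
lines); hemi-methylated sites (exactly 50% methylated reads) are dropped;
otherwise the state is the rounded read ratio. The "minimum 10 CpGs"
coverage rule is interpreted per cell per region (a cell covers a region
iff it observes at least `min_cpgs` CpGs there) — the pooled reading can
be obtained by setting `min_cpgs = 1` and filtering afterwards. The
variability filter removes regions whose covering cells all have exactly
equal mean rates, the weakest reasonable reading; anything stricter can be
layered on top. The train/test splitter guarantees at least one training
CpG per covered block so every block remains fittable.

## Problem sizes used by the tests and the acceptance script

The packaged checks run the default conditions with `M = 30` regions
(instead of 100) and use 5–10 generator seeds per claim. At this size a
`k = 10` fit takes a few seconds, and the qualitative results — exactly 4
effective components under the default conditions, 1 under a homogeneous
population, near-perfect ARI at coverage 0.2–0.4, and the AUC ordering
mixture > independent profiles > rate and mixture > rate-only mixture —
are stable across seeds. These sizes are the package's own choice of a
compact but representative regime.

## Known limitations

* The mean-field factorisation underestimates posterior variance, as
  usual; the Gibbs engine is the reference when calibrated uncertainty
  matters on small data.
* CAVI finds local optima. Soft initialisation plus restarts made every
  packaged check stable, but pathological splits remain possible at very
  low coverage; raising `n_init` is the first remedy.
* Imputation is defined only inside trained regions; genome-wide
  sliding-window imputation is out of scope.
* Components are never merged or deleted structurally; `effective_k` is a
  diagnostic count.

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_config(n_regions = 30, seed = 1))
parts <- split_train_test(sim$data, 0.5, seed = 1)
fit <- fit_methmix(parts$train, k = 10, seed = 1)
glance(fit)
preds <- impute_dataset(fit, parts$test)
evaluate_imputation(preds)
plot_profiles(fit, fit$regions[1:4])
```
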