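---
title: "Two-step genomic prediction with grouped marker variances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step genomic prediction with grouped marker variances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpgroups)
```

## The problem

Genomic prediction regresses a quantitative phenotype on thousands of SNP
dosages simultaneously and uses the estimated allele substitution effects to
predict breeding values of animals without records. The two classical
extremes are SNP-BLUP, where one shrinkage variance is shared by all markers,
and BayesA/B-type models, where every marker carries its own variance. The
first is too rigid when a trait is driven by a few large QTL; the second
spreads the information very thin — each marker contributes a single degree
of freedom to the posterior of its own variance.

`snpgroups` implements the intermediate: markers are *grouped* by the size of
their estimated effects and each group shares a variance, so a group of $p$
markers contributes $p$ degrees of freedom to its variance posterior. The
procedure has two steps:

1. **SNP-BLUP** (model 1): $y_i = \mu + \sum_j x_{ij}\beta_j + e_i$ with
   $\beta \sim N(0, I\sigma_\beta^2)$, $e \sim N(0, I\sigma_e^2)$ and flat
   priors on both variances, fitted by single-site Gibbs sampling. Dosages
   are coded 0/1/2 and centered column-wise.
2. Markers are ranked by the variance they explain, $p_j(1-p_j)\beta_j^2$,
   chunked into groups of 150 (group 1 = largest effects), and the model is
   refitted (model 2) with $\beta_{jk} \sim N(0, \sigma_k^2)$ and
   $\sigma_k^2 \sim \chi^{-2}(\mathrm{scale}, \mathrm{df})$, where df is a
   fixed hyperparameter and the scale has a uniform$(>0)$ prior and is
   sampled from its Gamma full conditional.

Reduced panels (e.g. the top 1500 or 450 markers by model-2 effect) can be
re-grouped and refitted through `select_top()` or
`run_two_step(select_top_k = ...)`.

## Full conditionals

Writing $r_i = y_i - \mu - \sum_j x_{ij}\beta_{jk}$, each Gibbs iteration
draws, in fixed order (mean, each marker in rank order, each group variance
in index order, residual variance, scale):

* $\mu \mid \cdot \sim N\!\big(n^{-1}\sum_i (y_i - \sum_j x_{ij}\beta_{jk}),\
  \sigma_e^2/n\big)$
* $\beta_{jk} \mid \cdot \sim N\!\big(C_j^{-1} \sum_i x_{ij}\,\tilde r_{ij},\
  C_j^{-1}\sigma_e^2\big)$ with $C_j = \sum_i x_{ij}^2 +
  \sigma_e^2/\sigma_k^2$ and $\tilde r$ the partial residual excluding
  marker $j$ (maintained incrementally; a full recomputation check is
  available via `check_every`)
* $\sigma_k^2 \mid \cdot \sim \chi^{-2}\!\big((n_k + \mathrm{df})^{-1}
  (\sum_{j\in k}\beta_{jk}^2 + \mathrm{scale}\cdot\mathrm{df}),\ n_k +
  \mathrm{df}\big)$
* $\sigma_e^2 \mid \cdot \sim \chi^{-2}\!\big((n-2)^{-1}\sum_i r_i^2,\
  n-2\big)$
* $\mathrm{scale} \mid \cdot \sim
  \mathrm{Gamma}\!\big(g\cdot\mathrm{df}/2 + 1,\
  \mathrm{rate} = (\mathrm{df}/2)\sum_k 1/\sigma_k^2\big)$.

The Gamma conditional deserves a note, because the second argument is often
printed as $2/(\mathrm{df}\sum_k 1/\sigma_k^2)$: deriving it from a
uniform$(>0)$ prior on the scale against $g$ scaled-inverse-$\chi^2$
likelihood terms gives a density $\propto \mathrm{scale}^{g\,\mathrm{df}/2}
\exp(-\mathrm{scale}\cdot(\mathrm{df}/2)\sum_k 1/\sigma_k^2)$, i.e. the
printed second argument is a *scale* parameter and the rate is its
reciprocal. That is how `sample_scale()` is parameterized.

In SNP-BLUP the single common variance uses the flat-prior conditional
$\sigma_\beta^2 \mid \cdot \sim \chi^{-2}\big(\sum_j\beta_j^2/(q-2),\,
q-2\big)$, mirroring the $n-2$ degrees of freedom of the residual
conditional. With df $= 0$ and scale $= 0$ the group prior is the Jeffreys
prior $1/\sigma_k^2$; estimating the scale at df $= 0$ is rejected because
the scale then has a flat likelihood and its Gamma conditional is improper.

## Design choices

**Degrees of freedom for the common variance.** No conditional for
$\sigma_\beta^2$ is printed in the usual statements of the flat-prior model;
we use $q-2$ by symmetry with the residual's $n-2$. The grouped sampler with
one group and the matched conditional reproduces SNP-BLUP (tested), and at
realistic $q$ the $q$ vs $q-2$ convention is numerically irrelevant.

**Heritability estimator.** Per saved iteration the genomic heritability is
$h^2 = V_g/(V_g + \sigma_e^2)$ where $V_g$ is the empirical variance over
training animals of the genetic values $g_i = \sum_j x_{ij}\beta_{jk}$ at
the current state. Per-group heritabilities use the covariance
decomposition $h^2_k = \mathrm{cov}(g_{ik}, g_i)/(V_g + \sigma_e^2)$, which
allocates between-group covariance proportionally, so the $h^2_k$ sum to the
total exactly in every sample. Other estimators (e.g. based on
$\sum_j 2p_j(1-p_j)\sigma^2_{k(j)}$) exist; the empirical-variance form was
chosen because it is well defined for any state of the chain and does not
assume linkage equilibrium.

**Marker ranking score.** The ranking uses $p(1-p)\beta^2$ as stated; the
conventional additive variance carries a factor 2, which changes no ranks
(`explained_variance(..., factor2 = TRUE)` reports the conventional form).
When the marker count is not a multiple of the group size, the remainder
forms its own smaller final group and every group's $n_k$ is carried through
the sampler, so unequal sizes are handled exactly. Ties in the ranking break
by original marker position, keeping the grouping deterministic.

**Numerical safeguards.** All sampled variances are floored at $10^{-12}$.
Initialization is a neutral split: $\mu = \bar y$, $\beta = 0$,
$\sigma_e^2 = 0.5\,\mathrm{var}(y)$, $\sigma_\beta^2 =
0.5\,\mathrm{var}(y) / \sum_j 2p_j(1-p_j)$. Chains are driven by a single
seeded generator with draws consumed in a fixed documented order, so runs
are bit-reproducible. The default protocol is 50,000 iterations, 20,000
burn-in, thinning 30 (1,000 saved samples).

**Missing genotypes** are imputed to the column mean at load time, which
keeps centered columns exactly mean zero. The MAF filter keeps markers with
minor allele frequency *strictly* greater than the threshold (default 0.01).

## The pedigree baseline

`fit_animal_model()` implements the classical animal model
$y = 1\mu + a + e$, $a \sim N(0, A\sigma_a^2)$, with the numerator
relationship matrix built densely by the tabular method (desk-scale
pedigrees of up to $\sim 10^4$ individuals do not need sparse inverse
tricks). Variance components come from EM-REML: the relationship submatrix
of the phenotyped animals is eigendecomposed once and the EM expectations
(of $a'A^{-1}a$ and $e'e$ given the data, REML-adjusted for the estimated
mean) are iterated in the eigenbasis at $O(n)$ per step. EM converges
linearly and can need a few thousand iterations near flat regions of the
likelihood; since a step costs microseconds the default cap is 5,000
iterations at a relative tolerance of $10^{-6}$. The fixed point was
verified against direct maximization of the restricted likelihood.
Breeding values of animals without records follow by relationship
propagation, which for an animal with no phenotyped descendants is the
parent average — the reason pedigree BLUP is the weakest predictor for
within-family validation designs.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the study design the methods are evaluated
on: unrelated founder sires and dams (Hardy–Weinberg genotypes, counted
allele frequencies uniform on `founder_maf_range`, default 0.05–0.5), dams
nested within sires, and full-sib progeny families produced by Mendelian
gene dropping at unlinked loci. Defaults are 20 sires, 200 dams, 10 progeny
per dam (2,000 genotyped and phenotyped progeny), 2,000 markers of which 8
are causative QTL, and a narrow-sense heritability of 0.30: the last progeny
of each dam then forms a 200-animal validation set, with 1,800 animals
training the model. QTL effects are standard normal draws rescaled so the
empirical additive variance over the progeny equals the target against a
residual variance of $1 - h^2$; the QTL are members of the marker panel, so
prediction can in principle be exact.

Deliberately *not* emulated: linkage (the prediction models never use
positions, and a two-generation pedigree already induces the family
structure the hold-out design needs), imprinted or epistatic QTL,
selection, and multi-generation drift. Consequently, passing tests show the
machinery recovers the architecture it assumes — few additive QTL tagged by
genotyped markers plus family structure — not that it handles LD decay
between markers and unobserved causal variants, which in real data lowers
all accuracies and shifts the balance between the methods.

## Problem sizes used in validation

The packaged checks run the full study design (2,000 progeny, 2,000
markers) with chains of 4,000–10,000 iterations rather than the 50,000 of
the default protocol; for these posterior means the shorter chains are
converged to well within the Monte-Carlo tolerances the tests use (batch
mean standard errors of $h^2$ are below $10^{-3}$ at 50,000 iterations and
about $2\times10^{-3}$ at 10,000). Distributional checks on the conditional
kernels use $10^5$ independent draws, and the joint (Geweke-style)
validation runs a 20-animal, 10-marker, 2-group model with proper priors —
the generalized conditionals with proper-prior parameters exist exactly so
that this forward/successive-conditional comparison is available.

## Known limitations

* Single trait, intercept-only fixed effects, no repeated records.
* The grouped prior needs a sensible ranking to group on; with a poorly
  estimated step 1 (tiny training sets) the grouping is noise and the model
  reverts to SNP-BLUP-like behaviour at best.
* With the Jeffreys prior (df = 0, scale = 0) a group whose effects are all
  essentially zero can collapse to the variance floor; this is the known
  absorbing behaviour of Jeffreys priors in variance mixtures and is the
  reason the prior-df sensitivity analysis exists.
* EM-REML handles one random effect; pedigrees with tens of thousands of
  individuals would want sparse-inverse methods that are out of scope here.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(seed = 1)
geno <- filter_maf(sim$genotypes, 0.01)
split <- holdout_last_progeny_per_dam(sim$pedigree, animal_ids(geno))
train <- center_genotypes(subset_animals(geno, split$train_ids))
phen <- dplyr::filter(sim$phenotypes, id %in% split$train_ids)

fit1 <- run_snp_blup(train, phen, chain_config(4000, 1500, 5, seed = 1))
groups <- tidy(fit1) |>
  dplyr::transmute(marker_id, score = explained_variance) |>
  assign_groups(group_size = 150)
fit2 <- run_grouped(train, phen, groups, df = 0, scale = 0,
                    chain = chain_config(4000, 1500, 5, seed = 1))

pbv <- predict_pbv(fit2, subset_animals(geno, split$validation_ids))
true_accuracy(pbv, sim$true_bv)
heritability_report(fit2)
plot_group_h2(fit2)
```
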