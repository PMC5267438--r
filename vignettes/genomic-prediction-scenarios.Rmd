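---
title: "Evaluating genomic prediction scenarios in composite sheep populations"
author: "gsheval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating genomic prediction scenarios in composite sheep populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsheval)
```

## The problem

Composite terminal-sire sheep populations descend from several founder
breeds and show admixed cluster structure. Implementing genomic selection
in such a population raises design questions that are hard to answer on
real data alone, because the answers are confounded with the particular
families that happen to be genotyped: which genomic relationship matrix
to fit, whether population structure should be removed from the
phenotypes, and how optimistic a validation design is allowed to be.
`gsheval` implements the full evaluation pipeline and a population
simulator rich enough to exercise every branch of it, so each design can
be compared under known truth.

## Model

The evaluation is two-stage. First, phenotypes are adjusted for
systematic and contemporary-group (CG) effects by ordinary least squares;
the CG is the joint flock x birth-year x sex x mob level fitted as a
single factor. Second, GBLUP is fitted to the residuals:

$$y = 1\mu + Wa + e, \qquad
\mathrm{var}(a) = K\sigma_g^2, \quad \mathrm{var}(e) = I\sigma_e^2,$$

where every animal in the kernel $K$ enters the random effect and only
phenotyped animals enter the incidence matrix $W$; candidates without
records receive molecular breeding values (mBVs) through their kernel
relationships. A joint fixed-and-random fit is deliberately not offered:
the two-stage route matches how large sheep evaluations separate the
fixed-effect model (run once, centrally) from repeated genomic analyses.

The kernels are:

* `GB0` — VanRaden method 1,
  $G = (M-2P)(M-2P)'/(2\sum_i p_i(1-p_i))$, with observed counted-allele
  frequencies. With observed frequencies the centred dosages sum to zero
  per SNP, so each row of $G$ sums to zero — relationships are expressed
  relative to the current genotyped population.
* `GBBP` — the same formula with base-population frequencies estimated
  per SNP by generalized least squares,
  $\hat p = (1'A^{-1}m)/(2\,1'A^{-1}1)$, using the pedigree matrix $A$
  as the drift covariance. This is an equivalent-intent, openly specified
  replacement for proprietary indirect algorithms; on founder-only data
  it returns the observed founder frequency exactly.
* `GB10`, `GB20` — the polygenic blend $(1-w)G + wA$ with $w$ = 0.10 or
  0.20, equivalent to a residual polygenic effect. The published weights
  "10 and 20" are percentages, implemented as fractions.

Variance components come from average-information REML on the adjusted
phenotypes with the scenario kernel. The solver eigen-decomposes the
(ridged) kernel once, making each AI iteration O(n); it starts from an
equal split of the phenotypic variance, halves steps that leave the
parameter space, floors variances at $10^{-8}$ of the phenotypic
variance, declares convergence when successive $h^2$ change by less than
$10^{-6}$ (at most 200 iterations), and finishes with a one-dimensional
profiled-likelihood polish so the reported estimate sits at the
restricted-likelihood maximum to optimiser precision rather than the
iteration stop rule. The $h^2$ standard error comes from the inverse AI
matrix by the delta method. The $h^2$ used for accuracy scaling is
estimated from the full data (training plus validation), matching how
published evaluations estimate heritability from the same dataset.

## Validation designs and metrics

Fourteen named scenarios are registered (`scenarioRegistry()`). Forward
validation trains on birth years before the cutoff (default 2014) and
validates on the cutoff cohort. Random cross-validation uses five
balanced folds. k-means designs cluster animals with Hartigan-Wong
k-means on the ten leading principal components of `GB0` (k-means needs
coordinates, not a distance matrix; the component count is
configurable), keeping the best of 25 restarts. Hierarchical designs cut
an agglomerative tree of either the kernel-induced metric
$d_{ij} = \sqrt{G_{ii}+G_{jj}-2G_{ij}}$ or the Euclidean genotype
distance; complete linkage is the default (average and Ward are
options), and clusters below a minimum size are excluded rather than
merged. Validation groups at or below `minValid` animals (default 150,
the usual reporting threshold for real evaluations) are skipped and
logged; retained groups are combined by record-weighted means. At
simulation scale we override `minValid` downwards and say so — the
default expresses reporting practice, not a statistical necessity.

Per validation group the package reports: observed accuracy
$r = \mathrm{cor}(\mathrm{mBV}, y_{adj})/\sqrt{h^2}$ (unclipped — values
beyond 1 are possible by sampling and are reported as computed);
theoretical accuracy per animal from the inverted mixed-model equations,
$\mathrm{AccT}_i = \sqrt{1 - \mathrm{PEV}_i/(\sigma_g^2 K_{ii})}$;
expected accuracy $\mathrm{AccE} = \sqrt{N_p h^2/(N_p h^2 + M_e)}$ with
$M_e = 2 N_e L/\log(4 N_e L)$; the effective number of progeny
$\mathrm{ENP} = r^2\alpha/(1-r^2)$, $\alpha = (4-h^2)/h^2$; and the
spread factor $K = r\,\sigma_A/\mathrm{sd}(\mathrm{mBV})$, equal to 1
for well-calibrated mBVs.

Three conventions deserve a note. The logarithm in $M_e$ is natural
(configurable): the usual derivation of the effective-loci formula uses
natural logs, and the choice is visible in the `logBase` argument. $N_e$
is an input, not an estimate from linkage disequilibrium;
`pedigreeNe()` offers a census stand-in, $4N_mN_f/(N_m+N_f)$ with
parents counted per generation (distinct sires and dams per drop year
scaled by the mean generation interval). And $r$ entering ENP and K is
the scenario's observed accuracy for the trait.

## The simulator

`simulatePopulation()` emulates the statistical structure the analysis
assumes, not a particular genome:

* **Breeds.** Per-SNP ancestral frequencies are uniform on
  (0.05, 0.95); breed frequencies follow the Balding-Nichols model with
  an Fst-like divergence parameter (default 0.15, a moderate between-breed
  divergence for sheep), and founders are drawn in Hardy-Weinberg
  proportions within breed.
* **Pedigree.** Founders occupy the first two birth years (2007-2008 by
  default); recorded progeny are born 2010-2014. Every dam aged two or
  more produces one lamb per year; sires aged one or more are drawn with
  family sizes 1 + Poisson(16), reproducing the ~17 progeny-per-sire
  half-sib structure the cluster designs exploit.
* **Genome.** 26 chromosomes of equal genetic length summing to 26
  Morgans, uniform SNP positions (1 cM per Mb), crossover counts Poisson
  per chromosome, uniform crossover positions. This yields non-zero
  linkage disequilibrium without a coalescent.
* **Trait.** A configurable number of panel SNPs (default 300 of 2000)
  receive i.i.d. normal effects, rescaled so the realized TBV variance
  equals the configured $\sigma_A^2$ exactly. Phenotypes are
  $y = \mu + \mathrm{CG} + \mathrm{TBV} + e$ with
  $\sigma_e^2 = \sigma_A^2(1-h^2)/h^2$ and CG effects of SD 1 drawn at
  the joint flock x year x sex x mob level (so the default fixed-effect
  model is exactly right for the generated data — deviations between the
  fitted and generating model are an experiment the user sets up
  deliberately, not an accident of the defaults).

What the simulator does **not** reproduce: coalescent-accurate LD decay,
selection or assortative mating (matings are random within the
availability rules), genotype-calling error, and the real population's
unequal breed proportions. Passing tests therefore demonstrate that the
pipeline's algebra and designs behave as specified under the assumed
model — not that any particular accuracy level transfers to a real
flock.

## Numerical choices

* Kernels are ridged by $10^{-6}$ of their mean diagonal before any
  factorisation; G is accepted as PSD up to an eigenvalue of $-10^{-8}$.
* The Hardy-Weinberg screen is the 1-df chi-square (p < 1e-15 removal);
  at evaluation sample sizes an exact test changes nothing while costing
  more. Monomorphic SNPs return p = 1 by convention and are caught by
  the MAF rule instead.
* MAF is computed from observed calls after call-rate masking and
  before imputation, so imputation can never rescue a SNP.
* Phenotype outlier statistics include the candidate record and run in
  a single pass; the CG-size rule is re-applied once afterwards. A
  consequence worth knowing: with the candidate included, a 3-SD
  outlier is only detectable in groups of 11 or more records.
* PCA scores carry the scale $\sqrt{\lambda_k}$ so the full score
  matrix reconstructs G; the sign convention makes each component's
  largest-magnitude loading positive.
* `GB0`'s observed-frequency centring shifts relationships relative to
  pedigree expectations in drifted or related populations; comparisons
  against pedigree values (e.g. parent-offspring 0.5) are exact only
  under base-population frequencies, which is why `GBBP` exists.

## Problem sizes used by the tests

The test suite exercises the pipeline at sizes a desk machine handles
comfortably: hand-checkable toys (3-5 animals) for exact algebra;
~400-animal two-breed populations for structure-sensitive behaviour;
~2,000-record populations for heritability recovery and the agreement
between theoretical accuracy and realized correlation with true breeding
values; ten ~800-record replicates for K-factor calibration and the
qualitative ordering of validation designs (random CV highest,
within-cluster forward validation lowest). These sizes are the package's
chosen trade-off between Monte-Carlo error and convenience.

## Known limitations

* The two-stage fit (pre-adjust, then REML/GBLUP on residuals) loses the
  degrees of freedom absorbed by the fixed effects, giving a small
  downward bias in $\hat h^2$ (a few hundredths at ~60 CG levels per
  2,000 records) relative to a joint animal model. The same bias then
  inflates observed accuracies and K slightly, since both divide by
  functions of $\hat h^2$.
* The expected-accuracy formula assumes unrelated training and
  validation individuals; under family-structured forward validation its
  agreement with realized accuracy depends strongly on the $N_e$
  definition. With the generation-scaled census $N_e$ the agreement at
  desk scale is within about 0.1 — adequate for sanity checks, not for
  calibration.
* The naive mean-dosage imputer is a single-site stand-in: it preserves
  frequencies and adds no spurious relationship signal, but makes no use
  of linkage, unlike haplotype-based imputation software.
* Single-trait only; maternal and permanent-environment effects,
  multi-trait REML and Bayesian whole-genome regression are out of
  scope.
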