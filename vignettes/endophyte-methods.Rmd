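---
title: "Methods: endophyte communities across plant functional groups"
author: "leafEndophytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: endophyte communities across plant functional groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical methods it
implements, the choices made where the design was genuinely open, and
what the synthetic-data studies in the test suite do and do not
demonstrate.

## The data model

The central object is an `EndophyteExperiment`, a
`SummarizedExperiment` whose `counts` assay holds OTU abundances (OTUs
as rows, samples as columns), whose `colData` maps each sample to a host
species, a plant functional group and a replicate index, and which
additionally carries a species-level trait table and a host phylogeny.
Surveys of this kind sample a fixed number of replicate leaf pools per
host species; the default study design is four functional groups of
6 (grasses), 4 (legumes), 32 (dicot forbs) and 3 (monocot forbs) species
with 3 replicates each, i.e. 45 species and 135 samples.

Abundance tables may hold read counts or relative abundances; a flag on
the object records which. Every analysis that is sensitive to library
size (Bray–Curtis distances, SPEC–OCCU) converts samples to proportions
first by default. Whether the original study rarefied or
proportion-normalized is not documented in this literature; per-sample
proportions are the default here because they use all reads and make the
specificity statistic library-size-invariant, and a raw-count mode is
retained for sensitivity analysis.

## Alpha diversity

Richness is the number of OTUs with positive abundance; Shannon
diversity is $H = -\sum_i p_i \ln p_i$ in nats (natural log, the vegan
convention). Per-sample values are averaged over a species' replicates
before any between-group inference, so the experimental unit is the host
species (consistent with trait models on $N = 45$ species). Group
differences use one-way ANOVA with Tukey HSD and a compact letter
display at $p < 0.05$; with a Gaussian identity link this is equivalent
to the generalized-linear-model formulation common in this literature.
Trait models are deliberately univariate — one Gaussian linear model per
trait and response — because the five traits are strongly collinear
across functional groups; a joint model would not have interpretable
coefficients at $n = 45$.

## Beta diversity

Bray–Curtis dissimilarity, PCoA and PERMANOVA are implemented from
first principles (and cross-checked against vegan in the tests):

* PCoA is the eigendecomposition of $-\tfrac12 J D^2 J$; coordinates
  are eigenvectors scaled by $\sqrt{\lambda}$. Negative eigenvalues are
  reported but excluded from coordinates; no Cailliez/Lingoes correction
  is applied by default because the corrected axes change distances,
  and the variance-explained proportions are computed over positive
  eigenvalues only.
* PERMANOVA uses Anderson's partition:
  $SS_\text{total} = \sum_{i<j} d_{ij}^2 / n$, within-group sums over
  within-group pairs, $F = (SS_b/(g-1))/(SS_w/(n-g))$, and
  $p = (1 + \#\{F_\pi \ge F\})/(1 + n_\pi)$ under uniform label
  permutations. On Euclidean distances of one-dimensional data this
  pseudo-F equals the classical ANOVA F exactly, which the tests check
  to $10^{-8}$. For very small designs an exact mode enumerates all
  distinct labelings instead of sampling.
* Pairwise PERMANOVA runs the one-factor test on every unordered group
  pair's sub-matrix. Raw p-values are what comparable pairwise tools
  report; Holm-adjusted values are reported alongside as a conservative
  default, without hiding the raw ones.
* The ordination/PERMANOVA unit is the host species by default (mean of
  replicate proportion vectors; pooling counts is available), matching
  the species-level pair design downstream; permutation counts default
  to 999 and a seed is required so runs are reproducible.

## SPEC–OCCU marker OTUs

For OTU $S$ and group $H$, specificity is the mean abundance of $S$
across group-$H$ samples divided by the sum of those group means over
all groups, and occupancy is the fraction of group-$H$ samples
containing $S$ (presence = abundance strictly greater than zero; no
minimum-count filter). Specificity therefore sums to one over groups
for every OTU present anywhere, so with the dual threshold of 0.7
(inclusive) an OTU can mark at most one group — the implementation
asserts this. Guild composition of a group's markers is weighted by
marker abundance by default (a count-weighted mode exists), and the
marker functional ordination collapses each sample to its trophic-mode
profile over marker OTUs before reusing the Bray–Curtis/PCoA/PERMANOVA
machinery.

## The cross-group pair design and distance mixed model

One row per unordered pair of species from *different* functional
groups: with group sizes 6/4/32/3 that is
$6{\cdot}4 + 6{\cdot}32 + 6{\cdot}3 + 4{\cdot}32 + 4{\cdot}3 + 32{\cdot}3 = 470$
rows. The response is the species-level Bray–Curtis dissimilarity; the
predictors are the absolute trait differences (the one-dimensional
Euclidean distance) for LMA (g/cm²), leaf N (mg/g), C:N, water content
(% of fresh weight) and plot abundance, plus the cophenetic distance on
the host tree. Predictors are z-standardized by default (the constants
are recorded); standardization affects coefficients, not the R²
ordering.

Because each row names two species, "species identity as a random
factor" is a multi-membership effect: a latent intercept per species
entering every row that species belongs to, with a single shared
variance. With membership matrix $M$ (two 1s per row),

$$y = X\beta + Mu + e, \qquad u \sim N(0, \sigma_u^2 I), \qquad
  e \sim N(0, \sigma_e^2 I),$$

so $V = \sigma_e^2 I + \sigma_u^2 M M^\top$. The fit is exact REML: the
Woodbury identity and a one-off eigendecomposition of $M^\top M$ reduce
the profiled criterion to a one-dimensional optimization over
$\lambda = \sigma_u^2/\sigma_e^2$, with the boundary $\sigma_u^2 = 0$
checked explicitly (at which the fixed estimates equal ordinary least
squares — a test asserts this to $10^{-6}$). The solver is verified
against lme4's modular interface with the same membership matrix
supplied as a custom random-effect design; agreement is to $10^{-6}$ in
coefficients, variance components and standard errors. Two *separate*
crossed intercepts (one per pair column) were rejected because the
column assignment of a species within an unordered pair is arbitrary.

Per-predictor F statistics are squared t statistics (1 numerator df)
with a Satterthwaite-style denominator df computed by the delta method
on the two-parameter REML information (numerical Hessian and gradients;
when $\hat\sigma_u^2$ is at the boundary the residual df $n - p$ is
used). An alternative permutation test is not implemented; under a
pure-noise response the Satterthwaite p-values are calibrated (checked
by simulation in the tests).

Marginal R² follows the fixed-effects-variance convention:
$\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + 2\sigma_u^2 +
\sigma_e^2)$, the factor 2 reflecting the two memberships per row;
conditional R² adds the random-effect variance to the numerator and is
reported but not partitioned. Hierarchical partitioning refits all
$2^k$ predictor subsets with the same random structure and assigns each
predictor the Chevan–Sutherland average of its R² increments. The raw
increments sum to the full model's marginal R² exactly (a telescoping
identity, asserted to $10^{-6}$); negative averages, which correlated
predictors can produce, are clipped to zero in the reported column with
the raw value kept alongside. Reported F values are marginal
(each coefficient tested in the full model), not sequential.

## The synthetic community generator

`simulateCommunity()` emulates the features of the field design the
analyses rely on:

* **Traits** are species-level constants drawn from group means plus
  Gaussian noise (replicate leaf pools in such surveys come from
  different individuals than the trait measurements, so replicate-level
  trait noise is not modeled). Defaults are typical alpine-meadow
  values, e.g. grass LMA 0.0062 g/cm² vs forb ~0.004, legume leaf N
  32 mg/g, monocot forbs with the highest water content, grasses most
  abundant.
* **Turnover** follows a Gaussian-niche gradient model: each species
  sits at $g_s = \text{strength} \times z(\text{driver trait}) +
  \text{jitter}$, and each background OTU responds to the gradient
  through a Gaussian niche (breadth 1 gradient unit, lognormal base
  abundances). `turnover_strength = 0` makes composition independent of
  traits (the calibration null); strength 2 is the "strong turnover"
  regime used in the recovery studies. Species-specific jitter
  (sd 0.25) keeps species individuality even at strength 0.
* **Markers** for group $H$ are planted in a fixed random subset of
  $\lceil \text{occupancy} \times n_H \rceil$ group samples at a
  relative abundance calibrated so the group mean hits
  `marker_mean_abundance` (default 0.02), and leak into other groups'
  samples at the abundance that makes the *expected* specificity equal
  the target: $\text{leak} = m(1-t)/((G-1)t)$. Infeasible
  combinations — a specificity target of 1 with nonzero leakage, or
  markers claiming more than ~95% of a sample — are rejected with an
  explanation.
* **Counts** are multinomial draws of `sequencing_depth` reads
  (default 10⁴), or Dirichlet-multinomial with concentration
  `composition / dispersion` when overdispersion is requested — the
  standard amplicon noise model.
* **Trees** are random coalescents; a flag builds per-group subtrees
  joined at the root so phylogeny can be made collinear with groups
  when the phylogeny term of the mixed model is under study.

Marker-recovery studies run with `turnover_strength = 0`. This is a
property of the statistic, not a convenience: under strong trait-driven
turnover, background OTUs whose niches sit at a gradient extreme
occupied by a single group genuinely satisfy the specificity/occupancy
definition — they *are* markers — so the planted set is the complete
truth only when the background carries no group signal of its own.

What passing these studies does **not** show about real data: the
generator has no sequencing error, chimeras, taxonomic mis-assignment,
compositional correlations among OTUs, spatial or temporal structure,
or trait measurement error; its group trait contrasts are cleanly
Gaussian. Recovery and calibration results are statements about the
implementation under the stated generative model, not about field
performance.

## Numerical choices and degenerate inputs

* Distance matrices are validated for symmetry (10⁻¹²), zero diagonal
  and non-negativity; an all-zero community is a hard error naming the
  sample, as is a sample lacking metadata or a non-numeric cell (with
  its row/column).
* OTU columns that are zero everywhere are dropped on load with a
  warning; OTUs absent everywhere are likewise excluded from SPEC–OCCU
  with a message.
* Permutation p-values use the add-one estimator and count ties
  ($F_\pi \ge F - 10^{-12}$) as exceedances.
* Zero-variance predictors are skipped (alpha trait models) or raise a
  rank-deficiency error naming the aliased columns (distance LMM).
* Groups with fewer than two species are excluded from group tests with
  a message; PERMANOVA refuses groups of size one.

## Problem sizes used by the automated studies

The test suite and acceptance script size their Monte-Carlo studies at
desk scale: 100 seeds for planted-marker recovery at depth 10⁵, 500
(tests) / 300 (script) label-shuffled null communities of 12 samples
for PERMANOVA calibration at 199 permutations, 100 (tests) / 60
(script) end-to-end communities for the lma-importance study, and the
full default design (45 species, 135 samples, 470 pairs, 64 subset
REML fits) everywhere a single realization suffices. These sizes give
binomial standard errors comfortably inside the asserted bands.

## Known limitations

* The distance LMM treats pair rows as conditionally independent given
  the two species effects; higher-order dependence among pairs sharing
  no species is ignored, as in standard multiple-regression-on-
  distance-matrices practice.
* Satterthwaite df are a delta-method approximation; for severely
  unbalanced designs a permutation test would be more robust.
* Hierarchical partitioning refits $2^k$ models; it is exact but not
  intended for more than 12 predictors.
* The compact letter display uses insert-and-absorb, which is adequate
  for the handful of groups in this design but not optimized for many
  groups.
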