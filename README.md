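# leafEndophytes

Community analysis of leaf fungal endophytes (LFEs) across host plant
functional groups.

Leaf fungal endophytes live asymptomatically inside leaf tissue, and the
communities they form differ between host species growing in the same
habitat. When host species are organized into *functional groups* —
grasses, legumes, dicot forbs, monocot forbs — two questions follow: do
the groups carry distinguishable endophyte communities, and which host
attributes (leaf functional traits, plant abundance, phylogeny) explain
the turnover between them? This package implements that full analysis
for OTU-table data from amplicon surveys, together with a synthetic
community generator so every stage can be validated against a known
truth.

## What it computes

Given an OTU abundance table (samples × OTUs), per-sample host metadata
(species, functional group, replicate), a species-level trait table,
FUNGuild-style trophic annotations and a host phylogeny:

* **Alpha diversity** — per-sample OTU richness and Shannon diversity
  *H* = −Σ *p*ᵢ ln *p*ᵢ, aggregated to species and group level, with
  one-way ANOVA + Tukey letters across groups and univariate linear
  models of each trait on species-level diversity.
* **Beta diversity** — Bray–Curtis dissimilarity
  *d*ᵢⱼ = Σ|*x*ᵢ−*x*ⱼ| / Σ(*x*ᵢ+*x*ⱼ), principal coordinates analysis,
  and one-factor PERMANOVA (Anderson's pseudo-F, label-permutation p,
  optional exact enumeration) with pairwise group comparisons and Holm
  adjustment — all implemented from first principles and cross-checked
  against vegan in the test suite.
* **Marker OTUs** — per-(OTU, group) specificity
  (group-mean abundance over the sum of group means) and occupancy
  (fraction of the group's samples containing the OTU); OTUs with both
  ≥ 0.7 are that group's markers. Marker sets are profiled by trophic
  guild and ordinated at guild level (PCoA + pairwise PERMANOVA).
* **Distance mixed model** — one row per cross-group species pair:
  Bray–Curtis community dissimilarity regressed on |Δ| of five scalar
  predictors (LMA, leaf N, C:N, water content, plot abundance) plus
  cophenetic phylogenetic distance, with a multi-membership random
  intercept for the two species in each pair (shared variance, exact
  REML via the Woodbury identity). Each predictor's contribution to the
  marginal R² is isolated by hierarchical (Chevan–Sutherland)
  partitioning over all 2⁶ predictor subsets.
* **Synthetic data** — grouped communities with planted group-specific
  marker OTUs (controllable specificity/occupancy targets) and
  trait-driven compositional turnover, plus exchangeable null
  communities for calibration studies.

## Worked example

```r
library(leafEndophytes)

cfg <- simConfig(seed = 42)              # 4 groups, 6/4/32/3 species, 3 reps
sim <- simulateCommunity(cfg)
ee  <- sim$experiment
ee
#> EndophyteExperiment: 170 OTUs x 135 samples
#>   45 host species in 4 functional group(s): dicot_forb, grass, legume, monocot_forb
#>   abundances: counts
#>   traits: 45 species;  tree: present ;  guilds: annotated

alphaDiversity(ee)
#> AlphaDiversity: 135 samples, 45 species, 4 groups
#>      group_id n_species richness_mean richness_se richness_letters ...
#>    dicot_forb        32      151.7500    1.571119                a
#>         grass         6      127.5556    3.185228                b
#>        legume         4      154.8333    1.618756                a
#>  monocot_forb         3      155.3333    2.516611                a

mk <- filterMarkers(specOccu(ee))        # dual 0.7 threshold
table(mk$group_id)
#>   dicot_forb        grass       legume monocot_forb
#>            5           27            5            5

bc  <- brayCurtis(ee, level = "species")
ph  <- copheneticDistances(hostTree(ee), species = rownames(bc))
des <- buildPairDesign(bc, speciesTraits(ee), ph)
nrow(des)                                # 470 cross-group species pairs
fitDistanceLmm(des)
#> Distance LMM (n = 470): marginal R2 = 0.8472, conditional R2 = 0.9591
#>   variance components: species 0.00642, residual 0.0047
#>      predictor   estimate       se         F    df          p
#>      abundance  0.0004599 0.004005 1.318e-02 446.7  9.086e-01
#>         n_conc -0.0114855 0.006420 3.201e+00 461.2  7.425e-02
#>       cn_ratio -0.0009184 0.005220 3.095e-02 458.9  8.604e-01
#>  water_content  0.0056406 0.005684 9.846e-01 462.5  3.216e-01
#>            lma  0.3089793 0.008862 1.216e+03 384.7 3.984e-121
#>          phylo -0.0018240 0.005051 1.304e-01 461.2  7.182e-01
hierarchicalPartition(des)               # per-predictor individual R2
```

The group table above reads: each functional group's mean species-level
OTU richness ± its standard error, with shared letters marking groups
that are statistically indistinguishable at p < 0.05 (here grass alone
differs). The marker table shows 5 planted markers per group plus, in
grasses, background OTUs that this seed's trait-driven turnover made
genuinely group-specific and ubiquitous — SPEC-OCCU markers are defined
by the statistic, not by the simulation truth (the methods vignette
discusses this). In the mixed-model output the simulation's planted
driver (LMA distance) dominates: its F is three orders of magnitude
above the rest, and `hierarchicalPartition()` assigns it an individual
R² of 0.83 of the 0.85 total marginal R², with the five remaining
predictors sharing the rest.

A complete run — input files (or a simulation block), alpha, beta,
markers and the distance model, with every output hashed into a
manifest — is one call:

```r
runPipeline(list(outdir = "run1", seed = 42, simulate = list(seed = 42)))
```

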