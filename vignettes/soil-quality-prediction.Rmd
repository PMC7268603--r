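---
title: "Predicting soil quality from bacterial communities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting soil quality from bacterial communities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`microsoilq` predicts land use, soil physico-chemical variables and
guideline-based soil-quality categories from soil bacterial community
composition. This vignette is the package's account of the statistical
machinery: the models and their assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, the
numerical conventions, and the design decisions taken where more than
one reasonable choice existed.

## The prediction chain

The pipeline assumes a replicate-level OTU count table (several soil
cores per site), per-sample metadata (site, land use), and per-site
measurements of seven soil variables: pH, carbon (%), total nitrogen
(%), anaerobically mineralizable nitrogen (AMN, mg/kg), Olsen P (mg/kg),
macroporosity (% v/v) and bulk density (t/m³). Upstream read processing
and OTU calling are out of scope; the OTU table is the entry point.

1. *Rarefaction* (`rarefy()`): each sample is subsampled without
   replacement (hypergeometric) to a common depth, 2000 reads by
   default. Samples below the depth cannot be equalized and are dropped
   with a warning rather than an error, since surveys routinely lose a
   few shallow samples. Rarefaction removes depth as a confounder at the
   cost of discarding reads.
2. *Replicate averaging* (`average_replicates()`): the arithmetic mean
   of the (rarefied) replicate rows gives one community per site. This
   matches chemistry measured on composite cores: the community and the
   chemistry then describe the same support.
3. *Bray–Curtis dissimilarity* (`bray_curtis()`) between all site
   pairs, in [0, 1]; with equal-depth rows it is invariant to a common
   rescaling, so absolute and relative abundances give the same matrix.
4. *PERMANOVA* (`permanova()`, `pairwise_permanova()`): one-way
   partitioning of the squared dissimilarities between and within
   groups, with pseudo-F significance by free permutation of labels and
   the (1 + #{F* ≥ F})/(1 + n_perm) convention, so p is never 0.
   Pairwise tests adjust over the group pairs, Bonferroni by default
   (Benjamini–Hochberg available): the conservative choice, since the
   pairwise p-values feed a significance claim, not a ranking.
5. *Ward clustering and cut selection* (`ward_cluster()`,
   `select_cut_level()`): agglomerative clustering under the Ward
   criterion in the Ward.D2 convention (Lance–Williams on squared
   dissimilarities), the modern default. Sites are clustered twice: by
   community (Bray–Curtis) and by chemistry. Chemistry is standardized
   to zero mean and unit variance per variable before Euclidean
   distance, because the seven variables have incommensurate units; a
   pH unit must not weigh less than a mg/kg of AMN.
6. *Indicator OTU selection* (`indicator_scores()`,
   `select_indicator_otus()`): for OTU k and cluster g, specificity
   A(k,g) is the group-size-corrected share of the OTU's mean abundance
   concentrated in g (A sums to 1 over clusters), and fidelity B(k,g)
   is the fraction of g's sites where the OTU occurs. An OTU is kept if
   some cluster gives it A and B strictly above the thresholds (0.4 by
   default; 0.5 is conventional for finer cluster sets). Specificity is
   abundance-based and fidelity presence-based by default; a
   `specificity = "presence"` switch gives the fully presence-based
   variant. Only single-OTU indicators are evaluated; indicator
   combinations are out of scope, since selection feeds a feature list,
   not an inference.
7. *Probabilistic PCA* (`ppca_em()`): the latent model x = Wz + μ + ε
   with isotropic noise, fit by EM on standardized variables, missing
   cells marginalized in the E-step. On complete data the fitted
   subspace equals classical PCA (the test suite checks principal
   angles below 1e−6), which makes the contract verifiable; a full
   Bayesian treatment with ARD priors would add machinery without
   changing the axis scores the pipeline needs. Two components are
   retained by default — the first two axes carry the interpretable
   fertility/compaction contrasts, and downstream models treat the
   scores as just two more regression targets.
8. *Random forests* (`fit_classifier()`, `fit_regressor()`): 500 trees,
   mtry = ⌊√p⌋ for classification and max(1, ⌊p/3⌋) for regression —
   the conventional defaults. Sites are split 80/20 by stratified
   sampling within land use (nearest-integer rounding, ties up), so
   rare land uses keep test representation. Disjointness of train and
   test is asserted before every fit.
9. *Evaluation*: classification by confusion matrix and accuracy;
   regression by OLS of held-out *predicted on actual* values. The
   predicted-on-actual direction treats the identity line as the
   perfect-prediction reference, so shrinkage of the forest's
   predictions shows up as a slope below 1 rather than above it; the
   opposite regression direction is a one-line change if preferred.
   Adjusted R² uses 1 − (1 − R²)(n − 1)/(n − 2), the form for a
   single-predictor regression.
10. *Permutation importance* (`permutation_importance()`): mean relative
    error increase (MSE for regression, 1 − accuracy for
    classification) when one feature's values are permuted in the
    held-out data, times 100 — an explicit, library-independent analog
    of the usual % increase in MSE. Held-out data is used rather than
    out-of-bag predictions so the computation does not depend on any
    forest internals. The top 15 features per model are aggregated by
    phylum, and cross-model overlap of top OTUs is tabulated.
11. *Quality scoring* (`assign_category()`, `score_table()`): values are
    binned by four breakpoints into very low / low / normal / high /
    very high. A prediction is *correct* (same category as truth),
    *opposite* (same distance from the optimal category but on the
    other side), *better* (strictly closer to the optimum than the
    truth) or *worse* (anything else). The optimal category defaults to
    "normal" for every variable and is overridable per variable.

### Choosing the dendrogram cutting level

`select_cut_level()` computes, for every candidate k, the mean
silhouette width, the Pearson correlation between the dissimilarities
and the binary different-cluster indicator (lower triangle), and — when
an OTU table is supplied — the species-fidelity profile (how many OTUs
reach an indicator value of 0.25, and their summed indicator value).
Candidates whose smallest cluster falls below `min_cluster_size` are
excluded so every cluster keeps enough sites for stratified modelling.
The chosen k is the candidate that is best on the most criteria.

Vote ties are broken by the higher mean silhouette, then by the smaller
k. The binary matrix correlation is a point-biserial correlation and is
systematically maximized by coarse, balanced splits: on data with g
planted, well-separated groups it typically peaks below g while the
silhouette peaks at g. A plain smallest-k tie-break therefore
under-splits; with the silhouette tie-break, the selection recovers the
planted number of groups in over 90% of the package's 50-replicate test
corpus. The full diagnostics table is always returned for audit, and
judgment can override the vote by cutting at any k with `cut_tree()`.

### Dunn's test

Chemistry clusters are characterized by Dunn's rank-based multiple
comparisons: mid-ranks over all observations, the tie-corrected variance
N(N+1)/12 − Σ(t³ − t)/(12(N − 1)), two-sided normal p-values and
Bonferroni adjustment over all cluster pairs. The z statistics are
checked in the tests against an independent rank computation.

## The synthetic-data generator

`generate_scenario()` produces surveys with the structure the analysis
assumes, with full ground truth for recovery tests.

*Chemistry.* Each site's seven variables are drawn from a multivariate
normal whose mean depends on the site's land use (or, when cluster
centres are supplied, its latent chemistry group). Default per-land-use
means are chosen as plausible for temperate surveyed soils — indigenous
forest acidic and organic (pH 5.4, C 8%), horticulture limed,
phosphorus-enriched and compacted (pH 6.3, Olsen P 60 mg/kg, bulk
density 1.25 t/m³), pastoral grassland intermediate with high N — with
SDs (0.35 pH units, 1.5% C, 0.10% TN, 30 mg/kg AMN, 15 mg/kg Olsen P,
5% macroporosity, 0.12 t/m³ BD) wide enough that land uses overlap, as
they do in real surveys. Macroporosity and bulk density are negatively
correlated (−0.7 by default), the compaction signature. Values are
generated on natural scales and clipped to physical ranges (pH to
[3, 10], percentages to [0, 100], concentrations and BD positive)
because the quality thresholds operate in natural units. Cells are then
masked completely at random at `missing_chem_rate` (default 5%) to
exercise the missing-data path of the PPCA; real missingness is rarely
this benign, which is one reason imputation quality on real data should
be checked rather than assumed.

*Counts.* Site-level expected relative abundances follow a softmax
(multinomial-logit) model: per-OTU baselines drawn N(0, 1.5), plus, for
each of `n_responsive_otus` responsive OTUs, a coefficient of magnitude
`effect_size_chem` on one standardized chemistry variable (pH drawn with
weight 0.3 by default — pH is the dominant driver of soil bacterial
composition — the rest uniform) and a land-use offset of magnitude
`effect_size_landuse`. The softmax guarantees a valid composition for
any coefficients. Replicate counts are Dirichlet-multinomial
(concentration = `overdispersion` × expected composition, default 200)
with Poisson(depth_mean) total reads: replicate soil cores are
overdispersed relative to a plain multinomial, and the pipeline's
replicate averaging only makes sense if there is replicate-level noise
to average away.

*What it does not emulate.* No spatial autocorrelation across a
geographic gradient, no taxonomy errors or chimeras, no
sequencing-run batch effects, no non-random missingness, and the
synthetic taxonomy assigns phyla at random. Passing tests on this
generator therefore demonstrate that the machinery recovers known
structure under the stated model — not that real soils satisfy that
model. The headline benchmark numbers below are upper bounds of a kind:
real surveys carry nuisance variation the generator deliberately omits.

## Reference simulation studies

Three fixed scenarios serve as standing benchmarks (run by the test
suite and `scripts/acceptance.R`); sizes are chosen to exercise the full
chain at desk scale.

- `sim_landuse_benchmark()`: 300 sites in unbalanced land-use
  proportions (10/12/23/55%), 5 replicates, 500 OTUs with 60 responsive,
  depth 2000, land-use effect 2 — a strong-signal survey. Full chain
  with the community dendrogram cut at k = 5 and indicator thresholds
  0.4/0.4; the metric is held-out land-use accuracy, median over five
  seeds.
- `sim_chem_cluster_benchmark()`: 200 sites in the two non-pastoral
  managed land uses; chemistry drawn around four planted regimes
  (compacted/high-P, fertile, acidic organic, alkaline low-fertility)
  whose centres differ by at least 3 within-cluster SDs on several
  variables (within-cluster SDs are half the survey defaults), with
  composition strongly coupled to pH and carbon (effect 2). Chemistry
  clusters come from Ward + cut selection on the silhouette and
  matrix-correlation criteria — the fidelity criterion is omitted here
  because, under continuous chemistry→composition coupling, it favours
  a two-cluster cut and would make the classification target trivially
  coarse. Indicator thresholds are 0.5/0.5 on the k = 7 community
  clustering; the metric is held-out cluster accuracy.
- `sim_regression_benchmark()`: the land-use survey with chemistry
  effect 2; one regressor per soil variable, evaluated by adjusted R²
  and by quality-category scoring under the example thresholds. The
  `ph_weight = 2` variant doubles the responsive-OTU coefficients on pH
  to represent a variable with dominant coupling to composition.

## Numerical conventions and degenerate inputs

- Permutation p-values use the +1 convention and are never 0; with two
  equal-sized groups the observed partition recurs under free label
  permutation, so the attainable floor sits slightly above
  1/(n_perm + 1).
- Quality-category intervals are lower-closed/upper-open: a value
  exactly on a breakpoint takes the higher category. Any fixed
  convention works; this one is documented and tested.
- PPCA converges on the relative change in observed-data log-likelihood
  (tol 1e−6, max 500 iterations by default; the likelihood is checked
  non-decreasing to 1e−8). Initialization is the SVD of the
  mean-imputed table — deterministic and close to the optimum; a seeded
  random initialization is available. Component signs are fixed by
  making each component's largest-magnitude loading positive.
- Degenerate inputs error early with the offending identifiers: all-zero
  community rows, unmapped samples, empty clusters, constant distance
  matrices, single-site strata, constant regression targets, variables
  that are entirely missing, non-monotone threshold breakpoints.
- All-zero OTUs get specificity 0 everywhere, are flagged, and are never
  selected as indicators.
- Determinism: every stochastic step (scenario generation, rarefaction,
  permutations, splits, forests, importance) takes a seed, and the
  pipeline derives fixed offsets from its master seed, so a rerun with
  the same configuration is identical; the run manifest (configuration,
  seed, versions) suffices to reproduce any artifact.

## Limitations

- The shipped quality thresholds are illustrative placeholders, not
  regulatory guideline values; real assessments must supply the
  jurisdiction's breakpoints (per land use and/or soil type via the
  context mechanism).
- The indicator statistics are used for feature screening only — no
  permutation significance test of indicator values is provided.
- Random-forest hyperparameters are deliberately fixed at the
  conventional defaults; no tuning, class weighting or alternative
  learners.
- NMDS ordination and other visualization layers are out of scope; the
  pipeline's outputs are tables.
- Chemistry clustering operates on PPCA-completed values when cells are
  missing; with substantial or non-random missingness the cluster
  boundaries inherit imputation uncertainty that the pipeline does not
  propagate.
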