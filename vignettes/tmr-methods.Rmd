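---
title: "Treatment-Measured-Response integration: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treatment-Measured-Response integration: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmrnet)
```

## The problem and the model

Multi-omics studies of the gut-lung axis collect several blocks of
measurements on the same animals: 16S taxa profiles from stool DNA and RNA,
metabolite panels from several compartments, host gene expression, and
forced-oscillation lung-function readouts. tmrnet integrates such blocks by
assigning every variable group one of three roles and fitting three
categories of covariate-adjusted linear models between them:

* **Treatment** groups hold experimenter-controlled or fixed covariates
  (binary treatment indicators; body weight as a continuous surrogate for a
  high-fat-diet exposure, entered both as final weight and percentage
  increase). They are always predictors.
* **Measured** groups are the omics layers. They can respond to treatments
  and predict (or respond to) other measured groups.
* **Response** groups hold the clinical readouts — here lung-function
  parameters summarized as a baseline value and a methacholine
  dose-response slope — and are always responses.

With `T` the joint treatment covariates, the fitted models are

1. `Measured[i] ~ T` — one edge per covariate per measured variable;
2. `Measured[j] ~ Measured[i] + T`, for every ordered cross-group variable
   pair (both directions are fit);
3. `Response ~ Measured[i] + T`, one measured variable at a time.

Every fit is ordinary least squares with an intercept; inference is the
Wald t-test with the usual residual degrees of freedom. Within-group
associations are deliberately never tested: variables inside one omics
block are expected to be correlated for uninteresting reasons (shared
pathways, compositional closure), whereas cross-block associations are the
integration signal. When both directions of a measured-measured pair are
significant at the working level, only the stronger one is kept; "stronger"
is defined as the smaller p-value, with larger |t| and then lexicographic
order as tie-breaks, since the p-value is the significance currency used
throughout the framework. A covariate can also surface as significant
inside a category-2/3 model while a measured predictor is controlled for;
such edges are kept but flagged (`covariate_surfaced`), because they are
re-reports of treatment associations under a different adjustment set, not
new cross-omics links.

Significant associations are assembled into a signed directed network at a
strict p-value cutoff (default `alpha = 0.005`), with positive edges drawn
solid black and negative edges dotted magenta by `autoplot()`. No
multiple-testing correction is applied by default — the network cutoff is a
raw p-value, which is how such association networks are usually reported —
but `tmr_scan(adjust = "BH")` appends a Benjamini-Hochberg adjusted column
for users who prefer FDR control. The practical consequence of raw cutoffs
is quantified below ("What the synthetic benchmarks show").

## Compositional 16S handling

Taxa tables are compositions: only relative information is meaningful, and
standard regression on raw proportions is distorted by the unit-sum
constraint. The package therefore (i) converts counts to relative
abundances, (ii) keeps the top 10 taxa by mean relative abundance and pools
the rest into a `Remainder` bucket (low-abundance taxa contribute little
abundance but large coefficients of variation), and (iii) applies the
additive log-ratio (ALR) transform
`alr_ij = ln((x_ij + c) / (x_i,ref + c))`, which maps a D-part composition
to D-1 unconstrained coordinates that can be treated as ordinary real-valued
predictors.

Two conventions here are genuinely open and are therefore explicit,
logged configuration:

* **Reference component.** The ALR coordinate system depends on the
  denominator. The default is the `Remainder` bucket when pooling occurred
  (it is stable and always positive after pooling, and it can never be a
  variable of scientific interest); otherwise the taxon with minimal
  variance of log abundance. The choice is recorded in the output metadata
  and in every written TSV header, and is always user-overridable.
* **Zero handling.** An additive pseudocount (default `1e-6` on the
  relative-abundance scale) is used rather than multiplicative replacement;
  it is the simplest defensible choice, and `pseudocount = 0` is allowed
  for strictly positive tables. Natural logarithms are used throughout.

Ties in mean abundance at the top-10 boundary are broken by taxon name so
the selection is deterministic.

## Variable selection

High-dimensional measured groups can be reduced before scanning. Each
variable is first tested for normality (Shapiro-Wilk); when normality is
rejected at 0.05, square-root and log transforms are compared and the
candidate with the largest W statistic wins ("improves normality" is
operationalized as a larger W; for a fixed sample size the W and p
orderings coincide). The square root requires a non-negative minimum; the
log requires positive values, with zeros accommodated by an
order-preserving offset of half the smallest positive value; variables with
negative values keep the identity. The gate (only transform when raw
normality is rejected) follows the framework's description; pass
`always_compare = TRUE` to rank the three candidates unconditionally.

PCA is then run on the correlation matrix of the (transformed) variables.
Components contributing strictly more than 1% of total variance are
retained, and each retained component, in order, is represented by the
not-yet-chosen observed variable with the largest absolute Pearson
correlation to its scores. Proxies are forced to be distinct across
components so the selected set is non-redundant; the unconstrained argmax
is also reported so the (rare) substitutions are visible. Using observed
proxies instead of PC scores keeps every downstream edge interpretable as a
named variable.

Selection is optional in `run_pipeline()` (default off). For the planted
studies used in the package's own validation it is not informative —
synthetic variables are exchangeable, so a proxy is an arbitrary
representative — whereas on real data with factor structure it is the
intended dimension-reduction step.

## Group-level structure: Mantel dissimilarity and Ward clustering

Whole variable groups are compared by reducing each to its Euclidean
inter-sample distance matrix, correlating the strict upper triangles of
each pair of matrices (the Mantel statistic, used purely as a similarity —
no permutation test is attached), and clustering the groups on the
dissimilarity `1 - |cor|` with Ward's minimum variance criterion. Two
defaults matter:

* Variables are z-scored within each group before the distance computation,
  because groups mix units (log-ratio coordinates, relative amounts,
  expression levels) and raw-scale distances would be dominated by whichever
  variable happens to have the largest numeric range. `standardize = FALSE`
  restores raw distances.
* The Ward update is applied directly to the `1 - |cor|` values
  (`hclust`'s `"ward.D"`); the squared-input variant is available as
  `method = "ward.D2"`. The variant used is recorded in the run log.

## Ordination and PERMANOVA

Classical MDS (principal coordinates) embeds samples from the ALR-Euclidean
distances of one measured layer: double-center `-0.5 D^2`, eigen-decompose,
scale axes by the square roots of the non-negative eigenvalues. Negative
eigenvalues are reported but excluded from axes.

PERMANOVA partitions the same distance matrix by the treatment covariates.
The implementation works on the Gower-centered inner-product matrix with
sequential (type-I) sums of squares in the order the covariates are given,
matching the default convention of the standard ecology implementation;
marginal SS is available as `by = "margin"`. Permutations are unrestricted
(no strata), and p-values use the add-one estimator
`(1 + #{F* >= F})/(1 + n_perm)`, so the attainable floor is
`1/(n_perm + 1)`. The implementation is validated in the test suite against
both a hand-computed six-sample decomposition and `vegan::adonis2`.

## Dose-response features

Each lung-function parameter measured across nebulized methacholine doses
(0, 3.125, 12.5, 25, 50 mg/mL) contributes two response features: the
baseline (the value at the lowest dose, dose 0 when present) and the OLS
slope of response against dose. The slope is fit on the raw dose scale with
the 0 dose included; because no convention is universal here, a
`dose_scale = "log"` option (using `log(dose + 1)`) is provided. Wide
tables following the `<param>@<dose>` column convention are reduced by
`derive_response_group()`.

## The synthetic study generator

`generate_study()` draws studies shaped like a four-arm murine experiment
(10 animals per arm by default, 40 total): a naive arm, an adjuvant-only
control arm, and two allergic-airway-disease arms of which one receives the
treatment compound. The treatment block carries the three binary indicators
plus two weight covariates (final weight ~ N(45 g, 3); weight gain ~
N(60%, 10), typical of diet-induced obesity protocols). Measured layers:

* **16S layers** are Dirichlet-multinomial: latent log-abundances with a
  base gradient from 2 to -1 (about a 20-fold spread between the most and
  least abundant taxa, as in real top-taxa profiles), Gaussian noise
  (sd 0.5), Dirichlet concentration 500 and a multinomial depth of 50,000
  reads. The gradient and concentration are deliberately moderate: extreme
  gradients or strong planted shifts push remainder taxa into the
  shape-below-one regime of the Dirichlet where log-ratio noise becomes
  skewed and planted coefficients are no longer recovered cleanly.
* **Metabolite and expression layers** are log-normal with sd 0.5 on the
  log scale.
* **Responses** are per-parameter baselines and slopes around typical
  forced-oscillation magnitudes, with sd-0.5 Gaussian noise; the full
  dose-response table they imply is also emitted.

Planted effects are linear shifts on the target's modeling scale (latent
log-abundance for taxa, log scale for metabolites/expression, feature scale
for responses), expressed per standard deviation of the realized source, so
`beta/noise_sd` is the standardized effect size. Defaults use beta 1.5
(treatment effects on taxa capped at 1.5 precisely to avoid the saturation
regime above) against noise 0.5 — essentially complete per-test power at
n = 40. The generator records the planted edge list and the realized
standardized source vectors, so recovery can be scored exactly.

What the generator does **not** emulate: phylogenetic structure and real
taxa co-occurrence, batch effects, missing data, heteroscedastic assay
noise, nonlinear dose-response shapes, and measurement error in the
covariates. Passing the recovery and calibration benchmarks therefore shows
the machinery is correct and calibrated under its own assumptions, not that
those assumptions hold for any particular real study.

## What the synthetic benchmarks show

* **Recovery** (`config_recovery_benchmark()`): a compact study — one
  16-taxon 16S layer, one 6-variable metabolite compartment, two
  lung-function parameters, eight planted effects across the three
  categories — scanned end to end at `alpha = 0.005` over ten seeds. The
  compact size is the point: the scan runs about 250 tests, so the expected
  number of false edges at a raw 0.005 cutoff is near one and
  precision/recall measure the planted signal. At the full default
  dimensionality (seven measured groups, ~3,900 tests) an uncorrected
  0.005 network necessarily carries ~20 false edges; that is a property of
  raw-p networks, and the reason the BH option exists.
* **Calibration**: on pure-null studies the per-test rejection rate at 0.05
  is checked against exact binomial 99% bounds. The rate is computed over a
  mutually independent subset of the scan's tests (one treatment-effect
  p-value per variable of one compartment plus disjoint diagonal
  category-2 pairs, replicated across 125 studies): tests sharing a
  variable are positively dependent, and a pooled rate over all of them
  fluctuates more than the binomial reference, which would make the check
  fail for a perfectly calibrated implementation. PERMANOVA null p-values
  are checked for uniformity (Kolmogorov-Smirnov at 0.01, 120 replicates,
  199 permutations each; the permutation grid's discreteness is negligible
  at that scale).
* **Group structure** (`config_latent_benchmark()`): two of three measured
  groups share a latent per-sample factor (loading 2); the Mantel/Ward
  dendrogram must merge the sharing pair first in at least 9 of 10 seeds.

Problem sizes throughout (10 benchmark seeds, 125 null replicates, 99-999
permutations) were chosen as the smallest designs whose pass/fail behavior
is statistically decisive for the properties being checked.

## Numerical and degenerate-input conventions

* Alignment intersects sample identifiers by strict string equality, keeps
  the first group's order, and is idempotent; samples with missing values
  are dropped per group (and counted) before alignment, since every model
  requires complete cases.
* Constant variables are rejected (not silently dropped) by the selection
  and normality steps; all-zero count rows, empty sample intersections,
  rank-deficient designs and too-few-sample fits raise typed errors
  (`tmrnet_error_*`) naming the offending samples or columns.
* `fit_ols` checks rank via QR before fitting, so collinear predictors
  produce an error listing the dependent columns rather than silently
  aliased coefficients.
* Determinism: every stochastic step (generator, PERMANOVA, network
  layout) takes an explicit seed, restores the caller's RNG state, and the
  pipeline writes a config hash plus every applied default (ALR reference,
  standardization, Ward variant, permutation count) to its run log.

## Known limitations

* Linear models only: no mixed effects, no robust or penalized variants,
  no mediation or causal orientation. The direction kept by bidirectional
  resolution is a significance heuristic, which is why recovery scoring
  matches edges as unordered pairs and reports orientation agreement
  separately.
* The ALR reference choice changes coordinates; results should be read as
  "relative to the reference", which is why it is always logged.
* Raw-p networks at 0.005 trade false-discovery control for sensitivity;
  at realistic omics widths they must be read as screening output.
* PERMANOVA assumes exchangeable samples under the null; designs needing
  restricted permutations (blocks, repeated measures) are out of scope.
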