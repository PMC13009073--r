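---
title: "Statistical methods behind the ThyroMetab pipeline"
author: "ThyroMetab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind the ThyroMetab pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThyroMetab)
```

ThyroMetab implements the statistical workflow of a case-control
untargeted-metabolomics study of feline hyperthyroidism (FHT): a serum
metabolome measured as semi-quantitative peak heights in ~19 euthyroid
controls and ~16 hyperthyroid cases, together with a targeted panel of
urinary endocrine-disrupting chemicals (EDCs; four parabens and ten
phthalate metabolites). This vignette documents the models, the parameters
that matter, the numerical conventions, and what the synthetic-data tests
do and do not establish.

## Preprocessing model

Raw intensities pass through four stages, each stamped onto the
`FeatureTable` so no stage can be applied twice or out of order:

1. **Blank-ratio filter.** Feature $j$ is kept iff
   $\max_i x_{ij} / \bar b_j \ge 10$, where $\bar b_j$ is the
   instrument-blank average. The rule removes strictly-below-threshold
   features; a zero blank is treated as an infinite ratio (absent from the
   blank is the cleanest possible pass). The threshold is a config key;
   10 is the default.
2. **mTIC normalization.** Each value is divided by its sample's total over
   the *annotated* features (the metabolite total ion chromatogram), so
   annotated features sum to exactly 1 per sample. Whether the divisor
   should cover annotated-only or all features is not determined by the
   upstream software's description; annotated-only is the default and an
   all-feature TIC is available by passing every feature id.
3. **log(value + 1).** Natural logarithm. The base is forced by the
   fold-change convention below: dividing a log-mean difference by
   $\ln 2$ yields a base-2 exponent only if the transform is natural-log.
   The $+1$ keeps zero intensities finite; at peak-height scales
   ($\sim 10^5$) its bias is negligible, but for near-zero intensities the
   "fold change" becomes a ratio of *shifted* geometric means — a known,
   documented bias, implemented as stated rather than corrected.
4. **Pareto scaling.** $s_{ij} = (y_{ij} - \bar y_j)/\sqrt{sd_j}$ with the
   $n-1$ standard deviation (conventional for small-n omics; the
   denominator convention is not otherwise fixed). Zero-variance features
   become all-zero with a warning. The per-feature center and divisor are
   retained so group means can always be reported back on the log scale.

Pareto scaling is a per-feature affine map, so one-way ANOVA F statistics
are identical on the log and Pareto stages; the test suite asserts this to
1e-9 relative tolerance.

## Differential abundance

Per feature, classical equal-variance one-way ANOVA between groups
($F = t^2$ of the pooled t test for two groups). Welch correction is
deliberately not applied: the originating analysis used classical ANOVA
and no heteroscedasticity adjustment. With exactly two groups a Tukey HSD
p equals the ANOVA p, so no separate post-hoc path exists.

Fold changes use $d = \bar y_{case} - \bar y_{control}$ on the
log(value + 1) scale: $FC = e^d$ and $L2FC = d/\ln 2$, so $FC = 2^{L2FC}$
identically and an L2FC of 1 is a doubling. The case-minus-control
direction is fixed by the convention that analytes elevated in the
hyperthyroid group report $FC > 1$.

Multiplicity is handled by Benjamini–Hochberg. Two variants are exposed:

* **monotone** (default): the standard step-up
  $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, capped at 1;
* **non-monotone**: plain $p \cdot m / \mathrm{rank}$ without the step-up
  minimum, ties ranked by order of appearance. Some published enrichment
  tables report exactly this variant, so it is provided for digit-level
  comparison against printed tables; it is never the default for
  inference.

## Pathway enrichment

For each of nine predefined pathway groups, the 2×2 table
(significant/non-significant × inside/outside pathway) is tested with a
two-sided Fisher exact test, where "two-sided" means the
minimum-likelihood convention: the sum of hypergeometric outcome
probabilities no larger than that of the observed table. Two-sided Fisher
conventions differ between software packages; this one matches
`stats::fisher.test` and the major statistical suites, and the
implementation (direct `dhyper` summation) is cross-checked against
`fisher.test` by exhaustive enumeration over all small tables in the test
suite. BH runs across exactly the nine pathway tests, never pooled with
the feature-level tests. A pathway containing every feature has an empty
out-group; its p is defined as 1 with a warning.

`enrichmentFromCounts()` recomputes the whole table from printed count
triples (packaged in `extdata/pathway_counts.csv`), which is how the
package's published-value checks are driven.

## Weighted sub-network analysis

From the Pareto-scaled table:

1. pairwise Pearson correlations $r_{ij}$;
2. signed soft-power adjacency
   $a_{ij} = \mathrm{sign}(r_{ij}) |r_{ij}|^\beta \cdot
   \mathbf{1}[|r_{ij}| \ge \tau]$, zero diagonal. Defaults $\beta = 6$
   (the customary signed-network power) and $\tau = 0.1$; neither value is
   dictated by the study description, so both are config keys;
3. topological overlap on $u = |a|$ (the standard TOM formula requires
   non-negative weights; the sign is retained in $r$ and $a$ for
   reporting):
   $\mathrm{TOM}_{ij} = \frac{\sum_l u_{il}u_{lj} + u_{ij}}
   {\min(k_i, k_j) + 1 - u_{ij}}$, $\mathrm{TOM}_{ii} = 1$, with
   $k_i = \sum_u u_{iu}$;
4. dissimilarity $1 - \mathrm{TOM}$, "normalized" here meaning divided by
   its maximum off-diagonal entry (other normalizations exist; this one is
   the config-exposed choice), diagonal forced to zero;
5. Ward clustering (`hclust` with `ward.D2`, the squared-distance update
   convention) cut at exactly $k = 5$ modules by default, mirroring the
   five-cluster structure the method is typically reported with; $k$ is
   configurable. Labels are deterministic: ordered by decreasing module
   size, ties by smallest member index;
6. per module, the **eigenmetabolite**: the unit-norm first left-singular
   vector of the member submatrix, oriented so its mean correlation with
   member features is positive (so "high module score" always means "high
   member abundance");
7. association with the outcome by point-biserial Pearson correlation and
   by univariate logistic regression on the eigenmetabolite standardized
   to unit variance, making odds ratios per-SD and hence comparable across
   modules. Complete separation is flagged (including the perfect-fit case
   where IRLS converges before fitted probabilities reach numerical 0/1,
   detected via a residual deviance of essentially zero) and the CI
   reported as unbounded.

The outcome is coded 1 = hyperthyroid throughout. Published module reports
in this design sometimes combine a positive correlation with an odds ratio
below 1, implying an inverted coding somewhere in the original chain; this
package fixes one coherent coding rather than reproducing the
inconsistency.

## PCA and PLS-DA

PCA is the SVD of the column-centered Pareto-scaled matrix — centering
only, no re-standardization, because the data were already scaled once.
Components carry a deterministic sign (largest-magnitude loading entry
positive) so runs are bit-reproducible. `nComponentsForVariance()` returns
the smallest component count reaching a cumulative explained-variance
fraction (0.90 by default), and `clusterLoadings()` Ward-clusters the
feature loading vectors over those components (default 15 clusters).
Feature–outcome point-biserial correlations, ordered within clusters from
most positive to most negative, form the heatmap input.

PLS-DA uses NIPALS with a single centered indicator response (two classes
need no dummy matrix): per latent variable, weights
$w \propto X^\top y$ (unit norm), scores $t = Xw$, then deflation of $X$
and $y$ by regression on $t$. Per-LV explained percentages come from the
deflation sums of squares. VIP is
$\sqrt{P \sum_a SSY_a w_{ja}^2 / \sum_a SSY_a}$, which makes
$\mathrm{mean}(VIP^2) = 1$ an algebraic identity — asserted in the tests
rather than assumed.

## The synthetic-data generator

No public dataset accompanies this study design, so the generator is the
package's testbed. It emulates, with known ground truth:

* a two-group cohort (default 19 controls, 16 cases) with log-normal urine
  creatinine (geometric mean 150 mg/dL, log-sd 0.5 — a realistic feline
  range chosen once as the default condition);
* latent log-normal intensities
  $z_{ij} \sim N(\mu_0 + d_j g_i, \Sigma)$, $x_{ij} = e^{z_{ij}}$, with
  $\mu_0 = 11.5$ (so intensities sit near $10^5$, the scale of peak
  heights surviving a typical minimum-peak-height cutoff) and marginal sd
  0.7. $\Sigma$ is block-exchangeable — constant correlation inside each
  planted module, zero between — chosen over factor models because its
  empirical-correlation behaviour is analytically checkable;
* 389 features by default, with nine pathway groups of sizes
  (22, 106, 74, 7, 108, 5, 8, 6, 53); pathway labels are shuffled by
  default so pathway and module structure stay independent (a flag aligns
  them for enrichment experiments);
* blank profiles in which a chosen fraction of features is planted to fail
  the ratio-10 filter;
* EDC panels drawn log-normally per analyte with case-multiplier group
  effects, censored against each analyte's LOQ; the truth retains the true
  values so imputation error is measurable.

Because intensities are generated on the natural-log scale, the pipeline's
log(value + 1) transform recovers normality only approximately — exactly
the bias the real convention carries; at the default intensity scale the
discrepancy is far below test tolerances.

**What passing tests show, and what they do not.** The generator draws
independent Gaussian blocks with exchangeable correlation and exact
log-normal margins. Real metabolome data have heavy tails,
intensity-dependent variance, correlated drift, and annotation errors —
none of which are emulated. Calibration and recovery results on synthetic
data therefore validate the *implementation* (formulas, conventions,
determinism, error control under the stated model), not the field
performance of the workflow on real cohorts. Likewise the study's
data-dependent results (counts of significant metabolites, module
correlations, PLS-DA variance percentages) are not reproducible without
the raw data; the package instead reproduces every quantity derivable from
printed summaries — notably the full nine-pathway enrichment table from
its count triples.

## Experiment sizes used by the checks

Chosen as the package's own test conditions: null calibration uses one
1,000-feature cohort (KS uniformity) plus 200 replicates of 400 features
(false-discovery proportion at $\alpha = 0.05$); module recovery uses 50
seeds of a 100-feature, 5-module design (sizes 30/25/20/15/10, within
correlation 0.8, n = 35) — all features belong to a module so the adjusted
Rand index compares complete partitions; fold-change recovery uses 50
replicates of 20 planted effects ($d = 1$) among 400 features; logistic
coverage uses 200 replicates at n = 500. Unit-level tests use smaller
replicate counts of the same designs.

## Known limitations

* The mTIC convention (divide to unit sample sum) interacts with
  log(value + 1): normalized intensities are far below 1, so
  $\log(x + 1) \approx x$ and fold changes computed downstream of mTIC
  compress toward 1 even for large true effects (test statistics and
  rankings are essentially unaffected, because the transform is then
  nearly linear). Fold changes in physical units come from running the
  log transform on the raw intensity scale, which is what the package's
  fold-change recovery experiments do; after mTIC, interpret `l2fc` as a
  relative ordering, not an effect size.
* The blank filter, mTIC divisor choice, and stage order
  (filter → mTIC → log → Pareto) follow the conventional reading of the
  upstream processing chain; the order is implied rather than prescribed.
* `sum_aa` is computed on the molar scale for consistency with the other
  molar indices, with default molar masses MBzP = 256 and MiBP = 222
  ug/umol (configurable); mass-based family sums are the default for
  `sum_paraben`/`sum_phthalate`.
* The network stage implements no scale-free-topology fit, dynamic tree
  cut, or module merging; module count is an explicit parameter.
* The pipeline targets exactly two groups; multi-group contrasts, covariate
  adjustment and mixed models are out of scope, as is the random-forest
  classification stage (an off-the-shelf ensemble with no bespoke
  statistical content).
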