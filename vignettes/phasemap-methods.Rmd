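---
title: "Methods behind phasemap: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind phasemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasemap)
```

`phasemap` maps profiles of behavioural problems across two developmental
waves: clean the ratings, reduce them to orthogonal factor scores,
cluster each wave hierarchically, compare the two clusterings, and test
cross-wave transitions. This vignette explains each model, the tunable
parameters and their defaults, the synthetic cohort the test suite runs
on, and the places where the design was genuinely open and a choice had
to be made.

## The data model

A wave is a subject × item `rating_matrix`. Childhood ratings are
visual-analogue scores in millimetres on a 0–100 scale; adolescent
ratings are 4-point ordinal scales. All downstream modelling assumes
that, after discretisation, each ordinal item is a coarsened view of a
latent standard-Normal variable, and that items follow an orthogonal
common-factor model: for item $j$,
$y_j = \sum_f \lambda_{jf} s_f + e_j$, with uncorrelated factors $s_f$
and unique noise variance $\psi_j = 1 - \sum_f \lambda_{jf}^2$, so the
implied correlation matrix $\Lambda\Lambda^\top + \Psi$ has unit
diagonal.

## Cleaning chain

The preprocessing order is fixed: missing-item screen → EM imputation →
item-level outlier screen → discretisation of analogue items.

* **Missing screen** (`screen_missing`): subjects with strictly more
  than `max_missing = 5` missing items (about 15% of a 40-item
  questionnaire) are excluded.
* **EM imputation** (`em_impute`): multivariate-Normal EM over items.
  The E-step fills conditional means (and adds the conditional
  covariance to the second-moment accumulator), the M-step re-estimates
  the mean and covariance; convergence when no parameter moves by more
  than `tol = 1e-6`, capped at 200 iterations. Unlike mean or regression
  substitution this preserves variances and covariances, which matters
  because everything downstream is correlation-based. Ordinal cells are
  rounded to valid levels afterwards because polychoric estimation needs
  categories. A singular observed-block covariance is ridge-stabilised
  with the constant $10^{-8}\,\mathrm{tr}(\Sigma)/p$ and flagged.
  Only MCAR missingness is handled by design; there is no MAR/MNAR
  modelling and no multiple imputation.
* **Outlier screen** (`remove_outliers`): a single pass on the
  pre-removal moments — no re-estimation loop, because iterating the
  moments makes the exclusion set depend on processing order. Univariate
  rule: any |z| > 3. Multivariate rule: squared Mahalanobis distance
  above `mahalanobis_cutoff(p, 0.001)`, the $\chi^2_{0.999}$ quantile at
  $p$ degrees of freedom (24.32 at 7 df). Subjects caught by both rules
  are reported as univariate so the screening report's id sets always
  partition the input. The same screen is applied a second time to the
  factor scores before clustering. The conventional 24.32 cut-off
  corresponds to 7 dimensions even when 6 factors are retained; the
  package therefore always derives the cut-off from the actual number of
  score dimensions rather than hard-coding a constant.
* **KDE discretisation** (`kde_discretise`): a Gaussian kernel density
  (Silverman's bandwidth by default, Scott as an option) is evaluated on
  a 512-point grid spanning the scale range, and the $L-1$ cut points are
  the deepest interior local minima of the density — ranked by the
  density value at the minimum, because a deeper valley separates more
  distinct response modes. When the density has fewer interior minima
  than needed (a unimodal response distribution), the remaining cut
  points fall back to equal-probability quantiles, so the mapping then
  reproduces quantile binning exactly. Degenerate input (all values
  equal) yields a single level and a flag. Level assignment is monotone
  in the raw score by construction.

## Polychoric exploratory factor analysis

`polychoric_corr` uses the standard two-step estimator: thresholds from
inverse-Normal cumulative marginal proportions, then a bounded 1-D
maximisation of the contingency-table likelihood over $\rho$ alone. Cell
probabilities are bivariate-Normal rectangle probabilities computed with
a vectorised Gauss–Legendre quadrature of the Drezner–Wesolowsky single
integral (24 nodes, plus a 48-node segment near the endpoint when
$|\rho| > 0.925$). Zero-count cells enter the likelihood directly; no
continuity correction. Perfect monotone association is clamped at
$|\rho| = 0.999$ and flagged. The two-step estimator is a documented
approximation to full joint ML; it is what practitioners use and is
consistent under the latent-Normal model. Pairwise matrices that are not
positive semi-definite are repaired by eigenvalue clipping at $10^{-6}$
and rescaling to unit diagonal (a nearest-correlation projection was
considered out of scope).

`efa` extracts by **minres**: alternate (i) the best rank-$k$
approximation of $R - \mathrm{diag}(\psi)$ (top-$k$ eigenstructure) and
(ii) $\psi \leftarrow \mathrm{diag}(R - \Lambda\Lambda^\top)$. Both
steps minimise the same Frobenius objective, so the recorded
off-diagonal mean squared residual is non-increasing — a property the
tests assert. Heywood cases are clamped at uniqueness 0.001 and flagged.
Rotation is **varimax** with Kaiser normalisation, implemented as
successive pairwise planar rotations with the closed-form optimal angle
per pair. (The SVD-iteration varimax in base R stalls at zero-gradient
configurations that are not optima — e.g. a 4-item, 2-factor matrix
rotated 30° from simple structure — which is why the rotation is done
with Jacobi sweeps here; a brute-force angle grid serves as the test
oracle.) Factor scores are regression (Thurstone) scores
$Z R^{-1} \Lambda$, re-standardized per column, since the clustering
operates on standardized score geometry.

**How many factors?** Two rules are implemented. *Parallel analysis*
compares polychoric eigenvalues against the 0.95 quantile of eigenvalues
from `n_sim = 100` null datasets — independent Normals discretised to
each item's observed margins, because the observed data are ordinal and
raw-Normal eigenvalue nulls would be miscalibrated. The suggestion is
the leading run of eigenvalues above their rank-matched null quantile
(Horn's rule); counting non-leading exceedances would suggest spurious
factors on pure noise roughly a quarter of the time at the 0.95
quantile. *Bootstrap stability* refits the EFA on row-resamples, aligns
bootstrap factors to the full-sample solution by greedy best match on
absolute Tucker congruence with sign alignment, and calls $k$ stable
when every factor's 95% percentile congruence interval has lower bound
≥ 0.90. The 0.90 bound is this package's operationalisation of a
stability criterion; it is reported in the output rather than silently
applied.

## Hybrid hierarchical clustering

The clustering input is the standardized factor-score matrix with
Euclidean distance (the natural metric once scores are standardized and
orthogonal). The hybrid scheme combines agglomerative strength at small
scales with divisive strength at large scales:

1. **Mutual clusters**: sets $S$ with
   $\max_{i,j \in S} d_{ij} < \min_{i \in S, k \notin S} d_{ik}$.
   No agglomerative linkage ever breaks a mutual cluster, so every one
   appears as a node of an average-linkage tree; the implementation
   scans those nodes and verifies the definition directly, which makes
   the enumeration complete (the tests confirm equality with exhaustive
   subset enumeration at small n).
2. **TSVQ**: maximal mutual clusters are collapsed to centroids weighted
   by their size, and a divisive tree is grown by recursive weighted
   2-means (k-means++-style seeding, 10 restarts per node, best split by
   weighted within-SSE, assignment ties toward the first centre,
   zero-variance nodes split by index at height 0).
3. **Grafting**: each mutual cluster grows its own TSVQ subtree, spliced
   in at its leaf with heights capped at the graft point.

Node heights are the weighted within-node sum of squared deviations from
the node centroid, capped by the parent height so the dendrogram is
monotone; the divisive literature leaves heights loosely specified, and
within-SSE makes `cut_tree` (remove the $k-1$ highest nodes, ties broken
by top-down creation order) equivalent to height thresholding.
Partitions are nested across $k$ by construction.

Cluster-number diagnostics report the full Calinski–Harabasz profile
with percent changes and *both* kinds of local extrema labelled, plus
silhouettes (via `cluster::silhouette`; singletons get $s = 0$). The
choice of $k$ is deliberately left to configuration: in this family of
analyses the CH profile is read for maxima by convention, but plateaus
and elbows are also inspected in practice, so the package reports rather
than decides.

## Comparing waves and testing transitions

The Fowlkes–Mallows index $B = T/\sqrt{PQ}$ is computed from the
cross-wave contingency table on the subjects present in both waves. The
null permutes the subject-to-leaf assignment of the first clustering;
for a fixed cut this is identical to permuting partition labels, which
is how it is implemented. The two-sided p-value uses the add-one
correction $2\min(r_{low}+1, r_{high}+1)/(n_{perm}+1)$, capped at 1, so
p can never be exactly 0.

Transitions are tested against the **equal-split null** exactly: with
$K$ destination clusters the null probability is $1/K$ for every cell —
not the marginal-based null, which would absorb the very differences in
cluster prevalence the analysis is about (this is a documented
limitation: a large destination cluster will trivially exceed 1/K). The
Bonferroni family is all $K_1 \times K_2$ cells, the most conservative
of the defensible choices. Covariate contrasts for specific transitions
use pooled-variance (Student) t-tests with $df = n_1 + n_2 - 2$, and
Cohen's d with the pooled SD, Bonferroni-adjusted over the covariates in
one call.

## ANOVA and power conventions

`rm_anova` is a textbook split-plot decomposition (between-subject
group, within-subject domain, interaction), with Mauchly's W computed
from the pooled within-group covariance of orthonormalised domain
contrasts (chi-squared approximation, no small-sample F adjustment) and
Greenhouse–Geisser
$\varepsilon = (\sum\lambda)^2 / ((m-1)\sum\lambda^2)$ from the
eigenvalues of the double-centred pooled covariance. Corrected dfs are
the raw dfs times $\varepsilon$; Huynh–Feldt is intentionally not
implemented. The implementation is cross-checked in the tests against an
independent mixed-ANOVA implementation (`car::Anova`).

The power functions use a fixed-effects noncentral-F convention with the
tested effect spanning $m$ numerator degrees of freedom ($m$ = number of
factor domains), denominator df $N - m - 1$, and noncentrality
$\lambda = f^2 N$. This is the convention — established numerically, not
assumed — under which the three standard design numbers cohere: minimum
$N = 2093$ for $f = 0.1$ at $\alpha = 0.05$, power 0.95 and 6 domains,
with detectable effects $f = 0.04$ at $N = 12{,}134$ and $f = 0.06$ at
$N = 6{,}744$. The common alternative (numerator df $= m - 1$) gives
1984 / 0.04 / 0.05 instead and is not consistent with that triplet.
`anova_min_n` bisects on $N$ (power is monotone in $N$);
`anova_detectable_f` root-finds on $f$.

## The synthetic cohort: what it emulates, what it does not

`cohort_config()` defines the study conditions the tests run under:
40 items loading 0.7 on one of 6 orthogonal factors (conduct,
hyperactivity, inattention, emotion, anxiety, motor), 7 childhood and 6
adolescence profile prototypes in factor-score SD units, a planted
7 × 6 row-stochastic transition matrix whose mass concentrates on
remission with specific enriched routes (anxiety → emotion, conduct →
anxiety/emotion/inattention, motor/hyperactivity/emotion → inattention),
2% MCAR missingness, and 15 univariate + 10 multivariate planted
outliers. Wave 1 is rendered on the 0–100 mm analogue scale by an affine
map placing ±3.5 model-implied SDs across the range (then truncating);
wave 2 is discretised at fixed equiprobable-Normal thresholds. Every
stage draws its seed from the master seed via the documented splitting
rule `(seed * 101 + stage) mod (2^31 - 1)`, so stages are independently
reproducible.

Two generator choices deserve explanation:

* **Per-cluster noise (floor effect).** Problem questionnaires compress
  the majority no-problems group against the scale floor, so its
  within-cluster spread is much smaller than that of problem profiles.
  The default noise SD is therefore 0.2 for the no-problems prototype
  and 0.5 for problem prototypes. This is also what makes the planted
  structure recoverable at the published cuts: with a common SD, the
  dominant cluster's within-SSE exceeds the height of the node joining
  the two closest problem profiles, and a height-based cut at $k = 7$
  splits the majority cluster instead of separating those profiles.
* **Prototype geometry.** The minimum pairwise prototype separation is
  1.9 SD (anxiety vs anxiety+hyperactivity); all other pairs are ≥ 2.1
  apart. These values were fixed once, during generator design, and the
  recovery tests run against them.

What the generator does **not** emulate: real item wording or marginal
distributions, informative (MAR/MNAR) missingness, attrition related to
group membership, measurement non-invariance across waves, or
correlated latent factors. Passing the recovery tests therefore shows
that the pipeline recovers the structure it assumes, at realistic sizes
— not that real cohort data satisfy those assumptions.

A consequence worth knowing: clustering the *generated* (latent) factor
scores recovers the 7 planted profiles almost perfectly (the acceptance
suite asserts adjusted Rand ≥ 0.8 at $n = 3000$; observed values are
around 0.93), while running the full pipeline — discretisation,
polychoric EFA, score estimation — attenuates recovery substantially at
moderate n, exactly as score unreliability predicts. The package reports
both, via `run_pipeline`'s `recovery` element.

## Problem sizes and numerical choices

The test suite and acceptance script use deliberately scaled problem
sizes chosen as the smallest at which each property is stable:
polychoric recovery and bias at $n = 5000$; parallel analysis on 18
items at $n = 1000$ with 40 null simulations; bootstrap stability with
30 resamples; clustering recovery at $n = 3000$; calibration rates from
400–1000 Monte-Carlo replicates. Other constants: EM ridge
$10^{-8}\,\mathrm{tr}/p$; PSD repair floor $10^{-6}$; polychoric
optimiser tolerance $10^{-6}$ with $|\rho| \le 0.999$; 2-means ties
toward the lower-index centroid; varimax sweeps until the largest
pairwise angle falls below $\sqrt{10^{-8}}$.

## Known limitations

Hard cluster assignments only (no soft/model-based clustering); single-k
Fowlkes–Mallows comparisons (no $B_k$ curves); equal-split transition
null; orthogonal rotations only; two waves only. The equal-split null
and the Bonferroni family size are the two analysis choices most likely
to matter in applications and both are explicit parameters of the
respective functions.
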