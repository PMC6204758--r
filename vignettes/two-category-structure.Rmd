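---
title: "Testing for two-category structure in morphometric data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for two-category structure in morphometric data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainmosaic)
```

## The question

Group-level mean differences between females and males exist for many
individual brain measures, but a mean difference per feature does not imply
that the joint distribution splits into two types. Two hypotheses make
different multivariate predictions. If there is a "female-typical" and a
"male-typical" brain, then (a) a model of normality trained on one category
should reject the other category much more often than its own held-out
members, (b) category-blind clustering should produce large clusters
dominated by one category, and (c) the supervised female/male boundary
learned in one population should transfer to another. If instead each brain
is a mosaic of features — some in the form more common in females, some in
the form more common in males — all three signatures should be weak, and
large category differences should be confined to rare feature combinations.
`brainmosaic` operationalizes both predictions so they can be checked on
any subjects-by-features table with a binary category label.

## The analyses

**Anomaly detection.** The score of a point is its mean Euclidean distance
to its $k$ nearest training points; training points score against the other
training points only (including a point in its own neighbor list would pin
one neighbor distance at zero for every subject, degenerating the
threshold). The threshold is the $p$-th percentile of training scores,
computed with linear interpolation between order statistics; a test point
is abnormal iff its score is *strictly* larger, so ties are normal and
raising $p$ can only increase the number of normals. Half of the training
category forms the training set; the held-out half and half of the other
category are scored. One half-split is drawn per training category and
data representation and reused across the $9 \times 8$ grid of
$k \in \{10, 15, \dots, 50\}$ and $p \in \{40, 45, \dots, 75\}$ — the grid
measures sensitivity to tuning, not split noise. The summary is the mean,
over runs with a nonzero denominator, of
(same-category % normal)/(other-category % normal); runs with a zero
denominator are counted and, when *all* denominators vanish, the summary is
flagged as complete separation rather than reported as a ratio.

**Cluster composition.** k-means (k-means++ seeding, Lloyd iterations via
`stats::kmeans`) and Ward agglomeration (`stats::hclust`, `ward.D2`) divide
the subjects into $k = 2, \dots, 10$ clusters. Two different "proportions"
are needed, and both are computed per cluster: the within-cluster share
$q_c$ of first-category members gives the disparity $P_c = \max(q_c, 1 -
q_c) \in [0.5, 1]$, while the across-cluster shares $f_c$ (fraction of all
females in cluster $c$) and $m_c$ (same for males) give the same-cluster
chances $fm = \sum_c f_c m_c$, $ff = \sum_c f_c^2$, $mm = \sum_c m_c^2$ —
the probabilities that two subjects drawn at random (with replacement) from
the stated categories land in the same cluster. Drawing with replacement is
deliberate: it makes the chances exact functions of the composition, equal
to exhaustive ordered-pair counting, with the without-replacement
correction only $O(1/n)$. The most separating division is the one with
minimal $fm$ (ties: larger $|f_c - m_c|$ in the largest cluster, then
algorithm name). The dependence of disparity on cluster size is modeled by
a Nadaraya–Watson smoother: Gaussian kernel on cluster size, pooled over
all clusters from both algorithms and all representations, returning the
running mean $p(n)$ and running SD $s(n)$; the default bandwidth is 0.3
times the observed size range — wide enough that the small-cluster region,
where disparities are granular (a cluster of size $n$ can only show
disparities in multiples of $1/n$), does not produce spurious wiggles.

**Supervised transfer.** Classifiers are a linear-kernel SVM (`e1071`) and
a 500-tree random forest (`randomForest`), evaluated by stratified 10-fold
cross-validation. Transfer between samples follows a fixed harmonization
order: z-score each sample separately, concatenate, z-score the combined
matrix, fit the chosen embedding on the combined data, train on the
reference sample, evaluate on the test sample (optionally restricted to a
common age window first). Agreement between the reference-sample model and
the test sample's own cross-validated model is compared against two closed
forms derived from the correctness rates $a_{self}$ and $a_{ref}$ (percent):
$U = (a_{self} a_{ref} + (100 - a_{self})(100 - a_{ref}))/100$, the
agreement expected if the two models' correct/incorrect indicators are
independent, and $P_{max} = 100 - |a_{self} - a_{ref}|$, the maximum
agreement the two rates allow. Observed agreement near $U$ but far below
$P_{max}$ means the two models carve the same subjects differently even
when both beat chance. The benchmarks are defined on correctness rates, not
label marginals — for binary labels, two classifiers agree on a subject iff
both are right or both are wrong, so label agreement and
correctness-indicator agreement coincide. Significance flags come from
two-sided exact binomial tests of the agreement count against $U/100$ and
$P_{max}/100$ at 0.05 and 0.01; the reference tables this mirrors do not
name their test, so the exact binomial is this package's choice.

**Mosaicism.** Per feature, the category scoring higher on average sets the
direction; the "male-end" zone is everything at or beyond the male
distribution's 67th percentile (male-higher features; 33rd otherwise), the
"female-end" zone mirrors it in the female distribution, and the open
interval between the cuts is intermediate. Quantiles use linear
interpolation and zones are closed on the extreme side, so the zone is
exactly "the scores of the 33% most extreme" members in the defining
category up to quantile estimation error. If the two cuts cross — possible
when the distributions barely differ — the feature is flagged degenerate,
classified entirely intermediate, and a warning is raised. Subjects with at
least one feature at each end are mosaics; the coarse typology assigns
male_type iff a subject has strictly more male-end than female-end
features, with ties (including all-intermediate) going to female_type.
Zones are defined on the analysis sample itself; no held-out zone
definition is attempted.

## Data representations

Six representations feed the anomaly and clustering stages: raw z-scores;
PCA scores keeping the components whose eigenvalues exceed the mean
eigenvalue (on the normalized cumulative-eigenvalue curve this is the point
where the slope falls below one); the diffusion map; and three
distance-preserving approximations. The diffusion kernel is
$W_{ij} = \exp(-\lVert x_i - x_j \rVert^2 / \varepsilon)$ with
$\varepsilon$ set to the cube of the mean off-diagonal pairwise distance —
a "mean value of the data" reading that stays strictly positive on
standardized data, where the literal mean of the entries is ~0. The map
itself row-normalizes $W$, takes the non-trivial eigenpairs (via the
symmetric conjugate $D^{-1/2} W D^{-1/2}$), and embeds subject $i$ as
$(\lambda_l \psi_l(i))_l$, so full-dimension Euclidean distances equal
one-step diffusion distances (verified against a dense oracle in the
tests). The default dimension keeps eigenvalues at least 5% of the leading
non-trivial one, capped at 94. The incomplete pivoted QR variants decompose
either the kernel (ICPQR) or the centered data matrix (ICPQRd), retaining
greedy pivots until the next pivot norm falls below $\mu$ times the first
($\mu \in \{10^{-8}, 10^{-6}, 10^{-4}, 10^{-2}\}$), and project onto the
retained orthonormal basis. The landmark ("isometric") diffusion map picks
its landmarks as the kernel's pivoted-QR pivots at tolerance $\mu$, builds
the Nyström low-rank approximation
$\widehat W = W_{:L} W_{LL}^{+} W_{L:}$, and runs the diffusion map on
$\widehat W$; as $\mu \to 0$ this converges to the dense map, which is the
contract the tests check (landmark pairwise distances within 1% of dense
diffusion distances at $\mu = 10^{-8}$).

## Preprocessing conventions

z-scoring uses the $n - 1$ denominator and errors on zero-variance columns.
The power-proportion correction fits, per feature, the OLS slope $b$ of
log volume on log ICV and divides by $\mathrm{ICV}^b$. The fit pools both
categories: the correction is meant to be category-blind preprocessing, and
a per-category fit would leak labels into the unsupervised stages. A
consequence worth knowing: with pooled fitting, the between-category share
of ICV variance is absorbed into $b$, so the correction also removes that
share of any sex signal that rides on ICV — on the synthetic volumes
(log-ICV d = 2, so half the ICV variance is between categories) this
halves the effective sex separation of the corrected features relative to
the ICV-free scores. That is a property of pooled allometric correction
itself, not an artifact. The median-ICV split labels subjects strictly
above the median "large", everything else "small" (a deterministic tie
rule, immaterial for continuous volumes), and refuses degenerate inputs
where everyone ties. Category balancing subsamples the larger category
uniformly at random with an explicit seed and keeps file order otherwise.

## The synthetic populations

No real imaging data ship with the package; every downstream stage is
exercised on generated populations whose printed facts match the regimes
the method is meant to distinguish. The generator is this package's own
construction — the studies it emulates publish effect-size facts, not a
generative model — and it works in standardized units:

$$x_{if} = \frac{d_f}{2} s_i t_{if} + a_i u_f +
  \sigma_f(\sqrt{\rho}\, h_i + \sqrt{1-\rho}\, e_{if}),$$

with $s_i = \pm 1$ the category sign, $d_f$ the target Cohen's d of feature
$f$, and three structural ingredients:

* **Congruence** $t_{if} = g_i + (1 - g_i)\eta_{if}$, $\eta_{if} \sim
  N(1, 1)$, $g_i \sim \mathrm{Beta}$ with mean `effect_correlation`. One
  dial spans the continuum the analyses contrast: at 1 every subject
  expresses every offset at its population value (species-like
  consistency); at 0 each feature's expression is idiosyncratic (mosaic).
  Because $E[t] = 1$ and $\sigma_f$ is set analytically so each feature has
  unit within-category variance, the dial changes the cross-feature
  dependence of a subject's displacements without moving the marginal
  effect sizes — the per-feature empirical d stays $d_f$ at every setting.
* **Axis noise** $a_i u_f$, $u = d/\lVert d \rVert$: individual variation
  along the very direction that separates the category means.
  Morphometric data have this property — many small univariate d's whose
  multivariate combination is nevertheless far from cleanly separable —
  and without it a generator with 116 independent d ~ U(−0.5, 0.5)
  features would be ~95% classifiable, which no brain dataset is. The
  variance is calibrated once per preset to land cross-validated linear-SVM
  accuracy in the published ~72–82% band: 0.4 for the volume preset
  (measured on power-proportion-corrected features, where pooled
  correction has already absorbed part of the signal), 1.9 for the
  thickness preset, 3.7 for the multi-site preset.
* **Size coupling** (volume presets): a latent ICV
  $= 1500 \cdot e^{\zeta}$ with $\zeta \sim N(\pm 0.1 \cdot
  \texttt{size\_factor\_d}/2, 0.1^2)$ — log-ICV Cohen's d equal to
  `size_factor_d` (2 by default, ~10% size CV) — multiplies the volumes
  with exponent exactly 1, making allometric recovery a sharp test
  ($\hat b \to 1$, post-correction slope $\to 0$). With this coupling
  ~83–84% of one category falls below the median ICV, log total volume has
  d ≈ 1.9, and uncorrected volumes cluster by size rather than by
  category.

The presets: `brain_volumes` (116 features, 466/category, d ~ U(−0.5, 0.5),
effect correlation 0.2, noise equicorrelation 0.3, size-coupled),
`brain_thickness` (68 features, 559/category, uncoupled),
`primate_faces` (190 inter-landmark distances, 31 + 59, |d| = 2.5, effect
correlation 0.95 — the genuinely two-population comparator),
`gendered_behaviors` (10 items, 101/category, |d| = 1.2, effect correlation
0.1, answers discretized to a unit grid), and `multisite_brain` (four sites
with location/scale distortions; one site age-restricted to 18–35). Each
preset's d vector is drawn once from a fixed internal stream, so a preset
names the same population model at every simulation seed.

The gendered preset's discretization deserves a note. On continuous
Gaussian features with |d| ≥ 1.05, the probability that a subject's
feature falls in the *other* category's 33%-extreme zone is below ~7%, and
internal consistency then narrowly outnumbers mosaicism — the opposite of
what coarse behavioral ratings show. Rating-scale data are tied in large
masses, and when a tie block straddles a zone cut the whole block is
classified into the zone (zones are closed on the extreme side), roughly
doubling cross-zone membership while barely moving Cohen's d (the pooled
empirical |d| stays ≈ 1.1–1.2). Discretizing at one SD reproduces exactly
this mechanism, and with it the mosaic-dominant regime, without touching
the printed effect sizes.

What the generator does *not* emulate: the empirical covariance of real
regional anatomy (only an equicorrelated factor plus the sex axis), age
effects on features (ages are drawn but uncorrelated with anatomy),
site-specific covariance rotations (sites differ in location/scale only,
except where a test constructs a reversed-axis site explicitly), and
measurement artifacts. Green tests therefore certify the pipeline's
statistical machinery and its behavior across separation regimes — not
that any particular real dataset would land at any particular number.

## Numerical choices and degenerate inputs

Percentiles and quantiles everywhere use R's default linear interpolation
(type 7); determinism across platforms matters more than the choice of
convention. Threshold ties are normal; median-ICV ties are small;
majority-type ties are female_type. k-means++ seeding takes an explicit
seed, and duplicated initial centers (possible on tied data) are replaced
by distinct points before Lloyd iterations. All stochastic operations
(balancing, half-splits, fold assignment, seeding, generation) route
through one scoped-RNG helper, so a single integer seed fixes a pipeline
run bit-for-bit and never disturbs the caller's RNG state. Degenerate
inputs fail loudly rather than silently: missing feature cells name their
row and column, zero-variance columns name the feature, identical points
make the diffusion kernel error, $\mu \ge 1$ retains nothing and says so,
crossed zone cuts warn and classify the feature intermediate, and a
complete-separation anomaly summary is flagged instead of dividing by
zero.

## Problem sizes

The shipped tests run the full grids only where they are the point (the
864-run bookkeeping check uses 110 subjects per category) and otherwise
exercise reduced grids on populations of 100–1000 subjects; oracle
comparisons (brute-force kNN, exhaustive pair counting, dense diffusion
distances) use 50–500 points, where the oracles are exact. Simulation
properties (null calibrations, regime orderings, monotonicity in the
congruence dial) aggregate 10–20 seeds. The whole suite runs in well under
a minute on one core; the preset populations at full published sizes
(466–622 per category) run through the complete pipeline in a few seconds
per representation.

## Limitations

The package consumes tabular features; image processing, atlas mapping,
and surface reconstruction are out of scope. Only the power-proportion
size correction is implemented — the ratio and ANCOVA-residual alternatives
debated in the allometry literature are not. The disparity-curve smoother
is a generic kernel estimator standing in for the original supplementary
estimator, which is not publicly specified. Cluster-number selection is
deliberately absent: the 2–10 sweep *is* the analysis. And the agreement
benchmarks U and P_max are derived from correctness rates printed as
integers in the reference tables, so recomputations from those tables can
sit up to one unit from the printed values; the package reports unrounded
values and leaves rounding to the caller.
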