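---
title: "Spatial TIME analysis with mesotime: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial TIME analysis with mesotime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesotime)
```

# Scope and data model

`mesotime` analyses per-cell measurement tables from multiplexed
immunofluorescence (mIF) tissue microarrays: one row per segmented cell
with centroid coordinates, per-channel mean intensities and (optionally) a
phenotype call. It does not touch images: spectral unmixing and
segmentation are upstream, and the pipeline begins where the phenotyping
software's export ends.

Coordinates are stored in micrometres with the origin at the core's
bounding-box corner. The cellular-neighborhood radii that define the
spatial analyses are physical distances (40–60 μm), so a physical unit is
the only coherent choice; exports in pixels must be converted by the
caller through the reader's column mapping. Tissue area is taken from an
input column when present and otherwise defaults to the area of the
declared circular punch (π·0.3² ≈ 0.2827 mm² for a 0.6 mm core), since
the density denominators need *some* estimator of tissue area and the
disc is the only geometry the table itself implies.

Cores with fewer than 50 cells are flagged by `validate_cohort()` but not
removed: below roughly that size the Delaunay graph and the neighborhood
k-means both become geometry-of-small-numbers exercises, but the decision
to drop a core belongs to the analyst.

# Phenotyping

Positivity is a strict threshold on intensity (`intensity > t`); a cell
exactly at threshold is negative. Phenotype assignment then applies, in
order:

1. **Co-positivity rules first.** CD4⁺FOXP3⁺ cells are Tregs regardless
   of what else they express. If co-expression did not take precedence,
   every Treg would be re-labelled by whichever single marker happened to
   be brightest, and the Treg class would be empty by construction.
2. **The intensity argmax for multi-positive cells**, excluding the tumor
   marker (pan-CK). Epithelial cytokeratin is bright and ubiquitous in
   tumor nests; letting it compete would absorb infiltrating immune cells
   into the tumor class. A cell positive *only* for pan-CK is Tumor.
3. **No positive marker → "unidentified".** FOXP3 single-positive cells
   (CD4⁻) have no rule of their own and also fall here; defining a
   separate class for them would claim a biology (CD8⁺FOXP3⁺, double-
   negative Tregs) the panel cannot resolve.

Intensity ties in the argmax are broken by panel marker order, which makes
assignment invariant to the column order of the input table.

The two staining rounds are segmented independently, so their
compositions cannot be joined cell-by-cell. `merge_panel_compositions()`
keeps round 1's proportions, appends round 2's NK and DC proportions, and
subtracts them from round 1's "unidentified" share — those cells are
unidentified in round 1 precisely because their defining markers sit on
the other panel. On noisy cores the subtraction can go negative; it is
clamped at zero with a warning and the result renormalized, so merged
compositions always lie on the simplex.

# Composition, density and entropy

Densities are counts over tissue area (cells/mm²), proportions are counts
over total cells, and patient-level profiles are unweighted means over the
patient's cores — weighting by cell count would let one large core
dominate a patient whose sampling happened to be uneven. Density values
are also carried as `log1p` copies for downstream testing; `log(1 + d)`
rather than `log(d)` because empty phenotype classes (density 0) are
routine in small cores.

Intratumor heterogeneity is summarized by the Chao–Shen coverage-adjusted
Shannon entropy of the per-core phenotype counts. With n cells, f₁
singleton types and coverage C = 1 − f₁/n, shrunken probabilities
p̃ᵢ = C·pᵢ enter a Horvitz–Thompson-weighted sum

H = −Σᵢ p̃ᵢ ln p̃ᵢ / (1 − (1 − p̃ᵢ)ⁿ).

The estimator needs integer counts, which is why entropy is computed on
counts rather than on densities (the two differ by the constant area
factor, which cannot change any diversity ranking within a core). Natural
logarithms throughout, so entropies are in nats. Two degenerate cases are
handled explicitly: a single observed type gives exactly 0, and the
all-singletons case (C = 0) returns `NaN` with a warning since coverage
adjustment is meaningless there. The estimator always dominates the
plug-in entropy, with near-equality when no type is a singleton; patient
entropy is the mean over cores and requires at least two cores, since a
single punch cannot speak to within-tumor variation.

Patients are split into high/low heterogeneity groups at the 0.6 and 0.4
empirical quantiles (type-7, strict inequalities), the same
top-40%/bottom-40% rule used for every other survival stratification in
the package; the middle band is excluded from two-group tests.

The within- vs between-patient consistency check correlates per-core
density vectors (Pearson) for all core pairs and compares the same-patient
against different-patient coefficient sets with a two-sided Wilcoxon
rank-sum test. Per-type density vectors are used rather than totals: the
question is whether cores from one patient share a *composition*, not a
cellularity.

# Delaunay contact scores

Cell contacts are first-tier neighbors in the Delaunay triangulation of
the centroids, with no edge-length pruning by default (a configurable
maximum length is available, off by default). Exact duplicate centroids —
segmentation artifacts — are jittered by 0.01 μm deterministically before
triangulation.

For a phenotype pair (A, B) the score is

score(A, B) = ln( observed / p_A·p_B ),

where the observed adjacency frequency is counted over *ordered* cell
pairs: each undirected edge contributes to both directions, and a
same-type edge contributes twice to its diagonal entry. This convention
matters. Under ordered counting the chance expectation of the (A, B)
adjacency frequency is exactly p_A·p_B (the product of the type
proportions), so the score is mean-zero under complete spatial randomness
for every composition; with unordered counting the same expectation term
would bias every off-diagonal score by ln 2. The observed frequency is
the mean of a Beta(α, total − α) posterior; smoothing it as
(α + ½)/(total + 1) keeps pairs with zero observed contacts finite
instead of −∞. The unsmoothed ratio is available (`smoothing = FALSE`)
and reproduces hand enumerations exactly. Pairs in which either type is
absent from the core are undefined (`NA`), not zero — absence of evidence
is not evidence of avoidance.

Min–max normalization to [0, 1] is per core by default: each core's
defined scores are rescaled by that core's extremes, which makes cores
comparable as rankings of their own pair structure. A cohort-wide scope is
available by flag for analyses that need absolute comparability; a core
with a single defined (or constant) score maps to 0.5. Group comparison is
a one-sided Mann–Whitney U test per pair on the per-core normalized
scores with Benjamini–Hochberg adjustment across pairs; the default
significance cut is FDR < 0.15, with the stricter 0.1 available as an
argument.

Nearest-neighbor distances (`nn_distances`) are the mean over cells of one
type of the distance to the nearest cell of another (or the same) type,
excluding the index cell for same-type queries, computed with a kd-tree
and verified exactly against an O(n²) scan in the tests.

# Cellular neighborhoods

Each cell's neighborhood is the set of cells within a fixed Euclidean
radius, *including the cell itself* — the convention of the CN literature
this module follows; an isolated cell's neighborhood is then itself rather
than an empty set. Neighbor vectors are proportions (composition on the
simplex) rather than raw counts by default, so that dense and sparse cores
cluster by *what surrounds the cell* rather than by how many cells the
core has; a counts mode exists for analyses of local cellularity.

Vectors pooled across cores are clustered with k-means (multiple starts,
fixed seed; the fit is deterministic given the seed). K is user-set — the
mesothelioma analyses use K = 6 at radius 50 μm — with `cn_elbow_scan()`
providing an inertia-vs-K table and a maximum-curvature (kneedle-style)
suggestion that is advisory only. CN enrichment of phenotype t in cluster
k is the log odds ratio ln(odds(c_kt)/odds(g_t)) of the centroid frequency
against the global frequency, with frequencies of exactly 0 or 1 smoothed
by half a pseudo-count before the odds. The [−5, 5] display range is
enforced by symmetric clipping by default — values inside the range are
reported untransformed, which keeps them interpretable as log odds ratios
— with a proportional rescale mode (largest magnitude onto ±5) available
where a filled range is wanted. Both are monotone and sign-preserving.

Radius robustness is checkable directly: `cn_radius_robustness()` refits
the model at 40/50/60 μm on the same cells and reports the adjusted Rand
index between adjacent labelings.

# Survival and association statistics

Risk groups use the same strict-quantile split as heterogeneity groups.
Kaplan–Meier estimates and the log-rank test are two-sided (a sidedness
for the log-rank would presuppose the direction under test); groups
without events are flagged, not dropped. Univariate Cox fits use the
Efron tie approximation — the standard default, and ties are common when
survival is recorded in whole months. Spearman correlations handle ties
through midranks; channel-vs-marker association tables are computed per
site group. Cores count as tumor-enriched when their pan-CK proportion
strictly exceeds 20%. Clinical summary tables print percentages in the
conventional two-significant-figure style of clinical cohort tables
(integers at ≥10%, one decimal below), rounded half-up.

# The synthetic-data generator

The generator exists so every stage can be tested against ground truth.
Its defaults describe the cohort the pipeline targets:

- circular cores of radius 300 μm; Poisson(2000) cells per core per
  staining round;
- a 9-type composition (tumor 0.33, CD8 T 0.12, CD4 T 0.10, Treg 0.03,
  macrophage 0.12, B 0.04, DC 0.05, NK 0.03, unidentified 0.18) chosen to
  match a lymphocyte/macrophage-dominated mesothelioma TIME with roughly
  a third tumor cells;
- cell placement CSR by default, or a Thomas (Poisson cluster) process
  (offspring dispersion σ = 30 μm, mean 30 offspring per parent) when
  within-type aggregation is needed; types listed in a shared group are
  placed around one common parent set, which plants positive contact
  enrichment between them — CSR is retained as the null everywhere;
- per-channel intensities from a two-component log-normal mixture driven
  by the type's positivity signature: negative median 1, positive median
  10, common log-scale 0.35. These defaults put the components ~3.3 SD
  apart on the log scale so threshold gating at the geometric mean
  (≈3.16) recovers ≥99% of true signatures — deliberately clean, see the
  caveats below;
- continuous protein channels (BAP1, NF2, MTAP, LAG3) with per-core
  log-normal means (between-core SD 0.5) and cell-level noise (SD 0.3);
  an optional coupling term ties the per-core BAP1 mean to the realized
  CD8 fraction for planted-association tests;
- 1–9 cores per patient (uniform); a per-patient log-normal perturbation
  of the composition (SD 0.25) so cores from one patient correlate more
  strongly than cores from different patients;
- exponential survival with baseline median 12 months (the cohort-scale
  figure for mesothelioma), log-hazard coefficients applied to realized
  per-patient phenotype proportions, and independent exponential
  censoring targeting 30% at baseline.

`plant_neighborhoods()` places cells uniformly and draws phenotypes from
region-specific compositions (half-plane or disc regions; overlapping
regions are rejected as ambiguous truth), recording the region per cell
for ARI scoring of CN recovery.

What the generator does **not** emulate: segmentation errors, spectral
bleed-through, intensity batch effects between TMAs, cell-shaped (non-
point) geometry, and tissue folds or necrotic regions. Tests passing on
this generator therefore show that the *estimators* are correct and
calibrated under their stated models, not that real mIF exports are free
of the upstream artifacts those estimators inherit.

# Validation suite: problem sizes and what is checked

The test suite and `scripts/acceptance.R` compute, from scratch:

- summary-table percentage arithmetic on a reference mesothelioma
  cohort's margins (115 patients);
- a 3-cell hand enumeration of the contact score (exact, unsmoothed
  ln 1.5) and adjacency recounts on 200-cell cores (exact);
- contact-score neutrality on 20 CSR cores of 2000 cells (all |score| <
  0.1);
- the entropy estimator against a literal transcription of its formula
  (1e−12) and its analytic limits (single type → 0; uniform → ln K);
- CN recovery on planted two-region cores (compositions 0.8/0.2 vs
  0.2/0.8, ~3000 cells): ARI ≥ 0.9 over 10 seeds, and ARI ≥ 0.8 between
  labelings at 40/50/60 μm;
- log-rank type-I error within [0.03, 0.07] over 500 null replicates of
  100 subjects, and ~95% Wald CI coverage of a planted Cox log-hazard
  β = 0.7 over 200 replicates of 200 subjects;
- ≥80% power of the contact group test at FDR < 0.15 with 30 cores per
  group over 100 replicates, against a planted infiltrated-vs-excluded
  Tumor/CD8 contrast (both groups have clustered tumor nests; only one
  has CD8 sharing them). A pure-CSR reference group is *not* used there:
  per-core min–max normalization rescales an all-noise core's scores to
  fill [0, 1], which makes "elevated vs CSR" a contrast of means near 0.55
  vs 0.5 and is not the biological question;
- exact agreement of kd-tree nearest-neighbor distances with the O(n²)
  scan on 50 cores.

These sizes keep the full suite in the low minutes while leaving every
stochastic check comfortably powered.

# Known limitations

- Phenotyping is rule-based gating; it does not reproduce trained
  classifier output, and cells mis-segmented upstream are phenotyped as
  observed.
- The two panels are joined only at the composition level; no cell-level
  registration across staining rounds is attempted.
- Contact scores are analytic (Beta-posterior against a product null),
  not permutation-based; strong density gradients within a core can move
  scores without any type-to-type interaction.
- The Cox interface is univariate by design; multivariable modelling and
  treatment-response analysis are out of scope.
- 2D only: the triangulation and radii assume thin sections.
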