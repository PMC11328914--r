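# mesotime

Spatial analysis of the tumor-immune microenvironment (TIME) in multiplexed
immunofluorescence (mIF) tissue-microarray (TMA) data, starting from the
per-cell segmentation tables that multispectral phenotyping software
exports (centroid x/y, per-channel intensity, optional phenotype call).
The package was built around mesothelioma TMA cohorts — circular 0.6 mm
cores, two staining rounds covering pan-CK, CD20, CD4, CD8, FOXP3, CD68,
CD11c and CD56 plus continuous BAP1/NF2/MTAP/LAG3 protein channels — but
every stage is generic over a configurable marker panel.

It is intended for computational pathology and tumor-immunology groups who
have cell tables and clinical outcomes and want the standard spatial TIME
readouts with a tested, reproducible implementation.

## What it computes

- **Phenotyping** (`gate_positivity`, `assign_cell_types`,
  `merge_panel_compositions`): threshold gating, rule-based cell typing
  (single positive marker → its type; CD4⁺FOXP3⁺ → Treg before anything
  else; multi-positive cells by highest-intensity marker *excluding*
  pan-CK; no positive marker → "unidentified"), and merging of the two
  staining rounds' compositions (NK/DC proportions subtracted from
  round 1's unidentified share).
- **Composition and heterogeneity** (`compute_composition`,
  `chao_shen_entropy`, `aggregate_patient`, `heterogeneity_groups`,
  `core_correlation_summary`): densities (cells/mm²), proportions, mean
  intensities, and the coverage-adjusted Shannon entropy
  H = −Σ p̃ᵢ ln p̃ᵢ / (1 − (1 − p̃ᵢ)ⁿ) with p̃ᵢ = C·pᵢ and coverage
  C = 1 − f₁/n (f₁ = singleton types).
- **Cell–cell contacts** (`delaunay_edges`, `contact_score_matrix`,
  `minmax_normalize`, `nn_distances`, `contact_group_test`): first-tier
  Delaunay adjacency; the contact score for a phenotype pair (A, B) is
  ln(observed adjacency frequency / p_A·p_B), with the observed frequency
  the mean of a Beta(α, total−α) posterior (Jeffreys-smoothed), counted
  over ordered pairs so the score is mean-zero under complete spatial
  randomness; per-core min–max normalization to [0, 1]; one-sided
  Mann–Whitney U group comparison with Benjamini–Hochberg FDR.
- **Cellular neighborhoods** (`neighbor_vectors`, `fit_cn_model`,
  `cn_enrichment`, `cn_prevalence`, `cn_radius_robustness`): per-cell
  composition vectors within a 40–60 μm radius, k-means clustering into
  CNs, log-odds-ratio enrichment of phenotypes per CN bounded to [−5, 5],
  per-sample CN prevalence, and an ARI-based radius-consistency harness.
- **Survival and marker associations** (`quantile_groups`, `km_logrank`,
  `cox_univariate`, `spearman_assoc`, `tumor_enriched_filter`,
  `cohort_summary_table`): top-40%/bottom-40% stratification,
  Kaplan–Meier/log-rank, univariate Cox (Efron ties), Spearman
  channel-marker associations, the pan-CK > 20% tumor-enriched core
  filter, and clinical characteristics tables.
- **Synthetic cohorts** (`sim_spec`, `generate_core`,
  `plant_neighborhoods`, `generate_cohort`, `simulate_survival`): a
  generative model of all of the above with known ground truth — CSR or
  Thomas-process placement, log-normal intensity mixtures, planted
  spatial regions, patient composition effects and exponential survival —
  used throughout the test suite.

## Worked example

```r
library(mesotime)

spec <- sim_spec()                      # 0.6 mm cores, ~2000 cells/core
g <- generate_core(spec, seed = 42)
p1 <- default_panels()$panel1
cells <- g$cells[g$cells$panel_id == "panel1", ]
cells <- gate_positivity(cells, default_gating(spec, p1), p1)
cells <- assign_cell_types(cells, p1)

prof <- compute_composition(cells, g$tissue_area)
round(prof$proportion, 3)
#>          B      CD4 T      CD8 T Macrophage       Treg      Tumor unidentified
#>      0.048      0.105      0.117      0.116      0.027      0.342        0.245
prof$entropy
#> [1] 1.691839

cm <- minmax_normalize(contact_score_matrix(cells))
round(cm$raw_score["Tumor", "CD8 T"], 3)
#> [1] 0.011
```

The proportions track the generative composition (tumor 0.33, CD8 T 0.12,
...; NK/DC cells are unlabelled by panel 1 and add to "unidentified"); the
entropy of ~1.69 nats reflects a diverse core; and the Tumor–CD8 contact
score sits at ~0 because cell placement here is completely spatially
random — no attraction or exclusion beyond chance.

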