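---
title: "Whole-section digital quantification of tertiary lymphoid structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-section digital quantification of tertiary lymphoid structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tertiary lymphoid structures (TLS) are organised lymphoid aggregates that
arise in inflamed and tumour tissue. In a single tissue section a TLS appears
as a circumscribed 2D "TLS domain" whose shape, size and cellular content
depend on how the section plane happens to transect a possibly large,
multi-lobular 3D structure. Because of this, counting and typing individual
domains summarises a patient's TLS activity poorly; pooling lymphocyte
phenotypes over *all* TLS domains in a whole section is simpler and more
stable. `tlsquant` implements that whole-section workflow over cell-level
multiplex immunofluorescence exports (one row per segmented cell, µm
coordinates, boolean positivity for CD20, CD3, CD8, Foxp3 and Ki-67), from
phenotyping through domain detection to pooled summaries, correlations and
patient rankings — plus a synthetic tissue generator with full ground truth
so every stage can be validated without images.

## Phenotyping model

Each cell receives exactly one of nine classes. The gates are:

* **B**: CD20+ CD3−
* **CD8T**: CD3+ CD8+ (Foxp3 ignored — the CD8 gate does not consult it)
* **CD4Tconv**: CD3+ CD8− Foxp3−
* **CD4Treg**: CD3+ CD8− Foxp3+
* **undefined**: everything else (typically DAPI-only cells: epithelium,
  stroma, myeloid cells outside the panel)

The four lymphocyte subsets are each split by Ki-67, giving eight lymphocyte
classes; undefined cells carry no Ki-67 sub-classification (nine classes, not
ten). CD20+CD3+ cells fall through to the T-cell gates because the B gate
requires CD3−; the gate order is recorded in the output manifest. The gating
is a total function of the 32 marker combinations, which the test suite
checks by enumeration. CD4 itself is not used: CD3+CD8− cells are taken as
CD4 T-cells, which is the accepted reading in colorectal tissue where
double-positive/negative T-cells are rare.

## Domain detection

TLS domains have historically been circled by eye. `tlsquant` replaces that
with a density-based procedure over lymphocyte centroids only (all four
subsets jointly — section planes can show a pure T-cell zone of a TLS):

1. **Core cells** have at least `min_neighbours` lymphocytes (self included)
   within `neighbour_radius_um`. Clusters are connected components of core
   cells at that radius; non-core lymphocytes within the radius of a core
   join the cluster of their lowest-`cell_id` core neighbour (a deterministic
   tie-break, so results are independent of row order). Everything else is
   noise.
2. **Strand merging.** Neighbouring follicles connected by strands of
   lymphocytes are cross-sections of one structure. Two clusters merge when
   a chain of lymphocytes (members or noise) links them with consecutive
   gaps at most `strand_link_radius_um` and the linking connected set holds
   at least `strand_min_path_cells` cells. Because any connecting path can
   be extended through cluster members (whose gaps are at most the core
   radius), the chain-length condition reduces to connectivity of the
   strand-radius neighbourhood graph together with a minimum component
   size — which is exactly the oracle the tests check against. Merging is
   transitive; merged clusters keep the union of their member cells, so
   bridge cells stay noise and clustered-cell counts are conserved.
3. **Polygonization.** Each cluster's boundary is its alpha shape: the union
   of Delaunay triangles with circumradius at most `hull_alpha_um`. The area
   is the summed triangle area; any member cell left uncovered by the
   circumradius filter has its smallest-circumradius incident triangle
   restored, so the boundary always contains all members. With a large
   alpha this is exactly the convex hull.

Defaults (`neighbour_radius_um` 30, `min_neighbours` 10,
`strand_link_radius_um` 40, `strand_min_path_cells` 5, `hull_alpha_um` 50 µm)
were set once from lymphocyte packing inside follicles (≈0.01 cells/µm², so
a 30 µm disc inside a follicle holds ≈28 lymphocytes, nearly 3× the core
threshold, while scattered stromal lymphocytes at ≈50 cells/mm² hold well
under one). They are configuration values, never hard-coded: no numeric
detection parameters exist in the source literature because detection there
was manual.

## Qualification and metrics

An aggregate qualifies as a TLS domain when it holds **≥ 250 cells** in
total (every cell inside the boundary, undefined included — the inclusion
criterion reads as a fraction of all cells in the aggregate) of which
**strictly more than 50%** are B- and/or T-cells. Both thresholds are
config-exposed; strictness is ≥ for size and > for fraction, exactly as
printed in the criteria the workflow encodes. In-boundary membership is a
boundary-inclusive point test on cell centroids, matching the
centroid-based phenotyping upstream.

Per domain, `tlsquant` reports the nine class counts, per-subset Ki-67
fractions (`NA` when a subset is absent — a sentinel, never an error) and
composition fractions over the eight lymphocyte classes (undefined excluded
from the denominator, so they sum to 1). Per section it reports:

* the qualified domain count,
* total TLS area — the union of domain boundaries, overlaps not
  double-counted (exact sums for disjoint shapes, grid-sampled unions
  otherwise), capped at tissue area so fractions stay in [0, 1],
* tissue area — from supplied annotation polygons when available, otherwise
  a 50 µm grid-occupancy estimate over the cell point pattern (a tile is
  tissue if it contains ≥ 1 cell; the point-pattern analogue of a
  pixel-thresholder tissue mask). Whole-section InForm-style exports
  segment *all* DAPI+ cells, so real tissue is dense in cells and the
  occupancy estimate is faithful; with very sparse exports it
  under-estimates, which is why supplied polygons take precedence,
* tumour area — the union of tumour polygons clipped to tissue by 10 µm
  grid sampling,
* pooled composition (exact element-wise count sums over qualified domains,
  so a pooled Ki-67 fraction is identically the count-weighted mean of
  per-domain fractions), and the unweighted mean over domains of each
  subset's Ki-67 fraction (each domain one vote).

One open reading: whether whole-section TLS area should include aggregates
too small to qualify. `tlsquant` sums qualified domains only; the choice is
recorded here and in the manifest.

## Statistics

Correlation analyses drop TLS domains with fewer than 50 cells of the
assessed phenotypes; we read "assessed phenotypes" as the eight lymphocyte
classes (`n_lymph`), with both the threshold and that semantics
config-exposed. The filter applies only on correlation paths — never to
rankings or areas.

Spearman's rho is computed as Pearson's correlation of average ranks (ties
averaged). Two-sided p-values use the t approximation for n ≥ 10 and the
exact permutation distribution below that; the suite cross-checks both
against `stats::cor`/`cor.test`. Rank correlation is invariant under
strictly monotone transforms, so the log10 scaling used for display never
changes rho or p; scatterplots place zero fractions at half the smallest
positive value rather than dropping them (a log axis cannot show zeros, and
silently dropping them would bias the view).

Domain-level correlations treat each TLS domain as one point and therefore
ignore patient-level clustering; the output metadata flags this caveat. A
generalised linear mixed model would account for it and is deliberately out
of scope — it is an off-the-shelf `lme4` fit, not part of this package's
contribution.

Patient rankings by B-cell proliferation come in the two flavours the
workflow compares: `per_domain_mean` (average per-domain B-cell Ki-67
fraction, each domain one vote) and `pooled` (whole-section pooled
fraction). Ties break by patient id. `compare_rankings()` reports rank-rho,
Spearman's footrule and top-k set overlap (k = 8 by default, matching the
cohort-comparison convention of the study design this emulates).

The non-proliferating Foxp3+ CD4 analysis correlates each domain's
Ki-67− Foxp3+ CD4 count as a fraction of domain lymphocytes against the
Ki-67 fraction of the other subsets. Note a structural coupling worth
knowing about: when a shared activation raises Ki-67 in *all* subsets, the
Ki-67− Treg fraction mechanically falls as activation rises, which produces
a negative correlation even with no suppression planted. The generator's
independence null therefore sets the activation spread to zero.

## The synthetic cohort generator

`cohort_config()` defaults describe the study conditions the pipeline is
meant for, chosen once for realism:

* 22 patients, one 9×9 mm section each.
* Per-section TLS counts drawn log-uniformly on [4, 100] (right-skewed,
  mean ≈ 28 — few structures in most sections, many in a few).
* Structures placed on a jittered grid guaranteeing ≥ 200 µm edge-to-edge
  separation (5× the strand-link radius); a configuration asking for more
  structures than the section can hold is rejected with a degenerate
  geometry error.
* Each structure has a primary lobe (radius 50–100 µm) and on average ~1.5
  lobes; secondary lobes either overlap the primary or (with probability
  0.25) sit apart bridged by a strand of lymphocytes at ≈12 µm spacing.
* Lymphocytes are placed as a homogeneous Poisson process at 0.01 cells/µm²
  per lobe; per-domain composition over (B, CD8T, CD4Tconv, CD4Treg) is
  Dirichlet(4, 1.5, 2.5, 1) — B-cell dominated on average, highly variable.
  B cells occupy the lobe core, T-cells the periphery.
* Ki-67 follows a logistic model: per-patient latent activation
  a ~ Normal(0, 1.5²) on the logit scale shifts all subsets jointly
  (baselines: B −1.8, CD8T −2.2, CD4Tconv −2.0, CD4Treg −1.4), inducing the
  cross-subset correlations the analysis detects. Half the domains carry a
  germinal-centre-like hotspot (radius 0.4× the primary lobe) that boosts
  B-cell Ki-67 by +2 logits, so per-domain B-cell Ki-67 spans roughly
  0–94% across a cohort. An optional `suppression_coeff` lowers activation
  with the domain's Treg fraction for sensitivity analyses (default 0).
* In-domain marker-negative cells at 15% of domain cells; scattered
  background at 0.002 cells/µm², 2.5% of it lymphocytes (≈50/mm²) —
  whole-section exports are dominated by segmented non-lymphocytes, which
  is what makes the occupancy tissue estimate work.
* Marker calls are generated *from* labels (with a little aberrant CD20 on
  T-cells and Foxp3 on CD8 T-cells to exercise gate precedence), so the
  phenotyping stage inverts them exactly — a zero-error oracle.
* One RNG stream per section keyed by (master seed, section index); the
  same config reproduces a byte-identical cohort.

`simulate_domain_table()` shares the composition/Ki-67 machinery but skips
spatial placement, for statistical properties that need many replicate
cohorts (null uniformity of p-values, ranking concordance across seeds).

What the generator does *not* emulate: real segmentation noise (split or
merged cells, thresholding errors), spatially varying background density,
epithelial crypts and vasculature perforating domains, tumour geometry, and
TLS abutting tissue edges. Passing tests therefore demonstrate correctness
of the computational pipeline under the stated spatial model, not
robustness to staining or segmentation artefacts.

## Numerical choices and problem sizes

* Delaunay triangulation is an incremental Bowyer–Watson implementation in
  C++ (no triangulation library being otherwise available to the package);
  cocircular point sets (e.g. a square's corners) accept either diagonal —
  areas are unaffected. Triangulation validity is tested against the
  empty-circumcircle property directly.
* Alpha-shape areas of sampled point sets under-estimate the generating
  region slightly (points do not reach the boundary); on 2,000 points in a
  100 µm disc the error is ≈3%, and truth-recovery tests use a 15%
  tolerance.
* Union areas use exact sums when shapes are pairwise disjoint (checked via
  bounding boxes then mutual vertex containment) and 5 µm grid sampling for
  genuinely overlapping groups, preserving "union ≤ sum with equality iff
  disjoint".
* Exact permutation p-values enumerate all n! rank permutations for n < 10;
  at n = 9 that is 362,880 permutations, evaluated vectorised.
* Test and validation cohorts are scaled to the question: full 22-patient
  spatial cohorts (~3.8M cells) for parameter recovery; 3-patient spatial
  cohorts for functional tests; placement-free domain tables for the
  200-replicate null-uniformity and 50-seed ranking-concordance checks.

## Worked example

```{r, eval = FALSE}
library(tlsquant)

res <- run_pipeline(run_config(generator = cohort_config(), seed = 1))
res
#> <tls_result>
#>   cells:      3796120
#>   domains:   511 qualified of 877
#>   sections:   22
#>   top-8 ranking overlap: 8

dplyr::filter(tidy(res$correlations), level == "section")
tidy(rank_patients(res$domains, "pooled"))
plot_domain_composition(dplyr::filter(res$domains, qualified))
```

## Known limitations

* Tissue-occupancy area needs dense whole-section exports; sparse
  lymphocyte-only exports require explicit tissue polygons.
* Polygon clipping of TLS shapes to tissue polygons is approximated by
  capping TLS area at tissue area (domain shapes derive from cells, which
  lie in tissue by construction).
* Ranking and correlation behaviour is validated on synthetic cohorts whose
  noise structure is simpler than real sections; the concordance numbers
  quoted by the validation scripts are properties of that model.
* No TLS maturity sub-classification (germinal-centre detection would need
  FDC/other markers) and no distance-to-tumour stratification.
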