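---
title: "Pareto task inference in stratified single-cell data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pareto task inference in stratified single-cell data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretocell)
```

## The model

Pareto optimality theory predicts that when cells must perform several
competing tasks, the phenotypes that survive selection are convex
combinations of a small number of *archetypes*, each optimal for a single
task. Geometrically, expression profiles are then bounded by a low-dimensional
polytope — specifically a simplex with `k` vertices — in linear expression
space, and cells near a vertex are specialists for that vertex's task.

`paretocell` tests this prediction within *strata*: donor–tissue–cell-type
subsets of a single-cell atlas, analysed independently so that between-donor,
between-tissue or between-cell-type variation cannot masquerade as within-type
structure. For each stratum the package asks three questions:

1. Is the cell cloud in PC space significantly better described by a
   `k`-vertex simplex than column-shuffled data (the t-ratio shuffle test)?
2. Do the vertices have significantly enriched genes (one-sided
   Mann–Whitney on the nearest cells, Benjamini–Hochberg FDR 0.10)?
3. Are the vertices reproducible across donors and tissues (graph-based
   alignment by shared enriched genes, donor-coverage filter)?

Stratum p-values are aggregated to cell-type calls by a donor-majority rule,
with an exact Poisson-binomial false-positive probability per cell type and a
total-FDR cut over the accepted set.

## Preprocessing and geometry

The preprocessing follows the standard conservative recipe for this analysis,
in a fixed order: genes expressed in fewer than 5 cells are removed; cells in
the upper decile of any of five QC metrics (mitochondrial fraction, artifact
fraction, genes expressed, total counts, UMI counts) are removed (strictly
above the linear-interpolation 0.9 quantile); cells at or below 100
protein-coding counts are removed; mitochondrial and dissociation-artifact
genes are stripped from the modeling matrix; each cell is scaled to 10,000
counts; strata need at least 50 cells and are downsampled (uniform, seeded,
without replacement) to at most 1,000.

All geometry is *linear scale*: no logging, no per-gene scaling. Those
transforms distort pairwise distances, and polytope detection is a statement
about distances. PCA is computed on the mean-centred normalized matrix with a
deterministic sign convention. Within each stratum we (1) compute PCA,
(2) remove the bottom 10% of cells by density in the first 3 components
(k-nearest-neighbour density with `k = ceiling(sqrt(n))`, density defined as
the inverse distance to the k-th neighbour, ties broken by cell index — the
estimator itself is a free choice, as the literature does not fix one),
(3) refit PCA on the surviving cells to stabilize the axes, and (4) drop
components whose |Pearson r| with mitochondrial or artifact fractions exceeds
0.3 (strictly; a component at exactly 0.3 is retained, and a constant signal
counts as correlation zero). The order — density filter on the first three
raw PCs, then refit, then the correlation drop — is one of several defensible
orders; it is fixed here so results are auditable.

## The fitting engine

`fit_simplex()` is classical archetypal analysis: alternating between an
exact projection of every cell onto the current simplex (the convex-weight
step, solved by subset enumeration of the KKT system, exact for k ≤ 6) and a
coordinate-descent vertex update in which each vertex moves to the projection
of its least-squares optimum onto the convex hull of the data (a short
Frank–Wolfe iteration). Constraining vertices to the data's convex hull is
essential: with unconstrained vertices *any* simplex that encloses the data
attains near-zero loss, so the optimizer drifts to arbitrarily inflated
simplices — we measured planted-vertex error growing with optimizer effort
before adopting the constraint. Initialization is furthest-point selection
from the data (first restart from the point furthest from the centroid,
later restarts from random points); ten restarts for observed fits, three for
shuffle refits.

The fitted `vertices` are the archetype positions used for enrichment,
bootstrap ellipses and recovery checks. Separately, for the significance
statistic the vertices are projected to the first `k − 1` components and
expanded outward about their centroid by the smallest factor that gives 99%
of cells non-negative barycentric coordinates. This *enclosing* simplex is
the denominator of the t-ratio (hull volume over simplex volume, values
near 1 meaning simplex-like data) and the reference for the percent of cells
inside the fit. Computing the expansion in the projection rather than in the
full fitting space matters: a `k`-vertex simplex spans only `k − 1`
dimensions, and barycentric coordinates relative to its tilted affine hull in
a higher-dimensional space are dominated by off-plane noise, which inflates
the expansion and destroys the statistic's power.

Convex-hull volumes (2–5 dimensions) are computed by an incremental
beneath–beyond construction with a deterministic relative `1e-8` joggle for
general position, cross-checked in the tests against shoelace areas, analytic
simplex volumes and Monte-Carlo rejection sampling.

## Significance: the shuffle test and the dimension sweep

Each trial permutes every PC column independently across cells (the PCs are
shuffled, never the genes), refits, and recomputes the statistic; the
p-value is `(1 + #better) / (1 + n_shuffles)` — the add-one convention, so a
p-value is never exactly zero. Observed and shuffled fits share the same
optimizer budget (`maxit = 15`, relative tolerance `1e-6`); only the restart
count differs (10 vs 3), a tractability compromise whose effect on
calibration is measured directly by the test suite (200 null strata must
reject within the binomial band around 0.05 and pass a KS uniformity check).

For `k = 2` a volume ratio is undefined in one dimension and shuffling a
single column is a no-op, so the statistic is the fraction of total variance
along the fitted segment direction, compared against the same shuffled-data
distribution.

The dimension sweep takes the first `d` retained PCs for `d = 5, 4, 3, 2`,
chooses `k` on each by the explained-variance elbow (maximal perpendicular
distance to the endpoint chord; ties to the smaller `k`; two-point curves are
anchored at `EV(1) = 0`, since one "archetype" — the mean — explains nothing),
tests at `k*`, and stops at the first `p < 0.05`. All computed p-values are
retained: a stratum swept through four dimensions contributes four p-values
to the aggregation, which deliberately overstates the multiplicity burden and
therefore the estimated FDR.

## Aggregation and FDR

A cell type is called significant when at least 50% of its available donors
have a tissue with any recorded `p < 0.05` (the majority threshold is
`ceiling(D/2)`). For qualifying cell types the probability of a false call
is computed exactly: a null donor with `m_d` recorded p-values is flagged
with probability `1 − (1 − π₀α)^{m_d}`, where `π₀` is the Storey estimate
(`λ = 0.5`, clipped to `[1/m, 1]`, conservative 1 below 20 p-values) of the
null proportion among all recorded p-values — the standard qvalue-style
deflation of the per-test null rate. The number of flagged donors is then
Poisson-binomial, and the tail at the majority threshold is computed by
dynamic programming (checked against exhaustive enumeration to `1e-12`).
Cell types are sorted by this false-positive probability and the largest
prefix with mean below 0.10 is accepted; that mean is the accepted set's
total FDR.

## Enrichment and alignment

For each vertex, cells are ranked by Euclidean distance in the fit space and
the nearest 10% (at least 10 cells) are compared with the rest by a
one-sided Mann–Whitney test per gene — exact where both groups are small and
tie-free, otherwise the tie-corrected normal approximation — over *all*
genes, including mitochondrial and artifact genes, precisely so that
artifact-driven vertices can be recognized. Effect size is the difference of
mean normalized expression, keeping the linear-scale philosophy. BH is
applied per vertex across genes at FDR 0.10, and up to the 10 strongest
positive markers per vertex feed the alignment step.

Alignment builds, within each cell type, a graph over vertices weighted by
the number of shared marker genes (plain set intersection), clusters it with
seeded Louvain modularity, accepts clusters covering at least 50% of the
cell type's donors (a stricter two-thirds variant is a parameter), and
summarizes each accepted archetype by its frequency-ranked consensus genes
after dropping frequency-one genes. Expression profiles use the 5% of cells
closest to each member vertex. A published variant of the coverage rule
includes an unspecified false-negative correction factor; since its form is
not stated anywhere we could verify, it is not implemented.

## The synthetic atlas generator

`generate_atlas()` emulates the study conditions the pipeline is designed
for: donor × tissue × cell-type strata (default 100–250 cells each);
per-cell-type archetype profiles with log-normal baseline expression
(`meanlog = 1`, `sdlog = 1`), mild per-archetype jitter on non-marker genes,
and 10 dedicated markers per archetype at fold 4; mixture weights
`Dirichlet(0.65)` so vertices are populated but the interior is non-empty;
per-cell library-size factors `log-normal(0, 0.3)` that the 10,000-count
normalization must remove; Poisson (or negative-binomial, dispersion 0.5)
counting noise; a contaminated cell fraction (default 5%) with inflated
mitochondrial/artifact counts for the QC filters to catch; and null cell
types with mutually independent log-normal-rate Poisson genes. A single
atlas seed derives all per-stratum seeds, so atlases are fully reproducible.

What the generator does *not* emulate: doublets, ambient RNA, batch effects
beyond library size, curved (non-simplicial) Pareto fronts, and realistic
gene–gene correlation structure outside the planted simplex. Passing the
planted-truth checks therefore demonstrates that the machinery is correct
and calibrated under its own assumptions, not that any particular real
tissue is polytopal.

## Parameter summary

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | per-stratum significance threshold |
| `n_shuffles` | 1000 | shuffle trials (p resolution 1/1001) |
| `dims` | 5,4,3,2 | PC dimensions swept (k between 2 and 6) |
| `r_threshold` | 0.3 | PC-vs-artifact correlation drop |
| `density_drop` | 0.10 | density-filter fraction, first 3 PCs |
| `min_cells`, `max_cells` | 50, 1000 | stratum size window |
| `enrichment_fdr_cap` | 0.10 | BH cap for vertex markers |
| `bin_fraction` | 0.10 | nearest-cell bin for enrichment |
| `closest_fraction` | 0.05 | cell bin for archetype profiles |
| `coverage_threshold` | 0.5 | donor coverage for an archetype |
| `celltype_fdr_cap` | 0.10 | total FDR over accepted cell types |
| `n_boot` | 100 | bootstrap replicates for vertex ellipses |

## Verification scale

The statistical checks shipped with the package run at desk scale on one
core: 200 null strata (500 cells × 300 genes) with 200 shuffles for
calibration; 50 planted triangle/tetrahedron strata (1,000 cells, vertex
noise 5% of edge) for power and recovery; 50 enrichment strata with 20
planted markers among 500 genes; and 10 replicate synthetic atlases
(4 donors × 2 tissues × 3 cell types, one null) for end-to-end
discrimination with 200 shuffles. The same quantities are recomputed from
scratch by `scripts/acceptance.R`.

## Known limitations

* The shuffle test is approximately calibrated: measured rejection on
  independent-gene nulls is near, but slightly above, the nominal 0.05
  (within the binomial acceptance band), and PCA-conditioned nulls tend to
  be slightly conservative. This mirrors the behaviour of permutation-on-PCs
  testing generally.
* The t-ratio loses resolution for `k = 2` (the variance-fraction surrogate)
  and for very small strata, where the hull estimate is coarse.
* Like all least-squares simplex estimators, the fitted vertices carry a
  small outward radial bias under ambient noise (only cells outside the
  simplex exert force on the vertices); at noise of 5% of the edge length
  the measured mean vertex error is about one noise standard deviation,
  concentrated in the radial direction for triangles.
* The total-FDR acceptance rule admits, by design, up to 10% false cell
  types among the accepted set. When very few cell types are analysed, a
  single spuriously qualifying cell type can ride along with strong true
  positives while the accepted set's FDR stays below the cap; the rule
  controls the error *rate*, not individual mistakes.
* Archetype annotation is a pluggable hook (`annotate` argument of
  `align_archetypes()`); the default label is "unannotated". No language-model
  or gene-set annotation is bundled.
* Alignment is within cell type only; no cross-cell-type archetype matching.

```{r example, eval = FALSE}
# a compact end-to-end run on a synthetic atlas
ga <- generate_atlas(4, 2, list(typeA = list(k = 3), null_type = "null"),
                     seed = 1)
res <- run_pipeline(ga$atlas, pipeline_config(n_shuffles = 200, seed = 1))
print(res)
plot(res$fits[[1]])
```
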