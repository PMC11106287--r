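# atlasquant

Atlas-based regional quantification of stained features in serial brain
sections, with nonlinear registration refinement, sampling-based quality
control, and integration of regional stain load with bulk gene expression.

The package is aimed at groups running atlas-registered histology pipelines
(e.g. for neurodegeneration models across ages and genetic backgrounds) who
need the analysis side of that workflow as programmable, testable R
functions: slicing a labeled 3D annotation volume into atlas plates,
refining a linear registration with anchor-point deformations, scoring
registration accuracy and section damage by systematic random sampling,
compiling custom region hierarchies, measuring per-region stain load, and
relating load to bulk RNA-seq expression with and without age adjustment.
A synthetic-data module generates every input with known ground truth, so
the whole pipeline is verifiable without any atlas or sequencing download.

## The quantities it computes

* **Load** — percent stain-positive coverage per atlas-region area:
  `load = 100 · stained_pixels / region_pixels`, with background,
  unassigned, and mask-excluded pixels outside both counts. Brain-level
  loads pool pixel counts over retained sections.
* **Registration QC scores** — over systematic-random-sampling markers with
  counts a/i/u (accurate/inaccurate/uncertain):
  `accuracy = a/(a+i)`, `uncertainty = u/(a+i+u)`; regional means are
  unweighted over assessments, excluding assessments whose markers were all
  uncertain. Sections whose damage fraction `d/(d+intact)` strictly exceeds
  30% are excluded from quantification.
* **Nonlinear refinement** — a continuous piecewise-affine deformation
  field over a Delaunay triangulation of dragged anchor points plus a fixed
  boundary frame; exact at anchors, identity at zero displacement.
* **Load–expression correlation** — per gene, Pearson r of normalized
  expression (median-of-ratios size factors, `log2(x+1)`) with regional
  load, unadjusted (df `n−2`) and age-adjusted by within-age-group
  centering (df `n−k−1`), FDR-corrected (Benjamini–Hochberg); genes are
  categorized `age_dependent` / `age_independent` / `both` / `neither` by
  exclusive significance at α = 0.05.

## Worked example

Simulate an 8-region mini-atlas, slice and warp three sections, refine them
back with the true inverse anchors, QC the registration, and quantify load
against the designed stain densities:

```r
library(atlasquant)

atlas <- generate_atlas(c(64, 64, 64), n_leaf_regions = 8, n_parents = 2, seed = 1)
leaves <- setdiff(atlas$tree$id, c(1L, 2L, 3L))
h <- compile_hierarchy(atlas$tree, leaves)
secs <- generate_sections(atlas, n_sections = 3, warp_amplitude = 6, seed = 1)

refined <- lapply(secs, function(s) refine_section(s$observed, s$anchors))

grids <- lapply(secs, function(s) make_grid(s$truth$width, s$truth$height, 15, seed = 1))
pre  <- qc_score(Map(function(s, g) oracle_assess(s$observed, s$truth, g, h), secs, grids))
post <- qc_score(Map(function(r, s, g) oracle_assess(r, s$truth, g, h), refined, secs, grids))
cbind(region_id = pre$regions$region_id,
      linear  = round(pre$regions$mean_accuracy, 3),
      refined = round(post$regions$mean_accuracy, 3))
#>      region_id linear refined
#> [1,]       101  0.946       1
#> [2,]       102  1.000       1
#> [3,]       103  1.000       1
#> [4,]       104  0.971       1
#> [5,]       105  1.000       1
#> [6,]       106  1.000       1
#> [7,]       107  0.963       1
#> [8,]       108  0.458       1
```

Every region's mean accuracy reaches 1.0 after refinement; region 108,
badly displaced by the 6 px warp (0.458 accurate under linear registration
alone), is fully recovered.

```r
dens <- setNames(rep(c(0.02, 0.05, 0.10, 0.30), 2), leaves)
counts <- Map(function(s, r, k) {
  seg <- generate_stains(s$truth, dens, stain = "Iba1", seed = k)
  section_load(relabel(r, h), seg)
}, secs, refined, seq_along(secs))
loads <- brain_load(counts, brain = "demo", stain = "Iba1")
transform(loads[, c("region_id", "region_pixels", "load")],
          designed = 100 * dens[as.character(loads$region_id)])
#>     region_id region_pixels      load designed
#> 101       101         14032  1.974059        2
#> 102       102          2708  4.948301        5
#> 103       103         10296 10.324398       10
#> 104       104          4040 30.668317       30
#> 105       105          1163  1.977644        2
#> 106       106          3596  5.116796        5
#> 107       107          7272  9.997250       10
#> 108       108          5280 29.848485       30
```

Measured loads track the designed densities to within binomial sampling
error of the pooled region areas (e.g. 1.97% vs 2%, 10.32% vs 10%,
30.67% vs 30%).

For the expression side, `simulate_load_cohort()` +
`generate_expression()` build a paired load/expression cohort and
`correlate_expression()` returns per-gene unadjusted and age-adjusted
correlations, q-values, and categories.

A thin command-line front end ships at `inst/cli/atlasquant.R` with
`simulate`, `quantify`, and `correlate` subcommands over the same
functions; `simulate` emits a complete ready-to-run project directory
(volume, hierarchy, anchorings, deformations, segmentations, masks,
counts, metadata, truth record).

## Vignette

`vignettes/atlasquant-methods.Rmd` documents the measurement model, score
definitions, the deformation-field design, what the synthetic generators
emulate (and what they do not), numerical conventions, and known
limitations.
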