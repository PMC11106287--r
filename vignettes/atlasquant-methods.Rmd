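---
title: "Methods: atlas-based quantification of stained features in serial sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: atlas-based quantification of stained features in serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasquant)
```

# The measurement model

`atlasquant` quantifies immunohistochemistry in serial brain sections
relative to a 3D reference atlas. The pipeline mirrors the registration →
refinement → quality-control → quantification → integration chain used in
atlas-based histology workflows:

1. **Atlas plates.** Each section is placed in atlas space by a linear
   anchoring: an origin `o` and two full-extent in-plane vectors `u`, `v`
   (voxel units). The atlas plate is obtained by sampling the annotation
   volume at each pixel center, `o + u(x+0.5)/W + v(y+0.5)/H`, with
   nearest-neighbor label lookup. Labels are categorical and are never
   averaged; sample points outside the volume become background 0.
2. **Nonlinear refinement.** Anchor points dragged from their overlay
   position (`start`) to their correct position on the section (`end`)
   induce a continuous deformation field over the whole image. We represent
   it as a piecewise-affine map over a Delaunay triangulation of the end
   points plus a fixed boundary frame (four corners and four edge midpoints
   with zero displacement). The stored field is the *pull-back* (section
   pixel → overlay coordinate) so label resampling needs no numerical
   inversion.
3. **Sampling QC.** Registration quality and tissue damage are scored by
   systematic random sampling: a regular lattice with a uniformly random
   global offset. Raters (or the built-in oracle) label each marker
   accurate / inaccurate / uncertain (QC) or damage / intact (integrity).
4. **Load.** For every atlas region, load is the percent stain-positive
   coverage per region area,
   `load = 100 * stained_pixels / region_pixels`.
5. **Integration.** Regional load is correlated with bulk RNA-seq
   expression per gene, with and without adjustment for age group, to
   separate age-dependent from age-independent load correlates.

# Score definitions

With per-region marker counts `a` (accurate), `i` (inaccurate),
`u` (uncertain):

* accuracy = `a / (a + i)` — defined only when at least one marker could be
  verified;
* uncertainty = `u / (a + i + u)`;
* regional mean accuracy = unweighted mean over assessments (one rater on
  one brain) with *defined* accuracy. An assessment whose markers in a
  region are all uncertain is excluded from that region's mean. The SEM is
  taken over the contributing rater-by-brain assessments.
* damage = `d / (d + intact)` per section; a section is excluded when
  damage strictly exceeds 30%. The strictness matters: a section at
  exactly 30% is retained.

Grid spacings default to 15 px for QC assessment and 5 px for damage
markup, both overridable. "Voxel" spacing is interpreted as pixels of the
registered overlay, since assessment happens at registration resolution.
Markers take the label of the pixel they fall in (pixel-center rule);
border ties are not special-cased.

# Design choices in the deformation field

The anchor-driven interpolant of the original interactive tool is
unpublished, so this package commits to a documented stand-in:

* **Piecewise-affine over Delaunay.** Continuous across triangle edges,
  exact at anchors (to machine precision), identity when no anchor moves,
  and cheap to evaluate. Smooth low-order warps are locally near-affine, so
  a modest anchor lattice approximates them well; correctness is asserted
  through behavior (the dense-anchor convergence and
  refinement-improves-accuracy tests), not bit-compatibility.
* **Fold-overs are permitted.** If dragged anchors cross, point location on
  the end triangulation decides, ties broken by lowest triangle index, and
  the affected pixels follow whichever triangle claims them first.
* **Out-of-frame pull-backs** produce background 0.
* **Degenerate configurations.** Gridded anchors create cocircular point
  sets; the triangulation breaks ties with an infinitesimal deterministic
  perturbation that affects topology only — the affine transfer always uses
  the exact anchor coordinates. No triangulation library for R is part of
  the package's dependency set; the incremental Bowyer–Watson construction
  is implemented here and exercised by the field's exactness and coverage
  properties.

# Regional loads

Background (0) and unassigned pixels are excluded from both numerator and
denominator, as are pixels under an exclusion (e.g. hemibrain) mask —
load is per atlas-region area only. Regions left with zero pixels are
absent from the output rather than reported as 0/0.

Brain-level loads **pool pixel counts** across the retained sections of a
brain and recompute the percentage from the pooled counts. The alternative
(averaging per-section loads) weights a region's sections equally however
little of the region they contain; pooling weights by sampled area, which
matches the counting character of the measurement. Two sections of
(100 px, 10 stained) and (300 px, 90 stained) therefore pool to 25.0%, not
to the 20.0% mean of 10% and 30%.

# Expression integration

* **Filtering.** A gene is kept when strictly more than 50% of samples have
  strictly more than 10 expected read counts. Both inequalities are strict,
  so a gene at exactly 50% fails.
* **Normalization.** Median-of-ratios size factors against a per-gene
  geometric-mean reference over genes with all-positive counts, then
  `log2(normalized + 1)`. This re-implements the standard bulk RNA-seq
  normalization rather than reproducing any particular package's pipeline
  bit-for-bit (a unit test cross-checks the size factors against DESeq2);
  `normalize_counts(log = FALSE)` gives the linear scale for users who
  prefer to correlate untransformed normalized counts.
* **Age adjustment.** The age-adjusted correlation centers load and
  expression within each age group and computes Pearson's r on the pooled
  centered values, with p from a t transform on `n - k - 1` degrees of
  freedom (`k` age groups). For a two-level grouping this is the standard
  repeated-measures estimator and is equivalent to the correlation from a
  random-intercept-per-group model; no richer random-effect structure is
  assumed. Groups with fewer than two samples cannot contribute a within-
  group contrast and are dropped with a warning.
* **Categories.** At α = 0.05 (uncorrected, by convention): significant
  only before adjustment → `age_dependent`; only after → `age_independent`;
  both → `both`; otherwise `neither`. Genes with undefined r in either
  method are `neither` and flagged. FDR control is Benjamini–Hochberg.

# What the synthetic data emulates

The generator provides every input with known ground truth so the full
pipeline is testable without downloads:

* **Atlas**: a 3D Voronoi tessellation of random sites — irregular,
  contiguous regions of varied size that exercise boundary-heavy QC
  behavior better than boxes would — grouped under parent regions and one
  root.
* **Sections**: anchoring planes across the volume with mild random
  obliquity; the "observed" (linearly registered) map is the truth
  resampled through a smooth random low-order warp whose boundary envelope
  vanishes at the image edge, so the piecewise-affine refinement can
  approximate it and the true inverse anchor set stays in frame. Damage is
  placed as contiguous blobs, mimicking tears and folds rather than
  salt-and-pepper noise.
* **Stains**: each pixel of region *r* is positive independently with
  probability `p_r`, so the measured load has an exact binomial reference
  distribution: with pooled region area `n`, the pipeline load should fall
  inside the 99% interval of `Binomial(n, p_r)`. This check is run on
  correctly registered sections, separating quantification error from
  registration error; the effect of registration error on loads is
  measured separately via the refined-vs-linear load difference, which is
  exactly zero at warp amplitude 0 and nonzero for boundary-heavy regions
  under warp.
* **Expression**: negative-binomial counts whose log-mean tracks the
  between-age-group load component (age-dependent genes), the
  within-group-centered load (age-independent genes), both, or neither.
  Effect sizes are calibrated from the negative-binomial log-scale noise to
  hit a requested correlation.

The default load cohort (`simulate_load_cohort`) uses group mean loads of
2% and 6% with a within-group standard deviation of 0.3%. This emulates a
strongly age-driven stain — the regime in which the age-dependent /
age-independent distinction is meaningful: when the age effect dominates
the within-group load variance, a gene tracking only within-group load
variation remains non-significant in the unadjusted analysis and the four
categories are recoverable. Were within-group variance comparable to the
age effect, genuinely age-independent genes would co-correlate with raw
load and collapse into the `both` category; that is a property of the
design, not of the estimator.

What the synthetic data does **not** emulate: photorealistic histology
(segmentation quality is assumed), rater disagreement beyond the
deterministic oracle, batch structure in expression, and anatomically
shaped regions. Passing tests therefore demonstrate correctness of the
measurement and inference machinery under known truth, not robustness to
real staining artifacts.

# Numerical conventions

* Voxels are 0-based with centers at integer coordinates; section pixels
  are 0-based, `(0,0)` top-left, with continuous image coordinates spanning
  `[0, W] × [0, H]` and pixel `(x, y)` owning `[x, x+1) × [y, y+1)`.
* Anchoring landmark fits (`fit_anchoring`) solve the least-squares system
  in continuous image coordinates and are exact on consistent pairs.
* The sampling-grid offset is drawn uniformly from `[0, spacing)²`,
  clamped to the image extent so a lattice coarser than the image still
  places one point.
* All generators are pure functions of (parameters, seed); seeds are
  restored after use so library calls do not disturb the caller's RNG
  state.

# Problem sizes

The shipped checks run the full pipeline on a 96³-voxel atlas with 8 leaf
regions, 6 sections of 192 × 192 px, designed densities
{0.02, 0.05, 0.10, 0.30}, a warp amplitude of 8 px for the refinement
study, an expression cohort of 200 samples with 500 genes per category at
target r = 0.6, and 500 null replicates of the two-way group comparison.
These sizes give the binomial and empirical-rate checks tight reference
distributions (pooled region areas of order 10⁴–10⁵ pixels; rate standard
errors below 0.01) while keeping a complete run in the order of seconds.

# Known limitations

* The deformation field is a documented stand-in for an unpublished
  interactive interpolant; agreement is behavioral, not bitwise.
* Two-way group comparisons use sequential (Type I) sums of squares via
  `aov`; with unbalanced designs the factor order matters, and the
  rank-based method comparison (`compare_methods`) covers only the paired
  refined-vs-linear contrast.
* Object-level counts (per-cell splitting), color deconvolution, automated
  linear registration, enrichment analysis itself, and batch correction are
  out of scope; `export_ranking` hands ranked coefficients to external
  enrichment tools.
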