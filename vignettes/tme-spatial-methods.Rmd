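---
title: "Methods: quantifying tumor-immune spatial organisation from MxIF cell tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying tumor-immune spatial organisation from MxIF cell tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmespat)
```

## The problem and the data model

Multiplexed immunofluorescence (MxIF) assigns each segmented cell of a
tissue section a centroid, an intensity per marker (optionally per
subcellular compartment), and quality-control metrics. `tmespat` starts at
that table — image processing, segmentation and registration are upstream
and out of scope — and asks two spatial questions about the tumor
microenvironment (TME): *where* are the cell-class aggregates (tumor
nests, T-cell infiltrates) and how much do they overlap, and *what* does
the immediate neighborhood of each cell look like?

A `cell_table` is a plain data frame with canonical columns (`cell_id`,
`fov_id`, `sample_id`, `x`, `y`, QC columns, one column per marker) plus a
unit flag. Conversion from pixels to microns is explicit
(`pixels_to_microns()`) and idempotent via the unit flag; the pixel size
has no defensible universal default (it depends on the objective and
camera) and must come from imaging metadata.

## QC filtering

Cells are excluded when the nuclear alignment score across staining rounds
falls below 0.85, when any of the nucleus/membrane/cytoplasm compartments
has fewer than 10 pixels, or when segmentation produced more than 2 nuclei
per cell. All boundaries are inclusive for retention, matching the usual
"≥ / ≤" reading of such thresholds. Cells with *missing* QC fields are
rejected by default — silently passing unvalidated cells is the worse
failure mode — with a `"pass"` override. The report counts exclusions per
rule; a cell may fail several rules, so per-rule counts can exceed the
unique total. The platform also reports an all-rounds alignment metric
with no established cutoff; an optional threshold for it exists and is
disabled by default.

## Phenotyping and HLA-1 calling

In place of a trained classifier (whose training data cannot be shipped),
phenotypes are assigned by explicit marker rules: a cell is positive for a
marker when its intensity is strictly above the rule threshold. The
default panel encodes the standard immunology: S100 marks tumor cells,
CD3 and CD20 are mutually exclusive (T vs B cells) — a cell above
threshold for both is labelled `ambiguous` and excluded from downstream
counts rather than guessed — CD8⁺PD1⁺ co-positivity defines exhausted-type
cytotoxic T cells (taking priority over plain CD3), and CD4⁺FOXP3⁺
co-expression defines regulatory T cells. Cells matching no rule are
`unclassified`, so the labels partition the table.

Tumor HLA-1 status is called against an internal control: CD3⁺ cells
express HLA-1 ubiquitously, so the positivity threshold is a fraction
(default 0.10) of the pooled CD3⁺ HLA-1 intensity. "10 % of the CD3⁺
intensity" is ambiguous about the statistic; the package defaults to
0.10 × median over CD3⁺ cells pooled across all regions, with the mean,
per-FOV pooling, and an alternative reading (the 10th percentile of the
CD3⁺ HLA-1 distribution) available as configuration. The call is
scale-equivariant — rescaling all HLA-1 intensities by a positive constant
changes nothing — and the threshold used is recorded on the result. A
table with no CD3⁺ cells in scope is an error, not a silent all-negative
call.

## The aggregation algorithm

For one cell class on one FOV window:

1. subdivide the window into squares of side $s$ (default 50 µm; the
   source analyses never state their grid size, so the default is chosen
   at the scale of a few cell diameters and is always explicit in
   configuration);
2. count the class's cells per square (half-open bins, last edge closed,
   so each cell lands in exactly one square);
3. form the distribution of per-square counts, zeros included;
4. seed aggregates at squares whose count is *strictly above* the
   $p$-th percentile (default 95) of that distribution, computed with
   linear interpolation (the standard type-7 quantile, pinned by tests —
   note that a perfectly uniform grid therefore yields no seeds);
5. grow each seed one layer at a time: adjacent squares (8-connectivity
   by default, i.e. the full surrounding ring; 4-connectivity optional)
   are absorbed when they hold at least $\tau$ cells (the growth cutoff),
   until no adjacent square qualifies;
6. merge aggregates that come to share squares — the result is therefore
   independent of seed processing order;
7. contain each aggregate's squares in a polygon: possibly multi-part,
   possibly with interior holes.

Two semantic points deserve emphasis because they are easy to get subtly
wrong. Growth only ever absorbs squares at or above the cutoff, so a seed
whose own count is below the cutoff (possible when $\tau$ exceeds the
95th-percentile count) is retained as an aggregate center but can *not*
act as a bridge merging two otherwise-separate dense components; and two
adjacent below-cutoff seeds remain two aggregates. The test suite pins
these cases against an independent layer-by-layer growth simulation on
random grids.

The growth cutoff default is `auto` = the median of the class's nonzero
per-square counts, a density-adaptive rule that needs no tuning input;
any integer can be supplied instead. For sparse diffuse classes the
`auto` rule can drop to 1 and aggregates then sprawl across background
squares — the end-to-end pipeline therefore pins an explicit cutoff
(3 cells/square ≈ 1 200 cells/mm², a modest aggregate density) in its
default configuration.

**Geometry.** Because aggregates are by construction unions of grid
squares, all region arithmetic is exact integer set arithmetic: area is
`n_squares × s²` identically, and the infiltration area (IA) — the
intersection of the tumor-aggregate union with the CD3⁺-aggregate union —
is a square-set intersection, so `IA ⊆ tumor` and `IA ⊆ CD3` hold exactly
rather than to floating-point tolerance. No geometry library is required
(none is available in the target environment); polygon outlines for
WKT/GeoJSON export are traced by cancelling shared edges and chaining the
survivors into rings, with counter-clockwise rings as outer boundaries and
clockwise rings as holes. Diagonally touching squares are emitted as
separate polygon parts that meet at a corner. Point-in-region tests are
boundary-inclusive (a centroid on an edge is inside), so inside/outside
splits partition a cell table exhaustively. The infiltration fraction
|IA| / |tumor| is undefined (missing, never infinite) when an FOV has no
tumor aggregate.

## The neighborhood analysis

Every cell of the configured center classes anchors a circular
neighborhood of radius $R$; cells at distance exactly $R$ are inside, the
center itself is not. Per neighborhood the algorithm records counts of
each subtype and the nearest-neighbor distance (NND) to each requested
target class *within the neighborhood* — NND is missing when no target
lies within $R$ (an unbounded diagnostic mode exists, off by default).
Records are tagged `inside_IA`/`outside_IA` by the boundary-inclusive
point test of the center.

The original description calls 12 µm the optimal "neighborhood size"
after scanning 2–50 µm, while elsewhere describing a 50 µm *diameter*
neighborhood; the parameter is therefore named `radius_um` everywhere and
every output records it, containing the ambiguity. The default is
12 µm — roughly one cell diameter of separation, the scale of direct
cell–cell contact.

NND summaries use a two-stage mean: per-cell NNDs averaged within each
FOV, then an unweighted mean across FOVs (matching the
triangles-plus-dotted-line convention of per-FOV reporting). Whether
published cross-FOV distance means were FOV- or cell-weighted is not
stated, so both weightings are emitted side by side. FOVs with no
non-missing NND are excluded from the cross-FOV mean and flagged with
`n = 0`. The fixed-radius search is grid-bucketed for speed and is pinned
exactly — counts and distances — against an $O(n^2)$ all-pairs oracle on
random instances.

## Quantification layer

Per-FOV ratio panels (HLA-1⁺ tumor / all tumor, CD3 / tumor,
CD8PD1 / tumor, CD20 / all immune, CD4FOXP3 / all immune, each
configurable) use missing values, never infinities, for zero
denominators, and can be restricted to a region such as the IA. Pearson
correlograms across FOVs use complete-case rows per pair, two-sided
p-values, an `insufficient_data` flag below a minimum n (default 3; the
question-mark cells of a published correlogram) and a `not_significant`
flag above α = 0.05 (the crossed-out cells). The coefficient of variation
is the sample (n−1) standard deviation over the mean.

The Cochran–Mantel–Haenszel chi-square over stratified 2×2 tables is
computed from the closed form (summed hypergeometric deviations over
summed variances, 1 df, continuity correction off by default and pinned
in configuration), which also covers the single-stratum case; it is
verified against `stats::mantelhaen.test` on random stratified tables.
How the published brisk/non-brisk comparison binarized and stratified its
infiltration fractions is not recoverable, so the package exposes the
generic test plus a documented recipe used by the pipeline: outcome =
FOV fraction above the cohort median, strata = sample. Reproducing the
published p-value is accordingly not asserted anywhere. "Welch t test to
compare median expression levels" is internally contradictory; the
package applies Welch's t (Satterthwaite df) to per-cell intensities, the
conventional reading, and the degenerate both-groups-constant case
returns p = 1 (equal) or 0 (different) by convention.

## The synthetic-data generator

`generate_fov()` emits a stated world, not a fitted one: circular tumor
nests with cells uniform in each disc (defaults: 600 × 600 µm window, two
nests of 120 µm radius, 400 tumor cells each ≈ 8 800 cells/mm², a
realistic tumor cellularity; absolute densities of the original material
are unpublished, so these are declared, not inferred), an i.i.d. HLA-1⁺
fraction per nest (default 0.6), and immune classes placed uniformly —
except T cells, which with mixture weight $a/(1+a)$ are displaced from a
random HLA-1⁺ tumor cell by an isotropic Gaussian of scale 15 µm.
`attraction = 0` is complete spatial randomness (verified by chi-square
uniformity tests at the expected false-positive rate); increasing $a$
monotonically deepens the NND contrast between CD3→HLA-1⁺ and
CD3→HLA-1⁻, which the recovery tests read back out. The
displacement-kernel mixture was chosen over a Gibbs/Strauss process
because it is exactly seedable, trivially reproducible, and sufficient to
induce the orderings under test.

Marker intensities are lognormal: background `lnN(log 8, 0.5)`, positive
`lnN(log 500, 0.5)`. The wide separation makes rule-thresholding errors
rare (≈ 10⁻⁴–10⁻³ per cell at the default threshold of 150), so phenotype
recovery is known and testable. A configurable `qc_noise` fraction of
cells receives exactly one failing QC value each; the QC stage must
remove exactly that planted set. Cohorts pair "brisk" samples (attraction
6, 400 CD3 cells/FOV) against "non-brisk" (attraction 0.5, 120 CD3
cells/FOV).

What a green test does *not* establish: the generator has no stroma, no
cell-size exclusion effects, no intensity batch drift, no spatial
autocorrelation of marker expression, and no segmentation artefacts
beyond the planted QC failures — so passing recovery tests validates the
algorithms' correctness on their stated assumptions, not robustness to
real-world imaging pathology.

**Cluster-recovery scoring.** Ground truth for nest recovery is the set
of grid squares whose center lies inside a nest disc — the squares the
disc covers by at least about half. Matching that rule, the recovery
tests grow aggregates with cutoff = half the expected interior density
per square (≈ 11 cells at the defaults, computed from the declared
generator parameters, not tuned): a square is then absorbed roughly iff
the nest covers half of it, which is the same coverage criterion the
ground truth uses. With the density-adaptive `auto` cutoff the recovered
set is systematically tighter and the Jaccard overlap correspondingly
lower (≈ 0.72 vs ≈ 0.92 median) — a definition mismatch, not an
algorithmic failure.

## Numerical and policy choices, collected

- Quantile definition: type-7 (linear interpolation), strictly-greater
  seeding.
- Binning: half-open with closed last edge; window default = tight
  bounding box of the FOV's cells (extents are never stated upstream),
  with explicit-bounds override used whenever grids must align with a
  known frame.
- Distances: Euclidean, boundary-inclusive at $R$; point-in-region
  boundary-inclusive with a 10⁻⁹ gridline tolerance.
- Missing over sentinel values throughout (zero-denominator ratios,
  absent NNDs, undefined CVs).
- Determinism: every stochastic routine takes a seed; the pipeline
  manifest records a configuration fingerprint, and reruns are
  byte-identical.

## Known limitations

Aggregate geometry is grid-resolution-limited: polygons are unions of
squares, not smooth outlines, and results depend on the declared square
size. The HLA-1 call presumes a usable CD3⁺ population in scope. The
rule-based phenotyper does not model intensity spillover or
autofluorescence. Survival analysis and any image-level processing are
deliberately absent.
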