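---
title: "Skeleton-graph morphometry of dural microvascular networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton-graph morphometry of dural microvascular networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duravasc)
```

## The measurement problem

Ovarian-hormone deficiency remodels the blood and lymphatic
microvasculature of the cranial dura mater. Quantifying that remodeling
from confocal images requires reducing annotated 2D vessel masks —
arterioles, venules, regions too ambiguous to attribute, and (in a
separate staining) podoplanin-positive lymphatics — to a small set of
per-image numbers: total and per-class vessel length, the lengths and
arc-chord tortuosities of *complete* centerline segments, the fractional
image area occupied by vessels, alpha-smooth-muscle-actin (α-SMA)
coverage of vessels and its stromal complement, and counts of
PDPL-positive cells. Per-image numbers are averaged per animal, and the
animal-level means of two groups (control vs ovariectomized) are
compared with an unpaired t-test.

This package implements that pipeline end to end, together with a
synthetic scene generator whose ground truth is analytic, so that every
stage can be validated without access to the original images.

## From mask to graph

**Skeletonization.** The union of all vessel classes is thinned to a
one-pixel-wide centerline by sequential deletion of *simple* points
(pixels whose removal provably preserves the topology of an 8-connected
foreground over a 4-connected background, tested with the standard
neighbourhood-component criterion). Deletion proceeds in four
directional subpasses with candidates collected before each subpass, so
at most one boundary layer is peeled per subpass and the skeleton stays
medial; a final cleanup removes residual two-pixel blocks and staircase
redundancy. Because every single deletion is of a simple point, the
component and hole structure of the mask is preserved exactly — this is
tested as a property over random blob masks.

**Node taxonomy.** Skeleton pixels with three or more skeleton
neighbours are junction pixels; 8-adjacent junction pixels are merged
into one *branching* node placed at the cluster pixel nearest the
cluster centroid (thinning produces two-pixel junction clusters that
would otherwise double-count nodes; ties break to the smallest
(row, col)). Pixels with exactly one neighbour are *endpoints*. Where
two consecutive centerline pixels carry different vessel classes, a
*transition* node is inserted at the first pixel of the new class and
shared by both resulting segments. A segment is **complete** when both
of its end nodes are branching or transition points; segment-level
statistics (length, tortuosity) are computed exclusively over complete
segments, whereas total network length sums all segments. Segments that
reach the image border end at an endpoint and are therefore never
complete.

Three degenerate situations are handled explicitly rather than
silently: node-free cycles receive one artificial anchor node at their
lexicographically smallest pixel (the cycle is excluded from tortuosity,
chord zero); isolated single pixels become flagged degenerate nodes;
and junction clusters whose realized incidence falls below three on
unusual thinned shapes are demoted or flagged. Flagged (artificial)
nodes are exempt from the class's degree invariants, which are otherwise
enforced by the `SkeletonGraph` validity method.

**Spur pruning.** Thinning sprouts short terminal branches at
vessel-wall irregularities. Terminal branches shorter than
`minSpurLength` (default **5 px**, configurable and recorded in the run
manifest) are deleted when their removal cannot disconnect the skeleton;
the operation iterates to a fixed point and is idempotent. The default
suppresses thinning artifacts at the widths used here (3–5 px vessels)
without deleting true branchlets, which in the synthetic scenes are at
least 12 px long.

## Metrics and their estimators

**Path length** is the weighted step sum along the pixel polyline: 1 per
axial step, √2 per diagonal step, times the pixel size (µm/px; default
1, in which case all lengths are reported in pixel units and the output
records the unit). **Tortuosity** is path length over the Euclidean
distance between the segment's endpoints, clamped to 1 from below within
1e−9 to absorb floating-point noise; zero-chord loops yield a flagged
missing value. **Vessel area fraction** is the count of non-background
pixels over the image area.

A limitation worth stating plainly: the (1, √2) step metric
over-measures 8-connected digitizations of curved paths — for a line at
angle θ the bias is cos θ + (√2−1) sin θ, up to ≈ 8% at 22.5° and ≈ 5.5%
averaged over directions. On synthetic scenes this appears as a small
systematic over-estimate of total length (a few percent, covered by the
±5% recovery check), and on a rasterized semicircle it places the
measured tortuosity near 1.63–1.65 rather than π/2 ≈ 1.571. No standard
topology-preserving thinning plus step-metric combination avoids this;
the package keeps the conventional estimator and documents the bias
rather than smoothing polylines, which would break the exactness of the
straight-line and L-path cases.

**Undetermined regions** (vessel areas that could not be attributed to
either class) are counted in total vessel length and in the pooled
segment statistics, but excluded from arteriole- and venule-specific
statistics; a determined-only total is also emitted.

## Fluorescence quantification

The blood-vessel mask for α-SMA coverage can be supplied externally or
produced by a deterministic classical segmenter (Gaussian smoothing,
Otsu or fixed threshold, small-object removal) standing in for learned
segmentation. **α-SMA signal is summed intensity**, not thresholded
area: vessel-associated signal is the sum over the vessel mask, coverage
is signal per vessel-mask pixel, and stromal signal is defined as total
minus vessel-associated, so vessel + stromal = total holds exactly by
construction. PDPL-positive lymphatic load is reported as lymphatic
pixels per image area. PDPL-positive cells are detected as thresholded
connected components within an area gate (default 10–400 px²,
threshold Otsu) that do not overlap the lymphatic vessel mask — cells
are vessel-external puncta; the rule is a declared substitute for an
unspecified manual procedure.

## Statistics

The experimental unit is the animal: per-image records are averaged per
animal first (missing per-image values, e.g. an image with no complete
venular segment, are dropped from that animal's mean with a logged
count), and the group comparison runs on animal-level means, so the
degrees of freedom reflect animal counts. The default test is the
classical pooled-variance Student t-test, two-sided — the common meaning
of "unpaired t-test" in mainstream analysis software — with Welch's
variant available by option. Significance is declared at p < 0.05. No
multiple-testing correction is applied; the report records the number of
tests run so users can apply their own. Western-blot densitometry enters
only as the normalization ratio of a target band to its loading-control
band.

## The synthetic world

The generator emulates 512 × 512 maximum-projection confocal fields.
Blood vessels grow as planar trees from border-anchored roots,
alternating arteriole/venule classes and top/bottom borders so the trees
interdigitate. Each segment's centerline is an analytic curve — a chord
plus a perpendicular sinusoidal perturbation — whose true arc length
comes from quadrature, so generator truth is exact and independent of
the pipeline's discrete estimators. Class transitions are inserted along
continuing paths at a configurable rate, and a configurable fraction of
segments is annotated "undetermined". A lymphatic network grows along a
horizontal suture-like band with side branches; fluorescence channels
render the vessel marker, α-SMA (vessel band plus stromal patches) and
PDPL (lymphatic vessels plus isolated cell disks), with additive
Gaussian or Poisson noise.

Default parameters are one considered choice of a plausible field:
3 trees per class, branching probability 0.35, depth 4, log-normal
segment lengths (median 60 px, σ = 0.3), widths 4 px (arteriole) and
5 px (venule), curvature amplitude 0.15 of the chord (baseline
tortuosity ≈ 1.05), transition rate 0.12, undetermined rate 0.05,
lymphatic width 8 px, PDPL cell count Poisson(12), noise σ = 5.

Three generator design points deserve emphasis. First, growth is
*occupancy-aware*: a proposed segment is retried with a fresh direction
and a progressively shorter length when its corridor (half-width +
2.5 px) would collide with already-placed vessels outside its own
junction vicinity — a vessel stops short of an obstacle rather than
vanishing — and accepted segments reserve a slightly narrower corridor,
so distinct vessels keep a ≥ 2 px gap and the rasterized classes never
merge. Real projections do contain crossings — the source annotations
resolve them as "undetermined"; the generator instead avoids them,
which keeps the analytic truth exactly attached to the raster and is
the main idealization a green recovery test does *not* probe. Second,
placement order matters on a shared occupancy grid: venule trees are
placed before arteriole trees (root positions still interleave), so
venular geometry is strictly independent of arteriolar parameters and a
class-specific injected effect cannot leak into the other class through
crowding; likewise, discarding blocked tips outright would delete whole
subtrees preferentially in the less crowded group and attenuate
injected length factors away from their nominal values — the
shorten-on-collision rule keeps the group truth ratio at the injected
factor to within a few percent. Third, terminal tips are rasterized
with butt caps so the painted vessel's extent matches the recorded
analytic centerline length; round caps would make every raster tip half
a width longer than its truth.

Cohorts mirror the study design (default 4 control and 5 treated
animals, 10 images each). Each animal receives log-normal random effects
(σ = 0.05) — a size factor on segment-length medians and lymphatic
width, an intensity factor on α-SMA gain and PDPL cell rate — making the
per-animal averaging step consequential. Group effects are injected via
`effectSpec()`: arteriolar shortening (< 1 length factor), raised
arteriolar curvature, lymphatic area expansion, more PDPL cells, higher
α-SMA gain. All randomness derives from one master seed through a
counter-based scheme, so any fixed-seed run is exactly reproducible.

```{r example, eval = FALSE}
cohort <- makeCohort(sceneParams(),
                     effectSpec(arterioleLengthFactor = 0.75),
                     nAnimals = c(4, 5), imagesPerAnimal = 10, seed = 1)
res <- runPipeline(pipelineConfig(simulate = cohort, outDir = "out",
                                  seed = 1))
res$comparisons
```

## Numerical and policy choices

* Coordinates are (row, col), origin top-left; the C++ core is 0-based,
  the R surface 1-based.
* Fused z-stacks are rendered as maximum-intensity projections; analysis
  is 2D only.
* Palette matching for mask PNGs is exact-RGB with no tolerance; masks
  are written losslessly, with pixel size and identifiers in a JSON
  sidecar. Multi-channel images are stored as one PNG per channel with
  16-bit precision (high/low bytes in two colour planes) because no
  TIFF library is assumed.
* Overlaps during rasterization paint arteriole over venule over
  undetermined; the policy is recorded in the truth.
* Degenerate statistics follow conventions: zero variance with equal
  means gives p = 1; with unequal means the comparison is flagged
  degenerate rather than fabricated.
* Pipeline failures on individual images are quarantined (row flagged,
  run continues), and the manifest records every tunable parameter that
  affects an output number.

## Known limitations

Vessel diameters are not quantified (no claim about compensatory
dilation can be made from these outputs); 3D structure is projected
away; the classical segmenter is a stand-in, not a reconstruction of
learned vessel segmentation; the chamfer-metric length bias discussed
above sets a floor of a few percent on absolute length accuracy, though
group *ratios* are unaffected since the bias cancels; and the synthetic
world's crossing-free vasculature means recovery tests do not exercise
the ambiguity that motivates the "undetermined" class in real
annotations.
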