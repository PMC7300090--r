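---
title: "Methods: quantifying tumor-microenvironment architecture from histology images"
author: "histoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying tumor-microenvironment architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoquant)
```

# Scope and design

`histoquant` quantifies four aspects of tumor-microenvironment biology from
standard brightfield and polarized-light micrographs:

1. **Collagen fiber architecture** from picrosirius-red (PSR) birefringence:
   per-fiber angle, length and width, and their distributions.
2. **Collagen bundling** from PSR hue (red/orange = thick, bundled, mature
   collagen; yellow/green = thin, reticular collagen) and blue/red pixel
   ratios of Masson's trichrome.
3. **Tumor-cell phenotype** from dual-chromogen IHC: Beer–Lambert stain
   deconvolution of hematoxylin, DAB and Vector Red, tumor-cell gating by
   CK-18/Vector Red, and per-marker subcellular positivity rules.
4. **Morphometry**: spheroid diameter over time and vessel-lumen counts.

No suitable public image set with per-fiber or per-cell ground truth exists
for these modalities, so validation is by *parameter recovery*: a
synthetic-histology generator renders every modality from a fully specified
model, and each pipeline stage must recover the generating parameters from
the rendered pixels. The generator is first-class, tested code — its output
is the reference for every downstream stage.

# Fiber architecture

## Segmentation of birefringent signal

Under crossed polarizers PSR-stained collagen appears as bright, saturated
signal on a near-black field. The foreground is taken as pixels with HSV
value ≥ `birefringence_value_min` (default 0.3) and saturation ≥
`birefringence_saturation_min` (default 0.2); connected components smaller
than 9 px are removed as shot noise. The thresholds are deliberately simple
and global — polarized-light backgrounds are dark and uniform — and are
configurable for dimmer acquisitions.

## Fiber extraction

Curvelet-based fiber extraction tools are widely used for this task but are
not open in the algorithmic sense needed here. `extractFibers()` uses an
open skeleton-tracing algorithm with every step fixed:

1. thin the mask to a one-pixel skeleton (Zhang–Suen);
2. split the skeleton at branch points, detected by crossing number
   (≥ 3 neighbour transitions) rather than raw neighbour count, which would
   falsely split diagonal staircases;
3. discard segments shorter than `min_fiber_length` (15 px);
4. re-merge segment pairs whose endpoints lie within `gap_max` (10 px) and
   whose axial orientations differ by < `merge_angle_max` (20°) — this heals
   fibers split where they cross other fibers;
5. measure each fiber.

Measurements and their numerical choices:

* **Length** is the arc length of the traced centreline, summed over
  anchors every 5 px. Summing unit/diagonal steps of the raw 8-connected
  chain would overestimate length by up to ~8% at intermediate angles; the
  anchor resampling removes this staircase bias (single-capsule recovery is
  within a few px of truth at any orientation).
* **Width** is `2 × mean(distance transform) − 1` over the centreline, the
  −1 correcting for the half-pixel offset between a pixel centre and the
  mask boundary on each side. On rendered capsules of width 3–10 px the
  estimate is within ±1.5 px at any orientation.
* **Angle** is the total-least-squares line through the centreline, folded
  into [0, 180). Fibers are undirected (axial data), so all circular
  statistics double the angles, average on the circle, and halve the mean
  back; the resultant length *R* is 0 for isotropic fields and 1 for
  perfect alignment, and circular variance is 1 − *R*.

Distribution summaries use Tukey box-plot conventions (type-7 quantiles,
whiskers at 1.5 × IQR clipped to the data, points beyond reported as
outliers) plus mean ± s.e.m. Non-parametric comparison of pooled fiber
parameter distributions uses the two-sample Kolmogorov–Smirnov test with
the asymptotic p-value. (The source protocol names
"Kolmogorov-Smirnov chi-square tests"; the two-sample KS test is the
standard reading and is what is implemented — the chi-square variant is
noted, not guessed.)

## What the generator emulates — and what it does not

`simulateFiberField()` renders straight, anti-aliased capsules whose HSV
value is the pixel coverage and whose hue encodes bundling through an
invertible mapping `hue = 160 − 150·clip(bundling·(w − w_min)/(w_max −
w_min))`, i.e. thin → green (160°), thick → red (10°). Angles come from a
uniform-axial or von Mises-axial model (Best–Fisher sampling), lengths and
widths from lognormals. Real collagen fibers are curved, vary in width
along their length, and overlap far more densely; none of that is
simulated, because the measured quantities (angle, length, width and their
distributions) are defined on straight capsules without ambiguity. Passing
recovery tests therefore demonstrates correctness of the measurement
chain, not robustness to dense clinical fields — on real data the fiber
*count* depends on segmentation parameters, which is why only
distributional quantities are treated as the recoverable surface.

Fibers whose geometry fits inside the frame are placed fully inside it, so
the recorded ground truth is exact; a fiber that cannot be placed after
100 attempts is an error.

# Hue and trichrome analysis

`hueProfile()` bins masked pixels by hue into red [0,25)∪[335,360), orange
[25,45), yellow [45,70) and green [70,160) degrees — conventional PSR hue
windows, fully configurable. Hues in [160,335) (cyan–magenta) do not occur
in PSR birefringence; they are counted separately and excluded from the
fractions rather than force-assigned, so the four fractions remain
interpretable and sum to 1. Because hue is invariant to intensity scaling,
the fractions are unchanged under uniform brightness changes of 0.5–1×,
which the tests assert.

`trichromeRatio()` classifies tissue pixels (non-white: value < 0.95 or
saturation > 0.1) into aniline-blue (hue 180–260°) and Biebrich-scarlet
(hue 300–20° through the wrap) at saturation > 0.2, reporting colored
pixels over total tissue pixels. The windows separate the two chromogens
unambiguously on synthetic fields and are configurable for real slides.
The trichrome generator's unstained remainder is rendered as a pale
(0.92) near-white that still counts as tissue, so generated fractions are
recovered exactly; rendering it as pure white would make the requested
fractions unrecoverable because white pixels are excluded from the tissue
denominator.

# IHC quantification

## Stain model

Chromogen amounts add linearly in optical density (Beer–Lambert):
`OD_c(x) = Σ_s D_s(x) · V_sc`, with transmitted intensity `exp(−OD)`. The
default stain vectors are the published unit OD directions for
hematoxylin (0.650, 0.704, 0.286), DAB (0.269, 0.568, 0.778) and Vector
Red (0.095, 0.708, 0.700), renormalized; their matrix has condition number
≈ 10, and any basis with condition ≥ 1000 is rejected. With three stains
the per-pixel least-squares solution is the plain matrix inverse;
negative densities (noise) are clipped to zero and the clipped mass
fraction reported. On noise-free synthetic fields the inversion is exact
to machine precision, which the acceptance suite asserts at 1e−6.

## Segmentation and gating

Nuclei are Otsu-thresholded from the hematoxylin density, hole-filled and
watershed-split on the distance transform; each nucleus is expanded to the
cell boundary by Voronoi propagation inside a dilation of radius
`cell_radius_px − nucleus_radius_px`, so neighbouring cells cap each
other. The membrane ring is the band of `ring_thickness_px` (3 px) just
inside the cell boundary; cytoplasm is the remainder. Cells touching the
frame edge have degenerate rings and are excluded (tallied, not silently
dropped). A cell is gated as tumor when its mean Vector Red OD over the
cell mask exceeds `ck18_threshold` (0.15) — the CK-18/Vector Red gate that
isolates tumor cells in co-culture.

The synthetic IHC generator places cells on a jittered grid with centre
spacing strictly above one cell diameter. That guarantees segmentability
by construction: the scoring-rule tests isolate the correctness of the
*rules*, not the hardness of segmentation. Clinical material with crowded,
overlapping cells is outside what these tests demonstrate.

## Scoring rules

All rules use a single global OD positivity threshold per marker (default
0.15), deliberately not adaptive: a global threshold makes scores
deterministic and monotone in the threshold, a property the test suite
checks over random threshold sweeps.

* **Nuclear** (Ki67, β-catenin): positive iff mean DAB OD over the nucleus
  exceeds the threshold.
* **Complete membrane** (E-cadherin, CD44, CD133): the ring is divided
  into 36 equal angular sectors about the centroid; completeness is the
  fraction of sectors whose mean DAB OD exceeds the threshold, and
  positivity requires completeness ≥ 0.95. "Complete membrane
  localization" is stated in the source protocol without a metric; sector
  coverage is the standard operationalization in membrane-completeness
  scoring and is directly testable (the generator draws partial arcs on
  negative cells).
* **Membrane or nuclear** (N-cadherin): the membrane rule, with nuclear
  positivity as an additional route, since nuclear signal indicates
  cytoplasmic marker not yet localized to the membrane.
* **Area fraction** (FAK): fraction of tumor-region pixels with DAB OD
  above threshold. This is the one per-pixel (rather than per-cell
  averaged) rule, and consequently the one sensitive to unmixing noise:
  OD noise of sd 0.02 amplifies through the stain-matrix inverse to
  ~0.09 sd on the DAB density, so ~4–5% of unpainted pixels exceed a 0.15
  threshold. At the stated noise level this bias stays within the ±0.05
  recovery band; for noisier acquisitions the FAK threshold should be
  raised.
* **Membrane + cytoplasm** (Caspase 3): positive iff mean DAB OD over the
  union of ring and cytoplasm exceeds the threshold.

# Morphometry

**Spheroid diameter.** Masks are opened with a disk of radius 3 px to
suppress the thin radial protrusions of migrating cells, then the average
diameter is the mean Feret (projection) extent over 36 equally spaced
directions of the largest component. Whether the original analysis used a
Feret-based or area-equivalent diameter is not stated; mean Feret matches
the "average diameter" language and is protrusion-robust after opening,
and the area is reported alongside so an area-equivalent diameter can be
derived. On a 100 px disk with 8 spurs the measured diameter is within
1% of truth.

**Vessels.** Lumens are bright components (value > 0.95) of plausible area
whose outer boundary is ≥ 70% adjacent to stained pixels — the signature
of a lumen enclosed by a vessel wall. Full histologic vessel recognition
is a research problem in its own right; this operational definition is
declared, configurable, and validated as exact on non-overlapping
synthetic fields of up to 50 vessels.

# Statistics

Parametric group comparisons use Student's t-test (equal variances by
default, Welch by flag) for two groups and one-way ANOVA with Tukey HSD
post hoc for three or more, reporting all pairwise comparisons; no
correction is applied across separate analyses beyond Tukey within an
ANOVA, matching the source protocol. Calibration is tested empirically:
over 500 null simulations the type-I error of both the KS comparison
(n = 200 per sample, asymptotic p) and the ANOVA (three groups of 15) must
lie in [0.03, 0.08] at α = 0.05. The asymptotic KS test is mildly
conservative at this sample size (long-run rejection ≈ 0.04), which the
band accommodates.

# Problem sizes, determinism and limitations

The validation suite runs fiber recovery at 500 fibers in a 2048² frame
(about 5% pixel coverage — sparse enough that crossings are healed by the
merge step), alignment monotonicity at four concentrations κ ∈ {0, 2, 8,
32}, marker recovery at 200 cells per field across all eight rules and
four generated fractions, and 500-replicate null calibrations. These sizes
were chosen so the full suite exercises every stage at the scale the
distributional claims need, while a complete run stays in the minutes
range on a single CPU.

Every stage is deterministic: equal inputs (including seeds) give
bit-identical images, fiber tables, scores and serialized outputs. All
physical outputs are in pixels, converted to micrometres only by the
user-supplied `pixel_size_um` (default 1), since image files carry no
reliable magnification metadata.

Known limitations: straight-capsule fiber models (no curvature metrics);
global rather than adaptive thresholds; chromogenic IHC only (fluorescent
channels are out of scope); no whole-slide formats or color-profile
management; vessel detection restricted to bright-lumen morphology.
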