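---
title: "platequant: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{platequant: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platequant)
```

`platequant` implements the quantitative layer of an automated
cell-culture / high-content-screening workflow: label-free confluency and
seeding-homogeneity QC for well scans, a nuclei-to-single-cell
immunofluorescence segmentation pipeline with tyrosine hydroxylase (TH)
positive calling, brightfield organoid morphometrics, rank-based group
statistics, and expansion/seeding capacity arithmetic. Every stage can be
exercised on synthetic images with exact ground truth, so the package
installs and tests with no external data. This vignette records the
models, the numerical conventions, and the choices made where the design
was genuinely open.

## Label-free confluency

Adherent cells in transmitted light are visible mainly through local
intensity texture, not absolute intensity. `detect_coverage()` therefore
scores each pixel by the sample standard deviation of its `window x
window` neighbourhood (default 15 px, mirror padding) and declares
foreground where that local sd exceeds an automatic, image-relative
threshold; a 3x3 morphological closing and removal of components smaller
than `min_object_px = 25` px suppress speckle-sized false positives. The
estimate is the foreground pixel fraction.

The threshold is `k_sd` (default 3) times a robust scale of the local-sd
map, `1.4826 x MAD`. One caveat is intrinsic to any MAD-based rule: its
breakdown point is 50%, so on a field about half covered by cells the
local-sd map is evenly bimodal and the MAD inflates to the distance
between the background and cell-texture modes, pushing the threshold
above every pixel. The threshold is therefore capped at half the 99th
percentile of the local-sd map, which sits strictly between the two modes
at every coverage. The rule is exactly invariant to adding a constant to
all intensities and to positive rescaling, because the local sd, the MAD
and the percentile all shift/scale together.

Two numerical details matter. Local variance is computed by windowed
sums after subtracting the image median, so constant regions give
*exactly* zero variance instead of catastrophic-cancellation dust;
variances below `1e-9` of the maximum are clamped to zero. And the
auto-threshold presumes an essentially texture-free background: camera
noise with a spread comparable to the cell texture would raise the
background's local-sd floor above any MAD-proportional cutoff. The
synthetic generator models this regime (flat background at level 500,
zero-mean speckle of sd 60 on cells); real acquisitions with appreciable
background noise would need `k_sd` raised or the image denoised first.

Well-level QC follows the screening convention: the well confluency is
`100 x mean` of the per-field coverages over the acquisition layout (38
fields for a well of a 6-well plate, 384 for a 1-well plate), and the
seeding-homogeneity score is the coefficient of variation `100 x sample
sd / mean` (n-1 denominator, the convention of Prism-style analyses; the
CV is identical whether computed on fractions or percents). A zero-mean
well has an undefined CV and is flagged rather than propagated as NaN.
The 38-field geometry is not published with coordinates; the default
layout packs rows of 4, 6, 6, 6, 6, 6, 4 fields into a round well and is
configuration-overridable, as is the 16 x 24 grid of the 1-well format.

## Serial-dilution linearity

Dilution series are summarized by fitting the saturating monotone model

    y = ymax * (1 - exp(-k * x))

by bounded Levenberg-Marquardt (`minpack.lm`), with `ymax` in (0, 120]
percent and `k > 0`, a fixed deterministic initializer (`ymax0 = max(y)`,
`k0` from the first point's implied rate) and `R^2 = 1 - SS_res/SS_tot`.
The instrument-side analyses this mirrors report only "non-linear curve
fitting"; this two-parameter model was chosen because it is monotone,
bounded, captures both the near-linear low-seeding regime (small `k x`)
and saturation near 100% confluency, and is refit-stable: noiseless
synthetic series are recovered to better than `1e-4` relative error, and
at 2 confluency-points of Gaussian noise the fit keeps `R^2 > 0.96` in
well over 95% of replicate series. A constant response makes `SS_tot`
zero; the fit is then flagged degenerate instead of reporting an
undefined `R^2`.

## The segmentation chain

The immunofluorescence pipeline is a fixed chain of elementary image
operations; every threshold is a strict `>` comparison.

**Kernels.** All Gaussian kernels are truncated to an explicit
`size x size` window, normalized to unit sum, at the `(size, sigma)`
pairs (10, 2) and (60, 20) for nuclei, (11, 1)/(11, 3) for the fine and
(99, 3)/(99, 11) for the coarse marker band-passes. Two window sizes are
even; the anchor pixel then sits at index `floor(size/2)` (0-based), half
a pixel off the window centre. Both terms of each difference of
Gaussians share that convention, so the half-pixel bias cancels in the
subtraction. This is why the kernels are built explicitly rather than
through odd-window helpers, and why filtering uses correlation with
mirror ("symmetric") boundary padding. Filtering is separable
(two 1-D passes); a constant image maps to exactly zero.

**Nuclei.** `nuc_mask = DoG(nuclei) > 50`. Touching nuclei are split on
the negated Euclidean distance transform after an h-minima transform of
depth 1, realized as grayscale reconstruction by dilation of `d - 1`
under `d` (the complement form `1 - d` used by some environments differs
from plain negation by an affine map that both the h-minima transform
and the watershed are invariant to). A basin whose saddle depth is
*exactly* 1 is suppressed — depth-1 features are the defined merge
boundary, not a rounding accident.

**Watershed.** Reproducibility down to the pixel requires pinning the
tie-breaking, so the transform is defined (and implemented twice,
independently, in the package and in the test suite) as level-synchronous
flooding with 8-connectivity: unique altitudes are processed in
ascending order; within a level, every unlabeled pixel adjacent to
exactly one basin adopts its label and every pixel adjacent to two or
more distinct basins becomes a ridge pixel, with all updates of one
iteration applied simultaneously; level pixels no basin reaches seed new
basins, numbered by ascending minimum column-major pixel index. The test
suite verifies bit-identical agreement between the two implementations
(and checks object counts against `EBImage::watershed` as an external
reference).

**Labels and ROIs.** Nuclei labels are watershed basin membership
restricted to the mask minus ridge pixels. Membership, not re-run
connected components: a ridge curve that runs diagonally does not
4-disconnect the plane, so 8-connected relabeling would leak labels
across it and merge the very nuclei the watershed just split. Single-cell
ROIs apply the same stencil to the mask dilated by the exact Euclidean
disk of radius 10 (`{(dx,dy): dx^2+dy^2 <= 100}`, 317 px — decomposed
"disc" brushes approximate this set and are not used); basins without a
nucleus are discarded, and by construction a ROI can contain only its
own nucleus. ROIs clip at image borders.

**Marker masks.** For each marker channel,
`mask = (DoG_fine > t_fine) | (DoG_big > t_big) | (median3x3 > t_global)`
with thresholds (3, 10, 50) for TH and (2, 3, 20) for Tuj1. The 3x3
median uses zero padding (the source environment's default); a
consequence worth knowing is that on a bright uniform field the four
corner windows are majority padding and stay below the global threshold.

**Classification.** `neuro_mask = th_mask | tuj1_mask`. A cell is a
neuron when its ROI overlaps the neuronal mask in at least one pixel
(the most literal reading of excluding "ROIs outside of neurons"; a
minimum-overlap fraction is available as an option). The TH background
is the mean TH intensity outside nuclei — if nuclei cover the whole
image the background falls back to 0 with a warning — and a neuron is
TH-positive when the ROI *mean* of the background-subtracted TH channel
strictly exceeds 20. The per-ROI statistic is configurable
(mean/median/max); mean is the default as the least outlier-sensitive
choice, but the upstream description does not pin this down, so it is
exposed rather than asserted as fact. At exactly 20 a cell is negative.

## Organoid morphometrics

The extraction method behind the published organoid sizes is not
described, so segmentation is a declared surrogate validated on
synthetic truth rather than on published absolute sizes: invert
intensities, Otsu's global threshold, keep the largest 8-connected
component, fill holes, and flag (not error) wells whose largest
component is under 500 px. Area is the foreground pixel count times
`pixel_size^2`. Feret's diameter is the maximum pairwise distance
between foreground pixel centers, computed over convex-hull vertices and
verified against the brute-force all-pairs maximum; a single-pixel
object has diameter 0 (center-to-center convention; the pixel-edge
convention adding ~1 px is available as an option since the original
tool is unstated). Batch quality uses the same sample-CV convention as
the confluency QC, per line, with optional pooling of batches — pooling
two internally tight batches with different means legitimately raises
the CV, which is the point of reporting it.

Pixel size is a required input: the published acquisitions show only a
scale bar, so physical calibration must come from the user's metadata.
The published day-30 area range (roughly 3.0-5.7 x 10^5 um^2) is used
only as a plausibility range for generator defaults, never as test
truth.

## Rank statistics and capacity arithmetic

`mann_whitney_u()` reports `U = min(U_a, U_b)` with midranks. With 12 or
fewer observations in total and no ties the two-sided p-value is exact
(the null U distribution; identical to enumerating all label
assignments — the suite checks this exhaustively against an enumeration
oracle); otherwise a normal approximation with tie correction and
continuity correction is used, which reproduces `wilcox.test`. The
exact/approximate switch is an argument because the figure-scale group
sizes (n = 3-12) are where exactness matters. Identical groups give
p = 1. `kruskal_wallis()` delegates to `stats::kruskal.test` (verified
against the hand rank-sum formula) and defines H = 0, p = 1 when every
observation is tied. For two tie-free groups, H equals the square of the
uncorrected Mann-Whitney z. `dunn_posthoc()` implements the standard
Dunn z with tie correction; the default adjustment is Bonferroni over
all `k(k-1)/2` pairs, capped at 1, chosen as the conservative
reproducible option since the multiple-comparison variant used upstream
is unstated; raw p-values are always reported alongside.

`assay_capacity()` is floor division — partial assay plates are
unusable. With ten source plates at the measured iPSC (1.18 x 10^7) or
smNPC (1.17 x 10^7) per-plate yields and 384-well plates at 20,000
cells/well it gives 15 plates. The analogous fibroblast computation with
the measured 1.67 x 10^7 yield gives 21, while the accompanying text
prints 19; the arithmetic here is the transparent floor rule, and the
discrepancy (possibly a dead-volume allowance) is noted rather than
imitated. `seeding_cells_per_well()` converts a suspension
concentration and dispense volume (30,000 cells/ml x 100 ul = 3,000
cells/well).

## The synthetic generators

All generators are pure functions of their parameters and an explicit
seed (one RNG stream per call, no hidden state), and every derived truth
quantity is recomputable from the emitted mask: adherent fields trim or
grow the placed patches pixel-by-pixel to hit the requested coverage
exactly; organoid truth stores the rasterized mask, its pixel count as
area and its brute-force boundary diameter as Feret; neuron scenes
realize marker fractions exactly by nearest-integer rounding (ties up).

Defaults encode the regimes the pipeline targets. Adherent fields place
few large elliptical patches (characteristic radius `min(width,
height)/4`), matching confluent monolayer islands at plate-reader
magnification; this also keeps the detector's edge halo (up to half a
local window around each patch) small relative to patch area, which is
what bounds the recovery error. Neuron scenes draw sigma-4 px nuclei at
peak amplitudes 160-220 over background below 10 with a minimum center
spacing of 13 px: an analysis of the chain shows nuclei closer than
about 11 px merge irresolvably (the difference-of-Gaussians midpoint
response stays above 50 and the distance-transform saddle depth falls to
the h = 1 merge boundary), so 13 px is the tightest spacing at which
counting the scene is a fair test of splitting rather than of the
generator. TH-positive somata and neurites are drawn bright enough that
the ROI-mean statistic separates positives from stroke leakage into
neighbouring ROIs.

What the generators deliberately do not model: optics (no PSF, no
defocus), photorealistic noise (no shot/read-noise calibration), 3-D
structure, background autofluorescence gradients in the fluorescence
channels, and cell morphology beyond blobs-plus-strokes. Passing the
recovery suites therefore demonstrates that the implementation computes
its stated operations correctly and recovers truth under the stated
image model — it does not certify performance on real microscopy, where
background texture (confluency) and staining variability (TH calling)
are the known sensitive points.

## Problem sizes and runtime choices

The test suite exercises the chain at sizes chosen to make the oracles
airtight yet quick: bit-level step equivalence on twenty 64 x 64 /
128 x 128 scenes against a literal straight-line re-execution; count and
TH-fraction recovery on fifty 192 x 192 scenes of 10-80 cells; coverage
recovery on 512 x 512 fields across coverages 0.1-0.9 plus a full
38-field homogeneous well at 256 x 256; two hundred refits of noisy
dilution series; two hundred Feret masks. `scripts/acceptance.R` re-runs
the same experiments from scratch with seeds derived from `--seed`.

## Known limitations

- The confluency surrogate is contrast-model-bound (texture on a quiet
  background); it does not reproduce any proprietary instrument's exact
  numbers, only the area-fraction readout those numbers feed.
- The watershed tie-break convention is pinned for reproducibility; other
  implementations may place individual ridge pixels differently on
  plateaus, so label *counts* transfer across tools but ridge pixels
  need not.
- Published figure-level results that depend on the original images
  (>95% neurons, ~25% TH-positive, per-line organoid CVs) are not
  reproducible from deposited data; the suite instead proves recovery of
  known synthetic truth under the same operations.
- `mann_whitney_u`'s exact branch deliberately refuses ties; tied data
  always take the corrected normal approximation.
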