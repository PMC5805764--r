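---
title: "Quantifying hemodialyzer fiber patency from micro-CT cross-sections"
author: "dialyzerCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hemodialyzer fiber patency from micro-CT cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialyzerCT)
```

## The measurement model

A hemodialyzer bundles roughly 10,000 hollow capillary fibers whose ends
are fixed in a polyurethane potting. In a reconstructed micro-CT
cross-section of the potting at 25 µm/pixel, an open (patent) fiber lumen
is an air-filled disk, darker than the surrounding polyurethane; a
clotted fiber shows no dark disk, and a partially occluded one shows a
smaller disk. Counting patent fibers therefore reduces to counting
sufficiently large, sufficiently round dark particles inside the fiber
bundle.

The classification rule is calibrated on non-used dialyzers: a full lumen
cross-section measures A₀ = 0.029143 mm², chosen so that the 70%
threshold corresponds to a particle area of 0.0204 mm² (the calibration
anchor; only that threshold area is given by the counting protocol, so A₀
is back-derived as 0.0204/0.70). A particle is an open fiber when

* its circularity 4πA/P² lies in [0.5, 1] (inclusive bounds), and
* its area strictly exceeds f·A₀ for threshold fraction f (default 0.70),
* but does not exceed 2·A₀ — anything larger is a merged region or
  an artifact, not a single lumen (this upper cut is this package's
  addition; without it a mostly-blocked section whose whole potting disk
  falls on the dark side of a global threshold would count as one giant
  "fiber").

Validity of a count is probed by recounting at f = 0.60 and 0.80;
reliability by recounting in a cross-section 2.5 mm proximal of the
reference slice. Both are expressed as percent differences
100·|n − n_ref|/N with N = 10748, the reference total of a fresh
dialyzer, and reported to one decimal.

## Pipeline stages and their parameters

**Thresholding.** The counting protocol says only that image brightness
was "optimized" by thresholding; this package defaults to Otsu's method
(256 histogram bins spanning the observed range, hence invariant to
affine intensity rescaling) with a fixed-value override, because an
automatic criterion is reproducible and operator-independent. Exact
replication of the original operator's binarization is not claimed. The
pipeline adds a *plateau refinement*: a dark component covering more than
a quarter of the image cannot be a lumen (a lumen is ~50 px at 25 µm);
such a component arises when the global split lands between potting and
outside background on heavily clotted sections, and is re-thresholded
internally. If its interior shows no dark sub-mode (a constant plateau,
or only the lower half of the noise), it is removed.

**Bundle ROI.** Morphological closing with a disc of radius 620 µm
(about twice the expected fiber pitch) glues lumen dots into blobs; the
blob containing the most mask pixels seeds the bundle, and its convex
hull is grown iteratively: mask components within 1240 µm (twice the
closing radius) of the current hull are merged and the hull recomputed
until stable. The expansion step matters on heavily clotted sections
where surviving dots are sparse and a single closing pass fragments the
bundle; genuinely distant dark objects (scanner artifacts outside the
bundle) stay excluded. Particles are retained downstream when their
centroid falls inside the ROI. An explicit user ROI can override
detection, mirroring the manually drawn region of the original protocol.

**Watershed.** Touching lumens are split by flooding the Euclidean
distance transform from its regional maxima. The maxima-suppression
radius defaults to half the expected lumen diameter
(½ · 2√(A₀/π) ≈ 96 µm ≈ 4 px), so one seed survives per fiber-sized
particle; the flooding tolerance is 1 px of distance-map depth. Isolated
particles pass through unchanged. Fibers fused into a solid slab (no
neck between them) cannot be separated by any watershed; at realistic
pitches (~300 µm vs ~193 µm lumen diameter) this regime does not occur.

**Measurement.** Area is pixel count × pixel area. Perimeter uses a
weighted boundary-step estimator: border pixels are classified by their
border neighbourhood into straight, diagonal and corner steps, weighted
1 : √2 : (1+√2)/2 and scaled by the Vossepoel–Smeulders digitization
correction (0.948), which removes the systematic overshoot of raw
chain-code lengths on smooth contours. Circularity is capped at 1 —
digital disks would otherwise exceed it slightly — matching the
classification range [0.5, 1]. A single-pixel particle has no boundary
steps; its circularity is defined as 1 (it is rejected by area anyway).
Labelling uses 8-connectivity; physical coordinates are mm with origin at
the image centre, pixel centres at half-integer offsets.

## The phantom generator

`phantomSpec()`/`generatePhantom()` emulate the imaging regime the
pipeline was designed for, with exactly known per-fiber ground truth:

* **Geometry.** Fiber centres on a hexagonal lattice (pitch 303 µm by
  default, jittered uniformly within 10% of the pitch) confined to a
  disk. The defaults — bundle radius 16.5 mm, pitch 303 µm — give ~10,750
  fibers, matching the fresh-dialyzer total; neither pitch nor lumen
  diameter is available from a datasheet, so both are back-derived from
  the fiber total and the 0.0204 mm² calibration area. Lumens are perfect
  disks.
* **Patency.** Each fiber is independently open / partially occluded /
  fully blocked with configurable probabilities ("uniform" pattern), or
  blocked fibers are placed outermost-first ("peripheral") to mimic
  rim-first clotting. Partial occlusion retains a uniform fraction
  (default 20–60%) of A₀, rendered as a concentric smaller disk — the
  area-based patency rule does not need clot morphology. Fully blocked
  fibers render at potting intensity.
* **Rendering.** Intensity levels on [0, 1]: background 0.85, potting
  0.70, lumen 0.10. The dark-dot polarity (lumen < potting) is the only
  hard constraint; the background is kept above the potting level so that
  the bundle, not the surround, carries the dark class. Disks are
  anti-aliased by 8× supersampled coverage (isolated-dot area error
  < 2%), then Gaussian blur (default σ = 12.5 µm, half a pixel) and
  additive Gaussian noise (default σ = 0.02, ~3% of the lumen–potting
  contrast) are applied. One seed controls jitter, patency assignment and
  noise; the same seed gives bit-identical images.

What the phantom does *not* emulate: X-ray physics (beam hardening,
reconstruction streaks, rings), intensity gradients across the field,
non-circular or wall-adherent clots, and 3D clot structure along the
fiber axis. Passing phantom tests therefore demonstrates the counting
logic — segmentation, separation, measurement, classification — under
controlled blur and noise, not robustness to every scanner artifact.

## Statistical layer

Summaries report mean, sample SD (n−1), median and quartiles; quartiles
interpolate linearly between order statistics at rank 1 + p(n−1) (R's
type 7). This rule was chosen because it uniquely reproduces the
published cohort quartiles [8763; 10330] from the 20 used-dialyzer
counts; Tukey hinges and the SPSS weighted-average rule do not. Instead
of a normality-test gate the summary carries an explicit flag
(`sd_defined`) — the test choice alters no number in scope. Regressions
are ordinary least squares of each surrogate on the open-fiber count,
reported as R² to two decimals; ordinal visual scores enter as numeric
values, as the published R² values imply.

## Data notes

The packaged fixtures transcribe the published measurement tables as
printed. Two internal inconsistencies are documented rather than
"fixed":

* The rinse-back volume column's published R² is 0.20, but the published
  per-session values yield 0.1827 → 0.18. An exhaustive re-parse of the
  source table (all admissible digit groupings) confirms no reading
  reproduces 0.20 while the other eight columns match exactly.
* Dialyzer 12's three published percent differences (2.5, 0.4, 0.5) are
  mutually consistent with a reference count of ~6052, not the printed
  6066; the formula applied to the printed counts gives 2.4, 0.3, 0.6.
  A single misprint in the reference column is the simplest explanation.

The two fixtures also disagree slightly on two reference counts
(dialyzer 15: 8908 vs 8921; dialyzer 17: 8994 vs 8998); each table is
kept as printed, and the count table is the one that reproduces the
published quartiles.

## Verification problem sizes

The test suite and `scripts/acceptance.R` exercise the pipeline on 20
phantoms of ~1000 fibers each (bundle radius 5.35 mm, ~450² px), with
blockage fractions spanning 0–1 and 10% partial occlusion: counts match
ground truth exactly with blur and noise off, and within 1% of the fiber
total under the default blur/noise regime; counts are monotone
non-increasing in the threshold fraction throughout. A thousand fibers
in a proportionally smaller bundle preserve the geometry that matters —
lumen size, pitch, dot density — while keeping a full 40-phantom sweep
around twenty seconds. Brute-force oracles (linear-scan filters,
sort-based quantiles, direct Pearson correlation) back the
classification, summary and regression routines on thousands of random
inputs.

## Known limitations

* Two-class thresholding assumes bimodal dot/potting contrast inside the
  bundle; strong illumination gradients would need local thresholding,
  which is out of scope.
* The ROI is convex; a genuinely concave bundle outline (damaged
  housing) would include some outside area.
* Watershed over-splitting is suppressed by the seed-separation radius,
  which assumes lumens of roughly the nominal size; dialyzers with very
  different fiber geometry require adjusting `minSeparationUm` and the
  patency calibration together.
* Counts are per-slice; no attempt is made to track fibers between
  slices or to localize clots axially.
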