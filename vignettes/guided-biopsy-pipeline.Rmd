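---
title: "Methods: a desk-scale multimodal pipeline for oral biopsy guidance"
author: "biopsyGuide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale multimodal pipeline for oral biopsy guidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Oral potentially malignant disorders are routinely triaged by visual
examination followed by biopsy, but choosing *where* to biopsy inside a
heterogeneous lesion is hard: widefield autofluorescence (AF) imaging is
sensitive to neoplastic change but not specific, and contact
microendoscopy is specific but samples less than a square millimeter at a
time. Clinical guidance systems address this by fusing the two: a widefield
camera computes a cancer-risk map over the whole field, a fiber-bundle
microendoscope is swept over the high-risk areas while being tracked in the
widefield video, and per-frame diagnostic scores are accumulated onto
anatomy so that a dual-threshold *biopsy guidance map* can be projected
back onto the tissue.

`biopsyGuide` implements the complete software core of such a workflow at
desk scale: every analysis stage, the data containers that connect them,
and a fully seeded synthetic phantom that emulates an imaging session with
ground truth, so each stage and the end-to-end behavior are testable
without any patient data or hardware.

## Coordinate conventions and calibration

All modules share one pixel convention: 0-based `(x, y)` with the origin at
the top-left pixel center, x rightward, y downward. Grayscale images are
`width x height` matrices, RGB images `width x height x 3` arrays on a
nominal 0..255 intensity scale; this storage order matches EBImage, the
image-processing backend.

The widefield calibration defaults to a 80 x 50 mm field of view imaged at
960 x 600 px, i.e. **0.0833 mm/px** on both axes. The microscope pixel
pitch defaults to a 790-um field of view across 720 px, **~1.10 um/px**.
Both are plain configuration values (`calibrationModel()`,
`microUmPerPx()`), not hard-wired constants.

## Risk mapping (normalized red-to-green ratio)

Neoplastic oral mucosa loses green (collagen crosslink) autofluorescence
and gains red (porphyrin) emission under ~405-nm excitation. The risk map
is the per-pixel ratio

$$ r = \frac{R}{G + \varepsilon}, \qquad
   \mathrm{rg} = \frac{r}{\operatorname{stat}(r \mid \text{mucosa mask})} $$

computed inside a clinician-drawn mucosa outline (rasterized by the
even-odd rule with boundary pixels included). Design choices:

* **epsilon = 1 intensity unit** guards the denominator against
  zero-green pixels without visibly biasing ordinary tissue values
  (mucosal green signal is two orders of magnitude larger).
* **Self-normalization** by the mask **mean** (configurable to median)
  makes the map invariant to exposure and global illumination; the
  normalizing statistic is recorded in the `RiskMap` object. Whether a
  clinical implementation normalizes by the whole mask or by a
  clinically normal reference region is not externally specified; the
  whole-mask statistic is the choice here because it needs no extra user
  input, and the option is exposed rather than hidden.
* Channel gains/white balance are assumed already applied in the stored
  image; no color calibration stage is modeled.
* Heatmap rendering maps rg linearly over a display range defaulting to
  the 2nd–98th percentile inside the mask (robust contrast), through a
  cold-to-warm palette, alpha-blended only inside the mask.

## Probe tracking

The microendoscope tip carries colored dental ligatures; tracking is color
segmentation in HSV space (wrap-aware hue interval, saturation and value
floors), one 3x3 morphological opening to drop speckle, 8-connected
labeling, and the centroid of the largest component whose area lies in the
gate's accepted range (ties broken toward smaller centroid y, then x).
Per-frame detections become a track by

1. linear interpolation across invalid runs of at most `maxGap` frames
   (flagged `interpolated`), and
2. a centered running median over `smoothWindow = 5` frames (shrunken at
   the edges) — robust to single-frame misdetections without assuming a
   motion model, which is why a median was chosen over a Kalman filter.

The output at frame *t* depends only on frames up to
*t + (smoothWindow-1)/2*, so the contract is streaming-capable. The default
gate is teal (hue 160–200 deg), a color absent from oral mucosa imagery.
The ligature blob centroid is treated as the probe tip; no tip-offset
correction is applied.

## Microscopy QC and scoring

Two quality-control checks gate scoring, standing in for probe-contact and
image-content checks whose clinical internals are not externally
specified:

* **contact**: fraction of fov-circle pixels at or above `contactFloor`
  (default 20/255) must reach `minCoverage` (default 0.3) — a probe off
  tissue returns almost no signal;
* **content**: mean squared gradient magnitude inside the fov must reach
  `minSharpness` (default 2) — defocus and motion blur suppress gradients,
  and the metric strictly decreases under Gaussian blur.

Scoring is a **pluggable contract**: any deterministic
`function(frame) -> [0, 1]`. The clinical system used a trained multitask
network here; shipping a network is out of scope, so the baseline is
transparent nuclear morphometry. Nuclei are segmented by white top-hat
background removal (disc about twice the expected nucleus radius), a light
Gaussian smooth (sigma 0.8 px), a global Otsu threshold over fov pixels
with a noise floor of median + 4 MAD (on a signal-free frame Otsu merely
bisects the noise distribution, so the floor is what keeps blank frames
blank), a watershed split on the distance transform, and an area filter.
Three geometric features — density (nuclei/mm^2), mean nuclear area
(um^2), and crowding (reciprocal mean nearest-neighbor distance, 1/um) —
are standardized by reference ranges and combined through a logistic.

The reference midpoints/scales (`morphometryReference()`) were fixed at
the design values of the two-regime phantom (normal: 300 nuclei/mm^2,
3.5-um radius; dysplastic: 3x density, 1.5x radius), i.e. the scorer is
calibrated to the phenotype contrast it is meant to separate, not tuned to
any test outcome. Because all features are geometric, scores are invariant
to global intensity scaling.

## Fusion and the guidance map

The two video streams share one acquisition clock; each microscope frame
is associated to the nearest-in-time widefield frame (ties toward the
earlier frame) within a tolerance of **0.1 s**, about two widefield frame
periods. Each scored frame's probability is deposited at every pixel
within `footprintRadiusPx` of the tracked tip — default the probe's
physical fov radius (~4.7 px at default calibration); radius 0 reproduces
a literal per-pixel deposit. The `ScoreField` keeps per-pixel running sum
and count; the mean is formed on demand.

A pixel enters the guidance map iff it is inside the mucosa mask, was
visited (count > 0), and both `rg >= tauRG` and mean score `>= tauMTN`.
Unvisited tissue is never recommended. The thresholds are clinician-set
and have no universal defaults; `thresholdSweep()` tabulates mask area
over a threshold grid as the non-interactive analogue of the clinical
slider interface, and `updateThresholds()` recomputes the map from the two
cached fields only — no raw video is touched — which is what makes
interactive updates effectively instantaneous.

For projection, the camera-to-projector mapping is modeled as a planar
homography estimated by normalized DLT (Hartley pre-conditioning, SVD);
binary masks are warped by inverse-mapped nearest neighbor so the
projected guidance map stays strictly binary. Lens distortion, 3D tongue
topography and projector hardware are not modeled. Whether the physical
system needs a full homography or only scale-plus-shift is unknown; the
homography subsumes both, and the estimation degrades gracefully to the
simpler model when the data contain no perspective.

## Mosaicking and the score-distance profile

At 90 fps consecutive microendoscopy frames overlap almost entirely, so
translation-only registration by phase correlation (fov-masked, subpixel
peak by parabolic fit) is used; rotation and non-rigid motion are out of
scope. Pairwise shifts are chained into global offsets; a pair whose
normalized correlation peak falls below 0.2 breaks the chain — the frame
keeps the last valid offset and is flagged, preserving data while marking
unreliable geometry. Compositing is feathered averaging weighted by
distance to the fov edge. The score-versus-distance profile assigns each
scored frame the cumulative arc length of its associated widefield frame
along the smoothed track and averages scores in 0.5-mm bins.

## The synthetic phantom

`phantomSpec()` defaults define the study conditions:

| parameter | default | rationale |
|---|---|---|
| widefield | 960 x 600 px, 20 fps | multimodal acquisition geometry |
| microscopy | 720 x 540 px, 90 fps, fov radius 260 px | device frame geometry; the fov circle is kept inside the frame |
| lesion | ellipse, semi-axes 130 x 85 px, rotated 20 deg | ~2 x 1.4 cm lesion at calibration |
| AF contrast | red gain 2.0, green loss 0.6 inside lesion | the loss-of-green/gain-of-red signature; in/out rg ratio ~3.3 |
| noise | Gaussian, sd 2% of dynamic range | unreported in the source setting; a plausible camera noise level |
| marker | teal disc, radius 6 px | ligature marker |
| trajectory | straight polyline crossing the lesion at 15 mm/s, 3 s | desk-scale session: the probe crosses normal -> lesion -> normal tissue in a few seconds |
| nuclei | normal 300 /mm^2, radius 3.5 +/- 0.4 um; dysplastic 3x density, 1.5x radius, hard-core point process | sparse/regular vs crowded/enlarged phenotypes |
| background glow | 30/255 inside fov | contact signal level, above the QC contact floor by design |

Regime switching is instantaneous at the lesion boundary; an optional
linear density ramp (`transitionWidthPx`) emulates a transition zone and
is off by default. Everything is a deterministic function of
`(seed, stream, frame index)` with all derived seeds kept below 2^31, and
frames are produced by lazy closures so a session never holds the full
video in memory.

**What the phantom does not emulate:** fiber-bundle honeycomb texture
(instrument-specific; the analysis modules do not model it either),
photorealistic tissue, optical PSFs, specular reflections, bleeding or
inflammation confounds, 3D surface geometry. Tests passing on the phantom
therefore demonstrate the correctness of the pipeline's computations and
contracts under the stated contrast model — not clinical performance on
real tissue, where inflammation alone is a known specificity confound.

## Numerical choices and degenerate inputs

* Homography estimation refuses duplicate/collinear configurations;
  `exact4` additionally requires no 3 source points collinear. Points
  mapping to infinity (homogeneous scale < 1e-12) are returned as NA by
  `applyHomography` and dropped by the mask warp.
* `polygonToMask` needs >= 3 vertices and nonzero area; vertices are
  clipped to the frame.
* An AF image with an all-zero green channel inside the mask is rejected
  as uninterpretable rather than silently producing an epsilon-dominated
  map.
* Empty marker masks, empty nuclei sets and empty score fields are valid
  results, not errors; tracking marks frames invalid and the guidance map
  is empty until data arrive.
* Hard-core nucleus placement retries up to 200 attempts per nucleus and
  errors with a diagnostic if the requested density is unachievable.
* Area ties in blob selection and time ties in stream association are
  broken deterministically (smaller y then x; earlier frame), so the whole
  pipeline is reproducible bit-for-bit.

## Problem sizes in the shipped tests

The test suite exercises the default 3-s session (60 widefield + 270
microscopy frames), 100 + 100 frames for the two-regime scorer comparison,
and toy grids (20 x 20 to 50 x 50) wherever a brute-force oracle is the
comparison; these sizes were chosen so the full suite, including the
end-to-end parameter-recovery experiment, completes comfortably on a
single CPU.

## Worked example

```{r example}
library(biopsyGuide)

spec <- phantomSpec(seed = 7)
ses  <- generateSession(spec)

track  <- trackVideo(ses$widefieldFrame, colorGate(),
                     timestamps = ses$widefieldTimestamps,
                     nFrames = ses$nWidefield)
evaluateTracking(track, ses$truth$track, ses$cal)

scores <- scoreStream(ses$microFrame, morphometryScorer(),
                      nFrames = ses$nMicro)
assoc  <- associateFrames(ses$microTimestamps, ses$widefieldTimestamps)
field  <- accumulateScores(track, scores, assoc, dims = spec@widefieldDims)

mucosa <- polygonToMask(cbind(c(5, 954, 954, 5), c(5, 5, 594, 594)), 960, 600)
risk   <- computeRGRatio(ses$af, mucosa)
gm     <- computeGuidanceMap(risk, field, tauRG = 1.9, tauMTN = 0.5)
gm
```

## Known limitations

* The morphometry baseline is a stand-in scorer: it separates the
  phantom's regimes by construction of its features, and it accepts any
  user model through the scorer contract, but it is not a validated
  clinical classifier.
* Tracking assumes a single marker of a tissue-atypical color; multi-probe
  scenes and occlusions are out of scope.
* Mosaicking is translation-only and chains pairwise estimates, so drift
  accumulates on long sequences; there is no loop closure.
* The projector path is a planar homography; curvature of the imaged
  surface is not corrected.
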