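---
title: "Quantifying actin-wave dynamics with actinwaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying actin-wave dynamics with actinwaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinwaves)
```

## The measurement problem

Actin waves are domains of locally elevated actin density that translocate
along neurites — the motion is that of a density pattern, not of monomers.
In single-channel fluorescence time-lapse movies of neurons expressing
labelled actin they appear as transient bright spots moving along processes
at tens of micrometres per minute, often reversing direction, and often
re-appearing near sites of earlier activity. `actinwaves` turns such a
movie into quantitative track statistics: speeds, persistence, spatial
recurrence, and alignment to a nanoridge substrate axis and to the
neurite's own orientation.

The pipeline is, in order:

1. **Preprocess** — translation registration to frame 1, photobleach
   correction by mean matching, temporal Gaussian smoothing over 5 frames;
2. **Motion** — Lucas–Kanade optical flow with a Gaussian weighting window
   (σ = 2 px = 0.72 µm) and a reliability gate at 0.1;
3. **Clustering** — a per-pixel coherence score (dot product of each flow
   vector with the Gaussian-weighted mean flow of its 11 × 11, σ = 5 px
   neighbourhood), smoothed briefly along time, in which wave positions are
   detected as pruned local maxima (diameter 5 px, minimum separation
   15 px) and refined to sub-pixel centroids;
4. **Linking** — frame-to-frame assignment with search range 5 px and a
   one-frame memory, solved exactly as a minimum-cost matching;
5. **Filtering** — only tracks spanning ≥ 8 frames (14 s) with average
   instantaneous speed > 0.5 px/frame (5.4 µm/min) are analysed;
6. **Statistics** — spatial recurrence across 1-min windows at a 10-µm
   radius, duration-weighted axial-angle distributions on 20 bins of
   [0°, 90°], 1-D Wasserstein (W1) comparisons of per-video CDF ensembles,
   frequency–area fits through the origin, growth-cone moments, and a
   Shapiro–Wilk-gated testing cascade (t test / ANOVA + Tukey vs.
   Mann–Whitney / Kruskal–Wallis + Dunn).

All length/time parameters are stored in pixels and frames (the native
parameter space of the method) and reported in physical units through the
calibration (default 0.36 µm/px, 2 s/frame, a 40× confocal setup). The
coordinate convention, stated once: `x` is the column and `y` the row
index, both 1-based, angles measured from +x towards +y, axial quantities
on [0°, 180°) with alignments folded into [0°, 90°].

## A worked example

```{r example, eval = FALSE}
library(actinwaves)

sim <- simulate_movie(seed = 1)        # 150 frames, 256 x 256 px
res <- track_waves(sim$movie)          # full pipeline
m   <- track_metrics(res$tracks)

nrow(m)                                # number of filtered wave tracks
median(m$avg_inst_speed_um_min)        # median wave speed, um/min
recurrence(res$tracks)                 # spatial recurrence, 1 min / 10 um
```

On the default synthetic conditions this recovers a median speed within a
few percent of the generated 21 µm/min (the exact values for a seed are
computed by `scripts/acceptance.R`; the test suite asserts the 10%/20%
recovery bounds).

## What the synthetic generator emulates

No public raw movies accompany the study design this package implements,
so the generator is a first-class, tested module. It renders:

- a static scene: a soma and straight neurite ribbons (Gaussian cross
  profile, σ = 1.5 px) radiating at axial angles that are uniform on
  [0°, 180°) for a flat substrate or wrapped-normal around a configured
  nanoridge axis;
- waves: isotropic 2-D Gaussian blobs (σ = 2 px, the fewest-parameter
  match to a moving bright spot) translocating along the ribbons with
  lognormal speeds (mean 21 µm/min, CV 0.3), exponential lifetimes (mean
  30 s), per-frame reversal probability 0.05, and endpoint reflection;
- event births as a per-process Poisson process (2 events/min/process) in
  which, with probability 0.5, a new origin is resampled within 10 px of
  an earlier origin on the same process — this produces the recurrence
  hotspots the recurrence statistic is designed to detect. The hotspot
  radius sits below the 10-µm (27.8 px) recurrence radius but above the
  scale at which two co-occurring waves would become unresolvable under
  the method's own 15-px peak-separation rule;
- degradations: exponential photobleaching, integer-pixel stage jitter
  (so registration recovery is exactly testable), additive Gaussian noise,
  and 16-bit camera quantisation.

The event rate is consistent with the frequency–area regime of real
neurons (order 0.01–0.02 tracks/min/µm² at the ~130 µm² mask area of the
default geometry). The generator deliberately omits shot-noise photon
statistics, PSF convolution beyond the Gaussian blob, curved or branching
processes, and glial background; passing tests therefore demonstrate
correctness of the *measurement chain* under the stated image model, not
robustness to every feature of real microscopy data. Wave lifetime and
amplitude distributions are order-of-magnitude choices — the study design
gives no quantitative values for them.

## Numerical and design choices

Choices the method description leaves open were fixed as follows.

- **"Gaussian-like" temporal filter**: a normalised 5-tap discrete
  Gaussian with σ = 1 frame. Its 10-s support is well below the ≥ 14-s
  persistence the track filter enforces, preserving wave dynamics; the
  suite verifies identity on constant movies, impulse response, and
  linear-trend preservation.
- **Registration**: translation-only, integer resolution, FFT
  cross-correlation against frame 1, out-of-frame pixels filled with the
  frame median; constant frames are flagged rather than shifted. Order is
  register → bleach → smooth, recorded in the report.
- **Bleach correction**: per-frame rescaling that matches each frame's
  mean to frame 1 — the simplest monotone correction, exact for
  exponential decay. No foreground mask exists at this pipeline stage, so
  the whole-frame mean is used.
- **Flow reliability**: the smaller eigenvalue of the Gaussian-weighted
  structure tensor, normalised by its image-wide maximum so the 0.1 gate
  is intensity-scale-free. Spatial gradients are central differences on
  the average of the frame pair (making frame-swap antisymmetry exact to
  first order); window truncated at 3σ; borders invalid.
- **Coherence in space and time**: waves are coherent objects across
  frames, so the score stack is smoothed along time with a 3-tap Gaussian
  (σ = 1 frame) before peak detection. Without it the per-pair argmax of
  the plateau-like coherence bump jitters by ~1 px frame to frame, which
  inflates the mean step length of slow tracks (E|d + ε| > |d|); the
  short kernel removes that bias. `temporal_window = 1` disables it.
- **Peak threshold**: `min_score = 0.25 (px/frame)²`, the square of the
  0.5 px/frame speed floor — a cluster scoring below it is, by the
  pipeline's own definition, static. A per-frame percentile threshold was
  rejected because the max-normalised reliability gate concentrates valid
  pixels on the strongest mover, which would couple detection of one wave
  to the speed of another.
- **Peak stabilisation**: the score map is smoothed at the blob scale
  (σ = diameter/2) before maximum filtering — the same role trackpy's
  bandpass plays — and centroids are recentred iteratively within the
  diameter window to undo integer-grid quantisation.
- **Linking objective**: minimise the sum of link distances plus one
  search-range penalty per unlinked endpoint, links beyond the search
  range forbidden; solved exactly per frame pair with an O(n³) Hungarian
  algorithm, so any feasible link is preferred to leaving both endpoints
  unlinked and the result is invariant to detection order. An exhaustive
  enumeration oracle checks optimality in the tests.
- **Durations**: `duration_frames` counts frames spanned (8 frames ↔
  14 s implies the companion `duration_intervals = duration_frames − 1`
  is what converts to seconds); both are reported, the filter uses
  frames, and time conversions use intervals.
- **Localisation scale**: the tracked object is the coherence cluster,
  not the underlying density blob; its centroid can sit up to the
  coherence neighbourhood scale (σ = 5 px) from the blob centre,
  systematically along the direction of motion. Recovery tests therefore
  bound the mean position error by that scale, while *speeds* — frame
  differences of a near-constant offset — are recovered to within the
  10%/20% bounds the acceptance suite asserts. Per-step movement *angles*
  inherit localisation noise of order atan(noise/step) ≈ 25° at
  21 µm/min, which broadens recovered alignment distributions relative to
  ground truth; alignment bounds are asserted on the ground-truth
  construction, with a concentration requirement (≥ 1.8× uniform in the
  first 22.5°) on the recovered tracks.
- **Recurrence gating**: the minimum-track rule (default 5) is applied to
  both windows of a pair; ties at exactly the radius count as recurrent; a
  partial trailing window is discarded; a track belongs to the window
  containing its first detection.
- **CDF ensembles**: per-bin quantiles across videos can be locally
  non-monotone; they are rectified by a running maximum before W1, with
  raw quantiles kept. With a single video per condition the quartile
  extremes are flagged degenerate.
- **Testing cascade**: normality gate at α = 0.05 per group; Welch's
  two-sample t test on the parametric branch; Dunn's post hoc z tests with
  tie correction and Bonferroni adjustment (configurable). A zero-variance
  group is treated as failing normality rather than erroring.
- **Growth cones**: orientation from second central moments; width is the
  pixel extent along the minor axis; regions with a major/minor
  eigenvalue ratio below 1.1 get an undefined orientation (isotropic);
  parallel is ≤ 15°, perpendicular ≥ 75°.
- **Orientation field**: 36 rotated elongated Laplacian-of-Gaussian
  kernels (σ = 2 px across, 3:1 elongation), argmax per masked pixel,
  ties to the smaller angle; pixels whose response spread
  (max − min)/(|max| + |min|) falls below 0.3 are flagged low-confidence.

## Problem sizes in the shipped checks

The test and acceptance runs use 150-frame 256 × 256 movies (the package's
default study conditions) for speed recovery, a 120-frame 192 × 192 movie
for ridge alignment, 10 windows × 30 tracks for recurrence, instances of
up to 10 detections per frame for the exhaustive linking oracle, and 1000
replicates for the type-I-error calibration of the testing cascade. These
sizes were chosen so each property is measured with comfortable statistical
margin on a single CPU.

## Known limitations

- Flow is single-scale Lucas–Kanade: displacements well above ~2 px/frame
  need faster sampling, not this estimator. Wave speeds at the default
  calibration (≈ 1.9 px/frame) are near the comfortable edge; speeds are
  measured from linked cluster positions, not from flow magnitudes, which
  is why recovery holds there.
- Registration is translation-only and integer-valued; rotational drift
  or sub-pixel drift will leave residuals.
- Track topology is simple: no merging or splitting, no motion model.
  Two waves approaching within the 15-px separation rule merge into one
  detection, and identity after crossings is decided by the assignment
  cost alone.
- The recurrence statistic has no built-in null calibration; compare
  conditions, not absolute values.
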