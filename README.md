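# actinwaves

Quantification of actin-wave dynamics in single-channel fluorescence
time-lapse movies of developing neurons.

Actin waves are translocating domains of locally elevated actin density —
moving bright spots that travel along neurites at tens of µm/min, reverse
direction, and recur at preferred sites. This package implements a complete
measurement chain for them, for microscopists and quantitative biologists
who want reproducible wave statistics from raw movies:

- **preprocessing** — translation registration, photobleach correction,
  5-frame temporal Gaussian smoothing;
- **motion estimation** — Gaussian-weighted Lucas–Kanade optical flow
  (σ = 2 px) with a reliability gate (smaller structure-tensor eigenvalue,
  max-normalised, threshold 0.1);
- **wave detection** — a spatiotemporal coherence score
  `c(p) = v(p) · ⟨v⟩_G(p)` (Gaussian-weighted mean flow of the 11 × 11,
  σ = 5 px neighbourhood), peak detection at diameter 5 px with 15 px
  minimum separation;
- **tracking** — exact minimum-cost frame-to-frame linking (search range
  5 px, memory 1 frame), then filtering to tracks of ≥ 8 frames with
  average instantaneous speed > 0.5 px/frame = 5.4 µm/min;
- **statistics** — per-track metrics (total length, net displacement,
  average speed, net velocity, sinuosity), spatial recurrence of track
  starts across 1-min windows within a 10-µm radius (mean ± SEM over
  window pairs), duration-weighted axial alignment histograms (20 bins on
  [0°, 90°]) against nanoridge and neurite axes, 1-D Wasserstein distances
  `W1 = ∫ |F(x) − G(x)| dx` between condition CDFs, through-origin
  frequency–area fits, growth-cone orientation from image moments, and a
  Shapiro–Wilk-gated testing cascade (t test / ANOVA + Tukey vs.
  Mann–Whitney U / Kruskal–Wallis + Dunn).

Because raw movies of this kind are rarely shareable, the package ships a
ground-truthed synthetic movie generator (neurite scaffold, moving Gaussian
blobs with reversals and recurrence hotspots, bleaching, integer stage
jitter, noise, 16-bit quantisation) so the whole chain is testable end to
end; see the methods vignette (`vignettes/actin-wave-quantification.Rmd`).

## Worked example

```r
library(actinwaves)

sim <- simulate_movie(seed = 1)      # 150 frames, 256 x 256 px, 0.36 um/px, 2 s/frame
res <- track_waves(sim$movie)        # preprocess -> flow -> coherence -> link -> filter
m   <- track_metrics(res$tracks)

nrow(m)
#> [1] 23
median(m$avg_inst_speed_um_min)
#> [1] 18.75827
recurrence(res$tracks, min_tracks = 2)
#> recurrence: mean 0.777 +/- 0.106 SEM over 4 window pair(s) (window 30 frames, radius 27.8 px)
```

The generator placed waves at a mean speed of 21 µm/min under noise,
bleaching and stage jitter; the pipeline's median recovered speed for this
seed is 18.8 µm/min (−11%, within the 20% recovery bound the acceptance
suite asserts for noisy movies; on the noiseless version of the same seed
it recovers 20.2 µm/min, −3.8%). The high recurrence fraction reflects the
generator's origin hotspots (`min_tracks` is lowered here because a desk-
scale movie yields few tracks per 1-min window). `res$tracks`
is a plain `data.frame` (track, frame, x, y) with the calibration attached;
`write_track_table()` exports it with a per-track summary in both
pixel/frame and µm/min units. `track_ridge_alignment()`,
`aggregate_cdfs()`, `w1_between()` and `compare_groups()` take it from
there for condition comparisons.

A thin command-line front end for per-movie batch work is installed at
`inst/cli/actinwaves.R` (`simulate`, `preprocess`, `track` subcommands, all
driven by a YAML config mirroring `default_config()`).

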