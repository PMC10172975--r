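---
title: "A digital frailty index from home-cage video annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A digital frailty index from home-cage video annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagefrail)
```

## The problem

Frailty indexes (FIs) quantify non-specific, age-associated health decline
as an average over many scored deficits. In mice the standard instrument
is a manual clinical FI (here "MFI"): a trained rater scores 29 items,
each 0 / 0.5 / 1, and the index is their mean. Manual scoring is
labor-intensive, requires handling that stresses the animal, and its
reproducibility depends on rater training.

`cagefrail` implements a *digital* frailty index (DFI) computed entirely
from per-frame annotations of continuous home-cage video of singly housed
mice. The package does not touch video: the machine-learning stages that
turn pixels into annotations (wheel-marker classification, mouse
detection and segmentation, per-frame weight estimates, nest
segmentation) are upstream of its input contract. What it consumes are
five *annotation channels* per cage:

* `wheel_emission` — per-frame probability that a marker stripe on the
  running wheel is in the "top" position;
* `track` — per-frame mouse centroid (pixels) with detection confidence;
* `weight` — per-minute body-weight estimates (grams) with confidence
  weights;
* `coat` — per-frame coat-roughness samples;
* `nest` — nest-material centroid and mask area samples.

## The eight measurements

One DFI value summarizes one **measurement period**: a contiguous run of
full local calendar days (2 to 6) during which one mouse occupied one
recorded cage. Periods are derived from cage-occupancy records;
incomplete days at either end are excluded, periods with fewer than two
full days are dropped, and only the first six full days of longer
episodes are used. A consecutive-window mode instead tiles up to three
abutting 6-day (144 h) periods from the first full day, for
within-animal consistency studies.

Eight measurements are computed per period:

1. **Wheel distance** (m/day). Per-frame marker probabilities are decoded
   into a maximum-a-posteriori state path over {top, bottom} by Viterbi
   under a symmetric two-state HMM (`P(obs|top) = p_top`, self-transition
   `p_stay`, default 0.98). Each bottom-to-top transition is one wheel
   rotation (a single stripe cannot distinguish direction); distance is
   rotations x circumference / days.
2. **Wheel gait speed** (m/s). Per-rotation speeds
   (circumference / inter-rotation interval) within running bouts
   (intervals at most `wheel_bout_gap_s`, default 8 s), summarized by the
   90th percentile — a peak-performance statistic robust to idle time.
3. **Wheel circadian fraction**. The fraction of rotations falling in the
   dark phase of the light cycle; reported only when at least 10
   rotations were observed. An intact nocturnal rhythm gives values near
   0.9; arrhythmic running gives the dark duty fraction (0.5 at 12:12).
4. **Floor gait speed** (cm/s). Centroid tracks are cleaned (confidence
   at least 0.5; splits at gaps over 2 s or physically impossible jumps
   over 20 cm/frame), sliding 1-s window speeds are computed per segment,
   idle windows (at or below 0.5 cm/s) are discarded, and the 90th
   percentile of the rest is reported.
5. **Floor circadian fraction**. The dark-phase share of per-hour
   distance traveled, mirroring the wheel definition with distance as the
   activity weight.
6. **Weight slope** (g/day). Weighted least squares of per-minute weight
   estimates against time, using the per-frame confidence weights; the
   closed-form solution of the weighted normal equations.
7. **Coat roughness**. Median over the period of per-frame Sobel
   roughness: the mean gradient magnitude `sqrt(Gx^2 + Gy^2)` (standard
   3x3 kernels) over the masked mouse pixels, excluding the one-pixel
   image border so every pixel has a full neighborhood (no padding —
   this avoids any padding-dialect ambiguity).
8. **Nest movement** (cm/h). Mean centroid speed of the nest material
   over consecutive samples with sufficient mask area (over 100 px),
   skipping gaps over 2 h.

## Parameterization and aggregation

Each measurement is mapped onto `[0, 1]` by a threshold-linear rule
anchored at a healthy value (score 0) and a frail value (score 1), with
linear interpolation between and clamping beyond; the anchor ordering
encodes direction (low activity, low speeds, weak rhythm, weight *loss*,
high roughness, and low nest movement score as frail). The DFI is the
unweighted mean of the 8 scores. By default the policy is strict — all
8 components must be present, matching the definition of the index as an
8-component mean — with a lenient mode (mean over at least
`min_components` present scores) for sparse data. An *optimized* DFI
averages a named 5-component subset (defaulting to the three gait/wheel
and two circadian components, which carry most of the age signal), and a
*combined* FI is the mean of paired MFI and DFI values.

The shipped threshold anchors are calibrated against this package's own
synthetic-cage simulator (below) so that its healthy phenotype scores
near 0 and its frail phenotype near 1 on every component. They are
placeholders in the same sense that any deployment must re-derive
anchors from age-stratified training data for its own hardware,
optics and strain background; all of them live in `dfi_config()` and can
be serialized to YAML.

## Benchmarking statistics

`linregress()` returns least-squares slope/intercept, Pearson R, and the
two-sided p value from the t statistic with n − 2 df. MFI/DFI pairs are
formed per DFI measurement by the same-mouse MFI nearest in date,
kept only if fewer than 8 whole days apart (equidistant candidates
resolve to the earlier MFI, a deterministic convention). Because both
indexes correlate with age, their mutual correlation is additionally
assessed on age-normalized residuals: each index is regressed on age over
the paired subset and the two residual vectors are correlated.
Component-by-component structure is summarized by a pairwise-complete
Pearson correlation matrix (manual items observed non-zero five times or
fewer are excluded) and clustered by WPGMA on `1 - R` distances
(switchable to `1 - |R|`; the correlation-to-distance transform is a
convention choice, and `1 - R` places anticorrelated traits far apart).
The WPGMA implementation records merges with deterministic lowest-index
tie-breaking and returns a standard `hclust` object, exportable as a
Newick dendrogram.

## The synthetic cage

Real inputs for this pipeline are video-derived and large; the package
therefore ships a fully seeded simulator that emulates the statistical
structure the pipeline assumes, with complete ground truth:

* wheel rotations arrive in bouts (Poisson bout starts at
  phase-specific rates, geometric bout sizes of mean 20, jittered
  per-rotation durations) and are rendered into per-frame marker
  emissions with classifier flip noise; the simulator enforces at least
  8 frames per rotation so the marker phase is observable at the
  configured frame rate;
* the floor track alternates rest with movement bouts (random-heading
  walks at the phenotype's speed, reflected at the cage walls), with
  continuous detection jitter while moving, sparse "twitches" at rest,
  and occasional low-confidence detections;
* weight samples follow a linear trajectory with CV noise and
  confidence weights (a few zero-weight frames); coat samples are
  gamma-distributed around the phenotype mean; the nest centroid
  performs a random walk calibrated to the phenotype's displacement
  rate, with occasional under-segmented (small-area) samples.

A `mouse_phenotype` interpolates every behavioral parameter between a
healthy and a frail anchor as a function of latent frailty.
`generate_cohort()` draws ages uniformly, maps age (plus Gaussian
latent noise) to latent frailty with a configurable effect size (0 gives
a null cohort), simulates channels per mouse, and emits occupancy, MFI,
date-of-birth and ground-truth tables. Simulated MFI items go non-zero
with probability increasing in a noisy copy of the same latent, which
reproduces both the sparse discrete structure of manual scores and the
shared non-age latent that the residual analysis is designed to detect.

What the simulator does *not* emulate: classifier errors correlated in
time or with posture, perspective distortion, arena occlusions,
multi-animal housing, and nonlinear age trajectories. Passing tests
therefore demonstrate correctness of the analytical pipeline given its
input contract, not performance of any upstream vision model on real
footage.

## Numerical choices and problem sizes

* Viterbi decoding runs in log space (emissions clamped to
  `[1e-12, 1 - 1e-12]`), so million-frame sequences decode without
  underflow; ties break toward staying in the current state.
* The default simulated frame rate is 4 Hz rather than full video rate:
  every downstream computation is rate-agnostic, and 4 Hz keeps a
  two-day, 60-mouse cohort below a minute of simulation time. Large
  repeated-cohort experiments (e.g. 50-seed null batteries of 40 mice)
  run at 1 Hz, where the null property being tested — no DFI~age
  correlation without an age effect — does not depend on rate.
* Cohort simulations default to 2-day periods, the minimum a period may
  have, which is also the dominant regime in large outbred studies.
* Percentiles use the standard linear-interpolation definition (R type
  7); the weighted regression uses the closed-form normal equations;
  degenerate inputs (no positively weighted points, a single distinct
  x, zero variance) are errors or flagged missing values rather than
  silent zeros, because a zero would masquerade as a legitimate frailty
  score.
* Missing measurements carry their reason as an attribute and propagate
  to the result table; under the strict policy they abort the period
  with the component names listed.

## Known limitations

* Threshold anchors shipped in the default config are
  simulator-calibrated placeholders, not field-calibrated values.
* Wheel rotation counting assumes a single marker stripe; direction and
  partial rotations are invisible by construction.
* The circadian summary is a single dark-fraction number; it cannot
  distinguish phase shifts from amplitude loss (an entropy-based
  alternative can be wired through the same interface).
* The weight-slope component scores loss only; two-sided scoring (|slope|)
  is a config change away but changes the deficit semantics.
* Coat roughness from Sobel gradients is sensitive to illumination
  texture; the median over a period mitigates but does not remove this.
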