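---
title: "Proximity Index methods: models, parameters and design choices"
author: "gazeproximity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proximity Index methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeproximity)
```

This vignette is the package's own account of its methods: what is
modelled, which parameters matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and
where genuinely open design choices were settled.

## 1. The reference distribution and the Proximity Index

### Model

For each video frame the reference group's gaze is summarized as a
probability density over the screen. One gaze point per reference
recording enters each frame (the centroid of the fixation active at the
frame's temporal midpoint); the pooled points are smoothed with Gaussian
kernels of per-point adaptive bandwidth. The adaptive scheme is the
pilot-plus-Abramson construction: a fixed-bandwidth pilot estimate
(Silverman's per-axis rule, $h_j = \hat\sigma_j\, n^{-1/6}$) is evaluated
at the data points, and each kernel is rescaled by
$\lambda_i = (f_{\mathrm{pilot}}(x_i)/g)^{-1/2}$ with $g$ the geometric
mean of the pilot densities. Sparse regions get wider kernels, tight
clusters sharper ones, so multimodal frames are neither over-smoothed at
their modes nor under-smoothed in their tails — exactly the regime
frame-wise gaze data live in, where the spread changes drastically from
frame to frame. A fixed-bandwidth fallback (`adaptive = FALSE`) is kept
for diagnostics and tests.

The density is cut into 100 isoline levels, linearly spaced from
$f_{\max}/100$ to the frame's own maximum $f_{\max}$. The Proximity Index
of a coordinate is $k/100$ for the highest level $k$ whose threshold the
local density still reaches, 0 below the lowest level. Contouring each
frame against its own maximum is what makes PI a per-frame 0–1 score:
it measures *relative* depth in that frame's distribution, so frames with
one sharp focus and frames with several equally tall foci are treated
symmetrically (two equally tall peaks both carry level-100 contours).
PI is therefore invariant to any monotone rescaling of the density, and
reference members are scored leave-one-out so their own gaze never
inflates their score.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `cellSizePx` | 4 px | density grid resolution (480 × 300 cells on the default screen) |
| `nLevels` | 100 | isolines per frame; fixes the 0.01 PI granularity |
| `minPointsPerFrame` | 10 | below this pooled count a frame is unusable and yields missing PI |
| `attendanceThreshold` | 0.65 | minimum fraction of frames with a binocular-valid sample |

Sub-fixation spatial precision is dominated by the 100-level
quantization, so a 4-px grid loses nothing while keeping a frame's
density fit to a single matrix product. The bandwidth is floored at one
grid cell so that even degenerate, near-coincident point sets produce a
surface the grid can resolve.

### Numerical choices

* Density at a gaze coordinate is obtained by **bilinear interpolation**
  of the grid, which removes grid-cell aliasing at contour boundaries.
  Point-in-polygon tests against traced contours would differ only
  exactly at boundaries; the interpolation route is deterministic and
  orders of magnitude cheaper.
* Ties (density exactly equal to a level) count as *inside*, which is
  what makes a coordinate at exactly half the maximum score 0.50.
* Kernels are truncated at the screen bounds and the surface renormalized
  **globally** (not per kernel). PI depends only on $f/f_{\max}$, so the
  choice of edge correction cannot change any score's ordering; global
  renormalization keeps the unit-integral invariant checkable.
* The sharp-peak limit is bounded by discretization: with near-identical
  reference points the surface collapses to a kernel-width spike, and a
  probe a fraction of a cell away from the grid peak interpolates to
  roughly 0.9 of the maximum rather than 1. Leave-one-out PI of a
  noise-free group therefore approaches but does not reach 1.

### Reference stability

`referenceStability()` asks how many reference recordings are enough:
bootstrap subsamples of each candidate size define sub-references, a
held-out probe set is scored against sub- and full reference, and
agreement is the correlation of the two mean-PI vectors. The summary —
the smallest size with mean agreement at or above 0.95 — is this
package's operationalization of "stable"; the threshold is a convention,
not an estimate, and the full curve is always returned.

## 2. Fixation extraction and attendance

The I-VT filter classifies samples by angular velocity: a centred
difference over a 20 ms window on the binocular midpoint trace, 30 °/s
threshold, adjacent fixations merged when separated by at most 75 ms and
0.5°. Gaps up to the merge limit are bridged by linear interpolation;
longer gaps split the trace, mirroring standard I-VT gap-fill behaviour
while keeping the merge limits authoritative. Velocity is computed on the
binocular **midpoint** (the average of the valid eyes); whether the
original filters used monocular or averaged traces is generally
unspecified in tracker documentation, and the midpoint is the
lower-variance choice. When the sampling interval exceeds the half
window (60 Hz recordings), the window is widened to the adjacent samples
so velocity never degenerates to zero. No minimum fixation duration is
imposed by default (`minDuration = 0`).

Screen attendance counts frames with at least one sample where *both*
eyes are valid and on screen; recordings under 65 % are flagged for
exclusion (an override exists for exploratory use). Monocular-valid
samples still contribute to fixation estimation — the attendance
criterion is deliberately stricter than the estimation input.

Fixations are classified **focal** (duration > 180 ms, preceding saccade
< 5°) or **ambient** (< 180 ms, > 5°). Both definitions are strict
inequalities, so boundary values, mixed cases (long fixation after a long
saccade and vice versa) and first fixations (no preceding saccade) are
*unclassified* and excluded from both proportions, which are normalized
by the overall fixation count.

## 3. Salience evaluation

The channel pipeline is a simplified Itti–Koch-style bank: intensity and
color-opponency center–surround differences at two Gaussian scale pairs
(σ = 1/4 and 2/8 px), Gabor energy at 0°, 45°, 90°, 135°, flicker as the
absolute intensity difference of successive frames, and Reichardt-style
directional motion energy probed at an 8 px shift. Graph-based
activation/normalization schemes are deliberately **not** reimplemented:
the analysis surface of interest is the AUC comparison, and
`salienceAUC()`/`aucSeries()` accept any externally computed map stack,
so a true graph-based model can be substituted without touching the
evaluation.

AUC uses the rank (Mann–Whitney) formulation with mid-ranks: positives
are map values at fixated pixels, negatives default to **all** pixels of
the frame grid (a uniform non-fixated baseline; a shuffled-fixation
negative set can be supplied instead). Constant maps score 0.5 by
convention, and the statistic is invariant under monotone transforms of
the map. Group comparison pairs per-frame AUC values with the Wilcoxon
signed-rank test; the effect size is emitted both as $r = Z/N$, as
printed in some applied reports, and as the conventional
$r = Z/\sqrt{N}$ — the former is nonstandard and the ambiguity cannot be
resolved from print, so both are labelled and returned.

## 4. Scene features

Visual complexity is the Canny edge-pixel count per frame:
derivative-of-Gaussian gradient (σ = 1.4), non-maximum suppression,
double threshold with hysteresis. Thresholds default to a median-based
automatic rule (high = 1.33 × median positive gradient magnitude,
low = 0.4 × high) because no fixed threshold suits both cluttered and
plain frames; fixed values are accepted wherever comparability across
scenes matters. Frames are processed at the resolution supplied.
Annotation rasterization assigns an event to every frame whose temporal
midpoint it covers; hard cuts are point events whose *following* frame is
coded 1; social complexity and the two speech codes are exclusive
channels and contradictory overlaps are validation errors rather than
silent overwrites.

## 5. Inference

**PLS correlation.** Both blocks are z-scored; $R = B^\top A/(n-1)$ is
decomposed by SVD. Significance: rows of **B only** are permuted, the
singular values recomputed and compared per component without re-sorting
— simpler than a Procrustes-rotated null and conservative for trailing
components; the +1-corrected p-value never reaches exactly zero.
Stability: rows are resampled with replacement, each resample's saliences
are Procrustes-aligned (rotation and sign) to the original before taking
5th–95th percentile intervals; a loading is stable when its interval
excludes zero. Imputation ahead of the analysis is column-median by
default (the natural robust single-value choice when nothing about the
missingness mechanism is known) and always returns its mask; age is
removed by exact least-squares residualization of each column on
[1, age].

**Sliding windows.** Recordings are age-sorted per group and a window of
20 recordings advances one recording at a time; any window containing two
recordings of one subject is skipped and logged, so windows are
independent across subjects within themselves. Windows are paired across
groups by index and their mean ages reported so age-matching can be
verified rather than assumed.

**Dispersion.** A group's dispersion on a frame is the mean pairwise
Euclidean distance of all gaze coordinates present; a window's value
averages over frames with at least two points. The per-window test
permutes individuals between the two groups (original group sizes
preserved) and compares $|{\rm disp}_A - {\rm disp}_B|$ two-sidedly —
sidedness is genuinely ambiguous for this statistic, and the two-sided
choice is the conservative default.

## 6. The synthetic-data generator

The generator provides ground truth the real world cannot: scripted
attention foci with per-frame weights, hard cuts, moving backgrounds,
character counts and speech intervals; cohorts whose members dwell
250–700 ms on a target, follow the script with probability
`onScriptProb`, otherwise revisit a subject-persistent idiosyncratic
focus; isotropic Gaussian landing noise truncated at the screen (with an
optional linear age trend); per-eye offsets; blink gaps of 120–400 ms
trimmed to the requested dropout; and phenotype matrices whose columns
load with chosen signs on a latent factor correlated with mean PI at a
chosen level. All generators are seed-deterministic.

Default study conditions: the 1920 × 1200 px / 45°53′ × 29°38′ / 60 cm
screen, 25 fps timelines, 300 Hz sampling (60 Hz supported), 20-subject
groups with 90 % on-script probability, 60 px landing noise and 5 %
dropout; desk-scale scenes of a few hundred frames keep the full pipeline
in minutes. The recovery and calibration analyses in the test suite use
the cohort sizes their designs require (for example n = 166 observations
with 12 behavioural variables and a planted latent correlation of 0.5 for
the PLS recovery check, 200 replicate null datasets for type-I-error
calibration, and two 40-recording groups with opposite age-noise slopes —
reference-like noise 80→30 px and test-like 40→160 px across ages 2–4 —
for the developmental-divergence scenario).

What the generator does **not** emulate: photorealistic content (salience
channels see synthetic discs and textures, not cartoon imagery),
cognitive gaze control (dwell targets are memoryless draws, not
scanpaths), smooth pursuit, tracker-specific noise spectra, or
calibration drift. Passing tests therefore demonstrate that the
*algorithms* are correct and that planted group structure of realistic
magnitude is recovered — not that any particular empirical effect size in
real cohorts will reproduce.

## 7. Known limitations

* PI granularity is fixed at 0.01 by the 100-level contouring; differences
  finer than that are invisible by design.
* Frames with fewer than `minPointsPerFrame` reference points yield
  missing PI; available-frame averaging means subjects are compared on
  partially different frame sets when attendance differs.
* The grid discretization bounds PI slightly below 1 for razor-sharp
  reference distributions (see §1); at realistic gaze noise this is
  negligible.
* The salience pipeline is a simplified channel bank; absolute AUC levels
  are not comparable to full graph-based models, although the group
  *comparison* machinery is model-agnostic.
* Leave-one-out scoring refits one KDE per member per frame; for very
  large cohorts and frame counts this is the dominant cost (it is linear
  in both).
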