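# gazeproximity

Quantifying how far an individual's moment-to-moment gaze diverges from a
reference group while both watch the same dynamic stimulus.

Classic area-of-interest analyses require hand-drawn regions decided in
advance. `gazeproximity` instead treats the reference group's own gaze as
the norm: for every video frame it estimates the group's gaze density on
the screen, contours that density into isolines, and scores any gaze
coordinate by how deep inside the group's distribution it lands. The
package is aimed at developmental and clinical eye-tracking studies (for
example, comparing children with autism to typically developing peers over
an animated scene), but nothing in it is tied to a particular population
or stimulus.

## The Proximity Index

Let \(f_t(x, y)\) be the reference group's gaze density on frame *t*,
estimated by Gaussian kernels with per-point adaptive (Abramson)
bandwidths from the pooled fixation locations of the reference
recordings. The density is cut into 100 linearly spaced isoline levels

\[ \ell_k = k \cdot \frac{\max f_t}{100}, \qquad k = 1, \dots, 100 . \]

A gaze coordinate \(g\) on frame *t* receives the **Proximity Index**

\[ \mathrm{PI}_t(g) = \frac{1}{100} \max \{ k : f_t(g) \ge \ell_k \}, \]

with \(\mathrm{PI} = 0\) when \(f_t(g)\) falls below the lowest level. A
coordinate at the density mode scores 1; one at half the frame maximum
sits on isoline 50 and scores 0.50; gaze far from everything the group
looked at scores 0. Because each frame is contoured against its own
maximum, PI is scaled 0–1 per frame, and a subject's summary score is the
mean over all scoreable frames. Members of the reference group itself are
scored leave-one-out, against a reference rebuilt without them.

Around that core the package provides the standard companion analyses:

* **I-VT fixation filtering** (30 °/s threshold, 20 ms velocity window,
  75 ms / 0.5° merging) with binocular screen-attendance QC (65 % rule);
* **focal/ambient fixation modes** (> 180 ms and < 5° vs < 180 ms and
  > 5°);
* **salience channels** (intensity, color, orientation, flicker, motion)
  and frame-wise ROC-AUC evaluation of how well any map predicts
  fixations, with paired Wilcoxon group comparison;
* **scene features**: Canny edge-length visual complexity, annotation
  rasterization (social complexity, monologue/directed speech, hard cuts,
  moving background);
* **inference**: PLS correlation with permutation significance and
  bootstrap loading stability, age residualization, sliding age windows
  with a subject-uniqueness rule, and permutation tests of group gaze
  dispersion (mean pairwise distance);
* **synthetic data**: a scripted scene generator with known ground truth
  (foci, cuts, cohorts with age-dependent gaze noise, phenotype tables
  with a planted latent factor) used throughout the test suite.

## Worked example

```r
library(gazeproximity)

geom     <- screenGeometry()                      # 1920x1200 px, 45°53' x 29°38', 60 cm
timeline <- frameTimeline(fps = 25, nFrames = 250)
script   <- sceneScript(nFrames = 250, fps = 25, geometry = geom, seed = 1)

## a 20-subject reference group following the scripted foci
refCohort <- generateCohortGaze(script,
  cohortSpec(nSubjects = 20, group = "reference", onScriptProb = 0.9,
             noiseSdPx = 60, samplingHz = 300), seed = 2)
reference <- buildReference(refCohort$recordings, timeline)
reference
#> ReferenceModel: 20 members, 250/250 usable frames (median 18 points)

## a test subject with reference-like gaze, and one mostly off-script
probe <- generateCohortGaze(script,
  cohortSpec(nSubjects = 1, group = "test", onScriptProb = 0.9,
             noiseSdPx = 60, samplingHz = 300), seed = 3)$recordings[[1]]
idio  <- generateCohortGaze(script,
  cohortSpec(nSubjects = 1, group = "test", onScriptProb = 0.2,
             noiseSdPx = 120, samplingHz = 300), seed = 4)$recordings[[1]]

proximityIndexSubject(probe, reference)
#> PIResult 'test_01': mean PI 0.576 over 232 frames
proximityIndexSubject(idio, reference)
#> PIResult 'test_01': mean PI 0.120 over 229 frames

modeProfile(ivtFixationFilter(probe))[, c("nFixations", "propFocal", "propAmbient")]
#>   nFixations propFocal propAmbient
#> 1         20      0.45           0
```

The reference-like subject lands deep inside the group's isolines on most
frames (mean PI 0.58); the idiosyncratic viewer rarely does (0.12).
Frames without fixated gaze (saccades, blinks, off-screen intervals) are
excluded from the mean rather than imputed, which is why fewer than 250
frames are scored.

## Command-line use

```sh
Rscript inst/cli/gazeproximity.R simulate --out ds --n-subjects 10 --n-frames 250
Rscript inst/cli/gazeproximity.R build-reference --gaze-dir ds/gaze --out ref --n-frames 250
Rscript inst/cli/gazeproximity.R pi --gaze-dir ds/gaze --reference ref --n-frames 250
```

See `vignettes/proximity-index-methods.Rmd` for the model, its
assumptions, parameter choices and known limitations.
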