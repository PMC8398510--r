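---
title: "Methods: dynamic segmentation and activity recognition for upper-limb rehabilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic segmentation and activity recognition for upper-limb rehabilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabrec)
```

## The problem

People recovering from spinal cord injury are prescribed repeated
shoulder and elbow exercises — shoulder abduction (SA), elbow extension
(EE), elbow flexion (EF), shoulder external and internal rotation (SER,
SIR), shoulder extension (SE) and shoulder flexion (SF) — and adherence is
usually verified only by self-report. A single wrist-worn tri-axial
accelerometer sampling at 30 Hz over a ±2 g range carries enough signal to
recognize which exercise was performed and to count repetitions. This
package implements that recognition pipeline end to end:

1. **Smoothing.** A trailing moving-average filter of 10 samples
   (`moving_average()`) suppresses sensor noise; body movement lives well
   below the Nyquist band, so a short mean acts as an adequate low-pass.
2. **Dynamic segmentation.** The continuous recording is split into one
   segment per exercise repetition by peak/valley analysis of the
   acceleration magnitude (`dynamic_segment()`), so segment length tracks
   the duration of the movement — in contrast to fixed sliding windows.
3. **Features.** 24 time-domain statistics per segment
   (`extract_features()`): minimum, maximum, range, mean, population
   standard deviation and root mean square of each axis $x, y, z$ and of
   the per-sample magnitude $m_i = \sqrt{x_i^2 + y_i^2 + z_i^2}$.
4. **Classification.** RBF-kernel SVM ($C = 2.0$, $\gamma = 0.01$),
   1-nearest-neighbour (Euclidean), a 100-tree random forest, or Gaussian
   naive Bayes (`fit_classifier()`).
5. **Evaluation.** Leave-one-subject-out cross-validation (`loso_cv()`),
   which measures generalization to unseen people; per-class recall,
   precision and F1 plus overall accuracy from the confusion matrix
   (`metrics_from_confusion()`).

No clinical recordings ship with the package. A seeded generator
(`simulate_study()`) emulates the study protocol — 10 subjects × 10
repetitions × 7 exercises = 700 labeled repetitions — so every stage is
exercised end to end, and the reported reference confusion matrices are
bundled so the metric arithmetic can be validated exactly.

## Conventions

Segments are half-open 0-based sample intervals on disk
(`start_sample,end_sample`) and 1-based inclusive `[start, end]` intervals
in memory, R's native convention; the row `0,90` and the interval
`[1, 90]` denote the same 90 samples. Acceleration is stored in g
throughout, matching the sensor's ±2 g specification. The canonical class
order — SA, EE, EF, SER, SIR, SE, SF — fixes rows and columns of every
confusion matrix.

## Dynamic segmentation in detail

### The detection channel

Peaks and valleys are detected on a one-dimensional channel derived from
the magnitude (`detection_channel()`). Two design choices matter here:

* **Zero-phase smoothing.** The channel is smoothed with a *centered*
  10-sample moving mean rather than the trailing filter used before
  feature extraction. A causal filter delays the waveform by
  $(L-1)/2$ samples; boundaries detected on it would be systematically
  late relative to the true repetition extent. Centered smoothing keeps
  boundary estimates unbiased, while features are still computed on the
  causally filtered signal.
* **Baseline removal.** At rest a wrist accelerometer reads the 1 g
  gravity vector, whatever the wrist orientation, so the resting
  *magnitude* is 1 g. The default channel is therefore the absolute
  deviation $|m - 1|$: rest gaps sit near zero and any movement — whether
  it adds to or opposes gravity — appears as a positive burst. Without
  baseline removal, a valley threshold derived multiplicatively from
  rest-gap levels (see below) would sit near 1.5 g and could not fall
  below the peak threshold. `baseline = "median"` is available for data
  whose calibration offsets the rest level, and `baseline = "none"`
  exposes the raw smoothed magnitude.

### Learning the thresholds

`learn_segmentation_params()` derives three quantities from an annotated
training set, each with a configurable safety margin:

* peak threshold $T_p = \alpha \cdot \min_r \max(h_r)$, the smallest
  per-repetition channel maximum, scaled by $\alpha = 0.9$ so a test
  subject slightly weaker than any training subject is still detected;
* minimum peak distance $D = \lfloor \beta \cdot \min_r \text{len}(r)
  \rfloor$ samples with $\beta = 0.8$, which suppresses secondary maxima
  inside one repetition while never bridging two distinct repetitions;
* valley threshold $T_v = \gamma \cdot \max_g \min(h_g)$ over the
  inter-repetition gaps, with $\gamma = 1.5$ of headroom above the
  noisiest rest level seen in training. With a single repetition and no
  gaps, $T_v$ falls back to $0.2 \, T_p$ with a warning.

$T_p > T_v$ is enforced; training data violating it (rest
indistinguishable from movement on the channel) raise a degenerate-data
error rather than silently producing arbitrary segments.

The boundary type is chosen by a simple rule: if the median per-gap
minimum is at most $T_v$ — rest dips exist between repetitions — segment
boundaries are the valleys nearest before and after each retained peak;
otherwise boundaries are the midpoints between neighbouring peaks. Both
modes are available explicitly. Tie-breaks are deterministic throughout:
peak suppression keeps the higher peak and, on exact ties, the earlier
index; a valley sample shared by two consecutive segments belongs to the
earlier one; plateau extrema report their midpoint sample.

### The sliding-window baseline

`sliding_windows()` implements the conventional fixed-length segmenter:
windows of 2, 2.5 or 3.5 s at 50% overlap, starting at sample 0, with the
trailing remainder dropped (padding would bias length-sensitive features).
Windows and detected segments are labeled the same way: one-to-one greedy
matching to ground-truth segments by descending interval
intersection-over-union, keeping matches with IoU ≥ 0.5
(`match_segments_to_labels()`). Unmatched windows are dropped from both
training and test, the strictest reading of window labeling; this slightly
favours the baseline, since surviving windows are exactly the
well-aligned ones.

## Features and classifiers

The standard deviation uses the population form
$\sqrt{\tfrac1N \sum (a_i - \bar a)^2}$, which keeps the identity
$\text{rms}^2 = \text{mean}^2 + \text{std}^2$ exact — asserted to
$10^{-9}$ in the tests. Features are *not* normalized in the feature
table; each classifier fits a z-score scaler on its training rows only and
applies it at prediction time, so no information leaks from test folds
into scaling.

Classifier configuration notes:

* The RBF kernel's "radius" parameter is read as the kernel width
  $\gamma = 0.01$, the usual axis of an RBF tuning grid alongside the
  complexity $C = 2.0$.
* KNN defaults to $k = 1$ (the common toolkit default; configurable), with
  Euclidean distance on the standardized features.
* The random forest pins "default values" to explicit numbers — 100 trees,
  $\lfloor\sqrt{p}\rfloor$ features per split, a fixed seed — so results
  are reproducible across library versions. Training rows are first
  sorted into a canonical order (label, then feature values) because the
  bootstrap consumes the RNG in row order; this makes fitting invariant
  to the row order of the input table.
* Gaussian naive Bayes applies a variance floor of $10^{-9}$ relative to
  the largest feature variance, so a feature that is constant within one
  class cannot produce a degenerate likelihood spike.
* A decision-tree classifier is deliberately absent: the four evaluated
  and reported configurations are SVM, KNN, random forest and naive
  Bayes, and the package follows the reported set.

## Evaluation choices

Leave-one-subject-out cross-validation re-learns *everything* per fold —
segmentation thresholds, feature scaler, classifier — on the nine training
subjects before touching the held-out subject. Headline numbers are the
mean ± standard deviation of per-fold metrics; per-class views come from
the pooled confusion matrix over all folds. Note the pooled per-class F1
and a per-fold-averaged F1 can differ in the second decimal; this package
computes the pooled form. On a balanced set, overall accuracy equals
macro recall exactly, which is why those two columns coincide in balanced
reports.

Degenerate-fold policy: a class never predicted has precision 0 (with a
warning); a class with precision + recall = 0 has F1 = 0; per-fold metrics
are computed over the classes actually present in that fold's truth.
10-fold cross-validation (`kfold_cv()`) stratifies folds by class, since
unstratified draws can starve a 10-repetition class.

## What the synthetic generator does and does not emulate

Each exercise is an archetypal raised-cosine acceleration burst
($\sin^2(\pi u)$ envelope) with an activity-specific duration (2.1–3.5 s
mean), amplitude (0.85–1.20 g), 3-D movement direction and small per-axis
phase lags, superimposed on a 1 g gravity baseline and white Gaussian
noise, hard-clipped to ±2 g. Subjects differ by an amplitude scale and a
duration scale (uniform on [0.85, 1.15]), a random orientation rotation
(angle ~ Normal(0, 8°)) and a noise level (uniform on [0.02, 0.06] g).
Rest gaps are uniform on [0.5, 1.5] s. Each subject's RNG substream is
derived from the study seed and the subject index, so adding subjects
never perturbs existing ones.

SA and SF — the pair that real data confuses, since both are forward/
lateral arm raises with similar extent — share duration, amplitude,
envelope and lags, and differ only by a rotation of the movement
direction. The rotation angle is mapped from the `confusability`
parameter as $\theta = 90° (1 - 2c)^4$: orthogonal directions at
$c = 0$, identical at $c = 0.5$, and about 22° at the default
$c = 0.15$ — comparable to the ±8° subject orientation spread, which is
what makes the pair genuinely confusable across subjects. The steep
exponent was chosen when the generator was designed so that the default
sits in the mild-confusion regime rather than either extreme.

The generator is deliberately *not* a biomechanical simulation: it
reproduces the statistical structure the pipeline must cope with
(distinct movement signatures, one deliberately similar pair,
inter-subject amplitude/duration/orientation/noise variation, gravity,
clipping) but not anatomy, fatigue, incorrect execution, motion artifacts
or drifting sensor placement. Consequently, passing the synthetic
end-to-end checks demonstrates that the pipeline's machinery is correct
and that its accuracy ordering (dynamic segmentation above long sliding
windows) holds under the emulated conditions — it does not certify
clinical-grade accuracy on real patients.

## Problem sizes and numerical tolerances used by the tests

The test suite runs the full default study (10 subjects, 700 repetitions)
for the segmentation-recovery and leave-one-subject-out checks, a
4-subject noiseless orthogonal mini-study for the exactness check, and
3-subject studies for the faster structural tests; these sizes keep the
suite comfortably within a coffee break while still exercising every code
path at study scale. Exact identities (range = max − min) are asserted
with `expect_identical`; floating-point identities at $10^{-9}$; CSV
round-trips at the 6-decimal precision of the on-disk format
($10^{-6}$ g absolute).

## Known limitations

* Thresholds are learned globally over the training subjects, not
  per subject; a subject radically weaker than every training subject can
  fall below $T_p$.
* Only dynamic (movement) activities are segmentable; postural holds have
  no magnitude bursts.
* Streaming/online segmentation is out of scope — the centered detection
  smoother and global thresholds assume a complete recording.
* Frequency-domain and wavelet features, feature selection, and artifact
  attenuation are natural extensions and intentionally absent.
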