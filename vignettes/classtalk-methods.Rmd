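---
title: "Detecting classroom interactions and measuring child-directed speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting classroom interactions and measuring child-directed speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(classtalk)
```

## The problem

Young children's language development is driven in large part by the talk
addressed to them — child-directed speech (CDS). Quantifying an individual
preschooler's CDS exposure normally requires hand-coding interaction
intervals from video and transcribing every directed utterance, which is
slow, expensive, and limits studies to short observation windows.

`classtalk` implements an automatic alternative built around feature streams
that can be extracted from a child-worn (egocentric) camera: face detections
with head pose and mouth/eyes-open confidences, face-identity matches, and
automatic speech recognition (ASR) output with word timings and
confidences. From these it

1. detects intervals in which the focal child interacts with an **adult** or
   with a **peer** (a bi-directional LSTM sequence classifier per partner
   class, at 250 ms resolution),
2. assigns each ASR utterance to adult-CDS, peer-CDS, or non-CDS by temporal
   intersection with those intervals, and
3. computes transcript measures per partner class — total number of
   utterances (TNU), total number of words (TNW), number of different words
   (NDW), mean length of utterance (MLU = TNW/TNU), type-token ratio
   (TTR = NDW/TNW) — plus interaction measures (frequency, median and SD of
   duration, total duration of interactions, TDI), all count measures normed
   to a 10-minute basis.

Because the pipeline is validated leave-one-subject-out (LOSO) and automatic
counts are systematically biased (ASR underestimates words in noisy
classrooms), raw measures are additionally **calibrated** with ordinary
least products (OLP, type II / geometric-mean) regression fitted on
training-fold children only.

Real classroom recordings are not distributable, so the package ships a
synthetic session generator that stands in for them end to end; everything
below is trainable and testable offline.

## The synthetic classroom session

`sim_config()` / `generate_session()` emulate the statistical structure of a
morning preschool recording rather than its pixels or audio:

* **Interactions.** Onsets per partner class follow a homogeneous Poisson
  process; durations are log-normal; overlapping same-class intervals are
  merged. The literature on such sessions reports only summary structure
  (frequency and duration contrasts), not a generative law, so this is the
  simplest process reproducing it; log-normal durations are a package
  choice. Defaults encode a 40-minute session with adult interactions that
  are longer and less frequent (2 per 10 min, median 30 s) than the sparse
  and short peer interactions (3 per 10 min, median 8 s).
* **Grid alignment.** Interval boundaries are snapped to the 500 ms native
  face-frame grid so the feature stream can represent them exactly. Real
  boundaries are asynchronous; on real data one to two boundary bins per
  interval edge are inherently ambiguous, and reported sample-level
  accuracies would be correspondingly lower.
* **Faces.** During a true interaction the partner's face appears every
  500 ms with probability `1 - occlusion_prob` (default 0.2), with a
  bounding box drawn stochastically larger (width/height 0.25–0.45) than
  background false faces (0.04–0.12) — box area is the proxy for proximity,
  without simulating geometry. Research-staff faces appear occasionally and
  carry an `other_adult` identity match; ingest must remove them. Teacher
  faces carry identity matches with similarity 93–100 against the 92
  threshold.
* **Speech.** Utterances are placed inside intervals (partner CDS, and
  focal-child speech with probability `focal_speech_prob` per slot) and
  outside them (background, non-CDS, `bg_speech_rate` per minute) with
  words drawn Zipf-weighted from a finite vocabulary that includes common
  contractions. Loudness is emitted directly as a numeric channel, higher
  inside interactions (acoustic proximity); no audio is synthesized.
* **ASR corruption.** The reference transcript is thinned word-wise:
  deletion with probability `wer_del` (default 0.3), substitution with
  `wer_sub` (default 0.1, with lowered confidence), so raw automatic counts
  underestimate the reference — the bias the OLP calibration exists to
  remove.
* **Determinism.** All randomness derives from one master seed through a
  fixed per-stream derivation (`derive_seed`); identical seeds give
  byte-identical sessions, and cohort children get independent derived
  seeds.

What the generator does **not** emulate: real ASR error structure
(insertions, confusions correlated with acoustics), face-detector failure
modes other than dropout, pose dynamics, and children moving between
partners mid-utterance. Passing tests therefore demonstrate correctness of
the pipeline's logic and its statistical machinery under the stated
generative assumptions — not field performance on real recordings.

## Feature building

The detector consumes a fixed-rate series of 15 channels per 250 ms bin:
six facial features (box area, yaw, roll, pitch, mouth-open and eyes-open
confidence) for the most representative adult face, the same six for the
most representative peer face, and three audio channels (speech-activity
Boolean, segment word confidence, loudness). "Most representative" is the
largest box per class per frame, ties broken by input order.

Processing order is fixed: **rasterize → infill → clip → normalize**.

* *Rasterize*: each face sample fills the bins its 500 ms window covers;
  bins without a face carry gap markers. Speech channels are broadcast from
  the covering utterance and are 0 (never gap) elsewhere.
* *Infill* (`infill_moving_average`, window 5 bins = 1.25 s): maximal gap
  runs no longer than the window — occlusion dropouts — are filled with the
  centered moving average of observed neighbors; longer absences are set to
  0, the face-absent baseline. Extending the last seen face across a long
  absence would fabricate proximity for the whole out-of-interaction
  region, so absence is kept informative.
* *Clip* (`clip_outliers`): per channel, values above the 0.99 quantile are
  set to that quantile. Upper tail only; Boolean channels untouched.
* *Normalize* (`fit_normalize` / `apply_normalize`): z-scoring with
  statistics pooled over **training sessions only**; constant channels pass
  through. Held-out children are always normalized with their fold's
  training statistics — the LOSO harness enforces this and the tests probe
  it by perturbation.

Clipping uses per-session quantiles (it is a robustness device, not a
learned statistic), so it cannot leak across folds.

## The detector

`detector_spec()` defaults to a bi-directional LSTM with 200 hidden units
per direction — the architecture class routinely used for voice-activity
and wearable-sensor sequence labeling — with a per-timestep softmax over
interaction/not-interaction, 30 training epochs, and one classifier per
partner class (adult and peer interactions differ enough in frequency and
duration that separate models work better than a shared one). The *full* feature set is all 15 channels; the *reduced* set
is the detector's own partner-class face area plus speech activity,
mimicking a proximity sensor. The recurrent core (forward pass and
backpropagation through time) is implemented in C++ (RcppArmadillo) and
verified against finite-difference gradients in the test suite; the
optimizer is Adam with one update per training sequence in fixed order, so
training is deterministic given the seed. The optimizer settings (learning
rate 0.02, gradient-norm clip 5, forget-gate bias 1) are package choices
recorded in the spec object.

Raw per-bin predictions are post-processed by `smooth_track`: gaps shorter
than one second are merged first, then intervals shorter than one second
are deleted. Sub-second spurious predictions could in principle be handled
by merging or by deletion in either order; merge-gaps-then-delete-intervals
is the ordering that is idempotent and leaves no sub-second structure of
either kind, and both properties are tested on random tracks.

**Problem sizes.** Tests and the acceptance script train at desk scale — 16
hidden units, 6–10 epochs, learning rate 0.05 — which recovers a separable
13-child, 40-minute cohort to F1 ≈ 100 in minutes on one core. The
200-unit architecture remains the `detector_spec()` default for users who
want it; nothing in the code depends on the smaller size.

## Diarization and measures

An utterance intersecting (positive overlap, half-open intervals) the adult
track is adult-CDS; otherwise intersecting the peer track, peer-CDS;
otherwise non-CDS. Simultaneous overlap goes to the adult. The rule is
purely temporal — an utterance's speaker label does not constrain its CDS
class — and whole utterances are labeled, never split at interval
boundaries. Focal-child utterances are partitioned the same way into
directed-to-adult / directed-to-peer, and focal speech outside any
interaction is excluded from measures.

Tokenization lowercases, strips punctuation, and expands contractions
("you're" → "you are") from a fixed shipped table (`contraction_table()`)
plus regular-suffix rules; a trailing `'s` outside the table is treated as
possessive and dropped. MLU and TTR are computed from raw counts — they are
scale-free ratios, so norming them would change nothing if applied
consistently and corrupt them if applied to numerator or denominator alone.
Counts (TNU, TNW, NDW, interaction frequency) are normed by
`10 / recording_minutes`; durations are not normed, being lengths rather
than counts. Zero-utterance classes yield count 0 and explicit `NA` (never
0) for MLU/TTR; children with a zero reference value for a measure are
excluded from that measure's error summaries, since a relative error
against zero is undefined.

## Evaluation and calibration

Detection quality is scored at the 250 ms sample level (accuracy,
precision, recall, F1 on a 0–100 scale) against the reference track.
Measure agreement uses the absolute relative error
`ARE = |X_ref − X_pred| / X_ref · 100` per child, summarized by its median
(mARE) and by the signed mean relative error
`MRE = mean((X_pred − X_ref)/X_ref · 100)`, negative meaning
underestimation, plus the Pearson correlation across children.

OLP (reduced major axis) calibration fits
`slope = sign(r)·sd(y)/sd(x)`, `intercept = mean(y) − slope·mean(x)` of
reference on raw values, per measure, on the training fold, and maps the
held-out child's raw value through it. Under pure word deletion at rate
`d` the raw TNW is approximately `(1−d)·TNW_ref`, so the fitted slope
concentrates on `1/(1−d)` — the package's calibration-recovery test checks
exactly this at `d = 0.3` over 200 corruption replicates, and that adapted
mARE falls strictly below raw mARE for the count measures.

Degenerate cases: fits require at least 3 complete pairs; zero variance
falls back to an identity calibration with a warning; correlations need at
least two complete pairs with positive variance.

## Numerical and design choices

* All timestamps are integer milliseconds; all intervals are half-open
  `[onset, offset)`; overlap requires strictly positive length, so
  boundary touching never counts.
* Bin `b` covers `[(b−1)·250, b·250)` ms and takes label 1 if any part of
  it lies in an interval.
* Representative-face ties break to the earliest detection in input order;
  same-class interval overlaps merge, with touching intervals coalescing.
* Unmatched faces (below the 92 similarity threshold, or no identity
  record) default to class *peer* — the classroom is child-dominated — and
  the threshold, timestamp tolerance (250 ms) and IoU minimum (0.5) for
  detection/match alignment are configurable; faces resolved to
  `other_adult` identities are dropped entirely.
* Loudness is consumed as data (pass-through channel); when absent, a
  documented energy proxy `(mean(x²))^0.3` is applied. No ISO-style
  psychoacoustic model is computed.
* Per-class presence masks are not part of the default feature set (the
  detector sees exactly the 12 facial + 3 audio channels).

## Known limitations

* The simulator's separability is optimistic: grid-aligned boundaries and
  clean face/box statistics have no real-data counterpart, so detector
  scores here are upper bounds, not forecasts.
* Speaker classes on ASR segments are taken as given (in the emulated
  deployment they come from manual labeling); no speaker recognition is
  attempted.
* Word-level accuracy is not modeled finely enough to support grammatical
  complexity measures beyond MLU.
* Architecture search for the recurrent classifier is out of scope; the
  desk-scale defaults are chosen for reproducibility, not optimality.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)
study <- run_study(cfg, n_children = 13)
study$detect_report    # LOSO detector means per partner class
study$measure_report   # mARE / MRE / r, raw vs OLP-adapted, per measure
write_study_report(study, "report.csv")
```

`scripts/acceptance.R` performs exactly this run from a command-line seed
and writes the headline quantities as JSON.
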