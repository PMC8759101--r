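---
title: "Classifying eye and head movements from HMD eye tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying eye and head movements from HMD eye tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazevr)
```

## The problem

Eye-tracking head-mounted displays record two coupled movement systems at
once: the eye rotating in the head and the head rotating in the world.
Their composition — the world-frame line of sight, or *gaze* — is what
actually samples the visual scene. Classifiers developed for
head-fixed, screen-based experiments only see eye-in-head velocity, so
they confuse vestibulo-ocular stabilisation with pursuit and miss
head-driven gaze shifts entirely. `gazevr` implements a
velocity-threshold pipeline designed for free head movement, together
with two validation surfaces: a synthetic session generator with
per-sample ground truth, and ray-cast foveated-object labels derived
from the known positions of objects in the virtual scene.

Three speeds drive everything (all in deg/s):

* **eye speed** — angular velocity of the eye relative to the head;
* **head speed** — angular velocity of the head relative to the world;
* **gaze speed** — angular velocity of the composed line of sight,
  computed from the head rotation applied to the eye direction (a
  composition of rotations, not a sum of speeds).

## The classification model

**Preprocessing.** Samples without a valid pupil measurement, plus a
40 ms guard band on each side, are noise and take no further part
(`mask_invalid()`). The guard band is implemented as
`ceiling(0.040 * fs)` samples per side — 5 samples at 120 Hz, so one
isolated invalid sample removes 11. Speeds are backward differences
assigned to the later sample (the first copies the second) and smoothed
with a five-sample (40 ms) running median; at the edges of the stream
the median window shrinks symmetrically rather than inventing padding
values.

**Head-speed scaling.** Every eye/gaze threshold is scaled by the
instantaneous head speed,

$$\theta_{\text{scaled}} = \left(1 + \frac{v_{\text{head}}}{60}\right)\theta,$$

so that a head turning at 60 deg/s doubles the threshold. This absorbs
the eye-in-head velocity that head rotation itself induces. The head
threshold (7 deg/s) is deliberately *not* scaled — scaling a head
threshold by head speed would be self-referential.

**Saccades first.** A saccade is any maximal run of usable samples
whose eye speed exceeds the scaled 35 deg/s threshold for at least
20 ms (a sample contributes one sampling interval, so 3 samples at
120 Hz count as 25 ms). Runs broken by noise are never bridged. For
analysis, only saccades over 3° in amplitude with peak velocity under
1,000 deg/s are kept; the rest are relabelled `excluded_saccade` but
still delimit intervals. Amplitude is measured on the world-frame gaze
direction across the run plus one bracketing usable sample per side:
the detected run covers only the above-threshold core of the movement,
and the brackets recover its sub-threshold onset and offset (without
them a scripted 10° saccade measures ~9.3°; with them ~9.9°).

**Epochs.** Intersaccadic intervals are tiled left-to-right with 100 ms
epochs. A trailing remainder of at least 50 ms becomes its own short
epoch; smaller remainders merge into the preceding epoch; an isolated
fragment under 50 ms is `unclassified`. Each epoch is labelled from its
mean filtered speeds by a fixed decision tree:

| gaze vs scaled 10 | eye vs scaled 10 | head vs 7 | label |
|---|---|---|---|
| below | — | below | fixation |
| below | — | above | VOR |
| above | below | — | head pursuit |
| above | above | below | smooth pursuit |
| above | above | above | smooth pursuit + VOR |

Ties at exact threshold equality resolve to the "slower" branch
(fixation / VOR / head pursuit), a deterministic choice on a
measure-zero boundary. Epoch statistics are means of the filtered
speeds over the epoch's samples; scaling inside saccade detection uses
the per-sample head speed, inside epoch classification the epoch-mean
head speed (per-time-point versus per-window decisions).

The low-eye threshold separating head pursuit from the other pursuit
labels defaults to 10 deg/s and scales like the gaze threshold; it is
configurable in `threshold_set()`. An optional high-gaze threshold
field is carried in the configuration but unused by the default tree.

## The synthetic paradigm

`build_schedule()` and `simulate_session()` emulate a cued
two-alternative discrimination task: 288 trials in 6 blocks of 48, two
blocks per condition (Static cued at 13 m, Static at 32 m, Dynamic),
cues on two concentric disk rings at 6 dva (parafoveal) and 20 dva
(peripheral) eccentricity, SOA uniform on 0.6–1.6 s, target shown for
1 s, cue-to-cue spacing uniform on 5.4–7.4 s (6.4 s mean), balanced
left/right targets, diametric distractors, and block order
counterbalanced by a Latin square over the participant index. In
Dynamic trials the observer translates forward at 5 m/s through
world-fixed disks cued at 32 m, so a disk's eccentricity and angular
speed grow as it approaches — parafoveal disks stay slow (a few deg/s)
while peripheral disks eventually exceed the 10 deg/s "moving gaze"
threshold. This asymmetry is the whole point of the design: it produces
pursuit that a fixed-threshold classifier can and cannot see.

Each trial is scripted in azimuth/elevation space: cross fixation; a
cue-triggered saccade whose latency is normal (mean 200 ms, SD 30 ms)
and whose velocity profile is a raised cosine with main-sequence peak
$v_{\max}(1 - e^{-A/c})$ ($v_{\max}=500$ deg/s, $c=14°$ — the
saturating form is this package's parameterisation; the functional
choice is conventional, not fitted); gain-0.95 pursuit (dynamic) or
fixation (static) on the disk; a button response ~550 ms after target
onset; and a return saccade. For peripheral targets the head carries
30% of the gaze shift as a minimum-jerk rotation timed so head speed
peaks 200 ms after the saccadic peak, with the eye counter-rotating
(VOR gain 0.95, retinal slip proportional to head velocity).
Fixational jitter is low-passed white angular noise rescaled so
fixation eye speed averages 2 deg/s, safely below every threshold.
Tracker dropout is emulated as contiguous invalid bursts (geometric
lengths, mean 3 samples) with onset probability solved so the expected
invalid fraction equals the 6% default. All randomness flows from one
seed.

**Ground truth is kinematic.** Per-sample labels are the noiseless
generated speed traces passed through the same decision boundaries at
sample resolution (`classify_samples()`). Slow pursuit of a parafoveal
dynamic target is therefore *truly* near-fixation by the taxonomy's own
definitions; whether the eye is on a moving object is tracked
separately in the ground-truth `object` column and via ray-casting.
This separation is what lets the pipeline both score high label
agreement *and* reproduce the central negative finding below.

## What the validation computes

`raycast_series()` intersects the world-frame gaze ray with the scene
(spheres at the cross and every disk; nearest hit wins; invalid samples
get no label). `pursuit_validation()` then reports the percentage of
on-object usable samples labelled as pursuit, split by stationary
objects (cross, static-trial disks) versus moving objects
(dynamic-trial disks) and by eccentricity — pursuit labels on
stationary objects are false positives, on moving objects they are the
detection rate. `target_interval_gaze_speed()` reproduces the follow-up
analysis: per trial, the longest intersaccadic interval whose modal
ray-cast label is the cued disk, averaging gaze speed over its usable
samples after dropping samples with eye speed above 20 deg/s (catch-up
saccade remnants). `reaction_times()` yields saccadic RT (first
included saccade after cue), button RT (first response between target
and next cue) and disengagement time (first post-target departure of
the ray-cast label from the cued disk).

On a full default session the pipeline recovers ~99% per-sample label
agreement, 100% of dropout-free true saccades ≥ 3°, a valid-sample
fraction of ~94%, and — the key qualitative result — smooth-pursuit
labelling of ~30% on dynamic peripheral disks versus ~10% on dynamic
parafoveal disks (mean on-target gaze speeds ~8 vs ~4.6 deg/s), with
~0.2% false pursuit on stationary objects. These numbers are computed,
not asserted: `scripts/acceptance.R` regenerates them from scratch.

## Numerical and design choices

* **Differentiation.** Plain backward differences; no Savitzky–Golay
  or model-based filtering. The median filter is the only smoothing,
  matching the pipeline the classifier assumes.
* **Angles.** Angles between unit vectors use `2*asin(|u-v|/2)`,
  which is well conditioned near zero where `acos` is not. Quaternion
  geodesics take `|<q1,q2>|`, so the sign ambiguity of the double cover
  never produces spurious head speed.
* **Guard band rounding.** `ceiling(pad * fs)` samples per side; at
  120 Hz this pads 41.7 ms rather than exactly 40 ms. The alternative
  (floor) under-covers; one sample of over-coverage is the conservative
  choice.
* **Epoch remainders.** The 50% rule (keep ≥ 50 ms, merge < 50 ms) is
  this package's convention; abutting, non-overlapping epochs are
  assumed.
* **Degenerate inputs.** Recordings shorter than 2 samples, duplicate
  timestamps, non-monotone time and zero-norm directions are hard
  errors; empty speed series classify to an empty segment table.
* **Evaluation conditioning.** Saccade recovery is scored over true
  saccades whose samples are all usable. A saccade coinciding with a
  dropout burst is unrecoverable *by construction*, because detection
  never bridges unusable samples; scoring it would measure the dropout
  process, not the detector. The unconditioned rate (~85% at default
  dropout) is also available via `require_usable = FALSE`.

## What the generator does not emulate

* Real pursuit contains catch-up saccades, anticipatory drift and
  gain fluctuations; the generator's velocity-gain pursuit is smooth,
  so pursuit-phase classification on real data will be noisier than the
  synthetic benchmarks suggest.
* Head movements in real data accompany pursuit and spontaneous
  re-orienting, not only cued gaze shifts; head-pursuit and
  pursuit-with-VOR epochs are therefore rarer in synthetic sessions
  than in unconstrained recordings.
* Dynamic-trial disengagement is late in the generator (the disk is
  tracked until it comes within ~6–7 m) so that on-target intervals
  span the slow-to-fast angular-speed regime the paradigm was built to
  probe. Human observers disengage moving targets *earlier*; the
  generator trades that fidelity for coverage of the speed regime, and
  disengagement-time comparisons across motion conditions should not be
  read as behaviourally realistic.
* Calibration error, vergence, torsion and pupil dynamics are not
  modelled (pupil diameter is a constant); sample validity is the only
  data-quality axis.

Passing tests on synthetic sessions therefore demonstrate that the
pipeline implements its stated decision rules correctly and recovers
movements generated under its own kinematic assumptions — not that
those thresholds are optimal for any particular real dataset.

## Problem sizes used in the shipped checks

The test suite and acceptance script run the full 288-trial session
(~220k samples at 120 Hz, ~31 min of simulated recording) twice — once
noiseless, once at default noise and dropout — plus 1,000 random traces
of up to 2,000 samples for the detector-versus-oracle equivalence
check. The complete pipeline on a full session (simulation,
classification, ray-casting, validation) takes a few seconds on one
CPU.
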