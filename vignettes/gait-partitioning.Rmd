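---
title: "Four-phase gait partitioning: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-phase gait partitioning: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitphase)
```

This vignette is the package's own account of the science it implements:
the four-phase model of the gait cycle, the reference labeling from
footswitches, the two threshold detectors and two hidden-Markov-model
segmenters, the evaluation metrics, and the Gait Phases Quality Index —
together with the modelling assumptions, the tunable parameters and the
design decisions taken where the methodology left room.

## The four-phase model and its reference

A gait cycle runs from one heel strike (HS) to the next of the same foot
and is partitioned into loading response (LR), flat foot (FF), pre-swing
(PS) and swing (Sw), delimited by the events HS, toe strike (TS), heel
off (HO) and toe off (TO). The reference sequence comes from four
footswitches per foot (heel, first and fifth metatarsophalangeal, toe):

* LR — only the heel switch closed;
* FF — all four closed;
* PS — at least one forefoot switch closed;
* Sw — none closed.

Taken literally, the FF condition implies the PS condition, so the rules
are applied with FF checked first: "all closed" is the more specific
state. A sample with heel plus a *partial* forefoot contact satisfies
neither the LR rule ("only heel") nor FF, and falls to PS. Runs shorter
than the debounce window (default 20 ms; footswitch conditioning was a
free choice, so it is a configuration knob) are merged into the
preceding phase. Analog force channels are binarized at 10% of each
channel's robust maximum (95th percentile), a threshold that clears the
open-channel noise floor by a wide margin while catching partial
contacts.

All streams are brought to a common 200 Hz grid: linear interpolation
for analog channels, zero-order hold for binarized contacts (so they
stay binary). Strides are delimited by Sw→LR transitions; the first and
last three cycles of a trial are discarded to avoid gait initiation and
termination effects, and strides whose internal order is not exactly
LR, FF, PS, Sw are excluded from percentage statistics (their events
remain in the stream for transition-level evaluation — the two analyses
consume different aspects of the sequence).

## Threshold detectors

**Gyroscope (S-method).** After a 2nd-order zero-phase Butterworth
low-pass at 15 Hz, cycles are anchored at positive mid-swing peaks
(≥ 50 °/s, a working definition for a quantity the methodology names but
does not define). Within a cycle, the longest run with |ω| below the
30 °/s stasis threshold is the flat-foot core; HO is the first sample
beyond it, TO the most negative extremum before the next mid-swing peak,
HS the negative trough after the peak — the "second clockwise maximum",
counting TO as the first — and TS the first sample after HS whose |ω|
stays below threshold for at least 40 ms.

**Accelerometer (R-method).** The detector works on the Euclidean
resultant of the two sagittal-plane accelerometer axes, which includes
gravity: a resting foot reads 9.81 m/s². Five signals are derived: the
6 Hz-filtered resultant (c50), its first and second central-difference
derivatives (d1, d2), and moving averages over 1.25 s (cA200) and 0.30 s
(cA50). The published description of this detector is a summary rather
than an algorithm; the concrete rule set here is a documented
interpretation, validated only against the synthetic generator:

1. flat-foot cores are runs (≥ 100 ms, with gaps ≤ 80 ms closed) where
   |c50 − cA200| < 1.0 m/s² and |d1| < 5 m/s³;
2. HO is the first steep-rise inflection (d2 zero crossing with
   d1 > 5 m/s³) within 250 ms after a core — if none exists the foot
   never lifted and no events are emitted;
3. TO is the descent inflection after the first turning point of c50
   exceeding cA50 (the push-off peak);
4. HS is the largest turning point above cA50 before the next core;
5. TS is the subsequent downward crossing of c50 below cA50 (impact
   transient over).

The band and slope tolerances started from tighter values (0.5 m/s²,
2 m/s³) but those cannot close a quiescent interval even on noiseless
data: impact and push-off transients keep the 1.25 s average about
0.5 m/s² above gravity, so the band must accommodate that standing
offset. The widened defaults are set from the flat-foot statistics of
the generator at its nominal noise level.

## The hidden Markov segmenters

The HMM is scalar and continuous: the observation is the 17 Hz-filtered
sagittal angular velocity, one state per phase. The transition matrix is
left-right and **cyclic** — state i may only persist or advance to its
successor, with Sw→LR closing the loop. The cited lineage of this model
is per-stride left-right; the cyclic closure is this package's choice so
that whole multi-stride trials decode in one pass. The initial
distribution is uniform over the four phases and is *not* re-estimated:
a trial may begin anywhere in the cycle, and the flat prior encodes
exactly that.

Supervised initialization takes per-phase moment estimates (for
mixtures, a k-means split of the phase's samples, seeded
deterministically on the quantiles) and sets each self-transition to
1 − 1/d̄, the geometric match to the mean phase dwell d̄ in samples.
Baum-Welch then runs with scaled forward-backward recursions (stable for
trials of tens of thousands of samples), re-imposing the structural
zeros and the emission-SD floor at every M-step. Convergence is declared
when the log-likelihood moves by less than `tol` (default 1e-4), with
`max_iter` as a guard. Viterbi decoding runs in log space with ties
broken toward the lower state index for determinism;
`decode_online()` provides the causal forward-filtering approximation
(argmax of the filtered posterior), which agrees with Viterbi on ≥ 95%
of samples on clean data and is the variant suited to real-time use.

Two deployments mirror clinical practice: `train_sst()` trains on two of
a subject's three trials and decodes the held-out one, rotating folds;
`train_spt()` pools a labeled control group once and transfers to any
test trial without retraining.

**Emission defaults.** Two defaults deviate from the minimal scalar-HMM
setup and deserve justification. First, `n_mix = 3`: the
phase-conditional distribution of angular velocity is strongly
multimodal — swing spans a 400 °/s plateau, a rise and a fall; pre-swing
spans a deep trough and its shoulders — and a single Gaussian per state
places the Viterbi boundary tens of milliseconds away from the contact
events. Three components per state recover the boundaries to within the
evaluation tolerance. Second, `sd_floor = 6` °/s: the floor exists to
prevent variance collapse on the quasi-constant flat-foot segment, but
it also encodes the measurement noise scale. A 1 °/s floor makes the FF
state overconfident relative to the ~5 °/s sensor/artifact noise, again
biasing boundaries; the default sits at the noise scale. Both remain
arguments (`n_mix` from 1 to 3, any positive floor).

## Evaluation

Transition-level scoring uses a 60 ms window centered on each reference
transition (±30 ms). Predictions are matched one-to-one within event
type, greedily by ascending time distance with ties to the earlier
prediction, so multiple predictions cannot share a window. TP/FP/FN
follow from the matching; TN is counted at sample level — samples
outside every window carrying no predicted transition — which is the
choice that gives TNR a well-defined denominator; because that
denominator is large, TNR is generous and G is in practice driven by
sensitivity. Pooled counts are reported, with a per-type breakdown
attached. The goodness index G = √((1−TNR)² + (1−TPR)²) classifies
performance as optimum (≤ 0.25), good (≤ 0.7) or random.

Phase-percentage errors compare trial-mean percentages per phase. GPQI
is implemented exactly as its formula is printed — the *sum over the two
sides* of the 4-D Euclidean distances to the control-group means — even
though the accompanying prose describes a single Euclidean distance; the
formula wins and the discrepancy is noted here. The default basis is the
trial mean (the formula carries no stride index); a per-stride basis
with temporal pairing of left and right strides is provided because the
GPQI *error* is described per stride. The bundled reference
distribution is (6.9, 39.4, 16.2, 37.7)%, which sums to 100.2 — printed
rounding — so validators accept a quarter point of slack around 100.
ICC(3,k) uses the two-way consistency, average-measures definition
(MS_subjects − MS_error)/MS_subjects; SEM = SD·√(1−ICC) with SD the
between-subject SD of trial means, and MDC95 = 1.96·√2·SEM. AUC uses
the rank-sum identity with ties counted half.

## The synthetic generator

`generate_trial()` emulates one foot's IMU (50 Hz) and footswitch
(2000 Hz) streams with exact ground truth. Per stride, a duration and a
phase-fraction 4-vector are drawn (Gaussian jitter, renormalized to
100%), events are laid out, and the sagittal angular velocity is built
from asymmetric generalized-Gaussian bumps: a fast foot-slap trough
whose peak lags initial contact by 5 ms, a V-shaped push-off trough at
toe off, and a swing plateau rising immediately after toe off and
collapsing just before the next contact. The bump widths on the sides
facing flat foot are *solved* so that |ω| crosses the 30 °/s stasis
level at the true TS and HO instants, with steepened (quartic) tails so
the flat-foot interior stays below 10 °/s — the template honors the
assumptions the detectors rely on, by construction. The acceleration
norm shows an impact spike at HS, gravity during FF, a heel-lift rise at
HO and a push-off peak near TO. Footswitch channels follow the contact
logic exactly before optional chatter noise (independent short flips
within 3 samples of contact edges, for debounce testing).

Default study conditions: healthy phase fractions (6.9, 39.4, 16.2,
37.7)% with per-phase jitter SDs (0.7, 2.3, 1.8, 0.9)% taken from the
published control-group spread; stride time 1.1 ± 0.03 s; gyroscope
noise 5 °/s (motion artifact dominates the sensor floor); accelerometer
noise 0.08 m/s² (a flat foot is genuinely still, so the MEMS noise
scale applies); peak amplitudes (100, 200, 400) °/s for slap, push-off
and mid-swing. The parkinsonian presets shift mass into flat foot —
`pd_mild` (6.9, 43.4, 14.2, 35.7)%, `pd_severe` (8, 48, 12, 32)% with
slower strides, attenuated peaks and a 15 °/s tremor sinusoid at 5 Hz
(the canonical parkinsonian rest-tremor band). No patient-specific
phase-distribution values were published; the presets are plausibility
fixtures for benchmarking, not claims about patients.

**What passing tests show — and what they do not.** The generator
provides known ground truth, controllable noise and the contact logic of
the reference instrumentation, so closed-loop tests demonstrate internal
consistency: each detector recovers the events its assumptions encode,
the HMM learns and decodes the phase structure, the metrics count what
they claim to count. The generator does **not** emulate turning,
freezing-of-gait episodes, festination, sensor misalignment, soft-tissue
artifact or biomechanically exact kinematics; performance numbers on
synthetic cohorts therefore bound what the code does under its stated
assumptions and are not clinical accuracy claims.

## Numerical choices and degenerate inputs

* Zero-phase filtering is the offline default (no group delay, so event
  timing is unbiased; the effective order doubles). Odd-symmetric end
  padding suppresses the start-up transient. A causal option exists for
  streaming.
* Moving averages use a centered window with truncation at the edges, so
  constants pass through unchanged.
* Resampling covers the original span; zero-order hold preserves binary
  values exactly.
* The sagittal gyroscope axis defaults to the maximal-variance axis over
  the trial (valid during straight walking); `flip_sign` accommodates
  opposite-handed mountings.
* A constant signal yields an empty phase sequence with a warning from
  either detector (no mid-swing peak / no heel lift); degenerate
  likelihoods in Baum-Welch raise an error naming the iteration; an
  all-equal reliability matrix returns ICC = 1 with SEM = 0 by
  definition.
* Sub-seeds for cohort simulation are derived from the master seed with
  modular arithmetic kept inside the 32-bit integer range.

## Problem sizes

The bundled benchmark (`benchmark_healthy_cohort()`, also used by
`scripts/acceptance.R`) simulates 20 healthy trials of 30 strides
(about 33 s each): 10 train / 10 test for the control-group HMM, five
3-trial subjects for the leave-one-trial-out HMM. Baum-Welch refinement
within the cohort harnesses is capped at 25 iterations — decoding
accuracy plateaus well before the 1e-4 log-likelihood tolerance
triggers on sequences of this length, and the cap keeps the benchmark
proportionate. The test suite uses 8-15-stride trials for the same
reason.

## Known limitations

* The R-method rule set is an interpretation of a prose summary; it is
  validated against the generator only and flagged as such.
* The HMM decodes whole trials; it does not handle pauses mid-trial
  (the cyclic topology will keep advancing phases).
* Left/right are evaluated separately and the stride pairing for
  per-stride GPQI is temporal-index based — the methodology never
  states a pairing.
* GPQI depends on a control-group reference; transferring the bundled
  reference to populations with different instrumentation or walking
  protocols is untested.
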