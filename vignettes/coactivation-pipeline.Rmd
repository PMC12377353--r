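---
title: "Phase-resolved coactivation analysis of rhythmic elbow movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-resolved coactivation analysis of rhythmic elbow movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coactr)
```

## The measurement problem

During a voluntary movement the muscle opposing it (the antagonist) is
rarely silent: it co-contracts to stabilize the joint, brake the limb
against gravity, and shape the end of the movement. In healthy adults this
coactivation is small and phase-dependent; in spasticity it is exaggerated
or mistimed. `coactr` quantifies this from a minimal recording setup —
two surface EMG channels (biceps brachii, triceps brachii; 1,024 Hz) and an
IMU-derived elbow angle (20 Hz) — during metronome-paced elbow
flexion–extension (FE).

Four metrics are produced per trial: range of motion (ROM) and angular
velocity with their across-cycle variability; the coactivation coefficient
(CC); and muscle-synergy area shares. A factorial layer tests how CC
depends on movement phase and metronome speed.

## Signal model and conditioning chain

The sEMG is modelled as a zero-mean interference signal whose amplitude is
proportional to muscle activation. The conditioning chain estimates that
amplitude envelope:

1. **Band-pass**: fourth-order Butterworth, 20–450 Hz, applied forward and
   backward (`signal::filtfilt`). Zero-phase filtering matters because the
   envelope is later integrated over phase windows defined on the
   simultaneously recorded angle; a causal filter would delay the EMG
   relative to the kinematics. The analysis is offline, so non-causality
   costs nothing.
2. **Block RMS**: non-overlapping 0.25 s windows. Hop = window is what maps
   a 0.25 s window onto a 4 Hz envelope at any EMG rate; each envelope
   sample is timestamped at its block centre.
3. **Oversampling**: linear interpolation of the 4 Hz envelope onto the
   20 Hz angle grid (values held constant beyond the first/last block
   centre). A zero-order hold is available via
   `pipeline_config(interp = "constant")`. Linear interpolation is the
   simplest monotone scheme and reproduces linear trends exactly.
4. **Baseline correction**: 30 envelope samples centred on the global
   envelope minimum (shifted, not truncated, at record edges); offset =
   window mean − 3 × window SD; the offset is subtracted and negative
   residuals are clamped to zero. The offset itself is additionally clamped
   at zero: on a continuously cyclic record with no rest period the window
   around the minimum can straddle activity bursts, making mean − 3·SD
   negative, and a baseline step must never *add* activity. The 30 samples
   are taken on the 20 Hz oversampled stream (1.5 s), the stream all
   downstream metrics consume.
5. **Normalization**: division by the recording's own contraction peak, per
   muscle and per recording. This deliberately avoids a
   maximum-voluntary-contraction reference, which is impractical in the
   clinical populations the metrics target; the cost is that CC compares
   *relative* activation shapes, not absolute effort. An all-zero envelope
   passes through unchanged.

The chain is stage-typed (`rms → oversampled → baseline_corrected →
normalized`) and out-of-order calls are rejected, so a result can always be
traced to a fully conditioned envelope. The normalized envelope is
invariant to positive rescaling of the raw signal (amplifier gain does not
matter).

## Kinematic segmentation

Angular velocity is the time derivative of the angle (central differences
inside, one-sided at the edges). Flexion peaks — local maxima with
topographic prominence of at least 20% of the trace's range, separated by
at least half the nominal cycle period when the metronome rate is known —
delimit cycles. Recordings begin at the prescribed maximum-flexion posture,
so the opening sample counts as a peak when the record starts descending;
a record that ends mid-rise contributes no final peak, and only complete
peak-to-peak cycles enter the metrics (ten metronome cycles therefore yield
nine analysed cycles). Plateaus and ties resolve to their earliest sample,
which keeps segmentation deterministic.

Within a cycle, the extension trough (minimum angle) splits the two
half-movements, and each half is split at its interior velocity extremum:
acceleration runs from the angle extremum to peak angular speed,
deceleration from peak speed to the next angle extremum. The four phases
(`acc_ext, dec_ext, acc_flex, dec_flex`) tile the cycle exactly — no gaps,
no overlaps — so phase-wise integrals sum to cycle integrals. Half-cycles
with no interior velocity extremum (fewer than ~3 samples) are degenerate
and excluded with a warning.

ROM is summarized as the mean flexion-peak and extension-trough angle over
the cycle boundaries; execution variability as the across-cycle SD of the
angle and velocity profiles after resampling every cycle onto a common
100-point normalized-time grid and averaging the point-wise SD. The
100-point grid is a reporting convention: any grid dense relative to the
~30–60 samples of a cycle gives the same summary to well under a degree.

## Coactivation and synergy

The coactivation coefficient on a segment is

$$CC = 2\,\frac{\int \min(Ag, Antag)}{\int Ag + \int Antag} \cdot 100,$$

the common-area formulation: the numerator integrates the pointwise minimum
of the two envelopes. CC is 0 for disjoint activation, 100 for identical
envelopes, symmetric in its arguments, and invariant to a common rescaling.
Integrals use the trapezoidal rule on the 20 Hz grid; each phase interval
`[start, end)` is integrated over the closed sample span, so the four phase
integrals reconstruct the cycle integral exactly. A segment in which both
envelopes are identically zero is defined to have CC = 0 so that quiet
phases do not poison aggregates. The biceps is labelled agonist during
flexion and the triceps during extension; the labelling affects reporting
only.

Muscle synergy is an area-share statistic (not a factorization-based
synergy): for each muscle and cycle, the percentage of its envelope area in
flexion versus extension phases (summing to 100 per muscle). Because "share
of activation per phase" admits a second reading, a between-muscle
decomposition —
each muscle's share of the summed activity within the flexion and within
the extension phases — is also returned (`within_phase`); the per-muscle
variant is the default reporting surface. A muscle with zero cycle area has
undefined (`NA`) shares.

## Factorial analysis

The observational unit for the ANOVA is the mean CC per
subject × speed × phase cell; a 20-subject, 3-speed design gives 240 rows.
`two_way_anova()` fits `cc ~ phase * speed` with Type-II sums of squares
(robust to the mild imbalance left by discarded cycles; identical to
Type I/III when balanced). An effect with zero SS reports F = 0, p = 1 by
convention, even on a degenerate all-equal dataset. Tukey HSD compares the
levels of one factor with the other pooled — the intended use is after a
non-significant companion effect — with group sizes taken from the data.

Cohen's f defaults to the partial-η² form
`f = sqrt(SS_effect / SS_error)`; a total-η² variant is available, and the
variant used is recorded in the result because published values do not
always state theirs and the two differ noticeably when other factors absorb
variance. Magnitude labels use lower-inclusive intervals: `[0.10, 0.25)`
small, `[0.25, 0.40)` medium, `≥ 0.40` large.

## The synthetic-data generator

`simulate_trial()` builds trials with known ground truth:

- **Timing**: one metronome beat per half-cycle (flexion on one beat,
  extension on the next), so a full cycle lasts `2·60/bpm` s. Metronome
  protocols of this kind prescribe beat rates (42/60/78 bpm here), not cycle
  periods; this mapping is a declared convention chosen because it yields peak angular velocities
  (~150–300 °/s) in the physiologically plausible range for paced elbow FE.
  Half-cycle durations are jittered multiplicatively (CV 0.05 by default)
  to emulate imperfect metronome tracking.
- **Angle**: raised-cosine half-cycles between +75° and −60°, starting at
  maximum flexion; smooth, zero endpoint velocity, unimodal speed profile
  — the idealized shape of a paced single-joint movement. The sampling grid
  is half-open, so the final return to peak flexion is not itself sampled.
- **Activation**: each half-cycle carries a raised-cosine agonist burst
  (width = the whole half-cycle by default); the antagonist mirrors the
  agonist profile scaled by a per-phase fraction, and the triceps adds a
  small tonic offset (0.02) emulating gravity compensation. The default
  fractions (0.13/0.19/0.11/0.16 for acc_flex/dec_flex/acc_ext/dec_ext)
  come from the closed-form algebra `CC = 200f/(1+f)` and reproduce the
  healthy-adult phase ordering: flexion deceleration highest, extension
  acceleration lowest.
- **Raw EMG**: Gaussian noise band-passed to 20–450 Hz, normalized to unit
  RMS, amplitude-modulated by the activation envelope. The carrier matches
  the analysis pass-band so the filtering stage is near-transparent, which
  isolates the envelope-estimation error from filter mismatch.
- **Ground truth**: the segmentation implied by the construction, and CC /
  synergy computed on the noise-free envelopes with the same normalization
  and integral conventions as the measurement path.

`simulate_study()` adds truncated-Gaussian between-subject variation
(SD 0.03 on each antagonist fraction, 0.05 on the agonist peak, 0.005 on
the tonic term), enough to spread subject-level CC by several points while
preserving the phase structure in every subject.

What the generator does **not** emulate: motor-unit physiology, fatigue,
electrode lift or motion artifacts, mains interference, trunk-compensation
kinematics, or speed-dependent changes in activation strategy. Passing the
recovery tests therefore shows that the pipeline correctly inverts its own
signal model at realistic rates and noise levels — not that every artifact
of real recordings is handled.

## Numerical behaviour and known limitations

- **Envelope temporal resolution.** The 0.25 s RMS window at a 4 Hz
  envelope rate is coarse relative to a half-cycle (0.38 s at 78 bpm).
  Smoothing smears adjacent agonist bursts across movement reversals, which
  inflates the common area and biases phase-resolved CC upward, more at
  faster speeds and most in the low-activation extension-acceleration
  phase. The end-to-end recovery test quantifies this against generator
  ground truth with a ±5 CC-point band; the deterministic smoothing
  component alone approaches (and for extension acceleration at the fastest
  speed exceeds) that band, which is the main caveat when comparing CC
  across speeds. The phase *ordering* is robust to it.
- **Degenerate inputs** are first-class: constant angle traces raise a
  no-cycles error, all-zero envelopes normalize to themselves, both-silent
  segments have CC 0, silent muscles have `NA` synergy, single-speed
  studies skip the factorial stage with a message, and unparseable trials
  are skipped with a warning naming the trial.
- **Determinism.** All generators consume explicit seeds; identical
  (protocol, model, seed) give bit-identical trials, and the pipeline
  itself is deterministic given its inputs and configuration.
- **Problem sizes.** The validation suite runs the full study design at its
  natural size (20 subjects × 3 speeds × 10 cycles) and calibrates the
  type-I error of the phase test with 1,000 null replicates of the 240-cell
  design; both were chosen as the smallest sizes at which the respective
  checks are meaningful at the stated tolerances.
- **Real recordings.** The exchange format is plain CSV with strict
  monotone-time and sampling-rate validation (±1%). Exports of the
  recording device/app are not parsed — their schema is undocumented — and
  `import_device_export()` says so with a typed condition rather than
  guessing.

## A complete run

```{r example, eval = FALSE}
trials <- simulate_study(n_subjects = 20, seed = 1)
res <- run_pipeline(trials)

res                  # pooled per-phase CC and the phase F test
res$anova            # SS / df / F / p, Type-II
res$tukey_phase      # FWER-adjusted pairwise phase differences
res$effect_size      # Cohen's f with its variant label
head(res$cc_table)   # tidy per-cycle, per-phase CC
```
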