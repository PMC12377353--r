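# coactr

Quantitative assessment of upper-limb motor control from surface
electromyography (sEMG) and inertial joint-angle recordings of rhythmic,
metronome-paced elbow flexion–extension (FE). The package is aimed at
movement scientists and rehabilitation researchers who want objective,
phase-resolved measures of neuromuscular coordination — range of motion,
angular velocity, agonist–antagonist coactivation, and muscle-synergy area
shares — from a simple two-channel (biceps brachii / triceps brachii) sEMG +
IMU setup. Such measures complement clinical scales when screening for
spasticity, involuntary coactivation or restricted mobility.

## What it computes

Raw sEMG (1,024 Hz) is conditioned into a normalized activity envelope:
fourth-order Butterworth band-pass (20–450 Hz, zero-phase), 0.25 s
non-overlapping RMS windows (4 Hz envelope), linear oversampling onto the
20 Hz angle grid, baseline correction (offset = mean − 3·SD of 30 samples
around the point of minimum activity, removal-only), and normalization to
the recording's contraction peak — no maximum-voluntary-contraction
reference needed.

The elbow-angle trace (positive = flexion, 0° = neutral at 90° elbow
flexion) is differentiated into angular velocity; flexion peaks delimit FE
cycles, and each cycle is split at angle/velocity extrema into four phases:
acceleration and deceleration of extension, then of flexion
(`acc_ext, dec_ext, acc_flex, dec_flex` in temporal order).

The coactivation coefficient (CC) on any segment follows the
Falconer–Winter common-area formulation,

```
CC = 2 · ∫ min(Ag, Antag) / ( ∫ Ag + ∫ Antag ) · 100   [%]
```

with Ag and Antag the agonist and antagonist envelopes; it is evaluated per
cycle and per phase. Muscle synergy is the percentage split of each
muscle's envelope area between flexion and extension phases. A factorial
layer fits the two-way (phase × speed) ANOVA on subject-cell mean CC, with
Tukey HSD post-hoc comparisons and Cohen's f effect sizes.

A synthetic-trial generator produces raised-cosine FE angle trajectories
(metronome speeds 42/60/78 bpm, one beat per half-cycle, +75° to −60°),
noise-free activation envelopes with phase-dependent antagonist
coactivation and a tonic triceps gravity-compensation term, and raw sEMG as
band-limited noise amplitude-modulated by those envelopes — with analytic
ground truth for end-to-end validation.

## Worked example

```r
library(coactr)

trial <- simulate_trial(movement_protocol(bpm = 60, n_cycles = 10), seed = 42)
res <- analyze_trial(trial$biceps_raw, trial$triceps_raw, trial$angle, bpm = 60)

res$cc
#> <coactivation_result>
#>   acc_flex CC = 32.96% (SD 1.58)
#>   dec_flex CC = 38.87% (SD 3.56)
#>   acc_ext  CC = 23.26% (SD 2.12)
#>   dec_ext  CC = 29.40% (SD 1.25)
#>   full cycle CC = 31.12% (mean over 9 cycles)

res$rom
#> <rom_summary> 9 cycles
#>   ROM [74.96, -59.93] deg (avg point SD 3.46)
#>   velocity [209.84, -210.37] deg/s (avg point SD 15.08)

trial$truth_cc
#> acc_flex dec_flex  acc_ext  dec_ext
#> 29.08212 36.49388 19.88688 26.78459
```

Ten metronome cycles yield nine complete peak-to-peak cycles (the record
starts at maximum flexion and ends mid-rise). Coactivation is highest in
flexion deceleration — the antagonist (triceps) brakes the forearm against
gravity at the end of flexion — and lowest in extension acceleration, where
gravity assists. The measured per-phase CC tracks the generator's
ground-truth values (`truth_cc`) with a modest upward offset contributed by
the 0.25 s envelope smoothing. ROM and peak velocity recover the configured
±75°/−60° excursion and its cosine-profile speed.

For a study-level analysis:

```r
trials <- simulate_study(n_subjects = 20, seed = 1)   # 20 subjects x 3 speeds
res <- run_pipeline(trials)
res$anova          # two-way phase x speed ANOVA (type II SS)
res$tukey_phase    # pairwise phase comparisons, FWER-adjusted
res$effect_size    # Cohen's f for the phase effect
```

Recorded data can be analysed the same way from plain CSVs
(`time_s, biceps_uV, triceps_uV` at the EMG rate and `time_s, angle_deg` at
the IMU rate) via `read_trial()` and manifests passed to `run_pipeline()`.

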