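# Synthetic-trial generator: metronome-paced elbow flexion-extension angle
# trajectories, noise-free muscle-activation envelopes with phase-dependent
# antagonist coactivation, and raw sEMG synthesized as band-limited noise
# amplitude-modulated by those envelopes. Every trial carries its analytic
# ground truth (segmentation, per-phase coactivation, synergy shares) so the
# full analysis pipeline can be validated end to end.

#' Movement protocol for a synthetic trial
#'
#' Describes one metronome-paced flexion-extension recording. One metronome
#' beat paces one half-cycle (flexion on one beat, extension on the next),
#' so a full cycle lasts `2 * 60/bpm` seconds. The movement starts and ends
#' at maximum flexion.
#'
#' @param bpm Metronome rate in beats/min (study speeds: 42, 60, 78).
#' @param n_cycles Number of flexion-extension repetitions (default 10).
#' @param flex_max Peak flexion angle in degrees (default +75).
#' @param ext_min Peak extension angle in degrees (default -60).
#' @param fs_imu Angle sampling rate in Hz (default 20).
#' @param fs_emg sEMG sampling rate in Hz (default 1024; must exceed 900 so
#'   the 450 Hz pass-band edge stays below Nyquist).
#' @param cycle_jitter Coefficient of variation of the half-cycle duration
#'   (default 0.05), emulating imperfect metronome tracking.
#' @return An object of class `movement_protocol`.
#' @export
movement_protocol <- function(bpm = 60, n_cycles = 10, flex_max = 75,
                              ext_min = -60, fs_imu = 20, fs_emg = 1024,
                              cycle_jitter = 0.05) {
  if (!is_number(bpm) || bpm <= 0)
    abort("invalid protocol: `bpm` must be a positive number")
  if (!is_number(n_cycles) || n_cycles < 1 || n_cycles != round(n_cycles))
    abort("invalid protocol: `n_cycles` must be a positive integer")
  if (!is_number(flex_max) || !is_number(ext_min) || flex_max <= ext_min)
    abort("invalid protocol: need flex_max > ext_min")
  if (!is_number(fs_imu) || fs_imu <= 0)
    abort("invalid protocol: `fs_imu` must be positive")
  if (!is_number(fs_emg) || fs_emg <= 900)
    abort("invalid protocol: `fs_emg` must exceed 900 Hz to admit the 450 Hz pass-band edge")
  if (!is_number(cycle_jitter) || cycle_jitter < 0)
    abort("invalid protocol: `cycle_jitter` must be >= 0")
  structure(list(bpm = bpm, n_cycles = as.integer(n_cycles),
                 flex_max = flex_max, ext_min = ext_min, fs_imu = fs_imu,
                 fs_emg = fs_emg, cycle_jitter = cycle_jitter),
            class = "movement_protocol")
}

#' Muscle-activation model for a synthetic trial
#'
#' Ground-truth activation structure: each half-cycle carries a smooth
#' unimodal agonist burst; the antagonist mirrors the agonist profile scaled
#' by a per-phase coactivation fraction; the triceps additionally carries a
#' small tonic component emulating gravity compensation. The default
#' fractions are chosen from the closed-form coactivation algebra
#' (`CC = 200 f / (1 + f)` for a pure fraction `f`) to reproduce the
#' qualitative phase ordering observed in healthy adults:
#' flexion deceleration highest, then flexion acceleration, extension
#' deceleration, extension acceleration.
#'
#' @param agonist_peak Peak agonist activation in normalized units (0, 1\].
#' @param antagonist_frac Named numeric of length 4 (names `acc_flex`,
#'   `dec_flex`, `acc_ext`, `dec_ext`), each in \[0, 1\]: antagonist-to-agonist
#'   ratio per phase.
#' @param tonic_triceps Constant triceps offset in normalized units (>= 0),
#'   the gravity-compensation component.
#' @param burst_shape Width of the raised-cosine agonist burst as a fraction
#'   of the half-cycle (0, 1\]; 1 means the burst spans the whole half-cycle.
#' @return An object of class `activation_model`.
#' @export
activation_model <- function(agonist_peak = 0.9,
                             antagonist_frac = c(acc_flex = 0.13,
                                                 dec_flex = 0.19,
                                                 acc_ext = 0.11,
                                                 dec_ext = 0.16),
                             tonic_triceps = 0.02,
                             burst_shape = 1) {
  if (!is_number(agonist_peak) || agonist_peak <= 0 || agonist_peak > 1)
    abort("invalid model: `agonist_peak` must be in (0, 1]")
  if (!is.numeric(antagonist_frac) || length(antagonist_frac) != 4 ||
      !all(PHASE_LEVELS %in% names(antagonist_frac)))
    abort("invalid model: `antagonist_frac` must be named for the four phases")
  antagonist_frac <- antagonist_frac[PHASE_LEVELS]
  if (any(antagonist_frac < 0) || any(antagonist_frac > 1))
    abort("invalid model: antagonist fractions must lie in [0, 1]")
  if (!is_number(tonic_triceps) || tonic_triceps < 0)
    abort("invalid model: `tonic_triceps` must be >= 0")
  if (!is_number(burst_shape) || burst_shape <= 0 || burst_shape > 1)
    abort("invalid model: `burst_shape` must be in (0, 1]")
  structure(list(agonist_peak = agonist_peak,
                 antagonist_frac = antagonist_frac,
                 tonic_triceps = tonic_triceps,
                 burst_shape = burst_shape),
            class = "activation_model")
}

# internal: half-cycle durations in seconds; one metronome beat each,
# multiplicatively jittered (truncated well away from zero).
half_cycle_durations <- function(protocol) {
  k <- 2L * protocol$n_cycles
  base <- 60 / protocol$bpm
  mult <- if (protocol$cycle_jitter > 0)
    pmax(0.2, stats::rnorm(k, mean = 1, sd = protocol$cycle_jitter))
  else rep(1, k)
  base * mult
}

# internal: angle samples + half-cycle boundary times. The sampling grid is
# half-open: t = 0, 1/fs, ..., (N-1)/fs with N = round(T * fs), so the final
# return to maximum flexion is not itself sampled (the record ends mid-rise,
# mirroring a recording stopped on the last beat).
build_angle <- function(protocol, durations) {
  tau <- c(0, cumsum(durations))
  fs <- protocol$fs_imu
  n <- round(tau[length(tau)] * fs)
  t <- (seq_len(n) - 1) / fs
  k <- findInterval(t, tau, rightmost.closed = FALSE)
  k[k > length(durations)] <- length(durations)
  s <- (t - tau[k]) / durations[k]
  ext_half <- k %% 2L == 1L  # odd half-cycles descend flexion -> extension
  from <- ifelse(ext_half, protocol$flex_max, protocol$ext_min)
  to <- ifelse(ext_half, protocol$ext_min, protocol$flex_max)
  ang <- from + (to - from) * (1 - cos(pi * s)) / 2
  list(angle = angle_trace(ang, fs = fs), tau = tau)
}

#' Generate a synthetic elbow-angle trace
#'
#' Raised-cosine half-cycles alternating between the protocol's flexion and
#' extension extrema, one half-cycle per metronome beat, starting at maximum
#' flexion. Half-cycle durations are multiplicatively jittered by
#' `cycle_jitter`. The returned trace carries the half-cycle boundary times
#' as attribute `"half_cycle_times"` for downstream ground-truth use.
#'
#' @param protocol A [movement_protocol()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return An [angle_trace()] at `fs_imu` with attribute
#'   `"half_cycle_times"`.
#' @export
#' @examples
#' a <- generate_angle_trace(movement_protocol(bpm = 60, cycle_jitter = 0), seed = 1)
#' range(a$samples)   # ~ [-60, 75]
generate_angle_trace <- function(protocol, seed = NULL) {
  if (!inherits(protocol, "movement_protocol"))
    abort("invalid protocol: pass a movement_protocol()")
  if (!is.null(seed)) set.seed(seed)
  built <- build_angle(protocol, half_cycle_durations(protocol))
  attr(built$angle, "half_cycle_times") <- built$tau
  built$angle
}

# internal: raised-cosine burst profile over normalized half-cycle time
# s in [0, 1), centred at s = 0.5 with width `w` (fraction of the half-cycle)
burst_profile <- function(s, w) {
  u <- (s - 0.5 + w / 2) / w
  ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
}

#' Noise-free activation envelopes for a synthetic trial
#'
#' Builds the ground-truth biceps and triceps activation envelopes on the
#' angle grid: the agonist of each half-cycle (biceps in flexion, triceps in
#' extension) carries the burst, the antagonist carries
#' `antagonist_frac[phase]` times the agonist profile, and the triceps adds
#' its tonic gravity-compensation offset.
#'
#' @param protocol The [movement_protocol()] the angle was generated from.
#' @param model An [activation_model()].
#' @param angle The [generate_angle_trace()] output for `protocol` (must
#'   carry the `"half_cycle_times"` attribute).
#' @return An object of class `activation_envelopes`: list with numeric
#'   `biceps`, `triceps` and `fs`.
#' @export
generate_activation_envelopes <- function(protocol, model, angle) {
  if (!inherits(model, "activation_model"))
    abort("invalid model: pass an activation_model()")
  tau <- attr(angle, "half_cycle_times")
  if (is.null(tau))
    abort("alignment error: `angle` must come from generate_angle_trace()")
  n <- length(angle$samples)
  fs <- angle$fs
  expected <- round(tau[length(tau)] * fs)
  if (abs(n - expected) > 1)
    abort("alignment error: angle length does not match the protocol timing")
  t <- (seq_len(n) - 1) / fs
  durations <- diff(tau)
  k <- findInterval(t, tau, rightmost.closed = FALSE)
  k[k > length(durations)] <- length(durations)
  s <- (t - tau[k]) / durations[k]
  g <- model$agonist_peak * burst_profile(s, model$burst_shape)
  ext_half <- k %% 2L == 1L
  acc <- s < 0.5
  phase <- ifelse(ext_half,
                  ifelse(acc, "acc_ext", "dec_ext"),
                  ifelse(acc, "acc_flex", "dec_flex"))
  frac <- model$antagonist_frac[phase]
  biceps <- ifelse(ext_half, frac * g, g)
  triceps <- ifelse(ext_half, g, frac * g) + model$tonic_triceps
  structure(list(biceps = as.numeric(biceps),
                 triceps = as.numeric(triceps), fs = fs),
            class = "activation_envelopes")
}

# internal: ground-truth segmentation from the construction: cycle
# boundaries at every other half-cycle boundary, velocity extrema at the
# temporal midpoints of the raised-cosine half-cycles.
truth_segmentation <- function(tau, fs, n) {
  to_idx <- function(x) pmin(pmax(round(x * fs) + 1L, 1L), n)
  n_half <- length(tau) - 1L
  peaks_t <- tau[seq(1L, n_half + 1L, by = 2L)]
  peaks <- to_idx(peaks_t)
  # the final return to maximum flexion lies beyond the half-open grid
  peaks <- peaks[round(peaks_t * fs) < n]
  if (length(peaks) < 2) abort("protocol too short for a complete cycle")
  mids <- to_idx((tau[-length(tau)] + tau[-1]) / 2)
  troughs <- to_idx(tau[seq(2L, n_half, by = 2L)])
  rows <- list()
  for (c_id in seq_len(length(peaks) - 1L)) {
    h <- 2L * (c_id - 1L) + 1L   # extension half-cycle index
    rows[[c_id]] <- data.frame(
      cycle = c_id,
      phase = CYCLE_PHASE_ORDER,
      start = c(peaks[c_id], mids[h], troughs[c_id], mids[h + 1L]),
      end   = c(mids[h], troughs[c_id], mids[h + 1L], peaks[c_id + 1L]))
  }
  structure(list(phases = do.call(rbind, rows), peaks = peaks,
                 troughs = troughs[seq_len(length(peaks) - 1L)], fs = fs),
            class = "cycle_segmentation")
}

#' Ground-truth metrics of a synthetic trial
#'
#' Computes the per-phase coactivation coefficient and the synergy area
#' shares on the noise-free activation envelopes, using the same peak
#' normalization and integral conventions as the measurement pipeline. These
#' values are the recovery targets for the full filter -> envelope ->
#' segmentation -> coactivation chain.
#'
#' @param envelopes An [generate_activation_envelopes()] result.
#' @param segmentation The trial's ground-truth `cycle_segmentation`.
#' @return List with `truth_cc` (named per-phase mean CC in percent, in
#'   reporting order), `cc` (the full `coactivation_result`), and `synergy`
#'   (a `synergy_result`).
#' @export
ground_truth_metrics <- function(envelopes, segmentation) {
  if (!inherits(envelopes, "activation_envelopes"))
    abort("`envelopes` must come from generate_activation_envelopes()")
  norm <- function(x) if (max(x) > 0) x / max(x) else x
  b <- norm(envelopes$biceps)
  t_ <- norm(envelopes$triceps)
  cc <- cc_by_phase(b, t_, segmentation)
  syn <- muscle_synergy(b, t_, segmentation)
  truth_cc <- stats::setNames(cc$summary$mean_cc, cc$summary$phase)
  list(truth_cc = truth_cc, cc = cc, synergy = syn)
}

#' Synthesize raw sEMG from an activation envelope
#'
#' Raw sEMG is modelled as zero-mean Gaussian noise band-limited to the
#' analysis pass-band (20-450 Hz), normalized to unit RMS and
#' amplitude-modulated by the activation envelope linearly upsampled to the
#' EMG rate. The long-run RMS of the output therefore tracks the envelope
#' itself. Deterministic given `seed`.
#'
#' @param envelope Numeric non-negative activation envelope.
#' @param fs_env Sampling rate of `envelope` in Hz.
#' @param fs_emg Output EMG rate in Hz (> 900).
#' @param seed Integer seed.
#' @param muscle Channel label for the output.
#' @return An [emg_signal()] of duration `length(envelope)/fs_env`.
#' @export
synthesize_raw_emg <- function(envelope, fs_env = 20, fs_emg = 1024,
                               seed = 1, muscle = c("biceps", "triceps")) {
  muscle <- match.arg(muscle)
  envelope <- as.numeric(envelope)
  if (any(!is.finite(envelope)) || (length(envelope) && min(envelope) < 0))
    abort("`envelope` must be finite and non-negative")
  if (!is_number(fs_emg) || fs_emg <= 900)
    abort("sampling-rate error: `fs_emg` must exceed 900 Hz")
  set.seed(seed)
  n <- round(length(envelope) / fs_env * fs_emg)
  noise <- stats::rnorm(n)
  bf <- signal::butter(4, c(20, 450) / (fs_emg / 2), type = "pass")
  carrier <- signal::filtfilt(bf, noise)
  carrier <- carrier / sqrt(mean(carrier^2))
  t_env <- (seq_along(envelope) - 1) / fs_env
  t_emg <- (seq_len(n) - 1) / fs_emg
  up <- stats::approx(t_env, envelope, xout = t_emg, rule = 2)$y
  emg_signal(up * carrier, fs = fs_emg, muscle = muscle)
}

#' Simulate one synthetic trial
#'
#' Generates a complete trial: jittered angle trace, noise-free activation
#' envelopes, ground-truth segmentation and metrics, and two raw sEMG
#' channels. Identical `(protocol, model, seed)` yield identical trials.
#'
#' @param protocol A [movement_protocol()].
#' @param model An [activation_model()].
#' @param seed Integer seed.
#' @return An object of class `synthetic_trial`: list with `biceps_raw`,
#'   `triceps_raw` ([emg_signal()]), `angle` ([angle_trace()]), `envelopes`
#'   (noise-free, at `fs_imu`), `truth_segmentation`, `truth_cc` (named
#'   per-phase CC in percent), `truth_synergy`, `protocol`, `model`, `seed`.
#' @export
#' @examples
#' trial <- simulate_trial(movement_protocol(n_cycles = 3), seed = 7)
#' trial$truth_cc
simulate_trial <- function(protocol = movement_protocol(),
                           model = activation_model(), seed = 1) {
  if (!inherits(protocol, "movement_protocol"))
    abort("invalid protocol: pass a movement_protocol()")
  if (!inherits(model, "activation_model"))
    abort("invalid model: pass an activation_model()")
  set.seed(seed)
  emg_seeds <- sample.int(2^31 - 2, 2)
  angle <- generate_angle_trace(protocol, seed = NULL)
  env <- generate_activation_envelopes(protocol, model, angle)
  seg <- truth_segmentation(attr(angle, "half_cycle_times"),
                            protocol$fs_imu, length(angle$samples))
  truth <- ground_truth_metrics(env, seg)
  structure(list(
    biceps_raw = synthesize_raw_emg(env$biceps, fs_env = protocol$fs_imu,
                                    fs_emg = protocol$fs_emg,
                                    seed = emg_seeds[1], muscle = "biceps"),
    triceps_raw = synthesize_raw_emg(env$triceps, fs_env = protocol$fs_imu,
                                     fs_emg = protocol$fs_emg,
                                     seed = emg_seeds[2], muscle = "triceps"),
    angle = angle,
    envelopes = env,
    truth_segmentation = seg,
    truth_cc = truth$truth_cc,
    truth_synergy = truth$synergy,
    protocol = protocol,
    model = model,
    seed = seed),
    class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> %g bpm, %d cycles, seed %d\n",
              x$protocol$bpm, x$protocol$n_cycles, x$seed))
  cat("  truth CC (%):",
      paste(sprintf("%s=%.1f", names(x$truth_cc), x$truth_cc),
            collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a multi-subject study
#'
#' Generates one trial per subject and metronome speed, with mild
#' between-subject variation of the activation model (truncated-Gaussian
#' perturbation of the antagonist fractions, agonist peak and tonic triceps
#' level) so subjects differ the way healthy adults do while sharing the
#' same qualitative phase structure.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param bpms Metronome speeds in beats/min (default `c(42, 60, 78)`).
#' @param n_cycles Repetitions per trial (default 10).
#' @param model Population-mean [activation_model()].
#' @param cycle_jitter Half-cycle duration CV passed to each protocol.
#' @param between_subject_sd SD of the per-subject perturbation of each
#'   antagonist fraction (default 0.03).
#' @param seed Integer master seed; all trial seeds derive from it.
#' @return List of `synthetic_trial` objects, each with added fields
#'   `subject` and `speed_bpm`.
#' @export
simulate_study <- function(n_subjects = 20, bpms = c(42, 60, 78),
                           n_cycles = 10, model = activation_model(),
                           cycle_jitter = 0.05, between_subject_sd = 0.03,
                           seed = 1) {
  set.seed(seed)
  trials <- list()
  for (subj in seq_len(n_subjects)) {
    frac <- pmin(pmax(model$antagonist_frac +
                        stats::rnorm(4, 0, between_subject_sd), 0), 0.9)
    names(frac) <- names(model$antagonist_frac)
    subj_model <- activation_model(
      agonist_peak = min(max(model$agonist_peak + stats::rnorm(1, 0, 0.05), 0.2), 1),
      antagonist_frac = frac,
      tonic_triceps = max(model$tonic_triceps + stats::rnorm(1, 0, 0.005), 0),
      burst_shape = model$burst_shape)
    for (bpm in bpms) {
      trial_seed <- sample.int(2^31 - 2, 1)
      protocol <- movement_protocol(bpm = bpm, n_cycles = n_cycles,
                                    cycle_jitter = cycle_jitter)
      trial <- simulate_trial(protocol, subj_model, seed = trial_seed)
      trial$subject <- subj
      trial$speed_bpm <- bpm
      trials[[length(trials) + 1L]] <- trial
    }
  }
  trials
}
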