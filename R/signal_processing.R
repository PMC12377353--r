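# sEMG conditioning: band-pass filter -> block RMS envelope -> oversampling
# -> baseline correction -> peak normalization. Stage order is enforced via
# the `stage` field of envelope_signal objects.

#' Raw sEMG signal
#'
#' Container for one muscle channel of raw surface EMG samples at a fixed
#' sampling rate.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units, e.g. uV).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param muscle Channel label, `"biceps"` or `"triceps"`.
#' @return An object of class `emg_signal` with fields `samples`, `fs`,
#'   `muscle`.
#' @export
#' @examples
#' emg_signal(rnorm(1024), fs = 1024, muscle = "biceps")
emg_signal <- function(samples, fs, muscle = c("biceps", "triceps")) {
  muscle <- match.arg(muscle)
  samples <- as.numeric(samples)
  if (!is_number(fs) || fs <= 0) abort("`fs` must be a positive number")
  if (anyNA(samples) || any(!is.finite(samples)))
    abort("EMG samples must be finite")
  structure(list(samples = samples, fs = fs, muscle = muscle),
            class = "emg_signal")
}

#' @export
print.emg_signal <- function(x, ...) {
  cat(sprintf("<emg_signal> %s: %d samples @ %g Hz (%.2f s)\n",
              x$muscle, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Band-pass filter specification
#'
#' Butterworth band-pass design used to restrict sEMG to its physiological
#' band before envelope extraction.
#'
#' @param order Filter order passed to the Butterworth design (default 4).
#' @param band Length-2 numeric `(low, high)` pass-band edges in Hz
#'   (default `c(20, 450)`).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, band = c(20, 450)) {
  if (!is_number(order) || order < 1 || order != round(order))
    abort("`order` must be a positive integer")
  if (!is.numeric(band) || length(band) != 2 || !all(is.finite(band)) ||
      band[1] <= 0 || band[2] <= band[1])
    abort("`band` must satisfy 0 < low < high")
  structure(list(order = as.integer(order), band = as.numeric(band),
                 family = "butterworth"),
            class = "filter_spec")
}

#' Zero-phase Butterworth band-pass filtering of raw sEMG
#'
#' Applies the band-pass forward and backward (`signal::filtfilt`) so the
#' filtered EMG stays time-aligned with the simultaneously recorded joint
#' angle; phase alignment matters because downstream metrics integrate the
#' envelope over kinematically defined phase windows.
#'
#' @param raw An [emg_signal()].
#' @param spec A [filter_spec()]; the default is the conventional 20-450 Hz
#'   fourth-order design for surface EMG.
#' @return A filtered [emg_signal()] of the same length and rate.
#' @export
bandpass_filter <- function(raw, spec = filter_spec()) {
  if (!inherits(raw, "emg_signal")) abort("`raw` must be an emg_signal")
  if (!inherits(spec, "filter_spec")) abort("`spec` must be a filter_spec")
  nyq <- raw$fs / 2
  if (spec$band[2] >= nyq)
    abort(sprintf(
      "filter configuration error: high edge %g Hz >= Nyquist %g Hz",
      spec$band[2], nyq))
  bf <- signal::butter(spec$order, spec$band / nyq, type = "pass")
  emg_signal(signal::filtfilt(bf, raw$samples), raw$fs, raw$muscle)
}

#' Muscle-activity envelope
#'
#' A rectified/smoothed representation of sEMG amplitude. The `stage` field
#' records progress through the conditioning chain
#' (`rms -> oversampled -> baseline_corrected -> normalized`); the stage
#' transitions are enforced by the processing functions, which reject
#' out-of-order calls.
#'
#' @param samples Numeric vector of non-negative activity values (raw units
#'   before normalization, dimensionless in \[0, 1\] after).
#' @param fs Envelope sampling rate in Hz.
#' @param stage One of `"rms"`, `"oversampled"`, `"baseline_corrected"`,
#'   `"normalized"`.
#' @param muscle Optional channel label carried through the chain.
#' @return An object of class `envelope_signal`.
#' @export
envelope_signal <- function(samples, fs,
                            stage = c("rms", "oversampled",
                                      "baseline_corrected", "normalized"),
                            muscle = NULL) {
  stage <- match.arg(stage)
  samples <- as.numeric(samples)
  if (!is_number(fs) || fs <= 0) abort("`fs` must be a positive number")
  if (anyNA(samples) || any(!is.finite(samples)))
    abort("envelope samples must be finite")
  if (length(samples) && min(samples) < 0)
    abort("envelope samples must be non-negative")
  structure(list(samples = samples, fs = fs, stage = stage, muscle = muscle),
            class = "envelope_signal")
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf("<envelope_signal> %s%d samples @ %g Hz, stage '%s'\n",
              if (is.null(x$muscle)) "" else paste0(x$muscle, ": "),
              length(x$samples), x$fs, x$stage))
  invisible(x)
}

expect_stage <- function(env, stage, caller) {
  if (!inherits(env, "envelope_signal"))
    abort(sprintf("`env` passed to %s must be an envelope_signal", caller))
  if (env$stage != stage)
    abort(sprintf(
      "%s expects an envelope at stage '%s', got '%s' (stage order is rms -> oversampled -> baseline_corrected -> normalized)",
      caller, stage, env$stage))
  invisible(env)
}

#' Block RMS envelope of filtered sEMG
#'
#' Smooths the filtered EMG with a root-mean-square window. Windows are
#' non-overlapping (hop = window), which is what maps a 0.25 s window at any
#' EMG rate onto a 4 Hz envelope: the output rate is `1/window_s`.
#'
#' @param filtered A band-pass filtered [emg_signal()].
#' @param window_s RMS window length in seconds (default 0.25).
#' @return An [envelope_signal()] at stage `"rms"` with rate `1/window_s`.
#' @export
#' @examples
#' x <- emg_signal(sin(2 * pi * 64 * (0:1023) / 1024), 1024)
#' rms_envelope(x)          # 4 samples at 4 Hz, each ~ 1/sqrt(2)
rms_envelope <- function(filtered, window_s = 0.25) {
  if (!inherits(filtered, "emg_signal"))
    abort("`filtered` must be an emg_signal")
  if (!is_number(window_s) || window_s <= 0)
    abort("`window_s` must be a positive number")
  w <- round(window_s * filtered$fs)
  if (w < 1) abort("RMS window shorter than one sample")
  n_win <- floor(length(filtered$samples) / w)
  if (n_win < 1)
    abort("empty envelope: record shorter than one RMS window")
  blocks <- matrix(filtered$samples[seq_len(n_win * w)]^2, nrow = w)
  envelope_signal(sqrt(colMeans(blocks)), fs = filtered$fs / w,
                  stage = "rms", muscle = filtered$muscle)
}

#' Oversample an RMS envelope onto the kinematic time grid
#'
#' Interpolates the block-RMS envelope (timestamped at block centres) onto a
#' denser uniform grid so that the envelope aligns sample-for-sample with the
#' joint-angle trace. Linear interpolation by default; a zero-order hold is
#' available. Values are held constant beyond the first/last block centre.
#'
#' @param env An [envelope_signal()] at stage `"rms"`.
#' @param target_fs Target rate in Hz (default 20, the IMU angle rate); must
#'   be at least the envelope rate.
#' @param times Optional explicit output time grid in seconds (overrides
#'   `target_fs`-derived grid); use the angle trace's own grid to guarantee
#'   equal lengths.
#' @param method `"linear"` (default) or `"constant"` (zero-order hold).
#' @return An [envelope_signal()] at stage `"oversampled"`.
#' @export
resample_envelope <- function(env, target_fs = 20, times = NULL,
                              method = c("linear", "constant")) {
  expect_stage(env, "rms", "resample_envelope")
  method <- match.arg(method)
  if (!is_number(target_fs) || target_fs < env$fs)
    abort(sprintf(
      "configuration error: target rate %g Hz below envelope rate %g Hz",
      target_fs, env$fs))
  centres <- (seq_along(env$samples) - 0.5) / env$fs
  if (is.null(times)) {
    dur <- length(env$samples) / env$fs
    times <- seq.int(0, floor(dur * target_fs)) / target_fs
    fs_out <- target_fs
  } else {
    if (!is.numeric(times) || length(times) < 1)
      abort("`times` must be a numeric time grid")
    fs_out <- if (length(times) > 1) 1 / stats::median(diff(times)) else target_fs
  }
  y <- if (length(env$samples) == 1L) {
    rep(env$samples, length(times))
  } else {
    stats::approx(centres, env$samples, xout = times, method = method,
                  rule = 2, f = 0)$y
  }
  envelope_signal(y, fs = fs_out, stage = "oversampled", muscle = env$muscle)
}

#' Baseline (resting-activity) correction of an envelope
#'
#' Estimates the resting offset from `n_samples` envelope points centred on
#' the point of minimum activity (the global envelope minimum; window shifted
#' to stay within the record at the edges). The offset is the window mean
#' minus three window standard deviations; it is subtracted and any negative
#' residuals are clamped to zero, so a constant (purely tonic) envelope is
#' zeroed and the quiet-window floor sits near 3 SD above zero. Baseline
#' correction only ever removes a resting offset: a negative offset estimate
#' (which arises when the window around the minimum catches bursts of a
#' continuously cyclic record with no rest period) is clamped to zero and
#' the envelope passes through unchanged.
#'
#' @param env An [envelope_signal()] at stage `"oversampled"`.
#' @param n_samples Number of points in the quiet window (default 30).
#' @return An [envelope_signal()] at stage `"baseline_corrected"`.
#' @export
baseline_correct <- function(env, n_samples = 30) {
  expect_stage(env, "oversampled", "baseline_correct")
  if (!is_number(n_samples) || n_samples < 2 || n_samples != round(n_samples))
    abort("`n_samples` must be an integer >= 2")
  x <- env$samples
  n <- length(x)
  if (n < n_samples)
    abort(sprintf("insufficient data: envelope has %d points, need %d",
                  n, n_samples))
  i_min <- which.min(x)
  start <- i_min - floor(n_samples / 2)
  start <- max(1L, min(start, n - n_samples + 1L))
  win <- x[start:(start + n_samples - 1L)]
  offset <- max(mean(win) - 3 * stats::sd(win), 0)
  envelope_signal(pmax(x - offset, 0), fs = env$fs,
                  stage = "baseline_corrected", muscle = env$muscle)
}

#' Peak normalization of an envelope
#'
#' Divides by the maximum contraction peak of the recording (per muscle, per
#' register), so the conditioned envelope lies in \[0, 1\] without requiring a
#' maximum-voluntary-contraction reference. An all-zero envelope passes
#' through unchanged.
#'
#' @param env An [envelope_signal()] at stage `"baseline_corrected"`.
#' @return An [envelope_signal()] at stage `"normalized"`.
#' @export
normalize_envelope <- function(env) {
  expect_stage(env, "baseline_corrected", "normalize_envelope")
  m <- if (length(env$samples)) max(env$samples) else 0
  y <- if (m > 0) env$samples / m else env$samples
  envelope_signal(y, fs = env$fs, stage = "normalized", muscle = env$muscle)
}

#' Full sEMG conditioning chain
#'
#' Convenience wrapper running filter -> block RMS -> oversampling ->
#' baseline correction -> normalization with the settings of a
#' [pipeline_config()].
#'
#' @param raw An [emg_signal()].
#' @param config A [pipeline_config()].
#' @param times Optional output time grid (seconds) for the oversampling
#'   step, typically the angle trace's grid.
#' @return A normalized [envelope_signal()] on the kinematic grid.
#' @export
process_emg <- function(raw, config = pipeline_config(), times = NULL) {
  env <- rms_envelope(
    bandpass_filter(raw, filter_spec(config$filter_order, config$filter_band)),
    window_s = config$rms_window_s)
  env <- resample_envelope(env, target_fs = config$envelope_fs, times = times,
                           method = config$interp)
  normalize_envelope(baseline_correct(env, config$baseline_n))
}
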