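# Plain-CSV interchange for trials and the pipeline configuration object.
# A trial is stored as two CSVs — EMG (time_s, biceps_uV, triceps_uV) at the
# EMG rate and angle (time_s, angle_deg) at the IMU rate — plus an optional
# JSON sidecar with ground truth for synthetic trials.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with its default. All
#' defaults are validated against the preconditions of the stage that
#' consumes them.
#'
#' @param filter_order Butterworth order (default 4).
#' @param filter_band Pass band in Hz (default `c(20, 450)`).
#' @param rms_window_s RMS window length in s (default 0.25; non-overlapping
#'   windows, so the envelope rate is `1/rms_window_s` = 4 Hz).
#' @param envelope_fs Target envelope rate in Hz after oversampling
#'   (default 20, the IMU rate).
#' @param baseline_n Quiet-window size for baseline correction (default 30).
#' @param interp Oversampling method, `"linear"` or `"constant"`.
#' @param peak_prominence Cycle-detection prominence as a fraction of the
#'   angle range (default 0.2).
#' @param peak_separation_frac Minimum peak separation as a fraction of the
#'   nominal cycle period (default 0.5; used when the trial's bpm is known).
#' @param cohens_f_variant `"ss_ratio"` or `"eta_squared"`.
#' @param fs_emg_nominal,fs_imu_nominal Nominal sampling rates used to
#'   validate files on read (Hz).
#' @param rate_tol Relative tolerance for the rate check (default 0.01).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(filter_order = 4, filter_band = c(20, 450),
                            rms_window_s = 0.25, envelope_fs = 20,
                            baseline_n = 30,
                            interp = c("linear", "constant"),
                            peak_prominence = 0.2,
                            peak_separation_frac = 0.5,
                            cohens_f_variant = c("ss_ratio", "eta_squared"),
                            fs_emg_nominal = 1024, fs_imu_nominal = 20,
                            rate_tol = 0.01) {
  filter_spec(filter_order, filter_band)  # validates order/band
  interp <- match.arg(interp)
  cohens_f_variant <- match.arg(cohens_f_variant)
  if (!is_number(rms_window_s) || rms_window_s <= 0)
    abort("`rms_window_s` must be positive")
  if (!is_number(envelope_fs) || envelope_fs < 1 / rms_window_s)
    abort("`envelope_fs` must be at least the RMS envelope rate")
  if (!is_number(baseline_n) || baseline_n < 2)
    abort("`baseline_n` must be an integer >= 2")
  if (!is_number(peak_prominence) || peak_prominence <= 0 || peak_prominence >= 1)
    abort("`peak_prominence` must lie in (0, 1)")
  if (!is_number(peak_separation_frac) || peak_separation_frac < 0 ||
      peak_separation_frac > 1)
    abort("`peak_separation_frac` must lie in [0, 1]")
  if (!is_number(rate_tol) || rate_tol <= 0)
    abort("`rate_tol` must be positive")
  structure(list(filter_order = filter_order, filter_band = filter_band,
                 rms_window_s = rms_window_s, envelope_fs = envelope_fs,
                 baseline_n = baseline_n, interp = interp,
                 peak_prominence = peak_prominence,
                 peak_separation_frac = peak_separation_frac,
                 cohens_f_variant = cohens_f_variant,
                 fs_emg_nominal = fs_emg_nominal,
                 fs_imu_nominal = fs_imu_nominal,
                 rate_tol = rate_tol),
            class = "pipeline_config")
}

check_time_column <- function(time_s, file) {
  bad <- which(diff(time_s) <= 0)
  if (length(bad))
    abort(sprintf("parse error in '%s': time not strictly increasing at row %d",
                  file, bad[1] + 1L))
}

infer_rate <- function(time_s) (length(time_s) - 1) / (time_s[length(time_s)] - time_s[1])

check_rate <- function(fs, nominal, tol, file) {
  if (abs(fs - nominal) > tol * nominal)
    abort(sprintf(
      "rate mismatch in '%s': inferred %.3f Hz, expected %g Hz (+/- %g%%)",
      file, fs, nominal, 100 * tol))
  nominal
}

#' Write a trial to plain CSV files
#'
#' Writes `<prefix>_emg.csv` (`time_s, biceps_uV, triceps_uV`),
#' `<prefix>_angle.csv` (`time_s, angle_deg`) and, for synthetic trials,
#' `<prefix>_truth.json` with the ground-truth per-phase coactivation and
#' the generating seed.
#'
#' @param trial A `synthetic_trial`, or a list with `biceps_raw`,
#'   `triceps_raw` and `angle`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"trial"`).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_trial <- function(trial, dir, prefix = "trial") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nb <- length(trial$biceps_raw$samples)
  if (length(trial$triceps_raw$samples) != nb)
    abort("EMG channels differ in length")
  emg_path <- file.path(dir, paste0(prefix, "_emg.csv"))
  ang_path <- file.path(dir, paste0(prefix, "_angle.csv"))
  utils::write.csv(data.frame(
    time_s = (seq_len(nb) - 1) / trial$biceps_raw$fs,
    biceps_uV = trial$biceps_raw$samples,
    triceps_uV = trial$triceps_raw$samples),
    emg_path, row.names = FALSE)
  utils::write.csv(data.frame(
    time_s = (seq_along(trial$angle$samples) - 1) / trial$angle$fs,
    angle_deg = trial$angle$samples),
    ang_path, row.names = FALSE)
  paths <- c(emg = emg_path, angle = ang_path)
  if (inherits(trial, "synthetic_trial")) {
    truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
    jsonlite::write_json(list(seed = trial$seed,
                              truth_cc = as.list(trial$truth_cc)),
                         truth_path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, truth = truth_path)
  }
  invisible(paths)
}

#' Read a trial from plain CSV files
#'
#' Parses the EMG and angle CSVs of one trial, checks that the time columns
#' are strictly increasing, infers the sampling rates from them and
#' validates the rates against the configured nominal values within
#' `rate_tol`.
#'
#' @param emg_csv Path to the EMG CSV (`time_s, biceps_uV, triceps_uV`).
#' @param angle_csv Path to the angle CSV (`time_s, angle_deg`).
#' @param config A [pipeline_config()].
#' @return List with `biceps`, `triceps` ([emg_signal()]) and `angle`
#'   ([angle_trace()]).
#' @export
read_trial <- function(emg_csv, angle_csv, config = pipeline_config()) {
  need_cols <- function(d, cols, file) {
    missing <- setdiff(cols, names(d))
    if (length(missing))
      abort(sprintf("parse error in '%s': missing column(s) %s",
                    file, paste(missing, collapse = ", ")))
  }
  emg <- utils::read.csv(emg_csv)
  need_cols(emg, c("time_s", "biceps_uV", "triceps_uV"), emg_csv)
  check_time_column(emg$time_s, emg_csv)
  fs_emg <- check_rate(infer_rate(emg$time_s), config$fs_emg_nominal,
                       config$rate_tol, emg_csv)
  ang <- utils::read.csv(angle_csv)
  need_cols(ang, c("time_s", "angle_deg"), angle_csv)
  check_time_column(ang$time_s, angle_csv)
  fs_imu <- check_rate(infer_rate(ang$time_s), config$fs_imu_nominal,
                       config$rate_tol, angle_csv)
  list(biceps = emg_signal(emg$biceps_uV, fs_emg, "biceps"),
       triceps = emg_signal(emg$triceps_uV, fs_emg, "triceps"),
       angle = angle_trace(ang$angle_deg, fs_imu))
}

#' Import hook for device exports
#'
#' Placeholder for converting exports of the recording device/app into the
#' package's CSV interchange format. No converter ships with the package
#' because the export schema is not publicly documented; calling this
#' function states that explicitly rather than guessing a parser.
#'
#' @param path Path to a device export file.
#' @return Never returns; signals a condition of class
#'   `coactr_unsupported_import`.
#' @export
import_device_export <- function(path) {
  stop(structure(class = c("coactr_unsupported_import", "error", "condition"),
                 list(message = paste0(
                   "no importer is available for device exports ('", path,
                   "'); convert the recording to the documented CSV ",
                   "interchange format (time_s, biceps_uV, triceps_uV / ",
                   "time_s, angle_deg) and use read_trial()"),
                   call = sys.call(-1))))
}
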