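# End-to-end analysis: per-trial processing (conditioning + segmentation +
# metrics) and the multi-trial pipeline feeding the factorial analysis.

#' Analyse one trial
#'
#' Runs the full measurement chain on one trial: band-pass filter and
#' envelope conditioning of both EMG channels (aligned to the angle grid),
#' angular velocity, cycle detection and four-phase segmentation, then
#' coactivation, synergy and ROM summaries.
#'
#' @param biceps,triceps Raw [emg_signal()] channels.
#' @param angle The trial's [angle_trace()].
#' @param config A [pipeline_config()].
#' @param bpm Optional metronome rate of the trial; when given it informs
#'   the minimum peak separation of cycle detection.
#' @return An object of class `trial_analysis`: list with `biceps_env`,
#'   `triceps_env` (normalized [envelope_signal()]), `velocity`,
#'   `segmentation`, `cc` ([cc_by_phase()] result), `synergy`
#'   ([muscle_synergy()] result), `rom` ([summarize_rom()] result).
#' @export
#' @examples
#' trial <- simulate_trial(movement_protocol(n_cycles = 4), seed = 3)
#' res <- analyze_trial(trial$biceps_raw, trial$triceps_raw, trial$angle,
#'                      bpm = trial$protocol$bpm)
#' res$cc$summary
analyze_trial <- function(biceps, triceps, angle,
                          config = pipeline_config(), bpm = NULL) {
  if (!inherits(config, "pipeline_config"))
    abort("`config` must be a pipeline_config")
  times <- (seq_along(angle$samples) - 1) / angle$fs
  b_env <- process_emg(biceps, config, times = times)
  t_env <- process_emg(triceps, config, times = times)
  vel <- angular_velocity(angle)
  sep <- if (!is.null(bpm))
    config$peak_separation_frac * 2 * 60 / bpm else NULL
  peaks <- detect_cycles(angle, min_prominence = config$peak_prominence,
                         min_separation_s = sep, bpm = bpm)
  seg <- segment_phases(angle, vel, peaks)
  structure(list(
    biceps_env = b_env, triceps_env = t_env, velocity = vel,
    segmentation = seg,
    cc = cc_by_phase(b_env, t_env, seg),
    synergy = muscle_synergy(b_env, t_env, seg),
    rom = summarize_rom(angle, vel, seg)),
    class = "trial_analysis")
}

as_trial_input <- function(trial, config) {
  if (inherits(trial, "synthetic_trial"))
    return(list(biceps = trial$biceps_raw, triceps = trial$triceps_raw,
                angle = trial$angle,
                subject = trial$subject, speed_bpm = trial$speed_bpm))
  if (is.list(trial) && !is.null(trial$emg_csv) && !is.null(trial$angle_csv)) {
    parsed <- read_trial(trial$emg_csv, trial$angle_csv, config)
    return(c(parsed, trial[c("subject", "speed_bpm")]))
  }
  if (is.list(trial) && all(c("biceps", "triceps", "angle") %in% names(trial)))
    return(trial)
  abort("each trial must be a synthetic_trial, a manifest with emg_csv/angle_csv, or a list with biceps/triceps/angle")
}

#' Run the full analysis pipeline over a set of trials
#'
#' Processes every trial with [analyze_trial()], assembles the tidy
#' coactivation, synergy and ROM tables, and — when both the phase and speed
#' factors have at least two levels — runs the factorial analysis: two-way
#' ANOVA on the subject x speed x phase cell means, Tukey HSD for both
#' factors, and Cohen's f for the phase effect. With a single speed level
#' the statistical stage is skipped with a message. Trials that fail to
#' process are dropped with a warning; an empty result set is an error.
#'
#' @param trials List of trials: `synthetic_trial` objects, manifests
#'   (lists with `emg_csv`, `angle_csv`, `subject`, `speed_bpm`) or lists
#'   with `biceps`/`triceps`/`angle` plus `subject`, `speed_bpm`.
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result`: list with
#'   `cc_table` (`subject, speed_bpm, cycle, phase, cc`),
#'   `synergy_table`, `rom_table`, `observations` (per-cell mean CC),
#'   `anova`, `tukey_phase`, `tukey_speed`, `effect_size`
#'   (`NULL` when the factorial stage is skipped), and `analyses` (the
#'   per-trial `trial_analysis` objects).
#' @export
run_pipeline <- function(trials, config = pipeline_config()) {
  if (!length(trials)) abort("need at least one trial")
  cc_rows <- list(); syn_rows <- list(); rom_rows <- list(); analyses <- list()
  for (i in seq_along(trials)) {
    res <- tryCatch({
      inp <- as_trial_input(trials[[i]], config)
      subject <- if (is.null(inp$subject)) i else inp$subject
      bpm <- if (is.null(inp$speed_bpm)) NA_real_ else inp$speed_bpm
      ana <- analyze_trial(inp$biceps, inp$triceps, inp$angle, config,
                           bpm = if (is.na(bpm)) NULL else bpm)
      list(subject = subject, bpm = bpm, ana = ana)
    }, error = function(e) {
      warning(sprintf("trial %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    ana <- res$ana
    cc <- ana$cc$per_phase
    cc$subject <- res$subject; cc$speed_bpm <- res$bpm
    cc_rows[[length(cc_rows) + 1L]] <- cc
    syn <- ana$synergy$per_cycle
    syn$subject <- res$subject; syn$speed_bpm <- res$bpm
    syn_rows[[length(syn_rows) + 1L]] <- syn
    rom_rows[[length(rom_rows) + 1L]] <- data.frame(
      subject = res$subject, speed_bpm = res$bpm,
      rom_max = ana$rom$rom_max, rom_min = ana$rom$rom_min,
      avg_sd_rom = ana$rom$avg_sd_rom,
      velocity_max = ana$rom$velocity_max,
      velocity_min = ana$rom$velocity_min,
      avg_sd_velocity = ana$rom$avg_sd_velocity)
    analyses[[length(analyses) + 1L]] <- ana
  }
  if (!length(cc_rows)) abort("no trial could be processed")
  cc_table <- do.call(rbind, cc_rows)
  cc_table <- cc_table[, c("subject", "speed_bpm", "cycle", "phase", "cc")]
  # one observation per subject x speed x phase cell: the mean over cycles
  obs <- stats::aggregate(cc ~ subject + speed_bpm + phase,
                          data = cc_table, FUN = mean)
  names(obs)[names(obs) == "speed_bpm"] <- "speed"
  anova <- tukey_phase <- tukey_speed <- effect <- NULL
  n_speeds <- length(unique(obs$speed[!is.na(obs$speed)]))
  n_phases <- length(unique(obs$phase))
  if (n_speeds >= 2 && n_phases >= 2) {
    anova <- two_way_anova(obs)
    tukey_phase <- tukey_hsd(obs, "phase")
    tukey_speed <- tukey_hsd(obs, "speed")
    effect <- cohens_f(anova, "phase", variant = config$cohens_f_variant)
  } else {
    message("factorial stage skipped: need >= 2 levels of both phase and speed")
  }
  structure(list(cc_table = cc_table,
                 synergy_table = do.call(rbind, syn_rows),
                 rom_table = do.call(rbind, rom_rows),
                 observations = obs,
                 anova = anova, tukey_phase = tukey_phase,
                 tukey_speed = tukey_speed, effect_size = effect,
                 analyses = analyses),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d trials, %d CC observations\n",
              length(x$analyses), nrow(x$cc_table)))
  agg <- stats::aggregate(cc ~ phase, data = x$observations, FUN = mean)
  agg <- agg[match(PHASE_LEVELS, agg$phase), ]
  cat("  pooled per-phase CC (%):",
      paste(sprintf("%s=%.2f", agg$phase, agg$cc), collapse = ", "), "\n")
  if (!is.null(x$anova)) {
    cat(sprintf("  phase effect: F(%d,%d) = %.2f, p = %.3g\n",
                x$anova$df[1], x$anova$df[4], x$anova$f[1], x$anova$p[1]))
  }
  invisible(x)
}
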