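# Kinematics: angular velocity, flexion-peak cycle detection, and the
# four-phase segmentation of each flexion-extension cycle.
#
# Sign convention: positive angle = flexion, 0 deg = neutral forearm position
# at 90 deg elbow flexion. A recording starts at maximum flexion, so each
# cycle runs flexion peak -> extension trough -> flexion peak and its phases
# appear in the temporal order acc_ext, dec_ext, acc_flex, dec_flex.

#' Elbow angle trace
#'
#' @param samples Elbow angle in degrees (positive = flexion; 0 deg is the
#'   neutral position at 90 deg elbow flexion).
#' @param fs Sampling rate in Hz (nominally 20, the IMU rate).
#' @param max_abs Physiological bound on `|angle|` in degrees (default 120).
#' @return An object of class `angle_trace`.
#' @export
angle_trace <- function(samples, fs = 20, max_abs = 120) {
  samples <- as.numeric(samples)
  if (!is_number(fs) || fs <= 0) abort("`fs` must be a positive number")
  if (anyNA(samples) || any(!is.finite(samples)))
    abort("angle samples must be finite")
  if (length(samples) && max(abs(samples)) > max_abs)
    abort(sprintf("angle exceeds the physiological bound of %g deg", max_abs))
  structure(list(samples = samples, fs = fs), class = "angle_trace")
}

#' @export
print.angle_trace <- function(x, ...) {
  cat(sprintf("<angle_trace> %d samples @ %g Hz, range [%.1f, %.1f] deg\n",
              length(x$samples), x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Angular velocity from an angle trace
#'
#' Time derivative of the joint angle: central finite differences in the
#' interior, one-sided differences at the record edges.
#'
#' @param angle An [angle_trace()] with at least 3 samples.
#' @return An object of class `velocity_trace` (fields `samples` in deg/s,
#'   `fs`), same length and rate as the input.
#' @export
angular_velocity <- function(angle) {
  if (!inherits(angle, "angle_trace")) abort("`angle` must be an angle_trace")
  x <- angle$samples
  n <- length(x)
  if (n < 3) abort("insufficient data: need at least 3 angle samples")
  dt <- 1 / angle$fs
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  structure(list(samples = v, fs = angle$fs), class = "velocity_trace")
}

# internal: all candidate local maxima with plateaus resolved to their first
# sample. The first sample is a candidate when the record opens descending
# (recordings begin at the prescribed maximum-flexion posture, so the opening
# sample is a genuine flexion peak). The last sample is never a candidate: a
# record ending mid-rise is an incomplete repetition.
peak_candidates <- function(x) {
  r <- rle(x)
  m <- length(r$values)
  if (m < 2) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-m]))
  v <- r$values
  keep <- logical(m)
  if (v[1] > v[2]) keep[1] <- TRUE
  if (m > 2) {
    j <- 2:(m - 1)
    keep[j] <- v[j] > v[j - 1] & v[j] > v[j + 1]
  }
  starts[keep]
}

# internal: topographic prominence of a peak at index i. Walk outward on each
# side until a strictly higher sample (or the record edge); the base on that
# side is the minimum encountered. For the first sample only the right side
# exists.
peak_prominence <- function(x, i) {
  p <- x[i]
  left_base <- if (i == 1L) -Inf else {
    seg <- x[seq_len(i - 1L)]
    higher <- which(seg > p)
    if (length(higher)) min(seg[(max(higher)):(i - 1L)]) else min(seg)
  }
  right_base <- if (i == length(x)) -Inf else {
    seg <- x[(i + 1L):length(x)]
    higher <- which(seg > p)
    if (length(higher)) min(seg[seq_len(min(higher))]) else min(seg)
  }
  p - max(left_base, right_base, -Inf)
}

#' Detect flexion peaks delimiting movement cycles
#'
#' Finds flexion peaks (local maxima of the angle trace) that delimit
#' flexion-extension cycles. A peak must have topographic prominence of at
#' least `min_prominence` times the trace's total range, and peaks closer
#' than the minimum separation are pruned keeping the higher one. When the
#' metronome rate is supplied the default separation is half the nominal
#' cycle period. Plateaus resolve to their first sample. The opening sample
#' counts as a peak when the recording starts descending from maximum
#' flexion; a record ending mid-rise contributes no final peak.
#'
#' @param angle An [angle_trace()].
#' @param min_prominence Minimum peak prominence as a fraction of the total
#'   angle range (default 0.2).
#' @param min_separation_s Minimum distance between retained peaks in
#'   seconds; defaults to `60/bpm` (half the nominal cycle period) when `bpm`
#'   is given, else 0.
#' @param bpm Optional metronome rate used to derive the default separation.
#' @return Integer vector of peak sample indices (at least 2, i.e. one
#'   complete cycle).
#' @export
detect_cycles <- function(angle, min_prominence = 0.2,
                          min_separation_s = NULL, bpm = NULL) {
  if (!inherits(angle, "angle_trace")) abort("`angle` must be an angle_trace")
  x <- angle$samples
  rng <- diff(range(x))
  if (rng <= 0) abort("no cycles: angle trace is constant")
  cand <- peak_candidates(x)
  if (length(cand)) {
    prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
    cand <- cand[prom >= min_prominence * rng]
  }
  if (is.null(min_separation_s))
    min_separation_s <- if (!is.null(bpm)) 60 / bpm else 0
  min_sep <- min_separation_s * angle$fs
  if (length(cand) > 1 && min_sep > 0) {
    ord <- cand[order(x[cand], cand, decreasing = c(TRUE, FALSE), method = "radix")]
    kept <- integer(0)
    for (i in ord) if (!length(kept) || all(abs(kept - i) >= min_sep))
      kept <- c(kept, i)
    cand <- sort(kept)
  }
  if (length(cand) < 2)
    abort("no cycles: fewer than two qualifying flexion peaks")
  cand
}

#' Segment cycles into acceleration/deceleration phases
#'
#' Splits each peak-to-peak cycle at the extension trough (minimum angle)
#' into its extension and flexion halves, then splits each half at its
#' angular-velocity extremum: the acceleration phase runs from the angle
#' extremum to peak angular speed, the deceleration phase from peak speed to
#' the next angle extremum. Ties and plateaus resolve to the earliest sample.
#' Half-cycles without an interior velocity extremum are degenerate; the
#' whole cycle is excluded with a warning.
#'
#' @param angle An [angle_trace()].
#' @param velocity The [angular_velocity()] of the same trace.
#' @param cycles Peak indices from [detect_cycles()].
#' @return An object of class `cycle_segmentation`: a list with
#'   `phases` (data frame `cycle, phase, start, end` of half-open sample
#'   intervals `[start, end)` in temporal order), `peaks`, `troughs`, `fs`.
#' @export
segment_phases <- function(angle, velocity, cycles) {
  if (!inherits(angle, "angle_trace")) abort("`angle` must be an angle_trace")
  if (!inherits(velocity, "velocity_trace") ||
      length(velocity$samples) != length(angle$samples))
    abort("`velocity` must be the velocity_trace of the same angle trace")
  x <- angle$samples
  v <- velocity$samples
  cycles <- as.integer(cycles)
  rows <- list()
  troughs <- integer(0)
  peaks_kept <- integer(0)
  cyc_id <- 0L
  for (k in seq_len(length(cycles) - 1L)) {
    p1 <- cycles[k]; p2 <- cycles[k + 1L]
    trough <- p1 - 1L + which.min(x[p1:p2])
    if (trough - p1 < 2L || p2 - trough < 2L) {
      warning(sprintf("degenerate cycle %d excluded (no interior velocity extremum)", k))
      next
    }
    v_ext <- p1 + which.min(v[(p1 + 1L):(trough - 1L)])        # extension speed peak
    v_flex <- trough + which.max(v[(trough + 1L):(p2 - 1L)])   # flexion speed peak
    cyc_id <- cyc_id + 1L
    rows[[cyc_id]] <- data.frame(
      cycle = cyc_id,
      phase = CYCLE_PHASE_ORDER,
      start = c(p1, v_ext, trough, v_flex),
      end   = c(v_ext, trough, v_flex, p2))
    troughs <- c(troughs, trough)
    peaks_kept <- c(peaks_kept, p1, p2)
  }
  if (!cyc_id) abort("no complete cycles after excluding degenerate ones")
  structure(list(phases = do.call(rbind, rows),
                 peaks = sort(unique(peaks_kept)),
                 troughs = troughs,
                 fs = angle$fs),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("<cycle_segmentation> %d cycles x 4 phases @ %g Hz\n",
              max(x$phases$cycle), x$fs))
  invisible(x)
}

#' Number of cycles in a segmentation
#' @param seg A `cycle_segmentation`.
#' @return Integer cycle count.
#' @export
n_cycles <- function(seg) {
  if (!inherits(seg, "cycle_segmentation"))
    abort("`seg` must be a cycle_segmentation")
  max(seg$phases$cycle)
}

#' Time-normalize cycles onto a common grid
#'
#' Linearly resamples each cycle (peak to peak, endpoints included) onto
#' `n_points` equally spaced points of normalized cycle time, so cycles of
#' different duration can be averaged point-by-point.
#'
#' @param x Numeric vector, [angle_trace()] or `velocity_trace` on the
#'   segmentation's sample grid.
#' @param seg A [segment_phases()] result.
#' @param n_points Grid size (default 100).
#' @return Matrix with one row per cycle and `n_points` columns.
#' @export
time_normalize_cycles <- function(x, seg, n_points = 100) {
  if (inherits(x, "angle_trace") || inherits(x, "velocity_trace")) x <- x$samples
  if (!inherits(seg, "cycle_segmentation"))
    abort("`seg` must be a cycle_segmentation")
  if (!is_number(n_points) || n_points < 2)
    abort("`n_points` must be an integer >= 2")
  ph <- seg$phases
  out <- matrix(NA_real_, nrow = max(ph$cycle), ncol = n_points)
  for (c_id in seq_len(max(ph$cycle))) {
    rows <- ph[ph$cycle == c_id, ]
    idx <- min(rows$start):max(rows$end)   # closed cycle, endpoints preserved
    out[c_id, ] <- stats::approx(seq_along(idx), x[idx],
                                 xout = seq(1, length(idx), length.out = n_points))$y
  }
  out
}

#' Range-of-motion and angular-velocity summary
#'
#' Per-trial kinematic summary: the mean flexion-peak and extension-trough
#' angle (averaged over the peaks/troughs bounding the complete cycles),
#' the mean over cycles of the per-cycle velocity maximum/minimum, plus the
#' mean across-cycle
#' standard deviation of the time-normalized angle and velocity profiles (a
#' point-wise SD on a 100-point normalized cycle, then averaged over points;
#' higher values indicate less consistent execution).
#'
#' @param angle An [angle_trace()].
#' @param velocity Its [angular_velocity()].
#' @param seg A [segment_phases()] result.
#' @param n_points Time-normalization grid size (default 100).
#' @return An object of class `rom_summary` with fields `rom_max`, `rom_min`,
#'   `avg_sd_rom`, `velocity_max`, `velocity_min`, `avg_sd_velocity`,
#'   `n_cycles`.
#' @export
summarize_rom <- function(angle, velocity, seg, n_points = 100) {
  if (!inherits(seg, "cycle_segmentation"))
    abort("`seg` must be a cycle_segmentation")
  ph <- seg$phases
  ids <- seq_len(max(ph$cycle))
  per_cycle <- function(x, fun) vapply(ids, function(c_id) {
    rows <- ph[ph$cycle == c_id, ]
    fun(x[min(rows$start):max(rows$end)])
  }, numeric(1))
  x <- angle$samples
  v <- velocity$samples
  a_mat <- time_normalize_cycles(x, seg, n_points)
  v_mat <- time_normalize_cycles(v, seg, n_points)
  point_sd <- function(m) if (nrow(m) > 1) mean(apply(m, 2, stats::sd)) else 0
  structure(list(
    rom_max = mean(x[seg$peaks]),
    rom_min = mean(x[seg$troughs]),
    avg_sd_rom = point_sd(a_mat),
    velocity_max = mean(per_cycle(v, max)),
    velocity_min = mean(per_cycle(v, min)),
    avg_sd_velocity = point_sd(v_mat),
    n_cycles = length(ids)),
    class = "rom_summary")
}

#' @export
print.rom_summary <- function(x, ...) {
  cat(sprintf(
    "<rom_summary> %d cycles\n  ROM [%.2f, %.2f] deg (avg point SD %.2f)\n  velocity [%.2f, %.2f] deg/s (avg point SD %.2f)\n",
    x$n_cycles, x$rom_max, x$rom_min, x$avg_sd_rom,
    x$velocity_max, x$velocity_min, x$avg_sd_velocity))
  invisible(x)
}
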