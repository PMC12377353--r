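# Coactivation coefficient (Falconer-Winter common-area formulation) and
# muscle-synergy area shares, evaluated per cycle and per movement phase.
#
# The common area of the two envelopes is the integral of their pointwise
# minimum; all integrals use the trapezoidal rule on the envelope grid.
# Because each phase interval [start, end) is integrated over the closed
# sample span start..end, phase integrals tile the cycle exactly and the sum
# of phase integrals equals the full-cycle integral.

env_values <- function(x, name) {
  if (inherits(x, "envelope_signal")) x$samples
  else if (is.numeric(x)) as.numeric(x)
  else abort(sprintf("`%s` must be numeric or an envelope_signal", name))
}

trapz_idx <- function(y, idx, dt) pracma::trapz(idx * dt, y[idx])

#' Coactivation coefficient of two aligned envelope segments
#'
#' The coactivation coefficient (CC) quantifies simultaneous
#' agonist-antagonist activation as
#' `CC = 2 * common / (area_ag + area_antag) * 100`,
#' where the areas are the integrals of the two activity envelopes over the
#' segment and the common area is the integral of their pointwise minimum.
#' The result lies in \[0, 100\]: 0 for disjoint activation, 100 for
#' identical envelopes. The formula is symmetric in its two arguments. A
#' segment in which both envelopes are identically zero returns 0 so that
#' quiet phases do not poison aggregates.
#'
#' @param ag,antag Equal-length non-negative numeric vectors (or
#'   [envelope_signal()] objects) on a common uniform time grid.
#' @param fs Sampling rate of the grid in Hz (default 20). The CC is a ratio
#'   of integrals and does not depend on `fs`; the argument exists for
#'   interface symmetry with the rest of the package.
#' @return CC in percent.
#' @export
#' @examples
#' coactivation_coefficient(rep(1, 21), rep(0.5, 21))  # 2*0.5/1.5*100 = 66.67
coactivation_coefficient <- function(ag, antag, fs = 20) {
  a <- env_values(ag, "ag")
  b <- env_values(antag, "antag")
  if (length(a) != length(b))
    abort("alignment error: envelope segments differ in length")
  if (length(a) < 2) abort("segment too short: need at least 2 samples")
  if (min(a) < 0 || min(b) < 0)
    abort("contract violation: envelopes must be non-negative")
  dt <- 1 / fs
  idx <- seq_along(a)
  area_a <- trapz_idx(a, idx, dt)
  area_b <- trapz_idx(b, idx, dt)
  if (area_a + area_b == 0) return(0)
  cc <- 200 * trapz_idx(pmin(a, b), idx, dt) / (area_a + area_b)
  min(max(cc, 0), 100)
}

#' Coactivation coefficient per cycle and per phase
#'
#' Evaluates the coactivation coefficient on every phase interval and on
#' every full cycle of a segmentation. The biceps is the agonist during the
#' flexion phases and the triceps during extension; the CC itself is
#' symmetric, so the labelling affects reporting only.
#'
#' @param biceps,triceps Conditioned [envelope_signal()] objects (or numeric
#'   vectors) aligned to the angle grid used for `seg`.
#' @param seg A [segment_phases()] result.
#' @return An object of class `coactivation_result`: list with `per_phase`
#'   (data frame `cycle, phase, cc`), `per_cycle` (`cycle, cc`), and
#'   `summary` (`phase, mean_cc, sd_cc` in reporting order).
#' @export
cc_by_phase <- function(biceps, triceps, seg) {
  if (!inherits(seg, "cycle_segmentation"))
    abort("`seg` must be a cycle_segmentation")
  b <- env_values(biceps, "biceps")
  t_ <- env_values(triceps, "triceps")
  if (length(b) != length(t_))
    abort("alignment error: biceps and triceps envelopes differ in length")
  if (max(seg$phases$end) > length(b))
    abort("alignment error: envelopes shorter than the segmented record")
  fs <- seg$fs
  ph <- seg$phases
  cc_one <- function(start, end) {
    idx <- start:end
    if (length(idx) < 2) return(NA_real_)
    coactivation_coefficient(b[idx], t_[idx], fs = fs)
  }
  per_phase <- ph[, c("cycle", "phase")]
  per_phase$cc <- mapply(cc_one, ph$start, ph$end)
  if (anyNA(per_phase$cc)) {
    warning("empty phase interval(s) skipped")
    per_phase <- per_phase[!is.na(per_phase$cc), ]
  }
  ids <- sort(unique(ph$cycle))
  per_cycle <- data.frame(
    cycle = ids,
    cc = vapply(ids, function(c_id) {
      rows <- ph[ph$cycle == c_id, ]
      cc_one(min(rows$start), max(rows$end))
    }, numeric(1)))
  agg <- lapply(PHASE_LEVELS, function(p) {
    v <- per_phase$cc[per_phase$phase == p]
    data.frame(phase = p, mean_cc = mean(v),
               sd_cc = if (length(v) > 1) stats::sd(v) else NA_real_)
  })
  structure(list(per_phase = per_phase, per_cycle = per_cycle,
                 summary = do.call(rbind, agg)),
            class = "coactivation_result")
}

#' @export
print.coactivation_result <- function(x, ...) {
  cat("<coactivation_result>\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s CC = %5.2f%% (SD %.2f)\n",
                s$phase[i], s$mean_cc[i], s$sd_cc[i]))
  cat(sprintf("  full cycle CC = %.2f%% (mean over %d cycles)\n",
              mean(x$per_cycle$cc), nrow(x$per_cycle)))
  invisible(x)
}

#' Muscle-synergy area shares
#'
#' For each muscle and cycle, the share of that muscle's envelope area that
#' falls in the flexion phases versus the extension phases, in percent (the
#' two shares sum to 100 per muscle). This is an area-share statistic, not a
#' factorization-based synergy. A secondary between-muscle decomposition
#' (each muscle's share of the summed activity within the flexion and within
#' the extension phases) is also returned, since both views are informative
#' for an antagonist pair. A muscle with zero total area in a cycle yields
#' `NA` shares for that cycle.
#'
#' @inheritParams cc_by_phase
#' @return An object of class `synergy_result`: list with `per_cycle`
#'   (data frame `cycle, muscle, flexion_pct, extension_pct`),
#'   `within_phase` (`cycle, phase_group, biceps_pct, triceps_pct`), and
#'   `summary` (mean/SD of the per-muscle shares).
#' @export
muscle_synergy <- function(biceps, triceps, seg) {
  if (!inherits(seg, "cycle_segmentation"))
    abort("`seg` must be a cycle_segmentation")
  b <- env_values(biceps, "biceps")
  t_ <- env_values(triceps, "triceps")
  if (length(b) != length(t_))
    abort("alignment error: biceps and triceps envelopes differ in length")
  dt <- 1 / seg$fs
  ph <- seg$phases
  flex_phases <- c("acc_flex", "dec_flex")
  ids <- sort(unique(ph$cycle))
  area <- function(x, rows) sum(vapply(seq_len(nrow(rows)), function(i) {
    idx <- rows$start[i]:rows$end[i]
    trapz_idx(x, idx, dt)
  }, numeric(1)))
  per_cycle <- list(); within <- list()
  for (c_id in ids) {
    rows <- ph[ph$cycle == c_id, ]
    fl <- rows[rows$phase %in% flex_phases, ]
    ex <- rows[!(rows$phase %in% flex_phases), ]
    ab <- c(flex = area(b, fl), ext = area(b, ex))
    at <- c(flex = area(t_, fl), ext = area(t_, ex))
    share <- function(a) if (sum(a) > 0) 100 * a / sum(a) else c(flex = NA_real_, ext = NA_real_)
    sb <- share(ab); st <- share(at)
    per_cycle[[length(per_cycle) + 1L]] <- data.frame(
      cycle = c_id, muscle = c("biceps", "triceps"),
      flexion_pct = c(sb[["flex"]], st[["flex"]]),
      extension_pct = c(sb[["ext"]], st[["ext"]]))
    btot <- function(i) {
      tot <- ab[[i]] + at[[i]]
      if (tot > 0) 100 * c(ab[[i]], at[[i]]) / tot else c(NA_real_, NA_real_)
    }
    wf <- btot("flex"); we <- btot("ext")
    within[[length(within) + 1L]] <- data.frame(
      cycle = c_id, phase_group = c("flexion", "extension"),
      biceps_pct = c(wf[1], we[1]), triceps_pct = c(wf[2], we[2]))
  }
  per_cycle <- do.call(rbind, per_cycle)
  summ <- do.call(rbind, lapply(c("biceps", "triceps"), function(m) {
    v <- per_cycle[per_cycle$muscle == m, ]
    data.frame(muscle = m,
               mean_flexion_pct = mean(v$flexion_pct, na.rm = TRUE),
               sd_flexion_pct = stats::sd(v$flexion_pct, na.rm = TRUE),
               mean_extension_pct = mean(v$extension_pct, na.rm = TRUE),
               sd_extension_pct = stats::sd(v$extension_pct, na.rm = TRUE))
  }))
  structure(list(per_cycle = per_cycle,
                 within_phase = do.call(rbind, within),
                 summary = summ),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("<synergy_result>\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-7s flexion %5.1f%% / extension %5.1f%%\n",
                s$muscle[i], s$mean_flexion_pct[i], s$mean_extension_pct[i]))
  invisible(x)
}
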