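test_that("angular velocity matches analytic derivatives", {
  const <- angular_velocity(angle_trace(rep(10, 50), 20))
  expect_true(all(const$samples == 0))

  # linear ramp a*t: central differences are exact
  a <- 12.5
  t <- (0:99) / 20
  ramp <- angular_velocity(angle_trace(a * t, 20))
  expect_equal(ramp$samples, rep(a, 100))

  # sinusoid: amplitude within 2% of 2*pi*f*A for f <= 1 Hz
  for (f in c(0.5, 1)) {
    A <- 60
    v <- angular_velocity(angle_trace(A * sin(2 * pi * f * t), 20))
    expect_equal(max(abs(v$samples[5:95])), 2 * pi * f * A, tolerance = 0.02)
  }

  expect_error(angular_velocity(angle_trace(c(1, 2), 20)), "at least 3")
})

test_that("cycle detection finds the flexion peaks of a rhythmic trace", {
  angle <- generate_angle_trace(rigid_protocol(bpm = 60, n_cycles = 10))
  peaks <- detect_cycles(angle, bpm = 60)
  expect_length(peaks, 10)
  expect_equal(peaks, seq(1, 361, by = 40))

  expect_error(detect_cycles(angle_trace((1:100) / 2, 20)), "no cycles")
  expect_error(detect_cycles(angle_trace(rep(5, 100), 20)), "no cycles")
})

test_that("low-prominence ripples are not counted as cycle peaks", {
  # two genuine peaks with a small bump between them; the bump's prominence
  # (checked by brute force below) is under 20% of the range
  t <- (0:160) / 20
  base <- 70 * cos(2 * pi * t / 4)
  bump <- 8 * exp(-((t - 2)^2) / 0.02)
  x <- angle_trace(base + bump, 20)
  peaks <- detect_cycles(x)
  # crests at t = 0 and t = 4 only: the record ends on the t = 8 crest, which
  # is never counted, and the bump is below the prominence threshold
  expect_length(peaks, 2)
  # brute force: the bump is a local maximum but its drop to the surrounding
  # valley floor is < 0.2 * range
  i_bump <- which.max(bump)
  expect_true(x$samples[i_bump] > x$samples[i_bump - 1] &&
                x$samples[i_bump] > x$samples[i_bump + 1])
  rng <- diff(range(x$samples))
  local_drop <- x$samples[i_bump] - min(x$samples[(i_bump - 10):(i_bump + 10)])
  expect_lt(local_drop, 0.2 * rng)
})

test_that("phase boundaries sit at angle and velocity extrema", {
  for (bpm in c(42, 60, 78)) {
    p <- rigid_protocol(bpm = bpm, n_cycles = 10)
    angle <- generate_angle_trace(p)
    vel <- angular_velocity(angle)
    seg <- segment_phases(angle, vel, detect_cycles(angle, bpm = bpm))
    truth <- simulate_trial(p, seed = 1)$truth_segmentation
    expect_equal(nrow(seg$phases), nrow(truth$phases))
    expect_lte(max(abs(seg$phases$start - truth$phases$start)), 1)
    expect_lte(max(abs(seg$phases$end - truth$phases$end)), 1)

    # cosinusoidal half-cycles: acceleration and deceleration sub-phases of
    # each half have equal length within one sample
    len <- seg$phases$end - seg$phases$start
    acc <- len[seg$phases$phase %in% c("acc_ext", "acc_flex")]
    dec <- len[seg$phases$phase %in% c("dec_ext", "dec_flex")]
    expect_lte(max(abs(acc - dec)), 1)
  }
})

test_that("plateaus at extrema resolve to the earliest sample", {
  # cosine cycles clipped into ~7-sample flat tops at each crest
  t <- (0:200) / 20
  x <- pmin(70 * cos(2 * pi * t / 4), 68)
  ang <- angle_trace(x, 20)
  peaks <- detect_cycles(ang)
  expect_length(peaks, 3)           # crests at t = 0, 4, 8; t = 10 ends mid-fall
  for (pk in peaks[-1]) {           # interior peaks start their plateau
    expect_equal(x[pk], 68)
    expect_lt(x[pk - 1], 68)
    expect_equal(x[pk + 1], 68)
  }
})

test_that("phases tile each cycle and respect the velocity sign convention", {
  trial <- simulate_trial(movement_protocol(bpm = 78, n_cycles = 8), seed = 21)
  angle <- trial$angle
  vel <- angular_velocity(angle)
  seg <- segment_phases(angle, vel, detect_cycles(angle, bpm = 78))
  ph <- seg$phases
  for (c_id in unique(ph$cycle)) {
    rows <- ph[ph$cycle == c_id, ]
    expect_equal(rows$phase, c("acc_ext", "dec_ext", "acc_flex", "dec_flex"))
    expect_equal(rows$start[-1], rows$end[-4])   # contiguous, no gaps/overlap
    expect_true(all(rows$end > rows$start))      # non-empty
  }
  mean_v <- vapply(seq_len(nrow(ph)), function(i)
    mean(vel$samples[ph$start[i]:(ph$end[i] - 1)]), numeric(1))
  expect_true(all(mean_v[ph$phase %in% c("acc_flex", "dec_flex")] > 0))
  expect_true(all(mean_v[ph$phase %in% c("acc_ext", "dec_ext")] < 0))

  # segmentation is invariant to adding a constant to the angle
  shifted <- angle_trace(angle$samples + 15, angle$fs)
  seg2 <- segment_phases(shifted, angular_velocity(shifted),
                         detect_cycles(shifted, bpm = 78))
  expect_equal(seg2$phases, ph)
})

test_that("ROM summary averages peak angles and tracks execution variability", {
  # a record whose detected flexion peaks are 70 and 80 degrees
  t1 <- seq(0, 2, by = 0.05); t2 <- seq(0.05, 2, by = 0.05)
  x <- c(10 + 60 * cos(pi * t1 / 2),            # 70 down to -50
         15 + 65 * -cos(pi * t2 / 2))           # up to 80, then partial fall
  ang <- angle_trace(c(x, 80 - 30 * (t2 / 2)^2), 20)
  vel <- angular_velocity(ang)
  seg <- segment_phases(ang, vel, detect_cycles(ang))
  rom <- summarize_rom(ang, vel, seg)
  expect_equal(rom$rom_max, 75)                  # mean of peaks 70 and 80
  expect_equal(rom$rom_min, -50, tolerance = 1e-6)

  # identical cycles -> zero across-cycle variability
  trial <- simulate_trial(rigid_protocol(), seed = 2)
  a2 <- trial$angle; v2 <- angular_velocity(a2)
  seg2 <- segment_phases(a2, v2, detect_cycles(a2, bpm = 60))
  rom2 <- summarize_rom(a2, v2, seg2)
  expect_lt(rom2$avg_sd_rom, 1e-8)
  expect_gt(rom2$rom_max, rom2$rom_min)

  # velocity variability grows with cycle-timing jitter (Monte Carlo)
  sd_at <- function(jit) {
    vals <- vapply(1:4, function(s) {
      tr <- simulate_trial(movement_protocol(bpm = 60, cycle_jitter = jit),
                           seed = 100 + s)
      a <- tr$angle; v <- angular_velocity(a)
      sg <- segment_phases(a, v, detect_cycles(a, bpm = 60))
      summarize_rom(a, v, sg)$avg_sd_velocity
    }, numeric(1))
    mean(vals)
  }
  sds <- vapply(c(0, 0.04, 0.1), sd_at, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("time normalization preserves endpoints and degenerate cases", {
  trial <- simulate_trial(rigid_protocol(n_cycles = 3), seed = 3)
  a <- trial$angle; v <- angular_velocity(a)
  seg <- segment_phases(a, v, detect_cycles(a, bpm = 60))
  m <- time_normalize_cycles(a, seg, n_points = 100)
  ph <- seg$phases
  for (c_id in unique(ph$cycle)) {
    rows <- ph[ph$cycle == c_id, ]
    expect_equal(m[c_id, 1], a$samples[min(rows$start)])
    expect_equal(m[c_id, 100], a$samples[max(rows$end)])
  }
  # identical cycles: per-point SD is zero and the mean equals any one cycle
  expect_lt(max(apply(m, 2, sd)), 1e-9)
  expect_equal(colMeans(m), m[1, ])
})
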