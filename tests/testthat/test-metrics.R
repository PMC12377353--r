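test_that("the coactivation coefficient reproduces its analytic cases", {
  n <- 41
  expect_equal(coactivation_coefficient(rep(0.8, n), rep(0.8, n)), 100,
               tolerance = 1e-9)
  a <- c(rep(1, 20), rep(0, 21))
  expect_equal(coactivation_coefficient(a, rev(a)), 0, tolerance = 1e-9)
  expect_equal(coactivation_coefficient(rep(1, n), rep(0.5, n)), 200 / 3,
               tolerance = 1e-9)
  expect_equal(coactivation_coefficient(rep(0, n), rep(0, n)), 0)
})

test_that("the coactivation coefficient enforces its contracts", {
  expect_error(coactivation_coefficient(1:5 / 5, 1:4 / 4), "alignment error")
  expect_error(coactivation_coefficient(c(-0.1, 0.2, 0.1), c(0, 0.1, 0)),
               "non-negative")
})

test_that("CC is symmetric, scale-invariant, and monotone in one-sided scaling", {
  set.seed(5)
  for (rep in 1:5) {
    a <- abs(sin(seq(0, 3 * pi, length.out = 80))) * runif(1, 0.5, 2)
    b <- abs(cos(seq(0, 3 * pi, length.out = 80))) * runif(1, 0.5, 2)
    expect_equal(coactivation_coefficient(a, b), coactivation_coefficient(b, a))
    k <- runif(1, 0.1, 10)
    expect_equal(coactivation_coefficient(k * a, k * b),
                 coactivation_coefficient(a, b), tolerance = 1e-12)
  }
  # scaling only one envelope: CC -> 0 as k -> 0 and approaches the
  # min-dominated limit monotonically as k grows
  a <- abs(sin(seq(0, 2 * pi, length.out = 60)))
  b <- abs(cos(seq(0, 2 * pi, length.out = 60)))
  ks <- c(1e-4, 0.01, 0.1, 0.5, 1)
  ccs <- vapply(ks, function(k) coactivation_coefficient(a, k * b), numeric(1))
  expect_true(all(diff(ccs) > 0))
  expect_lt(ccs[1], 0.05)
})

test_that("trapezoidal CC agrees with a dense brute-force evaluation", {
  t <- seq(0, 10, by = 1 / 2000)
  a <- (1 + sin(2 * pi * 0.5 * t)) / 2
  b <- (1 + cos(2 * pi * 0.5 * t + 0.7)) / 3
  got <- coactivation_coefficient(a, b, fs = 2000)
  expect_equal(got, oracle_cc(t, a, b), tolerance = 1e-6)
})

test_that("per-phase CC matches ground truth and phase concatenation is exact", {
  model <- activation_model(antagonist_frac = c(acc_flex = 0.2, dec_flex = 0.5,
                                                acc_ext = 0.2, dec_ext = 0.2),
                            tonic_triceps = 0)
  trial <- simulate_trial(rigid_protocol(), model = model, seed = 8)
  # flexion-deceleration coactivation dominates by construction
  cc <- trial$truth_cc
  expect_true(cc[["dec_flex"]] > max(cc[c("acc_flex", "acc_ext", "dec_ext")]))

  # pipeline estimate recovers the per-phase ground truth of a slow trial
  slow <- simulate_trial(rigid_protocol(bpm = 42), seed = 9)
  res <- analyze_trial(slow$biceps_raw, slow$triceps_raw, slow$angle, bpm = 42)
  est <- setNames(res$cc$summary$mean_cc, res$cc$summary$phase)
  expect_lt(max(abs(est[names(slow$truth_cc)] - slow$truth_cc)), 5)

  # all-silent antagonist: every phase CC is zero
  silent <- activation_model(antagonist_frac = c(acc_flex = 0, dec_flex = 0,
                                                 acc_ext = 0, dec_ext = 0),
                             tonic_triceps = 0)
  tr0 <- simulate_trial(rigid_protocol(n_cycles = 3), model = silent, seed = 2)
  env <- tr0$envelopes
  b <- env$biceps
  b[env$triceps > 0] <- 0   # make supports strictly disjoint
  cc0 <- cc_by_phase(b, env$triceps, tr0$truth_segmentation)
  expect_true(all(cc0$per_phase$cc == 0))

  # sum-of-integrals convention: full-cycle CC equals the CC assembled from
  # the four phase integrals (brute-force trapezoid oracle)
  seg <- trial$truth_segmentation
  envs <- trial$envelopes
  bb <- envs$biceps / max(envs$biceps)
  tt <- envs$triceps / max(envs$triceps)
  dt <- 1 / seg$fs
  ph <- seg$phases[seg$phases$cycle == 2, ]
  piecewise <- function(x) sum(vapply(seq_len(4), function(i) {
    idx <- ph$start[i]:ph$end[i]
    oracle_trapz(idx * dt, x[idx])
  }, numeric(1)))
  full_idx <- min(ph$start):max(ph$end)
  cc_pieces <- 200 * piecewise(pmin(bb, tt)) / (piecewise(bb) + piecewise(tt))
  cc_full <- coactivation_coefficient(bb[full_idx], tt[full_idx], seg$fs)
  expect_equal(cc_pieces, cc_full, tolerance = 1e-12)
})

test_that("synergy area shares split each muscle across flexion and extension", {
  # biceps active only in flexion: share (100, 0); per-muscle shares sum to 100
  model <- activation_model(antagonist_frac = c(acc_flex = 0, dec_flex = 0,
                                                acc_ext = 0, dec_ext = 0),
                            tonic_triceps = 0)
  trial <- simulate_trial(rigid_protocol(n_cycles = 4), model = model, seed = 4)
  env <- trial$envelopes
  syn <- muscle_synergy(env$biceps, env$triceps, trial$truth_segmentation)
  bic <- syn$per_cycle[syn$per_cycle$muscle == "biceps", ]
  expect_true(all(abs(bic$flexion_pct - 100) < 1e-9))
  expect_true(all(abs(bic$flexion_pct + bic$extension_pct - 100) < 1e-9))

  # tonic-only triceps: its flexion share equals the flexion share of the
  # cycle's duration (closed form for a constant envelope)
  tonic_model <- activation_model(antagonist_frac = c(acc_flex = 0, dec_flex = 0,
                                                      acc_ext = 0, dec_ext = 0),
                                  tonic_triceps = 0.1, agonist_peak = 1e-12)
  tr2 <- simulate_trial(rigid_protocol(n_cycles = 4), model = tonic_model, seed = 4)
  seg <- tr2$truth_segmentation
  syn2 <- muscle_synergy(tr2$envelopes$biceps, tr2$envelopes$triceps, seg)
  tri <- syn2$per_cycle[syn2$per_cycle$muscle == "triceps", ]
  ph <- seg$phases
  for (c_id in tri$cycle) {
    rows <- ph[ph$cycle == c_id, ]
    dur <- rows$end - rows$start
    flex_share <- 100 * sum(dur[rows$phase %in% c("acc_flex", "dec_flex")]) / sum(dur)
    expect_equal(tri$flexion_pct[tri$cycle == c_id], flex_share, tolerance = 0.2)
  }

  # mirrored activation: biceps and triceps synergies are mirror images
  sym_model <- activation_model(antagonist_frac = c(acc_flex = 0.3, dec_flex = 0.3,
                                                    acc_ext = 0.3, dec_ext = 0.3),
                                tonic_triceps = 0)
  tr3 <- simulate_trial(rigid_protocol(n_cycles = 4), model = sym_model, seed = 6)
  syn3 <- muscle_synergy(tr3$envelopes$biceps, tr3$envelopes$triceps,
                         tr3$truth_segmentation)
  s3 <- syn3$summary
  expect_equal(s3$mean_flexion_pct[s3$muscle == "biceps"],
               s3$mean_extension_pct[s3$muscle == "triceps"], tolerance = 0.005)

  # a silent muscle has undefined (NA) shares
  zero <- rep(0, length(tr3$envelopes$biceps))
  syn4 <- muscle_synergy(zero, tr3$envelopes$triceps, tr3$truth_segmentation)
  expect_true(all(is.na(syn4$per_cycle$flexion_pct[syn4$per_cycle$muscle == "biceps"])))
})
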