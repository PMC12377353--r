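# Shared fixtures, built in code at test time.

# jitter-free protocol at a study speed
rigid_protocol <- function(bpm = 60, n_cycles = 10, ...) {
  movement_protocol(bpm = bpm, n_cycles = n_cycles, cycle_jitter = 0, ...)
}

# envelope_signal at a given stage without running the earlier stages
staged_envelope <- function(samples, fs = 20, stage = "oversampled") {
  envelope_signal(samples, fs = fs, stage = stage)
}

# single-pass magnitude response of the package's Butterworth design at
# frequency f (Hz): independent polynomial evaluation of H(z) on the unit
# circle, used as the oracle for filter tests
butter_magnitude <- function(order, band, fs, f) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * f / fs)
  vapply(z, function(zz) {
    num <- sum(bf$b * zz^(0:(length(bf$b) - 1)))
    den <- sum(bf$a * zz^(0:(length(bf$a) - 1)))
    Mod(num / den)
  }, numeric(1))
}

# steady-state amplitude of a (possibly filtered) sinusoidal record,
# ignoring the first and last quarter to avoid filter transients
steady_amplitude <- function(x) {
  n <- length(x)
  max(abs(x[seq.int(floor(n / 4), ceiling(3 * n / 4))]))
}

# brute-force trapezoid integral used as an independent oracle
oracle_trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# independent Eq.-1 evaluation from raw sums (oracle path)
oracle_cc <- function(t, a, b) {
  200 * oracle_trapz(t, pmin(a, b)) / (oracle_trapz(t, a) + oracle_trapz(t, b))
}
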