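# Independent oracles, deliberately written as naive loops / closed forms so
# they share no code path with the package implementation.

# naive O(n) complex summation phasor
oracle_phasor <- function(signal, harmonic = 1) {
  n <- length(signal)
  acc <- complex(real = 0, imaginary = 0)
  tot <- 0
  for (k in seq_len(n)) {
    ang <- 2 * pi * harmonic * (k - 1) / n
    acc <- acc + signal[k] * complex(real = cos(ang), imaginary = sin(ang))
    tot <- tot + signal[k]
  }
  acc / tot
}

# continuous-limit phasor of exp(-t/tau) over duration T: with w = 2*pi/T,
# G = (1, i w tau) / (1 + (w tau)^2) for T >> tau
oracle_continuous <- function(tau, duration) {
  wt <- 2 * pi * tau / duration
  complex(real = 1 / (1 + wt^2), imaginary = wt / (1 + wt^2))
}

# unit-sum mono-exponential profile on an axis
mono_profile <- function(axis, tau) {
  p <- exp(-axis$values / tau)
  p / sum(p)
}

# linear solve for barycentric fractions (oracle for unmix_three)
oracle_barycentric <- function(p, coords) {
  A <- rbind(t(coords), rep(1, 3))
  as.vector(solve(A, c(p, 1)))
}

axis64 <- function() sampled_axis(7.23 * (1:64), "echo_time")
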