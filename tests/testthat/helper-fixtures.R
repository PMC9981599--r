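# shared fixtures and independent brute-force oracles

# brute-force Eq-style oracles, written directly from the definitions
plv_brute <- function(phi, psi) {
  Mod(sum(exp(1i * (phi - psi)))) / length(phi)
}
itc_brute <- function(phase_trials) {
  Mod(sum(exp(1i * phase_trials))) / length(phase_trials)
}

# closed-form PDC of a VAR written independently of pdc_from_var
pdc_brute <- function(A, f, fs) {
  p <- dim(A)[3]
  Abar <- diag(2) + 0i
  for (k in seq_len(p)) Abar <- Abar - A[, , k] * exp(-2i * pi * f * k / fs)
  M <- Mod(Abar)
  t(t(M) / sqrt(colSums(M^2)))
}

# stable bivariate VAR(5) ground truth used in order-recovery tests
var5_truth <- function() {
  A <- array(0, c(2, 2, 5))
  A[, , 1] <- matrix(c(0.3, 0.2, 0.1, 0.25), 2)
  A[, , 5] <- matrix(c(0.25, 0.15, -0.1, 0.2), 2)
  A
}

# small, fast dyad: 60 s at 128 Hz
quick_sim_config <- function(seed = 1, duration = 60, ...) {
  sim_config(seed = seed, duration = duration, fs = 128, ...)
}

# hand-built gaze timeline from run-length pairs, e.g. list(c("puppet", 3), ...)
make_timeline <- function(role, runs, frame_rate = 50) {
  states <- unlist(lapply(runs, function(r)
    rep(r[[1]], round(as.numeric(r[[2]]) * frame_rate))))
  structure(list(role = role, states = states, frame_rate = frame_rate,
                 duration = length(states) / frame_rate),
            class = "gaze_timeline")
}

# drifting-oscillator phase series (the synthetic world's phase model)
drift_phase <- function(n, fs, f = 4, drift_sd = 1.5) {
  2 * pi * f * seq_len(n) / fs + cumsum(rnorm(n, 0, drift_sd / sqrt(fs))) +
    runif(1, -pi, pi)
}
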