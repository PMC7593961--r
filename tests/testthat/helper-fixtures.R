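# Shared fixtures, built in code at test time.

# Averaged response containing Gaussian-windowed biphasic deflections with
# known peak-trough amplitudes (nV) and peak latencies (ms).
make_biphasic_response <- function(amps = c(I = 150), lats = c(I = 1.8),
                                   widths = c(I = 0.5), fs = 16384,
                                   window = c(-0.003, 0.012), noise_var = 0,
                                   offset = 0, n_epochs = 10) {
  times <- seq(window[1], window[2] - 1 / fs, by = 1 / fs)
  t_ms <- times * 1000
  w <- rep(offset, length(times))
  for (k in seq_along(amps)) {
    sdv <- widths[k] / 2
    g <- exp(-(t_ms - lats[k])^2 / (2 * sdv^2)) -
      exp(-(t_ms - (lats[k] + widths[k]))^2 / (2 * sdv^2))
    w <- w + amps[k] * g / (max(g) - min(g))
  }
  new_averaged_response(w, times, weights = 1, noise_var = noise_var,
                        n_epochs = n_epochs)
}

# Phase set with exact group delay tau (ms) and intercept phi0.
make_phase_set <- function(tau_ms, phi0 = 0,
                           freqs = c(93.3, 102.2, 111.1, 120),
                           source = "ENV") {
  phase_set(freqs, phi0 - 2 * pi * freqs * tau_ms / 1000, source)
}

# Averaged response holding an arbitrary waveform on a uniform time base.
make_response <- function(waveform, fs, t0 = 0, noise_var = 0, n_epochs = 2) {
  times <- t0 + (seq_along(waveform) - 1) / fs
  new_averaged_response(waveform, times, 1, noise_var, n_epochs)
}

# One subject row for simulator calls.
toy_subject <- function() {
  data.frame(subject = "S0001", age = 45.5, sex = factor("F", c("F", "M")),
             pta_0p5_2 = 10, pta_4_12 = 20, pta_1_2 = 10, log10_tcne = 1.5,
             mus = 1)
}
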