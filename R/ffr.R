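# FFR pipeline: polarity addition/subtraction, windowed-FFT spectral
# components with the twelve-bin noise estimator, ENV/TFS extraction, and
# the SNR inclusion criterion for group-delay estimation.

#' The four modulation frequencies
#'
#' @return Named vector `c(MF1 = 93.3, MF2 = 102.2, MF3 = 111.1, MF4 = 120)`
#'   Hz.
#' @export
ffr_mod_freqs <- function() c(MF1 = 93.3, MF2 = 102.2, MF3 = 111.1, MF4 = 120)

#' The four carrier/modulator pairings
#'
#' Each trial carries both AM tones, the low (0.6 kHz) and high (2 kHz)
#' carrier always modulated at different frequencies; the four pairings
#' cycle the modulators so that every modulation frequency visits every
#' carrier.
#'
#' @param lcf,hcf Low and high carrier frequencies in Hz.
#' @return `data.frame` with columns `config`, `lcf`, `hcf`, `lcf_mf`,
#'   `hcf_mf`.
#' @export
ffr_stimulus_configs <- function(lcf = 600, hcf = 2000) {
  mf <- ffr_mod_freqs()
  data.frame(config = c("LCF_MF1/HCF_MF3", "LCF_MF2/HCF_MF4",
                        "LCF_MF3/HCF_MF1", "LCF_MF4/HCF_MF2"),
             lcf = lcf, hcf = hcf,
             lcf_mf = unname(mf[c(1, 2, 3, 4)]),
             hcf_mf = unname(mf[c(3, 4, 1, 2)]))
}

#' Polarity addition and subtraction waveforms
#'
#' The envelope-following (ENV) response is polarity-invariant and survives
#' in the addition waveform `(r + c) / 2`; the temporal-fine-structure (TFS)
#' response inverts with polarity and survives in the subtraction waveform
#' `(r - c) / 2`. The halving keeps both on the single-response scale.
#'
#' @param rarefaction,condensation `averaged_response` objects for the two
#'   stimulus polarities, on identical time bases.
#' @param imbalance_tol Maximum tolerated relative epoch-count imbalance.
#' @return List with `addition` and `subtraction` (`averaged_response`).
#' @export
add_sub <- function(rarefaction, condensation, imbalance_tol = 0.1) {
  r <- rarefaction; c_ <- condensation
  stopifnot(inherits(r, "averaged_response"), inherits(c_, "averaged_response"))
  if (length(r$times) != length(c_$times) ||
      max(abs(r$times - c_$times)) > .Machine$double.eps * 100)
    stop("polarity pair must share the same time base")
  imb <- abs(r$n_epochs - c_$n_epochs) / (r$n_epochs + c_$n_epochs)
  if (imb > imbalance_tol)
    warning(sprintf("polarity epoch counts imbalanced (%d vs %d)",
                    r$n_epochs, c_$n_epochs))
  mk <- function(w) new_averaged_response(w, r$times, weights = rep(0.5, 2),
                                          noise_var = (r$noise_var + c_$noise_var) / 4,
                                          n_epochs = r$n_epochs + c_$n_epochs)
  list(addition = mk((r$waveform + c_$waveform) / 2),
       subtraction = mk((r$waveform - c_$waveform) / 2))
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Spectral component with twelve-bin noise estimate
#'
#' The waveform is Hamming-windowed and Fourier transformed without zero
#' padding. Signal power is the power at the FFT bin closest to
#' `target_freq`; noise power per bin is the mean power over the six bins
#' above and six below the signal bin, excluding the two bins adjacent on
#' each side (offsets -8..-3 and +3..+8) to limit leakage from the signal.
#' `snr = 10 log10(signal_power / noise_power_per_bin)`.
#'
#' @param x An `averaged_response`, or a numeric waveform (then supply
#'   `sampling_rate`).
#' @param target_freq Target frequency in Hz.
#' @param sampling_rate Required when `x` is a bare numeric vector.
#' @return A one-row `data.frame`: `freq` (the target), `bin_freq` (the bin
#'   actually used), `signal_power`, `noise_power` (per bin), `snr` (dB),
#'   `phase` (radians, in (-pi, pi\]).
#' @export
component_snr <- function(x, target_freq, sampling_rate = NULL) {
  if (inherits(x, "averaged_response")) {
    fs <- sampling_rate_of(x)
    w <- x$waveform
  } else {
    if (is.null(sampling_rate)) stop("supply `sampling_rate` for a bare waveform")
    fs <- sampling_rate
    w <- as.numeric(x)
  }
  n <- length(w)
  X <- stats::fft(w * hamming_window(n))
  freqs <- (0:(n - 1)) * fs / n
  half <- floor(n / 2)
  k <- which.min(abs(freqs[1:(half + 1)] - target_freq)) # 1-based bin index
  noise_off <- c(-8:-3, 3:8)
  kn <- k + noise_off
  if (any(kn < 1L | kn > half + 1L))
    stop("target too close to the spectrum edge for 12 valid noise bins")
  p <- Mod(X)^2
  sig <- p[k]
  noi <- mean(p[kn])
  data.frame(freq = target_freq, bin_freq = freqs[k], signal_power = sig,
             noise_power = noi, snr = 10 * log10(sig / noi),
             phase = wrap_phase(Arg(X[k])))
}

#' Extract ENV and TFS spectral components
#'
#' ENV components at both modulation frequencies are measured on the
#' addition waveform; TFS components at CF-MF, CF and CF+MF of the
#' low-frequency carrier are measured on the subtraction waveform. The
#' high-carrier TFS frequencies are not extracted (too high to elicit an
#' FFR).
#'
#' @param addition,subtraction `averaged_response` objects from [add_sub()].
#' @param config One row of [ffr_stimulus_configs()] (or a list with `lcf`,
#'   `hcf`, `lcf_mf`, `hcf_mf`).
#' @return `data.frame` of components with columns `kind` ("ENV"/"TFS"),
#'   `carrier`, `mf`, plus the [component_snr()] columns.
#' @export
extract_components <- function(addition, subtraction, config) {
  stopifnot(all(c("lcf", "hcf", "lcf_mf", "hcf_mf") %in% names(config)))
  rows <- list(
    cbind(kind = "ENV", carrier = config$lcf, mf = config$lcf_mf,
          component_snr(addition, config$lcf_mf)),
    cbind(kind = "ENV", carrier = config$hcf, mf = config$hcf_mf,
          component_snr(addition, config$hcf_mf)),
    cbind(kind = "TFS", carrier = config$lcf, mf = config$lcf_mf,
          component_snr(subtraction, config$lcf - config$lcf_mf)),
    cbind(kind = "TFS", carrier = config$lcf, mf = config$lcf_mf,
          component_snr(subtraction, config$lcf)),
    cbind(kind = "TFS", carrier = config$lcf, mf = config$lcf_mf,
          component_snr(subtraction, config$lcf + config$lcf_mf)))
  do.call(rbind, rows)
}

#' SNR inclusion criterion for group-delay estimation
#'
#' Components enter group-delay estimation only when their SNR strictly
#' exceeds `threshold_db` (default 6.64 dB, the 1% point of the F(2, 2m)
#' null distribution with m = 12 noise bins); a component at exactly the
#' threshold is excluded. The all-four rule ([all_components_pass()]) is
#' enforced downstream: a latency is attempted only when all four components
#' of a target frequency region pass.
#'
#' @param components `data.frame` with an `snr` column.
#' @param threshold_db Inclusion threshold in dB.
#' @return `apply_inclusion_criterion`: the rows with `snr > threshold_db`.
#'   `all_components_pass`: a single logical.
#' @export
apply_inclusion_criterion <- function(components, threshold_db = 6.64) {
  components[components$snr > threshold_db, , drop = FALSE]
}

#' @rdname apply_inclusion_criterion
#' @param snrs Numeric vector of the four component SNRs (dB).
#' @export
all_components_pass <- function(snrs, threshold_db = 6.64) {
  length(snrs) == 4L && all(is.finite(snrs)) && all(snrs > threshold_db)
}
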