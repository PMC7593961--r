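# Stimulus design: band-limited clicks, highpass pink-noise maskers, AM tones
# in ERB-notched pink noise, and the ABR presentation schedule.
#
# Calibration convention throughout: pressure waveforms are in pascals, with
# 0 dB SPL corresponding to an RMS of 20 uPa. Stated dB SPL / dB ppeSPL
# levels are stored as metadata and realized under this convention; no
# transducer model is applied.

P_REF <- 20e-6 # Pa, reference pressure for 0 dB SPL

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Overall level of a sinusoidally amplitude-modulated tone
#'
#' Modulating a carrier of level `carrier_level` with depth `m` adds sideband
#' power, raising the overall level to
#' `carrier_level + 10 log10(1 + m^2 / 2)` dB SPL. A 75 dB SPL carrier gives
#' 76.76 dB SPL at full modulation and 75.95 dB SPL at 70% depth.
#'
#' @param carrier_level Carrier level in dB SPL.
#' @param mod_depth Modulation depth, a fraction in \[0, 1\].
#' @return Overall level in dB SPL (not rounded).
#' @export
am_tone_level <- function(carrier_level, mod_depth) {
  if (any(mod_depth < 0 | mod_depth > 1))
    stop("`mod_depth` must lie in [0, 1]")
  carrier_level + 10 * log10(1 + mod_depth^2 / 2)
}

#' ERB-number (Cam) scale
#'
#' Cumulative equivalent-rectangular-bandwidth number of a frequency, using
#' the standard auditory-filter bandwidth ERB(f) = 24.7 (4.37 f/1000 + 1):
#' `Cam(f) = 21.4 log10(0.00437 f + 1)`.
#'
#' @param f Frequency in Hz.
#' @param cam ERB-number in Cam units.
#' @return `cam_scale` returns Cam units; `cam_inverse` returns Hz.
#' @export
cam_scale <- function(f) 21.4 * log10(0.00437 * f + 1)

#' @rdname cam_scale
#' @export
cam_inverse <- function(cam) (10^(cam / 21.4) - 1) / 0.00437

#' Notch edges one ERB-number around a carrier
#'
#' Returns the frequencies one ERB-number below and above the carrier on the
#' Cam scale, rounded (half away from zero) to the nearest Hz. For the 600
#' and 2000 Hz carriers this yields (515, 694) and (1773, 2253) Hz, i.e. the
#' edges of a two-ERB-wide spectral notch.
#'
#' @param carrier_freq Carrier frequency in Hz (> 0).
#' @return Named numeric vector `c(lower, upper)` in Hz.
#' @export
erb_notch_edges <- function(carrier_freq) {
  stopifnot(carrier_freq > 0)
  c(lower = round_half_up(cam_inverse(cam_scale(carrier_freq) - 1)),
    upper = round_half_up(cam_inverse(cam_scale(carrier_freq) + 1)))
}

#' ABR presentation schedule
#'
#' Clicks alternate between ears at a fixed combined rate; each presentation
#' is a masker burst (possibly containing the click) followed by silence.
#' With the default 14.1/s combined rate and 20 ms bursts the silent interval
#' is 50.9 ms and the per-ear rate 7.05/s. The click onset within the burst
#' is jittered uniformly over (5, 13) ms after noise onset.
#'
#' @param combined_rate Stimuli per second across the two ears.
#' @param burst_duration Masker burst duration in seconds.
#' @param click_onset_jitter Uniform jitter range (seconds) for the click
#'   onset after burst onset.
#' @return An object of class `presentation_schedule`.
#' @export
build_abr_schedule <- function(combined_rate = 14.1, burst_duration = 0.020,
                               click_onset_jitter = c(0.005, 0.013)) {
  stopifnot(combined_rate > 0)
  period <- 1 / combined_rate
  if (burst_duration > period)
    stop("`burst_duration` exceeds the stimulus period 1/combined_rate")
  structure(list(combined_rate = combined_rate,
                 per_ear_rate = combined_rate / 2,
                 burst_duration = burst_duration,
                 silent_interval = period - burst_duration,
                 click_onset_jitter = click_onset_jitter),
            class = "presentation_schedule")
}

# ---- stimulus specification constructors -----------------------------------

#' Stimulus specifications
#'
#' Constructors for the acoustic stimuli: a band-limited click, a highpass
#' pink-noise masker burst, a sinusoidally amplitude-modulated tone, and
#' pink noise with ERB-notches around a set of carriers. All return classed
#' lists holding parameters only; [synthesize_stimulus()] realizes waveforms.
#'
#' @param level,carrier_level,spectrum_level Levels in dB SPL (clicks in
#'   dB ppeSPL).
#' @param band Frequency band in Hz, `c(low, high)`.
#' @param duration,ramp Durations in seconds.
#' @param ref_freq Frequency (Hz) at which a noise spectrum level is stated.
#' @param carrier_freq,mod_freq AM-tone carrier and modulation frequency (Hz).
#' @param mod_depth Modulation depth, fraction in \[0, 1\].
#' @param carriers Carrier frequencies (Hz) around which notches are cut.
#' @return A classed stimulus specification list.
#' @export
click_stimulus <- function(level = 105, band = c(350, 3000), duration = 0.002) {
  structure(list(level = level, band = band, duration = duration,
                 pulse_width = 100e-6),
            class = c("click_stimulus", "stimulus_spec"))
}

#' @rdname click_stimulus
#' @export
highpass_masker <- function(spectrum_level = 65, band = c(3500, 8000),
                            ref_freq = 1000, duration = 0.020, ramp = 0.005) {
  structure(list(spectrum_level = spectrum_level, band = band,
                 ref_freq = ref_freq, duration = duration, ramp = ramp,
                 color = "pink"),
            class = c("highpass_masker", "stimulus_spec"))
}

#' @rdname click_stimulus
#' @export
am_tone <- function(carrier_freq, mod_freq, mod_depth = 1,
                    carrier_level = 75, duration = 0.450, ramp = 0.010) {
  structure(list(carrier_freq = carrier_freq, mod_freq = mod_freq,
                 mod_depth = mod_depth, carrier_level = carrier_level,
                 overall_level = am_tone_level(carrier_level, mod_depth),
                 duration = duration, ramp = ramp),
            class = c("am_tone", "stimulus_spec"))
}

#' @rdname click_stimulus
#' @export
notched_noise <- function(carriers = c(600, 2000), band = c(20, 3000),
                          spectrum_level = 40, ref_freq = 100,
                          duration = 0.450, ramp = 0.010) {
  edges <- lapply(sort(carriers), erb_notch_edges)
  lows <- c(band[1], vapply(edges, `[[`, 0, "upper"))
  highs <- c(vapply(edges, `[[`, 0, "lower"), band[2])
  bands <- Map(c, lows, highs)
  if (any(vapply(bands, function(b) b[1] >= b[2], TRUE)))
    stop("notches overlap or exceed the noise band")
  structure(list(carriers = sort(carriers), bands = bands,
                 spectrum_level = spectrum_level, ref_freq = ref_freq,
                 duration = duration, ramp = ramp, color = "pink"),
            class = c("notched_noise", "stimulus_spec"))
}

# ---- waveform synthesis ----------------------------------------------------

highest_edge <- function(spec) {
  switch(class(spec)[1],
         click_stimulus = spec$band[2],
         highpass_masker = spec$band[2],
         am_tone = spec$carrier_freq + spec$mod_freq,
         notched_noise = spec$bands[[length(spec$bands)]][2])
}

raised_cosine_ramps <- function(n, n_ramp) {
  env <- rep(1, n)
  if (n_ramp > 0) {
    r <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = n_ramp)))
    env[seq_len(n_ramp)] <- r
    env[n - n_ramp + seq_len(n_ramp)] <- rev(r)
  }
  env
}

# Band-limited pink noise by frequency-domain shaping of complex white
# Gaussian noise: magnitude proportional to 1/sqrt(f) inside the bands
# (-3 dB/octave), zero outside. Scaled so the PSD at `ref_freq` equals the
# stated spectrum level (dB SPL per Hz re 20 uPa).
pink_noise <- function(n, fs, bands, spectrum_level, ref_freq) {
  freqs <- seq(0, fs / 2, by = fs / n)
  shape <- rep(0, length(freqs))
  for (b in bands) {
    sel <- freqs >= b[1] & freqs <= b[2]
    shape[sel] <- 1 / sqrt(freqs[sel])
  }
  shape[1] <- 0
  nf <- length(freqs)
  z <- stats::rnorm(nf) + 1i * stats::rnorm(nf)
  half <- z * shape
  # Hermitian spectrum -> real signal
  if (n %% 2 == 0) {
    spec <- c(half[1:nf], Conj(half[(nf - 1):2]))
    spec[nf] <- Re(spec[nf])
  } else {
    spec <- c(half[1:nf], Conj(half[nf:2]))
  }
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  # The DFT of x equals the constructed spectrum, so the expected one-sided
  # periodogram PSD at bin k is 2 E|S_k|^2 / (fs n) = 4 shape_k^2 / (fs n).
  # Scale so the PSD at ref_freq equals P_ref^2 10^(L/10) (per Hz).
  k_ref <- which.min(abs(freqs - ref_freq))
  psd_model <- 4 * shape[k_ref]^2 / (fs * n)
  target <- P_REF^2 * 10^(spectrum_level / 10)
  x * sqrt(target / psd_model)
}

#' Realize a stimulus specification as a pressure waveform
#'
#' Deterministic given `seed` (for the stochastic noise stimuli). Requests
#' with a sampling rate below twice the highest band edge are rejected.
#'
#' @param spec A stimulus specification from [click_stimulus()],
#'   [highpass_masker()], [am_tone()] or [notched_noise()].
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Integer seed for noise realizations (ignored by deterministic
#'   stimuli).
#' @return Numeric pressure waveform (Pa) with attributes `sampling_rate` and
#'   `spec`.
#' @export
synthesize_stimulus <- function(spec, sampling_rate = 48000, seed = 1) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (sampling_rate < 2 * highest_edge(spec))
    stop(sprintf("sampling rate %g Hz undersamples the %g Hz band edge",
                 sampling_rate, highest_edge(spec)))
  x <- with_local_seed(seed, synthesize_impl(spec, sampling_rate))
  attr(x, "sampling_rate") <- sampling_rate
  attr(x, "spec") <- spec
  x
}

synthesize_impl <- function(spec, fs) UseMethod("synthesize_impl")

# Click: 100-us rectangular pulse convolved with a linear-phase windowed-sinc
# bandpass filter (order CLICK_FIR_ORDER, a documented module constant); a
# 2-ms window centered on the peak of the filtered sequence is retained and
# scaled to the stated peak-to-peak-equivalent SPL (peak-to-peak equal to
# that of a full-scale sinusoid at `level` dB SPL).
CLICK_FIR_ORDER <- 1024L

#' @export
synthesize_impl.click_stimulus <- function(spec, fs) {
  pulse <- rep(1, max(1L, round(spec$pulse_width * fs)))
  h <- signal::fir1(CLICK_FIR_ORDER, spec$band / (fs / 2), type = "pass")
  y <- stats::convolve(c(pulse, rep(0, length(h))), rev(h), type = "open")
  n_win <- round(spec$duration * fs)
  pk <- which.max(abs(y))
  lo <- pk - floor(n_win / 2)
  y <- y[pmax(1, lo):min(length(y), lo + n_win - 1)]
  if (length(y) < n_win) y <- c(y, rep(0, n_win - length(y)))
  pp_target <- 2 * sqrt(2) * P_REF * 10^(spec$level / 20)
  y * pp_target / (max(y) - min(y))
}

#' @export
synthesize_impl.highpass_masker <- function(spec, fs) {
  n <- round(spec$duration * fs)
  x <- pink_noise(n, fs, list(spec$band), spec$spectrum_level, spec$ref_freq)
  x * raised_cosine_ramps(n, round(spec$ramp * fs))
}

#' @export
synthesize_impl.am_tone <- function(spec, fs) {
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  a <- sqrt(2) * P_REF * 10^(spec$carrier_level / 20)
  x <- a * (1 + spec$mod_depth * sin(2 * pi * spec$mod_freq * t)) *
    sin(2 * pi * spec$carrier_freq * t)
  x * raised_cosine_ramps(n, round(spec$ramp * fs))
}

#' @export
synthesize_impl.notched_noise <- function(spec, fs) {
  n <- round(spec$duration * fs)
  x <- pink_noise(n, fs, spec$bands, spec$spectrum_level, spec$ref_freq)
  x * raised_cosine_ramps(n, round(spec$ramp * fs))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Serialize / deserialize stimulus specifications
#'
#' Stimulus specifications round-trip through plain YAML for configuration
#' files and provenance logs.
#'
#' @param spec A stimulus specification.
#' @param path File path.
#' @return `read_stimulus_spec` returns the specification.
#' @export
write_stimulus_spec <- function(spec, path) {
  yaml::write_yaml(c(list(type = class(spec)[1]), unclass(spec)), path)
  invisible(path)
}

#' @rdname write_stimulus_spec
#' @export
read_stimulus_spec <- function(path) {
  x <- yaml::read_yaml(path)
  type <- x$type
  x$type <- NULL
  if (type == "notched_noise") x$bands <- lapply(x$bands, unlist)
  structure(x, class = c(type, "stimulus_spec"))
}

#' Write a waveform as a 16-bit PCM WAV file
#'
#' For auditory inspection of synthesized stimuli. The waveform is scaled
#' by its absolute maximum (times `headroom`) to the 16-bit range.
#'
#' @param x Numeric waveform (e.g. from [synthesize_stimulus()]).
#' @param path Output file path.
#' @param sampling_rate Sampling rate in Hz; defaults to the waveform's
#'   `sampling_rate` attribute.
#' @param headroom Linear headroom factor below full scale.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sampling_rate = attr(x, "sampling_rate"),
                      headroom = 0.9) {
  if (is.null(sampling_rate)) stop("supply `sampling_rate`")
  pcm <- as.integer(round(as.numeric(x) / max(abs(x)) * headroom * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  w_int <- function(v, size) writeBin(as.integer(v), con, size = size,
                                      endian = "little")
  writeChar("RIFF", con, eos = NULL); w_int(36L + n_bytes, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_int(16L, 4)
  w_int(1L, 2); w_int(1L, 2) # PCM, mono
  w_int(sampling_rate, 4); w_int(sampling_rate * 2L, 4)
  w_int(2L, 2); w_int(16L, 2)
  writeChar("data", con, eos = NULL); w_int(n_bytes, 4)
  w_int(pcm, 2)
  invisible(path)
}
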