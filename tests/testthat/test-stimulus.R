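# Stimulus design: AM-tone levels, ERB notch edges, presentation schedule,
# and waveform synthesis.

test_that("AM tone overall level follows the modulation-power formula", {
  expect_equal(round(am_tone_level(75, 1.0), 2), 76.76)
  expect_equal(round(am_tone_level(75, 0.7), 2), 75.95)
  expect_equal(am_tone_level(75, 0), 75) # unmodulated carrier
  # monotone increasing in depth, anchored at the carrier level
  depths <- seq(0, 1, by = 0.05)
  lv <- am_tone_level(75, depths)
  expect_true(all(diff(lv) > 0))
  expect_error(am_tone_level(75, 1.2), "\\[0, 1\\]")
  expect_error(am_tone_level(75, -0.1), "\\[0, 1\\]")
})

test_that("ERB notch edges reproduce the printed noise-band boundaries", {
  expect_equal(unname(erb_notch_edges(600)), c(515, 694))
  expect_equal(unname(erb_notch_edges(2000)), c(1773, 2253))
})

test_that("Cam scale round-trips and notches are 2 Cam wide around the carrier", {
  f <- c(50, 123.4, 600, 2000, 7500)
  expect_equal(cam_inverse(cam_scale(f)), f, tolerance = 1e-10)
  for (cf in c(300, 600, 1000, 2000, 4000)) {
    e <- erb_notch_edges(cf)
    expect_lt(e["lower"], cf)
    expect_gt(e["upper"], cf)
    expect_equal(cam_scale(cam_inverse(cam_scale(cf) + 1)) -
                   cam_scale(cam_inverse(cam_scale(cf) - 1)), 2,
                 tolerance = 1e-10)
  }
})

test_that("presentation schedule conserves the stimulus period", {
  s <- build_abr_schedule(14.1, 0.020)
  expect_equal(round(s$silent_interval * 1000, 1), 50.9)
  expect_equal(s$per_ear_rate, 7.05)
  expect_equal(s$burst_duration + s$silent_interval, 1 / s$combined_rate)
  # burst exactly filling the period leaves no silence
  s0 <- build_abr_schedule(10, 0.100)
  expect_equal(s0$silent_interval, 0)
  expect_error(build_abr_schedule(10, 0.2), "exceeds")
  expect_equal(s$click_onset_jitter, c(0.005, 0.013))
})

test_that("synthesized AM tone realizes the overall level", {
  fs <- 48000
  spec <- am_tone(600, 111.1, 1.0)
  x <- synthesize_stimulus(spec, fs)
  # steady-state RMS over an integer number of modulation cycles
  n_cyc <- 40
  i0 <- round(0.02 * fs)
  i1 <- i0 + round(n_cyc / spec$mod_freq * fs) - 1
  rms_db <- 20 * log10(sqrt(mean(x[i0:i1]^2)) / 20e-6)
  expect_equal(rms_db, am_tone_level(75, 1.0), tolerance = 0.05)
})

test_that("zero-depth AM tone is a pure sinusoid", {
  fs <- 48000
  x <- synthesize_stimulus(am_tone(600, 111.1, 0), fs)
  seg <- x[round(0.02 * fs) + 0:(fs / 10 - 1)] # 0.1 s steady state, 600 Hz = 60 cycles
  p <- Mod(fft(seg))^2
  k <- which.max(p[1:(length(seg) / 2)])
  expect_equal((k - 1) * fs / length(seg), 600, tolerance = 1)
  expect_gt(p[k] / sum(p[2:(length(seg) / 2)]), 0.999)
})

test_that("notched noise is deep inside the notches and pink in band", {
  fs <- 48000
  nn <- notched_noise(duration = 2, ramp = 0.01)
  x <- as.numeric(synthesize_stimulus(nn, fs, seed = 7))
  n <- length(x)
  P <- 2 * Mod(fft(x))^2 / (fs * n)
  f <- (0:(n - 1)) * fs / n
  lvl <- function(f0, hw = 20)
    10 * log10(mean(P[f > f0 - hw & f < f0 + hw]) / (20e-6)^2)
  expect_equal(lvl(100), 40, tolerance = 2) # stated spectrum level at 100 Hz
  expect_equal(lvl(200) - lvl(400), 3, tolerance = 1.5) # -3 dB/octave
  # notch floor at the carriers at least 40 dB below the in-band level
  expect_lt(lvl(600), lvl(300) - 40)
  expect_lt(lvl(2000), lvl(1000) - 40)
})

test_that("click is a 2-ms band-limited transient at the stated ppeSPL", {
  fs <- 48000
  x <- synthesize_stimulus(click_stimulus(105), fs)
  expect_length(as.numeric(x), round(0.002 * fs))
  pp <- max(x) - min(x)
  expect_equal(20 * log10(pp / (2 * sqrt(2) * 20e-6)), 105, tolerance = 1e-6)
  # spectral energy concentrated inside the 350-3000 Hz band
  n <- length(x)
  p <- Mod(fft(as.numeric(x)))^2
  f <- (0:(n - 1)) * fs / n
  inband <- sum(p[f >= 350 & f <= 3000])
  outband <- sum(p[f > 4500 & f <= fs / 2])
  expect_gt(10 * log10(inband / outband), 30)
})

test_that("noise synthesis is deterministic given the seed and rejects undersampling", {
  hm <- highpass_masker()
  x1 <- synthesize_stimulus(hm, 48000, seed = 3)
  x2 <- synthesize_stimulus(hm, 48000, seed = 3)
  x3 <- synthesize_stimulus(hm, 48000, seed = 4)
  expect_identical(as.numeric(x1), as.numeric(x2))
  expect_false(identical(as.numeric(x1), as.numeric(x3)))
  expect_error(synthesize_stimulus(hm, 8000), "undersample")
})

test_that("stimulus specifications round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  spec <- notched_noise()
  write_stimulus_spec(spec, path)
  back <- read_stimulus_spec(path)
  expect_equal(back$bands, spec$bands)
  expect_s3_class(back, "notched_noise")
})

test_that("WAV export writes a well-formed PCM header", {
  x <- synthesize_stimulus(am_tone(600, 111.1, 1), 48000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, path)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_equal(readChar(con, 4), "RIFF")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  expect_equal(readChar(con, 4), "WAVE")
  expect_equal(file.size(path), 44 + 2 * length(x))
})
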