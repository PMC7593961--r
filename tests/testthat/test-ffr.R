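# FFR pipeline: polarity algebra, twelve-bin SNR estimator, component
# extraction, inclusion criterion.

make_pair <- function(env, tfs, fs = 4096, dur = 0.455) {
  t <- (0:(round(dur * fs) - 1)) / fs
  rar <- env(t) + tfs(t)
  con <- env(t) - tfs(t)
  list(rar = make_response(rar, fs), con = make_response(con, fs))
}

test_that("polarity addition/subtraction separates ENV from TFS", {
  env <- function(t) 30 * cos(2 * pi * 100 * t + 0.3)
  tfs <- function(t) 20 * cos(2 * pi * 500 * t - 0.8)
  p <- make_pair(env, tfs)
  ab <- add_sub(p$rar, p$con)
  t <- p$rar$times
  expect_equal(ab$addition$waveform, env(t), tolerance = 1e-10)
  expect_equal(ab$subtraction$waveform, tfs(t), tolerance = 1e-10)
  # cross-leakage below 1%
  leak_add <- component_snr(ab$addition, 500)$signal_power /
    component_snr(ab$addition, 100)$signal_power
  expect_lt(leak_add, 0.01)
  # identical polarities cancel the subtraction entirely
  ab2 <- add_sub(p$rar, p$rar)
  expect_true(all(abs(ab2$subtraction$waveform) < 1e-12))
  neg <- p$rar; neg$waveform <- -p$rar$waveform
  expect_true(all(abs(add_sub(p$rar, neg)$addition$waveform) < 1e-12))
})

test_that("polarity pairs must align and balance", {
  a <- make_response(rnorm(100), 1000)
  b <- make_response(rnorm(120), 1000)
  expect_error(add_sub(a, b), "time base")
  c_ <- make_response(rnorm(100), 1000, n_epochs = 50)
  expect_warning(add_sub(a, c_), "imbalanced")
})

test_that("a noiseless bin-centered tone yields a very large SNR", {
  fs <- 4096; n <- 2048
  t <- (0:(n - 1)) / fs
  x <- cos(2 * pi * 400 * t) # bin 200 exactly
  cs <- component_snr(x, 400, sampling_rate = fs)
  expect_gt(cs$snr, 60)
  expect_equal(cs$bin_freq, 400)
})

test_that("the noise estimate is the mean of the twelve offset bins", {
  fs <- 4096; n <- 1024
  set.seed(9)
  x <- rnorm(n)
  cs <- component_snr(x, 400, sampling_rate = fs)
  X <- fft(x * (0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))))
  k <- which.min(abs((0:(n / 2)) * fs / n - 400))
  p <- Mod(X)^2
  expect_equal(cs$noise_power, mean(p[k + c(-8:-3, 3:8)]))
  expect_equal(cs$signal_power, p[k])
  expect_equal(cs$snr, 10 * log10(p[k] / mean(p[k + c(-8:-3, 3:8)])))
})

test_that("targets too close to the spectrum edge are rejected", {
  x <- rnorm(1024)
  expect_error(component_snr(x, 5, sampling_rate = 4096), "edge")
  expect_error(component_snr(x, 2047, sampling_rate = 4096), "edge")
})

test_that("null SNR is calibrated near 0 dB under the per-bin-mean convention", {
  cal <- null_snr_calibration(n_draws = 800, seed = 3)
  expect_equal(cal$pooled_db, 0, tolerance = 0.5)
  # the raw-sum convention would sit near -10.8 dB
  expect_equal(cal$pooled_raw_sum_db, -10.79, tolerance = 0.6)
})

test_that("component extraction follows the CF/MF configuration", {
  fs <- 4096
  t <- (0:(round(0.455 * fs) - 1)) / fs
  addv <- make_response(cos(2 * pi * 93.3 * t) + cos(2 * pi * 111.1 * t), fs)
  subv <- make_response(cos(2 * pi * 506.7 * t) + cos(2 * pi * 600 * t) +
                          cos(2 * pi * 693.3 * t), fs)
  cfg <- ffr_stimulus_configs()[1, ] # LCF_MF1 / HCF_MF3
  comp <- extract_components(addv, subv, cfg)
  expect_equal(comp$freq[comp$kind == "ENV"], c(93.3, 111.1))
  expect_equal(comp$freq[comp$kind == "TFS"], c(506.7, 600, 693.3))
  # no TFS components of the high-frequency carrier
  expect_false(any(comp$freq > 1000))
  expect_true(all(comp$carrier[comp$kind == "TFS"] == 600))
})

test_that("the inclusion criterion is a strict inequality with an all-four rule", {
  comp <- data.frame(snr = c(6.64, 6.641, 10, 5))
  kept <- apply_inclusion_criterion(comp)
  expect_equal(kept$snr, c(6.641, 10)) # exactly 6.64 is excluded
  expect_false(all_components_pass(c(10, 10, 10, 5)))
  expect_false(all_components_pass(c(10, 10, 10, 6.64)))
  expect_true(all_components_pass(c(6.65, 7, 8, 9)))
  # failing the rule suppresses the latency estimate entirely
  f <- c(93.3, 102.2, 111.1, 120)
  gd <- group_delay_from_components(f, -2 * pi * f * 0.014, c(10, 10, 10, 5))
  expect_false(gd$accepted)
  expect_true(is.na(gd$latency_ms))
})

test_that("measured component SNR matches the configured injection level", {
  # single-component simulation: expected SNR is computable from the window
  fs <- 4096
  truth <- default_truth(ffr = list(tau_ms = 14, phi0 = 0.6,
                                    env_amp = c(30, 0), tfs_amp = 0, cf_amp = 0),
                         noise = list(rms = 15, f_knee = 100))
  sc <- as.list(ffr_stimulus_configs()[1, ]); sc$md <- 1
  snrs <- vapply(1:12, function(r) {
    rec <- simulate_ffr_recording(toy_subject(), sc, truth, n_sweeps = 2,
                                  seed = 100 + r, sampling_rate = fs)
    eps <- epoch_recording(rec, c(-0.005, 0.450), c(-0.005, 0))
    avg <- iterative_weighted_average(eps$epochs)
    post <- eps$times >= 0
    component_snr(avg$waveform[post], sc$lcf_mf, sampling_rate = fs)$snr
  }, 0)
  # expected: signal bin power vs per-bin noise power for white-ish noise
  n <- sum((0:(round(0.455 * fs) - 1)) / fs >= 0.005) # post-onset length
  n <- length(seq(0, 0.450 - 1 / fs, by = 1 / fs))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  k <- round(93.3 * n / fs)
  delta <- 93.3 * n / fs - k
  W <- sum(w * exp(-2i * pi * delta * (0:(n - 1)) / n))
  sig <- (30 / 2)^2 * Mod(W)^2
  noise_var_avg <- 15^2 / 2 # two averaged sweeps
  noi <- noise_var_avg * sum(w^2)
  expected <- 10 * log10(sig / noi)
  expect_equal(mean(snrs), expected, tolerance = 2)
})
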