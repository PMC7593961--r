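# Synthetic data: cohort copula, measurement tables, waveform generators.

test_that("cohort sampling is deterministic and respects marginal bounds", {
  a <- sample_cohort(50, seed = 3)
  b <- sample_cohort(50, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, sample_cohort(50, seed = 4)))
  expect_true(all(a$age >= 18 & a$age <= 73))
  expect_true(all(a$pta_0p5_2 <= 30.5))
  expect_setequal(levels(a$sex), c("F", "M"))
})

test_that("large cohorts reproduce the configured correlation structure", {
  co <- sample_cohort(10000, seed = 8)
  r <- cor(co[, c("age", "pta_0p5_2", "pta_4_12", "log10_tcne", "mus")])
  target <- default_covariate_correlation()
  expect_lt(abs(r["age", "pta_4_12"] - 0.84), 0.03)
  expect_lt(abs(r["age", "pta_0p5_2"] - 0.37), 0.03)
  expect_lt(abs(r["pta_0p5_2", "pta_4_12"] - 0.49), 0.03)
  expect_lt(max(abs(r - target)), 0.04)
})

test_that("an identity correlation config gives near-zero correlations", {
  co <- sample_cohort(10000, correlation = diag(5), seed = 9)
  r <- cor(co[, c("age", "pta_0p5_2", "pta_4_12", "log10_tcne", "mus")])
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("a non-positive-definite correlation config is rejected", {
  bad <- default_covariate_correlation()
  bad[1, 2] <- bad[2, 1] <- 0.999
  bad[1, 3] <- bad[3, 1] <- -0.999
  bad[2, 3] <- bad[3, 2] <- 0.999
  expect_error(sample_cohort(10, correlation = bad), "positive definite")
})

test_that("measurement-table censoring is monotone decreasing in amplitude", {
  co <- sample_cohort(300, seed = 5)
  rate <- vapply(c(0.3, 0.5, 1.2), function(base) {
    tr <- default_truth()
    tr$abr$base_amp["I_105"] <- base
    mean(simulate_abr_measurement_table(co, tr, seed = 6)$censored)
  }, 0)
  expect_true(all(diff(rate) < 0))
  expect_gt(rate[1], 0.3)
  expect_lt(rate[3], 0.1)
})

test_that("noiseless ABR simulation round-trips the embedded wave amplitudes", {
  rec <- simulate_abr_recording(toy_subject(), list(level = 105, masking = "quiet"),
                                n_sweeps = 8, seed = 2, noise_rms = 0,
                                wave_amplitudes = c(I = 150, V = 300))
  eps <- epoch_recording(rec, c(-0.003, 0.012), c(-0.003, 0))
  avg <- iterative_weighted_average(eps)
  avg$times <- eps$times
  mI <- pick_wave(avg, "I")
  mV <- pick_wave(avg, "V")
  expect_equal(mI$amplitude, 150, tolerance = 0.5)
  expect_equal(mV$amplitude, 300, tolerance = 1.5)
  man <- attr(rec, "manifest")
  expect_equal(unname(man$amplitudes), c(150, 300))
  expect_equal(mI$latency, unname(man$latencies["I"]),
               tolerance = 1000 / rec$sampling_rate)
})

test_that("sub-floor amplitudes are censored in nearly all replicates", {
  fs <- 8192
  tr <- default_truth()
  censored <- vapply(1:60, function(r) {
    rec <- simulate_abr_recording(toy_subject(), list(level = 80, masking = "hp"),
                                  truth = tr, n_sweeps = 24, seed = 300 + r,
                                  sampling_rate = fs, noise_rms = 12,
                                  wave_amplitudes = c(I = 0.3, V = 0.3))
    rec <- fir_bandpass(rec, c(100, 1500))
    eps <- epoch_recording(rec, c(-0.003, 0.012), c(-0.003, 0))
    avg <- iterative_weighted_average(eps)
    avg$times <- eps$times
    !pick_wave(avg, "I", level = 80)$detected
  }, NA)
  expect_gte(mean(censored), 0.9)
})

test_that("FFR polarity algebra is exact in noiseless runs", {
  sc <- as.list(ffr_stimulus_configs()[2, ]); sc$md <- 1
  rec <- simulate_ffr_recording(toy_subject(), sc, n_sweeps = 4, seed = 3,
                                sampling_rate = 4096, noise_rms = 0)
  eps <- epoch_recording(rec, c(-0.005, 0.450), c(-0.005, 0))
  avg <- lapply(c("rar", "cond"), function(pol) {
    a <- iterative_weighted_average(eps$epochs[eps$info$code == pol, ])
    a$times <- eps$times
    a
  })
  ab <- add_sub(avg[[1]], avg[[2]])
  man <- attr(rec, "manifest")$components
  post <- eps$times >= 0 & eps$times < 0.449 # steady overlap
  t_post <- eps$times[post]
  env_expect <- rowSums(vapply(which(man$kind == "ENV"), function(i)
    man$amp[i] * cos(2 * pi * man$freq[i] * t_post + man$phase[i]),
    numeric(length(t_post))))
  tfs_expect <- rowSums(vapply(which(man$kind == "TFS"), function(i)
    man$amp[i] * cos(2 * pi * man$freq[i] * t_post + man$phase[i]),
    numeric(length(t_post))))
  expect_equal(ab$addition$waveform[post], env_expect, tolerance = 1e-6)
  expect_equal(ab$subtraction$waveform[post], tfs_expect, tolerance = 1e-6)
})

test_that("odd FFR sweep counts are rejected", {
  sc <- as.list(ffr_stimulus_configs()[1, ])
  expect_error(simulate_ffr_recording(toy_subject(), sc, n_sweeps = 5),
               "even")
})

test_that("noiseless FFR recordings recover the configured group delay", {
  cfgs <- ffr_stimulus_configs()
  tr <- default_truth()
  fs <- 4096
  comp <- lapply(1:4, function(k) {
    sc <- as.list(cfgs[k, ]); sc$md <- 1
    rec <- simulate_ffr_recording(toy_subject(), sc, tr, n_sweeps = 4,
                                  seed = 20 + k, sampling_rate = fs,
                                  noise_rms = 0)
    eps <- epoch_recording(rec, c(-0.005, 0.450), c(-0.005, 0))
    avg <- lapply(c("rar", "cond"), function(pol) {
      a <- iterative_weighted_average(eps$epochs[eps$info$code == pol, ])
      a$times <- eps$times
      a
    })
    ab <- add_sub(avg[[1]], avg[[2]])
    post <- eps$times >= 0
    component_snr(ab$addition$waveform[post], sc$lcf_mf, sampling_rate = fs)
  })
  comp <- do.call(rbind, comp)
  gd <- group_delay_from_components(comp$bin_freq, comp$phase,
                                    rep(99, 4), source = "ENV")
  expect_true(gd$accepted)
  expect_equal(gd$latency_ms, tr$ffr$tau_ms, tolerance = 0.3) # bin quantization
})

test_that("recordings round-trip through the plain-text container", {
  rec <- simulate_abr_recording(toy_subject(), n_sweeps = 2, seed = 1,
                                sampling_rate = 2048, noise_rms = 1)
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  back <- read_recording(dir)
  expect_equal(back$channels, rec$channels, tolerance = 1e-12)
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_equal(back$triggers$time, rec$triggers$time)
})
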