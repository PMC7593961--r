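# Synthetic cohorts and EEG-like recordings with known ground truth, so
# every downstream stage is testable without external data.

#' Default covariate correlation structure
#'
#' The target Pearson correlation matrix among the continuous predictors:
#' age correlates strongly with the high-frequency pure-tone average (0.84),
#' moderately with the low-frequency average (0.37); the two averages
#' correlate at 0.49; noise exposure and musical experience are essentially
#' uncorrelated with everything.
#'
#' @return 5x5 correlation matrix over `age`, `pta_0p5_2`, `pta_4_12`,
#'   `log10_tcne`, `mus`.
#' @export
default_covariate_correlation <- function() {
  v <- c("age", "pta_0p5_2", "pta_4_12", "log10_tcne", "mus")
  R <- diag(5)
  dimnames(R) <- list(v, v)
  R["age", "pta_0p5_2"] <- 0.37
  R["age", "pta_4_12"] <- 0.84
  R["age", "log10_tcne"] <- 0.02
  R["age", "mus"] <- 0.10
  R["pta_0p5_2", "pta_4_12"] <- 0.49
  R["pta_0p5_2", "log10_tcne"] <- -0.11
  R["pta_0p5_2", "mus"] <- -0.03
  R["pta_4_12", "log10_tcne"] <- 0.06
  R["pta_4_12", "mus"] <- -0.06
  R["log10_tcne", "mus"] <- -0.01
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R
}

#' Sample a synthetic cohort
#'
#' Gaussian copula over the configured correlation matrix with
#' empirical-range marginals: age uniform over 18--73 (spanning the young /
#' middle-aged / older groups), pure-tone averages on bounded scaled-beta
#' ranges respecting the inclusion bound (low-frequency PTA <= 30.5 dB HL),
#' log10 noise exposure normal, and cube-root musical experience scaled
#' beta. Latent correlations are de-attenuated via `2 sin(pi r / 6)` so the
#' sampled Pearson correlations converge to the configured values. Sex is
#' drawn independently with the cohort's 27:7 female:male ratio.
#'
#' @param n Number of subjects (>= 2).
#' @param correlation Target correlation matrix (see
#'   [default_covariate_correlation()]); must be positive definite.
#' @param seed Integer seed.
#' @return `data.frame` with columns `subject`, `age`, `sex`, `pta_0p5_2`,
#'   `pta_4_12`, `pta_1_2`, `log10_tcne`, `mus`.
#' @export
sample_cohort <- function(n, correlation = default_covariate_correlation(),
                          seed = 1) {
  stopifnot(n >= 2)
  lat <- 2 * sin(pi * correlation / 6)
  diag(lat) <- 1
  ev <- eigen(lat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("correlation configuration is not positive definite")
  with_local_seed(seed, {
    Z <- MASS::mvrnorm(n, mu = rep(0, ncol(lat)), Sigma = lat)
    U <- stats::pnorm(Z)
    data.frame(
      subject = sprintf("S%04d", seq_len(n)),
      age = stats::qunif(U[, 1], 18, 73),
      sex = factor(ifelse(stats::runif(n) < 7 / 34, "M", "F"),
                   levels = c("F", "M")),
      pta_0p5_2 = stats::qbeta(U[, 2], 2, 4) * 35.5 - 5,
      pta_4_12 = stats::qbeta(U[, 3], 2, 3) * 75 - 5,
      pta_1_2 = stats::qbeta(U[, 2], 2, 4) * 35.5 - 5 + stats::rnorm(n, 0, 1.5),
      log10_tcne = stats::qnorm(U[, 4], 1.5, 0.8),
      mus = stats::qbeta(U[, 5], 1.2, 3) * 3)
  })
}

#' Ground truth for the synthetic generators
#'
#' All effects are on the scales used by the inference module: per-year
#' slopes on the natural-log amplitude scale (so `log(0.83)/10` per year is
#' a 17% amplitude drop per age decade), additive offsets for sex, per-dB
#' and per-log10-unit covariate slopes, a subject random-intercept SD, a
#' Student-t residual scale and df, and the detection floor (0.38 nV) below
#' which measurements are censored. FFR truth carries the group delay
#' `tau_ms` and per-component amplitudes (nV).
#'
#' @param ... Named overrides of any default element (nested lists are
#'   replaced wholesale).
#' @return List of class `ground_truth`.
#' @export
default_truth <- function(...) {
  truth <- list(
    abr = list(
      # baseline peak-trough amplitudes (nV) by wave and level, quiet
      base_amp = c(I_105 = 150, I_80 = 60, V_105 = 300, V_80 = 150),
      masking_gain = 0.5, # multiplicative amplitude factor under HP masking
      age_slope = log(0.83) / 10, # per year, log scale: -17%/decade
      sex_m = -0.15, # males lower, log scale
      pta_slope = -0.01, # per dB HL, log scale
      tcne_slope = 0, # per log10 exposure unit
      subject_sd = 0.25, # random-intercept SD, log scale
      sigma = 0.2, # residual t scale, log scale
      nu = 15, # residual t df
      latency_ms = list(I = c("105" = 1.7, "80" = 2.2),
                        V = c("105" = 5.6, "80" = 6.5)),
      width_ms = c(I = 0.5, V = 1.0)),
    ffr = list(
      tau_ms = 14, # group delay
      phi0 = 0.6, # common phase intercept (radians)
      env_amp = 30, # ENV amplitude (nV) at full modulation; length 2 = per carrier
      tfs_amp = 20, # TFS sideband amplitudes (nV)
      cf_amp = 25), # TFS amplitude at the carrier itself
    detection_floor = 0.38, # nV
    noise = list(rms = 10, f_knee = 100)) # background noise (nV), 1/f below knee
  over <- list(...)
  for (nm in names(over)) truth[[nm]] <- over[[nm]]
  structure(truth, class = "ground_truth")
}

#' @rdname default_truth
#' @param truth A `ground_truth`.
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

abr_linpred <- function(truth, subject, wave, level, masking, u = 0) {
  a <- truth$abr
  base <- unname(a$base_amp[paste(wave, level, sep = "_")])
  if (is.na(base)) stop("no baseline amplitude for ", wave, " at ", level)
  log(base) +
    log(a$masking_gain) * (masking == "hp") +
    a$age_slope * (subject$age - 45.5) +
    a$sex_m * (subject$sex == "M") +
    a$pta_slope * (subject$pta_0p5_2 - 10) +
    a$tcne_slope * (subject$log10_tcne - 1.5) +
    u
}

#' Simulate a censored ABR measurement table directly
#'
#' Measurement-level generator used for inference recovery studies: draws
#' per-subject random intercepts and Student-t residuals around the linear
#' predictor implied by `truth`, and censors amplitudes below the detection
#' floor. One row per subject x wave x level x masking x replicate.
#'
#' @param cohort Cohort from [sample_cohort()].
#' @param truth A `ground_truth`.
#' @param waves,levels,masking,replicates Condition grid; `replicates` names
#'   replicate measurements per cell (e.g. montages).
#' @param seed Integer seed.
#' @return Measurement table with `amplitude` (nV, `NA` when censored),
#'   `censored`, `censor_bound`, covariates joined; the generating truth is
#'   attached as attribute `truth`.
#' @export
simulate_abr_measurement_table <- function(cohort, truth = default_truth(),
                                           waves = "I", levels = 105,
                                           masking = "quiet",
                                           replicates = c("ITPR", "IERL"),
                                           seed = 1) {
  grid <- expand.grid(subject = cohort$subject, wave = waves, level = levels,
                      masking = masking, montage = replicates,
                      stringsAsFactors = FALSE)
  with_local_seed(seed, {
    u <- stats::rnorm(nrow(cohort), 0, truth$abr$subject_sd)
    names(u) <- cohort$subject
    rows <- merge(grid, cohort, by = "subject", sort = FALSE)
    lp <- vapply(seq_len(nrow(rows)), function(i)
      abr_linpred(truth, rows[i, ], rows$wave[i], rows$level[i],
                  rows$masking[i], u[rows$subject[i]]),
      numeric(1))
    resid <- truth$abr$sigma * stats::rt(nrow(rows), df = truth$abr$nu)
    amp <- exp(lp + resid)
    rows$amplitude <- amp
    rows$censored <- amp < truth$detection_floor
    rows$amplitude[rows$censored] <- NA_real_
    rows$censor_bound <- truth$detection_floor
    attr(rows, "truth") <- truth
    attr(rows, "random_intercepts") <- u
    rows
  })
}

# 1/f-plus-white background noise: power ~ 1/f below the knee, flat above,
# scaled to the requested RMS.
background_noise <- function(n, fs, rms, f_knee = 100) {
  if (rms <= 0) return(rep(0, n))
  freqs <- seq(0, fs / 2, by = fs / n)
  shape <- rep(1, length(freqs))
  low <- freqs > 0 & freqs < f_knee
  shape[low] <- sqrt(f_knee / freqs[low])
  shape[1] <- 0
  nf <- length(freqs)
  z <- (stats::rnorm(nf) + 1i * stats::rnorm(nf)) * shape
  if (n %% 2 == 0) {
    spec <- c(z[1:nf], Conj(z[(nf - 1):2])); spec[nf] <- Re(spec[nf])
  } else spec <- c(z[1:nf], Conj(z[nf:2]))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# Gaussian-windowed biphasic deflection (positive peak followed by a trough)
# with unit peak-trough amplitude; `width_ms` sets the Gaussian SD (width/2)
# and the peak-trough separation (one width).
biphasic_wave <- function(t_ms, peak_ms, width_ms) {
  sdv <- width_ms / 2
  g <- exp(-(t_ms - peak_ms)^2 / (2 * sdv^2)) -
    exp(-(t_ms - (peak_ms + width_ms))^2 / (2 * sdv^2))
  g / (max(g) - min(g))
}

#' Simulate a continuous ABR recording
#'
#' Builds an EEG-like continuous recording for one subject and condition:
#' sweeps at the presentation schedule's period, each containing fixed-shape
#' biphasic wave I and wave V deflections whose peak-trough amplitude is
#' `exp(linear predictor + subject random effect)` (nV), on a 1/f-plus-white
#' noise background. Triggers alternate ears. The embedded per-sweep truth
#' is attached as attribute `manifest`.
#'
#' @param subject One row of a cohort.
#' @param condition List with `level` (80 or 105) and `masking` (`"quiet"`
#'   or `"hp"`).
#' @param truth A `ground_truth`.
#' @param n_sweeps Number of sweeps (>= 1).
#' @param seed Integer seed.
#' @param sampling_rate Sampling rate in Hz.
#' @param noise_rms Background-noise RMS (nV); `NULL` uses `truth$noise$rms`.
#' @param wave_amplitudes Optional named override `c(I = ..., V = ...)` (nV)
#'   bypassing the linear predictor.
#' @param acoustic_delay Earphone-tube acoustic delay in seconds: the
#'   response is embedded this long after the trigger, to be undone by
#'   [compensate_trigger_delay()] downstream.
#' @return A `recording` (single channel, units nV) with attribute
#'   `manifest`.
#' @export
simulate_abr_recording <- function(subject, condition = list(level = 105, masking = "quiet"),
                                   truth = default_truth(), n_sweeps = 100,
                                   seed = 1, sampling_rate = 16384,
                                   noise_rms = NULL,
                                   wave_amplitudes = NULL,
                                   acoustic_delay = 0) {
  stopifnot(n_sweeps >= 1)
  if (!condition$masking %in% c("quiet", "hp"))
    stop("condition$masking must be 'quiet' or 'hp'")
  fs <- sampling_rate
  sched <- build_abr_schedule()
  period <- 1 / sched$combined_rate
  if (is.null(noise_rms)) noise_rms <- truth$noise$rms
  with_local_seed(seed, {
    u <- stats::rnorm(1, 0, truth$abr$subject_sd)
    amps <- if (!is.null(wave_amplitudes)) wave_amplitudes else
      c(I = exp(abr_linpred(truth, subject, "I", condition$level,
                            condition$masking, u)),
        V = exp(abr_linpred(truth, subject, "V", condition$level,
                            condition$masking, u)))
    lat <- c(I = truth$abr$latency_ms$I[[as.character(condition$level)]],
             V = truth$abr$latency_ms$V[[as.character(condition$level)]])
    n_total <- ceiling((n_sweeps + 2) * period * fs)
    x <- background_noise(n_total, fs, noise_rms, truth$noise$f_knee)
    trig_times <- period * (seq_len(n_sweeps) - 0.5)
    t_epoch_ms <- (0:(round(0.012 * fs) - 1)) / fs * 1000
    shape <- amps["I"] * biphasic_wave(t_epoch_ms, lat["I"], truth$abr$width_ms["I"]) +
      amps["V"] * biphasic_wave(t_epoch_ms, lat["V"], truth$abr$width_ms["V"])
    for (tt in trig_times) {
      s0 <- round((tt + acoustic_delay) * fs) + 1L
      idx <- s0:(s0 + length(shape) - 1L)
      x[idx] <- x[idx] + shape
    }
    rec <- new_recording(matrix(x, ncol = 1, dimnames = list(NULL, "HF")),
                         fs,
                         data.frame(time = trig_times,
                                    code = rep(c("L", "R"), length.out = n_sweeps)))
    attr(rec, "manifest") <- list(amplitudes = amps, latencies = lat,
                                  random_intercept = u, condition = condition)
    rec
  })
}

#' Simulate a continuous FFR recording
#'
#' Sweeps alternate rarefaction and condensation polarity (`n_sweeps` must
#' be even to balance them). Each epoch contains steady-state ENV components
#' at both modulation frequencies (identical sign across polarities) and
#' TFS components at CF-MF, CF and CF+MF of the low carrier (sign inverting
#' with polarity); every component's phase is `phi0 - 2 pi f tau` for the
#' configured group delay.
#'
#' @param subject One row of a cohort (unused by the default amplitudes but
#'   kept for signature symmetry with the ABR generator).
#' @param stim_config One row of [ffr_stimulus_configs()] plus an `md`
#'   element (modulation depth fraction) scaling the ENV amplitudes.
#' @param truth A `ground_truth`.
#' @param n_sweeps Even number of sweeps.
#' @param seed Integer seed.
#' @param sampling_rate Sampling rate in Hz.
#' @param noise_rms Background-noise RMS (nV); `NULL` uses `truth$noise$rms`.
#' @param acoustic_delay Earphone-tube acoustic delay in seconds (see
#'   [simulate_abr_recording()]).
#' @return A `recording` with attribute `manifest` (component table).
#' @export
simulate_ffr_recording <- function(subject, stim_config, truth = default_truth(),
                                   n_sweeps = 100, seed = 1,
                                   sampling_rate = 16384, noise_rms = NULL,
                                   acoustic_delay = 0) {
  if (n_sweeps %% 2 != 0)
    stop("`n_sweeps` must be even to balance the two polarities")
  fs <- sampling_rate
  if (is.null(noise_rms)) noise_rms <- truth$noise$rms
  md <- if (!is.null(stim_config$md)) stim_config$md else 1
  tau <- truth$ffr$tau_ms / 1000
  comp <- data.frame(
    kind = c("ENV", "ENV", "TFS", "TFS", "TFS"),
    freq = c(stim_config$lcf_mf, stim_config$hcf_mf,
             stim_config$lcf - stim_config$lcf_mf, stim_config$lcf,
             stim_config$lcf + stim_config$lcf_mf),
    amp = c(rep(truth$ffr$env_amp, length.out = 2) * md,
            truth$ffr$tfs_amp, truth$ffr$cf_amp, truth$ffr$tfs_amp))
  comp$phase <- wrap_phase(truth$ffr$phi0 - 2 * pi * comp$freq * tau)
  epoch_dur <- 0.455
  period <- 0.5
  with_local_seed(seed, {
    n_total <- ceiling((n_sweeps + 1) * period * fs)
    x <- background_noise(n_total, fs, noise_rms, truth$noise$f_knee)
    trig_times <- period * (seq_len(n_sweeps) - 0.5)
    pol <- rep(c(1, -1), length.out = n_sweeps)
    t_ep <- (0:(round(epoch_dur * fs) - 1)) / fs
    env_part <- rowSums(vapply(which(comp$kind == "ENV"), function(i)
      comp$amp[i] * cos(2 * pi * comp$freq[i] * t_ep + comp$phase[i]),
      numeric(length(t_ep))))
    tfs_part <- rowSums(vapply(which(comp$kind == "TFS"), function(i)
      comp$amp[i] * cos(2 * pi * comp$freq[i] * t_ep + comp$phase[i]),
      numeric(length(t_ep))))
    for (k in seq_len(n_sweeps)) {
      s0 <- round((trig_times[k] + acoustic_delay) * fs) + 1L
      idx <- s0:(s0 + length(t_ep) - 1L)
      x[idx] <- x[idx] + env_part + pol[k] * tfs_part
    }
    rec <- new_recording(matrix(x, ncol = 1, dimnames = list(NULL, "HF")),
                         fs,
                         data.frame(time = trig_times,
                                    code = ifelse(pol > 0, "rar", "cond")))
    attr(rec, "manifest") <- list(components = comp, tau_ms = truth$ffr$tau_ms,
                                  config = stim_config)
    rec
  })
}
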