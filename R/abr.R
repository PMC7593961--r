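# ABR pipeline: ear averaging, wave I/V peak-trough measurement with
# detection flags, pre-stimulus noise-floor estimation, and assembly of the
# censored measurement table.

#' Average left- and right-ear responses
#'
#' Pointwise mean of two averaged responses on identical time bases; epoch
#' counts are summed and the noise variance of the mean is `(v_L + v_R) / 4`.
#'
#' @param left,right `averaged_response` objects.
#' @return An `averaged_response`.
#' @export
average_ears <- function(left, right) {
  stopifnot(inherits(left, "averaged_response"),
            inherits(right, "averaged_response"))
  if (length(left$times) != length(right$times) ||
      max(abs(left$times - right$times)) > .Machine$double.eps * 100)
    stop("left and right responses must share the same time base")
  new_averaged_response((left$waveform + right$waveform) / 2, left$times,
                        weights = rep(1 / 2, 2),
                        noise_var = (left$noise_var + right$noise_var) / 4,
                        n_epochs = left$n_epochs + right$n_epochs)
}

#' Default wave search windows
#'
#' Search windows (ms) for the wave I and wave V peaks; the upper edge is
#' widened by 0.5 ms at the lower stimulus level, where latencies are longer.
#' These are configuration defaults, not constants: pass explicit windows to
#' [pick_wave()] to override.
#'
#' @param level Click level in dB ppeSPL.
#' @return Named list of `c(lo, hi)` windows in ms.
#' @export
default_peak_windows <- function(level = 105) {
  widen <- if (level < 105) 0.5 else 0
  list(I = c(1.0, 3.5 + widen), V = c(4.5, 9.0 + widen))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Sub-sample refinement of an extremum by parabolic interpolation around
# sample i; returns c(offset_in_samples, value).
parabolic_refine <- function(x, i) {
  if (i <= 1L || i >= length(x)) return(c(0, x[i]))
  denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  if (denom == 0) return(c(0, x[i]))
  d <- 0.5 * (x[i - 1L] - x[i + 1L]) / denom
  if (abs(d) > 1) return(c(0, x[i]))
  c(d, x[i] - 0.25 * (x[i - 1L] - x[i + 1L]) * d)
}

#' Measure an ABR wave as a peak-trough amplitude and peak latency
#'
#' The peak is the largest local maximum inside the search window (ties
#' resolved to the earlier latency); the trough is the first local minimum
#' after the peak within `trough_window_ms`. Both are refined to sub-sample
#' precision by parabolic interpolation. The measurement is flagged
#' undetected when no qualifying peak/trough pair exists or when the
#' peak-trough amplitude fails the detectability criterion: local SNR
#' `amplitude / (4.5 sqrt(noise_var)) >= snr_criterion`. The reference
#' `4.5 sqrt(noise_var)` approximates the 95th percentile of the
#' peak-trough amplitude that band-limited noise alone produces in the
#' default wave I search window, so at the default criterion of 1 a pure
#' noise response is called undetected about 95% of the time. With a zero
#' or unknown noise variance any positive amplitude is detected.
#'
#' @param response An `averaged_response` (waveform units are nV by
#'   convention).
#' @param wave `"I"` or `"V"` (labels the measurement; the search window
#'   carries the actual location).
#' @param search_window `c(lo, hi)` peak search window in ms; default from
#'   [default_peak_windows()].
#' @param trough_window_ms Maximum time after the peak (ms) to accept a
#'   trough.
#' @param snr_criterion Detectability criterion (default 1).
#' @param level Click level used only to pick the default window.
#' @return A one-row `data.frame`: `wave`, `amplitude` (nV), `latency` (ms),
#'   `detected`.
#' @export
pick_wave <- function(response, wave = c("I", "V"), search_window = NULL,
                      trough_window_ms = 4, snr_criterion = 1, level = 105) {
  wave <- match.arg(wave)
  stopifnot(inherits(response, "averaged_response"))
  if (is.null(search_window)) search_window <- default_peak_windows(level)[[wave]]
  t_ms <- response$times * 1000
  if (search_window[1] < min(t_ms) || search_window[2] > max(t_ms))
    stop("search window lies outside the response epoch")
  x <- response$waveform
  fs_ms <- 1 / stats::median(diff(t_ms)) # samples per ms
  undetected <- data.frame(wave = wave, amplitude = NA_real_,
                           latency = NA_real_, detected = FALSE)
  win <- which(t_ms >= search_window[1] & t_ms <= search_window[2])
  if (length(win) < 3L) return(undetected)
  pk_local <- local_maxima(x[win])
  if (length(pk_local) == 0L) return(undetected)
  pk <- win[pk_local[which.max(x[win][pk_local])]] # ties -> earliest
  # first local minimum after the peak within the trough window
  tw_hi <- t_ms[pk] + trough_window_ms
  seg <- which(t_ms > t_ms[pk] & t_ms <= tw_hi)
  if (length(seg) < 3L) return(undetected)
  tr_local <- local_maxima(-x[seg])
  if (length(tr_local) == 0L) return(undetected)
  tr <- seg[tr_local[1L]]
  pref <- parabolic_refine(x, pk)
  tref <- parabolic_refine(x, tr)
  amplitude <- pref[2] - tref[2]
  latency <- t_ms[pk] + pref[1] / fs_ms
  if (!is.finite(amplitude) || amplitude <= 0) return(undetected)
  nv <- response$noise_var
  detected <- if (is.finite(nv) && nv > 0)
    amplitude >= snr_criterion * 4.5 * sqrt(nv) else TRUE
  if (!detected) return(undetected)
  data.frame(wave = wave, amplitude = amplitude, latency = latency,
             detected = TRUE)
}

#' Noise-floor estimate from the pre-stimulus baseline
#'
#' Runs the wave-picking algorithm on a pre-stimulus window of the same
#' duration as the wave search window ("dummy wave") for every response, and
#' summarizes the measurable dummy amplitudes by their geometric mean and
#' geometric SD. The detectability criterion is disabled here: the dummy
#' wave *is* the noise.
#'
#' @param responses A list of `averaged_response` objects.
#' @param baseline_window `c(lo, hi)` window in ms, entirely before 0.
#' @return List with `amplitudes` (per-response dummy amplitudes, NA when
#'   unmeasurable), `geometric_mean`, `geometric_sd`, `fraction_unmeasurable`.
#' @export
estimate_noise_floor <- function(responses, baseline_window = c(-3, -0.5)) {
  if (baseline_window[2] > 0)
    stop("baseline window must precede 0 ms")
  if (inherits(responses, "averaged_response")) responses <- list(responses)
  amps <- vapply(responses, function(r) {
    pre <- r$times < 0 # restrict to the pre-stimulus baseline
    r0 <- new_averaged_response(r$waveform[pre], r$times[pre],
                                weights = 1, noise_var = r$noise_var,
                                n_epochs = r$n_epochs)
    m <- pick_wave(r0, wave = "I", search_window = baseline_window,
                   trough_window_ms = diff(baseline_window),
                   snr_criterion = 0)
    if (m$detected) m$amplitude else NA_real_
  }, numeric(1))
  ok <- is.finite(amps) & amps > 0
  list(amplitudes = amps,
       geometric_mean = if (any(ok)) exp(mean(log(amps[ok]))) else NA_real_,
       geometric_sd = if (sum(ok) > 1) exp(stats::sd(log(amps[ok]))) else NA_real_,
       fraction_unmeasurable = mean(!ok))
}

#' Assemble the censored measurement table
#'
#' One row per subject x wave x level x masking x montage measurement, with
#' subject covariates joined. Undetected amplitudes are censored at the
#' dataset-wide minimum detected amplitude (the detection bound used by the
#' censored likelihood); a dataset with no detected amplitude has no defined
#' bound and is rejected.
#'
#' @param measurements `data.frame` with at least `subject`, `amplitude`,
#'   `detected` (and any condition columns).
#' @param cohort Optional `data.frame` of per-subject covariates with a
#'   `subject` column.
#' @return The measurement table with columns `censored` and `censor_bound`
#'   added; censored rows carry `amplitude = NA`.
#' @export
assemble_measurement_table <- function(measurements, cohort = NULL) {
  stopifnot(all(c("subject", "amplitude", "detected") %in% names(measurements)))
  det <- measurements$detected & is.finite(measurements$amplitude)
  if (!any(det))
    stop("no detected amplitudes: censoring bound undefined")
  bound <- min(measurements$amplitude[det])
  out <- measurements
  out$censored <- !det
  out$amplitude[!det] <- NA_real_
  out$censor_bound <- bound
  if (!is.null(cohort)) {
    stopifnot("subject" %in% names(cohort))
    out <- merge(out, cohort, by = "subject", sort = FALSE)
  }
  out
}
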