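# Shared continuous-recording operations: trigger delay compensation,
# zero-phase FIR filtering, epoching with baseline correction, and
# iterative-weighted averaging of evoked-potential sweeps.

#' Compensate the acoustic trigger delay
#'
#' Shifts every trigger time by `+delay` seconds (e.g. 0.9 ms for insert
#' earphone tube delay), leaving the signals untouched.
#'
#' @param rec A `recording`.
#' @param delay Delay in seconds (>= 0; a negative delay undoes a previous
#'   compensation).
#' @return The recording with shifted trigger times.
#' @export
compensate_trigger_delay <- function(rec, delay) {
  stopifnot(inherits(rec, "recording"), is.numeric(delay), length(delay) == 1L)
  rec$triggers$time <- rec$triggers$time + delay
  rec
}

fir_bandpass_taps <- function(band, fs, n_taps = 256L) {
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop(sprintf("band (%g, %g) Hz must lie strictly inside (0, %g) Hz",
                 band[1], band[2], fs / 2))
  h <- signal::fir1(n_taps - 1L, band / (fs / 2), type = "pass")
  h - mean(h) # exact null at DC (electrode drift rejection)
}

# Apply a linear-phase FIR to x with exact (n_taps-1)/2-sample delay
# compensation. The compensation is a frequency-domain phase ramp, exact for
# any tap parity (a 256-tap filter has a 127.5-sample group delay).
filter_zero_phase <- function(x, h) {
  n <- length(x)
  d <- (length(h) - 1) / 2
  nfft <- stats::nextn(n + length(h) - 1, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  H <- stats::fft(c(h, rep(0, nfft - length(h))))
  k <- c(0:(nfft / 2), -(nfft / 2 - 1):-1) / nfft
  Y <- X * H * exp(2i * pi * k * d)
  Re(stats::fft(Y, inverse = TRUE))[seq_len(n)] / nfft
}

#' Zero-phase FIR bandpass filter
#'
#' Filters every channel with a linear-phase windowed (Hamming) FIR bandpass
#' filter applied forward, with the filter's group delay compensated exactly,
#' so the net phase shift is zero across the band. The default is the
#' 256-tap design used for ABR (0.1--1.5 kHz) and FFR (0.06--1 kHz)
#' continuous recordings.
#'
#' @param rec A `recording`.
#' @param band `c(low, high)` corner frequencies in Hz; must lie inside the
#'   Nyquist interval.
#' @param n_taps Number of filter taps (default 256).
#' @return The filtered recording.
#' @export
fir_bandpass <- function(rec, band, n_taps = 256L) {
  stopifnot(inherits(rec, "recording"))
  h <- fir_bandpass_taps(band, rec$sampling_rate, n_taps)
  rec$channels <- apply(rec$channels, 2L, filter_zero_phase, h = h)
  rec
}

#' Epoch a recording around its triggers
#'
#' Cuts one epoch per trigger over `window` (seconds relative to the trigger,
#' half-open `[t0, t1)` in samples, trigger sample at t = 0) and subtracts
#' the per-epoch mean over `baseline`. Triggers whose window falls outside
#' the recording are dropped with a message; the dropped count is stored in
#' the `n_dropped` attribute.
#'
#' @param rec A `recording`.
#' @param window `c(t0, t1)` epoch window in seconds (e.g. `c(-0.003, 0.012)`
#'   for ABR, `c(-0.005, 0.450)` for FFR).
#' @param baseline `c(b0, b1)` baseline window in seconds, contained in
#'   `window`; `NULL` skips baseline correction.
#' @param channel Channel name or index to epoch.
#' @return An `epoch_set`.
#' @export
epoch_recording <- function(rec, window, baseline = c(window[1], 0),
                            channel = 1L) {
  stopifnot(inherits(rec, "recording"), window[1] < window[2])
  if (!is.null(baseline) &&
      (baseline[1] < window[1] || baseline[2] > window[2]))
    stop("`baseline` must be contained in `window`")
  fs <- rec$sampling_rate
  x <- rec$channels[, channel]
  i0 <- round(window[1] * fs)
  i1 <- round(window[2] * fs) - 1L # half-open [t0, t1)
  idx_rel <- i0:i1
  times <- idx_rel / fs
  trig_samp <- round(rec$triggers$time * fs) + 1L
  ok <- trig_samp + i0 >= 1L & trig_samp + i1 <= length(x)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(sprintf("epoch_recording: dropped %d trigger(s) too close to the record edge",
                    n_dropped))
  if (!any(ok)) stop("no trigger has a full epoch window inside the recording")
  ep <- t(vapply(trig_samp[ok], function(s) x[s + idx_rel],
                 numeric(length(idx_rel))))
  info <- rec$triggers[ok, , drop = FALSE]
  rownames(info) <- NULL
  bc <- FALSE
  if (!is.null(baseline)) {
    bsel <- times >= baseline[1] & times < baseline[2]
    if (!any(bsel)) stop("baseline window contains no samples")
    ep <- ep - rowMeans(ep[, bsel, drop = FALSE])
    bc <- TRUE
  }
  out <- new_epoch_set(ep, times, info, baseline_corrected = bc)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Iterative-weighted average of epochs
#'
#' Averages epochs with weights inversely proportional to each block's
#' residual-noise variance (the time-domain variance of the block mean minus
#' the current grand estimate), iterating until the estimate changes by less
#' than `tol` (relative to the waveform RMS) or `max_iter` is reached. With
#' the default block size of one epoch this down-weights noisy sweeps,
#' subsuming amplitude-threshold artifact rejection.
#'
#' The residual-noise variance of the returned average is estimated as
#' `1 / sum(1 / v_b)` over the per-block variances `v_b` (the variance of an
#' inverse-variance-weighted mean).
#'
#' @param x An `epoch_set` or a numeric matrix (epochs x samples).
#' @param block_size Number of consecutive epochs per weighting block.
#' @param tol Relative convergence tolerance on the estimate.
#' @param max_iter Maximum number of reweighting iterations.
#' @return An `averaged_response`.
#' @export
iterative_weighted_average <- function(x, block_size = 1L, tol = 1e-6,
                                       max_iter = 50L) {
  ep <- if (inherits(x, "epoch_set")) x$epochs else as.matrix(x)
  times <- if (inherits(x, "epoch_set")) x$times
           else (seq_len(ncol(ep)) - 1)
  n <- nrow(ep)
  if (n < 1L) stop("no epochs to average")
  if (n == 1L) {
    warning("single epoch: returned as-is with infinite noise variance")
    return(new_averaged_response(ep[1L, ], times, weights = 1,
                                 noise_var = Inf, n_epochs = 1L))
  }
  blk <- rep(seq_len(ceiling(n / block_size)), each = block_size)[seq_len(n)]
  nb <- max(blk)
  B <- if (block_size == 1L) ep
       else t(vapply(seq_len(nb),
                     function(b) colMeans(ep[blk == b, , drop = FALSE]),
                     numeric(ncol(ep))))
  est <- colMeans(B)
  w <- rep(1 / nb, nb)
  scale_ref <- mean(B^2)
  for (it in seq_len(max_iter)) {
    rv <- rowMeans((B - rep(est, each = nb))^2)
    if (all(rv <= 1e-20 * scale_ref)) { # noiseless/identical blocks
      w <- rep(1 / nb, nb)
      break
    }
    w <- 1 / pmax(rv, max(rv) * 1e-12)
    w <- w / sum(w)
    new_est <- drop(w %*% B)
    delta <- sqrt(mean((new_est - est)^2))
    est <- new_est
    if (delta <= tol * (sqrt(mean(est^2)) + sqrt(scale_ref) * 1e-12)) break
  }
  rv <- rowMeans((B - rep(est, each = nb))^2)
  noise_var <- if (all(rv <= 1e-20 * scale_ref)) 0 else 1 / sum(1 / pmax(rv, max(rv) * 1e-12))
  ep_w <- (w / block_size)[blk] # expand block weights to epochs
  new_averaged_response(est, times, weights = ep_w / sum(ep_w),
                        noise_var = noise_var, n_epochs = n)
}
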