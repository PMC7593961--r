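# Group-delay (FFR latency) estimation: exhaustive enumeration of the phase
# unwrappings consistent with a latency range, ordinary least squares of
# unwrapped phase vs frequency, and an independent circular grid-search
# oracle used for verification.

# Wrap to the principal branch (-pi, pi].
wrap_phase <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

#' Phase set for group-delay estimation
#'
#' Four components at strictly increasing frequencies with principal-branch
#' phases, measured either on the addition (ENV) or subtraction (TFS)
#' waveform.
#'
#' @param freqs Frequencies in Hz, strictly increasing.
#' @param phases Phases in radians (wrapped to (-pi, pi\] on construction).
#' @param source `"ENV"` or `"TFS"`.
#' @return An object of class `phase_set`.
#' @export
phase_set <- function(freqs, phases, source = c("ENV", "TFS")) {
  source <- match.arg(source)
  stopifnot(length(freqs) == length(phases), length(freqs) >= 2L)
  if (is.unsorted(freqs, strictly = TRUE))
    stop("`freqs` must be strictly increasing")
  structure(list(freqs = as.numeric(freqs),
                 phases = wrap_phase(as.numeric(phases)),
                 source = source),
            class = "phase_set")
}

#' Enumerate phase unwrappings consistent with a latency range
#'
#' A group delay tau implies phases `phi0 - 2 pi f tau`; each measured phase
#' is known only up to an integer multiple of 2 pi. This enumerates every
#' vector of 2-pi adjustments (the first component fixed at zero, since a
#' common shift changes only the intercept) for which some tau in
#' `latency_range_ms` makes the adjusted phase the principal-branch value,
#' i.e. all unwrappings consistent with a delay in the range. The list is
#' finite, duplicates removed, and grows monotonically with the range.
#'
#' @param ps A `phase_set`.
#' @param latency_range_ms `c(lo, hi)` latency range in ms (default 0--30).
#' @return Matrix of candidate unwrapped phase vectors (one row per
#'   candidate) with attribute `freqs`.
#' @export
enumerate_unwrappings <- function(ps, latency_range_ms = c(0, 30)) {
  stopifnot(inherits(ps, "phase_set"), latency_range_ms[1] <= latency_range_ms[2])
  f <- ps$freqs
  phi <- ps$phases
  tau <- latency_range_ms / 1000
  m <- length(f)
  k_ranges <- vector("list", m)
  k_ranges[[1]] <- 0L
  for (i in 2:m) {
    df <- f[i] - f[1]
    # k_i nearest-integer-consistent with tau: k = round((-2 pi df tau - (phi_i - phi_1)) / 2 pi)
    k_at <- function(tt) round((-df * tt) - (phi[i] - phi[1]) / (2 * pi))
    k_ranges[[i]] <- seq(k_at(tau[2]), k_at(tau[1]))
  }
  grid <- as.matrix(expand.grid(k_ranges))
  cand <- grid * (2 * pi) + rep(phi, each = nrow(grid))
  cand <- unique(cand)
  dimnames(cand) <- NULL
  attr(cand, "freqs") <- f
  cand
}

#' Fit the group delay from candidate unwrappings
#'
#' Ordinary least squares of unwrapped phase vs frequency for every
#' candidate; the latency is `-slope / (2 pi)` (reported in ms) and the best
#' candidate minimizes the mean squared phase residual (radians^2). Ties in
#' MSE are broken toward the smallest latency. The estimate is accepted only
#' when the latency lies in `latency_range_ms` and the MSE is strictly below
#' `mse_criterion` (default 0.01 rad^2).
#'
#' @param candidates Candidate matrix from [enumerate_unwrappings()] (with
#'   its `freqs` attribute), or a `phase_set` (then enumeration is run
#'   internally).
#' @param latency_range_ms Acceptance range in ms.
#' @param mse_criterion Maximum accepted MSE (strict inequality).
#' @return List of class `group_delay_estimate`: `latency_ms`, `intercept`,
#'   `fit_mse`, `n_candidates_considered`, `accepted`.
#' @export
fit_group_delay <- function(candidates, latency_range_ms = c(0, 30),
                            mse_criterion = 0.01) {
  if (inherits(candidates, "phase_set"))
    candidates <- enumerate_unwrappings(candidates, latency_range_ms)
  f <- attr(candidates, "freqs")
  nc <- nrow(candidates)
  if (is.null(nc) || nc == 0L)
    return(structure(list(latency_ms = NA_real_, intercept = NA_real_,
                          fit_mse = NA_real_, n_candidates_considered = 0L,
                          accepted = FALSE),
                     class = "group_delay_estimate"))
  fc <- f - mean(f)
  sxx <- sum(fc^2)
  slopes <- drop(candidates %*% fc) / sxx
  means <- rowMeans(candidates)
  fitted <- outer(slopes, fc) + means
  mse <- rowMeans((candidates - fitted)^2)
  lat <- -slopes / (2 * pi) * 1000
  in_range <- lat >= latency_range_ms[1] & lat <= latency_range_ms[2]
  pool <- if (any(in_range)) which(in_range) else seq_len(nc)
  ord <- pool[order(mse[pool], lat[pool])] # min MSE, ties -> smallest latency
  best <- ord[1L]
  accepted <- in_range[best] && mse[best] < mse_criterion
  structure(list(latency_ms = lat[best],
                 intercept = means[best] - slopes[best] * mean(f),
                 fit_mse = mse[best],
                 n_candidates_considered = nc,
                 accepted = accepted),
            class = "group_delay_estimate")
}

#' @export
print.group_delay_estimate <- function(x, ...) {
  cat(sprintf("<group_delay> %.3f ms (MSE %.2g, %d candidates, %s)\n",
              x$latency_ms, x$fit_mse, x$n_candidates_considered,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Estimate the group delay of a phase set
#'
#' Convenience wrapper: enumerate unwrappings, fit, return the estimate.
#'
#' @inheritParams enumerate_unwrappings
#' @inheritParams fit_group_delay
#' @return A `group_delay_estimate`.
#' @export
estimate_group_delay <- function(ps, latency_range_ms = c(0, 30),
                                 mse_criterion = 0.01) {
  fit_group_delay(enumerate_unwrappings(ps, latency_range_ms),
                  latency_range_ms, mse_criterion)
}

#' Brute-force circular grid oracle for the group delay
#'
#' Independent verification path: scans tau over the latency range on a
#' fixed grid and minimizes the circular residual
#' `sum(wrap(phi_i + 2 pi f_i tau - mu)^2)` where `mu` is the circular
#' intercept (argument of the resultant of the rotated phases). Used to
#' cross-check [fit_group_delay()]; it shares no code with the unwrapping
#' path.
#'
#' @param ps A `phase_set`.
#' @param latency_range_ms `c(lo, hi)` in ms.
#' @param grid_step_ms Grid step in ms (default 0.01).
#' @return Latency in ms; attribute `boundary` is `TRUE` when the minimum
#'   sits on a range edge.
#' @export
oracle_grid_delay <- function(ps, latency_range_ms = c(0, 30),
                              grid_step_ms = 0.01) {
  stopifnot(inherits(ps, "phase_set"))
  taus <- seq(latency_range_ms[1], latency_range_ms[2], by = grid_step_ms) / 1000
  th <- outer(taus, 2 * pi * ps$freqs) + rep(ps$phases, each = length(taus))
  z <- exp(1i * th)
  mu <- Arg(rowSums(z))
  resid <- wrap_phase(th - mu)
  cost <- rowSums(resid^2)
  i <- which.min(cost)
  out <- taus[i] * 1000
  attr(out, "boundary") <- i == 1L || i == length(taus)
  out
}

#' Group delay from measured spectral components
#'
#' Applies the all-four SNR rule: the latency is estimated only when all
#' four components of the target frequency region strictly exceed the SNR
#' criterion; otherwise a non-accepted estimate with `NA` latency is
#' returned.
#'
#' @param freqs,phases,snrs The four component frequencies (Hz), phases
#'   (radians) and SNRs (dB), in matching order.
#' @param source `"ENV"` or `"TFS"`.
#' @param snr_threshold_db Inclusion criterion (strict, default 6.64 dB).
#' @inheritParams fit_group_delay
#' @return A `group_delay_estimate`.
#' @export
group_delay_from_components <- function(freqs, phases, snrs,
                                        source = c("ENV", "TFS"),
                                        snr_threshold_db = 6.64,
                                        latency_range_ms = c(0, 30),
                                        mse_criterion = 0.01) {
  source <- match.arg(source)
  if (!all_components_pass(snrs, snr_threshold_db))
    return(structure(list(latency_ms = NA_real_, intercept = NA_real_,
                          fit_mse = NA_real_, n_candidates_considered = 0L,
                          accepted = FALSE),
                     class = "group_delay_estimate"))
  ord <- order(freqs)
  estimate_group_delay(phase_set(freqs[ord], phases[ord], source),
                       latency_range_ms, mse_criterion)
}
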