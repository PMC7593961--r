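#' Continuous multichannel recording
#'
#' The in-memory container for continuous EEG-like data: a samples-by-channels
#' matrix, a sampling rate, and a table of stimulus trigger events. Trigger
#' times are in seconds from the start of the recording and must be strictly
#' increasing.
#'
#' @param channels Numeric matrix (samples x channels) or a numeric vector for
#'   a single channel. Column names identify electrodes/montages.
#' @param sampling_rate Sampling rate in Hz.
#' @param triggers `data.frame` with columns `time` (seconds) and `code`
#'   (character or integer event label).
#' @return An object of class `recording`.
#' @export
new_recording <- function(channels, sampling_rate, triggers) {
  if (is.vector(channels)) channels <- matrix(channels, ncol = 1L,
                                              dimnames = list(NULL, "ch1"))
  stopifnot(is.matrix(channels), is.numeric(channels),
            is.numeric(sampling_rate), length(sampling_rate) == 1L,
            sampling_rate > 0)
  if (!is.data.frame(triggers) || !all(c("time", "code") %in% names(triggers)))
    stop("`triggers` must be a data.frame with columns `time` and `code`")
  if (is.unsorted(triggers$time, strictly = TRUE))
    stop("trigger times must be strictly increasing")
  structure(list(channels = channels,
                 sampling_rate = sampling_rate,
                 triggers = triggers),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d samples x %d channel(s) @ %g Hz, %d triggers\n",
              nrow(x$channels), ncol(x$channels), x$sampling_rate,
              nrow(x$triggers)))
  invisible(x)
}

#' Epoched data
#'
#' @param epochs Numeric matrix, one row per epoch (sweep), one column per
#'   sample.
#' @param times Numeric vector of per-sample times relative to the trigger
#'   (seconds); length equals `ncol(epochs)`.
#' @param info `data.frame` of per-epoch metadata (ear, polarity, code, ...),
#'   one row per epoch; may be `NULL`.
#' @param baseline_corrected Logical flag.
#' @return An object of class `epoch_set`.
#' @export
new_epoch_set <- function(epochs, times, info = NULL, baseline_corrected = FALSE) {
  stopifnot(is.matrix(epochs), length(times) == ncol(epochs))
  if (!is.null(info)) stopifnot(nrow(info) == nrow(epochs))
  structure(list(epochs = epochs, times = times, info = info,
                 baseline_corrected = baseline_corrected),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d samples, t = [%.4f, %.4f] s%s\n",
              nrow(x$epochs), ncol(x$epochs), min(x$times), max(x$times),
              if (isTRUE(x$baseline_corrected)) ", baseline-corrected" else ""))
  invisible(x)
}

#' Weighted-average evoked response
#'
#' @param waveform Numeric vector, the averaged waveform.
#' @param times Per-sample times relative to the trigger (seconds).
#' @param weights Per-epoch weights used in the average (nonnegative, sum 1).
#' @param noise_var Residual-noise variance estimate of the average (same
#'   squared units as the waveform).
#' @param n_epochs Number of epochs that entered the average.
#' @return An object of class `averaged_response`.
#' @export
new_averaged_response <- function(waveform, times, weights, noise_var, n_epochs) {
  stopifnot(length(waveform) == length(times))
  if (any(weights < 0)) stop("weights must be nonnegative")
  s <- sum(weights)
  if (is.finite(s) && s > 0 && abs(s - 1) > 1e-8) weights <- weights / s
  structure(list(waveform = waveform, times = times, weights = weights,
                 noise_var = noise_var, n_epochs = n_epochs),
            class = "averaged_response")
}

#' @export
print.averaged_response <- function(x, ...) {
  cat(sprintf("<averaged_response> %d samples, %d epochs, noise var %.4g\n",
              length(x$waveform), x$n_epochs, x$noise_var))
  invisible(x)
}

sampling_rate_of <- function(x) {
  dt <- diff(x$times)
  1 / stats::median(dt)
}

#' Write / read a recording as a plain-text directory
#'
#' The documented on-disk container: `meta.json` (sampling rate, channel
#' names), `channels.csv` (one column per channel) and `triggers.csv`.
#' Intended for small exchange/inspection files, not bulk storage.
#'
#' @param rec A `recording`.
#' @param path Directory to create/fill.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(sampling_rate = rec$sampling_rate,
                            channel_names = colnames(rec$channels)),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(as.data.frame(rec$channels),
                   file.path(path, "channels.csv"), row.names = FALSE)
  utils::write.csv(rec$triggers, file.path(path, "triggers.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  ch <- as.matrix(utils::read.csv(file.path(path, "channels.csv")))
  colnames(ch) <- meta$channel_names
  trg <- utils::read.csv(file.path(path, "triggers.csv"),
                         colClasses = c(time = "numeric", code = "character"))
  new_recording(ch, meta$sampling_rate, trg)
}
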