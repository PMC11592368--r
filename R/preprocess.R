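#' Zero-phase band-pass and notch filtering
#'
#' Conditions a continuous recording with a Butterworth band-pass (default
#' 0.1-40 Hz, 4th order, realized as `signal::butter(2, band)` which yields a
#' 4th-order band-pass transfer function) plus an IIR notch (default 50 Hz
#' mains, biquad with quality factor `q`). Both are applied forward-backward
#' with [signal::filtfilt()], so the output is zero phase.
#'
#' @param x A [raw_recording()].
#' @param band Length-2 numeric `(low, high)` in Hz, `0 < low < high < fs/2`.
#' @param notch Notch center frequency in Hz (`NULL` to skip), below Nyquist.
#' @param q Notch quality factor (center frequency / -3 dB bandwidth).
#'   Default 30.
#'
#' @return A filtered [raw_recording()] of the same shape.
#' @export
filter_signal <- function(x, band = c(0.1, 40), notch = 50, q = 30) {
  if (!inherits(x, "raw_recording"))
    data_error("`x` must be a raw_recording")
  fs <- x$fs
  if (length(band) != 2L || !(0 < band[1] && band[1] < band[2] &&
                              band[2] < fs / 2))
    config_error("`band` must satisfy 0 < low < high < fs/2")
  if (!is.null(notch) && !(notch > 0 && notch < fs / 2))
    config_error("`notch` must lie below the Nyquist frequency")

  bp <- signal::butter(2, c(band[1], band[2]) / (fs / 2), type = "pass")
  flt <- function(v) signal::filtfilt(bp, v)
  if (!is.null(notch)) {
    nf <- notch_biquad(notch, fs, q)
    flt <- function(v) signal::filtfilt(nf, signal::filtfilt(bp, v))
  }
  out <- t(apply(x$data, 1L, flt))
  dimnames(out) <- dimnames(x$data)
  raw_recording(out, fs, markers = x$markers)
}

# Biquad notch (RBJ audio-EQ cookbook): unity gain away from f0, zero at f0.
notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Re-reference to the averaged mastoids
#'
#' Subtracts the sample-wise mean of the two mastoid channels from every
#' channel (binaural mastoid reference).
#'
#' @param x A [raw_recording()].
#' @param mastoids Length-2 character vector of mastoid channel labels.
#'   Default `c("TP9", "TP10")`, the mastoid-adjacent sites of a 64-channel
#'   10-20 cap.
#'
#' @return A re-referenced [raw_recording()].
#' @export
rereference <- function(x, mastoids = c("TP9", "TP10")) {
  if (!inherits(x, "raw_recording"))
    data_error("`x` must be a raw_recording")
  labels <- channel_labels(x)
  missing <- setdiff(mastoids, labels)
  if (length(mastoids) != 2L || length(missing) > 0)
    data_error(sprintf("mastoid channel(s) not present: %s",
                       paste(if (length(missing)) missing else mastoids,
                             collapse = ", ")))
  ref <- colMeans(x$data[mastoids, , drop = FALSE])
  out <- sweep(x$data, 2L, ref, "-")
  raw_recording(out, x$fs, markers = x$markers)
}

#' Cut stimulus-locked epochs with baseline correction
#'
#' Extracts one epoch per marker using the half-open sample convention
#' `[start, end)` in milliseconds relative to the marker (a (-500, 2000)
#' window at 1000 Hz gives 2500 samples), then subtracts the per-epoch,
#' per-channel mean over the baseline interval. Markers too close to the
#' record edge are dropped with a warning reporting the count; zero markers
#' yield an empty (0-epoch) result, not an error.
#'
#' @param x A [raw_recording()] with markers.
#' @param window_ms Epoch window `(start, end)` in ms, start < 0 <= end.
#' @param baseline_ms Baseline interval in ms, inside the window. Default
#'   `c(-500, 0)`, the pre-stimulus half second.
#'
#' @return An [epoched_recording()]; attribute `n_dropped` counts epochs
#'   discarded at the record edges.
#' @export
epoch_baseline <- function(x, window_ms = c(-500, 2000),
                           baseline_ms = c(-500, 0)) {
  if (!inherits(x, "raw_recording"))
    data_error("`x` must be a raw_recording")
  if (!(window_ms[1] < 0 && 0 <= window_ms[2]))
    config_error("epoch window must satisfy start < 0 <= end")
  if (baseline_ms[1] < window_ms[1] || baseline_ms[2] > window_ms[2])
    config_error("baseline interval must lie inside the epoch window")
  fs <- x$fs
  off_start <- as.integer(round(window_ms[1] * fs / 1000))
  off_end <- as.integer(round(window_ms[2] * fs / 1000)) - 1L
  bl_start <- as.integer(round(baseline_ms[1] * fs / 1000))
  bl_end <- as.integer(round(baseline_ms[2] * fs / 1000)) - 1L
  n_samp <- off_end - off_start + 1L
  n_ch <- nrow(x$data)
  labels <- channel_labels(x)

  pos <- x$markers$sample
  ok <- (pos + off_start >= 1L) & (pos + off_end <= ncol(x$data))
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    warning(sprintf("%d epoch(s) dropped: window exceeds record bounds",
                    n_dropped))
  pos <- pos[ok]
  arr <- array(NA_real_, dim = c(length(pos), n_ch, n_samp),
               dimnames = list(NULL, labels, NULL))
  bl_idx <- (bl_start:bl_end) - off_start + 1L
  for (e in seq_along(pos)) {
    seg <- x$data[, (pos[e] + off_start):(pos[e] + off_end), drop = FALSE]
    seg <- seg - rowMeans(seg[, bl_idx, drop = FALSE])
    arr[e, , ] <- seg
  }
  out <- epoched_recording(arr, fs, window_ms, baseline_ms)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Post-stimulus segment of an epoched recording
#'
#' Convenience accessor returning, per epoch and channel, the samples from
#' stimulus onset (t = 0) up to `dur_ms`, truncated at the window end. Used by
#' the spectral stage, which analyzes the first 10 s after the stimulus when
#' the epoch is long enough.
#'
#' @param x An [epoched_recording()].
#' @param dur_ms Requested post-stimulus duration in ms.
#' @return List with `data` (epochs x channels x samples array) and `dur_ms`
#'   (the duration actually available).
#' @keywords internal
post_stimulus_segment <- function(x, dur_ms) {
  avail <- x$window_ms[2]
  use <- min(dur_ms, avail)
  i0 <- as.integer(round(-x$window_ms[1] * x$fs / 1000)) + 1L
  n <- as.integer(round(use * x$fs / 1000))
  list(data = x$data[, , i0:(i0 + n - 1L), drop = FALSE], dur_ms = use)
}
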