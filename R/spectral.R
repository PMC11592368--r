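#' Frequency band scheme
#'
#' The five analysis bands: delta (2-4 Hz), theta (4-8 Hz), alpha (8-13 Hz),
#' beta (13-30 Hz) and low gamma (30-40 Hz). Bands share edges but do not
#' overlap; frequency bins are assigned half-open `[low, high)`, with the
#' final band additionally closed at its upper edge, so every bin is counted
#' exactly once.
#'
#' @param bands Named list of length-2 numeric `(low, high)` vectors in Hz.
#' @return Object of class `band_scheme`.
#' @export
band_scheme <- function(bands = list(delta = c(2, 4), theta = c(4, 8),
                                     alpha = c(8, 13), beta = c(13, 30),
                                     gamma_low = c(30, 40))) {
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    config_error("bands must be named")
  lims <- do.call(rbind, bands)
  if (any(lims[, 1] >= lims[, 2]))
    config_error("each band needs low < high")
  o <- order(lims[, 1])
  if (any(lims[o, 2][-nrow(lims)] > lims[o, 1][-1]))
    config_error("bands may share edges but must not overlap")
  structure(bands[o], class = "band_scheme")
}

#' Relative band power of a post-stimulus segment
#'
#' Computes the one-sided FFT periodogram (rectangular window) of each
#' channel, integrates it over the bands of `scheme`, and normalizes each
#' band's absolute power by the total power, defined as the sum over the five
#' bands so that the relative powers form a simplex (sum to 1 exactly).
#'
#' @param x Numeric vector (one channel) or channels-by-samples matrix.
#' @param fs Sampling rate in Hz.
#' @param scheme A [band_scheme()].
#' @param subject,task Identifier columns replicated into the output.
#'
#' @return Data frame with columns `subject`, `task`, `channel`, `band`,
#'   `absolute_power` (signal-squared units per the time-domain mean square)
#'   and `relative_power` (fraction in `[0, 1]`, summing to 1 per channel).
#' @export
#'
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 10, by = 1e-3))  # 10 Hz probe
#' bp <- band_relative_power(x, fs = 1000)
#' bp[bp$band == "alpha", "relative_power"]       # > 0.99
band_relative_power <- function(x, fs, scheme = band_scheme(),
                                subject = NA_character_,
                                task = NA_character_) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L, dimnames = list("ch1"))
  n <- ncol(x)
  if (n < 2 * fs)
    data_error("segment must be at least 2 s long")
  if (is.null(rownames(x))) rownames(x) <- paste0("ch", seq_len(nrow(x)))
  freqs <- fs * (0:(n - 1)) / n
  half <- which(freqs <= fs / 2)
  band_names <- names(scheme)
  top_edge <- max(vapply(scheme, `[`, numeric(1), 2))

  rows <- lapply(rownames(x), function(ch) {
    v <- x[ch, ]
    if (all(v == 0))
      numeric_error(sprintf("undefined power: channel %s is identically zero",
                            ch))
    pgram <- Mod(fft(v))^2 / n^2       # two-sided, sums to mean(v^2)
    onesided <- pgram[half]
    dup <- freqs[half] > 0 & freqs[half] < fs / 2
    onesided[dup] <- 2 * onesided[dup]
    fr <- freqs[half]
    absp <- vapply(band_names, function(b) {
      lim <- scheme[[b]]
      sel <- fr >= lim[1] & (fr < lim[2] | (lim[2] == top_edge & fr == lim[2]))
      sum(onesided[sel])
    }, numeric(1))
    total <- sum(absp)
    if (total == 0)
      numeric_error(sprintf("undefined power: channel %s has no energy in the analysis bands", ch))
    data.frame(subject = subject, task = task, channel = ch,
               band = band_names, absolute_power = unname(absp),
               relative_power = unname(absp / total))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Band power for an epoched recording
#'
#' Runs [band_relative_power()] on the post-stimulus segment of each epoch
#' (nominally the first 10 s after the stimulus; for epochs shorter than that
#' the full post-stimulus span is used and a deviation warning is emitted) and
#' averages the absolute powers across epochs before renormalizing.
#'
#' @param epochs An [epoched_recording()].
#' @param scheme A [band_scheme()].
#' @param segment_ms Nominal post-stimulus analysis duration in ms.
#'   Default 10000.
#' @inheritParams band_relative_power
#' @return Data frame as in [band_relative_power()].
#' @export
band_power_table <- function(epochs, scheme = band_scheme(),
                             segment_ms = 10000, subject = NA_character_,
                             task = NA_character_) {
  if (!inherits(epochs, "epoched_recording"))
    data_error("`epochs` must be an `epoched_recording`")
  seg <- post_stimulus_segment(epochs, segment_ms)
  if (seg$dur_ms < segment_ms)
    deviation_warning(sprintf(
      "spectral window shortened to %g ms (epoch too short for %g ms)",
      seg$dur_ms, segment_ms))
  n_ep <- dim(seg$data)[1L]
  labels <- dimnames(seg$data)[[2L]]
  per_epoch <- lapply(seq_len(n_ep), function(e) {
    m <- matrix(seg$data[e, , , drop = FALSE], nrow = dim(seg$data)[2L],
                dimnames = list(labels, NULL))
    band_relative_power(m, epochs$fs, scheme, subject = subject, task = task)
  })
  out <- per_epoch[[1L]]
  if (n_ep > 1L) {
    absmat <- vapply(per_epoch, function(d) d$absolute_power,
                     numeric(nrow(out)))
    out$absolute_power <- rowMeans(absmat)
    tot <- stats::ave(out$absolute_power,
                      out$channel, FUN = sum)
    out$relative_power <- out$absolute_power / tot
  }
  out
}
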