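#' Generate calibration noise
#'
#' Seeded white (flat spectrum) or pink (1/f spectrum) Gaussian noise,
#' standardized to zero mean and unit standard deviation. Pink noise is
#' produced by spectral shaping: the FFT of a white series is scaled by
#' `1/sqrt(f)` (DC zeroed, Hermitian symmetry preserved) so its power spectral
#' density is proportional to `1/f` by construction. These signals are the
#' validation inputs for the entropy core: white-noise multiscale entropy
#' declines with scale while pink noise stays approximately flat and exceeds
#' white noise at coarse scales.
#'
#' @param kind `"white"` or `"pink"`.
#' @param n Series length, at least 2.
#' @param fs Sampling rate in Hz; only sets the frequency axis of the shaping
#'   filter, the sample values do not depend on it. Default 1000.
#' @param seed Optional integer seed. When supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#'
#' @return Numeric vector of length `n`, zero mean, unit SD.
#' @export
#'
#' @examples
#' w <- gen_noise("white", 1024, seed = 1)
#' p <- gen_noise("pink", 1024, seed = 1)
gen_noise <- function(kind = c("white", "pink"), n, fs = 1000, seed = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L)
    numeric_error("invalid length: `n` must be an integer >= 2")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  w <- rnorm(n)
  x <- if (kind == "white") {
    w
  } else {
    f <- fs * (seq_len(n) - 1) / n
    f <- pmin(f, fs - f)          # alias frequencies above Nyquist
    amp <- c(0, 1 / sqrt(f[-1]))  # zero out DC
    Re(fft(fft(w) * amp, inverse = TRUE)) / n
  }
  x <- x - mean(x)
  x / sd(x)
}
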