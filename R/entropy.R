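#' Multiscale entropy parameters
#'
#' Bundle of the tunable quantities of the multiscale-entropy computation.
#'
#' @param m Template length (points compared per match). Default 2, the
#'   standard choice for EEG sample entropy.
#' @param r_factor Match tolerance expressed as a fraction of the standard
#'   deviation of the original (scale-1) series. The absolute tolerance
#'   `r = r_factor * sd(x)` is computed once and held fixed across scales
#'   (Costa convention), which is what makes the canonical white-noise decline
#'   across scales visible.
#' @param scales Integer vector of coarse-graining factors, strictly
#'   increasing. Default `1:20`.
#' @param min_coarse_length Minimum length a coarse-grained series must have
#'   for its sample entropy to be considered estimable; shorter scales are
#'   flagged invalid rather than fabricated. Default 50.
#'
#' @return An object of class `mse_params`.
#' @export
mse_params <- function(m = 2L, r_factor = 0.2, scales = 1:20,
                       min_coarse_length = 50L) {
  m <- as.integer(m)
  scales <- as.integer(scales)
  if (length(m) != 1L || is.na(m) || m < 1L)
    config_error("`m` must be a single integer >= 1")
  if (!is.numeric(r_factor) || length(r_factor) != 1L || r_factor <= 0)
    config_error("`r_factor` must be a single positive number")
  if (length(scales) < 1L || anyNA(scales) || any(scales < 1L) ||
      any(diff(scales) <= 0L))
    config_error("`scales` must be strictly increasing positive integers")
  min_coarse_length <- as.integer(min_coarse_length)
  if (is.na(min_coarse_length) || min_coarse_length < 1L)
    config_error("`min_coarse_length` must be a positive integer")
  structure(
    list(m = m, r_factor = r_factor, scales = scales,
         min_coarse_length = min_coarse_length),
    class = "mse_params"
  )
}

#' Coarse-grain a time series
#'
#' Replaces each non-overlapping window of `tau` consecutive samples by its
#' arithmetic mean, shortening the series to `floor(N / tau)` points. Trailing
#' samples that do not fill a complete window are discarded. With `tau = 1`
#' the output equals the input.
#'
#' @param x Numeric vector.
#' @param tau Scale factor (window length), a positive integer not exceeding
#'   `length(x)`.
#'
#' @return Numeric vector of length `floor(length(x) / tau)`.
#' @export
#'
#' @examples
#' coarse_grain(1:6, 2)  # 1.5 3.5 5.5
#' coarse_grain(1:6, 4)  # 2.5
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  if (length(tau) != 1L || is.na(tau) || tau < 1L)
    config_error("`tau` must be a single integer >= 1")
  n <- length(x)
  if (tau > n)
    numeric_error(sprintf("invalid scale: tau = %d exceeds series length %d",
                          tau, n))
  if (tau == 1L) return(as.numeric(x))
  nwin <- n %/% tau
  colMeans(matrix(x[seq_len(nwin * tau)], nrow = tau))
}

#' Sample entropy template-match counts
#'
#' Returns the raw pair counts underlying sample entropy: `B` is the number of
#' pairs `i < j` of m-length templates within Chebyshev distance `r` of each
#' other (self-matches excluded), and `A` the number of those pairs still
#' within `r` at the next point. Exposed so the production kernel can be
#' compared count-for-count against independent implementations.
#'
#' @inheritParams sample_entropy
#' @return Named numeric vector `c(A = , B = )`.
#' @export
sample_entropy_counts <- function(x, m = 2L, r) {
  m <- as.integer(m)
  if (length(x) < m + 2L)
    numeric_error(sprintf(
      "invalid length: need at least m + 2 = %d samples, got %d",
      m + 2L, length(x)))
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0)
    config_error("`r` must be a single positive number")
  sampen_counts_cpp(as.numeric(x), m, r)
}

#' Sample entropy
#'
#' Computes SampEn(m, r) = -ln(A / B), where `B` counts pairs of m-point
#' templates matching within absolute tolerance `r` under the Chebyshev
#' (maximum-coordinate) distance and `A` counts the pairs still matching at
#' the (m+1)-th point. Self-matches are excluded and the tolerance test uses
#' `<= r`. Lower values indicate a more regular (more predictable) series.
#'
#' When no template pair matches at either length (`A == 0` or `B == 0`) the
#' statistic is undefined and `NA` is returned with attribute
#' `undefined = TRUE`; callers propagate it as missing.
#'
#' @param x Numeric vector of length at least `m + 2`.
#' @param m Template length. Default 2.
#' @param r Absolute match tolerance (same units as `x`), positive.
#'
#' @return Sample entropy in nats, or `NA` (attribute `undefined = TRUE`)
#'   when the conditional probability is not estimable.
#' @export
#'
#' @examples
#' sample_entropy(rep(1, 50), m = 2, r = 0.2)        # 0: perfectly regular
#' x <- sin(seq(0, 20 * pi, length.out = 500))
#' sample_entropy(x, m = 2, r = 0.2 * sd(x))
sample_entropy <- function(x, m = 2L, r) {
  counts <- sample_entropy_counts(x, m, r)
  if (counts[["A"]] == 0 || counts[["B"]] == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  -log(counts[["A"]] / counts[["B"]])
}

#' Multiscale entropy curve
#'
#' Coarse-grains `x` at each scale in `params$scales` and computes sample
#' entropy of the coarse series with a fixed absolute tolerance
#' `r = r_factor * sd(x)` derived once from the original series. Scales whose
#' coarse-grained length falls below `params$min_coarse_length` (or below
#' `m + 2`) are flagged invalid and carry `NA`, never a fabricated value.
#'
#' @param x Numeric vector.
#' @param params An [mse_params()] object.
#'
#' @return Data frame with columns `scale`, `sampen`, `valid`, and attributes
#'   `params` and `r` (the absolute tolerance used). `valid` is `FALSE` for
#'   scales too short to estimate; `sampen` can also be `NA` on a valid scale
#'   when no template matches occurred (undefined SampEn).
#' @export
mse_curve <- function(x, params = mse_params()) {
  if (!inherits(params, "mse_params"))
    config_error("`params` must be an `mse_params` object")
  x <- as.numeric(x)
  n <- length(x)
  r <- params$r_factor * sd(x)
  min_len <- max(params$min_coarse_length, params$m + 2L)
  lens <- n %/% params$scales
  valid <- lens >= min_len
  if (!any(valid))
    numeric_error("empty curve: no scale satisfies the minimum coarse length")
  if (!is.finite(r) || r <= 0)
    numeric_error("series has zero variance; tolerance r is degenerate")
  vals <- rep(NA_real_, length(params$scales))
  for (i in seq_along(params$scales)) {
    if (!valid[i]) next
    cg <- coarse_grain(x, params$scales[i])
    vals[i] <- as.numeric(sample_entropy(cg, params$m, r))
  }
  structure(
    data.frame(scale = params$scales, sampen = vals, valid = valid),
    params = params, r = r
  )
}

#' Multiscale entropy averaged over epochs
#'
#' Computes one MSE curve per epoch and averages them pointwise, ignoring
#' undefined values. Short epochs (2.5 s at 1000 Hz) are too short at coarse
#' scales for concatenation to be meaningful, so per-epoch curves are the
#' natural unit; single long epochs reduce to [mse_curve()].
#'
#' @param epochs Numeric matrix, epochs in rows and samples in columns (or a
#'   single numeric vector treated as one epoch).
#' @param params An [mse_params()] object.
#'
#' @return Data frame as in [mse_curve()] plus column `n_epochs` giving, per
#'   scale, how many epochs contributed a defined value.
#' @export
mse_epochs <- function(epochs, params = mse_params()) {
  if (is.vector(epochs)) epochs <- matrix(epochs, nrow = 1L)
  if (!is.matrix(epochs) || nrow(epochs) < 1L)
    data_error("`epochs` must be a non-empty matrix (epochs x samples)")
  curves <- lapply(seq_len(nrow(epochs)), function(i)
    mse_curve(epochs[i, ], params))
  vals <- vapply(curves, function(cv) cv$sampen, numeric(length(params$scales)))
  vals <- matrix(vals, nrow = length(params$scales))
  n_def <- rowSums(!is.na(vals))
  out <- data.frame(
    scale = params$scales,
    sampen = ifelse(n_def > 0, rowMeans(vals, na.rm = TRUE), NA_real_),
    valid = curves[[1L]]$valid,
    n_epochs = n_def
  )
  structure(out, params = params)
}

#' Multiscale entropy table for an epoched recording
#'
#' Applies [mse_epochs()] to every channel of an [epoched_recording()] and
#' returns a tidy table, the package's native serialization of MSE results.
#'
#' @param epochs An `epoched_recording`.
#' @param params An [mse_params()] object.
#' @param subject,task Identifier columns replicated into the output.
#'
#' @return Data frame with columns `subject`, `task`, `channel`, `scale`,
#'   `sampen`, `valid`.
#' @export
mse_table <- function(epochs, params = mse_params(), subject = NA_character_,
                      task = NA_character_) {
  if (!inherits(epochs, "epoched_recording"))
    data_error("`epochs` must be an `epoched_recording`")
  ch <- channel_labels(epochs)
  res <- lapply(seq_along(ch), function(ci) {
    cv <- mse_epochs(epochs$data[, ci, , drop = TRUE], params)
    data.frame(subject = subject, task = task, channel = ch[ci],
               scale = cv$scale, sampen = cv$sampen, valid = cv$valid)
  })
  do.call(rbind, res)
}
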