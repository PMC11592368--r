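#' Continuous multichannel recording
#'
#' Container for a raw EEG record: a channels-by-samples matrix in microvolts,
#' the sampling rate, and stimulus markers (sample index + code).
#'
#' @param data Numeric matrix, channels in rows, samples in columns. Row names
#'   are used as channel labels when `labels` is missing.
#' @param fs Sampling rate in Hz, positive.
#' @param labels Character vector of unique channel labels (10-20 names).
#' @param markers Data frame with columns `sample` (1-based sample index) and
#'   `code` (event code). May have zero rows.
#'
#' @return Object of class `raw_recording` with elements `data`, `fs`,
#'   `markers`.
#' @export
raw_recording <- function(data, fs, labels = rownames(data),
                          markers = data.frame(sample = integer(),
                                               code = character())) {
  if (!is.matrix(data) || !is.numeric(data))
    data_error("`data` must be a numeric matrix (channels x samples)")
  if (!all(is.finite(data)))
    data_error("`data` contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    config_error("`fs` must be a single positive number")
  if (is.null(labels) || length(labels) != nrow(data))
    data_error("need one channel label per row of `data`")
  if (anyDuplicated(labels))
    data_error("channel labels must be unique")
  if (!all(c("sample", "code") %in% names(markers)))
    data_error("`markers` needs columns `sample` and `code`")
  if (nrow(markers) > 0 &&
      (any(markers$sample < 1) || any(markers$sample > ncol(data))))
    data_error("marker positions fall outside the record")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, markers = markers),
            class = "raw_recording")
}

#' Epoched recording
#'
#' Stimulus-locked epochs: an epochs x channels x samples array with its time
#' window, baseline interval and sampling rate. Sample convention is half-open
#' `[start, end)` in milliseconds, so a (-500, 2000) window at 1000 Hz holds
#' 2500 samples.
#'
#' @param data Numeric array, epochs x channels x samples. The channel
#'   dimension must carry dimnames.
#' @param fs Sampling rate in Hz.
#' @param window_ms Length-2 numeric, epoch window in ms relative to the
#'   stimulus; start must be negative, end non-negative.
#' @param baseline_ms Length-2 numeric, baseline interval, contained in
#'   `window_ms`.
#'
#' @return Object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, fs, window_ms, baseline_ms) {
  if (!is.array(data) || length(dim(data)) != 3L)
    data_error("`data` must be a 3-d array (epochs x channels x samples)")
  if (!(window_ms[1] < 0 && 0 <= window_ms[2]))
    config_error("epoch window must satisfy start < 0 <= end")
  if (baseline_ms[1] < window_ms[1] || baseline_ms[2] > window_ms[2])
    config_error("baseline interval must lie inside the epoch window")
  structure(list(data = data, fs = fs, window_ms = window_ms,
                 baseline_ms = baseline_ms),
            class = "epoched_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz, %d markers\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$markers)))
  invisible(x)
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_recording> %d epochs x %d channels x %d samples @ %g Hz, window [%g, %g) ms\n",
    d[1], d[2], d[3], x$fs, x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Channel labels of a recording
#' @param x A `raw_recording` or `epoched_recording`.
#' @return Character vector of channel labels.
#' @export
channel_labels <- function(x) {
  if (inherits(x, "raw_recording")) return(rownames(x$data))
  if (inherits(x, "epoched_recording")) return(dimnames(x$data)[[2L]])
  data_error("`x` must be a raw_recording or epoched_recording")
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `<basepath>.vhdr` (text header), `<basepath>.vmrk` (text markers)
#' and `<basepath>.eeg` (IEEE float32, multiplexed, microvolts) — the minimal
#' subset of the BrainVision Core format sufficient for round-tripping
#' continuous data with stimulus markers.
#'
#' @param x A [raw_recording()].
#' @param basepath Path without extension.
#' @return `basepath`, invisibly.
#' @export
write_brainvision <- function(x, basepath) {
  if (!inherits(x, "raw_recording"))
    data_error("`x` must be a raw_recording")
  base <- basename(basepath)
  labels <- channel_labels(x)
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(x$data)),
    sprintf("SamplingInterval=%.10g", 1e6 / x$fs),
    "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(labels), labels)
  )
  writeLines(hdr, paste0(basepath, ".vhdr"), useBytes = TRUE)
  mk <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    "", "[Marker Infos]"
  )
  if (nrow(x$markers) > 0) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(x$markers)),
                        x$markers$code, x$markers$sample))
  }
  writeLines(mk, paste0(basepath, ".vmrk"), useBytes = TRUE)
  con <- file(paste0(basepath, ".eeg"), "wb")
  on.exit(close(con))
  # multiplexed: sample-major, channels fastest
  writeBin(as.numeric(x$data), con, size = 4L, endian = "little")
  invisible(basepath)
}

#' Read a BrainVision triplet
#'
#' Minimal reader for BrainVision Core files as produced by
#' [write_brainvision()]: binary IEEE float32 or int16 data, multiplexed
#' orientation, with stimulus markers.
#'
#' @param vhdr Path to the `.vhdr` header file.
#' @return A [raw_recording()].
#' @export
read_brainvision <- function(vhdr) {
  if (!file.exists(vhdr)) data_error(sprintf("header file not found: %s", vhdr))
  lines <- readLines(vhdr, warn = FALSE, encoding = "UTF-8")
  get_field <- function(key) {
    hit <- grep(sprintf("^%s=", key), lines, value = TRUE)
    if (length(hit) == 0) data_error(sprintf("missing %s in %s", key, vhdr))
    sub(sprintf("^%s=", key), "", hit[1])
  }
  orient <- get_field("DataOrientation")
  if (toupper(orient) != "MULTIPLEXED")
    data_error("only MULTIPLEXED orientation is supported")
  fmt <- toupper(get_field("BinaryFormat"))
  if (!fmt %in% c("IEEE_FLOAT_32", "INT_16"))
    data_error(sprintf("unsupported BinaryFormat: %s", fmt))
  n_ch <- as.integer(get_field("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_field("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_idx <- as.integer(sub("^Ch([0-9]+)=.*", "\\1", ch_lines))
  ch_parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",", fixed = TRUE)
  labels <- vapply(ch_parts, `[`, character(1), 1)[order(ch_idx)]
  resol <- vapply(ch_parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, numeric(1))
  resol <- resol[order(ch_idx)]
  if (length(labels) != n_ch)
    data_error("channel count does not match [Channel Infos]")

  dir <- dirname(vhdr)
  eeg_path <- file.path(dir, get_field("DataFile"))
  size <- if (fmt == "IEEE_FLOAT_32") 4L else 2L
  n_vals <- file.info(eeg_path)$size %/% size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  raw_vals <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = n_vals, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", n = n_vals, size = 2L, signed = TRUE,
            endian = "little")
  }
  n_samp <- length(raw_vals) %/% n_ch
  data <- matrix(raw_vals[seq_len(n_samp * n_ch)], nrow = n_ch) * resol
  rownames(data) <- labels

  mrk_path <- file.path(dir, get_field("MarkerFile"))
  markers <- data.frame(sample = integer(), code = character())
  if (file.exists(mrk_path)) {
    mlines <- grep("^Mk[0-9]+=", readLines(mrk_path, warn = FALSE),
                   value = TRUE)
    mlines <- mlines[!grepl("=New Segment,", mlines, fixed = TRUE)]
    if (length(mlines) > 0) {
      parts <- strsplit(sub("^Mk[0-9]+=", "", mlines), ",", fixed = TRUE)
      markers <- data.frame(
        sample = vapply(parts, function(p) as.integer(p[3]), integer(1)),
        code = vapply(parts, `[`, character(1), 2)
      )
    }
  }
  raw_recording(data, fs, labels = labels, markers = markers)
}
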