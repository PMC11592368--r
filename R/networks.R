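#' Bundled electrode-to-network probability map
#'
#' Loads the package's electrode-to-functional-network probability table for a
#' 64-channel 10-20/10-10 montage, covering eight canonical cortical systems:
#' default mode (DMN), dorsal attention (DAN), frontoparietal (FPN), ventral
#' attention (VAN), visual (VN), somatomotor (SMN), limbic (LN) and salience
#' (SN). The bundled table is *synthetic*: a topographic approximation
#' constructed from the usual scalp correspondence of these systems (frontal
#' midline to salience, central strip to somatomotor, superior parietal to
#' dorsal attention, occipital to visual, and so on), not a published
#' projection; substitute your own table via `path` for production maps.
#'
#' @param path Optional path to a user-supplied delimited table with column
#'   `electrode` plus one probability column per network (rows sum to 1).
#' @return Data frame: `electrode` plus eight network probability columns.
#' @export
network_probability_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "network_map_synthetic.tsv",
                        package = "mseeg", mustWork = TRUE)
  }
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!"electrode" %in% names(tab))
    data_error("probability map needs an `electrode` column")
  tab
}

#' Names of the eight functional networks
#' @return Character vector of network codes.
#' @export
network_names <- function() {
  c("DAN", "DMN", "FPN", "LN", "SMN", "SN", "VAN", "VN")
}

#' Assign electrodes to functional networks
#'
#' Each electrode is assigned to its maximum-probability network. Exact ties
#' are broken deterministically in favor of the alphabetically first network
#' name; tied electrodes are recorded in the `ties` attribute.
#'
#' @param montage Character vector of electrode labels to assign.
#' @param table Probability map as returned by [network_probability_map()]:
#'   column `electrode` plus one column per network, rows summing to
#'   1 (tolerance 1e-6).
#' @return Named character vector (class `network_map`) mapping each montage
#'   electrode to a network; attribute `ties` lists electrodes whose maximum
#'   was tied.
#' @export
assign_electrodes <- function(montage, table = network_probability_map()) {
  nets <- setdiff(names(table), "electrode")
  if (length(nets) < 1L) data_error("probability map has no network columns")
  probs <- as.matrix(table[, nets, drop = FALSE])
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    data_error("probability rows must sum to 1 (tolerance 1e-6)")
  unknown <- setdiff(montage, table$electrode)
  if (length(unknown) > 0)
    data_error(sprintf("unknown electrode label(s): %s",
                       paste(unknown, collapse = ", ")))
  rownames(probs) <- table$electrode
  nets_sorted <- sort(nets)  # alphabetical tie-break
  probs <- probs[montage, nets_sorted, drop = FALSE]
  idx <- apply(probs, 1L, which.max)
  is_tie <- apply(probs, 1L, function(p) sum(p == max(p)) > 1L)
  map <- nets_sorted[idx]
  names(map) <- montage
  if (any(is_tie))
    message(sprintf("tie(s) broken alphabetically for: %s",
                    paste(montage[is_tie], collapse = ", ")))
  structure(map, ties = montage[is_tie], class = "network_map")
}

#' Network-level multiscale entropy sums
#'
#' For each subject and network: per mapped electrode, sample entropy is
#' summed over the scales in `scale_range` (inclusive), and the electrode sums
#' are then averaged across the network's electrodes. Undefined or invalid
#' scale values are excluded pairwise; their count is returned in the
#' `n_excluded` attribute. Networks with no mapped electrode in the data are
#' dropped with a warning.
#'
#' @param curves Tidy MSE table with columns `subject`, `channel`, `scale`,
#'   `sampen`, `valid` (as produced by [mse_table()]).
#' @param map A `network_map` from [assign_electrodes()].
#' @param scale_range Length-2 integer `(low, high)`, low <= high.
#'   Default `c(10, 15)`.
#' @return Data frame: `subject`, `network`, `value`.
#' @export
network_scale_sum <- function(curves, map, scale_range = c(10, 15)) {
  need <- c("subject", "channel", "scale", "sampen", "valid")
  if (!all(need %in% names(curves)))
    data_error("`curves` needs columns subject, channel, scale, sampen, valid")
  if (length(scale_range) != 2L || scale_range[1] > scale_range[2])
    config_error("empty scale range: need low <= high")
  sel <- curves$scale >= scale_range[1] & curves$scale <= scale_range[2] &
    curves$channel %in% names(map)
  d <- curves[sel, ]
  if (nrow(d) == 0) data_error("no curve values in the requested scale range")
  bad <- !d$valid | is.na(d$sampen)
  n_excluded <- sum(bad)
  d <- d[!bad, ]
  d$network <- unclass(map)[d$channel]

  # sum over scales per electrode, then mean over the network's electrodes
  elec <- stats::aggregate(sampen ~ subject + network + channel, data = d,
                           FUN = sum)
  out <- stats::aggregate(sampen ~ subject + network, data = elec, FUN = mean)
  names(out)[names(out) == "sampen"] <- "value"

  missing_nets <- setdiff(unique(unclass(map)), out$network)
  if (length(missing_nets) > 0)
    warning(sprintf("network(s) with no mapped electrodes dropped: %s",
                    paste(missing_nets, collapse = ", ")))
  out <- out[order(out$subject, out$network), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_excluded = n_excluded)
}
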