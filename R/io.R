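#' Read spike trains from Neurosuite .res/.clu files
#'
#' The `.res` file holds one spike-time sample index per line (integers at
#' the wide-band acquisition rate); the matching `.clu` file holds the
#' cluster count on its first line followed by one cluster label per spike.
#' Cluster labels listed in `drop_clusters` (artifact and noise by the usual
#' convention) are discarded. Plain-text files with one spike time in
#' seconds per line are auto-detected when no `.clu` file is given.
#'
#' @param res_path path to the `.res` (or plain-text seconds) file.
#' @param clu_path path to the `.clu` file, or `NULL` for the plain-text
#'   seconds dialect (all spikes become one unit).
#' @param wideband_rate wide-band sampling rate in samples/s used to convert
#'   `.res` indices to seconds (default 32000).
#' @param drop_clusters integer cluster labels to discard (default `c(0, 1)`).
#' @return A list of [spike_train] objects, one per retained cluster.
#' @export
read_spike_trains <- function(res_path, clu_path = NULL, wideband_rate = 32000,
                              drop_clusters = c(0L, 1L)) {
  if (is.null(clu_path)) {
    times <- scan(res_path, what = double(), quiet = TRUE)
    return(list(spike_train(sort(times), unit_id = "u1")))
  }
  idx <- scan(res_path, what = double(), quiet = TRUE)
  clu <- scan(clu_path, what = integer(), quiet = TRUE)
  if (length(clu) < 1) stop("empty .clu file")
  n_clusters <- clu[1]
  labels <- clu[-1]
  if (length(labels) != length(idx))
    stop(sprintf("res/clu length mismatch: %d spikes vs %d labels",
                 length(idx), length(labels)))
  if (is.unsorted(idx)) stop("non-monotonic sample indices in .res file")
  if (length(unique(labels)) > n_clusters)
    warning("more distinct labels than the .clu header declares")
  keep <- !(labels %in% drop_clusters)
  idx <- idx[keep]; labels <- labels[keep]
  out <- list()
  for (lab in sort(unique(labels))) {
    t_lab <- sort(idx[labels == lab]) / wideband_rate
    t_lab <- unique(t_lab)
    out[[length(out) + 1L]] <- spike_train(t_lab, unit_id = sprintf("u%d", lab))
  }
  out
}

#' Write spike trains to .res/.clu files
#'
#' Inverse of [read_spike_trains()]: merges the units, sorts by time, and
#' writes sample indices plus cluster labels (units are numbered from 2 so
#' the noise-cluster convention survives a round trip).
#'
#' @param units list of [spike_train] objects.
#' @param res_path,clu_path output paths.
#' @param wideband_rate samples/s used to convert seconds to indices.
#' @export
write_spike_trains <- function(units, res_path, clu_path, wideband_rate = 32000) {
  times <- unlist(lapply(units, `[[`, "times"))
  labels <- rep(seq_along(units) + 1L, vapply(units, function(u) length(u$times), 1L))
  ord <- order(times)
  idx <- round(times[ord] * wideband_rate)
  writeLines(format(idx, scientific = FALSE, trim = TRUE), res_path)
  writeLines(c(as.character(length(units) + 2L), as.character(labels[ord])), clu_path)
  invisible(NULL)
}

#' Read an LFP signal from a flat int16 binary file
#'
#' The `.eeg` dialect: little-endian int16 samples, channels interleaved.
#'
#' @param path file path.
#' @param rate sampling rate in Hz (default 1250).
#' @param n_channels number of interleaved channels (default 1).
#' @param channel which channel to extract (1-based).
#' @return An [lfp_signal].
#' @export
read_eeg <- function(path, rate = 1250, n_channels = 1, channel = 1) {
  n <- file.info(path)$size / 2
  raw <- readBin(path, what = "integer", size = 2, n = n, endian = "little",
                 signed = TRUE)
  if (n_channels > 1) {
    raw <- matrix(raw, nrow = n_channels)[channel, ]
  }
  lfp_signal(raw, rate = rate)
}

#' Write an LFP signal as flat int16 binary
#'
#' Samples are rounded and clamped to the int16 range.
#'
#' @param lfp an [lfp_signal].
#' @param path output file path.
#' @export
write_eeg <- function(lfp, path) {
  x <- as.integer(pmax(-32768, pmin(32767, round(lfp$samples))))
  writeBin(x, path, size = 2, endian = "little")
  invisible(NULL)
}

#' Read a position track from CSV
#'
#' Expects a header line `t,x,y` (an optional `speed` column is honoured).
#'
#' @param path CSV file path.
#' @return A [position_track].
#' @export
read_position_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t", "x", "y") %in% names(d)))
    stop("position CSV needs columns t, x, y")
  position_track(d$t, d$x, d$y, speed = if ("speed" %in% names(d)) d$speed)
}

#' Write a position track to CSV
#' @param track a [position_track].
#' @param path output CSV path.
#' @export
write_position_csv <- function(track, path) {
  d <- data.frame(t = track$t, x = track$x, y = track$y)
  if (!is.null(track$speed)) d$speed <- track$speed
  utils::write.csv(d, path, row.names = FALSE)
  invisible(NULL)
}

#' Read a light-pulse protocol from CSV
#'
#' Expects columns `onset` (s) and `duration` (s); optional `frequency_hz`
#' and `site` columns (constant) are honoured.
#'
#' @param path CSV file path.
#' @return A [light_protocol].
#' @export
read_light_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("onset", "duration") %in% names(d)))
    stop("light CSV needs columns onset, duration")
  light_protocol(d$onset, d$duration[1],
                 frequency_hz = if ("frequency_hz" %in% names(d)) d$frequency_hz[1] else NA_real_,
                 site = if ("site" %in% names(d)) d$site[1] else "hippocampus")
}

#' Write a light-pulse protocol to CSV
#' @param light a [light_protocol].
#' @param path output CSV path.
#' @export
write_light_csv <- function(light, path) {
  d <- data.frame(onset = light$pulse_onsets, duration = light$pulse_duration,
                  frequency_hz = light$frequency_hz, site = light$site)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(NULL)
}
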