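#' Spike train of a single unit
#'
#' Container for the sorted spike times of one putative single unit, with an
#' optional cell-class label. All times are seconds from session start.
#'
#' @param times numeric vector of spike times in seconds, strictly increasing.
#' @param unit_id character label for the unit.
#' @param cell_class one of `"pyramidal"`, `"interneuron"`, `"unclassified"`.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, unit_id = "unit", cell_class = "unclassified") {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must not contain NA")
  if (is.unsorted(times, strictly = TRUE)) {
    if (anyDuplicated(times)) stop("duplicate spike timestamps")
    stop("spike times must be strictly increasing")
  }
  if (length(times) && times[1] < 0) stop("spike times must be non-negative")
  cell_class <- match.arg(cell_class, c("pyramidal", "interneuron", "unclassified"))
  structure(list(times = times, unit_id = as.character(unit_id),
                 cell_class = cell_class),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train '%s'> %d spikes, class %s", x$unit_id,
              length(x$times), x$cell_class))
  if (length(x$times))
    cat(sprintf(", span [%.3f, %.3f] s", x$times[1], x$times[length(x$times)]))
  cat("\n")
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Local field potential signal
#'
#' @param samples numeric vector of amplitudes (arbitrary units; int16 on disk).
#' @param rate sampling rate in samples per second (default 1250, the
#'   conventional down-sampled LFP rate).
#' @return An object of class `lfp_signal`.
#' @export
lfp_signal <- function(samples, rate = 1250) {
  samples <- as.numeric(samples)
  if (length(samples) < 1) stop("LFP must contain at least one sample")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0")
  structure(list(samples = samples, rate = rate), class = "lfp_signal")
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("<lfp_signal> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Animal position track
#'
#' Position samples at a nominal 25 frames/s. Speed, if absent, is computed
#' on demand by [compute_speed()].
#'
#' @param t timestamps in seconds, strictly increasing.
#' @param x,y coordinates in cm.
#' @param speed optional instantaneous speed in cm/s.
#' @return An object of class `position_track`.
#' @export
position_track <- function(t, x, y, speed = NULL) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) != length(x) || length(t) != length(y))
    stop("t, x, y must have equal length")
  if (is.unsorted(t, strictly = TRUE)) stop("position timestamps must be strictly increasing")
  if (!is.null(speed)) {
    speed <- as.numeric(speed)
    if (length(speed) != length(t)) stop("speed length mismatch")
    if (any(speed < 0, na.rm = TRUE)) stop("speed must be >= 0")
  }
  structure(list(t = t, x = x, y = y, speed = speed), class = "position_track")
}

#' @export
print.position_track <- function(x, ...) {
  cat(sprintf("<position_track> %d frames over %.1f s%s\n", length(x$t),
              diff(range(x$t)), if (is.null(x$speed)) "" else ", speed attached"))
  invisible(x)
}

#' Optogenetic light-pulse protocol
#'
#' @param pulse_onsets pulse onset times in seconds, strictly increasing.
#' @param pulse_duration pulse duration in seconds (> 0).
#' @param frequency_hz nominal stimulation frequency in Hz.
#' @param site stimulation site, `"hippocampus"` or `"MS"` (medial septum).
#' @return An object of class `light_protocol`.
#' @export
light_protocol <- function(pulse_onsets, pulse_duration, frequency_hz = NA_real_,
                           site = c("hippocampus", "MS")) {
  pulse_onsets <- as.numeric(pulse_onsets)
  if (is.unsorted(pulse_onsets, strictly = TRUE))
    stop("pulse onsets must be strictly increasing")
  if (!is.numeric(pulse_duration) || pulse_duration <= 0)
    stop("pulse duration must be > 0")
  if (length(pulse_onsets) > 1 &&
      any(diff(pulse_onsets) < pulse_duration))
    stop("consecutive pulses overlap: onset spacing < pulse duration")
  site <- match.arg(site)
  structure(list(pulse_onsets = pulse_onsets, pulse_duration = pulse_duration,
                 frequency_hz = frequency_hz, site = site),
            class = "light_protocol")
}

#' @export
print.light_protocol <- function(x, ...) {
  cat(sprintf("<light_protocol> %d pulses of %g ms at %s Hz, site %s\n",
              length(x$pulse_onsets), 1000 * x$pulse_duration,
              format(x$frequency_hz), x$site))
  invisible(x)
}

#' Recording session
#'
#' Bundles the simultaneously recorded time series of one session. All
#' components share one time origin (t = 0 at session start).
#'
#' @param id session identifier.
#' @param units list of [spike_train] objects.
#' @param duration session duration in seconds.
#' @param lfp optional [lfp_signal].
#' @param position optional [position_track].
#' @param light optional [light_protocol].
#' @param genotype_label free-form label (e.g. `"control"`, `"mutant"`).
#' @return An object of class `session`.
#' @export
session <- function(id, units, duration, lfp = NULL, position = NULL,
                    light = NULL, genotype_label = "") {
  if (!is.list(units) || !all(vapply(units, inherits, TRUE, "spike_train")))
    stop("units must be a list of spike_train objects")
  duration <- as.numeric(duration)
  if (duration <= 0) stop("duration must be > 0")
  for (u in units) {
    if (length(u$times) && u$times[length(u$times)] > duration)
      stop(sprintf("unit '%s' has spikes beyond the session duration", u$unit_id))
  }
  structure(list(id = as.character(id), units = units, duration = duration,
                 lfp = lfp, position = position, light = light,
                 genotype_label = genotype_label),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session '%s'> %d units, %.1f s, genotype '%s'\n", x$id,
              length(x$units), x$duration, x$genotype_label))
  cat(sprintf("  lfp: %s | position: %s | light: %s\n",
              if (is.null(x$lfp)) "-" else "yes",
              if (is.null(x$position)) "-" else "yes",
              if (is.null(x$light)) "-" else "yes"))
  invisible(x)
}
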