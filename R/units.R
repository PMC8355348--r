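#' Classify a unit as pyramidal cell or interneuron by firing rate
#'
#' Applies the conventional extracellular criteria: mean rate below 3 Hz for
#' putative pyramidal cells, above 7 Hz for putative (basket) interneurons,
#' unclassified otherwise. A putative pyramidal cell must additionally show a
#' clear refractory period: the fraction of inter-spike intervals shorter
#' than `refractory_ms` must not exceed `refractory_ceiling`.
#'
#' @param unit a [spike_train].
#' @param duration recording duration in seconds (> 0).
#' @param refractory_ms refractory window in ms (default 3).
#' @param refractory_ceiling maximum tolerated fraction of ISIs below the
#'   refractory window (default 0.01).
#' @return The cell class as a character scalar; the input train with its
#'   `cell_class` field set is attached as attribute `"train"`.
#' @export
classify_units <- function(unit, duration, refractory_ms = 3,
                           refractory_ceiling = 0.01) {
  stopifnot(inherits(unit, "spike_train"))
  if (duration <= 0) stop("duration must be > 0")
  n <- length(unit$times)
  if (n == 0) {
    warning("empty spike train: unclassified")
    cls <- "unclassified"
  } else {
    rate <- n / duration
    if (rate > 7) {
      cls <- "interneuron"
    } else if (rate < 3) {
      isi <- diff(unit$times) * 1000
      frac_refr <- if (length(isi)) mean(isi < refractory_ms) else 0
      cls <- if (frac_refr <= refractory_ceiling) "pyramidal" else "unclassified"
    } else {
      cls <- "unclassified"
    }
  }
  unit$cell_class <- cls
  attr(cls, "train") <- unit
  cls
}

#' Compute instantaneous running speed from a position track
#'
#' Positions are smoothed with a boxcar of the given width, then speed is the
#' centred finite difference of the smoothed trajectory (one-sided at the
#' endpoints), in cm/s.
#'
#' @param track a [position_track].
#' @param smoothing_window boxcar width in seconds (default 0.4).
#' @return The track with its `speed` field filled in.
#' @export
compute_speed <- function(track, smoothing_window = 0.4) {
  stopifnot(inherits(track, "position_track"))
  n <- length(track$t)
  if (n < 2) stop("need at least 2 position samples")
  dt <- stats::median(diff(track$t))
  w <- max(1L, round(smoothing_window / dt))
  if (w %% 2 == 0) w <- w + 1L
  xs <- boxcar_smooth(track$x, w)
  ys <- boxcar_smooth(track$y, w)
  vx <- centered_gradient(xs, track$t)
  vy <- centered_gradient(ys, track$t)
  track$speed <- sqrt(vx^2 + vy^2)
  track
}

# boxcar smoothing; linear (odd-reflection) padding preserves ramps at the
# edges, so constant-velocity segments keep their slope to the first frame
boxcar_smooth <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  h <- (w - 1L) %/% 2L
  if (n <= h + 1) return(x)
  left <- 2 * x[1] - x[(h + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - h)]
  xp <- c(left, x, right)
  cs <- cumsum(c(0, xp))
  idx <- seq_len(n) + h
  (cs[idx + h + 1L] - cs[idx - h]) / (2L * h + 1L)
}

# centred finite difference, one-sided at the ends
centered_gradient <- function(x, t) {
  n <- length(x)
  g <- numeric(n)
  if (n >= 3) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  g[1] <- (x[2] - x[1]) / (t[2] - t[1])
  g[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  g
}

#' Classify behavioural state from running speed
#'
#' Running is speed above `run_threshold` (3 cm/s), immobility below
#' `immobility_threshold` (2 cm/s); speeds in between are unclassified.
#' Contiguous frames of one state are merged into intervals.
#'
#' @param track a [position_track] with speed (see [compute_speed()]).
#' @param run_threshold,immobility_threshold speed cut-offs in cm/s.
#' @return An object of class `behavioral_state`: a list with `running` and
#'   `immobility` interval matrices (columns `start`, `end`, seconds).
#' @export
behavioral_state <- function(track, run_threshold = 3, immobility_threshold = 2) {
  stopifnot(inherits(track, "position_track"))
  if (is.null(track$speed)) track <- compute_speed(track)
  lab <- ifelse(track$speed > run_threshold, "running",
                ifelse(track$speed < immobility_threshold, "immobility", "none"))
  out <- list(running = label_intervals(track$t, lab == "running"),
              immobility = label_intervals(track$t, lab == "immobility"))
  out$frame_label <- lab
  class(out) <- "behavioral_state"
  out
}

# contiguous TRUE runs of a frame mask -> [start, end] interval matrix
label_intervals <- function(t, mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = t[starts[keep]], end = t[ends[keep]])
}

#' @export
print.behavioral_state <- function(x, ...) {
  cat(sprintf("<behavioral_state> %d running intervals (%.1f s), %d immobility (%.1f s)\n",
              nrow(x$running), sum(x$running[, 2] - x$running[, 1]),
              nrow(x$immobility), sum(x$immobility[, 2] - x$immobility[, 1])))
  invisible(x)
}

# total duration covered by an interval matrix
interval_total <- function(iv) if (is.null(iv) || nrow(iv) == 0) 0 else sum(iv[, 2] - iv[, 1])

# membership of times in a set of [start, end] intervals
in_intervals <- function(times, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(rep(FALSE, length(times)))
  ivs <- iv[order(iv[, 1]), , drop = FALSE]
  i <- findInterval(times, ivs[, 1])
  i > 0 & times <= ivs[pmax(i, 1), 2]
}
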