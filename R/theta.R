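#' Detect theta epochs from the theta/delta power ratio
#'
#' The LFP is scanned in non-overlapping windows; in each window the band
#' power in the theta band (5-10 Hz) is divided by the power in the delta
#' band (1-4 Hz). Contiguous windows whose ratio exceeds the threshold are
#' merged into intervals, and intervals shorter than `min_duration` are
#' dropped.
#'
#' @param lfp an [lfp_signal] with rate >= 20 Hz.
#' @param ratio_threshold theta/delta power ratio threshold (default 2).
#' @param window window length in seconds (default 1).
#' @param min_duration minimum epoch duration in seconds (default 1).
#' @param theta_band,delta_band frequency bands in Hz.
#' @return An object of class `theta_epochs`: list with `intervals` (matrix
#'   of `start`, `end` in seconds), the bands and threshold, and the
#'   per-window `ratio` trace.
#' @export
detect_theta_epochs <- function(lfp, ratio_threshold = 2, window = 1,
                                min_duration = 1,
                                theta_band = c(5, 10), delta_band = c(1, 4)) {
  stopifnot(inherits(lfp, "lfp_signal"))
  if (lfp$rate < 20) stop("sampling rate too low for the theta band (need >= 20 Hz)")
  wlen <- round(window * lfp$rate)
  if (length(lfp$samples) < wlen) stop("signal shorter than one window")
  n_win <- floor(length(lfp$samples) / wlen)
  ratio <- numeric(n_win)
  freqs <- seq(0, lfp$rate / 2, length.out = floor(wlen / 2) + 1)
  th_idx <- freqs >= theta_band[1] & freqs <= theta_band[2]
  de_idx <- freqs >= delta_band[1] & freqs <= delta_band[2]
  for (k in seq_len(n_win)) {
    seg <- lfp$samples[((k - 1) * wlen + 1):(k * wlen)]
    seg <- seg - mean(seg)
    pw <- Mod(stats::fft(seg))^2
    pw <- pw[seq_len(floor(wlen / 2) + 1)]
    ratio[k] <- sum(pw[th_idx]) / max(sum(pw[de_idx]), .Machine$double.eps)
  }
  above <- ratio > ratio_threshold
  iv <- label_intervals(((seq_len(n_win)) - 1) * window, above)
  if (nrow(iv)) iv[, 2] <- iv[, 2] + window   # windows are [t, t + window)
  if (nrow(iv)) iv <- iv[iv[, 2] - iv[, 1] >= min_duration, , drop = FALSE]
  structure(list(intervals = iv, theta_band = theta_band,
                 delta_band = delta_band, ratio_threshold = ratio_threshold,
                 window = window, ratio = ratio),
            class = "theta_epochs")
}

#' @export
print.theta_epochs <- function(x, ...) {
  cat(sprintf("<theta_epochs> %d intervals, %.1f s total\n",
              nrow(x$intervals), interval_total(x$intervals)))
  invisible(x)
}

#' Instantaneous theta phase via the Hilbert transform
#'
#' Zero-phase band-pass (Butterworth, forward-backward) in the theta band,
#' analytic signal by the frequency-domain Hilbert transform, then the
#' instantaneous angle expressed in degrees with the convention that the
#' filtered-signal trough maps to 0/360 degrees and the peak to 180.
#'
#' @param lfp an [lfp_signal] with rate >= 20 Hz.
#' @param band pass band in Hz (default `c(5, 10)`).
#' @param order Butterworth order (default 3).
#' @return An object of class `phase_series`: list with `t` (sample times,
#'   s), `phase` (degrees in \[0, 360)), `amplitude` (envelope) and
#'   `filtered` (band-passed signal).
#' @export
instantaneous_phase <- function(lfp, band = c(5, 10), order = 3) {
  stopifnot(inherits(lfp, "lfp_signal"))
  if (lfp$rate < 20) stop("sampling rate too low for the theta band (need >= 20 Hz)")
  x <- lfp$samples - mean(lfp$samples)
  if (all(x == 0)) stop("all-zero signal: phase undefined")
  bf <- signal::butter(order, band / (lfp$rate / 2), type = "pass")
  # reflective padding suppresses filter and Hilbert edge transients
  npad <- min(length(x) - 1, round(2 * lfp$rate))
  xp <- c(rev(x[seq_len(npad) + 1]), x, rev(x[length(x) - seq_len(npad)]))
  xf <- signal::filtfilt(bf, xp)
  z <- analytic_signal(xf)
  z <- z[(npad + 1):(npad + length(x))]
  xf <- xf[(npad + 1):(npad + length(x))]
  # Arg(z) = 0 at the filtered peak; shift so the trough is 0/360 deg
  phase <- (Arg(z) / pi * 180 + 180) %% 360
  structure(list(t = (seq_along(x) - 1) / lfp$rate, phase = phase,
                 amplitude = Mod(z), filtered = xf, rate = lfp$rate),
            class = "phase_series")
}

# analytic signal via FFT (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d samples @ %g Hz\n", length(x$phase), x$rate))
  invisible(x)
}

# phase of events by linear interpolation on the unwrapped phase
event_phases <- function(events, phase) {
  unw <- unwrap_deg(phase$phase)
  stats::approx(phase$t, unw, xout = events, rule = 2)$y %% 360
}

unwrap_deg <- function(p) {
  d <- diff(p)
  d <- d - 360 * round(d / 360)
  cumsum(c(p[1], d))
}

#' Occupancy-corrected theta-phase histogram of events
#'
#' Events outside the theta epochs are discarded. Counts per phase bin are
#' corrected for any non-uniformity of the underlying LFP phase occupancy
#' (count divided by occupancy fraction times the number of bins), then
#' normalised to a probability that sums to 1. A circular Gaussian smoothing
#' (SD in bins) is applied to the displayed probability curve only; the mean
#' phase, resultant length and Rayleigh p are computed from the unsmoothed
#' event phases (raw by default; set `stats_corrected = TRUE` to weight
#' events by inverse phase occupancy).
#'
#' @param events event times in seconds.
#' @param phase a `phase_series` from [instantaneous_phase()].
#' @param epochs optional [detect_theta_epochs()] result; `NULL` keeps all
#'   events.
#' @param n_bins number of phase bins (default 20).
#' @param smooth_sd_bins SD of the circular Gaussian smoothing kernel in
#'   bins (default 2); 0 disables smoothing.
#' @param stats_corrected logical: compute the circular statistics from
#'   occupancy-weighted events instead of raw events.
#' @return An object of class `phase_histogram`: `bin_edges` and
#'   `bin_centers` (degrees), `probability` (smoothed, sums to 1),
#'   `probability_raw`, `mean_phase`, `R`, `rayleigh_p`, `n_events`.
#' @export
phase_histogram <- function(events, phase, epochs = NULL, n_bins = 20,
                            smooth_sd_bins = 2, stats_corrected = FALSE) {
  if (!is.null(epochs)) {
    keep_ev <- in_intervals(events, epochs$intervals)
    events <- events[keep_ev]
    keep_ph <- in_intervals(phase$t, epochs$intervals)
  } else {
    keep_ph <- rep(TRUE, length(phase$t))
  }
  if (length(events) < 1) stop("no events inside the theta epochs")
  ev_ph <- event_phases(events, phase)
  edges <- seq(0, 360, length.out = n_bins + 1)
  occ <- tabulate(findInterval(phase$phase[keep_ph], edges,
                               rightmost.closed = TRUE), nbins = n_bins)
  occ_frac <- occ / sum(occ)
  counts <- tabulate(findInterval(ev_ph, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  ok <- occ_frac > 0
  if (any(!ok)) {
    warning(sprintf("%d phase bin(s) with zero occupancy excluded", sum(!ok)))
  }
  corrected <- numeric(n_bins)
  corrected[ok] <- counts[ok] / (occ_frac[ok] * n_bins)
  prob_raw <- corrected / sum(corrected)
  prob <- if (smooth_sd_bins > 0) circ_gauss_smooth(prob_raw, smooth_sd_bins) else prob_raw
  prob <- prob / sum(prob)
  # circular statistics from events
  if (stats_corrected) {
    bin_of <- findInterval(ev_ph, edges, rightmost.closed = TRUE)
    w <- ifelse(occ_frac[bin_of] > 0, 1 / (occ_frac[bin_of] * n_bins), 0)
    rt <- rayleigh_test(ev_ph[w > 0], w = w[w > 0])
  } else {
    rt <- rayleigh_test(ev_ph)
  }
  structure(list(bin_edges = edges,
                 bin_centers = edges[-length(edges)] + 180 / n_bins,
                 probability = prob, probability_raw = prob_raw,
                 occupancy_fraction = occ_frac,
                 mean_phase = rt$mean_deg, R = rt$R, rayleigh_p = rt$p,
                 n_events = length(ev_ph), event_phases = ev_ph),
            class = "phase_histogram")
}

# circular convolution with a wrapped Gaussian kernel (SD in bins)
circ_gauss_smooth <- function(p, sd_bins) {
  n <- length(p)
  lag <- seq(0, n - 1)
  lag <- pmin(lag, n - lag)
  k <- exp(-lag^2 / (2 * sd_bins^2))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(p) * stats::fft(k), inverse = TRUE)) / n
}

#' @export
print.phase_histogram <- function(x, ...) {
  cat(sprintf("<phase_histogram> n = %d, mean phase %.1f deg, R = %.3f, Rayleigh p = %.3g\n",
              x$n_events, x$mean_phase, x$R, x$rayleigh_p))
  invisible(x)
}

#' @export
plot.phase_histogram <- function(x, ...) {
  graphics::plot(c(x$bin_centers, x$bin_centers + 360),
                 rep(x$probability, 2), type = "s",
                 xlab = "theta phase (deg)", ylab = "probability", ...)
  graphics::abline(v = x$mean_phase, lty = 2)
  invisible(x)
}

#' Per-bin squared differences between two phase histograms
#'
#' Returns the squared difference of the two probability curves bin by bin;
#' the n_bins values feed a downstream two-sample comparison across
#' behavioural states or genotypes.
#'
#' @param h1,h2 `phase_histogram` objects on identical binning.
#' @return Numeric vector of length n_bins.
#' @export
phase_histogram_squared_difference <- function(h1, h2) {
  if (length(h1$probability) != length(h2$probability) ||
      any(abs(h1$bin_edges - h2$bin_edges) > 1e-9))
    stop("histograms must share the same binning")
  (h1$probability - h2$probability)^2
}

#' Silverman bootstrap test of circular modality
#'
#' Tests whether a circular sample needs more than `k_null` modes: the
#' critical concentration is the largest von Mises kernel concentration
#' (narrowest bandwidth) whose kernel density still has at most `k_null`
#' modes; bootstrap samples are drawn from that critical-bandwidth density
#' and p is the fraction of bootstrap samples whose own critical bandwidth
#' is wider (smaller concentration) than the observed one. Small p rejects
#' `k_null` modes in favour of more.
#'
#' @param phases_deg angles in degrees (n >= 20).
#' @param k_null null number of modes (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param kappa_max largest concentration scanned (default 200).
#' @param grid_n density grid resolution (default 256).
#' @return List with `p`, `critical_kappa`, `k_null`, `n_boot`.
#' @export
silverman_modality_test <- function(phases_deg, k_null = 1, n_boot = 1000,
                                    seed, kappa_max = 200, grid_n = 256) {
  if (length(phases_deg) < 20) stop("need n >= 20")
  if (n_boot < 100) warning("n_boot < 100: p-value will be coarse")
  if (!missing(seed)) set.seed(seed)
  phases_deg <- phases_deg %% 360
  # degenerate sample: all angles (nearly) identical
  cm <- circular_mean(phases_deg)
  if (cm$R > 1 - 1e-12)
    return(list(p = 1, critical_kappa = NA_real_, k_null = k_null, n_boot = n_boot))
  grid <- seq(0, 360, length.out = grid_n + 1)[-(grid_n + 1)]
  crit <- critical_kappa(phases_deg, k_null, kappa_max, grid)
  n <- length(phases_deg)
  exceed <- 0L
  for (b in seq_len(n_boot)) {
    # smoothed bootstrap from the critical-bandwidth KDE
    xb <- sample(phases_deg, n, replace = TRUE) + rvonmises(n, 0, crit)
    cb <- critical_kappa(xb %% 360, k_null, kappa_max, grid)
    # bootstrap bandwidth exceeds the observed one <=> smaller concentration
    if (cb < crit) exceed <- exceed + 1L
  }
  list(p = (exceed + 1) / (n_boot + 1), critical_kappa = crit,
       k_null = k_null, n_boot = n_boot)
}

# largest kappa whose KDE has <= k modes (binary search; modes increase
# with kappa)
critical_kappa <- function(phases_deg, k, kappa_max, grid) {
  lo <- 0.05; hi <- kappa_max
  if (count_circ_modes(circ_kde(phases_deg, hi, grid)) <= k) return(hi)
  for (it in 1:30) {
    mid <- sqrt(lo * hi)
    if (count_circ_modes(circ_kde(phases_deg, mid, grid)) <= k) lo <- mid else hi <- mid
    if (hi / lo < 1.02) break
  }
  lo
}
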