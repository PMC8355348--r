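#' Entrainment fidelity of theta oscillations to optogenetic stimulation
#'
#' Per 10-s window of LFP, the multitaper PSD (NW = 3, window 1024 samples)
#' is computed and the fidelity is the cumulative power within +-0.5 Hz of
#' the stimulation frequency divided by the cumulative power in the theta
#' band (5-10 Hz). For 12 Hz stimulation the denominator band is extended by
#' \[11.5, 12.5\] Hz so the ratio stays bounded by 1. Windows with fidelity
#' above 0.3 count as highly entrained.
#'
#' @param lfp an [lfp_signal].
#' @param stim_f stimulation frequency in Hz (5-12; the protocol uses 6, 7,
#'   8, 9, 10 or 12 Hz).
#' @param window analysis window in seconds (default 10).
#' @param psd_window multitaper window in samples (default 1024).
#' @param psd_rate rate in Hz the LFP is decimated to before the PSD
#'   (default 125): a 1024-sample window then spans 8.2 s, giving the
#'   sub-Hz taper bandwidth that a +-0.5 Hz fidelity band requires.
#' @param nw multitaper time-bandwidth product (default 3).
#' @param threshold high-entrainment threshold (default 0.3).
#' @return An object of class `entrainment_result`: `window_starts` (s),
#'   `fidelity` per window, `high_entrainment` logical, `stim_frequency`.
#' @export
entrainment_fidelity <- function(lfp, stim_f, window = 10, psd_window = 1024,
                                 psd_rate = 125, nw = 3, threshold = 0.3) {
  stopifnot(inherits(lfp, "lfp_signal"))
  if (stim_f < 5 || stim_f > 12) stop("stim_f must lie in [5, 12] Hz")
  x <- lfp$samples
  rate <- lfp$rate
  if (rate > psd_rate) {
    dec <- floor(rate / psd_rate)
    bf <- signal::butter(6, 0.8 / dec, type = "low")
    x <- signal::filtfilt(bf, x - mean(x))
    x <- x[seq(1, length(x), by = dec)]
    rate <- rate / dec
  }
  wlen <- round(window * rate)
  if (wlen < psd_window) stop("analysis window shorter than the PSD window")
  n_win <- floor(length(x) / wlen)
  if (n_win < 1) stop("signal shorter than one analysis window")
  theta <- c(5, 10)
  fid <- numeric(n_win)
  for (k in seq_len(n_win)) {
    seg <- x[((k - 1) * wlen + 1):(k * wlen)]
    psd <- multitaper_psd(seg, nw = nw, window = psd_window, rate = rate)
    num <- band_power(psd, stim_f - 0.5, stim_f + 0.5)
    den <- band_power(psd, theta[1], theta[2])
    if (stim_f + 0.5 > theta[2])  # stim band partly outside 5-10 Hz
      den <- den + band_power(psd, max(theta[2], stim_f - 0.5) + 1e-9, stim_f + 0.5)
    fid[k] <- num / max(den, .Machine$double.eps)
  }
  structure(list(window_starts = (seq_len(n_win) - 1) * window,
                 fidelity = fid, high_entrainment = fid > threshold,
                 stim_frequency = stim_f, threshold = threshold),
            class = "entrainment_result")
}

#' @export
print.entrainment_result <- function(x, ...) {
  cat(sprintf("<entrainment_result> stim %g Hz: mean fidelity %.3f, %d/%d windows > %.2f\n",
              x$stim_frequency, mean(x$fidelity), sum(x$high_entrainment),
              length(x$fidelity), x$threshold))
  invisible(x)
}

#' Light-pulse-triggered cross-correlogram of a unit
#'
#' Spike counts in 1-ms bins on \[-10, +10\] ms around pulse onsets, plus the
#' peak post-pulse response expressed in SDs above the pre-pulse bin mean.
#'
#' @param train a [spike_train] (or numeric spike times).
#' @param pulses a [light_protocol] with at least 50 pulses.
#' @param half_window half-window in ms (default 10).
#' @param bin bin width in ms (default 1).
#' @return A `ccg` with 1-ms bins (raw counts) and attributes
#'   `response_sd` (peak post-pulse count in SD above the pre-pulse mean).
#' @export
light_triggered_ccg <- function(train, pulses, half_window = 10, bin = 1) {
  times <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  onsets <- pulses$pulse_onsets
  if (length(onsets) < 50) stop("need at least 50 pulses")
  edges <- seq(-half_window, half_window, by = bin)
  nb <- length(edges) - 1L
  w <- half_window / 1000
  lo <- findInterval(onsets - w, times) + 1L
  hi <- findInterval(onsets + w, times)
  len <- pmax(hi - lo + 1L, 0L)
  counts <- numeric(nb)
  if (sum(len)) {
    pi_ <- rep.int(seq_along(onsets), len)
    ti <- sequence(len) + rep.int(lo - 1L, len)
    lag <- (times[ti] - onsets[pi_]) * 1000
    b <- findInterval(lag, edges, rightmost.closed = TRUE)
    b <- b[b >= 1 & b <= nb]
    if (length(b)) counts <- tabulate(b, nbins = nb)
  }
  centers <- edges[-length(edges)] + bin / 2
  pre <- counts[centers < 0]
  post <- counts[centers > 0]
  resp_sd <- if (stats::sd(pre) > 0) (max(post) - mean(pre)) / stats::sd(pre) else Inf
  out <- structure(list(lags = centers, values = counts,
                        n_events_ref = length(onsets),
                        n_events_target = length(times),
                        bin = bin, max_lag = half_window,
                        normalization = "raw"),
                   class = "ccg")
  attr(out, "response_sd") <- resp_sd
  out
}

#' Optogenetic identification of light-responsive (ChAT+) units
#'
#' Circular-shift permutation test. A_obs and B_obs are the maximum 1-ms bin
#' counts in the \[-10, 0) and (0, +10\] ms windows around the true pulses.
#' The pulse train is then shifted into the pre-stimulation baseline by a
#' uniform random offset `n_shifts` times; p1 = P(A_i > A_obs) and
#' p2 = P(B_i > B_obs) over the surrogate maxima (strict inequality,
#' add-one corrected). The unit is classified `ChAT_plus` when p2 < 0.05
#' and p1 >= 0.05 for at least one stimulation epoch.
#'
#' Surrogate offsets are drawn on a 1-ms grid and evaluated against a 1-ms
#' spike-count histogram of the baseline via a single cross-correlation, so
#' all shifts cost one convolution.
#'
#' @param train a [spike_train].
#' @param pulses a [light_protocol] (its onsets define one stimulation
#'   epoch; call once per epoch for multi-epoch protocols and combine with
#'   [combine_optotag()]).
#' @param baseline `c(start, end)` of the pre-stimulation baseline in
#'   seconds; must be longer than the protocol span.
#' @param n_shifts number of surrogate shifts (default 10000).
#' @param seed RNG seed.
#' @param alpha significance level (default 0.05).
#' @return An object of class `optotag_result`: `A_obs`, `B_obs`, `p1`,
#'   `p2`, `n_shifts`, `classification`.
#' @export
identify_chat <- function(train, pulses, baseline, n_shifts = 10000, seed = NULL,
                          alpha = 0.05) {
  times <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  onsets <- pulses$pulse_onsets
  span <- max(onsets) - min(onsets)
  base_len <- baseline[2] - baseline[1]
  if (base_len <= span) stop("baseline shorter than the protocol span")
  if (!is.null(seed)) set.seed(seed)
  if (!length(times)) {
    return(structure(list(A_obs = 0, B_obs = 0, p1 = 1, p2 = 1,
                          n_shifts = n_shifts, classification = "not_identified"),
                     class = "optotag_result"))
  }
  obs <- light_triggered_ccg(times, pulses)
  A_obs <- max(obs$values[obs$lags < 0])
  B_obs <- max(obs$values[obs$lags > 0])
  # 1-ms spike histogram over the baseline
  bt <- times[times >= baseline[1] & times < baseline[2]]
  n_ms <- ceiling(base_len * 1000)
  H <- tabulate(floor((bt - baseline[1]) * 1000) + 1L, nbins = n_ms)
  p_ms <- round((onsets - min(onsets)) * 1000)   # pulse offsets within train, ms
  # cross-correlation G[m] = sum_p H[p_ms + m + 1] for m = 0 .. n_ms-1
  max_shift <- n_ms - ceiling(span * 1000) - 11L
  if (max_shift < 1) stop("baseline shorter than the protocol span")
  G <- pulse_train_xcorr(H, p_ms)
  offsets <- sample.int(max_shift - 11L, n_shifts, replace = TRUE) + 11L
  Ai <- rep(0L, n_shifts); Bi <- rep(0L, n_shifts)
  for (k in 1:10) {
    Ai <- pmax(Ai, G[offsets - k])
    Bi <- pmax(Bi, G[offsets + k])
  }
  p1 <- (1 + sum(Ai > A_obs)) / (n_shifts + 1)
  p2 <- (1 + sum(Bi > B_obs)) / (n_shifts + 1)
  cls <- if (p2 < alpha && p1 >= alpha) "ChAT_plus" else "not_identified"
  structure(list(A_obs = A_obs, B_obs = B_obs, p1 = p1, p2 = p2,
                 n_shifts = n_shifts, classification = cls),
            class = "optotag_result")
}

# G[m+1] = number of baseline spikes whose 1-ms bin sits at offset m from
# some pulse; computed by FFT cross-correlation of the pulse indicator with
# the spike histogram
pulse_train_xcorr <- function(H, p_ms) {
  n <- length(H)
  P <- numeric(n)
  keep <- p_ms + 1L <= n
  P[p_ms[keep] + 1L] <- P[p_ms[keep] + 1L] + 1
  L <- 2^ceiling(log2(2 * n))
  Hf <- stats::fft(c(H, numeric(L - n)))
  Pf <- stats::fft(c(P, numeric(L - n)))
  g <- Re(stats::fft(Hf * Conj(Pf), inverse = TRUE)) / L
  round(g[seq_len(n)])
}

#' Combine per-epoch optotag results
#'
#' @param results list of `optotag_result` objects (one per stimulation
#'   epoch).
#' @param alpha significance level (default 0.05).
#' @return `"ChAT_plus"` if any epoch satisfies p2 < alpha and p1 >= alpha,
#'   else `"not_identified"`.
#' @export
combine_optotag <- function(results, alpha = 0.05) {
  ok <- vapply(results, function(r) r$p2 < alpha && r$p1 >= alpha, logical(1))
  if (any(ok)) "ChAT_plus" else "not_identified"
}

#' @export
print.optotag_result <- function(x, ...) {
  cat(sprintf("<optotag_result> A=%g B=%g p1=%.4g p2=%.4g -> %s\n",
              x$A_obs, x$B_obs, x$p1, x$p2, x$classification))
  invisible(x)
}

#' Permutation test of burst-spike counts during light pulses
#'
#' Counts burst-class spikes inside the pulse windows (or in the 30 ms
#' after pulse offset with `window = "after"`), and compares against the
#' same count over randomly placed baseline windows of the same duration
#' and number; the p-value is the two-sided permutation rank.
#'
#' @param seg a `burst_segmentation`.
#' @param pulses a [light_protocol] (30 ms pulses in the original protocol).
#' @param baseline `c(start, end)` of the baseline period in seconds.
#' @param window `"during"` (default) or `"after"`: count within the pulse
#'   or within one pulse duration after pulse offset.
#' @param n_perm permutations (default 5000).
#' @param seed RNG seed.
#' @return List with `observed`, `p` and the null mean.
#' @export
pulse_burst_spike_test <- function(seg, pulses, baseline, window = c("during", "after"),
                                   n_perm = 5000, seed = NULL) {
  window <- match.arg(window)
  if (!is.null(seed)) set.seed(seed)
  bs <- burst_spike_times(seg)
  dur <- pulses$pulse_duration
  starts <- if (window == "during") pulses$pulse_onsets else pulses$pulse_onsets + dur
  n_pulse <- length(starts)
  base_len <- baseline[2] - baseline[1] - dur
  if (base_len <= 0 || (baseline[2] - baseline[1]) / dur < n_pulse)
    stop("baseline too short to place surrogate windows")
  if (!length(bs)) return(list(observed = 0, p = 1, null_mean = 0))
  observed <- count_in_windows(bs, starts, dur)
  null_counts <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    w0 <- baseline[1] + stats::runif(n_pulse, 0, base_len)
    null_counts[r] <- count_in_windows(bs, w0, dur)
  }
  p_hi <- (1 + sum(null_counts >= observed)) / (n_perm + 1)
  p_lo <- (1 + sum(null_counts <= observed)) / (n_perm + 1)
  list(observed = observed, p = min(1, 2 * min(p_hi, p_lo)),
       null_mean = mean(null_counts))
}

# total events within [w0, w0 + dur) over many window starts
count_in_windows <- function(ev, w0, dur) {
  sum(findInterval(w0 + dur, ev) - findInterval(w0, ev))
}

#' Pearson correlation of mean spike waveforms
#'
#' @param mean_waveform_baseline,mean_waveform_stim equal-length amplitude
#'   series (mean waveforms during baseline and stimulation).
#' @return Pearson r.
#' @export
waveform_similarity <- function(mean_waveform_baseline, mean_waveform_stim) {
  a <- as.numeric(mean_waveform_baseline); b <- as.numeric(mean_waveform_stim)
  if (length(a) != length(b)) stop("waveforms must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("constant waveform: undefined")
  stats::cor(a, b)
}
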