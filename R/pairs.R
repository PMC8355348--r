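#' Cross-correlogram of two event trains
#'
#' Histogram of target-minus-reference lags within `max_lag`, normalised by
#' the number of reference events to a per-event probability (or returned as
#' raw counts).
#'
#' @param ref,target event times in seconds (e.g. burst onsets of two
#'   simultaneously recorded cells).
#' @param max_lag maximum lag in ms (default 200).
#' @param bin bin width in ms (default 10).
#' @param normalization `"probability"` (per reference event) or `"raw"`.
#' @return An object of class `ccg`: list with `lags` (bin centres, ms),
#'   `values`, `n_events_ref`, `n_events_target`, `normalization`.
#' @export
burst_ccg <- function(ref, target, max_lag = 200, bin = 10,
                      normalization = c("probability", "raw")) {
  normalization <- match.arg(normalization)
  if (!length(ref) || !length(target)) stop("empty train: no joint firing")
  target <- sort(target); ref <- sort(ref)
  # bins centred on multiples of `bin`, including one centred at lag 0
  edges <- seq(-max_lag - bin / 2, max_lag + bin / 2, by = bin)
  nb <- length(edges) - 1L
  w <- (max_lag + bin / 2) / 1000
  lo <- findInterval(ref - w, target) + 1L
  hi <- findInterval(ref + w, target)
  len <- pmax(hi - lo + 1L, 0L)
  counts <- numeric(nb)
  if (sum(len)) {
    ri <- rep.int(seq_along(ref), len)
    ti <- sequence(len) + rep.int(lo - 1L, len)
    lags <- (target[ti] - ref[ri]) * 1000
    b <- findInterval(lags, edges, rightmost.closed = TRUE)
    b <- b[b >= 1 & b <= nb]
    if (length(b)) counts <- tabulate(b, nbins = nb)
  }
  values <- if (normalization == "probability") counts / length(ref) else counts
  structure(list(lags = edges[-length(edges)] + bin / 2, values = values,
                 n_events_ref = length(ref), n_events_target = length(target),
                 bin = bin, max_lag = max_lag, normalization = normalization),
            class = "ccg")
}

#' @export
print.ccg <- function(x, ...) {
  cat(sprintf("<ccg> %d bins of %g ms over +-%g ms (%s), %d ref / %d target events\n",
              length(x$lags), x$bin, x$max_lag, x$normalization,
              x$n_events_ref, x$n_events_target))
  invisible(x)
}

#' @export
plot.ccg <- function(x, ...) {
  graphics::plot(x$lags, x$values, type = "h", xlab = "lag (ms)",
                 ylab = x$normalization, ...)
  invisible(x)
}

#' Average cross-correlogram over cell pairs
#'
#' @param ccgs list of `ccg` objects on identical lag grids.
#' @return A `ccg` whose values are the per-bin mean, with `sem` attached.
#' @export
average_ccg <- function(ccgs) {
  if (!length(ccgs)) stop("no CCGs")
  lag0 <- ccgs[[1]]$lags
  for (c in ccgs) if (length(c$lags) != length(lag0) ||
                      any(abs(c$lags - lag0) > 1e-9)) stop("lag grid mismatch")
  m <- do.call(rbind, lapply(ccgs, `[[`, "values"))
  out <- ccgs[[1]]
  out$values <- colMeans(m)
  out$sem <- apply(m, 2, stats::sd) / sqrt(nrow(m))
  out$n_pairs <- nrow(m)
  out
}

#' Morlet spectrum of a cross-correlogram with permutation significance
#'
#' Morlet wavelet transform (frequencies below `f_max`) of the
#' mean-subtracted CCG curve; theta-band (5-10 Hz) power is summarised. When
#' the per-pair event trains and the session duration are supplied, a
#' permutation null is built by independently circularly shifting each
#' pair's target train, recomputing the average CCG and its theta power;
#' p is the fraction of null theta powers at least as large as observed
#' (add-one corrected).
#'
#' @param ccg a `ccg` (typically from [average_ccg()]).
#' @param f_max maximum analysis frequency in Hz (default 40).
#' @param pairs optional list of `list(ref=, target=)` event-time pairs used
#'   to build the permutation null.
#' @param duration session duration in seconds (required with `pairs`).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutation null.
#' @param theta_band theta band in Hz (default `c(5, 10)`).
#' @param omega0 Morlet parameter (default 6).
#' @return An object of class `ccg_spectrum`: `frequencies`, `power` (mean
#'   over lags per frequency), `power_map` (freq x lag), `theta_power`,
#'   `permutation_p` (NA without `pairs`), `n_perm`.
#' @export
ccg_spectrum <- function(ccg, f_max = 40, pairs = NULL, duration = NULL,
                         n_perm = 1000, seed = NULL, theta_band = c(5, 10),
                         omega0 = 6) {
  dt <- ccg$bin / 1000
  freqs <- seq(1, f_max - 1, by = 0.5)
  lowest_period_bins <- 1 / (freqs[1] * dt)
  if (length(ccg$values) < lowest_period_bins)
    freqs <- freqs[freqs >= 1 / (length(ccg$values) * dt)]
  if (all(ccg$values == 0)) {
    return(structure(list(frequencies = freqs,
                          power = numeric(length(freqs)),
                          power_map = matrix(0, length(freqs), length(ccg$values)),
                          theta_power = 0, permutation_p = 1, n_perm = 0),
                     class = "ccg_spectrum"))
  }
  cw <- morlet_cwt(ccg$values, dt, freqs, omega0)
  th <- cw$freqs >= theta_band[1] & cw$freqs <= theta_band[2]
  obs <- sum(cw$mean_power[th])
  p <- NA_real_
  if (!is.null(pairs)) {
    if (is.null(duration)) stop("duration required for the permutation null")
    if (!is.null(seed)) set.seed(seed)
    null_pow <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      shifted <- lapply(pairs, function(pr) {
        s <- stats::runif(1, 0, duration)
        list(ref = pr$ref, target = sort((pr$target + s) %% duration))
      })
      cl <- lapply(shifted, function(pr)
        burst_ccg(pr$ref, pr$target, max_lag = ccg$max_lag, bin = ccg$bin))
      av <- average_ccg(cl)
      cwn <- morlet_cwt(av$values, dt, freqs, omega0)
      null_pow[r] <- sum(cwn$mean_power[th])
    }
    p <- (1 + sum(null_pow >= obs)) / (n_perm + 1)
  }
  structure(list(frequencies = freqs, power = cw$mean_power,
                 power_map = cw$power, theta_power = obs,
                 permutation_p = p, n_perm = n_perm),
            class = "ccg_spectrum")
}

#' @export
print.ccg_spectrum <- function(x, ...) {
  pk <- x$frequencies[which.max(x$power)]
  cat(sprintf("<ccg_spectrum> peak %.1f Hz, theta power %.3g, permutation p = %s\n",
              pk, x$theta_power, format(x$permutation_p)))
  invisible(x)
}

#' Burst autocorrelogram and theta rhythmicity index
#'
#' Autocorrelation of burst onset times (zero-lag bin excluded). The
#' rhythmicity index is the theta-band Morlet power of the autocorrelogram
#' divided by its broadband (1-40 Hz) power.
#'
#' @param seg a `burst_segmentation` with at least 10 bursts.
#' @param max_lag maximum lag in ms (default 500).
#' @param bin bin width in ms (default 10).
#' @return List with the `ccg` (class `ccg`) and `rhythmicity_index`.
#' @export
burst_autocorrelogram <- function(seg, max_lag = 500, bin = 10) {
  onsets <- burst_onsets(seg)
  if (length(onsets) < 10) stop("need at least 10 bursts")
  ac <- burst_ccg(onsets, onsets, max_lag = max_lag, bin = bin)
  zero_bin <- which(abs(ac$lags) < bin / 2)
  # remove the self-pair contribution and interpolate across the centre bin
  ac$values[zero_bin] <- ac$values[zero_bin] - 1
  sp <- ccg_spectrum(ac, f_max = 40)
  broad <- sum(sp$power[sp$frequencies >= 1 & sp$frequencies <= 40])
  idx <- if (broad > 0) sp$theta_power / broad else 0
  list(ccg = ac, rhythmicity_index = idx, spectrum = sp)
}
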