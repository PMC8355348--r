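#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem; the first
#' `k` eigenvectors are the tapers, normalised to unit energy and with a
#' positive mean (even orders) or positive first lobe (odd orders).
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers (default `2 * nw - 1`).
#' @return An `n` x `k` matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 3, k = 2 * nw - 1) {
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (t[-1] * (n - t[-1])) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_main
  A[cbind(seq_len(n - 1), seq(2, n))] <- diag_off
  A[cbind(seq(2, n), seq_len(n - 1))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tapers[, j] <- tapers[, j] / sqrt(sum(tapers[, j]^2))
    if (sum(tapers[, j]) < 0) tapers[, j] <- -tapers[, j]
  }
  .dpss_cache[[key]] <- tapers
  tapers
}

# session-lifetime cache of computed taper sets
.dpss_cache <- new.env(parent = emptyenv())

#' Multitaper power spectral density
#'
#' Averages Slepian-tapered periodograms over sliding windows (50 % overlap)
#' of the signal, the standard NW = 3 / window 1024 configuration by
#' default.
#'
#' @param lfp an [lfp_signal] (or numeric vector, with `rate` given).
#' @param nw time-bandwidth product (default 3).
#' @param window window length in samples (default 1024).
#' @param rate sampling rate, required when `lfp` is a bare vector.
#' @return An object of class `psd`: list with `freq` (Hz) and `power`
#'   (mean squared amplitude per frequency bin).
#' @export
multitaper_psd <- function(lfp, nw = 3, window = 1024, rate = NULL) {
  if (inherits(lfp, "lfp_signal")) {
    x <- lfp$samples; rate <- lfp$rate
  } else {
    x <- as.numeric(lfp)
    if (is.null(rate)) stop("rate required for a bare numeric signal")
  }
  if (length(x) < window) stop("signal shorter than the PSD window")
  tapers <- dpss_tapers(window, nw)
  k <- ncol(tapers)
  step <- max(1L, window %/% 2L)
  starts <- seq(1L, length(x) - window + 1L, by = step)
  nf <- window %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + window - 1L)]
    seg <- seg - mean(seg)
    for (j in seq_len(k)) {
      sp <- Mod(stats::fft(seg * tapers[, j]))^2
      acc <- acc + sp[seq_len(nf)]
    }
  }
  power <- acc / (k * length(starts) * rate)
  structure(list(freq = (seq_len(nf) - 1) * rate / window, power = power,
                 nw = nw, window = window, rate = rate),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  pk <- x$freq[which.max(x$power[-1]) + 1]
  cat(sprintf("<psd> %d bins up to %.1f Hz (res %.3f Hz), peak near %.2f Hz\n",
              length(x$freq), max(x$freq), x$freq[2], pk))
  invisible(x)
}

#' @export
plot.psd <- function(x, xlim = c(0, 40), ...) {
  graphics::plot(x$freq, x$power, type = "l", xlim = xlim,
                 xlab = "frequency (Hz)", ylab = "power", ...)
  invisible(x)
}

#' Cumulative band power of a PSD
#'
#' @param psd a `psd` object.
#' @param f_lo,f_hi band limits in Hz (inclusive).
#' @return Summed power over the band.
#' @export
band_power <- function(psd, f_lo, f_hi) {
  sum(psd$power[psd$freq >= f_lo & psd$freq <= f_hi])
}

#' Continuous Morlet wavelet transform
#'
#' Complex Morlet wavelet (centre frequency parameter `omega0`, default 6)
#' evaluated by direct convolution; suited to short curves such as
#' cross-correlograms.
#'
#' @param x numeric signal (mean is removed).
#' @param dt sample interval in seconds.
#' @param freqs analysis frequencies in Hz.
#' @param omega0 Morlet parameter (default 6).
#' @return List with `freqs`, `power` (frequencies x time matrix of squared
#'   magnitude) and `mean_power` per frequency.
#' @export
morlet_cwt <- function(x, dt, freqs, omega0 = 6) {
  x <- x - mean(x)
  n <- length(x)
  power <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    s <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freqs[i])
    half <- ceiling(4 * s / dt)
    tt <- seq(-half, half) * dt
    psi <- pi^(-0.25) * exp(1i * omega0 * tt / s) * exp(-(tt / s)^2 / 2)
    psi <- psi * sqrt(dt / s)
    co <- conv_same(x, psi)
    power[i, ] <- Mod(co)^2
  }
  list(freqs = freqs, power = power, mean_power = rowMeans(power))
}

# 'same'-length complex convolution via zero-padded FFT
conv_same <- function(x, k) {
  n <- length(x); m <- length(k)
  L <- n + m - 1L
  full <- stats::fft(stats::fft(c(x, numeric(L - n))) *
                     stats::fft(c(k, numeric(L - m))), inverse = TRUE) / L
  off <- (m - 1L) %/% 2L
  full[(off + 1L):(off + n)]
}
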