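# Circular-statistics helpers. All user-facing angles are degrees in
# [0, 360); internal computation is in radians.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) (r * 180 / pi) %% 360

#' Circular mean and resultant vector length
#'
#' @param phases_deg angles in degrees.
#' @param w optional non-negative weights.
#' @return List with `mean_deg` (in \[0, 360)) and `R` (resultant length in
#'   \[0, 1\]).
#' @export
circular_mean <- function(phases_deg, w = NULL) {
  th <- deg2rad(phases_deg)
  if (is.null(w)) w <- rep(1, length(th))
  z <- sum(w * exp(1i * th)) / sum(w)
  list(mean_deg = rad2deg(Arg(z)), R = Mod(z))
}

#' Rayleigh test of circular uniformity
#'
#' Resultant length R = |sum exp(i theta)| / n and the large-sample
#' approximation p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n)).
#'
#' @param phases_deg angles in degrees (n >= 5).
#' @param w optional non-negative weights (effective n = sum of weights).
#' @return List with `R`, `p`, `n` and `mean_deg`.
#' @export
rayleigh_test <- function(phases_deg, w = NULL) {
  n_eff <- if (is.null(w)) length(phases_deg) else sum(w)
  if (n_eff < 5) stop("Rayleigh test needs n >= 5")
  cm <- circular_mean(phases_deg, w)
  Rn <- n_eff * cm$R
  p <- exp(sqrt(1 + 4 * n_eff + 4 * (n_eff^2 - Rn^2)) - (1 + 2 * n_eff))
  list(R = cm$R, p = min(1, p), n = n_eff, mean_deg = cm$mean_deg)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; kappa = 0 gives the uniform distribution.
#'
#' @param n number of draws.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration (>= 0).
#' @return Angles in degrees in \[0, 360).
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  rad2deg(out)
}

# von Mises density per degree (integrates to 1 over 360 degrees)
dvonmises_deg <- function(x_deg, mu_deg, kappa) {
  d <- deg2rad(x_deg - mu_deg)
  exp(kappa * (cos(d) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE)) *
    pi / 180
}

# circular KDE on a degree grid with von Mises kernel of concentration kappa;
# returns density per degree (integrates to 1 over 360 deg)
circ_kde <- function(phases_deg, kappa, grid_deg) {
  denom <- 2 * pi * besselI(kappa, 0, expon.scaled = TRUE)
  d <- outer(deg2rad(grid_deg), deg2rad(phases_deg), "-")
  dens <- rowMeans(exp(kappa * (cos(d) - 1))) / denom
  dens * pi / 180   # per degree
}

# number of modes (local maxima) of a periodic density sampled on a grid
count_circ_modes <- function(dens, tol = 1e-12) {
  n <- length(dens)
  prev <- dens[c(n, seq_len(n - 1))]
  nxt <- dens[c(seq(2, n), 1)]
  sum(dens > prev + tol & dens >= nxt + tol)
}
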