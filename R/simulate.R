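#' Synthetic-session configuration
#'
#' Bundles the generator parameters with genotype presets. The `control`
#' preset reproduces wild-type population statistics (burst-event rate
#' 0.23 Hz, single-spike rate 0.80 Hz, mean intra-burst ISI 7.42 ms,
#' theta-phase locking at 344 degrees with kappa = 1, spike-frequency
#' accommodation of +1.5 ms per interval, ~55 ms post-burst single-spike
#' suppression). The `mutant` preset removes accommodation and phase
#' locking during running (kappa 0, but control-level locking during
#' immobility), shifts bursts toward greater lengths, couples burst length
#' inversely to intra-burst ISI, and lowers the single-spike rate to
#' 0.49 Hz with mean ISI 6.67 ms. The intra-burst ISI offset is solved from
#' the target mean ISI given the burst-length distribution, so the emitted
#' ISIs average to the target by construction.
#'
#' @param preset `"control"`, `"mutant"` or `"custom"`.
#' @param duration session duration in seconds (default 600).
#' @param seed integer RNG seed (required; every simulation is fully
#'   deterministic given config + seed).
#' @param enclosure_type `"arena"` or `"track"`.
#' @param n_cells number of simulated pyramidal cells (default 50).
#' @param theta_frequency theta frequency in Hz (default 7).
#' @param run_block,immobility_block alternating state-block lengths in s.
#' @param ... overrides for any cell parameter (see the returned list).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(preset = c("control", "mutant", "custom"),
                         duration = 600, seed = 1,
                         enclosure_type = c("arena", "track"),
                         n_cells = 50, theta_frequency = 7,
                         run_block = 40, immobility_block = 20, ...) {
  preset <- match.arg(preset)
  enclosure_type <- match.arg(enclosure_type)
  cfg <- list(
    preset = preset, duration = duration, seed = as.integer(seed),
    enclosure_type = enclosure_type, n_cells = n_cells,
    theta_frequency = theta_frequency,
    run_block = run_block, immobility_block = immobility_block,
    lfp_rate = 1250, frame_rate = 25,
    theta_amplitude = 1000, noise_level = 0.25,
    # cell parameters (control defaults)
    burst_event_rate = 0.23, single_rate = 0.80,
    target_mean_isi = 7.42, isi_slope = 1.5,
    inverse_length_frequency_coupling = FALSE, isi_coupling = 0.5,
    # geometric decay of the length pmf over 2..6 spikes; 0.2 puts the mean
    # burst length at ~2.2 spikes so burst-spike + single rates compose to
    # the observed all-spike rate
    burst_length_ratio = 0.2,
    phase_mu = 344, phase_kappa = 1, phase_kappa_immobility = 1,
    single_phase_kappa = 0.5,
    field_sigma = 6, field_peak_gain = 5, field_baseline = 0.1,
    post_burst_suppression = 55,     # ms
    refractory = 2,                  # ms
    isi_jitter = 0.5,                # ms, uniform half-width
    single_isolation = 16,           # ms dead time around singles
    # light protocol
    light_baseline = 300, light_epoch = 240, light_pulse = 0.005,
    light_frequencies = c(2, 5), latency_ms = 3, latency_jitter_ms = 1,
    p_respond = 0.8, background_rate = 2
  )
  if (preset == "mutant") {
    cfg$burst_event_rate <- 0.24
    cfg$single_rate <- 0.49
    cfg$target_mean_isi <- 6.67
    cfg$isi_slope <- 0
    cfg$inverse_length_frequency_coupling <- TRUE
    cfg$burst_length_ratio <- 0.4    # longer bursts (mean ~2.6 spikes)
    cfg$phase_mu <- 315
    cfg$phase_kappa <- 0             # unlocked during running
    cfg$phase_kappa_immobility <- 1
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg$burst_length_pmf <- geometric_length_pmf(cfg$burst_length_ratio)
  cfg$isi_start <- solve_isi_start(cfg)
  validate_isi(cfg)
  structure(cfg, class = "synth_config")
}

geometric_length_pmf <- function(ratio, lengths = 2:6) {
  w <- ratio^(lengths - 2)
  stats::setNames(w / sum(w), lengths)
}

# solve the ISI offset so the expected mean ISI equals the target
solve_isi_start <- function(cfg) {
  L <- as.integer(names(cfg$burst_length_pmf))
  p <- cfg$burst_length_pmf
  n_int <- sum(p * (L - 1))
  if (cfg$inverse_length_frequency_coupling) {
    # constant ISI per burst: isi(L) = a - c (L - 2)
    cfg$target_mean_isi + cfg$isi_coupling * sum(p * (L - 1) * (L - 2)) / n_int
  } else {
    # accommodating ISI: isi_k = a + slope * k, k = 0 .. L-2
    e_order <- sum(p * (L - 2) * (L - 1) / 2) / n_int
    cfg$target_mean_isi - cfg$isi_slope * e_order
  }
}

validate_isi <- function(cfg) {
  L <- as.integer(names(cfg$burst_length_pmf))
  if (cfg$inverse_length_frequency_coupling) {
    isis <- cfg$isi_start - cfg$isi_coupling * (L - 2)
  } else {
    isis <- cfg$isi_start + cfg$isi_slope * (L - 2)
  }
  if (any(isis + cfg$isi_jitter > 15))
    stop("config would emit intra-burst ISIs above the 15 ms burst definition")
  if (any(isis - cfg$isi_jitter <= cfg$refractory))
    stop("config would emit intra-burst ISIs inside the refractory period")
  invisible(TRUE)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config '%s'> %g s, %d cells, seed %d, %s\n", x$preset,
              x$duration, x$n_cells, x$seed, x$enclosure_type))
  invisible(x)
}

#' Simulate a movement trajectory
#'
#' Arena: smoothed random-walk (Ornstein-Uhlenbeck heading and speed) with
#' reflecting walls. Track: unidirectional motion. Running and immobility
#' alternate per the state schedule; running frames exceed 3 cm/s and
#' immobility frames stay below 2 cm/s.
#'
#' @param config a [synth_config()].
#' @return A [position_track] with speed, and the state schedule as
#'   attribute `"schedule"` (matrix of `start`, `end`, `state`).
#' @export
simulate_trajectory <- function(config) {
  set.seed(config$seed + 1L)
  fr <- config$frame_rate
  dt <- 1 / fr
  n <- round(config$duration * fr)
  t <- (seq_len(n) - 1) * dt
  sched <- state_schedule(config)
  running <- schedule_mask(t, sched)
  enc <- enclosure(config$enclosure_type)
  # OU speed around 8 cm/s, clipped to [3.5, 16] during running
  sp <- numeric(n); sp[1] <- 8
  for (i in 2:n) sp[i] <- sp[i - 1] + (8 - sp[i - 1]) * dt / 2 +
    3 * sqrt(dt) * stats::rnorm(1)
  sp <- pmin(pmax(sp, 3.5), 16)
  if (config$enclosure_type == "arena") {
    head <- cumsum(c(stats::runif(1, 0, 2 * pi), 1.2 * sqrt(dt) * stats::rnorm(n - 1)))
    x <- numeric(n); y <- numeric(n)
    x[1] <- enc$width / 2; y[1] <- enc$height / 2
    for (i in 2:n) {
      if (running[i]) {
        dx <- sp[i] * cos(head[i]) * dt
        dy <- sp[i] * sin(head[i]) * dt
      } else {
        dx <- stats::rnorm(1, 0, 0.01); dy <- stats::rnorm(1, 0, 0.01)
      }
      xi <- x[i - 1] + dx; yi <- y[i - 1] + dy
      # reflect at the walls, and steer the heading away
      if (xi < 0) { xi <- -xi; head[i:n] <- pi - head[i:n] }
      if (xi > enc$width) { xi <- 2 * enc$width - xi; head[i:n] <- pi - head[i:n] }
      if (yi < 0) { yi <- -yi; head[i:n] <- -head[i:n] }
      if (yi > enc$height) { yi <- 2 * enc$height - yi; head[i:n] <- -head[i:n] }
      x[i] <- xi; y[i] <- yi
    }
  } else {
    r <- enc$diameter / 2
    ang <- numeric(n); ang[1] <- stats::runif(1, 0, 2 * pi)
    for (i in 2:n) {
      dang <- if (running[i]) sp[i] * dt / r else stats::rnorm(1, 0, 1e-4)
      ang[i] <- ang[i - 1] + dang
    }
    x <- r + r * cos(ang); y <- r + r * sin(ang)
  }
  track <- compute_speed(position_track(t, x, y))
  attr(track, "schedule") <- sched
  track
}

# alternating run/immobility blocks covering the session
state_schedule <- function(config) {
  starts <- c(); ends <- c(); states <- c()
  t0 <- 0
  while (t0 < config$duration) {
    t1 <- min(t0 + config$run_block, config$duration)
    starts <- c(starts, t0); ends <- c(ends, t1); states <- c(states, "run")
    t0 <- t1
    if (t0 >= config$duration || config$immobility_block <= 0) next
    t1 <- min(t0 + config$immobility_block, config$duration)
    starts <- c(starts, t0); ends <- c(ends, t1); states <- c(states, "immobility")
    t0 <- t1
  }
  data.frame(start = starts, end = ends, state = states)
}

schedule_mask <- function(t, sched) {
  run_iv <- as.matrix(sched[sched$state == "run", c("start", "end")])
  in_intervals(t, run_iv)
}

#' Simulate a theta-band LFP with ground-truth phase
#'
#' Theta sinusoid at the configured frequency with slow Ornstein-Uhlenbeck
#' amplitude and frequency jitter plus 1/f background noise, sampled at
#' 1250 Hz. Theta is present during both running and (alert) immobility
#' blocks, with lower amplitude during immobility. The true instantaneous
#' phase (trough = 0 degrees) is attached as ground truth.
#'
#' @param config a [synth_config()].
#' @param freq_jitter_sd SD of the slow frequency jitter in Hz (default
#'   0.3; 0 disables jitter).
#' @return An [lfp_signal] with attribute `"truth"`: list with `t`,
#'   `phase` (degrees, trough = 0) and the state schedule.
#' @export
simulate_lfp <- function(config, freq_jitter_sd = 0.3) {
  set.seed(config$seed + 2L)
  fs <- config$lfp_rate
  n <- round(config$duration * fs)
  dt <- 1 / fs
  t <- (seq_len(n) - 1) * dt
  # slow OU frequency jitter (time constant 2 s)
  f_dev <- numeric(n)
  if (freq_jitter_sd > 0) {
    tau <- 2
    sig <- freq_jitter_sd * sqrt(2 * dt / tau)
    innov <- stats::rnorm(n) * sig
    f_dev <- stats::filter(innov, 1 - dt / tau, method = "recursive")
    f_dev <- as.numeric(f_dev)
  }
  inst_f <- config$theta_frequency + f_dev
  phase_deg <- (cumsum(inst_f) * dt * 360) %% 360
  # slow amplitude modulation
  amp_mod <- 1 + 0.2 * sin(2 * pi * 0.05 * t + stats::runif(1, 0, 2 * pi))
  sched <- state_schedule(config)
  run_mask <- schedule_mask(t, sched)
  amp <- config$theta_amplitude * amp_mod * ifelse(run_mask, 1, 0.7)
  theta <- -amp * cos(deg2rad(phase_deg))   # trough at phase 0
  noise <- one_over_f_noise(n, fs) * config$noise_level * config$theta_amplitude
  lfp <- lfp_signal(theta + noise, rate = fs)
  attr(lfp, "truth") <- list(t = t, phase = phase_deg, schedule = sched)
  lfp
}

# 1/f-amplitude Gaussian noise, unit SD
one_over_f_noise <- function(n, fs) {
  nf <- n %/% 2
  f <- seq_len(nf) * fs / n
  mag <- 1 / sqrt(pmax(f, 0.1))
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = ph)
  full <- c(0, spec, if (n %% 2 == 0) Conj(rev(spec[-nf])) else Conj(rev(spec)))
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

#' Simulate one bursty theta-modulated place cell
#'
#' Burst events form an inhomogeneous Poisson process whose rate is the
#' burst-event rate times a Gaussian place-field gain and a von Mises
#' theta-phase gain (exact thinning; both gains are normalised to unit
#' session mean so the realised event rate matches the nominal one). Each
#' event draws a burst length from the configured pmf and emits spikes with
#' accommodating ISIs (control) or length-coupled constant ISIs (mutant),
#' jittered by +-0.5 ms. Single spikes are an independent place- and
#' phase-modulated Poisson process silenced for the post-burst suppression
#' window after each burst; spikes closer than the refractory period are
#' deleted.
#'
#' @param config a [synth_config()].
#' @param trajectory a [simulate_trajectory()] result.
#' @param lfp a [simulate_lfp()] result (its ground-truth phase is used).
#' @param cell_index index used to derive the cell's seed and field centre.
#' @param field_center optional `c(x, y)` in cm.
#' @return A [spike_train] with attribute `"truth"`: list with
#'   `burst_onsets`, `burst_lengths`, `spike_label` (burst id per spike, 0
#'   for singles), `field_center`, and the per-spike intended times.
#' @export
simulate_cell <- function(config, trajectory, lfp, cell_index = 1,
                          field_center = NULL) {
  set.seed(config$seed + 100L + cell_index)
  truth <- attr(lfp, "truth")
  if (is.null(truth)) stop("lfp must carry ground-truth phase (simulate_lfp)")
  dur <- config$duration
  enc <- enclosure(config$enclosure_type)
  if (is.null(field_center)) {
    field_center <- if (config$enclosure_type == "arena") {
      c(stats::runif(1, 5, enc$width - 5), stats::runif(1, 5, enc$height - 5))
    } else {
      r <- enc$diameter / 2
      a <- stats::runif(1, 0, 2 * pi)
      c(r + r * cos(a), r + r * sin(a))
    }
  }
  # frame-rate gain traces, normalised to unit mean
  d2 <- (trajectory$x - field_center[1])^2 + (trajectory$y - field_center[2])^2
  gf <- config$field_baseline +
    (config$field_peak_gain - config$field_baseline) * exp(-d2 / (2 * config$field_sigma^2))
  gf <- gf / mean(gf)
  run_mask_f <- schedule_mask(trajectory$t, truth$schedule)
  kappa_f <- ifelse(run_mask_f, config$phase_kappa, config$phase_kappa_immobility)
  gain_at <- function(times, kappa_scale = 1, mu = config$phase_mu) {
    fi <- pmin(pmax(findInterval(times, trajectory$t), 1L), length(trajectory$t))
    gfx <- gf[fi]
    kap <- kappa_f[fi] * kappa_scale
    li <- pmin(pmax(round(times * config$lfp_rate) + 1L, 1L), length(truth$phase))
    ph <- truth$phase[li]
    gph <- exp(kap * cos(deg2rad(ph - mu))) /
      (besselI(kap, 0, expon.scaled = TRUE) * exp(kap))
    list(field = gfx, phase = gph)
  }
  # empirical phase-gain normaliser over the session
  grid_t <- seq(0, dur, by = 0.02)
  g0 <- gain_at(grid_t)
  phase_norm <- mean(g0$phase)
  lambda_max <- config$burst_event_rate * max(gf) *
    max(g0$phase) / phase_norm * 1.2
  L_vals <- as.integer(names(config$burst_length_pmf))
  iso_b <- config$single_isolation / 1000
  # build bursts with a dead time after each burst (a cell cannot emit
  # overlapping bursts); events landing inside it are dropped
  gen_bursts <- function(scale) {
    cand <- thin_poisson(dur, lambda_max * scale * 1.05, function(tt) {
      g <- gain_at(tt)
      scale * config$burst_event_rate * g$field * g$phase / phase_norm
    })
    lens_c <- if (length(cand)) sample(L_vals, length(cand), replace = TRUE,
                                       prob = config$burst_length_pmf) else integer(0)
    onsets <- c(); lens <- c(); spike_t <- c(); label <- c(); burst_last <- c()
    last_end <- -Inf
    for (i in seq_along(cand)) {
      if (cand[i] < last_end + iso_b) next
      Li <- lens_c[i]
      base_isi <- if (config$inverse_length_frequency_coupling) {
        rep(config$isi_start - config$isi_coupling * (Li - 2), Li - 1)
      } else {
        config$isi_start + config$isi_slope * (0:(Li - 2))
      }
      isi <- base_isi + stats::runif(Li - 1, -config$isi_jitter, config$isi_jitter)
      st <- cand[i] + c(0, cumsum(isi)) / 1000
      k <- length(onsets) + 1L
      onsets[k] <- cand[i]; lens[k] <- Li
      spike_t <- c(spike_t, st); label <- c(label, rep(k, Li))
      burst_last[k] <- st[Li]
      last_end <- st[Li]
    }
    list(onsets = onsets, lens = lens, spike_t = spike_t, label = label,
         burst_last = burst_last, n_cand = length(cand))
  }
  pilot_b <- gen_bursts(1)
  keep_frac <- if (pilot_b$n_cand > 0) length(pilot_b$onsets) / pilot_b$n_cand else 1
  gb <- gen_bursts(1 / max(keep_frac, 0.5))
  onsets <- if (is.null(gb$onsets)) numeric(0) else gb$onsets
  lens <- if (is.null(gb$lens)) integer(0) else gb$lens
  spike_t <- gb$spike_t; label <- gb$label
  burst_last <- if (is.null(gb$burst_last)) numeric(0) else gb$burst_last
  # single spikes: place- and weakly phase-modulated, suppressed after bursts.
  # A dead time of `single_isolation` around burst spikes and between singles
  # keeps emitted singles from merging into detected bursts; the base rate is
  # compensated for suppression and (in a second pass) for the dead-time loss.
  sup_s <- config$post_burst_suppression / 1000
  sup_frac <- min(0.9, length(onsets) * sup_s / dur)
  base_single <- config$single_rate / (1 - sup_frac)
  ks <- config$single_phase_kappa
  g0s <- exp(ks * cos(deg2rad(seq(0, 359) - config$phase_mu))) /
    (besselI(ks, 0, expon.scaled = TRUE) * exp(ks))
  single_norm <- mean(g0s)
  s_lambda_max <- base_single * max(gf) * max(g0s) / single_norm * 1.2
  bl_sorted <- sort(burst_last)
  suppressed <- function(tt) {
    if (!length(bl_sorted)) return(rep(FALSE, length(tt)))
    i <- findInterval(tt, bl_sorted)
    i > 0 & tt - bl_sorted[pmax(i, 1)] < sup_s
  }
  single_rate_fn <- function(scale) {
    force(scale)
    function(tt) {
      fi <- pmin(pmax(findInterval(tt, trajectory$t), 1L), length(trajectory$t))
      li <- pmin(pmax(round(tt * config$lfp_rate) + 1L, 1L), length(truth$phase))
      gph <- exp(ks * cos(deg2rad(truth$phase[li] - config$phase_mu))) /
        (besselI(ks, 0, expon.scaled = TRUE) * exp(ks))
      lam <- scale * base_single * gf[fi] * gph / single_norm
      lam[suppressed(tt)] <- 0
      lam
    }
  }
  iso <- config$single_isolation / 1000
  bspk_sorted <- sort(spike_t)
  isolate_singles <- function(cand) {
    if (!length(cand)) return(cand)
    if (length(bspk_sorted)) {
      i <- findInterval(cand, bspk_sorted)
      d_prev <- ifelse(i > 0, cand - bspk_sorted[pmax(i, 1)], Inf)
      d_next <- ifelse(i < length(bspk_sorted),
                       bspk_sorted[pmin(i + 1L, length(bspk_sorted))] - cand, Inf)
      cand <- cand[pmin(d_prev, d_next) >= iso]
    }
    if (length(cand) > 1) {
      keep <- logical(length(cand)); last <- -Inf
      for (j in seq_along(cand)) {
        if (cand[j] - last >= iso) { keep[j] <- TRUE; last <- cand[j] }
      }
      cand <- cand[keep]
    }
    cand
  }
  # fixed-point compensation of the dead-time loss: each pass measures the
  # kept fraction and rescales the base rate (the loss itself grows with the
  # candidate rate, so one pilot pass under-corrects)
  target_n <- config$single_rate * dur
  scale <- 1
  singles <- numeric(0)
  for (pass in 1:3) {
    singles <- isolate_singles(
      thin_poisson(dur, s_lambda_max * max(scale, 1) * 1.1,
                   single_rate_fn(scale)))
    if (pass == 3 || target_n < 1) break
    ratio <- length(singles) / max(target_n, 1)
    if (ratio <= 0) break
    scale <- min(3, scale / ratio)
  }
  all_t <- c(spike_t, singles)
  all_lab <- c(label, rep(0L, length(singles)))
  ord <- order(all_t)
  all_t <- all_t[ord]; all_lab <- all_lab[ord]
  # refractory enforcement by deletion
  keep <- logical(length(all_t))
  last <- -Inf
  for (i in seq_along(all_t)) {
    if (all_t[i] - last >= config$refractory / 1000) {
      keep[i] <- TRUE; last <- all_t[i]
    }
  }
  all_t <- all_t[keep]; all_lab <- all_lab[keep]
  inside <- all_t >= 0 & all_t <= dur
  all_t <- all_t[inside]; all_lab <- all_lab[inside]
  dup <- duplicated(all_t)
  all_t <- all_t[!dup]; all_lab <- all_lab[!dup]
  tr <- spike_train(all_t, unit_id = sprintf("sim%03d", cell_index),
                    cell_class = "pyramidal")
  attr(tr, "truth") <- list(burst_onsets = onsets, burst_lengths = lens,
                            spike_label = all_lab, field_center = field_center)
  tr
}

# exact thinning sampler for an inhomogeneous Poisson process on [0, dur]
thin_poisson <- function(dur, lambda_max, rate_fn) {
  n_cand <- stats::rpois(1, lambda_max * dur)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, dur))
  lam <- rate_fn(cand)
  if (any(lam > lambda_max * (1 + 1e-6)))
    warning("thinning bound exceeded; rates clipped")
  acc <- stats::runif(n_cand) < lam / lambda_max
  cand[acc]
}

#' Simulate a full recording session
#'
#' Trajectory, LFP and `n_cells` place cells under one configuration; all
#' randomness derives from the config seed.
#'
#' @param config a [synth_config()].
#' @return A [session] whose units carry per-cell ground truth (attribute
#'   `"truth"` on each train); the LFP carries the true phase, the track
#'   the state schedule.
#' @export
simulate_session <- function(config) {
  track <- simulate_trajectory(config)
  lfp <- simulate_lfp(config)
  units <- lapply(seq_len(config$n_cells), function(i)
    simulate_cell(config, track, lfp, cell_index = i))
  session(id = sprintf("sim-%s-%d", config$preset, config$seed),
          units = units, duration = config$duration, lfp = lfp,
          position = track,
          genotype_label = config$preset)
}

#' Simulate an optogenetic identification session
#'
#' A pre-stimulation baseline followed by one 4-min epoch per stimulation
#' frequency (2 and 5 Hz by default; 5 ms pulses). Responsive cells add a
#' short-latency spike (latency 3 +- 1 ms, probability `p_respond`) per
#' pulse on top of their background Poisson process; non-responsive cells
#' are background-only.
#'
#' @param config a [synth_config()].
#' @param n_cells number of units (default `config$n_cells`).
#' @param responsive logical vector marking responsive units (default: the
#'   first 20 % of cells).
#' @return List with `units` (spike trains), `epochs` (list of
#'   [light_protocol] per frequency), `baseline` (`c(start, end)` s),
#'   `responsive`, `duration`.
#' @export
simulate_light_session <- function(config, n_cells = config$n_cells,
                                   responsive = NULL) {
  set.seed(config$seed + 5000L)
  if (is.null(responsive))
    responsive <- seq_len(n_cells) <= max(1, round(0.2 * n_cells))
  base_end <- config$light_baseline
  epochs <- list(); t0 <- base_end
  for (f in config$light_frequencies) {
    on <- seq(t0, t0 + config$light_epoch - 1 / f, by = 1 / f)
    epochs[[as.character(f)]] <- light_protocol(on, config$light_pulse,
                                                frequency_hz = f, site = "MS")
    t0 <- t0 + config$light_epoch
  }
  duration <- t0
  units <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    bg <- sort(stats::runif(stats::rpois(1, config$background_rate * duration),
                            0, duration))
    st <- bg
    if (responsive[i]) {
      for (ep in epochs) {
        hit <- stats::runif(length(ep$pulse_onsets)) < config$p_respond
        lat <- config$latency_ms +
          stats::runif(sum(hit), -config$latency_jitter_ms, config$latency_jitter_ms)
        st <- c(st, ep$pulse_onsets[hit] + lat / 1000)
      }
    }
    st <- sort(st)
    st <- st[c(TRUE, diff(st) >= config$refractory / 1000)]
    st <- unique(st)
    units[[i]] <- spike_train(st, unit_id = sprintf("opto%03d", i))
  }
  list(units = units, epochs = epochs, baseline = c(0, base_end),
       responsive = responsive, duration = duration)
}
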