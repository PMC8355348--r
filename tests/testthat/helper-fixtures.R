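# Shared fixtures built in code.

# independent brute-force burst scanner: walks the train spike by spike
brute_force_segment <- function(times, max_isi = 15) {
  n <- length(times)
  if (n == 0) return(list(bursts = list(), singles = numeric(0)))
  bursts <- list(); singles <- numeric(0)
  run <- times[1]
  for (i in seq_len(n - 1)) {
    if ((times[i + 1] - times[i]) * 1000 <= max_isi) {
      run <- c(run, times[i + 1])
    } else {
      if (length(run) >= 2) bursts[[length(bursts) + 1]] <- run
      else singles <- c(singles, run)
      run <- times[i + 1]
    }
  }
  if (length(run) >= 2) bursts[[length(bursts) + 1]] <- run
  else singles <- c(singles, run)
  list(bursts = bursts, singles = singles)
}

# a burst_segmentation built directly from onset times (one 2-spike burst
# per onset), for tests that need burst streams with known timing
seg_from_onsets <- function(onsets, isi_ms = 5, unit_id = "synth") {
  bursts <- lapply(onsets, function(o)
    list(spike_times = c(o, o + isi_ms / 1000), onset = o, n_spikes = 2L,
         isis = isi_ms))
  structure(list(bursts = bursts, single_spikes = numeric(0),
                 unit_id = unit_id, max_isi = 15),
            class = "burst_segmentation")
}

# burst onsets locked to a 7 Hz rhythm with von Mises phase scatter
locked_onsets <- function(n_cycles, kappa, freq = 7, mu_deg = 0, p_emit = 1) {
  ph <- rvonmises(n_cycles, mu_deg, kappa)
  t <- (seq_len(n_cycles) - 1 + ph / 360) / freq
  sort(t[stats::runif(n_cycles) < p_emit])
}

# random spike train with exponential ISIs (may contain bursts by chance)
random_train <- function(n, rate = 20) {
  cumsum(stats::rexp(n, rate))
}
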