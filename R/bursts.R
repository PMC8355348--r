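#' Segment a spike train into complex spike bursts and single spikes
#'
#' A complex spike burst is a maximal run of two or more consecutive spikes
#' whose inter-spike intervals are all no more than `max_isi` ms (the
#' comparison is inclusive). Every other spike is a single spike. The burst
#' timestamp is the time of its first spike.
#'
#' @param train a [spike_train] (or bare numeric vector of times in s).
#' @param max_isi burst ISI threshold in ms (default 15).
#' @return An object of class `burst_segmentation`: list with `bursts` (a
#'   list, each with `spike_times`, `onset`, `n_spikes`, `isis` in ms),
#'   `single_spikes` (numeric seconds), `spike_burst_id` (per-spike burst
#'   index, `NA` for singles), and `unit_id`.
#' @export
segment_bursts <- function(train, max_isi = 15) {
  if (inherits(train, "spike_train")) {
    times <- train$times; uid <- train$unit_id
  } else {
    times <- as.numeric(train); uid <- "unit"
    if (is.unsorted(times, strictly = TRUE)) stop("spike times must be strictly increasing")
  }
  n <- length(times)
  if (n == 0) {
    return(structure(list(bursts = list(), single_spikes = numeric(0),
                          spike_burst_id = integer(0), unit_id = uid,
                          max_isi = max_isi),
                     class = "burst_segmentation"))
  }
  close_next <- if (n > 1) diff(times) * 1000 <= max_isi else logical(0)
  # spike i is in a burst if joined to its predecessor or successor
  in_burst <- c(close_next, FALSE) | c(FALSE, close_next)
  # a burst member starts a new burst iff it is not linked to its predecessor
  starts <- in_burst & !c(FALSE, close_next)
  burst_id <- rep(NA_integer_, n)
  burst_id[in_burst] <- cumsum(starts)[in_burst]
  bursts <- list()
  if (any(in_burst)) {
    for (b in seq_len(max(burst_id, na.rm = TRUE))) {
      st <- times[which(burst_id == b)]
      bursts[[b]] <- list(spike_times = st, onset = st[1],
                          n_spikes = length(st), isis = diff(st) * 1000)
    }
  }
  structure(list(bursts = bursts, single_spikes = times[!in_burst],
                 spike_burst_id = burst_id, unit_id = uid, max_isi = max_isi),
            class = "burst_segmentation")
}

#' @export
print.burst_segmentation <- function(x, ...) {
  cat(sprintf("<burst_segmentation '%s'> %d bursts, %d single spikes\n",
              x$unit_id, length(x$bursts), length(x$single_spikes)))
  invisible(x)
}

#' Burst onset times of a segmentation
#' @param seg a `burst_segmentation`.
#' @return Numeric vector of burst onset times in seconds.
#' @export
burst_onsets <- function(seg) {
  vapply(seg$bursts, `[[`, numeric(1), "onset")
}

# all spikes emitted within bursts
burst_spike_times <- function(seg) {
  if (!length(seg$bursts)) return(numeric(0))
  sort(unlist(lapply(seg$bursts, `[[`, "spike_times")))
}

#' Burst and single-spike rates of a segmented train
#'
#' @param seg a `burst_segmentation`.
#' @param duration recording duration in seconds (> 0).
#' @return List with `burst_rate`, `single_rate`, `all_rate` (Hz) and
#'   `burst_spike_fraction` (fraction of all spikes emitted within bursts).
#' @export
burst_rate_stats <- function(seg, duration) {
  if (duration <= 0) stop("duration must be > 0")
  n_burst_spikes <- sum(vapply(seg$bursts, `[[`, numeric(1), "n_spikes"))
  n_single <- length(seg$single_spikes)
  n_all <- n_burst_spikes + n_single
  list(burst_rate = length(seg$bursts) / duration,
       single_rate = n_single / duration,
       all_rate = n_all / duration,
       burst_spike_fraction = if (n_all > 0) n_burst_spikes / n_all else 0)
}

#' Population histogram of burst lengths
#'
#' Per cell, the distribution of burst lengths over the bins 2, 3, 4, 5 and
#' >= 6 spikes is normalised to sum 1; the population summary is the median
#' and quartiles of the per-cell probabilities.
#'
#' @param segs list of `burst_segmentation` objects (one per cell).
#' @return List with `per_cell` (cells x bins probability matrix), `median`,
#'   `q25`, `q75` per bin, and the bin labels.
#' @export
burst_length_histogram <- function(segs) {
  bins <- c("2", "3", "4", "5", ">=6")
  rows <- list()
  for (seg in segs) {
    if (!length(seg$bursts)) {
      warning(sprintf("cell '%s' has no bursts: excluded", seg$unit_id))
      next
    }
    len <- vapply(seg$bursts, `[[`, numeric(1), "n_spikes")
    len_bin <- pmin(len, 6)
    counts <- tabulate(len_bin - 1L, nbins = 5L)  # bins 2..6+
    rows[[length(rows) + 1L]] <- counts / sum(counts)
  }
  if (!length(rows)) stop("no bursts in any cell")
  m <- do.call(rbind, rows)
  colnames(m) <- bins
  list(per_cell = m,
       median = apply(m, 2, stats::median),
       q25 = apply(m, 2, stats::quantile, 0.25),
       q75 = apply(m, 2, stats::quantile, 0.75),
       bins = bins)
}

#' Spike-frequency accommodation profile of bursts
#'
#' Pools ISIs over bursts and summarises them by their order within the
#' burst, separately per burst length (triplets, tetraplets, pentaplets),
#' plus the mean ISI per burst length and the accommodation rate: the
#' least-squares slope of ISI against order over the two intervals of
#' 3-spike bursts, in ms per interval.
#'
#' @param segs list of `burst_segmentation` objects.
#' @param max_length largest burst length reported separately (default 5).
#' @return An object of class `accommodation_profile` with
#'   `mean_isi_by_order` (rows = burst length, cols = ISI order; mean ms),
#'   `sem_isi_by_order`, `mean_isi_by_length`, `accommodation_rate` (ms per
#'   interval) and `overall_mean_isi` (ms).
#' @export
accommodation <- function(segs, max_length = 5) {
  all_bursts <- unlist(lapply(segs, `[[`, "bursts"), recursive = FALSE)
  if (!length(all_bursts)) stop("no bursts")
  len <- vapply(all_bursts, `[[`, numeric(1), "n_spikes")
  mean_by_order <- matrix(NA_real_, nrow = max_length - 1L, ncol = max_length - 1L,
                          dimnames = list(length = as.character(3:(max_length + 1))[seq_len(max_length - 1)],
                                          order = as.character(seq_len(max_length - 1))))
  sem_by_order <- mean_by_order
  for (L in 3:max_length) {
    bl <- all_bursts[len == L]
    if (!length(bl)) next
    isis <- do.call(rbind, lapply(bl, `[[`, "isis"))
    mean_by_order[as.character(L), seq_len(L - 1)] <- colMeans(isis)
    sem_by_order[as.character(L), seq_len(L - 1)] <-
      apply(isis, 2, stats::sd) / sqrt(nrow(isis))
  }
  lengths_present <- sort(unique(len))
  mean_by_length <- vapply(lengths_present, function(L)
    mean(unlist(lapply(all_bursts[len == L], `[[`, "isis"))), numeric(1))
  names(mean_by_length) <- lengths_present
  # slope over the two ISI orders of 3-spike bursts
  tri <- all_bursts[len == 3]
  if (length(tri)) {
    isis3 <- do.call(rbind, lapply(tri, `[[`, "isis"))
    m3 <- colMeans(isis3)
    rate <- m3[2] - m3[1]   # least-squares slope over two points
  } else {
    rate <- NA_real_
  }
  structure(list(mean_isi_by_order = mean_by_order,
                 sem_isi_by_order = sem_by_order,
                 mean_isi_by_length = mean_by_length,
                 accommodation_rate = unname(rate),
                 overall_mean_isi = mean(unlist(lapply(all_bursts, `[[`, "isis")))),
            class = "accommodation_profile")
}

#' @export
print.accommodation_profile <- function(x, ...) {
  cat(sprintf("<accommodation_profile> overall mean ISI %.2f ms, rate %+.2f ms/interval\n",
              x$overall_mean_isi, x$accommodation_rate))
  invisible(x)
}

#' Conditional probability of the next event class after a trigger event
#'
#' For each trigger event (burst or single spike), the elapsed silence until
#' the next emitted event is recorded together with that event's class. The
#' default hazard-style estimator reports, per elapsed-time bin, the
#' probability that the next event is of the response class given that the
#' silence reached that bin; `estimator = "histogram"` instead reports the
#' plain next-event time histogram restricted to the response class.
#'
#' @param seg a `burst_segmentation`.
#' @param trigger,response event classes, `"burst"` or `"single"`.
#' @param window analysis window in ms (default 300).
#' @param bin bin width in ms (default 5).
#' @param estimator `"hazard"` (default) or `"histogram"`.
#' @return List with `t` (bin centres, ms), `p` (probability per bin),
#'   `n_triggers` and the estimator used.
#' @export
post_event_conditional <- function(seg, trigger = c("burst", "single"),
                                   response = c("single", "burst"),
                                   window = 300, bin = 5,
                                   estimator = c("hazard", "histogram")) {
  trigger <- match.arg(trigger); response <- match.arg(response)
  estimator <- match.arg(estimator)
  if (window <= bin) stop("window must exceed bin")
  onsets <- burst_onsets(seg)
  # event table: (time, class); burst events are anchored at onset but the
  # silence after a burst starts at its last spike
  ev_t <- c(onsets, seg$single_spikes)
  ev_end <- c(vapply(seg$bursts, function(b) max(b$spike_times), numeric(1)),
              seg$single_spikes)
  ev_cls <- c(rep("burst", length(onsets)), rep("single", length(seg$single_spikes)))
  ord <- order(ev_t)
  ev_t <- ev_t[ord]; ev_end <- ev_end[ord]; ev_cls <- ev_cls[ord]
  trig_idx <- which(ev_cls == trigger)
  trig_idx <- trig_idx[trig_idx < length(ev_t)]
  if (length(trig_idx) < 10) stop("need at least 10 trigger events")
  gap_ms <- (ev_t[trig_idx + 1L] - ev_end[trig_idx]) * 1000
  next_cls <- ev_cls[trig_idx + 1L]
  edges <- seq(0, window, by = bin)
  nb <- length(edges) - 1L
  which_bin <- findInterval(gap_ms, edges, rightmost.closed = TRUE)
  inside <- which_bin >= 1 & which_bin <= nb
  p <- numeric(nb)
  if (estimator == "hazard") {
    for (k in seq_len(nb)) {
      at_risk <- sum(gap_ms >= edges[k])          # silence reached this bin
      hit <- sum(inside & which_bin == k & next_cls == response)
      p[k] <- if (at_risk > 0) hit / at_risk else NA_real_
    }
  } else {
    hits <- tabulate(which_bin[inside & next_cls == response], nbins = nb)
    p <- hits / length(trig_idx)
  }
  list(t = edges[-length(edges)] + bin / 2, p = p,
       n_triggers = length(trig_idx), estimator = estimator)
}
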