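test_that("burst segmentation follows the 15 ms inclusive rule", {
  seg <- segment_bursts(c(0, 0.010, 0.020, 0.100))
  expect_length(seg$bursts, 1)
  expect_equal(seg$bursts[[1]]$onset, 0)
  expect_equal(seg$bursts[[1]]$n_spikes, 3)
  expect_equal(seg$bursts[[1]]$isis, c(10, 10))
  expect_equal(seg$single_spikes, 0.1)

  # an ISI of exactly 15 ms still joins a burst ("no more than")
  seg15 <- segment_bursts(c(0, 0.015))
  expect_length(seg15$bursts, 1)
  seg16 <- segment_bursts(c(0, 0.0151))
  expect_length(seg16$bursts, 0)
  expect_length(seg16$single_spikes, 2)

  empty <- segment_bursts(numeric(0))
  expect_length(empty$bursts, 0)
  expect_length(empty$single_spikes, 0)
})

test_that("segmentation matches the brute-force scanner and conserves spikes", {
  set.seed(101)
  for (rep in 1:1000) {
    n <- sample(0:500, 1)
    times <- random_train(n, rate = runif(1, 5, 60))
    seg <- segment_bursts(times)
    oracle <- brute_force_segment(times)
    expect_length(seg$bursts, length(oracle$bursts))
    expect_equal(seg$single_spikes, oracle$singles)
    if (length(seg$bursts))
      expect_equal(lapply(seg$bursts, `[[`, "spike_times"), oracle$bursts)
    # partition property: every spike in exactly one class
    n_in_bursts <- sum(vapply(seg$bursts, `[[`, numeric(1), "n_spikes"))
    expect_equal(n_in_bursts + length(seg$single_spikes), length(times))
  }
})

test_that("segmentation is invariant under joint time rescaling", {
  set.seed(7)
  times <- random_train(300, rate = 40)
  a <- segment_bursts(times, max_isi = 15)
  b <- segment_bursts(times * 2.5, max_isi = 15 * 2.5)
  expect_length(b$bursts, length(a$bursts))
  if (length(a$bursts))
    expect_equal(vapply(b$bursts, `[[`, numeric(1), "n_spikes"),
                 vapply(a$bursts, `[[`, numeric(1), "n_spikes"))
  for (i in seq_along(a$bursts))
    expect_equal(b$bursts[[i]]$isis, a$bursts[[i]]$isis * 2.5)
})

test_that("burst and single-spike rates are counts over duration", {
  onsets <- seq(1, 56, by = 5)              # 12 bursts
  singles <- seq(0.5, 24, by = 0.5)         # 48 singles
  seg <- seg_from_onsets(onsets)
  seg$single_spikes <- singles
  st <- burst_rate_stats(seg, 60)
  expect_equal(st$burst_rate, 0.2)
  expect_equal(st$single_rate, 0.8)
  expect_equal(st$all_rate, (12 * 2 + 48) / 60)
  expect_equal(st$burst_spike_fraction, 24 / 72)

  st0 <- burst_rate_stats(segment_bursts(numeric(0)), 60)
  expect_equal(st0$all_rate, 0)
  expect_error(burst_rate_stats(seg, 0), "duration")
})

test_that("burst-length histogram normalises per cell and recovers a known pmf", {
  mk <- function(lengths) {
    bursts <- lapply(seq_along(lengths), function(i) {
      L <- lengths[i]
      st <- i + (0:(L - 1)) * 0.005
      list(spike_times = st, onset = st[1], n_spikes = L, isis = diff(st) * 1000)
    })
    structure(list(bursts = bursts, single_spikes = numeric(0), unit_id = "m",
                   max_isi = 15), class = "burst_segmentation")
  }
  h <- burst_length_histogram(list(mk(c(2, 2, 2, 3))))
  expect_equal(unname(h$median[1:2]), c(0.75, 0.25))
  h2 <- burst_length_histogram(list(mk(rep(2, 10))))
  expect_equal(unname(h2$median[1]), 1)

  expect_warning(burst_length_histogram(list(mk(c(2, 3)),
                                             segment_bursts(numeric(0)))),
                 "no bursts")

  # geometric pmf recovery at 1e4 bursts
  set.seed(31)
  pmf <- 0.5^(0:5); pmf <- pmf / sum(pmf)
  lens <- sample(2:7, 1e4, replace = TRUE, prob = pmf)
  h3 <- burst_length_histogram(list(mk(lens)))
  emp <- h3$per_cell[1, ]
  expected <- c(pmf[1:4], sum(pmf[5:6]))
  se <- sqrt(expected * (1 - expected) / 1e4)
  expect_true(all(abs(emp - expected) < 4 * se + 1e-6))
})

test_that("accommodation profile recovers order means and slope", {
  one <- structure(list(bursts = list(list(spike_times = c(0, 0.005, 0.015),
                                           onset = 0, n_spikes = 3,
                                           isis = c(5, 10))),
                        single_spikes = numeric(0), unit_id = "a", max_isi = 15),
                   class = "burst_segmentation")
  prof <- accommodation(list(one))
  expect_equal(unname(prof$mean_isi_by_order["3", 1:2]), c(5, 10))
  expect_equal(prof$accommodation_rate, 5)

  flat <- structure(list(bursts = lapply(1:20, function(i)
    list(spike_times = i + c(0, 0.007, 0.014), onset = i, n_spikes = 3,
         isis = c(7, 7))), single_spikes = numeric(0), unit_id = "f",
    max_isi = 15), class = "burst_segmentation")
  expect_equal(accommodation(list(flat))$accommodation_rate, 0)
  expect_error(accommodation(list(segment_bursts(numeric(0)))), "no bursts")
})

test_that("generator accommodation slope is recovered from simulated bursts", {
  cfg <- synth_config("control", duration = 600, n_cells = 12, seed = 5)
  s <- simulate_session(cfg)
  segs <- lapply(s$units, segment_bursts)
  prof <- accommodation(segs)
  n_bursts <- sum(vapply(segs, function(g) length(g$bursts), numeric(1)))
  expect_gt(n_bursts, 1000)
  expect_lt(abs(prof$accommodation_rate - cfg$isi_slope), 0.2)
})

test_that("post-event conditional localises a constructed response and suppression", {
  # every burst followed by a single spike 82 ms after its last spike
  onsets <- seq(1, 500, by = 1)
  seg <- seg_from_onsets(onsets, isi_ms = 5)
  seg$single_spikes <- onsets + 0.005 + 0.082
  pc <- post_event_conditional(seg, "burst", "single", window = 200, bin = 5)
  before <- pc$p[pc$t < 78]
  expect_true(all(before == 0, na.rm = TRUE))
  expect_equal(pc$p[which(pc$t == 82.5)], 1)
  expect_error(post_event_conditional(seg, window = 4, bin = 5), "window")

  # control preset: post-burst single suppression in the 0-60 ms range
  cfg <- synth_config("control", duration = 600, n_cells = 8, seed = 21)
  s <- simulate_session(cfg)
  curves <- lapply(s$units, function(u)
    post_event_conditional(segment_bursts(u), "burst", "single",
                           estimator = "histogram"))
  p_mat <- do.call(rbind, lapply(curves, `[[`, "p"))
  pop <- colMeans(p_mat)
  tt <- curves[[1]]$t
  early <- mean(pop[tt < 50])
  late <- mean(pop[tt > 60 & tt < 150])
  expect_lt(early, late)
})

test_that("next-event hazard of a sparse Poisson train matches the closed form", {
  set.seed(12)
  lambda <- 0.5                              # sparse: bursts essentially absent
  times <- cumsum(rexp(20000, lambda))
  seg <- segment_bursts(times)
  pc <- post_event_conditional(seg, "single", "single", window = 300, bin = 5,
                               estimator = "hazard")
  # memoryless beyond the 15 ms exclusion created by the burst rule
  expected <- 1 - exp(-lambda * 0.005)
  usable <- pc$t > 20 & pc$t < 200
  expect_lt(abs(mean(pc$p[usable], na.rm = TRUE) - expected), 0.2 * expected)
})
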