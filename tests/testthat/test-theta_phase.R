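make_lfp <- function(f, dur = 60, rate = 1250, amp = 1000) {
  lfp_signal(amp * sin(2 * pi * f * seq(0, dur, by = 1 / rate)), rate = rate)
}

test_that("theta epochs follow the theta/delta power ratio", {
  e8 <- detect_theta_epochs(make_lfp(8))
  expect_equal(nrow(e8$intervals), 1)
  expect_lt(e8$intervals[1, 1], 1.01)
  expect_gt(e8$intervals[1, 2], 59)

  expect_equal(nrow(detect_theta_epochs(make_lfp(2))$intervals), 0)

  # constructed switch: 30 s delta then 30 s theta
  t1 <- seq(0, 30, by = 1 / 1250); t2 <- seq(0, 30, by = 1 / 1250)
  x <- c(1000 * sin(2 * pi * 2 * t1), 1000 * sin(2 * pi * 8 * t2))
  ep <- detect_theta_epochs(lfp_signal(x, 1250))
  expect_equal(nrow(ep$intervals), 1)
  expect_lt(abs(ep$intervals[1, 1] - 30), 1.01)

  expect_error(detect_theta_epochs(lfp_signal(rnorm(100), rate = 10)), "rate")
})

test_that("instantaneous phase uses the trough-zero convention", {
  rate <- 1250
  lfp <- lfp_signal(cos(2 * pi * 8 * seq(0, 10, by = 1 / rate)), rate)
  ph <- instantaneous_phase(lfp)
  expect_lt(abs(ph$phase[1] - 180), 2)                       # peak at t = 0
  tr <- ph$phase[round(rate / 16) + 1]                       # trough at 1/16 s
  expect_lt(min(tr, 360 - tr), 2)
  # phase advances 360 deg per cycle
  mid <- 200:12000
  step <- diff(ph$phase[mid]) %% 360
  expect_lt(abs(mean(step) * rate - 8 * 360) / (8 * 360), 0.01)
  expect_error(instantaneous_phase(lfp_signal(rep(0, 1000), rate)), "zero")
})

test_that("phase zero-crossings track signal minima through a chirp", {
  rate <- 1250
  t <- seq(0, 20, by = 1 / rate)
  finst <- 6 + 3 * t / 20                                    # 6 -> 9 Hz
  phase_true <- 2 * pi * cumsum(finst) / rate
  x <- -cos(phase_true)                                      # minima at 2k*pi
  ph <- instantaneous_phase(lfp_signal(1000 * x, rate))
  # detected trough times: where wrapped phase crosses 0 (360 -> 0)
  wrapped <- ph$phase
  cross <- which(diff(wrapped) < -180) + 1L
  cross <- cross[cross > rate & cross < length(t) - rate]
  true_min <- which(diff(sign(diff(x))) > 0) + 1L
  for (ci in cross[seq(1, length(cross), by = 7)]) {
    expect_lte(min(abs(true_min - ci)), 1)
  }
})

test_that("phase histogram concentrates, corrects occupancy and recovers von Mises locking", {
  rate <- 1250; dur <- 200
  t <- seq(0, dur, by = 1 / rate)
  lfp <- lfp_signal(1000 * -cos(2 * pi * 7 * t), rate)
  ph <- instantaneous_phase(lfp)

  # events planted at 95 deg (inside a bin) of every 20th cycle
  cyc <- seq(20, dur * 7 - 20, by = 20)
  ev95 <- (cyc + 95 / 360) / 7
  h <- phase_histogram(ev95, ph, NULL, smooth_sd_bins = 0)
  expect_equal(sum(h$probability), 1)
  expect_gt(h$probability_raw[findInterval(95, h$bin_edges)], 0.99)
  expect_lt(abs(h$mean_phase - 95), 3)
  expect_gt(h$R, 0.99)

  # von Mises events at mu = 344 deg recover the mean within 10 deg
  set.seed(9)
  mu <- 344
  vm <- rvonmises(500, mu, 1)
  cyc2 <- sample(10:(dur * 7 - 10), 500, replace = TRUE)
  ev <- sort((cyc2 + vm / 360) / 7)
  h2 <- phase_histogram(ev, ph, NULL)
  d <- abs(h2$mean_phase - mu); d <- min(d, 360 - d)
  expect_lt(d, 10)
  expect_lt(h2$rayleigh_p, 1e-6)
})

test_that("occupancy correction flattens time-Poisson events on a distorted phase", {
  # phase series with nonuniform within-cycle speed: occupancy is skewed
  rate <- 1250; dur <- 400
  t <- seq(0, dur, by = 1 / rate)
  cycles <- 7 * t + 0.1 * sin(2 * pi * 7 * t)   # monotone, distorted
  ph <- structure(list(t = t, phase = (cycles * 360) %% 360, rate = rate),
                  class = "phase_series")
  occ <- tabulate(findInterval(ph$phase, seq(0, 360, length.out = 21),
                               rightmost.closed = TRUE), 20) / length(ph$phase)
  expect_gt(max(occ) / min(occ), 1.5)        # distortion is real

  set.seed(14)
  ev <- sort(runif(1e4, 1, dur - 1))
  h <- phase_histogram(ev, ph, NULL, smooth_sd_bins = 0)
  expect_equal(sum(h$probability_raw), 1)
  # flat within chi-square goodness of fit at the corrected scale
  chi <- sum((h$probability_raw - 0.05)^2) * 1e4 / 0.05
  expect_gt(stats::pchisq(chi, df = 19, lower.tail = FALSE), 0.01)
})

test_that("Rayleigh statistics behave at the extremes and under the null", {
  r1 <- rayleigh_test(rep(77, 100))
  expect_equal(r1$R, 1)
  expect_lt(r1$p, 1e-30)

  r0 <- rayleigh_test(seq(0, 360 - 3.6, by = 3.6))
  expect_lt(r0$R, 1e-10)
  expect_gt(r0$p, 0.99)
  expect_error(rayleigh_test(c(1, 2, 3)), "n >= 5")

  # power grows with concentration
  set.seed(3)
  power <- vapply(c(0.2, 0.5, 1, 2), function(k)
    mean(replicate(200, rayleigh_test(rvonmises(50, 120, k))$p < 0.05)),
    numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[4], 0.99)
})

test_that("squared histogram differences localise where histograms differ", {
  rate <- 1250
  lfp <- lfp_signal(1000 * -cos(2 * pi * 7 * seq(0, 100, by = 1 / rate)), rate)
  ph <- instantaneous_phase(lfp)
  ev <- sort((seq(10, 600, by = 2) + 90 / 360) / 7)
  h1 <- phase_histogram(ev, ph, NULL, smooth_sd_bins = 0)
  expect_equal(phase_histogram_squared_difference(h1, h1), rep(0, 20))

  ev2 <- sort((seq(10, 600, by = 2) + 270 / 360) / 7)
  h2 <- phase_histogram(ev2, ph, NULL, smooth_sd_bins = 0)
  d <- phase_histogram_squared_difference(h1, h2)
  big <- order(-d)[1:2]
  expect_setequal(findInterval(c(90, 270), h1$bin_edges), big)
})

test_that("Silverman bootstrap separates unimodal from bimodal phase samples", {
  set.seed(8)
  uni_p <- vapply(1:3, function(s)
    silverman_modality_test(rvonmises(500, 90, 2), n_boot = 200, seed = s)$p,
    numeric(1))
  expect_gt(mean(uni_p > 0.1), 0.5)

  bim <- c(rvonmises(250, 0, 8), rvonmises(250, 180, 8))
  bim_p <- vapply(1:3, function(s)
    silverman_modality_test(bim, n_boot = 200, seed = s)$p, numeric(1))
  expect_gt(mean(bim_p < 0.05), 0.5)

  expect_equal(silverman_modality_test(rep(42, 25), n_boot = 200, seed = 1)$p, 1)
})

test_that("multitaper PSD localises tones and scales power correctly", {
  rate <- 1250
  t <- seq(0, 60, by = 1 / rate)
  psd <- multitaper_psd(lfp_signal(1000 * sin(2 * pi * 7 * t), rate))
  expect_lt(abs(psd$freq[which.max(psd$power)] - 7), rate / 1024 + 1e-9)

  # white noise: band power proportional to bandwidth
  set.seed(2)
  wn <- multitaper_psd(rnorm(120 * rate), rate = rate)
  b1 <- band_power(wn, 100, 200); b2 <- band_power(wn, 200, 400)
  expect_lt(abs(b2 / b1 - 2), 0.1)

  # 2:1 amplitude tones give a 4:1 power ratio
  two <- multitaper_psd(lfp_signal(2 * sin(2 * pi * 7 * t) +
                                   sin(2 * pi * 30 * t), rate))
  p7 <- band_power(two, 6, 8); p30 <- band_power(two, 29, 31)
  expect_lt(abs(p7 / p30 - 4) / 4, 0.1)
  expect_error(multitaper_psd(rnorm(500), rate = 1250), "shorter")
})
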