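# occupancy map with uniform dwell on an arbitrary grid, for closed-form tests
flat_occupancy <- function(nr, nc, secs = 1, pixel = 2) {
  structure(list(seconds = matrix(secs, nr, nc), included = TRUE,
                 enclosure = enclosure("arena", width = nc * pixel,
                                       height = nr * pixel, pixel = pixel),
                 total_time = nr * nc * secs),
            class = "occupancy_map")
}

as_rate_map <- function(rates, occ, class = "all") {
  structure(list(rates = rates, counts = rates * occ$seconds,
                 peak_rate = max(rates, na.rm = TRUE),
                 n_spikes = sum(rates * occ$seconds, na.rm = TRUE),
                 spike_class = class, occupancy = occ),
            class = "rate_map")
}

test_that("occupancy accumulates dwell time and excludes immobility", {
  t <- seq(0, 60, by = 0.04)
  # dwell in one spot but labelled running via an artificial state
  tr <- compute_speed(position_track(t, rep(11, length(t)), rep(11, length(t))))
  occ <- occupancy_map(tr, NULL, enclosure("arena", width = 20, height = 20))
  expect_lt(abs(sum(occ$seconds) - 60), 0.1)
  expect_equal(sum(occ$seconds > 0), 1)
  expect_lt(abs(occ$seconds[6, 6] - 60), 0.1)

  # stationary animal: every frame is immobile, map empty
  st <- behavioral_state(tr)
  expect_warning(occ2 <- occupancy_map(tr, st,
                                       enclosure("arena", width = 20, height = 20)),
                 "insufficient")
  expect_equal(sum(occ2$seconds), 0)
})

test_that("a uniform sweep yields near-uniform occupancy", {
  # boustrophedon sweep visiting every pixel centre for equal time
  px <- seq(1, 19, by = 2)
  path <- do.call(rbind, lapply(seq_along(px), function(i) {
    ys <- rep(seq(1, 19, by = 2), each = 8)
    if (i %% 2 == 0) ys <- rev(ys)
    cbind(px[i], ys)
  }))
  n <- nrow(path)
  tr <- compute_speed(position_track(seq(0, by = 0.04, length.out = n),
                                     path[, 1], path[, 2]))
  occ <- occupancy_map(tr, NULL, enclosure("arena", width = 20, height = 20))
  cv <- sd(occ$seconds) / mean(occ$seconds)
  expect_lt(cv, 0.10)
})

test_that("rate maps divide counts by dwell time", {
  t <- seq(0, 50, by = 0.04)
  tr <- compute_speed(position_track(t, rep(5, length(t)), rep(5, length(t))))
  occ <- occupancy_map(tr, NULL, enclosure("arena", width = 10, height = 10))
  spikes <- seq(0.25, 50, by = 0.5)          # 100 spikes in 50 s
  rm <- rate_map(spikes, occ, tr)
  expect_lt(abs(rm$rates[3, 3] - 2), 0.01)
  expect_equal(rm$n_spikes, 100)

  rm0 <- rate_map(numeric(0), occ, tr)
  expect_equal(rm0$peak_rate, 0)
})

test_that("field detection finds connected components above 1 Hz", {
  occ <- flat_occupancy(10, 10)
  rates <- matrix(0, 10, 10); rates[5, 5] <- 200
  one <- detect_fields(as_rate_map(rates, occ), min_pixels = 1)
  expect_length(one, 1)
  expect_equal(one[[1]]$size_cm2, 4)
  expect_length(detect_fields(as_rate_map(rates, occ), min_pixels = 2), 0)

  rates2 <- matrix(0, 10, 10)
  rates2[2:3, 2:3] <- 5; rates2[8:9, 8:9] <- 3
  two <- detect_fields(as_rate_map(rates2, occ))
  expect_length(two, 2)

  expect_length(detect_fields(as_rate_map(matrix(0.5, 10, 10), occ)), 0)
})

test_that("Gaussian field area matches the analytic 1 Hz contour", {
  occ <- flat_occupancy(30, 30, pixel = 2)
  A <- 8; sig <- 6
  cx <- 30; cy <- 30                          # cm
  xs <- (col(occ$seconds) - 0.5) * 2; ys <- (row(occ$seconds) - 0.5) * 2
  rates <- A * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sig^2))
  f <- detect_fields(as_rate_map(rates, occ))
  expect_length(f, 1)
  analytic <- pi * 2 * sig^2 * log(A)        # area where rate > 1
  # discretisation error: at most the pixel ring crossing the contour
  r_c <- sig * sqrt(2 * log(A))
  ring <- 2 * pi * r_c * 2 * sqrt(2) * 2
  expect_lt(abs(f[[1]]$size_cm2 - analytic), ring)
})

test_that("sparsity and information match closed forms", {
  occ <- flat_occupancy(10, 10)
  uni <- field_statistics(as_rate_map(matrix(2, 10, 10), occ))
  expect_equal(uni$sparsity, 1)
  expect_equal(uni$information_density, 0)

  half <- matrix(0, 10, 10); half[, 1:5] <- 2
  hs <- field_statistics(as_rate_map(half, occ))
  expect_equal(hs$sparsity, 0.5)
  expect_equal(hs$information_density, 1)

  one <- matrix(0, 10, 10); one[4, 7] <- 100
  os <- field_statistics(as_rate_map(one, occ))
  expect_equal(os$sparsity, 0.01)
  expect_equal(os$information_density, log2(100))

  expect_error(field_statistics(as_rate_map(matrix(0, 10, 10), occ)), "zero")
})

test_that("sparsity and information are invariant to occupancy rescaling", {
  set.seed(33)
  occ1 <- flat_occupancy(8, 8, secs = 1)
  occ5 <- flat_occupancy(8, 8, secs = 5)
  rates <- matrix(rexp(64, 1), 8, 8)
  s1 <- field_statistics(as_rate_map(rates, occ1))
  s5 <- field_statistics(as_rate_map(rates, occ5))
  expect_equal(s1$sparsity, s5$sparsity)
  expect_equal(s1$information_density, s5$information_density)
})

test_that("map correlation flags degenerate cases and matches the Fisher null", {
  occ <- flat_occupancy(25, 20)
  set.seed(41)
  a <- as_rate_map(matrix(rexp(500), 25, 20), occ)
  dbl <- as_rate_map(a$rates * 2, occ)
  mc <- map_correlation(a, dbl)
  expect_equal(mc$flag, "perfect")
  expect_equal(mc$z, atanh(0.999999))

  zs <- replicate(200, {
    m1 <- as_rate_map(matrix(rexp(500), 25, 20), occ)
    m2 <- as_rate_map(matrix(rexp(500), 25, 20), occ)
    map_correlation(m1, m2)$z
  })
  expect_lt(abs(mean(zs)), 3 / sqrt(500 - 3) / sqrt(200) * 5)
  expect_lt(sd(zs), 1.5 / sqrt(500 - 3))
  expect_error(map_correlation(a, as_rate_map(matrix(1, 25, 20), occ)),
               "constant")
})

test_that("simulated place cell recovers field peak, location and class structure", {
  cfg <- synth_config("control", duration = 600, n_cells = 1, seed = 13,
                      field_peak_gain = 8)
  s <- simulate_session(cfg)
  truth <- attr(s$units[[1]], "truth")
  st <- behavioral_state(s$position)
  occ <- occupancy_map(s$position, st, enclosure("arena"))
  seg <- segment_bursts(s$units[[1]])
  res <- field_size_by_class(seg, occ, s$position)

  # spike-count conservation across classes
  expect_equal(res$maps$burst$n_spikes + res$maps$single$n_spikes,
               res$maps$all$n_spikes)
  expect_equal(sum(res$maps$all$counts), res$maps$all$n_spikes)
  expect_equal(res$size_fraction[["all"]], 1)

  # peak pixel near the true field centre
  pk <- which(res$maps$all$rates == res$maps$all$peak_rate, arr.ind = TRUE)[1, ]
  pk_xy <- c((pk[2] - 0.5) * 2, (pk[1] - 0.5) * 2)
  expect_lt(sqrt(sum((pk_xy - truth$field_center)^2)), 6)

  mc <- map_correlation(res$maps$burst, res$maps$single)
  expect_gt(mc$z, 0)
})
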