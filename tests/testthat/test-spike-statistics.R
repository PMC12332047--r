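test_that("spike trains validate their invariants", {
  expect_error(spike_train(c(2, 1), 5), class = "tn_input_error")
  expect_error(spike_train(c(1, 1), 5), class = "tn_input_error")
  expect_error(spike_train(c(1, 6), 5), class = "tn_input_error")
  st <- spike_train(c(1, 2, 3), 5)
  expect_equal(isi(st), c(1, 1))
})

test_that("CV1 and CV2 reproduce closed-form cases", {
  periodic <- spike_train(seq(1, 50), 51)
  expect_equal(cv1(periodic), 0)
  expect_equal(cv2(periodic), 0)
  # alternating ISIs 1, 3: mean 2, deviations +-1 -> CV1 = 0.5; every
  # consecutive pair gives 2 * 2 / 4 = 1 -> CV2 = 1
  alt <- spike_train(c(0, cumsum(rep(c(1, 3), 50))),
                     sum(rep(c(1, 3), 50)) + 1)
  expect_equal(cv1(alt), 0.5, tolerance = 1e-12)
  expect_equal(cv2(alt), 1, tolerance = 1e-12)
  # insufficient data
  expect_error(cv1(spike_train(c(1, 2, 3), 4)),
               class = "tn_insufficient_data")
  expect_error(cv2(spike_train(c(1, 2), 4)),
               class = "tn_insufficient_data")
  # sample vs population convention
  expect_gt(cv1(alt, type = "sample"), cv1(alt))
})

test_that("CV1 and CV2 are invariant to uniform time rescaling", {
  set.seed(1)
  ts <- cumsum(rexp(500))
  a <- spike_train(ts, max(ts) + 1)
  b <- spike_train(ts * 7.3, (max(ts) + 1) * 7.3)
  expect_equal(cv1(a), cv1(b), tolerance = 1e-12)
  expect_equal(cv2(a), cv2(b), tolerance = 1e-12)
})

test_that("CV2 stays below 2 on adversarial alternating trains", {
  set.seed(2)
  for (ratio in c(10, 1e3, 1e6)) {
    isis <- rep(c(1, ratio), 60)
    st <- spike_train(cumsum(isis), sum(isis) + 1)
    expect_lt(cv2(st), 2)
    expect_gte(cv2(st), 0)
  }
})

test_that("spike detection recovers constructed pulse fixtures", {
  fx <- generate_trace_with_spikes(c(1, 3, 5, 7, 9), duration = 10,
                                   dt = 0.005, amplitude = 1,
                                   pulse_width = 0.05)
  st <- detect_spikes(fx$trace)
  expect_length(st$timestamps, 5L)
  expect_true(all(abs(st$timestamps - fx$truth$timestamps) <= 0.01))
  # all-baseline trace -> empty train
  flat <- data.frame(t = seq(0, 10, 0.01), I = rep(0.3, 1001))
  expect_length(detect_spikes(flat)$timestamps, 0L)
  # pure noise -> empty train at default threshold
  noise <- generate_trace_with_spikes(numeric(0), duration = 10,
                                      dt = 0.005, noise_sd = 0.2,
                                      seed = 3)
  expect_length(detect_spikes(noise$trace)$timestamps, 0L)
  # non-finite samples are rejected
  bad <- data.frame(t = c(0, 1, 2), I = c(0, NA, 1))
  expect_error(detect_spikes(bad), class = "tn_input_error")
})

test_that("close detections merge to the taller peak", {
  tt <- seq(0, 4, by = 0.005)
  y <- 0.6 * exp(-(tt - 1.95)^2 / (2 * 0.03^2)) +
       1.0 * exp(-(tt - 2.05)^2 / (2 * 0.03^2))
  st <- detect_spikes(data.frame(t = tt, I = y), min_separation = 0.3)
  expect_length(st$timestamps, 1L)
  expect_equal(st$timestamps, 2.05, tolerance = 0.01)
})

test_that("detector achieves perfect recall and precision at SNR 10", {
  spikes <- seq(2, 399, by = 4)[1:100]
  fx <- generate_trace_with_spikes(spikes, duration = 402, dt = 0.01,
                                   amplitude = 1, pulse_width = 0.06,
                                   noise_sd = 0.1, seed = 9)
  st <- detect_spikes(fx$trace, min_separation = 0.5)
  matched <- vapply(spikes, function(s) {
    any(abs(st$timestamps - s) < 0.2)
  }, logical(1))
  expect_true(all(matched))                      # recall = 1
  expect_equal(length(st$timestamps), 100L)      # precision = 1
})

test_that("Welch spectra localise tones and conserve power", {
  fs <- 100
  tt <- seq(0, 80, by = 1 / fs)
  tone <- sin(2 * pi * 5 * tt)
  sp <- psd(data.frame(t = tt, I = tone))
  expect_equal(sp$frequency[which.max(sp$power)], 5, tolerance = 0.1)
  # white noise: flat spectrum, total power = variance within 5%
  set.seed(4)
  noise <- rnorm(2^15)
  spn <- psd(noise, fs = 1, segment_length = 1024L)
  df <- spn$frequency[2] - spn$frequency[1]
  expect_equal(sum(spn$power) * df, var(noise), tolerance = 0.05)
  lo <- mean(spn$power[spn$frequency < 0.2])
  hi <- mean(spn$power[spn$frequency > 0.3])
  expect_equal(lo / hi, 1, tolerance = 0.2)
  # a periodic pulse train shows the fundamental and harmonics
  fx <- generate_trace_with_spikes(seq(1, 79, by = 1), duration = 80,
                                   dt = 1 / fs, pulse_width = 0.03)
  spp <- psd(fx$trace, segment_length = 2048L)
  fund <- spp$power[which.min(abs(spp$frequency - 1))]
  second <- spp$power[which.min(abs(spp$frequency - 2))]
  floor_pow <- median(spp$power)
  expect_gt(fund, 10 * floor_pow)
  expect_gt(second, 10 * floor_pow)
  expect_error(psd(noise, fs = 1, segment_length = 2^16),
               class = "tn_config_error")
})

test_that("2-D ISI histograms track construction", {
  t_p <- c(0.5, 1, 2)
  trains <- lapply(t_p, function(p) {
    spike_train(seq(p, 200, by = p), 201)
  })
  m <- isi_histogram_2d(trains, t_p, n_bins = 64)
  expect_equal(m$mode$isi_mode, t_p, tolerance = 0.05)
  expect_equal(colSums(m$map), rep(1, 3), tolerance = 1e-12)
  # period-independent Poisson trains give a flat mode curve
  pois <- lapply(1:3, function(s) {
    generate_train("poisson", duration = 10000, seed = s, rate = 1)
  })
  mp <- isi_histogram_2d(pois, t_p, n_bins = 24)
  expect_lt(max(mp$mode$isi_mode) / min(mp$mode$isi_mode), 3)
})

test_that("preferred period interpolates the rate maximum", {
  # single nonzero-rate condition
  r1 <- rate_vs_period(rates = data.frame(t_p = c(1, 2, 3),
                                          rate = c(0, 2, 0)))
  expect_equal(r1$preferred$t_p_star, 2, tolerance = 0.2)
  # symmetric parabola: interpolated maximum at the symmetry centre
  tp <- seq(0.5, 1.5, by = 0.25)
  rate <- 5 - (tp - 1.05)^2 * 10
  r2 <- rate_vs_period(rates = data.frame(t_p = tp, rate = rate))
  expect_equal(r2$preferred$t_p_star, 1.05, tolerance = 1e-8)
  # all-zero rates flagged
  r3 <- rate_vs_period(rates = data.frame(t_p = tp, rate = 0 * tp))
  expect_true(r3$preferred$flagged)
})

test_that("CV maps mask undersampled cells", {
  tab <- data.frame(V_ext = c(1, 1, 2, 2), R_ext = c(1, 2, 1, 2),
                    cv1 = c(0.1, 0.2, 1.5, 1.0),
                    cv2 = c(0.1, 0.3, 1.2, 0.9),
                    n_isi = c(100, 2, 50, 80))
  m <- cv_map(tab)
  expect_true(is.na(m$cv1["2", "1"]))
  expect_equal(m$cv1["1", "1"], 0.1)
  expect_equal(m$cv2["2", "2"], 0.9)
  expect_error(cv_map(tab[, -1]), class = "tn_format_error")
})

test_that("hull coverage equals the brute-force oracle", {
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  inside <- cbind(runif(10, 0.2, 0.8), runif(10, 0.2, 0.8))
  expect_equal(hull_coverage(inside, square), 1)
  outside <- cbind(runif(10, 2, 3), runif(10, 2, 3))
  expect_equal(hull_coverage(outside, square), 0)
  set.seed(5)
  for (rep in 1:6) {
    cloud <- cbind(rnorm(25), rnorm(25))
    refpts <- cbind(rnorm(40, sd = 1.3), rnorm(40, sd = 1.3))
    expect_equal(hull_coverage(refpts, cloud),
                 oracle_hull_coverage(refpts, cloud))
  }
  collinear <- cbind(1:5, 2 * (1:5))
  expect_error(hull_coverage(inside, collinear),
               class = "tn_degenerate_hull")
})

test_that("burst segmentation splits trains at long gaps", {
  periodic <- spike_train(seq(1, 20), 21)
  one <- segment_bursts(periodic, isi_threshold = 2)
  expect_equal(nrow(one$bursts), 1L)
  expect_equal(one$bursts$n_spikes, 20L)
  # threshold below every ISI: every spike its own burst
  singles <- segment_bursts(periodic, isi_threshold = 0.5)
  expect_equal(nrow(singles$bursts), 20L)
  expect_true(all(singles$bursts$n_spikes == 1L))
  # constructed two-state train recovers the programmed burst count
  bursts <- lapply(seq(0, 90, by = 10), function(t0) t0 + seq(0, 2, 0.5))
  ts <- unlist(bursts)
  seg <- segment_bursts(spike_train(ts, 100), isi_threshold = 4)
  expect_equal(nrow(seg$bursts), 10L)
  expect_true(all(seg$bursts$n_spikes == 5L))
  expect_equal(length(seg$inter_train_intervals), 9L)
  expect_true(all(seg$inter_train_intervals >= 4))
})

test_that("spike trains round-trip through the timestamp CSV format", {
  st <- spike_train(c(0.5, 1.25, 3), 5)
  path <- tempfile(fileext = ".csv")
  write_spike_train(st, path)
  back <- read_spike_train(path, duration = 5)
  expect_equal(back$timestamps, st$timestamps)
  # non-monotone files are rejected
  write.csv(data.frame(timestamp = c(1, 0.5)), path, row.names = FALSE)
  expect_error(read_spike_train(path), class = "tn_format_error")
  write.csv(data.frame(time = 1:3), path, row.names = FALSE)
  expect_error(read_spike_train(path), class = "tn_format_error")
  unlink(path)
})
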