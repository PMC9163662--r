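test_that("noise-free raw recording is zero except the scheduled waveforms", {
  wf <- spike_waveform(10000, amplitude = 50)
  g <- gen_raw_recording(list(E1 = 1.0), waveform = wf, noise_sd = 0,
                         fs = 10000, duration = 3, seed = 1)
  x <- g$recording$samples[, "E1"]
  i0 <- 10000 + 1   # t = 1.0 s at 10 kHz, 1-based
  expect_equal(x[i0:(i0 + length(wf) - 1)], wf)
  expect_true(all(x[-(i0:(i0 + length(wf) - 1))] == 0))
  expect_equal(min(x), -50)
  expect_equal(g$truth$true_spike_times$E1, 1.0)
})

test_that("raw-recording noise has the requested SD and seeds reproduce bit-identically", {
  g1 <- gen_raw_recording(list(E1 = numeric(0), E2 = numeric(0)),
                          noise_sd = 5, fs = 10000, duration = 240, seed = 11)
  sds <- apply(g1$recording$samples, 2, sd)
  # sample SD concentrates as sd/sqrt(2n); 2% is dozens of SEs at n = 2.4e6
  expect_true(all(abs(sds - 5) / 5 < 0.02))
  g2 <- gen_raw_recording(list(E1 = numeric(0), E2 = numeric(0)),
                          noise_sd = 5, fs = 10000, duration = 240, seed = 11)
  expect_identical(g1$recording$samples, g2$recording$samples)
})

test_that("raw-recording schedule outside the recording is rejected naming the electrode", {
  expect_error(
    gen_raw_recording(list(E1 = 1, E2 = 5.2), noise_sd = 0, duration = 5,
                      seed = 1),
    "electrode E2.*5\\.2")
})

test_that("spike-train generator matches Poisson count statistics", {
  g <- gen_spike_trains(60, background_rate = 0, duration = 240, seed = 1)
  expect_true(all(lengths(g$trains$trains) == 0))

  total <- n_spikes(gen_spike_trains(60, 5, duration = 240, seed = 2)$trains)
  expect_lt(abs(total - 72000), 4 * sqrt(72000))

  # Poisson mean/variance over many seeds at small scale
  counts <- vapply(1:100, function(s)
    n_spikes(gen_spike_trains(5, 2, duration = 20, seed = s)$trains),
    numeric(1))
  mu <- 5 * 2 * 20
  expect_lt(abs(mean(counts) - mu), 4 * sqrt(mu / 100))
  expect_lt(abs(var(counts) - mu), 5 * mu * sqrt(2 / 99))
})

test_that("planted burst epochs concentrate spikes on the chosen electrodes", {
  b <- burst_spec(10, 0.5, rate_multiplier = 40, participation = 0.8)
  g <- gen_spike_trains(60, 5, bursts = list(b), duration = 240, seed = 3)
  chosen <- g$truth$true_burst_epochs$participants[[1]]
  expect_length(chosen, 48)
  in_epoch <- vapply(g$trains$trains, function(t)
    sum(t >= 10 & t < 10.5), numeric(1))
  expect_gte(sum(in_epoch[chosen]) / sum(in_epoch), 0.8)
})

test_that("overlapping burst specs are rejected", {
  expect_error(
    gen_spike_trains(10, 2, bursts = list(burst_spec(10, 1, 20, 0.5),
                                          burst_spec(10.5, 1, 20, 0.5)),
                     duration = 60, seed = 1),
    "overlap")
  expect_error(burst_spec(-1, 1, 20, 0.5), "start_s")
  expect_error(burst_spec(0, 1, 0.5, 0.5), "rate_multiplier")
})

test_that("contraction generator honours rates, refractory and determinism", {
  g0 <- gen_contraction_series(rate_pre = 12.4, rate_post = 0, seed = 4)
  expect_equal(sum(g0$series$events$window == "post"), 0)

  g1 <- gen_contraction_series(seed = 9)
  g2 <- gen_contraction_series(seed = 9)
  expect_identical(g1$series$events, g2$series$events)

  gaps <- diff(g1$series$events$time_s[g1$series$events$window == "pre"])
  expect_true(all(gaps >= 1))
  expect_error(gen_contraction_series(pre_window = -1, seed = 1), "window")
})

test_that("mean percent reduction over seeds matches the renewal-process oracle", {
  # frozen oracle value: mean of 100*(1 - post/pre) for refractory-thinned
  # Poisson counts (gaps refractory + Exp(rate)), rates 12.4 and 1.1 per
  # minute over 600 s, estimated from 2e5 independent renewal draws
  oracle_mean <- 89.40
  red <- vapply(1:200, function(s) {
    g <- gen_contraction_series(12.4, 1.1, 600, 600, 1, seed = s)
    percent_reduction(count_window(g$series, "pre"),
                      count_window(g$series, "post"))
  }, numeric(1))
  se <- sd(red) / sqrt(length(red))
  expect_lt(abs(mean(red) - oracle_mean), 3 * se)
})

test_that("generated event times stay inside their windows and are sorted", {
  for (s in 1:20) {
    g <- gen_spike_trains(8, 3, bursts = list(burst_spec(2, 0.5, 30, 0.5)),
                          duration = 20, seed = s)
    for (t in g$trains$trains) {
      expect_true(!is.unsorted(t, strictly = TRUE))
      if (length(t)) expect_true(min(t) >= 0 && max(t) <= 20)
    }
    gc <- gen_contraction_series(10, 2, 300, 300, 1, seed = s)
    for (w in c("pre", "post")) {
      t <- gc$series$events$time_s[gc$series$events$window == w]
      expect_true(!is.unsorted(t, strictly = TRUE))
      if (length(t)) expect_true(min(t) >= 0 && max(t) < 300)
    }
  }
})
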