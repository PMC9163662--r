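trains_fixture <- function(trains, duration) spike_train_set(trains, duration)

test_that("network firing rate is total spikes over duration", {
  expect_equal(network_firing_rate(
    trains_fixture(list(E1 = numeric(0), E2 = numeric(0)), 240)), 0)
  t1 <- trains_fixture(list(E1 = seq(0.1, 240, length.out = 400),
                            E2 = seq(0.2, 239, length.out = 200)), 240)
  expect_equal(network_firing_rate(t1), 600 / 240)

  total <- n_spikes(gen_spike_trains(50, 2, duration = 240, seed = 5)$trains)
  expect_lt(abs(total / 240 - 100), 4 * sqrt(100 * 240) / 240)
})

test_that("active-electrode rule is inclusive at the threshold", {
  tr <- trains_fixture(list(A = numeric(0),
                            B = seq(5, 235, length.out = 24),
                            C = c(1, 2)), 240)
  expect_identical(active_electrodes(trains_fixture(
    list(A = numeric(0), B = numeric(0)), 240)), character(0))
  expect_identical(active_electrodes(tr, 0.1), "B")   # 24/240 = 0.1 exactly
  expect_identical(active_electrodes(tr, 0), c("A", "B", "C"))
})

test_that("spike binning uses half-open 50-ms bins and conserves counts", {
  tr <- trains_fixture(list(E1 = c(0.049, 0.050, 0.3), E2 = c(0.050)), 1)
  h <- bin_spike_counts(tr, 0.05)
  expect_equal(h$n_bins, 20)
  expect_equal(h$counts[1], 1)        # 0.049 in bin 0
  expect_equal(h$counts[2], 2)        # both 0.050 spikes in bin 1
  expect_equal(sum(h$counts), 4)
  expect_true(h$flags["E1", 1] && h$flags["E1", 2] && !h$flags["E2", 1])

  g <- gen_spike_trains(10, 4, duration = 30, seed = 6)
  h2 <- bin_spike_counts(g$trains)
  expect_equal(sum(h2$counts), n_spikes(g$trains))
})

test_that("constant histograms produce no bursts under the strict threshold", {
  ids <- paste0("E", 1:4)
  flags <- matrix(TRUE, 4, 50, dimnames = list(ids, NULL))
  h <- make_histogram(rep(3L, 50), flags)
  b <- detect_network_bursts(h, ids)
  expect_equal(n_bursts(b), 0)
})

test_that("a planted 3-bin epoch is detected as one merged burst", {
  ids <- paste0("E", 1:60)
  counts <- rep(1L, 100)
  counts[40:42] <- 100L
  flags <- matrix(FALSE, 60, 100, dimnames = list(ids, NULL))
  flags[sample(60, 10), counts == 1L] <- TRUE
  flags[1:48, 40:42] <- TRUE
  h <- make_histogram(counts, flags)
  b <- detect_network_bursts(h, ids)
  expect_equal(n_bursts(b), 1)
  expect_equal(b$bursts$start_s, 39 * 0.05)
  expect_equal(b$bursts$end_s, 42 * 0.05)
  expect_equal(b$bursts$spike_count, 300)
  expect_setequal(b$participants[[1]],
                  unique(c(ids[1:48], ids[rowSums(flags[, 40:42]) > 0])))
})

test_that("high-count bins with low participation are pruned", {
  ids <- paste0("E", 1:10)
  counts <- rep(1L, 80)
  counts[30] <- 200L
  flags <- matrix(FALSE, 10, 80, dimnames = list(ids, NULL))
  flags[, counts >= 1] <- TRUE
  flags[, 30] <- c(TRUE, rep(FALSE, 9))   # 10% of active electrodes
  h <- make_histogram(counts, flags)
  expect_equal(n_bursts(detect_network_bursts(h, ids)), 0)
  # at exactly 20% participation the bin survives ("fewer than 20%" prunes)
  flags[, 30] <- c(TRUE, TRUE, rep(FALSE, 8))
  h2 <- make_histogram(counts, flags)
  expect_equal(n_bursts(detect_network_bursts(h2, ids)), 1)
})

test_that("an empty active set prunes every candidate bin with a warning", {
  ids <- paste0("E", 1:5)
  counts <- rep(0L, 60); counts[10] <- 50L
  flags <- matrix(FALSE, 5, 60, dimnames = list(ids, NULL))
  flags[, 10] <- TRUE
  h <- make_histogram(counts, flags)
  expect_warning(b <- detect_network_bursts(h, character(0)), "active set")
  expect_equal(n_bursts(b), 0)
})

test_that("burst detection matches the brute-force oracle on random instances", {
  set.seed(99)
  for (i in 1:400) {
    inst <- random_burst_instance()
    h <- make_histogram(inst$counts, inst$flags)
    b <- detect_network_bursts(h, inst$active)
    o <- oracle_detect_bursts(inst$counts, inst$flags, inst$active)
    expect_equal(n_bursts(b), length(o))
    if (length(o)) {
      expect_equal(b$bursts$start_s,
                   vapply(o, function(r) (r["start"] - 1) * 0.05, numeric(1)),
                   ignore_attr = TRUE)
      expect_equal(b$bursts$end_s,
                   vapply(o, function(r) r["end"] * 0.05, numeric(1)),
                   ignore_attr = TRUE)
    }
  }
})

test_that("merging is exhaustive: no two bursts occupy adjacent bins", {
  # deterministic two-epoch instance separated by a single quiet bin
  ids <- paste0("E", 1:6)
  counts <- rep(1L, 400)
  counts[c(200, 201, 203)] <- 100L
  flags <- matrix(TRUE, 6, 400, dimnames = list(ids, NULL))
  b0 <- detect_network_bursts(make_histogram(counts, flags), ids)
  expect_equal(n_bursts(b0), 2)
  expect_gte((b0$bursts$start_s[2] - b0$bursts$end_s[1]) / b0$bin_s, 1)

  set.seed(123)
  for (i in 1:100) {
    inst <- random_burst_instance(100, 6)
    b <- detect_network_bursts(make_histogram(inst$counts, inst$flags),
                               inst$active)
    if (n_bursts(b) > 1) {
      gap_bins <- (b$bursts$start_s[-1] - b$bursts$end_s[-n_bursts(b)]) / b$bin_s
      expect_true(all(gap_bins >= 1 - 1e-9))
    }
  }
})

test_that("burst spike fraction is bounded and recovers the planted share", {
  g <- gen_spike_trains(20, 2, duration = 60, seed = 7)
  empty <- burst_set(data.frame(start_s = numeric(0), end_s = numeric(0),
                                spike_count = numeric(0)))
  expect_equal(burst_spike_fraction(g$trains, empty), 0)

  all_b <- burst_set(data.frame(start_s = 0, end_s = 60.1, spike_count = 0))
  expect_equal(burst_spike_fraction(g$trains, all_b), 1)

  bs <- lapply(c(10, 25, 40), function(t0) burst_spec(t0, 0.5, 40, 0.8))
  gp <- gen_spike_trains(60, 2, bursts = bs, duration = 240, seed = 8)
  det <- find_network_bursts(gp$trains)
  truth_share <- {
    all_t <- unlist(gp$trains$trains, use.names = FALSE)
    ep <- gp$truth$true_burst_epochs
    mean(vapply(all_t, function(t)
      any(t >= ep$start_s & t < ep$end_s), logical(1)))
  }
  frac <- burst_spike_fraction(gp$trains, det)
  expect_true(frac >= 0 && frac <= 1)
  expect_lt(abs(frac - truth_share), 0.05)
})

test_that("maturity staging reproduces the three-category DIV partition", {
  days <- c(15, 22, 28, 35, 42, 49, 56, 63, 70)
  stages <- classify_stage(days)
  expect_equal(unname(table(stages)[c("young", "middle_aged", "old")]),
               c(4L, 3L, 2L), ignore_attr = TRUE)
  expect_equal(classify_stage(c(15, 35)), c("young", "young"))
  expect_equal(classify_stage(49), "middle_aged")
  expect_equal(classify_stage(c(8, 38, 60, 75)), rep("unstaged", 4))
  expect_error(classify_stage(-1), "div")
})

test_that("low-activity exclusion uses a strict lower bound", {
  expect_true(exclude_low_activity(0))
  expect_false(exclude_low_activity(2.5))
  expect_false(exclude_low_activity(0.05))   # exactly at threshold: retained
  expect_true(exclude_low_activity(0.049))
})

test_that("planted bursts are recovered with no spurious burst time", {
  starts <- c(30, 70, 110, 150, 190)
  bs <- lapply(starts, function(t0) burst_spec(t0, 0.5, 40, 0.8))
  for (s in 1:5) {
    g <- gen_spike_trains(60, 2, bursts = bs, duration = 240, seed = s)
    det <- find_network_bursts(g$trains)
    ep <- g$truth$true_burst_epochs
    hit <- vapply(seq_len(nrow(ep)), function(k)
      any(det$bursts$start_s < ep$end_s[k] & det$bursts$end_s > ep$start_s[k]),
      logical(1))
    expect_true(all(hit))
    overlap <- vapply(seq_len(n_bursts(det)), function(k) {
      sum(pmax(0, pmin(det$bursts$end_s[k], ep$end_s) -
                   pmax(det$bursts$start_s[k], ep$start_s)))
    }, numeric(1))
    total <- sum(det$bursts$end_s - det$bursts$start_s)
    expect_lte((total - sum(overlap)) / total, 0.05)
  }
})

test_that("network summary composes rate, bursts, active set and stage", {
  g <- gen_spike_trains(30, 2, bursts = list(burst_spec(10, 0.5, 40, 0.8)),
                        duration = 60, seed = 10)
  sm <- network_summary(g$trains, div = 49)
  expect_equal(sm$firing_rate_hz, n_spikes(g$trains) / 60)
  expect_equal(sm$stage, "middle_aged")
  expect_equal(sm$n_bursts, 1)
  expect_lte(sm$n_active_electrodes, 30)
  expect_false(exclude_low_activity(sm))
})
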