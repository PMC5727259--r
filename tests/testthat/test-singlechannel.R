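make_sweeps <- function(currents, sample_rate_hz = 30000) {
  currents <- rbind(currents)
  p <- step_protocol(step_ms = ncol(currents) * 1000 / sample_rate_hz,
                     sample_rate_hz = sample_rate_hz,
                     n_sweeps = nrow(currents))
  sweep_set(currents, p)
}

test_that("levels are recovered exactly from noiseless records", {
  m <- gating_model(rate_co = 0.5, rate_oi = 2, coupling_fraction = 0,
                    noise_sd = 0)
  ss <- simulate_sweeps(m, step_protocol(step_ms = 20, n_sweeps = 100),
                        seed = 4)
  lv <- estimate_levels(ss)
  expect_equal(lv$baseline, 0)
  expect_equal(lv$i1, -1.5)
  expect_equal(lv$i2, -3.0)
  expect_false(lv$i2_extrapolated)
})

test_that("all-closed records raise a no-openings error", {
  ss <- simulate_sweeps(gating_model(rate_co = 0, noise_sd = 0.1),
                        step_protocol(step_ms = 10, n_sweeps = 10), seed = 1)
  expect_error(estimate_levels(ss), "no openings detected")
})

test_that("levels are recovered within tolerance from noisy records", {
  m <- gating_model(rate_co = 0.5, rate_oi = 2, coupling_fraction = 0,
                    noise_sd = 0.15, unitary_current = -1.5)
  ss <- simulate_sweeps(m, step_protocol(step_ms = 20, n_sweeps = 600),
                        seed = 5)
  lv <- estimate_levels(ss)
  expect_lt(abs(lv$i1 - (-1.5)), 0.1)
  expect_lt(abs(lv$i2 - (-3.0)), 0.2)
})

test_that("idealization assigns segment means to nearest level with low tie-break", {
  # 0.2 ms at 30 kHz = 6 samples per segment; build three exact segments
  seg <- function(v) rep(v, 6)
  cur <- c(seg(0), seg(-1.5), seg(-3.0))
  ss <- make_sweeps(cur)
  lv <- level_estimate(0, -1.5, -3.0)
  ideal <- idealize(ss, lv)
  expect_equal(ideal[[1]]$labels, c(0L, 1L, 2L))

  # exact midpoint between baseline (0) and O1 (-1.5): tie goes to closed
  ss_tie <- make_sweeps(c(seg(-0.75), seg(-2.25)))
  ideal_tie <- idealize(ss_tie, lv)
  expect_equal(ideal_tie[[1]]$labels, c(0L, 1L))
})

test_that("idealization reproduces ground-truth labels on noiseless sweeps", {
  m <- gating_model(rate_co = 0.5, rate_oi = 2, coupling_fraction = 1,
                    noise_sd = 0)
  ss <- simulate_sweeps(m, step_protocol(step_ms = 20, n_sweeps = 200),
                        seed = 6)
  lv <- level_estimate(0, m$unitary_current, 2 * m$unitary_current)
  ideal <- idealize(ss, lv)
  truth <- ground_truth_labels(ss)
  for (i in seq_along(ideal))
    expect_identical(ideal[[i]]$labels, truth[[i]]$labels)
})

test_that("event classification follows the two-segment simultaneity rule", {
  sw <- function(labels, id = 1)
    structure(list(labels = as.integer(labels), segment_ms = 0.2,
                   sweep_id = id), class = "idealized_sweep")
  # direct closed -> double transition: coupled with zero offset
  ev <- extract_events(list(sw(c(0, 2, 2, 0))))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$classification, "coupled")
  expect_equal(ev$segments_to_level2, 0)
  # level 2 reached at offset 1 (within 0.4 ms): still coupled
  ev2 <- extract_events(list(sw(c(0, 1, 2, 0))))
  expect_equal(ev2$classification, "coupled")
  # offset 3 beyond the window: stacked, not simultaneous
  ev3 <- extract_events(list(sw(c(0, 1, 1, 1, 2, 2, 0))))
  expect_equal(ev3$classification, "uncoupled_stacked")
  expect_equal(ev3$segments_to_level2, 3)
  # boundary offset exactly 2 is inclusive
  ev4 <- extract_events(list(sw(c(0, 1, 1, 2, 0))))
  expect_equal(ev4$classification, "coupled")
  # single-level opening
  ev5 <- extract_events(list(sw(c(0, 1, 1, 0))))
  expect_equal(ev5$classification, "single")
  expect_true(is.na(ev5$segments_to_level2))
  # event truncated by sweep end keeps classification, flagged
  ev6 <- extract_events(list(sw(c(0, 0, 2, 2))))
  expect_equal(ev6$classification, "coupled")
  expect_true(ev6$truncated)
})

test_that("widening the coupling window never decreases the coupled count", {
  set.seed(21)
  sweeps <- lapply(1:40, function(i)
    structure(list(labels = sample(0:2, 50, replace = TRUE,
                                   prob = c(0.7, 0.2, 0.1)),
                   segment_ms = 0.2, sweep_id = i),
              class = "idealized_sweep"))
  counts <- vapply(1:6, function(w) {
    ev <- extract_events(sweeps, idealization_params(
      coupling_window_segments = w))
    sum(ev$classification == "coupled")
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("opening tallies conserve counts and place stacked pairs correctly", {
  sw <- function(labels, id = 1)
    structure(list(labels = as.integer(labels), segment_ms = 0.2,
                   sweep_id = id), class = "idealized_sweep")
  empty <- extract_events(list(sw(rep(0, 10))))
  h0 <- openings_vs_time(empty, bin_ms = 1, step_ms = 2)
  expect_true(all(h0$level1 == 0) && all(h0$level2 == 0))

  ev <- extract_events(list(sw(c(2, 2, 0, 0, 0))))   # coupled at onset 0
  h1 <- openings_vs_time(ev, bin_ms = 1, step_ms = 1)
  expect_equal(h1$level2, 1)
  expect_equal(h1$level1, 0)

  # a stacked event is two level-1 openings: one at onset, one when the
  # second channel joins
  ev2 <- extract_events(list(sw(c(0, 1, 1, 1, 2, 0))))
  h2 <- openings_vs_time(ev2, bin_ms = 0.2, step_ms = 1.2)
  expect_equal(sum(h2$level1), 2)
  expect_equal(sum(h2$level2), 0)
  expect_equal(h2$level1[h2$time_ms == 0.2], 1)  # onset segment 1
  expect_equal(h2$level1[h2$time_ms == 0.8], 1)  # level 2 reached at seg 4

  # conservation across a simulated record
  m <- gating_model(rate_co = 0.2, rate_oi = 1, coupling_fraction = 0.5)
  ss <- simulate_sweeps(m, step_protocol(step_ms = 20, n_sweeps = 150),
                        seed = 9)
  lv <- level_estimate(0, -1.5, -3)
  ev3 <- extract_events(idealize(ss, lv))
  h3 <- openings_vs_time(ev3, bin_ms = 1, step_ms = 20)
  n_single <- sum(ev3$classification == "single")
  n_coupled <- sum(ev3$classification == "coupled")
  n_stacked <- sum(ev3$classification == "uncoupled_stacked")
  expect_equal(sum(h3$level1), n_single + 2 * n_stacked)
  expect_equal(sum(h3$level2), n_coupled)
})

test_that("ensemble averaging is the pointwise sweep mean", {
  cur <- rbind(c(0, -1, -2, -1), c(0, -1, -2, -1))
  ss <- make_sweeps(cur, sample_rate_hz = 1000)
  avg <- ensemble_average(ss)
  expect_equal(avg$mean_pA, c(0, -1, -2, -1))
  # all-closed: average within noise_sd / sqrt(n)
  ssc <- simulate_sweeps(gating_model(rate_co = 0, noise_sd = 0.15),
                         step_protocol(step_ms = 10, n_sweeps = 400),
                         seed = 2)
  expect_lt(max(abs(ensemble_average(ssc)$mean_pA)),
            5 * 0.15 / sqrt(400))
})
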