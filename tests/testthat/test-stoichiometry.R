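test_that("step detection is exact on clean staircases and null on flat traces", {
  tr <- bleach_trace("m", c(rep(2, 8), rep(1, 7), rep(0, 10)), 0.1)
  res <- detect_steps(tr)
  expect_equal(res$step_count, 2L)
  expect_equal(res$step_times, c(8, 15) * 0.1)
  expect_equal(res$step_sizes, c(1, 1))

  flat <- detect_steps(bleach_trace("f", rep(3, 20), 0.1))
  expect_equal(flat$step_count, 0L)
  expect_error(detect_steps(bleach_trace("n", c(1, NA, 3, 4), 0.1)),
               "non-finite")
  # upward jumps (blinking recovery) are never counted
  blink <- detect_steps(bleach_trace("b", c(rep(1, 8), rep(2, 8), rep(1, 8)),
                                     0.1))
  expect_lte(blink$step_count, 1L)
})

test_that("greedy step detection matches the exhaustive search on short traces", {
  set.seed(31)
  n_agree <- 0L
  n_cases <- 60L
  for (i in seq_len(n_cases)) {
    n <- sample(10:30, 1)
    k <- sample(0:2, 1)
    cps <- sort(sample(3:(n - 3), k))
    lvl <- rev(seq_len(k + 1)) - 1
    y <- rep(lvl, diff(c(0, cps, n))) + rnorm(n, sd = 0.08)
    greedy <- chancoupler:::binseg_changepoints(y)
    exact <- dp_changepoints(y)
    if (identical(greedy, as.integer(exact))) n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, n_cases)
})

test_that("trace-level step counts recover the truth for most detectable dimers", {
  params <- bleach_population_params(n_subunits = 2, p_active = 0.7,
                                     bleach_rate = 0.2,
                                     frame_interval_s = 0.1,
                                     noise_sd = 0.1, n_molecules = 2000)
  pop <- simulate_bleach_population(params, seed = 7)
  det <- pop$molecules$detectable
  res <- lapply(pop$traces[det], detect_steps)
  counts <- vapply(res, `[[`, 0L, "step_count")
  truth <- pop$molecules$true_step_count[det]
  expect_gte(mean(counts == truth), 0.95)
  # and few spurious high counts: the over-segmentation rate stays small
  expect_lt(mean(counts >= 3), 0.05)
})

test_that("step histograms tally detected and undetected molecules", {
  h <- step_histogram(c(2, 2, 1))
  expect_equal(unname(h$counts[c("1", "2")]), c(1L, 2L))
  expect_equal(h$n_undetected, 0L)
  expect_error(step_histogram(integer(0)), "empty")

  pop <- simulate_bleach_population(
    bleach_population_params(n_molecules = 100000), seed = 42,
    traces = FALSE)
  h2 <- step_histogram(pop$molecules$true_step_count)
  expect_equal(h2$counts[["1"]], 42000, tolerance = 0.02)
  expect_equal(h2$counts[["2"]], 49000, tolerance = 0.02)
  expect_equal(h2$n_undetected, 9000, tolerance = 0.05)
})

test_that("subunit-count MLE identifies the stoichiometry", {
  # proportions at the enumerated conditional dimer distribution
  fit <- fit_subunit_count(step_histogram(c(rep(1, 462), rep(2, 538))),
                           p_active = 0.7)
  expect_equal(fit$n_hat, 2L)
  expect_equal(sum(fit$predicted), 1)
  expect_equal(unname(fit$predicted["2"]), cond_binom_pmf(2, 2, 0.7))

  # with full maturation any n > 1 leaves zero mass at k = 1
  fit1 <- fit_subunit_count(step_histogram(rep(1, 1000)), p_active = 1)
  expect_equal(fit1$n_hat, 1L)

  # tetramer recovery from sampled counts
  set.seed(12)
  k4 <- rbinom(10000, 4, 0.7)
  fit4 <- fit_subunit_count(step_histogram(k4[k4 > 0]), p_active = 0.7,
                            n_max = 8)
  expect_equal(fit4$n_hat, 4L)

  expect_error(fit_subunit_count(step_histogram(c(1, 2, 5)), n_max = 4),
               "exceeds")
})

test_that("MLE recovery improves with population size", {
  p <- 0.7
  for (true_n in 1:4) {
    hits <- vapply(c(100, 1000, 10000), function(nm) {
      set.seed(true_n * 1000 + nm)
      k <- rbinom(nm, true_n, p)
      k <- k[k > 0]
      fit_subunit_count(step_histogram(k), p_active = p, n_max = 8)$n_hat
    }, 0L)
    expect_equal(hits[length(hits)], true_n)
  }
})

test_that("bleach-time statistics match the order-statistic expectations", {
  kb <- 0.2
  pop2 <- simulate_bleach_population(
    bleach_population_params(n_subunits = 2, p_active = 1, bleach_rate = kb,
                             noise_sd = 0, n_molecules = 3000),
    seed = 5)
  two <- lapply(pop2$traces, `[[`, "true_step_times")
  pop1 <- simulate_bleach_population(
    bleach_population_params(n_subunits = 1, p_active = 1, bleach_rate = kb,
                             noise_sd = 0, n_molecules = 3000),
    seed = 6)
  one <- lapply(pop1$traces, `[[`, "true_step_times")
  st <- bleach_time_stats(c(two, one))
  expect_equal(st$mean_first_step_s, 1 / (2 * kb), tolerance = 0.05)
  expect_equal(st$mean_total_time_s, 3 / (2 * kb), tolerance = 0.05)
  expect_equal(st$mean_one_step_time_s, 1 / kb, tolerance = 0.05)
  expect_error(bleach_time_stats(two), "one-step")
})

test_that("binomial theoretical curves follow (1-x)^n", {
  expect_equal(binomial_theoretical(0, 5), 1)
  expect_equal(binomial_theoretical(1, 5), 0)
  expect_equal(binomial_theoretical(0.5, 2), 0.25)
  expect_equal(binomial_theoretical(0.5, 3), 0.125)
  x <- seq(0, 1, by = 0.05)
  expect_true(all(binomial_theoretical(x, 3) <= binomial_theoretical(x, 2)))
  expect_true(all(binomial_theoretical(x, 2) <= binomial_theoretical(x, 1)))
})

test_that("raw current densities normalize against the x = 0 reference", {
  raw <- data.frame(x = c(0, 0.5), current_density = c(100, 25),
                    sem = c(10, 5))
  dr <- normalize_dose_response(raw)
  expect_equal(dr$y, c(1, 0.25))
  expect_equal(dr$sem, c(0.1, 0.05))
  # replicated references average
  raw2 <- data.frame(x = c(0, 0, 0.5), current_density = c(90, 110, 50))
  dr2 <- normalize_dose_response(raw2)
  expect_equal(dr2$y[dr2$x == 0], 1)
  expect_equal(dr2$y[dr2$x == 0.5], 0.5)
  expect_error(normalize_dose_response(
    data.frame(x = 0.5, current_density = 50)), "reference")
  expect_error(normalize_dose_response(
    data.frame(x = 0, current_density = 0)), "reference")
})

test_that("exponent fitting identifies monomer, dimer and trimer curves", {
  ratios <- c(0, 1/11, 1/5, 1/2, 4/5, 10/11, 1)
  dr2 <- simulate_dose_response(2, ratios, noise_sd = 0, seed = 1)
  fit2 <- fit_binomial_exponent(dr2)
  expect_equal(fit2$n_best, 2L)
  expect_equal(unname(fit2$rss["2"]), 0)
  expect_equal(fit2$n_continuous, 2, tolerance = 1e-4)

  dr1 <- simulate_dose_response(1, ratios, noise_sd = 0, seed = 1)
  expect_equal(fit_binomial_exponent(dr1)$n_best, 1L)

  expect_error(fit_binomial_exponent(
    dose_response(c(0, 0.5, 1), c(0.4, 0.4, 0.4))), "degenerate")
})

test_that("exponent fitting is scale-free through normalization", {
  raw <- data.frame(x = c(0, 1/5, 1/2, 4/5, 1),
                    current_density = 120 * c(1, 0.64, 0.25, 0.04, 0),
                    sem = c(8, 6, 5, 2, 1))
  f1 <- fit_binomial_exponent(normalize_dose_response(raw))
  raw2 <- raw
  raw2$current_density <- raw2$current_density * 7.3
  raw2$sem <- raw2$sem * 7.3
  f2 <- fit_binomial_exponent(normalize_dose_response(raw2))
  expect_equal(f1$n_best, f2$n_best)
  expect_equal(f1$rss, f2$rss)
  expect_equal(f1$n_continuous, f2$n_continuous)
})
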