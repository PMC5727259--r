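test_that("peak I/V takes the signed extremum of the ensemble mean", {
  mk <- function(trace, v) {
    p <- step_protocol(step_mv = v, step_ms = length(trace) / 30,
                      n_sweeps = 1)
    sweep_set(rbind(trace), p)
  }
  zero <- lapply(c(-40, -20), function(v) mk(rep(0, 60), v))
  iv0 <- peak_iv(zero)
  expect_equal(iv0$peak_pA, c(0, 0))

  tr <- rep(0, 90); tr[60] <- -50
  iv <- peak_iv(list(mk(tr, -20), mk(rep(0, 90), 0)))
  expect_equal(iv$peak_pA[iv$voltage_mv == -20], -50)
  expect_error(peak_iv(list(mk(rep(0, 60), -20))), ">= 2 voltages")
})

test_that("conductance transform recovers the activation curve", {
  e_rev <- 40
  v <- seq(-100, 60, by = 10)
  # ohmic: constant conductance everywhere
  iv_ohm <- data.frame(voltage_mv = v, peak_pA = 2 * (v - e_rev))
  act <- activation_from_iv(iv_ohm, e_rev = e_rev)
  expect_true(all(abs(act$response - 1) < 1e-12))
  expect_false(e_rev %in% act$voltage_mv)

  # automatic reversal from the exact zero crossing
  g <- boltzmann(v, -45, 7)
  iv_gate <- data.frame(voltage_mv = v, peak_pA = g * 1.8 * (v - e_rev))
  act2 <- activation_from_iv(iv_gate, e_rev = "auto")
  keep <- v != e_rev
  expect_equal(act2$response, (g / max(g))[keep], tolerance = 1e-6)
})

test_that("Boltzmann fitting recovers exact parameters and flags bad input", {
  gc <- simulate_gating_curve(-85, -6, seq(-140, -30, by = 5),
                              noise_sd = 0, kind = "ssi")
  fit <- fit_boltzmann(gc)
  expect_equal(fit$v_half, -85, tolerance = 1e-6)
  expect_equal(fit$slope_k, -6, tolerance = 1e-6)

  act <- simulate_gating_curve(-45, 7, seq(-100, 20, by = 5), noise_sd = 0)
  fit2 <- fit_boltzmann(act)
  expect_equal(fit2$v_half, -45, tolerance = 1e-6)
  expect_equal(fit2$slope_k, 7, tolerance = 1e-6)

  flat <- gating_curve(seq(-100, -60, 10), rep(0.5, 5))
  expect_error(fit_boltzmann(flat), "dynamic range")
})

test_that("Boltzmann fit is translation-equivariant", {
  v <- seq(-120, -40, by = 5)
  gc <- simulate_gating_curve(-80, -7, v, noise_sd = 0.02, seed = 3,
                              kind = "ssi")
  f0 <- fit_boltzmann(gc)
  shifted <- gating_curve(v + 15, gc$response, kind = "ssi")
  f1 <- fit_boltzmann(shifted)
  expect_equal(f1$v_half, f0$v_half + 15, tolerance = 1e-6)
  expect_equal(f1$slope_k, f0$slope_k, tolerance = 1e-6)
})

test_that("biexponential decay parameters are recovered from a construction", {
  t <- seq(0, 40, by = 1 / 30)
  trace <- data.frame(time_ms = t,
                      mean_pA = -(0.5 * exp(-t / 0.5) + 0.5 * exp(-t / 5)))
  fit <- fit_decay(trace)
  expect_false(fit$single_exponential)
  expect_equal(fit$tau_f, 0.5, tolerance = 0.01)
  expect_equal(fit$tau_s, 5, tolerance = 0.01)
  expect_lte(fit$tau_f, fit$tau_s)
  expect_equal(fit$amp_f, -0.5, tolerance = 0.02)

  # single-exponential input: both components converge or fall back
  tr1 <- data.frame(time_ms = t, mean_pA = -exp(-t / 1))
  f1 <- fit_decay(tr1)
  if (f1$single_exponential) {
    expect_equal(f1$tau_f, 1, tolerance = 0.02)
  } else {
    expect_equal(unname(sort(c(f1$tau_f, f1$tau_s))[1]), 1,
                 tolerance = 0.25)
  }
  expect_error(fit_decay(data.frame(time_ms = t,
                                    mean_pA = rep(-2, length(t)))),
               "no decay")
})

test_that("independent mixture is a convex combination of the components", {
  fa <- structure(list(v_half = -90, slope_k = -6), class = "boltzmann_fit")
  fb <- structure(list(v_half = -60, slope_k = -6), class = "boltzmann_fit")
  v <- seq(-140, -30, by = 2)
  same <- independent_mixture(fa, fa, v, weight = 0.5)
  expect_equal(same$response, boltzmann(v, -90, -6))

  mix <- independent_mixture(fa, fb, v, weight = 0.5)
  ya <- boltzmann(v, -90, -6)
  yb <- boltzmann(v, -60, -6)
  expect_equal(mix$response, 0.5 * ya + 0.5 * yb)
  for (w in c(0, 0.25, 0.8, 1)) {
    mw <- independent_mixture(fa, fb, v, weight = w)$response
    expect_true(all(mw >= pmin(ya, yb) - 1e-12 &
                      mw <= pmax(ya, yb) + 1e-12))
  }
})

test_that("coupling deviation separates coupled data from the mixture null", {
  v <- seq(-140, -30, by = 5)
  wt <- gating_curve(v, boltzmann(v, -90, -6), kind = "ssi")
  mut <- gating_curve(v, boltzmann(v, -60, -6), kind = "ssi")
  theo <- gating_curve(v, 0.5 * wt$response + 0.5 * mut$response,
                       kind = "ssi")
  same <- coupling_deviation(theo, theo,
                             components = list(WT = theo, mut = theo))
  expect_equal(same$rms_dev, 0)
  expect_equal(same$max_dev, 0)
  expect_equal(same$nearer_component, "tie")

  asA <- coupling_deviation(wt, theo, components = list(WT = wt, mut = mut))
  expect_equal(asA$nearer_component, "WT")

  # coupled-like data tracking WT: closed-form quadrature of the deviation
  obs <- gating_curve(v, 0.9 * wt$response + 0.1 * mut$response,
                      kind = "ssi")
  dev <- coupling_deviation(obs, theo)
  expect_equal(dev$rms_dev,
               sqrt(mean((0.4 * (wt$response - mut$response))^2)))
  expect_error(coupling_deviation(
    gating_curve(1:5, rep(0.5, 5)), gating_curve(10:14, rep(0.5, 5))),
    "overlap")
})

test_that("FRET crosstalk correction is the stated linear map", {
  expect_equal(fret_correct(data.frame(fret = 100, cfp = 100,
                                       yfp = 100))$fretc, 67)
  expect_equal(fret_correct(data.frame(fret = 80, cfp = 10, yfp = 20),
                            a = 0, b = 0)$fretc, 80)
  # linearity
  r1 <- data.frame(fret = 120, cfp = 40, yfp = 60)
  r2 <- data.frame(fret = 30, cfp = 10, yfp = 5)
  rs <- data.frame(fret = 150, cfp = 50, yfp = 65)
  expect_equal(fret_correct(rs)$fretc,
               fret_correct(r1)$fretc + fret_correct(r2)$fretc)
  expect_error(fret_correct(data.frame(fret = -1, cfp = 0, yfp = 0)),
               ">= 0")
})

test_that("acceptor photobleaching statistics quantify donor dequenching", {
  same <- acceptor_photobleach_stat(c(100, 120, 90), c(100, 120, 90))
  expect_equal(same$mean_increase, 0)
  up <- acceptor_photobleach_stat(rep(100, 5), rep(110, 5))
  expect_equal(up$mean_increase, 10)
  # donor dequenching identity: quenched = (1 - E) * unquenched
  E <- 0.25
  set.seed(8)
  unq <- runif(40, 80, 120)
  stat <- acceptor_photobleach_stat((1 - E) * unq, unq)
  expect_equal(stat$mean_increase, 100 * E / (1 - E), tolerance = 1e-6)
  expect_lt(stat$p_value, 0.001)
  expect_warning(acceptor_photobleach_stat(c(0, 100, 100, 100),
                                           c(10, 110, 110, 110)),
                 "excluded")
})
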