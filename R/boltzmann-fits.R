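#' Construct a gating curve
#'
#' Voltage dependence of normalized conductance (activation) or channel
#' availability (steady-state inactivation, SSI).
#'
#' @param voltages voltage grid (mV), strictly increasing.
#' @param response normalized response; nominally in \[0, 1\] but noise
#'   may take points slightly outside.
#' @param kind `"activation"` or `"ssi"`.
#'
#' @return A `gating_curve` data frame with columns `voltage_mv`,
#'   `response` and attribute `kind`.
#' @export
gating_curve <- function(voltages, response, kind = c("activation", "ssi")) {
  kind <- match.arg(kind)
  voltages <- as.numeric(voltages)
  response <- as.numeric(response)
  if (length(voltages) != length(response))
    stop("length mismatch", call. = FALSE)
  if (any(diff(voltages) <= 0))
    stop("'voltages' must be strictly increasing", call. = FALSE)
  df <- data.frame(voltage_mv = voltages, response = response)
  attr(df, "kind") <- kind
  class(df) <- c("gating_curve", "data.frame")
  df
}

#' Peak currents of an I/V family
#'
#' For each test potential, the signed extremum of the ensemble-average
#' trace: the minimum for inward (negative) currents, the maximum
#' otherwise.
#'
#' @param sweepsets named or unnamed list of [sweep_set()] objects, one per
#'   test potential; the potential is read from each protocol's `step_mv`.
#'
#' @return A data frame with columns `voltage_mv` and `peak_pA`, sorted by
#'   voltage.
#' @export
peak_iv <- function(sweepsets) {
  if (length(sweepsets) < 2)
    stop("need sweeps at >= 2 voltages", call. = FALSE)
  rows <- lapply(sweepsets, function(ss) {
    stopifnot(inherits(ss, "sweep_set"))
    if (nrow(ss$sweeps) == 0) stop("empty sweep set", call. = FALSE)
    avg <- colMeans(ss$sweeps)
    pk <- if (abs(min(avg)) >= abs(max(avg))) min(avg) else max(avg)
    data.frame(voltage_mv = ss$protocol$step_mv, peak_pA = pk)
  })
  out <- do.call(rbind, rows)
  out[order(out$voltage_mv), , drop = FALSE]
}

#' Conductance-transform activation curve from peak I/V data
#'
#' Converts peak currents to conductances, G(V) = I / (V - E_rev), and
#' normalizes by the largest magnitude. The reversal potential can be
#' estimated automatically by linear interpolation of the zero crossing on
#' the positive (depolarized) limb of the I/V curve. The point at
#' V = E_rev, where the transform is singular, is excluded.
#'
#' @param iv data frame with columns `voltage_mv` and `peak_pA`.
#' @param e_rev reversal potential (mV), or `"auto"`.
#'
#' @return A [gating_curve()] of kind `"activation"`.
#' @export
activation_from_iv <- function(iv, e_rev = "auto") {
  iv <- as.data.frame(iv)
  stopifnot(all(c("voltage_mv", "peak_pA") %in% names(iv)))
  iv <- iv[order(iv$voltage_mv), ]
  if (identical(e_rev, "auto")) {
    i_pk <- which.max(abs(iv$peak_pA))
    v <- iv$voltage_mv
    p <- iv$peak_pA
    # zero crossing on the limb depolarized of the peak
    limb <- i_pk:nrow(iv)
    cross <- which(p[limb[-length(limb)]] * p[limb[-1]] <= 0 &
                     p[limb[-length(limb)]] != 0)
    exact0 <- limb[which(p[limb] == 0)]
    if (length(exact0)) {
      e_rev <- v[exact0[1]]
    } else if (length(cross)) {
      j <- limb[cross[1]]
      e_rev <- v[j] - p[j] * (v[j + 1] - v[j]) / (p[j + 1] - p[j])
    } else {
      stop("no zero crossing found for automatic E_rev", call. = FALSE)
    }
  }
  keep <- iv$voltage_mv != e_rev
  g <- iv$peak_pA[keep] / (iv$voltage_mv[keep] - e_rev)
  g <- g / max(abs(g))
  gating_curve(iv$voltage_mv[keep], g, kind = "activation")
}

#' Fit a Boltzmann function to a gating curve
#'
#' Nonlinear least-squares fit of
#' \eqn{Y = 1 / (1 + \exp(-(V - V_{1/2}) / k))}. Initialization takes
#' V1/2 as the voltage whose response is nearest the half-range and
#' k as (V at 80\% range - V at 20\% range) / 2.2, signed by the data's
#' monotonic direction. A warning is issued (and the fit still attempted)
#' when the curve is not clearly monotone (Spearman |rho| < 0.5).
#'
#' @param curve a [gating_curve()] (or data frame with `voltage_mv`,
#'   `response`).
#'
#' @return A `boltzmann_fit`: list with `v_half` (mV), `slope_k` (signed
#'   inverse slope factor, mV), `rss` and `fitted`.
#' @examples
#' gc <- simulate_gating_curve(-85, -6, seq(-140, -30, 5), noise_sd = 0)
#' fit_boltzmann(gc)
#' @export
fit_boltzmann <- function(curve) {
  v <- curve$voltage_mv
  y <- curve$response
  if (length(v) < 5) stop("need >= 5 points", call. = FALSE)
  rng <- range(y)
  if (diff(rng) < 0.2)
    stop("no dynamic range: response spans < 0.2", call. = FALSE)
  rho <- suppressWarnings(cor(v, y, method = "spearman"))
  if (is.na(rho) || abs(rho) < 0.5)
    warning("response is not clearly monotone in voltage; fitting anyway")
  direction <- if (is.na(rho) || rho >= 0) 1 else -1
  yn <- (y - rng[1]) / diff(rng)
  v_at <- function(q) v[which.min(abs(yn - q))]
  v_half0 <- v_at(0.5)
  k0 <- direction * max(abs(v_at(0.8) - v_at(0.2)) / 2.2,
                        min(diff(v)) / 2)
  fit <- minpack.lm::nlsLM(
    y ~ 1 / (1 + exp(-(v - v_half) / slope_k)),
    start = list(v_half = v_half0, slope_k = k0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12))
  est <- coef(fit)
  structure(list(v_half = unname(est["v_half"]),
                 slope_k = unname(est["slope_k"]),
                 rss = sum(resid(fit)^2),
                 fitted = boltzmann(v, est["v_half"], est["slope_k"])),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: V1/2 = %.2f mV, k = %.2f mV (RSS %.3g)\n",
              x$v_half, x$slope_k, x$rss))
  invisible(x)
}

#' Fit a biexponential decay to a macroscopic current
#'
#' Fits \eqn{I(t) = A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s} + C} from the
#' peak sample onward, the standard description of fast and slow sodium
#' current inactivation. Initialization splits the decay window in two and
#' fits log-linear slopes on each half; the convention \eqn{\tau_f \le
#' \tau_s} is enforced by swapping. If the two-component fit degenerates
#' (amplitudes of opposite sign on a monotone decay, or non-convergence),
#' a single-exponential fit is returned with `tau_s = NA` and
#' `single_exponential = TRUE`.
#'
#' @param trace data frame with columns `time_ms` and `mean_pA` (e.g. from
#'   [ensemble_average()]), or a numeric current vector.
#' @param time_ms sample times when `trace` is a bare vector.
#'
#' @return A `decay_fit`: list with `tau_f`, `tau_s` (ms), `amp_f`,
#'   `amp_s`, `offset` (pA), `rss`, `single_exponential`.
#' @export
fit_decay <- function(trace, time_ms = NULL) {
  if (is.numeric(trace))
    trace <- data.frame(time_ms = if (is.null(time_ms))
      seq_along(trace) - 1 else time_ms, mean_pA = trace)
  t_all <- trace$time_ms
  i_all <- trace$mean_pA
  pk <- which.max(abs(i_all))
  if (length(i_all) - pk + 1 < 20)
    stop("need >= 20 samples after the peak", call. = FALSE)
  t <- t_all[pk:length(t_all)] - t_all[pk]
  y <- i_all[pk:length(i_all)]
  s <- sign(i_all[pk])                    # work on magnitudes
  z <- s * y
  if (max(z) - min(z) < 10 * .Machine$double.eps * max(abs(z), 1) ||
      max(z) <= 0)
    stop("no decay: trace is flat after the peak", call. = FALSE)
  offset0 <- min(z)
  zz <- pmax(z - offset0, max(z) * 1e-9)
  t_span <- diff(range(t))
  slope_fit <- function(idx) {
    f <- lm(log(zz[idx]) ~ t[idx])
    c(a = exp(unname(coef(f)[1])), tau = -1 / unname(coef(f)[2]))
  }
  # peeling initialization: log-linear fit on the tail gives the slow
  # component; subtract it and fit the early remainder for the fast one
  tail_idx <- which(t > t_span / 3)
  if (length(tail_idx) < 3) tail_idx <- seq(length(t) - 2L, length(t))
  slow0 <- slope_fit(tail_idx)
  tau_s0 <- if (is.finite(slow0["tau"]) && slow0["tau"] > 0)
    unname(slow0["tau"]) else t_span / 3
  a_s0 <- if (is.finite(slow0["a"]) && slow0["a"] > 0)
    unname(slow0["a"]) else max(z) / 2
  z_fast <- z - offset0 - a_s0 * exp(-t / tau_s0)
  fast_idx <- which(z_fast > max(max(z_fast), 0) * 0.05)
  tau_f0 <- if (length(fast_idx) >= 3) {
    f2 <- try(lm(log(pmax(z_fast[fast_idx], max(z) * 1e-9)) ~ t[fast_idx]),
              silent = TRUE)
    tf <- if (!inherits(f2, "try-error")) -1 / unname(coef(f2)[2]) else NA
    if (is.finite(tf) && tf > 0 && tf < tau_s0) tf else tau_s0 / 10
  } else tau_s0 / 10
  resid_bi <- function(par)
    z - (par[1] * exp(-t / par[2]) + par[3] * exp(-t / par[4]) + par[5])
  starts <- list(
    c(max(z) / 2, tau_f0, a_s0, tau_s0, offset0),
    c(max(z) / 2, t_span / 20, max(z) / 2, t_span / 3, offset0),
    c(max(z) / 2, t_span / 100, max(z) / 2, t_span / 10, offset0))
  bi <- NULL
  for (st in starts) {
    cand <- try(minpack.lm::nls.lm(
      par = st, fn = resid_bi,
      lower = c(-Inf, 1e-6, -Inf, 1e-6, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15)),
      silent = TRUE)
    if (!inherits(cand, "try-error") && cand$info %in% 1:4 &&
        (is.null(bi) || cand$deviance < bi$deviance))
      bi <- cand
  }
  ok <- !is.null(bi)
  if (ok) {
    p <- bi$par
    if (p[2] > p[4]) p <- p[c(3, 4, 1, 2, 5)]   # enforce tau_f <= tau_s
    monotone <- all(diff(z) <= max(z) * 1e-9)
    ok <- !(monotone && sign(p[1]) != sign(p[3]))
  }
  if (ok) {
    return(structure(list(tau_f = p[2], tau_s = p[4],
                          amp_f = s * p[1], amp_s = s * p[3],
                          offset = s * p[5],
                          rss = sum(resid_bi(p)^2),
                          single_exponential = FALSE),
                     class = "decay_fit"))
  }
  resid_mono <- function(par) z - (par[1] * exp(-t / par[2]) + par[3])
  mono <- minpack.lm::nls.lm(
    par = c(max(z), unname(tau_f0), offset0), fn = resid_mono,
    lower = c(-Inf, 1e-6, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- mono$par
  structure(list(tau_f = p[2], tau_s = NA_real_,
                 amp_f = s * p[1], amp_s = NA_real_,
                 offset = s * p[3], rss = sum(resid_mono(p)^2),
                 single_exponential = TRUE),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$single_exponential)
    cat(sprintf("Decay fit (single exponential): tau = %.3g ms\n", x$tau_f))
  else
    cat(sprintf("Decay fit: tau_f = %.3g ms, tau_s = %.3g ms\n",
                x$tau_f, x$tau_s))
  invisible(x)
}
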