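#' Two-protomer gating model
#'
#' Describes the stochastic gating of a channel dimer. Each protomer follows
#' a three-state scheme C <-> O -> I (closed, open, inactivated) with
#' first-order rates; with probability `coupling_fraction` a dimer gates as
#' one concerted unit whose open state conducts twice the unitary current,
#' otherwise the two protomers gate independently.
#'
#' The three-state scheme is the smallest one with activation and absorbing
#' fast inactivation; recovery (`rate_ic`) defaults to 0 so inactivation is
#' absorbing within a sweep, as appropriate for brief depolarizing steps.
#'
#' @param rate_co closed -> open rate (ms^-1).
#' @param rate_oc open -> closed rate (ms^-1).
#' @param rate_oi open -> inactivated rate (ms^-1).
#' @param rate_ic inactivated -> closed recovery rate (ms^-1); 0 makes
#'   inactivation absorbing.
#' @param unitary_current single-channel current i in pA (negative for an
#'   inward current); a concerted dimer conducts 2i.
#' @param coupling_fraction probability phi in \[0, 1\] that a dimer gates
#'   as one concerted unit. phi = 1 is the fully coupled condition, phi = 0
#'   the independent (uncoupled, e.g. difopein-like) condition.
#' @param noise_sd Gaussian current noise SD in pA added to each sample.
#'
#' @return An object of class `gating_model`.
#' @examples
#' m <- gating_model(coupling_fraction = 1)
#' m
#' @seealso [simulate_sweeps()], [step_protocol()]
#' @export
gating_model <- function(rate_co = 0.05, rate_oc = 0.1, rate_oi = 0.5,
                         rate_ic = 0, unitary_current = -1.5,
                         coupling_fraction = 1, noise_sd = 0.15) {
  rates <- c(rate_co = rate_co, rate_oc = rate_oc,
             rate_oi = rate_oi, rate_ic = rate_ic)
  if (!all(is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0", call. = FALSE)
  if (!is.finite(unitary_current) || unitary_current == 0)
    stop("'unitary_current' must be finite and non-zero", call. = FALSE)
  if (!is.finite(coupling_fraction) || coupling_fraction < 0 ||
      coupling_fraction > 1)
    stop("'coupling_fraction' must lie in [0, 1]", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be finite and >= 0", call. = FALSE)
  structure(list(rate_co = rate_co, rate_oc = rate_oc, rate_oi = rate_oi,
                 rate_ic = rate_ic, unitary_current = unitary_current,
                 coupling_fraction = coupling_fraction, noise_sd = noise_sd),
            class = "gating_model")
}

#' @export
print.gating_model <- function(x, ...) {
  cat("Two-protomer gating model (C <-> O -> I per protomer)\n")
  cat(sprintf("  rates (ms^-1): C->O %.4g, O->C %.4g, O->I %.4g, I->C %.4g\n",
              x$rate_co, x$rate_oc, x$rate_oi, x$rate_ic))
  cat(sprintf("  unitary current i = %.3g pA, coupling fraction phi = %.3g, noise SD = %.3g pA\n",
              x$unitary_current, x$coupling_fraction, x$noise_sd))
  invisible(x)
}

#' Voltage-step stimulation protocol
#'
#' Episodic step protocol metadata for simulated or recorded sweeps. The
#' defaults follow a standard cell-attached single-channel protocol:
#' repeated depolarizations to -40 mV from a holding potential of -100 mV,
#' digitized at 30 kHz.
#'
#' @param holding_mv holding potential (mV).
#' @param step_mv test potential (mV).
#' @param step_ms step duration (ms).
#' @param sample_rate_hz digitization rate (Hz).
#' @param n_sweeps number of sweeps.
#'
#' @return An object of class `step_protocol`.
#' @examples
#' step_protocol(step_mv = -20, n_sweeps = 100)
#' @export
step_protocol <- function(holding_mv = -100, step_mv = -40, step_ms = 50,
                          sample_rate_hz = 30000, n_sweeps = 100) {
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("'sample_rate_hz' must be > 0", call. = FALSE)
  if (!is.finite(step_ms) || step_ms <= 0)
    stop("'step_ms' must be > 0", call. = FALSE)
  n_sweeps <- as.integer(n_sweeps)
  if (is.na(n_sweeps) || n_sweeps < 1)
    stop("'n_sweeps' must be >= 1", call. = FALSE)
  if (round(step_ms * sample_rate_hz / 1000) < 2)
    stop("protocol too short: step must hold at least 2 samples",
         call. = FALSE)
  structure(list(holding_mv = holding_mv, step_mv = step_mv,
                 step_ms = step_ms, sample_rate_hz = sample_rate_hz,
                 n_sweeps = n_sweeps),
            class = "step_protocol")
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf(
    "Step protocol: %g -> %g mV, %g ms at %g kHz, %d sweeps (%d samples/sweep)\n",
    x$holding_mv, x$step_mv, x$step_ms, x$sample_rate_hz / 1000,
    x$n_sweeps, n_samples(x)))
  invisible(x)
}

n_samples <- function(protocol) {
  as.integer(round(protocol$step_ms * protocol$sample_rate_hz / 1000))
}

#' Construct a sweep set
#'
#' Container for episodic current sweeps: a sweeps-by-samples current
#' matrix with its protocol and, for simulated data, the noise-free
#' conductance level (0, 1 or 2 open protomers) per sample.
#'
#' @param sweeps numeric matrix, `n_sweeps` rows by `n_samples` columns (pA).
#' @param protocol a [step_protocol()].
#' @param ground_truth optional integer matrix of identical shape giving the
#'   true conductance level per sample.
#'
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, protocol, ground_truth = NULL) {
  sweeps <- as.matrix(sweeps)
  stopifnot(inherits(protocol, "step_protocol"))
  if (nrow(sweeps) != protocol$n_sweeps)
    stop("row count does not match protocol n_sweeps", call. = FALSE)
  if (ncol(sweeps) != n_samples(protocol))
    stop("column count does not match protocol step_ms * sample_rate",
         call. = FALSE)
  if (!is.null(ground_truth)) {
    ground_truth <- as.matrix(ground_truth)
    if (!identical(dim(ground_truth), dim(sweeps)))
      stop("'ground_truth' must have the same shape as 'sweeps'",
           call. = FALSE)
  }
  structure(list(sweeps = sweeps, protocol = protocol,
                 ground_truth = ground_truth),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("Sweep set: %d sweeps x %d samples (%g ms at %g kHz)%s\n",
              nrow(x$sweeps), ncol(x$sweeps), x$protocol$step_ms,
              x$protocol$sample_rate_hz / 1000,
              if (is.null(x$ground_truth)) "" else ", with ground truth"))
  invisible(x)
}

#' Time axis of a sweep set
#'
#' @param x a `sweep_set` or `step_protocol`.
#' @return Sample times in ms from step onset (sample 0 at onset).
#' @export
sweep_times <- function(x) {
  protocol <- if (inherits(x, "sweep_set")) x$protocol else x
  stopifnot(inherits(protocol, "step_protocol"))
  (seq_len(n_samples(protocol)) - 1) * 1000 / protocol$sample_rate_hz
}
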