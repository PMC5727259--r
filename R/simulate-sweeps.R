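# Continuous-time Markov simulation of dimer gating and discretization to
# the digitizer grid. States are coded 1 = C (closed), 2 = O (open),
# 3 = I (inactivated).

# Event-driven (Gillespie) trajectory of one 3-state chain starting in C.
# Returns jump times (starting at 0) and the state entered at each time;
# the last state persists to t_end.
sim_chain <- function(rate_co, rate_oc, rate_oi, rate_ic, t_end) {
  times <- 0
  states <- 1L
  t <- 0
  s <- 1L
  repeat {
    if (s == 1L) {
      total <- rate_co
      if (total <= 0) break
      t <- t + rexp(1, total)
      if (t >= t_end) break
      s <- 2L
    } else if (s == 2L) {
      total <- rate_oc + rate_oi
      if (total <= 0) break
      t <- t + rexp(1, total)
      if (t >= t_end) break
      s <- if (runif(1) < rate_oc / total) 1L else 3L
    } else {
      total <- rate_ic
      if (total <= 0) break
      t <- t + rexp(1, total)
      if (t >= t_end) break
      s <- 1L
    }
    times <- c(times, t)
    states <- c(states, s)
  }
  list(times = times, states = states)
}

# Majority-occupancy discretization: assign to each of n samples of width dt
# the state occupying the largest share of its interval. Ties break toward
# the lower state code (C before O before I).
discretize_chain <- function(times, states, n, dt) {
  occ <- matrix(0, nrow = n, ncol = 3L)
  t_end <- n * dt
  k <- length(times)
  bounds <- c(times, t_end)
  for (j in seq_len(k)) {
    a <- bounds[j]
    b <- bounds[j + 1L]
    if (b <= a) next
    s <- states[j]
    s1 <- min(floor(a / dt), n - 1)
    s2 <- min(floor((b - 1e-12) / dt), n - 1)
    if (s1 == s2) {
      occ[s1 + 1, s] <- occ[s1 + 1, s] + (b - a)
    } else {
      occ[s1 + 1, s] <- occ[s1 + 1, s] + (s1 + 1) * dt - a
      occ[s2 + 1, s] <- occ[s2 + 1, s] + b - s2 * dt
      if (s2 > s1 + 1) {
        idx <- (s1 + 2):s2
        occ[idx, s] <- occ[idx, s] + dt
      }
    }
  }
  max.col(occ, ties.method = "first")
}

#' Simulate episodic single-channel sweeps from a dimer
#'
#' Generates current sweeps for one channel dimer under a voltage-step
#' protocol. For each sweep the dimer is drawn \emph{coupled} with
#' probability `coupling_fraction`: a coupled dimer evolves as a single
#' continuous-time Markov chain over \{C, O, I\} whose open state conducts
#' twice the unitary current (concerted openings, direct closed to
#' double-level transitions); an uncoupled dimer evolves as two independent
#' chains, each conducting the unitary current when open. Both protomers
#' start closed at step onset. Trajectories are simulated event-by-event
#' with exponential waiting times, then discretized so each sample carries
#' the state occupying the majority of its interval; Gaussian noise of SD
#' `noise_sd` is added to the current.
#'
#' @param model a [gating_model()].
#' @param protocol a [step_protocol()].
#' @param seed integer seed; identical `(model, protocol, seed)` give
#'   bit-identical output.
#'
#' @return A [sweep_set()] whose `ground_truth` holds the noise-free
#'   conductance level (0, 1 or 2) per sample.
#' @examples
#' ss <- simulate_sweeps(gating_model(coupling_fraction = 1, noise_sd = 0),
#'                       step_protocol(step_ms = 20, n_sweeps = 5), seed = 1)
#' unique(as.vector(ss$ground_truth))  # concerted unit: levels 0 and 2 only
#' @export
simulate_sweeps <- function(model, protocol, seed = 1L) {
  stopifnot(inherits(model, "gating_model"),
            inherits(protocol, "step_protocol"))
  set.seed(seed)
  ns <- n_samples(protocol)
  dt <- 1000 / protocol$sample_rate_hz   # sample period, ms
  t_end <- ns * dt
  nsw <- protocol$n_sweeps
  levels <- matrix(0L, nrow = nsw, ncol = ns)
  coupled <- runif(nsw) < model$coupling_fraction
  for (sw in seq_len(nsw)) {
    if (coupled[sw]) {
      ch <- sim_chain(model$rate_co, model$rate_oc, model$rate_oi,
                      model$rate_ic, t_end)
      st <- discretize_chain(ch$times, ch$states, ns, dt)
      levels[sw, ] <- 2L * (st == 2L)
    } else {
      ch1 <- sim_chain(model$rate_co, model$rate_oc, model$rate_oi,
                       model$rate_ic, t_end)
      ch2 <- sim_chain(model$rate_co, model$rate_oc, model$rate_oi,
                       model$rate_ic, t_end)
      st1 <- discretize_chain(ch1$times, ch1$states, ns, dt)
      st2 <- discretize_chain(ch2$times, ch2$states, ns, dt)
      levels[sw, ] <- (st1 == 2L) + (st2 == 2L)
    }
  }
  current <- levels * model$unitary_current
  if (model$noise_sd > 0)
    current <- current + matrix(rnorm(length(current), sd = model$noise_sd),
                                nrow = nsw)
  sweep_set(current, protocol, ground_truth = levels)
}
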