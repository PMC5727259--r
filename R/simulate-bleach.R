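#' Photobleaching population parameters
#'
#' Parameters for simulating a population of surface-immobilized molecules
#' imaged until their fluorophores bleach, as in single-molecule pull-down
#' (SiMPull). Each molecule carries `n_subunits` fluorophore tags, each
#' independently fluorescently active (matured) with probability
#' `p_active`; each active fluorophore bleaches at an independent
#' exponential time.
#'
#' The default maturation probability of 0.7 reflects the commonly used
#' figure that only about 70\% of GFP is fluorescently active, which
#' censors observable step counts.
#'
#' @param n_subunits true subunits (tags) per molecule, integer >= 1.
#' @param p_active per-subunit fluorophore maturation probability in
#'   \[0, 1\].
#' @param bleach_rate per-fluorophore exponential bleaching rate (s^-1).
#' @param frame_interval_s camera frame period (s).
#' @param duration_s movie length (s); the default covers eight mean
#'   fluorophore lifetimes so essentially all bleaching is observed.
#' @param unit_intensity intensity per active fluorophore (a.u.).
#' @param noise_sd per-frame Gaussian intensity noise SD (a.u.).
#' @param n_molecules population size.
#'
#' @return An object of class `bleach_population_params`.
#' @export
bleach_population_params <- function(n_subunits = 2, p_active = 0.7,
                                     bleach_rate = 0.2,
                                     frame_interval_s = 0.1,
                                     duration_s = 8 / bleach_rate,
                                     unit_intensity = 1,
                                     noise_sd = 0.1,
                                     n_molecules = 2000) {
  n_subunits <- as.integer(n_subunits)
  n_molecules <- as.integer(n_molecules)
  if (is.na(n_subunits) || n_subunits < 1)
    stop("'n_subunits' must be an integer >= 1", call. = FALSE)
  if (!is.finite(p_active) || p_active < 0 || p_active > 1)
    stop("'p_active' must lie in [0, 1]", call. = FALSE)
  if (!is.finite(bleach_rate) || bleach_rate <= 0)
    stop("'bleach_rate' must be > 0", call. = FALSE)
  if (!is.finite(frame_interval_s) || frame_interval_s <= 0)
    stop("'frame_interval_s' must be > 0", call. = FALSE)
  if (!is.finite(duration_s) || duration_s < 2 * frame_interval_s)
    stop("'duration_s' must cover at least 2 frames", call. = FALSE)
  if (!is.finite(unit_intensity) || unit_intensity <= 0)
    stop("'unit_intensity' must be > 0", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be >= 0", call. = FALSE)
  if (is.na(n_molecules) || n_molecules < 1)
    stop("'n_molecules' must be >= 1", call. = FALSE)
  structure(list(n_subunits = n_subunits, p_active = p_active,
                 bleach_rate = bleach_rate,
                 frame_interval_s = frame_interval_s,
                 duration_s = duration_s, unit_intensity = unit_intensity,
                 noise_sd = noise_sd, n_molecules = n_molecules),
            class = "bleach_population_params")
}

#' Construct a single photobleaching trace
#'
#' @param molecule_id identifier.
#' @param intensity numeric vector of per-frame fluorescence (a.u.),
#'   length >= 2.
#' @param frame_interval_s frame period (s).
#' @param true_step_count optional true number of active fluorophores.
#' @param true_step_times optional true bleach times (s); when both truth
#'   fields are given their lengths must agree.
#'
#' @return An object of class `bleach_trace`.
#' @export
bleach_trace <- function(molecule_id, intensity, frame_interval_s,
                         true_step_count = NULL, true_step_times = NULL) {
  intensity <- as.numeric(intensity)
  if (length(intensity) < 2)
    stop("'intensity' must have length >= 2", call. = FALSE)
  if (!is.null(true_step_count) && !is.null(true_step_times) &&
      true_step_count != length(true_step_times))
    stop("'true_step_count' must equal length(true_step_times)",
         call. = FALSE)
  structure(list(molecule_id = molecule_id, intensity = intensity,
                 frame_interval_s = frame_interval_s,
                 true_step_count = true_step_count,
                 true_step_times = true_step_times),
            class = "bleach_trace")
}

#' @export
print.bleach_trace <- function(x, ...) {
  cat(sprintf("Bleach trace '%s': %d frames at %g s%s\n", x$molecule_id,
              length(x$intensity), x$frame_interval_s,
              if (is.null(x$true_step_count)) ""
              else sprintf(", true steps = %d", x$true_step_count)))
  invisible(x)
}

#' Simulate a photobleaching population
#'
#' Draws, for each molecule, the number of active fluorophores
#' k ~ Binomial(`n_subunits`, `p_active`); each active fluorophore bleaches
#' at an independent exponential time with rate `bleach_rate`. The
#' per-frame intensity is `unit_intensity` times the number of surviving
#' fluorophores plus Gaussian noise. Molecules with k = 0 are never visible
#' in a real experiment; they are retained and flagged (`detectable =
#' FALSE`) so both conditional and unconditional tallies are possible.
#'
#' @param params a [bleach_population_params()].
#' @param seed integer seed.
#' @param traces if `FALSE`, skip intensity-trace synthesis and return only
#'   the per-molecule truth table (fast path for large populations where
#'   only step counts are needed).
#'
#' @return A list with elements `traces` (list of [bleach_trace()], or
#'   `NULL` when `traces = FALSE`) and `molecules`, a data frame with one
#'   row per molecule: `molecule_id`, `true_step_count`, `detectable`.
#' @examples
#' pop <- simulate_bleach_population(
#'   bleach_population_params(n_molecules = 50), seed = 1)
#' table(pop$molecules$true_step_count)
#' @export
simulate_bleach_population <- function(params, seed = 1L, traces = TRUE) {
  stopifnot(inherits(params, "bleach_population_params"))
  set.seed(seed)
  nm <- params$n_molecules
  k <- rbinom(nm, params$n_subunits, params$p_active)
  # bleach times, one row per molecule, Inf marks an inactive tag slot
  bt <- matrix(Inf, nrow = nm, ncol = params$n_subunits)
  active_total <- sum(k)
  draws <- rexp(active_total, rate = params$bleach_rate)
  pos <- 1L
  for (m in seq_len(nm)) {
    if (k[m] > 0) {
      bt[m, seq_len(k[m])] <- sort(draws[pos:(pos + k[m] - 1L)])
      pos <- pos + k[m]
    }
  }
  molecules <- data.frame(molecule_id = sprintf("mol%05d", seq_len(nm)),
                          true_step_count = k,
                          detectable = k > 0,
                          stringsAsFactors = FALSE)
  out_traces <- NULL
  if (traces) {
    n_frames <- max(2L, as.integer(floor(params$duration_s /
                                           params$frame_interval_s)))
    frame_t <- (seq_len(n_frames) - 1) * params$frame_interval_s
    # surviving fluorophores per frame, vectorized over tag slots
    surv <- matrix(0L, nrow = nm, ncol = n_frames)
    for (j in seq_len(params$n_subunits))
      surv <- surv + outer(bt[, j], frame_t, `>`)
    intens <- params$unit_intensity * surv
    if (params$noise_sd > 0)
      intens <- intens + matrix(rnorm(length(intens), sd = params$noise_sd),
                                nrow = nm)
    out_traces <- lapply(seq_len(nm), function(m) {
      tst <- bt[m, is.finite(bt[m, ])]
      bleach_trace(molecules$molecule_id[m], intens[m, ],
                   params$frame_interval_s,
                   true_step_count = k[m],
                   true_step_times = if (k[m] > 0) tst else numeric(0))
    })
  }
  list(traces = out_traces, molecules = molecules)
}
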