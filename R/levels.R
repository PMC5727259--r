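#' Idealization parameters
#'
#' @param segment_ms segment length in ms (default 0.2 ms, i.e. 6 samples
#'   at 30 kHz).
#' @param coupling_window_segments maximum number of segments (inclusive,
#'   0-based offset) from event onset to the first double-level segment for
#'   an opening to count as coupled; the default 2 encodes the 0.4-ms
#'   simultaneity window.
#' @param levels optional [level_estimate()] fixing the amplitudes.
#'
#' @return An object of class `idealization_params`.
#' @export
idealization_params <- function(segment_ms = 0.2,
                                coupling_window_segments = 2,
                                levels = NULL) {
  if (!is.finite(segment_ms) || segment_ms <= 0)
    stop("'segment_ms' must be > 0", call. = FALSE)
  coupling_window_segments <- as.integer(coupling_window_segments)
  if (is.na(coupling_window_segments) || coupling_window_segments < 1)
    stop("'coupling_window_segments' must be >= 1", call. = FALSE)
  if (!is.null(levels)) stopifnot(inherits(levels, "level_estimate"))
  structure(list(segment_ms = segment_ms,
                 coupling_window_segments = coupling_window_segments,
                 levels = levels),
            class = "idealization_params")
}

#' Conductance level estimate
#'
#' Closed-baseline and open-level amplitudes for a patch holding a channel
#' pair: `i1` is the single-open (O1) level and `i2` the double-open (O2)
#' level. Both open levels must sit on the same side of baseline, with
#' `i2` farther from baseline than `i1`.
#'
#' @param baseline closed-level current (pA).
#' @param i1 single-open (O1) amplitude (pA).
#' @param i2 double-open (O2) amplitude (pA).
#' @param i2_extrapolated flag set when `i2` was not observed and was taken
#'   as `2 * i1` under the dimer assumption.
#'
#' @return An object of class `level_estimate`.
#' @export
level_estimate <- function(baseline, i1, i2, i2_extrapolated = FALSE) {
  if (!all(is.finite(c(baseline, i1, i2))))
    stop("levels must be finite", call. = FALSE)
  if (abs(i2 - baseline) <= abs(i1 - baseline))
    stop("'i2' must lie farther from baseline than 'i1'", call. = FALSE)
  if (sign(i1 - baseline) != sign(i2 - baseline))
    stop("'i1' and 'i2' must lie on the same side of baseline",
         call. = FALSE)
  structure(list(baseline = baseline, i1 = i1, i2 = i2,
                 i2_extrapolated = i2_extrapolated),
            class = "level_estimate")
}

#' @export
print.level_estimate <- function(x, ...) {
  cat(sprintf("Levels (pA): baseline %.4g, O1 %.4g, O2 %.4g%s\n",
              x$baseline, x$i1, x$i2,
              if (x$i2_extrapolated) " (O2 = 2*O1, extrapolated)" else ""))
  invisible(x)
}

# Local maxima of a density estimate, ordered by height.
density_modes <- function(d) {
  y <- d$y
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                 y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_peak)
  idx[order(y[idx], decreasing = TRUE)]
}

#' Estimate conductance levels from an amplitude histogram
#'
#' Pools all samples of a sweep set into an all-points amplitude histogram
#' and locates the closed baseline and the two open-level amplitudes.
#' The baseline is the dominant histogram mode, refined as the median of
#' samples near it; a noise exclusion band of 3 robust noise SDs
#' (median absolute deviation around baseline) is drawn, and the two most
#' populated local modes beyond the band on the open-current side give O1
#' and O2, each refined as the median of the samples assigned to it. If
#' only one open mode is found, O2 is extrapolated as twice O1 under the
#' dimer assumption and flagged.
#'
#' @param sweeps a [sweep_set()].
#' @param open_sign direction of open current relative to baseline:
#'   `"auto"` (side holding more out-of-band samples), `"negative"`
#'   (inward) or `"positive"`.
#'
#' @return A [level_estimate()].
#' @examples
#' ss <- simulate_sweeps(gating_model(coupling_fraction = 0, rate_co = 0.5,
#'                                    noise_sd = 0),
#'                       step_protocol(step_ms = 20, n_sweeps = 50), seed = 2)
#' estimate_levels(ss)
#' @export
estimate_levels <- function(sweeps, open_sign = c("auto", "negative",
                                                  "positive")) {
  stopifnot(inherits(sweeps, "sweep_set"))
  open_sign <- match.arg(open_sign)
  x <- as.vector(sweeps$sweeps)
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)

  d <- density(x, n = 1024)
  modes <- density_modes(d)
  base0 <- d$x[modes[1]]
  # refine baseline on samples close to the dominant mode
  halfwin <- max(diff(range(x)) / 20, 1e-9)
  near <- x[abs(x - base0) <= halfwin]
  baseline <- median(near)
  # robust noise SD: first pass over all samples anchors the window so the
  # estimate is not truncated when openings are sparse or absent
  mad0 <- mad(x, center = baseline)
  w <- max(halfwin, 4 * mad0)
  noise_sd <- mad(x[abs(x - baseline) <= w], center = baseline)
  band <- 3 * max(noise_sd, 1e-9)

  open <- x[abs(x - baseline) > band]
  if (length(open) == 0) stop("no openings detected", call. = FALSE)
  if (open_sign == "auto") {
    open_sign <- if (sum(open < baseline) >= sum(open > baseline))
      "negative" else "positive"
  }
  open <- if (open_sign == "negative") open[open < baseline]
  else open[open > baseline]
  if (length(open) == 0) stop("no openings detected", call. = FALSE)

  if (length(unique(open)) == 1) {
    i1 <- open[1]
    return(level_estimate(baseline, i1, baseline + 2 * (i1 - baseline),
                          i2_extrapolated = TRUE))
  }
  do <- density(open, n = 1024)
  omodes <- density_modes(do)
  peaks <- do$x[omodes]
  # the exclusion cut truncates the baseline noise tail and can leave an
  # edge artifact next to the band; true open levels sit well beyond it
  peaks <- peaks[abs(peaks - baseline) >= 2 * band]
  if (length(peaks) >= 2) {
    # drop secondary maxima of the same level: peaks must be separated by
    # more than the noise band to count as distinct conductances
    keep <- rep(TRUE, length(peaks))
    for (i in seq_along(peaks)[-1])
      keep[i] <- all(abs(peaks[i] - peaks[seq_len(i - 1)][
        keep[seq_len(i - 1)]]) > band)
    peaks <- peaks[keep]
  }
  if (length(peaks) >= 2) {
    two <- peaks[1:2]
    # assign each open sample to its nearest peak and refine by median
    assign1 <- abs(open - two[1]) <= abs(open - two[2])
    a1 <- median(open[assign1])
    a2 <- median(open[!assign1])
    amps <- sort(c(a1, a2), decreasing = (open_sign == "negative"))
    i1 <- amps[1]
    i2 <- amps[2]
    # degenerate split (both medians effectively one level): fall back
    if (abs(i2 - i1) < band) {
      i1 <- median(open)
      return(level_estimate(baseline, i1, baseline + 2 * (i1 - baseline),
                            i2_extrapolated = TRUE))
    }
    level_estimate(baseline, i1, i2)
  } else if (length(peaks) == 1) {
    sel <- open[abs(open - peaks[1]) <= max(band, diff(range(open)) / 10)]
    i1 <- median(if (length(sel)) sel else open)
    level_estimate(baseline, i1, baseline + 2 * (i1 - baseline),
                   i2_extrapolated = TRUE)
  } else {
    # everything past the band is just the truncated noise tail
    stop("no openings detected", call. = FALSE)
  }
}
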