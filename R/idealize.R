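#' Idealize sweeps into per-segment conductance levels
#'
#' Segments each sweep into fixed-length windows (0.2 ms by default) and
#' assigns each segment the conductance level whose amplitude is nearest
#' to the segment's mean current: 0 (closed), 1 (single-open O1) or
#' 2 (double-open O2). Exact ties break toward the lower level. A trailing
#' partial segment is dropped.
#'
#' @param sweeps a [sweep_set()].
#' @param levels a [level_estimate()]; defaults to `params$levels`, or is
#'   estimated from the data with [estimate_levels()] when absent.
#' @param params an [idealization_params()].
#'
#' @return A list of `idealized_sweep` objects, each with fields `labels`
#'   (integer per-segment levels), `segment_ms` and `sweep_id`.
#' @export
idealize <- function(sweeps, levels = NULL,
                     params = idealization_params()) {
  stopifnot(inherits(sweeps, "sweep_set"),
            inherits(params, "idealization_params"))
  if (is.null(levels)) levels <- params$levels
  if (is.null(levels)) levels <- estimate_levels(sweeps)
  stopifnot(inherits(levels, "level_estimate"))
  spms <- sweeps$protocol$sample_rate_hz / 1000      # samples per ms
  n_per_seg <- as.integer(round(params$segment_ms * spms))
  if (n_per_seg < 2)
    stop("'segment_ms' must span at least 2 sample periods", call. = FALSE)
  ns <- ncol(sweeps$sweeps)
  n_seg <- ns %/% n_per_seg
  if (n_seg < 1) stop("sweeps shorter than one segment", call. = FALSE)
  used <- n_seg * n_per_seg
  amps <- c(levels$baseline, levels$i1, levels$i2)
  lapply(seq_len(nrow(sweeps$sweeps)), function(sw) {
    m <- matrix(sweeps$sweeps[sw, seq_len(used)], nrow = n_per_seg)
    seg_means <- colMeans(m)
    dist <- abs(outer(seg_means, amps, `-`))
    labels <- max.col(-dist, ties.method = "first") - 1L
    structure(list(labels = labels, segment_ms = params$segment_ms,
                   sweep_id = sw),
              class = "idealized_sweep")
  })
}

#' Ground-truth segment labels of a simulated sweep set
#'
#' Collapses the noise-free per-sample conductance levels of a simulated
#' [sweep_set()] to per-segment labels with the same rule [idealize()]
#' applies to measured currents: the level nearest the segment's mean
#' (exact cutoffs at 0.5 and 1.5 open protomers, ties toward the lower
#' level). On noiseless data idealization reproduces these labels exactly;
#' under noise they are the oracle it is compared against.
#'
#' @param sweeps a [sweep_set()] carrying `ground_truth`.
#' @param params an [idealization_params()].
#' @return A list of `idealized_sweep` objects.
#' @export
ground_truth_labels <- function(sweeps, params = idealization_params()) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (is.null(sweeps$ground_truth))
    stop("sweep set has no ground truth", call. = FALSE)
  spms <- sweeps$protocol$sample_rate_hz / 1000
  n_per_seg <- as.integer(round(params$segment_ms * spms))
  n_seg <- ncol(sweeps$ground_truth) %/% n_per_seg
  used <- n_seg * n_per_seg
  lapply(seq_len(nrow(sweeps$ground_truth)), function(sw) {
    m <- matrix(sweeps$ground_truth[sw, seq_len(used)], nrow = n_per_seg)
    mean_level <- colMeans(m)
    labels <- (mean_level > 0.5) + (mean_level > 1.5)
    structure(list(labels = as.integer(labels),
                   segment_ms = params$segment_ms, sweep_id = sw),
              class = "idealized_sweep")
  })
}

#' Extract openings from idealized sweeps and classify coupling
#'
#' Scans each idealized sweep for openings: an event starts at the first
#' non-closed segment following a closed segment (or the sweep start) and
#' ends at the next closed segment. Events reaching the double level are
#' classified \emph{coupled} when the first level-2 segment lies within
#' the coupling window of the event onset (0-based offset less than or
#' equal to `coupling_window_segments`, i.e. within 0.4 ms at the
#' defaults) and \emph{uncoupled_stacked} otherwise; events peaking at
#' level 1 are \emph{single}. A stacked event represents two channels
#' opening one after the other, so downstream tallies count it as two
#' single-level openings (one at the event onset, one at the first
#' level-2 segment).
#'
#' @param ideal list of `idealized_sweep` objects from [idealize()].
#' @param params an [idealization_params()].
#'
#' @return An `event_table`: a data frame with columns `sweep_id`,
#'   `onset_segment` (0-based), `max_level`, `segments_to_level2` (NA for
#'   single events), `classification`, `duration_segments`, `truncated`.
#' @examples
#' sw <- structure(list(labels = c(0L, 2L, 2L, 0L), segment_ms = 0.2,
#'                      sweep_id = 1), class = "idealized_sweep")
#' extract_events(list(sw))
#' @export
extract_events <- function(ideal, params = idealization_params()) {
  stopifnot(inherits(params, "idealization_params"))
  rows <- lapply(ideal, function(sw) {
    labels <- sw$labels
    n <- length(labels)
    open <- labels > 0L
    if (!any(open)) return(NULL)
    onset <- which(open & !c(FALSE, open[-n]))
    ends <- which(!open & c(FALSE, open[-n])) # first closed segment after
    truncated <- length(ends) < length(onset)
    if (truncated) ends <- c(ends, n + 1L)
    data.frame(
      sweep_id = sw$sweep_id,
      onset_segment = onset - 1L,
      end_segment = ends - 1L,
      truncated = c(rep(FALSE, length(onset) - 1L), truncated),
      stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    ev <- data.frame(sweep_id = integer(0), onset_segment = integer(0),
                     max_level = integer(0), segments_to_level2 = integer(0),
                     classification = character(0),
                     duration_segments = integer(0), truncated = logical(0),
                     stringsAsFactors = FALSE)
    class(ev) <- c("event_table", "data.frame")
    return(ev)
  }
  label_list <- setNames(lapply(ideal, `[[`, "labels"),
                         vapply(ideal, function(s) as.character(s$sweep_id),
                                ""))
  n_ev <- nrow(rows)
  max_level <- integer(n_ev)
  seg2 <- rep(NA_integer_, n_ev)
  for (e in seq_len(n_ev)) {
    labels <- label_list[[as.character(rows$sweep_id[e])]]
    span <- (rows$onset_segment[e] + 1L):rows$end_segment[e]
    lab <- labels[span]
    max_level[e] <- max(lab)
    if (max_level[e] == 2L) seg2[e] <- which(lab == 2L)[1] - 1L
  }
  classification <- ifelse(
    max_level == 2L,
    ifelse(seg2 <= params$coupling_window_segments, "coupled",
           "uncoupled_stacked"),
    "single")
  ev <- data.frame(
    sweep_id = rows$sweep_id,
    onset_segment = rows$onset_segment,
    max_level = max_level,
    segments_to_level2 = seg2,
    classification = classification,
    duration_segments = rows$end_segment - rows$onset_segment,
    truncated = rows$truncated,
    stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Tally openings against time within the depolarizing step
#'
#' Bins opening onsets over the step duration. Level-2 counts are coupled
#' events, binned at their onset. Level-1 counts are single events plus
#' two contributions per uncoupled stacked event (one at the event onset
#' and one at the first level-2 segment), since a stacked double-level
#' event is two non-simultaneous single-channel openings.
#'
#' @param events an `event_table` from [extract_events()].
#' @param bin_ms bin width (ms); must be at least one segment.
#' @param step_ms step duration (ms).
#' @param segment_ms segment length used at idealization (ms).
#'
#' @return A data frame with columns `time_ms` (bin left edge), `level1`
#'   and `level2` counts; bins tile \[0, `step_ms`).
#' @export
openings_vs_time <- function(events, bin_ms = 1, step_ms,
                             segment_ms = 0.2) {
  if (bin_ms < segment_ms)
    stop("'bin_ms' must be >= segment_ms", call. = FALSE)
  edges <- seq(0, step_ms, by = bin_ms)
  if (edges[length(edges)] < step_ms) edges <- c(edges, step_ms)
  n_bin <- length(edges) - 1L
  lvl1 <- lvl2 <- rep(0L, n_bin)
  if (nrow(events) > 0) {
    onset_ms <- events$onset_segment * segment_ms
    if (any(onset_ms >= step_ms))
      stop("event onset beyond step duration", call. = FALSE)
    bin_of <- function(t_ms) pmin(findInterval(t_ms, edges), n_bin)
    cp <- events$classification == "coupled"
    sg <- events$classification == "single"
    st <- events$classification == "uncoupled_stacked"
    if (any(cp)) lvl2 <- tabulate(bin_of(onset_ms[cp]), nbins = n_bin)
    ones <- c(onset_ms[sg],           # single openings at their onset
              onset_ms[st],           # first channel of a stacked pair
              (events$onset_segment[st] + events$segments_to_level2[st]) *
                segment_ms)           # second channel joins later
    if (any(ones >= step_ms))
      stop("event onset beyond step duration", call. = FALSE)
    if (length(ones)) lvl1 <- tabulate(bin_of(ones), nbins = n_bin)
  }
  data.frame(time_ms = edges[-length(edges)], level1 = lvl1, level2 = lvl2)
}

#' Ensemble average of a sweep set
#'
#' Pointwise mean current across sweeps, the macroscopic current expected
#' from summing many single-channel records.
#'
#' @param sweeps a [sweep_set()].
#' @return A data frame with columns `time_ms` and `mean_pA`.
#' @export
ensemble_average <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (nrow(sweeps$sweeps) < 1) stop("empty sweep set", call. = FALSE)
  data.frame(time_ms = sweep_times(sweeps),
             mean_pA = colMeans(sweeps$sweeps))
}
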