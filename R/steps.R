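# Change-point step counting for photobleaching traces.
#
# Detection is greedy binary segmentation of a piecewise-constant model:
# repeatedly insert the change-point giving the largest drop in residual
# sum of squares, accept it while the Gaussian BIC (one mean per segment
# plus a shared variance) improves, then keep only downward jumps of
# sufficient size relative to the unit step.

# Best single split of y[lo..hi] (1-based, inclusive): returns the index j
# (split between j and j+1) minimizing total RSS, with the RSS gain.
best_split <- function(cs, cs2, lo, hi) {
  n <- hi - lo + 1L
  if (n < 2L) return(NULL)
  sum_all <- cs[hi + 1L] - cs[lo]
  sq_all <- cs2[hi + 1L] - cs2[lo]
  rss0 <- sq_all - sum_all^2 / n
  j <- lo:(hi - 1L)
  nl <- j - lo + 1L
  sl <- cs[j + 1L] - cs[lo]
  sr <- sum_all - sl
  rss1 <- (cs2[j + 1L] - cs2[lo] - sl^2 / nl) +
    (sq_all - (cs2[j + 1L] - cs2[lo]) - sr^2 / (n - nl))
  k <- which.min(rss1)
  list(at = j[k], gain = rss0 - rss1[k], rss_after = rss1[k],
       rss_before = rss0)
}

# Greedy binary segmentation with BIC stopping. Returns sorted 1-based
# split indices (change between index and index + 1).
binseg_changepoints <- function(y) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  segs <- list(c(1L, n))
  splits <- integer(0)
  rss <- cs2[n + 1L] - cs[n + 1L]^2 / n
  bic <- function(rss, k) {
    # each added segment costs two parameters (its level and the location
    # of the new change-point) plus one shared variance; the plain
    # one-parameter count over-segments long noisy traces badly
    n * log(max(rss, 1e-300) / n) + 2 * k * log(n)
  }
  current_bic <- bic(rss, 1L)
  repeat {
    best <- NULL
    best_i <- 0L
    for (i in seq_along(segs)) {
      sp <- best_split(cs, cs2, segs[[i]][1], segs[[i]][2])
      if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
        best <- sp
        best_i <- i
      }
    }
    if (is.null(best) || best$gain <= 0) break
    new_rss <- rss - best$gain
    new_bic <- bic(new_rss, length(segs) + 1L)
    if (new_bic >= current_bic) break
    seg <- segs[[best_i]]
    segs[[best_i]] <- c(seg[1], best$at)
    segs[[length(segs) + 1L]] <- c(best$at + 1L, seg[2])
    splits <- c(splits, best$at)
    rss <- new_rss
    current_bic <- new_bic
  }
  sort(splits)
}

#' Count photobleaching steps in a single-molecule trace
#'
#' Fits a piecewise-constant model to the intensity trace by greedy binary
#' change-point segmentation with a Bayesian information criterion stopping
#' rule (Gaussian likelihood; each added segment is charged two parameters,
#' its level and its change-point location, plus one shared variance),
#' then counts the downward jumps. Small downward jumps and all upward
#' jumps (blinking recovery) are discarded: a jump is retained only if its
#' magnitude is at least `min_step_fraction` times the unit step estimate
#' (the median downward jump magnitude).
#'
#' @param trace a [bleach_trace()] (or a bare numeric intensity vector, in
#'   which case `frame_interval_s` defaults to 1).
#' @param min_step_fraction minimum retained jump size as a fraction of the
#'   unit step estimate.
#'
#' @return A list with `step_count`, `step_times` (s, at the boundary
#'   between the last frame of the old level and the first frame of the
#'   new one) and `step_sizes` (intensity drops, positive numbers).
#' @examples
#' tr <- bleach_trace("m1", c(2, 2, 2, 1, 1, 1, 0, 0, 0), 0.1)
#' detect_steps(tr)$step_count
#' @export
detect_steps <- function(trace, min_step_fraction = 0.5) {
  if (is.numeric(trace)) trace <- bleach_trace("trace", trace, 1)
  stopifnot(inherits(trace, "bleach_trace"))
  y <- trace$intensity
  if (any(!is.finite(y))) stop("non-finite intensities", call. = FALSE)
  if (length(y) < 4) stop("trace must have >= 4 frames", call. = FALSE)
  splits <- binseg_changepoints(y)
  if (length(splits) == 0)
    return(list(step_count = 0L, step_times = numeric(0),
                step_sizes = numeric(0)))
  bounds <- c(0L, splits, length(y))
  seg_means <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(y[(bounds[i] + 1L):bounds[i + 1L]]), 0)
  jumps <- diff(seg_means)              # negative = bleaching step
  down <- which(jumps < 0)
  if (length(down) == 0)
    return(list(step_count = 0L, step_times = numeric(0),
                step_sizes = numeric(0)))
  unit <- median(-jumps[down])
  keep <- down[-jumps[down] >= min_step_fraction * unit]
  list(step_count = length(keep),
       step_times = splits[keep] * trace$frame_interval_s,
       step_sizes = -jumps[keep])
}

#' Tally step counts into a histogram
#'
#' @param results integer vector of per-molecule step counts (e.g. from
#'   [detect_steps()] or the generator's true counts).
#'
#' @return A `step_count_histogram`: list with `counts` (named integer
#'   vector over k >= 1), `n_undetected` (zero-step tallies) and
#'   `n_detected`.
#' @examples
#' step_histogram(c(2, 2, 1))
#' @export
step_histogram <- function(results) {
  if (length(results) == 0) stop("empty input", call. = FALSE)
  results <- as.integer(results)
  if (any(is.na(results) | results < 0))
    stop("step counts must be non-negative integers", call. = FALSE)
  n_undetected <- sum(results == 0L)
  detected <- results[results > 0L]
  counts <- if (length(detected))
    table(factor(detected, levels = seq_len(max(detected))))
  else table(factor(integer(0), levels = 1))
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, n_undetected = n_undetected,
                 n_detected = length(detected)),
            class = "step_count_histogram")
}

#' @export
print.step_count_histogram <- function(x, ...) {
  cat("Photobleaching step-count histogram\n")
  for (k in names(x$counts))
    cat(sprintf("  %s step(s): %d (%.1f%% of detected)\n", k, x$counts[[k]],
                100 * x$counts[[k]] / max(x$n_detected, 1L)))
  cat(sprintf("  detected molecules: %d; zero-step tallies: %d\n",
              x$n_detected, x$n_undetected))
  invisible(x)
}

#' Infer the subunit count from a step-count histogram
#'
#' Maximum-likelihood inference of the number of subunits n from observed
#' photobleaching step counts, accounting for incomplete fluorophore
#' maturation. Since dark molecules are never spotted, the model is the
#' zero-truncated binomial: for a molecule with n tagged subunits each
#' active with probability p,
#' \deqn{P(k \mid n, p, k \ge 1) = \binom{n}{k} p^k (1-p)^{n-k} /
#'   (1 - (1-p)^n).}
#' The multinomial log-likelihood over the detected counts is evaluated
#' for each candidate n and the maximizer returned, ties broken toward the
#' smaller n.
#'
#' @param hist a [step_histogram()] result.
#' @param p_active fluorophore maturation probability (default 0.7).
#' @param n_max largest candidate subunit count.
#'
#' @return A `stoich_fit`: list with `n_hat`, `p_active`, `loglik` (named
#'   vector over candidates), `predicted` (conditional distribution at
#'   `n_hat`).
#' @examples
#' fit_subunit_count(step_histogram(c(rep(1, 462), rep(2, 538))))
#' @export
fit_subunit_count <- function(hist, p_active = 0.7, n_max = 6) {
  stopifnot(inherits(hist, "step_count_histogram"))
  if (!is.finite(p_active) || p_active <= 0 || p_active > 1)
    stop("'p_active' must lie in (0, 1]", call. = FALSE)
  ks <- as.integer(names(hist$counts))
  obs <- hist$counts
  k_max <- max(ks[obs > 0])
  if (k_max > n_max)
    stop(sprintf("observed %d steps exceeds n_max = %d", k_max, n_max),
         call. = FALSE)
  candidates <- k_max:n_max
  loglik <- vapply(candidates, function(n) {
    pk <- dbinom(ks, n, p_active) / (1 - (1 - p_active)^n)
    if (any(obs > 0 & pk <= 0)) return(-Inf)
    sum(obs[obs > 0] * log(pk[obs > 0]))
  }, 0)
  names(loglik) <- candidates
  n_hat <- candidates[which.max(loglik)]   # which.max takes the first tie
  kk <- seq_len(n_hat)
  predicted <- dbinom(kk, n_hat, p_active) / (1 - (1 - p_active)^n_hat)
  names(predicted) <- kk
  structure(list(n_hat = n_hat, p_active = p_active, loglik = loglik,
                 predicted = predicted),
            class = "stoich_fit")
}

#' @export
print.stoich_fit <- function(x, ...) {
  cat(sprintf("Subunit-count MLE: n = %d (p_active = %.2f)\n",
              x$n_hat, x$p_active))
  cat("  conditional P(k | n, p, k >= 1):",
      paste(sprintf("k=%s: %.3f", names(x$predicted), x$predicted),
            collapse = ", "), "\n")
  invisible(x)
}

#' Photobleaching-time summary statistics
#'
#' For molecules bleaching in two distinguishable steps, the mean time of
#' the first step and the mean total time to complete bleaching; for
#' one-step molecules, the mean single bleach time. With independent
#' fluorophores bleaching at rate kb, the expectations are 1/(2 kb),
#' 3/(2 kb) and 1/kb respectively.
#'
#' @param step_times list of numeric vectors of per-molecule step times (s).
#'
#' @return A list with `mean_first_step_s`, `mean_total_time_s` (over
#'   two-step molecules) and `mean_one_step_time_s`.
#' @export
bleach_time_stats <- function(step_times) {
  counts <- lengths(step_times)
  two <- step_times[counts == 2L]
  one <- step_times[counts == 1L]
  if (length(two) == 0 || length(one) == 0)
    stop("need at least one two-step and one one-step molecule",
         call. = FALSE)
  list(mean_first_step_s = mean(vapply(two, min, 0)),
       mean_total_time_s = mean(vapply(two, max, 0)),
       mean_one_step_time_s = mean(vapply(one, `[[`, 0, 1L)))
}
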