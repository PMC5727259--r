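#' Independent-channels theoretical mixture curve
#'
#' The null expectation when two channel populations function
#' independently: the observed gating curve is the weighted average of the
#' two single-population Boltzmann curves,
#' \eqn{Y_{mix}(V) = w Y_a(V) + (1 - w) Y_b(V)}. Coupled dimers are
#' detected as systematic deviation of the observed co-expression curve
#' from this mixture (see [coupling_deviation()]).
#'
#' @param fit_a,fit_b `boltzmann_fit` objects (from [fit_boltzmann()]) for
#'   the two populations.
#' @param voltages voltage grid to evaluate on (mV).
#' @param weight fraction w of population a; 0.5 corresponds to simple
#'   averaging of the two curves, appropriate for equal functional
#'   expression.
#' @param kind curve kind for the result.
#'
#' @return A [gating_curve()].
#' @export
independent_mixture <- function(fit_a, fit_b, voltages, weight = 0.5,
                                kind = c("ssi", "activation")) {
  kind <- match.arg(kind)
  stopifnot(inherits(fit_a, "boltzmann_fit"),
            inherits(fit_b, "boltzmann_fit"))
  if (!is.finite(weight) || weight < 0 || weight > 1)
    stop("'weight' must lie in [0, 1]", call. = FALSE)
  voltages <- sort(as.numeric(voltages))
  y <- weight * boltzmann(voltages, fit_a$v_half, fit_a$slope_k) +
    (1 - weight) * boltzmann(voltages, fit_b$v_half, fit_b$slope_k)
  gating_curve(voltages, y, kind = kind)
}

#' Deviation of an observed gating curve from the independence null
#'
#' Measures how far an observed co-expression curve sits from the
#' theoretical independent-channels mixture, and which single-population
#' component it more closely resembles. Coupled gating shows up as an
#' observed curve that deviates from the mixture and tracks one component
#' (e.g. wild type) instead.
#'
#' Curves on different grids are linearly interpolated onto the overlap of
#' their voltage ranges.
#'
#' @param observed a [gating_curve()] for the co-expressed condition.
#' @param theoretical the mixture curve from [independent_mixture()].
#' @param components optional named list of single-population gating
#'   curves; when supplied, the component with the smallest RMS distance
#'   to `observed` is reported.
#'
#' @return A list with `rms_dev`, `max_dev` and `nearer_component` (NA
#'   when no components are supplied, `"tie"` on exact ties).
#' @export
coupling_deviation <- function(observed, theoretical, components = NULL) {
  vmin <- max(min(observed$voltage_mv), min(theoretical$voltage_mv))
  vmax <- min(max(observed$voltage_mv), max(theoretical$voltage_mv))
  if (vmin >= vmax)
    stop("voltage ranges do not overlap", call. = FALSE)
  grid <- sort(unique(c(
    observed$voltage_mv[observed$voltage_mv >= vmin &
                          observed$voltage_mv <= vmax],
    theoretical$voltage_mv[theoretical$voltage_mv >= vmin &
                             theoretical$voltage_mv <= vmax])))
  on_grid <- function(curve)
    approx(curve$voltage_mv, curve$response, xout = grid)$y
  dev <- on_grid(observed) - on_grid(theoretical)
  nearer <- NA_character_
  if (!is.null(components) && length(components) >= 1) {
    rms_to <- vapply(components, function(cmp) {
      vr <- range(cmp$voltage_mv)
      g <- grid[grid >= vr[1] & grid <= vr[2]]
      sqrt(mean((approx(observed$voltage_mv, observed$response,
                        xout = g)$y -
                   approx(cmp$voltage_mv, cmp$response, xout = g)$y)^2))
    }, 0)
    nearer <- if (length(unique(round(rms_to, 12))) == 1 &&
                  length(rms_to) > 1) "tie"
    else names(components)[which.min(rms_to)]
  }
  list(rms_dev = sqrt(mean(dev^2)), max_dev = max(abs(dev)),
       nearer_component = nearer)
}
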