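#' Theoretical dominant-negative suppression curve
#'
#' Expected normalized current when a dominant-negative subunit is present
#' at cDNA fraction x and the channel conducts only when all n subunits of
#' an oligomer are functional, under random assembly:
#' \eqn{y = (1 - x)^n}. n = 1 gives the linear decrease expected for
#' independent monomers; n = 2 the dimer curve; n = 3 the trimer curve.
#'
#' @param x mutant cDNA fraction(s) in \[0, 1\].
#' @param n stoichiometry exponent, integer >= 1.
#' @return Expected normalized current, same length as `x`.
#' @examples
#' binomial_theoretical(0.5, 2)  # 0.25
#' @export
binomial_theoretical <- function(x, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("'n' must be an integer >= 1", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0 | x > 1))
    stop("'x' must lie in [0, 1]", call. = FALSE)
  (1 - x)^n
}

#' Construct a dose-response table
#'
#' Mutant cDNA fraction against normalized peak current density, with
#' per-point uncertainty. The table is the input to
#' [fit_binomial_exponent()]; build it from raw current densities with
#' [normalize_dose_response()].
#'
#' @param x mutant cDNA fractions, strictly increasing, in \[0, 1\].
#' @param y normalized peak current densities (1 at the x = 0 reference).
#' @param sem per-point SEM (same length, or NULL).
#' @param n_cells optional per-point cell counts.
#'
#' @return A `dose_response` data frame.
#' @export
dose_response <- function(x, y, sem = NULL, n_cells = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (any(diff(x) <= 0)) stop("'x' must be strictly increasing",
                              call. = FALSE)
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]", call. = FALSE)
  if (any(y < 0)) stop("'y' must be >= 0", call. = FALSE)
  if (is.null(sem)) sem <- rep(NA_real_, length(x))
  df <- data.frame(x = x, y = y, sem = as.numeric(sem))
  if (!is.null(n_cells)) df$n_cells <- as.integer(n_cells)
  class(df) <- c("dose_response", "data.frame")
  df
}

#' Normalize raw dose-response measurements
#'
#' Divides peak current densities (and their SEMs) by the mean density of
#' the x = 0 reference entries (100\% functional subunit) and sorts by
#' ascending mutant fraction.
#'
#' @param raw data frame with columns `x` (mutant cDNA fraction),
#'   `current_density` (e.g. pA/pF) and optionally `sem`.
#'
#' @return A [dose_response()] with `y = 1` at `x = 0`.
#' @export
normalize_dose_response <- function(raw) {
  raw <- as.data.frame(raw)
  if (!all(c("x", "current_density") %in% names(raw)))
    stop("'raw' needs columns 'x' and 'current_density'", call. = FALSE)
  ref_rows <- raw$x == 0
  if (!any(ref_rows)) stop("missing x = 0 reference entry", call. = FALSE)
  ref <- mean(raw$current_density[ref_rows])
  if (!is.finite(ref) || ref == 0)
    stop("x = 0 reference is zero or non-finite", call. = FALSE)
  agg <- aggregate(raw["current_density"], by = raw["x"], FUN = mean)
  sem <- if ("sem" %in% names(raw))
    aggregate(raw["sem"], by = raw["x"], FUN = mean)$sem / abs(ref)
  else NULL
  ord <- order(agg$x)
  dose_response(agg$x[ord], (agg$current_density / ref)[ord],
                sem = if (is.null(sem)) NULL else sem[ord])
}

#' Fit the stoichiometry exponent of a dose-response curve
#'
#' Compares the observed suppression curve against the parameter-free
#' theoretical curves \eqn{y = (1-x)^n} for n = 1 (monomer), 2 (dimer) and
#' 3 (trimer) by weighted residual sum of squares (weights 1/sem^2 where
#' the SEM is known and positive, else 1), and optionally profiles a
#' continuous exponent on \[0.5, 5\] by 1-D minimization.
#'
#' @param dr a [dose_response()].
#' @param fit_continuous also estimate a real-valued exponent.
#'
#' @return A `binomial_fit`: list with `n_best`, `rss` (named over n),
#'   `aic` (Gaussian AIC at the common weighting; all candidates have the
#'   same parameter count) and `n_continuous` (NULL unless requested).
#' @examples
#' dr <- simulate_dose_response(2, c(0, 1/11, 1/5, 1/2, 4/5, 10/11, 1),
#'                              noise_sd = 0, seed = 1)
#' fit_binomial_exponent(dr)$n_best
#' @export
fit_binomial_exponent <- function(dr, fit_continuous = TRUE) {
  stopifnot(inherits(dr, "dose_response") || is.data.frame(dr))
  if (nrow(dr) < 3 || sum(dr$x > 0 & dr$x < 1) < 1)
    stop("need >= 3 points spanning x in (0, 1)", call. = FALSE)
  if (length(unique(dr$y)) == 1)
    stop("degenerate response: all y identical", call. = FALSE)
  w <- ifelse(is.finite(dr$sem) & dr$sem > 0, 1 / dr$sem^2, 1)
  wrss <- function(n) sum(w * (dr$y - (1 - dr$x)^n)^2)
  ns <- 1:3
  rss <- vapply(ns, wrss, 0)
  names(rss) <- ns
  m <- nrow(dr)
  aic <- m * log(pmax(rss, 1e-300) / m) + 2  # one variance parameter each
  names(aic) <- ns
  n_best <- ns[which.min(rss)]
  n_continuous <- NULL
  if (fit_continuous)
    n_continuous <- optimize(wrss, c(0.5, 5))$minimum
  structure(list(n_best = n_best, rss = rss, aic = aic,
                 n_continuous = n_continuous),
            class = "binomial_fit")
}

#' @export
print.binomial_fit <- function(x, ...) {
  cat(sprintf("Dominant-negative stoichiometry fit: n = %d\n", x$n_best))
  cat("  weighted RSS:",
      paste(sprintf("n=%s: %.4g", names(x$rss), x$rss), collapse = ", "),
      "\n")
  if (!is.null(x$n_continuous))
    cat(sprintf("  continuous exponent: %.3f\n", x$n_continuous))
  invisible(x)
}
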