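#' Simulate a dominant-negative dose-response table
#'
#' Generates normalized peak-current suppression data under the binomial
#' assembly model: at mutant cDNA fraction x the expected normalized
#' current is \eqn{y = (1 - x)^n}, where n is the number of subunits that
#' must all be functional for the oligomer to conduct (n = 1: independent
#' monomers, linear decrease; n = 2: dimer; n = 3: trimer). Gaussian noise
#' is added and values clipped at zero; the `sem` column is populated with
#' `noise_sd`.
#'
#' @param n assumed stoichiometry exponent, integer >= 1.
#' @param ratios mutant cDNA fractions in \[0, 1\].
#' @param noise_sd Gaussian noise SD on the normalized current.
#' @param seed integer seed.
#'
#' @return A [dose_response()] object.
#' @examples
#' simulate_dose_response(2, c(0, 1/11, 1/5, 1/2, 4/5, 10/11, 1),
#'                        noise_sd = 0, seed = 1)
#' @export
simulate_dose_response <- function(n, ratios, noise_sd = 0.02, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("'n' must be an integer >= 1", call. = FALSE)
  ratios <- as.numeric(ratios)
  if (length(ratios) == 0) stop("'ratios' must be non-empty", call. = FALSE)
  if (any(!is.finite(ratios)) || any(ratios < 0 | ratios > 1))
    stop("'ratios' must lie in [0, 1]", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be >= 0", call. = FALSE)
  set.seed(seed)
  ratios <- sort(ratios)
  y <- binomial_theoretical(ratios, n)
  if (noise_sd > 0) y <- pmax(0, y + rnorm(length(y), sd = noise_sd))
  dose_response(x = ratios, y = y, sem = rep(noise_sd, length(ratios)))
}

#' Simulate a Boltzmann gating curve
#'
#' Evaluates the two-state Boltzmann function
#' \eqn{Y(V) = 1 / (1 + \exp(-(V - V_{1/2}) / k))} on a voltage grid and
#' adds Gaussian noise. Activation curves use positive `slope_k`;
#' steady-state inactivation (availability) curves use negative `slope_k`
#' so availability decreases with depolarization under the same equation.
#'
#' @param v_half midpoint voltage V1/2 (mV).
#' @param slope_k inverse slope factor k (mV), signed; must be non-zero.
#' @param voltages voltage grid (mV).
#' @param noise_sd Gaussian noise SD on the response.
#' @param seed integer seed.
#' @param kind `"activation"` or `"ssi"`, stored on the returned curve.
#'
#' @return A [gating_curve()] object.
#' @examples
#' simulate_gating_curve(-85, -6, seq(-140, -30, by = 5), noise_sd = 0,
#'                       seed = 1, kind = "ssi")
#' @export
simulate_gating_curve <- function(v_half, slope_k, voltages,
                                  noise_sd = 0.02, seed = 1L,
                                  kind = c("activation", "ssi")) {
  kind <- match.arg(kind)
  if (!is.finite(slope_k) || slope_k == 0)
    stop("'slope_k' must be non-zero", call. = FALSE)
  set.seed(seed)
  voltages <- sort(as.numeric(voltages))
  y <- boltzmann(voltages, v_half, slope_k)
  if (noise_sd > 0) y <- y + rnorm(length(y), sd = noise_sd)
  gating_curve(voltages, y, kind = kind)
}

#' Two-state Boltzmann function
#'
#' @param v membrane potential (mV).
#' @param v_half midpoint voltage (mV).
#' @param slope_k inverse slope factor (mV), signed.
#' @return \eqn{1 / (1 + \exp(-(v - v_{1/2}) / k))}.
#' @export
boltzmann <- function(v, v_half, slope_k) {
  1 / (1 + exp(-(v - v_half) / slope_k))
}
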