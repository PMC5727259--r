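#' Crosstalk-corrected FRET
#'
#' Applies the three-cube crosstalk correction
#' \deqn{FRET_c = FRET - a \cdot CFP - b \cdot YFP,}
#' where a is the donor (CFP) bleed-through coefficient into the FRET
#' channel and b the direct acceptor (YFP) excitation coefficient. The
#' defaults a = 0.29 and b = 0.04 are the calibration for a standard
#' CFP/YFP cube set. Corrected values may be negative and are not clipped.
#'
#' @param records data frame with columns `fret`, `cfp`, `yfp` (per-ROI
#'   intensities, a.u.); additional columns (e.g. `roi_id`) pass through.
#' @param a CFP crosstalk coefficient, in \[0, 1).
#' @param b YFP crosstalk coefficient, in \[0, 1).
#'
#' @return The input data frame with columns `a`, `b` and `fretc`
#'   appended.
#' @examples
#' fret_correct(data.frame(fret = 100, cfp = 100, yfp = 100))$fretc  # 67
#' @export
fret_correct <- function(records, a = 0.29, b = 0.04) {
  records <- as.data.frame(records)
  if (!all(c("fret", "cfp", "yfp") %in% names(records)))
    stop("'records' needs columns fret, cfp, yfp", call. = FALSE)
  if (!is.finite(a) || a < 0 || a >= 1 || !is.finite(b) || b < 0 || b >= 1)
    stop("crosstalk coefficients must lie in [0, 1)", call. = FALSE)
  if (any(records$fret < 0 | records$cfp < 0 | records$yfp < 0))
    stop("intensities must be >= 0", call. = FALSE)
  records$a <- a
  records$b <- b
  records$fretc <- records$fret - a * records$cfp - b * records$yfp
  records
}

#' Donor dequenching after acceptor photobleaching
#'
#' Summarizes the per-ROI percent increase in donor (CFP) intensity after
#' the acceptor (YFP) is photobleached. For a true FRET efficiency E the
#' expected increase is \eqn{100 E / (1 - E)} percent. ROIs with
#' non-positive pre-bleach intensity are excluded with a warning. The
#' paired comparison uses a two-sided paired t-test by default; the
#' Wilcoxon signed-rank test is available for non-Gaussian ROI
#' distributions.
#'
#' @param donor_pre,donor_post paired per-ROI donor intensities before and
#'   after acceptor photobleaching (equal length >= 3).
#' @param test `"t"` (paired t-test) or `"wilcoxon"`.
#'
#' @return A list with `percent_increase` (per ROI), `mean_increase`,
#'   `sem_increase`, `statistic`, `p_value`, `n_roi`, `test`.
#' @export
acceptor_photobleach_stat <- function(donor_pre, donor_post,
                                      test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(donor_pre) != length(donor_post))
    stop("pre/post must be paired (equal length)", call. = FALSE)
  keep <- donor_pre > 0
  if (any(!keep))
    warning(sprintf("%d ROI(s) with non-positive pre-bleach intensity excluded",
                    sum(!keep)))
  donor_pre <- donor_pre[keep]
  donor_post <- donor_post[keep]
  if (length(donor_pre) < 3)
    stop("need >= 3 usable paired ROIs", call. = FALSE)
  pct <- 100 * (donor_post - donor_pre) / donor_pre
  ht <- tryCatch(
    if (test == "t") t.test(donor_post, donor_pre, paired = TRUE)
    else suppressWarnings(wilcox.test(donor_post, donor_pre,
                                      paired = TRUE)),
    error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  list(percent_increase = pct,
       mean_increase = mean(pct),
       sem_increase = sd(pct) / sqrt(length(pct)),
       statistic = unname(ht$statistic),
       p_value = ht$p.value,
       n_roi = length(pct),
       test = test)
}
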