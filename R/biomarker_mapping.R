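# Conversion of fitted kinetic parameters to histopathology-scale
# biomarkers: Lambda -> intratumoral CD8+ T-cell density, mu -> PD-L1
# positivity percentage, plus objective-response-rate stratification at
# the standard PD-L1 cutoffs.

#' Default CD8+ T-cell density of the tumor microenvironment
#'
#' Cells per mm^2 measured immunohistochemically in melanoma; the
#' Lambda-to-CD8 conversion assumes one tumor cell killed per CD8+
#' T cell on average (unit mean immune-cell fitness).
#' @export
CD8_DENSITY_REFERENCE <- 5558

#' Published pooled-trial ORRs by PD-L1 cutoff (annotation constants)
#'
#' Reference objective response rates from pooled published checkpoint-
#' inhibitor trials, stratified by PD-L1 staining: below/at-or-above 1%
#' (n = 975) and 5% (n = 1492). Used only to annotate report tables.
#' @export
REFERENCE_ORR <- data.frame(
  cutoff_percent = c(1, 1, 5, 5),
  stratum = c("<cutoff", ">=cutoff", "<cutoff", ">=cutoff"),
  orr = c(0.15, 0.28, 0.21, 0.38))

#' Convert Lambda to an intratumoral CD8+ T-cell density
#'
#' Linear conversion \code{lam * cells_per_mm2}, assuming each CD8+
#' T cell kills one tumor cell on average.
#'
#' @param lam Anti-tumor immune state, >= 0. Vectorized.
#' @param cells_per_mm2 Microenvironment cell density; default
#'   \code{\link{CD8_DENSITY_REFERENCE}}.
#' @return Estimated CD8+ density, cells/mm^2.
#' @examples
#' lambda_to_cd8(0.0995)  # ~ 553 cells/mm^2
#' @export
lambda_to_cd8 <- function(lam, cells_per_mm2 = CD8_DENSITY_REFERENCE) {
  if (any(!is.finite(lam)) || any(lam < 0))
    stop("lam must be finite and >= 0")
  lam * cells_per_mm2
}

#' Convert mu to a PD-L1 positivity percentage
#'
#' \code{mu * 100}; no other scaling. The raw (possibly negative) value
#' is returned; cutoff stratification elsewhere clamps at 0 because a
#' staining percentage cannot be negative.
#'
#' @param mu Immunotherapy effect rate, 1/day. Vectorized.
#' @return PD-L1-scale percentage.
#' @examples
#' mu_to_pdl1_percent(0.054)  # 5.4
#' @export
mu_to_pdl1_percent <- function(mu) {
  if (any(!is.finite(mu))) stop("mu must be finite")
  mu * 100
}

#' Objective response rate by PD-L1-style cutoff
#'
#' Stratifies patients by the clamped PD-L1 percentage
#' \code{max(0, mu * 100)} against a cutoff and reports the fraction of
#' favorable responses in each stratum. An empty stratum yields NA with
#' a warning.
#'
#' @param mu Numeric vector of fitted mu values.
#' @param labels Character \code{"favorable"}/\code{"unfavorable"} or
#'   logical (TRUE = favorable), same length.
#' @param cutoff Percent cutoff, typically 1 or 5.
#' @return data.frame with columns \code{cutoff_percent},
#'   \code{stratum}, \code{n}, \code{orr}.
#' @export
orr_by_cutoff <- function(mu, labels, cutoff) {
  if (is.character(labels)) labels <- labels == "favorable"
  stopifnot(is.logical(labels), length(mu) == length(labels),
            length(cutoff) == 1L, cutoff > 0)
  pct <- pmax(0, mu_to_pdl1_percent(mu))
  hi <- pct >= cutoff
  orr_of <- function(sel, what) {
    if (!any(sel)) {
      warning("empty stratum ", what, " at cutoff ", cutoff, "%")
      return(NA_real_)
    }
    mean(labels[sel])
  }
  data.frame(cutoff_percent = cutoff,
             stratum = c("<cutoff", ">=cutoff"),
             n = c(sum(!hi), sum(hi)),
             orr = c(orr_of(!hi, "<cutoff"), orr_of(hi, ">=cutoff")))
}

#' Biomarker table for a fitted cohort
#'
#' @param fits List of \code{fit_result} objects.
#' @param labels Named character vector of response labels (patient id
#'   -> "favorable"/"unfavorable").
#' @return data.frame with patient_id, lam, cd8_density, mu,
#'   pdl1_percent, stratum_1pct, stratum_5pct, label.
#' @export
biomarker_table <- function(fits, labels) {
  ids <- vapply(fits, `[[`, character(1), "patient_id")
  lam <- vapply(fits, `[[`, numeric(1), "lam")
  mu <- vapply(fits, `[[`, numeric(1), "mu")
  pct <- mu_to_pdl1_percent(mu)
  clamped <- pmax(0, pct)
  data.frame(patient_id = ids, lam = lam,
             cd8_density = lambda_to_cd8(lam), mu = mu,
             pdl1_percent = pct,
             stratum_1pct = ifelse(clamped >= 1, ">=1%", "<1%"),
             stratum_5pct = ifelse(clamped >= 5, ">=5%", "<5%"),
             label = unname(labels[ids]), row.names = NULL)
}
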