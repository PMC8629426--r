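#' Published per-histology tumor proliferation rates
#'
#' Growth rates (alpha, 1/day) derived from the fastest-progressing
#' patient of six published anti-PD-1/PD-L1 trials, one row per tumor
#' histology: colorectal carcinoma (CRC), urothelial cell carcinoma
#' (UCC), small cell lung cancer (SCLC), malignant melanoma (MM),
#' non-small cell lung cancer (NSCLC) and renal cell carcinoma (RCC).
#' Doubling times follow the ln 2 / alpha convention (the published
#' values, e.g. 11 d at alpha = 0.0622, match ln 2 / alpha, not
#' 1 / alpha).
#'
#' @return Called for its value: a data.frame with columns
#'   \code{histology}, \code{antibody}, \code{alpha}.
#' @examples
#' with(calibration_growth_rates(), doubling_time(alpha))
#' @export
calibration_growth_rates <- function() {
  data.frame(
    histology = c("CRC", "UCC", "SCLC", "MM", "NSCLC", "RCC"),
    antibody = c("pembrolizumab", "atezolizumab", "nivolumab",
                 "nivolumab", "nivolumab", "nivolumab"),
    alpha = c(0.0622, 0.016, 0.014, 0.0069, 0.0069, 0.0034))
}

#' Published cohort parameter summaries
#'
#' Mean and standard error of the mean (SEM) of the fitted anti-tumor
#' immune state (Lambda) and immunotherapy effect (mu) reported for
#' responding (partial/complete response) and nonresponding
#' (stable/progressive disease) patients in the two cohorts: the pooled
#' six-trial calibration cohort (n = 55 responders / 134 nonresponders)
#' and the NSCLC validation cohort (n = 25 / 39). These anchor the
#' synthetic-cohort parameter families.
#'
#' @return data.frame with columns \code{cohort}, \code{group},
#'   \code{n}, \code{lam_mean}, \code{lam_sem}, \code{mu_mean},
#'   \code{mu_sem}.
#' @export
cohort_parameter_summaries <- function() {
  data.frame(
    cohort = c("calibration", "calibration", "validation", "validation"),
    group = c("responder", "nonresponder", "responder", "nonresponder"),
    n = c(55L, 134L, 25L, 39L),
    lam_mean = c(0.714, 0.0995, 0.876, 0.0297),
    lam_sem = c(0.257, 0.0264, 0.102, 0.469),
    mu_mean = c(0.054, 0.013, 0.0529, -0.0064),
    mu_sem = c(0.014, 0.0012, 0.00982, 0.0032))
}
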