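# RECIST-derived binary outcomes, long-horizon projection, truncated
# refitting and the two sensitivity analyses (parameter perturbation and
# data perturbation with refit).

#' RECIST-derived response threshold for a convention
#'
#' Two readings of the ">= 30% reduction" partial-response rule on
#' volume-normalized burden are supported: \code{"volume-0.7"} applies
#' the 30% reduction to the (volume) burden itself; \code{"diameter-
#' equivalent-0.343"} applies it to diameters, i.e. a 0.7^3 = 0.343
#' volume ratio.
#'
#' @param convention \code{"volume-0.7"} or
#'   \code{"diameter-equivalent-0.343"}.
#' @return The burden threshold (0.70 or 0.343).
#' @export
response_threshold <- function(convention = c("volume-0.7",
                                              "diameter-equivalent-0.343")) {
  convention <- match.arg(convention)
  if (convention == "volume-0.7") 0.70 else 0.7^3
}

#' Binary RECIST-derived response classification
#'
#' Classifies a patient as \code{"favorable"} (partial/complete
#' response) when the final observed normalized burden — or a supplied
#' projected burden — is at or below the convention's threshold, and
#' \code{"unfavorable"} (stable/progressive disease) otherwise. The last
#' recorded point is used because it reflects the most complete
#' long-term outcome.
#'
#' @param x A \code{\link{patient_series}} (the last post-baseline point
#'   is used) or a single numeric projected burden.
#' @param convention See \code{\link{response_threshold}}.
#' @param basis Recorded provenance of the burden value:
#'   \code{"observed-last-point"} (default for series input) or
#'   \code{"projected-700d"}.
#' @return A list of class \code{"response_label"} with
#'   \code{patient_id}, \code{label}, \code{basis},
#'   \code{threshold_convention}, \code{burden}.
#' @export
classify_response <- function(x, convention = c("volume-0.7",
                                                "diameter-equivalent-0.343"),
                              basis = NULL) {
  convention <- match.arg(convention)
  thr <- response_threshold(convention)
  if (inherits(x, "patient_series")) {
    if (length(x$times) < 2L)
      stop("patient ", x$patient_id,
           ": need at least one post-baseline burden to classify")
    burden <- x$burdens[length(x$burdens)]
    pid <- x$patient_id
    if (is.null(basis)) basis <- "observed-last-point"
  } else {
    stopifnot(is.numeric(x), length(x) == 1L, !is.na(x))
    burden <- x  # +Inf (divergent projection) is a valid unfavorable value
    pid <- NA_character_
    if (is.null(basis)) basis <- "projected-700d"
  }
  structure(list(patient_id = pid,
                 label = if (burden <= thr) "favorable" else "unfavorable",
                 basis = basis, threshold_convention = convention,
                 burden = burden),
            class = "response_label")
}

#' @export
print.response_label <- function(x, ...) {
  cat(sprintf("%s: %s (burden %.3g, %s, %s)\n",
              if (is.na(x$patient_id)) "response" else x$patient_id,
              x$label, x$burden, x$basis, x$threshold_convention))
  invisible(x)
}

# Projection that understands the model's finite-time blow-up. When
# mu * Lambda < 0 the trajectory has a vertical asymptote at
# t* = log(1 - rho_inf) / k (hyperprogression); any horizon at or past
# t* projects to +Inf rather than the nonphysical negative branch.
.project_raw <- function(alpha, lam, mu, horizon) {
  m <- trajectory_model(model_parameters(alpha, lam, mu))
  if (m$exponential_limit) return(exp(m$k * horizon))
  if (m$rho_inf < 1) {
    t_star <- log(1 - m$rho_inf) / m$k
    if (is.finite(t_star) && t_star > 0 && t_star <= horizon)
      return(Inf)
  }
  predict_burden(m, horizon)
}

#' Project the model burden at a horizon
#'
#' Evaluates the fitted trajectory at the projection horizon (default
#' 700 days, beyond the last follow-up of typical trials). Values are
#' clamped at zero and flagged when the fit is in the
#' complete-regression regime; fits whose trajectory diverges before
#' the horizon (possible when mu < 0) project to \code{Inf} with the
#' \code{"divergent"} flag set.
#'
#' @param fit A \code{\link{fit_patient}} result.
#' @param horizon Days, default 700.
#' @return Numeric burden with attributes \code{"complete_regression"}
#'   and \code{"divergent"}.
#' @export
project_burden <- function(fit, horizon = 700) {
  stopifnot(inherits(fit, "fit_result"), horizon > 0)
  m <- trajectory_model(model_parameters(fit$alpha, fit$lam, fit$mu))
  val <- .project_raw(fit$alpha, fit$lam, fit$mu, horizon)
  cr <- if (m$exponential_limit) m$k < 0 else
    (m$rho_inf <= 0 && m$k < 0)
  structure(max(0, val), complete_regression = cr,
            divergent = is.infinite(val))
}

#' Truncate a series at an early time point
#'
#' Keeps the baseline and all on-treatment points strictly before
#' \code{t_max}; the pretreatment point (if any) is retained.
#'
#' @param series A \code{\link{patient_series}}.
#' @param t_max Days, > 0.
#' @return A \code{\link{patient_series}}.
#' @export
truncate_series <- function(series, t_max) {
  stopifnot(inherits(series, "patient_series"), t_max > 0)
  keep <- series$times < t_max
  patient_series(series$patient_id, series$times[keep],
                 series$burdens[keep], pretreatment = series$pretreatment,
                 histology = series$histology, cohort = series$cohort)
}

#' Early-truncation stability analysis
#'
#' Refits every patient on data truncated at each window, then measures
#' (i) the Spearman rank correlation between windowed and full-data
#' Lambda and mu, and (ii) the misclassification rate: the fraction of
#' patients whose projected-horizon response label under the windowed
#' fit differs from the label under the full-data fit (both labels come
#' from model projections, the convention recorded in the output).
#' Patients with fewer than one post-baseline point inside a window are
#' excluded from that window's statistics and counted.
#'
#' @param x A \code{\link{cohort}}.
#' @param alphas Named alpha vector (see \code{\link{resolve_alpha}}).
#' @param windows Numeric vector of truncation bounds in days; the full
#'   data ("all") is always analyzed as the reference.
#' @param config A \code{\link{fit_config}}.
#' @param horizon Projection horizon in days.
#' @param convention RECIST convention for labels.
#' @return A list with \code{table} (data.frame: window, n, n_excluded,
#'   spearman_lambda, spearman_mu, misclassification), \code{full_fits},
#'   \code{window_fits} (list of per-window fit lists), and
#'   \code{convention} metadata.
#' @export
truncation_analysis <- function(x, alphas, windows = c(30, 60, 120, 200),
                                config = fit_config(), horizon = 700,
                                convention = "volume-0.7") {
  stopifnot(inherits(x, "cohort"))
  full_fits <- fit_cohort(x, alphas, config, truncation_window = "all")
  full_lab <- vapply(full_fits, function(f)
    classify_response(as.numeric(project_burden(f, horizon)),
                      convention)$label, character(1))
  full_lam <- vapply(full_fits, `[[`, numeric(1), "lam")
  full_mu <- vapply(full_fits, `[[`, numeric(1), "mu")

  window_fits <- list()
  rows <- lapply(windows, function(w) {
    usable <- vapply(x$patients, function(p) sum(p$times < w) >= 2,
                     logical(1))
    ids <- names(x$patients)[usable]
    n_excl <- sum(!usable)
    if (length(ids) == 0L) {
      window_fits[[as.character(w)]] <<- list()
      return(data.frame(window = w, n = 0L, n_excluded = n_excl,
                        spearman_lambda = NA_real_, spearman_mu = NA_real_,
                        misclassification = NA_real_))
    }
    sub <- cohort(lapply(ids, function(id)
      truncate_series(x$patients[[id]], w)), name = x$name)
    fits <- fit_cohort(sub, alphas[ids], config,
                       truncation_window = as.character(w))
    window_fits[[as.character(w)]] <<- fits
    lab <- vapply(fits, function(f)
      classify_response(as.numeric(project_burden(f, horizon)),
                        convention)$label, character(1))
    lam <- vapply(fits, `[[`, numeric(1), "lam")
    mu <- vapply(fits, `[[`, numeric(1), "mu")
    data.frame(window = w, n = length(ids), n_excluded = n_excl,
               spearman_lambda = spearman(lam, full_lam[ids]),
               spearman_mu = spearman(mu, full_mu[ids]),
               misclassification = mean(lab != full_lab[ids]))
  })
  all_row <- data.frame(window = Inf, n = length(x$patients),
                        n_excluded = 0L, spearman_lambda = 1,
                        spearman_mu = 1, misclassification = 0)
  list(table = rbind(do.call(rbind, rows), all_row),
       full_fits = full_fits, window_fits = window_fits,
       convention = convention, horizon = horizon,
       comparison = "projected-vs-full-data-fit-labels")
}

#' Parameter-perturbation sensitivity of the predicted burden
#'
#' Perturbs Lambda and mu one at a time by +/- the given fraction
#' (alpha is held fixed throughout) and evaluates the trajectory at
#' \code{eval_t}; returns the maximum absolute change from the
#' unperturbed prediction.
#'
#' @param fit A \code{fit_result}.
#' @param fraction Relative perturbation, default 0.10.
#' @param eval_t Evaluation time in days, default 200.
#' @return Maximum |delta rho'| over the four perturbations, with the
#'   per-perturbation values as attribute \code{"deltas"}.
#' @export
perturb_parameters <- function(fit, fraction = 0.10, eval_t = 200) {
  stopifnot(inherits(fit, "fit_result"))
  base <- .predict_burden_raw(fit$alpha, fit$lam, fit$mu, eval_t)
  pert <- list(
    lam_up = c(fit$lam * (1 + fraction), fit$mu),
    lam_down = c(fit$lam * (1 - fraction), fit$mu),
    mu_up = c(fit$lam, fit$mu * (1 + fraction)),
    mu_down = c(fit$lam, fit$mu * (1 - fraction)))
  deltas <- vapply(pert, function(p)
    abs(.predict_burden_raw(fit$alpha, p[1], p[2], eval_t) - base),
    numeric(1))
  structure(max(deltas), deltas = deltas)
}

#' Data-perturbation sensitivity (refit on noisy burdens)
#'
#' Adds independent Uniform(-amplitude, amplitude) noise to every
#' post-baseline burden (the baseline stays exactly 1 because burden is
#' defined relative to it), clamps at zero, refits every patient and
#' returns the Spearman rank correlation between perturbed and original
#' Lambda and mu.
#'
#' @param x A \code{\link{cohort}}.
#' @param alphas Named alpha vector.
#' @param amplitude Noise half-width on normalized burden, default 0.1.
#' @param seed Integer seed; the perturbation is fully reproducible.
#' @param config A \code{\link{fit_config}}.
#' @param fits Optional precomputed full-data fits (from
#'   \code{\link{fit_cohort}}) to avoid refitting the originals.
#' @return A list with \code{spearman_lambda}, \code{spearman_mu}, and
#'   the perturbed fit list.
#' @export
perturb_data_refit <- function(x, alphas, amplitude = 0.1, seed = 1,
                               config = fit_config(), fits = NULL) {
  stopifnot(inherits(x, "cohort"), amplitude >= 0, amplitude < 1)
  if (is.null(fits)) fits <- fit_cohort(x, alphas, config)
  set.seed(as.integer(seed))
  perturbed <- lapply(x$patients, function(p) {
    b <- p$burdens
    if (length(b) > 1L) {
      noise <- stats::runif(length(b) - 1L, -amplitude, amplitude)
      b[-1] <- pmax(0, b[-1] + noise)
    }
    patient_series(p$patient_id, p$times, b,
                   pretreatment = p$pretreatment,
                   histology = p$histology, cohort = p$cohort)
  })
  pert_fits <- fit_cohort(cohort(unname(perturbed), name = x$name),
                          alphas, config)
  ids <- names(x$patients)
  lam0 <- vapply(fits[ids], `[[`, numeric(1), "lam")
  mu0 <- vapply(fits[ids], `[[`, numeric(1), "mu")
  lam1 <- vapply(pert_fits[ids], `[[`, numeric(1), "lam")
  mu1 <- vapply(pert_fits[ids], `[[`, numeric(1), "mu")
  list(spearman_lambda = spearman(lam1, lam0),
       spearman_mu = spearman(mu1, mu0),
       perturbed_fits = pert_fits)
}

#' Burden landscape over a parameter grid
#'
#' Evaluates the trajectory at \code{eval_t} over the cross product of
#' alpha levels and Lambda/mu grids, attaching the RECIST-style
#' category under the chosen convention (favorable at or below the
#' partial-response threshold, progressive disease at or above the
#' +20%-diameter-equivalent volume ratio 1.2^3, stable in between).
#' Singular parameter/time combinations are flagged, not fatal.
#'
#' @param alpha_levels Numeric vector of alpha values.
#' @param lam_grid,mu_grid Numeric grids for Lambda and mu.
#' @param eval_t Evaluation time in days, default 200.
#' @param convention RECIST convention for the favorable threshold.
#' @return data.frame with columns alpha, lam, mu, rho, singular,
#'   category.
#' @export
parameter_sweep <- function(alpha_levels, lam_grid, mu_grid, eval_t = 200,
                            convention = "volume-0.7") {
  stopifnot(all(is.finite(alpha_levels)), all(is.finite(lam_grid)),
            all(is.finite(mu_grid)))
  grid <- expand.grid(mu = mu_grid, lam = lam_grid, alpha = alpha_levels,
                      KEEP.OUT.ATTRS = FALSE)[, c("alpha", "lam", "mu")]
  rho <- mapply(function(a, l, m) .predict_burden_raw(a, l, m, eval_t),
                grid$alpha, grid$lam, grid$mu)
  thr <- response_threshold(convention)
  pd_thr <- 1.2^3
  grid$rho <- rho
  # NA = evaluation singular; negative = past the finite-time blow-up
  # of a mu < 0 trajectory: both nonphysical at eval_t
  grid$singular <- !is.finite(rho) | rho < 0
  grid$category <- ifelse(grid$singular, NA_character_,
                          ifelse(rho <= thr, "PR/CR",
                                 ifelse(rho >= pd_thr, "PD", "SD")))
  grid
}
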