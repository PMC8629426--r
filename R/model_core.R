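# Closed-form trajectory model for normalized tumor burden under
# PD-1/PD-L1 checkpoint inhibition.
#
# rho'(t) = rho_inf / (1 - (1 - rho_inf) * exp(-k * t)),   rho'(0) = 1
# k       = alpha - mu + mu * Lambda
# rho_inf = 1 + (alpha - mu) / (mu * Lambda)
#
# alpha  : intrinsic tumor proliferation rate (1/day)
# Lambda : dimensionless anti-tumor immune state (>= 0)
# mu     : immunotherapy effect rate (1/day); may be negative

# |mu * Lambda| below this is treated as the exponential-limit regime
# (removable singularity of rho_inf); see predict_burden().
.EXP_LIMIT_EPS <- 1e-12

# |denominator| below this raises a singularity error rather than
# returning huge nonphysical values.
.SINGULARITY_TOL <- 1e-9

#' Model parameters for one patient
#'
#' Bundles the three kinetic parameters of the checkpoint-inhibition
#' response model: the tumor proliferation rate \code{alpha} (per day),
#' the dimensionless anti-tumor immune state \code{lam} (Lambda, >= 0),
#' and the immunotherapy effect rate \code{mu} (per day, possibly
#' negative for tumors that grow faster on treatment).
#'
#' @param alpha Tumor proliferation rate, 1/day.
#' @param lam Anti-tumor immune state Lambda, dimensionless, >= 0.
#' @param mu Immunotherapy effect rate, 1/day.
#' @return An object of class \code{"model_parameters"}.
#' @examples
#' model_parameters(alpha = 0.02, lam = 1, mu = 0.01)
#' @export
model_parameters <- function(alpha, lam, mu) {
  stopifnot(length(alpha) == 1L, length(lam) == 1L, length(mu) == 1L)
  if (!is.finite(alpha) || !is.finite(lam) || !is.finite(mu))
    stop("alpha, lam and mu must all be finite")
  if (lam < 0)
    stop("lam (Lambda) must be >= 0")
  structure(list(alpha = alpha, lam = lam, mu = mu),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("model parameters: alpha = %g /d, Lambda = %g, mu = %g /d\n",
              x$alpha, x$lam, x$mu))
  invisible(x)
}

#' Net exponential rate of the trajectory model
#'
#' The coefficient in the exponent of the closed-form trajectory,
#' \code{k = alpha - mu + mu * lam}. Positive \code{k} means net growth
#' toward \code{rho_inf}; negative \code{k} means regression toward zero
#' burden.
#'
#' @param params A \code{\link{model_parameters}} object.
#' @return The net rate k, 1/day.
#' @examples
#' effective_rate(model_parameters(0.02, 1, 0.01))  # 0.02
#' @export
effective_rate <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  params$alpha - params$mu + params$mu * params$lam
}

#' Long-term normalized tumor burden
#'
#' The asymptote of the trajectory model,
#' \code{rho_inf = 1 + (alpha - mu) / (mu * lam)}. The sign of
#' \code{alpha - mu} sets the direction of response: progressive disease
#' when alpha > mu, regression when alpha < mu. A negative value signals
#' the complete-regression regime (burden tends to zero).
#'
#' @param params A \code{\link{model_parameters}} object.
#' @return The dimensionless long-term burden.
#' @examples
#' long_term_burden(model_parameters(0.02, 1, 0.01))  # 2
#' @export
long_term_burden <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  p <- params$mu * params$lam
  if (abs(p) <= .EXP_LIMIT_EPS)
    stop("exponential-limit regime: |mu * Lambda| <= ", .EXP_LIMIT_EPS,
         ", no finite long-term burden")
  1 + (params$alpha - params$mu) / p
}

#' Trajectory model with derived quantities
#'
#' Couples a parameter triplet with its derived net rate \code{k} and
#' long-term burden \code{rho_inf}. When \code{|mu * lam|} is below the
#' exponential-limit threshold the model degenerates to pure exponential
#' growth/decay at rate \code{k} and \code{rho_inf} is undefined
#' (\code{NA}, flagged by \code{exponential_limit}).
#'
#' @param params A \code{\link{model_parameters}} object.
#' @return An object of class \code{"trajectory_model"} with elements
#'   \code{params}, \code{k}, \code{rho_inf}, \code{exponential_limit}.
#' @export
trajectory_model <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  k <- effective_rate(params)
  exp_limit <- abs(params$mu * params$lam) <= .EXP_LIMIT_EPS
  rho_inf <- if (exp_limit) NA_real_ else long_term_burden(params)
  structure(list(params = params, k = k, rho_inf = rho_inf,
                 exponential_limit = exp_limit),
            class = "trajectory_model")
}

#' @export
print.trajectory_model <- function(x, ...) {
  print(x$params)
  if (x$exponential_limit) {
    cat(sprintf("exponential-limit regime: rho'(t) = exp(%g t)\n", x$k))
  } else {
    cat(sprintf("k = %g /d, rho_inf = %g%s\n", x$k, x$rho_inf,
                if (x$rho_inf <= 0) " (complete-regression regime)" else ""))
  }
  invisible(x)
}

#' Predict normalized tumor burden
#'
#' Evaluates the closed-form trajectory at times \code{t} (days since the
#' first checkpoint-inhibitor dose). Burden is normalized so that
#' \code{rho'(0) = 1} in every regime. In the exponential-limit regime
#' (\code{|mu * lam|} below threshold) the analytic limit
#' \code{exp(k * t)} is returned, which keeps the prediction continuous
#' across the regime switch and reduces to \code{exp(alpha * t)} when
#' \code{mu = 0}.
#'
#' @param model A \code{\link{trajectory_model}} (or
#'   \code{\link{model_parameters}}, converted internally).
#' @param t Numeric vector of times in days, all >= 0.
#' @return Numeric vector of normalized burdens.
#' @examples
#' m <- trajectory_model(model_parameters(0.02, 1, 0.01))
#' predict_burden(m, c(0, 50, 700))
#' @export
predict_burden <- function(model, t) {
  if (inherits(model, "model_parameters")) model <- trajectory_model(model)
  stopifnot(inherits(model, "trajectory_model"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0")
  if (model$exponential_limit)
    return(exp(model$k * t))
  denom <- 1 - (1 - model$rho_inf) * exp(-model$k * t)
  if (any(abs(denom) < .SINGULARITY_TOL))
    stop("trajectory singularity: denominator vanishes at a requested time ",
         "(nonphysical parameter/time combination)")
  model$rho_inf / denom
}

# Unsafe vectorized evaluator used inside optimization loops: no class
# checks, singular/invalid values become NA instead of errors.
.predict_burden_raw <- function(alpha, lam, mu, t) {
  k <- alpha - mu + mu * lam
  p <- mu * lam
  if (abs(p) <= .EXP_LIMIT_EPS)
    return(exp(k * t))
  rho_inf <- 1 + (alpha - mu) / p
  denom <- 1 - (1 - rho_inf) * exp(-k * t)
  out <- rho_inf / denom
  out[abs(denom) < .SINGULARITY_TOL] <- NA_real_
  out
}

#' Tumor volume doubling time
#'
#' \code{log(2) / alpha} for a growing tumor. (Doubling times quoted for
#' published per-histology growth rates follow this ln 2 convention.)
#'
#' @param alpha Proliferation rate, 1/day; must be > 0.
#' @return Doubling time in days.
#' @examples
#' doubling_time(0.0622)  # ~ 11 days
#' @export
doubling_time <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("doubling time undefined for alpha <= 0")
  log(2) / alpha
}

#' Sphere volume from a diameter
#'
#' \code{V = (4/3) * pi * (d/2)^3}, the spherical-lesion volume used to
#' convert RECIST diameter measurements to volumes. Note the RECIST
#' partial-response cutoff (30\% diameter reduction) corresponds to a
#' volume ratio of 0.7^3 = 0.343.
#'
#' @param d Diameter in mm, >= 0. Vectorized.
#' @return Volume in mm^3.
#' @examples
#' diameter_to_volume(10)  # ~ 523.6 mm^3
#' @export
diameter_to_volume <- function(d) {
  if (any(!is.finite(d)) || any(d < 0))
    stop("diameter must be finite and >= 0")
  (4 / 3) * pi * (d / 2)^3
}
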