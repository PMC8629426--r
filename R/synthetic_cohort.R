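# Seeded virtual-cohort generator with known ground truth, emulating
# the statistical structure of the published calibration cohort (pooled
# six-trial, per-histology alpha) and the NSCLC validation cohort
# (per-patient pretreatment alpha, negative values allowed).

#' Configuration for the virtual-cohort generator
#'
#' @param n Number of patients.
#' @param responder_fraction Fraction of patients drawn from the
#'   responder parameter family (default 0.29, the calibration cohort's
#'   objective response rate).
#' @param noise Half-width of the uniform measurement noise added to
#'   post-baseline normalized burdens (default 0.1); must be < 1.
#' @param horizon Last possible follow-up, days (default 700).
#' @param style \code{"calibration"} (per-histology alpha from the six
#'   published trials) or \code{"validation"} (per-patient alpha uniform
#'   over the published range [-0.0129, 0.0602], with a pretreatment
#'   scan).
#' @param pretreatment Generate a pretreatment scan at -(17-91) days
#'   (default TRUE for validation style, FALSE otherwise).
#' @param visit_interval,visit_jitter Follow-up cadence: visits every
#'   \code{visit_interval} days with uniform +/- \code{visit_jitter}
#'   jitter (defaults 42 and 10, inside the published 17-91 d
#'   inter-scan range).
#' @param lesions Also decompose each patient's burden into 1-12
#'   indexed lesions (median 3) with back-solved axes (default FALSE).
#' @return A list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n, responder_fraction = 0.29, noise = 0.1,
                          horizon = 700,
                          style = c("calibration", "validation"),
                          pretreatment = NULL,
                          visit_interval = 42, visit_jitter = 10,
                          lesions = FALSE) {
  style <- match.arg(style)
  if (!is.numeric(n) || n < 1) stop("n must be a positive count")
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("responder_fraction must be in [0, 1]")
  if (noise < 0 || noise >= 1) stop("noise amplitude must be in [0, 1)")
  if (is.null(pretreatment)) pretreatment <- style == "validation"
  structure(list(n = as.integer(n),
                 responder_fraction = responder_fraction, noise = noise,
                 horizon = horizon, style = style,
                 pretreatment = pretreatment,
                 visit_interval = visit_interval,
                 visit_jitter = visit_jitter, lesions = lesions),
            class = "cohort_config")
}

# Per-patient substream: one deterministic 31-bit seed per (master seed,
# patient counter) pair, so partial regeneration reproduces patients.
.derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1000003 + i * 7919) %% 2147483647)
}

# Lognormal draw matched to a target mean and sd (cv capped at 3; the
# published SEMs imply cv up to ~99 in one group, taken as anomalous).
.rlnorm_meansd <- function(n, mean, sd, cv_cap = 3) {
  cv <- min(sd / mean, cv_cap)
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Class-conditional (Lambda, mu) families anchored at the published
# cohort means; sd = SEM * sqrt(n).
.draw_lam_mu <- function(responder, style) {
  s <- cohort_parameter_summaries()
  row <- s[s$cohort == style &
             s$group == if (responder) "responder" else "nonresponder", ]
  lam <- .rlnorm_meansd(1, row$lam_mean, row$lam_sem * sqrt(row$n))
  mu <- if (responder) {
    .rlnorm_meansd(1, row$mu_mean, row$mu_sem * sqrt(row$n))
  } else {
    # nonresponder mu can sit near (validation: below) zero
    stats::rnorm(1, row$mu_mean, row$mu_sem * sqrt(row$n))
  }
  c(lam = min(lam, 100), mu = max(min(mu, 1), -1))
}

# Model-projected response flag at the horizon under the volume-0.7
# convention; divergent (hyperprogressing) trajectories are
# nonresponders, singular evaluations are NA.
.truth_flag <- function(alpha, lam, mu, horizon) {
  val <- tryCatch(.project_raw(alpha, lam, mu, horizon),
                  error = function(e) NA_real_)
  if (is.na(val)) return(NA)
  max(0, val) <= 0.7
}

#' Generate a virtual cohort with known ground truth
#'
#' For each patient: a response class is drawn at the configured
#' responder fraction; (alpha, Lambda, mu) are drawn from
#' class-conditional families anchored at the published cohort means
#' (lognormal where the published data imply positivity, normal for
#' nonresponder mu), redrawing until the model-projected outcome at the
#' horizon is consistent with the drawn class; a visit schedule is
#' built (baseline at 0, follow-ups at the configured cadence, an
#' optional pretreatment scan at -(17-91) d); the closed-form
#' trajectory is evaluated at the visits; and bounded uniform noise is
#' added to post-baseline burdens (clamped at zero; the baseline stays
#' exactly 1). Optionally each burden series is decomposed into indexed
#' lesions with axes that back-solve to the assigned volumes.
#'
#' Regeneration with the same (config, seed) is bit-for-bit identical.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param seed Integer master seed.
#' @return A list with \code{cohort} (a \code{\link{cohort}}),
#'   \code{truth} (data.frame: patient_id, responder, alpha, lam, mu,
#'   k, rho_inf, n_visits, lesion_count, patient_seed), \code{lesions}
#'   (data.frame in the lesion-level CSV dialect, or NULL), and the
#'   echoed \code{config} and \code{seed}.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"), length(seed) == 1L)
  seed <- as.integer(seed)
  histologies <- calibration_growth_rates()
  patients <- vector("list", config$n)
  truth <- vector("list", config$n)
  lesion_rows <- list()
  for (i in seq_len(config$n)) {
    ps <- .derive_seed(seed, i)
    set.seed(ps)
    responder <- stats::runif(1) < config$responder_fraction
    if (config$style == "calibration") {
      h <- histologies[sample.int(nrow(histologies), 1), ]
      alpha <- h$alpha; histology <- h$histology
    } else {
      alpha <- stats::runif(1, -0.0129, 0.0602); histology <- "NSCLC"
    }
    # visit schedule
    times <- 0
    repeat {
      nxt <- times[length(times)] + config$visit_interval +
        stats::runif(1, -config$visit_jitter, config$visit_jitter)
      if (nxt > config$horizon) break
      times <- c(times, nxt)
    }
    # redraw until the projected outcome matches the drawn class and
    # the trajectory is valid through at least the first follow-up
    # (a hyperprogressing trajectory can diverge mid-schedule)
    for (try in seq_len(2000)) {
      pm <- .draw_lam_mu(responder, config$style)
      flag <- .truth_flag(alpha, pm["lam"], pm["mu"], config$horizon)
      vals <- vapply(times, function(tt) tryCatch(
        predict_burden(trajectory_model(
          model_parameters(alpha, pm["lam"], pm["mu"])), tt),
        error = function(e) NA_real_), numeric(1))
    # a diverging patient drops out at the first invalid scan
      bad <- which(is.na(vals) | vals < 0)
      n_valid <- if (length(bad)) bad[1] - 1L else length(times)
      if (isTRUE(flag) == responder && n_valid >= 2L) break
    }
    lam <- unname(pm["lam"]); mu <- unname(pm["mu"])
    responder <- isTRUE(flag)  # realized outcome (matches the class draw)
    times <- times[seq_len(n_valid)]
    model <- trajectory_model(model_parameters(alpha, lam, mu))
    burdens <- vals[seq_len(n_valid)]
    if (config$noise > 0 && length(burdens) > 1L) {
      burdens[-1] <- pmax(0, burdens[-1] +
                            stats::runif(length(burdens) - 1L,
                                         -config$noise, config$noise))
    }
    burdens[1] <- 1
    pretreatment <- NULL
    if (config$pretreatment) {
      t_pre <- -stats::runif(1, 17, 91)
      b_pre <- exp(alpha * t_pre)
      if (config$noise > 0)
        b_pre <- max(1e-3, b_pre + stats::runif(1, -config$noise,
                                                config$noise))
      pretreatment <- c(t_pre, b_pre)
    }
    id <- sprintf("P%04d", i)
    patients[[i]] <- patient_series(id, times, burdens,
                                    pretreatment = pretreatment,
                                    histology = histology,
                                    cohort = config$style)
    lesion_count <- NA_integer_
    if (config$lesions) {
      lesion_count <- .draw_lesion_count()
      baseline_volume <- stats::rlnorm(1, log(4000), 0.8)
      les <- decompose_to_lesions(times, burdens * baseline_volume,
                                  lesion_count, seed = .derive_seed(ps, 1))
      les$patient_id <- id
      lesion_rows[[length(lesion_rows) + 1L]] <-
        les[c("patient_id", "scan_time_days", "lesion_id",
              "long_axis_mm", "short_axis_mm")]
    }
    truth[[i]] <- data.frame(
      patient_id = id, responder = responder, alpha = alpha, lam = lam,
      mu = mu, k = model$k,
      rho_inf = if (model$exponential_limit) NA_real_ else model$rho_inf,
      histology = histology, n_visits = length(times) - 1L,
      lesion_count = lesion_count, patient_seed = ps, row.names = NULL)
  }
  list(cohort = cohort(patients, name = config$style),
       truth = do.call(rbind, truth),
       lesions = if (config$lesions) do.call(rbind, lesion_rows) else NULL,
       config = config, seed = seed)
}

# Truncated-geometric indexed-lesion count on 1..12 (median 3).
.draw_lesion_count <- function(p = 0.25, max_count = 12) {
  probs <- p * (1 - p)^(seq_len(max_count) - 1)
  sample.int(max_count, 1, prob = probs / sum(probs))
}

#' Decompose a total-volume series into indexed lesions
#'
#' Splits each scan's total volume across a fixed lesion set using
#' per-patient Dirichlet proportions (constant over scans, so every
#' lesion tracks the total), then back-solves spherical axes: each
#' lesion gets a fixed long/short axis ratio in [1, 2.5] and axes such
#' that the geometric-mean-diameter sphere reproduces the assigned
#' volume exactly.
#'
#' @param times Scan times, days.
#' @param volumes Total volumes per scan, mm^3.
#' @param lesion_count Number of indexed lesions, 1-12.
#' @param seed Integer seed for the proportions and axis ratios.
#' @return data.frame with scan_time_days, lesion_id, long_axis_mm,
#'   short_axis_mm.
#' @export
decompose_to_lesions <- function(times, volumes, lesion_count, seed) {
  stopifnot(length(times) == length(volumes), lesion_count >= 1,
            lesion_count <= 12, all(volumes >= 0))
  set.seed(as.integer(seed))
  w <- stats::rgamma(lesion_count, shape = 1)
  w <- w / sum(w)
  ratio <- stats::runif(lesion_count, 1, 2.5)
  rows <- lapply(seq_along(times), function(j) {
    v <- volumes[j] * w
    d <- (6 * v / pi)^(1 / 3)  # geometric-mean diameter of the sphere
    data.frame(scan_time_days = times[j],
               lesion_id = sprintf("L%02d", seq_len(lesion_count)),
               long_axis_mm = d * sqrt(ratio),
               short_axis_mm = d / sqrt(ratio))
  })
  do.call(rbind, rows)
}
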