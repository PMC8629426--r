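test_that("response classification applies the convention thresholds", {
  mk <- function(final) patient_series("p", c(0, 100), c(1, final))
  expect_equal(classify_response(mk(1.0))$label, "unfavorable")
  expect_equal(classify_response(mk(1.0),
                                 "diameter-equivalent-0.343")$label,
               "unfavorable")
  expect_equal(classify_response(mk(0.30))$label, "favorable")
  expect_equal(classify_response(mk(0.30),
                                 "diameter-equivalent-0.343")$label,
               "favorable")
  # 0.50 sits between the two readings of the 30%-reduction rule
  expect_equal(classify_response(mk(0.50), "volume-0.7")$label, "favorable")
  expect_equal(classify_response(mk(0.50),
                                 "diameter-equivalent-0.343")$label,
               "unfavorable")
  expect_error(classify_response(patient_series("p", 0, 1)),
               "post-baseline")
})

test_that("projection matches the closed form and handles divergence", {
  mk_fit <- function(alpha, lam, mu) {
    tt <- seq(0, 560, by = 70)
    fit_patient(make_noiseless_series(alpha, lam, mu, tt), alpha)
  }
  # steady state mu = alpha: burden 1 at any horizon
  f1 <- mk_fit(0.02, 1.5, 0.02)
  expect_equal(as.numeric(project_burden(f1, 700)), 1, tolerance = 1e-4)
  f2 <- mk_fit(0.02, 1, 0.01)
  expect_equal(as.numeric(project_burden(f2, 700)), 2 / (1 + exp(-14)),
               tolerance = 1e-4)
  # partial regression (k > 0, 0 < rho_inf < 1): decreasing projection
  f3 <- mk_fit(0.01, 1.2, 0.05)
  p500 <- as.numeric(project_burden(f3, 500))
  p700 <- as.numeric(project_burden(f3, 700))
  expect_true(p700 >= 0 && p700 < 1)
  expect_lte(p700, p500)
  # complete regression (k < 0, rho_inf < 0): burden heads to zero
  f5 <- mk_fit(0.01, 0.5, 0.05)
  expect_true(attr(project_burden(f5, 700), "complete_regression"))
  expect_lt(as.numeric(project_burden(f5, 700)),
            as.numeric(project_burden(f5, 500)))
  # hyperprogression (mu < 0): finite-time blow-up projects to Inf
  f4 <- structure(list(patient_id = "p", alpha = 0.02, lam = 0.03,
                       mu = -0.0064, rho_inf = NA, rmse = 0, n_points = 5,
                       converged = TRUE, truncation_window = "all",
                       ssr = 0), class = "fit_result")
  pr <- project_burden(f4, 700)
  expect_true(is.infinite(pr))
  expect_true(attr(pr, "divergent"))
  expect_equal(classify_response(as.numeric(pr))$label, "unfavorable")
})

test_that("truncation keeps baseline and points strictly before t_max", {
  s <- patient_series("p", c(0, 29, 30, 59), c(1, 1.1, 1.2, 1.3))
  expect_equal(truncate_series(s, 30)$times, c(0, 29))
  expect_equal(truncate_series(s, 1000)$times, s$times)
  g <- noiseless_cohort_small(10, seed = 31)
  for (p in g$cohort$patients)
    expect_equal(length(truncate_series(p, 120)$times),
                 sum(p$times < 120))
})

test_that("truncation analysis is self-consistent on noiseless cohorts", {
  g <- noiseless_cohort_small(30, seed = 202)
  ta <- truncation_analysis(g$cohort, truth_alphas(g),
                            windows = c(60, 120, 200))
  tab <- ta$table
  # full-data row is a self-comparison
  full <- tab[is.infinite(tab$window), ]
  expect_equal(full$spearman_lambda, 1)
  expect_equal(full$spearman_mu, 1)
  expect_equal(full$misclassification, 0)
  # windows with >= 2 post-baseline points for everyone classify
  # perfectly on noiseless data
  m <- tab$misclassification[!is.na(tab$misclassification)]
  expect_true(all(diff(m) <= 1e-12))
  expect_equal(tab$misclassification[tab$window == 200], 0)
  # excluded-patient accounting
  expect_true(all(tab$n + tab$n_excluded == length(g$cohort$patients)))
})

test_that("parameter perturbation measures trajectory sensitivity", {
  tt <- seq(0, 560, by = 70)
  # mu = 0: Lambda is inert, perturbing it changes nothing
  f0 <- structure(list(patient_id = "p", alpha = 0.01, lam = 1, mu = 0,
                       rho_inf = NA, rmse = 0, n_points = 5,
                       converged = TRUE, truncation_window = "all",
                       ssr = 0), class = "fit_result")
  d0 <- perturb_parameters(f0)
  deltas <- attr(d0, "deltas")
  expect_equal(unname(deltas[c("lam_up", "lam_down")]), c(0, 0))
  # brute-force equality over the four perturbations
  f <- fit_patient(make_noiseless_series(0.02, 1, 0.01, tt), 0.02)
  out <- perturb_parameters(f, fraction = 0.1, eval_t = 200)
  base <- predict_burden(trajectory_model(
    model_parameters(f$alpha, f$lam, f$mu)), 200)
  brute <- max(vapply(list(c(1.1, 1), c(0.9, 1), c(1, 1.1), c(1, 0.9)),
                      function(fac) abs(predict_burden(trajectory_model(
                        model_parameters(f$alpha, f$lam * fac[1],
                                         f$mu * fac[2])), 200) - base),
                      numeric(1)))
  expect_equal(as.numeric(out), brute)
  # continuity: the change vanishes with the perturbation fraction
  fr <- c(0.1, 0.01, 0.001, 1e-6)
  vals <- vapply(fr, function(x)
    as.numeric(perturb_parameters(f, fraction = x)), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[4], 1e-4)
})

test_that("data perturbation with refit is reproducible and bounded", {
  g <- generate_cohort(cohort_config(15, noise = 0.05), 77)
  al <- truth_alphas(g)
  fits <- fit_cohort(g$cohort, al)
  # amplitude 0: correlations exactly 1
  r0 <- perturb_data_refit(g$cohort, al, amplitude = 0, seed = 4,
                           fits = fits)
  expect_equal(r0$spearman_lambda, 1)
  expect_equal(r0$spearman_mu, 1)
  # fixed seed: bit-reproducible
  r1 <- perturb_data_refit(g$cohort, al, amplitude = 0.1, seed = 4,
                           fits = fits)
  r2 <- perturb_data_refit(g$cohort, al, amplitude = 0.1, seed = 4,
                           fits = fits)
  expect_identical(r1, r2)
})

test_that("parameter sweep is consistent with pointwise prediction", {
  sw <- parameter_sweep(alpha_levels = c(0.0034, 0.018, 0.0622),
                        lam_grid = c(0, 0.25, 0.5, 1, 2),
                        mu_grid = c(0, 0.01, 0.03, 0.06, 0.1))
  # mu = 0 slice equals pure exponential growth
  row0 <- sw[sw$mu == 0, ]
  expect_equal(row0$rho, exp(row0$alpha * 200), tolerance = 1e-12)
  # grid values match predict_burden pointwise
  for (i in sample(nrow(sw), 20)) {
    m <- trajectory_model(model_parameters(sw$alpha[i], sw$lam[i],
                                           sw$mu[i]))
    expect_equal(sw$rho[i], predict_burden(m, 200))
  }
  # rho decreases along mu at fixed alpha and Lambda > 0
  for (a in unique(sw$alpha))
    for (l in setdiff(unique(sw$lam), 0)) {
      sl <- sw[sw$alpha == a & sw$lam == l, ]
      sl <- sl[order(sl$mu), ]
      expect_true(all(diff(sl$rho) < 1e-12))
    }
})
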