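test_that("exponential rate is recovered exactly from noiseless data", {
  s <- patient_series("p", c(0, 30, 60), exp(0.02 * c(0, 30, 60)))
  expect_equal(fit_exponential_rate(s), 0.02, tolerance = 1e-12)
  flat <- patient_series("p", c(0, 30, 60), c(1, 1, 1))
  expect_equal(fit_exponential_rate(flat), 0)
  tt <- c(0, 20, 45, 70, 100)
  s2 <- patient_series("p", tt, exp(0.0622 * tt))
  expect_equal(fit_exponential_rate(s2), 0.0622, tolerance = 1e-8)
  expect_error(fit_exponential_rate(patient_series("p", 0, 1)), ">= 2")
})

test_that("cohort alpha is the fastest progressor's rate", {
  tt <- c(0, 30, 60, 90)
  mk <- function(id, a) patient_series(id, tt, exp(a * tt))
  co <- cohort(list(mk("a", 0.01), mk("b", 0.05), mk("c", 0.02)))
  expect_equal(cohort_alpha(co), 0.05, tolerance = 1e-10)
  expect_equal(cohort_alpha(cohort(list(mk("solo", 0.013)))), 0.013,
               tolerance = 1e-10)
  # brute force over a 20-patient synthetic cohort
  set.seed(8)
  rates <- runif(20, -0.01, 0.06)
  co2 <- cohort(lapply(seq_along(rates), function(i)
    mk(sprintf("p%02d", i), rates[i])))
  brute <- max(vapply(co2$patients, fit_exponential_rate, numeric(1)))
  expect_equal(cohort_alpha(co2), brute)
})

test_that("pretreatment alpha follows the two-scan exponential estimate", {
  mk <- function(rho_pre, t_pre)
    patient_series("p", c(0, 40), c(1, 1.1), pretreatment = c(t_pre, rho_pre))
  expect_equal(pretreatment_alpha(mk(0.8, -30)), log(1.25) / 30)
  expect_equal(pretreatment_alpha(mk(0.8, -30)), 0.007438, tolerance = 1e-4)
  expect_equal(pretreatment_alpha(mk(1, -50)), 0)
  expect_equal(pretreatment_alpha(mk(1.25, -30)), -log(1.25) / 30)
  expect_error(pretreatment_alpha(patient_series("p", 0, 1)),
               "no pretreatment")
})

test_that("noiseless (Lambda, mu) round-trips through the fit", {
  tt <- seq(0, 560, by = 80)
  s <- make_noiseless_series(0.02, 1, 0.01, tt)
  f <- fit_patient(s, alpha = 0.02)
  expect_lt(rel_err(f$lam, 1), 1e-5)
  expect_lt(rel_err(f$mu, 0.01), 1e-5)
  expect_true(f$converged)
  expect_lt(f$rmse, 1e-7)
  # flat series: steady state rho_inf ~ 1, i.e. mu ~ alpha
  flat <- patient_series("p", tt, rep(1, length(tt)))
  ff <- fit_patient(flat, alpha = 0.03)
  expect_equal(ff$rho_inf, 1, tolerance = 1e-3)
  expect_equal(ff$mu, 0.03, tolerance = 1e-3)
})

test_that("fitting is deterministic", {
  g <- generate_cohort(cohort_config(3, noise = 0.1), 17)
  p <- g$cohort$patients[[1]]
  f1 <- fit_patient(p, g$truth$alpha[1])
  f2 <- fit_patient(p, g$truth$alpha[1])
  expect_identical(f1, f2)
})

test_that("returned SSR is no worse than any grid start", {
  cfg <- fit_config()
  g <- noiseless_cohort_small(6, seed = 55)
  for (i in seq_len(3)) {
    p <- g$cohort$patients[[i]]
    f <- fit_patient(p, g$truth$alpha[i], cfg)
    for (lam0 in cfg$lam_starts)
      for (mu0 in cfg$mu_starts) {
        start_val <- icikin:::.fit_objective(c(lam0, mu0),
                                             g$truth$alpha[i],
                                             p$times, p$burdens)
        expect_lte(f$ssr, start_val + 1e-12)
      }
  }
})

test_that("analytic SSR gradient matches central finite differences", {
  tt <- seq(0, 400, by = 50)
  s <- make_noiseless_series(0.02, 0.8, 0.03, tt)
  y <- s$burdens + c(0, rep(0.02, length(tt) - 1))
  for (theta in list(c(0.5, 0.02), c(2, -0.005), c(0.1, 0.1))) {
    g_an <- icikin:::.fit_gradient(theta, 0.02, tt, y)
    h <- 1e-7
    g_fd <- vapply(1:2, function(j) {
      e <- numeric(2); e[j] <- h
      (icikin:::.fit_objective(theta + e, 0.02, tt, y) -
         icikin:::.fit_objective(theta - e, 0.02, tt, y)) / (2 * h)
    }, numeric(1))
    expect_equal(g_an, g_fd, tolerance = 1e-4)
  }
})

test_that("fit is locally stable under infinitesimal data perturbation", {
  tt <- seq(0, 480, by = 60)
  s <- make_noiseless_series(0.02, 1, 0.01, tt)
  f0 <- fit_patient(s, 0.02)
  b <- s$burdens
  b[-1] <- b[-1] + 1e-12
  f1 <- fit_patient(patient_series("p1", tt, b), 0.02)
  expect_lt(abs(f1$lam - f0$lam), 1e-6)
  expect_lt(abs(f1$mu - f0$mu), 1e-6)
})

test_that("alpha resolution modes agree with their definitions", {
  g <- generate_cohort(cohort_config(12, noise = 0, style = "validation"), 23)
  al <- resolve_alpha(g$cohort, "pretreatment")
  for (id in names(g$cohort$patients))
    expect_equal(al[[id]], pretreatment_alpha(g$cohort$patients[[id]]))
  fixed <- resolve_alpha(g$cohort, "fixed", value = 0.01)
  expect_true(all(fixed == 0.01))
  # fastest-progressor mode: one alpha per histology group
  g2 <- generate_cohort(cohort_config(15, noise = 0.05), 24)
  al2 <- resolve_alpha(g2$cohort, "fastest-progressor")
  hist <- vapply(g2$cohort$patients, `[[`, character(1), "histology")
  for (h in unique(hist)) {
    ids <- names(g2$cohort$patients)[hist == h]
    sub <- cohort(unname(g2$cohort$patients[ids]))
    expect_true(all(al2[ids] == cohort_alpha(sub)))
  }
})
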