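test_that("effective rate and long-term burden match hand evaluation", {
  expect_equal(effective_rate(model_parameters(0.02, 1, 0.01)), 0.02)
  expect_equal(effective_rate(model_parameters(0.01, 1, 0.01)), 0.01)
  expect_equal(effective_rate(model_parameters(0.01, 0.5, 0.05)), -0.015)

  expect_equal(long_term_burden(model_parameters(0.01, 2, 0.01)), 1)
  expect_equal(long_term_burden(model_parameters(0.02, 1, 0.01)), 2)
  expect_equal(long_term_burden(model_parameters(0.01, 0.5, 0.05)), -0.6)
  # removable singularity: no finite asymptote when mu * Lambda ~ 0
  expect_error(long_term_burden(model_parameters(0.01, 0, 0)),
               "exponential-limit")
})

test_that("burden is 1 at t = 0 and follows the closed form", {
  set.seed(11)
  for (i in 1:25) {
    p <- model_parameters(runif(1, -0.0129, 0.0622), runif(1, 0, 3),
                          runif(1, -0.05, 0.2))
    m <- trajectory_model(p)
    val0 <- predict_burden(m, 0)
    expect_identical(val0, 1)
  }
  m <- trajectory_model(model_parameters(0.02, 1, 0.01))
  expect_equal(predict_burden(m, 50), 2 / (1 + exp(-1)), tolerance = 1e-12)
  # exponential limit: mu = 0 leaves pure exponential growth at alpha
  m0 <- trajectory_model(model_parameters(0.01, 0, 0))
  expect_equal(predict_burden(m0, 100), exp(1), tolerance = 1e-12)
})

test_that("closed form agrees with independent ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  tt <- seq(0, 700, by = 7)
  for (i in 1:30) {
    alpha <- runif(1, -0.0129, 0.0622)
    lam <- runif(1, 0.01, 3)
    mu <- runif(1, 0.001, 0.15)
    m <- trajectory_model(model_parameters(alpha, lam, mu))
    closed <- predict_burden(m, tt)
    # pure relative error control: regression-regime trajectories decay
    # through many orders of magnitude
    ode <- deSolve::lsoda(
      c(rho = 1), tt,
      function(t, y, parms) list(parms$k * y * (1 - y / parms$rinf)),
      parms = list(k = m$k, rinf = m$rho_inf),
      rtol = 1e-10, atol = 0)
    expect_lt(max(abs(closed - ode[, "rho"]) /
                    pmax(abs(closed), 1e-300)), 1e-6)
  }
  # exponential-limit regime against d rho/dt = alpha * rho
  m0 <- trajectory_model(model_parameters(0.01, 0, 0))
  ode0 <- deSolve::lsoda(c(rho = 1), tt,
                         function(t, y, p) list(0.01 * y), NULL,
                         rtol = 1e-10, atol = 1e-12)
  expect_lt(max(rel_err(predict_burden(m0, tt), ode0[, "rho"])), 1e-6)
})

test_that("trajectories are monotone and approach the right asymptote", {
  tt <- seq(0, 700, length.out = 200)
  set.seed(7)
  for (i in 1:20) {
    p <- model_parameters(runif(1, 0.001, 0.06), runif(1, 0.05, 3),
                          runif(1, 0.001, 0.15))
    m <- trajectory_model(p)
    v <- predict_burden(m, tt)
    d <- diff(v)
    expect_true(all(d >= -1e-12) || all(d <= 1e-12))
    t_big <- max(1e4, 40 / abs(m$k))  # far past the transition time 1/k
    if (m$k > 0 && m$rho_inf > 0) {
      expect_lt(abs(predict_burden(m, t_big) - m$rho_inf),
                1e-6 * abs(m$rho_inf))
    }
    if (m$k < 0) {
      expect_lt(predict_burden(m, t_big), 1e-6)
    }
  }
})

test_that("prediction is continuous across the exponential-limit switch", {
  # shrink mu toward 0 at fixed Lambda: the closed form approaches the
  # limit branch monotonically (the gap scales like 1/rho_inf ~ mu)
  tt <- c(100, 400)
  lim <- predict_burden(trajectory_model(model_parameters(0.02, 1, 0)), tt)
  gaps <- vapply(10^seq(-6, -11), function(mu)
    max(abs(predict_burden(trajectory_model(
      model_parameters(0.02, 1, mu)), tt) - lim) / lim), numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[length(gaps)], 1e-5)
  # values just above and below the branch threshold agree to within
  # the size of the residual correction term (~ mu * (e^{kt}-1)/k)
  above <- predict_burden(trajectory_model(
    model_parameters(0.02, 1, 1.01e-12)), tt)
  below <- predict_burden(trajectory_model(
    model_parameters(0.02, 1, 0.99e-12)), tt)
  expect_equal(above, below, tolerance = 1e-6)
})

test_that("singularity at the finite-time blow-up is detected", {
  # mu < 0 gives rho_inf < 0 with k > 0: vertical asymptote at
  # t* = log(1 - rho_inf)/k
  p <- model_parameters(0.05, 0.5, -0.2)
  m <- trajectory_model(p)
  t_star <- log(1 - m$rho_inf) / m$k
  expect_error(predict_burden(m, t_star), "singular")
})

test_that("doubling time follows the ln 2 convention", {
  expect_equal(doubling_time(log(2)), 1)
  expect_equal(round(doubling_time(0.0622)), 11)
  expect_equal(round(doubling_time(0.0034)), 204)
  expect_error(doubling_time(0), "alpha <= 0")
  expect_error(doubling_time(-0.01), "alpha <= 0")
})

test_that("diameter-volume conversion is the sphere formula", {
  expect_equal(diameter_to_volume(2), 4 / 3 * pi)
  expect_equal(diameter_to_volume(10), 4 / 3 * pi * 125, tolerance = 1e-12)
  # 30% diameter reduction = 0.343 volume ratio (the RECIST PR cutoff)
  expect_equal(diameter_to_volume(7) / diameter_to_volume(10), 0.343)
  expect_error(diameter_to_volume(-1), ">= 0")
})
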