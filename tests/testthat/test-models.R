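test_that("registry exposes the six models with the right parameter counts", {
  expected_k <- c(exponential = 1L, logistic = 2L, gompertz = 2L,
                  general_gompertz = 3L, classic_bertalanffy = 2L,
                  general_bertalanffy = 3L)
  expect_setequal(growth_model_names(), names(expected_k))
  for (nm in names(expected_k)) {
    m <- growth_model(nm)
    expect_identical(m$k, expected_k[[nm]])
    expect_length(m$parameter_names, m$k)
    expect_true(all(is.finite(m$lower)) && all(is.finite(m$upper)))
    expect_true(all(m$upper > m$lower))
  }
})

test_that("closed forms reproduce textbook values and initial conditions", {
  # exponential: 0.1 * e^(0.01 * 100) = 0.1 e
  expect_equal(evaluate_volume("exponential", c(r = 0.01), 0.1, 100),
               0.1 * exp(1), tolerance = 1e-12)
  # V(0) = v0 for every model (numeric-integration tolerance for the ODE one)
  pars <- list(
    exponential = c(r = 0.01),
    logistic = c(gamma = 0.02, K = 0.8),
    gompertz = c(gamma = 0.02, delta = -0.01),
    general_gompertz = c(gamma = 0.02, delta = -0.01, lambda = 0.9),
    classic_bertalanffy = c(alpha = 0.03, beta = 0.05),
    general_bertalanffy = c(alpha = 0.03, beta = 0.05, lambda = 0.7))
  for (nm in names(pars)) {
    expect_equal(evaluate_volume(nm, pars[[nm]], 0.3, 0), 0.3,
                 tolerance = 1e-8, label = nm)
  }
})

test_that("long-time behavior approaches each model's fixed point", {
  t_inf <- 5e4
  # gompertz plateau exp(delta/gamma)
  g <- c(gamma = 0.02, delta = 0.02 * log(0.7))
  expect_equal(evaluate_volume("gompertz", g, 0.2, t_inf), 0.7,
               tolerance = 1e-6)
  # logistic plateau K, approached from below and above
  expect_equal(evaluate_volume("logistic", c(gamma = 0.02, K = 0.6), 0.1,
                               t_inf), 0.6, tolerance = 1e-6)
  expect_equal(evaluate_volume("logistic", c(gamma = 0.02, K = 0.6), 0.9,
                               t_inf), 0.6, tolerance = 1e-6)
  # classic Bertalanffy steady state (alpha/beta)^3
  cb <- c(alpha = 0.04, beta = 0.05)
  expect_equal(evaluate_volume("classic_bertalanffy", cb, 0.3, t_inf),
               (0.04 / 0.05)^3, tolerance = 1e-6)
})

test_that("nested models collapse onto their special cases", {
  grid <- c(0, 25, 50, 100, 200, 400)
  cases <- list(
    list(g = 0.02, d = -0.01, v0 = 0.3),
    list(g = 0.01, d = 0.01 * log(0.9), v0 = 0.05),
    list(g = 0.04, d = 0.04 * log(0.5), v0 = 0.6))
  for (cs in cases) {
    gg <- evaluate_volume("general_gompertz",
                          c(gamma = cs$g, delta = cs$d, lambda = 1),
                          cs$v0, grid)
    cg <- evaluate_volume("gompertz", c(gamma = cs$g, delta = cs$d),
                          cs$v0, grid)
    expect_lt(max(abs(gg - cg)), 1e-6)
  }
  for (ab in list(c(0.03, 0.05), c(0.06, 0.04))) {
    gb <- evaluate_volume("general_bertalanffy",
                          c(alpha = ab[1], beta = ab[2], lambda = 2 / 3),
                          0.3, grid)
    cb <- evaluate_volume("classic_bertalanffy",
                          c(alpha = ab[1], beta = ab[2]), 0.3, grid)
    expect_lt(max(abs(gb - cb)), 1e-6)
  }
})

test_that("general Bertalanffy near lambda = 1 uses the exponential limit", {
  grid <- c(0, 50, 150)
  v <- evaluate_volume("general_bertalanffy",
                       c(alpha = 0.03, beta = 0.02, lambda = 1 - 1e-9),
                       0.2, grid)
  expect_equal(v, 0.2 * exp(0.01 * grid), tolerance = 1e-6)
})

test_that("every closed form agrees with numeric integration of its ODE", {
  # representative in-bounds parameter sets with bounded trajectories
  cases <- list(
    list(m = "exponential", p = c(r = 0.008), v0 = 0.1),
    list(m = "exponential", p = c(r = -0.008), v0 = 0.5),
    list(m = "logistic", p = c(gamma = 0.02, K = 0.9), v0 = 0.1),
    list(m = "logistic", p = c(gamma = 0.03, K = 0.2), v0 = 0.6),
    list(m = "gompertz", p = c(gamma = 0.02, delta = -0.005), v0 = 0.4),
    list(m = "gompertz", p = c(gamma = 0.015, delta = 0.015 * log(0.9)),
         v0 = 0.05),
    list(m = "classic_bertalanffy", p = c(alpha = 0.03, beta = 0.04),
         v0 = 0.3),
    list(m = "general_bertalanffy",
         p = c(alpha = 0.03, beta = 0.04, lambda = 0.5), v0 = 0.3),
    list(m = "general_bertalanffy",
         p = c(alpha = 0.02, beta = 0.03, lambda = 1.2), v0 = 0.3))
  grid <- seq(0, 400, by = 20)
  for (cs in cases) {
    closed <- evaluate_volume(cs$m, cs$p, cs$v0, grid)
    ode <- deSolve::ode(
      y = c(V = cs$v0), times = grid,
      func = function(t, y, parms) list(growth_rhs(cs$m, cs$p, max(y, 1e-12))),
      parms = NULL, rtol = 1e-10, atol = 1e-12)[, "V"]
    expect_lt(max(abs(closed - ode) / pmax(abs(ode), 1e-12)), 1e-5,
              label = cs$m)
  }
})

test_that("the differential RHS matches a numeric derivative of the solution", {
  h <- 1e-3
  cases <- list(
    list(m = "exponential", p = c(r = 0.01), v0 = 0.2),
    list(m = "logistic", p = c(gamma = 0.02, K = 0.8), v0 = 0.2),
    list(m = "gompertz", p = c(gamma = 0.02, delta = -0.01), v0 = 0.4),
    list(m = "classic_bertalanffy", p = c(alpha = 0.03, beta = 0.04),
         v0 = 0.3),
    list(m = "general_bertalanffy",
         p = c(alpha = 0.03, beta = 0.04, lambda = 0.5), v0 = 0.3))
  for (cs in cases) {
    for (t0 in c(10, 100, 300)) {
      v <- evaluate_volume(cs$m, cs$p, cs$v0, c(t0 - h, t0, t0 + h))
      num <- (v[3] - v[1]) / (2 * h)
      expect_equal(growth_rhs(cs$m, cs$p, v[2]), num,
                   tolerance = 1e-4, label = paste(cs$m, t0))
    }
  }
})

test_that("RHS fixed points are zero and v <= 0 is a domain error", {
  expect_equal(growth_rhs("exponential", c(r = 0), 0.3), 0)
  expect_equal(growth_rhs("logistic", c(gamma = 0.02, K = 0.5), 0.5), 0)
  d <- 0.02 * log(0.7)
  expect_equal(growth_rhs("gompertz", c(gamma = 0.02, delta = d), 0.7), 0,
               tolerance = 1e-15)
  expect_error(growth_rhs("gompertz", c(gamma = 0.02, delta = d), 0),
               "positive")
  expect_error(growth_rhs("exponential", c(r = 0.1), -1), "positive")
})

test_that("monotone regimes stay monotone and bounded", {
  grid <- seq(0, 400, by = 10)
  up <- evaluate_volume("exponential", c(r = 0.01), 0.1, grid)
  expect_true(all(diff(up) > 0))
  down <- evaluate_volume("exponential", c(r = -0.01), 0.1, grid)
  expect_true(all(diff(down) < 0))
  lg <- evaluate_volume("logistic", c(gamma = 0.02, K = 0.8), 0.1, grid)
  expect_true(all(diff(lg) > 0) && all(lg <= 0.8 + 1e-12))
  gp <- evaluate_volume("gompertz",
                        c(gamma = 0.02, delta = 0.02 * log(0.6)), 0.1, grid)
  expect_true(all(diff(gp) > 0) && all(gp <= 0.6 + 1e-12))
})

test_that("input validation rejects unsorted or negative times", {
  expect_error(evaluate_volume("exponential", c(r = 0.01), 0.1, c(10, 5)),
               "sorted")
  expect_error(evaluate_volume("exponential", c(r = 0.01), 0.1, c(-5, 5)),
               "non-negative")
  expect_error(evaluate_volume("exponential", c(0.01, 0.02), 0.1, 0),
               "expects 1 parameter")
})
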