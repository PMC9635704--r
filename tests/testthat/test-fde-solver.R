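test_that("order-1 exponential decay is integrated to classical accuracy", {
  sys <- multiorder_system(1, function(t, y) -y, 1)
  tr <- solve_multiorder(sys, solver_config(0, 1, 2^-8))
  expect_lt(abs(tr$states[nrow(tr$states), 1] - exp(-1)), 1e-6)
  expect_identical(unname(tr$states[1, 1]), 1)
  expect_equal(diff(tr$time), rep(2^-8, length(tr$time) - 1L))
})

test_that("fractional relaxation matches the Mittag-Leffler solution", {
  # D^alpha y = -y, y(0) = 1  =>  y(t) = E_alpha(-t^alpha)
  for (a in c(0.3, 0.5, 0.7, 0.9)) {
    sys <- multiorder_system(a, function(t, y) -y, 1)
    tr <- solve_multiorder(sys, solver_config(0, 5, 2^-8))
    ref <- ml_eval(a, 1, -tr$time^a)
    expect_lt(max(abs(tr$states[, 1] - ref)), 1e-3)
  }
  sys5 <- multiorder_system(0.5, function(t, y) -y, 1)
  tr5 <- solve_multiorder(sys5, solver_config(0, 1, 2^-8))
  expect_equal(unname(tr5$states[nrow(tr5$states), 1]),
               0.427583576155807, tolerance = 1e-4)
})

test_that("coupled order-1 system matches an adaptive classical reference", {
  rhs <- function(t, y) c(-0.3 * y[1] - 0.5 * y[2], 0.5 * y[1] - 0.3 * y[2])
  sys <- multiorder_system(c(1, 1), rhs, c(1, 0))
  tr <- solve_multiorder(sys, solver_config(0, 2, 2^-8))
  ref <- deSolve::ode(c(1, 0), tr$time,
                      function(t, y, p) list(rhs(t, y)), NULL,
                      rtol = 1e-12, atol = 1e-14)
  expect_lt(max(abs(tr$states - ref[, -1])), 1e-6)
})

test_that("zero right-hand side keeps every order exactly constant", {
  sys <- multiorder_system(c(1, 0.5, 0.3), function(t, y) c(0, 0, 0),
                           c(2, -1, 0.25))
  tr <- solve_multiorder(sys, solver_config(0, 2, 2^-5))
  expect_identical(max(abs(sweep(tr$states, 2, c(2, -1, 0.25)))), 0)
})

test_that("at order one the scheme coincides with classical ABM PECE", {
  rhs <- function(t, y) c(cos(t) - 0.5 * y[1], y[1] - y[2])
  y0 <- c(0.3, -0.2)
  h <- 2^-6; N <- 128L
  sys <- multiorder_system(c(1, 1), rhs, y0)
  tr <- solve_multiorder(sys, solver_config(0, N * h, h))
  ref <- classical_abm(rhs, y0, 0, h, N)
  expect_lt(max(abs(tr$states - ref)), 1e-12)
})

test_that("empirical convergence rates are as expected", {
  frac <- multiorder_system(0.6, function(t, y) -y, 1)
  expect_gte(convergence_order_estimate(frac, 2^-(6:8))$rate, 1)
  lin <- multiorder_system(c(1, 1),
                           function(t, y) c(-y[2], y[1]) - 0.3 * y,
                           c(1, 0))
  expect_equal(convergence_order_estimate(lin, 2^-(6:9))$rate, 2,
               tolerance = 0.3)
  # constant solution: differences vanish, rate indeterminate
  const <- multiorder_system(0.5, function(t, y) 0 * y, 1)
  expect_warning(res <- convergence_order_estimate(const, 2^-(4:6)),
                 "indeterminate")
  expect_true(is.na(res$rate))
})

test_that("solver and constructors signal invalid input", {
  expect_error(multiorder_system(1.5, function(t, y) -y, 1), "orders")
  expect_error(multiorder_system(c(1, 0.5), function(t, y) -y[1], c(1, 1)),
               "derivative per state")
  expect_error(solver_config(0, 1, step = -0.1), "step")
  expect_error(solver_config(2, 1), "t_end")
  expect_error(
    convergence_order_estimate(multiorder_system(1, function(t, y) -y, 1),
                               c(0.1, 0.05)), "3 step sizes")
  expect_error(
    convergence_order_estimate(multiorder_system(1, function(t, y) -y, 1),
                               c(0.1, 0.05, 0.03)), "geometric")
  # failure mid-integration carries the failure time
  bad <- multiorder_system(0.7, function(t, y) if (t > 0.5) NaN else -y, 1)
  expect_error(solve_multiorder(bad, solver_config(0, 1, 2^-4)),
               "non-finite rhs output at t")
})
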