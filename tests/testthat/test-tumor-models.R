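test_that("k_in interpolates between exponential and linear growth", {
  g <- growth_parameters()
  # far below threshold: exponential regime, switch term negligible
  expect_equal(k_in(0.0121, 0.0121, g), 0.25 * 0.0121, tolerance = 1e-12)
  # at the threshold w = lambda1/lambda0 the bracket halves the rate^(1/phi)
  w_th <- g$lambda1 / g$lambda0
  expect_equal(k_in(1, w_th, g), g$lambda0 * 2^(-1 / g$phi),
               tolerance = 1e-12)
  # far above threshold: linear regime lambda1 * u / w
  expect_equal(k_in(2, 1e6, g), g$lambda1 * 2 / 1e6, tolerance = 1e-10)
  # no overflow at enormous masses thanks to log-domain evaluation
  expect_equal(k_in(1, 1e300, g), g$lambda1 / 1e300, tolerance = 1e-10)
  expect_equal(k_in(0.5, 0, g), g$lambda0 * 0.5)
  expect_error(k_in(-1, 1, g), ">= 0")
  expect_warning(growth_parameters(phi = 5), "phi")
})

test_that("k_out is the bilinear kill flux", {
  expect_identical(k_out(0, 1, 0.5), 0)
  expect_equal(k_out(100, 1, 0.24657), 24.657)
  expect_equal(k_out(2 * 7, 3, 0.1), 2 * k_out(7, 3, 0.1))
  expect_error(k_out(-1, 1, 0.1), ">= 0")
  expect_error(k_out(1, 1, -0.1), "eta")
})

test_that("the Erlang chain conserves the total-damage identity", {
  # d(sum y_i)/dt must equal k_out - k1 * y_n algebraically
  Cconst <- function(t) rep(5000, length(t))
  p <- erlang_parameters(eta = 0.3, k1 = 0.7, n = 5L)
  sys <- build_erlang_system(p, Cconst)
  set.seed(3)
  for (i in 1:100) {
    st <- runif(6, 0, 2)
    dy <- sys$rhs(runif(1, 0, 30), st)
    ko <- 0.3 * 5000 / 1e4 * st[1]
    expect_equal(sum(dy[-1]), ko - 0.7 * st[6], tolerance = 1e-12)
  }
  expect_identical(sys$initial_state, c(0.0121, rep(0, 5)))
})

test_that("without drug both models reduce to pure growth", {
  C0 <- function(t) rep(0, length(t))
  cfg <- coarse_cfg(20)
  te <- simulate_erlang_tcm(erlang_parameters(n = 2L), C0, cfg)
  expect_identical(max(abs(te$y)), 0)
  expect_true(all(diff(te$w) > 0))
  tf <- simulate_fractional_tcm(fractional_parameters(), C0, cfg)
  expect_identical(max(abs(tf$y)), 0)
  expect_identical(max(abs(tf$z)), 0)
  expect_true(all(diff(tf$w) > 0))
  # eta = 0 with a live concentration behaves the same way
  te0 <- simulate_erlang_tcm(erlang_parameters(eta = 0), std_C, cfg)
  expect_identical(max(abs(te0$y)), 0)
  expect_true(all(diff(te0$w) > 0))
})

test_that("linear chain trick matches the convolution oracle", {
  cfg <- coarse_cfg(30)
  tc <- simulate_convolution_tcm(growth_parameters(), 0.37847,
                                 delay_erlang(4, 0.54379), std_C, cfg)
  ea <- simulate_erlang_tcm(erlang_parameters(), std_C, cfg,
                            method = "abm")
  expect_lt(max(abs(tc$w - ea$w)), 1e-3)
  expect_true(all(tc$u >= 0 & tc$y >= -1e-12))
})

test_that("semigroup multi-order form matches the convolution oracle", {
  cfg <- coarse_cfg(30)
  tm <- simulate_convolution_tcm(growth_parameters(), 0.24657,
                                 delay_mittag_leffler(0.945, 3.6852),
                                 std_C, cfg)
  tf <- simulate_fractional_tcm(fractional_parameters(), std_C, cfg)
  expect_lt(max(abs(tm$w - tf$w)), 1e-2)
})

test_that("formulation equivalences hold across random parameter draws", {
  cfg <- coarse_cfg(25)
  set.seed(21)
  for (i in 1:3) {
    eta <- runif(1, 0.1, 0.5); k1 <- runif(1, 0.3, 1.5)
    n <- sample(1:5, 1)
    tc <- simulate_convolution_tcm(growth_parameters(), eta,
                                   delay_erlang(n, k1), std_C, cfg)
    ec <- simulate_erlang_tcm(erlang_parameters(eta = eta, k1 = k1, n = n),
                              std_C, cfg, method = "abm")
    expect_lt(max(abs(tc$w - ec$w)), 1e-3)
    al <- runif(1, 0.6, 0.95); ta <- runif(1, 1.5, 6)
    eta2 <- runif(1, 0.1, 0.4)
    tm <- simulate_convolution_tcm(growth_parameters(), eta2,
                                   delay_mittag_leffler(al, ta), std_C, cfg)
    tf <- simulate_fractional_tcm(
      fractional_parameters(eta = eta2, delay = ml_delay(al, ta)),
      std_C, cfg)
    expect_lt(max(abs(tm$w - tf$w)), 1e-2)
    expect_true(all(tf$u >= -1e-12 & tf$y >= -1e-12))
  }
})

test_that("alpha near one recovers the single-compartment chain", {
  cfg <- coarse_cfg(30)
  tau <- 3.6852
  f1 <- simulate_fractional_tcm(
    fractional_parameters(delay = ml_delay(0.999, tau)), std_C, cfg)
  e1 <- simulate_erlang_tcm(
    erlang_parameters(eta = 0.24657, k1 = 1 / tau, n = 1L), std_C, cfg,
    method = "abm")
  expect_lt(max(abs(f1$w - e1$w)) / max(e1$w), 0.01)
})

test_that("point delay and degenerate densities behave as specified", {
  C0 <- function(t) rep(0, length(t))
  cfg <- coarse_cfg(10)
  tp <- simulate_convolution_tcm(growth_parameters(), 0.3, delay_point(2),
                                 C0, cfg)
  expect_identical(max(abs(tp$y)), 0)
  # a malformed survival function is rejected
  bad <- structure(list(kind = "erlang",
                        survival = function(t) 0.5 * exp(-t)),
                   class = "delay_density")
  expect_error(
    simulate_convolution_tcm(growth_parameters(), 0.3, bad, C0, cfg),
    "normalize")
  expect_error(delay_erlang(0, 1), "positive integer")
  expect_error(delay_mittag_leffler(1.2, 1), "alpha")
  expect_error(delay_point(-1), "T")
})

test_that("fitted-parameter dynamics show treatment response and regrowth", {
  cfg <- solver_config(0, 40, 2^-5)
  tr <- simulate_fractional_tcm(fractional_parameters(), std_C, cfg)
  w13 <- tr$w[tr$time == 13]
  # decline during/after dosing, interior nadir, regrowth after dosing stops
  nt <- nadir_time(tr)
  expect_lt(min(tr$w[tr$time >= 13]), 0.3 * w13)
  expect_gt(nt, 22)
  expect_lt(nt, 39)
  expect_gt(tr$w[nrow(tr)], 2 * min(tr$w[tr$time >= 13]))
})
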