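test_that("Latin hypercube samples are stratified in every dimension", {
  for (n in c(4L, 10L)) {
    S <- lhs_sample(list(dist_uniform("a", 0, 1), dist_uniform("b", 2, 6)),
                    n, seed = 5)
    expect_identical(dim(S), c(n, 2L))
    # exactly one draw per probability stratum of width 1/n
    expect_setequal(floor(S[, "a"] * n), 0:(n - 1))
    expect_setequal(floor((S[, "b"] - 2) / 4 * n), 0:(n - 1))
  }
  expect_identical(lhs_sample(list(dist_uniform("a", 0, 1)), 8, seed = 1),
                   lhs_sample(list(dist_uniform("a", 0, 1)), 8, seed = 1))
  expect_false(all(lhs_sample(list(dist_uniform("a", 0, 1)), 8, seed = 2) ==
                   lhs_sample(list(dist_uniform("a", 0, 1)), 8, seed = 1)))
  expect_error(lhs_sample(list(dist_uniform("a", 0, 1)), 1), ">= 2")
  expect_error(dist_uniform("a", 1, 1), "lo")
  expect_error(dist_lognormal("t", 0, -1), "varlog")
})

test_that("large LHS samples reproduce the declared marginals", {
  dists <- list(dist_uniform("alpha", 0.5, 0.95),
                dist_uniform("eta", 0.05, 0.5),
                dist_lognormal("tau", log(3.685), 0.5))
  S <- lhs_sample(dists, 3000, seed = 17)
  means <- c((0.5 + 0.95) / 2, (0.05 + 0.5) / 2, exp(log(3.685) + 0.25))
  sds <- c(0.45 / sqrt(12), 0.45 / sqrt(12),
           sqrt((exp(0.5) - 1) * exp(2 * log(3.685) + 0.5)))
  for (j in 1:3)
    expect_lt(abs(mean(S[, j]) - means[j]), 3 * sds[j] / sqrt(3000))
})

test_that("PRCC behaves as a partial rank correlation", {
  set.seed(31)
  n <- 3000
  S <- cbind(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  # strictly monotone dependence on x1 only
  out <- exp(3 * S[, "x1"])
  p <- prcc(S, out)
  expect_gte(p[["x1"]], 0.99)
  # parameters the output does not depend on have null-scale coefficients
  expect_lt(abs(p[["x2"]]), 0.06)
  expect_lt(abs(p[["x3"]]), 0.06)
  expect_true(all(abs(p) <= 1))
  # invariance under strictly monotone transformation of a column
  S2 <- S; S2[, "x1"] <- S2[, "x1"]^3
  expect_equal(prcc(S2, out), p, tolerance = 1e-12)
})

test_that("PRCC matches a small-instance partial-correlation oracle", {
  S <- cbind(a = c(3, 1, 4, 1.5, 5, 9), b = c(2, 7, 1, 8, 2.5, 8.5))
  out <- c(1.1, 0.2, 2.3, 0.1, 2.0, 3.2)
  # oracle: partial correlation from the inverse rank-correlation matrix
  R <- cbind(apply(S, 2, rank), rank(out))
  P <- solve(stats::cor(R))
  oracle <- c(-P[1, 3] / sqrt(P[1, 1] * P[3, 3]),
              -P[2, 3] / sqrt(P[2, 2] * P[3, 3]))
  expect_equal(unname(prcc(S, out)), oracle, tolerance = 1e-12)
})

test_that("degenerate PRCC inputs are signalled", {
  S <- cbind(a = c(1, 1, 1, 1, 1, 1, 1), b = c(2, 7, 1, 8, 2.5, 9, 4))
  out <- c(1, 2, 3, 4, 5, 6, 7)
  expect_warning(p <- prcc(S, out), "zero rank variance")
  expect_true(is.na(p[["a"]]))
  expect_error(prcc(S[1:3, ], out[1:3]), "n_samples")
})

test_that("time-resolved PRCC reproduces the expected sensitivity pattern", {
  times <- c(5, 10, 16, 20, 25, 30)
  sr <- prcc_over_time(n = 60, times = times, seed = 2,
                       cfg = solver_config(0, 30, 2^-4))
  expect_s3_class(sr, "sensitivity_result")
  expect_identical(dim(sr$prcc), c(3L, length(times)))
  # pre-treatment outputs do not depend on the sampled parameters
  expect_identical(sr$degenerate, times < 13)
  expect_true(all(sr$prcc[, sr$degenerate] == 0))
  post <- times >= 16
  expect_true(all(sr$prcc["eta", post] < 0))
  inj <- times >= 16 & times <= 22
  expect_true(all(sr$prcc["tau", inj] > 0))
  expect_true(all(abs(sr$prcc[, !sr$degenerate]) <= 1))
  expect_identical(sr$n_failed, 0L)
})

test_that("robustness sweeps order the delay with alpha and tau", {
  cfg <- solver_config(0, 40, 2^-5)
  ra <- robustness_sweep(list(dist_uniform("alpha", 0.5, 0.95)), n = 8,
                         seed = 2, cfg = cfg)
  # more delay (smaller alpha) leaves a shallower nadir
  expect_lte(stats::cor(ra$samples[, "alpha"], ra$nadir_masses,
                        method = "spearman"), -0.9)
  rt <- robustness_sweep(list(dist_lognormal("tau", log(3.685), 0.5)),
                         n = 8, seed = 3, cfg = cfg)
  # more delay (larger tau) postpones and raises the nadir
  expect_gte(stats::cor(rt$samples[, "tau"], rt$nadir_times,
                        method = "spearman"), 0.9)
  expect_gte(stats::cor(rt$samples[, "tau"], rt$nadir_masses,
                        method = "spearman"), 0.9)
})

test_that("a single-trajectory sweep is a plain simulation", {
  cfg <- solver_config(0, 30, 2^-4)
  r1 <- robustness_sweep(list(dist_uniform("alpha", 0.945, 0.9450001)),
                         n = 1, cfg = cfg)
  tr <- simulate_fractional_tcm(fractional_parameters(), std_C, cfg)
  expect_equal(as.numeric(r1$w[1, ]), tr$w, tolerance = 1e-6)
})
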