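test_that("RMSE follows its definition", {
  expect_identical(compute_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(compute_rmse(c(1, 2), c(0, 2)), sqrt(0.5))
  d <- c(0.3, 1.4, 2.2); w <- c(0.1, 1.9, 2.0)
  expect_equal(compute_rmse(5 * d, 5 * w), 5 * compute_rmse(d, w))
  expect_error(compute_rmse(c(1, 2), c(1, 2, 3)), "equal length")
  ds <- tumor_dataset(c(1, 2), c(1, 2))
  expect_equal(compute_rmse(ds, c(0, 2)), sqrt(0.5))
})

test_that("AIC follows the RMSE-parameterized formula", {
  expect_equal(compute_aic(1, 1, 1), log(2 * pi) + 5, tolerance = 1e-12)
  # adding one parameter costs exactly 2
  for (k in 2:5)
    expect_equal(compute_aic(10, 0.37, k) - compute_aic(10, 0.37, k - 1), 2,
                 tolerance = 1e-12)
  # doubling N adds N*(ln(2pi)+1) + 2N ln(rmse)
  expect_error(compute_aic(10, 0, 2), "undefined")
  expect_error(compute_aic(0, 1, 2), "N")
})

test_that("tumor datasets validate and round-trip through files", {
  expect_error(tumor_dataset(c(1, 1), c(2, 2)), "strictly increasing")
  expect_error(tumor_dataset(c(1, 2), c(-1, 2)), ">= 0")
  expect_error(tumor_dataset(c(1, 2), 1:3), "equal length")
  ds <- tumor_dataset(c(0, 5, 10), c(0.01, 0.1, 0.5),
                      meta = list(source = "unit"))
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_tumor_dataset(ds, f)
  ds2 <- read_tumor_dataset(f)
  expect_equal(ds2$times, ds$times)
  expect_equal(ds2$masses, ds$masses)
})

test_that("a fit started at the generating parameters stays there", {
  truth <- erlang_parameters(eta = 0.1, k1 = 0.4, n = 4L)
  ds <- generate_dataset(truth, coarse_design(), seed = 1,
                         cfg = coarse_cfg())
  ft <- fit_model(ds, "erlang", cfg = coarse_cfg())
  expect_equal(unname(ft$parameters), c(0.4, 0.1), tolerance = 1e-4)
  expect_lt(ft$rmse, 1e-6)
})

test_that("fits are deterministic and recover Erlang truth from the standard start", {
  ds <- generate_dataset(erlang_parameters(), coarse_design(), seed = 1,
                         cfg = coarse_cfg())
  f1 <- fit_model(ds, "erlang", cfg = coarse_cfg())
  f2 <- fit_model(ds, "erlang", cfg = coarse_cfg())
  expect_identical(f1$parameters, f2$parameters)
  expect_equal(unname(f1$parameters), c(0.54379, 0.37847), tolerance = 0.01)
  expect_true(f1$converged)
  expect_s3_class(f1, "tumor_fit")
  expect_equal(f1$n_params, 2L)
})

test_that("start outside the bounds and short datasets are rejected", {
  ds <- tumor_dataset(c(0, 10), c(0.01, 0.1))
  expect_error(fit_model(tumor_dataset(5, 0.1), "erlang"), "at least 2")
  expect_error(fit_model(ds, "erlang", start = c(k1 = 20, eta = 0.1)),
               "within the bounds")
})

test_that("subset experiment evaluates refits against the full dataset", {
  des <- coarse_design(noise_sigma = 0.15)
  ds <- generate_dataset(erlang_parameters(), des, seed = 4,
                         cfg = coarse_cfg())
  se <- subset_experiment(ds, sizes = c(2, 5, 9), seed = 9,
                          model = "erlang", cfg = coarse_cfg())
  expect_identical(se$table$size, c(2, 5, 9))
  expect_identical(se$table$unreliable, c(TRUE, FALSE, FALSE))
  # size = N reproduces the full-data fit exactly
  expect_identical(se$fits[[3]]$parameters, se$full_fit$parameters)
  # few observations predict the withheld data worse than the full fit
  expect_gte(se$table$rmse_full[1], se$table$rmse_full[3])
  # subsampling is seed-reproducible
  se2 <- subset_experiment(ds, sizes = c(2, 5, 9), seed = 9,
                           model = "erlang", cfg = coarse_cfg())
  expect_identical(se$indices, se2$indices)
  expect_identical(se$table, se2$table)
  expect_error(subset_experiment(ds, sizes = 12, model = "erlang"), "<= N")
})

test_that("compartment-number selection recovers the generating n", {
  ds <- generate_dataset(erlang_parameters(), coarse_design(), seed = 1,
                         cfg = coarse_cfg())
  sel <- select_n_by_rmse(ds, n_candidates = c(3, 4, 5), cfg = coarse_cfg())
  expect_identical(sel$best_n, 4L)
  expect_false(any(sel$table$failed))
  expect_identical(which.min(sel$table$rmse), 2L)
})

test_that("without a kill term n is unidentifiable and parsimony wins", {
  ds <- generate_dataset(erlang_parameters(eta = 0), coarse_design(),
                         seed = 1, cfg = coarse_cfg())
  sel <- select_n_by_rmse(ds, n_candidates = c(2, 4), cfg = coarse_cfg())
  expect_identical(sel$best_n, 2L)
  # single candidate is returned as-is
  sel1 <- select_n_by_rmse(ds, n_candidates = 3, cfg = coarse_cfg())
  expect_identical(sel1$best_n, 3L)
  expect_error(select_n_by_rmse(ds, integer(0)), "nonempty")
})
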