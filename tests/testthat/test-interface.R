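test_that("run configurations merge defaults, file values, and overrides", {
  cfg <- read_run_config()
  expect_identical(cfg$model, "fractional")
  expect_equal(cfg$solver$step, 2^-8)
  expect_equal(cfg$pk$V, 1028)
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  yaml::write_yaml(list(model = "erlang",
                        solver = list(t_end = 20, step = 0.0625)), f)
  cfg2 <- read_run_config(f)
  expect_identical(cfg2$model, "erlang")
  expect_equal(cfg2$solver$t_end, 20)
  expect_equal(cfg2$solver$step, 0.0625)
  expect_equal(cfg2$solver$t_start, 0)      # untouched default
  cfg3 <- read_run_config(f, overrides = list(seed = 42L))
  expect_identical(cfg3$seed, 42L)
  yaml::write_yaml(list(modle = "erlang"), f)
  expect_error(read_run_config(f), "unknown config key")
  yaml::write_yaml(list(model = "spline"), f)
  expect_error(read_run_config(f), "erlang")
})

test_that("run_simulate writes deterministic trajectory tables", {
  d1 <- tempfile(); d2 <- tempfile()
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  ov <- list(solver = list(t_end = 16, step = 2^-4))
  tr1 <- run_simulate(read_run_config(overrides = c(ov, output_dir = d1)))
  tr2 <- run_simulate(read_run_config(overrides = c(ov, output_dir = d2)))
  expect_named(tr1, c("time", "u", "z", "y", "w", "C"))
  expect_identical(tr1, tr2, ignore_attr = TRUE)
  expect_identical(readLines(file.path(d1, "trajectory.tsv")),
                   readLines(file.path(d2, "trajectory.tsv")))
  expect_true(file.exists(file.path(d1, "provenance.yml")))
  # erlang variant exposes the n+1 chain states
  ov$model <- "erlang"
  tre <- run_simulate(read_run_config(overrides = c(ov, output_dir = d1)))
  expect_named(tre, c("time", "u", paste0("y", 1:4), "y", "w", "C"))
})

test_that("run_compare favors the generating model family", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  ds <- generate_dataset(erlang_parameters(), coarse_design(), seed = 1,
                         cfg = coarse_cfg())
  cfg <- read_run_config(overrides = list(
    output_dir = dir, solver = list(t_end = 30, step = 2^-6)))
  cmp <- run_compare(cfg, data = ds)
  expect_s3_class(cmp, "model_comparison")
  # the Erlang fit reproduces its own data essentially exactly
  expect_lt(cmp$erlang$rmse, 1e-4)
  expect_lt(cmp$erlang$aic, cmp$fractional$aic)
  expect_lt(cmp$delta_aic, 0)
  expect_false(cmp$unreliable)
  expect_true(file.exists(file.path(dir, "comparison.tsv")))
  expect_true(file.exists(file.path(dir, "comparison.yml")))
})

test_that("two-point datasets are flagged unreliable in the comparison", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  ds <- generate_dataset(erlang_parameters(), coarse_design(), seed = 1,
                         cfg = coarse_cfg())
  ds2 <- tumor_dataset(ds$times[c(3, 7)], ds$masses[c(3, 7)])
  cfg <- read_run_config(overrides = list(
    output_dir = dir, solver = list(t_end = 30, step = 2^-6)))
  cmp <- run_compare(cfg, data = ds2)
  expect_true(cmp$unreliable)
  rep <- yaml::read_yaml(file.path(dir, "comparison.yml"))
  expect_true(rep$unreliable)
})

test_that("the experiment dispatcher runs generate end to end", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- read_run_config(overrides = list(
    output_dir = dir, model = "erlang",
    solver = list(t_end = 30, step = 2^-5),
    observation_times = c(0, 7, 13, 16, 19, 22, 25, 28, 30)))
  ds <- run_experiment("generate", cfg)
  expect_s3_class(ds, "tumor_dataset")
  expect_true(file.exists(file.path(dir, "dataset.tsv")))
  expect_true(file.exists(file.path(dir, "dataset-truth.yml")))
  rt <- read_tumor_dataset(file.path(dir, "dataset.tsv"))
  expect_equal(rt$masses, ds$masses, tolerance = 1e-12)
})
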