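#' Read and validate a run configuration
#'
#' Experiments are driven by a single flat YAML configuration file whose
#' keys default to the standard tumor-experiment setup (growth, PK,
#' dosing, solver step 2^-8, published starts/bounds). Any key present in
#' the file overrides the default; unknown top-level keys are an error so
#' typos fail loudly.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file (used by the
#'   command-line wrapper for flag overrides).
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    model = "fractional",
    seed = 1L,
    output_dir = ".",
    solver = list(t_start = 0, t_end = 60, step = 2^-8,
                  corrector_iterations = 1L),
    growth = list(lambda0 = 0.25, lambda1 = 0.4603, phi = 20, w0 = 0.0121),
    pk = list(k01 = 1.6, k21 = 0.2353, k12 = 0.1699, V = 1028),
    dosing = list(n = 10L, amount = 4.5e7, start_day = 13),
    erlang = list(n = 4L, k1 = 0.54379, eta = 0.37847),
    fractional = list(alpha = 0.945, tau = 3.6852, eta = 0.24657),
    dataset = NULL,
    observation_times = default_observation_times(),
    noise_sigma = 0,
    subset_sizes = c(2, 3, 4, 5, 6, 8),
    n_candidates = 1:6,
    sensitivity = list(n = 200L, t_max = 45, step = 2^-5)
  )
  cfg <- defaults
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(cfg, user)
  if (!cfg$model %in% c("erlang", "fractional"))
    stop("config 'model' must be 'erlang' or 'fractional'", call. = FALSE)
  if (cfg$solver$step <= 0) stop("config 'solver$step' must be > 0",
                                 call. = FALSE)
  if (!is.null(cfg$dataset) && !file.exists(cfg$dataset))
    stop("config 'dataset' file not found: ", cfg$dataset, call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

# assemble the standard objects from a config
.cfg_objects <- function(cfg) {
  growth <- growth_parameters(cfg$growth$lambda0, cfg$growth$lambda1,
                              cfg$growth$phi, cfg$growth$w0)
  pk <- pk_parameters(cfg$pk$k01, cfg$pk$k21, cfg$pk$k12, cfg$pk$V)
  doses <- daily_dose_schedule(cfg$dosing$n, cfg$dosing$amount,
                               cfg$dosing$start_day)
  solver <- solver_config(cfg$solver$t_start, cfg$solver$t_end,
                          cfg$solver$step, cfg$solver$corrector_iterations)
  list(growth = growth, pk = pk, doses = doses, solver = solver,
       erlang = erlang_parameters(growth, cfg$erlang$eta, cfg$erlang$k1,
                                  cfg$erlang$n),
       fractional = fractional_parameters(
         growth, cfg$fractional$eta,
         ml_delay(cfg$fractional$alpha, cfg$fractional$tau)))
}

.write_provenance <- function(cfg, dir, extra = list()) {
  prov <- c(list(
    package = "fractcm",
    version = as.character(utils::packageVersion("fractcm")),
    seed = cfg$seed,
    config = unclass(cfg)), extra)
  yaml::write_yaml(prov, file.path(dir, "provenance.yml"))
}

#' Simulate a TCM trajectory from a configuration
#'
#' Runs the configured model over the configured window and writes the
#' trajectory as a delimited table (`trajectory.tsv`: columns `time`,
#' model states, `y`, `w`, `C`) plus a `provenance.yml` recording the
#' full configuration, seed, and package version. Deterministic:
#' identical configurations produce identical files.
#'
#' @param cfg A `run_config` (from [read_run_config()]) or a path to a
#'   YAML config file.
#' @return The trajectory data frame, invisibly; file paths in
#'   attribute `files`.
#' @export
run_simulate <- function(cfg = read_run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  obj <- .cfg_objects(cfg)
  C <- solve_pk(obj$pk, obj$doses)
  traj <- if (cfg$model == "erlang")
    simulate_erlang_tcm(obj$erlang, C, obj$solver)
  else simulate_fractional_tcm(obj$fractional, C, obj$solver)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(cfg$output_dir, "trajectory.tsv")
  utils::write.table(traj, out, row.names = FALSE, quote = FALSE,
                     sep = "\t")
  .write_provenance(cfg, cfg$output_dir,
                    list(experiment = "simulate", output = "trajectory.tsv"))
  attr(traj, "files") <- c(out, file.path(cfg$output_dir, "provenance.yml"))
  invisible(traj)
}

#' Compare Erlang and fractional TCM fits on a dataset
#'
#' Fits both models to the configured dataset (path in `cfg$dataset`, or
#' a [tumor_dataset()] passed directly) with the published starts and
#' bounds, and reports RMSE, AIC, and parameter estimates side by side
#' together with the AIC difference. Datasets with two or fewer points
#' carry an unreliability warning in the report (too few observations to
#' constrain either model).
#'
#' @param cfg A `run_config` or path to one.
#' @param data Optional [tumor_dataset()] overriding `cfg$dataset`.
#' @return An object of class `model_comparison`: both `tumor_fit`s, the
#'   comparison table, `delta_aic` (Erlang minus fractional), and the
#'   `unreliable` flag.
#' @export
run_compare <- function(cfg = read_run_config(), data = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (is.null(data)) {
    if (is.null(cfg$dataset))
      stop("no dataset: set 'dataset' in the config or pass 'data'",
           call. = FALSE)
    data <- read_tumor_dataset(cfg$dataset)
  }
  obj <- .cfg_objects(cfg)
  fit_e <- fit_model(data, "erlang", pk = obj$pk, doses = obj$doses,
                     n = cfg$erlang$n, growth = obj$growth,
                     cfg = solver_config(0, max(data$times),
                                         cfg$solver$step))
  fit_f <- fit_model(data, "fractional", pk = obj$pk, doses = obj$doses,
                     growth = obj$growth,
                     cfg = solver_config(0, max(data$times),
                                         cfg$solver$step))
  unreliable <- length(data$times) <= 2L
  tab <- data.frame(
    model = c("erlang", "fractional"),
    k = c(fit_e$n_params, fit_f$n_params),
    rmse = c(fit_e$rmse, fit_f$rmse),
    aic = c(fit_e$aic, fit_f$aic))
  res <- structure(list(erlang = fit_e, fractional = fit_f, table = tab,
                        delta_aic = fit_e$aic - fit_f$aic,
                        unreliable = unreliable, n_obs = length(data$times)),
                   class = "model_comparison")
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(tab, file.path(cfg$output_dir, "comparison.tsv"),
                     row.names = FALSE, quote = FALSE, sep = "\t")
  report <- list(
    erlang = c(as.list(fit_e$parameters), rmse = fit_e$rmse,
               aic = fit_e$aic, converged = fit_e$converged),
    fractional = c(as.list(fit_f$parameters), rmse = fit_f$rmse,
                   aic = fit_f$aic, converged = fit_f$converged),
    delta_aic = res$delta_aic,
    n_obs = res$n_obs,
    unreliable = unreliable)
  yaml::write_yaml(report, file.path(cfg$output_dir, "comparison.yml"))
  .write_provenance(cfg, cfg$output_dir, list(experiment = "compare"))
  res
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Erlang vs fractional TCM comparison:\n")
  print(x$table, row.names = FALSE, digits = 5)
  cat(sprintf("  delta AIC (Erlang - fractional) = %.4g\n", x$delta_aic))
  if (x$unreliable)
    cat("  WARNING: <= 2 observations; fits are unreliable\n")
  invisible(x)
}

#' Run a configured experiment end to end
#'
#' Thin dispatcher binding the configuration to the module functions;
#' this is what the command-line wrapper calls. Experiments: `simulate`,
#' `compare`, `generate` (write a synthetic dataset), `fit`, `select-n`,
#' `subset`, `sensitivity`, `robustness`.
#'
#' @param experiment Experiment name (see above).
#' @param cfg A `run_config` or path to one.
#' @return The experiment's result object, invisibly; results are also
#'   written to `cfg$output_dir`.
#' @export
run_experiment <- function(experiment = c("simulate", "compare", "generate",
                                          "fit", "select-n", "subset",
                                          "sensitivity", "robustness"),
                           cfg = read_run_config()) {
  experiment <- match.arg(experiment)
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  obj <- .cfg_objects(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(experiment,
    "simulate" = run_simulate(cfg),
    "compare" = run_compare(cfg),
    "generate" = {
      truth <- if (cfg$model == "erlang") obj$erlang else obj$fractional
      des <- study_design(w0 = cfg$growth$w0,
                          dose_start_day = cfg$dosing$start_day,
                          n_doses = cfg$dosing$n,
                          dose_amount = cfg$dosing$amount,
                          observation_times = cfg$observation_times,
                          noise_sigma = cfg$noise_sigma)
      ds <- generate_dataset(truth, des, obj$pk, seed = cfg$seed)
      write_tumor_dataset(ds, file.path(cfg$output_dir, "dataset.tsv"))
      yaml::write_yaml(
        list(truth_model = ds$meta$truth_model, seed = ds$meta$seed,
             observation_times = des$observation_times,
             noise_sigma = des$noise_sigma,
             w_true = ds$meta$w_true),
        file.path(cfg$output_dir, "dataset-truth.yml"))
      ds
    },
    "fit" = {
      data <- read_tumor_dataset(cfg$dataset)
      ft <- fit_model(data, cfg$model, pk = obj$pk, doses = obj$doses,
                      n = cfg$erlang$n, growth = obj$growth,
                      cfg = solver_config(0, max(data$times),
                                          cfg$solver$step))
      yaml::write_yaml(c(as.list(ft$parameters),
                         list(rmse = ft$rmse, aic = ft$aic,
                              converged = ft$converged)),
                       file.path(cfg$output_dir, "fit.yml"))
      ft
    },
    "select-n" = {
      data <- read_tumor_dataset(cfg$dataset)
      sel <- select_n_by_rmse(data, cfg$n_candidates, pk = obj$pk,
                              doses = obj$doses, growth = obj$growth,
                              cfg = solver_config(0, max(data$times),
                                                  cfg$solver$step))
      utils::write.table(sel$table,
                         file.path(cfg$output_dir, "select-n.tsv"),
                         row.names = FALSE, quote = FALSE, sep = "\t")
      sel
    },
    "subset" = {
      data <- read_tumor_dataset(cfg$dataset)
      se <- subset_experiment(data, cfg$subset_sizes, seed = cfg$seed,
                              model = cfg$model, pk = obj$pk,
                              doses = obj$doses, growth = obj$growth)
      utils::write.table(se$table,
                         file.path(cfg$output_dir, "subset.tsv"),
                         row.names = FALSE, quote = FALSE, sep = "\t")
      se
    },
    "sensitivity" = {
      sr <- prcc_over_time(n = cfg$sensitivity$n,
                           times = 0:cfg$sensitivity$t_max,
                           seed = cfg$seed, growth = obj$growth,
                           pk = obj$pk, doses = obj$doses,
                           cfg = solver_config(0, cfg$sensitivity$t_max,
                                               cfg$sensitivity$step))
      utils::write.table(
        data.frame(time = sr$times, t(sr$prcc),
                   degenerate = sr$degenerate),
        file.path(cfg$output_dir, "prcc.tsv"),
        row.names = FALSE, quote = FALSE, sep = "\t")
      utils::write.table(sr$samples,
                         file.path(cfg$output_dir, "lhs-samples.tsv"),
                         row.names = FALSE, quote = FALSE, sep = "\t")
      sr
    },
    "robustness" = {
      rs <- robustness_sweep(
        list(dist_uniform("alpha", 0.5, 0.95),
             dist_lognormal("tau", log(3.685), 0.5)),
        n = 10L, seed = cfg$seed, base = obj$fractional, pk = obj$pk,
        doses = obj$doses,
        cfg = solver_config(0, cfg$sensitivity$t_max,
                            cfg$sensitivity$step))
      utils::write.table(
        data.frame(rs$samples, nadir_time = rs$nadir_times),
        file.path(cfg$output_dir, "robustness.tsv"),
        row.names = FALSE, quote = FALSE, sep = "\t")
      rs
    })
  .write_provenance(cfg, cfg$output_dir, list(experiment = experiment))
  invisible(out)
}
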