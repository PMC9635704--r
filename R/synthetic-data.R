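#' Study design for synthetic tumor datasets
#'
#' Describes the experimental design the generator emulates: tumor
#' implanted at day 0 with mass `w0`, `n_doses` daily boluses of
#' `dose_amount` starting on `dose_start_day`, and ten observation times
#' spanning implantation, treatment, and regrowth. Defaults mirror the
#' design of the ten-point mouse tumor experiment (0.0121 g at day 0, ten
#' daily doses of 4.5e7 ng/kg from day 13).
#'
#' @param w0 Initial tumor mass (g).
#' @param dose_start_day First dose day.
#' @param n_doses Number of daily doses.
#' @param dose_amount Bolus amount per dose (ng/kg).
#' @param observation_times Observation times in days (strictly
#'   increasing); default [default_observation_times()].
#' @param noise_sigma Standard deviation of multiplicative lognormal
#'   observation noise on the log scale; 0 (default) disables noise.
#' @return An object of class `study_design`.
#' @export
study_design <- function(w0 = 0.0121, dose_start_day = 13, n_doses = 10,
                         dose_amount = 4.5e7,
                         observation_times = default_observation_times(),
                         noise_sigma = 0) {
  observation_times <- as.numeric(observation_times)
  if (any(diff(observation_times) <= 0))
    stop("'observation_times' must be strictly increasing", call. = FALSE)
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop("'noise_sigma' must be >= 0", call. = FALSE)
  if (!is.finite(w0) || w0 <= 0) stop("'w0' must be > 0", call. = FALSE)
  structure(list(w0 = w0, dose_start_day = dose_start_day,
                 n_doses = as.integer(n_doses), dose_amount = dose_amount,
                 observation_times = observation_times,
                 noise_sigma = noise_sigma),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "Study design: w0 = %g g; %d daily doses of %g ng/kg from day %g;\n",
    x$w0, x$n_doses, x$dose_amount, x$dose_start_day))
  cat(sprintf("  %d observations at days %s;\n  noise: %s\n",
              length(x$observation_times),
              paste(x$observation_times, collapse = ", "),
              if (x$noise_sigma > 0)
                sprintf("lognormal (sigma = %g)", x$noise_sigma)
              else "none"))
  invisible(x)
}

#' Default observation schedule
#'
#' Ten strictly increasing observation times on days 0-60 covering the
#' three phases of the experiment: pre-treatment growth (days 0, 7, 13),
#' on-treatment response (16, 19, 22), and post-treatment
#' nadir/regrowth (26, 32, 45, 60). The exact values are this package's
#' design choice (overridable in [study_design()]) and are stamped into
#' each generated dataset's metadata.
#'
#' @return Numeric vector of 10 times in days.
#' @export
default_observation_times <- function() {
  c(0, 7, 13, 16, 19, 22, 26, 32, 45, 60)
}

#' Generate a synthetic tumor dataset with known ground truth
#'
#' Simulates the chosen TCM at the supplied ground-truth parameters under
#' the study design's dosing regimen, reads total tumor mass `w = u + y`
#' at the observation times, and (optionally) applies multiplicative
#' lognormal observation noise `w * exp(N(0, sigma^2))` - multiplicative
#' because tumor masses span orders of magnitude. The ground truth, seed,
#' and design are embedded in the dataset metadata; generation is
#' deterministic under `seed` and does not disturb the caller's random
#' number stream.
#'
#' @param truth An [erlang_parameters()] or [fractional_parameters()]
#'   object (its `growth$w0` is overridden by the design's `w0`).
#' @param design A [study_design()].
#' @param pk A [pk_parameters()].
#' @param seed Integer seed (used only when `noise_sigma > 0`).
#' @param cfg A [solver_config()]; `NULL` covers the observation window
#'   at step 2^-8.
#' @return A [tumor_dataset()] with ground-truth metadata.
#' @export
generate_dataset <- function(truth, design = study_design(),
                             pk = pk_parameters(), seed = 1L, cfg = NULL) {
  stopifnot(inherits(design, "study_design"))
  obs <- design$observation_times
  if (is.null(cfg)) cfg <- solver_config(0, max(obs), 2^-8)
  if (max(obs) > cfg$t_end + 1e-9)
    stop("simulation window does not cover all observation times",
         call. = FALSE)
  doses <- daily_dose_schedule(design$n_doses, design$dose_amount,
                               design$dose_start_day)
  C <- solve_pk(pk, doses)
  g <- truth$growth
  g$w0 <- design$w0
  traj <- if (inherits(truth, "erlang_parameters")) {
    simulate_erlang_tcm(erlang_parameters(g, truth$eta, truth$k1, truth$n),
                        C, cfg)
  } else if (inherits(truth, "fractional_parameters")) {
    simulate_fractional_tcm(fractional_parameters(g, truth$eta, truth$delay),
                            C, cfg)
  } else stop("'truth' must be erlang_parameters or fractional_parameters",
              call. = FALSE)
  if (any(!is.finite(traj$w)))
    stop("dataset generation failed: non-finite simulated mass",
         call. = FALSE)
  idx <- pmin(pmax(round((obs - cfg$t_start) / cfg$step) + 1L, 1L),
              nrow(traj))
  w_true <- traj$w[idx]
  masses <- w_true
  if (design$noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
    masses <- w_true * exp(stats::rnorm(length(w_true), 0,
                                        design$noise_sigma))
  }
  model <- if (inherits(truth, "erlang_parameters")) "erlang" else "fractional"
  tumor_dataset(obs, masses, meta = list(
    truth_model = model,
    truth = truth, w_true = w_true, seed = seed, design = design,
    generator = paste0("fractcm ", as.character(utils::packageVersion("fractcm")))))
}
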