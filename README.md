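# fractcm

Transit compartment models (TCMs) for drug-delayed tumor growth
inhibition, in two flavors:

* the classical **Erlang TCM** — proliferating cells `u` feed a chain of
  `n` damaged compartments with transit rate `k1` (linear chain trick;
  Erlang-distributed stage residence, mean residence time `n/k1`);
* a **fractional TCM** — the chain is replaced by a single damaged state
  `y` whose delayed elimination is a Caputo fractional derivative,
  `y' = k_out − τ^{−α} D^{1−α} y`, equivalent to a Mittag-Leffler
  distributed residence time with survival `S(t) = E_α(−(t/τ)^α)`. The
  delay shape is estimated continuously through `(α, τ)` instead of
  through a pre-specified chain length.

Around the two models the package provides everything needed to run the
standard experiments end to end:

* one- and two-parameter **Mittag-Leffler** evaluation (series + integral
  representation, 10+ significant digits on the working range);
* a fixed-step **Adams–Bashforth–Moulton predictor–corrector** for
  multi-order Caputo systems (per-state orders in (0, 1], compiled core);
* a closed-form **two-compartment PK model** with repeated bolus dosing;
* a **convolution reference simulator** for arbitrary delay densities
  (Erlang, Mittag-Leffler, point delay) — the independent oracle against
  which both model formulations are cross-validated;
* bounded nonlinear least-squares **fitting** with RMSE and the
  RMSE-parameterized AIC `N(ln 2π + 1) + 2N ln RMSE + 2(k+1)`,
  compartment-number selection, and a data-amount subset experiment;
* **LHS/PRCC sensitivity analysis** (time-resolved partial rank
  correlations) and delay-robustness sweeps;
* a **synthetic-data generator** reproducing the reference study design
  (0.0121 g implant at day 0, ten daily boluses of 4.5e7 ng/kg from day
  13, ten observations over days 0–60) with known ground truth, so every
  module is testable without any external data.

## Worked example

```r
library(fractcm)

C <- solve_pk(pk_parameters(), daily_dose_schedule())
C(13)                                  # post-bolus plasma concentration
#> [1] 43774.32                        # ng/ml = dose/V

cfg <- solver_config(0, 60, step = 2^-8)
tr <- simulate_fractional_tcm(fractional_parameters(), C, cfg)
nadir_time(tr)                         # post-treatment minimum of w = u + y
#> [1] 28.76953                        # days: regrowth after dosing stops
range(tr$w)
#> [1] 0.0121000 7.7083957             # g

# round trip: generate a ten-point dataset at known truth, refit it
ds <- generate_dataset(fractional_parameters(), study_design(), seed = 1)
fit <- fit_model(ds, "fractional")     # published starts/bounds
fit
#> Fractional TCM fit: alpha = 0.95, eta = 0.24657, tau = 3.7048
#>   RMSE = 0.00051843 g, AIC = -114.92 (k = 3), converged after 8 iterations
```

The refit recovers the generating parameters (α = 0.945, η = 0.24657,
τ = 3.6852) to within 0.6 %, with α settling on its published estimation
bound of 0.95 — see the methods vignette
(`vignettes/fractional-tcm-methods.Rmd`) for why that bound exists and
for every numerical convention (solver weights, the concentration scale
in the kill term, dose-jump handling, PRCC details).

Model comparison on a dataset:

```r
cmp <- run_compare(read_run_config(), data = ds)
cmp$table        # model, k, rmse, aic side by side + delta AIC
```

A thin command-line wrapper over the same functions lives at
`inst/cli/fractcm.R` (subcommands: simulate, compare, generate, fit,
select-n, subset, sensitivity, robustness; YAML config, flag overrides).

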