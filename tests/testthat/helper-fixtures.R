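# shared fixtures: standard PK / dosing / growth setup and reference
# implementations used as independent oracles

std_pk <- pk_parameters()
std_doses <- daily_dose_schedule()
std_C <- solve_pk(std_pk, std_doses)

# frozen high-precision Mittag-Leffler reference values, computed with an
# arbitrary-precision series (precision scaled to the cancellation size)
# plus the large-argument asymptotic expansion as an independent route
ml_reference <- data.frame(
  alpha = c(0.5, 0.7, 0.7, 0.7, 0.7, 0.3, 0.9, 0.7, 0.7, 0.945, 0.5, 0.5,
            0.945, 0.999, 0.6, 0.8, 0.5),
  beta  = c(1, 1, 1, 1, 1, 1, 1, 0.7, 0.7, 0.945, 0.5, 0.5, 1, 1, 1, 1.5, 1),
  z     = c(-1, -0.5, -5, -30, -50, -2, -10, -0.5, -5, -3, -2, -6, -14, -1,
            -2.5, -4, -31.6227766016838),
  value = c(0.427583576155807, 0.60514759205956427, 0.077569357764769802,
            0.011444251527526973, 0.0067936656703830928,
            0.29023222616787535, 0.012820606051102103,
            0.38661080082252713, 0.012201124167156127,
            0.046399762203043819, 0.053398230926744799,
            0.0075301767445261606, 0.0047077729401797275,
            0.36794468034194147, 0.19091670740116979,
            0.19432625406215133, 0.017832333888542047))

# independent classical ABM PECE (cumulative-Euler predictor, composite
# trapezoidal corrector with post-correction evaluation), the order-1
# member of the product-integration family, written directly
classical_abm <- function(rhs, y0, t0, h, N) {
  d <- length(y0)
  Y <- matrix(0, N + 1L, d)
  F <- matrix(0, N + 1L, d)
  Y[1, ] <- y0
  F[1, ] <- rhs(t0, y0)
  for (n in seq_len(N)) {
    tn <- t0 + n * h
    yp <- y0 + h * colSums(F[1:n, , drop = FALSE])
    fp <- rhs(tn, yp)
    hist <- 0.5 * F[1, ]
    if (n > 1L) hist <- hist + colSums(F[2:n, , drop = FALSE])
    yc <- y0 + h * (hist + 0.5 * fp)
    F[n + 1L, ] <- rhs(tn, yc)
    Y[n + 1L, ] <- yc
  }
  Y
}

# quick dataset helpers (coarse grids keep the unit tests fast; the
# acceptance tests use the full-resolution setup)
coarse_cfg <- function(t_end = 30, step = 2^-6) solver_config(0, t_end, step)

coarse_design <- function(noise_sigma = 0)
  study_design(observation_times = c(0, 7, 13, 16, 19, 22, 25, 28, 30),
               noise_sigma = noise_sigma)
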