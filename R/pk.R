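#' Two-compartment pharmacokinetic parameters
#'
#' Rate constants of the linear two-compartment disposition model
#' \deqn{q_1' = -k_{01} q_1 - k_{21} q_1 + k_{12} q_2 + v(t), \quad
#'       q_2' = k_{21} q_1 - k_{12} q_2, \quad C = q_1 / V,}
#' with `q1` the drug amount in plasma (ng/kg), `q2` in the peripheral
#' compartment, and `v(t)` bolus input. Defaults are the mouse-xenograft
#' values used throughout the tumor experiments.
#'
#' @param k01 Elimination rate from plasma (1/day).
#' @param k21 Plasma-to-peripheral rate (1/day).
#' @param k12 Peripheral-to-plasma rate (1/day).
#' @param V Plasma volume (ml).
#' @return An object of class `pk_parameters`.
#' @export
pk_parameters <- function(k01 = 1.6, k21 = 0.2353, k12 = 0.1699, V = 1028) {
  vals <- c(k01 = k01, k21 = k21, k12 = k12, V = V)
  if (any(!is.finite(vals))) stop("PK parameters must be finite", call. = FALSE)
  if (k01 < 0 || k21 < 0 || k12 < 0)
    stop("rate constants must be >= 0", call. = FALSE)
  if (V <= 0) stop("'V' must be > 0", call. = FALSE)
  structure(list(k01 = k01, k21 = k21, k12 = k12, V = V),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf(
    "Two-compartment PK: k01 = %g, k21 = %g, k12 = %g /d, V = %g ml\n",
    x$k01, x$k21, x$k12, x$V))
  invisible(x)
}

#' Bolus dose schedule
#'
#' An ordered sequence of bolus events. Amounts are in ng/kg and are added
#' to the plasma compartment instantaneously at the event time
#' (right-limit convention: an observation at exactly a dose time sees the
#' post-dose concentration).
#'
#' @param times Strictly increasing event times in days.
#' @param amounts Positive bolus amounts in ng/kg; recycled if scalar.
#' @return An object of class `dose_schedule`.
#' @seealso [daily_dose_schedule()] for the standard repeated-daily
#'   regimen, [read_dose_schedule()] for file input.
#' @export
dose_schedule <- function(times, amounts) {
  times <- as.numeric(times)
  if (length(times) == 0L)
    return(structure(list(times = numeric(0), amounts = numeric(0)),
                     class = "dose_schedule"))
  amounts <- rep_len(as.numeric(amounts), length(times))
  if (any(!is.finite(times)) || any(!is.finite(amounts)))
    stop("dose times and amounts must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("dose times must be strictly increasing", call. = FALSE)
  if (any(amounts <= 0))
    stop("dose amounts must be > 0", call. = FALSE)
  structure(list(times = times, amounts = amounts), class = "dose_schedule")
}

#' Daily repeated-bolus schedule
#'
#' Convenience constructor for the regimen used in the tumor experiments:
#' `n` daily boluses of `amount` ng/kg starting on day `start`. Defaults
#' give ten daily doses of 4.5e7 ng/kg on days 13-22.
#'
#' @param n Number of daily doses.
#' @param amount Bolus amount per dose (ng/kg).
#' @param start First dose day.
#' @return A [dose_schedule()].
#' @export
daily_dose_schedule <- function(n = 10, amount = 4.5e7, start = 13) {
  stopifnot(n >= 1)
  dose_schedule(start + seq_len(n) - 1, amount)
}

#' @export
print.dose_schedule <- function(x, ...) {
  if (length(x$times) == 0L) {
    cat("Dose schedule: (empty)\n")
  } else {
    cat(sprintf("Dose schedule: %d bolus event(s), days %g-%g, total %g ng/kg\n",
                length(x$times), min(x$times), max(x$times), sum(x$amounts)))
  }
  invisible(x)
}

#' Read / write dose schedules as two-column delimited text
#'
#' The file format is one header line followed by `time amount` records
#' (whitespace or tab separated, dot decimal).
#'
#' @param file Path to read from or write to.
#' @param x A [dose_schedule()] (for writing).
#' @return `read_dose_schedule()` returns a [dose_schedule()];
#'   `write_dose_schedule()` returns `file` invisibly.
#' @export
read_dose_schedule <- function(file) {
  d <- utils::read.table(file, header = TRUE)
  if (ncol(d) < 2L) stop("expected two columns (time, amount)", call. = FALSE)
  dose_schedule(d[[1]], d[[2]])
}

#' @rdname read_dose_schedule
#' @export
write_dose_schedule <- function(x, file) {
  stopifnot(inherits(x, "dose_schedule"))
  utils::write.table(data.frame(time = x$times, amount = x$amounts),
                     file, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(file)
}

# 2x2 matrix exponential factors for the disposition matrix
#   A = [ -(k01+k21)  k12 ; k21  -k12 ]
# Returns a function (dt, q) -> q(dt) propagating a state across a
# dose-free interval, using the eigendecomposition, with the limiting
# (repeated-eigenvalue) formula e^{A dt} = e^{l dt}(I + (A - l I) dt)
# when the discriminant vanishes.
.pk_propagator <- function(p) {
  A <- matrix(c(-(p$k01 + p$k21), p$k21, p$k12, -p$k12), 2, 2)
  tr <- A[1, 1] + A[2, 2]
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  disc <- tr^2 - 4 * det
  if (disc > 1e-12 * max(tr^2, 1e-30)) {
    sq <- sqrt(disc)
    l1 <- (tr + sq) / 2
    l2 <- (tr - sq) / 2
    # eigenvectors for a 2x2: v = (k12, l + k01 + k21) works unless k12 = 0
    if (p$k12 != 0 || p$k21 != 0) {
      V <- cbind(c(A[1, 2], l1 - A[1, 1]), c(A[1, 2], l2 - A[1, 1]))
      if (abs(A[1, 2]) < 1e-300)  # k12 = 0: A lower triangular
        V <- cbind(c(l1 - A[2, 2], A[2, 1]), c(0, 1))
      Vi <- solve(V)
      function(dt, q) {
        w <- Vi %*% q
        as.numeric(V %*% (w * exp(c(l1, l2) * dt)))
      }
    } else {
      # diagonal A (k12 = k21 = 0)
      function(dt, q) q * exp(c(A[1, 1], A[2, 2]) * dt)
    }
  } else {
    l <- tr / 2
    B <- A - diag(l, 2)
    function(dt, q) as.numeric(exp(l * dt) * (q + dt * (B %*% q)))
  }
}

#' Solve the two-compartment PK model with repeated boluses
#'
#' Builds the plasma concentration `C(t) = q1(t)/V` in closed form: between
#' dose events the linear system is propagated exactly by its matrix
#' exponential (eigendecomposition, with the repeated-eigenvalue limit
#' handled analytically); at each event `q1` jumps by the bolus amount and
#' `q2` is continuous. Because the solution is analytic, the tumor solvers
#' can query `C` at arbitrary predictor/corrector nodes with no
#' interpolation error.
#'
#' @param p A [pk_parameters()].
#' @param doses A [dose_schedule()]; an empty schedule gives `C == 0`.
#' @return A function `C(t)` (vectorized, ng/ml) of class
#'   `concentration_function`, with an attribute `state`, a function
#'   returning the compartment amounts `cbind(q1, q2)` used by the
#'   mass-balance checks.
#' @examples
#' C <- solve_pk(pk_parameters(), daily_dose_schedule())
#' C(c(12, 13, 13.5))
#' @export
solve_pk <- function(p, doses) {
  stopifnot(inherits(p, "pk_parameters"), inherits(doses, "dose_schedule"))
  m <- length(doses$times)
  if (m == 0L) {
    f <- function(t) rep(0, length(t))
    attr(f, "state") <- function(t) cbind(q1 = rep(0, length(t)),
                                          q2 = rep(0, length(t)))
    attr(f, "dose_times") <- numeric(0)
    class(f) <- c("concentration_function", "function")
    return(f)
  }
  prop <- .pk_propagator(p)
  # segment-initial states: just after each dose
  Q <- matrix(0, m, 2)
  q <- c(0, 0)
  for (k in seq_len(m)) {
    if (k > 1L) q <- prop(doses$times[k] - doses$times[k - 1L], q)
    q[1] <- q[1] + doses$amounts[k]
    Q[k, ] <- q
  }
  starts <- doses$times
  state <- function(t) {
    t <- as.numeric(t)
    out <- matrix(0, length(t), 2, dimnames = list(NULL, c("q1", "q2")))
    seg <- findInterval(t, starts)   # 0 before the first dose; post-dose at ties
    for (k in unique(seg[seg > 0L])) {
      idx <- which(seg == k)
      for (ii in idx) out[ii, ] <- prop(t[ii] - starts[k], Q[k, ])
    }
    out
  }
  f <- function(t) unname(state(t)[, 1]) / p$V
  attr(f, "state") <- state
  attr(f, "dose_times") <- doses$times
  class(f) <- c("concentration_function", "function")
  f
}

#' @export
print.concentration_function <- function(x, ...) {
  cat("Closed-form plasma concentration function C(t) [ng/ml]\n")
  invisible(x)
}

#' Cross-check the closed-form PK solution against numerical integration
#'
#' Integrates the two-compartment system with `deSolve::lsoda` (bolus
#' events injected as state jumps) and returns the maximum relative
#' deviation of the closed-form `q1` from the numerical reference over a
#' fine grid. Used by the test suite to guard the analytic propagator.
#'
#' @param p A [pk_parameters()].
#' @param doses A [dose_schedule()].
#' @param t_end End of the comparison window (days); defaults to 10 days
#'   after the last dose.
#' @param n_grid Number of comparison points.
#' @return Maximum relative deviation (scalar); 0 when both are constant.
#' @export
pk_reference_check <- function(p, doses, t_end = NULL, n_grid = 400L) {
  stopifnot(inherits(p, "pk_parameters"), inherits(doses, "dose_schedule"))
  if (length(doses$times) == 0L) return(0)
  if (is.null(t_end)) t_end <- max(doses$times) + 10
  Cfun <- solve_pk(p, doses)
  # compare strictly between events: the closed form is right-continuous at
  # a bolus while the numerical integrator reports the pre-event state there
  grid <- sort(unique(c(seq(0, t_end, length.out = n_grid), doses$times)))
  deriv <- function(t, y, parms) {
    list(c(-(p$k01 + p$k21) * y[1] + p$k12 * y[2],
           p$k21 * y[1] - p$k12 * y[2]))
  }
  ev <- data.frame(var = "q1", time = doses$times, value = doses$amounts,
                   method = "add")
  num <- deSolve::ode(c(q1 = 0, q2 = 0), times = grid, func = deriv,
                      parms = NULL, events = list(data = ev),
                      rtol = 1e-11, atol = 1e-8)
  keep <- !grid %in% doses$times
  qa <- attr(Cfun, "state")(grid[keep])[, 1]
  qn <- num[keep, "q1"]
  scale <- max(abs(qn))
  if (scale == 0) return(0)
  max(abs(qa - qn)) / scale
}
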