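#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step predictor-corrector (PECE) scheme of Adams-Bashforth-Moulton
// type for multi-order Caputo systems, 0 < alpha_i <= 1. Each state is
// advanced with its own order's product-rectangle (predictor) and
// product-trapezoidal (corrector) weights while the right-hand side couples
// all states. Full history, O(N^2); weights depend only on the lag n-j and
// are precomputed once per call.
//
// Predictor: yP_i(t_n) = y0_i + h^a/Gamma(a+1) * sum_{j<n} b[n-j] f_ij
//   with b[m] = m^a - (m-1)^a.
// Corrector: y_i(t_n) = y0_i + h^a/Gamma(a+2) *
//   ( c0(n) f_i0 + sum_{0<j<n} a[n-j] f_ij + f_i(t_n, yP) ),
//   a[m] = (m+1)^{a+1} - 2 m^{a+1} + (m-1)^{a+1},
//   c0(n) = (n-1)^{a+1} - (n-1-a) n^a.
// At alpha = 1 this reduces exactly to the classical cumulative-Euler
// predictor / composite-trapezoidal corrector ABM scheme.
//
// The rhs is an R closure; it is invoked through a preallocated call with
// the time and state vectors updated in place, which keeps the per-step
// overhead small. History sums run over contiguous per-state buffers with
// unrolled accumulators (they dominate the cost at ~N^2/2 lags per state).

namespace {

struct RhsCaller {
  SEXP call, tS, yS, env;
  int d;
  RhsCaller(SEXP rhs, int d_, SEXP env_) : d(d_) {
    tS = PROTECT(Rf_allocVector(REALSXP, 1));
    yS = PROTECT(Rf_allocVector(REALSXP, d_));
    call = PROTECT(Rf_lang3(rhs, tS, yS));
    env = env_;
  }
  ~RhsCaller() { UNPROTECT(3); }
  // evaluate rhs(t, y) into out; returns false on wrong length
  bool eval(double t, const double* y, double* out) {
    REAL(tS)[0] = t;
    std::copy(y, y + d, REAL(yS));
    SEXP ans = PROTECT(Rf_eval(call, env));
    if (TYPEOF(ans) != REALSXP) {
      SEXP coerced = PROTECT(Rf_coerceVector(ans, REALSXP));
      UNPROTECT(2);
      PROTECT(ans = coerced);
    }
    if (Rf_length(ans) != d) { UNPROTECT(1); return false; }
    std::copy(REAL(ans), REAL(ans) + d, out);
    UNPROTECT(1);
    return true;
  }
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix fde_pece_cpp(NumericVector alpha, NumericVector y0, double t0,
                           double h, int nsteps, Function rhs,
                           int corrector_iterations) {
  const int d = y0.size();
  const int N = nsteps;
  NumericMatrix Y(N + 1, d);                       // states on the grid
  std::vector< std::vector<double> > F(d);         // rhs history per state
  std::vector< std::vector<double> > bw(d), aw(d); // lag weights per state
  std::vector<double> ha1(d), ha2(d);   // h^a/Gamma(a+1), h^a/Gamma(a+2)

  for (int i = 0; i < d; ++i) {
    double a = alpha[i];
    ha1[i] = std::pow(h, a) / std::tgamma(a + 1.0);
    ha2[i] = std::pow(h, a) / std::tgamma(a + 2.0);
    F[i].assign(N + 1, 0.0);
    bw[i].assign(N + 1, 0.0);
    aw[i].assign(N + 1, 0.0);
    for (int m = 1; m <= N; ++m) {
      bw[i][m] = std::pow((double)m, a) - std::pow((double)(m - 1), a);
      aw[i][m] = std::pow((double)(m + 1), a + 1.0)
               - 2.0 * std::pow((double)m, a + 1.0)
               + std::pow((double)(m - 1), a + 1.0);
    }
  }

  RhsCaller caller(rhs, d, R_GlobalEnv);
  std::vector<double> state(d), pred(d), fn(d), hist_c(d);
  for (int i = 0; i < d; ++i) { Y(0, i) = y0[i]; state[i] = y0[i]; }
  if (!caller.eval(t0, state.data(), fn.data()))
    stop("rhs returned a vector of wrong length");
  for (int i = 0; i < d; ++i) {
    if (!R_FINITE(fn[i])) stop("non-finite rhs output at t = %f", t0);
    F[i][0] = fn[i];
  }

  for (int n = 1; n <= N; ++n) {
    double tn = t0 + (double)n * h;
    // predictor + history part of the corrector in one pass per state
    for (int i = 0; i < d; ++i) {
      const double* __restrict b = bw[i].data();
      const double* __restrict aa = aw[i].data();
      const double* __restrict f = F[i].data();
      double sp0 = 0, sp1 = 0, sc0 = 0, sc1 = 0;
      int j = 1;
      for (; j + 1 < n; j += 2) {
        sp0 += b[n - j] * f[j];       sc0 += aa[n - j] * f[j];
        sp1 += b[n - j - 1] * f[j + 1]; sc1 += aa[n - j - 1] * f[j + 1];
      }
      for (; j < n; ++j) { sp0 += b[n - j] * f[j]; sc0 += aa[n - j] * f[j]; }
      double a = alpha[i];
      double c0 = std::pow((double)(n - 1), a + 1.0)
                - ((double)n - 1.0 - a) * std::pow((double)n, a);
      pred[i] = y0[i] + ha1[i] * (sp0 + sp1 + b[n] * f[0]);
      hist_c[i] = sc0 + sc1 + c0 * f[0];
    }
    if (!caller.eval(tn, pred.data(), fn.data()))
      stop("rhs returned a vector of wrong length");
    for (int it = 0; it < corrector_iterations; ++it) {
      for (int i = 0; i < d; ++i) {
        if (!R_FINITE(fn[i])) stop("non-finite rhs output at t = %f", tn);
        state[i] = y0[i] + ha2[i] * (hist_c[i] + fn[i]);
      }
      if (!caller.eval(tn, state.data(), fn.data()))
        stop("rhs returned a vector of wrong length");
    }
    for (int i = 0; i < d; ++i) {
      if (!R_FINITE(fn[i])) stop("non-finite rhs output at t = %f", tn);
      Y(n, i) = state[i];
      F[i][n] = fn[i];
    }
  }
  return Y;
}
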