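#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Four-parameter log-logistic model evaluated in log-dose:
//   y(x) = L + (U - L) * s,  s = 1 / (1 + exp(-hill * (x - m)))
// with x = log(dose), m = log(ec50). hill > 0: response rises with dose.
// x = -Inf (dose 0) is handled as the limiting value.
//
// Parameters are th[4] = {L, U, m, hill}. A logical mask marks which
// parameters are free; fixed parameters (e.g. a pinned lower asymptote in
// ZIP conditional fits) keep their starting value.

static inline double sigm(double z) {
  if (z > 0) {
    return 1.0 / (1.0 + std::exp(-z));
  } else {
    double e = std::exp(z);
    return e / (1.0 + e);
  }
}

static inline double pred1(const double* th, double x) {
  if (!std::isfinite(x)) {               // dose 0 -> limit
    if (x < 0) return (th[3] > 0) ? th[0] : th[1];
    return (th[3] > 0) ? th[1] : th[0];
  }
  double s = sigm(th[3] * (x - th[2]));
  return th[0] + (th[1] - th[0]) * s;
}

static double sse_of(const double* th, const double* x, const double* y, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double r = y[i] - pred1(th, x[i]);
    s += r * r;
  }
  return s;
}

// Solve A z = b for a k x k symmetric system by Gaussian elimination with
// partial pivoting. Returns false when (numerically) singular.
static bool solve_sym(double A[4][4], double b[4], double z[4], int k) {
  double M[4][5];
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j < k; ++j) M[i][j] = A[i][j];
    M[i][k] = b[i];
  }
  for (int c = 0; c < k; ++c) {
    int piv = c;
    for (int r = c + 1; r < k; ++r)
      if (std::fabs(M[r][c]) > std::fabs(M[piv][c])) piv = r;
    if (std::fabs(M[piv][c]) < 1e-300) return false;
    if (piv != c)
      for (int j = c; j <= k; ++j) std::swap(M[piv][j], M[c][j]);
    for (int r = c + 1; r < k; ++r) {
      double f = M[r][c] / M[c][c];
      for (int j = c; j <= k; ++j) M[r][j] -= f * M[c][j];
    }
  }
  for (int r = k - 1; r >= 0; --r) {
    double s = M[r][k];
    for (int j = r + 1; j < k; ++j) s -= M[r][j] * z[j];
    z[r] = s / M[r][r];
  }
  return true;
}

struct FitOut {
  double th[4];
  double sse;
  bool converged;
};

// Levenberg-Marquardt on the free parameters. tol is the relative SSE
// improvement below which we declare convergence; maxit caps LM steps.
static FitOut lm4pl(const double* x, const double* y, int n,
                    const double* start, const bool* freep,
                    int maxit, double tol) {
  FitOut out;
  double th[4] = {start[0], start[1], start[2], start[3]};
  int idx[4], k = 0;
  for (int j = 0; j < 4; ++j) if (freep[j]) idx[k++] = j;

  double sse = sse_of(th, x, y, n);
  double lambda = 1e-3;
  bool conv = false;

  for (int it = 0; it < maxit && k > 0; ++it) {
    // Jacobian of residuals r_i = y_i - f(x_i) w.r.t. free params
    double A[4][4] = {{0}}, g[4] = {0};
    for (int i = 0; i < n; ++i) {
      double xi = x[i];
      double L = th[0], U = th[1], m = th[2], h = th[3];
      double s, ds_dm, ds_dh;
      if (!std::isfinite(xi)) {
        s = (xi < 0) ? (h > 0 ? 0.0 : 1.0) : (h > 0 ? 1.0 : 0.0);
        ds_dm = 0.0; ds_dh = 0.0;
      } else {
        double z = h * (xi - m);
        s = sigm(z);
        double sp = s * (1.0 - s);
        ds_dm = -h * sp;
        ds_dh = (xi - m) * sp;
      }
      double f = L + (U - L) * s;
      double r = y[i] - f;
      double J[4];
      J[0] = 1.0 - s;
      J[1] = s;
      J[2] = (U - L) * ds_dm;
      J[3] = (U - L) * ds_dh;
      for (int a = 0; a < k; ++a) {
        g[a] += J[idx[a]] * r;
        for (int b = a; b < k; ++b)
          A[a][b] += J[idx[a]] * J[idx[b]];
      }
    }
    for (int a = 0; a < k; ++a)
      for (int b = 0; b < a; ++b) A[a][b] = A[b][a];

    bool stepped = false;
    for (int tries = 0; tries < 25; ++tries) {
      double Ad[4][4], d[4];
      for (int a = 0; a < k; ++a) {
        for (int b = 0; b < k; ++b) Ad[a][b] = A[a][b];
        double diag = A[a][a];
        if (diag <= 0) diag = 1e-12;
        Ad[a][a] = diag * (1.0 + lambda);
      }
      if (!solve_sym(Ad, g, d, k)) { lambda *= 10; continue; }
      double trial[4] = {th[0], th[1], th[2], th[3]};
      for (int a = 0; a < k; ++a) trial[idx[a]] += d[a];
      // keep parameters in a sane numeric box
      if (trial[2] > 1e4) trial[2] = 1e4;
      if (trial[2] < -1e4) trial[2] = -1e4;
      if (trial[3] > 100) trial[3] = 100;
      if (trial[3] < -100) trial[3] = -100;
      double s2 = sse_of(trial, x, y, n);
      if (std::isfinite(s2) && s2 <= sse) {
        double rel = (sse - s2) / (sse > 1e-300 ? sse : 1.0);
        for (int j = 0; j < 4; ++j) th[j] = trial[j];
        sse = s2;
        lambda = std::max(lambda / 3.0, 1e-12);
        stepped = true;
        if (rel < tol) conv = true;
        break;
      }
      lambda *= 5.0;
    }
    if (!stepped) { conv = true; break; }  // cannot improve further
    if (conv) break;
  }
  for (int j = 0; j < 4; ++j) out.th[j] = th[j];
  out.sse = sse;
  out.converged = conv;
  return out;
}

// [[Rcpp::export(name = ".cpp_fit4pl_best")]]
List cpp_fit4pl_best(NumericVector logdose, NumericVector y,
                     NumericMatrix starts, LogicalVector freep,
                     int maxit, double tol) {
  int n = logdose.size();
  bool fr[4];
  for (int j = 0; j < 4; ++j) fr[j] = freep[j];
  FitOut best;
  best.sse = std::numeric_limits<double>::infinity();
  best.converged = false;
  for (int j = 0; j < 4; ++j) best.th[j] = NA_REAL;
  for (int s = 0; s < starts.nrow(); ++s) {
    double st[4] = {starts(s, 0), starts(s, 1), starts(s, 2), starts(s, 3)};
    FitOut f = lm4pl(REAL(logdose), REAL(y), n, st, fr, maxit, tol);
    bool better = f.sse < best.sse * (1.0 - 1e-12);
    bool tie = std::fabs(f.sse - best.sse) <=
               1e-12 * std::max(1.0, std::fabs(best.sse));
    if (better || (tie && std::fabs(f.th[3]) < std::fabs(best.th[3]))) {
      best = f;
    }
  }
  return List::create(_["par"] = NumericVector::create(best.th[0], best.th[1],
                                                       best.th[2], best.th[3]),
                      _["sse"] = best.sse,
                      _["converged"] = best.converged);
}

// Batch fitter: row i of X/Y is one dataset; row i of starts its warm start.
// Returns an m x 6 matrix: L, U, m(log ec50), hill, sse, converged.
// [[Rcpp::export(name = ".cpp_fit4pl_batch")]]
NumericMatrix cpp_fit4pl_batch(NumericMatrix X, NumericMatrix Y,
                               NumericMatrix starts, LogicalVector freep,
                               int maxit, double tol) {
  int m = X.nrow(), n = X.ncol();
  bool fr[4];
  for (int j = 0; j < 4; ++j) fr[j] = freep[j];
  NumericMatrix out(m, 6);
  std::vector<double> x(n), y(n);
  for (int i = 0; i < m; ++i) {
    for (int c = 0; c < n; ++c) { x[c] = X(i, c); y[c] = Y(i, c); }
    double st[4] = {starts(i, 0), starts(i, 1), starts(i, 2), starts(i, 3)};
    FitOut f = lm4pl(x.data(), y.data(), n, st, fr, maxit, tol);
    out(i, 0) = f.th[0]; out(i, 1) = f.th[1];
    out(i, 2) = f.th[2]; out(i, 3) = f.th[3];
    out(i, 4) = f.sse;   out(i, 5) = f.converged ? 1.0 : 0.0;
  }
  return out;
}

// Null distribution for the paralog preference statistic. For each of
// n_sim null datasets (responses pre-generated in R), fit enzyme A and B
// curves per run, compute log(ICq_A / ICq_B) from the fitted parameters,
// and return |mean over runs| per simulation. YA/YB are (n_sim*R) x n
// matrices (simulation-major blocks of R runs); starts is the pooled-fit
// warm start per run (R x 4). q is the remaining-activity level (e.g. 75).
// [[Rcpp::export(name = ".cpp_paralog_null_stats")]]
NumericVector cpp_paralog_null_stats(NumericVector logdose,
                                     NumericMatrix YA, NumericMatrix YB,
                                     NumericMatrix starts, int n_sim, int R,
                                     double q, int maxit, double tol) {
  int n = logdose.size();
  bool fr[4] = {true, true, true, true};
  NumericVector out(n_sim);
  std::vector<double> x(n), y(n);
  for (int c = 0; c < n; ++c) x[c] = logdose[c];
  for (int s = 0; s < n_sim; ++s) {
    double sum = 0.0;
    int used = 0;
    for (int r = 0; r < R; ++r) {
      int row = s * R + r;
      double st[4] = {starts(r, 0), starts(r, 1), starts(r, 2), starts(r, 3)};
      double icq[2];
      bool ok = true;
      for (int e = 0; e < 2 && ok; ++e) {
        for (int c = 0; c < n; ++c)
          y[c] = (e == 0) ? YA(row, c) : YB(row, c);
        FitOut f = lm4pl(x.data(), y.data(), n, st, fr, maxit, tol);
        double L = f.th[0], U = f.th[1];
        double fl = (q - L) / (U - L);
        if (!(fl > 0.0 && fl < 1.0) || !std::isfinite(f.th[2])) { ok = false; break; }
        icq[e] = f.th[2] + std::log(fl / (1.0 - fl)) / f.th[3];
      }
      if (ok && std::isfinite(icq[0]) && std::isfinite(icq[1])) {
        sum += icq[0] - icq[1];   // log ratio (log doses subtract)
        ++used;
      }
    }
    out[s] = (used > 0) ? std::fabs(sum / used) : NA_REAL;
  }
  return out;
}
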