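#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Maximum-likelihood mixing weights for every kernel-size triple of a
// sigma grid. For each triple (ia, ir, ip) the per-step normalised
// component probabilities of the chosen pile are the columns A[,ia],
// R[,ir], X[,ip]; the log-likelihood of weights (w1, w2, w3 = 1-w1-w2) is
//   LL(w) = sum_j log(w1 A_j + w2 R_j + w3 X_j)
//         - sum_j log(w1 + w2 Zr_j + w3 Zp_j),
// the denominator renormalising when the reward (Zr = 0) or proximity
// (Zp = 0) field vanishes at step j. Maximised by a damped projected
// Newton iteration with backtracking line search on the simplex interior
// (margin EPSW), warm-started from the previous triple's solution.

static const double EPSW = 1e-6;

struct StepData {
  const double *a, *r, *x, *zr, *zp;
  const int *rows;
  int n;
};

static inline void clip_w(double &w1, double &w2) {
  if (w1 < EPSW) w1 = EPSW;
  if (w2 < EPSW) w2 = EPSW;
  double s = w1 + w2;
  if (s > 1.0 - EPSW) {
    double f = (1.0 - EPSW) / s;
    w1 *= f;
    w2 *= f;
  }
}

static double loglik(const StepData &d, double w1, double w2) {
  double w3 = 1.0 - w1 - w2, ll = 0.0;
  for (int j = 0; j < d.n; ++j) {
    int i = d.rows[j];
    double num = w1 * d.a[i] + w2 * d.r[i] + w3 * d.x[i];
    double den = w1 + w2 * d.zr[i] + w3 * d.zp[i];
    if (num <= 0.0 || den <= 0.0) return -1e300;
    ll += std::log(num) - std::log(den);
  }
  return ll;
}

static void gradhess(const StepData &d, double w1, double w2,
                     double *g, double *h) {
  double w3 = 1.0 - w1 - w2;
  double g1 = 0, g2 = 0, h11 = 0, h12 = 0, h22 = 0;
  for (int j = 0; j < d.n; ++j) {
    int i = d.rows[j];
    double P = w1 * d.a[i] + w2 * d.r[i] + w3 * d.x[i];
    double D = w1 + w2 * d.zr[i] + w3 * d.zp[i];
    double da = d.a[i] - d.x[i], dr = d.r[i] - d.x[i];
    double ea = 1.0 - d.zp[i], er = d.zr[i] - d.zp[i];
    if (P <= 0.0 || D <= 0.0) continue;
    g1 += da / P - ea / D;
    g2 += dr / P - er / D;
    h11 += -da * da / (P * P) + ea * ea / (D * D);
    h12 += -da * dr / (P * P) + ea * er / (D * D);
    h22 += -dr * dr / (P * P) + er * er / (D * D);
  }
  g[0] = g1; g[1] = g2;
  h[0] = h11; h[1] = h12; h[2] = h22;
}

// one weight fit; returns iterations used
static int fit_one(const StepData &d, double &w1, double &w2, double &ll,
                   int maxit) {
  clip_w(w1, w2);
  ll = loglik(d, w1, w2);
  double g[2], h[3];
  int it = 0;
  for (; it < maxit; ++it) {
    gradhess(d, w1, w2, g, h);
    double gn = std::sqrt(g[0] * g[0] + g[1] * g[1]);
    if (gn < 1e-8 * (1.0 + std::fabs(ll))) break;
    double d1, d2;
    double det = h[0] * h[2] - h[1] * h[1];
    if (h[0] < 0.0 && det > 0.0) {          // negative definite: Newton
      d1 = -(h[2] * g[0] - h[1] * g[1]) / det;
      d2 = -(h[0] * g[1] - h[1] * g[0]) / det;
    } else {                                 // fallback: scaled ascent
      d1 = g[0] / gn * 0.1;
      d2 = g[1] / gn * 0.1;
    }
    double lam = 1.0, nll = ll;
    double nw1 = w1, nw2 = w2;
    bool ok = false;
    for (int ls = 0; ls < 40; ++ls) {
      nw1 = w1 + lam * d1;
      nw2 = w2 + lam * d2;
      clip_w(nw1, nw2);
      nll = loglik(d, nw1, nw2);
      if (nll > ll + 1e-12) { ok = true; break; }
      lam *= 0.5;
    }
    if (!ok) break;
    if (nll - ll < 1e-10 * (1.0 + std::fabs(ll))) { w1 = nw1; w2 = nw2; ll = nll; break; }
    w1 = nw1; w2 = nw2; ll = nll;
  }
  return it;
}

// [[Rcpp::export]]
NumericMatrix fit_weights_grid_cpp(NumericMatrix A, NumericMatrix R,
                                   NumericMatrix X, NumericMatrix Zr,
                                   NumericMatrix Zp, IntegerMatrix triples,
                                   IntegerVector rows, NumericVector winit,
                                   int maxit = 100) {
  int K = triples.nrow();
  NumericMatrix out(K, 4);
  std::vector<int> rws(rows.begin(), rows.end());
  double w1 = winit[0], w2 = winit[1];
  for (int k = 0; k < K; ++k) {
    int ia = triples(k, 0), ir = triples(k, 1), ip = triples(k, 2);
    StepData d;
    d.a = &A(0, ia); d.r = &R(0, ir); d.x = &X(0, ip);
    d.zr = &Zr(0, ir); d.zp = &Zp(0, ip);
    d.rows = rws.data(); d.n = (int) rws.size();
    double ll;
    double s1 = w1, s2 = w2;  // warm start from the previous triple
    int it = fit_one(d, s1, s2, ll, maxit);
    out(k, 0) = s1; out(k, 1) = s2; out(k, 2) = ll; out(k, 3) = it;
    w1 = s1; w2 = s2;
  }
  return out;
}
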