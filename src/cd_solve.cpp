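#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for one node's Gibbs minimisation.
//
// Objective (extensive, dimensionless):
//   G(xi) = sum_i n_i (g_i + log(n_i / N)),  n = n0 + S xi,  N = sum(n),
// which is convex in n (ideal mixing) and hence in xi.  Along one extent the
// derivative  dG/dxi_r = sum_i S_ir (g_i + log x_i)  is monotone increasing,
// so each coordinate minimisation is a safeguarded bisection on the
// derivative over the feasible interval (amounts >= 0, irreversibility,
// capacity bounds).  Descent is monotone and the zero extent is feasible, so
// the solution never exceeds the starting free energy.

static double coordDeriv(const NumericMatrix& S, const NumericVector& n,
                         double N, const NumericVector& g0, int r) {
  double d = 0.0;
  const int m = S.nrow();
  for (int i = 0; i < m; ++i) {
    double s = S(i, r);
    if (s == 0.0) continue;
    double ni = n[i];
    double lx = (ni > 0.0) ? std::log(ni / N) : -690.0; // exp(-690) ~ 1e-300
    d += s * (g0[i] + lx);
  }
  return d;
}

// [[Rcpp::export(rng = false)]]
List cdSolveNode(NumericMatrix S, NumericVector n0, NumericVector g0,
                 LogicalVector irr, NumericVector cap,
                 int maxRounds = 200, double tol = 1e-11) {
  const int m = S.nrow(), nr = S.ncol();
  NumericVector n = clone(n0);
  NumericVector xi(nr);
  double N = 0.0;
  for (int i = 0; i < m; ++i) {
    if (n[i] < 0.0) n[i] = 0.0;
    N += n[i];
  }
  NumericVector colsum(nr);
  for (int r = 0; r < nr; ++r) {
    double cs = 0.0;
    for (int i = 0; i < m; ++i) cs += S(i, r);
    colsum[r] = cs;
  }

  for (int round = 0; round < maxRounds; ++round) {
    double maxStep = 0.0;
    for (int r = 0; r < nr; ++r) {
      // feasible interval for the increment delta of xi_r
      double dlo = -std::numeric_limits<double>::infinity();
      double dhi = std::numeric_limits<double>::infinity();
      for (int i = 0; i < m; ++i) {
        double s = S(i, r);
        if (s < 0.0) {
          double lim = n[i] / (-s);
          if (lim < dhi) dhi = lim;
        } else if (s > 0.0) {
          double lim = -(n[i] / s);
          if (lim > dlo) dlo = lim;
        }
      }
      if (irr[r] && -xi[r] > dlo) dlo = -xi[r];
      if (R_finite(cap[r])) {
        double lim = cap[r] - xi[r];
        if (lim < dhi) dhi = lim;
      }
      if (!(dhi > dlo)) continue;

      // derivative is monotone increasing in delta; find its zero
      double flo = coordDeriv(S, n, N, g0, r); // at delta = 0 as reference
      double delta;
      // evaluate at the bounds via temporary updates
      auto derivAt = [&](double d) {
        double Nd = N + colsum[r] * d;
        double v = 0.0;
        for (int i = 0; i < m; ++i) {
          double s = S(i, r);
          if (s == 0.0) continue;
          double ni = n[i] + s * d;
          double lx = (ni > 0.0) ? std::log(ni / Nd) : -690.0;
          v += s * (g0[i] + lx);
        }
        return v;
      };
      (void)flo;
      double lo = dlo, hi = dhi;
      double fl = R_finite(lo) ? derivAt(lo) : -1.0;
      double fh = R_finite(hi) ? derivAt(hi) : 1.0;
      if (fl >= 0.0) {
        delta = R_finite(lo) ? lo : 0.0;
      } else if (fh <= 0.0) {
        delta = R_finite(hi) ? hi : 0.0;
      } else {
        // bisection; bracket is finite because fl < 0 < fh
        if (!R_finite(lo)) { // walk out to bracket
          lo = -1.0;
          while (derivAt(lo) < 0.0 && lo > -1e12) lo *= 4.0;
        }
        if (!R_finite(hi)) {
          hi = 1.0;
          while (derivAt(hi) > 0.0 && hi < 1e12) hi *= 4.0;
        }
        for (int it = 0; it < 80; ++it) {
          double mid = 0.5 * (lo + hi);
          if (derivAt(mid) < 0.0) lo = mid; else hi = mid;
          if (hi - lo < 1e-13 * (1.0 + std::fabs(lo))) break;
        }
        delta = 0.5 * (lo + hi);
      }
      if (delta == 0.0) continue;
      // commit
      for (int i = 0; i < m; ++i) {
        double s = S(i, r);
        if (s != 0.0) {
          n[i] += s * delta;
          if (n[i] < 0.0) n[i] = 0.0;
        }
      }
      N += colsum[r] * delta;
      if (N <= 0.0) { // cannot happen for balanced reactions; guard anyway
        N = 0.0;
        for (int i = 0; i < m; ++i) N += n[i];
      }
      xi[r] += delta;
      double st = std::fabs(delta);
      if (st > maxStep) maxStep = st;
    }
    if (maxStep < tol) break;
  }

  double G = 0.0;
  for (int i = 0; i < m; ++i) {
    if (n[i] > 0.0) G += n[i] * (g0[i] + std::log(n[i] / N));
  }
  return List::create(_["xi"] = xi, _["gibbs"] = G);
}
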