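#include <Rcpp.h>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// Responsibilities for the constrained K(K-1) mixture: cluster c has
// centre (levels[from[c]], levels[to[c]]) and isotropic variance
// sigma2[c].  Components more than ~37 log units below the per-point
// maximum contribute nothing at double precision and are zeroed without
// calling exp().
static double resp_fill(const NumericMatrix &x, const NumericVector &levels,
                        const NumericVector &w, const NumericVector &sigma2,
                        const IntegerVector &from, const IntegerVector &to,
                        NumericMatrix &resp) {
  const int n = x.nrow(), C = from.size();
  double ll = 0.0;
  std::vector<double> cst(C), inv2(C), Lf(C), Lt(C);
  for (int c = 0; c < C; ++c) {
    cst[c] = (w[c] > 0 ? std::log(w[c]) : -1e300) - LOG2PI - std::log(sigma2[c]);
    inv2[c] = 1.0 / (2.0 * sigma2[c]);
    Lf[c] = levels[from[c]];
    Lt[c] = levels[to[c]];
  }
  const double *xp = &x(0, 0);
  double *rp = &resp(0, 0);
  std::vector<double> ld(C);
  for (int i = 0; i < n; ++i) {
    const double x1 = xp[i], x2 = xp[i + n];
    double m = -1e300;
    for (int c = 0; c < C; ++c) {
      double dx = x1 - Lf[c], dy = x2 - Lt[c];
      double v = cst[c] - (dx * dx + dy * dy) * inv2[c];
      ld[c] = v;
      if (v > m) m = v;
    }
    double s = 0.0;
    for (int c = 0; c < C; ++c) {
      double v = ld[c] - m;
      double e = v > -37.0 ? std::exp(v) : 0.0;
      ld[c] = e;
      s += e;
    }
    ll += m + std::log(s);
    const double inv = 1.0 / s;
    for (int c = 0; c < C; ++c) rp[i + (long)n * c] = ld[c] * inv;
  }
  return ll;
}

// [[Rcpp::export]]
List tdp_resp_cpp(NumericMatrix x, NumericVector levels, NumericVector w,
                  NumericVector sigma2, IntegerVector from, IntegerVector to) {
  NumericMatrix resp(x.nrow(), from.size());
  double ll = resp_fill(x, levels, w, sigma2, from, to, resp);
  return List::create(_["loglik"] = ll, _["resp"] = resp);
}

// EM for the constrained mixture.  from/to are 0-based level indices per
// cluster.  Levels are updated by pooling x-coordinate evidence over
// clusters departing a level and y-coordinate evidence over clusters
// arriving at it, precision-weighted by the cluster variances.
// Convergence: relative log-likelihood gain below tol.
// [[Rcpp::export]]
List tdp_em_cpp(NumericMatrix x, NumericVector levels0, NumericVector w0,
                NumericVector sigma20, IntegerVector from, IntegerVector to,
                int max_iter, double tol, double var_floor) {
  const int n = x.nrow(), C = from.size();
  int K = levels0.size();
  NumericVector levels = clone(levels0), w = clone(w0), sigma2 = clone(sigma20);
  NumericMatrix resp(n, C);
  double ll = -1e300, ll_prev;
  int iter = 0;
  std::vector<double> Nc(C), S1(C), S2(C), SS1(C), SS2(C);
  const double *xp = &x(0, 0);
  for (iter = 1; iter <= max_iter; ++iter) {
    ll_prev = ll;
    ll = resp_fill(x, levels, w, sigma2, from, to, resp);
    if (iter > 1 && std::fabs(ll - ll_prev) < tol * (1.0 + std::fabs(ll))) break;
    for (int c = 0; c < C; ++c) { Nc[c] = S1[c] = S2[c] = SS1[c] = SS2[c] = 0.0; }
    const double *rp = &resp(0, 0);
    for (int c = 0; c < C; ++c) {
      const double *rc = rp + (long)n * c;
      double nc = 0, s1 = 0, s2 = 0, ss1 = 0, ss2 = 0;
      for (int i = 0; i < n; ++i) {
        double r = rc[i];
        if (r == 0.0) continue;
        double x1 = xp[i], x2 = xp[i + n];
        nc += r;
        s1 += r * x1;  ss1 += r * x1 * x1;
        s2 += r * x2;  ss2 += r * x2 * x2;
      }
      Nc[c] = nc; S1[c] = s1; S2[c] = s2; SS1[c] = ss1; SS2[c] = ss2;
    }
    // level update (precision-weighted across incident clusters)
    for (int k = 0; k < K; ++k) {
      double num = 0.0, den = 0.0;
      for (int c = 0; c < C; ++c) {
        double prec = 1.0 / sigma2[c];
        if (from[c] == k) { num += S1[c] * prec; den += Nc[c] * prec; }
        if (to[c] == k)   { num += S2[c] * prec; den += Nc[c] * prec; }
      }
      if (den > 1e-12) levels[k] = num / den;
    }
    // weight and variance update
    double wsum = 0.0;
    for (int c = 0; c < C; ++c) {
      w[c] = Nc[c] / n;
      double Lf = levels[from[c]], Lt = levels[to[c]];
      double ss = SS1[c] - 2.0 * Lf * S1[c] + Nc[c] * Lf * Lf
                + SS2[c] - 2.0 * Lt * S2[c] + Nc[c] * Lt * Lt;
      double v = Nc[c] > 1e-12 ? ss / (2.0 * Nc[c]) : var_floor;
      sigma2[c] = v < var_floor ? var_floor : v;
      if (w[c] < 1e-12) w[c] = 1e-12;
      wsum += w[c];
    }
    for (int c = 0; c < C; ++c) w[c] /= wsum;
  }
  return List::create(_["levels"] = levels, _["w"] = w, _["sigma2"] = sigma2,
                      _["loglik"] = ll, _["iter"] = iter);
}
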