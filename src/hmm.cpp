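#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward E-step for a Gaussian-emission HMM.
// Returns the log-likelihood, per-frame posteriors gamma (n x K) and the
// expected transition counts xi summed over time (K x K).
// [[Rcpp::export]]
List hmm_estep_cpp(NumericVector obs, NumericVector mu, NumericVector sd,
                   NumericMatrix trans, NumericVector pi) {
  const int n = obs.size(), K = mu.size();
  NumericMatrix b(n, K);
  for (int t = 0; t < n; ++t) {
    for (int k = 0; k < K; ++k)
      b(t, k) = R::dnorm(obs[t], mu[k], sd[k], 0);
  }
  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K);
  NumericVector c(n);
  // forward (scaled)
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * b(0, k); s += alpha(0, k); }
  if (s <= 0) s = 1e-300;
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < n; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      a *= b(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0) s = 1e-300;
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  // backward (scaled by the same constants)
  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double v = 0.0;
      for (int j = 0; j < K; ++j) v += trans(k, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, k) = v / c[t + 1];
    }
  }
  double ll = 0.0;
  for (int t = 0; t < n; ++t) ll += std::log(c[t]);
  // posteriors
  for (int t = 0; t < n; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    if (g <= 0) g = 1e-300;
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  // expected transition counts
  NumericMatrix xi(K, K);
  for (int t = 0; t < n - 1; ++t) {
    double z = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        z += alpha(t, j) * trans(j, k) * b(t + 1, k) * beta(t + 1, k);
    if (z <= 0) z = 1e-300;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * trans(j, k) * b(t + 1, k) * beta(t + 1, k) / z;
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding in log space; ties are broken toward the lowest state
// index (strict inequality when comparing candidates).
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector obs, NumericVector mu,
                              NumericVector sd, NumericMatrix trans,
                              NumericVector pi) {
  const int n = obs.size(), K = mu.size();
  const double NEG = -1e300;
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  NumericMatrix lb(n, K);
  for (int t = 0; t < n; ++t)
    for (int k = 0; k < K; ++k)
      lb(t, k) = R::dnorm(obs[t], mu[k], sd[k], 1);
  NumericMatrix lt(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      lt(j, k) = trans(j, k) > 0 ? std::log(trans(j, k)) : NEG;
  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi[k] > 0 ? std::log(pi[k]) : NEG) + lb(0, k);
  for (int t = 1; t < n; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + lt(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + lt(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + lb(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(n);
  int arg = 0;
  double best = delta(n - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(n - 1, k) > best) { best = delta(n - 1, k); arg = k; }
  path[n - 1] = arg;
  for (int t = n - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;  // 1-based state indices
}

// Full Baum-Welch EM: scaled forward-backward E-step and closed-form
// M-step, iterated until the log-likelihood gain falls below tol.
// Variances are floored at var_floor.  Returns the fitted parameters and
// the per-iteration log-likelihood trace.
// When tied_sd is true a single emission width shared by all states is
// estimated (camera read-out noise is state-independent); otherwise each
// state has its own width.
// [[Rcpp::export]]
List hmm_bw_cpp(NumericVector obs, NumericVector mu0, NumericVector sd0,
                NumericMatrix trans0, NumericVector pi0, double tol,
                int max_iter, double var_floor, bool tied_sd) {
  const int n = obs.size(), K = mu0.size();
  NumericVector mu = clone(mu0), sd = clone(sd0), pi = clone(pi0);
  NumericMatrix trans = clone(trans0);
  std::vector<double> ll_trace;
  bool converged = false, floored = false;
  NumericMatrix alpha(n, K), beta(n, K), b(n, K);
  NumericVector c(n);
  for (int it = 0; it < max_iter; ++it) {
    // emission densities
    for (int t = 0; t < n; ++t)
      for (int k = 0; k < K; ++k)
        b(t, k) = R::dnorm(obs[t], mu[k], sd[k], 0);
    // forward
    double s = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * b(0, k); s += alpha(0, k); }
    if (s <= 0) s = 1e-300;
    c[0] = s;
    for (int k = 0; k < K; ++k) alpha(0, k) /= s;
    for (int t = 1; t < n; ++t) {
      s = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
        a *= b(t, k);
        alpha(t, k) = a; s += a;
      }
      if (s <= 0) s = 1e-300;
      c[t] = s;
      for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    }
    double ll = 0.0;
    for (int t = 0; t < n; ++t) ll += std::log(c[t]);
    ll_trace.push_back(ll);
    if (it > 0 && ll - ll_trace[it - 1] < tol) { converged = true; break; }
    // backward
    for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
    for (int t = n - 2; t >= 0; --t)
      for (int k = 0; k < K; ++k) {
        double v = 0.0;
        for (int j = 0; j < K; ++j) v += trans(k, j) * b(t + 1, j) * beta(t + 1, j);
        beta(t, k) = v / c[t + 1];
      }
    // M-step accumulators
    std::vector<double> Ng(K, 0.0), Sx(K, 0.0), Sxx(K, 0.0), g0(K, 0.0);
    std::vector<double> xi(K * K, 0.0);
    for (int t = 0; t < n; ++t) {
      double gs = 0.0;
      std::vector<double> g(K);
      for (int k = 0; k < K; ++k) { g[k] = alpha(t, k) * beta(t, k); gs += g[k]; }
      if (gs <= 0) gs = 1e-300;
      for (int k = 0; k < K; ++k) {
        double gk = g[k] / gs;
        Ng[k] += gk; Sx[k] += gk * obs[t]; Sxx[k] += gk * obs[t] * obs[t];
        if (t == 0) g0[k] = gk;
      }
      if (t < n - 1) {
        double z = 0.0;
        for (int j = 0; j < K; ++j)
          for (int k = 0; k < K; ++k)
            z += alpha(t, j) * trans(j, k) * b(t + 1, k) * beta(t + 1, k);
        if (z <= 0) z = 1e-300;
        for (int j = 0; j < K; ++j)
          for (int k = 0; k < K; ++k)
            xi[j * K + k] += alpha(t, j) * trans(j, k) * b(t + 1, k) * beta(t + 1, k) / z;
      }
    }
    for (int k = 0; k < K; ++k) {
      double nk = Ng[k] > 1e-12 ? Ng[k] : 1e-12;
      mu[k] = Sx[k] / nk;
      pi[k] = g0[k];
    }
    if (tied_sd) {
      double ssq = 0.0, ntot = 0.0;
      for (int k = 0; k < K; ++k) {
        ssq += Sxx[k] - 2.0 * mu[k] * Sx[k] + Ng[k] * mu[k] * mu[k];
        ntot += Ng[k];
      }
      double v = ntot > 0 ? ssq / ntot : var_floor;
      if (v < var_floor) { v = var_floor; floored = true; }
      for (int k = 0; k < K; ++k) sd[k] = std::sqrt(v);
    } else {
      for (int k = 0; k < K; ++k) {
        double nk = Ng[k] > 1e-12 ? Ng[k] : 1e-12;
        double v = Sxx[k] / nk - mu[k] * mu[k];
        if (v < var_floor) { v = var_floor; floored = true; }
        sd[k] = std::sqrt(v);
      }
    }
    for (int j = 0; j < K; ++j) {
      double rs = 0.0;
      for (int k = 0; k < K; ++k) rs += xi[j * K + k];
      if (rs > 1e-12)
        for (int k = 0; k < K; ++k) trans(j, k) = xi[j * K + k] / rs;
    }
  }
  return List::create(_["mu"] = mu, _["sd"] = sd, _["trans"] = trans,
                      _["pi"] = pi,
                      _["loglik"] = ll_trace.back(),
                      _["ll_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
                      _["converged"] = converged, _["floored"] = floored);
}
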