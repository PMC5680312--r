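#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Weighted elastic-net objective solved here:
//   f(theta) = 0.5 * sum_i w_i (y_i - x_i' theta)^2
//              + lambda1 * sum_j p1_j |theta_j|
//              + lambda2 * sum_j p2_j theta_j^2
// p1_j = +Inf marks an excluded coordinate (held at exactly zero).
// Cyclical coordinate descent; each update is the exact 1-d minimizer.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One pass over the coordinates in `idx`; returns max |change|.
static double cd_pass(const double *X, int n,
                      const std::vector<int> &idx,
                      const std::vector<double> &w,
                      const std::vector<double> &xtx,
                      const double *p1, const double *p2,
                      double lambda1, double lambda2,
                      std::vector<double> &theta,
                      std::vector<double> &resid) {
  double maxdel = 0.0;
  for (size_t k = 0; k < idx.size(); ++k) {
    int j = idx[k];
    const double *xj = X + (size_t)n * j;
    double old = theta[j];
    double z = xtx[j] * old;
    for (int i = 0; i < n; ++i) z += w[i] * xj[i] * resid[i];
    double denom = xtx[j] + 2.0 * lambda2 * p2[j];
    double nw;
    if (denom <= 0.0) {
      nw = 0.0;
    } else {
      nw = soft(z, lambda1 * p1[j]) / denom;
    }
    double del = nw - old;
    if (del != 0.0) {
      for (int i = 0; i < n; ++i) resid[i] -= del * xj[i];
      theta[j] = nw;
      double a = std::fabs(del);
      if (a > maxdel) maxdel = a;
    }
  }
  return maxdel;
}

// [[Rcpp::export]]
List cd_enet(NumericMatrix X, NumericVector y, NumericVector w,
             NumericVector p1, NumericVector p2,
             double lambda1, double lambda2,
             double tol, int max_sweeps, NumericVector init) {
  int n = X.nrow(), m = X.ncol();
  const double *Xp = X.begin();

  std::vector<double> theta(m), resid(n), ww(n), xtx(m);
  std::vector<int> all;
  all.reserve(m);
  for (int j = 0; j < m; ++j) {
    theta[j] = std::isinf(p1[j]) ? 0.0 : init[j];
    if (!std::isinf(p1[j])) all.push_back(j);
  }
  for (int i = 0; i < n; ++i) ww[i] = w[i];
  for (int j = 0; j < m; ++j) {
    const double *xj = Xp + (size_t)n * j;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += ww[i] * xj[i] * xj[i];
    xtx[j] = s;
  }
  for (int i = 0; i < n; ++i) {
    double s = y[i];
    for (int j = 0; j < m; ++j) s -= X(i, j) * theta[j];
    resid[i] = s;
  }

  int sweeps = 0;
  bool converged = false;
  while (sweeps < max_sweeps) {
    // full pass
    double maxdel = cd_pass(Xp, n, all, ww, xtx, p1.begin(), p2.begin(),
                            lambda1, lambda2, theta, resid);
    ++sweeps;
    if (maxdel <= tol) { converged = true; break; }
    // iterate over the active set until it stabilizes
    std::vector<int> act;
    for (size_t k = 0; k < all.size(); ++k)
      if (theta[all[k]] != 0.0) act.push_back(all[k]);
    while (sweeps < max_sweeps) {
      double d = cd_pass(Xp, n, act, ww, xtx, p1.begin(), p2.begin(),
                         lambda1, lambda2, theta, resid);
      ++sweeps;
      if (d <= tol) break;
    }
  }

  return List::create(_["coef"] = NumericVector(theta.begin(), theta.end()),
                      _["n_sweeps"] = sweeps,
                      _["converged"] = converged);
}

// Gram-form pathwise solver used by the cross-validation loops
// ("covariance updating"): takes G = X'WX and c = X'Wy and maintains the
// smooth gradient, so visiting an unchanged coordinate is O(1) and a
// coefficient change costs O(m) instead of O(n). Minimizes the same
// objective as cd_enet (up to the constant 0.5*y'Wy).
// [[Rcpp::export]]
List cd_enet_gram_path(NumericMatrix G, NumericVector c_,
                       NumericVector p1, NumericVector p2,
                       NumericVector lambda1_seq, double lambda2,
                       double tol, int max_sweeps) {
  int m = G.ncol(), L = lambda1_seq.size();
  NumericMatrix coefs(m, L);
  IntegerVector sweeps_out(L);
  LogicalVector conv(L);
  const double *Gp = G.begin();
  std::vector<double> theta(m, 0.0), grad(c_.begin(), c_.end());
  std::vector<int> all;
  all.reserve(m);
  for (int j = 0; j < m; ++j) if (!std::isinf(p1[j])) all.push_back(j);

  std::vector<double> Gact, gradAct, thAct, p1a, p2a;
  std::vector<int> act;

  for (int l = 0; l < L; ++l) {
    double lambda1 = lambda1_seq[l];
    int sweeps = 0;
    bool converged = false;
    while (sweeps < max_sweeps) {
      double maxdel = 0.0;
      for (size_t k = 0; k < all.size(); ++k) {
        int j = all[k];
        double gjj = Gp[(size_t)m * j + j];
        double z = grad[j] + gjj * theta[j];
        double denom = gjj + 2.0 * lambda2 * p2[j];
        double nw = denom > 0.0 ? soft(z, lambda1 * p1[j]) / denom : 0.0;
        double del = nw - theta[j];
        if (del != 0.0) {
          const double *gj = Gp + (size_t)m * j;
          for (int i = 0; i < m; ++i) grad[i] -= del * gj[i];
          theta[j] = nw;
          double a = std::fabs(del);
          if (a > maxdel) maxdel = a;
        }
      }
      ++sweeps;
      if (maxdel <= tol) { converged = true; break; }

      // Iterate on the active set using a compacted k x k Gram block:
      // each update then costs O(k) rather than O(m).
      act.clear();
      for (size_t k = 0; k < all.size(); ++k)
        if (theta[all[k]] != 0.0) act.push_back(all[k]);
      int K = (int)act.size();
      if (K > 0) {
        Gact.assign((size_t)K * K, 0.0);
        gradAct.resize(K); thAct.resize(K); p1a.resize(K); p2a.resize(K);
        for (int b = 0; b < K; ++b) {
          const double *gj = Gp + (size_t)m * act[b];
          for (int a2 = 0; a2 < K; ++a2) Gact[(size_t)K * b + a2] = gj[act[a2]];
          gradAct[b] = grad[act[b]];
          thAct[b] = theta[act[b]];
          p1a[b] = p1[act[b]]; p2a[b] = p2[act[b]];
        }
        while (sweeps < max_sweeps) {
          double d = 0.0;
          for (int b = 0; b < K; ++b) {
            double gjj = Gact[(size_t)K * b + b];
            double z = gradAct[b] + gjj * thAct[b];
            double denom = gjj + 2.0 * lambda2 * p2a[b];
            double nw = denom > 0.0 ? soft(z, lambda1 * p1a[b]) / denom : 0.0;
            double del = nw - thAct[b];
            if (del != 0.0) {
              const double *gb = Gact.data() + (size_t)K * b;
              for (int i = 0; i < K; ++i) gradAct[i] -= del * gb[i];
              thAct[b] = nw;
              double a = std::fabs(del);
              if (a > d) d = a;
            }
          }
          ++sweeps;
          if (d <= tol) break;
        }
        // write back and refresh the full gradient for the changed coords
        for (int b = 0; b < K; ++b) {
          double del = thAct[b] - theta[act[b]];
          if (del != 0.0) {
            const double *gj = Gp + (size_t)m * act[b];
            for (int i = 0; i < m; ++i) grad[i] -= del * gj[i];
            theta[act[b]] = thAct[b];
          }
        }
      }
    }
    for (int j = 0; j < m; ++j) coefs(j, l) = theta[j];
    sweeps_out[l] = sweeps;
    conv[l] = converged;
  }
  return List::create(_["coef"] = coefs, _["n_sweeps"] = sweeps_out,
                      _["converged"] = conv);
}

// Pathwise version: lambda1_seq must be decreasing; solutions are
// warm-started along the path. Returns an m x L coefficient matrix.
// [[Rcpp::export]]
List cd_enet_path(NumericMatrix X, NumericVector y, NumericVector w,
                  NumericVector p1, NumericVector p2,
                  NumericVector lambda1_seq, double lambda2,
                  double tol, int max_sweeps) {
  int m = X.ncol(), L = lambda1_seq.size();
  NumericMatrix coefs(m, L);
  IntegerVector sweeps(L);
  LogicalVector conv(L);
  NumericVector start(m); // zeros
  for (int l = 0; l < L; ++l) {
    List fit = cd_enet(X, y, w, p1, p2, lambda1_seq[l], lambda2,
                       tol, max_sweeps, start);
    NumericVector cf = fit["coef"];
    for (int j = 0; j < m; ++j) coefs(j, l) = cf[j];
    sweeps[l] = as<int>(fit["n_sweeps"]);
    conv[l] = as<bool>(fit["converged"]);
    start = cf;
  }
  return List::create(_["coef"] = coefs, _["n_sweeps"] = sweeps,
                      _["converged"] = conv);
}
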