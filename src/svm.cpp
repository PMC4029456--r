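#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// C-SVM with RBF kernel, trained by Platt's SMO with an error cache.
// Inputs are assumed pre-standardized by the caller. Labels in {-1, +1}.

static std::vector<double> kernel_matrix(const NumericMatrix &X, double gamma) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> K((size_t) n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t) i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < p; ++k) {
        double t = X(i, k) - X(j, k);
        d += t * t;
      }
      double v = std::exp(-gamma * d);
      K[(size_t) i * n + j] = v;
      K[(size_t) j * n + i] = v;
    }
  }
  return K;
}

struct SMO {
  int n;
  double C, tol, eps;
  const std::vector<double> &K;
  const std::vector<double> &y;
  std::vector<double> alpha, E;
  double b;
  std::mt19937 rng;

  SMO(int n_, double C_, double tol_, const std::vector<double> &K_,
      const std::vector<double> &y_, unsigned seed)
      : n(n_), C(C_), tol(tol_), eps(1e-12), K(K_), y(y_),
        alpha(n_, 0.0), E(n_), b(0.0), rng(seed) {
    for (int i = 0; i < n; ++i) E[i] = -y[i]; // f = 0 initially
  }

  bool take_step(int i1, int i2) {
    if (i1 == i2) return false;
    double a1 = alpha[i1], a2 = alpha[i2];
    double y1 = y[i1], y2 = y[i2];
    double E1 = E[i1], E2 = E[i2];
    double s = y1 * y2;
    double L, H;
    if (s < 0) {
      L = std::max(0.0, a2 - a1);
      H = std::min(C, C + a2 - a1);
    } else {
      L = std::max(0.0, a1 + a2 - C);
      H = std::min(C, a1 + a2);
    }
    if (H - L < eps) return false;
    double k11 = K[(size_t) i1 * n + i1], k22 = K[(size_t) i2 * n + i2],
           k12 = K[(size_t) i1 * n + i2];
    double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > eps) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L;
      else if (a2new > H) a2new = H;
    } else {
      // degenerate curvature: evaluate objective at both clip ends
      double f1 = y1 * (E1 + b) - a1 * k11 - s * a2 * k12;
      double f2 = y2 * (E2 + b) - s * a1 * k12 - a2 * k22;
      double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
      double objL = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 + 0.5 * L * L * k22 + s * L * L1 * k12;
      double objH = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 + 0.5 * H * H * k22 + s * H * H1 * k12;
      if (objL < objH - eps) a2new = L;
      else if (objL > objH + eps) a2new = H;
      else a2new = a2;
    }
    if (std::fabs(a2new - a2) < eps * (a2new + a2 + eps)) return false;
    double a1new = a1 + s * (a2 - a2new);
    if (a1new < 0) { a2new += s * a1new; a1new = 0; }
    else if (a1new > C) { a2new += s * (a1new - C); a1new = C; }

    double b1 = E1 + y1 * (a1new - a1) * k11 + y2 * (a2new - a2) * k12 + b;
    double b2 = E2 + y1 * (a1new - a1) * k12 + y2 * (a2new - a2) * k22 + b;
    double bnew;
    if (a1new > eps && a1new < C - eps) bnew = b1;
    else if (a2new > eps && a2new < C - eps) bnew = b2;
    else bnew = 0.5 * (b1 + b2);

    double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2), db = bnew - b;
    for (int i = 0; i < n; ++i)
      E[i] += d1 * K[(size_t) i1 * n + i] + d2 * K[(size_t) i2 * n + i] - db;
    alpha[i1] = a1new;
    alpha[i2] = a2new;
    b = bnew;
    return true;
  }

  bool examine(int i2) {
    double y2 = y[i2], a2 = alpha[i2], E2 = E[i2];
    double r2 = E2 * y2;
    if ((r2 < -tol && a2 < C) || (r2 > tol && a2 > 0)) {
      // heuristic 1: maximize |E1 - E2| over non-bound points
      int best = -1;
      double bestgap = 0.0;
      for (int i = 0; i < n; ++i)
        if (alpha[i] > eps && alpha[i] < C - eps) {
          double gap = std::fabs(E[i] - E2);
          if (gap > bestgap) { bestgap = gap; best = i; }
        }
      if (best >= 0 && take_step(best, i2)) return true;
      std::uniform_int_distribution<int> pick(0, n - 1);
      int start = pick(rng);
      for (int k = 0; k < n; ++k) {
        int i = (start + k) % n;
        if (alpha[i] > eps && alpha[i] < C - eps && take_step(i, i2)) return true;
      }
      start = pick(rng);
      for (int k = 0; k < n; ++k)
        if (take_step((start + k) % n, i2)) return true;
    }
    return false;
  }
};

// [[Rcpp::export(name = ".svm_train_cpp")]]
List svm_train_cpp(NumericMatrix X, NumericVector yin, double C, double gamma,
                   double tol, int max_iter, int seed) {
  const int n = X.nrow();
  std::vector<double> y(yin.begin(), yin.end());
  std::vector<double> K = kernel_matrix(X, gamma);
  SMO smo(n, C, tol, K, y, (unsigned) seed);

  int changed = 0;
  bool examine_all = true;
  int iter = 0;
  while ((changed > 0 || examine_all) && iter < max_iter) {
    changed = 0;
    if (examine_all) {
      for (int i = 0; i < n; ++i) changed += smo.examine(i);
    } else {
      for (int i = 0; i < n; ++i)
        if (smo.alpha[i] > 1e-12 && smo.alpha[i] < C - 1e-12)
          changed += smo.examine(i);
    }
    if (examine_all) examine_all = false;
    else if (changed == 0) examine_all = true;
    iter++;
  }

  std::vector<int> sv;
  for (int i = 0; i < n; ++i)
    if (smo.alpha[i] > 1e-8) sv.push_back(i);
  const int ns = (int) sv.size();
  NumericMatrix svX(ns, X.ncol());
  NumericVector coef(ns);
  for (int k = 0; k < ns; ++k) {
    for (int j = 0; j < X.ncol(); ++j) svX(k, j) = X(sv[k], j);
    coef[k] = smo.alpha[sv[k]] * y[sv[k]];
  }
  return List::create(_["sv"] = svX, _["coef"] = coef, _["b"] = smo.b,
                      _["iter"] = iter);
}

// decision values f(x) = sum_k coef_k K(sv_k, x) - b
// [[Rcpp::export(name = ".svm_decision_cpp")]]
NumericVector svm_decision_cpp(NumericMatrix sv, NumericVector coef, double b,
                               double gamma, NumericMatrix X) {
  const int n = X.nrow(), ns = sv.nrow(), p = X.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double f = 0.0;
    for (int k = 0; k < ns; ++k) {
      double d = 0.0;
      for (int j = 0; j < p; ++j) {
        double t = X(i, j) - sv(k, j);
        d += t * t;
      }
      f += coef[k] * std::exp(-gamma * d);
    }
    out[i] = f - b;
  }
  return out;
}
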