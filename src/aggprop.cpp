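#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment statistics with linear gap penalty.
// Identity denominator = alignment columns including gaps. Tie-break:
// diagonal > up > left, making the traceback deterministic.
// [[Rcpp::export(name = ".nw_align_stats")]]
List nw_align_stats(std::string a, std::string b,
                    double match = 1.0, double mismatch = 0.0,
                    double gap = -1.0) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence in alignment");
  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 0 diag, 1 up, 2 left
  for (int i = 1; i <= n; ++i) { S(i, 0) = i * gap; P(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { S(0, j) = j * gap; P(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double u = S(i - 1, j) + gap;
      double l = S(i, j - 1) + gap;
      double best = d; int ptr = 0;
      if (u > best) { best = u; ptr = 1; }
      if (l > best) { best = l; ptr = 2; }
      S(i, j) = best; P(i, j) = ptr;
    }
  }
  int i = n, j = m, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    ++cols;
    int ptr = P(i, j);
    if (ptr == 0) { if (a[i - 1] == b[j - 1]) ++matches; --i; --j; }
    else if (ptr == 1) { --i; }
    else { --j; }
  }
  return List::create(_["matches"] = matches,
                      _["alignment_length"] = cols,
                      _["identity"] = (double)matches / cols,
                      _["score"] = S(n, m));
}

static inline double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0.0;
  const int d = X.ncol();
  for (int k = 0; k < d; ++k) {
    double t = X(i, k) - X(j, k);
    s += t * t;
  }
  return std::exp(-gamma * s);
}

// SMO solver for the C-SVC dual with RBF kernel and per-class costs
// (maximal-violating-pair working set selection; LIBSVM-style updates).
// y must be +/-1. Returns alpha, bias b, and the iteration count.
// [[Rcpp::export(name = ".svm_smo_train")]]
List svm_smo_train(NumericMatrix X, NumericVector y,
                   double C_pos, double C_neg, double gamma,
                   double tol = 1e-3, int max_iter = 200000) {
  const int n = X.nrow();
  if (n < 2) stop("need at least two training rows");
  // Cache the full kernel matrix (training sizes here are modest).
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    K(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) K(i, j) = K(j, i) = rbf(X, i, j, gamma);
  }
  std::vector<double> alpha(n, 0.0), G(n, -1.0), C(n);
  for (int i = 0; i < n; ++i) C[i] = (y[i] > 0) ? C_pos : C_neg;

  int iter = 0;
  const double tau = 1e-12;
  for (; iter < max_iter; ++iter) {
    // select i in I_up maximizing -y G, j in I_low minimizing -y G
    int ii = -1, jj = -1;
    double gmax = -1e30, gmin = 1e30;
    for (int t = 0; t < n; ++t) {
      bool up  = (y[t] > 0) ? (alpha[t] < C[t]) : (alpha[t] > 0);
      bool low = (y[t] > 0) ? (alpha[t] > 0)    : (alpha[t] < C[t]);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; ii = t; }
      if (low && v < gmin) { gmin = v; jj = t; }
    }
    if (ii < 0 || jj < 0 || gmax - gmin < tol) break;

    double ai = alpha[ii], aj = alpha[jj];
    if (y[ii] != y[jj]) {
      double quad = K(ii, ii) + K(jj, jj) + 2.0 * K(ii, jj);
      if (quad <= 0) quad = tau;
      double delta = (-G[ii] - G[jj]) / quad;
      double diff = alpha[ii] - alpha[jj];
      alpha[ii] += delta; alpha[jj] += delta;
      if (diff > 0) {
        if (alpha[jj] < 0) { alpha[jj] = 0; alpha[ii] = diff; }
      } else {
        if (alpha[ii] < 0) { alpha[ii] = 0; alpha[jj] = -diff; }
      }
      if (diff > C[ii] - C[jj]) {
        if (alpha[ii] > C[ii]) { alpha[ii] = C[ii]; alpha[jj] = C[ii] - diff; }
      } else {
        if (alpha[jj] > C[jj]) { alpha[jj] = C[jj]; alpha[ii] = C[jj] + diff; }
      }
    } else {
      double quad = K(ii, ii) + K(jj, jj) - 2.0 * K(ii, jj);
      if (quad <= 0) quad = tau;
      double delta = (G[ii] - G[jj]) / quad;
      double sum = alpha[ii] + alpha[jj];
      alpha[ii] -= delta; alpha[jj] += delta;
      if (sum > C[ii]) {
        if (alpha[ii] > C[ii]) { alpha[ii] = C[ii]; alpha[jj] = sum - C[ii]; }
      } else {
        if (alpha[jj] < 0) { alpha[jj] = 0; alpha[ii] = sum; }
      }
      if (sum > C[jj]) {
        if (alpha[jj] > C[jj]) { alpha[jj] = C[jj]; alpha[ii] = sum - C[jj]; }
      } else {
        if (alpha[ii] < 0) { alpha[ii] = 0; alpha[jj] = sum; }
      }
    }
    double di = alpha[ii] - ai, dj = alpha[jj] - aj;
    if (di == 0.0 && dj == 0.0) break;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * y[ii] * K(t, ii) * di + y[t] * y[jj] * K(t, jj) * dj;
    }
  }

  // bias from free support vectors, else midpoint of the violating bounds
  double bsum = 0.0; int nfree = 0;
  double ub = 1e30, lb = -1e30;
  for (int t = 0; t < n; ++t) {
    double yg = -y[t] * G[t];
    bool up  = (y[t] > 0) ? (alpha[t] < C[t]) : (alpha[t] > 0);
    bool low = (y[t] > 0) ? (alpha[t] > 0)    : (alpha[t] < C[t]);
    if (alpha[t] > 0 && alpha[t] < C[t]) { bsum += yg; ++nfree; }
    if (up && yg < ub) ub = yg;
    if (low && yg > lb) lb = yg;
    (void)up; (void)low;
  }
  double b = nfree > 0 ? bsum / nfree : (ub + lb) / 2.0;
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter);
}

// Decision values f(x) = sum_i coef_i K(sv_i, x) + b for an RBF machine.
// [[Rcpp::export(name = ".rbf_decision")]]
NumericVector rbf_decision(NumericMatrix Xsv, NumericVector coef, double b,
                           double gamma, NumericMatrix Xnew) {
  const int nsv = Xsv.nrow(), m = Xnew.nrow(), d = Xsv.ncol();
  if (Xnew.ncol() != d) stop("feature dimension mismatch");
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    double f = b;
    for (int i = 0; i < nsv; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double t = Xsv(i, k) - Xnew(j, k);
        s += t * t;
      }
      f += coef[i] * std::exp(-gamma * s);
    }
    out[j] = f;
  }
  return out;
}
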