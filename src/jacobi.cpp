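#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Gauss-Jacobi nodes/weights on [-1, 1] for weight (1-x)^a (1+x)^b, via
// Golub-Welsch: eigenvalues of the symmetric tridiagonal Jacobi matrix give
// the nodes, squared first eigenvector components (times mu0) the weights.
// The implicit-shift QL iteration below tracks only the first components.
// [[Rcpp::export(name = ".jacobi_rule_cpp")]]
List jacobi_rule_cpp(int n, double a, double b) {
  if (n < 1) stop("order must be >= 1");
  std::vector<double> d(n), e(n, 0.0), z(n, 0.0);
  const double ab = a + b;
  d[0] = (b - a) / (ab + 2.0);
  for (int k = 1; k < n; ++k) {
    double kk = (double)k;
    d[k] = (b * b - a * a) / ((2.0 * kk + ab) * (2.0 * kk + ab + 2.0));
    double b2;
    if (k == 1) {
      b2 = 4.0 * (a + 1.0) * (b + 1.0) /
           ((ab + 2.0) * (ab + 2.0) * (ab + 3.0));
    } else {
      b2 = 4.0 * kk * (kk + a) * (kk + b) * (kk + ab) /
           ((2.0 * kk + ab) * (2.0 * kk + ab) *
            (2.0 * kk + ab + 1.0) * (2.0 * kk + ab - 1.0));
    }
    e[k - 1] = std::sqrt(b2);
  }
  z[0] = 1.0;

  // tqli: implicit QL with Wilkinson shifts on (d, e), rotations applied to z
  for (int l = 0; l < n; ++l) {
    int iter = 0;
    int m;
    do {
      for (m = l; m < n - 1; ++m) {
        double dd = std::fabs(d[m]) + std::fabs(d[m + 1]);
        if (std::fabs(e[m]) <= 1e-15 * dd) break;
      }
      if (m != l) {
        if (iter++ == 50) stop("QL iteration failed to converge");
        double g = (d[l + 1] - d[l]) / (2.0 * e[l]);
        double r = std::hypot(g, 1.0);
        g = d[m] - d[l] + e[l] / (g + (g >= 0 ? std::fabs(r) : -std::fabs(r)));
        double s = 1.0, c = 1.0, p = 0.0;
        for (int i = m - 1; i >= l; --i) {
          double f = s * e[i];
          double bb = c * e[i];
          r = std::hypot(f, g);
          e[i + 1] = r;
          if (r == 0.0) { d[i + 1] -= p; e[m] = 0.0; break; }
          s = f / r;
          c = g / r;
          g = d[i + 1] - p;
          r = (d[i] - g) * s + 2.0 * c * bb;
          p = s * r;
          d[i + 1] = g + p;
          g = c * r - bb;
          double fz = z[i + 1];
          z[i + 1] = s * z[i] + c * fz;
          z[i] = c * z[i] - s * fz;
        }
        if (r == 0.0 && m - 1 >= l) continue;
        d[l] -= p;
        e[l] = g;
        e[m] = 0.0;
      }
    } while (m != l);
  }

  // mu0 = total weight: 2^(a+b+1) * Beta(a+1, b+1)
  double mu0 = std::exp((ab + 1.0) * std::log(2.0) + R::lbeta(a + 1.0, b + 1.0));
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int i, int j) { return d[i] < d[j]; });
  NumericVector nodes(n), weights(n), z2(n);
  for (int i = 0; i < n; ++i) {
    nodes[i] = d[idx[i]];
    z2[i] = z[idx[i]] * z[idx[i]];
    weights[i] = mu0 * z2[i];
  }
  return List::create(_["nodes"] = nodes, _["weights"] = weights,
                      _["z2"] = z2);
}
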