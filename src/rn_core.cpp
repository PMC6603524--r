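#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise maximum-norm (Chebyshev) distances between rows of X.
// Returns the full symmetric N x N matrix with zero diagonal.
// [[Rcpp::export(name = ".cpp_maxnorm_dist")]]
NumericMatrix cpp_maxnorm_dist(const NumericMatrix& X) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(X(i, k) - X(j, k));
        if (a > d) d = a;
      }
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// Degree, per-vertex triangle count and connected-triple totals of a binary
// symmetric adjacency matrix (0/1 integer, zero diagonal).
// tri[i] counts unordered neighbour pairs {j,q} of i that are themselves
// adjacent, i.e. triangles through i.
// [[Rcpp::export(name = ".cpp_adjacency_counts")]]
List cpp_adjacency_counts(const IntegerMatrix& A) {
  const int n = A.nrow();
  IntegerVector deg(n);
  NumericVector tri(n);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int j = 0; j < n; ++j) k += A(i, j);
    deg[i] = k;
  }
  // collect neighbour lists once for cache-friendly triangle counting
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    nb[i].reserve(deg[i]);
    for (int j = 0; j < n; ++j) if (A(i, j)) nb[i].push_back(j);
  }
  for (int i = 0; i < n; ++i) {
    const std::vector<int>& v = nb[i];
    double t = 0.0;
    for (size_t a = 0; a < v.size(); ++a)
      for (size_t b = a + 1; b < v.size(); ++b)
        if (A(v[a], v[b])) t += 1.0;
    tri[i] = t;
  }
  double triples = 0.0, triangles3 = 0.0;
  for (int i = 0; i < n; ++i) {
    triples += (double)deg[i] * (deg[i] - 1) / 2.0; // unordered triples centred at i
    triangles3 += tri[i];                            // = 3 * (#triangles) in total
  }
  return List::create(_["degree"] = deg, _["tri"] = tri,
                      _["triples"] = triples, _["triangles3"] = triangles3);
}

// False-nearest-neighbour fractions (Kennel criterion) for m = 1..m_max at
// fixed delay tau. Euclidean nearest neighbour in dimension m; a neighbour is
// false when the extra (m+1)-th coordinate either inflates the distance by a
// factor > rtol or pushes the (m+1)-dim distance beyond atol * sd(x).
// Points whose nearest neighbour is farther than sd(x) are excluded
// (loneliness guard). Returns fraction per m; NA when no valid pairs.
// [[Rcpp::export(name = ".cpp_fnn_fractions")]]
NumericVector cpp_fnn_fractions(const NumericVector& x, int tau, int m_max,
                                double rtol, double atol) {
  const int N = x.size();
  double mu = 0.0;
  for (int i = 0; i < N; ++i) mu += x[i];
  mu /= N;
  double s2 = 0.0;
  for (int i = 0; i < N; ++i) s2 += (x[i] - mu) * (x[i] - mu);
  const double sdx = std::sqrt(s2 / (N - 1));
  NumericVector out(m_max, NA_REAL);

  for (int m = 1; m <= m_max; ++m) {
    // need the (m+1)-th coordinate for the test, so embed up to index N-1-m*tau
    const int npts = N - m * tau;
    if (npts < 2) break;
    int nfalse = 0, nvalid = 0;
    for (int i = 0; i < npts; ++i) {
      double best = R_PosInf;
      int jbest = -1;
      for (int j = 0; j < npts; ++j) {
        if (j == i) continue;
        double d2 = 0.0;
        for (int k = 0; k < m; ++k) {
          double a = x[i + k * tau] - x[j + k * tau];
          d2 += a * a;
          if (d2 >= best) break;
        }
        if (d2 < best) { best = d2; jbest = j; }
      }
      if (jbest < 0) continue;
      double Rm = std::sqrt(best);
      if (Rm > sdx) continue;       // lonely point: unreliable neighbour
      double extra = std::fabs(x[i + m * tau] - x[jbest + m * tau]);
      bool isfalse = false;
      // distance floor guards exact trajectory revisits (periodic
      // signals), where Rm is rounding noise and the ratio meaningless
      double floorR = 1e-8 * sdx;
      if (extra / std::max(Rm, floorR) > rtol) isfalse = true;
      if (!isfalse) {
        double Rm1 = std::sqrt(Rm * Rm + extra * extra);
        if (Rm1 / sdx > atol) isfalse = true;
      }
      nvalid++;
      if (isfalse) nfalse++;
    }
    out[m - 1] = (nvalid > 0) ? (double)nfalse / nvalid : NA_REAL;
  }
  return out;
}
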