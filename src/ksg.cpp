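// Kraskov-Stoegbauer-Grassberger (variant 1) k-nearest-neighbour mutual
// information between pairs of 3-dimensional displacement variables, with
// the Chebyshev (max-norm) metric in both the marginal and the joint space.
//
// For bead pair (a, b) over n frames:
//   eps_t = distance to the k-th nearest neighbour of frame t in the joint
//           6-D space (max of the two marginal Chebyshev distances);
//   n_x(t), n_y(t) = number of frames strictly within eps_t in each marginal;
//   I = psi(k) + psi(n) - < psi(n_x + 1) + psi(n_y + 1) >.
// Distance ties are broken upstream by a tiny seeded jitter.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline double cheb3(const double* X, R_xlen_t n, R_xlen_t col0,
                           R_xlen_t s, R_xlen_t t) {
  double m = 0.0;
  for (int d = 0; d < 3; ++d) {
    double v = std::fabs(X[s + (col0 + d) * n] - X[t + (col0 + d) * n]);
    if (v > m) m = v;
  }
  return m;
}

static double ksg_pair(const double* X, R_xlen_t n, R_xlen_t ca, R_xlen_t cb,
                       int k, const std::vector<double>& psi,
                       std::vector<double>& da, std::vector<double>& db,
                       std::vector<double>& dj, std::vector<double>& tmp) {
  double acc = 0.0;
  for (R_xlen_t t = 0; t < n; ++t) {
    for (R_xlen_t s = 0; s < n; ++s) {
      da[s] = cheb3(X, n, ca, s, t);
      db[s] = cheb3(X, n, cb, s, t);
      dj[s] = da[s] > db[s] ? da[s] : db[s];
    }
    dj[t] = R_PosInf;  // exclude self from the neighbour search
    std::copy(dj.begin(), dj.end(), tmp.begin());
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    double eps = tmp[k - 1];
    R_xlen_t nx = 0, ny = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
      if (s == t) continue;
      if (da[s] < eps) ++nx;
      if (db[s] < eps) ++ny;
    }
    acc += psi[nx + 1] + psi[ny + 1];
  }
  return R::digamma((double)k) + psi[n] - acc / (double)n;
}

// coords: n_frames x (3 * n_beads) matrix, bead b occupying columns
// 3(b-1)+1 .. 3(b-1)+3. pairs: p x 2 matrix of 1-based bead indices.
// Returns the KSG-1 mutual information estimate (nats) per pair.
// [[Rcpp::export]]
NumericVector ksg_mi_pairs_cpp(NumericMatrix coords, IntegerMatrix pairs,
                               int k) {
  R_xlen_t n = coords.nrow();
  R_xlen_t nbead = coords.ncol() / 3;
  if (coords.ncol() % 3 != 0)
    stop("coords must have 3 columns per bead");
  if (k < 1 || k >= n) stop("need 1 <= k < n_frames");
  std::vector<double> psi(n + 2);
  for (R_xlen_t i = 1; i <= n + 1; ++i) psi[i] = R::digamma((double)i);
  std::vector<double> da(n), db(n), dj(n), tmp(n);
  const double* X = coords.begin();
  NumericVector out(pairs.nrow());
  for (R_xlen_t p = 0; p < pairs.nrow(); ++p) {
    int a = pairs(p, 0), b = pairs(p, 1);
    if (a < 1 || b < 1 || a > nbead || b > nbead)
      stop("bead index out of range");
    out[p] = ksg_pair(X, n, 3 * (R_xlen_t)(a - 1), 3 * (R_xlen_t)(b - 1),
                      k, psi, da, db, dj, tmp);
    if (p % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
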