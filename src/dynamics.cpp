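// Overdamped Langevin (Euler-Maruyama) integration of the elastic network
// with an optional targeted-MD biasing force, in compiled code: the R-level
// force routines (enm_forces / tmd_force) define the model and serve as the
// reference implementation; this loop reproduces them step by step at the
// speed the desk-scale studies need.
//
// Thermal noise comes from R's RNG (norm_rand), so a set.seed() in the
// calling R code makes trajectories bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Optimal proper rotation (Horn quaternion method): rotate mobile onto ref.
// S = sum over selection of (mobile - cm) (ref - cr)^T accumulated by caller.
static void horn_rotation(const double S[3][3], double R[3][3]) {
  double N[4][4];
  N[0][0] = S[0][0] + S[1][1] + S[2][2];
  N[0][1] = S[1][2] - S[2][1];
  N[0][2] = S[2][0] - S[0][2];
  N[0][3] = S[0][1] - S[1][0];
  N[1][1] = S[0][0] - S[1][1] - S[2][2];
  N[1][2] = S[0][1] + S[1][0];
  N[1][3] = S[2][0] + S[0][2];
  N[2][2] = -S[0][0] + S[1][1] - S[2][2];
  N[2][3] = S[1][2] + S[2][1];
  N[3][3] = -S[0][0] - S[1][1] + S[2][2];
  for (int i = 1; i < 4; ++i)
    for (int j = 0; j < i; ++j) N[i][j] = N[j][i];
  // Jacobi eigen decomposition of the symmetric 4x4
  double V[4][4] = {{1,0,0,0},{0,1,0,0},{0,0,1,0},{0,0,0,1}};
  for (int sweep = 0; sweep < 60; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < 3; ++p)
      for (int q = p + 1; q < 4; ++q) off += N[p][q] * N[p][q];
    if (off < 1e-24) break;
    for (int p = 0; p < 3; ++p) {
      for (int q = p + 1; q < 4; ++q) {
        if (std::fabs(N[p][q]) < 1e-18) continue;
        double theta = (N[q][q] - N[p][p]) / (2.0 * N[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
          (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 4; ++k) {
          double npk = N[p][k], nqk = N[q][k];
          N[p][k] = c * npk - s * nqk;
          N[q][k] = s * npk + c * nqk;
        }
        for (int k = 0; k < 4; ++k) {
          double nkp = N[k][p], nkq = N[k][q];
          N[k][p] = c * nkp - s * nkq;
          N[k][q] = s * nkp + c * nkq;
          double vkp = V[k][p], vkq = V[k][q];
          V[k][p] = c * vkp - s * vkq;
          V[k][q] = s * vkp + c * vkq;
        }
      }
    }
  }
  int best = 0;
  for (int k = 1; k < 4; ++k) if (N[k][k] > N[best][best]) best = k;
  double q0 = V[0][best], q1 = V[1][best], q2 = V[2][best], q3 = V[3][best];
  double nq = std::sqrt(q0*q0 + q1*q1 + q2*q2 + q3*q3);
  q0 /= nq; q1 /= nq; q2 /= nq; q3 /= nq;
  R[0][0] = q0*q0 + q1*q1 - q2*q2 - q3*q3;
  R[0][1] = 2.0 * (q1*q2 - q0*q3);
  R[0][2] = 2.0 * (q1*q3 + q0*q2);
  R[1][0] = 2.0 * (q1*q2 + q0*q3);
  R[1][1] = q0*q0 - q1*q1 + q2*q2 - q3*q3;
  R[1][2] = 2.0 * (q2*q3 - q0*q1);
  R[2][0] = 2.0 * (q1*q3 - q0*q2);
  R[2][1] = 2.0 * (q2*q3 + q0*q1);
  R[2][2] = q0*q0 - q1*q1 - q2*q2 + q3*q3;
}

// [[Rcpp::export]]
List run_dynamics_cpp(NumericMatrix xyz0, IntegerVector bi, IntegerVector bj,
                      NumericVector r0, double spring, double dt, double gamma,
                      double kBT, int n_steps, int stride, double k_tmd,
                      IntegerVector sel, NumericMatrix target,
                      NumericVector sched, bool fit_all) {
  const R_xlen_t n = xyz0.nrow(), nb = bi.size(), ns = sel.size();
  const bool biased = (ns > 0) && (k_tmd > 0);
  std::vector<double> x(3 * n), y(3 * n);
  for (R_xlen_t i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xyz0(i, d);
  if (biased)
    for (R_xlen_t i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) y[3 * i + d] = target(i, d);
  std::vector<int> fit;
  if (biased) {
    if (fit_all) { fit.resize(n); for (R_xlen_t i = 0; i < n; ++i) fit[i] = i; }
    else for (R_xlen_t k = 0; k < ns; ++k) fit.push_back(sel[k] - 1);
  }
  std::vector<int> seli;
  for (R_xlen_t k = 0; k < ns; ++k) seli.push_back(sel[k] - 1);

  int nrec = n_steps / stride + 1;
  NumericVector coords(Dimension(n, 3, nrec));
  for (R_xlen_t i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) coords[i + d * n] = x[3 * i + d];
  NumericMatrix log(biased ? n_steps : 0, 3);

  const double mob = dt / gamma;
  const double noise_sd = std::sqrt(2.0 * kBT * dt / gamma);
  std::vector<double> F(3 * n);
  std::vector<double> yal(biased ? 3 * n : 0);

  GetRNGstate();
  int rec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    std::fill(F.begin(), F.end(), 0.0);
    // ENM bond forces
    for (R_xlen_t b = 0; b < nb; ++b) {
      int i = bi[b] - 1, j = bj[b] - 1;
      double dx = x[3*i] - x[3*j], dy_ = x[3*i+1] - x[3*j+1],
             dz = x[3*i+2] - x[3*j+2];
      double len = std::sqrt(dx*dx + dy_*dy_ + dz*dz);
      if (len < 1e-12) continue;
      double coef = -spring * (len - r0[b]) / len;
      F[3*i]   += coef * dx; F[3*j]   -= coef * dx;
      F[3*i+1] += coef * dy_; F[3*j+1] -= coef * dy_;
      F[3*i+2] += coef * dz; F[3*j+2] -= coef * dz;
    }
    if (biased) {
      // superpose target onto current over the fit selection
      double cm[3] = {0,0,0}, cr[3] = {0,0,0};
      for (size_t k = 0; k < fit.size(); ++k) {
        int i = fit[k];
        for (int d = 0; d < 3; ++d) { cm[d] += y[3*i+d]; cr[d] += x[3*i+d]; }
      }
      for (int d = 0; d < 3; ++d) { cm[d] /= fit.size(); cr[d] /= fit.size(); }
      double S[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
      for (size_t k = 0; k < fit.size(); ++k) {
        int i = fit[k];
        double m[3], r[3];
        for (int d = 0; d < 3; ++d) { m[d] = y[3*i+d] - cm[d]; r[d] = x[3*i+d] - cr[d]; }
        for (int a = 0; a < 3; ++a)
          for (int b2 = 0; b2 < 3; ++b2) S[a][b2] += m[a] * r[b2];
      }
      double R[3][3];
      horn_rotation(S, R);
      double ssum = 0.0;
      for (R_xlen_t i = 0; i < n; ++i) {
        double m[3];
        for (int d = 0; d < 3; ++d) m[d] = y[3*i+d] - cm[d];
        for (int d = 0; d < 3; ++d)
          yal[3*i+d] = R[d][0]*m[0] + R[d][1]*m[1] + R[d][2]*m[2] + cr[d];
      }
      for (size_t k = 0; k < seli.size(); ++k) {
        int i = seli[k];
        for (int d = 0; d < 3; ++d) {
          double dv = x[3*i+d] - yal[3*i+d];
          ssum += dv * dv;
        }
      }
      double s = std::sqrt(ssum / seli.size());
      double sstar = sched[step - 1];
      if (s > 1e-10) {
        double coef = -k_tmd * (s - sstar) / s;
        for (size_t k = 0; k < seli.size(); ++k) {
          int i = seli[k];
          for (int d = 0; d < 3; ++d)
            F[3*i+d] += coef * (x[3*i+d] - yal[3*i+d]);
        }
      }
      log(step - 1, 0) = s;
      log(step - 1, 1) = sstar;
      log(step - 1, 2) = 0.5 * k_tmd * seli.size() * (s - sstar) * (s - sstar);
    }
    bool bad = false;
    for (R_xlen_t i = 0; i < n && !bad; ++i) {
      for (int d = 0; d < 3; ++d) {
        double xi = x[3*i+d] + F[3*i+d] * mob + noise_sd * norm_rand();
        if (!std::isfinite(xi) || std::fabs(xi) > 1e6) { bad = true; break; }
        x[3*i+d] = xi;
      }
    }
    if (bad) {
      PutRNGstate();
      stop("numerical blow-up at step %d", step);
    }
    if (step % stride == 0) {
      ++rec;
      for (R_xlen_t i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          coords[i + d * n + (R_xlen_t)rec * 3 * n] = x[3 * i + d];
    }
    if (step % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();
  return List::create(_["coords"] = coords, _["log"] = log);
}
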