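#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise interaction sums for the SPP-obstacle model on the unit torus,
// dimensions 1 and 2. Compact quadratic kernels use a uniform cell list
// (cell edge >= interaction range); configurations where a cell grid is not
// applicable (range too large, non-compact kernel) fall back to the O(NM)
// double loop, which is also exported as the test oracle.

namespace {

struct Kern {
  int fam;      // 0 = quadratic_compact, 1 = exponential (1D only)
  double A, r;  // amplitude, range
  bool active;
};

inline double minimg(double d) { return d - std::round(d); }

// phi'(d) for a signed 1D displacement d, sign(0) = 0 convention
inline double force1d(const Kern &K, double d) {
  if (d == 0.0) return 0.0;
  double s = std::fabs(d), sg = d > 0 ? 1.0 : -1.0;
  if (K.fam == 0) {
    if (s >= K.r) return 0.0;
    return -3.0 * K.A / (K.r * K.r) * (1.0 - s / K.r) * sg;
  }
  return K.A / (2.0 * K.r * K.r) * std::exp(-s / K.r) * sg;
}

// grad phi(v) for a 2D displacement (quadratic compact only)
inline void force2d(const Kern &K, double dx, double dy, double &gx,
                    double &gy) {
  double s2 = dx * dx + dy * dy;
  double r = K.r;
  if (s2 >= r * r || s2 == 0.0) { gx = 0.0; gy = 0.0; return; }
  double s = std::sqrt(s2);
  double mag = -3.0 * K.A / (M_PI * r * r * r) * (r - s) / s;
  gx = mag * dx;
  gy = mag * dy;
}

struct CellList {
  int nc;
  std::vector<int> head, next;
  void build(const NumericMatrix &P, int nc_) {
    nc = nc_;
    int ncells = (P.ncol() == 1) ? nc : nc * nc;
    head.assign(ncells, -1);
    next.assign(P.nrow(), -1);
    for (int i = 0; i < P.nrow(); ++i) {
      int c = cell_of(P, i);
      next[i] = head[c];
      head[c] = i;
    }
  }
  inline int clampc(double x) const {
    int c = (int)(x * nc);
    if (c >= nc) c = nc - 1;
    if (c < 0) c = 0;
    return c;
  }
  inline int cell_of(const NumericMatrix &P, int i) const {
    if (P.ncol() == 1) return clampc(P(i, 0));
    return clampc(P(i, 0)) + nc * clampc(P(i, 1));
  }
};

Kern make_kern(int fam, double A, double r, bool active) {
  Kern K; K.fam = fam; K.A = A; K.r = r; K.active = active; return K;
}

// accumulate sum of grad phi(P(i,) - Q(k,)) over k in neighbouring cells
template <typename F>
void scan_neighbours(const NumericMatrix &P, int i, const NumericMatrix &Q,
                     const CellList &cl, F &&fun) {
  int dim = P.ncol();
  if (dim == 1) {
    int ci = cl.clampc(P(i, 0));
    for (int o = -1; o <= 1; ++o) {
      int c = ((ci + o) % cl.nc + cl.nc) % cl.nc;
      for (int k = cl.head[c]; k != -1; k = cl.next[k]) fun(k);
    }
  } else {
    int cx = cl.clampc(P(i, 0)), cy = cl.clampc(P(i, 1));
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy) {
        int c = ((cx + ox) % cl.nc + cl.nc) % cl.nc +
                cl.nc * (((cy + oy) % cl.nc + cl.nc) % cl.nc);
        for (int k = cl.head[c]; k != -1; k = cl.next[k]) fun(k);
      }
  }
}

} // namespace

// Interaction sums of the particle model:
//   obs(i)    = (1/M) sum_k grad phi(X_i - Z_k)
//   spp(k)    = (1/N) sum_i grad phi(Z_k - X_i)
//               + (1/M) sum_{l != k} grad psi(Z_k - Z_l)
// use_cells = false forces the brute-force O(NM) path (the oracle).
// [[Rcpp::export]]
List cpp_pair_sums(NumericMatrix X, NumericMatrix Z, int phi_fam,
                   double phi_A, double phi_r, bool phi_active, int psi_fam,
                   double psi_A, double psi_r, bool psi_active,
                   bool use_cells = true) {
  int N = X.nrow(), M = Z.nrow(), dim = X.ncol();
  Kern phi = make_kern(phi_fam, phi_A, phi_r, phi_active);
  Kern psi = make_kern(psi_fam, psi_A, psi_r, psi_active);
  NumericMatrix obs(N, dim), spp(M, dim);

  double edge = 0.0;
  if (phi.active) edge = std::max(edge, phi.fam == 0 ? phi.r : 1.0);
  if (psi.active) edge = std::max(edge, psi.fam == 0 ? psi.r : 1.0);
  int nc = edge > 0 ? (int)std::floor(1.0 / edge) : 0;
  bool cells = use_cells && nc >= 3 &&
               (!phi.active || phi.fam == 0) && (!psi.active || psi.fam == 0);

  if (cells) {
    CellList clZ, clX;
    clZ.build(Z, nc);
    clX.build(X, nc);
    if (phi.active) {
      for (int i = 0; i < N; ++i) {
        double ax = 0.0, ay = 0.0;
        scan_neighbours(X, i, Z, clZ, [&](int k) {
          if (dim == 1) {
            ax += force1d(phi, minimg(X(i, 0) - Z(k, 0)));
          } else {
            double gx, gy;
            force2d(phi, minimg(X(i, 0) - Z(k, 0)),
                    minimg(X(i, 1) - Z(k, 1)), gx, gy);
            ax += gx; ay += gy;
          }
        });
        obs(i, 0) = ax / M;
        if (dim == 2) obs(i, 1) = ay / M;
      }
    }
    for (int k = 0; k < M; ++k) {
      double ax = 0.0, ay = 0.0;
      if (phi.active) {
        scan_neighbours(Z, k, X, clX, [&](int i) {
          if (dim == 1) {
            ax += force1d(phi, minimg(Z(k, 0) - X(i, 0))) / N;
          } else {
            double gx, gy;
            force2d(phi, minimg(Z(k, 0) - X(i, 0)),
                    minimg(Z(k, 1) - X(i, 1)), gx, gy);
            ax += gx / N; ay += gy / N;
          }
        });
      }
      if (psi.active) {
        scan_neighbours(Z, k, Z, clZ, [&](int l) {
          if (l == k) return;
          if (dim == 1) {
            ax += force1d(psi, minimg(Z(k, 0) - Z(l, 0))) / M;
          } else {
            double gx, gy;
            force2d(psi, minimg(Z(k, 0) - Z(l, 0)),
                    minimg(Z(k, 1) - Z(l, 1)), gx, gy);
            ax += gx / M; ay += gy / M;
          }
        });
      }
      spp(k, 0) = ax;
      if (dim == 2) spp(k, 1) = ay;
    }
  } else {
    if (phi.active) {
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < M; ++k) {
          if (dim == 1) {
            double f = force1d(phi, minimg(X(i, 0) - Z(k, 0)));
            obs(i, 0) += f / M;
            spp(k, 0) -= f / N; // grad phi is odd
          } else {
            double gx, gy;
            force2d(phi, minimg(X(i, 0) - Z(k, 0)),
                    minimg(X(i, 1) - Z(k, 1)), gx, gy);
            obs(i, 0) += gx / M; obs(i, 1) += gy / M;
            spp(k, 0) -= gx / N; spp(k, 1) -= gy / N;
          }
        }
    }
    if (psi.active) {
      for (int k = 0; k < M; ++k)
        for (int l = 0; l < M; ++l) {
          if (l == k) continue;
          if (dim == 1) {
            spp(k, 0) += force1d(psi, minimg(Z(k, 0) - Z(l, 0))) / M;
          } else {
            double gx, gy;
            force2d(psi, minimg(Z(k, 0) - Z(l, 0)),
                    minimg(Z(k, 1) - Z(l, 1)), gx, gy);
            spp(k, 0) += gx / M; spp(k, 1) += gy / M;
          }
        }
    }
  }
  return List::create(Named("obs") = obs, Named("spp") = spp);
}

namespace {

// 1D interaction sums into pre-allocated buffers (cell list or brute force)
void pair_sums_1d(const std::vector<double> &X, const std::vector<double> &Z,
                  const Kern &phi, const Kern &psi, bool use_cells,
                  std::vector<double> &obs, std::vector<double> &spp) {
  int N = X.size(), M = Z.size();
  std::fill(obs.begin(), obs.end(), 0.0);
  std::fill(spp.begin(), spp.end(), 0.0);
  double edge = 0.0;
  if (phi.active) edge = std::max(edge, phi.fam == 0 ? phi.r : 1.0);
  if (psi.active) edge = std::max(edge, psi.fam == 0 ? psi.r : 1.0);
  int nc = edge > 0 ? (int)std::floor(1.0 / edge) : 0;
  if (use_cells && nc >= 3 && (!phi.active || phi.fam == 0) &&
      (!psi.active || psi.fam == 0)) {
    auto cell = [&](double x) {
      int c = (int)(x * nc);
      if (c >= nc) c = nc - 1;
      if (c < 0) c = 0;
      return c;
    };
    std::vector<int> headX(nc, -1), nextX(N, -1), headZ(nc, -1), nextZ(M, -1);
    for (int i = 0; i < N; ++i) { int c = cell(X[i]); nextX[i] = headX[c]; headX[c] = i; }
    for (int k = 0; k < M; ++k) { int c = cell(Z[k]); nextZ[k] = headZ[c]; headZ[c] = k; }
    if (phi.active)
      for (int i = 0; i < N; ++i) {
        int ci = cell(X[i]);
        double acc = 0.0;
        for (int o = -1; o <= 1; ++o) {
          int c = ((ci + o) % nc + nc) % nc;
          for (int k = headZ[c]; k != -1; k = nextZ[k])
            acc += force1d(phi, minimg(X[i] - Z[k]));
        }
        obs[i] = acc / M;
      }
    for (int k = 0; k < M; ++k) {
      int ck = cell(Z[k]);
      double acc = 0.0;
      for (int o = -1; o <= 1; ++o) {
        int c = ((ck + o) % nc + nc) % nc;
        if (phi.active)
          for (int i = headX[c]; i != -1; i = nextX[i])
            acc += force1d(phi, minimg(Z[k] - X[i])) / N;
        if (psi.active)
          for (int l = headZ[c]; l != -1; l = nextZ[l])
            if (l != k) acc += force1d(psi, minimg(Z[k] - Z[l])) / M;
      }
      spp[k] = acc;
    }
  } else {
    if (phi.active)
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < M; ++k) {
          double f = force1d(phi, minimg(X[i] - Z[k]));
          obs[i] += f / M;
          spp[k] -= f / N;
        }
    if (psi.active)
      for (int k = 0; k < M; ++k)
        for (int l = 0; l < M; ++l)
          if (l != k) spp[k] += force1d(psi, minimg(Z[k] - Z[l])) / M;
  }
}

} // namespace

// Fast inner loop for the 1D model (orientation-free; all particles
// self-propel to the right at unit speed). Obstacle positional noise draws
// use the R RNG, in obstacle order, matching the R-level integrator.
// [[Rcpp::export]]
List cpp_run_1d(NumericVector X0, NumericVector Y, NumericVector Z0,
                double kappa, double eta, double zeta, double d_o,
                int phi_fam, double phi_A, double phi_r, bool phi_active,
                int psi_fam, double psi_A, double psi_r, bool psi_active,
                double dt, int nsteps, bool use_cells = true) {
  int N = X0.size(), M = Z0.size();
  std::vector<double> X(X0.begin(), X0.end()), Z(Z0.begin(), Z0.end());
  std::vector<double> Yv(Y.begin(), Y.end());
  Kern phi = make_kern(phi_fam, phi_A, phi_r, phi_active);
  Kern psi = make_kern(psi_fam, psi_A, psi_r, psi_active);
  std::vector<double> obs(N), spp(M);
  double sig = d_o > 0 ? std::sqrt(2.0 * d_o * dt) : 0.0;
  for (int s = 0; s < nsteps; ++s) {
    pair_sums_1d(X, Z, phi, psi, use_cells, obs, spp);
    for (int i = 0; i < N; ++i) {
      double dxy = minimg(X[i] - Yv[i]);
      double xn = X[i] + dt * (-(kappa / eta) * dxy - obs[i] / eta);
      if (sig > 0) xn += sig * R::norm_rand();
      X[i] = xn - std::floor(xn);
    }
    for (int k = 0; k < M; ++k) {
      double zn = Z[k] + dt * (1.0 - spp[k] / zeta);
      Z[k] = zn - std::floor(zn);
    }
    if (s % 1024 == 0)
      for (int i = 0; i < N; ++i)
        if (!std::isfinite(X[i]))
          stop("non-finite obstacle coordinate during 1D run");
  }
  return List::create(Named("X") = NumericVector(X.begin(), X.end()),
                      Named("Z") = NumericVector(Z.begin(), Z.end()));
}

// Vicsek mean flux J_k = sum_{|Z_k - Z_j| <= r_A} (cos theta_j, sin theta_j),
// including j = k, with minimum-image distances.
// [[Rcpp::export]]
NumericMatrix cpp_mean_flux(NumericMatrix Z, NumericVector theta, double r_A,
                            bool use_cells = true) {
  int M = Z.nrow();
  NumericMatrix J(M, 2);
  std::vector<double> ct(M), st(M);
  for (int j = 0; j < M; ++j) { ct[j] = std::cos(theta[j]); st[j] = std::sin(theta[j]); }
  double r2 = r_A * r_A;
  int nc = r_A > 0 ? (int)std::floor(1.0 / r_A) : 0;
  if (use_cells && nc >= 3) {
    CellList cl;
    cl.build(Z, nc);
    for (int k = 0; k < M; ++k) {
      double jx = 0.0, jy = 0.0;
      scan_neighbours(Z, k, Z, cl, [&](int j) {
        double dx = minimg(Z(k, 0) - Z(j, 0));
        double dy = minimg(Z(k, 1) - Z(j, 1));
        if (dx * dx + dy * dy <= r2) { jx += ct[j]; jy += st[j]; }
      });
      J(k, 0) = jx; J(k, 1) = jy;
    }
  } else {
    for (int k = 0; k < M; ++k) {
      double jx = 0.0, jy = 0.0;
      for (int j = 0; j < M; ++j) {
        double dx = minimg(Z(k, 0) - Z(j, 0));
        double dy = minimg(Z(k, 1) - Z(j, 1));
        if (dx * dx + dy * dy <= r2) { jx += ct[j]; jy += st[j]; }
      }
      J(k, 0) = jx; J(k, 1) = jy;
    }
  }
  return J;
}
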