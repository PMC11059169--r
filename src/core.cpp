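// Compiled kernels for the two-field active nematic model:
//  - molecular fields of the shape/stress free energy
//  - hybrid solver step: D2Q9 BGK lattice Boltzmann (Guo forcing) for the
//    momentum balance, explicit finite differences for the Q-tensor dynamics
//  - full MDCK-scenario run loop and the LP-9 relaxation-only loop
//
// Conventions (fixed here, mirrored by the R layer):
//  - fields are nx x ny matrices, first index = x, column-major (R layout)
//  - Q is stored as its two independent components (Qxx, Qxy); Qyy = -Qxx
//  - full tensor contraction Q:P = 2*(Qxx*Pxx + Qxy*Pxy)
//  - vorticity scalar omega = dx(uy) - dy(ux); Omega_xy = omega/2 and both
//    directors co-rotate at angular velocity omega/2
//  - elastic energy uses compact forward differences so that the 5-point
//    Laplacian in H is its exact discrete functional derivative

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, n;
  std::vector<int> xp, xm, yp, ym; // periodic neighbour index tables
  Grid(int nx_, int ny_) : nx(nx_), ny(ny_), n(nx_ * ny_),
      xp(nx_), xm(nx_), yp(ny_), ym(ny_) {
    for (int i = 0; i < nx; ++i) { xp[i] = (i + 1) % nx; xm[i] = (i + nx - 1) % nx; }
    for (int j = 0; j < ny; ++j) { yp[j] = (j + 1) % ny; ym[j] = (j + ny - 1) % ny; }
  }
  inline int id(int i, int j) const { return i + nx * j; }
};

struct Params {
  double C, Kn, Km, J, gamma, zeta, rho0, tau, Cprime;
  double corot_sign = 1.0; // +1: directors co-rotate with the fluid
  bool backstress = false; // include elastic (Ericksen + antisymmetric) stress
  int coupling = 0;        // 0: quartic (J/2)(1-3 Qn:Qm)^2; 1: harmonic (J/2)|Qn-Qm|^2
};

// Molecular fields H^n, H^m at every site.
// interior == 1: bulk terms C (order) and J (shape-stress alignment).
// interior == 0: exterior quartic term C' that drives S -> 0 (circular-island
// geometry); elastic terms act everywhere.
void molecular_field_kernel(const Grid& g,
                            const double* Qnxx, const double* Qnxy,
                            const double* Qmxx, const double* Qmxy,
                            const int* interior, const Params& p,
                            double* Hnxx, double* Hnxy,
                            double* Hmxx, double* Hmxy) {
  for (int j = 0; j < g.ny; ++j) {
    int jp = g.yp[j], jm = g.ym[j];
    for (int i = 0; i < g.nx; ++i) {
      int ip = g.xp[i], im = g.xm[i];
      int k = g.id(i, j);
      double lap_nxx = Qnxx[g.id(ip, j)] + Qnxx[g.id(im, j)] +
                       Qnxx[g.id(i, jp)] + Qnxx[g.id(i, jm)] - 4.0 * Qnxx[k];
      double lap_nxy = Qnxy[g.id(ip, j)] + Qnxy[g.id(im, j)] +
                       Qnxy[g.id(i, jp)] + Qnxy[g.id(i, jm)] - 4.0 * Qnxy[k];
      double lap_mxx = Qmxx[g.id(ip, j)] + Qmxx[g.id(im, j)] +
                       Qmxx[g.id(i, jp)] + Qmxx[g.id(i, jm)] - 4.0 * Qmxx[k];
      double lap_mxy = Qmxy[g.id(ip, j)] + Qmxy[g.id(im, j)] +
                       Qmxy[g.id(i, jp)] + Qmxy[g.id(i, jm)] - 4.0 * Qmxy[k];
      double qqn = 2.0 * (Qnxx[k] * Qnxx[k] + Qnxy[k] * Qnxy[k]);
      double qqm = 2.0 * (Qmxx[k] * Qmxx[k] + Qmxy[k] * Qmxy[k]);
      if (interior[k]) {
        double an = 6.0 * p.C * (1.0 - 3.0 * qqn);
        double am = 6.0 * p.C * (1.0 - 3.0 * qqm);
        if (p.coupling == 0) {
          double qnm = 2.0 * (Qnxx[k] * Qmxx[k] + Qnxy[k] * Qmxy[k]);
          double aj = 3.0 * p.J * (1.0 - 3.0 * qnm);
          Hnxx[k] = an * Qnxx[k] + p.Kn * lap_nxx + aj * Qmxx[k];
          Hnxy[k] = an * Qnxy[k] + p.Kn * lap_nxy + aj * Qmxy[k];
          Hmxx[k] = am * Qmxx[k] + p.Km * lap_mxx + aj * Qnxx[k];
          Hmxy[k] = am * Qmxy[k] + p.Km * lap_mxy + aj * Qnxy[k];
        } else {
          Hnxx[k] = an * Qnxx[k] + p.Kn * lap_nxx + p.J * (Qmxx[k] - Qnxx[k]);
          Hnxy[k] = an * Qnxy[k] + p.Kn * lap_nxy + p.J * (Qmxy[k] - Qnxy[k]);
          Hmxx[k] = am * Qmxx[k] + p.Km * lap_mxx + p.J * (Qnxx[k] - Qmxx[k]);
          Hmxy[k] = am * Qmxy[k] + p.Km * lap_mxy + p.J * (Qnxy[k] - Qmxy[k]);
        }
      } else {
        Hnxx[k] = -2.0 * p.Cprime * qqn * Qnxx[k] + p.Kn * lap_nxx;
        Hnxy[k] = -2.0 * p.Cprime * qqn * Qnxy[k] + p.Kn * lap_nxy;
        Hmxx[k] = -2.0 * p.Cprime * qqm * Qmxx[k] + p.Km * lap_mxx;
        Hmxy[k] = -2.0 * p.Cprime * qqm * Qmxy[k] + p.Km * lap_mxy;
      }
    }
  }
}

// One explicit Euler step of the co-rotational Q dynamics for both tensors:
// (dt + u.grad) Q = -Omega.Q + Q.Omega + gamma H, central-difference advection.
void q_advance(const Grid& g,
               std::vector<double>& Qnxx, std::vector<double>& Qnxy,
               std::vector<double>& Qmxx, std::vector<double>& Qmxy,
               const double* ux, const double* uy,
               const Params& p, double dt, bool evolve_n, bool advect,
               const std::vector<double>& w0, const std::vector<double>& w1,
               const std::vector<double>& w2, const std::vector<double>& w3) {
  std::vector<double> nxx(Qnxx), nxy(Qnxy), mxx(Qmxx), mxy(Qmxy);
  for (int j = 0; j < g.ny; ++j) {
    int jp = g.yp[j], jm = g.ym[j];
    for (int i = 0; i < g.nx; ++i) {
      int ip = g.xp[i], im = g.xm[i];
      int k = g.id(i, j);
      double adv_nxx = 0.0, adv_nxy = 0.0, adv_mxx = 0.0, adv_mxy = 0.0;
      double omega = 0.0;
      if (advect) {
        double u = ux[k], v = uy[k];
        adv_nxx = u * 0.5 * (nxx[g.id(ip, j)] - nxx[g.id(im, j)]) +
                  v * 0.5 * (nxx[g.id(i, jp)] - nxx[g.id(i, jm)]);
        adv_nxy = u * 0.5 * (nxy[g.id(ip, j)] - nxy[g.id(im, j)]) +
                  v * 0.5 * (nxy[g.id(i, jp)] - nxy[g.id(i, jm)]);
        adv_mxx = u * 0.5 * (mxx[g.id(ip, j)] - mxx[g.id(im, j)]) +
                  v * 0.5 * (mxx[g.id(i, jp)] - mxx[g.id(i, jm)]);
        adv_mxy = u * 0.5 * (mxy[g.id(ip, j)] - mxy[g.id(im, j)]) +
                  v * 0.5 * (mxy[g.id(i, jp)] - mxy[g.id(i, jm)]);
        omega = 0.5 * (uy[g.id(ip, j)] - uy[g.id(im, j)]) -
                0.5 * (ux[g.id(i, jp)] - ux[g.id(i, jm)]);
        omega *= p.corot_sign;
      }
      if (evolve_n) {
        Qnxx[k] = nxx[k] + dt * (-adv_nxx - omega * nxy[k] + p.gamma * w0[k]);
        Qnxy[k] = nxy[k] + dt * (-adv_nxy + omega * nxx[k] + p.gamma * w1[k]);
      }
      Qmxx[k] = mxx[k] + dt * (-adv_mxx - omega * mxy[k] + p.gamma * w2[k]);
      Qmxy[k] = mxy[k] + dt * (-adv_mxy + omega * mxx[k] + p.gamma * w3[k]);
    }
  }
}

void q_step_kernel(const Grid& g,
                   std::vector<double>& Qnxx, std::vector<double>& Qnxy,
                   std::vector<double>& Qmxx, std::vector<double>& Qmxy,
                   const double* ux, const double* uy,
                   const int* interior, const Params& p, double dt,
                   bool evolve_n, bool advect,
                   std::vector<double>& w0, std::vector<double>& w1,
                   std::vector<double>& w2, std::vector<double>& w3) {
  molecular_field_kernel(g, Qnxx.data(), Qnxy.data(), Qmxx.data(), Qmxy.data(),
                         interior, p, w0.data(), w1.data(), w2.data(), w3.data());
  q_advance(g, Qnxx, Qnxy, Qmxx, Qmxy, ux, uy, p, dt, evolve_n, advect,
            w0, w1, w2, w3);
}

// Elastic passive stress of both tensors: Ericksen gradient stress plus the
// antisymmetric director-torque stress QH - HQ. Adds div(Pi_el) to (Fx, Fy).
void add_elastic_force(const Grid& g,
                       const std::vector<double>& Qnxx, const std::vector<double>& Qnxy,
                       const std::vector<double>& Qmxx, const std::vector<double>& Qmxy,
                       const std::vector<double>& Hnxx, const std::vector<double>& Hnxy,
                       const std::vector<double>& Hmxx, const std::vector<double>& Hmxy,
                       const Params& p,
                       std::vector<double>& Pxx, std::vector<double>& Pxy,
                       std::vector<double>& Pyx, std::vector<double>& Pyy,
                       double* Fx, double* Fy) {
  for (int j = 0; j < g.ny; ++j) {
    int jp = g.yp[j], jm = g.ym[j];
    for (int i = 0; i < g.nx; ++i) {
      int ip = g.xp[i], im = g.xm[i];
      int k = g.id(i, j);
      double dxnxx = 0.5 * (Qnxx[g.id(ip, j)] - Qnxx[g.id(im, j)]);
      double dynxx = 0.5 * (Qnxx[g.id(i, jp)] - Qnxx[g.id(i, jm)]);
      double dxnxy = 0.5 * (Qnxy[g.id(ip, j)] - Qnxy[g.id(im, j)]);
      double dynxy = 0.5 * (Qnxy[g.id(i, jp)] - Qnxy[g.id(i, jm)]);
      double dxmxx = 0.5 * (Qmxx[g.id(ip, j)] - Qmxx[g.id(im, j)]);
      double dymxx = 0.5 * (Qmxx[g.id(i, jp)] - Qmxx[g.id(i, jm)]);
      double dxmxy = 0.5 * (Qmxy[g.id(ip, j)] - Qmxy[g.id(im, j)]);
      double dymxy = 0.5 * (Qmxy[g.id(i, jp)] - Qmxy[g.id(i, jm)]);
      double exx = 2.0 * (p.Kn * (dxnxx * dxnxx + dxnxy * dxnxy) +
                          p.Km * (dxmxx * dxmxx + dxmxy * dxmxy));
      double eyy = 2.0 * (p.Kn * (dynxx * dynxx + dynxy * dynxy) +
                          p.Km * (dymxx * dymxx + dymxy * dymxy));
      double exy = 2.0 * (p.Kn * (dxnxx * dynxx + dxnxy * dynxy) +
                          p.Km * (dxmxx * dymxx + dxmxy * dymxy));
      double tau = 2.0 * (Qnxx[k] * Hnxy[k] - Qnxy[k] * Hnxx[k]) +
                   2.0 * (Qmxx[k] * Hmxy[k] - Qmxy[k] * Hmxx[k]);
      Pxx[k] = -exx;
      Pyy[k] = -eyy;
      Pxy[k] = -exy + tau;
      Pyx[k] = -exy - tau;
    }
  }
  for (int j = 0; j < g.ny; ++j) {
    int jp = g.yp[j], jm = g.ym[j];
    for (int i = 0; i < g.nx; ++i) {
      int ip = g.xp[i], im = g.xm[i];
      int k = g.id(i, j);
      Fx[k] += 0.5 * (Pxx[g.id(ip, j)] - Pxx[g.id(im, j)]) +
               0.5 * (Pyx[g.id(i, jp)] - Pyx[g.id(i, jm)]);
      Fy[k] += 0.5 * (Pxy[g.id(ip, j)] - Pxy[g.id(im, j)]) +
               0.5 * (Pyy[g.id(i, jp)] - Pyy[g.id(i, jm)]);
    }
  }
}

// ---- D2Q9 lattice Boltzmann ----
const int EX[9] = {0, 1, 0, -1, 0, 1, -1, -1, 1};
const int EY[9] = {0, 0, 1, 0, -1, 1, 1, -1, -1};
const double W9[9] = {4.0 / 9.0,
                      1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0,
                      1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0};

inline double feq(int q, double rho, double ux, double uy) {
  double eu = EX[q] * ux + EY[q] * uy;
  double uu = ux * ux + uy * uy;
  return W9[q] * rho * (1.0 + 3.0 * eu + 4.5 * eu * eu - 1.5 * uu);
}

inline double guo(int q, double tau, double ux, double uy,
                  double Fx, double Fy) {
  double eu = EX[q] * ux + EY[q] * uy;
  return (1.0 - 0.5 / tau) * W9[q] *
         (3.0 * ((EX[q] - ux) * Fx + (EY[q] - uy) * Fy) +
          9.0 * eu * (EX[q] * Fx + EY[q] * Fy));
}

void macroscopic(const Grid& g, const std::vector<double>& f,
                 const double* Fx, const double* Fy,
                 double* rho, double* ux, double* uy) {
  for (int k = 0; k < g.n; ++k) {
    double r = 0.0, mx = 0.0, my = 0.0;
    const double* fk = &f[(size_t)k * 9];
    for (int q = 0; q < 9; ++q) {
      r += fk[q];
      mx += fk[q] * EX[q];
      my += fk[q] * EY[q];
    }
    rho[k] = r;
    ux[k] = (mx + 0.5 * Fx[k]) / r;
    uy[k] = (my + 0.5 * Fy[k]) / r;
  }
}

// BGK collision with Guo forcing, then streaming (push).
void collide_stream(const Grid& g, std::vector<double>& f,
                    std::vector<double>& ftmp,
                    const double* rho, const double* ux, const double* uy,
                    const double* Fx, const double* Fy, double tau) {
  for (int j = 0; j < g.ny; ++j) {
    for (int i = 0; i < g.nx; ++i) {
      int k = g.id(i, j);
      const double* fk = &f[(size_t)k * 9];
      for (int q = 0; q < 9; ++q) {
        double fpost = fk[q] - (fk[q] - feq(q, rho[k], ux[k], uy[k])) / tau +
                       guo(q, tau, ux[k], uy[k], Fx[k], Fy[k]);
        int ii = i + EX[q]; if (ii < 0) ii += g.nx; else if (ii >= g.nx) ii -= g.nx;
        int jj = j + EY[q]; if (jj < 0) jj += g.ny; else if (jj >= g.ny) jj -= g.ny;
        ftmp[(size_t)g.id(ii, jj) * 9 + q] = fpost;
      }
    }
  }
  f.swap(ftmp);
}

// Body force f = div(Pi_act), Pi_act = -zeta * Q^m.
void active_force(const Grid& g, const double* Qmxx, const double* Qmxy,
                  double zeta, double* Fx, double* Fy) {
  for (int j = 0; j < g.ny; ++j) {
    int jp = g.yp[j], jm = g.ym[j];
    for (int i = 0; i < g.nx; ++i) {
      int ip = g.xp[i], im = g.xm[i];
      int k = g.id(i, j);
      double dxQxx = 0.5 * (Qmxx[g.id(ip, j)] - Qmxx[g.id(im, j)]);
      double dyQxx = 0.5 * (Qmxx[g.id(i, jp)] - Qmxx[g.id(i, jm)]);
      double dxQxy = 0.5 * (Qmxy[g.id(ip, j)] - Qmxy[g.id(im, j)]);
      double dyQxy = 0.5 * (Qmxy[g.id(i, jp)] - Qmxy[g.id(i, jm)]);
      Fx[k] = -zeta * (dxQxx + dyQxy);
      Fy[k] = -zeta * (dxQxy - dyQxx);
    }
  }
}

std::vector<double> copy_mat(const NumericMatrix& m) {
  return std::vector<double>(m.begin(), m.end());
}

NumericMatrix to_mat(const std::vector<double>& v, int nx, int ny) {
  NumericMatrix out(nx, ny);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

std::vector<int> interior_vec(SEXP interior, int n) {
  if (Rf_isNull(interior)) return std::vector<int>(n, 1);
  IntegerMatrix m(interior);
  return std::vector<int>(m.begin(), m.end());
}

} // namespace

// [[Rcpp::export(name = ".mol_field_cpp")]]
List mol_field_cpp(NumericMatrix Qnxx, NumericMatrix Qnxy,
                   NumericMatrix Qmxx, NumericMatrix Qmxy,
                   double C, double Kn, double Km, double J,
                   SEXP interior, double Cprime, int coupling) {
  int nx = Qnxx.nrow(), ny = Qnxx.ncol();
  Grid g(nx, ny);
  Params p; p.C = C; p.Kn = Kn; p.Km = Km; p.J = J; p.Cprime = Cprime;
  p.coupling = coupling;
  std::vector<int> in = interior_vec(interior, g.n);
  std::vector<double> h0(g.n), h1(g.n), h2(g.n), h3(g.n);
  molecular_field_kernel(g, REAL(Qnxx), REAL(Qnxy), REAL(Qmxx), REAL(Qmxy),
                         in.data(), p, h0.data(), h1.data(), h2.data(), h3.data());
  return List::create(_["Hnxx"] = to_mat(h0, nx, ny), _["Hnxy"] = to_mat(h1, nx, ny),
                      _["Hmxx"] = to_mat(h2, nx, ny), _["Hmxy"] = to_mat(h3, nx, ny));
}

// [[Rcpp::export(name = ".q_step_cpp")]]
List q_step_cpp(NumericMatrix Qnxx, NumericMatrix Qnxy,
                NumericMatrix Qmxx, NumericMatrix Qmxy,
                NumericMatrix ux, NumericMatrix uy,
                double C, double Kn, double Km, double J, double gamma,
                SEXP interior, double Cprime, double dt, int nsteps,
                bool evolve_n, int coupling) {
  int nx = Qnxx.nrow(), ny = Qnxx.ncol();
  Grid g(nx, ny);
  Params p; p.C = C; p.Kn = Kn; p.Km = Km; p.J = J; p.gamma = gamma; p.Cprime = Cprime;
  p.coupling = coupling;
  std::vector<int> in = interior_vec(interior, g.n);
  std::vector<double> qnxx = copy_mat(Qnxx), qnxy = copy_mat(Qnxy);
  std::vector<double> qmxx = copy_mat(Qmxx), qmxy = copy_mat(Qmxy);
  std::vector<double> w0(g.n), w1(g.n), w2(g.n), w3(g.n);
  for (int s = 0; s < nsteps; ++s)
    q_step_kernel(g, qnxx, qnxy, qmxx, qmxy, REAL(ux), REAL(uy),
                  in.data(), p, dt, evolve_n, true, w0, w1, w2, w3);
  return List::create(_["Qnxx"] = to_mat(qnxx, nx, ny), _["Qnxy"] = to_mat(qnxy, nx, ny),
                      _["Qmxx"] = to_mat(qmxx, nx, ny), _["Qmxy"] = to_mat(qmxy, nx, ny));
}

// [[Rcpp::export(name = ".lb_equilibrium_cpp")]]
NumericMatrix lb_equilibrium_cpp(NumericMatrix rho, NumericMatrix ux,
                                 NumericMatrix uy) {
  int n = rho.nrow() * rho.ncol();
  NumericMatrix f(9, n); // one column per site
  for (int k = 0; k < n; ++k)
    for (int q = 0; q < 9; ++q)
      f(q, k) = feq(q, rho[k], ux[k], uy[k]);
  return f;
}

// Pure-flow LB run (no Q coupling): populations in, populations + fields out.
// Used for viscometric checks and as the exposed single/multi LB step.
// [[Rcpp::export(name = ".lb_run_cpp")]]
List lb_run_cpp(NumericMatrix fpop, int nx, int ny,
                NumericMatrix Fx, NumericMatrix Fy, double tau, int steps) {
  Grid g(nx, ny);
  std::vector<double> f((size_t)g.n * 9), ftmp((size_t)g.n * 9);
  for (int k = 0; k < g.n; ++k)
    for (int q = 0; q < 9; ++q) f[(size_t)k * 9 + q] = fpop(q, k);
  std::vector<double> rho(g.n), ux(g.n), uy(g.n);
  for (int s = 0; s < steps; ++s) {
    macroscopic(g, f, REAL(Fx), REAL(Fy), rho.data(), ux.data(), uy.data());
    for (int k = 0; k < g.n; ++k)
      if (rho[k] <= 0.0) stop("negative density in LB step");
    collide_stream(g, f, ftmp, rho.data(), ux.data(), uy.data(),
                   REAL(Fx), REAL(Fy), tau);
  }
  macroscopic(g, f, REAL(Fx), REAL(Fy), rho.data(), ux.data(), uy.data());
  NumericMatrix fout(9, g.n);
  for (int k = 0; k < g.n; ++k)
    for (int q = 0; q < 9; ++q) fout(q, k) = f[(size_t)k * 9 + q];
  return List::create(_["f"] = fout, _["rho"] = to_mat(rho, nx, ny),
                      _["ux"] = to_mat(ux, nx, ny), _["uy"] = to_mat(uy, nx, ny));
}

// Full hybrid run: active forcing + flow + co-rotational Q dynamics.
// Frames (including the initial state) are recorded every frame_every steps.
// [[Rcpp::export(name = ".run_hybrid_cpp")]]
List run_hybrid_cpp(NumericMatrix Qnxx0, NumericMatrix Qnxy0,
                    NumericMatrix Qmxx0, NumericMatrix Qmxy0,
                    double C, double Kn, double Km, double J, double gamma,
                    double zeta, double rho0, double tau,
                    int steps, int frame_every, bool store_flow,
                    double corot_sign, bool backstress, int coupling) {
  int nx = Qnxx0.nrow(), ny = Qnxx0.ncol();
  Grid g(nx, ny);
  Params p; p.C = C; p.Kn = Kn; p.Km = Km; p.J = J; p.gamma = gamma;
  p.zeta = zeta; p.rho0 = rho0; p.tau = tau; p.Cprime = 0.0;
  p.corot_sign = corot_sign; p.backstress = backstress; p.coupling = coupling;
  std::vector<int> in(g.n, 1);

  std::vector<double> qnxx = copy_mat(Qnxx0), qnxy = copy_mat(Qnxy0);
  std::vector<double> qmxx = copy_mat(Qmxx0), qmxy = copy_mat(Qmxy0);
  std::vector<double> f((size_t)g.n * 9), ftmp((size_t)g.n * 9);
  for (int k = 0; k < g.n; ++k)
    for (int q = 0; q < 9; ++q) f[(size_t)k * 9 + q] = feq(q, rho0, 0.0, 0.0);
  std::vector<double> rho(g.n, rho0), ux(g.n, 0.0), uy(g.n, 0.0);
  std::vector<double> Fx(g.n, 0.0), Fy(g.n, 0.0);
  std::vector<double> w0(g.n), w1(g.n), w2(g.n), w3(g.n);
  std::vector<double> Pxx, Pxy, Pyx, Pyy;
  if (backstress) {
    Pxx.resize(g.n); Pxy.resize(g.n); Pyx.resize(g.n); Pyy.resize(g.n);
  }

  int nframes = steps / frame_every + 1;
  NumericVector Anxx(Dimension(nx, ny, nframes)), Anxy(Dimension(nx, ny, nframes));
  NumericVector Amxx(Dimension(nx, ny, nframes)), Amxy(Dimension(nx, ny, nframes));
  NumericVector Aux, Auy;
  if (store_flow) {
    Aux = NumericVector(Dimension(nx, ny, nframes));
    Auy = NumericVector(Dimension(nx, ny, nframes));
  }
  IntegerVector frame_steps(nframes);
  NumericVector mass(nframes), max_speed(nframes);

  int fr = 0;
  auto record = [&](int step) {
    size_t off = (size_t)fr * g.n;
    std::copy(qnxx.begin(), qnxx.end(), Anxx.begin() + off);
    std::copy(qnxy.begin(), qnxy.end(), Anxy.begin() + off);
    std::copy(qmxx.begin(), qmxx.end(), Amxx.begin() + off);
    std::copy(qmxy.begin(), qmxy.end(), Amxy.begin() + off);
    if (store_flow) {
      std::copy(ux.begin(), ux.end(), Aux.begin() + off);
      std::copy(uy.begin(), uy.end(), Auy.begin() + off);
    }
    double m = 0.0, mu = 0.0;
    for (int k = 0; k < g.n; ++k) {
      m += rho[k];
      double s = std::sqrt(ux[k] * ux[k] + uy[k] * uy[k]);
      if (s > mu) mu = s;
    }
    mass[fr] = m; max_speed[fr] = mu; frame_steps[fr] = step;
    ++fr;
  };
  record(0);

  for (int step = 1; step <= steps; ++step) {
    molecular_field_kernel(g, qnxx.data(), qnxy.data(), qmxx.data(), qmxy.data(),
                           in.data(), p, w0.data(), w1.data(), w2.data(), w3.data());
    active_force(g, qmxx.data(), qmxy.data(), p.zeta, Fx.data(), Fy.data());
    if (backstress)
      add_elastic_force(g, qnxx, qnxy, qmxx, qmxy, w0, w1, w2, w3, p,
                        Pxx, Pxy, Pyx, Pyy, Fx.data(), Fy.data());
    macroscopic(g, f, Fx.data(), Fy.data(), rho.data(), ux.data(), uy.data());
    q_advance(g, qnxx, qnxy, qmxx, qmxy, ux.data(), uy.data(),
              p, 1.0, true, true, w0, w1, w2, w3);
    collide_stream(g, f, ftmp, rho.data(), ux.data(), uy.data(),
                   Fx.data(), Fy.data(), p.tau);
    if (step % 1000 == 0) {
      checkUserInterrupt();
      int k0 = g.id(step % nx, (step / 7) % ny);
      if (!std::isfinite(qnxx[k0]) || !std::isfinite(qmxx[k0]) ||
          !std::isfinite(ux[k0]))
        stop("non-finite field value at step %d", step);
    }
    if (step % frame_every == 0) record(step);
  }

  List out = List::create(_["Qnxx"] = Anxx, _["Qnxy"] = Anxy,
                          _["Qmxx"] = Amxx, _["Qmxy"] = Amxy,
                          _["steps"] = frame_steps, _["mass"] = mass,
                          _["max_speed"] = max_speed);
  if (store_flow) { out["ux"] = Aux; out["uy"] = Auy; }
  return out;
}

// LP-9 relaxation: Q^n pinned, no flow; Q^m evolves by gamma*H^m alone until
// max |gamma H^m| < tol or the step cap. Snapshots every check_every steps.
// [[Rcpp::export(name = ".relax_stress_cpp")]]
List relax_stress_cpp(NumericMatrix Qnxx, NumericMatrix Qnxy,
                      NumericMatrix Qmxx0, NumericMatrix Qmxy0,
                      double C, double Kn, double Km, double J, double gamma,
                      IntegerMatrix interior, double Cprime,
                      double tol, int max_steps, int check_every, int coupling) {
  int nx = Qnxx.nrow(), ny = Qnxx.ncol();
  Grid g(nx, ny);
  Params p; p.C = C; p.Kn = Kn; p.Km = Km; p.J = J; p.gamma = gamma; p.Cprime = Cprime;
  p.coupling = coupling;
  std::vector<int> in(interior.begin(), interior.end());
  std::vector<double> qnxx = copy_mat(Qnxx), qnxy = copy_mat(Qnxy);
  std::vector<double> qmxx = copy_mat(Qmxx0), qmxy = copy_mat(Qmxy0);
  std::vector<double> h0(g.n), h1(g.n), h2(g.n), h3(g.n);

  int ncheck = max_steps / check_every + 2;
  NumericVector Sxx(Dimension(nx, ny, ncheck)), Sxy(Dimension(nx, ny, ncheck));
  IntegerVector snap_steps(ncheck);
  NumericVector maxH(ncheck);
  int sn = 0, step = 0;
  bool converged = false;

  auto residual = [&]() {
    molecular_field_kernel(g, qnxx.data(), qnxy.data(), qmxx.data(), qmxy.data(),
                           in.data(), p, h0.data(), h1.data(), h2.data(), h3.data());
    double mh = 0.0;
    for (int k = 0; k < g.n; ++k) {
      double a = std::fabs(p.gamma * h2[k]), b = std::fabs(p.gamma * h3[k]);
      if (a > mh) mh = a;
      if (b > mh) mh = b;
    }
    return mh;
  };
  auto snapshot = [&](double mh) {
    size_t off = (size_t)sn * g.n;
    std::copy(qmxx.begin(), qmxx.end(), Sxx.begin() + off);
    std::copy(qmxy.begin(), qmxy.end(), Sxy.begin() + off);
    snap_steps[sn] = step; maxH[sn] = mh;
    ++sn;
  };
  snapshot(residual());

  while (step < max_steps) {
    int burst = std::min(check_every, max_steps - step);
    for (int s = 0; s < burst; ++s) {
      molecular_field_kernel(g, qnxx.data(), qnxy.data(), qmxx.data(), qmxy.data(),
                             in.data(), p, h0.data(), h1.data(), h2.data(), h3.data());
      for (int k = 0; k < g.n; ++k) {
        qmxx[k] += p.gamma * h2[k];
        qmxy[k] += p.gamma * h3[k];
      }
    }
    step += burst;
    checkUserInterrupt();
    double mh = residual();
    snapshot(mh);
    if (!std::isfinite(mh)) stop("non-finite residual at step %d", step);
    if (mh < tol) { converged = true; break; }
  }

  return List::create(_["Qmxx"] = to_mat(qmxx, nx, ny),
                      _["Qmxy"] = to_mat(qmxy, nx, ny),
                      _["snap_Qmxx"] = Sxx, _["snap_Qmxy"] = Sxy,
                      _["snap_steps"] = snap_steps, _["snap_maxH"] = maxH,
                      _["n_snapshots"] = sn, _["steps"] = step,
                      _["converged"] = converged);
}
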