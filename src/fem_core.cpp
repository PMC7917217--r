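// Axisymmetric finite-element kernels: 8-node serendipity displacement elements
// with bilinear corner pore pressure (Taylor-Hood style u-p pair, 2x2 reduced
// Gauss integration), small-strain Biot poroelasticity, isotropic and
// transversely isotropic linear elasticity, and total-Lagrangian compressible
// neo-Hookean hyperelasticity. Assembly returns COO triplets + residual; the
// Newton loop, boundary conditions and contact live on the R side.
//
// Units: N, mm, s, MPa. Axisymmetric volume weight 2*pi*r is included, so
// assembled forces are true forces in N.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double GAMMA_W = 9.81e-6;  // unit weight of water, N/mm^3
static const double GPT = 0.5773502691896257;

// law codes
enum { LAW_PORO = 0, LAW_ELASTIC = 1, LAW_NEOHOOKE = 2, LAW_TRANSISO_PORO = 3 };

static void q8_shape(double xi, double eta, double* N, double* dxi, double* deta) {
  static const double xs[4] = {-1, 1, 1, -1};
  static const double es[4] = {-1, -1, 1, 1};
  for (int i = 0; i < 4; i++) {
    double a = xi * xs[i], b = eta * es[i];
    N[i]    = 0.25 * (1 + a) * (1 + b) * (a + b - 1);
    dxi[i]  = 0.25 * xs[i] * (1 + b) * (2 * a + b);
    deta[i] = 0.25 * es[i] * (1 + a) * (a + 2 * b);
  }
  N[4] = 0.5 * (1 - xi * xi) * (1 - eta); dxi[4] = -xi * (1 - eta); deta[4] = -0.5 * (1 - xi * xi);
  N[5] = 0.5 * (1 + xi) * (1 - eta * eta); dxi[5] = 0.5 * (1 - eta * eta); deta[5] = -(1 + xi) * eta;
  N[6] = 0.5 * (1 - xi * xi) * (1 + eta); dxi[6] = -xi * (1 + eta); deta[6] = 0.5 * (1 - xi * xi);
  N[7] = 0.5 * (1 - xi) * (1 - eta * eta); dxi[7] = -0.5 * (1 - eta * eta); deta[7] = -(1 - xi) * eta;
}

static void q4_shape(double xi, double eta, double* N, double* dxi, double* deta) {
  static const double xs[4] = {-1, 1, 1, -1};
  static const double es[4] = {-1, -1, 1, 1};
  for (int i = 0; i < 4; i++) {
    N[i]    = 0.25 * (1 + xi * xs[i]) * (1 + eta * es[i]);
    dxi[i]  = 0.25 * xs[i] * (1 + eta * es[i]);
    deta[i] = 0.25 * es[i] * (1 + xi * xs[i]);
  }
}

static arma::mat iso_D(double E, double nu) {
  double lam = E * nu / ((1 + nu) * (1 - 2 * nu));
  double mu = E / (2 * (1 + nu));
  arma::mat D(4, 4, arma::fill::zeros);
  for (int i = 0; i < 3; i++) {
    for (int j = 0; j < 3; j++) D(i, j) = lam;
    D(i, i) = lam + 2 * mu;
  }
  D(3, 3) = mu;
  return D;
}

// Biot coefficient / storage from drained bulk modulus and grain bulk modulus.
// K_g = 0 is read as "grains not limiting": alpha = 1, 1/M = 0. alpha is
// clamped to [0,1] and the storage term to >= 0 (subchondral bone has
// K_dr marginally above K_g).
static void biot_terms(double E, double nu, double Kg, double voide,
                       double* alpha, double* invM) {
  if (Kg <= 0) { *alpha = 1.0; *invM = 0.0; return; }
  double Kdr = E / (3.0 * (1 - 2 * nu));
  double a = 1.0 - Kdr / Kg;
  if (a < 0) a = 0; if (a > 1) a = 1;
  double n = voide / (1.0 + voide);
  double s = (a - n) / Kg;
  if (s < 0) s = 0;
  *alpha = a; *invM = s;
}

// First Piola-Kirchhoff stress for compressible neo-Hookean
// W = C10 (I1bar - 3) + (1/D1) (J - 1)^2, axisymmetric 5-component F:
// [F11 F12; F21 F22] in (r,z), F33 hoop.
static void nh_piola(const double* F, double C10, double D1, double* P) {
  double F11 = F[0], F12 = F[1], F21 = F[2], F22 = F[3], F33 = F[4];
  double det2 = F11 * F22 - F12 * F21;
  double J = det2 * F33;
  if (J < 1e-6) J = 1e-6;  // guard against transient element inversion
  double I1 = F11 * F11 + F12 * F12 + F21 * F21 + F22 * F22 + F33 * F33;
  double Jm23 = std::pow(J, -2.0 / 3.0);
  // F^{-T} components
  double iT11 = F22 / det2, iT12 = -F21 / det2, iT21 = -F12 / det2, iT22 = F11 / det2;
  double iT33 = 1.0 / F33;
  double c = -(2.0 / 3.0) * C10 * I1 * Jm23 + (2.0 / D1) * (J - 1.0) * J;
  P[0] = 2 * C10 * Jm23 * F11 + c * iT11;
  P[1] = 2 * C10 * Jm23 * F12 + c * iT12;
  P[2] = 2 * C10 * Jm23 * F21 + c * iT21;
  P[3] = 2 * C10 * Jm23 * F22 + c * iT22;
  P[4] = 2 * C10 * Jm23 * F33 + c * iT33;
}

struct Trip {
  std::vector<int> i, j;
  std::vector<double> x;
  void push(int a, int b, double v) { i.push_back(a); j.push_back(b); x.push_back(v); }
  void reserve(size_t n) { i.reserve(n); j.reserve(n); x.reserve(n); }
};

// Assemble residual and (optionally) Jacobian triplets of the coupled system.
// DOF layout: u = (2*node-1, 2*node) interleaved (1-based from R), pressures
// appended after 2*nn using pidx (0-based p index per node, -1 if none).
// Residual convention: R_u = F_int(u) - Q p  (external loads subtracted in R),
// R_p = Q^T (u - u_n) + S (p - p_n) + dt H p   (continuity x dt).
// [[Rcpp::export]]
List fem_assemble_cpp(const NumericMatrix& nodes, const IntegerMatrix& elems,
                      const IntegerVector& law, const NumericMatrix& matp,
                      const NumericMatrix& matD,
                      const NumericVector& u, const NumericVector& p,
                      const IntegerVector& pidx,
                      const NumericVector& un, const NumericVector& pn,
                      double dt, bool want_jac) {
  const int nn = nodes.nrow(), ne = elems.nrow();
  const int np = p.size();
  const int ndof = 2 * nn + np;
  NumericVector res(ndof);
  Trip T;
  if (want_jac) T.reserve((size_t)ne * 500);

  double N8[8], dxi8[8], deta8[8], N4[4], dxi4[4], deta4[4];
  const double gp[2] = {-GPT, GPT};

  for (int e = 0; e < ne; e++) {
    int conn[8];
    double X[8][2];
    for (int a = 0; a < 8; a++) {
      conn[a] = elems(e, a) - 1;
      X[a][0] = nodes(conn[a], 0);
      X[a][1] = nodes(conn[a], 1);
    }
    int lw = law[e];
    double E = matp(e, 0), nu = matp(e, 1), kperm = matp(e, 2),
           voide = matp(e, 3), Kg = matp(e, 4);

    if (lw == LAW_NEOHOOKE) {
      double C10 = matp(e, 5), D1 = matp(e, 6);
      arma::vec ue(16);
      for (int a = 0; a < 8; a++) {
        ue(2 * a) = u[2 * conn[a]];
        ue(2 * a + 1) = u[2 * conn[a] + 1];
      }
      arma::vec fe(16, arma::fill::zeros);
      arma::mat Ke(16, 16, arma::fill::zeros);
      for (int gx = 0; gx < 2; gx++) for (int gy = 0; gy < 2; gy++) {
        q8_shape(gp[gx], gp[gy], N8, dxi8, deta8);
        double J11 = 0, J12 = 0, J21 = 0, J22 = 0, R = 0;
        for (int a = 0; a < 8; a++) {
          J11 += dxi8[a] * X[a][0]; J12 += dxi8[a] * X[a][1];
          J21 += deta8[a] * X[a][0]; J22 += deta8[a] * X[a][1];
          R += N8[a] * X[a][0];
        }
        double detJ = J11 * J22 - J12 * J21;
        double dNX[8][2];
        for (int a = 0; a < 8; a++) {
          dNX[a][0] = (J22 * dxi8[a] - J21 * deta8[a]) / detJ;
          dNX[a][1] = (-J12 * dxi8[a] + J11 * deta8[a]) / detJ;
        }
        double w0 = detJ * 2 * M_PI * R;
        // deformation gradient
        double F[5] = {1, 0, 0, 1, 1};
        double ur = 0;
        for (int a = 0; a < 8; a++) {
          F[0] += ue(2 * a) * dNX[a][0];
          F[1] += ue(2 * a) * dNX[a][1];
          F[2] += ue(2 * a + 1) * dNX[a][0];
          F[3] += ue(2 * a + 1) * dNX[a][1];
          ur += N8[a] * ue(2 * a);
        }
        F[4] = 1 + ur / R;
        double P[5];
        nh_piola(F, C10, D1, P);
        // G maps nodal u to 5-component F variation
        arma::mat G(5, 16, arma::fill::zeros);
        for (int a = 0; a < 8; a++) {
          G(0, 2 * a) = dNX[a][0];
          G(1, 2 * a) = dNX[a][1];
          G(2, 2 * a + 1) = dNX[a][0];
          G(3, 2 * a + 1) = dNX[a][1];
          G(4, 2 * a) = N8[a] / R;
        }
        arma::vec Pv(5);
        for (int c = 0; c < 5; c++) Pv(c) = P[c];
        fe += w0 * (G.t() * Pv);
        if (want_jac) {
          // numerical material tangent dP/dF (central differences)
          arma::mat A(5, 5);
          for (int c = 0; c < 5; c++) {
            double h = 1e-7 * (std::fabs(F[c]) + 1.0);
            double Fp[5], Fm[5], Pp[5], Pm[5];
            for (int d2 = 0; d2 < 5; d2++) { Fp[d2] = F[d2]; Fm[d2] = F[d2]; }
            Fp[c] += h; Fm[c] -= h;
            nh_piola(Fp, C10, D1, Pp);
            nh_piola(Fm, C10, D1, Pm);
            for (int r2 = 0; r2 < 5; r2++) A(r2, c) = (Pp[r2] - Pm[r2]) / (2 * h);
          }
          Ke += w0 * (G.t() * A * G);
        }
      }
      for (int a = 0; a < 16; a++) {
        int ga = 2 * conn[a / 2] + (a % 2);
        res[ga] += fe(a);
        if (want_jac) for (int b = 0; b < 16; b++) {
          int gb = 2 * conn[b / 2] + (b % 2);
          T.push(ga, gb, Ke(a, b));
        }
      }
      continue;
    }

    // linear kinematics laws
    bool poro = (lw == LAW_PORO || lw == LAW_TRANSISO_PORO);
    arma::mat D(4, 4);
    if (lw == LAW_TRANSISO_PORO) {
      int c = 0;
      for (int i = 0; i < 4; i++) for (int j = i; j < 4; j++) {
        D(i, j) = matD(e, c); D(j, i) = matD(e, c); c++;
      }
    } else {
      D = iso_D(E, nu);
    }
    double alpha = 0, invM = 0, mob = 0;
    if (poro) {
      if (lw == LAW_TRANSISO_PORO) {
        alpha = 1.0;
        double n = voide / (1.0 + voide);
        invM = (Kg > 0) ? (1.0 - n) / Kg : 0.0;
      } else {
        biot_terms(E, nu, Kg, voide, &alpha, &invM);
      }
      mob = kperm / GAMMA_W;
    }

    arma::vec ue(16), uen(16), pe(4, arma::fill::zeros), pen(4, arma::fill::zeros);
    int pg[4] = {-1, -1, -1, -1};
    for (int a = 0; a < 8; a++) {
      ue(2 * a) = u[2 * conn[a]];
      ue(2 * a + 1) = u[2 * conn[a] + 1];
      uen(2 * a) = un[2 * conn[a]];
      uen(2 * a + 1) = un[2 * conn[a] + 1];
    }
    if (poro) for (int a = 0; a < 4; a++) {
      pg[a] = pidx[conn[a]];
      pe(a) = p[pg[a]];
      pen(a) = pn[pg[a]];
    }

    arma::mat Ke(16, 16, arma::fill::zeros), Qe(16, 4, arma::fill::zeros),
              Pe(4, 4, arma::fill::zeros);
    arma::vec ru(16, arma::fill::zeros), rp(4, arma::fill::zeros);

    for (int gx = 0; gx < 2; gx++) for (int gy = 0; gy < 2; gy++) {
      double xi = gp[gx], eta = gp[gy];
      q8_shape(xi, eta, N8, dxi8, deta8);
      double J11 = 0, J12 = 0, J21 = 0, J22 = 0, R = 0;
      for (int a = 0; a < 8; a++) {
        J11 += dxi8[a] * X[a][0]; J12 += dxi8[a] * X[a][1];
        J21 += deta8[a] * X[a][0]; J22 += deta8[a] * X[a][1];
        R += N8[a] * X[a][0];
      }
      double detJ = J11 * J22 - J12 * J21;
      double dNX[8][2];
      for (int a = 0; a < 8; a++) {
        dNX[a][0] = (J22 * dxi8[a] - J21 * deta8[a]) / detJ;
        dNX[a][1] = (-J12 * dxi8[a] + J11 * deta8[a]) / detJ;
      }
      double w2 = detJ * 2 * M_PI * R;
      arma::mat B(4, 16, arma::fill::zeros);
      for (int a = 0; a < 8; a++) {
        B(0, 2 * a) = dNX[a][0];
        B(1, 2 * a + 1) = dNX[a][1];
        B(2, 2 * a) = N8[a] / R;
        B(3, 2 * a) = dNX[a][1];
        B(3, 2 * a + 1) = dNX[a][0];
      }
      arma::vec eps = B * ue;
      arma::vec sig = D * eps;
      ru += w2 * (B.t() * sig);
      if (want_jac) Ke += w2 * (B.t() * D * B);
      if (poro) {
        q4_shape(xi, eta, N4, dxi4, deta4);
        double dNpX[4][2];
        for (int a = 0; a < 4; a++) {
          dNpX[a][0] = (J22 * dxi4[a] - J21 * deta4[a]) / detJ;
          dNpX[a][1] = (-J12 * dxi4[a] + J11 * deta4[a]) / detJ;
        }
        double pval = 0;
        for (int a = 0; a < 4; a++) pval += N4[a] * pe(a);
        arma::vec bm(16);
        for (int a = 0; a < 8; a++) {
          bm(2 * a) = B(0, 2 * a) + B(2, 2 * a);
          bm(2 * a + 1) = B(1, 2 * a + 1);
        }
        ru -= (w2 * alpha * pval) * bm;
        double evol = 0, evoln = 0;
        arma::vec epsn = B * uen;
        evol = eps(0) + eps(1) + eps(2);
        evoln = epsn(0) + epsn(1) + epsn(2);
        double dpv = 0;
        for (int a = 0; a < 4; a++) dpv += N4[a] * (pe(a) - pen(a));
        double gpr = 0, gpz = 0;
        for (int a = 0; a < 4; a++) { gpr += dNpX[a][0] * pe(a); gpz += dNpX[a][1] * pe(a); }
        for (int a = 0; a < 4; a++) {
          rp(a) += w2 * (alpha * (evol - evoln) + invM * dpv) * N4[a]
                 + dt * w2 * mob * (dNpX[a][0] * gpr + dNpX[a][1] * gpz);
        }
        if (want_jac) {
          for (int a = 0; a < 16; a++) for (int b = 0; b < 4; b++)
            Qe(a, b) += w2 * alpha * bm(a) * N4[b];
          for (int a = 0; a < 4; a++) for (int b = 0; b < 4; b++)
            Pe(a, b) += w2 * invM * N4[a] * N4[b]
                      + dt * w2 * mob * (dNpX[a][0] * dNpX[b][0] + dNpX[a][1] * dNpX[b][1]);
        }
      }
    }

    for (int a = 0; a < 16; a++) {
      int ga = 2 * conn[a / 2] + (a % 2);
      res[ga] += ru(a);
    }
    if (poro) for (int a = 0; a < 4; a++) res[2 * nn + pg[a]] += rp(a);
    if (want_jac) {
      for (int a = 0; a < 16; a++) {
        int ga = 2 * conn[a / 2] + (a % 2);
        for (int b = 0; b < 16; b++) {
          int gb = 2 * conn[b / 2] + (b % 2);
          T.push(ga, gb, Ke(a, b));
        }
        if (poro) for (int b = 0; b < 4; b++) {
          int gb = 2 * nn + pg[b];
          T.push(ga, gb, -Qe(a, b));
          T.push(gb, ga, Qe(a, b));
        }
      }
      if (poro) for (int a = 0; a < 4; a++) for (int b = 0; b < 4; b++)
        T.push(2 * nn + pg[a], 2 * nn + pg[b], Pe(a, b));
    }
  }

  List out = List::create(_["res"] = res);
  if (want_jac) {
    out["ti"] = IntegerVector(T.i.begin(), T.i.end());
    out["tj"] = IntegerVector(T.j.begin(), T.j.end());
    out["tx"] = NumericVector(T.x.begin(), T.x.end());
  }
  return out;
}

// Element-centroid strain/flux extraction (average of the 2x2 Gauss points).
// Columns: err, ezz, ethh, grz, gamma_oct (%), qr, qz, |q| (Darcy flux, mm/s).
// [[Rcpp::export]]
NumericMatrix fem_fields_cpp(const NumericMatrix& nodes, const IntegerMatrix& elems,
                             const IntegerVector& law, const NumericMatrix& matp,
                             const NumericVector& u, const NumericVector& p,
                             const IntegerVector& pidx) {
  const int ne = elems.nrow();
  NumericMatrix out(ne, 8);
  double N8[8], dxi8[8], deta8[8], N4[4], dxi4[4], deta4[4];
  const double gp[2] = {-GPT, GPT};
  for (int e = 0; e < ne; e++) {
    int conn[8];
    double X[8][2], ue[16];
    for (int a = 0; a < 8; a++) {
      conn[a] = elems(e, a) - 1;
      X[a][0] = nodes(conn[a], 0);
      X[a][1] = nodes(conn[a], 1);
      ue[2 * a] = u[2 * conn[a]];
      ue[2 * a + 1] = u[2 * conn[a] + 1];
    }
    int lw = law[e];
    bool poro = (lw == LAW_PORO || lw == LAW_TRANSISO_PORO);
    double pe[4] = {0, 0, 0, 0};
    if (poro) for (int a = 0; a < 4; a++) pe[a] = p[pidx[conn[a]]];
    double mob = poro ? matp(e, 2) / GAMMA_W : 0.0;
    double eps[4] = {0, 0, 0, 0}, q2[2] = {0, 0};
    for (int gx = 0; gx < 2; gx++) for (int gy = 0; gy < 2; gy++) {
      q8_shape(gp[gx], gp[gy], N8, dxi8, deta8);
      double J11 = 0, J12 = 0, J21 = 0, J22 = 0, R = 0;
      for (int a = 0; a < 8; a++) {
        J11 += dxi8[a] * X[a][0]; J12 += dxi8[a] * X[a][1];
        J21 += deta8[a] * X[a][0]; J22 += deta8[a] * X[a][1];
        R += N8[a] * X[a][0];
      }
      double detJ = J11 * J22 - J12 * J21;
      for (int a = 0; a < 8; a++) {
        double dr = (J22 * dxi8[a] - J21 * deta8[a]) / detJ;
        double dz = (-J12 * dxi8[a] + J11 * deta8[a]) / detJ;
        eps[0] += 0.25 * dr * ue[2 * a];
        eps[1] += 0.25 * dz * ue[2 * a + 1];
        eps[2] += 0.25 * N8[a] / R * ue[2 * a];
        eps[3] += 0.25 * (dz * ue[2 * a] + dr * ue[2 * a + 1]);
      }
      if (poro) {
        q4_shape(gp[gx], gp[gy], N4, dxi4, deta4);
        double gpr = 0, gpz = 0;
        for (int a = 0; a < 4; a++) {
          double dr = (J22 * dxi4[a] - J21 * deta4[a]) / detJ;
          double dz = (-J12 * dxi4[a] + J11 * deta4[a]) / detJ;
          gpr += dr * pe[a]; gpz += dz * pe[a];
        }
        q2[0] += -0.25 * mob * gpr;
        q2[1] += -0.25 * mob * gpz;
      }
    }
    // principal strains: in-plane eigenpair + hoop
    double cc = 0.5 * (eps[0] + eps[1]);
    double rr = std::sqrt(0.25 * (eps[0] - eps[1]) * (eps[0] - eps[1])
                          + 0.25 * eps[3] * eps[3]);
    double e1 = cc + rr, e2 = cc - rr, e3 = eps[2];
    double goct = (2.0 / 3.0) * std::sqrt((e1 - e2) * (e1 - e2)
                   + (e2 - e3) * (e2 - e3) + (e3 - e1) * (e3 - e1));
    out(e, 0) = eps[0]; out(e, 1) = eps[1]; out(e, 2) = eps[2]; out(e, 3) = eps[3];
    out(e, 4) = goct * 100.0;
    out(e, 5) = q2[0]; out(e, 6) = q2[1];
    out(e, 7) = std::sqrt(q2[0] * q2[0] + q2[1] * q2[1]);
  }
  return out;
}
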