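// Voxel hexahedral FE kernels: trilinear hex B-matrices, element stiffness,
// element-by-element matrix-vector products, Jacobi-preconditioned CG, and
// centroid stress recovery.  Dof layout: node i -> dofs 3i, 3i+1, 3i+2.
//
// Springs couple node pairs across interfaces (ties and compression-only
// contact).  Spring table columns: ia, ib (0-based node), kn, kt, nx, ny,
// nz, active.  k = kn n n' + kt (I - n n').
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// B matrices (6 x 24, engineering shear) for the 8 Gauss points (+-1/sqrt3)
// of a hex with edge lengths hx, hy, hz.  Local node l has offsets
// (l&1, (l>>1)&1, (l>>2)&1) on the voxel corner grid.
// [[Rcpp::export]]
List hex_B_cpp(double hx, double hy, double hz) {
  const double gp = 1.0 / std::sqrt(3.0);
  NumericMatrix Bg(144, 8);       // 6x24 column-major per Gauss point
  NumericMatrix Bc(6, 24);        // centroid
  double w = hx * hy * hz / 8.0;  // Gauss weight x Jacobian
  auto fill = [&](double xi, double eta, double zeta, double* B) {
    for (int i = 0; i < 144; i++) B[i] = 0.0;
    for (int l = 0; l < 8; l++) {
      double sx = 2.0 * (l & 1) - 1.0;
      double sy = 2.0 * ((l >> 1) & 1) - 1.0;
      double sz = 2.0 * ((l >> 2) & 1) - 1.0;
      double dNx = 0.125 * sx * (1 + sy * eta) * (1 + sz * zeta) * 2.0 / hx;
      double dNy = 0.125 * (1 + sx * xi) * sy * (1 + sz * zeta) * 2.0 / hy;
      double dNz = 0.125 * (1 + sx * xi) * (1 + sy * eta) * sz * 2.0 / hz;
      double* c0 = B + 6 * (3 * l);
      double* c1 = B + 6 * (3 * l + 1);
      double* c2 = B + 6 * (3 * l + 2);
      c0[0] = dNx; c1[1] = dNy; c2[2] = dNz;
      c0[3] = dNy; c1[3] = dNx;              // gxy
      c1[4] = dNz; c2[4] = dNy;              // gyz
      c0[5] = dNz; c2[5] = dNx;              // gxz
    }
  };
  for (int g = 0; g < 8; g++) {
    double xi = (2.0 * (g & 1) - 1.0) * gp;
    double eta = (2.0 * ((g >> 1) & 1) - 1.0) * gp;
    double zeta = (2.0 * ((g >> 2) & 1) - 1.0) * gp;
    fill(xi, eta, zeta, &Bg(0, g));
  }
  fill(0.0, 0.0, 0.0, Bc.begin());
  return List::create(_["Bg"] = Bg, _["Bc"] = Bc, _["w"] = w);
}

// ke = sum_g B' D B w for a 6x6 material matrix D.
// [[Rcpp::export]]
NumericMatrix hex_ke_cpp(NumericMatrix D, double hx, double hy, double hz) {
  List BL = hex_B_cpp(hx, hy, hz);
  NumericMatrix Bg = BL["Bg"];
  double w = BL["w"];
  NumericMatrix ke(24, 24);
  double BD[144];
  for (int g = 0; g < 8; g++) {
    const double* B = &Bg(0, g);
    for (int j = 0; j < 24; j++) {
      const double* Bc = B + 6 * j;
      for (int i = 0; i < 6; i++) {
        double s = 0.0;
        for (int k = 0; k < 6; k++) s += D(i, k) * Bc[k];
        BD[i + 6 * j] = s;
      }
    }
    for (int j = 0; j < 24; j++) {
      const double* BDc = BD + 6 * j;
      for (int i = 0; i < 24; i++) {
        const double* Bc = B + 6 * i;
        double s = 0.0;
        for (int k = 0; k < 6; k++) s += Bc[k] * BDc[k];
        ke(i, j) += s * w;
      }
    }
  }
  return ke;
}

static void apply_springs(const NumericMatrix& springs, const double* v,
                          double* out) {
  const int ns = springs.nrow();
  for (int s = 0; s < ns; s++) {
    if (springs(s, 7) == 0.0) continue;
    int ia = (int)springs(s, 0), ib = (int)springs(s, 1);
    double kn = springs(s, 2), kt = springs(s, 3);
    double n[3] = {springs(s, 4), springs(s, 5), springs(s, 6)};
    double rel[3], rn = 0.0;
    for (int c = 0; c < 3; c++) { rel[c] = v[3 * ia + c] - v[3 * ib + c]; }
    for (int c = 0; c < 3; c++) rn += rel[c] * n[c];
    for (int c = 0; c < 3; c++) {
      double f = kn * rn * n[c] + kt * (rel[c] - rn * n[c]);
      out[3 * ia + c] += f;
      out[3 * ib + c] -= f;
    }
  }
}

// Full K v (elements + active springs).
// [[Rcpp::export]]
NumericVector ebe_mul_cpp(IntegerMatrix edof24, IntegerVector keidx,
                          NumericMatrix kes, NumericMatrix springs,
                          NumericVector v) {
  const int nel = edof24.ncol();
  NumericVector out(v.size());
  double ue[24];
  for (int e = 0; e < nel; e++) {
    const int* ed = &edof24(0, e);
    const double* ke = &kes(0, keidx[e]);
    for (int j = 0; j < 24; j++) ue[j] = v[ed[j]];
    for (int i = 0; i < 24; i++) {
      double s = 0.0;
      for (int j = 0; j < 24; j++) s += ke[i + 24 * j] * ue[j];
      out[ed[i]] += s;
    }
  }
  apply_springs(springs, v.begin(), out.begin());
  return out;
}

// Jacobi-preconditioned CG on the free dofs.  `freemask` is 1 for free,
// 0 for fixed; the operator is P K P with P the mask projector.
// [[Rcpp::export]]
List ebe_pcg_cpp(IntegerMatrix edof24, IntegerVector keidx, NumericMatrix kes,
                 NumericMatrix springs, NumericVector b, NumericVector freemask,
                 NumericVector u0, double tol, int maxit) {
  const int nel = edof24.ncol();
  const int n = b.size();
  // diagonal
  std::vector<double> dg(n, 0.0);
  for (int e = 0; e < nel; e++) {
    const int* ed = &edof24(0, e);
    const double* ke = &kes(0, keidx[e]);
    for (int i = 0; i < 24; i++) dg[ed[i]] += ke[i + 24 * i];
  }
  for (int s = 0; s < springs.nrow(); s++) {
    if (springs(s, 7) == 0.0) continue;
    int ia = (int)springs(s, 0), ib = (int)springs(s, 1);
    double kn = springs(s, 2), kt = springs(s, 3);
    double nv[3] = {springs(s, 4), springs(s, 5), springs(s, 6)};
    for (int c = 0; c < 3; c++) {
      double kd = kn * nv[c] * nv[c] + kt * (1.0 - nv[c] * nv[c]);
      dg[3 * ia + c] += kd;
      dg[3 * ib + c] += kd;
    }
  }
  for (int i = 0; i < n; i++) if (dg[i] <= 0.0 || freemask[i] == 0.0) dg[i] = 1.0;

  std::vector<double> u(n), r(n), z(n), pv(n), q(n), tmp(n);
  for (int i = 0; i < n; i++) u[i] = u0[i] * freemask[i];
  double bnorm = 0.0;
  for (int i = 0; i < n; i++) bnorm += b[i] * b[i] * freemask[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    return List::create(_["u"] = NumericVector(n), _["iters"] = 0,
                        _["relres"] = 0.0, _["converged"] = true);
  }
  auto Kmul = [&](const std::vector<double>& x, std::vector<double>& y) {
    for (int i = 0; i < n; i++) tmp[i] = x[i] * freemask[i];
    for (int i = 0; i < n; i++) y[i] = 0.0;
    double ue[24];
    for (int e = 0; e < nel; e++) {
      const int* ed = &edof24(0, e);
      const double* ke = &kes(0, keidx[e]);
      for (int j = 0; j < 24; j++) ue[j] = tmp[ed[j]];
      for (int i = 0; i < 24; i++) {
        double s = 0.0;
        for (int j = 0; j < 24; j++) s += ke[i + 24 * j] * ue[j];
        y[ed[i]] += s;
      }
    }
    apply_springs(springs, tmp.data(), y.data());
    for (int i = 0; i < n; i++) y[i] *= freemask[i];
  };
  Kmul(u, q);
  double rz = 0.0;
  for (int i = 0; i < n; i++) {
    r[i] = (b[i] - q[i]) * freemask[i];
    z[i] = r[i] / dg[i];
    pv[i] = z[i];
    rz += r[i] * z[i];
  }
  double relres = 1.0;
  int it = 0;
  bool conv = false;
  for (it = 0; it < maxit; it++) {
    double rn = 0.0;
    for (int i = 0; i < n; i++) rn += r[i] * r[i];
    relres = std::sqrt(rn) / bnorm;
    if (relres < tol) { conv = true; break; }
    Kmul(pv, q);
    double pq = 0.0;
    for (int i = 0; i < n; i++) pq += pv[i] * q[i];
    if (pq <= 0.0) break;  // lost positive definiteness
    double alpha = rz / pq;
    for (int i = 0; i < n; i++) { u[i] += alpha * pv[i]; r[i] -= alpha * q[i]; }
    double rznew = 0.0;
    for (int i = 0; i < n; i++) { z[i] = r[i] / dg[i]; rznew += r[i] * z[i]; }
    double beta = rznew / rz;
    rz = rznew;
    for (int i = 0; i < n; i++) pv[i] = z[i] + beta * pv[i];
  }
  NumericVector uo(n);
  for (int i = 0; i < n; i++) uo[i] = u[i];
  return List::create(_["u"] = uo, _["iters"] = it, _["relres"] = relres,
                      _["converged"] = conv);
}

// Centroid strain/stress recovery for linear materials.
// Dmats: 36 x nmat (6x6 column-major per material), matidx 0-based per
// element, eps0 optional 6 x nel eigenstrain (pass 6 x 0 for none).
// [[Rcpp::export]]
List linear_stress_cpp(IntegerMatrix edof24, NumericVector u,
                       NumericMatrix Dmats, IntegerVector matidx,
                       NumericMatrix eps0, double hx, double hy, double hz) {
  const int nel = edof24.ncol();
  List BL = hex_B_cpp(hx, hy, hz);
  NumericMatrix Bc = BL["Bc"];
  NumericMatrix sig(6, nel), epsm(6, nel);
  NumericVector vm(nel);
  bool has0 = eps0.ncol() == nel;
  double ue[24], eps[6], s[6];
  for (int e = 0; e < nel; e++) {
    const int* ed = &edof24(0, e);
    for (int j = 0; j < 24; j++) ue[j] = u[ed[j]];
    for (int i = 0; i < 6; i++) eps[i] = 0.0;
    for (int j = 0; j < 24; j++)
      for (int i = 0; i < 6; i++) eps[i] += Bc(i, j) * ue[j];
    const double* D = &Dmats(0, matidx[e]);
    double ee[6];
    for (int i = 0; i < 6; i++)
      ee[i] = eps[i] - (has0 ? eps0(i, e) : 0.0);
    for (int i = 0; i < 6; i++) {
      double a = 0.0;
      for (int k = 0; k < 6; k++) a += D[i + 6 * k] * ee[k];
      s[i] = a;
    }
    for (int i = 0; i < 6; i++) { sig(i, e) = s[i]; epsm(i, e) = eps[i]; }
    double smn = (s[0] + s[1] + s[2]) / 3.0;
    double d0 = s[0] - smn, d1 = s[1] - smn, d2 = s[2] - smn;
    vm[e] = std::sqrt(0.5 * (3.0 * (d0 * d0 + d1 * d1 + d2 * d2))
                      + 3.0 * (s[3] * s[3] + s[4] * s[4] + s[5] * s[5]));
  }
  return List::create(_["sigma"] = sig, _["strain"] = epsm, _["vm"] = vm);
}

// Per-spring normal relative displacement and force for the current u.
// [[Rcpp::export]]
NumericMatrix spring_state_cpp(NumericMatrix springs, NumericVector u) {
  const int ns = springs.nrow();
  NumericMatrix out(ns, 2);  // columns: normal relative disp, normal force
  for (int s = 0; s < ns; s++) {
    int ia = (int)springs(s, 0), ib = (int)springs(s, 1);
    double n[3] = {springs(s, 4), springs(s, 5), springs(s, 6)};
    double rn = 0.0;
    for (int c = 0; c < 3; c++) rn += (u[3 * ia + c] - u[3 * ib + c]) * n[c];
    out(s, 0) = rn;
    out(s, 1) = springs(s, 7) != 0.0 ? springs(s, 2) * rn : 0.0;
  }
  return out;
}
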