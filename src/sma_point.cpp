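// Superelastic constitutive point model (small strain, 3D, von Mises driven).
//
// Phase-diagram model with linear transformation lines in stress-temperature
// space, Reuss mixing of the austenite/martensite moduli, and a radial
// return mapping on the martensite volume fraction xi.  Voigt convention
// throughout: (xx, yy, zz, xy, yz, xz) with engineering shear strains.
//
// Parameter vector `pars` (precomputed in R from SMAParams at T_op):
//   [0] E_A   austenite modulus (MPa)
//   [1] E_M   martensite modulus (MPa)
//   [2] nu    Poisson ratio
//   [3] H     maximum uniaxial transformation strain (-)
//   [4] sfs   forward (A->M) start stress (MPa)
//   [5] sff   forward finish stress (MPa)
//   [6] srs   reverse (M->A) start stress (MPa)
//   [7] srf   reverse finish stress (MPa)
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int MAX_RM_ITER = 50;     // return-mapping iteration cap
static const double RM_RTOL = 1e-8;    // relative tolerance on the plateau eq.

struct SmaPars {
  double EA, EM, nu, H, sfs, sff, srs, srf;
};

static inline SmaPars unpack(const double* p) {
  SmaPars s;
  s.EA = p[0]; s.EM = p[1]; s.nu = p[2]; s.H = p[3];
  s.sfs = p[4]; s.sff = p[5]; s.srs = p[6]; s.srf = p[7];
  return s;
}

// Reuss (series) mixture of phase moduli at fixed Poisson ratio.
static inline double mixE(const SmaPars& p, double xi) {
  return 1.0 / ((1.0 - xi) / p.EA + xi / p.EM);
}

// sigma = C(xi) : (eps - epst); eps, epst engineering Voigt.
static void elastic_stress(const SmaPars& p, double xi,
                           const double* eps, const double* epst,
                           double* sig) {
  double E = mixE(p, xi);
  double G = E / (2.0 * (1.0 + p.nu));
  double K = E / (3.0 * (1.0 - 2.0 * p.nu));
  double e[6];
  for (int i = 0; i < 6; i++) e[i] = eps[i] - epst[i];
  double vol = e[0] + e[1] + e[2];
  for (int i = 0; i < 3; i++) sig[i] = K * vol + 2.0 * G * (e[i] - vol / 3.0);
  for (int i = 3; i < 6; i++) sig[i] = G * e[i];
}

// Stress resolved along a (vm-unit, engineering-convention) transformation
// direction: the SIGNED equivalent stress.  For sigma deviatorically
// parallel to N this equals +-von Mises; using it in the plateau equations
// avoids the spurious root of the unsigned form where the transformation
// strain overshoots and the stress reverses sign.
static inline double resolved_stress(const double* sig, const double* N) {
  double sm = (sig[0] + sig[1] + sig[2]) / 3.0;
  return (sig[0] - sm) * N[0] + (sig[1] - sm) * N[1] + (sig[2] - sm) * N[2]
       + sig[3] * N[3] + sig[4] * N[4] + sig[5] * N[5];
}

static inline double von_mises(const double* sig) {
  double sm = (sig[0] + sig[1] + sig[2]) / 3.0;
  double s0 = sig[0] - sm, s1 = sig[1] - sm, s2 = sig[2] - sm;
  double j2 = 0.5 * (s0 * s0 + s1 * s1 + s2 * s2)
            + sig[3] * sig[3] + sig[4] * sig[4] + sig[5] * sig[5];
  return std::sqrt(3.0 * j2);
}

// Core update: given total strain and previous committed state, return the
// stress and the updated (trial) state.  Returns 0 on success.
static int sma_eval(const SmaPars& p, const double* eps,
                    double xi_n, const double* epst_n,
                    double* sig, double* xi_out, double* epst_out) {
  double sig_tr[6];
  elastic_stress(p, xi_n, eps, epst_n, sig_tr);
  double vm_tr = von_mises(sig_tr);
  double dsf = p.sff - p.sfs;
  double dsr = p.srs - p.srf;
  double tol = RM_RTOL * std::max(vm_tr, p.sfs);

  // Forward transformation (austenite -> stress-induced martensite).
  if (xi_n < 1.0 && vm_tr > p.sfs + dsf * xi_n + tol) {
    // Flow direction from the trial deviator (engineering components:
    // shears doubled so that epst acts as a strain vector).
    double sm = (sig_tr[0] + sig_tr[1] + sig_tr[2]) / 3.0;
    double N[6];
    if (vm_tr <= 0.0) return 1;
    N[0] = 1.5 * (sig_tr[0] - sm) / vm_tr;
    N[1] = 1.5 * (sig_tr[1] - sm) / vm_tr;
    N[2] = 1.5 * (sig_tr[2] - sm) / vm_tr;
    N[3] = 3.0 * sig_tr[3] / vm_tr;
    N[4] = 3.0 * sig_tr[4] / vm_tr;
    N[5] = 3.0 * sig_tr[5] / vm_tr;
    double lo = xi_n, hi = 1.0;
    double epst_x[6], sig_x[6];
    // f(xi) = resolved(sigma(xi)) - (sfs + dsf*xi); f(lo) > 0, monotone down.
    auto feval = [&](double x) {
      for (int i = 0; i < 6; i++) epst_x[i] = epst_n[i] + p.H * (x - xi_n) * N[i];
      elastic_stress(p, x, eps, epst_x, sig_x);
      return resolved_stress(sig_x, N) - (p.sfs + dsf * x);
    };
    double fhi = feval(hi);
    if (fhi >= 0.0) {
      // transformation completes; elastic martensite beyond
      *xi_out = 1.0;
      for (int i = 0; i < 6; i++) epst_out[i] = epst_x[i];
      for (int i = 0; i < 6; i++) sig[i] = sig_x[i];
      return 0;
    }
    double x = 0.5 * (lo + hi);
    for (int it = 0; it < MAX_RM_ITER; it++) {
      double fx = feval(x);
      if (std::fabs(fx) < tol) break;
      if (fx > 0.0) lo = x; else hi = x;
      x = 0.5 * (lo + hi);
      if (it == MAX_RM_ITER - 1 && hi - lo > 1e-10) return 2;
    }
    feval(x);
    *xi_out = x;
    for (int i = 0; i < 6; i++) epst_out[i] = epst_x[i];
    for (int i = 0; i < 6; i++) sig[i] = sig_x[i];
    return 0;
  }

  // Reverse transformation (unloading, martensite -> austenite).
  if (xi_n > 0.0 && vm_tr < p.srf + dsr * xi_n - tol) {
    double epst_x[6], sig_x[6];
    // reversal direction: along the accumulated transformation strain
    double Nr[6];
    double sc = p.H * xi_n;
    for (int i = 0; i < 6; i++) Nr[i] = epst_n[i] / sc;
    auto feval = [&](double x) {
      for (int i = 0; i < 6; i++) epst_x[i] = epst_n[i] * (x / xi_n);
      elastic_stress(p, x, eps, epst_x, sig_x);
      return resolved_stress(sig_x, Nr) - (p.srf + dsr * x);
    };
    double f0 = feval(0.0);
    if (f0 <= 0.0) {
      // full reversion to austenite
      *xi_out = 0.0;
      for (int i = 0; i < 6; i++) epst_out[i] = 0.0;
      elastic_stress(p, 0.0, eps, epst_out, sig);
      return 0;
    }
    double lo = 0.0, hi = xi_n;  // f(lo) > 0, f(hi) < 0
    double x = 0.5 * (lo + hi);
    for (int it = 0; it < MAX_RM_ITER; it++) {
      double fx = feval(x);
      if (std::fabs(fx) < tol) break;
      if (fx > 0.0) lo = x; else hi = x;
      x = 0.5 * (lo + hi);
      if (it == MAX_RM_ITER - 1 && hi - lo > 1e-10) return 2;
    }
    feval(x);
    *xi_out = x;
    for (int i = 0; i < 6; i++) epst_out[i] = epst_x[i];
    for (int i = 0; i < 6; i++) sig[i] = sig_x[i];
    return 0;
  }

  // Elastic branch.
  *xi_out = xi_n;
  for (int i = 0; i < 6; i++) epst_out[i] = epst_n[i];
  for (int i = 0; i < 6; i++) sig[i] = sig_tr[i];
  return 0;
}

// Algorithmic tangent by forward differences on the strain, symmetrized.
static void sma_tangent(const SmaPars& p, const double* eps,
                        double xi_n, const double* epst_n,
                        const double* sig0, double* D) {
  const double h = 1e-7;
  double epsp[6], sigp[6], xi_p, epst_p[6];
  for (int j = 0; j < 6; j++) {
    for (int i = 0; i < 6; i++) epsp[i] = eps[i];
    epsp[j] += h;
    sma_eval(p, epsp, xi_n, epst_n, sigp, &xi_p, epst_p);
    for (int i = 0; i < 6; i++) D[i + 6 * j] = (sigp[i] - sig0[i]) / h;
  }
  for (int i = 0; i < 6; i++)
    for (int j = i + 1; j < 6; j++) {
      double a = 0.5 * (D[i + 6 * j] + D[j + 6 * i]);
      D[i + 6 * j] = a; D[j + 6 * i] = a;
    }
}

//' @noRd
// [[Rcpp::export]]
List sma_point_cpp(NumericVector eps, double xi_n, NumericVector epst_n,
                   NumericVector pars, bool tangent = true) {
  SmaPars p = unpack(pars.begin());
  double sig[6], xi, epst[6];
  int err = sma_eval(p, eps.begin(), xi_n, epst_n.begin(), sig, &xi, epst);
  if (err != 0) stop("superelastic return mapping failed (code %d)", err);
  NumericVector sigv(6), epstv(6);
  for (int i = 0; i < 6; i++) { sigv[i] = sig[i]; epstv[i] = epst[i]; }
  List out = List::create(_["sigma"] = sigv, _["xi"] = xi, _["eps_t"] = epstv);
  if (tangent) {
    NumericMatrix D(6, 6);
    sma_tangent(p, eps.begin(), xi_n, epst_n.begin(), sig, D.begin());
    out["D"] = D;
  }
  return out;
}

// ---- FE-facing batch routine -------------------------------------------
// Gauss-point states are stored per element: xi (8 x nel), epst (48 x nel).
// B matrices for the 8 Gauss points of the voxel hexahedron are passed in
// as a 144 x 8 matrix (6x24 column-major per point) plus the weight.

// [[Rcpp::export]]
List sma_assemble_cpp(IntegerMatrix edof24, NumericVector u,
                      NumericMatrix xi_n, NumericMatrix epst_n,
                      NumericVector pars, NumericMatrix Bg, double wgt,
                      bool want_ke) {
  const int nel = edof24.ncol();
  const int ndof = u.size();
  SmaPars p = unpack(pars.begin());
  NumericVector fint(ndof);
  NumericMatrix xi_o(8, nel), epst_o(48, nel);
  NumericMatrix sigc(6, nel);
  NumericVector vmc(nel);
  NumericMatrix kes;
  if (want_ke) kes = NumericMatrix(576, nel);
  int errflag = 0;

  double ue[24], eps[6], sig[6], epst[6], xi, D[36], BD[144];
  for (int e = 0; e < nel; e++) {
    const int* ed = &edof24(0, e);
    for (int j = 0; j < 24; j++) ue[j] = u[ed[j]];
    double fe[24];
    for (int j = 0; j < 24; j++) fe[j] = 0.0;
    double* kep = want_ke ? &kes(0, e) : (double*)0;
    if (want_ke) for (int j = 0; j < 576; j++) kep[j] = 0.0;
    double sige[6] = {0, 0, 0, 0, 0, 0};
    for (int g = 0; g < 8; g++) {
      const double* B = &Bg(0, g);  // 6x24 column-major
      for (int i = 0; i < 6; i++) eps[i] = 0.0;
      for (int j = 0; j < 24; j++) {
        double uj = ue[j];
        const double* Bc = B + 6 * j;
        for (int i = 0; i < 6; i++) eps[i] += Bc[i] * uj;
      }
      int err = sma_eval(p, eps, xi_n(g, e), &epst_n(6 * g, e), sig, &xi, epst);
      if (err != 0) { errflag = err; }
      xi_o(g, e) = xi;
      for (int i = 0; i < 6; i++) epst_o(6 * g + i, e) = epst[i];
      for (int i = 0; i < 6; i++) sige[i] += 0.125 * sig[i];
      // f_e += B' sigma w
      for (int j = 0; j < 24; j++) {
        const double* Bc = B + 6 * j;
        double s = 0.0;
        for (int i = 0; i < 6; i++) s += Bc[i] * sig[i];
        fe[j] += s * wgt;
      }
      if (want_ke) {
        sma_tangent(p, eps, xi_n(g, e), &epst_n(6 * g, e), sig, D);
        // BD = D * B (6x24)
        for (int j = 0; j < 24; j++) {
          const double* Bc = B + 6 * j;
          for (int i = 0; i < 6; i++) {
            double s = 0.0;
            for (int k = 0; k < 6; k++) s += D[i + 6 * k] * Bc[k];
            BD[i + 6 * j] = s;
          }
        }
        // ke += B' * BD * w
        for (int j = 0; j < 24; j++) {
          const double* BDc = BD + 6 * j;
          for (int i = 0; i < 24; i++) {
            const double* Bc = B + 6 * i;
            double s = 0.0;
            for (int k = 0; k < 6; k++) s += Bc[k] * BDc[k];
            kep[i + 24 * j] += s * wgt;
          }
        }
      }
    }
    for (int i = 0; i < 6; i++) sigc(i, e) = sige[i];
    vmc[e] = von_mises(sige);
    for (int j = 0; j < 24; j++) fint[ed[j]] += fe[j];
  }
  List out = List::create(_["fint"] = fint, _["xi"] = xi_o, _["eps_t"] = epst_o,
                          _["sigma_c"] = sigc, _["vm_c"] = vmc,
                          _["err"] = errflag);
  if (want_ke) out["kes"] = kes;
  return out;
}
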