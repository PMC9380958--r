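#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Unsteady kinematic turbulence evaluated from its vector potential.
//
// The field is u = curl( g(z) * A0(x, t) ) with
//   A0 = sum_n [ c_n cos(phi_n) + d_n sin(phi_n) ],  phi_n = k_n . x + w_n t + chi_n,
// and c_n, d_n perpendicular to k_n. Because u is a curl it is exactly
// divergence-free, envelope included. Expanding,
//   u = g(z) u0 + g'(z) (zhat x A0),   u0 = sum_n [ (k_n x d_n) cos - (k_n x c_n) sin ]
// and the vorticity follows analytically:
//   w = g sum k^2 (c cos + d sin) + g' (zhat x u0)
//       + g' sum k_z (c sin - d cos) + g'' (zhat x (zhat x A0)).
// (With c, d perpendicular to k, div A0 = 0, which removes the grad(div) term.)

// Depth envelope g(z) = S(s) * L(z): a C2 quintic smoothstep ramp S rising
// from exactly 0 below z_lo to 1 above z_hi (the density-interface
// transition), times a linear tilt L that declines from 1 at the surface to
// (1 - beta) at z_lo, mimicking the monotone decay of turbulent kinetic
// energy with depth in a surface-cooled mixed layer. g(Lz) = 1 exactly and
// g = g' = g'' = 0 below z_lo (quiescent deep water).
struct Env {
  double zlo, zhi, beta, Lz;
  void eval(double z, double& g, double& gp, double& gpp) const {
    double h = zhi - zlo;
    double s = (z - zlo) / h;
    double S, Sp, Spp;
    if (s <= 0.0) { S = Sp = Spp = 0.0; }
    else if (s >= 1.0) { S = 1.0; Sp = Spp = 0.0; }
    else {
      S = ((6.0 * s - 15.0) * s + 10.0) * s * s * s;
      Sp = ((30.0 * s - 60.0) * s + 30.0) * s * s / h;
      Spp = ((120.0 * s - 180.0) * s + 60.0) * s / (h * h);
    }
    double L = 1.0 - beta * (Lz - z) / (Lz - zlo);
    double Lp = beta / (Lz - zlo);
    g = S * L;
    gp = Sp * L + S * Lp;
    gpp = Spp * L + 2.0 * Sp * Lp;
  }
};

// [[Rcpp::export]]
List kin_eval_cpp(NumericMatrix X, double t,
                  NumericMatrix K, NumericMatrix C, NumericMatrix D,
                  NumericMatrix KxC, NumericMatrix KxD,
                  NumericVector k2, NumericVector kz, NumericVector omega,
                  NumericVector chi,
                  double z_lo, double z_hi, double beta, double Lz,
                  bool want_vorticity) {
  const int n = X.nrow();
  const int m = K.nrow();
  const Env env = {z_lo, z_hi, beta, Lz};

  NumericMatrix U(n, 3);
  NumericMatrix W(want_vorticity ? n : 1, 3);

  const double* __restrict px = &X(0, 0);
  const double* __restrict py = px + n;
  const double* __restrict pz = py + n;

  // per-point accumulators, contiguous so the point loop vectorises
  std::vector<double> buf((want_vorticity ? 12 : 5) * (size_t)n, 0.0);
  double* __restrict A0x = buf.data();
  double* __restrict A0y = A0x + n;
  double* __restrict u0x = A0y + n;
  double* __restrict u0y = u0x + n;
  double* __restrict u0z = u0y + n;
  double* __restrict A0z = want_vorticity ? u0z + n : nullptr;
  double* __restrict cvx = want_vorticity ? A0z + n : nullptr;
  double* __restrict cvy = want_vorticity ? cvx + n : nullptr;
  double* __restrict cvz = want_vorticity ? cvy + n : nullptr;
  double* __restrict sdx = want_vorticity ? cvz + n : nullptr;
  double* __restrict sdy = want_vorticity ? sdx + n : nullptr;
  double* __restrict sdz = want_vorticity ? sdy + n : nullptr;

  for (int j = 0; j < m; ++j) {
    const double kx = K(j, 0), ky = K(j, 1), kzj = K(j, 2);
    const double off = omega[j] * t + chi[j];
    const double Cx = C(j, 0), Cy = C(j, 1), Cz = C(j, 2);
    const double Dx = D(j, 0), Dy = D(j, 1), Dz = D(j, 2);
    const double KxCx = KxC(j, 0), KxCy = KxC(j, 1), KxCz = KxC(j, 2);
    const double KxDx = KxD(j, 0), KxDy = KxD(j, 1), KxDz = KxD(j, 2);
    const double k2j = k2[j], kzz = kz[j];
    if (want_vorticity) {
      for (int i = 0; i < n; ++i) {
        const double ph = kx * px[i] + ky * py[i] + kzj * pz[i] + off;
        const double cp = std::cos(ph), sp = std::sin(ph);
        A0x[i] += Cx * cp + Dx * sp;
        A0y[i] += Cy * cp + Dy * sp;
        A0z[i] += Cz * cp + Dz * sp;
        u0x[i] += KxDx * cp - KxCx * sp;
        u0y[i] += KxDy * cp - KxCy * sp;
        u0z[i] += KxDz * cp - KxCz * sp;
        cvx[i] += k2j * (Cx * cp + Dx * sp);
        cvy[i] += k2j * (Cy * cp + Dy * sp);
        cvz[i] += k2j * (Cz * cp + Dz * sp);
        sdx[i] += kzz * (Cx * sp - Dx * cp);
        sdy[i] += kzz * (Cy * sp - Dy * cp);
        sdz[i] += kzz * (Cz * sp - Dz * cp);
      }
    } else {
      for (int i = 0; i < n; ++i) {
        const double ph = kx * px[i] + ky * py[i] + kzj * pz[i] + off;
        const double cp = std::cos(ph), sp = std::sin(ph);
        A0x[i] += Cx * cp + Dx * sp;
        A0y[i] += Cy * cp + Dy * sp;
        u0x[i] += KxDx * cp - KxCx * sp;
        u0y[i] += KxDy * cp - KxCy * sp;
        u0z[i] += KxDz * cp - KxCz * sp;
      }
    }
  }

  for (int i = 0; i < n; ++i) {
    double g, gp, gpp;
    env.eval(pz[i], g, gp, gpp);
    // u = g u0 + g' (zhat x A0); zhat x v = (-v_y, v_x, 0)
    U(i, 0) = g * u0x[i] - gp * A0y[i];
    U(i, 1) = g * u0y[i] + gp * A0x[i];
    U(i, 2) = g * u0z[i];
    if (want_vorticity) {
      W(i, 0) = g * cvx[i] - gp * u0y[i] + gp * sdx[i] - gpp * A0x[i];
      W(i, 1) = g * cvy[i] + gp * u0x[i] + gp * sdy[i] - gpp * A0y[i];
      W(i, 2) = g * cvz[i] + gp * sdz[i];
    }
  }
  if (want_vorticity) return List::create(_["u"] = U, _["w"] = W);
  return List::create(_["u"] = U);
}
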