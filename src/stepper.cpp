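#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Compiled stepping kernel for the microbe IBM: advances an ensemble by
// n_steps of (Euler orientation update from the vorticity at the pre-step
// position) then (RK4 position update with the orientation frozen) then
// (periodic wrap in x/y, reflection at the z walls). Supports the flow
// families evaluated in closed form -- uniform, Taylor-Green, and the
// kinematic turbulence modes -- and mirrors the reference R implementation
// of the same scheme.

struct KinField {
  int m;
  const double *kx, *ky, *kz, *cx, *cy, *cz, *dx, *dy, *dz;
  const double *kxcx, *kxcy, *kxcz, *kxdx, *kxdy, *kxdz;
  const double *k2, *kzv, *om, *chi;
  double z_lo, z_hi, beta, Lz;
};

static inline void env_eval(const KinField& f, double z, double& g, double& gp, double& gpp) {
  double h = f.z_hi - f.z_lo;
  double s = (z - f.z_lo) / h;
  double S, Sp, Spp;
  if (s <= 0.0) { S = Sp = Spp = 0.0; }
  else if (s >= 1.0) { S = 1.0; Sp = Spp = 0.0; }
  else {
    S = ((6.0 * s - 15.0) * s + 10.0) * s * s * s;
    Sp = ((30.0 * s - 60.0) * s + 30.0) * s * s / h;
    Spp = ((120.0 * s - 180.0) * s + 60.0) * s / (h * h);
  }
  double L = 1.0 - f.beta * (f.Lz - z) / (f.Lz - f.z_lo);
  double Lp = f.beta / (f.Lz - f.z_lo);
  g = S * L; gp = Sp * L + S * Lp; gpp = Spp * L + 2.0 * Sp * Lp;
}

// velocity (and optionally vorticity) of the kinematic field at one point
static inline void kin_point(const KinField& f, double x, double y, double z,
                             double t, double* u, double* w) {
  double A0x = 0, A0y = 0, u0x = 0, u0y = 0, u0z = 0;
  double cvx = 0, cvy = 0, cvz = 0, sdx = 0, sdy = 0, sdz = 0;
  for (int j = 0; j < f.m; ++j) {
    double ph = f.kx[j] * x + f.ky[j] * y + f.kz[j] * z + f.om[j] * t + f.chi[j];
    double cp = std::cos(ph), sp = std::sin(ph);
    A0x += f.cx[j] * cp + f.dx[j] * sp;
    A0y += f.cy[j] * cp + f.dy[j] * sp;
    u0x += f.kxdx[j] * cp - f.kxcx[j] * sp;
    u0y += f.kxdy[j] * cp - f.kxcy[j] * sp;
    u0z += f.kxdz[j] * cp - f.kxcz[j] * sp;
    if (w) {
      cvx += f.k2[j] * (f.cx[j] * cp + f.dx[j] * sp);
      cvy += f.k2[j] * (f.cy[j] * cp + f.dy[j] * sp);
      cvz += f.k2[j] * (f.cz[j] * cp + f.dz[j] * sp);
      sdx += f.kzv[j] * (f.cx[j] * sp - f.dx[j] * cp);
      sdy += f.kzv[j] * (f.cy[j] * sp - f.dy[j] * cp);
      sdz += f.kzv[j] * (f.cz[j] * sp - f.dz[j] * cp);
    }
  }
  double g, gp, gpp;
  env_eval(f, z, g, gp, gpp);
  u[0] = g * u0x - gp * A0y;
  u[1] = g * u0y + gp * A0x;
  u[2] = g * u0z;
  if (w) {
    w[0] = g * cvx - gp * u0y + gp * sdx - gpp * A0x;
    w[1] = g * cvy + gp * u0x + gp * sdy - gpp * A0y;
    w[2] = g * cvz + gp * sdz;
  }
}

// [[Rcpp::export]]
List step_ensemble_cpp(NumericMatrix X, NumericMatrix P,
                       int field_type, List field_params,
                       int mot_mode,  // 0 non_motile, 1 gyrotactic, 2 non_gyrotactic
                       double B, double v_swim,
                       double t0, double dt, int n_steps,
                       double Lx, double Ly, double Lz) {
  const int n = X.nrow();
  NumericMatrix Xo(clone(X)), Po(clone(P));

  double uni[3] = {0, 0, 0};
  double tgU = 0, tgK = 0;
  KinField kf = {};
  NumericMatrix Km, Cm, Dm, KxCm, KxDm;
  NumericVector k2v, kzv2, omv, chiv;
  if (field_type == 0) {
    NumericVector U = field_params["U"];
    uni[0] = U[0]; uni[1] = U[1]; uni[2] = U[2];
  } else if (field_type == 1) {
    tgU = as<double>(field_params["U"]);
    tgK = as<double>(field_params["kappa"]);
  } else {
    Km = as<NumericMatrix>(field_params["K"]);
    Cm = as<NumericMatrix>(field_params["C"]);
    Dm = as<NumericMatrix>(field_params["D"]);
    KxCm = as<NumericMatrix>(field_params["KxC"]);
    KxDm = as<NumericMatrix>(field_params["KxD"]);
    k2v = as<NumericVector>(field_params["k2"]);
    kzv2 = as<NumericVector>(field_params["kz"]);
    omv = as<NumericVector>(field_params["omega"]);
    chiv = as<NumericVector>(field_params["chi"]);
    kf.m = Km.nrow();
    kf.kx = &Km(0, 0); kf.ky = kf.kx + kf.m; kf.kz = kf.ky + kf.m;
    kf.cx = &Cm(0, 0); kf.cy = kf.cx + kf.m; kf.cz = kf.cy + kf.m;
    kf.dx = &Dm(0, 0); kf.dy = kf.dx + kf.m; kf.dz = kf.dy + kf.m;
    kf.kxcx = &KxCm(0, 0); kf.kxcy = kf.kxcx + kf.m; kf.kxcz = kf.kxcy + kf.m;
    kf.kxdx = &KxDm(0, 0); kf.kxdy = kf.kxdx + kf.m; kf.kxdz = kf.kxdy + kf.m;
    kf.k2 = &k2v[0]; kf.kzv = &kzv2[0]; kf.om = &omv[0]; kf.chi = &chiv[0];
    kf.z_lo = as<double>(field_params["z_lo"]);
    kf.z_hi = as<double>(field_params["z_hi"]);
    kf.beta = as<double>(field_params["beta"]);
    kf.Lz = as<double>(field_params["Lz"]);
  }

  auto velocity = [&](double x, double y, double z, double t, double* u) {
    if (field_type == 0) { u[0] = uni[0]; u[1] = uni[1]; u[2] = uni[2]; }
    else if (field_type == 1) {
      u[0] = tgU * std::sin(tgK * x) * std::cos(tgK * z);
      u[1] = 0.0;
      u[2] = -tgU * std::cos(tgK * x) * std::sin(tgK * z);
    } else kin_point(kf, x, y, z, t, u, nullptr);
  };
  auto vel_vort = [&](double x, double y, double z, double t, double* u, double* w) {
    if (field_type == 0) {
      u[0] = uni[0]; u[1] = uni[1]; u[2] = uni[2];
      w[0] = w[1] = w[2] = 0.0;
    } else if (field_type == 1) {
      double sx = std::sin(tgK * x), cx = std::cos(tgK * x);
      double sz = std::sin(tgK * z), cz = std::cos(tgK * z);
      u[0] = tgU * sx * cz; u[1] = 0.0; u[2] = -tgU * cx * sz;
      w[0] = 0.0; w[1] = -2.0 * tgU * tgK * sx * sz; w[2] = 0.0;
    } else kin_point(kf, x, y, z, t, u, w);
  };

  for (int s = 0; s < n_steps; ++s) {
    const double t = t0 + s * dt;
    for (int i = 0; i < n; ++i) {
      double x = Xo(i, 0), y = Xo(i, 1), z = Xo(i, 2);
      double px = Po(i, 0), py = Po(i, 1), pz = Po(i, 2);
      double u[3], w[3];

      if (mot_mode != 0) {
        vel_vort(x, y, z, t, u, w);
        // dp = (omega x p)/2 (+ gyrotactic restoring term)
        double dpx = 0.5 * (w[1] * pz - w[2] * py);
        double dpy = 0.5 * (w[2] * px - w[0] * pz);
        double dpz = 0.5 * (w[0] * py - w[1] * px);
        if (mot_mode == 1) {
          dpx += (-pz * px) / (2.0 * B);
          dpy += (-pz * py) / (2.0 * B);
          dpz += (1.0 - pz * pz) / (2.0 * B);
        }
        px += dt * dpx; py += dt * dpy; pz += dt * dpz;
        double nrm = std::sqrt(px * px + py * py + pz * pz);
        px /= nrm; py /= nrm; pz /= nrm;
        Po(i, 0) = px; Po(i, 1) = py; Po(i, 2) = pz;
      } else {
        velocity(x, y, z, t, u);
      }
      const double sx = v_swim * px, sy = v_swim * py, sz = v_swim * pz;
      // RK4 with the orientation frozen; k1 reuses the pre-step velocity
      double k1[3] = {u[0] + sx, u[1] + sy, u[2] + sz};
      double u2[3], u3[3], u4[3];
      velocity(x + 0.5 * dt * k1[0], y + 0.5 * dt * k1[1], z + 0.5 * dt * k1[2],
               t + 0.5 * dt, u2);
      double k2s[3] = {u2[0] + sx, u2[1] + sy, u2[2] + sz};
      velocity(x + 0.5 * dt * k2s[0], y + 0.5 * dt * k2s[1], z + 0.5 * dt * k2s[2],
               t + 0.5 * dt, u3);
      double k3[3] = {u3[0] + sx, u3[1] + sy, u3[2] + sz};
      velocity(x + dt * k3[0], y + dt * k3[1], z + dt * k3[2], t + dt, u4);
      double k4[3] = {u4[0] + sx, u4[1] + sy, u4[2] + sz};
      x += dt / 6.0 * (k1[0] + 2 * k2s[0] + 2 * k3[0] + k4[0]);
      y += dt / 6.0 * (k1[1] + 2 * k2s[1] + 2 * k3[1] + k4[1]);
      z += dt / 6.0 * (k1[2] + 2 * k2s[2] + 2 * k3[2] + k4[2]);

      // boundaries: periodic x/y, reflective z
      if (z > 2 * Lz || z < -Lz || !std::isfinite(x + y + z))
        stop("non-finite or out-of-range position at step %d, microbe %d (timestep too large?)",
             s + 1, i + 1);
      x -= Lx * std::floor(x / Lx);
      y -= Ly * std::floor(y / Ly);
      if (z < 0) z = -z;
      if (z > Lz) z = 2 * Lz - z;
      Xo(i, 0) = x; Xo(i, 1) = y; Xo(i, 2) = z;
    }
  }
  return List::create(_["X"] = Xo, _["P"] = Po);
}
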