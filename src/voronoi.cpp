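#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 3D Voronoi cell volumes with horizontal periodicity and planar walls at
// z = 0 and z = Lz. Each generator's cell starts as a box (half the domain
// period in each periodic direction, the full wall-to-wall slab in z) and is
// clipped by the perpendicular bisector plane of every nearby generator
// (minimal-image displacement; for small N all 9 horizontal images are
// used). Neighbours are visited in order of increasing distance and the
// clipping loop stops once no remaining bisector can reach the cell
// (d/2 > max vertex distance) -- the same strategy as Voro++.

typedef std::array<double, 3> V3;

static inline V3 sub(const V3& a, const V3& b) { return {a[0]-b[0], a[1]-b[1], a[2]-b[2]}; }
static inline V3 cross(const V3& a, const V3& b) {
  return {a[1]*b[2]-a[2]*b[1], a[2]*b[0]-a[0]*b[2], a[0]*b[1]-a[1]*b[0]};
}
static inline double dot(const V3& a, const V3& b) { return a[0]*b[0]+a[1]*b[1]+a[2]*b[2]; }
static inline double nrm2(const V3& a) { return dot(a, a); }

struct Poly {
  std::vector<std::vector<V3>> faces;  // outward winding
};

static double poly_volume(const Poly& P) {
  double v = 0.0;
  for (const auto& f : P.faces) {
    if (f.size() < 3) continue;
    for (size_t i = 1; i + 1 < f.size(); ++i) {
      v += dot(f[0], cross(f[i], f[i + 1]));
    }
  }
  return v / 6.0;
}

static double max_vertex_dist2(const Poly& P, const V3& g) {
  double r2 = 0.0;
  for (const auto& f : P.faces)
    for (const auto& v : f) r2 = std::max(r2, nrm2(sub(v, g)));
  return r2;
}

// clip P by half-space dot(n, x) <= c; returns false if cell untouched
// (the common case, detected without rebuilding the polyhedron)
static bool clip(Poly& P, const V3& n, double c, double tol) {
  bool touched = false;
  for (const auto& f : P.faces) {
    for (const auto& v : f)
      if (dot(n, v) - c > tol) { touched = true; break; }
    if (touched) break;
  }
  if (!touched) return false;
  std::vector<std::vector<V3>> out;
  out.reserve(P.faces.size() + 1);
  std::vector<V3> capPts;
  capPts.reserve(8);
  bool any_cut = false;
  for (auto& f : P.faces) {
    const size_t m = f.size();
    bool any_out = false;
    for (size_t i = 0; i < m; ++i)
      if (dot(n, f[i]) - c > tol) { any_out = true; break; }
    if (!any_out) { out.push_back(std::move(f)); continue; }
    std::vector<V3> nf;
    nf.reserve(m + 2);
    for (size_t i = 0; i < m; ++i) {
      const V3& a = f[i];
      const V3& b = f[(i + 1) % m];
      double da = dot(n, a) - c;
      double db = dot(n, b) - c;
      bool ina = da <= tol, inb = db <= tol;
      if (ina) nf.push_back(a);
      if (ina != inb) {
        double s = da / (da - db);
        V3 p = {a[0] + s * (b[0] - a[0]), a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2])};
        nf.push_back(p);
        capPts.push_back(p);
        any_cut = true;
      }
    }
    if (nf.size() >= 3) out.push_back(std::move(nf));
  }
  if (!any_cut) {
    // plane passed exactly through vertices/edges; keep surviving faces
    P.faces = std::move(out);
    return true;
  }
  // build closing face on the plane from unique cap points, ordered CCW about n
  std::vector<V3> uniq;
  for (const auto& p : capPts) {
    bool found = false;
    for (const auto& q : uniq)
      if (nrm2(sub(p, q)) < tol * tol * 1e4) { found = true; break; }
    if (!found) uniq.push_back(p);
  }
  if (uniq.size() >= 3) {
    V3 cen = {0, 0, 0};
    for (const auto& p : uniq) { cen[0] += p[0]; cen[1] += p[1]; cen[2] += p[2]; }
    for (int k = 0; k < 3; ++k) cen[k] /= uniq.size();
    // in-plane orthonormal basis
    V3 e1 = std::fabs(n[0]) < 0.9 ? V3{1, 0, 0} : V3{0, 1, 0};
    double pr = dot(e1, n);
    for (int k = 0; k < 3; ++k) e1[k] -= pr * n[k];
    double l1 = std::sqrt(nrm2(e1));
    for (int k = 0; k < 3; ++k) e1[k] /= l1;
    V3 e2 = cross(n, e1);
    std::sort(uniq.begin(), uniq.end(), [&](const V3& a, const V3& b) {
      V3 ra = sub(a, cen), rb = sub(b, cen);
      return std::atan2(dot(ra, e2), dot(ra, e1)) < std::atan2(dot(rb, e2), dot(rb, e1));
    });
    out.push_back(std::move(uniq));
  }
  if (out.empty()) { P.faces.clear(); return false; }
  P.faces = std::move(out);
  return true;
}

static Poly init_box(double x0, double x1, double y0, double y1, double z0, double z1) {
  V3 a = {x0, y0, z0}, b = {x1, y0, z0}, c = {x1, y1, z0}, d = {x0, y1, z0};
  V3 e = {x0, y0, z1}, f = {x1, y0, z1}, g = {x1, y1, z1}, h = {x0, y1, z1};
  Poly P;
  P.faces = {
    {a, d, c, b},  // bottom, outward -z
    {e, f, g, h},  // top, outward +z
    {a, b, f, e},  // y = y0, outward -y
    {c, d, h, g},  // y = y1, outward +y
    {a, e, h, d},  // x = x0, outward -x
    {b, c, g, f}   // x = x1, outward +x
  };
  return P;
}

struct Cand { double d2; V3 d; };

// [[Rcpp::export]]
NumericVector voro_volumes_cpp(NumericMatrix X, double Lx, double Ly, double Lz,
                               bool periodic_x, bool periodic_y) {
  const int N = X.nrow();
  NumericVector vol(N);
  const double scale = std::max(Lx, std::max(Ly, Lz));
  const double tol = 1e-12 * scale;

  // bin the generators (only used for large N)
  const bool brute = N < 64;
  int nbx = 1, nby = 1, nbz = 1;
  std::vector<std::vector<int>> bins;
  double bsx = Lx, bsy = Ly, bsz = Lz;
  if (!brute) {
    double target = std::cbrt(Lx * Ly * Lz / std::max(1.0, N / 2.0));
    nbx = std::max(1, (int)std::floor(Lx / target));
    nby = std::max(1, (int)std::floor(Ly / target));
    nbz = std::max(1, (int)std::floor(Lz / target));
    bsx = Lx / nbx; bsy = Ly / nby; bsz = Lz / nbz;
    bins.assign((size_t)nbx * nby * nbz, {});
    for (int i = 0; i < N; ++i) {
      int ix = std::min(nbx - 1, (int)(X(i, 0) / bsx));
      int iy = std::min(nby - 1, (int)(X(i, 1) / bsy));
      int iz = std::min(nbz - 1, (int)(X(i, 2) / bsz));
      bins[(size_t)(iz * nby + iy) * nbx + ix].push_back(i);
    }
  }
  const double bmin = std::min(bsx, std::min(bsy, bsz));
  const int max_shell = std::max(nbx, std::max(nby, nbz));
  std::vector<char> visited;
  if (!brute) visited.assign(bins.size(), 0);

  for (int i = 0; i < N; ++i) {
    const V3 gi = {X(i, 0), X(i, 1), X(i, 2)};
    double hx = periodic_x ? Lx / 2.0 : 0.0;
    double hy = periodic_y ? Ly / 2.0 : 0.0;
    Poly P = init_box(periodic_x ? gi[0] - hx : 0.0, periodic_x ? gi[0] + hx : Lx,
                      periodic_y ? gi[1] - hy : 0.0, periodic_y ? gi[1] + hy : Ly,
                      0.0, Lz);
    double r2 = max_vertex_dist2(P, gi);

    std::vector<Cand> cands;
    cands.reserve(64);
    auto add_cand = [&](int j) {
      if (j == i) return;
      if (brute) {
        // all horizontal images
        int mx = periodic_x ? 1 : 0, my = periodic_y ? 1 : 0;
        for (int sx = -mx; sx <= mx; ++sx)
          for (int sy = -my; sy <= my; ++sy) {
            V3 d = {X(j, 0) + sx * Lx - gi[0], X(j, 1) + sy * Ly - gi[1], X(j, 2) - gi[2]};
            double d2 = nrm2(d);
            if (d2 < tol * tol)
              stop("duplicate generator positions (points %d and %d)", i + 1, j + 1);
            cands.push_back({d2, d});
          }
      } else {
        V3 d = {X(j, 0) - gi[0], X(j, 1) - gi[1], X(j, 2) - gi[2]};
        if (periodic_x) d[0] -= Lx * std::round(d[0] / Lx);
        if (periodic_y) d[1] -= Ly * std::round(d[1] / Ly);
        double d2 = nrm2(d);
        if (d2 < tol * tol)
          stop("duplicate generator positions (points %d and %d)", i + 1, j + 1);
        // a bisector at d/2 beyond the current cell radius can never cut
        // (the cell only shrinks as clipping proceeds)
        if (d2 / 4.0 <= r2) cands.push_back({d2, d});
      }
    };

    auto clip_cands = [&](size_t from) {
      std::sort(cands.begin() + from, cands.end(),
                [](const Cand& a, const Cand& b) { return a.d2 < b.d2; });
      for (size_t k = from; k < cands.size(); ++k) {
        if (cands[k].d2 / 4.0 > r2) break;
        double dlen = std::sqrt(cands[k].d2);
        V3 n = {cands[k].d[0] / dlen, cands[k].d[1] / dlen, cands[k].d[2] / dlen};
        double c = dot(n, gi) + dlen / 2.0;
        if (clip(P, n, c, tol)) r2 = max_vertex_dist2(P, gi);
      }
    };

    if (brute) {
      for (int j = 0; j < N; ++j) add_cand(j);
      clip_cands(0);
    } else {
      int cix = std::min(nbx - 1, (int)(gi[0] / bsx));
      int ciy = std::min(nby - 1, (int)(gi[1] / bsy));
      int ciz = std::min(nbz - 1, (int)(gi[2] / bsz));
      std::vector<size_t> touched;
      for (int shell = 0; shell <= max_shell; ++shell) {
        if (shell > 1 && (shell - 1) * bmin / 2.0 > std::sqrt(r2)) break;
        size_t from = cands.size();
        bool any_bin = false;
        for (int dz = -shell; dz <= shell; ++dz) {
          int iz = ciz + dz;
          if (iz < 0 || iz >= nbz) continue;
          for (int dy = -shell; dy <= shell; ++dy) {
            for (int dx = -shell; dx <= shell; ++dx) {
              if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != shell)
                continue;
              int ix = cix + dx, iy = ciy + dy;
              if (periodic_x) ix = ((ix % nbx) + nbx) % nbx;
              else if (ix < 0 || ix >= nbx) continue;
              if (periodic_y) iy = ((iy % nby) + nby) % nby;
              else if (iy < 0 || iy >= nby) continue;
              if (std::abs(dx) >= nbx || std::abs(dy) >= nby) continue;
              size_t bi = (size_t)(iz * nby + iy) * nbx + ix;
              if (visited[bi]) continue;  // wrapped shells can revisit bins
              visited[bi] = 1;
              touched.push_back(bi);
              any_bin = true;
              for (int j : bins[bi]) add_cand(j);
            }
          }
        }
        if (cands.size() > from) clip_cands(from);
        if (!any_bin && shell > 0 && shell >= max_shell) break;
      }
      for (size_t bi : touched) visited[bi] = 0;
    }
    vol[i] = poly_volume(P);
  }
  return vol;
}
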