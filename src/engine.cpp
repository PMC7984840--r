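// Core simulator for the PSM/tailbud segmentation-clock model.
//
// Cells are particles in a U-shaped domain (two tubes joined by a half torus)
// obeying an overdamped equation of motion (advection + intrinsic motility +
// soft pairwise repulsion + boundary confinement) and carrying a phase
// oscillator with local Kuramoto coupling, a frequency profile and white noise.
// Integration is Euler-Maruyama at a fixed time step. All randomness comes from
// counter-seeded xoshiro256++ streams, one per noise channel, so runs are
// bit-reproducible for a given seed and toggling one noise source does not
// shift the draws of another.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double PC_TWO_PI = 6.28318530717958647692528676656;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ with splitmix64 seeding (platform-independent streams)
// ---------------------------------------------------------------------------

static inline uint64_t pc_splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct PcRng {
  uint64_t s[4];
  bool has_gauss;
  double gauss2;

  void seed(uint64_t sd, uint64_t stream) {
    uint64_t x = sd * 0x9E3779B97F4A7C15ULL + stream * 0xD1B54A32D192ED03ULL + 1ULL;
    for (int i = 0; i < 4; ++i) s[i] = pc_splitmix64(x);
    has_gauss = false;
    gauss2 = 0.0;
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 1.1102230246251565e-16; } // [0,1)
  inline double gauss() {                                    // Marsaglia polar
    if (has_gauss) { has_gauss = false; return gauss2; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    gauss2 = v * f;
    has_gauss = true;
    return u * f;
  }
};

// deterministic unit vector from a pair of ids (coincident-cell tie break)
static inline void pc_hash_unit(uint64_t a, uint64_t b, uint64_t c, double out[3]) {
  uint64_t x = (a + 1ULL) * 0x9E3779B97F4A7C15ULL ^ (b + 1ULL) * 0xD1B54A32D192ED03ULL ^ c;
  double u = (pc_splitmix64(x) >> 11) * 1.1102230246251565e-16;
  double v = (pc_splitmix64(x) >> 11) * 1.1102230246251565e-16;
  double ct = 2.0 * u - 1.0;
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double ph = PC_TWO_PI * v;
  out[0] = st * std::cos(ph);
  out[1] = st * std::sin(ph);
  out[2] = ct;
}

static inline double pc_wrap2pi(double a) {
  a -= PC_TWO_PI * std::floor(a / PC_TWO_PI);
  if (a >= PC_TWO_PI) a -= PC_TWO_PI;
  if (a < 0.0) a = 0.0;
  return a;
}

// ---------------------------------------------------------------------------
// Geometry
// ---------------------------------------------------------------------------

struct PcGeom {
  double r0, R, Xc, Yc, Zc, Lx;
};

static PcGeom pc_geom_from_list(List g) {
  PcGeom gm;
  gm.r0 = as<double>(g["r0"]);
  gm.R  = as<double>(g["R"]);
  gm.Xc = as<double>(g["Xc"]);
  gm.Yc = as<double>(g["Yc"]);
  gm.Zc = as<double>(g["Zc"]);
  gm.Lx = as<double>(g["Lx"]);
  return gm;
}

// 0 = anterior, 1 = left_psm, 2 = right_psm, 3 = tailbud
static inline int pc_classify(double x, double y, const PcGeom& g, double xa) {
  if (x < xa) return 0;
  if (x >= g.Xc) return 3;
  return (y < g.Yc) ? 1 : 2;
}

// Wall-normal confinement force: inward with magnitude mub * exp(-(r - rho)/rb),
// continuous across the tube/torus junction; optional relaxation wall at x = xa.
static inline void pc_boundary_force(double x, double y, double z, const PcGeom& g,
                                     double r, double xa, bool wall_a,
                                     double mub, double rb, double out[3]) {
  out[0] = 0.0; out[1] = 0.0; out[2] = 0.0;
  if (x >= g.Xc) { // half toroid
    double dx = x - g.Xc, dy = y - g.Yc, dz = z - g.Zc;
    double rho_mid = std::sqrt(dx * dx + dy * dy);
    double cp, sp;
    if (rho_mid < 1e-12) { cp = 1.0; sp = 0.0; } else { cp = dx / rho_mid; sp = dy / rho_mid; }
    double rad = rho_mid - g.R;
    double rho = std::sqrt(rad * rad + dz * dz);
    if (r - rho < 34.0 * rb) { // beyond ~34 rb the force underflows any tolerance
      double cq, sq;
      if (rho < 1e-12) { cq = 1.0; sq = 0.0; } else { cq = rad / rho; sq = dz / rho; }
      double mag = mub * std::exp(-(r - rho) / rb);
      out[0] = -mag * cp * cq;
      out[1] = -mag * sp * cq;
      out[2] = -mag * sq;
    }
  } else {        // PSM tube (pick side by y)
    double ay = (y < g.Yc) ? (g.Yc - g.R) : (g.Yc + g.R);
    double dy = y - ay, dz = z - g.Zc;
    double rho2 = dy * dy + dz * dz;
    double lim = r - 34.0 * rb;
    if (lim < 0.0 || rho2 > lim * lim) {
      double rho = std::sqrt(rho2);
      double cq, sq;
      if (rho < 1e-12) { cq = 1.0; sq = 0.0; } else { cq = dy / rho; sq = dz / rho; }
      double mag = mub * std::exp(-(r - rho) / rb);
      out[1] = -mag * cq;
      out[2] = -mag * sq;
    }
  }
  if (wall_a && x - xa < 34.0 * rb) out[0] += mub * std::exp(-(x - xa) / rb);
}

// advection speed v(chi) >= 0 (cells move in -x at this speed), Eq. piecewise linear
static inline double pc_adv_speed(double chi, double va, double vp, double xq) {
  if (chi < 0) chi = 0;
  if (chi > 1) chi = 1;
  if (chi <= xq) return va - (va - vp * (1.0 - xq)) / xq * chi;
  return vp * (1.0 - chi);
}

static inline double pc_motility(double chi, double vs, double Xv, double h) {
  if (chi < 0) chi = 0;
  if (chi > 1) chi = 1;
  return vs / (1.0 + std::pow((1.0 - chi) / Xv, h));
}

static inline double pc_freqU(double chi, double sigma, double k) {
  if (chi < 0) chi = 0;
  if (chi > 1) chi = 1;
  if (k == 0.0) return sigma + (1.0 - sigma) * chi;
  return sigma + (1.0 - sigma) * (1.0 - std::exp(-k * chi)) / (1.0 - std::exp(-k));
}

static inline double pc_kappa(double t, double t_washout, double ks, double k0) {
  if (t < t_washout) return 0.0;
  return ks * t + k0;
}

// ---------------------------------------------------------------------------
// Exported elementary operations (thin, shared with the stepper)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_classify_domain(NumericMatrix pos, List geom, double xa) {
  PcGeom g = pc_geom_from_list(geom);
  int n = pos.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pc_classify(pos(i, 0), pos(i, 1), g, xa);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_tube_coords(NumericMatrix pos, List geom, int side) {
  PcGeom g = pc_geom_from_list(geom);
  double ay = (side == 1) ? (g.Yc - g.R) : (g.Yc + g.R);
  int n = pos.nrow();
  NumericMatrix out(n, 3); // x, rho, q
  for (int i = 0; i < n; ++i) {
    double dy = pos(i, 1) - ay, dz = pos(i, 2) - g.Zc;
    double rho = std::sqrt(dy * dy + dz * dz);
    double q = (rho < 1e-12) ? 0.0 : pc_wrap2pi(std::atan2(dz, dy));
    out(i, 0) = pos(i, 0);
    out(i, 1) = rho;
    out(i, 2) = q;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_tube_position(NumericMatrix lc, List geom, int side) {
  PcGeom g = pc_geom_from_list(geom);
  double ay = (side == 1) ? (g.Yc - g.R) : (g.Yc + g.R);
  int n = lc.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = lc(i, 0);
    out(i, 1) = ay + lc(i, 1) * std::cos(lc(i, 2));
    out(i, 2) = g.Zc + lc(i, 1) * std::sin(lc(i, 2));
  }
  return out;
}

// p is measured in the torus mid-plane from the left-tube junction (p = 0 at
// the left tube, p = pi at the right tube), i.e. p = atan2(y - Yc, x - Xc) + pi/2.
// [[Rcpp::export]]
NumericMatrix cpp_torus_coords(NumericMatrix pos, List geom) {
  PcGeom g = pc_geom_from_list(geom);
  int n = pos.nrow();
  NumericMatrix out(n, 3); // p, rho, q
  for (int i = 0; i < n; ++i) {
    double dx = pos(i, 0) - g.Xc, dy = pos(i, 1) - g.Yc, dz = pos(i, 2) - g.Zc;
    double rho_mid = std::sqrt(dx * dx + dy * dy);
    double p = (rho_mid < 1e-12) ? 0.0 : std::atan2(dy, dx);
    double rad = rho_mid - g.R;
    double rho = std::sqrt(rad * rad + dz * dz);
    double q = (rho < 1e-12) ? 0.0 : pc_wrap2pi(std::atan2(dz, rad));
    out(i, 0) = p + PC_TWO_PI / 4.0;
    out(i, 1) = rho;
    out(i, 2) = q;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_torus_position(NumericMatrix lc, List geom) {
  PcGeom g = pc_geom_from_list(geom);
  int n = lc.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double p = lc(i, 0) - PC_TWO_PI / 4.0;
    double rho = lc(i, 1), q = lc(i, 2);
    double rm = g.R + rho * std::cos(q);
    out(i, 0) = g.Xc + rm * std::cos(p);
    out(i, 1) = g.Yc + rm * std::sin(p);
    out(i, 2) = g.Zc + rho * std::sin(q);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_boundary_force_mat(NumericMatrix pos, List geom, double xa,
                                     double r, bool anterior_wall,
                                     double mub, double rb) {
  PcGeom g = pc_geom_from_list(geom);
  int n = pos.nrow();
  NumericMatrix out(n, 3);
  double f[3];
  for (int i = 0; i < n; ++i) {
    pc_boundary_force(pos(i, 0), pos(i, 1), pos(i, 2), g, r, xa, anterior_wall, mub, rb, f);
    out(i, 0) = f[0]; out(i, 1) = f[1]; out(i, 2) = f[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_advection_speed(NumericVector chi, double va, double vp, double xq) {
  int n = chi.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pc_adv_speed(chi[i], va, vp, xq);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_motility_speed(NumericVector chi, double vs, double Xv, double h) {
  int n = chi.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pc_motility(chi[i], vs, Xv, h);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_frequency_factor(NumericVector chi, double sigma, double k) {
  int n = chi.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pc_freqU(chi[i], sigma, k);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_coupling_strength(NumericVector t, double t_washout, double ks, double k0) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pc_kappa(t[i], t_washout, ks, k0);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pair_force(NumericVector xi, NumericVector xj, double mu, double dc,
                             int id_i, int id_j, int seed) {
  double dx = xi[0] - xj[0], dy = xi[1] - xj[1], dz = xi[2] - xj[2];
  double d = std::sqrt(dx * dx + dy * dy + dz * dz);
  NumericVector out(3);
  if (d > dc) return out;
  if (d < 1e-12) {
    double u[3];
    pc_hash_unit((uint64_t)id_i, (uint64_t)id_j, (uint64_t)seed, u);
    double mag = mu;
    out[0] = mag * u[0]; out[1] = mag * u[1]; out[2] = mag * u[2];
    return out;
  }
  double mag = mu * (1.0 - d / dc) / d;
  out[0] = mag * dx; out[1] = mag * dy; out[2] = mag * dz;
  return out;
}

// Tangent-plane polarity step (uniform random walk on the unit sphere):
// n~ = n + sqrt(2 D dt) (xi1 * mx + xi2 * my), then renormalized.
// [[Rcpp::export]]
NumericVector cpp_polarity_step(NumericVector n, double dt, double Dphi,
                                double xi1, double xi2) {
  double nx = n[0], ny = n[1], nz = n[2];
  double amp = std::sqrt(2.0 * Dphi * dt);
  // mx = (n x ez)/|n x ez|, my = (mx x n)/|mx x n|
  double cxx = ny, cxy = -nx; // n x ez = (ny, -nx, 0)
  double nc = std::sqrt(cxx * cxx + cxy * cxy);
  double mx0, mx1, mx2;
  if (nc < 1e-12) { mx0 = 1.0; mx1 = 0.0; mx2 = 0.0; }
  else { mx0 = cxx / nc; mx1 = cxy / nc; mx2 = 0.0; }
  double my0 = mx1 * nz - mx2 * ny;
  double my1 = mx2 * nx - mx0 * nz;
  double my2 = mx0 * ny - mx1 * nx;
  double mn = std::sqrt(my0 * my0 + my1 * my1 + my2 * my2);
  my0 /= mn; my1 /= mn; my2 /= mn;
  double ox = nx + amp * (xi1 * mx0 + xi2 * my0);
  double oy = ny + amp * (xi1 * mx1 + xi2 * my1);
  double oz = nz + amp * (xi1 * mx2 + xi2 * my2);
  double no = std::sqrt(ox * ox + oy * oy + oz * oz);
  return NumericVector::create(ox / no, oy / no, oz / no);
}

// ---------------------------------------------------------------------------
// Neighbor machinery + velocity assembly
// ---------------------------------------------------------------------------

struct PcMech {
  double mu, dc, mub, rb, vs, Xv, h;
  double va, xq;
};

// Fills pair-interaction sums for active cells: repulsion forces, and (if th
// not NULL) neighbor counts and sin-coupling sums. Uses either a uniform grid
// with bin size dc (exact cutoff semantics) or the brute-force all-pairs loop.
static void pc_pair_sums(int n, const double* x, const double* y, const double* z,
                         const double* th, double mu, double dc,
                         bool use_grid, uint64_t pair_seed,
                         double* fx, double* fy, double* fz,
                         double* scoup, int* ncoup) {
  for (int i = 0; i < n; ++i) {
    fx[i] = 0.0; fy[i] = 0.0; fz[i] = 0.0;
    if (th) { scoup[i] = 0.0; ncoup[i] = 0; }
  }
  std::vector<double> sth, cth;
  if (th) {
    sth.resize(n); cth.resize(n);
    for (int i = 0; i < n; ++i) { sth[i] = std::sin(th[i]); cth[i] = std::cos(th[i]); }
  }
  double dc2 = dc * dc;

  auto interact = [&](int i, int j) {
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > dc2) return;
    double d = std::sqrt(d2);
    if (d < 1e-12) {
      double u[3];
      pc_hash_unit((uint64_t)i, (uint64_t)j, pair_seed, u);
      fx[i] += mu * u[0]; fy[i] += mu * u[1]; fz[i] += mu * u[2];
      fx[j] -= mu * u[0]; fy[j] -= mu * u[1]; fz[j] -= mu * u[2];
    } else {
      double mag = mu * (1.0 - d / dc) / d;
      fx[i] += mag * dx; fy[i] += mag * dy; fz[i] += mag * dz;
      fx[j] -= mag * dx; fy[j] -= mag * dy; fz[j] -= mag * dz;
    }
    if (th) {
      double s = sth[j] * cth[i] - cth[j] * sth[i]; // sin(th_j - th_i)
      scoup[i] += s;
      scoup[j] -= s;
      ncoup[i] += 1;
      ncoup[j] += 1;
    }
  };

  if (!use_grid || n < 32) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) interact(i, j);
    return;
  }

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0], zmin = z[0], zmax = z[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i]; if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i]; if (y[i] > ymax) ymax = y[i];
    if (z[i] < zmin) zmin = z[i]; if (z[i] > zmax) zmax = z[i];
  }
  int nx = std::max(1, (int)std::floor((xmax - xmin) / dc) + 1);
  int ny = std::max(1, (int)std::floor((ymax - ymin) / dc) + 1);
  int nz = std::max(1, (int)std::floor((zmax - zmin) / dc) + 1);
  std::vector<int> head((size_t)nx * ny * nz, -1), nxt(n, -1),
      binx(n), biny(n), binz(n);
  for (int i = 0; i < n; ++i) {
    int bx = std::min(nx - 1, (int)std::floor((x[i] - xmin) / dc));
    int by = std::min(ny - 1, (int)std::floor((y[i] - ymin) / dc));
    int bz = std::min(nz - 1, (int)std::floor((z[i] - zmin) / dc));
    binx[i] = bx; biny[i] = by; binz[i] = bz;
    size_t b = ((size_t)bx * ny + by) * nz + bz;
    nxt[i] = head[b];
    head[b] = i;
  }
  for (int i = 0; i < n; ++i) {
    for (int dxb = -1; dxb <= 1; ++dxb) {
      int bx = binx[i] + dxb;
      if (bx < 0 || bx >= nx) continue;
      for (int dyb = -1; dyb <= 1; ++dyb) {
        int by = biny[i] + dyb;
        if (by < 0 || by >= ny) continue;
        for (int dzb = -1; dzb <= 1; ++dzb) {
          int bz = binz[i] + dzb;
          if (bz < 0 || bz >= nz) continue;
          size_t b = ((size_t)bx * ny + by) * nz + bz;
          for (int j = head[b]; j != -1; j = nxt[j])
            if (j > i) interact(i, j);
        }
      }
    }
  }
}

// Full right-hand side of the equation of motion for a set of active cells.
// [[Rcpp::export]]
NumericMatrix cpp_net_velocities(NumericMatrix pos, NumericMatrix pol, List geom,
                                 List mech, double xa, double r, double vp,
                                 bool use_grid, bool anterior_wall, int seed) {
  PcGeom g = pc_geom_from_list(geom);
  double mu = as<double>(mech["mu"]), dc = as<double>(mech["dc"]);
  double mub = as<double>(mech["mub"]), rb = as<double>(mech["rb"]);
  double vs = as<double>(mech["vs"]), Xv = as<double>(mech["Xv"]), h = as<double>(mech["h"]);
  double va = as<double>(mech["va"]), xq = as<double>(mech["xq"]);
  int n = pos.nrow();
  double L = g.Lx - xa;
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  pc_pair_sums(n, x.data(), y.data(), z.data(), nullptr, mu, dc, use_grid,
               (uint64_t)seed, fx.data(), fy.data(), fz.data(), nullptr, nullptr);
  NumericMatrix out(n, 3);
  double fb[3];
  for (int i = 0; i < n; ++i) {
    double chi = (x[i] - xa) / L;
    double vadv = pc_adv_speed(chi, va, vp, xq);
    double v0 = pc_motility(chi, vs, Xv, h);
    pc_boundary_force(x[i], y[i], z[i], g, r, xa, anterior_wall, mub, rb, fb);
    out(i, 0) = -vadv + v0 * pol(i, 0) + fx[i] + fb[0];
    out(i, 1) = v0 * pol(i, 1) + fy[i] + fb[1];
    out(i, 2) = v0 * pol(i, 2) + fz[i] + fb[2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Full simulation
// ---------------------------------------------------------------------------

struct PcState {
  std::vector<double> x, y, z, th, nx, ny, nz, t_arr;
  std::vector<int> id, status; // status: 0 active, 1 arrested
  int next_id;
};

struct PcRecorder {
  std::vector<double> times, xa_s, r_s, kappa_s, nact_s;
  std::vector<double> zL, zR, psiL, psiR, post_phase;
  std::vector<double> prof_times;
  std::vector<double> profL, profR, prof_psiL, prof_psiR; // row-major, nprof cols
  int nprof;
  std::vector<double> snap_times;
  std::vector<NumericMatrix> snaps;
  std::vector<double> ev_time;
  std::vector<int> ev_type, ev_region, ev_id;
  std::vector<double> ev_x;
};

// circular statistics over a subset
struct PcPhasor { double c = 0.0, s = 0.0; int n = 0; };

static inline double pc_phasor_R(const PcPhasor& p) {
  if (p.n == 0) return NA_REAL;
  return std::sqrt(p.c * p.c + p.s * p.s) / p.n;
}
static inline double pc_phasor_arg(const PcPhasor& p) {
  if (p.n == 0) return NA_REAL;
  return pc_wrap2pi(std::atan2(p.s, p.c));
}

static NumericMatrix pc_snapshot(const PcState& st, double t) {
  int n = st.x.size();
  NumericMatrix m(n, 10);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = st.id[i];
    m(i, 1) = st.x[i]; m(i, 2) = st.y[i]; m(i, 3) = st.z[i];
    m(i, 4) = st.th[i];
    m(i, 5) = st.nx[i]; m(i, 6) = st.ny[i]; m(i, 7) = st.nz[i];
    m(i, 8) = st.status[i];
    m(i, 9) = st.status[i] ? st.t_arr[i] : NA_REAL;
  }
  colnames(m) = CharacterVector::create("id", "x", "y", "z", "theta",
                                        "nx", "ny", "nz", "arrested", "t_arrest");
  return m;
}

// place one cell uniformly in a region (1 left tube, 2 right tube, 3 tailbud)
static void pc_place_uniform(int region, const PcGeom& g, double r, double xa,
                             double x_lo, PcRng& rng, double out[3]) {
  if (region == 3) {
    // half torus: p uniform, (rho, q) by rejection against (R + rho cos q)
    for (;;) {
      double p = (rng.unif() - 0.5) * (PC_TWO_PI / 2.0); // (-pi/2, pi/2)
      double rho = r * std::sqrt(rng.unif());
      double q = PC_TWO_PI * rng.unif();
      double acc = (g.R + rho * std::cos(q)) / (g.R + r);
      if (rng.unif() < acc) {
        double rm = g.R + rho * std::cos(q);
        out[0] = g.Xc + rm * std::cos(p);
        out[1] = g.Yc + rm * std::sin(p);
        out[2] = g.Zc + rho * std::sin(q);
        return;
      }
    }
  }
  double ay = (region == 1) ? (g.Yc - g.R) : (g.Yc + g.R);
  double lo = (x_lo < g.Xc - 1.0) ? x_lo : xa;
  double xx = lo + rng.unif() * (g.Xc - lo);
  double rho = r * std::sqrt(rng.unif());
  double q = PC_TWO_PI * rng.unif();
  out[0] = xx;
  out[1] = ay + rho * std::cos(q);
  out[2] = g.Zc + rho * std::sin(q);
}

// [[Rcpp::export]]
List cpp_run(List args) {
  PcGeom g = pc_geom_from_list(args["geom"]);
  List mech = args["mech"];
  double mu = as<double>(mech["mu"]), dc = as<double>(mech["dc"]);
  double mub = as<double>(mech["mub"]), rb = as<double>(mech["rb"]);
  double vs = as<double>(mech["vs"]), Xv = as<double>(mech["Xv"]), hstp = as<double>(mech["h"]);
  double Dphi = as<double>(mech["Dphi"]);
  double va = as<double>(mech["va"]), xq = as<double>(mech["xq"]);
  double vp_early = as<double>(mech["vp_early"]), vp_late = as<double>(mech["vp_late"]);
  double tg = as<double>(mech["tg"]);

  List ph = args["phase"];
  double omega0 = as<double>(ph["omega0"]), sigma = as<double>(ph["sigma"]);
  double kshape = as<double>(ph["k"]), Dth = as<double>(ph["Dtheta"]);
  double kappa0 = as<double>(ph["kappa0"]), kappas = as<double>(ph["kappas"]);
  double t_washout = as<double>(ph["t_washout"]);

  List prog = args["program"];
  double ua = as<double>(prog["ua"]), sr = as<double>(prog["sr"]);
  double rho0 = as<double>(prog["rho0"]), zeta = as<double>(prog["zeta"]);

  double dt = as<double>(args["dt"]);
  double duration = as<double>(args["duration"]);
  double relax_minutes = as<double>(args["relax_minutes"]);
  double obs_dt = as<double>(args["obs_dt"]);
  double profile_dt = as<double>(args["profile_dt"]);
  double snapshot_dt = as<double>(args["snapshot_dt"]);
  double arrested_window = as<double>(args["arrested_window"]);
  double post_window = as<double>(args["post_window"]);
  int M = as<int>(args["M"]);
  int init_random = as<int>(args["init_random"]); // 1 random phases, 0 synchronized
  double theta0 = as<double>(args["theta0"]);
  uint64_t seed = (uint64_t)as<double>(args["seed"]);
  bool keep_snapshots = as<bool>(args["keep_snapshots"]);

  PcRng rng_init, rng_phase, rng_pol, rng_ins;
  rng_init.seed(seed, 1);
  rng_phase.seed(seed, 2);
  rng_pol.seed(seed, 3);
  rng_ins.seed(seed, 4);

  double r = g.r0;
  double xa = 0.0;
  double tube_len = g.Xc - xa;
  double vol = 2.0 * M_PI * r * r * tube_len + M_PI * M_PI * g.R * r * r;
  int N0 = (int)std::lround(rho0 * vol);
  if (N0 <= 0) stop("computed initial cell number is non-positive");

  PcState st;
  st.next_id = 0;
  st.x.reserve(2 * N0);
  // region volumes for placement weights
  double v_tube = M_PI * r * r * tube_len;
  double v_tor = M_PI * M_PI * g.R * r * r;
  for (int i = 0; i < N0; ++i) {
    double u = rng_init.unif() * (2.0 * v_tube + v_tor);
    int region = (u < v_tube) ? 1 : (u < 2.0 * v_tube ? 2 : 3);
    double p[3];
    pc_place_uniform(region, g, r, xa, xa, rng_init, p);
    st.x.push_back(p[0]); st.y.push_back(p[1]); st.z.push_back(p[2]);
    st.th.push_back(0.0);
    double phi = M_PI * rng_init.unif();           // polar angle uniform in (0, pi)
    double vph = PC_TWO_PI * rng_init.unif();
    st.nx.push_back(std::sin(phi) * std::cos(vph));
    st.ny.push_back(std::sin(phi) * std::sin(vph));
    st.nz.push_back(std::cos(phi));
    st.t_arr.push_back(0.0);
    st.id.push_back(st.next_id++);
    st.status.push_back(0);
  }

  int n_all = (int)st.x.size();
  std::vector<double> fx(n_all), fy(n_all), fz(n_all), scoup(n_all);
  std::vector<int> ncoup(n_all);
  std::vector<int> act; act.reserve(n_all);
  std::vector<double> ax, ay, az, ath;

  // tabulated motility and frequency profiles (smooth in chi; linear
  // interpolation at this resolution is exact to ~1e-7)
  const int NTAB = 2048;
  std::vector<double> tab_v0(NTAB + 1), tab_U(NTAB + 1);
  for (int i = 0; i <= NTAB; ++i) {
    double chi = (double)i / NTAB;
    tab_v0[i] = pc_motility(chi, vs, Xv, hstp);
    tab_U[i] = pc_freqU(chi, sigma, kshape);
  }
  auto lerp = [&](const std::vector<double>& tb, double chi) {
    if (chi <= 0.0) return tb[0];
    if (chi >= 1.0) return tb[NTAB];
    double f = chi * NTAB;
    int i = (int)f;
    double w = f - i;
    return tb[i] * (1.0 - w) + tb[i + 1] * w;
  };

  // ---------------- relaxation: Eq. of motion only, no advection, wall at xa
  int relax_steps = (int)std::lround(relax_minutes / dt);
  for (int s2 = 0; s2 < relax_steps; ++s2) {
    int n = (int)st.x.size();
    if ((int)fx.size() < n) { fx.resize(n); fy.resize(n); fz.resize(n); }
    pc_pair_sums(n, st.x.data(), st.y.data(), st.z.data(), nullptr, mu, dc, true,
                 seed, fx.data(), fy.data(), fz.data(), nullptr, nullptr);
    double fb[3];
    for (int i = 0; i < n; ++i) {
      double chi = (st.x[i] - xa) / (g.Lx - xa);
      double v0 = lerp(tab_v0, chi);
      pc_boundary_force(st.x[i], st.y[i], st.z[i], g, r, xa, true, mub, rb, fb);
      double vx = v0 * st.nx[i] + fx[i] + fb[0];
      double vy = v0 * st.ny[i] + fy[i] + fb[1];
      double vz = v0 * st.nz[i] + fz[i] + fb[2];
      st.x[i] += vx * dt; st.y[i] += vy * dt; st.z[i] += vz * dt;
      if (Dphi > 0) {
        double amp = std::sqrt(2.0 * Dphi * dt);
        double xi1 = rng_pol.gauss(), xi2 = rng_pol.gauss();
        double nxo = st.nx[i], nyo = st.ny[i], nzo = st.nz[i];
        double cxx = nyo, cxy = -nxo;
        double nc = std::sqrt(cxx * cxx + cxy * cxy);
        double mx0, mx1;
        if (nc < 1e-12) { mx0 = 1.0; mx1 = 0.0; } else { mx0 = cxx / nc; mx1 = cxy / nc; }
        double my0 = mx1 * nzo, my1 = -mx0 * nzo, my2 = mx0 * nyo - mx1 * nxo;
        double mn = std::sqrt(my0 * my0 + my1 * my1 + my2 * my2);
        my0 /= mn; my1 /= mn; my2 /= mn;
        double ox = nxo + amp * (xi1 * mx0 + xi2 * my0);
        double oy = nyo + amp * (xi1 * mx1 + xi2 * my1);
        double oz = nzo + amp * (xi2 * my2);
        double no = std::sqrt(ox * ox + oy * oy + oz * oz);
        st.nx[i] = ox / no; st.ny[i] = oy / no; st.nz[i] = oz / no;
      }
    }
  }

  // ---------------- assign phases after relaxation
  for (size_t i = 0; i < st.th.size(); ++i)
    st.th[i] = init_random ? PC_TWO_PI * rng_init.unif() : theta0;

  // ---------------- main loop
  int nsteps = (int)std::lround(duration / dt);
  int obs_every = std::max(1, (int)std::lround(obs_dt / dt));
  int prof_every = std::max(1, (int)std::lround(profile_dt / dt));
  int snap_every = snapshot_dt > 0 ? std::max(1, (int)std::lround(snapshot_dt / dt)) : 0;

  PcRecorder rec;
  rec.nprof = (int)std::floor(g.Lx / dc);
  std::string status = "ok";

  auto record_obs = [&](double t) {
    int n = (int)st.x.size();
    // Z over first M slices per side + Psi of first slice + posterior mean phase
    std::vector<PcPhasor> phL(M), phR(M);
    PcPhasor post;
    for (int i = 0; i < n; ++i) {
      if (st.status[i] != 0) continue;
      double xi = st.x[i];
      if (xi >= g.Lx - post_window) { post.c += std::cos(st.th[i]); post.s += std::sin(st.th[i]); post.n++; }
      int m = (int)std::floor((xi - xa) / dc);
      if (m >= 0 && m < M) {
        PcPhasor& p = (st.y[i] < g.Yc) ? phL[m] : phR[m];
        p.c += std::cos(st.th[i]); p.s += std::sin(st.th[i]); p.n++;
      }
    }
    auto zavg = [&](std::vector<PcPhasor>& v) {
      double sum = 0; int k = 0;
      for (int m = 0; m < M; ++m) { double rr = pc_phasor_R(v[m]); if (!ISNAN(rr)) { sum += rr; k++; } }
      return k ? sum / k : NA_REAL;
    };
    rec.times.push_back(t);
    rec.xa_s.push_back(xa);
    rec.r_s.push_back(r);
    rec.kappa_s.push_back(pc_kappa(t, t_washout, kappas, kappa0));
    int nact = 0;
    for (int i = 0; i < n; ++i) if (st.status[i] == 0) nact++;
    rec.nact_s.push_back(nact);
    rec.zL.push_back(zavg(phL));
    rec.zR.push_back(zavg(phR));
    rec.psiL.push_back(pc_phasor_arg(phL[0]));
    rec.psiR.push_back(pc_phasor_arg(phR[0]));
    rec.post_phase.push_back(pc_phasor_arg(post));
  };

  auto record_profile = [&](double t) {
    int n = (int)st.x.size();
    std::vector<PcPhasor> phL(rec.nprof), phR(rec.nprof);
    for (int i = 0; i < n; ++i) {
      if (st.status[i] != 0) continue;
      int m = (int)std::floor((st.x[i] - xa) / dc);
      if (m >= 0 && m < rec.nprof) {
        PcPhasor& p = (st.y[i] < g.Yc) ? phL[m] : phR[m];
        p.c += std::cos(st.th[i]); p.s += std::sin(st.th[i]); p.n++;
      }
    }
    rec.prof_times.push_back(t);
    for (int m = 0; m < rec.nprof; ++m) {
      rec.profL.push_back(pc_phasor_R(phL[m]));
      rec.profR.push_back(pc_phasor_R(phR[m]));
      rec.prof_psiL.push_back(pc_phasor_arg(phL[m]));
      rec.prof_psiR.push_back(pc_phasor_arg(phR[m]));
    }
  };

  record_obs(0.0);
  record_profile(0.0);
  if (keep_snapshots) { rec.snap_times.push_back(0.0); rec.snaps.push_back(pc_snapshot(st, 0.0)); }

  // Verlet neighbor list over active cells: all pairs within dc + skin at
  // build time, rebuilt when any cell has moved more than skin/2 since the
  // build. Every stored pair is distance-checked against dc each step, so
  // the interaction cutoff stays exact.
  const double skin = 3.0;
  const double half_skin2 = (skin / 2.0) * (skin / 2.0);
  std::vector<int> pr_i, pr_j;
  std::vector<double> bx0, by0, bz0; // positions at list build, st-aligned
  bool need_rebuild = true;
  std::vector<double> sth_st, cth_st, fxc, fyc, fzc, scoupc;
  std::vector<int> ncoupc;

  auto build_pairs = [&]() {
    int n = (int)st.x.size();
    pr_i.clear(); pr_j.clear();
    bx0.assign(st.x.begin(), st.x.end());
    by0.assign(st.y.begin(), st.y.end());
    bz0.assign(st.z.begin(), st.z.end());
    double cut = dc + skin, cut2 = cut * cut;
    std::vector<int> aidx;
    aidx.reserve(n);
    for (int i = 0; i < n; ++i) if (st.status[i] == 0) aidx.push_back(i);
    int na = (int)aidx.size();
    if (na == 0) { need_rebuild = false; return; }
    double xmin = 1e300, xmax = -1e300, ymin = 1e300, ymax = -1e300,
           zmin = 1e300, zmax = -1e300;
    for (int k = 0; k < na; ++k) {
      int i = aidx[k];
      xmin = std::min(xmin, st.x[i]); xmax = std::max(xmax, st.x[i]);
      ymin = std::min(ymin, st.y[i]); ymax = std::max(ymax, st.y[i]);
      zmin = std::min(zmin, st.z[i]); zmax = std::max(zmax, st.z[i]);
    }
    int nx = std::max(1, (int)std::floor((xmax - xmin) / cut) + 1);
    int ny = std::max(1, (int)std::floor((ymax - ymin) / cut) + 1);
    int nz = std::max(1, (int)std::floor((zmax - zmin) / cut) + 1);
    std::vector<int> head((size_t)nx * ny * nz, -1), nxt(na, -1);
    std::vector<int> binx(na), biny(na), binz(na);
    for (int k = 0; k < na; ++k) {
      int i = aidx[k];
      int bx = std::min(nx - 1, (int)std::floor((st.x[i] - xmin) / cut));
      int by = std::min(ny - 1, (int)std::floor((st.y[i] - ymin) / cut));
      int bz = std::min(nz - 1, (int)std::floor((st.z[i] - zmin) / cut));
      binx[k] = bx; biny[k] = by; binz[k] = bz;
      size_t b = ((size_t)bx * ny + by) * nz + bz;
      nxt[k] = head[b];
      head[b] = k;
    }
    for (int k = 0; k < na; ++k) {
      int i = aidx[k];
      for (int dxb = -1; dxb <= 1; ++dxb) {
        int bx = binx[k] + dxb;
        if (bx < 0 || bx >= nx) continue;
        for (int dyb = -1; dyb <= 1; ++dyb) {
          int by = biny[k] + dyb;
          if (by < 0 || by >= ny) continue;
          for (int dzb = -1; dzb <= 1; ++dzb) {
            int bz = binz[k] + dzb;
            if (bz < 0 || bz >= nz) continue;
            size_t b = ((size_t)bx * ny + by) * nz + bz;
            for (int m = head[b]; m != -1; m = nxt[m]) {
              if (m <= k) continue;
              int j = aidx[m];
              double ddx = st.x[i] - st.x[j], ddy = st.y[i] - st.y[j],
                     ddz = st.z[i] - st.z[j];
              if (ddx * ddx + ddy * ddy + ddz * ddz <= cut2) {
                pr_i.push_back(std::min(i, j));
                pr_j.push_back(std::max(i, j));
              }
            }
          }
        }
      }
    }
    need_rebuild = false;
  };

  for (int s2 = 1; s2 <= nsteps; ++s2) {
    double t = (s2 - 1) * dt; // state time entering the step
    double L = g.Lx - xa;
    // stop when the PSM is consumed: total length below 2 dc or the tubes
    // swallowed by the advancing anterior end
    if (L < 2.0 * dc || g.Xc - xa < dc) { status = "psm_consumed"; break; }
    double vp = (t < tg) ? vp_early : vp_late;
    double kap = pc_kappa(t, t_washout, kappas, kappa0);

    int n = (int)st.x.size();
    if (need_rebuild) build_pairs();

    // pair sums over the Verlet list, exact dc cutoff
    if ((int)fxc.size() < n) {
      fxc.resize(n); fyc.resize(n); fzc.resize(n);
      scoupc.resize(n); ncoupc.resize(n);
      sth_st.resize(n); cth_st.resize(n);
    }
    for (int i = 0; i < n; ++i) {
      fxc[i] = 0.0; fyc[i] = 0.0; fzc[i] = 0.0; scoupc[i] = 0.0; ncoupc[i] = 0;
      if (st.status[i] == 0) { sth_st[i] = std::sin(st.th[i]); cth_st[i] = std::cos(st.th[i]); }
    }
    double dc2 = dc * dc;
    size_t npr = pr_i.size();
    for (size_t p = 0; p < npr; ++p) {
      int i = pr_i[p], j = pr_j[p];
      if (st.status[i] != 0 || st.status[j] != 0) continue;
      double ddx = st.x[i] - st.x[j], ddy = st.y[i] - st.y[j], ddz = st.z[i] - st.z[j];
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 > dc2) continue;
      double d = std::sqrt(d2);
      if (d < 1e-12) {
        double u[3];
        pc_hash_unit((uint64_t)i, (uint64_t)j, seed, u);
        fxc[i] += mu * u[0]; fyc[i] += mu * u[1]; fzc[i] += mu * u[2];
        fxc[j] -= mu * u[0]; fyc[j] -= mu * u[1]; fzc[j] -= mu * u[2];
      } else {
        double mag = mu * (1.0 - d / dc) / d;
        fxc[i] += mag * ddx; fyc[i] += mag * ddy; fzc[i] += mag * ddz;
        fxc[j] -= mag * ddx; fyc[j] -= mag * ddy; fzc[j] -= mag * ddz;
      }
      double sdt = sth_st[j] * cth_st[i] - cth_st[j] * sth_st[i]; // sin(th_j - th_i)
      scoupc[i] += sdt;
      scoupc[j] -= sdt;
      ncoupc[i] += 1;
      ncoupc[j] += 1;
    }

    double fb[3];
    double sq2Dth = std::sqrt(2.0 * Dth * dt);
    double ampPol = std::sqrt(2.0 * Dphi * dt);
    for (int i = 0; i < n; ++i) {
      if (st.status[i] != 0) continue;
      double oxp = st.x[i], oyp = st.y[i], ozp = st.z[i], oth = st.th[i];
      double chi = (oxp - xa) / L;
      double vadv = pc_adv_speed(chi, va, vp, xq);
      double v0 = lerp(tab_v0, chi);
      pc_boundary_force(oxp, oyp, ozp, g, r, xa, false, mub, rb, fb);
      st.x[i] = oxp + (-vadv + v0 * st.nx[i] + fxc[i] + fb[0]) * dt;
      st.y[i] = oyp + (v0 * st.ny[i] + fyc[i] + fb[1]) * dt;
      st.z[i] = ozp + (v0 * st.nz[i] + fzc[i] + fb[2]) * dt;
      // displacement since list build triggers the next rebuild
      double mx = st.x[i] - bx0[i], my = st.y[i] - by0[i], mz = st.z[i] - bz0[i];
      if (mx * mx + my * my + mz * mz > half_skin2) need_rebuild = true;

      // phase update
      double om = omega0 * lerp(tab_U, chi);
      double dth = om * dt;
      if (kap > 0.0 && ncoupc[i] > 0) dth += kap / ncoupc[i] * scoupc[i] * dt;
      if (Dth > 0.0) dth += sq2Dth * rng_phase.gauss();
      st.th[i] = pc_wrap2pi(oth + dth);

      // polarity update (tangent-plane random walk)
      if (Dphi > 0.0) {
        double xi1 = rng_pol.gauss(), xi2 = rng_pol.gauss();
        double nxo = st.nx[i], nyo = st.ny[i], nzo = st.nz[i];
        double cxx = nyo, cxy = -nxo;
        double nc = std::sqrt(cxx * cxx + cxy * cxy);
        double mx0, mx1;
        if (nc < 1e-12) { mx0 = 1.0; mx1 = 0.0; } else { mx0 = cxx / nc; mx1 = cxy / nc; }
        double my0 = mx1 * nzo, my1 = -mx0 * nzo, my2 = mx0 * nyo - mx1 * nxo;
        double mn = std::sqrt(my0 * my0 + my1 * my1 + my2 * my2);
        my0 /= mn; my1 /= mn; my2 /= mn;
        double ox = nxo + ampPol * (xi1 * mx0 + xi2 * my0);
        double oy = nyo + ampPol * (xi1 * mx1 + xi2 * my1);
        double oz = nzo + ampPol * (xi2 * my2);
        double no = std::sqrt(ox * ox + oy * oy + oz * oz);
        st.nx[i] = ox / no; st.ny[i] = oy / no; st.nz[i] = oz / no;
      }
    }

    double tnew = s2 * dt;

    // arrested cells advect with the anterior end speed va
    for (int i = 0; i < n; ++i)
      if (st.status[i] == 1) st.x[i] -= va * dt;

    // schedules: anterior end and radius
    xa = ua * tnew;
    if (sr > 0.0) {
      double rnew = g.r0 - sr * tnew;
      double rfloor = std::min(2.0 * dc, g.r0);
      if (rnew < rfloor) rnew = rfloor;
      if (rnew != r) {
        r = rnew;
        // reposition cells left outside the shrunken domain: rho -> r - 2 rb
        for (int i = 0; i < (int)st.x.size(); ++i) {
          if (st.status[i] != 0) continue;
          if (st.x[i] >= g.Xc) {
            double dx2 = st.x[i] - g.Xc, dy2 = st.y[i] - g.Yc, dz2 = st.z[i] - g.Zc;
            double rho_mid = std::sqrt(dx2 * dx2 + dy2 * dy2);
            double cp = rho_mid < 1e-12 ? 1.0 : dx2 / rho_mid;
            double sp = rho_mid < 1e-12 ? 0.0 : dy2 / rho_mid;
            double rad = rho_mid - g.R;
            double rho = std::sqrt(rad * rad + dz2 * dz2);
            if (rho > r) {
              double cq = rho < 1e-12 ? 1.0 : rad / rho, sq = rho < 1e-12 ? 0.0 : dz2 / rho;
              double rnewi = r - 2.0 * rb;
              double rm = g.R + rnewi * cq;
              st.x[i] = g.Xc + rm * cp;
              st.y[i] = g.Yc + rm * sp;
              st.z[i] = g.Zc + rnewi * sq;
            }
          } else {
            double ay2 = (st.y[i] < g.Yc) ? (g.Yc - g.R) : (g.Yc + g.R);
            double dy2 = st.y[i] - ay2, dz2 = st.z[i] - g.Zc;
            double rho = std::sqrt(dy2 * dy2 + dz2 * dz2);
            if (rho > r) {
              double f = (r - 2.0 * rb) / rho;
              st.y[i] = ay2 + dy2 * f;
              st.z[i] = g.Zc + dz2 * f;
            }
          }
        }
      }
    }

    // arrest crossers; each removal from the active pool triggers the density
    // bookkeeping and possibly one insertion (cells inserted below are not
    // revisited within this pass)
    int n_now = (int)st.x.size();
    for (int i = 0; i < n_now; ++i) {
      if (st.status[i] != 0 || st.x[i] >= xa) continue;
      st.status[i] = 1;
      st.t_arr[i] = tnew;
      rec.ev_time.push_back(tnew); rec.ev_type.push_back(1);
      rec.ev_region.push_back(st.y[i] < g.Yc ? 1 : 2);
      rec.ev_id.push_back(st.id[i]); rec.ev_x.push_back(st.x[i]);

      // densities after removal
      int cl = 0, cr = 0, ct = 0;
      for (int j = 0; j < (int)st.x.size(); ++j) {
        if (st.status[j] != 0) continue;
        int reg = pc_classify(st.x[j], st.y[j], g, xa);
        if (reg == 1) cl++; else if (reg == 2) cr++; else if (reg == 3) ct++;
      }
      double tl = g.Xc - xa;
      double vtube = M_PI * r * r * tl, vtor = M_PI * M_PI * g.R * r * r;
      double dl = cl / vtube - rho0, dr = cr / vtube - rho0, dtb = ct / vtor - rho0;
      if (dl < 0 || dr < 0 || dtb < 0) {
        int region = 1;
        double best = dl;
        if (dr < best) { best = dr; region = 2; }
        if (dtb < best) { best = dtb; region = 3; }
        double p[3];
        pc_place_uniform(region, g, r, xa, xa + zeta, rng_ins, p);
        st.x.push_back(p[0]); st.y.push_back(p[1]); st.z.push_back(p[2]);
        st.th.push_back(PC_TWO_PI * rng_ins.unif());
        double phi = M_PI * rng_ins.unif();
        double vph = PC_TWO_PI * rng_ins.unif();
        st.nx.push_back(std::sin(phi) * std::cos(vph));
        st.ny.push_back(std::sin(phi) * std::sin(vph));
        st.nz.push_back(std::cos(phi));
        st.t_arr.push_back(0.0);
        st.id.push_back(st.next_id++);
        st.status.push_back(0);
        rec.ev_time.push_back(tnew); rec.ev_type.push_back(2);
        rec.ev_region.push_back(region);
        rec.ev_id.push_back(st.id.back()); rec.ev_x.push_back(p[0]);
        // splice the new cell into the Verlet list
        int inew = (int)st.x.size() - 1;
        bx0.push_back(p[0]); by0.push_back(p[1]); bz0.push_back(p[2]);
        double cut2 = (dc + skin) * (dc + skin);
        for (int j = 0; j < inew; ++j) {
          if (st.status[j] != 0) continue;
          double ddx = p[0] - st.x[j], ddy = p[1] - st.y[j], ddz = p[2] - st.z[j];
          if (ddx * ddx + ddy * ddy + ddz * ddz <= cut2) {
            pr_i.push_back(std::min(j, inew));
            pr_j.push_back(std::max(j, inew));
          }
        }
      }
    }

    // drop long-arrested cells (inert; bounded state size)
    if (s2 % obs_every == 0) {
      size_t w = 0;
      std::vector<int> remap(st.x.size(), -1);
      for (size_t i2 = 0; i2 < st.x.size(); ++i2) {
        if (st.status[i2] == 1 && tnew - st.t_arr[i2] > arrested_window) continue;
        if (w != i2) {
          st.x[w] = st.x[i2]; st.y[w] = st.y[i2]; st.z[w] = st.z[i2];
          st.th[w] = st.th[i2];
          st.nx[w] = st.nx[i2]; st.ny[w] = st.ny[i2]; st.nz[w] = st.nz[i2];
          st.t_arr[w] = st.t_arr[i2]; st.id[w] = st.id[i2]; st.status[w] = st.status[i2];
          bx0[w] = bx0[i2]; by0[w] = by0[i2]; bz0[w] = bz0[i2];
        }
        remap[i2] = (int)w;
        ++w;
      }
      if (w != st.x.size()) {
        // reindex the Verlet list, dropping pairs that lost a member
        size_t wp = 0;
        for (size_t p = 0; p < pr_i.size(); ++p) {
          int ni = remap[pr_i[p]], nj = remap[pr_j[p]];
          if (ni < 0 || nj < 0) continue;
          pr_i[wp] = std::min(ni, nj);
          pr_j[wp] = std::max(ni, nj);
          ++wp;
        }
        pr_i.resize(wp); pr_j.resize(wp);
        bx0.resize(w); by0.resize(w); bz0.resize(w);
      }
      st.x.resize(w); st.y.resize(w); st.z.resize(w); st.th.resize(w);
      st.nx.resize(w); st.ny.resize(w); st.nz.resize(w);
      st.t_arr.resize(w); st.id.resize(w); st.status.resize(w);

      // divergence guard
      bool bad = false;
      for (size_t i2 = 0; i2 < st.x.size() && !bad; ++i2)
        if (!std::isfinite(st.x[i2]) || !std::isfinite(st.th[i2])) bad = true;
      if (bad) { status = "diverged"; break; }
      record_obs(tnew);
    }
    if (s2 % prof_every == 0) record_profile(tnew);
    if (keep_snapshots && snap_every > 0 && s2 % snap_every == 0) {
      rec.snap_times.push_back(tnew);
      rec.snaps.push_back(pc_snapshot(st, tnew));
    }
    if (s2 % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  // assemble result
  int nt = (int)rec.times.size();
  DataFrame series = DataFrame::create(
      _["time"] = NumericVector(rec.times.begin(), rec.times.end()),
      _["xa"] = NumericVector(rec.xa_s.begin(), rec.xa_s.end()),
      _["r"] = NumericVector(rec.r_s.begin(), rec.r_s.end()),
      _["kappa"] = NumericVector(rec.kappa_s.begin(), rec.kappa_s.end()),
      _["n_active"] = NumericVector(rec.nact_s.begin(), rec.nact_s.end()),
      _["Z_left"] = NumericVector(rec.zL.begin(), rec.zL.end()),
      _["Z_right"] = NumericVector(rec.zR.begin(), rec.zR.end()),
      _["psi1_left"] = NumericVector(rec.psiL.begin(), rec.psiL.end()),
      _["psi1_right"] = NumericVector(rec.psiR.begin(), rec.psiR.end()),
      _["posterior_phase"] = NumericVector(rec.post_phase.begin(), rec.post_phase.end()));
  (void)nt;

  int np = (int)rec.prof_times.size();
  NumericMatrix pl(np, rec.nprof), pr(np, rec.nprof), ppl(np, rec.nprof), ppr(np, rec.nprof);
  for (int i = 0; i < np; ++i)
    for (int m = 0; m < rec.nprof; ++m) {
      pl(i, m) = rec.profL[(size_t)i * rec.nprof + m];
      pr(i, m) = rec.profR[(size_t)i * rec.nprof + m];
      ppl(i, m) = rec.prof_psiL[(size_t)i * rec.nprof + m];
      ppr(i, m) = rec.prof_psiR[(size_t)i * rec.nprof + m];
    }

  DataFrame events = DataFrame::create(
      _["time"] = NumericVector(rec.ev_time.begin(), rec.ev_time.end()),
      _["type"] = IntegerVector(rec.ev_type.begin(), rec.ev_type.end()),
      _["region"] = IntegerVector(rec.ev_region.begin(), rec.ev_region.end()),
      _["id"] = IntegerVector(rec.ev_id.begin(), rec.ev_id.end()),
      _["x"] = NumericVector(rec.ev_x.begin(), rec.ev_x.end()));

  List snaps(rec.snaps.size());
  for (size_t i = 0; i < rec.snaps.size(); ++i) snaps[i] = rec.snaps[i];

  return List::create(
      _["status"] = status,
      _["series"] = series,
      _["profile_times"] = NumericVector(rec.prof_times.begin(), rec.prof_times.end()),
      _["profile_Z_left"] = pl,
      _["profile_Z_right"] = pr,
      _["profile_psi_left"] = ppl,
      _["profile_psi_right"] = ppr,
      _["snapshot_times"] = NumericVector(rec.snap_times.begin(), rec.snap_times.end()),
      _["snapshots"] = snaps,
      _["events"] = events,
      _["final"] = pc_snapshot(st, duration),
      _["xa_final"] = xa,
      _["r_final"] = r);
}
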