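// Forced-detection Monte Carlo photon transport for a dual-head parallel-hole
// gamma camera. Phantoms are analytic (sphere / cylinder, centered at the
// origin, cylinder axis along z); detector heads sit at +/- y. At every
// emission or Compton vertex the expected detection weight toward each head
// is scored (geometric collimation, septal penetration, phantom attenuation,
// crystal interaction, energy blurring into acquisition windows); the analog
// history then continues with sampled free paths and Klein-Nishina
// scattering. An analog (no variance reduction) mode is kept for
// unbiasedness checks.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----
struct Rng {
  uint64_t s[2];
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 2; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  uint64_t next() {  // xorshift128+
    uint64_t x = s[0], y = s[1];
    s[0] = y;
    x ^= x << 23;
    s[1] = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s[1] + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {  // Box-Muller, one deviate per call (spare discarded)
    double u1 = unif(), u2 = unif();
    while (u1 <= 0) u1 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// ------------------------------------------------------- cross sections ---
struct XS {  // dense 1-keV grid, linear interpolation
  double emin;
  std::vector<double> pe, tot;
  double at(const std::vector<double>& v, double E) const {
    double x = E - emin;
    if (x <= 0) return v.front();
    size_t i = (size_t)x;
    if (i >= v.size() - 1) return v.back();
    double f = x - i;
    return v[i] * (1 - f) + v[i + 1] * f;
  }
  double total(double E) const { return at(tot, E); }
  double photo(double E) const { return at(pe, E); }
};

static XS make_xs(List t) {
  XS x;
  NumericVector e = t["energy"], pe = t["pe"], tt = t["total"];
  x.emin = e[0];
  x.pe.assign(pe.begin(), pe.end());
  x.tot.assign(tt.begin(), tt.end());
  return x;
}

// ------------------------------------------------------------- physics ----
static inline double compton_E(double E, double cost) {
  return E / (1.0 + (E / 511.0) * (1.0 - cost));
}

static inline double kn_dsdo(double E, double cost) {  // units r_e^2
  double Ep = compton_E(E, cost);
  double r = Ep / E;
  double sin2 = 1.0 - cost * cost;
  return 0.5 * r * r * (r + 1.0 / r - sin2);
}

static double kn_sigma(double E) {  // total, units r_e^2
  double a = E / 511.0;
  double t1 = (1 + a) / (a * a) *
              (2 * (1 + a) / (1 + 2 * a) - std::log(1 + 2 * a) / a);
  double t2 = std::log(1 + 2 * a) / (2 * a);
  double t3 = (1 + 3 * a) / ((1 + 2 * a) * (1 + 2 * a));
  return 2 * M_PI * (t1 + t2 - t3);
}

// Kahn's rejection sampling of the Klein-Nishina scattering angle.
static double kahn_cost(double E, Rng& rng) {
  double a = E / 511.0;
  for (;;) {
    double r1 = rng.unif(), r2 = rng.unif(), r3 = rng.unif();
    if (r1 <= (2 * a + 1) / (2 * a + 9)) {
      double x = 1 + 2 * a * r2;  // x = E/E'
      if (r3 <= 4 * (1 / x - 1 / (x * x))) return 1 - (x - 1) / a;
    } else {
      double x = (2 * a + 1) / (1 + 2 * a * r2);
      double cost = 1 - (x - 1) / a;
      if (r3 <= 0.5 * (cost * cost + 1 / x)) return cost;
    }
  }
}

static inline double phi_cdf(double z) { return 0.5 * std::erfc(-z * M_SQRT1_2); }

// ------------------------------------------------------------ geometry ----
// Water region: 0 = none, 1 = sphere(radius), 2 = cylinder(radius, halflen).
// Transport sampling uses the analytic solid; the forced-detection exit
// attenuation optionally uses the same voxelized water-occupancy map as the
// reconstruction system model (cumulated along +/- y), so that the
// attenuation correction and the simulated data share one discretization.
struct Water {
  int shape;
  double radius, halflen;
  int nvox = 0;          // voxel map edge length (0 = analytic paths)
  double vs = 0;         // voxel size, cm
  std::vector<double> cum_plus, cum_minus, occ;  // nvox^3 each

  void set_map(NumericVector m, int n, double voxel_cm) {
    nvox = n;
    vs = voxel_cm;
    occ.assign(m.begin(), m.end());
    cum_plus.assign(occ.size(), 0.0);
    cum_minus.assign(occ.size(), 0.0);
    // layout [i (x), j (y), k (z)] column-major
    for (int k = 0; k < n; ++k)
      for (int i = 0; i < n; ++i) {
        double acc = 0;
        for (int j = n - 1; j >= 0; --j) {
          size_t id = ((size_t)k * n + j) * n + i;
          cum_plus[id] = acc;
          acc += occ[id] * vs;
        }
        acc = 0;
        for (int j = 0; j < n; ++j) {
          size_t id = ((size_t)k * n + j) * n + i;
          cum_minus[id] = acc;
          acc += occ[id] * vs;
        }
      }
  }

  // water-equivalent path from p along (0, s, 0) using the voxel map
  double map_path(const double* p, double s) const {
    double half = nvox * vs / 2.0;
    int i = (int)std::floor(p[0] / vs + nvox / 2.0);
    int j = (int)std::floor(p[1] / vs + nvox / 2.0);
    int k = (int)std::floor(p[2] / vs + nvox / 2.0);
    if (i < 0 || i >= nvox || j < 0 || j >= nvox || k < 0 || k >= nvox)
      return 0.0;
    size_t id = ((size_t)k * nvox + j) * nvox + i;
    double y_lo = (j - nvox / 2.0) * vs, y_hi = y_lo + vs;
    double frac = (s > 0 ? (y_hi - p[1]) : (p[1] - y_lo));
    (void)half;
    return (s > 0 ? cum_plus[id] : cum_minus[id]) + occ[id] * frac;
  }
  bool inside(const double* p) const {
    if (shape == 1)
      return p[0] * p[0] + p[1] * p[1] + p[2] * p[2] <= radius * radius;
    if (shape == 2)
      return p[0] * p[0] + p[1] * p[1] <= radius * radius &&
             std::fabs(p[2]) <= halflen;
    return false;
  }
  // distance to exit along unit direction u from an interior point
  double exit_dist(const double* p, const double* u) const {
    if (shape == 0) return 0.0;
    if (shape == 1) {
      double b = p[0] * u[0] + p[1] * u[1] + p[2] * u[2];
      double c = p[0] * p[0] + p[1] * p[1] + p[2] * p[2] - radius * radius;
      double disc = b * b - c;
      if (disc < 0) return 0.0;
      return -b + std::sqrt(disc);
    }
    // cylinder: radial
    double a = u[0] * u[0] + u[1] * u[1];
    double t_rad = 1e30;
    if (a > 1e-12) {
      double b = p[0] * u[0] + p[1] * u[1];
      double c = p[0] * p[0] + p[1] * p[1] - radius * radius;
      double disc = b * b - a * c;
      if (disc >= 0) t_rad = (-b + std::sqrt(disc)) / a;
    }
    double t_cap = 1e30;
    if (std::fabs(u[2]) > 1e-12)
      t_cap = ((u[2] > 0 ? halflen : -halflen) - p[2]) / u[2];
    double t = std::min(t_rad, t_cap);
    return t > 0 ? t : 0.0;
  }
  // path length through water from p along (0, s, 0)
  double path_to_head(const double* p, double s) const {
    if (shape == 0) return 0.0;
    if (nvox > 0) return map_path(p, s);
    if (shape == 1) {
      double q = radius * radius - p[0] * p[0] - p[2] * p[2];
      if (q <= 0) return 0.0;
      return std::sqrt(q) - s * p[1];
    }
    double q = radius * radius - p[0] * p[0];
    if (q <= 0 || std::fabs(p[2]) > halflen) return 0.0;
    return std::sqrt(q) - s * p[1];
  }
};

// Source compartment: 1 = sphere, 2 = cylinder, 3 = cylinder minus sphere.
struct Source {
  int shape;
  double radius, halflen, inner_r, weight;
};

static void sample_position(const Source& s, Rng& rng, double* p) {
  for (;;) {
    if (s.shape == 1) {
      for (;;) {
        p[0] = (2 * rng.unif() - 1) * s.radius;
        p[1] = (2 * rng.unif() - 1) * s.radius;
        p[2] = (2 * rng.unif() - 1) * s.radius;
        if (p[0] * p[0] + p[1] * p[1] + p[2] * p[2] <= s.radius * s.radius)
          break;
      }
    } else {
      for (;;) {
        p[0] = (2 * rng.unif() - 1) * s.radius;
        p[1] = (2 * rng.unif() - 1) * s.radius;
        if (p[0] * p[0] + p[1] * p[1] <= s.radius * s.radius) break;
      }
      p[2] = (2 * rng.unif() - 1) * s.halflen;
    }
    if (s.shape == 3 &&
        p[0] * p[0] + p[1] * p[1] + p[2] * p[2] <= s.inner_r * s.inner_r)
      continue;  // carve out the hot sphere from the background
    return;
  }
}

static void iso_dir(Rng& rng, double* u) {
  double cost = 2 * rng.unif() - 1;
  double sint = std::sqrt(std::max(0.0, 1 - cost * cost));
  double phi = 2 * M_PI * rng.unif();
  u[0] = sint * std::cos(phi);
  u[1] = sint * std::sin(phi);
  u[2] = cost;
}

static void rotate_dir(const double* u, double cost, double phi, double* out) {
  // new direction at polar angle acos(cost) about u, azimuth phi
  double sint = std::sqrt(std::max(0.0, 1 - cost * cost));
  // orthonormal basis (a, b, u)
  double a[3];
  if (std::fabs(u[2]) < 0.99) {
    a[0] = -u[1]; a[1] = u[0]; a[2] = 0;
  } else {
    a[0] = 1; a[1] = 0; a[2] = 0;
  }
  double n = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
  a[0] /= n; a[1] /= n; a[2] /= n;
  double b[3] = {u[1] * a[2] - u[2] * a[1],
                 u[2] * a[0] - u[0] * a[2],
                 u[0] * a[1] - u[1] * a[0]};
  double cp = std::cos(phi), sp = std::sin(phi);
  for (int k = 0; k < 3; ++k)
    out[k] = sint * (cp * a[k] + sp * b[k]) + cost * u[k];
}

// -------------------------------------------------------------- camera ----
struct Camera {
  double dist, pix_cm, crystal_cm, fwhm_frac, fwhm_eref;
  double coll_d, coll_l, coll_t, coll_K;
  double kappa_pen, bs_slab_cm, kappa_bs;
  int npix;
  double g_geom(double E, const XS& pb) const {
    double le = coll_l - 2.0 / pb.total(E);
    if (le < 0.1) le = 0.1;
    double g = coll_K * (coll_d / le) * (coll_d / (coll_d + coll_t));
    return g * g;
  }
  double pen_T(double E, const XS& pb) const {
    double lsept = coll_l * coll_t / (coll_d + coll_t);
    return std::exp(-pb.total(E) * lsept);
  }
  double theta_acc(double E, const XS& pb) const {
    double le = coll_l - 2.0 / pb.total(E);
    if (le < 0.1) le = 0.1;
    return std::atan(coll_d / le);
  }
  double sigma_E(double E) const {
    return fwhm_frac * std::sqrt(fwhm_eref * E) / 2.35482;
  }
};

// components: 0 primary, 1 phantom scatter, 2 camera scatter, 3 septal pen.
enum { PRIMARY = 0, PH_SCAT = 1, CAM_SCAT = 2, SEPTAL = 3 };

struct Tally {
  int npix, nebins;
  // counts[pix_x][pix_z][window][head] and primary PW, stored flat
  std::vector<double> win;      // npix*npix*3*2
  std::vector<double> primary;  // npix*npix*2
  std::vector<double> spec;     // nebins*4 (1-keV bins, all heads summed)
  double sum_w = 0.0;
  Tally(int np, int ne) : npix(np), nebins(ne),
      win(np * np * 3 * 2, 0.0), primary(np * np * 2, 0.0),
      spec(ne * 4, 0.0) {}
  inline void add_win(int ix, int iz, int w, int head, double v) {
    win[((head * 3 + w) * npix + iz) * npix + ix] += v;
  }
  inline void add_primary(int ix, int iz, int head, double v) {
    primary[(head * npix + iz) * npix + ix] += v;
  }
  inline void add_spec(double E, int comp, double v) {
    int b = (int)E;
    if (b >= 0 && b < nebins) spec[comp * nebins + b] += v;
  }
};

struct Windows {
  double lo[3], hi[3];  // order: PW, LSW, USW
};

// Score a deposit of (unblurred) energy Edep with weight w into the three
// acquisition windows of one pixel, splitting by the Gaussian energy
// response; also tallies the blurred spectrum (one sampled deviate) and the
// primary-PW truth map for full-energy deposits of primary photons.
static void score_deposit(Tally& T, const Windows& W, const Camera& cam,
                          int ix, int iz, int head, double Edep, double w,
                          int comp, bool full_energy_primary, Rng& rng) {
  double sig = cam.sigma_E(Edep);
  for (int k = 0; k < 3; ++k) {
    double f = phi_cdf((W.hi[k] - Edep) / sig) - phi_cdf((W.lo[k] - Edep) / sig);
    if (f > 0) {
      T.add_win(ix, iz, k, head, w * f);
      if (k == 0 && full_energy_primary) T.add_primary(ix, iz, head, w * f);
    }
  }
  T.add_spec(Edep + sig * rng.norm(), comp, w);
}

// Full camera response for a photon of energy E arriving (along the head
// normal) at detector pixel (ix, iz) with weight w_in: crystal
// photoelectric (full deposit), crystal Compton (partial deposit), and the
// backscatter compartment behind the crystal.
static void camera_deposit(Tally& T, const Windows& W, const Camera& cam,
                           const XS& nai, const XS& water, int ix, int iz,
                           int head, double E, double w_in, int comp,
                           Rng& rng) {
  if (w_in <= 0) return;
  T.sum_w += w_in;
  double mu_t = nai.total(E);
  double P_int = 1.0 - std::exp(-mu_t * cam.crystal_cm);
  double f_pe = nai.photo(E) / mu_t;
  // photoelectric: full-energy deposit
  score_deposit(T, W, cam, ix, iz, head, E, w_in * P_int * f_pe, comp,
                comp == PRIMARY, rng);
  // Compton interaction in the crystal: the scattered photon is either
  // reabsorbed (full-energy deposit, i.e. a photopeak event) or escapes
  // (partial deposit forming the in-crystal continuum)
  double w_c = w_in * P_int * (1.0 - f_pe);
  if (w_c > 1e-14) {
    double cost = kahn_cost(E, rng);
    double Esc = compton_E(E, cost);
    double p_reabs = 1.0 - std::exp(-nai.total(Esc) * cam.crystal_cm);
    score_deposit(T, W, cam, ix, iz, head, E, w_c * p_reabs, comp,
                  comp == PRIMARY, rng);
    double Edep = E - Esc;
    if (Edep > 1.0)
      score_deposit(T, W, cam, ix, iz, head, Edep, w_c * (1 - p_reabs),
                    comp == PRIMARY ? CAM_SCAT : comp, false, rng);
  }
  // backscatter compartment: photon crosses the crystal uninteracted,
  // Compton-scatters in a water-equivalent slab, and the backscattered
  // photon re-enters the crystal
  double w_nb = w_in * (1.0 - P_int);
  if (w_nb > 1e-14 && cam.kappa_bs > 0) {
    double P_slab = 1.0 - std::exp(-water.total(E) * cam.bs_slab_cm);
    double cost = kahn_cost(E, rng);  // single-sample over all angles
    if (cost < 0) {                   // backward hemisphere returns
      double Eb = compton_E(E, cost);
      if (Eb > 30) {
        double P2 = 1.0 - std::exp(-nai.total(Eb) * cam.crystal_cm);
        double w_bs = w_nb * P_slab * cam.kappa_bs * P2;
        // deposit may be photo (full Eb) or Compton again; use photo share
        double fpe2 = nai.photo(Eb) / nai.total(Eb);
        score_deposit(T, W, cam, ix, iz, head, Eb, w_bs * fpe2,
                      CAM_SCAT, false, rng);
        double cost2 = kahn_cost(Eb, rng);
        double Ed2 = Eb - compton_E(Eb, cost2);
        if (Ed2 > 1.0)
          score_deposit(T, W, cam, ix, iz, head, Ed2, w_bs * (1 - fpe2),
                        CAM_SCAT, false, rng);
      }
    }
  }
}

// Forced-detection score from a vertex. q_dir is the angular density toward
// the head normal relative to isotropic (1 for emission vertices,
// 4*pi*KN(theta)/sigma for Compton vertices); E is the photon energy along
// the head direction.
static void fd_score(Tally& T, const Windows& W, const Camera& cam,
                     const XS& nai, const XS& water, const XS& pb,
                     const Water& wat, const double* pos, int head,
                     double q_dir, double E, int comp, Rng& rng) {
  double s = head == 0 ? 1.0 : -1.0;
  double ix_f = pos[0] * (head == 0 ? 1.0 : -1.0);  // mirror second head
  int ix = (int)std::floor(ix_f / cam.pix_cm + cam.npix / 2.0);
  int iz = (int)std::floor(pos[2] / cam.pix_cm + cam.npix / 2.0);
  if (ix < 0 || ix >= cam.npix || iz < 0 || iz >= cam.npix) return;
  double L = wat.path_to_head(pos, s);
  double T_att = std::exp(-water.total(E) * L);
  double g = cam.g_geom(E, pb);
  double w_geom = q_dir * T_att * g;
  camera_deposit(T, W, cam, nai, water, ix, iz, head, E, w_geom, comp, rng);
  double w_pen = w_geom * cam.kappa_pen * cam.pen_T(E, pb);
  if (w_pen > 1e-14)
    camera_deposit(T, W, cam, nai, water, ix, iz, head, E, w_pen, SEPTAL, rng);
}

// Analog detection of a photon leaving the phantom with direction u.
static void analog_detect(Tally& T, const Windows& W, const Camera& cam,
                          const XS& nai, const XS& water, const XS& pb,
                          const double* pos, const double* u, double E,
                          int comp, Rng& rng) {
  int head = u[1] > 0 ? 0 : 1;
  double s = head == 0 ? 1.0 : -1.0;
  double cost = s * u[1];
  if (cost <= 0) return;
  double th = std::acos(std::min(1.0, cost));
  double th_acc = cam.theta_acc(E, pb);
  double omega_frac = 0.5 * (1.0 - std::cos(th_acc));  // acceptance cone /4pi
  double g = cam.g_geom(E, pb);
  bool pen = false;
  double p_acc = 0.0;
  if (th < th_acc) {
    p_acc = g / omega_frac;
  } else {
    // penetration cone: solid angle kappa_pen times the geometric one
    double cos_pen = 1.0 - cam.kappa_pen * (1.0 - std::cos(th_acc));
    if (cos_pen > -1 && th < std::acos(cos_pen)) {
      p_acc = g / omega_frac * cam.pen_T(E, pb);
      pen = true;
    }
  }
  if (p_acc <= 0 || rng.unif() > p_acc) return;
  // propagate to the collimator plane for the pixel position
  double t = (s * cam.dist - pos[1]) / u[1];
  double x = pos[0] + t * u[0], z = pos[2] + t * u[2];
  double ix_f = x * (head == 0 ? 1.0 : -1.0);
  int ix = (int)std::floor(ix_f / cam.pix_cm + cam.npix / 2.0);
  int iz = (int)std::floor(z / cam.pix_cm + cam.npix / 2.0);
  if (ix < 0 || ix >= cam.npix || iz < 0 || iz >= cam.npix) return;
  camera_deposit(T, W, cam, nai, water, ix, iz, head, E, 1.0,
                 pen ? SEPTAL : comp, rng);
}

// ---------------------------------------------------------- main driver ---
// [[Rcpp::export]]
List mc_projection_cpp(List phantom, List camera, NumericMatrix windows,
                       NumericMatrix lines, double n_decays, double seed,
                       List xs_water, List xs_nai, List xs_pb,
                       bool analog = false, int nebins = 800,
                       double e_kill = 45.0) {
  XS water = make_xs(xs_water), nai = make_xs(xs_nai), pb = make_xs(xs_pb);

  Water wat;
  wat.shape = as<int>(phantom["water_shape"]);
  wat.radius = as<double>(phantom["water_radius"]);
  wat.halflen = as<double>(phantom["water_halflen"]);
  if (phantom.containsElementNamed("occupancy") &&
      !Rf_isNull(phantom["occupancy"])) {
    NumericVector occ = phantom["occupancy"];
    wat.set_map(occ, as<int>(phantom["occ_n"]),
                as<double>(phantom["occ_voxel_cm"]));
  }

  NumericMatrix sm = phantom["sources"];  // shape, radius, halflen, inner_r, w
  std::vector<Source> sources;
  double wsum = 0;
  for (int i = 0; i < sm.nrow(); ++i) {
    Source s{(int)sm(i, 0), sm(i, 1), sm(i, 2), sm(i, 3), sm(i, 4)};
    if (s.weight > 0) { sources.push_back(s); wsum += s.weight; }
  }
  if (sources.empty() || wsum <= 0) stop("phantom has zero activity");

  Camera cam;
  cam.dist = as<double>(camera["dist_cm"]);
  cam.pix_cm = as<double>(camera["pixel_cm"]);
  cam.crystal_cm = as<double>(camera["crystal_cm"]);
  cam.fwhm_frac = as<double>(camera["fwhm_frac"]);
  cam.fwhm_eref = as<double>(camera["fwhm_eref_kev"]);
  cam.coll_d = as<double>(camera["hole_diameter_cm"]);
  cam.coll_l = as<double>(camera["hole_length_cm"]);
  cam.coll_t = as<double>(camera["septa_cm"]);
  cam.coll_K = as<double>(camera["shape_K"]);
  cam.kappa_pen = as<double>(camera["kappa_penetration"]);
  cam.bs_slab_cm = as<double>(camera["backscatter_slab_cm"]);
  cam.kappa_bs = as<double>(camera["kappa_backscatter"]);
  cam.npix = as<int>(camera["npix"]);

  Windows W;
  for (int k = 0; k < 3; ++k) {
    W.lo[k] = windows(k, 0);
    W.hi[k] = windows(k, 1);
  }

  int nlines = lines.nrow();
  Tally T(cam.npix, nebins);
  Rng rng((uint64_t)seed);

  long long n_emitted = 0;
  const int max_scat = 25;
  long long nd = (long long)n_decays;

  for (long long d = 0; d < nd; ++d) {
    // compartment by activity weight
    double r = rng.unif() * wsum, acc = 0;
    const Source* src = &sources.back();
    for (const auto& s : sources) {
      acc += s.weight;
      if (r <= acc) { src = &s; break; }
    }
    double p0[3];
    sample_position(*src, rng, p0);
    for (int li = 0; li < nlines; ++li) {
      if (rng.unif() >= lines(li, 1)) continue;  // emission probability
      ++n_emitted;
      double E = lines(li, 0);
      double p[3] = {p0[0], p0[1], p0[2]};
      double u[3];
      iso_dir(rng, u);
      int nscat = 0;
      // emission vertex: forced-detection score toward both heads
      if (!analog)
        for (int h = 0; h < 2; ++h)
          fd_score(T, W, cam, nai, water, pb, wat, p, h, 1.0, E, PRIMARY, rng);
      // transport through the (single, convex) water region
      bool alive = true;
      while (alive) {
        if (!wat.inside(p)) {  // in air: fly to detector (analog) and stop
          if (analog) analog_detect(T, W, cam, nai, water, pb, p, u, E,
                                    nscat == 0 ? PRIMARY : PH_SCAT, rng);
          break;
        }
        double mu = water.total(E);
        double d_exit = wat.exit_dist(p, u);
        double step = -std::log(std::max(rng.unif(), 1e-300)) / mu;
        if (step >= d_exit) {  // leaves the phantom
          if (analog) {
            for (int k = 0; k < 3; ++k) p[k] += (d_exit + 1e-9) * u[k];
            analog_detect(T, W, cam, nai, water, pb, p, u, E,
                          nscat == 0 ? PRIMARY : PH_SCAT, rng);
          }
          break;
        }
        for (int k = 0; k < 3; ++k) p[k] += step * u[k];
        if (rng.unif() < water.photo(E) / mu) break;  // photoelectric
        // Compton vertex: score the scattered-toward-head contribution
        if (!analog) {
          double sig = kn_sigma(E);
          for (int h = 0; h < 2; ++h) {
            double s = h == 0 ? 1.0 : -1.0;
            double cost = s * u[1];  // angle between incoming dir and head
            double q = 4 * M_PI * kn_dsdo(E, cost) / sig;
            fd_score(T, W, cam, nai, water, pb, wat, p, h, q,
                     compton_E(E, cost), PH_SCAT, rng);
          }
        }
        double cost = kahn_cost(E, rng);
        double phi = 2 * M_PI * rng.unif();
        double nu[3];
        rotate_dir(u, cost, phi, nu);
        for (int k = 0; k < 3; ++k) u[k] = nu[k];
        E = compton_E(E, cost);
        if (++nscat > max_scat || E < e_kill) alive = false;
      }
    }
  }

  IntegerVector dim_w = IntegerVector::create(cam.npix, cam.npix, 3, 2);
  IntegerVector dim_p = IntegerVector::create(cam.npix, cam.npix, 2);
  NumericVector win(T.win.begin(), T.win.end());
  win.attr("dim") = dim_w;
  NumericVector prim(T.primary.begin(), T.primary.end());
  prim.attr("dim") = dim_p;
  NumericMatrix spec(nebins, 4);
  for (int c = 0; c < 4; ++c)
    for (int b = 0; b < nebins; ++b) spec(b, c) = T.spec[c * nebins + b];
  return List::create(_["windows"] = win, _["primary"] = prim,
                      _["spectra"] = spec, _["n_emitted"] = (double)n_emitted,
                      _["sum_weights"] = T.sum_w);
}

// Emission sampling diagnostics: positions, directions, energies of the
// photons emitted by the first n_decays decays.
// [[Rcpp::export]]
List mc_sample_emissions_cpp(List phantom, NumericMatrix lines,
                             double n_decays, double seed) {
  NumericMatrix sm = phantom["sources"];
  std::vector<Source> sources;
  double wsum = 0;
  for (int i = 0; i < sm.nrow(); ++i) {
    Source s{(int)sm(i, 0), sm(i, 1), sm(i, 2), sm(i, 3), sm(i, 4)};
    if (s.weight > 0) { sources.push_back(s); wsum += s.weight; }
  }
  if (sources.empty() || wsum <= 0) stop("phantom has zero activity");
  Rng rng((uint64_t)seed);
  long long nd = (long long)n_decays;
  std::vector<double> px, py, pz, ux, uy, uz, en;
  for (long long d = 0; d < nd; ++d) {
    double r = rng.unif() * wsum, acc = 0;
    const Source* src = &sources.back();
    for (const auto& s : sources) {
      acc += s.weight;
      if (r <= acc) { src = &s; break; }
    }
    double p[3];
    sample_position(*src, rng, p);
    for (int li = 0; li < lines.nrow(); ++li) {
      if (rng.unif() >= lines(li, 1)) continue;
      double u[3];
      iso_dir(rng, u);
      px.push_back(p[0]); py.push_back(p[1]); pz.push_back(p[2]);
      ux.push_back(u[0]); uy.push_back(u[1]); uz.push_back(u[2]);
      en.push_back(lines(li, 0));
    }
  }
  return List::create(_["x"] = px, _["y"] = py, _["z"] = pz,
                      _["ux"] = ux, _["uy"] = uy, _["uz"] = uz,
                      _["energy"] = en);
}

// Pencil-beam transmission oracle hook: photons fired along +y through
// L cm of water; returns the unscattered-transmission frequency.
// [[Rcpp::export]]
double mc_pencil_beam_cpp(double energy, double length_cm, double n,
                          double seed, List xs_water) {
  XS water = make_xs(xs_water);
  Rng rng((uint64_t)seed);
  double mu = water.total(energy);
  long long npass = 0, nn = (long long)n;
  for (long long i = 0; i < nn; ++i) {
    double step = -std::log(std::max(rng.unif(), 1e-300)) / mu;
    if (step >= length_cm) ++npass;
  }
  return (double)npass / (double)nn;
}

// Klein-Nishina angle-sampling diagnostics.
// [[Rcpp::export]]
NumericVector mc_kahn_sample_cpp(double energy, int n, double seed) {
  Rng rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = kahn_cost(energy, rng);
  return out;
}

// Single-photon transport diagnostics: track one photon from a given state
// through the phantom's water region; returns exit state.
// [[Rcpp::export]]
List mc_transport_photon_cpp(List phantom, NumericVector pos,
                             NumericVector dir, double energy, double seed,
                             List xs_water, double e_kill = 45.0) {
  XS water = make_xs(xs_water);
  Water wat;
  wat.shape = as<int>(phantom["water_shape"]);
  wat.radius = as<double>(phantom["water_radius"]);
  wat.halflen = as<double>(phantom["water_halflen"]);
  double n2 = dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2];
  if (std::fabs(n2 - 1.0) > 1e-6) stop("direction must be a unit vector");
  Rng rng((uint64_t)seed);
  double p[3] = {pos[0], pos[1], pos[2]}, u[3] = {dir[0], dir[1], dir[2]};
  double E = energy;
  int nscat = 0;
  bool absorbed = false;
  while (wat.inside(p)) {
    double mu = water.total(E);
    double d_exit = wat.exit_dist(p, u);
    double step = -std::log(std::max(rng.unif(), 1e-300)) / mu;
    if (step >= d_exit) {
      for (int k = 0; k < 3; ++k) p[k] += (d_exit + 1e-9) * u[k];
      break;
    }
    for (int k = 0; k < 3; ++k) p[k] += step * u[k];
    if (rng.unif() < water.photo(E) / mu) { absorbed = true; break; }
    double cost = kahn_cost(E, rng);
    double phi = 2 * M_PI * rng.unif();
    double nu[3];
    rotate_dir(u, cost, phi, nu);
    for (int k = 0; k < 3; ++k) u[k] = nu[k];
    E = compton_E(E, cost);
    ++nscat;
    if (E < e_kill) { absorbed = true; break; }
  }
  return List::create(_["position"] = NumericVector::create(p[0], p[1], p[2]),
                      _["direction"] = NumericVector::create(u[0], u[1], u[2]),
                      _["energy"] = E, _["n_scatters"] = nscat,
                      _["absorbed"] = absorbed);
}
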