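// Rotation-based attenuated parallel-beam projector, its exact adjoint, and
// the OSEM reconstruction loop. The volume is rotated (bilinear
// interpolation) so that each projection is a sum along +y toward the
// detector; attenuation is accumulated voxel-by-voxel along that axis with
// a half-voxel self-attenuation convention. Projections are in counts
// (unattenuated projection of a voxel sums its counts once per angle).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Bilinear gather rotation of a single z-slice: dst(i,j) samples
// src at the point obtained by rotating (i,j) by -angle about the center.
static void rot_gather(const double* src, double* dst, int n, double c,
                       double s) {
  double ctr = (n - 1) / 2.0;
  for (int j = 0; j < n; ++j) {
    double yj = j - ctr;
    for (int i = 0; i < n; ++i) {
      double xi = i - ctr;
      double xs = c * xi + s * yj + ctr;
      double ys = -s * xi + c * yj + ctr;
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      double fx = xs - x0, fy = ys - y0;
      double v = 0;
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          int xx = x0 + dx, yy = y0 + dy;
          if (xx < 0 || xx >= n || yy < 0 || yy >= n) continue;
          double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy);
          v += w * src[yy * n + xx];
        }
      dst[j * n + i] = v;
    }
  }
}

// Exact transpose of rot_gather: scatters dst-values back to src cells
// with the same bilinear weights.
static void rot_scatter(const double* dst, double* src, int n, double c,
                        double s) {
  double ctr = (n - 1) / 2.0;
  for (int j = 0; j < n; ++j) {
    double yj = j - ctr;
    for (int i = 0; i < n; ++i) {
      double v = dst[j * n + i];
      if (v == 0) continue;
      double xi = i - ctr;
      double xs = c * xi + s * yj + ctr;
      double ys = -s * xi + c * yj + ctr;
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      double fx = xs - x0, fy = ys - y0;
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          int xx = x0 + dx, yy = y0 + dy;
          if (xx < 0 || xx >= n || yy < 0 || yy >= n) continue;
          double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy);
          src[yy * n + xx] += w * v;
        }
    }
  }
}

// Attenuation factors for one rotated mu-slice: the optical depth from each
// voxel to the detector at +y, with a half-voxel self-attenuation term:
// A(i,j) = exp(-(0.5*mu(i,j) + sum_{j'>j} mu(i,j')) * vs).
static void att_factors(const double* muR, double* A, int n, double vs) {
  for (int i = 0; i < n; ++i) {
    double cum = 0;
    for (int j = n - 1; j >= 0; --j) {
      double m = muR[j * n + i] * vs;
      A[j * n + i] = std::exp(-(cum + 0.5 * m));
      cum += m;
    }
  }
}

struct Geom {
  int n, nang;
  double vs;
  std::vector<double> cosA, sinA;
};

static Geom make_geom(int n, NumericVector angles, double vs) {
  Geom g;
  g.n = n;
  g.nang = angles.size();
  g.vs = vs;
  for (double a : angles) {
    g.cosA.push_back(std::cos(a));
    g.sinA.push_back(std::sin(a));
  }
  return g;
}

// forward projection of one angle into proj (n*n, x by z)
static void fwd_angle(const double* img, const double* mu, const Geom& g,
                      int a, double* proj) {
  int n = g.n;
  std::vector<double> sliR(n * n), muR(n * n), A(n * n);
  for (int k = 0; k < n; ++k) {
    rot_gather(img + (size_t)k * n * n, sliR.data(), n, g.cosA[a], g.sinA[a]);
    rot_gather(mu + (size_t)k * n * n, muR.data(), n, g.cosA[a], g.sinA[a]);
    att_factors(muR.data(), A.data(), n, g.vs);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        proj[k * n + i] += sliR[j * n + i] * A[j * n + i];
  }
}

// adjoint of fwd_angle: spread proj (x by z) back into img
static void bck_angle(const double* proj, const double* mu, const Geom& g,
                      int a, double* img) {
  int n = g.n;
  std::vector<double> muR(n * n), A(n * n), tmp(n * n);
  for (int k = 0; k < n; ++k) {
    rot_gather(mu + (size_t)k * n * n, muR.data(), n, g.cosA[a], g.sinA[a]);
    att_factors(muR.data(), A.data(), n, g.vs);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        tmp[j * n + i] = A[j * n + i] * proj[k * n + i];
    rot_scatter(tmp.data(), img + (size_t)k * n * n, n, g.cosA[a], g.sinA[a]);
  }
}

// [[Rcpp::export]]
NumericVector forward_project_cpp(NumericVector image, NumericVector mu,
                                  int n, NumericVector angles,
                                  double voxel_cm) {
  if (angles.size() == 0) stop("angle list is empty");
  Geom g = make_geom(n, angles, voxel_cm);
  NumericVector out((size_t)n * n * g.nang);
  for (int a = 0; a < g.nang; ++a)
    fwd_angle(REAL(image), REAL(mu), g, a, REAL(out) + (size_t)a * n * n);
  out.attr("dim") = IntegerVector::create(n, n, g.nang);
  return out;
}

// [[Rcpp::export]]
NumericVector back_project_cpp(NumericVector proj, NumericVector mu, int n,
                               NumericVector angles, double voxel_cm) {
  if (angles.size() == 0) stop("angle list is empty");
  Geom g = make_geom(n, angles, voxel_cm);
  NumericVector out((size_t)n * n * n);
  for (int a = 0; a < g.nang; ++a)
    bck_angle(REAL(proj) + (size_t)a * n * n, REAL(mu), g, a, REAL(out));
  out.attr("dim") = IntegerVector::create(n, n, n);
  return out;
}

// Full OSEM loop with the scatter estimate in the denominator:
//   x <- x * Pt_s[ y / (P_s x + s) ] / Pt_s[1]
// Attenuation factors are cached per angle (float) to keep iterations fast.
// [[Rcpp::export]]
List osem_cpp(NumericVector proj, NumericVector scatter, NumericVector mu,
              int n, NumericVector angles, int n_iter, int n_subsets,
              double voxel_cm, double eps = 1e-12,
              bool track_loglik = false) {
  Geom g = make_geom(n, angles, voxel_cm);
  if (g.nang % n_subsets != 0)
    stop("number of subsets must divide the number of projection angles");
  size_t nvox = (size_t)n * n * n, npix = (size_t)n * n;

  // cache attenuation factors per angle (float to halve memory)
  std::vector<std::vector<float>> Acache(g.nang);
  {
    std::vector<double> muR(npix), A(npix);
    for (int a = 0; a < g.nang; ++a) {
      Acache[a].resize(nvox);
      for (int k = 0; k < n; ++k) {
        rot_gather(REAL(mu) + (size_t)k * npix, muR.data(), n, g.cosA[a],
                   g.sinA[a]);
        att_factors(muR.data(), A.data(), n, g.vs);
        for (size_t t = 0; t < npix; ++t)
          Acache[a][(size_t)k * npix + t] = (float)A[t];
      }
    }
  }

  auto fwd_cached = [&](const std::vector<double>& img, int a, double* out) {
    std::vector<double> sliR(npix);
    const float* A = Acache[a].data();
    for (int k = 0; k < n; ++k) {
      rot_gather(img.data() + (size_t)k * npix, sliR.data(), n, g.cosA[a],
                 g.sinA[a]);
      const float* Ak = A + (size_t)k * npix;
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i)
          out[(size_t)k * n + i] += sliR[(size_t)j * n + i] * Ak[(size_t)j * n + i];
    }
  };
  auto bck_cached = [&](const double* pr, int a, std::vector<double>& img) {
    std::vector<double> tmp(npix);
    const float* A = Acache[a].data();
    for (int k = 0; k < n; ++k) {
      const float* Ak = A + (size_t)k * npix;
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i)
          tmp[(size_t)j * n + i] = Ak[(size_t)j * n + i] * pr[(size_t)k * n + i];
      rot_scatter(tmp.data(), img.data() + (size_t)k * npix, n, g.cosA[a],
                  g.sinA[a]);
    }
  };

  // subset membership: interleaved angle indices
  std::vector<std::vector<int>> subsets(n_subsets);
  for (int a = 0; a < g.nang; ++a) subsets[a % n_subsets].push_back(a);

  // per-subset sensitivity images Pt_s[1]
  std::vector<std::vector<double>> sens(n_subsets,
                                        std::vector<double>(nvox, 0.0));
  {
    std::vector<double> ones(npix, 1.0);
    for (int s = 0; s < n_subsets; ++s)
      for (int a : subsets[s]) bck_cached(ones.data(), a, sens[s]);
  }

  std::vector<double> x(nvox, 1.0);
  NumericVector loglik(track_loglik ? n_iter : 0);
  std::vector<double> fp(npix), ratio(npix), upd(nvox);

  for (int it = 0; it < n_iter; ++it) {
    for (int s = 0; s < n_subsets; ++s) {
      std::fill(upd.begin(), upd.end(), 0.0);
      for (int a : subsets[s]) {
        std::fill(fp.begin(), fp.end(), 0.0);
        fwd_cached(x, a, fp.data());
        const double* y = REAL(proj) + (size_t)a * npix;
        const double* sc = REAL(scatter) + (size_t)a * npix;
        for (size_t t = 0; t < npix; ++t)
          ratio[t] = y[t] / (fp[t] + sc[t] + eps);
        bck_cached(ratio.data(), a, upd);
      }
      for (size_t v = 0; v < nvox; ++v) {
        double d = sens[s][v];
        x[v] = d > eps ? x[v] * upd[v] / d : 0.0;
      }
    }
    if (track_loglik) {
      double ll = 0;
      for (int a = 0; a < g.nang; ++a) {
        std::fill(fp.begin(), fp.end(), 0.0);
        fwd_cached(x, a, fp.data());
        const double* y = REAL(proj) + (size_t)a * npix;
        const double* sc = REAL(scatter) + (size_t)a * npix;
        for (size_t t = 0; t < npix; ++t) {
          double lam = fp[t] + sc[t] + eps;
          ll += y[t] * std::log(lam) - lam;
        }
      }
      loglik[it] = ll;
    }
  }

  NumericVector img(x.begin(), x.end());
  img.attr("dim") = IntegerVector::create(n, n, n);
  return List::create(_["image"] = img, _["loglik"] = loglik);
}
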