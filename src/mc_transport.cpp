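// Voxel Monte-Carlo photon transport for turbid media.
//
// Weighted-photon random walk: free paths are sampled from the local total
// interaction coefficient, absorption is handled by implicit capture at
// collision sites (w *= mus/mut) and fluence is tallied with the track-length
// estimator (sum of w * segment length per voxel), which is unbiased for the
// same transport kernel and has lower variance than the collision estimator,
// in particular in voxels where mua or mut is (near) zero.
//
// All lengths are in mm here; the R wrapper converts optical coefficients
// from 1/cm and normalizes the tally to fluence per unit delivered energy
// in 1/cm^2.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

// splitmix64: used both as a stream seeder and to decorrelate photon indices.
inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoshiro256+ seeded per photon so results do not depend on launch order.
struct Xoshiro {
  uint64_t s[4];
  void seed(uint64_t run_seed, uint64_t stream) {
    uint64_t x = run_seed * 0xD1342543DE82EF95ULL + (stream + 1) * 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform in (0, 1]
  inline double unif_pos() { return 1.0 - unif(); }
};

struct Vec3 { double x, y, z; };

// Unit vector on the circle without trig calls (Marsaglia polar method).
inline void circle_point(Xoshiro &rng, double &cosp, double &sinp) {
  double a, b, s;
  do {
    a = 2.0 * rng.unif() - 1.0;
    b = 2.0 * rng.unif() - 1.0;
    s = a * a + b * b;
  } while (s >= 1.0 || s < 1e-12);
  cosp = (a * a - b * b) / s;
  sinp = 2.0 * a * b / s;
}

// Rotate a direction sampled about +z (cost, cosp/sinp) into the frame of `d`.
inline Vec3 rotate_dir(const Vec3 &d, double cost, double cosp, double sinp) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  Vec3 out;
  if (std::fabs(d.z) > 0.999999) {
    out.x = sint * cosp;
    out.y = sint * sinp;
    out.z = cost * (d.z >= 0 ? 1.0 : -1.0);
  } else {
    double tmp = std::sqrt(1.0 - d.z * d.z);
    out.x = sint * (d.x * d.z * cosp - d.y * sinp) / tmp + d.x * cost;
    out.y = sint * (d.y * d.z * cosp + d.x * sinp) / tmp + d.y * cost;
    out.z = -sint * cosp * tmp + d.z * cost;
  }
  double n = std::sqrt(out.x * out.x + out.y * out.y + out.z * out.z);
  out.x /= n; out.y /= n; out.z /= n;
  return out;
}

// Henyey-Greenstein cos(theta) sample; g = 0 reduces to isotropic.
inline double hg_cost(double g, double u) {
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  return std::min(1.0, std::max(-1.0, c));
}

// Emission direction inside a cone of half-angle acos(cos_half) about `axis`.
// Uniform over solid angle by default; optional cosine weighting (only
// meaningful for half-angles <= 90 degrees).
inline Vec3 cone_dir(const Vec3 &axis, double cos_half, bool cosine, Xoshiro &rng) {
  double u = rng.unif();
  double cost;
  if (cosine && cos_half >= 0.0) {
    cost = std::sqrt(cos_half * cos_half + u * (1.0 - cos_half * cos_half));
  } else {
    cost = 1.0 - u * (1.0 - cos_half);
  }
  double cosp, sinp;
  circle_point(rng, cosp, sinp);
  return rotate_dir(axis, cost, cosp, sinp);
}

// Slab-method ray/box intersection; returns entry parameter t >= 0 or -1.
inline double ray_box(const Vec3 &p, const Vec3 &d,
                      const double lo[3], const double hi[3]) {
  double t0 = 0.0, t1 = std::numeric_limits<double>::infinity();
  const double pp[3] = { p.x, p.y, p.z };
  const double dd[3] = { d.x, d.y, d.z };
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(dd[k]) < 1e-15) {
      if (pp[k] < lo[k] || pp[k] > hi[k]) return -1.0;
    } else {
      double ta = (lo[k] - pp[k]) / dd[k];
      double tb = (hi[k] - pp[k]) / dd[k];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
      if (t0 > t1) return -1.0;
    }
  }
  return t0;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".mc_transport")]]
List mc_transport(IntegerVector dims, double spacing, NumericVector origin,
                  IntegerVector labels,
                  NumericVector mua, NumericVector mus, NumericVector gpar,
                  NumericMatrix src_pos, NumericMatrix src_axis,
                  NumericVector src_cos_half, NumericVector src_cumprob,
                  bool cosine_weighted,
                  double n_photons, int seed,
                  double rr_threshold, double rr_factor,
                  int max_steps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (labels.size() != nvox) stop("label volume does not match grid dims");
  const double h = spacing;
  const double lo[3] = { origin[0], origin[1], origin[2] };
  const double hi[3] = { origin[0] + nx * h, origin[1] + ny * h, origin[2] + nz * h };
  const int nsrc = src_pos.nrow();
  const int nlab = mua.size();
  const long long nph = (long long)n_photons;
  if (nph < 1) stop("n_photons must be >= 1");

  std::vector<double> flu(nvox, 0.0);
  const int *lab = INTEGER(labels);

  double absorbed = 0.0, escaped = 0.0;
  double roulette_loss = 0.0, roulette_gain = 0.0, residual = 0.0;
  const double eps = 1e-9;

  for (long long ip = 0; ip < nph; ++ip) {
    Xoshiro rng;
    rng.seed((uint64_t)(uint32_t)seed, (uint64_t)ip);

    // pick an emitting element proportional to its relative power
    double u = rng.unif();
    int el = 0;
    while (el < nsrc - 1 && u > src_cumprob[el]) ++el;

    Vec3 pos = { src_pos(el, 0), src_pos(el, 1), src_pos(el, 2) };
    Vec3 axis = { src_axis(el, 0), src_axis(el, 1), src_axis(el, 2) };
    Vec3 dir = cone_dir(axis, src_cos_half[el], cosine_weighted, rng);
    double w = 1.0;

    // photons starting outside the grid fly in a straight line to it
    if (pos.x < lo[0] || pos.x >= hi[0] || pos.y < lo[1] || pos.y >= hi[1] ||
        pos.z < lo[2] || pos.z >= hi[2]) {
      double t = ray_box(pos, dir, lo, hi);
      if (t < 0) { escaped += w; continue; }
      pos.x += dir.x * (t + eps);
      pos.y += dir.y * (t + eps);
      pos.z += dir.z * (t + eps);
    }

    int ix = (int)std::floor((pos.x - lo[0]) / h);
    int iy = (int)std::floor((pos.y - lo[1]) / h);
    int iz = (int)std::floor((pos.z - lo[2]) / h);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
      escaped += w; continue;
    }

    double tau = -std::log(rng.unif_pos());
    int steps = 0;
    bool alive = true;

    while (alive) {
      if (++steps > max_steps) { residual += w; break; }
      R_xlen_t idx = (R_xlen_t)ix + (R_xlen_t)nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
      int l = lab[idx];
      if (l < 0 || l >= nlab) stop("label out of range of property tables");
      double ma = mua[l], ms = mus[l];
      double mt = ma + ms;

      // distance to the nearest voxel face along dir
      double db = std::numeric_limits<double>::infinity();
      int bk = -1, bstep = 0;
      {
        double t;
        if (dir.x > 1e-12) { t = (lo[0] + (ix + 1) * h - pos.x) / dir.x; if (t < db) { db = t; bk = 0; bstep = 1; } }
        else if (dir.x < -1e-12) { t = (lo[0] + ix * h - pos.x) / dir.x; if (t < db) { db = t; bk = 0; bstep = -1; } }
        if (dir.y > 1e-12) { t = (lo[1] + (iy + 1) * h - pos.y) / dir.y; if (t < db) { db = t; bk = 1; bstep = 1; } }
        else if (dir.y < -1e-12) { t = (lo[1] + iy * h - pos.y) / dir.y; if (t < db) { db = t; bk = 1; bstep = -1; } }
        if (dir.z > 1e-12) { t = (lo[2] + (iz + 1) * h - pos.z) / dir.z; if (t < db) { db = t; bk = 2; bstep = 1; } }
        else if (dir.z < -1e-12) { t = (lo[2] + iz * h - pos.z) / dir.z; if (t < db) { db = t; bk = 2; bstep = -1; } }
        if (db < 0) db = 0;
      }

      double dcol = (mt > 0) ? tau / mt : std::numeric_limits<double>::infinity();

      if (dcol < db) {
        // collision inside this voxel
        pos.x += dir.x * dcol; pos.y += dir.y * dcol; pos.z += dir.z * dcol;
        flu[idx] += w * dcol;
        if (ma > 0) {
          double a = ma / mt;
          absorbed += w * a;
          w *= (1.0 - a);
        }
        double cosp, sinp;
        circle_point(rng, cosp, sinp);
        dir = rotate_dir(dir, hg_cost(gpar[l], rng.unif()), cosp, sinp);
        tau = -std::log(rng.unif_pos());
        if (w < rr_threshold) {
          if (rng.unif() * rr_factor < 1.0) {
            roulette_gain += w * (rr_factor - 1.0);
            w *= rr_factor;
          } else {
            roulette_loss += w;
            alive = false;
          }
        }
      } else {
        // advance to the voxel face and step into the neighbor
        flu[idx] += w * db;
        tau -= mt * db;
        pos.x += dir.x * db; pos.y += dir.y * db; pos.z += dir.z * db;
        if (bk == 0) { ix += bstep; pos.x = lo[0] + (bstep > 0 ? ix : ix + 1) * h; }
        else if (bk == 1) { iy += bstep; pos.y = lo[1] + (bstep > 0 ? iy : iy + 1) * h; }
        else if (bk == 2) { iz += bstep; pos.z = lo[2] + (bstep > 0 ? iz : iz + 1) * h; }
        else { residual += w; break; } // degenerate direction
        if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
          escaped += w;
          alive = false;
        }
      }
    }
    if ((ip & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector out(nvox);
  std::copy(flu.begin(), flu.end(), out.begin());
  return List::create(
    _["fluence"] = out,
    _["launched"] = (double)nph,
    _["absorbed"] = absorbed,
    _["escaped"] = escaped,
    _["roulette_loss"] = roulette_loss,
    _["roulette_gain"] = roulette_gain,
    _["residual"] = residual);
}

//' @noRd
// [[Rcpp::export(name = ".hg_sample")]]
NumericVector hg_sample(int n, double g, int seed) {
  NumericVector out(n);
  Xoshiro rng;
  rng.seed((uint64_t)(uint32_t)seed, 0x48474747ULL);
  for (int i = 0; i < n; ++i) out[i] = hg_cost(g, rng.unif());
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cone_sample")]]
NumericMatrix cone_sample(int n, NumericVector axis, double cos_half,
                          bool cosine, int seed) {
  NumericMatrix out(n, 3);
  Xoshiro rng;
  rng.seed((uint64_t)(uint32_t)seed, 0x434F4E45ULL);
  Vec3 ax = { axis[0], axis[1], axis[2] };
  for (int i = 0; i < n; ++i) {
    Vec3 d = cone_dir(ax, cos_half, cosine, rng);
    out(i, 0) = d.x; out(i, 1) = d.y; out(i, 2) = d.z;
  }
  return out;
}
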