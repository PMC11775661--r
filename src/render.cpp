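#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "prng.h"

// Band-wise backward path tracer with next-event estimation for scenes made
// of analytic primitives (z-aligned cylinder shells, discs, rectangles with
// an optional circular aperture) containing one homogeneous
// scattering/absorbing medium region (a z-aligned cylinder volume).
//
// Surface matrix layout (one row per surface, 18 columns):
//   0: type              1 = cylinder lateral, 2 = disc, 3 = rect
//   1..12: geometry
//     cylinder: cx, cy, z0, z1, R, orient (+1 outward normals, -1 inward)
//     disc:     cx, cy, cz, nx, ny, nz, R, hole_r
//     rect:     p0(3), u(3), v(3), hole_u, hole_v, hole_r  (hole in local
//               metric coordinates along unit u/v)
//   13: material         0 = matte, 1 = metal, 2 = thin glass, 3 = emitter
//   14: material param   matte albedo / metal reflectance / glass ior
//   15: emitted radiance on the current band (emitters only)
//   16: cone cos half-angle for spot emitters; <= -1.5 means diffuse
//   17: two-sided emission flag (0/1)
//   18: metal gloss fraction: share of the reflectance that is mirror-like;
//       the rest reflects diffusely (rough industrial steel)
//
// Medium vector: cx, cy, z0, z1, R, sigma_a, sigma_s, g (already scaled by
// the density multiplier); length 0 = no participating medium.
//
// Camera vector: pos(3), forward(3), right(3), up(3), tan(fov/2).

namespace {

const double EPS = 1e-7;

struct Vec {
  double x, y, z;
};
static inline Vec vec(double x, double y, double z) { Vec v{x, y, z}; return v; }
static inline Vec operator+(Vec a, Vec b) { return vec(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline Vec operator-(Vec a, Vec b) { return vec(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline Vec operator*(Vec a, double s) { return vec(a.x * s, a.y * s, a.z * s); }
static inline double dot(Vec a, Vec b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec cross(Vec a, Vec b) {
  return vec(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(Vec a) { return std::sqrt(dot(a, a)); }
static inline Vec normalize(Vec a) { double n = norm(a); return vec(a.x / n, a.y / n, a.z / n); }

static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double s = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - s * s) / (2.0 * g);
}
static inline double hg_phase_sr(double g, double mu) {  // pdf per steradian
  double denom = 1.0 + g * g - 2.0 * g * mu;
  return (1.0 - g * g) / (4.0 * M_PI * denom * std::sqrt(denom));
}

static inline Vec rotate_frame(Vec w, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  Vec a = (std::fabs(w.x) < 0.9) ? vec(1, 0, 0) : vec(0, 1, 0);
  Vec u = normalize(cross(w, a));
  Vec v = cross(w, u);
  return normalize(u * (st * std::cos(phi)) + v * (st * std::sin(phi)) + w * ct);
}

// exact unpolarized Fresnel reflectance, external/internal symmetric for a
// thin sheet entered from air
static inline double fresnel_reflect(double cosi, double ior) {
  cosi = std::fabs(cosi);
  double sint2 = (1.0 - cosi * cosi) / (ior * ior);
  if (sint2 >= 1.0) return 1.0;
  double cost = std::sqrt(1.0 - sint2);
  double rs = (cosi - ior * cost) / (cosi + ior * cost);
  double rp = (ior * cosi - cost) / (ior * cosi + cost);
  return 0.5 * (rs * rs + rp * rp);
}

struct Hit {
  double t;
  int idx;      // surface row
  Vec p, n;     // point, geometric normal (as stored orientation)
};

class Scene {
public:
  Rcpp::NumericMatrix S;
  bool has_medium;
  double mcx, mcy, mz0, mz1, mR, msa, mss, mst, mg;
  std::vector<int> emitters;
  std::vector<double> em_area, em_cum;
  double em_total;

  Scene(Rcpp::NumericMatrix S_, Rcpp::NumericVector med) : S(S_) {
    has_medium = med.size() >= 8;
    if (has_medium) {
      mcx = med[0]; mcy = med[1]; mz0 = med[2]; mz1 = med[3]; mR = med[4];
      msa = med[5]; mss = med[6]; mg = med[7];
      mst = msa + mss;
      if (mst <= 0) has_medium = false;
    } else {
      mcx = mcy = mz0 = mz1 = mR = msa = mss = mst = mg = 0.0;
    }
    em_total = 0.0;
    for (int i = 0; i < S.nrow(); ++i) {
      if ((int)S(i, 13) == 3 && S(i, 15) > 0) {
        emitters.push_back(i);
        double a = surface_area(i);
        em_area.push_back(a);
        em_total += a;
        em_cum.push_back(em_total);
      }
    }
  }

  double surface_area(int i) const {
    int type = (int)S(i, 0);
    if (type == 1) return 2.0 * M_PI * S(i, 5) * (S(i, 4) - S(i, 3));
    if (type == 2) {
      double R = S(i, 7), hr = S(i, 8);
      return M_PI * (R * R - hr * hr);
    }
    Vec u = vec(S(i, 4), S(i, 5), S(i, 6));
    Vec v = vec(S(i, 7), S(i, 8), S(i, 9));
    double a = norm(cross(u, v));
    double hr = S(i, 12);
    return a - M_PI * hr * hr;
  }

  // intersection of ray with surface i; returns t > tmin or -1; fills normal
  double intersect(int i, Vec o, Vec d, double tmin, Vec &nrm) const {
    int type = (int)S(i, 0);
    if (type == 1) {  // cylinder lateral
      double cx = S(i, 1), cy = S(i, 2), z0 = S(i, 3), z1 = S(i, 4), R = S(i, 5);
      double ox = o.x - cx, oy = o.y - cy;
      double a = d.x * d.x + d.y * d.y;
      if (a < 1e-16) return -1.0;
      double b = ox * d.x + oy * d.y;
      double c = ox * ox + oy * oy - R * R;
      double disc = b * b - a * c;
      if (disc < 0) return -1.0;
      double sq = std::sqrt(disc);
      for (int k = 0; k < 2; ++k) {
        double t = (k == 0) ? (-b - sq) / a : (-b + sq) / a;
        if (t <= tmin) continue;
        double z = o.z + t * d.z;
        if (z < z0 || z > z1) continue;
        Vec p = o + d * t;
        double sgn = S(i, 6); // orientation
        nrm = normalize(vec((p.x - cx) * sgn, (p.y - cy) * sgn, 0.0));
        return t;
      }
      return -1.0;
    }
    if (type == 2) {  // disc with optional hole
      Vec c = vec(S(i, 1), S(i, 2), S(i, 3));
      Vec n = normalize(vec(S(i, 4), S(i, 5), S(i, 6)));
      double denom = dot(n, d);
      if (std::fabs(denom) < 1e-14) return -1.0;
      double t = dot(n, c - o) / denom;
      if (t <= tmin) return -1.0;
      Vec p = o + d * t;
      double rr = norm(p - c);
      if (rr > S(i, 7) || rr < S(i, 8)) return -1.0;
      nrm = n;
      return t;
    }
    // rect with optional circular aperture
    Vec p0 = vec(S(i, 1), S(i, 2), S(i, 3));
    Vec u = vec(S(i, 4), S(i, 5), S(i, 6));
    Vec v = vec(S(i, 7), S(i, 8), S(i, 9));
    Vec n = normalize(cross(u, v));
    double denom = dot(n, d);
    if (std::fabs(denom) < 1e-14) return -1.0;
    double t = dot(n, p0 - o) / denom;
    if (t <= tmin) return -1.0;
    Vec p = o + d * t;
    Vec rel = p - p0;
    double lu = norm(u), lv = norm(v);
    double a = dot(rel, u) / lu, b = dot(rel, v) / lv;
    if (a < 0 || a > lu || b < 0 || b > lv) return -1.0;
    double hr = S(i, 12);
    if (hr > 0) {
      double da = a - S(i, 10), db = b - S(i, 11);
      if (da * da + db * db < hr * hr) return -1.0;  // passes through aperture
    }
    nrm = n;
    return t;
  }

  bool nearest(Vec o, Vec d, Hit &h) const {
    h.t = 1e300; h.idx = -1;
    Vec nrm;
    for (int i = 0; i < S.nrow(); ++i) {
      double t = intersect(i, o, d, EPS, nrm);
      if (t > 0 && t < h.t) { h.t = t; h.idx = i; h.n = nrm; }
    }
    if (h.idx < 0) return false;
    h.p = o + d * h.t;
    return true;
  }

  // overlap of ray segment [0, tmax] with the medium cylinder volume
  double medium_overlap(Vec o, Vec d, double tmax, double &t_in) const {
    t_in = 0.0;
    if (!has_medium || tmax <= 0) return 0.0;
    double ox = o.x - mcx, oy = o.y - mcy;
    double a = d.x * d.x + d.y * d.y;
    double t0, t1;
    if (a < 1e-16) {
      double rr = ox * ox + oy * oy;
      if (rr > mR * mR) return 0.0;
      t0 = -1e300; t1 = 1e300;
    } else {
      double b = ox * d.x + oy * d.y;
      double c = ox * ox + oy * oy - mR * mR;
      double disc = b * b - a * c;
      if (disc < 0) return 0.0;
      double sq = std::sqrt(disc);
      t0 = (-b - sq) / a;
      t1 = (-b + sq) / a;
    }
    // clip by z slabs
    if (std::fabs(d.z) > 1e-16) {
      double ta = (mz0 - o.z) / d.z, tb = (mz1 - o.z) / d.z;
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    } else if (o.z < mz0 || o.z > mz1) return 0.0;
    t0 = std::max(t0, 0.0);
    t1 = std::min(t1, tmax);
    if (t1 <= t0) return 0.0;
    t_in = t0;
    return t1 - t0;
  }

  // transmission from x to y (0 if blocked by an opaque surface; thin glass
  // multiplies; medium attenuates exponentially); `target` is the emitter
  // surface the endpoint lies on.
  double shadow_transmission(Vec x, Vec y, int target) const {
    Vec seg = y - x;
    double dist = norm(seg);
    if (dist < 1e-12) return 0.0;
    Vec d = seg * (1.0 / dist);
    double trans = 1.0;
    Vec nrm;
    for (int i = 0; i < S.nrow(); ++i) {
      // collect every crossing of surface i strictly inside the segment
      double tmin = EPS;
      for (int guard = 0; guard < 8; ++guard) {
        double t = intersect(i, x, d, tmin, nrm);
        if (t < 0 || t > dist - 1e-6) break;
        if (i == target) { tmin = t + EPS; continue; }  // grazing same-surface hit: treat conservatively
        int mat = (int)S(i, 13);
        if (mat == 2) {
          trans *= (1.0 - fresnel_reflect(dot(nrm, d), S(i, 14)));
          tmin = t + EPS;
          continue;
        }
        return 0.0;  // matte, metal and emitter surfaces are opaque
      }
    }
    if (has_medium) {
      double t_in;
      double len = medium_overlap(x, d, dist, t_in);
      trans *= std::exp(-mst * len);
    }
    return trans;
  }

  // pick an emitter point uniformly by area
  void sample_emitter(PbrRng &rng, Vec &p, Vec &n, int &idx) const {
    double u = rng.unif() * em_total;
    size_t k = 0;
    while (k + 1 < em_cum.size() && u > em_cum[k]) ++k;
    idx = emitters[k];
    int i = idx;
    int type = (int)S(i, 0);
    if (type == 1) {
      double phi = 2.0 * M_PI * rng.unif();
      double z = S(i, 3) + (S(i, 4) - S(i, 3)) * rng.unif();
      double R = S(i, 5), sgn = S(i, 6);
      p = vec(S(i, 1) + R * std::cos(phi), S(i, 2) + R * std::sin(phi), z);
      n = vec(std::cos(phi) * sgn, std::sin(phi) * sgn, 0.0);
    } else if (type == 2) {
      double R = S(i, 7), hr = S(i, 8);
      double r = std::sqrt(hr * hr + (R * R - hr * hr) * rng.unif());
      double phi = 2.0 * M_PI * rng.unif();
      Vec nn = normalize(vec(S(i, 4), S(i, 5), S(i, 6)));
      Vec a = (std::fabs(nn.x) < 0.9) ? vec(1, 0, 0) : vec(0, 1, 0);
      Vec e1 = normalize(cross(nn, a));
      Vec e2 = cross(nn, e1);
      p = vec(S(i, 1), S(i, 2), S(i, 3)) + e1 * (r * std::cos(phi)) + e2 * (r * std::sin(phi));
      n = nn;
    } else {
      Vec p0 = vec(S(i, 1), S(i, 2), S(i, 3));
      Vec uu = vec(S(i, 4), S(i, 5), S(i, 6));
      Vec vv = vec(S(i, 7), S(i, 8), S(i, 9));
      double lu = norm(uu), lv = norm(vv), hr = S(i, 12);
      double a, b;
      for (int guard = 0; guard < 64; ++guard) {
        a = lu * rng.unif(); b = lv * rng.unif();
        if (hr <= 0) break;
        double da = a - S(i, 10), db = b - S(i, 11);
        if (da * da + db * db >= hr * hr) break;
      }
      p = p0 + uu * (a / lu) + vv * (b / lv);
      n = normalize(cross(uu, vv));
    }
  }

  // emitted radiance from surface i at point with normal n toward direction
  // dir (unit, pointing away from the surface)
  double emitted(int i, Vec n, Vec dir) const {
    double L = S(i, 15);
    if (L <= 0) return 0.0;
    double c = dot(n, dir);
    bool two_sided = S(i, 17) > 0.5;
    double cone = S(i, 16);
    if (two_sided) c = std::fabs(c);
    if (c <= 0) return 0.0;
    if (cone > -1.5 && c < cone) return 0.0;  // outside the spot cone
    return L;
  }
};

struct Camera {
  Vec pos, fwd, right, up;
  double tanhalf;
  int W, H;
  Vec ray_dir(double px, double py) const {  // px,py in [0,1) across image
    double aspect = (double)W / (double)H;
    double sx = (2.0 * px - 1.0) * tanhalf * aspect;
    double sy = (1.0 - 2.0 * py) * tanhalf;
    return normalize(fwd + right * sx + up * sy);
  }
};

double trace_path(const Scene &sc, Vec o, Vec d, PbrRng &rng,
                  int max_bounces, int rr_start) {
  double L = 0.0, w = 1.0;
  bool specular_chain = true;
  for (int bounce = 0; bounce < max_bounces; ++bounce) {
    Hit h;
    bool hit = sc.nearest(o, d, h);
    double t_surf = hit ? h.t : 1e300;

    if (sc.has_medium) {
      double t_in;
      double len = sc.medium_overlap(o, d, t_surf, t_in);
      if (len > 0) {
        double s = -std::log(1.0 - rng.unif()) / sc.mst;
        if (s < len) {
          // volume scattering event
          Vec x = o + d * (t_in + s);
          w *= sc.mss / sc.mst;
          specular_chain = false;
          if (w <= 0) return L;
          if (sc.em_total > 0) {
            Vec ep, en; int eidx;
            sc.sample_emitter(rng, ep, en, eidx);
            Vec seg = ep - x;
            double dist = norm(seg);
            if (dist > 1e-9) {
              Vec dl = seg * (1.0 / dist);
              double Le = sc.emitted(eidx, en, dl * (-1.0));
              if (Le > 0) {
                double cos_e = std::fabs(dot(en, dl));
                double T = sc.shadow_transmission(x, ep, eidx);
                if (T > 0) {
                  double ph = hg_phase_sr(sc.mg, dot(d, dl));
                  L += w * Le * ph * cos_e / (dist * dist) * sc.em_total * T;
                }
              }
            }
          }
          double ct = hg_cos(sc.mg, rng.unif());
          double phi = 2.0 * M_PI * rng.unif();
          o = x;
          d = rotate_frame(d, ct, phi);
          if (bounce >= rr_start) {
            double q = std::min(1.0, std::max(w, 0.05));
            if (rng.unif() >= q) return L;
            w /= q;
          }
          continue;
        }
      }
    }

    if (!hit) return L;  // escaped to the black background

    int mat = (int)sc.S(h.idx, 13);
    if (mat == 3) {  // emitter: opaque, counted only on specular chains (NEE
                     // already accounts for scattered connections)
      if (specular_chain) {
        double Le = sc.emitted(h.idx, h.n, d * (-1.0));
        L += w * Le;
      }
      return L;
    }
    if (mat == 0) {  // matte (Lambertian); albedo 0 is the black absorber
      double rho = sc.S(h.idx, 14);
      if (rho <= 0) return L;
      Vec n = (dot(h.n, d) < 0) ? h.n : h.n * (-1.0);
      specular_chain = false;
      if (sc.em_total > 0) {
        Vec ep, en; int eidx;
        sc.sample_emitter(rng, ep, en, eidx);
        Vec x = h.p + n * (10 * EPS);
        Vec seg = ep - x;
        double dist = norm(seg);
        if (dist > 1e-9) {
          Vec dl = seg * (1.0 / dist);
          double cos_x = dot(n, dl);
          double Le = sc.emitted(eidx, en, dl * (-1.0));
          if (cos_x > 0 && Le > 0) {
            double cos_e = std::fabs(dot(en, dl));
            double T = sc.shadow_transmission(x, ep, eidx);
            if (T > 0)
              L += w * (rho / M_PI) * cos_x * cos_e / (dist * dist) *
                   sc.em_total * Le * T;
          }
        }
      }
      // cosine-weighted bounce
      w *= rho;
      double u1 = rng.unif(), u2 = rng.unif();
      double ct = std::sqrt(1.0 - u1);        // cos(theta) ~ sqrt(1-u)
      Vec nd = rotate_frame(n, ct, 2.0 * M_PI * u2);
      o = h.p + n * (10 * EPS);
      d = nd;
    } else if (mat == 1) {  // metal: glossy, flat reflectance split into a
                            // mirror lobe and a diffuse lobe
      double refl = sc.S(h.idx, 14);
      double gloss = sc.S(h.idx, 18);
      Vec n = (dot(h.n, d) < 0) ? h.n : h.n * (-1.0);
      w *= refl;
      if (rng.unif() < gloss) {          // mirror lobe
        d = d - n * (2.0 * dot(d, n));
        o = h.p + n * (10 * EPS);
      } else {                           // diffuse lobe with NEE
        specular_chain = false;
        if (sc.em_total > 0) {
          Vec ep, en; int eidx;
          sc.sample_emitter(rng, ep, en, eidx);
          Vec x = h.p + n * (10 * EPS);
          Vec seg = ep - x;
          double dist = norm(seg);
          if (dist > 1e-9) {
            Vec dl = seg * (1.0 / dist);
            double cos_x = dot(n, dl);
            double Le = sc.emitted(eidx, en, dl * (-1.0));
            if (cos_x > 0 && Le > 0) {
              double cos_e = std::fabs(dot(en, dl));
              double T = sc.shadow_transmission(x, ep, eidx);
              if (T > 0)
                L += w * (1.0 / M_PI) * cos_x * cos_e / (dist * dist) *
                     sc.em_total * Le * T;
            }
          }
        }
        double u1 = rng.unif(), u2 = rng.unif();
        double ct = std::sqrt(1.0 - u1);
        d = rotate_frame(n, ct, 2.0 * M_PI * u2);
        o = h.p + n * (10 * EPS);
      }
    } else {  // thin glass: Fresnel reflect or pass straight through
      double ior = sc.S(h.idx, 14);
      Vec n = (dot(h.n, d) < 0) ? h.n : h.n * (-1.0);
      double R = fresnel_reflect(dot(n, d), ior);
      if (rng.unif() < R) {
        d = d - n * (2.0 * dot(d, n));
        o = h.p + n * (10 * EPS);
      } else {
        o = h.p + d * (10 * EPS);  // continue straight (thin sheet)
      }
    }
    if (bounce >= rr_start) {
      double q = std::min(1.0, std::max(w, 0.05));
      if (rng.unif() >= q) return L;
      w /= q;
    }
  }
  return L;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_render_band(Rcpp::NumericMatrix surfaces,
                                    Rcpp::NumericVector medium,
                                    Rcpp::NumericVector camera,
                                    int width, int height,
                                    int spp, int max_bounces, int rr_start,
                                    double seed, int band_index) {
  Scene sc(surfaces, medium);
  Camera cam;
  cam.pos = vec(camera[0], camera[1], camera[2]);
  cam.fwd = vec(camera[3], camera[4], camera[5]);
  cam.right = vec(camera[6], camera[7], camera[8]);
  cam.up = vec(camera[9], camera[10], camera[11]);
  cam.tanhalf = camera[12];
  cam.W = width; cam.H = height;

  Rcpp::NumericMatrix img(height, width);
  const uint64_t seed64 = (uint64_t)seed;
  PbrRng rng;
  for (int i = 0; i < height; ++i) {
    for (int j = 0; j < width; ++j) {
      double acc = 0.0;
      uint64_t pix = (uint64_t)i * width + j;
      for (int s = 0; s < spp; ++s) {
        rng.seed_from(seed64, (uint64_t)band_index, pix, (uint64_t)s);
        double px = (j + rng.unif()) / width;
        double py = (i + rng.unif()) / height;
        Vec d = cam.ray_dir(px, py);
        acc += trace_path(sc, cam.pos, d, rng, max_bounces, rr_start);
      }
      img(i, j) = acc / spp;
    }
    Rcpp::checkUserInterrupt();
  }
  return img;
}

// First-hit classification for the surface mask: 1 where the primary ray's
// first hit is the top surface of the medium, 0 elsewhere. Surfaces
// coplanar with the medium top (lamp caps) win ties.
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_surface_mask(Rcpp::NumericMatrix surfaces,
                                     Rcpp::NumericVector medium,
                                     Rcpp::NumericVector camera,
                                     int width, int height) {
  Scene sc(surfaces, medium);
  Camera cam;
  cam.pos = vec(camera[0], camera[1], camera[2]);
  cam.fwd = vec(camera[3], camera[4], camera[5]);
  cam.right = vec(camera[6], camera[7], camera[8]);
  cam.up = vec(camera[9], camera[10], camera[11]);
  cam.tanhalf = camera[12];
  cam.W = width; cam.H = height;

  bool has_medium = medium.size() >= 5;
  Rcpp::IntegerMatrix mask(height, width);
  for (int i = 0; i < height; ++i) {
    for (int j = 0; j < width; ++j) {
      Vec d = cam.ray_dir((j + 0.5) / width, (i + 0.5) / height);
      Hit h;
      bool hit = sc.nearest(cam.pos, d, h);
      double t_surf = hit ? h.t : 1e300;
      int val = 0;
      if (has_medium && std::fabs(d.z) > 1e-14) {
        double t_top = (medium[3] - cam.pos.z) / d.z;  // medium top plane z1
        if (t_top > EPS && t_top < t_surf - 1e-9) {
          double x = cam.pos.x + t_top * d.x - medium[0];
          double y = cam.pos.y + t_top * d.y - medium[1];
          if (x * x + y * y <= medium[4] * medium[4]) val = 1;
        }
      }
      mask(i, j) = val;
    }
  }
  return mask;
}
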