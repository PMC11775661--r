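#include <Rcpp.h>
#include <cmath>
#include "prng.h"

// Monte Carlo photon walk through a rectangular slab of homogeneous
// scattering/absorbing medium, emulating a cuvette in an integrating-sphere
// configuration. Photons enter normally at the centre of the front face.
// Exit through the back face counts as transmitted, through the front face
// as reflected; side exits are counted as absorbed, replicating the
// port-loss convention of the measurement the model emulates.

static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double s = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - s * s) / (2.0 * g);
}

// rotate local (st*cos(phi), st*sin(phi), ct) into the frame of w
static inline void rotate_frame(double wx, double wy, double wz,
                                double ct, double phi,
                                double &ox, double &oy, double &oz) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double lx = st * std::cos(phi), ly = st * std::sin(phi), lz = ct;
  double ax, ay, az;
  if (std::fabs(wx) < 0.9) { ax = 1; ay = 0; az = 0; }
  else { ax = 0; ay = 1; az = 0; }
  double ux = wy * az - wz * ay;
  double uy = wz * ax - wx * az;
  double uz = wx * ay - wy * ax;
  double un = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= un; uy /= un; uz /= un;
  double vx = wy * uz - wz * uy;
  double vy = wz * ux - wx * uz;
  double vz = wx * uy - wy * ux;
  ox = lx * ux + ly * vx + lz * wx;
  oy = lx * uy + ly * vy + lz * wy;
  oz = lx * uz + ly * vz + lz * wz;
  double n = std::sqrt(ox * ox + oy * oy + oz * oz);
  ox /= n; oy /= n; oz /= n;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_simulate_slab(double sigma_a, double sigma_s, double g,
                                      double d, double face_w, double face_h,
                                      int n_photons, double seed) {
  const double st = sigma_a + sigma_s;
  const double albedo = st > 0 ? sigma_s / st : 0.0;
  const double hw = face_w / 2.0, hh = face_h / 2.0;
  long nr = 0, nt = 0;
  const uint64_t seed64 = (uint64_t)seed;
  PbrRng rng;
  for (int i = 0; i < n_photons; ++i) {
    rng.seed_from(seed64, 0x51abULL, (uint64_t)i, 0);
    double x = 0.0, y = 0.0, z = 0.0;
    double dx = 1.0, dy = 0.0, dz = 0.0;
    int fate = -1; // 0 = reflected, 1 = transmitted, 2 = absorbed/lost
    for (int step = 0; step < 100000; ++step) {
      double s = -std::log(1.0 - rng.unif()) / st;
      // distance to the nearest slab boundary along the current direction
      double tb = 1e300;
      int face = -1; // 0 front(x=0), 1 back(x=d), 2 side
      if (dx > 0) { double t = (d - x) / dx; if (t < tb) { tb = t; face = 1; } }
      else if (dx < 0) { double t = (0.0 - x) / dx; if (t < tb) { tb = t; face = 0; } }
      if (dy > 0) { double t = (hw - y) / dy; if (t < tb) { tb = t; face = 2; } }
      else if (dy < 0) { double t = (-hw - y) / dy; if (t < tb) { tb = t; face = 2; } }
      if (dz > 0) { double t = (hh - z) / dz; if (t < tb) { tb = t; face = 2; } }
      else if (dz < 0) { double t = (-hh - z) / dz; if (t < tb) { tb = t; face = 2; } }
      if (s >= tb) {           // escapes before colliding
        fate = (face == 1) ? 1 : (face == 0 ? 0 : 2);
        break;
      }
      x += s * dx; y += s * dy; z += s * dz;
      if (rng.unif() >= albedo) { fate = 2; break; }   // absorbed
      double ct = hg_cos(g, rng.unif());
      double phi = 2.0 * M_PI * rng.unif();
      double nx2, ny2, nz2;
      rotate_frame(dx, dy, dz, ct, phi, nx2, ny2, nz2);
      dx = nx2; dy = ny2; dz = nz2;
    }
    if (fate == 0) ++nr; else if (fate == 1) ++nt;
  }
  double r = (double)nr / n_photons;
  double t = (double)nt / n_photons;
  return Rcpp::NumericVector::create(r, t, 1.0 - r - t);
}
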