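// Brownian-dynamics steppers for confined single-molecule simulation.
// Geometry: spherocylinder in its local frame (long axis along x, centre at
// the origin); cytoplasmic molecules diffuse in the volume with reflecting
// walls, membrane molecules diffuse laterally on the surface.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// nearest point on the axis segment, then push the point onto the surface
static inline void project_surface(double &x, double &y, double &z,
                                   double R, double hc) {
  double ax = clampd(x, -hc, hc);
  double vx = x - ax, vy = y, vz = z;
  double d = std::sqrt(vx * vx + vy * vy + vz * vz);
  if (d < 1e-12) { vx = 0.0; vy = 0.0; vz = 1.0; d = 1.0; }
  double s = R / d;
  x = ax + vx * s; y = vy * s; z = vz * s;
}

static inline double axis_dist(double x, double y, double z, double hc) {
  double ax = clampd(x, -hc, hc);
  double dx = x - ax;
  return std::sqrt(dx * dx + y * y + z * z);
}

// mirror across the tangent plane at the nearest surface point; iterate
// in case a large step re-exits near a cap
static inline void reflect_inside(double &x, double &y, double &z,
                                  double R, double hc) {
  for (int it = 0; it < 8; ++it) {
    double d = axis_dist(x, y, z, hc);
    if (d <= R) return;
    double sx = x, sy = y, sz = z;
    project_surface(sx, sy, sz, R, hc);
    x = 2.0 * sx - x; y = 2.0 * sy - y; z = 2.0 * sz - z;
  }
  project_surface(x, y, z, R, hc);
}

// [[Rcpp::export(name = ".sim_path_cpp")]]
NumericVector sim_path_cpp(NumericMatrix p0, NumericVector intervals_ms,
                           double D_nm2_ms, int n_sub, double R, double hc,
                           bool caps_none, int compartment) {
  // compartment: 0 = cytoplasm_3d, 1 = membrane_surface, 2 = immobile
  int n = p0.nrow();
  int nt = intervals_ms.size() + 1;
  NumericVector out(Dimension(n, 3, nt));
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = p0(i, 0); y[i] = p0(i, 1); z[i] = p0(i, 2);
    out[i] = x[i]; out[n + i] = y[i]; out[2 * n + i] = z[i];
  }
  RNGScope scope;
  for (int t = 1; t < nt; ++t) {
    double dt = intervals_ms[t - 1];
    if (compartment != 2 && D_nm2_ms > 0.0 && dt > 0.0) {
      double h = dt / n_sub;
      double sd = std::sqrt(2.0 * D_nm2_ms * h);
      if (compartment == 0) {
        for (int s = 0; s < n_sub; ++s)
          for (int i = 0; i < n; ++i) {
            x[i] += R::rnorm(0.0, sd);
            y[i] += R::rnorm(0.0, sd);
            z[i] += R::rnorm(0.0, sd);
            reflect_inside(x[i], y[i], z[i], R, hc);
          }
      } else if (caps_none) {
        // open cylinder: the intrinsic update (axial + azimuthal arc
        // length) is exact, no substepping needed
        double sdf = std::sqrt(2.0 * D_nm2_ms * dt);
        for (int i = 0; i < n; ++i) {
          x[i] += R::rnorm(0.0, sdf);
          double phi = std::atan2(z[i], y[i]) + R::rnorm(0.0, sdf / R);
          y[i] = R * std::cos(phi);
          z[i] = R * std::sin(phi);
        }
      } else {
        // tangent-plane step + re-projection onto the spherocylinder
        for (int s = 0; s < n_sub; ++s)
          for (int i = 0; i < n; ++i) {
            double ax = clampd(x[i], -hc, hc);
            double nx = x[i] - ax, ny = y[i], nz = z[i];
            double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
            if (nn < 1e-12) { nx = 0; ny = 0; nz = 1; nn = 1; }
            nx /= nn; ny /= nn; nz /= nn;
            // tangent basis from a reference vector not parallel to n
            double rx = 1, ry = 0, rz = 0;
            if (std::fabs(nx) > 0.9) { rx = 0; ry = 1; rz = 0; }
            double t1x = ny * rz - nz * ry;
            double t1y = nz * rx - nx * rz;
            double t1z = nx * ry - ny * rx;
            double tn = std::sqrt(t1x * t1x + t1y * t1y + t1z * t1z);
            t1x /= tn; t1y /= tn; t1z /= tn;
            double t2x = ny * t1z - nz * t1y;
            double t2y = nz * t1x - nx * t1z;
            double t2z = nx * t1y - ny * t1x;
            double a = R::rnorm(0.0, sd), b = R::rnorm(0.0, sd);
            x[i] += a * t1x + b * t2x;
            y[i] += a * t1y + b * t2y;
            z[i] += a * t1z + b * t2z;
            project_surface(x[i], y[i], z[i], R, hc);
          }
      }
    }
    for (int i = 0; i < n; ++i) {
      out[(size_t)t * 3 * n + i] = x[i];
      out[(size_t)t * 3 * n + n + i] = y[i];
      out[(size_t)t * 3 * n + 2 * n + i] = z[i];
    }
  }
  return out;
}
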