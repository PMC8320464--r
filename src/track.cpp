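#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Trilinear interpolation on a cell-centred field: periodic in x and y,
// clamped in z. Positions in metres, cell centres at (i + 0.5) * h.
static inline double interp3(const double *fld, int nx, int ny, int nz,
                             double h, double x, double y, double z) {
  double gx = x / h - 0.5, gy = y / h - 0.5, gz = z / h - 0.5;
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  int i1 = i0 + 1, j1 = j0 + 1, k1 = k0 + 1;
  i0 = ((i0 % nx) + nx) % nx; i1 = ((i1 % nx) + nx) % nx;
  j0 = ((j0 % ny) + ny) % ny; j1 = ((j1 % ny) + ny) % ny;
  if (k0 < 0) k0 = 0; if (k0 > nz - 1) k0 = nz - 1;
  if (k1 < 0) k1 = 0; if (k1 > nz - 1) k1 = nz - 1;
  if (fz < 0) fz = 0; if (fz > 1) fz = 1;
  R_xlen_t sxy = (R_xlen_t)nx * ny;
#define F(I, J, K) fld[(I) + (R_xlen_t)(J)*nx + (R_xlen_t)(K)*sxy]
  double c00 = F(i0, j0, k0) * (1 - fx) + F(i1, j0, k0) * fx;
  double c10 = F(i0, j1, k0) * (1 - fx) + F(i1, j1, k0) * fx;
  double c01 = F(i0, j0, k1) * (1 - fx) + F(i1, j0, k1) * fx;
  double c11 = F(i0, j1, k1) * (1 - fx) + F(i1, j1, k1) * fx;
#undef F
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Lagrangian capture tracking of one particle size class through a frozen
// Stokes micro-flow field. Capture when the particle surface touches the
// solid phase (distance-to-surface <= radius); penetration when the particle
// crosses the downstream plane z = zexit. Uses R's RNG (seed-reproducible).
//
// dist : distance-to-solid-surface field (m), ucc/vcc/wcc : cell-centred
// velocity (m/s), all on the same grid. tau = Cc*rho_p*dp^2/(18 mu) is the
// particle relaxation time; Dbr the Brownian diffusivity; gz gravity along z.
// [[Rcpp::export]]
List track_particles_cpp(NumericVector dist, NumericVector ucc,
                         NumericVector vcc, NumericVector wcc,
                         IntegerVector dims, double h, int n, double dp,
                         double tau, double Dbr, double gz, double zstart,
                         double zexit, double faceVel, double cfl,
                         int maxSteps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *pd = REAL(dist), *pu = REAL(ucc), *pv = REAL(vcc), *pw = REAL(wcc);
  const double Lx = nx * h, Ly = ny * h;
  const double r = dp / 2.0;
  const double uref = 0.05 * faceVel;
  IntegerVector fate(n), mech(n);
  double totSteps = 0;

  for (int ip = 0; ip < n; ++ip) {
    double x = unif_rand() * Lx;
    double y = unif_rand() * Ly;
    double z = zstart;
    double ux = interp3(pu, nx, ny, nz, h, x, y, z);
    double uy = interp3(pv, nx, ny, nz, h, x, y, z);
    double uz = interp3(pw, nx, ny, nz, h, x, y, z);
    int f = 2; // unresolved unless decided
    int m = 0;

    for (int it = 0; it < maxSteps; ++it) {
      ++totSteps;
      double ds = interp3(pd, nx, ny, nz, h, x, y, z);
      if (ds <= r) { f = 0; break; }
      if (z >= zexit) { f = 1; break; }

      double fx = interp3(pu, nx, ny, nz, h, x, y, z);
      double fy = interp3(pv, nx, ny, nz, h, x, y, z);
      double fz = interp3(pw, nx, ny, nz, h, x, y, z);
      double sp = std::sqrt(ux * ux + uy * uy + uz * uz);
      double dt = cfl * h / std::max(sp, uref);
      if (Dbr > 0) {
        double dtb = 0.125 * h * h / Dbr;
        if (dtb < dt) dt = dtb;
      }
      // terminal-target exponential integrator, refined so that no sub-step
      // moves the particle more than ~one voxel
      double tx = fx, ty = fy, tz = fz + tau * gz;
      double nux, nuy, nuz, dxs, dys, dzs;
      for (int half = 0;; ++half) {
        double e = std::exp(-dt / tau), c = tau * (1.0 - e);
        nux = tx + (ux - tx) * e;
        nuy = ty + (uy - ty) * e;
        nuz = tz + (uz - tz) * e;
        dxs = tx * dt + (ux - tx) * c;
        dys = ty * dt + (uy - ty) * c;
        dzs = tz * dt + (uz - tz) * c;
        double dl = std::sqrt(dxs * dxs + dys * dys + dzs * dzs);
        if (dl <= 0.9 * h || half >= 20) break;
        dt *= 0.5;
      }
      double bx = 0, by = 0, bz = 0;
      if (Dbr > 0) {
        double sig = std::sqrt(2.0 * Dbr * dt);
        bx = sig * norm_rand(); by = sig * norm_rand(); bz = sig * norm_rand();
      }
      x += dxs + bx; y += dys + by; z += dzs + bz;
      ux = nux; uy = nuy; uz = nuz;
      x -= Lx * std::floor(x / Lx);
      y -= Ly * std::floor(y / Ly);
      if (z < 0) { z = -z; uz = -uz; } // reflect at the upstream face

      if (f == 2 && it == maxSteps - 1) break;
      // crude mechanism attribution for the capture tally
      double db = std::sqrt(bx * bx + by * by + bz * bz);
      double dd = std::sqrt(dxs * dxs + dys * dys + dzs * dzs);
      double slip = std::sqrt((ux - fx) * (ux - fx) + (uy - fy) * (uy - fy) +
                              (uz - fz) * (uz - fz));
      double fsp = std::sqrt(fx * fx + fy * fy + fz * fz);
      if (db > dd) m = 1;                 // diffusion-dominated step
      else if (slip > 0.3 * (fsp + 1e-12)) m = 3; // inertial slip
      else m = 2;                         // following flow: interception
    }
    fate[ip] = f;
    mech[ip] = (f == 0) ? m : 0;
  }
  return List::create(_["fate"] = fate, _["mech"] = mech,
                      _["steps"] = totSteps);
}
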