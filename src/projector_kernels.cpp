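#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Volumes are column-major with dims (nx, ny, nz): idx = x + nx*(y + ny*z).
// Projection stacks are column-major with dims (V, nx, nz): idx = v + V*(x + nx*z).
// Rays run along +y of the rotated frame; the detector sits at the y = ny-1 side.
// Rotation is a bilinear-interpolation gather; the backprojector scatters through
// the transposed weights so <Ax, y> == <x, A^T y> to machine precision.

static inline void bilinear_src(double xs, double ys, int nx, int ny,
                                int *ix, int *iy, double *w) {
  // 4 neighbours of (xs, ys); weights 0 for out-of-grid neighbours
  int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
  double fx = xs - x0, fy = ys - y0;
  double ww[4] = {(1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy};
  int xx[4] = {x0, x0 + 1, x0, x0 + 1};
  int yy[4] = {y0, y0, y0 + 1, y0 + 1};
  for (int k = 0; k < 4; ++k) {
    if (xx[k] < 0 || xx[k] >= nx || yy[k] < 0 || yy[k] >= ny) ww[k] = 0.0;
    ix[k] = xx[k]; iy[k] = yy[k]; w[k] = ww[k];
  }
}

// gather-rotate slice z of vol by angle theta about the in-plane centre
static void rotate_gather_slice(const double *vol, int nx, int ny, int z,
                                double ct, double st, double *out) {
  double xc = (nx - 1) / 2.0, yc = (ny - 1) / 2.0;
  const double *sl = vol + (size_t)z * nx * ny;
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      double dx = x - xc, dy = y - yc;
      double xs = xc + ct * dx - st * dy;
      double ys = yc + st * dx + ct * dy;
      int ix[4], iy[4]; double w[4];
      bilinear_src(xs, ys, nx, ny, ix, iy, w);
      double v = 0.0;
      for (int k = 0; k < 4; ++k)
        if (w[k] > 0.0) v += w[k] * sl[ix[k] + (size_t)nx * iy[k]];
      out[x + (size_t)nx * y] = v;
    }
  }
}

// transpose of rotate_gather_slice: scatter rotated-frame values back
static void rotate_scatter_slice(const double *rot, int nx, int ny, int z,
                                 double ct, double st, double *vol) {
  double xc = (nx - 1) / 2.0, yc = (ny - 1) / 2.0;
  double *sl = vol + (size_t)z * nx * ny;
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      double val = rot[x + (size_t)nx * y];
      if (val == 0.0) continue;
      double dx = x - xc, dy = y - yc;
      double xs = xc + ct * dx - st * dy;
      double ys = yc + st * dx + ct * dy;
      int ix[4], iy[4]; double w[4];
      bilinear_src(xs, ys, nx, ny, ix, iy, w);
      for (int k = 0; k < 4; ++k)
        if (w[k] > 0.0) sl[ix[k] + (size_t)nx * iy[k]] += w[k] * val;
    }
  }
}

// attenuation survival weights for one rotated mu slice: w(x,y) =
// exp(-dl * (0.5*mu(x,y) + sum_{y'>y} mu(x,y')))
static void atten_weights(const double *murot, int nx, int ny, double dl,
                          double *w) {
  for (int x = 0; x < nx; ++x) {
    double acc = 0.0;
    for (int y = ny - 1; y >= 0; --y) {
      double m = murot[x + (size_t)nx * y];
      w[x + (size_t)nx * y] = std::exp(-dl * (acc + 0.5 * m));
      acc += m;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_project_forward(NumericVector vol, IntegerVector dim,
                                  Nullable<NumericVector> mu,
                                  NumericVector angles_rad, double voxel_cm) {
  int nx = dim[0], ny = dim[1], nz = dim[2], V = angles_rad.size();
  NumericVector out((size_t)V * nx * nz);
  std::vector<double> rot(nx * ny), murot(nx * ny), w(nx * ny, 1.0);
  bool has_mu = mu.isNotNull();
  NumericVector muv;
  if (has_mu) {
    muv = mu.get();
    if (muv.size() != vol.size()) stop("activity/attenuation shape mismatch");
  }
  for (int v = 0; v < V; ++v) {
    double ct = std::cos(angles_rad[v]), st = std::sin(angles_rad[v]);
    for (int z = 0; z < nz; ++z) {
      rotate_gather_slice(REAL(vol), nx, ny, z, ct, st, rot.data());
      if (has_mu) {
        rotate_gather_slice(REAL(muv), nx, ny, z, ct, st, murot.data());
        atten_weights(murot.data(), nx, ny, voxel_cm, w.data());
      }
      for (int x = 0; x < nx; ++x) {
        double s = 0.0;
        for (int y = 0; y < ny; ++y) {
          double a = rot[x + (size_t)nx * y];
          s += has_mu ? a * w[x + (size_t)nx * y] : a;
        }
        out[v + (size_t)V * (x + (size_t)nx * z)] = s * voxel_cm;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_project_adjoint(NumericVector stack, IntegerVector dim,
                                  Nullable<NumericVector> mu,
                                  NumericVector angles_rad, double voxel_cm) {
  int nx = dim[0], ny = dim[1], nz = dim[2], V = angles_rad.size();
  NumericVector out((size_t)nx * ny * nz);
  std::vector<double> tmp(nx * ny), murot(nx * ny), w(nx * ny, 1.0);
  bool has_mu = mu.isNotNull();
  NumericVector muv;
  if (has_mu) muv = mu.get();
  for (int v = 0; v < V; ++v) {
    double ct = std::cos(angles_rad[v]), st = std::sin(angles_rad[v]);
    for (int z = 0; z < nz; ++z) {
      if (has_mu) {
        rotate_gather_slice(REAL(muv), nx, ny, z, ct, st, murot.data());
        atten_weights(murot.data(), nx, ny, voxel_cm, w.data());
      }
      for (int x = 0; x < nx; ++x) {
        double pv = stack[v + (size_t)V * (x + (size_t)nx * z)] * voxel_cm;
        for (int y = 0; y < ny; ++y)
          tmp[x + (size_t)nx * y] = has_mu ? pv * w[x + (size_t)nx * y] : pv;
      }
      rotate_scatter_slice(tmp.data(), nx, ny, z, ct, st, REAL(out));
    }
  }
  return out;
}
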