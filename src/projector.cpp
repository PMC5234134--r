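#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Pixel convention (shared with the R side): the image is centred on the
// isocenter, coordinates refer to pixel centres, column index increases with
// x, row index increases downward (decreasing y).  For a matrix with nr rows
// and nc columns and spacing s (mm/pixel):
//   x(j) = (j - (nc-1)/2) * s,   y(i) = ((nr-1)/2 - i) * s   (0-based i, j)

static inline double bilinear(const NumericMatrix& img, double x, double y,
                              double spacing, int nr, int nc) {
  double jf = x / spacing + 0.5 * (nc - 1);
  double ifr = 0.5 * (nr - 1) - y / spacing;
  if (jf <= -1.0 || jf >= nc || ifr <= -1.0 || ifr >= nr) return 0.0;
  int j0 = (int)std::floor(jf);
  int i0 = (int)std::floor(ifr);
  double fj = jf - j0, fi = ifr - i0;
  double v = 0.0;
  for (int di = 0; di <= 1; ++di) {
    int i = i0 + di;
    if (i < 0 || i >= nr) continue;
    double wi = di ? fi : 1.0 - fi;
    for (int dj = 0; dj <= 1; ++dj) {
      int j = j0 + dj;
      if (j < 0 || j >= nc) continue;
      double wj = dj ? fj : 1.0 - fj;
      v += wi * wj * img(i, j);
    }
  }
  return v;
}

// source position and unit ray direction for view angle b, detector bin d
static inline void ray_geometry(double b, int d, int n_det, double dist_iso,
                                double dist_det, double bin_width,
                                double& sx, double& sy, double& dx, double& dy) {
  const double cb = std::cos(b), sb = std::sin(b);
  sx = dist_iso * cb; sy = dist_iso * sb;
  const double u = (d - 0.5 * (n_det - 1)) * bin_width;
  double px = sx - dist_det * cb - u * sb;
  double py = sy - dist_det * sb + u * cb;
  dx = px - sx; dy = py - sy;
  const double len = std::sqrt(dx * dx + dy * dy);
  dx /= len; dy /= len;
}

// Joseph-style fan-beam forward projection: for each ray, march along the
// major axis one pixel line at a time and linearly interpolate along the
// minor axis; the sample sum is scaled by the path length per line crossing.
// Exact for images that are piecewise linear along the minor axis.
// [[Rcpp::export(name = ".forward_project_joseph_cpp")]]
NumericMatrix forward_project_joseph_cpp(NumericMatrix img, double spacing,
                                         NumericVector angles, int n_det,
                                         double dist_iso, double dist_det,
                                         double bin_width) {
  const int nr = img.nrow(), nc = img.ncol();
  const int nv = angles.size();
  NumericMatrix sino(nv, n_det);
  const double* im = img.begin();
  const double rimg = 0.5 * spacing * std::sqrt((double)nr * nr + (double)nc * nc);
  for (int v = 0; v < nv; ++v) {
    for (int d = 0; d < n_det; ++d) {
      double sx, sy, dx, dy;
      ray_geometry(angles[v], d, n_det, dist_iso, dist_det, bin_width,
                   sx, sy, dx, dy);
      // restrict the march to the grid bounding circle
      const double bq = sx * dx + sy * dy;
      const double cq = sx * sx + sy * sy - rimg * rimg;
      const double disc = bq * bq - cq;
      if (disc <= 0.0) { sino(v, d) = 0.0; continue; }
      const double sq = std::sqrt(disc);
      const double ta = -bq - sq, tb = -bq + sq;
      double acc = 0.0;
      if (std::fabs(dx) >= std::fabs(dy)) {
        // march over columns j, interpolate between rows
        const double w = spacing / std::fabs(dx);
        const double xa = sx + ta * dx, xb = sx + tb * dx;
        int j0r = (int)std::floor(std::min(xa, xb) / spacing + 0.5 * (nc - 1));
        int j1r = (int)std::ceil(std::max(xa, xb) / spacing + 0.5 * (nc - 1));
        if (j0r < 0) j0r = 0;
        if (j1r > nc - 1) j1r = nc - 1;
        for (int j = j0r; j <= j1r; ++j) {
          const double x = (j - 0.5 * (nc - 1)) * spacing;
          const double t = (x - sx) / dx;
          const double y = sy + t * dy;
          const double ifr = 0.5 * (nr - 1) - y / spacing;
          if (ifr <= -1.0 || ifr >= nr) continue;
          int i0 = (int)std::floor(ifr);
          const double f = ifr - i0;
          double val = 0.0;
          if (i0 >= 0) val += (1.0 - f) * im[i0 + j * nr];
          if (i0 + 1 < nr && i0 + 1 >= 0) val += f * im[i0 + 1 + j * nr];
          acc += val;
        }
        acc *= w;
      } else {
        // march over rows i, interpolate between columns
        const double w = spacing / std::fabs(dy);
        const double ya = sy + ta * dy, yb = sy + tb * dy;
        int i0r = (int)std::floor(0.5 * (nr - 1) - std::max(ya, yb) / spacing);
        int i1r = (int)std::ceil(0.5 * (nr - 1) - std::min(ya, yb) / spacing);
        if (i0r < 0) i0r = 0;
        if (i1r > nr - 1) i1r = nr - 1;
        for (int i = i0r; i <= i1r; ++i) {
          const double y = (0.5 * (nr - 1) - i) * spacing;
          const double t = (y - sy) / dy;
          const double x = sx + t * dx;
          const double jf = x / spacing + 0.5 * (nc - 1);
          if (jf <= -1.0 || jf >= nc) continue;
          int j0 = (int)std::floor(jf);
          const double f = jf - j0;
          double val = 0.0;
          if (j0 >= 0) val += (1.0 - f) * im[i + j0 * nr];
          if (j0 + 1 < nc && j0 + 1 >= 0) val += f * im[i + (j0 + 1) * nr];
          acc += val;
        }
        acc *= w;
      }
      sino(v, d) = acc;
    }
  }
  return sino;
}

// Fine-step fan-beam forward projection: midpoint-rule line integration with
// bilinear image sampling at a fixed step (mm).
// [[Rcpp::export(name = ".forward_project_fine_cpp")]]
NumericMatrix forward_project_fine_cpp(NumericMatrix img, double spacing,
                                       NumericVector angles, int n_det,
                                       double dist_iso, double dist_det,
                                       double bin_width, double step) {
  const int nr = img.nrow(), nc = img.ncol();
  const int nv = angles.size();
  NumericMatrix sino(nv, n_det);
  const double rimg = 0.5 * spacing * std::sqrt((double)nr * nr + (double)nc * nc);
  for (int v = 0; v < nv; ++v) {
    for (int d = 0; d < n_det; ++d) {
      double sx, sy, dx, dy;
      ray_geometry(angles[v], d, n_det, dist_iso, dist_det, bin_width,
                   sx, sy, dx, dy);
      // intersect with the grid bounding circle: |s + t dir|^2 = rimg^2
      const double b = sx * dx + sy * dy;
      const double c0 = sx * sx + sy * sy - rimg * rimg;
      const double disc = b * b - c0;
      if (disc <= 0.0) { sino(v, d) = 0.0; continue; }
      const double sq = std::sqrt(disc);
      const double t0 = -b - sq, t1 = -b + sq;
      const int n = (int)std::ceil((t1 - t0) / step);
      const double h = (t1 - t0) / n;
      double acc = 0.0;
      for (int k = 0; k < n; ++k) {
        const double t = t0 + (k + 0.5) * h;
        acc += bilinear(img, sx + t * dx, sy + t * dy, spacing, nr, nc);
      }
      sino(v, d) = acc * h;
    }
  }
  return sino;
}

// Pixel-driven fan-beam backprojection of a ramp-filtered sinogram.
// fsino_t is the filtered sinogram TRANSPOSED (detectors x views), indexed
// by the virtual detector coordinate u' = u * D/SDD (detector rescaled
// through the isocenter) with spacing du.  For each pixel and view:
//   U  = D - (x cos b + y sin b)      (distance along the central ray)
//   u' = D * (-x sin b + y cos b)/U   (virtual detector coordinate)
// weighted by D^2/U^2.  The caller applies the angular step factor.
// [[Rcpp::export(name = ".backproject_cpp")]]
NumericMatrix backproject_cpp(NumericMatrix fsino_t, double spacing,
                              int nr, int nc, NumericVector angles,
                              double dist_iso, double du) {
  const int nd = fsino_t.nrow(), nv = fsino_t.ncol();
  NumericMatrix img(nr, nc);
  const double D = dist_iso;
  const double dcent = 0.5 * (nd - 1);
  const double* fs = fsino_t.begin();
  for (int v = 0; v < nv; ++v) {
    const double cb = std::cos(angles[v]), sb = std::sin(angles[v]);
    const double* col = fs + (size_t)v * nd;
    for (int j = 0; j < nc; ++j) {
      const double x = (j - 0.5 * (nc - 1)) * spacing;
      const double xc = x * cb, xs = x * sb;
      for (int i = 0; i < nr; ++i) {
        const double y = (0.5 * (nr - 1) - i) * spacing;
        const double U = D - (xc + y * sb);
        if (U < 1e-6) continue;
        const double up = D * (-xs + y * cb) / U;
        const double fd = up / du + dcent;
        if (fd <= 0.0 || fd >= nd - 1) continue;
        const int d0 = (int)fd;
        const double f = fd - d0;
        const double q = (1.0 - f) * col[d0] + f * col[d0 + 1];
        img(i, j) += q * D * D / (U * U);
      }
    }
  }
  return img;
}
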