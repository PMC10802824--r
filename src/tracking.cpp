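#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Images are R matrices (row = y, col = x), intensities in [0, 1].
// Point coordinates are (x, y) = (column, row), 0-based pixel centers.

static inline double sample_bilinear_raw(const double *img, int nr, int nc,
                                         double x, double y) {
  if (x < 0.0) x = 0.0;
  if (y < 0.0) y = 0.0;
  if (x > nc - 1.0) x = nc - 1.0;
  if (y > nr - 1.0) y = nr - 1.0;
  int x0 = (int)x, y0 = (int)y;
  if (x0 > nc - 2) x0 = nc - 2;
  if (y0 > nr - 2) y0 = nr - 2;
  const double fx = x - x0, fy = y - y0;
  const double *c0 = img + (size_t)x0 * nr + y0;  // column-major
  const double *c1 = c0 + nr;
  return c0[0] * (1 - fx) * (1 - fy) + c1[0] * fx * (1 - fy) +
         c0[1] * (1 - fx) * fy + c1[1] * fx * fy;
}

static inline double sample_bilinear(const NumericMatrix &img, double x, double y) {
  return sample_bilinear_raw(REAL(img), img.nrow(), img.ncol(), x, y);
}

// fill a (side x side) patch buffer centered at (px, py), row-major in (i, j)
static void fill_patch(const double *img, int nr, int nc, double px, double py,
                       int half, double *buf) {
  int k = 0;
  for (int j = -half; j <= half; ++j)
    for (int i = -half; i <= half; ++i, ++k)
      buf[k] = sample_bilinear_raw(img, nr, nc, px + i, py + j);
}

static NumericMatrix downsample2(const NumericMatrix &img) {
  const int nr = img.nrow() / 2, nc = img.ncol() / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = 0.25 * (img(2 * i, 2 * j) + img(2 * i + 1, 2 * j) +
                          img(2 * i, 2 * j + 1) + img(2 * i + 1, 2 * j + 1));
  return out;
}

// Pyramidal Lucas-Kanade, translation model per point.
// Returns new point positions, per-point mean absolute patch residual at the
// finest level, and an out-of-image flag (clamped points).
// [[Rcpp::export]]
List lk_track_cpp(NumericMatrix img1, NumericMatrix img2, NumericMatrix pts,
                  int levels, int window, int max_iter, double eps) {
  const int n = pts.nrow();
  const int hw = window / 2;
  if (levels < 1) levels = 1;

  std::vector<NumericMatrix> pyr1, pyr2;
  pyr1.push_back(img1);
  pyr2.push_back(img2);
  for (int l = 1; l < levels; ++l) {
    if (pyr1.back().nrow() < 2 * (2 * hw + 3) || pyr1.back().ncol() < 2 * (2 * hw + 3))
      break;  // stop when a level would be smaller than the window
    pyr1.push_back(downsample2(pyr1.back()));
    pyr2.push_back(downsample2(pyr2.back()));
  }
  const int L = (int)pyr1.size();

  NumericMatrix out(n, 2);
  NumericVector resid(n);
  LogicalVector flagged(n);
  const int wpx = 2 * hw + 1;
  const int bpx = wpx + 2;  // padded buffer for in-buffer gradients
  std::vector<double> buf(bpx * bpx), cur(wpx * wpx);
  std::vector<double> tmpl(wpx * wpx), gx(wpx * wpx), gy(wpx * wpx);

  for (int p = 0; p < n; ++p) {
    double gxd = 0.0, gyd = 0.0;  // accumulated displacement guess
    double final_res = 0.0;
    for (int l = L - 1; l >= 0; --l) {
      const double *I1 = REAL(pyr1[l]);
      const double *I2 = REAL(pyr2[l]);
      const int nr1 = pyr1[l].nrow(), nc1 = pyr1[l].ncol();
      const double scale = (double)(1 << l);
      const double px = pts(p, 0) / scale, py = pts(p, 1) / scale;

      // one bilinear pass into a padded buffer; gradients by central
      // differences inside the buffer
      fill_patch(I1, nr1, nc1, px, py, hw + 1, buf.data());
      double g11 = 0.0, g12 = 0.0, g22 = 0.0;
      int k = 0;
      for (int j = 1; j <= wpx; ++j) {
        for (int i = 1; i <= wpx; ++i, ++k) {
          const int b = j * bpx + i;
          tmpl[k] = buf[b];
          gx[k] = 0.5 * (buf[b + 1] - buf[b - 1]);
          gy[k] = 0.5 * (buf[b + bpx] - buf[b - bpx]);
          g11 += gx[k] * gx[k];
          g12 += gx[k] * gy[k];
          g22 += gy[k] * gy[k];
        }
      }
      const double det = g11 * g22 - g12 * g12;
      double dx = 0.0, dy = 0.0;
      if (det > 1e-12) {
        for (int it = 0; it < max_iter; ++it) {
          fill_patch(I2, nr1, nc1, px + gxd + dx, py + gyd + dy, hw, cur.data());
          double b1 = 0.0, b2 = 0.0;
          for (k = 0; k < wpx * wpx; ++k) {
            const double e = cur[k] - tmpl[k];
            b1 += e * gx[k];
            b2 += e * gy[k];
          }
          const double sx = -(g22 * b1 - g12 * b2) / det;
          const double sy = -(-g12 * b1 + g11 * b2) / det;
          dx += sx;
          dy += sy;
          if (sx * sx + sy * sy < eps * eps) break;
        }
      }
      gxd += dx;
      gyd += dy;
      if (l == 0) {
        fill_patch(I2, nr1, nc1, px + gxd, py + gyd, hw, cur.data());
        double sres = 0.0;
        for (k = 0; k < wpx * wpx; ++k) sres += std::fabs(cur[k] - tmpl[k]);
        final_res = sres / (wpx * wpx);
      } else {
        gxd *= 2.0;
        gyd *= 2.0;
      }
    }
    double nx = pts(p, 0) + gxd, ny = pts(p, 1) + gyd;
    bool fl = false;
    if (nx < 0 || ny < 0 || nx > img1.ncol() - 1.0 || ny > img1.nrow() - 1.0) {
      fl = true;
      nx = std::min(std::max(nx, 0.0), img1.ncol() - 1.0);
      ny = std::min(std::max(ny, 0.0), img1.nrow() - 1.0);
    }
    out(p, 0) = nx;
    out(p, 1) = ny;
    resid[p] = final_res;
    flagged[p] = fl;
  }
  return List::create(_["points"] = out, _["residual"] = resid, _["flagged"] = flagged);
}

// Additively splat isotropic Gaussian kernels (speckle particles) onto a
// zero image of size nrow x ncol. pts are (x, y) 0-based pixel centers.
// [[Rcpp::export]]
NumericMatrix splat_gaussians_cpp(int nrow, int ncol, NumericMatrix pts,
                                  NumericVector amp, double sigma) {
  NumericMatrix img(nrow, ncol);
  const int r = (int)std::ceil(3.0 * sigma);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int p = 0; p < pts.nrow(); ++p) {
    const double x = pts(p, 0), y = pts(p, 1), a = amp[p];
    const int cx = (int)std::lround(x), cy = (int)std::lround(y);
    for (int j = cy - r; j <= cy + r; ++j) {
      if (j < 0 || j >= nrow) continue;
      for (int i = cx - r; i <= cx + r; ++i) {
        if (i < 0 || i >= ncol) continue;
        const double dx = i - x, dy = j - y;
        img(j, i) += a * std::exp(-(dx * dx + dy * dy) * inv2s2);
      }
    }
  }
  return img;
}
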