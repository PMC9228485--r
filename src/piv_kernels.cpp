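// Low-level kernels for the PIV engine and the particle-image generator.
// Conventions: images are R matrices indexed [row = y, col = x], 0-based in C++.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Zero-normalized linear cross-correlation of two equally sized windows,
// evaluated for integer lags dy in [-maxLagY, maxLagY], dx in [-maxLagX, maxLagX].
// C(dy, dx) = sum_a' b'(shifted) / (||a'|| ||b'||), primes = mean-subtracted.
// Computed by FFT on zero-padded arrays. Returns a (2*maxLagY+1) x (2*maxLagX+1)
// matrix; all-NA if either window has (near-)zero variance.
// [[Rcpp::export]]
NumericMatrix cpp_xcorr_plane(const arma::mat& a, const arma::mat& b,
                              int maxLagY, int maxLagX) {
  const arma::uword H = a.n_rows, W = a.n_cols;
  if (b.n_rows != H || b.n_cols != W)
    stop("windows must have identical dimensions");
  NumericMatrix out(2 * maxLagY + 1, 2 * maxLagX + 1);

  arma::mat am = a - arma::accu(a) / (double)(H * W);
  arma::mat bm = b - arma::accu(b) / (double)(H * W);
  double na = std::sqrt(arma::accu(am % am));
  double nb = std::sqrt(arma::accu(bm % bm));
  if (na < 1e-12 || nb < 1e-12) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }

  const arma::uword P = H + 2 * (arma::uword)maxLagY;
  const arma::uword Q = W + 2 * (arma::uword)maxLagX;
  arma::mat ap(P, Q, arma::fill::zeros), bp(P, Q, arma::fill::zeros);
  ap.submat(0, 0, H - 1, W - 1) = am;
  bp.submat(0, 0, H - 1, W - 1) = bm;

  arma::cx_mat FA = arma::fft2(ap), FB = arma::fft2(bp);
  arma::mat corr = arma::real(arma::ifft2(arma::conj(FA) % FB));

  const double norm = na * nb;
  for (int dy = -maxLagY; dy <= maxLagY; ++dy) {
    for (int dx = -maxLagX; dx <= maxLagX; ++dx) {
      arma::uword iy = (arma::uword)((dy + (int)P) % (int)P);
      arma::uword ix = (arma::uword)((dx + (int)Q) % (int)Q);
      out(dy + maxLagY, dx + maxLagX) = corr(iy, ix) / norm;
    }
  }
  return out;
}

static inline double cubic_kernel(double t) {
  // Catmull-Rom (a = -0.5)
  t = std::fabs(t);
  if (t < 1.0) return 1.0 + t * t * (1.5 * t - 2.5);
  if (t < 2.0) return 2.0 - t * (4.0 - t * (2.5 - 0.5 * t));
  return 0.0;
}

// Backward bicubic warp: out(y, x) = img(y + v(y,x), x + u(y,x)),
// edge-replicated sampling. u, v are dense pixel-resolution displacement maps.
// [[Rcpp::export]]
NumericMatrix cpp_warp_bicubic(const NumericMatrix& img,
                               const NumericMatrix& u,
                               const NumericMatrix& v) {
  const int H = img.nrow(), W = img.ncol();
  if (u.nrow() != H || u.ncol() != W || v.nrow() != H || v.ncol() != W)
    stop("displacement maps must match image dimensions");
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double sx = x + u(y, x);
      double sy = y + v(y, x);
      int x0 = (int)std::floor(sx);
      int y0 = (int)std::floor(sy);
      double fx = sx - x0, fy = sy - y0;
      double acc = 0.0, wsum = 0.0;
      for (int j = -1; j <= 2; ++j) {
        double wy = cubic_kernel(fy - j);
        if (wy == 0.0) continue;
        int yy = y0 + j;
        yy = yy < 0 ? 0 : (yy >= H ? H - 1 : yy);
        for (int i = -1; i <= 2; ++i) {
          double wx = cubic_kernel(fx - i);
          if (wx == 0.0) continue;
          int xx = x0 + i;
          xx = xx < 0 ? 0 : (xx >= W ? W - 1 : xx);
          acc += wy * wx * img(yy, xx);
          wsum += wy * wx;
        }
      }
      out(y, x) = wsum > 0 ? acc / wsum : 0.0;
    }
  }
  return out;
}

// Render tracer particles as pixel-integrated Gaussians.
// px, py are particle centers in pixel units (pixel (r, c) covers
// [c, c+1) x [r, r+1), center at (c+0.5, r+0.5)); sigma is the Gaussian
// standard deviation in px; amp is the desired peak pixel value of a
// pixel-centered particle. Values accumulate additively.
// [[Rcpp::export]]
NumericMatrix cpp_render_particles(int H, int W,
                                   const NumericVector& px,
                                   const NumericVector& py,
                                   const NumericVector& amp,
                                   double sigma) {
  NumericMatrix out(H, W);
  const double s2 = sigma * std::sqrt(2.0);
  // peak of the per-axis integrated profile for a pixel-centered particle
  const double f0 = std::erf(0.5 / s2);
  const int rad = (int)std::ceil(4.0 * sigma) + 1;
  const int n = px.size();
  for (int k = 0; k < n; ++k) {
    double cx = px[k], cy = py[k];
    int c0 = std::max(0, (int)std::floor(cx) - rad);
    int c1 = std::min(W - 1, (int)std::floor(cx) + rad);
    int r0 = std::max(0, (int)std::floor(cy) - rad);
    int r1 = std::min(H - 1, (int)std::floor(cy) + rad);
    if (c1 < c0 || r1 < r0) continue;
    double a = amp[k] / (f0 * f0);
    for (int c = c0; c <= c1; ++c) {
      double gx = 0.5 * (std::erf((c + 1 - cx) / s2) - std::erf((c - cx) / s2));
      for (int r = r0; r <= r1; ++r) {
        double gy = 0.5 * (std::erf((r + 1 - cy) / s2) - std::erf((r - cy) / s2));
        out(r, c) += a * gx * gy;
      }
    }
  }
  return out;
}

// Bilinear interpolation of a coarse grid field onto dense pixel positions.
// gx, gy: strictly increasing grid node coordinates (px); gvals: values at
// nodes [length(gy) x length(gx)]. Evaluated at every pixel of an H x W
// image (pixel centers x + 0.5, y + 0.5), constant extrapolation outside.
// [[Rcpp::export]]
NumericMatrix cpp_densify_bilinear(const NumericVector& gx,
                                   const NumericVector& gy,
                                   const NumericMatrix& gvals,
                                   int H, int W) {
  const int nx = gx.size(), ny = gy.size();
  if (gvals.nrow() != ny || gvals.ncol() != nx)
    stop("grid values must be length(gy) x length(gx)");
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x) {
    double xc = x + 0.5;
    int ix = 0;
    while (ix < nx - 2 && gx[ix + 1] < xc) ++ix;
    double tx = nx == 1 ? 0.0 : (xc - gx[ix]) / (gx[ix + 1] - gx[ix]);
    tx = std::min(1.0, std::max(0.0, tx));
    for (int y = 0; y < H; ++y) {
      double yc = y + 0.5;
      int iy = 0;
      while (iy < ny - 2 && gy[iy + 1] < yc) ++iy;
      double ty = ny == 1 ? 0.0 : (yc - gy[iy]) / (gy[iy + 1] - gy[iy]);
      ty = std::min(1.0, std::max(0.0, ty));
      double v00 = gvals(iy, ix);
      double v01 = nx > 1 ? gvals(iy, ix + 1) : v00;
      double v10 = ny > 1 ? gvals(iy + 1, ix) : v00;
      double v11 = (nx > 1 && ny > 1) ? gvals(iy + 1, ix + 1) : v00;
      out(y, x) = (1 - ty) * ((1 - tx) * v00 + tx * v01) +
                  ty * ((1 - tx) * v10 + tx * v11);
    }
  }
  return out;
}
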