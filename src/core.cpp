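// Low-level image primitives: sub-pixel PSF template evaluation (Catmull-Rom
// bicubic on an upsampled grid), event injection into raw frame stacks,
// candidate detection on ratiometric stacks, and Levenberg-Marquardt PSF fits.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Catmull-Rom cubic kernel weight for fractional offset t in [0,1)
static inline void cr_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2.0 * t2 - t);
  w[1] = 0.5 * (3.0 * t3 - 5.0 * t2 + 2.0);
  w[2] = 0.5 * (-3.0 * t3 + 4.0 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

// Bicubic interpolation of matrix G (nr x nc, 0-based grid coords) at (gr, gc).
// Returns 0 outside the valid interpolation domain (template support ends).
static double interp2(const NumericMatrix& G, double gr, double gc) {
  int nr = G.nrow(), nc = G.ncol();
  if (gr < 1.0 || gc < 1.0 || gr > nr - 3.0 || gc > nc - 3.0) {
    // fall back to bilinear near the border, 0 outside
    if (gr < 0.0 || gc < 0.0 || gr > nr - 1.0 || gc > nc - 1.0) return 0.0;
    int r0 = (int)std::floor(gr), c0 = (int)std::floor(gc);
    if (r0 >= nr - 1) r0 = nr - 2;
    if (c0 >= nc - 1) c0 = nc - 2;
    double fr = gr - r0, fc = gc - c0;
    return (1 - fr) * ((1 - fc) * G(r0, c0) + fc * G(r0, c0 + 1)) +
           fr * ((1 - fc) * G(r0 + 1, c0) + fc * G(r0 + 1, c0 + 1));
  }
  int r0 = (int)std::floor(gr), c0 = (int)std::floor(gc);
  double fr = gr - r0, fc = gc - c0;
  double wr[4], wc[4];
  cr_weights(fr, wr);
  cr_weights(fc, wc);
  double v = 0.0;
  for (int i = 0; i < 4; ++i) {
    double rowacc = 0.0;
    for (int j = 0; j < 4; ++j) rowacc += wc[j] * G(r0 - 1 + i, c0 - 1 + j);
    v += wr[i] * rowacc;
  }
  return v;
}

// Template value at pixel offset (x = column offset, y = row offset), in px.
static inline double psf_at(const NumericMatrix& G, int u, double orow0,
                            double ocol0, double x, double y) {
  return interp2(G, orow0 + y * u, ocol0 + x * u);
}

// [[Rcpp::export]]
NumericVector cpp_psf_value(NumericMatrix G, int u, double orow, double ocol,
                            NumericVector x, NumericVector y) {
  int n = std::max(x.size(), y.size());
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = psf_at(G, u, orow - 1.0, ocol - 1.0, x[i % x.size()],
                    y[i % y.size()]);
  return out;
}

// 17x17-style patch of the template centred on a (2*hw+1) pixel window with the
// peak at sub-pixel (dx, dy) relative to the window centre.
// [[Rcpp::export]]
NumericMatrix cpp_psf_patch(NumericMatrix G, int u, double orow, double ocol,
                            double dx, double dy, int hw) {
  int m = 2 * hw + 1;
  NumericMatrix out(m, m);
  double o_r = orow - 1.0, o_c = ocol - 1.0;
  for (int c = 0; c < m; ++c)
    for (int r = 0; r < m; ++r)
      out(r, c) = psf_at(G, u, o_r, o_c, (c - hw) - dx, (r - hw) - dy);
  return out;
}

// Resample a measured 2D patch (pixel grid, 1 px spacing) onto an upsampled
// grid centred at sub-pixel position (crow, ccol) (1-based pixel coords).
// [[Rcpp::export]]
NumericMatrix cpp_resample_centered(NumericMatrix patch, double crow,
                                    double ccol, int u, int hw) {
  int m = 2 * hw * u + 1;
  NumericMatrix out(m, m);
  double cr0 = crow - 1.0, cc0 = ccol - 1.0;
  for (int c = 0; c < m; ++c) {
    double gc = cc0 + (double)(c - hw * u) / u;
    for (int r = 0; r < m; ++r) {
      double gr = cr0 + (double)(r - hw * u) / u;
      out(r, c) = interp2(patch, gr, gc);
    }
  }
  return out;
}

// In-place additive injection of a PSF-shaped signal into a raw frame stack.
// frames: numeric array [T, H, W] (t fastest); t_idx 1-based frame indices.
// [[Rcpp::export]]
void cpp_inject_ip(NumericVector frames, int T, int H, int W,
                   IntegerVector t_idx, NumericVector xs, NumericVector ys,
                   NumericVector amps, NumericMatrix G, int u, double orow,
                   double ocol, int hw) {
  double o_r = orow - 1.0, o_c = ocol - 1.0;
  int n = t_idx.size();
  for (int i = 0; i < n; ++i) {
    int t = t_idx[i] - 1;
    double x = xs[i], y = ys[i], a = amps[i];
    if (t < 0 || t >= T) stop("injection frame %d outside movie [1, %d]", t + 1, T);
    if (x < 1.0 || x > (double)W || y < 1.0 || y > (double)H)
      stop("trajectory outside field of view at frame %d", t + 1);
    int rc = (int)std::lround(y) - 1, cc = (int)std::lround(x) - 1;
    int r0 = std::max(0, rc - hw), r1 = std::min(H - 1, rc + hw);
    int c0 = std::max(0, cc - hw), c1 = std::min(W - 1, cc + hw);
    for (int c = c0; c <= c1; ++c) {
      double px = (c + 1) - x;
      for (int r = r0; r <= r1; ++r) {
        double py = (r + 1) - y;
        frames[t + (size_t)T * (r + (size_t)H * c)] +=
            a * psf_at(G, u, o_r, o_c, px, py);
      }
    }
  }
}

// Candidate detection on a ratiometric stack: local extrema of |rat - 1|
// above thr1 whose 17x17 neighbourhood correlates with the template above
// thr2 in absolute value. K0 must be the zero-mean, unit-norm template patch.
// Returned contrast follows the landing-positive convention: -(rat - 1).
// [[Rcpp::export]]
DataFrame cpp_detect(NumericVector rat, int T, int H, int W, NumericMatrix K0,
                     double thr1, double thr2, int nms, int hw) {
  std::vector<int> out_t, out_x, out_y;
  std::vector<double> out_c, out_ncc;
  int k = K0.nrow();
  if (k != 2 * hw + 1) stop("kernel size mismatch");
  std::vector<double> patch(k * k);
  for (int t = 0; t < T; ++t) {
    for (int c = hw; c < W - hw; ++c) {
      for (int r = hw; r < H - hw; ++r) {
        double d = rat[t + (size_t)T * (r + (size_t)H * c)] - 1.0;
        double ad = std::fabs(d);
        if (ad < thr1) continue;
        // non-maximum suppression: strict max of |D| in (2*nms+1)^2 window
        bool ismax = true;
        int rr0 = std::max(0, r - nms), rr1 = std::min(H - 1, r + nms);
        int cc0 = std::max(0, c - nms), cc1 = std::min(W - 1, c + nms);
        for (int cc = cc0; cc <= cc1 && ismax; ++cc)
          for (int rr = rr0; rr <= rr1; ++rr) {
            if (rr == r && cc == c) continue;
            double o = std::fabs(rat[t + (size_t)T * (rr + (size_t)H * cc)] - 1.0);
            if (o > ad || (o == ad && (cc < c || (cc == c && rr < r)))) {
              ismax = false;
              break;
            }
          }
        if (!ismax) continue;
        // normalized cross-correlation with the template
        double sum = 0.0;
        int idx = 0;
        for (int cc = c - hw; cc <= c + hw; ++cc)
          for (int rr = r - hw; rr <= r + hw; ++rr) {
            double v = rat[t + (size_t)T * (rr + (size_t)H * cc)] - 1.0;
            patch[idx++] = v;
            sum += v;
          }
        double mean = sum / (k * k);
        double dot = 0.0, ss = 0.0;
        idx = 0;
        for (int cc = 0; cc < k; ++cc)
          for (int rr = 0; rr < k; ++rr) {
            double v = patch[idx++] - mean;
            dot += v * K0(rr, cc);
            ss += v * v;
          }
        double ncc = (ss > 0) ? dot / std::sqrt(ss) : 0.0;
        if (std::fabs(ncc) < thr2) continue;
        out_t.push_back(t + 1);
        out_x.push_back(c + 1);
        out_y.push_back(r + 1);
        out_c.push_back(-d);
        out_ncc.push_back(ncc);
      }
    }
  }
  return DataFrame::create(_["t"] = out_t, _["x"] = out_x, _["y"] = out_y,
                           _["contrast"] = out_c, _["ncc"] = out_ncc);
}

// Levenberg-Marquardt fit of a * psf(x - dx, y - dy) + c to a square patch.
// Parameters theta = (dx, dy, a, c); dx, dy relative to the patch centre.
// [[Rcpp::export]]
List cpp_fit_psf(NumericMatrix patch, NumericMatrix G, int u, double orow,
                 double ocol, double dx0, double dy0, double a0, double c0,
                 int max_iter = 100, double tol = 1e-8) {
  int m = patch.nrow(), hw = (m - 1) / 2;
  int n = m * m;
  double o_r = orow - 1.0, o_c = ocol - 1.0;
  double th[4] = {dx0, dy0, a0, c0};
  std::vector<double> resid(n), f(n), J(n * 4);
  const double h = 0.01;  // px step for positional derivatives
  auto model_resid = [&](const double* p, std::vector<double>& r,
                         std::vector<double>& fv) {
    double rss = 0.0;
    int idx = 0;
    for (int c = 0; c < m; ++c)
      for (int rr = 0; rr < m; ++rr) {
        double v = psf_at(G, u, o_r, o_c, (c - hw) - p[0], (rr - hw) - p[1]);
        fv[idx] = v;
        double e = patch(rr, c) - (p[2] * v + p[3]);
        r[idx] = e;
        rss += e * e;
        ++idx;
      }
    return rss;
  };
  double rss = model_resid(th, resid, f);
  double lambda = 1e-3;
  bool converged = false;
  int it = 0;
  std::vector<double> fx(n), fy(n), rtmp(n), ftmp(n);
  for (it = 0; it < max_iter; ++it) {
    // Jacobian (analytic in a, c; central differences in dx, dy)
    int idx = 0;
    for (int c = 0; c < m; ++c)
      for (int rr = 0; rr < m; ++rr) {
        double px = (c - hw) - th[0], py = (rr - hw) - th[1];
        double vx = (psf_at(G, u, o_r, o_c, px - h, py) -
                     psf_at(G, u, o_r, o_c, px + h, py)) / (2 * h);
        double vy = (psf_at(G, u, o_r, o_c, px, py - h) -
                     psf_at(G, u, o_r, o_c, px, py + h)) / (2 * h);
        // J = d(model)/d(theta); vx already carries the inner-derivative sign
        J[idx * 4 + 0] = th[2] * vx;
        J[idx * 4 + 1] = th[2] * vy;
        J[idx * 4 + 2] = f[idx];
        J[idx * 4 + 3] = 1.0;
        ++idx;
      }
    // normal equations JtJ, Jtr
    double A[16] = {0}, g[4] = {0};
    for (int i = 0; i < n; ++i) {
      for (int a = 0; a < 4; ++a) {
        g[a] += J[i * 4 + a] * resid[i];
        for (int b = a; b < 4; ++b) A[a * 4 + b] += J[i * 4 + a] * J[i * 4 + b];
      }
    }
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < a; ++b) A[a * 4 + b] = A[b * 4 + a];
    bool stepped = false;
    for (int tries = 0; tries < 12 && !stepped; ++tries) {
      double M[16];
      for (int i = 0; i < 16; ++i) M[i] = A[i];
      for (int a = 0; a < 4; ++a) M[a * 4 + a] += lambda * (A[a * 4 + a] + 1e-12);
      // solve M * delta = g by Gaussian elimination
      double Maug[20];
      double delta[4];
      double MM[4][5];
      for (int a = 0; a < 4; ++a) {
        for (int b = 0; b < 4; ++b) MM[a][b] = M[a * 4 + b];
        MM[a][4] = g[a];
      }
      bool singular = false;
      for (int a = 0; a < 4; ++a) {
        int piv = a;
        for (int b = a + 1; b < 4; ++b)
          if (std::fabs(MM[b][a]) > std::fabs(MM[piv][a])) piv = b;
        if (std::fabs(MM[piv][a]) < 1e-30) { singular = true; break; }
        if (piv != a)
          for (int cidx = 0; cidx < 5; ++cidx) std::swap(MM[a][cidx], MM[piv][cidx]);
        for (int b = a + 1; b < 4; ++b) {
          double fmul = MM[b][a] / MM[a][a];
          for (int cidx = a; cidx < 5; ++cidx) MM[b][cidx] -= fmul * MM[a][cidx];
        }
      }
      if (singular) { lambda *= 10; continue; }
      for (int a = 3; a >= 0; --a) {
        double s = MM[a][4];
        for (int b = a + 1; b < 4; ++b) s -= MM[a][b] * delta[b];
        delta[a] = s / MM[a][a];
      }
      double thn[4];
      for (int a = 0; a < 4; ++a) thn[a] = th[a] + delta[a];
      // keep the centre inside the patch
      if (std::fabs(thn[0]) > hw || std::fabs(thn[1]) > hw) { lambda *= 10; continue; }
      double rssn = model_resid(thn, rtmp, ftmp);
      if (rssn < rss) {
        double step = std::fabs(delta[0]) + std::fabs(delta[1]) +
                      std::fabs(delta[2] / (std::fabs(th[2]) + 1e-12)) +
                      std::fabs(delta[3] / (std::fabs(th[2]) + 1e-12));
        for (int a = 0; a < 4; ++a) th[a] = thn[a];
        resid.swap(rtmp);
        f.swap(ftmp);
        rss = rssn;
        lambda = std::max(lambda * 0.3, 1e-12);
        stepped = true;
        if (step < tol) converged = true;
      } else {
        lambda *= 10;
      }
      (void)Maug;
    }
    if (!stepped) { converged = true; }  // no admissible downhill step left
    if (converged) break;
  }
  return List::create(_["dx"] = th[0], _["dy"] = th[1], _["amplitude"] = th[2],
                      _["offset"] = th[3], _["rss"] = rss,
                      _["converged"] = converged, _["niter"] = it + 1);
}
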