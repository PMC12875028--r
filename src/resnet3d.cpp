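// 3D convolutional residual network for spatiotemporal event thumbnails.
// Minimal single-threaded tensor engine: conv3d via vol2col + BLAS sgemm,
// batch normalization, ReLU, 3x3x3 max pooling, bottleneck residual blocks
// (3/4/6/3 per stage), global average pooling and a two-layer head.
// Training: SGD + cross-entropy, global-norm gradient clipping, and a
// reduce-on-plateau learning-rate schedule; best-validation-accuracy snapshot.
#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
#include <random>
#include <vector>
#include <memory>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Large activation/col buffers are allocated and freed every batch; keep
// them on the program break instead of mmap so repeated batches do not pay
// page-fault churn.
static void tune_allocator() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
    done = true;
  }
#endif
}

// Engine scalar type: float for speed; switch all three lines to double
// when validating gradients at high precision.
typedef float real_t;
typedef arma::fmat FM;
typedef arma::fvec FV;

struct Dims {
  int C, T, H, W, N;
  int P() const { return T * H * W; }
};


struct Conv3d {
  int Cin = 0, Cout = 0, kt = 1, kh = 1, kw = 1;
  int st = 1, sh = 1, sw = 1, pt = 0, ph = 0, pw = 0;
  FM Wt, dW;  // Cout x (kt*kh*kw*Cin), column order ((it*kh+ih)*kw+iw)*Cin + c
  FM col;     // cached vol2col matrix for backward
  Dims in, out;

  void setup(int cin, int cout, int kt_, int kh_, int kw_, int s, int pt_,
             int ph_, int pw_, std::mt19937_64& rng) {
    Cin = cin; Cout = cout; kt = kt_; kh = kh_; kw = kw_;
    st = s; sh = s; sw = s; pt = pt_; ph = ph_; pw = pw_;
    int K = kt * kh * kw * Cin;
    Wt.set_size(Cout, K);
    double sd = std::sqrt(2.0 / (double)K);  // He initialization (fan-in)
    std::normal_distribution<double> nd(0.0, sd);
    for (arma::uword i = 0; i < Wt.n_elem; ++i) Wt[i] = (real_t)nd(rng);
    dW.zeros(Cout, K);
  }

  Dims out_dims(const Dims& d) const {
    Dims o;
    o.C = Cout;
    o.T = (d.T + 2 * pt - kt) / st + 1;
    o.H = (d.H + 2 * ph - kh) / sh + 1;
    o.W = (d.W + 2 * pw - kw) / sw + 1;
    o.N = d.N;
    return o;
  }

  void vol2col(const FM& X, int n, FM& C) const {
    // C: K x Po for sample n
    const int P = in.P();
    const int Ho = out.H, Wo = out.W, To = out.T;
    int po = 0;
    for (int to = 0; to < To; ++to) {
      int t0 = to * st - pt;
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = ho * sh - ph;
        for (int wo = 0; wo < Wo; ++wo) {
          int w0 = wo * sw - pw;
          real_t* dst = C.colptr(po);
          for (int it = 0; it < kt; ++it) {
            int t = t0 + it;
            for (int ih = 0; ih < kh; ++ih) {
              int h = h0 + ih;
              for (int iw = 0; iw < kw; ++iw) {
                int w = w0 + iw;
                if (t < 0 || t >= in.T || h < 0 || h >= in.H || w < 0 || w >= in.W) {
                  std::fill(dst, dst + Cin, (real_t)0);
                } else {
                  int p = (t * in.H + h) * in.W + w;
                  const real_t* src = X.colptr((size_t)n * P + p);
                  std::copy(src, src + Cin, dst);
                }
                dst += Cin;
              }
            }
          }
          ++po;
        }
      }
    }
  }

  bool pointwise() const {
    return kt == 1 && kh == 1 && kw == 1 && st == 1 && sh == 1 && sw == 1;
  }

  // Single-channel stride-1 stem: col stored transposed ((N*Po) x K) and
  // filled with contiguous width-runs; backward computes only the weight
  // gradient (no input gradient needed for the first layer).
  bool stem_path() const { return Cin == 1 && st == 1 && sh == 1 && sw == 1; }

  FM forward_stem(const FM& X, const Dims& d) {
    in = d;
    out = out_dims(d);
    int K = kt * kh * kw, Po = out.P();
    col.set_size((size_t)d.N * Po, K);
    const int Ti = d.T, Hi = d.H, Wi = d.W;
    for (int n = 0; n < d.N; ++n) {
      const real_t* xn = X.colptr((size_t)n * d.P());  // C=1: contiguous volume
      for (int k = 0; k < K; ++k) {
        int it = k / (kh * kw), ih = (k / kw) % kh, iw = k % kw;
        real_t* dst0 = col.colptr(k) + (size_t)n * Po;
        size_t po = 0;
        for (int to = 0; to < out.T; ++to) {
          int t = to - pt + it;
          for (int ho = 0; ho < out.H; ++ho) {
            int h = ho - ph + ih;
            real_t* dst = dst0 + po;
            po += out.W;
            if (t < 0 || t >= Ti || h < 0 || h >= Hi) {
              std::fill(dst, dst + out.W, (real_t)0);
              continue;
            }
            const real_t* src_row = xn + ((size_t)t * Hi + h) * Wi;
            // w = wo - pw + iw must lie in [0, Wi)
            int wo_lo = std::max(0, pw - iw), wo_hi = std::min(out.W - 1, Wi - 1 + pw - iw);
            for (int wo = 0; wo < wo_lo; ++wo) dst[wo] = (real_t)0;
            if (wo_hi >= wo_lo)
              std::copy(src_row + wo_lo - pw + iw, src_row + wo_hi + 1 - pw + iw,
                        dst + wo_lo);
            for (int wo = wo_hi + 1; wo < out.W; ++wo) dst[wo] = (real_t)0;
          }
        }
      }
    }
    return Wt * col.t();
  }

  void backward_stem(const FM& dY) { dW += dY * col; }

  FM forward(const FM& X, const Dims& d, bool keep) {
    in = d;
    out = out_dims(d);
    if (pointwise()) return Wt * X;  // 1x1x1 stride-1: col matrix = input
    int K = kt * kh * kw * Cin, Po = out.P();
    col.set_size(K, (size_t)d.N * Po);
    for (int n = 0; n < d.N; ++n) {
      FM sub(col.colptr((size_t)n * Po), K, Po, false, true);
      vol2col(X, n, sub);
    }
    FM Y = Wt * col;
    return Y;
  }

  FM backward(const FM& X, const FM& dY) {
    if (pointwise()) {
      dW += dY * X.t();
      return Wt.t() * dY;
    }
    dW += dY * col.t();
    FM dcol = Wt.t() * dY;  // K x N*Po
    FM dX(Cin, (size_t)in.N * in.P(), arma::fill::zeros);
    int Po = out.P();
    for (int n = 0; n < in.N; ++n) {
      int po = 0;
      for (int to = 0; to < out.T; ++to) {
        int t0 = to * st - pt;
        for (int ho = 0; ho < out.H; ++ho) {
          int h0 = ho * sh - ph;
          for (int wo = 0; wo < out.W; ++wo) {
            int w0 = wo * sw - pw;
            const real_t* src = dcol.colptr((size_t)n * Po + po);
            for (int it = 0; it < kt; ++it) {
              int t = t0 + it;
              for (int ih = 0; ih < kh; ++ih) {
                int h = h0 + ih;
                for (int iw = 0; iw < kw; ++iw) {
                  int w = w0 + iw;
                  if (!(t < 0 || t >= in.T || h < 0 || h >= in.H || w < 0 ||
                        w >= in.W)) {
                    int p = (t * in.H + h) * in.W + w;
                    real_t* dst = dX.colptr((size_t)n * in.P() + p);
                    for (int c = 0; c < Cin; ++c) dst[c] += src[c];
                  }
                  src += Cin;
                }
              }
            }
            ++po;
          }
        }
      }
    }
    return dX;
  }
};

struct BatchNorm {
  int C = 0;
  FV gamma, beta, dgamma, dbeta, rmean, rvar;
  FV invstd, bmean;
  FM xhat;
  real_t momentum = 0.1f, eps = 1e-5f;

  void setup(int c) {
    C = c;
    gamma.ones(C); beta.zeros(C);
    dgamma.zeros(C); dbeta.zeros(C);
    rmean.zeros(C); rvar.ones(C);
  }

  // normalizes X in place (column-major traversal: channels contiguous)
  void forward_ip(FM& X, bool train, bool keep) {
    size_t n = X.n_cols;
    if (train) {
      std::vector<double> s1(C, 0.0), s2(C, 0.0);
      for (size_t j = 0; j < n; ++j) {
        const real_t* p = X.colptr(j);
        for (int c = 0; c < C; ++c) {
          s1[c] += p[c];
          s2[c] += (double)p[c] * p[c];
        }
      }
      bmean.set_size(C);
      FV var(C);
      for (int c = 0; c < C; ++c) {
        bmean[c] = (real_t)(s1[c] / n);
        var[c] = (real_t)(s2[c] / n - (s1[c] / n) * (s1[c] / n));
        if (var[c] < 0) var[c] = 0;
      }
      invstd = (real_t)1 / arma::sqrt(var + eps);
      real_t corr = (n > 1) ? (real_t)n / (n - 1) : 1.0f;
      rmean = ((real_t)1 - momentum) * rmean + momentum * bmean;
      rvar = ((real_t)1 - momentum) * rvar + momentum * (var * corr);
      if (keep) xhat.set_size(C, n);
      for (size_t j = 0; j < n; ++j) {
        real_t* p = X.colptr(j);
        real_t* xh = keep ? xhat.colptr(j) : nullptr;
        for (int c = 0; c < C; ++c) {
          real_t z = (p[c] - bmean[c]) * invstd[c];
          if (keep) xh[c] = z;
          p[c] = gamma[c] * z + beta[c];
        }
      }
    } else {
      FV is = (real_t)1 / arma::sqrt(rvar + eps);
      for (size_t j = 0; j < n; ++j) {
        real_t* p = X.colptr(j);
        for (int c = 0; c < C; ++c)
          p[c] = gamma[c] * (p[c] - rmean[c]) * is[c] + beta[c];
      }
    }
  }

  // consumes dY in place, returns gradient w.r.t. the BN input
  void backward_ip(FM& dY) {
    size_t n = dY.n_cols;
    std::vector<double> sdy(C, 0.0), sdyx(C, 0.0);
    for (size_t j = 0; j < n; ++j) {
      const real_t* dp = dY.colptr(j);
      const real_t* xh = xhat.colptr(j);
      for (int c = 0; c < C; ++c) {
        sdy[c] += dp[c];
        sdyx[c] += (double)dp[c] * xh[c];
      }
    }
    std::vector<real_t> g(C), a1(C), a2(C);
    for (int c = 0; c < C; ++c) {
      dbeta[c] += (real_t)sdy[c];
      dgamma[c] += (real_t)sdyx[c];
      g[c] = gamma[c] * invstd[c];
      a1[c] = (real_t)(sdy[c] / n);
      a2[c] = (real_t)(sdyx[c] / n);
    }
    for (size_t j = 0; j < n; ++j) {
      real_t* dp = dY.colptr(j);
      const real_t* xh = xhat.colptr(j);
      for (int c = 0; c < C; ++c)
        dp[c] = g[c] * (dp[c] - a1[c] - xh[c] * a2[c]);
    }
  }
};

static void relu_ip(FM& X) {
  real_t* p = X.memptr();
  for (size_t i = 0; i < X.n_elem; ++i)
    if (p[i] < 0) p[i] = 0;
}
static void relu_bwd_ip(FM& dY, const FM& Y) {
  real_t* d = dY.memptr();
  const real_t* y = Y.memptr();
  for (size_t i = 0; i < dY.n_elem; ++i)
    if (y[i] <= 0) d[i] = 0;
}

struct MaxPool {
  int k = 3, s = 2, p = 1;
  Dims in, out;
  arma::Mat<arma::uword> idx;  // source column per (channel, out col)

  Dims out_dims(const Dims& d) const {
    Dims o = d;
    o.T = (d.T + 2 * p - k) / s + 1;
    o.H = (d.H + 2 * p - k) / s + 1;
    o.W = (d.W + 2 * p - k) / s + 1;
    return o;
  }

  FM forward(const FM& X, const Dims& d, bool keep) {
    in = d;
    out = out_dims(d);
    int C = d.C, Po = out.P(), P = d.P();
    FM Y(C, (size_t)d.N * Po);
    if (keep) idx.set_size(C, (size_t)d.N * Po);
    std::vector<size_t> cand;
    cand.reserve(27);
    for (int n = 0; n < d.N; ++n) {
      int po = 0;
      for (int to = 0; to < out.T; ++to)
        for (int ho = 0; ho < out.H; ++ho)
          for (int wo = 0; wo < out.W; ++wo) {
            cand.clear();
            for (int it = 0; it < k; ++it) {
              int t = to * s - p + it;
              if (t < 0 || t >= d.T) continue;
              for (int ih = 0; ih < k; ++ih) {
                int h = ho * s - p + ih;
                if (h < 0 || h >= d.H) continue;
                for (int iw = 0; iw < k; ++iw) {
                  int w = wo * s - p + iw;
                  if (w < 0 || w >= d.W) continue;
                  cand.push_back((size_t)n * P + (t * d.H + h) * d.W + w);
                }
              }
            }
            size_t oc = (size_t)n * Po + po;
            for (int c = 0; c < C; ++c) {
              real_t best = -std::numeric_limits<real_t>::infinity();
              size_t bi = cand[0];
              for (size_t ci : cand) {
                real_t v = X(c, ci);
                if (v > best) { best = v; bi = ci; }
              }
              Y(c, oc) = best;
              if (keep) idx(c, oc) = bi;
            }
            ++po;
          }
    }
    return Y;
  }

  FM backward(const FM& dY) {
    FM dX(dY.n_rows, (size_t)in.N * in.P(), arma::fill::zeros);
    for (size_t j = 0; j < dY.n_cols; ++j)
      for (arma::uword c = 0; c < dY.n_rows; ++c) dX(c, idx(c, j)) += dY(c, j);
    return dX;
  }
};

struct Bottleneck {
  Conv3d c1, c2, c3, cd;
  BatchNorm b1, b2, b3, bd;
  bool has_down = false;
  // caches (y1, y2: post-ReLU intra-block activations)
  FM y1, y2;
  Dims din;

  void setup(int cin, int cmid, int cout, int stride, bool down,
             std::mt19937_64& rng) {
    has_down = down;
    c1.setup(cin, cmid, 1, 1, 1, 1, 0, 0, 0, rng);
    c2.setup(cmid, cmid, 3, 3, 3, stride, 1, 1, 1, rng);
    c3.setup(cmid, cout, 1, 1, 1, 1, 0, 0, 0, rng);
    b1.setup(cmid); b2.setup(cmid); b3.setup(cout);
    b3.gamma.zeros();  // zero-init residual: block starts as identity,
                       // keeping initial gradient norms compatible with
                       // aggressive SGD + tight clipping
    if (down) {
      cd.setup(cin, cout, 1, 1, 1, stride, 0, 0, 0, rng);
      bd.setup(cout);
    }
  }

  FM forward(const FM& X, Dims& d, bool train) {
    din = d;
    FM h = c1.forward(X, d, train);
    Dims d1 = c1.out;
    b1.forward_ip(h, train, train);
    relu_ip(h);
    FM h2 = c2.forward(h, d1, train);
    if (train) y1 = std::move(h);
    Dims d2 = c2.out;
    b2.forward_ip(h2, train, train);
    relu_ip(h2);
    FM h3 = c3.forward(h2, d2, train);
    if (train) y2 = std::move(h2);
    Dims d3 = c3.out;
    b3.forward_ip(h3, train, train);
    if (has_down) {
      FM sc = cd.forward(X, d, train);
      bd.forward_ip(sc, train, train);
      h3 += sc;
    } else {
      h3 += X;
    }
    relu_ip(h3);
    d = d3;
    return h3;
  }

  // x_in / y_out are the block's input and (post-ReLU) output activations,
  // owned by the enclosing network's activation chain.
  FM backward(FM dOut, const FM& x_in, const FM& y_out) {
    relu_bwd_ip(dOut, y_out);
    FM dsc = dOut;  // shortcut-branch gradient, taken before b3 consumes dOut
    b3.backward_ip(dOut);
    FM dh = c3.backward(y2, dOut);
    relu_bwd_ip(dh, y2);
    b2.backward_ip(dh);
    dh = c2.backward(y1, dh);
    relu_bwd_ip(dh, y1);
    b1.backward_ip(dh);
    FM dX = c1.backward(x_in, dh);
    if (has_down) {
      bd.backward_ip(dsc);
      dX += cd.backward(x_in, dsc);
    } else {
      dX += dsc;
    }
    return dX;
  }
};

struct Net {
  int n_frames, base_width, n_classes, hidden;
  std::mt19937_64 rng;
  Conv3d stem;
  BatchNorm bn_stem;
  MaxPool pool;
  std::vector<Bottleneck> blocks;
  FM W1, dW1, W2, dW2;
  FV bias1, db1, bias2, db2;
  int feat_dim = 0;
  // caches
  FM stem_y, pool_y, feat, fc1_y;
  std::vector<FM> acts;  // per-block outputs (training mode)
  Dims d_in, d_pool;

  Net(int nf, int bw, int nc, unsigned int seed, int hidden_ = 256)
      : n_frames(nf), base_width(bw), n_classes(nc), hidden(hidden_), rng(seed) {
    stem.setup(1, bw, 7, 3, 3, 1, 3, 1, 1, rng);
    bn_stem.setup(bw);
    const int nblocks[4] = {3, 4, 6, 3};
    int cin = bw;
    for (int s = 0; s < 4; ++s) {
      int cmid = bw << s;          // bw, 2bw, 4bw, 8bw
      int cout = cmid * 4;         // x4 bottleneck expansion
      int stride = (s == 0) ? 1 : 2;
      for (int b = 0; b < nblocks[s]; ++b) {
        Bottleneck blk;
        blk.setup(cin, cmid, cout, b == 0 ? stride : 1, b == 0, rng);
        blocks.push_back(std::move(blk));
        cin = cout;
      }
    }
    feat_dim = cin;
    double sd1 = std::sqrt(2.0 / feat_dim), sd2 = std::sqrt(2.0 / hidden);
    std::normal_distribution<double> n1(0, sd1), n2(0, sd2);
    W1.set_size(hidden, feat_dim);
    for (arma::uword i = 0; i < W1.n_elem; ++i) W1[i] = (real_t)n1(rng);
    W2.set_size(n_classes, hidden);
    for (arma::uword i = 0; i < W2.n_elem; ++i) W2[i] = (real_t)n2(rng);
    bias1.zeros(hidden); bias2.zeros(n_classes);
    dW1.zeros(arma::size(W1)); dW2.zeros(arma::size(W2));
    db1.zeros(hidden); db2.zeros(n_classes);
  }

  // X: 1 x (N*P) with P = n_frames*17*17
  FM forward(const FM& X, int N, bool train) {
    Dims d{1, n_frames, 17, 17, N};
    d_in = d;
    FM h = stem.forward_stem(X, d);
    d = stem.out;
    bn_stem.forward_ip(h, train, train);
    relu_ip(h);
    if (train) stem_y = h;
    h = pool.forward(h, d, train);
    d = pool.out;
    d_pool = d;
    if (train) {
      acts.resize(blocks.size());
      pool_y = std::move(h);
      const FM* cur = &pool_y;
      for (size_t i = 0; i < blocks.size(); ++i) {
        acts[i] = blocks[i].forward(*cur, d, true);
        cur = &acts[i];
      }
      h = acts.back();  // copy of the final activation for the head
    } else {
      for (auto& blk : blocks) h = blk.forward(h, d, false);
    }
    // global average pooling -> feature matrix (feat_dim x N)
    int P = d.P();
    FM F(feat_dim, N);
    for (int n = 0; n < N; ++n)
      F.col(n) = arma::mean(h.cols((size_t)n * P, (size_t)(n + 1) * P - 1), 1);
    if (train) feat = F;
    FM h1 = W1 * F;
    h1.each_col() += bias1;
    relu_ip(h1);
    if (train) fc1_y = h1;
    FM logits = W2 * h1;
    logits.each_col() += bias2;
    if (train) { last_d = d; last_N = N; }
    return logits;
  }

  Dims last_d;
  int last_N = 0;

  void backward(const FM& dLogits) {
    dW2 += dLogits * fc1_y.t();
    db2 += arma::sum(dLogits, 1);
    FM dh1 = W2.t() * dLogits;
    relu_bwd_ip(dh1, fc1_y);
    dW1 += dh1 * feat.t();
    db1 += arma::sum(dh1, 1);
    FM dF = W1.t() * dh1;  // feat_dim x N
    int P = last_d.P();
    FM dh(feat_dim, (size_t)last_N * P);
    for (int n = 0; n < last_N; ++n) {
      FV g = dF.col(n) / (real_t)P;
      for (int p = 0; p < P; ++p) dh.col((size_t)n * P + p) = g;
    }
    for (int i = (int)blocks.size() - 1; i >= 0; --i) {
      const FM& x_in = (i == 0) ? pool_y : acts[i - 1];
      dh = blocks[i].backward(std::move(dh), x_in, acts[i]);
    }
    dh = pool.backward(dh);
    relu_bwd_ip(dh, stem_y);
    bn_stem.backward_ip(dh);
    stem.backward_stem(dh);
  }

  template <class F>
  void each_param(F f) {
    f(stem.Wt, stem.dW);
    auto bnp = [&](BatchNorm& b) {
      FM g(b.gamma.memptr(), b.C, 1, false, true);
      (void)g;
    };
    (void)bnp;
    for (auto& blk : blocks) {
      f(blk.c1.Wt, blk.c1.dW);
      f(blk.c2.Wt, blk.c2.dW);
      f(blk.c3.Wt, blk.c3.dW);
      if (blk.has_down) f(blk.cd.Wt, blk.cd.dW);
    }
    f(W1, dW1);
    f(W2, dW2);
  }

  template <class F>
  void each_bn(F f) {
    f(bn_stem);
    for (auto& blk : blocks) {
      f(blk.b1);
      f(blk.b2);
      f(blk.b3);
      if (blk.has_down) f(blk.bd);
    }
  }

  void zero_grad() {
    each_param([](FM&, FM& g) { g.zeros(); });
    each_bn([](BatchNorm& b) {
      b.dgamma.zeros();
      b.dbeta.zeros();
    });
    db1.zeros(); db2.zeros();
  }

  double grad_norm() {
    double s = 0;
    each_param([&](FM&, FM& g) { s += arma::dot(g, g); });
    each_bn([&](BatchNorm& b) {
      s += arma::dot(b.dgamma, b.dgamma) + arma::dot(b.dbeta, b.dbeta);
    });
    s += arma::dot(db1, db1) + arma::dot(db2, db2);
    return std::sqrt(s);
  }

  void sgd_step(double lr, double clip) {
    double gn = grad_norm();
    double scale = (clip > 0 && gn > clip) ? clip / gn : 1.0;
    real_t a = (real_t)(lr * scale);
    each_param([&](FM& w, FM& g) { w -= a * g; });
    each_bn([&](BatchNorm& b) {
      b.gamma -= a * b.dgamma;
      b.beta -= a * b.dbeta;
    });
    bias1 -= a * db1;
    bias2 -= a * db2;
  }

  size_t n_params() {
    size_t s = 0;
    each_param([&](FM& w, FM&) { s += w.n_elem; });
    each_bn([&](BatchNorm& b) { s += 2 * (size_t)b.C; });
    s += bias1.n_elem + bias2.n_elem;
    return s;
  }

  List get_params() {
    List out;
    std::vector<float> buf;
    int k = 0;
    each_param([&](FM& w, FM&) {
      out.push_back(NumericVector(w.begin(), w.end()));
      ++k;
    });
    each_bn([&](BatchNorm& b) {
      out.push_back(List::create(
          NumericVector(b.gamma.begin(), b.gamma.end()),
          NumericVector(b.beta.begin(), b.beta.end()),
          NumericVector(b.rmean.begin(), b.rmean.end()),
          NumericVector(b.rvar.begin(), b.rvar.end())));
    });
    out.push_back(NumericVector(bias1.begin(), bias1.end()));
    out.push_back(NumericVector(bias2.begin(), bias2.end()));
    return out;
  }

  void set_params(List p) {
    int i = 0;
    each_param([&](FM& w, FM&) {
      NumericVector v = p[i++];
      if ((size_t)v.size() != w.n_elem) stop("checkpoint weight size mismatch");
      std::copy(v.begin(), v.end(), w.begin());
    });
    each_bn([&](BatchNorm& b) {
      List l = p[i++];
      NumericVector g = l[0], be = l[1], rm = l[2], rv = l[3];
      std::copy(g.begin(), g.end(), b.gamma.begin());
      std::copy(be.begin(), be.end(), b.beta.begin());
      std::copy(rm.begin(), rm.end(), b.rmean.begin());
      std::copy(rv.begin(), rv.end(), b.rvar.begin());
    });
    NumericVector v1 = p[i++], v2 = p[i++];
    std::copy(v1.begin(), v1.end(), bias1.begin());
    std::copy(v2.begin(), v2.end(), bias2.begin());
  }
};

// Convert an R thumbnail array (n_frames, 17, 17, N) to engine layout 1 x N*P,
// p = (t*17 + h)*17 + w.
static FM to_engine(const NumericVector& x, int T, int N) {
  const int Hh = 17, Ww = 17;
  size_t P = (size_t)T * Hh * Ww;
  FM X(1, (size_t)N * P);
  const double* src = x.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < Ww; ++w)
      for (int h = 0; h < Hh; ++h)
        for (int t = 0; t < T; ++t) {
          size_t p = ((size_t)t * Hh + h) * Ww + w;
          X(0, (size_t)n * P + p) =
              (real_t)src[t + (size_t)T * (h + (size_t)Hh * (w + (size_t)Ww * n))];
        }
  return X;
}

// [[Rcpp::export]]
SEXP cpp_net_new(int n_frames, int base_width, int n_classes, int seed,
                 int hidden = 256) {
  Net* net = new Net(n_frames, base_width, n_classes, (unsigned int)seed, hidden);
  XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
NumericMatrix cpp_net_forward(SEXP netp, NumericVector x, int n_frames, int N,
                              int batch = 64) {
  tune_allocator();
  XPtr<Net> net(netp);
  if (n_frames != net->n_frames)
    stop("thumbnail has %d frames but model expects %d", n_frames, net->n_frames);
  FM X = to_engine(x, n_frames, N);
  size_t P = X.n_cols / N;
  NumericMatrix out(N, net->n_classes);
  for (int b0 = 0; b0 < N; b0 += batch) {
    int b1 = std::min(N, b0 + batch);
    FM Xb = X.cols((size_t)b0 * P, (size_t)b1 * P - 1);
    FM lg = net->forward(Xb, b1 - b0, false);
    for (int j = 0; j < b1 - b0; ++j)
      for (int c = 0; c < net->n_classes; ++c) out(b0 + j, c) = lg(c, j);
  }
  return out;
}

// [[Rcpp::export]]
int cpp_net_nparams(SEXP netp) {
  XPtr<Net> net(netp);
  return (int)net->n_params();
}

// [[Rcpp::export]]
List cpp_net_get_params(SEXP netp) {
  XPtr<Net> net(netp);
  return net->get_params();
}

// [[Rcpp::export]]
void cpp_net_set_params(SEXP netp, List p) {
  XPtr<Net> net(netp);
  net->set_params(p);
}

// [[Rcpp::export]]
List cpp_net_info(SEXP netp) {
  XPtr<Net> net(netp);
  return List::create(_["n_frames"] = net->n_frames,
                      _["base_width"] = net->base_width,
                      _["n_classes"] = net->n_classes,
                      _["hidden"] = net->hidden,
                      _["n_blocks"] = (int)net->blocks.size(),
                      _["n_params"] = (double)net->n_params());
}

// Debug/testing aid: one training-mode forward+backward pass; returns the
// mean cross-entropy and all parameter gradients (same order as get_params).
// [[Rcpp::export]]
List cpp_net_lossgrad(SEXP netp, NumericVector x, IntegerVector y, int N) {
  XPtr<Net> net(netp);
  FM X = to_engine(x, net->n_frames, N);
  net->zero_grad();
  FM lg = net->forward(X, N, true);
  double loss = 0;
  FM dlg(lg.n_rows, lg.n_cols);
  for (int j = 0; j < N; ++j) {
    FV l = lg.col(j);
    real_t mx = l.max();
    FV e = arma::exp(l - mx);
    real_t Z = arma::accu(e);
    int lab = y[j];
    loss += -(double)(l[lab] - mx - std::log(Z));
    FV probs = e / Z;
    probs[lab] -= 1;
    dlg.col(j) = probs / (real_t)N;
  }
  net->backward(dlg);
  List grads;
  net->each_param([&](FM&, FM& g) {
    grads.push_back(NumericVector(g.begin(), g.end()));
  });
  net->each_bn([&](BatchNorm& b) {
    grads.push_back(List::create(
        NumericVector(b.dgamma.begin(), b.dgamma.end()),
        NumericVector(b.dbeta.begin(), b.dbeta.end())));
  });
  grads.push_back(NumericVector(net->db1.begin(), net->db1.end()));
  grads.push_back(NumericVector(net->db2.begin(), net->db2.end()));
  return List::create(_["loss"] = loss / N, _["grads"] = grads);
}

static double eval_set(Net& net, const FM& X, const IntegerVector& y, int N,
                       int batch, double& acc) {
  size_t P = X.n_cols / N;
  double loss = 0;
  int correct = 0;
  for (int b0 = 0; b0 < N; b0 += batch) {
    int b1 = std::min(N, b0 + batch);
    FM Xb = X.cols((size_t)b0 * P, (size_t)b1 * P - 1);
    FM lg = net.forward(Xb, b1 - b0, false);
    for (int j = 0; j < b1 - b0; ++j) {
      FV l = lg.col(j);
      real_t mx = l.max();
      FV e = arma::exp(l - mx);
      real_t Z = arma::accu(e);
      int lab = y[b0 + j];
      loss += -(double)(l[lab] - mx - std::log(Z));
      if ((int)l.index_max() == lab) ++correct;
    }
  }
  acc = (double)correct / N;
  return loss / N;
}

// [[Rcpp::export]]
List cpp_net_train(SEXP netp, NumericVector xtr, IntegerVector ytr, int Ntr,
                   NumericVector xval, IntegerVector yval, int Nval, int epochs,
                   int batch_size, double lr, double clip, int patience,
                   double factor, int seed, bool snapshot_best = true,
                   bool use_scheduler = true, bool verbose = false,
                   bool augment = true) {
  tune_allocator();
  XPtr<Net> net(netp);
  int T = net->n_frames;
  FM Xtr = to_engine(xtr, T, Ntr);
  FM Xval;
  if (Nval > 0) Xval = to_engine(xval, T, Nval);
  size_t P = (size_t)T * 17 * 17;
  std::mt19937_64 shuf_rng((unsigned int)seed);
  std::vector<int> order(Ntr);
  for (int i = 0; i < Ntr; ++i) order[i] = i;
  std::vector<double> h_tl, h_ta, h_vl, h_va, h_lr;
  double best_vloss = std::numeric_limits<double>::infinity();
  double best_vacc = -1;
  int wait = 0, best_epoch = -1;
  List best_state;
  FM Xb;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), shuf_rng);
    double tloss = 0;
    int tcorrect = 0, seen = 0;
    for (int b0 = 0; b0 < Ntr; b0 += batch_size) {
      int b1 = std::min(Ntr, b0 + batch_size);
      int B = b1 - b0;
      Xb.set_size(1, (size_t)B * P);
      for (int j = 0; j < B; ++j) {
        const real_t* src = Xtr.colptr((size_t)order[b0 + j] * P);
        real_t* dst = Xb.colptr((size_t)j * P);
        int g = augment ? (int)(shuf_rng() & 7u) : 0;
        if (g == 0) {
          std::copy(src, src + P, dst);
        } else {
          // random dihedral transform of the 17x17 spatial plane; the event
          // distribution is exactly invariant under flips and rotations
          bool fh = g & 1, fv = g & 2, tr = g & 4;
          for (int w = 0; w < 17; ++w)
            for (int h = 0; h < 17; ++h) {
              int hs = fv ? 16 - h : h, ws = fh ? 16 - w : w;
              if (tr) std::swap(hs, ws);
              for (int t = 0; t < T; ++t)
                dst[((size_t)t * 17 + h) * 17 + w] =
                    src[((size_t)t * 17 + hs) * 17 + ws];
            }
        }
      }
      net->zero_grad();
      FM lg = net->forward(Xb, B, true);
      // softmax cross-entropy
      FM dlg(lg.n_rows, lg.n_cols);
      for (int j = 0; j < B; ++j) {
        FV l = lg.col(j);
        real_t mx = l.max();
        FV e = arma::exp(l - mx);
        real_t Z = arma::accu(e);
        int lab = ytr[order[b0 + j]];
        tloss += -(double)(l[lab] - mx - std::log(Z));
        if ((int)l.index_max() == lab) ++tcorrect;
        FV probs = e / Z;
        probs[lab] -= 1;
        dlg.col(j) = probs / (real_t)B;
      }
      if (!std::isfinite(tloss)) stop("training loss diverged (non-finite)");
      net->backward(dlg);
      net->sgd_step(lr, clip);
      seen += B;
      if ((b0 / batch_size) % 50 == 0) Rcpp::checkUserInterrupt();
    }
    double vacc = NA_REAL, vloss = NA_REAL;
    if (Nval > 0) vloss = eval_set(*net, Xval, yval, Nval, 64, vacc);
    h_tl.push_back(tloss / seen);
    h_ta.push_back((double)tcorrect / seen);
    h_vl.push_back(vloss);
    h_va.push_back(vacc);
    h_lr.push_back(lr);
    if (verbose)
      Rcout << "epoch " << ep + 1 << " train_loss " << tloss / seen
            << " train_acc " << (double)tcorrect / seen << " val_loss " << vloss
            << " val_acc " << vacc << " lr " << lr << "\n";
    if (Nval > 0) {
      if (snapshot_best && vacc > best_vacc) {
        best_vacc = vacc;
        best_epoch = ep + 1;
        best_state = net->get_params();
      }
      if (use_scheduler) {
        if (vloss < best_vloss - 1e-4) {
          best_vloss = vloss;
          wait = 0;
        } else if (++wait >= patience) {
          lr *= factor;
          wait = 0;
        }
      }
    }
  }
  if (snapshot_best && best_epoch > 0) net->set_params(best_state);
  return List::create(_["train_loss"] = h_tl, _["train_acc"] = h_ta,
                      _["val_loss"] = h_vl, _["val_acc"] = h_va, _["lr"] = h_lr,
                      _["best_epoch"] = best_epoch, _["best_val_acc"] = best_vacc);
}
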