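// Compact CNN engine for density-map seed counting.
//
// Feature maps are arma::fmat of shape (H*W) x C with pixel index
// p = x*H + y (column-major, matching R's matrix layout), so an R image
// matrix maps onto a single feature-map column without reshuffling.
// Convolutions use 'same' zero padding and im2col + sgemm; only the 2x2
// max pools (and the stride-2 transposed convolutions in the upsampling
// head) change spatial resolution.
//
// Single precision internally; parameters cross the R boundary as doubles.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fvec;
using arma::uvec;

namespace {

// ---------------------------------------------------------------------------
// parameter tensor with gradient and optimizer state
// ---------------------------------------------------------------------------
struct Param {
  fmat w, g, m, v;  // value, gradient, momentum / Adam first, Adam second
  void init(int r, int c, std::mt19937_64& rng, double sd) {
    w.set_size(r, c);
    std::normal_distribution<double> N(0.0, sd);
    for (arma::uword i = 0; i < w.n_elem; ++i) w[i] = (float)N(rng);
    g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
  void init_const(int r, int c, double val) {
    w.set_size(r, c); w.fill((float)val);
    g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
};

struct OptSpec {
  int kind = 0;        // 0 = SGD + momentum, 1 = Adam
  float lr = 1e-5f, momentum = 0.9f;
  float beta1 = 0.9f, beta2 = 0.999f, eps = 1e-8f;
  long t = 0;          // Adam step counter (shared across params)
};

void step_param(Param& p, const OptSpec& o) {
  if (o.kind == 0) {
    p.m = o.momentum * p.m + p.g;
    p.w -= o.lr * p.m;
  } else {
    p.m = o.beta1 * p.m + (1.0f - o.beta1) * p.g;
    p.v = o.beta2 * p.v + (1.0f - o.beta2) * arma::square(p.g);
    float bc1 = 1.0f - std::pow(o.beta1, (float)o.t);
    float bc2 = 1.0f - std::pow(o.beta2, (float)o.t);
    p.w -= o.lr * (p.m / bc1) / (arma::sqrt(p.v / bc2) + o.eps);
  }
}

// ---------------------------------------------------------------------------
// im2col / col2im ('same' padding, odd kernels)
// ---------------------------------------------------------------------------
// col(p, ci*k*k + kx*k + ky) = X(shifted p, ci), zero outside the image.
fmat im2col(const fmat& X, int H, int W, int k) {
  const int pad = k / 2, KK = k * k, cin = X.n_cols;
  fmat col(H * W, cin * KK, arma::fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    const float* src = X.colptr(ci);
    for (int kx = 0; kx < k; ++kx) {
      const int dx = kx - pad;
      for (int ky = 0; ky < k; ++ky) {
        const int dy = ky - pad;
        float* dst = col.colptr(ci * KK + kx * k + ky);
        const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        if (y1 <= y0) continue;
        for (int x = x0; x < x1; ++x)
          std::memcpy(dst + x * H + y0, src + (x + dx) * H + (y0 + dy),
                      sizeof(float) * (y1 - y0));
      }
    }
  }
  return col;
}

// scatter-add transpose of im2col
fmat col2im(const fmat& dcol, int H, int W, int k, int cin) {
  const int pad = k / 2, KK = k * k;
  fmat dX(H * W, cin, arma::fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    float* dst = dX.colptr(ci);
    for (int kx = 0; kx < k; ++kx) {
      const int dx = kx - pad;
      for (int ky = 0; ky < k; ++ky) {
        const int dy = ky - pad;
        const float* src = dcol.colptr(ci * KK + kx * k + ky);
        const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        if (y1 <= y0) continue;
        for (int x = x0; x < x1; ++x) {
          float* d = dst + (x + dx) * H + (y0 + dy);
          const float* s = src + x * H + y0;
          for (int y = 0; y < y1 - y0; ++y) d[y] += s[y];
        }
      }
    }
  }
  return dX;
}

// ---------------------------------------------------------------------------
// layers
// ---------------------------------------------------------------------------
enum Act { ACT_NONE = 0, ACT_RELU = 1, ACT_PRELU = 2 };

struct ConvLayer {
  int k = 3, cin = 1, cout = 1, act = ACT_RELU;
  bool pool = false;  // 2x2 max pool (stride 2) after activation
  Param W;            // (cin*k*k) x cout
  Param b;            // 1 x cout
  Param a;            // PReLU slope (1 x 1), used when act == ACT_PRELU
  // forward caches
  fmat col, pre;      // im2col of input; pre-activation output
  uvec poolidx;       // argmax source pixel per pooled element
  int Hin = 0, Win = 0, Hout = 0, Wout = 0;

  void init(int k_, int cin_, int cout_, int act_, bool pool_,
            std::mt19937_64& rng, double sd) {
    k = k_; cin = cin_; cout = cout_; act = act_; pool = pool_;
    if (sd <= 0) sd = std::sqrt(2.0 / (cin * k * k));  // fan-in scaled
    W.init(cin * k * k, cout, rng, sd);
    b.init_const(1, cout, 0.0);
    a.init_const(1, 1, 0.25);
  }

  fmat forward(const fmat& X, int H, int Wd) {
    Hin = H; Win = Wd;
    col = im2col(X, H, Wd, k);
    pre = col * W.w;
    pre.each_row() += b.w;
    fmat out;
    if (act == ACT_RELU)       out = arma::clamp(pre, 0.0f, arma::datum::inf);
    else if (act == ACT_PRELU) out = arma::max(pre, 0.0f * pre) + a.w(0, 0) * arma::min(pre, 0.0f * pre);
    else                       out = pre;
    if (!pool) { Hout = H; Wout = Wd; return out; }
    Hout = H / 2; Wout = Wd / 2;
    fmat pooled(Hout * Wout, cout);
    poolidx.set_size((arma::uword)Hout * Wout * cout);
    for (int c = 0; c < cout; ++c) {
      const float* s = out.colptr(c);
      float* d = pooled.colptr(c);
      for (int x = 0; x < Wout; ++x)
        for (int y = 0; y < Hout; ++y) {
          const int p00 = (2 * x) * H + 2 * y;
          int best = p00; float bv = s[p00];
          const int cand[3] = {p00 + 1, p00 + H, p00 + H + 1};
          for (int j = 0; j < 3; ++j)
            if (s[cand[j]] > bv) { bv = s[cand[j]]; best = cand[j]; }
          d[x * Hout + y] = bv;
          poolidx[(arma::uword)c * Hout * Wout + x * Hout + y] = best;
        }
    }
    return pooled;
  }

  // dOut at (Hout, Wout); returns dX at (Hin, Win); accumulates dW, db, da
  fmat backward(const fmat& dOut) {
    fmat dAct;
    if (pool) {
      dAct.zeros(Hin * Win, cout);
      for (int c = 0; c < cout; ++c) {
        const float* s = dOut.colptr(c);
        float* d = dAct.colptr(c);
        const arma::uword base = (arma::uword)c * Hout * Wout;
        for (int i = 0; i < Hout * Wout; ++i) d[poolidx[base + i]] += s[i];
      }
    } else dAct = dOut;
    fmat dPre;
    if (act == ACT_RELU) {
      dPre = dAct % arma::conv_to<fmat>::from(pre > 0.0f);
    } else if (act == ACT_PRELU) {
      fmat neg = arma::conv_to<fmat>::from(pre <= 0.0f);
      a.g(0, 0) += arma::accu(dAct % neg % pre);
      dPre = dAct % (1.0f - neg + a.w(0, 0) * neg);
    } else dPre = dAct;
    W.g += col.t() * dPre;
    b.g += arma::sum(dPre, 0);
    fmat dcol = dPre * W.w.t();
    return col2im(dcol, Hin, Win, k, cin);
  }
};

// stride-2 transposed convolution with a 2x2 kernel: each input pixel fills
// one 2x2 output block, so output blocks never overlap and resolution doubles
struct DeconvLayer {
  int cin = 1, cout = 1, act = ACT_PRELU;
  Param W;   // cin x (cout*4), sub-position j = dx*2 + dy
  Param b, a;
  fmat Xc, pre;
  int Hin = 0, Win = 0;

  void init(int cin_, int cout_, int act_, std::mt19937_64& rng, double sd) {
    cin = cin_; cout = cout_; act = act_;
    if (sd <= 0) sd = std::sqrt(2.0 / cin);
    W.init(cin, cout * 4, rng, sd);
    b.init_const(1, cout, 0.0);
    a.init_const(1, 1, 0.25);
  }

  fmat forward(const fmat& X, int H, int Wd) {
    Hin = H; Win = Wd; Xc = X;
    fmat T = X * W.w;  // (HW) x (cout*4)
    const int Ho = 2 * H;
    pre.set_size(4 * H * Wd, cout);
    for (int c = 0; c < cout; ++c) {
      float* d = pre.colptr(c);
      const float bc = b.w(0, c);
      for (int j = 0; j < 4; ++j) {
        const int dx = j / 2, dy = j % 2;
        const float* s = T.colptr(c * 4 + j);
        for (int x = 0; x < Wd; ++x)
          for (int y = 0; y < H; ++y)
            d[(2 * x + dx) * Ho + 2 * y + dy] = s[x * H + y] + bc;
      }
    }
    if (act == ACT_RELU)  return arma::clamp(pre, 0.0f, arma::datum::inf);
    if (act == ACT_PRELU) return arma::max(pre, 0.0f * pre) + a.w(0, 0) * arma::min(pre, 0.0f * pre);
    return pre;
  }

  fmat backward(const fmat& dOut) {
    fmat dPre;
    if (act == ACT_RELU) {
      dPre = dOut % arma::conv_to<fmat>::from(pre > 0.0f);
    } else if (act == ACT_PRELU) {
      fmat neg = arma::conv_to<fmat>::from(pre <= 0.0f);
      a.g(0, 0) += arma::accu(dOut % neg % pre);
      dPre = dOut % (1.0f - neg + a.w(0, 0) * neg);
    } else dPre = dOut;
    const int Ho = 2 * Hin;
    fmat dT(Hin * Win, cout * 4);
    for (int c = 0; c < cout; ++c) {
      const float* s = dPre.colptr(c);
      float acc = 0.0f;
      for (int j = 0; j < 4; ++j) {
        const int dx = j / 2, dy = j % 2;
        float* d = dT.colptr(c * 4 + j);
        for (int x = 0; x < Win; ++x)
          for (int y = 0; y < Hin; ++y)
            d[x * Hin + y] = s[(2 * x + dx) * Ho + 2 * y + dy];
      }
      for (arma::uword i = 0; i < dPre.n_rows; ++i) acc += dPre(i, c);
      b.g(0, c) += acc;
    }
    W.g += Xc.t() * dT;
    return dT * W.w.t();
  }
};

struct FCLayer {
  int nin = 1, nout = 1, act = ACT_PRELU;
  Param W;  // nin x nout
  Param b, a;
  fvec xin, pre;

  void init(int nin_, int nout_, int act_, std::mt19937_64& rng, double sd) {
    nin = nin_; nout = nout_; act = act_;
    if (sd <= 0) sd = std::sqrt(2.0 / nin);
    W.init(nin, nout, rng, sd);
    b.init_const(1, nout, 0.0);
    a.init_const(1, 1, 0.25);
  }
  fvec forward(const fvec& x) {
    xin = x;
    pre = W.w.t() * x + b.w.t();
    if (act == ACT_RELU)  return arma::clamp(pre, 0.0f, arma::datum::inf);
    if (act == ACT_PRELU) return arma::max(pre, arma::zeros<fvec>(nout)) + a.w(0, 0) * arma::min(pre, arma::zeros<fvec>(nout));
    return pre;
  }
  fvec backward(const fvec& dOut) {
    fvec dPre;
    if (act == ACT_RELU) {
      dPre = dOut % arma::conv_to<fvec>::from(pre > 0.0f);
    } else if (act == ACT_PRELU) {
      fvec neg = arma::conv_to<fvec>::from(pre <= 0.0f);
      a.g(0, 0) += arma::dot(dOut % neg, pre);
      dPre = dOut % (1.0f - neg + a.w(0, 0) * neg);
    } else dPre = dOut;
    W.g += xin * dPre.t();
    b.g += dPre.t();
    return W.w * dPre;
  }
};

// ---------------------------------------------------------------------------
// spatial pyramid pooling: per channel, max over each block of the 1x1, 2x2
// and 4x4 floor-boundary partitions -> 21 values per channel
// ---------------------------------------------------------------------------
struct SPP {
  std::vector<int> levels{1, 2, 4};
  uvec idx;        // flat (pixel, channel) argmax per output element
  int HW = 0, C = 0;

  int nbins() const {
    int n = 0;
    for (int l : levels) n += l * l;
    return n;
  }

  fvec forward(const fmat& X, int H, int W) {
    HW = H * W; C = X.n_cols;
    const int nb = nbins();
    fvec out((arma::uword)nb * C);
    idx.set_size((arma::uword)nb * C);
    arma::uword o = 0;
    for (int c = 0; c < C; ++c) {
      const float* s = X.colptr(c);
      for (int l : levels)
        for (int bx = 0; bx < l; ++bx) {
          const int x0 = (bx * W) / l, x1 = ((bx + 1) * W) / l;
          for (int by = 0; by < l; ++by) {
            const int y0 = (by * H) / l, y1 = ((by + 1) * H) / l;
            int bp = x0 * H + y0; float bv = s[bp];
            for (int x = x0; x < x1; ++x)
              for (int y = y0; y < y1; ++y) {
                const int p = x * H + y;
                if (s[p] > bv) { bv = s[p]; bp = p; }
              }
            out[o] = bv;
            idx[o] = (arma::uword)c * HW + bp;
            ++o;
          }
        }
    }
    return out;
  }

  fmat backward(const fvec& dOut) {
    fmat dX(HW, C, arma::fill::zeros);
    for (arma::uword o = 0; o < dOut.n_elem; ++o) dX[idx[o]] += dOut[o];
    return dX;
  }
};

// bilinear resize (align to pixel centers); identity when sizes match
fmat resize_bilinear(const fmat& X, int H, int W, int Ho, int Wo) {
  if (H == Ho && W == Wo) return X;
  const int C = X.n_cols;
  fmat out(Ho * Wo, C);
  const float sy = (float)H / Ho, sx = (float)W / Wo;
  for (int c = 0; c < C; ++c) {
    const float* s = X.colptr(c);
    float* d = out.colptr(c);
    for (int x = 0; x < Wo; ++x) {
      float fx = std::max(0.0f, std::min((x + 0.5f) * sx - 0.5f, (float)(W - 1)));
      int x0 = (int)fx, x1 = std::min(x0 + 1, W - 1);
      float wx = fx - x0;
      for (int y = 0; y < Ho; ++y) {
        float fy = std::max(0.0f, std::min((y + 0.5f) * sy - 0.5f, (float)(H - 1)));
        int y0 = (int)fy, y1 = std::min(y0 + 1, H - 1);
        float wy = fy - y0;
        d[x * Ho + y] =
          (1 - wx) * ((1 - wy) * s[x0 * H + y0] + wy * s[x0 * H + y1]) +
          wx * ((1 - wy) * s[x1 * H + y0] + wy * s[x1 * H + y1]);
      }
    }
  }
  return out;
}

fmat resize_bilinear_back(const fmat& dOut, int H, int W, int Ho, int Wo) {
  if (H == Ho && W == Wo) return dOut;
  const int C = dOut.n_cols;
  fmat dX(H * W, C, arma::fill::zeros);
  const float sy = (float)H / Ho, sx = (float)W / Wo;
  for (int c = 0; c < C; ++c) {
    const float* s = dOut.colptr(c);
    float* d = dX.colptr(c);
    for (int x = 0; x < Wo; ++x) {
      float fx = std::max(0.0f, std::min((x + 0.5f) * sx - 0.5f, (float)(W - 1)));
      int x0 = (int)fx, x1 = std::min(x0 + 1, W - 1);
      float wx = fx - x0;
      for (int y = 0; y < Ho; ++y) {
        float fy = std::max(0.0f, std::min((y + 0.5f) * sy - 0.5f, (float)(H - 1)));
        int y0 = (int)fy, y1 = std::min(y0 + 1, H - 1);
        float wy = fy - y0;
        const float g = s[x * Ho + y];
        d[x0 * H + y0] += (1 - wx) * (1 - wy) * g;
        d[x0 * H + y1] += (1 - wx) * wy * g;
        d[x1 * H + y0] += wx * (1 - wy) * g;
        d[x1 * H + y1] += wx * wy * g;
      }
    }
  }
  return dX;
}

// ---------------------------------------------------------------------------
// networks
// ---------------------------------------------------------------------------
struct Net {
  std::string kind;                       // "mcnn" | "improved"
  std::vector<std::vector<ConvLayer>> cols;
  ConvLayer fuse;                         // mcnn: 1x1 fusion conv
  // improved-only parts
  std::vector<ConvLayer> prior;
  SPP spp;
  std::vector<FCLayer> fcs;
  std::vector<ConvLayer> head;            // two 3x3 fusion convs
  DeconvLayer up1, up2;
  ConvLayer final1x1;
  int n_classes = 5;
  bool prior_on_image = true;             // prior consumes the raw image
  OptSpec opt;
  std::mt19937_64 rng;
  // caches for backward
  std::vector<int> col_ch;                // channels per column at trunk output
  int Ht = 0, Wt = 0;                     // trunk (1/4) resolution
  int Hp = 0, Wp = 0;                     // prior feature resolution
  fvec logits_cache, sm_cache;
  fmat ci_cache;                          // prior conv output (pre-resize)

  std::vector<std::pair<std::string, Param*>> params() {
    std::vector<std::pair<std::string, Param*>> out;
    auto add_conv = [&](const std::string& nm, ConvLayer& c) {
      out.push_back({nm + ".W", &c.W});
      out.push_back({nm + ".b", &c.b});
      if (c.act == ACT_PRELU) out.push_back({nm + ".a", &c.a});
    };
    for (size_t i = 0; i < cols.size(); ++i)
      for (size_t j = 0; j < cols[i].size(); ++j)
        add_conv("col" + std::to_string(i + 1) + ".conv" + std::to_string(j + 1), cols[i][j]);
    if (kind == "mcnn") add_conv("fuse", fuse);
    else {
      for (size_t j = 0; j < prior.size(); ++j)
        add_conv("prior.conv" + std::to_string(j + 1), prior[j]);
      for (size_t j = 0; j < fcs.size(); ++j) {
        FCLayer& f = fcs[j];
        std::string nm = "prior.fc" + std::to_string(j + 1);
        out.push_back({nm + ".W", &f.W});
        out.push_back({nm + ".b", &f.b});
        if (f.act == ACT_PRELU) out.push_back({nm + ".a", &f.a});
      }
      for (size_t j = 0; j < head.size(); ++j)
        add_conv("head.conv" + std::to_string(j + 1), head[j]);
      out.push_back({"head.up1.W", &up1.W});
      out.push_back({"head.up1.b", &up1.b});
      out.push_back({"head.up1.a", &up1.a});
      out.push_back({"head.up2.W", &up2.W});
      out.push_back({"head.up2.b", &up2.b});
      out.push_back({"head.up2.a", &up2.a});
      add_conv("head.final", final1x1);
    }
    return out;
  }

  void zero_grad() {
    for (auto& pr : params()) pr.second->g.zeros();
  }

  // trunk: run all columns, return channel-concatenated 1/4-resolution map
  fmat trunk_forward(const fmat& img, int H, int W) {
    fmat cat;
    col_ch.clear();
    for (auto& column : cols) {
      fmat x = img;
      int h = H, w = W;
      for (auto& ly : column) {
        x = ly.forward(x, h, w);
        h = ly.Hout; w = ly.Wout;
      }
      Ht = h; Wt = w;
      col_ch.push_back(x.n_cols);
      cat = cat.n_elem ? arma::join_horiz(cat, x) : x;
    }
    return cat;
  }

  fmat trunk_backward(const fmat& dCat) {
    fmat dImg;
    int off = 0;
    for (size_t i = 0; i < cols.size(); ++i) {
      fmat d = dCat.cols(off, off + col_ch[i] - 1);
      off += col_ch[i];
      for (int j = (int)cols[i].size() - 1; j >= 0; --j) d = cols[i][j].backward(d);
      dImg = dImg.n_elem ? fmat(dImg + d) : d;
    }
    return dImg;
  }

  // prior branch up to Ci; logits computed separately so the density pass
  // can reuse Ci
  fmat prior_conv_forward(const fmat& img, int H, int W) {
    fmat x = img;
    int h = H, w = W;
    for (auto& ly : prior) {
      x = ly.forward(x, h, w);
      h = ly.Hout; w = ly.Wout;
    }
    Hp = h; Wp = w;
    return x;
  }

  fvec prior_head_forward(const fmat& ci) {
    fvec v = spp.forward(ci, Hp, Wp);
    for (auto& f : fcs) v = f.forward(v);
    return v;
  }

  // full forward; density in first element, logits (improved) in second
  std::pair<fmat, fvec> forward(const fmat& img, int H, int W) {
    if (kind == "mcnn") {
      fmat cat = trunk_forward(img, H, W);
      fmat den = fuse.forward(cat, Ht, Wt);
      return {den, fvec()};
    }
    fmat cat = trunk_forward(img, H, W);
    ci_cache = prior_conv_forward(img, H, W);
    logits_cache = prior_head_forward(ci_cache);
    fmat ci_r = resize_bilinear(ci_cache, Hp, Wp, Ht, Wt);
    fmat x = arma::join_horiz(cat, ci_r);
    int h = Ht, w = Wt;
    for (auto& ly : head) {
      x = ly.forward(x, h, w);
      h = ly.Hout; w = ly.Wout;
    }
    x = up1.forward(x, h, w); h *= 2; w *= 2;
    x = up2.forward(x, h, w); h *= 2; w *= 2;
    fmat den = final1x1.forward(x, h, w);
    return {den, logits_cache};
  }

  // backward from density gradient and (optional) scaled softmax-CE gradient
  void backward(const fmat& dDen, const fvec& dLogits) {
    if (kind == "mcnn") {
      fmat d = fuse.backward(dDen);
      trunk_backward(d);
      return;
    }
    fmat d = final1x1.backward(dDen);
    d = up2.backward(d);
    d = up1.backward(d);
    for (int j = (int)head.size() - 1; j >= 0; --j) d = head[j].backward(d);
    const int ntrunk = (int)d.n_cols - (int)prior.back().cout;
    fmat dCat = d.cols(0, ntrunk - 1);
    fmat dCiR = d.cols(ntrunk, d.n_cols - 1);
    trunk_backward(dCat);
    fmat dCi = resize_bilinear_back(dCiR, Hp, Wp, Ht, Wt);
    if (dLogits.n_elem) {
      fvec dv = dLogits;
      for (int j = (int)fcs.size() - 1; j >= 0; --j) dv = fcs[j].backward(dv);
      dCi += spp.backward(dv);
    }
    for (int j = (int)prior.size() - 1; j >= 0; --j) dCi = prior[j].backward(dCi);
  }
};

fvec softmax(const fvec& z) {
  fvec e = arma::exp(z - z.max());
  return e / arma::accu(e);
}

fmat r_to_fmat(const Rcpp::NumericMatrix& m) {
  fmat out(m.nrow() * m.ncol(), 1);
  for (int i = 0; i < m.nrow() * m.ncol(); ++i) out[i] = (float)m[i];
  return out;
}

}  // namespace

// ---------------------------------------------------------------------------
// exported interface
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP net_create(std::string kind, Rcpp::List config, int seed) {
  Rcpp::XPtr<Net> net(new Net(), true);
  net->kind = kind;
  net->rng.seed((unsigned long long)seed);
  const double sd = Rcpp::as<double>(config["init_sd"]);
  const int act_col = (kind == "mcnn") ? ACT_RELU : ACT_PRELU;

  Rcpp::List columns = config["columns"];
  for (int i = 0; i < columns.size(); ++i) {
    Rcpp::List cspec = columns[i];
    Rcpp::IntegerVector ks = cspec["kernels"], ch = cspec["channels"],
                        pa = cspec["pool_after"];
    std::vector<ConvLayer> column;
    int cin = 1;
    for (int j = 0; j < ks.size(); ++j) {
      ConvLayer ly;
      bool pool = std::find(pa.begin(), pa.end(), j + 1) != pa.end();
      ly.init(ks[j], cin, ch[j], act_col, pool, net->rng, sd);
      cin = ch[j];
      column.push_back(ly);
    }
    net->cols.push_back(column);
  }

  if (kind == "mcnn") {
    int total = 0;
    for (auto& c : net->cols) total += c.back().cout;
    net->fuse.init(1, total, 1, ACT_RELU, false, net->rng, sd);
  } else {
    Rcpp::List pspec = config["prior"];
    Rcpp::IntegerVector ks = pspec["kernels"], ch = pspec["channels"],
                        pa = pspec["pool_after"], fc = pspec["fc"],
                        lv = pspec["spp_levels"];
    net->n_classes = Rcpp::as<int>(pspec["n_classes"]);
    int cin = 1;
    for (int j = 0; j < ks.size(); ++j) {
      ConvLayer ly;
      bool pool = std::find(pa.begin(), pa.end(), j + 1) != pa.end();
      ly.init(ks[j], cin, ch[j], ACT_PRELU, pool, net->rng, sd);
      cin = ch[j];
      net->prior.push_back(ly);
    }
    net->spp.levels.assign(lv.begin(), lv.end());
    int nin = net->spp.nbins() * cin;
    for (int j = 0; j < fc.size(); ++j) {
      FCLayer f;
      f.init(nin, fc[j], ACT_PRELU, net->rng, sd);
      nin = fc[j];
      net->fcs.push_back(f);
    }
    FCLayer out;
    out.init(nin, net->n_classes, ACT_NONE, net->rng, sd);
    net->fcs.push_back(out);

    Rcpp::List hspec = config["head"];
    Rcpp::IntegerVector fch = hspec["fusion_channels"], uch = hspec["deconv_channels"];
    int total = 0;
    for (auto& c : net->cols) total += c.back().cout;
    total += ch[ch.size() - 1];
    int hin = total;
    for (int j = 0; j < fch.size(); ++j) {
      ConvLayer ly;
      ly.init(3, hin, fch[j], ACT_PRELU, false, net->rng, sd);
      hin = fch[j];
      net->head.push_back(ly);
    }
    net->up1.init(hin, uch[0], ACT_PRELU, net->rng, sd);
    net->up2.init(uch[0], uch[1], ACT_PRELU, net->rng, sd);
    net->final1x1.init(1, uch[1], 1, ACT_RELU, false, net->rng, sd);
  }
  return net;
}

// [[Rcpp::export]]
Rcpp::List net_forward_cpp(SEXP ptr, Rcpp::NumericMatrix image,
                           bool return_features = false) {
  Rcpp::XPtr<Net> net(ptr);
  const int H = image.nrow(), W = image.ncol();
  fmat img = r_to_fmat(image);
  auto res = net->forward(img, H, W);
  const int Ho = (net->kind == "mcnn") ? H / 4 : H;
  const int Wo = (net->kind == "mcnn") ? W / 4 : W;
  Rcpp::NumericMatrix den(Ho, Wo);
  for (int i = 0; i < Ho * Wo; ++i) den[i] = res.first[i];
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("density") = den);
  if (res.second.n_elem) {
    Rcpp::NumericVector lg(res.second.n_elem);
    for (arma::uword i = 0; i < res.second.n_elem; ++i) lg[i] = res.second[i];
    out["logits"] = lg;
  }
  if (return_features && net->kind == "mcnn") {
    // pre-fusion concatenated column features at 1/4 resolution
    fmat cat = net->trunk_forward(img, H, W);
    Rcpp::NumericMatrix f(cat.n_rows, cat.n_cols);
    for (arma::uword i = 0; i < cat.n_elem; ++i) f[i] = cat[i];
    out["features"] = f;
    out["feature_shape"] = Rcpp::IntegerVector::create(net->Ht, net->Wt);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List net_train_batch(SEXP ptr, Rcpp::List images, Rcpp::List targets,
                           Rcpp::IntegerVector labels, double lambda,
                           Rcpp::List opt) {
  Rcpp::XPtr<Net> net(ptr);
  const int B = images.size();
  net->opt.kind = Rcpp::as<std::string>(opt["kind"]) == "adam" ? 1 : 0;
  net->opt.lr = (float)Rcpp::as<double>(opt["lr"]);
  net->opt.momentum = (float)Rcpp::as<double>(opt["momentum"]);
  net->zero_grad();
  double ld_sum = 0.0, lc_sum = 0.0;
  Rcpp::NumericVector pred_counts(B);
  for (int s = 0; s < B; ++s) {
    Rcpp::NumericMatrix image = images[s];
    Rcpp::NumericMatrix target = targets[s];
    const int H = image.nrow(), W = image.ncol();
    fmat img = r_to_fmat(image);
    fmat tgt = r_to_fmat(target);
    auto res = net->forward(img, H, W);
    fmat diff = res.first - tgt;
    ld_sum += arma::accu(arma::square(diff));
    pred_counts[s] = arma::accu(res.first);
    fmat dDen = (2.0f / B) * diff;
    fvec dLogits;
    if (net->kind == "improved") {
      fvec sm = softmax(res.second);
      const int y = labels[s];
      lc_sum += -std::log(std::max(sm[y], 1e-12f));
      if (lambda > 0) {
        dLogits = sm;
        dLogits[y] -= 1.0f;
        dLogits *= (float)(lambda / B);
      }
    }
    net->backward(dDen, dLogits);
  }
  net->opt.t += 1;
  for (auto& pr : net->params()) step_param(*pr.second, net->opt);
  const double ld = ld_sum / B, lc = lc_sum / B;
  return Rcpp::List::create(
    Rcpp::Named("loss") = lambda * lc + ld,
    Rcpp::Named("ld") = ld, Rcpp::Named("lc") = lc,
    Rcpp::Named("pred_counts") = pred_counts);
}

// [[Rcpp::export]]
Rcpp::List net_grad_norms(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  auto ps = net->params();
  Rcpp::NumericVector v(ps.size());
  Rcpp::CharacterVector nm(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    nm[i] = ps[i].first;
    v[i] = arma::norm(arma::vectorise(ps[i].second->g), 2);
  }
  v.names() = nm;
  return Rcpp::List::create(Rcpp::Named("norms") = v);
}

// [[Rcpp::export]]
Rcpp::List net_get_params(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  auto ps = net->params();
  Rcpp::List out(ps.size());
  Rcpp::CharacterVector nm(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    nm[i] = ps[i].first;
    const fmat& w = ps[i].second->w;
    Rcpp::NumericMatrix m(w.n_rows, w.n_cols);
    for (arma::uword j = 0; j < w.n_elem; ++j) m[j] = w[j];
    out[i] = m;
  }
  out.names() = nm;
  return out;
}

// [[Rcpp::export]]
void net_set_params(SEXP ptr, Rcpp::List values) {
  Rcpp::XPtr<Net> net(ptr);
  auto ps = net->params();
  Rcpp::CharacterVector nm = values.names();
  for (int i = 0; i < values.size(); ++i) {
    std::string name = Rcpp::as<std::string>(nm[i]);
    for (auto& pr : ps)
      if (pr.first == name) {
        Rcpp::NumericMatrix m = values[i];
        if ((arma::uword)(m.nrow() * m.ncol()) != pr.second->w.n_elem)
          Rcpp::stop("parameter '%s' has wrong size", name.c_str());
        for (int j = 0; j < m.nrow() * m.ncol(); ++j) pr.second->w[j] = (float)m[j];
      }
  }
}

// [[Rcpp::export]]
double net_param_count(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  double n = 0;
  for (auto& pr : net->params()) n += pr.second->w.n_elem;
  return n;
}

// standalone double-precision SPP used by the R-level spp_pool()
// [[Rcpp::export]]
Rcpp::NumericVector spp_pool_cpp(Rcpp::NumericVector x, int H, int W, int C,
                                 Rcpp::IntegerVector levels) {
  int nb = 0;
  for (int i = 0; i < levels.size(); ++i) nb += levels[i] * levels[i];
  Rcpp::NumericVector out(nb * C);
  int o = 0;
  for (int c = 0; c < C; ++c) {
    const double* s = &x[(R_xlen_t)c * H * W];
    for (int li = 0; li < levels.size(); ++li) {
      const int l = levels[li];
      for (int bx = 0; bx < l; ++bx) {
        const int x0 = (bx * W) / l, x1 = ((bx + 1) * W) / l;
        for (int by = 0; by < l; ++by) {
          const int y0 = (by * H) / l, y1 = ((by + 1) * H) / l;
          double bv = s[x0 * H + y0];
          for (int xx = x0; xx < x1; ++xx)
            for (int yy = y0; yy < y1; ++yy)
              bv = std::max(bv, s[xx * H + yy]);
          out[o++] = bv;
        }
      }
    }
  }
  return out;
}
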