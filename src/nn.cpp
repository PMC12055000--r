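// Cascaded CNN-transformer pose network: hand-written forward/backward
// passes (no autodiff framework), AdamW optimiser, and the four output
// heads (heatmap, location refinement, LRSS, BAF) at 1/8 scale.
//
// Geometry: backbone stem -> 1/4 scale features; three branches compute
// 1/4, 1/8 and 1/16 scale features and are all brought to 1/8 (stride-2
// conv down, pixel-shuffle deconv up); the 1/16 branch is flattened to
// tokens, gets learned 2-D positional embeddings and runs through a
// pre-norm transformer encoder before upsampling. Branch outputs are
// concatenated (skip connections) and fused by convolution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Param {
  mat w, g, m, v;
  std::string kind;   // weight / bias / ln_gamma / ln_beta / posemb
  int fan_in;
  void init(int r, int c, const std::string& k, int fi) {
    w.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
    kind = k; fan_in = fi;
  }
};

// ---------------------------------------------------------------- conv
struct Conv {
  int kh, kw, cin, cout, stride, pad;
  Param W, b;
  mat Xcol;
  int Hi = 0, Wi = 0, Ho = 0, Wo = 0;

  void init(int k, int cin_, int cout_, int stride_) {
    kh = kw = k; cin = cin_; cout = cout_; stride = stride_; pad = (k - 1) / 2;
    W.init(kh * kw * cin, cout, "weight", kh * kw * cin);
    b.init(1, cout, "bias", 0);
  }

  cube forward(const cube& x, bool cache) {
    Hi = x.n_rows; Wi = x.n_cols;
    Ho = (Hi + 2 * pad - kh) / stride + 1;
    Wo = (Wi + 2 * pad - kw) / stride + 1;
    mat Xc(Ho * Wo, kh * kw * cin);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int r = i + j * Ho, col = 0;
        for (int c = 0; c < cin; ++c) {
          for (int kx = 0; kx < kw; ++kx) {
            for (int ky = 0; ky < kh; ++ky) {
              int sy = i * stride + ky - pad, sx = j * stride + kx - pad;
              Xc(r, col++) = (sy >= 0 && sy < Hi && sx >= 0 && sx < Wi)
                ? x(sy, sx, c) : 0.0;
            }
          }
        }
      }
    }
    mat Y = Xc * W.w;
    Y.each_row() += b.w.row(0);
    if (cache) Xcol = std::move(Xc);
    cube out(Ho, Wo, cout);
    for (int c = 0; c < cout; ++c) out.slice(c) = reshape(Y.col(c), Ho, Wo);
    return out;
  }

  cube backward(const cube& gy) {
    mat G(Ho * Wo, cout);
    for (int c = 0; c < cout; ++c) G.col(c) = vectorise(gy.slice(c));
    W.g += Xcol.t() * G;
    b.g += sum(G, 0);
    mat dX = G * W.w.t();
    cube dx(Hi, Wi, cin, fill::zeros);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int r = i + j * Ho, col = 0;
        for (int c = 0; c < cin; ++c) {
          for (int kx = 0; kx < kw; ++kx) {
            for (int ky = 0; ky < kh; ++ky) {
              int sy = i * stride + ky - pad, sx = j * stride + kx - pad;
              if (sy >= 0 && sy < Hi && sx >= 0 && sx < Wi)
                dx(sy, sx, c) += dX(r, col);
              ++col;
            }
          }
        }
      }
    }
    return dx;
  }
};

// ------------------------------------------- 2x pixel-shuffle deconv
struct Deconv2x {
  int cin, cout;
  Param W, b;   // W: cin x (4*cout), quadrant q = dy + 2*dx
  mat X;
  int Hi = 0, Wi = 0;

  void init(int cin_, int cout_) {
    cin = cin_; cout = cout_;
    W.init(cin, 4 * cout, "weight", cin);
    b.init(1, cout, "bias", 0);
  }

  cube forward(const cube& x, bool cache) {
    Hi = x.n_rows; Wi = x.n_cols;
    mat Xm(Hi * Wi, cin);
    for (int c = 0; c < cin; ++c) Xm.col(c) = vectorise(x.slice(c));
    mat Y = Xm * W.w;
    if (cache) X = std::move(Xm);
    cube out(2 * Hi, 2 * Wi, cout);
    for (int co = 0; co < cout; ++co) {
      for (int q = 0; q < 4; ++q) {
        int dy = q % 2, dx = q / 2;
        mat sl = reshape(Y.col(co * 4 + q), Hi, Wi) + b.w(0, co);
        for (int j = 0; j < Wi; ++j)
          for (int i = 0; i < Hi; ++i)
            out(2 * i + dy, 2 * j + dx, co) = sl(i, j);
      }
    }
    return out;
  }

  cube backward(const cube& gy) {
    mat G(Hi * Wi, 4 * cout, fill::zeros);
    for (int co = 0; co < cout; ++co) {
      double bg = 0;
      for (int q = 0; q < 4; ++q) {
        int dy = q % 2, dx = q / 2;
        mat sl(Hi, Wi);
        for (int j = 0; j < Wi; ++j)
          for (int i = 0; i < Hi; ++i)
            sl(i, j) = gy(2 * i + dy, 2 * j + dx, co);
        G.col(co * 4 + q) = vectorise(sl);
        bg += accu(sl);
      }
      b.g(0, co) += bg;
    }
    W.g += X.t() * G;
    mat dXm = G * W.w.t();
    cube dx(Hi, Wi, cin);
    for (int c = 0; c < cin; ++c) dx.slice(c) = reshape(dXm.col(c), Hi, Wi);
    return dx;
  }
};

// ---------------------------------------------------------------- relu
struct Relu {
  cube mask;
  cube forward(const cube& x, bool cache) {
    cube y = x;
    y.transform([](double v) { return v > 0 ? v : 0.0; });
    if (cache) {
      mask = x;
      mask.transform([](double v) { return v > 0 ? 1.0 : 0.0; });
    }
    return y;
  }
  cube backward(const cube& gy) { return gy % mask; }
};

// -------------------------------------------------------------- linear
struct Linear {
  Param W, b;
  mat X;
  void init(int din, int dout) {
    W.init(din, dout, "weight", din);
    b.init(1, dout, "bias", 0);
  }
  mat forward(const mat& x, bool cache) {
    if (cache) X = x;
    mat y = x * W.w;
    y.each_row() += b.w.row(0);
    return y;
  }
  mat backward(const mat& gy) {
    W.g += X.t() * gy;
    b.g += sum(gy, 0);
    return gy * W.w.t();
  }
};

// ----------------------------------------------------------- layernorm
struct LayerNorm {
  Param g, b;
  mat xhat;
  vec istd;
  int D = 0;
  void init(int d) {
    D = d;
    g.init(1, d, "ln_gamma", 0);
    b.init(1, d, "ln_beta", 0);
  }
  mat forward(const mat& x, bool cache) {
    vec mu = mean(x, 1);
    mat cen = x.each_col() - mu;
    vec var = mean(square(cen), 1);
    vec is = 1.0 / sqrt(var + 1e-5);
    mat xh = cen.each_col() % is;
    mat y = xh.each_row() % g.w.row(0);
    y.each_row() += b.w.row(0);
    if (cache) { xhat = xh; istd = is; }
    return y;
  }
  mat backward(const mat& gy) {
    g.g += sum(gy % xhat, 0);
    b.g += sum(gy, 0);
    mat dxh = gy.each_row() % g.w.row(0);
    vec m1 = mean(dxh, 1);
    vec m2 = mean(dxh % xhat, 1);
    mat dx = dxh;
    dx.each_col() -= m1;
    dx -= xhat.each_col() % m2;
    dx.each_col() %= istd;
    return dx;
  }
};

// ------------------------------------------------- multi-head attention
struct MHSA {
  int D, nh, dh;
  Linear lq, lk, lv, lo;
  mat Qm, Km, Vm;
  std::vector<mat> Ah;

  void init(int d, int heads) {
    D = d; nh = heads; dh = d / heads;
    lq.init(d, d); lk.init(d, d); lv.init(d, d); lo.init(d, d);
  }

  mat forward(const mat& x, bool cache) {
    mat Q = lq.forward(x, cache), K = lk.forward(x, cache), V = lv.forward(x, cache);
    int T = x.n_rows;
    mat O(T, D);
    std::vector<mat> As(nh);
    double sc = 1.0 / std::sqrt((double)dh);
    for (int h = 0; h < nh; ++h) {
      mat Qh = Q.cols(h * dh, (h + 1) * dh - 1);
      mat Kh = K.cols(h * dh, (h + 1) * dh - 1);
      mat Vh = V.cols(h * dh, (h + 1) * dh - 1);
      mat S = Qh * Kh.t() * sc;
      S.each_col() -= max(S, 1);
      mat A = exp(S);
      A.each_col() /= sum(A, 1);
      As[h] = A;
      O.cols(h * dh, (h + 1) * dh - 1) = A * Vh;
    }
    if (cache) { Qm = std::move(Q); Km = std::move(K); Vm = std::move(V); Ah = std::move(As); }
    return lo.forward(O, cache);
  }

  mat backward(const mat& gy) {
    mat dO = lo.backward(gy);
    int T = dO.n_rows;
    mat dQ(T, D, fill::zeros), dK(T, D, fill::zeros), dV(T, D, fill::zeros);
    double sc = 1.0 / std::sqrt((double)dh);
    for (int h = 0; h < nh; ++h) {
      mat Qh = Qm.cols(h * dh, (h + 1) * dh - 1);
      mat Kh = Km.cols(h * dh, (h + 1) * dh - 1);
      mat Vh = Vm.cols(h * dh, (h + 1) * dh - 1);
      mat dOh = dO.cols(h * dh, (h + 1) * dh - 1);
      mat dA = dOh * Vh.t();
      dV.cols(h * dh, (h + 1) * dh - 1) = Ah[h].t() * dOh;
      vec rs = sum(dA % Ah[h], 1);
      mat dS = Ah[h] % (dA.each_col() - rs);
      dS *= sc;
      dQ.cols(h * dh, (h + 1) * dh - 1) = dS * Kh;
      dK.cols(h * dh, (h + 1) * dh - 1) = dS.t() * Qh;
    }
    return lq.backward(dQ) + lk.backward(dK) + lv.backward(dV);
  }
};

// --------------------------------------------------- transformer block
struct TfBlock {
  LayerNorm ln1, ln2;
  MHSA att;
  Linear l1, l2;
  mat relu_mask;

  void init(int d, int heads, int dmlp) {
    ln1.init(d); ln2.init(d);
    att.init(d, heads);
    l1.init(d, dmlp); l2.init(dmlp, d);
  }

  mat forward(const mat& x, bool cache) {
    mat h = x + att.forward(ln1.forward(x, cache), cache);
    mat z = l1.forward(ln2.forward(h, cache), cache);
    mat zr = z;
    zr.transform([](double v) { return v > 0 ? v : 0.0; });
    if (cache) {
      relu_mask = z;
      relu_mask.transform([](double v) { return v > 0 ? 1.0 : 0.0; });
    }
    return h + l2.forward(zr, cache);
  }

  mat backward(const mat& gy) {
    mat dz = l2.backward(gy) % relu_mask;
    mat dh = gy + ln2.backward(l1.backward(dz));
    mat dx = dh + ln1.backward(att.backward(dh));
    return dx;
  }
};

struct ResBlock {
  Conv c1, c2;
  Relu r1, r2;
  void init(int c) { c1.init(3, c, c, 1); c2.init(3, c, c, 1); }
  cube forward(const cube& x, bool cache) {
    cube y = c2.forward(r1.forward(c1.forward(x, cache), cache), cache);
    y += x;
    return r2.forward(y, cache);
  }
  cube backward(const cube& gy) {
    cube g = r2.backward(gy);
    cube dx = c1.backward(r1.backward(c2.backward(g)));
    dx += g;
    return dx;
  }
};

// ----------------------------------------------------------- the model
struct Net {
  // config
  int in_channels, K, n_identities;
  bool with_baf, no_transformer, no_lrss, big_stem;
  int c_stem, c_backbone, n_res, c_branch, c_fuse;
  int tf_layers, tf_heads, tf_dim, tf_mlp;
  int tok_h, tok_w;             // token grid (input/16) for pos embedding

  Conv stem1, stem2;
  Relu sr1, sr2;
  std::vector<ResBlock> res;
  Conv b4a, b4b, b8a, b8b, b16a, b16b;
  Relu r4a, r4b, r8a, r8b, r16a, r16b, rup;
  Linear tok_in, tok_out;
  Param posemb;
  std::vector<TfBlock> tf;
  Deconv2x up16;
  Conv fuse;
  Relu rfuse;
  Conv head_hm, head_lr, head_seg, head_baf;

  // caches for backward
  cube x_b4, x_b8, x_b16up, x_fused;
  int h16 = 0, w16 = 0;
  long step_count = 0;

  std::vector<Param*> params;

  void build(Rcpp::List spec) {
    in_channels   = spec["in_channels"];
    K             = spec["K"];
    n_identities  = spec["n_identities"];
    with_baf      = spec["with_baf"];
    no_transformer = spec["no_transformer"];
    no_lrss       = spec["no_lrss"];
    big_stem      = std::string(Rcpp::as<std::string>(spec["preset"])) != "tiny";
    c_stem        = spec["c_stem"];
    c_backbone    = spec["c_backbone"];
    n_res         = spec["n_res"];
    c_branch      = spec["c_branch"];
    c_fuse        = spec["c_fuse"];
    tf_layers     = spec["tf_layers"];
    tf_heads      = spec["tf_heads"];
    tf_dim        = spec["tf_dim"];
    tf_mlp        = spec["tf_mlp"];
    Rcpp::IntegerVector isz = spec["input_size"];
    tok_h = (isz[0] + 15) / 16;
    tok_w = (isz[1] + 15) / 16;

    stem1.init(big_stem ? 7 : 3, in_channels, c_stem, 2);
    stem2.init(3, c_stem, c_backbone, 2);
    res.resize(n_res);
    for (auto& r : res) r.init(c_backbone);

    b4a.init(3, c_backbone, c_branch, 1);  b4b.init(3, c_branch, c_branch, 2);
    b8a.init(3, c_backbone, c_branch, 2);  b8b.init(3, c_branch, c_branch, 1);
    b16a.init(3, c_backbone, c_branch, 2); b16b.init(3, c_branch, c_branch, 2);

    tok_in.init(c_branch, tf_dim);
    tok_out.init(tf_dim, c_branch);
    posemb.init(tok_h * tok_w, tf_dim, "posemb", 0);
    tf.resize(no_transformer ? 0 : tf_layers);
    for (auto& b : tf) b.init(tf_dim, tf_heads, tf_mlp);

    up16.init(c_branch, c_branch);
    fuse.init(3, 3 * c_branch, c_fuse, 1);
    head_hm.init(1, c_fuse, K, 1);
    head_lr.init(1, c_fuse, 2 * K, 1);
    if (!no_lrss) head_seg.init(1, c_fuse, n_identities + 1, 1);
    if (with_baf) head_baf.init(1, c_fuse, 2, 1);

    collect_params();
  }

  void add_conv(Conv& c) { params.push_back(&c.W); params.push_back(&c.b); }
  void add_lin(Linear& l) { params.push_back(&l.W); params.push_back(&l.b); }
  void collect_params() {
    params.clear();
    add_conv(stem1); add_conv(stem2);
    for (auto& r : res) { add_conv(r.c1); add_conv(r.c2); }
    add_conv(b4a); add_conv(b4b); add_conv(b8a); add_conv(b8b);
    add_conv(b16a); add_conv(b16b);
    if (!no_transformer) {
      add_lin(tok_in); add_lin(tok_out);
      params.push_back(&posemb);
      for (auto& b : tf) {
        params.push_back(&b.ln1.g); params.push_back(&b.ln1.b);
        add_lin(b.att.lq); add_lin(b.att.lk); add_lin(b.att.lv); add_lin(b.att.lo);
        params.push_back(&b.ln2.g); params.push_back(&b.ln2.b);
        add_lin(b.l1); add_lin(b.l2);
      }
    }
    params.push_back(&up16.W); params.push_back(&up16.b);
    add_conv(fuse);
    add_conv(head_hm); add_conv(head_lr);
    if (!no_lrss) add_conv(head_seg);
    if (with_baf) add_conv(head_baf);
  }

  // tokens: row index t = i + j*h16 (column-major over the token grid)
  mat cube_to_tokens(const cube& x) {
    mat t(x.n_rows * x.n_cols, x.n_slices);
    for (unsigned c = 0; c < x.n_slices; ++c) t.col(c) = vectorise(x.slice(c));
    return t;
  }
  cube tokens_to_cube(const mat& t, int h, int w) {
    cube x(h, w, t.n_cols);
    for (unsigned c = 0; c < t.n_cols; ++c) x.slice(c) = reshape(t.col(c), h, w);
    return x;
  }

  mat posemb_for(int h, int w) {
    if (h == tok_h && w == tok_w) return posemb.w;
    // nearest-neighbour resample of the learned 2-D grid (inference only)
    mat out(h * w, posemb.w.n_cols);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        int si = std::min(tok_h - 1, (int)std::floor((i + 0.5) * tok_h / h));
        int sj = std::min(tok_w - 1, (int)std::floor((j + 0.5) * tok_w / w));
        out.row(i + j * h) = posemb.w.row(si + sj * tok_h);
      }
    }
    return out;
  }

  // forward to fused 1/8 features; caches when `cache`
  cube features(const cube& x, bool cache) {
    cube f = sr1.forward(stem1.forward(x, cache), cache);
    f = sr2.forward(stem2.forward(f, cache), cache);           // 1/4
    for (auto& r : res) f = r.forward(f, cache);

    cube f4 = r4b.forward(b4b.forward(
      r4a.forward(b4a.forward(f, cache), cache), cache), cache);   // 1/8
    cube f8 = r8b.forward(b8b.forward(
      r8a.forward(b8a.forward(f, cache), cache), cache), cache);   // 1/8
    cube f16 = r16b.forward(b16b.forward(
      r16a.forward(b16a.forward(f, cache), cache), cache), cache); // 1/16

    h16 = f16.n_rows; w16 = f16.n_cols;
    if (!no_transformer) {
      mat t = tok_in.forward(cube_to_tokens(f16), cache);
      t += posemb_for(h16, w16);
      for (auto& b : tf) t = b.forward(t, cache);
      f16 = tokens_to_cube(tok_out.forward(t, cache), h16, w16);
    }
    cube f16u = rup.forward(up16.forward(f16, cache), cache);      // 1/8

    if (cache) { x_b4 = f4; x_b8 = f8; x_b16up = f16u; }
    cube cc(f4.n_rows, f4.n_cols, 3 * c_branch);
    for (int c = 0; c < c_branch; ++c) {
      cc.slice(c) = f4.slice(c);
      cc.slice(c_branch + c) = f8.slice(c);
      cc.slice(2 * c_branch + c) = f16u.slice(c);
    }
    cube fu = rfuse.forward(fuse.forward(cc, cache), cache);
    if (cache) x_fused = fu;
    return fu;
  }

  void backward_features(const cube& gfused) {
    cube gcc = fuse.backward(rfuse.backward(gfused));
    int h = gcc.n_rows, w = gcc.n_cols;
    cube g4(h, w, c_branch), g8(h, w, c_branch), g16u(h, w, c_branch);
    for (int c = 0; c < c_branch; ++c) {
      g4.slice(c) = gcc.slice(c);
      g8.slice(c) = gcc.slice(c_branch + c);
      g16u.slice(c) = gcc.slice(2 * c_branch + c);
    }
    cube g16 = up16.backward(rup.backward(g16u));
    if (!no_transformer) {
      mat gt = tok_out.backward(cube_to_tokens(g16));
      for (int i = (int)tf.size() - 1; i >= 0; --i) gt = tf[i].backward(gt);
      posemb.g += gt;        // token grid matches during training
      g16 = tokens_to_cube(tok_in.backward(gt), h16, w16);
    }
    cube gf = b16a.backward(r16a.backward(b16b.backward(r16b.backward(g16))));
    gf += b8a.backward(r8a.backward(b8b.backward(r8b.backward(g8))));
    gf += b4a.backward(r4a.backward(b4b.backward(r4b.backward(g4))));
    for (int i = (int)res.size() - 1; i >= 0; --i) gf = res[i].backward(gf);
    stem1.backward(sr1.backward(stem2.backward(sr2.backward(gf))));
  }
};

static cube softmax_slices(const cube& logits) {
  cube p = logits;
  for (unsigned j = 0; j < p.n_cols; ++j) {
    for (unsigned i = 0; i < p.n_rows; ++i) {
      double mx = -datum::inf;
      for (unsigned c = 0; c < p.n_slices; ++c) mx = std::max(mx, p(i, j, c));
      double s = 0;
      for (unsigned c = 0; c < p.n_slices; ++c) { p(i, j, c) = std::exp(p(i, j, c) - mx); s += p(i, j, c); }
      for (unsigned c = 0; c < p.n_slices; ++c) p(i, j, c) /= s;
    }
  }
  return p;
}

// per-sample RMSE loss; fills grad, returns loss
static double rmse_loss(const cube& pred, const cube& targ, cube& grad) {
  double n = pred.n_elem;
  cube d = pred - targ;
  double mse = accu(square(d)) / n;
  double L = std::sqrt(mse);
  grad = (L > 1e-12) ? cube(d / (n * L)) : cube(size(d), fill::zeros);
  return L;
}

static double rmse_loss_masked(const cube& pred, const cube& targ,
                               const cube& mask, cube& grad) {
  // mask has K slices; applies to channel pairs (2k, 2k+1)
  grad.zeros(size(pred));
  double n = 0, ss = 0;
  int K = mask.n_slices;
  cube d = pred - targ;
  for (int k = 0; k < K; ++k) {
    for (unsigned j = 0; j < pred.n_cols; ++j) {
      for (unsigned i = 0; i < pred.n_rows; ++i) {
        if (mask(i, j, k) > 0) {
          ss += d(i, j, 2 * k) * d(i, j, 2 * k) + d(i, j, 2 * k + 1) * d(i, j, 2 * k + 1);
          n += 2;
        }
      }
    }
  }
  if (n == 0) return 0.0;
  double L = std::sqrt(ss / n);
  if (L <= 1e-12) return 0.0;
  for (int k = 0; k < K; ++k) {
    for (unsigned j = 0; j < pred.n_cols; ++j) {
      for (unsigned i = 0; i < pred.n_rows; ++i) {
        if (mask(i, j, k) > 0) {
          grad(i, j, 2 * k) = d(i, j, 2 * k) / (n * L);
          grad(i, j, 2 * k + 1) = d(i, j, 2 * k + 1) / (n * L);
        }
      }
    }
  }
  return L;
}

// sparse categorical cross-entropy over channel softmax; labels 0-based
static double ce_loss(const cube& logits, const imat& labels, cube& grad) {
  cube p = softmax_slices(logits);
  double npix = logits.n_rows * logits.n_cols;
  double L = 0;
  grad = p / npix;
  for (unsigned j = 0; j < logits.n_cols; ++j) {
    for (unsigned i = 0; i < logits.n_rows; ++i) {
      int lab = labels(i, j);
      L -= std::log(std::max(p(i, j, lab), 1e-12));
      grad(i, j, lab) -= 1.0 / npix;
    }
  }
  return L / npix;
}

// ---------------------------------------------------------------- API

// [[Rcpp::export]]
SEXP nn_create(Rcpp::List spec) {
  Rcpp::XPtr<Net> p(new Net(), true);
  p->build(spec);
  return p;
}

// [[Rcpp::export]]
Rcpp::List nn_param_info(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  Rcpp::List out(net->params.size());
  for (size_t i = 0; i < net->params.size(); ++i) {
    Param* p = net->params[i];
    out[i] = Rcpp::List::create(
      Rcpp::Named("nrow") = (int)p->w.n_rows,
      Rcpp::Named("ncol") = (int)p->w.n_cols,
      Rcpp::Named("kind") = p->kind,
      Rcpp::Named("fan_in") = p->fan_in);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_get_weights(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  Rcpp::List out(net->params.size());
  for (size_t i = 0; i < net->params.size(); ++i) out[i] = net->params[i]->w;
  return out;
}

// [[Rcpp::export]]
void nn_set_weights(SEXP ptr, Rcpp::List ws, bool reset_opt = true) {
  Rcpp::XPtr<Net> net(ptr);
  if ((size_t)ws.size() != net->params.size())
    Rcpp::stop("weight list length mismatch: got %d, need %d",
               (int)ws.size(), (int)net->params.size());
  for (size_t i = 0; i < net->params.size(); ++i) {
    mat w = Rcpp::as<mat>(ws[i]);
    Param* p = net->params[i];
    if (w.n_rows != p->w.n_rows || w.n_cols != p->w.n_cols)
      Rcpp::stop("weight %d shape mismatch", (int)i + 1);
    p->w = w;
    if (reset_opt) { p->m.zeros(); p->v.zeros(); p->g.zeros(); }
  }
  if (reset_opt) net->step_count = 0;
}

// [[Rcpp::export]]
long nn_n_params(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  long n = 0;
  for (auto* p : net->params) n += p->w.n_elem;
  return n;
}

static Rcpp::List heads_to_list(Net* net, const cube& feat) {
  cube hm = net->head_hm.forward(feat, false);
  cube lr = net->head_lr.forward(feat, false);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("heatmap") = hm,
    Rcpp::Named("locref") = lr);
  if (!net->no_lrss) {
    out["lrss_prob"] = softmax_slices(net->head_seg.forward(feat, false));
  }
  if (net->with_baf) out["baf"] = net->head_baf.forward(feat, false);
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_forward(SEXP ptr, arma::cube x) {
  Rcpp::XPtr<Net> net(ptr);
  cube feat = net->features(x, false);
  return heads_to_list(net, feat);
}

// One AdamW step over a mini-batch. `xs` is a list of H x W x C arrays;
// `targets` a list (same length) of lists with heatmap, locref,
// locref_mask, lrss (integer matrix, 0-based labels), baf (optional).
// [[Rcpp::export]]
Rcpp::List nn_train_step(SEXP ptr, Rcpp::List xs, Rcpp::List targets,
                         Rcpp::NumericVector loss_weights,
                         double lr, double weight_decay) {
  Rcpp::XPtr<Net> net(ptr);
  int B = xs.size();
  double w_hm = loss_weights["heatmap"], w_lr = loss_weights["locref"];
  double w_seg = loss_weights["lrss"], w_baf = loss_weights["baf"];
  for (auto* p : net->params) p->g.zeros();
  double L_hm = 0, L_lr = 0, L_seg = 0, L_baf = 0;

  for (int b = 0; b < B; ++b) {
    cube x = Rcpp::as<cube>(xs[b]);
    Rcpp::List tg = targets[b];
    cube feat = net->features(x, true);

    cube ghm, glr, gseg, gbaf;
    cube hm = net->head_hm.forward(feat, true);
    L_hm += rmse_loss(hm, Rcpp::as<cube>(tg["heatmap"]), ghm);
    cube lrp = net->head_lr.forward(feat, true);
    L_lr += rmse_loss_masked(lrp, Rcpp::as<cube>(tg["locref"]),
                             Rcpp::as<cube>(tg["locref_mask"]), glr);
    cube gfeat = net->head_hm.backward(ghm * (w_hm / B));
    gfeat += net->head_lr.backward(glr * (w_lr / B));
    if (!net->no_lrss) {
      cube sl = net->head_seg.forward(feat, true);
      imat labels = Rcpp::as<imat>(tg["lrss"]);
      L_seg += ce_loss(sl, labels, gseg);
      gfeat += net->head_seg.backward(gseg * (w_seg / B));
    }
    if (net->with_baf) {
      cube bp = net->head_baf.forward(feat, true);
      L_baf += rmse_loss(bp, Rcpp::as<cube>(tg["baf"]), gbaf);
      gfeat += net->head_baf.backward(gbaf * (w_baf / B));
    }
    net->backward_features(gfeat);
  }

  double total = (w_hm * L_hm + w_lr * L_lr + w_seg * L_seg + w_baf * L_baf) / B;
  if (!std::isfinite(total)) Rcpp::stop("non-finite loss in training batch");

  // AdamW
  net->step_count += 1;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double bc1 = 1 - std::pow(b1, (double)net->step_count);
  double bc2 = 1 - std::pow(b2, (double)net->step_count);
  for (auto* p : net->params) {
    p->m = b1 * p->m + (1 - b1) * p->g;
    p->v = b2 * p->v + (1 - b2) * square(p->g);
    mat mhat = p->m / bc1, vhat = p->v / bc2;
    bool decay = (p->kind == "weight");
    p->w -= lr * (mhat / (sqrt(vhat) + eps) + (decay ? weight_decay : 0.0) * p->w);
  }

  return Rcpp::List::create(
    Rcpp::Named("total") = total,
    Rcpp::Named("heatmap") = L_hm / B,
    Rcpp::Named("locref") = L_lr / B,
    Rcpp::Named("lrss") = L_seg / B,
    Rcpp::Named("baf") = L_baf / B);
}

// Loss and accumulated gradients without an optimiser step (used by the
// finite-difference gradient tests).
// [[Rcpp::export]]
Rcpp::List nn_loss_and_grad(SEXP ptr, Rcpp::List xs, Rcpp::List targets,
                            Rcpp::NumericVector loss_weights) {
  Rcpp::XPtr<Net> net(ptr);
  int B = xs.size();
  double w_hm = loss_weights["heatmap"], w_lr = loss_weights["locref"];
  double w_seg = loss_weights["lrss"], w_baf = loss_weights["baf"];
  for (auto* p : net->params) p->g.zeros();
  double L_hm = 0, L_lr = 0, L_seg = 0, L_baf = 0;
  for (int b = 0; b < B; ++b) {
    cube x = Rcpp::as<cube>(xs[b]);
    Rcpp::List tg = targets[b];
    cube feat = net->features(x, true);
    cube ghm, glr, gseg, gbaf;
    cube hm = net->head_hm.forward(feat, true);
    L_hm += rmse_loss(hm, Rcpp::as<cube>(tg["heatmap"]), ghm);
    cube lrp = net->head_lr.forward(feat, true);
    L_lr += rmse_loss_masked(lrp, Rcpp::as<cube>(tg["locref"]),
                             Rcpp::as<cube>(tg["locref_mask"]), glr);
    cube gfeat = net->head_hm.backward(ghm * (w_hm / B));
    gfeat += net->head_lr.backward(glr * (w_lr / B));
    if (!net->no_lrss) {
      cube sl = net->head_seg.forward(feat, true);
      imat labels = Rcpp::as<imat>(tg["lrss"]);
      L_seg += ce_loss(sl, labels, gseg);
      gfeat += net->head_seg.backward(gseg * (w_seg / B));
    }
    if (net->with_baf) {
      cube bp = net->head_baf.forward(feat, true);
      L_baf += rmse_loss(bp, Rcpp::as<cube>(tg["baf"]), gbaf);
      gfeat += net->head_baf.backward(gbaf * (w_baf / B));
    }
    net->backward_features(gfeat);
  }
  Rcpp::List grads(net->params.size());
  for (size_t i = 0; i < net->params.size(); ++i) grads[i] = net->params[i]->g;
  double total = (w_hm * L_hm + w_lr * L_lr + w_seg * L_seg + w_baf * L_baf) / B;
  return Rcpp::List::create(Rcpp::Named("total") = total,
                            Rcpp::Named("grads") = grads);
}

// Loss evaluation without a gradient step (validation monitoring).
// [[Rcpp::export]]
Rcpp::List nn_eval_loss(SEXP ptr, Rcpp::List xs, Rcpp::List targets,
                        Rcpp::NumericVector loss_weights) {
  Rcpp::XPtr<Net> net(ptr);
  int B = xs.size();
  double w_hm = loss_weights["heatmap"], w_lr = loss_weights["locref"];
  double w_seg = loss_weights["lrss"], w_baf = loss_weights["baf"];
  double L_hm = 0, L_lr = 0, L_seg = 0, L_baf = 0;
  cube g;
  for (int b = 0; b < B; ++b) {
    cube x = Rcpp::as<cube>(xs[b]);
    Rcpp::List tg = targets[b];
    cube feat = net->features(x, false);
    L_hm += rmse_loss(net->head_hm.forward(feat, false),
                      Rcpp::as<cube>(tg["heatmap"]), g);
    L_lr += rmse_loss_masked(net->head_lr.forward(feat, false),
                             Rcpp::as<cube>(tg["locref"]),
                             Rcpp::as<cube>(tg["locref_mask"]), g);
    if (!net->no_lrss) {
      imat labels = Rcpp::as<imat>(tg["lrss"]);
      L_seg += ce_loss(net->head_seg.forward(feat, false), labels, g);
    }
    if (net->with_baf) {
      L_baf += rmse_loss(net->head_baf.forward(feat, false),
                         Rcpp::as<cube>(tg["baf"]), g);
    }
  }
  double total = (w_hm * L_hm + w_lr * L_lr + w_seg * L_seg + w_baf * L_baf) / B;
  return Rcpp::List::create(
    Rcpp::Named("total") = total,
    Rcpp::Named("heatmap") = L_hm / B,
    Rcpp::Named("locref") = L_lr / B,
    Rcpp::Named("lrss") = L_seg / B,
    Rcpp::Named("baf") = L_baf / B);
}
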