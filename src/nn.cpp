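// Native engine for the dual-decoder residual encoder-decoder network family.
// Tensors are arma::mat with one row per voxel (sample-major, then z, y, x)
// and one column per channel. Convolutions are im2col + GEMM; gradients are
// exact (batch-norm, max-pool argmax, spatial dropout masks are all cached).
#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::rowvec;

struct Shape {
  int n, d, h, w;               // batch, depth (slices), rows, cols
  long spatial() const { return (long)d * h * w; }
  long rows() const { return (long)n * spatial(); }
};

// ---------------------------------------------------------------- im2col ----
// Column layout: channel-major taps, column index = c*K + t where t indexes
// (dz, dy, dx) offsets. Zero padding keeps the spatial shape.
// For a fixed kernel tap (dz, dy, dx) the valid output voxels of one
// (n, z, y) line form a contiguous x-run mapping to a contiguous source
// run, so both directions reduce to segment copies / accumulations.
static void im2col(const mat& X, const Shape& s, int kd, int kh, int kw,
                   mat& out) {
  const int K = kd * kh * kw, C = X.n_cols;
  const long R = X.n_rows;
  out.zeros(R, (arma::uword)C * K);
  const int rd = kd / 2, rh = kh / 2, rw = kw / 2;
  int t = 0;
  for (int dz = -rd; dz <= rd; ++dz)
    for (int dy = -rh; dy <= rh; ++dy)
      for (int dx = -rw; dx <= rw; ++dx, ++t) {
        const int x0 = std::max(0, -dx), x1 = std::min(s.w, s.w - dx);
        if (x1 <= x0) continue;
        const int len = x1 - x0;
        for (int c = 0; c < C; ++c) {
          const double* src0 = X.colptr(c);
          double* dst0 = out.colptr((arma::uword)c * K + t);
          for (int n = 0; n < s.n; ++n) {
            const long base = (long)n * s.spatial();
            for (int z = 0; z < s.d; ++z) {
              const int zz = z + dz;
              if (zz < 0 || zz >= s.d) continue;
              for (int y = 0; y < s.h; ++y) {
                const int yy = y + dy;
                if (yy < 0 || yy >= s.h) continue;
                const long r = base + ((long)z * s.h + y) * s.w + x0;
                const long src = base + ((long)zz * s.h + yy) * s.w + x0 + dx;
                std::memcpy(dst0 + r, src0 + src, sizeof(double) * len);
              }
            }
          }
        }
      }
}

static void col2im(const mat& dCols, const Shape& s, int kd, int kh, int kw,
                   int C, mat& dX) {
  const int K = kd * kh * kw;
  dX.zeros(dCols.n_rows, C);
  const int rd = kd / 2, rh = kh / 2, rw = kw / 2;
  int t = 0;
  for (int dz = -rd; dz <= rd; ++dz)
    for (int dy = -rh; dy <= rh; ++dy)
      for (int dx = -rw; dx <= rw; ++dx, ++t) {
        const int x0 = std::max(0, -dx), x1 = std::min(s.w, s.w - dx);
        if (x1 <= x0) continue;
        const int len = x1 - x0;
        for (int c = 0; c < C; ++c) {
          const double* g0 = dCols.colptr((arma::uword)c * K + t);
          double* dst0 = dX.colptr(c);
          for (int n = 0; n < s.n; ++n) {
            const long base = (long)n * s.spatial();
            for (int z = 0; z < s.d; ++z) {
              const int zz = z + dz;
              if (zz < 0 || zz >= s.d) continue;
              for (int y = 0; y < s.h; ++y) {
                const int yy = y + dy;
                if (yy < 0 || yy >= s.h) continue;
                const long r = base + ((long)z * s.h + y) * s.w + x0;
                const long src = base + ((long)zz * s.h + yy) * s.w + x0 + dx;
                double* d = dst0 + src;
                const double* g = g0 + r;
                for (int i = 0; i < len; ++i) d[i] += g[i];
              }
            }
          }
        }
      }
}

// ------------------------------------------------------------------ Adam ----
struct AdamState {
  mat mW, vW;
  void step(mat& W, const mat& g, double lr, double b1, double b2,
            double eps, long t) {
    if (mW.n_elem == 0) { mW.zeros(W.n_rows, W.n_cols); vW.zeros(W.n_rows, W.n_cols); }
    mW = b1 * mW + (1 - b1) * g;
    vW = b2 * vW + (1 - b2) * arma::square(g);
    const double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    W -= lr * (mW / c1) / (arma::sqrt(vW / c2) + eps);
  }
};

// ------------------------------------------------------------------ Conv ----
struct Conv {
  int cin = 0, cout = 0, kd = 1, kh = 1, kw = 1;
  mat W;        // (cin*K, cout)
  rowvec b;     // (cout)
  mat cols;     // cached im2col of last forward
  mat dW; rowvec db;
  AdamState aW, ab;

  void init(int ci, int co, int kdd, int khh, int kww, std::mt19937& rng) {
    cin = ci; cout = co; kd = kdd; kh = khh; kw = kww;
    const int K = kd * kh * kw;
    const double lim = std::sqrt(6.0 / ((double)cin * K));   // He-uniform
    std::uniform_real_distribution<double> U(-lim, lim);
    W.set_size((arma::uword)cin * K, cout);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = U(rng);
    b.zeros(cout);
  }
  long n_params() const { return (long)W.n_elem + b.n_elem; }

  mat forward(const mat& X, const Shape& s, bool keep) {
    mat C; im2col(X, s, kd, kh, kw, C);
    mat out = C * W;
    out.each_row() += b;
    if (keep) cols = std::move(C);
    return out;
  }
  mat backward(const mat& G, const Shape& s) {
    dW = cols.t() * G;
    db = arma::sum(G, 0);
    mat dCols = G * W.t();
    mat dX; col2im(dCols, s, kd, kh, kw, cin, dX);
    cols.reset();
    return dX;
  }
  void update(double lr, double b1, double b2, double eps, long t) {
    mat gb = arma::conv_to<mat>::from(db);
    aW.step(W, dW, lr, b1, b2, eps, t);
    mat bm(b.memptr(), 1, b.n_elem, false, true);
    ab.step(bm, gb, lr, b1, b2, eps, t);
  }
};

// ------------------------------------------------------------- BatchNorm ----
struct BatchNorm {
  rowvec gamma, beta, run_mean, run_var;
  double momentum = 0.9, eps = 1e-5;
  mat xhat; rowvec invstd;
  rowvec dgamma, dbeta;
  AdamState ag, ab;

  void init(int C) {
    gamma.ones(C); beta.zeros(C); run_mean.zeros(C); run_var.ones(C);
  }
  long n_params() const { return (long)gamma.n_elem + beta.n_elem; }

  mat forward(const mat& X, bool train, bool keep) {
    if (train) {
      rowvec mu = arma::mean(X, 0);
      rowvec var = arma::var(X, 1, 0);             // population variance
      run_mean = momentum * run_mean + (1 - momentum) * mu;
      run_var = momentum * run_var + (1 - momentum) * var;
      invstd = 1.0 / arma::sqrt(var + eps);
      mat xh = X;
      xh.each_row() -= mu;
      xh.each_row() %= invstd;
      mat out = xh;
      out.each_row() %= gamma;
      out.each_row() += beta;
      if (keep) xhat = std::move(xh);
      return out;
    }
    rowvec is = 1.0 / arma::sqrt(run_var + eps);
    mat out = X;
    out.each_row() -= run_mean;
    out.each_row() %= is % gamma;
    out.each_row() += beta;
    return out;
  }
  mat backward(const mat& G) {
    const double m = (double)G.n_rows;
    dgamma = arma::sum(G % xhat, 0);
    dbeta = arma::sum(G, 0);
    mat dX = m * G;
    dX.each_row() -= dbeta;
    dX -= xhat * arma::diagmat(dgamma.t());
    dX.each_row() %= (gamma % invstd) / m;
    xhat.reset();
    return dX;
  }
  void update(double lr, double b1, double b2, double eps_a, long t) {
    mat gm(gamma.memptr(), 1, gamma.n_elem, false, true);
    mat bm(beta.memptr(), 1, beta.n_elem, false, true);
    mat gg = arma::conv_to<mat>::from(dgamma), gb = arma::conv_to<mat>::from(dbeta);
    ag.step(gm, gg, lr, b1, b2, eps_a, t);
    ab.step(bm, gb, lr, b1, b2, eps_a, t);
  }
};

// ------------------------------------------------------------ Activation ----
struct Activation {
  int type = 0;                 // 0 relu, 1 elu, 2 leaky_relu (slope 0.01)
  mat inp;
  mat forward(const mat& X, bool keep) {
    mat out = X;
    if (type == 0)
      out.for_each([](double& v) { if (v < 0) v = 0.0; });
    else if (type == 1)
      out.for_each([](double& v) { if (v < 0) v = std::expm1(v); });
    else
      out.for_each([](double& v) { if (v < 0) v *= 0.01; });
    if (keep) inp = X;
    return out;
  }
  mat backward(const mat& G) {
    mat d = inp;
    if (type == 0)
      d.for_each([](double& v) { v = (v > 0) ? 1.0 : 0.0; });
    else if (type == 1)
      d.for_each([](double& v) { v = (v > 0) ? 1.0 : std::exp(v); });
    else
      d.for_each([](double& v) { v = (v > 0) ? 1.0 : 0.01; });
    inp.reset();
    return G % d;
  }
};

// ------------------------------------------------------- Spatial dropout ----
// Zeroes whole feature channels per sample, scaled by 1/(1-p) when active.
struct SpatialDropout {
  double p = 0.0;
  mat mask;                     // (n, C)
  mat forward(const mat& X, const Shape& s, bool train, std::mt19937& rng) {
    if (!train || p <= 0) return X;
    std::bernoulli_distribution B(1.0 - p);
    mask.set_size(s.n, X.n_cols);
    for (int n = 0; n < s.n; ++n)
      for (arma::uword c = 0; c < X.n_cols; ++c)
        mask(n, c) = B(rng) ? 1.0 / (1.0 - p) : 0.0;
    return apply(X, s);
  }
  mat apply(const mat& X, const Shape& s) const {
    mat out = X;
    const long sp = s.spatial();
    for (int n = 0; n < s.n; ++n)
      out.rows((arma::uword)n * sp, (arma::uword)(n + 1) * sp - 1) %=
        arma::repmat(mask.row(n), sp, 1);
    return out;
  }
  mat backward(const mat& G, const Shape& s) {
    if (mask.n_elem == 0) return G;
    mat d = apply(G, s);
    mask.reset();
    return d;
  }
};

// ------------------------------------------------- In-plane pool/upsample ----
// Pooling and upsampling act on rows/cols only (2x2x1) so the slice count is
// preserved at every scale (23 slices cannot be halved repeatedly).
struct MaxPool {
  arma::umat idx;               // (S_out, C) source rows
  mat forward(const mat& X, const Shape& s, Shape& so, bool keep) {
    so = { s.n, s.d, s.h / 2, s.w / 2 };
    mat out(so.rows(), X.n_cols);
    arma::umat id(so.rows(), X.n_cols);
    for (arma::uword c = 0; c < X.n_cols; ++c) {
      const double* src = X.colptr(c);
      double* dst = out.colptr(c);
      arma::uword* ip = id.colptr(c);
      for (int n = 0; n < s.n; ++n)
        for (int z = 0; z < s.d; ++z)
          for (int y = 0; y < so.h; ++y)
            for (int x = 0; x < so.w; ++x) {
              const long ro = ((long)n * so.d + z) * so.h * so.w +
                (long)y * so.w + x;
              double best = -arma::datum::inf; long bi = 0;
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const long ri = ((long)n * s.d + z) * s.h * s.w +
                    (long)(2 * y + dy) * s.w + (2 * x + dx);
                  if (src[ri] > best) { best = src[ri]; bi = ri; }
                }
              dst[ro] = best; ip[ro] = bi;
            }
    }
    if (keep) idx = std::move(id);
    return out;
  }
  mat backward(const mat& G, const Shape& s_in) {
    mat dX; dX.zeros(s_in.rows(), G.n_cols);
    for (arma::uword r = 0; r < G.n_rows; ++r)
      for (arma::uword c = 0; c < G.n_cols; ++c)
        dX(idx(r, c), c) += G(r, c);
    idx.reset();
    return dX;
  }
};

struct Upsample {                // nearest neighbour, 2x2x1
  mat forward(const mat& X, const Shape& s, Shape& so) {
    so = { s.n, s.d, s.h * 2, s.w * 2 };
    mat out(so.rows(), X.n_cols);
    for (arma::uword c = 0; c < X.n_cols; ++c) {
      const double* src = X.colptr(c);
      double* dst = out.colptr(c);
      for (int n = 0; n < so.n; ++n)
        for (int z = 0; z < so.d; ++z)
          for (int y = 0; y < so.h; ++y) {
            const long ro = ((long)n * so.d + z) * so.h * so.w + (long)y * so.w;
            const long ri = ((long)n * s.d + z) * s.h * s.w + (long)(y / 2) * s.w;
            for (int x = 0; x < so.w; ++x) dst[ro + x] = src[ri + x / 2];
          }
    }
    return out;
  }
  mat backward(const mat& G, const Shape& s_in) {
    Shape so = { s_in.n, s_in.d, s_in.h * 2, s_in.w * 2 };
    mat dX; dX.zeros(s_in.rows(), G.n_cols);
    for (arma::uword c = 0; c < G.n_cols; ++c) {
      const double* g = G.colptr(c);
      double* dst = dX.colptr(c);
      for (int n = 0; n < so.n; ++n)
        for (int z = 0; z < so.d; ++z)
          for (int y = 0; y < so.h; ++y) {
            const long ro = ((long)n * so.d + z) * so.h * so.w + (long)y * so.w;
            const long ri = ((long)n * s_in.d + z) * s_in.h * s_in.w +
              (long)(y / 2) * s_in.w;
            for (int x = 0; x < so.w; ++x) dst[ri + x / 2] += g[ro + x];
          }
    }
    return dX;
  }
};

// -------------------------------------------------------- Residual block ----
// 3 x [zero-padded conv -> batch norm -> activation] plus an additive
// shortcut; the shortcut is a 1-kernel projection when channel counts differ.
struct ResBlock {
  Conv c1, c2, c3, proj;
  BatchNorm b1, b2, b3;
  Activation a1, a2, a3;
  bool use_proj = false;
  mat in_cache;

  void init(int cin, int cout, int k1, int k2, int k3, int kd1, int kd2,
            int kd3, int act, std::mt19937& rng) {
    c1.init(cin, cout, kd1, k1, k1, rng);
    c2.init(cout, cout, kd2, k2, k2, rng);
    c3.init(cout, cout, kd3, k3, k3, rng);
    b1.init(cout); b2.init(cout); b3.init(cout);
    a1.type = a2.type = a3.type = act;
    use_proj = (cin != cout);
    if (use_proj) proj.init(cin, cout, 1, 1, 1, rng);
  }
  long n_params() const {
    long p = c1.n_params() + c2.n_params() + c3.n_params() +
      b1.n_params() + b2.n_params() + b3.n_params();
    if (use_proj) p += proj.n_params();
    return p;
  }
  mat forward(const mat& X, const Shape& s, bool train, bool keep) {
    mat y = a1.forward(b1.forward(c1.forward(X, s, keep), train, keep), keep);
    y = a2.forward(b2.forward(c2.forward(y, s, keep), train, keep), keep);
    y = a3.forward(b3.forward(c3.forward(y, s, keep), train, keep), keep);
    mat sc = use_proj ? proj.forward(X, s, keep) : X;
    if (keep) in_cache = X;
    return y + sc;
  }
  mat backward(const mat& G, const Shape& s) {
    mat g = a3.backward(G);
    g = b3.backward(g);
    g = c3.backward(g, s);
    g = a2.backward(g); g = b2.backward(g); g = c2.backward(g, s);
    g = a1.backward(g); g = b1.backward(g); g = c1.backward(g, s);
    mat gs = use_proj ? proj.backward(G, s) : G;
    in_cache.reset();
    return g + gs;
  }
  void update(double lr, double b1a, double b2a, double eps, long t) {
    c1.update(lr, b1a, b2a, eps, t); c2.update(lr, b1a, b2a, eps, t);
    c3.update(lr, b1a, b2a, eps, t);
    b1.update(lr, b1a, b2a, eps, t); b2.update(lr, b1a, b2a, eps, t);
    b3.update(lr, b1a, b2a, eps, t);
    if (use_proj) proj.update(lr, b1a, b2a, eps, t);
  }
};

// ------------------------------------------------------------------- Net ----
struct Net {
  int nb = 2, base = 8, act = 0, k1 = 3, k2 = 3, k3 = 3;
  double dropout = 0.0;
  bool is3d = false, skips = true;
  int in_d = 1, in_h = 0, in_w = 0;
  std::mt19937 rng;
  long adam_t = 0;

  std::vector<ResBlock> down;                 // nb blocks
  std::vector<SpatialDropout> dd;             // nb-1 (first block exempt)
  std::vector<MaxPool> pools;                 // nb
  SpatialDropout dmid;
  ResBlock mid;
  // two up paths: 0 = pz, 1 = pg
  std::vector<SpatialDropout> du[2];
  std::vector<Upsample> ups[2];
  std::vector<ResBlock> up[2];
  Conv head_pg, head_pz;

  // forward caches
  std::vector<mat> skip_feats;
  std::vector<Shape> shapes_down;             // shape at each level pre-pool
  Shape shape_mid;
  mat feat_path[2];
  mat prob_pg, prob_pz;
  Shape in_shape_cache;

  int kd(int k) const { return is3d ? k : 1; }

  void build(int nb_, int base_, int act_, int k1_, int k2_, int k3_,
             double drop, bool is3d_, bool skips_, int d, int h, int w,
             unsigned seed) {
    nb = nb_; base = base_; act = act_; k1 = k1_; k2 = k2_; k3 = k3_;
    dropout = drop; is3d = is3d_; skips = skips_;
    in_d = d; in_h = h; in_w = w;
    rng.seed(seed);
    down.resize(nb); dd.resize(nb > 0 ? nb - 1 : 0); pools.resize(nb);
    int cin = 1;
    for (int i = 0; i < nb; ++i) {
      const int f = base << i;
      down[i].init(cin, f, k1, k2, k3, kd(k1), kd(k2), kd(k3), act, rng);
      if (i > 0) dd[i - 1].p = dropout;
      cin = f;
    }
    dmid.p = dropout;
    mid.init(cin, base << nb, k1, k2, k3, kd(k1), kd(k2), kd(k3), act, rng);
    for (int p = 0; p < 2; ++p) {
      du[p].resize(nb); ups[p].resize(nb); up[p].resize(nb);
      int c = base << nb;
      for (int i = 0; i < nb; ++i) {
        const int f = base << (nb - 1 - i);
        const int ci = c + (skips ? f : 0);
        up[p][i].init(ci, f, k1, k2, k3, kd(k1), kd(k2), kd(k3), act, rng);
        du[p][i].p = dropout;
        c = f;
      }
    }
    head_pz.init(base, 1, 1, 1, 1, rng);
    head_pg.init(2 * base, 1, 1, 1, 1, rng);
  }

  long n_params() const {
    long p = 0;
    for (const auto& b : down) p += b.n_params();
    p += mid.n_params();
    for (int q = 0; q < 2; ++q) for (const auto& b : up[q]) p += b.n_params();
    p += head_pg.n_params() + head_pz.n_params();
    return p;
  }

  // X: rows = n*d*h*w (single input channel)
  void forward(const mat& X, int n, bool train, bool keep) {
    Shape s = { n, in_d, in_h, in_w };
    in_shape_cache = s;
    skip_feats.assign(nb, mat());
    shapes_down.assign(nb, Shape());
    mat cur = X;
    for (int i = 0; i < nb; ++i) {
      if (i > 0) cur = dd[i - 1].forward(cur, s, train, rng);
      cur = down[i].forward(cur, s, train, keep);
      shapes_down[i] = s;
      if (keep || skips) skip_feats[i] = cur;
      Shape so;
      cur = pools[i].forward(cur, s, so, keep);
      s = so;
    }
    cur = dmid.forward(cur, s, train, rng);
    cur = mid.forward(cur, s, train, keep);
    shape_mid = s;
    for (int p = 0; p < 2; ++p) {
      mat c = cur; Shape sp = s;
      for (int i = 0; i < nb; ++i) {
        c = du[p][i].forward(c, sp, train, rng);
        Shape so;
        c = ups[p][i].forward(c, sp, so);
        sp = so;
        if (skips) c = arma::join_rows(c, skip_feats[nb - 1 - i]);
        c = up[p][i].forward(c, sp, train, keep);
      }
      feat_path[p] = c;
    }
    Shape sf = in_shape_cache;
    mat zin = arma::join_rows(feat_path[1], feat_path[0]);  // pg feats + pz feats
    mat lg = head_pg.forward(zin, sf, keep);
    mat lz = head_pz.forward(feat_path[0], sf, keep);
    prob_pg = 1.0 / (1.0 + arma::exp(-lg));
    prob_pz = 1.0 / (1.0 + arma::exp(-lz));
  }

  // G*: gradients w.r.t. head logits (same rows as input, 1 col)
  void backward(const mat& Gpg, const mat& Gpz) {
    Shape sf = in_shape_cache;
    mat gz_in = head_pg.backward(Gpg, sf);                  // (rows, 2*base)
    mat g_pg_feat = gz_in.cols(0, base - 1);
    mat g_pz_feat = gz_in.cols(base, 2 * base - 1);
    g_pz_feat += head_pz.backward(Gpz, sf);
    mat g_mid_total; g_mid_total.zeros(shape_mid.rows(), base << nb);
    std::vector<mat> g_skip(nb);
    for (int i = 0; i < nb; ++i)
      g_skip[i].zeros(shapes_down[i].rows(), base << i);
    for (int p = 0; p < 2; ++p) {
      mat g = (p == 0) ? g_pz_feat : g_pg_feat;
      for (int i = nb - 1; i >= 0; --i) {
        // up level i works at the encoder shape of level nb-1-i
        Shape sp = shapes_down[nb - 1 - i];
        g = up[p][i].backward(g, sp);
        if (skips) {
          const int f = base << (nb - 1 - i);
          g_skip[nb - 1 - i] += g.cols(g.n_cols - f, g.n_cols - 1);
          g = g.cols(0, g.n_cols - f - 1);
        }
        Shape sdeep = { sp.n, sp.d, sp.h / 2, sp.w / 2 };
        g = ups[p][i].backward(g, sdeep);
        g = du[p][i].backward(g, sdeep);
      }
      g_mid_total += g;
    }
    mat g = mid.backward(g_mid_total, shape_mid);
    g = dmid.backward(g, shape_mid);
    for (int i = nb - 1; i >= 0; --i) {
      g = pools[i].backward(g, shapes_down[i]);
      g += g_skip[i];
      g = down[i].backward(g, shapes_down[i]);
      if (i > 0) g = dd[i - 1].backward(g, shapes_down[i]);
    }
  }

  void update(double lr, double b1, double b2, double eps) {
    ++adam_t;
    for (auto& b : down) b.update(lr, b1, b2, eps, adam_t);
    mid.update(lr, b1, b2, eps, adam_t);
    for (int p = 0; p < 2; ++p)
      for (auto& b : up[p]) b.update(lr, b1, b2, eps, adam_t);
    head_pg.update(lr, b1, b2, eps, adam_t);
    head_pz.update(lr, b1, b2, eps, adam_t);
  }
};

// ---------------------------------------------------------------- R glue ----
static int act_code(const std::string& a) {
  if (a == "relu") return 0;
  if (a == "elu") return 1;
  if (a == "leaky_relu") return 2;
  Rcpp::stop("unknown activation '%s'", a.c_str());
}

// [[Rcpp::export(name = ".nn_create")]]
SEXP nn_create(int n_blocks, int base_filters, std::string activation,
               int kernel_1, int kernel_2, int kernel_3, double dropout_p,
               bool is3d, bool lateral_skips, int d, int h, int w, int seed) {
  const int div = 1 << n_blocks;
  if (h % div != 0 || w % div != 0)
    Rcpp::stop("in-plane input shape (%d x %d) must be divisible by 2^n_blocks = %d",
               h, w, div);
  Net* net = new Net();
  net->build(n_blocks, base_filters, act_code(activation), kernel_1, kernel_2,
             kernel_3, dropout_p, is3d, lateral_skips, d, h, w,
             (unsigned)seed);
  Rcpp::XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export(name = ".ptr_is_valid")]]
bool ptr_is_valid(SEXP p) {
  return TYPEOF(p) == EXTPTRSXP && R_ExternalPtrAddr(p) != NULL;
}

// [[Rcpp::export(name = ".nn_n_params")]]
double nn_n_params(SEXP p) {
  Rcpp::XPtr<Net> net(p);
  return (double)net->n_params();
}

// [[Rcpp::export(name = ".nn_forward")]]
Rcpp::List nn_forward(SEXP p, Rcpp::NumericVector x, int n, bool train) {
  Rcpp::XPtr<Net> net(p);
  const long rows = (long)n * net->in_d * net->in_h * net->in_w;
  if ((long)x.size() != rows)
    Rcpp::stop("input length %d does not match batch of %d x (%d,%d,%d)",
               (int)x.size(), n, net->in_h, net->in_w, net->in_d);
  mat X(x.begin(), rows, 1);
  net->forward(X, n, train, false);
  return Rcpp::List::create(
    Rcpp::Named("pg") = Rcpp::NumericVector(net->prob_pg.begin(), net->prob_pg.end()),
    Rcpp::Named("pz") = Rcpp::NumericVector(net->prob_pz.begin(), net->prob_pz.end()));
}

// Squared-denominator soft Dice loss over the whole batch; returns the loss
// and writes d(loss)/d(logit) into G.
static double dice_term_grad(const mat& prob, const mat& y, double eps,
                             mat& G) {
  const double num = 2.0 * arma::dot(prob, y);
  const double den = arma::dot(prob, prob) + arma::dot(y, y) + eps;
  const double loss = 1.0 - num / den;
  // d/dp of (1 - num/den) = -(2*y*den - num*2*p)/den^2 ; chain through sigmoid
  G = -(2.0 * y * den - 2.0 * num * prob) / (den * den);
  G %= prob % (1.0 - prob);
  return loss;
}

// [[Rcpp::export(name = ".nn_loss_forward")]]
double nn_loss_forward(SEXP p, Rcpp::NumericVector x, Rcpp::NumericVector ypg,
                       Rcpp::NumericVector ypz, bool has_pz, double alpha,
                       double eps, int n) {
  Rcpp::XPtr<Net> net(p);
  const long rows = (long)n * net->in_d * net->in_h * net->in_w;
  mat X(x.begin(), rows, 1);
  net->forward(X, n, false, false);
  mat Ypg(ypg.begin(), rows, 1), G;
  double L = dice_term_grad(net->prob_pg, Ypg, eps, G);
  if (has_pz) {
    mat Ypz(ypz.begin(), rows, 1);
    L += alpha * dice_term_grad(net->prob_pz, Ypz, eps, G);
  }
  return L;
}

// [[Rcpp::export(name = ".nn_train_step")]]
double nn_train_step(SEXP p, Rcpp::NumericVector x, Rcpp::NumericVector ypg,
                     Rcpp::NumericVector ypz, bool has_pz, double alpha,
                     double eps, int n, double lr, double beta1, double beta2,
                     double adam_eps) {
  Rcpp::XPtr<Net> net(p);
  const long rows = (long)n * net->in_d * net->in_h * net->in_w;
  mat X(x.begin(), rows, 1);
  net->forward(X, n, true, true);
  mat Ypg(ypg.begin(), rows, 1);
  mat Gpg, Gpz;
  double L = dice_term_grad(net->prob_pg, Ypg, eps, Gpg);
  if (has_pz) {
    mat Ypz(ypz.begin(), rows, 1);
    L += alpha * dice_term_grad(net->prob_pz, Ypz, eps, Gpz);
    Gpz *= alpha;
  } else {
    Gpz.zeros(rows, 1);
  }
  net->backward(Gpg, Gpz);
  net->update(lr, beta1, beta2, adam_eps);
  return L;
}

static void push_conv(Rcpp::List& out, int& i, const Conv& c) {
  out[i++] = Rcpp::NumericVector(c.W.begin(), c.W.end());
  out[i++] = Rcpp::NumericVector(c.b.begin(), c.b.end());
}
static void push_bn(Rcpp::List& out, int& i, const BatchNorm& b) {
  out[i++] = Rcpp::NumericVector(b.gamma.begin(), b.gamma.end());
  out[i++] = Rcpp::NumericVector(b.beta.begin(), b.beta.end());
  out[i++] = Rcpp::NumericVector(b.run_mean.begin(), b.run_mean.end());
  out[i++] = Rcpp::NumericVector(b.run_var.begin(), b.run_var.end());
}
static void push_block(Rcpp::List& out, int& i, const ResBlock& b) {
  push_conv(out, i, b.c1); push_conv(out, i, b.c2); push_conv(out, i, b.c3);
  push_bn(out, i, b.b1); push_bn(out, i, b.b2); push_bn(out, i, b.b3);
  if (b.use_proj) push_conv(out, i, b.proj);
}
static int block_slots(const ResBlock& b) { return 6 + 12 + (b.use_proj ? 2 : 0); }

template <typename T>
static void pull_vec(const Rcpp::List& in, int& i, T& v) {
  Rcpp::NumericVector x = in[i++];
  if ((long)x.size() != (long)v.n_elem) Rcpp::stop("weight vector size mismatch");
  std::copy(x.begin(), x.end(), v.begin());
}
static void pull_conv(const Rcpp::List& in, int& i, Conv& c) {
  pull_vec(in, i, c.W); pull_vec(in, i, c.b);
}
static void pull_bn(const Rcpp::List& in, int& i, BatchNorm& b) {
  pull_vec(in, i, b.gamma); pull_vec(in, i, b.beta);
  pull_vec(in, i, b.run_mean); pull_vec(in, i, b.run_var);
}
static void pull_block(const Rcpp::List& in, int& i, ResBlock& b) {
  pull_conv(in, i, b.c1); pull_conv(in, i, b.c2); pull_conv(in, i, b.c3);
  pull_bn(in, i, b.b1); pull_bn(in, i, b.b2); pull_bn(in, i, b.b3);
  if (b.use_proj) pull_conv(in, i, b.proj);
}

// [[Rcpp::export(name = ".nn_get_params")]]
Rcpp::List nn_get_params(SEXP p) {
  Rcpp::XPtr<Net> net(p);
  int total = 0;
  for (auto& b : net->down) total += block_slots(b);
  total += block_slots(net->mid);
  for (int q = 0; q < 2; ++q) for (auto& b : net->up[q]) total += block_slots(b);
  total += 4;                    // two heads (W, b each)
  Rcpp::List out(total);
  int i = 0;
  for (auto& b : net->down) push_block(out, i, b);
  push_block(out, i, net->mid);
  for (int q = 0; q < 2; ++q) for (auto& b : net->up[q]) push_block(out, i, b);
  push_conv(out, i, net->head_pg); push_conv(out, i, net->head_pz);
  return out;
}

// [[Rcpp::export(name = ".nn_set_params")]]
void nn_set_params(SEXP p, Rcpp::List w) {
  Rcpp::XPtr<Net> net(p);
  int i = 0;
  for (auto& b : net->down) pull_block(w, i, b);
  pull_block(w, i, net->mid);
  for (int q = 0; q < 2; ++q) for (auto& b : net->up[q]) pull_block(w, i, b);
  pull_conv(w, i, net->head_pg); pull_conv(w, i, net->head_pz);
}
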