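// Single-precision training/inference engine for the four ablation
// architectures (CNN / CNN-FCN / CNN-KAN / CNN-KAN-F2CA) on 4x4x3
// pseudo-RGB inputs. All heavy steps are BLAS sgemm calls via Armadillo;
// elementwise stages are fused pointer loops.
//
// Layout conventions (shared with the R side):
//  * a batch is a 48 x N matrix; row index = channel + 3*(row + 4*col)
//  * conv kernels are (9*Cin) x Cout; row index = cin + Cin*((di+1)+3*(dj+1))
//  * activations are C x (16*N); column index = position + 16*sample
//  * flattening views C x (16*N) memory as (16*C) x N (channel fastest)
//  * KAN spline coefficients arrive as an R array (dIn, dOut, nCoef)

#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

static const float BN_EPS = 1e-3f;
static const float BN_MOMENTUM = 0.9f;
static const int MAX_KNOTS = 32;    // spline work-array bound (grid + 2k + 1)

// ---------------------------------------------------------------- utilities

struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  float unif() { return (next() >> 40) * (1.0f / 16777216.0f); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

static fmat asF(SEXP x, int nr, int nc) {
  NumericVector v(x);
  if ((int)v.size() != nr * nc) stop("parameter has unexpected size");
  fmat out(nr, nc);
  for (int i = 0; i < nr * nc; ++i) out.memptr()[i] = (float)v[i];
  return out;
}

static fvec asFv(SEXP x) {
  NumericVector v(x);
  fvec out(v.size());
  for (int i = 0; i < (int)v.size(); ++i) out[i] = (float)v[i];
  return out;
}

static NumericVector toR(const fmat& m, IntegerVector dims) {
  NumericVector out(m.n_elem);
  for (size_t i = 0; i < m.n_elem; ++i) out[i] = m.memptr()[i];
  out.attr("dim") = dims;
  return out;
}

static NumericVector toRv(const fvec& v) {
  NumericVector out(v.n_elem);
  for (size_t i = 0; i < v.n_elem; ++i) out[i] = v[i];
  return out;
}

// ------------------------------------------------------------ configuration

struct Cfg {
  int variant;                 // 0 cnn, 1 cnn_fcn, 2 cnn_kan, 3 cnn_kan_f2ca
  int f1, f2, f3, numClasses, ratio;
  float dc1, dc2, dc3, dfc, l2;
  int kanHidden, kanGrid, kanOrder;
  float kanLo, kanHi;
  bool hasF2ca() const { return variant == 3; }
  bool hasKan() const { return variant >= 2; }
  int nCoef() const { return kanGrid + kanOrder; }
};

static Cfg parseCfg(List cfg) {
  Cfg c;
  c.variant = as<int>(cfg["variant"]);
  IntegerVector f = cfg["filters"];
  c.f1 = f[0]; c.f2 = f[1]; c.f3 = f[2];
  c.numClasses = as<int>(cfg["numClasses"]);
  NumericVector dc = cfg["dropoutConv"];
  c.dc1 = dc[0]; c.dc2 = dc[1]; c.dc3 = dc[2];
  c.dfc = as<double>(cfg["dropoutFc"]);
  c.l2 = as<double>(cfg["l2"]);
  c.ratio = as<int>(cfg["ratio"]);
  c.kanHidden = as<int>(cfg["kanHidden"]);
  c.kanGrid = as<int>(cfg["kanGridSize"]);
  c.kanOrder = as<int>(cfg["kanOrder"]);
  c.kanLo = as<double>(cfg["kanLo"]);
  c.kanHi = as<double>(cfg["kanHi"]);
  if (c.kanGrid + 2 * c.kanOrder + 1 > MAX_KNOTS)
    stop("spline grid too large for the engine (grid + 2*order + 1 > %d)", MAX_KNOTS);
  return c;
}

// ------------------------------------------------------------------ network

struct Net {
  Cfg cfg;
  fmat c1W, c2W, c3W;
  fvec c1b, c2b, c3b;
  fvec bng[3], bnb[3], bnm[3], bnv[3];
  fmat fW1, fW2; fvec fb1, fb2;              // attention bottleneck
  fmat denseW; fvec denseb;
  fmat fc2W; fvec fc2b;
  fmat kanWb;                                 // dIn x hidden
  fmat kanWs;                                 // (nCoef*dIn) x hidden
  fmat kanSc;                                 // dIn x hidden
  fmat outW; fvec outb;
  fmat Fre;                                   // f3 x f3 real DFT matrix

  void load(List p, const Cfg& c) {
    cfg = c;
    c1W = asF(p["conv1_W"], 9 * 3, c.f1);       c1b = asFv(p["conv1_b"]);
    c2W = asF(p["conv2_W"], 9 * c.f1, c.f2);    c2b = asFv(p["conv2_b"]);
    c3W = asF(p["conv3_W"], 9 * c.f2, c.f3);    c3b = asFv(p["conv3_b"]);
    const char* nm[3] = {"bn1", "bn2", "bn3"};
    for (int i = 0; i < 3; ++i) {
      std::string b(nm[i]);
      bng[i] = asFv(p[b + "_gamma"]); bnb[i] = asFv(p[b + "_beta"]);
      bnm[i] = asFv(p[b + "_mean"]);  bnv[i] = asFv(p[b + "_var"]);
    }
    if (c.hasF2ca()) {
      int h = c.f3 / c.ratio;
      fW1 = asF(p["f2ca_W1"], h, c.f3); fb1 = asFv(p["f2ca_b1"]);
      fW2 = asF(p["f2ca_W2"], c.f3, h); fb2 = asFv(p["f2ca_b2"]);
      Fre.set_size(c.f3, c.f3);
      for (int a = 0; a < c.f3; ++a)
        for (int b = 0; b < c.f3; ++b)
          Fre(a, b) = std::cos(2.0 * M_PI * a * b / c.f3);
    }
    denseW = asF(p["dense_W"], 16 * c.f3, 256); denseb = asFv(p["dense_b"]);
    if (c.variant == 1) {
      fc2W = asF(p["fc2_W"], 256, 128); fc2b = asFv(p["fc2_b"]);
      outW = asF(p["out_W"], 128, c.numClasses);
    } else if (c.hasKan()) {
      kanWb = asF(p["kan_Wbase"], 256, c.kanHidden);
      // R array (dIn, dOut, nCoef) -> row k + nCoef*i, column o
      NumericVector ws(p["kan_Wspline"]);
      int dIn = 256, dOut = c.kanHidden, nc = c.nCoef();
      if ((int)ws.size() != dIn * dOut * nc) stop("kan_Wspline has unexpected size");
      kanWs.set_size(nc * dIn, dOut);
      for (int k = 0; k < nc; ++k)
        for (int o = 0; o < dOut; ++o)
          for (int i = 0; i < dIn; ++i)
            kanWs(k + nc * i, o) = (float)ws[i + dIn * o + dIn * dOut * k];
      kanSc = asF(p["kan_scaler"], 256, c.kanHidden);
      outW = asF(p["out_W"], c.kanHidden, c.numClasses);
    } else {
      outW = asF(p["out_W"], 256, c.numClasses);
    }
    outb = asFv(p["out_b"]);
  }

  List dump() const {
    List p;
    p["conv1_W"] = toR(c1W, IntegerVector::create(27, cfg.f1));
    p["conv1_b"] = toRv(c1b);
    p["conv2_W"] = toR(c2W, IntegerVector::create(9 * cfg.f1, cfg.f2));
    p["conv2_b"] = toRv(c2b);
    p["conv3_W"] = toR(c3W, IntegerVector::create(9 * cfg.f2, cfg.f3));
    p["conv3_b"] = toRv(c3b);
    const char* nm[3] = {"bn1", "bn2", "bn3"};
    for (int i = 0; i < 3; ++i) {
      std::string b(nm[i]);
      p[b + "_gamma"] = toRv(bng[i]); p[b + "_beta"] = toRv(bnb[i]);
      p[b + "_mean"] = toRv(bnm[i]);  p[b + "_var"] = toRv(bnv[i]);
    }
    if (cfg.hasF2ca()) {
      int h = cfg.f3 / cfg.ratio;
      p["f2ca_W1"] = toR(fW1, IntegerVector::create(h, cfg.f3));
      p["f2ca_b1"] = toRv(fb1);
      p["f2ca_W2"] = toR(fW2, IntegerVector::create(cfg.f3, h));
      p["f2ca_b2"] = toRv(fb2);
    }
    p["dense_W"] = toR(denseW, IntegerVector::create(16 * cfg.f3, 256));
    p["dense_b"] = toRv(denseb);
    if (cfg.variant == 1) {
      p["fc2_W"] = toR(fc2W, IntegerVector::create(256, 128));
      p["fc2_b"] = toRv(fc2b);
    } else if (cfg.hasKan()) {
      p["kan_Wbase"] = toR(kanWb, IntegerVector::create(256, cfg.kanHidden));
      int dIn = 256, dOut = cfg.kanHidden, nc = cfg.nCoef();
      NumericVector ws(dIn * dOut * nc);
      for (int k = 0; k < nc; ++k)
        for (int o = 0; o < dOut; ++o)
          for (int i = 0; i < dIn; ++i)
            ws[i + dIn * o + dIn * dOut * k] = kanWs(k + nc * i, o);
      ws.attr("dim") = IntegerVector::create(dIn, dOut, nc);
      p["kan_Wspline"] = ws;
      p["kan_scaler"] = toR(kanSc, IntegerVector::create(256, cfg.kanHidden));
    }
    p["out_W"] = toR(outW, IntegerVector::create(outW.n_rows, cfg.numClasses));
    p["out_b"] = toRv(outb);
    return p;
  }
};

// neighbor position (or -1 for zero padding) per position and 3x3 offset
static void makeNeigh(int neigh[16][9]) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj) {
          int ii = i + di, jj = j + dj;
          neigh[i + 4 * j][(di + 1) + 3 * (dj + 1)] =
            (ii >= 0 && ii < 4 && jj >= 0 && jj < 4) ? ii + 4 * jj : -1;
        }
}

static void im2col(const fmat& A, int Cin, int n, const int neigh[16][9], fmat& B) {
  B.zeros(9 * Cin, 16 * n);
  for (int s = 0; s < n; ++s)
    for (int p = 0; p < 16; ++p) {
      float* bcol = B.colptr(p + 16 * s);
      for (int o = 0; o < 9; ++o) {
        int q = neigh[p][o];
        if (q >= 0)
          std::memcpy(bcol + o * Cin, A.colptr(q + 16 * s), Cin * sizeof(float));
      }
    }
}

static void col2im(const fmat& dB, int Cin, int n, const int neigh[16][9], fmat& dA) {
  dA.zeros(Cin, 16 * n);
  for (int s = 0; s < n; ++s)
    for (int p = 0; p < 16; ++p) {
      const float* bcol = dB.colptr(p + 16 * s);
      for (int o = 0; o < 9; ++o) {
        int q = neigh[p][o];
        if (q >= 0) {
          float* acol = dA.colptr(q + 16 * s);
          const float* src = bcol + o * Cin;
          for (int c = 0; c < Cin; ++c) acol[c] += src[c];
        }
      }
    }
}

// B-spline basis (and derivative) of order k on a uniform extended grid;
// writes nCoef = G + k values for one input x (clamped to the span)
static void evalBasis(float x, float lo, float hi, int G, int k,
                      float* B, float* dB) {
  int nCoef = G + k;
  float h = (hi - lo) / G;
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  int cell = (int)((x - lo) / h);
  if (cell >= G) cell = G - 1;
  float cur[MAX_KNOTS] = {0}, nxt[MAX_KNOTS] = {0}, lower[MAX_KNOTS] = {0};
  cur[cell + k] = 1.0f;                  // order-0 indicator
  if (k == 0) {
    for (int j = 0; j < nCoef; ++j) { B[j] = cur[j]; dB[j] = 0.0f; }
    return;
  }
  int nKnots = G + 2 * k + 1;
  for (int ord = 1; ord <= k; ++ord) {
    if (ord == k) std::memcpy(lower, cur, sizeof(lower));
    int nb = nKnots - ord - 1;
    for (int j = 0; j < nb; ++j) {
      float tj = lo + (j - k) * h;
      float v = 0.0f;
      if (cur[j] != 0.0f)     v += (x - tj) / (ord * h) * cur[j];
      if (cur[j + 1] != 0.0f) v += (tj + (ord + 1) * h - x) / (ord * h) * cur[j + 1];
      nxt[j] = v;
    }
    std::memcpy(cur, nxt, sizeof(cur));
    std::memset(nxt, 0, sizeof(nxt));
  }
  for (int j = 0; j < nCoef; ++j) {
    B[j] = cur[j];
    dB[j] = (lower[j] - lower[j + 1]) / h;
  }
}

// fused ReLU + (inverted) dropout; in training mode the combined
// multiplicative mask is stored for the backward pass
static void reluDropout(fmat& Z, float rate, bool train, XRng& rng, fmat& M) {
  float* zp = Z.memptr();
  size_t N = Z.n_elem;
  if (!train) {
    for (size_t i = 0; i < N; ++i) if (zp[i] < 0) zp[i] = 0;
    M.reset();
    return;
  }
  M.set_size(Z.n_rows, Z.n_cols);
  float* mp = M.memptr();
  if (rate <= 0) {
    for (size_t i = 0; i < N; ++i) {
      if (zp[i] > 0) mp[i] = 1.0f;
      else { mp[i] = 0.0f; zp[i] = 0.0f; }
    }
  } else {
    float keep = 1.0f - rate, inv = 1.0f / keep;
    for (size_t i = 0; i < N; ++i) {
      if (zp[i] > 0 && rng.unif() < keep) { mp[i] = inv; zp[i] *= inv; }
      else { mp[i] = 0.0f; zp[i] = 0.0f; }
    }
  }
}

// caches kept between forward and backward
struct Cache {
  fmat B1, X1h, M1;                     // conv block caches
  fmat B2, X2h, M2;
  fmat B3, X3h, M3;
  fvec istd[3];
  fmat v1, freg, hAttVal, hAttMask, sAtt, A3pre;  // attention
  fmat A3, F, Mfc, Hd;                  // dense input/output
  fmat fc2M, H2;
  fmat Zk, siluZ, sigZ, Bsp, dBsp, scExp, WsEff;  // kan
  fmat P;                               // probabilities C x n
};

struct Grads {
  fmat c1W, c2W, c3W; fvec c1b, c2b, c3b;
  fvec bng[3], bnb[3];
  fmat fW1, fW2; fvec fb1, fb2;
  fmat denseW; fvec denseb;
  fmat fc2W; fvec fc2b;
  fmat kanWb, kanWs, kanSc;
  fmat outW; fvec outb;
};

static void bnForward(fmat& Z, const fvec& g, const fvec& b, fvec& mMov, fvec& vMov,
                      bool train, fmat& xhat, fvec& istdOut) {
  if (train) {
    fvec mu = arma::mean(Z, 1);
    Z.each_col() -= mu;
    fvec va = arma::mean(arma::square(Z), 1);
    fvec istd = 1.0f / arma::sqrt(va + BN_EPS);
    Z.each_col() %= istd;
    xhat = Z;
    istdOut = istd;
    mMov = BN_MOMENTUM * mMov + (1 - BN_MOMENTUM) * mu;
    vMov = BN_MOMENTUM * vMov + (1 - BN_MOMENTUM) * va;
  } else {
    fvec istd = 1.0f / arma::sqrt(vMov + BN_EPS);
    Z.each_col() -= mMov;
    Z.each_col() %= istd;
  }
  Z.each_col() %= g;
  Z.each_col() += b;
}

static void bnBackward(fmat& dY, const fmat& xhat, const fvec& istd, const fvec& g,
                       fvec& dg, fvec& db) {
  dg = arma::sum(dY % xhat, 1);
  db = arma::sum(dY, 1);
  dY.each_col() %= g;                       // now dxhat
  fvec m1 = arma::mean(dY, 1);
  fvec m2 = arma::mean(dY % xhat, 1);
  dY.each_col() -= m1;
  dY -= xhat.each_col() % m2;
  dY.each_col() %= istd;                    // now dZ (wrt normalized input)
}

// forward pass; fills cache when train = true
static void forward(Net& net, const fmat& X, bool train, bool useDropout,
                    XRng& rng, Cache& cc) {
  const Cfg& c = net.cfg;
  int n = X.n_cols;
  int neigh[16][9];
  makeNeigh(neigh);

  fmat A0 = arma::reshape(X, 3, 16 * n);
  im2col(A0, 3, n, neigh, cc.B1);
  fmat Z = net.c1W.t() * cc.B1;
  Z.each_col() += net.c1b;
  bnForward(Z, net.bng[0], net.bnb[0], net.bnm[0], net.bnv[0], train, cc.X1h, cc.istd[0]);
  reluDropout(Z, useDropout ? c.dc1 : 0.0f, train, rng, cc.M1);

  im2col(Z, c.f1, n, neigh, cc.B2);
  Z = net.c2W.t() * cc.B2;
  Z.each_col() += net.c2b;
  bnForward(Z, net.bng[1], net.bnb[1], net.bnm[1], net.bnv[1], train, cc.X2h, cc.istd[1]);
  reluDropout(Z, useDropout ? c.dc2 : 0.0f, train, rng, cc.M2);

  im2col(Z, c.f2, n, neigh, cc.B3);
  Z = net.c3W.t() * cc.B3;
  Z.each_col() += net.c3b;
  bnForward(Z, net.bng[2], net.bnb[2], net.bnm[2], net.bnv[2], train, cc.X3h, cc.istd[2]);
  reluDropout(Z, useDropout ? c.dc3 : 0.0f, train, rng, cc.M3);

  if (c.hasF2ca()) {
    if (train) cc.A3pre = Z;
    cc.v1.zeros(c.f3, n);
    for (int s = 0; s < n; ++s) {
      float* vp = cc.v1.colptr(s);
      for (int p = 0; p < 16; ++p) {
        const float* ap = Z.colptr(p + 16 * s);
        for (int ch = 0; ch < c.f3; ++ch) vp[ch] += ap[ch];
      }
      for (int ch = 0; ch < c.f3; ++ch) vp[ch] *= (1.0f / 16.0f);
    }
    cc.freg = net.Fre * cc.v1;
    fmat h = net.fW1 * cc.freg;
    h.each_col() += net.fb1;
    cc.hAttMask = arma::conv_to<fmat>::from(h > 0);
    h %= cc.hAttMask;
    cc.hAttVal = h;
    fmat zs = net.fW2 * h;
    zs.each_col() += net.fb2;
    cc.sAtt = 1.0f / (1.0f + arma::exp(-zs));
    for (int s = 0; s < n; ++s) {
      const float* sp = cc.sAtt.colptr(s);
      for (int p = 0; p < 16; ++p) {
        float* ap = Z.colptr(p + 16 * s);
        for (int ch = 0; ch < c.f3; ++ch) ap[ch] *= sp[ch];
      }
    }
  }
  cc.A3 = Z;

  cc.F = arma::reshape(cc.A3, 16 * c.f3, n);
  fmat H = net.denseW.t() * cc.F;
  H.each_col() += net.denseb;
  reluDropout(H, useDropout ? c.dfc : 0.0f, train, rng, cc.Mfc);
  cc.Hd = H;

  fmat Zout;
  if (c.variant == 0) {
    Zout = net.outW.t() * cc.Hd;
  } else if (c.variant == 1) {
    fmat h2 = net.fc2W.t() * cc.Hd;
    h2.each_col() += net.fc2b;
    reluDropout(h2, 0.0f, train, rng, cc.fc2M);
    cc.H2 = h2;
    Zout = net.outW.t() * cc.H2;
  } else {
    int dIn = 256, nc = c.nCoef();
    cc.Zk = cc.Hd;
    cc.sigZ = 1.0f / (1.0f + arma::exp(-cc.Zk));
    cc.siluZ = cc.Zk % cc.sigZ;
    cc.Bsp.set_size(nc * dIn, n);
    cc.dBsp.set_size(nc * dIn, n);
    for (int s = 0; s < n; ++s) {
      float* bp = cc.Bsp.colptr(s);
      float* dp = cc.dBsp.colptr(s);
      const float* zp = cc.Zk.colptr(s);
      for (int i = 0; i < dIn; ++i)
        evalBasis(zp[i], c.kanLo, c.kanHi, c.kanGrid, c.kanOrder,
                  bp + nc * i, dp + nc * i);
    }
    // effective spline weights: scaler-modulated coefficients
    cc.scExp.set_size(nc * dIn, c.kanHidden);
    for (int o = 0; o < c.kanHidden; ++o) {
      float* sp = cc.scExp.colptr(o);
      const float* kc = net.kanSc.colptr(o);
      for (int i = 0; i < dIn; ++i)
        for (int k = 0; k < nc; ++k) sp[k + nc * i] = kc[i];
    }
    cc.WsEff = net.kanWs % cc.scExp;
    cc.H2 = net.kanWb.t() * cc.siluZ + cc.WsEff.t() * cc.Bsp;
    Zout = net.outW.t() * cc.H2;
  }
  Zout.each_col() += net.outb;

  // softmax
  arma::frowvec mx = arma::max(Zout, 0);
  Zout.each_row() -= mx;
  cc.P = arma::exp(Zout);
  arma::frowvec denom = arma::sum(cc.P, 0);
  cc.P.each_row() /= denom;
}

static double l2Penalty(const Net& net) {
  const Cfg& c = net.cfg;
  double s = arma::accu(arma::square(net.c1W)) + arma::accu(arma::square(net.c2W)) +
             arma::accu(arma::square(net.c3W)) + arma::accu(arma::square(net.denseW)) +
             arma::accu(arma::square(net.outW));
  if (c.variant == 1) s += arma::accu(arma::square(net.fc2W));
  if (c.hasKan()) s += arma::accu(arma::square(net.kanWb)) +
                       arma::accu(arma::square(net.kanWs));
  if (c.hasF2ca()) s += arma::accu(arma::square(net.fW1)) +
                        arma::accu(arma::square(net.fW2));
  return s;
}

// backward pass from softmax cross-entropy; y is 0-based
static void backward(Net& net, const arma::ivec& y, Cache& cc, Grads& g) {
  const Cfg& c = net.cfg;
  int n = cc.P.n_cols;
  int neigh[16][9];
  makeNeigh(neigh);
  float inv = 1.0f / n;

  fmat dZ = cc.P;
  for (int s = 0; s < n; ++s) dZ(y[s], s) -= 1.0f;
  dZ *= inv;

  fmat dH;                                    // gradient wrt cc.Hd
  if (c.variant == 0) {
    g.outW = cc.Hd * dZ.t();
    g.outb = arma::sum(dZ, 1);
    dH = net.outW * dZ;
  } else if (c.variant == 1) {
    g.outW = cc.H2 * dZ.t();
    g.outb = arma::sum(dZ, 1);
    fmat dH2 = net.outW * dZ;
    dH2 %= cc.fc2M;
    g.fc2W = cc.Hd * dH2.t();
    g.fc2b = arma::sum(dH2, 1);
    dH = net.fc2W * dH2;
  } else {
    g.outW = cc.H2 * dZ.t();
    g.outb = arma::sum(dZ, 1);
    fmat dH2 = net.outW * dZ;                 // hidden x n
    int dIn = 256, nc = c.nCoef();
    // base path
    g.kanWb = cc.siluZ * dH2.t();
    fmat dSilu = net.kanWb * dH2;             // dIn x n
    dH = dSilu % (cc.sigZ % (1.0f + cc.Zk % (1.0f - cc.sigZ)));
    // spline path
    fmat dWeff = cc.Bsp * dH2.t();            // (nc*dIn) x hidden
    g.kanWs = dWeff % cc.scExp;
    fmat scNum = dWeff % net.kanWs;
    g.kanSc.set_size(dIn, c.kanHidden);
    for (int o = 0; o < c.kanHidden; ++o) {
      const float* sp = scNum.colptr(o);
      float* gp = g.kanSc.colptr(o);
      for (int i = 0; i < dIn; ++i) {
        float acc = 0.0f;
        for (int k = 0; k < nc; ++k) acc += sp[k + nc * i];
        gp[i] = acc;
      }
    }
    fmat dB = cc.WsEff * dH2;                 // (nc*dIn) x n
    dB %= cc.dBsp;
    for (int s = 0; s < n; ++s) {
      const float* dbp = dB.colptr(s);
      const float* zp = cc.Zk.colptr(s);
      float* dhp = dH.colptr(s);
      for (int i = 0; i < dIn; ++i) {
        if (zp[i] <= c.kanLo || zp[i] >= c.kanHi) continue;  // clamped
        float acc = 0.0f;
        for (int k = 0; k < nc; ++k) acc += dbp[k + nc * i];
        dhp[i] += acc;
      }
    }
  }

  dH %= cc.Mfc;
  g.denseW = cc.F * dH.t();
  g.denseb = arma::sum(dH, 1);
  fmat dF = net.denseW * dH;
  fmat dA3 = arma::reshape(dF, c.f3, 16 * n);

  if (c.hasF2ca()) {
    fmat ds(c.f3, n, arma::fill::zeros);
    for (int s = 0; s < n; ++s) {
      float* dsp = ds.colptr(s);
      const float* sp = cc.sAtt.colptr(s);
      for (int p = 0; p < 16; ++p) {
        float* dap = dA3.colptr(p + 16 * s);
        const float* xp = cc.A3pre.colptr(p + 16 * s);
        for (int ch = 0; ch < c.f3; ++ch) {
          dsp[ch] += dap[ch] * xp[ch];
          dap[ch] *= sp[ch];
        }
      }
    }
    fmat dzs = ds % cc.sAtt % (1.0f - cc.sAtt);
    g.fW2 = dzs * cc.hAttVal.t();
    g.fb2 = arma::sum(dzs, 1);
    fmat dh = net.fW2.t() * dzs;
    dh %= cc.hAttMask;
    g.fW1 = dh * cc.freg.t();
    g.fb1 = arma::sum(dh, 1);
    fmat dfreg = net.fW1.t() * dh;
    fmat dv1 = net.Fre.t() * dfreg;
    dv1 *= (1.0f / 16.0f);
    for (int s = 0; s < n; ++s) {
      const float* dvp = dv1.colptr(s);
      for (int p = 0; p < 16; ++p) {
        float* dap = dA3.colptr(p + 16 * s);
        for (int ch = 0; ch < c.f3; ++ch) dap[ch] += dvp[ch];
      }
    }
  }

  // conv block 3
  dA3 %= cc.M3;
  bnBackward(dA3, cc.X3h, cc.istd[2], net.bng[2], g.bng[2], g.bnb[2]);
  g.c3W = cc.B3 * dA3.t();
  g.c3b = arma::sum(dA3, 1);
  fmat dB3 = net.c3W * dA3;
  fmat dA2;
  col2im(dB3, c.f2, n, neigh, dA2);

  dA2 %= cc.M2;
  bnBackward(dA2, cc.X2h, cc.istd[1], net.bng[1], g.bng[1], g.bnb[1]);
  g.c2W = cc.B2 * dA2.t();
  g.c2b = arma::sum(dA2, 1);
  fmat dB2 = net.c2W * dA2;
  fmat dA1;
  col2im(dB2, c.f1, n, neigh, dA1);

  dA1 %= cc.M1;
  bnBackward(dA1, cc.X1h, cc.istd[0], net.bng[0], g.bng[0], g.bnb[0]);
  g.c1W = cc.B1 * dA1.t();
  g.c1b = arma::sum(dA1, 1);
  // input gradient not needed
}

// ------------------------------------------------------------------- Adam

struct Adam {
  std::vector<arma::Mat<float>*> w;
  std::vector<arma::Mat<float>*> gr;
  std::vector<bool> reg;
  std::vector<fmat> m, v;
  long t = 0;

  void add(arma::Mat<float>& wm, arma::Mat<float>& gm, bool l2flag) {
    w.push_back(&wm); gr.push_back(&gm); reg.push_back(l2flag);
    m.push_back(fmat(wm.n_rows, wm.n_cols, arma::fill::zeros));
    v.push_back(fmat(wm.n_rows, wm.n_cols, arma::fill::zeros));
  }

  void step(float lr, float l2) {
    ++t;
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
    float c1 = 1.0f - std::pow(b1, (float)t);
    float c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t i = 0; i < w.size(); ++i) {
      float* wp = w[i]->memptr();
      float* gp = gr[i]->memptr();
      float* mp = m[i].memptr();
      float* vp = v[i].memptr();
      float tl2 = reg[i] ? 2.0f * l2 : 0.0f;
      size_t N = w[i]->n_elem;
      for (size_t j = 0; j < N; ++j) {
        float gg = gp[j] + tl2 * wp[j];
        mp[j] = b1 * mp[j] + (1 - b1) * gg;
        vp[j] = b2 * vp[j] + (1 - b2) * gg * gg;
        wp[j] -= lr * (mp[j] / c1) / (std::sqrt(vp[j] / c2) + eps);
      }
    }
  }
};

static void registerParams(Net& net, Grads& g, Adam& ad) {
  const Cfg& c = net.cfg;
  ad.add(net.c1W, g.c1W, true); ad.add(net.c1b, g.c1b, false);
  ad.add(net.c2W, g.c2W, true); ad.add(net.c2b, g.c2b, false);
  ad.add(net.c3W, g.c3W, true); ad.add(net.c3b, g.c3b, false);
  for (int i = 0; i < 3; ++i) {
    ad.add(net.bng[i], g.bng[i], false);
    ad.add(net.bnb[i], g.bnb[i], false);
  }
  if (c.hasF2ca()) {
    ad.add(net.fW1, g.fW1, true); ad.add(net.fb1, g.fb1, false);
    ad.add(net.fW2, g.fW2, true); ad.add(net.fb2, g.fb2, false);
  }
  ad.add(net.denseW, g.denseW, true); ad.add(net.denseb, g.denseb, false);
  if (c.variant == 1) {
    ad.add(net.fc2W, g.fc2W, true); ad.add(net.fc2b, g.fc2b, false);
  } else if (c.hasKan()) {
    ad.add(net.kanWb, g.kanWb, true);
    ad.add(net.kanWs, g.kanWs, true);
    ad.add(net.kanSc, g.kanSc, false);
  }
  ad.add(net.outW, g.outW, true); ad.add(net.outb, g.outb, false);
}

static void sizeGrads(const Net& net, Grads& g) {
  const Cfg& c = net.cfg;
  g.c1W.zeros(net.c1W.n_rows, net.c1W.n_cols); g.c1b.zeros(net.c1b.n_elem);
  g.c2W.zeros(net.c2W.n_rows, net.c2W.n_cols); g.c2b.zeros(net.c2b.n_elem);
  g.c3W.zeros(net.c3W.n_rows, net.c3W.n_cols); g.c3b.zeros(net.c3b.n_elem);
  for (int i = 0; i < 3; ++i) {
    g.bng[i].zeros(net.bng[i].n_elem);
    g.bnb[i].zeros(net.bnb[i].n_elem);
  }
  if (c.hasF2ca()) {
    g.fW1.zeros(net.fW1.n_rows, net.fW1.n_cols); g.fb1.zeros(net.fb1.n_elem);
    g.fW2.zeros(net.fW2.n_rows, net.fW2.n_cols); g.fb2.zeros(net.fb2.n_elem);
  }
  g.denseW.zeros(net.denseW.n_rows, net.denseW.n_cols);
  g.denseb.zeros(net.denseb.n_elem);
  if (c.variant == 1) {
    g.fc2W.zeros(net.fc2W.n_rows, net.fc2W.n_cols); g.fc2b.zeros(net.fc2b.n_elem);
  } else if (c.hasKan()) {
    g.kanWb.zeros(net.kanWb.n_rows, net.kanWb.n_cols);
    g.kanWs.zeros(net.kanWs.n_rows, net.kanWs.n_cols);
    g.kanSc.zeros(net.kanSc.n_rows, net.kanSc.n_cols);
  }
  g.outW.zeros(net.outW.n_rows, net.outW.n_cols); g.outb.zeros(net.outb.n_elem);
}

// ------------------------------------------------------------- entry points

static fmat toBatchF(NumericMatrix X) {
  if (X.nrow() != 48) stop("engine batch must be 48 x N");
  fmat Xf(48, X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < 48; ++i) Xf(i, j) = (float)X(i, j);
  return Xf;
}

// [[Rcpp::export]]
NumericMatrix engine_forward(List params, List cfg, NumericMatrix X) {
  Cfg c = parseCfg(cfg);
  Net net;
  net.load(params, c);
  fmat Xf = toBatchF(X);
  int n = Xf.n_cols;
  Cache cc;
  XRng rng(1);
  forward(net, Xf, false, false, rng, cc);
  NumericMatrix out(n, c.numClasses);
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < c.numClasses; ++k) out(j, k) = cc.P(k, j);
  return out;
}

// [[Rcpp::export]]
List engine_loss_grad(List params, List cfg, NumericMatrix X, IntegerVector y) {
  // training-mode loss (batch-norm on batch statistics) without dropout;
  // used for gradient verification against independent oracles
  Cfg c = parseCfg(cfg);
  Net net;
  net.load(params, c);
  fmat Xf = toBatchF(X);
  int n = Xf.n_cols;
  arma::ivec yv(n);
  for (int j = 0; j < n; ++j) yv[j] = y[j];
  Cache cc;
  XRng rng(1);
  forward(net, Xf, true, false, rng, cc);
  double loss = 0;
  for (int j = 0; j < n; ++j) loss -= std::log(std::max(cc.P(yv[j], j), 1e-12f));
  loss = loss / n + c.l2 * l2Penalty(net);
  Grads g;
  sizeGrads(net, g);
  backward(net, yv, cc, g);
  float l2 = c.l2;
  g.c1W += 2.0f * l2 * net.c1W; g.c2W += 2.0f * l2 * net.c2W;
  g.c3W += 2.0f * l2 * net.c3W; g.denseW += 2.0f * l2 * net.denseW;
  g.outW += 2.0f * l2 * net.outW;
  if (c.variant == 1) g.fc2W += 2.0f * l2 * net.fc2W;
  if (c.hasKan()) { g.kanWb += 2.0f * l2 * net.kanWb; g.kanWs += 2.0f * l2 * net.kanWs; }
  if (c.hasF2ca()) { g.fW1 += 2.0f * l2 * net.fW1; g.fW2 += 2.0f * l2 * net.fW2; }

  Net gnet;                       // reuse dump() by viewing grads as a net
  gnet.cfg = c;
  gnet.c1W = g.c1W; gnet.c1b = g.c1b; gnet.c2W = g.c2W; gnet.c2b = g.c2b;
  gnet.c3W = g.c3W; gnet.c3b = g.c3b;
  for (int i = 0; i < 3; ++i) {
    gnet.bng[i] = g.bng[i]; gnet.bnb[i] = g.bnb[i];
    gnet.bnm[i] = fvec(net.bnm[i].n_elem, arma::fill::zeros);
    gnet.bnv[i] = fvec(net.bnv[i].n_elem, arma::fill::zeros);
  }
  if (c.hasF2ca()) {
    gnet.fW1 = g.fW1; gnet.fb1 = g.fb1; gnet.fW2 = g.fW2; gnet.fb2 = g.fb2;
  }
  gnet.denseW = g.denseW; gnet.denseb = g.denseb;
  if (c.variant == 1) { gnet.fc2W = g.fc2W; gnet.fc2b = g.fc2b; }
  else if (c.hasKan()) { gnet.kanWb = g.kanWb; gnet.kanWs = g.kanWs; gnet.kanSc = g.kanSc; }
  gnet.outW = g.outW; gnet.outb = g.outb;
  return List::create(_["loss"] = loss, _["grads"] = gnet.dump());
}

// [[Rcpp::export]]
List engine_train(List params, List cfg, NumericMatrix X, IntegerVector y,
                  List tcfg, Nullable<NumericMatrix> valX = R_NilValue,
                  Nullable<IntegerVector> valY = R_NilValue) {
  Cfg c = parseCfg(cfg);
  Net net;
  net.load(params, c);
  fmat Xf = toBatchF(X);
  int n = Xf.n_cols;
  if ((int)y.size() != n) stop("label length does not match batch");
  arma::ivec yv(n);
  for (int j = 0; j < n; ++j) {
    if (y[j] < 0 || y[j] >= c.numClasses) stop("label out of range");
    yv[j] = y[j];
  }

  double lr = as<double>(tcfg["lr"]);
  int batchSize = as<int>(tcfg["batchSize"]);
  int epochs = as<int>(tcfg["epochs"]);
  uint64_t seed = (uint64_t)as<double>(tcfg["seed"]);
  XRng rng(seed * 6364136223846793005ULL + 1442695040888963407ULL);

  bool hasVal = valX.isNotNull();
  fmat Xv;
  arma::ivec yvv;
  if (hasVal) {
    NumericMatrix vx(valX);
    IntegerVector vy(valY);
    Xv = toBatchF(vx);
    yvv.set_size(vy.size());
    for (int j = 0; j < (int)vy.size(); ++j) yvv[j] = vy[j];
  }

  Grads g;
  sizeGrads(net, g);
  Adam ad;
  registerParams(net, g, ad);

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  NumericVector hLoss(epochs), hAcc(epochs);
  NumericVector hValLoss(epochs, NA_REAL), hValAcc(epochs, NA_REAL);

  Cache cc;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n - 1; i > 0; --i) std::swap(idx[i], idx[rng.below(i + 1)]);
    double epLoss = 0;
    long correct = 0;
    for (int start = 0; start < n; start += batchSize) {
      int nb = std::min(batchSize, n - start);
      fmat Xb(48, nb);
      arma::ivec yb(nb);
      for (int j = 0; j < nb; ++j) {
        std::memcpy(Xb.colptr(j), Xf.colptr(idx[start + j]), 48 * sizeof(float));
        yb[j] = yv[idx[start + j]];
      }
      forward(net, Xb, true, true, rng, cc);
      for (int j = 0; j < nb; ++j) {
        epLoss -= std::log(std::max(cc.P(yb[j], j), 1e-12f));
        arma::uword am;
        cc.P.col(j).max(am);
        if ((int)am == yb[j]) ++correct;
      }
      backward(net, yb, cc, g);
      ad.step((float)lr, c.l2);
    }
    epLoss = epLoss / n + c.l2 * l2Penalty(net);
    if (!std::isfinite(epLoss))
      stop("training divergence: non-finite loss at epoch %d (lr=%g)", ep + 1, lr);
    hLoss[ep] = epLoss;
    hAcc[ep] = (double)correct / n;
    if (hasVal) {
      Cache cv;
      forward(net, Xv, false, false, rng, cv);
      double vl = 0;
      long vc = 0;
      for (int j = 0; j < (int)Xv.n_cols; ++j) {
        vl -= std::log(std::max(cv.P(yvv[j], j), 1e-12f));
        arma::uword am;
        cv.P.col(j).max(am);
        if ((int)am == yvv[j]) ++vc;
      }
      hValLoss[ep] = vl / Xv.n_cols;
      hValAcc[ep] = (double)vc / Xv.n_cols;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["params"] = net.dump(),
    _["history"] = List::create(
      _["loss"] = hLoss, _["accuracy"] = hAcc,
      _["valLoss"] = hValLoss, _["valAccuracy"] = hValAcc));
}
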