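// Small convolutional survival-risk network and convolutional auto-encoder.
//
// Architecture (risk net): conv 3x3/32 'same' + ReLU -> maxpool 2x2 ->
// conv 3x3/32 'same' + ReLU -> maxpool 2x2 -> FC 32 + ReLU -> FC 1 linear.
// Trained by SGD on the negative batch Cox partial likelihood (Breslow
// ties, batch-restricted risk sets, normalized by the number of events in
// the batch). The CAE decoder mirrors the encoder with nearest-neighbor
// x2 upsampling and a linear 3-channel reconstruction head (MSE loss).
//
// All arithmetic is float32 (im2col + BLAS sgemm); every source of
// randomness (weight init, epoch shuffles) is drawn in R and passed in, so
// results are reproducible from the R seed alone. Activations are stored
// as (B*S*S) x C matrices with row index b*S*S + r + c*S; buffers are
// reused across batches to keep the SGD loop allocation-free.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

typedef Mat<arma::u32> u32mat;

static fmat getW(const Rcpp::List& p, const char* nm) {
  Rcpp::NumericMatrix m = p[nm];
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}
static frowvec getB(const Rcpp::List& p, const char* nm) {
  Rcpp::NumericVector v = p[nm];
  frowvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out(i) = (float)v[i];
  return out;
}
static Rcpp::NumericMatrix putW(const fmat& m) {
  Rcpp::NumericMatrix out(m.n_rows, m.n_cols);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) out(i, j) = m(i, j);
  return out;
}
static Rcpp::NumericVector putB(const frowvec& v) {
  Rcpp::NumericVector out(v.n_elem);
  for (uword i = 0; i < v.n_elem; ++i) out[i] = v(i);
  return out;
}

static inline void reluInplace(fmat& A) {
  float* p = A.memptr();
  const size_t n = A.n_elem;
  for (size_t i = 0; i < n; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
}
// zero the entries of dA where the (post-ReLU) activation A is 0
static inline void reluMask(fmat& dA, const fmat& A) {
  float* d = dA.memptr();
  const float* a = A.memptr();
  const size_t n = dA.n_elem;
  for (size_t i = 0; i < n; ++i) if (a[i] <= 0.0f) d[i] = 0.0f;
}

// 3x3 'same' patch matrix: (B*S*S) x (9*Cin); column ch*9 + (dc+1)*3 + (dr+1)
static void im2col(const fmat& A, int B, int S, fmat& out) {
  const int Cin = A.n_cols;
  if (out.n_rows != A.n_rows || out.n_cols != (uword)(9 * Cin))
    out.zeros(A.n_rows, 9 * Cin);
  for (int ch = 0; ch < Cin; ++ch)
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        const int k = ch * 9 + (dc + 1) * 3 + (dr + 1);
        const int clo = std::max(0, -dc), chi = std::min(S, S - dc);
        if (dr == 0) {
          // whole column band is contiguous in source and destination
          for (int b = 0; b < B; ++b)
            std::memcpy(out.colptr(k) + (size_t)b * S * S + (size_t)clo * S,
                        A.colptr(ch) + (size_t)b * S * S + (size_t)(clo + dc) * S,
                        (size_t)(chi - clo) * S * sizeof(float));
        } else {
          const int rlo = std::max(0, -dr), rhi = std::min(S, S - dr);
          for (int b = 0; b < B; ++b)
            for (int c = clo; c < chi; ++c)
              std::memcpy(out.colptr(k) + (size_t)b * S * S + (size_t)c * S + rlo,
                          A.colptr(ch) + (size_t)b * S * S + (size_t)(c + dc) * S + rlo + dr,
                          (rhi - rlo) * sizeof(float));
        }
      }
}

// transpose of im2col: scatter-add column gradients back onto the input grid
static void col2im(const fmat& dCol, int B, int S, int Cin, fmat& dA) {
  dA.zeros((size_t)B * S * S, Cin);
  for (int ch = 0; ch < Cin; ++ch)
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        const int k = ch * 9 + (dc + 1) * 3 + (dr + 1);
        for (int b = 0; b < B; ++b)
          for (int c = 0; c < S; ++c) {
            const int cs = c + dc;
            if (cs < 0 || cs >= S) continue;
            const int rlo = std::max(0, -dr), rhi = std::min(S, S - dr);
            if (rhi <= rlo) continue;
            float* dst = dA.colptr(ch) + (size_t)b * S * S + (size_t)cs * S + rlo + dr;
            const float* src = dCol.colptr(k) + (size_t)b * S * S + (size_t)c * S + rlo;
            for (int i = 0; i < rhi - rlo; ++i) dst[i] += src[i];
          }
      }
}

static void maxpool(const fmat& A, int B, int S, fmat& out, u32mat& arg) {
  const int S2 = S / 2, K = A.n_cols;
  out.set_size((size_t)B * S2 * S2, K);
  arg.set_size((size_t)B * S2 * S2, K);
  for (int k = 0; k < K; ++k) {
    const float* a = A.colptr(k);
    float* o = out.colptr(k);
    arma::u32* g = arg.colptr(k);
    for (int b = 0; b < B; ++b) {
      const size_t base = (size_t)b * S * S;
      const size_t obase = (size_t)b * S2 * S2;
      for (int c2 = 0; c2 < S2; ++c2) {
        const float* col0 = a + base + (size_t)(2 * c2) * S;
        const float* col1 = col0 + S;
        float* oc = o + obase + (size_t)c2 * S2;
        arma::u32* gc = g + obase + (size_t)c2 * S2;
        for (int r2 = 0; r2 < S2; ++r2) {
          const int r = 2 * r2;
          float bv = col0[r];
          arma::u32 bi = (arma::u32)(base + r + (size_t)(2 * c2) * S);
          if (col0[r + 1] > bv) { bv = col0[r + 1]; bi = (arma::u32)(base + r + 1 + (size_t)(2 * c2) * S); }
          if (col1[r] > bv) { bv = col1[r]; bi = (arma::u32)(base + r + (size_t)(2 * c2 + 1) * S); }
          if (col1[r + 1] > bv) { bv = col1[r + 1]; bi = (arma::u32)(base + r + 1 + (size_t)(2 * c2 + 1) * S); }
          oc[r2] = bv;
          gc[r2] = bi;
        }
      }
    }
  }
}

static void unpool(const fmat& dOut, const u32mat& arg, size_t rowsA, fmat& dA) {
  dA.zeros(rowsA, dOut.n_cols);
  for (uword k = 0; k < dOut.n_cols; ++k) {
    const float* d = dOut.colptr(k);
    const arma::u32* g = arg.colptr(k);
    float* o = dA.colptr(k);
    for (uword i = 0; i < dOut.n_rows; ++i) o[g[i]] += d[i];
  }
}

// nearest-neighbor x2 upsample (S2 -> 2*S2)
static void upsample2(const fmat& A, int B, int S2, fmat& out) {
  const int S = 2 * S2, K = A.n_cols;
  out.set_size((size_t)B * S * S, K);
  for (int k = 0; k < K; ++k) {
    const float* a = A.colptr(k);
    float* o = out.colptr(k);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < S; ++c) {
        const float* ac = a + (size_t)b * S2 * S2 + (size_t)(c / 2) * S2;
        float* oc = o + (size_t)b * S * S + (size_t)c * S;
        for (int r = 0; r < S; ++r) oc[r] = ac[r / 2];
      }
  }
}

// backward of upsample2: sum each 2x2 block (S -> S/2)
static void downsum2(const fmat& dOut, int B, int S, fmat& dA) {
  const int S2 = S / 2, K = dOut.n_cols;
  dA.zeros((size_t)B * S2 * S2, K);
  for (int k = 0; k < K; ++k) {
    const float* d = dOut.colptr(k);
    float* o = dA.colptr(k);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < S; ++c) {
        const float* dc = d + (size_t)b * S * S + (size_t)c * S;
        float* oc = o + (size_t)b * S2 * S2 + (size_t)(c / 2) * S2;
        for (int r = 0; r < S; ++r) oc[r / 2] += dc[r];
      }
  }
}

// copy images idx (0-based) out of the R array (S,S,3,N) into (B*S*S) x 3
static void gatherBatch(const double* x, int S, const std::vector<int>& idx, fmat& out) {
  const int B = idx.size();
  const size_t px = (size_t)S * S;
  out.set_size(px * B, 3);
  for (int ch = 0; ch < 3; ++ch) {
    float* o = out.colptr(ch);
    for (int b = 0; b < B; ++b) {
      const double* src = x + px * (ch + 3 * (size_t)idx[b]);
      float* dst = o + (size_t)b * px;
      for (size_t i = 0; i < px; ++i) dst[i] = (float)src[i];
    }
  }
}

struct Net {
  fmat W1, W2, W3, W4;
  frowvec b1, b2, b3, b4;
};
static Net loadNet(const Rcpp::List& p) {
  Net n;
  n.W1 = getW(p, "W1"); n.b1 = getB(p, "b1");
  n.W2 = getW(p, "W2"); n.b2 = getB(p, "b2");
  n.W3 = getW(p, "W3"); n.b3 = getB(p, "b3");
  n.W4 = getW(p, "W4"); n.b4 = getB(p, "b4");
  return n;
}
static Rcpp::List dumpNet(const Net& n) {
  return Rcpp::List::create(
    Rcpp::Named("W1") = putW(n.W1), Rcpp::Named("b1") = putB(n.b1),
    Rcpp::Named("W2") = putW(n.W2), Rcpp::Named("b2") = putB(n.b2),
    Rcpp::Named("W3") = putW(n.W3), Rcpp::Named("b3") = putB(n.b3),
    Rcpp::Named("W4") = putW(n.W4), Rcpp::Named("b4") = putB(n.b4));
}

// forward/backward workspace, reused across batches
struct Cache {
  fmat X0, col1, a1, p1, col2, a2, p2, flatT, z1t;
  u32mat arg1, arg2;
  fmat dZ1t, dFlatT, dP2, dA2, dCol2, dP1, dA1;
};

// encoder trunk + FC head; returns eta (length B). flatT is F x B with
// flatT(k*f + p, b) = p2(b*f + p, k), f = (S/4)^2 (contiguous copies).
static fvec netForward(const Net& net, int B, int S, Cache& C) {
  const int S2 = S / 2, S4 = S / 4, K = net.W1.n_cols;
  im2col(C.X0, B, S, C.col1);
  C.a1 = C.col1 * net.W1;
  maxpool(C.a1, B, S, C.p1, C.arg1);   // bias/ReLU commute with max pooling
  C.p1.each_row() += net.b1;
  reluInplace(C.p1);
  im2col(C.p1, B, S2, C.col2);
  C.a2 = C.col2 * net.W2;
  maxpool(C.a2, B, S2, C.p2, C.arg2);
  C.p2.each_row() += net.b2;
  reluInplace(C.p2);
  const size_t f = (size_t)S4 * S4;
  C.flatT.set_size(f * K, B);
  for (int b = 0; b < B; ++b) {
    float* dst = C.flatT.colptr(b);
    for (int k = 0; k < K; ++k)
      std::memcpy(dst + (size_t)k * f, C.p2.colptr(k) + (size_t)b * f,
                  f * sizeof(float));
  }
  C.z1t = net.W3.t() * C.flatT;             // H x B
  C.z1t.each_col() += net.b3.t();
  reluInplace(C.z1t);
  fvec eta = (net.W4.col(0).t() * C.z1t).t();
  eta += net.b4(0);
  return eta;
}

// backprop from d(loss)/d(eta); writes gradients into g
static void netBackward(const Net& net, Cache& C, const fvec& dEta,
                        int B, int S, Net& g) {
  const int S2 = S / 2, S4 = S / 4, K = net.W1.n_cols;
  g.W4 = C.z1t * dEta;                       // H x 1
  g.b4 = frowvec(1);
  g.b4(0) = accu(dEta);
  C.dZ1t = net.W4.col(0) * dEta.t();         // H x B
  reluMask(C.dZ1t, C.z1t);
  g.W3 = C.flatT * C.dZ1t.t();               // F x H
  g.b3 = sum(C.dZ1t, 1).t();
  C.dFlatT = net.W3 * C.dZ1t;                // F x B
  const size_t f = (size_t)S4 * S4;
  C.dP2.set_size((size_t)B * f, K);
  for (int b = 0; b < B; ++b) {
    const float* src = C.dFlatT.colptr(b);
    for (int k = 0; k < K; ++k)
      std::memcpy(C.dP2.colptr(k) + (size_t)b * f, src + (size_t)k * f,
                  f * sizeof(float));
  }
  reluMask(C.dP2, C.p2);
  g.b2 = sum(C.dP2, 0);
  unpool(C.dP2, C.arg2, C.a2.n_rows, C.dA2);
  g.W2 = C.col2.t() * C.dA2;
  C.dCol2 = C.dA2 * net.W2.t();
  col2im(C.dCol2, B, S2, K, C.dP1);
  reluMask(C.dP1, C.p1);
  g.b1 = sum(C.dP1, 0);
  unpool(C.dP1, C.arg1, C.a1.n_rows, C.dA1);
  g.W1 = C.col1.t() * C.dA1;
}

// negative batch Cox partial log-likelihood (Breslow, batch risk sets,
// normalized by event count) and its gradient wrt eta; returns false when
// the batch holds no event (caller skips the step)
static bool coxBatch(const fvec& etaF, const std::vector<double>& tm,
                     const std::vector<int>& ev, double& loss, fvec& dEta) {
  const int B = etaF.n_elem;
  int D = 0;
  for (int i = 0; i < B; ++i) D += ev[i];
  if (D == 0) return false;
  std::vector<double> eta(B);
  double m = -1e300;
  for (int i = 0; i < B; ++i) { eta[i] = etaF(i); m = std::max(m, eta[i]); }
  std::vector<double> g(B, 0.0);
  double ll = 0.0;
  for (int i = 0; i < B; ++i) {
    if (!ev[i]) continue;
    double s = 0.0;
    for (int j = 0; j < B; ++j) if (tm[j] >= tm[i]) s += std::exp(eta[j] - m);
    ll += eta[i] - (m + std::log(s));
    for (int j = 0; j < B; ++j)
      if (tm[j] >= tm[i]) g[j] -= std::exp(eta[j] - m) / s;
    g[i] += 1.0;
  }
  loss = -ll / D;
  dEta.set_size(B);
  for (int i = 0; i < B; ++i) dEta(i) = (float)(-g[i] / D);
  return true;
}

// [[Rcpp::export]]
Rcpp::NumericVector rnForwardCpp(Rcpp::List params, Rcpp::NumericVector x,
                                 Rcpp::IntegerVector dims) {
  const int S = dims[0], N = dims[3];
  Net net = loadNet(params);
  Rcpp::NumericVector out(N);
  Cache C;
  const int chunk = 64;
  for (int s0 = 0; s0 < N; s0 += chunk) {
    std::vector<int> idx;
    for (int i = s0; i < std::min(N, s0 + chunk); ++i) idx.push_back(i);
    gatherBatch(x.begin(), S, idx, C.X0);
    fvec eta = netForward(net, idx.size(), S, C);
    for (size_t i = 0; i < idx.size(); ++i) out[idx[i]] = eta(i);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix rnPenultimateCpp(Rcpp::List params, Rcpp::NumericVector x,
                                     Rcpp::IntegerVector dims) {
  const int S = dims[0], N = dims[3];
  Net net = loadNet(params);
  Rcpp::NumericMatrix out(N, net.W3.n_cols);
  Cache C;
  const int chunk = 64;
  for (int s0 = 0; s0 < N; s0 += chunk) {
    std::vector<int> idx;
    for (int i = s0; i < std::min(N, s0 + chunk); ++i) idx.push_back(i);
    gatherBatch(x.begin(), S, idx, C.X0);
    netForward(net, idx.size(), S, C);
    for (size_t i = 0; i < idx.size(); ++i)
      for (uword k = 0; k < net.W3.n_cols; ++k) out(idx[i], k) = C.z1t(k, i);
  }
  return out;
}

static void sgdStep(Net& net, const Net& g, float lr) {
  net.W1 -= lr * g.W1; net.b1 -= lr * g.b1;
  net.W2 -= lr * g.W2; net.b2 -= lr * g.b2;
  net.W3 -= lr * g.W3; net.b3 -= lr * g.b3;
  net.W4 -= lr * g.W4; net.b4 -= lr * g.b4;
}

// [[Rcpp::export]]
Rcpp::List rnTrainCpp(Rcpp::List params, Rcpp::NumericVector x,
                      Rcpp::IntegerVector dims, Rcpp::NumericVector time,
                      Rcpp::IntegerVector event, Rcpp::IntegerMatrix perms,
                      int batchSize, double lr) {
  const int S = dims[0], N = dims[3], epochs = perms.nrow();
  Net net = loadNet(params), g;
  Cache C;
  Rcpp::NumericVector epochLoss(epochs);
  for (int e = 0; e < epochs; ++e) {
    double tot = 0.0;
    int nb = 0;
    for (int s0 = 0; s0 < N; s0 += batchSize) {
      const int s1 = std::min(N, s0 + batchSize);
      if (s1 - s0 < 2) continue;
      std::vector<int> idx;
      std::vector<double> tm;
      std::vector<int> ev;
      for (int i = s0; i < s1; ++i) {
        const int id = perms(e, i) - 1;
        idx.push_back(id);
        tm.push_back(time[id]);
        ev.push_back(event[id]);
      }
      gatherBatch(x.begin(), S, idx, C.X0);
      fvec eta = netForward(net, idx.size(), S, C);
      double loss;
      fvec dEta;
      if (!coxBatch(eta, tm, ev, loss, dEta)) continue;  // event-free: skip
      netBackward(net, C, dEta, idx.size(), S, g);
      sgdStep(net, g, (float)lr);
      tot += loss;
      ++nb;
    }
    epochLoss[e] = nb ? tot / nb : NA_REAL;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = dumpNet(net),
                            Rcpp::Named("epochLoss") = epochLoss);
}

struct Dec {
  fmat W5, W6, W7;
  frowvec b5, b6, b7;
};
static Dec loadDec(const Rcpp::List& p) {
  Dec d;
  d.W5 = getW(p, "W5"); d.b5 = getB(p, "b5");
  d.W6 = getW(p, "W6"); d.b6 = getB(p, "b6");
  d.W7 = getW(p, "W7"); d.b7 = getB(p, "b7");
  return d;
}
static Rcpp::List dumpDec(const Dec& d) {
  return Rcpp::List::create(
    Rcpp::Named("W5") = putW(d.W5), Rcpp::Named("b5") = putB(d.b5),
    Rcpp::Named("W6") = putW(d.W6), Rcpp::Named("b6") = putB(d.b6),
    Rcpp::Named("W7") = putW(d.W7), Rcpp::Named("b7") = putB(d.b7));
}

struct CaeCache {
  fmat up1, col5, d1, up2, col6, d2, col7, recon;
  fmat dRecon, dCol, dD2, dUp2, dD1, dUp1, dP2, dA2, dP1, dA1;
};

// decoder forward from the encoder's pooled features p2 (B*S4*S4 x K)
static double caeForward(const Dec& dec, Cache& C, int B, int S, CaeCache& D) {
  const int S2 = S / 2, S4 = S / 4;
  upsample2(C.p2, B, S4, D.up1);
  im2col(D.up1, B, S2, D.col5);
  D.d1 = D.col5 * dec.W5;
  D.d1.each_row() += dec.b5;
  reluInplace(D.d1);
  upsample2(D.d1, B, S2, D.up2);
  im2col(D.up2, B, S, D.col6);
  D.d2 = D.col6 * dec.W6;
  D.d2.each_row() += dec.b6;
  reluInplace(D.d2);
  im2col(D.d2, B, S, D.col7);
  D.recon = D.col7 * dec.W7;
  D.recon.each_row() += dec.b7;
  double tot = 0.0;
  const float* r = D.recon.memptr();
  const float* x0 = C.X0.memptr();
  for (size_t i = 0; i < D.recon.n_elem; ++i) {
    const double d = (double)r[i] - (double)x0[i];
    tot += d * d;
  }
  return tot / D.recon.n_elem;
}

// [[Rcpp::export]]
double caeLossCpp(Rcpp::List enc, Rcpp::List dec, Rcpp::NumericVector x,
                  Rcpp::IntegerVector dims) {
  const int S = dims[0], N = dims[3];
  Net net = loadNet(enc);
  Dec de = loadDec(dec);
  Cache C;
  CaeCache D;
  double tot = 0.0;
  const int chunk = 32;
  long cnt = 0;
  for (int s0 = 0; s0 < N; s0 += chunk) {
    std::vector<int> idx;
    for (int i = s0; i < std::min(N, s0 + chunk); ++i) idx.push_back(i);
    gatherBatch(x.begin(), S, idx, C.X0);
    netForward(net, idx.size(), S, C);
    tot += caeForward(de, C, idx.size(), S, D) * idx.size();
    cnt += idx.size();
  }
  return tot / cnt;
}

// [[Rcpp::export]]
Rcpp::List caeTrainCpp(Rcpp::List enc, Rcpp::List dec, Rcpp::NumericVector x,
                       Rcpp::IntegerVector dims, Rcpp::IntegerMatrix perms,
                       int batchSize, double lr) {
  const int S = dims[0], N = dims[3], epochs = perms.nrow();
  const int S2 = S / 2;
  Net net = loadNet(enc), g;
  Dec de = loadDec(dec), gd;
  Cache C;
  CaeCache D;
  Rcpp::NumericVector epochLoss(epochs);
  for (int e = 0; e < epochs; ++e) {
    double tot = 0.0;
    int nb = 0;
    for (int s0 = 0; s0 < N; s0 += batchSize) {
      const int s1 = std::min(N, s0 + batchSize);
      std::vector<int> idx;
      for (int i = s0; i < s1; ++i) idx.push_back(perms(e, i) - 1);
      const int B = idx.size();
      gatherBatch(x.begin(), S, idx, C.X0);
      netForward(net, B, S, C);
      const double loss = caeForward(de, C, B, S, D);
      // MSE head backward
      D.dRecon = D.recon - C.X0;
      D.dRecon *= 2.0f / (float)D.recon.n_elem;
      gd.W7 = D.col7.t() * D.dRecon;
      gd.b7 = sum(D.dRecon, 0);
      // de.W7 maps 9*K -> 3; its input grid has K = de.W6.n_cols channels
      D.dCol = D.dRecon * de.W7.t();
      col2im(D.dCol, B, S, (int)de.W6.n_cols, D.dD2);
      reluMask(D.dD2, D.d2);
      gd.W6 = D.col6.t() * D.dD2;
      gd.b6 = sum(D.dD2, 0);
      D.dCol = D.dD2 * de.W6.t();
      col2im(D.dCol, B, S, (int)de.W5.n_cols, D.dUp2);
      downsum2(D.dUp2, B, S, D.dD1);
      reluMask(D.dD1, D.d1);
      gd.W5 = D.col5.t() * D.dD1;
      gd.b5 = sum(D.dD1, 0);
      D.dCol = D.dD1 * de.W5.t();
      col2im(D.dCol, B, S2, (int)net.W2.n_cols, D.dUp1);
      downsum2(D.dUp1, B, S2, D.dP2);
      // encoder backward from dP2 (bias/ReLU live after the pools)
      reluMask(D.dP2, C.p2);
      g.b2 = sum(D.dP2, 0);
      unpool(D.dP2, C.arg2, C.a2.n_rows, D.dA2);
      g.W2 = C.col2.t() * D.dA2;
      D.dCol = D.dA2 * net.W2.t();
      col2im(D.dCol, B, S2, (int)net.W2.n_cols, D.dP1);
      reluMask(D.dP1, C.p1);
      g.b1 = sum(D.dP1, 0);
      unpool(D.dP1, C.arg1, C.a1.n_rows, D.dA1);
      g.W1 = C.col1.t() * D.dA1;
      const float flr = (float)lr;
      net.W1 -= flr * g.W1; net.b1 -= flr * g.b1;
      net.W2 -= flr * g.W2; net.b2 -= flr * g.b2;
      de.W5 -= flr * gd.W5; de.b5 -= flr * gd.b5;
      de.W6 -= flr * gd.W6; de.b6 -= flr * gd.b6;
      de.W7 -= flr * gd.W7; de.b7 -= flr * gd.b7;
      tot += loss;
      ++nb;
    }
    epochLoss[e] = nb ? tot / nb : NA_REAL;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("enc") = dumpNet(net),
                            Rcpp::Named("dec") = dumpDec(de),
                            Rcpp::Named("epochLoss") = epochLoss);
}
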