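// Multi-task CNN-LSTM surrogate network.
//
// Image branch: 3x3 conv (3->32, ReLU, same padding) -> 2x2 maxpool ->
// 3x3 conv (32->64, ReLU) -> 2x2 maxpool -> 1x1 projection (64->8) ->
// flatten to 2048. Sequence branch: LSTM 128->256 (sequence output) ->
// LSTM 256->128 with attention pooling over the 50 hidden states.
// Fusion 2048+128 = 2176 -> FC 512 (ReLU) -> 8 linear task heads.
// Trained with weighted multi-task MSE + L2, Adam (beta1 = momentum arg),
// global-norm gradient clipping; all mutable state lives behind an XPtr.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int IMG = 64, CH_IN = 3, C1 = 32, C2 = 64, CP = 8;
static const int T_SEQ = 50, D_SEQ = 128, H1 = 256, H2 = 128;
static const int CNN_DIM = 16 * 16 * CP;          // 2048
static const int FUSE = CNN_DIM + H2;             // 2176
static const int FC1 = 512, OUT = 8;

struct Param {
  mat w, m, v;  // weight and Adam moment buffers
  explicit Param(int r = 0, int c = 0) : w(r, c, fill::zeros),
                                         m(r, c, fill::zeros),
                                         v(r, c, fill::zeros) {}
};

struct Net {
  Param Wc1, bc1, Wc2, bc2, Wp, bp;
  Param Wi1, Ui1, b1l, Wi2, Ui2, b2l;
  Param attn_u;
  Param W1, b1, W2, b2;
  std::mt19937 rng;
  long step = 0;

  std::vector<Param*> params() {
    return {&Wc1, &bc1, &Wc2, &bc2, &Wp, &bp, &Wi1, &Ui1, &b1l,
            &Wi2, &Ui2, &b2l, &attn_u, &W1, &b1, &W2, &b2};
  }

  void init_mat(Param& p, int r, int c, double fan_in) {
    p.w.set_size(r, c);
    p.m.zeros(r, c);
    p.v.zeros(r, c);
    double s = std::sqrt(1.0 / fan_in);
    std::uniform_real_distribution<double> U(-s, s);
    for (uword i = 0; i < p.w.n_elem; ++i) p.w(i) = U(rng);
  }

  explicit Net(unsigned int seed) : rng(seed) {
    init_mat(Wc1, C1, 9 * CH_IN, 9 * CH_IN);
    init_mat(bc1, C1, 1, 9 * CH_IN);
    init_mat(Wc2, C2, 9 * C1, 9 * C1);
    init_mat(bc2, C2, 1, 9 * C1);
    init_mat(Wp, CP, C2, C2);
    init_mat(bp, CP, 1, C2);
    init_mat(Wi1, 4 * H1, D_SEQ, D_SEQ + H1);
    init_mat(Ui1, 4 * H1, H1, D_SEQ + H1);
    init_mat(b1l, 4 * H1, 1, D_SEQ + H1);
    init_mat(Wi2, 4 * H2, H1, H1 + H2);
    init_mat(Ui2, 4 * H2, H2, H1 + H2);
    init_mat(b2l, 4 * H2, 1, H1 + H2);
    init_mat(attn_u, H2, 1, H2);
    init_mat(W1, FC1, FUSE, FUSE);
    init_mat(b1, FC1, 1, FUSE);
    init_mat(W2, OUT, FC1, FC1);
    init_mat(b2, OUT, 1, FC1);
    // forget-gate bias 1 for stable early training
    b1l.w.rows(H1, 2 * H1 - 1).fill(1.0);
    b2l.w.rows(H2, 2 * H2 - 1).fill(1.0);
  }
};

// ---- helpers --------------------------------------------------------------

// im2col for 3x3 same-padding conv on a (cin, side*side) channel-major
// image block of n samples: out is (9*cin, side*side*n).
static void im2col3(const mat& X, int cin, int side, int n, mat& col) {
  col.zeros(9 * cin, side * side * n);
  for (int s = 0; s < n; ++s) {
    int base = s * side * side;
    for (int x = 0; x < side; ++x) {
      for (int y = 0; y < side; ++y) {
        int p = base + x * side + y;
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= side) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= side) continue;
            int q = base + xx * side + yy;
            int krow = (dx + 1) * 3 + (dy + 1);
            for (int c = 0; c < cin; ++c) {
              col(c * 9 + krow, p) = X(c, q);
            }
          }
        }
      }
    }
  }
}

// col2im: scatter-add the gradient of col back to the image layout.
static void col2im3(const mat& dcol, int cin, int side, int n, mat& dX) {
  dX.zeros(cin, side * side * n);
  for (int s = 0; s < n; ++s) {
    int base = s * side * side;
    for (int x = 0; x < side; ++x) {
      for (int y = 0; y < side; ++y) {
        int p = base + x * side + y;
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= side) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= side) continue;
            int q = base + xx * side + yy;
            int krow = (dx + 1) * 3 + (dy + 1);
            for (int c = 0; c < cin; ++c) {
              dX(c, q) += dcol(c * 9 + krow, p);
            }
          }
        }
      }
    }
  }
}

// 2x2 max pooling, (c, side*side*n) -> (c, (side/2)^2*n); argmax kept.
static void maxpool2(const mat& X, int cch, int side, int n, mat& Y,
                     umat& arg) {
  int half = side / 2;
  Y.set_size(cch, half * half * n);
  arg.set_size(cch, half * half * n);
  for (int s = 0; s < n; ++s) {
    int bi = s * side * side, bo = s * half * half;
    for (int x = 0; x < half; ++x) {
      for (int y = 0; y < half; ++y) {
        int po = bo + x * half + y;
        int cand[4] = {bi + (2 * x) * side + 2 * y,
                       bi + (2 * x) * side + 2 * y + 1,
                       bi + (2 * x + 1) * side + 2 * y,
                       bi + (2 * x + 1) * side + 2 * y + 1};
        for (int c = 0; c < cch; ++c) {
          double best = X(c, cand[0]);
          int bestq = cand[0];
          for (int k = 1; k < 4; ++k) {
            if (X(c, cand[k]) > best) { best = X(c, cand[k]); bestq = cand[k]; }
          }
          Y(c, po) = best;
          arg(c, po) = bestq;
        }
      }
    }
  }
}

static void unpool2(const mat& dY, const umat& arg, int cch, int side, int n,
                    mat& dX) {
  dX.zeros(cch, side * side * n);
  for (uword j = 0; j < dY.n_cols; ++j) {
    for (int c = 0; c < cch; ++c) {
      dX(c, arg(c, j)) += dY(c, j);
    }
  }
}

static mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmCache {
  std::vector<mat> i, f, g, o, c, h, tc;  // per-timestep activations
  mat h0, c0;
};

// LSTM forward over T steps. X[t] are (din, n) inputs.
static void lstm_forward(const Param& Wi, const Param& Ui, const Param& b,
                         const std::vector<mat>& X, int hid, int n,
                         LstmCache& cc) {
  int T = (int)X.size();
  cc.i.resize(T); cc.f.resize(T); cc.g.resize(T); cc.o.resize(T);
  cc.c.resize(T); cc.h.resize(T); cc.tc.resize(T);
  cc.h0.zeros(hid, n); cc.c0.zeros(hid, n);
  mat h = cc.h0, c = cc.c0;
  for (int t = 0; t < T; ++t) {
    mat G = Wi.w * X[t] + Ui.w * h;
    G.each_col() += b.w.col(0);
    cc.i[t] = sigm(G.rows(0, hid - 1));
    cc.f[t] = sigm(G.rows(hid, 2 * hid - 1));
    cc.g[t] = tanh(G.rows(2 * hid, 3 * hid - 1));
    cc.o[t] = sigm(G.rows(3 * hid, 4 * hid - 1));
    c = cc.f[t] % c + cc.i[t] % cc.g[t];
    cc.c[t] = c;
    cc.tc[t] = tanh(c);
    h = cc.o[t] % cc.tc[t];
    cc.h[t] = h;
  }
}

// LSTM backward; dH[t] is the gradient flowing into h_t from above.
// Accumulates parameter grads, returns input grads in dX (optional).
static void lstm_backward(const Param& Wi, const Param& Ui,
                          const std::vector<mat>& X, const LstmCache& cc,
                          std::vector<mat>& dH, int hid, int n,
                          mat& dWi, mat& dUi, mat& db,
                          std::vector<mat>* dX) {
  int T = (int)X.size();
  dWi.zeros(Wi.w.n_rows, Wi.w.n_cols);
  dUi.zeros(Ui.w.n_rows, Ui.w.n_cols);
  db.zeros(4 * hid, 1);
  mat dh_next(hid, n, fill::zeros), dc_next(hid, n, fill::zeros);
  if (dX) dX->resize(T);
  for (int t = T - 1; t >= 0; --t) {
    mat dh = dH[t] + dh_next;
    const mat& tc = cc.tc[t];
    mat do_ = dh % tc;
    mat dc = dc_next + dh % cc.o[t] % (1.0 - tc % tc);
    const mat& c_prev = (t == 0) ? cc.c0 : cc.c[t - 1];
    const mat& h_prev = (t == 0) ? cc.h0 : cc.h[t - 1];
    mat di = dc % cc.g[t];
    mat df = dc % c_prev;
    mat dg = dc % cc.i[t];
    dc_next = dc % cc.f[t];
    mat dz(4 * hid, n);
    dz.rows(0, hid - 1) = di % cc.i[t] % (1.0 - cc.i[t]);
    dz.rows(hid, 2 * hid - 1) = df % cc.f[t] % (1.0 - cc.f[t]);
    dz.rows(2 * hid, 3 * hid - 1) = dg % (1.0 - cc.g[t] % cc.g[t]);
    dz.rows(3 * hid, 4 * hid - 1) = do_ % cc.o[t] % (1.0 - cc.o[t]);
    dWi += dz * X[t].t();
    dUi += dz * h_prev.t();
    db += sum(dz, 1);
    dh_next = Ui.w.t() * dz;
    if (dX) (*dX)[t] = Wi.w.t() * dz;
  }
}

// Unpack an R image array (n,64,64,3) slice into channel-major (3, 4096*n).
static mat unpack_images(const Rcpp::NumericVector& img) {
  Rcpp::IntegerVector d = img.attr("dim");
  int n = d[0], H = d[1], W = d[2], C = d[3];
  if (H != IMG || W != IMG || C != CH_IN)
    Rcpp::stop("images must be (n, 64, 64, 3)");
  mat X(CH_IN, H * W * n);
  const double* p = img.begin();
  for (int c = 0; c < C; ++c) {
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        size_t off = (size_t)n * (y + (size_t)H * (x + (size_t)W * c));
        for (int s = 0; s < n; ++s) {
          X(c, s * H * W + x * H + y) = p[s + off];
        }
      }
    }
  }
  return X;
}

// Unpack an R sequence array (n,50,128) into T matrices of (128, n).
static std::vector<mat> unpack_seqs(const Rcpp::NumericVector& sq) {
  Rcpp::IntegerVector d = sq.attr("dim");
  int n = d[0], T = d[1], D = d[2];
  if (T != T_SEQ || D != D_SEQ) Rcpp::stop("sequences must be (n, 50, 128)");
  std::vector<mat> X(T);
  const double* p = sq.begin();
  for (int t = 0; t < T; ++t) {
    X[t].set_size(D, n);
    for (int j = 0; j < D; ++j) {
      size_t off = (size_t)n * (t + (size_t)T * j);
      for (int s = 0; s < n; ++s) X[t](j, s) = p[s + off];
    }
  }
  return X;
}

struct FwdCache {
  mat col1, Y1, P1, col2, Y2, P2, Proj, Z, A1, Out;
  umat arg1, arg2;
  LstmCache l1, l2;
  std::vector<mat> Xseq;
  mat scores, alpha, pooled;
  int n = 0;
};

static void forward(Net& net, const Rcpp::NumericVector& img,
                    const Rcpp::NumericVector& sq, FwdCache& f) {
  mat Ximg = unpack_images(img);
  int n = (int)(Ximg.n_cols / (IMG * IMG));
  f.n = n;
  // conv1
  im2col3(Ximg, CH_IN, IMG, n, f.col1);
  f.Y1 = net.Wc1.w * f.col1;
  f.Y1.each_col() += net.bc1.w.col(0);
  f.Y1.transform([](double x) { return x > 0 ? x : 0.0; });
  maxpool2(f.Y1, C1, IMG, n, f.P1, f.arg1);
  // conv2
  im2col3(f.P1, C1, IMG / 2, n, f.col2);
  f.Y2 = net.Wc2.w * f.col2;
  f.Y2.each_col() += net.bc2.w.col(0);
  f.Y2.transform([](double x) { return x > 0 ? x : 0.0; });
  maxpool2(f.Y2, C2, IMG / 2, n, f.P2, f.arg2);
  // 1x1 projection -> 2048 feature
  f.Proj = net.Wp.w * f.P2;
  f.Proj.each_col() += net.bp.w.col(0);
  // LSTM branch
  f.Xseq = unpack_seqs(sq);
  lstm_forward(net.Wi1, net.Ui1, net.b1l, f.Xseq, H1, n, f.l1);
  lstm_forward(net.Wi2, net.Ui2, net.b2l, f.l1.h, H2, n, f.l2);
  // attention over the H2 hidden-state sequence
  double sc = std::sqrt((double)H2);
  f.scores.set_size(T_SEQ, n);
  for (int t = 0; t < T_SEQ; ++t) {
    f.scores.row(t) = (net.attn_u.w.t() * f.l2.h[t]) / sc;
  }
  mat m = max(f.scores, 0);
  mat e = exp(f.scores.each_row() - m);
  f.alpha = e.each_row() / sum(e, 0);
  f.pooled.zeros(H2, n);
  for (int t = 0; t < T_SEQ; ++t) {
    f.pooled += f.l2.h[t].each_row() % f.alpha.row(t);
  }
  // fusion
  f.Z.set_size(FUSE, n);
  for (int s = 0; s < n; ++s) {
    f.Z.submat(0, s, CNN_DIM - 1, s) =
      vectorise(f.Proj.cols(s * 256, s * 256 + 255));
    f.Z.submat(CNN_DIM, s, FUSE - 1, s) = f.pooled.col(s);
  }
  f.A1 = net.W1.w * f.Z;
  f.A1.each_col() += net.b1.w.col(0);
  f.A1.transform([](double x) { return x > 0 ? x : 0.0; });
  f.Out = net.W2.w * f.A1;
  f.Out.each_col() += net.b2.w.col(0);
}

static double param_sqnorm(Net& net) {
  double s = 0;
  for (Param* p : net.params()) s += accu(square(p->w));
  return s;
}

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(int seed) {
  Rcpp::XPtr<Net> p(new Net((unsigned int)seed), true);
  return p;
}

// [[Rcpp::export(name = ".net_predict")]]
Rcpp::NumericMatrix net_predict(SEXP ptr, Rcpp::NumericVector images,
                                Rcpp::NumericVector seqs) {
  Rcpp::XPtr<Net> net(ptr);
  FwdCache f;
  forward(*net, images, seqs, f);
  Rcpp::NumericMatrix out(f.n, OUT);
  for (int s = 0; s < f.n; ++s)
    for (int j = 0; j < OUT; ++j) out(s, j) = f.Out(j, s);
  return out;
}

// [[Rcpp::export(name = ".net_shapes")]]
Rcpp::List net_shapes(SEXP ptr, Rcpp::NumericVector images,
                      Rcpp::NumericVector seqs) {
  Rcpp::XPtr<Net> net(ptr);
  FwdCache f;
  forward(*net, images, seqs, f);
  using Rcpp::IntegerVector;
  return Rcpp::List::create(
    Rcpp::Named("conv1") = IntegerVector::create(64, 64, C1),
    Rcpp::Named("pool1") = IntegerVector::create(32, 32, C1),
    Rcpp::Named("conv2") = IntegerVector::create(32, 32, C2),
    Rcpp::Named("pool2") = IntegerVector::create(16, 16, C2),
    Rcpp::Named("lstm1") = IntegerVector::create(T_SEQ, H1),
    Rcpp::Named("lstm2_out") = IntegerVector::create(H2),
    Rcpp::Named("fused") = IntegerVector::create(FUSE),
    Rcpp::Named("fc1") = IntegerVector::create(FC1),
    Rcpp::Named("output") = IntegerVector::create(OUT),
    Rcpp::Named("checked") = Rcpp::LogicalVector::create(
      (int)f.Y1.n_rows == C1 && f.Y1.n_cols == (uword)(64 * 64 * f.n),
      (int)f.P1.n_rows == C1 && f.P1.n_cols == (uword)(32 * 32 * f.n),
      (int)f.Y2.n_rows == C2 && f.Y2.n_cols == (uword)(32 * 32 * f.n),
      (int)f.P2.n_rows == C2 && f.P2.n_cols == (uword)(16 * 16 * f.n),
      (int)f.l1.h.size() == T_SEQ && (int)f.l1.h[0].n_rows == H1,
      (int)f.pooled.n_rows == H2,
      (int)f.Z.n_rows == FUSE,
      (int)f.A1.n_rows == FC1,
      (int)f.Out.n_rows == OUT));
}

// [[Rcpp::export(name = ".net_train_batch")]]
double net_train_batch(SEXP ptr, Rcpp::NumericVector images,
                       Rcpp::NumericVector seqs,
                       Rcpp::NumericMatrix targets,
                       double lr, Rcpp::NumericVector task_w,
                       double lambda, double clip, double momentum) {
  Rcpp::XPtr<Net> net(ptr);
  FwdCache f;
  forward(*net, images, seqs, f);
  int n = f.n;
  if (targets.nrow() != n || targets.ncol() != OUT)
    Rcpp::stop("targets must be (n, 8)");
  mat T(OUT, n);
  for (int s = 0; s < n; ++s)
    for (int j = 0; j < OUT; ++j) T(j, s) = targets(s, j);
  vec w(OUT);
  for (int j = 0; j < OUT; ++j) w(j) = task_w[j];

  mat diff = f.Out - T;
  double loss = 0;
  for (int j = 0; j < OUT; ++j) {
    loss += w(j) * accu(square(diff.row(j))) / n;
  }
  loss += lambda * param_sqnorm(*net);

  // ---- backward
  mat dOut = 2.0 * (diff.each_col() % w) / n;
  mat dW2 = dOut * f.A1.t();
  mat db2 = sum(dOut, 1);
  mat dA1 = net->W2.w.t() * dOut;
  dA1.elem(find(f.A1 == 0)).zeros();
  mat dW1 = dA1 * f.Z.t();
  mat db1 = sum(dA1, 1);
  mat dZ = net->W1.w.t() * dA1;

  // split fusion gradient
  mat dProj(CP, 256 * n);
  mat dPooled(H2, n);
  for (int s = 0; s < n; ++s) {
    dProj.cols(s * 256, s * 256 + 255) =
      reshape(dZ.submat(0, s, CNN_DIM - 1, s), CP, 256);
    dPooled.col(s) = dZ.submat(CNN_DIM, s, FUSE - 1, s);
  }

  // attention backward
  double sc = std::sqrt((double)H2);
  mat dalpha(T_SEQ, n);
  std::vector<mat> dH2(T_SEQ);
  for (int t = 0; t < T_SEQ; ++t) {
    dalpha.row(t) = sum(dPooled % f.l2.h[t], 0);
    dH2[t] = dPooled.each_row() % f.alpha.row(t);
  }
  mat dscores = f.alpha % (dalpha.each_row() - sum(f.alpha % dalpha, 0));
  mat du(H2, 1, fill::zeros);
  for (int t = 0; t < T_SEQ; ++t) {
    du += f.l2.h[t] * (dscores.row(t).t() / sc);
    dH2[t] += net->attn_u.w * (dscores.row(t) / sc);
  }

  // LSTM2 backward (input grads feed LSTM1 hidden grads)
  mat dWi2, dUi2, db2l;
  std::vector<mat> dH1;
  lstm_backward(net->Wi2, net->Ui2, f.l1.h, f.l2, dH2, H2, n,
                dWi2, dUi2, db2l, &dH1);
  mat dWi1, dUi1, db1l;
  lstm_backward(net->Wi1, net->Ui1, f.Xseq, f.l1, dH1, H1, n,
                dWi1, dUi1, db1l, nullptr);

  // projection backward
  mat dWp = dProj * f.P2.t();
  mat dbp = sum(dProj, 1);
  mat dP2 = net->Wp.w.t() * dProj;

  // conv2 backward
  mat dY2;
  unpool2(dP2, f.arg2, C2, IMG / 2, n, dY2);
  dY2.elem(find(f.Y2 == 0)).zeros();
  mat dWc2 = dY2 * f.col2.t();
  mat dbc2 = sum(dY2, 1);
  mat dcol2 = net->Wc2.w.t() * dY2;
  mat dP1;
  col2im3(dcol2, C1, IMG / 2, n, dP1);

  // conv1 backward
  mat dY1;
  unpool2(dP1, f.arg1, C1, IMG, n, dY1);
  dY1.elem(find(f.Y1 == 0)).zeros();
  mat dWc1 = dY1 * f.col1.t();
  mat dbc1 = sum(dY1, 1);

  std::vector<Param*> ps = net->params();
  std::vector<mat> gs = {dWc1, dbc1, dWc2, dbc2, dWp, dbp,
                         dWi1, dUi1, db1l, dWi2, dUi2, db2l,
                         du, dW1, db1, dW2, db2};
  // L2 term and global-norm clip
  double sq = 0;
  for (size_t k = 0; k < ps.size(); ++k) {
    gs[k] += 2.0 * lambda * ps[k]->w;
    sq += accu(square(gs[k]));
  }
  double norm = std::sqrt(sq);
  double scale = (clip > 0 && norm > clip) ? clip / norm : 1.0;
  // Adam update (beta1 = `momentum`, beta2 = 0.999) on clipped gradients
  const double beta1 = momentum, beta2 = 0.999, eps = 1e-8;
  net->step += 1;
  double bc1 = 1.0 - std::pow(beta1, (double)net->step);
  double bc2 = 1.0 - std::pow(beta2, (double)net->step);
  for (size_t k = 0; k < ps.size(); ++k) {
    mat g = scale * gs[k];
    ps[k]->m = beta1 * ps[k]->m + (1.0 - beta1) * g;
    ps[k]->v = beta2 * ps[k]->v + (1.0 - beta2) * square(g);
    ps[k]->w -= lr * (ps[k]->m / bc1) / (sqrt(ps[k]->v / bc2) + eps);
  }
  return loss;
}

// [[Rcpp::export(name = ".net_sqnorm")]]
double net_sqnorm(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  return param_sqnorm(*net);
}

// Snapshot / restore of the weight matrices (moment buffers untouched),
// used for best-validation-epoch checkpointing.
// [[Rcpp::export(name = ".net_get_weights")]]
Rcpp::List net_get_weights(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  std::vector<Param*> ps = net->params();
  Rcpp::List out(ps.size());
  for (size_t k = 0; k < ps.size(); ++k) {
    out[k] = Rcpp::wrap(ps[k]->w);
  }
  return out;
}

// [[Rcpp::export(name = ".net_set_weights")]]
void net_set_weights(SEXP ptr, Rcpp::List weights) {
  Rcpp::XPtr<Net> net(ptr);
  std::vector<Param*> ps = net->params();
  if ((size_t)weights.size() != ps.size())
    Rcpp::stop("weight list length mismatch");
  for (size_t k = 0; k < ps.size(); ++k) {
    mat w = Rcpp::as<mat>(weights[k]);
    if (w.n_rows != ps[k]->w.n_rows || w.n_cols != ps[k]->w.n_cols)
      Rcpp::stop("weight dimension mismatch");
    ps[k]->w = w;
  }
}
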