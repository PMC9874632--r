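// Reverse-mode training engine for the point-wise multiplet classifier:
// an inception-style bank of 1D convolutions over the raw spectrum,
// a time-distributed dense layer, a bidirectional LSTM, and a decreasing
// dense stack ending in a per-point softmax over the label classes.
//
// Batched layout: activations are (channels x N*B) matrices whose column
// index is t*B + b, so the B columns of one time step are contiguous and
// the LSTM recurrence works on contiguous column blocks.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

struct NetShape {
  arma::ivec kernels;   // conv kernel sizes
  int F;                // filters per conv branch
  int C0;               // concatenated conv channels = nk * F
  int D;                // post-conv dense units
  int U;                // LSTM units per direction
  arma::ivec stack;     // dense stack sizes, last == K
  int K;                // number of classes
  int nk() const { return (int)kernels.n_elem; }
  int nstack() const { return (int)stack.n_elem; }
};

NetShape parse_shape(const List& config) {
  NetShape s;
  s.kernels = as<arma::ivec>(config["kernels"]);
  s.F = as<int>(config["filters"]);
  s.C0 = s.nk() * s.F;
  s.D = as<int>(config["d0"]);
  s.U = as<int>(config["lstm"]);
  s.stack = as<arma::ivec>(config["stack"]);
  s.K = (int)s.stack(s.stack.n_elem - 1);
  return s;
}

// Canonical parameter order (matches the R-side weight template):
// convW_i (F x k_i) ... convb_i (F x 1) ... d0W, d0b,
// fWx, fWh, fb, bWx, bWh, bb, then sW_j, sb_j per stack layer.
std::vector<mat> parse_params(const List& weights) {
  std::vector<mat> p;
  p.reserve(weights.size());
  for (R_xlen_t i = 0; i < weights.size(); ++i) {
    NumericMatrix w = weights[i];
    p.push_back(as<mat>(w));
  }
  return p;
}

struct Idx {
  int nk, m;
  int convW(int i) const { return i; }
  int convb(int i) const { return nk + i; }
  int d0W() const { return 2 * nk; }
  int d0b() const { return 2 * nk + 1; }
  int fWx() const { return 2 * nk + 2; }
  int fWh() const { return 2 * nk + 3; }
  int fb()  const { return 2 * nk + 4; }
  int bWx() const { return 2 * nk + 5; }
  int bWh() const { return 2 * nk + 6; }
  int bb()  const { return 2 * nk + 7; }
  int sW(int j) const { return 2 * nk + 8 + 2 * j; }
  int sb(int j) const { return 2 * nk + 8 + 2 * j + 1; }
  int total() const { return 2 * nk + 8 + 2 * m; }
};

inline mat elu(const mat& x) {
  mat y = x;
  y.transform([](double v) { return v > 0.0 ? v : std::expm1(v); });
  return y;
}
// derivative of ELU expressed through its output (alpha = 1)
inline mat elu_deriv_from_out(const mat& y) {
  mat d = y;
  d.transform([](double v) { return v > 0.0 ? 1.0 : v + 1.0; });
  return d;
}
inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct Cache {
  int N = 0, B = 0;
  mat H0;                 // C0 x NB, post-ELU conv output
  mat A1;                 // D x NB, post-ELU dense output
  mat hf, hb;             // U x NB hidden states, both directions
  mat if_, ff_, gf_, of_, cf_;   // forward-direction gate activations
  mat ib_, fb_, gb_, ob_, cb_;   // backward-direction gate activations
  std::vector<mat> S;     // post-activation stack outputs (last = logits)
  mat P;                  // K x NB softmax probabilities
};

// "same" cross-correlation column matrix: row i of the result holds the
// input shifted so that out[t] = sum_i w[i] * x[t + i - padl].
mat conv_cols(const vec& x, int k) {
  const int N = (int)x.n_elem;
  const int padl = (k - 1) / 2;
  vec xp(N + k - 1, arma::fill::zeros);
  xp.subvec(padl, padl + N - 1) = x;
  mat Xc(k, N);
  for (int i = 0; i < k; ++i) Xc.row(i) = xp.subvec(i, i + N - 1).t();
  return Xc;
}

void lstm_forward(const mat& Zin, const mat& Wh, int U, int N, int B,
                  bool reverse, mat& i_, mat& f_, mat& g_, mat& o_,
                  mat& c_, mat& h_) {
  const int NB = N * B;
  i_.set_size(U, NB); f_.set_size(U, NB); g_.set_size(U, NB);
  o_.set_size(U, NB); c_.set_size(U, NB); h_.set_size(U, NB);
  mat hprev(U, B, arma::fill::zeros), cprev(U, B, arma::fill::zeros);
  for (int step = 0; step < N; ++step) {
    const int t = reverse ? (N - 1 - step) : step;
    const uword c0 = (uword)t * B, c1 = (uword)t * B + B - 1;
    mat z = Zin.cols(c0, c1) + Wh * hprev;
    mat zi = sigm(z.rows(0, U - 1));
    mat zf = sigm(z.rows(U, 2 * U - 1));
    mat zg = arma::tanh(z.rows(2 * U, 3 * U - 1));
    mat zo = sigm(z.rows(3 * U, 4 * U - 1));
    mat cc = zf % cprev + zi % zg;
    mat hh = zo % arma::tanh(cc);
    i_.cols(c0, c1) = zi; f_.cols(c0, c1) = zf; g_.cols(c0, c1) = zg;
    o_.cols(c0, c1) = zo; c_.cols(c0, c1) = cc; h_.cols(c0, c1) = hh;
    hprev = hh; cprev = cc;
  }
}

// Backward pass of one LSTM direction. dh_out is the gradient arriving at
// the hidden states; returns gate pre-activation gradients dZ (4U x NB).
mat lstm_backward(const mat& dh_out, const mat& Wh, int U, int N, int B,
                  bool reverse, const mat& i_, const mat& f_, const mat& g_,
                  const mat& o_, const mat& c_) {
  const int NB = N * B;
  mat dZ(4 * U, NB, arma::fill::zeros);
  mat dznext;         // gate gradient of the later step in scan order
  mat dcnext(U, B, arma::fill::zeros);
  for (int step = N - 1; step >= 0; --step) {
    const int t = reverse ? (N - 1 - step) : step;
    const uword c0 = (uword)t * B, c1 = (uword)t * B + B - 1;
    mat dh = dh_out.cols(c0, c1);
    if (dznext.n_elem) dh += Wh.t() * dznext;
    mat zi = i_.cols(c0, c1), zf = f_.cols(c0, c1), zg = g_.cols(c0, c1),
        zo = o_.cols(c0, c1), cc = c_.cols(c0, c1);
    mat tc = arma::tanh(cc);
    mat dc = dcnext + dh % zo % (1.0 - tc % tc);
    // previous cell state in scan order
    mat cprev(U, B, arma::fill::zeros);
    if (step > 0) {
      const int tp = reverse ? (N - step) : (step - 1);
      cprev = c_.cols((uword)tp * B, (uword)tp * B + B - 1);
    }
    mat dz(4 * U, B);
    dz.rows(0, U - 1)         = (dc % zg) % zi % (1.0 - zi);
    dz.rows(U, 2 * U - 1)     = (dc % cprev) % zf % (1.0 - zf);
    dz.rows(2 * U, 3 * U - 1) = (dc % zi) % (1.0 - zg % zg);
    dz.rows(3 * U, 4 * U - 1) = (dh % tc) % zo % (1.0 - zo);
    dZ.cols(c0, c1) = dz;
    dcnext = dc % zf;
    dznext = dz;
  }
  return dZ;
}

// shifted hidden-state matrix: col t*B+b holds h at the previous scan step
mat shift_hidden(const mat& h, int U, int N, int B, bool reverse) {
  mat hs(U, (uword)N * B, arma::fill::zeros);
  for (int step = 1; step < N; ++step) {
    const int t = reverse ? (N - 1 - step) : step;
    const int tp = reverse ? (N - step) : (step - 1);
    hs.cols((uword)t * B, (uword)t * B + B - 1) =
        h.cols((uword)tp * B, (uword)tp * B + B - 1);
  }
  return hs;
}

void forward_pass(const std::vector<mat>& p, const NetShape& s, const Idx& ix,
                  const mat& X, Cache& cc) {
  const int N = (int)X.n_rows, B = (int)X.n_cols;
  const uword NB = (uword)N * B;
  cc.N = N; cc.B = B;
  cc.H0.set_size(s.C0, NB);
  mat tmp(s.C0, N);
  for (int b = 0; b < B; ++b) {
    vec x = X.col(b);
    int row0 = 0;
    for (int j = 0; j < s.nk(); ++j) {
      mat Xc = conv_cols(x, (int)s.kernels(j));
      mat Y = p[ix.convW(j)] * Xc;
      Y.each_col() += p[ix.convb(j)].col(0);
      tmp.rows(row0, row0 + s.F - 1) = Y;
      row0 += s.F;
    }
    for (int t = 0; t < N; ++t) cc.H0.col((uword)t * B + b) = tmp.col(t);
  }
  cc.H0 = elu(cc.H0);

  cc.A1 = p[ix.d0W()] * cc.H0;
  cc.A1.each_col() += p[ix.d0b()].col(0);
  cc.A1 = elu(cc.A1);

  mat Zf = p[ix.fWx()] * cc.A1; Zf.each_col() += p[ix.fb()].col(0);
  lstm_forward(Zf, p[ix.fWh()], s.U, N, B, false,
               cc.if_, cc.ff_, cc.gf_, cc.of_, cc.cf_, cc.hf);
  mat Zb = p[ix.bWx()] * cc.A1; Zb.each_col() += p[ix.bb()].col(0);
  lstm_forward(Zb, p[ix.bWh()], s.U, N, B, true,
               cc.ib_, cc.fb_, cc.gb_, cc.ob_, cc.cb_, cc.hb);

  mat A = arma::join_cols(cc.hf, cc.hb);
  const int m = s.nstack();
  cc.S.assign(m, mat());
  for (int j = 0; j < m; ++j) {
    mat Z = p[ix.sW(j)] * A;
    Z.each_col() += p[ix.sb(j)].col(0);
    if (j < m - 1) { cc.S[j] = arma::clamp(Z, 0.0, arma::datum::inf); A = cc.S[j]; }
    else cc.S[j] = Z;   // logits
  }
  mat L = cc.S[m - 1];
  arma::rowvec mx = arma::max(L, 0);
  L.each_row() -= mx;
  L = arma::exp(L);
  arma::rowvec ssum = arma::sum(L, 0);
  L.each_row() /= ssum;
  cc.P = L;
}

// Cross-entropy loss and full gradient; Y is N x B integer labels 0..K-1.
// cw is an optional per-class weight vector (length K) for the loss.
double backward_pass(const std::vector<mat>& p, const NetShape& s,
                     const Idx& ix, const mat& X, const arma::imat& Y,
                     const vec& cw, Cache& cc, std::vector<mat>& g) {
  const int N = cc.N, B = cc.B, m = s.nstack();
  const uword NB = (uword)N * B;

  g.assign(p.size(), mat());
  for (size_t i = 0; i < p.size(); ++i) g[i].zeros(p[i].n_rows, p[i].n_cols);

  // loss + dLogits
  mat dA = cc.P;
  double loss = 0.0, wsum = 0.0;
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < N; ++t) {
      const uword col = (uword)t * B + b;
      const int y = (int)Y(t, b);
      const double w = cw.n_elem ? cw(y) : 1.0;
      loss += -w * std::log(cc.P(y, col) + 1e-12);
      wsum += w;
      if (cw.n_elem) dA.col(col) *= w;
      dA(y, col) -= w;
    }
  }
  loss /= wsum;
  dA /= wsum;

  // dense stack backward
  for (int j = m - 1; j >= 1; --j) {
    g[ix.sW(j)] = dA * cc.S[j - 1].t();
    g[ix.sb(j)] = arma::sum(dA, 1);
    dA = p[ix.sW(j)].t() * dA;
    dA %= arma::conv_to<mat>::from(cc.S[j - 1] > 0.0);
  }
  mat Hcat = arma::join_cols(cc.hf, cc.hb);
  g[ix.sW(0)] = dA * Hcat.t();
  g[ix.sb(0)] = arma::sum(dA, 1);
  mat dHcat = p[ix.sW(0)].t() * dA;

  mat dhf = dHcat.rows(0, s.U - 1);
  mat dhb = dHcat.rows(s.U, 2 * s.U - 1);

  mat dZf = lstm_backward(dhf, p[ix.fWh()], s.U, N, B, false,
                          cc.if_, cc.ff_, cc.gf_, cc.of_, cc.cf_);
  mat dZb = lstm_backward(dhb, p[ix.bWh()], s.U, N, B, true,
                          cc.ib_, cc.fb_, cc.gb_, cc.ob_, cc.cb_);

  g[ix.fWx()] = dZf * cc.A1.t();
  g[ix.fWh()] = dZf * shift_hidden(cc.hf, s.U, N, B, false).t();
  g[ix.fb()]  = arma::sum(dZf, 1);
  g[ix.bWx()] = dZb * cc.A1.t();
  g[ix.bWh()] = dZb * shift_hidden(cc.hb, s.U, N, B, true).t();
  g[ix.bb()]  = arma::sum(dZb, 1);

  mat dA1 = p[ix.fWx()].t() * dZf + p[ix.bWx()].t() * dZb;
  dA1 %= elu_deriv_from_out(cc.A1);

  g[ix.d0W()] = dA1 * cc.H0.t();
  g[ix.d0b()] = arma::sum(dA1, 1);
  mat dH0 = p[ix.d0W()].t() * dA1;
  dH0 %= elu_deriv_from_out(cc.H0);

  mat dtmp(s.C0, N);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < N; ++t) dtmp.col(t) = dH0.col((uword)t * B + b);
    vec x = X.col(b);
    int row0 = 0;
    for (int j = 0; j < s.nk(); ++j) {
      mat Xc = conv_cols(x, (int)s.kernels(j));
      mat dY = dtmp.rows(row0, row0 + s.F - 1);
      g[ix.convW(j)] += dY * Xc.t();
      g[ix.convb(j)] += arma::sum(dY, 1);
      row0 += s.F;
    }
  }
  return loss;
}

double accuracy_from_probs(const mat& P, const arma::imat& Y, int N, int B) {
  long correct = 0;
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < N; ++t) {
      arma::uword am = P.col((uword)t * B + b).index_max();
      if ((int)am == (int)Y(t, b)) ++correct;
    }
  return (double)correct / ((double)N * B);
}

} // namespace

// [[Rcpp::export]]
arma::cube cpp_nn_forward(List weights, List config, arma::mat X) {
  NetShape s = parse_shape(config);
  Idx ix{ s.nk(), s.nstack() };
  std::vector<mat> p = parse_params(weights);
  const int N = (int)X.n_rows, B = (int)X.n_cols;
  Cache cc;
  forward_pass(p, s, ix, X, cc);
  arma::cube out(N, s.K, B);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < N; ++t)
      for (int k = 0; k < s.K; ++k)
        out(t, k, b) = cc.P(k, (uword)t * B + b);
  return out;
}

// [[Rcpp::export]]
List cpp_nn_loss_grad(List weights, List config, arma::mat X, arma::imat Y,
                      Nullable<NumericVector> classWeights = R_NilValue) {
  NetShape s = parse_shape(config);
  Idx ix{ s.nk(), s.nstack() };
  std::vector<mat> p = parse_params(weights);
  vec cw;
  if (classWeights.isNotNull()) cw = as<vec>(classWeights.get());
  Cache cc;
  forward_pass(p, s, ix, X, cc);
  std::vector<mat> g;
  double loss = backward_pass(p, s, ix, X, Y, cw, cc, g);
  List gl(weights.size());
  for (size_t i = 0; i < g.size(); ++i) gl[i] = wrap(g[i]);
  gl.names() = weights.names();
  return List::create(_["loss"] = loss, _["grads"] = gl);
}

// [[Rcpp::export]]
List cpp_nn_train(List weights, List config, arma::mat Xtr, arma::imat Ytr,
                  arma::mat Xval, arma::imat Yval, List tconf) {
  NetShape s = parse_shape(config);
  Idx ix{ s.nk(), s.nstack() };
  std::vector<mat> p = parse_params(weights);

  const int epochs = as<int>(tconf["epochs"]);
  const int batch = as<int>(tconf["batch"]);
  const double lr = as<double>(tconf["lr"]);
  const unsigned seed = (unsigned)as<int>(tconf["seed"]);
  vec cw;
  if (tconf.containsElementNamed("class_weights") &&
      !Rf_isNull(tconf["class_weights"]))
    cw = as<vec>(tconf["class_weights"]);
  const double clip = tconf.containsElementNamed("clip_norm") ?
      as<double>(tconf["clip_norm"]) : 0.0;   // 0 disables clipping
  const double lrDecay = tconf.containsElementNamed("lr_decay") ?
      as<double>(tconf["lr_decay"]) : 1.0;    // per-epoch multiplier
  const bool verbose = tconf.containsElementNamed("verbose") ?
      as<bool>(tconf["verbose"]) : false;

  const int ntr = (int)Xtr.n_cols, nval = (int)Xval.n_cols;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  std::vector<mat> mM(p.size()), vM(p.size());
  for (size_t i = 0; i < p.size(); ++i) {
    mM[i].zeros(p[i].n_rows, p[i].n_cols);
    vM[i].zeros(p[i].n_rows, p[i].n_cols);
  }
  long step = 0;

  std::mt19937 rng(seed);
  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = i;

  NumericVector h_loss(epochs), h_acc(epochs), h_vloss(epochs), h_vacc(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    const double lrEp = lr * std::pow(lrDecay, (double)ep);
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0; long ep_pts = 0; double ep_acc_num = 0.0;
    for (int start = 0; start < ntr; start += batch) {
      Rcpp::checkUserInterrupt();
      const int B = std::min(batch, ntr - start);
      mat Xb(Xtr.n_rows, B);
      arma::imat Yb(Ytr.n_rows, B);
      for (int b = 0; b < B; ++b) {
        Xb.col(b) = Xtr.col(order[start + b]);
        Yb.col(b) = Ytr.col(order[start + b]);
      }
      Cache cc;
      forward_pass(p, s, ix, Xb, cc);
      std::vector<mat> g;
      double loss = backward_pass(p, s, ix, Xb, Yb, cw, cc, g);
      if (clip > 0.0) {
        double gn2 = 0.0;
        for (auto& gi : g) gn2 += arma::accu(arma::square(gi));
        const double gn = std::sqrt(gn2);
        if (gn > clip) for (auto& gi : g) gi *= clip / gn;
      }
      ep_loss += loss * B;
      ep_acc_num += accuracy_from_probs(cc.P, Yb, cc.N, cc.B) * B;
      ep_pts += B;
      ++step;
      const double corr = lrEp *
          std::sqrt(1.0 - std::pow(b2, (double)step)) /
          (1.0 - std::pow(b1, (double)step));
      for (size_t i = 0; i < p.size(); ++i) {
        mM[i] = b1 * mM[i] + (1.0 - b1) * g[i];
        vM[i] = b2 * vM[i] + (1.0 - b2) * arma::square(g[i]);
        p[i] -= corr * mM[i] / (arma::sqrt(vM[i]) + eps);
      }
    }
    h_loss[ep] = ep_loss / ep_pts;
    h_acc[ep] = ep_acc_num / ep_pts;

    // validation pass in chunks
    double vloss = 0.0, vacc = 0.0;
    if (nval > 0) {
      long vp = 0;
      for (int start = 0; start < nval; start += batch) {
        const int B = std::min(batch, nval - start);
        mat Xb = Xval.cols(start, start + B - 1);
        arma::imat Yb = Yval.cols(start, start + B - 1);
        Cache cc;
        forward_pass(p, s, ix, Xb, cc);
        double l = 0.0, wsum = 0.0;
        for (int b = 0; b < B; ++b)
          for (int t = 0; t < cc.N; ++t) {
            const int y = (int)Yb(t, b);
            const double w = cw.n_elem ? cw(y) : 1.0;
            l += -w * std::log(cc.P(y, (uword)t * B + b) + 1e-12);
            wsum += w;
          }
        vloss += (l / wsum) * B;
        vacc += accuracy_from_probs(cc.P, Yb, cc.N, cc.B) * B;
        vp += B;
      }
      vloss /= vp; vacc /= vp;
    }
    h_vloss[ep] = vloss; h_vacc[ep] = vacc;
    if (verbose)
      Rcpp::Rcerr << "epoch " << (ep + 1) << "/" << epochs
                  << " loss " << h_loss[ep] << " acc " << h_acc[ep]
                  << " val_loss " << vloss << " val_acc " << vacc << "\n";
  }

  List wl(weights.size());
  for (size_t i = 0; i < p.size(); ++i) wl[i] = wrap(p[i]);
  wl.names() = weights.names();
  DataFrame hist = DataFrame::create(
      _["epoch"] = seq_len(epochs), _["loss"] = h_loss, _["accuracy"] = h_acc,
      _["val_loss"] = h_vloss, _["val_accuracy"] = h_vacc);
  return List::create(_["weights"] = wl, _["history"] = hist);
}
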