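// Minimal LSTM / BiLSTM sequence classifier with full backpropagation
// through time and Adam, written against Armadillo. Layout:
//   input (T x F) -> forward LSTM(H) [and backward LSTM(H)] ->
//   concatenated final hidden states -> dropout -> dense -> softmax.
// Only the final hidden state of each direction feeds the dense layer, so
// the backward pass injects the output gradient at the last processed step
// and propagates through U only.
//
// Sequences are passed as an arma::cube of shape (F, T, N): slice i is the
// F x T matrix of sample i. All randomness (init, shuffling, dropout) comes
// from one std::mt19937 per call, so runs are reproducible given a seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Cache {
  cube I, F, G, O, TC, CP, HP, XT;  // slices indexed by processing step
  mat hT;
};

// One direction's forward pass over a minibatch. `rev` processes the
// sequence back-to-front. Caches are only filled when training.
static void dir_forward(const mat& W, const mat& U, const vec& b,
                        const cube& X, const uvec& idx, bool rev,
                        Cache& cc, bool store) {
  const int H = U.n_cols;
  const int T = X.n_cols;
  const int Fd = X.n_rows;
  const int B = idx.n_elem;
  if (store) {
    cc.I.set_size(H, B, T); cc.F.set_size(H, B, T); cc.G.set_size(H, B, T);
    cc.O.set_size(H, B, T); cc.TC.set_size(H, B, T); cc.CP.set_size(H, B, T);
    cc.HP.set_size(H, B, T); cc.XT.set_size(Fd, B, T);
  }
  mat h(H, B, fill::zeros), c(H, B, fill::zeros), Xt(Fd, B);
  for (int s = 0; s < T; ++s) {
    const int t = rev ? (T - 1 - s) : s;
    for (int bb = 0; bb < B; ++bb) Xt.col(bb) = X.slice(idx[bb]).col(t);
    mat A = W * Xt + U * h;
    A.each_col() += b;
    mat ig = sigm(A.rows(0, H - 1));
    mat fg = sigm(A.rows(H, 2 * H - 1));
    mat gg = tanh(A.rows(2 * H, 3 * H - 1));
    mat og = sigm(A.rows(3 * H, 4 * H - 1));
    if (store) {
      cc.CP.slice(s) = c; cc.HP.slice(s) = h; cc.XT.slice(s) = Xt;
    }
    c = fg % c + ig % gg;
    mat tc = tanh(c);
    h = og % tc;
    if (store) {
      cc.I.slice(s) = ig; cc.F.slice(s) = fg; cc.G.slice(s) = gg;
      cc.O.slice(s) = og; cc.TC.slice(s) = tc;
    }
  }
  cc.hT = h;
}

// BPTT for one direction given the gradient at the final hidden state.
static void dir_backward(const mat& U, const Cache& cc, const mat& dhT,
                         mat& dW, mat& dU, vec& db) {
  const int T = cc.I.n_slices;
  mat dh = dhT;
  mat dc(dh.n_rows, dh.n_cols, fill::zeros);
  dW.zeros(); dU.zeros(); db.zeros();
  for (int s = T - 1; s >= 0; --s) {
    const mat& ig = cc.I.slice(s); const mat& fg = cc.F.slice(s);
    const mat& gg = cc.G.slice(s); const mat& og = cc.O.slice(s);
    const mat& tc = cc.TC.slice(s); const mat& cp = cc.CP.slice(s);
    mat dO = dh % tc;
    dc += dh % og % (1.0 - tc % tc);
    mat dA = join_cols((dc % gg) % ig % (1.0 - ig),
                       (dc % cp) % fg % (1.0 - fg),
                       (dc % ig) % (1.0 - gg % gg),
                       dO % og % (1.0 - og));
    dW += dA * cc.XT.slice(s).t();
    dU += dA * cc.HP.slice(s).t();
    db += sum(dA, 1);
    dh = U.t() * dA;
    dc = dc % fg;
  }
}

static void adam_mat(mat& p, const mat& g, mat& m, mat& v,
                     double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  p -= lr * (m / (1 - std::pow(b1, t))) /
       (sqrt(v / (1 - std::pow(b2, t))) + eps);
}

static void adam_vec(vec& p, const vec& g, vec& m, vec& v,
                     double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  p -= lr * (m / (1 - std::pow(b1, t))) /
       (sqrt(v / (1 - std::pow(b2, t))) + eps);
}

struct Net {
  std::vector<mat> W, U;
  std::vector<vec> b;
  mat Wd;
  vec bd;
  int H, Fd, C, ndir;
};

static Net net_from_list(List params) {
  Net net;
  List dirs = params["dirs"];
  net.ndir = dirs.size();
  for (int d = 0; d < net.ndir; ++d) {
    List dl = dirs[d];
    net.W.push_back(as<mat>(dl["W"]));
    net.U.push_back(as<mat>(dl["U"]));
    net.b.push_back(as<vec>(dl["b"]));
  }
  net.Wd = as<mat>(params["Wd"]);
  net.bd = as<vec>(params["bd"]);
  net.H = net.U[0].n_cols;
  net.Fd = net.W[0].n_cols;
  net.C = net.Wd.n_rows;
  return net;
}

static List net_to_list(const Net& net, bool bidir) {
  List dirs(net.ndir);
  for (int d = 0; d < net.ndir; ++d) {
    dirs[d] = List::create(_["W"] = net.W[d], _["U"] = net.U[d],
                           _["b"] = net.b[d]);
  }
  return List::create(_["dirs"] = dirs, _["Wd"] = net.Wd, _["bd"] = net.bd,
                      _["hidden"] = net.H, _["input"] = net.Fd,
                      _["classes"] = net.C, _["bidirectional"] = bidir);
}

// Column-wise softmax probabilities of the dense output for a batch.
static mat batch_probs(const Net& net, const cube& X, const uvec& idx) {
  Cache cf, cb;
  dir_forward(net.W[0], net.U[0], net.b[0], X, idx, false, cf, false);
  mat z;
  if (net.ndir == 2) {
    dir_forward(net.W[1], net.U[1], net.b[1], X, idx, true, cb, false);
    z = join_cols(cf.hT, cb.hT);
  } else {
    z = cf.hT;
  }
  mat logits = net.Wd * z;
  logits.each_col() += net.bd;
  mat e = exp(logits.each_row() - max(logits, 0));
  return e.each_row() / sum(e, 0);
}

static double dataset_loss(const Net& net, const cube& X, const ivec& y) {
  const int N = X.n_slices;
  double loss = 0;
  for (int s0 = 0; s0 < N; s0 += 256) {
    const int s1 = std::min(N, s0 + 256);
    uvec idx(s1 - s0);
    for (int i = s0; i < s1; ++i) idx[i - s0] = i;
    mat p = batch_probs(net, X, idx);
    for (int i = s0; i < s1; ++i) loss += -std::log(p(y[i], i - s0) + 1e-12);
  }
  return loss / N;
}

// [[Rcpp::export]]
List lstm_init_cpp(int input, int hidden, int classes, bool bidirectional,
                   int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  auto glorot = [&](int rows, int cols, double fi, double fo) {
    const double lim = std::sqrt(6.0 / (fi + fo));
    std::uniform_real_distribution<double> u(-lim, lim);
    mat m(rows, cols);
    for (uword j = 0; j < m.n_cols; ++j)
      for (uword i = 0; i < m.n_rows; ++i) m(i, j) = u(rng);
    return m;
  };
  const int H = hidden;
  const int ndir = bidirectional ? 2 : 1;
  List dirs(ndir);
  for (int d = 0; d < ndir; ++d) {
    mat W = glorot(4 * H, input, input, H);
    mat U = glorot(4 * H, H, H, H);
    vec b(4 * H, fill::zeros);
    b.subvec(H, 2 * H - 1).fill(1.0);  // forget-gate bias
    dirs[d] = List::create(_["W"] = W, _["U"] = U, _["b"] = b);
  }
  mat Wd = glorot(classes, ndir * H, ndir * H, classes);
  vec bd(classes, fill::zeros);
  return List::create(_["dirs"] = dirs, _["Wd"] = Wd, _["bd"] = bd,
                      _["hidden"] = H, _["input"] = input,
                      _["classes"] = classes,
                      _["bidirectional"] = bidirectional);
}

// [[Rcpp::export]]
List lstm_train_cpp(List params, const arma::cube& X, const arma::ivec& y,
                    const arma::cube& Xval, const arma::ivec& yval,
                    int epochs, int batch, double lr, double l2,
                    double dropout, int seed) {
  Net net = net_from_list(params);
  const bool bidir = net.ndir == 2;
  const int N = X.n_slices;
  const int H = net.H;
  if (N == 0) stop("empty training set");
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::bernoulli_distribution keep_draw(1.0 - dropout);

  // Adam state, one slot per parameter tensor
  std::vector<mat> gW(net.ndir), gU(net.ndir);
  std::vector<vec> gb(net.ndir);
  std::vector<mat> mW(net.ndir), vW(net.ndir), mU(net.ndir), vU(net.ndir);
  std::vector<vec> mb(net.ndir), vb(net.ndir);
  for (int d = 0; d < net.ndir; ++d) {
    gW[d] = zeros<mat>(size(net.W[d])); gU[d] = zeros<mat>(size(net.U[d]));
    gb[d] = zeros<vec>(net.b[d].n_elem);
    mW[d] = gW[d]; vW[d] = gW[d]; mU[d] = gU[d]; vU[d] = gU[d];
    mb[d] = gb[d]; vb[d] = gb[d];
  }
  mat mWd = zeros<mat>(size(net.Wd)), vWd = mWd;
  vec mbd = zeros<vec>(net.bd.n_elem), vbd = mbd;

  std::vector<uword> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  NumericVector train_hist(epochs), val_hist(epochs);
  int step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double tot = 0;
    for (int s0 = 0; s0 < N; s0 += batch) {
      const int s1 = std::min(N, s0 + batch);
      const int B = s1 - s0;
      uvec idx(B);
      for (int i = 0; i < B; ++i) idx[i] = order[s0 + i];

      Cache cf, cb;
      dir_forward(net.W[0], net.U[0], net.b[0], X, idx, false, cf, true);
      mat z;
      if (bidir) {
        dir_forward(net.W[1], net.U[1], net.b[1], X, idx, true, cb, true);
        z = join_cols(cf.hT, cb.hT);
      } else {
        z = cf.hT;
      }
      mat mask;
      if (dropout > 0) {
        mask.set_size(size(z));
        for (uword k = 0; k < mask.n_elem; ++k) mask[k] = keep_draw(rng) ? 1.0 : 0.0;
        z = (z % mask) / (1.0 - dropout);
      }
      mat logits = net.Wd * z;
      logits.each_col() += net.bd;
      mat e = exp(logits.each_row() - max(logits, 0));
      mat p = e.each_row() / sum(e, 0);

      double loss = 0;
      mat dlog = p;
      for (int i = 0; i < B; ++i) {
        const int cls = y[idx[i]];
        loss += -std::log(p(cls, i) + 1e-12);
        dlog(cls, i) -= 1.0;
      }
      tot += loss;
      dlog /= B;

      mat dWd = dlog * z.t() + l2 * net.Wd;
      vec dbd = sum(dlog, 1);
      mat dz = net.Wd.t() * dlog;
      if (dropout > 0) dz = (dz % mask) / (1.0 - dropout);

      dir_backward(net.U[0], cf, dz.rows(0, H - 1), gW[0], gU[0], gb[0]);
      gW[0] += l2 * net.W[0];
      gU[0] += l2 * net.U[0];
      if (bidir) {
        dir_backward(net.U[1], cb, dz.rows(H, 2 * H - 1), gW[1], gU[1], gb[1]);
        gW[1] += l2 * net.W[1];
        gU[1] += l2 * net.U[1];
      }

      ++step;
      for (int d = 0; d < net.ndir; ++d) {
        adam_mat(net.W[d], gW[d], mW[d], vW[d], lr, step);
        adam_mat(net.U[d], gU[d], mU[d], vU[d], lr, step);
        adam_vec(net.b[d], gb[d], mb[d], vb[d], lr, step);
      }
      adam_mat(net.Wd, dWd, mWd, vWd, lr, step);
      adam_vec(net.bd, dbd, mbd, vbd, lr, step);
    }
    train_hist[ep] = tot / N;
    val_hist[ep] = (Xval.n_slices > 0) ? dataset_loss(net, Xval, yval)
                                       : NA_REAL;
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["params"] = net_to_list(net, bidir),
                      _["train_loss"] = train_hist,
                      _["val_loss"] = val_hist);
}

// [[Rcpp::export]]
arma::mat lstm_predict_cpp(List params, const arma::cube& X) {
  Net net = net_from_list(params);
  const int N = X.n_slices;
  mat out(N, net.C);
  for (int s0 = 0; s0 < N; s0 += 256) {
    const int s1 = std::min(N, s0 + 256);
    uvec idx(s1 - s0);
    for (int i = s0; i < s1; ++i) idx[i - s0] = i;
    mat p = batch_probs(net, X, idx);
    out.rows(s0, s1 - 1) = p.t();
  }
  return out;
}
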