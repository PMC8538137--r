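// Stacked-LSTM sequence classifier: forward pass, backpropagation
// through time, and Adam training loop. Weights travel as an R list so
// initialization, serialization and finite-difference checks stay on
// the R side; everything here is deterministic given its inputs (batch
// order is supplied by the caller).
//
// Layout: L LSTM layers (gate order i, f, g, o stacked row-wise in W/U/b),
// a dense ReLU layer on the last timestep's hidden state, and a softmax
// output. Loss is (class-weighted) sparse categorical cross-entropy.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

struct LstmLayer {
  mat W;  // (4*nh) x nin
  mat U;  // (4*nh) x nh
  vec b;  // 4*nh
};

struct Net {
  std::vector<LstmLayer> layers;
  mat Wd; vec bd;   // dense ReLU
  mat Wo; vec bo;   // softmax logits
};

static Net parse_net(const List& weights) {
  Net net;
  List lstm = weights["lstm"];
  for (int l = 0; l < lstm.size(); ++l) {
    List ly = lstm[l];
    LstmLayer layer;
    layer.W = as<mat>(ly["W"]);
    layer.U = as<mat>(ly["U"]);
    layer.b = as<vec>(ly["b"]);
    net.layers.push_back(layer);
  }
  net.Wd = as<mat>(weights["Wd"]);
  net.bd = as<vec>(weights["bd"]);
  net.Wo = as<mat>(weights["Wo"]);
  net.bo = as<vec>(weights["bo"]);
  return net;
}

static List net_to_list(const Net& net) {
  List lstm(net.layers.size());
  for (size_t l = 0; l < net.layers.size(); ++l) {
    lstm[l] = List::create(_["W"] = net.layers[l].W,
                           _["U"] = net.layers[l].U,
                           _["b"] = net.layers[l].b);
  }
  return List::create(_["lstm"] = lstm, _["Wd"] = net.Wd, _["bd"] = net.bd,
                      _["Wo"] = net.Wo, _["bo"] = net.bo);
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

static mat softmax_cols(mat z) {
  z.each_row() -= arma::max(z, 0);
  z = arma::exp(z);
  z.each_row() /= arma::sum(z, 0);
  return z;
}

// per-timestep activations of one layer, kept for BPTT
struct LayerTrace {
  std::vector<mat> x, i, f, g, o, c, tc, h_prev, c_prev, h;
};

// forward over a batch; fills traces when keep = true
static mat forward_batch(const Net& net, const cube& X,
                         const arma::uvec& idx, std::vector<LayerTrace>* traces,
                         mat* hT_out, mat* zd_out, mat* hd_out) {
  const arma::uword T = X.n_cols, B = idx.n_elem, L = net.layers.size();
  const bool keep = traces != nullptr;

  std::vector<mat> below(T);  // input sequence to the current layer
  for (arma::uword t = 0; t < T; ++t) {
    mat xt(X.n_rows, B);
    for (arma::uword k = 0; k < B; ++k) xt.col(k) = X.slice(idx[k]).col(t);
    below[t] = xt;
  }

  for (arma::uword l = 0; l < L; ++l) {
    const LstmLayer& ly = net.layers[l];
    const arma::uword nh = ly.U.n_cols;
    mat h(nh, B, arma::fill::zeros), c(nh, B, arma::fill::zeros);
    LayerTrace tr;
    if (keep) {
      tr.x.resize(T); tr.i.resize(T); tr.f.resize(T); tr.g.resize(T);
      tr.o.resize(T); tr.c.resize(T); tr.tc.resize(T);
      tr.h_prev.resize(T); tr.c_prev.resize(T); tr.h.resize(T);
    }
    std::vector<mat> out(T);
    for (arma::uword t = 0; t < T; ++t) {
      mat z = ly.W * below[t] + ly.U * h;
      z.each_col() += ly.b;
      mat gi = sigm(z.rows(0, nh - 1));
      mat gf = sigm(z.rows(nh, 2 * nh - 1));
      mat gg = arma::tanh(z.rows(2 * nh, 3 * nh - 1));
      mat go = sigm(z.rows(3 * nh, 4 * nh - 1));
      mat c_new = gf % c + gi % gg;
      mat tc = arma::tanh(c_new);
      mat h_new = go % tc;
      if (keep) {
        tr.x[t] = below[t]; tr.i[t] = gi; tr.f[t] = gf; tr.g[t] = gg;
        tr.o[t] = go; tr.c[t] = c_new; tr.tc[t] = tc;
        tr.h_prev[t] = h; tr.c_prev[t] = c; tr.h[t] = h_new;
      }
      h = h_new; c = c_new;
      out[t] = h;
    }
    if (keep) (*traces)[l] = std::move(tr);
    below = std::move(out);
  }

  mat hT = below[T - 1];
  mat zd = net.Wd * hT;
  zd.each_col() += net.bd;
  mat hd = arma::clamp(zd, 0.0, arma::datum::inf);
  mat logits = net.Wo * hd;
  logits.each_col() += net.bo;
  if (hT_out) *hT_out = hT;
  if (zd_out) *zd_out = zd;
  if (hd_out) *hd_out = hd;
  return softmax_cols(logits);
}

// loss + gradients on one batch; returns loss, fills grad net
static double batch_grad(const Net& net, const cube& X, const arma::ivec& y,
                         const vec& class_w, const arma::uvec& idx,
                         Net& grad, arma::uword* n_correct) {
  const arma::uword T = X.n_cols, B = idx.n_elem, L = net.layers.size();
  std::vector<LayerTrace> traces(L);
  mat hT, zd, hd;
  mat P = forward_batch(net, X, idx, &traces, &hT, &zd, &hd);

  vec wts(B);
  double wsum = 0.0, loss = 0.0;
  for (arma::uword k = 0; k < B; ++k) {
    wts[k] = class_w[y[idx[k]]];
    wsum += wts[k];
  }
  if (n_correct) *n_correct = 0;
  mat dlogits = P;
  for (arma::uword k = 0; k < B; ++k) {
    int yk = y[idx[k]];
    loss += -std::log(std::max(P(yk, k), 1e-12)) * wts[k];
    dlogits(yk, k) -= 1.0;
    dlogits.col(k) *= wts[k] / wsum;
    if (n_correct && (arma::uword)P.col(k).index_max() == (arma::uword)yk)
      ++(*n_correct);
  }
  loss /= wsum;

  grad.Wo = dlogits * hd.t();
  grad.bo = arma::sum(dlogits, 1);
  mat dhd = net.Wo.t() * dlogits;
  mat dzd = dhd % arma::conv_to<mat>::from(zd > 0);
  grad.Wd = dzd * hT.t();
  grad.bd = arma::sum(dzd, 1);

  // gradient wrt each layer's input sequence, propagated downward
  std::vector<mat> dseq(T);
  for (arma::uword t = 0; t < T; ++t) dseq[t].zeros(1, 1);  // placeholder

  grad.layers.resize(L);
  mat d_top = net.Wd.t() * dzd;  // dh at the last timestep of the top layer

  for (int l = (int)L - 1; l >= 0; --l) {
    const LstmLayer& ly = net.layers[l];
    const LayerTrace& tr = traces[l];
    const arma::uword nh = ly.U.n_cols, nin = ly.W.n_cols;
    LstmLayer g;
    g.W.zeros(4 * nh, nin); g.U.zeros(4 * nh, nh); g.b.zeros(4 * nh);
    std::vector<mat> dx(T);
    mat dh_rec(nh, B, arma::fill::zeros), dc(nh, B, arma::fill::zeros);
    for (int t = (int)T - 1; t >= 0; --t) {
      mat dh = dh_rec;
      if (l == (int)L - 1) {
        if (t == (int)T - 1) dh += d_top;
      } else {
        dh += dseq[t];
      }
      mat dgo = dh % tr.tc[t];
      dc += dh % tr.o[t] % (1.0 - arma::square(tr.tc[t]));
      mat dgi = dc % tr.g[t];
      mat dgg = dc % tr.i[t];
      mat dgf = dc % tr.c_prev[t];
      mat dc_prev = dc % tr.f[t];
      mat dz(4 * nh, B);
      dz.rows(0, nh - 1)          = dgi % tr.i[t] % (1.0 - tr.i[t]);
      dz.rows(nh, 2 * nh - 1)     = dgf % tr.f[t] % (1.0 - tr.f[t]);
      dz.rows(2 * nh, 3 * nh - 1) = dgg % (1.0 - arma::square(tr.g[t]));
      dz.rows(3 * nh, 4 * nh - 1) = dgo % tr.o[t] % (1.0 - tr.o[t]);
      g.W += dz * tr.x[t].t();
      g.U += dz * tr.h_prev[t].t();
      g.b += arma::sum(dz, 1);
      dx[t] = ly.W.t() * dz;
      dh_rec = ly.U.t() * dz;
      dc = dc_prev;
    }
    grad.layers[l] = std::move(g);
    dseq = std::move(dx);
  }
  return loss;
}

// [[Rcpp::export]]
List cpp_lstm_grad(List weights, NumericVector x_array, IntegerVector y,
                   NumericVector class_w) {
  IntegerVector dims = x_array.attr("dim");
  cube X(x_array.begin(), dims[0], dims[1], dims[2]);
  Net net = parse_net(weights);
  Net grad;
  arma::uvec idx = arma::regspace<arma::uvec>(0, X.n_slices - 1);
  arma::ivec yy = as<arma::ivec>(y);
  double loss = batch_grad(net, X, yy, as<vec>(class_w), idx, grad, nullptr);
  return List::create(_["loss"] = loss, _["grad"] = net_to_list(grad));
}

// [[Rcpp::export]]
NumericMatrix cpp_lstm_predict(List weights, NumericVector x_array) {
  IntegerVector dims = x_array.attr("dim");
  cube X(x_array.begin(), dims[0], dims[1], dims[2]);
  Net net = parse_net(weights);
  arma::uword N = X.n_slices;
  mat probs(net.Wo.n_rows, N);
  const arma::uword chunk = 256;
  for (arma::uword s = 0; s < N; s += chunk) {
    arma::uword e = std::min(N, s + chunk) - 1;
    arma::uvec idx = arma::regspace<arma::uvec>(s, e);
    probs.cols(s, e) = forward_batch(net, X, idx, nullptr, nullptr, nullptr,
                                     nullptr);
  }
  return wrap(mat(probs.t()));
}

template <typename T>
static void adam_update(T& p, const T& g, T& m, T& v, double lr,
                        double b1, double b2, double eps, double t) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  T mhat = m / (1.0 - std::pow(b1, t));
  T vhat = v / (1.0 - std::pow(b2, t));
  p -= lr * mhat / (arma::sqrt(vhat) + eps);
}

// [[Rcpp::export]]
List cpp_lstm_train(List weights, NumericVector x_array, IntegerVector y,
                    NumericVector class_w, double lr, int batch_size,
                    int epochs, IntegerMatrix order) {
  IntegerVector dims = x_array.attr("dim");
  cube X(x_array.begin(), dims[0], dims[1], dims[2]);
  Net net = parse_net(weights);
  arma::ivec yy = as<arma::ivec>(y);
  vec cw = as<vec>(class_w);
  const arma::uword N = X.n_slices, L = net.layers.size();

  // Adam state
  Net m, v;
  m.layers.resize(L); v.layers.resize(L);
  for (arma::uword l = 0; l < L; ++l) {
    m.layers[l].W.zeros(arma::size(net.layers[l].W));
    m.layers[l].U.zeros(arma::size(net.layers[l].U));
    m.layers[l].b.zeros(net.layers[l].b.n_elem);
    v.layers[l] = m.layers[l];
  }
  m.Wd.zeros(arma::size(net.Wd)); m.bd.zeros(net.bd.n_elem);
  m.Wo.zeros(arma::size(net.Wo)); m.bo.zeros(net.bo.n_elem);
  v.Wd = m.Wd; v.bd = m.bd; v.Wo = m.Wo; v.bo = m.bo;

  const double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  double step = 0.0;
  NumericVector hist_loss(epochs), hist_acc(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    arma::uword ep_correct = 0, n_batches = 0;
    for (arma::uword s = 0; s < N; s += batch_size) {
      arma::uword e = std::min<arma::uword>(N, s + batch_size) - 1;
      arma::uvec idx(e - s + 1);
      for (arma::uword k = s; k <= e; ++k) idx[k - s] = order(ep, k) - 1;
      Net grad;
      arma::uword nc = 0;
      double loss = batch_grad(net, X, yy, cw, idx, grad, &nc);
      step += 1.0;
      for (arma::uword l = 0; l < L; ++l) {
        adam_update(net.layers[l].W, grad.layers[l].W, m.layers[l].W,
                    v.layers[l].W, lr, b1, b2, eps, step);
        adam_update(net.layers[l].U, grad.layers[l].U, m.layers[l].U,
                    v.layers[l].U, lr, b1, b2, eps, step);
        adam_update(net.layers[l].b, grad.layers[l].b, m.layers[l].b,
                    v.layers[l].b, lr, b1, b2, eps, step);
      }
      adam_update(net.Wd, grad.Wd, m.Wd, v.Wd, lr, b1, b2, eps, step);
      adam_update(net.bd, grad.bd, m.bd, v.bd, lr, b1, b2, eps, step);
      adam_update(net.Wo, grad.Wo, m.Wo, v.Wo, lr, b1, b2, eps, step);
      adam_update(net.bo, grad.bo, m.bo, v.bo, lr, b1, b2, eps, step);
      if (!std::isfinite(loss)) {
        stop("NaN/Inf training loss at epoch %d", ep + 1);
      }
      ep_loss += loss;
      ep_correct += nc;
      ++n_batches;
    }
    hist_loss[ep] = ep_loss / n_batches;
    hist_acc[ep] = (double)ep_correct / N;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = net_to_list(net),
                      _["loss"] = hist_loss, _["accuracy"] = hist_acc);
}
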