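// Sigmoid feed-forward engine: forward pass, backprop gradient and the
// per-sample momentum-SGD training loop. Shuffling draws from R's RNG so a
// set.seed() on the R side makes whole runs reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec sigmoid(const arma::vec& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

static std::vector<arma::mat> as_mats(const List& W) {
  std::vector<arma::mat> out;
  for (int l = 0; l < W.size(); ++l) out.push_back(as<arma::mat>(W[l]));
  return out;
}
static std::vector<arma::vec> as_vecs(const List& b) {
  std::vector<arma::vec> out;
  for (int l = 0; l < b.size(); ++l) out.push_back(as<arma::vec>(b[l]));
  return out;
}

static std::vector<arma::vec> forward_all(const std::vector<arma::mat>& W,
                                          const std::vector<arma::vec>& b,
                                          const arma::vec& x) {
  std::vector<arma::vec> a;
  a.push_back(x);
  for (size_t l = 0; l < W.size(); ++l)
    a.push_back(sigmoid(W[l] * a.back() + b[l]));
  return a;
}

static double sum_sq_weights(const std::vector<arma::mat>& W) {
  double s = 0.0;
  for (size_t l = 0; l < W.size(); ++l) s += arma::accu(W[l] % W[l]);
  return s;
}

// [[Rcpp::export]]
List cpp_forward(List W, List b, arma::vec x) {
  std::vector<arma::mat> Wm = as_mats(W);
  std::vector<arma::vec> bv = as_vecs(b);
  std::vector<arma::vec> a = forward_all(Wm, bv, x);
  List out(a.size());
  for (size_t l = 0; l < a.size(); ++l) out[l] = a[l];
  return out;
}

// gradient of: mean over output units of squared error + lam * sum(w^2)
static void backprop(const std::vector<arma::mat>& W,
                     const std::vector<arma::vec>& b,
                     const arma::vec& x, const arma::vec& y, double lam,
                     std::vector<arma::mat>& gW, std::vector<arma::vec>& gb,
                     double* loss) {
  std::vector<arma::vec> a = forward_all(W, b, x);
  size_t L = W.size();
  arma::vec err = a.back() - y;
  if (loss) *loss = arma::mean(err % err) + lam * sum_sq_weights(W);
  arma::vec delta = (2.0 / y.n_elem) * err % a.back() % (1.0 - a.back());
  for (size_t l = L; l-- > 0;) {
    gW[l] = delta * a[l].t() + 2.0 * lam * W[l];
    gb[l] = delta;
    if (l > 0) delta = (W[l].t() * delta) % a[l] % (1.0 - a[l]);
  }
}

// [[Rcpp::export]]
List cpp_gradient(List W, List b, arma::vec x, arma::vec y, double lam) {
  std::vector<arma::mat> Wm = as_mats(W);
  std::vector<arma::vec> bv = as_vecs(b);
  size_t L = Wm.size();
  std::vector<arma::mat> gW(L);
  std::vector<arma::vec> gb(L);
  double loss = 0.0;
  backprop(Wm, bv, x, y, lam, gW, gb, &loss);
  List oW(L), ob(L);
  for (size_t l = 0; l < L; ++l) { oW[l] = gW[l]; ob[l] = gb[l]; }
  return List::create(_["gradW"] = oW, _["gradb"] = ob, _["loss"] = loss);
}

// [[Rcpp::export]]
double cpp_loss(List W, List b, arma::mat X, arma::mat Y, double lam) {
  std::vector<arma::mat> Wm = as_mats(W);
  std::vector<arma::vec> bv = as_vecs(b);
  double s = 0.0;
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    arma::vec out = forward_all(Wm, bv, X.row(i).t()).back();
    arma::vec err = out - Y.row(i).t();
    s += arma::mean(err % err);
  }
  return s / X.n_rows + lam * sum_sq_weights(Wm);
}

// [[Rcpp::export]]
arma::mat cpp_predict(List W, List b, arma::mat X) {
  std::vector<arma::mat> Wm = as_mats(W);
  std::vector<arma::vec> bv = as_vecs(b);
  arma::mat out(X.n_rows, as<arma::vec>(b[b.size() - 1]).n_elem);
  for (arma::uword i = 0; i < X.n_rows; ++i)
    out.row(i) = forward_all(Wm, bv, X.row(i).t()).back().t();
  return out;
}

// Per-sample momentum SGD: delta_w(t) = -eta * grad + alpha * delta_w(t-1),
// with eta = eta0 * decay^epoch and alpha = alpha0 * decay^epoch recomputed
// once per epoch. Returns updated parameters and the per-epoch mean training
// loss (data term at visit time + current penalty).
// [[Rcpp::export]]
List cpp_train(List W, List b, arma::mat X, arma::mat Y,
               double eta0, double alpha0, double decay, double lam,
               int epochs) {
  std::vector<arma::mat> Wm = as_mats(W);
  std::vector<arma::vec> bv = as_vecs(b);
  size_t L = Wm.size();
  std::vector<arma::mat> vW(L), gW(L);
  std::vector<arma::vec> vb(L), gb(L);
  for (size_t l = 0; l < L; ++l) {
    vW[l] = arma::zeros<arma::mat>(Wm[l].n_rows, Wm[l].n_cols);
    vb[l] = arma::zeros<arma::vec>(bv[l].n_elem);
    gW[l] = vW[l]; gb[l] = vb[l];
  }
  int n = X.n_rows;
  NumericVector trace(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    double eta = eta0 * std::pow(decay, ep);
    double alpha = alpha0 * std::pow(decay, ep);
    IntegerVector ord = Rcpp::sample(n, n, false);  // R RNG, 1-based
    double acc = 0.0;
    for (int s = 0; s < n; ++s) {
      int i = ord[s] - 1;
      double loss = 0.0;
      backprop(Wm, bv, X.row(i).t(), Y.row(i).t(), lam, gW, gb, &loss);
      acc += loss;
      for (size_t l = 0; l < L; ++l) {
        vW[l] = alpha * vW[l] - eta * gW[l];
        vb[l] = alpha * vb[l] - eta * gb[l];
        Wm[l] += vW[l];
        bv[l] += vb[l];
      }
    }
    trace[ep] = acc / n;
    if (!std::isfinite(trace[ep]))
      stop("training diverged: non-finite loss at epoch %d", ep + 1);
    if (ep % 50 == 0) Rcpp::checkUserInterrupt();
  }
  List oW(L), ob(L);
  for (size_t l = 0; l < L; ++l) { oW[l] = Wm[l]; ob[l] = bv[l]; }
  return List::create(_["weights"] = oW, _["biases"] = ob, _["trace"] = trace);
}
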