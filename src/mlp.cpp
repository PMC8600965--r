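// Minimal feed-forward binary classifier used as the Donsker-Varadhan
// likelihood-ratio model. Deliberately small and self-contained: ReLU hidden
// layers, sigmoid output, binary cross-entropy + L2 penalty, Adam updates,
// mini-batch order and weight initialisation driven by a private mt19937 so
// fits are bit-reproducible for a given seed and independent of R's RNG.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat glorot_init(int n_in, int n_out, std::mt19937 &rng) {
  double lim = std::sqrt(6.0 / (double)(n_in + n_out));
  std::uniform_real_distribution<double> unif(-lim, lim);
  arma::mat W(n_in, n_out);
  for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = unif(rng);
  return W;
}

static inline arma::mat relu(const arma::mat &z) {
  return arma::clamp(z, 0.0, arma::datum::inf);
}

static arma::vec forward_prob(const std::vector<arma::mat> &W,
                              const std::vector<arma::rowvec> &b,
                              const arma::mat &X) {
  int L = (int)W.size() - 1;
  arma::mat cur = X;
  for (int l = 0; l < L; ++l) {
    arma::mat z = cur * W[l];
    z.each_row() += b[l];
    cur = relu(z);
  }
  arma::vec logit = cur * W[L] + b[L](0);
  return 1.0 / (1.0 + arma::exp(-logit));
}

static double bce_loss(const arma::vec &p, const arma::vec &y) {
  arma::vec pc = arma::clamp(p, 1e-12, 1.0 - 1e-12);
  return -arma::mean(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc));
}

// Trains with mini-batch Adam; a fraction of the rows is held out as a
// validation set and the weights with the best validation BCE are kept
// (early stopping with patience). val_frac <= 0 disables early stopping.
// [[Rcpp::export]]
List cpp_mlp_train(const arma::mat &X, const arma::vec &y,
                   const arma::ivec &hidden, int epochs, int batch_size,
                   double lr, double l2, int seed,
                   double val_frac = 0.2, int patience = 10) {
  const int d = X.n_cols;
  const int L = hidden.n_elem;  // number of hidden layers
  std::mt19937 rng((unsigned)seed);

  // split off validation rows (deterministic shuffle)
  int n_all = X.n_rows;
  std::vector<arma::uword> allidx(n_all);
  for (int i = 0; i < n_all; ++i) allidx[i] = i;
  std::shuffle(allidx.begin(), allidx.end(), rng);
  int n_val = (val_frac > 0) ? (int)(val_frac * n_all) : 0;
  if (n_val < 10) n_val = 0;
  arma::uvec vidx(n_val), tidx(n_all - n_val);
  for (int i = 0; i < n_val; ++i) vidx[i] = allidx[i];
  for (int i = n_val; i < n_all; ++i) tidx[i - n_val] = allidx[i];
  arma::mat Xt = X.rows(tidx);
  arma::vec yt = y.elem(tidx);
  arma::mat Xv;
  arma::vec yv;
  if (n_val > 0) {
    Xv = X.rows(vidx);
    yv = y.elem(vidx);
  }
  const int n = Xt.n_rows;

  std::vector<arma::mat> W(L + 1);
  std::vector<arma::rowvec> b(L + 1);
  int prev = d;
  for (int l = 0; l < L; ++l) {
    W[l] = glorot_init(prev, hidden[l], rng);
    b[l] = arma::rowvec(hidden[l], arma::fill::zeros);
    prev = hidden[l];
  }
  W[L] = glorot_init(prev, 1, rng);
  b[L] = arma::rowvec(1, arma::fill::zeros);

  // Adam state
  std::vector<arma::mat> mW(L + 1), vW(L + 1);
  std::vector<arma::rowvec> mb(L + 1), vb(L + 1);
  for (int l = 0; l <= L; ++l) {
    mW[l] = arma::zeros<arma::mat>(W[l].n_rows, W[l].n_cols);
    vW[l] = mW[l];
    mb[l] = arma::zeros<arma::rowvec>(b[l].n_elem);
    vb[l] = mb[l];
  }
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long step = 0;

  std::vector<arma::uword> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  std::vector<arma::mat> acts(L + 1);  // inputs to each layer
  std::vector<arma::mat> zs(L);        // pre-activations of hidden layers

  std::vector<arma::mat> bestW = W;
  std::vector<arma::rowvec> bestb = b;
  double best_val = arma::datum::inf;
  int bad_epochs = 0;

  for (int e = 0; e < epochs; ++e) {
    std::shuffle(idx.begin(), idx.end(), rng);
    for (int start = 0; start < n; start += batch_size) {
      int stop = std::min(n, start + batch_size);
      arma::uvec bi(stop - start);
      for (int i = start; i < stop; ++i) bi[i - start] = idx[i];
      arma::mat A = Xt.rows(bi);
      arma::vec yb = yt.elem(bi);
      double m = (double)A.n_rows;

      // forward
      arma::mat cur = A;
      for (int l = 0; l < L; ++l) {
        acts[l] = cur;
        arma::mat z = cur * W[l];
        z.each_row() += b[l];
        zs[l] = z;
        cur = relu(z);
      }
      acts[L] = cur;
      arma::vec logit = acts[L] * W[L] + b[L](0);
      arma::vec p = 1.0 / (1.0 + arma::exp(-logit));

      // backward (BCE): d loss / d logit = (p - y) / m
      arma::mat delta = (p - yb) / m;  // n_batch x 1
      ++step;
      for (int l = L; l >= 0; --l) {
        arma::mat gW = acts[l].t() * delta + l2 * W[l];
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta.elem(arma::find(zs[l - 1] <= 0)).zeros();
        }
        // Adam
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * arma::square(gW);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * arma::square(gb);
        double c1 = 1.0 - std::pow(beta1, (double)step);
        double c2 = 1.0 - std::pow(beta2, (double)step);
        W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
        b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
      }
    }
    if (n_val > 0) {
      double vl = bce_loss(forward_prob(W, b, Xv), yv);
      if (vl < best_val - 1e-6) {
        best_val = vl;
        bestW = W;
        bestb = b;
        bad_epochs = 0;
      } else if (++bad_epochs >= patience) {
        break;
      }
    }
  }
  if (n_val > 0) {
    W = bestW;
    b = bestb;
  }

  List Wout(L + 1), bout(L + 1);
  for (int l = 0; l <= L; ++l) {
    Wout[l] = W[l];
    bout[l] = arma::vec(b[l].t());
  }
  return List::create(Named("W") = Wout, Named("b") = bout,
                      Named("hidden") = hidden, Named("d") = d);
}

// [[Rcpp::export]]
arma::vec cpp_mlp_predict(const List &model, const arma::mat &X) {
  List Wl = model["W"], bl = model["b"];
  int L = Wl.size() - 1;
  arma::mat cur = X;
  for (int l = 0; l < L; ++l) {
    arma::mat W = Wl[l];
    arma::vec b = bl[l];
    arma::mat z = cur * W;
    z.each_row() += b.t();
    cur = relu(z);
  }
  arma::mat Wo = Wl[L];
  arma::vec bo = bl[L];
  arma::vec logit = cur * Wo + bo(0);
  return 1.0 / (1.0 + arma::exp(-logit));
}
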