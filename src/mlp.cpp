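// Feed-forward binary classifier: ReLU hidden layers, sigmoid output,
// inverted dropout, Adam updates on mini-batches, early stopping on a
// monitored loss.  All randomness (init, shuffling, dropout) is drawn from
// R's RNG so results are reproducible under set.seed().
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

namespace {

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b;
};

arma::mat relu(const arma::mat& z) { return arma::clamp(z, 0.0, arma::datum::inf); }

arma::mat sigmoid(const arma::mat& z) { return 1.0 / (1.0 + arma::exp(-z)); }

// forward pass without dropout (evaluation mode)
arma::vec forward_eval(const Net& net, const arma::mat& X) {
  arma::mat a = X;
  const size_t L = net.W.size();
  for (size_t l = 0; l + 1 < L; ++l) {
    a = relu(a * net.W[l] + arma::repmat(net.b[l], a.n_rows, 1));
  }
  arma::mat out = sigmoid(a * net.W[L - 1] + arma::repmat(net.b[L - 1], a.n_rows, 1));
  return out.col(0);
}

double bce_loss(const arma::vec& p, const arma::vec& y) {
  arma::vec pc = arma::clamp(p, 1e-12, 1.0 - 1e-12);
  return arma::mean(-y % arma::log(pc) - (1.0 - y) % arma::log(1.0 - pc));
}

}  // namespace

// [[Rcpp::export]]
List mlp_fit_cpp(const arma::mat& X, const arma::vec& y,
                 const arma::mat& Xmon, const arma::vec& ymon,
                 IntegerVector hidden, double dropout, double lr,
                 int batch_size, int max_epochs, int patience) {
  const int n = X.n_rows, d = X.n_cols;
  std::vector<int> sizes;
  sizes.push_back(d);
  for (int h : hidden) sizes.push_back(h);
  sizes.push_back(1);
  const size_t L = sizes.size() - 1;

  Net net;
  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::rowvec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    arma::mat w(sizes[l], sizes[l + 1]);
    double sd = std::sqrt(2.0 / sizes[l]);  // He initialisation
    for (arma::uword i = 0; i < w.n_elem; ++i) w(i) = R::norm_rand() * sd;
    net.W.push_back(w);
    net.b.push_back(arma::rowvec(sizes[l + 1], arma::fill::zeros));
    mW[l].zeros(sizes[l], sizes[l + 1]);
    vW[l].zeros(sizes[l], sizes[l + 1]);
    mb[l].zeros(sizes[l + 1]);
    vb[l].zeros(sizes[l + 1]);
  }

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  const double keep = 1.0 - dropout;
  long step = 0;

  Net best = net;
  double best_loss = bce_loss(forward_eval(net, Xmon), ymon);
  int best_epoch = 0, wait = 0, epochs_run = 0;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    // Fisher-Yates shuffle from R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    for (int start = 0; start < n; start += batch_size) {
      int stop = std::min(start + batch_size, n);
      int bsz = stop - start;
      arma::uvec rows(bsz);
      for (int i = 0; i < bsz; ++i) rows(i) = idx[start + i];
      arma::mat a = X.rows(rows);
      arma::vec yb = y.elem(rows);

      // forward with dropout on hidden activations
      std::vector<arma::mat> acts(L + 1), zs(L), masks(L);
      acts[0] = a;
      for (size_t l = 0; l + 1 < L; ++l) {
        zs[l] = acts[l] * net.W[l] + arma::repmat(net.b[l], acts[l].n_rows, 1);
        arma::mat h = relu(zs[l]);
        if (dropout > 0.0) {
          arma::mat mask(h.n_rows, h.n_cols);
          for (arma::uword i = 0; i < mask.n_elem; ++i)
            mask(i) = (R::unif_rand() < keep) ? (1.0 / keep) : 0.0;
          h %= mask;
          masks[l] = mask;
        }
        acts[l + 1] = h;
      }
      zs[L - 1] = acts[L - 1] * net.W[L - 1] +
                  arma::repmat(net.b[L - 1], acts[L - 1].n_rows, 1);
      arma::vec p = sigmoid(zs[L - 1]).col(0);

      // backward
      arma::mat delta = (p - yb) / (double)bsz;  // d(mean BCE)/d(z_out)
      std::vector<arma::mat> gW(L);
      std::vector<arma::rowvec> gb(L);
      for (int l = (int)L - 1; l >= 0; --l) {
        gW[l] = acts[l].t() * delta;
        gb[l] = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * net.W[l].t();
          if (dropout > 0.0) delta %= masks[l - 1];
          delta %= arma::conv_to<arma::mat>::from(zs[l - 1] > 0.0);
        }
      }

      // Adam
      ++step;
      double bc1 = 1.0 - std::pow(beta1, (double)step);
      double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (size_t l = 0; l < L; ++l) {
        mW[l] = beta1 * mW[l] + (1.0 - beta1) * gW[l];
        vW[l] = beta2 * vW[l] + (1.0 - beta2) * arma::square(gW[l]);
        net.W[l] -= lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + eps);
        mb[l] = beta1 * mb[l] + (1.0 - beta1) * gb[l];
        vb[l] = beta2 * vb[l] + (1.0 - beta2) * arma::square(gb[l]);
        net.b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + eps);
      }
    }

    epochs_run = epoch;
    double mon = bce_loss(forward_eval(net, Xmon), ymon);
    if (mon < best_loss - 1e-6) {
      best_loss = mon;
      best = net;
      best_epoch = epoch;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }

  List Ws(L), bs(L);
  for (size_t l = 0; l < L; ++l) {
    Ws[l] = best.W[l];
    bs[l] = arma::vec(best.b[l].t());
  }
  return List::create(_["W"] = Ws, _["b"] = bs,
                      _["monitor_loss"] = best_loss,
                      _["best_epoch"] = best_epoch,
                      _["epochs_run"] = epochs_run);
}

// [[Rcpp::export]]
arma::vec mlp_predict_cpp(List W, List b, const arma::mat& X) {
  Net net;
  for (int l = 0; l < W.size(); ++l) {
    net.W.push_back(as<arma::mat>(W[l]));
    arma::vec bv = as<arma::vec>(b[l]);
    net.b.push_back(bv.t());
  }
  return forward_eval(net, X);
}
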