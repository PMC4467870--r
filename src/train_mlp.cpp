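#include <Rcpp.h>
using namespace Rcpp;

// Online backpropagation with momentum for a single-hidden-layer sigmoid
// network. One cycle = one (optionally shuffled) pass over all training
// rows, updating after every example. The error trace records, per cycle,
// the sum over examples of 0.5 * sum((d - y)^2) evaluated at the weights
// current when that example was visited.
//
// Shuffling uses R's RNG (unif_rand), so results are fully determined by
// the R-side seed.

static inline double sigmoid(double s) { return 1.0 / (1.0 + std::exp(-s)); }

// [[Rcpp::export]]
List train_mlp_cpp(NumericMatrix W1_, NumericVector b1_,
                   NumericMatrix W2_, NumericVector b2_,
                   NumericMatrix X, NumericMatrix D,
                   int cycles, double lr, double momentum, bool shuffle) {
  NumericMatrix W1 = clone(W1_);
  NumericVector b1 = clone(b1_);
  NumericMatrix W2 = clone(W2_);
  NumericVector b2 = clone(b2_);

  const int n_in = W1.nrow(), n_hid = W1.ncol(), n_out = W2.ncol();
  const int n = X.nrow();

  std::vector<double> dW1(n_in * n_hid, 0.0), db1(n_hid, 0.0);
  std::vector<double> dW2(n_hid * n_out, 0.0), db2(n_out, 0.0);
  std::vector<double> h(n_hid), y(n_out), delo(n_out), delh(n_hid);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  NumericVector trace(cycles);
  int bad_cycle = -1;

  for (int c = 0; c < cycles && bad_cycle < 0; ++c) {
    if (shuffle) {
      for (int i = n - 1; i > 0; --i) {
        int j = (int)std::floor(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(ord[i], ord[j]);
      }
    }
    double cycle_err = 0.0;
    for (int r = 0; r < n; ++r) {
      const int ex = ord[r];
      // forward
      for (int j = 0; j < n_hid; ++j) {
        double s = b1[j];
        for (int i = 0; i < n_in; ++i) s += X(ex, i) * W1(i, j);
        h[j] = sigmoid(s);
      }
      double err = 0.0;
      for (int o = 0; o < n_out; ++o) {
        double s = b2[o];
        for (int j = 0; j < n_hid; ++j) s += h[j] * W2(j, o);
        y[o] = sigmoid(s);
        const double diff = D(ex, o) - y[o];
        err += 0.5 * diff * diff;
        delo[o] = (y[o] - D(ex, o)) * y[o] * (1.0 - y[o]);
      }
      cycle_err += err;
      // backward
      for (int j = 0; j < n_hid; ++j) {
        double s = 0.0;
        for (int o = 0; o < n_out; ++o) s += W2(j, o) * delo[o];
        delh[j] = h[j] * (1.0 - h[j]) * s;
      }
      // hidden -> output updates
      for (int o = 0; o < n_out; ++o) {
        for (int j = 0; j < n_hid; ++j) {
          double &m = dW2[o * n_hid + j];
          m = -lr * h[j] * delo[o] + momentum * m;
          W2(j, o) += m;
        }
        double &mb = db2[o];
        mb = -lr * delo[o] + momentum * mb;
        b2[o] += mb;
      }
      // input -> hidden updates
      for (int j = 0; j < n_hid; ++j) {
        for (int i = 0; i < n_in; ++i) {
          double &m = dW1[j * n_in + i];
          m = -lr * X(ex, i) * delh[j] + momentum * m;
          W1(i, j) += m;
        }
        double &mb = db1[j];
        mb = -lr * delh[j] + momentum * mb;
        b1[j] += mb;
      }
    }
    trace[c] = cycle_err;
    if (!std::isfinite(cycle_err)) bad_cycle = c + 1;
  }

  return List::create(_["W1"] = W1, _["b1"] = b1, _["W2"] = W2, _["b2"] = b2,
                      _["trace"] = trace, _["bad_cycle"] = bad_cycle);
}
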