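#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Stochastic gradient descent for L2-regularized logistic regression on a
// sparse design matrix stored feature-by-sample (CSC with samples as
// columns, i.e. the transpose of the usual design matrix). The weight
// vector uses the lazy-scaling trick so the per-step L2 shrinkage is O(1)
// and the gradient touch is O(nnz of the sample).
//
// Objective: (1/n) * sum_i logloss(y_i, sigmoid(w'x_i + b)) +
//            (alpha/2) * ||w||^2        (intercept unpenalized)
// Learning rate: eta_t = eta0 / (1 + eta0 * alpha * t)  (inverse scaling)
// Early stop: average epoch loss fails to improve by `tol` for
// `n_no_change` consecutive epochs.

static inline double sigmoid(double z) {
  if (z > 0) {
    return 1.0 / (1.0 + std::exp(-z));
  }
  double e = std::exp(z);
  return e / (1.0 + e);
}

// [[Rcpp::export]]
List sgd_logreg_fit(S4 Xt, NumericVector y, double alpha, int max_epochs,
                    double tol, int n_no_change, double eta0,
                    uint32_t seed) {
  IntegerVector dims = Xt.slot("Dim");
  const int p = dims[0];      // features
  const int n = dims[1];      // samples
  IntegerVector Xi = Xt.slot("i");
  IntegerVector Xp = Xt.slot("p");
  NumericVector Xx = Xt.slot("x");

  std::vector<double> w(p, 0.0);
  double scale = 1.0, b = 0.0;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  // xorshift RNG + Fisher-Yates: deterministic across platforms.
  uint64_t state = (uint64_t)seed * 2654435769ULL + 1442695040888963407ULL;
  auto next_u64 = [&state]() {
    state ^= state << 13; state ^= state >> 7; state ^= state << 17;
    return state;
  };

  double best = R_PosInf;
  int stall = 0, epoch = 0;
  long t = 0;
  const double eps = 1e-12;

  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(next_u64() % (uint64_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    double loss = 0.0;
    for (int ii = 0; ii < n; ++ii) {
      int s = order[ii];
      ++t;
      double eta = eta0 / (1.0 + eta0 * alpha * (double)t);
      const int k0 = Xp[s], k1 = Xp[s + 1];
      const int *ri = &Xi[0];
      const double *rx = &Xx[0];
      double margin = b;
      for (int k = k0; k < k1; ++k) {
#ifdef __GNUC__
        if (k + 12 < k1) __builtin_prefetch(&w[ri[k + 12]], 0, 1);
#endif
        margin += scale * w[ri[k]] * rx[k];
      }
      double prob = sigmoid(margin);
      double yi = y[s];
      double pc = std::min(std::max(prob, eps), 1.0 - eps);
      loss += -(yi * std::log(pc) + (1.0 - yi) * std::log(1.0 - pc));
      double g = prob - yi;
      scale *= (1.0 - eta * alpha);
      if (scale < 1e-9) {
        for (int q = 0; q < p; ++q) w[q] *= scale;
        scale = 1.0;
      }
      if (g != 0.0) {
        double step = eta * g / scale;
        for (int k = k0; k < k1; ++k) {
          w[ri[k]] -= step * rx[k];
        }
        b -= eta * g;
      }
    }
    loss /= n;
    if (loss > best - tol) {
      if (++stall >= n_no_change) break;
    } else {
      stall = 0;
    }
    if (loss < best) best = loss;
  }

  NumericVector weights(p);
  for (int q = 0; q < p; ++q) weights[q] = scale * w[q];
  return List::create(_["weights"] = weights, _["intercept"] = b,
                      _["epochs"] = std::min(epoch, max_epochs),
                      _["final_loss"] = best);
}
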