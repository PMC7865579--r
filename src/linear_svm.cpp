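#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear SVC,
// one-vs-rest over k classes. Feature matrices are stored features x samples
// (column-major) so each sample is contiguous. The intercept is handled as an
// augmented constant feature of value 1 (regularized, liblinear-style), so a
// fitted weight vector has length p + 1 with the bias last.

namespace {

// deterministic xorshift RNG: results must not depend on R's RNG stream
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // unbiased enough for shuffling training orders
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

// Solve min_w 0.5 w'w + C sum_i max(0, 1 - y_i w'x_i) in the dual.
// X: p x m buffer (col-major, one sample per column), ybin in {-1,+1}.
// w (length p + 1) is overwritten with the solution.
void fit_binary(const double *X, int p, int m, const std::vector<int> &ybin,
                double C, double eps, int max_epochs, uint64_t seed,
                std::vector<double> &w) {
  std::vector<double> alpha(m, 0.0), qii(m);
  std::fill(w.begin(), w.end(), 0.0);
  for (int i = 0; i < m; ++i) {
    const double *xi = X + static_cast<size_t>(i) * p;
    double q = 1.0; // bias feature
    for (int j = 0; j < p; ++j) q += xi[j] * xi[j];
    qii[i] = q;
  }
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  XorShift rng(seed);

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates shuffle of the update order
    for (int i = m - 1; i > 0; --i) std::swap(order[i], order[rng.below(i + 1)]);
    double pg_max = -1e30, pg_min = 1e30;
    for (int t = 0; t < m; ++t) {
      const int i = order[t];
      const double *xi = X + static_cast<size_t>(i) * p;
      const double yi = ybin[i];
      double dec = w[p]; // bias feature value 1
      for (int j = 0; j < p; ++j) dec += w[j] * xi[j];
      const double G = yi * dec - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0) PG = std::min(G, 0.0);
      else if (alpha[i] >= C) PG = std::max(G, 0.0);
      if (PG > pg_max) pg_max = PG;
      if (PG < pg_min) pg_min = PG;
      if (std::fabs(PG) > 1e-12) {
        const double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        a_new = std::min(std::max(a_new, 0.0), C);
        const double d = (a_new - a_old) * yi;
        if (d != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += d * xi[j];
          w[p] += d;
          alpha[i] = a_new;
        }
      }
    }
    if (pg_max - pg_min < eps) break;
  }
}

// one-vs-rest fit; W is k x (p+1), row per class
void fit_ovr(const double *X, int p, int m, const std::vector<int> &y, int k,
             double C, double eps, int max_epochs, std::vector<double> &W) {
  std::vector<int> ybin(m);
  std::vector<double> w(p + 1);
  for (int c = 0; c < k; ++c) {
    for (int i = 0; i < m; ++i) ybin[i] = (y[i] == c) ? 1 : -1;
    // the shuffle seed must not depend on the class index, so that
    // relabelling classes permutes the decision functions exactly
    fit_binary(X, p, m, ybin, C, eps, max_epochs,
               0xB5297A4DULL + 31ULL * p + 7ULL * m, w);
    for (int j = 0; j <= p; ++j) W[static_cast<size_t>(c) * (p + 1) + j] = w[j];
  }
}

int predict_one(const std::vector<double> &W, int p, int k, const double *x) {
  int best = 0;
  double bestdec = -1e300;
  for (int c = 0; c < k; ++c) {
    const double *wc = W.data() + static_cast<size_t>(c) * (p + 1);
    double dec = wc[p];
    for (int j = 0; j < p; ++j) dec += wc[j] * x[j];
    if (dec > bestdec) { bestdec = dec; best = c; }
  }
  return best;
}

// gather selected feature rows / sample columns of X (p x n) into a compact
// a x m buffer
void gather(const double *X, int p, const std::vector<int> &genes,
            const std::vector<int> &samples, std::vector<double> &out) {
  const int a = static_cast<int>(genes.size());
  const int m = static_cast<int>(samples.size());
  out.resize(static_cast<size_t>(a) * m);
  for (int i = 0; i < m; ++i) {
    const double *col = X + static_cast<size_t>(samples[i]) * p;
    double *dst = out.data() + static_cast<size_t>(i) * a;
    for (int j = 0; j < a; ++j) dst[j] = col[genes[j]];
  }
}

// mean of per-fold held-out accuracies for a one-vs-rest fit on the given genes
double cv_accuracy(const double *X, int p, const std::vector<int> &y, int k,
                   const std::vector<int> &folds, int nfolds,
                   const std::vector<int> &genes, double C, double eps,
                   int max_epochs) {
  const int n = static_cast<int>(y.size());
  const int a = static_cast<int>(genes.size());
  std::vector<double> Xtr, W(static_cast<size_t>(k) * (a + 1));
  std::vector<double> xbuf(a);
  double acc_sum = 0.0;
  for (int f = 0; f < nfolds; ++f) {
    std::vector<int> tr, te;
    for (int i = 0; i < n; ++i) (folds[i] == f ? te : tr).push_back(i);
    std::vector<int> ytr(tr.size());
    for (size_t i = 0; i < tr.size(); ++i) ytr[i] = y[tr[i]];
    gather(X, p, genes, tr, Xtr);
    fit_ovr(Xtr.data(), a, static_cast<int>(tr.size()), ytr, k, C, eps,
            max_epochs, W);
    int correct = 0;
    for (size_t i = 0; i < te.size(); ++i) {
      const double *col = X + static_cast<size_t>(te[i]) * p;
      for (int j = 0; j < a; ++j) xbuf[j] = col[genes[j]];
      if (predict_one(W, a, k, xbuf.data()) == y[te[i]]) ++correct;
    }
    acc_sum += te.empty() ? 0.0 : static_cast<double>(correct) / te.size();
  }
  return acc_sum / nfolds;
}

std::vector<int> as_int_vec(const IntegerVector &v) {
  return std::vector<int>(v.begin(), v.end());
}

} // namespace

// [[Rcpp::export(name = ".cpp_svm_ovr")]]
NumericMatrix cpp_svm_ovr(NumericMatrix X, IntegerVector y, int k, double C,
                          double eps, int max_epochs) {
  const int p = X.nrow(), n = X.ncol();
  std::vector<int> yv = as_int_vec(y);
  std::vector<double> W(static_cast<size_t>(k) * (p + 1));
  fit_ovr(REAL(X), p, n, yv, k, C, eps, max_epochs, W);
  NumericMatrix out(k, p + 1);
  for (int c = 0; c < k; ++c)
    for (int j = 0; j <= p; ++j)
      out(c, j) = W[static_cast<size_t>(c) * (p + 1) + j];
  return out;
}

// [[Rcpp::export(name = ".cpp_svm_predict")]]
IntegerVector cpp_svm_predict(NumericMatrix W, NumericMatrix X) {
  const int k = W.nrow(), p = X.nrow(), n = X.ncol();
  if (W.ncol() != p + 1) stop("weight/feature dimension mismatch");
  std::vector<double> Wv(W.begin(), W.end());
  // W comes in col-major k x (p+1); repack row-major per class
  std::vector<double> Wr(static_cast<size_t>(k) * (p + 1));
  for (int c = 0; c < k; ++c)
    for (int j = 0; j <= p; ++j)
      Wr[static_cast<size_t>(c) * (p + 1) + j] = W(c, j);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = predict_one(Wr, p, k, REAL(X) + static_cast<size_t>(i) * p);
  return out;
}

// [[Rcpp::export(name = ".cpp_cv_accuracy")]]
double cpp_cv_accuracy(NumericMatrix X, IntegerVector y, int k,
                       IntegerVector folds, int nfolds, double C, double eps,
                       int max_epochs) {
  const int p = X.nrow();
  std::vector<int> yv = as_int_vec(y), fv = as_int_vec(folds);
  std::vector<int> genes(p);
  for (int j = 0; j < p; ++j) genes[j] = j;
  return cv_accuracy(REAL(X), p, yv, k, fv, nfolds, genes, C, eps, max_epochs);
}

// Recursive feature elimination: at each step record the mean CV accuracy of
// the current gene set, fit on all samples, rank genes by the sum of squared
// one-vs-rest weights, and drop the `step` lowest (never crossing min_genes).
// Returns the smallest recorded subset attaining the maximum recorded
// accuracy, refit on all samples.
// [[Rcpp::export(name = ".cpp_rfe")]]
List cpp_rfe(NumericMatrix X, IntegerVector y, int k, IntegerVector folds,
             int nfolds, int step, int min_genes, double C, double eps,
             int max_epochs) {
  const int p = X.nrow(), n = X.ncol();
  if (p < min_genes) stop("initial subset smaller than min_genes");
  std::vector<int> yv = as_int_vec(y), fv = as_int_vec(folds);

  std::vector<int> active(p);
  for (int j = 0; j < p; ++j) active[j] = j;
  std::vector<int> elim_order;          // gene indices in elimination order
  std::vector<int> rec_sizes;           // recorded subset sizes (descending)
  std::vector<double> rec_accs;
  std::vector<int> rec_elim;            // #eliminated before each record

  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  std::vector<double> Xa, W;

  for (;;) {
    const int a = static_cast<int>(active.size());
    rec_sizes.push_back(a);
    rec_elim.push_back(static_cast<int>(elim_order.size()));
    rec_accs.push_back(
        cv_accuracy(REAL(X), p, yv, k, fv, nfolds, active, C, eps, max_epochs));
    if (a <= min_genes) break;

    gather(REAL(X), p, active, all, Xa);
    W.assign(static_cast<size_t>(k) * (a + 1), 0.0);
    fit_ovr(Xa.data(), a, n, yv, k, C, eps, max_epochs, W);
    std::vector<double> rank(a, 0.0);
    for (int c = 0; c < k; ++c)
      for (int j = 0; j < a; ++j) {
        const double wj = W[static_cast<size_t>(c) * (a + 1) + j];
        rank[j] += wj * wj;
      }
    const int ndrop = std::min(step, a - min_genes);
    std::vector<int> idx(a);
    for (int j = 0; j < a; ++j) idx[j] = j;
    std::partial_sort(idx.begin(), idx.begin() + ndrop, idx.end(),
                      [&](int u, int v) {
                        if (rank[u] != rank[v]) return rank[u] < rank[v];
                        return active[u] < active[v]; // deterministic ties
                      });
    std::vector<bool> drop(a, false);
    for (int d = 0; d < ndrop; ++d) {
      drop[idx[d]] = true;
      elim_order.push_back(active[idx[d]]);
    }
    std::vector<int> keep;
    keep.reserve(a - ndrop);
    for (int j = 0; j < a; ++j)
      if (!drop[j]) keep.push_back(active[j]);
    active.swap(keep);
  }

  // smallest size attaining the maximum accuracy (sizes recorded descending)
  double best_acc = rec_accs[0];
  for (double v : rec_accs) best_acc = std::max(best_acc, v);
  int best_idx = 0;
  for (size_t i = 0; i < rec_accs.size(); ++i)
    if (rec_accs[i] == best_acc) best_idx = static_cast<int>(i);

  std::vector<bool> eliminated(p, false);
  for (int d = 0; d < rec_elim[best_idx]; ++d) eliminated[elim_order[d]] = true;
  std::vector<int> best_genes;
  for (int j = 0; j < p; ++j)
    if (!eliminated[j]) best_genes.push_back(j);

  const int a = static_cast<int>(best_genes.size());
  gather(REAL(X), p, best_genes, all, Xa);
  W.assign(static_cast<size_t>(k) * (a + 1), 0.0);
  fit_ovr(Xa.data(), a, n, yv, k, C, eps, max_epochs, W);
  NumericMatrix Wout(k, a + 1);
  for (int c = 0; c < k; ++c)
    for (int j = 0; j <= a; ++j)
      Wout(c, j) = W[static_cast<size_t>(c) * (a + 1) + j];

  return List::create(
      _["sizes"] = IntegerVector(rec_sizes.begin(), rec_sizes.end()),
      _["accuracies"] = NumericVector(rec_accs.begin(), rec_accs.end()),
      _["best_size"] = a, _["best_accuracy"] = best_acc,
      _["genes"] = IntegerVector(best_genes.begin(), best_genes.end()),
      _["weights"] = Wout);
}
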