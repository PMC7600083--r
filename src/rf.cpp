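// Regression random forest: CART with variance-reduction splits, per-tree
// subsampling WITHOUT replacement (train fraction configurable, default 2/3
// so the held-out third is the out-of-bag set), OOB predictions and
// permutation (MSE-increase) importance. All randomness uses R's RNG so that
// set.seed() in R makes fits reproducible.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Forest {
  // flattened node arrays, one tree after another
  std::vector<int> var;       // split variable (0-based), -1 => leaf
  std::vector<double> split;  // threshold: x <= split goes left
  std::vector<int> left, right;
  std::vector<double> pred;   // leaf prediction (node mean)
};

int runif_int(int n) {  // uniform on 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// grow one node over idx[lo,hi); returns node id
int grow(const NumericMatrix& X, const NumericVector& y,
         std::vector<int>& idx, int lo, int hi,
         int mtry, int min_node, Forest& f,
         std::vector<int>& varpool, std::vector<int>& used_vars) {
  const int n = hi - lo;
  double sum = 0.0, ss = 0.0;
  for (int k = lo; k < hi; ++k) { sum += y[idx[k]]; }
  const double mean = sum / n;
  for (int k = lo; k < hi; ++k) { double d = y[idx[k]] - mean; ss += d * d; }

  int node = (int)f.var.size();
  f.var.push_back(-1); f.split.push_back(0.0);
  f.left.push_back(-1); f.right.push_back(-1); f.pred.push_back(mean);
  if (n < 2 * min_node || ss <= 1e-12) return node;

  const int p = X.ncol();
  // partial Fisher-Yates draw of mtry candidate variables
  for (int j = 0; j < p; ++j) varpool[j] = j;
  int best_var = -1, best_pos = -1;
  double best_gain = 0.0, best_split = 0.0;

  std::vector<std::pair<double, int> > xv(n);
  for (int m = 0; m < mtry; ++m) {
    int r = m + runif_int(p - m);
    std::swap(varpool[m], varpool[r]);
    const int j = varpool[m];
    for (int k = 0; k < n; ++k)
      xv[k] = std::make_pair(X(idx[lo + k], j), idx[lo + k]);
    std::sort(xv.begin(), xv.end());
    if (xv.front().first >= xv.back().first) continue;  // constant in node
    // scan split positions; children must each have >= min_node rows
    double lsum = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      lsum += y[xv[k].second];
      if (k + 1 < min_node || n - k - 1 < min_node) continue;
      if (xv[k + 1].first <= xv[k].first) continue;  // tie, not a valid cut
      const int nl = k + 1, nr = n - nl;
      const double rsum = sum - lsum;
      const double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
      if (gain > best_gain + 1e-12) {
        best_gain = gain; best_var = j; best_pos = k;
        best_split = 0.5 * (xv[k].first + xv[k + 1].first);
      }
    }
  }
  if (best_var < 0) return node;

  // partition idx[lo,hi) by the chosen split (stable two-pass)
  std::vector<int> lbuf, rbuf;
  lbuf.reserve(n); rbuf.reserve(n);
  for (int k = lo; k < hi; ++k) {
    if (X(idx[k], best_var) <= best_split) lbuf.push_back(idx[k]);
    else rbuf.push_back(idx[k]);
  }
  for (size_t k = 0; k < lbuf.size(); ++k) idx[lo + k] = lbuf[k];
  for (size_t k = 0; k < rbuf.size(); ++k) idx[lo + lbuf.size() + k] = rbuf[k];

  f.var[node] = best_var; f.split[node] = best_split;
  used_vars.push_back(best_var);
  int mid = lo + (int)lbuf.size();
  f.left[node] = grow(X, y, idx, lo, mid, mtry, min_node, f, varpool, used_vars);
  f.right[node] = grow(X, y, idx, mid, hi, mtry, min_node, f, varpool, used_vars);
  return node;
}

double predict_row(const Forest& f, int root, const std::vector<double>& x) {
  int node = root;
  while (f.var[node] >= 0)
    node = (x[f.var[node]] <= f.split[node]) ? f.left[node] : f.right[node];
  return f.pred[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_node, double train_frac, bool importance) {
  const int n = X.nrow(), p = X.ncol();
  const int ntrain = std::max(2, (int)std::ceil(train_frac * n));
  if (ntrain >= n && importance)
    stop("train_frac leaves no out-of-bag samples");
  RNGScope scope;

  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_cnt(n, 0);
  NumericVector imp(p, 0.0);
  IntegerVector imp_cnt(p, 0);

  std::vector<int> perm(n), idx(ntrain), varpool(p), used_vars;
  std::vector<double> xrow(p);

  for (int t = 0; t < ntree; ++t) {
    // subsample without replacement: first ntrain of a partial shuffle
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = 0; i < ntrain; ++i) {
      int r = i + runif_int(n - i);
      std::swap(perm[i], perm[r]);
    }
    for (int i = 0; i < ntrain; ++i) idx[i] = perm[i];

    Forest f;
    used_vars.clear();
    int root = grow(X, y, idx, 0, ntrain, mtry, min_node, f, varpool, used_vars);

    const int noob = n - ntrain;
    if (noob == 0) continue;
    // local OOB copy so importance can shuffle columns in place
    std::vector<std::vector<double> > Xo(noob, std::vector<double>(p));
    std::vector<double> yo(noob), po(noob);
    for (int i = 0; i < noob; ++i) {
      const int r = perm[ntrain + i];
      for (int j = 0; j < p; ++j) Xo[i][j] = X(r, j);
      yo[i] = y[r];
      po[i] = predict_row(f, root, Xo[i]);
      oob_sum[r] += po[i];
      oob_cnt[r] += 1;
    }
    if (!importance) continue;

    double mse0 = 0.0;
    for (int i = 0; i < noob; ++i) { double d = yo[i] - po[i]; mse0 += d * d; }
    mse0 /= noob;

    std::sort(used_vars.begin(), used_vars.end());
    used_vars.erase(std::unique(used_vars.begin(), used_vars.end()),
                    used_vars.end());
    std::vector<double> col(noob);
    for (size_t u = 0; u < used_vars.size(); ++u) {
      const int j = used_vars[u];
      for (int i = 0; i < noob; ++i) col[i] = Xo[i][j];
      // Fisher-Yates shuffle of the OOB column
      for (int i = noob - 1; i > 0; --i) {
        int r = runif_int(i + 1);
        std::swap(col[i], col[r]);
      }
      double mse1 = 0.0;
      for (int i = 0; i < noob; ++i) {
        double saved = Xo[i][j];
        Xo[i][j] = col[i];
        double d = yo[i] - predict_row(f, root, Xo[i]);
        Xo[i][j] = saved;
        mse1 += d * d;
      }
      mse1 /= noob;
      imp[j] += (mse1 - mse0);
      imp_cnt[j] += 1;
    }
  }

  // average importance over ALL trees (vars unused in a tree contribute 0),
  // matching the mean-MSE-increase convention
  for (int j = 0; j < p; ++j) imp[j] /= ntree;

  NumericVector oob_pred(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (oob_cnt[i] > 0) oob_pred[i] = oob_sum[i] / oob_cnt[i];

  return List::create(_["oob_pred"] = oob_pred,
                      _["oob_count"] = oob_cnt,
                      _["importance"] = imp,
                      _["trees_using_var"] = imp_cnt);
}
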