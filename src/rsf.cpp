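// Random survival forest engine: log-rank splitting, Nelson-Aalen terminal
// nodes, ensemble prediction on the cumulative-hazard scale.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Standardized log-rank statistic for a two-group split of one node.
// rows: positions of node members (bootstrap multiset, indices into time/event)
// ord:  permutation of 0..m-1 sorting rows by time ascending
// isleft: per position in rows
// Variance term ((Y-d)/(Y-1)) d (Y_L/Y)(1 - Y_L/Y) summed over distinct
// event times; terms with Y == 1 contribute nothing.
double logrank_stat(const std::vector<int>& rows, const std::vector<int>& ord,
                    const double* time, const int* event,
                    const std::vector<char>& isleft) {
  const int m = (int)rows.size();
  double num = 0.0, var = 0.0;
  int Y = m;
  int YL = 0;
  for (int i = 0; i < m; ++i) if (isleft[i]) ++YL;
  int i = 0;
  while (i < m) {
    double t = time[rows[ord[i]]];
    int d = 0, dL = 0, grp = 0;
    int j = i;
    while (j < m && time[rows[ord[j]]] == t) {
      if (event[rows[ord[j]]]) { ++d; if (isleft[ord[j]]) ++dL; }
      ++grp; ++j;
    }
    if (d > 0) {
      double fl = (double)YL / (double)Y;
      num += dL - fl * d;
      if (Y > 1)
        var += fl * (1.0 - fl) * ((double)(Y - d) / (double)(Y - 1)) * d;
    }
    // remove this tied group from both risk sets
    for (int k = i; k < j; ++k) if (isleft[ord[k]]) --YL;
    Y -= grp;
    i = j;
  }
  if (var <= 0.0) return 0.0;
  return std::fabs(num) / std::sqrt(var);
}

struct TreeBuf {
  std::vector<int> var;         // split variable, -1 for leaf
  std::vector<double> val;      // split value (<= goes left)
  std::vector<int> left, right; // child node ids
  std::vector<int> leafid;      // leaf index, -1 for internal
  std::vector<int> leaf_off;    // CSR offsets into leaf_idx/leaf_dh
  std::vector<int> leaf_idx;    // global grid indices of event times
  std::vector<double> leaf_dh;  // hazard increments d/Y
};

int count_unique_deaths(const std::vector<int>& rows, const double* time,
                        const int* event) {
  std::vector<double> et;
  for (int r : rows) if (event[r]) et.push_back(time[r]);
  if (et.empty()) return 0;
  std::sort(et.begin(), et.end());
  int u = 1;
  for (size_t i = 1; i < et.size(); ++i) if (et[i] != et[i - 1]) ++u;
  return u;
}

// Nelson-Aalen increments of a terminal node from its in-bag multiset.
void leaf_hazard(const std::vector<int>& rows, const double* time,
                 const int* event, const int* evgrid, TreeBuf& tb) {
  std::vector<int> ord(rows.size());
  for (size_t i = 0; i < rows.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return time[rows[a]] < time[rows[b]];
  });
  int m = (int)rows.size();
  int Y = m, i = 0;
  while (i < m) {
    double t = time[rows[ord[i]]];
    int d = 0, grp = 0, gidx = -1;
    int j = i;
    while (j < m && time[rows[ord[j]]] == t) {
      if (event[rows[ord[j]]]) { ++d; gidx = evgrid[rows[ord[j]]]; }
      ++grp; ++j;
    }
    if (d > 0) {
      tb.leaf_idx.push_back(gidx);
      tb.leaf_dh.push_back((double)d / (double)Y);
    }
    Y -= grp;
    i = j;
  }
}

struct SplitResult {
  int var = -1;
  double val = 0.0;
  double stat = 0.0;
};

// Find best log-rank split over `mtry` sampled columns; candidate cutpoints
// are midpoints of sorted unique in-node values, at most ncand per column.
SplitResult find_split(const std::vector<int>& rows, const NumericMatrix& X,
                       const double* time, const int* event, int mtry,
                       int ncand, std::mt19937_64& rng) {
  const int p = X.ncol();
  const int m = (int)rows.size();
  SplitResult best;

  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return time[rows[a]] < time[rows[b]];
  });

  // sample mtry distinct columns (partial Fisher-Yates)
  std::vector<int> cols(p);
  for (int i = 0; i < p; ++i) cols[i] = i;
  int ms = std::min(mtry, p);
  for (int i = 0; i < ms; ++i) {
    std::uniform_int_distribution<int> u(i, p - 1);
    std::swap(cols[i], cols[u(rng)]);
  }

  std::vector<char> isleft(m);
  std::vector<double> vals(m), cuts;
  for (int ci = 0; ci < ms; ++ci) {
    int v = cols[ci];
    for (int i = 0; i < m; ++i) vals[i] = X(rows[i], v);
    std::vector<double> uq(vals);
    std::sort(uq.begin(), uq.end());
    uq.erase(std::unique(uq.begin(), uq.end()), uq.end());
    if (uq.size() < 2) continue;
    cuts.clear();
    for (size_t i = 0; i + 1 < uq.size(); ++i)
      cuts.push_back(0.5 * (uq[i] + uq[i + 1]));
    if ((int)cuts.size() > ncand) {
      for (int i = 0; i < ncand; ++i) {
        std::uniform_int_distribution<int> u(i, (int)cuts.size() - 1);
        std::swap(cuts[i], cuts[u(rng)]);
      }
      cuts.resize(ncand);
    }
    for (double c : cuts) {
      int nl = 0;
      for (int i = 0; i < m; ++i) {
        isleft[i] = (char)(vals[i] <= c);
        if (isleft[i]) ++nl;
      }
      if (nl == 0 || nl == m) continue;
      double s = logrank_stat(rows, ord, time, event, isleft);
      if (s > best.stat) { best.stat = s; best.var = v; best.val = c; }
    }
  }
  return best;
}

void grow_node(std::vector<int>& rows, const NumericMatrix& X,
               const double* time, const int* event, const int* evgrid,
               int mtry, int min_deaths, int ncand, std::mt19937_64& rng,
               TreeBuf& tb, int node_id) {
  bool make_leaf = ((int)rows.size() < 2) ||
                   (count_unique_deaths(rows, time, event) < min_deaths);
  SplitResult sp;
  if (!make_leaf) {
    sp = find_split(rows, X, time, event, mtry, ncand, rng);
    if (sp.var < 0 || sp.stat <= 1e-12) make_leaf = true;
  }
  if (make_leaf) {
    tb.var[node_id] = -1;
    int lid = (int)tb.leaf_off.size() - 1;
    tb.leafid[node_id] = lid;
    leaf_hazard(rows, time, event, evgrid, tb);
    tb.leaf_off.push_back((int)tb.leaf_idx.size());
    return;
  }
  std::vector<int> lrows, rrows;
  for (int r : rows) {
    if (X(r, sp.var) <= sp.val) lrows.push_back(r); else rrows.push_back(r);
  }
  rows.clear(); rows.shrink_to_fit();
  int lid = (int)tb.var.size(), rid = lid + 1;
  tb.var.push_back(0); tb.val.push_back(0); tb.left.push_back(-1);
  tb.right.push_back(-1); tb.leafid.push_back(-1);
  tb.var.push_back(0); tb.val.push_back(0); tb.left.push_back(-1);
  tb.right.push_back(-1); tb.leafid.push_back(-1);
  tb.var[node_id] = sp.var;
  tb.val[node_id] = sp.val;
  tb.left[node_id] = lid;
  tb.right[node_id] = rid;
  grow_node(lrows, X, time, event, evgrid, mtry, min_deaths, ncand, rng, tb, lid);
  grow_node(rrows, X, time, event, evgrid, mtry, min_deaths, ncand, rng, tb, rid);
}

} // namespace

// [[Rcpp::export(name = ".rsf_grow")]]
List rsf_grow(NumericMatrix X, NumericVector time, IntegerVector event,
              IntegerVector evgrid, int ntree, int mtry, int min_deaths,
              int ncand, double seed, bool bootstrap) {
  const int n = X.nrow();
  List trees(ntree);
  IntegerMatrix inbag(n, ntree);
  for (int t = 0; t < ntree; ++t) {
    std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + (uint64_t)t + 1ULL);
    std::vector<int> rows;
    rows.reserve(n);
    if (bootstrap) {
      std::uniform_int_distribution<int> u(0, n - 1);
      for (int i = 0; i < n; ++i) {
        int r = u(rng);
        rows.push_back(r);
        inbag(r, t) += 1;
      }
    } else {
      for (int i = 0; i < n; ++i) { rows.push_back(i); inbag(i, t) = 1; }
    }
    TreeBuf tb;
    tb.var.push_back(0); tb.val.push_back(0); tb.left.push_back(-1);
    tb.right.push_back(-1); tb.leafid.push_back(-1);
    tb.leaf_off.push_back(0);
    grow_node(rows, X, REAL(time), INTEGER(event), INTEGER(evgrid), mtry,
              min_deaths, ncand, rng, tb, 0);
    int K = (int)tb.var.size();
    IntegerMatrix nodes(K, 4);
    NumericVector val(K);
    for (int k = 0; k < K; ++k) {
      nodes(k, 0) = tb.var[k];
      nodes(k, 1) = tb.left[k];
      nodes(k, 2) = tb.right[k];
      nodes(k, 3) = tb.leafid[k];
      val[k] = tb.val[k];
    }
    trees[t] = List::create(
      _["nodes"] = nodes, _["val"] = val,
      _["leaf_off"] = wrap(tb.leaf_off),
      _["leaf_idx"] = wrap(tb.leaf_idx),
      _["leaf_dh"] = wrap(tb.leaf_dh));
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// Ensemble cumulative hazard on the forest grid. When oob is true, X must be
// the training matrix (same row order) and inbag the training in-bag counts;
// rows never out of bag get NaN (caller raises).
// [[Rcpp::export(name = ".rsf_chf")]]
NumericMatrix rsf_chf(List trees, NumericMatrix X, int ngrid,
                      IntegerMatrix inbag, bool oob) {
  const int n = X.nrow();
  const int T = trees.size();
  NumericMatrix H(n, ngrid);
  std::vector<double> acc(ngrid);

  // pre-extract tree components
  std::vector<IntegerMatrix> nodes(T);
  std::vector<NumericVector> vals(T);
  std::vector<IntegerVector> loff(T), lidx(T);
  std::vector<NumericVector> ldh(T);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    nodes[t] = as<IntegerMatrix>(tr["nodes"]);
    vals[t] = as<NumericVector>(tr["val"]);
    loff[t] = as<IntegerVector>(tr["leaf_off"]);
    lidx[t] = as<IntegerVector>(tr["leaf_idx"]);
    ldh[t] = as<NumericVector>(tr["leaf_dh"]);
  }

  for (int r = 0; r < n; ++r) {
    std::fill(acc.begin(), acc.end(), 0.0);
    int used = 0;
    for (int t = 0; t < T; ++t) {
      if (oob && inbag(r, t) > 0) continue;
      const IntegerMatrix& nd = nodes[t];
      int k = 0;
      while (nd(k, 0) >= 0) {
        k = (X(r, nd(k, 0)) <= vals[t][k]) ? nd(k, 1) : nd(k, 2);
      }
      int lf = nd(k, 3);
      for (int j = loff[t][lf]; j < loff[t][lf + 1]; ++j)
        acc[lidx[t][j]] += ldh[t][j];
      ++used;
    }
    if (used == 0) {
      for (int g = 0; g < ngrid; ++g) H(r, g) = NA_REAL;
    } else {
      double cum = 0.0;
      for (int g = 0; g < ngrid; ++g) {
        cum += acc[g];
        H(r, g) = cum / used;
      }
    }
  }
  return H;
}

// Standalone standardized log-rank statistic (exported for testing and reuse).
// [[Rcpp::export(name = ".logrank_stat")]]
double logrank_stat_r(NumericVector time, IntegerVector event,
                      LogicalVector left) {
  int m = time.size();
  std::vector<int> rows(m), ord(m);
  std::vector<char> isleft(m);
  for (int i = 0; i < m; ++i) {
    rows[i] = i; ord[i] = i; isleft[i] = (char)(left[i] == TRUE);
  }
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return time[a] < time[b];
  });
  return logrank_stat(rows, ord, REAL(time), INTEGER(event), isleft);
}

// Exhaustive best split over all columns and all midpoint cutpoints
// (no sampling); used to check the forest's split finder.
// [[Rcpp::export(name = ".rsf_best_split")]]
List rsf_best_split(NumericMatrix X, NumericVector time, IntegerVector event) {
  int n = X.nrow();
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  std::mt19937_64 rng(1);
  SplitResult sp = find_split(rows, X, REAL(time), INTEGER(event), X.ncol(),
                              1 << 30, rng);
  return List::create(_["var"] = sp.var + 1, _["val"] = sp.val,
                      _["stat"] = sp.stat);
}
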