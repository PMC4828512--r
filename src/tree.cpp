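#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Depth-limited CART-style tree with weighted Gini impurity, grown on a row
// subset of a shared feature matrix. Two split-search modes:
//  * exact: sort the node's values per feature, candidate thresholds are the
//    midpoints between consecutive distinct values (used when the node holds
//    at most `exact_cutoff` rows, and always when no binned matrix is given);
//  * histogram: weighted class counts per precomputed quantile bin, candidate
//    thresholds are the bin edges. Histograms are accumulated branchlessly
//    (total weight + label-signed weight) and a node's larger child inherits
//    its histogram by subtraction from the parent, so each level costs about
//    1.5 scans of the node rather than 2.
// Ties are broken deterministically: first (lowest-index) feature, then
// lowest threshold, via strict-improvement scanning in ascending order.

struct TreeAcc {
  std::vector<int> feature;      // 1-based feature index, NA_INTEGER at leaves
  std::vector<double> threshold; // split x <= thr goes left
  std::vector<int> left, right;  // 1-based node ids, NA_INTEGER at leaves
  std::vector<double> conf_pos;  // weighted fraction of +1 in the node
  std::vector<int> n_node;
};

struct Ctx {
  const double *X; const Rbyte *B;
  size_t n; int p; bool has_bins;
  const int *y;            // +1 / -1, full-length
  std::vector<int> nedges; // edges per feature
  std::vector<const double *> edges;
  int max_depth, exact_cutoff;
  int nbins;
};

static const double EPS_IMP = 1e-12;

// Per-node data: row indices plus aligned weights and signed weights.
struct NodeData {
  std::vector<int> idx;
  std::vector<double> w, sw; // sw = +w for y=+1, -w for y=-1
};

typedef std::vector<double> Hist; // layout: f * 2*nbins + (hw | hs)

static void scan_hist(const Ctx &ctx, const NodeData &nd, Hist &H) {
  const int nb = ctx.nbins;
  std::fill(H.begin(), H.end(), 0.0);
  const size_t m = nd.idx.size();
  for (int f = 0; f < ctx.p; f++) {
    if (ctx.nedges[f] == 0) continue;
    const Rbyte *col = ctx.B + (size_t)f * ctx.n;
    double *hw = &H[(size_t)f * 2 * nb];
    double *hs = hw + nb;
    for (size_t k = 0; k < m; k++) {
      const int b = col[nd.idx[k]];
      hw[b] += nd.w[k];
      hs[b] += nd.sw[k];
    }
  }
}

static int grow(Ctx &ctx, TreeAcc &acc, NodeData &nd, int depth,
                Hist *hist_in) {
  const size_t m = nd.idx.size();
  double wtot = 0.0, stot = 0.0;
  for (size_t k = 0; k < m; k++) { wtot += nd.w[k]; stot += nd.sw[k]; }
  const double wpos = (wtot + stot) / 2.0, wneg = wtot - wpos;

  const int id = (int)acc.feature.size();
  acc.feature.push_back(NA_INTEGER);
  acc.threshold.push_back(NA_REAL);
  acc.left.push_back(NA_INTEGER);
  acc.right.push_back(NA_INTEGER);
  acc.conf_pos.push_back(wtot > 0 ? wpos / wtot : 0.5);
  acc.n_node.push_back((int)m);

  if (depth >= ctx.max_depth || m < 2 || wpos <= 0.0 || wneg <= 0.0 ||
      wtot <= 0.0)
    return id;

  const double parent_score = wtot - (wpos * wpos + wneg * wneg) / wtot;
  double best_score = parent_score - EPS_IMP;
  int best_f = -1;
  double best_thr = 0.0;
  const bool use_exact = !ctx.has_bins || (int)m <= ctx.exact_cutoff;

  Hist own;
  const Hist *H = hist_in;
  if (!use_exact && H == NULL) {
    own.resize((size_t)ctx.p * 2 * ctx.nbins);
    scan_hist(ctx, nd, own);
    H = &own;
  }

  if (use_exact) {
    std::vector<std::pair<double, int> > sv(m);
    for (int f = 0; f < ctx.p; f++) {
      const double *col = ctx.X + (size_t)f * ctx.n;
      for (size_t k = 0; k < m; k++)
        sv[k] = std::make_pair(col[nd.idx[k]], (int)k);
      std::sort(sv.begin(), sv.end());
      double wl = 0.0, sl = 0.0;
      for (size_t k = 0; k + 1 < m; k++) {
        const int lk = sv[k].second;
        wl += nd.w[lk];
        sl += nd.sw[lk];
        if (sv[k].first >= sv[k + 1].first) continue;
        const double wr = wtot - wl;
        if (wl <= 0.0 || wr <= 0.0) continue;
        const double wlp = (wl + sl) / 2.0, wln = wl - wlp;
        const double wrp = wpos - wlp, wrn = wr - wrp;
        const double score = (wl - (wlp * wlp + wln * wln) / wl)
                           + (wr - (wrp * wrp + wrn * wrn) / wr);
        if (score < best_score) {
          best_score = score;
          best_f = f;
          best_thr = sv[k].first + (sv[k + 1].first - sv[k].first) / 2.0;
        }
      }
    }
  } else {
    const int nb = ctx.nbins;
    for (int f = 0; f < ctx.p; f++) {
      const int ne = ctx.nedges[f];
      if (ne == 0) continue;
      const double *hw = &(*H)[(size_t)f * 2 * nb];
      const double *hs = hw + nb;
      double wl = 0.0, sl = 0.0;
      for (int b = 0; b < ne; b++) { // split: bin <= b  <=>  x <= edges[b]
        wl += hw[b];
        sl += hs[b];
        const double wr = wtot - wl;
        if (wl <= 0.0 || wr <= 0.0) continue;
        const double wlp = (wl + sl) / 2.0, wln = wl - wlp;
        const double wrp = wpos - wlp, wrn = wr - wrp;
        const double score = (wl - (wlp * wlp + wln * wln) / wl)
                           + (wr - (wrp * wrp + wrn * wrn) / wr);
        if (score < best_score) {
          best_score = score;
          best_f = f;
          best_thr = ctx.edges[f][b];
        }
      }
    }
  }

  if (best_f < 0) return id;

  NodeData left, right;
  const double *col = ctx.X + (size_t)best_f * ctx.n;
  for (size_t k = 0; k < m; k++) {
    NodeData &dst = (col[nd.idx[k]] <= best_thr) ? left : right;
    dst.idx.push_back(nd.idx[k]);
    dst.w.push_back(nd.w[k]);
    dst.sw.push_back(nd.sw[k]);
  }
  if (left.idx.empty() || right.idx.empty()) return id;

  acc.feature[id] = best_f + 1;
  acc.threshold[id] = best_thr;

  // Sibling-subtraction: scan the smaller child, derive the larger one from
  // this node's histogram (only meaningful in the histogram regime).
  Hist small_hist;
  Hist *lh = NULL, *rh = NULL;
  if (!use_exact && H != NULL) {
    NodeData &small = (left.idx.size() <= right.idx.size()) ? left : right;
    small_hist.resize((size_t)ctx.p * 2 * ctx.nbins);
    scan_hist(ctx, small, small_hist);
    // reuse: larger child's hist = parent - smaller (overwrite `own` copy)
    if (hist_in == NULL) {
      for (size_t i = 0; i < own.size(); i++) own[i] -= small_hist[i];
      if (&small == &left) { lh = &small_hist; rh = &own; }
      else                 { rh = &small_hist; lh = &own; }
    } else {
      Hist &par = *hist_in;
      for (size_t i = 0; i < par.size(); i++) par[i] -= small_hist[i];
      if (&small == &left) { lh = &small_hist; rh = &par; }
      else                 { rh = &small_hist; lh = &par; }
    }
  }
  { NodeData tmp; std::swap(tmp, nd); } // free this node's rows before recursing

  const int lid = grow(ctx, acc, left, depth + 1, lh);
  const int rid = grow(ctx, acc, right, depth + 1, rh);
  acc.left[id] = lid + 1;
  acc.right[id] = rid + 1;
  return id;
}

// [[Rcpp::export]]
List fit_tree_cpp(NumericMatrix X, IntegerVector y, IntegerVector idx,
                  NumericVector w, int max_depth, RawMatrix Xbin,
                  List edges, int exact_cutoff) {
  Ctx ctx;
  ctx.X = REAL(X);
  ctx.n = X.nrow();
  ctx.p = X.ncol();
  ctx.y = INTEGER(y);
  ctx.has_bins = Xbin.nrow() == X.nrow() && Xbin.ncol() == X.ncol() &&
                 X.ncol() > 0;
  ctx.B = ctx.has_bins ? RAW(Xbin) : NULL;
  ctx.max_depth = max_depth;
  ctx.exact_cutoff = exact_cutoff;
  ctx.nedges.resize(ctx.p);
  ctx.edges.resize(ctx.p);
  int nbins = 1;
  for (int f = 0; f < ctx.p; f++) {
    NumericVector ed = edges[f];
    ctx.nedges[f] = ed.size();
    ctx.edges[f] = REAL(ed);
    if (ed.size() + 1 > nbins) nbins = ed.size() + 1;
  }
  ctx.nbins = nbins;

  NodeData root;
  const int mm = idx.size();
  root.idx.resize(mm); root.w.resize(mm); root.sw.resize(mm);
  for (int k = 0; k < mm; k++) {
    const int i = idx[k] - 1; // to 0-based rows
    root.idx[k] = i;
    root.w[k] = w[k];
    root.sw[k] = ctx.y[i] > 0 ? w[k] : -w[k];
  }
  TreeAcc acc;
  grow(ctx, acc, root, 0, NULL);
  return List::create(
    _["feature"] = wrap(acc.feature),
    _["threshold"] = wrap(acc.threshold),
    _["left"] = wrap(acc.left),
    _["right"] = wrap(acc.right),
    _["conf_pos"] = wrap(acc.conf_pos),
    _["n_node"] = wrap(acc.n_node));
}

// [[Rcpp::export]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector conf = tree["conf_pos"];
  const size_t n = X.nrow();
  const double *Xp = REAL(X);
  NumericVector out(n);
  for (size_t i = 0; i < n; i++) {
    int node = 0;
    while (feature[node] != NA_INTEGER) {
      double v = Xp[i + n * (size_t)(feature[node] - 1)];
      node = (v <= threshold[node] ? left[node] : right[node]) - 1;
    }
    out[i] = conf[node];
  }
  return out;
}

// Quantile-bin a numeric matrix: bin(x) = number of edges strictly < x,
// so the split "bin <= b" is exactly "x <= edges[b]".
// [[Rcpp::export]]
RawMatrix bin_matrix_cpp(NumericMatrix X, List edges) {
  const size_t n = X.nrow();
  const int p = X.ncol();
  RawMatrix B(n, p);
  for (int f = 0; f < p; f++) {
    NumericVector ed = edges[f];
    const double *col = REAL(X) + (size_t)f * n;
    Rbyte *bcol = RAW(B) + (size_t)f * n;
    for (size_t i = 0; i < n; i++) {
      int b = (int)(std::lower_bound(ed.begin(), ed.end(), col[i]) -
                    ed.begin());
      bcol[i] = (Rbyte)b;
    }
  }
  return B;
}
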