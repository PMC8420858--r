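#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// All randomness goes through R's RNG so that set.seed() on the R side
// makes trees bit-reproducible.

static inline int runif_index(int n) {
  return (int) R_unif_index((double) n);
}

// k indices sampled without replacement from 0..(n-1), partial Fisher-Yates.
static std::vector<int> sample_wor(int k, int n) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  std::vector<int> out(k);
  for (int i = 0; i < k; ++i) {
    int j = i + runif_index(n - i);
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
  return out;
}

// Multivariate (pseudo-response) split search over one node.
//
// For a candidate variable v, cases with X[,v] missing are discarded.
// Candidate split points are midpoints between consecutive distinct in-node
// values.  The split statistic is the sum over pseudo-response coordinates of
// within-daughter sums of squared deviations, computed on non-missing
// response values only, weighted by bootstrap multiplicity.  Ties are broken
// deterministically: lowest variable index, then lowest split value
// (candidates are scanned in ascending order with strict improvement).
// When random_ties is true, exact ties of the split statistic (within a tiny
// relative tolerance; typically distinct variables inducing the identical
// case partition in a small node) are resolved uniformly at random via
// reservoir sampling, which keeps the statistic free of variable-index bias;
// when false, ties keep the lowest variable index, then the lowest split
// value.
static bool best_split_impl(const NumericMatrix& X, const NumericMatrix& Y,
                            const IntegerVector& wt,
                            const std::vector<int>& in_ids,
                            std::vector<int> cand,
                            const std::vector<int>& resp,
                            bool random_ties,
                            int& bvar, double& bval, double& bstat) {
  const int q = (int) resp.size();
  bvar = -1; bval = NA_REAL; bstat = R_PosInf;
  int n_tied = 1;
  std::sort(cand.begin(), cand.end());
  std::vector< std::pair<double,int> > xs;
  std::vector<double> T1(q), T2(q), TC(q), S1(q), S2(q), SC(q);

  for (size_t ci = 0; ci < cand.size(); ++ci) {
    const int v = cand[ci];
    xs.clear();
    for (size_t a = 0; a < in_ids.size(); ++a) {
      const int id = in_ids[a];
      const double x = X(id, v);
      if (!ISNAN(x)) xs.push_back(std::make_pair(x, id));
    }
    if ((int) xs.size() < 2) continue;
    std::sort(xs.begin(), xs.end());
    if (xs.front().first == xs.back().first) continue;

    std::fill(T1.begin(), T1.end(), 0.0);
    std::fill(T2.begin(), T2.end(), 0.0);
    std::fill(TC.begin(), TC.end(), 0.0);
    for (size_t a = 0; a < xs.size(); ++a) {
      const int id = xs[a].second;
      const double w = (double) wt[id];
      for (int k = 0; k < q; ++k) {
        const double y = Y(id, resp[k]);
        if (!ISNAN(y)) { T1[k] += w * y; T2[k] += w * y * y; TC[k] += w; }
      }
    }
    std::fill(S1.begin(), S1.end(), 0.0);
    std::fill(S2.begin(), S2.end(), 0.0);
    std::fill(SC.begin(), SC.end(), 0.0);
    for (size_t a = 0; a + 1 < xs.size(); ++a) {
      const int id = xs[a].second;
      const double w = (double) wt[id];
      for (int k = 0; k < q; ++k) {
        const double y = Y(id, resp[k]);
        if (!ISNAN(y)) { S1[k] += w * y; S2[k] += w * y * y; SC[k] += w; }
      }
      if (xs[a].first < xs[a + 1].first) {
        double D = 0.0;
        for (int k = 0; k < q; ++k) {
          if (SC[k] > 0) D += S2[k] - S1[k] * S1[k] / SC[k];
          const double rc = TC[k] - SC[k];
          if (rc > 0) {
            const double r1 = T1[k] - S1[k];
            D += (T2[k] - S2[k]) - r1 * r1 / rc;
          }
        }
        if (D < 0 && D > -1e-9) D = 0.0;  // guard tiny negative round-off
        const double tol =
          (bstat == R_PosInf) ? 0.0 : 1e-10 * (1.0 + std::fabs(bstat));
        bool take = false;
        if (D < bstat - tol) {
          take = true;
          n_tied = 1;
        } else if (random_ties && D <= bstat + tol) {
          // reservoir sampling over the tied optima
          ++n_tied;
          take = runif_index(n_tied) == 0;
        }
        if (take) {
          bstat = std::min(D, bstat);
          bvar = v;
          bval = (xs[a].first + xs[a + 1].first) / 2.0;
        }
      }
    }
  }
  return bvar >= 0;
}

// [[Rcpp::export]]
SEXP cpp_best_split(NumericMatrix X, NumericMatrix Y,
                    IntegerVector node_ids, IntegerVector cand,
                    IntegerVector resp) {
  std::vector<int> ids(node_ids.size());
  for (int i = 0; i < node_ids.size(); ++i) ids[i] = node_ids[i] - 1;
  std::vector<int> cv(cand.size()), rv(resp.size());
  for (int i = 0; i < cand.size(); ++i) cv[i] = cand[i] - 1;
  for (int i = 0; i < resp.size(); ++i) rv[i] = resp[i] - 1;
  IntegerVector wt(X.nrow(), 1);
  int bvar; double bval, bstat;
  if (!best_split_impl(X, Y, wt, ids, cv, rv, false, bvar, bval, bstat))
    return R_NilValue;
  return List::create(_["var"] = bvar + 1, _["value"] = bval,
                      _["stat"] = bstat);
}

struct TreeBuilder {
  const NumericMatrix& X;
  const NumericMatrix& Y;
  const IntegerVector& wt;          // in-bag multiplicity per case (0 = OOB)
  int n, p, py;
  int mtry, q, nodesize, max_depth; // max_depth < 0 means unlimited
  bool impute;
  NumericMatrix& imp_acc;           // n x p accumulator, modified in place
  const NumericVector& col_mean;    // observed column means (imputation fallback)
  int fb_inbag, fb_colmean;         // fallback counters

  std::vector<int> split_var, left, right, depth;
  std::vector<double> split_val;
  std::vector<int> term_of_case;    // 1-based node id per case

  TreeBuilder(const NumericMatrix& X_, const NumericMatrix& Y_,
              const IntegerVector& wt_, int mtry_, int q_, int nodesize_,
              int max_depth_, bool impute_, NumericMatrix& imp_acc_,
              const NumericVector& col_mean_)
    : X(X_), Y(Y_), wt(wt_), n(X_.nrow()), p(X_.ncol()), py(Y_.ncol()),
      mtry(mtry_), q(q_), nodesize(nodesize_), max_depth(max_depth_),
      impute(impute_), imp_acc(imp_acc_), col_mean(col_mean_),
      fb_inbag(0), fb_colmean(0), term_of_case(X_.nrow(), 0) {}

  void make_terminal(int me, const std::vector<int>& in_ids,
                     const std::vector<int>& oob_ids) {
    for (size_t a = 0; a < in_ids.size(); ++a) term_of_case[in_ids[a]] = me + 1;
    for (size_t a = 0; a < oob_ids.size(); ++a) term_of_case[oob_ids[a]] = me + 1;
    if (!impute) return;
    // Impute every missing cell of every member from OOB non-missing terminal
    // values of that column; fall back to in-bag values, then column mean.
    for (int g = 0; g < p; ++g) {
      double os = 0.0; int oc = 0;
      for (size_t a = 0; a < oob_ids.size(); ++a) {
        const double x = X(oob_ids[a], g);
        if (!ISNAN(x)) { os += x; ++oc; }
      }
      double is = 0.0, ic = 0.0;
      if (oc == 0) {
        for (size_t a = 0; a < in_ids.size(); ++a) {
          const double x = X(in_ids[a], g);
          if (!ISNAN(x)) { is += x * wt[in_ids[a]]; ic += wt[in_ids[a]]; }
        }
      }
      double val;
      if (oc > 0) val = os / oc;
      else if (ic > 0) { val = is / ic; ++fb_inbag; }
      else { val = col_mean[g]; ++fb_colmean; }
      for (size_t a = 0; a < in_ids.size(); ++a)
        if (ISNAN(X(in_ids[a], g))) imp_acc(in_ids[a], g) += val;
      for (size_t a = 0; a < oob_ids.size(); ++a)
        if (ISNAN(X(oob_ids[a], g))) imp_acc(oob_ids[a], g) += val;
    }
  }

  int grow(std::vector<int> in_ids, std::vector<int> oob_ids, int d) {
    const int me = (int) split_var.size();
    split_var.push_back(NA_INTEGER);
    split_val.push_back(NA_REAL);
    left.push_back(NA_INTEGER);
    right.push_back(NA_INTEGER);
    depth.push_back(d);

    long total = 0;
    for (size_t a = 0; a < in_ids.size(); ++a) total += wt[in_ids[a]];
    bool can = total >= 2L * nodesize && (max_depth < 0 || d < max_depth);

    int bvar = -1; double bval = 0.0, bstat = 0.0;
    if (can) {
      std::vector<int> resp = sample_wor(q, py);
      std::vector<int> cand = sample_wor(mtry, p);
      can = best_split_impl(X, Y, wt, in_ids, cand, resp, true,
                            bvar, bval, bstat);
    }
    if (!can) { make_terminal(me, in_ids, oob_ids); return me; }

    split_var[me] = bvar + 1;
    split_val[me] = bval;

    // In-node in-bag non-missing values of the split variable, cumulative
    // weights for random routing of cases whose split value is missing.
    std::vector<double> vals, cum;
    double wtot = 0.0;
    for (size_t a = 0; a < in_ids.size(); ++a) {
      const double x = X(in_ids[a], bvar);
      if (!ISNAN(x)) { wtot += wt[in_ids[a]]; vals.push_back(x); cum.push_back(wtot); }
    }

    std::vector<int> inL, inR, oobL, oobR;
    for (int pass = 0; pass < 2; ++pass) {
      const std::vector<int>& ids = (pass == 0) ? in_ids : oob_ids;
      std::vector<int>& L = (pass == 0) ? inL : oobL;
      std::vector<int>& R = (pass == 0) ? inR : oobR;
      for (size_t a = 0; a < ids.size(); ++a) {
        double x = X(ids[a], bvar);
        if (ISNAN(x)) {
          const double r = unif_rand() * wtot;
          size_t j = std::upper_bound(cum.begin(), cum.end(), r) - cum.begin();
          if (j >= vals.size()) j = vals.size() - 1;
          x = vals[j];
        }
        if (x <= bval) L.push_back(ids[a]); else R.push_back(ids[a]);
      }
    }
    in_ids.clear(); in_ids.shrink_to_fit();
    oob_ids.clear(); oob_ids.shrink_to_fit();

    const int l = grow(inL, oobL, d + 1);
    const int r = grow(inR, oobR, d + 1);
    left[me] = l + 1;
    right[me] = r + 1;
    return me;
  }
};

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, NumericMatrix Y, IntegerVector inbag_count,
                   int mtry, int q, int nodesize, int max_depth,
                   bool impute, NumericMatrix imp_acc, NumericVector col_mean) {
  const int n = X.nrow();
  TreeBuilder tb(X, Y, inbag_count, mtry, q, nodesize, max_depth,
                 impute, imp_acc, col_mean);
  std::vector<int> in_ids, oob_ids;
  for (int i = 0; i < n; ++i) {
    if (inbag_count[i] > 0) in_ids.push_back(i); else oob_ids.push_back(i);
  }
  tb.grow(in_ids, oob_ids, 0);
  return List::create(
    _["split_var"] = wrap(tb.split_var),
    _["split_value"] = wrap(tb.split_val),
    _["left"] = wrap(tb.left),
    _["right"] = wrap(tb.right),
    _["depth"] = wrap(tb.depth),
    _["term_of_case"] = wrap(tb.term_of_case),
    _["n_fallback_inbag"] = tb.fb_inbag,
    _["n_fallback_colmean"] = tb.fb_colmean);
}

// Single depth-first scan that accumulates, for every maximal v-subtree
// (v in the tracked variable subset), the within-subtree depth of the
// closest w-splitting node for every tracked w, and the subtree depth m.
// One observation of value d/m (or value_table[d] in CDF mode) per
// (maximal v-subtree, w) with at least one w split is added to sum_acc,
// and 1 to cnt_acc.
struct PairDepthScan {
  const IntegerVector& split_var;   // 1-based data variable, NA at terminals
  const IntegerVector& left;        // 1-based node ids, NA at terminals
  const IntegerVector& right;
  const IntegerVector& depth;
  const std::vector<int>& var_map;  // data var (0-based) -> subset index or -1
  int k;
  NumericMatrix& sum_acc;
  IntegerMatrix& cnt_acc;
  bool use_table;
  const NumericVector& table;

  struct Rec { int vsub; int root_depth; int m; std::vector<int> minw; };
  std::vector<Rec> recs;
  std::vector<int> open_count;      // per subset var, # active subtrees

  PairDepthScan(const IntegerVector& sv, const IntegerVector& l,
                const IntegerVector& r, const IntegerVector& d,
                const std::vector<int>& vm, int k_,
                NumericMatrix& s, IntegerMatrix& c,
                bool ut, const NumericVector& tab)
    : split_var(sv), left(l), right(r), depth(d), var_map(vm), k(k_),
      sum_acc(s), cnt_acc(c), use_table(ut), table(tab), open_count(k_, 0) {}

  void dfs(int node) {
    const bool terminal = (split_var[node] == NA_INTEGER);
    const int d = depth[node];
    int vsub = -1;
    if (!terminal) {
      const int v = split_var[node] - 1;
      if (v >= 0 && v < (int) var_map.size()) vsub = var_map[v];
    }
    // update active records
    for (size_t a = 0; a < recs.size(); ++a) {
      Rec& R = recs[a];
      const int rel = d - R.root_depth;
      if (terminal) {
        if (rel > R.m) R.m = rel;
      } else if (vsub >= 0 && vsub != R.vsub && rel < R.minw[vsub]) {
        R.minw[vsub] = rel;
      }
    }
    bool opened = false;
    if (!terminal && vsub >= 0 && open_count[vsub] == 0) {
      Rec R;
      R.vsub = vsub; R.root_depth = d; R.m = 0;
      R.minw.assign(k, INT_MAX);
      recs.push_back(R);
      ++open_count[vsub];
      opened = true;
    }
    if (!terminal) {
      dfs(left[node] - 1);
      dfs(right[node] - 1);
    }
    if (opened) {
      Rec& R = recs.back();
      for (int w = 0; w < k; ++w) {
        if (R.minw[w] == INT_MAX) continue;
        double val;
        if (use_table) {
          int dd = R.minw[w];
          if (dd >= table.size()) dd = table.size() - 1;
          val = table[dd];
        } else {
          val = (double) R.minw[w] / (double) R.m;
        }
        sum_acc(R.vsub, w) += val;
        cnt_acc(R.vsub, w) += 1;
      }
      --open_count[R.vsub];
      recs.pop_back();
    }
  }
};

// [[Rcpp::export(rng = false)]]
void cpp_pair_depth(IntegerVector split_var, IntegerVector left,
                    IntegerVector right, IntegerVector depth,
                    IntegerVector var_ids, int n_vars,
                    NumericMatrix sum_acc, IntegerMatrix cnt_acc,
                    Nullable<NumericVector> value_table) {
  const int k = var_ids.size();
  std::vector<int> var_map(n_vars, -1);
  for (int i = 0; i < k; ++i) var_map[var_ids[i] - 1] = i;
  NumericVector tab;
  bool ut = value_table.isNotNull();
  if (ut) tab = value_table.get();
  PairDepthScan scan(split_var, left, right, depth, var_map, k,
                     sum_acc, cnt_acc, ut, tab);
  scan.dfs(0);
}
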