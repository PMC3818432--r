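#include "ires_common.h"
using namespace Rcpp;

// Minimum-free-energy nested folding with a pluggable pair/stack scoring model.
//
// mode 0 ("bp"):  every pair scores -1, stacks score 0 (Nussinov-style
//                 base-pair maximisation expressed as an energy).
// mode 1 ("nn"):  pairs score 0, adjacent stacked pairs score the entry of a
//                 6x6 stack table indexed by (outer pair type, inner pair type).
//
// Ties are broken by (energy, number of pairs) lexicographically; traceback
// uses a fixed deterministic preference (leftmost position pairs with its
// smallest co-optimal partner; stacked continuations preferred inside a helix).

namespace {

struct Cell {
  double e;
  int np;
};

inline bool better(const Cell& x, const Cell& y) {
  const double eps = 1e-9;
  if (x.e < y.e - eps) return true;
  if (x.e > y.e + eps) return false;
  return x.np < y.np;
}

struct FoldDP {
  int n, mode, min_loop;
  const std::vector<int>* res;
  const NumericMatrix* stack;
  // E: optimal over interval; X: optimal excluding the (i,j) top-level pair;
  // C: optimal given (i,j) paired. Flattened (i * n + j), i<=j.
  std::vector<Cell> E, X, C;

  inline int id(int i, int j) const { return i * n + j; }

  inline double pcost() const { return mode == 0 ? -1.0 : 0.0; }

  inline double stack_e(int pt_out, int pt_in) const {
    return mode == 0 ? 0.0 : (*stack)(pt_out, pt_in);
  }

  inline Cell getE(int i, int j) const {
    if (i > j) return {0.0, 0};
    return E[id(i, j)];
  }
  inline Cell getX(int i, int j) const {
    if (i > j) return {0.0, 0};
    return X[id(i, j)];
  }

  void run() {
    E.assign(n * n, {0.0, 0});
    X.assign(n * n, {0.0, 0});
    C.assign(n * n, {1e100, 0});
    for (int span = 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // C(i,j): (i,j) paired
        if (span >= min_loop + 1 && pair_type((*res)[i], (*res)[j]) >= 0) {
          int pt = pair_type((*res)[i], (*res)[j]);
          Cell best = {1e100, 0};
          // stacked inner pair
          if (span - 2 >= min_loop + 1) {
            int pti = pair_type((*res)[i + 1], (*res)[j - 1]);
            if (pti >= 0) {
              Cell c = C[id(i + 1, j - 1)];
              if (c.e < 1e99) {
                Cell cand = {c.e + stack_e(pt, pti), c.np};
                if (better(cand, best)) best = cand;
              }
            }
          }
          // inner content without the (i+1, j-1) pair
          Cell x = getX(i + 1, j - 1);
          Cell cand = {x.e, x.np};
          if (better(cand, best)) best = cand;
          C[id(i, j)] = {best.e + pcost(), best.np + 1};
        }
        // E(i,j) and X(i,j): leftmost-position decomposition
        Cell bestE = getE(i + 1, j);  // i unpaired
        Cell bestX = bestE;
        for (int k = i + min_loop + 1; k <= j; ++k) {
          if (pair_type((*res)[i], (*res)[k]) < 0) continue;
          Cell c = C[id(i, k)];
          if (c.e > 1e99) continue;
          Cell rest = getE(k + 1, j);
          Cell cand = {c.e + rest.e, c.np + rest.np};
          if (better(cand, bestE)) bestE = cand;
          if (k < j && better(cand, bestX)) bestX = cand;
        }
        E[id(i, j)] = bestE;
        X[id(i, j)] = bestX;
      }
    }
  }

  // traceback helpers -------------------------------------------------------
  void traceC(int i, int j, std::vector<std::pair<int, int> >& arcs) const {
    arcs.push_back(std::make_pair(i, j));
    Cell target = C[id(i, j)];
    int pt = pair_type((*res)[i], (*res)[j]);
    double inner_e = target.e - pcost();
    int inner_np = target.np - 1;
    const double eps = 1e-9;
    // prefer the stacked continuation (keeps helices contiguous, deterministic)
    if (j - i - 2 >= min_loop + 1) {
      int pti = pair_type((*res)[i + 1], (*res)[j - 1]);
      if (pti >= 0) {
        Cell c = C[id(i + 1, j - 1)];
        if (c.e < 1e99 && std::abs(c.e + stack_e(pt, pti) - inner_e) < eps &&
            c.np == inner_np) {
          traceC(i + 1, j - 1, arcs);
          return;
        }
      }
    }
    traceEX(i + 1, j - 1, inner_e, inner_np, true, arcs);
  }

  // trace interval [i,j] whose optimal (possibly X-restricted) value is known
  void traceEX(int i, int j, double e, int np, bool exclude_ij,
               std::vector<std::pair<int, int> >& arcs) const {
    const double eps = 1e-9;
    while (i <= j) {
      if (np == 0) return;  // remaining structure empty
      bool advanced = false;
      // try pairing i with ascending k
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (exclude_ij && k == j) continue;
        if (pair_type((*res)[i], (*res)[k]) < 0) continue;
        Cell c = C[id(i, k)];
        if (c.e > 1e99) continue;
        Cell rest = getE(k + 1, j);
        if (std::abs(c.e + rest.e - e) < eps && c.np + rest.np == np) {
          traceC(i, k, arcs);
          i = k + 1;
          e = rest.e;
          np = rest.np;
          exclude_ij = false;
          advanced = true;
          break;
        }
      }
      if (advanced) continue;
      // i unpaired
      Cell r = getE(i + 1, j);
      // (must hold by construction)
      i = i + 1;
      e = r.e;
      np = r.np;
      exclude_ij = false;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_fold")]]
List cpp_fold(IntegerVector residues, int mode, NumericMatrix stack,
              int min_loop) {
  int n = residues.size();
  std::vector<int> res(residues.begin(), residues.end());
  if (n == 0) {
    return List::create(_["arcs"] = IntegerMatrix(0, 2), _["mfe"] = 0.0,
                        _["npairs"] = 0);
  }
  FoldDP dp;
  dp.n = n;
  dp.mode = mode;
  dp.min_loop = min_loop;
  dp.res = &res;
  dp.stack = &stack;
  dp.run();
  Cell opt = dp.getE(0, n - 1);
  std::vector<std::pair<int, int> > arcs;
  dp.traceEX(0, n - 1, opt.e, opt.np, false, arcs);
  IntegerMatrix am(arcs.size(), 2);
  for (size_t a = 0; a < arcs.size(); ++a) {
    am(a, 0) = arcs[a].first + 1;  // 1-based at the R boundary
    am(a, 1) = arcs[a].second + 1;
  }
  return List::create(_["arcs"] = am, _["mfe"] = opt.e, _["npairs"] = opt.np);
}
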