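#include "ires_common.h"
using namespace Rcpp;

// Global alignment of two nested arc-annotated sequences under the six-operation
// edit model (base match/mismatch/deletion, arc match/mismatch, arc-breaking,
// arc-altering, arc-removing).
//
// An unmatched ("dissolved") arc charges its cost on its two endpoints:
//   endpoint kept in an aligned column  -> arc_breaking/2 + usual base cost
//   endpoint deleted                    -> arc_removing/2
// so breaking = both kept, removing = both deleted, altering = one of each,
// which is exact when arc_altering == (arc_breaking + arc_removing)/2 (the
// default cost family; validated on the R side).
//
// Matched arcs are handled by a decomposition over arc pairs: G(x, y) is the
// optimal cost of aligning arc x of a to arc y of b including their interiors,
// computed bottom-up over spans. The top-level alignment is a prefix DP over
// the whole sequences in which an arc-match move at the right endpoints jumps
// across the whole arc using G. Per-column costs are position-local and are
// precomputed once per alignment.

namespace {

struct Aligner {
  int n, m;
  std::vector<int> ares, bres, apart, bpart;  // partners: -1 if unpaired
  double wdel, wmis, warcmis, wbreak, wremove;

  std::vector<std::pair<int, int> > arcsA, arcsB;  // sorted by span ascending
  std::vector<int> rightA, rightB;  // position -> arc id if right endpoint
  std::vector<double> G;            // arc-pair costs
  std::vector<double> SC;           // substitution column costs, n x m
  std::vector<double> GA, GB;       // per-position gap costs
  mutable std::vector<double> buf;  // window DP scratch

  void prepare() {
    rightA.assign(n, -1);
    rightB.assign(m, -1);
    for (int i = 0; i < n; ++i)
      if (apart[i] > i) arcsA.push_back(std::make_pair(i, apart[i]));
    for (int j = 0; j < m; ++j)
      if (bpart[j] > j) arcsB.push_back(std::make_pair(j, bpart[j]));
    auto by_span = [](const std::pair<int, int>& u,
                      const std::pair<int, int>& v) {
      int su = u.second - u.first, sv = v.second - v.first;
      if (su != sv) return su < sv;
      return u.first < v.first;
    };
    std::sort(arcsA.begin(), arcsA.end(), by_span);
    std::sort(arcsB.begin(), arcsB.end(), by_span);
    for (size_t x = 0; x < arcsA.size(); ++x) rightA[arcsA[x].second] = (int)x;
    for (size_t y = 0; y < arcsB.size(); ++y) rightB[arcsB[y].second] = (int)y;
    GA.resize(n);
    GB.resize(m);
    for (int p = 0; p < n; ++p)
      GA[p] = apart[p] >= 0 ? wremove / 2.0 : wdel;
    for (int q = 0; q < m; ++q)
      GB[q] = bpart[q] >= 0 ? wremove / 2.0 : wdel;
    SC.resize((size_t)n * m);
    for (int p = 0; p < n; ++p) {
      double extra = apart[p] >= 0 ? wbreak / 2.0 : 0.0;
      for (int q = 0; q < m; ++q) {
        double c = (ares[p] == bres[q]) ? 0.0 : wmis;  // N matches N only
        if (bpart[q] >= 0) c += wbreak / 2.0;
        SC[(size_t)p * m + q] = c + extra;
      }
    }
  }

  inline double arcSub(int x, int y) const {
    int l1 = arcsA[x].first, r1 = arcsA[x].second;
    int l2 = arcsB[y].first, r2 = arcsB[y].second;
    bool match = ares[l1] == bres[l2] && ares[r1] == bres[r2] &&
                 ares[l1] != 4 && ares[r1] != 4;
    return match ? 0.0 : warcmis;
  }

  // prefix DP over window [al..ar] x [bl..br] (inclusive; empty if lo > hi)
  double window(int al, int ar, int bl, int br, std::vector<double>& D) const {
    int la = ar - al + 1;
    if (la < 0) la = 0;
    int lb = br - bl + 1;
    if (lb < 0) lb = 0;
    size_t W = lb + 1;
    if (D.size() < (size_t)(la + 1) * W) D.resize((size_t)(la + 1) * W);
    D[0] = 0.0;
    for (int j = 1; j <= lb; ++j) D[j] = D[j - 1] + GB[bl + j - 1];
    size_t nb = arcsB.size();
    for (int i = 1; i <= la; ++i) {
      int p = al + i - 1;
      double* row = &D[i * W];
      const double* prev = &D[(i - 1) * W];
      double ga = GA[p];
      row[0] = prev[0] + ga;
      if (lb == 0) continue;
      const double* sc = SC.data() + (size_t)p * m + bl;
      int x = rightA[p];
      bool amove = x >= 0 && arcsA[x].first >= al;
      int li = amove ? arcsA[x].first - al : 0;
      const double* Grow = amove ? &G[(size_t)x * nb] : (const double*)0;
      const double* Drow = amove ? &D[li * W] : (const double*)0;
      for (int j = 1; j <= lb; ++j) {
        double best = prev[j] + ga;
        double c = row[j - 1] + GB[bl + j - 1];
        if (c < best) best = c;
        c = prev[j - 1] + sc[j - 1];
        if (c < best) best = c;
        if (amove) {
          int q = bl + j - 1;
          int y = rightB[q];
          if (y >= 0 && arcsB[y].first >= bl) {
            int lj = arcsB[y].first - bl;
            c = Drow[lj] + Grow[y];
            if (c < best) best = c;
          }
        }
        row[j] = best;
      }
    }
    return D[(size_t)la * W + lb];
  }

  void compute_G() {
    G.assign(arcsA.size() * arcsB.size(), 0.0);
    for (size_t x = 0; x < arcsA.size(); ++x) {
      for (size_t y = 0; y < arcsB.size(); ++y) {
        double w = window(arcsA[x].first + 1, arcsA[x].second - 1,
                          arcsB[y].first + 1, arcsB[y].second - 1, buf);
        G[x * arcsB.size() + y] = arcSub((int)x, (int)y) + w;
      }
    }
  }

  // traceback: recompute each window on the optimal path and walk it.
  void trace(int al, int ar, int bl, int br, std::vector<int>& ci,
             std::vector<int>& cj) const {
    std::vector<double> D;
    window(al, ar, bl, br, D);
    int la = std::max(0, ar - al + 1), lb = std::max(0, br - bl + 1);
    size_t W = lb + 1;
    const double eps = 1e-9;
    struct Move {
      int kind;  // 0 sub, 1 delA, 2 delB, 3 arc-match
      int p, q, x, y;
    };
    std::vector<Move> moves;
    int i = la, j = lb;
    while (i > 0 || j > 0) {
      int p = al + i - 1, q = bl + j - 1;
      double cur = D[(size_t)i * W + j];
      bool done = false;
      if (i > 0 && j > 0) {
        int x = rightA[p], y = rightB[q];
        if (x >= 0 && y >= 0 && arcsA[x].first >= al && arcsB[y].first >= bl) {
          int li = arcsA[x].first - al, lj = arcsB[y].first - bl;
          if (std::abs(D[(size_t)li * W + lj] + G[x * arcsB.size() + y] - cur) <
              eps) {
            moves.push_back({3, p, q, x, y});
            i = li;
            j = lj;
            done = true;
          }
        }
        if (!done && std::abs(D[(size_t)(i - 1) * W + (j - 1)] +
                              SC[(size_t)p * m + q] - cur) < eps) {
          moves.push_back({0, p, q, -1, -1});
          --i;
          --j;
          done = true;
        }
      }
      if (!done && i > 0 &&
          std::abs(D[(size_t)(i - 1) * W + j] + GA[p] - cur) < eps) {
        moves.push_back({1, p, -1, -1, -1});
        --i;
        done = true;
      }
      if (!done) {
        moves.push_back({2, -1, q, -1, -1});
        --j;
      }
    }
    for (int k = (int)moves.size() - 1; k >= 0; --k) {
      const Move& mv = moves[k];
      if (mv.kind == 0) {
        ci.push_back(mv.p + 1);
        cj.push_back(mv.q + 1);
      } else if (mv.kind == 1) {
        ci.push_back(mv.p + 1);
        cj.push_back(0);
      } else if (mv.kind == 2) {
        ci.push_back(0);
        cj.push_back(mv.q + 1);
      } else {
        int l1 = arcsA[mv.x].first, r1 = arcsA[mv.x].second;
        int l2 = arcsB[mv.y].first, r2 = arcsB[mv.y].second;
        ci.push_back(l1 + 1);
        cj.push_back(l2 + 1);
        trace(l1 + 1, r1 - 1, l2 + 1, r2 - 1, ci, cj);
        ci.push_back(r1 + 1);
        cj.push_back(r2 + 1);
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_align")]]
List cpp_align(IntegerVector a_res, IntegerVector a_partner,
               IntegerVector b_res, IntegerVector b_partner,
               NumericVector costs) {
  // costs: del, mis, arcmis, break, remove
  Aligner al;
  al.n = a_res.size();
  al.m = b_res.size();
  al.ares.assign(a_res.begin(), a_res.end());
  al.bres.assign(b_res.begin(), b_res.end());
  al.apart.assign(a_partner.begin(), a_partner.end());
  al.bpart.assign(b_partner.begin(), b_partner.end());
  al.wdel = costs[0];
  al.wmis = costs[1];
  al.warcmis = costs[2];
  al.wbreak = costs[3];
  al.wremove = costs[4];
  al.prepare();
  al.compute_G();
  std::vector<double> D;
  double dist = al.window(0, al.n - 1, 0, al.m - 1, D);
  std::vector<int> ci, cj;
  al.trace(0, al.n - 1, 0, al.m - 1, ci, cj);
  return List::create(_["dist"] = dist,
                      _["col_a"] = IntegerVector(ci.begin(), ci.end()),
                      _["col_b"] = IntegerVector(cj.begin(), cj.end()));
}
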