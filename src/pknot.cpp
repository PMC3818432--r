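#include "ires_common.h"
using namespace Rcpp;

// H-type pseudoknot search: two crossing helices H1 = (i+t, j-t), H2 =
// (k+t, l-t) with i < k < j < l, each at least min_helix contiguous allowed
// pairs, every pair spanning at least min_loop+1 (the global arc invariant),
// helix segments disjoint. Score = sum of both helices' energies under the
// energy model (bp: -1 per pair; nn: stacking sum). Returns the best-scoring
// configuration over the exhaustive set of outer-pair anchors and lengths.

// [[Rcpp::export(name = ".cpp_pknot")]]
List cpp_pknot(IntegerVector residues, int mode, NumericMatrix stack,
               int min_helix, int min_loop) {
  int n = residues.size();
  std::vector<int> res(residues.begin(), residues.end());

  // ext(i,j): inward run length of allowed pairs starting at outer pair (i,j),
  // capped by the per-pair span constraint.
  // seeds: outer anchors (i,j) admitting a helix of >= min_helix pairs.
  struct Seed {
    int i, j, maxlen;
    std::vector<double> cum;  // cum[h-1] = energy of helix of h pairs
  };
  std::vector<Seed> seeds;
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_loop + 1; j < n; ++j) {
      int pt = pair_type(res[i], res[j]);
      if (pt < 0) continue;
      // max inward extension
      int maxlen = 0;
      while (true) {
        int a = i + maxlen, b = j - maxlen;
        if (b - a < min_loop + 1) break;
        if (pair_type(res[a], res[b]) < 0) break;
        ++maxlen;
      }
      if (maxlen < min_helix) continue;
      Seed s;
      s.i = i;
      s.j = j;
      s.maxlen = maxlen;
      s.cum.resize(maxlen);
      double e = mode == 0 ? -1.0 : 0.0;
      s.cum[0] = e;
      for (int t = 1; t < maxlen; ++t) {
        double add = mode == 0 ? -1.0
                               : stack(pair_type(res[i + t - 1], res[j - t + 1]),
                                       pair_type(res[i + t], res[j - t]));
        e += add + (mode == 0 ? 0.0 : 0.0);
        s.cum[t] = e;
      }
      seeds.push_back(s);
    }
  }

  double bestE = 1e100;
  int bi = -1, bj = -1, bh1 = 0, bk = -1, bl = -1, bh2 = 0;
  for (size_t s1 = 0; s1 < seeds.size(); ++s1) {
    const Seed& A = seeds[s1];
    for (size_t s2 = 0; s2 < seeds.size(); ++s2) {
      const Seed& B = seeds[s2];
      // geometry: i < k < j < l
      if (!(A.i < B.i && B.i < A.j && A.j < B.j)) continue;
      int i = A.i, j = A.j, k = B.i, l = B.j;
      int h2cap = std::min(B.maxlen, l - j);  // right segment after j
      for (int h2 = min_helix; h2 <= h2cap; ++h2) {
        // H1 inner end before k; H2 left segment before H1 right segment
        int h1max = std::min(A.maxlen, std::min(k - i, j - k + 1 - h2));
        if (h1max < min_helix) continue;
        // energies are non-increasing in helix length (all stack terms <= 0
        // in the packaged table; exact for bp), but scan all lengths to stay
        // faithful for arbitrary tables
        for (int h1 = min_helix; h1 <= h1max; ++h1) {
          double e = A.cum[h1 - 1] + B.cum[h2 - 1];
          if (e < bestE - 1e-12) {
            bestE = e;
            bi = i;
            bj = j;
            bh1 = h1;
            bk = k;
            bl = l;
            bh2 = h2;
          }
        }
      }
    }
  }

  bool found = bi >= 0;
  IntegerMatrix h1(found ? bh1 : 0, 2), h2(found ? bh2 : 0, 2);
  if (found) {
    for (int t = 0; t < bh1; ++t) {
      h1(t, 0) = bi + t + 1;
      h1(t, 1) = bj - t + 1;
    }
    for (int t = 0; t < bh2; ++t) {
      h2(t, 0) = bk + t + 1;
      h2(t, 1) = bl - t + 1;
    }
  }
  return List::create(_["found"] = found, _["energy"] = found ? bestE : 0.0,
                      _["helix1"] = h1, _["helix2"] = h2);
}
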