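#ifndef IRES_COMMON_H
#define IRES_COMMON_H

#include <Rcpp.h>

// residue codes: A=0, C=1, G=2, U=3, N=4
// pair types (outer i, j): AU=0, UA=1, GC=2, CG=3, GU=4, UG=5, none=-1
inline int pair_type(int x, int y) {
  if (x == 0 && y == 3) return 0;
  if (x == 3 && y == 0) return 1;
  if (x == 2 && y == 1) return 2;
  if (x == 1 && y == 2) return 3;
  if (x == 2 && y == 3) return 4;
  if (x == 3 && y == 2) return 5;
  return -1;
}

#endif
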