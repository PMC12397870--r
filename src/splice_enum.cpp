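#include <Rcpp.h>
using namespace Rcpp;

// Brute-force enumeration of valid splice-reactant coordinate 4-tuples
// (i, j, k, n): (i, j) bounds the first reactant, (k, n) the second, both in
// substrate coordinates. Serves as the independent oracle for the closed-form
// counts and the vectorized index builder. Loop ranges are tightened to the
// feasible windows but every candidate tuple inside them is visited.

// [[Rcpp::export]]
double enum_cis_events_cpp(int L, int N, int Lext, double Imax,
                           std::string direction) {
  if (L > 200) stop("L too large for brute-force enumeration (max 200)");
  if (L < 1 || N < 1) return 0.0;
  double count = 0.0;
  const bool fwd = (direction == "forward");
  if (fwd) {
    for (int i = 1; i <= L; ++i) {
      for (int j = i; j <= L; ++j) {
        int a = j - i + 1;              // first reactant length
        if (a > N - Lext) break;
        if (a < Lext) continue;
        for (int k = j + 2; k <= L; ++k) {   // gap = k - j - 1 >= 1
          double gap = k - j - 1;
          if (gap > Imax) break;
          for (int n = k; n <= L; ++n) {
            int b = n - k + 1;          // second reactant length
            if (b > N - a) break;
            if (b < Lext) continue;
            if (a + b == N) count += 1.0;
          }
        }
      }
    }
  } else {
    // reverse: second reactant (k, n) lies upstream of the first (i, j)
    for (int k = 1; k <= L; ++k) {
      for (int n = k; n <= L; ++n) {
        int b = n - k + 1;
        if (b > N - Lext) break;
        if (b < Lext) continue;
        for (int i = n + 1; i <= L; ++i) {   // gap = i - n - 1 >= 0
          double gap = i - n - 1;
          if (gap > Imax) break;
          for (int j = i; j <= L; ++j) {
            int a = j - i + 1;
            if (a > N - b) break;
            if (a < Lext) continue;
            if (a + b == N) count += 1.0;
          }
        }
      }
    }
  }
  return count;
}

// Trans-splicing oracle: first reactant from substrate A (length L1), second
// from substrate B (length L2); any positions, total length N.
// [[Rcpp::export]]
double enum_trans_events_cpp(int L1, int L2, int N, int Lext) {
  if (L1 > 200 || L2 > 200) stop("L too large for brute-force enumeration (max 200)");
  double count = 0.0;
  for (int i = 1; i <= L1; ++i) {
    for (int j = i; j <= L1; ++j) {
      int a = j - i + 1;
      if (a > N - Lext) break;
      if (a < Lext) continue;
      for (int k = 1; k <= L2; ++k) {
        for (int n = k; n <= L2; ++n) {
          int b = n - k + 1;
          if (b > N - a) break;
          if (b < Lext) continue;
          if (a + b == N) count += 1.0;
        }
      }
    }
  }
  return count;
}
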