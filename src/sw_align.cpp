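#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman / Gotoh). A gap of length L
// costs gap_open + L * gap_extend, the convention used by common pairwise
// aligners. Returns the optimal score and the 1-based inclusive extents of
// one best local alignment on both sequences.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) {
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  }
  const double NEG = -1e18;
  const double gopen = gap_open + gap_extend;  // cost of the first gap base
  const int W = m + 1;
  // H: best local score ending at (i, j); E: gap in a (consumes b[j]);
  // F: gap in b (consumes a[i]).
  std::vector<double> H((n + 1) * W, 0.0), E((n + 1) * W, NEG),
      F((n + 1) * W, NEG);
  // pointer codes -- pH: 0 fresh start, 1 diagonal, 2 E, 3 F;
  // pE: 1 from H, 2 extend E; pF: 1 from H, 3 extend F.
  std::vector<unsigned char> pH((n + 1) * W, 0), pE((n + 1) * W, 0),
      pF((n + 1) * W, 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int k = i * W + j, kup = k - W, kleft = k - 1, kdiag = kup - 1;
      double e_open = H[kleft] - gopen, e_ext = E[kleft] - gap_extend;
      if (e_open >= e_ext) { E[k] = e_open; pE[k] = 1; }
      else { E[k] = e_ext; pE[k] = 2; }
      double f_open = H[kup] - gopen, f_ext = F[kup] - gap_extend;
      if (f_open >= f_ext) { F[k] = f_open; pF[k] = 1; }
      else { F[k] = f_ext; pF[k] = 3; }
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double diag = H[kdiag] + s;
      double val = 0.0;
      unsigned char code = 0;
      if (diag > val) { val = diag; code = 1; }
      if (E[k] > val) { val = E[k]; code = 2; }
      if (F[k] > val) { val = F[k]; code = 3; }
      H[k] = val;
      pH[k] = code;
      if (val > best) { best = val; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  }
  int i = bi, j = bj, state = 1;  // 1 = H, 2 = E, 3 = F
  int a_start = bi, b_start = bj;
  for (;;) {
    const int k = i * W + j;
    if (state == 1) {
      const unsigned char p = pH[k];
      if (p == 0) break;            // defensive: H == 0 cell
      if (p == 1) {
        a_start = i; b_start = j;
        if (H[k - W - 1] == 0.0) break;  // local alignment starts here
        --i; --j;
      } else {
        state = p;                  // enter gap state at the same cell
      }
    } else if (state == 2) {        // E: gap in a, move left
      const unsigned char p = pE[k];
      --j;
      state = (p == 1) ? 1 : 2;
    } else {                        // F: gap in b, move up
      const unsigned char p = pF[k];
      --i;
      state = (p == 1) ? 1 : 3;
    }
  }
  return List::create(_["score"] = best, _["a_start"] = a_start,
                      _["a_end"] = bi, _["b_start"] = b_start,
                      _["b_end"] = bj);
}
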