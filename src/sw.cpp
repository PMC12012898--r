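#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh) local alignment score with the start of
// the optimal local path tracked so the aligned query span can be reported
// without a full traceback. Penalties are positive costs.
// [[Rcpp::export(name = ".sw_align_cpp")]]
NumericVector sw_align_cpp(std::string a, std::string b,
                           double match, double mismatch,
                           double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  const double NEG = -1e18;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  std::vector<int> Hbeg(m + 1, 0), Ebeg(m + 1, 0);
  double best = 0.0;
  int best_end_i = 0, best_beg_i = 0;
  for (int i = 1; i <= n; ++i) {
    double Hdiag = 0.0;          // H[i-1][0]
    int HdiagBeg = i - 1;        // local alignment starting here spans nothing yet
    double F = NEG;
    int Fbeg = 0;
    H[0] = 0.0; Hbeg[0] = i;
    for (int j = 1; j <= m; ++j) {
      double e_open = H[j] - gap_open, e_ext = E[j] - gap_extend;
      int ebeg;
      double e;
      if (e_open >= e_ext) { e = e_open; ebeg = Hbeg[j]; }
      else { e = e_ext; ebeg = Ebeg[j]; }
      E[j] = e; Ebeg[j] = ebeg;

      double f_open = H[j - 1] - gap_open, f_ext = F - gap_extend;
      if (f_open >= f_ext) { F = f_open; Fbeg = Hbeg[j - 1]; }
      else { F = f_ext; }

      double diag = Hdiag + (a[i - 1] == b[j - 1] ? match : mismatch);
      int dbeg = (Hdiag == 0.0 && HdiagBeg == 0) ? i - 1 : HdiagBeg;
      // a fresh local alignment starting at (i-1, j-1)
      if (Hdiag <= 0.0) dbeg = i - 1;

      double h = 0.0;
      int hbeg = i;               // empty alignment ending at row i
      if (diag > h) { h = diag; hbeg = dbeg; }
      if (E[j] > h) { h = E[j]; hbeg = Ebeg[j]; }
      if (F > h)    { h = F;    hbeg = Fbeg; }

      Hdiag = H[j]; HdiagBeg = Hbeg[j];
      H[j] = h; Hbeg[j] = hbeg;
      if (h > best) { best = h; best_end_i = i; best_beg_i = hbeg; }
    }
  }
  int alen = best > 0 ? best_end_i - best_beg_i : 0;
  return NumericVector::create(_["score"] = best,
                               _["query_aln_len"] = (double)alen);
}
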