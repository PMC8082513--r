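#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo ancestor-tracing algorithm.
// sire/dam are 1-based row indices into the topologically ordered pedigree,
// 0 = unknown. Memory is O(n): one path-coefficient workspace reused per
// animal, never the n x n relationship matrix.
//
// For animal i with both parents known, F_i = sum_j L_j^2 D_j - 1 over the
// ancestors j of i, where L_j is the expected genetic contribution of j to i
// (accumulated by halving down the pedigree) and D_j is the Mendelian
// sampling variance of j given its parents' F (already computed, since
// parents precede offspring).
// [[Rcpp::export(name = ".ml_inbreeding")]]
NumericVector ml_inbreeding(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n), L(n, 0.0);
  std::vector<int> touched;
  touched.reserve(64);

  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i)
      stop("pedigree is not topologically ordered at row %d", i + 1);
    double fs = (s >= 0) ? F[s] : 0.0;
    double fd = (d >= 0) ? F[d] : 0.0;
    if (s < 0 && d < 0)
      D[i] = 1.0;
    else if (s < 0 || d < 0)
      D[i] = 0.75 - 0.25 * (s >= 0 ? fs : fd);
    else
      D[i] = 0.5 - 0.25 * (fs + fd);

    if (s < 0 || d < 0) { F[i] = 0.0; continue; }

    // trace ancestors of i: seed at i itself (L=1), walk indices downward
    touched.clear();
    L[i] = 1.0;
    touched.push_back(i);
    double a = 0.0;
    for (int j = i; j >= 0; --j) {
      if (L[j] == 0.0) continue;
      a += L[j] * L[j] * D[j];
      int js = sire[j] - 1, jd = dam[j] - 1;
      if (js >= 0) { if (L[js] == 0.0) touched.push_back(js); L[js] += 0.5 * L[j]; }
      if (jd >= 0) { if (L[jd] == 0.0) touched.push_back(jd); L[jd] += 0.5 * L[j]; }
    }
    F[i] = a - 1.0;
    for (size_t k = 0; k < touched.size(); ++k) L[touched[k]] = 0.0;
  }
  return F;
}
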