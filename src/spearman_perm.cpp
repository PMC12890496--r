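#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact two-sided permutation p-value for the Spearman correlation of two
// rank vectors (midranks allowed). Enumerates every distinct permutation of
// ry with std::next_permutation; with tied ranks each distinct arrangement
// stands for an equal number of raw permutations, so counting distinct
// arrangements gives the exact p. Feasible up to n = 10 (10! = 3,628,800).
// Because rank means and variances are permutation-invariant, |rho| ordering
// is equivalent to |sum(rx * ry_perm) - n * mean(rx) * mean(ry)| ordering.
// [[Rcpp::export(name = ".spearman_perm_p")]]
double spearman_perm_p(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  if (n != ry.size()) stop("rank vectors differ in length");
  if (n > 10) stop("exact permutation only supported for n <= 10");
  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += rx[i]; my += ry[i]; }
  mx /= n; my /= n;
  const double centre = n * mx * my;
  double s_obs = 0.0;
  for (int i = 0; i < n; ++i) s_obs += rx[i] * ry[i];
  const double t_obs = std::fabs(s_obs - centre);
  std::vector<double> perm(ry.begin(), ry.end());
  std::sort(perm.begin(), perm.end());
  const double eps = 1e-9;
  long long total = 0, extreme = 0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += rx[i] * perm[i];
    if (std::fabs(s - centre) >= t_obs - eps) ++extreme;
    ++total;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return static_cast<double>(extreme) / static_cast<double>(total);
}
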