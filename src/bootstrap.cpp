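#include <Rcpp.h>
using namespace Rcpp;

// Two-level (site, observation) bootstrap of the group mean.
//
// One iteration resamples S sites with replacement (S = number of distinct
// sites in the group), then for each chosen site resamples that site's
// observations with replacement; the replicate statistic is the mean of the
// pooled resampled values. Driven by R's RNG so set.seed() governs the
// stream.
//
// values: flux observations of one (gas, pathway, water body, zone, month)
//         group; site: 1-based site index per observation; B: replicates.
// [[Rcpp::export(name = ".boot_group_means")]]
NumericVector boot_group_means(NumericVector values, IntegerVector site, int B) {
  int n = values.size();
  if (n == 0 || site.size() != n || B < 1)
    stop("invalid bootstrap inputs");

  int S = 0;
  for (int i = 0; i < n; ++i) {
    if (site[i] < 1) stop("site indices must be 1-based");
    if (site[i] > S) S = site[i];
  }

  // observation indices grouped by site
  std::vector< std::vector<int> > by_site(S);
  for (int i = 0; i < n; ++i) by_site[site[i] - 1].push_back(i);
  for (int s = 0; s < S; ++s)
    if (by_site[s].empty()) stop("site index with no observations");

  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    double sum = 0.0;
    int cnt = 0;
    for (int j = 0; j < S; ++j) {
      int s = (int) R_unif_index(S);          // level 1: site
      const std::vector<int>& obs = by_site[s];
      int m = obs.size();
      for (int k = 0; k < m; ++k) {           // level 2: observations
        sum += values[obs[(int) R_unif_index(m)]];
        ++cnt;
      }
    }
    out[b] = sum / cnt;
  }
  return out;
}

// Plain observation-level bootstrap of the group mean (comparison mode).
// [[Rcpp::export(name = ".boot_obs_means")]]
NumericVector boot_obs_means(NumericVector values, int B) {
  int n = values.size();
  if (n == 0 || B < 1) stop("invalid bootstrap inputs");
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    double sum = 0.0;
    for (int i = 0; i < n; ++i) sum += values[(int) R_unif_index(n)];
    out[b] = sum / n;
  }
  return out;
}
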