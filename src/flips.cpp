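#include <Rcpp.h>
using namespace Rcpp;

// Checkerboard-flip machinery for group-by-individual matrices.
//
// The elementary move of the group-permutation null model swaps two
// individuals between two groups of the same sampling period when they
// show the checkerboard pattern (i in g1 only, j in g2 only). The move
// preserves all group sizes (row sums) and, within each period, every
// individual's number of groups (per-period column sums). Uses R's RNG so
// chains are reproducible under set.seed().

namespace {

struct PeriodIndex {
  // groups (row indices) of each sampling period that has >= 2 groups
  std::vector<std::vector<int>> groups;
};

PeriodIndex build_period_index(const IntegerVector& period, int nrow) {
  std::map<int, std::vector<int>> by_period;
  for (int g = 0; g < nrow; ++g) by_period[period[g]].push_back(g);
  PeriodIndex idx;
  for (auto& kv : by_period)
    if (kv.second.size() >= 2) idx.groups.push_back(kv.second);
  return idx;
}

inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// pick the k-th member (1-entry) of row g by scanning
inline int kth_member(const IntegerMatrix& m, int g, int k) {
  int seen = -1;
  for (int j = 0; j < m.ncol(); ++j) {
    if (m(g, j) == 1) {
      if (++seen == k) return j;
    }
  }
  return -1; // not reached when k < row sum
}

// Perform `nflips` successful flips in place. Returns the number of
// attempts made, or throws if `retry_cap` consecutive draws are
// infeasible.
long do_flips(IntegerMatrix& m, const PeriodIndex& idx,
              const std::vector<int>& rowsum, int nflips, int retry_cap) {
  if (idx.groups.empty())
    stop("no sampling period contains two or more groups; data are unswappable");
  long attempts = 0;
  int done = 0, misses = 0;
  while (done < nflips) {
    ++attempts;
    const std::vector<int>& per = idx.groups[runif_int(idx.groups.size())];
    int a = runif_int(per.size());
    int b = runif_int(per.size() - 1);
    if (b >= a) ++b;
    int g1 = per[a], g2 = per[b];
    int i = kth_member(m, g1, runif_int(rowsum[g1]));
    int j = kth_member(m, g2, runif_int(rowsum[g2]));
    if (i != j && m(g2, i) == 0 && m(g1, j) == 0) {
      m(g1, i) = 0; m(g2, i) = 1;
      m(g2, j) = 0; m(g1, j) = 1;
      ++done;
      misses = 0;
    } else if (++misses >= retry_cap) {
      stop("no feasible checkerboard flip found after %d attempts; "
           "data are unswappable", retry_cap);
    }
  }
  return attempts;
}

std::vector<int> row_sums(const IntegerMatrix& m) {
  std::vector<int> rs(m.nrow(), 0);
  for (int g = 0; g < m.nrow(); ++g)
    for (int j = 0; j < m.ncol(); ++j) rs[g] += m(g, j);
  return rs;
}

// SD, CV and mean of the off-diagonal half-weight indices of m.
// d (total column sums) is flip-invariant and supplied by the caller.
void hwi_stats(const IntegerMatrix& m, const std::vector<double>& d,
               double* out_sd, double* out_cv, double* out_mean) {
  const int n = m.ncol(), G = m.nrow();
  std::vector<double> x((size_t)n * n, 0.0);
  std::vector<int> members;
  members.reserve(n);
  for (int g = 0; g < G; ++g) {
    members.clear();
    for (int j = 0; j < n; ++j)
      if (m(g, j) == 1) members.push_back(j);
    for (size_t a = 0; a < members.size(); ++a)
      for (size_t b = a + 1; b < members.size(); ++b)
        x[(size_t)members[a] * n + members[b]] += 1.0;
  }
  double s = 0.0, s2 = 0.0;
  long k = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double denom = d[i] + d[j];
      if (denom <= 0) continue;
      double h = 2.0 * x[(size_t)i * n + j] / denom;
      s += h; s2 += h * h; ++k;
    }
  }
  double mean = k > 0 ? s / k : NA_REAL;
  double var = k > 1 ? (s2 - k * mean * mean) / (k - 1) : NA_REAL;
  double sdv = var >= 0 ? std::sqrt(var) : 0.0;
  *out_mean = mean;
  *out_sd = sdv;
  *out_cv = (k > 0 && mean > 0) ? sdv / mean : NA_REAL;
}

} // namespace

// [[Rcpp::export]]
long cpp_flips(IntegerMatrix m, IntegerVector period, int nflips,
               int retry_cap) {
  PeriodIndex idx = build_period_index(period, m.nrow());
  std::vector<int> rs = row_sums(m);
  return do_flips(m, idx, rs, nflips, retry_cap);
}

// [[Rcpp::export]]
List cpp_chain_stats(IntegerMatrix gbi, IntegerVector period, int n_samples,
                     int flips_per, int burn_in, int retry_cap) {
  IntegerMatrix m = clone(gbi);
  PeriodIndex idx = build_period_index(period, m.nrow());
  std::vector<int> rs = row_sums(m);
  std::vector<double> d(m.ncol(), 0.0);
  for (int j = 0; j < m.ncol(); ++j)
    for (int g = 0; g < m.nrow(); ++g) d[j] += m(g, j);
  long attempts = 0;
  if (burn_in > 0) attempts += do_flips(m, idx, rs, burn_in, retry_cap);
  NumericMatrix out(n_samples, 3);
  colnames(out) = CharacterVector::create("sd", "cv", "mean");
  for (int s = 0; s < n_samples; ++s) {
    attempts += do_flips(m, idx, rs, flips_per, retry_cap);
    double sdv, cv, mean;
    hwi_stats(m, d, &sdv, &cv, &mean);
    out(s, 0) = sdv; out(s, 1) = cv; out(s, 2) = mean;
  }
  return List::create(_["stats"] = out, _["attempts"] = (double)attempts,
                      _["final"] = m);
}

// [[Rcpp::export]]
List cpp_chain_gbis(IntegerMatrix gbi, IntegerVector period, int n_samples,
                    int flips_per, int burn_in, int retry_cap) {
  IntegerMatrix m = clone(gbi);
  PeriodIndex idx = build_period_index(period, m.nrow());
  std::vector<int> rs = row_sums(m);
  long attempts = 0;
  if (burn_in > 0) attempts += do_flips(m, idx, rs, burn_in, retry_cap);
  List samples(n_samples);
  for (int s = 0; s < n_samples; ++s) {
    attempts += do_flips(m, idx, rs, flips_per, retry_cap);
    samples[s] = clone(m);
  }
  return List::create(_["samples"] = samples, _["attempts"] = (double)attempts);
}
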