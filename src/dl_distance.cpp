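#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

// Unrestricted Damerau-Levenshtein distance (Lowrance-Wagner): substitution,
// insertion, deletion and adjacent transposition each cost 1, and transposed
// blocks may be edited again.  Quadratic DP with the `da` last-occurrence
// bookkeeping over a 256-entry byte alphabet.
static int dl_unrestricted(const std::string &a, const std::string &b) {
  const int m = a.size(), n = b.size();
  if (m == 0) return n;
  if (n == 0) return m;
  const int INF = m + n;
  // h is (m+2) x (n+2) with an INF border at index 0
  std::vector<int> h((m + 2) * (n + 2));
  const int W = n + 2;
  h[0] = INF;
  for (int i = 0; i <= m; ++i) { h[(i + 1) * W] = INF; h[(i + 1) * W + 1] = i; }
  for (int j = 0; j <= n; ++j) { h[j + 1] = INF; h[W + j + 1] = j; }
  int da[256];
  std::memset(da, 0, sizeof(da));
  for (int i = 1; i <= m; ++i) {
    int db = 0;
    const unsigned char ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      const unsigned char bj = b[j - 1];
      const int k = da[bj], l = db;
      int cost = 1;
      if (ai == bj) { cost = 0; db = j; }
      int val = h[i * W + j] + cost;                       // substitution/match
      val = std::min(val, h[(i + 1) * W + j] + 1);         // insertion
      val = std::min(val, h[i * W + j + 1] + 1);           // deletion
      val = std::min(val, h[k * W + l] + (i - k - 1) + 1 + (j - l - 1)); // transposition
      h[(i + 1) * W + j + 1] = val;
    }
    da[ai] = i;
  }
  return h[(m + 1) * W + n + 1];
}

// Restricted variant (optimal string alignment): a transposed pair may not be
// edited again.  Classic three-row DP.
static int dl_osa(const std::string &a, const std::string &b) {
  const int m = a.size(), n = b.size();
  if (m == 0) return n;
  if (n == 0) return m;
  std::vector<int> prev2(n + 1), prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      const int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int val = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), prev[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        val = std::min(val, prev2[j - 2] + 1);
      cur[j] = val;
    }
    std::swap(prev2, prev);
    std::swap(prev, cur);
  }
  return prev[n];
}

// Plain Levenshtein capped at `cap`: returns cap + 1 as soon as the distance
// provably exceeds cap (banded rows + row-minimum early exit, both exact for
// Levenshtein).  Used only as a screen: Lev <= 2 * DL, so Lev > 2*d implies
// DL > d.
static int lev_capped(const std::string &a, const std::string &b, int cap) {
  const int m = a.size(), n = b.size();
  if (std::abs(m - n) > cap) return cap + 1;
  if (m == 0 || n == 0) return std::max(m, n) <= cap ? std::max(m, n) : cap + 1;
  const int INF = cap + 1;
  std::vector<int> prev(n + 1, INF), cur(n + 1, INF);
  for (int j = 0; j <= std::min(n, cap); ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    const int lo = std::max(1, i - cap), hi = std::min(n, i + cap);
    cur[lo - 1] = (i - (lo - 1) <= cap && lo == 1) ? i : INF;
    int rowmin = cur[lo - 1];
    for (int j = lo; j <= hi; ++j) {
      const int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int val = prev[j - 1] + cost;
      if (prev[j] < INF) val = std::min(val, prev[j] + 1);
      if (cur[j - 1] < INF) val = std::min(val, cur[j - 1] + 1);
      cur[j] = std::min(val, INF);
      rowmin = std::min(rowmin, cur[j]);
    }
    if (hi < n) cur[hi + 1] = INF;
    if (rowmin > cap) return cap + 1;
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), INF);
  }
  return std::min(prev[n], INF);
}

// Full DL capped at `cap` via the Levenshtein screen.
static int dl_capped(const std::string &a, const std::string &b, int cap) {
  if (std::abs((int)a.size() - (int)b.size()) > cap) return cap + 1;
  if (lev_capped(a, b, 2 * cap) > 2 * cap) return cap + 1;
  const int d = dl_unrestricted(a, b);
  return d > cap ? cap + 1 : d;
}

// [[Rcpp::export(name = ".dl_distance_cpp")]]
IntegerVector dl_distance_cpp(CharacterVector a, CharacterVector b, bool restricted) {
  const R_xlen_t n = a.size();
  if (b.size() != n) stop("'a' and 'b' must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string sa = as<std::string>(a[i]), sb = as<std::string>(b[i]);
    out[i] = restricted ? dl_osa(sa, sb) : dl_unrestricted(sa, sb);
  }
  return out;
}

// Capped distances from one query to many references (cap + 1 = "farther").
// [[Rcpp::export(name = ".dl_capped_many_cpp")]]
IntegerVector dl_capped_many_cpp(std::string query, CharacterVector refs, int cap) {
  IntegerVector out(refs.size());
  for (R_xlen_t i = 0; i < refs.size(); ++i)
    out[i] = dl_capped(query, as<std::string>(refs[i]), cap);
  return out;
}

// Greedy abundance-ordered family assignment.  `seqs` must already be sorted
// by descending total count, ties lexicographic.  A sequence starts a new
// family iff no existing representative lies within d_max; otherwise it joins
// the nearest representative, ties going to the earliest (= most abundant,
// then lexicographically smallest) representative.  Returns the 1-based index
// (into `seqs`) of each sequence's representative and the distance to it.
// [[Rcpp::export(name = ".greedy_join_cpp")]]
List greedy_join_cpp(CharacterVector seqs, int d_max) {
  const R_xlen_t n = seqs.size();
  std::vector<std::string> s(n);
  for (R_xlen_t i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  IntegerVector rep(n), dist(n);
  std::vector<int> reps;  // indices of current representatives, in order
  reps.reserve(1024);
  for (R_xlen_t i = 0; i < n; ++i) {
    int best = d_max + 1, best_rep = -1;
    const int len_i = s[i].size();
    for (size_t r = 0; r < reps.size(); ++r) {
      const int j = reps[r];
      if (std::abs(len_i - (int)s[j].size()) > d_max) continue;
      const int d = dl_capped(s[i], s[j], best - 1);  // only improvements matter
      if (d < best) { best = d; best_rep = j; if (best == 0) break; }
    }
    if (best_rep >= 0 && best <= d_max) {
      rep[i] = best_rep + 1;
      dist[i] = best;
    } else {
      rep[i] = i + 1;
      dist[i] = 0;
      reps.push_back(i);
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["rep"] = rep, _["dist"] = dist);
}

// Pairwise minimum-separation check: TRUE iff all pairwise unrestricted DL
// distances exceed `min_gt`.  Early exit on first violation.
// [[Rcpp::export(name = ".all_separated_cpp")]]
bool all_separated_cpp(CharacterVector seqs, int min_gt) {
  const R_xlen_t n = seqs.size();
  std::vector<std::string> s(n);
  for (R_xlen_t i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (R_xlen_t i = 0; i < n; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j)
      if (dl_capped(s[i], s[j], min_gt) <= min_gt) return false;
    if ((i & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return true;
}

// Distances from a candidate to a set, capped: used by rejection sampling.
// [[Rcpp::export(name = ".min_dist_capped_cpp")]]
int min_dist_capped_cpp(std::string candidate, CharacterVector accepted, int cap) {
  int best = cap + 1;
  for (R_xlen_t i = 0; i < accepted.size(); ++i) {
    const int d = dl_capped(candidate, as<std::string>(accepted[i]), best - 1);
    if (d < best) best = d;
    if (best == 0) break;
  }
  return best;
}
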