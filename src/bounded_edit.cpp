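#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstdlib>
#include <climits>
#include <functional>
using namespace Rcpp;

// Banded Levenshtein distance with early abandoning.
// Returns the edit distance if it is <= maxd, otherwise -1.
// Only cells within +/- maxd of the diagonal can hold values <= maxd,
// so the DP is restricted to that band; if every cell of a row exceeds
// maxd the computation aborts.
// Row i holds cells j in [i - maxd, i + maxd], stored band-locally at
// k = j - (i - maxd), so each row costs O(2*maxd + 1) regardless of length.
static int banded_lev(const std::string &a, const std::string &b, int maxd) {
  const int n = (int)a.size(), m = (int)b.size();
  if (std::abs(n - m) > maxd) return -1;
  const int w = 2 * maxd + 1;
  const int INF = maxd + 1;
  static thread_local std::vector<int> prev, cur;
  if ((int)prev.size() < w + 1) { prev.resize(w + 1); cur.resize(w + 1); }
  // row 0: cell j (0..maxd) sits at k = j + maxd
  for (int k = 0; k < w; ++k) {
    int j = k - maxd;
    prev[k] = (j >= 0 && j <= m) ? j : INF;
  }
  prev[w] = INF;
  for (int i = 1; i <= n; ++i) {
    int rowmin = INF;
    for (int k = 0; k < w; ++k) {
      const int j = i - maxd + k;
      if (j < 0 || j > m) { cur[k] = INF; continue; }
      int v;
      if (j == 0) {
        v = i;  // first column
      } else {
        v = prev[k] + (a[i - 1] != b[j - 1] ? 1 : 0);   // diagonal (i-1, j-1)
        const int up = (k + 1 <= w - 1) ? prev[k + 1] : INF;  // (i-1, j)
        if (up + 1 < v) v = up + 1;
        const int left = (k >= 1) ? cur[k - 1] : INF;         // (i, j-1)
        if (left + 1 < v) v = left + 1;
      }
      cur[k] = v > INF ? INF : v;
      if (cur[k] < rowmin) rowmin = cur[k];
    }
    if (rowmin > maxd) return -1;
    std::swap(prev, cur);
  }
  const int kfin = m - n + maxd;  // cell (n, m)
  return prev[kfin] <= maxd ? prev[kfin] : -1;
}

// [[Rcpp::export]]
int cpp_bounded_dist(std::string a, std::string b, int maxd) {
  if (maxd < 0) stop("maxd must be >= 0");
  return banded_lev(a, b, maxd);
}

// For each candidate, TRUE if any frontier sequence lies within edit
// distance d. Drives the breadth-first expansion of swarm components.
// [[Rcpp::export]]
LogicalVector cpp_match_any(CharacterVector candidates, CharacterVector frontier,
                            int d) {
  const int nc = candidates.size(), nf = frontier.size();
  std::vector<std::string> fr(nf);
  for (int j = 0; j < nf; ++j) fr[j] = as<std::string>(frontier[j]);
  LogicalVector out(nc);
  for (int i = 0; i < nc; ++i) {
    std::string ci = as<std::string>(candidates[i]);
    bool hit = false;
    for (int j = 0; j < nf && !hit; ++j) {
      if (banded_lev(ci, fr[j], d) >= 0) hit = true;
    }
    out[i] = hit;
  }
  return out;
}

// Exact single-linkage components at edit distance <= d (swarm semantics)
// via union-find over all pairs, skipping pairs already connected. Input
// order matters only for speed: with sequences sorted by abundance, cloud
// members connect to their seed early and subsequent within-cloud pairs are
// skipped before any alignment.
// [[Rcpp::export]]
IntegerVector cpp_swarm_components(CharacterVector seqs, int d) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  std::vector<int> parent(n), rank_(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
  };
  for (int j = 1; j < n; ++j) {
    const int lj = (int)s[j].size();
    for (int i = 0; i < j; ++i) {
      if (std::abs((int)s[i].size() - lj) > d) continue;
      if (find(i) == find(j)) continue;
      if (banded_lev(s[i], s[j], d) >= 0) unite(i, j);
    }
  }
  // relabel components by first appearance
  IntegerVector out(n);
  std::vector<int> label(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (label[r] == 0) label[r] = ++next;
    out[i] = label[r];
  }
  return out;
}

// Approximate two-parent chimera score of a query against equal-length
// parents (substitution model): best_two = min over breakpoints k and
// ordered parent pairs A != B of mismatches(q[0..k) vs A) +
// mismatches(q[k..L) vs B); best_single = min over parents of the full
// mismatch count. Returns {best_two, best_single}; NA-like sentinel
// INT_MAX when fewer than two equal-length parents exist.
// [[Rcpp::export]]
IntegerVector cpp_chimera_score(std::string q, CharacterVector parents) {
  const int L = (int)q.size();
  const int BIG = INT_MAX / 4;
  std::vector<std::vector<int> > cum;
  for (int p = 0; p < parents.size(); ++p) {
    std::string s = as<std::string>(parents[p]);
    if ((int)s.size() != L) continue;
    std::vector<int> c(L + 1, 0);
    for (int i = 0; i < L; ++i) c[i + 1] = c[i] + (q[i] != s[i] ? 1 : 0);
    cum.push_back(c);
  }
  const int m = (int)cum.size();
  if (m < 2) return IntegerVector::create(BIG, BIG);
  int best_single = BIG;
  for (int p = 0; p < m; ++p) best_single = std::min(best_single, cum[p][L]);
  int best_two = BIG;
  for (int k = 1; k < L; ++k) {
    // top-2 prefix scores and top-2 suffix scores at this breakpoint
    int a1 = BIG, a2 = BIG, ai = -1;
    int b1 = BIG, b2 = BIG, bi = -1;
    for (int p = 0; p < m; ++p) {
      const int pre = cum[p][k];
      if (pre < a1) { a2 = a1; a1 = pre; ai = p; }
      else if (pre < a2) a2 = pre;
      const int suf = cum[p][L] - cum[p][k];
      if (suf < b1) { b2 = b1; b1 = suf; bi = p; }
      else if (suf < b2) b2 = suf;
    }
    const int v = (ai != bi) ? a1 + b1 : std::min(a1 + b2, a2 + b1);
    if (v < best_two) best_two = v;
  }
  return IntegerVector::create(best_two, best_single);
}

// Longest common prefix / suffix lengths of one query against many
// subjects (chimera decomposition checks).
// [[Rcpp::export]]
IntegerVector cpp_lcp(std::string query, CharacterVector subjects) {
  const int n = subjects.size();
  IntegerVector out(n);
  const int lq = (int)query.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(subjects[i]);
    const int lim = std::min(lq, (int)s.size());
    int k = 0;
    while (k < lim && query[k] == s[k]) ++k;
    out[i] = k;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_lcs(std::string query, CharacterVector subjects) {
  const int n = subjects.size();
  IntegerVector out(n);
  const int lq = (int)query.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(subjects[i]);
    const int ls = (int)s.size();
    const int lim = std::min(lq, ls);
    int k = 0;
    while (k < lim && query[lq - 1 - k] == s[ls - 1 - k]) ++k;
    out[i] = k;
  }
  return out;
}

// Full pairwise bounded-distance matrix (d_ij <= maxd, else -1); used by
// the small-instance clustering path and evaluation cross-referencing.
// [[Rcpp::export]]
IntegerMatrix cpp_bounded_dist_matrix(CharacterVector x, int maxd) {
  const int n = x.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 0;
    for (int j = i + 1; j < n; ++j) {
      int v = banded_lev(s[i], s[j], maxd);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
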