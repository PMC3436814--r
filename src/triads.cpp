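// Colored triad census and degree-preserving edge-switch randomization.
// These are the inner loops of motif significance testing (one census per
// randomized replicate), hence compiled code.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

static const int PERMS[6][3] = {
  {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
};

// bit position of the arc from triad position i to position j, in the order
// (1->2, 1->3, 2->1, 2->3, 3->1, 3->2) from the most significant bit
static const int BITPOS[3][3] = {
  {-1, 5, 4},
  { 3, -1, 2},
  { 1, 0, -1}
};

// canonical code = min over the 6 vertex orderings of
// (role triple base-3) * 64 + (6-bit adjacency pattern)
static int canon_code(const int a[3][3], const int r[3]) {
  int best = INT_MAX;
  for (int p = 0; p < 6; ++p) {
    const int* pm = PERMS[p];
    int bits = 0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        if (i != j && a[pm[i]][pm[j]]) bits |= (1 << BITPOS[i][j]);
    int code = ((r[pm[0]] * 3 + r[pm[1]]) * 3 + r[pm[2]]) * 64 + bits;
    if (code < best) best = code;
  }
  return best;
}

// Enumerate every unordered vertex triple whose induced subgraph is weakly
// connected, once, returning its canonical colored signature code and the
// (sorted) vertex triple. Vertices and roles are 0-based internally;
// from/to/roles come in 1-based / 0-based from R respectively.
// [[Rcpp::export]]
List census_triads_cpp(int n, IntegerVector from, IntegerVector to,
                       IntegerVector role) {
  std::unordered_set<long long> eset;
  std::vector< std::vector<int> > nbr(n);
  int m = from.size();
  eset.reserve(2 * m + 1);
  for (int e = 0; e < m; ++e) {
    int u = from[e] - 1, v = to[e] - 1;
    if (eset.insert((long long)u * n + v).second) {
      nbr[u].push_back(v);
      nbr[v].push_back(u);
    }
  }
  for (int u = 0; u < n; ++u) {
    std::sort(nbr[u].begin(), nbr[u].end());
    nbr[u].erase(std::unique(nbr[u].begin(), nbr[u].end()), nbr[u].end());
  }

  std::unordered_set<long long> seen;
  std::vector<int> codes, t1, t2, t3;
  int r[3], a[3][3];
  for (int u = 0; u < n; ++u) {
    for (size_t iv = 0; iv < nbr[u].size(); ++iv) {
      int v = nbr[u][iv];
      if (v <= u) continue;  // each undirected pair once
      // any connected triple containing the pair (u,v) has its third vertex
      // adjacent to u or v
      for (int side = 0; side < 2; ++side) {
        const std::vector<int>& cand = side == 0 ? nbr[u] : nbr[v];
        for (size_t iw = 0; iw < cand.size(); ++iw) {
          int w = cand[iw];
          if (w == u || w == v) continue;
          int x = u, y = v, z = w;
          if (z < y) std::swap(y, z);
          if (y < x) std::swap(x, y);
          if (z < y) std::swap(y, z);
          long long key = ((long long)x * n + y) * n + z;
          if (!seen.insert(key).second) continue;
          int vtx[3] = {x, y, z};
          for (int i = 0; i < 3; ++i) {
            r[i] = role[vtx[i]];
            for (int j = 0; j < 3; ++j)
              a[i][j] = (i != j) &&
                eset.count((long long)vtx[i] * n + vtx[j]) > 0;
          }
          codes.push_back(canon_code(a, r));
          t1.push_back(x + 1);
          t2.push_back(y + 1);
          t3.push_back(z + 1);
        }
      }
    }
  }
  return List::create(_["code"] = wrap(codes), _["v1"] = wrap(t1),
                      _["v2"] = wrap(t2), _["v3"] = wrap(t3));
}

// Degree-preserving randomization by repeated double-arc switches:
// (a->b, c->d) => (a->d, c->b), rejecting swaps that would introduce a
// self-loop or a duplicate arc. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List switch_randomize_cpp(int n, IntegerVector from, IntegerVector to,
                          int n_attempts) {
  std::vector<int> src(from.begin(), from.end());
  std::vector<int> tgt(to.begin(), to.end());
  int m = (int)src.size();
  std::unordered_set<long long> eset;
  eset.reserve(2 * m + 1);
  for (int e = 0; e < m; ++e)
    eset.insert((long long)(src[e] - 1) * n + (tgt[e] - 1));

  for (int it = 0; it < n_attempts; ++it) {
    int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = m - 1;
    int e2 = (int)(unif_rand() * m); if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = src[e1], b = tgt[e1], c = src[e2], d = tgt[e2];
    if (a == d || c == b) continue;  // would create self-loops
    long long k1 = (long long)(a - 1) * n + (d - 1);
    long long k2 = (long long)(c - 1) * n + (b - 1);
    if (eset.count(k1) || eset.count(k2)) continue;  // duplicates (incl. b==d, a==c)
    eset.erase((long long)(a - 1) * n + (b - 1));
    eset.erase((long long)(c - 1) * n + (d - 1));
    eset.insert(k1);
    eset.insert(k2);
    tgt[e1] = d;
    tgt[e2] = b;
  }
  return List::create(_["from"] = wrap(src), _["to"] = wrap(tgt));
}
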