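#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving rewiring of a bipartite edge list by double-edge swaps.
// Edges are (patient, comorbidity) pairs in 0-based indices. A swap replaces
// {(i1,j1),(i2,j2)} with {(i1,j2),(i2,j1)} and is accepted only when neither
// replacement edge already exists, so both degree sequences and m are exact
// invariants. Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix bipartite_edge_swap_cpp(IntegerVector ei, IntegerVector ej,
                                      int n_comorbidities, int nswap,
                                      int max_attempts) {
  int m = ei.size();
  std::vector<int> vi(ei.begin(), ei.end());
  std::vector<int> vj(ej.begin(), ej.end());
  std::unordered_set<long long> edges;
  edges.reserve(2 * m);
  long long d = n_comorbidities;
  for (int e = 0; e < m; ++e)
    edges.insert((long long)vi[e] * d + vj[e]);

  int done = 0, attempts = 0;
  while (done < nswap && attempts < max_attempts) {
    ++attempts;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int i1 = vi[e1], j1 = vj[e1], i2 = vi[e2], j2 = vj[e2];
    if (i1 == i2 || j1 == j2) continue;
    long long k1 = (long long)i1 * d + j2;
    long long k2 = (long long)i2 * d + j1;
    if (edges.count(k1) || edges.count(k2)) continue;
    edges.erase((long long)i1 * d + j1);
    edges.erase((long long)i2 * d + j2);
    edges.insert(k1);
    edges.insert(k2);
    vj[e1] = j2;
    vj[e2] = j1;
    ++done;
  }

  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = vi[e];
    out(e, 1) = vj[e];
  }
  out.attr("swaps_done") = done;
  return out;
}
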