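// Directed-simplex enumeration by ordered extension: a directed k-simplex is
// a sequence v0 -> v1 -> ... -> vk with an edge vi -> vj for every i < j.
// Counting proceeds source-first; the candidate set for extending a chain is
// the intersection of the out-neighbourhoods of all chain members, so every
// valid ordering is enumerated exactly once.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

void extend_chain(const std::vector<std::vector<int>> &out,
                  std::vector<int> &chain,
                  const std::vector<int> &cand,
                  int max_dim,
                  std::vector<std::vector<double>> &par) {
  int dim_here = (int) chain.size(); // dimension of simplices formed by adding one node
  if (dim_here > max_dim) return;
  for (size_t ci = 0; ci < cand.size(); ++ci) {
    int v = cand[ci];
    chain.push_back(v);
    for (size_t j = 0; j < chain.size(); ++j) par[dim_here - 1][chain[j]] += 1.0;
    if (dim_here < max_dim) {
      std::vector<int> nc;
      const std::vector<int> &ov = out[v];
      std::set_intersection(cand.begin(), cand.end(), ov.begin(), ov.end(),
                            std::back_inserter(nc));
      if (!nc.empty()) extend_chain(out, chain, nc, max_dim, par);
    }
    chain.pop_back();
  }
}

} // namespace

// [[Rcpp::export(name = ".count_simplices")]]
NumericMatrix count_simplices(int n, IntegerVector from, IntegerVector to, int max_dim) {
  std::vector<std::vector<int>> out(n);
  for (int e = 0; e < from.size(); ++e) out[from[e] - 1].push_back(to[e] - 1);
  for (int i = 0; i < n; ++i) {
    std::sort(out[i].begin(), out[i].end());
    out[i].erase(std::unique(out[i].begin(), out[i].end()), out[i].end());
  }
  std::vector<std::vector<double>> par(max_dim, std::vector<double>(n, 0.0));
  std::vector<int> chain;
  chain.reserve(max_dim + 1);
  for (int v = 0; v < n; ++v) {
    chain.push_back(v);
    extend_chain(out, chain, out[v], max_dim, par);
    chain.pop_back();
  }
  NumericMatrix res(n, max_dim);
  for (int k = 0; k < max_dim; ++k)
    for (int i = 0; i < n; ++i) res(i, k) = par[k][i];
  return res;
}
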