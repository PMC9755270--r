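#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Uniform integer in [0, m) from R's RNG stream.
static inline int runif_int(int m) {
  int k = (int)(unif_rand() * m);
  if (k >= m) k = m - 1;
  return k;
}

// BFS connectivity of the induced subgraph on `members` (in_set is the
// membership indicator over all vertices).
static bool subset_connected(const std::vector<std::vector<int> > &adj,
                             const std::vector<int> &members,
                             const std::vector<char> &in_set) {
  int k = (int)members.size();
  if (k <= 1) return true;
  std::vector<char> seen(in_set.size(), 0);
  std::vector<int> stack;
  stack.reserve(k);
  stack.push_back(members[0]);
  seen[members[0]] = 1;
  int found = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    const std::vector<int> &nb = adj[v];
    for (size_t i = 0; i < nb.size(); ++i) {
      int u = nb[i];
      if (in_set[u] && !seen[u]) {
        seen[u] = 1;
        ++found;
        stack.push_back(u);
      }
    }
  }
  return found == k;
}

// Boundary N(S): vertices not in S adjacent to at least one member of S.
static void boundary_of(const std::vector<std::vector<int> > &adj,
                        const std::vector<int> &members,
                        const std::vector<char> &in_set,
                        std::vector<int> &out,
                        std::vector<char> &mark) {
  out.clear();
  for (size_t i = 0; i < members.size(); ++i) {
    const std::vector<int> &nb = adj[members[i]];
    for (size_t j = 0; j < nb.size(); ++j) {
      int u = nb[j];
      if (!in_set[u] && !mark[u]) {
        mark[u] = 1;
        out.push_back(u);
      }
    }
  }
  for (size_t i = 0; i < out.size(); ++i) mark[out[i]] = 0;
}

// Draw `n_draws` connected induced k-subsets of a connected graph.
// Each draw runs a fresh Metropolis swap chain for `iterations` steps:
// propose u uniform from N(S), v uniform from S, S' = S \ {v} + {u};
// accept connected proposals with probability min(1, |N(S)|/|N(S')|),
// which makes the uniform distribution over connected k-subsets
// stationary.  Uses R's RNG so draws are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix nrs_sample_cpp(List adj_r, int size, int n_draws, int iterations) {
  int n = adj_r.size();
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj_r[i];
    adj[i].assign(nb.begin(), nb.end());
  }
  IntegerMatrix out(n_draws, size);
  std::vector<char> in_set(n, 0), mark(n, 0);
  std::vector<int> members, bnd, bnd2;
  members.reserve(size);
  bnd.reserve(n);
  bnd2.reserve(n);

  for (int d = 0; d < n_draws; ++d) {
    // random connected seed set: grow from a random start via random
    // frontier additions
    std::fill(in_set.begin(), in_set.end(), 0);
    members.clear();
    int start = runif_int(n);
    members.push_back(start);
    in_set[start] = 1;
    while ((int)members.size() < size) {
      boundary_of(adj, members, in_set, bnd, mark);
      int u = bnd[runif_int((int)bnd.size())];
      members.push_back(u);
      in_set[u] = 1;
    }
    if (size < n) {
      boundary_of(adj, members, in_set, bnd, mark);
      for (int it = 0; it < iterations; ++it) {
        if (bnd.empty()) break;
        int u = bnd[runif_int((int)bnd.size())];
        int vi = runif_int(size);
        int v = members[vi];
        // propose swap v -> u
        in_set[v] = 0;
        in_set[u] = 1;
        members[vi] = u;
        bool ok = subset_connected(adj, members, in_set);
        if (ok) {
          boundary_of(adj, members, in_set, bnd2, mark);
          double acc = (double)bnd.size() / (double)bnd2.size();
          if (acc >= 1.0 || unif_rand() < acc) {
            bnd.swap(bnd2);
            continue;  // accepted
          }
        }
        // reject: revert
        members[vi] = v;
        in_set[u] = 0;
        in_set[v] = 1;
      }
    }
    for (int j = 0; j < size; ++j) out(d, j) = members[j] + 1;  // 1-based
  }
  return out;
}
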