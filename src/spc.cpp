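// Swendsen-Wang Monte Carlo for q-state Potts spins on a sparse
// nearest-neighbour graph: the computational core of super-paramagnetic
// clustering. For each temperature, bonds between equal spins freeze with
// probability 1 - exp(-J_ij / T); frozen components flip together to a fresh
// random state; the pairwise same-spin frequency after burn-in estimates the
// spin-spin correlation G_ij.
#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];  // path halving
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a != b) parent[b] = a;
}

// [[Rcpp::export]]
NumericMatrix spc_sweep_cpp(int n_nodes, IntegerVector edge_i,
                            IntegerVector edge_j, NumericVector J,
                            int q, NumericVector temps, int sweeps,
                            int burnin, int seed) {
  const int nE = edge_i.size();
  const int nT = temps.size();
  NumericMatrix G(nE, nT);
  std::vector<int> parent(n_nodes), spin(n_nodes);

  for (int ti = 0; ti < nT; ++ti) {
    const double T = temps[ti];
    if (T < 1e-9) {
      // zero-temperature limit: every connected component is one frozen
      // ferromagnetic domain, so G = 1 on all its edges
      for (int v = 0; v < n_nodes; ++v) parent[v] = v;
      for (int e = 0; e < nE; ++e) uf_union(parent, edge_i[e], edge_j[e]);
      for (int e = 0; e < nE; ++e)
        G(e, ti) = (uf_find(parent, edge_i[e]) == uf_find(parent, edge_j[e]))
                       ? 1.0 : 0.0;
      continue;
    }
    std::mt19937_64 rng(static_cast<uint64_t>(seed) * 1000003ull +
                        static_cast<uint64_t>(ti));
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    std::uniform_int_distribution<int> qdraw(0, q - 1);
    std::vector<double> pfreeze(nE);
    for (int e = 0; e < nE; ++e) pfreeze[e] = 1.0 - std::exp(-J[e] / T);

    for (int v = 0; v < n_nodes; ++v) spin[v] = qdraw(rng);
    for (int sweep = 0; sweep < burnin + sweeps; ++sweep) {
      for (int v = 0; v < n_nodes; ++v) parent[v] = v;
      for (int e = 0; e < nE; ++e) {
        if (spin[edge_i[e]] == spin[edge_j[e]] && unif(rng) < pfreeze[e])
          uf_union(parent, edge_i[e], edge_j[e]);
      }
      // fresh random state per frozen component
      std::vector<int> newspin(n_nodes, -1);
      for (int v = 0; v < n_nodes; ++v) {
        int r = uf_find(parent, v);
        if (newspin[r] < 0) newspin[r] = qdraw(rng);
        spin[v] = newspin[r];
      }
      if (sweep >= burnin) {
        for (int e = 0; e < nE; ++e)
          if (spin[edge_i[e]] == spin[edge_j[e]]) G(e, ti) += 1.0;
      }
    }
    for (int e = 0; e < nE; ++e) G(e, ti) /= sweeps;
  }
  return G;
}
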