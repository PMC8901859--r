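#include <Rcpp.h>
using namespace Rcpp;

// Count-preserving surrogate generator for the n-order synchrony null.
//
// For each shuffle and neuron the spike frames are redrawn, either as a
// uniform random permutation of that neuron's binary time series (method 0:
// equivalent to sampling its spike count's worth of distinct frames) or as
// a circular shift of its observed frames (method 1). Per-neuron spike
// counts are preserved exactly by construction. Returns, per shuffle, the
// Firing(n) histogram: the number of frames in which exactly n neurons
// spike, n = 1..N.
//
// spikes: list of 0-based integer frame vectors, one per neuron.
// [[Rcpp::export]]
IntegerMatrix cpp_shuffle_firing(List spikes, int total_n, int n_shuffles,
                                 int method) {
  const int n_neurons = spikes.size();
  if (total_n <= 0 || n_shuffles < 1)
    stop("total_n and n_shuffles must be positive");

  std::vector<std::vector<int>> pos(n_neurons);
  for (int i = 0; i < n_neurons; ++i) {
    IntegerVector v = spikes[i];
    pos[i].assign(v.begin(), v.end());
    for (int p : pos[i])
      if (p < 0 || p >= total_n) stop("spike frame out of range");
  }

  IntegerMatrix firing(n_shuffles, n_neurons);
  std::vector<int> idx(total_n), occ(total_n, 0), drawn;
  for (int t = 0; t < total_n; ++t) idx[t] = t;

  for (int s = 0; s < n_shuffles; ++s) {
    drawn.clear();
    for (int i = 0; i < n_neurons; ++i) {
      const int c = pos[i].size();
      if (c == 0) continue;
      if (method == 0) {
        // partial Fisher-Yates: first c entries of idx become the new frames
        for (int j = 0; j < c; ++j) {
          int k = j + (int)(unif_rand() * (total_n - j));
          if (k >= total_n) k = total_n - 1;
          std::swap(idx[j], idx[k]);
          occ[idx[j]]++;
          drawn.push_back(idx[j]);
        }
      } else {
        int shift = (int)(unif_rand() * total_n);
        if (shift >= total_n) shift = total_n - 1;
        for (int j = 0; j < c; ++j) {
          int fr = pos[i][j] + shift;
          if (fr >= total_n) fr -= total_n;
          occ[fr]++;
          drawn.push_back(fr);
        }
      }
    }
    for (int fr : drawn) {
      const int k = occ[fr];
      if (k > 0) {
        firing(s, k - 1) += 1;
        occ[fr] = 0;
      }
    }
  }
  return firing;
}
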