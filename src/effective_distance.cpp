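#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Mean contact map over sampled loop configurations on a 1D lattice.
//
// For one configuration, the effective distance between bins i and j is the
// shortest path in the graph whose edges are adjacent-bin steps (weight 1)
// plus one anchor-tip shortcut (weight 1) per extruded loop. Contact is
// (d_eff + d0)^(-alpha), averaged over configurations. BFS from every bin;
// all edge weights are 1 so BFS is exact.
//
// samples: list of integer matrices, each with columns (left, right),
// 1-based bin indices on a chromosome of n_bins bins.
// [[Rcpp::export(name = ".contact_from_loops_cpp")]]
NumericMatrix contact_from_loops_cpp(int n_bins, List samples,
                                     double alpha, double d0) {
  const int n = n_bins;
  NumericMatrix acc(n, n);
  std::vector<double> pow_table(2 * n + 2);
  for (int d = 0; d <= 2 * n + 1; ++d)
    pow_table[d] = std::pow((double)d + d0, -alpha);

  std::vector<int> dist(n);
  std::vector<int> queue(n);
  const int S = samples.size();
  for (int s = 0; s < S; ++s) {
    IntegerMatrix loops = samples[s];
    std::vector<std::vector<int> > extra(n);
    for (int l = 0; l < loops.nrow(); ++l) {
      int a = loops(l, 0) - 1, b = loops(l, 1) - 1;
      if (a < 0 || b < 0 || a >= n || b >= n)
        stop("loop endpoint out of bounds");
      if (a != b) {
        extra[a].push_back(b);
        extra[b].push_back(a);
      }
    }
    for (int src = 0; src < n; ++src) {
      std::fill(dist.begin(), dist.end(), -1);
      int head = 0, tail = 0;
      dist[src] = 0;
      queue[tail++] = src;
      while (head < tail) {
        int u = queue[head++];
        int du = dist[u];
        if (u > 0 && dist[u - 1] < 0) { dist[u - 1] = du + 1; queue[tail++] = u - 1; }
        if (u < n - 1 && dist[u + 1] < 0) { dist[u + 1] = du + 1; queue[tail++] = u + 1; }
        for (size_t k = 0; k < extra[u].size(); ++k) {
          int v = extra[u][k];
          if (dist[v] < 0) { dist[v] = du + 1; queue[tail++] = v; }
        }
      }
      double *col = &acc(0, src);
      for (int i = 0; i < n; ++i) col[i] += pow_table[dist[i]];
    }
  }
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      acc(i, j) /= (double)S;
  return acc;
}
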