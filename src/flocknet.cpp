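#include <Rcpp.h>
using namespace Rcpp;

// Curveball trades on a binary presence matrix. Rows trade the species that
// are exclusive to one of the two rows, keeping both row sums and column sums
// intact. Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export]]
IntegerMatrix curveball_cpp(const IntegerMatrix& m, int n_trades) {
  const int nr = m.nrow(), nc = m.ncol();
  std::vector< std::vector<int> > rows(nr);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (m(i, j) == 1) rows[i].push_back(j);

  if (nr >= 2) {
    std::vector<char> inA(nc, 0), inB(nc, 0);
    std::vector<int> pool, newA, newB;
    for (int t = 0; t < n_trades; ++t) {
      int a = (int)(unif_rand() * nr); if (a == nr) --a;
      int b = (int)(unif_rand() * (nr - 1)); if (b == nr - 1) --b;
      if (b >= a) ++b;
      for (size_t k = 0; k < rows[a].size(); ++k) inA[rows[a][k]] = 1;
      for (size_t k = 0; k < rows[b].size(); ++k) inB[rows[b][k]] = 1;
      pool.clear();
      int ka = 0;
      for (size_t k = 0; k < rows[a].size(); ++k)
        if (!inB[rows[a][k]]) { pool.push_back(rows[a][k]); ++ka; }
      int kb = 0;
      for (size_t k = 0; k < rows[b].size(); ++k)
        if (!inA[rows[b][k]]) { pool.push_back(rows[b][k]); ++kb; }
      if (ka > 0 && kb > 0) {
        for (int i = (int)pool.size() - 1; i > 0; --i) {
          int j = (int)(unif_rand() * (i + 1)); if (j > i) j = i;
          std::swap(pool[i], pool[j]);
        }
        newA.clear(); newB.clear();
        for (size_t k = 0; k < rows[a].size(); ++k)
          if (inB[rows[a][k]]) newA.push_back(rows[a][k]);
        for (size_t k = 0; k < rows[b].size(); ++k)
          if (inA[rows[b][k]]) newB.push_back(rows[b][k]);
        for (int k = 0; k < ka; ++k) newA.push_back(pool[k]);
        for (size_t k = ka; k < pool.size(); ++k) newB.push_back(pool[k]);
        for (size_t k = 0; k < rows[a].size(); ++k) inA[rows[a][k]] = 0;
        for (size_t k = 0; k < rows[b].size(); ++k) inB[rows[b][k]] = 0;
        rows[a].swap(newA);
        rows[b].swap(newB);
      } else {
        for (size_t k = 0; k < rows[a].size(); ++k) inA[rows[a][k]] = 0;
        for (size_t k = 0; k < rows[b].size(); ++k) inB[rows[b][k]] = 0;
      }
    }
  }

  IntegerMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (size_t k = 0; k < rows[i].size(); ++k) out(i, rows[i][k]) = 1;
  return out;
}

// All-pairs shortest paths (Floyd-Warshall) on a matrix of edge lengths.
// len(i, j) <= 0 means "no edge". Lengths must be positive for real edges.
// [[Rcpp::export]]
NumericMatrix shortest_paths_cpp(const NumericMatrix& len) {
  const int n = len.nrow();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      d(i, j) = (i == j) ? 0.0 : (len(i, j) > 0.0 ? len(i, j) : R_PosInf);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i) {
      const double dik = d(i, k);
      if (!R_FINITE(dik)) continue;
      for (int j = 0; j < n; ++j) {
        const double alt = dik + d(k, j);
        if (alt < d(i, j)) d(i, j) = alt;
      }
    }
  return d;
}
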