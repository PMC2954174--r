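#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D connected-component labeling of a logical volume by breadth-first
// search, with 6-, 18- or 26-neighborhood connectivity. Returns an integer
// volume: 0 outside the foreground, component id (1-based) inside.
// [[Rcpp::export(name = ".labelComponents")]]
IntegerVector labelComponents(LogicalVector mask, IntegerVector dims,
                              int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int ord = std::abs(a) + std::abs(b) + std::abs(c);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const int nn = (int)di.size();

  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  std::vector<R_xlen_t> queue;
  int current = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++current;
    labels[s] = current;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int k = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v % ((R_xlen_t)nx * ny));
      int j = rem / nx;
      int i = rem % nx;
      for (int m = 0; m < nn; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          queue.push_back(w);
        }
      }
    }
  }
  return labels;
}
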