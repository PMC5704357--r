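#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected components of a 3D binary mask by breadth-first flood
// fill. `offsets` is an n x 3 integer matrix of neighbour displacements
// (row, col, slice); passing the 6/18/26-neighbourhood (or an in-plane
// 4/8 set) selects the adjacency. Labels are assigned in first-encounter
// (column-major scan) order, 1..K; background stays 0.
// [[Rcpp::export]]
IntegerVector cc_label(const LogicalVector& mask, const IntegerVector& dims,
                       const IntegerMatrix& offsets) {
  const int nr = dims[0], nc = dims[1], ns = dims[2];
  const R_xlen_t n = (R_xlen_t)nr * nc * ns;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  const int noff = offsets.nrow();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++next;
    labels[seed] = next;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      const int r = (int)(v % nr);
      const int c = (int)((v / nr) % nc);
      const int s = (int)(v / ((R_xlen_t)nr * nc));
      for (int o = 0; o < noff; ++o) {
        const int r2 = r + offsets(o, 0);
        const int c2 = c + offsets(o, 1);
        const int s2 = s + offsets(o, 2);
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc || s2 < 0 || s2 >= ns)
          continue;
        const R_xlen_t w = (R_xlen_t)r2 + (R_xlen_t)nr * (c2 + (R_xlen_t)nc * s2);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}
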