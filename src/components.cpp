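#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connectivity (3D) / 8-connectivity (2D via a singleton dimension)
// connected-component labeling of a binary volume by breadth-first search.
// Labels are 1..K in decreasing order of component size.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  size_t n = (size_t)d1 * d2 * d3;
  IntegerVector labels(n, 0);
  std::vector<size_t> sizes;  // per raw label
  std::vector<size_t> queue;
  int next = 0;
  for (size_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next;
    size_t sz = 0;
    queue.clear();
    queue.push_back(start);
    labels[start] = next;
    while (!queue.empty()) {
      size_t cur = queue.back();
      queue.pop_back();
      ++sz;
      int k = cur / ((size_t)d1 * d2);
      int rem = cur - (size_t)k * d1 * d2;
      int j = rem / d1;
      int i = rem - j * d1;
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= d3) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= d2) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= d1) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            size_t idx = ii + (size_t)d1 * (jj + (size_t)d2 * kk);
            if (mask[idx] && labels[idx] == 0) {
              labels[idx] = next;
              queue.push_back(idx);
            }
          }
        }
      }
    }
    sizes.push_back(sz);
  }
  // relabel so that label 1 is the largest component
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&sizes](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> remap(next + 1, 0);
  for (int rank = 0; rank < next; ++rank) remap[order[rank] + 1] = rank + 1;
  for (size_t i = 0; i < n; ++i)
    if (labels[i] != 0) labels[i] = remap[labels[i]];
  labels.attr("dim") = dims;
  return labels;
}
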