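#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Separable 3-D convolution with half-sample symmetric (edge-repeating)
// boundary reflection. `kernels` holds one odd-length tap vector per
// axis; a length-1 kernel skips that axis.
//
// [[Rcpp::export(name = ".conv3d_sep")]]
NumericVector conv3d_sep(NumericVector src, IntegerVector dim,
                         List kernels) {
  const int dims[3] = {dim[0], dim[1], dim[2]};
  const long strides[3] = {1L, (long)dims[0], (long)dims[0] * dims[1]};
  std::vector<double> a(src.begin(), src.end());
  std::vector<double> b(a.size());

  for (int axis = 0; axis < 3; ++axis) {
    NumericVector w = kernels[axis];
    const int L = w.size();
    if (L <= 1) continue;
    const int r = (L - 1) / 2;
    const int n = dims[axis];
    std::vector<long> tab(n + 2 * r);
    for (int i = 0; i < n + 2 * r; ++i) {
      long j = ((long)i - r) % (2L * n);
      if (j < 0) j += 2L * n;
      tab[i] = (j < n) ? j : (2L * n - 1 - j);
    }
    const int o1 = (axis == 0) ? 1 : 0;
    const int o2 = (axis == 2) ? 1 : 2;
    const long s = strides[axis];
    for (int c2 = 0; c2 < dims[o2]; ++c2) {
      for (int c1 = 0; c1 < dims[o1]; ++c1) {
        const long base = c1 * strides[o1] + c2 * strides[o2];
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          for (int t = 0; t < L; ++t)
            acc += w[t] * a[base + tab[i + t] * s];
          b[base + i * s] = acc;
        }
      }
    }
    a.swap(b);
  }
  return NumericVector(a.begin(), a.end());
}
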