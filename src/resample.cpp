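#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Trilinear resampling of a 3-D array under an affine voxel map.
//
// M is a 4x4 matrix mapping 0-based output voxel indices (homogeneous
// column vectors) to continuous 0-based source voxel coordinates.
// Output voxels that map outside the source grid are set to 0.
//
// [[Rcpp::export(name = ".affine_resample")]]
NumericVector affine_resample(NumericVector src, IntegerVector src_dim,
                              IntegerVector out_dim, NumericMatrix M) {
  const int sx = src_dim[0], sy = src_dim[1], sz = src_dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out(static_cast<R_xlen_t>(ox) * oy * oz);

  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);

  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      // Start of row (i varies fastest): precompute j,k contribution.
      const double bx = m01 * j + m02 * k + m03;
      const double by = m11 * j + m12 * k + m13;
      const double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < ox; ++i, ++idx) {
        const double x = m00 * i + bx;
        const double y = m10 * i + by;
        const double z = m20 * i + bz;
        if (x < 0 || y < 0 || z < 0 ||
            x > sx - 1 || y > sy - 1 || z > sz - 1) {
          out[idx] = 0.0;
          continue;
        }
        int x0 = static_cast<int>(std::floor(x));
        int y0 = static_cast<int>(std::floor(y));
        int z0 = static_cast<int>(std::floor(z));
        if (x0 == sx - 1) x0 = sx - 2 >= 0 ? sx - 2 : 0;
        if (y0 == sy - 1) y0 = sy - 2 >= 0 ? sy - 2 : 0;
        if (z0 == sz - 1) z0 = sz - 2 >= 0 ? sz - 2 : 0;
        const int x1 = (sx > 1) ? x0 + 1 : x0;
        const int y1 = (sy > 1) ? y0 + 1 : y0;
        const int z1 = (sz > 1) ? z0 + 1 : z0;
        const double fx = x - x0, fy = y - y0, fz = z - z0;

        const R_xlen_t sxy = static_cast<R_xlen_t>(sx) * sy;
        #define SRC(a, b, c) src[(a) + (b) * sx + (c) * sxy]
        const double c00 = SRC(x0,y0,z0) * (1-fx) + SRC(x1,y0,z0) * fx;
        const double c10 = SRC(x0,y1,z0) * (1-fx) + SRC(x1,y1,z0) * fx;
        const double c01 = SRC(x0,y0,z1) * (1-fx) + SRC(x1,y0,z1) * fx;
        const double c11 = SRC(x0,y1,z1) * (1-fx) + SRC(x1,y1,z1) * fx;
        #undef SRC
        const double c0 = c00 * (1-fy) + c10 * fy;
        const double c1 = c01 * (1-fy) + c11 * fy;
        out[idx] = c0 * (1-fz) + c1 * fz;
      }
    }
  }
  return out;
}
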