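#include <Rcpp.h>
using namespace Rcpp;

// Trilinear resampling of a 3D volume under an affine index map.
// src: numeric vector with dim attribute (nz, ny, nx), R column-major.
// A (3x3) and b (3): source index = A * target index + b, 0-based,
// component order (z, y, x). Targets mapping outside the source domain
// receive `fill` (0 for the fusion pipeline, so vacated space stays
// background).
// [[Rcpp::export]]
NumericVector c_resample_trilinear(NumericVector src, IntegerVector src_dim,
                                   NumericMatrix A, NumericVector b,
                                   IntegerVector out_dim, double fill) {
  const int sz = src_dim[0], sy = src_dim[1], sx = src_dim[2];
  const int oz = out_dim[0], oy = out_dim[1], ox = out_dim[2];
  NumericVector out(static_cast<R_xlen_t>(oz) * oy * ox);
  const double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  const double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  const double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  const double b0 = b[0], b1 = b[1], b2 = b[2];
  const double *s = src.begin();
  double *o = out.begin();

  // R layout: linear index = z + nz*y + nz*ny*x
  for (int x = 0; x < ox; ++x) {
    for (int y = 0; y < oy; ++y) {
      const double pz0 = a01 * y + a02 * x + b0;
      const double py0 = a11 * y + a12 * x + b1;
      const double px0 = a21 * y + a22 * x + b2;
      R_xlen_t base = (static_cast<R_xlen_t>(x) * oy + y) * oz;
      for (int z = 0; z < oz; ++z) {
        const double pz = a00 * z + pz0;
        const double py = a10 * z + py0;
        const double px = a20 * z + px0;
        double val = fill;
        if (pz >= 0 && pz <= sz - 1 && py >= 0 && py <= sy - 1 &&
            px >= 0 && px <= sx - 1) {
          int z0 = static_cast<int>(std::floor(pz));
          int y0 = static_cast<int>(std::floor(py));
          int x0 = static_cast<int>(std::floor(px));
          if (z0 == sz - 1) --z0;
          if (y0 == sy - 1) --y0;
          if (x0 == sx - 1) --x0;
          if (sz == 1) z0 = 0;
          if (sy == 1) y0 = 0;
          if (sx == 1) x0 = 0;
          const double fz = pz - z0, fy = py - y0, fx = px - x0;
          const int z1 = (sz == 1) ? z0 : z0 + 1;
          const int y1 = (sy == 1) ? y0 : y0 + 1;
          const int x1 = (sx == 1) ? x0 : x0 + 1;
          #define SRC(zz, yy, xx) \
            s[(static_cast<R_xlen_t>(xx) * sy + (yy)) * sz + (zz)]
          const double c00 = SRC(z0, y0, x0) * (1 - fz) + SRC(z1, y0, x0) * fz;
          const double c01 = SRC(z0, y0, x1) * (1 - fz) + SRC(z1, y0, x1) * fz;
          const double c10 = SRC(z0, y1, x0) * (1 - fz) + SRC(z1, y1, x0) * fz;
          const double c11 = SRC(z0, y1, x1) * (1 - fz) + SRC(z1, y1, x1) * fz;
          const double c0 = c00 * (1 - fy) + c10 * fy;
          const double c1 = c01 * (1 - fy) + c11 * fy;
          val = c0 * (1 - fx) + c1 * fx;
          #undef SRC
        }
        o[base + z] = val;
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}
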