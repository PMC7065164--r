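#include <Rcpp.h>
using namespace Rcpp;

// Pull-back resampling of a 3-D volume.
//
// `m` is the combined 4x4 map from 0-based *output* voxel indices to 0-based
// *source* voxel indices, i.e. m = inv(A_src) * inv(T) * A_ref for a
// world-to-world transform T and voxel-to-world affines A_src, A_ref.
// interp: 0 = nearest neighbour, 1 = trilinear. Out-of-field -> fill.
// [[Rcpp::export]]
NumericVector resample_core(NumericVector src, IntegerVector dim_src,
                            NumericMatrix m, IntegerVector dim_out,
                            int interp, double fill) {
  const int nx = dim_src[0], ny = dim_src[1], nz = dim_src[2];
  const int ox = dim_out[0], oy = dim_out[1], oz = dim_out[2];
  NumericVector out((R_xlen_t)ox * oy * oz);

  const double m00 = m(0,0), m01 = m(0,1), m02 = m(0,2), m03 = m(0,3);
  const double m10 = m(1,0), m11 = m(1,1), m12 = m(1,2), m13 = m(1,3);
  const double m20 = m(2,0), m21 = m(2,1), m22 = m(2,2), m23 = m(2,3);

  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      for (int i = 0; i < ox; ++i, ++idx) {
        const double sx = m00*i + m01*j + m02*k + m03;
        const double sy = m10*i + m11*j + m12*k + m13;
        const double sz = m20*i + m21*j + m22*k + m23;
        if (interp == 0) {
          const int ri = (int)std::floor(sx + 0.5);
          const int rj = (int)std::floor(sy + 0.5);
          const int rk = (int)std::floor(sz + 0.5);
          if (ri < 0 || rj < 0 || rk < 0 || ri >= nx || rj >= ny || rk >= nz) {
            out[idx] = fill;
          } else {
            out[idx] = src[(R_xlen_t)ri + nx * ((R_xlen_t)rj + (R_xlen_t)ny * rk)];
          }
        } else {
          const int i0 = (int)std::floor(sx);
          const int j0 = (int)std::floor(sy);
          const int k0 = (int)std::floor(sz);
          if (i0 < 0 || j0 < 0 || k0 < 0 ||
              i0 + 1 >= nx || j0 + 1 >= ny || k0 + 1 >= nz) {
            // allow exact upper-boundary hits
            if (sx >= 0 && sy >= 0 && sz >= 0 &&
                sx <= nx - 1 && sy <= ny - 1 && sz <= nz - 1) {
              const int ci = (int)std::min((double)(nx - 1), std::max(0.0, std::floor(sx + 0.5)));
              const int cj = (int)std::min((double)(ny - 1), std::max(0.0, std::floor(sy + 0.5)));
              const int ck = (int)std::min((double)(nz - 1), std::max(0.0, std::floor(sz + 0.5)));
              out[idx] = src[(R_xlen_t)ci + nx * ((R_xlen_t)cj + (R_xlen_t)ny * ck)];
            } else {
              out[idx] = fill;
            }
            continue;
          }
          const double fx = sx - i0, fy = sy - j0, fz = sz - k0;
          const R_xlen_t base = (R_xlen_t)i0 + nx * ((R_xlen_t)j0 + (R_xlen_t)ny * k0);
          const R_xlen_t dx = 1, dy2 = nx, dz2 = (R_xlen_t)nx * ny;
          const double c000 = src[base];
          const double c100 = src[base + dx];
          const double c010 = src[base + dy2];
          const double c110 = src[base + dx + dy2];
          const double c001 = src[base + dz2];
          const double c101 = src[base + dx + dz2];
          const double c011 = src[base + dy2 + dz2];
          const double c111 = src[base + dx + dy2 + dz2];
          const double c00 = c000 * (1 - fx) + c100 * fx;
          const double c10 = c010 * (1 - fx) + c110 * fx;
          const double c01 = c001 * (1 - fx) + c101 * fx;
          const double c11 = c011 * (1 - fx) + c111 * fx;
          const double c0 = c00 * (1 - fy) + c10 * fy;
          const double c1 = c01 * (1 - fy) + c11 * fy;
          out[idx] = c0 * (1 - fz) + c1 * fz;
        }
      }
    }
  }
  out.attr("dim") = dim_out;
  return out;
}

// Normalized cross-correlation between two equal-length vectors,
// restricted to positions where `use` is TRUE and both values are finite.
// [[Rcpp::export]]
double ncc_masked(NumericVector a, NumericVector b, LogicalVector use) {
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  R_xlen_t n = 0;
  const R_xlen_t len = a.size();
  for (R_xlen_t i = 0; i < len; ++i) {
    if (!use[i]) continue;
    const double x = a[i], y = b[i];
    if (!R_finite(x) || !R_finite(y)) continue;
    sa += x; sb += y; saa += x * x; sbb += y * y; sab += x * y;
    ++n;
  }
  if (n < 10) return NA_REAL;
  const double va = saa - sa * sa / n;
  const double vb = sbb - sb * sb / n;
  if (va <= 0 || vb <= 0) return NA_REAL;
  return (sab - sa * sb / n) / std::sqrt(va * vb);
}
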