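#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of a 3D scalar grid at continuous voxel
// coordinates (0-based; voxel i is centered at coordinate i). Points
// outside the grid sample as 0, matching a mask embedded in empty
// space.
// [[Rcpp::export]]
NumericVector sample_trilinear(NumericVector vol, IntegerVector dims,
                               NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (int p = 0; p < n; ++p) {
    const double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < -1 || y < -1 || z < -1 || x > nx || y > ny || z > nz) {
      out[p] = 0.0;
      continue;
    }
    const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0.0;
    for (int dz = 0; dz <= 1; ++dz) {
      const int zz = z0 + dz;
      if (zz < 0 || zz >= nz) continue;
      const double wz = dz ? fz : 1.0 - fz;
      for (int dy = 0; dy <= 1; ++dy) {
        const int yy = y0 + dy;
        if (yy < 0 || yy >= ny) continue;
        const double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx <= 1; ++dx) {
          const int xx = x0 + dx;
          if (xx < 0 || xx >= nx) continue;
          const double wx = dx ? fx : 1.0 - fx;
          acc += wx * wy * wz * v[xx * sx + yy * sy + zz * sz];
        }
      }
    }
    out[p] = acc;
  }
  return out;
}
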