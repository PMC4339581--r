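#include <Rcpp.h>
using namespace Rcpp;

// Scaling index transform of a cubic (or box) gray-level volume.
//
// Every voxel i is a 4-D point (x, y, z, s * g) with unit voxel spacing and
// intensity scaling s. Its scaling index is
//   alpha_i = 2 * sum_j u_ij^2 exp(-u_ij^2) / sum_j exp(-u_ij^2),
//   u_ij = d_ij / r,
// with d_ij the 4-D Euclidean distance and the sum over all voxels j of the
// volume (self term included: adds 0 to the numerator, 1 to the denominator).
//
// cutoff <= 0 or non-finite means exact mode (all pairs). Otherwise voxels
// whose *spatial* distance exceeds cutoff * r are omitted, and a per-voxel
// absolute error bound on alpha is returned alongside:
//   |alpha_exact - alpha_trunc| <= (2 n_om M + n_om e^{-c^2} alpha_trunc) / S0
// where n_om is the number of omitted voxels, c = cutoff, S0 the retained
// Gaussian mass and M = max_{u >= c} u^2 e^{-u^2}.
// [[Rcpp::export(name = ".sim_alpha_cpp")]]
List sim_alpha_cpp(NumericVector g, IntegerVector dims, double r,
                   double iscale, double cutoff) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  NumericVector alpha(n), bound(n);
  const bool exact = !R_finite(cutoff) || cutoff <= 0.0;
  const double r2 = r * r;
  const double c2 = exact ? 0.0 : cutoff * cutoff;
  // max of u^2 e^{-u^2} on [cutoff, Inf): e^{-1} if cutoff <= 1
  const double M = exact ? 0.0
                         : (cutoff <= 1.0 ? std::exp(-1.0)
                                          : c2 * std::exp(-c2));
  const int w = exact ? 0 : (int)std::ceil(cutoff * r);

  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        const int i = ix + nx * (iy + ny * iz);
        const double gi = iscale * g[i];
        double s0 = 0.0, s1 = 0.0;
        long n_kept = 0;
        const int x0 = exact ? 0 : std::max(0, ix - w);
        const int x1 = exact ? nx - 1 : std::min(nx - 1, ix + w);
        const int y0 = exact ? 0 : std::max(0, iy - w);
        const int y1 = exact ? ny - 1 : std::min(ny - 1, iy + w);
        const int z0 = exact ? 0 : std::max(0, iz - w);
        const int z1 = exact ? nz - 1 : std::min(nz - 1, iz + w);
        for (int jz = z0; jz <= z1; ++jz) {
          const double dz2 = (double)(jz - iz) * (jz - iz);
          for (int jy = y0; jy <= y1; ++jy) {
            const double dy2 = (double)(jy - iy) * (jy - iy);
            for (int jx = x0; jx <= x1; ++jx) {
              const double dx2 = (double)(jx - ix) * (jx - ix);
              const double sp2 = dx2 + dy2 + dz2;
              if (!exact && sp2 > c2 * r2) continue;
              const int j = jx + nx * (jy + ny * jz);
              const double dg = gi - iscale * g[j];
              const double u2 = (sp2 + dg * dg) / r2;
              const double wgt = std::exp(-u2);
              s0 += wgt;
              s1 += u2 * wgt;
              ++n_kept;
            }
          }
        }
        alpha[i] = 2.0 * s1 / s0;
        if (!exact) {
          const double n_om = (double)(n - n_kept);
          bound[i] = (2.0 * n_om * M + n_om * std::exp(-c2) * alpha[i]) / s0;
        }
      }
    }
  }
  return List::create(_["alpha"] = alpha, _["error_bound"] = bound);
}
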