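#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian-bead density kernels.  All coordinates are in Angstrom; grids use
// MRC semantics (x fastest, physical position of voxel (i,j,k), 0-based, is
// origin + voxel * (i,j,k)).  Beads are rendered as normalised isotropic
// Gaussians w * exp(-r^2 / (2 sigma^2)) / (2 pi sigma^2)^(3/2) so that the
// continuous integral of one bead equals its weight.

// [[Rcpp::export]]
NumericVector cpp_render_gaussians(IntegerVector dim, double voxel,
                                   NumericVector origin, NumericMatrix coords,
                                   NumericVector weights, double sigma,
                                   double cutoff_sd) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  const double cut = cutoff_sd * sigma;
  const double cut2 = cut * cut;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double norm = 1.0 / std::pow(2.0 * M_PI * sigma * sigma, 1.5);
  const int n = coords.nrow();
  for (int p = 0; p < n; ++p) {
    const double px = coords(p, 0), py = coords(p, 1), pz = coords(p, 2);
    const double amp = weights[p] * norm;
    // local cube of voxels within the cutoff
    int i0 = (int)std::ceil((px - cut - origin[0]) / voxel);
    int i1 = (int)std::floor((px + cut - origin[0]) / voxel);
    int j0 = (int)std::ceil((py - cut - origin[1]) / voxel);
    int j1 = (int)std::floor((py + cut - origin[1]) / voxel);
    int k0 = (int)std::ceil((pz - cut - origin[2]) / voxel);
    int k1 = (int)std::floor((pz + cut - origin[2]) / voxel);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + voxel * k - pz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + voxel * j - py;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > cut2) continue;
        R_xlen_t base = (static_cast<R_xlen_t>(k) * ny + j) * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + voxel * i - px;
          const double r2 = dx * dx + dyz2;
          if (r2 <= cut2) out[base + i] += amp * std::exp(-r2 * inv2s2);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_density_at_points(NumericMatrix points, NumericMatrix coords,
                                    NumericVector weights, double sigma,
                                    double cutoff_sd) {
  const int m = points.nrow(), n = coords.nrow();
  NumericVector out(m);
  const double cut2 = cutoff_sd * sigma * cutoff_sd * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double norm = 1.0 / std::pow(2.0 * M_PI * sigma * sigma, 1.5);
  for (int p = 0; p < n; ++p) {
    const double px = coords(p, 0), py = coords(p, 1), pz = coords(p, 2);
    const double amp = weights[p] * norm;
    for (int q = 0; q < m; ++q) {
      const double dx = points(q, 0) - px;
      const double dy = points(q, 1) - py;
      const double dz = points(q, 2) - pz;
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= cut2) out[q] += amp * std::exp(-r2 * inv2s2);
    }
  }
  return out;
}

// Indices (1-based, into the flattened x-fastest grid) of voxels lying within
// `radius` of any row of `coords`.  `stride` subsamples the grid (every
// stride-th voxel along each axis) for cheap global scoring masks.
// [[Rcpp::export]]
IntegerVector cpp_mask_near_points(IntegerVector dim, double voxel,
                                   NumericVector origin, NumericMatrix coords,
                                   double radius, int stride) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> hit(static_cast<size_t>(nx) * ny * nz, 0);
  const double r2max = radius * radius;
  const int n = coords.nrow();
  for (int p = 0; p < n; ++p) {
    const double px = coords(p, 0), py = coords(p, 1), pz = coords(p, 2);
    int i0 = (int)std::ceil((px - radius - origin[0]) / voxel);
    int i1 = (int)std::floor((px + radius - origin[0]) / voxel);
    int j0 = (int)std::ceil((py - radius - origin[1]) / voxel);
    int j1 = (int)std::floor((py + radius - origin[1]) / voxel);
    int k0 = (int)std::ceil((pz - radius - origin[2]) / voxel);
    int k1 = (int)std::floor((pz + radius - origin[2]) / voxel);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      if (k % stride) continue;
      const double dz = origin[2] + voxel * k - pz;
      for (int j = j0; j <= j1; ++j) {
        if (j % stride) continue;
        const double dy = origin[1] + voxel * j - py;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2max) continue;
        size_t base = (static_cast<size_t>(k) * ny + j) * nx;
        for (int i = i0; i <= i1; ++i) {
          if (i % stride) continue;
          const double dx = origin[0] + voxel * i - px;
          if (dx * dx + dyz2 <= r2max) hit[base + i] = 1;
        }
      }
    }
  }
  std::vector<int> idx;
  for (size_t v = 0; v < hit.size(); ++v)
    if (hit[v]) idx.push_back(static_cast<int>(v) + 1);
  return wrap(idx);
}

// Cylindrical pose scan used by both the global and the localised fit.
// For every combination of azimuth (deg, about the +z axis through x=y=0),
// axial shift dz (A) and radial shift dr (A, beads pushed away from the axis),
// the bead set is transformed, its Gaussian density is evaluated at the mask
// points, and the Pearson correlation against `map_vals` is recorded.
// Returns an az x dz x dr array (as a vector, az fastest).
// [[Rcpp::export]]
NumericVector cpp_score_pose_grid(NumericMatrix points, NumericVector map_vals,
                                  NumericMatrix coords, NumericVector weights,
                                  double sigma, double cutoff_sd,
                                  NumericVector az_deg, NumericVector dz_grid,
                                  NumericVector dr_grid) {
  const int m = points.nrow(), n = coords.nrow();
  const int na = az_deg.size(), nz = dz_grid.size(), nr = dr_grid.size();
  NumericVector out(static_cast<R_xlen_t>(na) * nz * nr);
  const double cut2 = cutoff_sd * sigma * cutoff_sd * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double norm = 1.0 / std::pow(2.0 * M_PI * sigma * sigma, 1.5);

  // map-side Pearson terms are fixed
  double msum = 0.0, msum2 = 0.0;
  for (int q = 0; q < m; ++q) { msum += map_vals[q]; msum2 += map_vals[q] * map_vals[q]; }
  const double mmean = msum / m;
  const double mvar = msum2 / m - mmean * mmean;

  std::vector<double> bx(n), by(n), bz(n), dens(m);
  for (int ir = 0; ir < nr; ++ir) {
    const double dr = dr_grid[ir];
    for (int iz = 0; iz < nz; ++iz) {
      const double dz = dz_grid[iz];
      for (int ia = 0; ia < na; ++ia) {
        const double th = az_deg[ia] * M_PI / 180.0;
        const double c = std::cos(th), s = std::sin(th);
        for (int p = 0; p < n; ++p) {
          double x = coords(p, 0) * c - coords(p, 1) * s;
          double y = coords(p, 0) * s + coords(p, 1) * c;
          if (dr != 0.0) {
            double r = std::sqrt(x * x + y * y);
            if (r > 1e-9) { double f = (r + dr) / r; x *= f; y *= f; }
          }
          bx[p] = x; by[p] = y; bz[p] = coords(p, 2) + dz;
        }
        std::fill(dens.begin(), dens.end(), 0.0);
        for (int p = 0; p < n; ++p) {
          const double amp = weights[p] * norm;
          const double px = bx[p], py = by[p], pz = bz[p];
          for (int q = 0; q < m; ++q) {
            const double ddx = points(q, 0) - px;
            const double ddy = points(q, 1) - py;
            const double ddz = points(q, 2) - pz;
            const double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (r2 <= cut2) dens[q] += amp * std::exp(-r2 * inv2s2);
          }
        }
        double dsum = 0.0, dsum2 = 0.0, cross = 0.0;
        for (int q = 0; q < m; ++q) {
          dsum += dens[q]; dsum2 += dens[q] * dens[q];
          cross += dens[q] * map_vals[q];
        }
        const double dmean = dsum / m;
        const double dvar = dsum2 / m - dmean * dmean;
        double score = 0.0;
        if (dvar > 1e-30 && mvar > 1e-30)
          score = (cross / m - mmean * dmean) / std::sqrt(dvar * mvar);
        out[(static_cast<R_xlen_t>(ir) * nz + iz) * na + ia] = score;
      }
    }
  }
  return out;
}
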