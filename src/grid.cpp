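#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel-grid classification of the space around a structure.
// Lattice point (ix,iy,iz) sits at origin + step * (ix,iy,iz), 0-based.
// Labels: 0 = EMPTY, 1 = SURFACE, 2 = INTERIOR.
// A lattice point is "protein" when within `radius` (Euclidean, <=) of any
// atom center; a protein point is INTERIOR when all six axis neighbours are
// protein, SURFACE otherwise. Out-of-extent neighbours count as non-protein,
// so extent-boundary points can never be INTERIOR.

static inline size_t idx3(int ix, int iy, int iz, int nx, int ny) {
  return (size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * (size_t)iz);
}

// [[Rcpp::export(name = ".grid_label_cpp")]]
IntegerVector grid_label_cpp(NumericMatrix coords, NumericVector origin,
                             IntegerVector dims, double step, double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  std::vector<char> protein(N, 0);
  const double r2 = radius * radius;
  const int reach = (int)std::ceil(radius / step);
  for (int k = 0; k < coords.nrow(); ++k) {
    const double x = coords(k, 0), y = coords(k, 1), z = coords(k, 2);
    const int cx = (int)std::floor((x - origin[0]) / step + 0.5);
    const int cy = (int)std::floor((y - origin[1]) / step + 0.5);
    const int cz = (int)std::floor((z - origin[2]) / step + 0.5);
    for (int iz = std::max(0, cz - reach); iz <= std::min(nz - 1, cz + reach); ++iz) {
      const double dz = origin[2] + step * iz - z;
      for (int iy = std::max(0, cy - reach); iy <= std::min(ny - 1, cy + reach); ++iy) {
        const double dy = origin[1] + step * iy - y;
        for (int ix = std::max(0, cx - reach); ix <= std::min(nx - 1, cx + reach); ++ix) {
          const double dx = origin[0] + step * ix - x;
          if (dx * dx + dy * dy + dz * dz <= r2)
            protein[idx3(ix, iy, iz, nx, ny)] = 1;
        }
      }
    }
  }
  IntegerVector labels(N, 0);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const size_t i = idx3(ix, iy, iz, nx, ny);
        if (!protein[i]) continue;
        const bool interior =
          ix > 0 && protein[idx3(ix - 1, iy, iz, nx, ny)] &&
          ix < nx - 1 && protein[idx3(ix + 1, iy, iz, nx, ny)] &&
          iy > 0 && protein[idx3(ix, iy - 1, iz, nx, ny)] &&
          iy < ny - 1 && protein[idx3(ix, iy + 1, iz, nx, ny)] &&
          iz > 0 && protein[idx3(ix, iy, iz - 1, nx, ny)] &&
          iz < nz - 1 && protein[idx3(ix, iy, iz + 1, nx, ny)];
        labels[i] = interior ? 2 : 1;
      }
  return labels;
}

// Per-atom surface flag: TRUE when some SURFACE lattice point lies within
// `radius` (<=) of the atom center.
// [[Rcpp::export(name = ".surface_atoms_cpp")]]
LogicalVector surface_atoms_cpp(NumericMatrix coords, NumericVector origin,
                                IntegerVector dims, double step,
                                IntegerVector labels, double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double r2 = radius * radius;
  const int reach = (int)std::ceil(radius / step);
  LogicalVector out(coords.nrow());
  for (int k = 0; k < coords.nrow(); ++k) {
    const double x = coords(k, 0), y = coords(k, 1), z = coords(k, 2);
    const int cx = (int)std::floor((x - origin[0]) / step + 0.5);
    const int cy = (int)std::floor((y - origin[1]) / step + 0.5);
    const int cz = (int)std::floor((z - origin[2]) / step + 0.5);
    bool hit = false;
    for (int iz = std::max(0, cz - reach); !hit && iz <= std::min(nz - 1, cz + reach); ++iz) {
      const double dz = origin[2] + step * iz - z;
      for (int iy = std::max(0, cy - reach); !hit && iy <= std::min(ny - 1, cy + reach); ++iy) {
        const double dy = origin[1] + step * iy - y;
        for (int ix = std::max(0, cx - reach); ix <= std::min(nx - 1, cx + reach); ++ix) {
          if (labels[idx3(ix, iy, iz, nx, ny)] != 1) continue;
          const double dx = origin[0] + step * ix - x;
          if (dx * dx + dy * dy + dz * dz <= r2) { hit = true; break; }
        }
      }
    }
    out[k] = hit;
  }
  return out;
}
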