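#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area on a deterministic
// Fibonacci sphere lattice. Points are identical for every atom and every
// call, so results are reproducible across platforms and runs. Neighbours
// are visited nearest-first so occluded points exit early.

// [[Rcpp::export(name = ".sasa_atoms")]]
NumericVector sasa_atoms(const NumericMatrix& xyz,
                         const NumericVector& radii,
                         const double probe,
                         const int n_points) {
  const int n = xyz.nrow();
  NumericVector area(n);
  if (n == 0) return area;

  // Fibonacci lattice on the unit sphere
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));  // golden angle
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    px[k] = r * std::cos(ga * k);
    py[k] = r * std::sin(ga * k);
    pz[k] = z;
  }

  std::vector<double> x(n), y(n), z(n), rext(n);
  for (int i = 0; i < n; ++i) {
    x[i] = xyz(i, 0);
    y[i] = xyz(i, 1);
    z[i] = xyz(i, 2);
    rext[i] = radii[i] + probe;
  }

  // neighbour scratch: squared distance to atom i, delta coords, r_j^2
  struct Nbr { double d2, dx, dy, dz, r2; };
  std::vector<Nbr> nbr;
  nbr.reserve(64);

  for (int i = 0; i < n; ++i) {
    const double ri = rext[i];
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double rr = ri + rext[j];
      if (d2 < rr * rr) {
        nbr.push_back({d2, dx, dy, dz, rext[j] * rext[j]});
      }
    }
    std::sort(nbr.begin(), nbr.end(),
              [](const Nbr& a, const Nbr& b) { return a.d2 < b.d2; });
    const size_t m = nbr.size();

    int accessible = 0;
    for (int k = 0; k < n_points; ++k) {
      const double qx = ri * px[k], qy = ri * py[k], qz = ri * pz[k];
      bool free_point = true;
      for (size_t t = 0; t < m; ++t) {
        const double dx = qx - nbr[t].dx, dy = qy - nbr[t].dy,
                     dz = qz - nbr[t].dz;
        if (dx * dx + dy * dy + dz * dz < nbr[t].r2) {
          free_point = false;
          break;
        }
      }
      if (free_point) ++accessible;
    }
    area[i] = 4.0 * M_PI * ri * ri * accessible / n_points;
  }
  return area;
}
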