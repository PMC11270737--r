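#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
// Test points on each atom's solvent sphere (radius + probe) are placed
// on a golden-spiral lattice; a point is exposed if it lies outside every
// neighbour's solvent sphere.  Area = exposed fraction * sphere area.

// [[Rcpp::export(name = ".sasa_frame")]]
NumericVector sasa_frame(NumericMatrix coords, NumericVector radii,
                         double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector area(n);

  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }

  std::vector<double> rs(n);
  for (int i = 0; i < n; ++i) rs[i] = radii[i] + probe;

  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double ri = rs[i];
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - coords(i, 0);
      double dy = coords(j, 1) - coords(i, 1);
      double dz = coords(j, 2) - coords(i, 2);
      double cut = ri + rs[j];
      if (dx * dx + dy * dy + dz * dz < cut * cut) nbr.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      double x = coords(i, 0) + ri * px[k];
      double y = coords(i, 1) + ri * py[k];
      double z = coords(i, 2) + ri * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nbr.size(); ++m) {
        int j = nbr[m];
        double dx = x - coords(j, 0);
        double dy = y - coords(j, 1);
        double dz = z - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rs[j] * rs[j]) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++exposed;
    }
    area[i] = 4.0 * M_PI * ri * ri * exposed / n_points;
  }
  return area;
}
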