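#include <Rcpp.h>
using namespace Rcpp;

// Golden-spiral (Fibonacci) quasi-uniform points on the unit sphere.
// Deterministic; no RNG.
// [[Rcpp::export(name = ".fibonacci_sphere_cpp")]]
NumericMatrix fibonacci_sphere_cpp(int n) {
  NumericMatrix pts(n, 3);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * i;
    pts(i, 0) = r * std::cos(phi);
    pts(i, 1) = r * std::sin(phi);
    pts(i, 2) = z;
  }
  return pts;
}

static inline double min_image(double d, double L, bool periodic) {
  if (periodic) d -= L * std::nearbyint(d / L);
  return d;
}

// Shrake-Rupley exposed area per atom. coords: n x 3 (nm), radii: vdW radii
// (nm), probe: probe radius (nm). Burial tests use minimum-image distances on
// periodic axes.
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points, NumericVector box,
                       LogicalVector periodic) {
  int n = coords.nrow();
  NumericVector area(n);
  if (n == 0) return area;
  NumericMatrix sp = fibonacci_sphere_cpp(n_points);
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;
  double Lx = box[0], Ly = box[1], Lz = box[2];
  bool px = periodic[0], py = periodic[1], pz = periodic[2];

  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = min_image(coords(j, 0) - coords(i, 0), Lx, px);
      double dy = min_image(coords(j, 1) - coords(i, 1), Ly, py);
      double dz = min_image(coords(j, 2) - coords(i, 2), Lz, pz);
      double cut = R[i] + R[j];
      if (dx * dx + dy * dy + dz * dz < cut * cut) nbr.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      double pxp = coords(i, 0) + R[i] * sp(k, 0);
      double pyp = coords(i, 1) + R[i] * sp(k, 1);
      double pzp = coords(i, 2) + R[i] * sp(k, 2);
      bool buried = false;
      for (size_t q = 0; q < nbr.size(); ++q) {
        int j = nbr[q];
        double dx = min_image(coords(j, 0) - pxp, Lx, px);
        double dy = min_image(coords(j, 1) - pyp, Ly, py);
        double dz = min_image(coords(j, 2) - pzp, Lz, pz);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) { buried = true; break; }
      }
      if (!buried) ++exposed;
    }
    area[i] = 4.0 * M_PI * R[i] * R[i] * exposed / n_points;
  }
  return area;
}
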