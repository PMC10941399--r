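#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Minimum Euclidean distance from each row of `a` to any row of `b`.
// Both matrices are n x 3 coordinate sets in Angstrom.
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    const double xi = a(i, 0), yi = a(i, 1), zi = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - b(j, 0), dy = yi - b(j, 1), dz = zi - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Band membership: for each row of `pts`, TRUE iff its nearest-atom
// distance lies in [dmin, dmax]. Early exit once any atom is closer than
// dmin (the point is inside the exclusion zone).
// [[Rcpp::export]]
LogicalVector cpp_band_filter(NumericMatrix pts, NumericMatrix atoms,
                              double dmin, double dmax) {
  const int np = pts.nrow(), na = atoms.nrow();
  const double lo2 = dmin * dmin, hi2 = dmax * dmax;
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    double best = R_PosInf;
    bool inside = false;
    for (int j = 0; j < na; ++j) {
      const double dx = xi - atoms(j, 0), dy = yi - atoms(j, 1),
                   dz = zi - atoms(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < lo2) { inside = true; break; }
      if (d2 < best) best = d2;
    }
    out[i] = !inside && best >= lo2 && best <= hi2;
  }
  return out;
}

// For each query point, count how many distinct groups (1-based ids in
// `group`, one per atom row) have at least one atom within `radius`.
// Used for cloud-point multiplicity: groups are predicted binding residues.
// [[Rcpp::export]]
IntegerVector cpp_count_groups_within(NumericMatrix points, NumericMatrix atoms,
                                      IntegerVector group, int n_groups,
                                      double radius) {
  const int np = points.nrow(), na = atoms.nrow();
  const double r2 = radius * radius;
  IntegerVector out(np);
  std::vector<int> seen(n_groups + 1, -1);
  for (int i = 0; i < np; ++i) {
    int count = 0;
    const double xi = points(i, 0), yi = points(i, 1), zi = points(i, 2);
    for (int j = 0; j < na; ++j) {
      const int g = group[j];
      if (seen[g] == i) continue;
      const double dx = xi - atoms(j, 0), dy = yi - atoms(j, 1),
                   dz = zi - atoms(j, 2);
      if (dx * dx + dy * dy + dz * dz <= r2) {
        seen[g] = i;
        ++count;
      }
    }
    out[i] = count;
  }
  return out;
}

// Radius-neighbour lists (inclusive cutoff, self excluded), 1-based indices.
// [[Rcpp::export]]
List cpp_radius_neighbors(NumericMatrix pts, double eps) {
  const int n = pts.nrow();
  const double e2 = eps * eps;
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = pts(i, 0) - pts(j, 0), dy = pts(i, 1) - pts(j, 1),
                   dz = pts(i, 2) - pts(j, 2);
      if (dx * dx + dy * dy + dz * dz <= e2) {
        nb[i].push_back(j + 1);
        nb[j].push_back(i + 1);
      }
    }
  }
  List out(n);
  for (int i = 0; i < n; ++i) out[i] = wrap(nb[i]);
  return out;
}

// Shrake-Rupley solvent-accessible surface area per atom.
// Test points are placed on each atom's solvent-expanded sphere
// (radius + probe) along a deterministic golden-spiral lattice; a point is
// accessible if it lies outside every neighbour's expanded sphere.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       int n_sphere, double probe) {
  const int n = coords.nrow();
  // golden-spiral unit sphere points
  std::vector<double> sx(n_sphere), sy(n_sphere), sz(n_sphere);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_sphere; ++k) {
    const double z = 1.0 - (2.0 * k + 1.0) / n_sphere;
    const double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    const double th = golden * k;
    sx[k] = r * std::cos(th);
    sy[k] = r * std::sin(th);
    sz[k] = z;
  }
  NumericVector out(n);
  std::vector<int> neigh;
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    neigh.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double reach = ri + radii[j] + probe;
      const double dx = coords(i, 0) - coords(j, 0),
                   dy = coords(i, 1) - coords(j, 1),
                   dz = coords(i, 2) - coords(j, 2);
      if (dx * dx + dy * dy + dz * dz < reach * reach) neigh.push_back(j);
    }
    int accessible = 0;
    for (int k = 0; k < n_sphere; ++k) {
      const double px = coords(i, 0) + ri * sx[k],
                   py = coords(i, 1) + ri * sy[k],
                   pz = coords(i, 2) + ri * sz[k];
      bool free_pt = true;
      for (size_t m = 0; m < neigh.size(); ++m) {
        const int j = neigh[m];
        const double rj = radii[j] + probe;
        const double dx = px - coords(j, 0), dy = py - coords(j, 1),
                     dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++accessible;
    }
    out[i] = 4.0 * M_PI * ri * ri * accessible / n_sphere;
  }
  return out;
}
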