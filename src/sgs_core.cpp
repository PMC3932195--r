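#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Covariance function matching the variogram model: C(h) = sill - gamma(h).
// model: 1 spherical (actual range), 2 gaussian (practical range),
//        3 exponential (practical range). Nugget contributes only at h == 0.
static inline double cov_at(double h, int model, double c0, double c, double a) {
  if (h <= 0.0) return c0 + c;
  double g;
  switch (model) {
  case 1: {
    if (h >= a) return 0.0;
    double r = h / a;
    g = 1.0 - (1.5 * r - 0.5 * r * r * r);
    break;
  }
  case 2: {
    double r = h / a;
    g = std::exp(-3.0 * r * r);
    break;
  }
  default:
    g = std::exp(-3.0 * h / a);
  }
  return c * g;
}

struct Offset {
  int dx, dy;
  double d;
};

// One conditional SGS realization of standard-normal scores on an
// nx-by-ny cell-centred grid. Nodes are indexed iy*nx + ix (x fastest,
// bottom row first). data_node (0-based) holds conditioning node indices
// whose values are fixed; remaining nodes are visited along a uniform
// random path and simulated by simple kriging (known mean 0) from up to
// nmax informed nodes within `radius` metres. Uses R's RNG, so results
// are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector sgs_core(int nx, int ny, double cell,
                       IntegerVector data_node, NumericVector data_value,
                       int model, double c0, double c, double range_a,
                       int nmax, double radius) {
  const int ncell = nx * ny;
  const double sill = c0 + c;
  NumericVector sim(ncell, NA_REAL);
  std::vector<char> informed(ncell, 0);

  for (int k = 0; k < data_node.size(); ++k) {
    int idx = data_node[k];
    sim[idx] = data_value[k];
    informed[idx] = 1;
  }

  // search template: in-radius offsets sorted by distance
  int rc = (int)std::ceil(radius / cell);
  std::vector<Offset> offs;
  offs.reserve((2 * rc + 1) * (2 * rc + 1));
  for (int dy = -rc; dy <= rc; ++dy) {
    for (int dx = -rc; dx <= rc; ++dx) {
      if (dx == 0 && dy == 0) continue;
      double d = cell * std::sqrt((double)(dx * dx + dy * dy));
      if (d <= radius) offs.push_back({dx, dy, d});
    }
  }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) { return a.d < b.d; });

  // random path over the not-yet-informed nodes (Fisher-Yates on R's RNG)
  std::vector<int> path;
  path.reserve(ncell);
  for (int i = 0; i < ncell; ++i)
    if (!informed[i]) path.push_back(i);
  for (int i = (int)path.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(path[i], path[j]);
  }

  std::vector<int> nix(nmax), niy(nmax);
  std::vector<double> nval(nmax);

  for (size_t p = 0; p < path.size(); ++p) {
    int node = path[p];
    int ix = node % nx, iy = node / nx;

    int k = 0;
    for (size_t o = 0; o < offs.size() && k < nmax; ++o) {
      int jx = ix + offs[o].dx, jy = iy + offs[o].dy;
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny) continue;
      int j = jy * nx + jx;
      if (informed[j]) {
        nix[k] = jx;
        niy[k] = jy;
        nval[k] = sim[j];
        ++k;
      }
    }

    double mean = 0.0, var = sill;
    if (k > 0) {
      arma::mat K(k, k);
      arma::vec rhs(k), zv(k);
      for (int i = 0; i < k; ++i) {
        zv(i) = nval[i];
        double ddx = cell * (nix[i] - ix), ddy = cell * (niy[i] - iy);
        rhs(i) = cov_at(std::sqrt(ddx * ddx + ddy * ddy), model, c0, c, range_a);
        K(i, i) = sill;
        for (int j = i + 1; j < k; ++j) {
          double ex = cell * (nix[i] - nix[j]), ey = cell * (niy[i] - niy[j]);
          double cv = cov_at(std::sqrt(ex * ex + ey * ey), model, c0, c, range_a);
          K(i, j) = cv;
          K(j, i) = cv;
        }
      }
      arma::vec w;
      bool ok = arma::solve(w, K, rhs,
                            arma::solve_opts::no_approx + arma::solve_opts::likely_sympd);
      if (ok) {
        mean = arma::dot(w, zv);
        var = sill - arma::dot(w, rhs);
        if (var < 0.0) var = 0.0;
        if (var > sill) var = sill;
      } // singular system: fall back to the marginal N(0, sill) draw
    }
    sim[node] = mean + norm_rand() * std::sqrt(var);
    informed[node] = 1;
  }

  return sim;
}
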