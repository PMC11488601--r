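#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Neighbour offsets for 6-, 18- or 26-connectivity on a 3-D lattice.
static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  return offs;
}

// Label connected components of a boolean 3-D set (column-major flat layout).
// Returns labels 1..n_components, 0 outside the set.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector in_set, IntegerVector dim,
                                   int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (in_set.size() != n) stop("in_set length does not match dim");
  IntegerVector labels(n, 0);
  auto offs = neighbour_offsets(connectivity);
  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!in_set[s] || labels[s] != 0) continue;
    ++current;
    labels[s] = current;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (const auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (in_set[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

// Threshold-free cluster enhancement of a nonnegative 3-D statistic map.
// For each threshold h = dh, 2dh, ... <= max(stat), every voxel v with
// stat[v] >= h accumulates extent(v,h)^E * h^H * dh, where extent is the size
// of the connected supra-threshold component containing v. Values <= 0 (or
// NA) never contribute.
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dim, double E,
                       double H, double dh, int connectivity) {
  if (dh <= 0) stop("dh must be positive");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (stat.size() != n) stop("stat length does not match dim");
  NumericVector out(n, 0.0);
  double mx = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = stat[i];
    if (R_finite(v) && v > mx) mx = v;
  }
  if (mx <= 0.0) return out;
  auto offs = neighbour_offsets(connectivity);
  std::vector<char> in_set(n);
  std::vector<int> labels(n);
  std::vector<R_xlen_t> stack;
  std::vector<double> comp_size;
  int nsteps = (int)std::floor(mx / dh + 1e-12);
  for (int step = 1; step <= nsteps; ++step) {
    double h = step * dh;
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = stat[i];
      in_set[i] = (R_finite(v) && v >= h) ? 1 : 0;
      labels[i] = 0;
    }
    comp_size.clear();
    comp_size.push_back(0.0);  // label 0 sentinel
    int current = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
      if (!in_set[s] || labels[s] != 0) continue;
      ++current;
      comp_size.push_back(0.0);
      labels[s] = current;
      stack.clear();
      stack.push_back(s);
      double size = 1.0;
      while (!stack.empty()) {
        R_xlen_t v = stack.back();
        stack.pop_back();
        int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
        for (const auto& o : offs) {
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
          if (in_set[w] && labels[w] == 0) {
            labels[w] = current;
            stack.push_back(w);
            size += 1.0;
          }
        }
      }
      comp_size[current] = size;
    }
    double hH = std::pow(h, H) * dh;
    for (R_xlen_t i = 0; i < n; ++i) {
      if (labels[i] > 0)
        out[i] += std::pow(comp_size[labels[i]], E) * hH;
    }
  }
  return out;
}
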