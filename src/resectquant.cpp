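#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D lower-envelope squared-distance transform (Felzenszwalb & Huttenlocher)
// on a sampled line with physical spacing `s`. f holds squared distances,
// INF where no source yet. Exact for anisotropic grids because each axis is
// processed in physical units.
static void dt1d(std::vector<double>& f, double s) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  // only finite parabolas enter the envelope (INF = no source on this line)
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (!(f[q] < INF)) continue;
    double xq = q * s;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    while (true) {
      double xv = v[k] * s;
      double sep = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (sep <= z[k] && k > 0) { --k; }
      else if (sep <= z[k]) {   // replaces the only parabola
        v[0] = q; z[1] = INF;
        break;
      } else {
        ++k; v[k] = q; z[k] = sep; z[k + 1] = INF;
        break;
      }
    }
  }
  if (k < 0) return;  // no finite source anywhere on the line
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact squared Euclidean distance (mm^2) from every voxel center to the
// nearest zero voxel center. mask: integer array (0 = background).
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(IntegerVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = mask[i] == 0 ? 0.0 : INF;

  std::vector<double> line;
  // x lines
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) line[x] = out[base + x];
      dt1d(line, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = line[x];
    }
  // y lines
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) line[y] = out[base + (R_xlen_t)y * nx];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = line[y];
    }
  // z lines
  line.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) line[z] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(line, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = line[z];
    }
  return out;
}

// Connected-component labelling of a binary 3D array.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector labels(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t seed = 0; seed < mask.size(); ++seed) {
    if (mask[seed] == 0 || labels[seed] != 0) continue;
    ++next_label;
    labels[seed] = next_label;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int z = (int)(idx / ((R_xlen_t)nx * ny));
      int rem = (int)(idx % ((R_xlen_t)nx * ny));
      int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (ad == 0) continue;
            if (connectivity == 6 && ad != 1) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            R_xlen_t nidx = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
            if (mask[nidx] != 0 && labels[nidx] == 0) {
              labels[nidx] = next_label;
              stack.push_back(nidx);
            }
          }
    }
  }
  return labels;
}
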