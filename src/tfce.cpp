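#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// neighbour offsets for 6/18/26-connectivity on a 3-D lattice
static int build_offsets(int conn, int off[26][3]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (conn == 6 && m > 1) continue;
        if (conn == 18 && m > 2) continue;
        off[k][0] = dx; off[k][1] = dy; off[k][2] = dz;
        ++k;
      }
  return k;
}

// Label connected components of `active` voxels; returns component sizes
// and writes labels (0-based, -1 = inactive) into `label`.
static void components(const std::vector<char>& active,
                       int nx, int ny, int nz, int conn,
                       std::vector<int>& label,
                       std::vector<int>& sizes) {
  int off[26][3];
  int noff = build_offsets(conn, off);
  const int n = nx * ny * nz;
  std::fill(label.begin(), label.end(), -1);
  sizes.clear();
  std::vector<int> stack;
  for (int v = 0; v < n; ++v) {
    if (!active[v] || label[v] >= 0) continue;
    int comp = (int)sizes.size();
    int size = 0;
    stack.clear();
    stack.push_back(v);
    label[v] = comp;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      ++size;
      int cz = cur / (nx * ny);
      int rem = cur - cz * nx * ny;
      int cy = rem / nx;
      int cx = rem - cy * nx;
      for (int o = 0; o < noff; ++o) {
        int x = cx + off[o][0], y = cy + off[o][1], z = cz + off[o][2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
          continue;
        int nb = x + nx * (y + ny * z);
        if (active[nb] && label[nb] < 0) {
          label[nb] = comp;
          stack.push_back(nb);
        }
      }
    }
    sizes.push_back(size);
  }
}

// Threshold-free cluster enhancement of a non-negative statistic map.
// enhanced(v) = sum over h = dh, 2dh, ... <= stat(v) of
//   size(component of v at threshold h)^E * h^H * dh
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dim,
                       LogicalVector mask, double H, double E, double dh,
                       int conn) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  NumericVector out(n);
  double mx = 0.0;
  for (int v = 0; v < n; ++v)
    if (mask[v] && stat[v] > mx) mx = stat[v];
  if (mx <= 0.0) return out;
  std::vector<char> active(n);
  std::vector<int> label(n), sizes;
  const int nlev = (int)std::floor(mx / dh + 1e-9);
  for (int l = 1; l <= nlev; ++l) {
    const double h = l * dh;
    for (int v = 0; v < n; ++v)
      active[v] = (mask[v] && stat[v] >= h - 1e-12) ? 1 : 0;
    components(active, nx, ny, nz, conn, label, sizes);
    const double hterm = std::pow(h, H) * dh;
    for (int v = 0; v < n; ++v)
      if (active[v])
        out[v] += std::pow((double)sizes[label[v]], E) * hterm;
  }
  return out;
}

// 26/18/6-connectivity component labelling exposed for cluster summaries.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector active, IntegerVector dim,
                                   int conn) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<char> act(n);
  for (int v = 0; v < n; ++v) act[v] = active[v] ? 1 : 0;
  std::vector<int> label(n), sizes;
  components(act, nx, ny, nz, conn, label, sizes);
  IntegerVector out(n);
  for (int v = 0; v < n; ++v) out[v] = label[v] + 1; // 0 = background
  return out;
}
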