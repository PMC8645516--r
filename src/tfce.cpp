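#include <Rcpp.h>
using namespace Rcpp;

// union-find with path compression
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, std::vector<int> &size,
                     int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a == b) return;
  if (size[a] < size[b]) std::swap(a, b);
  parent[b] = a;
  size[a] += size[b];
}

// neighbour offsets for 6/18/26 connectivity
static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// [[Rcpp::export(name = ".tfce_enhance")]]
NumericVector tfce_enhance(NumericVector stat, LogicalVector mask,
                           IntegerVector dims, double dh, double E, double H,
                           int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  NumericVector out(n);
  double hmax = 0.0;
  for (int i = 0; i < n; ++i)
    if (mask[i] && stat[i] > hmax) hmax = stat[i];
  if (hmax <= 0.0 || dh <= 0.0) return out;

  auto off = neighbour_offsets(connectivity);
  std::vector<int> parent(n), csize(n);

  for (double h = dh; h <= hmax + 1e-12; h += dh) {
    // label connected components of {stat >= h} within mask
    for (int i = 0; i < n; ++i) { parent[i] = i; csize[i] = 1; }
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = x + nx * (y + ny * z);
          if (!mask[i] || stat[i] < h) continue;
          for (auto &d : off) {
            int x2 = x + d[0], y2 = y + d[1], z2 = z + d[2];
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                z2 < 0 || z2 >= nz) continue;
            int j = x2 + nx * (y2 + ny * z2);
            if (mask[j] && stat[j] >= h) uf_union(parent, csize, i, j);
          }
        }
    double hterm = std::pow(h, H) * dh;
    for (int i = 0; i < n; ++i) {
      if (!mask[i] || stat[i] < h) continue;
      int root = uf_find(parent, i);
      out[i] += std::pow((double)csize[root], E) * hterm;
    }
  }
  return out;
}
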