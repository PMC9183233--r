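// Low-level 3D image operations for nucleus segmentation.
// All volumes are R arrays with dim = c(ny, nx, nz), column-major, so the
// linear index of voxel (y, x, z) (0-based) is y + ny * (x + nx * z).
#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int y, int x, int z, int ny, int nx) {
  return y + ny * (x + nx * z);
}

// 3x3x3 median filter with replicate padding at borders.
// [[Rcpp::export]]
NumericVector median_filter3_cpp(NumericVector vol, IntegerVector dim) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  std::vector<double> nb(27);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy) {
              int yy = std::min(std::max(y + dy, 0), ny - 1);
              int xx = std::min(std::max(x + dx, 0), nx - 1);
              int zz = std::min(std::max(z + dz, 0), nz - 1);
              nb[k++] = vol[idx3(yy, xx, zz, ny, nx)];
            }
        std::nth_element(nb.begin(), nb.begin() + 13, nb.end());
        out[idx3(y, x, z, ny, nx)] = nb[13];
      }
  return out;
}

// Connected-component labelling of a binary mask; connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity = 26) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int n = mask.size();
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int manh = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dy, dx, dz});
      }
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    labels[i] = ++next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int z = cur / (ny * nx), rem = cur % (ny * nx);
      int x = rem / ny, y = rem % ny;
      for (auto &o : offs) {
        int yy = y + o[0], xx = x + o[1], zz = z + o[2];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        int j = idx3(yy, xx, zz, ny, nx);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with
// physical sample spacing w: d(p) = min_q (w*(p-q))^2 + f(q).
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double w, int n) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  double w2 = w * w;
  int k = 0;
  v[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Anisotropic Euclidean distance transform of a mask: distance (in the units
// of `spacing`) from each true voxel to the nearest false voxel.
// [[Rcpp::export]]
NumericVector edt3_cpp(LogicalVector mask, IntegerVector dim,
                       NumericVector spacing) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int n = mask.size();
  std::vector<double> d(n);
  const double INF = 1e30;
  for (int i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;
  std::vector<double> f(std::max(ny, std::max(nx, nz)));
  std::vector<double> g(std::max(ny, std::max(nx, nz)));
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[idx3(y, x, z, ny, nx)];
      dt1d(f, g, spacing[0], ny);
      for (int y = 0; y < ny; ++y) d[idx3(y, x, z, ny, nx)] = g[y];
    }
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d[idx3(y, x, z, ny, nx)];
      dt1d(f, g, spacing[1], nx);
      for (int x = 0; x < nx; ++x) d[idx3(y, x, z, ny, nx)] = g[x];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[idx3(y, x, z, ny, nx)];
      dt1d(f, g, spacing[2], nz);
      for (int z = 0; z < nz; ++z) d[idx3(y, x, z, ny, nx)] = g[z];
    }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(d[i]);
  return out;
}

// Local maxima of `vol` within `mask`, using a box neighbourhood with the
// given half-widths (voxels) per axis. Plateaus yield one seed per connected
// plateau component (the first voxel in scan order).
// [[Rcpp::export]]
IntegerVector local_maxima_cpp(NumericVector vol, LogicalVector mask,
                               IntegerVector dim, IntegerVector radii) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int ry = radii[0], rx = radii[1], rz = radii[2];
  int n = vol.size();
  LogicalVector cand(n, false);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int i = idx3(y, x, z, ny, nx);
        if (!mask[i]) continue;
        double v = vol[i];
        bool ismax = true;
        for (int dz = -rz; dz <= rz && ismax; ++dz)
          for (int dx = -rx; dx <= rx && ismax; ++dx)
            for (int dy = -ry; dy <= ry && ismax; ++dy) {
              int yy = y + dy, xx = x + dx, zz = z + dz;
              if (yy < 0 || yy >= ny || xx < 0 || xx >= nx ||
                  zz < 0 || zz >= nz) continue;
              if (vol[idx3(yy, xx, zz, ny, nx)] > v) ismax = false;
            }
        cand[i] = ismax;
      }
  // collapse plateau components to single representative voxels
  IntegerVector comp = label_components_cpp(cand, dim, 26);
  int ncomp = 0;
  for (int i = 0; i < n; ++i) ncomp = std::max(ncomp, comp[i]);
  std::vector<int> rep(ncomp + 1, -1);
  IntegerVector seeds(n, 0);
  int nseed = 0;
  for (int i = 0; i < n; ++i) {
    if (comp[i] > 0 && rep[comp[i]] < 0) {
      rep[comp[i]] = i;
      seeds[i] = ++nseed;
    }
  }
  return seeds;
}

struct WsNode {
  double prio;
  long order;
  int index;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;   // lower priority first
    return a.order > b.order;                        // FIFO tie-break
  }
};

// Seeded watershed by priority flooding within a mask (6-connected).
// Voxels are assigned in order of increasing `prio` (pass -distance to flood
// deepest basins first). Labels never merge.
// [[Rcpp::export]]
IntegerVector watershed_seeded_cpp(NumericVector prio, IntegerVector seeds,
                                   LogicalVector mask, IntegerVector dim) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int n = prio.size();
  IntegerVector labels(n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int i = 0; i < n; ++i)
    if (seeds[i] > 0 && mask[i]) {
      labels[i] = seeds[i];
      pq.push({prio[i], order++, i, seeds[i]});
    }
  const int dys[6] = {-1, 1, 0, 0, 0, 0};
  const int dxs[6] = {0, 0, -1, 1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int cur = nd.index;
    int z = cur / (ny * nx), rem = cur % (ny * nx);
    int x = rem / ny, y = rem % ny;
    for (int k = 0; k < 6; ++k) {
      int yy = y + dys[k], xx = x + dxs[k], zz = z + dzs[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
        continue;
      int j = idx3(yy, xx, zz, ny, nx);
      if (!mask[j] || labels[j] != 0) continue;
      labels[j] = nd.label;
      pq.push({prio[j], order++, j, nd.label});
    }
  }
  return labels;
}

// Thicken every labelled object by one voxel without overlap: each background
// voxel adjacent (26-connectivity) to at least one labelled voxel takes the
// label of the physically nearest labelled neighbour; exact ties go to the
// lower label. Originally labelled voxels are never changed.
// [[Rcpp::export]]
IntegerVector dilate_labels_cpp(IntegerVector labels, IntegerVector dim,
                                NumericVector spacing) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int n = labels.size();
  IntegerVector out = clone(labels);
  double sy = spacing[0], sx = spacing[1], sz = spacing[2];
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int i = idx3(y, x, z, ny, nx);
        if (labels[i] != 0) continue;
        double best = 1e30;
        int bestlab = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy) {
              if (dy == 0 && dx == 0 && dz == 0) continue;
              int yy = y + dy, xx = x + dx, zz = z + dz;
              if (yy < 0 || yy >= ny || xx < 0 || xx >= nx ||
                  zz < 0 || zz >= nz) continue;
              int lab = labels[idx3(yy, xx, zz, ny, nx)];
              if (lab == 0) continue;
              double d = dy * sy * dy * sy + dx * sx * dx * sx +
                         dz * sz * dz * sz;
              if (d < best - 1e-12 ||
                  (std::abs(d - best) <= 1e-12 && lab < bestlab)) {
                best = d;
                bestlab = lab;
              }
            }
        if (bestlab > 0) out[i] = bestlab;
      }
  return out;
}
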