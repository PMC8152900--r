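// 3D connected components and threshold-free cluster enhancement.
//
// Both use a union-find over the voxel lattice. TFCE processes thresholds
// from high to low so each voxel is inserted exactly once; per threshold
// step the component extent is read off the union-find, giving
// O(n_steps * n_active) with near-O(1) finds (path halving).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Offsets {
  std::vector<int> dx, dy, dz;
};

// neighbor offsets for 6/18/26 connectivity (half not needed: insertion
// order is value-driven, so scan the full neighborhood)
Offsets make_offsets(int connectivity) {
  Offsets o;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        o.dx.push_back(dx); o.dy.push_back(dy); o.dz.push_back(dz);
      }
  return o;
}

inline int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];  // path halving
    i = parent[i];
  }
  return i;
}

inline void uf_union(std::vector<int>& parent, std::vector<int>& csize,
                     int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a == b) return;
  if (csize[a] < csize[b]) std::swap(a, b);
  parent[b] = a;
  csize[a] += csize[b];
}

// Core TFCE on a raw vector laid out in (x fastest) order. dh must be > 0.
void tfce_core(const double* x, int nx, int ny, int nz,
               double E, double H, int nsteps, double dh,
               const Offsets& off, double* out,
               std::vector<int>& parent, std::vector<int>& csize,
               std::vector<int>& order, std::vector<char>& active,
               std::vector<double>& powE) {
  const int n = nx * ny * nz;
  std::fill(out, out + n, 0.0);
  order.clear();
  for (int i = 0; i < n; ++i)
    if (x[i] > 0.0 && R_finite(x[i])) order.push_back(i);
  if (order.empty()) return;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return x[a] > x[b]; });
  std::fill(active.begin(), active.end(), 0);
  const int nb = (int)off.dx.size();
  size_t next = 0;  // next voxel (descending) to activate
  std::vector<int>& act_list = order;  // activated prefix of `order`

  // keep the caller's dh but let the ladder reach this map's own maximum,
  // so maps exceeding the reference map are not truncated
  const double mx = x[order[0]];
  int ksteps = nsteps;
  if (mx > nsteps * dh)
    ksteps = (int)std::ceil(mx / dh - 1e-12);

  for (int k = ksteps; k >= 1; --k) {
    const double h = dh * k;
    // activate voxels with x >= h
    while (next < order.size() && x[order[next]] >= h) {
      const int i = order[next];
      parent[i] = i; csize[i] = 1; active[i] = 1;
      const int ix = i % nx, iy = (i / nx) % ny, iz = i / (nx * ny);
      for (int m = 0; m < nb; ++m) {
        const int jx = ix + off.dx[m], jy = iy + off.dy[m],
                  jz = iz + off.dz[m];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
          continue;
        const int j = i + off.dx[m] + off.dy[m] * nx + off.dz[m] * nx * ny;
        if (active[j]) uf_union(parent, csize, i, j);
      }
      ++next;
    }
    if (next == 0) continue;
    const double hh = std::pow(h, H) * dh;
    for (size_t t = 0; t < next; ++t) {
      const int i = act_list[t];
      const int sz = csize[uf_find(parent, i)];
      if (powE[sz] < 0.0) powE[sz] = std::pow((double)sz, E);
      out[i] += powE[sz] * hh;
    }
  }
  for (size_t t = 0; t < order.size(); ++t) active[order[t]] = 0;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector x, IntegerVector dim,
                       double E, double H, int nsteps, double dh,
                       int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if (x.size() != n) stop("value vector does not match grid dimensions");
  NumericVector out(n);
  double mx = 0.0;
  for (int i = 0; i < n; ++i)
    if (R_finite(x[i]) && x[i] > mx) mx = x[i];
  if (mx <= 0.0) return out;
  if (dh <= 0.0) dh = mx / nsteps;
  Offsets off = make_offsets(connectivity);
  std::vector<int> parent(n), csize(n), order;
  std::vector<char> active(n, 0);
  std::vector<double> powE(n + 1, -1.0);
  order.reserve(n);
  tfce_core(REAL(x), nx, ny, nz, E, H, nsteps, dh, off, REAL(out),
            parent, csize, order, active, powE);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".tfce_max_batch_cpp")]]
NumericVector tfce_max_batch_cpp(NumericMatrix stats, IntegerVector vox_index,
                                 IntegerVector dim, double E, double H,
                                 int nsteps, double dh, int connectivity) {
  // stats: draws x masked-voxels; vox_index: 0-based linear index into grid
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  const int B = stats.nrow(), V = stats.ncol();
  if (vox_index.size() != V) stop("voxel index does not match stat columns");
  // dh <= 0: each draw uses its own dh = max/nsteps (draw-symmetric)
  const bool own_dh = dh <= 0.0;
  Offsets off = make_offsets(connectivity);
  std::vector<double> grid(n, 0.0), enh(n, 0.0);
  std::vector<int> parent(n), csize(n), order;
  std::vector<char> active(n, 0);
  std::vector<double> powE(n + 1, -1.0);
  order.reserve(V);
  NumericVector maxima(B);
  for (int b = 0; b < B; ++b) {
    double row_mx = 0.0;
    for (int v = 0; v < V; ++v) {
      const double s = stats(b, v);
      grid[vox_index[v]] = s;
      if (R_finite(s) && s > row_mx) row_mx = s;
    }
    if (own_dh) {
      if (row_mx <= 0.0) {
        maxima[b] = 0.0;
        for (int v = 0; v < V; ++v) grid[vox_index[v]] = 0.0;
        continue;
      }
      dh = row_mx / nsteps;
    }
    tfce_core(grid.data(), nx, ny, nz, E, H, nsteps, dh, off, enh.data(),
              parent, csize, order, active, powE);
    double mx = 0.0;
    for (int v = 0; v < V; ++v) {
      const double e = enh[vox_index[v]];
      if (e > mx) mx = e;
    }
    maxima[b] = mx;
    for (int v = 0; v < V; ++v) grid[vox_index[v]] = 0.0;
  }
  return maxima;
}

//' @noRd
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector fg, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if (fg.size() != n) stop("foreground vector does not match grid dimensions");
  Offsets off = make_offsets(connectivity);
  std::vector<int> parent(n), csize(n);
  std::vector<char> active(n, 0);
  const int nb = (int)off.dx.size();
  for (int i = 0; i < n; ++i) {
    if (fg[i] != TRUE) continue;
    parent[i] = i; csize[i] = 1; active[i] = 1;
    const int ix = i % nx, iy = (i / nx) % ny, iz = i / (nx * ny);
    for (int m = 0; m < nb; ++m) {
      const int jx = ix + off.dx[m], jy = iy + off.dy[m], jz = iz + off.dz[m];
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
        continue;
      const int j = i + off.dx[m] + off.dy[m] * nx + off.dz[m] * nx * ny;
      if (active[j]) uf_union(parent, csize, i, j);
    }
  }
  IntegerVector labels(n, 0);
  std::vector<int> remap(n, 0);
  int next_label = 0;
  for (int i = 0; i < n; ++i) {
    if (!active[i]) continue;
    int r = uf_find(parent, i);
    if (remap[r] == 0) remap[r] = ++next_label;
    labels[i] = remap[r];
  }
  return labels;
}
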