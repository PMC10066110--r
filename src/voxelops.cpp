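#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Neighborhood offsets for 6/18/26 connectivity.
static void neighbor_offsets(int connectivity,
                             std::vector<int>& dx, std::vector<int>& dy,
                             std::vector<int>& dz) {
  for (int z = -1; z <= 1; ++z)
    for (int y = -1; y <= 1; ++y)
      for (int x = -1; x <= 1; ++x) {
        int m = std::abs(x) + std::abs(y) + std::abs(z);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx.push_back(x); dy.push_back(y); dz.push_back(z);
      }
}

// Label connected foreground components; labels returned are ordered 1..C by
// decreasing voxel count (ties broken by discovery order).
// [[Rcpp::export]]
IntegerVector cc_label_cpp(IntegerVector mask, IntegerVector dims,
                           int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> dxs, dys, dzs;
  neighbor_offsets(connectivity, dxs, dys, dzs);
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  std::vector<R_xlen_t> sizes; // per raw label
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    R_xlen_t count = 0;
    stack.push_back(i); lab[i] = next;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back(); ++count;
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < dxs.size(); ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] != 0 && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
      }
    }
    sizes.push_back(count);
  }
  // rank labels by decreasing size
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return sizes[a] > sizes[b];
  });
  std::vector<int> remap(next + 1, 0);
  for (int r = 0; r < next; ++r) remap[order[r] + 1] = r + 1;
  for (R_xlen_t i = 0; i < n; ++i) if (lab[i] != 0) lab[i] = remap[lab[i]];
  lab.attr("n_components") = next;
  return lab;
}

// Two-pass 26-neighbor chamfer distance transform: distance (mm, approximate
// Euclidean) from each foreground voxel to the nearest background voxel.
// [[Rcpp::export]]
NumericVector chamfer_dt_cpp(IntegerVector mask, IntegerVector dims,
                             NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> dxs, dys, dzs;
  neighbor_offsets(26, dxs, dys, dzs);
  std::vector<double> w(dxs.size());
  for (size_t k = 0; k < dxs.size(); ++k)
    w[k] = std::sqrt(std::pow(dxs[k] * spacing[0], 2) +
                     std::pow(dys[k] * spacing[1], 2) +
                     std::pow(dzs[k] * spacing[2], 2));
  const double INF = 1e30;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;
  // forward, then backward raster scan; each relaxes over all 26 neighbors
  // (a slight superset of the strictly causal set; still converges in 2 passes
  // for tubular masks and never underestimates less than the causal variant).
  for (int pass = 0; pass < 2; ++pass) {
    bool fwd = (pass == 0);
    for (R_xlen_t s = 0; s < n; ++s) {
      R_xlen_t i = fwd ? s : (n - 1 - s);
      if (mask[i] == 0) continue;
      int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((R_xlen_t)nx * ny));
      double best = d[i];
      for (size_t k = 0; k < dxs.size(); ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
          // outside the lattice counts as background
          if (w[k] < best) best = w[k];
          continue;
        }
        R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        double cand = d[j] + w[k];
        if (cand < best) best = cand;
      }
      d[i] = best;
    }
  }
  return d;
}

// Dijkstra shortest path between two foreground voxels with a medialness
// cost: edge cost = step_mm / (mean boundary distance + eps)^2, so the
// geodesic tracks the centerline ridge of the distance transform.
// Returns 1-based linear indices from start to end, or empty if unreachable.
// [[Rcpp::export]]
IntegerVector medial_path_cpp(IntegerVector mask, IntegerVector dims,
                              NumericVector spacing, NumericVector dt,
                              int start1, int end1) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> dxs, dys, dzs;
  neighbor_offsets(26, dxs, dys, dzs);
  std::vector<double> step(dxs.size());
  for (size_t k = 0; k < dxs.size(); ++k)
    step[k] = std::sqrt(std::pow(dxs[k] * spacing[0], 2) +
                        std::pow(dys[k] * spacing[1], 2) +
                        std::pow(dzs[k] * spacing[2], 2));
  const double eps = 0.1 * std::min(spacing[0], std::min(spacing[1], spacing[2]));
  std::vector<double> dist(n, 1e30);
  std::vector<R_xlen_t> prev(n, -1);
  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  R_xlen_t s0 = start1 - 1, e0 = end1 - 1;
  dist[s0] = 0.0; pq.push(QE(0.0, s0));
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    R_xlen_t u = top.second;
    if (top.first > dist[u]) continue;
    if (u == e0) break;
    int x = (int)(u % nx), y = (int)((u / nx) % ny), z = (int)(u / ((R_xlen_t)nx * ny));
    for (size_t k = 0; k < dxs.size(); ++k) {
      int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      R_xlen_t v = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (mask[v] == 0) continue;
      double m = 0.5 * (dt[u] + dt[v]) + eps;
      double nd = dist[u] + step[k] / (m * m);
      if (nd < dist[v]) { dist[v] = nd; prev[v] = u; pq.push(QE(nd, v)); }
    }
  }
  if (dist[e0] >= 1e30) return IntegerVector(0);
  std::vector<int> path;
  for (R_xlen_t v = e0; v != -1; v = prev[v]) path.push_back((int)(v + 1));
  std::reverse(path.begin(), path.end());
  return wrap(path);
}

// Separable Gaussian blur; sigma given in voxels per axis, kernel truncated
// at 3 sigma and renormalized at the volume borders.
// [[Rcpp::export]]
NumericVector gauss_blur_cpp(NumericVector vol, IntegerVector dims,
                             NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector cur = clone(vol);
  const int dmsz[3] = { nx, ny, nz };
  const R_xlen_t stride[3] = { 1, nx, (R_xlen_t)nx * ny };
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 1e-9) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    for (int k = -r; k <= r; ++k) ker[k + r] = std::exp(-0.5 * k * k / (s * s));
    NumericVector nxt(n);
    for (R_xlen_t i = 0; i < n; ++i) {
      int pos[3];
      pos[0] = (int)(i % nx); pos[1] = (int)((i / nx) % ny);
      pos[2] = (int)(i / ((R_xlen_t)nx * ny));
      double acc = 0.0, wsum = 0.0;
      int p = pos[ax];
      int lo = std::max(-r, -p), hi = std::min(r, dmsz[ax] - 1 - p);
      for (int k = lo; k <= hi; ++k) {
        double wk = ker[k + r];
        acc += wk * cur[i + (R_xlen_t)k * stride[ax]];
        wsum += wk;
      }
      nxt[i] = acc / wsum;
    }
    cur = nxt;
  }
  return cur;
}
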