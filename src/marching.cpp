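#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra on the Freudenthal (Kuhn)
// 6-tetrahedra subdivision of each lattice cell. The subdivision tiles the
// lattice consistently, so shared cell faces carry identical triangulations
// and the resulting surface is watertight whenever the iso-set does not
// touch the lattice boundary (callers pad). Crossing vertices are welded on
// their (grid-edge) identity; triangles are oriented with normals pointing
// from values above the iso level ("inside") to below ("outside") flipped to
// outward, i.e. away from the enclosed region.

struct EdgeKeyHash {
  size_t operator()(const uint64_t& k) const { return std::hash<uint64_t>()(k); }
};

// Freudenthal tetrahedra: corner ids use bit0 = x, bit1 = y, bit2 = z.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

// [[Rcpp::export]]
List march_tets_cpp(NumericVector field, IntegerVector dims, double iso,
                    NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::unordered_map<uint64_t, int, EdgeKeyHash> edge_vertex;
  std::vector<double> verts; // x,y,z triples
  std::vector<int> faces;    // 1-based triples

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const R_xlen_t corner_off[8] = {
    0, sx, sy, sx + sy, sz, sx + sz, sy + sz, sx + sy + sz
  };

  auto corner_pos = [&](R_xlen_t lin, double* p) {
    int x = (int)(lin % nx), y = (int)((lin / nx) % ny), z = (int)(lin / sz);
    p[0] = origin[0] + x * spacing[0];
    p[1] = origin[1] + y * spacing[1];
    p[2] = origin[2] + z * spacing[2];
  };

  auto edge_vert = [&](R_xlen_t a, R_xlen_t b) -> int {
    if (a > b) std::swap(a, b);
    uint64_t key = (uint64_t)a * (uint64_t)(sz * (R_xlen_t)nz + 1) + (uint64_t)b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double va = field[a], vb = field[b];
    double t = (iso - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    double pa[3], pb[3];
    corner_pos(a, pa); corner_pos(b, pb);
    verts.push_back(pa[0] + t * (pb[0] - pa[0]));
    verts.push_back(pa[1] + t * (pb[1] - pa[1]));
    verts.push_back(pa[2] + t * (pb[2] - pa[2]));
    int id = (int)(verts.size() / 3); // 1-based
    edge_vertex[key] = id;
    return id;
  };

  auto emit = [&](int v1, int v2, int v3,
                  const double* ci, const double* co) {
    // orient so the normal points from inside (ci) toward outside (co)
    const double* p1 = &verts[(v1 - 1) * 3];
    const double* p2 = &verts[(v2 - 1) * 3];
    const double* p3 = &verts[(v3 - 1) * 3];
    double u[3] = { p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2] };
    double w[3] = { p3[0] - p1[0], p3[1] - p1[1], p3[2] - p1[2] };
    double nrm[3] = { u[1] * w[2] - u[2] * w[1],
                      u[2] * w[0] - u[0] * w[2],
                      u[0] * w[1] - u[1] * w[0] };
    double dir[3] = { co[0] - ci[0], co[1] - ci[1], co[2] - ci[2] };
    double dot = nrm[0] * dir[0] + nrm[1] * dir[1] + nrm[2] * dir[2];
    if (dot < 0) std::swap(v2, v3);
    faces.push_back(v1); faces.push_back(v2); faces.push_back(v3);
  };

  double cpos[8][3];
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        R_xlen_t base = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        double v[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          v[c] = field[base + corner_off[c]];
          (v[c] > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int c = 0; c < 8; ++c) corner_pos(base + corner_off[c], cpos[c]);
        for (int t = 0; t < 6; ++t) {
          int ids[4] = { TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3] };
          int in[4], out[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (v[ids[c]] > iso) in[ni++] = ids[c]; else out[no++] = ids[c];
          }
          if (ni == 0 || ni == 4) continue;
          double ci[3] = {0, 0, 0}, co[3] = {0, 0, 0};
          for (int c = 0; c < ni; ++c)
            for (int d = 0; d < 3; ++d) ci[d] += cpos[in[c]][d] / ni;
          for (int c = 0; c < no; ++c)
            for (int d = 0; d < 3; ++d) co[d] += cpos[out[c]][d] / no;
          if (ni == 1) {
            int a = edge_vert(base + corner_off[in[0]], base + corner_off[out[0]]);
            int b = edge_vert(base + corner_off[in[0]], base + corner_off[out[1]]);
            int c = edge_vert(base + corner_off[in[0]], base + corner_off[out[2]]);
            emit(a, b, c, ci, co);
          } else if (ni == 3) {
            int a = edge_vert(base + corner_off[out[0]], base + corner_off[in[0]]);
            int b = edge_vert(base + corner_off[out[0]], base + corner_off[in[1]]);
            int c = edge_vert(base + corner_off[out[0]], base + corner_off[in[2]]);
            emit(a, b, c, ci, co);
          } else { // 2 in, 2 out: quad split into two triangles
            int a = edge_vert(base + corner_off[in[0]], base + corner_off[out[0]]);
            int b = edge_vert(base + corner_off[in[0]], base + corner_off[out[1]]);
            int c = edge_vert(base + corner_off[in[1]], base + corner_off[out[1]]);
            int d = edge_vert(base + corner_off[in[1]], base + corner_off[out[0]]);
            emit(a, b, c, ci, co);
            emit(a, c, d, ci, co);
          }
        }
      }

  int nv = (int)(verts.size() / 3), nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int d = 0; d < 3; ++d) V(i, d) = verts[i * 3 + d];
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i)
    for (int d = 0; d < 3; ++d) F(i, d) = faces[i * 3 + d];
  return List::create(_["vertices"] = V, _["faces"] = F);
}
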