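// Isosurface extraction by marching tetrahedra on a regular grid.
// Each cell is split into the 6 Kuhn tetrahedra around the main diagonal,
// which is face-consistent across neighbouring cells, so the extracted
// surface is watertight whenever the isosurface does not touch the grid
// boundary. "Inside" is field < iso; triangles are oriented outward
// (normals pointing away from the inside region).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// corner id bits: 1 = +x, 2 = +y, 4 = +z
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector field, IntegerVector dims,
                             NumericVector origin, double spacing,
                             double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  auto node = [nx, ny](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };
  int64_t nnode = (int64_t)nx * ny * nz;

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> VX, VY, VZ;
  std::vector<int> FA, FB, FC;

  auto corner_pos = [&](int i, int j, int k, double* p) {
    p[0] = origin[0] + spacing * i;
    p[1] = origin[1] + spacing * j;
    p[2] = origin[2] + spacing * k;
  };

  // vertex on the iso crossing of grid-node segment (ga, gb)
  auto edge_point = [&](int64_t ga, double fa, const double* pa,
                        int64_t gb, double fb, const double* pb) -> int {
    uint64_t key;
    if (ga < gb) key = (uint64_t)ga * (uint64_t)nnode + (uint64_t)gb;
    else         key = (uint64_t)gb * (uint64_t)nnode + (uint64_t)ga;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - fa) / (fb - fa);
    if (t < 1e-8) t = 1e-8;
    if (t > 1 - 1e-8) t = 1 - 1e-8;
    VX.push_back(pa[0] + t * (pb[0] - pa[0]));
    VY.push_back(pa[1] + t * (pb[1] - pa[1]));
    VZ.push_back(pa[2] + t * (pb[2] - pa[2]));
    int id = (int)VX.size() - 1;
    edge_vertex[key] = id;
    return id;
  };

  auto emit = [&](int v1, int v2, int v3,
                  const double* in_cen, const double* out_cen) {
    // orient so the normal points from inside toward outside
    double e1[3] = { VX[v2] - VX[v1], VY[v2] - VY[v1], VZ[v2] - VZ[v1] };
    double e2[3] = { VX[v3] - VX[v1], VY[v3] - VY[v1], VZ[v3] - VZ[v1] };
    double n[3] = { e1[1] * e2[2] - e1[2] * e2[1],
                    e1[2] * e2[0] - e1[0] * e2[2],
                    e1[0] * e2[1] - e1[1] * e2[0] };
    double ref[3] = { out_cen[0] - in_cen[0], out_cen[1] - in_cen[1],
                      out_cen[2] - in_cen[2] };
    double d = n[0] * ref[0] + n[1] * ref[1] + n[2] * ref[2];
    if (d < 0) std::swap(v2, v3);
    FA.push_back(v1); FB.push_back(v2); FC.push_back(v3);
  };

  double cf[8], cp[8][3];
  int64_t cg[8];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          cg[c] = node(ci, cj, ck);
          cf[c] = field[cg[c]];
          corner_pos(ci, cj, ck, cp[c]);
        }
        // quick reject: all corners on one side
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) (cf[c] < iso ? any_in : any_out) = true;
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vin[4], vout[4], n_in = 0, n_out = 0;
          for (int c = 0; c < 4; ++c) {
            int cc = TETS[t][c];
            if (cf[cc] < iso) vin[n_in++] = cc; else vout[n_out++] = cc;
          }
          if (n_in == 0 || n_out == 0) continue;
          double in_cen[3] = {0, 0, 0}, out_cen[3] = {0, 0, 0};
          for (int c = 0; c < n_in; ++c)
            for (int d = 0; d < 3; ++d) in_cen[d] += cp[vin[c]][d] / n_in;
          for (int c = 0; c < n_out; ++c)
            for (int d = 0; d < 3; ++d) out_cen[d] += cp[vout[c]][d] / n_out;
          if (n_in == 1) {
            int a = vin[0];
            int p1 = edge_point(cg[a], cf[a], cp[a], cg[vout[0]], cf[vout[0]], cp[vout[0]]);
            int p2 = edge_point(cg[a], cf[a], cp[a], cg[vout[1]], cf[vout[1]], cp[vout[1]]);
            int p3 = edge_point(cg[a], cf[a], cp[a], cg[vout[2]], cf[vout[2]], cp[vout[2]]);
            emit(p1, p2, p3, in_cen, out_cen);
          } else if (n_in == 3) {
            int a = vout[0];
            int p1 = edge_point(cg[a], cf[a], cp[a], cg[vin[0]], cf[vin[0]], cp[vin[0]]);
            int p2 = edge_point(cg[a], cf[a], cp[a], cg[vin[1]], cf[vin[1]], cp[vin[1]]);
            int p3 = edge_point(cg[a], cf[a], cp[a], cg[vin[2]], cf[vin[2]], cp[vin[2]]);
            emit(p1, p2, p3, in_cen, out_cen);
          } else { // 2 in, 2 out: quad split into two triangles
            int a = vin[0], b = vin[1], c = vout[0], d = vout[1];
            int pac = edge_point(cg[a], cf[a], cp[a], cg[c], cf[c], cp[c]);
            int pad = edge_point(cg[a], cf[a], cp[a], cg[d], cf[d], cp[d]);
            int pbc = edge_point(cg[b], cf[b], cp[b], cg[c], cf[c], cp[c]);
            int pbd = edge_point(cg[b], cf[b], cp[b], cg[d], cf[d], cp[d]);
            emit(pac, pad, pbd, in_cen, out_cen);
            emit(pac, pbd, pbc, in_cen, out_cen);
          }
        }
      }

  int nv = (int)VX.size(), nf = (int)FA.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = VX[v]; V(v, 1) = VY[v]; V(v, 2) = VZ[v]; }
  for (int f = 0; f < nf; ++f) { F(f, 0) = FA[f] + 1; F(f, 1) = FB[f] + 1; F(f, 2) = FC[f] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
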