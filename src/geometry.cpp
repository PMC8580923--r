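#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

// ---- exact closest point on a triangle (Ericson, region-based) ------------

static inline void closest_pt_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

static inline double dist2(const double *p, const double *q) {
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// ---- uniform-grid spatial index over triangles ----------------------------
//
// Triangles are registered in every grid cell their AABB overlaps; a query
// expands cell shells outward from the query point, pruning with the current
// best distance, so the reported minimum is exact (not approximate).

struct MeshIndex {
  std::vector<double> V;       // 3 * nv, column per vertex
  std::vector<int>    F;       // 3 * nf
  int nv = 0, nf = 0;
  double lo[3], hi[3], h[3];
  int dim[3];
  std::vector<int> cell_start; // CSR layout: triangles per cell
  std::vector<int> cell_tris;
  mutable std::vector<int> stamp;
  mutable int qid = 0;

  inline int cell_of(int ix, int iy, int iz) const {
    return ix + dim[0] * (iy + dim[1] * iz);
  }
  inline void clampc(const double *p, int *c) const {
    for (int k = 0; k < 3; ++k) {
      int i = (int)std::floor((p[k] - lo[k]) / h[k]);
      if (i < 0) i = 0;
      if (i >= dim[k]) i = dim[k] - 1;
      c[k] = i;
    }
  }
  inline double cell_box_dist2(const double *p, int ix, int iy, int iz) const {
    double d2 = 0.0;
    double cl[3] = { lo[0] + ix * h[0], lo[1] + iy * h[1], lo[2] + iz * h[2] };
    double ch[3] = { cl[0] + h[0], cl[1] + h[1], cl[2] + h[2] };
    for (int k = 0; k < 3; ++k) {
      double v = p[k];
      if (v < cl[k]) { double d = cl[k] - v; d2 += d * d; }
      else if (v > ch[k]) { double d = v - ch[k]; d2 += d * d; }
    }
    return d2;
  }
};

static void build_index(MeshIndex &mi, const NumericMatrix &V, const IntegerMatrix &F) {
  mi.nv = V.nrow();
  mi.nf = F.nrow();
  mi.V.resize(3 * mi.nv);
  for (int i = 0; i < mi.nv; ++i)
    for (int k = 0; k < 3; ++k) mi.V[3*i+k] = V(i, k);
  mi.F.resize(3 * mi.nf);
  for (int i = 0; i < mi.nf; ++i)
    for (int k = 0; k < 3; ++k) mi.F[3*i+k] = F(i, k) - 1;  // to 0-based

  for (int k = 0; k < 3; ++k) { mi.lo[k] = R_PosInf; mi.hi[k] = R_NegInf; }
  for (int i = 0; i < mi.nv; ++i)
    for (int k = 0; k < 3; ++k) {
      mi.lo[k] = std::min(mi.lo[k], mi.V[3*i+k]);
      mi.hi[k] = std::max(mi.hi[k], mi.V[3*i+k]);
    }

  // target: a handful of triangles per occupied cell, grid capped at 160^3
  double ext[3];
  double maxext = 0.0;
  for (int k = 0; k < 3; ++k) {
    ext[k] = std::max(mi.hi[k] - mi.lo[k], 1e-9);
    maxext = std::max(maxext, ext[k]);
  }
  double target = maxext / std::min(160.0, std::max(4.0, std::cbrt((double)mi.nf) * 2.0));
  for (int k = 0; k < 3; ++k) {
    mi.dim[k] = std::max(1, (int)std::ceil(ext[k] / target));
    mi.h[k] = ext[k] / mi.dim[k] * (1.0 + 1e-12);
  }

  long ncell = (long)mi.dim[0] * mi.dim[1] * mi.dim[2];
  std::vector<int> count(ncell, 0);
  std::vector<int> tlo(3 * mi.nf), thi(3 * mi.nf);
  for (int t = 0; t < mi.nf; ++t) {
    double bl[3] = {R_PosInf, R_PosInf, R_PosInf}, bh[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int j = 0; j < 3; ++j) {
      const double *v = &mi.V[3 * mi.F[3*t+j]];
      for (int k = 0; k < 3; ++k) {
        bl[k] = std::min(bl[k], v[k]);
        bh[k] = std::max(bh[k], v[k]);
      }
    }
    int cl[3], ch[3];
    mi.clampc(bl, cl);
    mi.clampc(bh, ch);
    for (int k = 0; k < 3; ++k) { tlo[3*t+k] = cl[k]; thi[3*t+k] = ch[k]; }
    for (int iz = cl[2]; iz <= ch[2]; ++iz)
      for (int iy = cl[1]; iy <= ch[1]; ++iy)
        for (int ix = cl[0]; ix <= ch[0]; ++ix)
          count[mi.cell_of(ix, iy, iz)]++;
  }
  mi.cell_start.assign(ncell + 1, 0);
  for (long c = 0; c < ncell; ++c) mi.cell_start[c + 1] = mi.cell_start[c] + count[c];
  mi.cell_tris.resize(mi.cell_start[ncell]);
  std::vector<int> fill(ncell, 0);
  for (int t = 0; t < mi.nf; ++t) {
    for (int iz = tlo[3*t+2]; iz <= thi[3*t+2]; ++iz)
      for (int iy = tlo[3*t+1]; iy <= thi[3*t+1]; ++iy)
        for (int ix = tlo[3*t+0]; ix <= thi[3*t+0]; ++ix) {
          int c = mi.cell_of(ix, iy, iz);
          mi.cell_tris[mi.cell_start[c] + fill[c]++] = t;
        }
  }
  mi.stamp.assign(mi.nf, -1);
  mi.qid = 0;
}

// query one point; returns best face (0-based) via *face and closest point
static double query_index(const MeshIndex &mi, const double *p, int *face, double *cp) {
  int c0[3];
  mi.clampc(p, c0);
  double best2 = R_PosInf;
  int bestf = -1;
  double bestp[3] = {0, 0, 0};
  mi.qid++;
  double minh = std::min(mi.h[0], std::min(mi.h[1], mi.h[2]));
  // distance from p to the grid box (0 if inside)
  double d0_2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    if (p[k] < mi.lo[k]) { double d = mi.lo[k] - p[k]; d0_2 += d * d; }
    else if (p[k] > mi.hi[k]) { double d = p[k] - mi.hi[k]; d0_2 += d * d; }
  }
  int rmax = mi.dim[0] + mi.dim[1] + mi.dim[2];
  for (int r = 0; r <= rmax; ++r) {
    if (bestf >= 0) {
      double lb = std::max(std::sqrt(d0_2), (r - 1) * minh);
      if (lb * lb > best2) break;
    }
    int xl = c0[0] - r, xh = c0[0] + r;
    int yl = c0[1] - r, yh = c0[1] + r;
    int zl = c0[2] - r, zh = c0[2] + r;
    for (int iz = std::max(0, zl); iz <= std::min(mi.dim[2] - 1, zh); ++iz)
      for (int iy = std::max(0, yl); iy <= std::min(mi.dim[1] - 1, yh); ++iy)
        for (int ix = std::max(0, xl); ix <= std::min(mi.dim[0] - 1, xh); ++ix) {
          // shell only: at least one coordinate at Chebyshev distance r
          if (std::max(std::abs(ix - c0[0]),
              std::max(std::abs(iy - c0[1]), std::abs(iz - c0[2]))) != r)
            continue;
          if (mi.cell_box_dist2(p, ix, iy, iz) > best2) continue;
          int c = mi.cell_of(ix, iy, iz);
          for (int s = mi.cell_start[c]; s < mi.cell_start[c + 1]; ++s) {
            int t = mi.cell_tris[s];
            if (mi.stamp[t] == mi.qid) continue;
            mi.stamp[t] = mi.qid;
            const double *a = &mi.V[3 * mi.F[3*t+0]];
            const double *b = &mi.V[3 * mi.F[3*t+1]];
            const double *cc = &mi.V[3 * mi.F[3*t+2]];
            double q[3];
            closest_pt_triangle(p, a, b, cc, q);
            double d2 = dist2(p, q);
            // tie-break deterministically on the lowest face index
            if (d2 < best2 - 1e-18 || (std::abs(d2 - best2) <= 1e-18 && t < bestf)) {
              best2 = d2;
              bestf = t;
              bestp[0] = q[0]; bestp[1] = q[1]; bestp[2] = q[2];
            }
          }
        }
  }
  *face = bestf;
  cp[0] = bestp[0]; cp[1] = bestp[1]; cp[2] = bestp[2];
  return std::sqrt(best2);
}

// [[Rcpp::export]]
SEXP cpp_mesh_index_build(NumericMatrix V, IntegerMatrix F) {
  MeshIndex *mi = new MeshIndex();
  build_index(*mi, V, F);
  XPtr<MeshIndex> xp(mi, true);
  return xp;
}

// [[Rcpp::export]]
List cpp_mesh_index_query(SEXP xp_, NumericMatrix P) {
  XPtr<MeshIndex> xp(xp_);
  int n = P.nrow();
  NumericVector dist(n);
  IntegerVector face(n);
  NumericMatrix closest(n, 3);
  double p[3], cp[3];
  for (int i = 0; i < n; ++i) {
    p[0] = P(i, 0); p[1] = P(i, 1); p[2] = P(i, 2);
    int f;
    dist[i] = query_index(*xp, p, &f, cp);
    face[i] = f + 1;  // back to 1-based
    closest(i, 0) = cp[0]; closest(i, 1) = cp[1]; closest(i, 2) = cp[2];
  }
  return List::create(_["distance"] = dist, _["face"] = face, _["point"] = closest);
}

// [[Rcpp::export]]
int cpp_mesh_index_size(SEXP xp_) {
  XPtr<MeshIndex> xp(xp_);
  return xp->nf;
}

// ---- marching tetrahedra ---------------------------------------------------
//
// Extracts the iso==0 surface of a scalar field sampled on a regular
// (possibly anisotropic) grid. Each cube is split into 6 tetrahedra sharing
// the main diagonal; iso-crossing vertices are welded through a global edge
// map so the output mesh is vertex-connected.

struct EdgeKeyHash {
  size_t operator()(const uint64_t &k) const { return std::hash<uint64_t>()(k); }
};

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vals, IntegerVector dims,
                       NumericVector origin, NumericVector spacing,
                       double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double *v = REAL(vals);

  auto gid = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };

  // cube corner offsets, binary order x + 2y + 4z
  static const int co[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
  };
  // Kuhn decomposition: 6 tets sharing diagonal corner0-corner7
  static const int tets[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}
  };

  std::vector<double> VX;    // output vertex coords, flattened
  std::vector<int> FACES;    // output faces, 0-based
  std::unordered_map<uint64_t, int, EdgeKeyHash> edge_map;

  auto edge_vertex = [&](int64_t ga, int64_t gb, double va, double vb,
                         const double *pa, const double *pb) -> int {
    int64_t a = ga, b = gb;
    const double *p0 = pa, *p1 = pb;
    double v0 = va, v1 = vb;
    if (a > b) { std::swap(a, b); std::swap(v0, v1); std::swap(p0, p1); }
    uint64_t key = ((uint64_t)a << 32) | (uint64_t)b;
    auto it = edge_map.find(key);
    if (it != edge_map.end()) return it->second;
    double t = (iso - v0) / (v1 - v0);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    int id = (int)(VX.size() / 3);
    VX.push_back(p0[0] + t * (p1[0] - p0[0]));
    VX.push_back(p0[1] + t * (p1[1] - p0[1]));
    VX.push_back(p0[2] + t * (p1[2] - p0[2]));
    edge_map.emplace(key, id);
    return id;
  };

  double cpos[8][3];
  double cval[8];
  int64_t cgid[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          cgid[c] = gid(ii, jj, kk);
          cval[c] = v[cgid[c]];
          cpos[c][0] = ox + ii * hx;
          cpos[c][1] = oy + jj * hy;
          cpos[c][2] = oz + kk * hz;
          if (cval[c] < iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int ci[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int inside[4], nin = 0;
          for (int m = 0; m < 4; ++m) {
            inside[m] = cval[ci[m]] < iso;
            nin += inside[m];
          }
          if (nin == 0 || nin == 4) continue;
          int sel[4], nsel = 0, oth[4], noth = 0;
          bool flag = (nin == 1 || nin == 2);
          for (int m = 0; m < 4; ++m) {
            if ((inside[m] && (nin != 3)) || (!inside[m] && nin == 3))
              sel[nsel++] = ci[m];
            else
              oth[noth++] = ci[m];
          }
          (void)flag;
          if (nsel == 1) {
            // one corner isolated: single triangle
            int e0 = edge_vertex(cgid[sel[0]], cgid[oth[0]], cval[sel[0]], cval[oth[0]], cpos[sel[0]], cpos[oth[0]]);
            int e1 = edge_vertex(cgid[sel[0]], cgid[oth[1]], cval[sel[0]], cval[oth[1]], cpos[sel[0]], cpos[oth[1]]);
            int e2 = edge_vertex(cgid[sel[0]], cgid[oth[2]], cval[sel[0]], cval[oth[2]], cpos[sel[0]], cpos[oth[2]]);
            if (e0 != e1 && e1 != e2 && e0 != e2) {
              FACES.push_back(e0); FACES.push_back(e1); FACES.push_back(e2);
            }
          } else {
            // 2-2 split: quad from the four crossing edges
            int A = sel[0], B = sel[1], C = oth[0], D = oth[1];
            int eAC = edge_vertex(cgid[A], cgid[C], cval[A], cval[C], cpos[A], cpos[C]);
            int eAD = edge_vertex(cgid[A], cgid[D], cval[A], cval[D], cpos[A], cpos[D]);
            int eBD = edge_vertex(cgid[B], cgid[D], cval[B], cval[D], cpos[B], cpos[D]);
            int eBC = edge_vertex(cgid[B], cgid[C], cval[B], cval[C], cpos[B], cpos[C]);
            if (eAC != eAD && eAD != eBD && eAC != eBD) {
              FACES.push_back(eAC); FACES.push_back(eAD); FACES.push_back(eBD);
            }
            if (eAC != eBD && eBD != eBC && eAC != eBC) {
              FACES.push_back(eAC); FACES.push_back(eBD); FACES.push_back(eBC);
            }
          }
        }
      }
    }
  }

  int nvert = (int)(VX.size() / 3);
  NumericMatrix Vout(nvert, 3);
  for (int i = 0; i < nvert; ++i) {
    Vout(i, 0) = VX[3*i+0];
    Vout(i, 1) = VX[3*i+1];
    Vout(i, 2) = VX[3*i+2];
  }
  int nface = (int)(FACES.size() / 3);
  IntegerMatrix Fout(nface, 3);
  for (int i = 0; i < nface; ++i) {
    Fout(i, 0) = FACES[3*i+0] + 1;
    Fout(i, 1) = FACES[3*i+1] + 1;
    Fout(i, 2) = FACES[3*i+2] + 1;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
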