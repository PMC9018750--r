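#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Connected-component labeling of a 3D logical array (BFS flood fill).
// connectivity: 6 or 26. Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
      for (const auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  return lab;
}

struct TetGrid {
  int ng[3];
  double lo[3], cell[3];
  std::vector<std::vector<int>> cells; // tet indices (0-based), sorted
};

static inline int clampi(int v, int a, int b) {
  return v < a ? a : (v > b ? b : v);
}

// Locate query points in tetrahedra. Returns 1-based tet index (0 if not
// found) and barycentric coordinates. Candidates are scanned in increasing
// tet index; a containing positively-oriented tet wins over a folded one.
// [[Rcpp::export]]
List locate_points_tets_cpp(NumericMatrix pts, NumericMatrix verts,
                            IntegerMatrix tets, double eps) {
  const int T = tets.nrow(), Q = pts.nrow();
  std::vector<double> vol(T);
  // bounding boxes
  std::vector<double> bmin(3 * T), bmax(3 * T);
  double glo[3] = {1e300, 1e300, 1e300}, ghi[3] = {-1e300, -1e300, -1e300};
  for (int t = 0; t < T; ++t) {
    double mn[3] = {1e300, 1e300, 1e300}, mx[3] = {-1e300, -1e300, -1e300};
    for (int k = 0; k < 4; ++k) {
      int v = tets(t, k) - 1;
      for (int d = 0; d < 3; ++d) {
        double c = verts(v, d);
        if (c < mn[d]) mn[d] = c;
        if (c > mx[d]) mx[d] = c;
      }
    }
    for (int d = 0; d < 3; ++d) {
      bmin[3 * t + d] = mn[d]; bmax[3 * t + d] = mx[d];
      if (mn[d] < glo[d]) glo[d] = mn[d];
      if (mx[d] > ghi[d]) ghi[d] = mx[d];
    }
    // signed volume
    int a = tets(t, 0) - 1, b = tets(t, 1) - 1, c = tets(t, 2) - 1,
        dd = tets(t, 3) - 1;
    double ux = verts(b,0)-verts(a,0), uy = verts(b,1)-verts(a,1), uz = verts(b,2)-verts(a,2);
    double vx = verts(c,0)-verts(a,0), vy = verts(c,1)-verts(a,1), vz = verts(c,2)-verts(a,2);
    double wx = verts(dd,0)-verts(a,0), wy = verts(dd,1)-verts(a,1), wz = verts(dd,2)-verts(a,2);
    vol[t] = (ux*(vy*wz - vz*wy) - uy*(vx*wz - vz*wx) + uz*(vx*wy - vy*wx)) / 6.0;
  }
  TetGrid grid;
  int ngAll = std::max(1, (int)std::floor(std::cbrt((double)T / 4.0)));
  for (int d = 0; d < 3; ++d) {
    grid.ng[d] = std::min(ngAll, 160);
    grid.lo[d] = glo[d];
    double span = ghi[d] - glo[d];
    grid.cell[d] = span > 0 ? span / grid.ng[d] : 1.0;
  }
  grid.cells.assign((size_t)grid.ng[0] * grid.ng[1] * grid.ng[2], {});
  for (int t = 0; t < T; ++t) {
    int i0[3], i1[3];
    for (int d = 0; d < 3; ++d) {
      i0[d] = clampi((int)std::floor((bmin[3*t+d] - grid.lo[d]) / grid.cell[d]), 0, grid.ng[d]-1);
      i1[d] = clampi((int)std::floor((bmax[3*t+d] - grid.lo[d]) / grid.cell[d]), 0, grid.ng[d]-1);
    }
    for (int z = i0[2]; z <= i1[2]; ++z)
      for (int y = i0[1]; y <= i1[1]; ++y)
        for (int x = i0[0]; x <= i1[0]; ++x)
          grid.cells[x + (size_t)grid.ng[0] * (y + (size_t)grid.ng[1] * z)].push_back(t);
  }
  IntegerVector hit(Q, 0);
  NumericMatrix bary(Q, 4);
  for (int q = 0; q < Q; ++q) {
    double p[3] = {pts(q, 0), pts(q, 1), pts(q, 2)};
    bool outside = false;
    int ci[3];
    for (int d = 0; d < 3; ++d) {
      if (p[d] < glo[d] - grid.cell[d] || p[d] > ghi[d] + grid.cell[d]) { outside = true; break; }
      ci[d] = clampi((int)std::floor((p[d] - grid.lo[d]) / grid.cell[d]), 0, grid.ng[d]-1);
    }
    if (outside) continue;
    const std::vector<int> &cand =
      grid.cells[ci[0] + (size_t)grid.ng[0] * (ci[1] + (size_t)grid.ng[1] * ci[2])];
    int bestPos = -1, bestAny = -1;
    double bb[4], bbAny[4];
    for (int idx : cand) {
      if (p[0] < bmin[3*idx] - 0 || p[0] > bmax[3*idx]) continue;
      if (p[1] < bmin[3*idx+1] || p[1] > bmax[3*idx+1]) continue;
      if (p[2] < bmin[3*idx+2] || p[2] > bmax[3*idx+2]) continue;
      double V = vol[idx];
      if (V == 0) continue;
      int vi[4] = {tets(idx,0)-1, tets(idx,1)-1, tets(idx,2)-1, tets(idx,3)-1};
      // barycentric via sub-volumes (replace vertex k by p)
      double b[4]; bool in = true;
      for (int k = 0; k < 4 && in; ++k) {
        double pt0[3], pt1[3], pt2[3], pt3[3];
        for (int d = 0; d < 3; ++d) {
          pt0[d] = (k == 0) ? p[d] : verts(vi[0], d);
          pt1[d] = (k == 1) ? p[d] : verts(vi[1], d);
          pt2[d] = (k == 2) ? p[d] : verts(vi[2], d);
          pt3[d] = (k == 3) ? p[d] : verts(vi[3], d);
        }
        double ux = pt1[0]-pt0[0], uy = pt1[1]-pt0[1], uz = pt1[2]-pt0[2];
        double vx = pt2[0]-pt0[0], vy = pt2[1]-pt0[1], vz = pt2[2]-pt0[2];
        double wx = pt3[0]-pt0[0], wy = pt3[1]-pt0[1], wz = pt3[2]-pt0[2];
        double Vk = (ux*(vy*wz - vz*wy) - uy*(vx*wz - vz*wx) + uz*(vx*wy - vy*wx)) / 6.0;
        b[k] = Vk / V;
        if (b[k] < -eps) in = false;
      }
      if (!in) continue;
      if (V > 0) {
        if (bestPos < 0) { bestPos = idx; for (int k=0;k<4;++k) bb[k]=b[k]; }
      } else if (bestAny < 0) {
        bestAny = idx; for (int k=0;k<4;++k) bbAny[k]=b[k];
      }
      if (bestPos >= 0) break; // candidates sorted by index: first positive wins
    }
    if (bestPos >= 0) {
      hit[q] = bestPos + 1;
      for (int k = 0; k < 4; ++k) bary(q, k) = bb[k];
    } else if (bestAny >= 0) {
      hit[q] = bestAny + 1;
      for (int k = 0; k < 4; ++k) bary(q, k) = bbAny[k];
    }
  }
  return List::create(_["tet"] = hit, _["bary"] = bary);
}

// Locate unit direction vectors inside spherical triangles of a genus-zero
// triangulation (vertices on the unit sphere). q is inside triangle (A,B,C)
// iff q = c1 A + c2 B + c3 C with all ci >= -eps. Returns 1-based triangle
// index (0 if unresolved) and the normalized coefficients.
// [[Rcpp::export]]
List locate_dirs_tris_cpp(NumericMatrix q, NumericMatrix verts,
                          IntegerMatrix tris, double eps) {
  const int F = tris.nrow(), Q = q.nrow();
  // Precompute inverse matrices (columns A,B,C).
  std::vector<double> inv(9 * F);
  std::vector<bool> ok(F, true);
  for (int f = 0; f < F; ++f) {
    double M[9];
    for (int k = 0; k < 3; ++k) {
      int v = tris(f, k) - 1;
      M[0 + k] = verts(v, 0);
      M[3 + k] = verts(v, 1);
      M[6 + k] = verts(v, 2);
    }
    double det = M[0]*(M[4]*M[8]-M[5]*M[7]) - M[1]*(M[3]*M[8]-M[5]*M[6])
               + M[2]*(M[3]*M[7]-M[4]*M[6]);
    if (std::fabs(det) < 1e-14) { ok[f] = false; continue; }
    double *Iv = &inv[9 * f];
    Iv[0] = (M[4]*M[8]-M[5]*M[7])/det; Iv[1] = (M[2]*M[7]-M[1]*M[8])/det; Iv[2] = (M[1]*M[5]-M[2]*M[4])/det;
    Iv[3] = (M[5]*M[6]-M[3]*M[8])/det; Iv[4] = (M[0]*M[8]-M[2]*M[6])/det; Iv[5] = (M[2]*M[3]-M[0]*M[5])/det;
    Iv[6] = (M[3]*M[7]-M[4]*M[6])/det; Iv[7] = (M[1]*M[6]-M[0]*M[7])/det; Iv[8] = (M[0]*M[4]-M[1]*M[3])/det;
  }
  // Hash triangles by direction into a grid over [-1,1]^3.
  const int NG = 24;
  std::vector<std::vector<int>> cells((size_t)NG * NG * NG);
  auto cellOf = [&](double x, int &i) {
    i = clampi((int)std::floor((x + 1.0) / 2.0 * NG), 0, NG - 1);
  };
  for (int f = 0; f < F; ++f) {
    double mn[3] = {1e300,1e300,1e300}, mx[3] = {-1e300,-1e300,-1e300};
    for (int k = 0; k < 3; ++k) {
      int v = tris(f, k) - 1;
      for (int d = 0; d < 3; ++d) {
        double c = verts(v, d);
        if (c < mn[d]) mn[d] = c;
        if (c > mx[d]) mx[d] = c;
      }
    }
    int i0[3], i1[3];
    for (int d = 0; d < 3; ++d) {
      cellOf(mn[d] - 0.10, i0[d]);
      cellOf(mx[d] + 0.10, i1[d]);
    }
    for (int z = i0[2]; z <= i1[2]; ++z)
      for (int y = i0[1]; y <= i1[1]; ++y)
        for (int x = i0[0]; x <= i1[0]; ++x)
          cells[x + (size_t)NG * (y + (size_t)NG * z)].push_back(f);
  }
  IntegerVector hit(Q, 0);
  NumericMatrix coef(Q, 3);
  for (int iq = 0; iq < Q; ++iq) {
    double p[3] = {q(iq, 0), q(iq, 1), q(iq, 2)};
    int ci[3];
    for (int d = 0; d < 3; ++d) cellOf(p[d], ci[d]);
    const std::vector<int> *cand =
      &cells[ci[0] + (size_t)NG * (ci[1] + (size_t)NG * ci[2])];
    for (int pass = 0; pass < 2 && !hit[iq]; ++pass) {
      if (pass == 1) { // brute force fallback
        static std::vector<int> all;
        if ((int)all.size() != F) { all.resize(F); for (int f = 0; f < F; ++f) all[f] = f; }
        cand = &all;
      }
      int best = -1; double bc[3]; double bestSlack = -1e300;
      for (int f : *cand) {
        if (!ok[f]) continue;
        const double *Iv = &inv[9 * f];
        double c1 = Iv[0]*p[0] + Iv[1]*p[1] + Iv[2]*p[2];
        double c2 = Iv[3]*p[0] + Iv[4]*p[1] + Iv[5]*p[2];
        double c3 = Iv[6]*p[0] + Iv[7]*p[1] + Iv[8]*p[2];
        double s = c1 + c2 + c3;
        if (s <= 0) continue;
        c1 /= s; c2 /= s; c3 /= s;
        double slack = std::min(c1, std::min(c2, c3));
        if (slack >= -eps) { best = f; bc[0]=c1; bc[1]=c2; bc[2]=c3; break; }
        if (slack > bestSlack) { bestSlack = slack; best = -2 - f; bc[0]=c1; bc[1]=c2; bc[2]=c3; }
      }
      if (best >= 0) {
        hit[iq] = best + 1;
        for (int k = 0; k < 3; ++k) coef(iq, k) = bc[k];
      } else if (pass == 1 && best <= -2 && bestSlack > -1e-3) {
        // tolerance expansion: accept the nearest triangle if slack is tiny
        int f = -2 - best;
        hit[iq] = f + 1;
        double c1 = std::max(bc[0], 0.0), c2 = std::max(bc[1], 0.0),
               c3 = std::max(bc[2], 0.0);
        double s = c1 + c2 + c3;
        coef(iq, 0) = c1 / s; coef(iq, 1) = c2 / s; coef(iq, 2) = c3 / s;
      }
    }
  }
  return List::create(_["tri"] = hit, _["coef"] = coef);
}

// For each row of a, the minimum Euclidean distance to the rows of b.
// [[Rcpp::export]]
NumericVector min_dists_cpp(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double ax = a(i,0), ay = a(i,1), az = a(i,2);
    double best = 1e300;
    for (int j = 0; j < nb; ++j) {
      double dx = ax - b(j,0), dy = ay - b(j,1), dz = az - b(j,2);
      double d = dx*dx + dy*dy + dz*dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
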