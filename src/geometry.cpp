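#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform (lower envelope of parabolas) on a grid with
// physical sample spacing s. f and d have length n; v/z are scratch.
static void dt1d(const double *f, double *d, int n, double s,
                 std::vector<int> &v, std::vector<double> &z) {
  // only sites with finite f enter the envelope; callers skip all-infinite rows
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * s;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double sint;
    while (true) {
      double xv = v[k] * s;
      sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (sint <= z[k] && k > 0) { --k; } else break;
    }
    if (sint <= z[k]) {        // k == 0 and new parabola dominates everywhere
      v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      ++k; v[k] = q; z[k] = sint; z[k + 1] = INF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance, in mm^2, of every voxel to the nearest
// foreground (TRUE) voxel centre, honouring anisotropic spacing.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
      bool any = false;
      for (int xx = 0; xx < nx; ++xx) { f[xx] = D[base + xx]; if (f[xx] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), nx, spacing[0], v, z);
      for (int xx = 0; xx < nx; ++xx) D[base + xx] = d[xx];
    }
  // pass along y
  for (int zz = 0; zz < nz; ++zz)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + xx;
      bool any = false;
      for (int yy = 0; yy < ny; ++yy) { f[yy] = D[base + (R_xlen_t)yy * nx]; if (f[yy] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int yy = 0; yy < ny; ++yy) D[base + (R_xlen_t)yy * nx] = d[yy];
    }
  // pass along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int yy = 0; yy < ny; ++yy)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = (R_xlen_t)yy * nx + xx;
      bool any = false;
      for (int zz = 0; zz < nz; ++zz) { f[zz] = D[base + zz * nxy]; if (f[zz] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int zz = 0; zz < nz; ++zz) D[base + zz * nxy] = d[zz];
    }
  return D;
}

// For each row of src (mm coordinates), the distance to and 1-based index of
// the nearest row of tgt. Brute force; patches are at most a few thousand points.
// [[Rcpp::export]]
List cpp_nearest(NumericMatrix src, NumericMatrix tgt) {
  int n = src.nrow(), m = tgt.nrow();
  NumericVector dist(n);
  IntegerVector idx(n);
  for (int i = 0; i < n; ++i) {
    double best = INF;
    int bj = 0;
    double sx = src(i, 0), sy = src(i, 1), sz = src(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = sx - tgt(j, 0), dy = sy - tgt(j, 1), dz = sz - tgt(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    dist[i] = std::sqrt(best);
    idx[i] = bj + 1;
  }
  return List::create(_["dist"] = dist, _["index"] = idx);
}

// Connected-component labels (0 = background) for a 3D logical array.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nn = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nn == 0) continue;
        if (connectivity == 6 && nn > 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int cz = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur % ((R_xlen_t)nx * ny));
      int cy = rem / nx, cx = rem % nx;
      for (auto &o : offs) {
        int xx = cx + o[0], yy = cy + o[1], zz = cz + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        R_xlen_t t = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[t] && lab[t] == 0) { lab[t] = next; q.push(t); }
      }
    }
  }
  return lab;
}

// Marching-tetrahedra triangulation of the iso-level surface of a scalar
// field. Returns one row per triangle: centroid (mm) and area (mm^2).
// Cells are decomposed into 6 tetrahedra around the (0,0,0)-(1,1,1) diagonal.
// [[Rcpp::export]]
NumericMatrix cpp_iso_triangles(NumericVector vals, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  // cube corner offsets
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  std::vector<double> out; // cx, cy, cz, area
  double cx[8], cy[8], cz[8], cv[8];
  auto interp = [&](int a, int b, double *p) {
    double t = (iso - cv[a]) / (cv[b] - cv[a]);
    p[0] = cx[a] + t * (cx[b] - cx[a]);
    p[1] = cy[a] + t * (cy[b] - cy[a]);
    p[2] = cz[a] + t * (cz[b] - cz[a]);
  };
  auto emit = [&](double *p, double *q, double *r) {
    double ux = q[0]-p[0], uy = q[1]-p[1], uz = q[2]-p[2];
    double vx = r[0]-p[0], vy = r[1]-p[1], vz = r[2]-p[2];
    double nxv = uy*vz - uz*vy, nyv = uz*vx - ux*vz, nzv = ux*vy - uy*vx;
    double area = 0.5 * std::sqrt(nxv*nxv + nyv*nyv + nzv*nzv);
    if (area <= 0) return;
    out.push_back((p[0]+q[0]+r[0])/3.0);
    out.push_back((p[1]+q[1]+r[1])/3.0);
    out.push_back((p[2]+q[2]+r[2])/3.0);
    out.push_back(area);
  };
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool anyAbove = false, anyBelow = false;
        for (int c = 0; c < 8; ++c) {
          int xi = i + corner[c][0], yi = j + corner[c][1], zi = k + corner[c][2];
          cv[c] = vals[(R_xlen_t)zi * nxy + (R_xlen_t)yi * nx + xi];
          // voxel-centre coordinates in mm (origin at grid corner)
          cx[c] = origin[0] + (xi + 0.5) * spacing[0];
          cy[c] = origin[1] + (yi + 0.5) * spacing[1];
          cz[c] = origin[2] + (zi + 0.5) * spacing[2];
          if (cv[c] > iso) anyAbove = true; else anyBelow = true;
        }
        if (!anyAbove || !anyBelow) continue;
        for (int t = 0; t < 6; ++t) {
          int a[4]; int nab = 0, nbe = 0;
          int above[4], below[4];
          for (int c = 0; c < 4; ++c) {
            a[c] = tets[t][c];
            if (cv[a[c]] > iso) above[nab++] = a[c]; else below[nbe++] = a[c];
          }
          double p1[3], p2[3], p3[3], p4[3];
          if (nab == 0 || nab == 4) continue;
          if (nab == 1) {
            interp(above[0], below[0], p1);
            interp(above[0], below[1], p2);
            interp(above[0], below[2], p3);
            emit(p1, p2, p3);
          } else if (nab == 3) {
            interp(below[0], above[0], p1);
            interp(below[0], above[1], p2);
            interp(below[0], above[2], p3);
            emit(p1, p2, p3);
          } else { // 2 above, 2 below -> quad
            interp(above[0], below[0], p1);
            interp(above[0], below[1], p2);
            interp(above[1], below[1], p3);
            interp(above[1], below[0], p4);
            emit(p1, p2, p3);
            emit(p1, p3, p4);
          }
        }
      }
  int ntri = (int)(out.size() / 4);
  NumericMatrix res(ntri, 4);
  for (int r = 0; r < ntri; ++r)
    for (int c = 0; c < 4; ++c) res(r, c) = out[(R_xlen_t)r * 4 + c];
  colnames(res) = CharacterVector::create("cx", "cy", "cz", "area");
  return res;
}
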