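#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gray-level texture matrices over a 3D labelled volume.
// `levels` is an integer array (nx, ny, nz); 0 marks voxels outside the VOI,
// values 1..ng are discretized gray levels inside the VOI.

static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector levels, int ng) {
  IntegerVector dm = levels.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  NumericVector out(ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double *P = &out[d * ng * ng];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int li = levels[idx3(x, y, z, nx, ny)];
          if (li == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int lj = levels[idx3(x2, y2, z2, nx, ny)];
          if (lj == 0) continue;
          // symmetric: count both (i,j) and (j,i)
          P[(li - 1) + ng * (lj - 1)] += 1.0;
          P[(lj - 1) + ng * (li - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector levels, int ng) {
  IntegerVector dm = levels.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  int maxrun = std::max(nx, std::max(ny, nz));
  NumericVector out(ng * maxrun * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double *P = &out[d * ng * maxrun];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int li = levels[idx3(x, y, z, nx, ny)];
          if (li == 0) continue;
          // only start a run if the previous voxel along -d is not part of it
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
              levels[idx3(xp, yp, zp, nx, ny)] == li)
            continue;
          int len = 1;
          int xc = x + dx, yc = y + dy, zc = z + dz;
          while (xc >= 0 && xc < nx && yc >= 0 && yc < ny && zc >= 0 &&
                 zc < nz && levels[idx3(xc, yc, zc, nx, ny)] == li) {
            ++len;
            xc += dx; yc += dy; zc += dz;
          }
          P[(li - 1) + ng * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxrun, 13);
  return out;
}

// zones of identical gray level, 26-connectivity
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector levels, int ng) {
  IntegerVector dm = levels.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs; // zone level, zone size
  std::vector<int> stack;
  int maxsize = 1;
  for (int start = 0; start < n; ++start) {
    if (seen[start] || levels[start] == 0) continue;
    int lev = levels[start];
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int cz = cur / (nx * ny);
      int rem = cur - cz * nx * ny;
      int cy = rem / nx;
      int cx = rem - cy * nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                z2 >= nz)
              continue;
            int j = idx3(x2, y2, z2, nx, ny);
            if (!seen[j] && levels[j] == lev) {
              seen[j] = 1;
              stack.push_back(j);
            }
          }
    }
    zl.push_back(lev);
    zs.push_back(size);
    if (size > maxsize) maxsize = size;
  }
  NumericMatrix out(ng, maxsize);
  for (size_t k = 0; k < zl.size(); ++k)
    out(zl[k] - 1, zs[k] - 1) += 1.0;
  return out;
}

// dependence matrix: column j = (number of 26-neighbours within alpha) + 1
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, int ng, int alpha) {
  IntegerVector dm = levels.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                continue;
              int lj = levels[idx3(x2, y2, z2, nx, ny)];
              if (lj == 0) continue;
              if (std::abs(lj - li) <= alpha) ++dep;
            }
        out(li - 1, dep) += 1.0;
      }
  return out;
}

// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector levels, int ng) {
  IntegerVector dm = levels.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  NumericVector ni(ng), si(ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                continue;
              int lj = levels[idx3(x2, y2, z2, nx, ny)];
              if (lj == 0) continue;
              sum += lj;
              ++cnt;
            }
        ni[li - 1] += 1.0;
        if (cnt > 0) si[li - 1] += std::fabs(li - sum / cnt);
      }
  return List::create(_["n"] = ni, _["s"] = si);
}

// ---- shape: marching-tetrahedra surface mesh on a binary mask -------------

struct Vec3 {
  double x, y, z;
};
static inline Vec3 mid(const Vec3 &a, const Vec3 &b) {
  Vec3 m = {0.5 * (a.x + b.x), 0.5 * (a.y + b.y), 0.5 * (a.z + b.z)};
  return m;
}
static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  Vec3 m = {a.x - b.x, a.y - b.y, a.z - b.z};
  return m;
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  Vec3 m = {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x};
  return m;
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

static void add_tri(const Vec3 &p0, const Vec3 &p1, const Vec3 &p2,
                    const Vec3 &inside_ref, double &area, double &vol) {
  Vec3 e1 = sub(p1, p0), e2 = sub(p2, p0);
  Vec3 n = cross(e1, e2);
  double a2 = std::sqrt(dot(n, n));
  area += 0.5 * a2;
  // orient outward (away from a point known to be inside)
  Vec3 c = {(p0.x + p1.x + p2.x) / 3.0, (p0.y + p1.y + p2.y) / 3.0,
            (p0.z + p1.z + p2.z) / 3.0};
  Vec3 ref = sub(c, inside_ref);
  double s = dot(n, ref) >= 0 ? 1.0 : -1.0;
  // signed volume of tetrahedron (origin, p0, p1, p2), outward orientation
  vol += s * dot(p0, cross(p1, p2)) / 6.0;
}

// 6-tetrahedra decomposition of the unit cube (corner indices)
static const int TET6[6][4] = {{0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
                               {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
// cube corner offsets
static const int CORNER[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                                 {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};

static inline Vec3 lerp(const Vec3 &a, double va, const Vec3 &b, double vb,
                        double level) {
  double t = (va == vb) ? 0.5 : (level - va) / (vb - va);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  Vec3 m = {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y),
            a.z + t * (b.z - a.z)};
  return m;
}

// Surface area and enclosed volume of the `level` iso-surface of a
// real-valued field (marching tetrahedra with linear edge interpolation);
// samples at voxel centres, physical units via `spacing`. Values outside
// the array are treated as 0 (background).
// [[Rcpp::export]]
List cpp_mesh(NumericVector field, NumericVector spacing, double level) {
  IntegerVector dm = field.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double area = 0.0, vol = 0.0;
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        double val[8];
        int in[8];
        int cnt = 0;
        for (int c = 0; c < 8; ++c) {
          int cx = x + CORNER[c][0], cy = y + CORNER[c][1],
              cz = z + CORNER[c][2];
          double v = 0.0;
          if (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz)
            v = field[idx3(cx, cy, cz, nx, ny)];
          val[c] = v;
          in[c] = v > level ? 1 : 0;
          cnt += in[c];
        }
        if (cnt == 0 || cnt == 8) continue;
        Vec3 P[8];
        for (int c = 0; c < 8; ++c) {
          P[c].x = (x + CORNER[c][0]) * sx;
          P[c].y = (y + CORNER[c][1]) * sy;
          P[c].z = (z + CORNER[c][2]) * sz;
        }
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {TET6[t][0], TET6[t][1], TET6[t][2], TET6[t][3]};
          int flags[4], nin = 0;
          for (int k = 0; k < 4; ++k) {
            flags[k] = in[vi[k]];
            nin += flags[k];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int lone = -1;
            int want = (nin == 1) ? 1 : 0;
            for (int k = 0; k < 4; ++k)
              if (flags[k] == want) lone = k;
            Vec3 others[3];
            int m = 0;
            Vec3 ip = {0, 0, 0};
            int ic = 0;
            for (int k = 0; k < 4; ++k) {
              if (k != lone)
                others[m++] = lerp(P[vi[lone]], val[vi[lone]], P[vi[k]],
                                   val[vi[k]], level);
              if (flags[k]) {
                ip.x += P[vi[k]].x; ip.y += P[vi[k]].y; ip.z += P[vi[k]].z;
                ++ic;
              }
            }
            ip.x /= ic; ip.y /= ic; ip.z /= ic;
            add_tri(others[0], others[1], others[2], ip, area, vol);
          } else {
            // 2 in, 2 out: quad across the four crossing edges
            int ins[2], outs[2], a = 0, b = 0;
            for (int k = 0; k < 4; ++k)
              if (flags[k]) ins[a++] = k; else outs[b++] = k;
            Vec3 m00 = lerp(P[vi[ins[0]]], val[vi[ins[0]]],
                            P[vi[outs[0]]], val[vi[outs[0]]], level);
            Vec3 m01 = lerp(P[vi[ins[0]]], val[vi[ins[0]]],
                            P[vi[outs[1]]], val[vi[outs[1]]], level);
            Vec3 m11 = lerp(P[vi[ins[1]]], val[vi[ins[1]]],
                            P[vi[outs[1]]], val[vi[outs[1]]], level);
            Vec3 m10 = lerp(P[vi[ins[1]]], val[vi[ins[1]]],
                            P[vi[outs[0]]], val[vi[outs[0]]], level);
            Vec3 ip = mid(P[vi[ins[0]]], P[vi[ins[1]]]);
            add_tri(m00, m01, m11, ip, area, vol);
            add_tri(m00, m11, m10, ip, area, vol);
          }
        }
      }
  return List::create(_["area"] = area, _["volume"] = std::fabs(vol));
}

// maximum pairwise distances between boundary voxel centres:
// overall 3D and restricted to shared slice (z), column (y), row (x)
// [[Rcpp::export]]
NumericVector cpp_max_diameters(NumericMatrix pts) {
  int n = pts.nrow();
  double d3 = 0, dsl = 0, dcol = 0, drow = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double q = dx * dx + dy * dy + dz * dz;
      if (q > d3) d3 = q;
      if (dz == 0 && dx * dx + dy * dy > dsl) dsl = dx * dx + dy * dy;
      if (dy == 0 && dx * dx + dz * dz > dcol) dcol = dx * dx + dz * dz;
      if (dx == 0 && dy * dy + dz * dz > drow) drow = dy * dy + dz * dz;
    }
  return NumericVector::create(std::sqrt(d3), std::sqrt(dsl),
                               std::sqrt(dcol), std::sqrt(drow));
}
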