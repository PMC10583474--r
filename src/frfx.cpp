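#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Column-major linear index, 0-based.
static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// The 13 unique 3-D direction offsets at Chebyshev distance 1 (half of the 26
// neighbourhood; the other half are their negations).
static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// Separable 3-D convolution with the same symmetric 1-D kernel along every
// axis, zero padding at the borders.
// [[Rcpp::export]]
NumericVector sep_conv3_cpp(NumericVector x, IntegerVector dim, NumericVector kernel) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nk = kernel.size();
  int kr = (nk - 1) / 2;
  std::vector<double> a(x.begin(), x.end());
  std::vector<double> b(x.size(), 0.0);
  // axis 0
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int xx = 0; xx < nx; ++xx) {
        double s = 0.0;
        int lo = std::max(0, xx - kr), hi = std::min(nx - 1, xx + kr);
        for (int t = lo; t <= hi; ++t) s += a[idx3(t, y, z, nx, ny)] * kernel[t - xx + kr];
        b[idx3(xx, y, z, nx, ny)] = s;
      }
  std::swap(a, b);
  // axis 1
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      int lo = std::max(0, y - kr), hi = std::min(ny - 1, y + kr);
      for (int xx = 0; xx < nx; ++xx) {
        double s = 0.0;
        for (int t = lo; t <= hi; ++t) s += a[idx3(xx, t, z, nx, ny)] * kernel[t - y + kr];
        b[idx3(xx, y, z, nx, ny)] = s;
      }
    }
  std::swap(a, b);
  // axis 2
  for (int z = 0; z < nz; ++z) {
    int lo = std::max(0, z - kr), hi = std::min(nz - 1, z + kr);
    for (int y = 0; y < ny; ++y)
      for (int xx = 0; xx < nx; ++xx) {
        double s = 0.0;
        for (int t = lo; t <= hi; ++t) s += a[idx3(xx, y, t, nx, ny)] * kernel[t - z + kr];
        b[idx3(xx, y, z, nx, ny)] = s;
      }
  }
  return NumericVector(b.begin(), b.end());
}

// Two-pass chamfer (3-4-5) distance transform to the seed set, whole grid.
// Returned in chamfer units (divide by 3 for approximate voxel units).
// [[Rcpp::export]]
NumericVector chamfer_dist_cpp(LogicalVector seed, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = 1e30;
  std::vector<double> d(seed.size());
  for (R_xlen_t i = 0; i < seed.size(); ++i) d[i] = seed[i] ? 0.0 : INF;
  // forward neighbours: strictly earlier in (z, y, x) scan order
  int off[13][4]; int no = 0;
  for (int dz = -1; dz <= 0; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
        int w = 3 + (std::abs(dx) + std::abs(dy) + std::abs(dz) - 1);
        // face 3, edge 4, corner 5
        w = (std::abs(dx) + std::abs(dy) + std::abs(dz) == 1) ? 3 :
            (std::abs(dx) + std::abs(dy) + std::abs(dz) == 2) ? 4 : 5;
        off[no][0] = dx; off[no][1] = dy; off[no][2] = dz; off[no][3] = w; ++no;
      }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = idx3(x, y, z, nx, ny);
        double v = d[i];
        for (int k = 0; k < no; ++k) {
          int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          double c = d[idx3(xx, yy, zz, nx, ny)] + off[k][3];
          if (c < v) v = c;
        }
        d[i] = v;
      }
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        R_xlen_t i = idx3(x, y, z, nx, ny);
        double v = d[i];
        for (int k = 0; k < no; ++k) {
          int xx = x - off[k][0], yy = y - off[k][1], zz = z - off[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          double c = d[idx3(xx, yy, zz, nx, ny)] + off[k][3];
          if (c < v) v = c;
        }
        d[i] = v;
      }
  return NumericVector(d.begin(), d.end());
}

// Grey-level co-occurrence counts for the 13 unique directions at distance 1.
// bins: integer grid, 0 = outside mask. Returns a list of 13 ng x ng
// (unsymmetrised) count matrices.
// [[Rcpp::export]]
List glcm_cpp(IntegerVector bins, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  List out(13);
  for (int k = 0; k < 13; ++k) {
    int dx = DIR13[k][0], dy = DIR13[k][1], dz = DIR13[k][2];
    NumericMatrix M(ng, ng);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = bins[idx3(x, y, z, nx, ny)];
          if (a <= 0) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          int b = bins[idx3(xx, yy, zz, nx, ny)];
          if (b <= 0) continue;
          M(a - 1, b - 1) += 1.0;
        }
    out[k] = M;
  }
  return out;
}

// Grey-level run-length counts per direction.
// [[Rcpp::export]]
List glrlm_cpp(IntegerVector bins, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int lmax = nx + ny + nz;
  List out(13);
  for (int k = 0; k < 13; ++k) {
    int dx = DIR13[k][0], dy = DIR13[k][1], dz = DIR13[k][2];
    NumericMatrix M(ng, lmax);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = bins[idx3(x, y, z, nx, ny)];
          if (a <= 0) continue;
          // run start: predecessor along -d absent or different
          int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz &&
              bins[idx3(px, py, pz, nx, ny)] == a) continue;
          int len = 1;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          while (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz &&
                 bins[idx3(xx, yy, zz, nx, ny)] == a) {
            ++len; xx += dx; yy += dy; zz += dz;
          }
          M(a - 1, len - 1) += 1.0;
        }
    out[k] = M;
  }
  return out;
}

// Grey-level size-zone decomposition: 26-connected components of constant
// level. Returns the level and voxel count of every zone.
// [[Rcpp::export]]
List glszm_cpp(IntegerVector bins, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> seen(bins.size(), 0);
  std::vector<int> lev, sz;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i0 = idx3(x, y, z, nx, ny);
        int a = bins[i0];
        if (a <= 0 || seen[i0]) continue;
        int count = 0;
        stack.clear(); stack.push_back(i0); seen[i0] = 1;
        while (!stack.empty()) {
          R_xlen_t i = stack.back(); stack.pop_back();
          ++count;
          int cz = (int)(i / ((R_xlen_t)nx * ny));
          int rem = (int)(i - (R_xlen_t)cz * nx * ny);
          int cy = rem / nx, cx = rem % nx;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int xx = cx + dx, yy = cy + dy, zz = cz + dz;
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
                R_xlen_t j = idx3(xx, yy, zz, nx, ny);
                if (!seen[j] && bins[j] == a) { seen[j] = 1; stack.push_back(j); }
              }
        }
        lev.push_back(a); sz.push_back(count);
      }
  return List::create(_["level"] = IntegerVector(lev.begin(), lev.end()),
                      _["size"] = IntegerVector(sz.begin(), sz.end()));
}

// Grey-level dependence counts: dependence = 1 + number of 26-neighbours
// inside the mask with identical level (alpha = 0). ng x 27 matrix.
// [[Rcpp::export]]
NumericMatrix gldm_cpp(IntegerVector bins, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix M(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = bins[idx3(x, y, z, nx, ny)];
        if (a <= 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
              if (bins[idx3(xx, yy, zz, nx, ny)] == a) ++dep;
            }
        M(a - 1, dep) += 1.0;
      }
  return M;
}

// Neighbourhood grey-tone difference accumulators: per level, the count of
// voxels having at least one in-mask neighbour and the summed absolute
// difference between the voxel level and its mean in-mask neighbour level.
// [[Rcpp::export]]
List ngtdm_cpp(IntegerVector bins, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector s(ng), n(ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = bins[idx3(x, y, z, nx, ny)];
        if (a <= 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
              int b = bins[idx3(xx, yy, zz, nx, ny)];
              if (b > 0) { sum += b; ++cnt; }
            }
        if (cnt > 0) {
          n[a - 1] += 1.0;
          s[a - 1] += std::fabs((double)a - sum / cnt);
        }
      }
  return List::create(_["n"] = n, _["s"] = s);
}

// Rasterise a cylinder of radius r (mm) around segment A-B (mm) into `vess`,
// restricted to `allowed` voxels; modifies `vess` in place and returns the
// number of voxels newly covered.
// [[Rcpp::export]]
int add_cylinder_cpp(LogicalVector vess, LogicalVector allowed, IntegerVector dim,
                     NumericVector spacing, NumericVector A, NumericVector B,
                     double r) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  auto lo_vox = [&](double a, double b, double s, int n) {
    int v = (int)std::floor((std::min(a, b) - r) / s - 0.5);
    return std::max(0, std::min(n - 1, v));
  };
  auto hi_vox = [&](double a, double b, double s, int n) {
    int v = (int)std::ceil((std::max(a, b) + r) / s + 0.5);
    return std::max(0, std::min(n - 1, v));
  };
  int xlo = lo_vox(A[0], B[0], sx, nx), xhi = hi_vox(A[0], B[0], sx, nx);
  int ylo = lo_vox(A[1], B[1], sy, ny), yhi = hi_vox(A[1], B[1], sy, ny);
  int zlo = lo_vox(A[2], B[2], sz, nz), zhi = hi_vox(A[2], B[2], sz, nz);
  double ux = B[0] - A[0], uy = B[1] - A[1], uz = B[2] - A[2];
  double len2 = ux * ux + uy * uy + uz * uz;
  double r2 = r * r;
  int added = 0;
  for (int z = zlo; z <= zhi; ++z) {
    double pz = (z + 0.5) * sz;
    for (int y = ylo; y <= yhi; ++y) {
      double py = (y + 0.5) * sy;
      for (int x = xlo; x <= xhi; ++x) {
        R_xlen_t i = idx3(x, y, z, nx, ny);
        if (!allowed[i] || vess[i]) continue;
        double px = (x + 0.5) * sx;
        double t = 0.0;
        if (len2 > 0) {
          t = ((px - A[0]) * ux + (py - A[1]) * uy + (pz - A[2]) * uz) / len2;
          if (t < 0) t = 0; else if (t > 1) t = 1;
        }
        double dx = px - A[0] - t * ux, dy = py - A[1] - t * uy, dz = pz - A[2] - t * uz;
        if (dx * dx + dy * dy + dz * dz <= r2) { vess[i] = true; ++added; }
      }
    }
  }
  return added;
}

// Largest pairwise Euclidean distance between rows of a point matrix (mm).
// [[Rcpp::export]]
double max_pairwise_dist_cpp(NumericMatrix pts) {
  R_xlen_t n = pts.nrow();
  double best = 0.0;
  for (R_xlen_t i = 0; i < n; ++i)
    for (R_xlen_t j = i + 1; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}

// Marching-tetrahedra iso-surface of a scalar field (linear interpolation
// along cut edges), Kuhn 6-fold cube decomposition; returns total triangle
// area (mm^2) and the enclosed mesh volume (mm^3) via the divergence theorem
// with outward orientation. Voxels outside the grid take value 0.
// [[Rcpp::export]]
List mesh_area_volume_cpp(NumericVector field, IntegerVector dim,
                          NumericVector spacing, double level) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // Kuhn tetrahedra: paths 0 -> e_i -> e_i+e_j -> (1,1,1); corner bit code x=1,y=2,z=4
  static const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7}, {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
  };
  double area = 0.0, vol = 0.0;
  double P[8][3], V8[8]; bool F[8];
  // interpolated cut point on edge a-b, written into out[3]
  auto cut = [&](int a, int b, double out[3]) {
    double t = (level - V8[a]) / (V8[b] - V8[a]);
    if (t < 0) t = 0; else if (t > 1) t = 1;
    for (int d = 0; d < 3; ++d) out[d] = P[a][d] + t * (P[b][d] - P[a][d]);
  };
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        bool any_in = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + (c & 1), cy = y + ((c >> 1) & 1), cz = z + ((c >> 2) & 1);
          double v = (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz) ?
                     field[idx3(cx, cy, cz, nx, ny)] : 0.0;
          V8[c] = v;
          F[c] = v > level; if (F[c]) any_in = true;
          P[c][0] = cx * sx; P[c][1] = cy * sy; P[c][2] = cz * sz;
        }
        if (!any_in) continue;
        bool all_in = F[0] && F[1] && F[2] && F[3] && F[4] && F[5] && F[6] && F[7];
        if (all_in) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int nin = F[T[0]] + F[T[1]] + F[T[2]] + F[T[3]];
          if (nin == 0 || nin == 4) continue;
          int in_idx[4], out_idx[4], ni = 0, noo = 0;
          for (int c = 0; c < 4; ++c) { if (F[T[c]]) in_idx[ni++] = T[c]; else out_idx[noo++] = T[c]; }
          // inside reference point (centroid of inside corners)
          double ref[3] = {0, 0, 0};
          for (int c = 0; c < ni; ++c)
            for (int d = 0; d < 3; ++d) ref[d] += P[in_idx[c]][d] / ni;
          double tri[2][3][3]; int ntri = 0;
          if (nin == 1 || nin == 3) {
            int a = (nin == 1) ? in_idx[0] : out_idx[0];
            int others[3]; int m = 0;
            for (int c = 0; c < 4; ++c) if (T[c] != a) others[m++] = T[c];
            for (int v = 0; v < 3; ++v) cut(a, others[v], tri[0][v]);
            ntri = 1;
          } else { // 2-2: cut points on edges in0-out0, in0-out1, in1-out1, in1-out0
            double q[4][3];
            int e[4][2] = {{in_idx[0], out_idx[0]}, {in_idx[0], out_idx[1]},
                           {in_idx[1], out_idx[1]}, {in_idx[1], out_idx[0]}};
            for (int v = 0; v < 4; ++v) cut(e[v][0], e[v][1], q[v]);
            for (int d = 0; d < 3; ++d) {
              tri[0][0][d] = q[0][d]; tri[0][1][d] = q[1][d]; tri[0][2][d] = q[2][d];
              tri[1][0][d] = q[0][d]; tri[1][1][d] = q[2][d]; tri[1][2][d] = q[3][d];
            }
            ntri = 2;
          }
          for (int m = 0; m < ntri; ++m) {
            double *a = tri[m][0], *b = tri[m][1], *c = tri[m][2];
            double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
            double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
            double nrm[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                             u[0] * v[1] - u[1] * v[0]};
            double cen[3] = {(a[0] + b[0] + c[0]) / 3 - ref[0],
                             (a[1] + b[1] + c[1]) / 3 - ref[1],
                             (a[2] + b[2] + c[2]) / 3 - ref[2]};
            double dot = nrm[0] * cen[0] + nrm[1] * cen[1] + nrm[2] * cen[2];
            if (dot < 0) { // flip to outward orientation
              double tmp;
              for (int d = 0; d < 3; ++d) { tmp = b[d]; b[d] = c[d]; c[d] = tmp; }
              nrm[0] = -nrm[0]; nrm[1] = -nrm[1]; nrm[2] = -nrm[2];
            }
            double nlen = std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] + nrm[2] * nrm[2]);
            area += 0.5 * nlen;
            // signed volume contribution, outward normals
            vol += (a[0] * (b[1] * c[2] - b[2] * c[1]) -
                    a[1] * (b[0] * c[2] - b[2] * c[0]) +
                    a[2] * (b[0] * c[1] - b[1] * c[0])) / 6.0;
          }
        }
      }
  return List::create(_["area"] = area, _["volume"] = std::fabs(vol));
}
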