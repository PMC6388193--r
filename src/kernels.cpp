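// Core numerical kernels: voxelization, iso-surfacing, distance transforms,
// local thickness, minimal-cost paths, image filters, RBF evaluation.
// Array layout follows R: column-major, index = i + nx*(j + ny*k).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static inline double sq(double x) { return x * x; }

static double point_tri_dist2(const double* p, const double* a,
                              const double* b, const double* c);

// ---------------------------------------------------------------------------
// Mesh voxelization: parity fill with rays along the x axis.
// Nodes are at origin + index*spacing (0-based index). Triangles are binned
// by their (y,z) bounding rectangle so each ray only tests nearby triangles.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_voxelize_mesh(NumericMatrix V, IntegerMatrix F,
                                NumericVector origin, NumericVector spacing,
                                IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nf = F.nrow();
  LogicalVector out((R_xlen_t)nx * ny * nz);
  if (nf == 0) return out;

  // small deterministic offset keeps rays off triangle edges/vertices
  const double ey = 0.3183e-3 * spacing[1];
  const double ez = 0.2718e-3 * spacing[2];

  // bin triangles into (j,k) ray cells
  std::vector<std::vector<int>> bins((size_t)ny * nz);
  for (int t = 0; t < nf; ++t) {
    double ymin = 1e300, ymax = -1e300, zmin = 1e300, zmax = -1e300;
    for (int c = 0; c < 3; ++c) {
      int v = F(t, c);
      ymin = std::min(ymin, V(v, 1)); ymax = std::max(ymax, V(v, 1));
      zmin = std::min(zmin, V(v, 2)); zmax = std::max(zmax, V(v, 2));
    }
    int j0 = (int)std::ceil((ymin - ey - origin[1]) / spacing[1]);
    int j1 = (int)std::floor((ymax - ey - origin[1]) / spacing[1]);
    int k0 = (int)std::ceil((zmin - ez - origin[2]) / spacing[2]);
    int k1 = (int)std::floor((zmax - ez - origin[2]) / spacing[2]);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        bins[(size_t)j + (size_t)ny * k].push_back(t);
  }

  std::vector<double> xs;
  for (int k = 0; k < nz; ++k) {
    const double rz = origin[2] + k * spacing[2] + ez;
    for (int j = 0; j < ny; ++j) {
      const double ry = origin[1] + j * spacing[1] + ey;
      const std::vector<int>& tri = bins[(size_t)j + (size_t)ny * k];
      if (tri.empty()) continue;
      xs.clear();
      for (int t : tri) {
        const int a = F(t, 0), b = F(t, 1), c = F(t, 2);
        // 2D point-in-triangle in the (y,z) plane, then solve for x
        const double y0 = V(a, 1) - ry, z0 = V(a, 2) - rz;
        const double y1 = V(b, 1) - ry, z1 = V(b, 2) - rz;
        const double y2 = V(c, 1) - ry, z2 = V(c, 2) - rz;
        const double d0 = y0 * z1 - y1 * z0;
        const double d1 = y1 * z2 - y2 * z1;
        const double d2 = y2 * z0 - y0 * z2;
        const bool pos = (d0 > 0) && (d1 > 0) && (d2 > 0);
        const bool neg = (d0 < 0) && (d1 < 0) && (d2 < 0);
        if (!pos && !neg) continue;
        const double area = d0 + d1 + d2;
        if (area == 0.0) continue;
        // barycentric: a weighted by d1, b by d2, c by d0
        const double x = (d1 * V(a, 0) + d2 * V(b, 0) + d0 * V(c, 0)) / area;
        xs.push_back(x);
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      // parity fill along the row of voxel nodes
      size_t m = xs.size();
      for (size_t s = 0; s + 1 < m; s += 2) {
        int i0 = (int)std::ceil((xs[s] - origin[0]) / spacing[0]);
        int i1 = (int)std::floor((xs[s + 1] - origin[0]) / spacing[0]);
        i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
        for (int i = i0; i <= i1; ++i)
          out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra over a scalar grid (Freudenthal 6-tet decomposition).
// Extracts the boundary of {field < iso} when inside_below, else {field > iso}.
// Vertices on shared cell edges are welded, so closed level sets give
// watertight meshes with outward-oriented triangles.
// ---------------------------------------------------------------------------

struct MTState {
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  std::unordered_map<uint64_t, int> edge_vertex;
};

static int mt_edge_vertex(MTState& st, int64_t g0, int64_t g1,
                          double t,
                          double x0, double y0, double z0,
                          double x1, double y1, double z1) {
  uint64_t lo = (uint64_t)std::min(g0, g1), hi = (uint64_t)std::max(g0, g1);
  if (lo == (uint64_t)g1) t = 1.0 - t;  // parametrize from the smaller id
  uint64_t key = lo * 2654435761ULL ^ (hi << 1);
  // resolve rare hash collisions by storing the full pair alongside
  // (use a composite key instead: lo in high bits is safe for < 2^31 nodes)
  key = (lo << 32) | (hi & 0xffffffffULL);
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double px, py, pz;
  if (lo == (uint64_t)g0) {
    px = x0 + t * (x1 - x0); py = y0 + t * (y1 - y0); pz = z0 + t * (z1 - z0);
  } else {
    px = x1 + t * (x0 - x1); py = y1 + t * (y0 - y1); pz = z1 + t * (z0 - z1);
  }
  int id = (int)st.vx.size();
  st.vx.push_back(px); st.vy.push_back(py); st.vz.push_back(pz);
  st.edge_vertex[key] = id;
  return id;
}

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dims,
                        NumericVector origin, NumericVector spacing,
                        double iso, bool inside_below) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  MTState st;
  // 6 tetrahedra around the 0-7 diagonal; cube vertex bits: x=1, y=2, z=4
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  double cx[8], cy[8], cz[8], cf[8];
  int64_t cg[8];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        for (int v = 0; v < 8; ++v) {
          int ii = i + (v & 1), jj = j + ((v >> 1) & 1), kk = k + ((v >> 2) & 1);
          cx[v] = origin[0] + ii * spacing[0];
          cy[v] = origin[1] + jj * spacing[1];
          cz[v] = origin[2] + kk * spacing[2];
          cg[v] = (int64_t)ii + (int64_t)nx * (jj + (int64_t)ny * kk);
          double f = field[cg[v]];
          cf[v] = inside_below ? (iso - f) : (f - iso);  // inside > 0
        }
        // quick reject
        bool any_in = false, any_out = false;
        for (int v = 0; v < 8; ++v) (cf[v] > 0 ? any_in : any_out) = true;
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in_idx[4], out_idx[4], nin = 0, nout = 0;
          for (int v = 0; v < 4; ++v)
            (cf[vi[v]] > 0 ? in_idx[nin++] : out_idx[nout++]) = vi[v];
          if (nin == 0 || nin == 4) continue;

          // inside centroid for orientation
          double pix = 0, piy = 0, piz = 0;
          for (int v = 0; v < nin; ++v) {
            pix += cx[in_idx[v]]; piy += cy[in_idx[v]]; piz += cz[in_idx[v]];
          }
          pix /= nin; piy /= nin; piz /= nin;

          auto cut = [&](int a, int b) {
            double fa_ = cf[a], fb_ = cf[b];
            double tt = fa_ / (fa_ - fb_);
            return mt_edge_vertex(st, cg[a], cg[b], tt,
                                  cx[a], cy[a], cz[a], cx[b], cy[b], cz[b]);
          };
          auto emit = [&](int a, int b, int c) {
            double ax = st.vx[a], ay = st.vy[a], az = st.vz[a];
            double nxv = (st.vy[b] - ay) * (st.vz[c] - az) -
                         (st.vz[b] - az) * (st.vy[c] - ay);
            double nyv = (st.vz[b] - az) * (st.vx[c] - ax) -
                         (st.vx[b] - ax) * (st.vz[c] - az);
            double nzv = (st.vx[b] - ax) * (st.vy[c] - ay) -
                         (st.vy[b] - ay) * (st.vx[c] - ax);
            double gx = (ax + st.vx[b] + st.vx[c]) / 3.0 - pix;
            double gy = (ay + st.vy[b] + st.vy[c]) / 3.0 - piy;
            double gz = (az + st.vz[b] + st.vz[c]) / 3.0 - piz;
            if (nxv * gx + nyv * gy + nzv * gz < 0) std::swap(b, c);
            st.fa.push_back(a); st.fb.push_back(b); st.fc.push_back(c);
          };

          if (nin == 1) {
            int a = in_idx[0];
            emit(cut(a, out_idx[0]), cut(a, out_idx[1]), cut(a, out_idx[2]));
          } else if (nin == 3) {
            int o = out_idx[0];
            emit(cut(in_idx[0], o), cut(in_idx[1], o), cut(in_idx[2], o));
          } else {  // 2 in, 2 out -> quad
            int a = in_idx[0], b = in_idx[1], p = out_idx[0], q = out_idx[1];
            int v0 = cut(a, p), v1 = cut(a, q), v2 = cut(b, q), v3 = cut(b, p);
            emit(v0, v1, v2);
            emit(v0, v2, v3);
          }
        }
      }

  int nv = (int)st.vx.size(), nf = (int)st.fa.size();
  NumericMatrix Vm(nv, 3);
  for (int v = 0; v < nv; ++v) {
    Vm(v, 0) = st.vx[v]; Vm(v, 1) = st.vy[v]; Vm(v, 2) = st.vz[v];
  }
  IntegerMatrix Fm(nf, 3);
  for (int f = 0; f < nf; ++f) {
    Fm(f, 0) = st.fa[f] + 1; Fm(f, 1) = st.fb[f] + 1; Fm(f, 2) = st.fc[f] + 1;
  }
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// anisotropic spacing. Distance from every voxel to the nearest seed voxel.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  const double s2 = s * s;
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  int k = 0;
  v[0] = q0;
  z[0] = -INF; z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;  // +inf parabola never forms the envelope
    double sfq = f[q] + s2 * (double)q * q;
    double sx;
    while (true) {
      sx = (sfq - (f[v[k]] + s2 * (double)v[k] * v[k])) /
           (2.0 * s2 * (q - v[k]));
      if (sx > z[k]) break;
      --k;  // z[0] = -inf guarantees k >= 0 here
    }
    ++k; v[k] = q; z[k] = sx; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = s * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector seed, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  for (R_xlen_t t = 0; t < n; ++t) D[t] = seed[t] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      bool all_inf = true;
      for (int i = 0; i < nx; ++i) { f[i] = D[base + i]; if (f[i] < INF) all_inf = false; }
      if (all_inf) continue;
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) D[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)nx * ny * (R_xlen_t)k;
      bool all_inf = true;
      for (int j = 0; j < ny; ++j) { f[j] = D[base + (R_xlen_t)nx * j]; if (f[j] < INF) all_inf = false; }
      if (all_inf) continue;
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)nx * j] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)nx * j;
      bool all_inf = true;
      for (int k = 0; k < nz; ++k) { f[k] = D[base + (R_xlen_t)nx * ny * k]; if (f[k] < INF) all_inf = false; }
      if (all_inf) continue;
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) D[base + (R_xlen_t)nx * ny * k] = d[k];
    }
  return D;
}

// ---------------------------------------------------------------------------
// Local thickness by inscribed-sphere painting: thickness(v) = diameter of
// the largest ball fully inside the mask that contains v. Radii in voxel
// units (isotropic spacing assumed by the caller).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector rvox, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector th(n);
  std::vector<R_xlen_t> order;
  order.reserve(1024);
  for (R_xlen_t t = 0; t < n; ++t) if (rvox[t] > 0) order.push_back(t);
  std::sort(order.begin(), order.end(),
            [&](R_xlen_t a, R_xlen_t b) { return rvox[a] > rvox[b]; });
  for (R_xlen_t idx : order) {
    double r = rvox[idx];
    double dia = 2.0 * r;
    if (th[idx] >= dia) continue;  // already covered by a larger sphere
    int i = (int)(idx % nx), j = (int)((idx / nx) % ny), k = (int)(idx / ((R_xlen_t)nx * ny));
    int ir = (int)std::floor(r);
    double r2 = r * r;
    for (int dk = -ir; dk <= ir; ++dk) {
      int kk = k + dk; if (kk < 0 || kk >= nz) continue;
      for (int dj = -ir; dj <= ir; ++dj) {
        int jj = j + dj; if (jj < 0 || jj >= ny) continue;
        double d2 = (double)dk * dk + (double)dj * dj;
        if (d2 > r2) continue;
        int rim = (int)std::floor(std::sqrt(r2 - d2));
        int i0 = std::max(i - rim, 0), i1 = std::min(i + rim, nx - 1);
        R_xlen_t base = (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        for (int ii = i0; ii <= i1; ++ii) {
          R_xlen_t q = base + ii;
          if (th[q] < dia && rvox[q] > 0) th[q] = dia;
        }
      }
    }
  }
  return th;
}

// ---------------------------------------------------------------------------
// F* minimal-cost path: iterative raster-scan dynamic programming over the
// 8-connected pixel graph. Step cost = mean of the two pixel costs times
// the step length (1 axial, sqrt(2) diagonal), so path cost is invariant
// under endpoint reversal. Sweeps alternate forward/backward
// until no label improves, which yields Dijkstra-equivalent costs.
// Matrix is nr x nc, column-major; start/end are 0-based (row, col).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_fstar_path(NumericMatrix cost, IntegerVector start, IntegerVector end) {
  const int nr = cost.nrow(), nc = cost.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  const double SQ2 = std::sqrt(2.0);
  std::vector<double> g((size_t)nr * nc, INF);
  std::vector<int> pred((size_t)nr * nc, -1);
  auto id = [&](int r, int c) { return (size_t)r + (size_t)nr * c; };
  g[id(start[0], start[1])] = 0.0;

  // fixed neighbour enumeration order (deterministic tie-break)
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double dl[8] = {SQ2, 1, SQ2, 1, 1, SQ2, 1, SQ2};

  bool changed = true;
  int iter = 0, max_iter = 4 * (nr + nc) + 16;
  while (changed && iter++ < max_iter) {
    changed = false;
    // forward sweep
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double best = g[id(r, c)];
        int bp = pred[id(r, c)];
        for (int m = 0; m < 8; ++m) {
          int rr = r - dr[m], cc = c - dc[m];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          double cand = g[id(rr, cc)] + 0.5 * (cost(r, c) + cost(rr, cc)) * dl[m];
          if (cand < best) { best = cand; bp = (int)id(rr, cc); }
        }
        if (best < g[id(r, c)]) { g[id(r, c)] = best; pred[id(r, c)] = bp; changed = true; }
      }
    // backward sweep
    for (int c = nc - 1; c >= 0; --c)
      for (int r = nr - 1; r >= 0; --r) {
        double best = g[id(r, c)];
        int bp = pred[id(r, c)];
        for (int m = 0; m < 8; ++m) {
          int rr = r - dr[m], cc = c - dc[m];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          double cand = g[id(rr, cc)] + 0.5 * (cost(r, c) + cost(rr, cc)) * dl[m];
          if (cand < best) { best = cand; bp = (int)id(rr, cc); }
        }
        if (best < g[id(r, c)]) { g[id(r, c)] = best; pred[id(r, c)] = bp; changed = true; }
      }
  }

  // backtrack
  std::vector<int> rev;
  int cur = (int)id(end[0], end[1]);
  while (cur >= 0) { rev.push_back(cur); cur = pred[cur]; }
  std::reverse(rev.begin(), rev.end());
  IntegerMatrix path((int)rev.size(), 2);
  for (size_t t = 0; t < rev.size(); ++t) {
    path((int)t, 0) = rev[t] % nr;
    path((int)t, 1) = rev[t] / nr;
  }
  return List::create(_["path"] = path, _["cost"] = g[id(end[0], end[1])]);
}

// ---------------------------------------------------------------------------
// 3D median filter, cubic (2r+1)^3 neighbourhood, nearest (replicate) padding.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector vol, IntegerVector dims, int radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> buf;
  const int side = 2 * radius + 1;
  buf.reserve((size_t)side * side * side);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        buf.clear();
        for (int dk = -radius; dk <= radius; ++dk) {
          int kk = std::min(std::max(k + dk, 0), nz - 1);
          for (int dj = -radius; dj <= radius; ++dj) {
            int jj = std::min(std::max(j + dj, 0), ny - 1);
            for (int di = -radius; di <= radius; ++di) {
              int ii = std::min(std::max(i + di, 0), nx - 1);
              buf.push_back(vol[(R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)]);
            }
          }
        }
        size_t mid = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        double med = buf[mid];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
          med = 0.5 * (med + buf[mid - 1]);
        }
        out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = med;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, replicate padding; sigma per axis in voxel units.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3(NumericVector vol, IntegerVector dims,
                                 NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int half = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * half + 1);
    double sum = 0;
    for (int t = -half; t <= half; ++t) { ker[t + half] = std::exp(-0.5 * sq(t / s)); sum += ker[t + half]; }
    for (double& kv : ker) kv /= sum;
    const int len = nd[ax];
    const R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    R_xlen_t nlines = n / len;
    const int oa1 = (ax == 0) ? 1 : 0;          // other axes
    const int oa2 = (ax == 2) ? 1 : 2;
    const R_xlen_t s1 = stride[oa1], s2 = stride[oa2];
    const int n1 = nd[oa1], n2 = nd[oa2];
    (void)nlines;
    for (int q2 = 0; q2 < n2; ++q2)
      for (int q1 = 0; q1 < n1; ++q1) {
        R_xlen_t base = s1 * q1 + s2 * q2;
        for (int p = 0; p < len; ++p) {
          double acc = 0;
          for (int t = -half; t <= half; ++t) {
            int pp = std::min(std::max(p + t, 0), len - 1);
            acc += ker[t + half] * a[base + st * pp];
          }
          b[base + st * p] = acc;
        }
      }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// ---------------------------------------------------------------------------
// Triharmonic RBF evaluation: s(x) = sum_i w_i |x - c_i|^3 + p0 + p . x
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_rbf_eval(NumericMatrix centers, NumericVector weights,
                           NumericVector poly, NumericMatrix pts) {
  const int nc = centers.nrow(), np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    double acc = poly[0] + poly[1] * x + poly[2] * y + poly[3] * z;
    for (int c = 0; c < nc; ++c) {
      double r2 = sq(x - centers(c, 0)) + sq(y - centers(c, 1)) + sq(z - centers(c, 2));
      double r = std::sqrt(r2);
      acc += weights[c] * r2 * r;
    }
    out[p] = acc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Ray-mesh intersection utilities: per-point inward ray thickness and
// point-to-surface distance (brute force over faces).
// ---------------------------------------------------------------------------

static bool ray_tri(const double* o, const double* d,
                    const double* a, const double* b, const double* c,
                    double& t) {
  const double EPS = 1e-12;
  double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double p[3] = {d[1] * e2[2] - d[2] * e2[1], d[2] * e2[0] - d[0] * e2[2],
                 d[0] * e2[1] - d[1] * e2[0]};
  double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
  if (std::fabs(det) < EPS) return false;
  double inv = 1.0 / det;
  double tv[3] = {o[0] - a[0], o[1] - a[1], o[2] - a[2]};
  double u = (tv[0] * p[0] + tv[1] * p[1] + tv[2] * p[2]) * inv;
  if (u < -1e-9 || u > 1 + 1e-9) return false;
  double q[3] = {tv[1] * e1[2] - tv[2] * e1[1], tv[2] * e1[0] - tv[0] * e1[2],
                 tv[0] * e1[1] - tv[1] * e1[0]};
  double v = (d[0] * q[0] + d[1] * q[1] + d[2] * q[2]) * inv;
  if (v < -1e-9 || u + v > 1 + 1e-9) return false;
  t = (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]) * inv;
  return t > 0;
}

// Grid-accelerated: triangles binned by bounding box; each ray walks cells
// with a 3D-DDA and stops once the best hit precedes the next cell.
// [[Rcpp::export]]
NumericVector cpp_ray_thickness(NumericMatrix V, IntegerMatrix F,
                                NumericMatrix origins, NumericMatrix dirs,
                                double eps) {
  const int np = origins.nrow(), nf = F.nrow();
  NumericVector out(np, NA_REAL);
  if (nf == 0) return out;
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int v = 0; v < V.nrow(); ++v)
    for (int c = 0; c < 3; ++c) {
      lo[c] = std::min(lo[c], V(v, c)); hi[c] = std::max(hi[c], V(v, c));
    }
  double ext = 0;
  for (int c = 0; c < 3; ++c) ext = std::max(ext, hi[c] - lo[c]);
  // ~32 cells along the largest extent keeps bins small
  double cell = std::max(ext / 32.0, 1e-6);
  int nc[3];
  for (int c = 0; c < 3; ++c) {
    lo[c] -= 0.5 * cell; hi[c] += 0.5 * cell;
    nc[c] = std::max(1, (int)std::ceil((hi[c] - lo[c]) / cell));
  }
  auto cidx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nc[0] * (j + (size_t)nc[1] * k);
  };
  std::vector<std::vector<int>> bins((size_t)nc[0] * nc[1] * nc[2]);
  for (int f = 0; f < nf; ++f) {
    double tlo[3] = {1e300, 1e300, 1e300}, thi[3] = {-1e300, -1e300, -1e300};
    for (int c = 0; c < 3; ++c)
      for (int vv = 0; vv < 3; ++vv) {
        double x = V(F(f, vv) - 1, c);
        tlo[c] = std::min(tlo[c], x); thi[c] = std::max(thi[c], x);
      }
    int i0[3], i1[3];
    for (int c = 0; c < 3; ++c) {
      i0[c] = std::max(0, (int)((tlo[c] - lo[c]) / cell));
      i1[c] = std::min(nc[c] - 1, (int)((thi[c] - lo[c]) / cell));
    }
    for (int k = i0[2]; k <= i1[2]; ++k)
      for (int j = i0[1]; j <= i1[1]; ++j)
        for (int i = i0[0]; i <= i1[0]; ++i)
          bins[cidx(i, j, k)].push_back(f);
  }

  double va[3], vb[3], vc3[3], o[3], d[3];
  for (int p = 0; p < np; ++p) {
    double dl = 0;
    for (int c = 0; c < 3; ++c) { o[c] = origins(p, c); d[c] = dirs(p, c); dl += d[c] * d[c]; }
    dl = std::sqrt(dl);
    if (dl == 0) continue;
    for (int c = 0; c < 3; ++c) d[c] /= dl;
    double best = std::numeric_limits<double>::infinity();
    // DDA setup
    int ci[3], step[3];
    double tmaxc[3], tdelta[3];
    bool outside = false;
    for (int c = 0; c < 3; ++c) {
      ci[c] = (int)((o[c] - lo[c]) / cell);
      if (ci[c] < 0 || ci[c] >= nc[c]) outside = true;
      step[c] = d[c] > 0 ? 1 : (d[c] < 0 ? -1 : 0);
      if (d[c] != 0) {
        double edge = lo[c] + (ci[c] + (step[c] > 0 ? 1 : 0)) * cell;
        tmaxc[c] = (edge - o[c]) / d[c];
        tdelta[c] = cell / std::fabs(d[c]);
      } else {
        tmaxc[c] = std::numeric_limits<double>::infinity();
        tdelta[c] = std::numeric_limits<double>::infinity();
      }
    }
    if (outside) continue;  // thickness rays start on the mesh
    double tcell_exit = 0;
    while (true) {
      for (int f : bins[cidx(ci[0], ci[1], ci[2])]) {
        for (int c = 0; c < 3; ++c) {
          va[c] = V(F(f, 0) - 1, c); vb[c] = V(F(f, 1) - 1, c);
          vc3[c] = V(F(f, 2) - 1, c);
        }
        double t;
        if (ray_tri(o, d, va, vb, vc3, t) && t > eps && t < best) best = t;
      }
      tcell_exit = std::min(tmaxc[0], std::min(tmaxc[1], tmaxc[2]));
      if (best <= tcell_exit) break;
      int ax = (tmaxc[0] <= tmaxc[1] && tmaxc[0] <= tmaxc[2]) ? 0 :
               (tmaxc[1] <= tmaxc[2] ? 1 : 2);
      ci[ax] += step[ax];
      if (ci[ax] < 0 || ci[ax] >= nc[ax]) break;
      tmaxc[ax] += tdelta[ax];
    }
    if (std::isfinite(best)) out[p] = best;
  }
  return out;
}

static double point_tri_dist2(const double* p, const double* a,
                              const double* b, const double* c) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  auto dist2 = [&](double qx, double qy, double qz) {
    return sq(p[0] - qx) + sq(p[1] - qy) + sq(p[2] - qz);
  };
  if (d1 <= 0 && d2 <= 0) return dist2(a[0], a[1], a[2]);
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) return dist2(b[0], b[1], b[2]);
  double vc_ = d1 * d4 - d3 * d2;
  if (vc_ <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return dist2(a[0] + v * ab[0], a[1] + v * ab[1], a[2] + v * ab[2]);
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) return dist2(c[0], c[1], c[2]);
  double vb_ = d5 * d2 - d1 * d6;
  if (vb_ <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return dist2(a[0] + w * ac[0], a[1] + w * ac[1], a[2] + w * ac[2]);
  }
  double va_ = d3 * d6 - d5 * d4;
  if (va_ <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist2(b[0] + w * (c[0] - b[0]), b[1] + w * (c[1] - b[1]),
                 b[2] + w * (c[2] - b[2]));
  }
  double denom = 1.0 / (va_ + vb_ + vc_);
  double v = vb_ * denom, w = vc_ * denom;
  return dist2(a[0] + ab[0] * v + ac[0] * w, a[1] + ab[1] * v + ac[1] * w,
               a[2] + ab[2] * v + ac[2] * w);
}

// ---------------------------------------------------------------------------
// Grid-accelerated unsigned distance from many points to a triangle mesh.
// Triangles are binned into a uniform grid by bounding box; each query does
// an expanding ring search with a lower-bound cutoff.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_grid_point_mesh_dist(NumericMatrix pts, NumericMatrix V,
                                       IntegerMatrix F, double cell) {
  const int np = pts.nrow(), nf = F.nrow();
  NumericVector out(np);
  if (nf == 0) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int v = 0; v < V.nrow(); ++v)
    for (int c = 0; c < 3; ++c) {
      lo[c] = std::min(lo[c], V(v, c)); hi[c] = std::max(hi[c], V(v, c));
    }
  int nc[3];
  for (int c = 0; c < 3; ++c) {
    lo[c] -= 0.5 * cell; hi[c] += 0.5 * cell;
    nc[c] = std::max(1, (int)std::ceil((hi[c] - lo[c]) / cell));
  }
  auto cidx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nc[0] * (j + (size_t)nc[1] * k);
  };
  std::vector<std::vector<int>> bins((size_t)nc[0] * nc[1] * nc[2]);
  for (int f = 0; f < nf; ++f) {
    double tlo[3] = {1e300, 1e300, 1e300}, thi[3] = {-1e300, -1e300, -1e300};
    for (int c = 0; c < 3; ++c)
      for (int vv = 0; vv < 3; ++vv) {
        double x = V(F(f, vv) - 1, c);
        tlo[c] = std::min(tlo[c], x); thi[c] = std::max(thi[c], x);
      }
    int i0[3], i1[3];
    for (int c = 0; c < 3; ++c) {
      i0[c] = std::max(0, (int)((tlo[c] - lo[c]) / cell));
      i1[c] = std::min(nc[c] - 1, (int)((thi[c] - lo[c]) / cell));
    }
    for (int k = i0[2]; k <= i1[2]; ++k)
      for (int j = i0[1]; j <= i1[1]; ++j)
        for (int i = i0[0]; i <= i1[0]; ++i)
          bins[cidx(i, j, k)].push_back(f);
  }

  double p[3], a[3], b[3], c3[3];
  for (int q = 0; q < np; ++q) {
    for (int c = 0; c < 3; ++c) p[c] = pts(q, c);
    int ci[3];
    for (int c = 0; c < 3; ++c)
      ci[c] = std::min(nc[c] - 1, std::max(0, (int)((p[c] - lo[c]) / cell)));
    double best = std::numeric_limits<double>::infinity();
    int max_ring = std::max(nc[0], std::max(nc[1], nc[2]));
    for (int ring = 0; ring <= max_ring; ++ring) {
      // lower bound for cells in this ring
      if (ring > 0) {
        double lb = (ring - 1) * cell;
        if (lb * lb > best) break;
      }
      for (int k = ci[2] - ring; k <= ci[2] + ring; ++k) {
        if (k < 0 || k >= nc[2]) continue;
        for (int j = ci[1] - ring; j <= ci[1] + ring; ++j) {
          if (j < 0 || j >= nc[1]) continue;
          for (int i = ci[0] - ring; i <= ci[0] + ring; ++i) {
            if (i < 0 || i >= nc[0]) continue;
            if (std::max(std::abs(i - ci[0]),
                         std::max(std::abs(j - ci[1]), std::abs(k - ci[2]))) != ring)
              continue;  // shell only
            for (int f : bins[cidx(i, j, k)]) {
              for (int c = 0; c < 3; ++c) {
                a[c] = V(F(f, 0) - 1, c); b[c] = V(F(f, 1) - 1, c);
                c3[c] = V(F(f, 2) - 1, c);
              }
              double d2 = point_tri_dist2(p, a, b, c3);
              if (d2 < best) best = d2;
            }
          }
        }
      }
    }
    out[q] = std::sqrt(best);
  }
  return out;
}

static void closest_on_tri(const double* p, const double* a, const double* b,
                           const double* c, double* q) {
  // gradient-free: evaluate the closest point by clamped barycentric search
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int k = 0; k < 3; ++k) q[k] = a[k]; return; }
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int k = 0; k < 3; ++k) q[k] = b[k]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) q[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int k = 0; k < 3; ++k) q[k] = c[k]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) q[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) q[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) q[k] = a[k] + ab[k] * v + ac[k] * w;
}

// closest surface point for each query (same binning as the distance query)
// [[Rcpp::export]]
List cpp_grid_closest_point(NumericMatrix pts, NumericMatrix V,
                            IntegerMatrix F, double cell) {
  const int np = pts.nrow(), nf = F.nrow();
  NumericVector dist(np);
  NumericMatrix close(np, 3);
  if (nf == 0) stop("empty mesh");
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int v = 0; v < V.nrow(); ++v)
    for (int c = 0; c < 3; ++c) {
      lo[c] = std::min(lo[c], V(v, c)); hi[c] = std::max(hi[c], V(v, c));
    }
  int nc[3];
  for (int c = 0; c < 3; ++c) {
    lo[c] -= 0.5 * cell; hi[c] += 0.5 * cell;
    nc[c] = std::max(1, (int)std::ceil((hi[c] - lo[c]) / cell));
  }
  auto cidx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nc[0] * (j + (size_t)nc[1] * k);
  };
  std::vector<std::vector<int>> bins((size_t)nc[0] * nc[1] * nc[2]);
  for (int f = 0; f < nf; ++f) {
    double tlo[3] = {1e300, 1e300, 1e300}, thi[3] = {-1e300, -1e300, -1e300};
    for (int c = 0; c < 3; ++c)
      for (int vv = 0; vv < 3; ++vv) {
        double x = V(F(f, vv) - 1, c);
        tlo[c] = std::min(tlo[c], x); thi[c] = std::max(thi[c], x);
      }
    int i0[3], i1[3];
    for (int c = 0; c < 3; ++c) {
      i0[c] = std::max(0, (int)((tlo[c] - lo[c]) / cell));
      i1[c] = std::min(nc[c] - 1, (int)((thi[c] - lo[c]) / cell));
    }
    for (int k = i0[2]; k <= i1[2]; ++k)
      for (int j = i0[1]; j <= i1[1]; ++j)
        for (int i = i0[0]; i <= i1[0]; ++i)
          bins[cidx(i, j, k)].push_back(f);
  }
  double p[3], a[3], b[3], c3[3], q[3], qbest[3];
  for (int s = 0; s < np; ++s) {
    for (int k = 0; k < 3; ++k) p[k] = pts(s, k);
    int ci[3];
    for (int c = 0; c < 3; ++c)
      ci[c] = std::min(nc[c] - 1, std::max(0, (int)((p[c] - lo[c]) / cell)));
    double best = std::numeric_limits<double>::infinity();
    int max_ring = std::max(nc[0], std::max(nc[1], nc[2]));
    for (int ring = 0; ring <= max_ring; ++ring) {
      if (ring > 0) {
        double lb = (ring - 1) * cell;
        if (lb * lb > best) break;
      }
      for (int k = ci[2] - ring; k <= ci[2] + ring; ++k) {
        if (k < 0 || k >= nc[2]) continue;
        for (int j = ci[1] - ring; j <= ci[1] + ring; ++j) {
          if (j < 0 || j >= nc[1]) continue;
          for (int i = ci[0] - ring; i <= ci[0] + ring; ++i) {
            if (i < 0 || i >= nc[0]) continue;
            if (std::max(std::abs(i - ci[0]),
                         std::max(std::abs(j - ci[1]), std::abs(k - ci[2]))) != ring)
              continue;
            for (int f : bins[cidx(i, j, k)]) {
              for (int c = 0; c < 3; ++c) {
                a[c] = V(F(f, 0) - 1, c); b[c] = V(F(f, 1) - 1, c);
                c3[c] = V(F(f, 2) - 1, c);
              }
              closest_on_tri(p, a, b, c3, q);
              double d2 = sq(p[0] - q[0]) + sq(p[1] - q[1]) + sq(p[2] - q[2]);
              if (d2 < best) {
                best = d2;
                for (int c = 0; c < 3; ++c) qbest[c] = q[c];
              }
            }
          }
        }
      }
    }
    dist[s] = std::sqrt(best);
    for (int c = 0; c < 3; ++c) close(s, c) = qbest[c];
  }
  return List::create(_["dist"] = dist, _["points"] = close);
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a 3D mask (6-connectivity), BFS.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const R_xlen_t dn[6] = {1, -1, nx, -nx, (R_xlen_t)nx * ny, -(R_xlen_t)nx * ny};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t q = stack.back(); stack.pop_back();
      int i = (int)(q % nx), j = (int)((q / nx) % ny), k = (int)(q / ((R_xlen_t)nx * ny));
      for (int m = 0; m < 6; ++m) {
        int ii = i + (m == 0) - (m == 1);
        int jj = j + (m == 2) - (m == 3);
        int kk = k + (m == 4) - (m == 5);
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t t = q + dn[m];
        if (mask[t] && lab[t] == 0) { lab[t] = next; stack.push_back(t); }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix pts, NumericMatrix V,
                                  IntegerMatrix F) {
  const int np = pts.nrow(), nf = F.nrow();
  NumericVector out(np);
  double p[3], a[3], b[3], c[3];
  for (int q = 0; q < np; ++q) {
    for (int k = 0; k < 3; ++k) p[k] = pts(q, k);
    double best = std::numeric_limits<double>::infinity();
    for (int f = 0; f < nf; ++f) {
      for (int k = 0; k < 3; ++k) {
        a[k] = V(F(f, 0) - 1, k); b[k] = V(F(f, 1) - 1, k); c[k] = V(F(f, 2) - 1, k);
      }
      double d2 = point_tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}
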