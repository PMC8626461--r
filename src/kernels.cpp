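// Low-level voxel kernels: anisotropic EDT, connected components, capsule
// rasterisation, separable Gaussian blur, 3D local maxima, topological
// thinning, marching-tetrahedra isosurface area, trilinear sampling.
// Arrays are R column-major with dim (nx, ny, nz); voxel (i,j,k) sits at
// physical (i*sx, j*sy, k*sz) µm, 0-based.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double BIG = 1e30;

// ---------------------------------------------------------------------------
// 1D squared distance transform (Felzenszwalb & Huttenlocher), sample step w.
// f: input squared distances at line positions; d: output. Work in index
// coordinates, scale by w^2.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w, std::vector<int>& v, std::vector<double>& z) {
  double w2 = w * w;
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double fq = f[q] / w2;
    double s = ((fq + (double)q * q) -
                (f[v[k]] / w2 + (double)v[k] * v[k])) /
               (2.0 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = ((fq + (double)q * q) -
           (f[v[k]] / w2 + (double)v[k] * v[k])) /
          (2.0 * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < (double)q) k++;
    double dq = (double)(q - v[k]) * w;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; t++) out[t] = mask[t] ? 0.0 : BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, nx, spacing[0], v, z);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, ny, spacing[1], v, z);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t step = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; k++) f[k] = out[base + step * k];
      dt1d(f, d, nz, spacing[2], v, z);
      for (int k = 0; k < nz; k++) out[base + step * k] = d[k];
    }
  for (R_xlen_t t = 0; t < n; t++)
    out[t] = (out[t] >= BIG) ? R_PosInf : std::sqrt(out[t]);
  return out;
}

// ---------------------------------------------------------------------------
// Connected component labelling, 6- or 26-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> offs_di, offs_dj, offs_dk;
  for (int dk = -1; dk <= 1; dk++)
    for (int dj = -1; dj <= 1; dj++)
      for (int di = -1; di <= 1; di++) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int man = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && man != 1) continue;
        offs_di.push_back(di);
        offs_dj.push_back(dj);
        offs_dk.push_back(dk);
      }
  int nextlab = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    nextlab++;
    lab[s] = nextlab;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t t = 0; t < offs_di.size(); t++) {
        int ii = i + offs_di[t], jj = j + offs_dj[t], kk = k + offs_dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[q] && lab[q] == 0) {
          lab[q] = nextlab;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Paint capsules: union of spheres centred at pts (µm) with given radii.
// Ties between labels resolved by nearest centre. Updates label and bestd in
// place (bestd must be initialised to +Inf, label to 0).
// [[Rcpp::export]]
void cpp_paint_spheres(IntegerVector label, NumericVector bestd,
                       IntegerVector dims, NumericVector spacing,
                       NumericMatrix pts, NumericVector radius,
                       IntegerVector ptlab) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  int npts = pts.nrow();
  for (int p = 0; p < npts; p++) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double r = radius[p];
    double r2 = r * r;
    int i0 = std::max(0, (int)std::ceil((px - r) / sx));
    int i1 = std::min(nx - 1, (int)std::floor((px + r) / sx));
    int j0 = std::max(0, (int)std::ceil((py - r) / sy));
    int j1 = std::min(ny - 1, (int)std::floor((py + r) / sy));
    int k0 = std::max(0, (int)std::ceil((pz - r) / sz));
    int k1 = std::min(nz - 1, (int)std::floor((pz + r) / sz));
    for (int k = k0; k <= k1; k++) {
      double dz = k * sz - pz;
      for (int j = j0; j <= j1; j++) {
        double dy = j * sy - py;
        double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; i++) {
          double dx = i * sx - px;
          double d2 = dx * dx + dyz;
          if (d2 <= r2 && d2 < bestd[base + i]) {
            bestd[base + i] = d2;
            label[base + i] = ptlab[p];
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, sigma per axis in voxel units; kernel renormalised
// at the borders.
static void blur_axis(std::vector<double>& a, std::vector<double>& tmp, int n,
                      const std::vector<double>& kern) {
  int r = (int)kern.size() / 2;
  for (int i = 0; i < n; i++) {
    double acc = 0.0, wsum = 0.0;
    int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
    for (int q = lo; q <= hi; q++) {
      double w = kern[q - i + r];
      acc += w * a[q];
      wsum += w;
    }
    tmp[i] = acc / wsum;
  }
  for (int i = 0; i < n; i++) a[i] = tmp[i];
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; i++) k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector arr, IntegerVector dims,
                         NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(arr);
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax), tmp(nmax);

  if (sigma_vox[0] > 0) {
    std::vector<double> k = gauss_kernel(sigma_vox[0]);
    for (int kk = 0; kk < nz; kk++)
      for (int j = 0; j < ny; j++) {
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * kk);
        for (int i = 0; i < nx; i++) line[i] = out[base + i];
        blur_axis(line, tmp, nx, k);
        for (int i = 0; i < nx; i++) out[base + i] = line[i];
      }
  }
  if (sigma_vox[1] > 0) {
    std::vector<double> k = gauss_kernel(sigma_vox[1]);
    for (int kk = 0; kk < nz; kk++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t base = i + (R_xlen_t)nx * ny * kk;
        for (int j = 0; j < ny; j++) line[j] = out[base + (R_xlen_t)nx * j];
        blur_axis(line, tmp, ny, k);
        for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = line[j];
      }
  }
  if (sigma_vox[2] > 0) {
    std::vector<double> k = gauss_kernel(sigma_vox[2]);
    R_xlen_t step = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t base = i + (R_xlen_t)nx * j;
        for (int kk = 0; kk < nz; kk++) line[kk] = out[base + step * kk];
        blur_axis(line, tmp, nz, k);
        for (int kk = 0; kk < nz; kk++) out[base + step * kk] = line[kk];
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 26-neighbourhood local maxima above threshold. Plateau ties broken by
// linear index (lowest index wins) so detection is deterministic.
// Returns n x 3 matrix of 0-based (i, j, k).
// [[Rcpp::export]]
IntegerMatrix cpp_local_maxima(NumericVector arr, IntegerVector dims,
                               double threshold) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> out;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        double v = arr[idx];
        if (!(v > threshold)) continue;
        bool ismax = true;
        for (int dk = -1; dk <= 1 && ismax; dk++)
          for (int dj = -1; dj <= 1 && ismax; dj++)
            for (int di = -1; di <= 1 && ismax; di++) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                  kk >= nz)
                continue;
              R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
              double nv = arr[q];
              if (nv > v || (nv == v && q < idx)) ismax = false;
            }
        if (ismax) {
          out.push_back(i);
          out.push_back(j);
          out.push_back(k);
        }
      }
  int nmax = (int)(out.size() / 3);
  IntegerMatrix res(nmax, 3);
  for (int t = 0; t < nmax; t++) {
    res(t, 0) = out[3 * t];
    res(t, 1) = out[3 * t + 1];
    res(t, 2) = out[3 * t + 2];
  }
  return res;
}

// ---------------------------------------------------------------------------
// Simple-point test for (26, 6) digital topology.
// obj holds the 3x3x3 neighbourhood occupancy (object=true), centre at (1,1,1).
static inline int nb_idx(int i, int j, int k) { return i + 3 * (j + 3 * k); }

static bool is_simple(const bool obj[27]) {
  // Condition A: object voxels of N26* form exactly one 26-connected component.
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; s++) {
    if (s == 13 || !obj[s] || seen[s]) continue;
    comps++;
    if (comps > 1) return false;
    // BFS with 26-adjacency inside the cube, skipping the centre
    std::vector<int> st;
    st.push_back(s);
    seen[s] = true;
    while (!st.empty()) {
      int cur = st.back();
      st.pop_back();
      int ci = cur % 3, cj = (cur / 3) % 3, ck = cur / 9;
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii > 2 || jj > 2 || kk > 2)
              continue;
            int q = nb_idx(ii, jj, kk);
            if (q == 13 || q == cur || seen[q] || !obj[q]) continue;
            seen[q] = true;
            st.push_back(q);
          }
    }
  }
  if (comps != 1) return false;

  // Condition B: background voxels of N18 that are 6-adjacent to the centre
  // form exactly one 6-connected component within N18.
  // N18: cube positions with Chebyshev distance 1 from centre along at most
  // two axes (i.e. exclude the 8 corners).
  bool inN18[27];
  for (int s = 0; s < 27; s++) {
    int ci = s % 3 - 1, cj = (s / 3) % 3 - 1, ck = s / 9 - 1;
    int man = std::abs(ci) + std::abs(cj) + std::abs(ck);
    inN18[s] = (s != 13) && (man <= 2) && (man >= 1);
  }
  static const int face[6] = {nb_idx(0, 1, 1), nb_idx(2, 1, 1), nb_idx(1, 0, 1),
                              nb_idx(1, 2, 1), nb_idx(1, 1, 0), nb_idx(1, 1, 2)};
  bool seenb[27] = {false};
  int bcomps = 0;
  for (int fi = 0; fi < 6; fi++) {
    int s = face[fi];
    if (obj[s] || seenb[s]) continue;
    bcomps++;
    if (bcomps > 1) return false;
    std::vector<int> st;
    st.push_back(s);
    seenb[s] = true;
    while (!st.empty()) {
      int cur = st.back();
      st.pop_back();
      int ci = cur % 3, cj = (cur / 3) % 3, ck = cur / 9;
      const int d6[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                            {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
      for (int t = 0; t < 6; t++) {
        int ii = ci + d6[t][0], jj = cj + d6[t][1], kk = ck + d6[t][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii > 2 || jj > 2 || kk > 2) continue;
        int q = nb_idx(ii, jj, kk);
        if (!inN18[q] || obj[q] || seenb[q]) continue;
        seenb[q] = true;
        st.push_back(q);
      }
    }
  }
  return bcomps == 1;
}

// Curve thinning: remove simple, non-endpoint voxels in increasing order of
// interior depth (priority), preserving 26-connectivity of the object and
// 6-connectivity of the background. Endpoints (<= 1 object neighbour) kept.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dims,
                              NumericVector priority) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> obj(n);
  for (R_xlen_t t = 0; t < n; t++) obj[t] = mask[t] ? 1 : 0;

  typedef std::pair<double, R_xlen_t> PD;
  std::priority_queue<PD, std::vector<PD>, std::greater<PD> > pq;

  for (R_xlen_t t = 0; t < n; t++)
    if (obj[t]) pq.push(PD(priority[t], t));

  bool nb[27];
  while (!pq.empty()) {
    R_xlen_t idx = pq.top().second;
    pq.pop();
    if (!obj[idx]) continue;
    int i = (int)(idx % nx);
    int j = (int)((idx / nx) % ny);
    int k = (int)(idx / ((R_xlen_t)nx * ny));
    int ncount = 0;
    for (int dk = -1; dk <= 1; dk++)
      for (int dj = -1; dj <= 1; dj++)
        for (int di = -1; di <= 1; di++) {
          int ii = i + di, jj = j + dj, kk = k + dk;
          bool inb = (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny &&
                      kk < nz);
          bool val = inb &&
                     obj[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          nb[nb_idx(di + 1, dj + 1, dk + 1)] = val;
          if (val && !(di == 0 && dj == 0 && dk == 0)) ncount++;
        }
    if (ncount <= 1) continue; // endpoint or isolated: keep
    if (!is_simple(nb)) continue;
    obj[idx] = 0;
    // neighbours may become removable; requeue them
    for (int dk = -1; dk <= 1; dk++)
      for (int dj = -1; dj <= 1; dj++)
        for (int di = -1; di <= 1; di++) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (obj[q]) pq.push(PD(priority[q], q));
        }
  }
  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; t++) out[t] = obj[t] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra: total isosurface area of `field` at level `iso`,
// physical coordinates. Field sampled at voxel centres.
static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector field, IntegerVector dims,
                           NumericVector spacing, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // cube corner offsets (unit cube bit order: x, y, z)
  static const int corner[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                                   {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  // six tetrahedra sharing the 0-6 diagonal
  static const int tets[6][4] = {{0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
                                 {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
  double area = 0.0;
  double val[8];
  double pos[8][3];
  for (int k = 0; k + 1 < nz; k++)
    for (int j = 0; j + 1 < ny; j++)
      for (int i = 0; i + 1 < nx; i++) {
        bool anyAbove = false, anyBelow = false;
        for (int c = 0; c < 8; c++) {
          int ii = i + corner[c][0], jj = j + corner[c][1], kk = k + corner[c][2];
          val[c] = field[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          pos[c][0] = ii * sx;
          pos[c][1] = jj * sy;
          pos[c][2] = kk * sz;
          if (val[c] >= iso) anyAbove = true; else anyBelow = true;
        }
        if (!anyAbove || !anyBelow) continue;
        for (int t = 0; t < 6; t++) {
          const int* tv = tets[t];
          int above[4], nab = 0, below[4], nbe = 0;
          for (int c = 0; c < 4; c++) {
            if (val[tv[c]] >= iso) above[nab++] = tv[c];
            else below[nbe++] = tv[c];
          }
          if (nab == 0 || nab == 4) continue;
          double p[4][3];
          int np = 0;
          // edge crossings between each (above, below) pair
          for (int a = 0; a < nab; a++)
            for (int b = 0; b < nbe; b++) {
              double va = val[above[a]], vb = val[below[b]];
              double tt = (iso - va) / (vb - va);
              for (int d = 0; d < 3; d++)
                p[np][d] = pos[above[a]][d] +
                           tt * (pos[below[b]][d] - pos[above[a]][d]);
              np++;
            }
          if (np == 3) {
            area += tri_area(p[0], p[1], p[2]);
          } else if (np == 4) {
            // order from pairs (a0b0, a0b1, a1b0, a1b1): quad is
            // p0-p1-p3-p2
            area += tri_area(p[0], p[1], p[3]);
            area += tri_area(p[0], p[3], p[2]);
          }
        }
      }
  return area;
}

// ---------------------------------------------------------------------------
// Trilinear interpolation of a field at physical points (µm). Points outside
// the grid are clamped to the boundary sample positions.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector field, IntegerVector dims,
                            NumericVector spacing, NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int npts = pts.nrow();
  NumericVector out(npts);
  for (int p = 0; p < npts; p++) {
    double gx = pts(p, 0) / spacing[0];
    double gy = pts(p, 1) / spacing[1];
    double gz = pts(p, 2) / spacing[2];
    gx = std::min(std::max(gx, 0.0), (double)(nx - 1));
    gy = std::min(std::max(gy, 0.0), (double)(ny - 1));
    gz = std::min(std::max(gz, 0.0), (double)(nz - 1));
    int i0 = std::min((int)std::floor(gx), nx - 2 >= 0 ? nx - 2 : 0);
    int j0 = std::min((int)std::floor(gy), ny - 2 >= 0 ? ny - 2 : 0);
    int k0 = std::min((int)std::floor(gz), nz - 2 >= 0 ? nz - 2 : 0);
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    double acc = 0.0;
    for (int dk = 0; dk <= 1; dk++)
      for (int dj = 0; dj <= 1; dj++)
        for (int di = 0; di <= 1; di++) {
          int ii = std::min(i0 + di, nx - 1);
          int jj = std::min(j0 + dj, ny - 1);
          int kk = std::min(k0 + dk, nz - 1);
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                     (dk ? fz : 1 - fz);
          acc += w * field[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
        }
    out[p] = acc;
  }
  return out;
}
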