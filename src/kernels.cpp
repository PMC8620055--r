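#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// All 3D arrays arrive as R arrays with dim (nz, ny, nx), column-major:
// linear index of (k, j, i) [0-based] is k + nz * (j + ny * i).

static inline R_xlen_t idx3(int k, int j, int i, int nz, int ny) {
  return (R_xlen_t)k + (R_xlen_t)nz * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)i);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Majority-vote (binary median) filter over a window^3 neighbourhood.
// Borders use edge replication via index clamping.
// [[Rcpp::export]]
IntegerVector median3d_cpp(IntegerVector mask, int nz, int ny, int nx,
                           int window) {
  if (window < 1 || window % 2 == 0)
    stop("window must be a positive odd integer");
  if (window > nz || window > ny || window > nx)
    stop("window larger than a stack dimension");
  const int h = window / 2;
  const int w3 = window * window * window;
  IntegerVector out(mask.size());
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      for (int k = 0; k < nz; ++k) {
        int cnt = 0;
        for (int di = -h; di <= h; ++di) {
          int ii = clampi(i + di, 0, nx - 1);
          for (int dj = -h; dj <= h; ++dj) {
            int jj = clampi(j + dj, 0, ny - 1);
            for (int dk = -h; dk <= h; ++dk) {
              int kk = clampi(k + dk, 0, nz - 1);
              cnt += mask[idx3(kk, jj, ii, nz, ny)];
            }
          }
        }
        out[idx3(k, j, i, nz, ny)] = (2 * cnt > w3) ? 1 : 0;
      }
    }
  }
  return out;
}

// Connected-component labelling (6 or 26 connectivity), flood fill.
// Returns labels 1..n; attribute "n" carries the component count.
// [[Rcpp::export]]
IntegerVector label3d_cpp(IntegerVector mask, int nz, int ny, int nx,
                          int connectivity) {
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  std::vector<int> dk, dj, di;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dk.push_back(a); dj.push_back(b); di.push_back(c);
      }
  const int noff = (int)dk.size();
  IntegerVector labels(mask.size(), 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        R_xlen_t p = idx3(k, j, i, nz, ny);
        if (mask[p] == 0 || labels[p] != 0) continue;
        ++next;
        labels[p] = next;
        stack.clear();
        stack.push_back(p);
        // decode (k,j,i) back from linear index while flooding
        while (!stack.empty()) {
          R_xlen_t q = stack.back(); stack.pop_back();
          int kk = (int)(q % nz);
          R_xlen_t rest = q / nz;
          int jj = (int)(rest % ny);
          int ii = (int)(rest / ny);
          for (int o = 0; o < noff; ++o) {
            int k2 = kk + dk[o], j2 = jj + dj[o], i2 = ii + di[o];
            if (k2 < 0 || k2 >= nz || j2 < 0 || j2 >= ny || i2 < 0 || i2 >= nx)
              continue;
            R_xlen_t p2 = idx3(k2, j2, i2, nz, ny);
            if (mask[p2] != 0 && labels[p2] == 0) {
              labels[p2] = next;
              stack.push_back(p2);
            }
          }
        }
      }
  labels.attr("n") = next;
  return labels;
}

// Separable Gaussian smoothing, zero boundary, kernel truncated at 3 sigma.
// sigma is in voxels, one value per axis (z, y, x); sigma <= 0 skips an axis.
// [[Rcpp::export]]
NumericVector gauss3d_cpp(NumericVector field, int nz, int ny, int nx,
                          NumericVector sigma) {
  if (sigma.size() != 3) stop("sigma must have length 3");
  NumericVector cur = clone(field);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + r];
    }
    for (double &v : ker) v /= sum;
    NumericVector nxt(cur.size(), 0.0);
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j)
        for (int k = 0; k < nz; ++k) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int kk = k, jj = j, ii = i;
            if (axis == 0) kk += t;
            else if (axis == 1) jj += t;
            else ii += t;
            if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx)
              continue; // zero boundary
            acc += ker[t + r] * cur[idx3(kk, jj, ii, nz, ny)];
          }
          nxt[idx3(k, j, i, nz, ny)] = acc;
        }
    cur = nxt;
  }
  return cur;
}

// Marching tetrahedra isosurface area. Each grid cell is split into six
// tetrahedra sharing the 0-6 cube diagonal so that faces of adjacent cells
// match and the mesh is watertight. Vertices are placed by linear
// interpolation at the iso level; physical spacing (dz, dy, dx) is applied
// before triangle areas are summed.
static const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};
// cube corner offsets in (z, y, x)
static const int CORN[8][3] = {
  {0, 0, 0}, {0, 0, 1}, {0, 1, 1}, {0, 1, 0},
  {1, 0, 0}, {1, 0, 1}, {1, 1, 1}, {1, 1, 0}
};

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w0 = u[1] * v[2] - u[2] * v[1];
  double w1 = u[2] * v[0] - u[0] * v[2];
  double w2 = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(w0 * w0 + w1 * w1 + w2 * w2);
}

// [[Rcpp::export]]
double mt_area_cpp(NumericVector field, int nz, int ny, int nx,
                   double dz, double dy, double dx, double iso) {
  double area = 0.0;
  double pts[8][3], vals[8];
  for (int i = 0; i < nx - 1; ++i)
    for (int j = 0; j < ny - 1; ++j)
      for (int k = 0; k < nz - 1; ++k) {
        double vmin = 1e300, vmax = -1e300;
        for (int c = 0; c < 8; ++c) {
          double v = field[idx3(k + CORN[c][0], j + CORN[c][1],
                                i + CORN[c][2], nz, ny)];
          vals[c] = v;
          if (v < vmin) vmin = v;
          if (v > vmax) vmax = v;
        }
        if (vmax < iso || vmin >= iso) continue;
        for (int c = 0; c < 8; ++c) {
          pts[c][0] = (k + CORN[c][0]) * dz;
          pts[c][1] = (j + CORN[c][1]) * dy;
          pts[c][2] = (i + CORN[c][2]) * dx;
        }
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          bool in[4];
          int nin = 0;
          for (int q = 0; q < 4; ++q) {
            in[q] = vals[T[q]] >= iso;
            nin += in[q];
          }
          if (nin == 0 || nin == 4) continue;
          int ins[4], outs[4];
          int a = 0, b = 0;
          for (int q = 0; q < 4; ++q) {
            if (in[q]) ins[a++] = q; else outs[b++] = q;
          }
          double ip[4][3];
          // interpolate along edge (u -> v) of the tetrahedron
          auto interp = [&](int u, int v, double out[3]) {
            double vu = vals[T[u]], vv = vals[T[v]];
            double tt = (iso - vu) / (vv - vu);
            for (int d = 0; d < 3; ++d)
              out[d] = pts[T[u]][d] + tt * (pts[T[v]][d] - pts[T[u]][d]);
          };
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? ins[0] : outs[0];
            int m = 0;
            for (int q = 0; q < 4; ++q)
              if (q != apex) interp(apex, q, ip[m++]);
            area += tri_area(ip[0], ip[1], ip[2]);
          } else { // quad: two in, two out
            interp(ins[0], outs[0], ip[0]);
            interp(ins[0], outs[1], ip[1]);
            interp(ins[1], outs[1], ip[2]);
            interp(ins[1], outs[0], ip[3]);
            area += tri_area(ip[0], ip[1], ip[2]);
            area += tri_area(ip[0], ip[2], ip[3]);
          }
        }
      }
  return area;
}

// Count exposed voxel faces, weighted by physical face area. Used by the
// "faces" surface estimator and by the single-voxel fallback of "mesh".
// [[Rcpp::export]]
double face_area_cpp(IntegerVector mask, int nz, int ny, int nx,
                     double dz, double dy, double dx) {
  const double az = dy * dx, ay = dz * dx, ax = dz * dy;
  double area = 0.0;
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        if (mask[idx3(k, j, i, nz, ny)] == 0) continue;
        if (k == 0 || mask[idx3(k - 1, j, i, nz, ny)] == 0) area += az;
        if (k == nz - 1 || mask[idx3(k + 1, j, i, nz, ny)] == 0) area += az;
        if (j == 0 || mask[idx3(k, j - 1, i, nz, ny)] == 0) area += ay;
        if (j == ny - 1 || mask[idx3(k, j + 1, i, nz, ny)] == 0) area += ay;
        if (i == 0 || mask[idx3(k, j, i - 1, nz, ny)] == 0) area += ax;
        if (i == nx - 1 || mask[idx3(k, j, i + 1, nz, ny)] == 0) area += ax;
      }
  return area;
}

// Indices (1-based, linear) of mask voxels with at least one of their six
// face neighbours outside the mask (stack borders count as outside).
// [[Rcpp::export]]
IntegerVector boundary_voxels_cpp(IntegerVector mask, int nz, int ny, int nx) {
  std::vector<int> out;
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        R_xlen_t p = idx3(k, j, i, nz, ny);
        if (mask[p] == 0) continue;
        bool bd = (k == 0 || j == 0 || i == 0 ||
                   k == nz - 1 || j == ny - 1 || i == nx - 1);
        if (!bd)
          bd = mask[idx3(k - 1, j, i, nz, ny)] == 0 ||
               mask[idx3(k + 1, j, i, nz, ny)] == 0 ||
               mask[idx3(k, j - 1, i, nz, ny)] == 0 ||
               mask[idx3(k, j + 1, i, nz, ny)] == 0 ||
               mask[idx3(k, j, i - 1, nz, ny)] == 0 ||
               mask[idx3(k, j, i + 1, nz, ny)] == 0;
        if (bd) out.push_back((int)(p + 1));
      }
  return IntegerVector(out.begin(), out.end());
}
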