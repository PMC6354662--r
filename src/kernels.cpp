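// Voxel kernels: flood fill, median / Gaussian smoothing, ball dilation,
// and isosurface extraction by marching tetrahedra.
//
// All grids are passed as flat vectors in R array order (x fastest), with
// dim = c(nx, ny, nz). Linear index of (i,j,k), 0-based: i + nx*(j + ny*k).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

namespace {

struct Off { int dx, dy, dz; };

std::vector<Off> conn_offsets(int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<Off> out;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        out.push_back({dx, dy, dz});
      }
  return out;
}

inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

} // namespace

// Connected component of `mask` containing 0-based linear index `seed0`.
// [[Rcpp::export]]
LogicalVector cpp_flood_fill(const LogicalVector& mask, const IntegerVector& dim,
                             double seed0, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  R_xlen_t s = (R_xlen_t)seed0;
  if (s < 0 || s >= n) stop("seed index out of range");
  if (!mask[s]) stop("seed voxel is not set in mask");
  std::vector<Off> offs = conn_offsets(connectivity);
  std::vector<char> vis(n, 0);
  std::queue<R_xlen_t> q;
  vis[s] = 1; q.push(s);
  while (!q.empty()) {
    R_xlen_t c = q.front(); q.pop();
    int i = (int)(c % nx);
    R_xlen_t r = c / nx;
    int j = (int)(r % ny);
    int k = (int)(r / ny);
    for (const Off& o : offs) {
      int ii = i + o.dx, jj = j + o.dy, kk = k + o.dz;
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      R_xlen_t t = lin(ii, jj, kk, nx, ny);
      if (!vis[t] && mask[t]) { vis[t] = 1; q.push(t); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = vis[t] != 0;
  return out;
}

// TRUE iff seeds a and b (0-based linear) lie in the same component of mask.
// Early exit once b is reached.
// [[Rcpp::export]]
bool cpp_connected(const LogicalVector& mask, const IntegerVector& dim,
                   double seed_a, double seed_b, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  R_xlen_t a = (R_xlen_t)seed_a, b = (R_xlen_t)seed_b;
  if (a < 0 || a >= n || b < 0 || b >= n) stop("seed index out of range");
  if (!mask[a] || !mask[b]) stop("seed voxel is not set in mask");
  if (a == b) return true;
  std::vector<Off> offs = conn_offsets(connectivity);
  std::vector<char> vis(n, 0);
  std::queue<R_xlen_t> q;
  vis[a] = 1; q.push(a);
  while (!q.empty()) {
    R_xlen_t c = q.front(); q.pop();
    int i = (int)(c % nx);
    R_xlen_t r = c / nx;
    int j = (int)(r % ny);
    int k = (int)(r / ny);
    for (const Off& o : offs) {
      int ii = i + o.dx, jj = j + o.dy, kk = k + o.dz;
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      R_xlen_t t = lin(ii, jj, kk, nx, ny);
      if (!vis[t] && mask[t]) {
        if (t == b) return true;
        vis[t] = 1; q.push(t);
      }
    }
  }
  return false;
}

// Cubic median filter of half-width `radius`; borders by edge replication
// (indices clamped to the grid).
// [[Rcpp::export]]
NumericVector cpp_median_filter(const NumericVector& x, const IntegerVector& dim,
                                int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (x.size() != n) stop("length does not match dim");
  if (radius < 0) stop("radius must be >= 0");
  if (radius == 0) return clone(x);
  NumericVector out(n);
  const int w = 2 * radius + 1;
  std::vector<double> win((size_t)w * w * w);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t m = 0;
        for (int dk = -radius; dk <= radius; ++dk) {
          int kk = std::min(std::max(k + dk, 0), nz - 1);
          for (int dj = -radius; dj <= radius; ++dj) {
            int jj = std::min(std::max(j + dj, 0), ny - 1);
            for (int di = -radius; di <= radius; ++di) {
              int ii = std::min(std::max(i + di, 0), nx - 1);
              win[m++] = x[lin(ii, jj, kk, nx, ny)];
            }
          }
        }
        size_t mid = m / 2;
        std::nth_element(win.begin(), win.begin() + mid, win.begin() + m);
        out[lin(i, j, k, nx, ny)] = win[mid];
      }
  return out;
}

// Separable Gaussian blur; sigma given per axis in voxel units; kernel
// truncated at 4 sigma; borders by edge replication.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(const NumericVector& x, const IntegerVector& dim,
                                const NumericVector& sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (x.size() != n) stop("length does not match dim");
  NumericVector cur = clone(x);
  const int dims[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(4.0 * s);
    std::vector<double> ker(2 * r + 1);
    double sum = 0;
    for (int t = -r; t <= r; ++t) { ker[t + r] = std::exp(-0.5 * t * t / (s * s)); sum += ker[t + r]; }
    for (double& v : ker) v /= sum;
    NumericVector nxt(n);
    const int len = dims[ax];
    const R_xlen_t st = strides[ax];
    // iterate over all lines along axis ax
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int pos[3] = {i, j, k};
          if (pos[ax] != 0) continue; // start of a line only
          R_xlen_t base = lin(i, j, k, nx, ny);
          for (int p = 0; p < len; ++p) {
            double acc = 0;
            for (int t = -r; t <= r; ++t) {
              int q = std::min(std::max(p + t, 0), len - 1);
              acc += ker[t + r] * cur[base + (R_xlen_t)q * st];
            }
            nxt[base + (R_xlen_t)p * st] = acc;
          }
        }
    cur = nxt;
  }
  return cur;
}

// Morphological dilation by an arbitrary structuring element given as an
// integer matrix of (dx,dy,dz) offsets (voxel units).
// [[Rcpp::export]]
LogicalVector cpp_dilate(const LogicalVector& mask, const IntegerVector& dim,
                         const IntegerMatrix& offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<char> out(n, 0);
  const int no = offsets.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask[lin(i, j, k, nx, ny)]) continue;
        for (int o = 0; o < no; ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          out[lin(ii, jj, kk, nx, ny)] = 1;
        }
      }
  LogicalVector res(n);
  for (R_xlen_t t = 0; t < n; ++t) res[t] = out[t] != 0;
  return res;
}

// Isosurface of a scalar field sampled at voxel centers, by marching
// tetrahedra on the uniform conforming 6-tet decomposition of each grid cell
// (all tets share the cell's main diagonal, so faces match between adjacent
// cells and the surface is watertight when the iso-set does not touch the
// grid boundary). Shared vertices are deduplicated by the lattice edge they
// lie on. Triangles are oriented with normals pointing away from the
// above-iso ("inside") region, i.e. outward for a padded binary mask.
// [[Rcpp::export]]
List cpp_marching_tets(const NumericVector& field, const IntegerVector& dim,
                       const NumericVector& spacing, const NumericVector& origin,
                       double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (field.size() != n) stop("field length does not match dim");
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  static const int TET[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
  };
  static const int CB[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
  };

  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  std::unordered_map<long long, int> edge_vertex;

  auto node_pos = [&](R_xlen_t g, double* p) {
    int i = (int)(g % nx);
    R_xlen_t r = g / nx;
    int j = (int)(r % ny);
    int k = (int)(r / ny);
    p[0] = ox + (i + 0.5) * sx;
    p[1] = oy + (j + 0.5) * sy;
    p[2] = oz + (k + 0.5) * sz;
  };

  auto edge_vert = [&](R_xlen_t ga, R_xlen_t gb) -> int {
    long long a = (long long)std::min(ga, gb), b = (long long)std::max(ga, gb);
    long long key = a * (long long)n + b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double pa[3], pb[3];
    node_pos((R_xlen_t)a, pa); node_pos((R_xlen_t)b, pb);
    double fav = field[(R_xlen_t)a], fbv = field[(R_xlen_t)b];
    double t = (iso - fav) / (fbv - fav);
    int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vertex.emplace(key, id);
    return id;
  };

  // emit triangle (v1,v2,v3); flip if its normal does not point away from ref
  auto emit = [&](int a, int b, int c, const double* ref) {
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nxv = uy * wz - uz * wy;
    double nyv = uz * wx - ux * wz;
    double nzv = ux * wy - uy * wx;
    double cx = (vx[a] + vx[b] + vx[c]) / 3.0 - ref[0];
    double cy = (vy[a] + vy[b] + vy[c]) / 3.0 - ref[1];
    double cz = (vz[a] + vz[b] + vz[c]) / 3.0 - ref[2];
    double d = nxv * cx + nyv * cy + nzv * cz;
    if (d < 0) std::swap(b, c);
    fa.push_back(a); fb.push_back(b); fc.push_back(c);
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        R_xlen_t g[8];
        double val[8];
        bool in[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          g[c] = lin(i + CB[c][0], j + CB[c][1], k + CB[c][2], nx, ny);
          val[c] = field[g[c]];
          in[c] = val[c] >= iso;
          if (in[c]) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vA = TET[t][0], vB = TET[t][1], vC = TET[t][2], vD = TET[t][3];
          int node[4] = {vA, vB, vC, vD};
          int ins[4], nin = 0;
          for (int c = 0; c < 4; ++c) ins[c] = in[node[c]] ? 1 : 0, nin += ins[c];
          if (nin == 0 || nin == 4) continue;
          // reference point: centroid of inside nodes
          double ref[3] = {0, 0, 0};
          int cnt = 0;
          for (int c = 0; c < 4; ++c) {
            if (!ins[c]) continue;
            double p[3]; node_pos(g[node[c]], p);
            ref[0] += p[0]; ref[1] += p[1]; ref[2] += p[2]; ++cnt;
          }
          ref[0] /= cnt; ref[1] /= cnt; ref[2] /= cnt;
          if (nin == 1 || nin == 3) {
            // single node s on the minority side; triangle on its 3 edges
            int s = -1;
            for (int c = 0; c < 4; ++c) if (ins[c] == (nin == 1 ? 1 : 0)) s = c;
            int o[3], m = 0;
            for (int c = 0; c < 4; ++c) if (c != s) o[m++] = c;
            int e1 = edge_vert(g[node[s]], g[node[o[0]]]);
            int e2 = edge_vert(g[node[s]], g[node[o[1]]]);
            int e3 = edge_vert(g[node[s]], g[node[o[2]]]);
            emit(e1, e2, e3, ref);
          } else {
            // two in (p,q), two out (r,s): quad e_pr, e_ps, e_qs, e_qr
            int pin[2], pout[2], mi = 0, mo = 0;
            for (int c = 0; c < 4; ++c) (ins[c] ? pin[mi++] : pout[mo++]) = c;
            int e_pr = edge_vert(g[node[pin[0]]], g[node[pout[0]]]);
            int e_ps = edge_vert(g[node[pin[0]]], g[node[pout[1]]]);
            int e_qs = edge_vert(g[node[pin[1]]], g[node[pout[1]]]);
            int e_qr = edge_vert(g[node[pin[1]]], g[node[pout[0]]]);
            emit(e_pr, e_ps, e_qs, ref);
            emit(e_pr, e_qs, e_qr, ref);
          }
        }
      }

  const int nv = (int)vx.size(), nf = (int)fa.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vz[v]; }
  for (int f = 0; f < nf; ++f) { F(f, 0) = fa[f] + 1; F(f, 1) = fb[f] + 1; F(f, 2) = fc[f] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
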