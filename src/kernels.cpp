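// Numerical kernels: interpolation, separable blur, convolutional network
// primitives (im2col + GEMM), surface-distance search, marching tetrahedra.
#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Trilinear sampling of a 3D volume at world points, edge-replicate padding.
// vol is an R array (column-major, dims d); world = origin + index * spacing.
// [[Rcpp::export]]
NumericVector cpp_trilinear_sample(NumericVector vol, IntegerVector dim,
                                   NumericVector spacing, NumericVector origin,
                                   NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  for (int p = 0; p < n; ++p) {
    double fx = clampd((pts(p, 0) - origin[0]) / spacing[0], 0.0, nx - 1.0);
    double fy = clampd((pts(p, 1) - origin[1]) / spacing[1], 0.0, ny - 1.0);
    double fz = clampd((pts(p, 2) - origin[2]) / spacing[2], 0.0, nz - 1.0);
    int x0 = (int)fx, y0 = (int)fy, z0 = (int)fz;
    int x1 = x0 + 1 < nx ? x0 + 1 : x0;
    int y1 = y0 + 1 < ny ? y0 + 1 : y0;
    int z1 = z0 + 1 < nz ? z0 + 1 : z0;
    double tx = fx - x0, ty = fy - y0, tz = fz - z0;
    const long sxy = (long)nx * ny;
    double c000 = v[x0 + nx * y0 + sxy * z0], c100 = v[x1 + nx * y0 + sxy * z0];
    double c010 = v[x0 + nx * y1 + sxy * z0], c110 = v[x1 + nx * y1 + sxy * z0];
    double c001 = v[x0 + nx * y0 + sxy * z1], c101 = v[x1 + nx * y0 + sxy * z1];
    double c011 = v[x0 + nx * y1 + sxy * z1], c111 = v[x1 + nx * y1 + sxy * z1];
    double c00 = c000 * (1 - tx) + c100 * tx;
    double c10 = c010 * (1 - tx) + c110 * tx;
    double c01 = c001 * (1 - tx) + c101 * tx;
    double c11 = c011 * (1 - tx) + c111 * tx;
    double c0 = c00 * (1 - ty) + c10 * ty;
    double c1 = c01 * (1 - ty) + c11 * ty;
    out[p] = c0 * (1 - tz) + c1 * tz;
  }
  return out;
}

// Bilinear sampling of a 2D image on a regular grid, edge-replicate padding.
// img: ns x nz matrix; pixel (i,j) sits at (s0 + i*ds, z0 + j*dz).
// [[Rcpp::export]]
NumericVector cpp_bilinear_sample(NumericMatrix img, double s0, double ds,
                                  double z0, double dz,
                                  NumericVector s, NumericVector z) {
  const int ns = img.nrow(), nz = img.ncol();
  const int n = s.size();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double fi = clampd((s[p] - s0) / ds, 0.0, ns - 1.0);
    double fj = clampd((z[p] - z0) / dz, 0.0, nz - 1.0);
    int i0 = (int)fi, j0 = (int)fj;
    int i1 = i0 + 1 < ns ? i0 + 1 : i0;
    int j1 = j0 + 1 < nz ? j0 + 1 : j0;
    double ti = fi - i0, tj = fj - j0;
    double a = img(i0, j0) * (1 - ti) + img(i1, j0) * ti;
    double b = img(i0, j1) * (1 - ti) + img(i1, j1) * ti;
    out[p] = a * (1 - tj) + b * tj;
  }
  return out;
}

// Separable Gaussian blur of a 3D array; sigma per axis in voxel units.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector vol, IntegerVector dim,
                              NumericVector sigma) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> tmp(buf.size());
  const long stride[3] = {1, (long)d[0], (long)d[0] * d[1]};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double sum = 0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); sum += k[i + r]; }
    for (auto &w : k) w /= sum;
    const int n = d[ax];
    const long st = stride[ax];
    // iterate over all lines along axis ax
    long nLines = (long)d[0] * d[1] * d[2] / n;
    int o1 = (ax == 0) ? 1 : 0, o2 = (ax == 2) ? 1 : 2;
    for (long li = 0; li < nLines; ++li) {
      long i1 = li % d[o1], i2 = li / d[o1];
      long base = i1 * stride[o1] + i2 * stride[o2];
      for (int i = 0; i < n; ++i) {
        double acc = 0;
        for (int j = -r; j <= r; ++j) {
          int ii = i + j;
          if (ii < 0) ii = 0; else if (ii >= n) ii = n - 1;  // edge replicate
          acc += k[j + r] * buf[base + (long)ii * st];
        }
        tmp[base + (long)i * st] = acc;
      }
    }
    buf.swap(tmp);
  }
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = dim;
  return out;
}

// ---- Convolutional network primitives ---------------------------------
// Feature maps are (H*W) x C matrices, column-major, pixel index i + H*j.
// 3x3 convolution, zero padding, via im2col + GEMM.

static arma::mat im2col3(const arma::mat &X, int H, int W) {
  const int C = X.n_cols;
  arma::mat col(H * W, 9 * C, arma::fill::zeros);
  int cc = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      for (int c = 0; c < C; ++c, ++cc) {
        // destination pixel (i,j) takes X[(i+di, j+dj), c]
        int i_lo = std::max(0, -di), i_hi = std::min(H, H - di);
        int j_lo = std::max(0, -dj), j_hi = std::min(W, W - dj);
        for (int j = j_lo; j < j_hi; ++j) {
          double *dst = col.colptr(cc) + (long)j * H + i_lo;
          const double *src = X.colptr(c) + (long)(j + dj) * H + (i_lo + di);
          std::memcpy(dst, src, sizeof(double) * (i_hi - i_lo));
        }
      }
    }
  }
  return col;
}

static arma::mat col2im3(const arma::mat &col, int H, int W, int C) {
  arma::mat X(H * W, C, arma::fill::zeros);
  int cc = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      for (int c = 0; c < C; ++c, ++cc) {
        int i_lo = std::max(0, -di), i_hi = std::min(H, H - di);
        int j_lo = std::max(0, -dj), j_hi = std::min(W, W - dj);
        for (int j = j_lo; j < j_hi; ++j) {
          double *dst = X.colptr(c) + (long)(j + dj) * H + (i_lo + di);
          const double *src = col.colptr(cc) + (long)j * H + i_lo;
          for (int i = 0; i < i_hi - i_lo; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat &X, int H, int W,
                        const arma::mat &Wt, const arma::rowvec &b) {
  arma::mat Y = im2col3(X, H, W) * Wt;
  Y.each_row() += b;
  return Y;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::mat &X, int H, int W, const arma::mat &Wt,
                   const arma::mat &dY) {
  arma::mat col = im2col3(X, H, W);
  arma::mat dW = col.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dcol = dY * Wt.t();
  arma::mat dX = col2im3(dcol, H, W, X.n_cols);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling (stride 2); H, W must be even.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::mat &X, int H, int W) {
  const int C = X.n_cols, h = H / 2, w = W / 2;
  arma::mat Y(h * w, C);
  arma::umat idx(h * w, C);
  for (int c = 0; c < C; ++c) {
    const double *x = X.colptr(c);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        long p00 = 2 * i + (long)H * (2 * j);
        long cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
        int best = 0;
        for (int q = 1; q < 4; ++q) if (x[cand[q]] > x[cand[best]]) best = q;
        Y(i + (long)h * j, c) = x[cand[best]];
        idx(i + (long)h * j, c) = cand[best];
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool2_bwd(const arma::umat &idx, const arma::mat &dY,
                           int H, int W) {
  const int C = dY.n_cols;
  arma::mat dX(H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double *dx = dX.colptr(c);
    const double *dy = dY.colptr(c);
    const arma::uword *ix = idx.colptr(c);
    for (arma::uword p = 0; p < dY.n_rows; ++p) dx[ix[p]] += dy[p];
  }
  return dX;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
arma::mat cpp_upsample2_fwd(const arma::mat &X, int h, int w) {
  const int C = X.n_cols, H = 2 * h, W = 2 * w;
  arma::mat Y(H * W, C);
  for (int c = 0; c < C; ++c) {
    const double *x = X.colptr(c);
    double *y = Y.colptr(c);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        y[i + (long)H * j] = x[(i / 2) + (long)h * (j / 2)];
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_upsample2_bwd(const arma::mat &dY, int h, int w) {
  const int C = dY.n_cols, H = 2 * h, W = 2 * w;
  arma::mat dX(h * w, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double *dx = dX.colptr(c);
    const double *dy = dY.colptr(c);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx[(i / 2) + (long)h * (j / 2)] += dy[i + (long)H * j];
  }
  return dX;
}

// ---- Surface extraction and distances ---------------------------------

// Centers (world mm) of foreground voxels with >= 1 six-connected background
// neighbour; voxels beyond the grid count as background.
// [[Rcpp::export]]
NumericMatrix cpp_surface_points(IntegerVector mask, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  const long sxy = (long)nx * ny;
  const int *m = mask.begin();
  std::vector<double> pts;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        long p = x + (long)nx * y + sxy * z;
        if (!m[p]) continue;
        bool surf =
          (x == 0 || !m[p - 1]) || (x == nx - 1 || !m[p + 1]) ||
          (y == 0 || !m[p - nx]) || (y == ny - 1 || !m[p + nx]) ||
          (nz > 1 && ((z == 0 || !m[p - sxy]) || (z == nz - 1 || !m[p + sxy]))) ||
          (nz == 1 && false);
        if (surf) {
          pts.push_back(origin[0] + x * spacing[0]);
          pts.push_back(origin[1] + y * spacing[1]);
          pts.push_back(nz > 1 ? origin[2] + z * spacing[2] : 0.0);
        }
      }
  const int n = pts.size() / 3;
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = pts[3 * i + j];
  return out;
}

// For each row of A, the distance to the nearest row of B (brute force).
// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---- Marching tetrahedra isosurface -----------------------------------
// Each grid cell is split into 6 tetrahedra sharing the main diagonal;
// crossing-edge vertices are interpolated and deduplicated by grid-node
// pair, and triangles are oriented with normals pointing away from the
// above-level side.

struct EdgeKey {
  long a, b;
  bool operator==(const EdgeKey &o) const { return a == o.a && b == o.b; }
};
struct EdgeKeyHash {
  size_t operator()(const EdgeKey &k) const {
    return std::hash<long>()(k.a) * 1315423911u ^ std::hash<long>()(k.b);
  }
};

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dim,
                       NumericVector spacing, NumericVector origin,
                       double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long sxy = (long)nx * ny;
  const double *f = field.begin();
  std::vector<double> verts;
  std::vector<int> faces;
  std::unordered_map<EdgeKey, int, EdgeKeyHash> edgeMap;

  auto nodePos = [&](long idx, double *p) {
    long z = idx / sxy, r = idx % sxy;
    long y = r / nx, x = r % nx;
    p[0] = origin[0] + x * spacing[0];
    p[1] = origin[1] + y * spacing[1];
    p[2] = origin[2] + z * spacing[2];
  };
  auto edgeVertex = [&](long a, long b) -> int {
    if (a > b) std::swap(a, b);
    EdgeKey k{a, b};
    auto it = edgeMap.find(k);
    if (it != edgeMap.end()) return it->second;
    double pa[3], pb[3];
    nodePos(a, pa); nodePos(b, pb);
    double va = f[a], vb = f[b];
    double t = (level - va) / (vb - va);
    t = clampd(t, 0.0, 1.0);
    int id = verts.size() / 3;
    for (int q = 0; q < 3; ++q) verts.push_back(pa[q] + t * (pb[q] - pa[q]));
    edgeMap.emplace(k, id);
    return id;
  };
  auto emitTri = [&](int v0, int v1, int v2, const double *insidePt) {
    // orient so the normal points away from the inside (above-level) point
    const double *p0 = &verts[3 * v0], *p1 = &verts[3 * v1], *p2 = &verts[3 * v2];
    double u[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
    double w[3] = {p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2]};
    double nvec[3] = {u[1] * w[2] - u[2] * w[1], u[2] * w[0] - u[0] * w[2],
                      u[0] * w[1] - u[1] * w[0]};
    double cx = (p0[0] + p1[0] + p2[0]) / 3.0 - insidePt[0];
    double cy = (p0[1] + p1[1] + p2[1]) / 3.0 - insidePt[1];
    double cz = (p0[2] + p1[2] + p2[2]) / 3.0 - insidePt[2];
    if (nvec[0] * cx + nvec[1] * cy + nvec[2] * cz < 0) std::swap(v1, v2);
    faces.push_back(v0); faces.push_back(v1); faces.push_back(v2);
  };

  // 6-tet decomposition of the unit cube along diagonal 0-7
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                                 {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        long c[8];
        for (int q = 0; q < 8; ++q)
          c[q] = (x + (q & 1)) + (long)nx * (y + ((q >> 1) & 1)) +
                 sxy * (z + ((q >> 2) & 1));
        // skip cells entirely inside or outside
        bool anyIn = false, anyOut = false;
        for (int q = 0; q < 8; ++q) (f[c[q]] > level ? anyIn : anyOut) = true;
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          long n0 = c[tets[t][0]], n1 = c[tets[t][1]],
               n2 = c[tets[t][2]], n3 = c[tets[t][3]];
          long nd[4] = {n0, n1, n2, n3};
          bool in[4];
          int nin = 0;
          for (int q = 0; q < 4; ++q) { in[q] = f[nd[q]] > level; nin += in[q]; }
          if (nin == 0 || nin == 4) continue;
          double insidePt[3];
          for (int q = 0; q < 4; ++q)
            if (in[q]) { nodePos(nd[q], insidePt); break; }
          if (nin == 1 || nin == 3) {
            // single vertex on the minority side; triangle on its 3 edges
            bool want = (nin == 1);
            int solo = 0;
            for (int q = 0; q < 4; ++q) if (in[q] == want) solo = q;
            int vs[3], k = 0;
            for (int q = 0; q < 4; ++q)
              if (q != solo) vs[k++] = edgeVertex(nd[solo], nd[q]);
            emitTri(vs[0], vs[1], vs[2], insidePt);
          } else {
            // 2-2 split: quad on the 4 crossing edges
            int a1 = -1, a2 = -1, b1 = -1, b2 = -1;
            for (int q = 0; q < 4; ++q)
              (in[q] ? (a1 < 0 ? a1 : a2) : (b1 < 0 ? b1 : b2)) = q;
            int e11 = edgeVertex(nd[a1], nd[b1]);
            int e12 = edgeVertex(nd[a1], nd[b2]);
            int e21 = edgeVertex(nd[a2], nd[b1]);
            int e22 = edgeVertex(nd[a2], nd[b2]);
            emitTri(e11, e12, e22, insidePt);
            emitTri(e11, e22, e21, insidePt);
          }
        }
      }
  const int nv = verts.size() / 3, nf = faces.size() / 3;
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) V(i, j) = verts[3 * i + j];
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < 3; ++j) F(i, j) = faces[3 * i + j] + 1;  // 1-based
  return List::create(_["vertices"] = V, _["faces"] = F);
}
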