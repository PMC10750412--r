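// Low-level voxel kernels: 3x3x3 convolution (im2col + BLAS), 2x2x2 max
// pooling, x2 nearest-neighbour upsampling, brute-force directed Hausdorff,
// binary ball morphology and 6-connected component labelling.
//
// Volumes are R arrays in (x, y, z[, channel]) order, x fastest. Convolution
// weights are K x Cout matrices with K = 27 * Cin; row index is
// ci*27 + (kx+1) + 3*((ky+1) + 3*(kz+1)) for kernel offsets kx,ky,kz in
// {-1,0,1} (scaled by the dilation). Padding is zero ("same" output size).
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill the im2col block for z slices [k0, k1): rows index voxels of those
// slices (x fastest), columns index (ci, kernel offset). `col` must hold
// (k1-k0)*nx*ny rows.
static void im2col_slab(const double* x, int nx, int ny, int nz, int cin,
                        int d, int k0, int k1, double* col) {
  const size_t N = (size_t)nx * ny * nz;
  const size_t rows = (size_t)nx * ny * (k1 - k0);
  const size_t plane = (size_t)nx * ny;
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + N * ci;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int q = ci * 27 + (kx + 1) + 3 * ((ky + 1) + 3 * (kz + 1));
          double* dst = col + rows * q;
          const int ox = kx * d, oy = ky * d, oz = kz * d;
          const int lo = std::min(std::max(0, -ox), nx);
          const int hi = std::max(std::min(nx, nx - ox), lo);
          // within-plane linear shift; one bulk copy per z-plane, then
          // zero the x/y edges the wrap made invalid
          const long off = (long)ox + (long)nx * oy;
          for (int k = k0; k < k1; ++k) {
            const int sz = k + oz;
            double* dpl = dst + plane * (k - k0);
            if (sz < 0 || sz >= nz) {
              std::memset(dpl, 0, plane * sizeof(double));
              continue;
            }
            const double* spl = xc + plane * sz;
            const size_t t0 =
                std::min((size_t)std::max(0L, -off), plane);
            const size_t t1 = std::max(
                (size_t)std::max(0L, (long)plane - std::max(0L, off)), t0);
            if (t0 > 0) std::memset(dpl, 0, t0 * sizeof(double));
            if (t1 < plane)
              std::memset(dpl + t1, 0, (plane - t1) * sizeof(double));
            if (t1 > t0)
              std::memcpy(dpl + t0, spl + t0 + off,
                          (t1 - t0) * sizeof(double));
            // y rows that read outside [0, ny)
            for (int j = 0; j < ny; ++j) {
              const int sy = j + oy;
              if (sy < 0 || sy >= ny)
                std::memset(dpl + (size_t)nx * j, 0, nx * sizeof(double));
            }
            // x border columns
            if (lo > 0 || hi < nx) {
              for (int j = 0; j < ny; ++j) {
                double* drow = dpl + (size_t)nx * j;
                for (int i = 0; i < lo; ++i) drow[i] = 0.0;
                for (int i = hi; i < nx; ++i) drow[i] = 0.0;
              }
            }
          }
        }
  }
}

// scratch reused across calls to avoid large per-call allocations
static std::vector<double>& conv_scratch() {
  static std::vector<double> buf;
  return buf;
}

// z-slab height keeping the im2col block near L2-cache size
static int slab_height(int nx, int ny, int K) {
  const double target = 2.0 * 1024 * 1024 / sizeof(double);
  int h = (int)(target / ((double)nx * ny * K));
  return std::max(1, std::min(h, 8));
}

// activation codes: 0 = identity, 1 = ReLU, 2 = sigmoid
// [[Rcpp::export]]
NumericVector cf_conv3d_fwd(NumericVector x, NumericMatrix W, NumericVector b,
                            int dilation, int act = 0) {
  IntegerVector dm = x.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2], cin = dm[3];
  const int K = W.nrow(), cout = W.ncol();
  if (K != 27 * cin) stop("weight rows do not match 27 * input channels");
  const size_t N = (size_t)nx * ny * nz;
  const int sh = slab_height(nx, ny, K);
  std::vector<double>& buf = conv_scratch();
  buf.resize((size_t)nx * ny * sh * K);
  arma::mat Wm(W.begin(), K, cout, false);
  NumericVector out((R_xlen_t)(N * cout));
  double* op = REAL(out);
  for (int k0 = 0; k0 < nz; k0 += sh) {
    const int k1 = std::min(nz, k0 + sh);
    const size_t rows = (size_t)nx * ny * (k1 - k0);
    im2col_slab(REAL(x), nx, ny, nz, cin, dilation, k0, k1, buf.data());
    arma::mat col(buf.data(), rows, K, false, true);
    arma::mat yslab = col * Wm;
    for (int co = 0; co < cout; ++co) {
      double* yc = op + (size_t)nx * ny * k0 + N * co;
      const double* ys = yslab.colptr(co);
      const double bc = b[co];
      if (act == 1) {
        for (size_t r = 0; r < rows; ++r)
          yc[r] = std::max(ys[r] + bc, 0.0);
      } else if (act == 2) {
        for (size_t r = 0; r < rows; ++r)
          yc[r] = 1.0 / (1.0 + std::exp(-(ys[r] + bc)));
      } else {
        for (size_t r = 0; r < rows; ++r) yc[r] = ys[r] + bc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return out;
}

// [[Rcpp::export]]
List cf_conv3d_bwd(NumericVector x, NumericMatrix W, NumericVector gy,
                   int dilation, bool need_gx = true) {
  IntegerVector dm = x.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2], cin = dm[3];
  const int K = W.nrow(), cout = W.ncol();
  const size_t N = (size_t)nx * ny * nz;
  arma::mat Wm(W.begin(), K, cout, false);
  NumericMatrix gWr(K, cout);
  NumericVector gbr(cout);
  NumericVector gx((R_xlen_t)(N * cin));
  double* gxp = REAL(gx);
  arma::mat gWa(REAL(gWr), K, cout, false, true);
  const int sh = slab_height(nx, ny, K);
  std::vector<double>& buf = conv_scratch();
  const size_t slabcap = (size_t)nx * ny * sh;
  buf.resize(slabcap * K * 2);
  double* colbuf = buf.data();
  double* gcolbuf = buf.data() + slabcap * K;
  for (int k0 = 0; k0 < nz; k0 += sh) {
    const int k1 = std::min(nz, k0 + sh);
    const size_t rows = (size_t)nx * ny * (k1 - k0);
    im2col_slab(REAL(x), nx, ny, nz, cin, dilation, k0, k1, colbuf);
    arma::mat col(colbuf, rows, K, false, true);
    // gy channel planes are N apart, not rows apart: gather the slab
    arma::mat gys(rows, cout);
    for (int co = 0; co < cout; ++co)
      std::copy(REAL(gy) + (size_t)nx * ny * k0 + N * co,
                REAL(gy) + (size_t)nx * ny * k0 + N * co + rows,
                gys.colptr(co));
    gWa += col.t() * gys;
    for (int co = 0; co < cout; ++co) gbr[co] += arma::accu(gys.col(co));
    if (!need_gx) continue;
    arma::mat gcol(gcolbuf, rows, K, false, true);
    gcol = gys * Wm.t();
    // Scatter-add the slab's columns back into gx. Taps that read padding
    // carry no gradient: zero them first, then the scatter is one
    // contiguous shifted add per plane (wrapped edge positions only ever
    // add zeros).
    const size_t plane = (size_t)nx * ny;
    for (int ci = 0; ci < cin; ++ci) {
      double* gxc = gxp + N * ci;
      for (int kz = -1; kz <= 1; ++kz)
        for (int ky = -1; ky <= 1; ++ky)
          for (int kx = -1; kx <= 1; ++kx) {
            const int q = ci * 27 + (kx + 1) + 3 * ((ky + 1) + 3 * (kz + 1));
            double* src = gcolbuf + rows * q;
            const int ox = kx * dilation, oy = ky * dilation,
                      oz = kz * dilation;
            const int lo = std::min(std::max(0, -ox), nx),
                      hi = std::max(std::min(nx, nx - ox), lo);
            const long off = (long)ox + (long)nx * oy;
            for (int k = k0; k < k1; ++k) {
              const int sz = k + oz;
              double* spl = src + plane * (k - k0);
              if (sz < 0 || sz >= nz) continue;
              for (int j = 0; j < ny; ++j) {
                const int sy = j + oy;
                double* srow = spl + (size_t)nx * j;
                if (sy < 0 || sy >= ny) {
                  std::memset(srow, 0, nx * sizeof(double));
                  continue;
                }
                for (int i = 0; i < lo; ++i) srow[i] = 0.0;
                for (int i = hi; i < nx; ++i) srow[i] = 0.0;
              }
              double* dpl = gxc + plane * sz;
              const size_t t0 =
                  std::min((size_t)std::max(0L, -off), plane);
              const size_t t1 = std::max(
                  (size_t)std::max(0L, (long)plane - std::max(0L, off)), t0);
              const double* s = spl + t0;
              double* d2 = dpl + t0 + off;
              for (size_t t = 0; t < t1 - t0; ++t) d2[t] += s[t];
            }
          }
    }
  }
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  return List::create(_["gx"] = gx, _["gW"] = gWr, _["gb"] = gbr);
}

// [[Rcpp::export]]
List cf_maxpool_fwd(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2], nc = dm[3];
  if (nx % 2 || ny % 2 || nz % 2) stop("pooling needs even spatial dims");
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const size_t N = (size_t)nx * ny * nz, M = (size_t)mx * my * mz;
  const double* xp = REAL(x);
  NumericVector y((R_xlen_t)(M * nc));
  IntegerVector idx((R_xlen_t)(M * nc));
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  for (int c = 0; c < nc; ++c) {
    const double* xc = xp + N * c;
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          size_t barg = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                size_t s = (size_t)(2 * i + dx) +
                           (size_t)nx * ((2 * j + dy) + (size_t)ny * (2 * k + dz));
                if (xc[s] > best) { best = xc[s]; barg = s; }
              }
          size_t t = (size_t)i + (size_t)mx * (j + (size_t)my * k) + M * c;
          yp[t] = best;
          ip[t] = (int)(barg + N * c);
        }
  }
  y.attr("dim") = IntegerVector::create(mx, my, mz, nc);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cf_maxpool_bwd(IntegerVector idx, NumericVector gy,
                             IntegerVector xdim) {
  size_t N = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx((R_xlen_t)N);
  double* gxp = REAL(gx);
  const double* gyp = REAL(gy);
  const int* ip = INTEGER(idx);
  for (R_xlen_t t = 0; t < gy.size(); ++t) gxp[ip[t]] += gyp[t];
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector cf_upsample_fwd(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2], nc = dm[3];
  const int ux = 2 * nx, uy = 2 * ny, uz = 2 * nz;
  NumericVector y((R_xlen_t)((size_t)ux * uy * uz * nc));
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < nc; ++c)
    for (int k = 0; k < uz; ++k)
      for (int j = 0; j < uy; ++j) {
        const double* srow =
            xp + (size_t)nx * ((j / 2) + (size_t)ny * (k / 2)) +
            (size_t)nx * ny * nz * c;
        double* drow = yp + (size_t)ux * (j + (size_t)uy * k) +
                       (size_t)ux * uy * uz * c;
        for (int i = 0; i < ux; ++i) drow[i] = srow[i / 2];
      }
  y.attr("dim") = IntegerVector::create(ux, uy, uz, nc);
  return y;
}

// [[Rcpp::export]]
NumericVector cf_upsample_bwd(NumericVector gy) {
  IntegerVector dm = gy.attr("dim");
  const int ux = dm[0], uy = dm[1], uz = dm[2], nc = dm[3];
  const int nx = ux / 2, ny = uy / 2, nz = uz / 2;
  NumericVector gx((R_xlen_t)((size_t)nx * ny * nz * nc));
  const double* gyp = REAL(gy);
  double* gxp = REAL(gx);
  for (int c = 0; c < nc; ++c)
    for (int k = 0; k < uz; ++k)
      for (int j = 0; j < uy; ++j) {
        const double* srow = gyp + (size_t)ux * (j + (size_t)uy * k) +
                             (size_t)ux * uy * uz * c;
        double* drow = gxp + (size_t)nx * ((j / 2) + (size_t)ny * (k / 2)) +
                       (size_t)nx * ny * nz * c;
        for (int i = 0; i < ux; ++i) drow[i / 2] += srow[i];
      }
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return gx;
}

// Directed Hausdorff: max over rows of G of the min Euclidean distance to
// rows of P. Coordinates are arbitrary (lattice or mm). Early exit once a
// point's running minimum cannot exceed the current maximum.
// [[Rcpp::export]]
double cf_directed_hausdorff(NumericMatrix G, NumericMatrix P) {
  const int ng = G.nrow(), np = P.nrow();
  if (ng == 0 || np == 0) stop("empty voxel set");
  double h2 = 0.0;
  for (int g = 0; g < ng; ++g) {
    const double gx = G(g, 0), gy = G(g, 1), gz = G(g, 2);
    double dmin = std::numeric_limits<double>::infinity();
    for (int p = 0; p < np; ++p) {
      const double dx = gx - P(p, 0), dy = gy - P(p, 1), dz = gz - P(p, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < dmin) {
        dmin = d2;
        if (dmin <= h2) break;  // cannot raise the maximum
      }
    }
    if (dmin > h2 && std::isfinite(dmin)) h2 = dmin;
  }
  return std::sqrt(h2);
}

// [[Rcpp::export]]
IntegerVector cf_binary_morph(IntegerVector x, IntegerMatrix offsets,
                              bool erode) {
  IntegerVector dm = x.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const int no = offsets.nrow();
  IntegerVector out((R_xlen_t)((size_t)nx * ny * nz));
  const int* xp = INTEGER(x);
  int* op = INTEGER(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t t = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
        int acc = erode ? 1 : 0;
        for (int o = 0; o < no; ++o) {
          const int si = i + offsets(o, 0), sj = j + offsets(o, 1),
                    sk = k + offsets(o, 2);
          int v = 0;
          if (si >= 0 && si < nx && sj >= 0 && sj < ny && sk >= 0 && sk < nz)
            v = xp[(size_t)si + (size_t)nx * (sj + (size_t)ny * sk)];
          if (erode) {
            if (!v) { acc = 0; break; }
          } else {
            if (v) { acc = 1; break; }
          }
        }
        op[t] = acc;
      }
  out.attr("dim") = dm;
  return out;
}

// 6-connected component labelling (1-based labels, 0 = background).
// [[Rcpp::export]]
IntegerVector cf_label_components(IntegerVector x) {
  IntegerVector dm = x.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const size_t N = (size_t)nx * ny * nz;
  IntegerVector lab((R_xlen_t)N);
  const int* xp = INTEGER(x);
  int* lp = INTEGER(lab);
  std::vector<size_t> stack;
  int next = 0;
  const int step[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                          {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  for (size_t s = 0; s < N; ++s) {
    if (!xp[s] || lp[s]) continue;
    ++next;
    lp[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t t = stack.back();
      stack.pop_back();
      const int i = (int)(t % nx), j = (int)((t / nx) % ny),
                k = (int)(t / ((size_t)nx * ny));
      for (int d = 0; d < 6; ++d) {
        const int si = i + step[d][0], sj = j + step[d][1], sk = k + step[d][2];
        if (si < 0 || si >= nx || sj < 0 || sj >= ny || sk < 0 || sk >= nz)
          continue;
        const size_t u = (size_t)si + (size_t)nx * (sj + (size_t)ny * sk);
        if (xp[u] && !lp[u]) {
          lp[u] = next;
          stack.push_back(u);
        }
      }
    }
  }
  lab.attr("dim") = dm;
  return lab;
}
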