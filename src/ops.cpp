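// Low-level numerical kernels for the segmentation network and image plumbing.
//
// Feature-map layout ("NHWC-as-matrix"): a batch of N maps of size H x W with C
// channels is stored as an arma::mat with N*H*W rows and C columns. Row index
// r = n*(H*W) + w*H + h with h fastest (matching R's column-major flattening of
// an H x W matrix, images stacked along the first dimension). All kernels below
// assume and preserve this ordering.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Unfold k x k patches so convolution becomes one GEMM. Column index of the
// output is c*k*k + kj*k + ki (ki = row offset, fastest); weight matrices must
// use the same ordering, i.e. W has C*k*k rows and C_out columns.
// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::mat& x, int N, int H, int W, int k,
                     int stride, int pad) {
  const int C = x.n_cols;
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  arma::mat out(static_cast<size_t>(N) * Ho * Wo, static_cast<size_t>(C) * k * k,
                arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* oc = out.colptr(static_cast<size_t>(c) * k * k + kj * k + ki);
        for (int n = 0; n < N; ++n) {
          const double* xn = xc + static_cast<size_t>(n) * H * W;
          double* on = oc + static_cast<size_t>(n) * Ho * Wo;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            const double* xcol = xn + static_cast<size_t>(wi) * H;
            double* ocol = on + static_cast<size_t>(wo) * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              ocol[ho] = xcol[hi];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export]]
arma::mat cpp_col2im(const arma::mat& dcol, int N, int H, int W, int C, int k,
                     int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  arma::mat dx(static_cast<size_t>(N) * H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xc = dx.colptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* oc = dcol.colptr(static_cast<size_t>(c) * k * k + kj * k + ki);
        for (int n = 0; n < N; ++n) {
          double* xn = xc + static_cast<size_t>(n) * H * W;
          const double* on = oc + static_cast<size_t>(n) * Ho * Wo;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            double* xcol = xn + static_cast<size_t>(wi) * H;
            const double* ocol = on + static_cast<size_t>(wo) * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              xcol[hi] += ocol[ho];
            }
          }
        }
      }
    }
  }
  return dx;
}

// Depthwise k x k convolution; w has k*k rows (kj*k + ki ordering) and C cols.
// [[Rcpp::export]]
arma::mat cpp_dwconv_fw(const arma::mat& x, const arma::mat& w, int N, int H,
                        int W, int k, int stride, int pad) {
  const int C = x.n_cols;
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  arma::mat y(static_cast<size_t>(N) * Ho * Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    const double* wc = w.colptr(c);
    double* yc = y.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double* xn = xc + static_cast<size_t>(n) * H * W;
      double* yn = yc + static_cast<size_t>(n) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        double* ycol = yn + static_cast<size_t>(wo) * Ho;
        for (int kj = 0; kj < k; ++kj) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xn + static_cast<size_t>(wi) * H;
          for (int ki = 0; ki < k; ++ki) {
            const double wv = wc[kj * k + ki];
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              ycol[ho] += wv * xcol[hi];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bw(const arma::mat& dy, const arma::mat& x, const arma::mat& w,
                   int N, int H, int W, int k, int stride, int pad) {
  const int C = x.n_cols;
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  arma::mat dx(arma::size(x), arma::fill::zeros);
  arma::mat dw(arma::size(w), arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    const double* wc = w.colptr(c);
    const double* dyc = dy.colptr(c);
    double* dxc = dx.colptr(c);
    double* dwc = dw.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double* xn = xc + static_cast<size_t>(n) * H * W;
      double* dxn = dxc + static_cast<size_t>(n) * H * W;
      const double* dyn = dyc + static_cast<size_t>(n) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        const double* dycol = dyn + static_cast<size_t>(wo) * Ho;
        for (int kj = 0; kj < k; ++kj) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xn + static_cast<size_t>(wi) * H;
          double* dxcol = dxn + static_cast<size_t>(wi) * H;
          for (int ki = 0; ki < k; ++ki) {
            const double wv = wc[kj * k + ki];
            double acc = 0.0;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              const double g = dycol[ho];
              dxcol[hi] += wv * g;
              acc += g * xcol[hi];
            }
            dwc[kj * k + ki] += acc;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Bilinear upsampling by integer factor, align_corners = FALSE convention:
// source coordinate of destination pixel i is (i + 0.5)/scale - 0.5, clamped.
// [[Rcpp::export]]
arma::mat cpp_upsample_fw(const arma::mat& x, int N, int H, int W, int scale) {
  const int C = x.n_cols;
  const int Ho = H * scale, Wo = W * scale;
  arma::mat y(static_cast<size_t>(N) * Ho * Wo, C, arma::fill::zeros);
  std::vector<int> i0(Ho), i1(Ho);
  std::vector<double> fi(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / scale - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    i0[i] = static_cast<int>(std::floor(s));
    i1[i] = std::min(i0[i] + 1, H - 1);
    fi[i] = s - i0[i];
  }
  std::vector<int> j0(Wo), j1(Wo);
  std::vector<double> fj(Wo);
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) / scale - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    j0[j] = static_cast<int>(std::floor(s));
    j1[j] = std::min(j0[j] + 1, W - 1);
    fj[j] = s - j0[j];
  }
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    double* yc = y.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double* xn = xc + static_cast<size_t>(n) * H * W;
      double* yn = yc + static_cast<size_t>(n) * Ho * Wo;
      for (int j = 0; j < Wo; ++j) {
        const double* xl = xn + static_cast<size_t>(j0[j]) * H;
        const double* xr = xn + static_cast<size_t>(j1[j]) * H;
        double* ycol = yn + static_cast<size_t>(j) * Ho;
        const double wj = fj[j];
        for (int i = 0; i < Ho; ++i) {
          const double wi = fi[i];
          ycol[i] = (1 - wi) * ((1 - wj) * xl[i0[i]] + wj * xr[i0[i]]) +
                    wi * ((1 - wj) * xl[i1[i]] + wj * xr[i1[i]]);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::mat cpp_upsample_bw(const arma::mat& dy, int N, int H, int W, int scale) {
  const int C = dy.n_cols;
  const int Ho = H * scale, Wo = W * scale;
  arma::mat dx(static_cast<size_t>(N) * H * W, C, arma::fill::zeros);
  std::vector<int> i0(Ho), i1(Ho);
  std::vector<double> fi(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / scale - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    i0[i] = static_cast<int>(std::floor(s));
    i1[i] = std::min(i0[i] + 1, H - 1);
    fi[i] = s - i0[i];
  }
  std::vector<int> j0(Wo), j1(Wo);
  std::vector<double> fj(Wo);
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) / scale - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    j0[j] = static_cast<int>(std::floor(s));
    j1[j] = std::min(j0[j] + 1, W - 1);
    fj[j] = s - j0[j];
  }
  for (int c = 0; c < C; ++c) {
    const double* dyc = dy.colptr(c);
    double* dxc = dx.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double* dyn = dyc + static_cast<size_t>(n) * Ho * Wo;
      double* dxn = dxc + static_cast<size_t>(n) * H * W;
      for (int j = 0; j < Wo; ++j) {
        double* xl = dxn + static_cast<size_t>(j0[j]) * H;
        double* xr = dxn + static_cast<size_t>(j1[j]) * H;
        const double* dycol = dyn + static_cast<size_t>(j) * Ho;
        const double wj = fj[j];
        for (int i = 0; i < Ho; ++i) {
          const double g = dycol[i];
          const double wi = fi[i];
          xl[i0[i]] += (1 - wi) * (1 - wj) * g;
          xr[i0[i]] += (1 - wi) * wj * g;
          xl[i1[i]] += wi * (1 - wj) * g;
          xr[i1[i]] += wi * wj * g;
        }
      }
    }
  }
  return dx;
}

// Generic geometric resampling: for each destination pixel, sample the source
// image at (map_x, map_y) (0-based continuous coordinates, x = column, y = row)
// with nearest-neighbour (method 0) or bilinear (method 1) interpolation.
// Out-of-bounds samples return `fill`.
// [[Rcpp::export]]
NumericMatrix cpp_remap(const NumericMatrix& src, const NumericMatrix& map_x,
                        const NumericMatrix& map_y, int method, double fill) {
  const int H = src.nrow(), W = src.ncol();
  const int Ho = map_x.nrow(), Wo = map_x.ncol();
  NumericMatrix out(Ho, Wo);
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const double sx = map_x(i, j), sy = map_y(i, j);
      if (method == 0) {
        const int r = static_cast<int>(std::lround(sy));
        const int c = static_cast<int>(std::lround(sx));
        out(i, j) = (r < 0 || r >= H || c < 0 || c >= W) ? fill : src(r, c);
      } else {
        if (sx < -0.5 || sx > W - 0.5 || sy < -0.5 || sy > H - 0.5) {
          out(i, j) = fill;
          continue;
        }
        double x0 = std::floor(sx), y0 = std::floor(sy);
        const double fx = sx - x0, fy = sy - y0;
        int c0 = std::max(0, std::min(W - 1, static_cast<int>(x0)));
        int c1 = std::max(0, std::min(W - 1, static_cast<int>(x0) + 1));
        int r0 = std::max(0, std::min(H - 1, static_cast<int>(y0)));
        int r1 = std::max(0, std::min(H - 1, static_cast<int>(y0) + 1));
        out(i, j) = (1 - fy) * ((1 - fx) * src(r0, c0) + fx * src(r0, c1)) +
                    fy * ((1 - fx) * src(r1, c0) + fx * src(r1, c1));
      }
    }
  }
  return out;
}

// 8-connected component labelling of a binary mask (BFS, deterministic label
// order: first-visited in column-major scan gets the lowest label).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        const int cr = q.front().first, cc = q.front().second;
        q.pop();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            const int nr = cr + dr, nc = cc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              q.push(std::make_pair(nr, nc));
            }
          }
        }
      }
    }
  }
  return lab;
}

static bool on_segment(double px, double py, double x1, double y1, double x2,
                       double y2, double tol) {
  const double cross = (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1);
  const double len = std::hypot(x2 - x1, y2 - y1);
  if (len == 0.0) return std::hypot(px - x1, py - y1) <= tol;
  if (std::fabs(cross) / len > tol) return false;
  const double dot = (px - x1) * (x2 - x1) + (py - y1) * (y2 - y1);
  return dot >= -tol * len && dot <= len * len + tol * len;
}

// Rasterize polygons onto an H x W grid: pixel (r, c) (0-based) has its centre
// at (x = c + 0.5, y = r + 0.5); it is set iff the centre is strictly inside
// (even-odd rule) or on the boundary of any polygon. Polygons are n x 2
// matrices of (x, y) vertices.
// [[Rcpp::export]]
IntegerMatrix cpp_poly_mask(int H, int W, const List& polys) {
  IntegerMatrix out(H, W);
  const double tol = 1e-9;
  for (int p = 0; p < polys.size(); ++p) {
    NumericMatrix poly = polys[p];
    const int nv = poly.nrow();
    if (nv < 3) continue;
    double xmin = poly(0, 0), xmax = xmin, ymin = poly(0, 1), ymax = ymin;
    for (int v = 1; v < nv; ++v) {
      xmin = std::min(xmin, poly(v, 0));
      xmax = std::max(xmax, poly(v, 0));
      ymin = std::min(ymin, poly(v, 1));
      ymax = std::max(ymax, poly(v, 1));
    }
    const int c_lo = std::max(0, static_cast<int>(std::floor(xmin - 1)));
    const int c_hi = std::min(W - 1, static_cast<int>(std::ceil(xmax)));
    const int r_lo = std::max(0, static_cast<int>(std::floor(ymin - 1)));
    const int r_hi = std::min(H - 1, static_cast<int>(std::ceil(ymax)));
    for (int c = c_lo; c <= c_hi; ++c) {
      const double px = c + 0.5;
      for (int r = r_lo; r <= r_hi; ++r) {
        if (out(r, c)) continue;
        const double py = r + 0.5;
        bool inside = false, boundary = false;
        for (int v = 0; v < nv && !boundary; ++v) {
          const double x1 = poly(v, 0), y1 = poly(v, 1);
          const double x2 = poly((v + 1) % nv, 0), y2 = poly((v + 1) % nv, 1);
          if (on_segment(px, py, x1, y1, x2, y2, tol)) {
            boundary = true;
            break;
          }
          if ((y1 > py) != (y2 > py)) {
            const double xint = x1 + (py - y1) * (x2 - x1) / (y2 - y1);
            if (px < xint) inside = !inside;
          }
        }
        if (inside || boundary) out(r, c) = 1;
      }
    }
  }
  return out;
}

// Fused batch-norm forward: xhat = (x - mean) * istd; y = xhat*gamma + beta.
// [[Rcpp::export]]
List cpp_bn_fw(const arma::mat& x, const arma::vec& mean, const arma::vec& istd,
               const arma::vec& gamma, const arma::vec& beta) {
  arma::mat xhat(arma::size(x)), y(arma::size(x));
  const size_t M = x.n_rows;
  for (size_t c = 0; c < x.n_cols; ++c) {
    const double mu = mean[c], is = istd[c], g = gamma[c], b = beta[c];
    const double* xc = x.colptr(c);
    double* hc = xhat.colptr(c);
    double* yc = y.colptr(c);
    for (size_t i = 0; i < M; ++i) {
      const double h = (xc[i] - mu) * is;
      hc[i] = h;
      yc[i] = h * g + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// Fused batch-norm backward: dx = a[c] * (dy - b1[c] - xhat * b2[c]).
// [[Rcpp::export]]
arma::mat cpp_bn_bw(const arma::mat& dy, const arma::mat& xhat,
                    const arma::vec& a, const arma::vec& b1,
                    const arma::vec& b2) {
  arma::mat dx(arma::size(dy));
  const size_t M = dy.n_rows;
  for (size_t c = 0; c < dy.n_cols; ++c) {
    const double ac = a[c], b1c = b1[c], b2c = b2[c];
    const double* dyc = dy.colptr(c);
    const double* hc = xhat.colptr(c);
    double* dxc = dx.colptr(c);
    for (size_t i = 0; i < M; ++i) dxc[i] = ac * (dyc[i] - b1c - hc[i] * b2c);
  }
  return dx;
}

// Elementwise activations, fused: type 0 = ReLU, 1 = hard-swish,
// 2 = hard-sigmoid, 3 = sigmoid.
// [[Rcpp::export]]
arma::mat cpp_act_fw(const arma::mat& x, int type) {
  arma::mat y(arma::size(x));
  const size_t n = x.n_elem;
  const double* xp = x.memptr();
  double* yp = y.memptr();
  for (size_t i = 0; i < n; ++i) {
    const double v = xp[i];
    switch (type) {
      case 0: yp[i] = v > 0 ? v : 0; break;
      case 1: yp[i] = v <= -3 ? 0 : (v >= 3 ? v : v * (v + 3) / 6); break;
      case 2: yp[i] = v <= -3 ? 0 : (v >= 3 ? 1 : (v + 3) / 6); break;
      default: yp[i] = 1 / (1 + std::exp(-v));
    }
  }
  return y;
}

// Backward for cpp_act_fw; `cache` is the input x for types 0-2, the output
// y for sigmoid.
// [[Rcpp::export]]
arma::mat cpp_act_bw(const arma::mat& dy, const arma::mat& cache, int type) {
  arma::mat dx(arma::size(dy));
  const size_t n = dy.n_elem;
  const double* dp = dy.memptr();
  const double* cp = cache.memptr();
  double* xp = dx.memptr();
  for (size_t i = 0; i < n; ++i) {
    const double v = cp[i];
    double g;
    switch (type) {
      case 0: g = v > 0 ? 1 : 0; break;
      case 1: g = v <= -3 ? 0 : (v >= 3 ? 1 : (2 * v + 3) / 6); break;
      case 2: g = (v > -3 && v < 3) ? 1.0 / 6 : 0; break;
      default: g = v * (1 - v);
    }
    xp[i] = dp[i] * g;
  }
  return dx;
}

// Moore-neighbour contour tracing: polygonal chain length of the outer
// boundary of the (single-component) foreground region, axial steps weighted
// 1 and diagonal steps sqrt(2) -- the standard contour arc-length estimate.
// Returns 0 for a single-pixel region.
// [[Rcpp::export]]
double cpp_chain_perimeter(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  // clockwise Moore neighbourhood starting east, in (dr, dc)
  const int dr[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int dc[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  auto fg = [&](int r, int c) {
    return r >= 0 && r < H && c >= 0 && c < W && mask(r, c) != 0;
  };
  // start: first foreground pixel in column-major scan (its west neighbour
  // is background by construction)
  int sr = -1, sc = -1;
  for (int c = 0; c < W && sr < 0; ++c)
    for (int r = 0; r < H; ++r)
      if (mask(r, c) != 0) { sr = r; sc = c; break; }
  if (sr < 0) return 0.0;
  // check isolation
  bool lone = true;
  for (int k = 0; k < 8; ++k)
    if (fg(sr + dr[k], sc + dc[k])) { lone = false; break; }
  if (lone) return 0.0;

  double per = 0.0;
  int r = sr, c = sc;
  int dir = 4;  // backtrack direction: came from the west (bg side)
  const long maxit = 4L * H * W + 8;
  long it = 0;
  int first_dir = -1;
  while (it++ < maxit) {
    // search clockwise starting just after the backtrack direction
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (dir + k) % 8;
      if (fg(r + dr[d], c + dc[d])) { found = d; break; }
    }
    if (found < 0) break;  // unreachable for non-lone pixel
    r += dr[found];
    c += dc[found];
    per += (found % 2 == 0) ? 1.0 : std::sqrt(2.0);
    if (first_dir < 0) first_dir = found;
    // Jacob's stopping criterion: back at start, leaving in the same
    // direction as the first move
    if (r == sr && c == sc) {
      int next = -1;
      int back = (found + 4) % 8;
      for (int k = 1; k <= 8; ++k) {
        int d = (back + k) % 8;
        if (fg(r + dr[d], c + dc[d])) { next = d; break; }
      }
      if (next == first_dir) break;
    }
    dir = (found + 4) % 8;  // new backtrack = direction we came from
  }
  return per;
}
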