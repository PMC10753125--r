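// Low-level numeric kernels for the segmentation network and the geometric
// augmentations. Feature maps are H x W x C cubes (channels last, matching
// R's array layout); convolution weights are (C_out) x (k*k*C_in) matrices
// with the row-within-patch order (channel, kernel col, kernel row).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using namespace Rcpp;

// im2col with zero same-padding, patch-major layout: row j of the result
// corresponds to output pixel (r, c) with j = r + c*H (column-major,
// matching R); column ((ch*k + dc)*k + dr) holds the shifted input. With
// this layout both source and destination runs are contiguous, so the
// copy is memcpy-speed and the GEMM below dominates.
static mat im2col_t(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = k / 2;
  const size_t HW = (size_t)H * W;
  mat cols(HW, (size_t)k * k * C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const double* xs = x.slice_memptr(ch);
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        double* dst = cols.colptr(((size_t)ch * k + dc) * k + dr);
        const int r0 = std::max(0, pad - dr);
        const int r1 = std::min(H, H + pad - dr);
        if (r1 <= r0) continue;
        for (int c = 0; c < W; ++c) {
          const int sc = c + dc - pad;
          if (sc < 0 || sc >= W) continue;
          std::memcpy(dst + (size_t)c * H + r0,
                      xs + (size_t)sc * H + r0 + dr - pad,
                      (size_t)(r1 - r0) * sizeof(double));
        }
      }
    }
  }
  return cols;
}

static void col2im_t_add(cube& gx, const mat& gcols, const int k) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  const int pad = k / 2;
  for (int ch = 0; ch < C; ++ch) {
    double* gs = gx.slice_memptr(ch);
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        const double* src = gcols.colptr(((size_t)ch * k + dc) * k + dr);
        const int r0 = std::max(0, pad - dr);
        const int r1 = std::min(H, H + pad - dr);
        if (r1 <= r0) continue;
        for (int c = 0; c < W; ++c) {
          const int sc = c + dc - pad;
          if (sc < 0 || sc >= W) continue;
          double* d = gs + (size_t)sc * H + r0 + dr - pad;
          const double* s = src + (size_t)c * H + r0;
          for (int r = 0; r < r1 - r0; ++r) d[r] += s[r];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, const int k) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_rows;
  mat cols = im2col_t(x, k);      // (H*W) x (k*k*Cin)
  mat out = cols * W.t();         // (H*W) x Cout
  out.each_row() += b.t();
  cube y(H, Wd, Cout);
  std::memcpy(y.memptr(), out.memptr(), out.n_elem * sizeof(double));
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& W,
                      const arma::cube& gy, const int k) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  const size_t HW = (size_t)H * Wd;
  mat G(const_cast<double*>(gy.memptr()), HW, Cout, false, true);
  mat cols = im2col_t(x, k);
  mat gW = G.t() * cols;          // Cout x (k*k*Cin)
  vec gb = sum(G, 0).t();
  mat gcols = G * W;              // (H*W) x (k*k*Cin)
  cube gx(H, Wd, Cin, fill::zeros);
  col2im_t_add(gx, gcols, k);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// 2x2 max pooling, stride 2; input dims must be even. idx stores, per output
// element, the 0-based linear index (r + c*H) of the chosen input pixel.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const mat& xs = x.slice(ch);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        int br = 2 * r, bc = 2 * c;
        double best = xs(br, bc);
        int bi = br + bc * H;
        if (xs(br + 1, bc) > best) { best = xs(br + 1, bc); bi = br + 1 + bc * H; }
        if (xs(br, bc + 1) > best) { best = xs(br, bc + 1); bi = br + (bc + 1) * H; }
        if (xs(br + 1, bc + 1) > best) { best = xs(br + 1, bc + 1); bi = br + 1 + (bc + 1) * H; }
        y(r, c, ch) = best;
        idx(r, c, ch) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
arma::cube maxpool2_bwd(const arma::ucube& idx, const arma::cube& gy,
                        const int H, const int W) {
  const int C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    mat& gs = gx.slice(ch);
    const mat& gys = gy.slice(ch);
    const umat& is = idx.slice(ch);
    for (uword j = 0; j < gys.n_elem; ++j) gs(is(j)) += gys(j);
  }
  return gx;
}

// Bilinear x2 upsampling with half-pixel centers (align_corners = false).
static void up2_weights(const int Ho, const int H, std::vector<int>& i0,
                        std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(Ho); i1.resize(Ho); w1.resize(Ho);
  for (int r = 0; r < Ho; ++r) {
    double s = (r + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    int f = (int)std::floor(s);
    if (f > H - 2) f = H - 2;
    if (f < 0) f = 0;
    i0[r] = f; i1[r] = (H > 1) ? f + 1 : f;
    w1[r] = (H > 1) ? s - f : 0.0;
  }
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1; std::vector<double> wr, wc;
  up2_weights(Ho, H, r0, r1, wr);
  up2_weights(Wo, W, c0, c1, wc);
  cube y(Ho, Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const mat& xs = x.slice(ch);
    mat& ys = y.slice(ch);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        double a = xs(r0[r], c0[c]) * (1 - wr[r]) * (1 - wc[c])
                 + xs(r1[r], c0[c]) * wr[r] * (1 - wc[c])
                 + xs(r0[r], c1[c]) * (1 - wr[r]) * wc[c]
                 + xs(r1[r], c1[c]) * wr[r] * wc[c];
        ys(r, c) = a;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
arma::cube upsample2_bwd(const arma::cube& gy, const int H, const int W) {
  const int C = gy.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  std::vector<int> r0, r1, c0, c1; std::vector<double> wr, wc;
  up2_weights(Ho, H, r0, r1, wr);
  up2_weights(Wo, W, c0, c1, wc);
  cube gx(H, W, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    mat& gs = gx.slice(ch);
    const mat& gys = gy.slice(ch);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const double g = gys(r, c);
        gs(r0[r], c0[c]) += g * (1 - wr[r]) * (1 - wc[c]);
        gs(r1[r], c0[c]) += g * wr[r] * (1 - wc[c]);
        gs(r0[r], c1[c]) += g * (1 - wr[r]) * wc[c];
        gs(r1[r], c1[c]) += g * wr[r] * wc[c];
      }
    }
  }
  return gx;
}

// Backward warp: out(r, c) = img(map_r(r, c), map_c(r, c)) with bilinear
// interpolation; source coordinates are 0-based, out-of-bounds -> fill.
// [[Rcpp::export(name = ".warp_bilinear")]]
arma::mat warp_bilinear(const arma::mat& img, const arma::mat& map_r,
                        const arma::mat& map_c, const double fill) {
  const int H = img.n_rows, W = img.n_cols;
  const int Ho = map_r.n_rows, Wo = map_r.n_cols;
  mat out(Ho, Wo);
  for (int c = 0; c < Wo; ++c) {
    for (int r = 0; r < Ho; ++r) {
      const double sr = map_r(r, c), sc = map_c(r, c);
      if (sr < 0 || sc < 0 || sr > H - 1 || sc > W - 1) { out(r, c) = fill; continue; }
      int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      if (r0 > H - 2) r0 = H - 2;
      if (c0 > W - 2) c0 = W - 2;
      if (r0 < 0) r0 = 0;
      if (c0 < 0) c0 = 0;
      const double fr = sr - r0, fc = sc - c0;
      const int r1 = (H > 1) ? r0 + 1 : r0, c1 = (W > 1) ? c0 + 1 : c0;
      out(r, c) = img(r0, c0) * (1 - fr) * (1 - fc)
                + img(r1, c0) * fr * (1 - fc)
                + img(r0, c1) * (1 - fr) * fc
                + img(r1, c1) * fr * fc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".warp_nearest")]]
arma::mat warp_nearest(const arma::mat& img, const arma::mat& map_r,
                       const arma::mat& map_c, const double fill) {
  const int H = img.n_rows, W = img.n_cols;
  const int Ho = map_r.n_rows, Wo = map_r.n_cols;
  mat out(Ho, Wo);
  for (int c = 0; c < Wo; ++c) {
    for (int r = 0; r < Ho; ++r) {
      const double sr = map_r(r, c), sc = map_c(r, c);
      const long ri = std::lround(sr), ci = std::lround(sc);
      if (ri < 0 || ci < 0 || ri >= H || ci >= W) { out(r, c) = fill; continue; }
      out(r, c) = img(ri, ci);
    }
  }
  return out;
}
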