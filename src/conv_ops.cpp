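// Convolutional primitives for the U-net: 2-D "same" convolution via
// im2col + BLAS gemm, 2x2 max pooling and 2x nearest-neighbour upsampling,
// each with its adjoint for backpropagation.
//
// Feature maps cross the R boundary as numeric vectors with a dim
// attribute (H, W, C), column-major; they are viewed in place (no copy on
// entry) and results are written directly into freshly allocated R arrays.
//
// Layouts:
//   conv weights  : (k*k*Cin) x Cout, column index q encodes (ci, kj, ki)
//                   as q = ci*k*k + (kj+p)*k + (ki+p), p = k/2
//   im2col matrix : (H*W) x (k*k*Cin), pixel rows ordered column-major

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static cube view_cube(Rcpp::NumericVector x) {
  Rcpp::IntegerVector d = x.attr("dim");
  return cube(x.begin(), d[0], d[1], d.size() == 3 ? d[2] : 1, false, true);
}

static Rcpp::NumericVector alloc_array(const int H, const int W,
                                       const int C) {
  Rcpp::NumericVector out(static_cast<R_xlen_t>(H) * W * C);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, C);
  return out;
}

// Fill the im2col matrix; only the border strips that shifted copies do
// not reach are zeroed, the interior is written directly.
static void im2col_same(const cube& x, const int k, mat& cols) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = k / 2;
  for (int ci = 0; ci < C; ++ci) {
    const mat& xs = x.slice(ci);
    for (int kj = -p; kj <= p; ++kj) {
      for (int ki = -p; ki <= p; ++ki) {
        const uword q = ci * k * k + (kj + p) * k + (ki + p);
        mat qview(cols.colptr(q), H, W, false, true);
        const int r0 = std::max(0, -ki), r1 = std::min(H - 1, H - 1 - ki);
        const int c0 = std::max(0, -kj), c1 = std::min(W - 1, W - 1 - kj);
        if (c0 > 0) qview.cols(0, c0 - 1).zeros();
        if (c1 < W - 1) qview.cols(c1 + 1, W - 1).zeros();
        if (r0 > 0) qview.rows(0, r0 - 1).zeros();
        if (r1 < H - 1) qview.rows(r1 + 1, H - 1).zeros();
        if (r0 <= r1 && c0 <= c1)
          qview.submat(r0, c0, r1, c1) =
              xs.submat(r0 + ki, c0 + kj, r1 + ki, c1 + kj);
      }
    }
  }
}

static void col2im_same_add(cube& dx, const mat& dcols, const int k) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices, p = k / 2;
  dx.zeros();
  for (int ci = 0; ci < C; ++ci) {
    mat& dxs = dx.slice(ci);
    for (int kj = -p; kj <= p; ++kj) {
      for (int ki = -p; ki <= p; ++ki) {
        const uword q = ci * k * k + (kj + p) * k + (ki + p);
        const mat qview(const_cast<double*>(dcols.colptr(q)), H, W, false,
                        true);
        const int r0 = std::max(0, -ki), r1 = std::min(H - 1, H - 1 - ki);
        const int c0 = std::max(0, -kj), c1 = std::min(W - 1, W - 1 - kj);
        if (r0 <= r1 && c0 <= c1)
          dxs.submat(r0 + ki, c0 + kj, r1 + ki, c1 + kj) +=
              qview.submat(r0, c0, r1, c1);
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv2d(Rcpp::NumericVector x, const arma::mat& w,
                               const arma::vec& b, const int k) {
  const cube xc = view_cube(x);
  const uword H = xc.n_rows, W = xc.n_cols, Cout = w.n_cols;
  Rcpp::NumericVector out = alloc_array(H, W, Cout);
  mat outm(out.begin(), H * W, Cout, false, true);
  if (k == 1) {
    const mat xm(const_cast<double*>(xc.memptr()), H * W, xc.n_slices,
                 false, true);
    outm = xm * w;
  } else {
    mat cols(H * W, w.n_rows, fill::none);
    im2col_same(xc, k, cols);
    outm = cols * w;
  }
  outm.each_row() += b.t();
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_grad(Rcpp::NumericVector x, const arma::mat& w,
                           Rcpp::NumericVector dout, const int k) {
  const cube xc = view_cube(x);
  const cube dc = view_cube(dout);
  const uword H = xc.n_rows, W = xc.n_cols, Cin = xc.n_slices;
  const mat doutm(const_cast<double*>(dc.memptr()), H * W, dc.n_slices,
                  false, true);
  Rcpp::NumericVector dxr = alloc_array(H, W, Cin);
  cube dx(dxr.begin(), H, W, Cin, false, true);
  mat dw;
  if (k == 1) {
    const mat xm(const_cast<double*>(xc.memptr()), H * W, Cin, false, true);
    dw = xm.t() * doutm;
    mat dxm(dxr.begin(), H * W, Cin, false, true);
    dxm = doutm * w.t();
  } else {
    mat cols(H * W, w.n_rows, fill::none);
    im2col_same(xc, k, cols);
    dw = cols.t() * doutm;
    cols = doutm * w.t();  // reuse the buffer for dcols
    col2im_same_add(dx, cols, k);
  }
  vec db = sum(doutm, 0).t();
  return Rcpp::List::create(Rcpp::Named("dx") = dxr, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool2(Rcpp::NumericVector x) {
  const cube xc = view_cube(x);
  const uword H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  Rcpp::NumericVector yr = alloc_array(Ho, Wo, C);
  cube y(yr.begin(), Ho, Wo, C, false, true);
  arma::umat idx(Ho * Wo, C);  // linear index into an H x W slice
  for (uword c = 0; c < C; ++c) {
    const mat& xs = xc.slice(c);
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        const uword i0 = 2 * i, j0 = 2 * j;
        double best = xs(i0, j0);
        uword bi = i0, bj = j0;
        if (xs(i0 + 1, j0) > best) { best = xs(i0 + 1, j0); bi = i0 + 1; }
        if (xs(i0, j0 + 1) > best) { best = xs(i0, j0 + 1); bi = i0; bj = j0 + 1; }
        if (xs(i0 + 1, j0 + 1) > best) { best = xs(i0 + 1, j0 + 1); bi = i0 + 1; bj = j0 + 1; }
        y(i, j, c) = best;
        idx(j * Ho + i, c) = bj * H + bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = yr, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_maxpool2_grad(Rcpp::NumericVector dy,
                                      const arma::umat& idx, const int H,
                                      const int W) {
  const cube dc = view_cube(dy);
  const uword C = dc.n_slices, Ho = dc.n_rows, Wo = dc.n_cols;
  Rcpp::NumericVector dxr = alloc_array(H, W, C);
  cube dx(dxr.begin(), H, W, C, false, true);
  dx.zeros();
  for (uword c = 0; c < C; ++c) {
    double* dxs = dx.slice_memptr(c);
    const mat& dys = dc.slice(c);
    for (uword j = 0; j < Wo; ++j)
      for (uword i = 0; i < Ho; ++i)
        dxs[idx(j * Ho + i, c)] += dys(i, j);
  }
  return dxr;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_upsample2(Rcpp::NumericVector x) {
  const cube xc = view_cube(x);
  const uword H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  Rcpp::NumericVector yr = alloc_array(2 * H, 2 * W, C);
  cube y(yr.begin(), 2 * H, 2 * W, C, false, true);
  for (uword c = 0; c < C; ++c) {
    const mat& xs = xc.slice(c);
    mat& ys = y.slice(c);
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        const double v = xs(i, j);
        ys(2 * i, 2 * j) = v;
        ys(2 * i + 1, 2 * j) = v;
        ys(2 * i, 2 * j + 1) = v;
        ys(2 * i + 1, 2 * j + 1) = v;
      }
  }
  return yr;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_upsample2_grad(Rcpp::NumericVector dy) {
  const cube dc = view_cube(dy);
  const uword H = dc.n_rows / 2, W = dc.n_cols / 2, C = dc.n_slices;
  Rcpp::NumericVector dxr = alloc_array(H, W, C);
  cube dx(dxr.begin(), H, W, C, false, true);
  for (uword c = 0; c < C; ++c) {
    const mat& dys = dc.slice(c);
    mat& dxs = dx.slice(c);
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i)
        dxs(i, j) = dys(2 * i, 2 * j) + dys(2 * i + 1, 2 * j) +
                    dys(2 * i, 2 * j + 1) + dys(2 * i + 1, 2 * j + 1);
  }
  return dxr;
}
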