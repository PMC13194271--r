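// Volumetric convolution and interpolation kernels for the white-reference
// predictor. Feature maps are (n_voxels x n_channels) matrices with voxel
// linear index v = d + D*(h + H*w) (spectral axis fastest). Convolution is
// im2col + GEMM in single precision, chunked over output voxels to bound
// memory; the patch matrix is stored transposed (patch rows x voxel
// columns) so the fill writes contiguously. Weight matrices have rows
// indexed by (ci, kd, kh, kw) with the input channel fastest:
// r = ci + Cin*(kd + KD*(kh + KH*kw)). 1x1x1 stride-1 convolutions
// (residual projections) bypass im2col entirely.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

static const arma::uword CHUNK = 8192;

static arma::fmat to_fmat(const NumericMatrix& X) {
  arma::fmat Y(X.nrow(), X.ncol());
  std::copy(X.begin(), X.end(), Y.begin());
  return Y;
}

struct ConvGeom {
  int D, H, W, KD, KH, KW, s, pd, ph, pw, OD, OH, OW, Cin, Cout;
};

static inline int out_extent(int n, int k, int p, int s) {
  return (n + 2 * p - k) / s + 1;
}

static ConvGeom make_geom(int D, int H, int W, int Cin, int Cout,
                          int KD, int KH, int KW, int stride,
                          int pd, int ph, int pw) {
  ConvGeom g;
  g.D = D; g.H = H; g.W = W; g.KD = KD; g.KH = KH; g.KW = KW;
  g.s = stride; g.pd = pd; g.ph = ph; g.pw = pw;
  g.OD = out_extent(D, KD, pd, stride);
  g.OH = out_extent(H, KH, ph, stride);
  g.OW = out_extent(W, KW, pw, stride);
  g.Cin = Cin; g.Cout = Cout;
  if (g.OD < 1 || g.OH < 1 || g.OW < 1)
    stop("conv3d: input extent too small for kernel/stride");
  return g;
}

static inline bool is_pointwise(const ConvGeom& g) {
  return g.KD == 1 && g.KH == 1 && g.KW == 1 && g.s == 1;
}

// Fill the transposed im2col chunk: colT(ci + Cin*koff, r) for output
// voxels [v0, v0+cols). Xt is channel-major (Cin x n_voxels) so each patch
// entry is a contiguous run of Cin floats; writes run down each column.
static void fill_colsT(const arma::fmat& Xt, arma::fmat& colT,
                       const ConvGeom& g, arma::uword v0, arma::uword cols) {
  const float* xp = Xt.memptr();
  float* cp = colT.memptr();
  const arma::uword crows = colT.n_rows;
  for (arma::uword r = 0; r < cols; ++r) {
    arma::uword v = v0 + r;
    int od = v % g.OD;
    int oh = (v / g.OD) % g.OH;
    int ow = v / (g.OD * g.OH);
    int id0 = od * g.s - g.pd, ih0 = oh * g.s - g.ph, iw0 = ow * g.s - g.pw;
    float* col = cp + r * crows;
    for (int kw = 0; kw < g.KW; ++kw) {
      int iw = iw0 + kw;
      bool okw = iw >= 0 && iw < g.W;
      for (int kh = 0; kh < g.KH; ++kh) {
        int ih = ih0 + kh;
        bool okh = okw && ih >= 0 && ih < g.H;
        for (int kd = 0; kd < g.KD; ++kd) {
          int id = id0 + kd;
          int koff = kd + g.KD * (kh + g.KH * kw);
          float* dst = col + (arma::uword)g.Cin * koff;
          if (okh && id >= 0 && id < g.D) {
            arma::uword src = id + g.D * (ih + (arma::uword)g.H * iw);
            std::memcpy(dst, xp + src * (arma::uword)g.Cin,
                        g.Cin * sizeof(float));
          } else {
            std::memset(dst, 0, g.Cin * sizeof(float));
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3d_fwd(const NumericMatrix& Xr, IntegerVector dims,
                             const NumericMatrix& Wr, NumericVector br,
                             IntegerVector kernel, int stride,
                             IntegerVector pad) {
  int Cin = Xr.ncol(), Cout = Wr.ncol();
  ConvGeom g = make_geom(dims[0], dims[1], dims[2], Cin, Cout,
                         kernel[0], kernel[1], kernel[2], stride,
                         pad[0], pad[1], pad[2]);
  if ((int)Wr.nrow() != Cin * g.KD * g.KH * g.KW)
    stop("conv3d: weight rows do not match Cin * kernel volume");
  arma::fmat X = to_fmat(Xr);
  arma::fmat Wm = to_fmat(Wr);
  arma::frowvec b(br.size());
  std::copy(br.begin(), br.end(), b.begin());

  arma::uword n_out = (arma::uword)g.OD * g.OH * g.OW;
  arma::fmat out;
  if (is_pointwise(g)) {
    out = X * Wm;
  } else {
    arma::fmat Xt = X.t();
    out.set_size(n_out, Cout);
    arma::fmat colT;
    for (arma::uword v0 = 0; v0 < n_out; v0 += CHUNK) {
      arma::uword cols = std::min(CHUNK, n_out - v0);
      colT.set_size(Wm.n_rows, cols);
      fill_colsT(Xt, colT, g, v0, cols);
      out.rows(v0, v0 + cols - 1) = colT.t() * Wm;
    }
  }
  out.each_row() += b;
  NumericMatrix res(n_out, Cout);
  std::copy(out.begin(), out.end(), res.begin());
  res.attr("out_dims") = IntegerVector::create(g.OD, g.OH, g.OW);
  return res;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(const NumericMatrix& Xr, IntegerVector dims,
                    const NumericMatrix& dYr, const NumericMatrix& Wr,
                    IntegerVector kernel, int stride, IntegerVector pad,
                    bool want_dx = true) {
  int Cin = Xr.ncol(), Cout = Wr.ncol();
  ConvGeom g = make_geom(dims[0], dims[1], dims[2], Cin, Cout,
                         kernel[0], kernel[1], kernel[2], stride,
                         pad[0], pad[1], pad[2]);
  arma::fmat X = to_fmat(Xr);
  arma::fmat dY = to_fmat(dYr);
  arma::fmat Wm = to_fmat(Wr);

  arma::uword n_out = (arma::uword)g.OD * g.OH * g.OW;
  if (dY.n_rows != n_out) stop("conv3d backward: dY voxel count mismatch");
  arma::fmat dW(Wm.n_rows, Cout, arma::fill::zeros);
  arma::fmat dX(X.n_rows, Cin, arma::fill::zeros);
  if (is_pointwise(g)) {
    dW = X.t() * dY;
    if (want_dx) dX = dY * Wm.t();
  } else {
    arma::fmat Xt = X.t();
    arma::fmat colT;
    for (arma::uword v0 = 0; v0 < n_out; v0 += CHUNK) {
      arma::uword cols = std::min(CHUNK, n_out - v0);
      colT.set_size(Wm.n_rows, cols);
      fill_colsT(Xt, colT, g, v0, cols);
      dW += colT * dY.rows(v0, v0 + cols - 1);
    }
    if (want_dx && g.s == 1) {
      // stride 1: dX is a correlation of dY with the spatially flipped
      // kernel and swapped channel roles -- reuse the gather + GEMM path
      arma::fmat Wf((arma::uword)Cout * g.KD * g.KH * g.KW, Cin);
      for (int kw = 0; kw < g.KW; ++kw)
        for (int kh = 0; kh < g.KH; ++kh)
          for (int kd = 0; kd < g.KD; ++kd) {
            int koff = kd + g.KD * (kh + g.KH * kw);
            int kflip = (g.KD - 1 - kd) +
              g.KD * ((g.KH - 1 - kh) + g.KH * (g.KW - 1 - kw));
            for (int ci = 0; ci < Cin; ++ci)
              for (int co = 0; co < Cout; ++co)
                Wf(co + (arma::uword)Cout * kflip, ci) =
                  Wm(ci + (arma::uword)Cin * koff, co);
          }
      ConvGeom gb = make_geom(g.OD, g.OH, g.OW, Cout, Cin,
                              g.KD, g.KH, g.KW, 1,
                              g.KD - 1 - g.pd, g.KH - 1 - g.ph,
                              g.KW - 1 - g.pw);
      arma::fmat dYt = dY.t();
      arma::uword n_in = X.n_rows;
      for (arma::uword v0 = 0; v0 < n_in; v0 += CHUNK) {
        arma::uword cols = std::min(CHUNK, n_in - v0);
        colT.set_size(Wf.n_rows, cols);
        fill_colsT(dYt, colT, gb, v0, cols);
        dX.rows(v0, v0 + cols - 1) = colT.t() * Wf;
      }
    } else if (want_dx) {
      arma::fmat dXt(Cin, X.n_rows, arma::fill::zeros);
      float* dxp = dXt.memptr();
      arma::fmat dcolT;
      for (arma::uword v0 = 0; v0 < n_out; v0 += CHUNK) {
        arma::uword cols = std::min(CHUNK, n_out - v0);
        arma::fmat dYc = dY.rows(v0, v0 + cols - 1);
        dcolT = Wm * dYc.t();     // (Cin*K3) x cols
        const float* dcp = dcolT.memptr();
        const arma::uword crows = dcolT.n_rows;
        for (arma::uword r = 0; r < cols; ++r) {
          arma::uword v = v0 + r;
          int od = v % g.OD;
          int oh = (v / g.OD) % g.OH;
          int ow = v / (g.OD * g.OH);
          int id0 = od * g.s - g.pd, ih0 = oh * g.s - g.ph,
              iw0 = ow * g.s - g.pw;
          const float* col = dcp + r * crows;
          for (int kw = 0; kw < g.KW; ++kw) {
            int iw = iw0 + kw;
            if (iw < 0 || iw >= g.W) continue;
            for (int kh = 0; kh < g.KH; ++kh) {
              int ih = ih0 + kh;
              if (ih < 0 || ih >= g.H) continue;
              for (int kd = 0; kd < g.KD; ++kd) {
                int id = id0 + kd;
                if (id < 0 || id >= g.D) continue;
                int koff = kd + g.KD * (kh + g.KH * kw);
                const float* src = col + (arma::uword)g.Cin * koff;
                arma::uword dst = id + g.D * (ih + (arma::uword)g.H * iw);
                float* dp = dxp + dst * (arma::uword)g.Cin;
                for (int ci = 0; ci < g.Cin; ++ci)
                  dp[ci] += src[ci];
              }
            }
          }
        }
      }
      dX = dXt.t();
    }
  }
  arma::frowvec db = arma::sum(dY, 0);
  NumericMatrix dXr(dX.n_rows, Cin), dWr(dW.n_rows, Cout);
  NumericVector dbr(Cout);
  std::copy(dX.begin(), dX.end(), dXr.begin());
  std::copy(dW.begin(), dW.end(), dWr.begin());
  std::copy(db.begin(), db.end(), dbr.begin());
  return List::create(_["dX"] = dXr, _["dW"] = dWr, _["db"] = dbr);
}

struct AxisMap {
  std::vector<int> i0, i1;
  std::vector<float> w1;
};

static AxisMap axis_map(int n_in, int n_out) {
  AxisMap m;
  m.i0.resize(n_out); m.i1.resize(n_out); m.w1.resize(n_out);
  for (int o = 0; o < n_out; ++o) {
    double f = (o + 0.5) * (double)n_in / n_out - 0.5;
    if (f < 0) f = 0;
    if (f > n_in - 1) f = n_in - 1;
    int i0 = (int)std::floor(f);
    m.i0[o] = i0;
    m.i1[o] = std::min(i0 + 1, n_in - 1);
    m.w1[o] = (float)(f - i0);
  }
  return m;
}

// Trilinear interpolation to an arbitrary target extent per axis.
// [[Rcpp::export]]
NumericMatrix cpp_upsample3d(const NumericMatrix& Xr, IntegerVector in_dims,
                             IntegerVector out_dims) {
  int D = in_dims[0], H = in_dims[1], W = in_dims[2];
  int OD = out_dims[0], OH = out_dims[1], OW = out_dims[2];
  int C = Xr.ncol();
  arma::fmat X = to_fmat(Xr);
  AxisMap md = axis_map(D, OD), mh = axis_map(H, OH), mw = axis_map(W, OW);
  arma::uword n_out = (arma::uword)OD * OH * OW;
  arma::fmat out(n_out, C, arma::fill::zeros);
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      for (int od = 0; od < OD; ++od) {
        arma::uword v = od + (arma::uword)OD * (oh + (arma::uword)OH * ow);
        for (int cw = 0; cw < 2; ++cw) {
          int iw = cw ? mw.i1[ow] : mw.i0[ow];
          float fw = cw ? mw.w1[ow] : 1.0f - mw.w1[ow];
          if (fw == 0.0f) continue;
          for (int ch = 0; ch < 2; ++ch) {
            int ih = ch ? mh.i1[oh] : mh.i0[oh];
            float fh = ch ? mh.w1[oh] : 1.0f - mh.w1[oh];
            if (fh == 0.0f) continue;
            for (int cd = 0; cd < 2; ++cd) {
              int id = cd ? md.i1[od] : md.i0[od];
              float fd = cd ? md.w1[od] : 1.0f - md.w1[od];
              if (fd == 0.0f) continue;
              arma::uword src = id + (arma::uword)D *
                (ih + (arma::uword)H * iw);
              out.row(v) += (fw * fh * fd) * X.row(src);
            }
          }
        }
      }
    }
  }
  NumericMatrix res(n_out, C);
  std::copy(out.begin(), out.end(), res.begin());
  return res;
}

// [[Rcpp::export]]
NumericMatrix cpp_upsample3d_bwd(const NumericMatrix& dYr,
                                 IntegerVector in_dims,
                                 IntegerVector out_dims) {
  int D = in_dims[0], H = in_dims[1], W = in_dims[2];
  int OD = out_dims[0], OH = out_dims[1], OW = out_dims[2];
  int C = dYr.ncol();
  arma::fmat dY = to_fmat(dYr);
  AxisMap md = axis_map(D, OD), mh = axis_map(H, OH), mw = axis_map(W, OW);
  arma::fmat dX((arma::uword)D * H * W, C, arma::fill::zeros);
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      for (int od = 0; od < OD; ++od) {
        arma::uword v = od + (arma::uword)OD * (oh + (arma::uword)OH * ow);
        for (int cw = 0; cw < 2; ++cw) {
          int iw = cw ? mw.i1[ow] : mw.i0[ow];
          float fw = cw ? mw.w1[ow] : 1.0f - mw.w1[ow];
          if (fw == 0.0f) continue;
          for (int ch = 0; ch < 2; ++ch) {
            int ih = ch ? mh.i1[oh] : mh.i0[oh];
            float fh = ch ? mh.w1[oh] : 1.0f - mh.w1[oh];
            if (fh == 0.0f) continue;
            for (int cd = 0; cd < 2; ++cd) {
              int id = cd ? md.i1[od] : md.i0[od];
              float fd = cd ? md.w1[od] : 1.0f - md.w1[od];
              if (fd == 0.0f) continue;
              arma::uword src = id + (arma::uword)D *
                (ih + (arma::uword)H * iw);
              dX.row(src) += (fw * fh * fd) * dY.row(v);
            }
          }
        }
      }
    }
  }
  NumericMatrix res(dX.n_rows, C);
  std::copy(dX.begin(), dX.end(), res.begin());
  return res;
}
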