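// Spatio-temporal convolution / pooling kernels for the motion-estimation
// networks.  Layout conventions (column-major, first index fastest):
//   activations x : (X, Y, Z, T, C, B)   B = batch, C = channels
//   weights     w : (KX, KY, KZ, KT, Cin, Cout)
// A pure 3D convolution is the T = 1, KT = 1 case of the same kernel.
//
// "same" padding: spatial kernels centred (KX,KY,KZ odd), temporal padding
// causal (output at time t sees input times t-KT+1 .. t).  "valid" padding
// shrinks every convolved axis.
//
// The convolution is evaluated chunk-wise as im2col + GEMM; the backward
// pass re-packs the same patch matrix to form the weight gradient and
// scatter-adds dY * W^T back through the packing (col2im).  Both a double
// and a single precision instantiation are compiled: double for the
// reference conv4d operator and gradient checks, single for training.

#include <RcppArmadillo.h>
#include <memory>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ConvDims {
  int X, Y, Z, T, Cin, B;       // input
  int KX, KY, KZ, KT, Cout;     // kernel
  int Xo, Yo, Zo, To;           // output
  int px, py, pz, pt;           // padding offsets (input idx = out + k - p)
  int Min, Mout, K;             // voxels per channel (in/out), patch length

  ConvDims(const IntegerVector& xdim, const IntegerVector& wdim, bool same) {
    X = xdim[0]; Y = xdim[1]; Z = xdim[2]; T = xdim[3];
    Cin = xdim[4]; B = xdim[5];
    KX = wdim[0]; KY = wdim[1]; KZ = wdim[2]; KT = wdim[3];
    Cout = wdim[5];
    if (wdim[4] != Cin) stop("kernel input channels (%d) do not match input (%d)",
                             (int)wdim[4], Cin);
    if (same) {
      if (KX % 2 == 0 || KY % 2 == 0 || KZ % 2 == 0)
        stop("'same' padding requires odd spatial kernel sizes");
      px = (KX - 1) / 2; py = (KY - 1) / 2; pz = (KZ - 1) / 2;
      pt = KT - 1;  // causal: pad past time steps only
      Xo = X; Yo = Y; Zo = Z; To = T;
    } else {
      px = py = pz = pt = 0;
      Xo = X - KX + 1; Yo = Y - KY + 1; Zo = Z - KZ + 1; To = T - KT + 1;
      if (Xo < 1 || Yo < 1 || Zo < 1 || To < 1)
        stop("kernel larger than input under 'valid' padding");
    }
    Min = X * Y * Z * T;
    Mout = Xo * Yo * Zo * To;
    K = KX * KY * KZ * KT * Cin;
  }
};

// The convolution is evaluated per sample as a sum over kernel offsets of
// small GEMMs on zero-padded buffers: Y (Mout x Cout) += G_o (Mout x Cin) *
// W_o (Cin x Cout), where G_o gathers the padded input at offset o. The
// gather buffers stay cache-resident at the layer sizes used here, which is
// what makes this faster than materializing the full im2col patch matrix.
// The backward pass reuses the same gather: dW_o = G_o^T * dY, and dX is the
// transposed convolution, i.e. the same offset-GEMM applied to the padded
// output gradient with the mirrored kernel.

// copy one sample (src, dims idim x C) into a zero-padded buffer
template <typename eT>
void pad_sample(const eT* src, const int idim[4], int C, const int padlo[4],
                const int pdim[4], arma::Col<eT>& out) {
  out.zeros();
  const size_t pvol = (size_t)pdim[0] * pdim[1] * pdim[2] * pdim[3];
  const size_t ivol = (size_t)idim[0] * idim[1] * idim[2] * idim[3];
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < idim[3]; ++t)
    for (int z = 0; z < idim[2]; ++z)
    for (int y = 0; y < idim[1]; ++y) {
      const eT* s = src + c * ivol +
        (size_t)idim[0] * (y + (size_t)idim[1] * (z + (size_t)idim[2] * t));
      eT* o = out.memptr() + c * pvol + padlo[0] +
        (size_t)pdim[0] * ((y + padlo[1]) +
        (size_t)pdim[1] * ((z + padlo[2]) + (size_t)pdim[2] * (t + padlo[3])));
      std::copy(s, s + idim[0], o);
    }
}

// gather padded source at a fixed offset into G (M x C), M = prod(odim)
template <typename eT>
void gather_offset(const arma::Col<eT>& pad, const int pdim[4], int C,
                   const int off[4], const int odim[4], arma::Mat<eT>& G) {
  const size_t pvol = (size_t)pdim[0] * pdim[1] * pdim[2] * pdim[3];
  const int Xo = odim[0];
  for (int c = 0; c < C; ++c) {
    eT* dst = G.colptr(c);
    const eT* base = pad.memptr() + c * pvol;
    for (int t = 0; t < odim[3]; ++t)
    for (int z = 0; z < odim[2]; ++z)
    for (int y = 0; y < odim[1]; ++y) {
      const eT* s = base + off[0] +
        (size_t)pdim[0] * ((y + off[1]) +
        (size_t)pdim[1] * ((z + off[2]) + (size_t)pdim[2] * (t + off[3])));
      std::copy(s, s + Xo, dst);
      dst += Xo;
    }
  }
}

// per-offset Cin x Cout weight slices, in (kx, ky, kz, kt) order
template <typename eT>
std::vector<arma::Mat<eT>> offset_weights(const arma::Mat<eT>& Wm,
                                          const ConvDims& d) {
  const int noff = d.KX * d.KY * d.KZ * d.KT;
  const int kvol = noff;
  std::vector<arma::Mat<eT>> Wo(noff);
  for (int o = 0; o < noff; ++o) {
    Wo[o].set_size(d.Cin, d.Cout);
    for (int c = 0; c < d.Cin; ++c)
      for (int q = 0; q < d.Cout; ++q)
        Wo[o](c, q) = Wm(o + kvol * c, q);
  }
  return Wo;
}

template <typename eT>
void conv_forward(const arma::Col<eT>& x, const arma::Mat<eT>& Wm,
                  const arma::Col<eT>& bias, const ConvDims& d,
                  arma::Col<eT>& y) {
  const int idim[4] = {d.X, d.Y, d.Z, d.T};
  const int odim[4] = {d.Xo, d.Yo, d.Zo, d.To};
  const int padlo[4] = {d.px, d.py, d.pz, d.pt};
  const int pdim[4] = {d.Xo + d.KX - 1, d.Yo + d.KY - 1, d.Zo + d.KZ - 1,
                       d.To + d.KT - 1};
  std::vector<arma::Mat<eT>> Wo = offset_weights(Wm, d);
  arma::Col<eT> pad((size_t)pdim[0] * pdim[1] * pdim[2] * pdim[3] * d.Cin);
  arma::Mat<eT> G(d.Mout, d.Cin);
  for (int b = 0; b < d.B; ++b) {
    pad_sample(x.memptr() + (size_t)b * d.Min * d.Cin, idim, d.Cin, padlo,
               pdim, pad);
    arma::Mat<eT> Yv(y.memptr() + (size_t)b * d.Mout * d.Cout, d.Mout, d.Cout,
                     false, true);
    Yv.zeros();
    int o = 0;
    for (int kt = 0; kt < d.KT; ++kt)
    for (int kz = 0; kz < d.KZ; ++kz)
    for (int ky = 0; ky < d.KY; ++ky)
    for (int kx = 0; kx < d.KX; ++kx, ++o) {
      const int off[4] = {kx, ky, kz, kt};
      const int oi = kx + d.KX * (ky + d.KY * (kz + d.KZ * kt));
      gather_offset(pad, pdim, d.Cin, off, odim, G);
      Yv += G * Wo[oi];
    }
    Yv.each_row() += bias.t();
  }
}

template <typename eT>
void conv_backward(const arma::Col<eT>& x, const arma::Mat<eT>& Wm,
                   const arma::Col<eT>& dy, const ConvDims& d, bool need_dx,
                   arma::Col<eT>& dx, arma::Mat<eT>& dW, arma::Col<eT>& db) {
  const int idim[4] = {d.X, d.Y, d.Z, d.T};
  const int odim[4] = {d.Xo, d.Yo, d.Zo, d.To};
  const int padlo[4] = {d.px, d.py, d.pz, d.pt};
  const int pdim[4] = {d.Xo + d.KX - 1, d.Yo + d.KY - 1, d.Zo + d.KZ - 1,
                       d.To + d.KT - 1};
  // padding of dY for the transposed convolution: mirrored offsets
  const int qlo[4] = {d.KX - 1 - d.px, d.KY - 1 - d.py, d.KZ - 1 - d.pz,
                      d.KT - 1 - d.pt};
  const int qdim[4] = {d.X + d.KX - 1, d.Y + d.KY - 1, d.Z + d.KZ - 1,
                       d.T + d.KT - 1};
  std::vector<arma::Mat<eT>> Wo = offset_weights(Wm, d);
  const int noff = d.KX * d.KY * d.KZ * d.KT;
  std::vector<arma::Mat<eT>> dWo(noff, arma::Mat<eT>(d.Cin, d.Cout,
                                                     arma::fill::zeros));
  db.zeros(d.Cout);
  if (need_dx) dx.zeros(x.n_elem);
  arma::Col<eT> pad((size_t)pdim[0] * pdim[1] * pdim[2] * pdim[3] * d.Cin);
  arma::Col<eT> qpad(need_dx ?
      (size_t)qdim[0] * qdim[1] * qdim[2] * qdim[3] * d.Cout : 1);
  arma::Mat<eT> G(d.Mout, d.Cin);
  arma::Mat<eT> Gq(need_dx ? d.Min : 1, need_dx ? d.Cout : 1);
  for (int b = 0; b < d.B; ++b) {
    const eT* xs = x.memptr() + (size_t)b * d.Min * d.Cin;
    pad_sample(xs, idim, d.Cin, padlo, pdim, pad);
    arma::Mat<eT> dYv(const_cast<eT*>(dy.memptr()) + (size_t)b * d.Mout * d.Cout,
                      d.Mout, d.Cout, false, true);
    db += arma::sum(dYv, 0).t();
    if (need_dx)
      pad_sample(dy.memptr() + (size_t)b * d.Mout * d.Cout, odim, d.Cout,
                 qlo, qdim, qpad);
    std::unique_ptr<arma::Mat<eT>> dXv;
    if (need_dx)
      dXv.reset(new arma::Mat<eT>(dx.memptr() + (size_t)b * d.Min * d.Cin,
                                  d.Min, d.Cin, false, true));
    int o = 0;
    for (int kt = 0; kt < d.KT; ++kt)
    for (int kz = 0; kz < d.KZ; ++kz)
    for (int ky = 0; ky < d.KY; ++ky)
    for (int kx = 0; kx < d.KX; ++kx, ++o) {
      const int oi = kx + d.KX * (ky + d.KY * (kz + d.KZ * kt));
      const int off[4] = {kx, ky, kz, kt};
      gather_offset(pad, pdim, d.Cin, off, odim, G);
      dWo[oi] += G.t() * dYv;
      if (need_dx) {
        const int moff[4] = {d.KX - 1 - kx, d.KY - 1 - ky, d.KZ - 1 - kz,
                             d.KT - 1 - kt};
        gather_offset(qpad, qdim, d.Cout, moff, idim, Gq);
        *dXv += Gq * Wo[oi].t();
      }
    }
  }
  dW.set_size(d.K, d.Cout);
  for (int o = 0; o < noff; ++o)
    for (int c = 0; c < d.Cin; ++c)
      for (int q = 0; q < d.Cout; ++q)
        dW(o + noff * c, q) = dWo[o](c, q);
}

// ---- average pooling -------------------------------------------------------
// Spatial axes pooled by 'factor' (must divide X, Y, Z); time pooled by the
// same factor when pool_time, with a shorter trailing window when T is not
// divisible (ceil semantics, mean over the true window size).

struct PoolDims {
  int X, Y, Z, T, C, B, f, Xo, Yo, Zo, To;
  bool pt;
  PoolDims(const IntegerVector& xdim, int factor, bool pool_time) {
    X = xdim[0]; Y = xdim[1]; Z = xdim[2]; T = xdim[3]; C = xdim[4]; B = xdim[5];
    f = factor; pt = pool_time;
    if (X % f || Y % f || Z % f)
      stop("spatial size (%d,%d,%d) not divisible by pool factor %d", X, Y, Z, f);
    Xo = X / f; Yo = Y / f; Zo = Z / f;
    To = pt ? (T + f - 1) / f : T;
  }
};

template <typename eT>
void pool_forward(const arma::Col<eT>& x, const PoolDims& p, arma::Col<eT>& y) {
  const size_t Mi = (size_t)p.X * p.Y * p.Z * p.T;
  const size_t Mo = (size_t)p.Xo * p.Yo * p.Zo * p.To;
  for (int cb = 0; cb < p.C * p.B; ++cb) {
    const eT* xs = x.memptr() + cb * Mi;
    eT* ys = y.memptr() + cb * Mo;
    for (int to = 0; to < p.To; ++to) {
      const int t0 = p.pt ? to * p.f : to;
      const int tw = p.pt ? std::min(p.f, p.T - t0) : 1;
      for (int zo = 0; zo < p.Zo; ++zo)
      for (int yo = 0; yo < p.Yo; ++yo)
      for (int xo = 0; xo < p.Xo; ++xo) {
        eT acc = 0;
        for (int dt = 0; dt < tw; ++dt)
        for (int dz = 0; dz < p.f; ++dz)
        for (int dy = 0; dy < p.f; ++dy)
        for (int dx = 0; dx < p.f; ++dx)
          acc += xs[(size_t)(xo * p.f + dx) +
                    (size_t)p.X * ((yo * p.f + dy) +
                    (size_t)p.Y * ((zo * p.f + dz) + (size_t)p.Z * (t0 + dt)))];
        ys[(size_t)xo + (size_t)p.Xo * (yo + (size_t)p.Yo * (zo + (size_t)p.Zo * to))] =
            acc / eT(tw * p.f * p.f * p.f);
      }
    }
  }
}

template <typename eT>
void pool_backward(const arma::Col<eT>& dy, const PoolDims& p, arma::Col<eT>& dx) {
  const size_t Mi = (size_t)p.X * p.Y * p.Z * p.T;
  const size_t Mo = (size_t)p.Xo * p.Yo * p.Zo * p.To;
  dx.zeros((size_t)Mi * p.C * p.B);
  for (int cb = 0; cb < p.C * p.B; ++cb) {
    eT* dxs = dx.memptr() + cb * Mi;
    const eT* dys = dy.memptr() + cb * Mo;
    for (int to = 0; to < p.To; ++to) {
      const int t0 = p.pt ? to * p.f : to;
      const int tw = p.pt ? std::min(p.f, p.T - t0) : 1;
      for (int zo = 0; zo < p.Zo; ++zo)
      for (int yo = 0; yo < p.Yo; ++yo)
      for (int xo = 0; xo < p.Xo; ++xo) {
        const eT g = dys[(size_t)xo + (size_t)p.Xo *
                         (yo + (size_t)p.Yo * (zo + (size_t)p.Zo * to))] /
                     eT(tw * p.f * p.f * p.f);
        for (int dt = 0; dt < tw; ++dt)
        for (int dz = 0; dz < p.f; ++dz)
        for (int dy2 = 0; dy2 < p.f; ++dy2)
        for (int dx2 = 0; dx2 < p.f; ++dx2)
          dxs[(size_t)(xo * p.f + dx2) +
              (size_t)p.X * ((yo * p.f + dy2) +
              (size_t)p.Y * ((zo * p.f + dz) + (size_t)p.Z * (t0 + dt)))] += g;
      }
    }
  }
}

template <typename eT>
arma::Col<eT> as_col(const NumericVector& v) {
  arma::Col<eT> out(v.size());
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

NumericVector to_numeric(const arma::Col<double>& v) {
  return NumericVector(v.begin(), v.end());
}
NumericVector to_numeric(const arma::Col<float>& v) {
  NumericVector out(v.n_elem);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

template <typename eT>
NumericVector conv_fwd_impl(const NumericVector& x, const IntegerVector& xdim,
                            const NumericVector& w, const IntegerVector& wdim,
                            const NumericVector& bias, bool same) {
  ConvDims d(xdim, wdim, same);
  if ((R_xlen_t)d.Min * d.Cin * d.B != x.size()) stop("input length mismatch");
  if ((R_xlen_t)d.K * d.Cout != w.size()) stop("weight length mismatch");
  arma::Col<eT> xa = as_col<eT>(x), wa = as_col<eT>(w), ba = as_col<eT>(bias);
  arma::Mat<eT> Wm(wa.memptr(), d.K, d.Cout, false, true);
  arma::Col<eT> y((size_t)d.Mout * d.Cout * d.B);
  conv_forward(xa, Wm, ba, d, y);
  NumericVector out = to_numeric(y);
  out.attr("dim") = IntegerVector::create(d.Xo, d.Yo, d.Zo, d.To, d.Cout, d.B);
  return out;
}

template <typename eT>
List conv_bwd_impl(const NumericVector& x, const IntegerVector& xdim,
                   const NumericVector& w, const IntegerVector& wdim,
                   const NumericVector& dy, bool need_dx, bool same) {
  ConvDims d(xdim, wdim, same);
  arma::Col<eT> xa = as_col<eT>(x), wa = as_col<eT>(w), dya = as_col<eT>(dy);
  if ((R_xlen_t)d.Mout * d.Cout * d.B != dy.size()) stop("dy length mismatch");
  arma::Mat<eT> Wm(wa.memptr(), d.K, d.Cout, false, true);
  arma::Col<eT> dx;
  arma::Mat<eT> dW;
  arma::Col<eT> db;
  conv_backward(xa, Wm, dya, d, need_dx, dx, dW, db);
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wdim;
  List out = List::create(_["dw"] = dwv,
                          _["db"] = NumericVector(db.begin(), db.end()));
  if (need_dx) {
    NumericVector dxv = to_numeric(dx);
    dxv.attr("dim") = xdim;
    out["dx"] = dxv;
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector xdim, NumericVector w,
                           IntegerVector wdim, NumericVector bias, bool same,
                           bool single) {
  return single ? conv_fwd_impl<float>(x, xdim, w, wdim, bias, same)
                : conv_fwd_impl<double>(x, xdim, w, wdim, bias, same);
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, IntegerVector xdim, NumericVector w,
                  IntegerVector wdim, NumericVector dy, bool need_dx, bool same,
                  bool single) {
  return single ? conv_bwd_impl<float>(x, xdim, w, wdim, dy, need_dx, same)
                : conv_bwd_impl<double>(x, xdim, w, wdim, dy, need_dx, same);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector out(x.size());
  const double* xi = x.begin();
  double* o = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) o[i] = xi[i] > 0 ? xi[i] : 0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  if (dy.size() != y.size()) stop("relu gradient size mismatch");
  NumericVector out(dy.size());
  const double* d = dy.begin();
  const double* yy = y.begin();
  double* o = out.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) o[i] = yy[i] > 0 ? d[i] : 0;
  out.attr("dim") = dy.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pool_fwd(NumericVector x, IntegerVector xdim, int factor,
                           bool pool_time) {
  PoolDims p(xdim, factor, pool_time);
  arma::Col<double> xa = as_col<double>(x);
  arma::Col<double> y((size_t)p.Xo * p.Yo * p.Zo * p.To * p.C * p.B);
  pool_forward(xa, p, y);
  NumericVector out = to_numeric(y);
  out.attr("dim") = IntegerVector::create(p.Xo, p.Yo, p.Zo, p.To, p.C, p.B);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pool_bwd(NumericVector dy, IntegerVector xdim, int factor,
                           bool pool_time) {
  PoolDims p(xdim, factor, pool_time);
  arma::Col<double> dya = as_col<double>(dy);
  arma::Col<double> dx;
  pool_backward(dya, p, dx);
  NumericVector out = to_numeric(dx);
  out.attr("dim") = xdim;
  return out;
}
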