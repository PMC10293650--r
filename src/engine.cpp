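// R-facing layer primitives.  These exist so the backpropagation of every
// layer type can be checked in isolation (against naive R convolutions and
// numeric gradients); training uses the fused network in net.cpp, which
// shares the same core.

// [[Rcpp::depends(RcppArmadillo)]]
#include "core.h"

using namespace Rcpp;
using namespace qsmdi;

// [[Rcpp::export(name = ".cn_conv3_fw")]]
NumericVector cn_conv3_fw(NumericVector x, NumericVector w, NumericVector b) {
  FTensor xt = from_r(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5) stop("weight must be a 5-D array");
  FTensor y;
  if (wd[0] == 1) {
    fmat W1(wd[3], wd[4]);
    const double* p = REAL(w);
    for (long i = 0; i < (long)w.size(); ++i) W1(i) = float(p[i]);
    conv1_fw(xt, W1, fvec_from_r(b), y);
  } else {
    conv3_fw(xt, conv_w_from_r(w), fvec_from_r(b), y, nullptr);
  }
  return to_r(y);
}

// [[Rcpp::export(name = ".cn_conv3_bw")]]
List cn_conv3_bw(NumericVector x, NumericVector w, NumericVector dy,
                 bool need_dx = true) {
  FTensor xt = from_r(x), dyt = from_r(dy);
  IntegerVector wd = w.attr("dim");
  FTensor dx;
  if (wd[0] == 1) {
    fmat W1(wd[3], wd[4]);
    const double* p = REAL(w);
    for (long i = 0; i < (long)w.size(); ++i) W1(i) = float(p[i]);
    fmat dW1; fvec db;
    conv1_bw(xt, W1, dyt, need_dx ? &dx : nullptr, dW1, db);
    NumericVector dwr(w.size());
    dwr.attr("dim") = w.attr("dim");
    for (long i = 0; i < (long)w.size(); ++i) dwr[i] = double(dW1(i));
    return List::create(_["dx"] = need_dx ? SEXP(to_r(dx)) : R_NilValue,
                        _["dw"] = dwr, _["db"] = fvec_to_r(db));
  }
  std::vector<fmat> W = conv_w_from_r(w), dW;
  std::vector<fmat> pads;
  FTensor ytmp;
  conv3_fw(xt, W, fvec(W[0].n_cols, arma::fill::zeros), ytmp, &pads);
  fvec db;
  conv3_bw(pads, W, dyt, need_dx ? &dx : nullptr, dW, db);
  return List::create(_["dx"] = need_dx ? SEXP(to_r(dx)) : R_NilValue,
                      _["dw"] = conv_w_to_r(dW), _["db"] = fvec_to_r(db));
}

// [[Rcpp::export(name = ".cn_convt3_fw")]]
NumericVector cn_convt3_fw(NumericVector x, NumericVector w, NumericVector b) {
  FTensor xt = from_r(x), y;
  convt3_fw(xt, convt_w_from_r(w), fvec_from_r(b), y);
  return to_r(y);
}

// [[Rcpp::export(name = ".cn_convt3_bw")]]
List cn_convt3_bw(NumericVector x, NumericVector w, NumericVector dy,
                  bool need_dx = true) {
  FTensor xt = from_r(x), dyt = from_r(dy), dx;
  fmat Wm = convt_w_from_r(w), dWm;
  fvec db;
  convt3_bw(xt, Wm, dyt, need_dx ? &dx : nullptr, dWm, db);
  return List::create(_["dx"] = need_dx ? SEXP(to_r(dx)) : R_NilValue,
                      _["dw"] = convt_w_to_r(dWm), _["db"] = fvec_to_r(db));
}

// [[Rcpp::export(name = ".cn_maxpool_fw")]]
List cn_maxpool_fw(NumericVector x) {
  FTensor xt = from_r(x), y;
  if (xt.nx % 2 || xt.ny % 2 || xt.nz % 2)
    stop("max pooling requires even spatial dimensions");
  std::vector<long> idx;
  maxpool_fw(xt, y, idx);
  IntegerVector ir(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) ir[i] = int(idx[i] + 1);
  return List::create(_["y"] = to_r(y), _["idx"] = ir);
}

// [[Rcpp::export(name = ".cn_maxpool_bw")]]
NumericVector cn_maxpool_bw(NumericVector dy, IntegerVector idx,
                            IntegerVector dim_in) {
  FTensor dyt = from_r(dy), dx;
  std::vector<long> ix(idx.size());
  for (R_xlen_t i = 0; i < idx.size(); ++i) ix[i] = idx[i] - 1;
  maxpool_bw(dyt, ix, dim_in[0], dim_in[1], dim_in[2], dx);
  return to_r(dx);
}

// [[Rcpp::export(name = ".cn_bn_fw")]]
List cn_bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
              NumericVector rmean, NumericVector rvar,
              double eps, double momentum, bool training) {
  FTensor xt = from_r(x), y;
  fvec rm = fvec_from_r(rmean), rv = fvec_from_r(rvar), mean, var;
  bn_fw(xt, fvec_from_r(gamma), fvec_from_r(beta), rm, rv,
        float(eps), float(momentum), training, y, mean, var);
  return List::create(_["y"] = to_r(y), _["mean"] = fvec_to_r(mean),
                      _["var"] = fvec_to_r(var), _["rmean"] = fvec_to_r(rm),
                      _["rvar"] = fvec_to_r(rv));
}

// [[Rcpp::export(name = ".cn_bn_bw")]]
List cn_bn_bw(NumericVector x, NumericVector dy, NumericVector gamma,
              NumericVector mean, NumericVector var, double eps) {
  FTensor xt = from_r(x), dyt = from_r(dy), dx;
  fvec dgamma, dbeta;
  bn_bw(xt, dyt, fvec_from_r(gamma), fvec_from_r(mean), fvec_from_r(var),
        float(eps), dx, dgamma, dbeta);
  return List::create(_["dx"] = to_r(dx), _["dgamma"] = fvec_to_r(dgamma),
                      _["dbeta"] = fvec_to_r(dbeta));
}

// [[Rcpp::export(name = ".cn_relu_fw")]]
NumericVector cn_relu_fw(NumericVector x) {
  FTensor xt = from_r(x);
  relu_fw(xt);
  return to_r(xt);
}

// [[Rcpp::export(name = ".cn_relu_bw")]]
NumericVector cn_relu_bw(NumericVector dy, NumericVector y) {
  FTensor dyt = from_r(dy), yt = from_r(y);
  relu_bw(yt, dyt);
  return to_r(dyt);
}

// Masked L1 and gradient-magnitude loss terms and their gradient for a
// batch (nx, ny, nz, 1, B) in one pass (the spectral model term is computed
// in R, where the FFT lives).  Forward differences with replicate boundary.
// [[Rcpp::export(name = ".cn_loss_terms")]]
List cn_loss_terms(NumericVector pred, NumericVector label, NumericVector mask,
                   double w_l1, double w_grad, bool grad) {
  IntegerVector d = pred.attr("dim");
  if (d.size() != 5) stop("expected a 5-D batch");
  const int nx = d[0], ny = d[1], nz = d[2], B = d[4];
  const long nv = (long)nx * ny * nz;
  const double* p = REAL(pred);
  const double* l = REAL(label);
  const double* m = REAL(mask);
  NumericVector l1_s(B), grad_s(B), S_s(B);
  NumericVector g;
  double* gp = nullptr;
  if (grad) {
    g = NumericVector(pred.size());
    g.attr("dim") = pred.attr("dim");
    gp = REAL(g);
  }
  const long strides[3] = {1, nx, (long)nx * ny};
  const int sizes[3] = {nx, ny, nz};
  for (int s = 0; s < B; ++s) {
    const double* ps = p + s * nv;
    const double* ls = l + s * nv;
    const double* ms = m + s * nv;
    double* gs = grad ? gp + s * nv : nullptr;
    double S = 0, acc1 = 0;
    for (long i = 0; i < nv; ++i) S += ms[i];
    if (S <= 0) stop("empty mask in batch sample");
    for (long i = 0; i < nv; ++i) {
      const double dv = ps[i] - ls[i];
      acc1 += ms[i] * std::fabs(dv);
      if (grad) gs[i] = w_l1 * ms[i] * (dv > 0 ? 1.0 : (dv < 0 ? -1.0 : 0.0));
    }
    double accg = 0;
    for (int a = 0; a < 3; ++a) {
      const long st = strides[a];
      for (long i = 0; i < nv; ++i) {
        // voxel index along axis a
        const long ia = (i / st) % sizes[a];
        double dp = 0, dl = 0;
        if (ia + 1 < sizes[a]) {
          dp = ps[i + st] - ps[i];
          dl = ls[i + st] - ls[i];
        }
        const double dmag = std::fabs(dp) - std::fabs(dl);
        accg += ms[i] * std::fabs(dmag);
        if (grad && ia + 1 < sizes[a]) {
          const double sg = ms[i] *
            (dmag > 0 ? 1.0 : (dmag < 0 ? -1.0 : 0.0)) *
            (dp > 0 ? 1.0 : (dp < 0 ? -1.0 : 0.0));
          gs[i + st] += w_grad * sg;
          gs[i] -= w_grad * sg;
        }
      }
    }
    l1_s[s] = acc1 / S;
    grad_s[s] = accg / S;
    S_s[s] = S;
    if (grad) {
      const double inv = 1.0 / (S * B);
      for (long i = 0; i < nv; ++i) gs[i] *= inv;
    }
  }
  return List::create(_["l1"] = l1_s, _["grad"] = grad_s, _["S"] = S_s,
                      _["g"] = grad ? SEXP(g) : R_NilValue);
}
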