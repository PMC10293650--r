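// Fused multichannel 3D encoder-decoder network.
//
// The layer program is built in R (see unet_plan()) as a linear sequence of
// ops over a single current tensor plus named skip slots:
//   conv3 / conv1 / convt / bn / relu / pool / save / concat
// The whole forward and backward pass for a batch runs in C++ with float32
// activations cached layer-by-layer; R supplies the input batch and the
// gradient of the loss with respect to the prediction, and drives the Adam
// updates (moments are kept here).

// [[Rcpp::depends(RcppArmadillo)]]
#include "core.h"
#include <map>

using namespace Rcpp;
using namespace qsmdi;

namespace {

constexpr float BN_EPS = 1e-5f;
constexpr float BN_MOMENTUM = 0.1f;

enum OpType { CONV3, CONV1, CONVT, BN, RELU, POOL, SAVE, CONCAT };

struct Layer {
  OpType op;
  int cin = 0, cout = 0, slot = -1;
  // parameters
  std::vector<fmat> W;          // conv3: 27 x (cin x cout)
  fmat W1;                      // conv1 (cin x cout) or convt (27*cout x cin)
  fvec b;
  fvec gamma, beta, rmean, rvar;
  // gradients
  std::vector<fmat> gW;
  fmat gW1;
  fvec gb, ggamma, gbeta;
  // Adam moments
  std::vector<fmat> mW, vW;
  fmat mW1, vW1;
  fvec mb, vb, mgamma, vgamma, mbeta, vbeta;
  // caches
  std::vector<fmat> pads;       // conv3 padded inputs
  FTensor xin;                  // conv1/convt/bn input
  FTensor yout;                 // relu output
  fvec mean, var;               // bn batch stats
  std::vector<long> poolidx;
  int pre_pool[3] = {0, 0, 0};
};

struct Net {
  std::vector<Layer> layers;
  std::map<int, FTensor> slots, slotgrad;
  FTensor cur;
  long adam_t = 0;
};

void concat_channels(const FTensor& a, const FTensor& b, FTensor& out) {
  out.resize(a.nx, a.ny, a.nz, a.c + b.c, a.n);
  const long nv = a.nvox();
  for (int s = 0; s < a.n; ++s) {
    std::memcpy(out.sample(s), a.sample(s), sizeof(float) * nv * a.c);
    std::memcpy(out.sample(s) + nv * a.c, b.sample(s), sizeof(float) * nv * b.c);
  }
}

void split_channels(const FTensor& d, int ca, FTensor& da, FTensor& db) {
  da.resize(d.nx, d.ny, d.nz, ca, d.n);
  db.resize(d.nx, d.ny, d.nz, d.c - ca, d.n);
  const long nv = d.nvox();
  for (int s = 0; s < d.n; ++s) {
    std::memcpy(da.sample(s), d.sample(s), sizeof(float) * nv * ca);
    std::memcpy(db.sample(s), d.sample(s) + nv * ca,
                sizeof(float) * nv * (d.c - ca));
  }
}

void adam_update(fmat& p, fmat& g, fmat& m, fmat& v,
                 float lr, float b1, float b2, float eps, long t) {
  if (m.n_elem != p.n_elem) { m.zeros(p.n_rows, p.n_cols); v.zeros(p.n_rows, p.n_cols); }
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  const float c1 = 1 - std::pow(b1, float(t)), c2 = 1 - std::pow(b2, float(t));
  p -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}

void adam_update(fvec& p, fvec& g, fvec& m, fvec& v,
                 float lr, float b1, float b2, float eps, long t) {
  if (m.n_elem != p.n_elem) { m.zeros(p.n_elem); v.zeros(p.n_elem); }
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  const float c1 = 1 - std::pow(b1, float(t)), c2 = 1 - std::pow(b2, float(t));
  p -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}

} // namespace

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(List plan, List params) {
  Net* net = new Net();
  for (int i = 0; i < plan.size(); ++i) {
    List ld = plan[i];
    std::string op = as<std::string>(ld["op"]);
    Layer l;
    List pr = params[i];
    if (op == "conv3") {
      l.op = CONV3;
      l.W = conv_w_from_r(pr["w"]);
      l.b = fvec_from_r(pr["b"]);
      l.cin = l.W[0].n_rows; l.cout = l.W[0].n_cols;
    } else if (op == "conv1") {
      l.op = CONV1;
      NumericVector w = pr["w"];
      IntegerVector wd = w.attr("dim");
      l.cin = wd[3]; l.cout = wd[4];
      l.W1.set_size(l.cin, l.cout);
      for (long j = 0; j < (long)w.size(); ++j) l.W1(j) = float(w[j]);
      l.b = fvec_from_r(pr["b"]);
    } else if (op == "convt") {
      l.op = CONVT;
      l.W1 = convt_w_from_r(pr["w"]);
      l.b = fvec_from_r(pr["b"]);
      l.cout = l.W1.n_rows / 27; l.cin = l.W1.n_cols;
    } else if (op == "bn") {
      l.op = BN;
      l.gamma = fvec_from_r(pr["gamma"]);
      l.beta = fvec_from_r(pr["beta"]);
      l.rmean = fvec_from_r(pr["rmean"]);
      l.rvar = fvec_from_r(pr["rvar"]);
      l.cin = l.cout = l.gamma.n_elem;
    } else if (op == "relu") {
      l.op = RELU;
    } else if (op == "pool") {
      l.op = POOL;
    } else if (op == "save") {
      l.op = SAVE; l.slot = as<int>(ld["slot"]);
    } else if (op == "concat") {
      l.op = CONCAT; l.slot = as<int>(ld["slot"]);
    } else {
      stop("unknown layer op: %s", op.c_str());
    }
    net->layers.push_back(std::move(l));
  }
  XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export(name = ".net_forward")]]
NumericVector net_forward(SEXP handle, NumericVector x, bool training) {
  XPtr<Net> net(handle);
  net->cur = from_r(x);
  net->slots.clear();
  FTensor tmp;
  for (auto& l : net->layers) {
    switch (l.op) {
    case CONV3:
      conv3_fw(net->cur, l.W, l.b, tmp, training ? &l.pads : nullptr);
      std::swap(net->cur, tmp);
      break;
    case CONV1:
      if (training) l.xin = net->cur;
      conv1_fw(net->cur, l.W1, l.b, tmp);
      std::swap(net->cur, tmp);
      break;
    case CONVT:
      if (training) l.xin = net->cur;
      convt3_fw(net->cur, l.W1, l.b, tmp);
      std::swap(net->cur, tmp);
      break;
    case BN:
      if (training) l.xin = net->cur;
      bn_fw(net->cur, l.gamma, l.beta, l.rmean, l.rvar, BN_EPS, BN_MOMENTUM,
            training, tmp, l.mean, l.var);
      std::swap(net->cur, tmp);
      break;
    case RELU:
      relu_fw(net->cur);
      if (training) l.yout = net->cur;
      break;
    case POOL:
      if (net->cur.nx % 2 || net->cur.ny % 2 || net->cur.nz % 2)
        stop("max pooling requires even spatial dimensions");
      l.pre_pool[0] = net->cur.nx; l.pre_pool[1] = net->cur.ny;
      l.pre_pool[2] = net->cur.nz;
      maxpool_fw(net->cur, tmp, l.poolidx);
      std::swap(net->cur, tmp);
      break;
    case SAVE:
      net->slots[l.slot] = net->cur;
      break;
    case CONCAT:
      concat_channels(net->cur, net->slots[l.slot], tmp);
      std::swap(net->cur, tmp);
      break;
    }
  }
  return to_r(net->cur);
}

// [[Rcpp::export(name = ".net_backward")]]
void net_backward(SEXP handle, NumericVector dpred) {
  XPtr<Net> net(handle);
  FTensor dcur = from_r(dpred), tmp, dskip;
  net->slotgrad.clear();
  for (auto it = net->layers.rbegin(); it != net->layers.rend(); ++it) {
    Layer& l = *it;
    switch (l.op) {
    case CONV3:
      // the input gradient of the first layer is never used
      if (&l == &net->layers.front()) {
        conv3_bw(l.pads, l.W, dcur, nullptr, l.gW, l.gb);
      } else {
        conv3_bw(l.pads, l.W, dcur, &tmp, l.gW, l.gb);
        std::swap(dcur, tmp);
      }
      break;
    case CONV1:
      conv1_bw(l.xin, l.W1, dcur, &tmp, l.gW1, l.gb);
      std::swap(dcur, tmp);
      break;
    case CONVT:
      convt3_bw(l.xin, l.W1, dcur, &tmp, l.gW1, l.gb);
      std::swap(dcur, tmp);
      break;
    case BN:
      bn_bw(l.xin, dcur, l.gamma, l.mean, l.var, BN_EPS, tmp, l.ggamma, l.gbeta);
      std::swap(dcur, tmp);
      break;
    case RELU:
      relu_bw(l.yout, dcur);
      break;
    case POOL:
      maxpool_bw(dcur, l.poolidx, l.pre_pool[0], l.pre_pool[1], l.pre_pool[2],
                 tmp);
      std::swap(dcur, tmp);
      break;
    case SAVE: {
      auto g = net->slotgrad.find(l.slot);
      if (g != net->slotgrad.end())
        for (long i = 0; i < (long)dcur.size(); ++i)
          dcur.v[i] += g->second.v[i];
      break;
    }
    case CONCAT:
      split_channels(dcur, dcur.c - net->slots[l.slot].c, tmp, dskip);
      net->slotgrad[l.slot] = dskip;
      std::swap(dcur, tmp);
      break;
    }
  }
}

// [[Rcpp::export(name = ".net_adam_step")]]
void net_adam_step(SEXP handle, double lr, double beta1 = 0.9,
                   double beta2 = 0.999, double eps = 1e-8) {
  XPtr<Net> net(handle);
  const long t = ++net->adam_t;
  const float flr = float(lr), b1 = float(beta1), b2 = float(beta2),
              fe = float(eps);
  for (auto& l : net->layers) {
    switch (l.op) {
    case CONV3:
      if (l.mW.empty()) { l.mW.resize(27); l.vW.resize(27); }
      for (int ti = 0; ti < 27; ++ti)
        adam_update(l.W[ti], l.gW[ti], l.mW[ti], l.vW[ti], flr, b1, b2, fe, t);
      adam_update(l.b, l.gb, l.mb, l.vb, flr, b1, b2, fe, t);
      break;
    case CONV1:
    case CONVT:
      adam_update(l.W1, l.gW1, l.mW1, l.vW1, flr, b1, b2, fe, t);
      adam_update(l.b, l.gb, l.mb, l.vb, flr, b1, b2, fe, t);
      break;
    case BN:
      adam_update(l.gamma, l.ggamma, l.mgamma, l.vgamma, flr, b1, b2, fe, t);
      adam_update(l.beta, l.gbeta, l.mbeta, l.vbeta, flr, b1, b2, fe, t);
      break;
    default:
      break;
    }
  }
}

// [[Rcpp::export(name = ".net_get_params")]]
List net_get_params(SEXP handle) {
  XPtr<Net> net(handle);
  List out(net->layers.size());
  for (size_t i = 0; i < net->layers.size(); ++i) {
    Layer& l = net->layers[i];
    switch (l.op) {
    case CONV3:
      out[i] = List::create(_["w"] = conv_w_to_r(l.W), _["b"] = fvec_to_r(l.b));
      break;
    case CONV1: {
      NumericVector w((R_xlen_t)l.cin * l.cout);
      w.attr("dim") = IntegerVector::create(1, 1, 1, l.cin, l.cout);
      for (long j = 0; j < (long)w.size(); ++j) w[j] = double(l.W1(j));
      out[i] = List::create(_["w"] = w, _["b"] = fvec_to_r(l.b));
      break;
    }
    case CONVT:
      out[i] = List::create(_["w"] = convt_w_to_r(l.W1),
                            _["b"] = fvec_to_r(l.b));
      break;
    case BN:
      out[i] = List::create(_["gamma"] = fvec_to_r(l.gamma),
                            _["beta"] = fvec_to_r(l.beta),
                            _["rmean"] = fvec_to_r(l.rmean),
                            _["rvar"] = fvec_to_r(l.rvar));
      break;
    default:
      out[i] = R_NilValue;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".net_get_grads")]]
List net_get_grads(SEXP handle) {
  XPtr<Net> net(handle);
  List out(net->layers.size());
  for (size_t i = 0; i < net->layers.size(); ++i) {
    Layer& l = net->layers[i];
    switch (l.op) {
    case CONV3:
      out[i] = List::create(_["w"] = conv_w_to_r(l.gW), _["b"] = fvec_to_r(l.gb));
      break;
    case CONV1: {
      NumericVector w((R_xlen_t)l.cin * l.cout);
      w.attr("dim") = IntegerVector::create(1, 1, 1, l.cin, l.cout);
      for (long j = 0; j < (long)w.size(); ++j) w[j] = double(l.gW1(j));
      out[i] = List::create(_["w"] = w, _["b"] = fvec_to_r(l.gb));
      break;
    }
    case CONVT:
      out[i] = List::create(_["w"] = convt_w_to_r(l.gW1),
                            _["b"] = fvec_to_r(l.gb));
      break;
    case BN:
      out[i] = List::create(_["gamma"] = fvec_to_r(l.ggamma),
                            _["beta"] = fvec_to_r(l.gbeta));
      break;
    default:
      out[i] = R_NilValue;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".net_set_params")]]
void net_set_params(SEXP handle, List params) {
  XPtr<Net> net(handle);
  if ((size_t)params.size() != net->layers.size())
    stop("parameter list length does not match the network");
  for (size_t i = 0; i < net->layers.size(); ++i) {
    Layer& l = net->layers[i];
    if (Rf_isNull(params[i])) continue;
    List pr = params[i];
    switch (l.op) {
    case CONV3:
      l.W = conv_w_from_r(pr["w"]);
      l.b = fvec_from_r(pr["b"]);
      break;
    case CONV1: {
      NumericVector w = pr["w"];
      for (long j = 0; j < (long)w.size(); ++j) l.W1(j) = float(w[j]);
      l.b = fvec_from_r(pr["b"]);
      break;
    }
    case CONVT:
      l.W1 = convt_w_from_r(pr["w"]);
      l.b = fvec_from_r(pr["b"]);
      break;
    case BN:
      l.gamma = fvec_from_r(pr["gamma"]);
      l.beta = fvec_from_r(pr["beta"]);
      l.rmean = fvec_from_r(pr["rmean"]);
      l.rvar = fvec_from_r(pr["rvar"]);
      break;
    default:
      break;
    }
  }
}

// [[Rcpp::export(name = ".net_release_cache")]]
void net_release_cache(SEXP handle) {
  XPtr<Net> net(handle);
  for (auto& l : net->layers) {
    l.pads.clear(); l.pads.shrink_to_fit();
    l.xin = FTensor(); l.yout = FTensor();
    l.poolidx.clear(); l.poolidx.shrink_to_fit();
  }
  net->slots.clear();
  net->slotgrad.clear();
  net->cur = FTensor();
}
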