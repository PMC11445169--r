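// Minimal residual-network engine: im2col convolutions, max pooling,
// global average pooling, dense softmax head, and residual units with
// optional 1x1 projection skips. Forward, backprop and SGD (optional
// momentum) are implemented here; architecture and weights live in an R
// list so initialization and shuffling stay on R's RNG stream.
//
// Layout conventions: feature maps are arma::cube (H, W, C); an im2col
// matrix has rows indexed by (c*k*k + ki*k + kj) and columns by the
// column-major output position (oj*Ho + oi). Weight matrices are
// (cout x cin*k*k). All code is single-threaded and deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uvec;

struct ConvP {
  int k = 3, stride = 1, pad = 1, cin = 1, cout = 1;
  bool relu = false;
  mat W;  vec b;
  mat dW; vec db;
  mat vW; vec vb;
};

struct Unit {
  std::string type;            // "conv", "maxpool", "res", "gap", "dense"
  ConvP conv;                  // conv
  std::vector<ConvP> convs;    // res main chain
  bool has_proj = false;
  ConvP proj;                  // res skip projection
  int psize = 2, pstride = 2, ppad = 0;  // maxpool
  mat Wd;  vec bd;             // dense
  mat dWd; vec dbd;
  mat vWd; vec vbd;
};

static ConvP parse_conv(const List& L) {
  ConvP c;
  c.k = as<int>(L["k"]); c.stride = as<int>(L["stride"]);
  c.pad = as<int>(L["pad"]); c.cin = as<int>(L["cin"]);
  c.cout = as<int>(L["cout"]); c.relu = as<bool>(L["relu"]);
  c.W = as<mat>(L["W"]); c.b = as<vec>(L["b"]);
  c.dW.zeros(c.W.n_rows, c.W.n_cols); c.db.zeros(c.b.n_elem);
  c.vW.zeros(c.W.n_rows, c.W.n_cols); c.vb.zeros(c.b.n_elem);
  return c;
}

static std::vector<Unit> parse_net(const List& net) {
  std::vector<Unit> units;
  for (int i = 0; i < net.size(); ++i) {
    List L = net[i];
    Unit u;
    u.type = as<std::string>(L["type"]);
    if (u.type == "conv") {
      u.conv = parse_conv(L);
    } else if (u.type == "maxpool") {
      u.psize = as<int>(L["size"]); u.pstride = as<int>(L["stride"]);
      u.ppad = as<int>(L["pad"]);
    } else if (u.type == "res") {
      List convs = L["convs"];
      for (int j = 0; j < convs.size(); ++j)
        u.convs.push_back(parse_conv(convs[j]));
      if (!Rf_isNull(L["proj"])) {
        u.has_proj = true;
        u.proj = parse_conv(L["proj"]);
      }
    } else if (u.type == "dense") {
      u.Wd = as<mat>(L["W"]); u.bd = as<vec>(L["b"]);
      u.dWd.zeros(u.Wd.n_rows, u.Wd.n_cols); u.dbd.zeros(u.bd.n_elem);
      u.vWd.zeros(u.Wd.n_rows, u.Wd.n_cols); u.vbd.zeros(u.bd.n_elem);
    } else if (u.type != "gap") {
      stop("unknown unit type: " + u.type);
    }
    units.push_back(std::move(u));
  }
  return units;
}

static List write_back(const std::vector<Unit>& units, List net) {
  List out = clone(net);
  for (size_t i = 0; i < units.size(); ++i) {
    const Unit& u = units[i];
    List L = out[i];
    if (u.type == "conv") {
      L["W"] = u.conv.W; L["b"] = u.conv.b;
    } else if (u.type == "res") {
      List convs = L["convs"];
      for (size_t j = 0; j < u.convs.size(); ++j) {
        List cj = convs[j];
        cj["W"] = u.convs[j].W; cj["b"] = u.convs[j].b;
        convs[j] = cj;
      }
      L["convs"] = convs;
      if (u.has_proj) {
        List pj = L["proj"];
        pj["W"] = u.proj.W; pj["b"] = u.proj.b;
        L["proj"] = pj;
      }
    } else if (u.type == "dense") {
      L["W"] = u.Wd; L["b"] = u.bd;
    }
    out[i] = L;
  }
  return out;
}

// ---- primitive ops --------------------------------------------------------

static void out_dims(int Hi, int Wi, int k, int s, int p, int& Ho, int& Wo) {
  Ho = (Hi + 2 * p - k) / s + 1;
  Wo = (Wi + 2 * p - k) / s + 1;
}

static mat im2col(const cube& X, int k, int s, int p, int Ho, int Wo) {
  const int Hi = X.n_rows, Wi = X.n_cols, C = X.n_slices;
  mat cols(C * k * k, Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& Xs = X.slice(c);
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int rr = c * k * k + ki * k + kj;
        for (int oj = 0; oj < Wo; ++oj) {
          const int jj = oj * s + kj - p;
          if (jj < 0 || jj >= Wi) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * s + ki - p;
            if (ii < 0 || ii >= Hi) continue;
            cols(rr, oj * Ho + oi) = Xs(ii, jj);
          }
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& dcols, int Hi, int Wi, int C,
                   int k, int s, int p, int Ho, int Wo) {
  cube dX(Hi, Wi, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& dXs = dX.slice(c);
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int rr = c * k * k + ki * k + kj;
        for (int oj = 0; oj < Wo; ++oj) {
          const int jj = oj * s + kj - p;
          if (jj < 0 || jj >= Wi) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * s + ki - p;
            if (ii < 0 || ii >= Hi) continue;
            dXs(ii, jj) += dcols(rr, oj * Ho + oi);
          }
        }
      }
    }
  }
  return dX;
}

struct ConvCache { mat cols; cube out; int Hi = 0, Wi = 0; };

static cube conv_forward(const ConvP& c, const cube& X, ConvCache* cache) {
  int Ho, Wo;
  out_dims(X.n_rows, X.n_cols, c.k, c.stride, c.pad, Ho, Wo);
  mat cols = im2col(X, c.k, c.stride, c.pad, Ho, Wo);
  mat Y = c.W * cols;
  Y.each_col() += c.b;
  cube out(Ho, Wo, c.cout);
  for (int ch = 0; ch < c.cout; ++ch)
    out.slice(ch) = arma::reshape(Y.row(ch), Ho, Wo);
  if (c.relu) out.transform([](double v) { return v > 0 ? v : 0.0; });
  if (cache) {
    cache->cols = std::move(cols);
    cache->out = out;
    cache->Hi = X.n_rows; cache->Wi = X.n_cols;
  }
  return out;
}

// dOut is the gradient w.r.t. the (post-activation) output
static cube conv_backward(ConvP& c, cube dOut, const ConvCache& cache) {
  const int Ho = dOut.n_rows, Wo = dOut.n_cols;
  if (c.relu) dOut %= arma::conv_to<cube>::from(cache.out > 0);
  mat dY(c.cout, Ho * Wo);
  for (int ch = 0; ch < c.cout; ++ch)
    dY.row(ch) = arma::vectorise(dOut.slice(ch)).t();
  c.dW += dY * cache.cols.t();
  c.db += arma::sum(dY, 1);
  mat dcols = c.W.t() * dY;
  return col2im(dcols, cache.Hi, cache.Wi, c.cin,
                c.k, c.stride, c.pad, Ho, Wo);
}

struct UnitCache {
  cube in;
  std::vector<ConvCache> cc;
  ConvCache pc;
  cube out;
  arma::ucube pool_src;  // source linear index per pooled element
};

static cube maxpool_forward(const Unit& u, const cube& X, UnitCache* cache) {
  const int Hi = X.n_rows, Wi = X.n_cols, C = X.n_slices;
  int Ho, Wo;
  out_dims(Hi, Wi, u.psize, u.pstride, u.ppad, Ho, Wo);
  cube out(Ho, Wo, C);
  arma::ucube src(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& Xs = X.slice(c);
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        double best = -arma::datum::inf;
        arma::uword bidx = 0;
        for (int kj = 0; kj < u.psize; ++kj) {
          const int jj = oj * u.pstride + kj - u.ppad;
          if (jj < 0 || jj >= Wi) continue;
          for (int ki = 0; ki < u.psize; ++ki) {
            const int ii = oi * u.pstride + ki - u.ppad;
            if (ii < 0 || ii >= Hi) continue;
            const double v = Xs(ii, jj);
            if (v > best) { best = v; bidx = jj * Hi + ii; }
          }
        }
        out(oi, oj, c) = best;
        src(oi, oj, c) = bidx;
      }
    }
  }
  if (cache) cache->pool_src = src;
  return out;
}

static cube maxpool_backward(const Unit& u, const cube& dOut,
                             const UnitCache& cache, int Hi, int Wi) {
  const int C = dOut.n_slices;
  cube dX(Hi, Wi, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& dXs = dX.slice(c);
    for (arma::uword oj = 0; oj < dOut.n_cols; ++oj)
      for (arma::uword oi = 0; oi < dOut.n_rows; ++oi)
        dXs(cache.pool_src(oi, oj, c)) += dOut(oi, oj, c);
  }
  return dX;
}

// forward through all units; fills caches when train != nullptr;
// returns the logit vector
static vec net_forward(std::vector<Unit>& units, const cube& X0,
                       std::vector<UnitCache>* caches) {
  cube cur = X0;
  vec feat;  // after gap
  vec logits;
  for (size_t i = 0; i < units.size(); ++i) {
    Unit& u = units[i];
    UnitCache* uc = caches ? &(*caches)[i] : nullptr;
    if (uc) uc->in = cur;
    if (u.type == "conv") {
      ConvCache cc;
      cur = conv_forward(u.conv, cur, uc ? &cc : nullptr);
      if (uc) { uc->cc.clear(); uc->cc.push_back(std::move(cc)); }
    } else if (u.type == "maxpool") {
      cur = maxpool_forward(u, cur, uc);
    } else if (u.type == "res") {
      cube chain = cur;
      std::vector<ConvCache> ccs(u.convs.size());
      for (size_t j = 0; j < u.convs.size(); ++j)
        chain = conv_forward(u.convs[j], chain, uc ? &ccs[j] : nullptr);
      cube skip;
      ConvCache pcc;
      if (u.has_proj) skip = conv_forward(u.proj, cur, uc ? &pcc : nullptr);
      else skip = cur;
      cube out = chain + skip;
      out.transform([](double v) { return v > 0 ? v : 0.0; });
      if (uc) {
        uc->cc = std::move(ccs);
        uc->pc = std::move(pcc);
        uc->out = out;
      }
      cur = out;
    } else if (u.type == "gap") {
      feat.set_size(cur.n_slices);
      for (arma::uword c = 0; c < cur.n_slices; ++c)
        feat(c) = arma::accu(cur.slice(c)) / (cur.n_rows * cur.n_cols);
      if (uc) uc->out = cur;  // keep dims for backward
    } else if (u.type == "dense") {
      logits = u.Wd * feat + u.bd;
      if (uc) uc->out = cube(feat.n_elem, 1, 1);  // store feat below
      if (uc) uc->out.slice(0).col(0) = feat;
    }
  }
  return logits;
}

static void net_backward(std::vector<Unit>& units,
                         std::vector<UnitCache>& caches, const vec& dlogits) {
  cube dcur;
  vec dfeat;
  for (int i = (int)units.size() - 1; i >= 0; --i) {
    Unit& u = units[i];
    UnitCache& uc = caches[i];
    if (u.type == "dense") {
      vec feat = uc.out.slice(0).col(0);
      u.dWd += dlogits * feat.t();
      u.dbd += dlogits;
      dfeat = u.Wd.t() * dlogits;
    } else if (u.type == "gap") {
      const cube& in = uc.in;
      dcur.set_size(in.n_rows, in.n_cols, in.n_slices);
      const double sc = 1.0 / (in.n_rows * in.n_cols);
      for (arma::uword c = 0; c < in.n_slices; ++c)
        dcur.slice(c).fill(dfeat(c) * sc);
    } else if (u.type == "maxpool") {
      dcur = maxpool_backward(u, dcur, uc, uc.in.n_rows, uc.in.n_cols);
    } else if (u.type == "conv") {
      dcur = conv_backward(u.conv, dcur, uc.cc[0]);
    } else if (u.type == "res") {
      cube dpre = dcur % arma::conv_to<cube>::from(uc.out > 0);
      cube dchain = dpre;
      for (int j = (int)u.convs.size() - 1; j >= 0; --j)
        dchain = conv_backward(u.convs[j], dchain, uc.cc[j]);
      if (u.has_proj) {
        cube dskip = conv_backward(u.proj, dpre, uc.pc);
        dcur = dchain + dskip;
      } else {
        dcur = dchain + dpre;
      }
    }
  }
}

static vec softmax(const vec& z) {
  vec s = arma::exp(z - z.max());
  return s / arma::accu(s);
}

// replicate the single grayscale channel cin times
static cube expand_input(const cube& X, int n, int cin) {
  cube out(X.n_rows, X.n_cols, cin);
  for (int c = 0; c < cin; ++c) out.slice(c) = X.slice(n);
  return out;
}

static void zero_grads(std::vector<Unit>& units) {
  for (Unit& u : units) {
    if (u.type == "conv") { u.conv.dW.zeros(); u.conv.db.zeros(); }
    else if (u.type == "res") {
      for (ConvP& c : u.convs) { c.dW.zeros(); c.db.zeros(); }
      if (u.has_proj) { u.proj.dW.zeros(); u.proj.db.zeros(); }
    } else if (u.type == "dense") { u.dWd.zeros(); u.dbd.zeros(); }
  }
}

static void sgd_conv(ConvP& c, double lr, double mom, double scale) {
  if (mom > 0) {
    c.vW = mom * c.vW - lr * scale * c.dW;
    c.vb = mom * c.vb - lr * scale * c.db;
    c.W += c.vW; c.b += c.vb;
  } else {
    c.W -= lr * scale * c.dW; c.b -= lr * scale * c.db;
  }
}

static void sgd_step(std::vector<Unit>& units, double lr, double mom,
                     double scale) {
  for (Unit& u : units) {
    if (u.type == "conv") sgd_conv(u.conv, lr, mom, scale);
    else if (u.type == "res") {
      for (ConvP& c : u.convs) sgd_conv(c, lr, mom, scale);
      if (u.has_proj) sgd_conv(u.proj, lr, mom, scale);
    } else if (u.type == "dense") {
      if (mom > 0) {
        u.vWd = mom * u.vWd - lr * scale * u.dWd;
        u.vbd = mom * u.vbd - lr * scale * u.dbd;
        u.Wd += u.vWd; u.bd += u.vbd;
      } else {
        u.Wd -= lr * scale * u.dWd; u.bd -= lr * scale * u.dbd;
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_net_predict(List net, const arma::cube& X, int cin) {
  std::vector<Unit> units = parse_net(net);
  const int N = X.n_slices;
  int ncls = 0;
  for (const Unit& u : units) if (u.type == "dense") ncls = u.Wd.n_rows;
  mat probs(N, ncls);
  for (int n = 0; n < N; ++n) {
    cube x = expand_input(X, n, cin);
    vec p = softmax(net_forward(units, x, nullptr));
    probs.row(n) = p.t();
  }
  return probs;
}

// [[Rcpp::export]]
double cpp_net_loss(List net, const arma::cube& X,
                    const arma::ivec& y, int cin) {
  std::vector<Unit> units = parse_net(net);
  double loss = 0;
  const int N = X.n_slices;
  for (int n = 0; n < N; ++n) {
    cube x = expand_input(X, n, cin);
    vec p = softmax(net_forward(units, x, nullptr));
    loss += -std::log(std::max(p(y(n)), 1e-12));
  }
  return loss / N;
}

// [[Rcpp::export]]
List cpp_net_train(List net, const arma::cube& X, const arma::ivec& y,
                   const arma::cube& Xval, const arma::ivec& yval,
                   int cin, int epochs, int batch, double lr,
                   double momentum, std::string reduction,
                   const arma::imat& order) {
  std::vector<Unit> units = parse_net(net);
  const int N = X.n_slices;
  const int Nval = Xval.n_slices;
  std::vector<UnitCache> caches(units.size());
  NumericVector tr_loss(epochs), tr_acc(epochs), va_loss(epochs),
      va_acc(epochs);

  for (int e = 0; e < epochs; ++e) {
    double eloss = 0; int ecorrect = 0;
    for (int start = 0; start < N; start += batch) {
      const int end = std::min(start + batch, N);
      const int bs = end - start;
      zero_grads(units);
      for (int bi = start; bi < end; ++bi) {
        const int n = order(bi, e) - 1;  // 1-based from R
        cube x = expand_input(X, n, cin);
        vec logits = net_forward(units, x, &caches);
        vec p = softmax(logits);
        eloss += -std::log(std::max(p(y(n)), 1e-12));
        if ((int)p.index_max() == y(n)) ++ecorrect;
        vec dlogits = p;
        dlogits(y(n)) -= 1.0;
        net_backward(units, caches, dlogits);
      }
      const double scale = (reduction == "mean") ? 1.0 / bs : 1.0;
      sgd_step(units, lr, momentum, scale);
      Rcpp::checkUserInterrupt();
    }
    tr_loss[e] = eloss / N;
    tr_acc[e] = (double)ecorrect / N;
    double vloss = 0; int vcorrect = 0;
    for (int n = 0; n < Nval; ++n) {
      cube x = expand_input(Xval, n, cin);
      vec p = softmax(net_forward(units, x, nullptr));
      vloss += -std::log(std::max(p(yval(n)), 1e-12));
      if ((int)p.index_max() == yval(n)) ++vcorrect;
    }
    va_loss[e] = Nval ? vloss / Nval : NA_REAL;
    va_acc[e] = Nval ? (double)vcorrect / Nval : NA_REAL;
  }

  return List::create(
      _["net"] = write_back(units, net),
      _["history"] = DataFrame::create(
          _["epoch"] = seq_len(epochs), _["train_loss"] = tr_loss,
          _["train_acc"] = tr_acc, _["val_loss"] = va_loss,
          _["val_acc"] = va_acc));
}

// single accumulated gradient pass over a (small) set, for gradient checks
// [[Rcpp::export]]
List cpp_net_grad(List net, const arma::cube& X, const arma::ivec& y,
                  int cin) {
  std::vector<Unit> units = parse_net(net);
  std::vector<UnitCache> caches(units.size());
  zero_grads(units);
  const int N = X.n_slices;
  double loss = 0;
  for (int n = 0; n < N; ++n) {
    cube x = expand_input(X, n, cin);
    vec logits = net_forward(units, x, &caches);
    vec p = softmax(logits);
    loss += -std::log(std::max(p(y(n)), 1e-12));
    vec dlogits = p;
    dlogits(y(n)) -= 1.0;
    net_backward(units, caches, dlogits);
  }
  // report gradients of the mean loss
  List grads;
  for (const Unit& u : units) {
    if (u.type == "conv")
      grads.push_back(List::create(_["dW"] = mat(u.conv.dW / N),
                                   _["db"] = vec(u.conv.db / N)));
    else if (u.type == "res") {
      List cl;
      for (const ConvP& c : u.convs)
        cl.push_back(List::create(_["dW"] = mat(c.dW / N),
                                  _["db"] = vec(c.db / N)));
      grads.push_back(List::create(
          _["convs"] = cl,
          _["proj"] = u.has_proj
              ? (SEXP)List::create(_["dW"] = mat(u.proj.dW / N),
                                   _["db"] = vec(u.proj.db / N))
              : R_NilValue));
    } else if (u.type == "dense")
      grads.push_back(List::create(_["dW"] = mat(u.dWd / N),
                                   _["db"] = vec(u.dbd / N)));
    else
      grads.push_back(R_NilValue);
  }
  return List::create(_["loss"] = loss / N, _["grads"] = grads);
}
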