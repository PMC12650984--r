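// Dual-branch attention network: forward pass, manual backpropagation and
// training loop. Feature tensors are arma::cube (H x W x C) per sample;
// convolutions are im2col + BLAS gemm with stride 1 and zero 'same'
// padding. Channel attention follows
//   M_c = sigmoid(l1*MLP(avg) + l2*MLP(max) + l3*MLP(relu(BN(W0 M_prev))))
// and spatial attention
//   M_s = sigmoid(Ws * [avg, max, Wl * pool(M_prev)])
// with the cross-layer term dropped at the first block. Batch norm uses
// batch statistics during training and running statistics at inference.

#include <RcppArmadillo.h>
#include <map>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;

static const double BN_EPS = 1e-5;
// exponential-average momentum during training; the final recalibration
// pass overrides this with cumulative-average weights (see cpp_train)
static double g_bn_momentum = 0.1;

enum ActKind { ACT_RELU = 0, ACT_SIGMOID = 1, ACT_ELU = 2, ACT_SOFTMAX = 3 };
enum AttMode { ATT_OFF = 0, ATT_FROZEN = 1, ATT_ON = 2 };

// ---------------------------------------------------------------------------
// parameter store

struct ParamStore {
  std::map<std::string, vec> values;

  vec& at(const std::string& name) {
    auto it = values.find(name);
    if (it == values.end())
      Rcpp::stop("missing parameter: " + name);
    return it->second;
  }
  bool has(const std::string& name) const {
    return values.count(name) > 0;
  }
  // matrix view over a flat parameter (column-major, no copy)
  mat as_mat(const std::string& name, uword r, uword c) {
    vec& v = at(name);
    if (v.n_elem != r * c)
      Rcpp::stop("parameter " + name + " has wrong size");
    return mat(v.memptr(), r, c, false, true);
  }
};

static ParamStore params_from_list(const List& lst) {
  ParamStore ps;
  Rcpp::CharacterVector names = lst.names();
  for (int i = 0; i < lst.size(); ++i) {
    NumericVector v = lst[i];
    ps.values[std::string(names[i])] = vec(v.begin(), v.size());
  }
  return ps;
}

static List params_to_list(ParamStore& ps, const List& proto) {
  List out = Rcpp::clone(proto);
  Rcpp::CharacterVector names = proto.names();
  for (int i = 0; i < proto.size(); ++i) {
    std::string nm(names[i]);
    NumericVector tgt = out[i];
    const vec& src = ps.at(nm);
    std::copy(src.begin(), src.end(), tgt.begin());
  }
  return out;
}

static bool is_buffer(const std::string& name) {
  size_t n = name.size();
  auto ends = [&](const char* suf) {
    size_t m = strlen(suf);
    return n >= m && name.compare(n - m, m, suf) == 0;
  };
  return ends("_mean") || ends("_var");
}

// ---------------------------------------------------------------------------
// batch container: one cube per sample

typedef std::vector<cube> Batch;

static Batch batch_from_array(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) Rcpp::stop("patch array must be 4-D (H, W, C, N)");
  uword H = d[0], W = d[1], C = d[2], N = d[3];
  Batch b(N);
  const double* p = x.begin();
  uword per = H * W * C;
  for (uword i = 0; i < N; ++i) {
    b[i] = cube(p + i * per, H, W, C);
  }
  return b;
}

// ---------------------------------------------------------------------------
// activations (elementwise on cubes/vectors; softmax across channels/units)

static void act_forward(cube& x, int kind) {
  if (kind == ACT_RELU) {
    x.transform([](double v) { return v > 0 ? v : 0.0; });
  } else if (kind == ACT_SIGMOID) {
    x.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
  } else if (kind == ACT_ELU) {
    x.transform([](double v) { return v > 0 ? v : std::expm1(v); });
  } else { // softmax across channels, per pixel
    for (uword h = 0; h < x.n_rows; ++h)
      for (uword w = 0; w < x.n_cols; ++w) {
        vec t = x.tube(h, w);
        t -= t.max();
        t = exp(t);
        t /= accu(t);
        x.tube(h, w) = t;
      }
  }
}

// dy in place -> dx, given post-activation values y
static void act_backward(cube& dy, const cube& y, int kind) {
  if (kind == ACT_RELU) {
    dy %= conv_to<cube>::from(y > 0);
  } else if (kind == ACT_SIGMOID) {
    dy %= y % (1.0 - y);
  } else if (kind == ACT_ELU) {
    cube g = y;
    g.transform([](double v) { return v > 0 ? 1.0 : v + 1.0; });
    dy %= g;
  } else {
    for (uword h = 0; h < dy.n_rows; ++h)
      for (uword w = 0; w < dy.n_cols; ++w) {
        vec yv = y.tube(h, w), dv = dy.tube(h, w);
        double s = dot(dv, yv);
        dy.tube(h, w) = yv % (dv - s);
      }
  }
}

static void act_forward_vec(vec& x, int kind) {
  if (kind == ACT_RELU) x.transform([](double v) { return v > 0 ? v : 0.0; });
  else if (kind == ACT_SIGMOID)
    x.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
  else if (kind == ACT_ELU)
    x.transform([](double v) { return v > 0 ? v : std::expm1(v); });
  else {
    x -= x.max(); x = exp(x); x /= accu(x);
  }
}

static void act_backward_vec(vec& dy, const vec& y, int kind) {
  if (kind == ACT_RELU) dy %= conv_to<vec>::from(y > 0);
  else if (kind == ACT_SIGMOID) dy %= y % (1.0 - y);
  else if (kind == ACT_ELU) {
    vec g = y; g.transform([](double v) { return v > 0 ? 1.0 : v + 1.0; });
    dy %= g;
  } else {
    dy = y % (dy - dot(dy, y));
  }
}

// ---------------------------------------------------------------------------
// im2col convolution, stride 1, zero 'same' padding

// dst[(h, w)] = plane(h + dr, w + dc), zero outside
static void shifted_plane(const mat& plane, int dr, int dc, double* dst) {
  int H = plane.n_rows, W = plane.n_cols;
  std::fill(dst, dst + (size_t)H * W, 0.0);
  int h0 = std::max(0, -dr), h1 = std::min(H, H - dr);
  int w0 = std::max(0, -dc), w1 = std::min(W, W - dc);
  if (h1 <= h0 || w1 <= w0) return;
  for (int w = w0; w < w1; ++w) {
    const double* src = plane.colptr(w + dc) + (h0 + dr);
    std::copy(src, src + (h1 - h0), dst + (size_t)w * H + h0);
  }
}

// scatter-add transpose of shifted_plane
static void shifted_plane_add(mat& plane, int dr, int dc, const double* src) {
  int H = plane.n_rows, W = plane.n_cols;
  int h0 = std::max(0, -dr), h1 = std::min(H, H - dr);
  int w0 = std::max(0, -dc), w1 = std::min(W, W - dc);
  if (h1 <= h0 || w1 <= w0) return;
  for (int w = w0; w < w1; ++w) {
    double* dst = plane.colptr(w + dc) + (h0 + dr);
    const double* s = src + (size_t)w * H + h0;
    for (int h = 0; h < h1 - h0; ++h) dst[h] += s[h];
  }
}

// columns ordered (kr fastest, then kc, then ic), matching an R array
// with dim (k, k, Cin, Cout) flattened as a (k*k*Cin) x Cout matrix
static mat im2col(const cube& x, int k) {
  int H = x.n_rows, W = x.n_cols, Cin = x.n_slices, half = (k - 1) / 2;
  mat xcol((size_t)H * W, (size_t)k * k * Cin);
  for (int ic = 0; ic < Cin; ++ic)
    for (int kc = 0; kc < k; ++kc)
      for (int kr = 0; kr < k; ++kr) {
        size_t cidx = (size_t)kr + (size_t)k * kc + (size_t)k * k * ic;
        shifted_plane(x.slice(ic), kr - half, kc - half, xcol.colptr(cidx));
      }
  return xcol;
}

static cube col2im_grad(const mat& dxcol, int H, int W, int Cin, int k) {
  cube dx(H, W, Cin, fill::zeros);
  int half = (k - 1) / 2;
  for (int ic = 0; ic < Cin; ++ic)
    for (int kc = 0; kc < k; ++kc)
      for (int kr = 0; kr < k; ++kr) {
        size_t cidx = (size_t)kr + (size_t)k * kc + (size_t)k * k * ic;
        shifted_plane_add(dx.slice(ic), kr - half, kc - half,
                          dxcol.colptr(cidx));
      }
  return dx;
}

struct ConvCache {
  std::vector<mat> xcol; // per sample
  int H = 0, W = 0, Cin = 0, k = 0;
};

// wmat: (k*k*Cin) x Cout, bias length Cout
static Batch conv_forward(const Batch& x, const mat& wmat, const vec& bias,
                          int k, ConvCache* cache) {
  Batch out(x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    mat xcol = im2col(x[i], k);
    mat y = xcol * wmat;
    y.each_row() += bias.t();
    out[i] = cube(y.memptr(), x[i].n_rows, x[i].n_cols, wmat.n_cols);
    if (cache) {
      if (i == 0) {
        cache->xcol.clear();
        cache->H = x[i].n_rows; cache->W = x[i].n_cols;
        cache->Cin = x[i].n_slices; cache->k = k;
      }
      cache->xcol.push_back(std::move(xcol));
    }
  }
  return out;
}

static Batch conv_backward(const Batch& dout, const ConvCache& cache,
                           const mat& wmat, mat& dw, vec& db) {
  Batch dx(dout.size());
  for (size_t i = 0; i < dout.size(); ++i) {
    mat dy(const_cast<double*>(dout[i].memptr()),
           (size_t)cache.H * cache.W, wmat.n_cols, false, true);
    dw += cache.xcol[i].t() * dy;
    db += sum(dy, 0).t();
    mat dxcol = dy * wmat.t();
    dx[i] = col2im_grad(dxcol, cache.H, cache.W, cache.Cin, cache.k);
  }
  return dx;
}

// ---------------------------------------------------------------------------
// batch normalisation (2-D features, per channel over batch and space)

struct Bn2dCache {
  std::vector<cube> xhat;
  vec invstd;
};

static Batch bn2d_forward(const Batch& x, vec& gamma, vec& beta,
                          vec& run_mean, vec& run_var, bool training,
                          Bn2dCache* cache) {
  uword C = x[0].n_slices, H = x[0].n_rows, W = x[0].n_cols;
  double n = (double)x.size() * H * W;
  vec mean_(C), var_(C);
  if (training) {
    mean_.zeros(); var_.zeros();
    for (const cube& xi : x)
      for (uword c = 0; c < C; ++c) mean_(c) += accu(xi.slice(c));
    mean_ /= n;
    for (const cube& xi : x)
      for (uword c = 0; c < C; ++c)
        var_(c) += accu(square(xi.slice(c) - mean_(c)));
    var_ /= n;
    run_mean = (1 - g_bn_momentum) * run_mean + g_bn_momentum * mean_;
    run_var = (1 - g_bn_momentum) * run_var + g_bn_momentum * var_;
  } else {
    mean_ = run_mean; var_ = run_var;
  }
  vec invstd = 1.0 / sqrt(var_ + BN_EPS);
  Batch out(x.size());
  if (cache) { cache->xhat.clear(); cache->invstd = invstd; }
  for (size_t i = 0; i < x.size(); ++i) {
    cube xhat = x[i];
    for (uword c = 0; c < C; ++c)
      xhat.slice(c) = (xhat.slice(c) - mean_(c)) * invstd(c);
    out[i] = xhat;
    for (uword c = 0; c < C; ++c)
      out[i].slice(c) = gamma(c) * xhat.slice(c) + beta(c);
    if (cache) cache->xhat.push_back(std::move(xhat));
  }
  return out;
}

static Batch bn2d_backward(const Batch& dy, const Bn2dCache& cache,
                           const vec& gamma, vec& dgamma, vec& dbeta) {
  uword C = dy[0].n_slices, H = dy[0].n_rows, W = dy[0].n_cols;
  double n = (double)dy.size() * H * W;
  vec sum_dy(C, fill::zeros), sum_dy_xhat(C, fill::zeros);
  for (size_t i = 0; i < dy.size(); ++i)
    for (uword c = 0; c < C; ++c) {
      sum_dy(c) += accu(dy[i].slice(c));
      sum_dy_xhat(c) += accu(dy[i].slice(c) % cache.xhat[i].slice(c));
    }
  dgamma += sum_dy_xhat;
  dbeta += sum_dy;
  Batch dx(dy.size());
  for (size_t i = 0; i < dy.size(); ++i) {
    dx[i] = dy[i];
    for (uword c = 0; c < C; ++c) {
      dx[i].slice(c) = gamma(c) * cache.invstd(c) / n *
        (n * dy[i].slice(c) - sum_dy(c) -
         cache.xhat[i].slice(c) * sum_dy_xhat(c));
    }
  }
  return dx;
}

// 1-D batch norm over a batch of vectors (used on the W0 pathway)
struct Bn1dCache {
  mat xhat; // C x N
  vec invstd;
};

static mat bn1d_forward(const mat& x, vec& gamma, vec& beta, vec& run_mean,
                        vec& run_var, bool training, Bn1dCache* cache) {
  double n = x.n_cols;
  vec mean_, var_;
  if (training && x.n_cols > 1) {
    mean_ = mean(x, 1);
    var_ = mean(square(x.each_col() - mean_), 1);
    run_mean = (1 - g_bn_momentum) * run_mean + g_bn_momentum * mean_;
    run_var = (1 - g_bn_momentum) * run_var + g_bn_momentum * var_;
  } else {
    mean_ = run_mean; var_ = run_var;
  }
  vec invstd = 1.0 / sqrt(var_ + BN_EPS);
  mat xhat = x.each_col() - mean_;
  xhat.each_col() %= invstd;
  if (cache) { cache->xhat = xhat; cache->invstd = invstd; }
  mat out = xhat.each_col() % gamma;
  out.each_col() += beta;
  (void)n;
  return out;
}

static mat bn1d_backward(const mat& dy, const Bn1dCache& cache,
                         const vec& gamma, vec& dgamma, vec& dbeta,
                         bool batch_stats) {
  double n = dy.n_cols;
  vec sum_dy = sum(dy, 1);
  vec sum_dy_xhat = sum(dy % cache.xhat, 1);
  dgamma += sum_dy_xhat;
  dbeta += sum_dy;
  if (!batch_stats) {
    // stats were not functions of the batch: plain affine backprop
    mat dx = dy.each_col() % (gamma % cache.invstd);
    return dx;
  }
  mat dx = n * dy;
  dx.each_col() -= sum_dy;
  dx -= cache.xhat.each_col() % sum_dy_xhat;
  dx.each_col() %= gamma % cache.invstd / n;
  return dx;
}

// ---------------------------------------------------------------------------
// max pooling (features), with argmax cache

struct PoolCache {
  // argmax linear index (within the input plane) per output cell/channel
  std::vector<umat> argmax; // per sample: (Hout*Wout) x C
  int Hin = 0, Win = 0, Hout = 0, Wout = 0;
  bool skipped = false;
};

static Batch maxpool_forward(const Batch& x, int size, int stride,
                             PoolCache* cache) {
  int H = x[0].n_rows, W = x[0].n_cols, C = x[0].n_slices;
  if (H < size || W < size) { // window larger than map: identity
    if (cache) { cache->skipped = true; }
    return x;
  }
  int Hout = (H - size) / stride + 1, Wout = (W - size) / stride + 1;
  if (cache) {
    cache->argmax.clear();
    cache->Hin = H; cache->Win = W; cache->Hout = Hout; cache->Wout = Wout;
    cache->skipped = false;
  }
  Batch out(x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    cube o(Hout, Wout, C);
    umat am((size_t)Hout * Wout, C);
    for (int c = 0; c < C; ++c) {
      const mat& plane = x[i].slice(c);
      for (int ow = 0; ow < Wout; ++ow)
        for (int oh = 0; oh < Hout; ++oh) {
          int r0 = oh * stride, c0 = ow * stride;
          double best = plane(r0, c0);
          int br = r0, bc = c0;
          for (int dc = 0; dc < size; ++dc)
            for (int dr = 0; dr < size; ++dr) {
              double v = plane(r0 + dr, c0 + dc);
              if (v > best) { best = v; br = r0 + dr; bc = c0 + dc; }
            }
          o(oh, ow, c) = best;
          am((size_t)oh + (size_t)Hout * ow, c) = (uword)br + (uword)H * bc;
        }
    }
    out[i] = std::move(o);
    if (cache) cache->argmax.push_back(std::move(am));
  }
  return out;
}

static Batch maxpool_backward(const Batch& dy, const PoolCache& cache, int C) {
  if (cache.skipped) return dy;
  Batch dx(dy.size());
  for (size_t i = 0; i < dy.size(); ++i) {
    cube d(cache.Hin, cache.Win, C, fill::zeros);
    for (int c = 0; c < C; ++c) {
      const mat& dplane = dy[i].slice(c);
      mat& dst = d.slice(c);
      for (uword j = 0; j < dplane.n_elem; ++j)
        dst(cache.argmax[i](j, c)) += dplane(j);
    }
    dx[i] = std::move(d);
  }
  return dx;
}

// max pool for a single 2-D map (cross-layer spatial attention transfer)
static mat maxpool_map(const mat& x, int size, int stride, umat* argmax) {
  int H = x.n_rows, W = x.n_cols;
  int Hout = (H - size) / stride + 1, Wout = (W - size) / stride + 1;
  mat out(Hout, Wout);
  if (argmax) argmax->set_size(Hout, Wout);
  for (int ow = 0; ow < Wout; ++ow)
    for (int oh = 0; oh < Hout; ++oh) {
      int r0 = oh * stride, c0 = ow * stride;
      double best = x(r0, c0);
      uword bi = (uword)r0 + (uword)H * c0;
      for (int dc = 0; dc < size; ++dc)
        for (int dr = 0; dr < size; ++dr) {
          double v = x(r0 + dr, c0 + dc);
          if (v > best) { best = v; bi = (uword)(r0 + dr) + (uword)H * (c0 + dc); }
        }
      out(oh, ow) = best;
      if (argmax) (*argmax)(oh, ow) = bi;
    }
  return out;
}

// ---------------------------------------------------------------------------
// shared MLP of the channel attention (C -> hidden -> C, ReLU inside)

struct MlpCache {
  vec input, hidden_act, out;
};

static vec mlp_forward(ParamStore& ps, const std::string& pre, const vec& v,
                       MlpCache* cache) {
  uword C = ps.at(pre + "_b2").n_elem;
  uword h = ps.at(pre + "_b1").n_elem;
  mat w1 = ps.as_mat(pre + "_w1", h, C);
  mat w2 = ps.as_mat(pre + "_w2", C, h);
  vec hid = w1 * v + ps.at(pre + "_b1");
  hid.transform([](double x) { return x > 0 ? x : 0.0; });
  vec out = w2 * hid + ps.at(pre + "_b2");
  if (cache) { cache->input = v; cache->hidden_act = hid; cache->out = out; }
  return out;
}

static vec mlp_backward(ParamStore& ps, ParamStore& grads,
                        const std::string& pre, const vec& dout,
                        const MlpCache& cache) {
  uword C = ps.at(pre + "_b2").n_elem;
  uword h = ps.at(pre + "_b1").n_elem;
  mat w1 = ps.as_mat(pre + "_w1", h, C);
  mat w2 = ps.as_mat(pre + "_w2", C, h);
  mat dw2 = grads.as_mat(pre + "_w2", C, h);
  mat dw1 = grads.as_mat(pre + "_w1", h, C);
  dw2 += dout * cache.hidden_act.t();
  grads.at(pre + "_b2") += dout;
  vec dh = w2.t() * dout;
  dh %= conv_to<vec>::from(cache.hidden_act > 0);
  dw1 += dh * cache.input.t();
  grads.at(pre + "_b1") += dh;
  return w1.t() * dh;
}

// ---------------------------------------------------------------------------
// channel attention block

struct ChannelAttCache {
  std::vector<vec> avg, mx, z, weights;     // per sample
  std::vector<uvec> argmax;                 // spatial argmax per channel
  std::vector<MlpCache> mlp_avg, mlp_max, mlp_prev;
  std::vector<vec> w0_relu;                 // relu(BN(W0 m_prev)) per sample
  Bn1dCache w0bn;
  mat w0_in;                                // C_prev x N (previous weights)
  bool has_prev = false;
  bool training = false;
};

// F -> F', filling cache; prev_weights may be empty (first block)
static Batch channel_att_forward(ParamStore& ps, const std::string& pre,
                                 const Batch& f,
                                 const std::vector<vec>& prev_weights,
                                 bool training, ChannelAttCache* cache) {
  uword C = f[0].n_slices;
  size_t N = f.size();
  bool has_prev = !prev_weights.empty();
  vec lambda = ps.at(pre + "_lambda");

  mat w0_relu_all;
  Bn1dCache w0bn_cache;
  std::vector<MlpCache> mlp_prev_cache(N);
  if (has_prev) {
    uword Cprev = prev_weights[0].n_elem;
    mat w0 = ps.as_mat(pre + "_w0_w", C, Cprev);
    mat u(C, N);
    for (size_t i = 0; i < N; ++i)
      u.col(i) = w0 * prev_weights[i] + ps.at(pre + "_w0_b");
    mat ubn = bn1d_forward(u, ps.at(pre + "_w0bn_gamma"),
                           ps.at(pre + "_w0bn_beta"),
                           ps.at(pre + "_w0bn_mean"),
                           ps.at(pre + "_w0bn_var"),
                           training, &w0bn_cache);
    ubn.transform([](double x) { return x > 0 ? x : 0.0; });
    w0_relu_all = ubn;
    if (cache) {
      cache->w0bn = w0bn_cache;
      cache->w0_in.set_size(Cprev, N);
      for (size_t i = 0; i < N; ++i) cache->w0_in.col(i) = prev_weights[i];
    }
  }

  Batch out(N);
  if (cache) {
    cache->avg.assign(N, vec()); cache->mx.assign(N, vec());
    cache->z.assign(N, vec()); cache->weights.assign(N, vec());
    cache->argmax.assign(N, uvec());
    cache->mlp_avg.assign(N, MlpCache()); cache->mlp_max.assign(N, MlpCache());
    cache->mlp_prev.assign(N, MlpCache());
    cache->w0_relu.assign(N, vec());
    cache->has_prev = has_prev;
    cache->training = training;
  }
  for (size_t i = 0; i < N; ++i) {
    vec avg(C), mx(C);
    uvec am(C);
    for (uword c = 0; c < C; ++c) {
      const mat& plane = f[i].slice(c);
      avg(c) = accu(plane) / plane.n_elem;
      am(c) = plane.index_max();
      mx(c) = plane(am(c));
    }
    MlpCache ca, cm;
    vec za = mlp_forward(ps, pre + "_mlp", avg, cache ? &ca : nullptr);
    vec zm = mlp_forward(ps, pre + "_mlp", mx, cache ? &cm : nullptr);
    vec z = lambda(0) * za + lambda(1) * zm;
    if (has_prev) {
      vec r = w0_relu_all.col(i);
      MlpCache cp;
      vec zp = mlp_forward(ps, pre + "_mlp", r, cache ? &cp : nullptr);
      z += lambda(2) * zp;
      if (cache) { cache->mlp_prev[i] = cp; cache->w0_relu[i] = r; }
    }
    vec w = 1.0 / (1.0 + exp(-z));
    out[i] = f[i];
    for (uword c = 0; c < C; ++c) out[i].slice(c) *= w(c);
    if (cache) {
      cache->avg[i] = avg; cache->mx[i] = mx;
      cache->argmax[i] = am;
      cache->z[i] = z; cache->weights[i] = w;
      cache->mlp_avg[i] = ca; cache->mlp_max[i] = cm;
    }
  }
  return out;
}

// returns dF; dprev (if any) accumulated into dprev_out
static Batch channel_att_backward(ParamStore& ps, ParamStore& grads,
                                  const std::string& pre, const Batch& f,
                                  const Batch& dfp,
                                  const std::vector<vec>& dw_ext,
                                  ChannelAttCache& cache,
                                  std::vector<vec>* dprev_out) {
  uword C = f[0].n_slices;
  size_t N = f.size();
  vec lambda = ps.at(pre + "_lambda");
  vec dlambda(lambda.n_elem, fill::zeros);
  Batch df(N);
  mat d_w0relu;
  if (cache.has_prev) d_w0relu.zeros(C, N);

  for (size_t i = 0; i < N; ++i) {
    const vec& w = cache.weights[i];
    // dM from the product path plus any external contribution
    vec dM(C, fill::zeros);
    for (uword c = 0; c < C; ++c)
      dM(c) = accu(dfp[i].slice(c) % f[i].slice(c));
    if (!dw_ext.empty()) dM += dw_ext[i];
    // dF from the product path
    df[i] = dfp[i];
    for (uword c = 0; c < C; ++c) df[i].slice(c) *= w(c);
    // through the sigmoid
    vec dz = dM % w % (1.0 - w);
    // lambda gradients
    dlambda(0) += dot(dz, cache.mlp_avg[i].out);
    dlambda(1) += dot(dz, cache.mlp_max[i].out);
    // through the shared MLP, avg branch
    vec davg = mlp_backward(ps, grads, pre + "_mlp", lambda(0) * dz,
                            cache.mlp_avg[i]);
    vec dmx = mlp_backward(ps, grads, pre + "_mlp", lambda(1) * dz,
                           cache.mlp_max[i]);
    double hw = f[i].n_rows * f[i].n_cols;
    for (uword c = 0; c < C; ++c) {
      df[i].slice(c) += davg(c) / hw;
      df[i].slice(c)(cache.argmax[i](c)) += dmx(c);
    }
    if (cache.has_prev) {
      dlambda(2) += dot(dz, cache.mlp_prev[i].out);
      vec dr = mlp_backward(ps, grads, pre + "_mlp", lambda(2) * dz,
                            cache.mlp_prev[i]);
      // relu gate
      dr %= conv_to<vec>::from(cache.w0_relu[i] > 0);
      d_w0relu.col(i) = dr;
    }
  }
  grads.at(pre + "_lambda") += dlambda;

  if (cache.has_prev && dprev_out) {
    uword Cprev = cache.w0_in.n_rows;
    mat du = bn1d_backward(d_w0relu, cache.w0bn,
                           ps.at(pre + "_w0bn_gamma"),
                           grads.at(pre + "_w0bn_gamma"),
                           grads.at(pre + "_w0bn_beta"),
                           cache.training && N > 1);
    mat w0 = ps.as_mat(pre + "_w0_w", C, Cprev);
    mat dw0 = grads.as_mat(pre + "_w0_w", C, Cprev);
    dw0 += du * cache.w0_in.t();
    grads.at(pre + "_w0_b") += sum(du, 1);
    mat dprev = w0.t() * du;
    dprev_out->resize(N);
    for (size_t i = 0; i < N; ++i) (*dprev_out)[i] = dprev.col(i);
  }
  return df;
}

// ---------------------------------------------------------------------------
// spatial attention block

struct SpatialAttCache {
  std::vector<mat> avg, mx, z, map;  // per sample
  std::vector<umat> argmax_chan;     // channel index of per-pixel max
  std::vector<mat> stack_xcol;       // im2col of the stacked maps (ws conv)
  std::vector<mat> wl_xcol;          // im2col of the pooled prev map
  std::vector<umat> pool_argmax;     // argmax of prev-map pooling
  std::vector<mat> pooled_prev;
  int Hprev = 0, Wprev = 0;
  bool pooled = false;
  bool has_prev = false;
  int n_in = 2;
};

static Batch spatial_att_forward(ParamStore& ps, const std::string& pre,
                                 const Batch& f,
                                 const std::vector<mat>& prev_maps,
                                 int pool_size, int pool_stride,
                                 SpatialAttCache* cache) {
  uword H = f[0].n_rows, W = f[0].n_cols, C = f[0].n_slices;
  size_t N = f.size();
  bool has_prev = !prev_maps.empty();
  int n_in = has_prev ? 3 : 2;
  int ws_k = std::lround(std::sqrt((double)ps.at(pre + "_ws_w").n_elem / n_in));
  mat ws = mat(ps.at(pre + "_ws_w").memptr(), (size_t)ws_k * ws_k * n_in, 1,
               false, true);
  double ws_b = ps.at(pre + "_ws_b")(0);

  if (cache) {
    cache->avg.assign(N, mat()); cache->mx.assign(N, mat());
    cache->z.assign(N, mat()); cache->map.assign(N, mat());
    cache->argmax_chan.assign(N, umat());
    cache->stack_xcol.assign(N, mat());
    cache->wl_xcol.assign(N, mat());
    cache->pool_argmax.assign(N, umat());
    cache->pooled_prev.assign(N, mat());
    cache->has_prev = has_prev;
    cache->n_in = n_in;
  }

  Batch out(N);
  for (size_t i = 0; i < N; ++i) {
    mat avg(H, W, fill::zeros), mx(H, W);
    umat amc(H, W);
    for (uword c = 0; c < C; ++c) avg += f[i].slice(c);
    avg /= (double)C;
    mx = f[i].slice(0); amc.fill(0);
    for (uword c = 1; c < C; ++c) {
      const mat& plane = f[i].slice(c);
      for (uword j = 0; j < mx.n_elem; ++j)
        if (plane(j) > mx(j)) { mx(j) = plane(j); amc(j) = c; }
    }
    cube stacked(H, W, n_in);
    stacked.slice(0) = avg;
    stacked.slice(1) = mx;
    if (has_prev) {
      mat pm = prev_maps[i];
      umat pam;
      bool pooled = false;
      if (pm.n_rows != H || pm.n_cols != W) {
        pm = maxpool_map(pm, pool_size, pool_stride, &pam);
        pooled = true;
        if (pm.n_rows != H || pm.n_cols != W)
          Rcpp::stop("cannot pool previous attention map to feature size");
      }
      int wl_k = std::lround(std::sqrt((double)ps.at(pre + "_wl_w").n_elem));
      cube pmc(pm.memptr(), H, W, 1);
      mat wl_xcol = im2col(pmc, wl_k);
      mat wl = mat(ps.at(pre + "_wl_w").memptr(), (size_t)wl_k * wl_k, 1,
                   false, true);
      vec t = wl_xcol * wl + ps.at(pre + "_wl_b")(0);
      stacked.slice(2) = mat(t.memptr(), H, W);
      if (cache) {
        cache->wl_xcol[i] = std::move(wl_xcol);
        cache->pool_argmax[i] = pam;
        cache->pooled_prev[i] = pm;
        cache->pooled = pooled;
        cache->Hprev = prev_maps[i].n_rows;
        cache->Wprev = prev_maps[i].n_cols;
      }
    }
    mat st_xcol = im2col(stacked, ws_k);
    vec zv = st_xcol * ws + ws_b;
    mat z(zv.memptr(), H, W);
    mat m = 1.0 / (1.0 + exp(-z));
    out[i] = f[i];
    for (uword c = 0; c < C; ++c) out[i].slice(c) %= m;
    if (cache) {
      cache->avg[i] = std::move(avg); cache->mx[i] = std::move(mx);
      cache->argmax_chan[i] = std::move(amc);
      cache->stack_xcol[i] = std::move(st_xcol);
      cache->z[i] = z; cache->map[i] = m;
    }
  }
  return out;
}

static Batch spatial_att_backward(ParamStore& ps, ParamStore& grads,
                                  const std::string& pre, const Batch& f,
                                  const Batch& dfp,
                                  const std::vector<mat>& dmap_ext,
                                  SpatialAttCache& cache,
                                  std::vector<mat>* dprev_out) {
  uword H = f[0].n_rows, W = f[0].n_cols, C = f[0].n_slices;
  size_t N = f.size();
  int n_in = cache.n_in;
  int ws_k = std::lround(std::sqrt((double)ps.at(pre + "_ws_w").n_elem / n_in));
  mat ws = mat(ps.at(pre + "_ws_w").memptr(), (size_t)ws_k * ws_k * n_in, 1,
               false, true);
  mat dws = mat(grads.at(pre + "_ws_w").memptr(),
                (size_t)ws_k * ws_k * n_in, 1, false, true);
  if (dprev_out) dprev_out->assign(N, mat());

  Batch df(N);
  for (size_t i = 0; i < N; ++i) {
    const mat& m = cache.map[i];
    mat dM(H, W, fill::zeros);
    for (uword c = 0; c < C; ++c) dM += dfp[i].slice(c) % f[i].slice(c);
    if (!dmap_ext.empty() && dmap_ext[i].n_elem > 0) dM += dmap_ext[i];
    df[i] = dfp[i];
    for (uword c = 0; c < C; ++c) df[i].slice(c) %= m;
    mat dz = dM % m % (1.0 - m);
    // ws conv backward
    mat dzcol(dz.memptr(), (size_t)H * W, 1, false, true);
    dws += cache.stack_xcol[i].t() * dzcol;
    grads.at(pre + "_ws_b")(0) += accu(dz);
    mat dstack_col = dzcol * ws.t();
    cube dstack = col2im_grad(dstack_col, H, W, n_in, ws_k);
    // avg map: spread over channels
    for (uword c = 0; c < C; ++c) df[i].slice(c) += dstack.slice(0) / (double)C;
    // max map: route to argmax channel
    const umat& amc = cache.argmax_chan[i];
    const mat& dmx = dstack.slice(1);
    for (uword j = 0; j < dmx.n_elem; ++j)
      df[i].slice(amc(j))(j) += dmx(j);
    if (cache.has_prev) {
      int wl_k = std::lround(std::sqrt((double)ps.at(pre + "_wl_w").n_elem));
      mat wl = mat(ps.at(pre + "_wl_w").memptr(), (size_t)wl_k * wl_k, 1,
                   false, true);
      mat dwl = mat(grads.at(pre + "_wl_w").memptr(), (size_t)wl_k * wl_k, 1,
                    false, true);
      mat dt = dstack.slice(2);
      mat dtcol(dt.memptr(), (size_t)H * W, 1, false, true);
      dwl += cache.wl_xcol[i].t() * dtcol;
      grads.at(pre + "_wl_b")(0) += accu(dt);
      mat dpooled_col = dtcol * wl.t();
      cube dpooled_c = col2im_grad(dpooled_col, H, W, 1, wl_k);
      mat dpooled = dpooled_c.slice(0);
      if (dprev_out) {
        if (cache.pooled) {
          mat dprev(cache.Hprev, cache.Wprev, fill::zeros);
          const umat& pam = cache.pool_argmax[i];
          for (uword j = 0; j < dpooled.n_elem; ++j)
            dprev(pam(j)) += dpooled(j);
          (*dprev_out)[i] = std::move(dprev);
        } else {
          (*dprev_out)[i] = std::move(dpooled);
        }
      }
    }
  }
  return df;
}

// ---------------------------------------------------------------------------
// network configuration

struct NetConfig {
  bool has_spectral, has_spatial;
  ivec spec_filters, spat_filters, spec_kernels, spat_kernels;
  int spec_pool_size, spec_pool_stride, spat_pool_size, spat_pool_stride;
  int fc1, fc2;
  int act;
  int att_mode;
  int bands;
};

static NetConfig config_from_list(const List& cfg) {
  NetConfig c;
  c.has_spectral = Rcpp::as<bool>(cfg["has_spectral"]);
  c.has_spatial = Rcpp::as<bool>(cfg["has_spatial"]);
  c.spec_filters = Rcpp::as<ivec>(cfg["spec_filters"]);
  c.spat_filters = Rcpp::as<ivec>(cfg["spat_filters"]);
  c.spec_kernels = Rcpp::as<ivec>(cfg["spec_kernels"]);
  c.spat_kernels = Rcpp::as<ivec>(cfg["spat_kernels"]);
  c.spec_pool_size = Rcpp::as<int>(cfg["spec_pool_size"]);
  c.spec_pool_stride = Rcpp::as<int>(cfg["spec_pool_stride"]);
  c.spat_pool_size = Rcpp::as<int>(cfg["spat_pool_size"]);
  c.spat_pool_stride = Rcpp::as<int>(cfg["spat_pool_stride"]);
  IntegerVector fc = cfg["fc"];
  c.fc1 = fc[0]; c.fc2 = fc[1];
  c.act = Rcpp::as<int>(cfg["activation"]);
  c.att_mode = Rcpp::as<int>(cfg["attention"]);
  c.bands = Rcpp::as<int>(cfg["bands"]);
  return c;
}

// per-branch forward caches for one pass
struct BlockCache {
  ConvCache conv;
  Bn2dCache bn;
  Batch bn_out;        // pre-activation not needed; post-act stored below
  Batch act_out;       // F^l (input to attention)
  ChannelAttCache catt;
  SpatialAttCache satt;
  Batch att_out;
  PoolCache pool;
  int C = 0;
};

struct BranchCache {
  std::vector<BlockCache> blocks;
  Batch gap_in; // input of global average pooling
};

// run one branch (3 conv blocks + GAP); attention kind: 0 channel, 1 spatial
static mat branch_forward(ParamStore& ps, const NetConfig& cfg,
                          const std::string& prefix, int att_kind,
                          const Batch& input, bool training,
                          BranchCache* bc) {
  const ivec& filters = att_kind == 0 ? cfg.spec_filters : cfg.spat_filters;
  const ivec& kernels = att_kind == 0 ? cfg.spec_kernels : cfg.spat_kernels;
  int pool_size = att_kind == 0 ? cfg.spec_pool_size : cfg.spat_pool_size;
  int pool_stride = att_kind == 0 ? cfg.spec_pool_stride : cfg.spat_pool_stride;

  Batch x = input;
  std::vector<vec> prev_w;  // channel attention state
  std::vector<mat> prev_m;  // spatial attention state
  if (bc) bc->blocks.assign(3, BlockCache());

  for (int l = 0; l < 3; ++l) {
    std::string li = std::to_string(l + 1);
    int cin = x[0].n_slices, cout = filters(l), k = kernels(l);
    mat w = ps.as_mat(prefix + "_conv" + li + "_w",
                      (uword)k * k * cin, cout);
    BlockCache* blk = bc ? &bc->blocks[l] : nullptr;
    if (blk) blk->C = cout;
    x = conv_forward(x, w, ps.at(prefix + "_conv" + li + "_b"), k,
                     blk ? &blk->conv : nullptr);
    x = bn2d_forward(x, ps.at(prefix + "_bn" + li + "_gamma"),
                     ps.at(prefix + "_bn" + li + "_beta"),
                     ps.at(prefix + "_bn" + li + "_mean"),
                     ps.at(prefix + "_bn" + li + "_var"),
                     training, blk ? &blk->bn : nullptr);
    for (cube& xi : x) act_forward(xi, cfg.act);
    if (blk) blk->act_out = x;
    if (cfg.att_mode == ATT_ON) {
      std::string ap = prefix + "_att" + li;
      if (att_kind == 0) {
        ChannelAttCache* ac = blk ? &blk->catt : nullptr;
        ChannelAttCache tmp;
        if (!ac) ac = &tmp;
        x = channel_att_forward(ps, ap, x, prev_w, training, ac);
        prev_w = ac->weights;
      } else {
        SpatialAttCache* ac = blk ? &blk->satt : nullptr;
        SpatialAttCache tmp;
        if (!ac) ac = &tmp;
        x = spatial_att_forward(ps, ap, x, prev_m, pool_size, pool_stride, ac);
        prev_m = ac->map;
      }
    } else if (cfg.att_mode == ATT_FROZEN) {
      // attention map frozen at 1: multiply through for bit-level parity
      for (cube& xi : x) xi *= 1.0;
    }
    if (blk) blk->att_out = x;
    x = maxpool_forward(x, pool_size, pool_stride, blk ? &blk->pool : nullptr);
  }
  if (bc) bc->gap_in = x;
  // global average pooling to a feature vector per sample
  uword C = x[0].n_slices;
  mat feats(C, x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    for (uword c = 0; c < C; ++c)
      feats(c, i) = accu(x[i].slice(c)) / (double)x[i].slice(c).n_elem;
  }
  return feats;
}

static Batch branch_backward(ParamStore& ps, ParamStore& grads,
                             const NetConfig& cfg, const std::string& prefix,
                             int att_kind, const mat& dfeat,
                             BranchCache& bc) {
  const ivec& filters = att_kind == 0 ? cfg.spec_filters : cfg.spat_filters;
  const ivec& kernels = att_kind == 0 ? cfg.spec_kernels : cfg.spat_kernels;
  size_t N = dfeat.n_cols;

  // GAP backward
  Batch dx(N);
  uword C = bc.gap_in[0].n_slices;
  for (size_t i = 0; i < N; ++i) {
    dx[i] = cube(bc.gap_in[i].n_rows, bc.gap_in[i].n_cols, C);
    double hw = bc.gap_in[i].n_rows * bc.gap_in[i].n_cols;
    for (uword c = 0; c < C; ++c) dx[i].slice(c).fill(dfeat(c, i) / hw);
  }

  std::vector<vec> dprev_w;  // gradient w.r.t. previous block's weights
  std::vector<mat> dprev_m;
  for (int l = 2; l >= 0; --l) {
    std::string li = std::to_string(l + 1);
    BlockCache& blk = bc.blocks[l];
    dx = maxpool_backward(dx, blk.pool, blk.C);
    if (cfg.att_mode == ATT_ON) {
      std::string ap = prefix + "_att" + li;
      if (att_kind == 0) {
        std::vector<vec> dprev_next;
        dx = channel_att_backward(ps, grads, ap, blk.act_out, dx, dprev_w,
                                  blk.catt, l > 0 ? &dprev_next : nullptr);
        dprev_w = dprev_next;
      } else {
        std::vector<mat> dprev_next;
        dx = spatial_att_backward(ps, grads, ap, blk.act_out, dx, dprev_m,
                                  blk.satt, l > 0 ? &dprev_next : nullptr);
        dprev_m = dprev_next;
      }
    }
    for (size_t i = 0; i < N; ++i)
      act_backward(dx[i], blk.act_out[i], cfg.act);
    dx = bn2d_backward(dx, blk.bn, ps.at(prefix + "_bn" + li + "_gamma"),
                       grads.at(prefix + "_bn" + li + "_gamma"),
                       grads.at(prefix + "_bn" + li + "_beta"));
    int cin = blk.conv.Cin, k = kernels(l);
    mat w = ps.as_mat(prefix + "_conv" + li + "_w",
                      (uword)k * k * cin, filters(l));
    mat dw = grads.as_mat(prefix + "_conv" + li + "_w",
                          (uword)k * k * cin, filters(l));
    dx = conv_backward(dx, blk.conv, w, dw,
                       grads.at(prefix + "_conv" + li + "_b"));
  }
  return dx;
}

struct HeadCache {
  mat input, h1, h2; // post-activation
};

static vec head_forward(ParamStore& ps, const NetConfig& cfg,
                        const mat& feats, HeadCache* hc) {
  uword nin = feats.n_rows;
  mat w1 = ps.as_mat("fc1_w", cfg.fc1, nin);
  mat w2 = ps.as_mat("fc2_w", cfg.fc2, cfg.fc1);
  mat wo = ps.as_mat("out_w", 1, cfg.fc2);
  mat h1 = w1 * feats;
  h1.each_col() += ps.at("fc1_b");
  for (uword i = 0; i < h1.n_cols; ++i) {
    vec col = h1.col(i); act_forward_vec(col, cfg.act); h1.col(i) = col;
  }
  mat h2 = w2 * h1;
  h2.each_col() += ps.at("fc2_b");
  for (uword i = 0; i < h2.n_cols; ++i) {
    vec col = h2.col(i); act_forward_vec(col, cfg.act); h2.col(i) = col;
  }
  vec yhat = (wo * h2).t() + ps.at("out_b")(0);
  if (hc) { hc->input = feats; hc->h1 = h1; hc->h2 = h2; }
  return yhat;
}

static mat head_backward(ParamStore& ps, ParamStore& grads,
                         const NetConfig& cfg, const vec& dyhat,
                         const HeadCache& hc) {
  uword nin = hc.input.n_rows;
  mat w1 = ps.as_mat("fc1_w", cfg.fc1, nin);
  mat w2 = ps.as_mat("fc2_w", cfg.fc2, cfg.fc1);
  mat wo = ps.as_mat("out_w", 1, cfg.fc2);
  mat dwo = grads.as_mat("out_w", 1, cfg.fc2);
  dwo += dyhat.t() * hc.h2.t();
  grads.at("out_b")(0) += accu(dyhat);
  mat dh2 = wo.t() * dyhat.t();
  for (uword i = 0; i < dh2.n_cols; ++i) {
    vec col = dh2.col(i), y = hc.h2.col(i);
    act_backward_vec(col, y, cfg.act);
    dh2.col(i) = col;
  }
  mat dw2 = grads.as_mat("fc2_w", cfg.fc2, cfg.fc1);
  dw2 += dh2 * hc.h1.t();
  grads.at("fc2_b") += sum(dh2, 1);
  mat dh1 = w2.t() * dh2;
  for (uword i = 0; i < dh1.n_cols; ++i) {
    vec col = dh1.col(i), y = hc.h1.col(i);
    act_backward_vec(col, y, cfg.act);
    dh1.col(i) = col;
  }
  mat dw1 = grads.as_mat("fc1_w", cfg.fc1, nin);
  dw1 += dh1 * hc.input.t();
  grads.at("fc1_b") += sum(dh1, 1);
  return w1.t() * dh1;
}

struct NetCache {
  BranchCache spec, spat;
  HeadCache head;
  uword n_spec_feat = 0, n_spat_feat = 0;
};

static vec net_forward(ParamStore& ps, const NetConfig& cfg,
                       const Batch& xs, const Batch& xp, bool training,
                       NetCache* nc) {
  mat feats;
  if (cfg.has_spectral) {
    mat fs = branch_forward(ps, cfg, "c", 0, xs, training,
                            nc ? &nc->spec : nullptr);
    if (nc) nc->n_spec_feat = fs.n_rows;
    feats = fs;
  }
  if (cfg.has_spatial) {
    mat fp = branch_forward(ps, cfg, "s", 1, xp, training,
                            nc ? &nc->spat : nullptr);
    if (nc) nc->n_spat_feat = fp.n_rows;
    feats = cfg.has_spectral ? join_cols(feats, fp) : fp;
  }
  return head_forward(ps, cfg, feats, nc ? &nc->head : nullptr);
}

static void net_backward(ParamStore& ps, ParamStore& grads,
                         const NetConfig& cfg, const vec& dyhat,
                         NetCache& nc) {
  mat dfeat = head_backward(ps, grads, cfg, dyhat, nc.head);
  if (cfg.has_spectral) {
    mat dfs = dfeat.rows(0, nc.n_spec_feat - 1);
    branch_backward(ps, grads, cfg, "c", 0, dfs, nc.spec);
  }
  if (cfg.has_spatial) {
    uword first = cfg.has_spectral ? nc.n_spec_feat : 0;
    mat dfp = dfeat.rows(first, first + nc.n_spat_feat - 1);
    branch_backward(ps, grads, cfg, "s", 1, dfp, nc.spat);
  }
}

// ---------------------------------------------------------------------------
// optimisers

enum OptKind { OPT_SGD = 0, OPT_ADAM = 1, OPT_ADABOUND = 2, OPT_RMSPROP = 3 };

struct Optimizer {
  int kind;
  double lr;
  double weight_decay = 0.0;
  std::map<std::string, vec> m, v;
  long t = 0;

  void step(ParamStore& ps, ParamStore& grads) {
    ++t;
    for (auto& kvp : ps.values) {
      const std::string& name = kvp.first;
      if (is_buffer(name)) continue;
      vec& p = kvp.second;
      vec& g = grads.at(name);
      if (weight_decay > 0) g += weight_decay * p;
      if (kind == OPT_SGD) {
        p -= lr * g;
      } else if (kind == OPT_RMSPROP) {
        vec& vv = state(v, name, p.n_elem);
        vv = 0.9 * vv + 0.1 * square(g);
        p -= lr * g / (sqrt(vv) + 1e-8);
      } else { // Adam / AdaBound
        vec& mm = state(m, name, p.n_elem);
        vec& vv = state(v, name, p.n_elem);
        mm = 0.9 * mm + 0.1 * g;
        vv = 0.999 * vv + 0.001 * square(g);
        double bc1 = 1.0 - std::pow(0.9, (double)t);
        double bc2 = 1.0 - std::pow(0.999, (double)t);
        if (kind == OPT_ADAM) {
          p -= lr * (mm / bc1) / (sqrt(vv / bc2) + 1e-8);
        } else {
          // AdaBound: per-element step size clipped into a band that
          // converges to final_lr, interpolating Adam -> SGD
          double final_lr = 0.1;
          double gamma_ = 1e-3;
          double lower = final_lr * (1.0 - 1.0 / (gamma_ * t + 1.0));
          double upper = final_lr * (1.0 + 1.0 / (gamma_ * t));
          vec eta = lr / (sqrt(vv / bc2) + 1e-8);
          eta.transform([&](double e) {
            return std::min(std::max(e, lower), upper);
          });
          p -= eta % (mm / bc1);
        }
      }
    }
  }

  vec& state(std::map<std::string, vec>& store, const std::string& name,
             uword n) {
    auto it = store.find(name);
    if (it == store.end()) {
      store[name] = vec(n, fill::zeros);
      return store[name];
    }
    return it->second;
  }
};

// ---------------------------------------------------------------------------
// exported entry points

static ParamStore zero_grads(const ParamStore& ps) {
  ParamStore g;
  for (const auto& kvp : ps.values)
    g.values[kvp.first] = vec(kvp.second.n_elem, fill::zeros);
  return g;
}

static Batch subset_batch(const Batch& b, const std::vector<uword>& idx) {
  Batch out(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) out[i] = b[idx[i]];
  return out;
}

// [[Rcpp::export]]
List cpp_train(List params_list, List cfg_list, NumericVector xs,
               NumericVector xp, NumericVector y, int epochs,
               int batch_size, double lr, int optimizer, double weight_decay,
               int seed, NumericVector xs_val, NumericVector xp_val,
               NumericVector y_val) {
  NetConfig cfg = config_from_list(cfg_list);
  ParamStore ps = params_from_list(params_list);
  Batch bxs, bxp;
  size_t n = 0;
  if (cfg.has_spectral) { bxs = batch_from_array(xs); n = bxs.size(); }
  if (cfg.has_spatial) { bxp = batch_from_array(xp); n = bxp.size(); }
  if (n == 0) Rcpp::stop("empty training set");
  vec yv(y.begin(), y.size());
  if (yv.n_elem != n) Rcpp::stop("labels do not match the number of patches");

  bool has_val = y_val.size() > 0;
  Batch vxs, vxp;
  vec yval;
  if (has_val) {
    if (cfg.has_spectral) vxs = batch_from_array(xs_val);
    if (cfg.has_spatial) vxp = batch_from_array(xp_val);
    yval = vec(y_val.begin(), y_val.size());
  }

  Optimizer opt;
  opt.kind = optimizer;
  opt.lr = lr;
  opt.weight_decay = weight_decay;
  std::mt19937 rng(seed);

  std::vector<double> loss_hist, val_hist;
  std::vector<uword> order(n);
  for (size_t i = 0; i < n; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    size_t nb = 0;
    for (size_t start = 0; start < n; start += batch_size) {
      size_t stop = std::min(n, start + (size_t)batch_size);
      std::vector<uword> idx(order.begin() + start, order.begin() + stop);
      Batch mxs = cfg.has_spectral ? subset_batch(bxs, idx) : Batch();
      Batch mxp = cfg.has_spatial ? subset_batch(bxp, idx) : Batch();
      vec my(idx.size());
      for (size_t i = 0; i < idx.size(); ++i) my(i) = yv(idx[i]);

      NetCache nc;
      vec yhat = net_forward(ps, cfg, mxs, mxp, true, &nc);
      vec resid = yhat - my;
      double loss = dot(resid, resid) / resid.n_elem;
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged (non-finite loss) at learning rate " +
                   std::to_string(lr));
      ep_loss += loss;
      ++nb;
      vec dyhat = 2.0 * resid / (double)resid.n_elem;
      ParamStore grads = zero_grads(ps);
      net_backward(ps, grads, cfg, dyhat, nc);
      opt.step(ps, grads);
    }
    loss_hist.push_back(ep_loss / nb);
    bool last_epoch = (ep == epochs - 1);
    if (has_val || last_epoch) {
      // precise batch-norm recalibration: replace the lagging exponential
      // running statistics with exact cumulative averages of the batch
      // statistics under the final weights, so inference matches training
      for (auto& kvp : ps.values) {
        if (!is_buffer(kvp.first)) continue;
        kvp.second.zeros();
      }
      size_t bi = 0;
      for (size_t start = 0; start < n; start += batch_size) {
        size_t stop = std::min(n, start + (size_t)batch_size);
        if (stop - start < 2) break; // a size-1 tail adds no usable stats
        std::vector<uword> idx(order.begin() + start, order.begin() + stop);
        Batch mxs = cfg.has_spectral ? subset_batch(bxs, idx) : Batch();
        Batch mxp = cfg.has_spatial ? subset_batch(bxp, idx) : Batch();
        g_bn_momentum = 1.0 / (double)(bi + 1);
        net_forward(ps, cfg, mxs, mxp, true, nullptr);
        ++bi;
      }
      g_bn_momentum = 0.1;
    }
    if (has_val) {
      vec yh = net_forward(ps, cfg, vxs, vxp, false, nullptr);
      double sst = accu(square(yval - mean(yval)));
      double ssr = accu(square(yval - yh));
      val_hist.push_back(sst > 0 ? 1.0 - ssr / sst : datum::nan);
    }
  }

  List out;
  out["params"] = params_to_list(ps, params_list);
  out["loss"] = loss_hist;
  if (has_val) out["val_r2"] = val_hist;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict(List params_list, List cfg_list, NumericVector xs,
                          NumericVector xp) {
  NetConfig cfg = config_from_list(cfg_list);
  ParamStore ps = params_from_list(params_list);
  Batch bxs, bxp;
  if (cfg.has_spectral) bxs = batch_from_array(xs);
  if (cfg.has_spatial) bxp = batch_from_array(xp);
  vec yhat = net_forward(ps, cfg, bxs, bxp, false, nullptr);
  return NumericVector(yhat.begin(), yhat.end());
}

// Analytic gradients for one batch (testing hook for gradient checks)
// [[Rcpp::export]]
List cpp_gradients(List params_list, List cfg_list, NumericVector xs,
                   NumericVector xp, NumericVector y) {
  NetConfig cfg = config_from_list(cfg_list);
  ParamStore ps = params_from_list(params_list);
  Batch bxs, bxp;
  if (cfg.has_spectral) bxs = batch_from_array(xs);
  if (cfg.has_spatial) bxp = batch_from_array(xp);
  vec yv(y.begin(), y.size());
  NetCache nc;
  vec yhat = net_forward(ps, cfg, bxs, bxp, true, &nc);
  vec resid = yhat - yv;
  double loss = dot(resid, resid) / resid.n_elem;
  vec dyhat = 2.0 * resid / (double)resid.n_elem;
  ParamStore grads = zero_grads(ps);
  net_backward(ps, grads, cfg, dyhat, nc);
  List gl = params_to_list(grads, params_list);
  return List::create(Rcpp::Named("loss") = loss,
                      Rcpp::Named("gradients") = gl);
}

// Training-mode loss without side effects (finite-difference companion of
// cpp_gradients; batch norm uses batch statistics in both)
// [[Rcpp::export]]
double cpp_loss(List params_list, List cfg_list, NumericVector xs,
                NumericVector xp, NumericVector y) {
  NetConfig cfg = config_from_list(cfg_list);
  ParamStore ps = params_from_list(params_list);
  Batch bxs, bxp;
  if (cfg.has_spectral) bxs = batch_from_array(xs);
  if (cfg.has_spatial) bxp = batch_from_array(xp);
  vec yv(y.begin(), y.size());
  vec yhat = net_forward(ps, cfg, bxs, bxp, true, nullptr);
  vec resid = yhat - yv;
  return dot(resid, resid) / resid.n_elem;
}

// Single channel-attention block forward in inference mode (testing hook;
// must agree with the R reference implementation)
// [[Rcpp::export]]
NumericVector cpp_channel_attention(List params_list, NumericVector f,
                                    NumericVector prev, std::string prefix) {
  ParamStore ps = params_from_list(params_list);
  IntegerVector d = f.attr("dim");
  cube fc(f.begin(), d[0], d[1], d[2]);
  Batch b(1, fc);
  std::vector<vec> prev_w;
  if (prev.size() > 0) prev_w.push_back(vec(prev.begin(), prev.size()));
  ChannelAttCache cache;
  channel_att_forward(ps, prefix, b, prev_w, false, &cache);
  return NumericVector(cache.weights[0].begin(), cache.weights[0].end());
}

// [[Rcpp::export]]
NumericVector cpp_spatial_attention(List params_list, NumericVector f,
                                    NumericVector prev, std::string prefix,
                                    int pool_size, int pool_stride) {
  ParamStore ps = params_from_list(params_list);
  IntegerVector d = f.attr("dim");
  cube fc(f.begin(), d[0], d[1], d[2]);
  Batch b(1, fc);
  std::vector<mat> prev_m;
  if (prev.size() > 0) {
    IntegerVector pd = prev.attr("dim");
    prev_m.push_back(mat(prev.begin(), pd[0], pd[1]));
  }
  SpatialAttCache cache;
  spatial_att_forward(ps, prefix, b, prev_m, pool_size, pool_stride, &cache);
  mat m = cache.map[0];
  NumericVector out(m.begin(), m.end());
  out.attr("dim") = IntegerVector::create(m.n_rows, m.n_cols);
  return out;
}
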