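// Minimal CNN engine for 2-D grayscale grain images.
//
// Architecture family (VGG-style blocks, 3x3 kernels, 'same' padding):
//   front  : conv(1->f), conv(f->f), maxpool          [frozen, forward-only]
//   core   : conv(f->f), conv(f->f), maxpool,
//            conv(f->2f), conv(2f->2f), maxpool
//   deep   : + conv(2f->4f), maxpool
//   head   : dropout, flatten, dense(relu), dense(softmax)
//
// Convolutions run as im2col + GEMM with an (HW x 9C) column layout so that
// patch extraction is contiguous memcpy per image column. Training is
// per-image backprop with per-batch Adam updates; the frozen front block
// receives no gradient. All stochastic elements (shuffling, dropout masks)
// are driven by seeds supplied from R, so runs are bit-reproducible.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// 3x3 im2col with zero padding. Input H x W x C, output (H*W) x (9C).
// Row p corresponds to pixel (y = p % H, x = p / H) (column-major order);
// column c*9 + (dx+1)*3 + (dy+1) holds A(y+dy, x+dx, c).
mat im2col3(const cube& A) {
  const int H = A.n_rows, W = A.n_cols, C = A.n_slices;
  mat out(H * W, 9 * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& S = A.slice(c);
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int r = c * 9 + (dx + 1) * 3 + (dy + 1);
        double* dstcol = out.colptr(r);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        for (int x = x0; x < x1; ++x) {
          const double* src = S.colptr(x + dx) + (y0 + dy);
          std::memcpy(dstcol + (size_t)x * H + y0, src,
                      (size_t)(y1 - y0) * sizeof(double));
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter (H*W) x (9C) gradients back onto H x W x C.
cube col2im3(const mat& G, int H, int W, int C) {
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& S = out.slice(c);
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int r = c * 9 + (dx + 1) * 3 + (dy + 1);
        const double* srccol = G.colptr(r);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        for (int x = x0; x < x1; ++x) {
          double* dst = S.colptr(x + dx) + (y0 + dy);
          const double* src = srccol + (size_t)x * H + y0;
          for (int y = 0; y < y1 - y0; ++y) dst[y] += src[y];
        }
      }
    }
  }
  return out;
}

// conv + ReLU. W is Cout x 9Cin. Optionally caches the im2col matrix and
// the pre-activation relu mask for backward.
cube conv_relu(const cube& X, const mat& Wm, const vec& b, mat* cols_out,
               umat* relu_mask) {
  const uword H = X.n_rows, Wd = X.n_cols;
  const uword Cout = Wm.n_rows;
  mat cols = im2col3(X);
  mat Z = cols * Wm.t();        // HW x Cout
  Z.each_row() += b.t();
  if (relu_mask) *relu_mask = Z > 0.0;
  Z = clamp(Z, 0.0, datum::inf);
  cube Y(H, Wd, Cout);
  std::memcpy(Y.memptr(), Z.memptr(), Z.n_elem * sizeof(double));
  if (cols_out) *cols_out = std::move(cols);
  return Y;
}

// 2x2 max pooling, stride 2. Records argmax linear index per output cell.
cube maxpool2(const cube& X, ucube* idx_out) {
  const uword H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  cube Y(H, W, C);
  if (idx_out) idx_out->set_size(H, W, C);
  for (uword c = 0; c < C; ++c) {
    const mat& S = X.slice(c);
    for (uword x = 0; x < W; ++x) {
      for (uword y = 0; y < H; ++y) {
        const uword yy = 2 * y, xx = 2 * x;
        double v = S(yy, xx);
        uword best = yy + xx * X.n_rows;
        if (S(yy + 1, xx) > v) { v = S(yy + 1, xx); best = yy + 1 + xx * X.n_rows; }
        if (S(yy, xx + 1) > v) { v = S(yy, xx + 1); best = yy + (xx + 1) * X.n_rows; }
        if (S(yy + 1, xx + 1) > v) { v = S(yy + 1, xx + 1); best = yy + 1 + (xx + 1) * X.n_rows; }
        Y(y, x, c) = v;
        if (idx_out) (*idx_out)(y, x, c) = best;
      }
    }
  }
  return Y;
}

cube maxpool2_back(const cube& dY, const ucube& idx, uword H, uword W) {
  cube dX(H, W, dY.n_slices, fill::zeros);
  for (uword c = 0; c < dY.n_slices; ++c) {
    mat& S = dX.slice(c);
    for (uword x = 0; x < dY.n_cols; ++x) {
      for (uword y = 0; y < dY.n_rows; ++y) {
        S(idx(y, x, c)) += dY(y, x, c);
      }
    }
  }
  return dX;
}

struct Arch {
  int n_conv;        // total convs incl. frozen front
  int frozen;        // leading frozen convs (2)
  std::vector<bool> pool_after;
  int dense_width;
  int n_classes;
};

Arch read_arch(const Rcpp::List& arch) {
  Arch a;
  a.n_conv = Rcpp::as<int>(arch["n_conv"]);
  a.frozen = Rcpp::as<int>(arch["n_frozen"]);
  Rcpp::LogicalVector pa = arch["pool_after"];
  for (int i = 0; i < pa.size(); ++i) a.pool_after.push_back(pa[i]);
  a.dense_width = Rcpp::as<int>(arch["dense_width"]);
  a.n_classes = Rcpp::as<int>(arch["n_classes"]);
  return a;
}

// weights in plain arma form (avoids repeated R list conversions)
struct Weights {
  std::vector<mat> convW;
  std::vector<vec> convB;
  mat W1, W2;
  vec b1, b2;
};

Weights read_weights(const Rcpp::List& wts) {
  Weights w;
  Rcpp::List convW = wts["convW"], convB = wts["convB"];
  for (int i = 0; i < convW.size(); ++i) {
    w.convW.push_back(Rcpp::as<mat>(convW[i]));
    w.convB.push_back(Rcpp::as<vec>(convB[i]));
  }
  w.W1 = Rcpp::as<mat>(wts["W1"]);
  w.b1 = Rcpp::as<vec>(wts["b1"]);
  w.W2 = Rcpp::as<mat>(wts["W2"]);
  w.b2 = Rcpp::as<vec>(wts["b2"]);
  return w;
}

Rcpp::List wrap_weights(const Weights& w) {
  Rcpp::List convW(w.convW.size()), convB(w.convB.size());
  for (size_t i = 0; i < w.convW.size(); ++i) {
    convW[i] = Rcpp::wrap(w.convW[i]);
    convB[i] = Rcpp::wrap(w.convB[i]);
  }
  return Rcpp::List::create(
      Rcpp::Named("convW") = convW, Rcpp::Named("convB") = convB,
      Rcpp::Named("W1") = Rcpp::wrap(w.W1), Rcpp::Named("b1") = Rcpp::wrap(w.b1),
      Rcpp::Named("W2") = Rcpp::wrap(w.W2), Rcpp::Named("b2") = Rcpp::wrap(w.b2));
}

struct Caches {
  std::vector<mat> cols;         // im2col input of each trained conv
  std::vector<umat> relu;        // relu masks of trained convs
  std::vector<ucube> pool_idx;   // pool argmax, aligned with trained convs
  std::vector<uvec> conv_in_dim; // H,W,C of each trained conv input
  vec flat, flat_dropped, hidden;
  uvec hidden_mask;
};

vec forward_one(const cube& img, const Weights& w, const Arch& a,
                bool training, const vec& drop_mask, double dropout,
                Caches* cc) {
  cube x = img;
  for (int i = 0; i < a.n_conv; ++i) {
    const bool trained = i >= a.frozen;
    if (trained && cc) {
      cc->conv_in_dim.push_back(uvec{x.n_rows, x.n_cols, x.n_slices});
      mat cols;
      umat mask;
      x = conv_relu(x, w.convW[i], w.convB[i], &cols, &mask);
      cc->cols.push_back(std::move(cols));
      cc->relu.push_back(std::move(mask));
    } else {
      x = conv_relu(x, w.convW[i], w.convB[i], nullptr, nullptr);
    }
    if (a.pool_after[i]) {
      if (trained && cc) {
        ucube idx;
        cube y = maxpool2(x, &idx);
        cc->pool_idx.push_back(std::move(idx));
        x = std::move(y);
      } else {
        x = maxpool2(x, nullptr);
      }
    } else if (trained && cc) {
      cc->pool_idx.push_back(ucube());  // placeholder keeps alignment
    }
  }
  vec flat = vectorise(x);
  if (cc) cc->flat = flat;
  if (training && dropout > 0) flat %= drop_mask;
  if (cc) cc->flat_dropped = flat;
  vec h = w.W1 * flat + w.b1;
  uvec hm = h > 0.0;
  h = clamp(h, 0.0, datum::inf);
  vec logits = w.W2 * h + w.b2;
  if (cc) {
    cc->hidden = h;
    cc->hidden_mask = hm;
  }
  return logits;
}

vec softmax_vec(const vec& z) {
  vec e = exp(z - z.max());
  return e / accu(e);
}

struct Grads {
  std::vector<mat> convW;  // trained convs only
  std::vector<vec> convB;
  mat W1, W2;
  vec b1, b2;
};

void grads_init(Grads& g, const Weights& w, const Arch& a) {
  g.convW.clear(); g.convB.clear();
  for (int i = a.frozen; i < a.n_conv; ++i) {
    g.convW.push_back(zeros<mat>(w.convW[i].n_rows, w.convW[i].n_cols));
    g.convB.push_back(zeros<vec>(w.convB[i].n_elem));
  }
  g.W1 = zeros<mat>(w.W1.n_rows, w.W1.n_cols);
  g.b1 = zeros<vec>(w.b1.n_elem);
  g.W2 = zeros<mat>(w.W2.n_rows, w.W2.n_cols);
  g.b2 = zeros<vec>(w.b2.n_elem);
}

// Accumulate one image's gradients; dlogits = softmax(logits) - onehot(y).
void backward_one(const Weights& w, const Arch& a, const Caches& cc,
                  const vec& dlogits, const vec& drop_mask, double dropout,
                  Grads& g) {
  g.W2 += dlogits * cc.hidden.t();
  g.b2 += dlogits;
  vec dh = w.W2.t() * dlogits;
  dh %= conv_to<vec>::from(cc.hidden_mask);
  g.W1 += dh * cc.flat_dropped.t();
  g.b1 += dh;
  vec dflat = w.W1.t() * dh;
  if (dropout > 0) dflat %= drop_mask;

  const int n_tr = a.n_conv - a.frozen;
  cube dx;
  {
    const uword Cout = w.convW[a.n_conv - 1].n_rows;
    const uword hw = cc.flat.n_elem / Cout;
    const uword side = (uword)std::lround(std::sqrt((double)hw));
    dx = cube(dflat.memptr(), side, side, Cout);
  }
  for (int t = n_tr - 1; t >= 0; --t) {
    const int i = a.frozen + t;
    const uvec& ind = cc.conv_in_dim[t];
    const uword Hin = ind[0], Win = ind[1], Cin = ind[2];
    if (a.pool_after[i]) {
      // conv output size = conv input size ('same' padding)
      dx = maxpool2_back(dx, cc.pool_idx[t], Hin, Win);
    }
    const mat& Wm = w.convW[i];
    const uword Cout = Wm.n_rows;
    mat dZ(Hin * Win, Cout);
    std::memcpy(dZ.memptr(), dx.memptr(), dx.n_elem * sizeof(double));
    dZ %= conv_to<mat>::from(cc.relu[t]);
    g.convW[t] += dZ.t() * cc.cols[t];
    g.convB[t] += sum(dZ, 0).t();
    if (t > 0) {
      mat dcols = dZ * Wm;                    // HW x 9Cin
      dx = col2im3(dcols, Hin, Win, Cin);
    }
  }
}

void adam_update(mat& w, mat& m, mat& v, const mat& grad, double lr,
                 double b1, double b2, double eps, int t) {
  m = b1 * m + (1 - b1) * grad;
  v = b2 * v + (1 - b2) * square(grad);
  w -= lr * (m / (1 - std::pow(b1, t))) /
       (sqrt(v / (1 - std::pow(b2, t))) + eps);
}

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_cnn_logits(Rcpp::List weights, const arma::cube& X,
                         Rcpp::List arch) {
  Arch a = read_arch(arch);
  Weights w = read_weights(weights);
  const uword n = X.n_slices;
  mat out(n, a.n_classes);
  vec dummy;
  cube img(X.n_rows, X.n_cols, 1);
  for (uword i = 0; i < n; ++i) {
    img.slice(0) = X.slice(i);
    out.row(i) = forward_one(img, w, a, false, dummy, 0.0, nullptr).t();
  }
  return out;
}

// One epoch of minibatch Adam. y is 0-based; order is a 0-based permutation
// (from R's RNG). Returns updated weights, Adam state and the mean training
// cross-entropy.
// [[Rcpp::export]]
Rcpp::List cpp_cnn_epoch(Rcpp::List weights, Rcpp::List adam,
                         const arma::cube& X, const arma::ivec& y,
                         Rcpp::List arch, const arma::ivec& order,
                         int batch, double lr, double dropout, int seed) {
  Arch a = read_arch(arch);
  Weights w = read_weights(weights);
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // adam state aligned with [convW3,convB3,...,W1,b1,W2,b2]
  Rcpp::List m_in = adam["m"], v_in = adam["v"];
  std::vector<mat> am, av;
  for (int i = 0; i < m_in.size(); ++i) {
    am.push_back(Rcpp::as<mat>(m_in[i]));
    av.push_back(Rcpp::as<mat>(v_in[i]));
  }
  int tstep = Rcpp::as<int>(adam["t"]);
  const double ab1 = 0.9, ab2 = 0.999, eps = 1e-8;
  const uword n = X.n_slices;
  const uword flat_len = w.W1.n_cols;
  const int n_tr = a.n_conv - a.frozen;

  double total_loss = 0.0;
  Grads g;
  cube img(X.n_rows, X.n_cols, 1);
  for (uword start = 0; start < n; start += batch) {
    const uword stop = std::min<uword>(start + batch, n);
    grads_init(g, w, a);
    for (uword k = start; k < stop; ++k) {
      const uword idx = (uword)order[k];
      img.slice(0) = X.slice(idx);
      vec drop_mask;
      if (dropout > 0) {
        drop_mask.set_size(flat_len);
        for (uword j = 0; j < flat_len; ++j) {
          drop_mask[j] = unif(rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
        }
      }
      Caches cc;
      vec logits = forward_one(img, w, a, true, drop_mask, dropout, &cc);
      vec p = softmax_vec(logits);
      const int yi = (int)y[idx];
      total_loss += -std::log(std::max(p[yi], 1e-12));
      vec dlogits = p;
      dlogits[yi] -= 1.0;
      backward_one(w, a, cc, dlogits, drop_mask, dropout, g);
    }
    const double bs = (double)(stop - start);
    ++tstep;
    int s = 0;
    for (int t = 0; t < n_tr; ++t) {
      adam_update(w.convW[a.frozen + t], am[s], av[s], g.convW[t] / bs,
                  lr, ab1, ab2, eps, tstep);
      ++s;
      mat bB = w.convB[a.frozen + t];
      adam_update(bB, am[s], av[s], g.convB[t] / bs, lr, ab1, ab2, eps, tstep);
      w.convB[a.frozen + t] = bB.col(0);
      ++s;
    }
    adam_update(w.W1, am[s], av[s], g.W1 / bs, lr, ab1, ab2, eps, tstep); ++s;
    {
      mat bB = w.b1;
      adam_update(bB, am[s], av[s], g.b1 / bs, lr, ab1, ab2, eps, tstep);
      w.b1 = bB.col(0); ++s;
    }
    adam_update(w.W2, am[s], av[s], g.W2 / bs, lr, ab1, ab2, eps, tstep); ++s;
    {
      mat bB = w.b2;
      adam_update(bB, am[s], av[s], g.b2 / bs, lr, ab1, ab2, eps, tstep);
      w.b2 = bB.col(0); ++s;
    }
  }

  Rcpp::List m_out(am.size()), v_out(av.size());
  for (size_t i = 0; i < am.size(); ++i) {
    m_out[i] = Rcpp::wrap(am[i]);
    v_out[i] = Rcpp::wrap(av[i]);
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = wrap_weights(w),
      Rcpp::Named("adam") = Rcpp::List::create(
          Rcpp::Named("m") = m_out, Rcpp::Named("v") = v_out,
          Rcpp::Named("t") = tstep),
      Rcpp::Named("loss") = total_loss / (double)n);
}
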