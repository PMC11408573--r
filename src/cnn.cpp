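// Small fixed-architecture convolutional network for two-class slice
// classification: conv(3x3)-ReLU-maxpool(2) x2, conv(3x3)-ReLU (last conv),
// global average pooling, dense 2-way head. Forward and analytic backward
// passes; the training loop and optimiser live on the R side.
//
// Weight layout (matching im2col):
//   W_l : (C_out, 9 * C_in) with row-block order channel-major
//         (c_in * 9 + dj * 3 + di), b_l : C_out
//   Wfc : (2, C3), bfc : 2
// Images are H x W (x C) cubes, column-major like R matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int K = 3; // kernel size everywhere

// im2col for valid 3x3 convolution: (9*C) x (Ho*Wo), output pixel (i,j)
// mapped to column j*Ho + i.
static arma::mat im2col3(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H - K + 1, Wo = W - K + 1;
  arma::mat cols(9 * C, Ho * Wo);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < K; ++dj) {
      for (int di = 0; di < K; ++di) {
        const int r = c * 9 + dj * K + di;
        for (int j = 0; j < Wo; ++j) {
          const double* src = &x(di, j + dj, c);
          double* dst = &cols(r, j * Ho);
          for (int i = 0; i < Ho; ++i) dst[i * (9 * C)] = src[i];
        }
      }
    }
  }
  return cols;
}

// scatter-add of column gradients back onto the input cube
static arma::cube col2im3(const arma::mat& dcols, int H, int W, int C) {
  const int Ho = H - K + 1, Wo = W - K + 1;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < K; ++dj) {
      for (int di = 0; di < K; ++di) {
        const int r = c * 9 + dj * K + di;
        for (int j = 0; j < Wo; ++j)
          for (int i = 0; i < Ho; ++i)
            dx(i + di, j + dj, c) += dcols(r, j * Ho + i);
      }
    }
  }
  return dx;
}

static arma::cube conv3_forward(const arma::cube& x, const arma::mat& W,
                                const arma::vec& b, arma::mat& cols_out) {
  const int Ho = x.n_rows - K + 1, Wo = x.n_cols - K + 1;
  cols_out = im2col3(x);
  arma::mat y = W * cols_out;          // Cout x (Ho*Wo)
  y.each_col() += b;
  arma::cube out(Ho, Wo, W.n_rows);
  for (arma::uword c = 0; c < W.n_rows; ++c)
    out.slice(c) = arma::reshape(y.row(c), Ho, Wo);
  return out;
}

// 2x2 max pooling, stride 2, trailing row/col dropped when odd;
// argmax (0..3, dj*2+di) recorded for the backward pass
static arma::cube maxpool2(const arma::cube& x, arma::ucube& arg) {
  const int Ho = x.n_rows / 2, Wo = x.n_cols / 2, C = x.n_slices;
  arma::cube out(Ho, Wo, C);
  arg.set_size(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        unsigned a = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; a = dj * 2 + di; }
          }
        out(i, j, c) = best;
        arg(i, j, c) = a;
      }
  return out;
}

static arma::cube maxpool2_backward(const arma::cube& dout,
                                    const arma::ucube& arg,
                                    int H, int W) {
  const int Ho = dout.n_rows, Wo = dout.n_cols, C = dout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const unsigned a = arg(i, j, c);
        dx(2 * i + (a % 2), 2 * j + (a / 2), c) += dout(i, j, c);
      }
  return dx;
}

struct Params {
  arma::mat W1, W2, W3, Wfc;
  arma::vec b1, b2, b3, bfc;
};

static Params unpack(const List& p) {
  Params q;
  q.W1 = as<arma::mat>(p["W1"]); q.b1 = as<arma::vec>(p["b1"]);
  q.W2 = as<arma::mat>(p["W2"]); q.b2 = as<arma::vec>(p["b2"]);
  q.W3 = as<arma::mat>(p["W3"]); q.b3 = as<arma::vec>(p["b3"]);
  q.Wfc = as<arma::mat>(p["Wfc"]); q.bfc = as<arma::vec>(p["bfc"]);
  return q;
}

struct ForwardState {
  arma::cube a1, p1, a2, p2, a3;   // post-ReLU conv outputs and pooled maps
  arma::mat cols1, cols2, cols3;
  arma::ucube arg1, arg2;
  arma::vec gap, logits, probs;
};

static void forward_one(const arma::cube& x, const Params& q,
                        ForwardState& s) {
  s.a1 = conv3_forward(x, q.W1, q.b1, s.cols1);
  s.a1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  s.p1 = maxpool2(s.a1, s.arg1);
  s.a2 = conv3_forward(s.p1, q.W2, q.b2, s.cols2);
  s.a2.transform([](double v) { return v > 0.0 ? v : 0.0; });
  s.p2 = maxpool2(s.a2, s.arg2);
  s.a3 = conv3_forward(s.p2, q.W3, q.b3, s.cols3);
  s.a3.transform([](double v) { return v > 0.0 ? v : 0.0; });
  const int C3 = s.a3.n_slices;
  s.gap.set_size(C3);
  for (int c = 0; c < C3; ++c) s.gap(c) = arma::accu(s.a3.slice(c)) /
    (s.a3.n_rows * s.a3.n_cols);
  s.logits = q.Wfc * s.gap + q.bfc;
  const double m = s.logits.max();
  arma::vec e = arma::exp(s.logits - m);
  s.probs = e / arma::accu(e);
}

// [[Rcpp::export(name = ".cpp_cnn_forward")]]
arma::mat cpp_cnn_forward(const arma::cube& X, const List& params) {
  const Params q = unpack(params);
  const int N = X.n_slices;
  arma::mat probs(N, 2);
  ForwardState s;
  for (int n = 0; n < N; ++n) {
    arma::cube x(X.n_rows, X.n_cols, 1);
    x.slice(0) = X.slice(n);
    forward_one(x, q, s);
    probs.row(n) = s.probs.t();
  }
  return probs;
}

// last-conv (post-ReLU) activations for one image: Ho3 x Wo3 x C3
// [[Rcpp::export(name = ".cpp_cnn_activations")]]
arma::cube cpp_cnn_activations(const arma::mat& x, const List& params) {
  const Params q = unpack(params);
  arma::cube xin(x.n_rows, x.n_cols, 1);
  xin.slice(0) = x;
  ForwardState s;
  forward_one(xin, q, s);
  return s.a3;
}

// Mean weighted cross-entropy loss and parameter gradients over a batch.
// y is 0/1, w a per-sample weight. Returns summed gradients / batch size.
// [[Rcpp::export(name = ".cpp_cnn_batch_grad")]]
List cpp_cnn_batch_grad(const arma::cube& X, const arma::ivec& y,
                        const arma::vec& w, const List& params) {
  const Params q = unpack(params);
  const int N = X.n_slices;
  arma::mat dW1(arma::size(q.W1), arma::fill::zeros), dW2(arma::size(q.W2), arma::fill::zeros),
            dW3(arma::size(q.W3), arma::fill::zeros), dWfc(arma::size(q.Wfc), arma::fill::zeros);
  arma::vec db1(q.b1.n_elem, arma::fill::zeros), db2(q.b2.n_elem, arma::fill::zeros),
            db3(q.b3.n_elem, arma::fill::zeros), dbfc(q.bfc.n_elem, arma::fill::zeros);
  double loss = 0.0;
  int correct = 0;
  ForwardState s;
  for (int n = 0; n < N; ++n) {
    arma::cube x(X.n_rows, X.n_cols, 1);
    x.slice(0) = X.slice(n);
    forward_one(x, q, s);
    const int yi = y(n);
    loss += -w(n) * std::log(std::max(s.probs(yi), 1e-12));
    if ((s.probs(1) > s.probs(0) ? 1 : 0) == yi) ++correct;

    arma::vec dlogit = s.probs;
    dlogit(yi) -= 1.0;
    dlogit *= w(n);

    dWfc += dlogit * s.gap.t();
    dbfc += dlogit;
    arma::vec dgap = q.Wfc.t() * dlogit;

    const int H3 = s.a3.n_rows, W3 = s.a3.n_cols, C3 = s.a3.n_slices;
    arma::cube da3(H3, W3, C3);
    for (int c = 0; c < C3; ++c)
      da3.slice(c).fill(dgap(c) / (H3 * W3));
    // ReLU gate at conv3
    for (arma::uword i = 0; i < da3.n_elem; ++i)
      if (s.a3(i) <= 0.0) da3(i) = 0.0;

    arma::mat da3m(q.W3.n_rows, H3 * W3);
    for (int c = 0; c < C3; ++c)
      da3m.row(c) = arma::vectorise(da3.slice(c)).t();
    dW3 += da3m * s.cols3.t();
    db3 += arma::sum(da3m, 1);
    arma::cube dp2 = col2im3(q.W3.t() * da3m, s.p2.n_rows, s.p2.n_cols,
                             s.p2.n_slices);

    arma::cube da2 = maxpool2_backward(dp2, s.arg2, s.a2.n_rows, s.a2.n_cols);
    for (arma::uword i = 0; i < da2.n_elem; ++i)
      if (s.a2(i) <= 0.0) da2(i) = 0.0;
    const int H2 = s.a2.n_rows, W2c = s.a2.n_cols, C2 = s.a2.n_slices;
    arma::mat da2m(C2, H2 * W2c);
    for (int c = 0; c < C2; ++c)
      da2m.row(c) = arma::vectorise(da2.slice(c)).t();
    dW2 += da2m * s.cols2.t();
    db2 += arma::sum(da2m, 1);
    arma::cube dp1 = col2im3(q.W2.t() * da2m, s.p1.n_rows, s.p1.n_cols,
                             s.p1.n_slices);

    arma::cube da1 = maxpool2_backward(dp1, s.arg1, s.a1.n_rows, s.a1.n_cols);
    for (arma::uword i = 0; i < da1.n_elem; ++i)
      if (s.a1(i) <= 0.0) da1(i) = 0.0;
    const int H1 = s.a1.n_rows, W1c = s.a1.n_cols, C1 = s.a1.n_slices;
    arma::mat da1m(C1, H1 * W1c);
    for (int c = 0; c < C1; ++c)
      da1m.row(c) = arma::vectorise(da1.slice(c)).t();
    dW1 += da1m * s.cols1.t();
    db1 += arma::sum(da1m, 1);
  }
  const double inv = 1.0 / N;
  return List::create(
    _["loss"] = loss * inv,
    _["correct"] = correct,
    _["grads"] = List::create(
      _["W1"] = dW1 * inv, _["b1"] = db1 * inv,
      _["W2"] = dW2 * inv, _["b2"] = db2 * inv,
      _["W3"] = dW3 * inv, _["b3"] = db3 * inv,
      _["Wfc"] = dWfc * inv, _["bfc"] = dbfc * inv));
}
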