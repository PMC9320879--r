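// Multi-frame convolutional gaze classifier: forward pass and
// backpropagation for a stack of valid 3x3/stride-1 convolution blocks
// (ReLU + 2x2 max-pool after each block) followed by one hidden dense
// layer and a softmax output. Inputs are feature columns holding C
// channels of H x W column-major pixel planes (C = 5 crops x 3 channels).
// All randomness lives on the R side; these routines are deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// A: C x (H*W), pixel index p = r + c*H. Output: (C*9) x (H-2)*(W-2),
// patch column q = i + j*(H-2) for output pixel (i, j).
static mat im2col3(const mat& A, int H, int W) {
  const int C = A.n_rows, H2 = H - 2, W2 = W - 2;
  mat K(C * 9, H2 * W2);
  for (int j = 0; j < W2; ++j) {
    for (int i = 0; i < H2; ++i) {
      const int q = i + j * H2;
      for (int dc = 0; dc < 3; ++dc) {
        for (int dr = 0; dr < 3; ++dr) {
          const int p = (i + dr) + (j + dc) * H;
          const int o = dr + dc * 3;
          for (int c = 0; c < C; ++c) K(c * 9 + o, q) = A(c, p);
        }
      }
    }
  }
  return K;
}

static mat col2im3(const mat& dK, int H, int W) {
  const int C = dK.n_rows / 9, H2 = H - 2, W2 = W - 2;
  mat dA(C, H * W, fill::zeros);
  for (int j = 0; j < W2; ++j) {
    for (int i = 0; i < H2; ++i) {
      const int q = i + j * H2;
      for (int dc = 0; dc < 3; ++dc) {
        for (int dr = 0; dr < 3; ++dr) {
          const int p = (i + dr) + (j + dc) * H;
          const int o = dr + dc * 3;
          for (int c = 0; c < C; ++c) dA(c, p) += dK(c * 9 + o, q);
        }
      }
    }
  }
  return dA;
}

// 2x2/stride-2 max pool over Z (F x H2*W2); odd trailing row/col dropped.
// idx records the argmax pixel index within the H2 x W2 plane.
static mat maxpool2(const mat& Z, int H2, int W2, umat& idx) {
  const int F = Z.n_rows, Hp = H2 / 2, Wp = W2 / 2;
  mat P(F, Hp * Wp);
  idx.set_size(F, Hp * Wp);
  for (int j = 0; j < Wp; ++j) {
    for (int i = 0; i < Hp; ++i) {
      const int q = i + j * Hp;
      const int p00 = 2 * i + 2 * j * H2;
      const int cand[4] = {p00, p00 + 1, p00 + H2, p00 + H2 + 1};
      for (int f = 0; f < F; ++f) {
        double best = Z(f, cand[0]);
        int bi = cand[0];
        for (int k = 1; k < 4; ++k) {
          if (Z(f, cand[k]) > best) { best = Z(f, cand[k]); bi = cand[k]; }
        }
        P(f, q) = best;
        idx(f, q) = bi;
      }
    }
  }
  return P;
}

struct NetShape {
  int H, W, C, n_blocks;
};

static NetShape read_shape(const Rcpp::List& cfg) {
  NetShape s;
  s.H = Rcpp::as<int>(cfg["input_size"]);
  s.W = s.H;
  s.C = Rcpp::as<int>(cfg["in_channels"]);
  s.n_blocks = Rcpp::as<int>(cfg["n_blocks"]);
  return s;
}

// Forward one sample through the conv stack. Caches (when train) the
// pre-pool activations, pool indices and im2col matrices per block.
static mat conv_stack_forward(const std::vector<mat>& Wc,
                              const std::vector<vec>& bc,
                              const vec& x0, const NetShape& s,
                              bool train,
                              std::vector<mat>* Ks, std::vector<mat>* Zs,
                              std::vector<umat>* idxs,
                              std::vector<std::pair<int, int>>* dims) {
  mat A(x0);
  A.reshape(s.H * s.W, s.C);
  A = A.t();  // C x (H*W)
  int H = s.H, W = s.W;
  for (int b = 0; b < s.n_blocks; ++b) {
    if (dims) dims->push_back({H, W});
    mat K = im2col3(A, H, W);
    mat Z = Wc[b] * K;
    Z.each_col() += bc[b];
    Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    umat idx;
    const int H2 = H - 2, W2 = W - 2;
    mat P = maxpool2(Z, H2, W2, idx);
    if (train) {
      Ks->push_back(std::move(K));
      Zs->push_back(std::move(Z));
      idxs->push_back(std::move(idx));
    }
    A = std::move(P);
    H = H2 / 2;
    W = W2 / 2;
  }
  return A;  // F_last x (H*W)
}

static void softmax_col(vec& z) {
  z -= z.max();
  z = exp(z);
  z /= accu(z);
}

// [[Rcpp::export(name = "cnn_forward_cpp")]]
arma::mat cnn_forward_cpp(const Rcpp::List& params, const arma::mat& X,
                          const Rcpp::List& cfg) {
  NetShape s = read_shape(cfg);
  std::vector<mat> Wc;
  std::vector<vec> bc;
  Rcpp::List cW = params["conv_W"], cb = params["conv_b"];
  for (int b = 0; b < s.n_blocks; ++b) {
    Wc.push_back(Rcpp::as<mat>(cW[b]));
    bc.push_back(Rcpp::as<vec>(cb[b]));
  }
  mat Wd = Rcpp::as<mat>(params["dense_W"]);
  vec bd = Rcpp::as<vec>(params["dense_b"]);
  mat Wo = Rcpp::as<mat>(params["out_W"]);
  vec bo = Rcpp::as<vec>(params["out_b"]);
  const int n = X.n_cols, K = Wo.n_rows;
  mat probs(K, n);
  for (int i = 0; i < n; ++i) {
    mat A = conv_stack_forward(Wc, bc, X.col(i), s, false,
                               nullptr, nullptr, nullptr, nullptr);
    vec flat = vectorise(A);
    vec h = Wd * flat + bd;
    h.transform([](double v) { return v > 0.0 ? v : 0.0; });
    vec z = Wo * h + bo;
    softmax_col(z);
    probs.col(i) = z;
  }
  return probs;
}

// Weighted categorical cross-entropy loss and full gradient for a batch.
// y is 0-based class per column of X; loss = mean_i w[y_i] * -log p_i[y_i].
// [[Rcpp::export(name = "cnn_loss_grad_cpp")]]
Rcpp::List cnn_loss_grad_cpp(const Rcpp::List& params, const arma::mat& X,
                             const arma::ivec& y,
                             const arma::vec& class_weights,
                             const Rcpp::List& cfg) {
  NetShape s = read_shape(cfg);
  std::vector<mat> Wc;
  std::vector<vec> bc;
  Rcpp::List cW = params["conv_W"], cb = params["conv_b"];
  for (int b = 0; b < s.n_blocks; ++b) {
    Wc.push_back(Rcpp::as<mat>(cW[b]));
    bc.push_back(Rcpp::as<vec>(cb[b]));
  }
  mat Wd = Rcpp::as<mat>(params["dense_W"]);
  vec bd = Rcpp::as<vec>(params["dense_b"]);
  mat Wo = Rcpp::as<mat>(params["out_W"]);
  vec bo = Rcpp::as<vec>(params["out_b"]);
  const int n = X.n_cols, K = Wo.n_rows;
  const double eps = 1e-12, inv_n = 1.0 / n;

  std::vector<mat> gWc(s.n_blocks);
  std::vector<vec> gbc(s.n_blocks);
  for (int b = 0; b < s.n_blocks; ++b) {
    gWc[b] = mat(Wc[b].n_rows, Wc[b].n_cols, fill::zeros);
    gbc[b] = vec(bc[b].n_elem, fill::zeros);
  }
  mat gWd(Wd.n_rows, Wd.n_cols, fill::zeros);
  vec gbd(bd.n_elem, fill::zeros);
  mat gWo(Wo.n_rows, Wo.n_cols, fill::zeros);
  vec gbo(bo.n_elem, fill::zeros);
  double loss = 0.0;
  mat probs(K, n);

  for (int i = 0; i < n; ++i) {
    std::vector<mat> Ks, Zs;
    std::vector<umat> idxs;
    std::vector<std::pair<int, int>> dims;
    mat A = conv_stack_forward(Wc, bc, X.col(i), s, true,
                               &Ks, &Zs, &idxs, &dims);
    const int Fl = A.n_rows, Pl = A.n_cols;
    vec flat = vectorise(A);
    vec hpre = Wd * flat + bd;
    vec h = hpre;
    h.transform([](double v) { return v > 0.0 ? v : 0.0; });
    vec z = Wo * h + bo;
    softmax_col(z);
    probs.col(i) = z;
    const int yi = y(i);
    const double w = class_weights(yi);
    loss += -w * std::log(std::max(z(yi), eps)) * inv_n;

    vec dz = z;
    dz(yi) -= 1.0;
    dz *= w * inv_n;
    gWo += dz * h.t();
    gbo += dz;
    vec dh = Wo.t() * dz;
    for (uword u = 0; u < dh.n_elem; ++u) if (hpre(u) <= 0.0) dh(u) = 0.0;
    gWd += dh * flat.t();
    gbd += dh;
    vec dflat = Wd.t() * dh;
    mat dA(dflat.memptr(), Fl, Pl);  // copies

    for (int b = s.n_blocks - 1; b >= 0; --b) {
      const int H = dims[b].first, W2 = dims[b].second - 2,
                H2 = dims[b].first - 2;
      // un-pool: scatter into pre-pool activation grad
      mat dZ(Zs[b].n_rows, Zs[b].n_cols, fill::zeros);
      const umat& idx = idxs[b];
      for (uword q = 0; q < dA.n_cols; ++q) {
        for (uword f = 0; f < dA.n_rows; ++f) {
          dZ(f, idx(f, q)) += dA(f, q);
        }
      }
      // ReLU gate (Zs holds post-ReLU values; zero means gradient blocked)
      for (uword e = 0; e < dZ.n_elem; ++e) {
        if (Zs[b](e) <= 0.0) dZ(e) = 0.0;
      }
      gWc[b] += dZ * Ks[b].t();
      gbc[b] += sum(dZ, 1);
      if (b > 0) {
        mat dK = Wc[b].t() * dZ;
        mat prev = col2im3(dK, H, dims[b].second);
        (void)H2; (void)W2;
        dA = std::move(prev);
      }
    }
  }

  Rcpp::List gcW(s.n_blocks), gcb(s.n_blocks);
  for (int b = 0; b < s.n_blocks; ++b) {
    gcW[b] = gWc[b];
    gcb[b] = gbc[b];
  }
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("probs") = probs,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("conv_W") = gcW, Rcpp::Named("conv_b") = gcb,
          Rcpp::Named("dense_W") = gWd, Rcpp::Named("dense_b") = gbd,
          Rcpp::Named("out_W") = gWo, Rcpp::Named("out_b") = gbo));
}
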