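// Compact U-Net-style encoder-decoder with manual backpropagation.
// Feature maps are (C x H*W) matrices, pixel index p = r + c*H (column-major,
// matching R). Two 2x encoder levels, a bottleneck, skip connections by
// channel concatenation, nearest-neighbor upsampling, per-channel sigmoid
// outputs trained with weighted binary cross-entropy. H and W must be
// divisible by 4.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct ConvSpec { int cin, cout, k; };

static std::vector<ConvSpec> layer_specs(int nb, int K) {
  return {
    {3,      nb,     3},  // enc1
    {nb,     2 * nb, 3},  // enc2
    {2 * nb, 4 * nb, 3},  // bottleneck
    {6 * nb, 2 * nb, 3},  // dec2 (4nb up + 2nb skip)
    {3 * nb, nb,     3},  // dec1 (2nb up + nb skip)
    {nb,     K,      1}   // 1x1 head
  };
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_unet_layout(int nb, int K) {
  auto specs = layer_specs(nb, K);
  Rcpp::IntegerMatrix m(specs.size(), 3);
  for (size_t i = 0; i < specs.size(); ++i) {
    m(i, 0) = specs[i].cin; m(i, 1) = specs[i].cout; m(i, 2) = specs[i].k;
  }
  return m;
}

struct Layer { mat W; vec b; };

static std::vector<Layer> unpack(const vec& params, int nb, int K) {
  auto specs = layer_specs(nb, K);
  std::vector<Layer> layers;
  size_t off = 0;
  for (auto& s : specs) {
    int wn = s.cout * s.cin * s.k * s.k;
    Layer L;
    L.W = reshape(params.subvec(off, off + wn - 1), s.cin * s.k * s.k, s.cout).t();
    off += wn;
    L.b = params.subvec(off, off + s.cout - 1);
    off += s.cout;
    layers.push_back(std::move(L));
  }
  return layers;
}

static vec pack_grads(const std::vector<mat>& dW, const std::vector<vec>& db) {
  size_t n = 0;
  for (size_t i = 0; i < dW.size(); ++i) n += dW[i].n_elem + db[i].n_elem;
  vec out(n);
  size_t off = 0;
  for (size_t i = 0; i < dW.size(); ++i) {
    vec w = vectorise(dW[i].t());
    out.subvec(off, off + w.n_elem - 1) = w; off += w.n_elem;
    out.subvec(off, off + db[i].n_elem - 1) = db[i]; off += db[i].n_elem;
  }
  return out;
}

// 3x3 same-padding im2col: (C*9 x N)
static mat im2col3(const mat& F, int H, int W) {
  int C = F.n_rows;
  mat X(C * 9, H * W, fill::zeros);
  int idx = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++idx) {
      for (int c = 0; c < W; ++c) {
        int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        if (r1 <= r0) continue;
        X.submat(idx * C, c * H + r0, idx * C + C - 1, c * H + r1 - 1) =
          F.submat(0, cc * H + r0 + dr, C - 1, cc * H + r1 - 1 + dr);
      }
    }
  }
  return X;
}

static mat col2im3(const mat& dX, int C, int H, int W) {
  mat dF(C, H * W, fill::zeros);
  int idx = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++idx) {
      for (int c = 0; c < W; ++c) {
        int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        if (r1 <= r0) continue;
        dF.submat(0, cc * H + r0 + dr, C - 1, cc * H + r1 - 1 + dr) +=
          dX.submat(idx * C, c * H + r0, idx * C + C - 1, c * H + r1 - 1);
      }
    }
  }
  return dF;
}

static mat maxpool2(const mat& F, int H, int W, umat& argmax) {
  int C = F.n_rows, H2 = H / 2, W2 = W / 2;
  mat O(C, H2 * W2);
  argmax.set_size(C, H2 * W2);
  for (int c2 = 0; c2 < W2; ++c2) {
    for (int r2 = 0; r2 < H2; ++r2) {
      int p2 = r2 + c2 * H2;
      int cand[4] = {2 * r2 + 2 * c2 * H, 2 * r2 + 1 + 2 * c2 * H,
                     2 * r2 + (2 * c2 + 1) * H, 2 * r2 + 1 + (2 * c2 + 1) * H};
      for (int ch = 0; ch < C; ++ch) {
        double best = F(ch, cand[0]); int bi = cand[0];
        for (int t = 1; t < 4; ++t)
          if (F(ch, cand[t]) > best) { best = F(ch, cand[t]); bi = cand[t]; }
        O(ch, p2) = best; argmax(ch, p2) = bi;
      }
    }
  }
  return O;
}

static mat maxpool2_back(const mat& dO, const umat& argmax, int N) {
  mat dF(dO.n_rows, N, fill::zeros);
  for (uword p = 0; p < dO.n_cols; ++p)
    for (uword ch = 0; ch < dO.n_rows; ++ch)
      dF(ch, argmax(ch, p)) += dO(ch, p);
  return dF;
}

static mat upsample2(const mat& F, int H2, int W2) {
  int C = F.n_rows, H = H2 * 2, W = W2 * 2;
  mat O(C, H * W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      O.col(r + c * H) = F.col(r / 2 + (c / 2) * H2);
  return O;
}

static mat upsample2_back(const mat& dO, int H2, int W2) {
  int C = dO.n_rows, H = H2 * 2;
  mat dF(C, H2 * W2, fill::zeros);
  for (int c = 0; c < 2 * W2; ++c)
    for (int r = 0; r < H; ++r)
      dF.col(r / 2 + (c / 2) * H2) += dO.col(r + c * H);
  return dF;
}


// in-place ReLU backward: zero gradient entries where the pre-activation
// was non-positive (cheaper than materializing a 0/1 mask matrix)
static void relu_back(mat& dZ, const mat& Z) {
  double* d = dZ.memptr();
  const double* z = Z.memptr();
  const uword n = dZ.n_elem;
  for (uword i = 0; i < n; ++i) if (z[i] <= 0.0) d[i] = 0.0;
}

struct ForwardCache {
  mat X1, X2, X3, X4, X5, A5;  // im2col inputs / head input
  mat Z1, Z2, Z3, Z4, Z5, Z6;  // pre-activations
  mat A1, A2;                  // skip activations
  umat arg1, arg2;
  int H, W;
};

static mat cube_to_feat(const cube& img) {
  int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  mat F(C, H * W);
  for (int c = 0; c < C; ++c) {
    mat sl = img.slice(c);
    F.row(c) = vectorise(sl).t();
  }
  return F;
}

static mat forward(const std::vector<Layer>& L, const cube& img,
                   ForwardCache* cache) {
  int H = img.n_rows, W = img.n_cols;
  int H2 = H / 2, W2 = W / 2, H4 = H / 4, W4 = W / 4;
  mat F0 = cube_to_feat(img);
  mat X1 = im2col3(F0, H, W);
  mat Z1 = L[0].W * X1; Z1.each_col() += L[0].b;
  mat A1 = clamp(Z1, 0.0, datum::inf);
  umat arg1; mat P1 = maxpool2(A1, H, W, arg1);
  mat X2 = im2col3(P1, H2, W2);
  mat Z2 = L[1].W * X2; Z2.each_col() += L[1].b;
  mat A2 = clamp(Z2, 0.0, datum::inf);
  umat arg2; mat P2 = maxpool2(A2, H2, W2, arg2);
  mat X3 = im2col3(P2, H4, W4);
  mat Z3 = L[2].W * X3; Z3.each_col() += L[2].b;
  mat A3 = clamp(Z3, 0.0, datum::inf);
  mat C2 = join_cols(upsample2(A3, H4, W4), A2);
  mat X4 = im2col3(C2, H2, W2);
  mat Z4 = L[3].W * X4; Z4.each_col() += L[3].b;
  mat A4 = clamp(Z4, 0.0, datum::inf);
  mat C1 = join_cols(upsample2(A4, H2, W2), A1);
  mat X5 = im2col3(C1, H, W);
  mat Z5 = L[4].W * X5; Z5.each_col() += L[4].b;
  mat A5 = clamp(Z5, 0.0, datum::inf);
  mat Z6 = L[5].W * A5; Z6.each_col() += L[5].b;
  if (cache) {
    cache->X1 = std::move(X1); cache->X2 = std::move(X2);
    cache->X3 = std::move(X3); cache->X4 = std::move(X4);
    cache->X5 = std::move(X5); cache->A5 = std::move(A5);
    cache->Z1 = std::move(Z1); cache->Z2 = std::move(Z2);
    cache->Z3 = std::move(Z3); cache->Z4 = std::move(Z4);
    cache->Z5 = std::move(Z5); cache->Z6 = Z6;
    cache->A1 = std::move(A1); cache->A2 = std::move(A2);
    cache->arg1 = std::move(arg1); cache->arg2 = std::move(arg2);
    cache->H = H; cache->W = W;
  }
  return Z6;
}

// [[Rcpp::export]]
arma::cube cpp_unet_forward(const arma::vec& params, const arma::cube& img,
                            int nb, int K) {
  if (img.n_rows % 4 || img.n_cols % 4)
    Rcpp::stop("image height and width must be divisible by 4");
  auto L = unpack(params, nb, K);
  mat Z6 = forward(L, img, nullptr);
  mat S = 1.0 / (1.0 + exp(-Z6));
  cube out(img.n_rows, img.n_cols, K);
  for (int k = 0; k < K; ++k)
    out.slice(k) = reshape(S.row(k).t(), img.n_rows, img.n_cols);
  return out;
}

// Weighted per-channel binary cross-entropy + full gradient.
// target: H x W x K one-hot planes; weight: H x W (0 on ignore pixels).
// [[Rcpp::export]]
Rcpp::List cpp_unet_loss_grad(const arma::vec& params, const arma::cube& img,
                              const arma::cube& target,
                              const arma::mat& weight, int nb, int K) {
  if (img.n_rows % 4 || img.n_cols % 4)
    Rcpp::stop("image height and width must be divisible by 4");
  auto L = unpack(params, nb, K);
  ForwardCache cc;
  mat Z6 = forward(L, img, &cc);
  int H = cc.H, W = cc.W, N = H * W;
  int H2 = H / 2, W2 = W / 2, H4 = H / 4, W4 = W / 4;
  int nb2 = 2 * nb, nb4 = 4 * nb;

  mat T(K, N);
  for (int k = 0; k < K; ++k) T.row(k) = vectorise(target.slice(k)).t();
  rowvec w = vectorise(weight).t();
  double denom = accu(w) * K;
  if (denom <= 0) denom = 1.0;

  // numerically stable BCE-with-logits
  mat S = 1.0 / (1.0 + exp(-Z6));
  mat l = clamp(Z6, 0.0, datum::inf) - Z6 % T + log1p(exp(-abs(Z6)));
  l.each_row() %= w;
  double loss = accu(l) / denom;

  mat dZ6 = (S - T) / denom;
  dZ6.each_row() %= w;

  std::vector<mat> dW(6); std::vector<vec> db(6);
  dW[5] = dZ6 * cc.A5.t(); db[5] = sum(dZ6, 1);
  mat dA5 = L[5].W.t() * dZ6;
  mat dZ5 = dA5; relu_back(dZ5, cc.Z5);
  dW[4] = dZ5 * cc.X5.t(); db[4] = sum(dZ5, 1);
  mat dC1 = col2im3(L[4].W.t() * dZ5, 3 * nb, H, W);
  mat dU1 = dC1.rows(0, nb2 - 1);
  mat dA1 = dC1.rows(nb2, 3 * nb - 1);
  mat dA4 = upsample2_back(dU1, H2, W2);
  mat dZ4 = dA4; relu_back(dZ4, cc.Z4);
  dW[3] = dZ4 * cc.X4.t(); db[3] = sum(dZ4, 1);
  mat dC2 = col2im3(L[3].W.t() * dZ4, 6 * nb, H2, W2);
  mat dU2 = dC2.rows(0, nb4 - 1);
  mat dA2 = dC2.rows(nb4, 6 * nb - 1);
  mat dA3 = upsample2_back(dU2, H4, W4);
  mat dZ3 = dA3; relu_back(dZ3, cc.Z3);
  dW[2] = dZ3 * cc.X3.t(); db[2] = sum(dZ3, 1);
  mat dP2 = col2im3(L[2].W.t() * dZ3, nb2, H4, W4);
  dA2 += maxpool2_back(dP2, cc.arg2, H2 * W2);
  mat dZ2 = dA2; relu_back(dZ2, cc.Z2);
  dW[1] = dZ2 * cc.X2.t(); db[1] = sum(dZ2, 1);
  mat dP1 = col2im3(L[1].W.t() * dZ2, nb, H2, W2);
  dA1 += maxpool2_back(dP1, cc.arg1, H * W);
  mat dZ1 = dA1; relu_back(dZ1, cc.Z1);
  dW[0] = dZ1 * cc.X1.t(); db[0] = sum(dZ1, 1);

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = pack_grads(dW, db));
}
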