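// Minimal convolutional network used as the trainable "black box" classifier.
//
// Architecture (fixed topology, configurable widths):
//   repeat L times: conv 3x3 (pad 1, stride 1) -> ReLU -> max-pool 2x2
//   global average pool -> penultimate feature vector -> single logit -> sigmoid
//
// Feature maps are stored as (channels x spatial) matrices with spatial index
// s = x*H + y, i.e. the column-major flattening of an HxW grid, matching R's
// array layout. Convolutions are im2col + GEMM; gradients are exact (checked
// against finite differences in the test suite).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// X: (C x H*W) -> (9C x H*W), 3x3 neighbourhood with zero padding.
arma::mat im2col3(const arma::mat& X, const int H, const int W) {
  const int C = X.n_rows;
  arma::mat out(9 * C, H * W, arma::fill::zeros);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const int s = x * H + y;
      for (int dx = -1; dx <= 1; ++dx) {
        const int xx = x + dx;
        if (xx < 0 || xx >= W) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= H) continue;
          const int k = (dx + 1) * 3 + (dy + 1);
          out.submat(k * C, s, k * C + C - 1, s) = X.col(xx * H + yy);
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add column blocks back onto the input grid.
arma::mat col2im3(const arma::mat& dcols, const int H, const int W, const int C) {
  arma::mat dX(C, H * W, arma::fill::zeros);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const int s = x * H + y;
      for (int dx = -1; dx <= 1; ++dx) {
        const int xx = x + dx;
        if (xx < 0 || xx >= W) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= H) continue;
          const int k = (dx + 1) * 3 + (dy + 1);
          dX.col(xx * H + yy) += dcols.submat(k * C, s, k * C + C - 1, s);
        }
      }
    }
  }
  return dX;
}

// 2x2 max pool; records the winning input spatial index per (channel, output).
void maxpool2(const arma::mat& A, const int H, const int W,
              arma::mat& out, arma::umat& argmax) {
  const int C = A.n_rows, H2 = H / 2, W2 = W / 2;
  out.set_size(C, H2 * W2);
  argmax.set_size(C, H2 * W2);
  for (int x2 = 0; x2 < W2; ++x2) {
    for (int y2 = 0; y2 < H2; ++y2) {
      const int s2 = x2 * H2 + y2;
      const int cand[4] = {
        (2 * x2) * H + 2 * y2,     (2 * x2) * H + 2 * y2 + 1,
        (2 * x2 + 1) * H + 2 * y2, (2 * x2 + 1) * H + 2 * y2 + 1};
      for (int c = 0; c < C; ++c) {
        double best = A(c, cand[0]);
        int besti = cand[0];
        for (int q = 1; q < 4; ++q) {
          if (A(c, cand[q]) > best) { best = A(c, cand[q]); besti = cand[q]; }
        }
        out(c, s2) = best;
        argmax(c, s2) = besti;
      }
    }
  }
}

struct Cache {
  std::vector<arma::mat> cols;   // im2col inputs per layer
  std::vector<arma::mat> Z;      // pre-ReLU conv outputs
  std::vector<arma::mat> P;      // post-pool activations
  std::vector<arma::umat> amax;  // pool argmax
  std::vector<int> Hs, Ws;       // spatial dims entering each layer
  arma::vec feat;                // global-average-pooled features
  double logit = 0.0, prob = 0.0;
};

void forward_one(const std::vector<arma::mat>& Wc,
                 const std::vector<arma::vec>& bc,
                 const arma::vec& wd, const double bd,
                 const arma::mat& X0, int H, int W,
                 Cache* cache, arma::vec* feat_out, double* prob_out) {
  const int L = static_cast<int>(Wc.size());
  arma::mat A = X0;
  for (int l = 0; l < L; ++l) {
    if (cache) { cache->Hs.push_back(H); cache->Ws.push_back(W); }
    arma::mat cols = im2col3(A, H, W);
    arma::mat Z = Wc[l] * cols;
    Z.each_col() += bc[l];
    arma::mat R = Z;
    R.elem(arma::find(R < 0.0)).zeros();
    arma::mat Pm;
    arma::umat am;
    maxpool2(R, H, W, Pm, am);
    if (cache) {
      cache->cols.push_back(std::move(cols));
      cache->Z.push_back(std::move(Z));
      cache->P.push_back(Pm);
      cache->amax.push_back(std::move(am));
    }
    A = std::move(Pm);
    H /= 2;
    W /= 2;
  }
  arma::vec f = arma::mean(A, 1);
  const double logit = arma::dot(wd, f) + bd;
  const double prob = 1.0 / (1.0 + std::exp(-logit));
  if (cache) { cache->feat = f; cache->logit = logit; cache->prob = prob; }
  if (feat_out) *feat_out = f;
  if (prob_out) *prob_out = prob;
}

void unpack_params(const List& conv_w, const List& conv_b,
                   std::vector<arma::mat>& Wc, std::vector<arma::vec>& bc) {
  const int L = conv_w.size();
  Wc.resize(L);
  bc.resize(L);
  for (int l = 0; l < L; ++l) {
    Wc[l] = as<arma::mat>(conv_w[l]);
    bc[l] = as<arma::vec>(conv_b[l]);
  }
}

arma::mat image_slice(const NumericVector& X, const int H, const int W,
                      const int C, const int i) {
  // R array (H, W, C, n): channel c of image i occupies a contiguous H*W block.
  arma::mat Xi(C, H * W);
  const int S = H * W;
  const double* base = X.begin() + static_cast<R_xlen_t>(i) * C * S;
  for (int c = 0; c < C; ++c) {
    Xi.row(c) = arma::rowvec(const_cast<double*>(base + c * S), S);
  }
  return Xi;
}

}  // namespace

// [[Rcpp::export]]
List cnn_forward_cpp(List conv_w, List conv_b, arma::vec dense_w, double dense_b,
                     NumericVector X, int H, int W, int C, int n,
                     bool want_features) {
  std::vector<arma::mat> Wc;
  std::vector<arma::vec> bc;
  unpack_params(conv_w, conv_b, Wc, bc);
  NumericVector probs(n);
  arma::mat feats;
  if (want_features) feats.set_size(n, dense_w.n_elem);
  for (int i = 0; i < n; ++i) {
    arma::mat Xi = image_slice(X, H, W, C, i);
    arma::vec f;
    double p;
    forward_one(Wc, bc, dense_w, dense_b, Xi, H, W, nullptr, &f, &p);
    probs[i] = p;
    if (want_features) feats.row(i) = f.t();
  }
  if (want_features) {
    return List::create(_["prob"] = probs, _["features"] = feats);
  }
  return List::create(_["prob"] = probs);
}

// [[Rcpp::export]]
List cnn_grad_cpp(List conv_w, List conv_b, arma::vec dense_w, double dense_b,
                  NumericVector X, int H, int W, int C, int n, arma::vec y) {
  std::vector<arma::mat> Wc;
  std::vector<arma::vec> bc;
  unpack_params(conv_w, conv_b, Wc, bc);
  const int L = static_cast<int>(Wc.size());

  std::vector<arma::mat> gW(L);
  std::vector<arma::vec> gb(L);
  for (int l = 0; l < L; ++l) {
    gW[l].zeros(Wc[l].n_rows, Wc[l].n_cols);
    gb[l].zeros(bc[l].n_elem);
  }
  arma::vec gwd(dense_w.n_elem, arma::fill::zeros);
  double gbd = 0.0;
  double loss = 0.0;
  NumericVector probs(n);

  for (int i = 0; i < n; ++i) {
    arma::mat Xi = image_slice(X, H, W, C, i);
    Cache cache;
    forward_one(Wc, bc, dense_w, dense_b, Xi, H, W, &cache, nullptr, nullptr);
    const double p = std::min(std::max(cache.prob, 1e-12), 1.0 - 1e-12);
    probs[i] = cache.prob;
    loss += -(y[i] * std::log(p) + (1.0 - y[i]) * std::log(1.0 - p)) / n;

    // sigmoid + binary cross-entropy: dL/dlogit = (p - y) / n
    const double dlogit = (cache.prob - y[i]) / n;
    gwd += dlogit * cache.feat;
    gbd += dlogit;

    // back through global average pool
    const int Hl = cache.Hs[L - 1] / 2, Wl = cache.Ws[L - 1] / 2;
    arma::mat dA(dense_w.n_elem, Hl * Wl);
    dA.each_col() = (dlogit / (Hl * Wl)) * dense_w;

    for (int l = L - 1; l >= 0; --l) {
      const int Hi = cache.Hs[l], Wi = cache.Ws[l];
      // pool backward: route gradient to argmax positions
      arma::mat dR(Wc[l].n_rows, Hi * Wi, arma::fill::zeros);
      const arma::umat& am = cache.amax[l];
      for (arma::uword s2 = 0; s2 < am.n_cols; ++s2) {
        for (arma::uword c = 0; c < am.n_rows; ++c) {
          dR(c, am(c, s2)) += dA(c, s2);
        }
      }
      // ReLU backward
      arma::mat dZ = dR % arma::conv_to<arma::mat>::from(cache.Z[l] > 0.0);
      gW[l] += dZ * cache.cols[l].t();
      gb[l] += arma::sum(dZ, 1);
      if (l > 0) {
        arma::mat dcols = Wc[l].t() * dZ;
        dA = col2im3(dcols, Hi, Wi, Wc[l - 1].n_rows);
      }
    }
  }

  List gWl(L), gbl(L);
  for (int l = 0; l < L; ++l) {
    gWl[l] = gW[l];
    gbl[l] = gb[l];
  }
  return List::create(_["loss"] = loss, _["prob"] = probs,
                      _["conv_w"] = gWl, _["conv_b"] = gbl,
                      _["dense_w"] = gwd, _["dense_b"] = gbd);
}
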