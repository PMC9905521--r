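// Minibatch forward/backward kernels for the two benchmark classifiers:
// a small LSTM (recurrent layer -> dropout -> 2-unit dense) and 1-D CNN
// (conv -> ReLU -> batch norm -> dropout blocks -> flatten -> dense).
// Training loop and Adam updates live in R; these kernels return the loss,
// batch accuracy and parameter gradients for one minibatch. Dropout masks
// are drawn from the R RNG stream so training is reproducible under
// set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double PROB_EPS = 1e-7;

// ---------------------------------------------------------------------
// output layer: dense(2) with sigmoid (probabilities normalized for the
// cross-entropy, as TensorFlow's categorical cross-entropy does for
// non-logit inputs) or softmax.
// P: n x d features, Wd: d x 2, bd: 2, Y: n x 2 one-hot.
// Returns loss (mean over batch) and fills probs, dP, gWd, gbd.
// ---------------------------------------------------------------------
static arma::mat output_probs(const arma::mat& P, const arma::mat& Wd,
                              const arma::rowvec& bd, bool softmax) {
  arma::mat z = P * Wd;
  z.each_row() += bd;
  if (softmax) {
    arma::vec zmax = arma::max(z, 1);
    z.each_col() -= zmax;
    arma::mat e = arma::exp(z);
    arma::vec s = arma::sum(e, 1);
    e.each_col() /= s;
    return e;
  }
  return 1.0 / (1.0 + arma::exp(-z));
}

static double output_backward(const arma::mat& P, const arma::mat& Wd,
                              const arma::rowvec& bd, const arma::mat& Y,
                              bool softmax, double& acc, arma::mat& dP,
                              arma::mat& gWd, arma::rowvec& gbd) {
  const double n = (double)P.n_rows;
  arma::mat p = output_probs(P, Wd, bd, softmax);
  arma::mat dz(p.n_rows, p.n_cols);
  double loss = 0.0;
  arma::uword nc = 0;
  for (arma::uword i = 0; i < p.n_rows; ++i) {
    if ((p(i, 1) > p(i, 0)) == (Y(i, 1) > Y(i, 0))) ++nc;
    if (softmax) {
      for (arma::uword j = 0; j < 2; ++j) {
        double pc = std::min(std::max(p(i, j), PROB_EPS), 1.0 - PROB_EPS);
        loss -= Y(i, j) * std::log(pc);
        dz(i, j) = (p(i, j) - Y(i, j)) / n;
      }
    } else {
      // clip the raw sigmoid scores before normalizing so that fully
      // saturated outputs (both scores underflowing to 0) stay finite
      double p0 = std::min(std::max(p(i, 0), PROB_EPS), 1.0 - PROB_EPS);
      double p1 = std::min(std::max(p(i, 1), PROB_EPS), 1.0 - PROB_EPS);
      double s = p0 + p1;
      for (arma::uword j = 0; j < 2; ++j) {
        double pc = (j == 0) ? p0 : p1;
        loss -= Y(i, j) * std::log(pc / s);
        // d/dyhat of -sum y log(yhat/S), then through the sigmoid
        double dldp = -Y(i, j) / pc + 1.0 / s;
        dz(i, j) = dldp * pc * (1.0 - pc) / n;
      }
    }
  }
  acc = (double)nc / n;
  gWd = P.t() * dz;
  gbd = arma::sum(dz, 0);
  dP = dz * Wd.t();
  return loss / n;
}

static arma::mat dropout_mask(arma::uword n, arma::uword d, double rate) {
  arma::mat m(n, d, arma::fill::ones);
  if (rate <= 0.0) return m;
  double keep = 1.0 - rate;
  for (arma::uword j = 0; j < d; ++j)
    for (arma::uword i = 0; i < n; ++i)
      m(i, j) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  return m;
}

// ---------------------------------------------------------------------
// LSTM. Gate order i, f, g, o in the 4u columns of Wx (1 x 4u),
// Wh (u x 4u), b (4u). X: n x T univariate sequences.
// ---------------------------------------------------------------------
static void lstm_forward_pass(const arma::mat& X, const arma::mat& Wx,
                              const arma::mat& Wh, const arma::rowvec& b,
                              arma::cube* cache, arma::mat& H) {
  const arma::uword n = X.n_rows, T = X.n_cols, u = Wh.n_rows;
  arma::mat C(n, u, arma::fill::zeros);
  H.zeros(n, u);
  for (arma::uword t = 0; t < T; ++t) {
    arma::mat z = X.col(t) * Wx + H * Wh; // n x 4u
    z.each_row() += b;
    arma::mat I = 1.0 / (1.0 + arma::exp(-z.cols(0, u - 1)));
    arma::mat F = 1.0 / (1.0 + arma::exp(-z.cols(u, 2 * u - 1)));
    arma::mat G = arma::tanh(z.cols(2 * u, 3 * u - 1));
    arma::mat O = 1.0 / (1.0 + arma::exp(-z.cols(3 * u, 4 * u - 1)));
    C = F % C + I % G;
    H = O % arma::tanh(C);
    if (cache) {
      cache[0].slice(t) = I; cache[1].slice(t) = F;
      cache[2].slice(t) = G; cache[3].slice(t) = O;
      cache[4].slice(t) = C; cache[5].slice(t) = H;
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_lstm_predict(const arma::mat& X, const arma::mat& Wx,
                           const arma::mat& Wh, const arma::rowvec& b,
                           const arma::mat& Wd, const arma::rowvec& bd,
                           bool softmax) {
  arma::mat H;
  lstm_forward_pass(X, Wx, Wh, b, nullptr, H);
  return output_probs(H, Wd, bd, softmax);
}

// [[Rcpp::export]]
List cpp_lstm_grad(const arma::mat& X, const arma::mat& Y,
                   const arma::mat& Wx, const arma::mat& Wh,
                   const arma::rowvec& b, const arma::mat& Wd,
                   const arma::rowvec& bd, double dropout, bool softmax) {
  const arma::uword n = X.n_rows, T = X.n_cols, u = Wh.n_rows;
  // caches: I, F, G, O, C, H
  arma::cube cache[6];
  for (int k = 0; k < 6; ++k) cache[k].set_size(n, u, T);
  arma::mat H;
  lstm_forward_pass(X, Wx, Wh, b, cache, H);

  arma::mat mask = dropout_mask(n, u, dropout);
  arma::mat Hd = H % mask;

  double acc = 0.0;
  arma::mat dP, gWd;
  arma::rowvec gbd;
  double loss = output_backward(Hd, Wd, bd, Y, softmax, acc, dP, gWd, gbd);

  arma::mat dH = dP % mask;
  arma::mat dC(n, u, arma::fill::zeros);
  arma::mat gWx(arma::size(Wx), arma::fill::zeros);
  arma::mat gWh(arma::size(Wh), arma::fill::zeros);
  arma::rowvec gb(4 * u, arma::fill::zeros);

  for (arma::uword ts = T; ts-- > 0;) {
    const arma::mat& I = cache[0].slice(ts);
    const arma::mat& F = cache[1].slice(ts);
    const arma::mat& G = cache[2].slice(ts);
    const arma::mat& O = cache[3].slice(ts);
    const arma::mat& C = cache[4].slice(ts);
    arma::mat Cprev = (ts == 0) ? arma::mat(n, u, arma::fill::zeros)
                                : cache[4].slice(ts - 1);
    arma::mat Hprev = (ts == 0) ? arma::mat(n, u, arma::fill::zeros)
                                : cache[5].slice(ts - 1);
    arma::mat tc = arma::tanh(C);
    arma::mat dO = dH % tc;
    dC += dH % O % (1.0 - tc % tc);
    arma::mat dI = dC % G;
    arma::mat dF = dC % Cprev;
    arma::mat dG = dC % I;
    arma::mat dZ(n, 4 * u);
    dZ.cols(0, u - 1) = dI % I % (1.0 - I);
    dZ.cols(u, 2 * u - 1) = dF % F % (1.0 - F);
    dZ.cols(2 * u, 3 * u - 1) = dG % (1.0 - G % G);
    dZ.cols(3 * u, 4 * u - 1) = dO % O % (1.0 - O);
    gWx += X.col(ts).t() * dZ;
    gWh += Hprev.t() * dZ;
    gb += arma::sum(dZ, 0);
    dH = dZ * Wh.t();
    dC = dC % F;
  }
  return List::create(_["loss"] = loss, _["acc"] = acc,
                      _["gWx"] = gWx, _["gWh"] = gWh, _["gb"] = gb,
                      _["gWd"] = gWd, _["gbd"] = gbd);
}

// ---------------------------------------------------------------------
// 1-D CNN. Each block: valid conv (kernel k) -> ReLU -> batch norm over
// (batch, time) per filter -> dropout. Blocks are followed by flatten and
// the dense output layer. Block parameters come in as a list:
// W (k x cin x F cube), b (F), gamma, beta, rmean, rvar (F each).
// ---------------------------------------------------------------------
static arma::cube conv1d_forward(const arma::cube& A, const arma::cube& W,
                                 const arma::rowvec& b) {
  const arma::uword n = A.n_rows, L = A.n_cols, cin = A.n_slices;
  const arma::uword k = W.n_rows, F = W.n_slices;
  const arma::uword Lout = L - k + 1;
  arma::cube Z(n, Lout, F);
  for (arma::uword f = 0; f < F; ++f) {
    arma::mat acc(n, Lout, arma::fill::zeros);
    for (arma::uword c = 0; c < cin; ++c)
      for (arma::uword j = 0; j < k; ++j)
        acc += A.slice(c).cols(j, j + Lout - 1) * W(j, c, f);
    acc += b(f);
    Z.slice(f) = acc;
  }
  return Z;
}

struct BlockCache {
  arma::cube Ain, Z, Xhat, Out;
  arma::rowvec mean, var;
  arma::cube mask;
};

static arma::cube cnn_block_forward(const arma::cube& A, const List& blk,
                                    bool training, double dropout,
                                    double bnEps, BlockCache* cache) {
  arma::cube W = as<arma::cube>(blk["W"]);
  arma::rowvec b = as<arma::rowvec>(blk["b"]);
  arma::rowvec gamma = as<arma::rowvec>(blk["gamma"]);
  arma::rowvec beta = as<arma::rowvec>(blk["beta"]);
  arma::rowvec rmean = as<arma::rowvec>(blk["rmean"]);
  arma::rowvec rvar = as<arma::rowvec>(blk["rvar"]);
  arma::cube Z = conv1d_forward(A, W, b);
  const arma::uword n = Z.n_rows, L = Z.n_cols, F = Z.n_slices;
  arma::cube R = arma::max(Z, arma::cube(arma::size(Z), arma::fill::zeros));
  arma::cube Out(n, L, F), Xhat(n, L, F);
  arma::rowvec mean(F), var(F);
  for (arma::uword f = 0; f < F; ++f) {
    double m, v;
    if (training) {
      m = arma::accu(R.slice(f)) / (double)(n * L);
      arma::mat d = R.slice(f) - m;
      v = arma::accu(d % d) / (double)(n * L);
    } else {
      m = rmean(f);
      v = rvar(f);
    }
    mean(f) = m; var(f) = v;
    arma::mat xh = (R.slice(f) - m) / std::sqrt(v + bnEps);
    Xhat.slice(f) = xh;
    Out.slice(f) = gamma(f) * xh + beta(f);
  }
  if (cache) {
    cache->Ain = A; cache->Z = Z; cache->Xhat = Xhat;
    cache->mean = mean; cache->var = var;
  }
  if (training && dropout > 0.0) {
    arma::cube mask(n, L, F);
    double keep = 1.0 - dropout;
    for (arma::uword f = 0; f < F; ++f)
      for (arma::uword t = 0; t < L; ++t)
        for (arma::uword i = 0; i < n; ++i)
          mask(i, t, f) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
    Out %= mask;
    if (cache) cache->mask = mask;
  } else if (cache) {
    cache->mask = arma::cube(n, L, F, arma::fill::ones);
  }
  if (cache) cache->Out = Out;
  return Out;
}

// flatten cube (n, L, F) to matrix (n, L*F); column index = f*L + t.
static arma::mat flatten_cube(const arma::cube& A) {
  const arma::uword n = A.n_rows, L = A.n_cols, F = A.n_slices;
  arma::mat P(n, L * F);
  for (arma::uword f = 0; f < F; ++f)
    P.cols(f * L, f * L + L - 1) = A.slice(f);
  return P;
}

static arma::cube unflatten_mat(const arma::mat& P, arma::uword L,
                                arma::uword F) {
  arma::cube A(P.n_rows, L, F);
  for (arma::uword f = 0; f < F; ++f)
    A.slice(f) = P.cols(f * L, f * L + L - 1);
  return A;
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(const arma::mat& X, const List& blocks,
                          const arma::mat& Wd, const arma::rowvec& bd,
                          double bnEps, bool softmax) {
  arma::cube A(X.n_rows, X.n_cols, 1);
  A.slice(0) = X;
  for (R_xlen_t i = 0; i < blocks.size(); ++i)
    A = cnn_block_forward(A, blocks[i], false, 0.0, bnEps, nullptr);
  return output_probs(flatten_cube(A), Wd, bd, softmax);
}

// [[Rcpp::export]]
List cpp_cnn_grad(const arma::mat& X, const arma::mat& Y, const List& blocks,
                  const arma::mat& Wd, const arma::rowvec& bd, double dropout,
                  double bnEps, double bnMomentum, bool softmax) {
  const arma::uword nb = blocks.size();
  std::vector<BlockCache> caches(nb);
  arma::cube A(X.n_rows, X.n_cols, 1);
  A.slice(0) = X;
  for (arma::uword i = 0; i < nb; ++i)
    A = cnn_block_forward(A, blocks[i], true, dropout, bnEps, &caches[i]);

  double acc = 0.0;
  arma::mat dP, gWd;
  arma::rowvec gbd;
  double loss = output_backward(flatten_cube(A), Wd, bd, Y, softmax, acc,
                                dP, gWd, gbd);
  arma::cube dA = unflatten_mat(dP, A.n_cols, A.n_slices);

  List blockGrads(nb);
  for (arma::uword ib = nb; ib-- > 0;) {
    const BlockCache& cc = caches[ib];
    List blk = blocks[ib];
    arma::cube W = as<arma::cube>(blk["W"]);
    arma::rowvec gamma = as<arma::rowvec>(blk["gamma"]);
    arma::rowvec rmean = as<arma::rowvec>(blk["rmean"]);
    arma::rowvec rvar = as<arma::rowvec>(blk["rvar"]);
    const arma::uword n = cc.Z.n_rows, L = cc.Z.n_cols, F = cc.Z.n_slices;
    const arma::uword k = W.n_rows, cin = W.n_cols;
    const double m = (double)(n * L);

    arma::cube dOut = dA % cc.mask;
    arma::rowvec ggamma(F), gbeta(F);
    arma::cube dZ(n, L, F);
    for (arma::uword f = 0; f < F; ++f) {
      const arma::mat& xh = cc.Xhat.slice(f);
      const arma::mat& dout = dOut.slice(f);
      ggamma(f) = arma::accu(dout % xh);
      gbeta(f) = arma::accu(dout);
      arma::mat dxhat = dout * gamma(f);
      double sd = std::sqrt(cc.var(f) + bnEps);
      arma::mat dR = (dxhat * m - arma::accu(dxhat) -
                      xh * arma::accu(dxhat % xh)) / (m * sd);
      dZ.slice(f) = dR % arma::conv_to<arma::mat>::from(cc.Z.slice(f) > 0.0);
    }
    arma::cube gW(k, cin, F, arma::fill::zeros);
    arma::rowvec gb(F);
    const arma::uword Lin = cc.Ain.n_cols;
    arma::cube dAin(n, Lin, cin, arma::fill::zeros);
    for (arma::uword f = 0; f < F; ++f) {
      gb(f) = arma::accu(dZ.slice(f));
      for (arma::uword c = 0; c < cin; ++c)
        for (arma::uword j = 0; j < k; ++j) {
          gW(j, c, f) = arma::accu(cc.Ain.slice(c).cols(j, j + L - 1) %
                                   dZ.slice(f));
          dAin.slice(c).cols(j, j + L - 1) += W(j, c, f) * dZ.slice(f);
        }
    }
    // updated running statistics (batch stats, momentum as in Keras)
    arma::rowvec newMean = bnMomentum * rmean + (1.0 - bnMomentum) * cc.mean;
    arma::rowvec newVar = bnMomentum * rvar + (1.0 - bnMomentum) * cc.var;
    blockGrads[ib] = List::create(_["gW"] = gW, _["gb"] = gb,
                                  _["ggamma"] = ggamma, _["gbeta"] = gbeta,
                                  _["rmean"] = newMean, _["rvar"] = newVar);
    dA = dAin;
  }
  return List::create(_["loss"] = loss, _["acc"] = acc,
                      _["blocks"] = blockGrads,
                      _["gWd"] = gWd, _["gbd"] = gbd);
}

// ---------------------------------------------------------------------
// CRC-32 (IEEE 802.3), used by the store-only zip writer.
// ---------------------------------------------------------------------
// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int j = 0; j < 8; ++j)
        c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
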