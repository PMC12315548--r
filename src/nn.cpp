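// Dual-pathway network core: a 1-D two-stage conv/pool branch over the
// selected pre-constructed features, a bidirectional LSTM branch over
// integer-encoded residues (final state of each direction), a single affine
// head with sigmoid output, and full analytic gradients (BPTT) for the
// weighted cross-entropy plus prior-band penalty objective. No RNG lives
// here; initialization and shuffling happen on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::IntegerMatrix;
using Rcpp::IntegerVector;
using Rcpp::Named;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmCache {
  cube G;   // B x 4H x T, post-activation gates (i|f|g|o), zero when masked
  cube H;   // B x H x (T+1), hidden states incl. initial zeros
  cube C;   // B x H x (T+1), cell states incl. initial zeros
};

// Run one LSTM direction over a token matrix (B x T, 0 = padding). The
// per-row final state is the state after consuming lengths[b] tokens;
// masked steps carry states through unchanged.
static mat lstm_forward(const mat& emb, const mat& Wx, const mat& Wh,
                        const rowvec& b, const IntegerMatrix& tok,
                        const IntegerVector& len, LstmCache* cache) {
  const int B = tok.nrow(), T = tok.ncol();
  const int H = Wh.n_rows;
  mat Hprev(B, H, fill::zeros), Cprev(B, H, fill::zeros);
  if (cache) {
    cache->G.zeros(B, 4 * H, T);
    cache->H.zeros(B, H, T + 1);
    cache->C.zeros(B, H, T + 1);
  }
  mat Xt(B, emb.n_cols);
  uvec rows(B);
  for (int t = 0; t < T; ++t) {
    vec m(B);
    for (int bb = 0; bb < B; ++bb) {
      rows[bb] = tok(bb, t);
      m[bb] = (len[bb] > t) ? 1.0 : 0.0;
    }
    Xt = emb.rows(rows);
    mat A = Xt * Wx + Hprev * Wh;
    A.each_row() += b;
    mat gi = sigm(A.cols(0, H - 1));
    mat gf = sigm(A.cols(H, 2 * H - 1));
    mat gg = tanh(A.cols(2 * H, 3 * H - 1));
    mat go = sigm(A.cols(3 * H, 4 * H - 1));
    gi.each_col() %= m; gf.each_col() %= m;
    gg.each_col() %= m; go.each_col() %= m;
    mat Cn = gf % Cprev + gi % gg;
    mat Hn = go % tanh(Cn);
    // inactive rows carry their state through unchanged
    Cn.each_col() %= m; Hn.each_col() %= m;
    vec mc = 1.0 - m;
    mat keepC = Cprev, keepH = Hprev;
    keepC.each_col() %= mc; keepH.each_col() %= mc;
    Cn += keepC; Hn += keepH;
    if (cache) {
      cache->G.slice(t) = join_rows(join_rows(gi, gf), join_rows(gg, go));
      cache->H.slice(t + 1) = Hn;
      cache->C.slice(t + 1) = Cn;
    }
    Hprev = Hn; Cprev = Cn;
  }
  return Hprev;
}

// BPTT for one direction given d(final hidden state); accumulates gradients
// and the embedding gradient.
static void lstm_backward(const mat& emb, const mat& Wx, const mat& Wh,
                          const IntegerMatrix& tok, const IntegerVector& len,
                          const LstmCache& cache, const mat& dHfinal,
                          mat& gWx, mat& gWh, rowvec& gb, mat& gemb) {
  const int B = tok.nrow(), T = tok.ncol();
  const int H = Wh.n_rows;
  mat dH = dHfinal, dC(B, H, fill::zeros);
  mat Xt(B, emb.n_cols);
  uvec rows(B);
  for (int t = T - 1; t >= 0; --t) {
    vec m(B);
    for (int bb = 0; bb < B; ++bb) m[bb] = (len[bb] > t) ? 1.0 : 0.0;
    const mat& G = cache.G.slice(t);
    mat gi = G.cols(0, H - 1), gf = G.cols(H, 2 * H - 1);
    mat gg = G.cols(2 * H, 3 * H - 1), go = G.cols(3 * H, 4 * H - 1);
    mat Ct = cache.C.slice(t + 1), Cp = cache.C.slice(t);
    mat tc = tanh(Ct);
    mat dCtot = dC + dH % go % (1.0 - tc % tc);  // go==0 on masked rows
    mat dAi = (dCtot % gg) % gi % (1.0 - gi);
    mat dAf = (dCtot % Cp) % gf % (1.0 - gf);
    mat dAg = (dCtot % gi) % (1.0 - gg % gg);
    mat dAo = (dH % tc) % go % (1.0 - go);
    mat dA = join_rows(join_rows(dAi, dAf), join_rows(dAg, dAo));
    dA.each_col() %= m;
    for (int bb = 0; bb < B; ++bb) rows[bb] = tok(bb, t);
    Xt = emb.rows(rows);
    gWx += Xt.t() * dA;
    gWh += cache.H.slice(t).t() * dA;
    gb += sum(dA, 0);
    mat dXt = dA * Wx.t();
    for (int bb = 0; bb < B; ++bb) {
      if (m[bb] > 0) gemb.row(tok(bb, t)) += dXt.row(bb);
    }
    mat dHp = dA * Wh.t();
    mat dCp_ = dCtot % gf;
    mat carryH = dH, carryC = dCtot;
    carryH.each_col() %= (1.0 - m);
    carryC.each_col() %= (1.0 - m);
    dH = dHp + carryH;
    dC = dCp_ + carryC;
  }
}

struct ConvCache {
  cube R1, P1, R2, P2;    // post-ReLU conv maps and pooled maps
  ucube A1, A2;           // pooling argmax offsets (0/1)
};

// Two conv(k=3,valid)/ReLU/maxpool(2) stages over the feature vector treated
// as a one-channel 1-D signal; returns the flattened map (B x F2*n4,
// filter-major).
static mat conv_forward(const mat& X, const mat& W1, const vec& b1,
                        const mat& W2, const vec& b2, ConvCache* cache) {
  const int B = X.n_rows, K = W1.n_cols;
  const int F1 = W1.n_rows, F2 = W2.n_rows;
  const int n1 = X.n_cols - K + 1, n2 = n1 / 2;
  const int n3 = n2 - K + 1, n4 = n3 / 2;
  cube R1(B, n1, F1), P1(B, n2, F1), R2(B, n3, F2), P2(B, n4, F2);
  ucube A1(B, n2, F1), A2(B, n4, F2);
  for (int f = 0; f < F1; ++f) {
    mat acc(B, n1, fill::zeros);
    for (int k = 0; k < K; ++k) acc += X.cols(k, k + n1 - 1) * W1(f, k);
    acc += b1[f];
    R1.slice(f) = clamp(acc, 0.0, datum::inf);
    for (int p = 0; p < n2; ++p) {
      for (int bb = 0; bb < B; ++bb) {
        double a = R1(bb, 2 * p, f), c = R1(bb, 2 * p + 1, f);
        A1(bb, p, f) = (c > a) ? 1 : 0;
        P1(bb, p, f) = (c > a) ? c : a;
      }
    }
  }
  for (int g = 0; g < F2; ++g) {
    mat acc(B, n3, fill::zeros);
    for (int f = 0; f < F1; ++f) {
      for (int k = 0; k < K; ++k) {
        acc += P1.slice(f).cols(k, k + n3 - 1) * W2(g, f * K + k);
      }
    }
    acc += b2[g];
    R2.slice(g) = clamp(acc, 0.0, datum::inf);
    for (int p = 0; p < n4; ++p) {
      for (int bb = 0; bb < B; ++bb) {
        double a = R2(bb, 2 * p, g), c = R2(bb, 2 * p + 1, g);
        A2(bb, p, g) = (c > a) ? 1 : 0;
        P2(bb, p, g) = (c > a) ? c : a;
      }
    }
  }
  mat Z(B, F2 * n4);
  for (int g = 0; g < F2; ++g) Z.cols(g * n4, (g + 1) * n4 - 1) = P2.slice(g);
  if (cache) { cache->R1 = R1; cache->P1 = P1; cache->R2 = R2;
               cache->P2 = P2; cache->A1 = A1; cache->A2 = A2; }
  return Z;
}

static void conv_backward(const mat& X, const mat& W1, const mat& W2,
                          const ConvCache& cc, const mat& dZ,
                          mat& gW1, vec& gb1, mat& gW2, vec& gb2) {
  const int B = X.n_rows, K = W1.n_cols;
  const int F1 = W1.n_rows, F2 = W2.n_rows;
  const int n1 = X.n_cols - K + 1, n2 = n1 / 2;
  const int n3 = n2 - K + 1, n4 = n3 / 2;
  cube dP1(B, n2, F1, fill::zeros);
  for (int g = 0; g < F2; ++g) {
    mat dP2 = dZ.cols(g * n4, (g + 1) * n4 - 1);
    mat dR2(B, n3, fill::zeros);
    for (int p = 0; p < n4; ++p) {
      for (int bb = 0; bb < B; ++bb) {
        dR2(bb, 2 * p + cc.A2(bb, p, g)) += dP2(bb, p);
      }
    }
    dR2 %= conv_to<mat>::from(cc.R2.slice(g) > 0);
    gb2[g] += accu(dR2);
    for (int f = 0; f < F1; ++f) {
      for (int k = 0; k < K; ++k) {
        gW2(g, f * K + k) += accu(dR2 % cc.P1.slice(f).cols(k, k + n3 - 1));
        dP1.slice(f).cols(k, k + n3 - 1) += dR2 * W2(g, f * K + k);
      }
    }
  }
  for (int f = 0; f < F1; ++f) {
    mat dR1(B, n1, fill::zeros);
    for (int p = 0; p < n2; ++p) {
      for (int bb = 0; bb < B; ++bb) {
        dR1(bb, 2 * p + cc.A1(bb, p, f)) += dP1(bb, p, f);
      }
    }
    dR1 %= conv_to<mat>::from(cc.R1.slice(f) > 0);
    gb1[f] += accu(dR1);
    for (int k = 0; k < K; ++k) {
      gW1(f, k) += accu(dR1 % X.cols(k, k + n1 - 1));
    }
  }
}

struct Params {
  mat emb, fWx, fWh, bWx, bWh, W1, W2;
  rowvec fb, bb_;
  vec b1, b2, hw;
  double hb;
};

static Params unpack(const List& params) {
  Params P;
  P.emb = Rcpp::as<mat>(params["emb"]);
  P.fWx = Rcpp::as<mat>(params["lstm_f_Wx"]);
  P.fWh = Rcpp::as<mat>(params["lstm_f_Wh"]);
  P.fb  = Rcpp::as<rowvec>(params["lstm_f_b"]);
  P.bWx = Rcpp::as<mat>(params["lstm_b_Wx"]);
  P.bWh = Rcpp::as<mat>(params["lstm_b_Wh"]);
  P.bb_ = Rcpp::as<rowvec>(params["lstm_b_b"]);
  P.W1  = Rcpp::as<mat>(params["conv1_W"]);
  P.b1  = Rcpp::as<vec>(params["conv1_b"]);
  P.W2  = Rcpp::as<mat>(params["conv2_W"]);
  P.b2  = Rcpp::as<vec>(params["conv2_b"]);
  P.hw  = Rcpp::as<vec>(params["head_w"]);
  P.hb  = Rcpp::as<double>(params["head_b"]);
  return P;
}

// Reverse each row's first len[b] tokens (the backward-direction input).
static IntegerMatrix reverse_tokens(const IntegerMatrix& tok,
                                    const IntegerVector& len) {
  IntegerMatrix out(tok.nrow(), tok.ncol());
  for (int b = 0; b < tok.nrow(); ++b) {
    for (int t = 0; t < len[b]; ++t) out(b, t) = tok(b, len[b] - 1 - t);
    for (int t = len[b]; t < tok.ncol(); ++t) out(b, t) = 0;
  }
  return out;
}

static mat forward_all(const Params& P, const mat& X,
                       const IntegerMatrix& tok, const IntegerMatrix& rtok,
                       const IntegerVector& len,
                       LstmCache* cf, LstmCache* cb, ConvCache* cc,
                       vec* logit) {
  mat Z1 = conv_forward(X, P.W1, P.b1, P.W2, P.b2, cc);
  mat Hf = lstm_forward(P.emb, P.fWx, P.fWh, P.fb, tok, len, cf);
  mat Hb = lstm_forward(P.emb, P.bWx, P.bWh, P.bb_, rtok, len, cb);
  mat Z = join_rows(Z1, join_rows(Hf, Hb));
  *logit = Z * P.hw + P.hb;
  return Z;
}

// [[Rcpp::export]]
arma::vec nn_forward_cpp(List params, arma::mat X, IntegerMatrix tokens,
                         IntegerVector lengths) {
  Params P = unpack(params);
  IntegerMatrix rtok = reverse_tokens(tokens, lengths);
  vec logit;
  forward_all(P, X, tokens, rtok, lengths, nullptr, nullptr, nullptr, &logit);
  return 1.0 / (1.0 + exp(-logit));
}

// One full objective evaluation with gradients. y < 0 marks rows that do not
// enter the cross-entropy (penalty-only rows); `reg` marks membership of the
// soft positive-proportion set. Returns probabilities, the weighted
// cross-entropy, the penalty value and gradients for every parameter.
// [[Rcpp::export]]
List nn_step_cpp(List params, arma::mat X, IntegerMatrix tokens,
                 IntegerVector lengths, arma::vec y, arma::vec w,
                 arma::uvec reg, double band_lo, double band_hi,
                 double coef) {
  Params P = unpack(params);
  IntegerMatrix rtok = reverse_tokens(tokens, lengths);
  LstmCache cf, cb;
  ConvCache cc;
  vec logit;
  mat Z = forward_all(P, X, tokens, rtok, lengths, &cf, &cb, &cc, &logit);
  vec p = 1.0 / (1.0 + exp(-logit));
  const double eps = 1e-7;
  vec pc = clamp(p, eps, 1.0 - eps);

  uvec bce_idx = find(y >= 0);
  double n_bce = bce_idx.n_elem;
  double loss = 0.0;
  vec dlogit(p.n_elem, fill::zeros);
  if (n_bce > 0) {
    for (uword k = 0; k < bce_idx.n_elem; ++k) {
      uword i = bce_idx[k];
      loss += -w[i] * (y[i] * std::log(pc[i]) +
                       (1.0 - y[i]) * std::log(1.0 - pc[i]));
      dlogit[i] += w[i] * (p[i] - y[i]) / n_bce;
    }
    loss /= n_bce;
  }

  double penalty = 0.0;
  uvec reg_idx = find(reg > 0);
  if (reg_idx.n_elem > 0 && coef > 0) {
    double pbar = mean(p.elem(reg_idx));
    double sgn = 0.0;
    if (pbar < band_lo) { penalty = coef * (band_lo - pbar); sgn = -1.0; }
    else if (pbar > band_hi) { penalty = coef * (pbar - band_hi); sgn = 1.0; }
    if (sgn != 0.0) {
      double d = sgn * coef / reg_idx.n_elem;
      for (uword k = 0; k < reg_idx.n_elem; ++k) {
        uword i = reg_idx[k];
        dlogit[i] += d * p[i] * (1.0 - p[i]);
      }
    }
  }

  // Head.
  const int n_flat = Z.n_cols - 2 * P.fWh.n_rows;
  vec g_hw = Z.t() * dlogit;
  double g_hb = accu(dlogit);
  mat dZ = dlogit * P.hw.t();
  mat dZ1 = dZ.cols(0, n_flat - 1);
  const int H = P.fWh.n_rows;
  mat dHf = dZ.cols(n_flat, n_flat + H - 1);
  mat dHb = dZ.cols(n_flat + H, n_flat + 2 * H - 1);

  mat gW1(size(P.W1), fill::zeros), gW2(size(P.W2), fill::zeros);
  vec gb1(P.b1.n_elem, fill::zeros), gb2(P.b2.n_elem, fill::zeros);
  conv_backward(X, P.W1, P.W2, cc, dZ1, gW1, gb1, gW2, gb2);

  mat gfWx(size(P.fWx), fill::zeros), gfWh(size(P.fWh), fill::zeros);
  mat gbWx(size(P.bWx), fill::zeros), gbWh(size(P.bWh), fill::zeros);
  rowvec gfb(P.fb.n_elem, fill::zeros), gbb(P.bb_.n_elem, fill::zeros);
  mat gemb(size(P.emb), fill::zeros);
  lstm_backward(P.emb, P.fWx, P.fWh, tokens, lengths, cf, dHf,
                gfWx, gfWh, gfb, gemb);
  lstm_backward(P.emb, P.bWx, P.bWh, rtok, lengths, cb, dHb,
                gbWx, gbWh, gbb, gemb);
  gemb.row(0).zeros();   // padding embedding is fixed

  return List::create(
    Named("probabilities") = p,
    Named("loss_bce") = loss,
    Named("penalty") = penalty,
    Named("grads") = List::create(
      Named("emb") = gemb,
      Named("lstm_f_Wx") = gfWx, Named("lstm_f_Wh") = gfWh,
      Named("lstm_f_b") = gfb,
      Named("lstm_b_Wx") = gbWx, Named("lstm_b_Wh") = gbWh,
      Named("lstm_b_b") = gbb,
      Named("conv1_W") = gW1, Named("conv1_b") = gb1,
      Named("conv2_W") = gW2, Named("conv2_b") = gb2,
      Named("head_w") = g_hw, Named("head_b") = g_hb));
}
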