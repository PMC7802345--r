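// LSTM encoder-decoder with Luong attention: forward, backpropagation
// through time, and greedy decoding. Armadillo; batches are column-major
// (features x batch), sequences time-major.
//
// Token id convention (0-based here, 1-based on the R side):
//   0 = PAD, 1 = SOS, 2 = EOS, 3 = SEP, >= 4 fragment words.
//
// Layout notes. The input-side GEMMs of every LSTM layer are batched over
// all timesteps (W * [x_1 ... x_T]), and since the decoder uses teacher
// forcing without input feeding, the whole decoder runs layer-major as
// well; only the recurrent U * h products go step by step. Padded encoder
// positions are handled by a masked state carry so each sequence's final
// forward state is the one at its true length; attention masks padded
// source positions. Local attention follows Luong's predictive alignment:
// a learned sigmoid picks a center p, scores outside [p-D, p+D] are
// excluded and a Gaussian penalty (sigma = D/2) is added inside the window
// before the softmax, so the weights always form a probability
// distribution over the attended positions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const int ID_PAD = 0, ID_SOS = 1, ID_EOS = 2;

struct Cfg {
  int V, d, H, L, dirs, D;
  bool local, feed;
  double dropout;
};

static Cfg readCfg(const List& cfg) {
  Cfg c;
  c.V = as<int>(cfg["vocab_size"]);
  c.d = as<int>(cfg["embedding_dim"]);
  c.H = as<int>(cfg["hidden_units"]);
  c.L = as<int>(cfg["num_layers"]);
  c.dirs = as<bool>(cfg["bidirectional"]) ? 2 : 1;
  c.local = as<std::string>(cfg["attention"]) == "local";
  c.D = as<int>(cfg["local_window"]);
  c.dropout = as<double>(cfg["dropout"]);
  c.feed = cfg.containsElementNamed("input_feed")
             ? as<bool>(cfg["input_feed"]) : false;
  return c;
}

struct Params {
  std::map<std::string, mat> M;
  std::map<std::string, vec> Vv;
  mat& m(const std::string& k) { return M.at(k); }
  vec& v(const std::string& k) { return Vv.at(k); }
};

static Params readParams(const List& p) {
  Params P;
  CharacterVector nm = p.names();
  for (R_xlen_t i = 0; i < nm.size(); ++i) {
    std::string k = as<std::string>(nm[i]);
    RObject o = p[k];
    NumericVector nv(o);
    if (nv.hasAttribute("dim")) P.M[k] = as<mat>(o);
    else P.Vv[k] = as<vec>(o);
  }
  return P;
}

struct Grads {
  std::map<std::string, mat> M;
  std::map<std::string, vec> V;
  void init(const Params& P) {
    for (auto& kv : P.M)
      M[kv.first] = arma::zeros<mat>(kv.second.n_rows, kv.second.n_cols);
    for (auto& kv : P.Vv) V[kv.first] = arma::zeros<vec>(kv.second.n_elem);
  }
  List toList() {
    List out;
    for (auto& kv : M) out[kv.first] = wrap(kv.second);
    for (auto& kv : V)  // plain vectors, so R-side updates keep them dimless
      out[kv.first] = NumericVector(kv.second.begin(), kv.second.end());
    return out;
  }
};

static std::string pn(const char* stem, int l, char dir = 0) {
  std::string s(stem);
  s += "_" + std::to_string(l);
  if (dir) { s += "_"; s += dir; }
  return s;
}

// Per-timestep cell cache (gate activations, carried states, mask).
struct Cell {
  mat i, f, g, o, cn, tcn, cprev, hprev;
  rowvec m;
};

// One step given the precomputed input contribution zin = W x + b.
static void lstmStepZ(const mat& zin, const mat& U, const rowvec& m, mat& h,
                      mat& c, Cell& cc) {
  const int H = h.n_rows;
  cc.hprev = h; cc.cprev = c; cc.m = m;
  mat z = zin + U * h;
  cc.i = 1.0 / (1.0 + arma::exp(-z.rows(0, H - 1)));
  cc.f = 1.0 / (1.0 + arma::exp(-z.rows(H, 2 * H - 1)));
  cc.g = arma::tanh(z.rows(2 * H, 3 * H - 1));
  cc.o = 1.0 / (1.0 + arma::exp(-z.rows(3 * H, 4 * H - 1)));
  cc.cn = cc.f % c + cc.i % cc.g;
  cc.tcn = arma::tanh(cc.cn);
  mat hn = cc.o % cc.tcn;
  mat mm = arma::repmat(m, H, 1);
  c = cc.cn % mm + cc.cprev % (1.0 - mm);
  h = hn % mm + cc.hprev % (1.0 - mm);
}

// Backward for one step: returns dz; updates dh/dc in place to the
// previous step's gradients (recurrent part only; the input-side GEMMs are
// batched by the caller).
static mat lstmBackZ(const mat& U, const Cell& cc, mat& dh, mat& dc) {
  const int H = dh.n_rows;
  mat mm = arma::repmat(cc.m, H, 1);
  mat dhn = dh % mm;
  mat dhcarry = dh % (1.0 - mm);
  mat dcn = dc % mm + dhn % cc.o % (1.0 - cc.tcn % cc.tcn);
  mat dccarry = dc % (1.0 - mm);
  mat dz(4 * H, dh.n_cols);
  dz.rows(0, H - 1) = (dcn % cc.g) % cc.i % (1.0 - cc.i);
  dz.rows(H, 2 * H - 1) = (dcn % cc.cprev) % cc.f % (1.0 - cc.f);
  dz.rows(2 * H, 3 * H - 1) = (dcn % cc.i) % (1.0 - cc.g % cc.g);
  dz.rows(3 * H, 4 * H - 1) = (dhn % cc.tcn) % cc.o % (1.0 - cc.o);
  dh = U.t() * dz + dhcarry;
  dc = cc.f % dcn + dccarry;
  return dz;
}

// One direction of one layer run over a whole (time-major) sequence batch.
struct SeqRun {
  std::vector<Cell> cells;   // per t
  mat hFinal, cFinal;
};

// Forward a full layer direction. Xall: (in x B*T); masks per t; outputs
// written into out[t] (H x B). reverseTime runs t = T-1..0.
static SeqRun runLSTM(const mat& W, const mat& U, const vec& b,
                      const mat& Xall, const std::vector<rowvec>& masks,
                      std::vector<mat>& out, bool reverseTime, int B) {
  const int T = masks.size(), H = U.n_cols;
  SeqRun R;
  R.cells.resize(T);
  mat Zin = W * Xall;
  Zin.each_col() += b;
  mat h = arma::zeros<mat>(H, B), c = arma::zeros<mat>(H, B);
  for (int k = 0; k < T; ++k) {
    int t = reverseTime ? T - 1 - k : k;
    lstmStepZ(Zin.cols((arma::uword)t * B, (arma::uword)(t + 1) * B - 1), U,
              masks[t], h, c, R.cells[t]);
    out[t] = h;
  }
  R.hFinal = h; R.cFinal = c;
  return R;
}

// Backward a full layer direction. dOut[t] (H x B) are the gradients on the
// outputs; dhFinal/dcFinal seed the recurrence. Accumulates dW, dU, db and
// adds W^T dz into dXall.
static void backLSTM(const mat& W, const mat& U, const SeqRun& R,
                     const mat& Xall, const std::vector<mat>& dOut,
                     mat dhFinal, mat dcFinal, bool reverseTime, int B,
                     mat& dW, mat& dU, vec& db, mat& dXall) {
  const int T = R.cells.size(), H = U.n_cols;
  mat DZ(4 * H, Xall.n_cols);
  mat Hprev(H, Xall.n_cols);
  mat dh = dhFinal, dc = dcFinal;
  for (int k = T - 1; k >= 0; --k) {
    int t = reverseTime ? T - 1 - k : k;
    dh += dOut[t];
    mat dz = lstmBackZ(U, R.cells[t], dh, dc);
    DZ.cols((arma::uword)t * B, (arma::uword)(t + 1) * B - 1) = dz;
    Hprev.cols((arma::uword)t * B, (arma::uword)(t + 1) * B - 1) =
      R.cells[t].hprev;
  }
  dW += DZ * Xall.t();
  dU += DZ * Hprev.t();
  db += arma::sum(DZ, 1);
  dXall += W.t() * DZ;
}

static mat dropoutMask(int nr, int nc, double rate, std::mt19937& rng) {
  mat m(nr, nc, arma::fill::ones);
  if (rate > 0) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    for (arma::uword i = 0; i < m.n_elem; ++i)
      m[i] = (unif(rng) < rate) ? 0.0 : 1.0 / (1.0 - rate);
  }
  return m;
}

struct EncState {
  std::vector<mat> Xall;                 // per layer: input (in x B*T)
  std::vector<SeqRun> runF, runB;        // per layer
  std::vector<mat> dropMask;             // per layer below the next
  std::vector<std::vector<mat> > outF, outB;  // per layer, per t
  std::vector<mat> hcat, h0, c0;         // bridge caches per layer
  arma::cube encOut;                     // encDim x B x Ts (top layer)
  std::vector<rowvec> masks;
};

static void encodeForward(const Cfg& c, Params& P, const arma::imat& src,
                          const arma::ivec& srcLen, bool train,
                          std::mt19937& rng, EncState& E) {
  const int Ts = src.n_rows, B = src.n_cols, H = c.H;
  mat& Emb = P.m("E");
  E.masks.resize(Ts);
  for (int t = 0; t < Ts; ++t) {
    E.masks[t].set_size(B);
    for (int b = 0; b < B; ++b) E.masks[t][b] = (t < srcLen[b]) ? 1.0 : 0.0;
  }
  E.Xall.resize(c.L);
  E.runF.resize(c.L); E.runB.resize(c.L);
  E.outF.assign(c.L, std::vector<mat>(Ts));
  E.outB.assign(c.L, std::vector<mat>(Ts));
  E.dropMask.resize(c.L);
  mat X(c.d, (arma::uword)B * Ts);
  for (int t = 0; t < Ts; ++t)
    for (int b = 0; b < B; ++b)
      X.col((arma::uword)t * B + b) = Emb.col(src(t, b));
  for (int l = 0; l < c.L; ++l) {
    E.Xall[l] = X;
    E.runF[l] = runLSTM(P.m(pn("encW", l + 1, 'f')),
                        P.m(pn("encU", l + 1, 'f')),
                        P.v(pn("encb", l + 1, 'f')), E.Xall[l], E.masks,
                        E.outF[l], false, B);
    if (c.dirs == 2)
      E.runB[l] = runLSTM(P.m(pn("encW", l + 1, 'b')),
                          P.m(pn("encU", l + 1, 'b')),
                          P.v(pn("encb", l + 1, 'b')), E.Xall[l], E.masks,
                          E.outB[l], true, B);
    if (l < c.L - 1) {
      X.set_size(H * c.dirs, (arma::uword)B * Ts);
      for (int t = 0; t < Ts; ++t) {
        X.cols((arma::uword)t * B, (arma::uword)(t + 1) * B - 1) =
          (c.dirs == 2) ? arma::join_cols(E.outF[l][t], E.outB[l][t])
                        : E.outF[l][t];
      }
      E.dropMask[l] = train ? dropoutMask(H * c.dirs, (arma::uword)B * Ts,
                                          c.dropout, rng)
                            : mat(H * c.dirs, (arma::uword)B * Ts,
                                  arma::fill::ones);
      X %= E.dropMask[l];
    }
  }
  const int encDim = H * c.dirs;
  E.encOut.set_size(encDim, B, Ts);
  for (int t = 0; t < Ts; ++t)
    E.encOut.slice(t) = (c.dirs == 2)
      ? arma::join_cols(E.outF[c.L - 1][t], E.outB[c.L - 1][t])
      : E.outF[c.L - 1][t];
  E.hcat.resize(c.L); E.h0.resize(c.L); E.c0.resize(c.L);
  for (int l = 0; l < c.L; ++l) {
    E.hcat[l] = (c.dirs == 2)
      ? arma::join_cols(E.runF[l].hFinal, E.runB[l].hFinal)
      : E.runF[l].hFinal;
    E.h0[l] = arma::tanh(P.m(pn("brh", l + 1)) * E.hcat[l]);
    mat ccat = (c.dirs == 2)
      ? arma::join_cols(E.runF[l].cFinal, E.runB[l].cFinal)
      : E.runF[l].cFinal;
    E.c0[l] = arma::tanh(P.m(pn("brc", l + 1)) * ccat);
  }
}

struct AttCache {
  mat alpha, ctx, htop, qa;
  mat a;            // local: tanh(Wp h)
  rowvec sig, p;    // local: sigmoid and predicted center
};

static mat attention(const Cfg& c, Params& P, const arma::cube& encOut,
                     const arma::ivec& srcLen, const mat& htop,
                     AttCache& ac) {
  const int S = encOut.n_slices, B = htop.n_cols;
  ac.htop = htop;
  ac.qa = P.m("Wa").t() * htop;
  mat scores(S, B);
  for (int s = 0; s < S; ++s)
    scores.row(s) = arma::sum(encOut.slice(s) % ac.qa, 0);
  for (int b = 0; b < B; ++b)
    for (int s = srcLen[b]; s < S; ++s) scores(s, b) = -1e30;
  if (c.local) {
    ac.a = arma::tanh(P.m("Wp") * htop);
    rowvec u = P.v("vp").t() * ac.a;
    ac.sig = 1.0 / (1.0 + arma::exp(-u));
    ac.p = ac.sig;
    const double sig2 = (c.D / 2.0) * (c.D / 2.0);
    for (int b = 0; b < B; ++b) {
      ac.p[b] = ac.sig[b] * std::max(0, srcLen[b] - 1);
      for (int s = 0; s < srcLen[b]; ++s) {
        double dist = s - ac.p[b];
        if (std::fabs(dist) > c.D) scores(s, b) = -1e30;
        else scores(s, b) -= dist * dist / (2.0 * sig2);
      }
    }
  }
  rowvec mx = arma::max(scores, 0);
  scores.each_row() -= mx;
  mat ex = arma::exp(scores);
  rowvec tot = arma::sum(ex, 0);
  ac.alpha = ex;
  ac.alpha.each_row() /= tot;
  mat ctx = arma::zeros<mat>(encOut.n_rows, B);
  for (int s = 0; s < S; ++s) {
    mat sl = encOut.slice(s);
    sl.each_row() %= ac.alpha.row(s);
    ctx += sl;
  }
  ac.ctx = ctx;
  return ctx;
}

static mat attentionBack(const Cfg& c, Params& P, Grads& G,
                         const arma::cube& encOut, const arma::ivec& srcLen,
                         const AttCache& ac, const mat& dctx,
                         arma::cube& dEnc) {
  const int S = encOut.n_slices, B = dctx.n_cols;
  mat dalpha(S, B);
  for (int s = 0; s < S; ++s) {
    dalpha.row(s) = arma::sum(encOut.slice(s) % dctx, 0);
    mat add = dctx;
    add.each_row() %= ac.alpha.row(s);
    dEnc.slice(s) += add;
  }
  mat tmp = ac.alpha % dalpha;
  rowvec colsum = arma::sum(tmp, 0);
  mat dscores = tmp - (ac.alpha.each_row() % colsum);
  mat dqa = arma::zeros<mat>(encOut.n_rows, B);
  for (int s = 0; s < S; ++s) {
    dqa += encOut.slice(s).each_row() % dscores.row(s);
    mat add = ac.qa;
    add.each_row() %= dscores.row(s);
    dEnc.slice(s) += add;
  }
  G.M["Wa"] += ac.htop * dqa.t();
  mat dhtop = P.m("Wa") * dqa;
  if (c.local) {
    const double sig2 = (c.D / 2.0) * (c.D / 2.0);
    rowvec dp(B, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int s = 0; s < srcLen[b]; ++s) {
        double dist = s - ac.p[b];
        if (std::fabs(dist) <= c.D) dp[b] += dscores(s, b) * dist / sig2;
      }
    rowvec scale(B);
    for (int b = 0; b < B; ++b) scale[b] = std::max(0, srcLen[b] - 1);
    rowvec du = (dp % scale) % ac.sig % (1.0 - ac.sig);
    G.V["vp"] += ac.a * du.t();
    mat dpa = (P.v("vp") * du) % (1.0 - ac.a % ac.a);
    G.M["Wp"] += dpa * ac.htop.t();
    dhtop += P.m("Wp").t() * dpa;
  }
  return dhtop;
}

// [[Rcpp::export]]
List cppS2SLossGrad(List params, List cfg, IntegerMatrix srcR,
                    IntegerVector srcLenR, IntegerMatrix tgtR,
                    IntegerVector tgtLenR, bool train, bool wantGrad,
                    int seed) {
  Cfg c = readCfg(cfg);
  Params P = readParams(params);
  std::mt19937 rng((unsigned)seed);
  const int Ts = srcR.nrow(), B = srcR.ncol(), Tt = tgtR.nrow();
  arma::imat src(Ts, B), tgt(Tt, B);
  for (int t = 0; t < Ts; ++t)
    for (int b = 0; b < B; ++b) src(t, b) = srcR(t, b);
  for (int t = 0; t < Tt; ++t)
    for (int b = 0; b < B; ++b) tgt(t, b) = tgtR(t, b);
  arma::ivec srcLen(B), tgtLen(B);
  for (int b = 0; b < B; ++b) {
    srcLen[b] = srcLenR[b];
    tgtLen[b] = tgtLenR[b];
  }
  EncState E;
  encodeForward(c, P, src, srcLen, train, rng, E);

  const int H = c.H, encDim = H * c.dirs;
  mat& Emb = P.m("E");
  arma::imat din(Tt, B);
  for (int t = 0; t < Tt; ++t)
    for (int b = 0; b < B; ++b)
      din(t, b) = (t == 0) ? ID_SOS : tgt(t - 1, b);

  // decoder, step-major: with input feeding the previous step's
  // attentional state joins the token embedding, so each step depends on
  // the last one. Weight-gradient GEMMs are still batched after the loop.
  const int dIn = c.d + (c.feed ? H : 0);
  rowvec ones1(B, arma::fill::ones);
  std::vector<mat> decXall(c.L);      // layer inputs, (in x B*Tt)
  decXall[0].set_size(dIn, (arma::uword)B * Tt);
  for (int l = 1; l < c.L; ++l)
    decXall[l].set_size(H, (arma::uword)B * Tt);
  std::vector<SeqRun> decRun(c.L);
  for (int l = 0; l < c.L; ++l) decRun[l].cells.resize(Tt);
  std::vector<mat> decDrop(c.L);
  for (int l = 0; l + 1 < c.L; ++l)
    decDrop[l] = train ? dropoutMask(H, (arma::uword)B * Tt, c.dropout, rng)
                       : mat(H, (arma::uword)B * Tt, arma::fill::ones);
  std::vector<mat> h(c.L), ccell(c.L);
  for (int l = 0; l < c.L; ++l) { h[l] = E.h0[l]; ccell[l] = E.c0[l]; }
  std::vector<AttCache> att(Tt);
  mat CatAll(encDim + H, (arma::uword)B * Tt);
  mat HtildeAll(H, (arma::uword)B * Tt);
  mat htildePrev = arma::zeros<mat>(H, B);
  for (int t = 0; t < Tt; ++t) {
    arma::uword c0 = (arma::uword)t * B, c1 = (arma::uword)(t + 1) * B - 1;
    mat x(dIn, B);
    for (int b = 0; b < B; ++b)
      x.col(b).rows(0, c.d - 1) = Emb.col(din(t, b));
    if (c.feed) x.rows(c.d, c.d + H - 1) = htildePrev;
    for (int l = 0; l < c.L; ++l) {
      decXall[l].cols(c0, c1) = x;
      mat zin = P.m(pn("decW", l + 1)) * x;
      zin.each_col() += P.v(pn("decb", l + 1));
      lstmStepZ(zin, P.m(pn("decU", l + 1)), ones1, h[l], ccell[l],
                decRun[l].cells[t]);
      if (l + 1 < c.L) x = h[l] % decDrop[l].cols(c0, c1);
    }
    mat ctx = attention(c, P, E.encOut, srcLen, h[c.L - 1], att[t]);
    CatAll.cols(c0, c1) = arma::join_cols(ctx, h[c.L - 1]);
    mat pre = P.m("Wc") * CatAll.cols(c0, c1);
    pre.each_col() += P.v("bc");
    mat htilde = arma::tanh(pre);
    HtildeAll.cols(c0, c1) = htilde;
    htildePrev = htilde;
  }
  // dropout "following the hidden layer" also applies to the attentional
  // hidden state, the only hidden layer a 1-layer decoder has
  mat outDrop = train ? dropoutMask(H, (arma::uword)B * Tt, c.dropout, rng)
                      : mat(H, (arma::uword)B * Tt, arma::fill::ones);
  mat HtildeDrop = HtildeAll % outDrop;
  mat Logits = P.m("Wo") * HtildeDrop;
  Logits.each_col() += P.v("bo");
  rowvec mx = arma::max(Logits, 0);
  Logits.each_row() -= mx;
  mat Sm = arma::exp(Logits);
  rowvec tot = arma::sum(Sm, 0);
  Sm.each_row() /= tot;
  double loss = 0.0, ntok = 0.0;
  for (int b = 0; b < B; ++b) ntok += tgtLen[b];
  mat DLogits = Sm;
  for (int t = 0; t < Tt; ++t)
    for (int b = 0; b < B; ++b) {
      arma::uword col = (arma::uword)t * B + b;
      if (t < tgtLen[b]) {
        int y = tgt(t, b);
        loss -= std::log(std::max(Sm(y, col), 1e-300));
        DLogits(y, col) -= 1.0;
      } else {
        DLogits.col(col).zeros();
      }
    }
  loss /= ntok;

  List out = List::create(_["loss"] = loss, _["ntokens"] = ntok);
  if (!wantGrad) return out;

  Grads G;
  G.init(P);
  DLogits /= ntok;
  G.M["Wo"] += DLogits * HtildeDrop.t();
  G.V["bo"] += arma::sum(DLogits, 1);
  mat DHtildeOut = (P.m("Wo").t() * DLogits) % outDrop;

  // step-major decoder backward: the input-feeding path carries the
  // attentional-state gradient into the previous timestep
  arma::cube dEnc(encDim, B, Ts, arma::fill::zeros);
  std::vector<mat> DZ(c.L);
  for (int l = 0; l < c.L; ++l)
    DZ[l].set_size(4 * H, (arma::uword)B * Tt);
  mat DPreAll(H, (arma::uword)B * Tt);
  std::vector<mat> ddh(c.L), ddc(c.L);
  for (int l = 0; l < c.L; ++l) {
    ddh[l] = arma::zeros<mat>(H, B);
    ddc[l] = arma::zeros<mat>(H, B);
  }
  mat dhtildeCarry = arma::zeros<mat>(H, B);
  for (int t = Tt - 1; t >= 0; --t) {
    arma::uword c0 = (arma::uword)t * B, c1 = (arma::uword)(t + 1) * B - 1;
    mat htilde = HtildeAll.cols(c0, c1);
    mat dhtilde = DHtildeOut.cols(c0, c1) + dhtildeCarry;
    mat dpre = dhtilde % (1.0 - htilde % htilde);
    DPreAll.cols(c0, c1) = dpre;
    mat dcat = P.m("Wc").t() * dpre;
    mat dctx = dcat.rows(0, encDim - 1);
    mat dhtop = dcat.rows(encDim, encDim + H - 1);
    dhtop += attentionBack(c, P, G, E.encOut, srcLen, att[t], dctx, dEnc);
    mat dx;
    for (int l = c.L - 1; l >= 0; --l) {
      ddh[l] += (l == c.L - 1) ? dhtop : (dx % decDrop[l].cols(c0, c1));
      mat dz = lstmBackZ(P.m(pn("decU", l + 1)), decRun[l].cells[t],
                         ddh[l], ddc[l]);
      DZ[l].cols(c0, c1) = dz;
      dx = P.m(pn("decW", l + 1)).t() * dz;
    }
    for (int b = 0; b < B; ++b)
      G.M["E"].col(din(t, b)) += dx.col(b).rows(0, c.d - 1);
    if (c.feed) dhtildeCarry = dx.rows(c.d, c.d + H - 1);
  }
  G.M["Wc"] += DPreAll * CatAll.t();
  G.V["bc"] += arma::sum(DPreAll, 1);
  std::vector<mat> ddec_h0(c.L), ddec_c0(c.L);
  for (int l = 0; l < c.L; ++l) {
    mat Hprev(H, (arma::uword)B * Tt);
    for (int t = 0; t < Tt; ++t)
      Hprev.cols((arma::uword)t * B, (arma::uword)(t + 1) * B - 1) =
        decRun[l].cells[t].hprev;
    G.M[pn("decW", l + 1)] += DZ[l] * decXall[l].t();
    G.M[pn("decU", l + 1)] += DZ[l] * Hprev.t();
    G.V[pn("decb", l + 1)] += arma::sum(DZ[l], 1);
    ddec_h0[l] = ddh[l];
    ddec_c0[l] = ddc[l];
  }

  // bridge backward
  std::vector<mat> dhF(c.L), dcF(c.L), dhB(c.L), dcB(c.L);
  for (int l = 0; l < c.L; ++l) {
    mat dpreh = ddec_h0[l] % (1.0 - E.h0[l] % E.h0[l]);
    G.M[pn("brh", l + 1)] += dpreh * E.hcat[l].t();
    mat dhcat = P.m(pn("brh", l + 1)).t() * dpreh;
    mat ccat = (c.dirs == 2)
      ? arma::join_cols(E.runF[l].cFinal, E.runB[l].cFinal)
      : E.runF[l].cFinal;
    mat dprec = ddec_c0[l] % (1.0 - E.c0[l] % E.c0[l]);
    G.M[pn("brc", l + 1)] += dprec * ccat.t();
    mat dccat = P.m(pn("brc", l + 1)).t() * dprec;
    dhF[l] = dhcat.rows(0, H - 1);
    dcF[l] = dccat.rows(0, H - 1);
    if (c.dirs == 2) {
      dhB[l] = dhcat.rows(H, 2 * H - 1);
      dcB[l] = dccat.rows(H, 2 * H - 1);
    }
  }

  // encoder backward, top layer down
  std::vector<mat> dOut(Ts);
  for (int t = 0; t < Ts; ++t) dOut[t] = dEnc.slice(t);
  for (int l = c.L - 1; l >= 0; --l) {
    mat dXall = arma::zeros<mat>(E.Xall[l].n_rows, E.Xall[l].n_cols);
    std::vector<mat> dF(Ts), dBk(Ts);
    for (int t = 0; t < Ts; ++t) {
      dF[t] = dOut[t].rows(0, H - 1);
      if (c.dirs == 2) dBk[t] = dOut[t].rows(H, 2 * H - 1);
    }
    backLSTM(P.m(pn("encW", l + 1, 'f')), P.m(pn("encU", l + 1, 'f')),
             E.runF[l], E.Xall[l], dF, dhF[l], dcF[l], false, B,
             G.M[pn("encW", l + 1, 'f')], G.M[pn("encU", l + 1, 'f')],
             G.V[pn("encb", l + 1, 'f')], dXall);
    if (c.dirs == 2)
      backLSTM(P.m(pn("encW", l + 1, 'b')), P.m(pn("encU", l + 1, 'b')),
               E.runB[l], E.Xall[l], dBk, dhB[l], dcB[l], true, B,
               G.M[pn("encW", l + 1, 'b')], G.M[pn("encU", l + 1, 'b')],
               G.V[pn("encb", l + 1, 'b')], dXall);
    if (l > 0) {
      dXall %= E.dropMask[l - 1];
      for (int t = 0; t < Ts; ++t)
        dOut[t] =
          dXall.cols((arma::uword)t * B, (arma::uword)(t + 1) * B - 1);
    } else {
      for (int t = 0; t < Ts; ++t)
        for (int b = 0; b < B; ++b)
          G.M["E"].col(src(t, b)) += dXall.col((arma::uword)t * B + b);
    }
  }
  out["grads"] = G.toList();
  return out;
}

// [[Rcpp::export]]
List cppS2SDecode(List params, List cfg, IntegerVector srcR, int maxLen,
                  bool returnAttention) {
  Cfg c = readCfg(cfg);
  Params P = readParams(params);
  std::mt19937 rng(0);
  const int Ts = srcR.size();
  arma::imat src(Ts, 1);
  for (int t = 0; t < Ts; ++t) src(t, 0) = srcR[t];
  arma::ivec srcLen(1);
  srcLen[0] = Ts;
  EncState E;
  encodeForward(c, P, src, srcLen, false, rng, E);
  const int H = c.H;
  mat& Emb = P.m("E");
  std::vector<mat> h(c.L), cc(c.L);
  for (int l = 0; l < c.L; ++l) { h[l] = E.h0[l]; cc[l] = E.c0[l]; }
  std::vector<int> outTokens;
  std::vector<rowvec> attRows;
  rowvec ones1(1, arma::fill::ones);
  Cell scratch;
  mat htildePrev = arma::zeros<mat>(H, 1);
  int prev = ID_SOS;
  for (int step = 0; step < maxLen; ++step) {
    mat x = c.feed ? arma::join_cols(mat(Emb.col(prev)), htildePrev)
                   : mat(Emb.col(prev));
    for (int l = 0; l < c.L; ++l) {
      mat zin = P.m(pn("decW", l + 1)) * x;
      zin.each_col() += P.v(pn("decb", l + 1));
      lstmStepZ(zin, P.m(pn("decU", l + 1)), ones1, h[l], cc[l], scratch);
      if (l + 1 < c.L) x = h[l];
    }
    AttCache ac;
    mat ctx = attention(c, P, E.encOut, srcLen, h[c.L - 1], ac);
    mat cat = arma::join_cols(ctx, h[c.L - 1]);
    mat pre = P.m("Wc") * cat;
    pre.each_col() += P.v("bc");
    mat htilde = arma::tanh(pre);
    htildePrev = htilde;
    vec logits = P.m("Wo") * htilde.col(0) + P.v("bo");
    logits[ID_PAD] = -1e30;
    logits[ID_SOS] = -1e30;
    int best = logits.index_max();
    if (returnAttention) attRows.push_back(ac.alpha.col(0).t());
    if (best == ID_EOS) break;
    outTokens.push_back(best);
    prev = best;
  }
  IntegerVector tok(outTokens.begin(), outTokens.end());
  List out = List::create(_["tokens"] = tok);
  if (returnAttention) {
    NumericMatrix am(attRows.size(), Ts);
    for (size_t i = 0; i < attRows.size(); ++i)
      for (int s = 0; s < Ts; ++s) am(i, s) = attRows[i][s];
    out["attention"] = am;
  }
  return out;
}

// Attention weights and context for one decoder state against a set of
// encoder states; exposed for unit-testing the attention contract.
// [[Rcpp::export]]
List cppAttentionStep(arma::mat encStates, arma::vec h, List params,
                      List cfg, int srcLen) {
  Cfg c = readCfg(cfg);
  Params P = readParams(params);
  const int S = encStates.n_cols;
  arma::cube eo(encStates.n_rows, 1, S);
  for (int s = 0; s < S; ++s) eo.slice(s) = encStates.col(s);
  arma::ivec sl(1);
  sl[0] = srcLen;
  AttCache ac;
  mat ctx = attention(c, P, eo, sl, mat(h), ac);
  return List::create(_["context"] = ctx.col(0),
                      _["weights"] = ac.alpha.col(0));
}
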