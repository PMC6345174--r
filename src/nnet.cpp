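// Batched forward/backward kernels for the record-conditioned LSTM decoder
// and the GRU diagnosis classifier. Layout conventions:
//   - embedding matrix E has V + 1 rows; row 0 is the padding row and is
//     kept at zero (its gradient is zeroed before returning);
//   - token index i (1-based over the vocabulary) uses E row i and output
//     unit i - 1; target index 0 marks a masked (padding) position;
//   - LSTM gate blocks in Wx/Wh/b are ordered [input, forget, output,
//     candidate]; GRU blocks in Wx/Wh/b are [update, reset].
// Losses and gradients are means over unmasked target tokens (LSTM) or
// over rows (GRU), ready for Adam on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// softmax rows in place, returns row-wise log-sum-exp-normalised probs
static mat softmax_rows(mat logits) {
  vec m = max(logits, 1);
  logits.each_col() -= m;
  logits = exp(logits);
  vec s = sum(logits, 1);
  logits.each_col() /= s;
  return logits;
}

// [[Rcpp::export]]
Rcpp::List lstm_grad_cpp(const arma::mat& E, const arma::mat& Wenc,
                         const arma::rowvec& benc, const arma::mat& Wx,
                         const arma::mat& Wh, const arma::rowvec& b,
                         const arma::mat& Wout, const arma::rowvec& bout,
                         const arma::mat& Rmat,
                         const arma::imat& input, const arma::imat& target,
                         const bool wantGrad = true) {
  const uword B = Rmat.n_rows, T = input.n_cols, H = Wenc.n_cols;
  const uword V = Wout.n_cols;

  uword ntok = 0;
  for (uword t = 0; t < T; ++t)
    for (uword bi = 0; bi < B; ++bi)
      if (target(bi, t) > 0) ++ntok;
  if (ntok == 0) Rcpp::stop("no unmasked target tokens");
  const double scale = 1.0 / double(ntok);

  mat enc = tanh(Rmat * Wenc + repmat(benc, B, 1));

  cube I(B, H, T), F(B, H, T), O(B, H, T), G(B, H, T);
  cube C(B, H, T), TC(B, H, T), Hs(B, H, T), DHOUT(B, H, T);
  mat gWout(H, V, fill::zeros);
  rowvec gbout(V, fill::zeros);

  double loss = 0.0;
  mat h = enc, c = enc;
  for (uword t = 0; t < T; ++t) {
    uvec idx(B);
    for (uword bi = 0; bi < B; ++bi) idx(bi) = (uword) input(bi, t);
    mat X = E.rows(idx);
    mat Z = X * Wx + h * Wh;
    Z.each_row() += b;
    mat ig = sigm(Z.cols(0, H - 1));
    mat fg = sigm(Z.cols(H, 2 * H - 1));
    mat og = sigm(Z.cols(2 * H, 3 * H - 1));
    mat gg = tanh(Z.cols(3 * H, 4 * H - 1));
    mat cNew = fg % c + ig % gg;
    mat tc = tanh(cNew);
    mat hNew = og % tc;

    mat logits = hNew * Wout;
    logits.each_row() += bout;
    mat p = softmax_rows(logits);
    mat dlogit = p;
    for (uword bi = 0; bi < B; ++bi) {
      int y = target(bi, t);
      if (y > 0) {
        loss -= std::log(std::max(p(bi, y - 1), 1e-12));
        dlogit(bi, y - 1) -= 1.0;
      } else {
        dlogit.row(bi).zeros();
      }
    }
    if (wantGrad) {
      dlogit *= scale;
      gWout += hNew.t() * dlogit;
      gbout += sum(dlogit, 0);
      DHOUT.slice(t) = dlogit * Wout.t();
      I.slice(t) = ig; F.slice(t) = fg; O.slice(t) = og; G.slice(t) = gg;
      C.slice(t) = cNew; TC.slice(t) = tc; Hs.slice(t) = hNew;
    }
    h = hNew; c = cNew;
  }
  loss *= scale;
  if (!wantGrad)
    return Rcpp::List::create(Rcpp::Named("loss") = loss,
                              Rcpp::Named("ntok") = (double) ntok);

  mat gE(E.n_rows, E.n_cols, fill::zeros);
  mat gWx(Wx.n_rows, Wx.n_cols, fill::zeros);
  mat gWh(Wh.n_rows, Wh.n_cols, fill::zeros);
  rowvec gb(b.n_elem, fill::zeros);

  mat dhNext(B, H, fill::zeros), dcNext(B, H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    mat dh = DHOUT.slice(t) + dhNext;
    const mat& tc = TC.slice(t);
    const mat& og = O.slice(t);
    mat dog = dh % tc;
    mat dc = dcNext + (dh % og) % (1.0 - tc % tc);
    const mat& ig = I.slice(t);
    const mat& fg = F.slice(t);
    const mat& gg = G.slice(t);
    mat cPrev = (t == 0) ? enc : C.slice(t - 1);
    mat hPrev = (t == 0) ? enc : Hs.slice(t - 1);
    mat dig = dc % gg;
    mat dgg = dc % ig;
    mat dfg = dc % cPrev;
    dcNext = dc % fg;

    mat dZ(B, 4 * H);
    dZ.cols(0, H - 1)         = dig % ig % (1.0 - ig);
    dZ.cols(H, 2 * H - 1)     = dfg % fg % (1.0 - fg);
    dZ.cols(2 * H, 3 * H - 1) = dog % og % (1.0 - og);
    dZ.cols(3 * H, 4 * H - 1) = dgg % (1.0 - gg % gg);

    uvec idx(B);
    for (uword bi = 0; bi < B; ++bi) idx(bi) = (uword) input(bi, t);
    mat X = E.rows(idx);
    gWx += X.t() * dZ;
    gWh += hPrev.t() * dZ;
    gb += sum(dZ, 0);
    mat dX = dZ * Wx.t();
    for (uword bi = 0; bi < B; ++bi)
      if (idx(bi) > 0) gE.row(idx(bi)) += dX.row(bi);
    dhNext = dZ * Wh.t();
  }
  mat denc = dhNext + dcNext;            // h0 and c0 both come from enc
  mat dpre = denc % (1.0 - enc % enc);
  mat gWenc = Rmat.t() * dpre;
  rowvec gbenc = sum(dpre, 0);
  gE.row(0).zeros();

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss, Rcpp::Named("ntok") = (double) ntok,
    Rcpp::Named("gE") = gE, Rcpp::Named("gWenc") = gWenc,
    Rcpp::Named("gbenc") = gbenc, Rcpp::Named("gWx") = gWx,
    Rcpp::Named("gWh") = gWh, Rcpp::Named("gb") = gb,
    Rcpp::Named("gWout") = gWout, Rcpp::Named("gbout") = gbout);
}

// [[Rcpp::export]]
Rcpp::List gru_grad_cpp(const arma::mat& E, const arma::mat& Wx,
                        const arma::mat& Wh, const arma::rowvec& b,
                        const arma::mat& Wxn, const arma::mat& Whn,
                        const arma::rowvec& bn, const arma::mat& Wout,
                        const arma::rowvec& bout, const arma::imat& input,
                        const arma::ivec& lastPos, const arma::ivec& label,
                        const bool wantGrad = true) {
  const uword B = input.n_rows, T = input.n_cols, H = Whn.n_rows;
  const uword Cn = Wout.n_cols;
  const double scale = 1.0 / double(B);

  cube Zc(B, H, T), Rc(B, H, T), Nc(B, H, T), Hc(B, H, T), Qc(B, H, T);
  mat h(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    uvec idx(B);
    for (uword bi = 0; bi < B; ++bi) idx(bi) = (uword) input(bi, t);
    mat X = E.rows(idx);
    mat ZR = X * Wx + h * Wh;
    ZR.each_row() += b;
    mat zg = sigm(ZR.cols(0, H - 1));
    mat rg = sigm(ZR.cols(H, 2 * H - 1));
    mat q = h * Whn;
    mat ng = tanh(X * Wxn + rg % q + repmat(bn, B, 1));
    mat hNew = (1.0 - zg) % ng + zg % h;
    Zc.slice(t) = zg; Rc.slice(t) = rg; Nc.slice(t) = ng; Qc.slice(t) = q;
    Hc.slice(t) = hNew;
    h = hNew;
  }

  mat hLast(B, H);
  for (uword bi = 0; bi < B; ++bi)
    hLast.row(bi) = Hc.slice((uword) lastPos(bi) - 1).row(bi);

  mat logits = hLast * Wout;
  logits.each_row() += bout;
  mat p = softmax_rows(logits);
  double loss = 0.0;
  mat dlogit = p;
  for (uword bi = 0; bi < B; ++bi) {
    int y = label(bi);
    loss -= std::log(std::max(p(bi, y - 1), 1e-12));
    dlogit(bi, y - 1) -= 1.0;
  }
  loss *= scale;
  if (!wantGrad)
    return Rcpp::List::create(Rcpp::Named("loss") = loss,
                              Rcpp::Named("pred") = p);
  dlogit *= scale;

  mat gWout = hLast.t() * dlogit;
  rowvec gbout = sum(dlogit, 0);
  mat dhLast = dlogit * Wout.t();

  mat gE(E.n_rows, E.n_cols, fill::zeros);
  mat gWx(Wx.n_rows, Wx.n_cols, fill::zeros);
  mat gWh(Wh.n_rows, Wh.n_cols, fill::zeros);
  rowvec gb(b.n_elem, fill::zeros);
  mat gWxn(Wxn.n_rows, Wxn.n_cols, fill::zeros);
  mat gWhn(Whn.n_rows, Whn.n_cols, fill::zeros);
  rowvec gbn(bn.n_elem, fill::zeros);

  mat dhNext(B, H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    mat dh = dhNext;
    for (uword bi = 0; bi < B; ++bi)
      if ((uword) lastPos(bi) - 1 == t) dh.row(bi) += dhLast.row(bi);
    const mat& zg = Zc.slice(t);
    const mat& rg = Rc.slice(t);
    const mat& ng = Nc.slice(t);
    const mat& q = Qc.slice(t);
    mat hPrev = (t == 0) ? mat(B, H, fill::zeros) : Hc.slice(t - 1);

    mat dz = dh % (hPrev - ng);
    mat dn = dh % (1.0 - zg);
    mat dhPrev = dh % zg;
    mat dnpre = dn % (1.0 - ng % ng);
    mat dq = dnpre % rg;
    mat dr = dnpre % q;
    gWhn += hPrev.t() * dq;
    dhPrev += dq * Whn.t();
    gbn += sum(dnpre, 0);

    mat dZR(B, 2 * H);
    dZR.cols(0, H - 1)     = dz % zg % (1.0 - zg);
    dZR.cols(H, 2 * H - 1) = dr % rg % (1.0 - rg);

    uvec idx(B);
    for (uword bi = 0; bi < B; ++bi) idx(bi) = (uword) input(bi, t);
    mat X = E.rows(idx);
    gWx += X.t() * dZR;
    gWh += hPrev.t() * dZR;
    gb += sum(dZR, 0);
    gWxn += X.t() * dnpre;
    mat dX = dZR * Wx.t() + dnpre * Wxn.t();
    for (uword bi = 0; bi < B; ++bi)
      if (idx(bi) > 0) gE.row(idx(bi)) += dX.row(bi);
    dhNext = dhPrev + dZR * Wh.t();
  }
  gE.row(0).zeros();

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss, Rcpp::Named("pred") = p,
    Rcpp::Named("gE") = gE, Rcpp::Named("gWx") = gWx,
    Rcpp::Named("gWh") = gWh, Rcpp::Named("gb") = gb,
    Rcpp::Named("gWxn") = gWxn, Rcpp::Named("gWhn") = gWhn,
    Rcpp::Named("gbn") = gbn, Rcpp::Named("gWout") = gWout,
    Rcpp::Named("gbout") = gbout);
}

// One decoder step for a batch of partial sequences: given current hidden
// and cell states and the previous token of each row, returns the next
// probabilities and updated states. Used by the greedy / temperature / beam
// decoders on the R side.
// [[Rcpp::export]]
Rcpp::List lstm_step_cpp(const arma::mat& E, const arma::mat& Wx,
                         const arma::mat& Wh, const arma::rowvec& b,
                         const arma::mat& Wout, const arma::rowvec& bout,
                         const arma::ivec& prevToken, const arma::mat& h,
                         const arma::mat& c) {
  const uword B = h.n_rows, H = h.n_cols;
  uvec idx(B);
  for (uword bi = 0; bi < B; ++bi) idx(bi) = (uword) prevToken(bi);
  mat X = E.rows(idx);
  mat Z = X * Wx + h * Wh;
  Z.each_row() += b;
  mat ig = sigm(Z.cols(0, H - 1));
  mat fg = sigm(Z.cols(H, 2 * H - 1));
  mat og = sigm(Z.cols(2 * H, 3 * H - 1));
  mat gg = tanh(Z.cols(3 * H, 4 * H - 1));
  mat cNew = fg % c + ig % gg;
  mat hNew = og % tanh(cNew);
  mat logits = hNew * Wout;
  logits.each_row() += bout;
  return Rcpp::List::create(Rcpp::Named("logits") = logits,
                            Rcpp::Named("h") = hNew,
                            Rcpp::Named("c") = cNew);
}

// GRU forward only: class probabilities for a batch of sequences
// [[Rcpp::export]]
arma::mat gru_forward_cpp(const arma::mat& E, const arma::mat& Wx,
                          const arma::mat& Wh, const arma::rowvec& b,
                          const arma::mat& Wxn, const arma::mat& Whn,
                          const arma::rowvec& bn, const arma::mat& Wout,
                          const arma::rowvec& bout, const arma::imat& input,
                          const arma::ivec& lastPos) {
  const uword B = input.n_rows, T = input.n_cols, H = Whn.n_rows;
  mat h(B, H, fill::zeros), hLast(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    uvec idx(B);
    for (uword bi = 0; bi < B; ++bi) idx(bi) = (uword) input(bi, t);
    mat X = E.rows(idx);
    mat ZR = X * Wx + h * Wh;
    ZR.each_row() += b;
    mat zg = sigm(ZR.cols(0, H - 1));
    mat rg = sigm(ZR.cols(H, 2 * H - 1));
    mat ng = tanh(X * Wxn + rg % (h * Whn) + repmat(bn, B, 1));
    h = (1.0 - zg) % ng + zg % h;
    for (uword bi = 0; bi < B; ++bi)
      if ((uword) lastPos(bi) - 1 == t) hLast.row(bi) = h.row(bi);
  }
  mat logits = hLast * Wout;
  logits.each_row() += bout;
  vec m = max(logits, 1);
  logits.each_col() -= m;
  logits = exp(logits);
  vec s = sum(logits, 1);
  logits.each_col() /= s;
  return logits;
}

// Sequential skipgram-with-negative-sampling updates, word2vec style:
// one SGD update per (center, context) pair with `negatives` draws from
// the unigram^0.75 table, learning rate decaying linearly over all pairs.
// Deterministic: own RNG, single thread.
// [[Rcpp::export]]
arma::mat sgns_train_cpp(arma::ivec centers, arma::ivec contexts,
                         const int V, const int dim,
                         const arma::vec& negCdf, const int negatives,
                         const int epochs, const double lr0,
                         const int seed) {
  const uword n = centers.n_elem;
  std::mt19937 rng((uint32_t) seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  mat Win(V, dim);
  for (uword i = 0; i < (uword) V; ++i)
    for (int j = 0; j < dim; ++j)
      Win(i, j) = (unif(rng) - 0.5) / dim;
  mat Wout(V, dim, fill::zeros);

  std::vector<uword> ord(n);
  for (uword i = 0; i < n; ++i) ord[i] = i;

  const double total = (double) n * epochs;
  double seen = 0.0;
  rowvec dv(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle
    for (uword i = n - 1; i > 0; --i) {
      uword j = (uword) (unif(rng) * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    for (uword t = 0; t < n; ++t) {
      const double lr = lr0 * std::max(1e-4, 1.0 - seen / total);
      seen += 1.0;
      const uword ci = (uword) centers(ord[t]) - 1;
      const uword oi = (uword) contexts(ord[t]) - 1;
      dv.zeros();
      for (int k = 0; k <= negatives; ++k) {
        uword ui;
        double lab;
        if (k == 0) { ui = oi; lab = 1.0; }
        else {
          double u = unif(rng);
          // binary search in the cumulative unigram^0.75 table
          uword lo = 0, hi = (uword) V - 1;
          while (lo < hi) {
            uword mid = (lo + hi) / 2;
            if (negCdf(mid) < u) lo = mid + 1; else hi = mid;
          }
          ui = lo;
          lab = 0.0;
          if (ui == oi) continue;
        }
        double s = dot(Win.row(ci), Wout.row(ui));
        double g = (1.0 / (1.0 + std::exp(-s)) - lab) * lr;
        dv += g * Wout.row(ui);
        Wout.row(ui) -= g * Win.row(ci);
      }
      Win.row(ci) -= dv;
    }
  }
  return Win;
}
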