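// Sequence risk models trained by manual backpropagation.
//
// Implements (1) a transformer encoder over variable-length medical-code
// sequences -- token + positional + time-bucket embeddings, post-LN
// multi-head self-attention blocks, masked mean pooling, static-covariate
// fusion, two-layer sigmoid head -- and (2) an LSTM baseline with the same
// embedding and head structure. Training is Adam on binary cross-entropy
// with early stopping on a validation split. All randomness (init,
// shuffling, dropout) comes from one std::mt19937_64 seeded from R, and
// execution is single-threaded, so training is bit-reproducible for a
// fixed seed on a given platform.
//
// Sequences are processed at their true length (padding stripped on the R
// side), which makes padding invariance exact by construction.

#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LN_EPS = 1e-5;

// ---------------------------------------------------------------------------
// parameter registry

struct ParamSet {
  std::vector<std::string> names;
  std::vector<mat> P, G, M, V;

  int add(const std::string& name, int r, int c) {
    names.push_back(name);
    P.push_back(zeros<mat>(r, c));
    G.push_back(zeros<mat>(r, c));
    M.push_back(zeros<mat>(r, c));
    V.push_back(zeros<mat>(r, c));
    return (int)P.size() - 1;
  }
  void zeroGrad() { for (auto& g : G) g.zeros(); }

  void adamStep(double lr, double scale, long t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8, clip = 5.0;
    double nrm = 0.0;
    for (auto& g : G) nrm += accu(square(g * scale));
    nrm = std::sqrt(nrm);
    double cs = (nrm > clip) ? clip / nrm : 1.0;
    double bc1 = 1.0 - std::pow(b1, (double)t);
    double bc2 = 1.0 - std::pow(b2, (double)t);
    for (size_t k = 0; k < P.size(); ++k) {
      mat g = G[k] * (scale * cs);
      M[k] = b1 * M[k] + (1 - b1) * g;
      V[k] = b2 * V[k] + (1 - b2) * square(g);
      P[k] -= lr * (M[k] / bc1) / (sqrt(V[k] / bc2) + eps);
    }
  }

  Rcpp::List exportWeights() const {
    Rcpp::List out(P.size());
    Rcpp::CharacterVector nm(P.size());
    for (size_t k = 0; k < P.size(); ++k) {
      out[k] = Rcpp::wrap(P[k]);
      nm[k] = names[k];
    }
    out.attr("names") = nm;
    return out;
  }
  void importWeights(const Rcpp::List& w) {
    for (size_t k = 0; k < P.size(); ++k)
      P[k] = Rcpp::as<mat>(w[names[k]]);
  }
};

struct Rng {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  std::normal_distribution<double> norm{0.0, 1.0};
  explicit Rng(uint64_t seed) : eng(seed) {}
  double u() { return unif(eng); }
  double n() { return norm(eng); }
};

static void initXavier(mat& W, Rng& rng) {
  double lim = std::sqrt(6.0 / (W.n_rows + W.n_cols));
  for (uword i = 0; i < W.n_elem; ++i) W(i) = (2 * rng.u() - 1) * lim;
}
static void initNormal(mat& W, Rng& rng, double sd) {
  for (uword i = 0; i < W.n_elem; ++i) W(i) = rng.n() * sd;
}

static rowvec softmaxRow(const rowvec& s) {
  rowvec e = exp(s - s.max());
  return e / accu(e);
}

// Row-wise layer norm forward; stores xhat and istd for backward.
static mat lnForward(const mat& x, const mat& g, const mat& b,
                     mat& xhat, vec& istd) {
  mat y(size(x));
  xhat.set_size(size(x));
  istd.set_size(x.n_rows);
  for (uword i = 0; i < x.n_rows; ++i) {
    double mu = mean(x.row(i));
    double v = accu(square(x.row(i) - mu)) / x.n_cols;
    double is = 1.0 / std::sqrt(v + LN_EPS);
    istd(i) = is;
    xhat.row(i) = (x.row(i) - mu) * is;
    y.row(i) = g % xhat.row(i) + b;
  }
  return y;
}

static mat lnBackward(const mat& dy, const mat& g, const mat& xhat,
                      const vec& istd, mat& dg, mat& db) {
  mat dx(size(dy));
  for (uword i = 0; i < dy.n_rows; ++i) {
    rowvec dxh = dy.row(i) % g;
    dg += dy.row(i) % xhat.row(i);
    db += dy.row(i);
    double m1 = mean(dxh);
    double m2 = mean(dxh % xhat.row(i));
    dx.row(i) = istd(i) * (dxh - m1 - xhat.row(i) * m2);
  }
  return dx;
}

// ---------------------------------------------------------------------------
// transformer

struct Transformer {
  int V, Lmax, d, nh, dh, dff, nb, p, hd, nl;
  double pdrop;
  ParamSet ps;
  // parameter indices
  int iEtok, iEpos, iEtime;
  std::vector<int> iWq, iWk, iWv, iWo, ibq, ibk, ibv, ibo;
  std::vector<int> iW1, ib1, iW2, ib2, ig1, ibe1, ig2, ibe2;
  int iWh1, ibh1, iWh2, ibh2;

  Transformer(int V_, int Lmax_, int d_, int nh_, int nl_, int dff_,
              int nb_, int p_, int hd_, double pdrop_)
      : V(V_), Lmax(Lmax_), d(d_), nh(nh_), dh(d_ / nh_), dff(dff_),
        nb(nb_), p(p_), hd(hd_), nl(nl_), pdrop(pdrop_) {
    iEtok = ps.add("Etok", V, d);
    iEpos = ps.add("Epos", Lmax, d);
    iEtime = ps.add("Etime", nb, d);
    for (int l = 0; l < nl; ++l) {
      std::string s = std::to_string(l + 1);
      iWq.push_back(ps.add("Wq" + s, d, d));
      iWk.push_back(ps.add("Wk" + s, d, d));
      iWv.push_back(ps.add("Wv" + s, d, d));
      iWo.push_back(ps.add("Wo" + s, d, d));
      ibq.push_back(ps.add("bq" + s, 1, d));
      ibk.push_back(ps.add("bk" + s, 1, d));
      ibv.push_back(ps.add("bv" + s, 1, d));
      ibo.push_back(ps.add("bo" + s, 1, d));
      iW1.push_back(ps.add("W1" + s, d, dff));
      ib1.push_back(ps.add("b1" + s, 1, dff));
      iW2.push_back(ps.add("W2" + s, dff, d));
      ib2.push_back(ps.add("b2" + s, 1, d));
      ig1.push_back(ps.add("g1" + s, 1, d));
      ibe1.push_back(ps.add("be1" + s, 1, d));
      ig2.push_back(ps.add("g2" + s, 1, d));
      ibe2.push_back(ps.add("be2" + s, 1, d));
    }
    iWh1 = ps.add("Wh1", d + p, hd);
    ibh1 = ps.add("bh1", 1, hd);
    iWh2 = ps.add("Wh2", hd, 1);
    ibh2 = ps.add("bh2", 1, 1);
  }

  void init(Rng& rng) {
    initNormal(ps.P[iEtok], rng, 0.02);
    initNormal(ps.P[iEpos], rng, 0.02);
    initNormal(ps.P[iEtime], rng, 0.02);
    for (int l = 0; l < nl; ++l) {
      initXavier(ps.P[iWq[l]], rng);
      initXavier(ps.P[iWk[l]], rng);
      initXavier(ps.P[iWv[l]], rng);
      initXavier(ps.P[iWo[l]], rng);
      initXavier(ps.P[iW1[l]], rng);
      initXavier(ps.P[iW2[l]], rng);
      ps.P[ig1[l]].ones();
      ps.P[ig2[l]].ones();
    }
    initXavier(ps.P[iWh1], rng);
    initXavier(ps.P[iWh2], rng);
  }

  // Forward pass for one sample; caches are filled only when training.
  struct Cache {
    mat X0;
    std::vector<mat> Xin, Q, K, Vv, O, A, R1xh, X1, F1pre, F1, F2, R2xh;
    std::vector<vec> R1istd, R2istd;
    std::vector<std::vector<mat>> Pheads;
    std::vector<mat> dropA, dropF;
    mat Xout;
    vec u, z1pre, z1, dropZ;
    double logit = 0.0, prob = 0.5;
    int nr = 0;
  };

  double forward(const ivec& tok, const ivec& buck, const rowvec& statics,
                 Cache& c, bool train, Rng* rng) {
    int nr = (int)tok.n_elem;
    c.nr = nr;
    vec hbar = zeros<vec>(d);
    if (nr > 0) {
      mat X(nr, d);
      for (int t = 0; t < nr; ++t)
        X.row(t) = ps.P[iEtok].row(tok(t)) + ps.P[iEpos].row(t) +
                   ps.P[iEtime].row(buck(t));
      c.X0 = X;
      if (train) {
        c.Xin.resize(nl); c.Q.resize(nl); c.K.resize(nl); c.Vv.resize(nl);
        c.O.resize(nl); c.A.resize(nl); c.R1xh.resize(nl); c.X1.resize(nl);
        c.F1pre.resize(nl); c.F1.resize(nl); c.F2.resize(nl);
        c.R2xh.resize(nl); c.R1istd.resize(nl); c.R2istd.resize(nl);
        c.Pheads.assign(nl, std::vector<mat>(nh));
        c.dropA.resize(nl); c.dropF.resize(nl);
      }
      double scale = 1.0 / std::sqrt((double)dh);
      for (int l = 0; l < nl; ++l) {
        if (train) c.Xin[l] = X;
        mat Q = X * ps.P[iWq[l]];
        Q.each_row() += ps.P[ibq[l]].row(0);
        mat K = X * ps.P[iWk[l]];
        K.each_row() += ps.P[ibk[l]].row(0);
        mat Vm = X * ps.P[iWv[l]];
        Vm.each_row() += ps.P[ibv[l]].row(0);
        mat O(nr, d);
        for (int h = 0; h < nh; ++h) {
          span cs(h * dh, (h + 1) * dh - 1);
          mat S = Q.cols(cs) * K.cols(cs).t() * scale;
          mat P(nr, nr);
          for (int i = 0; i < nr; ++i) P.row(i) = softmaxRow(S.row(i));
          O.cols(cs) = P * Vm.cols(cs);
          if (train) c.Pheads[l][h] = P;
        }
        mat A = O * ps.P[iWo[l]];
        A.each_row() += ps.P[ibo[l]].row(0);
        if (train) { c.Q[l] = Q; c.K[l] = K; c.Vv[l] = Vm; c.O[l] = O; }
        if (train && pdrop > 0) {
          mat m(nr, d);
          for (uword i = 0; i < m.n_elem; ++i)
            m(i) = (rng->u() >= pdrop) ? 1.0 / (1.0 - pdrop) : 0.0;
          c.dropA[l] = m;
          A %= m;
        }
        if (train) c.A[l] = A;
        mat xh1; vec is1;
        mat X1 = lnForward(X + A, ps.P[ig1[l]].row(0), ps.P[ibe1[l]].row(0),
                           xh1, is1);
        mat F1pre = X1 * ps.P[iW1[l]];
        F1pre.each_row() += ps.P[ib1[l]].row(0);
        mat F1 = F1pre % conv_to<mat>::from(F1pre > 0);  // ReLU
        mat F2 = F1 * ps.P[iW2[l]];
        F2.each_row() += ps.P[ib2[l]].row(0);
        if (train && pdrop > 0) {
          mat m(nr, d);
          for (uword i = 0; i < m.n_elem; ++i)
            m(i) = (rng->u() >= pdrop) ? 1.0 / (1.0 - pdrop) : 0.0;
          c.dropF[l] = m;
          F2 %= m;
        }
        mat xh2; vec is2;
        mat Xn = lnForward(X1 + F2, ps.P[ig2[l]].row(0),
                           ps.P[ibe2[l]].row(0), xh2, is2);
        if (train) {
          c.R1xh[l] = xh1; c.R1istd[l] = is1; c.X1[l] = X1;
          c.F1pre[l] = F1pre; c.F1[l] = F1; c.F2[l] = F2;
          c.R2xh[l] = xh2; c.R2istd[l] = is2;
        }
        X = Xn;
      }
      c.Xout = X;
      hbar = mean(X, 0).t();
    }
    vec u(d + p);
    u.head(d) = hbar;
    u.tail(p) = statics.t();
    vec z1pre = ps.P[iWh1].t() * u + ps.P[ibh1].row(0).t();
    vec z1 = z1pre % conv_to<vec>::from(z1pre > 0);  // ReLU
    vec z1d = z1;
    if (train && pdrop > 0) {
      c.dropZ.set_size(hd);
      for (int j = 0; j < hd; ++j)
        c.dropZ(j) = (rng->u() >= pdrop) ? 1.0 / (1.0 - pdrop) : 0.0;
      z1d = z1 % c.dropZ;
    }
    double logit = as_scalar(ps.P[iWh2].t() * z1d) + ps.P[ibh2](0, 0);
    c.u = u; c.z1pre = z1pre; c.z1 = z1d;
    c.logit = logit;
    c.prob = 1.0 / (1.0 + std::exp(-logit));
    return c.prob;
  }

  void backward(const ivec& tok, const ivec& buck, const Cache& c,
                double y) {
    double dlogit = c.prob - y;
    ps.G[iWh2] += c.z1 * dlogit;
    ps.G[ibh2](0, 0) += dlogit;
    vec dz1d = ps.P[iWh2].col(0) * dlogit;
    vec dz1 = dz1d;
    if (pdrop > 0 && c.dropZ.n_elem) dz1 %= c.dropZ;
    vec dz1pre = dz1 % conv_to<vec>::from(c.z1pre > 0);
    ps.G[iWh1] += c.u * dz1pre.t();
    ps.G[ibh1] += dz1pre.t();
    vec du = ps.P[iWh1] * dz1pre;
    int nr = c.nr;
    if (nr == 0) return;
    rowvec dhbar = du.head(d).t();
    mat dX = repmat(dhbar / nr, nr, 1);
    double scale = 1.0 / std::sqrt((double)dh);
    for (int l = nl - 1; l >= 0; --l) {
      mat dg2(1, d, fill::zeros), dbe2(1, d, fill::zeros);
      mat dR2 = lnBackward(dX, ps.P[ig2[l]].row(0), c.R2xh[l],
                           c.R2istd[l], dg2, dbe2);
      ps.G[ig2[l]] += dg2;
      ps.G[ibe2[l]] += dbe2;
      mat dF2 = dR2;
      if (pdrop > 0 && c.dropF[l].n_elem) dF2 %= c.dropF[l];
      ps.G[iW2[l]] += c.F1[l].t() * dF2;
      ps.G[ib2[l]] += sum(dF2, 0);
      mat dF1 = dF2 * ps.P[iW2[l]].t();
      dF1 %= conv_to<mat>::from(c.F1pre[l] > 0);
      ps.G[iW1[l]] += c.X1[l].t() * dF1;
      ps.G[ib1[l]] += sum(dF1, 0);
      mat dX1 = dR2 + dF1 * ps.P[iW1[l]].t();
      mat dg1(1, d, fill::zeros), dbe1(1, d, fill::zeros);
      mat dR1 = lnBackward(dX1, ps.P[ig1[l]].row(0), c.R1xh[l],
                           c.R1istd[l], dg1, dbe1);
      ps.G[ig1[l]] += dg1;
      ps.G[ibe1[l]] += dbe1;
      mat dA = dR1;
      if (pdrop > 0 && c.dropA[l].n_elem) dA %= c.dropA[l];
      ps.G[iWo[l]] += c.O[l].t() * dA;
      ps.G[ibo[l]] += sum(dA, 0);
      mat dO = dA * ps.P[iWo[l]].t();
      mat dQ(nr, d, fill::zeros), dK(nr, d, fill::zeros),
          dV(nr, d, fill::zeros);
      for (int h = 0; h < nh; ++h) {
        span cs(h * dh, (h + 1) * dh - 1);
        const mat& P = c.Pheads[l][h];
        mat dOh = dO.cols(cs);
        mat dP = dOh * c.Vv[l].cols(cs).t();
        dV.cols(cs) = P.t() * dOh;
        mat dS(nr, nr);
        for (int i = 0; i < nr; ++i) {
          double rowdot = dot(dP.row(i), P.row(i));
          dS.row(i) = P.row(i) % (dP.row(i) - rowdot);
        }
        dQ.cols(cs) = dS * c.K[l].cols(cs) * scale;
        dK.cols(cs) = dS.t() * c.Q[l].cols(cs) * scale;
      }
      ps.G[iWq[l]] += c.Xin[l].t() * dQ;
      ps.G[ibq[l]] += sum(dQ, 0);
      ps.G[iWk[l]] += c.Xin[l].t() * dK;
      ps.G[ibk[l]] += sum(dK, 0);
      ps.G[iWv[l]] += c.Xin[l].t() * dV;
      ps.G[ibv[l]] += sum(dV, 0);
      dX = dR1 + dQ * ps.P[iWq[l]].t() + dK * ps.P[iWk[l]].t() +
           dV * ps.P[iWv[l]].t();
    }
    for (int t = 0; t < nr; ++t) {
      ps.G[iEtok].row(tok(t)) += dX.row(t);
      ps.G[iEpos].row(t) += dX.row(t);
      ps.G[iEtime].row(buck(t)) += dX.row(t);
    }
  }
};

static double bceLoss(double p, double y) {
  const double e = 1e-12;
  return -(y * std::log(p + e) + (1 - y) * std::log(1 - p + e));
}

struct SeqData {
  std::vector<ivec> tok, buck;
  mat statics;
};

static SeqData unpackSeqs(const Rcpp::List& tokens,
                          const Rcpp::List& buckets,
                          const Rcpp::NumericMatrix& statics) {
  SeqData dat;
  int n = tokens.size();
  dat.tok.resize(n);
  dat.buck.resize(n);
  for (int i = 0; i < n; ++i) {
    dat.tok[i] = Rcpp::as<ivec>(tokens[i]);
    dat.buck[i] = Rcpp::as<ivec>(buckets[i]);
  }
  dat.statics = Rcpp::as<mat>(statics);
  return dat;
}

// [[Rcpp::export]]
Rcpp::List cpp_transformer_train(Rcpp::List tokens, Rcpp::List buckets,
                                 Rcpp::NumericMatrix statics,
                                 Rcpp::NumericVector y,
                                 Rcpp::IntegerVector trainIdx,
                                 Rcpp::IntegerVector valIdx,
                                 Rcpp::List dims, Rcpp::List hyper,
                                 int seed) {
  SeqData dat = unpackSeqs(tokens, buckets, statics);
  int V = dims["vocab_size"], Lmax = dims["max_len"], d = dims["embed_dim"],
      nh = dims["n_heads"], nl = dims["n_layers"], dff = dims["ff_dim"],
      nb = dims["n_buckets"], hd = dims["head_dim"];
  int p = dat.statics.n_cols;
  double lr = hyper["learning_rate"], pdrop = hyper["dropout"];
  int bs = hyper["batch_size"], epochs = hyper["epochs"],
      patience = hyper["patience"];

  Transformer net(V, Lmax, d, nh, nl, dff, nb, p, hd, pdrop);
  Rng rng((uint64_t)seed + 0x9E3779B97F4A7C15ULL);
  net.init(rng);

  std::vector<int> tr(trainIdx.begin(), trainIdx.end());
  std::vector<int> va(valIdx.begin(), valIdx.end());
  std::vector<double> trainLoss, valLoss;
  std::vector<mat> best;
  double bestVal = datum::inf;
  int wait = 0;
  long step = 0;
  bool nanFlag = false;

  auto evalLoss = [&](const std::vector<int>& idx) {
    double s = 0;
    Transformer::Cache c;
    for (int i : idx) {
      double pr = net.forward(dat.tok[i], dat.buck[i], dat.statics.row(i),
                              c, false, nullptr);
      s += bceLoss(pr, y[i]);
    }
    return idx.empty() ? datum::nan : s / idx.size();
  };

  for (int ep = 0; ep < epochs && !nanFlag; ++ep) {
    std::shuffle(tr.begin(), tr.end(), rng.eng);
    double epLoss = 0;
    int nSeen = 0;
    for (size_t start = 0; start < tr.size(); start += bs) {
      size_t stop = std::min(start + (size_t)bs, tr.size());
      net.ps.zeroGrad();
      double bl = 0;
      for (size_t k = start; k < stop; ++k) {
        int i = tr[k];
        Transformer::Cache c;
        double pr = net.forward(dat.tok[i], dat.buck[i],
                                dat.statics.row(i), c, true, &rng);
        bl += bceLoss(pr, y[i]);
        net.backward(dat.tok[i], dat.buck[i], c, y[i]);
      }
      int bn = (int)(stop - start);
      if (!std::isfinite(bl)) { nanFlag = true; break; }
      net.ps.adamStep(lr, 1.0 / bn, ++step);
      epLoss += bl;
      nSeen += bn;
    }
    if (nanFlag) break;
    trainLoss.push_back(epLoss / std::max(nSeen, 1));
    double vl = evalLoss(va);
    valLoss.push_back(vl);
    if (std::isnan(vl)) { nanFlag = true; break; }
    if (vl < bestVal - 1e-6) {
      bestVal = vl;
      best = net.ps.P;
      wait = 0;
    } else if (++wait > patience) {
      break;
    }
  }
  if (!best.empty()) net.ps.P = best;

  return Rcpp::List::create(
      Rcpp::Named("weights") = net.ps.exportWeights(),
      Rcpp::Named("train_loss") = trainLoss,
      Rcpp::Named("val_loss") = valLoss,
      Rcpp::Named("nan") = nanFlag);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_transformer_predict(Rcpp::List weights,
                                            Rcpp::List dims,
                                            Rcpp::List tokens,
                                            Rcpp::List buckets,
                                            Rcpp::NumericMatrix statics) {
  SeqData dat = unpackSeqs(tokens, buckets, statics);
  int V = dims["vocab_size"], Lmax = dims["max_len"], d = dims["embed_dim"],
      nh = dims["n_heads"], nl = dims["n_layers"], dff = dims["ff_dim"],
      nb = dims["n_buckets"], hd = dims["head_dim"];
  Transformer net(V, Lmax, d, nh, nl, dff, nb, dat.statics.n_cols, hd, 0.0);
  net.ps.importWeights(weights);
  int n = dat.tok.size();
  Rcpp::NumericVector out(n);
  Transformer::Cache c;
  for (int i = 0; i < n; ++i)
    out[i] = net.forward(dat.tok[i], dat.buck[i], dat.statics.row(i), c,
                         false, nullptr);
  return out;
}

// Finite-difference aid: loss and gradient of a tiny batch at the current
// initialisation, used by the test suite to verify the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_transformer_gradcheck(Rcpp::List tokens, Rcpp::List buckets,
                                     Rcpp::NumericMatrix statics,
                                     Rcpp::NumericVector y,
                                     Rcpp::List dims, int seed,
                                     std::string paramName, int elem,
                                     double delta) {
  SeqData dat = unpackSeqs(tokens, buckets, statics);
  int V = dims["vocab_size"], Lmax = dims["max_len"], d = dims["embed_dim"],
      nh = dims["n_heads"], nl = dims["n_layers"], dff = dims["ff_dim"],
      nb = dims["n_buckets"], hd = dims["head_dim"];
  Transformer net(V, Lmax, d, nh, nl, dff, nb, dat.statics.n_cols, hd, 0.0);
  Rng rng((uint64_t)seed + 0x9E3779B97F4A7C15ULL);
  net.init(rng);
  int n = dat.tok.size();

  auto totalLoss = [&]() {
    double s = 0;
    Transformer::Cache c;
    for (int i = 0; i < n; ++i) {
      double pr = net.forward(dat.tok[i], dat.buck[i], dat.statics.row(i),
                              c, false, nullptr);
      s += bceLoss(pr, y[i]);
    }
    return s;
  };

  net.ps.zeroGrad();
  for (int i = 0; i < n; ++i) {
    Transformer::Cache c;
    net.forward(dat.tok[i], dat.buck[i], dat.statics.row(i), c, true,
                nullptr);
    net.backward(dat.tok[i], dat.buck[i], c, y[i]);
  }
  int k = -1;
  for (size_t j = 0; j < net.ps.names.size(); ++j)
    if (net.ps.names[j] == paramName) k = (int)j;
  if (k < 0) Rcpp::stop("unknown parameter name");
  double analytic = net.ps.G[k](elem);
  double orig = net.ps.P[k](elem);
  net.ps.P[k](elem) = orig + delta;
  double lp = totalLoss();
  net.ps.P[k](elem) = orig - delta;
  double lm = totalLoss();
  net.ps.P[k](elem) = orig;
  return Rcpp::List::create(
      Rcpp::Named("analytic") = analytic,
      Rcpp::Named("numeric") = (lp - lm) / (2 * delta));
}

// ---------------------------------------------------------------------------
// LSTM baseline

struct Lstm {
  int V, d, h, nb, p, hd;
  double pdrop;
  ParamSet ps;
  int iEtok, iEtime, iWx, iWh, ib, iWh1, ibh1, iWh2, ibh2;

  Lstm(int V_, int d_, int h_, int nb_, int p_, int hd_, double pdrop_)
      : V(V_), d(d_), h(h_), nb(nb_), p(p_), hd(hd_), pdrop(pdrop_) {
    iEtok = ps.add("Etok", V, d);
    iEtime = ps.add("Etime", nb, d);
    iWx = ps.add("Wx", d, 4 * h);
    iWh = ps.add("Wh", h, 4 * h);
    ib = ps.add("b", 1, 4 * h);
    iWh1 = ps.add("Wh1", h + p, hd);
    ibh1 = ps.add("bh1", 1, hd);
    iWh2 = ps.add("Wh2", hd, 1);
    ibh2 = ps.add("bh2", 1, 1);
  }
  void init(Rng& rng) {
    initNormal(ps.P[iEtok], rng, 0.02);
    initNormal(ps.P[iEtime], rng, 0.02);
    initXavier(ps.P[iWx], rng);
    initXavier(ps.P[iWh], rng);
    // forget-gate bias 1 stabilises early training
    ps.P[ib].cols(h, 2 * h - 1).fill(1.0);
    initXavier(ps.P[iWh1], rng);
    initXavier(ps.P[iWh2], rng);
  }

  struct Cache {
    std::vector<vec> x, ig, fg, gg, og, cc, tc, hh;
    vec u, z1pre, z1, dropZ;
    double logit = 0, prob = 0.5;
    int nr = 0;
  };

  static double sig(double z) { return 1.0 / (1.0 + std::exp(-z)); }

  double forward(const ivec& tok, const ivec& buck, const rowvec& statics,
                 Cache& c, bool train, Rng* rng) {
    int nr = (int)tok.n_elem;
    c.nr = nr;
    vec hprev = zeros<vec>(h), cprev = zeros<vec>(h);
    if (train) {
      c.x.assign(nr, vec());
      c.ig = c.fg = c.gg = c.og = c.cc = c.tc = c.hh = c.x;
    }
    for (int t = 0; t < nr; ++t) {
      vec x = (ps.P[iEtok].row(tok(t)) + ps.P[iEtime].row(buck(t))).t();
      vec z = ps.P[iWx].t() * x + ps.P[iWh].t() * hprev +
              ps.P[ib].row(0).t();
      vec i(h), f(h), g(h), o(h);
      for (int j = 0; j < h; ++j) {
        i(j) = sig(z(j));
        f(j) = sig(z(h + j));
        g(j) = std::tanh(z(2 * h + j));
        o(j) = sig(z(3 * h + j));
      }
      vec cnew = f % cprev + i % g;
      vec tc = tanh(cnew);
      vec hnew = o % tc;
      if (train) {
        c.x[t] = x; c.ig[t] = i; c.fg[t] = f; c.gg[t] = g; c.og[t] = o;
        c.cc[t] = cnew; c.tc[t] = tc; c.hh[t] = hnew;
      }
      hprev = hnew;
      cprev = cnew;
    }
    vec u(h + p);
    u.head(h) = hprev;
    u.tail(p) = statics.t();
    vec z1pre = ps.P[iWh1].t() * u + ps.P[ibh1].row(0).t();
    vec z1 = z1pre % conv_to<vec>::from(z1pre > 0);  // ReLU
    vec z1d = z1;
    if (train && pdrop > 0) {
      c.dropZ.set_size(hd);
      for (int j = 0; j < hd; ++j)
        c.dropZ(j) = (rng->u() >= pdrop) ? 1.0 / (1.0 - pdrop) : 0.0;
      z1d = z1 % c.dropZ;
    }
    c.u = u; c.z1pre = z1pre; c.z1 = z1d;
    c.logit = as_scalar(ps.P[iWh2].t() * z1d) + ps.P[ibh2](0, 0);
    c.prob = 1.0 / (1.0 + std::exp(-c.logit));
    return c.prob;
  }

  void backward(const ivec& tok, const ivec& buck, const Cache& c,
                double y) {
    double dlogit = c.prob - y;
    ps.G[iWh2] += c.z1 * dlogit;
    ps.G[ibh2](0, 0) += dlogit;
    vec dz1d = ps.P[iWh2].col(0) * dlogit;
    if (pdrop > 0 && c.dropZ.n_elem) dz1d %= c.dropZ;
    vec dz1pre = dz1d % conv_to<vec>::from(c.z1pre > 0);
    ps.G[iWh1] += c.u * dz1pre.t();
    ps.G[ibh1] += dz1pre.t();
    vec du = ps.P[iWh1] * dz1pre;
    int nr = c.nr;
    if (nr == 0) return;
    vec dh = du.head(h);
    vec dc = zeros<vec>(h);
    for (int t = nr - 1; t >= 0; --t) {
      vec cprev = (t > 0) ? c.cc[t - 1] : zeros<vec>(h);
      vec hprev = (t > 0) ? c.hh[t - 1] : zeros<vec>(h);
      vec do_ = dh % c.tc[t];
      dc += dh % c.og[t] % (1 - square(c.tc[t]));
      vec di = dc % c.gg[t];
      vec df = dc % cprev;
      vec dg = dc % c.ig[t];
      vec dz(4 * h);
      dz.subvec(0, h - 1) = di % c.ig[t] % (1 - c.ig[t]);
      dz.subvec(h, 2 * h - 1) = df % c.fg[t] % (1 - c.fg[t]);
      dz.subvec(2 * h, 3 * h - 1) = dg % (1 - square(c.gg[t]));
      dz.subvec(3 * h, 4 * h - 1) = do_ % c.og[t] % (1 - c.og[t]);
      ps.G[iWx] += c.x[t] * dz.t();
      ps.G[iWh] += hprev * dz.t();
      ps.G[ib] += dz.t();
      vec dx = ps.P[iWx] * dz;
      ps.G[iEtok].row(tok(t)) += dx.t();
      ps.G[iEtime].row(buck(t)) += dx.t();
      dh = ps.P[iWh] * dz;
      dc = dc % c.fg[t];
    }
  }
};

// [[Rcpp::export]]
Rcpp::List cpp_lstm_train(Rcpp::List tokens, Rcpp::List buckets,
                          Rcpp::NumericMatrix statics,
                          Rcpp::NumericVector y,
                          Rcpp::IntegerVector trainIdx,
                          Rcpp::IntegerVector valIdx,
                          Rcpp::List dims, Rcpp::List hyper, int seed) {
  SeqData dat = unpackSeqs(tokens, buckets, statics);
  int V = dims["vocab_size"], d = dims["embed_dim"], h = dims["hidden_dim"],
      nb = dims["n_buckets"], hd = dims["head_dim"];
  double lr = hyper["learning_rate"], pdrop = hyper["dropout"];
  int bs = hyper["batch_size"], epochs = hyper["epochs"],
      patience = hyper["patience"];
  Lstm net(V, d, h, nb, dat.statics.n_cols, hd, pdrop);
  Rng rng((uint64_t)seed + 0x51ED2701ULL);
  net.init(rng);

  std::vector<int> tr(trainIdx.begin(), trainIdx.end());
  std::vector<int> va(valIdx.begin(), valIdx.end());
  std::vector<double> trainLoss, valLoss;
  std::vector<mat> best;
  double bestVal = datum::inf;
  int wait = 0;
  long step = 0;
  bool nanFlag = false;

  for (int ep = 0; ep < epochs && !nanFlag; ++ep) {
    std::shuffle(tr.begin(), tr.end(), rng.eng);
    double epLoss = 0;
    int nSeen = 0;
    for (size_t start = 0; start < tr.size(); start += bs) {
      size_t stop = std::min(start + (size_t)bs, tr.size());
      net.ps.zeroGrad();
      double bl = 0;
      for (size_t k = start; k < stop; ++k) {
        int i = tr[k];
        Lstm::Cache c;
        double pr = net.forward(dat.tok[i], dat.buck[i],
                                dat.statics.row(i), c, true, &rng);
        bl += bceLoss(pr, y[i]);
        net.backward(dat.tok[i], dat.buck[i], c, y[i]);
      }
      int bn = (int)(stop - start);
      if (!std::isfinite(bl)) { nanFlag = true; break; }
      net.ps.adamStep(lr, 1.0 / bn, ++step);
      epLoss += bl;
      nSeen += bn;
    }
    if (nanFlag) break;
    trainLoss.push_back(epLoss / std::max(nSeen, 1));
    double vl = 0;
    Lstm::Cache c;
    for (int i : va)
      vl += bceLoss(net.forward(dat.tok[i], dat.buck[i],
                                dat.statics.row(i), c, false, nullptr),
                    y[i]);
    vl = va.empty() ? datum::nan : vl / va.size();
    valLoss.push_back(vl);
    if (std::isnan(vl)) { nanFlag = true; break; }
    if (vl < bestVal - 1e-6) {
      bestVal = vl;
      best = net.ps.P;
      wait = 0;
    } else if (++wait > patience) {
      break;
    }
  }
  if (!best.empty()) net.ps.P = best;
  return Rcpp::List::create(
      Rcpp::Named("weights") = net.ps.exportWeights(),
      Rcpp::Named("train_loss") = trainLoss,
      Rcpp::Named("val_loss") = valLoss,
      Rcpp::Named("nan") = nanFlag);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_lstm_predict(Rcpp::List weights, Rcpp::List dims,
                                     Rcpp::List tokens, Rcpp::List buckets,
                                     Rcpp::NumericMatrix statics) {
  SeqData dat = unpackSeqs(tokens, buckets, statics);
  int V = dims["vocab_size"], d = dims["embed_dim"], h = dims["hidden_dim"],
      nb = dims["n_buckets"], hd = dims["head_dim"];
  Lstm net(V, d, h, nb, dat.statics.n_cols, hd, 0.0);
  net.ps.importWeights(weights);
  int n = dat.tok.size();
  Rcpp::NumericVector out(n);
  Lstm::Cache c;
  for (int i = 0; i < n; ++i)
    out[i] = net.forward(dat.tok[i], dat.buck[i], dat.statics.row(i), c,
                         false, nullptr);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_gradcheck(Rcpp::List tokens, Rcpp::List buckets,
                              Rcpp::NumericMatrix statics,
                              Rcpp::NumericVector y, Rcpp::List dims,
                              int seed, std::string paramName, int elem,
                              double delta) {
  SeqData dat = unpackSeqs(tokens, buckets, statics);
  int V = dims["vocab_size"], d = dims["embed_dim"], h = dims["hidden_dim"],
      nb = dims["n_buckets"], hd = dims["head_dim"];
  Lstm net(V, d, h, nb, dat.statics.n_cols, hd, 0.0);
  Rng rng((uint64_t)seed + 0x51ED2701ULL);
  net.init(rng);
  int n = dat.tok.size();
  auto totalLoss = [&]() {
    double s = 0;
    Lstm::Cache c;
    for (int i = 0; i < n; ++i)
      s += bceLoss(net.forward(dat.tok[i], dat.buck[i],
                               dat.statics.row(i), c, false, nullptr),
                   y[i]);
    return s;
  };
  net.ps.zeroGrad();
  for (int i = 0; i < n; ++i) {
    Lstm::Cache c;
    net.forward(dat.tok[i], dat.buck[i], dat.statics.row(i), c, true,
                nullptr);
    net.backward(dat.tok[i], dat.buck[i], c, y[i]);
  }
  int k = -1;
  for (size_t j = 0; j < net.ps.names.size(); ++j)
    if (net.ps.names[j] == paramName) k = (int)j;
  if (k < 0) Rcpp::stop("unknown parameter name");
  double analytic = net.ps.G[k](elem);
  double orig = net.ps.P[k](elem);
  net.ps.P[k](elem) = orig + delta;
  double lp = totalLoss();
  net.ps.P[k](elem) = orig - delta;
  double lm = totalLoss();
  net.ps.P[k](elem) = orig;
  return Rcpp::List::create(Rcpp::Named("analytic") = analytic,
                            Rcpp::Named("numeric") = (lp - lm) / (2 * delta));
}
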