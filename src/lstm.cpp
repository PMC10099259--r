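// Sequence-to-sequence LSTM regressor: stacked LSTM+FC blocks with a linear
// regression head, trained with Adam on masked mean-squared error over
// padded minibatches. Parameters are exchanged with R as a named list of
// matrices so fitted models serialize as plain R objects.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// Parameter layout, in order, for widths w_1..w_K (input n_in, output n_out):
//   per block k: Wx (in x 4w), Wh (w x 4w), b (1 x 4w), fcW (w x w), fcb (1 x w)
//   head: W (w_K x n_out), b (1 x n_out)
// Gate column order within the 4w blocks: input, forget, cell, output.

static std::vector<mat> params_from_list(const Rcpp::List& plist) {
  std::vector<mat> P;
  P.reserve(plist.size());
  for (int i = 0; i < plist.size(); ++i)
    P.push_back(Rcpp::as<mat>(plist[i]));
  return P;
}

static Rcpp::List params_to_list(const std::vector<mat>& P,
                                 const std::vector<std::string>& nm) {
  Rcpp::List out(P.size());
  for (size_t i = 0; i < P.size(); ++i) out[i] = Rcpp::wrap(P[i]);
  out.attr("names") = Rcpp::wrap(nm);
  return out;
}

static std::vector<std::string> param_names(const ivec& widths) {
  std::vector<std::string> nm;
  for (uword k = 0; k < widths.n_elem; ++k) {
    std::string p = "l" + std::to_string(k + 1) + "_";
    nm.push_back(p + "Wx"); nm.push_back(p + "Wh"); nm.push_back(p + "b");
    nm.push_back(p + "fcW"); nm.push_back(p + "fcb");
  }
  nm.push_back("head_W"); nm.push_back("head_b");
  return nm;
}

// [[Rcpp::export]]
Rcpp::List lstm_init(Rcpp::IntegerVector widths_r, int n_in, int n_out,
                     int seed) {
  ivec widths = Rcpp::as<ivec>(widths_r);
  std::mt19937 gen(static_cast<uint32_t>(seed));
  auto uni = [&](double s) {
    std::uniform_real_distribution<double> d(-s, s);
    return [&gen, d]() mutable { return d(gen); };
  };
  auto fill_mat = [&](uword r, uword c, double s) {
    mat M(r, c);
    std::uniform_real_distribution<double> d(-s, s);
    // column-major fill so layout matches R's
    for (uword j = 0; j < c; ++j)
      for (uword i = 0; i < r; ++i) M(i, j) = d(gen);
    return M;
  };
  (void)uni;
  std::vector<mat> P;
  int in = n_in;
  for (uword k = 0; k < widths.n_elem; ++k) {
    int h = widths[k];
    double s = 1.0 / std::sqrt((double)h);
    P.push_back(fill_mat(in, 4 * h, s));
    P.push_back(fill_mat(h, 4 * h, s));
    mat b = fill_mat(1, 4 * h, s);
    b.cols(h, 2 * h - 1) += 1.0;  // forget-gate bias offset
    P.push_back(b);
    double sf = 1.0 / std::sqrt((double)h);
    P.push_back(fill_mat(h, h, sf));
    P.push_back(fill_mat(1, h, sf));
    in = h;
  }
  double sh = 1.0 / std::sqrt((double)in);
  P.push_back(fill_mat(in, n_out, sh));
  P.push_back(fill_mat(1, n_out, sh));
  return params_to_list(P, param_names(widths));
}

struct LstmCache {
  std::vector<mat> x, gi, gf, gg, go, c, tc;  // per timestep, B x dim
};

struct FcCache { std::vector<mat> x; };

// Forward pass over a padded batch; xs[t] is B x features. Caches are only
// populated when `keep` is true (training); inference skips them.
static std::vector<mat> net_forward(const std::vector<mat>& P,
                                    const ivec& widths,
                                    const std::vector<mat>& xs,
                                    std::vector<LstmCache>* lcache,
                                    std::vector<FcCache>* fcache,
                                    bool keep) {
  size_t T = xs.size();
  uword B = xs[0].n_rows;
  std::vector<mat> cur = xs;
  size_t pi = 0;
  for (uword k = 0; k < widths.n_elem; ++k) {
    int h = widths[k];
    const mat& Wx = P[pi]; const mat& Wh = P[pi + 1]; const mat& b = P[pi + 2];
    const mat& fW = P[pi + 3]; const mat& fb = P[pi + 4];
    pi += 5;
    LstmCache LC;
    mat hprev(B, h, fill::zeros), cprev(B, h, fill::zeros);
    std::vector<mat> hs(T);
    for (size_t t = 0; t < T; ++t) {
      mat Z = cur[t] * Wx + hprev * Wh;
      Z.each_row() += b;
      mat gi = sigm(Z.cols(0, h - 1));
      mat gf = sigm(Z.cols(h, 2 * h - 1));
      mat gg = tanh(Z.cols(2 * h, 3 * h - 1));
      mat go = sigm(Z.cols(3 * h, 4 * h - 1));
      mat c = gf % cprev + gi % gg;
      mat tc = tanh(c);
      mat hh = go % tc;
      if (keep) {
        LC.x.push_back(cur[t]); LC.gi.push_back(gi); LC.gf.push_back(gf);
        LC.gg.push_back(gg); LC.go.push_back(go); LC.c.push_back(c);
        LC.tc.push_back(tc);
      }
      hprev = hh; cprev = c;
      hs[t] = hh;
    }
    if (keep) lcache->push_back(std::move(LC));
    FcCache FC;
    for (size_t t = 0; t < T; ++t) {
      if (keep) FC.x.push_back(hs[t]);
      hs[t] = hs[t] * fW;
      hs[t].each_row() += fb;
    }
    if (keep) fcache->push_back(std::move(FC));
    cur = std::move(hs);
  }
  const mat& hW = P[pi]; const mat& hb = P[pi + 1];
  if (keep) {
    FcCache FC;
    FC.x = cur;
    fcache->push_back(std::move(FC));
  }
  for (size_t t = 0; t < T; ++t) {
    cur[t] = cur[t] * hW;
    cur[t].each_row() += hb;
  }
  return cur;
}

// Backward pass; dys[t] is B x n_out loss gradient. Returns grads in the
// same layout as P.
static std::vector<mat> net_backward(const std::vector<mat>& P,
                                     const ivec& widths,
                                     const std::vector<LstmCache>& lcache,
                                     const std::vector<FcCache>& fcache,
                                     std::vector<mat> dys) {
  size_t T = dys.size();
  uword B = dys[0].n_rows;
  std::vector<mat> G(P.size());
  for (size_t i = 0; i < P.size(); ++i) G[i] = zeros<mat>(size(P[i]));
  size_t K = widths.n_elem;
  // head
  size_t hp = 5 * K;
  const mat& hW = P[hp];
  const FcCache& HC = fcache[K];
  for (size_t t = 0; t < T; ++t) {
    G[hp] += HC.x[t].t() * dys[t];
    G[hp + 1] += sum(dys[t], 0);
    dys[t] = dys[t] * hW.t();
  }
  for (int k = (int)K - 1; k >= 0; --k) {
    int h = widths[k];
    size_t pi = 5 * k;
    const mat& Wx = P[pi]; const mat& Wh = P[pi + 1];
    const mat& fW = P[pi + 3];
    const LstmCache& LC = lcache[k];
    const FcCache& FC = fcache[k];
    // FC block
    for (size_t t = 0; t < T; ++t) {
      G[pi + 3] += FC.x[t].t() * dys[t];
      G[pi + 4] += sum(dys[t], 0);
      dys[t] = dys[t] * fW.t();
    }
    // LSTM block (BPTT)
    mat dh_next(B, h, fill::zeros), dc_next(B, h, fill::zeros);
    std::vector<mat> dxs(T);
    for (int t = (int)T - 1; t >= 0; --t) {
      mat dh = dys[t] + dh_next;
      const mat& gi = LC.gi[t]; const mat& gf = LC.gf[t];
      const mat& gg = LC.gg[t]; const mat& go = LC.go[t];
      const mat& tc = LC.tc[t];
      mat dc = dc_next + dh % go % (1.0 - tc % tc);
      mat dgo = dh % tc;
      mat dgi = dc % gg;
      mat dgg = dc % gi;
      mat cprev = (t > 0) ? LC.c[t - 1] : mat(B, h, fill::zeros);
      mat dgf = dc % cprev;
      dc_next = dc % gf;
      mat dZ(B, 4 * h);
      dZ.cols(0, h - 1) = dgi % gi % (1.0 - gi);
      dZ.cols(h, 2 * h - 1) = dgf % gf % (1.0 - gf);
      dZ.cols(2 * h, 3 * h - 1) = dgg % (1.0 - gg % gg);
      dZ.cols(3 * h, 4 * h - 1) = dgo % go % (1.0 - go);
      G[pi] += LC.x[t].t() * dZ;
      mat hprev = (t > 0) ? mat(LC.go[t - 1] % LC.tc[t - 1])
                          : mat(B, h, fill::zeros);
      G[pi + 1] += hprev.t() * dZ;
      G[pi + 2] += sum(dZ, 0);
      dxs[t] = dZ * Wx.t();
      dh_next = dZ * Wh.t();
    }
    dys = std::move(dxs);
  }
  return G;
}

// Pack a set of sequences (T_i x F matrices) into per-timestep B x F slices
// padded with zeros, plus a T x B validity mask.
static void pack_batch(const std::vector<mat>& seqs,
                       const std::vector<int>& idx,
                       int F, std::vector<mat>& xs, umat& mask) {
  size_t B = idx.size();
  size_t T = 0;
  for (size_t b = 0; b < B; ++b) T = std::max(T, (size_t)seqs[idx[b]].n_rows);
  xs.assign(T, zeros<mat>(B, F));
  mask = zeros<umat>(T, B);
  for (size_t b = 0; b < B; ++b) {
    const mat& s = seqs[idx[b]];
    for (uword t = 0; t < s.n_rows; ++t) {
      xs[t].row(b) = s.row(t);
      mask(t, b) = 1;
    }
  }
}

// Masked MSE (mean over valid positions x channels) and its gradient.
static double masked_mse(const std::vector<mat>& pred,
                         const std::vector<mat>& ys, const umat& mask,
                         std::vector<mat>* dys) {
  size_t T = pred.size();
  double denom = 3.0 * accu(mask);
  double loss = 0.0;
  if (dys) dys->assign(T, zeros<mat>(size(pred[0])));
  for (size_t t = 0; t < T; ++t) {
    mat d = pred[t] - ys[t];
    vec m = conv_to<vec>::from(mask.row(t).t());
    d.each_col() %= m;
    loss += accu(d % d);
    if (dys) (*dys)[t] = (2.0 / denom) * d;
  }
  return loss / denom;
}

static double batch_loss(const std::vector<mat>& P, const ivec& widths,
                         const std::vector<mat>& X, const std::vector<mat>& Y,
                         const std::vector<int>& idx) {
  std::vector<mat> xs, ys;
  umat mask;
  pack_batch(X, idx, X[0].n_cols, xs, mask);
  pack_batch(Y, idx, Y[0].n_cols, ys, mask);
  std::vector<mat> pred = net_forward(P, widths, xs, nullptr, nullptr, false);
  return masked_mse(pred, ys, mask, nullptr);
}

// [[Rcpp::export]]
double lstm_loss(Rcpp::List params, Rcpp::IntegerVector widths_r,
                 Rcpp::List Xlist, Rcpp::List Ylist) {
  std::vector<mat> P = params_from_list(params);
  ivec widths = Rcpp::as<ivec>(widths_r);
  std::vector<mat> X, Y;
  for (int i = 0; i < Xlist.size(); ++i) {
    X.push_back(Rcpp::as<mat>(Xlist[i]));
    Y.push_back(Rcpp::as<mat>(Ylist[i]));
  }
  std::vector<int> idx(X.size());
  for (size_t i = 0; i < X.size(); ++i) idx[i] = (int)i;
  return batch_loss(P, widths, X, Y, idx);
}

// [[Rcpp::export]]
Rcpp::List lstm_grad(Rcpp::List params, Rcpp::IntegerVector widths_r,
                     Rcpp::List Xlist, Rcpp::List Ylist) {
  std::vector<mat> P = params_from_list(params);
  ivec widths = Rcpp::as<ivec>(widths_r);
  std::vector<mat> X, Y;
  for (int i = 0; i < Xlist.size(); ++i) {
    X.push_back(Rcpp::as<mat>(Xlist[i]));
    Y.push_back(Rcpp::as<mat>(Ylist[i]));
  }
  std::vector<int> idx(X.size());
  for (size_t i = 0; i < X.size(); ++i) idx[i] = (int)i;
  std::vector<mat> xs, ys;
  umat mask;
  pack_batch(X, idx, X[0].n_cols, xs, mask);
  pack_batch(Y, idx, Y[0].n_cols, ys, mask);
  std::vector<LstmCache> lc;
  std::vector<FcCache> fc;
  std::vector<mat> pred = net_forward(P, widths, xs, &lc, &fc, true);
  std::vector<mat> dys;
  masked_mse(pred, ys, mask, &dys);
  std::vector<mat> G = net_backward(P, widths, lc, fc, dys);
  return params_to_list(G, param_names(widths));
}

// [[Rcpp::export]]
arma::mat lstm_forward_one(Rcpp::List params, Rcpp::IntegerVector widths_r,
                           arma::mat X) {
  std::vector<mat> P = params_from_list(params);
  ivec widths = Rcpp::as<ivec>(widths_r);
  std::vector<mat> xs(X.n_rows);
  for (uword t = 0; t < X.n_rows; ++t) xs[t] = X.row(t);
  std::vector<mat> pred = net_forward(P, widths, xs, nullptr, nullptr, false);
  mat out(X.n_rows, pred[0].n_cols);
  for (uword t = 0; t < X.n_rows; ++t) out.row(t) = pred[t];
  return out;
}

// [[Rcpp::export]]
Rcpp::List lstm_forward_batch(Rcpp::List params, Rcpp::IntegerVector widths_r,
                              Rcpp::List Xlist) {
  std::vector<mat> P = params_from_list(params);
  ivec widths = Rcpp::as<ivec>(widths_r);
  std::vector<mat> X;
  for (int i = 0; i < Xlist.size(); ++i) X.push_back(Rcpp::as<mat>(Xlist[i]));
  std::vector<int> idx(X.size());
  for (size_t i = 0; i < X.size(); ++i) idx[i] = (int)i;
  std::vector<mat> xs;
  umat mask;
  pack_batch(X, idx, X[0].n_cols, xs, mask);
  std::vector<mat> pred = net_forward(P, widths, xs, nullptr, nullptr, false);
  Rcpp::List out(X.size());
  for (size_t b = 0; b < X.size(); ++b) {
    mat o(X[b].n_rows, pred[0].n_cols);
    for (uword t = 0; t < X[b].n_rows; ++t) o.row(t) = pred[t].row(b);
    out[b] = Rcpp::wrap(o);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List lstm_train(Rcpp::List params, Rcpp::IntegerVector widths_r,
                      Rcpp::List Xlist, Rcpp::List Ylist,
                      Rcpp::List Xval, Rcpp::List Yval,
                      int epochs, double lr, int batch_size, int seed,
                      double clip_norm, bool track_best) {
  std::vector<mat> P = params_from_list(params);
  ivec widths = Rcpp::as<ivec>(widths_r);
  std::vector<mat> X, Y, Xv, Yv;
  for (int i = 0; i < Xlist.size(); ++i) {
    X.push_back(Rcpp::as<mat>(Xlist[i]));
    Y.push_back(Rcpp::as<mat>(Ylist[i]));
  }
  for (int i = 0; i < Xval.size(); ++i) {
    Xv.push_back(Rcpp::as<mat>(Xval[i]));
    Yv.push_back(Rcpp::as<mat>(Yval[i]));
  }
  size_t N = X.size();
  bool has_val = !Xv.empty();
  std::vector<int> val_idx(Xv.size());
  for (size_t i = 0; i < Xv.size(); ++i) val_idx[i] = (int)i;

  std::vector<mat> M(P.size()), V(P.size());
  for (size_t i = 0; i < P.size(); ++i) {
    M[i] = zeros<mat>(size(P[i]));
    V[i] = zeros<mat>(size(P[i]));
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::mt19937 gen(static_cast<uint32_t>(seed));
  std::vector<int> order(N);
  for (size_t i = 0; i < N; ++i) order[i] = (int)i;

  std::vector<double> hist_train, hist_val;
  std::vector<mat> bestP = P;
  double best_val = datum::inf;
  int best_epoch = 0;

  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), gen);
    double epoch_loss = 0.0, epoch_w = 0.0;
    for (size_t start = 0; start < N; start += batch_size) {
      size_t end = std::min(N, start + (size_t)batch_size);
      std::vector<int> idx(order.begin() + start, order.begin() + end);
      std::vector<mat> xs, ys;
      umat mask;
      pack_batch(X, idx, X[0].n_cols, xs, mask);
      pack_batch(Y, idx, Y[0].n_cols, ys, mask);
      std::vector<LstmCache> lc;
      std::vector<FcCache> fc;
      std::vector<mat> pred = net_forward(P, widths, xs, &lc, &fc, true);
      std::vector<mat> dys;
      double loss = masked_mse(pred, ys, mask, &dys);
      double w = accu(mask);
      epoch_loss += loss * w;
      epoch_w += w;
      std::vector<mat> G = net_backward(P, widths, lc, fc, dys);
      if (clip_norm > 0) {
        double nrm2 = 0.0;
        for (auto& g : G) nrm2 += accu(g % g);
        double nrm = std::sqrt(nrm2);
        if (nrm > clip_norm)
          for (auto& g : G) g *= clip_norm / nrm;
      }
      ++step;
      double corr = lr * std::sqrt(1.0 - std::pow(b2, (double)step)) /
                    (1.0 - std::pow(b1, (double)step));
      for (size_t i = 0; i < P.size(); ++i) {
        M[i] = b1 * M[i] + (1.0 - b1) * G[i];
        V[i] = b2 * V[i] + (1.0 - b2) * (G[i] % G[i]);
        P[i] -= corr * M[i] / (sqrt(V[i]) + eps);
      }
    }
    hist_train.push_back(epoch_loss / epoch_w);
    if (has_val) {
      double vl = batch_loss(P, widths, Xv, Yv, val_idx);
      hist_val.push_back(vl);
      if (track_best && vl < best_val) {
        best_val = vl;
        bestP = P;
        best_epoch = e + 1;
      }
    }
    if ((e + 1) % 25 == 0) Rcpp::checkUserInterrupt();
  }
  std::vector<std::string> nm = param_names(widths);
  return Rcpp::List::create(
      Rcpp::Named("params") = params_to_list(P, nm),
      Rcpp::Named("best_params") =
          (track_best && best_epoch > 0) ? params_to_list(bestP, nm)
                                         : params_to_list(P, nm),
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("train_loss") = hist_train,
      Rcpp::Named("val_loss") = hist_val);
}
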