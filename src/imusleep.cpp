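// Core numerics: a small bidirectional GRU sequence classifier (forward,
// backprop-through-time, full-batch Adam) and a zero-phase cascaded-biquad
// filter. Sequences of equal length are processed as one batch so each
// timestep is a matrix-matrix product; whole-night cross-validation then
// trains in seconds. Kept in C++ also so the per-epoch band-pass stays
// cheap enough to run thousands of times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct GruDims {
  int input, hidden, layers, classes;
};

static int layer_input(const GruDims &d, int l) {
  return l == 0 ? d.input : 2 * d.hidden;
}

struct GruParams {
  // index (l * 2 + dir): W is 3H x I, U is 3H x H, b is 3H (gate order z, r, n)
  std::vector<arma::mat> W, U;
  std::vector<arma::vec> b;
  arma::mat Wo; // classes x 2H
  arma::vec bo; // classes
};

static int n_params(const GruDims &d) {
  int n = 0;
  for (int l = 0; l < d.layers; ++l)
    n += 2 * (3 * d.hidden * layer_input(d, l) + 3 * d.hidden * d.hidden + 3 * d.hidden);
  n += d.classes * 2 * d.hidden + d.classes;
  return n;
}

static GruParams unflatten(const arma::vec &p, const GruDims &d) {
  GruParams v;
  int off = 0, H = d.hidden;
  for (int l = 0; l < d.layers; ++l) {
    for (int dir = 0; dir < 2; ++dir) {
      int I = layer_input(d, l);
      v.W.push_back(arma::reshape(p.subvec(off, off + 3 * H * I - 1), 3 * H, I));
      off += 3 * H * I;
      v.U.push_back(arma::reshape(p.subvec(off, off + 3 * H * H - 1), 3 * H, H));
      off += 3 * H * H;
      v.b.push_back(p.subvec(off, off + 3 * H - 1));
      off += 3 * H;
    }
  }
  v.Wo = arma::reshape(p.subvec(off, off + d.classes * 2 * H - 1), d.classes, 2 * H);
  off += d.classes * 2 * H;
  v.bo = p.subvec(off, off + d.classes - 1);
  return v;
}

static arma::vec flatten(const GruParams &v, const GruDims &d) {
  arma::vec p(n_params(d));
  int off = 0;
  for (size_t i = 0; i < v.W.size(); ++i) {
    p.subvec(off, off + v.W[i].n_elem - 1) = arma::vectorise(v.W[i]);
    off += v.W[i].n_elem;
    p.subvec(off, off + v.U[i].n_elem - 1) = arma::vectorise(v.U[i]);
    off += v.U[i].n_elem;
    p.subvec(off, off + v.b[i].n_elem - 1) = v.b[i];
    off += v.b[i].n_elem;
  }
  p.subvec(off, off + v.Wo.n_elem - 1) = arma::vectorise(v.Wo);
  off += v.Wo.n_elem;
  p.subvec(off, off + v.bo.n_elem - 1) = v.bo;
  return p;
}

static GruParams zeros_like(const GruDims &d) {
  GruParams g;
  int H = d.hidden;
  for (int l = 0; l < d.layers; ++l)
    for (int dir = 0; dir < 2; ++dir) {
      int I = layer_input(d, l);
      g.W.push_back(arma::mat(3 * H, I, arma::fill::zeros));
      g.U.push_back(arma::mat(3 * H, H, arma::fill::zeros));
      g.b.push_back(arma::vec(3 * H, arma::fill::zeros));
    }
  g.Wo = arma::mat(d.classes, 2 * H, arma::fill::zeros);
  g.bo = arma::vec(d.classes, arma::fill::zeros);
  return g;
}

// batched caches: cube slices are (B x H) per timestep
struct DirCache {
  arma::cube Hs, Z, R, N, UN;
};

static arma::mat sigm(const arma::mat &x) { return 1.0 / (1.0 + arma::exp(-x)); }

// single-direction GRU over a batch cube X (B x I x T); PyTorch gate form:
//   z = sigm(Wz x + Uz h + bz); r = sigm(Wr x + Ur h + br)
//   n = tanh(Wn x + bn + r .* (Un h)); h' = (1 - z) .* n + z .* h
static void dir_forward(const arma::cube &X, const arma::mat &W, const arma::mat &U,
                        const arma::vec &b, DirCache &c) {
  int B = X.n_rows, T = X.n_slices, H = U.n_cols;
  c.Hs.set_size(B, H, T); c.Z.set_size(B, H, T); c.R.set_size(B, H, T);
  c.N.set_size(B, H, T); c.UN.set_size(B, H, T);
  arma::mat Wt = W.t(), Ut = U.t();
  arma::mat h(B, H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::mat a = X.slice(t) * Wt; // B x 3H
    a.each_row() += b.t();
    arma::mat uh = h * Ut;
    arma::mat z = sigm(a.cols(0, H - 1) + uh.cols(0, H - 1));
    arma::mat r = sigm(a.cols(H, 2 * H - 1) + uh.cols(H, 2 * H - 1));
    arma::mat un = uh.cols(2 * H, 3 * H - 1);
    arma::mat n = arma::tanh(a.cols(2 * H, 3 * H - 1) + r % un);
    h = (1.0 - z) % n + z % h;
    c.Z.slice(t) = z; c.R.slice(t) = r; c.N.slice(t) = n;
    c.UN.slice(t) = un; c.Hs.slice(t) = h;
  }
}

static void dir_backward(const arma::cube &X, const arma::mat &W, const arma::mat &U,
                         const DirCache &c, const arma::cube &dH,
                         arma::mat &dW, arma::mat &dU, arma::vec &db, arma::cube &dX) {
  int B = X.n_rows, T = X.n_slices, H = U.n_cols;
  dX.set_size(B, X.n_cols, T);
  arma::mat dh(B, H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    dh += dH.slice(t);
    arma::mat hprev = (t == 0) ? arma::mat(B, H, arma::fill::zeros)
                               : arma::mat(c.Hs.slice(t - 1));
    const arma::mat &z = c.Z.slice(t), &r = c.R.slice(t), &n = c.N.slice(t),
                    &un = c.UN.slice(t);
    arma::mat dn = dh % (1.0 - z);
    arma::mat dz = dh % (hprev - n);
    arma::mat dhprev = dh % z;
    arma::mat dan = dn % (1.0 - n % n);
    arma::mat daz = dz % z % (1.0 - z);
    arma::mat dar = (dan % un) % r % (1.0 - r);
    arma::mat danr = dan % r;
    arma::mat DA = arma::join_rows(daz, dar, dan);   // B x 3H, for W/b/x paths
    arma::mat DU = arma::join_rows(daz, dar, danr);  // B x 3H, for U/h paths
    dW += DA.t() * X.slice(t);
    db += arma::sum(DA, 0).t();
    dU += DU.t() * hprev;
    dhprev += DU * U;
    dX.slice(t) = DA * W;
    dh = dhprev;
  }
}

struct BatchCache {
  std::vector<arma::cube> layer_in; // input to each layer (+ final hidden)
  std::vector<DirCache> fwd, bwd;
  arma::cube P; // B x classes x T
};

static arma::cube reverse_time(const arma::cube &X) {
  arma::cube Y(X.n_rows, X.n_cols, X.n_slices);
  for (arma::uword t = 0; t < X.n_slices; ++t) Y.slice(t) = X.slice(X.n_slices - 1 - t);
  return Y;
}

// forward pass over a batch of equal-length sequences
static void batch_forward(const arma::cube &X, const GruParams &v, const GruDims &d,
                          BatchCache &c) {
  int B = X.n_rows, T = X.n_slices, H = d.hidden;
  arma::cube cur = X;
  c.layer_in.clear();
  c.fwd.assign(d.layers, DirCache());
  c.bwd.assign(d.layers, DirCache());
  for (int l = 0; l < d.layers; ++l) {
    c.layer_in.push_back(cur);
    dir_forward(cur, v.W[l * 2], v.U[l * 2], v.b[l * 2], c.fwd[l]);
    arma::cube Xr = reverse_time(cur);
    dir_forward(Xr, v.W[l * 2 + 1], v.U[l * 2 + 1], v.b[l * 2 + 1], c.bwd[l]);
    arma::cube nxt(B, 2 * H, T);
    for (int t = 0; t < T; ++t) {
      nxt.slice(t) = arma::join_rows(c.fwd[l].Hs.slice(t),
                                     c.bwd[l].Hs.slice(T - 1 - t));
    }
    cur = nxt;
  }
  c.layer_in.push_back(cur);
  c.P.set_size(B, d.classes, T);
  arma::mat Wot = v.Wo.t();
  for (int t = 0; t < T; ++t) {
    arma::mat logits = cur.slice(t) * Wot; // B x classes
    logits.each_row() += v.bo.t();
    logits.each_col() -= arma::max(logits, 1);
    arma::mat e = arma::exp(logits);
    e.each_col() /= arma::sum(e, 1);
    c.P.slice(t) = e;
  }
}

// group sequences by length so each group forms one batch cube
struct SeqGroup {
  int T;
  std::vector<int> idx;
  arma::cube X;       // B x I x T
  arma::imat y;       // B x T (may be empty for predict)
};

static std::vector<SeqGroup> make_groups(const std::vector<arma::mat> &Xs,
                                         const std::vector<arma::ivec> &ys,
                                         bool with_labels) {
  std::map<int, std::vector<int>> by_len;
  for (size_t i = 0; i < Xs.size(); ++i) by_len[Xs[i].n_rows].push_back(i);
  std::vector<SeqGroup> groups;
  for (auto &kv : by_len) {
    SeqGroup g;
    g.T = kv.first;
    g.idx = kv.second;
    int B = g.idx.size(), I = Xs[g.idx[0]].n_cols;
    g.X.set_size(B, I, g.T);
    if (with_labels) g.y.set_size(B, g.T);
    for (int b = 0; b < B; ++b) {
      const arma::mat &S = Xs[g.idx[b]];
      for (int t = 0; t < g.T; ++t) g.X.subcube(b, 0, t, b, I - 1, t) = S.row(t);
      if (with_labels)
        for (int t = 0; t < g.T; ++t) g.y(b, t) = ys[g.idx[b]](t);
    }
    groups.push_back(std::move(g));
  }
  return groups;
}

// weighted mean cross-entropy (+ gradient) over groups of sequences
static double groups_loss_grad(const arma::vec &params,
                               const std::vector<SeqGroup> &groups,
                               const GruDims &d, const arma::vec &class_w,
                               arma::vec *grad_out) {
  GruParams v = unflatten(params, d);
  GruParams g = zeros_like(d);
  double wtot = 0.0;
  for (const auto &gr : groups)
    for (arma::uword i = 0; i < gr.y.n_elem; ++i) wtot += class_w(gr.y(i));
  double loss = 0.0;
  for (const auto &gr : groups) {
    BatchCache c;
    batch_forward(gr.X, v, d, c);
    int B = gr.X.n_rows, T = gr.T, H = d.hidden;
    arma::cube dH;
    if (grad_out) dH.zeros(B, 2 * H, T);
    for (int t = 0; t < T; ++t) {
      arma::mat dlogits(B, d.classes, arma::fill::zeros);
      for (int b = 0; b < B; ++b) {
        int y = gr.y(b, t);
        double w = class_w(y);
        loss += -w * std::log(std::max(c.P(b, y, t), 1e-12));
        if (grad_out) {
          for (int k = 0; k < d.classes; ++k)
            dlogits(b, k) = w * (c.P(b, k, t) - (k == y ? 1.0 : 0.0)) / wtot;
        }
      }
      if (grad_out) {
        const arma::mat &Hl = c.layer_in[d.layers].slice(t);
        g.Wo += dlogits.t() * Hl;
        g.bo += arma::sum(dlogits, 0).t();
        dH.slice(t) = dlogits * v.Wo;
      }
    }
    if (!grad_out) continue;
    arma::cube dcur = dH;
    for (int l = d.layers - 1; l >= 0; --l) {
      arma::cube dHf(B, H, T), dHb(B, H, T);
      for (int t = 0; t < T; ++t) {
        dHf.slice(t) = dcur.slice(t).cols(0, H - 1);
        dHb.slice(t) = dcur.slice(T - 1 - t).cols(H, 2 * H - 1);
      }
      arma::cube dXf, dXb;
      dir_backward(c.layer_in[l], v.W[l * 2], v.U[l * 2], c.fwd[l], dHf,
                   g.W[l * 2], g.U[l * 2], g.b[l * 2], dXf);
      arma::cube Xr = reverse_time(c.layer_in[l]);
      dir_backward(Xr, v.W[l * 2 + 1], v.U[l * 2 + 1], c.bwd[l], dHb,
                   g.W[l * 2 + 1], g.U[l * 2 + 1], g.b[l * 2 + 1], dXb);
      arma::cube nxt(B, dXf.n_cols, T);
      for (int t = 0; t < T; ++t)
        nxt.slice(t) = dXf.slice(t) + dXb.slice(T - 1 - t);
      dcur = nxt;
    }
  }
  if (grad_out) *grad_out = flatten(g, d);
  return loss / wtot;
}

static void as_batch(const List &Xl, const List &yl,
                     std::vector<arma::mat> &Xs, std::vector<arma::ivec> &ys) {
  for (int i = 0; i < Xl.size(); ++i) {
    Xs.push_back(as<arma::mat>(Xl[i]));
    IntegerVector y = yl[i];
    arma::ivec yv(y.size());
    for (int j = 0; j < y.size(); ++j) yv(j) = y[j];
    ys.push_back(yv);
  }
}

// [[Rcpp::export]]
arma::mat cpp_gru_predict(const arma::vec &params, const arma::mat &X,
                          int input, int hidden, int layers, int classes) {
  GruDims d{input, hidden, layers, classes};
  GruParams v = unflatten(params, d);
  int T = X.n_rows;
  arma::cube Xc(1, X.n_cols, T);
  for (int t = 0; t < T; ++t) Xc.subcube(0, 0, t, 0, X.n_cols - 1, t) = X.row(t);
  BatchCache c;
  batch_forward(Xc, v, d, c);
  arma::mat P(T, classes);
  for (int t = 0; t < T; ++t) P.row(t) = c.P.slice(t).row(0);
  return P;
}

// [[Rcpp::export]]
List cpp_gru_loss_grad(const arma::vec &params, List X, List y,
                       int input, int hidden, int layers, int classes,
                       const arma::vec &class_w, bool with_grad) {
  GruDims d{input, hidden, layers, classes};
  std::vector<arma::mat> Xs; std::vector<arma::ivec> ys;
  as_batch(X, y, Xs, ys);
  std::vector<SeqGroup> groups = make_groups(Xs, ys, true);
  arma::vec grad;
  double loss = groups_loss_grad(params, groups, d, class_w, with_grad ? &grad : nullptr);
  if (with_grad) return List::create(_["loss"] = loss, _["grad"] = grad);
  return List::create(_["loss"] = loss);
}

// [[Rcpp::export]]
arma::vec cpp_gru_init(int input, int hidden, int layers, int classes, int seed) {
  GruDims d{input, hidden, layers, classes};
  std::mt19937 rng(static_cast<unsigned int>(seed));
  double k = 1.0 / std::sqrt((double)hidden);
  std::uniform_real_distribution<double> unif(-k, k);
  arma::vec p(n_params(d));
  for (arma::uword i = 0; i < p.n_elem; ++i) p(i) = unif(rng);
  return p;
}

// [[Rcpp::export]]
List cpp_gru_train(const arma::vec &params0, List Xtrain, List ytrain,
                   List Xval, List yval,
                   int input, int hidden, int layers, int classes,
                   const arma::vec &class_w, double lr, int max_iter, int patience) {
  GruDims d{input, hidden, layers, classes};
  std::vector<arma::mat> Xs, Xv; std::vector<arma::ivec> ys, yv;
  as_batch(Xtrain, ytrain, Xs, ys);
  as_batch(Xval, yval, Xv, yv);
  std::vector<SeqGroup> gtrain = make_groups(Xs, ys, true);
  std::vector<SeqGroup> gval = make_groups(Xv, yv, true);
  bool has_val = !gval.empty();

  arma::vec p = params0;
  arma::vec m(p.n_elem, arma::fill::zeros), v2(p.n_elem, arma::fill::zeros);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  arma::vec best_p = p;
  double best_score = std::numeric_limits<double>::infinity();
  int best_iter = 0, since_best = 0;
  std::vector<double> tr_trace, val_trace;

  for (int it = 1; it <= max_iter; ++it) {
    arma::vec grad;
    double tr_loss = groups_loss_grad(p, gtrain, d, class_w, &grad);
    tr_trace.push_back(tr_loss);
    m = b1 * m + (1 - b1) * grad;
    v2 = b2 * v2 + (1 - b2) * arma::square(grad);
    arma::vec mhat = m / (1 - std::pow(b1, it));
    arma::vec vhat = v2 / (1 - std::pow(b2, it));
    p -= lr * mhat / (arma::sqrt(vhat) + eps);

    double score;
    if (has_val) {
      score = groups_loss_grad(p, gval, d, class_w, nullptr);
      val_trace.push_back(score);
    } else {
      score = groups_loss_grad(p, gtrain, d, class_w, nullptr);
    }
    if (score < best_score - 1e-9) {
      best_score = score; best_p = p; best_iter = it; since_best = 0;
    } else if (++since_best >= patience && has_val) {
      break;
    }
  }
  return List::create(_["params"] = best_p,
                      _["best_iter"] = best_iter,
                      _["best_score"] = best_score,
                      _["train_loss"] = tr_trace,
                      _["val_loss"] = val_trace);
}

// forward-backward (zero-phase) filtering through a cascade of biquads.
// sos: K x 6 rows (b0 b1 b2 a0 a1 a2) with a0 == 1. Odd-reflection padding
// of `padlen` samples at both ends limits start-up transients.
static void sos_forward(arma::vec &x, const arma::mat &sos) {
  for (arma::uword k = 0; k < sos.n_rows; ++k) {
    double b0 = sos(k, 0), b1 = sos(k, 1), b2 = sos(k, 2);
    double a1 = sos(k, 4), a2 = sos(k, 5);
    double z1 = 0.0, z2 = 0.0;
    for (arma::uword i = 0; i < x.n_elem; ++i) {
      double xi = x(i);
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      x(i) = yi;
    }
  }
}

// [[Rcpp::export]]
arma::vec cpp_sosfiltfilt(const arma::vec &x, const arma::mat &sos, int padlen) {
  int n = x.n_elem;
  if (padlen >= n) padlen = n - 1;
  arma::vec ext(n + 2 * padlen);
  for (int i = 0; i < padlen; ++i) ext(i) = 2.0 * x(0) - x(padlen - i);
  ext.subvec(padlen, padlen + n - 1) = x;
  for (int i = 0; i < padlen; ++i) ext(padlen + n + i) = 2.0 * x(n - 1) - x(n - 2 - i);
  sos_forward(ext, sos);
  ext = arma::reverse(ext);
  sos_forward(ext, sos);
  ext = arma::reverse(ext);
  return ext.subvec(padlen, padlen + n - 1);
}
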