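// Single-layer unidirectional LSTM with a per-timestep linear readout,
// trained by Adam on mean squared error over all output steps.
// Gate block order in the stacked weight matrices: input, forget, cell, output.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Params {
  mat Wx, Wh, Wy;  // 4H x D, 4H x H, 1 x H
  vec b;           // 4H
  double by;
};

static Params params_from_list(const Rcpp::List& p) {
  Params w;
  w.Wx = Rcpp::as<mat>(p["Wx"]);
  w.Wh = Rcpp::as<mat>(p["Wh"]);
  w.Wy = Rcpp::as<mat>(p["Wy"]);
  w.b  = Rcpp::as<vec>(p["b"]);
  w.by = Rcpp::as<double>(p["by"]);
  return w;
}

static Rcpp::List params_to_list(const Params& w) {
  return Rcpp::List::create(Rcpp::Named("Wx") = w.Wx,
                            Rcpp::Named("Wh") = w.Wh,
                            Rcpp::Named("Wy") = w.Wy,
                            Rcpp::Named("b") = w.b,
                            Rcpp::Named("by") = w.by);
}

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// Forward pass for a batch. X: cube T x D x B. Returns Y (T x B) and,
// if keep, caches gate activations for backprop.
struct Cache {
  std::vector<mat> i, f, g, o, c, tc, h;  // each H x B, length T
  mat Y;                                  // T x B
};

static void forward(const Params& w, const cube& X, Cache& cc, bool keep) {
  const uword T = X.n_rows, D = X.n_cols, B = X.n_slices;
  const uword H = w.Wh.n_cols;
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  cc.Y.set_size(T, B);
  if (keep) {
    cc.i.resize(T); cc.f.resize(T); cc.g.resize(T); cc.o.resize(T);
    cc.c.resize(T); cc.tc.resize(T); cc.h.resize(T);
  }
  mat Xt(D, B);
  for (uword t = 0; t < T; ++t) {
    for (uword bidx = 0; bidx < B; ++bidx)
      Xt.col(bidx) = X.slice(bidx).row(t).t();
    mat z = w.Wx * Xt + w.Wh * h;
    z.each_col() += w.b;
    mat ig = sigm(z.rows(0, H - 1));
    mat fg = sigm(z.rows(H, 2 * H - 1));
    mat gg = tanh(z.rows(2 * H, 3 * H - 1));
    mat og = sigm(z.rows(3 * H, 4 * H - 1));
    c = fg % c + ig % gg;
    mat tc = tanh(c);
    h = og % tc;
    cc.Y.row(t) = w.Wy * h + w.by;
    if (keep) {
      cc.i[t] = ig; cc.f[t] = fg; cc.g[t] = gg; cc.o[t] = og;
      cc.c[t] = c; cc.tc[t] = tc; cc.h[t] = h;
    }
  }
}

struct Grads {
  mat Wx, Wh, Wy;
  vec b;
  double by;
  void zeros_like(const Params& w) {
    Wx.zeros(size(w.Wx)); Wh.zeros(size(w.Wh)); Wy.zeros(size(w.Wy));
    b.zeros(w.b.n_elem); by = 0.0;
  }
};

// Backward pass; dY is T x B (dL/dY). Accumulates into gr.
static void backward(const Params& w, const cube& X, const Cache& cc,
                     const mat& dY, Grads& gr) {
  const uword T = X.n_rows, D = X.n_cols, B = X.n_slices;
  const uword H = w.Wh.n_cols;
  mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
  mat Xt(D, B);
  for (uword t = T; t-- > 0;) {
    for (uword bidx = 0; bidx < B; ++bidx)
      Xt.col(bidx) = X.slice(bidx).row(t).t();
    const mat& h = cc.h[t];
    mat dy = dY.row(t);                      // 1 x B
    gr.Wy += dy * h.t();
    gr.by += accu(dy);
    mat dh = w.Wy.t() * dy + dh_next;        // H x B
    mat dc = dc_next + dh % cc.o[t] % (1.0 - square(cc.tc[t]));
    mat do_ = dh % cc.tc[t];
    mat c_prev = (t == 0) ? mat(H, B, fill::zeros) : cc.c[t - 1];
    mat di = dc % cc.g[t];
    mat df = dc % c_prev;
    mat dg = dc % cc.i[t];
    // pre-activation gradients
    mat dzi = di % cc.i[t] % (1.0 - cc.i[t]);
    mat dzf = df % cc.f[t] % (1.0 - cc.f[t]);
    mat dzg = dg % (1.0 - square(cc.g[t]));
    mat dzo = do_ % cc.o[t] % (1.0 - cc.o[t]);
    mat dz = join_cols(dzi, dzf, dzg, dzo);  // 4H x B
    mat h_prev = (t == 0) ? mat(H, B, fill::zeros) : cc.h[t - 1];
    gr.Wx += dz * Xt.t();
    gr.Wh += dz * h_prev.t();
    gr.b += sum(dz, 1);
    dh_next = w.Wh.t() * dz;
    dc_next = dc % cc.f[t];
  }
}

static cube gather(const cube& X, const std::vector<uword>& idx) {
  cube out(X.n_rows, X.n_cols, idx.size());
  for (size_t k = 0; k < idx.size(); ++k) out.slice(k) = X.slice(idx[k]);
  return out;
}

// [[Rcpp::export(name = ".lstm_train_cpp")]]
Rcpp::List lstm_train_cpp(const arma::cube& X, const arma::mat& Y,
                          Rcpp::List init, int epochs, double lr,
                          double beta1, double beta2, double eps,
                          double l2, int batch_size, double clip,
                          int shuffle_seed) {
  Params w = params_from_list(init);
  const uword N = X.n_slices, T = X.n_rows;
  Grads m, v;
  m.zeros_like(w); v.zeros_like(w);
  std::mt19937 rng(static_cast<unsigned>(shuffle_seed));
  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;
  std::vector<double> trace;
  trace.reserve(epochs);
  long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with explicit draws (stable across standard libraries)
    for (uword i = N - 1; i > 0; --i) {
      uword j = rng() % (i + 1);
      std::swap(order[i], order[j]);
    }
    double ep_loss = 0.0;
    uword nb = 0;
    for (uword s = 0; s < N; s += batch_size) {
      uword e = std::min<uword>(s + batch_size, N);
      std::vector<uword> idx(order.begin() + s, order.begin() + e);
      cube Xb = gather(X, idx);
      mat Yb(T, idx.size());
      for (size_t k = 0; k < idx.size(); ++k) Yb.col(k) = Y.col(idx[k]);
      Cache cc;
      forward(w, Xb, cc, true);
      mat err = cc.Y - Yb;
      double loss = accu(square(err)) / err.n_elem;
      if (!std::isfinite(loss))
        Rcpp::stop("training error: non-finite loss at epoch %d", ep + 1);
      ep_loss += loss; ++nb;
      mat dY = 2.0 * err / static_cast<double>(err.n_elem);
      Grads gr; gr.zeros_like(w);
      backward(w, Xb, cc, dY, gr);
      // L2 penalty on weight matrices only
      gr.Wx += l2 * w.Wx; gr.Wh += l2 * w.Wh; gr.Wy += l2 * w.Wy;
      double gn = std::sqrt(accu(square(gr.Wx)) + accu(square(gr.Wh)) +
                            accu(square(gr.Wy)) + accu(square(gr.b)) +
                            gr.by * gr.by);
      if (clip > 0 && gn > clip) {
        double sc = clip / gn;
        gr.Wx *= sc; gr.Wh *= sc; gr.Wy *= sc; gr.b *= sc; gr.by *= sc;
      }
      ++step;
      double bc1 = 1.0 - std::pow(beta1, (double)step);
      double bc2 = 1.0 - std::pow(beta2, (double)step);
      auto adam = [&](mat& p, mat& mm, mat& vv, const mat& g) {
        mm = beta1 * mm + (1 - beta1) * g;
        vv = beta2 * vv + (1 - beta2) * square(g);
        p -= lr * (mm / bc1) / (sqrt(vv / bc2) + eps);
      };
      adam(w.Wx, m.Wx, v.Wx, gr.Wx);
      adam(w.Wh, m.Wh, v.Wh, gr.Wh);
      adam(w.Wy, m.Wy, v.Wy, gr.Wy);
      m.b = beta1 * m.b + (1 - beta1) * gr.b;
      v.b = beta2 * v.b + (1 - beta2) * square(gr.b);
      w.b -= lr * (m.b / bc1) / (sqrt(v.b / bc2) + eps);
      m.by = beta1 * m.by + (1 - beta1) * gr.by;
      v.by = beta2 * v.by + (1 - beta2) * gr.by * gr.by;
      w.by -= lr * (m.by / bc1) / (std::sqrt(v.by / bc2) + eps);
    }
    trace.push_back(ep_loss / nb);
  }
  return Rcpp::List::create(Rcpp::Named("params") = params_to_list(w),
                            Rcpp::Named("loss_trace") = trace);
}

// [[Rcpp::export(name = ".lstm_predict_cpp")]]
arma::mat lstm_predict_cpp(Rcpp::List params, const arma::cube& X) {
  Params w = params_from_list(params);
  Cache cc;
  forward(w, X, cc, false);
  return cc.Y;  // T x N
}
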