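// Stacked BatchNorm/LSTM/Dense character language model over token indices.
// Teacher-forced training with PAD-masked categorical cross-entropy, full
// backpropagation through time, Adam, per-layer freezing, and a single-step
// forward pass used by the beam-search and temperature-sampling decoders.
//
// Conventions:
//  - token ids are 0-based; PAD = 0. A sequence row is START ... END PAD...
//  - input features are one-hot of width `vocab`.
//  - LSTM gate order in the stacked weight matrices is [i; f; g; o].
//  - BatchNorm normalizes each feature over all (batch x time) positions
//    during training (momentum 0.99, eps 1e-3) and uses moving statistics
//    in step (inference) mode.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

const double BN_EPS = 1e-3;
const double BN_MOMENTUM = 0.99;

struct Layer {
  int type;        // 0 = batchnorm, 1 = lstm, 2 = dense
  int in, out;
  vec gamma, beta, rmean, rvar;
  mat W, U;
  vec b;
};

struct Grads {
  vec gamma, beta;
  mat W, U;
  vec b;
};

struct Cache {
  // batchnorm
  cube xhat;
  vec invstd;
  // lstm
  cube X;                 // post-dropout input
  cube I, F, G, O, C, H;  // gates and states; H slice t is h_t (t = 1..T)
  mat h0, c0;
  mat dropmask;
  // dense
  cube A;                 // input to dense
};

int layer_type_code(const std::string& s) {
  if (s == "batchnorm") return 0;
  if (s == "lstm") return 1;
  if (s == "dense") return 2;
  stop("unknown layer type '%s'", s);
  return -1;
}

std::vector<Layer> parse_model(const List& layers, const List& weights, int vocab) {
  int n = layers.size();
  if ((int)weights.size() != n) stop("weights/layer plan length mismatch");
  std::vector<Layer> out(n);
  int d = vocab;
  for (int l = 0; l < n; ++l) {
    List ls = layers[l];
    List ws = weights[l];
    Layer& L = out[l];
    L.type = layer_type_code(as<std::string>(ls["type"]));
    L.in = d;
    if (L.type == 0) {
      L.gamma = as<vec>(ws["gamma"]);
      L.beta = as<vec>(ws["beta"]);
      L.rmean = as<vec>(ws["rmean"]);
      L.rvar = as<vec>(ws["rvar"]);
      if ((int)L.gamma.n_elem != d) stop("batchnorm width mismatch at layer %d", l + 1);
      L.out = d;
    } else if (L.type == 1) {
      L.W = as<mat>(ws["W"]);
      L.U = as<mat>(ws["U"]);
      L.b = as<vec>(ws["b"]);
      int u = L.U.n_cols;
      if ((int)L.W.n_rows != 4 * u || (int)L.W.n_cols != d)
        stop("lstm weight shape mismatch at layer %d", l + 1);
      L.out = u;
    } else {
      L.W = as<mat>(ws["W"]);
      L.b = as<vec>(ws["b"]);
      if ((int)L.W.n_cols != d) stop("dense weight shape mismatch at layer %d", l + 1);
      L.out = L.W.n_rows;
    }
    d = L.out;
  }
  return out;
}

List export_weights(const std::vector<Layer>& model) {
  int n = model.size();
  List out(n);
  for (int l = 0; l < n; ++l) {
    const Layer& L = model[l];
    if (L.type == 0) {
      out[l] = List::create(_["gamma"] = L.gamma, _["beta"] = L.beta,
                            _["rmean"] = L.rmean, _["rvar"] = L.rvar);
    } else if (L.type == 1) {
      out[l] = List::create(_["W"] = L.W, _["U"] = L.U, _["b"] = L.b);
    } else {
      out[l] = List::create(_["W"] = L.W, _["b"] = L.b);
    }
  }
  return out;
}

mat onehot(const imat& Xb, int t, int vocab) {
  int B = Xb.n_rows;
  mat x(B, vocab, fill::zeros);
  for (int i = 0; i < B; ++i) x(i, Xb(i, t)) = 1.0;
  return x;
}

// Forward + (optionally) backward over one batch. Returns summed masked
// negative log-likelihood; `ntok` receives the number of unmasked targets.
// When `grads` is non-null the per-layer gradients of the *mean* per-token
// loss are accumulated there.
double batch_pass(std::vector<Layer>& model, const imat& Xb, int vocab,
                  double dropout, std::mt19937& rng, bool training,
                  std::vector<Grads>* grads, double& ntok) {
  int B = Xb.n_rows;
  int T = Xb.n_cols - 1;  // predict columns 1..T from 0..T-1
  int nl = model.size();
  std::vector<Cache> cache(nl);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // ---- forward ----
  cube A(B, vocab, T);
  for (int t = 0; t < T; ++t) A.slice(t) = onehot(Xb, t, vocab);

  for (int l = 0; l < nl; ++l) {
    Layer& L = model[l];
    Cache& ch = cache[l];
    if (L.type == 0) {
      int f = L.in;
      double N = (double)B * T;
      vec mu(f, fill::zeros), var(f, fill::zeros);
      if (training) {
        for (int t = 0; t < T; ++t) mu += sum(A.slice(t), 0).t();
        mu /= N;
        for (int t = 0; t < T; ++t) {
          mat d = A.slice(t);
          d.each_row() -= mu.t();
          var += sum(square(d), 0).t();
        }
        var /= N;
        L.rmean = BN_MOMENTUM * L.rmean + (1.0 - BN_MOMENTUM) * mu;
        L.rvar = BN_MOMENTUM * L.rvar + (1.0 - BN_MOMENTUM) * var;
      } else {
        mu = L.rmean;
        var = L.rvar;
      }
      ch.invstd = 1.0 / sqrt(var + BN_EPS);
      ch.xhat.set_size(B, f, T);
      for (int t = 0; t < T; ++t) {
        mat xh = A.slice(t);
        xh.each_row() -= mu.t();
        xh.each_row() %= ch.invstd.t();
        ch.xhat.slice(t) = xh;
        xh.each_row() %= L.gamma.t();
        xh.each_row() += L.beta.t();
        A.slice(t) = xh;
      }
    } else if (L.type == 1) {
      int u = L.out, d = L.in;
      ch.dropmask.set_size(B, d);
      if (training && dropout > 0) {
        for (uword i = 0; i < ch.dropmask.n_elem; ++i)
          ch.dropmask(i) = unif(rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
      } else {
        ch.dropmask.ones();
      }
      ch.X.set_size(B, d, T);
      ch.I.set_size(B, u, T); ch.F.set_size(B, u, T); ch.G.set_size(B, u, T);
      ch.O.set_size(B, u, T); ch.C.set_size(B, u, T); ch.H.set_size(B, u, T);
      ch.h0.zeros(B, u);
      ch.c0.zeros(B, u);
      mat h = ch.h0, c = ch.c0;
      cube Anew(B, u, T);
      for (int t = 0; t < T; ++t) {
        mat x = A.slice(t) % ch.dropmask;
        ch.X.slice(t) = x;
        mat z = x * L.W.t() + h * L.U.t();  // B x 4u
        z.each_row() += L.b.t();
        mat zi = z.cols(0, u - 1), zf = z.cols(u, 2 * u - 1),
            zg = z.cols(2 * u, 3 * u - 1), zo = z.cols(3 * u, 4 * u - 1);
        mat gi = 1.0 / (1.0 + exp(-zi));
        mat gf = 1.0 / (1.0 + exp(-zf));
        mat gg = tanh(zg);
        mat go = 1.0 / (1.0 + exp(-zo));
        c = gf % c + gi % gg;
        h = go % tanh(c);
        ch.I.slice(t) = gi; ch.F.slice(t) = gf; ch.G.slice(t) = gg;
        ch.O.slice(t) = go; ch.C.slice(t) = c; ch.H.slice(t) = h;
        Anew.slice(t) = h;
      }
      A = Anew;
    } else {
      ch.A = A;
      cube Anew(B, L.out, T);
      for (int t = 0; t < T; ++t) {
        mat z = A.slice(t) * L.W.t();
        z.each_row() += L.b.t();
        Anew.slice(t) = z;
      }
      A = Anew;
    }
  }

  // ---- masked softmax cross-entropy ----
  ntok = 0;
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < B; ++i)
      if (Xb(i, t + 1) != 0) ntok += 1.0;
  if (ntok == 0) return 0.0;

  double nll = 0.0;
  cube dA(B, A.n_cols, T, fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat logits = A.slice(t);
    vec mx = max(logits, 1);
    logits.each_col() -= mx;
    mat e = exp(logits);
    vec se = sum(e, 1);
    mat p = e.each_col() / se;
    for (int i = 0; i < B; ++i) {
      int y = Xb(i, t + 1);
      if (y == 0) continue;
      nll -= std::log(std::max(p(i, y), 1e-300));
      if (grads) {
        rowvec dl = p.row(i) / ntok;
        dl(y) -= 1.0 / ntok;
        dA.slice(t).row(i) = dl;
      }
    }
  }
  if (!grads) return nll;

  // ---- backward ----
  for (int l = nl - 1; l >= 0; --l) {
    Layer& L = model[l];
    Cache& ch = cache[l];
    Grads& G = (*grads)[l];
    if (L.type == 2) {
      cube dAin(B, L.in, T);
      for (int t = 0; t < T; ++t) {
        G.W += dA.slice(t).t() * ch.A.slice(t);
        G.b += sum(dA.slice(t), 0).t();
        dAin.slice(t) = dA.slice(t) * L.W;
      }
      dA = dAin;
    } else if (L.type == 1) {
      int u = L.out;
      cube dAin(B, L.in, T);
      mat dh_next(B, u, fill::zeros), dc_next(B, u, fill::zeros);
      for (int t = T - 1; t >= 0; --t) {
        mat dh = dA.slice(t) + dh_next;
        mat tc = tanh(ch.C.slice(t));
        mat go = ch.O.slice(t), gi = ch.I.slice(t), gf = ch.F.slice(t),
            gg = ch.G.slice(t);
        mat do_ = dh % tc;
        mat dc = dh % go % (1.0 - square(tc)) + dc_next;
        const mat& cprev = (t == 0) ? ch.c0 : ch.C.slice(t - 1);
        const mat& hprev = (t == 0) ? ch.h0 : ch.H.slice(t - 1);
        mat di = dc % gg;
        mat dg = dc % gi;
        mat df = dc % cprev;
        dc_next = dc % gf;
        mat dz(B, 4 * u);
        dz.cols(0, u - 1) = di % gi % (1.0 - gi);
        dz.cols(u, 2 * u - 1) = df % gf % (1.0 - gf);
        dz.cols(2 * u, 3 * u - 1) = dg % (1.0 - square(gg));
        dz.cols(3 * u, 4 * u - 1) = do_ % go % (1.0 - go);
        G.W += dz.t() * ch.X.slice(t);
        G.U += dz.t() * hprev;
        G.b += sum(dz, 0).t();
        dh_next = dz * L.U;
        dAin.slice(t) = (dz * L.W) % ch.dropmask;
      }
      dA = dAin;
    } else {
      int f = L.in;
      double N = (double)B * T;
      vec sum_dxhat(f, fill::zeros), sum_dxhat_xhat(f, fill::zeros);
      cube dxhat(B, f, T);
      for (int t = 0; t < T; ++t) {
        G.gamma += sum(dA.slice(t) % ch.xhat.slice(t), 0).t();
        G.beta += sum(dA.slice(t), 0).t();
        mat dxh = dA.slice(t);
        dxh.each_row() %= L.gamma.t();
        dxhat.slice(t) = dxh;
        sum_dxhat += sum(dxh, 0).t();
        sum_dxhat_xhat += sum(dxh % ch.xhat.slice(t), 0).t();
      }
      for (int t = 0; t < T; ++t) {
        mat dx = N * dxhat.slice(t);
        dx.each_row() -= sum_dxhat.t();
        mat corr = ch.xhat.slice(t);
        corr.each_row() %= sum_dxhat_xhat.t();
        dx -= corr;
        dx.each_row() %= (ch.invstd.t() / N);
        dA.slice(t) = dx;
      }
    }
  }
  return nll;
}

std::vector<Grads> zero_grads(const std::vector<Layer>& model) {
  std::vector<Grads> g(model.size());
  for (size_t l = 0; l < model.size(); ++l) {
    const Layer& L = model[l];
    if (L.type == 0) {
      g[l].gamma.zeros(L.in);
      g[l].beta.zeros(L.in);
    } else if (L.type == 1) {
      g[l].W.zeros(4 * L.out, L.in);
      g[l].U.zeros(4 * L.out, L.out);
      g[l].b.zeros(4 * L.out);
    } else {
      g[l].W.zeros(L.out, L.in);
      g[l].b.zeros(L.out);
    }
  }
  return g;
}

struct AdamState {
  double t;
  std::vector<Grads> m, v;
};

void adam_update_one(mat& w, mat& m, mat& v, const mat& g, double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * square(g);
  mat mhat = m / (1 - std::pow(b1, t));
  mat vhat = v / (1 - std::pow(b2, t));
  w -= lr * mhat / (sqrt(vhat) + eps);
}

void adam_update_vec(vec& w, vec& m, vec& v, const vec& g, double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * square(g);
  vec mhat = m / (1 - std::pow(b1, t));
  vec vhat = v / (1 - std::pow(b2, t));
  w -= lr * mhat / (sqrt(vhat) + eps);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_clm_epoch")]]
List cpp_clm_epoch(List layers, List weights, List adam, IntegerMatrix Xr,
                   int vocab, double lr, int batch_size, double dropout,
                   IntegerVector frozen, int seed, bool update) {
  std::vector<Layer> model = parse_model(layers, weights, vocab);
  int nl = model.size();

  AdamState ad;
  ad.m = zero_grads(model);
  ad.v = zero_grads(model);
  ad.t = 0.0;
  if (adam.size() > 0) {
    ad.t = as<double>(adam["t"]);
    List ml = adam["m"], vl = adam["v"];
    for (int l = 0; l < nl; ++l) {
      List m_l = ml[l], v_l = vl[l];
      if (model[l].type == 0) {
        ad.m[l].gamma = as<vec>(m_l["gamma"]); ad.m[l].beta = as<vec>(m_l["beta"]);
        ad.v[l].gamma = as<vec>(v_l["gamma"]); ad.v[l].beta = as<vec>(v_l["beta"]);
      } else if (model[l].type == 1) {
        ad.m[l].W = as<mat>(m_l["W"]); ad.m[l].U = as<mat>(m_l["U"]); ad.m[l].b = as<vec>(m_l["b"]);
        ad.v[l].W = as<mat>(v_l["W"]); ad.v[l].U = as<mat>(v_l["U"]); ad.v[l].b = as<vec>(v_l["b"]);
      } else {
        ad.m[l].W = as<mat>(m_l["W"]); ad.m[l].b = as<vec>(m_l["b"]);
        ad.v[l].W = as<mat>(v_l["W"]); ad.v[l].b = as<vec>(v_l["b"]);
      }
    }
  }

  std::set<int> frozen_set(frozen.begin(), frozen.end());  // 1-based layer ids
  imat X(Xr.nrow(), Xr.ncol());
  for (int i = 0; i < Xr.nrow(); ++i)
    for (int j = 0; j < Xr.ncol(); ++j) X(i, j) = Xr(i, j);

  std::mt19937 rng(seed);
  int n = X.n_rows;
  double tot_nll = 0.0, tot_tok = 0.0;
  for (int start = 0; start < n; start += batch_size) {
    int end = std::min(n, start + batch_size) - 1;
    imat Xb = X.rows(start, end);
    double ntok = 0.0;
    if (update) {
      std::vector<Grads> g = zero_grads(model);
      tot_nll += batch_pass(model, Xb, vocab, dropout, rng, true, &g, ntok);
      tot_tok += ntok;
      ad.t += 1.0;
      for (int l = 0; l < nl; ++l) {
        if (frozen_set.count(l + 1)) continue;
        Layer& L = model[l];
        if (L.type == 0) {
          adam_update_vec(L.gamma, ad.m[l].gamma, ad.v[l].gamma, g[l].gamma, lr, ad.t);
          adam_update_vec(L.beta, ad.m[l].beta, ad.v[l].beta, g[l].beta, lr, ad.t);
        } else if (L.type == 1) {
          adam_update_one(L.W, ad.m[l].W, ad.v[l].W, g[l].W, lr, ad.t);
          adam_update_one(L.U, ad.m[l].U, ad.v[l].U, g[l].U, lr, ad.t);
          adam_update_vec(L.b, ad.m[l].b, ad.v[l].b, g[l].b, lr, ad.t);
        } else {
          adam_update_one(L.W, ad.m[l].W, ad.v[l].W, g[l].W, lr, ad.t);
          adam_update_vec(L.b, ad.m[l].b, ad.v[l].b, g[l].b, lr, ad.t);
        }
      }
    } else {
      tot_nll += batch_pass(model, Xb, vocab, 0.0, rng, false, nullptr, ntok);
      tot_tok += ntok;
    }
  }

  List adam_out;
  {
    int nlay = nl;
    List ml(nlay), vl(nlay);
    for (int l = 0; l < nlay; ++l) {
      if (model[l].type == 0) {
        ml[l] = List::create(_["gamma"] = ad.m[l].gamma, _["beta"] = ad.m[l].beta);
        vl[l] = List::create(_["gamma"] = ad.v[l].gamma, _["beta"] = ad.v[l].beta);
      } else if (model[l].type == 1) {
        ml[l] = List::create(_["W"] = ad.m[l].W, _["U"] = ad.m[l].U, _["b"] = ad.m[l].b);
        vl[l] = List::create(_["W"] = ad.v[l].W, _["U"] = ad.v[l].U, _["b"] = ad.v[l].b);
      } else {
        ml[l] = List::create(_["W"] = ad.m[l].W, _["b"] = ad.m[l].b);
        vl[l] = List::create(_["W"] = ad.v[l].W, _["b"] = ad.v[l].b);
      }
    }
    adam_out = List::create(_["t"] = ad.t, _["m"] = ml, _["v"] = vl);
  }

  return List::create(_["weights"] = export_weights(model), _["adam"] = adam_out,
                      _["loss"] = tot_tok > 0 ? tot_nll / tot_tok : NA_REAL);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_clm_loss_grads")]]
List cpp_clm_loss_grads(List layers, List weights, IntegerMatrix Xr, int vocab) {
  std::vector<Layer> model = parse_model(layers, weights, vocab);
  imat X(Xr.nrow(), Xr.ncol());
  for (int i = 0; i < Xr.nrow(); ++i)
    for (int j = 0; j < Xr.ncol(); ++j) X(i, j) = Xr(i, j);
  std::mt19937 rng(1);
  std::vector<Grads> g = zero_grads(model);
  double ntok = 0.0;
  // no dropout, batch statistics in use (training-mode BN) for determinism
  double nll = batch_pass(model, X, vocab, 0.0, rng, true, &g, ntok);
  int nl = model.size();
  List gl(nl);
  for (int l = 0; l < nl; ++l) {
    if (model[l].type == 0)
      gl[l] = List::create(_["gamma"] = g[l].gamma, _["beta"] = g[l].beta);
    else if (model[l].type == 1)
      gl[l] = List::create(_["W"] = g[l].W, _["U"] = g[l].U, _["b"] = g[l].b);
    else
      gl[l] = List::create(_["W"] = g[l].W, _["b"] = g[l].b);
  }
  return List::create(_["loss"] = ntok > 0 ? nll / ntok : NA_REAL,
                      _["grads"] = gl, _["ntok"] = ntok);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_clm_step")]]
List cpp_clm_step(List layers, List weights, List state, IntegerVector tokens,
                  int vocab) {
  std::vector<Layer> model = parse_model(layers, weights, vocab);
  int nl = model.size();
  int B = tokens.size();
  mat a(B, vocab, fill::zeros);
  for (int i = 0; i < B; ++i) a(i, tokens[i]) = 1.0;

  List new_state(state.size());
  int si = 0;
  for (int l = 0; l < nl; ++l) {
    Layer& L = model[l];
    if (L.type == 0) {
      vec invstd = 1.0 / sqrt(L.rvar + BN_EPS);
      a.each_row() -= L.rmean.t();
      a.each_row() %= (invstd % L.gamma).t();
      a.each_row() += L.beta.t();
    } else if (L.type == 1) {
      int u = L.out;
      List st = state[si];
      mat h = as<mat>(st["h"]), c = as<mat>(st["c"]);
      mat z = a * L.W.t() + h * L.U.t();
      z.each_row() += L.b.t();
      mat gi = 1.0 / (1.0 + exp(-z.cols(0, u - 1)));
      mat gf = 1.0 / (1.0 + exp(-z.cols(u, 2 * u - 1)));
      mat gg = tanh(z.cols(2 * u, 3 * u - 1));
      mat go = 1.0 / (1.0 + exp(-z.cols(3 * u, 4 * u - 1)));
      c = gf % c + gi % gg;
      h = go % tanh(c);
      new_state[si] = List::create(_["h"] = h, _["c"] = c);
      a = h;
      ++si;
    } else {
      a = a * L.W.t();
      a.each_row() += L.b.t();
    }
  }
  return List::create(_["logits"] = a, _["state"] = new_state);
}
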