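// Training/prediction engine for the hybrid capsule coder.
//
// One translation unit implements the full network forward pass and the exact
// reverse-mode gradients, including backprop through the unrolled dynamic
// routing iterations (no stop-gradient approximation on the couplings).
// Conventions shared with the R reference implementations:
//   - gate row order in stacked LSTM weights: f, g, o, i (blocks of u rows)
//   - convolution window vector = window rows concatenated in order
//   - primary capsule index i = channel * Np + position   (0-based,
//     channel-major so each channel's capsules are contiguous)
//   - routing transform slice index = channel * k + class
//   - head input = vectorise(V [d x k], column-major) followed by D

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

struct Cfg {
  int e, L, u, K1, A, ch, d, iters, loss_mode; // loss_mode 0=bce 1=softmax-ce
  bool use_bilstm, use_fusion;
  int n_in() const { return e + L; }
  int e_conv() const { return use_bilstm ? 2 * u : n_in(); }
};

static Cfg get_cfg(const List& cl) {
  Cfg c;
  c.e = as<int>(cl["e"]);
  c.L = as<int>(cl["L"]);
  c.u = as<int>(cl["u"]);
  c.K1 = as<int>(cl["K1"]);
  c.A = as<int>(cl["A"]);
  c.ch = as<int>(cl["ch"]);
  c.d = as<int>(cl["d"]);
  c.iters = as<int>(cl["iters"]);
  c.loss_mode = as<int>(cl["loss_mode"]);
  c.use_bilstm = as<bool>(cl["use_bilstm"]);
  c.use_fusion = as<bool>(cl["use_fusion"]);
  return c;
}

struct Par {
  mat lfW, lfU, lbW, lbU, convW, capsW, projW, headW;
  vec lfb, lbb, convb, capsb, headb;
  cube routeW;
};

static Par get_par(const List& P) {
  Par p;
  p.lfW = as<mat>(P["lf_W"]);  p.lfU = as<mat>(P["lf_U"]);
  p.lfb = as<vec>(P["lf_b"]);
  p.lbW = as<mat>(P["lb_W"]);  p.lbU = as<mat>(P["lb_U"]);
  p.lbb = as<vec>(P["lb_b"]);
  p.convW = as<mat>(P["conv_W"]); p.convb = as<vec>(P["conv_b"]);
  p.capsW = as<mat>(P["caps_W"]); p.capsb = as<vec>(P["caps_b"]);
  p.routeW = as<cube>(P["route_W"]);
  p.projW = as<mat>(P["proj_W"]);
  p.headW = as<mat>(P["head_W"]); p.headb = as<vec>(P["head_b"]);
  return p;
}

static Par zero_like(const Par& p) {
  Par g;
  g.lfW = zeros<mat>(size(p.lfW));   g.lfU = zeros<mat>(size(p.lfU));
  g.lfb = zeros<vec>(size(p.lfb));
  g.lbW = zeros<mat>(size(p.lbW));   g.lbU = zeros<mat>(size(p.lbU));
  g.lbb = zeros<vec>(size(p.lbb));
  g.convW = zeros<mat>(size(p.convW)); g.convb = zeros<vec>(size(p.convb));
  g.capsW = zeros<mat>(size(p.capsW)); g.capsb = zeros<vec>(size(p.capsb));
  g.routeW = zeros<cube>(size(p.routeW));
  g.projW = zeros<mat>(size(p.projW));
  g.headW = zeros<mat>(size(p.headW)); g.headb = zeros<vec>(size(p.headb));
  return g;
}

static List par_to_list(const Par& p) {
  return List::create(
    _["lf_W"] = p.lfW, _["lf_U"] = p.lfU, _["lf_b"] = p.lfb,
    _["lb_W"] = p.lbW, _["lb_U"] = p.lbU, _["lb_b"] = p.lbb,
    _["conv_W"] = p.convW, _["conv_b"] = p.convb,
    _["caps_W"] = p.capsW, _["caps_b"] = p.capsb,
    _["route_W"] = p.routeW, _["proj_W"] = p.projW,
    _["head_W"] = p.headW, _["head_b"] = p.headb);
}

// ---------- primitives ----------

static inline vec sigm(const vec& z) { return 1.0 / (1.0 + exp(-z)); }

static vec squash_v(const vec& s) {
  double n2 = dot(s, s);
  return s * (n2 / ((1.0 + n2) * (std::sqrt(n2) + 1e-12)));
}

// pullback of squash at input s applied to cotangent dv
static vec squash_bwd(const vec& s, const vec& dv) {
  double n2 = dot(s, s), n = std::sqrt(n2);
  if (n < 1e-12) return zeros<vec>(s.n_elem);
  double beta = n / (1.0 + n2);
  double bp = (1.0 - n2) / ((1.0 + n2) * (1.0 + n2));
  return beta * dv + (bp / n) * dot(s, dv) * s;
}

static mat softmax_rows_c(const mat& b) {
  mat e = exp(b.each_col() - max(b, 1));
  return e.each_col() / sum(e, 1);
}

struct LstmCache { mat f, g, o, i, c, tc, h; };

static void lstm_fwd(const mat& X, const mat& W, const mat& U, const vec& b,
                     int u, LstmCache& L) {
  int T = X.n_rows;
  L.f.set_size(u, T); L.g.set_size(u, T); L.o.set_size(u, T);
  L.i.set_size(u, T); L.c.set_size(u, T); L.tc.set_size(u, T);
  L.h.set_size(u, T);
  mat Wx = W * X.t(); // input transform for all positions at once
  Wx.each_col() += b;
  vec h(u, fill::zeros), c(u, fill::zeros);
  for (int t = 0; t < T; ++t) {
    vec z = Wx.col(t) + U * h;
    vec f = sigm(z.subvec(0, u - 1));
    vec g = tanh(z.subvec(u, 2 * u - 1));
    vec o = sigm(z.subvec(2 * u, 3 * u - 1));
    vec ii = sigm(z.subvec(3 * u, 4 * u - 1));
    c = f % c + ii % g;
    vec tc = tanh(c);
    h = o % tc;
    L.f.col(t) = f; L.g.col(t) = g; L.o.col(t) = o; L.i.col(t) = ii;
    L.c.col(t) = c; L.tc.col(t) = tc; L.h.col(t) = h;
  }
}

static void lstm_bwd(const mat& X, const mat& U, const LstmCache& L,
                     const mat& dH, int u, mat& dW, mat& dU, vec& db) {
  int T = X.n_rows;
  vec dh_c(u, fill::zeros), dc_c(u, fill::zeros);
  mat dZ(4 * u, T); // gate pre-activation cotangents, for batched dW/dU
  for (int t = T - 1; t >= 0; --t) {
    vec dh = dH.col(t) + dh_c;
    vec o = L.o.col(t), tc = L.tc.col(t), f = L.f.col(t);
    vec g = L.g.col(t), ii = L.i.col(t);
    vec do_ = dh % tc;
    vec dc = dc_c + dh % o % (1.0 - tc % tc);
    vec cprev = (t > 0) ? vec(L.c.col(t - 1)) : zeros<vec>(u);
    vec dz(4 * u);
    dz.subvec(0, u - 1) = (dc % cprev) % f % (1.0 - f);
    dz.subvec(u, 2 * u - 1) = (dc % ii) % (1.0 - g % g);
    dz.subvec(2 * u, 3 * u - 1) = do_ % o % (1.0 - o);
    dz.subvec(3 * u, 4 * u - 1) = (dc % g) % ii % (1.0 - ii);
    dZ.col(t) = dz;
    dh_c = U.t() * dz;
    dc_c = dc % f;
  }
  dW += dZ * X;
  db += sum(dZ, 1);
  if (T > 1) {
    // dU accumulates dz_t * h_{t-1}'; h_{-1} = 0
    dU += dZ.cols(1, T - 1) * L.h.cols(0, T - 2).t();
  }
}

// ---------- full forward ----------

struct Fwd {
  int T, Np, Ncap;
  mat Xaug, Xrev;            // T x n_in (and reversed copy)
  LstmCache Lf, Lb;
  mat Fseq;                  // T x e_conv
  mat Wmat;                  // Np x K1*e_conv window matrix
  mat Mpre, M;               // Np x A
  mat CapPre, Pcap;          // Ncap x d (pre-squash and squashed)
  std::vector<mat> Uj;       // per class j: d x Ncap prediction vectors
  std::vector<mat> r_c;      // per iteration: Ncap x k couplings
  std::vector<mat> r_s, r_v; // per iteration: d x k
  vec zpool, zproj, D;
  vec fused, logits, scores;
};

static double forward_note(const uvec& toks, const vec* y, const Par& par,
                           const mat& Vemb, const mat& Gv, const mat& Cl,
                           const Cfg& cfg, Fwd& F) {
  const int T = toks.n_elem, k = cfg.L, d = cfg.d, CH = cfg.ch;
  const int nin = cfg.n_in(), E = cfg.e_conv();
  F.T = T;
  F.Xaug.set_size(T, nin);
  for (int t = 0; t < T; ++t) {
    F.Xaug(t, span(0, cfg.e - 1)) = Vemb.row(toks[t]);
    if (cfg.use_fusion)
      F.Xaug(t, span(cfg.e, nin - 1)) = Gv.row(toks[t]);
    else
      F.Xaug(t, span(cfg.e, nin - 1)).zeros();
  }
  if (cfg.use_bilstm) {
    F.Xrev = flipud(F.Xaug);
    lstm_fwd(F.Xaug, par.lfW, par.lfU, par.lfb, cfg.u, F.Lf);
    lstm_fwd(F.Xrev, par.lbW, par.lbU, par.lbb, cfg.u, F.Lb);
    F.Fseq.set_size(T, 2 * cfg.u);
    for (int t = 0; t < T; ++t) {
      F.Fseq(t, span(0, cfg.u - 1)) = F.Lf.h.col(t).t();
      F.Fseq(t, span(cfg.u, 2 * cfg.u - 1)) = F.Lb.h.col(T - 1 - t).t();
    }
  } else {
    F.Fseq = F.Xaug;
  }

  // n-gram convolution over valid windows
  F.Np = T - cfg.K1 + 1;
  F.Wmat.set_size(F.Np, cfg.K1 * E);
  for (int r = 0; r < cfg.K1; ++r)
    F.Wmat.cols(r * E, (r + 1) * E - 1) = F.Fseq.rows(r, r + F.Np - 1);
  F.Mpre = F.Wmat * par.convW.t();
  F.Mpre.each_row() += par.convb.t();
  F.M = clamp(F.Mpre, 0.0, datum::inf);

  // primary capsules (channel-major: capsule i = ch * Np + p)
  F.Ncap = F.Np * CH;
  mat PreAll = F.M * par.capsW.t(); // Np x ch*d
  PreAll.each_row() += par.capsb.t();
  F.CapPre.set_size(F.Ncap, d);
  F.Pcap.set_size(F.Ncap, d);
  for (int cc = 0; cc < CH; ++cc)
    for (int p = 0; p < F.Np; ++p) {
      int i = cc * F.Np + p;
      vec s = PreAll(p, span(cc * d, (cc + 1) * d - 1)).t();
      F.CapPre.row(i) = s.t();
      F.Pcap.row(i) = squash_v(s).t();
    }

  // prediction vectors, one d x Ncap matrix per class
  F.Uj.assign(k, mat());
  for (int j = 0; j < k; ++j) {
    F.Uj[j].set_size(d, F.Ncap);
    for (int cc = 0; cc < CH; ++cc)
      F.Uj[j].cols(cc * F.Np, (cc + 1) * F.Np - 1) =
        par.routeW.slice(cc * k + j) *
        F.Pcap.rows(cc * F.Np, (cc + 1) * F.Np - 1).t();
  }

  // dynamic routing (full trace kept)
  F.r_c.assign(cfg.iters, mat());
  F.r_s.assign(cfg.iters, mat());
  F.r_v.assign(cfg.iters, mat());
  mat b(F.Ncap, k, fill::zeros);
  mat v(d, k, fill::zeros);
  for (int it = 0; it < cfg.iters; ++it) {
    mat c = softmax_rows_c(b);
    mat s(d, k);
    for (int j = 0; j < k; ++j) s.col(j) = F.Uj[j] * c.col(j);
    for (int j = 0; j < k; ++j) v.col(j) = squash_v(s.col(j));
    if (it < cfg.iters - 1)
      for (int j = 0; j < k; ++j) b.col(j) += F.Uj[j].t() * v.col(j);
    F.r_c[it] = c; F.r_s[it] = s; F.r_v[it] = v;
  }

  // sentence-label similarity D
  F.D.zeros(k);
  if (cfg.use_fusion) {
    F.zpool = mean(F.Fseq, 0).t();
    F.zproj = par.projW * F.zpool;
    double nz = norm(F.zproj);
    for (int j = 0; j < k; ++j) {
      double nc = norm(Cl.row(j));
      F.D[j] = (nz < 1e-12 || nc < 1e-12)
                 ? 0.0 : dot(F.zproj, Cl.row(j).t()) / (nz * nc);
    }
  }

  // classification head
  F.fused = join_cols(vectorise(v), F.D);
  F.logits = par.headW * F.fused + par.headb;
  if (cfg.loss_mode == 0) {
    F.scores = sigm(F.logits);
  } else {
    vec e = exp(F.logits - F.logits.max());
    F.scores = e / accu(e);
  }

  if (!y) return 0.0;
  if (cfg.loss_mode == 0) {
    vec p = clamp(F.scores, 1e-12, 1.0 - 1e-12);
    return -accu((*y) % log(p) + (1.0 - *y) % log(1.0 - p)) / k;
  }
  vec q = (*y) / accu(*y);
  vec p = clamp(F.scores, 1e-12, 1.0);
  return -accu(q % log(p));
}

// ---------- full backward ----------

static void backward_note(const Par& par, const mat& Cl, const vec& y,
                          const Cfg& cfg, const Fwd& F, Par& g) {
  const int T = F.T, k = cfg.L, d = cfg.d, CH = cfg.ch;
  const int E = cfg.e_conv();

  vec dlogits(k);
  if (cfg.loss_mode == 0) {
    dlogits = (F.scores - y) / k;
  } else {
    dlogits = F.scores - y / accu(y);
  }
  g.headW += dlogits * F.fused.t();
  g.headb += dlogits;
  vec dfused = par.headW.t() * dlogits;

  mat dVout = reshape(dfused.subvec(0, (uword)k * d - 1), d, k);
  vec dD = dfused.subvec((uword)k * d, dfused.n_elem - 1);

  mat dFseq(T, E, fill::zeros);

  // D path
  if (cfg.use_fusion) {
    double nz = norm(F.zproj);
    vec dz(F.zproj.n_elem, fill::zeros);
    if (nz > 1e-12) {
      for (int j = 0; j < k; ++j) {
        double nc = norm(Cl.row(j));
        if (nc < 1e-12) continue;
        dz += dD[j] * (Cl.row(j).t() / (nz * nc)
                       - F.D[j] * F.zproj / (nz * nz));
      }
    }
    g.projW += dz * F.zpool.t();
    vec dzpool = par.projW.t() * dz;
    dFseq.each_row() += (dzpool / T).t();
  }

  // routing backward (exact, through all iterations)
  std::vector<mat> dUj(k, mat(d, F.Ncap, fill::zeros));
  mat db(F.Ncap, k, fill::zeros);
  for (int r = cfg.iters - 1; r >= 0; --r) {
    mat dv = (r == cfg.iters - 1) ? dVout : mat(d, k, fill::zeros);
    if (r < cfg.iters - 1) {
      // b_{r+1} = b_r + <u_hat, v_r> per (i, j); db holds dL/db_{r+1}
      for (int j = 0; j < k; ++j) {
        dUj[j] += F.r_v[r].col(j) * db.col(j).t();
        dv.col(j) += F.Uj[j] * db.col(j);
      }
    }
    mat ds(d, k);
    for (int j = 0; j < k; ++j)
      ds.col(j) = squash_bwd(F.r_s[r].col(j), dv.col(j));
    mat dc(F.Ncap, k);
    for (int j = 0; j < k; ++j) {
      dc.col(j) = F.Uj[j].t() * ds.col(j);
      dUj[j] += ds.col(j) * F.r_c[r].col(j).t();
    }
    // softmax pullback, rows of c against rows of dc
    vec rowdot = sum(F.r_c[r] % dc, 1);
    db += F.r_c[r] % (dc.each_col() - rowdot);
  }

  // prediction transforms and primary capsules
  mat dPcap(F.Ncap, d, fill::zeros);
  for (int j = 0; j < k; ++j)
    for (int cc = 0; cc < CH; ++cc) {
      const mat Pc = F.Pcap.rows(cc * F.Np, (cc + 1) * F.Np - 1);
      const mat dU = dUj[j].cols(cc * F.Np, (cc + 1) * F.Np - 1);
      g.routeW.slice(cc * k + j) += dU * Pc;
      dPcap.rows(cc * F.Np, (cc + 1) * F.Np - 1) +=
        dU.t() * par.routeW.slice(cc * k + j);
    }

  mat dPreAll(F.Np, CH * d);
  for (int cc = 0; cc < CH; ++cc)
    for (int p = 0; p < F.Np; ++p) {
      int i = cc * F.Np + p;
      dPreAll(p, span(cc * d, (cc + 1) * d - 1)) =
        squash_bwd(F.CapPre.row(i).t(), dPcap.row(i).t()).t();
    }
  g.capsW += dPreAll.t() * F.M;
  g.capsb += sum(dPreAll, 0).t();
  mat dM = dPreAll * par.capsW;

  // convolution backward
  mat dMpre = dM % conv_to<mat>::from(F.Mpre > 0);
  g.convW += dMpre.t() * F.Wmat;
  g.convb += sum(dMpre, 0).t();
  mat dWmat = dMpre * par.convW;
  for (int r = 0; r < cfg.K1; ++r)
    dFseq.rows(r, r + F.Np - 1) += dWmat.cols(r * E, (r + 1) * E - 1);

  // encoder backward (inputs are frozen embeddings; no dX needed)
  if (cfg.use_bilstm) {
    mat dHf(cfg.u, T), dHbrev(cfg.u, T);
    for (int t = 0; t < T; ++t) {
      dHf.col(t) = dFseq(t, span(0, cfg.u - 1)).t();
      dHbrev.col(T - 1 - t) = dFseq(t, span(cfg.u, 2 * cfg.u - 1)).t();
    }
    lstm_bwd(F.Xaug, par.lfU, F.Lf, dHf, cfg.u, g.lfW, g.lfU, g.lfb);
    lstm_bwd(F.Xrev, par.lbU, F.Lb, dHbrev, cfg.u, g.lbW, g.lbU, g.lbb);
  }
}

// ---------- exported entry points ----------

// Batched forward (and optionally backward) over a list of notes.
// tok_list: list of 0-based integer vectors (rows into Vemb/Gv).
// Y: N x L multi-hot gold matrix (may be 0 x 0 when only scores are needed).
// [[Rcpp::export]]
List cpp_run_batch(List tok_list, arma::mat Y, List par_list,
                   arma::mat Vemb, arma::mat Gv, arma::mat Cl,
                   List cfg_list, bool want_grad, bool want_scores) {
  Cfg cfg = get_cfg(cfg_list);
  Par par = get_par(par_list);
  int N = tok_list.size();
  bool have_y = Y.n_rows == (uword)N && Y.n_cols == (uword)cfg.L;
  if (want_grad && !have_y) stop("gradients require a gold matrix Y");
  Par grad = want_grad ? zero_like(par) : Par();
  mat scores;
  if (want_scores) scores.set_size(N, cfg.L);
  double loss_sum = 0.0;
  Fwd F;
  for (int n = 0; n < N; ++n) {
    IntegerVector tv = tok_list[n];
    uvec toks(tv.size());
    for (int t = 0; t < tv.size(); ++t) toks[t] = (uword)tv[t];
    if ((int)toks.n_elem < cfg.K1)
      stop("note %d is shorter than the convolution window", n + 1);
    vec y;
    if (have_y) y = Y.row(n).t();
    loss_sum += forward_note(toks, have_y ? &y : nullptr, par,
                             Vemb, Gv, Cl, cfg, F);
    if (want_scores) scores.row(n) = F.scores.t();
    if (want_grad) backward_note(par, Cl, y, cfg, F, grad);
  }
  List out = List::create(_["loss_sum"] = loss_sum, _["n"] = N);
  if (want_scores) out["scores"] = scores;
  if (want_grad) out["grads"] = par_to_list(grad);
  return out;
}

// Forward pass for one note with the routing trace exposed (for attribution).
// [[Rcpp::export]]
List cpp_forward_trace(IntegerVector toks_r, List par_list,
                       arma::mat Vemb, arma::mat Gv, arma::mat Cl,
                       List cfg_list) {
  Cfg cfg = get_cfg(cfg_list);
  Par par = get_par(par_list);
  uvec toks(toks_r.size());
  for (int t = 0; t < toks_r.size(); ++t) toks[t] = (uword)toks_r[t];
  if ((int)toks.n_elem < cfg.K1)
    stop("note is shorter than the convolution window");
  Fwd F;
  forward_note(toks, nullptr, par, Vemb, Gv, Cl, cfg, F);
  return List::create(
    _["scores"] = F.scores,
    _["logits"] = F.logits,
    _["v"] = F.r_v[cfg.iters - 1].t(),          // k x d
    _["coupling"] = F.r_c[cfg.iters - 1],       // Ncap x k, final iteration
    _["D"] = F.D,
    _["np"] = F.Np,
    _["channels"] = cfg.ch);
}
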