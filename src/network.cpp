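// Two-branch stacked recurrent classifier (and a 1-d CNN baseline):
// batched forward, exact backpropagation through time, and an Adam
// training loop. Everything is deterministic: initial parameters and
// the per-epoch shuffle order come from R, and no RNG is used here.
//
// Recurrent cells (z = [h_{t-1}, x_t]):
//   rnn : h = tanh(W z + b)
//   gru : z_g = s(Wz z + bz); r = s(Wr z + br);
//         n = tanh(Wn [r*h_{t-1}, x] + bn); h = (1-z_g)*n + z_g*h_{t-1}
//   lstm: f = s(Wf z + bf); i = s(Wi z + bi); g = tanh(Wc z + bc);
//         c = f*c_{t-1} + i*g; o = s(Wo z + bo); h = o*tanh(c)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;
using arma::cube;

enum CellType { CELL_RNN, CELL_GRU, CELL_LSTM };

static CellType cell_from_string(const std::string& s) {
  if (s == "rnn") return CELL_RNN;
  if (s == "gru") return CELL_GRU;
  if (s == "lstm") return CELL_LSTM;
  Rcpp::stop("unknown cell type '%s'", s);
}

static const char* LSTM_NAMES[8] = {"W_f", "W_i", "W_c", "W_o", "b_f", "b_i", "b_c", "b_o"};
static const char* GRU_NAMES[6] = {"W_z", "W_r", "W_n", "b_z", "b_r", "b_n"};
static const char* RNN_NAMES[2] = {"W", "b"};

struct CellParams {
  CellType type;
  std::vector<mat> W;
  std::vector<vec> b;
  int hidden = 0, input = 0;

  void parse(const Rcpp::List& lst, CellType ty) {
    type = ty;
    int nw = ty == CELL_LSTM ? 4 : (ty == CELL_GRU ? 3 : 1);
    const char** names = ty == CELL_LSTM ? LSTM_NAMES : (ty == CELL_GRU ? GRU_NAMES : RNN_NAMES);
    W.resize(nw);
    b.resize(nw);
    for (int k = 0; k < nw; ++k) {
      W[k] = Rcpp::as<mat>(lst[names[k]]);
      b[k] = Rcpp::as<vec>(lst[names[k + nw]]);
    }
    hidden = W[0].n_rows;
    input = W[0].n_cols - hidden;
    if (input <= 0) Rcpp::stop("cell weight matrix narrower than its hidden size");
  }

  Rcpp::List as_list() const {
    int nw = W.size();
    const char** names = type == CELL_LSTM ? LSTM_NAMES : (type == CELL_GRU ? GRU_NAMES : RNN_NAMES);
    Rcpp::List out;
    for (int k = 0; k < nw; ++k) out[names[k]] = W[k];
    for (int k = 0; k < nw; ++k) out[names[k + nw]] = b[k];
    return out;
  }

  void zeros_like(const CellParams& p) {
    type = p.type;
    hidden = p.hidden;
    input = p.input;
    W.resize(p.W.size());
    b.resize(p.b.size());
    for (size_t k = 0; k < p.W.size(); ++k) {
      W[k].zeros(p.W[k].n_rows, p.W[k].n_cols);
      b[k].zeros(p.b[k].n_elem);
    }
  }
};

struct CellCache {
  mat H;                 // T x h outputs
  mat C;                 // lstm cell states
  mat G1, G2, G3, G4;    // gates: lstm f,i,g,o; gru z,r,n in G1..G3
};

static void cell_forward(const mat& X, const CellParams& P, CellCache& cc) {
  const int T = X.n_rows, h = P.hidden;
  if ((int)X.n_cols != P.input)
    Rcpp::stop("cell expected input width %d, got %d", P.input, (int)X.n_cols);
  cc.H.set_size(T, h);
  vec hprev(h, arma::fill::zeros);
  if (P.type == CELL_LSTM) {
    cc.C.set_size(T, h);
    cc.G1.set_size(T, h); cc.G2.set_size(T, h); cc.G3.set_size(T, h); cc.G4.set_size(T, h);
    vec cprev(h, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      vec z = arma::join_cols(hprev, X.row(t).t());
      vec f = 1.0 / (1.0 + arma::exp(-(P.W[0] * z + P.b[0])));
      vec i = 1.0 / (1.0 + arma::exp(-(P.W[1] * z + P.b[1])));
      vec g = arma::tanh(P.W[2] * z + P.b[2]);
      vec c = f % cprev + i % g;
      vec o = 1.0 / (1.0 + arma::exp(-(P.W[3] * z + P.b[3])));
      vec hh = o % arma::tanh(c);
      cc.G1.row(t) = f.t(); cc.G2.row(t) = i.t(); cc.G3.row(t) = g.t(); cc.G4.row(t) = o.t();
      cc.C.row(t) = c.t();
      cc.H.row(t) = hh.t();
      hprev = hh;
      cprev = c;
    }
  } else if (P.type == CELL_GRU) {
    cc.G1.set_size(T, h); cc.G2.set_size(T, h); cc.G3.set_size(T, h);
    for (int t = 0; t < T; ++t) {
      vec z = arma::join_cols(hprev, X.row(t).t());
      vec zg = 1.0 / (1.0 + arma::exp(-(P.W[0] * z + P.b[0])));
      vec r = 1.0 / (1.0 + arma::exp(-(P.W[1] * z + P.b[1])));
      vec zn = arma::join_cols(r % hprev, X.row(t).t());
      vec n = arma::tanh(P.W[2] * zn + P.b[2]);
      vec hh = (1.0 - zg) % n + zg % hprev;
      cc.G1.row(t) = zg.t(); cc.G2.row(t) = r.t(); cc.G3.row(t) = n.t();
      cc.H.row(t) = hh.t();
      hprev = hh;
    }
  } else {
    for (int t = 0; t < T; ++t) {
      vec z = arma::join_cols(hprev, X.row(t).t());
      vec hh = arma::tanh(P.W[0] * z + P.b[0]);
      cc.H.row(t) = hh.t();
      hprev = hh;
    }
  }
}

// dH: T x h gradient on every output row. Accumulates into G; returns dX.
static void cell_backward(const mat& X, const CellParams& P, const CellCache& cc,
                          const mat& dH, CellParams& G, mat& dX) {
  const int T = X.n_rows, h = P.hidden, in = P.input;
  dX.zeros(T, in);
  vec dh_next(h, arma::fill::zeros);
  if (P.type == CELL_LSTM) {
    vec dc_next(h, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      vec hprev = t > 0 ? cc.H.row(t - 1).t() : vec(h, arma::fill::zeros);
      vec cprev = t > 0 ? cc.C.row(t - 1).t() : vec(h, arma::fill::zeros);
      vec f = cc.G1.row(t).t(), i = cc.G2.row(t).t(), g = cc.G3.row(t).t(), o = cc.G4.row(t).t();
      vec c = cc.C.row(t).t();
      vec tc = arma::tanh(c);
      vec dh = dH.row(t).t() + dh_next;
      vec dO = dh % tc;
      vec dc = dh % o % (1.0 - tc % tc) + dc_next;
      vec dF = dc % cprev;
      vec dI = dc % g;
      vec dG = dc % i;
      dc_next = dc % f;
      vec da_f = dF % f % (1.0 - f);
      vec da_i = dI % i % (1.0 - i);
      vec da_g = dG % (1.0 - g % g);
      vec da_o = dO % o % (1.0 - o);
      vec z = arma::join_cols(hprev, X.row(t).t());
      G.W[0] += da_f * z.t(); G.b[0] += da_f;
      G.W[1] += da_i * z.t(); G.b[1] += da_i;
      G.W[2] += da_g * z.t(); G.b[2] += da_g;
      G.W[3] += da_o * z.t(); G.b[3] += da_o;
      vec dz = P.W[0].t() * da_f + P.W[1].t() * da_i + P.W[2].t() * da_g + P.W[3].t() * da_o;
      dh_next = dz.subvec(0, h - 1);
      dX.row(t) = dz.subvec(h, h + in - 1).t();
    }
  } else if (P.type == CELL_GRU) {
    for (int t = T - 1; t >= 0; --t) {
      vec hprev = t > 0 ? cc.H.row(t - 1).t() : vec(h, arma::fill::zeros);
      vec zg = cc.G1.row(t).t(), r = cc.G2.row(t).t(), n = cc.G3.row(t).t();
      vec dh = dH.row(t).t() + dh_next;
      vec dZg = dh % (hprev - n);
      vec dN = dh % (1.0 - zg);
      vec dhprev = dh % zg;
      vec da_n = dN % (1.0 - n % n);
      vec zn = arma::join_cols(r % hprev, X.row(t).t());
      G.W[2] += da_n * zn.t(); G.b[2] += da_n;
      vec dzn = P.W[2].t() * da_n;
      vec d_rh = dzn.subvec(0, h - 1);
      vec dR = d_rh % hprev;
      dhprev += d_rh % r;
      dX.row(t) += dzn.subvec(h, h + in - 1).t();
      vec da_z = dZg % zg % (1.0 - zg);
      vec da_r = dR % r % (1.0 - r);
      vec z = arma::join_cols(hprev, X.row(t).t());
      G.W[0] += da_z * z.t(); G.b[0] += da_z;
      G.W[1] += da_r * z.t(); G.b[1] += da_r;
      vec dz = P.W[0].t() * da_z + P.W[1].t() * da_r;
      dhprev += dz.subvec(0, h - 1);
      dX.row(t) += dz.subvec(h, h + in - 1).t();
      dh_next = dhprev;
    }
  } else {
    for (int t = T - 1; t >= 0; --t) {
      vec hprev = t > 0 ? cc.H.row(t - 1).t() : vec(h, arma::fill::zeros);
      vec hh = cc.H.row(t).t();
      vec dh = dH.row(t).t() + dh_next;
      vec da = dh % (1.0 - hh % hh);
      vec z = arma::join_cols(hprev, X.row(t).t());
      G.W[0] += da * z.t(); G.b[0] += da;
      vec dz = P.W[0].t() * da;
      dh_next = dz.subvec(0, h - 1);
      dX.row(t) = dz.subvec(h, h + in - 1).t();
    }
  }
}

static mat reverse_rows(const mat& X) { return arma::flipud(X); }

// Bidirectional (or single-direction) layer over one feature map.
struct LayerCache {
  CellCache fwd, bwd;
  mat Xrev;           // reversed input fed to the bwd cell
  mat out;            // T x (D*h), aligned by position
};

static void layer_forward(const mat& X, const CellParams& Pf, const CellParams* Pb,
                          LayerCache& lc) {
  cell_forward(X, Pf, lc.fwd);
  if (Pb) {
    lc.Xrev = reverse_rows(X);
    cell_forward(lc.Xrev, *Pb, lc.bwd);
    lc.out = arma::join_rows(lc.fwd.H, reverse_rows(lc.bwd.H));
  } else {
    lc.out = lc.fwd.H;
  }
}

static void layer_backward(const mat& X, const CellParams& Pf, const CellParams* Pb,
                           const LayerCache& lc, const mat& dOut,
                           CellParams& Gf, CellParams* Gb, mat& dX) {
  const int h = Pf.hidden;
  if (Pb) {
    mat dHf = dOut.cols(0, h - 1);
    mat dHb_rev = reverse_rows(dOut.cols(h, 2 * h - 1));
    mat dXf, dXb_rev;
    cell_backward(X, Pf, lc.fwd, dHf, Gf, dXf);
    cell_backward(lc.Xrev, *Pb, lc.bwd, dHb_rev, *Gb, dXb_rev);
    dX = dXf + reverse_rows(dXb_rev);
  } else {
    cell_backward(X, Pf, lc.fwd, dOut, Gf, dX);
  }
}

// ---------------- parameter containers ----------------------------------

struct NetConfig {
  std::string kind;
  int dim = 0;
  // recurrent
  CellType cell1 = CELL_LSTM, cell2 = CELL_LSTM;
  bool bidir1 = true, bidir2 = true, share = false;
  int hidden1 = 0, hidden2 = 0, linear1 = 0;
  int pooling = 0;  // 0 = final states, 1 = max over time, 2 = mean over time
  // cnn
  int f1 = 0, f2 = 0, kernel = 0, pool = 0, flat = 0;

  static NetConfig parse(const Rcpp::List& cfg) {
    NetConfig c;
    c.kind = Rcpp::as<std::string>(cfg["kind"]);
    c.dim = Rcpp::as<int>(cfg["dim"]);
    if (c.kind == "recurrent") {
      c.cell1 = cell_from_string(Rcpp::as<std::string>(cfg["cell1"]));
      c.cell2 = cell_from_string(Rcpp::as<std::string>(cfg["cell2"]));
      c.bidir1 = Rcpp::as<bool>(cfg["bidir1"]);
      c.bidir2 = Rcpp::as<bool>(cfg["bidir2"]);
      c.share = Rcpp::as<bool>(cfg["share_branches"]);
      c.hidden1 = Rcpp::as<int>(cfg["hidden1"]);
      c.hidden2 = Rcpp::as<int>(cfg["hidden2"]);
      c.linear1 = Rcpp::as<int>(cfg["linear1"]);
      std::string pool = Rcpp::as<std::string>(cfg["pooling"]);
      c.pooling = pool == "final" ? 0 : (pool == "max" ? 1 : (pool == "mean" ? 2 : -1));
      if (c.pooling < 0) Rcpp::stop("unknown pooling '%s'", pool);
    } else if (c.kind == "cnn1d") {
      Rcpp::IntegerVector f = cfg["filters"];
      c.f1 = f[0];
      c.f2 = f[1];
      c.kernel = Rcpp::as<int>(cfg["kernel"]);
      c.pool = Rcpp::as<int>(cfg["pool"]);
      c.flat = Rcpp::as<int>(cfg["flat"]);
    } else {
      Rcpp::stop("unknown model kind '%s'", c.kind);
    }
    return c;
  }
};

struct RecParams {
  // order: mi_l1_fwd [mi_l1_bwd] [cts_l1_fwd cts_l1_bwd] l2_fwd [l2_bwd]
  CellParams mi_f, mi_b, cts_f, cts_b, l2_f, l2_b;
  mat lin1_W, lin2_W;
  vec lin1_b, lin2_b;

  void parse(const Rcpp::List& p, const NetConfig& c) {
    mi_f.parse(p["mi_l1_fwd"], c.cell1);
    if (c.bidir1) mi_b.parse(p["mi_l1_bwd"], c.cell1);
    if (!c.share) {
      cts_f.parse(p["cts_l1_fwd"], c.cell1);
      if (c.bidir1) cts_b.parse(p["cts_l1_bwd"], c.cell1);
    }
    l2_f.parse(p["l2_fwd"], c.cell2);
    if (c.bidir2) l2_b.parse(p["l2_bwd"], c.cell2);
    lin1_W = Rcpp::as<mat>(p["lin1_W"]);
    lin1_b = Rcpp::as<vec>(p["lin1_b"]);
    lin2_W = Rcpp::as<mat>(p["lin2_W"]);
    lin2_b = Rcpp::as<vec>(p["lin2_b"]);
  }

  Rcpp::List as_list(const NetConfig& c) const {
    Rcpp::List p;
    p["mi_l1_fwd"] = mi_f.as_list();
    if (c.bidir1) p["mi_l1_bwd"] = mi_b.as_list();
    if (!c.share) {
      p["cts_l1_fwd"] = cts_f.as_list();
      if (c.bidir1) p["cts_l1_bwd"] = cts_b.as_list();
    }
    p["l2_fwd"] = l2_f.as_list();
    if (c.bidir2) p["l2_bwd"] = l2_b.as_list();
    p["lin1_W"] = lin1_W;
    p["lin1_b"] = lin1_b;
    p["lin2_W"] = lin2_W;
    p["lin2_b"] = lin2_b;
    return p;
  }

  void zeros_like(const RecParams& o, const NetConfig& c) {
    mi_f.zeros_like(o.mi_f);
    if (c.bidir1) mi_b.zeros_like(o.mi_b);
    if (!c.share) {
      cts_f.zeros_like(o.cts_f);
      if (c.bidir1) cts_b.zeros_like(o.cts_b);
    }
    l2_f.zeros_like(o.l2_f);
    if (c.bidir2) l2_b.zeros_like(o.l2_b);
    lin1_W.zeros(o.lin1_W.n_rows, o.lin1_W.n_cols);
    lin1_b.zeros(o.lin1_b.n_elem);
    lin2_W.zeros(o.lin2_W.n_rows, o.lin2_W.n_cols);
    lin2_b.zeros(o.lin2_b.n_elem);
  }

  // flat traversal for the optimiser
  template <typename F>
  void each(const NetConfig& c, F f) {
    auto cell = [&](CellParams& p) {
      for (auto& w : p.W) f(w);
      for (auto& b : p.b) f(b);
    };
    cell(mi_f);
    if (c.bidir1) cell(mi_b);
    if (!c.share) {
      cell(cts_f);
      if (c.bidir1) cell(cts_b);
    }
    cell(l2_f);
    if (c.bidir2) cell(l2_b);
    f(lin1_W);
    f(lin1_b);
    f(lin2_W);
    f(lin2_b);
  }
};

struct CnnParams {
  mat c1_W, c2_W, lin_W;
  vec c1_b, c2_b, lin_b;

  void parse(const Rcpp::List& p) {
    c1_W = Rcpp::as<mat>(p["conv1_W"]);
    c1_b = Rcpp::as<vec>(p["conv1_b"]);
    c2_W = Rcpp::as<mat>(p["conv2_W"]);
    c2_b = Rcpp::as<vec>(p["conv2_b"]);
    lin_W = Rcpp::as<mat>(p["lin_W"]);
    lin_b = Rcpp::as<vec>(p["lin_b"]);
  }
  Rcpp::List as_list() const {
    return Rcpp::List::create(
        Rcpp::Named("conv1_W") = c1_W, Rcpp::Named("conv1_b") = c1_b,
        Rcpp::Named("conv2_W") = c2_W, Rcpp::Named("conv2_b") = c2_b,
        Rcpp::Named("lin_W") = lin_W, Rcpp::Named("lin_b") = lin_b);
  }
  void zeros_like(const CnnParams& o) {
    c1_W.zeros(o.c1_W.n_rows, o.c1_W.n_cols);
    c1_b.zeros(o.c1_b.n_elem);
    c2_W.zeros(o.c2_W.n_rows, o.c2_W.n_cols);
    c2_b.zeros(o.c2_b.n_elem);
    lin_W.zeros(o.lin_W.n_rows, o.lin_W.n_cols);
    lin_b.zeros(o.lin_b.n_elem);
  }
  template <typename F>
  void each(F f) {
    f(c1_W); f(c1_b); f(c2_W); f(c2_b); f(lin_W); f(lin_b);
  }
};

// ---------------- recurrent network forward/backward ---------------------

struct RecCache {
  LayerCache mi, cts, l2;
  mat Z;        // 60 x w1 concatenated layer-1 output
  arma::uvec pool_arg;  // per-feature argmax rows (max pooling)
  vec pooled, u_pre, u;
  vec logits;
};

static void rec_forward(const mat& Xmi, const mat& Xcts, const RecParams& P,
                        const NetConfig& c, RecCache& rc) {
  layer_forward(Xmi, P.mi_f, c.bidir1 ? &P.mi_b : nullptr, rc.mi);
  const CellParams& bf = c.share ? P.mi_f : P.cts_f;
  const CellParams& bb = c.share ? P.mi_b : P.cts_b;
  layer_forward(Xcts, bf, c.bidir1 ? &bb : nullptr, rc.cts);
  rc.Z = arma::join_cols(rc.mi.out, rc.cts.out);
  layer_forward(rc.Z, P.l2_f, c.bidir2 ? &P.l2_b : nullptr, rc.l2);
  const int T = rc.Z.n_rows;
  if (c.pooling == 1) {
    rc.pool_arg = arma::index_max(rc.l2.out, 0).t();
    rc.pooled = arma::max(rc.l2.out, 0).t();
  } else if (c.pooling == 2) {
    rc.pooled = arma::mean(rc.l2.out, 0).t();
  } else if (c.bidir2) {
    // forward summary at the last position, backward summary at position 1
    rc.pooled = arma::join_cols(rc.l2.fwd.H.row(T - 1).t(), rc.l2.bwd.H.row(T - 1).t());
  } else {
    rc.pooled = rc.l2.fwd.H.row(T - 1).t();
  }
  rc.u_pre = P.lin1_W * rc.pooled + P.lin1_b;
  rc.u = arma::clamp(rc.u_pre, 0.0, arma::datum::inf);
  rc.logits = P.lin2_W * rc.u + P.lin2_b;
}

static void rec_backward(const mat& Xmi, const mat& Xcts, const RecParams& P,
                         const NetConfig& c, const RecCache& rc,
                         const vec& dlogits, RecParams& G) {
  G.lin2_W += dlogits * rc.u.t();
  G.lin2_b += dlogits;
  vec du = P.lin2_W.t() * dlogits;
  du.elem(arma::find(rc.u_pre <= 0.0)).zeros();
  G.lin1_W += du * rc.pooled.t();
  G.lin1_b += du;
  vec dpooled = P.lin1_W.t() * du;
  const int T = rc.Z.n_rows;
  const int h2 = P.l2_f.hidden;
  mat dM2(T, (c.bidir2 ? 2 : 1) * h2, arma::fill::zeros);
  if (c.pooling == 1) {
    for (arma::uword j = 0; j < dM2.n_cols; ++j)
      dM2(rc.pool_arg[j], j) += dpooled[j];
  } else if (c.pooling == 2) {
    for (arma::uword j = 0; j < dM2.n_cols; ++j)
      dM2.col(j).fill(dpooled[j] / T);
  } else if (c.bidir2) {
    // fwd summary lives at aligned row T-1 (left half); bwd summary is the
    // bwd cell's last computed state, i.e. aligned row 0 (right half)
    dM2.row(T - 1).cols(0, h2 - 1) = dpooled.subvec(0, h2 - 1).t();
    dM2.row(0).cols(h2, 2 * h2 - 1) = dpooled.subvec(h2, 2 * h2 - 1).t();
  } else {
    dM2.row(T - 1) = dpooled.t();
  }
  mat dZ;
  layer_backward(rc.Z, P.l2_f, c.bidir2 ? &P.l2_b : nullptr, rc.l2, dM2,
                 G.l2_f, c.bidir2 ? &G.l2_b : nullptr, dZ);
  const int Tmi = Xmi.n_rows;
  mat dMi = dZ.rows(0, Tmi - 1);
  mat dCts = dZ.rows(Tmi, T - 1);
  mat dXmi, dXcts;
  layer_backward(Xmi, P.mi_f, c.bidir1 ? &P.mi_b : nullptr, rc.mi, dMi,
                 G.mi_f, c.bidir1 ? &G.mi_b : nullptr, dXmi);
  if (c.share) {
    layer_backward(Xcts, P.mi_f, c.bidir1 ? &P.mi_b : nullptr, rc.cts, dCts,
                   G.mi_f, c.bidir1 ? &G.mi_b : nullptr, dXcts);
  } else {
    layer_backward(Xcts, P.cts_f, c.bidir1 ? &P.cts_b : nullptr, rc.cts, dCts,
                   G.cts_f, c.bidir1 ? &G.cts_b : nullptr, dXcts);
  }
}

// ---------------- cnn1d forward/backward ---------------------------------

struct CnnCache {
  mat X;       // 60 x d concatenated input
  mat col1;    // im2col of X
  mat A1;      // conv1 pre-activation
  mat R1;      // relu
  mat P1;      // pooled
  arma::umat arg1;
  mat col2, A2, R2, P2;
  arma::umat arg2;
  vec flatv;
  vec logits;
};

static mat im2col(const mat& X, int K) {
  const int T = X.n_rows, d = X.n_cols, To = T - K + 1;
  mat C(To, K * d);
  for (int t = 0; t < To; ++t)
    for (int k = 0; k < K; ++k)
      C.row(t).cols(k * d, (k + 1) * d - 1) = X.row(t + k);
  return C;
}

static void maxpool(const mat& A, int p, mat& P, arma::umat& arg) {
  const int To = A.n_rows / p, F = A.n_cols;
  P.set_size(To, F);
  arg.set_size(To, F);
  for (int t = 0; t < To; ++t)
    for (int f = 0; f < F; ++f) {
      int best = t * p;
      for (int j = 1; j < p; ++j)
        if (A(t * p + j, f) > A(best, f)) best = t * p + j;
      arg(t, f) = best;
      P(t, f) = A(best, f);
    }
}

static void cnn_forward(const mat& Xmi, const mat& Xcts, const CnnParams& P,
                        const NetConfig& c, CnnCache& cc) {
  cc.X = arma::join_cols(Xmi, Xcts);
  cc.col1 = im2col(cc.X, c.kernel);
  cc.A1 = cc.col1 * P.c1_W.t();
  cc.A1.each_row() += P.c1_b.t();
  cc.R1 = arma::clamp(cc.A1, 0.0, arma::datum::inf);
  maxpool(cc.R1, c.pool, cc.P1, cc.arg1);
  cc.col2 = im2col(cc.P1, c.kernel);
  cc.A2 = cc.col2 * P.c2_W.t();
  cc.A2.each_row() += P.c2_b.t();
  cc.R2 = arma::clamp(cc.A2, 0.0, arma::datum::inf);
  maxpool(cc.R2, c.pool, cc.P2, cc.arg2);
  cc.flatv = arma::vectorise(cc.P2);
  cc.logits = P.lin_W * cc.flatv + P.lin_b;
}

static void cnn_backward(const CnnParams& P, const NetConfig& c, const CnnCache& cc,
                         const vec& dlogits, CnnParams& G) {
  G.lin_W += dlogits * cc.flatv.t();
  G.lin_b += dlogits;
  vec dflat = P.lin_W.t() * dlogits;
  mat dP2(arma::size(cc.P2), arma::fill::zeros);
  dP2 = arma::reshape(dflat, cc.P2.n_rows, cc.P2.n_cols);
  mat dR2(arma::size(cc.R2), arma::fill::zeros);
  for (arma::uword t = 0; t < cc.P2.n_rows; ++t)
    for (arma::uword f = 0; f < cc.P2.n_cols; ++f)
      dR2(cc.arg2(t, f), f) += dP2(t, f);
  mat dA2 = dR2;
  dA2.elem(arma::find(cc.A2 <= 0.0)).zeros();
  G.c2_W += dA2.t() * cc.col2;
  G.c2_b += arma::sum(dA2, 0).t();
  mat dcol2 = dA2 * P.c2_W;
  // un-im2col
  mat dP1(arma::size(cc.P1), arma::fill::zeros);
  const int d1 = cc.P1.n_cols;
  for (arma::uword t = 0; t < dcol2.n_rows; ++t)
    for (int k = 0; k < c.kernel; ++k)
      dP1.row(t + k) += dcol2.row(t).cols(k * d1, (k + 1) * d1 - 1);
  mat dR1(arma::size(cc.R1), arma::fill::zeros);
  for (arma::uword t = 0; t < cc.P1.n_rows; ++t)
    for (arma::uword f = 0; f < cc.P1.n_cols; ++f)
      dR1(cc.arg1(t, f), f) += dP1(t, f);
  mat dA1 = dR1;
  dA1.elem(arma::find(cc.A1 <= 0.0)).zeros();
  G.c1_W += dA1.t() * cc.col1;
  G.c1_b += arma::sum(dA1, 0).t();
}

// ---------------- exported entry points -----------------------------------

static vec softmax_vec(const vec& z) {
  vec e = arma::exp(z - z.max());
  return e / arma::accu(e);
}

// weighted CE from logits (log-sum-exp)
static double wce(const vec& logits, int label, const vec& w) {
  double m = logits.max();
  double lse = m + std::log(arma::accu(arma::exp(logits - m)));
  return -w[label] * (logits[label] - lse);
}

// [[Rcpp::export]]
arma::mat cpp_model_forward(const arma::cube& Xmi, const arma::cube& Xcts,
                            const Rcpp::List& params, const Rcpp::List& config) {
  NetConfig c = NetConfig::parse(config);
  const int n = Xmi.n_slices;
  mat out(n, 2);
  if (c.kind == "recurrent") {
    RecParams P;
    P.parse(params, c);
    RecCache rc;
    for (int i = 0; i < n; ++i) {
      rec_forward(Xmi.slice(i), Xcts.slice(i), P, c, rc);
      out.row(i) = rc.logits.t();
    }
  } else {
    CnnParams P;
    P.parse(params);
    CnnCache cc;
    for (int i = 0; i < n; ++i) {
      cnn_forward(Xmi.slice(i), Xcts.slice(i), P, c, cc);
      out.row(i) = cc.logits.t();
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_model_loss_grad(const arma::cube& Xmi, const arma::cube& Xcts,
                               const arma::ivec& labels, const arma::vec& weights,
                               const Rcpp::List& params, const Rcpp::List& config) {
  NetConfig c = NetConfig::parse(config);
  const int n = Xmi.n_slices;
  double loss = 0.0;
  if (c.kind == "recurrent") {
    RecParams P, G;
    P.parse(params, c);
    G.zeros_like(P, c);
    RecCache rc;
    for (int i = 0; i < n; ++i) {
      rec_forward(Xmi.slice(i), Xcts.slice(i), P, c, rc);
      int y = labels[i];
      loss += wce(rc.logits, y, weights) / n;
      vec dl = softmax_vec(rc.logits) * weights[y];
      dl[y] -= weights[y];
      dl /= n;
      rec_backward(Xmi.slice(i), Xcts.slice(i), P, c, rc, dl, G);
    }
    return Rcpp::List::create(Rcpp::Named("loss") = loss,
                              Rcpp::Named("grads") = G.as_list(c));
  } else {
    CnnParams P, G;
    P.parse(params);
    G.zeros_like(P);
    CnnCache cc;
    for (int i = 0; i < n; ++i) {
      cnn_forward(Xmi.slice(i), Xcts.slice(i), P, c, cc);
      int y = labels[i];
      loss += wce(cc.logits, y, weights) / n;
      vec dl = softmax_vec(cc.logits) * weights[y];
      dl[y] -= weights[y];
      dl /= n;
      cnn_backward(P, c, cc, dl, G);
    }
    return Rcpp::List::create(Rcpp::Named("loss") = loss,
                              Rcpp::Named("grads") = G.as_list());
  }
}

// Direct single-layer entry for cross-checks against the R reference.
// [[Rcpp::export]]
arma::mat cpp_cell_forward(const arma::mat& X, const Rcpp::List& params,
                           const std::string& type, bool bidir) {
  CellType ty = cell_from_string(type);
  CellParams Pf;
  if (bidir) {
    CellParams Pb;
    Pf.parse(params["fwd"], ty);
    Pb.parse(params["bwd"], ty);
    LayerCache lc;
    layer_forward(X, Pf, &Pb, lc);
    return lc.out;
  }
  Pf.parse(params, ty);
  LayerCache lc;
  layer_forward(X, Pf, nullptr, lc);
  return lc.out;
}


// ---------------- Adam training loop --------------------------------------

struct ParamRefs {
  std::vector<mat*> M;
  std::vector<vec*> V;
};

static void collect_cell(CellParams& p, ParamRefs& r) {
  for (auto& w : p.W) r.M.push_back(&w);
  for (auto& b : p.b) r.V.push_back(&b);
}

static void collect_rec(RecParams& P, const NetConfig& c, ParamRefs& r) {
  collect_cell(P.mi_f, r);
  if (c.bidir1) collect_cell(P.mi_b, r);
  if (!c.share) {
    collect_cell(P.cts_f, r);
    if (c.bidir1) collect_cell(P.cts_b, r);
  }
  collect_cell(P.l2_f, r);
  if (c.bidir2) collect_cell(P.l2_b, r);
  r.M.push_back(&P.lin1_W);
  r.V.push_back(&P.lin1_b);
  r.M.push_back(&P.lin2_W);
  r.V.push_back(&P.lin2_b);
}

static void collect_cnn(CnnParams& P, ParamRefs& r) {
  r.M.push_back(&P.c1_W);
  r.V.push_back(&P.c1_b);
  r.M.push_back(&P.c2_W);
  r.V.push_back(&P.c2_b);
  r.M.push_back(&P.lin_W);
  r.V.push_back(&P.lin_b);
}

// One Adam (or SGD) run over the dataset; fwd/bwd close over the model
// parameters, their gradients and a per-example cache.
template <typename Fwd, typename Bwd, typename Pred, typename ToList>
static Rcpp::List train_loop(int n, const arma::ivec& labels,
                             const arma::imat& shuffles, double lr, int batch,
                             int epochs, bool adam, double beta1, double beta2,
                             double eps, double clip, const vec& weights,
                             bool has_val, const cube& Vmi, const cube& Vcts,
                             const arma::ivec& Vlab, ParamRefs& pr,
                             ParamRefs& gr, Fwd fwd, Bwd bwd, Pred pred,
                             ToList to_list) {
  std::vector<mat> Mm, Vm;
  std::vector<vec> Mv, Vv;
  for (auto* m : pr.M) {
    Mm.emplace_back(arma::size(*m), arma::fill::zeros);
    Vm.emplace_back(arma::size(*m), arma::fill::zeros);
  }
  for (auto* v : pr.V) {
    Mv.emplace_back(arma::size(*v), arma::fill::zeros);
    Vv.emplace_back(arma::size(*v), arma::fill::zeros);
  }
  vec ep_loss(epochs, arma::fill::zeros), ep_acc(epochs, arma::fill::zeros),
      ep_val(epochs, arma::fill::value(arma::datum::nan));
  long long tstep = 0;
  double best_val = -1.0;
  Rcpp::List best_params = R_NilValue;

  for (int e = 0; e < epochs; ++e) {
    double lsum = 0.0;
    int correct = 0;
    for (int start = 0; start < n; start += batch) {
      const int bend = std::min(start + batch, n);
      const int bs = bend - start;
      for (auto* g : gr.M) g->zeros();
      for (auto* g : gr.V) g->zeros();
      for (int bi = start; bi < bend; ++bi) {
        const int i = shuffles(bi, e);
        const int y = labels[i];
        vec logits = fwd(i);
        if (!logits.is_finite())
          Rcpp::stop("non-finite activations in batch starting at example %d of epoch %d",
                     start + 1, e + 1);
        lsum += wce(logits, y, weights);
        if ((logits[1] >= logits[0]) == (y == 1)) ++correct;
        vec dl = softmax_vec(logits) * weights[y];
        dl[y] -= weights[y];
        dl /= bs;
        bwd(i, dl);
      }
      if (clip > 0.0) {
        double nrm2 = 0.0;
        for (auto* g : gr.M) nrm2 += arma::accu((*g) % (*g));
        for (auto* g : gr.V) nrm2 += arma::accu((*g) % (*g));
        const double nrm = std::sqrt(nrm2);
        if (nrm > clip) {
          for (auto* g : gr.M) (*g) *= clip / nrm;
          for (auto* g : gr.V) (*g) *= clip / nrm;
        }
      }
      ++tstep;
      if (adam) {
        const double bc1 = 1.0 - std::pow(beta1, (double)tstep);
        const double bc2 = 1.0 - std::pow(beta2, (double)tstep);
        for (size_t k = 0; k < pr.M.size(); ++k) {
          Mm[k] = beta1 * Mm[k] + (1.0 - beta1) * (*gr.M[k]);
          Vm[k] = beta2 * Vm[k] + (1.0 - beta2) * ((*gr.M[k]) % (*gr.M[k]));
          (*pr.M[k]) -= lr * (Mm[k] / bc1) / (arma::sqrt(Vm[k] / bc2) + eps);
        }
        for (size_t k = 0; k < pr.V.size(); ++k) {
          Mv[k] = beta1 * Mv[k] + (1.0 - beta1) * (*gr.V[k]);
          Vv[k] = beta2 * Vv[k] + (1.0 - beta2) * ((*gr.V[k]) % (*gr.V[k]));
          (*pr.V[k]) -= lr * (Mv[k] / bc1) / (arma::sqrt(Vv[k] / bc2) + eps);
        }
      } else {
        for (size_t k = 0; k < pr.M.size(); ++k) (*pr.M[k]) -= lr * (*gr.M[k]);
        for (size_t k = 0; k < pr.V.size(); ++k) (*pr.V[k]) -= lr * (*gr.V[k]);
      }
    }
    ep_loss[e] = lsum / n;
    ep_acc[e] = (double)correct / n;
    if (has_val) {
      int vc = 0;
      for (arma::uword i = 0; i < Vmi.n_slices; ++i) {
        vec lg = pred(Vmi.slice(i), Vcts.slice(i));
        if ((lg[1] >= lg[0]) == (Vlab[i] == 1)) ++vc;
      }
      ep_val[e] = (double)vc / Vmi.n_slices;
      if (ep_val[e] > best_val) {
        best_val = ep_val[e];
        best_params = to_list();
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = to_list(), Rcpp::Named("loss") = ep_loss,
      Rcpp::Named("train_acc") = ep_acc, Rcpp::Named("val_acc") = ep_val,
      Rcpp::Named("best_params") = best_params);
}

// [[Rcpp::export]]
Rcpp::List cpp_model_train(const arma::cube& Xmi, const arma::cube& Xcts,
                           const arma::ivec& labels, const Rcpp::List& params,
                           const Rcpp::List& config, const Rcpp::List& train,
                           const arma::imat& shuffles,
                           Rcpp::Nullable<Rcpp::NumericVector> val_mi = R_NilValue,
                           Rcpp::Nullable<Rcpp::NumericVector> val_cts = R_NilValue,
                           Rcpp::Nullable<Rcpp::IntegerVector> val_labels = R_NilValue) {
  NetConfig c = NetConfig::parse(config);
  const int n = Xmi.n_slices;
  if (n == 0) Rcpp::stop("empty training set");
  const double lr = Rcpp::as<double>(train["lr"]);
  const int batch = Rcpp::as<int>(train["batch"]);
  const int epochs = Rcpp::as<int>(train["epochs"]);
  const bool adam = Rcpp::as<bool>(train["adam"]);
  const double beta1 = Rcpp::as<double>(train["beta1"]);
  const double beta2 = Rcpp::as<double>(train["beta2"]);
  const double eps = Rcpp::as<double>(train["eps"]);
  const double clip = Rcpp::as<double>(train["clip"]);
  const vec weights = Rcpp::as<vec>(train["weights"]);
  if ((int)shuffles.n_rows != n || (int)shuffles.n_cols != epochs)
    Rcpp::stop("shuffle matrix must be n x epochs");

  const bool has_val = val_mi.isNotNull();
  cube Vmi, Vcts;
  arma::ivec Vlab;
  if (has_val) {
    Rcpp::NumericVector vm(val_mi), vc_(val_cts);
    Rcpp::IntegerVector dm = vm.attr("dim"), dc = vc_.attr("dim");
    Vmi = cube(vm.begin(), dm[0], dm[1], dm[2]);
    Vcts = cube(vc_.begin(), dc[0], dc[1], dc[2]);
    Vlab = Rcpp::as<arma::ivec>(Rcpp::IntegerVector(val_labels));
  }

  if (c.kind == "recurrent") {
    RecParams P, G;
    P.parse(params, c);
    G.zeros_like(P, c);
    ParamRefs pr, gr;
    collect_rec(P, c, pr);
    collect_rec(G, c, gr);
    RecCache rc;
    return train_loop(
        n, labels, shuffles, lr, batch, epochs, adam, beta1, beta2, eps, clip,
        weights, has_val, Vmi, Vcts, Vlab, pr, gr,
        [&](int i) {
          rec_forward(Xmi.slice(i), Xcts.slice(i), P, c, rc);
          return rc.logits;
        },
        [&](int i, const vec& dl) {
          rec_backward(Xmi.slice(i), Xcts.slice(i), P, c, rc, dl, G);
        },
        [&](const mat& xm, const mat& xc) {
          RecCache tmp;
          rec_forward(xm, xc, P, c, tmp);
          return tmp.logits;
        },
        [&]() { return P.as_list(c); });
  } else {
    CnnParams P, G;
    P.parse(params);
    G.zeros_like(P);
    ParamRefs pr, gr;
    collect_cnn(P, pr);
    collect_cnn(G, gr);
    CnnCache cc;
    return train_loop(
        n, labels, shuffles, lr, batch, epochs, adam, beta1, beta2, eps, clip,
        weights, has_val, Vmi, Vcts, Vlab, pr, gr,
        [&](int i) {
          cnn_forward(Xmi.slice(i), Xcts.slice(i), P, c, cc);
          return cc.logits;
        },
        [&](int i, const vec& dl) { cnn_backward(P, c, cc, dl, G); },
        [&](const mat& xm, const mat& xc) {
          CnnCache tmp;
          cnn_forward(xm, xc, P, c, tmp);
          return tmp.logits;
        },
        [&]() { return P.as_list(); });
  }
}
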