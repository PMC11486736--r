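// Training core for the bipartite graph network.
//
// The graph is complete bipartite: n observation nodes x m1 feature nodes,
// one edge per table cell, observation index fastest in the edge order.
// Edge embeddings after layer l are pure concatenations
//   e^l = [Vo^l_i, Vf^l_j, e^{l-1}]  (recursively down to the scalar edge
// weight e^0), so they are never materialized: every product of the edge
// matrix with layer weights decomposes into small per-block GEMMs against
// the node embedding matrices followed by row expansions, and every
// gradient through the edge matrix decomposes into grouped sums followed by
// small GEMMs. This keeps the per-epoch cost at O(L^2) small matrix
// products plus O(L * n_edges * hidden) memory-bound passes.
//
// Node update per layer (degree-normalized neighbor aggregation; the
// neighborhood size is constant per node type in the complete graph, so
// this equals the plain sum with the constant absorbed into L_B):
//   V_i' = relu(L_B[ mean_j relu(L_A[V_j, e_ij]), V_i ])
// Gradients are hand-derived reverse mode; optimizer is Adam. All
// randomness (dropout, per-epoch re-hiding) draws from R's RNG so runs are
// reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Layer {
  mat Wa; rowvec ba; mat Wb; rowvec bb; double p;
};

struct Head {
  mat W1; rowvec b1; vec W2; double b2;
};

struct Grads {
  std::vector<mat> Wa, Wb;
  std::vector<rowvec> ba, bb;
  mat W1; rowvec b1; vec W2; double b2;
};

// everything the backward pass needs from one forward pass
struct ForwardState {
  std::vector<mat> Vo, Vf;      // [0..L] node embeddings (post-dropout)
  std::vector<mat> Mo, Mf;      // [1..L] post-relu messages (ne x h)
  std::vector<mat> Bo, Bf;      // [1..L] inputs to L_B
  std::vector<mat> Ro, Rf;      // [1..L] relu masks of L_B pre-activations
  std::vector<mat> Do, Df;      // [1..L] dropout masks (empty if unused)
  vec e0;                       // initial edge weights (length ne)
};

std::vector<Layer> layers_from_list(const Rcpp::List& params) {
  Rcpp::List lys = params["layers"];
  std::vector<Layer> out(lys.size());
  for (int l = 0; l < lys.size(); ++l) {
    Rcpp::List ll = lys[l];
    out[l].Wa = Rcpp::as<mat>(ll["Wa"]);
    out[l].ba = Rcpp::as<rowvec>(ll["ba"]);
    out[l].Wb = Rcpp::as<mat>(ll["Wb"]);
    out[l].bb = Rcpp::as<rowvec>(ll["bb"]);
    out[l].p  = Rcpp::as<double>(ll["p"]);
  }
  return out;
}

Head head_from_list(const Rcpp::List& params) {
  Rcpp::List h = params["head"];
  Head out;
  out.W1 = Rcpp::as<mat>(h["W1"]);
  out.b1 = Rcpp::as<rowvec>(h["b1"]);
  out.W2 = Rcpp::as<vec>(h["W2"]);
  out.b2 = Rcpp::as<double>(h["b2"]);
  return out;
}

Rcpp::List layers_to_list(const std::vector<Layer>& layers) {
  Rcpp::List out(layers.size());
  for (size_t l = 0; l < layers.size(); ++l) {
    out[l] = Rcpp::List::create(
      Rcpp::Named("Wa") = layers[l].Wa, Rcpp::Named("ba") = layers[l].ba,
      Rcpp::Named("Wb") = layers[l].Wb, Rcpp::Named("bb") = layers[l].bb,
      Rcpp::Named("p") = layers[l].p);
  }
  return out;
}

// out(g, c) = sum over edges k with idx[k] == g of X(k, c)
mat group_sum(const mat& X, const uvec& idx, uword ng) {
  mat out(ng, X.n_cols, fill::zeros);
  for (uword c = 0; c < X.n_cols; ++c) {
    const double* xc = X.colptr(c);
    double* oc = out.colptr(c);
    for (uword k = 0; k < X.n_rows; ++k) oc[idx[k]] += xc[k];
  }
  return out;
}

// add S.rows(idx) to X in place
void add_expanded(mat& X, const mat& S, const uvec& idx) {
  for (uword c = 0; c < X.n_cols; ++c) {
    const double* sc = S.colptr(c);
    double* xc = X.colptr(c);
    for (uword k = 0; k < X.n_rows; ++k) xc[k] += sc[idx[k]];
  }
}

void relu_inplace(mat& X) {
  X.transform([](double z) { return z > 0 ? z : 0.0; });
}

mat dropout_mask(uword nr, uword nc, double p) {
  mat m(nr, nc);
  const double scale = 1.0 / (1.0 - p);
  for (uword j = 0; j < nc; ++j)
    for (uword i = 0; i < nr; ++i)
      m(i, j) = (R::unif_rand() >= p) ? scale : 0.0;
  return m;
}

// E_in of layer l (1-based) is the concatenation of blocks
// [Vo^{l-1}, Vf^{l-1}, ..., Vo^1, Vf^1] (h columns each) then e0 (1 column);
// the corresponding rows of Wa start right after the d_v node block.
// Accumulates P = E_in * Wa_e into a preallocated ne x h matrix.
void edge_times_weights(const ForwardState& fs, const Layer& L, int l,
                        uword dv, const uvec& oidx, const uvec& fidx,
                        mat& P) {
  P.zeros();
  uword off = dv;
  const uword h = L.Wb.n_cols;
  for (int k = l - 1; k >= 1; --k) {
    {
      mat small = fs.Vo[k] * L.Wa.rows(off, off + h - 1);
      add_expanded(P, small, oidx);
      off += h;
    }
    {
      mat small = fs.Vf[k] * L.Wa.rows(off, off + h - 1);
      add_expanded(P, small, fidx);
      off += h;
    }
  }
  P += fs.e0 * L.Wa.row(off);  // ne x 1 times 1 x h
}

// forward through all layers; fills fs (Vo[0]/Vf[0]/e0 must be set)
void forward_layers(const std::vector<Layer>& layers, ForwardState& fs,
                    const uvec& oidx, const uvec& fidx, bool training) {
  const uword n = fs.Vo[0].n_rows, m1 = fs.Vf[0].n_rows;
  const uword ne = fs.e0.n_elem;
  const size_t L = layers.size();
  fs.Vo.resize(L + 1); fs.Vf.resize(L + 1);
  fs.Mo.resize(L + 1); fs.Mf.resize(L + 1);
  fs.Bo.resize(L + 1); fs.Bf.resize(L + 1);
  fs.Ro.resize(L + 1); fs.Rf.resize(L + 1);
  fs.Do.resize(L + 1); fs.Df.resize(L + 1);

  for (size_t l = 1; l <= L; ++l) {
    const Layer& Ly = layers[l - 1];
    const uword dv = fs.Vo[l - 1].n_cols;
    const uword h = Ly.Wb.n_cols;

    mat P(ne, h);
    edge_times_weights(fs, Ly, (int)l, dv, oidx, fidx, P);

    mat Mo = P;              // shared edge term feeds both directions
    mat Mf = std::move(P);
    {
      mat small = fs.Vf[l - 1] * Ly.Wa.rows(0, dv - 1);
      add_expanded(Mo, small, fidx);
    }
    {
      mat small = fs.Vo[l - 1] * Ly.Wa.rows(0, dv - 1);
      add_expanded(Mf, small, oidx);
    }
    Mo.each_row() += Ly.ba; relu_inplace(Mo);
    Mf.each_row() += Ly.ba; relu_inplace(Mf);

    mat Bo = join_rows(group_sum(Mo, oidx, n) / (double)m1, fs.Vo[l - 1]);
    mat Bf = join_rows(group_sum(Mf, fidx, m1) / (double)n, fs.Vf[l - 1]);
    mat Zo = Bo * Ly.Wb; Zo.each_row() += Ly.bb;
    mat Zf = Bf * Ly.Wb; Zf.each_row() += Ly.bb;
    mat Ro = conv_to<mat>::from(Zo > 0);
    mat Rf = conv_to<mat>::from(Zf > 0);
    Zo %= Ro; Zf %= Rf;
    if (training && Ly.p > 0) {
      fs.Do[l] = dropout_mask(Zo.n_rows, Zo.n_cols, Ly.p);
      fs.Df[l] = dropout_mask(Zf.n_rows, Zf.n_cols, Ly.p);
      Zo %= fs.Do[l]; Zf %= fs.Df[l];
    } else {
      fs.Do[l].reset(); fs.Df[l].reset();
    }
    fs.Mo[l] = std::move(Mo); fs.Mf[l] = std::move(Mf);
    fs.Bo[l] = std::move(Bo); fs.Bf[l] = std::move(Bf);
    fs.Ro[l] = std::move(Ro); fs.Rf[l] = std::move(Rf);
    fs.Vo[l] = std::move(Zo); fs.Vf[l] = std::move(Zf);
  }
}

vec head_forward(const Head& H, const mat& Vo, const mat& Vf,
                 const uvec& pi, const uvec& pj, mat& Hin, mat& Z1) {
  Hin = join_rows(Vo.rows(pi), Vf.rows(pj));
  Z1 = Hin * H.W1;
  Z1.each_row() += H.b1;
  relu_inplace(Z1);
  return Z1 * H.W2 + H.b2;
}

double loss_and_grad(const vec& pred, const vec& target, int kind,
                     double alpha, bool signed_variant, vec& gpred) {
  vec d = pred - target;
  const uword n = d.n_elem;
  gpred.set_size(n);
  double total = 0.0;
  for (uword i = 0; i < n; ++i) {
    double di = d[i], s = (di > 0) - (di < 0);
    if (kind == 0) {            // L1
      total += std::abs(di);
      gpred[i] = s;
    } else if (kind == 1) {     // L2
      total += di * di;
      gpred[i] = 2.0 * di;
    } else {                    // gradient-harmonized L1
      double q = di * di + alpha * alpha;
      double rq = std::sqrt(q);
      double harm = signed_variant ? di / rq : std::abs(di) / rq;
      total += std::abs(di) + harm;
      double dh = alpha * alpha / (q * rq);
      gpred[i] = s + (signed_variant ? dh : s * dh);
    }
  }
  gpred /= (double)n;
  return total / (double)n;
}

Grads zero_grads(const std::vector<Layer>& layers, const Head& H) {
  Grads G;
  G.Wa.resize(layers.size()); G.Wb.resize(layers.size());
  G.ba.resize(layers.size()); G.bb.resize(layers.size());
  for (size_t l = 0; l < layers.size(); ++l) {
    G.Wa[l] = zeros(size(layers[l].Wa));
    G.ba[l] = zeros<rowvec>(layers[l].ba.n_elem);
    G.Wb[l] = zeros(size(layers[l].Wb));
    G.bb[l] = zeros<rowvec>(layers[l].bb.n_elem);
  }
  G.W1 = zeros(size(H.W1));
  G.b1 = zeros<rowvec>(H.b1.n_elem);
  G.W2 = zeros<vec>(H.W2.n_elem);
  G.b2 = 0.0;
  return G;
}

// full backward; fills G (assumed zeroed)
void backward_all(const std::vector<Layer>& layers, const ForwardState& fs,
                  const Head& H, const uvec& oidx, const uvec& fidx,
                  const mat& Hin, const mat& Z1,
                  const uvec& pi, const uvec& pj, const vec& gpred,
                  Grads& G) {
  const size_t L = layers.size();
  const uword n = fs.Vo[0].n_rows, m1 = fs.Vf[0].n_rows;
  const uword h = H.W2.n_elem;

  // head
  mat gZ1 = gpred * H.W2.t();
  gZ1 %= conv_to<mat>::from(Z1 > 0);
  G.W2 += Z1.t() * gpred;
  G.b2 += accu(gpred);
  G.W1 += Hin.t() * gZ1;
  G.b1 += sum(gZ1, 0);
  mat gHin = gZ1 * H.W1.t();

  // per-layer accumulators for node-embedding gradients
  std::vector<mat> gVo(L + 1), gVf(L + 1);
  for (size_t l = 1; l <= L; ++l) {
    gVo[l] = zeros(n, layers[l - 1].Wb.n_cols);
    gVf[l] = zeros(m1, layers[l - 1].Wb.n_cols);
  }
  for (uword k = 0; k < pi.n_elem; ++k) {
    gVo[L].row(pi[k]) += gHin(k, span(0, h - 1));
    gVf[L].row(pj[k]) += gHin(k, span(h, 2 * h - 1));
  }

  for (int l = (int)L; l >= 1; --l) {
    const Layer& Ly = layers[l - 1];
    const uword dv = fs.Vo[l - 1].n_cols;
    const uword hh = Ly.Wb.n_cols;

    mat go = gVo[l], gf = gVf[l];
    if (fs.Do[l].n_elem > 0) { go %= fs.Do[l]; gf %= fs.Df[l]; }
    go %= fs.Ro[l]; gf %= fs.Rf[l];
    G.Wb[l - 1] += fs.Bo[l].t() * go + fs.Bf[l].t() * gf;
    G.bb[l - 1] += sum(go, 0) + sum(gf, 0);
    mat gBo = go * Ly.Wb.t();
    mat gBf = gf * Ly.Wb.t();
    if (l >= 2) {
      gVo[l - 1] += gBo.cols(hh, hh + dv - 1);
      gVf[l - 1] += gBf.cols(hh, hh + dv - 1);
    }

    // messages: gMo = expand(gSo / m1) masked by relu
    mat gSo = gBo.cols(0, hh - 1) / (double)m1;
    mat gSf = gBf.cols(0, hh - 1) / (double)n;
    mat gMo(fs.Mo[l].n_rows, hh, fill::zeros);
    add_expanded(gMo, gSo, oidx);
    gMo %= conv_to<mat>::from(fs.Mo[l] > 0);
    mat gMf(fs.Mf[l].n_rows, hh, fill::zeros);
    add_expanded(gMf, gSf, fidx);
    gMf %= conv_to<mat>::from(fs.Mf[l] > 0);

    G.ba[l - 1] += sum(gMo, 0) + sum(gMf, 0);

    // node block of L_A: Mo uses Vf^{l-1} endpoints, Mf uses Vo^{l-1}
    mat gMo_f = group_sum(gMo, fidx, m1);   // m1 x h
    mat gMf_o = group_sum(gMf, oidx, n);    // n x h
    G.Wa[l - 1].rows(0, dv - 1) +=
      fs.Vf[l - 1].t() * gMo_f + fs.Vo[l - 1].t() * gMf_o;
    if (l >= 2) {
      gVf[l - 1] += gMo_f * Ly.Wa.rows(0, dv - 1).t();
      gVo[l - 1] += gMf_o * Ly.Wa.rows(0, dv - 1).t();
    }

    // edge blocks: the shared term P enters both messages, so its gradient
    // is gMo + gMf, and each concat block sees only grouped sums of it
    mat gP = gMo + gMf;
    mat gP_o = group_sum(gP, oidx, n);      // n x h
    mat gP_f = group_sum(gP, fidx, m1);     // m1 x h
    uword off = dv;
    for (int k = l - 1; k >= 1; --k) {
      G.Wa[l - 1].rows(off, off + hh - 1) += fs.Vo[k].t() * gP_o;
      gVo[k] += gP_o * Ly.Wa.rows(off, off + hh - 1).t();
      off += hh;
      G.Wa[l - 1].rows(off, off + hh - 1) += fs.Vf[k].t() * gP_f;
      gVf[k] += gP_f * Ly.Wa.rows(off, off + hh - 1).t();
      off += hh;
    }
    G.Wa[l - 1].row(off) += fs.e0.t() * gP;  // scalar edge-weight block
  }
}

struct Adam {
  std::vector<mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;

  void init(const std::vector<mat*>& ps) {
    m.resize(ps.size()); v.resize(ps.size());
    for (size_t i = 0; i < ps.size(); ++i) {
      m[i] = zeros(size(*ps[i]));
      v[i] = zeros(size(*ps[i]));
    }
  }
  void step(std::vector<mat*>& ps, const std::vector<mat>& gs, double lr) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < ps.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * gs[i];
      v[i] = b2 * v[i] + (1 - b2) * square(gs[i]);
      *ps[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

void make_indices(uword n, uword m1, uvec& oidx, uvec& fidx) {
  oidx = repmat(regspace<uvec>(0, n - 1), m1, 1);
  fidx.set_size(n * m1);
  for (uword j = 0; j < m1; ++j) fidx.subvec(j * n, (j + 1) * n - 1).fill(j);
}

}  // namespace

// Evaluation-mode forward pass: predictions for (pi, pj) pairs (1-based).
// [[Rcpp::export]]
arma::vec cpp_bgnn_eval(Rcpp::List params, const arma::mat& W,
                        const arma::mat& obs_init,
                        const arma::uvec& pi, const arma::uvec& pj) {
  std::vector<Layer> layers = layers_from_list(params);
  Head H = head_from_list(params);
  const uword n = W.n_rows, m1 = W.n_cols;
  uvec oidx, fidx;
  make_indices(n, m1, oidx, fidx);

  ForwardState fs;
  fs.Vo.resize(1); fs.Vf.resize(1);
  fs.Vo[0] = obs_init; fs.Vf[0] = eye(m1, m1);
  fs.e0 = vectorise(W);
  forward_layers(layers, fs, oidx, fidx, false);
  mat Hin, Z1;
  return head_forward(H, fs.Vo.back(), fs.Vf.back(), pi - 1, pj - 1, Hin, Z1);
}

// Loss and analytic gradients for a fixed supervision set, no dropout or
// re-hiding randomness — used for finite-difference verification.
// [[Rcpp::export]]
Rcpp::List cpp_bgnn_loss_grad(Rcpp::List params, const arma::mat& W,
                              const arma::mat& obs_init,
                              const arma::uvec& pi, const arma::uvec& pj,
                              const arma::vec& target,
                              int loss_kind, double alpha, bool signed_variant) {
  std::vector<Layer> layers = layers_from_list(params);
  Head H = head_from_list(params);
  const uword n = W.n_rows, m1 = W.n_cols;
  uvec oidx, fidx;
  make_indices(n, m1, oidx, fidx);

  ForwardState fs;
  fs.Vo.resize(1); fs.Vf.resize(1);
  fs.Vo[0] = obs_init; fs.Vf[0] = eye(m1, m1);
  fs.e0 = vectorise(W);
  forward_layers(layers, fs, oidx, fidx, false);
  mat Hin, Z1;
  uvec pi0 = pi - 1, pj0 = pj - 1;
  vec pred = head_forward(H, fs.Vo.back(), fs.Vf.back(), pi0, pj0, Hin, Z1);
  vec gpred;
  double loss = loss_and_grad(pred, target, loss_kind, alpha, signed_variant,
                              gpred);
  Grads G = zero_grads(layers, H);
  backward_all(layers, fs, H, oidx, fidx, Hin, Z1, pi0, pj0, gpred, G);

  Rcpp::List glayers(layers.size());
  for (size_t l = 0; l < layers.size(); ++l) {
    glayers[l] = Rcpp::List::create(
      Rcpp::Named("Wa") = G.Wa[l], Rcpp::Named("ba") = G.ba[l],
      Rcpp::Named("Wb") = G.Wb[l], Rcpp::Named("bb") = G.bb[l]);
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("pred") = pred,
    Rcpp::Named("layers") = glayers,
    Rcpp::Named("head") = Rcpp::List::create(
      Rcpp::Named("W1") = G.W1, Rcpp::Named("b1") = G.b1,
      Rcpp::Named("W2") = G.W2, Rcpp::Named("b2") = G.b2));
}

// Full training loop.
//   W, obs_init:    base graph (test-row yields already zeroed)
//   yrows, ytarget: supervised yield rows (1-based) and standardized targets
//   fcells:         K x 2 (1-based) observed feature cells available for
//                   per-epoch re-hiding, with standardized values fvalues
//   rehide_rate:    per-epoch probability a candidate feature cell is hidden
//                   from the input and supervised
//   yield_hide:     per-epoch probability a supervised yield edge is hidden
//                   from the *input* (supervision unchanged)
// Loss: mean yield loss + lambda * mean re-hidden-cell loss.
// [[Rcpp::export]]
Rcpp::List cpp_bgnn_train(Rcpp::List params, const arma::mat& W,
                          const arma::mat& obs_init,
                          const arma::uvec& yrows, const arma::vec& ytarget,
                          const arma::umat& fcells, const arma::vec& fvalues,
                          double rehide_rate, double yield_hide,
                          int epochs, double lr, double lambda,
                          int loss_kind, double alpha, bool signed_variant,
                          int patience, double tol, bool verbose) {
  std::vector<Layer> layers = layers_from_list(params);
  Head H = head_from_list(params);
  const uword n = W.n_rows, m1 = W.n_cols;
  const uword ny = yrows.n_elem, K = fcells.n_rows;
  if (ny == 0 && K == 0) Rcpp::stop("no supervision: no yield rows and no feature cells");

  uvec oidx, fidx;
  make_indices(n, m1, oidx, fidx);

  // parameter registry for Adam; order: per layer Wa, ba, Wb, bb, then head
  Adam opt;
  std::vector<mat> pm;
  for (auto& L : layers) {
    pm.push_back(L.Wa); pm.push_back(mat(L.ba));
    pm.push_back(L.Wb); pm.push_back(mat(L.bb));
  }
  pm.push_back(H.W1); pm.push_back(mat(H.b1)); pm.push_back(mat(H.W2));
  pm.push_back(mat(1, 1, fill::value(H.b2)));
  std::vector<mat*> pptrs(pm.size());
  for (size_t i = 0; i < pm.size(); ++i) pptrs[i] = &pm[i];
  opt.init(pptrs);

  auto sync_from_pm = [&]() {
    size_t k = 0;
    for (auto& L : layers) {
      L.Wa = pm[k++]; L.ba = rowvec(pm[k++]);
      L.Wb = pm[k++]; L.bb = rowvec(pm[k++]);
    }
    H.W1 = pm[k++]; H.b1 = rowvec(pm[k++]); H.W2 = vectorise(pm[k++]);
    H.b2 = pm[k++](0, 0);
  };

  vec hist_total(epochs, fill::zeros), hist_yield(epochs, fill::zeros),
      hist_feat(epochs, fill::zeros);
  double best = datum::inf;
  int since_best = 0, ran = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    // --- per-epoch input hiding -------------------------------------------
    mat Wep = W;
    mat Iep = obs_init;
    std::vector<uword> hid_i, hid_k;
    for (uword k = 0; k < K; ++k) {
      if (R::unif_rand() < rehide_rate) {
        uword i = fcells(k, 0) - 1, j = fcells(k, 1) - 1;
        Wep(i, j) = 0.0;
        Iep(i, j) = 0.0;
        hid_i.push_back(i); hid_k.push_back(k);
      }
    }
    if (ny > 0 && yield_hide > 0) {
      for (uword k = 0; k < ny; ++k) {
        if (R::unif_rand() < yield_hide) {
          Wep(yrows[k] - 1, m1 - 1) = 0.0;
          Iep(yrows[k] - 1, m1 - 1) = 0.0;
        }
      }
    }

    // --- forward ----------------------------------------------------------
    ForwardState fs;
    fs.Vo.resize(1); fs.Vf.resize(1);
    fs.Vo[0] = std::move(Iep); fs.Vf[0] = eye(m1, m1);
    fs.e0 = vectorise(Wep);
    forward_layers(layers, fs, oidx, fidx, true);

    const uword nh = hid_i.size();
    uvec pi0(ny + nh), pj0(ny + nh);
    for (uword k = 0; k < ny; ++k) { pi0[k] = yrows[k] - 1; pj0[k] = m1 - 1; }
    for (uword k = 0; k < nh; ++k) {
      pi0[ny + k] = hid_i[k];
      pj0[ny + k] = fcells(hid_k[k], 1) - 1;
    }
    mat Hin, Z1;
    vec pred = head_forward(H, fs.Vo.back(), fs.Vf.back(), pi0, pj0, Hin, Z1);

    double yloss = 0.0, floss = 0.0;
    vec gpred(ny + nh, fill::zeros);
    if (ny > 0) {
      vec gy;
      yloss = loss_and_grad(pred.subvec(0, ny - 1), ytarget, loss_kind, alpha,
                            signed_variant, gy);
      gpred.subvec(0, ny - 1) = gy;
    }
    if (nh > 0) {
      vec ft(nh);
      for (uword k = 0; k < nh; ++k) ft[k] = fvalues[hid_k[k]];
      vec gf;
      floss = loss_and_grad(pred.subvec(ny, ny + nh - 1), ft, loss_kind, alpha,
                            signed_variant, gf);
      double wf = (ny > 0) ? lambda : 1.0;
      gpred.subvec(ny, ny + nh - 1) = wf * gf;
      floss *= wf;
    }
    double total = yloss + floss;
    hist_total[ep] = total; hist_yield[ep] = yloss; hist_feat[ep] = floss;
    if (!std::isfinite(total)) {
      Rcpp::stop("training diverged: non-finite loss at epoch %d", ep + 1);
    }

    // --- backward + update ------------------------------------------------
    Grads G = zero_grads(layers, H);
    backward_all(layers, fs, H, oidx, fidx, Hin, Z1, pi0, pj0, gpred, G);

    std::vector<mat> gm;
    for (size_t l = 0; l < layers.size(); ++l) {
      gm.push_back(G.Wa[l]); gm.push_back(mat(G.ba[l]));
      gm.push_back(G.Wb[l]); gm.push_back(mat(G.bb[l]));
    }
    gm.push_back(G.W1); gm.push_back(mat(G.b1)); gm.push_back(mat(G.W2));
    gm.push_back(mat(1, 1, fill::value(G.b2)));
    opt.step(pptrs, gm, lr);
    sync_from_pm();

    ran = ep + 1;
    if (verbose && (ep % 50 == 0 || ep == epochs - 1)) {
      Rcpp::Rcout << "epoch " << ep + 1 << "  loss " << total
                  << "  (yield " << yloss << ", feat " << floss << ")\n";
    }
    if (total < best * (1.0 - tol)) { best = total; since_best = 0; }
    else if (++since_best >= patience && patience > 0) break;
    if (ep % 20 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("layers") = layers_to_list(layers),
    Rcpp::Named("head") = Rcpp::List::create(
      Rcpp::Named("W1") = H.W1, Rcpp::Named("b1") = H.b1,
      Rcpp::Named("W2") = H.W2, Rcpp::Named("b2") = H.b2),
    Rcpp::Named("history") = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = regspace<vec>(1, ran),
      Rcpp::Named("loss") = hist_total.head(ran),
      Rcpp::Named("yield_loss") = hist_yield.head(ran),
      Rcpp::Named("feature_loss") = hist_feat.head(ran)),
    Rcpp::Named("epochs_run") = ran);
}
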