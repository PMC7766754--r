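// Three-layer bidirectional GRU with a per-step fully connected head.
//
// The GRU cell follows the printed equations of the model this package
// implements: z = sigma(Wz [h, x] + bz), r = sigma(Wr [h, x] + br),
// h' = tanh(Wc [r*h, x] (+ bc)), h_new = (1 - z)*h + z*h'.
// Note the update-gate convention: z multiplies the CANDIDATE state
// (the framework-standard GRU has the roles of z and 1-z swapped).
// The candidate bias bc is optional (candidate_bias flag, default off).
//
// Everything here is batched over windows: a time slice is a d x B matrix.
// Gradients are hand-derived backpropagation-through-time; the training
// loop runs Adam entirely in C++ so R only prepares batches.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct GRUDir {
  mat Wz, Wr, Wc;  // d x (d+m)
  vec bz, br, bc;  // bc unused unless use_bc
  bool use_bc;
};

struct Net {
  int d;
  bool use_bc;
  std::vector<GRUDir> dirs;  // 6: layer-major, fwd then bwd
  vec fc_w;                  // 2d
  double fc_b;
};

GRUDir dir_from_list(const Rcpp::List& L, bool use_bc) {
  GRUDir g;
  g.Wz = Rcpp::as<mat>(L["Wz"]);
  g.Wr = Rcpp::as<mat>(L["Wr"]);
  g.Wc = Rcpp::as<mat>(L["Wc"]);
  g.bz = Rcpp::as<vec>(L["bz"]);
  g.br = Rcpp::as<vec>(L["br"]);
  g.use_bc = use_bc;
  if (use_bc) g.bc = Rcpp::as<vec>(L["bc"]);
  else g.bc = zeros<vec>(g.bz.n_elem);
  return g;
}

Net net_from_list(const Rcpp::List& net) {
  Net N;
  N.d = Rcpp::as<int>(net["hidden_size"]);
  N.use_bc = Rcpp::as<bool>(net["candidate_bias"]);
  Rcpp::List layers = net["layers"];
  for (int l = 0; l < 3; ++l) {
    Rcpp::List lay = layers[l];
    N.dirs.push_back(dir_from_list(lay["fwd"], N.use_bc));
    N.dirs.push_back(dir_from_list(lay["bwd"], N.use_bc));
  }
  N.fc_w = Rcpp::as<vec>(net["fc_weight"]);
  N.fc_b = Rcpp::as<double>(net["fc_bias"]);
  return N;
}

Rcpp::List dir_to_list(const GRUDir& g) {
  Rcpp::List L = Rcpp::List::create(
      Rcpp::Named("Wz") = g.Wz, Rcpp::Named("Wr") = g.Wr,
      Rcpp::Named("Wc") = g.Wc, Rcpp::Named("bz") = g.bz,
      Rcpp::Named("br") = g.br);
  if (g.use_bc) L["bc"] = g.bc;
  return L;
}

Rcpp::List net_to_list(const Net& N) {
  Rcpp::List layers(3);
  for (int l = 0; l < 3; ++l) {
    layers[l] = Rcpp::List::create(Rcpp::Named("fwd") = dir_to_list(N.dirs[2 * l]),
                                   Rcpp::Named("bwd") = dir_to_list(N.dirs[2 * l + 1]));
  }
  return Rcpp::List::create(
      Rcpp::Named("hidden_size") = N.d,
      Rcpp::Named("candidate_bias") = N.use_bc,
      Rcpp::Named("layers") = layers,
      Rcpp::Named("fc_weight") = N.fc_w,
      Rcpp::Named("fc_bias") = N.fc_b);
}

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// caches for one direction over one layer
struct DirCache {
  cube z, r, hc, h;  // each d x B x T
};

// X: m x B x T layer input; outputs/caches at true time index t.
// Weight matrices are split once per pass into their hidden and input
// blocks so the hot loop runs without per-step concatenation.
void dir_forward(const GRUDir& P, const cube& X, bool rev, DirCache& C) {
  const int d = P.bz.n_elem, B = X.n_cols, T = X.n_slices;
  const int m = X.n_rows;
  const mat Wzh = P.Wz.cols(0, d - 1), Wzx = P.Wz.cols(d, d + m - 1);
  const mat Wrh = P.Wr.cols(0, d - 1), Wrx = P.Wr.cols(d, d + m - 1);
  const mat Wch = P.Wc.cols(0, d - 1), Wcx = P.Wc.cols(d, d + m - 1);
  C.z.set_size(d, B, T); C.r.set_size(d, B, T);
  C.hc.set_size(d, B, T); C.h.set_size(d, B, T);
  mat h_prev(d, B, fill::zeros);
  for (int k = 0; k < T; ++k) {
    const int t = rev ? T - 1 - k : k;
    const mat& x = X.slice(t);
    mat az = Wzh * h_prev + Wzx * x; az.each_col() += P.bz;
    mat ar = Wrh * h_prev + Wrx * x; ar.each_col() += P.br;
    mat z = sigmoid(az), r = sigmoid(ar);
    mat pre = Wch * (r % h_prev) + Wcx * x;
    if (P.use_bc) pre.each_col() += P.bc;
    mat hc = tanh(pre);
    mat h = (1.0 - z) % h_prev + z % hc;
    C.z.slice(t) = z; C.r.slice(t) = r; C.hc.slice(t) = hc; C.h.slice(t) = h;
    h_prev = h;
  }
}

// dH: d x B x T gradient w.r.t. this direction's output states.
// Accumulates parameter grads into G and input grads into dX.
void dir_backward(const GRUDir& P, const cube& X, bool rev, const DirCache& C,
                  const cube& dH, GRUDir& G, cube& dX) {
  const int d = P.bz.n_elem, B = X.n_cols, T = X.n_slices;
  const int m = X.n_rows;
  const mat Wzh = P.Wz.cols(0, d - 1), Wzx = P.Wz.cols(d, d + m - 1);
  const mat Wrh = P.Wr.cols(0, d - 1), Wrx = P.Wr.cols(d, d + m - 1);
  const mat Wch = P.Wc.cols(0, d - 1), Wcx = P.Wc.cols(d, d + m - 1);
  mat gWzh(d, d, fill::zeros), gWzx(d, m, fill::zeros);
  mat gWrh(d, d, fill::zeros), gWrx(d, m, fill::zeros);
  mat gWch(d, d, fill::zeros), gWcx(d, m, fill::zeros);
  mat carry(d, B, fill::zeros);
  for (int k = T - 1; k >= 0; --k) {
    // reverse of processing order
    const int t = rev ? T - 1 - k : k;
    mat h_prev;
    if (k == 0) h_prev = zeros<mat>(d, B);
    else h_prev = C.h.slice(rev ? t + 1 : t - 1);
    const mat& z = C.z.slice(t);
    const mat& r = C.r.slice(t);
    const mat& hc = C.hc.slice(t);
    const mat& x = X.slice(t);
    mat dh = dH.slice(t) + carry;

    mat dz = dh % (hc - h_prev);
    mat dhc = dh % z;
    mat dh_prev = dh % (1.0 - z);

    mat da_c = dhc % (1.0 - hc % hc);
    gWch += da_c * (r % h_prev).t();
    gWcx += da_c * x.t();
    if (P.use_bc) G.bc += sum(da_c, 1);
    mat drhp = Wch.t() * da_c;
    mat dx = Wcx.t() * da_c;
    mat dr = drhp % h_prev;
    dh_prev += drhp % r;

    mat da_z = dz % z % (1.0 - z);
    mat da_r = dr % r % (1.0 - r);
    gWzh += da_z * h_prev.t(); gWzx += da_z * x.t();
    gWrh += da_r * h_prev.t(); gWrx += da_r * x.t();
    G.bz += sum(da_z, 1);
    G.br += sum(da_r, 1);
    dh_prev += Wzh.t() * da_z + Wrh.t() * da_r;
    dx += Wzx.t() * da_z + Wrx.t() * da_r;
    dX.slice(t) += dx;

    carry = dh_prev;
  }
  G.Wz += join_rows(gWzh, gWzx);
  G.Wr += join_rows(gWrh, gWrx);
  G.Wc += join_rows(gWch, gWcx);
}

struct FwdState {
  std::vector<cube> inputs;      // per layer: m x B x T
  std::vector<DirCache> caches;  // 6
  cube top;                      // 2d x B x T
  mat O;                         // T x B
};

void net_forward(const Net& N, const cube& X1, FwdState& S) {
  const int B = X1.n_cols, T = X1.n_slices, d = N.d;
  S.inputs.clear(); S.caches.assign(6, DirCache());
  cube A = X1;
  for (int l = 0; l < 3; ++l) {
    S.inputs.push_back(A);
    dir_forward(N.dirs[2 * l], A, false, S.caches[2 * l]);
    dir_forward(N.dirs[2 * l + 1], A, true, S.caches[2 * l + 1]);
    cube H(2 * d, B, T);
    for (int t = 0; t < T; ++t)
      H.slice(t) = join_cols(S.caches[2 * l].h.slice(t),
                             S.caches[2 * l + 1].h.slice(t));
    A = H;
  }
  S.top = A;
  S.O.set_size(T, B);
  for (int t = 0; t < T; ++t)
    S.O.row(t) = N.fc_w.t() * A.slice(t) + N.fc_b;
}

double safe_logcosh(double x) {
  const double ax = std::fabs(x);
  if (ax > 20.0) return ax - M_LN2;
  return std::log(std::cosh(x));
}

// dO: T x B gradient on the head output
void net_backward(const Net& N, const FwdState& S, const mat& dO,
                  Net& G) {
  const int B = S.O.n_cols, T = S.O.n_rows, d = N.d;
  cube dA(2 * d, B, T, fill::zeros);
  G.fc_b = 0.0;
  for (int t = 0; t < T; ++t) {
    rowvec g = dO.row(t);                    // 1 x B
    G.fc_w += S.top.slice(t) * g.t();        // 2d x 1
    G.fc_b += accu(g);
    dA.slice(t) = N.fc_w * g;                // 2d x B
  }
  for (int l = 2; l >= 0; --l) {
    const cube& A = S.inputs[l];
    cube dX(A.n_rows, B, T, fill::zeros);
    cube dHf(d, B, T), dHb(d, B, T);
    for (int t = 0; t < T; ++t) {
      dHf.slice(t) = dA.slice(t).rows(0, d - 1);
      dHb.slice(t) = dA.slice(t).rows(d, 2 * d - 1);
    }
    dir_backward(N.dirs[2 * l], A, false, S.caches[2 * l], dHf,
                 G.dirs[2 * l], dX);
    dir_backward(N.dirs[2 * l + 1], A, true, S.caches[2 * l + 1], dHb,
                 G.dirs[2 * l + 1], dX);
    if (l > 0) dA = dX;
  }
}

Net zero_like(const Net& N) {
  Net G = N;
  for (auto& g : G.dirs) {
    g.Wz.zeros(); g.Wr.zeros(); g.Wc.zeros();
    g.bz.zeros(); g.br.zeros(); g.bc.zeros();
  }
  G.fc_w.zeros();
  G.fc_b = 0.0;
  return G;
}

struct AdamState {
  Net m, v;
  int t = 0;
};

void adam_field(mat& p, mat& g, mat& m, mat& v, double lr, double b1,
                double b2, double eps, double c1, double c2) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  p -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

void adam_vec(vec& p, vec& g, vec& m, vec& v, double lr, double b1,
              double b2, double eps, double c1, double c2) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  p -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

void adam_update(Net& N, Net& G, AdamState& A, double lr, double b1,
                 double b2, double eps) {
  A.t += 1;
  const double c1 = 1.0 - std::pow(b1, A.t);
  const double c2 = 1.0 - std::pow(b2, A.t);
  for (size_t i = 0; i < N.dirs.size(); ++i) {
    adam_field(N.dirs[i].Wz, G.dirs[i].Wz, A.m.dirs[i].Wz, A.v.dirs[i].Wz, lr, b1, b2, eps, c1, c2);
    adam_field(N.dirs[i].Wr, G.dirs[i].Wr, A.m.dirs[i].Wr, A.v.dirs[i].Wr, lr, b1, b2, eps, c1, c2);
    adam_field(N.dirs[i].Wc, G.dirs[i].Wc, A.m.dirs[i].Wc, A.v.dirs[i].Wc, lr, b1, b2, eps, c1, c2);
    adam_vec(N.dirs[i].bz, G.dirs[i].bz, A.m.dirs[i].bz, A.v.dirs[i].bz, lr, b1, b2, eps, c1, c2);
    adam_vec(N.dirs[i].br, G.dirs[i].br, A.m.dirs[i].br, A.v.dirs[i].br, lr, b1, b2, eps, c1, c2);
    if (N.use_bc)
      adam_vec(N.dirs[i].bc, G.dirs[i].bc, A.m.dirs[i].bc, A.v.dirs[i].bc, lr, b1, b2, eps, c1, c2);
  }
  adam_vec(N.fc_w, G.fc_w, A.m.fc_w, A.v.fc_w, lr, b1, b2, eps, c1, c2);
  // scalar bias
  A.m.fc_b = b1 * A.m.fc_b + (1.0 - b1) * G.fc_b;
  A.v.fc_b = b2 * A.v.fc_b + (1.0 - b2) * G.fc_b * G.fc_b;
  N.fc_b -= lr * (A.m.fc_b / c1) / (std::sqrt(A.v.fc_b / c2) + eps);
}

cube cols_to_cube(const mat& M, const uvec& idx) {
  // M: T x N -> cube 1 x B x T
  const int T = M.n_rows, B = idx.n_elem;
  cube X(1, B, T);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t)
      X(0, b, t) = M(t, idx[b]);
  return X;
}

}  // namespace

// [[Rcpp::export]]
arma::vec cpp_network_forward(Rcpp::List net, const arma::vec& x) {
  Net N = net_from_list(net);
  const int T = x.n_elem;
  cube X(1, 1, T);
  for (int t = 0; t < T; ++t) X(0, 0, t) = x[t];
  FwdState S;
  net_forward(N, X, S);
  return S.O.col(0);
}

// mean log-cosh loss over masked positions and its gradients, for
// finite-difference checks and held-out evaluation
// [[Rcpp::export]]
Rcpp::List cpp_network_loss_grad(Rcpp::List net, const arma::mat& I,
                                 const arma::mat& R, const arma::mat& M,
                                 bool want_grad) {
  Net N = net_from_list(net);
  const int T = I.n_rows, B = I.n_cols;
  uvec idx = regspace<uvec>(0, B - 1);
  cube X = cols_to_cube(I, idx);
  FwdState S;
  net_forward(N, X, S);
  mat diff = S.O - R;
  const double nvalid = accu(M);
  double loss = 0.0;
  for (int j = 0; j < B; ++j)
    for (int t = 0; t < T; ++t)
      if (M(t, j) > 0) loss += safe_logcosh(diff(t, j));
  loss /= nvalid;
  if (!want_grad)
    return Rcpp::List::create(Rcpp::Named("loss") = loss);
  mat dO = tanh(diff) % M / nvalid;
  Net G = zero_like(N);
  net_backward(N, S, dO, G);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = net_to_list(G));
}

// Adam training loop. I, R, M are T x Nwin (windows in columns);
// batches is a list of 1-based column-index vectors, one per step.
// [[Rcpp::export]]
Rcpp::List cpp_train_bigru(Rcpp::List net, const arma::mat& I,
                           const arma::mat& R, const arma::mat& M,
                           Rcpp::List batches, double lr, double beta1,
                           double beta2, double eps) {
  Net N = net_from_list(net);
  AdamState A;
  A.m = zero_like(N);
  A.v = zero_like(N);
  A.m.fc_b = 0.0; A.v.fc_b = 0.0;
  const int steps = batches.size();
  vec losses(steps);
  for (int s = 0; s < steps; ++s) {
    uvec idx = Rcpp::as<uvec>(batches[s]) - 1;
    cube X = cols_to_cube(I, idx);
    mat Rb(I.n_rows, idx.n_elem), Mb(I.n_rows, idx.n_elem);
    for (uword b = 0; b < idx.n_elem; ++b) {
      Rb.col(b) = R.col(idx[b]);
      Mb.col(b) = M.col(idx[b]);
    }
    FwdState S;
    net_forward(N, X, S);
    mat diff = S.O - Rb;
    const double nvalid = accu(Mb);
    double loss = 0.0;
    const int T = I.n_rows, B = idx.n_elem;
    for (int j = 0; j < B; ++j)
      for (int t = 0; t < T; ++t)
        if (Mb(t, j) > 0) loss += safe_logcosh(diff(t, j));
    loss /= nvalid;
    losses[s] = loss;
    if (!std::isfinite(loss))
      Rcpp::stop("non-finite training loss at step %d; check the learning rate and the training pairs", s + 1);
    mat dO = tanh(diff) % Mb / nvalid;
    Net G = zero_like(N);
    net_backward(N, S, dO, G);
    adam_update(N, G, A, lr, beta1, beta2, eps);
    if (s % 20 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("net") = net_to_list(N),
                            Rcpp::Named("loss") = losses);
}
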