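// Compiled kernels for the message-passing network. The R implementation in
// gnn.R (.forward/.backward) is the readable reference; these kernels compute
// the identical quantities (asserted in the test suite) but hold all states
// transposed (features x items) so that edge gathers, atom scatters and
// batch-norm reductions run over contiguous columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BN_EPS = 1e-3;
static const double BN_MOMENTUM = 0.99;

struct BnCache {
  mat xhat;          // d x m
  vec istd, mu, va;  // d
};

// batch normalization over columns (features are rows)
static mat bn_forward(const mat& x, const vec& g, const vec& b,
                      const vec& rm, const vec& rv, bool training,
                      BnCache& cache) {
  vec mu, va;
  if (training && x.n_cols > 1) {
    mu = mean(x, 1);
    mat xc = x.each_col() - mu;
    va = mean(square(xc), 1);
  } else {
    mu = rm;
    va = rv;
  }
  vec istd = 1.0 / sqrt(va + BN_EPS);
  mat xhat = (x.each_col() - mu).each_col() % istd;
  cache.xhat = xhat;
  cache.istd = istd;
  cache.mu = mu;
  cache.va = va;
  return (xhat.each_col() % g).each_col() + b;
}

static mat bn_backward(const mat& dy, const BnCache& cache, const vec& g,
                       vec& dg, vec& db) {
  double m = (double)dy.n_cols;
  mat dxhat = dy.each_col() % g;
  vec s1 = sum(dxhat, 1);
  vec s2 = sum(dxhat % cache.xhat, 1);
  dg = sum(dy % cache.xhat, 1);
  db = sum(dy, 1);
  mat dx = m * dxhat;
  dx.each_col() -= s1;
  dx -= cache.xhat.each_col() % s2;
  dx.each_col() %= (cache.istd / m);
  return dx;
}

// sum columns of x grouped by idx (0-based) into an n-column matrix
static mat scatter_cols(const mat& x, const uvec& idx, unsigned int n) {
  mat out(x.n_rows, n, fill::zeros);
  for (unsigned int e = 0; e < idx.n_elem; ++e) out.col(idx(e)) += x.col(e);
  return out;
}

static mat relu(const mat& x) { return x % (x > 0); }

// One training batch: forward with batch statistics, masked per-edge MAE,
// full backward. Returns loss, gradients (mirroring the parameter list) and
// updated running statistics.
// [[Rcpp::export(name = ".gnn_batch_cpp")]]
Rcpp::List gnn_batch_cpp(const Rcpp::List& params, const Rcpp::List& bn,
                         const arma::uvec& atom_ids, const arma::uvec& edge_ids,
                         const arma::uvec& src, const arma::uvec& dst,
                         const arma::vec& cm_edge, const arma::vec& y_edge,
                         const arma::uvec& mask, bool training) {
  mat EAt = trans(Rcpp::as<mat>(params["EA"]));
  mat EBt = trans(Rcpp::as<mat>(params["EB"]));
  vec head_w = params["head_w"];
  double head_b = Rcpp::as<double>(params["head_b"]);
  Rcpp::List blocks = params["blocks"];
  int K = blocks.size();
  unsigned int N = atom_ids.n_elem, E = edge_ids.n_elem;
  int d = EAt.n_rows;

  mat A = EAt.cols(atom_ids);  // d x N; ids carry the +1 offset, 0-based
  mat B = EBt.cols(edge_ids);  // d x E

  std::vector<BnCache> cA(K), cB(K);
  std::vector<mat> Hpre_v(K), Ppre_v(K), Bnew_v(K), Any_v(K), Bny_v(K);
  std::vector<mat> W1t(K), W2t(K), W3t(K), Wa_v(K);
  Rcpp::List bn_out(K);

  for (int k = 0; k < K; ++k) {
    Rcpp::List blk = blocks[k];
    vec gA = blk["gA"], bA = blk["bA"], gB = blk["gB"], bB = blk["bB"];
    mat Wb = blk["Wb"], Wa = blk["Wa"];
    vec bb = blk["bb"], ba = blk["ba"];
    Rcpp::List st = bn[k];
    vec rmA = st["rmA"], rvA = st["rvA"], rmB = st["rmB"], rvB = st["rvB"];
    W1t[k] = trans(Wb.rows(0, d - 1));
    W2t[k] = trans(Wb.rows(d, 2 * d - 1));
    W3t[k] = trans(Wb.rows(2 * d, 3 * d - 1));
    Wa_v[k] = Wa;

    mat Any = bn_forward(A, gA, bA, rmA, rvA, training, cA[k]);
    mat Bny = bn_forward(B, gB, bB, rmB, rvB, training, cB[k]);
    if (training && N > 1) {
      rmA = BN_MOMENTUM * rmA + (1 - BN_MOMENTUM) * cA[k].mu;
      rvA = BN_MOMENTUM * rvA + (1 - BN_MOMENTUM) * cA[k].va;
      rmB = BN_MOMENTUM * rmB + (1 - BN_MOMENTUM) * cB[k].mu;
      rvB = BN_MOMENTUM * rvB + (1 - BN_MOMENTUM) * cB[k].va;
    }
    bn_out[k] = Rcpp::List::create(
        Rcpp::Named("rmA") = rmA, Rcpp::Named("rvA") = rvA,
        Rcpp::Named("rmB") = rmB, Rcpp::Named("rvB") = rvB);

    mat AW1 = W1t[k] * Any;
    mat AW2 = W2t[k] * Any;
    mat Hpre = AW1.cols(src) + AW2.cols(dst) + W3t[k] * Bny;
    Hpre.each_col() += bb;
    mat B_new = B + relu(Hpre);
    mat Ppre = Wa_v[k].t() * B_new;
    Ppre.each_col() += ba;
    A = A + scatter_cols(relu(Ppre), dst, N);
    Any_v[k] = std::move(Any); Bny_v[k] = std::move(Bny);
    Hpre_v[k] = std::move(Hpre); Ppre_v[k] = std::move(Ppre);
    Bnew_v[k] = B_new;
    B = std::move(B_new);
  }

  vec s_edge = B.t() * head_w + head_b + cm_edge;
  if (!s_edge.is_finite()) Rcpp::stop("non-finite activation in forward pass");

  uvec mi = find(mask == 1);
  double nm = (double)mi.n_elem;
  vec diff = s_edge.elem(mi) - y_edge.elem(mi);
  double loss = mean(abs(diff));
  vec ds(E, fill::zeros);
  ds.elem(mi) = sign(diff) / nm;

  Rcpp::List gblocks(K);
  vec ghead_w = B * ds;
  double ghead_b = accu(ds);
  mat dB = head_w * ds.t();  // d x E
  mat dA(d, N, fill::zeros);
  for (int k = K - 1; k >= 0; --k) {
    Rcpp::List blk = blocks[k];
    vec gA = blk["gA"], gB = blk["gB"];
    mat dPpre = dA.cols(dst) % (Ppre_v[k] > 0);
    mat dWa = Bnew_v[k] * dPpre.t();
    vec dba = sum(dPpre, 1);
    mat dB_out = dB + Wa_v[k] * dPpre;
    mat dHpre = dB_out % (Hpre_v[k] > 0);
    mat S1 = scatter_cols(dHpre, src, N);
    mat S2 = scatter_cols(dHpre, dst, N);
    mat dWb = join_cols(Any_v[k] * S1.t(), Any_v[k] * S2.t(),
                        Bny_v[k] * dHpre.t());
    vec dbb = sum(dHpre, 1);
    mat dAn = W1t[k].t() * S1 + W2t[k].t() * S2;
    mat dBn = W3t[k].t() * dHpre;
    vec dgA, dbA, dgB, dbB;
    mat dxA = bn_backward(dAn, cA[k], gA, dgA, dbA);
    mat dxB = bn_backward(dBn, cB[k], gB, dgB, dbB);
    dA += dxA;            // dA already holds dA_in (residual)
    dB = dB_out + dxB;
    gblocks[k] = Rcpp::List::create(
        Rcpp::Named("gA") = dgA, Rcpp::Named("bA") = dbA,
        Rcpp::Named("gB") = dgB, Rcpp::Named("bB") = dbB,
        Rcpp::Named("Wb") = dWb, Rcpp::Named("bb") = dbb,
        Rcpp::Named("Wa") = dWa, Rcpp::Named("ba") = dba);
  }
  mat gEA = scatter_cols(dA, atom_ids, EAt.n_cols);
  mat gEB = scatter_cols(dB, edge_ids, EBt.n_cols);

  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("EA") = trans(gEA), Rcpp::Named("EB") = trans(gEB),
          Rcpp::Named("blocks") = gblocks,
          Rcpp::Named("head_w") = ghead_w, Rcpp::Named("head_b") = ghead_b),
      Rcpp::Named("bn") = bn_out);
}

// Inference forward: running statistics, per-edge scalars and final edge
// states (returned edges x d).
// [[Rcpp::export(name = ".gnn_infer_cpp")]]
Rcpp::List gnn_infer_cpp(const Rcpp::List& params, const Rcpp::List& bn,
                         const arma::uvec& atom_ids, const arma::uvec& edge_ids,
                         const arma::uvec& src, const arma::uvec& dst,
                         const arma::vec& cm_edge) {
  mat EAt = trans(Rcpp::as<mat>(params["EA"]));
  mat EBt = trans(Rcpp::as<mat>(params["EB"]));
  vec head_w = params["head_w"];
  double head_b = Rcpp::as<double>(params["head_b"]);
  Rcpp::List blocks = params["blocks"];
  int K = blocks.size();
  unsigned int N = atom_ids.n_elem;
  int d = EAt.n_rows;

  mat A = EAt.cols(atom_ids);
  mat B = EBt.cols(edge_ids);
  BnCache tmpA, tmpB;
  for (int k = 0; k < K; ++k) {
    Rcpp::List blk = blocks[k];
    vec gA = blk["gA"], bA = blk["bA"], gB = blk["gB"], bB = blk["bB"];
    mat Wb = blk["Wb"], Wa = blk["Wa"];
    vec bb = blk["bb"], ba = blk["ba"];
    Rcpp::List st = bn[k];
    vec rmA = st["rmA"], rvA = st["rvA"], rmB = st["rmB"], rvB = st["rvB"];
    mat Any = bn_forward(A, gA, bA, rmA, rvA, false, tmpA);
    mat Bny = bn_forward(B, gB, bB, rmB, rvB, false, tmpB);
    mat AW1 = trans(Wb.rows(0, d - 1)) * Any;
    mat AW2 = trans(Wb.rows(d, 2 * d - 1)) * Any;
    mat Hpre = AW1.cols(src) + AW2.cols(dst) +
               trans(Wb.rows(2 * d, 3 * d - 1)) * Bny;
    Hpre.each_col() += bb;
    mat B_new = B + relu(Hpre);
    mat Ppre = Wa.t() * B_new;
    Ppre.each_col() += ba;
    A = A + scatter_cols(relu(Ppre), dst, N);
    B = std::move(B_new);
  }
  vec s_edge = B.t() * head_w + head_b + cm_edge;
  if (!s_edge.is_finite()) Rcpp::stop("non-finite activation in forward pass");
  return Rcpp::List::create(Rcpp::Named("s_edge") = s_edge,
                            Rcpp::Named("B_final") = trans(B));
}
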