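// Pruning log-likelihood for reversible codon models.
//
// The generator is symmetrized with the stationary distribution and
// diagonalized once per call; per-edge transition operators are applied in
// the eigenbasis, so each edge costs two small dense matrix products (one
// for tip edges, whose partials are indicator columns). Per-node column
// rescaling guards against underflow on deep trees.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct EigenQ {
  vec lam;
  mat A;     // diag(1/sqrt(pi)) U
  mat B;     // U' diag(sqrt(pi))
  vec Brow1; // B * 1 (missing-data tip message)
  bool ok;
};

EigenQ decompose(const mat& Q, const vec& pi) {
  EigenQ eq;
  const int n = Q.n_rows;
  vec sq = sqrt(pi);
  mat S = Q;
  for (int j = 0; j < n; j++)
    for (int i = 0; i < n; i++)
      S(i, j) *= sq(i) / sq(j);
  S = 0.5 * (S + S.t());
  mat U;
  eq.ok = eig_sym(eq.lam, U, S, "dc");
  if (!eq.ok) return eq;
  eq.A = U;
  eq.A.each_col() /= sq;
  eq.B = U.t();
  eq.B.each_row() %= sq.t();
  eq.Brow1 = eq.B * ones<vec>(n);
  return eq;
}

// B applied to a tip's indicator partials
void tip_message(const EigenQ& eq, const imat& tipdata, int trow, mat& out) {
  const int P = tipdata.n_cols;
  for (int j = 0; j < P; j++) {
    int s = tipdata(trow, j);
    if (s > 0)
      out.col(j) = eq.B.col(s - 1);
    else
      out.col(j) = eq.Brow1;
  }
}

// Raw indicator partials of a tip (identity transition).
void tip_raw(int n, const imat& tipdata, int trow, mat& out) {
  const int P = tipdata.n_cols;
  out.zeros();
  for (int j = 0; j < P; j++) {
    int s = tipdata(trow, j);
    if (s > 0)
      out(s - 1, j) = 1.0;
    else
      out.col(j).ones();
  }
}

// Transition message across one edge: exp(Q t) applied to the child's raw
// partials; a zero-length edge is an exact identity.
void cross_edge(const EigenQ& eq, double t, const imat& tipdata,
                int child, int ntip, const std::vector<mat>& part,
                const std::vector<rowvec>& lsc, mat& out, rowvec& out_ls) {
  const int n = eq.A.n_rows;
  const int P = tipdata.n_cols;
  if (t <= 0.0) {
    if (child <= ntip) {
      out.set_size(n, P);
      tip_raw(n, tipdata, child - 1, out);
      out_ls = zeros<rowvec>(P);
    } else {
      out = part[child - ntip - 1];
      out_ls = lsc[child - ntip - 1];
    }
    return;
  }
  mat tmp(n, P);
  if (child <= ntip) {
    tip_message(eq, tipdata, child - 1, tmp);
    out_ls = zeros<rowvec>(P);
  } else {
    tmp = eq.B * part[child - ntip - 1];
    out_ls = lsc[child - ntip - 1];
  }
  vec eet = exp(eq.lam * t);
  tmp.each_col() %= eet;
  out = eq.A * tmp;
  out.clamp(0.0, datum::inf);
}

// Down-pass (postorder) partials for all internal nodes, with per-pattern
// log scaling. part[k], lsc[k] indexed by internal node id - ntip - 1.
bool down_partials(const EigenQ& eq, const imat& edge, const vec& len,
                   const imat& tipdata, int nnode,
                   std::vector<mat>& part, std::vector<rowvec>& lsc) {
  const int P = tipdata.n_cols;
  const int ntip = tipdata.n_rows;
  const int E = edge.n_rows;
  part.assign(nnode, mat());
  lsc.assign(nnode, rowvec());
  std::vector<bool> init(nnode, false);
  for (int e = 0; e < E; e++) {
    int parent = edge(e, 0) - ntip - 1;
    int child = edge(e, 1);
    rowvec child_ls;
    mat contrib;
    cross_edge(eq, len(e), tipdata, child, ntip, part, lsc, contrib,
               child_ls);
    if (!init[parent]) {
      part[parent] = contrib;
      lsc[parent] = child_ls;
      init[parent] = true;
    } else {
      part[parent] %= contrib;
      lsc[parent] += child_ls;
      rowvec mx = max(part[parent], 0);
      for (int j = 0; j < P; j++) {
        double m = mx(j);
        if (m > 0 && (m < 1e-200 || m > 1e200)) {
          part[parent].col(j) /= m;
          lsc[parent](j) += std::log(m);
        }
      }
    }
  }
  return true;
}

// P_e applied to the down message of child `child` of edge e.
void edge_down_message(const EigenQ& eq, const imat& edge, const vec& len,
                       const imat& tipdata,
                       const std::vector<mat>& part,
                       const std::vector<rowvec>& lsc, int e,
                       mat& out, rowvec& out_ls) {
  cross_edge(eq, len(e), tipdata, edge(e, 1), tipdata.n_rows, part, lsc,
             out, out_ls);
}

}  // namespace

// edge: E x 2 (parent, child), 1-based ape node ids, postorder.
// tipdata: ntip x P, 1-based state index, 0 = missing.
// [[Rcpp::export(name = ".cpp_pruning_loglik")]]
double cpp_pruning_loglik(const arma::mat& Q,
                          const arma::vec& pi,
                          const arma::imat& edge,
                          const arma::vec& len,
                          const arma::imat& tipdata,
                          const arma::vec& wt,
                          int nnode) {
  const int P = tipdata.n_cols;
  EigenQ eq = decompose(Q, pi);
  if (!eq.ok) return R_NegInf;
  std::vector<mat> part;
  std::vector<rowvec> lsc;
  down_partials(eq, edge, len, tipdata, nnode, part, lsc);

  // root is the first internal node (ape convention: ntip + 1)
  const mat& Lr = part[0];
  const rowvec& lsr = lsc[0];
  double ll = 0.0;
  for (int j = 0; j < P; j++) {
    double sp = dot(pi, Lr.col(j));
    if (sp <= 0.0 || !std::isfinite(sp)) return R_NegInf;
    ll += wt(j) * (std::log(sp) + lsr(j));
  }
  return ll;
}

// Branch-length profile for one edge: returns F (n x P), G (n x P), lam,
// and ls (P) such that the site likelihood at branch length t is
// sum_k F(k,j) * exp(lam_k * t) * G(k,j), times exp(ls_j).
// target is the 0-based row of `edge`.
// [[Rcpp::export(name = ".cpp_branch_profile")]]
Rcpp::List cpp_branch_profile(const arma::mat& Q,
                              const arma::vec& pi,
                              const arma::imat& edge,
                              const arma::vec& len,
                              const arma::imat& tipdata,
                              int nnode, int target) {
  const int n = Q.n_rows;
  const int P = tipdata.n_cols;
  const int ntip = tipdata.n_rows;
  const int E = edge.n_rows;
  EigenQ eq = decompose(Q, pi);
  if (!eq.ok) Rcpp::stop("eigendecomposition failed");
  std::vector<mat> part;
  std::vector<rowvec> lsc;
  down_partials(eq, edge, len, tipdata, nnode, part, lsc);

  // parent pointers (by edge row) and root-to-target-parent path
  std::vector<int> parent_edge(ntip + nnode + 1, -1);
  for (int e = 0; e < E; e++) parent_edge[edge(e, 1)] = e;
  int u = edge(target, 0);
  std::vector<int> path;  // edges from u up to the root
  for (int node = u; parent_edge[node] >= 0; node = edge(parent_edge[node], 0))
    path.push_back(parent_edge[node]);

  // up message at the root: the stationary prior, flat over patterns
  mat up(n, P);
  up.each_col() = pi;
  rowvec up_ls = zeros<rowvec>(P);

  // walk down the path, at each step absorbing sibling messages
  for (int k = (int)path.size() - 1; k >= 0; k--) {
    int e = path[k];
    int node = edge(e, 0);  // current node whose child we descend into
    mat prod = up;
    rowvec prod_ls = up_ls;
    for (int e2 = 0; e2 < E; e2++) {
      if (edge(e2, 0) != node || e2 == e) continue;
      mat msg;
      rowvec msg_ls;
      edge_down_message(eq, edge, len, tipdata, part, lsc, e2, msg, msg_ls);
      prod %= msg;
      prod_ls += msg_ls;
    }
    // cross edge e downward: up(child) = P_e^T prod (identity at t = 0)
    if (len(e) <= 0.0) {
      up = prod;
    } else {
      mat tmp = eq.A.t() * prod;
      vec eet = exp(eq.lam * len(e));
      tmp.each_col() %= eet;
      up = eq.B.t() * tmp;
      up.clamp(0.0, datum::inf);
    }
    up_ls = prod_ls;
    rowvec mx = max(up, 0);
    for (int j = 0; j < P; j++) {
      double m = mx(j);
      if (m > 0 && (m < 1e-200 || m > 1e200)) {
        up.col(j) /= m;
        up_ls(j) += std::log(m);
      }
    }
  }

  // combine with the target's sibling messages at node u
  mat f = up;
  rowvec f_ls = up_ls;
  for (int e2 = 0; e2 < E; e2++) {
    if (edge(e2, 0) != u || e2 == target) continue;
    mat msg;
    rowvec msg_ls;
    edge_down_message(eq, edge, len, tipdata, part, lsc, e2, msg, msg_ls);
    f %= msg;
    f_ls += msg_ls;
  }

  // child-side message of the target edge (before applying P_target)
  mat G(n, P);
  rowvec g_ls;
  int child = edge(target, 1);
  if (child <= ntip) {
    tip_message(eq, tipdata, child - 1, G);
    g_ls = zeros<rowvec>(P);
  } else {
    G = eq.B * part[child - ntip - 1];
    g_ls = lsc[child - ntip - 1];
  }
  mat F = eq.A.t() * f;
  return Rcpp::List::create(Rcpp::_["F"] = F, Rcpp::_["G"] = G,
                            Rcpp::_["lam"] = eq.lam,
                            Rcpp::_["ls"] = f_ls + g_ls);
}
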